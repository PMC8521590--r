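# Most scenario checks run on a reduced marker count; the preset-scale scenario
# is exercised in the acceptance suite.
small_params <- function(seed = 1, ...) {
  scenario_params(n_markers = 60, seed = seed, ...)
}

test_that("the simulated ancestor distributes markers deterministically", {
  p <- scenario_params(n_markers = 6, n_chromosomes_ancestor = 6, seed = 2)
  set.seed(2); a <- simulate_ancestor(p)
  expect_equal(n_chromosomes(a), 6)
  expect_equal(lengths(a$chromosomes), rep(1L, 6))
  p2 <- scenario_params(n_markers = 200, seed = 9)
  set.seed(9); g1 <- simulate_ancestor(p2)
  set.seed(9); g2 <- simulate_ancestor(p2)
  expect_identical(g1$chromosomes, g2$chromosomes)
  expect_equal(n_marker_copies(g1), 200)
  expect_error(scenario_params(n_markers = 3, n_chromosomes_ancestor = 6),
               "n_markers")
})

test_that("whole-genome duplication doubles chromosomes, adjacencies and copies", {
  set.seed(4)
  g <- simulate_ancestor(small_params())
  d <- apply_wgd(g)
  expect_equal(n_chromosomes(d), 2 * n_chromosomes(g))
  expect_equal(length(adjacency_set(d)), 2 * length(adjacency_set(g)))
  d2 <- apply_wgd(d)
  mult <- table(key_marker(genome_markers(d2)))
  expect_true(all(mult == 4))  # two rounds give the 4-copy tier of 1:2:4
  ## the duplicate is SCJ-identical to a doubling of the same genome
  expect_equal(scj_distance(d, apply_wgd(g)), 0)
})

test_that("branch evolution respects bookkeeping and the loss healing rule", {
  set.seed(6)
  g <- simulate_ancestor(small_params())
  same <- evolve_branch(g, c(fission = 0, fusion = 0, translocation = 0))
  expect_true(genomes_equal(same$genome, g))
  ev <- evolve_branch(g, c(fission = 3, fusion = 1, translocation = 0))
  expect_equal(n_chromosomes(ev$genome), n_chromosomes(g) + 2)
  tr <- evolve_branch(g, c(fission = 0, fusion = 0, translocation = 4))
  expect_equal(n_chromosomes(tr$genome), n_chromosomes(g))
  expect_equal(sort(genome_markers(tr$genome)), sort(genome_markers(g)))
  ## healing: internal loss joins the freed flanks
  toy <- genome(list(c("+a.0", "+b.0", "+c.0")))
  healed <- delete_marker_copy(toy, "b.0")
  expect_equal(adjacency_set(healed), "a.0:h|c.0:t")
  expect_equal(n_chromosomes(healed), 1)
})

test_that("the three-species scenario yields 1:2:4 copies and correct karyotypes", {
  tr <- simulate_three_species_scenario(small_params(seed = 3))
  expect_equal(n_chromosomes(tr$ancestor_preWGD1), 6)
  expect_equal(n_chromosomes(tr$genome_R), 7)        # 6 + 5 - 4
  expect_equal(n_chromosomes(tr$ancestor_postWGD1), 11)  # 12 + 11 - 12
  expect_equal(n_chromosomes(tr$genome_S), 22)       # 22 + 20 - 20
  counts <- list(R = tr$genome_R, P = tr$genome_P, S = tr$genome_S)
  want <- c(R = 1, P = 2, S = 4)
  for (gn in names(counts)) {
    mult <- table(key_marker(genome_markers(counts[[gn]])))
    expect_true(all(mult == want[[gn]]), info = gn)
  }
  ## zero-event scenario: extant genomes equal their ancestors (up to labels)
  p0 <- scenario_params(n_markers = 40, seed = 5, events_per_branch = list(
    R = 0L, stem = 0L, P = 0L, S_pre = 0L, S_post = 0L))
  tr0 <- simulate_three_species_scenario(p0)
  expect_true(genomes_equal(tr0$genome_R, tr0$ancestor_preWGD1))
  expect_true(genomes_equal(tr0$genome_P, tr0$ancestor_postWGD1))
  expect_equal(scj_distance(tr0$genome_S, apply_wgd(tr0$ancestor_preWGD2)), 0)
})

test_that("replaying the event log reproduces every simulated genome exactly", {
  tr <- simulate_three_species_scenario(small_params(seed = 7))
  branch_log <- function(b) tr$event_log[tr$event_log$branch == b, , drop = FALSE]
  gR <- replay_events(tr$ancestor_preWGD1, branch_log("R"))
  expect_true(genomes_equal(gR, tr$genome_R))
  gP <- replay_events(tr$ancestor_postWGD1, branch_log("P"))
  expect_true(genomes_equal(gP, tr$genome_P))
  stem <- replay_events(apply_wgd(tr$ancestor_preWGD1), branch_log("stem"))
  expect_true(genomes_equal(stem, tr$ancestor_postWGD1))
  gS <- replay_events(apply_wgd(tr$ancestor_preWGD2), branch_log("S_post"))
  expect_true(genomes_equal(gS, tr$genome_S))
})

test_that("the scenario is fully deterministic under a fixed seed", {
  t1 <- simulate_three_species_scenario(small_params(seed = 12))
  t2 <- simulate_three_species_scenario(small_params(seed = 12))
  expect_identical(t1$genome_S$chromosomes, t2$genome_S$chromosomes)
  expect_identical(t1$event_log, t2$event_log)
  t3 <- simulate_three_species_scenario(small_params(seed = 13))
  expect_false(identical(t1$genome_S$chromosomes, t3$genome_S$chromosomes))
})

test_that("losses keep bookkeeping consistent and reduce copy counts", {
  p <- scenario_params(n_markers = 80, seed = 21, loss_rate = 0.05)
  tr <- simulate_three_species_scenario(p)
  expect_equal(n_chromosomes(tr$genome_R), 7)
  mult <- table(key_marker(genome_markers(tr$genome_S)))
  expect_true(all(mult <= 4) && any(mult < 4))
  expect_true(any(tr$event_log$kind == "loss"))
})

test_that("emitted ortholog tables connect marker copies with configurable noise", {
  tr <- simulate_three_species_scenario(small_params(seed = 4))
  clean <- suppressMessages(emit_ortholog_table(tr, c(missing = 0, spurious = 0)))
  ## each marker yields one clique over its 7 copies: choose(7, 2) edges
  expect_equal(nrow(clean), 60 * choose(7, 2))
  g <- igraph::graph_from_data_frame(clean[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  expect_equal(comp$no, 60)
  expect_true(all(comp$csize == 7))
  none <- suppressMessages(emit_ortholog_table(tr, c(missing = 1, spurious = 0)))
  expect_equal(nrow(none), 0)
  noisy <- suppressMessages(emit_ortholog_table(tr, c(missing = 0.2,
                                                      spurious = 0.05)))
  expect_lt(nrow(noisy[noisy$bitscore > 0, ]), nrow(clean) * 1.05)
})

test_that("Ks samples follow the requested mixture and TPM matrices are non-negative", {
  comp <- data.frame(weight = 1, mean = 0.12, sd = 0.02)
  ks <- emit_ks_samples(comp, n = 2000, seed = 42)
  expect_true(all(ks$ks >= 0))
  ## CLT bound: sample mean within 3 sd/sqrt(n) of the component mean
  expect_lt(abs(mean(ks$ks) - 0.12), 3 * 0.02 / sqrt(2000))
  tr <- simulate_three_species_scenario(small_params(seed = 2))
  tpm <- emit_tpm_matrix(tr, seed = 1)
  expect_setequal(names(tpm), c("P", "R", "S"))
  expect_true(all(vapply(tpm, function(m) all(m >= 0), logical(1))))
  expect_equal(ncol(tpm$R), 6)
})
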