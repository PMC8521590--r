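test_that("the SCJ median is the majority adjacency set", {
  g1 <- genome(list(c("+a.0", "+b.0", "+c.0")))
  g3 <- genome(list(c("+a.0", "-b.0", "+c.0")))
  same <- scj_median(g1, g1, g1)
  expect_true(genomes_equal(same$genome, g1))
  expect_equal(same$total_distance, 0)
  maj <- scj_median(g1, g1, g3)
  expect_true(genomes_equal(maj$genome, g1))
  expect_equal(maj$total_distance, scj_distance(g1, g3))
  expect_error(scj_median(g1, g1, genome(list("+z.0"))), "mismatch")
})

test_that("the majority median attains the brute-force optimum on random instances", {
  ## exhaustive oracle over every linear genome on 4 markers, 60 random trials
  ## (the acceptance suite runs the larger 5-marker/200-trial version)
  M <- enumerate_genomes(paste0("m", 1:4))
  set.seed(19)
  keys <- paste0("m", 1:4, ".0")
  for (i in 1:60) {
    g1 <- random_genome(keys); g2 <- random_genome(keys)
    g3 <- random_genome(keys)
    med <- scj_median(g1, g2, g3)
    expect_equal(med$total_distance, brute_median_total(M, g1, g2, g3))
  }
})

test_that("guided halving recovers a clean doubling and matches brute force", {
  guide <- genome(list(c("+x.0", "+y.0"), "+z.0"), name = "guide")
  h <- guided_halving(apply_wgd(guide), guide)
  expect_true(genomes_equal(h$ancestor, guide))
  expect_equal(h$total_distance, 0)
  ## random doubled genomes with up to 4 markers against the enumeration +
  ## 2^n pairing oracle
  M <- enumerate_genomes(paste0("m", 1:3))
  set.seed(23)
  for (i in 1:25) {
    guide_r <- random_genome(paste0("m", 1:3, ".0"))
    dkeys <- c(paste0("m", 1:3, ".0"), paste0("m", 1:3, ".1"))
    doubled <- random_genome(dkeys)
    h <- guided_halving(doubled, guide_r)
    expect_equal(h$matching$method, "exhaustive")
    expect_equal(h$total_distance, brute_halving_total(M, doubled, guide_r))
  }
})

test_that("copy matching against a 2-copy guide finds the exhaustive optimum", {
  ## 2 markers with 4 copies each against a 2-copy guide: the engine must
  ## agree with its own exhaustive search run from a cold start
  guide <- genome(list(c("+a.0", "+b.0"), c("+a.1", "-b.1")), name = "g2")
  doubled <- genome(list(c("+a.0", "+b.0"), c("+a.1", "+b.1"),
                         c("+a.2", "-b.2"), c("+a.3", "-b.3")))
  ms <- match_copies(doubled, guide)
  expect_equal(ms$method, "exhaustive")
  ## perfect agreement is achievable: both guide chromosomes appear twice
  expect_equal(ms$cost, 0)
  ## cost is reproducible from the assignment itself
  expect_equal(nrow(ms$assignment), 8)
  expect_true(all(table(ms$assignment$marker, ms$assignment$p) == 2))
})

test_that("relabelling against an anchor minimizes SCJ distance per-marker", {
  anchor <- genome(list(c("+x.0", "+y.0"), c("+x.1", "+z.0")))
  g <- genome(list(c("+x.1", "+y.0"), c("+x.0", "+z.0")))
  rl <- relabel_against(g, anchor)
  expect_equal(rl$distance, 0)
  expect_true(genomes_equal(rl$genome, canonical_genome(anchor)))
  expect_error(relabel_against(g, genome(list("+q.0"))), "mismatch")
})

test_that("majority adjacency sets are conflict-free on random halving instances", {
  set.seed(31)
  for (i in 1:20) {
    guide <- random_genome(paste0("m", 1:5, ".0"))
    doubled <- random_genome(c(paste0("m", 1:5, ".0"), paste0("m", 1:5, ".1")))
    h <- guided_halving(doubled, guide)   # errors internally on conflicts
    expect_s3_class(h$ancestor, "scj_genome")
    expect_true(all(table(key_marker(genome_markers(h$ancestor))) == 1))
  }
})

test_that("gene orders within blocks follow the greedy weighted topological sort", {
  mkpaint <- function(chroms_by_genome) {
    genomes <- lapply(chroms_by_genome, genome)
    structure(list(genomes = genomes,
                   core_ppgs = unique(key_marker(token_key(
                     unlist(lapply(genomes, function(g)
                       unlist(g$chromosomes)))))),
                   gene_of = list()), class = "painted_genomes")
  }
  ## all copies agree
  pa <- mkpaint(list(A = list(c("+p1.0", "+p2.0", "+p3.0")),
                     B = list(c("+p1.0", "+p2.0", "+p3.0"))))
  block <- list(block_id = "B1", ppg_order = c("+p1", "+p2", "+p3"),
                copies = data.frame(genome = c("A", "B"), chromosome = 1,
                                    start_index = 1, end_index = 3,
                                    sign = "+", copy_label = 0))
  expect_equal(order_genes_in_block(block, pa), c("+p1", "+p2", "+p3"))
  ## two copies [1,2,3] vs one [1,3,2]: weights 1->2:2, 2->3:2, 1->3:1,
  ## 3->2:1; greedy order keeps [1,2,3]
  pa2 <- mkpaint(list(A = list(c("+p1.0", "+p2.0", "+p3.0")),
                      B = list(c("+p1.0", "+p2.0", "+p3.0")),
                      C = list(c("+p1.0", "+p3.0", "+p2.0"))))
  block2 <- list(block_id = "B1", ppg_order = c("+p1", "+p2", "+p3"),
                 copies = data.frame(genome = c("A", "B", "C"), chromosome = 1,
                                     start_index = 1, end_index = 3,
                                     sign = "+", copy_label = 0))
  expect_equal(order_genes_in_block(block2, pa2), c("+p1", "+p2", "+p3"))
  ## a 2-cycle from conflicting copies resolves deterministically
  pa3 <- mkpaint(list(A = list(c("+p1.0", "+p2.0")),
                      B = list(c("+p2.0", "+p1.0"))))
  block3 <- list(block_id = "B1", ppg_order = c("+p1", "+p2"),
                 copies = data.frame(genome = c("A", "B"), chromosome = 1,
                                     start_index = 1, end_index = 2,
                                     sign = "+", copy_label = 0))
  o1 <- order_genes_in_block(block3, pa3)
  o2 <- order_genes_in_block(block3, pa3)
  expect_identical(o1, o2)
  expect_setequal(substring(o1, 2), c("p1", "p2"))
  expect_error(order_genes_in_block(list(block_id = "B", ppg_order = "+p1",
                                         copies = NULL), pa3), "empty")
})

test_that("the bottom-up pipeline reconstructs a zero-event scenario exactly", {
  p0 <- scenario_params(n_markers = 48, seed = 14, events_per_branch = list(
    R = 0L, stem = 0L, P = 0L, S_pre = 0L, S_post = 0L))
  tr <- simulate_three_species_scenario(p0)
  ot <- suppressMessages(emit_ortholog_table(tr))
  ps <- classify_core(build_ppgs(ot, tr$genes))
  pa <- paint_genomes(ps, tr$genes)
  ## min_len = 1 keeps even one-marker ancestral chromosomes as blocks, so
  ## the no-signal scenario must be recovered exactly
  bl <- filter_blocks_by_ratio(find_no_blocks(pa, 1))
  anc <- reconstruct_ancestors(bl, pa)
  expect_equal(n_chromosomes(anc$pre_wgd1), 6)
  expect_equal(n_chromosomes(anc$post_wgd1), 12)
  ## expanded ancestor equals the true one after pPG -> marker renaming
  mem <- ps$membership
  mem$marker <- tr$genes$marker[match(mem$gene_id, tr$genes$gene_id)]
  map <- vapply(split(mem$marker, mem$ppg_id), function(x) x[1], "")
  pred <- rename_markers(expand_ancestor(anc$pre_wgd1, anc$orders), map)
  f1 <- adjacency_f1(pred, tr$ancestor_preWGD1)
  expect_equal(unname(f1["f1"]), 1)
})

test_that("reconstruction is deterministic and reports support per adjacency", {
  p <- scenario_params(n_markers = 80, seed = 17)
  tr <- simulate_three_species_scenario(p)
  ot <- suppressMessages(emit_ortholog_table(tr))
  ps <- classify_core(build_ppgs(ot, tr$genes))
  pa <- paint_genomes(ps, tr$genes)
  bl <- filter_blocks_by_ratio(find_no_blocks(pa, 3))
  a1 <- reconstruct_ancestors(bl, pa)
  a2 <- reconstruct_ancestors(bl, pa)
  expect_identical(a1$pre_wgd1$chromosomes, a2$pre_wgd1$chromosomes)
  expect_identical(a1$support, a2$support)
  expect_true(all(a1$support$stepC$votes >= 1))
  ## both median modes run and expose the same interface
  a3 <- reconstruct_ancestors(bl, pa, median_mode = "single")
  expect_s3_class(a3$pre_wgd1, "scj_genome")
  ## ratio violations are reported with the offending blocks
  expect_error(reconstruct_ancestors(bl, pa, ratio = c(R = 2, P = 2, S = 4)),
               "ratio")
})
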