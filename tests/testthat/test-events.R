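test_that("painting merges same-unit runs and flags unassigned segments", {
  g <- genome(list(c("+a.0", "+b.0", "+c.0", "+d.0")), name = "m")
  um <- c(a.0 = "A1", b.0 = "A1", c.0 = "A2", d.0 = "A2")
  p <- paint_by_ancestor(g, um)
  expect_equal(nrow(p), 2)
  expect_equal(p$unit, c("A1", "A2"))
  expect_equal(p$n_markers, c(2, 2))
  expect_warning(paint_by_ancestor(g, um[1:2]), "unassigned")
})

test_that("fission/fusion counting satisfies the bookkeeping identity", {
  ## identity painting: all zeros
  g <- genome(list(c("+a.0", "+b.0"), c("+c.0", "+d.0")))
  um <- c(a.0 = "A1", b.0 = "A1", c.0 = "A2", d.0 = "A2")
  cnt <- count_fissions_fusions(paint_by_ancestor(g, um), n_units = 2)
  expect_equal(cnt$total_fissions, 0)
  expect_equal(cnt$total_fusions, 0)
  expect_true(cnt$bookkeeping_ok)
  ## one ancestral unit split over two modern chromosomes
  g2 <- genome(list(c("+a.0", "+b.0"), "+c.0"))
  um2 <- c(a.0 = "A1", b.0 = "A1", c.0 = "A1")
  cnt2 <- count_fissions_fusions(paint_by_ancestor(g2, um2), n_units = 1)
  expect_equal(cnt2$total_fissions, 1)
  expect_equal(cnt2$total_fusions, 0)
  expect_true(cnt2$bookkeeping_ok)
  ## a chromosome concatenating two ancestral halves: one fusion
  g3 <- genome(list(c("+a.0", "+c.0")))
  um3 <- c(a.0 = "A1", c.0 = "A2")
  cnt3 <- count_fissions_fusions(paint_by_ancestor(g3, um3), n_units = 2)
  expect_equal(cnt3$total_fusions, 1)
  expect_true(cnt3$bookkeeping_ok)
})

test_that("simulated branch paintings are parsimony-consistent with the event log", {
  ## painting-derived counts are parsimony minima: never above the applied
  ## counts, and (when the bookkeeping identity holds) their difference must
  ## equal the applied fission - fusion balance exactly
  for (seed in 1:5) {
    tr <- simulate_three_species_scenario(
      scenario_params(n_markers = 150, seed = seed))
    logR <- tr$event_log[tr$event_log$branch == "R", ]
    fis_applied <- sum(logR$kind == "fission")
    fus_applied <- sum(logR$kind == "fusion")
    cnt <- count_fissions_fusions(
      paint_by_ancestor(tr$genome_R, tr$unit_maps$R), n_units = 6)
    expect_equal(cnt$n_modern, 7)
    expect_lte(cnt$total_fissions, fis_applied)
    expect_lte(cnt$total_fusions, fus_applied)
    if (cnt$bookkeeping_ok) {
      expect_equal(cnt$total_fissions - cnt$total_fusions,
                   fis_applied - fus_applied)
    }
  }
})

test_that("the enrichment z-test reproduces hand-computed statistics", {
  ## perfectly uniform counts: z = 0, p = 0.5 everywhere
  zt <- event_enrichment_ztest(rep(2L, 5))
  expect_true(all(abs(zt$z) < 1e-12))
  expect_true(all(abs(zt$p_enrich - 0.5) < 1e-12))
  ## N = 10 over 5 units, one unit with k = 6: z = (6-2)/sqrt(1.6)
  zt2 <- event_enrichment_ztest(c(6L, 1L, 1L, 1L, 1L))
  expect_equal(zt2$z[1], 4 / sqrt(10 * 0.2 * 0.8), tolerance = 1e-12)
  expect_equal(zt2$p_enrich[1], pnorm(4 / sqrt(1.6), lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(zt2$p_enrich + zt2$p_deplete, rep(1, 5), tolerance = 1e-12)
  ## weighted null shifts the expectation
  ztw <- event_enrichment_ztest(c(6L, 4L), weights = c(3, 2))
  expect_equal(ztw$expected, c(6, 4))
  expect_true(all(abs(ztw$z) < 1e-12))
  expect_error(event_enrichment_ztest(c(0L, 0L)), "zero events")
})

test_that("z-test tails track the exact binomial when N p >= 5", {
  ## the normal approximation must stay within its classical error bound
  for (case in list(c(n = 60, k = 15, units = 6), c(n = 120, k = 30, units = 5),
                    c(n = 200, k = 28, units = 8))) {
    N <- case[["n"]]; k <- case[["k"]]; u <- case[["units"]]
    p <- 1 / u
    counts <- integer(u); counts[1] <- k; counts[2:u] <- diff(round(seq(k, N, length.out = u)))
    counts[u] <- N - sum(counts[-u])
    zt <- event_enrichment_ztest(counts, total_events = N)
    exact <- pbinom(k - 1, N, p, lower.tail = FALSE)
    bound <- 0.8 / sqrt(N * p * (1 - p))   # Berry-Esseen style bound
    expect_lt(abs(zt$p_enrich[1] - exact), bound)
  }
})
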