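test_that("adjacency sets enumerate consecutive extremities", {
  expect_equal(adjacency_set(genome(list(c("+a.0", "+b.0")))),
               "a.0:h|b.0:t")
  expect_equal(adjacency_set(genome(list("+a.0", "+b.0"))), character())
  expect_setequal(adjacency_set(genome(list(c("+1.0", "-2.0", "+3.0")))),
                  c("1.0:h|2.0:h", "2.0:t|3.0:t"))
  expect_error(genome(list(c("+a.0", "+a.0"))), "duplicate")
})

test_that("SCJ distance is the symmetric difference of adjacency sets", {
  g1 <- genome(list(c("+1.0", "+2.0", "+3.0")))
  g2 <- genome(list(c("+1.0", "-2.0", "+3.0")))
  expect_equal(scj_distance(g1, g1), 0)
  expect_equal(scj_distance(genome(list(c("+a.0", "+b.0"))),
                            genome(list("+a.0", "+b.0"))), 1)
  expect_equal(scj_distance(g1, g2), 4)
  expect_equal(scj_distance(g2, g1), 4)
  expect_error(scj_distance(g1, genome(list("+9.0"))), "mismatch")
})

test_that("SCJ distance is a metric on random small genomes", {
  set.seed(11)
  keys <- paste0(letters[1:6], ".0")
  for (i in 1:40) {
    ga <- random_genome(keys); gb <- random_genome(keys)
    gc_ <- random_genome(keys)
    dab <- scj_distance(ga, gb)
    expect_equal(dab, scj_distance(gb, ga))
    expect_equal(scj_distance(ga, ga), 0)
    if (dab == 0) expect_true(genomes_equal(ga, gb))
    expect_lte(scj_distance(ga, gc_), dab + scj_distance(gb, gc_))
  }
})

test_that("single SCJ operations move distance and chromosome count by one", {
  g <- genome(list(c("+a.0", "+b.0", "+c.0")))
  cut <- apply_scj(g, scj_op("cut", adjacency = "a.0:h|b.0:t"))
  expect_equal(n_chromosomes(cut), 2)
  expect_equal(scj_distance(g, cut), 1)
  back <- apply_scj(cut, scj_op("join", extremities = c("a.0:h", "b.0:t")))
  expect_true(genomes_equal(back, g))
  ## a cut+join pair realizes a reciprocal translocation at distance 2
  two <- genome(list(c("+a.0", "+b.0"), c("+c.0")))
  t1 <- apply_scj(two, scj_op("cut", adjacency = "a.0:h|b.0:t"))
  t2 <- apply_scj(t1, scj_op("join", extremities = c("a.0:h", "c.0:t")))
  expect_equal(scj_distance(two, t2), 2)
  expect_equal(n_chromosomes(t2), 2)
  ## invalid moves
  expect_error(apply_scj(g, scj_op("cut", adjacency = "a.0:h|c.0:t")),
               "invalid")
  expect_error(apply_scj(cut, scj_op("join",
                                     extremities = c("a.0:t", "a.0:h"))),
               "circular|invalid")
})

test_that("linearize builds paths, opens cycles deterministically and inverts adjacency_set", {
  expect_equal(n_chromosomes(linearize(character(), c("a.0", "b.0", "c.0"))), 3)
  path <- linearize(c("a.0:h|b.0:t", "b.0:h|c.0:t"), c("a.0", "b.0", "c.0"))
  expect_equal(n_chromosomes(path), 1)
  expect_length(attr(path, "opened"), 0)
  ## 3-cycle: opened at its lexicographically smallest adjacency
  cyc <- c("a.0:h|b.0:t", "b.0:h|c.0:t", "a.0:t|c.0:h")
  lz <- linearize(cyc, c("a.0", "b.0", "c.0"))
  expect_equal(n_chromosomes(lz), 1)
  expect_equal(attr(lz, "opened"), "a.0:h|b.0:t")
  expect_setequal(adjacency_set(lz), setdiff(cyc, "a.0:h|b.0:t"))
  ## conflict detection
  expect_error(linearize(c("a.0:h|b.0:t", "a.0:h|c.0:t"),
                         c("a.0", "b.0", "c.0")), "conflict")
  ## round trip on random genomes
  set.seed(5)
  keys <- paste0("m", 1:8, ".0")
  for (i in 1:25) {
    g <- random_genome(keys)
    expect_true(genomes_equal(g, linearize(adjacency_set(g), keys)))
  }
})

test_that("event bookkeeping predicts the three karyotype transitions", {
  expect_equal(validate_event_bookkeeping(6, 5, 4, 0), 7)
  expect_equal(validate_event_bookkeeping(6, 11, 12, 1), 11)
  expect_equal(validate_event_bookkeeping(11, 20, 20, 1), 22)
  expect_error(validate_event_bookkeeping(1, 0, 5, 0), "inconsistent")
  expect_error(validate_event_bookkeeping(-1, 0, 0, 0), "non-negative")
  ## identity holds across random bookkeeping entries
  set.seed(3)
  for (i in 1:50) {
    n0 <- sample(1:12, 1); w <- sample(0:2, 1)
    fis <- sample(0:20, 1); fus <- sample(0:(n0 * 2^w + fis - 1), 1)
    expect_equal(validate_event_bookkeeping(n0, fis, fus, w),
                 n0 * 2^w + fis - fus)
  }
})
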