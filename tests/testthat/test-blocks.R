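# A hand-built three-genome toy: 7 genes over two pPG components plus
# singletons, used for the graph stage; simulated scenarios cover the rest.
toy_positions <- function() {
  data.frame(
    gene_id = c("r1", "r2", "r3", "r4", "p1", "p2", "s1"),
    genome = c("R", "R", "R", "R", "P", "P", "S"),
    chromosome = c("c1", "c1", "c1", "c2", "c1", "c1", "c1"),
    start = c(0, 100, 200, 0, 0, 100, 0),
    end = c(50, 150, 250, 50, 50, 150, 50),
    strand = c("+", "-", "+", "+", "+", "+", "-"),
    stringsAsFactors = FALSE)
}

test_that("pPGs are the connected components of the ortholog graph", {
  pos <- toy_positions()
  ## two components drawn by hand: {r1, p1, s1, p2} and {r2, r3, r4}
  pairs <- data.frame(gene_a = c("r1", "p1", "p2", "r2", "r3"),
                      gene_b = c("p1", "s1", "s1", "r3", "r4"))
  ps <- build_ppgs(pairs, pos)
  expect_equal(sort(ps$ppgs$size), c(3, 4))
  expect_equal(nrow(ps$ppgs), 2)
  ## every gene in exactly one pPG; genes without edges become singletons
  expect_setequal(ps$membership$gene_id, pos$gene_id)
  expect_equal(anyDuplicated(ps$membership$gene_id), 0)
  none <- build_ppgs(pairs[0, ], pos)
  expect_equal(nrow(none$ppgs), 7)
  expect_error(build_ppgs(data.frame(gene_a = "zz", gene_b = "r1"), pos),
               "unknown gene")
})

test_that("core classification requires the exact per-genome ratio", {
  pos <- toy_positions()
  pairs <- data.frame(gene_a = c("r1", "p1", "p2", "s1"),
                      gene_b = c("p1", "p2", "s1", "r1"))
  ps <- classify_core(build_ppgs(pairs, pos), c(R = 1, P = 2, S = 1))
  core_sizes <- ps$ppgs$size[ps$ppgs$is_core]
  expect_equal(core_sizes, 4)  # the {r1,p1,p2,s1} component matches (1,2,1)
  ps2 <- classify_core(build_ppgs(pairs, pos), c(R = 1, P = 2, S = 4))
  expect_false(any(ps2$ppgs$is_core))   # counts (1,2,1) != (1,2,4)
})

test_that("painting preserves gene order, strands and assigns copy labels deterministically", {
  pos <- toy_positions()
  pairs <- data.frame(gene_a = "r1", gene_b = "p1")
  ps <- classify_core(build_ppgs(pairs, pos), c(R = 1, P = 1, S = 0))
  pa <- paint_genomes(ps, pos)
  expect_setequal(names(pa$genomes), c("R", "P", "S"))
  ## strand propagated: r2 is on "-"
  rtoks <- unlist(pa$genomes$R$chromosomes)
  expect_equal(sum(token_sign(rtoks) == "-"), 1)
  ## duplicated pPG gets copy labels 0 and 1 in chromosome-sorted order
  pos2 <- pos
  pos2$gene_id[pos2$gene_id == "p2"] <- "p1b"
  pairs2 <- data.frame(gene_a = c("p1", "r1"), gene_b = c("p1b", "p1"))
  ps2 <- classify_core(build_ppgs(pairs2, pos2), c(R = 1, P = 2, S = 0))
  pa2 <- paint_genomes(ps2, pos2)
  ptoks <- unlist(pa2$genomes$P$chromosomes)
  copies <- sort(as.integer(key_copy(token_key(ptoks))))
  expect_equal(copies, c(0L, 1L))
})

# simulated loss-free scenario shared by the block-detection tests
sim_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- scenario_params(n_markers = 120, seed = 7)
      tr <- simulate_three_species_scenario(p)
      ot <- suppressMessages(emit_ortholog_table(tr))
      ps <- classify_core(build_ppgs(ot, tr$genes))
      pa <- paint_genomes(ps, tr$genes)
      cache <<- list(tr = tr, ps = ps, pa = pa,
                     bl = find_no_blocks(pa, min_len = 3))
    }
    cache
  }
})

test_that("loss-free simulation gives all-core pPGs that mirror the markers", {
  fx <- sim_fixture()
  expect_equal(nrow(fx$ps$ppgs), 120)
  expect_true(all(fx$ps$ppgs$is_core))
  expect_true(all(fx$ps$ppgs$size == 7))
})

test_that("conserved chains are split by breakpoints and respect min_len", {
  ## identical painted genomes: one block spanning everything
  pos <- data.frame(
    gene_id = paste0("g", 1:6), genome = rep(c("A", "B"), each = 3),
    chromosome = "c1", start = rep(c(0, 100, 200), 2),
    end = rep(c(50, 150, 250), 2), strand = "+", stringsAsFactors = FALSE)
  pairs <- data.frame(gene_a = c("g1", "g2", "g3"),
                      gene_b = c("g4", "g5", "g6"))
  ps <- classify_core(build_ppgs(pairs, pos), c(A = 1, B = 1))
  pa <- paint_genomes(ps, pos)
  bl <- find_no_blocks(pa, min_len = 3)
  expect_length(bl$blocks, 1)
  expect_length(bl$blocks[[1]]$ppg_order, 3)
  expect_equal(nrow(bl$blocks[[1]]$copies), 2)
  ## a breakpoint inside one copy splits the run
  pos_split <- pos
  pos_split$chromosome[5:6] <- "c2"          # B: g4 | g5 g6
  pos_split$start[5:6] <- c(0, 100); pos_split$end[5:6] <- c(50, 150)
  ps2 <- classify_core(build_ppgs(pairs, pos_split), c(A = 1, B = 1))
  pa2 <- paint_genomes(ps2, pos_split)
  bl2 <- find_no_blocks(pa2, min_len = 1)
  expect_length(bl2$blocks, 2)
  expect_setequal(lengths(lapply(bl2$blocks, `[[`, "ppg_order")), c(1L, 2L))
  ## min_len = 3 discards both short runs
  expect_length(find_no_blocks(pa2, min_len = 3)$blocks, 0)
})

test_that("block copies realize the chain order in every occurrence", {
  fx <- sim_fixture()
  expect_gt(length(fx$bl$blocks), 0)
  for (b in fx$bl$blocks) {
    for (r in seq_len(nrow(b$copies))) {
      cp <- b$copies[r, ]
      ch <- fx$pa$genomes[[cp$genome]]$chromosomes[[cp$chromosome]]
      toks <- ch[cp$start_index:cp$end_index]
      signed <- paste0(token_sign(toks), key_marker(token_key(toks)))
      want <- b$ppg_order
      if (cp$sign == "-") want <- rev(ifelse(substr(want, 1, 1) == "+",
                                             sub("^\\+", "-", want),
                                             sub("^-", "+", want)))
      expect_identical(signed, want)
    }
  }
})

test_that("the ratio filter keeps exactly the 1:2:4 blocks (none removed when loss-free)", {
  fx <- sim_fixture()
  cc <- block_copy_counts(fx$bl)
  expect_true(all(cc$R == 1 & cc$P == 2 & cc$S == 4))
  fb <- filter_blocks_by_ratio(fx$bl, c(R = 1, P = 2, S = 4))
  expect_length(attr(fb, "removed"), 0)
  expect_equal(length(fb$blocks), length(fx$bl$blocks))
  ## a block violating the ratio is removed
  fb2 <- filter_blocks_by_ratio(fx$bl, c(R = 2, P = 2, S = 4))
  expect_length(fb2$blocks, 0)
})

test_that("non-core fill-in inserts consistently-flanked pPGs and reports the rest", {
  ## A/B genomes where x sits between core g2 and g3 in every copy
  pos <- data.frame(
    gene_id = c("a1", "a2", "ax", "a3", "b1", "b2", "bx", "b3"),
    genome = rep(c("A", "B"), each = 4),
    chromosome = "c1", start = rep(c(0, 100, 150, 200), 2),
    end = rep(c(50, 140, 190, 250), 2), strand = "+",
    stringsAsFactors = FALSE)
  pairs <- data.frame(gene_a = c("a1", "a2", "a3"),
                      gene_b = c("b1", "b2", "b3"))
  ps <- classify_core(build_ppgs(pairs, pos), c(A = 1, B = 1))
  pa <- paint_genomes(ps, pos)
  bl <- filter_blocks_by_ratio(find_no_blocks(pa, 3), c(A = 1, B = 1))
  expect_length(bl$blocks, 1)
  filled <- fill_noncore(bl, ps, pa)
  ## ax and bx are singleton non-core pPGs between cores of the same block
  expect_equal(length(filled$blocks[[1]]$ppg_order), 5)
  expect_equal(nrow(attr(filled, "unplaced")), 0)
  ## no non-core pPGs: blocks unchanged
  ps_all <- classify_core(build_ppgs(
    data.frame(gene_a = c("a1", "a2", "ax", "a3"),
               gene_b = c("b1", "b2", "bx", "b3")), pos), c(A = 1, B = 1))
  pa_all <- paint_genomes(ps_all, pos)
  bl_all <- find_no_blocks(pa_all, 3)
  filled_all <- fill_noncore(bl_all, ps_all, pa_all)
  expect_identical(lapply(filled_all$blocks, `[[`, "ppg_order"),
                   lapply(bl_all$blocks, `[[`, "ppg_order"))
  ## a non-core pPG at a chromosome boundary stays unplaced
  pos_b <- pos
  pos_b$start[pos_b$gene_id == "bx"] <- 300   # bx now after b3
  pos_b$end[pos_b$gene_id == "bx"] <- 350
  ps_b <- classify_core(build_ppgs(pairs, pos_b), c(A = 1, B = 1))
  pa_b <- paint_genomes(ps_b, pos_b)
  bl_b <- filter_blocks_by_ratio(find_no_blocks(pa_b, 3), c(A = 1, B = 1))
  filled_b <- fill_noncore(bl_b, ps_b, pa_b)
  expect_gt(nrow(attr(filled_b, "unplaced")), 0)
})

test_that("WGD multiplicity is the log2 of the normalized modal copy number", {
  fx <- sim_fixture()
  wm <- infer_wgd_multiplicity(fx$bl)
  expect_equal(setNames(wm$wgd_count, wm$genome)[c("R", "P", "S")],
               c(R = 0, P = 1, S = 2))
  expect_true(all(wm$power_of_two))
  expect_error(infer_wgd_multiplicity(
    structure(list(blocks = list(), min_len = 3), class = "synteny_blocks")),
    "insufficient")
})
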