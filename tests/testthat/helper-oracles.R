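# Brute-force oracles and random-instance generators used across tests.
# The oracles are independent of the implementation paths they check: they
# enumerate complete genome spaces and score candidates with nothing more
# than adjacency-set symmetric differences.

# all linear genomes over a set of single-copy markers, as a 0/1 adjacency
# incidence matrix over the universe of candidate adjacencies
enumerate_genomes <- function(markers) {
  keys <- paste0(markers, ".0")
  exts <- c(outer(keys, c(":t", ":h"), paste0))
  universe <- character()
  for (i in seq_along(exts)) for (j in seq_len(i - 1L)) {
    if (sub(":[th]$", "", exts[i]) == sub(":[th]$", "", exts[j])) next
    universe <- c(universe, paste(sort(c(exts[i], exts[j]), method = "radix"), collapse = "|"))
  }
  universe <- sort(universe)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  cols <- list()

  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  n <- length(keys)
  sign_grid <- expand.grid(rep(list(c("+", "-")), n), stringsAsFactors = FALSE)
  break_grid <- if (n > 1) {
    expand.grid(rep(list(c(FALSE, TRUE)), n - 1), stringsAsFactors = FALSE)
  } else data.frame(row.names = 1)
  for (perm in perms(keys)) {
    for (si in seq_len(nrow(sign_grid))) {
      toks <- paste0(unlist(sign_grid[si, ]), perm)
      for (bi in seq_len(nrow(break_grid))) {
        breaks <- if (n > 1) which(unlist(break_grid[bi, ])) else integer()
        bounds <- c(0L, breaks, n)
        chroms <- lapply(seq_len(length(bounds) - 1L), function(k)
          toks[(bounds[k] + 1L):bounds[k + 1L]])
        g <- genome(chroms)
        a <- adjacency_set(g)
        id <- paste(c("g", a), collapse = ";")
        if (is.null(seen[[id]])) {
          seen[[id]] <- TRUE
          cols[[length(cols) + 1L]] <- as.integer(universe %in% a)
        }
      }
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- universe
  m
}

# random linear genome over given marker-copy keys
random_genome <- function(keys, name = "rand") {
  keys <- sample(keys)
  n <- length(keys)
  signs <- sample(c("+", "-"), n, replace = TRUE)
  toks <- paste0(signs, keys)
  nbreak <- sample(0:(n - 1), 1)
  breaks <- sort(sample(seq_len(n - 1), nbreak))
  bounds <- c(0L, breaks, n)
  genome(lapply(seq_len(length(bounds) - 1L), function(k)
    toks[(bounds[k] + 1L):bounds[k + 1L]]), name = name)
}

# brute-force SCJ median score: minimal total distance over all genomes on
# the same content (uses an enumerated incidence matrix)
brute_median_total <- function(M, g1, g2, g3) {
  a <- rownames(M) %in% adjacency_set(g1)
  b <- rownames(M) %in% adjacency_set(g2)
  c_ <- rownames(M) %in% adjacency_set(g3)
  tot <- colSums(M != a) + colSums(M != b) + colSums(M != c_)
  min(tot)
}

# brute-force guided halving: minimum over all ancestors (columns of M, on
# the guide's content) and all 2^n sub-genome pairings of
# d(ancestor x2 as paired, doubled) + d(ancestor, guide)
brute_halving_total <- function(M, doubled, guide) {
  guide_adj <- adjacency_set(guide)
  gvec <- rownames(M) %in% guide_adj
  n_anc_adj <- colSums(M)
  d_guide <- colSums(M != gvec)

  gkeys <- sort(genome_markers(guide))
  gmark <- sub("\\.[0-9]+$", "", gkeys)
  dkeys <- sort(genome_markers(doubled))
  dmark <- sub("\\.[0-9]+$", "", dkeys)
  copies <- split(dkeys, dmark)[gmark]

  dadj <- adjacency_set(doubled)
  split_adj <- strsplit(dadj, "|", fixed = TRUE)
  n <- length(gkeys)
  best <- Inf
  for (mask in 0:(2^n - 1)) {
    s_of <- integer()
    for (i in seq_len(n)) {
      bit <- bitwAnd(mask, bitwShiftL(1L, i - 1L)) > 0L
      s_of[copies[[i]][1]] <- as.integer(bit)
      s_of[copies[[i]][2]] <- 1L - as.integer(bit)
    }
    # map doubled adjacencies with matching s to collapsed guide-label keys
    w <- integer(nrow(M))
    mismatch <- 0L
    for (pp in split_adj) {
      k1 <- sub(":[th]$", "", pp[1]); k2 <- sub(":[th]$", "", pp[2])
      if (s_of[[k1]] != s_of[[k2]]) { mismatch <- mismatch + 1L; next }
      m1 <- sub("\\.[0-9]+$", "", k1); m2 <- sub("\\.[0-9]+$", "", k2)
      e1 <- paste0(gkeys[match(m1, gmark)], ":", sub("^.*:", "", pp[1]))
      e2 <- paste0(gkeys[match(m2, gmark)], ":", sub("^.*:", "", pp[2]))
      key <- paste(sort(c(e1, e2), method = "radix"), collapse = "|")
      idx <- match(key, rownames(M))
      if (!is.na(idx)) w[idx] <- w[idx] + 1L
    }
    # d(anc x2 paired, doubled) = |A(D)| + 2|anc| - 2 * matches
    matches <- as.vector(w %*% M)
    d_doub <- length(dadj) + 2L * n_anc_adj - 2L * matches
    best <- min(best, min(d_doub + d_guide))
  }
  best
}
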