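#' @importFrom stats pnorm rnorm runif setNames sd kmeans dnorm
#' @importFrom utils head tail read.delim write.table modifyList
NULL

## ---------------------------------------------------------------------------
## Signed marker tokens
##
## A marker copy is written "<sign><marker_id>.<copy_label>", e.g. "+m12.0" or
## "-B3.1".  Marker ids must not contain ".", "|" or ":" (those characters are
## reserved for the copy separator, adjacency keys and extremity keys).
## ---------------------------------------------------------------------------

TOKEN_RE <- "^[+-][^.|:[:space:]]+\\.[0-9]+$"

## locale-independent deterministic ordering (radix = C locale)
c_sort <- function(x) sort(x, method = "radix")
c_min <- function(x) sort(x, method = "radix")[1L]
c_order <- function(x) order(x, method = "radix")


token_sign <- function(x) substr(x, 1L, 1L)
token_key <- function(x) substring(x, 2L)
key_marker <- function(k) sub("\\.[0-9]+$", "", k)
key_copy <- function(k) sub("^.*\\.", "", k)

flip_token <- function(x) {
  s <- token_sign(x)
  paste0(ifelse(s == "+", "-", "+"), token_key(x))
}

#' Reverse-complement a chromosome (reverse order, flip all signs)
#' @param chrom character vector of signed marker tokens
#' @return character vector
#' @keywords internal
rc_chrom <- function(chrom) rev(flip_token(chrom))

mk_token <- function(marker, copy, sign = "+") paste0(sign, marker, ".", copy)

## Extremities: "<key>:t" (tail) and "<key>:h" (head).  Reading a marker in
## "+" orientation encounters tail first, then head.
ext_tail <- function(key) paste0(key, ":t")
ext_head <- function(key) paste0(key, ":h")
ext_key <- function(e) sub(":[th]$", "", e)
ext_end <- function(e) substring(e, nchar(e))
ext_other <- function(e) {
  k <- ext_key(e)
  if (ext_end(e) == "t") ext_head(k) else ext_tail(k)
}

## extremity on the right/left side of a signed token as laid on a chromosome
right_ext <- function(token) {
  k <- token_key(token)
  ifelse(token_sign(token) == "+", ext_head(k), ext_tail(k))
}
left_ext <- function(token) {
  k <- token_key(token)
  ifelse(token_sign(token) == "+", ext_tail(k), ext_head(k))
}

#' Canonical adjacency key for two extremities
#'
#' Adjacencies are unordered pairs of extremities of distinct marker copies;
#' the canonical key sorts the two extremity strings and joins them with "|".
#'
#' @param e1,e2 extremity strings such as `"m1.0:h"`
#' @return character scalar
#' @keywords internal
adj_key <- function(e1, e2) {
  if (ext_key(e1) == ext_key(e2)) {
    stop("adjacency joins two ends of the same marker copy: ", e1, " / ", e2)
  }
  paste(c_sort(c(e1, e2)), collapse = "|")
}

adj_exts <- function(a) strsplit(a, "|", fixed = TRUE)

## ---------------------------------------------------------------------------
## Genome class
## ---------------------------------------------------------------------------

#' Construct a genome of linear chromosomes of signed marker copies
#'
#' A genome is a set of linear chromosomes, each an ordered sequence of signed
#' marker copies.  Marker copies are written `"<sign><marker>.<copy>"`, e.g.
#' `"+m3.0"`.  `(marker, copy)` pairs must be unique across the genome.
#'
#' @param chromosomes list of character vectors of signed tokens
#' @param name genome name
#' @return an object of class `scj_genome`
#' @examples
#' g <- genome(list(c("+a.0", "+b.0"), "+c.0"), name = "toy")
#' adjacency_set(g)
#' @export
genome <- function(chromosomes, name = "genome") {
  if (is.character(chromosomes)) chromosomes <- list(chromosomes)
  stopifnot(is.list(chromosomes))
  chromosomes <- lapply(chromosomes, as.character)
  toks <- unlist(chromosomes, use.names = FALSE)
  if (length(toks)) {
    bad <- toks[!grepl(TOKEN_RE, toks)]
    if (length(bad)) stop("malformed marker tokens: ", paste(head(bad, 5), collapse = ", "))
    keys <- token_key(toks)
    if (anyDuplicated(keys)) {
      stop("malformed genome: duplicate (marker, copy) pairs: ",
           paste(unique(keys[duplicated(keys)]), collapse = ", "))
    }
  }
  structure(list(name = name, chromosomes = chromosomes), class = "scj_genome")
}

#' @export
print.scj_genome <- function(x, ...) {
  cat(sprintf("<scj_genome '%s': %d chromosomes, %d marker copies>\n",
              x$name, length(x$chromosomes), n_marker_copies(x)))
  for (i in seq_along(x$chromosomes)) {
    ch <- x$chromosomes[[i]]
    if (length(ch) > 12) ch <- c(head(ch, 10), sprintf("... (%d more)", length(ch) - 10))
    cat(sprintf("  [%d] %s\n", i, paste(ch, collapse = " ")))
  }
  invisible(x)
}

#' Marker-copy keys of a genome
#' @param g an `scj_genome`
#' @return character vector of unsigned `"marker.copy"` keys
#' @export
genome_markers <- function(g) token_key(unlist(g$chromosomes, use.names = FALSE))

n_marker_copies <- function(g) length(genome_markers(g))

#' Number of chromosomes
#' @param g an `scj_genome`
#' @export
n_chromosomes <- function(g) length(g$chromosomes)

#' Adjacency set of a genome
#'
#' Returns the canonical keys of all adjacencies between consecutive signed
#' marker copies on each chromosome.  Telomeres carry no adjacency, so a
#' genome with `m` marker copies and `c` linear chromosomes has exactly
#' `m - c` adjacencies.
#'
#' @param g an `scj_genome`
#' @return sorted character vector of adjacency keys
#' @export
adjacency_set <- function(g) {
  e1 <- unlist(lapply(g$chromosomes, function(ch) {
    n <- length(ch)
    if (n < 2) character() else right_ext(ch[-n])
  }), use.names = FALSE)
  e2 <- unlist(lapply(g$chromosomes, function(ch) {
    n <- length(ch)
    if (n < 2) character() else left_ext(ch[-1])
  }), use.names = FALSE)
  if (!length(e1)) return(character())
  ## pairwise C-locale min/max via radix ranks
  n <- length(e1)
  pos <- integer(2L * n)
  pos[order(c(e1, e2), method = "radix")] <- seq_len(2L * n)
  swap <- pos[seq_len(n)] > pos[n + seq_len(n)]
  c_sort(paste0(ifelse(swap, e2, e1), "|", ifelse(swap, e1, e2)))
}

#' Single-cut-or-join (SCJ) distance between two genomes
#'
#' The SCJ distance between genomes with identical marker-copy content is the
#' size of the symmetric difference of their adjacency sets: each adjacency
#' present in one genome but not the other costs exactly one cut or one join.
#'
#' @param g1,g2 `scj_genome` objects over the same `(marker, copy)` multiset
#' @return non-negative integer
#' @examples
#' g1 <- genome(list(c("+a.0", "+b.0", "+c.0")))
#' g2 <- genome(list(c("+a.0", "-b.0", "+c.0")))
#' scj_distance(g1, g2)  # 4
#' @export
scj_distance <- function(g1, g2) {
  m1 <- c_sort(genome_markers(g1)); m2 <- c_sort(genome_markers(g2))
  if (!identical(m1, m2)) {
    d <- c(setdiff(m1, m2), setdiff(m2, m1))
    stop("marker content mismatch between genomes: ",
         paste(head(unique(d), 8), collapse = ", "))
  }
  a1 <- adjacency_set(g1); a2 <- adjacency_set(g2)
  length(setdiff(a1, a2)) + length(setdiff(a2, a1))
}

scj_set_distance <- function(a1, a2) {
  length(setdiff(a1, a2)) + length(setdiff(a2, a1))
}

## ---------------------------------------------------------------------------
## Linearization: adjacency set -> genome
## ---------------------------------------------------------------------------

#' Assemble a genome from an adjacency set
#'
#' Builds maximal paths over the given marker copies and returns them as
#' linear chromosomes.  Any cycle is opened deterministically by removing its
#' lexicographically smallest adjacency; removed adjacencies are reported in
#' the `opened` attribute.  Chromosomes are orientation-canonicalized (a
#' chromosome equals its reverse complement; the lexicographically smaller
#' reading is kept) and sorted.
#'
#' @param adjacencies character vector of adjacency keys
#' @param markers character vector of unsigned `"marker.copy"` keys
#' @param name genome name
#' @return an `scj_genome`; attribute `"opened"` lists removed cycle-opening
#'   adjacencies
#' @export
linearize <- function(adjacencies, markers, name = "genome") {
  adjacencies <- c_sort(unique(adjacencies))
  markers <- c_sort(unique(markers))
  exts <- unlist(adj_exts(adjacencies), use.names = FALSE)
  if (anyDuplicated(exts)) {
    bad <- unique(exts[duplicated(exts)])
    conf <- adjacencies[vapply(adj_exts(adjacencies),
                               function(p) any(p %in% bad), logical(1))]
    stop("conflicting adjacencies (extremity used twice): ",
         paste(conf, collapse = "; "))
  }
  unknown <- setdiff(ext_key(exts), markers)
  if (length(unknown)) stop("adjacency references unknown markers: ",
                            paste(unique(unknown), collapse = ", "))

  ## integer encoding: marker i has extremities 2i-1 (tail) and 2i (head)
  nm <- length(markers)
  ext_id <- function(e) {
    i <- match(ext_key(e), markers)
    2L * i - (ext_end(e) == "t")
  }
  partner <- integer(2L * nm)          # 0 = free
  adj_of <- integer(2L * nm)           # adjacency index per extremity
  if (length(adjacencies)) {
    pp <- adj_exts(adjacencies)
    i1 <- ext_id(vapply(pp, `[`, "", 1L))
    i2 <- ext_id(vapply(pp, `[`, "", 2L))
    partner[i1] <- i2; partner[i2] <- i1
    adj_of[i1] <- seq_along(adjacencies); adj_of[i2] <- seq_along(adjacencies)
  }
  visited <- logical(nm)
  opened <- character()
  chroms <- list()

  walk <- function(start_ext_id) {
    toks <- character(nm); nt <- 0L
    e <- start_ext_id
    repeat {
      i <- (e + 1L) %/% 2L
      visited[i] <<- TRUE
      nt <- nt + 1L
      ## entering at tail (odd id) reads the marker forward
      toks[nt] <- paste0(if (e %% 2L == 1L) "+" else "-", markers[i])
      other <- if (e %% 2L == 1L) e + 1L else e - 1L
      nxt <- partner[other]
      if (nxt == 0L) break
      e <- nxt
    }
    toks[seq_len(nt)]
  }

  ## path starts: free extremities, in deterministic (tail-then-head within
  ## marker, markers already sorted) extremity-string order
  free <- which(partner == 0L)
  free_keys <- if (length(free)) {
    paste0(markers[(free + 1L) %/% 2L], ":",
           ifelse(free %% 2L == 1L, "t", "h"))
  } else character()
  for (e in free[c_order(free_keys)]) {
    i <- (e + 1L) %/% 2L
    if (!visited[i]) chroms[[length(chroms) + 1L]] <- walk(e)
  }
  ## remaining markers sit on cycles: open each at its smallest adjacency
  repeat {
    left <- which(!visited)
    if (!length(left)) break
    cyc_adj_idx <- unique(adj_of[c(2L * left - 1L, 2L * left)])
    cyc_adj_idx <- cyc_adj_idx[cyc_adj_idx > 0L]
    cut_idx <- cyc_adj_idx[c_order(adjacencies[cyc_adj_idx])[1L]]
    cut <- adjacencies[cut_idx]
    opened <- c(opened, cut)
    pr <- adj_exts(cut)[[1]]
    pi <- ext_id(pr)
    partner[pi] <- 0L
    chroms[[length(chroms) + 1L]] <- walk(pi[c_order(pr)[1L]])
  }

  ## canonical orientation and chromosome order
  chroms <- lapply(chroms, function(ch) {
    r <- rc_chrom(ch)
    if (c_min(c(paste(r, collapse = " "), paste(ch, collapse = " "))) ==
        paste(r, collapse = " ") &&
        !identical(r, ch)) r else ch
  })
  ord <- c_order(vapply(chroms, function(ch) paste(ch, collapse = " "), ""))
  g <- genome(chroms[ord], name = name)
  attr(g, "opened") <- opened
  g
}

#' Canonicalize a genome
#'
#' Chromosomes are compared as an unordered set and each chromosome is
#' identified with its reverse complement; the canonical form fixes both.
#'
#' @param g an `scj_genome`
#' @return an `scj_genome` in canonical form
#' @export
canonical_genome <- function(g) {
  out <- linearize(adjacency_set(g), genome_markers(g), name = g$name)
  attr(out, "opened") <- NULL
  out
}

#' Test two genomes for canonical equality
#' @param g1,g2 `scj_genome` objects
#' @return logical
#' @export
genomes_equal <- function(g1, g2) {
  c1 <- canonical_genome(g1)$chromosomes
  c2 <- canonical_genome(g2)$chromosomes
  identical(c1, c2)
}

## ---------------------------------------------------------------------------
## SCJ operations
## ---------------------------------------------------------------------------

#' Construct a single-cut-or-join operation
#'
#' @param kind `"cut"` or `"join"`
#' @param adjacency for a cut, the adjacency key to remove
#' @param extremities for a join, the two free extremities to connect
#' @return an `scj_op`
#' @export
scj_op <- function(kind = c("cut", "join"), adjacency = NULL, extremities = NULL) {
  kind <- match.arg(kind)
  if (kind == "cut" && (is.null(adjacency) || length(adjacency) != 1L))
    stop("a cut targets exactly one adjacency")
  if (kind == "join" && (is.null(extremities) || length(extremities) != 2L))
    stop("a join targets exactly two extremities")
  structure(list(kind = kind, adjacency = adjacency,
                 extremities = extremities), class = "scj_op")
}

#' Apply a single SCJ operation to a genome
#'
#' A cut removes one existing adjacency (chromosome count +1); a join connects
#' two currently free telomeric extremities of different chromosomes
#' (chromosome count -1).  Either way the SCJ distance between input and
#' output is exactly 1 and marker content is unchanged.
#'
#' @param g an `scj_genome`
#' @param op an [scj_op()]
#' @return the rearranged `scj_genome` (canonical form)
#' @export
apply_scj <- function(g, op) {
  stopifnot(inherits(op, "scj_op"))
  adj <- adjacency_set(g)
  if (op$kind == "cut") {
    if (!op$adjacency %in% adj)
      stop("invalid operation: adjacency not present: ", op$adjacency)
    adj <- setdiff(adj, op$adjacency)
  } else {
    e <- op$extremities
    used <- unlist(adj_exts(adj), use.names = FALSE)
    if (any(e %in% used))
      stop("invalid operation: extremity not free: ",
           paste(e[e %in% used], collapse = ", "))
    if (!all(ext_key(e) %in% genome_markers(g)))
      stop("invalid operation: unknown extremities")
    ## forbid circularization: both extremities on the same chromosome
    chrom_of <- chromosome_index(g)
    if (chrom_of[[ext_key(e[1])]] == chrom_of[[ext_key(e[2])]])
      stop("invalid operation: join would create a circular chromosome")
    adj <- c(adj, adj_key(e[1], e[2]))
  }
  linearize(adj, genome_markers(g), name = g$name)
}

chromosome_index <- function(g) {
  idx <- integer(0)
  for (i in seq_along(g$chromosomes)) {
    k <- token_key(g$chromosomes[[i]])
    idx[k] <- i
  }
  idx
}

#' Free (telomeric) extremities of a genome
#' @param g an `scj_genome`
#' @return character vector of extremities at chromosome ends
#' @export
telomeric_extremities <- function(g) {
  unlist(lapply(g$chromosomes, function(ch) {
    c(left_ext(ch[1]), right_ext(ch[length(ch)]))
  }), use.names = FALSE)
}

## ---------------------------------------------------------------------------
## Event bookkeeping
## ---------------------------------------------------------------------------

#' Predict a chromosome count from event bookkeeping
#'
#' Starting from `n_initial` chromosomes, each whole-genome duplication
#' doubles the count, each fission adds one and each fusion removes one:
#' `n_initial * 2^wgd_doublings + fissions - fusions`.
#'
#' @param n_initial ancestral chromosome count
#' @param fissions,fusions non-negative event counts
#' @param wgd_doublings number of whole-genome duplications applied before
#'   the fissions/fusions
#' @return predicted chromosome count (positive integer)
#' @examples
#' validate_event_bookkeeping(6, 5, 4)          # 7
#' validate_event_bookkeeping(6, 11, 12, 1)     # 11
#' validate_event_bookkeeping(11, 20, 20, 1)    # 22
#' @export
validate_event_bookkeeping <- function(n_initial, fissions, fusions,
                                       wgd_doublings = 0) {
  v <- c(n_initial, fissions, fusions, wgd_doublings)
  if (any(v < 0) || any(v != round(v)))
    stop("bookkeeping counts must be non-negative integers")
  n <- n_initial * 2^wgd_doublings + fissions - fusions
  if (n <= 0)
    stop("inconsistent bookkeeping: predicted chromosome count ", n, " <= 0")
  as.integer(n)
}
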