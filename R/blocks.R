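## ---------------------------------------------------------------------------
## Stage 1: putative protogenes (pPGs) from the ortholog graph, genome
## painting, conserved-adjacency synteny blocks, ratio filtering, non-core
## fill-in, and WGD multiplicity inference.
## ---------------------------------------------------------------------------

#' Build putative protogenes (pPGs) from ortholog pairs
#'
#' pPGs are the connected components of the graph whose vertices are genes
#' and whose edges are ortholog pairs; genes absent from the pair table form
#' singleton pPGs.
#'
#' @param pairs data.frame with `gene_a, gene_b` (e.g. from
#'   [read_ortholog_pairs()] or [emit_ortholog_table()])
#' @param gene_positions gene position table (`gene_id, genome, chromosome,
#'   start, end, strand`)
#' @return a `ppg_set`: list with `membership` (gene_id -> ppg_id) and
#'   `ppgs` (per-pPG per-genome counts)
#' @export
build_ppgs <- function(pairs, gene_positions) {
  genes <- gene_positions$gene_id
  unknown <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), genes)
  if (length(unknown))
    stop("ortholog pairs reference unknown gene id(s): ",
         paste(head(unknown, 5), collapse = ", "))
  g <- igraph::graph_from_data_frame(
    pairs[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = genes))
  comp <- igraph::components(g)$membership
  ## deterministic ppg ids: order components by their smallest gene id
  smallest <- vapply(split(names(comp), comp), c_min, "")
  rank <- match(smallest, c_sort(smallest))
  ids <- sprintf("p%05d", rank[comp])
  membership <- data.frame(gene_id = names(comp), ppg_id = ids,
                           stringsAsFactors = FALSE)
  gm <- gene_positions$genome[match(membership$gene_id, gene_positions$gene_id)]
  counts <- as.data.frame.matrix(table(membership$ppg_id, gm))
  ppgs <- data.frame(ppg_id = rownames(counts), counts,
                     size = rowSums(counts), row.names = NULL,
                     check.names = FALSE, stringsAsFactors = FALSE)
  ppgs <- ppgs[c_order(ppgs$ppg_id), , drop = FALSE]
  rownames(ppgs) <- NULL
  structure(list(membership = membership, ppgs = ppgs,
                 genomes = c_sort(unique(gene_positions$genome))),
            class = "ppg_set")
}

#' @export
print.ppg_set <- function(x, ...) {
  cat(sprintf("<ppg_set: %d pPGs over %d genes; genomes: %s>\n",
              nrow(x$ppgs), nrow(x$membership),
              paste(x$genomes, collapse = ", ")))
  if ("is_core" %in% names(x$ppgs))
    cat("  core pPGs:", sum(x$ppgs$is_core), "\n")
  invisible(x)
}

#' Classify core pPGs by an exact per-genome copy ratio
#'
#' A pPG is core when its per-genome member counts equal the ratio implied by
#' the WGD history exactly — by default 1:2:4 for the no-WGD, one-WGD and
#' two-WGD genomes.
#'
#' @param ppg_set a [build_ppgs()] result
#' @param core_ratio named integer vector, names = genome names
#' @return the `ppg_set` with an `is_core` column filled in
#' @export
classify_core <- function(ppg_set, core_ratio = c(R = 1, P = 2, S = 4)) {
  stopifnot(inherits(ppg_set, "ppg_set"))
  if (is.null(names(core_ratio)) || !all(names(core_ratio) %in% ppg_set$genomes))
    stop("core_ratio must be named by genome; known genomes: ",
         paste(ppg_set$genomes, collapse = ", "))
  tab <- ppg_set$ppgs
  ok <- rep(TRUE, nrow(tab))
  for (gn in ppg_set$genomes) {
    want <- if (gn %in% names(core_ratio)) core_ratio[[gn]] else 0
    ok <- ok & (tab[[gn]] == want)
  }
  ppg_set$ppgs$is_core <- ok
  ppg_set$core_ratio <- core_ratio
  ppg_set
}

#' Paint genomes with pPG ids
#'
#' Each chromosome becomes its gene order with every gene replaced by its pPG
#' id and the gene's strand.  Copy labels are assigned per pPG and genome in
#' (chromosome, start) order, so painting is deterministic.  Non-core pPG
#' positions are retained and flagged for the fill-in step.
#'
#' @param ppg_set a [classify_core()] result
#' @param gene_positions gene position table
#' @return a `painted_genomes` list: `genomes` (named list of `scj_genome`
#'   over pPG tokens), `core_ppgs`, and `gene_of` (per genome, token key ->
#'   gene id)
#' @export
paint_genomes <- function(ppg_set, gene_positions) {
  stopifnot(inherits(ppg_set, "ppg_set"))
  if (!"is_core" %in% names(ppg_set$ppgs))
    stop("run classify_core() before painting")
  ppg_of <- setNames(ppg_set$membership$ppg_id, ppg_set$membership$gene_id)
  core <- ppg_set$ppgs$ppg_id[ppg_set$ppgs$is_core]
  genomes <- list(); gene_of <- list()
  for (gn in ppg_set$genomes) {
    df <- gene_positions[gene_positions$genome == gn, , drop = FALSE]
    df <- df[order(df$chromosome, df$start, df$gene_id, method = "radix"), ,
             drop = FALSE]
    df$ppg <- ppg_of[df$gene_id]
    ## copy labels per pPG in chromosome-sorted order
    df$copy <- stats::ave(seq_len(nrow(df)), df$ppg,
                          FUN = function(i) seq_along(i) - 1L)
    df$token <- mk_token(df$ppg, df$copy, df$strand)
    chroms <- split(df$token, df$chromosome)
    chroms <- chroms[c_sort(names(chroms))]
    genomes[[gn]] <- genome(unname(chroms), name = gn)
    gene_of[[gn]] <- setNames(df$gene_id, token_key(df$token))
  }
  structure(list(genomes = genomes, core_ppgs = core, gene_of = gene_of),
            class = "painted_genomes")
}

## ---------------------------------------------------------------------------
## Conserved-adjacency chain finder (non-overlapping synteny blocks)
## ---------------------------------------------------------------------------

#' Find non-overlapping synteny blocks by conserved-adjacency chaining
#'
#' A pPG-level adjacency is conserved when it is realized, sign-aware, in
#' every occurrence of both partner pPGs across all genome copies (a
#' chromosome end or a single deviating copy breaks it).  Conserved
#' adjacencies form a partial matching on pPG extremities, so the maximal
#' chains are simply the paths of that matching; each core pPG belongs to at
#' most one chain, making the blocks non-overlapping.  Chains shorter than
#' `min_len` pPGs are discarded (kept as single-pPG blocks only when
#' `min_len = 1`).
#'
#' @param painted a [paint_genomes()] result
#' @param min_len minimum chain length in pPGs (default 3)
#' @return a `synteny_blocks` object
#' @export
find_no_blocks <- function(painted, min_len = 3L) {
  stopifnot(inherits(painted, "painted_genomes"))
  core <- painted$core_ppgs
  obs <- new.env(hash = TRUE, parent = emptyenv())
  note <- function(e, v) assign(e, c(get0(e, envir = obs), v), envir = obs)
  seen <- character()
  for (gn in names(painted$genomes)) {
    g <- painted$genomes[[gn]]
    for (ch in g$chromosomes) {
      keep <- key_marker(token_key(ch)) %in% core
      seqc <- ch[keep]
      n <- length(seqc)
      if (!n) next
      ppg <- key_marker(token_key(seqc))
      seen <- union(seen, ppg)
      sgn <- token_sign(seqc)
      re <- ifelse(sgn == "+", paste0(ppg, ".0:h"), paste0(ppg, ".0:t"))
      le <- ifelse(sgn == "+", paste0(ppg, ".0:t"), paste0(ppg, ".0:h"))
      for (i in seq_len(n)) {
        note(le[i], if (i > 1) re[i - 1] else NA_character_)
        note(re[i], if (i < n) le[i + 1] else NA_character_)
      }
    }
  }
  partner <- list()
  for (e in ls(obs)) {
    v <- get(e, envir = obs)
    u <- unique(v)
    if (length(u) == 1L && !is.na(u)) partner[[e]] <- u
  }
  adjs <- character()
  for (e in names(partner)) {
    f <- partner[[e]]
    if (identical(partner[[f]], e)) adjs <- c(adjs, adj_key(e, f))
  }
  adjs <- unique(adjs)
  lz <- linearize(adjs, paste0(seen, ".0"), name = "chains")
  chains <- lapply(lz$chromosomes, function(toks)
    paste0(token_sign(toks), key_marker(token_key(toks))))
  chains <- Filter(function(ch) length(ch) >= min_len, chains)
  ord <- c_order(vapply(chains, function(ch) c_min(substring(ch, 2)), ""))
  chains <- chains[ord]
  blocks <- lapply(seq_along(chains), function(i) {
    list(block_id = sprintf("B%04d", i), ppg_order = chains[[i]],
         copies = NULL)
  })
  blocks <- locate_block_copies(blocks, painted)
  structure(list(blocks = blocks, min_len = min_len,
                 opened_cycles = attr(lz, "opened")),
            class = "synteny_blocks")
}

flip_signed <- function(x) {
  ifelse(is.na(x), NA,
         paste0(ifelse(substr(x, 1, 1) == "+", "-", "+"), substring(x, 2)))
}

## find every occurrence (maximal run) of each chain in the painted genomes
locate_block_copies <- function(blocks, painted) {
  chain_of <- list()  # ppg -> c(block index, position)
  for (i in seq_along(blocks)) {
    ch <- blocks[[i]]$ppg_order
    for (j in seq_along(ch)) chain_of[[substring(ch[j], 2)]] <- c(i, j)
  }
  copies <- vector("list", length(blocks))
  core <- painted$core_ppgs
  for (gn in names(painted$genomes)) {
    g <- painted$genomes[[gn]]
    for (ci in seq_along(g$chromosomes)) {
      ch <- g$chromosomes[[ci]]
      ppg <- key_marker(token_key(ch))
      ## runs live in the core-filtered order: interleaved non-core tokens
      ## are invisible to the chains (the fill-in step places them later)
      cpos <- which(ppg %in% core)
      in_chain <- vapply(ppg, function(p) !is.null(chain_of[[p]]), logical(1))
      t <- 1L
      while (t <= length(cpos)) {
        pos <- cpos[t]
        if (!in_chain[pos]) { t <- t + 1L; next }
        bi <- chain_of[[ppg[pos]]][1]
        bp <- chain_of[[ppg[pos]]][2]
        chain <- blocks[[bi]]$ppg_order
        signed_here <- paste0(token_sign(ch[pos]), ppg[pos])
        dirn <- if (identical(signed_here, chain[bp])) +1L else -1L
        endt <- t; cur <- bp
        k <- t + 1L
        while (k <= length(cpos)) {
          kp <- cpos[k]
          if (!in_chain[kp]) break
          nxt_info <- chain_of[[ppg[kp]]]
          if (nxt_info[1] != bi || nxt_info[2] != cur + dirn) break
          want <- chain[cur + dirn]
          here <- paste0(token_sign(ch[kp]), ppg[kp])
          ok <- if (dirn > 0) identical(here, want)
                else identical(here, flip_signed(want))
          if (!ok) break
          cur <- cur + dirn; endt <- k; k <- k + 1L
        }
        copies[[bi]] <- rbind(copies[[bi]], data.frame(
          genome = gn, chromosome = ci, start_index = cpos[t],
          end_index = cpos[endt], sign = if (dirn > 0) "+" else "-",
          stringsAsFactors = FALSE))
        t <- endt + 1L
      }
    }
  }
  for (i in seq_along(blocks)) {
    cp <- copies[[i]]
    if (is.null(cp)) {
      cp <- data.frame(genome = character(), chromosome = integer(),
                       start_index = integer(), end_index = integer(),
                       sign = character(), copy_label = integer())
    } else {
      cp <- cp[order(cp$genome, cp$chromosome, cp$start_index,
                     method = "radix"), , drop = FALSE]
      cp$copy_label <- stats::ave(seq_len(nrow(cp)), cp$genome,
                                  FUN = function(x) seq_along(x) - 1L)
      rownames(cp) <- NULL
    }
    blocks[[i]]$copies <- cp
  }
  blocks
}

#' @export
print.synteny_blocks <- function(x, ...) {
  lens <- vapply(x$blocks, function(b) length(b$ppg_order), 0L)
  cat(sprintf("<synteny_blocks: %d blocks, %d pPGs, min_len = %d>\n",
              length(x$blocks), sum(lens), x$min_len))
  invisible(x)
}

#' Per-genome copy counts for every block
#' @param blocks a `synteny_blocks`
#' @return data.frame block_id x genome counts
#' @export
block_copy_counts <- function(blocks) {
  rows <- lapply(blocks$blocks, function(b) {
    tb <- table(b$copies$genome)
    data.frame(block_id = b$block_id, genome = names(tb),
               copies = as.integer(tb), stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  if (is.null(long)) return(data.frame(block_id = character()))
  stats::reshape(long, idvar = "block_id", timevar = "genome",
                 direction = "wide") |>
    (\(d) { names(d) <- sub("^copies\\.", "", names(d)); d })()
}

#' Long-format table of all block copies
#' @param blocks a `synteny_blocks`
#' @return data.frame `block_id, genome, chromosome, start_index, end_index,
#'   sign, copy_label`
#' @export
block_copy_table <- function(blocks) {
  rows <- lapply(blocks$blocks, function(b) {
    if (!nrow(b$copies)) return(NULL)
    cbind(block_id = b$block_id, b$copies)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(block_id = character())
  rownames(out) <- NULL
  out
}

#' Filter blocks by an exact per-genome copy-number ratio
#'
#' Keeps exactly the blocks whose per-genome copy counts equal the ratio
#' (default 4:2:1 in the two-WGD, one-WGD and no-WGD genomes).
#'
#' @param blocks a `synteny_blocks`
#' @param ratio named integer vector (genome -> expected copies)
#' @return filtered `synteny_blocks`; attribute `"removed"` lists dropped
#'   block ids
#' @export
filter_blocks_by_ratio <- function(blocks, ratio = c(R = 1, P = 2, S = 4)) {
  keep <- vapply(blocks$blocks, function(b) {
    cp <- b$copies
    all(vapply(names(ratio), function(gn)
      sum(cp$genome == gn) == ratio[[gn]], logical(1)))
  }, logical(1))
  removed <- vapply(blocks$blocks[!keep], function(b) b$block_id, "")
  blocks$blocks <- blocks$blocks[keep]
  attr(blocks, "removed") <- removed
  blocks
}

#' Fill non-core pPGs into the synteny blocks
#'
#' A non-core pPG is inserted into a block when, in every genome copy where
#' it occurs, it lies strictly between two core pPGs of that same block, in
#' the same inter-core slot.  Contradictory or boundary placements are
#' reported as unplaced with a reason.
#'
#' @param blocks a (typically ratio-filtered) `synteny_blocks`
#' @param ppg_set the [classify_core()] result
#' @param painted the [paint_genomes()] result
#' @return `blocks` with updated `ppg_order`; attribute `"unplaced"` is a
#'   data.frame of non-core pPGs left out
#' @export
fill_noncore <- function(blocks, ppg_set, painted) {
  core <- painted$core_ppgs
  noncore <- setdiff(ppg_set$ppgs$ppg_id, core)
  if (!length(noncore)) {
    attr(blocks, "unplaced") <- data.frame(ppg_id = character(),
                                           reason = character())
    return(blocks)
  }
  ## index: core ppg -> (block, position)
  slot_of <- list()
  for (i in seq_along(blocks$blocks)) {
    ch <- blocks$blocks[[i]]$ppg_order
    for (j in seq_along(ch)) {
      p <- substring(ch[j], 2)
      if (p %in% core) slot_of[[p]] <- c(i, j)
    }
  }
  ## occurrences of non-core pPGs with nearest core neighbours
  occs <- list()
  for (gn in names(painted$genomes)) {
    g <- painted$genomes[[gn]]
    for (ci in seq_along(g$chromosomes)) {
      ch <- g$chromosomes[[ci]]
      ppg <- key_marker(token_key(ch))
      is_core <- ppg %in% core
      core_pos <- which(is_core)
      for (k in which(!is_core)) {
        if (!ppg[k] %in% noncore) next
        lpos <- core_pos[core_pos < k]
        rpos <- core_pos[core_pos > k]
        occs[[length(occs) + 1L]] <- list(
          ppg = ppg[k], sign = token_sign(ch[k]),
          left = if (length(lpos)) ppg[max(lpos)] else NA,
          left_sign = if (length(lpos)) token_sign(ch[max(lpos)]) else NA,
          right = if (length(rpos)) ppg[min(rpos)] else NA)
      }
    }
  }
  placements <- list(); unplaced <- list()
  by_ppg <- split(occs, vapply(occs, function(o) o$ppg, ""))
  for (p in names(by_ppg)) {
    slots <- unique(lapply(by_ppg[[p]], function(o) {
      if (is.na(o$left) || is.na(o$right)) return("boundary")
      sl <- slot_of[[o$left]]; sr <- slot_of[[o$right]]
      if (is.null(sl) || is.null(sr) || sl[1] != sr[1]) return("split")
      ## slot = after the leftmost (in block frame) of the two cores
      c(sl[1], min(sl[2], sr[2]),
        if (identical(o$left_sign, o$sign)) "+" else "-")
    }))
    if (length(slots) != 1L || is.character(slots[[1]]) && length(slots[[1]]) == 1L) {
      reason <- if (length(slots) > 1) "contradictory placements"
                else slots[[1]][1]
      reason <- switch(reason,
                       boundary = "not strictly between core pPGs",
                       split = "flanking cores in different blocks",
                       reason)
      unplaced[[p]] <- reason
      next
    }
    placements[[p]] <- slots[[1]]
  }
  ## insert, processing each block's placements right-to-left
  if (length(placements)) {
    byblock <- split(names(placements),
                     vapply(placements, function(s) as.integer(s[1]), 0L))
    for (bi_chr in names(byblock)) {
      bi <- as.integer(bi_chr)
      ps <- byblock[[bi_chr]]
      at <- vapply(placements[ps], function(s) as.integer(s[2]), 0L)
      sgn <- vapply(placements[ps], function(s) s[3], "")
      o <- order(-at, ps, method = "radix")
      ch <- blocks$blocks[[bi]]$ppg_order
      for (ix in o) {
        pos <- at[ix]
        ch <- append(ch, paste0(sgn[ix], ps[ix]), after = pos)
      }
      blocks$blocks[[bi]]$ppg_order <- ch
    }
  }
  attr(blocks, "unplaced") <- if (length(unplaced)) {
    data.frame(ppg_id = names(unplaced), reason = unlist(unplaced),
               row.names = NULL, stringsAsFactors = FALSE)
  } else data.frame(ppg_id = character(), reason = character())
  blocks
}

#' Infer per-genome WGD counts from block copy numbers
#'
#' Takes the modal block copy number per genome, normalizes by the smallest
#' genome's mode and reports `log2` of the normalized mode as the WGD count;
#' a non-power-of-two mode is flagged.
#'
#' @param blocks a `synteny_blocks`
#' @return data.frame `genome, modal_copies, normalized, wgd_count,
#'   power_of_two`
#' @export
infer_wgd_multiplicity <- function(blocks) {
  tab <- block_copy_table(blocks)
  if (!nrow(tab)) stop("insufficient data: no synteny blocks")
  cnt <- table(tab$block_id, tab$genome)
  modes <- vapply(colnames(cnt), function(gn) {
    v <- cnt[, gn]
    tb <- table(v[v > 0])
    as.integer(names(tb)[which.max(tb)])  # smallest mode on ties
  }, 0L)
  norm <- modes / min(modes)
  p2 <- abs(log2(norm) - round(log2(norm))) < 1e-9
  data.frame(genome = names(modes), modal_copies = as.integer(modes),
             normalized = norm, wgd_count = ifelse(p2, round(log2(norm)), NA),
             power_of_two = p2, row.names = NULL, stringsAsFactors = FALSE)
}

#' Block-level genomes from located block copies
#'
#' Rewrites each painted chromosome as the ordered sequence of its block
#' copies (signed block ids with per-genome copy labels), the input to the
#' ancestor-reconstruction stage.
#'
#' @param blocks a `synteny_blocks`
#' @param painted the [paint_genomes()] result
#' @return named list of `scj_genome` objects over block markers
#' @export
block_genomes <- function(blocks, painted) {
  tab <- block_copy_table(blocks)
  out <- list()
  for (gn in names(painted$genomes)) {
    sub <- tab[tab$genome == gn, , drop = FALSE]
    chroms <- list()
    for (ci in seq_along(painted$genomes[[gn]]$chromosomes)) {
      rows <- sub[sub$chromosome == ci, , drop = FALSE]
      if (!nrow(rows)) next
      rows <- rows[order(rows$start_index), , drop = FALSE]
      chroms[[length(chroms) + 1L]] <-
        mk_token(rows$block_id, rows$copy_label, rows$sign)
    }
    out[[gn]] <- genome(chroms, name = gn)
  }
  out
}
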