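## ---------------------------------------------------------------------------
## Stage 2/3: copy matching by SCJ minimization (MO), SCJ genome median
## (GMP), guided genome halving (GGHP), the bottom-up ancestor pipeline and
## greedy-topological gene ordering within blocks.
##
## SCJ theory used here: for genomes with identical labelled content the SCJ
## median is exactly the majority-vote adjacency set, and once duplicated
## copies are matched the guided-halving ancestor is the majority vote of
## {sub-genome 1, sub-genome 2, guide}.  Majority sets are conflict-free: two
## adjacencies sharing an extremity would have to co-occur in at least one
## input genome (pigeonhole over 2-of-3 votes), which no valid genome allows.
## ---------------------------------------------------------------------------

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (i in seq_len(n)) out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
  }
  out
}

## ---------------------------------------------------------------------------
## MO engine: assign each copy of a 2k-multiplicity genome to a slot
## (guide copy label p, sub-genome s in {0,1}) minimizing the guided-halving
## objective  d(anc x2 as paired, doubled) + d(anc, guide)  where anc is the
## majority-vote ancestor implied by the assignment.
## ---------------------------------------------------------------------------

mo_engine <- function(doubled, guide, max_exhaustive = 20000L,
                      max_sweeps = 25L) {
  dk <- genome_markers(doubled)
  gk <- genome_markers(guide)
  dm <- key_marker(dk); gm <- key_marker(gk)
  guide_labels <- lapply(split(key_copy(gk), gm), c_sort)
  copies_by_m <- lapply(split(seq_along(dk), dm), function(i) i[c_order(dk[i])])
  if (!setequal(names(copies_by_m), names(guide_labels)))
    stop("marker content mismatch between doubled genome and guide")
  for (m in names(copies_by_m)) {
    if (length(copies_by_m[[m]]) != 2L * length(guide_labels[[m]]))
      stop("marker ", m, ": doubled multiplicity ", length(copies_by_m[[m]]),
           " != 2 x guide multiplicity ", length(guide_labels[[m]]))
  }
  markers <- c_sort(names(copies_by_m))
  mindex <- setNames(seq_along(markers), markers)
  kvec <- setNames(lengths(guide_labels)[markers], markers)
  kmax <- max(kvec)
  Emax <- length(markers) * kmax * 2L
  if (as.double(Emax)^2 > .Machine$integer.max)
    stop("instance too large for the matching engine")

  ## extremity code: ((mi-1)*kmax + (pidx-1))*2 + end01 + 1, end01: t=0, h=1
  ecode <- function(mi, pidx, end01) (mi - 1L) * kmax * 2L + (pidx - 1L) * 2L +
    end01 + 1L
  ecode_str <- function(code) {
    mi <- (code - 1L) %/% (kmax * 2L) + 1L
    rem <- (code - 1L) %% (kmax * 2L)
    pidx <- rem %/% 2L + 1L
    end <- if (rem %% 2L == 0L) "t" else "h"
    m <- markers[mi]
    paste0(m, ".", guide_labels[[m]][pidx], ":", end)
  }

  ## doubled adjacencies -> endpoint arrays
  dadj <- adjacency_set(doubled)
  nA <- length(dadj)
  ends <- adj_exts(dadj)
  ekey1 <- vapply(ends, function(p) ext_key(p[1]), "")
  eend1 <- vapply(ends, function(p) ext_end(p[1]), "")
  ekey2 <- vapply(ends, function(p) ext_key(p[2]), "")
  eend2 <- vapply(ends, function(p) ext_end(p[2]), "")
  c1 <- match(ekey1, dk); c2 <- match(ekey2, dk)
  mi1 <- mindex[key_marker(ekey1)]; mi2 <- mindex[key_marker(ekey2)]
  base1 <- (mi1 - 1L) * kmax * 2L + (eend1 == "h") + 1L
  base2 <- (mi2 - 1L) * kmax * 2L + (eend2 == "h") + 1L
  incident <- lapply(setNames(markers, markers), function(m)
    which(dm[c1] == m | dm[c2] == m))

  ## guide adjacencies -> pair-key flags
  gadj <- adjacency_set(guide)
  gends <- adj_exts(gadj)
  gcode <- function(e) {
    k <- ext_key(e); m <- key_marker(k)
    ecode(mindex[[m]], match(key_copy(k), guide_labels[[m]]),
          as.integer(ext_end(e) == "h"))
  }
  gflag <- logical(Emax * Emax)
  for (pp in gends) {
    a <- gcode(pp[1]); b <- gcode(pp[2])
    gflag[(min(a, b) - 1L) * Emax + max(a, b)] <- TRUE
  }

  ## assignment state: per copy, guide-copy index (pidx) and sub-genome (s)
  nC <- length(dk)
  cp_pidx <- integer(nC); cp_s <- integer(nC)
  votes <- integer(Emax * Emax)
  state <- new.env(parent = emptyenv())
  state$mismatch <- 0L
  state$total <- length(gadj)   # every guide adjacency starts unsupported

  pair_keys <- function(I) {
    a <- base1[I] + (cp_pidx[c1[I]] - 1L) * 2L
    b <- base2[I] + (cp_pidx[c2[I]] - 1L) * 2L
    (pmin(a, b) - 1L) * Emax + pmax(a, b)
  }
  costf <- function(v) as.numeric(v == 1L | v == 2L)
  rm_batch <- function(I) {
    if (!length(I)) return(invisible())
    m0 <- cp_s[c1[I]] == cp_s[c2[I]]
    nmis <- sum(!m0)
    if (nmis) {
      state$mismatch <- state$mismatch - nmis
      state$total <- state$total - nmis
    }
    K <- pair_keys(I[m0])
    if (length(K)) {
      uk <- unique(K)
      cnt <- tabulate(match(K, uk), length(uk))
      vold <- votes[uk]; vnew <- vold - cnt
      g <- as.integer(gflag[uk])
      state$total <- state$total + sum(costf(vnew + g) - costf(vold + g))
      votes[uk] <<- vnew
    }
    invisible()
  }
  add_batch <- function(I) {
    if (!length(I)) return(invisible())
    m0 <- cp_s[c1[I]] == cp_s[c2[I]]
    nmis <- sum(!m0)
    if (nmis) {
      state$mismatch <- state$mismatch + nmis
      state$total <- state$total + nmis
    }
    K <- pair_keys(I[m0])
    if (length(K)) {
      uk <- unique(K)
      cnt <- tabulate(match(K, uk), length(uk))
      vold <- votes[uk]; vnew <- vold + cnt
      g <- as.integer(gflag[uk])
      state$total <- state$total + sum(costf(vnew + g) - costf(vold + g))
      votes[uk] <<- vnew
    }
    invisible()
  }
  ## slot j (1..2k, guide-copy-major): pidx = (j-1) %/% 2 + 1, s = (j-1) %% 2
  set_marker <- function(m, perm) {
    I <- incident[[m]]
    rm_batch(I)
    cps <- copies_by_m[[m]]
    cp_pidx[cps] <<- (perm - 1L) %/% 2L + 1L
    cp_s[cps] <<- (perm - 1L) %% 2L
    add_batch(I)
  }

  ## initial identity assignment
  cur <- list()
  nperm <- numeric(length(markers)); names(nperm) <- markers
  for (m in markers) {
    n <- length(copies_by_m[[m]])
    cps <- copies_by_m[[m]]
    cp_pidx[cps] <- (seq_len(n) - 1L) %/% 2L + 1L
    cp_s[cps] <- (seq_len(n) - 1L) %% 2L
    cur[[m]] <- seq_len(n)
    nperm[[m]] <- factorial(n)
  }

  ## propagation initialization along doubled chromosomes: follow guide
  ## adjacencies where possible; when the guide lacks the adjacency,
  ## continue with the same sub-genome label on a free slot (post-WGD
  ## chromosomes are contiguous sub-genome segments)
  gpart <- integer(Emax)
  for (pp in gends) {
    a <- gcode(pp[1]); b <- gcode(pp[2])
    gpart[a] <- b; gpart[b] <- a
  }
  assigned <- logical(nC)
  slot_used <- lapply(copies_by_m, function(cps) logical(length(cps)))
  propose <- function(ci, m, pidx, s) {
    j <- (pidx - 1L) * 2L + s + 1L
    if (j > length(slot_used[[m]]) || slot_used[[m]][j]) return(FALSE)
    slot_used[[m]][j] <<- TRUE
    assigned[ci] <<- TRUE
    cp_pidx[ci] <<- pidx; cp_s[ci] <<- s
    TRUE
  }
  for (ch in doubled$chromosomes) {
    keys <- token_key(ch)
    cis <- match(keys, dk)
    mis <- mindex[key_marker(keys)]
    for (i in seq_along(keys)) {
      if (i == 1L) {
        if (!assigned[cis[i]]) {
          m <- markers[mis[i]]
          j <- which(!slot_used[[m]])[1]
          if (!is.na(j)) propose(cis[i], m, (j - 1L) %/% 2L + 1L,
                                 (j - 1L) %% 2L)
        }
        next
      }
      if (assigned[cis[i]] || !assigned[cis[i - 1L]]) next
      m <- markers[mis[i]]
      s_prev <- cp_s[cis[i - 1L]]
      prev_code <- ecode(mis[i - 1L], cp_pidx[cis[i - 1L]],
                         as.integer(ext_end(right_ext(ch[i - 1L])) == "h"))
      f <- gpart[prev_code]
      done <- FALSE
      if (f > 0L) {
        f_mi <- (f - 1L) %/% (kmax * 2L) + 1L
        rem <- (f - 1L) %% (kmax * 2L)
        f_pidx <- rem %/% 2L + 1L
        f_end <- rem %% 2L
        want_end <- as.integer(ext_end(left_ext(ch[i])) == "h")
        if (f_mi == mis[i] && f_end == want_end)
          done <- propose(cis[i], m, f_pidx, s_prev)
      }
      if (!done) {
        for (j in which(!slot_used[[m]])) {
          if ((j - 1L) %% 2L == s_prev &&
              propose(cis[i], m, (j - 1L) %/% 2L + 1L, s_prev)) break
        }
      }
    }
  }
  ## complete: unassigned copies take the remaining slots in sorted order
  for (m in markers) {
    cps <- copies_by_m[[m]]
    left_c <- cps[!assigned[cps]]
    left_j <- which(!slot_used[[m]])
    if (length(left_c)) {
      cp_pidx[left_c] <- (left_j[seq_along(left_c)] - 1L) %/% 2L + 1L
      cp_s[left_c] <- (left_j[seq_along(left_c)] - 1L) %% 2L
    }
    cur[[m]] <- (cp_pidx[cps] - 1L) * 2L + cp_s[cps] + 1L
  }
  ## build vote state under the initial assignment
  add_batch(seq_len(nA))

  perm_cache <- list()
  get_perms <- function(n) {
    key <- as.character(n)
    if (is.null(perm_cache[[key]])) perm_cache[[key]] <<- all_perms(n)
    perm_cache[[key]]
  }

  method <- "heuristic"
  if (prod(nperm) <= max_exhaustive) {
    method <- "exhaustive"
    best <- list(total = Inf, cur = cur)
    dfs <- function(idx) {
      if (idx > length(markers)) {
        if (state$total < best$total - 1e-9)
          best <<- list(total = state$total, cur = cur)
        return(invisible())
      }
      m <- markers[idx]
      for (perm in get_perms(length(copies_by_m[[m]]))) {
        set_marker(m, perm); cur[[m]] <<- perm
        dfs(idx + 1L)
      }
    }
    dfs(1L)
    for (m in markers) { set_marker(m, best$cur[[m]]); cur[[m]] <- best$cur[[m]] }
  } else {
    ## coherent slot transforms for chromosome-suffix moves: permute the
    ## guide-copy labels and/or swap the sub-genome label per guide copy.
    ## These fix the cost-neutral plateaus single-marker moves cannot leave.
    transforms <- list()
    pperms <- if (kmax >= 2L) list(c(1L, 2L), c(2L, 1L)) else list(1L)
    for (pp in pperms) for (f1 in c(FALSE, TRUE)) for (f2 in c(FALSE, TRUE)) {
      if (length(pp) == 1L && f2) next
      if (identical(pp, seq_along(pp)) && !f1 && !f2) next
      transforms[[length(transforms) + 1L]] <- list(pperm = pp,
                                                    sflip = c(f1, f2))
    }
    apply_suffix <- function(suffix_cis, tr) {
      touched <- unique(dm[suffix_cis])
      prev <- cur[touched]
      for (m in touched) {
        km <- kvec[[m]]
        cps <- copies_by_m[[m]]
        oldj <- (cp_pidx[cps] - 1L) * 2L + cp_s[cps] + 1L
        newj <- oldj
        in_suf <- cps %in% suffix_cis
        for (ci in which(in_suf)) {
          pi <- (oldj[ci] - 1L) %/% 2L + 1L
          si <- (oldj[ci] - 1L) %% 2L
          pi2 <- if (km >= 2L) tr$pperm[pi] else pi
          si2 <- if (tr$sflip[min(pi2, length(tr$sflip))]) 1L - si else si
          newj[ci] <- (pi2 - 1L) * 2L + si2 + 1L
        }
        left <- setdiff(seq_along(cps), newj[in_suf])
        out <- which(!in_suf)
        out <- out[order(oldj[out])]
        newj[out] <- left[seq_along(out)]
        set_marker(m, newj)
        cur[[m]] <<- newj
      }
      prev
    }
    revert <- function(prev) {
      for (m in names(prev)) { set_marker(m, prev[[m]]); cur[[m]] <<- prev[[m]] }
    }
    marker_sweep <- function() {
      improved <- FALSE
      for (m in markers) {
        best_perm <- cur[[m]]; best_total <- state$total
        for (perm in get_perms(length(copies_by_m[[m]]))) {
          if (identical(perm, cur[[m]])) next
          set_marker(m, perm)
          if (state$total < best_total - 1e-9) {
            best_total <- state$total; best_perm <- perm
          }
        }
        set_marker(m, best_perm)
        if (!identical(best_perm, cur[[m]])) improved <- TRUE
        cur[[m]] <<- best_perm
      }
      improved
    }
    ## windows considered for coherent flips start and end at positions
    ## where the current assignment disagrees with the guide (s-mismatch or
    ## an adjacency the guide lacks); flipping inside a fully aligned run
    ## can only lose agreement, so those windows are skipped
    window_sweep <- function() {
      if (kmax > 2L) return(FALSE)
      improved <- FALSE
      for (ch in doubled$chromosomes) {
        cis <- match(token_key(ch), dk)
        L <- length(cis)
        if (L < 1L) next
        mis <- mindex[key_marker(token_key(ch))]
        enda <- as.integer(ext_end(right_ext(ch)) == "h")
        endb <- as.integer(ext_end(left_ext(ch)) == "h")
        aligned <- function(t) {
          if (cp_s[cis[t - 1L]] != cp_s[cis[t]]) return(FALSE)
          a <- ecode(mis[t - 1L], cp_pidx[cis[t - 1L]], enda[t - 1L])
          b <- ecode(mis[t], cp_pidx[cis[t]], endb[t])
          gflag[(min(a, b) - 1L) * Emax + max(a, b)]
        }
        bnd <- c(1L, if (L > 1L) (2:L)[!vapply(2:L, aligned, logical(1))],
                 L + 1L)
        bnd <- unique(bnd)
        for (bi in seq_len(length(bnd) - 1L)) for (bj in (bi + 1L):length(bnd)) {
          win <- cis[bnd[bi]:(bnd[bj] - 1L)]
          for (tr in transforms) {
            before <- state$total
            prev <- apply_suffix(win, tr)
            if (state$total < before - 1e-9) improved <- TRUE else revert(prev)
          }
        }
      }
      improved
    }
    for (sweep in seq_len(max_sweeps)) {
      imp <- marker_sweep()
      imp <- window_sweep() || imp
      if (!imp) break
    }
  }

  ## majority-vote support table in string space
  vk <- which(votes > 0L)
  adj_str <- vapply(vk, function(key) {
    lo <- (key - 1L) %/% Emax + 1L
    hi <- (key - 1L) %% Emax + 1L
    paste(c_sort(c(ecode_str(lo), ecode_str(hi))), collapse = "|")
  }, "")
  gstr <- vapply(gadj, function(a) {
    pp <- adj_exts(a)[[1]]
    paste(c_sort(c(ecode_str(gcode(pp[1])), ecode_str(gcode(pp[2])))),
          collapse = "|")
  }, "")
  support <- data.frame(adjacency = adj_str, proj_votes = votes[vk],
                        guide_vote = as.integer(gflag[vk]),
                        stringsAsFactors = FALSE)
  extra_g <- gstr[!gstr %in% adj_str]
  if (length(extra_g)) {
    support <- rbind(support, data.frame(adjacency = extra_g,
                                         proj_votes = 0L, guide_vote = 1L,
                                         stringsAsFactors = FALSE))
  }
  support$votes <- support$proj_votes + support$guide_vote
  support <- support[c_order(support$adjacency), , drop = FALSE]
  rownames(support) <- NULL

  plabel <- vapply(seq_len(nC), function(ci) {
    guide_labels[[dm[ci]]][cp_pidx[ci]]
  }, "")
  assignment <- data.frame(key = dk, marker = dm, p = plabel, s = cp_s,
                           row.names = NULL, stringsAsFactors = FALSE)
  list(assignment = assignment, cost = state$total, method = method,
       support = support, collapsed_markers = unique(gk))
}


#' Match duplicated copies against a guide genome (MO)
#'
#' Pairs the `2k` copies of every marker in `genome` into `k` pairs labelled
#' by the guide's `k` copies, so that the implied guided-halving objective
#' (SCJ distance from the paired doubling of the majority-vote ancestor to
#' `genome`, plus SCJ distance from the ancestor to `guide`) is minimal.
#' Small instances are solved exhaustively; larger ones by seeded propagation
#' along chromosomes followed by local-improvement sweeps.
#'
#' @param genome `scj_genome` with `2k` copies of every marker
#' @param guide `scj_genome` with `k` copies of every marker
#' @param max_exhaustive exhaustive search bound on the number of joint
#'   assignments
#' @return a `matching_solution`: `assignment` (copy key -> guide label `p`,
#'   sub-genome `s`), `cost`, `method`, per-adjacency `support`
#' @export
match_copies <- function(genome, guide, max_exhaustive = 20000L) {
  res <- mo_engine(genome, guide, max_exhaustive = max_exhaustive)
  structure(res, class = "matching_solution")
}

#' @export
print.matching_solution <- function(x, ...) {
  cat(sprintf("<matching_solution: %d copies matched, cost %g, method %s>\n",
              nrow(x$assignment), x$cost, x$method))
  invisible(x)
}

#' SCJ genome median of three genomes (GMP)
#'
#' For identical labelled marker content the SCJ median is exactly the set of
#' adjacencies present in at least two of the three genomes; any two majority
#' adjacencies co-occur in some input genome, so the set is conflict-free.
#'
#' @param g1,g2,g3 `scj_genome` objects with identical labelled content
#' @return list: `genome` (linearized median), `total_distance`, `support`
#' @export
scj_median <- function(g1, g2, g3) {
  m <- c_sort(genome_markers(g1))
  if (!identical(m, c_sort(genome_markers(g2))) ||
      !identical(m, c_sort(genome_markers(g3))))
    stop("marker content mismatch among median inputs")
  a1 <- adjacency_set(g1); a2 <- adjacency_set(g2); a3 <- adjacency_set(g3)
  all_adj <- c_sort(unique(c(a1, a2, a3)))
  votes <- (all_adj %in% a1) + (all_adj %in% a2) + (all_adj %in% a3)
  maj <- all_adj[votes >= 2]
  exts <- unlist(adj_exts(maj), use.names = FALSE)
  if (anyDuplicated(exts))
    stop("internal error: majority adjacency set is not conflict-free")
  med <- linearize(maj, m, name = "median")
  total <- scj_set_distance(adjacency_set(med), a1) +
    scj_set_distance(adjacency_set(med), a2) +
    scj_set_distance(adjacency_set(med), a3)
  list(genome = med,
       total_distance = total,
       support = data.frame(adjacency = all_adj, votes = votes,
                            stringsAsFactors = FALSE))
}

#' Guided genome halving under SCJ (GGHP)
#'
#' Finds the single-copy ancestor of a doubled genome (two copies per
#' marker), guided by an outgroup with one copy per marker.  The copy
#' matching fixes which copy belongs to which post-WGD sub-genome
#' ([match_copies()] with `k = 1`); given the matching, an ancestral
#' adjacency is included iff it is present in at least two of {sub-genome 1,
#' sub-genome 2, guide}.
#'
#' @param doubled `scj_genome` with exactly two copies per marker
#' @param guide `scj_genome` with one copy per marker
#' @param max_exhaustive passed to the matching engine
#' @return list: `ancestor` (`scj_genome` on the guide's labels),
#'   `total_distance` (halving objective), `matching`, `support`,
#'   `opened_cycles`
#' @export
guided_halving <- function(doubled, guide, max_exhaustive = 20000L) {
  res <- mo_engine(doubled, guide, max_exhaustive = max_exhaustive)
  maj <- res$support$adjacency[res$support$votes >= 2]
  exts <- unlist(adj_exts(maj), use.names = FALSE)
  if (anyDuplicated(exts))
    stop("internal error: majority adjacency set is not conflict-free")
  anc <- linearize(maj, unique(res$collapsed_markers), name = "ancestor")
  structure(list(ancestor = anc, total_distance = res$cost,
                 matching = structure(res, class = "matching_solution"),
                 support = res$support,
                 opened_cycles = attr(anc, "opened")),
            class = "halving_solution")
}

#' @export
print.halving_solution <- function(x, ...) {
  cat(sprintf("<halving_solution: ancestor with %d chromosomes, objective %g>\n",
              n_chromosomes(x$ancestor), x$total_distance))
  invisible(x)
}

#' Relabel copies of a genome against an equal-multiplicity anchor
#'
#' Chooses, independently per marker, a bijection between the genome's copy
#' labels and the anchor's so that the SCJ distance to the anchor is minimal
#' (propagation-seeded local search; exhaustive on small instances).  Used to
#' harmonize the in-silico doubled outgroup with the anchor's label space
#' before taking a median.
#'
#' @param g `scj_genome`
#' @param anchor `scj_genome` with the same markers and multiplicities
#' @param max_exhaustive exhaustive bound on joint label choices
#' @return list: `genome` (relabelled), `distance`, `mapping`
#' @export
relabel_against <- function(g, anchor, max_exhaustive = 20000L) {
  gk <- genome_markers(g); ak <- genome_markers(anchor)
  gsplit <- split(key_copy(gk), key_marker(gk))
  asplit <- split(key_copy(ak), key_marker(ak))
  if (!setequal(names(gsplit), names(asplit)))
    stop("marker content mismatch between genome and anchor")
  if (!all(lengths(gsplit)[names(asplit)] == lengths(asplit)))
    stop("copy multiplicity mismatch between genome and anchor")
  markers <- c_sort(names(gsplit))
  gsplit <- lapply(gsplit, c_sort); asplit <- lapply(asplit, c_sort)

  aadj <- adjacency_set(anchor)
  in_anchor <- new.env(hash = TRUE, parent = emptyenv())
  for (a in aadj) assign(a, TRUE, envir = in_anchor)

  gadj <- adjacency_set(g)
  ends <- adj_exts(gadj)
  a_key1 <- vapply(ends, function(p) ext_key(p[1]), "")
  a_end1 <- vapply(ends, function(p) ext_end(p[1]), "")
  a_key2 <- vapply(ends, function(p) ext_key(p[2]), "")
  a_end2 <- vapply(ends, function(p) ext_end(p[2]), "")
  a_m1 <- key_marker(a_key1); a_m2 <- key_marker(a_key2)
  incident <- lapply(setNames(markers, markers), function(m)
    which(a_m1 == m | a_m2 == m))

  lab <- character()   # copy key -> anchor label
  state <- new.env(parent = emptyenv()); state$matches <- 0L
  mapped_key <- function(i) {
    e1 <- paste0(a_m1[i], ".", lab[[a_key1[i]]], ":", a_end1[i])
    e2 <- paste0(a_m2[i], ".", lab[[a_key2[i]]], ":", a_end2[i])
    paste(c_sort(c(e1, e2)), collapse = "|")
  }
  add <- function(i) if (!is.null(get0(mapped_key(i), envir = in_anchor)))
    state$matches <- state$matches + 1L
  rm_ <- function(i) if (!is.null(get0(mapped_key(i), envir = in_anchor)))
    state$matches <- state$matches - 1L
  set_marker <- function(m, perm) {
    for (i in incident[[m]]) rm_(i)
    for (j in seq_along(gsplit[[m]])) {
      key <- paste0(m, ".", gsplit[[m]][j])
      lab[[key]] <<- asplit[[m]][perm[j]]
    }
    for (i in incident[[m]]) add(i)
  }
  cur <- list()
  for (m in markers) {
    for (j in seq_along(gsplit[[m]]))
      lab[[paste0(m, ".", gsplit[[m]][j])]] <- asplit[[m]][j]
    cur[[m]] <- seq_along(gsplit[[m]])
  }
  for (i in seq_along(gadj)) add(i)

  nperm <- vapply(markers, function(m) factorial(length(gsplit[[m]])), 0)
  perm_cache <- list()
  get_perms <- function(n) {
    key <- as.character(n)
    if (is.null(perm_cache[[key]])) perm_cache[[key]] <<- all_perms(n)
    perm_cache[[key]]
  }
  if (prod(nperm) <= max_exhaustive) {
    best <- list(matches = -Inf, cur = cur)
    dfs <- function(idx) {
      if (idx > length(markers)) {
        if (state$matches > best$matches) best <<- list(matches = state$matches,
                                                        cur = cur)
        return(invisible())
      }
      m <- markers[idx]
      for (perm in get_perms(length(gsplit[[m]]))) {
        set_marker(m, perm); cur[[m]] <<- perm
        dfs(idx + 1L)
      }
    }
    dfs(1L)
    for (m in markers) { set_marker(m, best$cur[[m]]); cur[[m]] <- best$cur[[m]] }
  } else {
    marker_sweep <- function() {
      improved <- FALSE
      for (m in markers) {
        best_perm <- cur[[m]]; best_m <- state$matches
        for (perm in get_perms(length(gsplit[[m]]))) {
          if (identical(perm, cur[[m]])) next
          set_marker(m, perm)
          if (state$matches > best_m) { best_m <- state$matches; best_perm <- perm }
        }
        set_marker(m, best_perm)
        if (!identical(best_perm, cur[[m]])) improved <- TRUE
        cur[[m]] <<- best_perm
      }
      improved
    }
    ## window moves: swap the two copy labels coherently for a run of
    ## markers on one chromosome (multiplicity-2 markers only); escapes the
    ## label-swap plateaus single-marker moves cannot leave
    window_sweep <- function() {
      improved <- FALSE
      in_anchor_now <- function(ch, t) {
        k1 <- token_key(ch[t - 1L]); k2 <- token_key(ch[t])
        e1 <- paste0(key_marker(k1), ".", lab[[k1]], ":",
                     ext_end(right_ext(ch[t - 1L])))
        e2 <- paste0(key_marker(k2), ".", lab[[k2]], ":",
                     ext_end(left_ext(ch[t])))
        !is.null(get0(paste(c_sort(c(e1, e2)), collapse = "|"),
                      envir = in_anchor))
      }
      for (ch in g$chromosomes) {
        ms <- key_marker(token_key(ch))
        L <- length(ms)
        bnd <- c(1L, if (L > 1L)
          (2:L)[!vapply(2:L, function(t) in_anchor_now(ch, t), logical(1))],
          L + 1L)
        bnd <- unique(bnd)
        for (bi in seq_len(length(bnd) - 1L)) for (bj in (bi + 1L):length(bnd)) {
          touched <- unique(ms[bnd[bi]:(bnd[bj] - 1L)])
          touched <- touched[vapply(touched, function(m)
            length(gsplit[[m]]) == 2L, logical(1))]
          if (!length(touched)) next
          prev <- cur[touched]
          before <- state$matches
          for (m in touched) {
            swapped <- rev(cur[[m]])
            set_marker(m, swapped); cur[[m]] <<- swapped
          }
          if (state$matches > before) improved <- TRUE else {
            for (m in touched) { set_marker(m, prev[[m]]); cur[[m]] <<- prev[[m]] }
          }
        }
      }
      improved
    }
    for (sweep in seq_len(25L)) {
      imp <- marker_sweep()
      imp <- window_sweep() || imp
      if (!imp) break
    }
  }
  ## build the relabelled genome
  relab <- lapply(g$chromosomes, function(ch) {
    k <- token_key(ch)
    paste0(token_sign(ch), key_marker(k), ".",
           vapply(k, function(x) lab[[x]], ""))
  })
  out <- genome(relab, name = g$name)
  list(genome = canonical_genome(out),
       distance = scj_distance(out, anchor),
       mapping = data.frame(key = gk,
                            label = vapply(gk, function(x) lab[[x]], ""),
                            row.names = NULL, stringsAsFactors = FALSE))
}

## ---------------------------------------------------------------------------
## Stage 3: gene order within blocks
## ---------------------------------------------------------------------------

#' Order pPGs within a block by greedy topological sorting
#'
#' Builds a directed weighted graph over the block's pPGs: an edge `u -> v`
#' with weight equal to the number of block copies where `u` immediately
#' precedes `v` (copies on the minus strand are reverse-complemented first).
#' Cycles are broken by deleting the lowest-weight edge of each cycle (ties:
#' lexicographically smallest edge); the greedy topological order emits,
#' among in-degree-0 nodes, the one with the greatest total outgoing weight
#' (ties lexicographic).
#'
#' @param block one element of a `synteny_blocks` object
#' @param painted the [paint_genomes()] result the blocks were located in
#' @return character vector of signed pPG ids (majority sign per pPG)
#' @export
order_genes_in_block <- function(block, painted) {
  if (is.null(block$copies) || !nrow(block$copies)) stop("empty block")
  members <- substring(block$ppg_order, 2)
  seqs <- list()
  for (r in seq_len(nrow(block$copies))) {
    cp <- block$copies[r, ]
    ch <- painted$genomes[[cp$genome]]$chromosomes[[cp$chromosome]]
    toks <- ch[cp$start_index:cp$end_index]
    toks <- toks[key_marker(token_key(toks)) %in% members]
    signed <- paste0(token_sign(toks), key_marker(token_key(toks)))
    if (cp$sign == "-") signed <- rev(flip_signed(signed))
    seqs[[r]] <- signed
  }
  ## edge weights
  w <- new.env(hash = TRUE, parent = emptyenv())
  for (s in seqs) {
    if (length(s) < 2) next
    u <- substring(s[-length(s)], 2); v <- substring(s[-1], 2)
    for (j in seq_along(u)) {
      k <- paste(u[j], v[j], sep = "\r")
      assign(k, get0(k, envir = w, ifnotfound = 0L) + 1L, envir = w)
    }
  }
  ekeys <- ls(w)
  if (length(ekeys)) {
    eu <- vapply(strsplit(ekeys, "\r"), `[`, "", 1L)
    ev <- vapply(strsplit(ekeys, "\r"), `[`, "", 2L)
    ew <- vapply(ekeys, function(k) get(k, envir = w), 0L)
  } else eu <- ev <- character(0)

  nodes <- c_sort(unique(members))
  edges <- data.frame(u = eu, v = ev, w = if (length(ekeys)) ew else integer(),
                      stringsAsFactors = FALSE)
  ## break cycles: delete lowest-weight edge per cycle, ties lexicographic
  find_cycle <- function(edges) {
    adj <- split(seq_len(nrow(edges)), edges$u)
    color <- setNames(rep(0L, length(nodes)), nodes)
    stack_e <- integer()
    res <- NULL
    dfs <- function(u) {
      color[[u]] <<- 1L
      for (ei in adj[[u]] %||% integer()) {
        v <- edges$v[ei]
        if (color[[v]] == 1L) {
          path_u <- edges$u[stack_e]
          k <- which(path_u == v)
          res <<- c(if (length(k)) stack_e[k[length(k)]:length(stack_e)], ei)
          return(TRUE)
        }
        if (color[[v]] == 0L) {
          stack_e <<- c(stack_e, ei)
          if (dfs(v)) return(TRUE)
          stack_e <<- stack_e[-length(stack_e)]
        }
      }
      color[[u]] <<- 2L
      FALSE
    }
    for (n in nodes) if (color[[n]] == 0L && dfs(n)) return(res)
    NULL
  }
  repeat {
    cyc <- find_cycle(edges)
    if (is.null(cyc)) break
    sub <- edges[cyc, , drop = FALSE]
    cand <- cyc[sub$w == min(sub$w)]
    lbl <- paste(edges$u[cand], edges$v[cand])
    drop <- cand[c_order(lbl)[1]]
    edges <- edges[-drop, , drop = FALSE]
  }
  ## greedy topological order
  out_w <- vapply(nodes, function(n) sum(edges$w[edges$u == n]), 0)
  indeg <- vapply(nodes, function(n) sum(edges$v == n), 0)
  remaining <- nodes
  order_out <- character()
  while (length(remaining)) {
    zero <- remaining[indeg[remaining] == 0]
    if (!length(zero)) stop("internal error: no in-degree-0 node after cycle removal")
    pick <- zero[order(-out_w[zero], zero, method = "radix")][1]
    order_out <- c(order_out, pick)
    drop_e <- edges$u == pick
    for (v in edges$v[drop_e]) indeg[[v]] <- indeg[[v]] - 1L
    edges <- edges[!drop_e, , drop = FALSE]
    remaining <- setdiff(remaining, pick)
  }
  ## majority sign per pPG over normalized copies (ties: "+")
  sign_votes <- list()
  for (s in seqs) {
    for (tok in s) {
      p <- substring(tok, 2)
      sign_votes[[p]] <- c(sign_votes[[p]], substr(tok, 1, 1))
    }
  }
  sgn <- vapply(order_out, function(p) {
    v <- sign_votes[[p]]
    if (sum(v == "-") > sum(v == "+")) "-" else "+"
  }, "")
  paste0(sgn, order_out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## Bottom-up ancestor reconstruction
## ---------------------------------------------------------------------------

#' Reconstruct pre- and post-WGD-1 ancestors from synteny blocks
#'
#' Three steps on the block-level genomes: (A) guided halving of the
#' twice-duplicated genome against the once-duplicated guide gives the
#' pre-WGD-2 ancestor; (B) the in-silico doubled no-WGD genome is relabelled
#' against the once-duplicated anchor and the SCJ median of
#' {pre-WGD-2 ancestor, once-duplicated genome, doubled no-WGD genome}
#' gives the post-WGD-1 ancestor; (C) guided halving of that ancestor
#' against the no-WGD genome gives the pre-WGD-1 ancestor.
#'
#' @param blocks ratio-filtered (and optionally filled) `synteny_blocks`
#' @param painted the [paint_genomes()] result
#' @param ratio named copy-ratio vector identifying the no-WGD (1), one-WGD
#'   (2) and two-WGD (4) genomes
#' @param median_mode `"double"` votes with the relabelled doubled no-WGD
#'   genome; `"single"` lets the no-WGD genome vote label-free
#' @param max_exhaustive exhaustive bound for the matching engine
#' @return an `ancestor_set`: genomes `pre_wgd1`, `post_wgd1`, `pre_wgd2`,
#'   per-adjacency `support`, `opened_cycles`, copy `assignments`, and the
#'   per-block `orders` from [order_genes_in_block()]
#' @export
reconstruct_ancestors <- function(blocks, painted,
                                  ratio = c(R = 1, P = 2, S = 4),
                                  median_mode = c("double", "single"),
                                  max_exhaustive = 20000L) {
  median_mode <- match.arg(median_mode)
  cc <- block_copy_counts(blocks)
  if (!nrow(cc)) stop("no synteny blocks to reconstruct from")
  for (gn in names(ratio)) {
    bad <- cc$block_id[is.na(cc[[gn]]) | cc[[gn]] != ratio[[gn]]]
    if (length(bad))
      stop("block(s) violating the copy ratio in ", gn, ": ",
           paste(head(bad, 5), collapse = ", "), "; filter blocks first")
  }
  gn1 <- names(ratio)[ratio == 1]
  gn2 <- names(ratio)[ratio == 2]
  gn4 <- names(ratio)[ratio == 4]
  if (length(gn1) != 1 || length(gn2) != 1 || length(gn4) != 1)
    stop("ratio must identify exactly one genome each with 1, 2 and 4 copies")
  bg <- block_genomes(blocks, painted)

  ## Step A: halve the 4-copy genome guided by the 2-copy genome
  stepA <- guided_halving(bg[[gn4]], bg[[gn2]], max_exhaustive = max_exhaustive)
  pre_wgd2 <- stepA$ancestor; pre_wgd2$name <- "preWGD2"

  ## Step B: median with the (relabelled) doubled no-WGD genome
  r2 <- apply_wgd(bg[[gn1]], name = paste0(gn1, "x2"))
  rl <- relabel_against(r2, bg[[gn2]], max_exhaustive = max_exhaustive)
  if (median_mode == "double") {
    med <- scj_median(pre_wgd2, bg[[gn2]], rl$genome)
  } else {
    med <- scj_median_label_free(pre_wgd2, bg[[gn2]], bg[[gn1]])
  }
  post_wgd1 <- med$genome; post_wgd1$name <- "postWGD1"

  ## Step C: halve the post-WGD-1 ancestor guided by the no-WGD genome
  stepC <- guided_halving(post_wgd1, bg[[gn1]], max_exhaustive = max_exhaustive)
  pre_wgd1 <- stepC$ancestor; pre_wgd1$name <- "preWGD1"

  orders <- lapply(blocks$blocks, function(b)
    order_genes_in_block(b, painted))
  names(orders) <- vapply(blocks$blocks, function(b) b$block_id, "")

  structure(list(
    pre_wgd1 = pre_wgd1, post_wgd1 = post_wgd1, pre_wgd2 = pre_wgd2,
    support = list(stepA = stepA$support, median = med$support,
                   stepC = stepC$support),
    opened_cycles = length(stepA$opened_cycles) +
      length(attr(med$genome, "opened")) + length(stepC$opened_cycles),
    assignments = list(stepA = stepA$matching$assignment,
                       relabel = rl$mapping,
                       stepC = stepC$matching$assignment),
    orders = orders,
    genomes = setNames(c(gn1, gn2, gn4), c("none", "one", "two")),
    total_distances = c(stepA = stepA$total_distance,
                        median = med$total_distance,
                        stepC = stepC$total_distance)),
    class = "ancestor_set")
}

## median where the single-copy outgroup votes for a collapsed adjacency
## irrespective of copy labels
scj_median_label_free <- function(g1, g2, outgroup) {
  m <- c_sort(genome_markers(g1))
  stopifnot(identical(m, c_sort(genome_markers(g2))))
  a1 <- adjacency_set(g1); a2 <- adjacency_set(g2)
  strip <- function(adj) {
    vapply(adj_exts(adj), function(p) {
      e <- paste0(key_marker(ext_key(p)), ":", ext_end(p))
      paste(c_sort(e), collapse = "|")
    }, "")
  }
  og <- unique(strip(adjacency_set(outgroup)))
  all_adj <- c_sort(unique(c(a1, a2)))
  votes <- (all_adj %in% a1) + (all_adj %in% a2) + (strip(all_adj) %in% og)
  maj <- all_adj[votes >= 2]
  exts <- unlist(adj_exts(maj), use.names = FALSE)
  if (anyDuplicated(exts)) {
    ## label-free outgroup votes can create conflicts; resolve by keeping the
    ## better-voted adjacency (ties lexicographic)
    keep <- rep(TRUE, length(maj))
    v <- votes[match(maj, all_adj)]
    o <- order(-v, maj, method = "radix")
    used <- new.env(hash = TRUE, parent = emptyenv())
    for (i in o) {
      pr <- adj_exts(maj[i])[[1]]
      if (!is.null(get0(pr[1], envir = used)) ||
          !is.null(get0(pr[2], envir = used))) { keep[i] <- FALSE; next }
      assign(pr[1], TRUE, envir = used); assign(pr[2], TRUE, envir = used)
    }
    maj <- maj[keep]
  }
  med <- linearize(maj, m, name = "median")
  total <- scj_set_distance(adjacency_set(med), a1) +
    scj_set_distance(adjacency_set(med), a2)
  list(genome = med, total_distance = total,
       support = data.frame(adjacency = all_adj, votes = votes,
                            stringsAsFactors = FALSE))
}

#' @export
print.ancestor_set <- function(x, ...) {
  cat("<ancestor_set>\n")
  for (nm in c("pre_wgd1", "post_wgd1", "pre_wgd2"))
    cat(sprintf("  %-9s %3d chromosomes, %4d block copies\n", nm,
                n_chromosomes(x[[nm]]), n_marker_copies(x[[nm]])))
  cat("  opened cycles:", x$opened_cycles, "\n")
  invisible(x)
}

#' Expand a block-level ancestor to pPG (gene) level
#'
#' Replaces every signed block token by its ordered pPG content (from
#' [order_genes_in_block()] via `ancestors$orders`, or the block's
#' `ppg_order`), reverse-complemented for minus-sign blocks.  pPG copies
#' inherit the block's copy label.
#'
#' @param ancestor_genome block-level `scj_genome` (e.g. `pre_wgd1`)
#' @param orders named list block_id -> signed pPG vector
#' @return `scj_genome` over pPG markers
#' @export
expand_ancestor <- function(ancestor_genome, orders) {
  chroms <- lapply(ancestor_genome$chromosomes, function(ch) {
    unlist(lapply(ch, function(tok) {
      b <- key_marker(token_key(tok)); cp <- key_copy(token_key(tok))
      ord <- orders[[b]]
      if (is.null(ord)) stop("no pPG order for block ", b)
      if (token_sign(tok) == "-") ord <- rev(flip_signed(ord))
      mk_token(substring(ord, 2), cp, substr(ord, 1, 1))
    }), use.names = FALSE)
  })
  genome(chroms, name = ancestor_genome$name)
}

#' Adjacency precision, recall and F1 between two genomes
#'
#' Copy labels are ignored on both sides (every copy is relabelled 0), which
#' compares single-copy genomes such as a reconstructed and a true pre-WGD
#' ancestor on marker content alone.
#'
#' @param predicted,truth `scj_genome` objects with single-copy markers
#' @return named numeric vector `precision, recall, f1`
#' @export
adjacency_f1 <- function(predicted, truth) {
  strip0 <- function(g) {
    genome(lapply(g$chromosomes, function(ch)
      mk_token(key_marker(token_key(ch)), 0L, token_sign(ch))), name = g$name)
  }
  pa <- adjacency_set(strip0(predicted))
  ta <- adjacency_set(strip0(truth))
  tp <- length(intersect(pa, ta))
  prec <- if (length(pa)) tp / length(pa) else 0
  rec <- if (length(ta)) tp / length(ta) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(precision = prec, recall = rec, f1 = f1)
}

#' Rename the markers of a genome through a mapping
#' @param g an `scj_genome`
#' @param map named character vector old marker id -> new marker id
#' @return `scj_genome`
#' @export
rename_markers <- function(g, map) {
  chroms <- lapply(g$chromosomes, function(ch) {
    k <- token_key(ch)
    m <- key_marker(k)
    new <- map[m]
    if (anyNA(new)) stop("no mapping for marker(s): ",
                         paste(head(unique(m[is.na(new)]), 5), collapse = ", "))
    mk_token(new, key_copy(k), token_sign(ch))
  })
  genome(chroms, name = g$name)
}
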