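## ---------------------------------------------------------------------------
## Ground-truthed simulator of the two-WGD, three-species scenario:
##
##   pre-WGD-1 ancestor (6 chromosomes)
##     |-- branch R  (no WGD)                      -> genome R
##     `-- WGD-1 -> shared stem events -> post-WGD-1 ancestor (P/S split)
##           |-- branch P                          -> genome P
##           `-- branch S: pre-WGD-2 events -> WGD-2 -> post-WGD-2 events
##                                                   -> genome S
##
## Branch lengths in years are labels of the emulated scenario (speciations
## ~7.7 and ~4.9 Mya, WGDs ~7.2 and ~4.0 Mya); the simulator works in event
## counts, not time.
## ---------------------------------------------------------------------------

#' Parameters of the three-species two-WGD scenario
#'
#' @param n_chromosomes_ancestor chromosomes of the pre-WGD-1 ancestor
#' @param n_markers total markers in the ancestor
#' @param events_per_branch named list over branches `R`, `stem`, `P`,
#'   `S_pre`, `S_post`; each entry is either a single integer (event kinds
#'   drawn from `event_mix`) or a named vector
#'   `c(fission=, fusion=, translocation=)` of exact counts
#' @param event_mix probabilities of `fission`, `fusion`, `translocation`
#'   when a branch gives only a total count
#' @param loss_rate probability that a marker copy is deleted on a branch
#' @param ortholog_noise `c(missing=, spurious=)` edge rates for the emitted
#'   ortholog table
#' @param seed integer seed; the whole scenario is deterministic given it
#' @return a `scenario_params` list
#' @export
scenario_params <- function(n_chromosomes_ancestor = 6L,
                            n_markers = 200L,
                            events_per_branch = list(
                              R = c(fission = 5, fusion = 4, translocation = 0),
                              stem = c(fission = 11, fusion = 12, translocation = 0),
                              P = c(fission = 0, fusion = 0, translocation = 0),
                              S_pre = c(fission = 0, fusion = 0, translocation = 0),
                              S_post = c(fission = 20, fusion = 20, translocation = 0)),
                            event_mix = c(fission = 0.4, fusion = 0.4,
                                          translocation = 0.2),
                            loss_rate = 0,
                            ortholog_noise = c(missing = 0, spurious = 0),
                            seed = 1L) {
  if (n_markers < n_chromosomes_ancestor)
    stop("n_markers must be >= n_chromosomes_ancestor")
  if (abs(sum(event_mix) - 1) > 1e-9 || any(event_mix < 0))
    stop("event_mix must be non-negative probabilities summing to 1")
  if (loss_rate < 0 || loss_rate > 1) stop("loss_rate must be in [0, 1]")
  if (any(ortholog_noise < 0) || any(ortholog_noise > 1))
    stop("ortholog_noise rates must be in [0, 1]")
  need <- c("R", "stem", "P", "S_pre", "S_post")
  if (!all(need %in% names(events_per_branch)))
    stop("events_per_branch must name branches: ", paste(need, collapse = ", "))
  structure(list(n_chromosomes_ancestor = as.integer(n_chromosomes_ancestor),
                 n_markers = as.integer(n_markers),
                 events_per_branch = events_per_branch,
                 event_mix = event_mix, loss_rate = loss_rate,
                 ortholog_noise = ortholog_noise, seed = as.integer(seed)),
            class = "scenario_params")
}

#' Named simulation presets
#'
#' `"papaver-minima"` encodes the emulated scenario: a six-chromosome ancestor
#' and, per branch, the minimal fission/fusion counts implied by the three
#' modern karyotypes (5/4 on the no-WGD branch, 11/12 on the shared
#' post-WGD-1 stem, 20/20 after the lineage-specific WGD-2), no gene loss and
#' noise-free ortholog tables.  1000 markers keep the breakpoint density per
#' marker adjacency low, as in the real multi-thousand-gene genomes, so
#' conserved runs stay long relative to the block-length threshold while the
#' scenario remains desk-scale.
#'
#' @param name preset name
#' @param seed integer seed
#' @param n_markers marker count override
#' @return a [scenario_params()] object
#' @export
scenario_preset <- function(name = "papaver-minima", seed = 1L,
                            n_markers = 1000L) {
  switch(name,
    "papaver-minima" = scenario_params(
      n_chromosomes_ancestor = 6L, n_markers = n_markers,
      events_per_branch = list(
        R = c(fission = 5, fusion = 4, translocation = 0),
        stem = c(fission = 11, fusion = 12, translocation = 0),
        P = c(fission = 0, fusion = 0, translocation = 0),
        S_pre = c(fission = 0, fusion = 0, translocation = 0),
        S_post = c(fission = 20, fusion = 20, translocation = 0)),
      loss_rate = 0, ortholog_noise = c(missing = 0, spurious = 0),
      seed = seed),
    stop("unknown preset: ", name))
}

#' Simulate the pre-WGD-1 ancestor
#'
#' Markers `m1..mN` are laid out in `n_chromosomes` contiguous runs with
#' random run boundaries and random orientations; deterministic given the
#' seed set by the caller.
#'
#' @param params a [scenario_params()]
#' @return an `scj_genome` with one copy (label 0) of every marker
#' @export
simulate_ancestor <- function(params) {
  n <- params$n_markers; k <- params$n_chromosomes_ancestor
  if (n < k) stop("n_markers must be >= n_chromosomes_ancestor")
  cuts <- if (k > 1) sort(sample(seq_len(n - 1L), k - 1L)) else integer()
  bounds <- c(0L, cuts, n)
  signs <- sample(c("+", "-"), n, replace = TRUE)
  chroms <- lapply(seq_len(k), function(i) {
    idx <- (bounds[i] + 1L):bounds[i + 1L]
    mk_token(paste0("m", idx), 0L, signs[idx])
  })
  genome(chroms, name = "preWGD1")
}

#' Apply a whole-genome duplication
#'
#' Every chromosome is duplicated; each new marker copy receives a fresh copy
#' label (`old + k` where `k` is the marker's pre-WGD multiplicity).  The
#' attribute `"parent_of"` maps every new copy key to its parent.
#'
#' @param g an `scj_genome`
#' @param name name for the doubled genome
#' @return an `scj_genome` with doubled content
#' @export
apply_wgd <- function(g, name = paste0(g$name, "x2")) {
  keys <- genome_markers(g)
  mult <- table(key_marker(keys))
  dup <- lapply(g$chromosomes, function(ch) {
    k <- token_key(ch)
    m <- key_marker(k)
    newc <- as.integer(key_copy(k)) + as.integer(mult[m])
    paste0(token_sign(ch), m, ".", newc)
  })
  out <- genome(c(g$chromosomes, dup), name = name)
  parent <- setNames(keys, token_key(unlist(dup, use.names = FALSE)))
  attr(out, "parent_of") <- parent
  out
}

## Direct chromosome-list surgery.  `chroms` is a plain list of token
## vectors; each helper returns list(chroms, ops) or NULL when infeasible.
## Logged ops use adjacency keys so evolution is replayable with apply_scj.

surgery_fission <- function(chroms) {
  lens <- lengths(chroms)
  w <- lens - 1L
  if (sum(w) == 0L) return(NULL)
  ci <- sample.int(length(chroms), 1L, prob = w)
  j <- sample.int(lens[ci] - 1L, 1L)
  ch <- chroms[[ci]]
  cut <- adj_key(right_ext(ch[j]), left_ext(ch[j + 1L]))
  chroms[[ci]] <- ch[seq_len(j)]
  chroms[[length(chroms) + 1L]] <- ch[(j + 1L):length(ch)]
  list(chroms = chroms, ops = list(c("cut", cut)))
}

surgery_fusion <- function(chroms, ci = NULL, avoid_adj = NULL) {
  if (length(chroms) < 2L) return(NULL)
  if (is.null(ci)) ci <- sample.int(length(chroms), 2L)
  c1 <- chroms[[ci[1]]]; c2 <- chroms[[ci[2]]]
  if (sample(c(TRUE, FALSE), 1L)) c1 <- rc_chrom(c1)   # join at left end of c1
  if (sample(c(TRUE, FALSE), 1L)) c2 <- rc_chrom(c2)
  joined_adj <- adj_key(right_ext(c1[length(c1)]), left_ext(c2[1L]))
  if (!is.null(avoid_adj) && joined_adj == avoid_adj) return(NULL)
  chroms[[ci[1]]] <- c(c1, c2)
  chroms[[ci[2]]] <- NULL
  list(chroms = chroms, ops = list(c("join", joined_adj)))
}

surgery_translocation <- function(chroms) {
  cut <- surgery_fission(chroms)
  if (is.null(cut)) return(NULL)
  nc <- length(cut$chroms)
  ## rejoin the detached piece (last element) with some other chromosome,
  ## without recreating the cut adjacency
  others <- setdiff(seq_len(nc), nc)
  for (oi in sample(others)) {
    fus <- surgery_fusion(cut$chroms, ci = c(oi, nc),
                          avoid_adj = cut$ops[[1]][2])
    if (!is.null(fus) && fus$ops[[1]][2] != cut$ops[[1]][2])
      return(list(chroms = fus$chroms, ops = c(cut$ops, fus$ops)))
  }
  NULL
}

#' Evolve a genome along one branch
#'
#' Applies SCJ rearrangements (fission = one cut, fusion = one end-to-end
#' join of telomeres of two chromosomes, translocation = one cut plus one
#' join) followed by independent marker-copy losses.  A loss deletes the copy
#' and heals the gap by joining the freed flanking extremities.  Infeasible
#' event draws are resampled (cap 100 per event).
#'
#' @param g starting `scj_genome`
#' @param events single integer (kinds drawn from `event_mix`) or named
#'   vector `c(fission=, fusion=, translocation=)`
#' @param event_mix kind probabilities used when `events` is a single count
#' @param loss_rate per-copy loss probability
#' @param branch branch label recorded in the event log
#' @return list with `genome` and `log` (data.frame: branch, kind, detail)
#' @export
evolve_branch <- function(g, events, event_mix = c(fission = 0.4, fusion = 0.4,
                                                   translocation = 0.2),
                          loss_rate = 0, branch = "branch") {
  if (length(events) == 1L && is.null(names(events))) {
    kinds <- sample(names(event_mix), events, replace = TRUE, prob = event_mix)
  } else {
    kinds <- rep(names(events), times = events)
  }
  kinds <- if (length(kinds)) sample(kinds) else character()
  chroms <- g$chromosomes
  log <- list()
  for (kind in kinds) {
    done <- FALSE
    for (try in seq_len(100L)) {
      res <- switch(kind,
                    fission = surgery_fission(chroms),
                    fusion = surgery_fusion(chroms),
                    translocation = surgery_translocation(chroms),
                    stop("unknown event kind: ", kind))
      if (is.null(res)) next
      chroms <- res$chroms
      log[[length(log) + 1L]] <- data.frame(
        branch = branch, kind = kind,
        detail = paste(vapply(res$ops, paste, "", collapse = " "),
                       collapse = "; "),
        stringsAsFactors = FALSE)
      done <- TRUE
      break
    }
    if (!done) stop("no feasible '", kind, "' event on branch ", branch)
  }
  if (loss_rate > 0) {
    keys <- token_key(unlist(chroms, use.names = FALSE))
    lost <- keys[runif(length(keys)) < loss_rate]
    mult <- table(key_marker(keys))
    for (k in lost) {
      ## never delete the last copy of a marker in this genome
      if (mult[[key_marker(k)]] <= 1L) next
      mult[[key_marker(k)]] <- mult[[key_marker(k)]] - 1L
      for (ci in seq_along(chroms)) {
        hit <- which(token_key(chroms[[ci]]) == k)
        if (length(hit)) {
          ## dropping the token joins the freed flanks (the healing rule)
          chroms[[ci]] <- chroms[[ci]][-hit]
          break
        }
      }
      chroms <- chroms[lengths(chroms) > 0L]
      log[[length(log) + 1L]] <- data.frame(branch = branch, kind = "loss",
                                            detail = k, stringsAsFactors = FALSE)
    }
  }
  g <- genome(chroms, name = g$name)
  list(genome = g,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(branch = character(), kind = character(),
                    detail = character(), stringsAsFactors = FALSE))
}

#' Delete one marker copy, healing the flanking adjacency
#' @param g an `scj_genome`
#' @param key unsigned `"marker.copy"` key to remove
#' @return an `scj_genome`
#' @export
delete_marker_copy <- function(g, key) {
  adj <- adjacency_set(g)
  mine <- adj[vapply(adj_exts(adj), function(p) any(ext_key(p) == key), logical(1))]
  keep <- setdiff(adj, mine)
  if (length(mine) == 2L) {  # internal copy: join the freed flanks
    others <- unlist(lapply(adj_exts(mine), function(p) p[ext_key(p) != key]))
    keep <- c(keep, adj_key(others[1], others[2]))
  }
  linearize(keep, setdiff(genome_markers(g), key), name = g$name)
}

#' Simulate the full three-species scenario with ground truth
#'
#' Runs the scenario tree (ancestor, WGD-1, shared stem, speciation, WGD-2,
#' per-branch rearrangements and losses) under a single seeded RNG stream.
#' With `loss_rate = 0` every marker ends with copy counts exactly 1:2:4 in
#' R:P:S.
#'
#' @param params a [scenario_params()] or [scenario_preset()]
#' @return a `scenario_truth` list: extant genomes `genome_R/P/S`, true
#'   ancestors `ancestor_preWGD1/postWGD1/preWGD2`, `event_log`, per-genome
#'   `unit_maps` (marker copy -> protochromosome lineage unit), a `genes`
#'   position table and `params`
#' @export
simulate_three_species_scenario <- function(params) {
  stopifnot(inherits(params, "scenario_params"))
  set.seed(params$seed)
  eb <- params$events_per_branch
  anc1 <- simulate_ancestor(params)

  ## protochromosome unit of every copy key: "A<i>" plus WGD sub-copy path
  unit <- character()
  for (i in seq_along(anc1$chromosomes))
    unit[token_key(anc1$chromosomes[[i]])] <- paste0("A", i)

  extend_units <- function(unit, doubled) {
    parent <- attr(doubled, "parent_of")
    u <- c(setNames(paste0(unit, "/0"), names(unit)),
           setNames(paste0(unit[parent], "/1"), names(parent)))
    u
  }

  ## branch R: no WGD
  bR <- evolve_branch(anc1, eb$R, params$event_mix, params$loss_rate, "R")
  gR <- bR$genome; gR$name <- "R"

  ## shared stem: WGD-1 then events
  d1 <- apply_wgd(anc1, name = "postWGD1x")
  unit2 <- extend_units(unit, d1)
  bStem <- evolve_branch(d1, eb$stem, params$event_mix, params$loss_rate, "stem")
  anc2 <- bStem$genome; anc2$name <- "postWGD1"

  ## branch P
  bP <- evolve_branch(anc2, eb$P, params$event_mix, params$loss_rate, "P")
  gP <- bP$genome; gP$name <- "P"

  ## branch S: optional pre-WGD-2 events, WGD-2, post-WGD-2 events
  bSpre <- evolve_branch(anc2, eb$S_pre, params$event_mix, params$loss_rate, "S_pre")
  anc3 <- bSpre$genome; anc3$name <- "preWGD2"
  d2 <- apply_wgd(anc3, name = "postWGD2x")
  unit4 <- extend_units(unit2[intersect(names(unit2), genome_markers(anc3))], d2)
  bSpost <- evolve_branch(d2, eb$S_post, params$event_mix, params$loss_rate, "S_post")
  gS <- bSpost$genome; gS$name <- "S"

  keep_units <- function(u, g) u[intersect(names(u), genome_markers(g))]
  truth <- structure(list(
    genome_R = gR, genome_P = gP, genome_S = gS,
    ancestor_preWGD1 = anc1, ancestor_postWGD1 = anc2,
    ancestor_preWGD2 = anc3,
    event_log = rbind(bR$log, bStem$log, bP$log, bSpre$log, bSpost$log),
    unit_maps = list(R = keep_units(unit, gR),
                     P = keep_units(unit2, gP),
                     S = keep_units(unit4, gS)),
    params = params), class = "scenario_truth")
  truth$genes <- scenario_gene_table(truth)
  truth
}

#' @export
print.scenario_truth <- function(x, ...) {
  cat("<scenario_truth>\n")
  for (nm in c("ancestor_preWGD1", "ancestor_postWGD1", "ancestor_preWGD2",
               "genome_R", "genome_P", "genome_S"))
    cat(sprintf("  %-18s %3d chromosomes, %5d marker copies\n", nm,
                n_chromosomes(x[[nm]]), n_marker_copies(x[[nm]])))
  cat("  events:", nrow(x$event_log), "\n")
  invisible(x)
}

## gene ids: "<genome>_<marker>_<copy>"; positions are order indices * 1000
scenario_gene_table <- function(truth) {
  per_genome <- function(g, gname) {
    rows <- lapply(seq_along(g$chromosomes), function(i) {
      ch <- g$chromosomes[[i]]
      k <- token_key(ch)
      data.frame(
        gene_id = paste0(gname, "_", sub("\\.", "_", k)),
        genome = gname,
        chromosome = paste0(gname, "_chr", i),
        start = (seq_along(ch) - 1L) * 1000L,
        end = (seq_along(ch) - 1L) * 1000L + 500L,
        strand = token_sign(ch),
        marker = key_marker(k), copy = key_copy(k),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  out <- rbind(per_genome(truth$genome_R, "R"),
               per_genome(truth$genome_P, "P"),
               per_genome(truth$genome_S, "S"))
  rownames(out) <- NULL
  out
}

#' Emit a noisy ortholog table from simulated truth
#'
#' Ortholog edges connect all pairs of copies of each marker, within and
#' between genomes.  Each edge is dropped independently with the missing-edge
#' rate; spurious edges between random non-homologous genes are added at the
#' spurious rate (relative to the true edge count).
#'
#' @param truth a `scenario_truth`
#' @param noise `c(missing=, spurious=)`; defaults to the scenario parameters
#' @return data.frame `gene_a, gene_b, identity, bitscore`
#' @export
emit_ortholog_table <- function(truth, noise = truth$params$ortholog_noise) {
  if (any(noise < 0) || any(noise > 1)) stop("noise rates must be in [0, 1]")
  genes <- truth$genes
  by_marker <- split(genes$gene_id, genes$marker)
  edges <- lapply(by_marker, function(ids) {
    if (length(ids) < 2) return(NULL)
    cmb <- utils::combn(c_sort(ids), 2L)
    data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, edges)
  rownames(df) <- NULL
  if (is.null(df)) df <- data.frame(gene_a = character(), gene_b = character())
  if (noise[["missing"]] > 0 && nrow(df)) {
    df <- df[runif(nrow(df)) >= noise[["missing"]], , drop = FALSE]
  }
  n_spur <- round(noise[["spurious"]] * nrow(df))
  if (n_spur > 0) {
    a <- sample(genes$gene_id, n_spur, replace = TRUE)
    b <- sample(genes$gene_id, n_spur, replace = TRUE)
    keep <- a != b & genes$marker[match(a, genes$gene_id)] !=
      genes$marker[match(b, genes$gene_id)]
    df <- rbind(df, data.frame(gene_a = a[keep], gene_b = b[keep],
                               stringsAsFactors = FALSE))
  }
  if (!nrow(df)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      identity = numeric(), bitscore = numeric()))
  }
  df$identity <- round(runif(nrow(df), 80, 99), 2)
  df$bitscore <- round(runif(nrow(df), 200, 2000), 1)
  dedup_ortholog_pairs(df)
}

#' Draw Ks values from a Gaussian mixture truncated at zero
#'
#' @param components data.frame with columns `weight, mean, sd`
#' @param n number of draws
#' @param seed optional seed
#' @return data.frame `gene_a, gene_b, ks, component`
#' @export
emit_ks_samples <- function(components, n, seed = NULL) {
  stopifnot(all(c("weight", "mean", "sd") %in% names(components)))
  if (abs(sum(components$weight) - 1) > 1e-9)
    stop("component weights must sum to 1")
  if (any(components$sd <= 0)) stop("component sd must be > 0")
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(nrow(components), n, replace = TRUE,
                     prob = components$weight)
  ks <- rnorm(n, components$mean[comp], components$sd[comp])
  while (any(ks < 0)) {  # truncate at 0 by resampling negative proposals
    i <- which(ks < 0)
    ks[i] <- rnorm(length(i), components$mean[comp[i]], components$sd[comp[i]])
  }
  data.frame(gene_a = sprintf("pairA%05d", seq_len(n)),
             gene_b = sprintf("pairB%05d", seq_len(n)),
             ks = ks, component = comp, stringsAsFactors = FALSE)
}

#' Emit TPM matrices for the simulated genomes
#'
#' Log-normal expression with a species-specific scale factor, one matrix per
#' genome, tissues as columns.
#'
#' @param truth a `scenario_truth`
#' @param tissues tissue names
#' @param species_scale named multipliers per genome
#' @param seed optional seed
#' @return named list of numeric matrices (genes x tissues)
#' @export
emit_tpm_matrix <- function(truth,
                            tissues = c("root", "stem", "leaf", "flower",
                                        "capsule", "seed"),
                            species_scale = c(R = 1, P = 2.5, S = 4),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- truth$genes
  out <- lapply(c_sort(unique(genes$genome)), function(gn) {
    ids <- genes$gene_id[genes$genome == gn]
    m <- matrix(exp(rnorm(length(ids) * length(tissues), mean = 1, sd = 1)),
                nrow = length(ids),
                dimnames = list(ids, tissues)) * species_scale[[gn]]
    round(m, 4)
  })
  names(out) <- c_sort(unique(genes$genome))
  out
}

#' Replay a branch event log on an ancestor
#'
#' Applies the recorded cut/join/loss operations in order; used to verify
#' that the event log reproduces the simulated genomes exactly.
#'
#' @param g starting `scj_genome`
#' @param log event-log data.frame (rows of one branch, in order)
#' @return an `scj_genome`
#' @export
replay_events <- function(g, log) {
  for (i in seq_len(nrow(log))) {
    if (log$kind[i] == "loss") {
      g <- delete_marker_copy(g, log$detail[i])
      next
    }
    for (op in strsplit(log$detail[i], "; ", fixed = TRUE)[[1]]) {
      parts <- strsplit(op, " ", fixed = TRUE)[[1]]
      if (parts[1] == "cut") {
        g <- apply_scj(g, scj_op("cut", adjacency = parts[2]))
      } else {
        g <- apply_scj(g, scj_op("join",
                                 extremities = adj_exts(parts[2])[[1]]))
      }
    }
  }
  g
}
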