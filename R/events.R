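## ---------------------------------------------------------------------------
## Painting modern chromosomes by ancestral protochromosome, fission/fusion
## counting and z-tests for non-random event placement.
## ---------------------------------------------------------------------------

#' Paint a modern genome by ancestral protochromosome units
#'
#' Every marker copy of the modern genome is labelled with its ancestral
#' unit — a protochromosome identity, optionally refined by the post-WGD
#' sub-genome lineage (so a `w`-WGD genome has `n_ancestor * 2^w` units).
#' Runs of consecutive markers with the same unit merge into segments.
#'
#' @param modern an `scj_genome`
#' @param unit_map named character vector: marker-copy key -> unit label
#'   (`NA` or missing keys give unassigned segments, which are reported)
#' @return a `painting`: data.frame with `chromosome, segment, unit, n_markers`
#' @export
paint_by_ancestor <- function(modern, unit_map) {
  rows <- list()
  for (ci in seq_along(modern$chromosomes)) {
    keys <- token_key(modern$chromosomes[[ci]])
    units <- unname(unit_map[keys])
    r <- rle(ifelse(is.na(units), "<unassigned>", units))
    rows[[ci]] <- data.frame(
      chromosome = ci, segment = seq_along(r$values),
      unit = ifelse(r$values == "<unassigned>", NA_character_, r$values),
      n_markers = r$lengths, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (anyNA(out$unit))
    warning(sum(is.na(out$unit)), " unassigned segment(s) in painting")
  structure(out, class = c("painting", "data.frame"))
}

#' Count fissions and fusions from a painting
#'
#' Fusions: per modern chromosome, the number of maximal distinct-unit
#' segments minus one, i.e. the end-joins needed to assemble the chromosome
#' from ancestral material.  Fissions: per ancestral unit, the number of
#' modern chromosomes carrying at least one segment of that unit minus one.
#' With `n_units` ancestral units the bookkeeping identity
#' `n_modern = n_units + fissions - fusions` holds whenever no unit recurs in
#' disjoint segments of one chromosome (the `bookkeeping_ok` flag).
#'
#' @param painting a [paint_by_ancestor()] result
#' @param n_units number of ancestral units (`n_ancestor * 2^w`)
#' @return list: `fusions_per_chromosome`, `fissions_per_unit`, totals,
#'   `n_modern`, `predicted`, `bookkeeping_ok`
#' @export
count_fissions_fusions <- function(painting, n_units) {
  p <- painting[!is.na(painting$unit), , drop = FALSE]
  if (nrow(p) < nrow(painting))
    warning("unassigned segments excluded from event counting")
  fus <- vapply(split(p$unit, p$chromosome),
                function(u) length(rle(u)$values) - 1L, 0L)
  carriers <- vapply(split(p$chromosome, p$unit),
                     function(ch) length(unique(ch)), 0L)
  fis <- pmax(carriers - 1L, 0L)
  n_modern <- length(unique(painting$chromosome))
  predicted <- n_units + sum(fis) - sum(fus)
  list(fusions_per_chromosome = fus,
       fissions_per_unit = fis,
       total_fissions = sum(fis), total_fusions = sum(fus),
       n_modern = n_modern, predicted = predicted,
       bookkeeping_ok = predicted == n_modern)
}

#' z-test for enrichment/depletion of events across units
#'
#' Under the null each of `total_events` events hits unit `i` independently
#' with probability `p_i` (uniform `1/n_units`, or proportional to `weights`
#' when given).  For observed count `k_i`,
#' `z_i = (k_i - N p_i) / sqrt(N p_i (1 - p_i))`; `p_enrich` is the upper
#' normal tail and `p_deplete` the lower.  Flags use alpha = 0.05 with no
#' multiple-testing correction (one test per unit, reported as such).
#'
#' @param counts named (or plain) integer vector of per-unit event counts
#' @param n_units number of units tested (defaults to `length(counts)`)
#' @param total_events total number of events (defaults to `sum(counts)`)
#' @param weights optional unit sizes for a weight-proportional null
#' @param alpha flag threshold
#' @return data.frame `unit, observed, expected, z, p_enrich, p_deplete,
#'   enriched, depleted`
#' @export
event_enrichment_ztest <- function(counts, n_units = length(counts),
                                   total_events = sum(counts),
                                   weights = NULL, alpha = 0.05) {
  if (total_events == 0) stop("undefined test: zero events")
  if (length(counts) != n_units)
    stop("counts must have one entry per unit")
  p <- if (is.null(weights)) rep(1 / n_units, n_units) else {
    if (length(weights) != n_units || any(weights <= 0))
      stop("weights must be positive, one per unit")
    weights / sum(weights)
  }
  expected <- total_events * p
  z <- (counts - expected) / sqrt(total_events * p * (1 - p))
  data.frame(
    unit = if (!is.null(names(counts))) names(counts) else
      as.character(seq_len(n_units)),
    observed = as.integer(counts), expected = expected, z = z,
    p_enrich = pnorm(z, lower.tail = FALSE),
    p_deplete = pnorm(z, lower.tail = TRUE),
    enriched = pnorm(z, lower.tail = FALSE) < alpha,
    depleted = pnorm(z, lower.tail = TRUE) < alpha,
    row.names = NULL, stringsAsFactors = FALSE)
}
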