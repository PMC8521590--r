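## ---------------------------------------------------------------------------
## End-to-end orchestration: simulate -> pPGs -> blocks -> ancestors ->
## fission/fusion tests -> Ks dating -> TPM normalization, with a
## machine-readable report.  All randomness flows from config$seed.
## ---------------------------------------------------------------------------

#' Build and validate a pipeline configuration
#'
#' @param preset scenario preset name (see [scenario_preset()])
#' @param seed integer seed controlling every stage
#' @param n_markers markers in the simulated ancestor
#' @param min_len minimum synteny-block length in pPGs
#' @param core_ratio named per-genome copy ratio
#' @param median_mode `"double"` or `"single"` (see [reconstruct_ancestors()])
#' @param null_model `"uniform"` or `"weighted"` expectation for the
#'   fission/fusion z-tests
#' @param k_range candidate component counts for the Ks mixture
#' @param ks_components data.frame (weight, mean, sd) of the simulated Ks
#'   mixture; defaults to WGD-2 and WGD-1 peaks placed by the scenario's
#'   nominal ages and rate
#' @param interspecies_ks_mean mean Ks of cross-species ortholog pairs used
#'   to calibrate the substitution rate
#' @param divergence_time_years calibration divergence time for the rate
#' @param out_dir optional output directory; when given, results and the
#'   resolved configuration are written there
#' @return a validated `pipeline_config` list
#' @export
pipeline_config <- function(preset = "papaver-minima", seed = 1L,
                            n_markers = 1000L, min_len = 3L,
                            core_ratio = c(R = 1, P = 2, S = 4),
                            median_mode = "double",
                            null_model = "uniform",
                            k_range = 1:3,
                            ks_components = data.frame(
                              weight = c(0.5, 0.5),
                              mean = c(0.065, 0.116),
                              sd = c(0.012, 0.012)),
                            interspecies_ks_mean = 0.12,
                            divergence_time_years = 7.7e6,
                            out_dir = NULL) {
  cfg <- list(preset = preset, seed = as.integer(seed),
              n_markers = as.integer(n_markers), min_len = as.integer(min_len),
              core_ratio = core_ratio, median_mode = median_mode,
              null_model = null_model, k_range = k_range,
              ks_components = ks_components,
              interspecies_ks_mean = interspecies_ks_mean,
              divergence_time_years = divergence_time_years,
              out_dir = out_dir)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  need <- c("preset", "seed", "n_markers", "min_len", "core_ratio",
            "median_mode", "null_model", "k_range", "ks_components",
            "interspecies_ks_mean", "divergence_time_years")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("pipeline config is missing field(s): ",
         paste(missing, collapse = ", "))
  stopifnot(cfg$n_markers > 0, cfg$min_len >= 1,
            cfg$median_mode %in% c("double", "single"),
            cfg$null_model %in% c("uniform", "weighted"),
            all(c("weight", "mean", "sd") %in% names(cfg$ks_components)),
            cfg$divergence_time_years > 0)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with the fields of [pipeline_config()]
#' @return a validated `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$ks_components)) raw$ks_components <-
      as.data.frame(raw$ks_components)
  if (!is.null(raw$core_ratio)) raw$core_ratio <- unlist(raw$core_ratio)
  defaults <- pipeline_config()
  cfg <- modifyList(unclass(defaults), raw)
  validate_pipeline_config(cfg)
}

#' Run the full analysis pipeline on a simulated scenario
#'
#' Chains every stage on ground-truthed synthetic data: scenario simulation,
#' ortholog-table emission, pPG construction and core classification,
#' painting, block detection and ratio filtering, non-core fill-in, ancestor
#' reconstruction, protochromosome painting with fission/fusion z-tests, Ks
#' mixture dating, and TPM normalization.  Returns a machine-readable report
#' including truth-based recovery metrics; with an `out_dir` set, writes
#' GRIMM ancestors, block/event/stat TSVs, the JSON report and the resolved
#' configuration.
#'
#' @param config a [pipeline_config()]
#' @return a `pipeline_report` list
#' @export
run_full_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  params <- stage("simulate", scenario_preset(config$preset,
                                              seed = config$seed,
                                              n_markers = config$n_markers))
  truth <- stage("simulate", simulate_three_species_scenario(params))
  orth <- stage("simulate",
                suppressMessages(emit_ortholog_table(truth)))
  pos <- truth$genes

  ppgs <- stage("blocks", classify_core(build_ppgs(orth, pos),
                                        config$core_ratio))
  painted <- stage("blocks", paint_genomes(ppgs, pos))
  blocks <- stage("blocks", find_no_blocks(painted, config$min_len))
  filtered <- stage("blocks", filter_blocks_by_ratio(blocks,
                                                     config$core_ratio))
  filled <- stage("blocks", fill_noncore(filtered, ppgs, painted))

  anc <- stage("reconstruct",
               reconstruct_ancestors(filled, painted,
                                     ratio = config$core_ratio,
                                     median_mode = config$median_mode))

  ## truth-based recovery metrics
  mem <- ppgs$membership
  mem$marker <- pos$marker[match(mem$gene_id, pos$gene_id)]
  ppg2marker <- vapply(split(mem$marker, mem$ppg_id), function(x)
    names(sort(table(x), decreasing = TRUE))[1], "")
  pre1_expanded <- stage("reconstruct",
                         expand_ancestor(anc$pre_wgd1, anc$orders))
  f1 <- stage("reconstruct",
              adjacency_f1(rename_markers(pre1_expanded, ppg2marker),
                           truth$ancestor_preWGD1))

  ## fission/fusion counting against the true painting units
  nchr_anc <- n_chromosomes(truth$ancestor_preWGD1)
  events <- list()
  ztests <- list()
  for (gn in c("R", "P", "S")) {
    w <- c(R = 0L, P = 1L, S = 2L)[[gn]]
    painting <- paint_by_ancestor(truth[[paste0("genome_", gn)]],
                                  truth$unit_maps[[gn]])
    cnt <- count_fissions_fusions(painting, n_units = nchr_anc * 2^w)
    events[[gn]] <- cnt
    if (cnt$total_fissions > 0) {
      per_proto <- integer(nchr_anc)
      names(per_proto) <- paste0("A", seq_len(nchr_anc))
      fis <- cnt$fissions_per_unit
      proto <- sub("/.*$", "", names(fis))
      for (u in seq_along(fis)) per_proto[[proto[u]]] <-
          per_proto[[proto[u]]] + fis[[u]]
      ztests[[gn]] <- event_enrichment_ztest(per_proto,
                                             total_events = sum(per_proto))
    }
  }

  ## Ks dating
  ksdat <- stage("ksdate", emit_ks_samples(config$ks_components, n = 2000L,
                                           seed = config$seed))
  fit <- stage("ksdate", fit_ks_mixture(ksdat$ks, k_range = config$k_range,
                                        seed = config$seed))
  rate <- stage("ksdate", estimate_rate(config$interspecies_ks_mean,
                                        config$divergence_time_years))
  timing <- data.frame(
    component = seq_len(nrow(fit$components)),
    ks_mean = fit$components$mean,
    T_years = vapply(fit$components$mean, estimate_time, 0, r = rate))

  ## TPM normalization
  tpm <- stage("normtpm", emit_tpm_matrix(truth, seed = config$seed))
  norms <- lapply(tpm, normalize_tpm)

  report <- structure(list(
    config = unclass(config),
    n_blocks = length(filled$blocks),
    blocks_removed_by_ratio = length(attr(filtered, "removed")),
    noncore_unplaced = nrow(attr(filled, "unplaced")),
    wgd_multiplicity = infer_wgd_multiplicity(filled),
    chromosome_counts = list(
      pre_wgd1 = n_chromosomes(anc$pre_wgd1),
      post_wgd1 = n_chromosomes(anc$post_wgd1),
      pre_wgd2 = n_chromosomes(anc$pre_wgd2),
      truth_pre_wgd1 = n_chromosomes(truth$ancestor_preWGD1),
      truth_post_wgd1 = n_chromosomes(truth$ancestor_postWGD1)),
    recovery = as.list(f1),
    events = lapply(events, function(e)
      e[c("total_fissions", "total_fusions", "n_modern", "predicted",
          "bookkeeping_ok")]),
    ztests = ztests,
    ks_fit = list(k = fit$k, components = fit$components),
    rate = rate, timing = timing,
    tpm_checks = lapply(norms, function(nr) list(
      mean_z = mean(nr$tpm_z), sd_z = sd_pop(nr$tpm_z),
      min_n = min(nr$tpm_n))),
    bookkeeping_all_ok = all(vapply(events, function(e) e$bookkeeping_ok,
                                    logical(1)))),
    class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_outputs(config$out_dir,
                  ancestors = list(anc$pre_wgd1, anc$post_wgd1, anc$pre_wgd2),
                  blocks = filled,
                  events = truth$event_log,
                  stats = data.frame(
                    metric = c("pre_wgd1_chromosomes", "adjacency_f1"),
                    value = c(n_chromosomes(anc$pre_wgd1), f1[["f1"]])))
    jsonlite::write_json(report[setdiff(names(report), "config")],
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    yaml::write_yaml(unclass(config)[setdiff(names(config), "out_dir")],
                     file.path(config$out_dir, "config.yaml"))
  }
  report
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cc <- x$chromosome_counts
  cat(sprintf("  blocks: %d (ratio-removed %d, unplaced non-core %d)\n",
              x$n_blocks, x$blocks_removed_by_ratio, x$noncore_unplaced))
  cat(sprintf("  chromosomes: pre-WGD-1 %d (truth %d), post-WGD-1 %d (truth %d), pre-WGD-2 %d\n",
              cc$pre_wgd1, cc$truth_pre_wgd1, cc$post_wgd1,
              cc$truth_post_wgd1, cc$pre_wgd2))
  cat(sprintf("  pre-WGD-1 adjacency F1: %.3f (precision %.3f, recall %.3f)\n",
              x$recovery$f1, x$recovery$precision, x$recovery$recall))
  cat(sprintf("  bookkeeping identity: %s\n",
              if (x$bookkeeping_all_ok) "pass" else "FAIL"))
  cat(sprintf("  Ks mixture: k = %d; rate %.3e subs/site/year\n",
              x$ks_fit$k, x$rate))
  invisible(x)
}
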