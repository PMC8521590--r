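## ---------------------------------------------------------------------------
## Cross-species TPM normalization and per-family total expression.
## ---------------------------------------------------------------------------

#' Normalize a TPM matrix by species-wide z-scoring
#'
#' The z-score uses the mean and (population, divide-by-n) standard
#' deviation over all entries of the species' matrix:
#' `TPM_z = (TPM - mean) / sd`.  The non-negative variant shifts by the
#' minimum z-score, `TPM_n = TPM_z - min(TPM_z)`, so that `min(TPM_n) = 0`.
#'
#' @param m numeric TPM matrix (genes x tissues) of one species
#' @return a `tpm_norm`: matrices `tpm_z` and `tpm_n`, scalars
#'   `species_mean`, `species_sd`, `min_tpm_z`
#' @examples
#' norm <- normalize_tpm(matrix(c(10, 20, 30), 3, 1,
#'                              dimnames = list(c("g1", "g2", "g3"), "stem")))
#' round(norm$tpm_z, 4)
#' @export
normalize_tpm <- function(m) {
  if (!is.matrix(m) || !is.numeric(m) || !length(m))
    stop("m must be a non-empty numeric matrix")
  if (any(m < 0)) stop("TPM values must be non-negative")
  mu <- mean(m)
  sd_pop <- sqrt(mean((m - mu)^2))
  if (sd_pop <= 0) stop("degenerate matrix: all TPM values equal")
  z <- (m - mu) / sd_pop
  structure(list(tpm_z = z, tpm_n = z - min(z),
                 species_mean = mu, species_sd = sd_pop,
                 min_tpm_z = min(z)), class = "tpm_norm")
}

#' @export
print.tpm_norm <- function(x, ...) {
  cat(sprintf("<tpm_norm: %d genes x %d tissues; mean %.3f, sd %.3f, min z %.3f>\n",
              nrow(x$tpm_z), ncol(x$tpm_z), x$species_mean, x$species_sd,
              x$min_tpm_z))
  invisible(x)
}

#' Total normalized expression over all copies of each gene family
#'
#' Sums the non-negative normalized expression (`tpm_n`) of every family
#' member in one tissue; reports the copy number alongside, since both the
#' per-copy dose and the copy count shape a family's total output.
#'
#' @param norm a [normalize_tpm()] result
#' @param families named list family -> character vector of gene ids, or a
#'   data.frame with columns `gene_id, family`
#' @param tissue column name of the tissue to total over
#' @return data.frame `family, n_copies, total_tpm_n`
#' @export
total_copy_expression <- function(norm, families, tissue) {
  stopifnot(inherits(norm, "tpm_norm"))
  if (is.data.frame(families)) {
    families <- split(families$gene_id, families$family)
  }
  if (!tissue %in% colnames(norm$tpm_n))
    stop("unknown tissue: ", tissue)
  unknown <- setdiff(unlist(families), rownames(norm$tpm_n))
  if (length(unknown))
    stop("gene(s) absent from the matrix: ",
         paste(head(unknown, 5), collapse = ", "))
  out <- data.frame(
    family = names(families),
    n_copies = lengths(families),
    total_tpm_n = vapply(families, function(g)
      sum(norm$tpm_n[g, tissue]), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  out[c_order(out$family), , drop = FALSE]
}
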