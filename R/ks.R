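## ---------------------------------------------------------------------------
## WGD dating from Ks distributions: reciprocal-best-match classification of
## syntenic pairs, Gaussian-mixture fitting with BIC model choice, and the
## molecular-clock identities r = Ks/(2T), T = Ks/(2r).
## ---------------------------------------------------------------------------

#' Classify syntenic gene pairs into WGD rounds
#'
#' In a genome shaped by two WGDs, the most recent duplication produced the
#' most similar paralog pairs: a pair `(a, b)` is assigned to the second WGD
#' (WGD-2) iff `b` is `a`'s best-scoring syntenic partner and vice versa
#' (reciprocal best match); all other pairs are assigned to WGD-1.
#'
#' @param pairs data.frame with `gene_a, gene_b, bitscore`
#' @return the data.frame with a `pair_class` column (`"WGD-2"`/`"WGD-1"`)
#' @export
classify_wgd_pairs <- function(pairs) {
  need <- c("gene_a", "gene_b", "bitscore")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns: ", paste(need, collapse = ", "))
  if (anyNA(pairs$bitscore)) stop("missing bitscores")
  long <- rbind(
    data.frame(gene = pairs$gene_a, partner = pairs$gene_b,
               bitscore = pairs$bitscore, stringsAsFactors = FALSE),
    data.frame(gene = pairs$gene_b, partner = pairs$gene_a,
               bitscore = pairs$bitscore, stringsAsFactors = FALSE))
  o <- order(long$gene, -long$bitscore, long$partner, method = "radix")
  long <- long[o, , drop = FALSE]
  best <- long[!duplicated(long$gene), , drop = FALSE]
  best_of <- setNames(best$partner, best$gene)
  recip <- best_of[pairs$gene_a] == pairs$gene_b &
    best_of[pairs$gene_b] == pairs$gene_a
  pairs$pair_class <- ifelse(recip, "WGD-2", "WGD-1")
  pairs
}

## log-likelihood of a univariate Gaussian mixture
gmm_loglik <- function(x, w, mu, sd) {
  dens <- vapply(seq_along(w), function(j) w[j] * dnorm(x, mu[j], sd[j]),
                 numeric(length(x)))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(x))
  sum(log(pmax(rowSums(dens), 1e-300)))
}

fit_gmm_k <- function(x, k, max_iter = 500L, tol = 1e-8) {
  n <- length(x)
  if (k == 1L) {
    mu <- mean(x); s <- sqrt(mean((x - mu)^2))
    if (s < 1e-8) stop("degenerate fit: values are (nearly) constant")
    return(list(w = 1, mu = mu, sd = s, loglik = gmm_loglik(x, 1, mu, s)))
  }
  cl <- kmeans(x, centers = k, nstart = 5L)
  w <- as.numeric(table(factor(cl$cluster, levels = seq_len(k)))) / n
  mu <- as.numeric(cl$centers)
  s <- vapply(seq_len(k), function(j) {
    v <- x[cl$cluster == j]
    max(sqrt(mean((v - mu[j])^2)), 1e-4)
  }, 0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], s[j]),
                   numeric(n))
    rs <- rowSums(dens)
    resp <- dens / pmax(rs, 1e-300)
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / pmax(nk, 1e-12)
    s <- sqrt(colSums(resp * (x - rep(mu, each = n))^2) / pmax(nk, 1e-12))
    s <- pmax(s, 1e-6)
    ll <- sum(log(pmax(rs, 1e-300)))
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(w = w, mu = mu, sd = s, loglik = gmm_loglik(x, w, mu, s))
}

#' Fit a Gaussian mixture to Ks values with BIC model selection
#'
#' Expectation-maximization with k-means initialization under a fixed seed;
#' the number of components is chosen by BIC over `k_range`.  Ks values are
#' non-negative by construction; following standard Ks practice the fit uses
#' untruncated Gaussians on the observed values.
#'
#' @param ks numeric vector of Ks values (>= 0, not all equal)
#' @param k_range candidate component counts
#' @param seed RNG seed for the k-means initialization
#' @param max_iter,tol EM controls
#' @return a `ks_mixture`: `components` (weight, mean, sd; sorted by mean),
#'   chosen `k`, `bic` table, `loglik`
#' @export
fit_ks_mixture <- function(ks, k_range = 1:3, seed = 1L, max_iter = 500L,
                           tol = 1e-8) {
  ks <- as.numeric(ks)
  if (anyNA(ks) || any(ks < 0)) stop("Ks values must be non-negative, no NA")
  if (length(unique(ks)) < 2L) stop("degenerate fit: values are constant")
  k_range <- k_range[10L * k_range <= length(ks)]
  if (!length(k_range)) stop("need >= 10 observations per requested component")
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(k_range, function(k)
    tryCatch(fit_gmm_k(ks, k, max_iter, tol), error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  k_range <- k_range[ok]; fits <- fits[ok]
  if (!length(fits)) stop("mixture fitting failed for all k")
  n <- length(ks)
  bic <- vapply(seq_along(fits), function(i) {
    p <- 3L * k_range[i] - 1L
    -2 * fits[[i]]$loglik + p * log(n)
  }, 0)
  best <- which.min(bic)
  f <- fits[[best]]
  o <- order(f$mu)
  structure(list(
    components = data.frame(weight = f$w[o], mean = f$mu[o], sd = f$sd[o]),
    k = k_range[best],
    bic = data.frame(k = k_range, bic = bic),
    loglik = f$loglik), class = "ks_mixture")
}

#' @export
print.ks_mixture <- function(x, ...) {
  cat(sprintf("<ks_mixture: k = %d (BIC-selected), loglik = %.2f>\n",
              x$k, x$loglik))
  print(round(x$components, 4))
  invisible(x)
}

#' Synonymous substitution rate from a Ks peak and a known divergence time
#'
#' `r = Ks / (2T)`: the mean Ks of orthologs separated at time `T` counts
#' substitutions accumulated along both branches.
#'
#' @param ks_mean mean Ks of the dated pair set (substitutions/site)
#' @param T divergence time in years
#' @return r in substitutions/site/year
#' @examples
#' estimate_rate(0.12, 7.7e6)   # ~7.79e-9
#' @export
estimate_rate <- function(ks_mean, T) {
  if (T <= 0) stop("domain error: T must be > 0")
  if (ks_mean < 0) stop("domain error: Ks must be >= 0")
  ks_mean / (2 * T)
}

#' Date an event from a Ks peak and a substitution rate
#'
#' `T = Ks / (2r)`, the inverse of [estimate_rate()]; the round trip
#' `estimate_time(ks, estimate_rate(ks, T)) == T` is exact.
#'
#' @param ks_mean mean Ks of the event's pair set
#' @param r substitution rate in substitutions/site/year
#' @return time in years
#' @export
estimate_time <- function(ks_mean, r) {
  if (r <= 0) stop("domain error: r must be > 0")
  if (ks_mean < 0) stop("domain error: Ks must be >= 0")
  ks_mean / (2 * r)
}
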