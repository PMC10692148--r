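#' Drop genes with low total counts
#'
#' Removes genes whose summed count across all samples is below `min_total`
#' (default 10, the usual pre-filter for bulk count matrices).
#'
#' @param counts Tibble with `gene_id` plus one integer column per sample.
#' @param min_total Minimum summed count across samples for a gene to be kept.
#' @return The filtered counts tibble, gene order preserved.
#' @export
filter_low_counts <- function(counts, min_total = 10) {
  validate_counts(counts)
  keep <- rowSums(counts_matrix(counts)) >= min_total
  if (!any(keep)) warn("all genes removed by the count filter")
  counts[keep, , drop = FALSE]
}

#' Relative log expression (median-of-ratios) size factors
#'
#' For each sample, the size factor is the median across reference genes of
#' the ratio between the gene's count and its across-sample geometric mean.
#' Reference genes are those with no zero count in any sample. Factors are
#' rescaled so their geometric mean is 1.
#'
#' @param counts Tibble with `gene_id` plus one count column per sample.
#' @return A tibble with columns `sample_id` and `size_factor`.
#' @export
estimate_size_factors <- function(counts) {
  validate_counts(counts)
  m <- counts_matrix(counts)
  ref <- rowSums(m == 0) == 0
  if (!any(ref)) {
    abort(paste(
      "no gene has all-positive counts; RLE needs at least one zero-free",
      "reference gene (consider a pseudo-reference fallback upstream)"
    ))
  }
  logm <- log(m[ref, , drop = FALSE])
  geo <- rowMeans(logm)
  s <- apply(exp(logm - geo), 2, stats::median)
  s <- s / exp(mean(log(s)))
  tibble(sample_id = colnames(m), size_factor = unname(s))
}

#' Gene-wise method-of-moments dispersion estimates
#'
#' Estimates the negative-binomial dispersion \eqn{\alpha} in
#' \eqn{Var = \mu + \alpha \mu^2} from normalized counts within design cells
#' (fraction-by-condition groups), pooling the per-cell moment estimates
#' weighted by their degrees of freedom. The mean-driven (shot-noise) part of
#' the variance is removed using the cell-average reciprocal size factor, so
#' the estimate targets the biological over-dispersion only.
#'
#' @param counts Tibble with `gene_id` plus one count column per sample.
#' @param samples Sample sheet tibble (`sample_id`, `fraction`, `condition`,
#'   `pair_id`).
#' @param size_factors Tibble from [estimate_size_factors()].
#' @param floor Lower bound applied to every estimate.
#' @param moderate If `TRUE`, follow the moment estimates with trend
#'   moderation: per-gene Cox-Reid-adjusted profile likelihoods are shrunk
#'   towards a gamma-GLM mean-dispersion trend through a log-normal prior
#'   (maximum a posteriori estimate), the standard stabilization for designs
#'   with few replicates per cell. Off by default.
#' @param pair_term Include pair effects in the design used for the
#'   moderated fit (ignored when `moderate = FALSE`).
#' @param prior_sd_min Lower bound for the log-normal prior width of the
#'   moderated estimator.
#' @param prior_sd_scale Multiplier applied to the estimated prior width.
#'   The plug-in width (spread of gene-wise estimates around the trend minus
#'   their sampling variance) over-shrinks under small-replicate designs;
#'   widening it by this factor keeps null Wald p-values uniform (calibrated
#'   on global-null simulations of the default study design).
#' @return A tibble with columns `gene_id` and `dispersion`.
#' @export
estimate_dispersions <- function(counts, samples, size_factors,
                                 floor = 1e-8, moderate = FALSE,
                                 pair_term = TRUE, prior_sd_min = 0.25,
                                 prior_sd_scale = 1.8) {
  validate_counts(counts, samples)
  m <- counts_matrix(counts)
  if (ncol(m) < 3) abort("dispersion estimation needs at least 3 samples")
  sf <- size_factors$size_factor[match(colnames(m), size_factors$sample_id)]
  norm <- sweep(m, 2, sf, "/")
  meta <- samples[match(colnames(m), samples$sample_id), ]
  cell <- interaction(meta$fraction, meta$condition, drop = TRUE)

  num <- rep(0, nrow(m))
  den <- rep(0, nrow(m))
  base <- rep(0, nrow(m))
  for (cl in levels(cell)) {
    j <- which(cell == cl)
    if (length(j) < 2) next
    nc <- length(j)
    mu <- rowMeans(norm[, j, drop = FALSE])
    v <- rowSums((norm[, j, drop = FALSE] - mu)^2) / (nc - 1)
    hbar <- mean(1 / sf[j])
    num <- num + (nc - 1) * (v - mu * hbar)
    den <- den + (nc - 1) * mu^2
    base <- base + mu * length(j)
  }
  alpha <- ifelse(den > 0, pmax(floor, num / den), floor)
  base_mean <- base / ncol(m)

  if (moderate) {
    alpha <- moderate_dispersions(
      m, samples, sf, alpha, base_mean,
      floor = floor, pair_term = pair_term, prior_sd_min = prior_sd_min,
      prior_sd_scale = prior_sd_scale
    )
  }
  tibble(gene_id = counts$gene_id, dispersion = unname(alpha))
}

# Cox-Reid adjusted profile log-likelihood of log-dispersion at fixed means
cr_profile_nll <- function(log_alpha, y, mu, X) {
  a <- exp(log_alpha)
  w <- mu / (1 + a * mu)
  ll <- sum(stats::dnbinom(y, size = 1 / a, mu = mu, log = TRUE))
  cr <- 0.5 * determinant(crossprod(X, X * w), logarithm = TRUE)$modulus
  -(ll - as.numeric(cr))
}

moderate_dispersions <- function(m, samples, sf, alpha_init, base_mean,
                                 floor, pair_term, prior_sd_min,
                                 prior_sd_scale = 1.8) {
  X <- build_design(samples, interaction = TRUE, pair_term = pair_term)
  X <- X[colnames(m), , drop = FALSE]
  offset <- log(sf)
  n_genes <- nrow(m)
  bounds <- log(c(1e-8, 20))

  mu_hat <- matrix(0, n_genes, ncol(m))
  a_cr <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    f <- irls_nb_one(m[g, ], X, offset, alpha_init[g], max_iter = 50, tol = 1e-6)
    mu_hat[g, ] <- pmax(exp(pmin(drop(X %*% f$beta) + offset, 30)), 1e-8)
    a_cr[g] <- exp(stats::optimize(
      cr_profile_nll, bounds,
      y = m[g, ], mu = mu_hat[g, ], X = X
    )$minimum)
  }

  ok <- a_cr > 1e-6 & base_mean > 0
  trend <- rep(max(mean(a_cr[ok]), floor), n_genes)
  if (sum(ok) > 20) {
    tr <- tryCatch(
      stats::glm(a_cr[ok] ~ I(1 / base_mean[ok]),
        family = stats::Gamma(link = "identity"),
        start = c(mean(a_cr[ok]), 1)
      ),
      error = function(e) NULL
    )
    if (!is.null(tr) && all(is.finite(stats::coef(tr)))) {
      trend <- pmax(stats::coef(tr)[1] + stats::coef(tr)[2] / base_mean, floor)
    }
  }
  resid_df <- (ncol(m) - ncol(X)) / 2
  s2 <- max(
    stats::mad(log(a_cr[ok]) - log(trend[ok]))^2 - trigamma(resid_df),
    prior_sd_min^2
  )
  prior_sd <- prior_sd_scale * sqrt(s2)

  out <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    nll <- function(la) {
      cr_profile_nll(la, m[g, ], mu_hat[g, ], X) -
        stats::dnorm(la, log(trend[g]), prior_sd, log = TRUE)
    }
    out[g] <- exp(stats::optimize(nll, bounds)$minimum)
  }
  pmax(out, floor)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment over the non-missing p-values;
#' missing entries stay missing and do not enter the correction.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`, `NA` allowed.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Principal component summary of normalized log counts
#'
#' Runs PCA on `log2(normalized count + 1)` with genes as variables
#' (gene-centered) and samples as observations.
#'
#' @param counts Filtered counts tibble.
#' @param samples Sample sheet tibble.
#' @param size_factors Tibble from [estimate_size_factors()].
#' @param k Number of components for which to keep scores.
#' @return An object of class `ribotag_pca`: list with `variance` (tibble of
#'   per-component variance fractions over all components) and `scores`
#'   (tibble of per-sample scores for the first `k` components joined to the
#'   sample sheet).
#' @export
pca_variance <- function(counts, samples, size_factors, k = 2) {
  validate_counts(counts, samples)
  m <- counts_matrix(counts)
  sf <- size_factors$size_factor[match(colnames(m), size_factors$sample_id)]
  x <- t(log2(sweep(m, 2, sf, "/") + 1))
  if (k > nrow(x)) {
    warn("k exceeds the number of samples; clipping")
    k <- nrow(x)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  fr <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as_tibble(pc$x[, seq_len(k), drop = FALSE])
  scores$sample_id <- rownames(pc$x)
  out <- list(
    variance = tibble(component = seq_along(fr), variance_fraction = fr),
    scores = dplyr::left_join(scores, samples, by = "sample_id")
  )
  class(out) <- "ribotag_pca"
  out
}

#' @export
print.ribotag_pca <- function(x, ...) {
  v <- x$variance$variance_fraction
  cat("PCA summary:", length(v), "components\n")
  cat("  PC1..PC3 variance:", paste0(round(100 * head(v, 3), 1), "%", collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.ribotag_pca <- function(x, ...) x$variance

#' Plot sample scores from a PCA summary
#'
#' @param object A `ribotag_pca` object.
#' @param ... Unused.
#' @return A ggplot object: PC1 vs PC2 scores, colored by condition, shaped
#'   by fraction.
#' @export
autoplot.ribotag_pca <- function(object, ...) {
  v <- object$variance$variance_fraction
  lab <- function(i) sprintf("PC%d (%.1f%%)", i, 100 * v[i])
  ggplot2::ggplot(
    object$scores,
    ggplot2::aes(.data$PC1, .data$PC2, colour = .data$condition, shape = .data$fraction)
  ) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_bw()
}
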