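#' Build the paired fraction-by-condition design matrix
#'
#' Columns, in order: intercept, condition levels (baseline dropped), pair
#' indicators, the IP-fraction indicator, and fraction-by-condition
#' interaction terms. Pair indicators that are linearly dependent on earlier
#' columns (one per condition, since pairs are nested in conditions) are
#' dropped deterministically in input order.
#'
#' @param samples Sample sheet tibble with `sample_id`, `fraction`
#'   (`total`/`OL`), `condition` (factor, baseline first) and `pair_id`.
#' @param interaction Include fraction-by-condition interaction columns
#'   (`TRUE` for the full model, `FALSE` for the reduced model of the
#'   likelihood ratio test).
#' @param pair_term Include pair indicators.
#' @return A numeric design matrix with samples as rows (named by
#'   `sample_id`) and an attribute `terms` mapping columns to model terms.
#' @export
build_design <- function(samples, interaction = TRUE, pair_term = TRUE) {
  if (!is.factor(samples$condition)) {
    samples$condition <- factor(samples$condition, levels = unique(samples$condition))
  }
  if (!is.factor(samples$fraction)) {
    samples$fraction <- factor(samples$fraction, levels = c("total", "OL"))
  }
  cond <- samples$condition
  frac <- samples$fraction
  cols <- list(`(Intercept)` = rep(1, nrow(samples)))
  for (lv in levels(cond)[-1]) {
    cols[[paste0("condition", lv)]] <- as.numeric(cond == lv)
  }
  if (pair_term) {
    pair <- paste(cond, samples$pair_id, sep = ":")
    for (pv in unique(pair)) {
      cols[[paste0("pair", pv)]] <- as.numeric(pair == pv)
    }
  }
  cols[["fractionOL"]] <- as.numeric(frac == "OL")
  if (interaction) {
    for (lv in levels(cond)[-1]) {
      cols[[paste0("fractionOL:condition", lv)]] <-
        as.numeric(frac == "OL" & cond == lv)
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- samples$sample_id
  # sequential rank check: keep a column only if it adds rank
  keep <- logical(ncol(x))
  r <- 0
  for (j in seq_len(ncol(x))) {
    cand <- x[, c(which(keep), j), drop = FALSE]
    rj <- qr(cand)$rank
    if (rj > r) {
      keep[j] <- TRUE
      r <- rj
    }
  }
  x <- x[, keep, drop = FALSE]
  attr(x, "interaction") <- interaction
  x
}

nb_loglik <- function(y, mu, alpha) {
  if (alpha < 1e-10) {
    sum(stats::dpois(y, mu, log = TRUE))
  } else {
    sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
  }
}

irls_nb_one <- function(y, X, offset, alpha, max_iter = 100, tol = 1e-8) {
  p <- ncol(X)
  mu <- pmax(y, 0.25) # positive starting means
  eta <- log(mu)
  beta <- rep(0, p)
  ll_old <- -Inf
  converged <- FALSE
  XtWX <- NULL
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    XtWX <- crossprod(X, X * w)
    XtWz <- crossprod(X, w * z)
    beta_new <- tryCatch(
      solve(XtWX + diag(1e-10, p), XtWz),
      error = function(e) NULL
    )
    if (is.null(beta_new)) break
    beta <- drop(beta_new)
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    ll <- nb_loglik(y, mu, alpha)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 0.1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  w <- mu / (1 + alpha * mu)
  XtWX <- crossprod(X, X * w)
  vcov <- tryCatch(solve(XtWX + diag(1e-10, p)), error = function(e) matrix(NA_real_, p, p))
  list(beta = beta, vcov = vcov, loglik = ll_old, converged = converged)
}

#' Fit gene-wise negative-binomial log-linear models
#'
#' Per-gene iteratively reweighted least squares fit of a negative-binomial
#' GLM with log link, using log size factors as offsets and a fixed
#' (pre-estimated) dispersion per gene. Coefficients and their covariance are
#' reported on the log2 scale. Non-converged genes are flagged, not dropped.
#'
#' @param counts Filtered counts tibble.
#' @param samples Sample sheet tibble.
#' @param size_factors Tibble from [estimate_size_factors()].
#' @param dispersions Tibble from [estimate_dispersions()]; the same
#'   dispersions should be passed to the full and the reduced fit so the
#'   likelihood ratio test compares means only.
#' @param design Either `"full"` (fraction-by-condition interaction included)
#'   or `"reduced"` (interaction omitted), or a design matrix from
#'   [build_design()].
#' @param pair_term Include pair indicators when building the design.
#' @param max_iter,tol IRLS iteration cap and relative log-likelihood
#'   tolerance.
#' @return An object of class `nb_fit` with per-gene coefficients (log2),
#'   covariance, log-likelihood and convergence flags. Use [tidy()] for a
#'   long coefficient table and [wald_contrast()] / [lrt_interaction()] for
#'   inference.
#' @export
fit_nb_glm <- function(counts, samples, size_factors, dispersions,
                       design = c("full", "reduced"), pair_term = TRUE,
                       max_iter = 100, tol = 1e-8) {
  validate_counts(counts, samples)
  if (is.character(design)) {
    design <- match.arg(design)
    X <- build_design(samples, interaction = design == "full", pair_term = pair_term)
  } else {
    X <- design
  }
  m <- counts_matrix(counts)
  X <- X[colnames(m), , drop = FALSE]
  if (qr(X)$rank < ncol(X)) abort("design matrix is rank-deficient")
  sf <- size_factors$size_factor[match(colnames(m), size_factors$sample_id)]
  alpha <- dispersions$dispersion[match(counts$gene_id, dispersions$gene_id)]
  if (anyNA(alpha)) abort("dispersions missing for some genes")
  offset <- log(sf)

  n_genes <- nrow(m)
  p <- ncol(X)
  beta <- matrix(NA_real_, n_genes, p, dimnames = list(counts$gene_id, colnames(X)))
  vcov <- array(NA_real_, c(p, p, n_genes))
  ll <- rep(NA_real_, n_genes)
  conv <- logical(n_genes)
  log2e <- log(2)
  for (g in seq_len(n_genes)) {
    fit <- irls_nb_one(m[g, ], X, offset, alpha[g], max_iter, tol)
    beta[g, ] <- fit$beta / log2e
    vcov[, , g] <- fit$vcov / log2e^2
    ll[g] <- fit$loglik
    conv[g] <- fit$converged
  }
  structure(
    list(
      gene_id = counts$gene_id,
      coefficients = beta,
      vcov = vcov,
      loglik = ll,
      converged = conv,
      dispersion = alpha,
      base_mean = rowMeans(sweep(m, 2, sf, "/")),
      design = X,
      samples = samples,
      interaction = isTRUE(attr(X, "interaction"))
    ),
    class = "nb_fit"
  )
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(
    "Negative-binomial GLM fit:", length(x$gene_id), "genes,",
    ncol(x$coefficients), "coefficients;",
    sum(!x$converged), "non-converged\n"
  )
  invisible(x)
}

#' @export
tidy.nb_fit <- function(x, ...) {
  se <- t(vapply(
    seq_along(x$gene_id),
    function(g) sqrt(pmax(diag(x$vcov[, , g]), 0)),
    numeric(ncol(x$coefficients))
  ))
  tibble(
    gene_id = rep(x$gene_id, each = ncol(x$coefficients)),
    term = rep(colnames(x$coefficients), length(x$gene_id)),
    estimate = as.vector(t(x$coefficients)),
    std.error = as.vector(t(se))
  )
}

#' @export
glance.nb_fit <- function(x, ...) {
  tibble(
    n_genes = length(x$gene_id),
    n_coef = ncol(x$coefficients),
    n_samples = nrow(x$design),
    prop_converged = mean(x$converged),
    median_dispersion = stats::median(x$dispersion)
  )
}

resolve_contrast <- function(fit, contrast) {
  terms <- colnames(fit$coefficients)
  if (is.character(contrast) || (!is.null(names(contrast)) && is.numeric(contrast))) {
    if (is.character(contrast)) contrast <- setNames(rep(1, length(contrast)), contrast)
    missing <- setdiff(names(contrast), terms)
    if (length(missing) > 0) {
      abort(paste0("unknown design term(s): ", paste(missing, collapse = ", ")))
    }
    cvec <- setNames(rep(0, length(terms)), terms)
    cvec[names(contrast)] <- contrast
  } else {
    if (length(contrast) != length(terms)) abort("contrast length does not match design")
    cvec <- setNames(as.numeric(contrast), terms)
  }
  if (all(cvec == 0)) abort("contrast is the zero vector")
  cvec
}

#' Wald test for a coefficient combination
#'
#' Computes `log2fc = c'beta`, its standard error from the coefficient
#' covariance, the Wald statistic and a two-sided normal p-value, with
#' Benjamini-Hochberg q-values across genes. Non-converged genes get missing
#' p-values and are excluded from the correction.
#'
#' @param fit An `nb_fit` object.
#' @param contrast A named numeric vector of coefficient weights (or a
#'   character vector of terms, each weighted 1), or a full-length numeric
#'   vector in design-column order.
#' @return A tibble with columns `gene_id`, `baseMean`, `log2fc`, `se`,
#'   `stat`, `pvalue`, `qvalue`, `test_kind`.
#' @export
wald_contrast <- function(fit, contrast) {
  cvec <- resolve_contrast(fit, contrast)
  n <- length(fit$gene_id)
  lfc <- drop(fit$coefficients %*% cvec)
  varc <- vapply(
    seq_len(n),
    function(g) drop(t(cvec) %*% fit$vcov[, , g] %*% cvec),
    numeric(1)
  )
  se <- sqrt(pmax(varc, 0))
  stat <- lfc / se
  p <- 2 * stats::pnorm(-abs(stat))
  p[!fit$converged | !is.finite(stat)] <- NA_real_
  tibble(
    gene_id = fit$gene_id,
    baseMean = fit$base_mean,
    log2fc = lfc,
    se = se,
    stat = stat,
    pvalue = p,
    qvalue = bh_adjust(p),
    test_kind = "wald"
  )
}

#' Likelihood ratio test of the fraction-by-condition interaction
#'
#' Compares a full fit (with interaction) against a nested reduced fit
#' (without), gene by gene, using the chi-squared reference with degrees of
#' freedom equal to the difference in free coefficients. Both fits must use
#' the same genes and the same dispersions. Negative statistics (numerical
#' noise) are clipped to zero with a warning.
#'
#' @param fit_full,fit_reduced `nb_fit` objects for nested designs.
#' @return A tibble in the same shape as [wald_contrast()] with
#'   `test_kind = "lrt"` (the `log2fc` column is `NA`: the test is an
#'   omnibus screen, not an effect estimate).
#' @export
lrt_interaction <- function(fit_full, fit_reduced) {
  if (!identical(fit_full$gene_id, fit_reduced$gene_id)) {
    abort("fits cover different genes")
  }
  if (!isTRUE(all.equal(fit_full$dispersion, fit_reduced$dispersion))) {
    abort("full and reduced fits must share dispersions")
  }
  terms_full <- colnames(fit_full$coefficients)
  terms_red <- colnames(fit_reduced$coefficients)
  if (!all(terms_red %in% terms_full) || length(terms_full) <= length(terms_red)) {
    abort("designs are not strictly nested (reduced terms must be a proper subset)")
  }
  df <- length(terms_full) - length(terms_red)
  stat <- 2 * (fit_full$loglik - fit_reduced$loglik)
  if (any(stat < -1e-6, na.rm = TRUE)) {
    warn("negative LRT statistics clipped to 0; consider refitting the affected genes")
  }
  stat <- pmax(stat, 0)
  ok <- fit_full$converged & fit_reduced$converged & is.finite(stat)
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  p[!ok] <- NA_real_
  tibble(
    gene_id = fit_full$gene_id,
    baseMean = fit_full$base_mean,
    log2fc = NA_real_,
    se = NA_real_,
    stat = stat,
    pvalue = p,
    qvalue = bh_adjust(p),
    test_kind = "lrt"
  )
}
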