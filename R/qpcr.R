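#' Delta-delta-Ct fold changes of IP over paired total
#'
#' Technical replicates are averaged on the Ct scale; per sample,
#' `dCt = Ct_target - mean(Ct_references)`; per pair,
#' `ddCt = dCt_OL - dCt_total`; the reported fold is `2^(-ddCt)`. The three
#' (or more) reference transcripts are combined by the arithmetic mean of
#' their Ct values, i.e. the geometric mean of their expression.
#'
#' @param plate qPCR tibble with columns `sample_id`, `fraction`
#'   (`total`/`OL`), `condition`, `pair_id`, `target`, `replicate`, `ct`, and
#'   optionally `undetected` (logical).
#' @param targets Target gene(s) to quantify; defaults to every non-reference
#'   target on the plate.
#' @param refs Character vector of reference transcripts.
#' @return Tibble, one row per (pair, target): `pair_id`, `condition`,
#'   `target`, `fold`, `reason` (`NA` when quantified; otherwise why the fold
#'   is missing).
#' @export
ddct_fold <- function(plate, targets = NULL, refs) {
  if (!"undetected" %in% names(plate)) plate$undetected <- FALSE
  targets <- targets %||% setdiff(unique(plate$target), refs)
  if (length(refs) == 0) abort("at least one reference transcript is required")

  well <- plate |>
    dplyr::group_by(
      .data$pair_id, .data$condition, .data$fraction, .data$target
    ) |>
    dplyr::summarise(
      ct = mean(.data$ct),
      undetected = any(.data$undetected),
      .groups = "drop"
    )

  purrr::map_dfr(unique(well$pair_id), function(pid) {
    pw <- dplyr::filter(well, .data$pair_id == pid)
    purrr::map_dfr(targets, function(tg) {
      row <- tibble(
        pair_id = pid,
        condition = pw$condition[1],
        target = tg,
        fold = NA_real_,
        reason = NA_character_
      )
      dct <- vapply(c("OL", "total"), function(fr) {
        t_row <- dplyr::filter(pw, .data$fraction == fr, .data$target == tg)
        r_rows <- dplyr::filter(pw, .data$fraction == fr, .data$target %in% refs)
        if (nrow(t_row) != 1 || nrow(r_rows) != length(refs)) {
          return(NA_real_)
        }
        if (t_row$undetected || any(r_rows$undetected)) {
          return(NaN)
        }
        t_row$ct - mean(r_rows$ct)
      }, numeric(1))
      if (anyNA(dct) && !any(is.nan(dct))) {
        row$reason <- "missing wells"
      } else if (any(is.nan(dct))) {
        row$reason <- "undetected Ct in a required well"
      } else {
        row$fold <- 2^(-(dct[["OL"]] - dct[["total"]]))
      }
      row
    })
  })
}

#' Per-condition summary of ddCt folds
#'
#' @param folds Tibble from [ddct_fold()].
#' @return Tibble per (target, condition): `n`, `mean_fold`, `sd_fold`.
#' @export
summarize_folds <- function(folds) {
  folds |>
    dplyr::filter(!is.na(.data$fold)) |>
    dplyr::group_by(.data$target, .data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_fold = mean(.data$fold),
      sd_fold = stats::sd(.data$fold),
      .groups = "drop"
    )
}

mw_u_stat <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Two-sided Mann-Whitney U test
#'
#' Exact two-sided p-values where feasible: with no ties and
#' `n1 * n2 <= 400`, via the exact Wilcoxon rank-sum distribution (equivalent
#' to full enumeration); with ties, by enumerating every assignment of the
#' observed values to the two groups when `choose(n1 + n2, n1) <= 2e5`
#' (mid-rank U statistic). Otherwise the normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y Numeric vectors (each with at least one value).
#' @return One-row tibble: `U` (for the first group), `p`, `method`,
#'   `n1`, `n2`.
#' @export
mann_whitney_two_sided <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1 || n2 < 1) abort("each group needs at least one value")
  u <- mw_u_stat(x, y)
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && n1 * n2 <= 400) {
    p <- 2 * min(
      stats::pwilcox(u, n1, n2),
      stats::pwilcox(n1 * n2 - u, n1, n2)
    )
    method <- "exact"
  } else if (ties && choose(n1 + n2, n1) <= 2e5) {
    vals <- c(x, y)
    dev_obs <- abs(u - n1 * n2 / 2)
    idx <- combn(n1 + n2, n1)
    devs <- apply(idx, 2, function(i) {
      abs(mw_u_stat(vals[i], vals[-i]) - n1 * n2 / 2)
    })
    p <- mean(devs >= dev_obs - 1e-9)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    r <- rank(c(x, y))
    tie_tab <- table(r)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * (n + 1 - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-max(z, 0))
    method <- "normal_approx"
  }
  tibble(U = u, p = min(p, 1), method = method, n1 = n1, n2 = n2)
}
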