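#' Hypergeometric overlap between two gene lists
#'
#' Reports the observed overlap `k`, the overlap expected under independence
#' (`n1 * n2 / N`), the representation factor `k / expected` (1 = chance
#' level) and the exact upper-tail hypergeometric probability `P(X >= k)`.
#' List members outside the universe are dropped with a warning.
#'
#' @param list1,list2 Character vectors of gene ids.
#' @param universe Character vector: the gene universe.
#' @return One-row tibble: `k`, `n1`, `n2`, `N`, `expected`,
#'   `representation_factor`, `p_hyper`, `n_dropped`.
#' @export
hypergeom_overlap <- function(list1, list2, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("universe is empty")
  l1 <- unique(list1)
  l2 <- unique(list2)
  dropped <- sum(!l1 %in% universe) + sum(!l2 %in% universe)
  if (dropped > 0) {
    warn(sprintf("%d gene(s) outside the universe were dropped", dropped))
    l1 <- intersect(l1, universe)
    l2 <- intersect(l2, universe)
  }
  k <- length(intersect(l1, l2))
  n1 <- length(l1)
  n2 <- length(l2)
  N <- length(universe)
  expected <- n1 * n2 / N
  tibble(
    k = k, n1 = n1, n2 = n2, N = N,
    expected = expected,
    representation_factor = if (expected > 0) k / expected else NA_real_,
    p_hyper = stats::phyper(k - 1, n1, N - n1, n2, lower.tail = FALSE),
    n_dropped = dropped
  )
}

#' Exact moments of the hypergeometric overlap null
#'
#' Mean and standard deviation of the overlap between a random size-`n`
#' subset of an `N`-gene universe and a fixed set of `K` genes:
#' `mean = nK/N`, `var = nK(N-K)(N-n) / (N^2 (N-1))`.
#'
#' @param n Query set size.
#' @param K Target set size (within the universe).
#' @param N Universe size.
#' @return One-row tibble with `mean` and `sd`.
#' @export
analytic_overlap_moments <- function(n, K, N) {
  if (n < 0 || K < 0 || n > N || K > N) abort("need 0 <= n, K <= N")
  n <- as.numeric(n)
  K <- as.numeric(K)
  N <- as.numeric(N)
  m <- n * K / N
  v <- if (N > 1) n * K * (N - K) * (N - n) / (N^2 * (N - 1)) else 0
  tibble(mean = m, sd = sqrt(v))
}

#' Resampling z-score for operon (regulon) overlap
#'
#' Compares the observed overlap between a query gene list and each operon
#' gene set against the overlap of `R` random gene sets of the same size
#' drawn without replacement from the expressed universe. The z-score uses
#' the resampled mean and sample standard deviation (denominator `R - 1`);
#' the analytic hypergeometric moments are reported alongside. The same `R`
#' random sets are reused across operons.
#'
#' @param query_set Character vector (e.g. upregulated high-confidence
#'   genes); must be a subset of the universe (outside genes are dropped).
#' @param operon_sets A named list of character vectors, or a single
#'   character vector.
#' @param expressed_universe Character vector of expressed genes.
#' @param R Number of random sets (the classic choice of 10 is statistically
#'   fragile; a warning is issued below 100).
#' @param seed Integer seed for the resampling.
#' @return Tibble, one row per operon: `operon_id`, `k_observed`,
#'   `null_mean`, `null_sd`, `z`, `analytic_mean`, `analytic_sd`,
#'   `z_analytic`, `n_resamples`, `seed`.
#' @export
operon_zscore <- function(query_set, operon_sets, expressed_universe,
                          R = 10, seed = 1L) {
  if (R < 2) abort("R must be at least 2 (the null sd is undefined otherwise)")
  if (R < 100) warn("R < 100 random sets: the resampled null sd is noisy")
  if (!is.list(operon_sets)) operon_sets <- list(operon = operon_sets)
  universe <- unique(expressed_universe)
  query <- intersect(unique(query_set), universe)
  if (length(query) > length(universe)) abort("query set larger than universe")
  n <- length(query)
  N <- length(universe)

  withr::with_seed(seed, {
    random_sets <- replicate(R, sample(universe, n), simplify = FALSE)
    purrr::imap_dfr(operon_sets, function(op, nm) {
      op <- intersect(unique(op), universe)
      K <- length(op)
      k_obs <- length(intersect(query, op))
      null_k <- vapply(random_sets, function(s) length(intersect(s, op)), numeric(1))
      mu <- mean(null_k)
      sdev <- stats::sd(null_k)
      an <- analytic_overlap_moments(n, K, N)
      tibble(
        operon_id = nm,
        k_observed = k_obs,
        null_mean = mu,
        null_sd = sdev,
        z = if (sdev > 0) (k_obs - mu) / sdev else NA_real_,
        analytic_mean = an$mean,
        analytic_sd = an$sd,
        z_analytic = if (an$sd > 0) (k_obs - an$mean) / an$sd else NA_real_,
        n_resamples = R,
        seed = as.integer(seed)
      )
    })
  })
}

#' Marker-overlap contamination panel
#'
#' Crosses DEG lists (e.g. per timepoint and direction) with cell-type
#' marker sets, computing one hypergeometric overlap per combination and
#' flagging cell types whose markers are over-represented (representation
#' factor above 1 with Benjamini-Hochberg `q < 0.05` across the panel).
#'
#' @param deg_lists Named list of character vectors.
#' @param marker_sets Named list of character vectors (one per cell type).
#' @param universe Character vector: the gene universe.
#' @return Tibble, one row per (DEG list, cell type): the overlap columns of
#'   [hypergeom_overlap()] plus `deg_list`, `cell_type`, `qvalue`, `flagged`.
#' @export
marker_contamination_panel <- function(deg_lists, marker_sets, universe) {
  grid <- tidyr::expand_grid(
    deg_list = names(deg_lists),
    cell_type = names(marker_sets)
  )
  res <- purrr::pmap_dfr(grid, function(deg_list, cell_type) {
    ov <- suppressWarnings(
      hypergeom_overlap(deg_lists[[deg_list]], marker_sets[[cell_type]], universe)
    )
    dplyr::bind_cols(tibble(deg_list = deg_list, cell_type = cell_type), ov)
  })
  res$qvalue <- bh_adjust(res$p_hyper)
  res$flagged <- !is.na(res$qvalue) & res$qvalue < 0.05 &
    !is.na(res$representation_factor) & res$representation_factor > 1
  res
}

#' Plot a marker-overlap contamination panel
#'
#' @param panel Tibble from [marker_contamination_panel()].
#' @return A ggplot bar chart of representation factors per cell type and
#'   DEG list, flagged cells highlighted.
#' @export
plot_contamination_panel <- function(panel) {
  ggplot2::ggplot(
    panel,
    ggplot2::aes(.data$cell_type, .data$representation_factor, fill = .data$flagged)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::facet_wrap(~deg_list) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "representation factor") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
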