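# Shared builders for small synthetic inputs used across test files.

# counts tibble from a plain matrix
counts_tbl <- function(m, gene_ids = sprintf("g%03d", seq_len(nrow(m)))) {
  colnames(m) <- colnames(m) %||% sprintf("s%02d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(gene_id = gene_ids), tibble::as_tibble(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample sheet for a paired design: conditions x pairs x (total, OL)
paired_samples <- function(conditions, n_pairs) {
  grid <- expand.grid(
    fraction = c("total", "OL"),
    pair = seq_len(n_pairs),
    condition = conditions,
    stringsAsFactors = FALSE
  )
  tibble::tibble(
    sample_id = paste0(grid$condition, "_p", grid$pair, "_", grid$fraction),
    fraction = factor(grid$fraction, levels = c("total", "OL")),
    condition = factor(grid$condition, levels = conditions),
    pair_id = paste0(grid$condition, "_p", grid$pair)
  )
}

# NB counts for a paired layout with per-cell means given as a genes x cells
# matrix (cells ordered as interaction(fraction, condition))
nb_counts <- function(mu_cells, samples, alpha, seed = 1) {
  withr::with_seed(seed, {
    cell <- paste(samples$fraction, samples$condition)
    cells <- unique(cell)
    m <- matrix(0, nrow(mu_cells), nrow(samples))
    for (j in seq_len(nrow(samples))) {
      mu <- mu_cells[, match(cell[j], cells)]
      m[, j] <- stats::rnbinom(nrow(mu_cells), mu = mu, size = 1 / alpha)
    }
    colnames(m) <- samples$sample_id
    m
  })
}

# hand-built enrichment profile row
profile_row <- function(gene_id, condition, log2fc_total = 0, q_total = 1,
                        delta_log2fc = NA, q_delta = NA,
                        ol_log2fc_vs_naive = NA, q_ol = NA,
                        total_log2fc_vs_naive = NA, q_total_change = NA) {
  tibble::tibble(
    gene_id = gene_id, condition = condition, baseMean = 100,
    log2fc_total = log2fc_total, q_total = q_total,
    delta_log2fc = delta_log2fc, q_delta = q_delta,
    ol_log2fc_vs_naive = ol_log2fc_vs_naive, q_ol = q_ol,
    total_log2fc_vs_naive = total_log2fc_vs_naive,
    q_total_change = q_total_change,
    lrt_stat = NA_real_, lrt_q = NA_real_
  )
}

# exhaustive hypergeometric upper tail by enumeration (independent oracle)
enum_hyper_tail <- function(k, n1, n2, N) {
  universe <- seq_len(N)
  set1 <- seq_len(n1)
  draws <- utils::combn(N, n2)
  hits <- apply(draws, 2, function(d) sum(d %in% set1))
  mean(hits >= k)
}

# exhaustive two-sided Mann-Whitney by enumeration (independent oracle)
enum_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  vals <- c(x, y)
  ustat <- function(a, b) {
    r <- rank(c(a, b))
    sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  }
  dev_obs <- abs(ustat(x, y) - n1 * n2 / 2)
  idx <- utils::combn(n1 + n2, n1)
  devs <- apply(idx, 2, function(i) abs(ustat(vals[i], vals[-i]) - n1 * n2 / 2))
  mean(devs >= dev_obs - 1e-9)
}

# one-pair qPCR plate with two identical technical replicates per well
make_plate <- function(ct_by_target) {
  rows <- purrr::imap_dfr(ct_by_target, function(cts, tg) {
    tibble::tibble(
      sample_id = paste0("naive_p1_", c("total", "OL")),
      fraction = factor(c("total", "OL"), levels = c("total", "OL")),
      condition = "naive", pair_id = "naive_p1",
      target = tg, ct = cts
    )
  })
  dplyr::bind_rows(
    dplyr::mutate(rows, replicate = 1L),
    dplyr::mutate(rows, replicate = 2L)
  )
}
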