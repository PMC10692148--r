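#' Decision thresholds for translatome enrichment analysis
#'
#' All fold-change thresholds are on the log2 scale: `enrich_lfc` (0.5) calls
#' a gene OL-enriched against its paired total; `high_specific_lfc` (2) calls
#' highly selective OL expression; `deg_lfc` (1) calls injury-regulated
#' transcripts vs naive; `delta_lfc` (1) is the differential-enrichment
#' magnitude of filtration arm 1; `arm2_total_lfc` (1) is the constant-
#' enrichment requirement of arm 2; `q_cut` (0.05) applies throughout.
#'
#' @param enrich_lfc,high_specific_lfc,deg_lfc,delta_lfc,arm2_total_lfc
#'   Positive log2 thresholds.
#' @param q_cut FDR cutoff in (0, 1).
#' @return A named list of class `ol_thresholds`.
#' @export
default_thresholds <- function(enrich_lfc = 0.5, high_specific_lfc = 2,
                               deg_lfc = 1, delta_lfc = 1,
                               arm2_total_lfc = 1, q_cut = 0.05) {
  th <- list(
    enrich_lfc = enrich_lfc, high_specific_lfc = high_specific_lfc,
    deg_lfc = deg_lfc, delta_lfc = delta_lfc,
    arm2_total_lfc = arm2_total_lfc, q_cut = q_cut
  )
  if (any(unlist(th[1:5]) <= 0)) abort("log2 thresholds must be positive")
  if (q_cut <= 0 || q_cut >= 1) abort("q_cut must be in (0, 1)")
  structure(th, class = "ol_thresholds")
}

#' Per-gene, per-condition OL enrichment profile
#'
#' Runs the full modelling chain on a paired IP/total count matrix: low-count
#' filter, RLE size factors, moderated dispersions, negative-binomial fits,
#' and the four Wald contrast families per condition: OL-vs-total enrichment
#' (`log2fc_total`), differential enrichment vs naive (`delta_log2fc`, the
#' interaction term), OL change vs naive (`ol_log2fc_vs_naive`) and total
#' change vs naive (`total_log2fc_vs_naive`), plus the gene-level
#' interaction likelihood ratio test. Samples from the same tissue are
#' paired for the within-pair quantities (enrichment, differential
#' enrichment, LRT); the between-condition contrasts come from a companion
#' fit without pair terms, since pairs are nested in conditions and spending
#' coefficients on them only inflates the variance of condition effects.
#'
#' @param counts Counts tibble (`gene_id` + one column per sample).
#' @param samples Sample sheet tibble.
#' @param min_total Low-count filter threshold (summed across samples).
#' @param pair_term Include pair effects in the design.
#' @param moderate_dispersion Moderate gene-wise dispersions towards a
#'   mean-dispersion trend (default `TRUE`: with three pairs per condition
#'   the raw gene-wise estimates are too noisy for well-calibrated Wald
#'   tests, so the profile uses the moderated estimator, as the standard
#'   count-model toolchains do).
#' @return A tibble with one row per gene x condition: `gene_id`,
#'   `condition`, `baseMean`, `log2fc_total`, `q_total`, `delta_log2fc`,
#'   `q_delta` (both `NA` at baseline), `ol_log2fc_vs_naive`, `q_ol`,
#'   `total_log2fc_vs_naive`, `q_total_change`, `lrt_stat`, `lrt_q`.
#' @export
enrichment_profile <- function(counts, samples, min_total = 10,
                               pair_term = TRUE, moderate_dispersion = TRUE) {
  counts <- filter_low_counts(counts, min_total)
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersions(counts, samples, sf,
    moderate = moderate_dispersion, pair_term = pair_term
  )
  fit_full <- fit_nb_glm(counts, samples, sf, disp, "full", pair_term = pair_term)
  fit_red <- fit_nb_glm(counts, samples, sf, disp, "reduced", pair_term = pair_term)
  lrt <- lrt_interaction(fit_full, fit_red)
  fit_cond <- if (pair_term) {
    fit_nb_glm(counts, samples, sf, disp, "full", pair_term = FALSE)
  } else {
    fit_full
  }

  conds <- levels(samples$condition)
  baseline <- conds[1]
  per_cond <- purrr::map(conds, function(cond) {
    enr <- wald_contrast(fit_full, enrichment_contrast(cond, baseline))
    out <- tibble(
      gene_id = enr$gene_id,
      condition = cond,
      baseMean = enr$baseMean,
      log2fc_total = enr$log2fc,
      q_total = enr$qvalue,
      delta_log2fc = NA_real_, q_delta = NA_real_,
      ol_log2fc_vs_naive = NA_real_, q_ol = NA_real_,
      total_log2fc_vs_naive = NA_real_, q_total_change = NA_real_
    )
    if (cond != baseline) {
      dlt <- wald_contrast(fit_full, c(delta_term(cond)))
      olc <- wald_contrast(
        fit_cond,
        setNames(c(1, 1), c(paste0("condition", cond), delta_term(cond)))
      )
      tot <- wald_contrast(fit_cond, paste0("condition", cond))
      out$delta_log2fc <- dlt$log2fc
      out$q_delta <- dlt$qvalue
      out$ol_log2fc_vs_naive <- olc$log2fc
      out$q_ol <- olc$qvalue
      out$total_log2fc_vs_naive <- tot$log2fc
      out$q_total_change <- tot$qvalue
    }
    out
  })
  profile <- dplyr::bind_rows(per_cond)
  profile <- dplyr::left_join(
    profile,
    tibble(gene_id = lrt$gene_id, lrt_stat = lrt$stat, lrt_q = lrt$qvalue),
    by = "gene_id"
  )
  profile$condition <- factor(profile$condition, levels = conds)
  profile
}

enrichment_contrast <- function(cond, baseline) {
  if (cond == baseline) {
    c(fractionOL = 1)
  } else {
    setNames(c(1, 1), c("fractionOL", delta_term(cond)))
  }
}

delta_term <- function(cond) paste0("fractionOL:condition", cond)

#' Classify OL expression of each gene at a condition
#'
#' Labels genes by their IP-vs-total enrichment: `enriched` when
#' `log2fc_total` exceeds `enrich_lfc` with `q < q_cut`; `highly_specific`
#' when it additionally exceeds `high_specific_lfc`; `depleted` below
#' `-enrich_lfc` with `q < q_cut`; otherwise `neutral`.
#'
#' @param profile Tibble from [enrichment_profile()].
#' @param condition Condition label to classify at.
#' @param thresholds A [default_thresholds()] list.
#' @return Tibble `gene_id`, `condition`, `log2fc_total`, `q_total`, `class`.
#' @export
classify_ol_expression <- function(profile, condition,
                                   thresholds = default_thresholds()) {
  th <- thresholds
  x <- dplyr::filter(profile, .data$condition == !!condition)
  if (nrow(x) == 0) abort(paste0("no profile rows for condition ", condition))
  sig <- !is.na(x$q_total) & x$q_total < th$q_cut
  cls <- dplyr::case_when(
    sig & x$log2fc_total > th$high_specific_lfc ~ "highly_specific",
    sig & x$log2fc_total > th$enrich_lfc ~ "enriched",
    sig & x$log2fc_total < -th$enrich_lfc ~ "depleted",
    TRUE ~ "neutral"
  )
  tibble(
    gene_id = x$gene_id, condition = condition,
    log2fc_total = x$log2fc_total, q_total = x$q_total,
    class = factor(cls, levels = c("highly_specific", "enriched", "depleted", "neutral"))
  )
}

#' Call injury-regulated transcripts in the OL fraction
#'
#' A gene is an `up` DEG at a timepoint when its OL-fraction change vs naive
#' exceeds `deg_lfc` with `q < q_cut`, and a `down` DEG when it falls below
#' `-deg_lfc`.
#'
#' @param profile Tibble from [enrichment_profile()].
#' @param timepoint A post-injury condition label.
#' @param thresholds A [default_thresholds()] list.
#' @return Tibble `gene_id`, `timepoint`, `direction`, `ol_log2fc_vs_naive`,
#'   `q_ol` (DEGs only).
#' @export
call_sci_degs <- function(profile, timepoint,
                          thresholds = default_thresholds()) {
  th <- thresholds
  x <- dplyr::filter(profile, .data$condition == !!timepoint)
  sig <- !is.na(x$q_ol) & x$q_ol < th$q_cut
  up <- sig & x$ol_log2fc_vs_naive > th$deg_lfc
  down <- sig & x$ol_log2fc_vs_naive < -th$deg_lfc
  out <- tibble(
    gene_id = x$gene_id,
    timepoint = timepoint,
    direction = dplyr::case_when(up ~ "up", down ~ "down", TRUE ~ NA_character_),
    ol_log2fc_vs_naive = x$ol_log2fc_vs_naive,
    q_ol = x$q_ol
  )
  dplyr::filter(out, !is.na(.data$direction))
}

#' Two-arm filtration of injury-regulated OL transcripts
#'
#' Separates genuine OL translatome regulation from contamination by other
#' cell types. Arm 1 accepts a DEG whose OL enrichment itself changed
#' concordantly: `|delta_log2fc| > delta_lfc`, `q_delta < q_cut`, and the
#' sign of the change matches the DEG direction. Arm 2 accepts constitutively
#' OL-enriched transcripts: `log2fc_total > arm2_total_lfc` with
#' `q_total < q_cut` in the naive condition and at the focal timepoint (set
#' `arm2_scope = "all"` to require it at every condition). A DEG is high
#' confidence when either arm passes; non-DEGs are never high confidence.
#'
#' @param degs Tibble from [call_sci_degs()] on the same profile.
#' @param profile Tibble from [enrichment_profile()].
#' @param timepoint The focal post-injury condition.
#' @param thresholds A [default_thresholds()] list.
#' @param arm2_scope `"naive_and_focal"` (default) or `"all"`.
#' @return Verdict tibble: `gene_id`, `timepoint`, `direction`,
#'   `is_raw_deg`, `passes_arm1`, `passes_arm2`, `high_confidence`.
#' @export
two_arm_filter <- function(degs, profile, timepoint,
                           thresholds = default_thresholds(),
                           arm2_scope = c("naive_and_focal", "all")) {
  th <- thresholds
  arm2_scope <- match.arg(arm2_scope)
  focal <- dplyr::filter(profile, .data$condition == !!timepoint)
  missing <- setdiff(degs$gene_id, focal$gene_id)
  if (length(missing) > 0) {
    abort(paste0(
      "DEG gene(s) absent from profile: ",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  idx <- match(degs$gene_id, focal$gene_id)
  delta <- focal$delta_log2fc[idx]
  q_delta <- focal$q_delta[idx]
  dir_sign <- ifelse(degs$direction == "up", 1, -1)
  passes_arm1 <- !is.na(delta) & !is.na(q_delta) &
    abs(delta) > th$delta_lfc & q_delta < th$q_cut &
    sign(delta) == dir_sign

  arm2_conds <- if (arm2_scope == "all") {
    levels(profile$condition)
  } else {
    unique(c(levels(profile$condition)[1], timepoint))
  }
  arm2_ok <- rep(TRUE, nrow(degs))
  for (cond in arm2_conds) {
    pc <- dplyr::filter(profile, .data$condition == !!cond)
    j <- match(degs$gene_id, pc$gene_id)
    ok <- !is.na(pc$log2fc_total[j]) & !is.na(pc$q_total[j]) &
      pc$log2fc_total[j] > th$arm2_total_lfc & pc$q_total[j] < th$q_cut
    arm2_ok <- arm2_ok & ok
  }
  tibble(
    gene_id = degs$gene_id,
    timepoint = timepoint,
    direction = degs$direction,
    is_raw_deg = TRUE,
    passes_arm1 = passes_arm1,
    passes_arm2 = arm2_ok,
    high_confidence = passes_arm1 | arm2_ok
  )
}

#' Acute-phase candidate genes
#'
#' From the high-confidence upregulated genes at the first post-injury
#' timepoint, keeps those whose late-timepoint expression normalized (`q >=
#' q_cut` or `ol_log2fc_vs_naive <= deg_lfc` at the late timepoint) or fell
#' at least two-fold below the acute level (`late lfc <= acute lfc - 1`).
#'
#' @param verdicts Verdict tibble for the acute timepoint (upregulated,
#'   high-confidence rows are used).
#' @param profile Tibble from [enrichment_profile()].
#' @param acute,late Condition labels (defaults `dpi2`, `dpi42`).
#' @param thresholds A [default_thresholds()] list.
#' @return Tibble of candidate genes with acute and late effect estimates and
#'   the branch of the rule they satisfied.
#' @export
acute_candidates <- function(verdicts, profile, acute = "dpi2", late = "dpi42",
                             thresholds = default_thresholds()) {
  th <- thresholds
  genes <- verdicts$gene_id[verdicts$direction == "up" & verdicts$high_confidence]
  pa <- dplyr::filter(profile, .data$condition == !!acute)
  pl <- dplyr::filter(profile, .data$condition == !!late)
  ia <- match(genes, pa$gene_id)
  il <- match(genes, pl$gene_id)
  lfc_a <- pa$ol_log2fc_vs_naive[ia]
  lfc_l <- pl$ol_log2fc_vs_naive[il]
  q_l <- pl$q_ol[il]
  not_sig_late <- is.na(q_l) | q_l >= th$q_cut | lfc_l <= th$deg_lfc
  dropped_twofold <- !is.na(lfc_l) & lfc_l <= lfc_a - 1
  keep <- not_sig_late | dropped_twofold
  tibble(
    gene_id = genes,
    acute_log2fc = lfc_a,
    late_log2fc = lfc_l,
    late_q = q_l,
    rule = dplyr::case_when(
      not_sig_late ~ "late_not_upregulated",
      dropped_twofold ~ "late_twofold_lower",
      TRUE ~ NA_character_
    )
  )[keep, ]
}

#' Summarize regulation of a gene set
#'
#' Counts, within a gene set, how many mapped genes moved up or down in the
#' OL fraction at a condition (`|ol_log2fc_vs_naive| > lfc_cut`,
#' `q < q_cut`), with the median log2 fold change over each regulated subset.
#'
#' @param profile Tibble from [enrichment_profile()].
#' @param geneset Character vector of gene ids.
#' @param condition Post-injury condition to summarize at.
#' @param lfc_cut Log2 threshold for calling a set member regulated.
#' @param q_cut FDR cutoff.
#' @return One-row tibble: `condition`, `n_set`, `n_mapped`, `n_up`,
#'   `n_down`, `median_lfc_up`, `median_lfc_down`, and a `genes` list-column
#'   with the per-gene table.
#' @export
summarize_geneset <- function(profile, geneset, condition,
                              lfc_cut = 0.5, q_cut = 0.05) {
  x <- dplyr::filter(profile, .data$condition == !!condition)
  geneset <- unique(geneset)
  mapped <- intersect(geneset, x$gene_id)
  i <- match(mapped, x$gene_id)
  lfc <- x$ol_log2fc_vs_naive[i]
  q <- x$q_ol[i]
  sig <- !is.na(q) & q < q_cut
  up <- sig & lfc > lfc_cut
  down <- sig & lfc < -lfc_cut
  per_gene <- tibble(
    gene_id = mapped, ol_log2fc_vs_naive = lfc, q_ol = q,
    status = dplyr::case_when(up ~ "up", down ~ "down", TRUE ~ "unchanged")
  )
  tibble(
    condition = condition,
    n_set = length(geneset),
    n_mapped = length(mapped),
    n_up = sum(up),
    n_down = sum(down),
    median_lfc_up = if (any(up)) stats::median(lfc[up]) else NA_real_,
    median_lfc_down = if (any(down)) stats::median(lfc[down]) else NA_real_,
    genes = list(per_gene)
  )
}
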