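#' Configuration of an end-to-end pipeline run
#'
#' Exactly one input source must be active: either file paths to a counts
#' TSV + sample sheet TSV (plus optional marker/operon GMT files), or a
#' [sim_config()] for a fully synthetic run with ground truth.
#'
#' @param counts_path,samples_path Paths to input TSV files.
#' @param markers_gmt,operons_gmt Optional GMT paths with cell-type marker
#'   and operon gene sets.
#' @param simulation A [sim_config()]; mutually exclusive with the paths.
#' @param thresholds A [default_thresholds()] list.
#' @param pair_term Include pair effects in the design.
#' @param arm2_scope Arm-2 scope passed to [two_arm_filter()].
#' @param n_random_sets `R` for [operon_zscore()].
#' @param min_total Low-count filter threshold.
#' @param seed Integer seed covering every stochastic stage.
#' @param out_dir Output directory.
#' @return A validated `run_config` list.
#' @export
run_config <- function(counts_path = NULL, samples_path = NULL,
                       markers_gmt = NULL, operons_gmt = NULL,
                       simulation = NULL,
                       thresholds = default_thresholds(),
                       pair_term = TRUE,
                       arm2_scope = "naive_and_focal",
                       n_random_sets = 10,
                       min_total = 10,
                       seed = 1L,
                       out_dir = tempfile("ribotag_run_")) {
  has_paths <- !is.null(counts_path) || !is.null(samples_path)
  has_sim <- !is.null(simulation)
  if (has_paths && has_sim) {
    abort("give either input paths or a simulation config, not both")
  }
  if (!has_paths && !has_sim) {
    abort("one of input paths or a simulation config is required")
  }
  if (has_paths && (is.null(counts_path) || is.null(samples_path))) {
    abort("both counts_path and samples_path are required for file input")
  }
  structure(
    list(
      counts_path = counts_path, samples_path = samples_path,
      markers_gmt = markers_gmt, operons_gmt = operons_gmt,
      simulation = simulation, thresholds = thresholds,
      pair_term = pair_term, arm2_scope = arm2_scope,
      n_random_sets = n_random_sets, min_total = min_total,
      seed = as.integer(seed), out_dir = out_dir
    ),
    class = "run_config"
  )
}

pipeline_log <- function(stage, seed, msg) {
  message(sprintf("[%s] stage=%s seed=%d %s", format(Sys.time(), "%H:%M:%S"), stage, seed, msg))
}

write_stage_tsv <- function(x, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  readr::write_tsv(x, path)
  path
}

#' Run the full translatome analysis pipeline
#'
#' Simulates or loads a paired IP/total experiment, fits the enrichment
#' profile, calls injury DEGs per timepoint, applies the two-arm filtration,
#' computes the marker contamination panel before and after filtration, the
#' operon overlap z-scores for the acute upregulated set, acute-phase
#' candidates, and the PCA summary, writing every result as TSV plus a
#' manifest. Identical configuration and seed give byte-identical tables.
#'
#' @param config A [run_config()].
#' @return A manifest tibble (`artifact`, `path`, `md5`, `n_rows`),
#'   invisibly classed `ribotag_manifest` with the run metadata attached.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) abort("config must come from run_config()")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  th <- config$thresholds
  truth <- NULL
  marker_sets <- NULL
  operon_sets <- NULL

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      unlink(config$out_dir, recursive = TRUE)
      abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
    })
  }

  pipeline_log("input", seed, "loading or simulating counts")
  run_stage("input", {
    if (!is.null(config$simulation)) {
      sim_cfg <- config$simulation
      sim_cfg$seed <- seed
      sim <- generate_experiment(sim_cfg)
      counts <- sim$counts
      samples <- sim$samples
      truth <- sim$truth
      marker_sets <- truth$marker_sets
      operon_sets <- truth$operon_sets
      write_simulation(sim, file.path(config$out_dir, "simulation"))
    } else {
      counts <- read_counts_tsv(config$counts_path)
      samples <- read_samples_tsv(config$samples_path)
      if (!is.null(config$markers_gmt)) marker_sets <- read_gmt(config$markers_gmt)
      if (!is.null(config$operons_gmt)) operon_sets <- read_gmt(config$operons_gmt)
    }
    counts <- counts
    samples <- samples
  })

  pipeline_log("model", seed, "filtering, normalizing and fitting")
  artifacts <- list()
  run_stage("model", {
    counts_f <- filter_low_counts(counts, config$min_total)
    sf <- estimate_size_factors(counts_f)
    profile <- enrichment_profile(counts_f, samples,
      min_total = 1, pair_term = config$pair_term
    )
    pca <- pca_variance(counts_f, samples, sf, k = 4)
    universe <- unique(counts_f$gene_id)
    artifacts$size_factors <- sf
    artifacts$enrichment_profile <- profile
    artifacts$pca_variance <- pca$variance
    artifacts$pca_scores <- pca$scores
    universe <- universe
    profile <- profile
  })

  pipeline_log("filter", seed, "DEG calling and two-arm filtration")
  run_stage("filter", {
    timepoints <- levels(samples$condition)[-1]
    degs <- purrr::map_dfr(timepoints, ~ call_sci_degs(profile, .x, th))
    verdicts <- purrr::map_dfr(
      timepoints,
      function(tp) {
        two_arm_filter(
          dplyr::filter(degs, .data$timepoint == tp),
          profile, tp, th, config$arm2_scope
        )
      }
    )
    hc <- dplyr::filter(verdicts, .data$high_confidence)
    artifacts$raw_degs <- degs
    artifacts$verdicts <- verdicts
    artifacts$high_confidence <- hc
    acute_tp <- timepoints[1]
    late_tp <- timepoints[length(timepoints)]
    if (acute_tp != late_tp) {
      artifacts$acute_candidates <- acute_candidates(
        dplyr::filter(verdicts, .data$timepoint == acute_tp),
        profile,
        acute = acute_tp, late = late_tp, thresholds = th
      )
    }
    degs <- degs
    verdicts <- verdicts
    hc <- hc
    timepoints <- timepoints
  })

  pipeline_log("genesets", seed, "overlap statistics")
  run_stage("genesets", {
    if (!is.null(marker_sets)) {
      deg_lists <- c(
        split(degs$gene_id, paste0("raw_", degs$timepoint, "_", degs$direction)),
        split(hc$gene_id, paste0("filtered_", hc$timepoint, "_", hc$direction))
      )
      deg_lists <- deg_lists[lengths(deg_lists) > 0]
      if (length(deg_lists) > 0) {
        artifacts$contamination_panel <-
          marker_contamination_panel(deg_lists, marker_sets, universe)
      }
    }
    if (!is.null(operon_sets)) {
      acute_up <- hc$gene_id[hc$timepoint == timepoints[1] & hc$direction == "up"]
      if (length(acute_up) > 1) {
        artifacts$operon_zscores <- suppressWarnings(operon_zscore(
          acute_up, operon_sets, universe,
          R = config$n_random_sets, seed = seed
        ))
      }
    }
    if (!is.null(truth)) {
      artifacts$truth_recovery <- recovery_metrics(verdicts, degs, truth, timepoints)
    }
  })

  pipeline_log("write", seed, "writing result tables")
  manifest <- run_stage("write", {
    paths <- purrr::imap_chr(
      artifacts,
      ~ write_stage_tsv(flatten_for_tsv(.x), config$out_dir, .y)
    )
    meta <- list(
      seed = seed,
      thresholds = unclass(th),
      arm2_scope = config$arm2_scope,
      n_random_sets = config$n_random_sets,
      min_total = config$min_total,
      package_version = as.character(utils::packageVersion("ribotag"))
    )
    yaml::write_yaml(meta, file.path(config$out_dir, "run_info.yaml"))
    tibble(
      artifact = names(paths),
      path = unname(paths),
      md5 = unname(tools::md5sum(paths)),
      n_rows = vapply(artifacts, nrow, integer(1))
    )
  })
  class(manifest) <- c("ribotag_manifest", class(manifest))
  attr(manifest, "out_dir") <- config$out_dir
  attr(manifest, "seed") <- seed
  invisible(manifest)
}

flatten_for_tsv <- function(x) {
  is_list_col <- vapply(x, is.list, logical(1))
  x[!is_list_col]
}

recovery_metrics <- function(verdicts, degs, truth, timepoints) {
  purrr::map_dfr(timepoints, function(tp) {
    true_up <- rownames(truth$true_lfc_ol)[truth$true_lfc_ol[, tp] > 0]
    true_dn <- rownames(truth$true_lfc_ol)[truth$true_lfc_ol[, tp] < 0]
    contam <- truth$surge_genes
    v <- verdicts[verdicts$timepoint == tp, ]
    hc <- v$gene_id[v$high_confidence]
    raw_up <- v$gene_id[v$direction == "up"]
    raw_true_up <- intersect(raw_up, true_up)
    raw_contam_up <- intersect(raw_up, contam)
    tibble(
      timepoint = tp,
      n_true_up = length(true_up),
      n_raw_up = length(raw_up),
      n_high_confidence = length(hc),
      true_up_retained = length(intersect(hc, raw_true_up)),
      true_up_retention =
        if (length(raw_true_up) > 0) {
          length(intersect(hc, raw_true_up)) / length(raw_true_up)
        } else {
          NA_real_
        },
      contam_raw_up = length(raw_contam_up),
      contam_removed =
        if (length(raw_contam_up) > 0) {
          1 - length(intersect(hc, raw_contam_up)) / length(raw_contam_up)
        } else {
          NA_real_
        },
      true_down_retained = length(intersect(hc, intersect(v$gene_id[v$direction == "down"], true_dn)))
    )
  })
}

#' Render a human-readable report of a pipeline run
#'
#' Every number in the report is re-read from the emitted TSV tables.
#'
#' @param manifest A `ribotag_manifest` from [run_pipeline()], or an output
#'   directory path.
#' @param path Output file; defaults to `report.txt` inside the run
#'   directory.
#' @return The report path, invisibly.
#' @export
write_report <- function(manifest, path = NULL) {
  out_dir <- if (is.character(manifest)) manifest else attr(manifest, "out_dir")
  path <- path %||% file.path(out_dir, "report.txt")
  grab <- function(name) {
    f <- file.path(out_dir, paste0(name, ".tsv"))
    if (file.exists(f)) readr::read_tsv(f, show_col_types = FALSE) else NULL
  }
  lines <- c("Ribotag translatome pipeline report", strrep("=", 36), "")
  verdicts <- grab("verdicts")
  if (!is.null(verdicts) && nrow(verdicts) > 0) {
    tab <- verdicts |>
      dplyr::group_by(.data$timepoint, .data$direction) |>
      dplyr::summarise(
        raw = dplyr::n(),
        high_confidence = sum(.data$high_confidence),
        .groups = "drop"
      )
    lines <- c(lines, "DEG counts (raw -> high confidence):")
    lines <- c(lines, sprintf(
      "  %-8s %-5s %5d -> %5d",
      tab$timepoint, tab$direction, tab$raw, tab$high_confidence
    ))
  } else {
    lines <- c(lines, "DEG counts: none called")
  }
  panel <- grab("contamination_panel")
  if (!is.null(panel) && nrow(panel) > 0) {
    flagged <- panel[panel$flagged, ]
    lines <- c(lines, "", sprintf(
      "Marker over-representation flags: %d of %d panel cells",
      nrow(flagged), nrow(panel)
    ))
    if (nrow(flagged) > 0) {
      lines <- c(lines, sprintf(
        "  %-28s %-12s RF=%.2f q=%.3g",
        flagged$deg_list, flagged$cell_type,
        flagged$representation_factor, flagged$qvalue
      ))
    }
  }
  z <- grab("operon_zscores")
  if (!is.null(z) && nrow(z) > 0) {
    top <- dplyr::arrange(z, dplyr::desc(.data$z)) |> head(5)
    lines <- c(lines, "", "Top operon overlap z-scores:")
    lines <- c(lines, sprintf(
      "  %-12s k=%3d null=%.1f+/-%.2f z=%.2f",
      top$operon_id, top$k_observed, top$null_mean, top$null_sd, top$z
    ))
  }
  rec <- grab("truth_recovery")
  if (!is.null(rec) && nrow(rec) > 0) {
    lines <- c(lines, "", "Filtration vs planted truth:")
    lines <- c(lines, sprintf(
      "  %-8s retention=%.3f contaminant removal=%.3f (raw up: %d true, %d contaminant)",
      rec$timepoint,
      rec$true_up_retention, rec$contam_removed,
      rec$n_raw_up, rec$contam_raw_up
    ))
  }
  pca <- grab("pca_variance")
  if (!is.null(pca) && nrow(pca) > 0) {
    lines <- c(lines, "", sprintf(
      "PCA: PC1 %.1f%%, PC2 %.1f%% of variance",
      100 * pca$variance_fraction[1], 100 * pca$variance_fraction[2]
    ))
  }
  writeLines(lines, path)
  invisible(path)
}
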