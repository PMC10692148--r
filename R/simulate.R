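#' Configuration for the paired IP/total translatome simulator
#'
#' Describes a Ribotag-style experiment: a tissue made of several cell types
#' whose mixture proportions may shift across conditions, an
#' immunoprecipitated (IP) fraction that draws a `ip_target_purity` share of
#' its reads from the tagged cell type (oligodendrocytes, "OL") and the rest
#' from the ambient non-OL mixture, planted OL-specific and shared condition
#' effects, cell-type marker genes, a contaminant expression surge in one
#' cell type after injury, regulon ("operon") gene sets with planted overlap
#' with the OL-upregulated genes, and negative-binomial counting noise.
#'
#' @param n_genes Number of genes.
#' @param conditions Ordered condition labels, baseline first.
#' @param cell_types Cell-type labels; the first is the tagged type.
#' @param mixture Matrix (conditions x cell types) of tissue mRNA mixture
#'   proportions; rows must sum to 1.
#' @param ip_target_purity Named per-condition fraction of the IP library
#'   originating from the tagged cell type, in (0, 1].
#' @param n_pairs_per_condition Biological replicate pairs per condition.
#' @param lib_size_mean,lib_size_cv Expected total counts per sample and
#'   their coefficient of variation (log-normal library sizes).
#' @param dispersion Either a scalar negative-binomial dispersion alpha or a
#'   list `list(mean=, shape=)` for gene-wise gamma-distributed dispersions.
#' @param n_regulated_ol Number of genes with planted OL-specific condition
#'   effects; effect sizes cycle through `ol_effect_sizes`; half the genes
#'   keep the effect at all post-injury timepoints ("sustained"), half decay
#'   ("acute": full effect at the first post-injury timepoint, half at the
#'   second, none at the last).
#' @param ol_effect_sizes Planted log2 effect sizes for OL-regulated genes.
#' @param ol_profile_fold Relative over-expression of OL-regulated genes in
#'   the tagged type (they emulate genuinely OL-enriched transcripts).
#' @param n_regulated_shared Number of genes regulated identically in every
#'   cell type (effect sizes cycle through `shared_effect_sizes`).
#' @param shared_effect_sizes Planted log2 effect sizes for shared effects.
#' @param marker_set_sizes Named integer vector: marker genes per cell type;
#'   markers are constructed `marker_fold`-fold enriched in their own type.
#' @param marker_fold Marker over-expression factor (must be at least 8 so
#'   marker identity is unambiguous by construction).
#' @param contam_surge List describing the inflammatory contaminant surge:
#'   `cell_type` (whose markers surge) and `lfc`, a named per-condition log2
#'   change of their expression within that cell type. Set `lfc` to zeros to
#'   disable.
#' @param n_housekeeping Uniformly expressed genes (qPCR reference
#'   candidates).
#' @param operon_config List: `n_operons`, `operon_size`, `n_enriched`
#'   (operons built to overlap planted OL-upregulated genes), `enrich_frac`
#'   (share of planted OL-up genes included in each enriched operon).
#' @param qpcr List: `noise_sd` (cycles), `ct_intercept`, `ct_max`,
#'   `n_technical`, `targets_per_type` (marker targets per cell type).
#' @param baseline_log2_mean,baseline_log2_sd Log2-normal baseline expression
#'   across genes.
#' @param type_noise_sd Log2 sd of cell-type-specific expression wobble for
#'   unremarkable genes.
#' @param seed Integer seed; all draws flow from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 16000,
                       conditions = c("naive", "dpi2", "dpi10", "dpi42"),
                       cell_types = c("OL", "astrocyte", "neuron", "microglia"),
                       mixture = NULL,
                       ip_target_purity = NULL,
                       n_pairs_per_condition = 3,
                       lib_size_mean = 5e6,
                       lib_size_cv = 0.15,
                       dispersion = list(mean = 0.02, shape = 2),
                       n_regulated_ol = 400,
                       ol_effect_sizes = c(-2, -1, 1, 2),
                       ol_profile_fold = 16,
                       n_regulated_shared = 200,
                       shared_effect_sizes = c(-2, 2),
                       marker_set_sizes = NULL,
                       marker_fold = 16,
                       contam_surge = NULL,
                       n_housekeeping = 5,
                       operon_config = list(
                         n_operons = 12, operon_size = 500,
                         n_enriched = 2, enrich_frac = 0.4
                       ),
                       qpcr = list(
                         noise_sd = 0.15, ct_intercept = 20, ct_max = 40,
                         n_technical = 2, targets_per_type = 3
                       ),
                       baseline_log2_mean = 5,
                       baseline_log2_sd = 1.8,
                       type_noise_sd = 0.25,
                       seed = 1L) {
  if (is.null(mixture)) {
    mixture <- rbind(
      naive = c(0.12, 0.30, 0.50, 0.08),
      dpi2  = c(0.08, 0.27, 0.35, 0.30),
      dpi10 = c(0.09, 0.30, 0.38, 0.23),
      dpi42 = c(0.11, 0.30, 0.44, 0.15)
    )[seq_along(conditions), , drop = FALSE]
    rownames(mixture) <- conditions
    colnames(mixture) <- cell_types
  }
  if (is.null(ip_target_purity)) {
    ip_target_purity <- setNames(rep(0.75, length(conditions)), conditions)
  }
  if (is.null(marker_set_sizes)) {
    per_type <- min(500L, max(1L, n_genes %/% (4L * length(cell_types))))
    marker_set_sizes <- setNames(rep(per_type, length(cell_types)), cell_types)
  }
  if (missing(n_regulated_ol)) n_regulated_ol <- min(n_regulated_ol, n_genes %/% 10)
  if (missing(n_regulated_shared)) {
    n_regulated_shared <- min(n_regulated_shared, n_genes %/% 20)
  }
  if (missing(operon_config)) {
    operon_config$operon_size <- min(500L, max(5L, n_genes %/% 8L))
  }
  if (is.null(contam_surge)) {
    lfc <- setNames(rep(0, length(conditions)), conditions)
    if (all(c("dpi2", "dpi10", "dpi42") %in% conditions)) {
      lfc[c("dpi2", "dpi10", "dpi42")] <- c(3, 2, 1)
    }
    contam_surge <- list(cell_type = cell_types[length(cell_types)], lfc = lfc)
  }
  cfg <- structure(
    list(
      n_genes = as.integer(n_genes), conditions = conditions,
      cell_types = cell_types, mixture = mixture,
      ip_target_purity = ip_target_purity,
      n_pairs_per_condition = as.integer(n_pairs_per_condition),
      lib_size_mean = lib_size_mean, lib_size_cv = lib_size_cv,
      dispersion = dispersion,
      n_regulated_ol = as.integer(n_regulated_ol),
      ol_effect_sizes = ol_effect_sizes,
      ol_profile_fold = ol_profile_fold,
      n_regulated_shared = as.integer(n_regulated_shared),
      shared_effect_sizes = shared_effect_sizes,
      marker_set_sizes = marker_set_sizes, marker_fold = marker_fold,
      contam_surge = contam_surge, n_housekeeping = as.integer(n_housekeeping),
      operon_config = operon_config, qpcr = qpcr,
      baseline_log2_mean = baseline_log2_mean,
      baseline_log2_sd = baseline_log2_sd,
      type_noise_sd = type_noise_sd,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1 || cfg$n_pairs_per_condition < 1) {
    abort("counts in the configuration must be at least 1")
  }
  if (any(abs(rowSums(cfg$mixture) - 1) > 1e-9)) {
    abort("mixture proportions must sum to 1 per condition")
  }
  if (!identical(rownames(cfg$mixture), cfg$conditions) ||
    !identical(colnames(cfg$mixture), cfg$cell_types)) {
    abort("mixture must be a conditions x cell_types matrix with matching names")
  }
  p <- cfg$ip_target_purity[cfg$conditions]
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    abort("ip_target_purity must be in (0, 1] for every condition")
  }
  if (!all(is.finite(c(cfg$ol_effect_sizes, cfg$shared_effect_sizes)))) {
    abort("effect sizes must be finite")
  }
  if (cfg$marker_fold < 8) {
    abort("marker_fold must be at least 8 (markers are defined by >= 8-fold enrichment)")
  }
  reserved <- sum(cfg$marker_set_sizes) + cfg$n_regulated_ol +
    cfg$n_regulated_shared + cfg$n_housekeeping
  if (reserved > cfg$n_genes) {
    abort(sprintf(
      "marker/regulated/housekeeping genes (%d) exceed n_genes (%d)",
      reserved, cfg$n_genes
    ))
  }
  if (!cfg$contam_surge$cell_type %in% cfg$cell_types) {
    abort("contam_surge cell_type is not a declared cell type")
  }
  cfg
}

draw_dispersions <- function(cfg) {
  if (is.list(cfg$dispersion)) {
    shape <- cfg$dispersion$shape
    rgamma(cfg$n_genes, shape = shape, rate = shape / cfg$dispersion$mean)
  } else {
    rep(cfg$dispersion, cfg$n_genes)
  }
}

# all random draws for profiles; callers must seed the RNG
gen_profiles_impl <- function(cfg) {
  n <- cfg$n_genes
  types <- cfg$cell_types
  gene_id <- sprintf("gene%05d", seq_len(n))
  baseline <- 2^rnorm(n, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  mult <- matrix(2^rnorm(n * length(types), 0, cfg$type_noise_sd),
    nrow = n, dimnames = list(gene_id, types)
  )

  pool <- sample(gene_id) # random role assignment
  take <- function(k) {
    if (k == 0) return(character(0))
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  markers <- lapply(cfg$marker_set_sizes[types], take)
  regulated_ol <- take(cfg$n_regulated_ol)
  regulated_shared <- take(cfg$n_regulated_shared)
  housekeeping <- take(cfg$n_housekeeping)

  # enriched genes keep a typical abundance in their own cell type and are
  # fold-fold lower elsewhere, so planted sets do not dominate the mRNA mass
  for (t in types) {
    mult[markers[[t]], ] <- 1 / cfg$marker_fold
    mult[markers[[t]], t] <- 1
  }
  mult[regulated_ol, ] <- 1 / cfg$ol_profile_fold
  mult[regulated_ol, types[1]] <- 1
  mult[housekeeping, ] <- 1
  # planted regulated transcripts emulate the moderately-to-highly expressed
  # range where injury-regulated OL mRNAs live; keeps them clear of the
  # shot-noise floor without dominating the transcriptome mass
  if (length(regulated_ol) > 0) {
    baseline[match(regulated_ol, gene_id)] <-
      2^rnorm(length(regulated_ol), cfg$baseline_log2_mean + 1, 1)
  }

  profile <- baseline * mult
  membership <- tibble(
    gene_id = unlist(markers, use.names = FALSE),
    cell_type = rep(types, lengths(markers))
  )
  structure(
    list(
      profile = profile,
      marker_membership = membership,
      marker_sets = markers,
      regulated_ol = regulated_ol,
      regulated_shared = regulated_shared,
      housekeeping = housekeeping,
      gene_id = gene_id
    ),
    class = "cell_profiles"
  )
}

#' Generate cell-type expression profiles
#'
#' Draws per-gene baseline expression and cell-type multipliers, assigns
#' disjoint marker sets (each marker is `marker_fold`-fold enriched in its own
#' type by construction), OL-skewed regulated genes, shared-regulation genes,
#' and uniformly expressed housekeeping genes.
#'
#' @param config A [sim_config()].
#' @return A `cell_profiles` object: relative expression matrix (genes x cell
#'   types), marker membership tibble, and the role assignments.
#' @export
generate_profiles <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, gen_profiles_impl(config))
}

# planted log2 effect matrices (deterministic given profiles)
planted_effects <- function(cfg, prof) {
  n <- cfg$n_genes
  conds <- cfg$conditions
  sci <- conds[-1]
  lfc_ol <- matrix(0, n, length(conds), dimnames = list(prof$gene_id, conds))
  if (cfg$n_regulated_ol > 0 && length(sci) > 0) {
    eff <- rep_len(cfg$ol_effect_sizes, cfg$n_regulated_ol)
    timing <- if (isTRUE(cfg$sustained_only)) {
      rep("sustained", cfg$n_regulated_ol)
    } else {
      rep_len(c("sustained", "acute"), cfg$n_regulated_ol)
    }
    decay <- setNames(2^-(seq_along(sci) - 1), sci) # 1, 1/2, 1/4 ...
    for (i in seq_len(cfg$n_regulated_ol)) {
      g <- prof$regulated_ol[i]
      if (timing[i] == "sustained") {
        lfc_ol[g, sci] <- eff[i]
      } else {
        lfc_ol[g, sci] <- eff[i] * decay
        lfc_ol[g, sci[length(sci)]] <- 0
      }
    }
  } else {
    eff <- numeric(0)
    timing <- character(0)
  }
  lfc_shared <- matrix(0, n, length(conds), dimnames = list(prof$gene_id, conds))
  if (cfg$n_regulated_shared > 0 && length(sci) > 0) {
    eff_s <- rep_len(cfg$shared_effect_sizes, cfg$n_regulated_shared)
    lfc_shared[prof$regulated_shared, sci] <- eff_s
  }
  list(
    lfc_ol = lfc_ol, lfc_shared = lfc_shared,
    ol_table = tibble(
      gene_id = prof$regulated_ol,
      effect_size = eff, timing = timing
    )
  )
}

# expected IP and total composition (shares summing to 1) per condition
expected_shares <- function(cfg, prof, effects) {
  tagged <- cfg$cell_types[1]
  surge <- cfg$contam_surge
  surge_genes <- prof$marker_sets[[surge$cell_type]]
  out <- list()
  for (cond in cfg$conditions) {
    expr <- prof$profile
    expr[, tagged] <- expr[, tagged] * 2^effects$lfc_ol[, cond]
    expr <- expr * 2^effects$lfc_shared[, cond]
    s_lfc <- surge$lfc[[cond]] %||% 0
    if (s_lfc != 0) {
      expr[surge_genes, surge$cell_type] <-
        expr[surge_genes, surge$cell_type] * 2^s_lfc
    }
    e <- sweep(expr, 2, colSums(expr), "/")
    pi_c <- cfg$mixture[cond, ]
    total <- drop(e %*% pi_c)
    amb_w <- pi_c[names(pi_c) != tagged]
    ambient <- drop(e[, names(amb_w), drop = FALSE] %*% (amb_w / sum(amb_w)))
    p <- cfg$ip_target_purity[[cond]]
    ip <- p * e[, tagged] + (1 - p) * ambient
    if (!all(is.finite(total)) || !all(is.finite(ip))) {
      bad <- prof$gene_id[!is.finite(total) | !is.finite(ip)][1]
      abort(paste0("non-finite expected expression for gene ", bad))
    }
    out[[cond]] <- list(total = total, ip = ip)
  }
  out
}

build_operons <- function(cfg, prof, effects) {
  oc <- cfg$operon_config
  up <- prof$regulated_ol[
    rowSums(effects$lfc_ol[prof$regulated_ol, , drop = FALSE] > 0) > 0
  ]
  ops <- list()
  for (i in seq_len(oc$n_operons)) {
    nm <- sprintf("operon%02d", i)
    if (i <= oc$n_enriched && length(up) > 0) {
      seeded <- sample(up, min(round(oc$enrich_frac * length(up)), oc$operon_size))
      rest <- sample(setdiff(prof$gene_id, seeded), oc$operon_size - length(seeded))
      ops[[nm]] <- sample(c(seeded, rest))
    } else {
      ops[[nm]] <- sample(prof$gene_id, oc$operon_size)
    }
  }
  ops
}

#' Simulate a paired IP/total count experiment with known truth
#'
#' Draws the full study layout (conditions x pairs x two fractions): the
#' total fraction follows the mixture-weighted cell-type profiles with
#' condition effects; the IP fraction is `purity x tagged-cell profile plus
#' (1 - purity) x ambient non-tagged mixture`. Counts are negative-binomial
#' around library-size-scaled expected shares.
#'
#' @param config A [sim_config()].
#' @return A list of class `ribotag_sim` with elements `counts` (tibble,
#'   `gene_id` + one column per sample), `samples` (sample sheet tibble) and
#'   `truth` (planted ground truth, class `synth_truth`).
#' @export
generate_experiment <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    prof <- gen_profiles_impl(config)
    effects <- planted_effects(config, prof)
    shares <- expected_shares(config, prof, effects)
    alpha <- draw_dispersions(config)
    operons <- build_operons(config, prof, effects)

    sdlog <- sqrt(log(1 + config$lib_size_cv^2))
    meanlog <- log(config$lib_size_mean) - sdlog^2 / 2

    samples <- tidyr::expand_grid(
      condition = config$conditions,
      pair = seq_len(config$n_pairs_per_condition),
      fraction = c("total", "OL")
    )
    samples <- dplyr::mutate(samples,
      pair_id = paste0(.data$condition, "_p", .data$pair),
      sample_id = paste0(.data$pair_id, "_", .data$fraction)
    )
    counts <- matrix(0L, config$n_genes, nrow(samples),
      dimnames = list(prof$gene_id, samples$sample_id)
    )
    lib <- rlnorm(nrow(samples), meanlog, sdlog)
    for (j in seq_len(nrow(samples))) {
      sh <- shares[[samples$condition[j]]]
      mu <- lib[j] * (if (samples$fraction[j] == "OL") sh$ip else sh$total)
      counts[, j] <- rnbinom(config$n_genes, mu = mu, size = 1 / alpha)
    }

    counts_tbl <- dplyr::bind_cols(
      tibble(gene_id = prof$gene_id),
      as_tibble(counts)
    )
    samples_tbl <- tibble(
      sample_id = samples$sample_id,
      fraction = factor(samples$fraction, levels = c("total", "OL")),
      condition = factor(samples$condition, levels = config$conditions),
      pair_id = samples$pair_id
    )
    contam <- dplyr::filter(samples_tbl, .data$fraction == "OL")
    truth <- structure(
      list(
        profiles = prof,
        true_lfc_ol = effects$lfc_ol,
        true_lfc_shared = effects$lfc_shared,
        regulated_ol = effects$ol_table,
        regulated_shared = prof$regulated_shared,
        surge_genes = prof$marker_sets[[config$contam_surge$cell_type]],
        surge = config$contam_surge,
        contamination_fraction = tibble(
          sample_id = contam$sample_id,
          contamination_fraction =
            1 - config$ip_target_purity[as.character(contam$condition)]
        ),
        marker_sets = prof$marker_sets,
        operon_sets = operons,
        housekeeping = prof$housekeeping,
        dispersion = tibble(gene_id = prof$gene_id, dispersion = alpha),
        expected_shares = shares,
        config = config
      ),
      class = "synth_truth"
    )
    structure(
      list(counts = counts_tbl, samples = samples_tbl, truth = truth),
      class = "ribotag_sim"
    )
  })
}

#' @export
print.ribotag_sim <- function(x, ...) {
  cat(
    "Synthetic Ribotag experiment:", nrow(x$counts), "genes x",
    nrow(x$samples), "samples (",
    length(unique(x$samples$condition)), "conditions )\n"
  )
  invisible(x)
}

#' Simulate a qPCR plate from planted truth
#'
#' Ct values follow `ct_intercept - log2(expected expression per million) +
#' Gaussian noise`. Reference (housekeeping) transcripts are constructed with
#' equal expected expression in IP and total fractions. Wells with zero
#' expected expression are set to `ct_max` and flagged undetected.
#'
#' @param truth A `synth_truth` object from [generate_experiment()].
#' @param config The same [sim_config()] used to generate it.
#' @return A tibble plate: `sample_id`, `fraction`, `condition`, `pair_id`,
#'   `target`, `replicate`, `ct`, `undetected`, plus an attribute
#'   `reference_targets`.
#' @export
generate_qpcr <- function(truth, config) {
  qc <- config$qpcr
  prof <- truth$profiles
  targets <- unlist(lapply(
    prof$marker_sets,
    function(g) head(g, qc$targets_per_type)
  ), use.names = FALSE)
  refs <- head(prof$housekeeping, 3)
  all_targets <- c(targets, refs)

  grid <- tidyr::expand_grid(
    condition = config$conditions,
    pair = seq_len(config$n_pairs_per_condition),
    fraction = c("total", "OL"),
    target = all_targets,
    replicate = seq_len(qc$n_technical)
  )
  grid <- dplyr::mutate(grid,
    pair_id = paste0(.data$condition, "_p", .data$pair),
    sample_id = paste0(.data$pair_id, "_", .data$fraction)
  )
  withr::with_seed(config$seed, {
    expr <- purrr::pmap_dbl(
      list(grid$condition, grid$fraction, grid$target),
      function(cond, frac, tg) {
        sh <- truth$expected_shares[[cond]]
        if (tg %in% refs) sh$total[[tg]] else {
          if (frac == "OL") sh$ip[[tg]] else sh$total[[tg]]
        }
      }
    )
    undetected <- expr <= 0
    ct <- ifelse(
      undetected,
      qc$ct_max,
      qc$ct_intercept - log2(expr * 1e6) + rnorm(nrow(grid), 0, qc$noise_sd)
    )
    plate <- tibble(
      sample_id = grid$sample_id,
      fraction = factor(grid$fraction, levels = c("total", "OL")),
      condition = factor(grid$condition, levels = config$conditions),
      pair_id = grid$pair_id,
      target = grid$target,
      replicate = grid$replicate,
      ct = ct,
      undetected = undetected
    )
    attr(plate, "reference_targets") <- refs
    plate
  })
}

#' Write a simulated experiment to plain-text files
#'
#' Emits the counts TSV, sample sheet TSV, marker/operon/truth GMT files,
#' truth tables (planted effects, contamination fractions) and the
#' configuration as YAML.
#'
#' @param sim A `ribotag_sim` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- sim$truth
  cfg <- truth$config
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    markers = file.path(dir, "markers.gmt"),
    operons = file.path(dir, "operons.gmt"),
    truth_sets = file.path(dir, "truth_sets.gmt"),
    truth_lfc = file.path(dir, "truth_lfc_ol.tsv"),
    contamination = file.path(dir, "truth_contamination.tsv"),
    config = file.path(dir, "config.yaml")
  )
  write_counts_tsv(sim$counts, paths[["counts"]])
  readr::write_tsv(sim$samples, paths[["samples"]])
  write_gmt(truth$marker_sets, paths[["markers"]], "cell type markers")
  write_gmt(truth$operon_sets, paths[["operons"]], "regulon gene sets")
  reg <- truth$regulated_ol
  truth_sets <- list(
    regulated_ol_up = reg$gene_id[reg$effect_size > 0],
    regulated_ol_down = reg$gene_id[reg$effect_size < 0],
    regulated_shared = truth$regulated_shared,
    contaminant_surge = truth$surge_genes,
    housekeeping = truth$housekeeping
  )
  write_gmt(truth_sets[lengths(truth_sets) > 0], paths[["truth_sets"]], "planted truth")
  lfc <- as_tibble(truth$true_lfc_ol)
  lfc$gene_id <- rownames(truth$true_lfc_ol)
  readr::write_tsv(lfc[, c("gene_id", cfg$conditions)], paths[["truth_lfc"]])
  readr::write_tsv(truth$contamination_fraction, paths[["contamination"]])
  cfg_out <- cfg
  cfg_out$mixture <- apply(cfg$mixture, 1, as.list, simplify = FALSE)
  yaml::write_yaml(cfg_out, paths[["config"]])
  invisible(paths)
}

#' Preset simulator configurations for standard validation scenarios
#'
#' `sim_config_null()` has no planted effects, no contaminant surge, and
#' condition-constant mixture/purity, so every contrast is a true null.
#' `sim_config_recovery()` plants OL-specific effects of +/-1 and +/-2 log2
#' units (sustained across timepoints) with no surge or shared effects.
#' `sim_config_contamination()` is the injury scenario: contaminant surge in
#' microglia plus planted OL effects.
#'
#' @param n_genes Number of genes.
#' @param genes_per_effect Genes per planted effect size (recovery scenario).
#' @param seed Integer seed.
#' @param ... Passed through to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_null <- function(n_genes = 5000, seed = 1L, ...) {
  base <- sim_config(n_genes = n_genes, seed = seed)
  mix <- base$mixture
  for (i in seq_len(nrow(mix))) mix[i, ] <- mix["naive", ]
  surge <- base$contam_surge
  surge$lfc[] <- 0
  sim_config(
    n_genes = n_genes, seed = seed, mixture = mix,
    n_regulated_ol = 0, n_regulated_shared = 0,
    contam_surge = surge, lib_size_mean = 2e6, ...
  )
}

#' @rdname sim_config_null
#' @export
sim_config_recovery <- function(n_genes = 8000, genes_per_effect = 200,
                                seed = 1L, ...) {
  base <- sim_config(n_genes = n_genes, seed = seed)
  surge <- base$contam_surge
  surge$lfc[] <- 0
  cfg <- sim_config(
    n_genes = n_genes, seed = seed,
    n_regulated_ol = 4 * genes_per_effect,
    ol_effect_sizes = c(-1, -2, 1, 2),
    n_regulated_shared = 0, contam_surge = surge, ...
  )
  # recovery wants the planted value at every timepoint: sustained only
  cfg$sustained_only <- TRUE
  cfg
}

#' @rdname sim_config_null
#' @export
sim_config_contamination <- function(n_genes = 4000, seed = 1L, ...) {
  sim_config(
    n_genes = n_genes, seed = seed,
    n_regulated_ol = min(300L, n_genes %/% 8L),
    n_regulated_shared = min(100L, n_genes %/% 40L),
    lib_size_mean = 2e6, ...
  )
}
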