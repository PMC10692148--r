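th <- default_thresholds()

test_that("OL expression classes follow the enrichment thresholds", {
  prof <- dplyr::bind_rows(
    profile_row("a", "naive", log2fc_total = 2.40, q_total = 0.001), # highly specific
    profile_row("b", "naive", log2fc_total = 0.9, q_total = 0.01), # enriched
    profile_row("c", "naive", log2fc_total = 0, q_total = 0.001), # neutral
    profile_row("d", "naive", log2fc_total = 0.7, q_total = 0.2), # fails q
    profile_row("e", "naive", log2fc_total = -0.8, q_total = 0.001) # depleted
  )
  cls <- classify_ol_expression(prof, "naive", th)
  expect_equal(
    as.character(cls$class),
    c("highly_specific", "enriched", "neutral", "neutral", "depleted")
  )
  expect_error(classify_ol_expression(prof, "dpi9", th), "no profile rows")
})

test_that("injury DEG calls need both effect size and significance", {
  prof <- dplyr::bind_rows(
    profile_row("steap3_like", "dpi2", ol_log2fc_vs_naive = 6.52, q_ol = 0.001),
    profile_row("subthresh", "dpi2", ol_log2fc_vs_naive = 0.9, q_ol = 0.001),
    profile_row("nonsig", "dpi2", ol_log2fc_vs_naive = 3, q_ol = 0.2),
    profile_row("down", "dpi2", ol_log2fc_vs_naive = -1.4, q_ol = 0.01)
  )
  degs <- call_sci_degs(prof, "dpi2", th)
  expect_equal(degs$gene_id[degs$direction == "up"], "steap3_like")
  expect_equal(degs$gene_id[degs$direction == "down"], "down")

  empty <- call_sci_degs(prof[0, ], "dpi2", th)
  expect_equal(nrow(empty), 0)
})

test_that("the two-arm filter separates OL-driven from total-driven changes", {
  mk <- function(id, delta, q_delta, lfc_tot_naive, q_tot_naive, lfc_tot, q_tot) {
    dplyr::bind_rows(
      profile_row(id, "naive", log2fc_total = lfc_tot_naive, q_total = q_tot_naive),
      profile_row(id, "dpi2",
        log2fc_total = lfc_tot, q_total = q_tot,
        delta_log2fc = delta, q_delta = q_delta,
        ol_log2fc_vs_naive = 2, q_ol = 0.001
      )
    )
  }
  prof <- dplyr::bind_rows(
    # concordant differential enrichment: arm 1
    mk("arm1_gene", +1.3, 0.01, 0.2, 0.5, 0.4, 0.5),
    # flat enrichment but constitutively OL-enriched: arm 2
    mk("arm2_gene", 0.0, 0.9, 1.5, 0.01, 1.5, 0.01),
    # microglia-like contaminant: depleted, enrichment unchanged
    mk("contam_gene", 0.1, 0.8, -2, 0.001, -2, 0.001),
    # differential enrichment in the WRONG direction
    mk("discordant", -1.5, 0.01, 0.2, 0.5, 0.2, 0.5)
  )
  degs <- call_sci_degs(prof, "dpi2", th)
  expect_setequal(degs$gene_id, c("arm1_gene", "arm2_gene", "contam_gene", "discordant"))
  v <- two_arm_filter(degs, prof, "dpi2", th)

  get <- function(id) v[v$gene_id == id, ]
  expect_true(get("arm1_gene")$passes_arm1)
  expect_false(get("arm1_gene")$passes_arm2)
  expect_true(get("arm2_gene")$passes_arm2)
  expect_false(get("arm2_gene")$passes_arm1)
  expect_true(get("arm2_gene")$high_confidence)
  expect_false(get("contam_gene")$high_confidence)
  expect_false(get("discordant")$high_confidence)

  # verdicts respect the invariant high_confidence => raw DEG
  expect_true(all(v$is_raw_deg[v$high_confidence]))

  # DEG absent from the profile is an error naming the gene
  bad <- degs
  bad$gene_id[1] <- "ghost"
  expect_error(two_arm_filter(bad, prof, "dpi2", th), "ghost")
})

test_that("arm 2 scope can require enrichment at every condition", {
  prof <- dplyr::bind_rows(
    profile_row("g", "naive", log2fc_total = 1.5, q_total = 0.01),
    profile_row("g", "dpi2",
      log2fc_total = 1.5, q_total = 0.01,
      delta_log2fc = 0, q_delta = 0.9,
      ol_log2fc_vs_naive = 2, q_ol = 0.001
    ),
    profile_row("g", "dpi10", log2fc_total = 0.2, q_total = 0.5),
    profile_row("g", "dpi42", log2fc_total = 1.5, q_total = 0.01)
  )
  prof$condition <- factor(prof$condition, levels = c("naive", "dpi2", "dpi10", "dpi42"))
  degs <- call_sci_degs(prof, "dpi2", th)
  expect_true(two_arm_filter(degs, prof, "dpi2", th)$passes_arm2)
  expect_false(two_arm_filter(degs, prof, "dpi2", th, arm2_scope = "all")$passes_arm2)
})

test_that("raising the arm-1 threshold never grows the pass set", {
  withr::local_seed(31)
  n <- 200
  prof <- dplyr::bind_rows(
    profile_row(sprintf("g%03d", 1:n), "naive"),
    profile_row(sprintf("g%03d", 1:n), "dpi2",
      delta_log2fc = rnorm(n, 0, 1.5),
      q_delta = runif(n),
      ol_log2fc_vs_naive = rnorm(n, 0, 2),
      q_ol = runif(n, 0, 0.1)
    )
  )
  degs <- call_sci_degs(prof, "dpi2", th)
  prev <- NULL
  for (cut in c(0.5, 1, 1.5, 2)) {
    thc <- default_thresholds(delta_lfc = cut)
    v <- two_arm_filter(degs, prof, "dpi2", thc)
    pass <- v$gene_id[v$passes_arm1]
    if (!is.null(prev)) expect_true(all(pass %in% prev))
    prev <- pass
  }
})

test_that("acute candidates keep genes that normalize or fall two-fold by the late timepoint", {
  mk <- function(id, lfc2, lfc42, q42) {
    dplyr::bind_rows(
      profile_row(id, "dpi2", ol_log2fc_vs_naive = lfc2, q_ol = 0.001),
      profile_row(id, "dpi42", ol_log2fc_vs_naive = lfc42, q_ol = q42)
    )
  }
  prof <- dplyr::bind_rows(
    mk("norm_q", 2.0, 2.0, 0.2), # late change not significant: kept
    mk("norm_lfc", 2.0, 0.8, 0.001), # late below the DEG threshold: kept
    mk("dropped", 3.0, 1.5, 0.001), # two-fold lower than acute: kept
    mk("sustained", 2.0, 1.8, 0.001) # still high: excluded
  )
  verdicts <- tibble::tibble(
    gene_id = c("norm_q", "norm_lfc", "dropped", "sustained"),
    timepoint = "dpi2", direction = "up",
    is_raw_deg = TRUE, passes_arm1 = TRUE, passes_arm2 = FALSE,
    high_confidence = TRUE
  )
  out <- acute_candidates(verdicts, prof, thresholds = th)
  expect_setequal(out$gene_id, c("norm_q", "norm_lfc", "dropped"))
  expect_equal(out$rule[out$gene_id == "dropped"], "late_twofold_lower")
})

test_that("gene-set regulation summaries count and summarize the regulated subset", {
  prof <- profile_row(
    c("a", "b", "c", "d"), "dpi2",
    ol_log2fc_vs_naive = c(0.6, 0.9, 1.2, 0.1), q_ol = 0.01
  )
  s <- summarize_geneset(prof, c("a", "b", "c", "d"), "dpi2")
  expect_equal(s$n_up, 3)
  expect_equal(s$median_lfc_up, 0.9)
  expect_equal(s$n_down, 0)

  empty <- summarize_geneset(prof, character(0), "dpi2")
  expect_equal(empty$n_mapped, 0)
  expect_true(is.na(empty$median_lfc_up))

  nosig <- summarize_geneset(
    profile_row(c("a", "b"), "dpi2", ol_log2fc_vs_naive = 2, q_ol = 0.5),
    c("a", "b"), "dpi2"
  )
  expect_equal(nosig$n_up, 0)
})

test_that("high-confidence genes appear in exactly one direction per timepoint", {
  sim <- generate_experiment(sim_config_contamination(n_genes = 600, seed = 33))
  prof <- enrichment_profile(sim$counts, sim$samples)
  for (tp in c("dpi2", "dpi42")) {
    degs <- call_sci_degs(prof, tp, th)
    v <- two_arm_filter(degs, prof, tp, th)
    hc <- v[v$high_confidence, ]
    expect_equal(anyDuplicated(hc$gene_id), 0)
  }
})
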