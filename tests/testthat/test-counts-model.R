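test_that("the low-count filter keeps genes with summed count >= 10", {
  m <- rbind(
    c(3, 3, 3), # sum 9: removed
    c(4, 3, 3), # sum 10: retained
    c(50, 25, 25), # retained
    c(0, 0, 0) # all-zero: removed
  )
  out <- filter_low_counts(counts_tbl(m))
  expect_equal(out$gene_id, c("g002", "g003"))
  expect_warning(filter_low_counts(counts_tbl(m), min_total = 1000), "removed")
})

test_that("RLE size factors match the median-of-ratios definition", {
  withr::local_seed(1)
  m <- matrix(rpois(200, 100) + 1, 50, 4)
  sf_id <- estimate_size_factors(counts_tbl(cbind(m[, 1], m[, 1], m[, 1])))
  expect_equal(sf_id$size_factor, rep(1, 3))

  doubled <- cbind(m, 2 * m[, 1])
  sf <- estimate_size_factors(counts_tbl(doubled))
  expect_equal(sf$size_factor[5] / sf$size_factor[1], 2, tolerance = 1e-12)

  # invariance to gene order
  perm <- sample(nrow(m))
  sf_a <- estimate_size_factors(counts_tbl(m))
  sf_b <- estimate_size_factors(counts_tbl(m[perm, ], gene_ids = sprintf("g%03d", perm)))
  expect_equal(sf_a$size_factor, sf_b$size_factor)

  # scaling one sample by c scales its factor by c (zero-free reference)
  scaled <- m
  scaled[, 2] <- m[, 2] * 3
  sf_s <- estimate_size_factors(counts_tbl(scaled))
  expect_equal(
    (sf_s$size_factor[2] / sf_s$size_factor[1]) /
      (sf_a$size_factor[2] / sf_a$size_factor[1]),
    3,
    tolerance = 1e-12
  )

  expect_error(
    estimate_size_factors(counts_tbl(matrix(c(0, 1, 1, 0), 2, 2))),
    "zero-free"
  )
})

test_that("moment dispersions recover the generating dispersion", {
  samples <- paired_samples(c("naive", "dpi2", "dpi10", "dpi42"), 3)
  sf <- tibble::tibble(sample_id = samples$sample_id, size_factor = 1)

  # Poisson genes: small estimates for the bulk of genes
  withr::local_seed(4)
  m <- matrix(rpois(200 * 24, 500), 200, 24)
  colnames(m) <- samples$sample_id
  d <- estimate_dispersions(counts_tbl(m), samples, sf)
  expect_gt(mean(d$dispersion <= 0.05), 0.9)

  # NB genes with alpha = 0.5, many samples: consistent estimates
  big <- paired_samples("naive", 100)
  sf_big <- tibble::tibble(sample_id = big$sample_id, size_factor = 1)
  mb <- matrix(rnbinom(200 * 200, mu = 300, size = 2), 200, 200)
  colnames(mb) <- big$sample_id
  db <- estimate_dispersions(counts_tbl(mb), big, sf_big)
  expect_gt(mean(db$dispersion), 0.4)
  expect_lt(mean(db$dispersion), 0.6)

  # degenerate all-zero gene sits at the floor
  mz <- rbind(m[1:5, ], 0)
  colnames(mz) <- samples$sample_id
  dz <- estimate_dispersions(counts_tbl(mz), samples, sf)
  expect_equal(dz$dispersion[6], 1e-8)
})

test_that("the NB fit matches Poisson and fixed-theta GLM oracles", {
  skip_if_not_installed("MASS")
  samples <- paired_samples("naive", 6)
  withr::local_seed(8)
  mu <- cbind(rep(200, 5), rep(400, 5)) # total, OL cell means
  m <- nb_counts(mu, samples, alpha = 1e-9, seed = 8)
  sf <- tibble::tibble(sample_id = samples$sample_id, size_factor = 1)

  # alpha -> 0: matches a Poisson GLM
  d0 <- tibble::tibble(gene_id = sprintf("g%03d", 1:5), dispersion = 1e-9)
  fit <- fit_nb_glm(counts_tbl(m), samples, sf, d0, "full", pair_term = FALSE)
  X <- build_design(samples, interaction = TRUE, pair_term = FALSE)
  for (g in 1:3) {
    oracle <- glm(m[g, ] ~ X[colnames(m), "fractionOL"], family = poisson())
    expect_equal(
      unname(fit$coefficients[g, "fractionOL"] * log(2)),
      unname(coef(oracle)[2]),
      tolerance = 1e-4
    )
  }

  # fixed dispersion: matches glm with a negative.binomial family
  m2 <- nb_counts(mu, samples, alpha = 0.1, seed = 9)
  d2 <- tibble::tibble(gene_id = sprintf("g%03d", 1:5), dispersion = 0.1)
  fit2 <- fit_nb_glm(counts_tbl(m2), samples, sf, d2, "full", pair_term = FALSE)
  for (g in 1:3) {
    oracle <- glm(m2[g, ] ~ X[colnames(m2), "fractionOL"],
      family = MASS::negative.binomial(theta = 10)
    )
    expect_equal(
      unname(fit2$coefficients[g, "fractionOL"] * log(2)),
      unname(coef(oracle)[2]),
      tolerance = 1e-4
    )
  }
})

test_that("planted fraction effects are recovered and nulls stay null", {
  samples <- paired_samples("naive", 12) # 12 per group
  sf <- tibble::tibble(sample_id = samples$sample_id, size_factor = 1)
  n <- 200

  # planted log2FC = 1 between fractions, alpha = 0.1
  mu <- cbind(rep(200, n), rep(400, n))
  m <- nb_counts(mu, samples, alpha = 0.1, seed = 10)
  d <- estimate_dispersions(counts_tbl(m), samples, sf)
  fit <- fit_nb_glm(counts_tbl(m), samples, sf, d, "full", pair_term = FALSE)
  betas <- fit$coefficients[, "fractionOL"]
  expect_gt(mean(betas), 0.9)
  expect_lt(mean(betas), 1.1)

  # equal group means: coefficient within 3 se almost always
  mu0 <- cbind(rep(300, n), rep(300, n))
  m0 <- nb_counts(mu0, samples, alpha = 0.1, seed = 11)
  d0 <- estimate_dispersions(counts_tbl(m0), samples, sf)
  fit0 <- fit_nb_glm(counts_tbl(m0), samples, sf, d0, "full", pair_term = FALSE)
  w0 <- wald_contrast(fit0, "fractionOL")
  expect_gt(mean(abs(w0$log2fc) < 3 * w0$se), 0.95)
})

test_that("Wald contrasts reject degenerate input and calibrate under the null", {
  samples <- paired_samples("naive", 12)
  sf <- tibble::tibble(sample_id = samples$sample_id, size_factor = 1)
  n <- 2000
  mu0 <- cbind(rep(300, n), rep(300, n))
  m0 <- nb_counts(mu0, samples, alpha = 0.05, seed = 12)
  d_true <- tibble::tibble(gene_id = sprintf("g%03d", 1:n), dispersion = 0.05)
  fit <- fit_nb_glm(counts_tbl(m0), samples, sf, d_true, "full", pair_term = FALSE)

  expect_error(wald_contrast(fit, c(fractionOL = 0)), "zero")
  expect_error(wald_contrast(fit, "no_such_term"), "unknown")

  w <- wald_contrast(fit, "fractionOL")
  expect_gt(stats::ks.test(w$pvalue, "punif")$p.value, 0.01)
})

test_that("the interaction LRT is calibrated, powered, and validates nesting", {
  conds <- c("naive", "dpi2")
  samples <- paired_samples(conds, 3)
  sf <- tibble::tibble(sample_id = samples$sample_id, size_factor = 1)
  n <- 200

  # planted interaction: OL rises 4-fold at dpi2, total unchanged
  mu <- cbind(rep(300, n), rep(300, n), rep(300, n), rep(1200, n))
  colnames(mu) <- c("total naive", "OL naive", "total dpi2", "OL dpi2")
  m <- nb_counts(mu, samples, alpha = 0.1, seed = 14)
  d <- estimate_dispersions(counts_tbl(m), samples, sf)
  fit_f <- fit_nb_glm(counts_tbl(m), samples, sf, d, "full")
  fit_r <- fit_nb_glm(counts_tbl(m), samples, sf, d, "reduced")
  lrt <- lrt_interaction(fit_f, fit_r)
  expect_lt(stats::median(lrt$pvalue, na.rm = TRUE), 0.01)
  expect_true(all(lrt$stat >= 0))

  # identical designs are rejected as non-nested
  expect_error(lrt_interaction(fit_f, fit_f), "nested")
  # mismatched dispersions are rejected
  d_alt <- d
  d_alt$dispersion <- d_alt$dispersion + 0.05
  fit_r2 <- fit_nb_glm(counts_tbl(m), samples, sf, d_alt, "reduced")
  expect_error(lrt_interaction(fit_f, fit_r2), "dispersion")

  # null interaction: uniform p
  mu0 <- cbind(rep(300, n), rep(600, n), rep(300, n), rep(600, n))
  colnames(mu0) <- colnames(mu)
  m0 <- nb_counts(mu0, samples, alpha = 0.02, seed = 15)
  d0 <- tibble::tibble(gene_id = sprintf("g%03d", 1:n), dispersion = 0.02)
  l0 <- lrt_interaction(
    fit_nb_glm(counts_tbl(m0), samples, sf, d0, "full"),
    fit_nb_glm(counts_tbl(m0), samples, sf, d0, "reduced")
  )
  expect_gt(stats::ks.test(l0$pvalue, "punif")$p.value, 0.01)
})

test_that("Wald and LRT agree asymptotically", {
  conds <- c("naive", "dpi2")
  samples <- paired_samples(conds, 100)
  sf <- tibble::tibble(sample_id = samples$sample_id, size_factor = 1)
  n <- 200
  withr::local_seed(16)
  shift <- 2^runif(n, -0.5, 0.5)
  mu <- cbind(300, 300, 300, 300 * shift)
  m <- nb_counts(mu, samples, alpha = 0.05, seed = 16)
  d <- tibble::tibble(gene_id = sprintf("g%03d", 1:n), dispersion = 0.05)
  fit_f <- fit_nb_glm(counts_tbl(m), samples, sf, d, "full", pair_term = FALSE)
  fit_r <- fit_nb_glm(counts_tbl(m), samples, sf, d, "reduced", pair_term = FALSE)
  w <- wald_contrast(fit_f, "fractionOL:conditiondpi2")
  l <- lrt_interaction(fit_f, fit_r)
  signed_root <- sign(w$stat) * sqrt(l$stat)
  expect_gt(stats::cor(signed_root, w$stat), 0.99)
})

test_that("BH adjustment follows the step-up rule and keeps NAs", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.123), 0.123)
  out <- bh_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(out[2]))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("PCA summaries capture dominant structure and conserve variance", {
  samples <- paired_samples(c("naive", "dpi2"), 3)
  sf <- tibble::tibble(sample_id = samples$sample_id, size_factor = 1)
  withr::local_seed(17)
  base <- matrix(rpois(100 * 12, 100), 100, 12)
  colnames(base) <- samples$sample_id
  # rank-1 structure: OL samples scaled up for half the genes
  ol <- samples$fraction == "OL"
  base[1:50, ol] <- base[1:50, ol] * 8
  pca <- pca_variance(counts_tbl(base), samples, sf, k = 2)
  expect_gt(pca$variance$variance_fraction[1], 0.9)
  expect_equal(sum(pca$variance$variance_fraction), 1, tolerance = 1e-9)
  expect_warning(
    pca_variance(counts_tbl(base), samples, sf, k = 50),
    "clipping"
  )
  # PC1 separates the fractions with fully consistent score signs
  s1 <- pca$scores$PC1[pca$scores$fraction == "OL"]
  s0 <- pca$scores$PC1[pca$scores$fraction == "total"]
  expect_true(all(sign(s1) == sign(s1[1])))
  expect_true(all(sign(s0) == -sign(s1[1])))
})
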