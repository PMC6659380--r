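# Summary-statistics partitioning and LDSC-based overlap estimation.

test_that("independent GWAS give a null cross-trait intercept", {
  zz <- simulate_gwas_zscores(m = 4000, n1 = 50000, n2 = 50000,
                              n_overlap = 0, h2_1 = 0.3, h2_2 = 0.3,
                              rho_g = 0, seed = 411)
  ov <- ldsc_overlap(zz, n1 = 50000, n2 = 50000)
  expect_lt(abs(ov$intercept), 2 * ov$se_intercept)
})

test_that("complete overlap recovers the phenotypic-correlation intercept", {
  n <- 60000
  zz <- simulate_gwas_zscores(m = 4000, n1 = n, n2 = n, n_overlap = n,
                              rho_p = 0.23, seed = 412)
  ov <- ldsc_overlap(zz, n1 = n, n2 = n, rho_p = 0.23)
  expect_lt(abs(ov$intercept - 0.23), 2 * ov$se_intercept)
  expect_equal(ov$n_overlap, min(ov$intercept * n / 0.23, n),
               tolerance = 1e-10)
  expect_lte(ov$n_overlap, n)
})

test_that("zero genetic correlation gives a null LD-dependent slope", {
  # Polygenic variance scaled as in genome-wide data: n * h2 * l / m
  # of order one per SNP.
  zz <- simulate_gwas_zscores(m = 20000, n1 = 20000, n2 = 20000,
                              n_overlap = 10000, rho_p = 0.23,
                              h2_1 = 0.25, h2_2 = 0.25, rho_g = 0,
                              seed = 413)
  ov <- ldsc_overlap(zz, n1 = 20000, n2 = 20000)
  expect_lt(abs(ov$slope), 2 * ov$se_slope)
  expect_lt(abs(ov$intercept - overlap_intercept(10000, 20000, 20000,
                                                 0.23)),
            2 * ov$se_intercept)
})

test_that("too few SNPs for LDSC is an error", {
  zz <- simulate_gwas_zscores(m = 150, n1 = 1000, n2 = 1000, seed = 1)
  expect_error(ldsc_overlap(zz, n1 = 1000, n2 = 1000), "200")
})

test_that("null input betas give null partitioned effects with propagated SEs", {
  own <- tibble::tibble(snp_id = "rs1", beta = 0, se = 0.01)
  off <- tibble::tibble(snp_id = "rs1", beta = 0, se = 0.02)
  fit <- fit_sem_summary(own, off, intercept = 0)
  expect_equal(fit$beta_m, 0)
  expect_equal(fit$beta_o, 0)
  expect_equal(fit$se_m, sqrt((4 / 9) * 0.01^2 + (16 / 9) * 0.02^2))
  expect_equal(fit$se_o, sqrt((16 / 9) * 0.01^2 + (4 / 9) * 0.02^2))
})

test_that("published unadjusted slopes invert to the published adjusted effects", {
  own <- tibble::tibble(snp_id = "rs1", beta = -0.025, se = 0.007)
  off <- tibble::tibble(snp_id = "rs1", beta = 0.0145, se = 0.007)
  fit <- fit_sem_summary(own, off, intercept = 0)
  expect_equal(fit$beta_m, 0.036, tolerance = 1e-6)
  expect_equal(fit$beta_o, -0.043, tolerance = 0.015)
})

test_that("propagated SEs match the sampling distribution (coverage)", {
  set.seed(414)
  n_snp <- 500
  truth_m <- 0.05
  truth_o <- -0.03
  u <- unconditional_expectations(truth_m, truth_o)
  se1 <- 0.01
  se2 <- 0.012
  intercept <- 0.4
  cv <- intercept * se1 * se2
  z <- matrix(rnorm(2 * n_snp), n_snp, 2)
  d1 <- se1 * z[, 1]
  d2 <- (cv / se1) * z[, 1] + sqrt(se2^2 - (cv / se1)^2) * z[, 2]
  own <- tibble::tibble(snp_id = paste0("rs", 1:n_snp),
                        beta = u$b_own + d1, se = se1)
  off <- tibble::tibble(snp_id = paste0("rs", 1:n_snp),
                        beta = u$b_off + d2, se = se2)
  fit <- fit_sem_summary(own, off, intercept = intercept)
  covered <- abs(fit$beta_m - truth_m) <= 1.96 * fit$se_m
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
  # Empirical SD of the estimates matches the propagated SE.
  expect_equal(sd(fit$beta_m), mean(fit$se_m), tolerance = 0.08)
})

test_that("known-overlap and LDSC-estimated-overlap fits coincide", {
  n <- 60000
  n_s <- 40000
  rho_p <- 0.23
  zz <- simulate_gwas_zscores(m = 5000, n1 = n, n2 = n, n_overlap = n_s,
                              rho_p = rho_p, seed = 415)
  ov <- ldsc_overlap(zz, n1 = n, n2 = n, rho_p = rho_p)
  known <- overlap_intercept(n_s, n, n, rho_p)
  sim <- simulate_mr_study(n_snps = 50, theta_m = 0.4, theta_o = -0.2,
                           mode = "summary", overlap = n_s / n,
                           rho_p = rho_p, n1 = n, n2 = n, seed = 416)
  fit_known <- fit_sem_summary(sim$own_gwas, sim$off_gwas,
                               intercept = known)
  fit_ldsc <- fit_sem_summary(sim$own_gwas, sim$off_gwas, overlap = ov)
  # Point estimates do not depend on the overlap at all.
  expect_equal(fit_ldsc$beta_m, fit_known$beta_m, tolerance = 1e-12)
  expect_equal(fit_ldsc$beta_o, fit_known$beta_o, tolerance = 1e-12)
  # SEs agree within the jackknife noise of the intercept.
  expect_lt(max(abs(fit_ldsc$se_m / fit_known$se_m - 1)), 0.05)
  expect_lt(max(abs(fit_ldsc$se_o / fit_known$se_o - 1)), 0.05)
})

test_that("misspecifying the phenotypic correlation leaves estimates unchanged", {
  # rho_p enters only the implied overlapping-sample count; the
  # effect-estimate covariance uses the intercept itself.
  n <- 60000
  zz <- simulate_gwas_zscores(m = 4000, n1 = n, n2 = n, n_overlap = 30000,
                              rho_p = 0.23, seed = 417)
  sim <- simulate_mr_study(n_snps = 40, theta_m = 0.3, mode = "summary",
                           overlap = 0.5, rho_p = 0.23, n1 = n, n2 = n,
                           seed = 418)
  fits <- lapply(c(0.1, 0.2, 0.3), function(rp) {
    ov <- ldsc_overlap(zz, n1 = n, n2 = n, rho_p = rp)
    fit_sem_summary(sim$own_gwas, sim$off_gwas, overlap = ov)
  })
  expect_equal(fits[[1]]$beta_m, fits[[3]]$beta_m, tolerance = 1e-12)
  expect_equal(fits[[1]]$se_m, fits[[2]]$se_m, tolerance = 1e-12)
  expect_equal(fits[[2]]$se_o, fits[[3]]$se_o, tolerance = 1e-12)
})

test_that("summary fit aligns swapped alleles and rejects mismatches", {
  own <- tibble::tibble(snp_id = c("rs1", "rs2"),
                        effect_allele = c("A", "C"),
                        other_allele = c("G", "T"),
                        beta = c(0.1, -0.05), se = c(0.01, 0.01))
  off <- tibble::tibble(snp_id = c("rs1", "rs2"),
                        effect_allele = c("G", "C"),
                        other_allele = c("A", "T"),
                        beta = c(-0.2, 0.05), se = c(0.01, 0.01))
  fit <- fit_sem_summary(own, off, intercept = 0)
  expect_equal(fit$flipped, c(TRUE, FALSE))
  expect_equal(fit$b_off, c(0.2, 0.05))
  off$effect_allele[2] <- "A"
  expect_error(fit_sem_summary(own, off), "incompatible alleles")
})
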