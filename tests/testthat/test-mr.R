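# Two-sample MR estimators and harmonization.

make_exposure <- function(n = 5, ea = "A", oa = "G", eaf = 0.3,
                          beta = 0.1, se = 0.01) {
  tibble::tibble(snp_id = paste0("rs", seq_len(n)), effect_allele = ea,
                 other_allele = oa, eaf = eaf, beta = beta, se = se)
}

make_outcome <- function(n = 5, beta_m = 0.05, se_m = 0.01,
                         beta_o = -0.02, se_o = 0.01, ...) {
  tibble::tibble(snp_id = paste0("rs", seq_len(n)), beta_m = beta_m,
                 se_m = se_m, beta_o = beta_o, se_o = se_o, ...)
}

test_that("harmonization flips outcome effects to the exposure effect allele", {
  exposure <- make_exposure(1, ea = "A", oa = "G", beta = 0.10)
  outcome <- make_outcome(1, beta_m = -0.05,
                          effect_allele = "G", other_allele = "A")
  h <- harmonize_instruments(exposure, outcome)
  expect_true(h$flipped)
  expect_equal(h$beta_out_m, 0.05)
})

test_that("rare and ambiguous-palindromic SNPs are excluded with reasons", {
  exposure <- make_exposure(3)
  exposure$eaf <- c(3.9e-5, 0.5, 0.3)
  exposure$effect_allele <- c("A", "A", "A")
  exposure$other_allele <- c("G", "T", "G")
  outcome <- make_outcome(3)
  expect_message(h <- harmonize_instruments(exposure, outcome,
                                            maf_min = 1e-3),
                 "excluded 2")
  excl <- attr(h, "exclusions")
  expect_equal(excl$reason[excl$snp_id == "rs1"], "maf_below_threshold")
  expect_equal(excl$reason[excl$snp_id == "rs2"],
               "palindromic_ambiguous")
  expect_equal(h$snp_id, "rs3")
})

test_that("non-converged outcome fits are excluded and empty sets error", {
  exposure <- make_exposure(2)
  outcome <- make_outcome(2, converged = c(TRUE, FALSE))
  expect_message(h <- harmonize_instruments(exposure, outcome),
                 "not_converged")
  expect_equal(h$snp_id, "rs1")
  outcome$converged <- FALSE
  expect_error(suppressMessages(
    harmonize_instruments(exposure, outcome)), "no instruments")
})

test_that("Wald ratios follow the delta rule", {
  expect_equal(wald_ratio(0.05, 0.01, 0.10),
               tibble::tibble(estimate = 0.5, se = 0.1))
  expect_equal(wald_ratio(0, 0.02, 0.4)$se, 0.05)
  expect_equal(wald_ratio(-0.05, 0.01, 0.10)$estimate, -0.5)
  expect_error(wald_ratio(0.1, 0.01, 0), "nonzero")
  # Second-order SE adds the exposure-uncertainty term.
  w2 <- wald_ratio(0.05, 0.01, 0.10, se_exp = 0.02, second_order = TRUE)
  expect_equal(w2$se, sqrt(0.01^2 / 0.01 + 0.05^2 * 0.02^2 / 1e-4))
})

test_that("IVW reduces to closed forms", {
  one <- mr_ivw(tibble::tibble(estimate = 0.37, se = 0.21))
  expect_equal(one$estimate, 0.37)
  expect_equal(one$se, 0.21)

  two <- mr_ivw(tibble::tibble(estimate = c(0.5, 0.3), se = 0.1),
                random = FALSE)
  expect_equal(two$estimate, 0.4)
  expect_equal(two$se, 0.1 / sqrt(2))
  expect_equal(two$q_statistic, 2.0)
  expect_equal(two$q_df, 1)

  # Identical ratios: no heterogeneity, random = fixed.
  same <- mr_ivw(tibble::tibble(estimate = rep(0.2, 5), se = 0.05))
  expect_equal(same$q_statistic, 0)
  expect_equal(same$se, 0.05 / sqrt(5))

  # Equal weights: IVW is the arithmetic mean.
  set.seed(419)
  r <- rnorm(10)
  expect_equal(mr_ivw(tibble::tibble(estimate = r, se = 0.3))$estimate,
               mean(r))
})

test_that("random-effects scaling never deflates below the fixed-effect SE", {
  set.seed(420)
  for (i in 1:10) {
    ratios <- tibble::tibble(estimate = rnorm(8, 0.2, 0.3),
                             se = runif(8, 0.05, 0.2))
    expect_gte(mr_ivw(ratios)$se, mr_ivw(ratios, random = FALSE)$se)
  }
})

test_that("Egger fits exact collinear points and needs 3+ spread instruments", {
  d <- tibble::tibble(beta_exp = c(0.05, 0.10, 0.20),
                      se_out = 0.01)
  d$beta_out <- 0.2 * d$beta_exp + 0.01
  fit <- mr_egger(d)
  expect_equal(fit$estimate, 0.2, tolerance = 1e-10)
  expect_equal(fit$egger_intercept, 0.01, tolerance = 1e-10)
  expect_equal(fit$q_statistic, 0, tolerance = 1e-16)
  expect_error(mr_egger(d[1:2, ]), "3")
  d$beta_exp <- 0.1
  expect_error(mr_egger(d), "spread")
})

test_that("Egger separates the causal slope from directional pleiotropy", {
  theta <- 0.3
  reps <- 60
  sl <- ic <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(3000 + r)
    k <- 50
    bx <- rnorm(k, 0.08, 0.03)
    # balanced for slope check, directional for intercept check below
    pleio <- rnorm(k, 0.02, 0.01)
    by <- theta * bx + pleio + rnorm(k, 0, 0.005)
    fit <- mr_egger(tibble::tibble(beta_exp = bx, beta_out = by,
                                   se_out = 0.005))
    sl[r] <- fit$estimate
    ic[r] <- fit$egger_intercept
  }
  expect_lt(abs(mean(sl) - theta), 2 * sd(sl) / sqrt(reps))
  expect_lt(abs(mean(ic) - 0.02), 2 * sd(ic) / sqrt(reps))
})

test_that("Egger with the intercept constrained to zero is the fixed-effects IVW slope", {
  set.seed(421)
  k <- 20
  bx <- rnorm(k, 0.1, 0.04)
  by <- 0.25 * bx + rnorm(k, 0, 0.01)
  se_out <- runif(k, 0.005, 0.02)
  w <- 1 / se_out^2
  slope0 <- sum(w * bx * by) / sum(w * bx^2)
  ivw <- mr_ivw(wald_ratio(by, se_out, bx), random = FALSE)
  expect_equal(ivw$estimate, slope0, tolerance = 1e-12)
})

test_that("weighted median matches its brute-force definition", {
  same <- mr_weighted_median(tibble::tibble(estimate = rep(0.4, 4),
                                            se = c(0.1, 0.2, 0.1, 0.3)))
  expect_equal(same$estimate, 0.4)
  trio <- mr_weighted_median(tibble::tibble(estimate = c(0.1, 0.2, 0.9),
                                            se = 1))
  expect_equal(trio$estimate, 0.2)
  set.seed(422)
  for (i in 1:10) {
    x <- rnorm(7)
    se <- runif(7, 0.5, 2)
    est <- mr_weighted_median(tibble::tibble(estimate = x, se = se),
                              n_boot = 10)$estimate
    expect_equal(est, brute_weighted_median(x, 1 / se^2))
  }
  expect_error(mr_weighted_median(tibble::tibble(estimate = 1:2,
                                                 se = 1)), "3")
})

test_that("weighted median resists a minority of pleiotropic instruments", {
  # 80% of the weight on valid instruments around theta; 20% shifted by
  # +0.5.  The weighted median stays near theta while the IVW mean is
  # pulled by the full contamination.
  theta <- 0.25
  reps <- 40
  est_wm <- est_ivw <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(4000 + r)
    ratios <- tibble::tibble(
      estimate = c(rnorm(24, theta, 0.02), rnorm(6, theta + 0.5, 0.02)),
      se = 0.02)
    est_wm[r] <- mr_weighted_median(ratios, n_boot = 200,
                                    seed = r)$estimate
    est_ivw[r] <- mr_ivw(ratios)$estimate
  }
  expect_lt(abs(mean(est_wm) - theta), 0.02)
  expect_gt(abs(mean(est_ivw) - theta), 0.05)
  expect_lt(abs(mean(est_wm) - theta), abs(mean(est_ivw) - theta) / 3)
})

test_that("estimators are equivariant under global allele flips", {
  set.seed(423)
  k <- 10
  exposure <- make_exposure(k, beta = rnorm(k, 0.1, 0.03),
                            se = 0.01, eaf = runif(k, 0.1, 0.4))
  outcome <- make_outcome(k, beta_m = rnorm(k, 0.05, 0.02), se_m = 0.01,
                          beta_o = rnorm(k, -0.02, 0.02), se_o = 0.01,
                          effect_allele = "A", other_allele = "G")
  flipped_exposure <- exposure
  flipped_exposure$effect_allele <- "G"
  flipped_exposure$other_allele <- "A"
  flipped_exposure$beta <- -exposure$beta
  flipped_exposure$eaf <- 1 - exposure$eaf
  g1 <- mr_pipeline(exposure, outcome, seed = 9)
  g2 <- suppressMessages(mr_pipeline(flipped_exposure, outcome, seed = 9))
  expect_equal(g1$estimate, g2$estimate, tolerance = 1e-12)
  expect_equal(g1$se, g2$se, tolerance = 1e-12)
})

test_that("single-instrument input yields IVW only, others flagged", {
  exposure <- make_exposure(1)
  outcome <- make_outcome(1, b_own = 0.02, se_own = 0.01, b_off = 0.04,
                          se_off = 0.01)
  grid <- mr_pipeline(exposure, outcome)
  ivw <- dplyr::filter(grid, method == "ivw")
  expect_true(all(!is.na(ivw$estimate)))
  other <- dplyr::filter(grid, method != "ivw")
  expect_true(all(is.na(other$estimate)))
  expect_true(all(other$note == "insufficient_instruments"))
})

test_that("pipeline recovers causal effects and shows unadjusted mixing", {
  theta_m <- 0.3
  theta_o <- -0.2
  sim <- simulate_mr_study(n_snps = 150, theta_m = theta_m,
                           theta_o = theta_o, mode = "summary",
                           n1 = 300000, n2 = 300000, seed = 424)
  outcome <- fit_sem_summary(sim$own_gwas, sim$off_gwas, intercept = 0)
  grid <- mr_pipeline(sim$exposure, outcome, seed = 5)
  pick <- function(a, adj) {
    dplyr::filter(grid, arm == a, adjustment == adj, method == "ivw")
  }
  adj_m <- pick("maternal", "sem")
  adj_o <- pick("offspring", "sem")
  una_m <- pick("maternal", "unadjusted")
  una_o <- pick("offspring", "unadjusted")
  expect_lt(abs(adj_m$estimate - theta_m), 3 * adj_m$se)
  expect_lt(abs(adj_o$estimate - theta_o), 3 * adj_o$se)
  expect_lt(abs(una_m$estimate - (theta_m + theta_o / 2)), 3 * una_m$se)
  expect_lt(abs(una_o$estimate - (theta_o + theta_m / 2)), 3 * una_o$se)
  # Opposing maternal and offspring effects attenuate the unadjusted
  # estimates relative to the partitioned ones, in both arms.
  expect_lt(abs(una_m$estimate), abs(adj_m$estimate))
  expect_lt(abs(una_o$estimate), abs(adj_o$estimate))
})

test_that("null causal effects reject at the nominal rate", {
  reps <- 500
  pvals <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_mr_study(n_snps = 30, theta_m = 0, theta_o = 0,
                             mode = "summary", n1 = 100000, n2 = 100000,
                             seed = 5000 + r)
    outcome <- fit_sem_summary(sim$own_gwas, sim$off_gwas, intercept = 0)
    h <- harmonize_instruments(sim$exposure, outcome)
    ratios <- wald_ratio(h$beta_out_m, h$se_out_m, h$beta_exp)
    pvals[r] <- mr_ivw(ratios)$p
  }
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})
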