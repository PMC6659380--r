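# Synthetic-data engine: Mendelian transmission across three
# generations, phenotypes under the latent-genotype SEM, and two-sample
# GWAS summary statistics with configurable overlap.
#
# Transmission is genuine allele sampling, not a Gaussian approximation:
# a parent with dosage g transmits an allele with probability g/2, which
# is exact Mendelian segregation at a biallelic locus.  The 0.5
# parent-offspring path and the phi/4 grandmother-grandchild covariance
# therefore emerge from the sampling scheme rather than being imposed,
# which keeps the covariance-algebra oracles in the test suite
# non-circular.

.transmit <- function(dosage) {
  stats::rbinom(length(dosage), 1L, dosage / 2)
}

#' Simulate three-generation families under the latent-genotype model
#'
#' Draws grandmother and founder genotypes from Hardy-Weinberg
#' equilibrium at allele frequency `maf`, transmits alleles Mendelianly
#' to each woman and to her first offspring, and generates the two
#' phenotypes as `own = mu_bw + beta_o * snp + beta_m * gg + e` and
#' `offspring = mu_bwo + beta_m * snp + beta_o * go + e_o` with
#' `(e, e_o)` bivariate normal with covariance `rho`.  Missingness
#' patterns are assigned deterministically according to the requested
#' counts.  A separate table of genotyped mother-offspring pairs (both
#' dosages observed, offspring phenotype only) is drawn for the
#' conditional design.
#'
#' @param n_both,n_own_only,n_off_only,n_snp_only Numbers of women whose
#'   records carry both phenotypes, own phenotype only, offspring
#'   phenotype only, or dosage only.
#' @param n_pairs Number of genotyped mother-offspring pairs.
#' @param maf Allele frequency of the counted allele.
#' @param beta_m,beta_o Maternal and offspring genetic effects.
#' @param rho Residual covariance between the two phenotypes.
#' @param sigma2_e,sigma2_eo Residual variances.
#' @param mu_bw,mu_bwo Phenotype means.
#' @param seed Integer seed; every draw derives from it.
#' @return A list with `families` (tibble: `id`, `snp`, `own_pheno`,
#'   `offspring_pheno`, `pattern`), `pairs` (tibble: `offspring_pheno`,
#'   `offspring_snp`, `maternal_snp`) and `params`, the generating
#'   [sem_params()].
#' @export
#' @examples
#' sim <- simulate_families(n_both = 1000, maf = 0.3, beta_m = 0.1,
#'                          beta_o = -0.1, rho = 0.2, seed = 42)
#' head(sim$families)
simulate_families <- function(n_both = 0, n_own_only = 0, n_off_only = 0,
                              n_snp_only = 0, n_pairs = 0,
                              maf, beta_m = 0, beta_o = 0, rho = 0,
                              sigma2_e = 1, sigma2_eo = 1,
                              mu_bw = 0, mu_bwo = 0, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (maf <= 0 || maf >= 1) stop("maf must lie in (0, 1)", call. = FALSE)
  counts <- c(n_both, n_own_only, n_off_only, n_snp_only, n_pairs)
  if (any(counts < 0) || sum(counts) == 0) {
    stop("sample sizes must be non-negative with at least one positive",
         call. = FALSE)
  }
  # Observed-variable means: every genotype (grandmother, woman,
  # offspring) has expectation 2 * maf, so both genetic paths shift each
  # phenotype mean by (beta_m + beta_o) * 2 * maf on top of the
  # intercepts mu_bw / mu_bwo.
  mean_shift <- (beta_m + beta_o) * 2 * maf
  params <- sem_params(beta_m = beta_m, beta_o = beta_o,
                       phi = 2 * maf * (1 - maf), rho = rho,
                       sigma2_e = sigma2_e, sigma2_eo = sigma2_eo,
                       mu_bw = mu_bw + mean_shift,
                       mu_bwo = mu_bwo + mean_shift, mu_snp = 2 * maf)
  set.seed(seed)
  n <- n_both + n_own_only + n_off_only + n_snp_only
  families <- NULL
  if (n > 0) {
    gg <- stats::rbinom(n, 2L, maf)
    snp <- .transmit(gg) + stats::rbinom(n, 1L, maf)
    go <- .transmit(snp) + stats::rbinom(n, 1L, maf)
    e1 <- stats::rnorm(n, 0, sqrt(sigma2_e))
    cond_sd <- sqrt(sigma2_eo - rho^2 / sigma2_e)
    e2 <- (rho / sigma2_e) * e1 + stats::rnorm(n, 0, cond_sd)
    own <- mu_bw + beta_o * snp + beta_m * gg + e1
    off <- mu_bwo + beta_m * snp + beta_o * go + e2
    pattern <- rep(.pattern_levels,
                   c(n_both, n_own_only, n_off_only, n_snp_only))
    own[!pattern %in% c("both", "own_only")] <- NA_real_
    off[!pattern %in% c("both", "offspring_only")] <- NA_real_
    families <- tibble::tibble(id = paste0("fam_", seq_len(n)),
                               snp = as.numeric(snp),
                               own_pheno = own, offspring_pheno = off,
                               pattern = factor(pattern,
                                                levels = .pattern_levels))
  }
  pairs <- NULL
  if (n_pairs > 0) {
    msnp <- stats::rbinom(n_pairs, 2L, maf)
    osnp <- .transmit(msnp) + stats::rbinom(n_pairs, 1L, maf)
    eo <- stats::rnorm(n_pairs, 0, sqrt(sigma2_eo))
    pairs <- tibble::tibble(
      offspring_pheno = mu_bwo + beta_m * msnp + beta_o * osnp + eo,
      offspring_snp = as.numeric(osnp),
      maternal_snp = as.numeric(msnp))
  }
  list(families = families, pairs = pairs, params = params)
}

#' Simulate a multi-SNP two-sample MR study
#'
#' Generates `n_snps` independent biallelic instruments with exposure
#' effects drawn from a normal distribution, and sets each SNP's
#' conditional maternal and offspring effects on the outcome phenotype to
#' `theta_m * beta_exp + pleiotropy` and `theta_o * beta_exp +
#' pleiotropy` respectively, so `theta_m` and `theta_o` are the causal
#' effects of the maternal and offspring exposure on the outcome.
#'
#' In `mode = "individual"` a duo cohort of `n_both` women is simulated
#' carrying every SNP (Mendelian transmission per locus; effects of all
#' loci add on the phenotypes, with residual variances scaled so each
#' phenotype has unit variance and residual correlation `rho_resid`).  In
#' `mode = "summary"` the two unconditional outcome GWAS are emitted
#' directly with sampling noise whose across-GWAS covariance per SNP is
#' `overlap * rho_p * se1 * se2`.
#'
#' @param n_snps Number of independent instruments.
#' @param theta_m,theta_o Causal effects of the maternal and offspring
#'   exposure on the outcome (outcome units per exposure unit).
#' @param n_both Cohort size (individual mode).
#' @param maf_range Range of the uniform allele-frequency distribution.
#' @param exposure_mean,exposure_sd Distribution of true SNP-exposure
#'   effects.
#' @param exposure_se Sampling standard error added to the exposure GWAS
#'   betas.
#' @param pleiotropy_mean,pleiotropy_sd Direct (horizontal) SNP-outcome
#'   effects added to the maternal component, bypassing the exposure;
#'   nonzero mean gives directional pleiotropy.
#' @param rho_resid Residual correlation between own and offspring
#'   phenotypes (individual mode).
#' @param n1,n2 Sample sizes of the own- and offspring-phenotype GWAS
#'   (summary mode).
#' @param overlap Fraction of overlapping samples between the two
#'   outcome GWAS (summary mode).
#' @param rho_p Phenotypic correlation between the two phenotypes in the
#'   overlapping samples (summary mode).
#' @param mode `"individual"` or `"summary"`.
#' @param seed Integer seed.
#' @return A list with `exposure` (GWAS tibble: `snp_id`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`), `truth`
#'   (per-SNP generating effects plus `theta_m`, `theta_o` as
#'   attributes), and either `phenotypes` + `genotypes` (individual
#'   mode) or `own_gwas` + `off_gwas` (summary mode).
#' @export
simulate_mr_study <- function(n_snps, theta_m = 0, theta_o = 0,
                              n_both = 10000,
                              maf_range = c(0.05, 0.5),
                              exposure_mean = 0.08, exposure_sd = 0.02,
                              exposure_se = 0.001,
                              pleiotropy_mean = 0, pleiotropy_sd = 0,
                              rho_resid = 0.2,
                              n1 = 200000, n2 = 200000,
                              overlap = 0, rho_p = 0.23,
                              mode = c("individual", "summary"), seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  mode <- match.arg(mode)
  if (n_snps < 1) stop("n_snps must be >= 1", call. = FALSE)
  if (exposure_sd < 0 || pleiotropy_sd < 0) {
    stop("distribution SDs must be non-negative", call. = FALSE)
  }
  set.seed(seed)
  snp_id <- sprintf("rs%05d", seq_len(n_snps))
  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  phi <- 2 * maf * (1 - maf)
  beta_exp <- stats::rnorm(n_snps, exposure_mean, exposure_sd)
  pleio <- stats::rnorm(n_snps, pleiotropy_mean, pleiotropy_sd)
  beta_m <- theta_m * beta_exp + pleio
  beta_o <- theta_o * beta_exp
  truth <- tibble::tibble(snp_id = snp_id, maf = maf, phi = phi,
                          beta_exp = beta_exp, beta_m = beta_m,
                          beta_o = beta_o, pleiotropy = pleio)
  attr(truth, "theta_m") <- theta_m
  attr(truth, "theta_o") <- theta_o
  exposure <- tibble::tibble(snp_id = snp_id, effect_allele = "A",
                             other_allele = "G", eaf = maf,
                             beta = beta_exp +
                               stats::rnorm(n_snps, 0, exposure_se),
                             se = pmax(exposure_se, 1e-8))
  out <- list(exposure = exposure, truth = truth)

  if (mode == "individual") {
    # Per-locus Mendelian transmission; all loci contribute additively.
    gg <- matrix(stats::rbinom(n_both * n_snps, 2L, rep(maf, each = n_both)),
                 n_both, n_snps)
    snp <- matrix(stats::rbinom(n_both * n_snps, 1L, gg / 2), n_both,
                  n_snps) +
      matrix(stats::rbinom(n_both * n_snps, 1L, rep(maf, each = n_both)),
             n_both, n_snps)
    go <- matrix(stats::rbinom(n_both * n_snps, 1L, snp / 2), n_both,
                 n_snps) +
      matrix(stats::rbinom(n_both * n_snps, 1L, rep(maf, each = n_both)),
             n_both, n_snps)
    gen_var <- sum(phi * (beta_m^2 + beta_o^2 + beta_m * beta_o))
    if (gen_var >= 1) {
      stop("genetic variance implied by the configuration exceeds the unit ",
           "phenotype variance; reduce effect sizes or n_snps", call. = FALSE)
    }
    s2 <- 1 - gen_var
    e1 <- stats::rnorm(n_both, 0, sqrt(s2))
    e2 <- rho_resid * e1 + stats::rnorm(n_both, 0,
                                        sqrt(s2 * (1 - rho_resid^2)))
    own <- drop(snp %*% beta_o + gg %*% beta_m) + e1
    off <- drop(snp %*% beta_m + go %*% beta_o) + e2
    colnames(snp) <- snp_id
    out$phenotypes <- tibble::tibble(own_pheno = own, offspring_pheno = off)
    out$genotypes <- snp
  } else {
    uncond <- unconditional_expectations(beta_m, beta_o)
    se1 <- 1 / sqrt(n1 * phi)
    se2 <- 1 / sqrt(n2 * phi)
    cov12 <- overlap * rho_p * se1 * se2
    z <- matrix(stats::rnorm(2 * n_snps), n_snps, 2)
    d1 <- se1 * z[, 1]
    d2 <- cov12 / se1 * z[, 1] +
      sqrt(pmax(se2^2 - (cov12 / se1)^2, 0)) * z[, 2]
    gwas <- function(b, d, se, n) {
      tibble::tibble(snp_id = snp_id, effect_allele = "A",
                     other_allele = "G", eaf = maf,
                     beta = b + d, se = se, n = n)
    }
    out$own_gwas <- gwas(uncond$b_own, d1, se1, n1)
    out$off_gwas <- gwas(uncond$b_off, d2, se2, n2)
  }
  out
}

#' Simulate paired GWAS z-scores with LD-dependent polygenic signal
#'
#' Stylized generator for the cross-trait LD score regression intercept:
#' per-SNP z-score pairs are drawn from a bivariate normal with
#' `var(z_k) = 1 + n_k * h2_k * l_j / m` and
#' `cov(z_1, z_2) = sqrt(n1 * n2) * rho_g * l_j / m +
#' rho_p * n_overlap / sqrt(n1 * n2)`, where `l_j` is the SNP's LD score
#' (drawn from a shifted gamma distribution).
#'
#' @param m Number of SNPs.
#' @param n1,n2 GWAS sample sizes.
#' @param n_overlap Number of samples contributing to both GWAS.
#' @param rho_p Phenotypic correlation in the overlapping samples.
#' @param h2_1,h2_2 Trait heritabilities.
#' @param rho_g Genetic correlation.
#' @param ld_mean Mean LD score.
#' @param seed Integer seed.
#' @return A tibble with `snp_id`, `ld_score`, `z_own`, `z_off`.
#' @export
simulate_gwas_zscores <- function(m, n1, n2, n_overlap = 0, rho_p = 0.23,
                                  h2_1 = 0, h2_2 = 0, rho_g = 0,
                                  ld_mean = 40, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  ld <- 1 + stats::rgamma(m, shape = 2, scale = (ld_mean - 1) / 2)
  v1 <- 1 + n1 * h2_1 * ld / m
  v2 <- 1 + n2 * h2_2 * ld / m
  c12 <- sqrt(n1 * n2) * rho_g * ld / m + rho_p * n_overlap / sqrt(n1 * n2)
  z <- matrix(stats::rnorm(2 * m), m, 2)
  z1 <- sqrt(v1) * z[, 1]
  a <- c12 / sqrt(v1)
  z2 <- a * z[, 1] + sqrt(pmax(v2 - a^2, 1e-12)) * z[, 2]
  tibble::tibble(snp_id = sprintf("rs%06d", seq_len(m)),
                 ld_score = ld, z_own = z1, z_off = z2)
}
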