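# Parameter container and implied moments for the latent-genotype SEM.
#
# Observed variables for one genotyped woman: her own phenotype ("own",
# e.g. her own birthweight), her first offspring's phenotype ("offspring")
# and her allele dosage at one SNP ("snp").  The genotypes of her mother
# and of her offspring are latent; each is connected to her own genotype
# by the meiotic transmission path of 0.5 and all three genotypic
# variances equal phi.

.sem_par_names <- c("beta_m", "beta_o", "phi", "rho",
                    "sigma2_e", "sigma2_eo", "mu_bw", "mu_bwo", "mu_snp")

.pattern_levels <- c("both", "own_only", "offspring_only", "snp_only")

.pattern_vars <- list(
  both           = c("own", "offspring", "snp"),
  own_only       = c("own", "snp"),
  offspring_only = c("offspring", "snp"),
  snp_only       = "snp"
)

#' Parameters of the latent-genotype structural equation model
#'
#' Bundles the free parameters of the maternal/offspring effect SEM: the
#' maternal (`beta_m`) and offspring (`beta_o`) per-allele genetic effects,
#' the genotypic variance `phi`, the residual covariance `rho` between a
#' woman's own phenotype and her offspring's phenotype, the two residual
#' variances, and the means of the three observed variables.
#'
#' @param beta_m Maternal genetic effect (phenotype units per allele): the
#'   effect of the mother's genotype on the offspring phenotype conditional
#'   on the offspring's own genotype.
#' @param beta_o Offspring (fetal) genetic effect (phenotype units per
#'   allele): the effect of an individual's own genotype on their own
#'   phenotype conditional on maternal genotype.
#' @param phi Variance of the allele dosage at the locus; under
#'   Hardy-Weinberg equilibrium `2 * p * (1 - p)`.  Estimated freely.
#' @param rho Residual covariance between own and offspring phenotypes
#'   (phenotype^2 units), capturing shared environment and polygenic
#'   background not attributable to the modelled locus.
#' @param sigma2_e,sigma2_eo Residual variances of the own and offspring
#'   phenotypes.
#' @param mu_bw,mu_bwo,mu_snp Means of the own phenotype, offspring
#'   phenotype and dosage.
#'
#' @return An object of class `sem_params`: a named list of the nine
#'   parameters.
#' @seealso [implied_moments()], [fit_sem()]
#' @export
#' @examples
#' sem_params(beta_m = 0.1, beta_o = -0.1, phi = 0.42, rho = 0.2)
sem_params <- function(beta_m = 0, beta_o = 0, phi = 0.5, rho = 0,
                       sigma2_e = 1, sigma2_eo = 1,
                       mu_bw = 0, mu_bwo = 0, mu_snp = NULL) {
  if (is.null(mu_snp)) mu_snp <- 0
  p <- list(beta_m = beta_m, beta_o = beta_o, phi = phi, rho = rho,
            sigma2_e = sigma2_e, sigma2_eo = sigma2_eo,
            mu_bw = mu_bw, mu_bwo = mu_bwo, mu_snp = mu_snp)
  bad <- names(p)[!vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                            is.finite(x), logical(1))]
  if (length(bad)) {
    stop("sem_params fields must be finite scalars: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  validate_sem_params(structure(p, class = "sem_params"))
}

#' @rdname sem_params
#' @param x Object to validate.
#' @export
validate_sem_params <- function(x) {
  if (x$phi <= 0) stop("parameter domain error: phi must be > 0", call. = FALSE)
  if (x$sigma2_e <= 0) {
    stop("parameter domain error: sigma2_e must be > 0", call. = FALSE)
  }
  if (x$sigma2_eo <= 0) {
    stop("parameter domain error: sigma2_eo must be > 0", call. = FALSE)
  }
  if (abs(x$rho) >= sqrt(x$sigma2_e * x$sigma2_eo)) {
    stop("parameter domain error: |rho| must be < sqrt(sigma2_e * sigma2_eo)",
         call. = FALSE)
  }
  x
}

#' @export
print.sem_params <- function(x, ...) {
  cat("<sem_params>\n")
  print(unlist(x))
  invisible(x)
}

# Internal fast path: th is a numeric vector in .sem_par_names order,
# no validation.  Returns 3x3 covariance over (own, offspring, snp).
.sem_sigma <- function(th) {
  bm <- th[[1L]]; bo <- th[[2L]]; phi <- th[[3L]]; rho <- th[[4L]]
  s2e <- th[[5L]]; s2eo <- th[[6L]]
  v_own  <- phi * (bo^2 + bm^2 + bo * bm) + s2e
  v_off  <- phi * (bm^2 + bo^2 + bm * bo) + s2eo
  c_oo   <- phi * (1.25 * bo * bm + (bo^2 + bm^2) / 2) + rho
  c_own  <- bo * phi + bm * phi / 2
  c_off  <- bm * phi + bo * phi / 2
  matrix(c(v_own, c_oo,  c_own,
           c_oo,  v_off, c_off,
           c_own, c_off, phi),
         3L, 3L, dimnames = list(c("own", "offspring", "snp"),
                                 c("own", "offspring", "snp")))
}

.sem_mu <- function(th) {
  c(own = th[[7L]], offspring = th[[8L]], snp = th[[9L]])
}

#' Model-implied moments of the observed variables
#'
#' Integrates the two latent genotypes out of the SEM by covariance
#' algebra: with transmission paths of 0.5 the dosage covaries with each
#' latent genotype by `phi / 2` and the two latent genotypes with each
#' other by `phi / 4`, which yields closed-form expressions for the 3x3
#' covariance matrix and mean vector of (own phenotype, offspring
#' phenotype, dosage).  Marginal moments for each missingness pattern are
#' the corresponding principal submatrices.
#'
#' @param params A [sem_params()] object.
#' @return A list with elements `sigma` (3x3 covariance matrix), `mu`
#'   (named mean vector) and `patterns`, a list with one `(sigma, mu)`
#'   pair per missingness pattern (`both`, `own_only`, `offspring_only`,
#'   `snp_only`).
#' @export
#' @examples
#' implied_moments(sem_params(beta_m = 0.1, beta_o = -0.1, phi = 0.42))$sigma
implied_moments <- function(params) {
  stopifnot(inherits(params, "sem_params"))
  validate_sem_params(params)
  th <- unlist(params)[.sem_par_names]
  sigma <- .sem_sigma(th)
  mu <- .sem_mu(th)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    # With phi, sigma2_e, sigma2_eo > 0 and |rho| below its correlation
    # bound only the residual covariance can push the matrix off the cone.
    stop("parameter domain error: implied covariance matrix is not ",
         "positive definite (check rho against the residual variances)",
         call. = FALSE)
  }
  patterns <- lapply(.pattern_vars, function(v) {
    list(sigma = sigma[v, v, drop = FALSE], mu = mu[v])
  })
  list(sigma = sigma, mu = mu, patterns = patterns)
}

#' Map conditional effects to unconditional regression slopes
#'
#' A simple regression of a person's own phenotype on their own dosage has
#' population slope `b_own = beta_o + beta_m / 2`, and a regression of the
#' offspring phenotype on the maternal dosage has slope
#' `b_off = beta_m + beta_o / 2`: each unconditional slope mixes the two
#' conditional effects through the 0.5 transmission path.  Vectorised.
#'
#' @param beta_m,beta_o Conditional maternal and offspring effects.
#' @return A tibble with columns `b_own` and `b_off`.
#' @seealso [invert_unconditional()]
#' @export
#' @examples
#' unconditional_expectations(beta_m = 0.036, beta_o = -0.043)
unconditional_expectations <- function(beta_m, beta_o) {
  tibble::tibble(b_own = beta_o + beta_m / 2,
                 b_off = beta_m + beta_o / 2)
}

#' Recover conditional effects from unconditional slopes
#'
#' Exact inverse of [unconditional_expectations()]:
#' `beta_m = (4 * b_off - 2 * b_own) / 3` and
#' `beta_o = (4 * b_own - 2 * b_off) / 3`.  This is the closed form behind
#' the summary-statistics estimator: two unconditional GWAS slopes are
#' enough to identify both conditional effects.  Vectorised.
#'
#' @param b_own Slope of own phenotype on own dosage.
#' @param b_off Slope of offspring phenotype on maternal dosage.
#' @return A tibble with columns `beta_m` and `beta_o`.
#' @export
#' @examples
#' invert_unconditional(b_own = -0.024, b_off = 0.015)
invert_unconditional <- function(b_own, b_off) {
  tibble::tibble(beta_m = (4 * b_off - 2 * b_own) / 3,
                 beta_o = (4 * b_own - 2 * b_off) / 3)
}
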