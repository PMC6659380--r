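# Asymptotic power to detect maternal genetic effects under three study
# designs: genotyped mother-offspring pairs analysed by the conditional
# regression, the latent-genotype SEM on duos and singletons, and their
# combination.
#
# Effects are standardized to unit phenotype variance: q_m (q_o) is the
# marginal phenotypic variance explained by the maternal (offspring)
# path, so beta = sqrt(q / phi) with phi = 2 * maf * (1 - maf).  Because
# the observed-variable means are free parameters of a multivariate
# normal, the information matrix is block-diagonal between means and
# covariance parameters; power computations therefore work with the
# covariance block (beta_m, beta_o, phi, rho, sigma2_e, sigma2_eo) only.

#' Specify a maternal-effect power calculation
#'
#' @param design `"pairs"` (conditional regression on genotyped
#'   mother-offspring pairs), `"sem"` (latent-genotype SEM on duos and
#'   singletons) or `"combined"`.
#' @param n_pairs Number of genotyped mother-offspring pairs.
#' @param n_both,n_own_only,n_off_only Women with both phenotypes / own
#'   phenotype only / offspring phenotype only.
#' @param q_m Fraction of phenotypic variance explained by the maternal
#'   effect.
#' @param q_o Fraction explained by the offspring effect (may be 0).
#' @param rho Residual correlation between own and offspring phenotypes.
#' @param maf Allele frequency.
#' @param alpha Significance threshold (two-sided chi-square-1 test).
#' @return A validated `power_spec` object.
#' @export
#' @examples
#' power_spec("pairs", n_pairs = 50000, q_m = 0.001, maf = 0.3)
power_spec <- function(design = c("pairs", "sem", "combined"),
                       n_pairs = 0, n_both = 0, n_own_only = 0,
                       n_off_only = 0, q_m, q_o = 0, rho = 0.2,
                       maf = 0.3, alpha = 5e-8) {
  design <- match.arg(design)
  ns <- c(n_pairs = n_pairs, n_both = n_both, n_own_only = n_own_only,
          n_off_only = n_off_only)
  if (any(ns < 0)) stop("sample sizes must be non-negative", call. = FALSE)
  used <- switch(design,
                 pairs = ns["n_pairs"],
                 sem = sum(ns[c("n_both", "n_own_only", "n_off_only")]),
                 combined = sum(ns))
  if (used <= 0) {
    stop("design '", design, "' has no samples", call. = FALSE)
  }
  if (q_m < 0 || q_o < 0 || q_m + q_o >= 1) {
    stop("variance fractions must satisfy 0 <= q_m + q_o < 1",
         call. = FALSE)
  }
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  if (maf <= 0 || maf >= 1) stop("maf must lie in (0, 1)", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  structure(list(design = design, n_pairs = n_pairs, n_both = n_both,
                 n_own_only = n_own_only, n_off_only = n_off_only,
                 q_m = q_m, q_o = q_o, rho = rho, maf = maf,
                 alpha = alpha),
            class = "power_spec")
}

# Covariance-block parameter vector implied by a power_spec, on the
# unit-phenotype-variance scale.
.power_theta <- function(spec) {
  phi <- 2 * spec$maf * (1 - spec$maf)
  bm <- sqrt(spec$q_m / phi)
  bo <- sqrt(spec$q_o / phi)
  gen_var <- phi * (bm^2 + bo^2 + bm * bo)
  if (gen_var >= 1) {
    stop("q_m and q_o jointly imply genetic variance >= 1", call. = FALSE)
  }
  s2 <- 1 - gen_var
  c(beta_m = bm, beta_o = bo, phi = phi, rho = spec$rho * s2,
    sigma2_e = s2, sigma2_eo = s2)
}

# Implied covariance of (Y, oSNP, mSNP) in the pairs design; th as above
# (rho and sigma2_e do not enter).
.pairs_sigma <- function(th) {
  bm <- th[[1L]]; bo <- th[[2L]]; phi <- th[[3L]]; s2eo <- th[[6L]]
  vy <- bo^2 * phi + bm^2 * phi + bo * bm * phi + s2eo
  matrix(c(vy, bo * phi + bm * phi / 2, bm * phi + bo * phi / 2,
           bo * phi + bm * phi / 2, phi, phi / 2,
           bm * phi + bo * phi / 2, phi / 2, phi),
         3L, 3L)
}

# Per-record expected Fisher information for the covariance block of a
# zero-mean Gaussian family sigma_fun(th):
# I[i, j] = 0.5 * tr(S^-1 dS_i S^-1 dS_j), derivatives by central
# differences.
.gaussian_info <- function(sigma_fun, th, h_scale = 1e-6) {
  k <- length(th)
  S <- sigma_fun(th)
  Sinv <- solve(S)
  dS <- lapply(seq_len(k), function(i) {
    h <- h_scale * max(1, abs(th[i]))
    tp <- th; tp[i] <- th[i] + h
    tm <- th; tm[i] <- th[i] - h
    (sigma_fun(tp) - sigma_fun(tm)) / (2 * h)
  })
  A <- lapply(dS, function(D) Sinv %*% D)
  I <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      I[i, j] <- I[j, i] <- 0.5 * sum(A[[i]] * t(A[[j]]))
    }
  }
  I
}

# Total expected information over the patterns a design observes.
.design_info <- function(spec, th) {
  I <- matrix(0, length(th), length(th),
              dimnames = list(names(th), names(th)))
  add <- function(I, n, sigma_fun) {
    if (n <= 0) return(I)
    I + n * .gaussian_info(sigma_fun, th)
  }
  if (spec$design %in% c("sem", "combined")) {
    sub <- function(v) function(t) .sem_sigma(c(t, 0, 0, 0))[v, v,
                                                             drop = FALSE]
    I <- add(I, spec$n_both, sub(c("own", "offspring", "snp")))
    I <- add(I, spec$n_own_only, sub(c("own", "snp")))
    I <- add(I, spec$n_off_only, sub(c("offspring", "snp")))
  }
  if (spec$design %in% c("pairs", "combined")) {
    I <- add(I, spec$n_pairs, .pairs_sigma)
  }
  I
}

#' Asymptotic variance of the maternal-effect estimator
#'
#' Computes the expected per-study Fisher information for the covariance
#' parameters under the chosen design, pattern by pattern from the
#' implied moments, sums `n_pattern * I_pattern`, inverts, and returns
#' the `beta_m` diagonal entry.  Parameters without information under
#' the design (e.g. the residual covariance in a pairs-only design) are
#' profiled out of the inversion; if the `beta_m` block is nonetheless
#' singular a Moore-Penrose inverse is used with a warning.
#'
#' @param spec A [power_spec()].
#' @return The asymptotic variance of `beta_m` (phenotype-variance
#'   units per allele^2).
#' @export
asymptotic_var_beta_m <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  th <- .power_theta(spec)
  I <- .design_info(spec, th)
  live <- which(apply(abs(I) > 1e-12, 1L, any))
  I <- I[live, live, drop = FALSE]
  m <- which(names(th)[live] == "beta_m")
  V <- tryCatch(solve(I), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(diag(V))) || V[m, m] <= 0) {
    warning("information matrix singular under this design; ",
            "using a generalized inverse", call. = FALSE)
    V <- MASS::ginv(I)
  }
  unname(V[m, m])
}

#' Power to detect a maternal genetic effect
#'
#' Noncentral chi-square power for the two-sided single-parameter test:
#' the noncentrality parameter is `beta_m^2 / var(beta_m_hat)` with the
#' variance from [asymptotic_var_beta_m()], and power is the probability
#' that a noncentral chi-square(1) exceeds the central critical value at
#' `alpha`.
#'
#' @param spec A [power_spec()].
#' @return Power in `[0, 1]`.
#' @export
#' @examples
#' power_maternal(power_spec("pairs", n_pairs = 50000, q_m = 0.002,
#'                           maf = 0.3))
power_maternal <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  th <- .power_theta(spec)
  if (spec$q_m == 0) return(spec$alpha)
  ncp <- th[["beta_m"]]^2 / asymptotic_var_beta_m(spec)
  crit <- stats::qchisq(1 - spec$alpha, df = 1)
  stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Power curve over the variance explained by the maternal effect
#'
#' Evaluates [power_maternal()] on a grid of `q_m` values for one or
#' more designs, holding all other design quantities fixed.
#'
#' @param q_m Numeric vector of variance-explained values.
#' @param designs Character vector of designs to compare.
#' @param ... Sample sizes and model settings passed to [power_spec()].
#' @return A tibble with columns `design`, `q_m`, `power`.
#' @export
#' @examples
#' power_curve(q_m = c(5e-4, 1e-3), designs = "pairs", n_pairs = 50000)
power_curve <- function(q_m, designs = c("pairs", "sem", "combined"),
                        ...) {
  grid <- tidyr::expand_grid(design = designs, q_m = q_m)
  grid$power <- purrr::map2_dbl(grid$design, grid$q_m, function(d, q) {
    power_maternal(power_spec(design = d, q_m = q, ...))
  })
  grid
}
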