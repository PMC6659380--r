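# Full-information maximum likelihood for the latent-genotype SEM.
#
# Each record contributes the multivariate-normal density of its observed
# subvector under the pattern-marginalized implied moments, so singletons
# (own phenotype only, offspring phenotype only) and dosage-only records
# all inform the fit.  The likelihood depends on the data only through
# per-pattern counts, means and ML covariance matrices, which makes a
# single evaluation O(1) in the sample size.

#' Assign missingness patterns to a family table
#'
#' @param data A data frame with columns `snp`, `own_pheno`,
#'   `offspring_pheno` (an `id` column is carried through if present).
#' @return The input as a tibble with a `pattern` factor column in
#'   `{both, own_only, offspring_only, snp_only}`.  Rows with missing
#'   `snp` are dropped with a message.
#' @export
family_patterns <- function(data) {
  data <- tibble::as_tibble(data)
  req <- c("snp", "own_pheno", "offspring_pheno")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop("family table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n_drop <- sum(is.na(data$snp))
  if (n_drop > 0) {
    message("dropping ", n_drop, " record(s) with missing snp dosage")
    data <- data[!is.na(data$snp), , drop = FALSE]
  }
  has_own <- !is.na(data$own_pheno)
  has_off <- !is.na(data$offspring_pheno)
  pattern <- dplyr::case_when(
    has_own & has_off ~ "both",
    has_own ~ "own_only",
    has_off ~ "offspring_only",
    TRUE ~ "snp_only"
  )
  data$pattern <- factor(pattern, levels = .pattern_levels)
  attr(data, "n_dropped_missing_snp") <- n_drop
  data
}

# Per-pattern sufficient statistics: n, mean vector and ML covariance
# (divisor n) over that pattern's observed variables.
.family_stats <- function(data) {
  cols <- c(own = "own_pheno", offspring = "offspring_pheno", snp = "snp")
  stats <- list()
  for (p in .pattern_levels) {
    idx <- which(data$pattern == p)
    v <- .pattern_vars[[p]]
    if (!length(idx)) {
      stats[[p]] <- list(n = 0L)
      next
    }
    x <- as.matrix(data[idx, cols[v], drop = FALSE])
    colnames(x) <- v
    n <- nrow(x)
    m <- colMeans(x)
    xc <- sweep(x, 2L, m)
    stats[[p]] <- list(n = n, mean = m, S = crossprod(xc) / n)
  }
  stats
}

# Log-likelihood from sufficient statistics; th in .sem_par_names order.
# Returns -Inf outside the domain so optimizers can step freely.
.sem_loglik_stats <- function(th, stats) {
  if (th[[3L]] <= 0 || th[[5L]] <= 0 || th[[6L]] <= 0) return(-Inf)
  sigma <- .sem_sigma(th)
  mu <- .sem_mu(th)
  ll <- 0
  for (p in names(stats)) {
    st <- stats[[p]]
    if (st$n == 0L) next
    v <- .pattern_vars[[p]]
    S <- sigma[v, v, drop = FALSE]
    R <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(R)) return(-Inf)
    Sinv <- chol2inv(R)
    d <- st$mean - mu[v]
    ll <- ll - 0.5 * st$n *
      (length(v) * log(2 * pi) + 2 * sum(log(diag(R))) +
         sum(Sinv * st$S) + drop(crossprod(d, Sinv %*% d)))
  }
  ll
}

#' Full-information log-likelihood of a family table
#'
#' Sums, over records, the multivariate-normal log-density of each
#' record's observed subvector under the pattern-marginalized moments of
#' [implied_moments()].  Dosage-only records contribute through the
#' univariate dosage density and therefore inform only `phi` and
#' `mu_snp`.
#'
#' @param params A [sem_params()] object.
#' @param data A family table (see [family_patterns()]); the `pattern`
#'   column is derived if absent.
#' @return The log-likelihood (scalar).
#' @export
fiml_loglik <- function(params, data) {
  stopifnot(inherits(params, "sem_params"))
  validate_sem_params(params)
  if (!"pattern" %in% names(data)) data <- family_patterns(data)
  if (nrow(data) == 0L) stop("empty family table", call. = FALSE)
  th <- unlist(params)[.sem_par_names]
  .sem_loglik_stats(th, .family_stats(data))
}

# Unconstrained <-> natural parameterization.  Variances on the log
# scale; rho through the Fisher transform of its residual correlation.
.sem_free_to_nat <- function(fr) {
  s2e <- exp(fr[[5L]]); s2eo <- exp(fr[[6L]])
  c(fr[[1L]], fr[[2L]], exp(fr[[3L]]),
    tanh(fr[[4L]]) * sqrt(s2e * s2eo), s2e, s2eo,
    fr[[7L]], fr[[8L]], fr[[9L]])
}

.sem_nat_to_free <- function(th) {
  r <- th[[4L]] / sqrt(th[[5L]] * th[[6L]])
  r <- max(min(r, 0.99), -0.99)
  c(th[[1L]], th[[2L]], log(th[[3L]]), atanh(r),
    log(th[[5L]]), log(th[[6L]]), th[[7L]], th[[8L]], th[[9L]])
}

# Central-difference gradient and Hessian (step scaled per coordinate).
.num_grad <- function(f, x, h_scale = 1e-6) {
  vapply(seq_along(x), function(i) {
    h <- h_scale * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

.num_hessian <- function(f, x, h_scale = 1e-5) {
  k <- length(x)
  h <- h_scale * pmax(1, abs(x))
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    xp <- x; xp[i] <- x[i] + h[i]
    xm <- x; xm[i] <- x[i] - h[i]
    H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
    if (i < k) {
      for (j in seq((i + 1L), k)) {
        xpp <- x; xpp[i] <- x[i] + h[i]; xpp[j] <- x[j] + h[j]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[i] <- x[i] - h[i]; xmm[j] <- x[j] - h[j]
        H[i, j] <- H[j, i] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

# Core optimizer working from sufficient statistics.  start: natural
# parameter vector.  Returns the pieces of a sem_fit.
.fit_sem_stats <- function(stats, start, se = TRUE,
                           grad_tol = 1e-6, maxit = 500L) {
  nll_free <- function(fr) -.sem_loglik_stats(.sem_free_to_nat(fr), stats)
  fr0 <- .sem_nat_to_free(start)
  opt <- stats::optim(fr0, nll_free, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  th <- .sem_free_to_nat(opt$par)
  names(th) <- .sem_par_names
  n_tot <- sum(vapply(stats, `[[`, integer(1), "n"))
  # Honest convergence: per-record average score near zero at the optimum.
  g <- .num_grad(nll_free, opt$par)
  converged <- opt$convergence == 0L && sqrt(sum(g^2)) / n_tot < grad_tol
  vcov <- matrix(NA_real_, 9L, 9L, dimnames = list(.sem_par_names,
                                                   .sem_par_names))
  if (se) {
    nll_nat <- function(x) -.sem_loglik_stats(x, stats)
    H <- .num_hessian(nll_nat, th)
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V) > 0)) {
      vcov[] <- V
    } else {
      # Parameters the observed patterns carry no information on (e.g.
      # rho without any dual-phenotype record) make the full observed
      # information singular; invert the identified block and leave the
      # rest NA.
      live <- which(abs(diag(H)) > 1e-8 * max(abs(diag(H)), 1e-300))
      Vs <- tryCatch(solve(H[live, live, drop = FALSE]),
                     error = function(e) NULL)
      if (!is.null(Vs) && all(diag(Vs) > 0)) {
        vcov[live, live] <- Vs
        warning("observed information singular; standard errors ",
                "reported for the identified parameter block only",
                call. = FALSE)
      } else {
        warning("observed information not invertible; standard errors ",
                "unavailable", call. = FALSE)
      }
    }
  }
  list(theta = th, vcov = vcov, loglik = -opt$value, converged = converged)
}

# Starting values from the two unconditional regressions (slopes computed
# from per-pattern sufficient statistics), the closed-form inverse map,
# sample variances and zero residual covariance.
.sem_start <- function(stats) {
  pool <- function(patterns, var) {
    n <- 0; sxy <- 0; sxx <- 0
    for (p in patterns) {
      st <- stats[[p]]
      if (st$n == 0L) next
      n <- n + st$n
      sxx <- sxx + st$n * st$S["snp", "snp"]
      sxy <- sxy + st$n * st$S[var, "snp"]
    }
    if (n == 0L || sxx <= 0) return(0)
    sxy / sxx
  }
  b_own <- pool(c("both", "own_only"), "own")
  b_off <- pool(c("both", "offspring_only"), "offspring")
  cb <- invert_unconditional(b_own, b_off)
  wmean <- function(patterns, var, what = "mean") {
    n <- 0; acc <- 0
    for (p in patterns) {
      st <- stats[[p]]
      if (st$n == 0L) next
      n <- n + st$n
      acc <- acc + st$n * (if (what == "mean") st$mean[var]
                           else st$S[var, var])
    }
    if (n == 0L) return(NA_real_)
    acc / n
  }
  phi <- wmean(.pattern_levels, "snp", "var")
  v_own <- wmean(c("both", "own_only"), "own", "var")
  v_off <- wmean(c("both", "offspring_only"), "offspring", "var")
  s2e <- max(v_own - phi * b_own^2, 0.1 * v_own, 1e-4)
  s2eo <- max(v_off - phi * b_off^2, 0.1 * v_off, 1e-4)
  c(cb$beta_m, cb$beta_o, phi, 0, s2e, s2eo,
    wmean(c("both", "own_only"), "own"),
    wmean(c("both", "offspring_only"), "offspring"),
    wmean(.pattern_levels, "snp"))
}

.new_sem_fit <- function(core, stats, n_dropped = 0L) {
  th <- core$theta
  params <- sem_params(beta_m = th[["beta_m"]], beta_o = th[["beta_o"]],
                       phi = th[["phi"]], rho = th[["rho"]],
                       sigma2_e = th[["sigma2_e"]],
                       sigma2_eo = th[["sigma2_eo"]],
                       mu_bw = th[["mu_bw"]], mu_bwo = th[["mu_bwo"]],
                       mu_snp = th[["mu_snp"]])
  se <- sqrt(diag(core$vcov))
  structure(list(params = params,
                 estimates = th,
                 se = se,
                 vcov = core$vcov,
                 loglik = core$loglik,
                 converged = core$converged,
                 n_by_pattern = vapply(stats, `[[`, integer(1), "n"),
                 n_dropped_missing_snp = n_dropped),
            class = "sem_fit")
}

#' Fit the latent-genotype SEM by full-information maximum likelihood
#'
#' Maximizes [fiml_loglik()] over the nine free parameters.  Variances
#' are searched on the log scale and the residual covariance through the
#' Fisher transform of its correlation, so the optimization is
#' unconstrained and the implied covariance matrix stays positive
#' definite.  Standard errors come from the inverse of the observed
#' information, evaluated by central finite differences at the optimum.
#'
#' @param data A family table: one row per genotyped woman with columns
#'   `snp` (allele dosage, possibly fractional), `own_pheno` and
#'   `offspring_pheno` (either may be `NA`).  Rows with missing `snp`
#'   are dropped with a message.
#' @param se Compute standard errors (a 9x9 numerical Hessian)?  Skipping
#'   them speeds up large per-SNP scans.
#' @param start Optional named vector of starting values in natural
#'   parameterization; defaults to closed-form starts from the two
#'   unconditional regressions.
#' @param grad_tol Convergence declared when the per-record average score
#'   norm falls below this value at the optimum.
#' @param maxit Maximum BFGS iterations.
#' @return A `sem_fit` object; see [tidy.sem_fit()] and
#'   [glance.sem_fit()] for tibble views.
#' @export
#' @examples
#' sim <- simulate_families(n_both = 2000, maf = 0.3, beta_m = 0.1,
#'                          beta_o = -0.1, rho = 0.2, seed = 1)
#' fit <- fit_sem(sim$families)
#' generics::tidy(fit)
fit_sem <- function(data, se = TRUE, start = NULL,
                    grad_tol = 1e-6, maxit = 500L) {
  if (!"pattern" %in% names(data)) data <- family_patterns(data)
  n_dropped <- attr(data, "n_dropped_missing_snp") %||% 0L
  if (nrow(data) == 0L) stop("empty family table", call. = FALSE)
  if (!any(!is.na(data$own_pheno))) {
    stop("need at least one record with own_pheno", call. = FALSE)
  }
  if (!any(!is.na(data$offspring_pheno))) {
    stop("need at least one record with offspring_pheno", call. = FALSE)
  }
  if (stats::var(data$snp) < 1e-10) {
    stop("degenerate input: snp dosage is (near) constant, the SEM is not ",
         "identified at a monomorphic locus", call. = FALSE)
  }
  st <- .family_stats(data)
  if (is.null(start)) start <- .sem_start(st)
  core <- .fit_sem_stats(st, start, se = se,
                         grad_tol = grad_tol, maxit = maxit)
  .new_sem_fit(core, st, n_dropped)
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("<sem_fit>  logLik:", format(x$loglik),
      " converged:", x$converged, "\n")
  cat("records:", paste(names(x$n_by_pattern), x$n_by_pattern,
                        sep = "=", collapse = ", "), "\n")
  est <- cbind(estimate = x$estimates, se = x$se)
  print(round(est, 5))
  invisible(x)
}

#' Conditional regression of offspring phenotype in mother-offspring pairs
#'
#' Ordinary least squares of the offspring phenotype on the offspring and
#' maternal allele dosages jointly, `Y = alpha + beta_o * oSNP +
#' beta_m * mSNP + e`, which separates the maternal from the offspring
#' genetic effect in genotyped pairs.  When both dosages are hard calls
#' the pairs are screened for Mendelian consistency (`|oSNP - mSNP| <= 1`);
#' violations are reported but retained, since imputed dosages need not be
#' consistent.
#'
#' @param data A data frame with columns `offspring_pheno`,
#'   `offspring_snp`, `maternal_snp`.
#' @return A tibble with one row per term (`intercept`, `beta_o`,
#'   `beta_m`) and columns `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
#' @examples
#' sim <- simulate_families(n_pairs = 5000, maf = 0.3, beta_m = 0.1,
#'                          beta_o = -0.1, seed = 1)
#' conditional_regression(sim$pairs)
conditional_regression <- function(data) {
  req <- c("offspring_pheno", "offspring_snp", "maternal_snp")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop("pair table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  data <- tibble::as_tibble(data)[req]
  data <- data[stats::complete.cases(data), , drop = FALSE]
  if (nrow(data) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  hard <- all(data$offspring_snp == round(data$offspring_snp)) &&
    all(data$maternal_snp == round(data$maternal_snp))
  if (hard) {
    n_bad <- sum(abs(data$offspring_snp - data$maternal_snp) > 1)
    if (n_bad > 0) {
      warning(n_bad, " pair(s) violate Mendelian consistency ",
              "(|offspring_snp - maternal_snp| > 1); retained", call. = FALSE)
    }
  }
  X <- cbind(1, data$offspring_snp, data$maternal_snp)
  if (qr(X)$rank < 3L) {
    stop("collinear design: offspring and maternal dosages do not separate ",
         "(rank-deficient model matrix)", call. = FALSE)
  }
  fit <- stats::lm(offspring_pheno ~ offspring_snp + maternal_snp,
                   data = data)
  sm <- summary(fit)$coefficients
  tibble::tibble(term = c("intercept", "beta_o", "beta_m"),
                 estimate = unname(sm[, 1]), std.error = unname(sm[, 2]),
                 statistic = unname(sm[, 3]), p.value = unname(sm[, 4]))
}

#' Per-SNP SEM fits across a dosage matrix
#'
#' Fits the latent-genotype SEM independently at each locus of a cohort in
#' which every woman has the same two phenotypes and a dosage per SNP.
#' Evaluation works from per-pattern sufficient statistics, so the cost
#' per SNP is independent of the sample size.  Unconditional slopes (own
#' phenotype on own dosage; offspring phenotype on maternal dosage) and
#' their classical standard errors are returned alongside for
#' adjusted-versus-unadjusted comparisons.
#'
#' @param phenotypes A data frame with columns `own_pheno` and
#'   `offspring_pheno` (either may be `NA` per row).
#' @param genotypes A numeric matrix, rows matching `phenotypes`, one
#'   column per SNP (column names become `snp_id`).
#' @param se Compute per-SNP standard errors?
#' @return A tibble with one row per SNP: `snp_id`, `beta_m`, `se_m`,
#'   `p_m`, `beta_o`, `se_o`, `p_o`, `phi`, `rho`, `loglik`, `converged`,
#'   pattern counts, and unconditional `b_own`, `se_own`, `b_off`,
#'   `se_off`.
#' @export
fit_sem_loci <- function(phenotypes, genotypes, se = TRUE) {
  genotypes <- as.matrix(genotypes)
  stopifnot(nrow(phenotypes) == nrow(genotypes))
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- paste0("snp_", seq_len(ncol(genotypes)))
  res <- purrr::map(seq_len(ncol(genotypes)), function(j) {
    fam <- tibble::tibble(snp = genotypes[, j],
                          own_pheno = phenotypes$own_pheno,
                          offspring_pheno = phenotypes$offspring_pheno)
    fit <- tryCatch(fit_sem(fam, se = se), error = function(e) NULL)
    uncond <- .uncond_slopes(fam)
    if (is.null(fit)) {
      return(tibble::tibble(snp_id = ids[j], beta_m = NA_real_,
                            se_m = NA_real_, p_m = NA_real_,
                            beta_o = NA_real_, se_o = NA_real_,
                            p_o = NA_real_, phi = NA_real_, rho = NA_real_,
                            loglik = NA_real_, converged = FALSE,
                            n_both = NA_integer_, n_own_only = NA_integer_,
                            n_off_only = NA_integer_, !!!uncond))
    }
    z_m <- fit$estimates[["beta_m"]] / fit$se[["beta_m"]]
    z_o <- fit$estimates[["beta_o"]] / fit$se[["beta_o"]]
    tibble::tibble(snp_id = ids[j],
                   beta_m = fit$estimates[["beta_m"]],
                   se_m = fit$se[["beta_m"]],
                   p_m = 2 * stats::pnorm(-abs(z_m)),
                   beta_o = fit$estimates[["beta_o"]],
                   se_o = fit$se[["beta_o"]],
                   p_o = 2 * stats::pnorm(-abs(z_o)),
                   phi = fit$estimates[["phi"]],
                   rho = fit$estimates[["rho"]],
                   loglik = fit$loglik,
                   converged = fit$converged,
                   n_both = fit$n_by_pattern[["both"]],
                   n_own_only = fit$n_by_pattern[["own_only"]],
                   n_off_only = fit$n_by_pattern[["offspring_only"]],
                   !!!uncond)
  })
  dplyr::bind_rows(res)
}

# Simple-regression slopes of each phenotype on the dosage with classical
# standard errors, from the rows where the phenotype is observed.
.uncond_slopes <- function(fam) {
  slope <- function(y, x) {
    ok <- !is.na(y) & !is.na(x)
    y <- y[ok]; x <- x[ok]
    n <- length(y)
    if (n < 3L || stats::var(x) < 1e-12) {
      return(c(NA_real_, NA_real_))
    }
    vx <- stats::var(x)
    b <- stats::cov(x, y) / vx
    res <- (y - mean(y)) - b * (x - mean(x))
    s2 <- sum(res^2) / (n - 2)
    c(b, sqrt(s2 / ((n - 1) * vx)))
  }
  own <- slope(fam$own_pheno, fam$snp)
  off <- slope(fam$offspring_pheno, fam$snp)
  list(b_own = own[1], se_own = own[2], b_off = off[1], se_off = off[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
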