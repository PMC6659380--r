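# Two-sample Mendelian randomization on partitioned SNP effects.
#
# The maternal arm divides the conditional maternal SNP-outcome effect by
# the SNP-exposure effect (Wald ratio) and meta-analyses the ratios; the
# offspring arm does the same with the conditional offspring effect.
# Using the unconditional slopes instead reproduces the biased
# "unadjusted" analysis in which maternal and offspring effects mix
# through the transmitted genotype.

.palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonize exposure and partitioned-outcome summary data
#'
#' Joins the exposure GWAS to the per-SNP partitioned outcome effects by
#' `snp_id`, flips the sign of outcome effects where the effect alleles
#' are swapped relative to the exposure, and excludes SNPs that cannot be
#' used as instruments: strand-ambiguous palindromic SNPs (A/T or C/G
#' with minor allele frequency above `palindromic_maf`), SNPs below the
#' minor-allele-frequency floor `maf_min`, and SNPs whose outcome fit did
#' not converge.  Every exclusion is logged with a reason.
#'
#' @param exposure GWAS tibble: `snp_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`.
#' @param outcome Partitioned outcome tibble (from [fit_sem_loci()] or
#'   [fit_sem_summary()]): `snp_id`, `beta_m`, `se_m`, `beta_o`, `se_o`,
#'   optionally allele columns, `converged`, and unconditional `b_own`,
#'   `se_own`, `b_off`, `se_off`.  Without allele columns the outcome is
#'   assumed already aligned to the exposure effect allele.
#' @param maf_min Minimum minor allele frequency (judged from the
#'   exposure `eaf`).
#' @param palindromic_maf Palindromic SNPs whose MAF exceeds this value
#'   are dropped as strand-ambiguous.
#' @return A tibble of harmonized instruments with columns `snp_id`,
#'   `beta_exp`, `se_exp`, `beta_out_m`, `se_out_m`, `beta_out_o`,
#'   `se_out_o` (plus `b_own`/`b_off` columns when present) and
#'   `flipped`.  Exclusions (tibble `snp_id`, `reason`) are attached as
#'   attribute `"exclusions"`.
#' @export
harmonize_instruments <- function(exposure, outcome, maf_min = 1e-3,
                                  palindromic_maf = 0.42) {
  for (nm in c("snp_id", "beta", "se")) {
    if (!nm %in% names(exposure)) {
      stop("exposure GWAS needs columns snp_id, beta, se", call. = FALSE)
    }
  }
  if (!all(c("snp_id", "beta_m", "se_m", "beta_o", "se_o") %in%
             names(outcome))) {
    stop("outcome table needs columns snp_id, beta_m, se_m, beta_o, se_o",
         call. = FALSE)
  }
  exposure <- tibble::as_tibble(exposure)
  outcome <- tibble::as_tibble(outcome)
  excl <- list()
  drop_snps <- function(ids, reason) {
    if (length(ids)) {
      excl[[length(excl) + 1L]] <<- tibble::tibble(snp_id = ids,
                                                   reason = reason)
    }
  }
  missing_out <- setdiff(exposure$snp_id, outcome$snp_id)
  drop_snps(missing_out, "missing_in_outcome")
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  exp <- exposure[match(shared, exposure$snp_id), ]
  out <- outcome[match(shared, outcome$snp_id), ]
  keep <- rep(TRUE, length(shared))
  if ("eaf" %in% names(exp)) {
    maf <- pmin(exp$eaf, 1 - exp$eaf)
    low <- keep & !is.na(maf) & maf < maf_min
    drop_snps(exp$snp_id[low], "maf_below_threshold")
    keep <- keep & !low
    if (all(c("effect_allele", "other_allele") %in% names(exp))) {
      pal <- keep & .palindromic(exp$effect_allele, exp$other_allele) &
        !is.na(maf) & maf > palindromic_maf
      drop_snps(exp$snp_id[pal], "palindromic_ambiguous")
      keep <- keep & !pal
    }
  }
  if ("converged" %in% names(out)) {
    nc <- keep & (!out$converged | is.na(out$converged))
    drop_snps(exp$snp_id[nc], "not_converged")
    keep <- keep & !nc
  }
  exp <- exp[keep, ]
  out <- out[keep, ]
  out <- .align_alleles(exp, out)
  res <- tibble::tibble(snp_id = exp$snp_id,
                        beta_exp = exp$beta, se_exp = exp$se,
                        beta_out_m = out$beta_m, se_out_m = out$se_m,
                        beta_out_o = out$beta_o, se_out_o = out$se_o)
  for (cc in c("b_own", "se_own", "b_off", "se_off")) {
    if (cc %in% names(out)) res[[cc]] <- out[[cc]]
  }
  res$flipped <- out$flipped
  exclusions <- dplyr::bind_rows(excl)
  if (nrow(res) == 0L) {
    stop("no instruments survived harmonization (",
         nrow(exclusions), " exclusion(s))", call. = FALSE)
  }
  if (nrow(exclusions)) {
    message("excluded ", nrow(exclusions), " SNP(s): ",
            paste(sprintf("%s=%d", names(table(exclusions$reason)),
                          table(exclusions$reason)), collapse = ", "))
  } else {
    exclusions <- tibble::tibble(snp_id = character(), reason = character())
  }
  attr(res, "exclusions") <- exclusions
  res
}

#' Per-SNP Wald ratio causal estimate
#'
#' `estimate = beta_out / beta_exp` with first-order delta-method
#' standard error `se_out / |beta_exp|` (the exposure uncertainty is
#' ignored unless `second_order = TRUE`).  Vectorised.
#'
#' @param beta_out,se_out SNP-outcome effect and its SE.
#' @param beta_exp SNP-exposure effect (must be nonzero).
#' @param se_exp SNP-exposure SE, used only when `second_order = TRUE`.
#' @param second_order Add the exposure-uncertainty term
#'   `beta_out^2 * se_exp^2 / beta_exp^4` to the variance.
#' @return A tibble with columns `estimate` and `se`.
#' @export
#' @examples
#' wald_ratio(0.05, 0.01, 0.10)
wald_ratio <- function(beta_out, se_out, beta_exp, se_exp = NULL,
                       second_order = FALSE) {
  if (any(beta_exp == 0)) {
    stop("beta_exp must be nonzero for a Wald ratio", call. = FALSE)
  }
  est <- beta_out / beta_exp
  v <- se_out^2 / beta_exp^2
  if (second_order) {
    if (is.null(se_exp)) {
      stop("second_order = TRUE requires se_exp", call. = FALSE)
    }
    v <- v + beta_out^2 * se_exp^2 / beta_exp^4
  }
  tibble::tibble(estimate = est, se = sqrt(v))
}

.new_mr_result <- function(method, estimate, se, p, q = NA_real_,
                           q_df = NA_real_, egger_intercept = NA_real_,
                           egger_intercept_se = NA_real_,
                           egger_intercept_p = NA_real_, n_snps) {
  structure(tibble::tibble(method = method, estimate = estimate, se = se,
                           p = p, q_statistic = q, q_df = q_df,
                           egger_intercept = egger_intercept,
                           egger_intercept_se = egger_intercept_se,
                           egger_intercept_p = egger_intercept_p,
                           n_snps = n_snps),
            class = c("mr_result", class(tibble::tibble())))
}

#' Inverse-variance-weighted meta-analysis of Wald ratios
#'
#' Combines per-SNP ratios with weights `1 / se^2`.  The fixed-effect
#' standard error is `(sum w)^(-1/2)`; the random-effects (multiplicative
#' overdispersion) standard error inflates it by
#' `max(1, sqrt(Q / (k - 1)))`, so heterogeneity can widen but never
#' shrink the interval.  Cochran's Q and its degrees of freedom are
#' reported.
#'
#' @param ratios A data frame with columns `estimate` and `se` (e.g.
#'   from [wald_ratio()]).
#' @param random Use the random-effects standard error (default)?
#' @return A one-row `mr_result` tibble.
#' @export
#' @examples
#' mr_ivw(tibble::tibble(estimate = c(0.5, 0.3), se = c(0.1, 0.1)))
mr_ivw <- function(ratios, random = TRUE) {
  if (nrow(ratios) < 1L) stop("no instruments", call. = FALSE)
  stopifnot(all(c("estimate", "se") %in% names(ratios)))
  if (any(ratios$se <= 0)) stop("ratio SEs must be positive", call. = FALSE)
  w <- 1 / ratios$se^2
  k <- nrow(ratios)
  est <- sum(w * ratios$estimate) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  q <- sum(w * (ratios$estimate - est)^2)
  se <- se_fixed
  if (random && k > 1L) se <- se_fixed * max(1, sqrt(q / (k - 1)))
  p <- 2 * stats::pnorm(-abs(est / se))
  .new_mr_result("ivw", est, se, p, q = q, q_df = k - 1, n_snps = k)
}

#' MR-Egger regression
#'
#' Weighted least squares of the SNP-outcome effects on the SNP-exposure
#' effects with a free intercept, weights `1 / se_out^2`, after orienting
#' every SNP so its exposure effect is non-negative.  The slope estimates
#' the causal effect allowing all instruments to have (InSIDE-compliant)
#' directional pleiotropy, which the intercept captures.  Standard errors
#' are inflated by `max(1, sqrt(Q / (k - 2)))`; p-values use t with
#' `k - 2` degrees of freedom.
#'
#' @param data A data frame with columns `beta_exp`, `beta_out`,
#'   `se_out`.
#' @return A one-row `mr_result` tibble including the intercept
#'   diagnostics.
#' @export
mr_egger <- function(data) {
  stopifnot(all(c("beta_exp", "beta_out", "se_out") %in% names(data)))
  k <- nrow(data)
  if (k < 3L) stop("MR-Egger needs at least 3 instruments", call. = FALSE)
  flip <- sign(data$beta_exp)
  flip[flip == 0] <- 1
  bx <- data$beta_exp * flip
  by <- data$beta_out * flip
  if (max(bx) - min(bx) < 1e-12) {
    stop("slope unidentified: no spread in |beta_exp|", call. = FALSE)
  }
  w <- 1 / data$se_out^2
  fit <- stats::lm.wfit(cbind(1, bx), by, w)
  cf <- fit$coefficients
  resid <- by - cf[1] - cf[2] * bx
  q <- sum(w * resid^2)
  scale <- max(1, sqrt(q / (k - 2)))
  XtWX <- crossprod(cbind(1, bx) * sqrt(w))
  V <- solve(XtWX) * scale^2
  se_b <- sqrt(V[2, 2]); se_a <- sqrt(V[1, 1])
  p_b <- 2 * stats::pt(-abs(cf[2] / se_b), df = k - 2)
  p_a <- 2 * stats::pt(-abs(cf[1] / se_a), df = k - 2)
  .new_mr_result("egger", unname(cf[2]), se_b, p_b, q = q, q_df = k - 2,
                 egger_intercept = unname(cf[1]), egger_intercept_se = se_a,
                 egger_intercept_p = p_a, n_snps = k)
}

# Weighted median of x with weights w (interpolated percentile
# definition); used both for the estimate and inside the bootstrap.
.weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (p[1] >= 0.5) return(x[1])
  if (p[length(p)] <= 0.5) return(x[length(x)])
  stats::approx(p, x, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR estimator
#'
#' The weighted median of the per-SNP Wald ratios with weights
#' `1 / se^2`, consistent when at least half the weight comes from valid
#' instruments.  The standard error is obtained by parametric bootstrap:
#' each ratio is redrawn from `N(estimate_i, se_i^2)` and the weighted
#' median recomputed.
#'
#' @param ratios A data frame with columns `estimate` and `se`.
#' @param n_boot Number of bootstrap draws.
#' @param seed Seed for the bootstrap.
#' @return A one-row `mr_result` tibble.
#' @export
mr_weighted_median <- function(ratios, n_boot = 5000, seed = 1) {
  stopifnot(all(c("estimate", "se") %in% names(ratios)))
  k <- nrow(ratios)
  if (k < 3L) {
    stop("weighted-median MR needs at least 3 instruments", call. = FALSE)
  }
  w <- 1 / ratios$se^2
  est <- .weighted_median(ratios$estimate, w)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    .weighted_median(stats::rnorm(k, ratios$estimate, ratios$se), w)
  }, numeric(1))
  se <- stats::sd(boot)
  p <- 2 * stats::pnorm(-abs(est / se))
  .new_mr_result("wmedian", est, se, p, n_snps = k)
}

#' Full MR grid over arms, adjustments and estimators
#'
#' Runs the maternal and offspring arms of a two-sample MR study with
#' both the SEM-partitioned (adjusted) and the unconditional
#' (unadjusted) SNP-outcome effects, through IVW, MR-Egger and the
#' weighted median.  The maternal arm uses `beta_out_m` (adjusted) or
#' the offspring-phenotype-on-maternal-dosage slope `b_off`
#' (unadjusted); the offspring arm uses `beta_out_o` or the
#' own-phenotype slope `b_own`.  When fewer than three instruments are
#' available the Egger and weighted-median rows are emitted with missing
#' estimates and a note.
#'
#' @param exposure Exposure GWAS tibble (see
#'   [harmonize_instruments()]).
#' @param outcome Partitioned outcome tibble; include `b_own`, `se_own`,
#'   `b_off`, `se_off` columns for the unadjusted arm (present in
#'   [fit_sem_loci()] and [fit_sem_summary()] output).
#' @param maf_min,palindromic_maf Passed to
#'   [harmonize_instruments()].
#' @param n_boot,seed Weighted-median bootstrap settings.
#' @return A long tibble with columns `arm` (maternal/offspring),
#'   `adjustment` (sem/unadjusted), `method`, `estimate`, `se`, `p`,
#'   `q_statistic`, `q_df`, `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_p`, `n_snps`, `note`; the harmonized instrument
#'   set is attached as attribute `"instruments"`.
#' @export
mr_pipeline <- function(exposure, outcome, maf_min = 1e-3,
                        palindromic_maf = 0.42, n_boot = 5000, seed = 1) {
  h <- harmonize_instruments(exposure, outcome, maf_min = maf_min,
                             palindromic_maf = palindromic_maf)
  arms <- list(
    list(arm = "maternal", adjustment = "sem",
         beta = h$beta_out_m, se = h$se_out_m),
    list(arm = "offspring", adjustment = "sem",
         beta = h$beta_out_o, se = h$se_out_o))
  if (all(c("b_off", "se_off", "b_own", "se_own") %in% names(h))) {
    arms <- c(arms, list(
      list(arm = "maternal", adjustment = "unadjusted",
           beta = h$b_off, se = h$se_off),
      list(arm = "offspring", adjustment = "unadjusted",
           beta = h$b_own, se = h$se_own)))
  } else {
    message("outcome table has no unconditional slopes; ",
            "unadjusted arm skipped")
  }
  rows <- purrr::map(arms, function(a) {
    ok <- !is.na(a$beta) & !is.na(a$se) & a$se > 0
    ratios <- wald_ratio(a$beta[ok], a$se[ok], h$beta_exp[ok])
    k <- sum(ok)
    res <- list(dplyr::mutate(mr_ivw(ratios), note = NA_character_))
    if (k >= 3L) {
      eg <- mr_egger(tibble::tibble(beta_exp = h$beta_exp[ok],
                                    beta_out = a$beta[ok],
                                    se_out = a$se[ok]))
      wm <- mr_weighted_median(ratios, n_boot = n_boot, seed = seed)
      res <- c(res, list(dplyr::mutate(eg, note = NA_character_),
                         dplyr::mutate(wm, note = NA_character_)))
    } else {
      res <- c(res, list(
        .new_mr_result(c("egger", "wmedian"), NA_real_, NA_real_,
                       NA_real_, n_snps = k) |>
          dplyr::mutate(note = "insufficient_instruments")))
    }
    dplyr::bind_rows(res) |>
      dplyr::mutate(arm = a$arm, adjustment = a$adjustment,
                    .before = 1L)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "instruments") <- h
  class(out) <- c("mr_grid", class(out))
  out
}
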