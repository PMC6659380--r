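# Conditional maternal/offspring effects from two unconditional GWAS.
#
# The two unconditional slopes identify the two conditional effects
# exactly (see invert_unconditional()); the only subtlety is the sampling
# covariance between the two GWAS betas when the same individuals
# contribute to both.  That covariance per SNP is intercept * se1 * se2,
# where the intercept is the cross-trait LD score regression intercept
# rho_p * N_s / sqrt(N1 * N2) -- supplied when the overlap is known, or
# estimated from genome-wide z-scores when it is not.

#' Expected cross-trait LDSC intercept for a known overlap
#'
#' @param n_overlap Number of samples in both GWAS.
#' @param n1,n2 GWAS sample sizes.
#' @param rho_p Phenotypic correlation between the two traits in the
#'   overlapping samples.
#' @return The intercept `rho_p * n_overlap / sqrt(n1 * n2)`.
#' @export
overlap_intercept <- function(n_overlap, n1, n2, rho_p) {
  rho_p * n_overlap / sqrt(n1 * n2)
}

#' Estimate GWAS sample overlap by cross-trait LD score regression
#'
#' Regresses the per-SNP product of z-scores from the two GWAS on the LD
#' score.  The LD-dependent slope absorbs the shared polygenic signal;
#' the intercept equals the sampling correlation between the two sets of
#' betas, `rho_p * N_s / sqrt(N1 * N2)`, from which the overlapping
#' sample count is recovered given an assumed phenotypic correlation
#' `rho_p`.  Weighted least squares with two-pass 1/LD weighting,
#' z-score products winsorized at +/-100, and a block-jackknife standard
#' error for the intercept.
#'
#' @param data A data frame with one row per SNP and columns `z_own`,
#'   `z_off`, `ld_score` (e.g. from [simulate_gwas_zscores()] or a join
#'   of real summary files onto an LD-score table).
#' @param n1,n2 GWAS sample sizes.
#' @param m Number of SNPs used to scale the LD-dependent term; defaults
#'   to `nrow(data)`.
#' @param rho_p Assumed phenotypic correlation between the two traits.
#' @param n_blocks Number of contiguous jackknife blocks.
#' @param winsor Bound applied to `|z_own * z_off|`.
#' @return A one-row tibble: `intercept`, `se_intercept`, `slope`
#'   (estimated genetic correlation scale), `se_slope`, `n_overlap`,
#'   `rho_p`, `n_snps`.  The intercept is clamped to
#'   `[-1, 1]` and `n_overlap` to `[0, min(n1, n2)]` (with a warning
#'   when clamping binds).
#' @export
ldsc_overlap <- function(data, n1, n2, m = nrow(data), rho_p = 0.23,
                         n_blocks = 200, winsor = 100) {
  req <- c("z_own", "z_off", "ld_score")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop("ldsc_overlap input is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(data)[req]
  data <- data[stats::complete.cases(data), , drop = FALSE]
  if (nrow(data) < 200L) {
    stop("need at least 200 SNPs with z-scores and LD scores; got ",
         nrow(data), call. = FALSE)
  }
  y <- pmin(pmax(data$z_own * data$z_off, -winsor), winsor)
  x <- sqrt(n1 * n2) * data$ld_score / m
  ld <- pmax(data$ld_score, 1)
  wls <- function(keep, w) {
    fit <- stats::lm.wfit(cbind(1, x[keep]), y[keep], w[keep])
    fit$coefficients
  }
  all_idx <- rep(TRUE, nrow(data))
  w1 <- 1 / ld
  pass1 <- wls(all_idx, w1)
  w2 <- 1 / (ld * (1 + abs(pass1[1])))
  est <- wls(all_idx, w2)
  # Delete-one-block jackknife over SNP order for the intercept SE.
  n_blocks <- min(n_blocks, nrow(data) %/% 2L)
  block <- cut(seq_len(nrow(data)), n_blocks, labels = FALSE)
  jk <- vapply(seq_len(n_blocks),
               function(b) wls(block != b, w2), numeric(2))
  jk_se <- sqrt((n_blocks - 1) / n_blocks *
                  rowSums((jk - rowMeans(jk))^2))
  se_int <- jk_se[1]
  intercept <- est[1]
  if (abs(intercept) > 1) {
    warning("LDSC intercept ", signif(intercept, 3),
            " clamped to [-1, 1]", call. = FALSE)
    intercept <- sign(intercept)
  }
  n_overlap <- NA_real_
  if (rho_p != 0) {
    n_overlap <- intercept * sqrt(n1 * n2) / rho_p
    if (n_overlap < 0) {
      warning("negative implied sample overlap clamped to 0", call. = FALSE)
      n_overlap <- 0
    }
    n_overlap <- min(n_overlap, min(n1, n2))
  }
  tibble::tibble(intercept = unname(intercept),
                 se_intercept = se_int,
                 slope = unname(est[2]),
                 se_slope = jk_se[2],
                 n_overlap = n_overlap,
                 rho_p = rho_p,
                 n_snps = nrow(data))
}

# Align the second GWAS to the first's effect alleles: flips beta sign
# and eaf where alleles are swapped; errors on incompatible alleles.
# Returns the second table aligned, with a `flipped` column.
.align_alleles <- function(ref, other, label = "outcome") {
  has_ref <- all(c("effect_allele", "other_allele") %in% names(ref))
  has_oth <- all(c("effect_allele", "other_allele") %in% names(other))
  if (!has_ref || !has_oth) {
    other$flipped <- FALSE
    return(other)
  }
  same <- other$effect_allele == ref$effect_allele &
    other$other_allele == ref$other_allele
  swapped <- other$effect_allele == ref$other_allele &
    other$other_allele == ref$effect_allele
  bad <- !(same | swapped)
  if (any(bad)) {
    stop("harmonization error: incompatible alleles between inputs for ",
         sum(bad), " SNP(s), e.g. ",
         paste(utils::head(ref$snp_id[bad], 3), collapse = ", "),
         call. = FALSE)
  }
  flip_cols <- intersect(c("beta", "beta_m", "beta_o", "b_own", "b_off"),
                         names(other))
  for (cc in flip_cols) other[[cc]][swapped] <- -other[[cc]][swapped]
  if ("eaf" %in% names(other)) {
    other$eaf[swapped] <- 1 - other$eaf[swapped]
  }
  other$effect_allele[swapped] <- ref$effect_allele[swapped]
  other$other_allele[swapped] <- ref$other_allele[swapped]
  other$flipped <- swapped
  other
}

#' Partition genetic effects from two unconditional GWAS summary files
#'
#' For each SNP present in both GWAS, recovers the conditional maternal
#' and offspring effects by the exact linear inversion
#' [invert_unconditional()] and propagates their sampling covariance by
#' generalized least squares: with `S` the 2x2 sampling covariance of the
#' two input betas (off-diagonal `intercept * se_own * se_off`) and `A`
#' the inverse-map matrix, the covariance of `(beta_m, beta_o)` is
#' `A S A'`.  For this just-identified two-equation system the linear
#' inversion coincides with the moment-matrix SEM estimator.
#'
#' @param own GWAS tibble for the own-phenotype GWAS (columns `snp_id`,
#'   `beta`, `se`, optionally `effect_allele`, `other_allele`, `eaf`).
#' @param off GWAS tibble for the offspring-phenotype GWAS (maternal
#'   genotype on offspring phenotype), same columns.
#' @param overlap Either a one-row tibble from [ldsc_overlap()], or
#'   `NULL` to use `intercept` directly.
#' @param intercept Cross-trait sampling correlation between the two
#'   GWAS; ignored when `overlap` is supplied.
#' @return A tibble with one row per shared SNP: `snp_id`, allele
#'   columns when available, `beta_m`, `se_m`, `p_m`, `beta_o`, `se_o`,
#'   `p_o`, `cov_mo`, `flipped`; the overlap estimate used is attached
#'   as attribute `"overlap"`.
#' @export
#' @examples
#' own <- tibble::tibble(snp_id = "rs1", beta = -0.025, se = 0.007)
#' off <- tibble::tibble(snp_id = "rs1", beta = 0.0145, se = 0.007)
#' fit_sem_summary(own, off, intercept = 0)
fit_sem_summary <- function(own, off, overlap = NULL, intercept = 0) {
  for (nm in c("snp_id", "beta", "se")) {
    if (!nm %in% names(own) || !nm %in% names(off)) {
      stop("GWAS inputs need columns snp_id, beta, se", call. = FALSE)
    }
  }
  if (!is.null(overlap)) intercept <- overlap$intercept[1]
  if (abs(intercept) > 1) {
    stop("intercept must lie in [-1, 1]", call. = FALSE)
  }
  own <- tibble::as_tibble(own)
  off <- tibble::as_tibble(off)
  shared <- intersect(own$snp_id, off$snp_id)
  if (!length(shared)) {
    stop("harmonization error: no shared snp_id between the two GWAS",
         call. = FALSE)
  }
  own <- own[match(shared, own$snp_id), ]
  off <- off[match(shared, off$snp_id), ]
  if (any(own$se <= 0) || any(off$se <= 0)) {
    stop("standard errors must be positive", call. = FALSE)
  }
  off <- .align_alleles(own, off)
  A <- matrix(c(-2 / 3, 4 / 3, 4 / 3, -2 / 3), 2, 2, byrow = TRUE)
  est <- invert_unconditional(own$beta, off$beta)
  cv <- intercept * own$se * off$se
  # A S A' written out elementwise for the vectorized per-SNP case.
  v_m <- A[1, 1]^2 * own$se^2 + A[1, 2]^2 * off$se^2 +
    2 * A[1, 1] * A[1, 2] * cv
  v_o <- A[2, 1]^2 * own$se^2 + A[2, 2]^2 * off$se^2 +
    2 * A[2, 1] * A[2, 2] * cv
  c_mo <- A[1, 1] * A[2, 1] * own$se^2 + A[1, 2] * A[2, 2] * off$se^2 +
    (A[1, 1] * A[2, 2] + A[1, 2] * A[2, 1]) * cv
  res <- tibble::tibble(snp_id = shared)
  for (cc in c("effect_allele", "other_allele", "eaf")) {
    if (cc %in% names(own)) res[[cc]] <- own[[cc]]
  }
  res$beta_m <- est$beta_m
  res$se_m <- sqrt(v_m)
  res$p_m <- 2 * stats::pnorm(-abs(res$beta_m / res$se_m))
  res$beta_o <- est$beta_o
  res$se_o <- sqrt(v_o)
  res$p_o <- 2 * stats::pnorm(-abs(res$beta_o / res$se_o))
  res$cov_mo <- c_mo
  res$b_own <- own$beta
  res$se_own <- own$se
  res$b_off <- off$beta
  res$se_off <- off$se
  res$converged <- TRUE
  res$flipped <- off$flipped
  attr(res, "overlap") <- overlap %||%
    tibble::tibble(intercept = intercept, se_intercept = NA_real_,
                   slope = NA_real_, n_overlap = NA_real_,
                   rho_p = NA_real_, n_snps = NA_integer_)
  res
}
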