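# Independent oracles used across the suite.

# Record-at-a-time multivariate-normal log-likelihood: evaluates each
# record's observed subvector against the marginal implied moments,
# without the sufficient-statistic shortcut of the implementation.
naive_fiml_loglik <- function(params, data) {
  mom <- implied_moments(params)
  data <- family_patterns(data)
  ll <- 0
  for (i in seq_len(nrow(data))) {
    pm <- mom$patterns[[as.character(data$pattern[i])]]
    x <- c(own = data$own_pheno[i], offspring = data$offspring_pheno[i],
           snp = data$snp[i])[colnames(pm$sigma)]
    k <- length(x)
    Sinv <- solve(pm$sigma)
    d <- x - pm$mu
    ll <- ll - 0.5 * (k * log(2 * pi) +
                        determinant(pm$sigma)$modulus[1] +
                        drop(t(d) %*% Sinv %*% d))
  }
  ll
}

# OLS by explicit normal equations.
ols_normal_equations <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Brute-force weighted median: smallest x at which the cumulative
# weight (interpolated at half-weight steps) reaches one half.
brute_weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (p[1] >= 0.5) return(x[1])
  if (p[length(p)] <= 0.5) return(x[length(x)])
  i <- max(which(p < 0.5))
  x[i] + (x[i + 1] - x[i]) * (0.5 - p[i]) / (p[i + 1] - p[i])
}

# Random valid SEM parameter draws for property-style loops.
random_sem_params <- function() {
  s2e <- runif(1, 0.5, 2)
  s2eo <- runif(1, 0.5, 2)
  sem_params(beta_m = runif(1, -0.5, 0.5), beta_o = runif(1, -0.5, 0.5),
             phi = runif(1, 0.1, 0.6),
             rho = runif(1, -0.6, 0.6) * sqrt(s2e * s2eo),
             sigma2_e = s2e, sigma2_eo = s2eo,
             mu_bw = runif(1, -1, 1), mu_bwo = runif(1, -1, 1),
             mu_snp = runif(1, 0.2, 1.5))
}
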