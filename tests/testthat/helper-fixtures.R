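# Shared fixtures and independent oracles, built in code at test time.

# dose-group summaries straight from probabilities (no censoring machinery)
groups_from_p <- function(dose, p, n = 1000) {
  data.frame(radiation_label = "O16", let_value = 98, n_fractions = 1L,
             total_dose = dose, n_crude = n, p_actuarial = p,
             var_p = p * (1 - p) / n, n_eff = n, r_eff = n * p)
}

# a well-conditioned reference fit used across tests
reference_fit <- function() {
  fit_logistic(groups_from_p(c(10, 12.5, 15, 17.5, 20),
                             plogis(0.8 * (c(10, 12.5, 15, 17.5, 20) - 15)),
                             n = 50))
}

# hand product-limit estimator (independent oracle for the actuarial
# module): events precede censorings at tied days
hand_km <- function(time, status, horizon) {
  ord <- order(time, -status)
  time <- time[ord]; status <- status[ord]
  s <- 1; gw <- 0
  at_risk <- length(time)
  for (tt in sort(unique(time[status == 1]))) {
    if (tt > horizon) break
    n_i <- sum(time >= tt)                 # at risk just before tt
    d_i <- sum(time == tt & status == 1)
    s <- s * (1 - d_i / n_i)
    gw <- gw + d_i / (n_i * (n_i - d_i))
  }
  list(p = 1 - s, var = s^2 * gw)
}

# profile-likelihood CI for ED50 (independent of the Fieller path)
profile_ed50_ci <- function(groups, level = 0.90) {
  x <- groups$total_dose; r <- groups$r_eff; n <- groups$n_eff
  prof <- function(rho) {
    opt <- optimize(function(b1) {
      eta <- b1 * (x - rho)
      sum(r * eta - n * log1p(exp(eta)))
    }, c(1e-6, 50), maximum = TRUE)
    opt$objective
  }
  fit <- fit_logistic(groups)
  ll0 <- fit$loglik
  target <- ll0 - qchisq(level, 1) / 2
  e <- -fit$coef[1] / fit$coef[2]
  lo <- uniroot(function(rho) prof(rho) - target, c(e - 10, e))$root
  hi <- uniroot(function(rho) prof(rho) - target, c(e, e + 10))$root
  c(lo, hi)
}

# multivariate-normal draws via the Cholesky factor (bootstrap oracles)
mvn_draws <- function(n, mean, vcov, seed) {
  set.seed(seed)
  z <- matrix(rnorm(n * length(mean)), n)
  sweep(z %*% chol(vcov), 2, mean, "+")
}
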