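test_that("ML fit recovers the analytic logistic law at large n", {
  # empirical logits exactly linear: the MLE is the interpolating curve
  g <- groups_from_p(c(10, 15, 20), c(0.1, 0.5, 0.9))
  fit <- fit_logistic(g)
  expect_true(fit$converged)
  expect_equal(unname(fit$coef[2]), log(9) / 5, tolerance = 0.01)
  e <- ed50(fit)
  expect_equal(e$ed50, 15, tolerance = 0.01 * 15)

  # symmetric two-point data: ED50 is the midpoint
  g2 <- groups_from_p(c(10, 20), c(0.25, 0.75))
  expect_equal(ed50(fit_logistic(g2))$ed50, 15, tolerance = 1e-6)

  # glm oracle (same likelihood, independent optimizer)
  g3 <- groups_from_p(c(11, 13, 15, 17), c(0.15, 0.4, 0.7, 0.93), n = 40)
  fit3 <- fit_logistic(g3)
  or <- suppressWarnings(glm(cbind(r_eff, n_eff - r_eff) ~ total_dose,
                             family = binomial, data = g3))
  expect_equal(unname(fit3$coef), unname(coef(or)), tolerance = 1e-5)
  expect_equal(unname(fit3$vcov), unname(vcov(or)), tolerance = 1e-4)
})

test_that("ed50 arithmetic, delta SE and bootstrap agree", {
  fit <- structure(list(coef = c(b0 = -3, b1 = 0.2),
                        vcov = diag(c(0.04, 1e-4)), loglik = 0,
                        converged = TRUE, separated = FALSE,
                        covariate = "dose"),
                   class = "logistic_fit")
  expect_equal(ed50(fit)$ed50, 15)

  ref <- reference_fit()
  e <- ed50(ref)
  draws <- mvn_draws(10000, ref$coef, ref$vcov, seed = 99)
  boot_se <- sd(-draws[, 1] / draws[, 2])
  expect_equal(e$se, boot_se, tolerance = 0.1)

  bad <- structure(list(coef = c(b0 = 1, b1 = -0.5), vcov = diag(2),
                        loglik = 0, converged = TRUE, separated = FALSE,
                        covariate = "dose"), class = "logistic_fit")
  expect_error(ed50(bad), class = "ionrbe_degenerate_fit")
})

test_that("Fieller limits reduce to the delta interval and match profile likelihood", {
  # v01 = 0, v11 -> 0: interval collapses to ed50 +/- z sqrt(v00)/b1
  fit <- structure(list(coef = c(b0 = -3, b1 = 0.2),
                        vcov = diag(c(0.04, 1e-12)), loglik = 0,
                        converged = TRUE, separated = FALSE,
                        covariate = "dose"), class = "logistic_fit")
  cl <- fieller_cl(fit)
  z <- qnorm(0.95)
  expect_equal(as.numeric(cl), 15 + c(-1, 1) * z * 0.2 / 0.2,
               tolerance = 1e-4)

  # profile-likelihood oracle on a well-conditioned fit
  g <- groups_from_p(c(10, 12.5, 15, 17.5, 20),
                     plogis(0.8 * (c(10, 12.5, 15, 17.5, 20) - 15)), n = 50)
  fit2 <- fit_logistic(g)
  f_cl <- fieller_cl(fit2)
  p_cl <- profile_ed50_ci(g)
  w <- diff(unname(f_cl))
  expect_lt(abs(f_cl[1] - p_cl[1]), 0.05 * w)
  expect_lt(abs(f_cl[2] - p_cl[2]), 0.05 * w)

  # an insignificant slope gives an unbounded, flagged set
  noisy <- structure(list(coef = c(b0 = -0.5, b1 = 0.05),
                          vcov = matrix(c(4, -0.1, -0.1, 0.01), 2),
                          loglik = 0, converged = TRUE, separated = FALSE,
                          covariate = "dose"), class = "logistic_fit")
  cl3 <- fieller_cl(noisy)
  expect_false(attr(cl3, "bounded"))
})

test_that("ED50 and Fieller limits are dose-scale equivariant", {
  g <- groups_from_p(c(10, 13, 16, 19), c(0.1, 0.35, 0.75, 0.95), n = 60)
  f1 <- fit_logistic(g)
  g_c <- g
  g_c$total_dose <- g$total_dose * 100          # Gy -> cGy
  f2 <- fit_logistic(g_c)
  expect_equal(ed50(f2)$ed50, 100 * ed50(f1)$ed50, tolerance = 1e-4)
  expect_equal(unname(f2$coef[2]), unname(f1$coef[2]) / 100,
               tolerance = 1e-4)
  expect_equal(as.numeric(fieller_cl(f2)), 100 * as.numeric(fieller_cl(f1)),
               tolerance = 1e-3)
})

test_that("separation routes to the documented fallback", {
  expect_equal(se_fallback(data.frame(total_dose = c(12, 13, 14, 15),
                                      p_actuarial = c(0, 0, 1, 1))), 0.25)
  expect_equal(se_fallback(data.frame(total_dose = c(10, 20),
                                      p_actuarial = c(0, 1))), 2.5)
  expect_error(se_fallback(data.frame(total_dose = c(10, 20),
                                      p_actuarial = c(0.2, 0.8))),
               class = "ionrbe_no_jump")

  g <- groups_from_p(c(12, 13, 14, 15), c(0, 0, 1, 1), n = 5)
  est <- estimate_ed50(g)
  expect_equal(est$method, "fallback")
  expect_equal(est$ed50, 13.5)
  expect_equal(est$se, 0.25)
})

test_that("latency shows the expected LET trend behaviour", {
  lets <- c(26, 66, 98, 141)
  flat <- latency_trend(lets, rep(150, 4))
  expect_equal(flat$slope, 0)
  expect_equal(flat$p_value, 1)

  line <- latency_trend(lets, 100 + 0.5 * lets)
  expect_equal(line$p_value, 0)

  # simulated null rejects at roughly the nominal 5% level
  set.seed(12)
  rej <- mean(replicate(2000, {
    latency_trend(lets, rnorm(4, 150, 20))$p_value < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)

  expect_error(latency_trend(c(26, 26), c(100, 110)),
               class = "ionrbe_bad_argument")
})
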