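make_group <- function(responder, event_day, followup_day, excluded,
                       dose = 13.5) {
  n <- length(responder)
  data.frame(animal_id = sprintf("a%02d", seq_len(n)),
             radiation_label = "O16", let_value = 98, depth = 120,
             n_fractions = 1L, total_dose = dose, responder = responder,
             event_day = event_day, followup_day = followup_day,
             excluded = excluded,
             exclusion_reason = ifelse(excluded, "intercurrent", ""))
}

test_that("uncensored groups reduce exactly to the crude binomial summary", {
  g <- make_group(c(TRUE, TRUE, TRUE, FALSE, FALSE),
                  c(120, 150, 200, NA, NA), c(120, 150, 200, 300, 300),
                  rep(FALSE, 5))
  s <- actuarial_rate(g)
  expect_equal(s$p_actuarial, 0.6)
  expect_equal(s$var_p, 0.6 * 0.4 / 5)
  expect_equal(s$n_eff, 5)
  expect_equal(s$r_eff, 3)

  # property: random uncensored groups over several seeds
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(3:12, 1)
    resp <- runif(n) < runif(1)
    g <- make_group(resp, ifelse(resp, runif(n, 50, 290), NA),
                    ifelse(resp, NA, 300), rep(FALSE, n))
    g$followup_day[resp] <- g$event_day[resp]
    s <- actuarial_rate(g)
    expect_equal(s$p_actuarial, mean(resp))
    expect_equal(s$n_eff, n)
    expect_equal(s$r_eff, sum(resp))
  }
})

test_that("censored group matches the hand product-limit oracle", {
  # 5 animals: events at days 120 and 150, one censored at day 100,
  # two followed to day 300; risk sets 4 and 3
  g <- make_group(c(TRUE, TRUE, FALSE, FALSE, FALSE),
                  c(120, 150, NA, NA, NA), c(120, 150, 100, 300, 300),
                  c(FALSE, FALSE, TRUE, FALSE, FALSE))
  s <- actuarial_rate(g)
  expect_equal(s$p_actuarial, 0.5)               # 1 - (3/4)(2/3)
  expect_equal(s$var_p, 0.0625)                  # Greenwood by hand
  expect_equal(s$n_eff, 4)                       # p(1-p)/var
  expect_equal(s$r_eff, 2)

  # oracle agreement on arbitrary censored configurations
  for (seed in 1:15) {
    set.seed(100 + seed)
    n <- sample(5:15, 1)
    resp <- runif(n) < 0.5
    cens <- !resp & runif(n) < 0.5
    ev <- ifelse(resp, round(runif(n, 30, 290)), NA)
    fu <- ifelse(resp, ev, ifelse(cens, round(runif(n, 10, 290)), 300))
    g <- make_group(resp, ev, fu, cens)
    s <- actuarial_rate(g)
    km <- hand_km(ifelse(resp, ev, fu), as.integer(resp), 300)
    expect_equal(s$p_actuarial, km$p, tolerance = 1e-10)
    expect_equal(s$var_p, km$var, tolerance = 1e-10)
  }
})

test_that("boundary and invariance rules hold", {
  # all respond, no censoring: p = 1, fallback n_eff = n_crude
  g <- make_group(rep(TRUE, 5), c(100, 120, 140, 160, 180),
                  c(100, 120, 140, 160, 180), rep(FALSE, 5))
  s <- actuarial_rate(g)
  expect_equal(s$p_actuarial, 1)
  expect_equal(s$n_eff, 5)

  # permutation invariance
  g2 <- make_group(c(TRUE, FALSE, TRUE, FALSE, FALSE),
                   c(110, NA, 230, NA, NA), c(110, 80, 230, 300, 300),
                   c(FALSE, TRUE, FALSE, FALSE, FALSE))
  s_ref <- actuarial_rate(g2)
  perm <- g2[c(4, 2, 5, 1, 3), ]
  perm$animal_id <- g2$animal_id
  expect_equal(actuarial_rate(perm)$p_actuarial, s_ref$p_actuarial)
  expect_equal(actuarial_rate(perm)$n_eff, s_ref$n_eff)

  # censoring before the first event loses information: n_eff <= n_crude
  expect_lte(s_ref$n_eff, s_ref$n_crude + 1e-9)

  # day-0 exclusions contribute no risk time
  g3 <- rbind(g2, make_group(FALSE, NA, 0, TRUE)[1, ])
  s3 <- actuarial_rate(g3)
  expect_equal(s3$n_crude, 5)
  expect_equal(s3$p_actuarial, s_ref$p_actuarial)
})

test_that("error paths are informative", {
  empty <- make_group(FALSE, NA, 300, FALSE)[0, ]
  expect_error(actuarial_rate(empty), class = "ionrbe_empty_group")
  g <- make_group(c(TRUE, FALSE), c(120, NA), c(120, 350), c(FALSE, FALSE))
  expect_error(actuarial_rate(g), class = "ionrbe_bad_argument")
  mixed <- rbind(make_group(TRUE, 120, 120, FALSE, dose = 12),
                 make_group(FALSE, NA, 300, FALSE, dose = 13))
  expect_error(actuarial_rate(mixed), class = "ionrbe_mixed_group")
})

test_that("summarize_dose_groups splits a simulated cohort correctly", {
  rec <- simulate_cohort(cohort_design("O16", 98, 120, 1L, seq(10.5, 15.5, 1)),
                         response_params(13.5, 1.5, censor_hazard = 2e-3),
                         seed = 3)
  g <- summarize_dose_groups(rec)
  expect_equal(nrow(g), 6)
  expect_equal(g$total_dose, seq(10.5, 15.5, 1))
  expect_equal(sum(g$n_crude), 30)
  expect_true(all(g$p_actuarial >= 0 & g$p_actuarial <= 1))
  expect_equal(g$r_eff, g$n_eff * g$p_actuarial)
})
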