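# Recovery/coverage simulators for the stochastic acceptance criteria.
# Stated world: Table-1 group sizes (5 animals/level), dose-axis slope
# 1.5 /Gy at ED50, intercurrent censoring hazard 1e-4 /day.

# single-schedule ED50 recovery at the 98 keV/um single-dose design
sim_ed50_replicates <- function(n_rep, seed0 = 50000, level = 0.90) {
  design <- cohort_design("O16", 98, 120, 1L, seq(10.5, 15.5, 1))
  truth <- response_params(13.5, 1.5, censor_hazard = 1e-4, law = "dose")
  t(vapply(seq_len(n_rep), function(i) {
    rec <- simulate_cohort(design, truth, seed = seed0 + i)
    g <- summarize_dose_groups(rec)
    est <- estimate_ed50(g, level = level)
    c(ed50 = est$ed50, low = unname(est$cl[1]), high = unname(est$cl[2]),
      fallback = as.numeric(est$method == "fallback"))
  }, numeric(4)))
}

# two-schedule alpha/beta + BED50 recovery at the 26 keV/um designs
sim_lq_replicates <- function(n_rep, seed0 = 70000, level = 0.90) {
  d1 <- cohort_design("O16", 26, 35, 1L, seq(15.5, 20.5, 1))
  d2 <- cohort_design("O16", 26, 35, 2L, seq(18, 25, 1))
  truth <- response_params(17.2, 1.5, alpha_beta = 13.4,
                           censor_hazard = 1e-4, law = "bed")
  t(vapply(seq_len(n_rep), function(i) {
    rec <- rbind(simulate_cohort(d1, truth, seed = seed0 + 2 * i),
                 simulate_cohort(d2, truth, seed = seed0 + 2 * i + 1))
    g <- summarize_dose_groups(rec)
    out <- tryCatch({
      fit <- fit_lq_logistic(g)
      b <- bed50(fit, level = level)
      c(ab = b$alpha_beta, ab_low = unname(b$alpha_beta_cl[1]),
        ab_high = unname(b$alpha_beta_cl[2]), bed50 = b$bed50,
        bed_low = unname(b$cl[1]), bed_high = unname(b$cl[2]),
        ok = 1)
    }, error = function(e) c(ab = NA, ab_low = NA, ab_high = NA,
                             bed50 = NA, bed_low = NA, bed_high = NA,
                             ok = 0))
    out
  }, numeric(7)))
}
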