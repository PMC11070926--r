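## Synthetic cohort generation emulating the rat spinal-cord study design:
## dose groups of 5 animals, single or split (2 x) doses, 300-day follow-up,
## binary endpoint (paresis grade II), sporadic intercurrent censoring.

#' Cohort design for one radiation quality and schedule
#'
#' @param radiation_label text label ("O16", "photon", "control", ...)
#' @param let_value dose-averaged LET in keV/um (0 for photons/controls)
#' @param depth position in the beam, mm (NA if not applicable)
#' @param n_fractions number of equal fractions (>= 1)
#' @param dose_levels strictly increasing total doses, Gy
#' @param animals_per_level animals irradiated at each level (default 5)
#' @param n_controls unirradiated controls appended to this design
#' @param followup_horizon follow-up horizon in days (default 300)
#' @return object of class `cohort_design`
#' @export
cohort_design <- function(radiation_label, let_value, depth = NA_real_,
                          n_fractions, dose_levels, animals_per_level = 5L,
                          n_controls = 0L, followup_horizon = 300) {
  stopifnot(is.character(radiation_label), length(radiation_label) == 1L)
  check_number(let_value, "let_value", 0)
  check_number(n_fractions, "n_fractions", 1)
  check_number(animals_per_level, "animals_per_level", 1)
  check_number(n_controls, "n_controls", 0)
  check_number(followup_horizon, "followup_horizon", 0, strict = TRUE)
  if (!is.numeric(dose_levels) || any(!is.finite(dose_levels)) ||
      any(dose_levels < 0) || is.unsorted(dose_levels, strictly = TRUE))
    stop_ionrbe("dose_levels must be non-negative and strictly increasing",
                "ionrbe_bad_argument")
  structure(list(radiation_label = radiation_label, let_value = let_value,
                 depth = depth, n_fractions = as.integer(n_fractions),
                 dose_levels = dose_levels,
                 animals_per_level = as.integer(animals_per_level),
                 n_controls = as.integer(n_controls),
                 followup_horizon = followup_horizon),
            class = "cohort_design")
}

#' True dose--response law for simulation
#'
#' The generating law is logistic either in total dose (`law = "dose"`,
#' single-schedule studies) or in the LQ biologically effective dose
#' (`law = "bed"`, the default, which makes alpha/beta recovery across
#' schedules well-posed). In both cases the response probability at
#' `ed50_total_dose` delivered in one fraction is exactly 0.5, and
#' `logistic_slope` is the slope of p(D) on the dose axis at that point.
#'
#' @param ed50_total_dose single-fraction ED50, Gy
#' @param logistic_slope dose-axis logistic slope at ED50, 1/Gy (> 0)
#' @param alpha_beta LQ alpha/beta ratio, Gy (> 0; used by the BED law)
#' @param censor_hazard exponential intercurrent-loss hazard, 1/day (>= 0)
#' @param latency_meanlog,latency_sdlog log-normal responder latency
#'   parameters (days), truncated at the horizon
#' @param law "bed" or "dose"
#' @return object of class `response_params`
#' @export
response_params <- function(ed50_total_dose, logistic_slope, alpha_beta = 10,
                            censor_hazard = 1e-4,
                            latency_meanlog = log(150), latency_sdlog = 0.35,
                            law = c("bed", "dose")) {
  law <- match.arg(law)
  check_number(ed50_total_dose, "ed50_total_dose", 0, strict = TRUE)
  check_number(logistic_slope, "logistic_slope", 0, strict = TRUE)
  check_number(alpha_beta, "alpha_beta", 0, strict = TRUE, allow_inf = TRUE)
  check_number(censor_hazard, "censor_hazard", 0)
  check_number(latency_sdlog, "latency_sdlog", 0, strict = TRUE)
  structure(list(ed50_total_dose = ed50_total_dose,
                 logistic_slope = logistic_slope, alpha_beta = alpha_beta,
                 censor_hazard = censor_hazard,
                 latency_meanlog = latency_meanlog,
                 latency_sdlog = latency_sdlog, law = law),
            class = "response_params")
}

#' Response probability under the generating law
#'
#' @param truth a [response_params()] object
#' @param total_dose total dose, Gy (vectorised)
#' @param n_fractions schedule
#' @return probability of the endpoint within the horizon
#' @export
response_prob <- function(truth, total_dose, n_fractions = 1L) {
  stopifnot(inherits(truth, "response_params"))
  if (truth$law == "dose") {
    plogis(truth$logistic_slope * (total_dose - truth$ed50_total_dose))
  } else {
    ed50 <- truth$ed50_total_dose
    bed50 <- bed(ed50, 1L, truth$alpha_beta)
    g1 <- truth$logistic_slope / (1 + 2 * ed50 / truth$alpha_beta)
    b <- ifelse(total_dose > 0,
                bed(pmax(total_dose, .Machine$double.eps), n_fractions,
                    truth$alpha_beta), 0)
    plogis(g1 * (b - bed50))
  }
}

#' Simulate one cohort
#'
#' Per animal, in fixed draw order (response, latency, censoring):
#' the responder flag is Bernoulli with the law's probability at the
#' animal's dose; responders receive a log-normal latency truncated at the
#' horizon; an independent exponential censoring day excludes the animal
#' (endpoint unobserved) if it precedes the event or the horizon.
#'
#' @param design a [cohort_design()]
#' @param truth a [response_params()]
#' @param seed integer seed; identical seeds give identical tables
#' @return data.frame of animal records (class `animal_cohort`)
#' @export
#' @examples
#' d <- cohort_design("O16", 98, 120, 1L, seq(10.5, 15.5, 1))
#' tr <- response_params(13.5, 1.5, alpha_beta = 29.5)
#' head(simulate_cohort(d, tr, seed = 1))
simulate_cohort <- function(design, truth, seed) {
  stopifnot(inherits(design, "cohort_design"), inherits(truth, "response_params"))
  check_number(seed, "seed")
  doses <- c(rep(design$dose_levels, each = design$animals_per_level),
             rep(0, design$n_controls))
  n <- length(doses)
  hor <- design$followup_horizon
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  u <- matrix(runif(3L * n), ncol = 3L, byrow = TRUE)  # fixed per-animal order

  p <- response_prob(truth, doses, design$n_fractions)
  responder <- u[, 1L] < p
  ptrunc <- plnorm(hor, truth$latency_meanlog, truth$latency_sdlog)
  event_day <- ifelse(responder,
                      qlnorm(u[, 2L] * ptrunc, truth$latency_meanlog,
                             truth$latency_sdlog), NA_real_)
  censor_day <- if (truth$censor_hazard > 0)
    qexp(u[, 3L], rate = truth$censor_hazard) else rep(Inf, n)

  end_day <- ifelse(responder, pmin(event_day, hor), hor)
  excluded <- censor_day < end_day
  responder[excluded] <- FALSE
  event_day[excluded] <- NA_real_
  followup <- ifelse(excluded, censor_day, ifelse(responder, event_day, hor))
  # keep the "excluded before the horizon" invariant through rounding
  followup[excluded] <- pmin(followup[excluded], hor - 0.1)

  data.frame(
    animal_id = sprintf("%s_%gkeV_%dFx_%03d", design$radiation_label,
                        design$let_value, design$n_fractions, seq_len(n)),
    radiation_label = design$radiation_label,
    let_value = design$let_value,
    depth = design$depth,
    n_fractions = design$n_fractions,
    total_dose = doses,
    responder = responder,
    event_day = round(event_day, 1),
    followup_day = round(followup, 1),
    excluded = excluded,
    exclusion_reason = ifelse(excluded, "intercurrent", ""),
    stringsAsFactors = FALSE
  ) -> rec
  class(rec) <- c("animal_cohort", "data.frame")
  rec
}

#' Simulate several designs with sub-seeds derived from one master seed
#'
#' @param designs list of [cohort_design()] objects
#' @param truths single [response_params()] or list parallel to `designs`
#' @param seed master seed; design i uses `seed * 100 + i`
#' @return combined `animal_cohort` data.frame
#' @export
simulate_cohorts <- function(designs, truths, seed) {
  if (inherits(truths, "response_params"))
    truths <- rep(list(truths), length(designs))
  stopifnot(length(truths) == length(designs))
  out <- Map(function(d, tr, i) simulate_cohort(d, tr, seed * 100 + i),
             designs, truths, seq_along(designs))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("animal_cohort", "data.frame")
  res
}

#' The packaged study design (four SOBP positions, two schedules, controls)
#'
#' Built-in designs for the four dose-averaged LET positions (26, 66, 98,
#' 141 keV/um at depths 35, 100, 120, 127 mm) with the published dose
#' levels, 5 animals per level, single and split schedules, plus 10
#' unirradiated controls as a separate design. Totals 280 animals.
#'
#' @return named list of [cohort_design()] objects
#' @export
#' @examples
#' sum(vapply(design_table1(), function(d)
#'   length(d$dose_levels) * d$animals_per_level, 0))  # 280
design_table1 <- function() {
  pos <- data.frame(depth = c(35, 100, 120, 127),
                    let = c(26, 66, 98, 141))
  single <- list(seq(15.5, 20.5, 1), seq(12.5, 17.5, 1),
                 seq(10.5, 15.5, 1), seq(12.5, 19.5, 1))
  split <- list(seq(18, 25, 1), seq(15, 20, 1),
                seq(12.5, 17.5, 1), seq(12, 19, 1))
  out <- list()
  for (i in seq_len(4)) {
    out[[sprintf("O16_%gkeV_1Fx", pos$let[i])]] <-
      cohort_design("O16", pos$let[i], pos$depth[i], 1L, single[[i]])
    out[[sprintf("O16_%gkeV_2Fx", pos$let[i])]] <-
      cohort_design("O16", pos$let[i], pos$depth[i], 2L, split[[i]])
  }
  out[["controls"]] <- cohort_design("control", 0, NA_real_, 1L,
                                     dose_levels = 0, animals_per_level = 10L)
  out
}

#' Total animal count of a list of designs
#' @param designs list of [cohort_design()]
#' @return integer count
#' @export
design_animal_count <- function(designs) {
  sum(vapply(designs, function(d)
    length(d$dose_levels) * d$animals_per_level + d$n_controls, numeric(1)))
}
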