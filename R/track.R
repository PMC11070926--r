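## Amorphous-track RBE prediction: LEM I in the published low-dose
## single-track approximation and the modified MKM with the
## saturation-corrected dose-mean specific energy. Both models convert an
## ion track's radial dose profile into LQ coefficients relative to a
## model-internal photon reference curve.

#' Photon LQ reference curve for the track models
#'
#' The local photon effect is N_x(D) = alpha_x D + beta_x D^2 up to the
#' threshold dose `d_t`, beyond which it continues linearly with slope
#' s_max = alpha_x + 2 beta_x d_t (LEM convention).
#'
#' @param alpha_x photon alpha, 1/Gy
#' @param alpha_beta photon alpha/beta, Gy (sets beta_x)
#' @param d_t threshold dose, Gy (LEM only; Inf disables the cut)
#' @return object of class `photon_lq` with `alpha_x`, `beta_x`, `d_t`,
#'   `s_max`
#' @export
#' @examples
#' photon_lq(0.1, 2, 30)$s_max  # 3.1 /Gy
photon_lq <- function(alpha_x, alpha_beta = 2, d_t = 30) {
  check_number(alpha_x, "alpha_x", 0)
  check_number(alpha_beta, "alpha_beta", 0, strict = TRUE)
  check_number(d_t, "d_t", 0, strict = TRUE, allow_inf = TRUE)
  beta_x <- alpha_x / alpha_beta
  structure(list(alpha_x = alpha_x, beta_x = beta_x, d_t = d_t,
                 s_max = alpha_x + 2 * beta_x * d_t),
            class = "photon_lq")
}

#' LEM I track and geometry parameters
#'
#' @param r_min inner (core) track radius, um (default 0.3)
#' @param track_coeff penumbra-radius coefficient, um (MeV/u)^-track_exp
#' @param track_exp penumbra-radius energy exponent
#' @param nucleus_radius sensitive-nucleus radius, um (default 5;
#'   placeholder for CNS tissue, cancels in the low-dose alpha)
#' @return object of class `lem_params`
#' @export
lem_params <- function(r_min = 0.3, track_coeff = 0.05, track_exp = 1.7,
                       nucleus_radius = 5) {
  for (nm in c("r_min", "track_coeff", "track_exp", "nucleus_radius"))
    check_number(get(nm), nm, 0, strict = TRUE)
  structure(list(r_min = r_min, track_coeff = track_coeff,
                 track_exp = track_exp, nucleus_radius = nucleus_radius),
            class = "lem_params")
}

#' mMKM parameters
#'
#' `z_0` (saturation specific energy) derives from the lineal-energy
#' saturation parameter `y_0` through the spherical-domain mean-chord
#' relation z = 0.1602 y / (pi r_d^2) (Gy, keV/um, um); pass `z_0`
#' directly to override the convention.
#'
#' @param r_d sub-nuclear domain radius, um (default 0.3)
#' @param r_n nucleus radius, um (default 3.6)
#' @param alpha_0 limiting alpha at zero LET, 1/Gy (default 0.003)
#' @param alpha_beta reference alpha/beta, Gy (sets beta_m = alpha_0/ab)
#' @param y_0 saturation parameter, keV/um (default 150)
#' @param z_0 optional direct saturation specific energy, Gy
#' @return object of class `mkm_params`
#' @export
mkm_params <- function(r_d = 0.3, r_n = 3.6, alpha_0 = 0.003,
                       alpha_beta = 2, y_0 = 150, z_0 = NULL) {
  for (nm in c("r_d", "r_n", "alpha_0", "alpha_beta", "y_0"))
    check_number(get(nm), nm, 0, strict = TRUE)
  if (is.null(z_0)) z_0 <- KEV_UM_TO_GY_UM2 * y_0 / (pi * r_d^2)
  check_number(z_0, "z_0", 0, strict = TRUE, allow_inf = TRUE)
  structure(list(r_d = r_d, r_n = r_n, alpha_0 = alpha_0,
                 beta_m = alpha_0 / alpha_beta, y_0 = y_0, z_0 = z_0,
                 z0_convention = "sphere-mean-chord 0.1602*y0/(pi*r_d^2)"),
            class = "mkm_params")
}

## piecewise 1/r^2 amorphous track with constant core, normalised so that
## the radial integral returns the full LET
track_norm_const <- function(let_value, r_core, r_max) {
  if (r_max <= r_core)
    stop_ionrbe("track outer radius must exceed the core radius",
                "ionrbe_bad_track")
  KEV_UM_TO_GY_UM2 * let_value / (pi * (1 + 2 * log(r_max / r_core)))
}

track_dose <- function(r, let_value, r_core, r_max) {
  k <- track_norm_const(let_value, r_core, r_max)
  ifelse(r <= r_core, k / r_core^2,
         ifelse(r <= r_max, k / r^2, 0))
}

#' LEM I radial dose profile
#'
#' Constant core dose for r <= r_min, 1/r^2 penumbra out to
#' r_max = track_coeff * E^track_exp, zero beyond; normalised so that
#' the track integral 2 pi int D(r) r dr equals 0.1602 * LET (Gy um^2,
#' water at unit density).
#'
#' @param r radius, um (vectorised)
#' @param beam an [ion_beam()]
#' @param params a [lem_params()]
#' @return local dose in Gy
#' @export
radial_dose <- function(r, beam, params = lem_params()) {
  stopifnot(inherits(beam, "ion_beam"), inherits(params, "lem_params"))
  stopifnot(all(r >= 0))
  r_max <- params$track_coeff * beam$energy^params$track_exp
  track_dose(r, beam$let_value, params$r_min, r_max)
}

#' LEM I low-dose (single-track) LQ coefficients
#'
#' Single-track lethal-event yield
#' N1 = int N_x(D(r)) 2 pi r dr / A_n over the radial dose profile, with
#' the photon local-effect curve N_x; single-track specific energy
#' z1 = 0.1602 LET / A_n. The low-dose slope is alpha_ion = N1/z1 (the
#' nucleus area A_n cancels), and
#' beta_ion = max(0, (s_max - alpha_ion)) / (2 d_t).
#' Integrals by adaptive quadrature split at the core radius and the
#' threshold-dose radius (relative tolerance 1e-8).
#'
#' @param beam an [ion_beam()]
#' @param photon a [photon_lq()] (model-internal reference)
#' @param params a [lem_params()]
#' @return list `alpha_ion`, `beta_ion` (1/Gy, 1/Gy^2) plus diagnostics
#' @export
lem1_alpha_beta <- function(beam, photon = photon_lq(0.1, 2, 30),
                            params = lem_params()) {
  stopifnot(inherits(beam, "ion_beam"), inherits(photon, "photon_lq"),
            inherits(params, "lem_params"))
  r_min <- params$r_min
  r_max <- params$track_coeff * beam$energy^params$track_exp
  k <- track_norm_const(beam$let_value, r_min, r_max)
  nx <- function(d) {
    ifelse(d <= photon$d_t, photon$alpha_x * d + photon$beta_x * d^2,
           photon$alpha_x * photon$d_t + photon$beta_x * photon$d_t^2 +
             photon$s_max * (d - photon$d_t))
  }
  core_dose <- k / r_min^2
  # core contributes analytically; penumbra by quadrature split where D = d_t
  core_int <- pi * r_min^2 * nx(core_dose)
  f <- function(r) nx(k / r^2) * 2 * pi * r
  r_t <- sqrt(k / photon$d_t)                  # D(r_t) = d_t
  brk <- sort(unique(pmin(pmax(c(r_t), r_min), r_max)))
  lims <- unique(c(r_min, brk, r_max))
  pen_int <- 0
  for (i in seq_len(length(lims) - 1L)) {
    q <- integrate(f, lims[i], lims[i + 1L], rel.tol = 1e-8,
                   subdivisions = 500L)
    if (q$message != "OK")
      stop_ionrbe(paste("quadrature failure:", q$message),
                  "ionrbe_quadrature")
    pen_int <- pen_int + q$value
  }
  total_let_gy_um2 <- KEV_UM_TO_GY_UM2 * beam$let_value
  alpha_ion <- (core_int + pen_int) / total_let_gy_um2
  list(alpha_ion = alpha_ion,
       beta_ion = max(0, photon$s_max - alpha_ion) / (2 * photon$d_t),
       saturated = core_dose > photon$d_t,
       alpha_exceeds_smax = alpha_ion > photon$s_max,
       r_max = r_max, core_dose = core_dose)
}

## Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch, base R)
gauss_legendre <- function(n, a = 0, b = 1) {
  i <- seq_len(n - 1L)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- beta
  J[cbind(i + 1L, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1L, ]^2
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}

#' mMKM saturation-corrected dose-mean specific energy
#'
#' The track follows a Kiefer--Chatterjee-type profile (core radius
#' 0.0116 beta um, penumbra radius 0.0616 E^1.7 um, 1/r^2 penumbra, core
#' set by the total-LET normalisation). The domain specific energy z(b)
#' is the areal mean dose over a disc of radius `r_d` at impact parameter
#' b; the saturation-corrected dose-mean is
#' z*1D = int z'(b) z(b) 2 pi b db / int z(b) 2 pi b db with
#' z'(b) = z_0 sqrt(1 - exp(-z(b)^2/z_0^2)).
#'
#' @param beam an [ion_beam()]
#' @param params a [mkm_params()]
#' @param saturation apply the correction (FALSE returns the plain
#'   dose-mean z1D)
#' @return z*1D in Gy
#' @export
mkm_zstar <- function(beam, params = mkm_params(), saturation = TRUE) {
  stopifnot(inherits(beam, "ion_beam"), inherits(params, "mkm_params"))
  r_c <- 0.0116 * beam$beta_v
  r_p <- 0.0616 * beam$energy^1.7
  r_d <- params$r_d
  if (r_p <= r_c)
    stop_ionrbe("penumbra radius below core radius", "ionrbe_bad_track")

  gs <- gauss_legendre(24L, 0, r_d)     # domain radial nodes
  nphi <- 64L
  phi <- (seq_len(nphi) - 0.5) * pi / nphi   # half circle, symmetric
  cphi <- cos(phi)
  # mean dose over the disc at impact parameter b
  z_of_b <- function(b) {
    # matrix of distances track-centre -> domain points
    s <- gs$nodes
    d2 <- outer(s^2, rep(1, nphi)) + b^2 -
      2 * b * outer(s, cphi)
    dd <- track_dose(sqrt(pmax(d2, 0)), beam$let_value, r_c, r_p)
    ring_mean <- rowMeans(dd)                 # phi average
    sum(gs$weights * s * ring_mean) * 2 / r_d^2
  }
  bmax <- r_p + r_d
  bg <- c(0, exp(seq(log(1e-4), log(bmax), length.out = 240L)))
  zb <- vapply(bg, z_of_b, numeric(1))
  w <- zb * bg                                  # z(b) * b
  zp <- if (saturation && is.finite(params$z_0))
    params$z_0 * sqrt(1 - exp(-zb^2 / params$z_0^2)) else zb
  trap <- function(y) sum(diff(bg) * (head(y, -1) + y[-1]) / 2)
  num <- trap(zp * w)
  den <- trap(w)
  if (!is.finite(num) || !is.finite(den) || den <= 0)
    stop_ionrbe("specific-energy quadrature failed", "ionrbe_quadrature")
  num / den
}

#' mMKM LQ coefficients from z*1D
#'
#' alpha_ion = alpha_0 + beta_m z*1D; beta_ion = beta_m.
#'
#' @param zstar saturation-corrected dose-mean specific energy, Gy
#' @param params a [mkm_params()]
#' @return list `alpha_ion`, `beta_ion`
#' @export
mkm_alpha_beta <- function(zstar, params = mkm_params()) {
  check_number(zstar, "zstar", 0)
  list(alpha_ion = params$alpha_0 + params$beta_m * zstar,
       beta_ion = params$beta_m)
}

#' Dose-weighted mixed-field LQ averaging
#'
#' alpha_mix = sum w_i alpha_i; sqrt(beta_mix) = sum w_i sqrt(beta_i)
#' (Zaider--Rossi form) for dose weights w_i summing to 1.
#'
#' @param weights dose weights (>= 0, sum 1)
#' @param alpha,beta component LQ coefficients
#' @return list `alpha_mix`, `beta_mix`
#' @export
mixed_field <- function(weights, alpha, beta) {
  stopifnot(length(weights) == length(alpha),
            length(weights) == length(beta))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop_ionrbe("weights must be non-negative and sum to 1",
                "ionrbe_bad_argument")
  list(alpha_mix = sum(weights * alpha),
       beta_mix = sum(weights * sqrt(beta))^2)
}

#' Model-predicted RBE at a given fractional dose
#'
#' Per-fraction iso-effect: E = alpha_ion d + beta_ion d^2; the
#' iso-effective photon fraction dose solves the photon LQ,
#' d_x = (-alpha_x + sqrt(alpha_x^2 + 4 beta_x E)) / (2 beta_x), and
#' RBE = d_x/d (independent of the number of fractions for equal
#' per-fraction effect).
#'
#' @param alpha_ion,beta_ion ion LQ coefficients (1/Gy, 1/Gy^2)
#' @param photon a [photon_lq()] (same reference the model used)
#' @param dose_per_fraction ion dose per fraction, Gy (vectorised)
#' @param n_fractions schedule bookkeeping for the output row
#' @param model_name label ("LEM1", "mMKM", "external")
#' @param let_value LET bookkeeping for the output row
#' @return data.frame (`model_prediction`): model_name, let_value,
#'   n_fractions, dose_per_fraction, alpha_ion, beta_ion, rbe
#' @export
predict_rbe <- function(alpha_ion, beta_ion, photon, dose_per_fraction,
                        n_fractions = 1L, model_name = "external",
                        let_value = NA_real_) {
  stopifnot(inherits(photon, "photon_lq"))
  if (photon$beta_x <= 0)
    stop_ionrbe("photon beta_x must be positive", "ionrbe_bad_argument")
  stopifnot(all(dose_per_fraction > 0), alpha_ion >= 0, beta_ion >= 0)
  d <- dose_per_fraction
  eff <- alpha_ion * d + beta_ion * d^2
  disc <- photon$alpha_x^2 + 4 * photon$beta_x * eff
  dx <- (-photon$alpha_x + sqrt(disc)) / (2 * photon$beta_x)
  data.frame(model_name = model_name, let_value = let_value,
             n_fractions = as.integer(n_fractions),
             dose_per_fraction = d, alpha_ion = alpha_ion,
             beta_ion = beta_ion, rbe = dx / d,
             stringsAsFactors = FALSE)
}

#' Study-level model predictions at the measured ED50 dose levels
#'
#' Monoenergetic surrogate: each SOBP position is represented by its
#' dose-averaged LET with the energy taken from the embedded oxygen-water
#' table, and the RBE is evaluated at the measured ED50 per-fraction dose.
#'
#' @param model "lem1" or "mkm"
#' @param measured data.frame with `let_value`, `n_fractions`, `ed50`
#' @param photon a [photon_lq()]; default chooses the standard reference
#'   of the model (alpha_x 0.1 for LEM I, 0.003 for mMKM, alpha/beta 2)
#' @param params [lem_params()] or [mkm_params()]
#' @return data.frame of model predictions
#' @export
predict_study <- function(model = c("lem1", "mkm"), measured,
                          photon = NULL, params = NULL) {
  model <- match.arg(model)
  if (is.null(photon))
    photon <- if (model == "lem1") photon_lq(0.1, 2, 30)
              else photon_lq(0.003, 2, Inf)
  if (is.null(params))
    params <- if (model == "lem1") lem_params() else mkm_params()
  out <- lapply(seq_len(nrow(measured)), function(i) {
    beam <- ion_beam(let_value = measured$let_value[i])
    ab <- if (model == "lem1") lem1_alpha_beta(beam, photon, params)
    else mkm_alpha_beta(mkm_zstar(beam, params), params)
    predict_rbe(ab$alpha_ion, ab$beta_ion, photon,
                measured$ed50[i] / measured$n_fractions[i],
                measured$n_fractions[i],
                model_name = if (model == "lem1") "LEM1" else "mMKM",
                let_value = measured$let_value[i])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Predicted-versus-measured RBE deviation table
#'
#' Joins predictions to measurements on (LET, schedule), reports signed
#' deviations (predicted - measured), flags a prediction significant when
#' it falls outside the measured 90 % confidence limits, and summarises
#' the plateau value and the in-SOBP mean +/- SD per model and schedule.
#'
#' @param measured data.frame with `let_value`, `n_fractions`, `rbe`,
#'   `cl_low`, `cl_high`, and logical `in_sobp`
#' @param predicted data.frame from [predict_rbe()]/[predict_study()]
#' @return list `table` (per-point deviations) and `summary`
#'   (per model x schedule: plateau deviation, SOBP mean and SD)
#' @export
model_comparison <- function(measured, predicted) {
  tab <- merge(predicted, measured, by = c("let_value", "n_fractions"),
               suffixes = c("_pred", "_meas"))
  if (nrow(tab) < nrow(predicted))
    stop_ionrbe("unmatched (LET, schedule) keys between predictions and measurements",
                "ionrbe_unmatched")
  tab$deviation <- tab$rbe_pred - tab$rbe_meas
  tab$significant <- tab$rbe_pred < tab$cl_low | tab$rbe_pred > tab$cl_high
  key <- interaction(tab$model_name, tab$n_fractions, drop = TRUE)
  summ <- do.call(rbind, lapply(split(tab, key), function(d) {
    sobp <- d$deviation[d$in_sobp]
    data.frame(model_name = d$model_name[1L],
               n_fractions = d$n_fractions[1L],
               plateau_deviation =
                 if (any(!d$in_sobp)) mean(d$deviation[!d$in_sobp]) else NA_real_,
               sobp_mean = mean(sobp), sobp_sd = stats::sd(sobp),
               n_significant = sum(d$significant),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(table = tab[order(tab$model_name, tab$n_fractions, tab$let_value), ],
       summary = summ)
}
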