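## RBE point estimates, error propagation and the trend summaries
## (RBE vs LET polynomial, LQ-based RBE vs dose-per-fraction curves).

## shared ratio machinery: photon/ion treated as independent experiments
ratio_estimate <- function(a, se_a, b, se_b, level = 0.90,
                           method = c("fieller", "normal"),
                           label = "ratio") {
  method <- match.arg(method)
  check_number(a, "numerator", 0, strict = TRUE)
  check_number(b, "denominator", 0, strict = TRUE)
  est <- a / b
  rel <- sqrt((se_a / a)^2 + (se_b / b)^2)
  se <- est * rel
  z <- qnorm(1 - (1 - level) / 2)
  cl <- if (method == "fieller")
    fieller_ratio(a, b, se_a^2, se_b^2, vab = 0, level = level)
  else structure(c(low = est - z * se, high = est + z * se), bounded = TRUE)
  structure(list(estimate = est, se = se, cl = cl, level = level,
                 method = method, label = label,
                 numerator = a, denominator = b),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf("%s = %.3f +/- %.3f (%d%% CL %.3f - %.3f, %s)\n", x$label,
              x$estimate, x$se, round(100 * x$level), x$cl[1], x$cl[2],
              x$method))
  invisible(x)
}

#' RBE as the ratio of photon to ion ED50
#'
#' RBE = ED50_photon / ED50_ion at matched fractionation. The SE follows
#' independent relative-variance propagation,
#' (SE_R/R)^2 = (SE_x/D_x)^2 + (SE_i/D_i)^2 (photon and ion experiments
#' are independent; the within-fit intercept/slope correlation is already
#' inside each delta-method SE). Confidence limits by Fieller's theorem
#' (default; reproduces the published asymmetric intervals) or normal
#' propagation.
#'
#' @param photon,ion `ed50_result`s, or lists with `ed50` and `se`
#' @param level confidence level (default 0.90)
#' @param method "fieller" or "normal"
#' @return `ratio_result` with `estimate`, `se`, `cl`
#' @export
#' @examples
#' rbe_ratio(list(ed50 = 34.3, se = 0.7), list(ed50 = 21.7, se = 0.4))
rbe_ratio <- function(photon, ion, level = 0.90,
                      method = c("fieller", "normal")) {
  ratio_estimate(photon$ed50, photon$se, ion$ed50, ion$se,
                 level = level, method = match.arg(method), label = "RBE")
}

#' Weighted quadratic trend of RBE with LET
#'
#' Inverse-variance weighted least squares of RBE on LET and LET^2,
#' one schedule at a time.
#'
#' @param let_value LET points, keV/um (>= 3 distinct)
#' @param rbe measured RBE values
#' @param se standard errors (weights 1/se^2); equal weights if NULL
#' @return list with `coef` (intercept, linear, quadratic), `fitted`,
#'   `peak_let` (vertex of the parabola, NA if convex), `fit`
#' @export
let_trend <- function(let_value, rbe, se = NULL) {
  if (length(unique(let_value)) < 3L)
    stop_ionrbe("need >= 3 distinct LET values", "ionrbe_bad_argument")
  w <- if (is.null(se)) rep(1, length(rbe)) else 1 / se^2
  fit <- lm(rbe ~ let_value + I(let_value^2), weights = w)
  cf <- coef(fit)
  if (any(!is.finite(cf)))
    stop_ionrbe("rank-deficient LET design", "ionrbe_bad_argument")
  peak <- if (cf[3] < 0) unname(-cf[2] / (2 * cf[3])) else NA_real_
  list(coef = setNames(unname(cf), c("c0", "c1", "c2")),
       fitted = unname(fitted(fit)), peak_let = peak, fit = fit)
}

#' LQ-based RBE vs dose-per-fraction curve anchored at a measurement
#'
#' From the measured anchor (dose per fraction d0, RBE R0) and the ion and
#' photon alpha/beta ratios, the iso-effect relation
#' d_x (1 + d_x/abx) = RBE_max d (1 + d/abi) inter-/extrapolates RBE to
#' other fractional doses; RBE_max is implied by the anchor. The curve
#' passes through the anchor exactly and approaches RBE_max as d -> 0.
#'
#' @param anchor_d measured dose per fraction, Gy
#' @param anchor_rbe measured RBE at `anchor_d`
#' @param alpha_beta_ion ion alpha/beta, Gy
#' @param alpha_beta_photon photon alpha/beta, Gy
#' @param dose_per_fraction doses at which to evaluate, Gy (vectorised)
#' @return data.frame `dose_per_fraction`, `rbe`, plus attribute `rbe_max`
#' @export
dose_interp <- function(anchor_d, anchor_rbe, alpha_beta_ion,
                        alpha_beta_photon, dose_per_fraction) {
  check_number(anchor_d, "anchor_d", 0, strict = TRUE)
  check_number(anchor_rbe, "anchor_rbe", 0, strict = TRUE)
  check_number(alpha_beta_ion, "alpha_beta_ion", 0, strict = TRUE)
  check_number(alpha_beta_photon, "alpha_beta_photon", 0, strict = TRUE)
  stopifnot(all(dose_per_fraction > 0))
  dx0 <- anchor_rbe * anchor_d
  rbe_mx <- dx0 * (1 + dx0 / alpha_beta_photon) /
    (anchor_d * (1 + anchor_d / alpha_beta_ion))
  d <- dose_per_fraction
  rhs <- rbe_mx * d * (1 + d / alpha_beta_ion)
  dx <- (alpha_beta_photon / 2) *
    (-1 + sqrt(1 + 4 * rhs / alpha_beta_photon))
  structure(data.frame(dose_per_fraction = d, rbe = dx / d),
            rbe_max = rbe_mx)
}
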