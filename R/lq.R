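## Linear-quadratic biologically effective dose and the generalized
## (two-schedule) logistic regression yielding alpha/beta, BED50, RBE_max.

#' Biologically effective dose of the LQ model
#'
#' BED = D (1 + d / (alpha/beta)) with dose per fraction d = D/n. Places
#' different fractionation schedules on a common effect scale; as
#' alpha/beta grows (or n grows at fixed D) BED approaches the physical
#' dose.
#'
#' @param total_dose total dose D, Gy (vectorised)
#' @param n_fractions number of equal fractions
#' @param alpha_beta LQ alpha/beta ratio, Gy (> 0; Inf allowed)
#' @return BED in Gy
#' @export
#' @examples
#' bed(13.5, 1, 29.5)  # 19.7 Gy
bed <- function(total_dose, n_fractions, alpha_beta) {
  if (!is.numeric(alpha_beta) || any(is.na(alpha_beta)) ||
      any(alpha_beta <= 0))
    stop_ionrbe("alpha_beta must be positive", "ionrbe_bad_argument")
  stopifnot(all(total_dose >= 0), all(n_fractions >= 1))
  total_dose * (1 + (total_dose / n_fractions) / alpha_beta)
}

#' Closed-form alpha/beta from a single/split-dose ED50 pair
#'
#' Solves the LQ iso-effect identity
#' ED1 (1 + ED1/x) = ED2 (1 + (ED2/2)/x) for x, i.e.
#' x = (ED1^2 - ED2^2/2) / (ED2 - ED1).
#' The pair is compatible with a positive alpha/beta only for
#' ED1 < ED2 < sqrt(2) ED1; x diverges as ED2 approaches ED1 (pure-alpha
#' limit) and reaches 0 at ED2 = sqrt(2) ED1 (pure-beta limit).
#'
#' This reduced estimator uses only the two ED50s; where a study pools
#' more schedules into its generalized fit, the pair solve legitimately
#' deviates from the jointly fitted alpha/beta.
#'
#' @param ed50_1fx single-dose ED50, Gy
#' @param ed50_2fx split-dose (2 fraction) ED50, Gy
#' @return alpha/beta in Gy
#' @export
#' @examples
#' alpha_beta_from_ed50_pair(17.2, 21.7)  # 13.4 Gy
alpha_beta_from_ed50_pair <- function(ed50_1fx, ed50_2fx) {
  check_number(ed50_1fx, "ed50_1fx", 0, strict = TRUE)
  check_number(ed50_2fx, "ed50_2fx", 0, strict = TRUE)
  if (ed50_2fx <= ed50_1fx)
    stop_ionrbe("split-dose ED50 must exceed the single-dose ED50",
                "ionrbe_incompatible_pair")
  x <- (ed50_1fx^2 - ed50_2fx^2 / 2) / (ed50_2fx - ed50_1fx)
  if (!is.finite(x) || x <= 0)
    stop_ionrbe(sprintf(paste0("incompatible pair: ED50(2Fx) = %.3g is at or ",
                               "beyond the pure-beta limit sqrt(2)*ED50(1Fx) ",
                               "= %.3g"), ed50_2fx, sqrt(2) * ed50_1fx),
                "ionrbe_incompatible_pair")
  x
}

lq_nll <- function(theta, D, nfx, r, n) {
  ab <- exp(theta[3])
  eta <- theta[1] + theta[2] * bed(D, nfx, ab)
  -sum(r * eta - n * log1p(exp(eta)))
}

#' Generalized logistic regression through the LQ BED
#'
#' Jointly fits p = 1/(1+exp(-(g0 + g1 BED(D, n, alpha/beta)))) to
#' dose-group summaries spanning at least two fractionation schedules,
#' with alpha/beta a free positive parameter optimised on the log scale
#' (ratio parameter with a heavy right tail). Multi-start `nlminb` over a
#' grid of alpha/beta initials, each seeded by a conditional two-parameter
#' logistic fit; covariance from the inverse observed information
#' (numerical Hessian), transformed to the (g0, g1, alpha/beta) scale.
#'
#' With `alpha_beta` supplied the value is held fixed (conditional fit) --
#' used e.g. to show equivalence with [fit_logistic()] after the BED
#' change of variables.
#'
#' @param groups `dose_group_summary` rows (`total_dose`, `n_fractions`,
#'   `n_eff`, `r_eff`)
#' @param alpha_beta optional fixed alpha/beta, Gy
#' @return object of class `lq_fit`: `coef` (g0, g1, alpha_beta), `vcov`
#'   (3x3), `loglik`, `converged`, `ab_fixed`
#' @export
fit_lq_logistic <- function(groups, alpha_beta = NULL) {
  g <- groups[groups$n_eff > 0, , drop = FALSE]
  if (is.null(alpha_beta) && length(unique(g$n_fractions)) < 2L)
    stop_ionrbe("alpha/beta is unidentifiable from a single schedule",
                "ionrbe_unidentifiable")
  D <- g$total_dose
  nfx <- g$n_fractions
  r <- pmin(pmax(g$r_eff, 0), g$n_eff)
  n <- g$n_eff

  cond_fit <- function(ab) {           # 2-parameter fit at fixed alpha/beta
    gg <- data.frame(total_dose = bed(D, nfx, ab), n_eff = n, r_eff = r)
    fit_logistic(gg)
  }

  if (!is.null(alpha_beta)) {
    check_number(alpha_beta, "alpha_beta", 0, strict = TRUE)
    cf <- cond_fit(alpha_beta)
    vc <- matrix(0, 3, 3,
                 dimnames = list(NULL, c("g0", "g1", "alpha_beta")))
    vc[1:2, 1:2] <- cf$vcov
    return(structure(list(coef = c(g0 = unname(cf$coef[1]),
                                   g1 = unname(cf$coef[2]),
                                   alpha_beta = alpha_beta),
                          vcov = vc, loglik = cf$loglik,
                          converged = cf$converged, ab_fixed = TRUE,
                          separated = cf$separated, groups = g),
                     class = "lq_fit"))
  }

  best <- NULL
  for (ab0 in c(2, 5, 15, 40, 120)) {
    cf <- tryCatch(cond_fit(ab0), error = function(e) NULL)
    th0 <- if (is.null(cf)) c(-2, 0.1, log(ab0))
           else c(cf$coef, log(ab0))
    opt <- tryCatch(
      nlminb(th0, lq_nll, D = D, nfx = nfx, r = r, n = n,
             lower = c(-Inf, 1e-8, log(0.1)), upper = c(Inf, Inf, log(1000)),
             control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (!is.null(opt) &&
        (is.null(best) || opt$objective < best$objective - 1e-10))
      best <- opt
  }
  if (is.null(best))
    stop_ionrbe("LQ-logistic fit failed from all starts",
                "ionrbe_nonconvergence")
  th <- best$par
  H <- tryCatch(optimHess(th, lq_nll, D = D, nfx = nfx, r = r, n = n),
                error = function(e) NULL)
  vc_theta <- if (!is.null(H))
    tryCatch(solve(H), error = function(e) matrix(NA_real_, 3, 3))
  else matrix(NA_real_, 3, 3)
  ab <- exp(th[3])
  J <- diag(c(1, 1, ab))                     # log(ab) -> ab
  vc <- J %*% vc_theta %*% J
  dimnames(vc) <- list(NULL, c("g0", "g1", "alpha_beta"))
  at_bound <- th[3] <= log(0.1) + 1e-6 || th[3] >= log(1000) - 1e-6
  structure(list(coef = c(g0 = th[1], g1 = th[2], alpha_beta = ab),
                 vcov = vc, vcov_log_ab = vc_theta,
                 loglik = -best$objective,
                 converged = best$convergence == 0 && !at_bound,
                 ab_fixed = FALSE, separated = FALSE, groups = g),
            class = "lq_fit")
}

#' @export
print.lq_fit <- function(x, ...) {
  cat(sprintf("<lq_fit> g0 = %.4g, g1 = %.4g /Gy, alpha/beta = %.4g Gy%s\n",
              x$coef[1], x$coef[2], x$coef[3],
              if (x$ab_fixed) " (fixed)" else ""))
  invisible(x)
}

#' BED50 from an LQ-logistic fit
#'
#' BED50 = -g0/g1 with delta-method SE from the (g0, g1) covariance block
#' (the alpha/beta uncertainty enters through its correlation with g0 and
#' g1) and Fieller confidence limits on the same block.
#'
#' @param fit an [fit_lq_logistic()] result
#' @param level confidence level (default 0.90)
#' @return object of class `bed50_result`: `bed50`, `se`, `cl`,
#'   `alpha_beta`, `alpha_beta_se`, `alpha_beta_cl`
#' @export
bed50 <- function(fit, level = 0.90) {
  stopifnot(inherits(fit, "lq_fit"))
  cf <- fit$coef
  if (!is.finite(cf[2]) || cf[2] <= 0)
    stop_ionrbe("BED slope g1 must be positive", "ionrbe_degenerate_fit")
  est <- -cf[1] / cf[2]
  v <- fit$vcov
  se <- ratio_delta_se(cf[1], cf[2], v[1, 1], v[2, 2], v[1, 2])
  cl <- fieller_ratio(a = -cf[1], b = cf[2], va = v[1, 1], vb = v[2, 2],
                      vab = -v[1, 2], level = level)
  # alpha/beta interval on the log scale (positivity, right-skewed)
  z <- qnorm(1 - (1 - level) / 2)
  ab <- unname(cf[3])
  ab_se <- sqrt(v[3, 3])
  ab_cl <- if (!fit$ab_fixed && is.finite(fit$vcov_log_ab[3, 3]) &&
               fit$vcov_log_ab[3, 3] > 0) {
    sl <- sqrt(fit$vcov_log_ab[3, 3])
    c(low = ab * exp(-z * sl), high = ab * exp(z * sl))
  } else c(low = NA_real_, high = NA_real_)
  structure(list(bed50 = unname(est), se = unname(se), cl = cl,
                 level = level, alpha_beta = ab, alpha_beta_se = ab_se,
                 alpha_beta_cl = ab_cl),
            class = "bed50_result")
}

#' @export
print.bed50_result <- function(x, ...) {
  cat(sprintf("BED50 = %.3f +/- %.3f Gy (%d%% CL %.3f - %.3f); alpha/beta = %.3f Gy\n",
              x$bed50, x$se, round(100 * x$level), x$cl[1], x$cl[2],
              x$alpha_beta))
  invisible(x)
}

#' Maximum RBE (zero fractional dose limit) from photon and ion BED50
#'
#' RBE_max = BED50_photon / BED50_ion; SE from independent relative
#' variances, CL by Fieller (which reproduces the asymmetric published
#' intervals) or normal propagation.
#'
#' @param photon,ion lists or `bed50_result`s carrying `bed50` and `se`
#' @param level confidence level (default 0.90)
#' @param method "fieller" (default) or "normal"
#' @return object of class `ratio_result` (`estimate`, `se`, `cl`)
#' @export
#' @examples
#' rbe_max(list(bed50 = 244.9, se = 24.3), list(bed50 = 39.3, se = 6.8))
rbe_max <- function(photon, ion, level = 0.90,
                    method = c("fieller", "normal")) {
  ratio_estimate(photon$bed50, photon$se, ion$bed50, ion$se,
                 level = level, method = match.arg(method),
                 label = "RBE_max")
}
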