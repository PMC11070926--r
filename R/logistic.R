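## Maximum-likelihood logistic dose-response fitting on effective counts,
## ED50 with delta-method SE and Fieller confidence limits.
##
## The likelihood uses fractional successes r_eff out of n_eff (effective
## sample sizes are non-integer), so the fit is hand-rolled damped Newton
## rather than glm(); glm serves as an independent oracle in the tests.

logistic_loglik <- function(b, x, r, n) {
  eta <- b[1] + b[2] * x
  sum(r * eta - n * log1p(exp(eta)))
}

#' Fit the logistic dose--response model to dose-group summaries
#'
#' Maximises the (fractional-count) binomial log-likelihood of
#' p(D) = 1 / (1 + exp(-(b0 + b1 D))) with successes `r_eff` out of `n_eff`
#' per group, by damped Newton iteration started from the empirical-logit
#' regression line, with documented fallback restarts. The covariance is
#' the inverse observed information at the optimum. Complete separation
#' (a perfect 0/1 split along the dose axis) is detected and flagged; such
#' fits carry no usable covariance and callers fall back to
#' [se_fallback()].
#'
#' @param groups `dose_group_summary` data.frame (needs `total_dose`,
#'   `n_eff`, `r_eff`; at least two distinct dose levels)
#' @param covariate "dose" (default, the scale on which ED50s are quoted)
#'   or "log_dose"
#' @return object of class `logistic_fit`: `coef` (b0, b1), `vcov`,
#'   `loglik`, `converged`, `separated`, `groups`
#' @export
#' @examples
#' g <- data.frame(total_dose = c(10, 15, 20),
#'                 n_eff = 1000, r_eff = 1000 * c(0.1, 0.5, 0.9))
#' fit <- fit_logistic(g)
#' ed50(fit)
fit_logistic <- function(groups, covariate = c("dose", "log_dose")) {
  covariate <- match.arg(covariate)
  g <- groups[groups$n_eff > 0, , drop = FALSE]
  if (length(unique(g$total_dose)) < 2L)
    stop_ionrbe("need >= 2 distinct dose levels", "ionrbe_bad_argument")
  x <- if (covariate == "dose") g$total_dose else log(g$total_dose)
  r <- g$r_eff
  n <- g$n_eff
  stopifnot(all(r >= -1e-9), all(r <= n + 1e-9))
  r <- pmin(pmax(r, 0), n)

  newton <- function(b) {
    ll <- logistic_loglik(b, x, r, n)
    for (it in 1:200) {
      p <- plogis(b[1] + b[2] * x)
      w <- n * p * (1 - p)
      grad <- c(sum(r - n * p), sum((r - n * p) * x))
      info <- matrix(c(sum(w), sum(w * x), sum(w * x), sum(w * x^2)), 2L)
      if (max(abs(grad)) < 1e-8 * max(1, sum(n)))
        return(list(b = b, ll = ll, info = info, converged = TRUE))
      step <- tryCatch(solve(info, grad), error = function(e) NULL)
      if (is.null(step)) return(list(b = b, ll = ll, info = info,
                                     converged = FALSE))
      s <- 1
      repeat {                                    # damping
        bn <- b + s * step
        lln <- logistic_loglik(bn, x, r, n)
        if (is.finite(lln) && lln >= ll - 1e-12) break
        s <- s / 2
        if (s < 1e-10) return(list(b = b, ll = ll, info = info,
                                   converged = FALSE))
      }
      b <- bn; ll <- lln
    }
    list(b = b, ll = ll, info = info, converged = FALSE)
  }

  # start: weighted empirical-logit line, then documented restarts
  z <- log((r + 0.5) / (n - r + 0.5))
  sl <- tryCatch(coef(lm(z ~ x, weights = n)), error = function(e) c(0, 0.5))
  starts <- list(c(sl[1], max(sl[2], 1e-3)),
                 c(-mean(x), 1), c(0, 0.1), c(0, 1))
  best <- NULL
  for (b0 in starts) {
    fit <- newton(as.numeric(b0))
    if (is.null(best) || fit$ll > best$ll) best <- fit
    if (best$converged) break
  }

  p_hat <- plogis(best$b[1] + best$b[2] * x)
  separated <- abs(best$b[2]) * diff(range(x)) > 100 &&
    all(pmin(p_hat, 1 - p_hat) < 1e-4 | abs(r / n - p_hat) < 1e-6)
  vc <- tryCatch(solve(best$info), error = function(e) matrix(NA_real_, 2, 2))
  if (separated) vc[] <- NA_real_

  structure(list(coef = setNames(as.numeric(best$b), c("b0", "b1")),
                 vcov = vc, loglik = best$ll, converged = best$converged,
                 separated = separated, covariate = covariate, groups = g),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> b0 = %.4g, b1 = %.4g /Gy, loglik = %.3f%s\n",
              x$coef[1], x$coef[2], x$loglik,
              if (x$separated) " [SEPARATED]" else ""))
  invisible(x)
}

#' ED50 with delta-method standard error
#'
#' ED50 = -b0/b1; SE via the delta method on the fit covariance.
#'
#' @param fit a [fit_logistic()] result
#' @param level confidence level for the Fieller limits (default 0.90)
#' @return object of class `ed50_result`: `ed50`, `se`, `cl`, `level`,
#'   `method` ("delta"), `cl_bounded`
#' @export
ed50 <- function(fit, level = 0.90) {
  stopifnot(inherits(fit, "logistic_fit"))
  b <- fit$coef
  if (fit$separated || !is.finite(b[2]) || b[2] <= 0)
    stop_ionrbe("slope not positive (or separated fit); use the fallback path",
                "ionrbe_degenerate_fit")
  est <- -b[1] / b[2]
  se <- ratio_delta_se(b[1], b[2], fit$vcov[1, 1], fit$vcov[2, 2],
                       fit$vcov[1, 2])
  cl <- fieller_cl(fit, level)
  structure(list(ed50 = unname(est), se = unname(se), cl = cl,
                 level = level, method = "delta",
                 cl_bounded = attr(cl, "bounded")),
            class = "ed50_result")
}

#' @export
print.ed50_result <- function(x, ...) {
  cat(sprintf("ED50 = %.3f +/- %.3f Gy (%d%% CL %.3f - %.3f, %s)\n",
              x$ed50, x$se, round(100 * x$level), x$cl[1], x$cl[2], x$method))
  invisible(x)
}

#' Fieller confidence limits for ED50
#'
#' Roots in rho of (b0 + rho b1)^2 = z^2 (v00 + 2 rho v01 + rho^2 v11).
#' When the discriminant is negative or the slope is not significant at
#' the level (unbounded set), returns (-Inf, Inf) flagged unbounded --
#' the analogue of the study's "CL could not be calculated" entries.
#'
#' @inheritParams ed50
#' @return length-2 vector (low, high) with attribute `bounded`
#' @export
fieller_cl <- function(fit, level = 0.90) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (any(!is.finite(fit$vcov)))
    return(structure(c(low = -Inf, high = Inf), bounded = FALSE))
  fieller_ratio(a = -fit$coef[1], b = fit$coef[2],
                va = fit$vcov[1, 1], vb = fit$vcov[2, 2],
                vab = -fit$vcov[1, 2], level = level)
}

#' Fallback ED50 standard error from the response-level gap
#'
#' When the ML standard error is unavailable (separation), the SE is
#' estimated as 25 % of the dose difference between the neighbouring 0 %
#' and 100 % response levels.
#'
#' @param groups `dose_group_summary` data.frame with `total_dose` and
#'   `p_actuarial`
#' @return SE in Gy
#' @export
#' @examples
#' se_fallback(data.frame(total_dose = 12:15,
#'                        p_actuarial = c(0, 0, 1, 1)))  # 0.25
se_fallback <- function(groups) {
  g <- groups[order(groups$total_dose), , drop = FALSE]
  ones <- which(g$p_actuarial >= 1 - 1e-9)
  if (length(ones) == 0L)
    stop_ionrbe("no 100% response level", "ionrbe_no_jump")
  d1 <- g$total_dose[min(ones)]
  zeros <- which(g$p_actuarial <= 1e-9 & g$total_dose < d1)
  if (length(zeros) == 0L)
    stop_ionrbe("no 0% response level below the first 100% level",
                "ionrbe_no_jump")
  0.25 * (d1 - max(g$total_dose[zeros]))
}

#' ED50 estimate with automatic fallback path
#'
#' Tries the ML delta/Fieller route; on separation (or a non-positive
#' slope) the point estimate becomes the midpoint of the 0-to-100 %% jump,
#' the SE comes from [se_fallback()], and the CL is the normal interval --
#' the procedure the study used when the ML SE could not be computed.
#'
#' @param groups `dose_group_summary` data.frame
#' @param level confidence level
#' @param covariate passed to [fit_logistic()]
#' @return `ed50_result` (method "delta" or "fallback")
#' @export
estimate_ed50 <- function(groups, level = 0.90, covariate = "dose") {
  fit <- tryCatch(fit_logistic(groups, covariate), error = function(e) NULL)
  res <- if (!is.null(fit))
    tryCatch(ed50(fit, level), error = function(e) NULL)
  if (!is.null(res)) return(res)
  g <- groups[order(groups$total_dose), , drop = FALSE]
  ones <- which(g$p_actuarial >= 0.5)
  if (length(ones) == 0L || min(ones) == 1L)
    stop_ionrbe("cannot locate the response jump for the fallback estimate",
                "ionrbe_no_jump")
  mid <- mean(g$total_dose[c(min(ones) - 1L, min(ones))])
  se <- tryCatch(se_fallback(g), error = function(e) {
    0.25 * diff(g$total_dose[c(min(ones) - 1L, min(ones))])
  })
  z <- qnorm(1 - (1 - level) / 2)
  structure(list(ed50 = mid, se = se,
                 cl = structure(c(low = mid - z * se, high = mid + z * se),
                                bounded = TRUE),
                 level = level, method = "fallback", cl_bounded = TRUE),
            class = "ed50_result")
}

#' Linear trend of response latency with LET
#'
#' Ordinary least-squares regression of a latency summary (minimum or mean
#' days per position) on LET with a two-sided test of zero slope. Used to
#' check that latency does not depend on radiation quality.
#'
#' @param let_value LET values, keV/um (>= 3 distinct)
#' @param days latency summaries, days
#' @return list with `slope`, `se`, `p_value`, `fit`
#' @export
latency_trend <- function(let_value, days) {
  stopifnot(length(let_value) == length(days))
  if (length(unique(let_value)) < 3L)
    stop_ionrbe("need >= 3 distinct LET values", "ionrbe_bad_argument")
  fit <- lm(days ~ let_value)
  sm <- suppressWarnings(summary(fit))   # degenerate exact fits handled below
  slope <- unname(coef(fit)[2])
  if (sm$sigma < 1e-10) {     # degenerate: exact fit
    p <- if (abs(slope) < 1e-10) 1 else 0
    se <- 0
  } else {
    se <- sm$coefficients[2, 2]
    p <- sm$coefficients[2, 4]
  }
  list(slope = slope, se = se, p_value = p, fit = fit)
}
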