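#' @keywords internal
"_PACKAGE"

#' @importFrom stats qnorm plogis qlnorm plnorm qexp runif lm coef vcov
#'   integrate optimHess nlminb pchisq uniroot approx setNames rnorm
#'   fitted
#' @importFrom utils read.csv write.csv packageVersion head
NULL

## unit constant: 1 keV/um deposited over 1 um^2 in unit-density water equals
## 0.1602 Gy * um^2 (1 keV = 1.602e-16 J, 1 um^3 water = 1e-18 kg)
KEV_UM_TO_GY_UM2 <- 0.1602

stop_ionrbe <- function(msg, class) {
  stop(structure(class = c(class, "ionrbe_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict = FALSE, allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (allow_inf || is.finite(x))
  if (ok) {
    ok <- if (allow_inf && is.infinite(x)) x > lower
          else if (strict) x > lower && x < upper
          else x >= lower && x <= upper
  }
  if (!ok) stop_ionrbe(sprintf("`%s` must be a number in %s%s, %s%s; got %s",
                               name, if (strict) "(" else "[", lower, upper,
                               if (strict) ")" else "]",
                               deparse(substitute(x))), "ionrbe_bad_argument")
  invisible(x)
}

## Fieller confidence set for a ratio a/b of jointly normal estimates.
## Roots of (a - rho*b)^2 = z^2 (va - 2 rho vab + rho^2 vb).
## Returns c(low, high) with attr "bounded"; unbounded sets come back as
## (-Inf, Inf) flagged FALSE, matching the paper's "CL could not be
## calculated" entries.
fieller_ratio <- function(a, b, va, vb, vab = 0, level = 0.90) {
  check_number(level, "level", 0, 1, strict = TRUE)
  z2 <- qnorm(1 - (1 - level) / 2)^2
  A <- b^2 - z2 * vb
  B <- a * b - z2 * vab
  C <- a^2 - z2 * va
  disc <- B^2 - A * C
  if (!is.finite(A) || A <= 0 || disc < 0) {
    return(structure(c(low = -Inf, high = Inf), bounded = FALSE))
  }
  r <- sort(c((B - sqrt(disc)) / A, (B + sqrt(disc)) / A))
  structure(c(low = r[1], high = r[2]), bounded = TRUE)
}

## Delta-method SE for the ratio -num/den from the 2x2 covariance of
## (num, den); used for ED50 = -b0/b1 and BED50 = -g0/g1.
ratio_delta_se <- function(num, den, v11, v22, v12) {
  g <- -num / den
  sqrt((v11 + 2 * g * v12 + g^2 * v22) / den^2)
}

## md5 of a serialized R object via a temp file (no extra deps)
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}
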