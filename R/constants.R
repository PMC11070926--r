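## Packaged study constants: the photon reference curve summaries (the
## photon raw data are external to the oxygen study and enter only as
## constants with SEs) and the published oxygen summary table used for
## ratio identities and model comparison.

constants_env <- new.env(parent = emptyenv())

read_extdata <- function(fname) {
  f <- system.file("extdata", fname, package = "ionrbe", mustWork = TRUE)
  utils::read.csv(f, comment.char = "#", stringsAsFactors = FALSE)
}

#' Photon reference constants
#'
#' ED50 for single and split schedules, pooled BED50 and alpha/beta of the
#' photon reference experiments, each with SE and 90 % CL.
#'
#' @return data.frame with one row per quantity (`quantity`, `value`,
#'   `se`, `cl_low`, `cl_high`)
#' @export
#' @examples
#' photon_reference()
photon_reference <- function() {
  if (is.null(constants_env$photon))
    constants_env$photon <- read_extdata("photon_reference.csv")
  constants_env$photon
}

photon_ref_value <- function(quantity) {
  p <- photon_reference()
  row <- p[p$quantity == quantity, ]
  if (nrow(row) != 1L)
    stop_ionrbe(paste("unknown photon quantity:", quantity),
                "ionrbe_bad_argument")
  list(value = row$value, se = row$se,
       cl = c(low = row$cl_low, high = row$cl_high))
}

#' Published oxygen ED50/RBE summary per LET and schedule
#'
#' @return data.frame: `let_value`, `depth`, `n_fractions`, `in_sobp`,
#'   `ed50`, `ed50_se`, `ed50_cl_low`, `ed50_cl_high`, `rbe`, `rbe_se`,
#'   `cl_low`, `cl_high`
#' @export
oxygen_ed50_summary <- function() {
  if (is.null(constants_env$ed50))
    constants_env$ed50 <- read_extdata("oxygen_ed50_summary.csv")
  constants_env$ed50
}

#' Published oxygen LQ summary (BED50, RBE_max, alpha/beta) per LET
#'
#' @return data.frame: `let_value`, `bed50`, `bed50_se`, `bed50_cl_low`,
#'   `bed50_cl_high`, `rbe_max`, `rbe_max_se`, `rbe_max_cl_low`,
#'   `rbe_max_cl_high`, `alpha_beta`, `ab_se`, `ab_cl_low`, `ab_cl_high`
#' @export
oxygen_lq_summary <- function() {
  if (is.null(constants_env$lq))
    constants_env$lq <- read_extdata("oxygen_lq_summary.csv")
  constants_env$lq
}
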