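## Animal-record CSV dialect (UTF-8, header row, '.' decimal) and JSON
## result writing. Schema violations are reported with column names and
## row numbers.

ANIMAL_COLUMNS <- c(
  animal_id = "character", radiation_label = "character",
  let_value = "numeric", depth = "numeric", n_fractions = "integer",
  total_dose = "numeric", responder = "logical", event_day = "numeric",
  followup_day = "numeric", excluded = "logical",
  exclusion_reason = "character")

#' Write an animal-record table to CSV
#'
#' @param records `animal_cohort` data.frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_animal_table <- function(records, path) {
  missing <- setdiff(names(ANIMAL_COLUMNS), names(records))
  if (length(missing))
    stop_ionrbe(paste("missing column(s):", paste(missing, collapse = ", ")),
                "ionrbe_schema")
  utils::write.csv(records[names(ANIMAL_COLUMNS)], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read an animal-record table from CSV
#'
#' Validates the schema; malformed numeric fields are reported with their
#' row number. `read_animal_table(write_animal_table(x, f))` is the
#' identity.
#'
#' @param path CSV file in the documented dialect
#' @return `animal_cohort` data.frame
#' @export
read_animal_table <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         fileEncoding = "UTF-8")
  missing <- setdiff(names(ANIMAL_COLUMNS), names(raw))
  if (length(missing))
    stop_ionrbe(paste("missing column(s):", paste(missing, collapse = ", ")),
                "ionrbe_schema")
  out <- raw[names(ANIMAL_COLUMNS)]
  for (col in names(ANIMAL_COLUMNS)) {
    type <- ANIMAL_COLUMNS[[col]]
    v <- out[[col]]
    if (type %in% c("numeric", "integer")) {
      blank <- !nzchar(v)
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!blank & is.na(conv))
      if (length(bad))
        stop_ionrbe(sprintf("column `%s`: malformed value '%s' at row %d",
                            col, v[bad[1L]], bad[1L]), "ionrbe_schema")
      out[[col]] <- if (type == "integer") as.integer(conv) else conv
    } else if (type == "logical") {
      conv <- as.logical(v)
      bad <- which(is.na(conv))
      if (length(bad))
        stop_ionrbe(sprintf("column `%s`: malformed value '%s' at row %d",
                            col, v[bad[1L]], bad[1L]), "ionrbe_schema")
      out[[col]] <- conv
    }
  }
  if (any(out$total_dose < 0, na.rm = TRUE))
    stop_ionrbe("negative doses present", "ionrbe_schema")
  class(out) <- c("animal_cohort", "data.frame")
  out
}

#' Write a results object as JSON
#'
#' Numbers are written at full precision (no rounding, no length-1
#' arrays); every bundle carries the package version.
#'
#' @param object list or data.frame of results
#' @param path output JSON file
#' @return `path`, invisibly
#' @export
write_results <- function(object, path) {
  payload <- list(package = "ionrbe",
                  version = as.character(utils::packageVersion("ionrbe")),
                  results = object)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}
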