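# CSV round-trip for cohort tables.  Schemas are fixed; unknown or missing
# columns are reported by name.

COHORT_SCHEMAS <- list(
  patients = c(patient_id = "character", sex = "character",
               birth_date = "Date", cart_start = "Date",
               regimen_nnrti = "integer", regimen_boosted_pi = "integer",
               regimen_nonboosted_pi = "integer", abacavir = "integer",
               hepatitis_bc = "integer"),
  labs = c(patient_id = "character", date = "Date",
           analyte = "character", value = "numeric"),
  events = c(patient_id = "character", date = "Date", event = "character"),
  treatments = c(patient_id = "character", start = "Date", stop = "Date",
                 classes = "character")
)

#' Write a cohort to a directory of CSV files
#'
#' Writes \code{patients.csv}, \code{labs.csv}, \code{events.csv} and
#' \code{treatments.csv} with ISO-8601 dates.  \code{read_cohort()} of the
#' result reproduces the cohort field-for-field.
#'
#' @param cohort a \code{\link{cohort_tables}} object.
#' @param directory output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "cd4_cohort"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (tab in names(COHORT_SCHEMAS)) {
    df <- cohort[[tab]]
    for (j in seq_along(df)) {
      if (inherits(df[[j]], "Date"))
        df[[j]] <- format(df[[j]], "%Y-%m-%d")
      else if (is.double(df[[j]]))
        df[[j]] <- formatC(df[[j]], digits = 15, format = "g")
    }
    path <- file.path(directory, paste0(tab, ".csv"))
    # quote only genuinely textual columns; stringified numerics must stay
    # bare so that read.csv(colClasses = "numeric") can parse them
    quote_cols <- which(unname(COHORT_SCHEMAS[[tab]]) %in%
                          c("character", "Date"))
    utils::write.csv(df, path, row.names = FALSE, quote = quote_cols)
    paths <- c(paths, path)
  }
  invisible(paths)
}

read_cohort_table <- function(directory, tab) {
  path <- file.path(directory, paste0(tab, ".csv"))
  if (!file.exists(path))
    stop("read_cohort: missing file ", path, call. = FALSE)
  schema <- COHORT_SCHEMAS[[tab]]
  header <- names(utils::read.csv(path, nrows = 0, check.names = FALSE))
  missing <- setdiff(names(schema), header)
  if (length(missing))
    stop("read_cohort: ", tab, ".csv is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(header, names(schema))
  if (length(extra))
    stop("read_cohort: ", tab, ".csv has unknown column(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  classes <- unname(schema)
  df <- utils::read.csv(path, colClasses = classes, check.names = FALSE,
                        stringsAsFactors = FALSE)
  df[, names(schema), drop = FALSE]
}

#' Read a cohort written by \code{write_cohort}
#'
#' @param directory directory holding the four CSV files.
#' @param pretreatment_window_days validation window, see
#'   \code{\link{cohort_tables}}.
#' @return a \code{\link{cohort_tables}} object.
#' @export
read_cohort <- function(directory, pretreatment_window_days = 30) {
  cohort_tables(patients = read_cohort_table(directory, "patients"),
                labs = read_cohort_table(directory, "labs"),
                events = read_cohort_table(directory, "events"),
                treatments = read_cohort_table(directory, "treatments"),
                pretreatment_window_days = pretreatment_window_days)
}
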