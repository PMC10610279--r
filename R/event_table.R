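#' Event tables
#'
#' An event table is the canonical dataset of this package: one row per dosing
#' or observation event, in the NONMEM-style dialect with columns `ID`,
#' `TIME` (period-relative hours), `AMT` (mg, dose rows only), `DV`
#' (concentration in ug/L, observation rows only), `EVID` (1 = dose,
#' 0 = observation), `MDV`, `FORM` (formulation label), `PERIOD` and `BLQ`
#' (below-quantification flag on observation rows).
#'
#' @param df A data frame with the columns above.
#' @return The validated `event_table`.
#' @export
event_table <- function(df) {
  validate_event_table(df)
  class(df) <- c("event_table", "data.frame")
  df
}

event_table_columns <- function() {
  c("ID", "TIME", "AMT", "DV", "EVID", "MDV", "FORM", "PERIOD", "BLQ")
}

validate_event_table <- function(df) {
  missing_cols <- setdiff(event_table_columns(), names(df))
  if (length(missing_cols)) {
    stop("event table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$TIME < 0, na.rm = TRUE)) {
    stop("event table has negative TIME values", call. = FALSE)
  }
  if (!all(df$EVID %in% c(0L, 1L))) {
    stop("EVID must be 0 (observation) or 1 (dose)", call. = FALSE)
  }
  bad <- which(df$EVID == 1L & !is.na(df$DV))
  if (length(bad)) {
    stop("dose rows must have empty DV (rows ", paste(utils::head(bad, 5), collapse = ", "),
         ")", call. = FALSE)
  }
  bad <- which(df$EVID == 0L & !is.na(df$AMT))
  if (length(bad)) {
    stop("observation rows must have empty AMT (rows ",
         paste(utils::head(bad, 5), collapse = ", "), ")", call. = FALSE)
  }
  bad <- which(!is.na(df$AMT) & !is.na(df$DV))
  if (length(bad)) {
    stop("rows cannot carry both AMT and DV (rows ",
         paste(utils::head(bad, 5), collapse = ", "), ")", call. = FALSE)
  }
  sp <- split(df$TIME, list(df$ID, df$PERIOD), drop = TRUE)
  if (any(vapply(sp, is.unsorted, logical(1)))) {
    stop("TIME must be sorted within each subject x period", call. = FALSE)
  }
  invisible(df)
}

#' Write an event table as CSV
#'
#' Comma-separated, header, dot decimal; empty cells for the inapplicable
#' `AMT`/`DV` fields. `write_event_table()` followed by [read_event_table()]
#' round-trips bit-identically.
#'
#' @param x An `event_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(x, path) {
  validate_event_table(x)
  out <- as.data.frame(x)[, event_table_columns()]
  out$BLQ <- ifelse(is.na(out$BLQ), "", ifelse(out$BLQ, "1", "0"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read an event table from CSV
#'
#' Parses and validates the canonical NONMEM-style dialect (see
#' [event_table()]). Malformed files raise descriptive errors naming the
#' offending column or rows.
#'
#' @param path CSV file path.
#' @return An `event_table`.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing_cols <- setdiff(event_table_columns(), names(df))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$FORM <- as.character(df$FORM)
  for (col in c("ID", "TIME", "AMT", "DV", "EVID", "MDV", "PERIOD")) {
    if (!is.numeric(df[[col]]) && !all(is.na(df[[col]]))) {
      stop("column ", col, " must be numeric", call. = FALSE)
    }
  }
  df$EVID <- as.integer(df$EVID)
  df$MDV <- as.integer(df$MDV)
  df$ID <- as.integer(df$ID)
  df$PERIOD <- as.integer(df$PERIOD)
  df$BLQ <- ifelse(is.na(df$BLQ), NA, df$BLQ == 1)
  event_table(df)
}
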