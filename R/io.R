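# schema-validated CSV readers for the pipeline's file formats

check_columns <- function(df, path, required) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

check_no_na <- function(df, path, cols) {
  for (col in cols) {
    bad <- which(is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("%s: column '%s' has missing values at row(s) %s", path,
                   col, paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
  }
  invisible(df)
}

read_table_checked <- function(path, required, na_forbidden = required) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, path, required)
  check_no_na(df, path, na_forbidden)
  df
}

#' Read pipeline input tables with schema validation
#'
#' Errors name the offending file, column and rows. Timestamps are parsed
#' as UTC.
#'
#' @param path CSV file.
#' @return data.frame with parsed columns.
#' @name readers
NULL

#' @rdname readers
#' @export
read_relocations <- function(path) {
  df <- read_table_checked(path, c("group_id", "timestamp", "x_km", "y_km"))
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             format = "%Y-%m-%dT%H:%M:%SZ")
  check_no_na(df, path, "timestamp")
  df
}

#' @rdname readers
#' @export
read_individuals <- function(path) {
  df <- read_table_checked(path, c("individual_id", "group_id", "sex",
                                   "present_from", "present_to"),
                           na_forbidden = c("individual_id", "group_id"))
  df$present_from <- as.Date(df$present_from)
  df$present_to <- as.Date(df$present_to)
  bad <- which(df$present_from > df$present_to)
  if (length(bad))
    stop(sprintf("%s: present_from after present_to at row(s) %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  df
}

#' @rdname readers
#' @export
read_scans <- function(path) {
  df <- read_table_checked(path, c("scan_id", "timestamp", "individual_id"))
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             format = "%Y-%m-%dT%H:%M:%SZ")
  check_no_na(df, path, "timestamp")
  df
}

#' @rdname readers
#' @export
read_hunts <- function(path) {
  df <- read_table_checked(path, c("hunt_id", "timestamp", "x_km", "y_km",
                                   "prey", "catcher_group", "success"),
                           na_forbidden = c("hunt_id", "timestamp",
                                            "catcher_group", "success"))
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             format = "%Y-%m-%dT%H:%M:%SZ")
  check_no_na(df, path, "timestamp")
  df
}
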