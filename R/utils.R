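# Internal helpers shared across modules.

# Classed error constructor so callers can dispatch on failure mode.
.at_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(errorCondition(msg, class = c(paste0("aquatherm_", class), "aquatherm_error")))
}

.at_assert <- function(cond, class, fmt, ...) {
  if (!isTRUE(cond)) .at_stop(class, fmt, ...)
  invisible(TRUE)
}

# Parse ISO-8601-ish timestamps to POSIXct (UTC). Returns NA for rows that
# do not parse; callers decide whether that is fatal.
.at_parse_time <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  out
}

# Combine a Date (or parseable date string) and a decimal clock hour into a
# POSIXct instant on the UTC day.
.at_instant <- function(date, hour) {
  as.POSIXct(as.character(as.Date(date)), tz = "UTC") + hour * 3600
}

.at_check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    .at_stop("format", "%s is missing required column(s): %s",
             what, paste(missing, collapse = ", "))
  invisible(TRUE)
}

# Read a CSV that may carry '#'-prefixed header comments (e.g. the seed
# stamp written by the simulator).
.at_read_csv <- function(path, what) {
  .at_assert(file.exists(path), "io", "%s file not found: %s", what, path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  df
}
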