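# Internal helpers: time parsing, number formatting, assertions.

# Default local zone for the study site (fixed UTC-4; no DST ambiguity).
DVM_DEFAULT_TZ <- "Etc/GMT+4"

#' @keywords internal
abort_dvm <- function(msg, class) {
  stop(structure(
    class = c(class, "dvm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Parse ISO-8601 timestamps that carry an explicit UTC offset
# ("2016-08-16T12:00:00-04:00" or "...-0400"). Timestamps without an offset
# are accepted with a warning and interpreted as local UTC-4 clock time.
parse_time_iso <- function(x, tz = DVM_DEFAULT_TZ) {
  x <- trimws(x)
  has_offset <- grepl("([+-][0-9]{2}:?[0-9]{2}|Z)$", x)
  if (!all(has_offset)) {
    warning(sprintf(
      "%d timestamp(s) carry no UTC offset; assuming local clock time (%s)",
      sum(!has_offset), tz
    ), call. = FALSE)
  }
  out <- rep(as.POSIXct(NA), length(x))
  xo <- sub("Z$", "+0000", x)
  xo <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", xo)
  if (any(has_offset)) {
    p <- as.POSIXct(strptime(xo[has_offset], "%Y-%m-%dT%H:%M:%S%z", tz = "UTC"))
    out[has_offset] <- p
  }
  if (any(!has_offset)) {
    p <- as.POSIXct(strptime(x[!has_offset], "%Y-%m-%dT%H:%M:%S", tz = tz))
    out[!has_offset] <- p
  }
  attr(out, "tzone") <- tz
  out
}

# Format a POSIXct back to ISO-8601 with numeric offset, in its display zone.
format_time_iso <- function(t) {
  format(t, "%Y-%m-%dT%H:%M:%S%z", tz = attr(t, "tzone") %||% DVM_DEFAULT_TZ)
}

# Lossless decimal rendering of doubles for CSV round-trips.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Decimal clock hour (0-24) of a POSIXct in its display zone.
clock_hour <- function(t, tz = attr(t, "tzone") %||% DVM_DEFAULT_TZ) {
  as.numeric(format(t, "%H", tz = tz)) +
    as.numeric(format(t, "%M", tz = tz)) / 60 +
    as.numeric(format(t, "%S", tz = tz)) / 3600
}

# "HH:MM" -> decimal hour.
parse_clock <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L || anyNA(suppressWarnings(as.numeric(parts)))) {
    abort_dvm(sprintf("clock time '%s' is not HH:MM", x), "dvm_validation_error")
  }
  as.numeric(parts[1]) + as.numeric(parts[2]) / 60
}
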