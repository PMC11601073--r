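#' Construct a single vertical cast
#'
#' A cast is one profiling deployment of a sonde: depth-indexed fluorescence
#' (and optionally calibrated chlorophyll, temperature, salinity) at one
#' timestamp. Rows are canonically sorted by increasing depth; duplicate
#' depths within a cast are an error.
#'
#' @param cast_id Character scalar identifying the cast.
#' @param time POSIXct timestamp of the cast (one instant per cast). Character
#'   input is parsed as ISO-8601; an explicit UTC offset is expected, and
#'   offset-free times are assumed local (UTC-4) with a warning.
#' @param depth_m Numeric vector of sample depths in metres, positive
#'   downward, 0 at the surface.
#' @param fluorescence Raw sonde fluorescence (instrument units), same length
#'   as `depth_m`.
#' @param chl_ug_L Calibrated chlorophyll-a (ug/L), optional until a
#'   calibration has been applied.
#' @param temperature_C,salinity_PSU Optional hydrographic channels.
#' @return An object of class `dvm_cast`.
#' @export
cast <- function(cast_id, time, depth_m, fluorescence,
                 chl_ug_L = NULL, temperature_C = NULL, salinity_PSU = NULL) {
  if (is.character(time)) time <- parse_time_iso(time)
  n <- length(depth_m)
  chans <- list(
    fluorescence = fluorescence, chl_ug_L = chl_ug_L,
    temperature_C = temperature_C, salinity_PSU = salinity_PSU
  )
  for (nm in names(chans)) {
    v <- chans[[nm]]
    if (!is.null(v) && length(v) != n) {
      abort_dvm(sprintf("channel '%s' has length %d but %d depths", nm, length(v), n),
                "dvm_validation_error")
    }
  }
  if (anyNA(depth_m) || any(depth_m < 0)) {
    abort_dvm("depths must be non-missing and >= 0", "dvm_validation_error")
  }
  if (anyDuplicated(depth_m)) {
    abort_dvm(sprintf("duplicate depth within cast '%s'", cast_id),
              "dvm_validation_error")
  }
  ord <- order(depth_m)
  x <- list(
    cast_id = as.character(cast_id),
    time = time,
    depth_m = depth_m[ord],
    fluorescence = fluorescence[ord],
    chl_ug_L = if (!is.null(chl_ug_L)) chl_ug_L[ord],
    temperature_C = if (!is.null(temperature_C)) temperature_C[ord],
    salinity_PSU = if (!is.null(salinity_PSU)) salinity_PSU[ord]
  )
  class(x) <- "dvm_cast"
  x
}

#' @export
print.dvm_cast <- function(x, ...) {
  cat(sprintf(
    "<dvm_cast> %s @ %s: %d depths, %.2f-%.2f m%s\n",
    x$cast_id, format_time_iso(x$time), length(x$depth_m),
    min(x$depth_m), max(x$depth_m),
    if (is.null(x$chl_ug_L)) " (uncalibrated)" else ""
  ))
  invisible(x)
}

#' Construct a time-ordered series of casts
#'
#' One diel study: repeated casts at a fixed site of nominal bottom depth
#' `site_depth_m`. Cast times must be strictly increasing and no cast may
#' reach deeper than the site depth (plus a small tolerance).
#'
#' @param casts List of [cast()] objects.
#' @param site_depth_m Nominal bottom depth `d` in metres (> 0).
#' @param depth_tolerance_m Slack allowed beyond `site_depth_m` (default 0.25).
#' @return An object of class `dvm_cast_series`.
#' @export
cast_series <- function(casts, site_depth_m, depth_tolerance_m = 0.25) {
  if (!length(casts)) abort_dvm("a cast series needs at least one cast", "dvm_validation_error")
  if (!is.numeric(site_depth_m) || site_depth_m <= 0) {
    abort_dvm("site_depth_m must be > 0", "dvm_validation_error")
  }
  times <- do.call(c, lapply(casts, function(cc) cc$time))
  ord <- order(times)
  casts <- casts[ord]
  times <- times[ord]
  if (length(times) > 1 && any(diff(as.numeric(times)) <= 0)) {
    abort_dvm("cast times must be strictly increasing", "dvm_validation_error")
  }
  deepest <- max(vapply(casts, function(cc) max(cc$depth_m), numeric(1)))
  if (deepest > site_depth_m + depth_tolerance_m) {
    abort_dvm(sprintf("cast reaches %.2f m, deeper than site depth %.2f m",
                      deepest, site_depth_m), "dvm_validation_error")
  }
  structure(list(casts = casts, site_depth_m = site_depth_m),
            class = "dvm_cast_series")
}

#' @export
print.dvm_cast_series <- function(x, ...) {
  t0 <- x$casts[[1]]$time
  t1 <- x$casts[[length(x$casts)]]$time
  cat(sprintf("<dvm_cast_series> %d casts, %s to %s, site depth %.1f m\n",
              length(x$casts), format_time_iso(t0), format_time_iso(t1),
              x$site_depth_m))
  invisible(x)
}

#' @export
length.dvm_cast_series <- function(x) length(x$casts)

#' Construct a discrete bottle sample
#'
#' A whole-water sample taken at one time and depth, carrying extracted
#' chlorophyll and/or per-taxon cell counts, with optional per-cell carbon
#' weights used for biomass-fraction calculations.
#'
#' @param time POSIXct (or ISO-8601 character) sampling time.
#' @param depth_m Sample depth in metres (>= 0).
#' @param chl_ug_L Extracted chlorophyll-a (ug/L), optional.
#' @param taxon_counts Named numeric vector, cells/mL per taxon (>= 0).
#' @param carbon_per_cell Named numeric vector, pg C per cell, optional.
#' @return An object of class `dvm_discrete_sample`.
#' @export
discrete_sample <- function(time, depth_m, chl_ug_L = NA_real_,
                            taxon_counts = numeric(0),
                            carbon_per_cell = NULL) {
  if (is.character(time)) time <- parse_time_iso(time)
  if (is.na(depth_m) || depth_m < 0) {
    abort_dvm("sample depth must be >= 0", "dvm_validation_error")
  }
  if (length(taxon_counts) && any(taxon_counts < 0, na.rm = TRUE)) {
    abort_dvm("cell counts must be >= 0", "dvm_validation_error")
  }
  storage.mode(taxon_counts) <- "double"
  structure(list(
    time = time, depth_m = depth_m, chl_ug_L = chl_ug_L,
    taxon_counts = taxon_counts, carbon_per_cell = carbon_per_cell
  ), class = "dvm_discrete_sample")
}
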