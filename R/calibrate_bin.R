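#' Fit a fluorescence-to-chlorophyll calibration
#'
#' Ordinary least-squares fit of extracted chlorophyll against raw sonde
#' fluorescence from paired discrete samples:
#' `chl = slope * F + intercept`. One pooled fit is used per diel study;
#' per-cast fits would be underdetermined with the handful of bottle samples
#' available.
#'
#' @param fluorescence Raw fluorescence values (instrument units).
#' @param chl_ug_L Paired extracted chlorophyll-a (ug/L).
#' @param through_origin Force `intercept = 0` (default `FALSE`: full OLS).
#' @return An object of class `dvm_calibration` with fields `slope`
#'   (ug/L per fluorescence unit), `intercept` (ug/L), `r_squared`
#'   (squared Pearson correlation of the pairs) and `n_pairs`.
#' @export
fit_calibration <- function(fluorescence, chl_ug_L, through_origin = FALSE) {
  ok <- is.finite(fluorescence) & is.finite(chl_ug_L)
  f <- fluorescence[ok]
  y <- chl_ug_L[ok]
  n <- length(f)
  if (n < 2L) abort_dvm("calibration needs at least 2 pairs", "dvm_calibration_error")
  if (stats::var(f) == 0) {
    abort_dvm("calibration fluorescence values have zero variance", "dvm_calibration_error")
  }
  if (through_origin) {
    fit <- stats::lm.fit(cbind(F = f), y)
    slope <- unname(fit$coefficients[1])
    intercept <- 0
  } else {
    fit <- stats::lm.fit(cbind(intercept = 1, F = f), y)
    slope <- unname(fit$coefficients["F"])
    intercept <- unname(fit$coefficients["intercept"])
  }
  r2 <- if (stats::var(y) == 0) 1 else stats::cor(f, y)^2
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r2, n_pairs = n),
            class = "dvm_calibration")
}

#' @export
print.dvm_calibration <- function(x, ...) {
  cat(sprintf("<dvm_calibration> chl = %.4g * F + %.4g (r^2 = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_pairs))
  invisible(x)
}

#' Serialize / restore a calibration fit as YAML
#'
#' @param fit A `dvm_calibration`.
#' @param path YAML file path.
#' @return `write_calibration` returns `path` invisibly;
#'   `read_calibration` returns the `dvm_calibration`.
#' @export
write_calibration <- function(fit, path) {
  writeLines(yaml::as.yaml(unclass(fit), precision = 17L), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- yaml::read_yaml(path)
  structure(x[c("slope", "intercept", "r_squared", "n_pairs")],
            class = "dvm_calibration")
}

#' Apply a calibration to a cast
#'
#' Sets the cast's `chl_ug_L` channel to `slope * fluorescence + intercept`,
#' clipping negative predictions to zero (chlorophyll is a concentration)
#' with a warning. The raw fluorescence channel is retained.
#'
#' @param x A [cast()] or [cast_series()].
#' @param fit A `dvm_calibration` from [fit_calibration()].
#' @return The input with `chl_ug_L` populated.
#' @export
apply_calibration <- function(x, fit) {
  UseMethod("apply_calibration")
}

#' @export
apply_calibration.dvm_cast <- function(x, fit) {
  if (is.null(x$fluorescence)) {
    abort_dvm(sprintf("cast '%s' has no fluorescence channel", x$cast_id),
              "dvm_state_error")
  }
  chl <- fit$slope * x$fluorescence + fit$intercept
  if (any(chl < 0, na.rm = TRUE)) {
    warning(sprintf("cast '%s': %d negative calibrated value(s) clipped to 0",
                    x$cast_id, sum(chl < 0, na.rm = TRUE)), call. = FALSE)
    chl <- pmax(chl, 0)
  }
  x$chl_ug_L <- chl
  x
}

#' @export
apply_calibration.dvm_cast_series <- function(x, fit) {
  x$casts <- lapply(x$casts, apply_calibration, fit = fit)
  x
}

#' Average a cast's chlorophyll into fixed-width depth bins
#'
#' Bins are half-open intervals `[k*w, (k+1)*w)` anchored at the surface and
#' extending to the bottom depth; each bin's value is the arithmetic mean of
#' the chlorophyll samples falling in it, the bin centre is `(k + 0.5) * w`.
#' Bins containing no samples are recorded as `NA` and are skipped (never
#' treated as zero) by all downstream computations.
#'
#' @param cast A [cast()] with a populated `chl_ug_L` channel.
#' @param bin_width_m Bin width in metres (default 0.2).
#' @param bottom_depth_m Bottom depth `d` in metres; the binned profile spans
#'   `[0, bottom_depth_m)`.
#' @return An object of class `dvm_binned` with fields `cast_id`, `time`,
#'   `bin_width_m`, `bin_centers_m`, `chl_ug_L`, `bottom_depth_m`.
#' @export
bin_profile <- function(cast, bin_width_m = 0.2, bottom_depth_m) {
  stopifnot(inherits(cast, "dvm_cast"))
  if (is.null(cast$chl_ug_L)) {
    abort_dvm(sprintf("cast '%s' has no chl_ug_L channel; calibrate first", cast$cast_id),
              "dvm_state_error")
  }
  if (!is.numeric(bin_width_m) || bin_width_m <= 0) {
    abort_dvm("bin_width_m must be > 0", "dvm_validation_error")
  }
  n_bins <- ceiling(bottom_depth_m / bin_width_m - 1e-9)
  idx <- floor(cast$depth_m / bin_width_m) + 1L  # half-open [k*w, (k+1)*w)
  keep <- idx >= 1L & idx <= n_bins & !is.na(cast$chl_ug_L)
  if (!any(keep)) abort_dvm("no samples fall in any bin", "dvm_empty_profile_error")
  sums <- tapply(cast$chl_ug_L[keep], factor(idx[keep], levels = seq_len(n_bins)), mean)
  vals <- as.numeric(sums)
  structure(list(
    cast_id = cast$cast_id, time = cast$time,
    bin_width_m = bin_width_m,
    bin_centers_m = (seq_len(n_bins) - 0.5) * bin_width_m,
    chl_ug_L = vals,
    bottom_depth_m = bottom_depth_m
  ), class = "dvm_binned")
}

#' @export
print.dvm_binned <- function(x, ...) {
  cat(sprintf("<dvm_binned> %s @ %s: %d x %.2g m bins (%d sampled), d = %.1f m\n",
              x$cast_id, format_time_iso(x$time), length(x$bin_centers_m),
              x$bin_width_m, sum(!is.na(x$chl_ug_L)), x$bottom_depth_m))
  invisible(x)
}
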