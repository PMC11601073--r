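# Relative-chlorophyll profile: per-profile normalization by depth-integrated
# chlorophyll, homogeneity (CV) screening, and the depth of maximum z_max.

#' Depth-integrated chlorophyll of a binned profile
#'
#' Rectangle rule on the uniform bins: sum over non-missing bins of
#' `chl * bin_width`. With chlorophyll in ug/L (= mg/m^3) and depth in m the
#' result is mg/m^2. Missing bins are skipped, not treated as zero.
#'
#' @param profile A `dvm_binned` from [bin_profile()].
#' @return Depth-integrated chlorophyll (mg/m^2).
#' @export
depth_integral <- function(profile) {
  stopifnot(inherits(profile, "dvm_binned"))
  v <- profile$chl_ug_L
  if (all(is.na(v))) abort_dvm("all bins are missing", "dvm_empty_profile_error")
  sum(v[!is.na(v)]) * profile$bin_width_m
}

#' Coefficient of variation of a binned chlorophyll profile
#'
#' `100 * sd / mean` over the non-missing binned values. The sample (n-1)
#' standard deviation is the default; set `sd_type = "population"` for the
#' n denominator. Low CV means chlorophyll is nearly homogeneous with depth,
#' i.e. no unambiguous chlorophyll maximum exists.
#'
#' @param profile A `dvm_binned`.
#' @param sd_type `"sample"` (n-1, default) or `"population"` (n).
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(profile, sd_type = c("sample", "population")) {
  stopifnot(inherits(profile, "dvm_binned"))
  sd_type <- match.arg(sd_type)
  v <- profile$chl_ug_L
  v <- v[!is.na(v)]
  if (length(v) < 2L) {
    abort_dvm("CV needs at least 2 non-missing bins", "dvm_degenerate_profile_error")
  }
  m <- mean(v)
  if (m <= 0) abort_dvm("CV undefined for non-positive mean", "dvm_degenerate_profile_error")
  s <- stats::sd(v)
  if (sd_type == "population") s <- s * sqrt((length(v) - 1) / length(v))
  100 * s / m
}

#' Compute the relative-chlorophyll profile
#'
#' Divides each bin's chlorophyll by the profile's depth-integrated
#' chlorophyll, giving the proportion of the water column's chlorophyll found
#' at each depth per metre (units 1/m). The transform is invariant to
#' multiplying the whole profile by any positive constant, which is what
#' makes the chlorophyll-maximum depth trackable across casts despite
#' advective cast-to-cast changes in total biomass. Also computes the CV
#' homogeneity flag and the depth of maximum `z_max`.
#'
#' @param profile A `dvm_binned`.
#' @param cv_threshold_percent Profiles with CV at or below this are flagged
#'   homogeneous and excluded from rate calculations downstream (default 5).
#' @param sd_type Passed to [coefficient_of_variation()].
#' @param tie_break Passed to [find_zmax()].
#' @return An object of class `dvm_relchl` with fields `cast_id`, `time`,
#'   `bin_width_m`, `bin_centers_m`, `rel_chl_per_m`, `integral_mg_m2`,
#'   `cv_percent`, `z_max_m`, `is_homogeneous`.
#' @export
rel_chl <- function(profile, cv_threshold_percent = 5,
                    sd_type = c("sample", "population"),
                    tie_break = c("shallowest", "nearest_previous")) {
  stopifnot(inherits(profile, "dvm_binned"))
  integral <- depth_integral(profile)
  if (integral <= 0) {
    abort_dvm("depth-integrated chlorophyll is not positive", "dvm_degenerate_profile_error")
  }
  rel <- profile$chl_ug_L / integral
  out <- structure(list(
    cast_id = profile$cast_id, time = profile$time,
    bin_width_m = profile$bin_width_m,
    bin_centers_m = profile$bin_centers_m,
    rel_chl_per_m = rel,
    integral_mg_m2 = integral,
    cv_percent = coefficient_of_variation(profile, sd_type = match.arg(sd_type)),
    z_max_m = NA_real_, is_homogeneous = NA
  ), class = "dvm_relchl")
  out$z_max_m <- find_zmax(out, tie_break = match.arg(tie_break))
  out$is_homogeneous <- flag_homogeneous(out, cv_threshold_percent)
  out
}

#' Depth of the relative-chlorophyll maximum
#'
#' Returns the bin centre holding the largest relative chlorophyll value.
#' Exact ties go to the shallowest tied bin by default (a fixed,
#' deterministic rule; ties are measure-zero on real data). The alternative
#' `"nearest_previous"` mode resolves a tie to the tied bin closest to a
#' previously tracked maximum depth.
#'
#' @param rel A `dvm_relchl`.
#' @param tie_break Tie rule, `"shallowest"` (default) or `"nearest_previous"`.
#' @param previous_z_m Previous maximum depth, required for
#'   `"nearest_previous"`.
#' @return Depth in metres (one of `bin_centers_m`).
#' @export
find_zmax <- function(rel, tie_break = c("shallowest", "nearest_previous"),
                      previous_z_m = NULL) {
  stopifnot(inherits(rel, "dvm_relchl"))
  tie_break <- match.arg(tie_break)
  v <- rel$rel_chl_per_m
  if (all(is.na(v))) abort_dvm("all bins are missing", "dvm_empty_profile_error")
  top <- which(!is.na(v) & v == max(v, na.rm = TRUE))
  if (length(top) > 1L && tie_break == "nearest_previous") {
    if (is.null(previous_z_m)) {
      abort_dvm("tie_break = 'nearest_previous' needs previous_z_m", "dvm_validation_error")
    }
    top <- top[order(abs(rel$bin_centers_m[top] - previous_z_m))]
  }
  rel$bin_centers_m[top[1]]
}

#' Homogeneity flag from the CV screen
#'
#' `TRUE` when the profile's chlorophyll CV is at or below the threshold
#' (default 5%), marking a vertically near-homogeneous water column in which
#' no chlorophyll maximum can be identified unambiguously. Flagged profiles
#' are excluded from all migration-rate calculations.
#'
#' @param rel A `dvm_relchl`.
#' @param threshold_percent Exclusion threshold in percent (default 5).
#' @return Logical flag.
#' @export
flag_homogeneous <- function(rel, threshold_percent = 5) {
  stopifnot(inherits(rel, "dvm_relchl"))
  rel$cv_percent <= threshold_percent
}

#' @export
print.dvm_relchl <- function(x, ...) {
  cat(sprintf(
    "<dvm_relchl> %s @ %s: z_max %.2f m, CV %.1f%%%s, integral %.1f mg/m^2\n",
    x$cast_id, format_time_iso(x$time), x$z_max_m, x$cv_percent,
    if (isTRUE(x$is_homogeneous)) " (homogeneous, excluded)" else "",
    x$integral_mg_m2
  ))
  invisible(x)
}

#' Summarize relative-chlorophyll profiles as a data frame
#'
#' One row per profile with the quantities used for plotting and rate
#' estimation; suitable for CSV export.
#'
#' @param rel_profiles List of `dvm_relchl` objects.
#' @return A data.frame with columns `cast_id`, `time`, `z_max_m`,
#'   `cv_percent`, `is_homogeneous`, `integral_mg_m2`.
#' @export
relchl_table <- function(rel_profiles) {
  data.frame(
    cast_id = vapply(rel_profiles, function(p) p$cast_id, character(1)),
    time = format_time_iso(do.call(c, lapply(rel_profiles, function(p) p$time))),
    z_max_m = vapply(rel_profiles, function(p) p$z_max_m, numeric(1)),
    cv_percent = vapply(rel_profiles, function(p) p$cv_percent, numeric(1)),
    is_homogeneous = vapply(rel_profiles, function(p) p$is_homogeneous, logical(1)),
    integral_mg_m2 = vapply(rel_profiles, function(p) p$integral_mg_m2, numeric(1)),
    stringsAsFactors = FALSE
  )
}
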