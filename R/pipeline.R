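# End-to-end drivers: one call from a cast series to the rate table, and
# one from bottle samples to the proxy-validation statistics. These are the
# entry points the analysis scripts and the acceptance checks use.

#' Analysis configuration
#'
#' Collects the tunable thresholds of the rate-estimation pipeline with the
#' documented defaults: 0.2 m bins, 5% CV exclusion, 04:00-09:00 /
#' 16:00-20:00 ascent/descent windows, 1 m surface and bottom bands, 2.5 h
#' window grace.
#'
#' @param bin_width_m Depth bin width (m).
#' @param cv_threshold_percent Homogeneity exclusion threshold (%).
#' @param ascent_start,ascent_end,descent_start,descent_end Clock times.
#' @param surface_band_m,bottom_band_m Arrival/departure bands (m).
#' @param grace_h Window overhang for bounding profiles (h).
#' @return A list of class `dvm_config`.
#' @export
dvm_config <- function(bin_width_m = 0.2, cv_threshold_percent = 5,
                       ascent_start = "04:00", ascent_end = "09:00",
                       descent_start = "16:00", descent_end = "20:00",
                       surface_band_m = 1, bottom_band_m = 1, grace_h = 2.5) {
  structure(as.list(environment()), class = "dvm_config")
}

#' @rdname dvm_config
#' @param path YAML file path.
#' @export
write_dvm_config <- function(cfg, path) {
  writeLines(yaml::as.yaml(unclass(cfg), precision = 17L), path)
  invisible(path)
}

#' @rdname dvm_config
#' @param cfg A `dvm_config`.
#' @export
read_dvm_config <- function(path) {
  do.call(dvm_config, yaml::read_yaml(path))
}

#' Estimate migration rates from a cast series
#'
#' Runs the full chain: (optional) fluorescence calibration, 0.2 m depth
#' binning, relative-chlorophyll transform with CV screening, tracking of
#' the chlorophyll-maximum depth, and ascent/descent event detection with
#' mean and maximum rates per calendar day.
#'
#' @param series A [cast_series()].
#' @param config A [dvm_config()].
#' @param calibration Optional `dvm_calibration` applied to raw
#'   fluorescence first; omit when casts already carry `chl_ug_L`.
#' @param study Optional study label for the rate table.
#' @return List with `rel_profiles`, `track`, `events`, `rate_table`,
#'   `profile_table` (per-profile diagnostics from [relchl_table()]).
#' @export
estimate_dvm_rates <- function(series, config = dvm_config(),
                               calibration = NULL, study = NA_character_) {
  stopifnot(inherits(series, "dvm_cast_series"))
  if (!is.null(calibration)) series <- apply_calibration(series, calibration)
  rel_profiles <- lapply(series$casts, function(cc) {
    rel_chl(
      bin_profile(cc, bin_width_m = config$bin_width_m,
                  bottom_depth_m = series$site_depth_m),
      cv_threshold_percent = config$cv_threshold_percent
    )
  })
  track <- zmax_track(rel_profiles)
  windows <- list(
    migration_window("ascent", config$ascent_start, config$ascent_end),
    migration_window("descent", config$descent_start, config$descent_end)
  )
  events <- detect_events(
    track, site_depth_m = series$site_depth_m, windows = windows,
    surface_band_m = config$surface_band_m, bottom_band_m = config$bottom_band_m,
    grace_h = config$grace_h
  )
  list(
    rel_profiles = rel_profiles, track = track, events = events,
    rate_table = summarize_rates(events, study = study),
    profile_table = relchl_table(rel_profiles)
  )
}

#' Validate relative chlorophyll as a species proxy
#'
#' Pairs relative chlorophyll with relative focal-taxon abundance at the
#' sampled depths and times, and computes the Spearman rank correlation
#' between them. A strong positive correlation supports using the bulk
#' chlorophyll distribution to track the focal species' vertical position.
#'
#' @param rel_profiles List of `dvm_relchl` objects.
#' @param samples List of [discrete_sample()]s with focal-taxon counts.
#' @param focal Focal taxon name.
#' @param match_tolerance_min Cast-to-bottle matching tolerance (minutes).
#' @return List with `points` (the paired data.frame), `rho`, `p_value`,
#'   `n`, `method`.
#' @export
validate_proxy <- function(rel_profiles, samples, focal,
                           match_tolerance_min = 30) {
  points <- pair_depth_points(rel_profiles, samples, focal,
                              match_tolerance_min = match_tolerance_min)
  if (nrow(points) < 3L) {
    abort_dvm("fewer than 3 paired depth points", "dvm_validation_error")
  }
  s <- spearman_rho(points$rel_chl_per_m, points$rel_abundance_per_m)
  c(list(points = points), s)
}

#' Write a reproducibility manifest
#'
#' Records the package version, seed, and configuration used by a run so
#' outputs can be regenerated exactly.
#'
#' @param path YAML file path.
#' @param seed Seed used for the run.
#' @param config Any configuration list (serialized as-is).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, seed, config = list()) {
  yaml::write_yaml(list(
    package = "dvmtrack",
    version = as.character(utils::packageVersion("dvmtrack")),
    seed = seed,
    config = lapply(unclass(config), function(x) {
      if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
    })
  ), path)
  invisible(path)
}
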