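# Migration-rate estimation: track the depth of maximum relative chlorophyll
# through time, segment into dawn ascent / dusk descent events, and report
# pairwise, mean and maximum rates w = |dz|/dt (m/h).

#' Define an ascent or descent clock window
#'
#' Migrations are searched inside fixed local clock windows: by default
#' 04:00-09:00 for ascent and 16:00-20:00 for descent, matching when the
#' chlorophyll maximum consistently leaves the bottom before dawn and the
#' surface before dusk at the study site.
#'
#' @param kind `"ascent"` or `"descent"`.
#' @param start,end Clock times `"HH:MM"`; defaults depend on `kind`.
#' @return An object of class `dvm_window`.
#' @export
migration_window <- function(kind = c("ascent", "descent"), start = NULL, end = NULL) {
  kind <- match.arg(kind)
  defaults <- list(ascent = c("04:00", "09:00"), descent = c("16:00", "20:00"))
  start <- start %||% defaults[[kind]][1]
  end <- end %||% defaults[[kind]][2]
  s <- parse_clock(start)
  e <- parse_clock(end)
  if (s >= e) abort_dvm("window start must precede end within one day", "dvm_validation_error")
  structure(list(kind = kind, start_clock = start, end_clock = end,
                 start_hour = s, end_hour = e), class = "dvm_window")
}

#' Track the chlorophyll-maximum depth through a cast series
#'
#' One row per profile, in time order, with the z_max depth and the
#' homogeneity flag. Homogeneous profiles stay in the track (for plotting)
#' but are marked excluded and ignored by every rate computation.
#'
#' @param rel_profiles List of `dvm_relchl` objects from [rel_chl()].
#' @return A data.frame of class `dvm_zmax_track` with columns `time`
#'   (POSIXct), `z_max_m`, `is_homogeneous`.
#' @export
zmax_track <- function(rel_profiles) {
  if (length(rel_profiles) < 2L) {
    abort_dvm("a z_max track needs at least 2 profiles", "dvm_validation_error")
  }
  times <- do.call(c, lapply(rel_profiles, function(p) p$time))
  ord <- order(times)
  out <- data.frame(
    time = times[ord],
    z_max_m = vapply(rel_profiles, function(p) p$z_max_m, numeric(1))[ord],
    is_homogeneous = vapply(rel_profiles, function(p) p$is_homogeneous, logical(1))[ord]
  )
  class(out) <- c("dvm_zmax_track", "data.frame")
  out
}

#' Pairwise migration rates between adjacent retained profiles
#'
#' For every consecutive pair of retained (non-homogeneous) track entries,
#' computes the signed depth change `dz` (positive downward), the true
#' elapsed time `dt` (hours; excluded profiles in between are spanned, so
#' their time still counts), and the rate `w = |dz| / dt` in m/h.
#'
#' @param track A `dvm_zmax_track` from [zmax_track()].
#' @return A data.frame with one row per segment: `t0`, `t1`, `z0_m`,
#'   `z1_m`, `dt_h`, `dz_m`, `w_dvm_m_per_h`.
#' @export
pairwise_rates <- function(track) {
  keep <- !track$is_homogeneous
  tt <- track$time[keep]
  zz <- track$z_max_m[keep]
  if (length(tt) < 2L) {
    return(data.frame(t0 = tt[0], t1 = tt[0], z0_m = numeric(0), z1_m = numeric(0),
                      dt_h = numeric(0), dz_m = numeric(0), w_dvm_m_per_h = numeric(0)))
  }
  if (any(diff(as.numeric(tt)) <= 0)) {
    abort_dvm("track timestamps must be strictly increasing", "dvm_validation_error")
  }
  n <- length(tt)
  dt_h <- as.numeric(difftime(tt[-1], tt[-n], units = "hours"))
  dz <- zz[-1] - zz[-n]
  data.frame(
    t0 = tt[-n], t1 = tt[-1], z0_m = zz[-n], z1_m = zz[-1],
    dt_h = dt_h, dz_m = dz, w_dvm_m_per_h = abs(dz) / dt_h
  )
}

#' Detect one migration event within a clock window on one day
#'
#' For an ascent, finds the last retained profile whose chlorophyll maximum
#' sits in the bottom band (`z >= site_depth - bottom_band_m`) near the
#' window, then the first retained profile whose maximum has reached the
#' surface band (`z <= surface_band_m`); the event is the run of retained
#' profiles between them. Descent is symmetric (surface band to bottom
#' band). The bounding start profile may precede the clock window start by
#' up to `grace_h` hours (departures often just predate the nominal window
#' at coarse sampling), and the arrival may run past the window end by the
#' same grace.
#'
#' Status is `"observed"` when the event is resolved by more than two
#' profiles, `"max_suppressed"` when it is resolved by exactly two (the mean
#' rate is then reported but no maximum, which would be meaningless with a
#' single segment), and `"not_observed"` when no bracketing bottom-to-surface
#' (or surface-to-bottom) pair exists in the window.
#'
#' @param track A `dvm_zmax_track`.
#' @param window A [migration_window()].
#' @param site_depth_m Bottom depth of the site (m).
#' @param day A `Date` giving the calendar day of the window (local);
#'   default: the first day the track covers at the window start.
#' @param surface_band_m Depths at or above this count as "at the surface"
#'   (default 1 m).
#' @param bottom_band_m Depths within this of the bottom count as "at the
#'   bottom" (default 1 m).
#' @param grace_h Hours the bounding profiles may overhang the clock window
#'   (default 2.5).
#' @return An object of class `dvm_event`: list with `kind`, `day`,
#'   `segments` (as [pairwise_rates()]), `mean_rate_m_per_h`,
#'   `max_rate_m_per_h` (NA unless > 1 segment), `status`, `reason`.
#' @export
detect_event <- function(track, window, site_depth_m, day = NULL,
                         surface_band_m = 1, bottom_band_m = 1, grace_h = 2.5) {
  stopifnot(inherits(track, "dvm_zmax_track"), inherits(window, "dvm_window"))
  tz <- attr(track$time, "tzone") %||% DVM_DEFAULT_TZ
  if (is.null(day)) day <- as.Date(format(track$time[1], "%Y-%m-%d", tz = tz))
  w_start <- as.POSIXct(paste(format(day), window$start_clock), tz = tz)
  w_end <- as.POSIXct(paste(format(day), window$end_clock), tz = tz)

  empty_event <- function(reason) {
    structure(list(kind = window$kind, day = day,
                   segments = pairwise_rates(track)[0, ],
                   mean_rate_m_per_h = NA_real_, max_rate_m_per_h = NA_real_,
                   status = "not_observed", reason = reason),
              class = "dvm_event")
  }

  keep <- !track$is_homogeneous
  tt <- track$time[keep]
  zz <- track$z_max_m[keep]
  lo <- w_start - grace_h * 3600
  hi <- w_end + grace_h * 3600
  if (!any(tt >= lo & tt <= hi)) return(empty_event("insufficient coverage"))

  at_surface <- zz <= surface_band_m
  at_bottom <- zz >= site_depth_m - bottom_band_m
  from <- if (window$kind == "ascent") at_bottom else at_surface
  to <- if (window$kind == "ascent") at_surface else at_bottom

  # candidate arrivals: first profile in the destination band inside the
  # (grace-extended) window that has a departure-band profile before it
  arrivals <- which(to & tt >= lo & tt <= hi)
  for (j in arrivals) {
    starts <- which(from & tt < tt[j] & tt >= lo & tt <= w_end)
    if (!length(starts)) next
    i <- max(starts)  # last seen in the departure band
    idx <- seq(i, j)
    sub <- track[track$time >= tt[i] & track$time <= tt[j], , drop = FALSE]
    class(sub) <- class(track)
    segs <- pairwise_rates(sub)
    net_dz <- zz[j] - zz[i]
    if (window$kind == "ascent" && net_dz >= 0) next
    if (window$kind == "descent" && net_dz <= 0) next
    status <- if (nrow(segs) == 1L) "max_suppressed" else "observed"
    return(structure(list(
      kind = window$kind, day = day, segments = segs,
      mean_rate_m_per_h = mean(segs$w_dvm_m_per_h),
      max_rate_m_per_h = if (nrow(segs) > 1L) max(segs$w_dvm_m_per_h) else NA_real_,
      status = status,
      reason = if (status == "max_suppressed") "event resolved by only two profiles" else ""
    ), class = "dvm_event"))
  }
  empty_event(sprintf("no %s bracketing pair in window", window$kind))
}

#' @export
print.dvm_event <- function(x, ...) {
  if (x$status == "not_observed") {
    cat(sprintf("<dvm_event> %s %s: not observed (%s)\n", format(x$day), x$kind, x$reason))
  } else {
    cat(sprintf("<dvm_event> %s %s: mean %.2f m/h, max %s, %d segment(s)%s\n",
                format(x$day), x$kind, x$mean_rate_m_per_h,
                if (is.na(x$max_rate_m_per_h)) "suppressed" else sprintf("%.2f m/h", x$max_rate_m_per_h),
                nrow(x$segments),
                if (x$status == "max_suppressed") " [max suppressed]" else ""))
  }
  invisible(x)
}

#' Detect all migration events in a multi-day track
#'
#' Runs [detect_event()] for each calendar day the track covers and each
#' window kind, yielding one event (possibly `not_observed`) per day per
#' kind.
#'
#' @inheritParams detect_event
#' @param windows List of [migration_window()]s (default: the standard
#'   ascent and descent windows).
#' @return List of `dvm_event` objects.
#' @export
detect_events <- function(track, site_depth_m,
                          windows = list(migration_window("ascent"),
                                         migration_window("descent")),
                          surface_band_m = 1, bottom_band_m = 1, grace_h = 2.5) {
  tz <- attr(track$time, "tzone") %||% DVM_DEFAULT_TZ
  days <- unique(as.Date(format(track$time, "%Y-%m-%d", tz = tz)))
  out <- list()
  for (day in as.list(days)) {
    for (w in windows) {
      out[[length(out) + 1L]] <- detect_event(
        track, w, site_depth_m = site_depth_m, day = day,
        surface_band_m = surface_band_m, bottom_band_m = bottom_band_m,
        grace_h = grace_h
      )
    }
  }
  out
}

#' Tabulate detected migration events
#'
#' One row per event with its mean and maximum rate (m/h) and status;
#' mirrors the per-study ascent/descent rate tables such analyses report.
#'
#' @param events List of `dvm_event` objects.
#' @param study Optional study label recycled across rows.
#' @return A data.frame with columns `study`, `day`, `kind`,
#'   `mean_rate_m_per_h`, `max_rate_m_per_h`, `n_segments`, `status`,
#'   `reason`.
#' @export
summarize_rates <- function(events, study = NA_character_) {
  if (!length(events)) abort_dvm("no events to summarize", "dvm_validation_error")
  data.frame(
    study = rep(study, length(events)),
    day = as.Date(vapply(events, function(e) format(e$day), character(1))),
    kind = vapply(events, function(e) e$kind, character(1)),
    mean_rate_m_per_h = vapply(events, function(e) e$mean_rate_m_per_h, numeric(1)),
    max_rate_m_per_h = vapply(events, function(e) e$max_rate_m_per_h, numeric(1)),
    n_segments = vapply(events, function(e) nrow(e$segments), integer(1)),
    status = vapply(events, function(e) e$status, character(1)),
    reason = vapply(events, function(e) e$reason, character(1)),
    stringsAsFactors = FALSE
  )
}
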