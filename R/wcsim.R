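# Synthetic water column: a 1-D conservative advection-diffusion model of a
# vertically migrating chlorophyll layer, plus a cast-sampling observation
# operator with multiplicative heterogeneity and sensor noise. Used for
# parameter-recovery testing of the whole rate-estimation pipeline.

#' Simulation configuration
#'
#' Parameters of the forward model and observation operator. Defaults
#' emulate a shallow (6 m) estuarine bloom site profiled at 1-2 h intervals:
#' a coherent chlorophyll layer that ascends before dawn, holds near the
#' surface through midday, descends around dusk, and holds near the bottom
#' overnight, at swimming speeds of order 1-3 m/h.
#'
#' @param site_depth_m Water-column depth (m, default 6).
#' @param grid_dz_m Grid spacing (m, default 0.1).
#' @param step_dt_s Time step (s, default 30). Construction fails unless the
#'   combined stability condition `v*dt/dz + 2*K*dt/dz^2 <= 1` holds (the
#'   sufficient condition for positivity of explicit upwind transport).
#' @param v_ascend_m_per_h,v_descend_m_per_h True swimming speeds (m/h,
#'   defaults 1.3 and 1.4).
#' @param ascent_start,ascent_end,descent_start,descent_end Clock times
#'   "HH:MM" bounding the migration phases (defaults 04:00/09:00 and
#'   16:00/20:00).
#' @param diffusivity_m2_per_h Vertical eddy diffusivity (default 0.04,
#'   about 1e-5 m^2/s: weak interior mixing under the strong summer
#'   stratification in which these blooms form; the swimming layer stays
#'   coherent, as the field profiles show).
#' @param background_chl_ug_L Non-migrating background chlorophyll added at
#'   observation (default 5).
#' @param layer_sigma_m Initial Gaussian layer width (m, default 0.5).
#' @param layer_peak_ug_L Initial layer peak concentration (ug/L, default 80).
#' @param hold_band_m Velocity is zeroed once the layer centre enters this
#'   band around its surface/bottom hold depth (default 0.5 m), keeping the
#'   layer coherent instead of piling onto the boundary.
#' @param obs_noise_cv Per-depth multiplicative lognormal sensor noise CV
#'   (default 0.05).
#' @param heterogeneity_cv Per-cast lognormal total-biomass factor CV,
#'   emulating advection of patchy water past the fixed site (default 0.3).
#' @param cast_interval_h Hours between casts, in \[0.25, 4\] (default 1.5).
#' @param n_days Series duration in days (default 1).
#' @param start_date,start_clock Local start of the series (defaults
#'   "2016-08-16" and "12:00", i.e. a roughly 24 h study started at noon).
#' @param homogeneous_episodes List of `c(start_h, end_h)` intervals (hours
#'   since series start) during which the observed field is replaced by its
#'   depth mean before sampling, emulating strong mixing (default none).
#' @param focal_fraction Dominant-taxon biomass fraction at the layer peak
#'   (default 0.9).
#' @param cells_per_ug_chl Focal cell density per unit chlorophyll
#'   (cells/mL per ug/L, default 20).
#' @param carbon_per_cell Named vector of per-cell carbon (pg C/cell) for
#'   the focal and background taxa.
#' @param sensor_slope,sensor_intercept True sensor response used to emit
#'   raw fluorescence: `F = (chl - intercept)/slope` (defaults 2 and 0.5);
#'   a calibration fit should recover these.
#' @param seed RNG seed driving every random draw (default 1).
#' @return An object of class `dvm_sim_config`.
#' @export
simulation_config <- function(site_depth_m = 6, grid_dz_m = 0.1, step_dt_s = 30,
                              v_ascend_m_per_h = 1.3, v_descend_m_per_h = 1.4,
                              ascent_start = "04:00", ascent_end = "09:00",
                              descent_start = "16:00", descent_end = "20:00",
                              diffusivity_m2_per_h = 0.04,
                              background_chl_ug_L = 5,
                              layer_sigma_m = 0.5, layer_peak_ug_L = 80,
                              hold_band_m = 0.5,
                              obs_noise_cv = 0.05, heterogeneity_cv = 0.3,
                              cast_interval_h = 1.5, n_days = 1,
                              start_date = "2016-08-16", start_clock = "12:00",
                              homogeneous_episodes = list(),
                              focal_fraction = 0.9, cells_per_ug_chl = 20,
                              carbon_per_cell = c(Mpoly = 1500, Background = 20),
                              sensor_slope = 2, sensor_intercept = 0.5,
                              seed = 1L) {
  cfg <- as.list(environment())
  if (site_depth_m <= layer_sigma_m) {
    abort_dvm("site depth must exceed the layer width", "dvm_configuration_error")
  }
  if (obs_noise_cv < 0 || heterogeneity_cv < 0) {
    abort_dvm("noise CVs must be >= 0", "dvm_configuration_error")
  }
  if (cast_interval_h < 0.25 || cast_interval_h > 4) {
    abort_dvm("cast_interval_h must lie in [0.25, 4]", "dvm_configuration_error")
  }
  dt_h <- step_dt_s / 3600
  vmax <- max(abs(v_ascend_m_per_h), abs(v_descend_m_per_h))
  courant <- vmax * dt_h / grid_dz_m + 2 * diffusivity_m2_per_h * dt_h / grid_dz_m^2
  if (courant > 1 + 1e-12) {
    abort_dvm(sprintf(
      "stability condition violated: v*dt/dz + 2*K*dt/dz^2 = %.3f > 1 (reduce step_dt_s or coarsen grid_dz_m)",
      courant), "dvm_configuration_error")
  }
  for (w in list(c(ascent_start, ascent_end), c(descent_start, descent_end))) {
    if (parse_clock(w[1]) >= parse_clock(w[2])) {
      abort_dvm("migration window start must precede its end", "dvm_configuration_error")
    }
  }
  class(cfg) <- "dvm_sim_config"
  cfg
}

#' Serialize / restore a simulation configuration as YAML
#'
#' Numeric fields are written with 17 significant digits so the
#' configuration round-trips exactly.
#'
#' @param cfg A [simulation_config()].
#' @param path YAML file path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns the `dvm_sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$carbon_per_cell <- as.list(x$carbon_per_cell)
  writeLines(yaml::as.yaml(x, precision = 17L), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$carbon_per_cell <- unlist(x$carbon_per_cell)
  x$homogeneous_episodes <- lapply(x$homogeneous_episodes, as.numeric)
  do.call(simulation_config, x)
}

#' Migration velocity schedule
#'
#' Signed vertical velocity (m/h, positive downward) of the layer centre.
#' The diel cycle has two target-seeking phases: from `ascent_start` until
#' `descent_start` the layer swims upward at `v_ascend` until its centre
#' reaches the surface hold depth (`hold_band_m`), then holds; from
#' `descent_start` until the next `ascent_start` it swims downward at
#' `v_descend` until the centre reaches the bottom hold depth, then holds.
#' Swimming therefore continues past the nominal window end when the column
#' has not yet been crossed (a 6 m column at 1 m/h takes longer than the
#' 4-5 h windows); the windows' end times bound the estimator's search, not
#' the organism's behaviour.
#'
#' @param t POSIXct time (evaluated in its display zone).
#' @param cfg A [simulation_config()].
#' @param current_center Current layer-centre depth (m).
#' @return Velocity in m/h.
#' @export
velocity_schedule <- function(t, cfg, current_center) {
  h <- clock_hour(t)
  surface_hold <- cfg$hold_band_m
  bottom_hold <- cfg$site_depth_m - cfg$hold_band_m
  up <- h >= parse_clock(cfg$ascent_start) && h < parse_clock(cfg$descent_start)
  if (up) {
    if (current_center > surface_hold + 1e-9) return(-cfg$v_ascend_m_per_h)
  } else {
    if (current_center < bottom_hold - 1e-9) return(cfg$v_descend_m_per_h)
  }
  0
}

# Cell-wise swimming velocity: the schedule's speed, ramped to zero at the
# phase's hold depth so cells stagnate there instead of piling onto the
# boundary. Ramp width is half the hold band.
velocity_field <- function(t, cfg, z) {
  h <- clock_hour(t)
  ramp <- cfg$hold_band_m / 2
  up <- h >= parse_clock(cfg$ascent_start) && h < parse_clock(cfg$descent_start)
  if (up) {
    -cfg$v_ascend_m_per_h * pmin(pmax((z - cfg$hold_band_m) / ramp, 0), 1)
  } else {
    bottom_hold <- cfg$site_depth_m - cfg$hold_band_m
    cfg$v_descend_m_per_h * pmin(pmax((bottom_hold - z) / ramp, 0), 1)
  }
}

#' One forward step of the transport model
#'
#' First-order upwind advection plus explicit centred diffusion in
#' conservative (finite-volume) form with no-flux reflective boundaries at
#' the surface and bottom: total mass `sum(conc)*dz` is conserved to
#' rounding, and upwinding preserves positivity under the CFL conditions
#' enforced at configuration time.
#'
#' @param conc Concentration on the cell-centred grid (ug/L).
#' @param v Advection velocity (m/h, positive downward): a scalar, or one
#'   value per cell (interface velocities are the mean of the adjacent
#'   cells').
#' @param K Diffusivity (m^2/h).
#' @param dt_s Time step (s).
#' @param dz_m Grid spacing (m).
#' @return Updated concentration field.
#' @export
step_population <- function(conc, v, K, dt_s, dz_m) {
  dt_h <- dt_s / 3600
  if (max(abs(v)) * dt_h / dz_m + 2 * K * dt_h / dz_m^2 > 1 + 1e-12) {
    abort_dvm("stability condition violated in step_population", "dvm_configuration_error")
  }
  n <- length(conc)
  # interface fluxes (n-1 interior interfaces; boundary fluxes are zero)
  upper <- conc[-n]  # cell above each interface
  lower <- conc[-1]  # cell below
  v_int <- if (length(v) == 1L) rep(v, n - 1L) else (v[-n] + v[-1]) / 2
  adv <- ifelse(v_int >= 0, v_int * upper, v_int * lower)
  dif <- -K * (lower - upper) / dz_m
  flux <- adv + dif                      # positive = downward transport
  conc + dt_h / dz_m * (c(0, flux) - c(flux, 0))
}

#' Observe a cast from a concentration field
#'
#' Applies the observation operator
#' `obs(z) = L * conc(z) * eps(z) + background`, with `L` one per-cast
#' lognormal heterogeneity factor (mean 1, CV `heterogeneity_cv`) and
#' `eps` per-depth lognormal sensor noise (mean 1, CV `obs_noise_cv`), then
#' emits a [cast()] at grid resolution. Raw fluorescence is derived from
#' observed chlorophyll through the configured sensor response; the
#' `chl_ug_L` channel also carries the observed values so the cast can be
#' used directly or re-calibrated. Temperature and salinity are filled with
#' simple diel/tidal sinusoids (cosmetic only). Consumes RNG draws in
#' documented order: one for `L`, then one per depth for `eps`.
#'
#' @param conc Concentration field (ug/L) on the grid.
#' @param t POSIXct cast time.
#' @param cfg A [simulation_config()].
#' @param cast_id Cast identifier.
#' @return A list: `cast` (the observed [cast()]) and `L` (the
#'   heterogeneity factor drawn).
#' @export
sample_cast <- function(conc, t, cfg, cast_id = "C001") {
  n <- length(conc)
  z <- (seq_len(n) - 0.5) * cfg$grid_dz_m
  sdL <- sqrt(log(1 + cfg$heterogeneity_cv^2))
  sde <- sqrt(log(1 + cfg$obs_noise_cv^2))
  L <- stats::rlnorm(1, meanlog = -sdL^2 / 2, sdlog = sdL)
  eps <- stats::rlnorm(n, meanlog = -sde^2 / 2, sdlog = sde)
  obs <- L * conc * eps + cfg$background_chl_ug_L
  h <- clock_hour(t)
  temperature <- 28 + 2 * sin(pi * (h - 8) / 12) * exp(-z / 3)
  salinity <- 22 + 1.5 * sin(2 * pi * h / 12.42) * (z / cfg$site_depth_m)
  list(
    cast = cast(
      cast_id = cast_id, time = t, depth_m = z,
      fluorescence = (obs - cfg$sensor_intercept) / cfg$sensor_slope,
      chl_ug_L = obs, temperature_C = temperature, salinity_PSU = salinity
    ),
    L = L
  )
}

#' Run the forward model and emit a synthetic diel study
#'
#' Integrates the layer trajectory and transport model from the configured
#' start, observing a cast every `cast_interval_h` hours. During configured
#' homogeneous episodes the field is replaced by its depth mean before
#' sampling (the transport state itself is untouched), exercising the CV
#' filter downstream. Deterministic given `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return A list:
#'   `series` — the observed [cast_series()];
#'   `truth` — data.frame (time, true_center_depth_m, true_velocity_m_per_h,
#'     heterogeneity_factor, is_homogenized) at cast times;
#'   `fields` — matrix of true concentration fields (depth x cast), after
#'     any episode homogenization, for discrete-sample generation;
#'   `grid_z_m` — grid cell-centre depths.
#' @export
generate_series <- function(cfg) {
  stopifnot(inherits(cfg, "dvm_sim_config"))
  set.seed(cfg$seed)
  n <- round(cfg$site_depth_m / cfg$grid_dz_m)
  z <- (seq_len(n) - 0.5) * cfg$grid_dz_m

  # initial layer position from the start clock: at the surface hold depth
  # after the morning ascent, otherwise at the bottom hold depth
  h0 <- parse_clock(cfg$start_clock)
  center <- if (h0 >= parse_clock(cfg$ascent_end) && h0 < parse_clock(cfg$descent_end)) {
    cfg$hold_band_m
  } else {
    cfg$site_depth_m - cfg$hold_band_m
  }
  conc <- cfg$layer_peak_ug_L * exp(-(z - center)^2 / (2 * cfg$layer_sigma_m^2))

  t0 <- as.POSIXct(paste(cfg$start_date, cfg$start_clock), tz = DVM_DEFAULT_TZ)
  total_h <- cfg$n_days * 24
  cast_h <- seq(0, total_h, by = cfg$cast_interval_h)
  cast_steps <- round(cast_h * 3600 / cfg$step_dt_s)
  n_steps <- max(cast_steps)

  casts <- vector("list", length(cast_h))
  fields <- matrix(NA_real_, n, length(cast_h))
  truth <- data.frame(
    time = t0 + cast_h * 3600, true_center_depth_m = NA_real_,
    true_velocity_m_per_h = NA_real_, heterogeneity_factor = NA_real_,
    is_homogenized = FALSE
  )

  observe <- function(k, step) {
    t <- t0 + step * cfg$step_dt_s
    f <- conc
    homog <- any(vapply(cfg$homogeneous_episodes, function(ep) {
      cast_h[k] >= ep[1] && cast_h[k] <= ep[2]
    }, logical(1)))
    if (homog) f <- rep(mean(f), length(f))
    s <- sample_cast(f, t, cfg, cast_id = sprintf("C%03d", k))
    casts[[k]] <<- s$cast
    fields[, k] <<- f
    truth$true_center_depth_m[k] <<- center
    truth$true_velocity_m_per_h[k] <<- velocity_schedule(t, cfg, center)
    truth$heterogeneity_factor[k] <<- s$L
    truth$is_homogenized[k] <<- homog
  }

  next_cast <- 1L
  for (step in 0:n_steps) {
    if (next_cast <= length(cast_steps) && step == cast_steps[next_cast]) {
      observe(next_cast, step)
      next_cast <- next_cast + 1L
    }
    if (step == n_steps) break
    t <- t0 + step * cfg$step_dt_s
    v <- velocity_schedule(t, cfg, center)
    dt_h <- cfg$step_dt_s / 3600
    conc <- step_population(conc, velocity_field(t, cfg, z),
                            cfg$diffusivity_m2_per_h, cfg$step_dt_s, cfg$grid_dz_m)
    center <- min(max(center + v * dt_h, 0), cfg$site_depth_m)
  }

  list(
    series = cast_series(casts, site_depth_m = cfg$site_depth_m),
    truth = truth, fields = fields, grid_z_m = z
  )
}

#' Write / read the ground-truth trajectory
#'
#' @param truth The `truth` data.frame from [generate_series()].
#' @param path CSV path.
#' @return `write_truth` returns `path` invisibly; `read_truth` the
#'   data.frame.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  out$time <- format_time_iso(out$time)
  for (col in c("true_center_depth_m", "true_velocity_m_per_h", "heterogeneity_factor")) {
    out[[col]] <- fmt_num(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  data.frame(
    time = parse_time_iso(df$time),
    true_center_depth_m = as.numeric(df$true_center_depth_m),
    true_velocity_m_per_h = as.numeric(df$true_velocity_m_per_h),
    heterogeneity_factor = as.numeric(df$heterogeneity_factor),
    is_homogenized = as.logical(df$is_homogenized)
  )
}

#' Generate discrete bottle samples from simulated fields
#'
#' Draws focal-taxon counts as `Poisson(cells_per_ug_chl * L * conc(depth))`
#' and a uniformly distributed background taxon whose Poisson level is set
#' so that the focal biomass fraction at the layer peak is approximately
#' `cfg$focal_fraction`; attaches the configured carbon weights and an
#' extracted-chlorophyll value (`L * conc` + background, with 3% lognormal
#' extraction noise) usable for sensor calibration. `L` is the cast's
#' heterogeneity factor: a bottle fills with the same water the sonde
#' profiled, so both observations share the cast-level biomass factor.
#' Consumes RNG draws per sample in documented order: focal count,
#' background count, chlorophyll noise.
#'
#' @param cfg A [simulation_config()].
#' @param sim Output of [generate_series()] (for `fields` and `grid_z_m`).
#' @param times POSIXct times, a subset of the cast times.
#' @param depths Depths (m) to sample at each requested time.
#' @param seed RNG seed for the sampling draws (default `cfg$seed + 1`, a
#'   documented substream so cast and bottle noise are independent).
#' @return List of [discrete_sample()] objects (one per time x depth).
#' @export
generate_discrete_samples <- function(cfg, sim, times, depths,
                                      seed = cfg$seed + 1L) {
  set.seed(seed)
  cast_times <- as.numeric(sim$truth$time)
  focal <- names(cfg$carbon_per_cell)[1]
  bg <- names(cfg$carbon_per_cell)[2]
  # background count level: focal fraction ~ focal_fraction at the layer peak
  peak_cells <- cfg$cells_per_ug_chl * cfg$layer_peak_ug_L
  bg_cells <- peak_cells * cfg$carbon_per_cell[[focal]] *
    (1 - cfg$focal_fraction) /
    (cfg$focal_fraction * cfg$carbon_per_cell[[bg]])
  out <- list()
  for (t in as.list(times)) {
    k <- which(abs(cast_times - as.numeric(t)) < 1)
    if (!length(k)) {
      abort_dvm("requested sample time is not a cast time", "dvm_validation_error")
    }
    conc <- sim$fields[, k[1]] * sim$truth$heterogeneity_factor[k[1]]
    for (d in depths) {
      j <- which.min(abs(sim$grid_z_m - d))
      n_focal <- stats::rpois(1, cfg$cells_per_ug_chl * conc[j])
      n_bg <- stats::rpois(1, bg_cells)
      chl <- (conc[j] + cfg$background_chl_ug_L) *
        stats::rlnorm(1, meanlog = -log(1 + 0.03^2) / 2, sdlog = sqrt(log(1 + 0.03^2)))
      counts <- c(n_focal, n_bg)
      names(counts) <- c(focal, bg)
      out[[length(out) + 1L]] <- discrete_sample(
        time = t, depth_m = d, chl_ug_L = chl,
        taxon_counts = counts, carbon_per_cell = cfg$carbon_per_cell
      )
    }
  }
  out
}
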