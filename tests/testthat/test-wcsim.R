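test_that("CFL violations are rejected at configuration time", {
  expect_error(simulation_config(v_ascend_m_per_h = 10, step_dt_s = 60),
               class = "dvm_configuration_error")
  expect_error(simulation_config(diffusivity_m2_per_h = 1, grid_dz_m = 0.05,
                                 step_dt_s = 30),
               class = "dvm_configuration_error")
  expect_s3_class(simulation_config(), "dvm_sim_config")
})

test_that("simulation configs round-trip through YAML exactly", {
  cfg <- simulation_config(v_ascend_m_per_h = 1.37, seed = 99,
                           homogeneous_episodes = list(c(2, 4.5)))
  f <- withr::local_tempfile(fileext = ".yml")
  write_sim_config(cfg, f)
  back <- read_sim_config(f)
  for (nm in names(unclass(cfg))) expect_equal(back[[nm]], cfg[[nm]], info = nm)
})

test_that("the velocity schedule ascends at dawn, holds at midday", {
  cfg <- simulation_config()
  expect_equal(velocity_schedule(t_local("2016-08-16 05:00:00"), cfg, 5),
               -cfg$v_ascend_m_per_h)
  expect_equal(velocity_schedule(t_local("2016-08-16 12:00:00"), cfg, 0.5), 0)
  expect_equal(velocity_schedule(t_local("2016-08-16 17:00:00"), cfg, 2),
               cfg$v_descend_m_per_h)
  # at the hold depth the velocity switches off
  expect_equal(velocity_schedule(t_local("2016-08-16 05:00:00"), cfg, 0.5), 0)
})

test_that("the integrated daily trajectory closes on itself", {
  cfg <- simulation_config(v_ascend_m_per_h = 1.3, v_descend_m_per_h = 1.4)
  t0 <- t_local("2016-08-16 00:00:00")
  dt_h <- cfg$step_dt_s / 3600
  center <- cfg$site_depth_m - cfg$hold_band_m
  for (s in seq_len(24 * 3600 / cfg$step_dt_s)) {
    v <- velocity_schedule(t0 + (s - 1) * cfg$step_dt_s, cfg, center)
    center <- center + v * dt_h
  }
  expect_lt(abs(center - (cfg$site_depth_m - cfg$hold_band_m)), cfg$grid_dz_m)
})

test_that("the transport step is the identity with zero velocity and diffusivity", {
  conc <- c(0, 1, 5, 2, 0.5)
  expect_identical(step_population(conc, 0, 0, 30, 0.05), conc)
})

test_that("the transport step conserves mass over ten thousand steps", {
  set.seed(40)
  conc <- rlnorm(120, 1, 1)
  m0 <- sum(conc) * 0.05
  for (s in 1:5000) conc <- step_population(conc, 1.3, 0.02, 30, 0.05)
  for (s in 1:5000) conc <- step_population(conc, -1.3, 0.02, 30, 0.05)
  expect_equal(sum(conc) * 0.05, m0, tolerance = 1e-8)
  expect_true(all(conc >= 0))  # upwinding preserves positivity
})

test_that("pure diffusion spreads a pulse with variance 2Kt", {
  dz <- 0.05
  n <- 120
  z <- (seq_len(n) - 0.5) * dz
  conc <- numeric(n)
  conc[60] <- 1 / dz  # unit-mass pulse at mid-depth
  K <- 0.1
  steps <- 1 * 3600 / 30  # one hour
  for (s in seq_len(steps)) conc <- step_population(conc, 0, K, 30, dz)
  p <- conc * dz / sum(conc * dz)
  mu <- sum(p * z)
  v <- sum(p * (z - mu)^2)
  expect_equal(v, 2 * K * 1, tolerance = 0.05)
})

test_that("a noiseless observation is the field plus background", {
  cfg <- simulation_config(obs_noise_cv = 0, heterogeneity_cv = 0,
                           background_chl_ug_L = 0)
  conc <- seq(1, 120) / 10
  set.seed(1)
  s <- sample_cast(conc, t_local("2016-08-16 12:00:00"), cfg)
  expect_equal(s$cast$chl_ug_L, conc)
  expect_equal(s$L, 1)
  expect_equal(s$cast$fluorescence, (conc - cfg$sensor_intercept) / cfg$sensor_slope)
})

test_that("heterogeneity alone leaves relative chlorophyll unchanged end-to-end", {
  cfg <- simulation_config(obs_noise_cv = 0, heterogeneity_cv = 0.5,
                           background_chl_ug_L = 0)
  z <- (seq_len(60) - 0.5) * 0.1
  conc <- 80 * exp(-(z - 3)^2 / 0.5)
  set.seed(33)
  s <- sample_cast(conc, t_local("2016-08-16 12:00:00"), cfg)
  expect_false(isTRUE(all.equal(s$L, 1)))
  r_obs <- rel_chl(bin_profile(s$cast, bin_width_m = 0.2, bottom_depth_m = 6))
  truth_cast <- cast("T", s$cast$time, depth_m = z, fluorescence = conc, chl_ug_L = conc)
  r_true <- rel_chl(bin_profile(truth_cast, bin_width_m = 0.2, bottom_depth_m = 6))
  expect_equal(r_obs$rel_chl_per_m, r_true$rel_chl_per_m, tolerance = 1e-12)
  expect_identical(r_obs$z_max_m, r_true$z_max_m)
})

test_that("the observation noise factors have mean one", {
  cfg <- simulation_config(obs_noise_cv = 0.3, heterogeneity_cv = 0.4)
  set.seed(55)
  draws <- replicate(10000, sample_cast(5, t_local("2016-08-16 12:00:00"), cfg)$L)
  expect_equal(mean(draws), 1, tolerance = 0.01)
})

test_that("series generation is deterministic given the seed", {
  cfg <- simulation_config(seed = 123, n_days = 1, cast_interval_h = 2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cast_series(generate_series(cfg)$series, f1)
  write_cast_series(generate_series(cfg)$series, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a day at hourly casts yields 24-25 casts", {
  env <- quiet_sim()
  expect_true(length(env$sim$series) %in% 24:25)
  expect_equal(nrow(env$sim$truth), length(env$sim$series))
})

test_that("the layer centre stays in the water column and below the speed cap", {
  env <- quiet_sim()
  tr <- env$sim$truth
  expect_true(all(tr$true_center_depth_m >= 0 & tr$true_center_depth_m <= 6))
  vmax <- max(env$cfg$v_ascend_m_per_h, env$cfg$v_descend_m_per_h)
  expect_true(all(abs(tr$true_velocity_m_per_h) <= vmax))
})

test_that("homogenized episodes are recovered by the CV filter at zero noise", {
  cfg <- simulation_config(obs_noise_cv = 0, heterogeneity_cv = 0,
                           cast_interval_h = 1,
                           homogeneous_episodes = list(c(3, 6)), seed = 4)
  sim <- generate_series(cfg)
  res <- estimate_dvm_rates(sim$series)
  flagged <- res$profile_table$is_homogeneous
  expect_true(all(flagged[sim$truth$is_homogenized]))
  expect_true(any(sim$truth$is_homogenized))
})

test_that("truth records round-trip through CSV", {
  env <- quiet_sim()
  f <- withr::local_tempfile(fileext = ".csv")
  write_truth(env$sim$truth, f)
  back <- read_truth(f)
  expect_equal(back$true_center_depth_m, env$sim$truth$true_center_depth_m)
  expect_equal(as.numeric(back$time), as.numeric(env$sim$truth$time))
  expect_equal(back$is_homogenized, env$sim$truth$is_homogenized)
})

test_that("discrete samples follow the field's Poisson intensities", {
  env <- quiet_sim()
  cfg <- env$cfg
  sim <- env$sim
  # zero concentration -> zero focal counts almost surely
  zero_sim <- sim
  zero_sim$fields[, 1] <- 0
  s <- generate_discrete_samples(cfg, zero_sim, sim$truth$time[1], c(0.25, 3), seed = 8)
  expect_true(all(vapply(s, function(x) unname(x$taxon_counts["Mpoly"]), numeric(1)) == 0))

  # large kappa: relative abundance converges to the concentration shape
  big <- simulation_config(obs_noise_cv = 0, heterogeneity_cv = 0,
                           cast_interval_h = 1, cells_per_ug_chl = 1e5, seed = 11)
  depths <- c(0.25, 1.5, 3, 4.5, 5.75)
  sb <- generate_discrete_samples(big, sim, sim$truth$time[1], depths, seed = 9)
  counts <- vapply(sb, function(x) unname(x$taxon_counts["Mpoly"]), numeric(1))
  conc <- vapply(depths, function(d) sim$fields[which.min(abs(sim$grid_z_m - d)), 1],
                 numeric(1))
  dz <- c(depths[2] - depths[1], (depths[3:5] - depths[1:3]) / 2,
          depths[5] - depths[4])
  expect_equal(counts / sum(counts * dz), conc / sum(conc * dz), tolerance = 0.01)
})

test_that("generated samples are dominated by the focal taxon in the layer", {
  env <- quiet_sim()
  fracs <- vapply(1:30, function(k) {
    s <- generate_discrete_samples(env$cfg, env$sim, env$sim$truth$time[1],
                                   depths = 0.25, seed = 100 + k)[[1]]
    biomass_fraction(s, "Mpoly")
  }, numeric(1))
  expect_true(all(fracs >= 0.8 & fracs <= 1))
  expect_equal(mean(fracs), 0.9, tolerance = 0.05)
})
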