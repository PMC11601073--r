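# Shared fixture builders. All fixtures are generated in code; times use the
# site's fixed UTC-4 zone.

t_local <- function(x) as.POSIXct(x, tz = "Etc/GMT+4")

# A binned profile built directly from bin values (depths at bin centres).
binned_from_values <- function(values, bin_width_m = 0.2,
                               bottom_depth_m = length(values) * bin_width_m,
                               cast_id = "B1", time = t_local("2016-08-16 12:00:00")) {
  centers <- (seq_along(values) - 0.5) * bin_width_m
  cc <- cast(cast_id, time, depth_m = centers,
             fluorescence = values, chl_ug_L = values)
  bin_profile(cc, bin_width_m = bin_width_m, bottom_depth_m = bottom_depth_m)
}

# Bin values with an exact sample CV (percent), strictly positive.
values_with_cv <- function(cv_percent, n = 30, mean_chl = 20, seed = 42) {
  set.seed(seed)
  u <- as.numeric(scale(rnorm(n)))  # mean 0, sample sd 1
  mean_chl * (1 + cv_percent / 100 * u)
}

# A z_max track from parallel vectors of hours-offset, depth, and flag.
make_track <- function(hours, z, homog = rep(FALSE, length(z)),
                       origin = t_local("2016-08-16 00:00:00")) {
  out <- data.frame(time = origin + hours * 3600, z_max_m = z,
                    is_homogeneous = homog)
  class(out) <- c("dvm_zmax_track", "data.frame")
  out
}

# Small noiseless simulation shared by several tests (cached per session).
quiet_sim <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      cfg <- simulation_config(obs_noise_cv = 0, heterogeneity_cv = 0,
                               cast_interval_h = 1, seed = 11)
      memo <<- list(cfg = cfg, sim = generate_series(cfg))
    }
    memo
  }
})
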