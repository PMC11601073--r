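#!/usr/bin/env Rscript
# The core analysis: bin calibrated profiles to 0.2 m, normalize each by its
# depth-integrated chlorophyll, screen homogeneous profiles (CV <= 5%),
# track the depth of the relative-chlorophyll maximum, and report mean and
# maximum ascent/descent rates. Run after 02_calibrate.R.

library(dvmtrack)

out <- "results"
series <- read_cast_series(file.path(out, "sim_casts.csv"), site_depth_m = 6)
fit <- read_calibration(file.path(out, "calibration.yml"))
truth <- read_truth(file.path(out, "sim_truth.csv"))

# estimate from raw fluorescence through the fitted calibration
raw <- series
raw$casts <- lapply(raw$casts, function(cc) { cc$chl_ug_L <- NULL; cc })
config <- dvm_config()
res <- estimate_dvm_rates(raw, config = config, calibration = fit, study = "SIM")

utils::write.csv(res$profile_table, file.path(out, "profile_diagnostics.csv"),
                 row.names = FALSE)
utils::write.csv(res$rate_table, file.path(out, "rate_table.csv"), row.names = FALSE)
write_run_manifest(file.path(out, "manifest_rates.yml"), seed = NA, config = config)

cat("Per-event migration rates (m/h):\n")
print(res$rate_table[, c("day", "kind", "mean_rate_m_per_h", "max_rate_m_per_h",
                         "n_segments", "status")], row.names = FALSE)

obs <- res$rate_table[res$rate_table$status != "not_observed", ]
cat(sprintf("\nTruth: ascent 1.3 m/h, descent 1.4 m/h; recovered means are within\n"))
cat(sprintf("%.2f m/h of truth (depth bins quantize each endpoint by +/- 0.1 m).\n",
            max(abs(obs$mean_rate_m_per_h - c(1.4, 1.3)[match(obs$kind, c("descent", "ascent"))]))))
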