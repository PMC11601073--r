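# Validation of relative chlorophyll as a proxy for the focal species'
# vertical position: carbon-biomass dominance gating and the rank
# correlation between relative chlorophyll and relative cell abundance.

#' Carbon biomass fraction of a focal taxon in a bottle sample
#'
#' `(count_focal * carbon_focal) / sum_t(count_t * carbon_t)` using the
#' sample's per-taxon cell counts and user-supplied per-cell carbon weights.
#' Invariant to rescaling all carbon weights by a common factor.
#'
#' @param sample A [discrete_sample()] with counts for every taxon and a
#'   carbon weight for every counted taxon.
#' @param focal Name of the focal taxon.
#' @param carbon_per_cell Optional named vector of carbon weights
#'   (pg C/cell), overriding any weights stored on the sample.
#' @return Fraction in \[0, 1\].
#' @export
biomass_fraction <- function(sample, focal, carbon_per_cell = NULL) {
  counts <- sample$taxon_counts
  if (!length(counts)) abort_dvm("sample has no taxon counts", "dvm_validation_error")
  carbon <- carbon_per_cell %||% sample$carbon_per_cell
  missing_w <- setdiff(names(counts), names(carbon))
  if (length(missing_w)) {
    abort_dvm(sprintf("no carbon weight for counted taxon/taxa: %s",
                      paste(missing_w, collapse = ", ")), "dvm_configuration_error")
  }
  if (!(focal %in% names(counts))) {
    abort_dvm(sprintf("focal taxon '%s' not counted in sample", focal),
              "dvm_configuration_error")
  }
  biomass <- counts * carbon[names(counts)]
  unname(biomass[focal] / sum(biomass))
}

#' Gate a diel study on focal-taxon dominance
#'
#' A study is admissible when the focal taxon exceeds the biomass threshold
#' (default 80% of total phytoplankton carbon) at study initiation — the
#' condition that licenses bulk chlorophyll as a proxy for the one species.
#' Later records below threshold are reported with a warning but do not
#' invalidate a study that was initiated above threshold.
#'
#' @param records data.frame with columns `time` (POSIXct), and
#'   `biomass_fraction` (fraction of total carbon in \[0,1\]); optionally
#'   `abundance_cells_mL`.
#' @param threshold Dominance threshold as a fraction (default 0.8,
#'   pass requires strictly greater).
#' @return List with `pass` (logical, from the earliest record) and
#'   `report` (the records with a per-row `pass` column).
#' @export
gate_study <- function(records, threshold = 0.8) {
  if (!nrow(records)) abort_dvm("no dominance records", "dvm_validation_error")
  if (any(records$biomass_fraction < 0 | records$biomass_fraction > 1)) {
    abort_dvm("biomass fractions must lie in [0, 1]", "dvm_validation_error")
  }
  ord <- order(records$time)
  records <- records[ord, , drop = FALSE]
  records$pass <- records$biomass_fraction > threshold
  pass <- records$pass[1]
  if (pass && any(!records$pass)) {
    warning(sprintf(
      "%d later record(s) fall below the %.0f%% dominance threshold; study retained (gated at initiation)",
      sum(!records$pass), 100 * threshold), call. = FALSE)
  }
  list(pass = pass, report = records)
}

#' Pair relative chlorophyll with relative cell abundance at depth
#'
#' For each bottle sample carrying counts of the focal taxon, looks up the
#' relative chlorophyll at the nearest bin centre of the time-matched
#' relative-chlorophyll profile (nearest cast within `match_tolerance_min`),
#' and computes the focal taxon's relative abundance per metre at that
#' depth: `count_i / sum_j(count_j * dz_j)` over the depths sampled at the
#' same time, with `dz_j` the local depth spacing (midpoint rule; edge
#' depths take their single-sided spacing). Per profile time the relative
#' abundances integrate to 1.
#'
#' @param rel_profiles List of `dvm_relchl` objects.
#' @param samples List of [discrete_sample()]s with focal-taxon counts;
#'   sampling times must group into profile times with >= 2 depths each.
#' @param focal Focal taxon name.
#' @param match_tolerance_min Maximum cast-to-bottle time offset in minutes
#'   (default 30); unmatched profile times are dropped with a warning.
#' @return A data.frame with columns `time`, `depth_m`, `rel_chl_per_m`,
#'   `rel_abundance_per_m`.
#' @export
pair_depth_points <- function(rel_profiles, samples, focal,
                              match_tolerance_min = 30) {
  times <- do.call(c, lapply(samples, function(s) s$time))
  counts <- vapply(samples, function(s) {
    cnt <- s$taxon_counts[focal]
    if (is.na(cnt)) 0 else unname(cnt)
  }, numeric(1))
  depths <- vapply(samples, function(s) s$depth_m, numeric(1))
  prof_times <- do.call(c, lapply(rel_profiles, function(p) p$time))
  out <- NULL
  for (tkey in unique(as.numeric(times))) {
    sel <- which(as.numeric(times) == tkey)
    if (length(sel) < 2L) next  # relative abundance needs >= 2 depths
    dt_min <- abs(as.numeric(difftime(prof_times, times[sel[1]], units = "mins")))
    if (min(dt_min) > match_tolerance_min) {
      warning(sprintf("no cast within %g min of bottle time %s; %d point(s) dropped",
                      match_tolerance_min, format_time_iso(times[sel[1]]), length(sel)),
              call. = FALSE)
      next
    }
    prof <- rel_profiles[[which.min(dt_min)]]
    ord <- sel[order(depths[sel])]
    z <- depths[ord]
    cnt <- counts[ord]
    # local spacing: midpoint rule inside, single-sided at the edges
    n <- length(z)
    dz <- if (n == 2L) rep(diff(z), 2L) else {
      c(z[2] - z[1], (z[3:n] - z[1:(n - 2)]) / 2, z[n] - z[n - 1])
    }
    denom <- sum(cnt * dz)
    if (denom <= 0) next
    bin_idx <- vapply(z, function(zz) which.min(abs(prof$bin_centers_m - zz)), integer(1))
    out <- rbind(out, data.frame(
      time = times[ord], depth_m = z,
      rel_chl_per_m = prof$rel_chl_per_m[bin_idx],
      rel_abundance_per_m = cnt / denom
    ))
  }
  if (is.null(out)) {
    out <- data.frame(time = times[0], depth_m = numeric(0),
                      rel_chl_per_m = numeric(0), rel_abundance_per_m = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation with average ranks
#'
#' Pearson correlation of the average (mid-) ranks of the two variables.
#' The two-sided p-value uses the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on `n-2` degrees of freedom for
#' `n > 10`, and an exact permutation distribution (all `n!` orderings,
#' respecting ties through the average ranks) for `n <= 10`.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return List with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) abort_dvm("Spearman correlation needs >= 3 points", "dvm_validation_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_dvm("correlation undefined for constant input", "dvm_degenerate_input_error")
  }
  rx <- rank(x)  # average ranks for ties
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n > 10L) {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  } else {
    p <- exact_perm_p(rx, ry, rho)
    method <- "exact permutation"
  }
  list(rho = rho, p_value = min(p, 1), n = n, method = method)
}

# Exact two-sided permutation p-value for the rank correlation: proportion
# of the n! orderings of y-ranks with |rho| >= |rho_obs| (within fp slack).
exact_perm_p <- function(rx, ry, rho_obs) {
  n <- length(rx)
  perms <- all_permutations(n)
  # rho is affine in sum(rx * ry_perm); compute via matrix product
  s <- matrix(ry[perms], nrow = nrow(perms)) %*% rx
  mx <- mean(rx); my <- mean(ry)
  denom <- (n - 1) * stats::sd(rx) * stats::sd(ry)
  rho_all <- (as.numeric(s) - n * mx * my) / denom
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

# All permutations of 1..n as an n!-by-n integer matrix (n <= 10).
all_permutations <- function(n) {
  if (n > 10L) abort_dvm("permutation enumeration capped at n = 10", "dvm_validation_error")
  p <- matrix(1L, 1L, 1L)
  for (k in 2L:n) {
    m <- nrow(p)
    out <- matrix(0L, m * k, k)
    for (pos in seq_len(k)) {
      rows <- (pos - 1L) * m + seq_len(m)
      out[rows, pos] <- k
      out[rows, -pos] <- p
    }
    p <- out
  }
  p
}
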