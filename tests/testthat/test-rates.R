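test_that("the z_max track preserves order and homogeneity flags", {
  profiles <- list(
    rel_chl(binned_from_values(c(1, 2, 9, 2, 1), bottom_depth_m = 1,
                               time = t_local("2016-08-16 04:00:00"))),
    rel_chl(binned_from_values(values_with_cv(3, n = 5), bottom_depth_m = 1,
                               time = t_local("2016-08-16 06:00:00"))),
    rel_chl(binned_from_values(c(9, 2, 1, 1, 1), bottom_depth_m = 1,
                               time = t_local("2016-08-16 08:00:00")))
  )
  tr <- zmax_track(profiles[c(2, 1, 3)])  # shuffled input
  expect_equal(nrow(tr), 3)
  expect_equal(tr$is_homogeneous, c(FALSE, TRUE, FALSE))
  expect_equal(tr$z_max_m[1], 0.5)
  expect_equal(tr$z_max_m, vapply(profiles, function(p) p$z_max_m, numeric(1)))
})

test_that("the track equals per-profile z_max applied independently", {
  sim <- quiet_sim()$sim
  res <- estimate_dvm_rates(sim$series)
  indep <- vapply(res$rel_profiles, find_zmax, numeric(1))
  expect_equal(res$track$z_max_m, indep)
})

test_that("pairwise rates implement |dz|/dt over retained profiles", {
  tr <- make_track(c(4, 6), z = c(4.8, 2.4))
  seg <- pairwise_rates(tr)
  expect_equal(seg$w_dvm_m_per_h, 1.2)
  expect_equal(seg$dz_m, -2.4)
  expect_equal(seg$dt_h, 2)

  flat <- pairwise_rates(make_track(c(0, 1), z = c(3, 3)))
  expect_equal(flat$w_dvm_m_per_h, 0)
})

test_that("excluded profiles are spanned: dt is true elapsed time", {
  tr <- make_track(c(4, 5, 6), z = c(5, 3, 3.2), homog = c(FALSE, TRUE, FALSE))
  seg <- pairwise_rates(tr)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$dt_h, 2)
  expect_equal(seg$w_dvm_m_per_h, abs(3.2 - 5) / 2)
})

test_that("pairwise rates match a brute-force subsequence oracle", {
  set.seed(14)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    tr <- make_track(cumsum(runif(n, 0.5, 2.5)),
                     z = round(runif(n, 0.1, 5.9), 1),
                     homog = runif(n) < 0.3)
    seg <- pairwise_rates(tr)
    kept <- which(!tr$is_homogeneous)
    if (length(kept) < 2) {
      expect_equal(nrow(seg), 0)
      next
    }
    for (j in seq_len(length(kept) - 1)) {
      a <- kept[j]; b <- kept[j + 1]
      dt <- as.numeric(difftime(tr$time[b], tr$time[a], units = "hours"))
      expect_equal(seg$w_dvm_m_per_h[j], abs(tr$z_max_m[b] - tr$z_max_m[a]) / dt,
                   tolerance = 1e-12)
      expect_equal(seg$w_dvm_m_per_h[j] * seg$dt_h[j], abs(seg$dz_m[j]),
                   tolerance = 1e-12)
    }
  }
})

test_that("non-increasing timestamps are rejected", {
  tr <- make_track(c(4, 4), z = c(5, 3))
  expect_error(pairwise_rates(tr), class = "dvm_validation_error")
})

test_that("an ascent bracketed bottom-to-surface is detected with mean and max", {
  tr <- make_track(c(4, 6, 8), z = c(5.5, 3, 0.7))
  ev <- detect_event(tr, migration_window("ascent"), site_depth_m = 6)
  expect_equal(ev$status, "observed")
  expect_equal(nrow(ev$segments), 2)
  w <- c(2.5 / 2, 2.3 / 2)
  expect_equal(ev$mean_rate_m_per_h, mean(w))
  expect_equal(ev$max_rate_m_per_h, max(w))
  expect_lt(sum(ev$segments$dz_m), 0)  # net shallowing
})

test_that("a track that never leaves the surface band yields not_observed", {
  tr <- make_track(c(2, 4, 6, 8, 10), z = c(0.5, 0.7, 0.5, 0.9, 0.5))
  ev <- detect_event(tr, migration_window("ascent"), site_depth_m = 6)
  expect_equal(ev$status, "not_observed")
  expect_true(is.na(ev$mean_rate_m_per_h))
})

test_that("an event resolved by exactly two profiles suppresses the maximum", {
  tr <- make_track(c(5, 7.5), z = c(5.5, 0.5))
  ev <- detect_event(tr, migration_window("ascent"), site_depth_m = 6)
  expect_equal(ev$status, "max_suppressed")
  expect_equal(ev$mean_rate_m_per_h, 2)
  expect_true(is.na(ev$max_rate_m_per_h))
})

test_that("descent detection is symmetric and nets positive dz", {
  tr <- make_track(c(15.5, 17, 18.5, 20.5), z = c(0.5, 2.4, 4.1, 5.6))
  ev <- detect_event(tr, migration_window("descent"), site_depth_m = 6)
  expect_equal(ev$status, "observed")
  expect_equal(nrow(ev$segments), 3)
  expect_gt(sum(ev$segments$dz_m), 0)
  expect_equal(ev$mean_rate_m_per_h,
               mean(c(1.9 / 1.5, 1.7 / 1.5, 1.5 / 2)))
})

test_that("grace allows a departure just before the clock window", {
  tr <- make_track(c(3, 5, 7), z = c(5.5, 3, 0.7))  # departs 03:00
  ev <- detect_event(tr, migration_window("ascent"), site_depth_m = 6)
  expect_equal(ev$status, "observed")
  ev0 <- detect_event(tr, migration_window("ascent"), site_depth_m = 6, grace_h = 0.5)
  expect_equal(ev0$status, "not_observed")
})

test_that("a track with no profiles near the window is insufficient coverage", {
  tr <- make_track(c(12, 14), z = c(0.5, 0.5))
  ev <- detect_event(tr, migration_window("ascent"), site_depth_m = 6)
  expect_equal(ev$status, "not_observed")
  expect_match(ev$reason, "coverage")
})

test_that("inserting an extra homogeneous profile changes no reported rate", {
  set.seed(77)
  base_hours <- c(3.5, 5, 6.5, 8)
  base_z <- c(5.3, 3.8, 2.1, 0.6)
  ev0 <- detect_event(make_track(base_hours, base_z),
                      migration_window("ascent"), site_depth_m = 6)
  for (i in 1:10) {
    at <- runif(1, 3.6, 7.9)
    hrs <- c(base_hours, at)
    zz <- c(base_z, runif(1, 0, 6))
    hm <- c(rep(FALSE, 4), TRUE)
    ord <- order(hrs)
    ev <- detect_event(make_track(hrs[ord], zz[ord], hm[ord]),
                       migration_window("ascent"), site_depth_m = 6)
    expect_equal(ev$mean_rate_m_per_h, ev0$mean_rate_m_per_h)
    expect_equal(ev$max_rate_m_per_h, ev0$max_rate_m_per_h)
    expect_equal(ev$status, ev0$status)
  }
})

test_that("all-homogeneous tracks report not_observed downstream", {
  tr <- make_track(c(4, 6, 8), z = c(5.5, 3, 0.5), homog = rep(TRUE, 3))
  ev <- detect_event(tr, migration_window("ascent"), site_depth_m = 6)
  expect_equal(ev$status, "not_observed")
})

test_that("rate summaries recompute means and maxima correctly", {
  tr <- make_track(c(4, 5, 6, 7), z = c(5.5, 3.1, 2.3, 1.9))
  tr$z_max_m <- c(5.5, 3.1, 2.3, 0.5)
  ev <- detect_event(tr, migration_window("ascent"), site_depth_m = 6)
  expect_equal(ev$segments$w_dvm_m_per_h, c(2.4, 0.8, 1.8))

  # constructed event with the target arithmetic
  ev$segments$w_dvm_m_per_h <- c(2.4, 0.8, 0.4)
  ev$mean_rate_m_per_h <- mean(ev$segments$w_dvm_m_per_h)
  ev$max_rate_m_per_h <- max(ev$segments$w_dvm_m_per_h)
  tab <- summarize_rates(list(ev), study = "DSX")
  expect_equal(tab$mean_rate_m_per_h, 1.2)
  expect_equal(tab$max_rate_m_per_h, 2.4)
  expect_equal(tab$study, "DSX")

  single <- detect_event(make_track(c(5, 7), z = c(5.5, 0.5)),
                         migration_window("ascent"), site_depth_m = 6)
  tab2 <- summarize_rates(list(single))
  expect_equal(tab2$mean_rate_m_per_h, 2.5)
  expect_true(is.na(tab2$max_rate_m_per_h))

  set.seed(6)
  evs <- lapply(1:5, function(i) {
    hrs <- sort(runif(4, 3.5, 9))
    detect_event(make_track(hrs, z = c(5.5, 4, 2, 0.5)),
                 migration_window("ascent"), site_depth_m = 6)
  })
  tab3 <- summarize_rates(evs)
  for (k in seq_along(evs)) {
    expect_equal(tab3$mean_rate_m_per_h[k], mean(evs[[k]]$segments$w_dvm_m_per_h))
    expect_equal(tab3$n_segments[k], nrow(evs[[k]]$segments))
  }
})

test_that("multi-day tracks yield one event per day per kind", {
  sim <- quiet_sim()$sim
  res <- estimate_dvm_rates(sim$series)
  tab <- res$rate_table
  expect_equal(nrow(tab), 4)  # 2 days x ascent/descent
  expect_setequal(unique(tab$kind), c("ascent", "descent"))
  observed <- tab[tab$status == "observed", ]
  expect_equal(sort(observed$kind), c("ascent", "descent"))
})
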