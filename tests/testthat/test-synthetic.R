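test_that("trajectory simulation is deterministic and respects the corridor", {
  cfg <- synth_config(n_trials = 8, seed = 7)
  t1 <- simulate_trajectory(cfg)
  t2 <- simulate_trajectory(cfg)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$trials, t2$trials)

  expect_equal(nrow(t1$trials), 8)
  expect_true(all(t1$frames$position >= 0 & t1$frames$position <= 180))
  ## every traversal reaches the end of the track
  expect_true(all(t1$frames$position[t1$trials$end] == 180))
  ## frames evenly spaced at 1/frame_rate
  expect_equal(unique(round(diff(t1$frames$time), 10)), 1 / 3)
  ## position nondecreasing within monodirectional trials
  for (i in seq_len(nrow(t1$trials))) {
    p <- t1$frames$position[t1$trials$start[i]:t1$trials$end[i]]
    expect_true(all(diff(p) >= 0))
  }
})

test_that("zero-trial configuration yields an empty trajectory", {
  tr <- simulate_trajectory(synth_config(n_trials = 0, seed = 1))
  expect_equal(nrow(tr$frames), 0)
  expect_equal(nrow(tr$trials), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(frame_rate_hz = 0), "frame_rate_hz")
  expect_error(synth_config(corridor_length_cm = 170), "multiple")
  expect_error(synth_config(n_trials = -1), "n_trials")
})

test_that("cue map uses left-closed right-open zones with the end included", {
  zone <- make_cue_map(synth_config())
  expect_identical(zone(30), 0L)
  expect_identical(zone(60), 1L)
  expect_identical(zone(119.99), 1L)
  expect_identical(zone(120), 2L)
  expect_identical(zone(179.9), 2L)
  expect_identical(zone(180), 2L)
})

test_that("null signal and zero noise give constant traces at baseline", {
  cfg <- synth_config(n_trials = 3, seed = 2)
  tun <- make_tuning(2, 0, 2, config = cfg, amplitude = 0, noise_sd = 0,
                     seed = 3)
  ses <- simulate_session(cfg, tun)
  expect_true(all(ses$dff == 0))
  expect_true(all(ses$raw == 100))
})

test_that("trial-averaged profiles peak where the noiseless response peaks", {
  cfg <- synth_config(n_trials = 20, seed = 5)
  tun <- make_tuning(1, 0, 1, config = cfg, seed = 6)
  ses <- simulate_session(cfg, tun)
  trials <- find_running_trials(ses$trajectory)
  for (j in 1:2) {
    ## oracle: the analytic (noiseless) tuning curve convolved with the
    ## indicator kernel, mapped through the same binning
    rp_truth <- response_profile(
      compute_maps(ses$signal[, j], ses$trajectory, trials))
    rp_data <- response_profile(
      compute_maps(ses$dff[, j], ses$trajectory, trials))
    peak_truth <- rp_truth$bin_centers[which.max(rp_truth$rp)]
    peak_data <- rp_data$bin_centers[which.max(rp_data$rp)]
    expect_lte(abs(peak_data - peak_truth), 2.25 + 1e-9)
    ## the exported observable field center summarizes the same curve
    expect_lt(abs(ses$tuning$expected_center[j] - peak_truth),
              ses$tuning$expected_sigma[j])
  }
})

test_that("population simulation is reproducible and per-ROI streams are stable", {
  cfg <- synth_config(n_trials = 4, seed = 9)
  traj <- simulate_trajectory(cfg)
  tun <- make_tuning(2, 2, 2, config = cfg, seed = 10)
  s1 <- simulate_population(traj, tun, cfg, seed = 11)
  s2 <- simulate_population(traj, tun, cfg, seed = 11)
  expect_identical(s1$dff, s2$dff)
  ## dropping the last ROI leaves the other traces untouched
  s3 <- simulate_population(traj, tun[-nrow(tun), ], cfg, seed = 11)
  expect_identical(s3$dff, s1$dff[, -ncol(s1$dff)])
})

test_that("independent noise leaves residuals uncorrelated", {
  cfg <- synth_config(n_trials = 60, seed = 12)
  tun <- make_tuning(3, 0, 3, config = cfg, tuning_mode = "untuned", seed = 13)
  ses <- simulate_session(cfg, tun, shared_noise_gain = 0)
  cm <- stats::cor(ses$dff)
  off <- cm[upper.tri(cm)]
  expect_lt(max(abs(off)), 0.05)
})

test_that("shared noise induces distance-decaying correlations", {
  cfg <- synth_config(n_trials = 40, seed = 14)
  tun <- make_tuning(6, 0, 6, config = cfg, tuning_mode = "untuned", seed = 15)
  ses <- simulate_session(cfg, tun, shared_noise_gain = 1.5,
                          distance_corr_tau = 40)
  cm <- stats::cor(ses$dff)
  d <- as.matrix(stats::dist(cbind(tun$x_um, tun$y_um)))
  near <- d < 100 & upper.tri(d)
  far <- d > 250 & upper.tri(d)
  expect_gt(mean(cm[near]), mean(cm[far]))
  expect_gt(mean(cm[near]), 0.1)
})

test_that("cue-periodic rate repeats exactly with the cue period", {
  cfg <- synth_config()
  tun <- make_tuning(1, 0, 0, config = cfg, tuning_mode = "cue-periodic",
                     seed = 16)
  x <- seq(0, 59.9, by = 0.1)
  r0 <- astroplace:::tuning_rate(x, tun[1, ], cfg$cue_zone_length_cm)
  r1 <- astroplace:::tuning_rate(x + 60, tun[1, ], cfg$cue_zone_length_cm)
  r2 <- astroplace:::tuning_rate(x + 120, tun[1, ], cfg$cue_zone_length_cm)
  expect_equal(r0, r1, tolerance = 1e-12)
  expect_equal(r0, r2, tolerance = 1e-12)
})

test_that("zone-identity tuning is constant within zones and differs across", {
  cfg <- synth_config()
  tun <- make_tuning(0, 0, 1, config = cfg, tuning_mode = "cue-zone", seed = 17)
  r <- astroplace:::tuning_rate(c(5, 55, 65, 115, 125, 175), tun[1, ],
                                cfg$cue_zone_length_cm)
  expect_equal(r[1], r[2])
  expect_equal(r[3], r[4])
  expect_equal(r[5], r[6])
  expect_equal(length(unique(r)), 3)
})

test_that("a process ROI referencing a missing parent cell is rejected", {
  cfg <- synth_config(n_trials = 2, seed = 18)
  tun <- make_tuning(1, 1, 0, config = cfg, seed = 19)
  tun$parent_cell_id[tun$kind == "astro-process"] <- "roi999"
  traj <- simulate_trajectory(cfg)
  expect_error(simulate_population(traj, tun, cfg), "absent parent")
})

test_that("in-field pair noise plants position-dependent correlations", {
  cfg <- synth_config(n_trials = 40, seed = 20)
  tun <- make_tuning(1, 0, 1, config = cfg, seed = 21)
  tun$pair_tag <- "p1"
  ses <- simulate_session(cfg, tun, infield_corr_gain = 2)
  fr <- ses$trajectory$frames
  gate <- fr$in_trial &
    abs(fr$position - tun$field_center[1]) <= tun$field_sigma[1]
  res <- ses$dff - ses$signal
  expect_gt(stats::cor(res[gate, 1], res[gate, 2]),
            stats::cor(res[!gate, 1], res[!gate, 2]) + 0.3)
})
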