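make_traj_df <- function(position, speed, direction = 1L) {
  structure(list(
    frames = data.frame(time = (seq_along(position) - 1) / 3,
                        position = position, speed = speed,
                        direction = rep_len(direction, length(position)),
                        in_trial = TRUE),
    trials = NULL, frame_rate_hz = 3), class = "trajectory")
}

test_that("running-trial segmentation applies the speed and merge rules", {
  ## constant suprathreshold speed: one trial spanning all frames
  tr <- make_traj_df(seq(0, 99) * 0.5, rep(2, 100))
  trials <- find_running_trials(tr)
  expect_equal(nrow(trials), 1)
  expect_equal(c(trials$start, trials$end), c(1, 100))

  ## two runs separated by a 0.5-s pause are merged
  sp <- c(rep(2, 30), rep(0.5, 1), rep(2, 30))   # 1 frame gap < 1 s
  tr <- make_traj_df(cumsum(sp) / 3, sp)
  expect_equal(nrow(find_running_trials(tr)), 1)

  ## a 2-s pause separates trials
  sp <- c(rep(2, 30), rep(0.5, 6), rep(2, 30))
  tr <- make_traj_df(cumsum(sp) / 3, sp)
  expect_equal(nrow(find_running_trials(tr)), 2)

  ## all subthreshold: empty
  tr <- make_traj_df(rep(1, 50), rep(0.5, 50))
  expect_equal(nrow(find_running_trials(tr)), 0)
})

test_that("direction changes split running trials", {
  sp <- rep(3, 40)
  tr <- make_traj_df(c(seq(0, 57, 3), seq(57, 0, -3)), sp,
                     direction = c(rep(1L, 20), rep(-1L, 20)))
  trials <- find_running_trials(tr)
  expect_equal(nrow(trials), 2)
  expect_equal(trials$direction, c(1L, -1L))
})

test_that("maps are normalized, smoothed, and uniform under uniform dwell", {
  pos <- rep(seq(1.125, 178.875, by = 2.25), times = 6)   # equal bin dwell
  tr <- make_traj_df(pos, rep(5, length(pos)))
  trials <- data.frame(start = 1, end = length(pos), direction = 1)
  set.seed(1)
  maps <- compute_maps(rnorm(length(pos)), tr, trials)
  expect_equal(sum(maps$occupancy), 1, tolerance = 1e-10)
  expect_equal(sum(maps$activity), 1, tolerance = 1e-10)
  expect_lt(diff(range(maps$occupancy)) / mean(maps$occupancy), 0.01)

  ## all-zero activity propagates as a zero response profile
  maps0 <- compute_maps(rep(0, length(pos)), tr, trials)
  expect_true(all(response_profile(maps0)$rp == 0))
})

test_that("response profile is the activity/occupancy ratio", {
  maps <- structure(list(occupancy = rep(1 / 80, 80),
                         activity = rep(1 / 80, 80),
                         bin_width_cm = 2.25,
                         bin_centers = (1:80 - 0.5) * 2.25, n_bins = 80),
                    class = "spatial_maps")
  expect_equal(response_profile(maps)$rp, rep(1, 80))
  maps$activity[10] <- 2 / 80
  expect_equal(response_profile(maps)$rp[10], 2)

  set.seed(2)
  occ <- runif(80, 0.5, 1.5); occ <- occ / sum(occ)
  act <- runif(80); act <- act / sum(act)
  maps$occupancy <- occ; maps$activity <- act
  expect_equal(response_profile(maps)$rp, act / occ, tolerance = 1e-12)

  maps$occupancy[5] <- 0
  expect_error(response_profile(maps), "bin\\(s\\) 5")
})

test_that("field fitting recovers a noiseless Gaussian and picks the dominant peak", {
  x <- (1:80 - 0.5) * 2.25
  rp <- exp(-(x - 90)^2 / (2 * 20^2))
  f <- fit_response_field(rp)
  expect_equal(f$status, "ok")
  expect_lt(abs(f$center - 90), 0.5 * 2.25)
  expect_lt(abs(f$sigma - 20) / 20, 0.05)
  expect_equal(f$width, 2 * f$sigma)

  expect_equal(fit_response_field(rep(1, 80))$status, "no_field")

  rp2 <- exp(-(x - 50)^2 / (2 * 12^2)) + 0.6 * exp(-(x - 140)^2 / (2 * 12^2))
  f2 <- fit_response_field(rp2)
  expect_lt(abs(f2$center - 50), 2.25)
  expect_equal(nrow(f2$components), 2)
})

test_that("reliability compares odd/even field centers against the narrower width", {
  mkf <- function(c, s) structure(list(center = c, sigma = s, width = 2 * s,
                                       amplitude = 1, status = "ok"),
                                  class = "response_field")
  expect_equal(compute_reliability(mkf(50, 10), mkf(50, 12)), 1)
  expect_equal(compute_reliability(mkf(50, 10), mkf(70, 12)), 0)
  expect_equal(compute_reliability(mkf(50, 10), mkf(60, 20)), 0.5)
  expect_error(compute_reliability(mkf(50, 0), mkf(60, 20)), "zero")
  expect_error(compute_reliability(mkf(50, 10),
                                   structure(list(status = "no_field"),
                                             class = "response_field")),
               "exist")
})

test_that("stability uses a strict 15-cm cutoff and missing fields fail it", {
  mkf <- function(c) structure(list(center = c, sigma = 10, status = "ok"),
                               class = "response_field")
  none <- structure(list(status = "no_field"), class = "response_field")
  expect_true(classify_stability(mkf(50), mkf(50)))
  expect_false(classify_stability(mkf(50), mkf(65)))
  expect_true(classify_stability(mkf(50), mkf(64.9)))
  expect_false(classify_stability(mkf(50), none))
})

test_that("jackknife profile matches the leave-one-out formula", {
  ses <- small_session(n_trials = 6)
  trials <- find_running_trials(ses$trajectory)
  jk <- jackknife_profile(ses$dff[, 1], ses$trajectory, trials)
  n <- nrow(trials)
  mu <- colMeans(jk$profiles)
  se <- sqrt((n - 1) / n * colSums((jk$profiles -
                                      matrix(mu, n, 80, byrow = TRUE))^2))
  expect_equal(jk$se, se, tolerance = 1e-12)
  expect_equal(jk$mean, mu, tolerance = 1e-12)
  ## n = 2: SE reduces to half the absolute profile difference
  jk2 <- jackknife_profile(ses$dff[, 1], ses$trajectory, trials[1:2, ])
  expect_equal(jk2$se, abs(jk2$profiles[1, ] - jk2$profiles[2, ]) / 2,
               tolerance = 1e-12)
  expect_error(jackknife_profile(ses$dff[, 1], ses$trajectory, trials[1, ]),
               "at least 2")
})

test_that("spatial precision follows the weighted center-of-mass dispersion", {
  ## two trials with point-like activity at known bins
  pos <- c(seq(0.5, 179.5, by = 1), seq(0.5, 179.5, by = 1))
  tr <- make_traj_df(pos, rep(5, length(pos)))
  trials <- data.frame(start = c(1, 181), end = c(180, 360), direction = 1)
  ev <- rep(0, 360)
  ev[50] <- 2                      # trial 1: activity at 49.5 cm
  ev[180 + 60] <- 2                # trial 2: activity at 59.5 cm
  sp <- spatial_precision(ev, tr, trials, m = 40)
  com <- attr(sp, "com")
  ## bin centers (width 4.5): position 49.5 falls in bin 12 (center 51.75),
  ## position 59.5 in bin 14 (center 60.75)
  expect_equal(com, c(51.75, 60.75))
  comw <- mean(com)                 # equal amplitudes
  expect_equal(as.numeric(sp), 1 / mean((com - comw)^2), tolerance = 1e-12)

  ## amplitude rescaling leaves the index unchanged
  sp2 <- spatial_precision(2 * ev, tr, trials, m = 40)
  expect_equal(as.numeric(sp2), as.numeric(sp), tolerance = 1e-12)

  ## identical trials: infinite precision, flagged
  ev2 <- rep(0, 360); ev2[c(50, 230)] <- 2
  sp3 <- spatial_precision(ev2, tr, trials, m = 40)
  expect_true(is.infinite(sp3))
  expect_true(attr(sp3, "zero_dispersion"))
})

test_that("dynamic-range correction rescales by the indicator ratio", {
  expect_equal(dynamic_range_correction(c(1, 2), 0.8, 0.8), c(1, 2))
  expect_equal(dynamic_range_correction(1, 0.95, 0.54), 0.95 / 0.54)
  expect_error(dynamic_range_correction(1, 0, 1), "positive")
  expect_equal(dynamic_range(c(0, 0.2, 1.1, 0)), 1.1)
})

test_that("directionality index contrasts in-field responses by direction", {
  pos <- c(seq(1, 180, by = 1), seq(180, 1, by = -1))
  tr <- make_traj_df(pos, rep(5, length(pos)),
                     direction = c(rep(1L, 180), rep(-1L, 180)))
  fwd <- data.frame(start = 1, end = 180, direction = 1)
  bwd <- data.frame(start = 181, end = 360, direction = -1)
  field <- structure(list(center = 90, sigma = 15, status = "ok"),
                     class = "response_field")
  infield <- abs(pos - 90) <= 15
  dff <- ifelse(infield, 3, 0)
  dff[181:360] <- ifelse(infield[181:360], 1, 0)
  expect_equal(directionality_index(dff, field, tr, fwd, bwd), 0.5)
  dff[181:360] <- 0
  expect_equal(directionality_index(dff, field, tr, fwd, bwd), 1)
  dff[181:360] <- ifelse(infield[181:360], 3, 0)
  expect_equal(directionality_index(dff, field, tr, fwd, bwd), 0)
  expect_error(directionality_index(rep(0, 360), field, tr, fwd, bwd),
               "undefined")

  ## surrogate distribution lies in [-1, 1] for nonnegative traces
  nulls <- directionality_null(list(pmax(dff, 0)), list(field), tr, fwd, bwd,
                               n_draws = 200, seed = 1)
  expect_true(all(abs(nulls[!is.na(nulls)]) <= 1))
})
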