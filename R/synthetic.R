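#' Configuration for a synthetic virtual-navigation session
#'
#' Describes the virtual corridor and the behavioural sampling regime used by
#' [simulate_trajectory()] and [simulate_population()]. Defaults reproduce the
#' study conditions: a 180-cm corridor carrying three 60-cm visual-cue zones,
#' reward at 115 cm, imaging at ~3 Hz, and a 5-s intertrial timeout after the
#' mouse is teleported back to the track start.
#'
#' @param corridor_length_cm Track length (cm). Must be an integer multiple of
#'   `cue_zone_length_cm`.
#' @param cue_zone_length_cm Length of one visual-cue zone (cm).
#' @param reward_position_cm Reward delivery position (cm); metadata only.
#' @param frame_rate_hz Imaging frame rate (Hz); must be positive.
#' @param n_trials Number of traversal episodes to simulate.
#' @param speed_mean,speed_sd Mean and SD of frame-wise running speed (cm/s).
#' @param pause_prob Per-frame probability of entering a brief (< 1 cm/s)
#'   pause while running, so trial segmentation is exercised.
#' @param intertrial_timeout_s Timeout between trials (s).
#' @param bidirectional If `TRUE`, alternate forward/backward traversals with
#'   no teleport (reward at alternating track ends).
#' @param seed Integer seed; the simulation is bit-reproducible given the
#'   config.
#' @return An object of class `synth_config` (a list).
#' @export
synth_config <- function(corridor_length_cm = 180,
                         cue_zone_length_cm = 60,
                         reward_position_cm = 115,
                         frame_rate_hz = 3,
                         n_trials = 30,
                         speed_mean = 15,
                         speed_sd = 4,
                         pause_prob = 0.015,
                         intertrial_timeout_s = 5,
                         bidirectional = FALSE,
                         seed = 1L) {
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be positive", call. = FALSE)
  if (n_trials < 0) stop("n_trials must be >= 0", call. = FALSE)
  if (corridor_length_cm %% cue_zone_length_cm != 0)
    stop("corridor_length_cm must be an integer multiple of cue_zone_length_cm",
         call. = FALSE)
  structure(list(
    corridor_length_cm = corridor_length_cm,
    cue_zone_length_cm = cue_zone_length_cm,
    reward_position_cm = reward_position_cm,
    frame_rate_hz = frame_rate_hz,
    n_trials = as.integer(n_trials),
    speed_mean = speed_mean,
    speed_sd = speed_sd,
    pause_prob = pause_prob,
    intertrial_timeout_s = intertrial_timeout_s,
    bidirectional = isTRUE(bidirectional),
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Map track positions to visual-cue zones
#'
#' Zone boundaries are left-closed/right-open (`[0, 60)`, `[60, 120)`,
#' `[120, 180]`); the final position is included in the last zone.
#'
#' @param config A [synth_config()].
#' @return A function mapping a numeric vector of positions (cm) to integer
#'   zone indices `0 .. n_zones - 1`.
#' @export
make_cue_map <- function(config) {
  len <- config$cue_zone_length_cm
  n_zones <- as.integer(config$corridor_length_cm / len)
  function(position) {
    z <- floor(position / len)
    as.integer(pmin(pmax(z, 0), n_zones - 1L))
  }
}

#' Simulate a virtual-track running trajectory
#'
#' Generates frame-by-frame behaviour: `n_trials` traversals of the corridor
#' at speeds drawn from the configured profile, with occasional sub-1 cm/s
#' pauses injected inside trials and timeout gaps (speed 0, not in trial)
#' between trials. Monodirectional trials teleport the mouse to 0 cm after it
#' reaches the end of the track; bidirectional trials alternate direction.
#'
#' @param config A [synth_config()].
#' @return A list of class `trajectory` with elements `frames` (data.frame:
#'   `time`, `position`, `speed`, `direction`, `in_trial`), `trials`
#'   (data.frame: `trial`, `start`, `end`, `direction`), and `frame_rate_hz`.
#' @export
simulate_trajectory <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, 1L))
  dt <- 1 / config$frame_rate_hz
  L <- config$corridor_length_cm
  n_timeout <- round(config$intertrial_timeout_s * config$frame_rate_hz)

  time <- position <- speed <- direction <- numeric(0)
  in_trial <- logical(0)
  trials <- data.frame(trial = integer(0), start = integer(0),
                       end = integer(0), direction = integer(0))
  dirn <- 1L
  pos0 <- 0
  for (tr in seq_len(config$n_trials)) {
    p <- pos0
    pv <- sv <- numeric(0)
    pause_left <- 0L
    repeat {
      if (pause_left > 0L) {
        v <- stats::runif(1, 0, 0.9)
        pause_left <- pause_left - 1L
      } else if (stats::runif(1) < config$pause_prob) {
        pause_left <- sample(2:6, 1L)
        v <- stats::runif(1, 0, 0.9)
      } else {
        v <- max(stats::rnorm(1, config$speed_mean, config$speed_sd), 1.5)
      }
      pv <- c(pv, p)
      sv <- c(sv, v)
      p <- p + dirn * v * dt
      if (dirn > 0 && p >= L) break
      if (dirn < 0 && p <= 0) break
    }
    ## final frame of the traversal pinned at the track end
    pv <- c(pv, if (dirn > 0) L else 0)
    sv <- c(sv, sv[length(sv)])
    nfr <- length(pv)
    start <- length(position) + 1L
    position <- c(position, pv)
    speed <- c(speed, sv)
    direction <- c(direction, rep(dirn, nfr))
    in_trial <- c(in_trial, rep(TRUE, nfr))
    trials <- rbind(trials, data.frame(trial = tr, start = start,
                                       end = start + nfr - 1L,
                                       direction = dirn))
    ## intertrial timeout
    rest_pos <- if (config$bidirectional) pv[nfr] else 0
    position <- c(position, rep(rest_pos, n_timeout))
    speed <- c(speed, rep(0, n_timeout))
    direction <- c(direction, rep(dirn, n_timeout))
    in_trial <- c(in_trial, rep(FALSE, n_timeout))
    if (config$bidirectional) {
      dirn <- -dirn
      pos0 <- rest_pos
    } else {
      pos0 <- 0
    }
  }
  n <- length(position)
  structure(list(
    frames = data.frame(
      time = if (n) (seq_len(n) - 1) * dt else numeric(0),
      position = position, speed = speed,
      direction = as.integer(direction), in_trial = in_trial),
    trials = trials,
    frame_rate_hz = config$frame_rate_hz
  ), class = "trajectory")
}

#' Build a tuning table for a synthetic ROI population
#'
#' One row per ROI. Defaults give astrocytic fields wider than neuronal ones
#' and slow astrocytic versus fast neuronal indicator kinetics.
#'
#' @param n_astro_soma,n_astro_process,n_neuron ROI counts per kind. Each
#'   astrocyte process is assigned a parent soma (round-robin).
#' @param config A [synth_config()]; field centers are drawn away from the
#'   track ends.
#' @param tuning_mode `"place"`, `"cue-periodic"` or `"untuned"` (recycled).
#' @param amplitude Response amplitude, dF/F0 units (recycled).
#' @param noise_sd Independent noise SD, dF/F0 units (recycled).
#' @param fov_um Field-of-view side (um) for centroid placement.
#' @param seed Integer seed.
#' @return A data.frame of class `tuning_spec` with columns `roi_id`, `kind`,
#'   `parent_cell_id`, `x_um`, `y_um`, `field_center`, `field_sigma`,
#'   `amplitude`, `baseline`, `tuning_mode`, `tau_rise`, `tau_decay`,
#'   `noise_sd`, `pair_tag`.
#' @export
make_tuning <- function(n_astro_soma = 5, n_astro_process = 15, n_neuron = 30,
                        config = synth_config(),
                        tuning_mode = "place",
                        amplitude = 1.0,
                        noise_sd = 0.15,
                        fov_um = 300,
                        seed = 1L) {
  set.seed(derive_seed(seed, 2L))
  kinds <- c(rep("astro-soma", n_astro_soma),
             rep("astro-process", n_astro_process),
             rep("neuron", n_neuron))
  n <- length(kinds)
  if (n == 0L) stop("empty population", call. = FALSE)
  L <- config$corridor_length_cm
  soma_ids <- paste0("roi", sprintf("%03d", seq_len(n_astro_soma)))
  parent <- rep(NA_character_, n)
  if (n_astro_process > 0) {
    if (n_astro_soma == 0) stop("processes require at least one soma parent",
                                call. = FALSE)
    parent[kinds == "astro-process"] <-
      soma_ids[rep_len(seq_len(n_astro_soma), n_astro_process)]
  }
  is_astro <- kinds != "neuron"
  tuning <- data.frame(
    roi_id = paste0("roi", sprintf("%03d", seq_len(n))),
    kind = kinds,
    parent_cell_id = parent,
    x_um = stats::runif(n, 0, fov_um),
    y_um = stats::runif(n, 0, fov_um),
    field_center = stats::runif(n, 0.2 * L, 0.9 * L),
    field_sigma = ifelse(is_astro,
                         stats::runif(n, 14, 22),
                         stats::runif(n, 7, 12)),
    amplitude = rep_len(amplitude, n),
    baseline = 0,
    tuning_mode = rep_len(tuning_mode, n),
    tau_rise = ifelse(is_astro, 1.0, 0.1),
    tau_decay = ifelse(is_astro, 3.0, 1.0),
    noise_sd = rep_len(noise_sd, n),
    pair_tag = NA_character_,
    stringsAsFactors = FALSE
  )
  class(tuning) <- c("tuning_spec", "data.frame")
  tuning
}

validate_tuning <- function(tuning) {
  req <- c("roi_id", "kind", "field_center", "field_sigma", "amplitude",
           "baseline", "tuning_mode", "tau_rise", "tau_decay", "noise_sd")
  miss <- setdiff(req, names(tuning))
  if (length(miss)) stop("tuning table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  tuned <- tuning$tuning_mode != "untuned"
  if (any(tuned & !(tuning$field_sigma > 0)))
    stop("tuned ROIs must have field_sigma > 0", call. = FALSE)
  if (any(!(tuning$tau_decay > tuning$tau_rise & tuning$tau_rise > 0)))
    stop("indicator kinetics require tau_decay > tau_rise > 0", call. = FALSE)
  proc <- tuning$kind == "astro-process"
  if (any(proc)) {
    soma_ids <- tuning$roi_id[tuning$kind == "astro-soma"]
    bad <- proc & !(tuning$parent_cell_id %in% soma_ids)
    if (any(bad))
      stop("astro-process ROI(s) reference absent parent cell: ",
           paste(tuning$roi_id[bad], collapse = ", "), call. = FALSE)
  }
  invisible(tuning)
}

## Double-exponential indicator impulse response, sampled at dt and normalized
## to unit sum so a sustained rate of a maps to a steady-state response of a.
indicator_kernel <- function(tau_rise, tau_decay, dt) {
  tmax <- 6 * tau_decay
  t <- seq(0, tmax, by = dt)
  k <- exp(-t / tau_decay) - exp(-t / tau_rise)
  k / sum(k)
}

## Positional tuning evaluated at arbitrary (possibly negative) positions.
## Cue-periodic tuning repeats with the cue-zone period; distances are
## circular within the period so the noiseless rate is exactly periodic.
tuning_rate <- function(x, row, cue_len) {
  switch(row$tuning_mode,
    "place" = row$amplitude * exp(-(x - row$field_center)^2 /
                                    (2 * row$field_sigma^2)),
    "cue-periodic" = {
      m <- x %% cue_len
      cm <- row$field_center %% cue_len
      d <- abs(m - cm)
      d <- pmin(d, cue_len - d)
      row$amplitude * exp(-d^2 / (2 * row$field_sigma^2))
    },
    "cue-zone" = {
      ## response locked to visual-cue (zone) identity: one level per zone,
      ## the ROI's preferred zone (the one holding field_center) strongest
      n_zones <- 3L
      z <- pmin(pmax(floor(x / cue_len), 0), n_zones - 1L)
      pref <- min(max(floor(row$field_center / cue_len), 0), n_zones - 1L)
      levels <- c(1, 0.3, 0.1)[((0:(n_zones - 1L)) - pref) %% n_zones + 1L]
      row$amplitude * levels[z + 1L]
    },
    "untuned" = rep(0, length(x)),
    stop("unknown tuning_mode: ", row$tuning_mode, call. = FALSE)
  )
}

## Convolve a rate segment with the indicator kernel, center-of-mass aligned.
## The segment carries steady-state warm-up and run-out extensions (n_warm
## frames each) so neither trial onset nor the center-of-mass realignment
## reads zero-padded rate; otherwise trial edges would imprint position-locked
## artifacts on the responses.
convolve_segment <- function(rate_ext, k, n_warm) {
  lag_com <- round(sum((seq_along(k) - 1) * k) / sum(k))
  full <- stats::convolve(rate_ext, rev(k), type = "open")
  n <- length(rate_ext) - 2L * n_warm
  idx <- n_warm + seq_len(n) + lag_com
  idx <- pmin(idx, length(full))
  full[idx]
}

#' Simulate calcium fluorescence for an ROI population
#'
#' Each tuned ROI's underlying rate is a Gaussian (or cue-periodic) function
#' of track position, convolved with a double-exponential indicator kernel
#' (center-of-mass aligned, so nominal field centers match observable response
#' centers), baseline-shifted and corrupted with independent plus shared
#' Gaussian noise. Shared-noise weight between ROI pairs decays exponentially
#' with centroid distance. When `infield_corr_gain > 0`, ROIs sharing a
#' `pair_tag` receive an extra common noise source that is switched on only
#' while the animal is inside the tagged astrocytic ROI's ground-truth field,
#' planting position-dependent noise correlations.
#'
#' @param trajectory A [simulate_trajectory()] result.
#' @param tuning A [make_tuning()] table.
#' @param config The [synth_config()] used for the trajectory.
#' @param shared_noise_gain Weight of the distance-correlated shared noise.
#' @param infield_corr_gain Weight of the in-field pair noise (see above).
#' @param distance_corr_tau Length scale (um) of the shared-noise decay.
#' @param f0_level Baseline fluorescence level (arbitrary units) used to build
#'   raw traces `f0_level * (1 + dff)`.
#' @param seed Integer seed; per-ROI noise streams are derived
#'   deterministically, so adding ROIs does not perturb existing ones.
#' @return A list of class `synth_session`: `dff` (frames x ROI matrix of
#'   dF/F0), `raw` (raw fluorescence), `signal` (the noiseless response
#'   component, for ground-truth constructions), `tuning` (input table
#'   augmented with `expected_center`/`expected_sigma`, the observable field
#'   parameters of the noiseless signal on this trajectory), `trajectory`,
#'   `config`.
#' @export
simulate_population <- function(trajectory, tuning, config,
                                shared_noise_gain = 0,
                                infield_corr_gain = 0,
                                distance_corr_tau = 50,
                                f0_level = 100,
                                seed = config$seed) {
  stopifnot(inherits(trajectory, "trajectory"))
  validate_tuning(tuning)
  if (nrow(trajectory$frames) == 0L) stop("empty trajectory", call. = FALSE)
  fr <- trajectory$frames
  nt <- nrow(fr)
  nroi <- nrow(tuning)

  signal <- noiseless_signal(trajectory, tuning, config)

  ## noise: independent per-ROI streams + distance-correlated shared part
  noise <- matrix(0, nt, nroi)
  for (i in seq_len(nroi)) {
    set.seed(derive_seed(seed, 10L + i))
    noise[, i] <- stats::rnorm(nt)
  }
  if (shared_noise_gain > 0 && nroi > 1) {
    set.seed(derive_seed(seed, 3L))
    d <- as.matrix(stats::dist(cbind(tuning$x_um, tuning$y_um)))
    K <- exp(-d / distance_corr_tau) + diag(1e-8, nroi)
    A <- t(chol(K))
    shared <- matrix(stats::rnorm(nt * nroi), nt, nroi) %*% t(A)
    g <- shared_noise_gain
    noise <- (noise + g * shared) / sqrt(1 + g^2)
  }
  noise <- sweep(noise, 2, tuning$noise_sd, `*`)

  if (infield_corr_gain > 0 && any(!is.na(tuning$pair_tag))) {
    tags <- unique(stats::na.omit(tuning$pair_tag))
    for (tg in seq_along(tags)) {
      members <- which(tuning$pair_tag == tags[tg] & !is.na(tuning$pair_tag))
      anchor <- members[tuning$kind[members] != "neuron"][1]
      if (is.na(anchor)) anchor <- members[1]
      cf <- tuning$field_center[anchor]
      sf <- tuning$field_sigma[anchor]
      gate <- fr$in_trial & abs(fr$position - cf) <= sf
      set.seed(derive_seed(seed, 1000L + tg))
      xi <- stats::rnorm(nt) * gate
      for (m in members)
        noise[, m] <- noise[, m] + infield_corr_gain * tuning$noise_sd[m] * xi
    }
  }

  dff <- sweep(signal + noise, 2, tuning$baseline, `+`)
  raw <- f0_level * pmax(1 + dff, 0.05)
  colnames(raw) <- tuning$roi_id

  ef <- expected_fields(tuning, config, trajectory, signal = signal)
  tuning$expected_center <- ef$center
  tuning$expected_sigma <- ef$sigma

  structure(list(dff = dff, raw = raw, signal = signal, tuning = tuning,
                 trajectory = trajectory, config = config),
            class = "synth_session")
}

## Noiseless calcium signal for every ROI on a given trajectory: positional
## tuning convolved per trial (with steady-state warm-up) with the indicator
## kernel.
noiseless_signal <- function(trajectory, tuning, config) {
  fr <- trajectory$frames
  dt <- 1 / trajectory$frame_rate_hz
  cue_len <- config$cue_zone_length_cm
  signal <- matrix(0, nrow(fr), nrow(tuning),
                   dimnames = list(NULL, tuning$roi_id))
  for (i in seq_len(nrow(tuning))) {
    row <- tuning[i, ]
    if (row$tuning_mode == "cue-zone") {
      ## instantaneous zone-identity response: the pure visual-cue hypothesis
      ## (no positional structure within a zone), used as the negative control
      ## for the cue-constrained shuffle; indicator kinetics are omitted so
      ## zone transitions do not imprint within-zone position information
      for (j in seq_len(nrow(trajectory$trials))) {
        s <- trajectory$trials$start[j]
        e <- trajectory$trials$end[j]
        signal[s:e, i] <- tuning_rate(fr$position[s:e], row, cue_len)
      }
      next
    }
    k <- indicator_kernel(row$tau_rise, row$tau_decay, dt)
    n_warm <- length(k)
    for (j in seq_len(nrow(trajectory$trials))) {
      s <- trajectory$trials$start[j]
      e <- trajectory$trials$end[j]
      dirn <- trajectory$trials$direction[j]
      v0 <- max(mean(fr$speed[s:min(s + 2, e)]), 2)
      v1 <- max(mean(fr$speed[max(s, e - 2):e]), 2)
      warm_pos <- fr$position[s] - dirn * v0 * dt * (n_warm:1)
      post_pos <- fr$position[e] + dirn * v1 * dt * seq_len(n_warm)
      rate_ext <- tuning_rate(c(warm_pos, fr$position[s:e], post_pos),
                              row, cue_len)
      signal[s:e, i] <- convolve_segment(rate_ext, k, n_warm)
    }
    ## amplitude is the observed response peak in dF/F0 units: rescale so the
    ## kernel (unit-sum) does not dilute transient passages through the field
    mx <- max(signal[, i])
    if (mx > 0) signal[, i] <- signal[, i] * (row$amplitude / mx)
  }
  signal
}

## Observable ground-truth field per ROI: the noiseless signal on the realized
## trajectory, mapped through the same binning/smoothing as the analysis
## pipeline and summarized by a single bounded-Gaussian fit. This is the
## estimand (conditional expectation given the trajectory) that field fitting
## on the noisy data should recover; indicator kinetics shift and broaden it
## relative to the latent tuning parameters.
expected_fields <- function(tuning, config, trajectory, signal = NULL,
                            n_bins = 80, kernel_sigma_bins = 3) {
  if (is.null(signal)) signal <- noiseless_signal(trajectory, tuning, config)
  L <- config$corridor_length_cm
  trials <- find_running_trials(trajectory)
  centers <- rep(NA_real_, nrow(tuning))
  sigmas <- rep(NA_real_, nrow(tuning))
  if (!nrow(trials)) return(list(center = centers, sigma = sigmas))
  bin_x <- (seq_len(n_bins) - 0.5) * L / n_bins
  for (i in seq_len(nrow(tuning))) {
    row <- tuning[i, ]
    if (row$tuning_mode != "place" || row$amplitude == 0) next
    maps <- compute_maps(signal[, i], trajectory, trials, n_bins, L,
                         kernel_sigma_bins)
    prof <- response_profile(maps)$rp
    ok <- !is.na(prof)
    if (!any(ok) || max(prof[ok]) <= 0) next
    prof <- prof / max(prof[ok])
    i0 <- which.max(prof)
    fit <- tryCatch(minpack.lm::nlsLM(
      y ~ a * exp(-(x - c)^2 / (2 * s^2)),
      data = data.frame(x = bin_x[ok], y = prof[ok]),
      start = list(a = 1, c = bin_x[i0], s = row$field_sigma),
      lower = c(0, 0, 0.1), upper = c(1.5, L, L / 2),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      centers[i] <- bin_x[i0]
    } else {
      cf <- stats::coef(fit)
      centers[i] <- cf[["c"]]
      sigmas[i] <- cf[["s"]]
    }
  }
  list(center = centers, sigma = sigmas)
}

#' Synthetic traces with planted transients for detector validation
#'
#' Builds dF/F0-like traces of unit-SD Gaussian noise with boxcar transients
#' of given amplitude (in noise-SD units) and duration planted at random
#' non-overlapping positions, for measuring the transient detector's
#' false-discovery rate against known ground truth.
#'
#' @param n_traces,n_frames Fixture dimensions.
#' @param frame_rate_hz Sampling rate (Hz).
#' @param noise_sd Noise SD (dF/F0 units).
#' @param n_events Planted transients per trace.
#' @param amp_range Amplitude range (multiples of `noise_sd`).
#' @param dur_range_s Duration range (s).
#' @param seed Integer seed.
#' @return List: `traces` (frames x traces matrix), `onsets` (list of planted
#'   start frames per trace), `durations` (frames, per trace).
#' @export
simulate_event_fixture <- function(n_traces = 50, n_frames = 750,
                                   frame_rate_hz = 3, noise_sd = 1,
                                   n_events = 8, amp_range = c(4, 6),
                                   dur_range_s = c(1, 2), seed = 1L) {
  traces <- matrix(NA_real_, n_frames, n_traces)
  onsets <- durations <- vector("list", n_traces)
  dmin <- max(1L, round(dur_range_s[1] * frame_rate_hz))
  dmax <- max(dmin, round(dur_range_s[2] * frame_rate_hz))
  for (tr in seq_len(n_traces)) {
    set.seed(derive_seed(seed, 20L + tr))
    x <- stats::rnorm(n_frames, 0, noise_sd)
    taken <- rep(FALSE, n_frames)
    st <- integer(0)
    du <- integer(0)
    guard <- 0L
    while (length(st) < n_events && guard < 1000L) {
      guard <- guard + 1L
      d <- sample(dmin:dmax, 1L)
      o <- sample.int(n_frames - d + 1L, 1L)
      span <- max(1L, o - 2L):min(n_frames, o + d + 1L)
      if (any(taken[span])) next
      amp <- stats::runif(1, amp_range[1], amp_range[2]) * noise_sd
      x[o:(o + d - 1L)] <- x[o:(o + d - 1L)] + amp
      taken[span] <- TRUE
      st <- c(st, o)
      du <- c(du, d)
    }
    traces[, tr] <- x
    onsets[[tr]] <- st
    durations[[tr]] <- du
  }
  list(traces = traces, onsets = onsets, durations = durations,
       frame_rate_hz = frame_rate_hz)
}

#' Simulate a complete synthetic session
#'
#' Convenience wrapper: trajectory plus population traces and ground truth.
#'
#' @param config A [synth_config()].
#' @param tuning A [make_tuning()] table (default population if omitted).
#' @param ... Passed to [simulate_population()].
#' @return A `synth_session` (see [simulate_population()]).
#' @export
simulate_session <- function(config = synth_config(),
                             tuning = make_tuning(config = config,
                                                  seed = config$seed),
                             ...) {
  traj <- simulate_trajectory(config)
  simulate_population(traj, tuning, config, ...)
}
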