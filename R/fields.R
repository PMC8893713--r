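#' Segment running trials from a trajectory
#'
#' Running trials are maximal runs of consecutive frames of locomotion in one
#' direction with speed strictly greater than `speed_threshold`; runs in the
#' same direction separated by less than `merge_gap_s` are merged.
#'
#' @param trajectory A `trajectory` object (see [simulate_trajectory()]) or a
#'   data.frame with `position`, `speed`, `direction` columns.
#' @param speed_threshold Speed cutoff (cm/s), strict.
#' @param merge_gap_s Gaps shorter than this (s) are merged.
#' @return data.frame with `start`, `end` (frames), `direction`, `length_cm`.
#' @export
find_running_trials <- function(trajectory, speed_threshold = 1,
                                merge_gap_s = 1) {
  fr <- if (inherits(trajectory, "trajectory")) trajectory$frames else trajectory
  frame_rate <- if (inherits(trajectory, "trajectory"))
    trajectory$frame_rate_hz else attr(trajectory, "frame_rate_hz") %||% 3
  run <- fr$speed > speed_threshold
  if (!any(run))
    return(data.frame(start = integer(0), end = integer(0),
                      direction = integer(0), length_cm = numeric(0)))
  r <- rle(run & TRUE)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  seg$direction <- fr$direction[seg$start]
  ## split segments containing a direction change
  out <- list()
  for (i in seq_len(nrow(seg))) {
    idx <- seg$start[i]:seg$end[i]
    d <- fr$direction[idx]
    ch <- c(0L, which(d[-1] != d[-length(d)]), length(d))
    for (j in seq_len(length(ch) - 1L))
      out[[length(out) + 1L]] <- data.frame(
        start = idx[ch[j] + 1L], end = idx[ch[j + 1L]],
        direction = d[ch[j] + 1L])
  }
  seg <- do.call(rbind, out)
  ## merge same-direction runs separated by < merge_gap_s
  max_gap <- merge_gap_s * frame_rate
  merged <- seg[1, , drop = FALSE]
  for (i in seq_len(nrow(seg))[-1]) {
    last <- nrow(merged)
    gap <- seg$start[i] - merged$end[last] - 1L
    if (gap < max_gap && seg$direction[i] == merged$direction[last]) {
      merged$end[last] <- seg$end[i]
    } else {
      merged <- rbind(merged, seg[i, ])
    }
  }
  merged$length_cm <- vapply(seq_len(nrow(merged)), function(i) {
    p <- fr$position[merged$start[i]:merged$end[i]]
    abs(p[length(p)] - p[1])
  }, numeric(1))
  rownames(merged) <- NULL
  merged
}

trial_frames <- function(trials) {
  if (!nrow(trials)) return(integer(0))
  unlist(lapply(seq_len(nrow(trials)),
                function(i) trials$start[i]:trials$end[i]), use.names = FALSE)
}

#' Occupancy and activity maps
#'
#' Bins running-trial frames over the corridor (80 bins of 2.25 cm by
#' default). The occupancy map is time spent per bin; the activity map the
#' average fluorescence per bin. Both are normalized to sum 1 and convolved
#' with a Gaussian kernel of 3 bins (6.75 cm), then renormalized to sum 1.
#' Bins with zero occupancy after smoothing are flagged `NA`.
#'
#' @param event_values Per-frame fluorescence values (typically an event
#'   trace), aligned with the trajectory.
#' @param trajectory `trajectory` object or frame data.frame with `position`.
#' @param trials Running trials from [find_running_trials()].
#' @param n_bins Number of spatial bins.
#' @param corridor_length_cm Track length (cm).
#' @param kernel_sigma_bins Smoothing kernel SD, in bins.
#' @return List of class `spatial_maps`: `occupancy`, `activity` (length
#'   `n_bins`), `bin_width_cm`, `bin_centers`, `n_bins`.
#' @export
compute_maps <- function(event_values, trajectory, trials, n_bins = 80,
                         corridor_length_cm = 180, kernel_sigma_bins = 3) {
  if (!nrow(trials)) stop("no running trials", call. = FALSE)
  fr <- if (inherits(trajectory, "trajectory")) trajectory$frames else trajectory
  idx <- trial_frames(trials)
  bw <- corridor_length_cm / n_bins
  bin <- pmin(pmax(floor(fr$position[idx] / bw), 0), n_bins - 1L) + 1L
  occ <- tabulate(bin, nbins = n_bins)
  act <- vapply(seq_len(n_bins), function(b) {
    v <- event_values[idx][bin == b]
    if (length(v)) mean(v) else 0
  }, numeric(1))
  norm1 <- function(m) if (sum(m) > 0) m / sum(m) else m
  occ_s <- gaussian_smooth(norm1(occ), kernel_sigma_bins)
  act_s <- gaussian_smooth(norm1(act), kernel_sigma_bins)
  occ_s <- norm1(occ_s)
  act_s <- norm1(act_s)
  undefined <- occ_s == 0
  occ_s[undefined] <- NA_real_
  structure(list(occupancy = occ_s, activity = act_s,
                 bin_width_cm = bw,
                 bin_centers = (seq_len(n_bins) - 0.5) * bw,
                 n_bins = n_bins),
            class = "spatial_maps")
}

#' Response profile
#'
#' Ratio of the (smoothed, normalized) activity map over the occupancy map.
#' Bins flagged undefined in the occupancy map propagate as `NA`.
#'
#' @param maps A [compute_maps()] result.
#' @return List of class `response_profile`: `rp`, `bin_centers`,
#'   `bin_width_cm`.
#' @export
response_profile <- function(maps) {
  occ <- maps$occupancy
  zero <- which(!is.na(occ) & occ == 0)
  if (length(zero))
    stop("zero occupancy in bin(s) ", paste(utils::head(zero, 5L),
         collapse = ", "), "; response profile undefined there",
         call. = FALSE)
  structure(list(rp = maps$activity / occ,
                 bin_centers = maps$bin_centers,
                 bin_width_cm = maps$bin_width_cm),
            class = "response_profile")
}

## local maxima strictly above both neighbors; plateaus (runs of equal values)
## count once, seeded at their center; array edges count when strictly greater
## than their single inner neighbor
local_maxima <- function(y) {
  n <- length(y)
  if (n < 2L) return(integer(0))
  out <- integer(0)
  i <- 1L
  while (i <= n) {
    if (is.na(y[i])) {
      i <- i + 1L
      next
    }
    j <- i
    while (j < n && !is.na(y[j + 1L]) && y[j + 1L] == y[i]) j <- j + 1L
    ok_left <- i == 1L || (!is.na(y[i - 1L]) && y[i] > y[i - 1L])
    ok_right <- j == n || (!is.na(y[j + 1L]) && y[i] > y[j + 1L])
    if (ok_left && ok_right && !(i == 1L && j == n))
      out <- c(out, as.integer((i + j) %/% 2))
    i <- j + 1L
  }
  out
}

#' Fit a response field to a response profile
#'
#' The profile is peak-normalized to 1; local maxima above its 25th percentile
#' seed a bounded nonlinear least-squares fit of a sum of Gaussians
#' (`0 <= c <= L`, `0 <= a <= 1`, `0 <= sigma <= L/2`). The response field is
#' the component with the largest fitted amplitude (ties: smaller sigma, then
#' smaller center); field width is `2 * sigma`. Undefined profile bins are
#' excluded from the fit.
#'
#' @param rp A `response_profile`, or a numeric profile vector.
#' @param corridor_length_cm Track length (cm), used when `rp` is a bare
#'   vector.
#' @return Object of class `response_field`: list with `center`, `sigma`,
#'   `width`, `amplitude`, `status` (`"ok"`, `"no_field"` or `"fit_failed"`)
#'   and `components` (data.frame of all fitted Gaussians).
#' @export
fit_response_field <- function(rp, corridor_length_cm = 180) {
  if (inherits(rp, "response_profile")) {
    y <- rp$rp
    x <- rp$bin_centers
    L <- rp$bin_width_cm * length(y)
  } else {
    y <- as.numeric(rp)
    L <- corridor_length_cm
    x <- (seq_along(y) - 0.5) * L / length(y)
  }
  no_field <- structure(list(center = NA_real_, sigma = NA_real_,
                             width = NA_real_, amplitude = NA_real_,
                             status = "no_field",
                             components = NULL), class = "response_field")
  ok <- !is.na(y) & is.finite(y)
  if (!any(ok) || max(y[ok]) <= 0) return(no_field)
  yn <- y / max(y[ok])
  seeds <- local_maxima(yn)
  thr <- stats::quantile(yn[ok], 0.25, names = FALSE, type = 7)
  seeds <- seeds[!is.na(yn[seeds]) & yn[seeds] > thr]
  if (!length(seeds)) return(no_field)

  m <- length(seeds)
  par0 <- c(pmin(yn[seeds], 1), x[seeds], rep(10, m))
  lower <- c(rep(0, m), rep(0, m), rep(0, m))
  upper <- c(rep(1, m), rep(L, m), rep(L / 2, m))
  model <- function(p, xx) {
    a <- p[seq_len(m)]; cc <- p[m + seq_len(m)]; s <- p[2 * m + seq_len(m)]
    rowSums(vapply(seq_len(m), function(i)
      a[i] * exp(-(xx - cc[i])^2 / (2 * pmax(s[i], 1e-6)^2)), numeric(length(xx))))
  }
  fit <- tryCatch(minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper,
    fn = function(p) yn[ok] - model(p, x[ok]),
    control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- no_field
    out$status <- "fit_failed"
    return(out)
  }
  p <- fit$par
  comps <- data.frame(amplitude = p[seq_len(m)],
                      center = p[m + seq_len(m)],
                      sigma = p[2 * m + seq_len(m)])
  ## deterministic selection: max amplitude, ties to smaller sigma, smaller c
  ordc <- order(-comps$amplitude, comps$sigma, comps$center)
  best <- comps[ordc[1L], ]
  structure(list(center = best$center, sigma = best$sigma,
                 width = 2 * best$sigma, amplitude = best$amplitude,
                 status = "ok", components = comps),
            class = "response_field")
}

#' Response-field reliability (odd versus even trials)
#'
#' `1 - |c_odd - c_even| / (2 * min(sigma_odd, sigma_even))`: the field-center
#' displacement between trial subsets, inversely weighted by the most
#' conservative width estimate. An ROI is reliable when this exceeds 0.
#'
#' @param field_odd,field_even `response_field` objects fitted on odd / even
#'   running trials.
#' @return Numeric reliability index.
#' @export
compute_reliability <- function(field_odd, field_even) {
  if (field_odd$status != "ok" || field_even$status != "ok")
    stop("both response fields must exist", call. = FALSE)
  ms <- min(field_odd$sigma, field_even$sigma)
  if (ms == 0) stop("zero field width: reliability undefined", call. = FALSE)
  1 - abs(field_odd$center - field_even$center) / (2 * ms)
}

#' Response-field stability (session halves)
#'
#' Stable if the field centers fitted on the first and second half of the
#' session differ by less than 15 cm (strict). A missing field in either half
#' counts as not stable.
#'
#' @param field_h1,field_h2 `response_field` objects from the session halves.
#' @param max_shift_cm Stability cutoff (cm).
#' @return Logical flag.
#' @export
classify_stability <- function(field_h1, field_h2, max_shift_cm = 15) {
  if (field_h1$status != "ok" || field_h2$status != "ok") return(FALSE)
  abs(field_h1$center - field_h2$center) < max_shift_cm
}

#' Jackknife mean and standard error of the response profile
#'
#' Leave-one-trial-out profiles `RP_i`; jackknife mean and
#' `SE = sqrt((n-1)/n * sum_i (RP_i - mean)^2)` per bin.
#'
#' @inheritParams compute_maps
#' @return List with `mean`, `se` (per bin) and `profiles`
#'   (trials x bins matrix).
#' @export
jackknife_profile <- function(event_values, trajectory, trials, n_bins = 80,
                              corridor_length_cm = 180,
                              kernel_sigma_bins = 3) {
  n <- nrow(trials)
  if (n < 2L) stop("jackknife requires at least 2 running trials",
                   call. = FALSE)
  profiles <- matrix(NA_real_, n, n_bins)
  for (i in seq_len(n)) {
    maps <- compute_maps(event_values, trajectory, trials[-i, , drop = FALSE],
                         n_bins, corridor_length_cm, kernel_sigma_bins)
    profiles[i, ] <- response_profile(maps)$rp
  }
  mu <- colMeans(profiles)
  se <- sqrt((n - 1) / n * colSums(sweep(profiles, 2, mu)^2))
  list(mean = mu, se = se, profiles = profiles)
}

#' Spatial precision of calcium responses
#'
#' Bins the corridor in `m` bins (40 by default), computes per-trial centers
#' of mass of the event trace, their amplitude-weighted mean, and the inverse
#' amplitude-weighted trial-by-trial squared dispersion. Trials with no events
#' are skipped; zero dispersion yields `+Inf` with attribute
#' `zero_dispersion = TRUE`.
#'
#' @inheritParams compute_maps
#' @param m Number of spatial bins for the center-of-mass computation.
#' @return Spatial precision (scalar) with attributes `com` (per-trial
#'   centers of mass), `weights` and `zero_dispersion`.
#' @export
spatial_precision <- function(event_values, trajectory, trials, m = 40,
                              corridor_length_cm = 180) {
  fr <- if (inherits(trajectory, "trajectory")) trajectory$frames else trajectory
  bw <- corridor_length_cm / m
  xc <- (seq_len(m) - 0.5) * bw
  com <- amp <- numeric(0)
  for (i in seq_len(nrow(trials))) {
    idx <- trials$start[i]:trials$end[i]
    v <- event_values[idx]
    if (all(v == 0)) next
    bin <- pmin(pmax(floor(fr$position[idx] / bw), 0), m - 1L) + 1L
    df <- vapply(seq_len(m), function(b) {
      vv <- v[bin == b]
      if (length(vv)) mean(vv) else 0
    }, numeric(1))
    if (sum(df) <= 0) next
    com <- c(com, sum(df * xc) / sum(df))
    amp <- c(amp, max(v))
  }
  if (length(com) < 2L)
    stop("spatial precision requires >= 2 trials with events", call. = FALSE)
  comw <- sum(amp * com) / sum(amp)
  disp <- sum(amp * (com - comw)^2) / sum(amp)
  sp <- if (disp == 0) Inf else 1 / disp
  attr(sp, "com") <- com
  attr(sp, "weights") <- amp
  attr(sp, "zero_dispersion") <- disp == 0
  sp
}

#' Dynamic range of an event trace
#'
#' `max - min` of the event-trace values; used to put astrocytic and neuronal
#' indicators on a comparable scale.
#'
#' @param event_trace An `event_trace` or numeric vector.
#' @return Scalar dynamic range.
#' @export
dynamic_range <- function(event_trace) {
  v <- if (inherits(event_trace, "event_trace")) event_trace$values else
    event_trace
  max(v) - min(v)
}

#' Correct neuronal spatial precision for indicator dynamic range
#'
#' Multiplies neuronal spatial-precision values by the ratio of the session's
#' mean astrocytic to mean neuronal event-trace dynamic range.
#'
#' @param sp_values Neuronal spatial-precision values.
#' @param dr_astro_mean,dr_neuron_mean Session mean dynamic ranges; must be
#'   positive.
#' @return Corrected values.
#' @export
dynamic_range_correction <- function(sp_values, dr_astro_mean,
                                     dr_neuron_mean) {
  if (dr_astro_mean <= 0 || dr_neuron_mean <= 0)
    stop("dynamic ranges must be positive", call. = FALSE)
  sp_values * (dr_astro_mean / dr_neuron_mean)
}

field_membership <- function(position, center, sigma, corridor_length_cm = 180,
                             circular = FALSE) {
  if (!circular) return(abs(position - center) <= sigma)
  d <- abs((position - center) %% corridor_length_cm)
  pmin(d, corridor_length_cm - d) <= sigma
}

#' Directionality index of a spatially modulated response
#'
#' `DI = (Fd - Fo) / (Fd + Fo)` where `Fd` is the mean dF/F0 inside the
#' response field while running in the field's direction and `Fo` the mean at
#' the same positions in the opposite direction.
#'
#' @param dff Per-frame dF/F0 values aligned to the trajectory.
#' @param field A `response_field` (fitted in the field's running direction).
#' @param trajectory `trajectory` object or frame data.frame.
#' @param trials_field,trials_opposite Running trials in the field's and the
#'   opposite direction.
#' @return Numeric DI.
#' @export
directionality_index <- function(dff, field, trajectory, trials_field,
                                 trials_opposite) {
  fr <- if (inherits(trajectory, "trajectory")) trajectory$frames else trajectory
  pick <- function(trials) {
    idx <- trial_frames(trials)
    idx[field_membership(fr$position[idx], field$center, field$sigma)]
  }
  fd <- mean(dff[pick(trials_field)])
  fo <- mean(dff[pick(trials_opposite)])
  if (fd + fo == 0) stop("in-field response sums to zero: DI undefined",
                         call. = FALSE)
  (fd - fo) / (fd + fo)
}

#' Null distribution for the directionality index
#'
#' Each draw picks one informative ROI at random and circularly shifts its
#' response-field location along the track (preserving the width) before
#' recomputing the DI, yielding the distribution of DI values at arbitrary
#' field locations.
#'
#' @param dff_list List of per-frame dF/F0 vectors (informative ROIs).
#' @param fields List of matching `response_field` objects.
#' @param trajectory `trajectory` object or frame data.frame.
#' @param trials_field,trials_opposite Running trials in each direction.
#' @param n_draws Number of surrogate draws.
#' @param seed Integer seed.
#' @return Numeric vector of surrogate DI values (`NA` for degenerate draws).
#' @export
directionality_null <- function(dff_list, fields, trajectory, trials_field,
                                trials_opposite, n_draws = 1e5, seed = 1L) {
  stopifnot(length(dff_list) == length(fields), length(fields) > 0)
  fr <- if (inherits(trajectory, "trajectory")) trajectory$frames else trajectory
  idx_d <- trial_frames(trials_field)
  idx_o <- trial_frames(trials_opposite)
  set.seed(derive_seed(seed, 4L))
  rois <- sample.int(length(fields), n_draws, replace = TRUE)
  shifts <- stats::runif(n_draws, 0, 180)
  vapply(seq_len(n_draws), function(k) {
    f <- fields[[rois[k]]]
    dff <- dff_list[[rois[k]]]
    c2 <- (f$center + shifts[k]) %% 180
    ind <- field_membership(fr$position[idx_d], c2, f$sigma, circular = TRUE)
    ino <- field_membership(fr$position[idx_o], c2, f$sigma, circular = TRUE)
    fd <- mean(dff[idx_d[ind]])
    fo <- mean(dff[idx_o[ino]])
    if (!is.finite(fd) || !is.finite(fo) || fd + fo == 0) return(NA_real_)
    (fd - fo) / (fd + fo)
  }, numeric(1))
}
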