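#' Pairwise metric versus anatomical distance
#'
#' Computes a metric (Pearson correlation of event traces, or absolute
#' response-field center difference) for every qualifying ROI pair and bins it
#' by Euclidean centroid distance (20-um bins centered at 10, 30, ..., um).
#' Pair classes follow the study's taxonomy: astro-astro within the same cell
#' (`"A-A-same"`), astro-astro across cells (`"A-A-other"`), neuron-neuron
#' (`"N-N"`) and mixed (`"A-N"`).
#'
#' @param rois data.frame with one row per ROI: `roi_id`, `kind`, `x_um`,
#'   `y_um`, optionally `parent_cell_id` and `field_center`.
#' @param metric `"correlation"` (requires `traces`) or `"field_distance"`
#'   (requires `field_center`).
#' @param traces Frames x ROI matrix of event-trace (or dF/F0) values,
#'   columns matching `rois$roi_id`.
#' @param pair_class Optional filter: one of `"A-A-same"`, `"A-A-other"`,
#'   `"N-N"`, `"A-N"`; `NULL` keeps all pairs.
#' @param bin_width_um Distance bin width (um).
#' @return List of class `distance_profile`: `pairs` (per-pair data.frame
#'   with `distance_um`, `value`, `class`), `profile` (per-bin data.frame with
#'   `bin_center_um`, `mean`, `sem`, `n`).
#' @export
pair_metric_vs_distance <- function(rois, metric = c("correlation",
                                                     "field_distance"),
                                    traces = NULL, pair_class = NULL,
                                    bin_width_um = 20) {
  metric <- match.arg(metric)
  n <- nrow(rois)
  if (n < 2L) stop("need at least 2 ROIs", call. = FALSE)
  if (metric == "correlation" && is.null(traces))
    stop("metric 'correlation' requires traces", call. = FALSE)
  if (metric == "field_distance" && is.null(rois$field_center))
    stop("metric 'field_distance' requires a field_center column",
         call. = FALSE)
  is_astro <- grepl("^astro", rois$kind)
  parent <- rois$parent_cell_id %||% rep(NA_character_, n)
  ## cell identity: a soma is its own cell; processes belong to their parent
  cell <- ifelse(rois$kind == "astro-soma", rois$roi_id, parent)
  pairs <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    cls <- if (is_astro[i] && is_astro[j]) {
      if (!is.na(cell[i]) && !is.na(cell[j]) && cell[i] == cell[j])
        "A-A-same" else "A-A-other"
    } else if (!is_astro[i] && !is_astro[j]) "N-N" else "A-N"
    if (!is.null(pair_class) && cls != pair_class) next
    val <- if (metric == "correlation") {
      stats::cor(traces[, rois$roi_id[i]], traces[, rois$roi_id[j]])
    } else {
      abs(rois$field_center[i] - rois$field_center[j])
    }
    if (is.na(val)) next
    pairs[[length(pairs) + 1L]] <- data.frame(
      roi_i = rois$roi_id[i], roi_j = rois$roi_id[j],
      distance_um = sqrt((rois$x_um[i] - rois$x_um[j])^2 +
                           (rois$y_um[i] - rois$y_um[j])^2),
      value = val, class = cls)
  }
  if (!length(pairs)) stop("no qualifying pairs", call. = FALSE)
  pairs <- do.call(rbind, pairs)
  bin <- floor(pairs$distance_um / bin_width_um)
  profile <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    v <- pairs$value[bin == b]
    data.frame(bin_center_um = (b + 0.5) * bin_width_um,
               mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                     else NA_real_,
               n = length(v))
  }))
  structure(list(pairs = pairs, profile = profile,
                 metric = metric, bin_width_um = bin_width_um),
            class = "distance_profile")
}

#' Exponential fit of a distance profile
#'
#' Fits `y = y_inf + (y_0 - y_inf) * exp(-d / tau)` (decay toward a plateau)
#' or the mirrored rise `y = y_inf - (y_inf - y_0) * exp(-d / tau)` by
#' nonlinear least squares, reporting the length constant, the plateau and
#' R-squared. Constant profiles leave tau unidentifiable and are flagged.
#'
#' @param distances,values Profile points (>= 4 distinct distances).
#' @param kind `"decay"` or `"rise"` (the two parameterizations are
#'   algebraically identical; the label records the expected direction).
#' @return List: `tau`, `y0`, `plateau`, `r_squared`, `converged`.
#' @export
fit_exponential_profile <- function(distances, values,
                                    kind = c("decay", "rise")) {
  kind <- match.arg(kind)
  ok <- is.finite(distances) & is.finite(values)
  d <- distances[ok]; y <- values[ok]
  if (length(unique(d)) < 4L)
    stop("need at least 4 distance bins", call. = FALSE)
  flagged <- list(tau = NA_real_, y0 = NA_real_, plateau = NA_real_,
                  r_squared = NA_real_, converged = FALSE)
  if (stats::sd(y) == 0) return(flagged)
  tau0 <- max(diff(range(d)) / 3, 1e-6)
  fit <- tryCatch(minpack.lm::nlsLM(
    y ~ yinf + (y0 - yinf) * exp(-d / tau),
    data = data.frame(d = d, y = y),
    start = list(yinf = y[which.max(d)], y0 = y[which.min(d)], tau = tau0),
    lower = c(-Inf, -Inf, 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(flagged)
  cf <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(tau = cf[["tau"]], y0 = cf[["y0"]], plateau = cf[["yinf"]],
       r_squared = 1 - ss_res / ss_tot, converged = TRUE)
}

#' Position-dependent pairwise correlation
#'
#' Splits the frames of a pair of traces into inside-field and outside-field
#' sets (inside = positions within one half-width, `[c - sigma, c + sigma]`,
#' of the response-field center). The larger set is repeatedly subsampled to
#' the smaller set's size, preserving temporal ordering, and the Pearson
#' correlation is averaged over the draws.
#'
#' @param r1,r2 Aligned per-frame traces.
#' @param position Per-frame positions (cm).
#' @param field A `response_field` (defines inside/outside).
#' @param n_resample Number of balanced resampling draws.
#' @param seed Integer seed.
#' @return List: `r_inside`, `r_outside`, `n_inside`, `n_outside`,
#'   `draws_inside`, `draws_outside`.
#' @export
position_dependent_correlation <- function(r1, r2, position, field,
                                           n_resample = 100, seed = 1L) {
  stopifnot(length(r1) == length(r2), length(r1) == length(position))
  inside <- which(field_membership(position, field$center, field$sigma))
  outside <- setdiff(seq_along(position), inside)
  if (!length(inside) || !length(outside))
    stop("empty inside or outside set", call. = FALSE)
  m <- min(length(inside), length(outside))
  set.seed(derive_seed(seed, 15L))
  draw_cor <- function(idx) {
    sub <- if (length(idx) > m) sort(sample(idx, m)) else idx
    stats::cor(r1[sub], r2[sub])
  }
  di <- vapply(seq_len(n_resample), function(k) draw_cor(inside), numeric(1))
  do <- vapply(seq_len(n_resample), function(k) draw_cor(outside), numeric(1))
  list(r_inside = mean(di, na.rm = TRUE), r_outside = mean(do, na.rm = TRUE),
       n_inside = length(inside), n_outside = length(outside),
       draws_inside = di, draws_outside = do)
}

#' Event-triggered average
#'
#' Averages segments of a receiver trace aligned to the onsets (first frame)
#' of the source ROI's detected events; returns the mean and SD bands over
#' events. Onsets whose window would leave the recording are dropped.
#'
#' @param source_events An `event_trace` (or data.frame of events with a
#'   `start` column and, if present, a `sign` column; only positive events
#'   are used).
#' @param receiver_dff Receiver dF/F0 trace.
#' @param window_s Half-window (s) on each side of the onset.
#' @param frame_rate_hz Sampling rate (Hz).
#' @return List: `lag_s`, `mean`, `sd`, `n_events`, `segments` (events x
#'   lags matrix).
#' @export
event_triggered_average <- function(source_events, receiver_dff,
                                    window_s = 10, frame_rate_hz = 3) {
  ev <- if (inherits(source_events, "event_trace")) source_events$events
        else source_events
  if (!is.null(ev$sign)) ev <- ev[ev$sign > 0, , drop = FALSE]
  if (!nrow(ev)) stop("no source events", call. = FALSE)
  w <- round(window_s * frame_rate_hz)
  onsets <- ev$start
  onsets <- onsets[onsets - w >= 1 & onsets + w <= length(receiver_dff)]
  if (!length(onsets))
    stop("no events with a full window inside the recording", call. = FALSE)
  seg <- t(vapply(onsets, function(o) receiver_dff[(o - w):(o + w)],
                  numeric(2 * w + 1)))
  list(lag_s = (-w:w) / frame_rate_hz,
       mean = colMeans(seg),
       sd = apply(seg, 2, stats::sd),
       n_events = length(onsets),
       segments = seg)
}
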