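#' Two-stage noise estimate for a dF/F0 trace
#'
#' `sigma1` is the SD of the full trace; samples with `|x| > sigma1` are then
#' removed (suppressing the influence of large transients) and `sigma2` is the
#' SD of what remains, an estimate of baseline fluctuation amplitude.
#'
#' @param dff Numeric dF/F0 trace.
#' @return List of class `noise_sigmas` with `sigma1`, `sigma2`.
#' @export
estimate_noise_sigmas <- function(dff) {
  if (!length(dff)) stop("empty trace", call. = FALSE)
  sigma1 <- stats::sd(dff)
  if (length(dff) == 1L || is.na(sigma1)) sigma1 <- 0
  kept <- dff[abs(dff) <= sigma1]
  if (!length(kept))
    stop("all samples removed by sigma1 thresholding; degenerate trace",
         call. = FALSE)
  sigma2 <- if (length(kept) > 1L) stats::sd(kept) else 0
  structure(list(sigma1 = sigma1, sigma2 = sigma2), class = "noise_sigmas")
}

## Events on one side of the trace. An event is a maximal contiguous run of
## frames beyond the return threshold that contains at least one crossing of
## the entry threshold; its duration runs from the first entry-level frame to
## the return below the return threshold, and must exceed min_dur_s (strict).
side_events <- function(x, entry, ret, frame_rate, min_dur_s = 0.5) {
  runs <- rle(x > ret)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- list()
  for (k in seq_along(runs$lengths)) {
    if (!runs$values[k]) next
    s <- starts[k]; e <- ends[k]
    ent <- which(x[s:e] > entry)
    if (!length(ent)) next
    entry_frame <- s + ent[1L] - 1L
    dur_s <- (e + 1L - entry_frame) / frame_rate
    if (dur_s > min_dur_s)
      out[[length(out) + 1L]] <- c(start = s, end = e, entry = entry_frame)
  }
  out
}

#' Detect statistically significant calcium transients
#'
#' Applies the two-threshold rule on the dF/F0 trace: astrocytic events cross
#' `+/- 2 sigma2` and return within `+/- sigma2` only after more than 0.5 s;
#' neuronal events cross `+/- 3 sigma2` and return within `+/- 2 sigma2` after
#' more than 0.5 s. Positive and negative deflections are both detected
#' (negatives enter only the false-discovery-rate estimate, [compute_fdr()]).
#' The event trace zeroes every frame outside positive events.
#'
#' @param dff Numeric dF/F0 trace.
#' @param roi_kind `"astro"` (also `"astro-soma"`, `"astro-process"`) or
#'   `"neuron"`.
#' @param frame_rate_hz Sampling rate (Hz); must be positive.
#' @param min_duration_s Minimum event duration (s), strict.
#' @param sigmas Optional precomputed [estimate_noise_sigmas()] result;
#'   computed from `dff` when omitted (once per full session trace).
#' @return Object of class `event_trace`: list with `values` (event trace),
#'   `events` (data.frame `start`, `end`, `sign`, `peak`), `sigmas`, `n_pos`,
#'   `n_neg`, `roi_kind`, `frame_rate_hz`.
#' @export
detect_transients <- function(dff, roi_kind = "astro", frame_rate_hz = 3,
                              min_duration_s = 0.5, sigmas = NULL) {
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be positive", call. = FALSE)
  if (is.null(sigmas)) sigmas <- estimate_noise_sigmas(dff)
  mult <- if (grepl("^astro", roi_kind)) c(entry = 2, ret = 1) else
    c(entry = 3, ret = 2)
  entry <- mult[["entry"]] * sigmas$sigma2
  ret <- mult[["ret"]] * sigmas$sigma2

  collect <- function(ev, x, sign) {
    if (!length(ev)) return(NULL)
    do.call(rbind, lapply(ev, function(v) data.frame(
      start = v[["start"]], end = v[["end"]], sign = sign,
      peak = sign * max(x[v[["start"]]:v[["end"]]]))))
  }
  pos <- side_events(dff, entry, ret, frame_rate_hz, min_duration_s)
  neg <- side_events(-dff, entry, ret, frame_rate_hz, min_duration_s)
  events <- rbind(collect(pos, dff, 1L), collect(neg, -dff, -1L))
  if (is.null(events))
    events <- data.frame(start = integer(0), end = integer(0),
                         sign = integer(0), peak = numeric(0))
  events <- events[order(events$start), , drop = FALSE]
  rownames(events) <- NULL

  values <- numeric(length(dff))
  for (i in which(events$sign == 1L))
    values[events$start[i]:events$end[i]] <-
      dff[events$start[i]:events$end[i]]

  structure(list(values = values, events = events, sigmas = sigmas,
                 n_pos = sum(events$sign == 1L),
                 n_neg = sum(events$sign == -1L),
                 roi_kind = roi_kind, frame_rate_hz = frame_rate_hz),
            class = "event_trace")
}

#' False discovery rate of event detection
#'
#' `FDR = NEn / (NEp + NEn)` from the counts of positive and negative
#' detected deflections; the detector's thresholds were designed so this
#' stays below 5 percent on real recordings.
#'
#' @param n_pos,n_neg Counts of positive / negative detected deflections, or
#'   an `event_trace` as the first argument.
#' @return Fraction in `[0, 1]`.
#' @export
compute_fdr <- function(n_pos, n_neg = NULL) {
  if (inherits(n_pos, "event_trace")) {
    n_neg <- n_pos$n_neg
    n_pos <- n_pos$n_pos
  }
  if (n_pos + n_neg == 0)
    stop("no detected events: FDR undefined; detect transients first or ",
         "check thresholds", call. = FALSE)
  n_neg / (n_pos + n_neg)
}

#' Export an event table for a set of ROIs
#'
#' @param event_traces Named list of `event_trace` objects.
#' @return data.frame with `roi_id`, `start_frame`, `end_frame`, `sign`,
#'   `peak_dff`.
#' @export
event_table <- function(event_traces) {
  out <- lapply(names(event_traces), function(id) {
    ev <- event_traces[[id]]$events
    if (!nrow(ev)) return(NULL)
    data.frame(roi_id = id, start_frame = ev$start, end_frame = ev$end,
               sign = ev$sign, peak_dff = ev$peak)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(roi_id = character(0), start_frame = integer(0),
                      end_frame = integer(0), sign = integer(0),
                      peak_dff = numeric(0))
  out
}
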