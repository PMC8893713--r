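#' Rolling-percentile baseline dF/F0
#'
#' Computes `F0(t)` as a low percentile of the raw trace in a centered rolling
#' window (truncated, not padded, at the trace ends) and returns
#' `(F - F0) / F0`. Astrocytic traces use a 30-s window; neuronal traces a
#' 10-s window; both use the 20th percentile.
#'
#' @param trace Raw fluorescence trace (positive where division occurs).
#' @param frame_rate_hz Sampling rate (Hz).
#' @param window_s Rolling window length (s); must be positive.
#' @param percentile Baseline percentile (0-100).
#' @param roi_kind Optional convenience: `"astro"`/`"astro-soma"`/
#'   `"astro-process"` selects 30 s, `"neuron"` 10 s, overriding `window_s`.
#' @return An object of class `dff_trace`: list with `values` (dF/F0 per
#'   frame), `baseline` (F0 per frame), `window_s`, `percentile`, `roi_kind`.
#' @export
rolling_baseline_dff <- function(trace, frame_rate_hz, window_s = 30,
                                 percentile = 20, roi_kind = NULL) {
  if (!is.null(roi_kind)) {
    window_s <- if (grepl("^astro", roi_kind)) 30 else 10
  }
  if (window_s <= 0) stop("window_s must be positive", call. = FALSE)
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be positive", call. = FALSE)
  half <- max(1L, round(window_s * frame_rate_hz / 2))
  f0 <- rolling_percentile(trace, half, percentile)
  bad <- which(f0 == 0)
  if (length(bad))
    stop("baseline F0 is zero at frame(s) ", paste(utils::head(bad, 5L),
         collapse = ", "), "; dF/F0 undefined", call. = FALSE)
  structure(list(values = (trace - f0) / f0, baseline = f0,
                 window_s = window_s, percentile = percentile,
                 roi_kind = roi_kind %||% NA_character_),
            class = "dff_trace")
}

#' Neuropil subtraction
#'
#' Subtracts a scaled neuropil trace from a neuronal somatic trace before
#' dF/F0 normalization: `trace - r * neuropil_trace`.
#'
#' @param trace Somatic fluorescence trace.
#' @param neuropil_trace Neuropil trace of equal length.
#' @param r Contamination factor (default 0.7).
#' @return Corrected trace.
#' @export
neuropil_subtract <- function(trace, neuropil_trace, r = 0.7) {
  if (length(trace) != length(neuropil_trace))
    stop("trace and neuropil_trace lengths differ", call. = FALSE)
  trace - r * neuropil_trace
}

#' Select ROI pixels by signal-to-noise ratio
#'
#' Per-pixel SNR is the peak fluorescence divided by the SD of the samples
#' below that pixel's 25th fluorescence percentile; pixels whose SNR is
#' strictly greater than the 80th percentile of the box's SNR distribution are
#' kept. Pixels with zero sub-quartile variance get infinite SNR (always
#' selected) and are reported via the `n_infinite` attribute.
#'
#' @param pixel_stack Matrix (frames x pixels) of per-pixel time series within
#'   a bounding box.
#' @return Logical pixel mask with attributes `snr` (per-pixel values) and
#'   `n_infinite`.
#' @export
select_pixels_by_snr <- function(pixel_stack) {
  stopifnot(is.matrix(pixel_stack), nrow(pixel_stack) > 1)
  snr <- apply(pixel_stack, 2, function(px) {
    q25 <- stats::quantile(px, 0.25, names = FALSE, type = 7)
    noise <- stats::sd(px[px < q25])
    if (is.na(noise) || noise == 0) Inf else max(px) / noise
  })
  thr <- stats::quantile(snr[is.finite(snr)], 0.80, names = FALSE, type = 7)
  if (is.na(thr)) thr <- -Inf   # all-infinite degenerate box
  mask <- snr > thr
  attr(mask, "snr") <- snr
  attr(mask, "n_infinite") <- sum(is.infinite(snr))
  mask
}
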