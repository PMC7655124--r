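#' Background scaling factor for spike detection
#'
#' The detector normalizes channels against a reference background level so
#' amplitude/slope thresholds transfer across recordings: the channel is
#' filtered to 1-35 Hz and the scale is
#' `reference_background_uv / median(|filtered|)`. Multiplying the channel by
#' this scale maps its background to the reference level; thresholds are then
#' expressed in scaled (reference) units.
#'
#' @param x Signal vector (uV).
#' @param fs Sampling rate, Hz.
#' @param reference_background_uv Reference background amplitude (default 30,
#'   the median absolute 1-35 Hz amplitude the thresholds were chosen for).
#' @param band Background band, Hz (default 1-35).
#' @return A positive scalar scale factor.
#' @examples
#' x <- generate_background(10, 2000, seed = 1)
#' compute_scaling_factor(2 * x, 2000) / compute_scaling_factor(x, 2000)  # 0.5
#' @export
compute_scaling_factor <- function(x, fs, reference_background_uv = 30,
                                   band = c(1, 35)) {
  bg <- bandpass(x, fs, band[1], band[2])
  m <- median(abs(bg))
  if (m == 0) abort("compute_scaling_factor: degenerate (zero-variance) signal")
  reference_background_uv / m
}

#' Detect interictal epileptiform discharges
#'
#' Amplitude/slope spike detector in the style of Barkmeier et al.: the
#' channel is scaled by the 1-35 Hz background factor, filtered to 20-50 Hz,
#' and candidate peaks (local extrema of the scaled filtered signal) become
#' detections when the peak-to-trough amplitude to both neighboring extrema
#' and the corresponding rising and falling slopes exceed their thresholds.
#' Detections closer than the refractory gap are merged keeping the larger.
#' The reported amplitude is measured peak-to-trough on the unfiltered
#' wide-band signal around the detection (physiological uV), not on the
#' 20-50 Hz trace.
#'
#' @param x Signal vector (uV), or a [recording_segment()] (then all channels
#'   are processed and a `channel_id` column is added).
#' @param fs Sampling rate, Hz (taken from the segment if given).
#' @param scale Scaling factor; computed by [compute_scaling_factor()] when
#'   `NULL`.
#' @param amp_threshold Minimum scaled peak-to-trough amplitude in the
#'   20-50 Hz trace, uV (default 60).
#' @param slope_threshold Minimum scaled slope, uV/ms (default 3).
#' @param refractory_s Merge gap, seconds (default 0.2).
#' @param spike_band Detection band, Hz (default 20-50).
#' @param config Optional [pipeline_config()]; its `ied` section overrides
#'   the individual defaults.
#' @return A tibble with one row per event: `t_peak` (s), `amplitude_uv`
#'   (wide-band peak-to-trough), `slope_uv_ms` (scaled 20-50 Hz slope), and
#'   `channel_id` when a segment was given.
#' @export
detect_ied <- function(x, fs = NULL, scale = NULL, amp_threshold = 60,
                       slope_threshold = 3, refractory_s = 0.2,
                       spike_band = c(20, 50), config = NULL) {
  if (!is.null(config)) {
    ie <- config$ied
    amp_threshold <- ie$amp_threshold_uv
    slope_threshold <- ie$slope_threshold_uv_ms
    refractory_s <- ie$refractory_s
    spike_band <- ie$spike_band
  }
  if (inherits(x, "recording_segment")) {
    res <- lapply(seq_len(ncol(x$signals)), function(j) {
      ev <- detect_ied(x$signals[, j], x$fs, scale = NULL,
                       amp_threshold = amp_threshold,
                       slope_threshold = slope_threshold,
                       refractory_s = refractory_s, spike_band = spike_band)
      if (nrow(ev) > 0) ev$channel_id <- x$channels$channel_id[j]
      ev
    })
    out <- dplyr::bind_rows(res)
    if (nrow(out) == 0) {
      out <- tibble::tibble(t_peak = numeric(), amplitude_uv = numeric(),
                            slope_uv_ms = numeric(), channel_id = character())
    }
    return(dplyr::relocate(out, "channel_id"))
  }
  if (is.null(fs)) abort("detect_ied: fs required")
  if (!(amp_threshold > 0 && slope_threshold > 0)) {
    abort("detect_ied: thresholds must be positive")
  }
  empty <- tibble::tibble(t_peak = numeric(), amplitude_uv = numeric(),
                          slope_uv_ms = numeric())
  if (sd(x) == 0) return(empty)
  if (is.null(scale)) scale <- compute_scaling_factor(x, fs)
  y <- scale * bandpass(x, fs, spike_band[1], spike_band[2])
  d <- diff(y)
  ext <- which(d[-1] * d[-length(d)] < 0) + 1L  # local extrema
  if (length(ext) < 3) return(empty)
  cand <- ext[-c(1, length(ext))]
  prev <- ext[seq_along(cand)]
  nxt <- ext[seq_along(cand) + 2L]
  a1 <- abs(y[cand] - y[prev]); a2 <- abs(y[nxt] - y[cand])
  s1 <- a1 / ((cand - prev) / fs * 1000)  # uV/ms
  s2 <- a2 / ((nxt - cand) / fs * 1000)
  keep <- pmin(a1, a2) >= amp_threshold & pmin(s1, s2) >= slope_threshold
  if (!any(keep)) return(empty)
  cand <- cand[keep]
  strength <- pmin(a1, a2)[keep]
  slope <- pmin(s1, s2)[keep]
  # refractory suppression: accept strongest first, drop anything closer
  # than the gap to an accepted event
  ord <- order(-strength)
  accepted <- integer(0)
  gap <- refractory_s * fs
  for (i in ord) {
    if (!any(abs(cand[accepted] - cand[i]) < gap)) {
      accepted <- c(accepted, i)
    }
  }
  accepted <- sort(accepted)
  cand <- cand[accepted]; slope <- slope[accepted]
  half <- round(0.04 * fs)
  amp_wb <- vapply(cand, function(p) {
    w <- x[max(1, p - half):min(length(x), p + half)]
    max(w) - min(w)
  }, 0)
  tibble::tibble(t_peak = (cand - 1) / fs, amplitude_uv = amp_wb,
                 slope_uv_ms = slope)
}

#' Screen a hippocampus by its spiking rate
#'
#' Putative non-epileptic hippocampi with excessive interictal spiking
#' (50 or more per 10 min) require visual review of whether the discharges
#' propagate from elsewhere; below that they pass automatically.
#'
#' @param ied_rate_per_10min Non-negative spike rate per 10 minutes.
#' @param threshold Review threshold (default 50; strict `<` passes).
#' @return `"pass"` or `"review"` (vectorized).
#' @examples
#' screen_hippocampus(c(49.9, 50, 0))
#' @export
screen_hippocampus <- function(ied_rate_per_10min, threshold = 50) {
  if (any(ied_rate_per_10min < 0)) {
    abort("screen_hippocampus: rate must be non-negative")
  }
  ifelse(ied_rate_per_10min < threshold, "pass", "review")
}
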