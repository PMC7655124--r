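#' Analysis band layout for the HFO detector
#'
#' 300 logarithmically spaced center frequencies between 60 and 800 Hz. Each
#' center is realized as a Gaussian band-pass whose spectral sigma is
#' `center / band_q`, i.e. constant-Q: bandwidth grows with frequency so that
#' the filter's impulse response always rings for about the same number of
#' cycles (`band_q / (2 pi)` cycles sigma). Oscillations lasting a handful of
#' cycles are therefore resolved in time at every frequency, which a gapless
#' tiling of ~1 Hz-wide bands could not do (a 1.5 Hz-wide filter rings for
#' roughly a second, an order of magnitude longer than a ripple).
#' Neighboring bands overlap heavily; "adjacent" in the joining step means
#' neighboring center frequencies.
#'
#' @param n_bands Number of bands (default 300).
#' @param fmin,fmax Frequency range, Hz (default 60-800).
#' @param band_q Center-to-sigma ratio (default 4.5).
#' @return A tibble with columns `band`, `center`, `sigma`, `f_lo`, `f_hi`
#'   (full-width-half-maximum edges) and `width` (FWHM, Hz).
#' @examples
#' b <- hfo_bands()
#' b$center[c(1, 300)]           # 60 and 800
#' b$center[2] / b$center[1]     # constant neighbor ratio
#' @export
hfo_bands <- function(n_bands = 300, fmin = 60, fmax = 800, band_q = 4.5) {
  stopifnot(n_bands >= 2, fmin > 0, fmin < fmax)
  centers <- exp(seq(log(fmin), log(fmax), length.out = n_bands))
  sigma <- centers / band_q
  fwhm <- 2 * sqrt(2 * log(2)) * sigma
  tibble::tibble(
    band = seq_len(n_bands), center = centers, sigma = sigma,
    f_lo = centers - fwhm / 2, f_hi = centers + fwhm / 2, width = fwhm
  )
}

# --- internal: decimated analytic envelope of one Gaussian band -------------
#
# X: fft of the mirror-padded signal (length nfft, a power of two).
# Returns the band's analytic amplitude sampled at fs_env = fs * m / nfft,
# computed by heterodyning the band's spectral support to baseband and
# inverse-transforming at a length m just large enough to hold it, so the
# cost per band scales with its bandwidth, not the signal length.
band_envelope_dec <- function(X, nfft, fs, center, sigma, truncate_sd = 2.5,
                              rate_mult = 5) {
  df <- fs / nfft
  k1 <- max(1L, floor((center - truncate_sd * sigma) / df))
  k2 <- min(nfft %/% 2 - 1L, ceiling((center + truncate_sd * sigma) / df))
  need <- max(k2 - k1 + 1L, ceiling(rate_mult * sigma / df), 64L)
  m <- nfft %/% smooth_divisor(nfft, nfft %/% need)
  idx <- k1:k2
  g <- exp(-0.5 * ((idx * df - center) / sigma)^2)
  y <- complex(m)
  y[(idx %% m) + 1L] <- 2 * g * X[idx + 1L]
  env <- Mod(fft(y, inverse = TRUE)) / nfft
  list(env = env, fs_env = fs * m / nfft)
}

# z-score an envelope in consecutive statistical windows of stat_window_s.
# The final partial window reuses the last complete window's mean/SD.
zscore_windows <- function(env, fs_env, stat_window_s) {
  n <- length(env)
  w <- max(2L, round(stat_window_s * fs_env))
  k <- n %/% w
  if (k < 1L) abort("signal shorter than one statistical window")
  full <- seq_len(k * w)
  mat <- matrix(env[full], nrow = w)
  mu <- colMeans(mat)
  sdv <- sqrt(colMeans(mat^2) - mu^2) * sqrt(w / (w - 1))
  sdv[sdv == 0] <- Inf  # flat window: no detections there
  win <- pmin(((seq_len(n) - 1L) %/% w) + 1L, k)
  (env - mu[win]) / sdv[win]
}

# Suprathreshold runs of z with sub-sample boundary refinement.
# Returns a data.frame of runs: start/end (1-based sample indices of the run,
# half-open on the grid), refined t_start/t_end in seconds, z_max, t_peak.
supra_runs <- function(z, fs_env, threshold) {
  above <- z > threshold
  if (!any(above)) return(NULL)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  s <- starts[keep]; e <- ends[keep]
  t_start <- (s - 1) / fs_env
  ref <- s > 1L
  t_start[ref] <- (s[ref] - 2 +
    (threshold - z[s[ref] - 1L]) / (z[s[ref]] - z[s[ref] - 1L])) / fs_env
  t_end <- e / fs_env
  ref <- e < length(z)
  t_end[ref] <- (e[ref] - 1 +
    (z[e[ref]] - threshold) / (z[e[ref]] - z[e[ref] + 1L])) / fs_env
  z_max <- numeric(length(s)); t_peak <- numeric(length(s))
  for (i in seq_along(s)) {
    seg <- z[s[i]:e[i]]
    j <- which.max(seg)
    z_max[i] <- seg[j]
    t_peak[i] <- (s[i] + j - 2) / fs_env
  }
  data.frame(start = s, end = e + 1L, t_start = t_start, t_end = t_end,
             z_max = z_max, t_peak = t_peak)
}

#' Band-wise z-scored Hilbert envelopes
#'
#' Decomposes one channel into the detector's analysis bands (see
#' [hfo_bands()]), computes each band's analytic amplitude envelope, and
#' z-scores it against the mean and SD estimated in consecutive statistical
#' windows of `stat_window_s` seconds (the final partial window reuses the
#' last complete window's statistics). Intended for inspection and testing;
#' the full-rate band-by-time matrix is large, so [detect_hfo()] uses an
#' internally decimated equivalent instead.
#'
#' @param x Numeric signal (uV).
#' @param fs Sampling rate, Hz.
#' @param n_bands,fmin,fmax,band_q Band layout, see [hfo_bands()].
#' @param stat_window_s Statistical window length, seconds (default 10).
#' @return A `band_envelope_stack`: list with `z` (n_bands x n matrix),
#'   `bands` (the [hfo_bands()] tibble), `fs`, `stat_window_s`.
#' @export
compute_band_envelopes <- function(x, fs, n_bands = 300, fmin = 60,
                                   fmax = 800, band_q = 4.5,
                                   stat_window_s = 10) {
  n <- length(x)
  if (n < stat_window_s * fs) abort("signal shorter than one statistical window")
  bands <- hfo_bands(n_bands, fmin, fmax, band_q)
  nfft <- pad_mirror_nfft(n)
  X <- fft(pad_mirror(x - mean(x)))
  z <- matrix(0, nrow = n_bands, ncol = n)
  tt <- (seq_len(n) - 1) / fs
  for (b in seq_len(n_bands)) {
    be <- band_envelope_dec(X, nfft, fs, bands$center[b], bands$sigma[b])
    te <- (seq_along(be$env) - 1) / be$fs_env
    env <- approx(te, be$env, xout = tt, rule = 2)$y
    z[b, ] <- zscore_windows(env, fs, stat_window_s)
  }
  structure(list(z = z, bands = bands, fs = fs,
                 stat_window_s = stat_window_s),
            class = "band_envelope_stack")
}

#' Construct a band-envelope stack from a precomputed z matrix
#'
#' Mainly for tests and for feeding synthetic z matrices to
#' [threshold_bands()].
#'
#' @param z Bands-by-time numeric matrix of z-scored envelopes.
#' @param bands Band table as from [hfo_bands()]; defaults to a layout with
#'   `nrow(z)` bands.
#' @param fs Sampling rate of the columns, Hz.
#' @param stat_window_s Statistical window used to produce `z`.
#' @return A `band_envelope_stack`.
#' @export
band_envelope_stack <- function(z, bands = hfo_bands(nrow(z)), fs,
                                stat_window_s = 10) {
  stopifnot(is.matrix(z), nrow(z) == nrow(bands))
  structure(list(z = z, bands = bands, fs = fs,
                 stat_window_s = stat_window_s),
            class = "band_envelope_stack")
}

#' Threshold band envelopes into suprathreshold intervals
#'
#' Finds, per band, the maximal runs of samples with `z > z_threshold`.
#' Intervals are half-open sample ranges `[start, end)` (0-based) on the
#' stack's time grid; `t_start`/`t_end` give the corresponding times in
#' seconds with the threshold crossing refined by linear interpolation
#' between the samples straddling it.
#'
#' @param stack A `band_envelope_stack`.
#' @param z_threshold Detection threshold in SD units (default 3).
#' @return A tibble with columns `band`, `start`, `end`, `t_start`, `t_end`,
#'   `z_max`, `t_peak`; zero rows if nothing is suprathreshold.
#' @export
threshold_bands <- function(stack, z_threshold = 3) {
  stopifnot(inherits(stack, "band_envelope_stack"))
  out <- vector("list", nrow(stack$z))
  for (b in seq_len(nrow(stack$z))) {
    runs <- supra_runs(stack$z[b, ], stack$fs, z_threshold)
    if (!is.null(runs)) {
      runs$band <- stack$bands$band[b]
      out[[b]] <- runs
    }
  }
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble::tibble(band = integer(), start = integer(),
                          end = integer(), t_start = numeric(),
                          t_end = numeric(), z_max = numeric(),
                          t_peak = numeric()))
  }
  out$start <- out$start - 1L  # 0-based half-open
  out$end <- out$end - 1L
  tibble::as_tibble(out[c("band", "start", "end", "t_start", "t_end",
                          "z_max", "t_peak")])
}

#' Join suprathreshold intervals into time-frequency blobs
#'
#' Builds the graph whose nodes are (band, interval) pairs and whose edges
#' connect intervals in *adjacent* bands that overlap in time (half-open
#' interval intersection: a shared boundary instant alone does not join), and
#' labels its connected components. Each component is one putative HFO
#' spanning a temporal and spectral extent.
#'
#' @param intervals A tibble as returned by [threshold_bands()] (columns
#'   `band`, `t_start`, `t_end` required; others carried through).
#' @return The input tibble with an added integer column `blob` labelling
#'   connected components (1..n_blobs, ordered by first occurrence).
#' @export
join_detections <- function(intervals) {
  if (nrow(intervals) == 0) return(dplyr::mutate(intervals, blob = integer()))
  blob <- .join_interval_components(as.integer(intervals$band),
                                    intervals$t_start, intervals$t_end)
  dplyr::mutate(intervals, blob = blob)
}

#' Characterize blobs and apply the event-level filtering rules
#'
#' For each blob: `peak_frequency` is the center frequency of the band
#' holding the blob's maximum z, `relative_amplitude` is that maximum z
#' (unitless), the temporal span is the union of member intervals, and
#' `f_min`/`f_max` are the lowest/highest member band centers. Blobs are then
#' filtered by the two false-positive rules: the time span must exceed
#' `min_cycles` cycles at the peak frequency (strict inequality), and blobs
#' whose lowest member band is the floor band (the band at 60 Hz) are
#' discarded as putative filtered spikes.
#'
#' @param joined Output of [join_detections()].
#' @param bands Band table used for detection ([hfo_bands()]).
#' @param min_cycles Minimum cycle count (default 4, strict `>`).
#' @param floor_band Index of the floor band (default 1).
#' @return A tibble of events: `t_start`, `t_end`, `duration_ms`, `f_min`,
#'   `f_max`, `peak_freq`, `amplitude_z`, `n_bands_spanned`.
#' @export
characterize_and_filter <- function(joined, bands, min_cycles = 4,
                                    floor_band = 1L) {
  empty <- tibble::tibble(t_start = numeric(), t_end = numeric(),
                          duration_ms = numeric(), f_min = numeric(),
                          f_max = numeric(), peak_freq = numeric(),
                          amplitude_z = numeric(), n_bands_spanned = integer())
  if (nrow(joined) == 0) return(empty)
  lev <- sort(unique(joined$blob))
  fb <- factor(joined$blob, levels = lev)
  agg <- function(v, f) vapply(split(v, fb), f, numeric(1), USE.NAMES = FALSE)
  ord <- order(joined$blob, -joined$z_max)
  first <- !duplicated(joined$blob[ord])
  ev <- tibble::tibble(
    blob = lev,
    t_start = agg(joined$t_start, min),
    t_end = agg(joined$t_end, max),
    band_lo = as.integer(agg(joined$band, min)),
    band_hi = as.integer(agg(joined$band, max)),
    peak_band = joined$band[ord][first],
    amplitude_z = joined$z_max[ord][first],
    n_bands_spanned = as.integer(
      agg(joined$band, function(b) length(unique(b))))
  )
  ev$peak_freq <- bands$center[ev$peak_band]
  ev$f_min <- bands$center[ev$band_lo]
  ev$f_max <- bands$center[ev$band_hi]
  ev$duration_ms <- (ev$t_end - ev$t_start) * 1000
  keep <- (ev$t_end - ev$t_start) * ev$peak_freq > min_cycles &
    ev$band_lo != floor_band
  ev <- ev[keep, ]
  ev <- ev[order(ev$t_start), ]
  tibble::as_tibble(ev[c("t_start", "t_end", "duration_ms", "f_min", "f_max",
                         "peak_freq", "amplitude_z", "n_bands_spanned")])
}

#' Label an event's band by its dominant frequency
#'
#' Ripple (`"R"`) for peak frequency in \[80, 250) Hz, fast ripple (`"FR"`)
#' for \[250, 600) Hz, `"none"` otherwise (excluded from features).
#'
#' @param peak_freq Numeric vector of peak frequencies, Hz.
#' @param r_band,fr_band Band edges, Hz.
#' @return Character vector of `"R"`, `"FR"`, `"none"`.
#' @examples
#' label_band(c(176.75, 399.6, 700))
#' @export
label_band <- function(peak_freq, r_band = c(80, 250), fr_band = c(250, 600)) {
  dplyr::case_when(
    peak_freq >= r_band[1] & peak_freq < r_band[2] ~ "R",
    peak_freq >= fr_band[1] & peak_freq < fr_band[2] ~ "FR",
    TRUE ~ "none"
  )
}

# Internal single-channel detection on the decimated filter bank.
detect_hfo_channel <- function(x, fs, h) {
  n <- length(x)
  if (n < h$stat_window_s * fs) abort("signal shorter than one statistical window")
  bands <- hfo_bands(h$n_bands, h$fmin, h$fmax, h$band_q)
  nfft <- pad_mirror_nfft(n)
  X <- fft(pad_mirror(x - mean(x)))
  t_max <- n / fs
  intervals <- .hfo_band_intervals(X, nfft, fs, n, bands$center,
                                   bands$sigma, h$stat_window_s,
                                   h$z_threshold, 2.5, 5)
  if (nrow(intervals) == 0) {
    ev <- characterize_and_filter(
      tibble::tibble(band = integer(), t_start = numeric(),
                     t_end = numeric(), z_max = numeric(),
                     t_peak = numeric(), blob = integer()),
      bands, h$min_cycles)
  } else {
    ev <- characterize_and_filter(join_detections(tibble::as_tibble(intervals)),
                                  bands, h$min_cycles)
  }
  ev$t_end <- pmin(ev$t_end, t_max)
  ev$band <- label_band(ev$peak_freq, h$r_band, h$fr_band)
  ev
}

#' Detect high-frequency oscillations
#'
#' Runs the multi-band Hilbert-envelope detector on every channel of a
#' recording segment: per band, the analytic amplitude envelope is z-scored
#' in 10-s statistical windows and thresholded at 3 SD; temporally
#' overlapping detections in adjacent bands are joined; joined events must
#' exceed 4 cycles at their peak frequency, and events reaching the 60-Hz
#' floor band are discarded as filtered spikes. Surviving events are labelled
#' ripple (R, 80-250 Hz) or fast ripple (FR, 250-600 Hz) by dominant
#' frequency.
#'
#' @param segment A [recording_segment()], or a plain numeric vector together
#'   with `fs`.
#' @param config A [pipeline_config()]; the `hfo` section parameterizes the
#'   detector.
#' @param fs Sampling rate, required when `segment` is a bare vector.
#' @return A tibble with one row per detected event: `channel_id`, `t_start`,
#'   `t_end`, `duration_ms`, `f_min`, `f_max`, `peak_freq`, `amplitude_z`,
#'   `band` (`"R"`/`"FR"`/`"none"`).
#' @examples
#' \donttest{
#' seg <- simulate_segment_pair(group_params(), seed = 1,
#'                              duration_s = 20, fs = 2000)$rest
#' detect_hfo(seg)
#' }
#' @export
detect_hfo <- function(segment, config = pipeline_config(), fs = NULL) {
  h <- config$hfo
  if (is.numeric(segment) && is.null(dim(segment))) {
    if (is.null(fs)) abort("detect_hfo: fs required for a bare signal vector")
    ev <- detect_hfo_channel(segment, fs, h)
    return(dplyr::bind_cols(tibble::tibble(channel_id = rep("ch1", nrow(ev))),
                            ev))
  }
  stopifnot(inherits(segment, "recording_segment"))
  res <- lapply(seq_len(ncol(segment$signals)), function(j) {
    ev <- detect_hfo_channel(segment$signals[, j], segment$fs, h)
    dplyr::bind_cols(
      tibble::tibble(channel_id = rep(segment$channels$channel_id[j],
                                      nrow(ev))),
      ev)
  })
  dplyr::bind_rows(res)
}
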