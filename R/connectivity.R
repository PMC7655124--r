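#' Pearson linear correlation between two windows
#'
#' `corr(X,Y) = cov(X,Y) / (std(X) std(Y))`.
#'
#' @param x,y Equal-length numeric vectors (length >= 2).
#' @return Correlation in \[-1, 1\]; `NA` with a warning if either input is
#'   constant (the window is skipped upstream).
#' @export
linear_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (sd(x) == 0 || sd(y) == 0) {
    warn("linear_correlation: constant input, window skipped")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Relative entropy (Kullback-Leibler divergence) between two windows
#'
#' `REN(X,Y) = sum(pX * log(pX / pY))` where `pX`, `pY` are histogram
#' probability estimates over `n_bins` shared equal-width bins spanning the
#' pooled range of both windows. Both distributions receive additive
#' smoothing `eps = 1 / (n_samples * n_bins)` (then renormalized) so the
#' divergence stays finite when a bin is empty under `pY`. Directed:
#' `relative_entropy(x, y)` != `relative_entropy(y, x)` in general.
#'
#' @param x,y Equal-length numeric vectors.
#' @param n_bins Number of histogram bins (default 10).
#' @param log_base `"natural"` (nats, default) or `"log2"` (bits).
#' @return Non-negative divergence; `NA` with a warning when the pooled range
#'   is degenerate (all samples equal).
#' @examples
#' relative_entropy(rnorm(1000), rnorm(1000))
#' relative_entropy(1:100, 1:100)  # 0
#' @export
relative_entropy <- function(x, y, n_bins = 10, log_base = "natural") {
  stopifnot(length(x) == length(y), n_bins >= 2)
  rng <- range(c(x, y))
  if (rng[1] == rng[2]) {
    warn("relative_entropy: degenerate pooled range, window skipped")
    return(NA_real_)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  cx <- bin_counts(x, breaks)
  cy <- bin_counts(y, breaks)
  eps <- 1 / (length(x) * n_bins)
  px <- cx / length(x) + eps; px <- px / sum(px)
  py <- cy / length(y) + eps; py <- py / sum(py)
  v <- sum(px * log(px / py))
  if (log_base == "log2") v <- v / log(2)
  max(v, 0)
}

bin_counts <- function(v, breaks) {
  idx <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  tabulate(idx, nbins = length(breaks) - 1)
}

adjacent_pairs <- function(channels) {
  ch <- channels[order(channels$electrode_id, channels$contact_index), ]
  out <- list()
  for (el in split(ch, paste(ch$subject_id, ch$electrode_id, ch$hippocampus_id))) {
    if (nrow(el) < 2) next
    consec <- diff(el$contact_index) == 1
    out[[length(out) + 1]] <- tibble::tibble(
      channel_a = el$channel_id[-nrow(el)][consec],
      channel_b = el$channel_id[-1][consec]
    )
  }
  dplyr::bind_rows(out) %||%
    tibble::tibble(channel_a = character(), channel_b = character())
}

#' Windowed high-frequency connectivity between adjacent contacts
#'
#' Band-passes every hippocampal channel into the ripple (80-250 Hz) and
#' fast-ripple (250-600 Hz) bands, splits the segment into non-overlapping
#' 1-s windows, and computes, per adjacent contact pair (consecutive
#' `contact_index` on the same electrode within one hippocampus) and window,
#' the Pearson correlation and the relative entropy in both directions.
#'
#' @param segment A [recording_segment()].
#' @param r_band,fr_band Band edges, Hz.
#' @param window_s Window length, seconds (default 1).
#' @param n_bins Histogram bins for [relative_entropy()] (default 10).
#' @param log_base Logarithm for REN (`"natural"` or `"log2"`).
#' @param config Optional [pipeline_config()] overriding window/bin/log
#'   settings and bands.
#' @return A long tibble: `channel_a`, `channel_b`, `band` (`"R"`/`"FR"`),
#'   `window` (1-based index), `corr`, `ren_ab`, `ren_ba`, `ren`
#'   (symmetrized mean of the two directions). Zero rows (with a warning)
#'   for a single-contact hippocampus.
#' @export
windowed_connectivity <- function(segment, r_band = c(80, 250),
                                  fr_band = c(250, 600), window_s = 1,
                                  n_bins = 10, log_base = "natural",
                                  config = NULL) {
  stopifnot(inherits(segment, "recording_segment"))
  if (!is.null(config)) {
    window_s <- config$connectivity$window_s
    n_bins <- config$connectivity$n_bins
    log_base <- config$connectivity$log_base
    r_band <- config$hfo$r_band
    fr_band <- config$hfo$fr_band
  }
  pairs <- adjacent_pairs(segment$channels)
  empty <- tibble::tibble(channel_a = character(), channel_b = character(),
                          band = character(), window = integer(),
                          corr = numeric(), ren_ab = numeric(),
                          ren_ba = numeric(), ren = numeric())
  if (nrow(pairs) == 0) {
    warn("windowed_connectivity: no adjacent contact pairs")
    return(empty)
  }
  fs <- segment$fs
  w <- round(window_s * fs)
  n_win <- nrow(segment$signals) %/% w
  if (n_win < 1) abort("windowed_connectivity: segment shorter than one window")
  bands <- list(R = r_band, FR = fr_band)
  used <- unique(c(pairs$channel_a, pairs$channel_b))
  out <- list()
  for (bname in names(bands)) {
    bd <- bands[[bname]]
    filt <- lapply(setNames(used, used), function(id) {
      bandpass(segment$signals[, id], fs, bd[1], bd[2])
    })
    for (pidx in seq_len(nrow(pairs))) {
      xa <- filt[[pairs$channel_a[pidx]]]
      xb <- filt[[pairs$channel_b[pidx]]]
      res <- vapply(seq_len(n_win), function(wi) {
        sl <- ((wi - 1) * w + 1):(wi * w)
        a <- xa[sl]; b <- xb[sl]
        if (sd(a) == 0 || sd(b) == 0 || max(a, b) == min(a, b)) {
          return(c(NA_real_, NA_real_, NA_real_))
        }
        c(stats::cor(a, b),
          relative_entropy(a, b, n_bins, log_base),
          relative_entropy(b, a, n_bins, log_base))
      }, numeric(3))
      out[[length(out) + 1]] <- tibble::tibble(
        channel_a = pairs$channel_a[pidx], channel_b = pairs$channel_b[pidx],
        band = bname, window = seq_len(n_win),
        corr = res[1, ], ren_ab = res[2, ], ren_ba = res[3, ],
        ren = (res[2, ] + res[3, ]) / 2
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Per-channel connectivity summary
#'
#' Each channel's connectivity feature is the mean over all windows of all
#' adjacent pairs that include it, per band and metric.
#'
#' @param series Output of [windowed_connectivity()].
#' @return A tibble: `channel_id`, `band`, `corr`, `ren` (window means,
#'   `NA` windows dropped).
#' @export
channel_connectivity_summary <- function(series) {
  if (nrow(series) == 0) {
    return(tibble::tibble(channel_id = character(), band = character(),
                          corr = numeric(), ren = numeric()))
  }
  long <- dplyr::bind_rows(
    dplyr::rename(series, channel_id = "channel_a"),
    dplyr::rename(series, channel_id = "channel_b")
  )
  long |>
    dplyr::group_by(.data$channel_id, .data$band) |>
    dplyr::summarise(corr = mean(.data$corr, na.rm = TRUE),
                     ren = mean(.data$ren, na.rm = TRUE),
                     .groups = "drop")
}
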