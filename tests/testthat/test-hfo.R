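test_that("band layout is geometric from 60 to 800 Hz", {
  b <- hfo_bands(300, 60, 800)
  expect_equal(nrow(b), 300)
  expect_equal(b$center[1], 60)
  expect_equal(b$center[300], 800)
  ratios <- b$center[-1] / b$center[-300]
  expect_lt(diff(range(ratios)), 1e-10)  # constant neighbor ratio
  expect_true(all(diff(b$center) > 0))
})

test_that("white-noise envelopes are z-scored per statistical window", {
  set.seed(3)
  fs <- 2000
  stack <- compute_band_envelopes(rnorm(6 * fs), fs, n_bands = 12,
                                  stat_window_s = 2)
  for (b in c(1, 6, 12)) {
    for (w in 0:2) {
      z <- stack$z[b, (w * 2 * fs + 1):((w + 1) * 2 * fs)]
      expect_equal(mean(z), 0, tolerance = 1e-8)
      expect_equal(sd(z), 1, tolerance = 1e-3)
    }
  }
})

test_that("a sustained tone dominates the band containing its frequency", {
  set.seed(4)
  fs <- 2000
  x <- sin(2 * pi * 200 * seq(0, 12, by = 1 / fs))[-1] + 0.1 * rnorm(12 * fs)
  bands <- hfo_bands(40)
  # mean analytic envelope per band (z-scoring would null a stationary tone)
  nfft <- hippofeat:::pad_mirror_nfft(length(x))
  X <- fft(hippofeat:::pad_mirror(x - mean(x)))
  me <- vapply(seq_len(40), function(b) {
    be <- hippofeat:::band_envelope_dec(X, nfft, fs, bands$center[b],
                                        bands$sigma[b])
    mean(be$env)
  }, 0)
  best <- bands$center[which.max(me)]
  expect_lt(abs(log(best / 200)), log(1.1))
})

test_that("thresholding returns exact maximal runs", {
  z <- matrix(0, nrow = 3, ncol = 400)
  z[2, 101:150] <- 5
  stack <- band_envelope_stack(z, hfo_bands(3), fs = 1000)
  iv <- threshold_bands(stack, 3)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$band, 2)
  expect_equal(iv$start, 100)  # 0-based half-open [100, 150)
  expect_equal(iv$end, 150)
  expect_equal(iv$z_max, 5)
  empty <- threshold_bands(band_envelope_stack(matrix(0, 2, 100),
                                               hfo_bands(2), 1000))
  expect_equal(nrow(empty), 0)
})

test_that("suprathreshold fraction of Gaussian z matches the normal tail", {
  set.seed(5)
  z <- matrix(rnorm(2e5), nrow = 2)
  stack <- band_envelope_stack(z, hfo_bands(2), fs = 1000)
  iv <- threshold_bands(stack, 3)
  frac <- sum(iv$end - iv$start) / length(z)
  expect_gt(frac, 0.00135 * 0.5)
  expect_lt(frac, 0.00135 * 1.5)
})

test_that("temporally overlapping detections in adjacent bands join", {
  iv <- tibble::tibble(band = c(10L, 11L), t_start = c(0.10, 0.12),
                       t_end = c(0.15, 0.18), z_max = c(4, 5),
                       t_peak = c(0.12, 0.13))
  expect_equal(max(join_detections(iv)$blob), 1)
  iv$band <- c(10L, 12L)  # gap at band 11
  expect_equal(max(join_detections(iv)$blob), 2)
  # a shared boundary instant alone does not join (half-open intervals)
  iv2 <- tibble::tibble(band = c(5L, 6L), t_start = c(0.1, 0.2),
                        t_end = c(0.2, 0.3), z_max = c(4, 4),
                        t_peak = c(0.15, 0.25))
  expect_equal(max(join_detections(iv2)$blob), 2)
})

test_that("joining matches a brute-force union-find oracle", {
  set.seed(6)
  for (rep in 1:5) {
    # disjoint maximal runs per band, as threshold_bands produces
    iv <- dplyr::bind_rows(lapply(1:8, function(b) {
      k <- sample(3:10, 1)
      edges <- sort(runif(2 * k, 0, 2))
      tibble::tibble(band = b, t_start = edges[seq(1, 2 * k, by = 2)],
                     t_end = edges[seq(2, 2 * k, by = 2)])
    }))
    iv <- iv[iv$t_end > iv$t_start, ]
    iv$z_max <- runif(nrow(iv), 3, 8)
    iv$t_peak <- iv$t_start
    got <- join_detections(iv)$blob
    want <- brute_force_components(iv)
    # same partition (labels may differ)
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(want, got, function(v) length(unique(v))) == 1))
  }
})

test_that("cycle and floor rules filter blobs as specified", {
  bands <- hfo_bands(300)
  band150 <- which.min(abs(bands$center - 150))
  mk <- function(dur_s, band) {
    tibble::tibble(band = band, t_start = 1, t_end = 1 + dur_s,
                   z_max = 6, t_peak = 1.01, blob = 1L)
  }
  # 150 Hz for 20 ms = 3 cycles < 4: rejected
  expect_equal(nrow(characterize_and_filter(mk(0.020, band150), bands)), 0)
  # 150 Hz for 40 ms = 6 cycles: kept
  kept <- characterize_and_filter(mk(0.040, band150), bands)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$duration_ms, 40)
  expect_equal(kept$peak_freq, bands$center[band150], tolerance = 0.01)
  # exactly 4 cycles fails the strict inequality
  expect_equal(nrow(characterize_and_filter(
    mk(4 / bands$center[band150], band150), bands)), 0)
  # a blob whose lowest member band is the floor band is discarded
  floorblob <- tibble::tibble(band = c(1L, 2L), t_start = 1,
                              t_end = 1.5, z_max = c(8, 7),
                              t_peak = 1.1, blob = 1L)
  expect_equal(nrow(characterize_and_filter(floorblob, bands)), 0)
})

test_that("events are labelled ripple/fast-ripple by dominant frequency", {
  expect_equal(label_band(c(176.75, 399.6, 700, 79, 80, 249.9, 250, 599.9)),
               c("R", "FR", "none", "none", "R", "R", "FR", "FR"))
})

test_that("detector recovers an injected burst with correct properties", {
  fs <- 2000
  x <- generate_background(20, fs, 2, 50, seed = 8)
  st <- hippofeat:::band_envelope_stats(x, fs, 176)
  amp <- (7 * st[, "sd"] + st[, "mean"]) / calibrate_hfo_amplitude(7)
  r <- inject_hfo(x, fs, 9.5, 176, 7, amplitude = amp)
  ev <- detect_hfo(r$signal, fs = fs)
  hit <- ev[ev$t_start < 9.55 & ev$t_end > 9.5, ]
  expect_gte(nrow(hit), 1)
  expect_equal(hit$band[1], "R")
  expect_lt(abs(hit$peak_freq[1] - 176), 40)
  expect_true(all(ev$t_end > ev$t_start))
  expect_true(all(ev$f_min <= ev$peak_freq & ev$peak_freq <= ev$f_max))
  # every emitted event satisfies the cycle rule by construction
  expect_true(all((ev$t_end - ev$t_start) * ev$peak_freq > 4))
  expect_true(all(ev$f_min > 60))
})

test_that("raising the threshold never increases the event count", {
  fs <- 2000
  x <- generate_background(30, fs, 2, 50, seed = 9)
  for (i in 1:5) {
    r <- inject_hfo(x, fs, 3 + 5 * i, 150 + 40 * i, 6, amplitude = 2)
    x <- r$signal
  }
  counts <- vapply(c(2.5, 3, 3.5, 4.5, 6), function(thr) {
    nrow(detect_hfo(x, pipeline_config(hfo = list(z_threshold = thr)),
                    fs = fs))
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("compiled and reference band decompositions agree", {
  fs <- 2000
  x <- generate_background(12, fs, 2, 50, seed = 10)
  x <- inject_hfo(x, fs, 6, 200, 8, amplitude = 2)$signal
  bands <- hfo_bands(30, 100, 400)
  nfft <- hippofeat:::pad_mirror_nfft(length(x))
  X <- fft(hippofeat:::pad_mirror(x - mean(x)))
  cpp <- .hfo_band_intervals(X, nfft, fs, length(x), bands$center,
                             bands$sigma, 10, 3, 2.5, 5)
  ref <- do.call(rbind, lapply(seq_len(30), function(b) {
    be <- hippofeat:::band_envelope_dec(X, nfft, fs, bands$center[b],
                                        bands$sigma[b])
    n_env <- min(length(be$env), ceiling(length(x) / fs * be$fs_env))
    z <- hippofeat:::zscore_windows(be$env[seq_len(n_env)], be$fs_env, 10)
    runs <- hippofeat:::supra_runs(z, be$fs_env, 3)
    if (is.null(runs)) return(NULL)
    runs$band <- b
    runs
  }))
  expect_equal(nrow(cpp), nrow(ref))
  expect_equal(cpp$t_start, ref$t_start, tolerance = 1e-9)
  expect_equal(cpp$t_end, ref$t_end, tolerance = 1e-9)
  expect_equal(cpp$z_max, ref$z_max, tolerance = 1e-9)
  expect_equal(cpp$band, ref$band)
})

test_that("signals shorter than one statistical window are rejected", {
  expect_error(detect_hfo(rnorm(2000), fs = 2000), "statistical window")
})
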