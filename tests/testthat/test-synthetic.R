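test_that("colored noise has the requested spectral slope", {
  fs <- 1000
  slope_of <- function(exponent) {
    # averaged-periodogram least-squares slope oracle
    set.seed(60)
    ps <- 0
    for (i in 1:8) {
      x <- generate_background(4, fs, exponent, 50, seed = 600 + i)
      p <- Mod(fft(x))^2
      ps <- ps + p
    }
    f <- (seq_along(ps) - 1) * fs / length(ps)
    keep <- f > 5 & f < 400
    unname(coef(lm(log(ps[keep]) ~ log(f[keep])))[2])
  }
  expect_lt(abs(slope_of(0)), 0.1)
  expect_lt(abs(slope_of(1) + 1), 0.2)
  expect_error(generate_background(-1, fs), "positive")
})

test_that("background generation is reproducible and restores RNG state", {
  a <- generate_background(1, 2000, 2, 50, seed = 9)
  b <- generate_background(1, 2000, 2, 50, seed = 9)
  expect_identical(a, b)
  set.seed(123); r1 <- rnorm(1)
  set.seed(123); invisible(generate_background(1, 2000, 2, 50, seed = 9))
  r2 <- rnorm(1)
  expect_identical(r1, r2)
})

test_that("HFO injection obeys its contract", {
  fs <- 2000
  x <- rep(0, 10 * fs)
  # 150 Hz, 6 cycles: truth duration 40 ms
  r <- inject_hfo(x, fs, 2, 150, 6, amplitude = 5)
  expect_equal(r$truth$duration_s, 0.040)
  # amplitude 0 leaves the signal unchanged
  expect_identical(inject_hfo(x, fs, 2, 150, 6, 0)$signal, x)
  # periodogram peak within one frequency bin of the injected frequency
  y <- r$signal
  p <- Mod(fft(y))^2
  f <- (seq_along(p) - 1) * fs / length(p)
  half <- f <= fs / 2
  expect_lt(abs(f[half][which.max(p[half])] - 150), fs / length(y) + 1e-9)
  expect_error(inject_hfo(x, fs, 9.99, 150, 6, 1), "fit")
  expect_error(inject_hfo(x, fs, 2, 30, 6, 1), "freq")
})

test_that("IED injection obeys its contract", {
  fs <- 2000
  x <- rep(0, 10 * fs)
  expect_identical(inject_ied(x, fs, 2, 0)$signal, x)
  r <- inject_ied(x, fs, 3, 300)
  expect_equal(max(abs(r$signal)), 300 * max(abs(hippofeat:::ied_template(
    fs, 55, TRUE)$y)), tolerance = 0.05)
  expect_lt(abs(max(r$signal) - (300 * max(hippofeat:::ied_template(
    fs, 55, TRUE)$y))), 0.05 * 300)
  # spike energy concentrates in 20-50 Hz, not in the ripple band
  tpl <- r$signal
  expect_gt(sum(bandpass(tpl, fs, 20, 50)^2), sum(bandpass(tpl, fs, 80, 250)^2))
  expect_error(inject_ied(x, fs, 9.99, 300), "fit")
})

test_that("zero rates and zero coupling give an empty truth", {
  p0 <- group_params(r_rate = rep(0, 4), fr_rate = rep(0, 4),
                     ied_rate = rep(0, 4), coupling_r = rep(0, 4),
                     coupling_fr = rep(0, 4), ren_contrast = rep(0, 4))
  co <- generate_cohort(1, 1, 2, params = p0, duration_s = 20, fs = 2000,
                        seed = 61)
  expect_equal(nrow(co$truth$hfo), 0)
  expect_equal(nrow(co$truth$ied), 0)
})

test_that("injected counts follow the Poisson law of the requested rate", {
  # 20 channels x 60 s at 120 ripples / 10 min: expected total 240
  p <- group_params(r_rate = rep(120, 4), fr_rate = rep(0, 4),
                    ied_rate = rep(0, 4))
  co <- generate_cohort(n_eh = 10, n_neh = 0, channels_per_hippocampus = 2,
                        params = p, duration_s = 60, fs = 2000, seed = 62)
  rest_ids <- co$index$segment_id[co$index$condition == "rest"]
  n_rest <- sum(co$truth$hfo$segment_id %in% rest_ids)
  lambda <- 10 * 2 * 120 * 60 / 600
  expect_gt(n_rest, lambda - 3 * sqrt(lambda))
  expect_lt(n_rest, lambda + 3 * sqrt(lambda))
  # truth conservation: every injection call leaves one record
  expect_equal(nrow(co$truth$hfo),
               sum(co$truth$hfo$band %in% c("R", "FR")))
})

test_that("identical seeds give byte-identical cohorts", {
  co1 <- generate_cohort(1, 1, 2, duration_s = 15, fs = 2000, seed = 63)
  co2 <- generate_cohort(1, 1, 2, duration_s = 15, fs = 2000, seed = 63)
  expect_identical(co1$segments[["EH01_rest"]]$signals,
                   co2$segments[["EH01_rest"]]$signals)
  expect_identical(co1$truth$hfo, co2$truth$hfo)
  co3 <- generate_cohort(1, 1, 2, duration_s = 15, fs = 2000, seed = 64)
  expect_false(identical(co1$segments[["EH01_rest"]]$signals,
                         co3$segments[["EH01_rest"]]$signals))
})

test_that("raising the ripple rate raises the detected ripple rate", {
  rates <- c(30, 240)
  det <- vapply(rates, function(rt) {
    p <- group_params(r_rate = rep(rt, 4), fr_rate = rep(0, 4),
                      ied_rate = rep(0, 4))
    n <- 0
    for (s in 1:2) {
      co <- generate_cohort(1, 0, 1, params = p, duration_s = 60, fs = 2000,
                            seed = 650 + s)
      ev <- detect_hfo(co$segments[["EH01_rest"]])
      n <- n + sum(ev$band == "R")
    }
    n
  }, 0)
  expect_gt(det[2], det[1])
})

test_that("burst calibration lands detected amplitude near its target", {
  fs <- 2000
  p <- group_params(r_rate = c(60, 0, 0, 0), fr_rate = rep(0, 4),
                    ied_rate = rep(0, 4))
  co <- generate_cohort(1, 0, 1, params = p, duration_s = 120, fs = fs,
                        seed = 66)
  ev <- detect_hfo(co$segments[["EH01_rest"]])
  ev <- ev[ev$band == "R", ]
  # target z is 6.87; allow generous slack for extreme-value bias
  expect_gt(mean(ev$amplitude_z), 4.5)
  expect_lt(mean(ev$amplitude_z), 9.5)
})

test_that("cohorts round-trip to fixture files on disk", {
  co <- tiny_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "channels.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  seg_id <- co$index$segment_id[1]
  back <- read_recording(file.path(dir, paste0(seg_id, ".csv")))
  expect_equal(unname(back$signals),
               unname(co$segments[[seg_id]]$signals), tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth$hfo), nrow(co$truth$hfo))
})

test_that("degenerate cohort requests are rejected", {
  expect_error(generate_cohort(0, 0, 2, duration_s = 10, seed = 1),
               "no hippocampi")
  expect_error(generate_cohort(1, 1, 0, duration_s = 10, seed = 1),
               "zero channels")
})
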