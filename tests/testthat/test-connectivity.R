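test_that("linear correlation matches its defining formula", {
  x <- rnorm(100)
  expect_equal(linear_correlation(x, x), 1)
  expect_equal(linear_correlation(x, -x), -1)
  # hand computation via the covariance formula
  a <- c(1, 2, 3, 4); b <- c(2, 1, 4, 3)
  expect_equal(linear_correlation(a, b), 0.6)
  expect_warning(v <- linear_correlation(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(v))
  # invariant under positive affine rescaling
  expect_equal(linear_correlation(2 * a + 5, 0.3 * b - 1),
               linear_correlation(a, b))
})

test_that("relative entropy matches a direct-summation oracle", {
  set.seed(20)
  for (rep in 1:10) {
    x <- rnorm(200); y <- rnorm(200, sd = runif(1, 0.5, 2))
    n_bins <- sample(4:12, 1)
    got <- relative_entropy(x, y, n_bins)
    # independently coded: shared equal-width bins over the pooled range,
    # additive smoothing 1/(n*bins), renormalized, sum px log(px/py)
    breaks <- seq(min(c(x, y)), max(c(x, y)), length.out = n_bins + 1)
    cx <- table(cut(x, breaks, include.lowest = TRUE))
    cy <- table(cut(y, breaks, include.lowest = TRUE))
    eps <- 1 / (200 * n_bins)
    px <- as.numeric(cx) / 200 + eps; px <- px / sum(px)
    py <- as.numeric(cy) / 200 + eps; py <- py / sum(py)
    expect_equal(got, sum(px * log(px / py)), tolerance = 1e-12)
  }
})

test_that("relative entropy is zero for identical windows and directed", {
  x <- rnorm(500)
  expect_identical(relative_entropy(x, x), 0)
  y <- rnorm(500, sd = 3)
  expect_false(isTRUE(all.equal(relative_entropy(x, y),
                                relative_entropy(y, x))))
  expect_gte(relative_entropy(x, y), 0)
  expect_warning(v <- relative_entropy(rep(2, 10), rep(2, 10)), "degenerate")
  expect_true(is.na(v))
  # two-bin closed form approached as smoothing vanishes
  x2 <- c(rep(0.25, 500), rep(0.75, 500))
  y2 <- c(rep(0.25, 250), rep(0.75, 750))
  expect_equal(relative_entropy(x2, y2, n_bins = 2),
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-2)
  expect_equal(relative_entropy(x2, y2, n_bins = 2, log_base = "log2"),
               relative_entropy(x2, y2, n_bins = 2) / log(2))
})

test_that("windowed connectivity tiles the segment and matches a loop oracle", {
  fs <- 2000
  set.seed(21)
  meta <- example_channel_metadata(2)
  sig <- matrix(rnorm(2 * 10 * fs), ncol = 2)
  seg <- recording_segment(sig, fs, meta)
  cw <- windowed_connectivity(seg)
  expect_equal(sort(unique(cw$window)), 1:10)  # 10-s segment, 10 windows
  expect_equal(nrow(cw), 2 * 10)               # 2 bands x 10 windows x 1 pair
  # brute-force oracle for one band
  xr <- bandpass(sig[, 1], fs, 80, 250); yr <- bandpass(sig[, 2], fs, 80, 250)
  for (w in c(1, 5, 10)) {
    sl <- ((w - 1) * fs + 1):(w * fs)
    row <- cw[cw$band == "R" & cw$window == w, ]
    expect_equal(row$corr, cor(xr[sl], yr[sl]), tolerance = 1e-10)
    expect_equal(row$ren_ab, relative_entropy(xr[sl], yr[sl], 10),
                 tolerance = 1e-10)
    expect_equal(row$ren, (row$ren_ab + row$ren_ba) / 2)
  }
})

test_that("independent channels have near-zero mean correlation", {
  fs <- 2000
  set.seed(22)
  seg <- recording_segment(matrix(rnorm(2 * 20 * fs), ncol = 2), fs,
                           example_channel_metadata(2))
  cw <- windowed_connectivity(seg)
  n_eff <- 170  # approximate dof of 1-s windows band-limited to 80-250 Hz
  m <- mean(cw$corr[cw$band == "R"])
  expect_lt(abs(m), 3 / sqrt(n_eff * 20))
})

test_that("requested coupling is realized within the mixing-algebra band", {
  p <- group_params(r_rate = rep(0, 4), fr_rate = rep(0, 4),
                    ied_rate = rep(0, 4), ren_contrast = rep(0, 4),
                    coupling_r = rep(0.8, 4), coupling_fr = rep(0.8, 4))
  co <- generate_cohort(1, 0, 2, params = p, duration_s = 30, fs = 2000,
                        seed = 23)
  cw <- windowed_connectivity(co$segments[["EH01_rest"]])
  expect_gt(mean(cw$corr[cw$band == "R"]), 0.7)
  expect_lt(mean(cw$corr[cw$band == "R"]), 0.9)
  expect_gt(mean(cw$corr[cw$band == "FR"]), 0.7)
  expect_lt(mean(cw$corr[cw$band == "FR"]), 0.9)
})

test_that("single-contact hippocampi yield an empty result with a warning", {
  seg <- recording_segment(matrix(rnorm(2000 * 2), ncol = 1), 2000,
                           example_channel_metadata(1))
  expect_warning(cw <- windowed_connectivity(seg), "no adjacent")
  expect_equal(nrow(cw), 0)
  expect_equal(nrow(channel_connectivity_summary(cw)), 0)
})

test_that("per-channel summary averages all pairs including the channel", {
  series <- tibble::tibble(
    channel_a = c("c1", "c2"), channel_b = c("c2", "c3"),
    band = "R", window = 1L,
    corr = c(0.4, 0.6), ren_ab = c(0.1, 0.3), ren_ba = c(0.1, 0.3),
    ren = c(0.1, 0.3)
  )
  s <- channel_connectivity_summary(series)
  expect_equal(s$corr[s$channel_id == "c1"], 0.4)   # one pair: pair mean
  expect_equal(s$corr[s$channel_id == "c2"], 0.5)   # middle contact: mean
  expect_equal(s$ren[s$channel_id == "c2"], 0.2)
  # constant windows propagate unchanged
  const <- tibble::tibble(channel_a = "c1", channel_b = "c2", band = "FR",
                          window = 1:5, corr = 0.3, ren_ab = 0.2,
                          ren_ba = 0.2, ren = 0.2)
  s2 <- channel_connectivity_summary(const)
  expect_true(all(s2$corr == 0.3) && all(s2$ren == 0.2))
})

test_that("relative-entropy contrast separates EH from NEH pairs", {
  vals <- vapply(1:4, function(s) {
    co <- generate_cohort(1, 1, 2, params = group_params(
      r_rate = rep(0, 4), fr_rate = rep(0, 4), ied_rate = rep(0, 4)),
      duration_s = 30, fs = 2000, seed = 30 + s)
    eh <- windowed_connectivity(co$segments[["EH01_rest"]])
    neh <- windowed_connectivity(co$segments[["NEH01_rest"]])
    c(mean(eh$ren, na.rm = TRUE), mean(neh$ren, na.rm = TRUE))
  }, c(0, 0))
  expect_gt(mean(vals[1, ]), mean(vals[2, ]))
})
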