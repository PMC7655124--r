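#' Group-level generative parameters for the synthetic iEEG cohort
#'
#' One row per (hippocampus label, condition) cell with the event rates,
#' event-feature distributions and coupling knobs the generator draws from.
#' Defaults are the per-channel feature means (and, for event-level spreads,
#' SDs) reported for epileptic (EH) and non-epileptic (NEH) hippocampus
#' during rest and cognitive-task recordings: ripple/fast-ripple rates per
#' 10 min, relative amplitudes (unitless detector z), center frequencies and
#' durations, spike rate and amplitude, and band-wise adjacent-contact
#' coupling targets. `ren_contrast` is the static log-gain contrast between
#' adjacent contacts' band content that drives relative-entropy divergence;
#' its defaults were calibrated once against the measured REN-versus-contrast
#' mapping so the per-channel relative entropies land near the emulated
#' study's cell means.
#'
#' @param ... Named overrides applied to matching columns after the defaults
#'   are built, e.g. `r_rate = c(0, 0, 0, 0)` (row order EH-rest, NEH-rest,
#'   EH-task, NEH-task).
#' @return A tibble with columns `label`, `condition` and the generative
#'   parameters.
#' @examples
#' group_params()
#' group_params(ied_rate = rep(0, 4))
#' @export
group_params <- function(...) {
  p <- tibble::tibble(
    label     = c("EH", "NEH", "EH", "NEH"),
    condition = c("rest", "rest", "task", "task"),
    r_rate    = c(120.1, 44.94, 64.84, 21.13),
    fr_rate   = c(214.16, 44.28, 137.15, 35.39),
    r_amp     = c(6.87, 5.35, 6.28, 4.95),
    r_amp_sd  = c(1.26, 0.93, 1.06, 0.81),
    fr_amp    = c(6.62, 5.15, 6.12, 5.05),
    fr_amp_sd = c(1.26, 0.86, 0.93, 0.54),
    r_freq    = c(176.75, 153.99, 175.69, 156.96),
    r_freq_sd = c(13.83, 17.42, 11.37, 18.25),
    fr_freq   = c(399.6, 400.05, 412.24, 412.36),
    fr_freq_sd = c(28.81, 30.43, 29.2, 22.14),
    r_dur     = c(34.56, 38.09, 34.41, 35.78),
    r_dur_sd  = c(4.13, 4.2, 3.61, 4.19),
    fr_dur    = c(18.19, 15.11, 17.11, 14.07),
    fr_dur_sd = c(2.68, 3.35, 2.69, 1.86),
    ied_rate  = c(158.84, 44.81, 105.03, 16.27),
    ied_amp   = c(378.61, 339.8, 370.88, 320.24),
    ied_amp_sd = c(152.44, 172.27, 139.48, 214.9),
    coupling_r  = c(0.43, 0.43, 0.44, 0.44),
    coupling_fr = c(0.49, 0.44, 0.51, 0.48),
    ren_contrast = c(0.27, 0.15, 0.22, 0.14)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad) > 0) {
    abort(sprintf("group_params: unknown parameter(s) %s",
                  paste(bad, collapse = ", ")))
  }
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  stopifnot(all(p$r_rate >= 0), all(p$fr_rate >= 0), all(p$ied_rate >= 0),
            all(p$coupling_r >= 0 & p$coupling_r <= 1),
            all(p$coupling_fr >= 0 & p$coupling_fr <= 1),
            all(p$r_dur > 0), all(p$fr_dur > 0))
  p
}

#' Colored-noise background signal
#'
#' Gaussian noise with power spectral density proportional to
#' `1/f^spectral_exponent`, generated by spectral shaping of white noise,
#' standing in for the aperiodic interictal iEEG background.
#'
#' @param duration_s Length in seconds (> 0).
#' @param fs Sampling rate, Hz.
#' @param spectral_exponent PSD exponent (0 = white; iEEG backgrounds are
#'   typically 1-3; default 2).
#' @param amplitude_scale Target signal SD in uV (default 50).
#' @param seed Optional integer seed; identical seeds give identical signals.
#' @return Numeric vector of `round(duration_s * fs)` samples.
#' @examples
#' x <- generate_background(2, 2000, spectral_exponent = 1, seed = 1)
#' @export
generate_background <- function(duration_s, fs, spectral_exponent = 2,
                                amplitude_scale = 50, seed = NULL) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    abort("generate_background: duration_s must be positive")
  }
  n <- round(duration_s * fs)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  colored_noise(n, fs, spectral_exponent, amplitude_scale)
}

# Spectral shaping core (uses the current RNG stream).
colored_noise <- function(n, fs, exponent, sd_target,
                          f_lo = 0.5, f_hi = NULL) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  gain <- c(0, f[-1]^(-exponent / 2))
  # recordings are AC-coupled: suppress content below f_lo (default 0.5 Hz)
  gain[f < f_lo] <- 0
  if (!is.null(f_hi)) gain[f > f_hi] <- 0
  x <- Re(fft(W * gain, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0) return(x)
  x * (sd_target / s)
}

rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (n == 0) return(numeric())
  x <- rnorm(n, mean, sd)
  for (i in 1:20) {
    bad <- x < lo | x > hi
    if (!any(bad)) break
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lo), hi)
}

#' Inject a tapered oscillatory burst
#'
#' Adds a Tukey-tapered sinusoid of `n_cycles` cycles at `freq_hz` (duration
#' `n_cycles / freq_hz` seconds) starting at `onset_s`, and returns the
#' modified signal together with the ground-truth record.
#'
#' @param x Signal vector (uV).
#' @param fs Sampling rate, Hz.
#' @param onset_s Burst onset, seconds; the burst must fit in the signal.
#' @param freq_hz Oscillation frequency, Hz (60-800).
#' @param n_cycles Number of cycles (> 0).
#' @param amplitude Peak amplitude, uV.
#' @param taper Taper fraction of the Tukey window (0 = rectangular,
#'   1 = Hann; default 0.5).
#' @return A list with `signal` (modified vector) and `truth` (one-row tibble:
#'   `onset_s`, `duration_s`, `freq_hz`, `n_cycles`, `amplitude`).
#' @export
inject_hfo <- function(x, fs, onset_s, freq_hz, n_cycles, amplitude,
                       taper = 0.5) {
  if (freq_hz <= 60 || freq_hz >= 800) {
    abort("inject_hfo: freq_hz must lie in (60, 800)")
  }
  dur <- n_cycles / freq_hz
  if (onset_s < 0 || onset_s + dur > length(x) / fs) {
    abort("inject_hfo: burst does not fit inside the signal")
  }
  i0 <- round(onset_s * fs)
  len <- max(2L, round(dur * fs))
  tt <- (seq_len(len) - 1) / fs
  burst <- amplitude * sin(2 * pi * freq_hz * tt) * tukey_window(len, taper)
  x[(i0 + 1):(i0 + len)] <- x[(i0 + 1):(i0 + len)] + burst
  list(signal = x,
       truth = tibble::tibble(onset_s = onset_s, duration_s = dur,
                              freq_hz = freq_hz, n_cycles = n_cycles,
                              amplitude = amplitude))
}

tukey_window <- function(n, r) {
  if (r <= 0) return(rep(1, n))
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  a <- t < r / 2
  w[a] <- 0.5 * (1 + cos(pi * (2 * t[a] / r - 1)))
  b <- t > 1 - r / 2
  w[b] <- 0.5 * (1 + cos(pi * (2 * t[b] / r - 2 / r + 1)))
  w
}

#' Inject an interictal spike
#'
#' Adds a biphasic sharp transient (derivative-of-Gaussian waveform, energy
#' concentrated in the 20-50 Hz range for the default width), optionally
#' followed by a slow after-wave, and returns the ground truth.
#'
#' @param x Signal vector (uV).
#' @param fs Sampling rate, Hz.
#' @param onset_s Spike onset, seconds.
#' @param amplitude_uv Peak-to-trough amplitude, uV.
#' @param spike_width_ms Overall transient width, ms (20-70 recommended;
#'   default 55: sharp enough for 20-50 Hz detectability, slow enough that
#'   leakage into the ripple band stays below the band's background).
#' @param wave Add a slow wave (half-sine, 150 ms, 30 % amplitude) after the
#'   spike (default TRUE).
#' @return List with `signal` and `truth` (tibble: `onset_s`, `t_peak`,
#'   `amplitude_uv`, `spike_width_ms`).
#' @export
inject_ied <- function(x, fs, onset_s, amplitude_uv, spike_width_ms = 55,
                       wave = TRUE) {
  tpl <- ied_template(fs, spike_width_ms, wave)
  dur <- length(tpl$y) / fs
  if (onset_s < 0 || onset_s + dur > length(x) / fs) {
    abort("inject_ied: spike does not fit inside the signal")
  }
  i0 <- round(onset_s * fs)
  y <- tpl$y * amplitude_uv
  x[(i0 + 1):(i0 + length(y))] <- x[(i0 + 1):(i0 + length(y))] + y
  list(signal = x,
       truth = tibble::tibble(onset_s = onset_s,
                              t_peak = onset_s + tpl$t_peak,
                              amplitude_uv = amplitude_uv,
                              spike_width_ms = spike_width_ms))
}

# Biphasic template with unit peak-to-trough amplitude. The sharp transient
# is a derivative-of-Gaussian windowed to zero at its edges, and the slow
# wave is a smooth sin^2 bump, so the template has no edge discontinuities
# that would leak broadband energy into the HFO detection range.
ied_template <- function(fs, spike_width_ms, wave = TRUE) {
  sigma <- spike_width_ms / 6 / 1000
  tt <- seq(-4 * sigma, 4 * sigma, by = 1 / fs)
  y <- -tt * exp(-tt^2 / (2 * sigma^2))
  y <- y * tukey_window(length(y), 0.5)
  y <- y / (max(y) - min(y))
  t_peak <- tt[which.max(y)] - tt[1]
  if (wave) {
    nw <- round(0.15 * fs)
    slow <- -0.3 * sin(pi * seq_len(nw) / nw)^2
    y <- c(y, slow)
  }
  list(y = y, t_peak = t_peak)
}

#' Detector-band gain of an injected burst
#'
#' Peak analytic-envelope gain of a Tukey-tapered `n_cycles`-cycle burst
#' passed through the constant-Q Gaussian analysis band centered at its own
#' frequency. Used to calibrate injected amplitudes so the detector's
#' relative amplitude (z) lands at the requested target: short bursts are
#' wider than the band and lose amplitude. The gain is dimensionless and
#' depends only on `n_cycles`, `band_q` and the taper.
#'
#' @param n_cycles Cycle count(s).
#' @param band_q Detector band Q (default 8).
#' @param taper Tukey taper fraction (default 0.5).
#' @return Numeric gain in (0, 1], same length as `n_cycles`.
#' @export
calibrate_hfo_amplitude <- function(n_cycles, band_q = 4.5, taper = 0.5) {
  vapply(n_cycles, function(nc) burst_response(nc, band_q, taper)$gain,
         numeric(1))
}

# Filtered envelope of a unit-amplitude burst of nc cycles through its own
# analysis band: peak gain and the envelope itself (for span measurements).
burst_response <- function(nc, band_q, taper) {
  f0 <- 100; fs <- 8192
  len <- max(8L, round(nc / f0 * fs))
  n <- next_pow2(len * 8L)
  x <- numeric(n)
  tt <- (seq_len(len) - 1) / fs
  x[seq_len(len) + n %/% 4] <- sin(2 * pi * f0 * tt) * tukey_window(len, taper)
  X <- fft(x)
  f <- (seq_len(n) - 1) * fs / n
  g <- numeric(n)
  pos <- seq_len(n %/% 2)
  g[pos] <- 2 * exp(-0.5 * ((f[pos] - f0) / (f0 / band_q))^2)
  env <- Mod(fft(X * g, inverse = TRUE)) / n
  list(gain = max(env), env = env, fs = fs, f0 = f0)
}

# Rayleigh envelope mean/SD ratio: threshold crossings of the z-scored
# background envelope happen at env = mu + z * sd = sd * (RAYLEIGH_MS + z).
RAYLEIGH_MS <- sqrt(pi / 2) / sqrt(2 - pi / 2)

# Detected-span calibration: find the injected cycle count whose filtered
# envelope stays above the detector's crossing level (a fraction of its peak
# determined by the amplitude z target) for the *target* number of cycles.
# The z > 3 crossing truncates the flanks of a burst, so the raw injection
# must be somewhat longer than the duration the detector should measure.
calibrate_burst <- function(nc_target, amp_z, band_q, taper = 0.5) {
  key <- sprintf("%.1f_%.2f_%.3f_%.2f", nc_target, amp_z, band_q, taper)
  hit <- .calib_cache[[key]]
  if (!is.null(hit)) return(hit)
  thr_frac <- (RAYLEIGH_MS + 3) / (RAYLEIGH_MS + max(amp_z, 3.2))
  nc_inj <- nc_target
  gain <- 1
  for (iter in 1:3) {
    br <- burst_response(nc_inj, band_q, taper)
    gain <- br$gain
    span_cycles <- sum(br$env > thr_frac * br$gain) / br$fs * br$f0
    nc_inj <- max(1, min(3 * nc_target, nc_inj + (nc_target - span_cycles)))
  }
  out <- list(n_cycles_inj = nc_inj, gain = gain)
  .calib_cache[[key]] <- out
  out
}

.calib_cache <- new.env(parent = emptyenv())

# Envelope mean/SD of `x` in the analysis band at each frequency of `freqs`,
# measured with the same constant-Q Gaussian bands the detector uses.
band_envelope_stats <- function(x, fs, freqs, band_q = 4.5) {
  nfft <- pad_mirror_nfft(length(x))
  X <- fft(pad_mirror(x - mean(x)))
  t(vapply(freqs, function(fc) {
    be <- band_envelope_dec(X, nfft, fs, fc, fc / band_q)
    nv <- min(length(be$env), ceiling(length(x) / fs * be$fs_env))
    e <- be$env[seq_len(nv)]
    c(mean = mean(e), sd = sd(e))
  }, c(mean = 0, sd = 0)))
}

#' Generate a synthetic multi-hippocampus iEEG cohort
#'
#' Builds rest and task recording segments for `n_eh` epileptic and `n_neh`
#' non-epileptic hippocampi, each with `channels_per_hippocampus` contacts on
#' one electrode, emulating the statistical structure of interictal
#' hippocampal recordings: 1/f background, Poisson-injected ripple and
#' fast-ripple bursts and interictal spikes with group-dependent
#' rate/amplitude/frequency/duration, shared band-limited components giving
#' controllable adjacent-contact correlation, and log-normal amplitude
#' modulation driving relative-entropy contrast (independent modulators in
#' EH channels, a shared modulator in NEH channels). Injected HFO amplitudes
#' are calibrated in units of the local band-envelope statistics so the
#' detector's relative amplitude lands near the requested z target
#' (see [calibrate_hfo_amplitude()]).
#'
#' @param n_eh,n_neh Number of epileptic / non-epileptic hippocampi
#'   (defaults 22 and 23, the emulated study design).
#' @param channels_per_hippocampus Contacts per hippocampus (default 6,
#'   approximating 254 channels over 45 hippocampi).
#' @param params A [group_params()] tibble.
#' @param duration_s Segment length per condition, seconds (default 600; the
#'   feature normalization basis is 10 min).
#' @param fs Sampling rate, Hz (default 5000).
#' @param background_exponent,background_uv Background PSD exponent and SD.
#' @param tasks Character vector of task names; one task segment is generated
#'   per name, all drawn from the `task` parameter row.
#' @param seed Integer seed; identical (arguments, seed) give identical
#'   cohorts.
#' @return An object of class `ieeg_cohort`: list with `segments` (named list
#'   of [recording_segment()]), `index` (tibble: `segment_id`,
#'   `hippocampus_id`, `label`, `condition`, `task_name`), `channels`
#'   (metadata for all channels), `truth` (list of tibbles `hfo`, `ied`),
#'   `params`, `seed`.
#' @examples
#' \donttest{
#' co <- generate_cohort(n_eh = 1, n_neh = 1, channels_per_hippocampus = 2,
#'                       duration_s = 20, fs = 2000, seed = 1)
#' co$index
#' }
#' @export
generate_cohort <- function(n_eh = 22, n_neh = 23,
                            channels_per_hippocampus = 6,
                            params = group_params(),
                            duration_s = 600, fs = 5000,
                            background_exponent = 2, background_uv = 50,
                            tasks = "task", band_q = 4.5, seed = 1) {
  if (channels_per_hippocampus < 1) abort("generate_cohort: zero channels")
  if (n_eh + n_neh < 1) abort("generate_cohort: no hippocampi")
  set.seed(seed)
  hips <- tibble::tibble(
    hippocampus_id = c(sprintf("EH%02d", seq_len(n_eh)),
                       sprintf("NEH%02d", seq_len(n_neh))),
    label = c(rep("EH", n_eh), rep("NEH", n_neh))
  )
  segments <- list(); index <- list(); truth_hfo <- list(); truth_ied <- list()
  channels_all <- list()
  conds <- c("rest", tasks)
  for (i in seq_len(nrow(hips))) {
    hip <- hips$hippocampus_id[i]; lab <- hips$label[i]
    nch <- channels_per_hippocampus
    meta <- tibble::tibble(
      channel_id = sprintf("%s-c%d", hip, seq_len(nch)),
      subject_id = sprintf("s%02d", i), electrode_id = "A",
      contact_index = seq_len(nch), hippocampus_id = hip, label = lab
    )
    channels_all[[i]] <- meta
    for (cond_name in conds) {
      condition <- if (cond_name == "rest") "rest" else "task"
      p <- params[params$label == lab & params$condition == condition, ]
      sig <- build_segment_signals(nch, duration_s, fs, p,
                                   background_exponent, background_uv)
      inj <- inject_segment_events(sig, fs, p, band_q)
      seg_id <- paste(hip, cond_name, sep = "_")
      segments[[seg_id]] <- recording_segment(
        inj$signals, fs, meta, condition = condition,
        task_name = if (condition == "task") cond_name else NULL
      )
      index[[seg_id]] <- tibble::tibble(
        segment_id = seg_id, hippocampus_id = hip, label = lab,
        condition = condition,
        task_name = if (condition == "task") cond_name else NA_character_
      )
      if (nrow(inj$hfo) > 0) {
        inj$hfo$channel_id <- meta$channel_id[inj$hfo$channel]
        inj$hfo$segment_id <- seg_id
        truth_hfo[[seg_id]] <- inj$hfo
      }
      if (nrow(inj$ied) > 0) {
        inj$ied$channel_id <- meta$channel_id[inj$ied$channel]
        inj$ied$segment_id <- seg_id
        truth_ied[[seg_id]] <- inj$ied
      }
    }
  }
  structure(
    list(segments = segments, index = dplyr::bind_rows(index),
         channels = dplyr::bind_rows(channels_all),
         truth = list(hfo = dplyr::bind_rows(truth_hfo),
                      ied = dplyr::bind_rows(truth_ied)),
         params = params, seed = seed),
    class = "ieeg_cohort"
  )
}

#' @export
print.ieeg_cohort <- function(x, ...) {
  cat(sprintf(
    "<ieeg_cohort> %d segments, %d channels, %d injected HFO, %d injected IED (seed %s)\n",
    length(x$segments), nrow(x$channels), nrow(x$truth$hfo),
    nrow(x$truth$ied), format(x$seed)))
  invisible(x)
}

# Backgrounds + adjacent-contact coupling + REN amplitude modulation for one
# segment. Returns a samples x channels matrix.
build_segment_signals <- function(nch, duration_s, fs, p,
                                  background_exponent, background_uv) {
  n <- round(duration_s * fs)
  sig <- matrix(0, n, nch)
  for (j in seq_len(nch)) {
    sig[, j] <- colored_noise(n, fs, background_exponent, background_uv)
  }
  # replacement bands extend past the measurement bands (80-250 / 250-600)
  # so the analysis filters' transition skirts see fully coupled content
  # rather than a seam of unreplaced background
  bands <- list(r = c(70, 250, p$coupling_r),
                fr = c(250, min(690, fs / 2 - 10), p$coupling_fr))
  kappa <- p$ren_contrast
  for (bd in bands) {
    f_lo <- bd[1]; f_hi <- bd[2]; rho <- bd[3]
    shared <- colored_noise(n, fs, background_exponent, 1, f_lo = f_lo,
                            f_hi = f_hi)
    shared <- shared / sd(shared)
    bps <- lapply(seq_len(nch), function(j) bandpass(sig[, j], fs, f_lo, f_hi))
    # one band scale for the whole hippocampus: per-channel normalization
    # jitter would masquerade as relative-entropy contrast
    s_bar <- mean(vapply(bps, sd, 0))
    for (j in seq_len(nch)) {
      bp <- bps[[j]] * (s_bar / sd(bps[[j]]))
      sig[, j] <- sig[, j] - bps[[j]] + bp
      mixed <- sqrt(rho) * shared * s_bar + sqrt(1 - rho) * bp
      # REN contrast: static alternating-parity log gain on the band
      # content (adjacent contacts differ by a factor exp(2*kappa)).
      # Invisible to the z-scored detector (mean and SD scale together) and
      # to within-window Pearson correlation, but it scales the
      # amplitude-sample distributions that relative entropy compares.
      gain <- exp(kappa * if (j %% 2 == 1) 1 else -1)
      sig[, j] <- sig[, j] - bp + gain * mixed
    }
  }
  sig
}

# Poisson event injection for one segment; amplitudes calibrated in local
# band-envelope units, injected durations calibrated so the detector's
# threshold-crossing span recovers the drawn (target) duration.
inject_segment_events <- function(sig, fs, p, band_q = 4.5) {
  n <- nrow(sig); nch <- ncol(sig); duration_s <- n / fs
  scale10 <- duration_s / 600
  probe <- exp(seq(log(70), log(700), length.out = 8))
  hfo_rows <- list(); ied_rows <- list(); k <- 0L; ki <- 0L
  # non-overlapping placement: events are kept one event-duration apart so
  # that distinct injections cannot merge into one detection and bias the
  # measured duration/amplitude means of event-dense channels
  draw_onset <- function(occ, dur, lo, hi) {
    for (try in 1:50) {
      onset <- runif(1, lo, max(hi, lo))
      if (!any(onset < occ[, 2] + dur & occ[, 1] - dur < onset + dur)) {
        return(onset)
      }
    }
    onset
  }
  for (j in seq_len(nch)) {
    occupied <- matrix(numeric(0), ncol = 2)
    st <- band_envelope_stats(sig[, j], fs, probe)
    env_mean <- function(f) exp(approx(log(probe), log(st[, "mean"]), log(f),
                                       rule = 2)$y)
    env_sd <- function(f) exp(approx(log(probe), log(st[, "sd"]), log(f),
                                     rule = 2)$y)
    for (type in c("r", "fr")) {
      rate <- p[[paste0(type, "_rate")]]
      n_ev <- rpois(1, rate * scale10)
      if (n_ev == 0) next
      f_rng <- if (type == "r") c(80, 250) else c(250, 600)
      freq <- rnorm_trunc(n_ev, p[[paste0(type, "_freq")]],
                          p[[paste0(type, "_freq_sd")]],
                          f_rng[1], f_rng[2] - 1e-6)
      dur_ms <- rnorm_trunc(n_ev, p[[paste0(type, "_dur")]],
                            p[[paste0(type, "_dur_sd")]], lo = 5)
      amp_z <- rnorm_trunc(n_ev, p[[paste0(type, "_amp")]],
                           p[[paste0(type, "_amp_sd")]], lo = 2)
      n_cycles <- dur_ms / 1000 * freq
      # the events themselves inflate the statistical-window SD the detector
      # z-scores against; compensate to first order so detected z lands at
      # the target in event-dense channels too
      phi <- rate / 600 * p[[paste0(type, "_dur")]] / 1000
      infl <- sqrt(1 + phi * (0.75 * p[[paste0(type, "_amp")]])^2)
      for (e in seq_len(n_ev)) {
        cal <- calibrate_burst(round(n_cycles[e] * 4) / 4,
                               round(amp_z[e] * 4) / 4, band_q)
        amp_uv <- infl * (amp_z[e] * env_sd(freq[e]) + env_mean(freq[e])) /
          cal$gain
        dur_inj <- cal$n_cycles_inj / freq[e]
        onset <- draw_onset(occupied, dur_inj, dur_inj,
                            duration_s - 2 * dur_inj)
        occupied <- rbind(occupied, c(onset, onset + dur_inj))
        res <- inject_hfo(sig[, j], fs, onset, freq[e], cal$n_cycles_inj,
                          amp_uv)
        sig[, j] <- res$signal
        k <- k + 1L
        tr <- res$truth
        # duration_s/n_cycles report the calibrated target the detector
        # should measure; the raw injected span is kept alongside
        tr$inj_duration_s <- tr$duration_s
        tr$duration_s <- n_cycles[e] / freq[e]
        tr$n_cycles <- n_cycles[e]
        tr$channel <- j
        tr$band <- toupper(type)
        tr$amp_z <- amp_z[e]
        hfo_rows[[k]] <- tr
      }
    }
    n_sp <- rpois(1, p$ied_rate * scale10)
    if (n_sp > 0) {
      amp <- rnorm_trunc(n_sp, p$ied_amp, p$ied_amp_sd, lo = 50)
      for (e in seq_len(n_sp)) {
        onset <- draw_onset(occupied, 0.3, 0.2, duration_s - 0.5)
        occupied <- rbind(occupied, c(onset, onset + 0.3))
        res <- inject_ied(sig[, j], fs, onset, amp[e])
        sig[, j] <- res$signal
        ki <- ki + 1L
        ied_rows[[ki]] <- dplyr::mutate(res$truth, channel = j)
      }
    }
  }
  list(signals = sig,
       hfo = dplyr::bind_rows(hfo_rows) %||% tibble::tibble(),
       ied = dplyr::bind_rows(ied_rows) %||% tibble::tibble())
}

#' Generate a single rest/task segment pair
#'
#' Convenience wrapper around [generate_cohort()] for one hippocampus.
#'
#' @param params A [group_params()] row set.
#' @param seed Integer seed.
#' @param duration_s,fs,n_channels,label See [generate_cohort()].
#' @return List with elements `rest` and `task` ([recording_segment()]s) and
#'   `truth`.
#' @export
simulate_segment_pair <- function(params = group_params(), seed = 1,
                                  duration_s = 600, fs = 5000,
                                  n_channels = 2, label = "EH") {
  co <- generate_cohort(
    n_eh = as.integer(label == "EH"), n_neh = as.integer(label == "NEH"),
    channels_per_hippocampus = n_channels, params = params,
    duration_s = duration_s, fs = fs, seed = seed
  )
  rest_id <- co$index$segment_id[co$index$condition == "rest"]
  task_id <- co$index$segment_id[co$index$condition == "task"]
  list(rest = co$segments[[rest_id]], task = co$segments[[task_id]],
       truth = co$truth)
}

#' Write a cohort to disk as fixture files
#'
#' One CSV+JSON segment pair per recording (see [write_recording()]), a
#' combined channel-metadata CSV, and the ground truth as JSON.
#'
#' @param cohort An `ieeg_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ieeg_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$segments)) {
    write_recording(cohort$segments[[id]], file.path(dir, id))
  }
  write_channel_metadata(cohort$channels, file.path(dir, "channels.csv"))
  jsonlite::write_json(
    list(hfo = cohort$truth$hfo, ied = cohort$truth$ied,
         params = cohort$params, seed = cohort$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
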