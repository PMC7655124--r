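#' Expected group-contrast directions under the default generative parameters
#'
#' The catalogue of significant rest-versus-task and EH-versus-NEH contrasts
#' the default [group_params()] encode, with their expected signs: `+1` means
#' rest > task (paired comparisons) or EH > NEH (group comparisons). Only
#' contrasts reported as significant in the emulated study design are
#' listed; near-zero contrasts the study found non-significant are excluded.
#'
#' @return A tibble with columns `feature`, `comparison`
#'   (`"rest_vs_task"`/`"eh_vs_neh"`), `group` (label or condition), `sign`.
#' @export
direction_catalogue <- function() {
  paired <- function(group, feature, sign) {
    tibble::tibble(feature = feature, comparison = "rest_vs_task",
                   group = group, sign = sign)
  }
  grp <- function(cond, feature, sign) {
    tibble::tibble(feature = feature, comparison = "eh_vs_neh",
                   group = cond, sign = sign)
  }
  dplyr::bind_rows(
    paired("EH", c("r_rate", "fr_rate", "r_amp", "fr_amp", "fr_dur",
                   "fr_freq", "ied_rate", "fr_corr", "r_ren", "fr_ren"),
           c(1, 1, 1, 1, 1, -1, 1, -1, 1, 1)),
    paired("NEH", c("r_rate", "r_amp", "r_dur", "fr_dur", "r_freq",
                    "fr_freq", "ied_rate", "r_corr", "fr_corr", "r_ren",
                    "fr_ren"),
           c(1, 1, 1, 1, -1, -1, 1, -1, -1, 1, 1)),
    grp("rest", c("r_rate", "fr_rate", "r_amp", "fr_amp", "r_dur", "fr_dur",
                  "r_freq", "ied_rate", "ied_amp", "fr_corr", "r_ren",
                  "fr_ren"),
        c(1, 1, 1, 1, -1, 1, 1, 1, 1, 1, 1, 1)),
    grp("task", c("r_rate", "fr_rate", "r_amp", "fr_amp", "r_dur", "fr_dur",
                  "r_freq", "ied_rate", "ied_amp", "r_ren", "fr_ren"),
        c(1, 1, 1, 1, -1, 1, 1, 1, 1, 1, 1))
  )
}

#' HFO detector injection-recovery experiment
#'
#' Generates channels of 1/f background carrying calibrated ripple and
#' fast-ripple injections at the epileptic-hippocampus resting-state rates
#' and amplitude/frequency/duration distributions (no spikes, no coupling),
#' runs the detector, matches detections to injections (temporal overlap and
#' peak frequency within a factor of 1.5), and scores recovery on the
#' injections that meet the scoring floor (amplitude target >= 3 envelope-SD
#' z units, >= `min_cycles_scored` cycles).
#'
#' @param n_channels Number of channels (default 20).
#' @param duration_s Channel length, seconds.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed.
#' @param config A [pipeline_config()].
#' @param min_cycles_scored Scoring floor on injected cycle count (default 6).
#' @return A list: `summary` (one-row tibble: `sensitivity`,
#'   `freq_error_hz`, `freq_error_bandwidths`, `duration_error_ms`,
#'   `n_scored`), `events` (per-injection match table).
#' @export
hfo_recovery_experiment <- function(n_channels = 20, duration_s = 300,
                                    fs = 2000, seed = 1,
                                    config = pipeline_config(),
                                    min_cycles_scored = 6) {
  p <- group_params(ied_rate = rep(0, 4), coupling_r = rep(0, 4),
                    coupling_fr = rep(0, 4), ren_contrast = rep(0, 4))
  co <- generate_cohort(n_eh = n_channels, n_neh = 0,
                        channels_per_hippocampus = 1, params = p,
                        duration_s = duration_s, fs = fs,
                        band_q = config$hfo$band_q, seed = seed)
  rest_ids <- co$index$segment_id[co$index$condition == "rest"]
  rows <- list()
  for (id in rest_ids) {
    ev <- detect_hfo(co$segments[[id]], config)
    ev <- ev[ev$band %in% c("R", "FR"), ]
    tr <- co$truth$hfo[co$truth$hfo$segment_id == id, ]
    for (i in seq_len(nrow(tr))) {
      hit <- which(ev$t_start < tr$onset_s[i] + tr$inj_duration_s[i] &
                     tr$onset_s[i] < ev$t_end &
                     abs(log(ev$peak_freq / tr$freq_hz[i])) < log(1.5))
      j <- if (length(hit) > 0) hit[which.max(ev$amplitude_z[hit])] else NA
      rows[[length(rows) + 1]] <- tibble::tibble(
        segment_id = id, freq_hz = tr$freq_hz[i],
        n_cycles = tr$n_cycles[i], amp_z = tr$amp_z[i],
        duration_ms = tr$duration_s[i] * 1000,
        detected = length(hit) > 0,
        det_freq = if (is.na(j)) NA_real_ else ev$peak_freq[j],
        det_duration_ms = if (is.na(j)) NA_real_ else ev$duration_ms[j],
        det_amp_z = if (is.na(j)) NA_real_ else ev$amplitude_z[j]
      )
    }
  }
  events <- dplyr::bind_rows(rows)
  scored <- events[events$amp_z >= 3 & events$n_cycles >= min_cycles_scored, ]
  hit <- scored[scored$detected, ]
  bw <- 2 * sqrt(2 * log(2)) / config$hfo$band_q  # FWHM as fraction of center
  summary <- tibble::tibble(
    sensitivity = mean(scored$detected),
    freq_error_hz = median(abs(hit$det_freq - hit$freq_hz)),
    freq_error_bandwidths = median(abs(hit$det_freq - hit$freq_hz) /
                                     (bw * hit$freq_hz)),
    duration_error_ms = median(abs(hit$det_duration_ms - hit$duration_ms)),
    n_scored = nrow(scored)
  )
  list(summary = summary, events = events)
}

#' False-positive rate of the HFO detector on pure colored noise
#'
#' @param duration_s,fs,seed,config As in [hfo_recovery_experiment()].
#' @param n_channels Number of noise channels.
#' @return Detected R+FR events per 10 minutes (averaged over channels).
#' @export
hfo_false_positive_rate <- function(n_channels = 2, duration_s = 600,
                                    fs = 2000, seed = 1,
                                    config = pipeline_config()) {
  counts <- vapply(seq_len(n_channels), function(i) {
    x <- generate_background(duration_s, fs, 2, 50, seed = seed + i)
    ev <- detect_hfo(x, config, fs = fs)
    sum(ev$band %in% c("R", "FR"))
  }, 0)
  mean(counts) * 600 / duration_s
}

#' Type-I error calibration on null cohorts
#'
#' Generates cohorts in which EH and NEH (and rest and task) are
#' generatively identical - every [group_params()] row is set to the overall
#' default mean - runs the full feature pipeline and the statistical battery,
#' and collects the channel-level p-values of all paired and group tests.
#' Channels of one hippocampus are correlated by construction (shared
#' coupling components, pair-based connectivity features), so the battery is
#' scored on one contact per hippocampus - the tests' independence
#' assumption then holds and the fraction significant at `alpha` estimates
#' the battery's type-I error.
#'
#' @param n_cohorts Number of independent null cohorts.
#' @param n_eh,n_neh,channels_per_hippocampus,duration_s,fs Cohort geometry.
#' @param seed Integer seed.
#' @param config A [pipeline_config()].
#' @return A list: `p_values` (numeric vector), `fraction_significant`,
#'   `n_tests`, and `features` (the feature tibble of the first cohort, for
#'   reuse in permutation nulls).
#' @export
type1_experiment <- function(n_cohorts = 5, n_eh = 8, n_neh = 8,
                             channels_per_hippocampus = 2, duration_s = 60,
                             fs = 2000, seed = 1,
                             config = pipeline_config()) {
  null_params <- null_group_params()
  ps <- c(); first_features <- NULL
  for (ci in seq_len(n_cohorts)) {
    co <- generate_cohort(n_eh = n_eh, n_neh = n_neh,
                          channels_per_hippocampus = channels_per_hippocampus,
                          params = null_params, duration_s = duration_s,
                          fs = fs, seed = seed * 1000 + ci)
    feats <- extract_features(co, config)
    if (is.null(first_features)) first_features <- feats
    feats1 <- feats[grepl("-c1$", feats$channel_id), ]
    bat <- feature_battery(feats1, config)
    # channel level: one contact per hippocampus; hippocampus level: median
    # over that hippocampus's contacts - both are independent across units
    bat_h <- feature_battery(feats, config)
    tests <- dplyr::bind_rows(
      bat$tests[bat$tests$level == "channel", ],
      bat_h$tests[bat_h$tests$level == "hippocampus", ])
    ps <- c(ps, tests$p_value[!is.na(tests$p_value)])
  }
  list(p_values = ps,
       fraction_significant = mean(ps < config$stats$alpha),
       n_tests = length(ps),
       features = first_features)
}

# Null generative parameters: every (label, condition) cell identical,
# set to the across-cell mean of the defaults.
null_group_params <- function() {
  p <- group_params()
  for (nm in setdiff(names(p), c("label", "condition"))) {
    p[[nm]] <- mean(p[[nm]])
  }
  p
}

#' Direction-recovery experiment
#'
#' Runs the full pipeline on many small cohorts drawn with the default
#' (study-condition) parameters and averages the per-(label, condition)
#' feature means over seeds; each catalogued contrast
#' ([direction_catalogue()]) is then scored by the sign of its pooled mean
#' difference.
#'
#' @param n_seeds Number of independent cohorts (default 50).
#' @param n_eh,n_neh,channels_per_hippocampus,duration_s,fs Cohort geometry
#'   per seed.
#' @param seed Base seed.
#' @param config A [pipeline_config()].
#' @return A list: `directions` (catalogue with observed mean differences
#'   and `correct` flags), `fraction_correct`, `cell_means` (per-seed group
#'   x condition feature means).
#' @export
direction_experiment <- function(n_seeds = 50, n_eh = 1, n_neh = 1,
                                 channels_per_hippocampus = 2,
                                 duration_s = 30, fs = 2000, seed = 1,
                                 config = pipeline_config()) {
  cells <- list()
  for (s in seq_len(n_seeds)) {
    co <- generate_cohort(n_eh = n_eh, n_neh = n_neh,
                          channels_per_hippocampus = channels_per_hippocampus,
                          duration_s = duration_s, fs = fs,
                          seed = seed * 1000 + s)
    feats <- extract_features(co, config)
    cells[[s]] <- feats |>
      dplyr::group_by(.data$label, .data$condition) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(feature_names()),
                                     ~ mean(.x, na.rm = TRUE)),
                       .groups = "drop") |>
      dplyr::mutate(seed = s)
  }
  cells <- dplyr::bind_rows(cells)
  pooled <- cells |>
    dplyr::group_by(.data$label, .data$condition) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(feature_names()),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  cell <- function(lab, cond, f) {
    pooled[[f]][pooled$label == lab & pooled$condition == cond]
  }
  cat <- direction_catalogue()
  cat$observed <- vapply(seq_len(nrow(cat)), function(i) {
    f <- cat$feature[i]
    if (cat$comparison[i] == "rest_vs_task") {
      cell(cat$group[i], "rest", f) - cell(cat$group[i], "task", f)
    } else {
      cell("EH", cat$group[i], f) - cell("NEH", cat$group[i], f)
    }
  }, 0)
  cat$correct <- sign(cat$observed) == cat$sign
  list(directions = cat, fraction_correct = mean(cat$correct),
       cell_means = cells)
}

#' End-to-end classification experiment on a default synthetic cohort
#'
#' Generates a cohort with the default group parameters, extracts features,
#' selects the ROC-significant (feature, scope) combinations on grouped-task
#' channel-level data, and tunes the leave-one-hippocampus-out SVM by grid
#' search.
#'
#' @param n_eh,n_neh,channels_per_hippocampus,duration_s,fs Cohort geometry.
#' @param seed Integer seed.
#' @param config A [pipeline_config()].
#' @param scopes Feature scopes admitted (see [select_features()]).
#' @return A list: `grid` (the `svm_grid`), `matrix` (design list),
#'   `features`, `selected`, `battery`.
#' @export
classification_experiment <- function(n_eh = 6, n_neh = 6,
                                      channels_per_hippocampus = 2,
                                      duration_s = 90, fs = 2000, seed = 1,
                                      config = pipeline_config(),
                                      scopes = c("rest", "task", "diff")) {
  co <- generate_cohort(n_eh = n_eh, n_neh = n_neh,
                        channels_per_hippocampus = channels_per_hippocampus,
                        duration_s = duration_s, fs = fs, seed = seed)
  feats <- extract_features(co, config)
  bat <- feature_battery(feats, config)
  sel <- select_features(bat$roc, alpha = config$stats$alpha, scopes = scopes)
  fm <- build_feature_matrix(grouped_task_reduce(feats), sel)
  gs <- grid_search(fm, kernels = config$svm$kernels,
                    c_grid = config$svm$c_grid,
                    gamma_grid = config$svm$gamma_grid,
                    refine = config$svm$refine, seed = seed)
  list(grid = gs, matrix = fm, features = feats, selected = sel,
       battery = bat)
}

#' Permutation null of the pooled LOHO AUC
#'
#' Permutes hippocampus labels (keeping channels of a hippocampus together,
#' preserving the class balance) of a design matrix and refits the
#' cross-validated SVM.
#'
#' @param matrix Design list from [build_feature_matrix()].
#' @param n_perms Number of permutations (default 20).
#' @param seed Base seed.
#' @param kernel,cost SVM settings for the refits.
#' @return Numeric vector of pooled AUCs, one per permutation.
#' @export
permutation_null_auc <- function(matrix, n_perms = 20, seed = 1,
                                 kernel = "linear", cost = 1) {
  hips <- unique(matrix$hippocampus_id)
  lab_of <- as.character(
    matrix$label[!duplicated(matrix$hippocampus_id)])
  vapply(seq_len(n_perms), function(s) {
    set.seed(seed * 100 + s)
    new_lab <- sample(lab_of)
    perm <- matrix
    perm$label <- factor(new_lab[match(matrix$hippocampus_id, hips)],
                         c("NEH", "EH"))
    fit_loho(perm, kernel = kernel, cost = cost, seed = s)$auc
  }, 0)
}
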