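#' Names of the 14 per-channel iEEG features
#'
#' Rates are events per 10 min; amplitudes are detector z units (HFO) or uV
#' (IED); frequencies Hz; durations ms; connectivity unitless.
#' @return Character vector of the 14 feature column names.
#' @export
feature_names <- function() {
  c("r_rate", "fr_rate", "r_amp", "fr_amp", "r_freq", "fr_freq",
    "r_dur", "fr_dur", "ied_rate", "ied_amp",
    "r_corr", "fr_corr", "r_ren", "fr_ren")
}

#' Aggregate detections into per-channel feature vectors
#'
#' Builds the 14-feature vector for every channel of one segment: R and FR
#' rate (scaled to a 10-min basis regardless of segment length), mean
#' relative amplitude, dominant frequency and duration per band; spike rate
#' and mean spike amplitude; and the per-channel connectivity summaries.
#' Channels with no events of a class get rate 0 and missing (`NA`)
#' event-derived features - a mean frequency of zero events is meaningless
#' and zero-imputation would bias group statistics.
#'
#' @param hfo_events Tibble from [detect_hfo()] (may have zero rows).
#' @param ied_events Tibble from [detect_ied()].
#' @param conn_summary Tibble from [channel_connectivity_summary()].
#' @param segment_duration_s Segment length in seconds.
#' @param channel_ids Channels to report (defaults to all ids present in the
#'   inputs; pass the segment's channel list to include event-free channels).
#' @return A tibble with `channel_id` plus the [feature_names()] columns.
#' @export
aggregate_features <- function(hfo_events, ied_events, conn_summary,
                               segment_duration_s, channel_ids = NULL) {
  stopifnot(segment_duration_s > 0)
  if (is.null(channel_ids)) {
    channel_ids <- unique(c(hfo_events$channel_id, ied_events$channel_id,
                            conn_summary$channel_id))
  }
  base <- tibble::tibble(channel_id = channel_ids)
  k10 <- 600 / segment_duration_s
  hfo_f <- if (nrow(hfo_events) > 0) {
    hfo_events |>
      dplyr::filter(.data$band %in% c("R", "FR")) |>
      dplyr::group_by(.data$channel_id, .data$band) |>
      dplyr::summarise(rate = dplyr::n() * k10,
                       amp = mean(.data$amplitude_z),
                       freq = mean(.data$peak_freq),
                       dur = mean(.data$duration_ms), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "band",
                         values_from = c("rate", "amp", "freq", "dur"),
                         names_glue = "{tolower(band)}_{.value}")
  } else tibble::tibble(channel_id = character())
  ied_f <- if (nrow(ied_events) > 0) {
    ied_events |>
      dplyr::group_by(.data$channel_id) |>
      dplyr::summarise(ied_rate = dplyr::n() * k10,
                       ied_amp = mean(.data$amplitude_uv), .groups = "drop")
  } else tibble::tibble(channel_id = character())
  conn_f <- if (nrow(conn_summary) > 0) {
    conn_summary |>
      tidyr::pivot_wider(names_from = "band", values_from = c("corr", "ren"),
                         names_glue = "{tolower(band)}_{.value}")
  } else tibble::tibble(channel_id = character())
  out <- base |>
    dplyr::left_join(hfo_f, by = "channel_id") |>
    dplyr::left_join(ied_f, by = "channel_id") |>
    dplyr::left_join(conn_f, by = "channel_id")
  for (nm in feature_names()) if (is.null(out[[nm]])) out[[nm]] <- NA_real_
  # absent events mean a true rate of zero, not a missing rate
  for (nm in c("r_rate", "fr_rate", "ied_rate")) {
    out[[nm]][is.na(out[[nm]])] <- 0
  }
  out[c("channel_id", feature_names())]
}

#' Run the full feature pipeline on a cohort
#'
#' For every segment: HFO detection, IED detection, adjacent-contact
#' connectivity, and per-channel aggregation; results are bound with the
#' cohort's channel metadata.
#'
#' @param cohort An `ieeg_cohort` from [generate_cohort()], or a list with
#'   elements `segments` (list of [recording_segment()]) and `index`.
#' @param config A [pipeline_config()].
#' @return A tibble with one row per channel x segment: metadata columns
#'   (`channel_id`, `hippocampus_id`, `label`, `condition`, `task_name`)
#'   plus the 14 features.
#' @export
extract_features <- function(cohort, config = pipeline_config()) {
  rows <- lapply(names(cohort$segments), function(id) {
    seg <- cohort$segments[[id]]
    hfo <- detect_hfo(seg, config)
    ied <- detect_ied(seg, config = config)
    conn <- suppressWarnings(windowed_connectivity(seg, config = config))
    feats <- aggregate_features(hfo, ied,
                                channel_connectivity_summary(conn),
                                seg$duration_s,
                                channel_ids = seg$channels$channel_id)
    meta <- cohort$index[cohort$index$segment_id == id, ]
    dplyr::bind_cols(
      tibble::tibble(
        channel_id = feats$channel_id,
        hippocampus_id = meta$hippocampus_id,
        label = seg$channels$label,
        condition = meta$condition,
        task_name = meta$task_name
      ),
      feats[feature_names()]
    )
  })
  dplyr::bind_rows(rows)
}

#' Average features across performed tasks
#'
#' When a subject performed several tasks, the task-condition feature vector
#' used for statistics is the element-wise mean across tasks, ignoring
#' missing values (a feature missing in one task contributes nothing to the
#' mean rather than dropping the channel).
#'
#' @param features Feature tibble from [extract_features()].
#' @return The same layout with one row per channel x condition and
#'   `task_name` collapsed to `"grouped"` for task rows.
#' @export
grouped_task_reduce <- function(features) {
  features |>
    dplyr::group_by(.data$channel_id, .data$hippocampus_id, .data$label,
                    .data$condition) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(feature_names()),
                                   ~ mean_or_na(.x)), .groups = "drop") |>
    dplyr::mutate(task_name = ifelse(.data$condition == "task", "grouped",
                                     NA_character_),
                  .after = "condition")
}

mean_or_na <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0) NA_real_ else mean(v)
}

#' Reduce channel features to one vector per hippocampus
#'
#' Element-wise median of all channels of a hippocampus (per condition),
#' guarding the statistics against subgroups of channels with outlying
#' features. With an even channel count the median is the mean of the two
#' middle values (the R convention).
#'
#' @param features Feature tibble from [extract_features()] or
#'   [grouped_task_reduce()].
#' @return A tibble with one row per hippocampus x condition; `channel_id`
#'   is replaced by the hippocampus id.
#' @export
per_hippocampus_reduce <- function(features) {
  features |>
    dplyr::group_by(.data$hippocampus_id, .data$label, .data$condition) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(feature_names()),
                                   ~ median_or_na(.x)), .groups = "drop") |>
    dplyr::mutate(channel_id = .data$hippocampus_id, .before = 1)
}

median_or_na <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0) NA_real_ else median(v)
}
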