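#' Paired rest-versus-task test for one feature
#'
#' Two-sided paired t-test of a feature between the resting-state and
#' task-condition values of the channels (or hippocampi) carrying a given
#' label. Pairs with a missing value in either condition are dropped and
#' counted in `n_dropped`.
#'
#' @param features Feature tibble (one row per channel x condition).
#' @param feature One of [feature_names()].
#' @param label_group `"EH"` or `"NEH"`.
#' @return One-row tibble: `feature`, `comparison`, `group`, `test`,
#'   `statistic`, `p_value`, `n`, `n_dropped`.
#' @export
paired_rest_task_test <- function(features, feature, label_group) {
  wide <- features |>
    dplyr::filter(.data$label == label_group) |>
    dplyr::select("channel_id", "condition", dplyr::all_of(feature)) |>
    tidyr::pivot_wider(names_from = "condition", values_from =
                         dplyr::all_of(feature))
  if (!all(c("rest", "task") %in% names(wide))) {
    abort("paired_rest_task_test: both conditions required")
  }
  ok <- complete.cases(wide[c("rest", "task")])
  n <- sum(ok)
  if (n < 2) abort("paired_rest_task_test: fewer than 2 complete pairs")
  d <- wide$rest[ok] - wide$task[ok]
  if (all(d == 0)) {
    stat <- 0; p <- 1
  } else if (sd(d) == 0) {
    # noiseless constant shift: degenerate paired t
    stat <- sign(mean(d)) * Inf; p <- 0
  } else {
    tt <- t.test(wide$rest[ok], wide$task[ok], paired = TRUE)
    stat <- unname(tt$statistic); p <- tt$p.value
  }
  tibble::tibble(feature = feature, comparison = "rest_vs_task",
                 group = label_group, test = "paired_t", statistic = stat,
                 p_value = p, n = n, n_dropped = sum(!ok))
}

#' Mann-Whitney test of a feature between EH and NEH
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test comparing epileptic
#' against non-epileptic channels within one condition. The reported
#' statistic is U, the number of (EH, NEH) pairs in which the EH value ranks
#' higher (ties counted 1/2).
#'
#' @param features Feature tibble.
#' @param feature One of [feature_names()].
#' @param condition `"rest"` or `"task"`.
#' @return One-row tibble in the same layout as [paired_rest_task_test()].
#' @export
group_test_eh_vs_neh <- function(features, feature, condition) {
  sub <- features[features$condition == condition, ]
  x <- sub[[feature]][sub$label == "EH"]
  y <- sub[[feature]][sub$label == "NEH"]
  dropped <- sum(is.na(x)) + sum(is.na(y))
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    abort("group_test_eh_vs_neh: both groups must be non-empty")
  }
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
  tibble::tibble(feature = feature, comparison = "eh_vs_neh",
                 group = condition, test = "mann_whitney",
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 n = length(x) + length(y), n_dropped = dropped)
}

#' Area under the ROC curve
#'
#' `AUC = P(score_EH > score_NEH) + 1/2 P(tie)` over all positive-negative
#' pairs, computed via midranks. EH is coded positive; an AUC below 0.5 is
#' reported as-is.
#'
#' @param scores Numeric scores (`NA` dropped pairwise with labels).
#' @param labels Logical, or anything coercible where `"EH"`/`TRUE`/`1` is
#'   positive.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))  # 1
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_positive(labels)
  ok <- !is.na(scores) & !is.na(pos)
  scores <- scores[ok]; pos <- pos[ok]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort("roc_auc: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1, NA))) abort("labels must be 0/1")
    return(labels == 1)
  }
  labels == "EH"
}

#' Hanley-McNeil test of an AUC against chance
#'
#' Closed-form standard error of a trapezoidal AUC,
#' `Q1 = A / (2 - A)`, `Q2 = 2 A^2 / (1 + A)`,
#' `SE^2 = (A(1-A) + (n_pos-1)(Q1-A^2) + (n_neg-1)(Q2-A^2)) / (n_pos n_neg)`,
#' with a two-sided normal test of `H0: AUC = 0.5`.
#'
#' @param auc AUC in \[0, 1\].
#' @param n_pos,n_neg Class sizes (>= 1).
#' @return Two-sided p-value.
#' @examples
#' hanley_mcneil_p(0.5, 20, 20)  # 1
#' @export
hanley_mcneil_p <- function(auc, n_pos, n_neg) {
  if (any(auc < 0 | auc > 1)) abort("hanley_mcneil_p: auc must be in [0, 1]")
  stopifnot(n_pos >= 1, n_neg >= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se2 <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
            (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  if (se2 <= 0) return(as.numeric(auc == 0.5))
  z <- (auc - 0.5) / sqrt(se2)
  2 * pnorm(-abs(z))
}

#' ROC analysis of one feature across scopes
#'
#' AUC (EH positive) with Hanley-McNeil p for the feature's resting-state
#' values, task values, and rest-minus-task differences.
#'
#' @param features Feature tibble (rest and task rows per channel).
#' @param feature One of [feature_names()].
#' @return Tibble with rows for scopes `rest`, `task`, `diff`: `feature`,
#'   `scope`, `auc`, `n_pos`, `n_neg`, `p_value`.
#' @export
roc_feature <- function(features, feature) {
  wide <- features |>
    dplyr::select("channel_id", "label", "condition",
                  dplyr::all_of(feature)) |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = dplyr::all_of(feature))
  scopes <- list(rest = wide$rest, task = wide$task,
                 diff = wide$rest - wide$task)
  purrr::map_dfr(names(scopes), function(sc) {
    v <- scopes[[sc]]
    ok <- !is.na(v)
    pos <- wide$label[ok] == "EH"
    if (sum(pos) == 0 || sum(!pos) == 0) {
      return(tibble::tibble(feature = feature, scope = sc, auc = NA_real_,
                            n_pos = sum(pos), n_neg = sum(!pos),
                            p_value = NA_real_))
    }
    a <- roc_auc(v[ok], pos)
    tibble::tibble(feature = feature, scope = sc, auc = a,
                   n_pos = sum(pos), n_neg = sum(!pos),
                   p_value = hanley_mcneil_p(a, sum(pos), sum(!pos)))
  })
}

#' Full statistical battery over the 14 features
#'
#' Runs, per feature: the paired rest-vs-task t-test within each label, the
#' EH-vs-NEH Mann-Whitney test within each condition, and the ROC analysis
#' (rest, task, rest-minus-task), at the channel level and again after
#' [per_hippocampus_reduce()]. Task rows are first collapsed with
#' [grouped_task_reduce()] unless already reduced. No multiple-testing
#' correction is applied by default (`p_adjust = "BH"` in the config enables
#' Benjamini-Hochberg across each table).
#'
#' @param features Feature tibble from [extract_features()].
#' @param config A [pipeline_config()].
#' @return Object of class `feature_battery`: list of tibbles `tests` and
#'   `roc`, each with a `level` column (`channel` / `hippocampus`), plus
#'   `alpha`.
#' @export
feature_battery <- function(features, config = pipeline_config()) {
  grouped <- grouped_task_reduce(features)
  levels <- list(channel = grouped,
                 hippocampus = per_hippocampus_reduce(grouped))
  tests <- list(); rocs <- list()
  for (lv in names(levels)) {
    dat <- levels[[lv]]
    for (f in feature_names()) {
      for (lab in intersect(c("EH", "NEH"), unique(dat$label))) {
        res <- try_stat(paired_rest_task_test(dat, f, lab))
        if (!is.null(res)) tests[[length(tests) + 1]] <-
            dplyr::mutate(res, level = lv)
      }
      for (cond in c("rest", "task")) {
        res <- try_stat(group_test_eh_vs_neh(dat, f, cond))
        if (!is.null(res)) tests[[length(tests) + 1]] <-
            dplyr::mutate(res, level = lv)
      }
      rocs[[length(rocs) + 1]] <- dplyr::mutate(roc_feature(dat, f),
                                                level = lv)
    }
  }
  tests <- dplyr::bind_rows(tests)
  rocs <- dplyr::bind_rows(rocs)
  if (config$stats$p_adjust == "BH") {
    tests$p_value <- stats::p.adjust(tests$p_value, "BH")
    rocs$p_value <- stats::p.adjust(rocs$p_value, "BH")
  }
  structure(list(tests = tests, roc = rocs, alpha = config$stats$alpha),
            class = "feature_battery")
}

try_stat <- function(expr) {
  tryCatch(expr, error = function(e) NULL)
}

#' @export
print.feature_battery <- function(x, ...) {
  cat(sprintf("<feature_battery> %d tests, %d ROC rows (alpha = %g)\n",
              nrow(x$tests), nrow(x$roc), x$alpha))
  sig <- x$tests[!is.na(x$tests$p_value) & x$tests$p_value < x$alpha, ]
  cat(sprintf("  significant tests: %d\n", nrow(sig)))
  invisible(x)
}

#' Significance heatmap of the statistical battery
#'
#' Tile map of test significance across features, in the style of a
#' channel/hippocampus significance matrix: one facet per comparison and
#' level, features on the y axis, tiles shaded by -log10(p) and annotated
#' with significance stars.
#'
#' @param object A `feature_battery`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_battery <- function(object, ...) {
  dat <- dplyr::mutate(
    object$tests,
    stars = dplyr::case_when(
      is.na(.data$p_value) ~ "",
      .data$p_value < 1e-4 ~ "****", .data$p_value < 1e-3 ~ "***",
      .data$p_value < 1e-2 ~ "**", .data$p_value < 0.05 ~ "*",
      TRUE ~ "ns"),
    neglog = -log10(pmax(.data$p_value, 1e-16))
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$feature,
                                    fill = .data$neglog)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 3) +
    ggplot2::facet_grid(.data$level ~ .data$comparison, scales = "free_x") +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 name = "-log10 p") +
    ggplot2::labs(x = NULL, y = NULL)
}
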