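#' Select features by ROC significance
#'
#' Keeps the (feature, scope) combinations whose grouped-task ROC is
#' significantly different from chance by the Hanley-McNeil test, where scope
#' is the resting-state value, the task value, or the rest-minus-task
#' difference. Scope subsets (`"rest"`, `"task"`, `"diff"`, or all three)
#' mirror building the model from each information source separately or
#' jointly.
#'
#' @param roc_results ROC tibble from [feature_battery()] (`$roc`) or
#'   [roc_feature()]; channel-level rows are used if a `level` column exists.
#' @param alpha Significance level (default 0.05).
#' @param scopes Scopes to admit (subset of `rest`, `task`, `diff`).
#' @return Tibble of selected rows (`feature`, `scope`, `auc`, `p_value`).
#' @export
select_features <- function(roc_results, alpha = 0.05,
                            scopes = c("rest", "task", "diff")) {
  scopes <- match.arg(scopes, c("rest", "task", "diff"), several.ok = TRUE)
  if (!is.null(roc_results[["level"]])) {
    roc_results <- roc_results[roc_results$level == "channel", ]
  }
  sel <- roc_results[roc_results$scope %in% scopes &
                       !is.na(roc_results$p_value) &
                       roc_results$p_value < alpha, ]
  if (nrow(sel) == 0) {
    abort(paste0(
      "select_features: no feature reaches ROC significance at alpha = ",
      alpha, " in scope(s) ", paste(scopes, collapse = "/"),
      "; smallest p = ", format(suppressWarnings(
        min(roc_results$p_value, na.rm = TRUE)), digits = 3)))
  }
  sel[c("feature", "scope", "auc", "p_value")]
}

#' Assemble the channel-by-feature design matrix
#'
#' One row per channel; one column per selected (feature, scope), where the
#' rest/task scopes take the condition's value and `diff` takes rest minus
#' task. Missing values are retained (imputed per training fold during
#' cross-validation).
#'
#' @param features Grouped-task channel-level feature tibble (rest and task
#'   rows per channel, e.g. from [grouped_task_reduce()]).
#' @param selected Selection tibble from [select_features()].
#' @return A list: `x` (numeric matrix, columns `<feature>_<scope>`),
#'   `label` (factor NEH/EH), `hippocampus_id`, `channel_id`.
#' @export
build_feature_matrix <- function(features, selected) {
  wide <- features |>
    dplyr::select("channel_id", "hippocampus_id", "label", "condition",
                  dplyr::all_of(feature_names())) |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = dplyr::all_of(feature_names()))
  cols <- lapply(seq_len(nrow(selected)), function(i) {
    f <- selected$feature[i]; sc <- selected$scope[i]
    switch(sc,
           rest = wide[[paste0(f, "_rest")]],
           task = wide[[paste0(f, "_task")]],
           diff = wide[[paste0(f, "_rest")]] - wide[[paste0(f, "_task")]])
  })
  x <- do.call(cbind, cols)
  colnames(x) <- paste(selected$feature, selected$scope, sep = "_")
  list(x = x,
       label = factor(wide$label, levels = c("NEH", "EH")),
       hippocampus_id = wide$hippocampus_id,
       channel_id = wide$channel_id)
}

# Training-fold preprocessing: median imputation, standardization, PCA
# (all components retained). Parameters come from the training rows only.
fit_preprocess <- function(x_train) {
  med <- apply(x_train, 2, median, na.rm = TRUE)
  med[is.na(med)] <- 0
  for (j in seq_len(ncol(x_train))) {
    x_train[is.na(x_train[, j]), j] <- med[j]
  }
  mu <- colMeans(x_train)
  sdv <- apply(x_train, 2, sd)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(x_train, 2, mu), 2, sdv, "/")
  pca <- prcomp(xs, center = FALSE, scale. = FALSE)
  list(median = med, mean = mu, sd = sdv, rotation = pca$rotation,
       scores = xs %*% pca$rotation)
}

# EH-oriented SVM decision values (libsvm's sign convention depends on which
# class it saw first).
svm_scores <- function(fit, x) {
  pr <- predict(fit, x, decision.values = TRUE)
  d <- attr(pr, "decision.values")
  if (grepl("^EH", colnames(d)[1])) as.numeric(d[, 1]) else -as.numeric(d[, 1])
}

# Platt-style probability calibration: logistic sigmoid fitted to the
# training fold's decision values. The slope is positive whenever the SVM
# fits its own training data, so calibrated probabilities preserve the
# decision-value ranking (e1071's built-in Platt CV can invert under weak
# signal on small folds).
platt_sigmoid <- function(dv, is_pos) {
  # class-balanced weights: the training fold is imbalanced by construction
  # (one hippocampus held out), and an imbalance-tracking intercept would
  # systematically depress the held-out class's probabilities across folds
  w <- ifelse(is_pos, 0.5 / max(mean(is_pos), 1e-6),
              0.5 / max(mean(!is_pos), 1e-6))
  cal <- suppressWarnings(
    tryCatch(stats::glm(is_pos ~ dv, family = stats::binomial(), weights = w),
             error = function(e) NULL))
  if (is.null(cal) || !is.finite(coef(cal)[2]) || coef(cal)[2] <= 0) {
    scale <- max(stats::sd(dv), 1e-8)
    return(function(z) stats::plogis(z / scale))
  }
  a <- coef(cal)[1]; b <- coef(cal)[2]
  function(z) stats::plogis(a + b * z)
}

apply_preprocess <- function(prep, x) {
  for (j in seq_len(ncol(x))) {
    x[is.na(x[, j]), j] <- prep$median[j]
  }
  xs <- sweep(sweep(x, 2, prep$mean), 2, prep$sd, "/")
  xs %*% prep$rotation
}

#' Leave-one-hippocampus-out SVM cross-validation
#'
#' For each hippocampus in turn, all its channels are held out; the SVM is
#' trained on the remaining channels (with median imputation,
#' standardization and PCA decorrelation fitted on the training fold only)
#' and emits calibrated probabilities of the held-out channels being
#' epileptic (a Platt-style sigmoid fitted to the training fold's decision
#' values). Held-out probabilities are pooled across folds into one ROC
#' (a per-fold ROC is undefined when the fold holds a single class, which is
#' always the case here). A hippocampus is predicted pathologic when the
#' mean probability of its channels exceeds 0.5.
#'
#' @param matrix A design list from [build_feature_matrix()].
#' @param kernel `"linear"` or `"radial"`.
#' @param cost SVM cost parameter C.
#' @param gamma RBF kernel width (ignored for linear).
#' @param seed Integer seed recorded in the report and applied before each
#'   fold's fit, keeping the report reproducible.
#' @return Object of class `loho_cv`: `channel` tibble (id, hippocampus,
#'   label, probability), `hippocampus` tibble (id, label, mean_prob,
#'   predicted), `auc`, `kernel`, `cost`, `gamma`, `seed`.
#' @export
fit_loho <- function(matrix, kernel = "linear", cost = 1, gamma = NULL,
                     seed = 1) {
  lab <- matrix$label; hip <- matrix$hippocampus_id
  hips <- unique(hip)
  per_class <- table(unique(data.frame(hip, lab))$lab)
  if (any(per_class < 2)) {
    abort("fit_loho: need at least 2 hippocampi per class")
  }
  if (is.null(gamma)) gamma <- 1 / ncol(matrix$x)
  prob <- rep(NA_real_, length(lab))
  for (k in seq_along(hips)) {
    test <- hip == hips[k]
    prep <- fit_preprocess(matrix$x[!test, , drop = FALSE])
    # inverse-frequency class weights: leaving a hippocampus out unbalances
    # the training classes, which would otherwise shift every held-out
    # probability toward the majority class
    tab <- table(lab[!test])
    wts <- as.numeric(sum(tab) / (2 * tab))
    names(wts) <- names(tab)
    set.seed(seed + k)
    fit <- e1071::svm(x = prep$scores, y = lab[!test], kernel = kernel,
                      cost = cost, gamma = gamma,
                      class.weights = wts, scale = FALSE)
    dv_train <- svm_scores(fit, prep$scores)
    cal <- platt_sigmoid(dv_train, lab[!test] == "EH")
    dv_test <- svm_scores(
      fit, apply_preprocess(prep, matrix$x[test, , drop = FALSE]))
    prob[test] <- cal(dv_test)
  }
  channel <- tibble::tibble(
    channel_id = matrix$channel_id, hippocampus_id = hip,
    label = as.character(lab), probability = prob
  )
  hippo <- channel |>
    dplyr::group_by(.data$hippocampus_id, .data$label) |>
    dplyr::summarise(mean_prob = mean(.data$probability), .groups = "drop") |>
    dplyr::mutate(predicted = ifelse(.data$mean_prob > 0.5, "EH", "NEH"))
  structure(
    list(channel = channel, hippocampus = hippo,
         auc = roc_auc(prob, lab == "EH"),
         kernel = kernel, cost = cost,
         gamma = if (kernel == "linear") NA_real_ else gamma,
         seed = seed),
    class = "loho_cv"
  )
}

#' @export
print.loho_cv <- function(x, ...) {
  cat(sprintf(
    "<loho_cv> pooled AUC %.3f (%s kernel, C=%g%s), %d channels / %d hippocampi\n",
    x$auc, x$kernel, x$cost,
    if (is.na(x$gamma)) "" else sprintf(", gamma=%g", x$gamma),
    nrow(x$channel), nrow(x$hippocampus)))
  invisible(x)
}

#' @rdname fit_loho
#' @param x A `loho_cv` object.
#' @param ... Unused.
#' @export
tidy.loho_cv <- function(x, ...) x$channel

#' @rdname fit_loho
#' @export
glance.loho_cv <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, kernel = x$kernel, cost = x$cost, gamma = x$gamma,
    n_channels = nrow(x$channel), n_hippocampi = nrow(x$hippocampus),
    hippocampus_accuracy = mean(x$hippocampus$predicted ==
                                  x$hippocampus$label)
  )
}

#' ROC curve of pooled cross-validated probabilities
#'
#' @param object A `loho_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loho_cv <- function(object, ...) {
  rc <- roc_curve_points(object$channel$probability,
                         object$channel$label == "EH")
  ggplot2::ggplot(rc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("Pooled LOHO ROC (AUC = %.2f)", object$auc))
}

roc_curve_points <- function(scores, pos) {
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  tibble::tibble(fpr = c(0, fp / sum(!pos)), tpr = c(0, tp / sum(pos)))
}

#' Iterative grid search over SVM hyperparameters
#'
#' Evaluates [fit_loho()] for every (kernel, C, gamma) cell (gamma applies to
#' the RBF kernel only), then refines once with a finer geometric grid around
#' the best cell. The best cell maximizes pooled AUC; ties are broken by
#' smaller C, then linear before RBF.
#'
#' @param matrix Design list from [build_feature_matrix()].
#' @param kernels Kernels to try (`"linear"`, `"radial"`).
#' @param c_grid,gamma_grid Initial geometric grids.
#' @param refine Run one zoom level around the best cell (default TRUE).
#' @param seed Integer seed.
#' @return Object of class `svm_grid`: `report` tibble (kernel, cost, gamma,
#'   auc for every evaluated cell), `best` (`loho_cv` of the winning cell).
#' @export
grid_search <- function(matrix, kernels = c("linear", "radial"),
                        c_grid = 10^(-3:2), gamma_grid = 10^(-3:2),
                        refine = TRUE, seed = 1) {
  stopifnot(length(kernels) > 0, length(c_grid) > 0)
  cells <- grid_cells(kernels, c_grid, gamma_grid)
  fits <- eval_cells(matrix, cells, seed)
  best <- pick_best(fits)
  if (refine) {
    b <- fits$report[best, ]
    zoom_c <- b$cost * 10^seq(-0.5, 0.5, by = 0.25)
    zoom_g <- if (b$kernel == "radial") {
      b$gamma * 10^seq(-0.5, 0.5, by = 0.25)
    } else NA_real_
    cells2 <- grid_cells(b$kernel, zoom_c, zoom_g)
    fits2 <- eval_cells(matrix, cells2, seed)
    fits <- list(report = dplyr::bind_rows(fits$report, fits2$report),
                 cv = c(fits$cv, fits2$cv))
    best <- pick_best(fits)
  }
  structure(list(report = fits$report, best = fits$cv[[best]]),
            class = "svm_grid")
}

grid_cells <- function(kernels, c_grid, gamma_grid) {
  out <- list()
  if ("linear" %in% kernels) {
    out$lin <- tidyr::expand_grid(kernel = "linear", cost = c_grid,
                                  gamma = NA_real_)
  }
  if ("radial" %in% kernels) {
    out$rbf <- tidyr::expand_grid(kernel = "radial", cost = c_grid,
                                  gamma = gamma_grid[!is.na(gamma_grid)])
  }
  dplyr::bind_rows(out)
}

eval_cells <- function(matrix, cells, seed) {
  cv <- vector("list", nrow(cells))
  auc <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cv[[i]] <- fit_loho(matrix, kernel = cells$kernel[i],
                        cost = cells$cost[i],
                        gamma = if (is.na(cells$gamma[i])) NULL else
                          cells$gamma[i],
                        seed = seed)
    auc[i] <- cv[[i]]$auc
  }
  list(report = dplyr::mutate(cells, auc = auc), cv = cv)
}

pick_best <- function(fits) {
  r <- fits$report
  order(-r$auc, r$cost, r$kernel != "linear")[1]
}

#' @export
print.svm_grid <- function(x, ...) {
  cat(sprintf("<svm_grid> %d cells evaluated\n", nrow(x$report)))
  print(x$best)
  invisible(x)
}

#' @rdname grid_search
#' @export
glance.svm_grid <- function(x, ...) glance(x$best)

#' @rdname grid_search
#' @export
tidy.svm_grid <- function(x, ...) dplyr::arrange(x$report, dplyr::desc(.data$auc))
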