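# Synthetic feature-level design: n_hip hippocampi per class, nch channels,
# k informative + k noise columns.
mk_design <- function(n_hip = 5, nch = 3, effect = 2.5, seed = 50) {
  set.seed(seed)
  n <- 2 * n_hip * nch
  hip <- rep(sprintf("h%02d", 1:(2 * n_hip)), each = nch)
  lab <- rep(c("EH", "NEH"), each = n_hip * nch)
  x <- cbind(
    matrix(rnorm(n * 2), ncol = 2),
    matrix(rnorm(n * 2, mean = ifelse(lab == "EH", effect, 0)), ncol = 2)
  )
  colnames(x) <- paste0("f", 1:4)
  list(x = x, label = factor(lab, c("NEH", "EH")), hippocampus_id = hip,
       channel_id = sprintf("c%03d", 1:n))
}

test_that("feature selection keeps only ROC-significant combinations", {
  roc <- tibble::tibble(
    feature = c("r_rate", "r_rate", "ied_amp", "fr_ren"),
    scope = c("rest", "task", "rest", "diff"),
    auc = c(0.9, 0.85, 0.55, 0.8),
    n_pos = 20, n_neg = 20,
    p_value = c(0.001, 0.02, 0.8, 0.04)
  )
  sel <- select_features(roc)
  expect_equal(nrow(sel), 3)
  expect_false("ied_amp" %in% sel$feature)
  sel_rest <- select_features(roc, scopes = "rest")
  expect_equal(sel_rest$feature, "r_rate")
  roc$p_value <- 1
  expect_error(select_features(roc), "no feature reaches")
})

test_that("the design matrix encodes rest, task and difference scopes", {
  f <- dplyr::bind_rows(
    lapply(c("rest", "task"), function(cond) {
      out <- tibble::tibble(channel_id = c("c1", "c2"),
                            hippocampus_id = c("h1", "h2"),
                            label = c("EH", "NEH"), condition = cond,
                            task_name = NA_character_)
      for (nm in feature_names()) {
        out[[nm]] <- if (cond == "rest") c(10, 6) else c(7, 5)
      }
      out
    })
  )
  sel <- tibble::tibble(feature = c("r_rate", "r_rate", "r_rate"),
                        scope = c("rest", "task", "diff"),
                        auc = 0.9, p_value = 0.01)
  fm <- build_feature_matrix(f, sel)
  expect_equal(colnames(fm$x), c("r_rate_rest", "r_rate_task", "r_rate_diff"))
  expect_equal(fm$x[, "r_rate_diff"], c(3, 1))
  expect_equal(as.character(fm$label), c("EH", "NEH"))
})

test_that("separable features give a perfect pooled ROC", {
  fm <- mk_design(effect = 8)
  cv <- fit_loho(fm, kernel = "linear", cost = 10, seed = 1)
  expect_equal(cv$auc, 1)
  expect_true(all(cv$hippocampus$predicted == cv$hippocampus$label))
  expect_equal(nrow(cv$channel), nrow(fm$x))   # every channel predicted once
  expect_false(any(is.na(cv$channel$probability)))
  g <- glance(cv)
  expect_equal(g$hippocampus_accuracy, 1)
  expect_s3_class(autoplot(cv), "ggplot")
})

test_that("label permutation drives the pooled AUC to chance", {
  # null design: features carry no class structure, so permuted labels must
  # yield chance-level pooled AUC (grouped CV shows anti-learning bias when
  # features cluster strongly, which is why the null uses unstructured ones)
  fm <- mk_design(n_hip = 6, effect = 0)
  aucs <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    perm <- fm
    # permute hippocampus labels (keeping channels of a hippocampus together)
    hips <- unique(fm$hippocampus_id)
    lab_of <- setNames(as.character(fm$label[!duplicated(fm$hippocampus_id)]),
                       hips)
    new_lab <- sample(unname(lab_of))
    perm$label <- factor(new_lab[match(fm$hippocampus_id, hips)],
                         c("NEH", "EH"))
    fit_loho(perm, kernel = "linear", cost = 1, seed = s)$auc
  }, 0)
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("one channel per hippocampus reduces to thresholding", {
  fm <- mk_design(n_hip = 4, nch = 1, effect = 6)
  cv <- fit_loho(fm, kernel = "linear", cost = 10, seed = 2)
  expect_equal(cv$hippocampus$mean_prob,
               cv$channel$probability[match(cv$hippocampus$hippocampus_id,
                                            cv$channel$hippocampus_id)])
  expect_equal(cv$hippocampus$predicted,
               ifelse(cv$hippocampus$mean_prob > 0.5, "EH", "NEH"))
})

test_that("training-fold transforms ignore held-out content", {
  fm <- mk_design()
  test_rows <- fm$hippocampus_id == "h01"
  prep1 <- hippofeat:::fit_preprocess(fm$x[!test_rows, ])
  fm2 <- fm
  fm2$x[test_rows, ] <- fm2$x[test_rows, sample(ncol(fm2$x))] * 100
  prep2 <- hippofeat:::fit_preprocess(fm2$x[!test_rows, ])
  expect_identical(rlang::hash(prep1), rlang::hash(prep2))
  # and imputation/standardization parameters come from training rows only
  expect_equal(prep1$mean, colMeans(fm$x[!test_rows, ]))
})

test_that("cross-validation is deterministic given the seed", {
  fm <- mk_design(effect = 1.5)
  cv1 <- fit_loho(fm, kernel = "radial", cost = 1, gamma = 0.1, seed = 7)
  cv2 <- fit_loho(fm, kernel = "radial", cost = 1, gamma = 0.1, seed = 7)
  expect_identical(rlang::hash(tidy(cv1)), rlang::hash(tidy(cv2)))
  expect_equal(cv1$auc, cv2$auc)
})

test_that("grid search refines around the best cell and breaks ties", {
  fm <- mk_design(effect = 4)
  gs1 <- grid_search(fm, kernels = "linear", c_grid = 1, refine = FALSE,
                     seed = 3)
  expect_equal(nrow(gs1$report), 1)
  expect_equal(gs1$best$cost, 1)
  gs <- grid_search(fm, kernels = c("linear", "radial"),
                    c_grid = c(0.1, 1), gamma_grid = c(0.1, 1), seed = 3)
  expect_s3_class(tidy(gs), "tbl_df")
  expect_gte(nrow(gs$report), 6)
  expect_equal(glance(gs)$auc, max(gs$report$auc))
  # tie-break: smaller C, then linear before radial
  rep_tie <- tibble::tibble(kernel = c("radial", "linear", "linear"),
                            cost = c(0.1, 1, 0.1), gamma = c(0.1, NA, NA),
                            auc = c(0.9, 0.9, 0.9))
  expect_equal(hippofeat:::pick_best(list(report = rep_tie)), 3L)
})

test_that("too few hippocampi per class is an error", {
  fm <- mk_design(n_hip = 1)
  expect_error(fit_loho(fm), "2 hippocampi")
})
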