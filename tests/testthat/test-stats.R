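mk_features <- function(rest, task, label = "EH",
                        hip = rep("h1", length(rest))) {
  n <- length(rest)
  base <- function(cond, vals) {
    out <- tibble::tibble(
      channel_id = sprintf("c%02d", seq_len(n)),
      hippocampus_id = hip,
      label = if (length(label) == 1) rep(label, n) else label,
      condition = cond, task_name = NA_character_
    )
    for (nm in feature_names()) out[[nm]] <- vals
    out
  }
  dplyr::bind_rows(base("rest", rest), base("task", task))
}

test_that("paired t-test handles identity and strong shifts", {
  f <- mk_features(rest = c(1, 2, 3, 4), task = c(1, 2, 3, 4))
  r <- paired_rest_task_test(f, "r_rate", "EH")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$n, 4)
  set.seed(40)
  rest <- rnorm(30, 10, 0.1)
  f2 <- mk_features(rest = rest, task = rest - 2)
  expect_lt(paired_rest_task_test(f2, "r_rate", "EH")$p_value, 1e-10)
  f3 <- mk_features(rest = c(1, NA, 3), task = c(2, 5, NA))
  expect_error(paired_rest_task_test(f3, "r_rate", "EH"), "pairs")
})

test_that("Mann-Whitney U equals the pair-counting oracle", {
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1)  # EH
  y <- c(0.8, 2.2, 1.9, 3.3, 2.8)  # NEH
  f <- mk_features(rest = c(x, y), task = c(x, y),
                   label = rep(c("EH", "NEH"), each = 5),
                   hip = rep(c("h1", "h2"), each = 5))
  r <- group_test_eh_vs_neh(f, "r_rate", "rest")
  u_oracle <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(unname(r$statistic), u_oracle)
  expect_equal(r$n, 10)
  # completely separated groups reach the extreme U
  f2 <- mk_features(rest = c(10, 11, 12, 1, 2, 3), task = rep(0, 6),
                    label = rep(c("EH", "NEH"), each = 3),
                    hip = rep(c("h1", "h2"), each = 3))
  r2 <- group_test_eh_vs_neh(f2, "r_rate", "rest")
  expect_equal(unname(r2$statistic), 9)
  f3 <- f[f$label == "EH", ]
  expect_error(group_test_eh_vs_neh(f3, "r_rate", "rest"), "non-empty")
})

test_that("null Mann-Whitney p-values are not systematically small", {
  set.seed(41)
  ps <- replicate(40, {
    f <- mk_features(rest = rnorm(24), task = rnorm(24),
                     label = rep(c("EH", "NEH"), each = 12),
                     hip = rep(c("h1", "h2"), each = 12))
    group_test_eh_vs_neh(f, "r_rate", "rest")$p_value
  })
  expect_gt(median(ps), 0.1)
})

test_that("AUC matches the exhaustive pair oracle and its symmetries", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(2, 8), rep(c(0, 1), 4)), 0.5)
  pair_oracle <- function(s, l) {
    pos <- s[l]; neg <- s[!l]
    (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
      (length(pos) * length(neg))
  }
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(6:50, 1)
    s <- sample(rnorm(n), n, replace = TRUE)  # induce ties
    l <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(l) || all(l)) next
    expect_equal(roc_auc(s, l), pair_oracle(s, l), tolerance = 1e-12)
    expect_equal(roc_auc(s, l) + roc_auc(-s, l), 1, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  s <- rnorm(60)
  l <- rbinom(60, 1, plogis(s))
  if (sum(l) > 0 && sum(1 - l) > 0) {
    ref <- suppressMessages(as.numeric(pROC::auc(l, s, direction = "<")))
    expect_equal(roc_auc(s, l), ref, tolerance = 1e-10)
  }
})

test_that("Hanley-McNeil inference follows the closed form", {
  expect_equal(hanley_mcneil_p(0.5, 20, 20), 1)
  # independently coded formula
  hm_oracle <- function(a, n1, n2) {
    v <- (a - a^2 + (n1 - 1) * (a / (2 - a) - a^2) +
            (n2 - 1) * (2 * a^2 / (1 + a) - a^2)) / (n1 * n2)
    2 * pnorm(abs(a - 0.5) / sqrt(v), lower.tail = FALSE)
  }
  for (a in c(0.55, 0.65, 0.75, 0.9, 0.99)) {
    expect_equal(hanley_mcneil_p(a, 20, 20), hm_oracle(a, 20, 20),
                 tolerance = 1e-12)
    expect_equal(hanley_mcneil_p(a, 14, 23), hm_oracle(a, 14, 23),
                 tolerance = 1e-12)
    # two-sidedness: symmetric under auc -> 1 - auc (classes swapped)
    expect_equal(hanley_mcneil_p(a, 20, 20), hanley_mcneil_p(1 - a, 20, 20),
                 tolerance = 1e-12)
    expect_equal(hanley_mcneil_p(a, 14, 23), hanley_mcneil_p(1 - a, 23, 14),
                 tolerance = 1e-12)
  }
  expect_error(hanley_mcneil_p(1.2, 5, 5), "0, 1|\\[0, 1\\]")
})

test_that("ROC scopes cover rest, task and their difference", {
  set.seed(44)
  n <- 20
  rest <- c(rnorm(n, 2), rnorm(n, 0))
  task <- c(rnorm(n, 1), rnorm(n, 0))
  f <- mk_features(rest = rest, task = task,
                   label = rep(c("EH", "NEH"), each = n),
                   hip = rep(c("h1", "h2"), each = n))
  r <- roc_feature(f, "r_rate")
  expect_setequal(r$scope, c("rest", "task", "diff"))
  expect_gt(r$auc[r$scope == "rest"], 0.8)
  d <- rest - task
  expect_equal(r$auc[r$scope == "diff"],
               roc_auc(d, rep(c(TRUE, FALSE), each = n)))
})

test_that("the battery runs both levels and flags expected contrasts", {
  feats <- tiny_features()
  bat <- feature_battery(feats)
  expect_setequal(unique(bat$tests$level), c("channel", "hippocampus"))
  expect_setequal(unique(bat$tests$test), c("paired_t", "mann_whitney"))
  expect_true(all(bat$tests$p_value >= 0 & bat$tests$p_value <= 1,
                  na.rm = TRUE))
  expect_equal(nrow(bat$roc), 14 * 3 * 2)
  # rate contrasts between EH and NEH are the strongest in the design
  rate_p <- bat$tests$p_value[bat$tests$feature == "fr_rate" &
                                bat$tests$comparison == "eh_vs_neh" &
                                bat$tests$level == "channel"]
  expect_true(any(rate_p < 0.05))
  p <- autoplot(bat)
  expect_s3_class(p, "ggplot")
})
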