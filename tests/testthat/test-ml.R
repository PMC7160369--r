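test_that("robust scaling centers on Q1 and divides by the IQR", {
  m <- tibble::tibble(x = c(1, 2, 3, 4, 5))
  scaled <- robust_scale(m)
  expect_equal(scaled$x, c(-0.5, 0, 0.5, 1.0, 1.5))

  # values at Q1 map to 0 and at Q3 to 1, on random columns
  set.seed(23)
  for (trial in 1:10) {
    x <- rnorm(sample(8:30, 1))
    q <- unname(quantile(x, c(0.25, 0.75)))
    fitted <- robust_scale(tibble::tibble(x = x))
    probes <- robust_scale(tibble::tibble(x = q),
                           scaler = attr(fitted, "vf_scaler"))
    expect_equal(probes$x, c(0, 1))
  }

  expect_warning(robust_scale(tibble::tibble(x = rep(2, 5))), "constant")
  expect_equal(suppressWarnings(robust_scale(tibble::tibble(x = rep(2, 5)))$x),
               rep(0, 5))
})

test_that("refitted robust scaling is idempotent on the training rows", {
  set.seed(29)
  m <- tibble::tibble(a = rnorm(20), b = rexp(20), c = runif(20, -5, 5))
  once <- robust_scale(m)
  twice <- robust_scale(once)
  expect_equal(as.data.frame(twice)[c("a", "b", "c")],
               as.data.frame(once)[c("a", "b", "c")])
})

test_that("a stored scaler reproduces the training transform on new rows", {
  train <- tibble::tibble(x = c(1, 2, 3, 4, 5))
  fitted <- robust_scale(train)
  test <- robust_scale(tibble::tibble(x = c(2, 4, 6)),
                       scaler = attr(fitted, "vf_scaler"))
  expect_equal(test$x, c(0, 1, 2))
})

test_that("median scaling centers the median at zero", {
  m <- tibble::tibble(x = c(1, 2, 3, 4, 5))
  expect_equal(robust_scale(m, center = "median")$x,
               c(-1, -0.5, 0, 0.5, 1))
})

test_that("AUC equals brute-force concordant-pair counting", {
  auc_oracle <- function(scores, labels, positive = "MCI") {
    pos <- scores[labels == positive]
    neg <- scores[labels != positive]
    total <- 0
    for (p in pos) for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
    total / (length(pos) * length(neg))
  }
  expect_equal(auc_roc(c(3, 2, 1), c("MCI", "MCI", "CI")), 1.0)
  expect_equal(auc_roc(c(0.9, 0.8, 0.3), c("MCI", "CI", "MCI")), 0.5)
  set.seed(31)
  for (trial in 1:40) {
    n <- sample(4:8, 1)
    labels <- c("MCI", "CI", sample(c("MCI", "CI"), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # many ties
    expect_equal(auc_roc(scores, labels), auc_oracle(scores, labels))
  }
  expect_error(auc_roc(c(1, 2), c("MCI", "MCI")),
               class = "vfforage_undefined_metric")
})

test_that("label-independent scores give chance-level AUC at large n", {
  set.seed(37)
  labels <- rep(c("MCI", "CI"), c(2000, 3000))
  expect_equal(auc_roc(runif(5000), labels), 0.5, tolerance = 0.03)
})

test_that("sensitivity and specificity follow the confusion table", {
  expect_equal(
    sensitivity_specificity(c("MCI", "CI"), c("MCI", "CI")),
    tibble::tibble(sensitivity = 1, specificity = 1)
  )
  all_mci <- sensitivity_specificity(rep("MCI", 4),
                                     c("MCI", "MCI", "CI", "CI"))
  expect_equal(all_mci$sensitivity, 1)
  expect_equal(all_mci$specificity, 0)
  # TP = 3, FN = 1, TN = 4, FP = 2
  truth <- rep(c("MCI", "CI"), c(4, 6))
  pred <- c("MCI", "MCI", "MCI", "CI", "MCI", "MCI", "CI", "CI", "CI", "CI")
  ss <- sensitivity_specificity(pred, truth)
  expect_equal(ss$sensitivity, 0.75)
  expect_equal(ss$specificity, 2 / 3, tolerance = 1e-12)
})

test_that("linear SVMs separate linearly separable data under both penalties", {
  set.seed(41)
  x <- rbind(matrix(rnorm(40, -2), ncol = 2), matrix(rnorm(40, 2), ncol = 2))
  colnames(x) <- c("f1", "f2")
  y <- factor(rep(c("CI", "MCI"), each = 20), levels = c("CI", "MCI"))
  for (penalty in c("L2", "L1")) {
    model <- fit_linear_svm(x, y, C = 1, penalty = penalty, positive = "MCI")
    scores <- predict(model, x)
    expect_equal(auc_roc(scores, as.character(y)), 1.0)
    expect_true(all(predict(model, x, type = "class") == as.character(y)))
    # scores oriented toward the positive class
    expect_gt(mean(scores[y == "MCI"]), mean(scores[y == "CI"]))
  }
})

test_that("the L1 penalty produces sparser coefficients than L2", {
  set.seed(43)
  n <- 60
  x <- cbind(signal = c(rnorm(n / 2, -1.5), rnorm(n / 2, 1.5)),
             matrix(rnorm(n * 6), ncol = 6,
                    dimnames = list(NULL, paste0("noise", 1:6))))
  y <- factor(rep(c("CI", "MCI"), each = n / 2), levels = c("CI", "MCI"))
  m_l1 <- fit_linear_svm(x, y, C = 0.5, penalty = "L1", positive = "MCI")
  expect_gt(sum(abs(m_l1$w) < 1e-6), 0)
  expect_equal(names(which.max(abs(m_l1$w))), "signal")
})

test_that("RFECV keeps informative features and drops pure noise", {
  make_data <- function(seed) {
    set.seed(seed)
    n <- 60
    y <- factor(rep(c("CI", "MCI"), each = n / 2), levels = c("CI", "MCI"))
    shift <- ifelse(y == "MCI", 1.8, 0)
    x <- cbind(inf1 = rnorm(n) + shift, inf2 = rnorm(n) + shift,
               matrix(rnorm(n * 8), ncol = 8,
                      dimnames = list(NULL, paste0("noise", 1:8))))
    list(x = x, y = y)
  }
  cfg <- classifier_config(C = 1, penalty = "L2", inner_cv_folds = 3)
  hits <- vapply(1:5, function(s) {
    d <- make_data(100 + s)
    sel <- rfecv_select(d$x, cfg = cfg, seed = s, y = d$y)
    all(c("inf1", "inf2") %in% sel)
  }, TRUE)
  expect_gte(sum(hits), 4L)

  # single feature in -> that feature out
  d <- make_data(1)
  expect_equal(rfecv_select(d$x[, "inf1", drop = FALSE], cfg = cfg,
                            seed = 1, y = d$y), "inf1")
})

test_that("LOPO folds are balanced pairs with balanced training sets", {
  labels <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:20),
    label = rep(c("MCI", "CI"), c(8, 12))
  )
  splits <- lopo_splits(labels, n_repeats = 3, seed = 5)
  per_fold <- dplyr::summarise(
    dplyr::group_by(splits, .data$repeat_id, .data$fold),
    n_test_mci = sum(role == "test" & label == "MCI"),
    n_test_ci = sum(role == "test" & label == "CI"),
    n_train_mci = sum(role == "train" & label == "MCI"),
    n_train_ci = sum(role == "train" & label == "CI"),
    leak = length(intersect(subject_id[role == "test"],
                            subject_id[role == "train"]))
  )
  expect_equal(nrow(per_fold), 3 * 8)
  expect_true(all(per_fold$n_test_mci == 1))
  expect_true(all(per_fold$n_test_ci == 1))
  expect_true(all(per_fold$n_train_mci == 7))
  expect_true(all(per_fold$n_train_ci == 7))
  expect_true(all(per_fold$leak == 0))
  # every minority subject appears as test exactly once per repeat
  tests <- splits[splits$role == "test" & splits$label == "MCI", ]
  expect_equal(sort(table(tests$repeat_id, tests$subject_id)[1, ]),
               sort(rep(1L, 8)), ignore_attr = TRUE)
})

test_that("lopo_cv is reproducible and separates a strongly shifted cohort", {
  set.seed(47)
  n <- 30
  feats <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:n),
    osr_mean = c(rnorm(12, 2.5, 0.5), rnorm(18, 1.0, 0.5)),
    af_score = c(rnorm(12, 12, 2), rnorm(18, 18, 2)),
    noise = rnorm(n),
    label = rep(c("MCI", "CI"), c(12, 18))
  )
  cfg <- classifier_config(C = 10, penalty = "L2")
  cv1 <- lopo_cv(feats, cfg = cfg, n_repeats = 10, seed = 7)
  cv2 <- lopo_cv(feats, cfg = cfg, n_repeats = 10, seed = 7)
  expect_identical(tidy(cv1), tidy(cv2))
  expect_gt(cv1$auc, 80)
  g <- glance(cv1)
  expect_equal(g$n_repeats, 10)
  expect_true(all(c(g$auc, g$sensitivity, g$specificity) >= 0 &
                    c(g$auc, g$sensitivity, g$specificity) <= 100))
  expect_error(lopo_cv(feats, n_repeats = 0), class = "vfforage_validation")
})

test_that("missing feature cells are imputed from the training fold", {
  set.seed(53)
  n <- 24
  feats <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:n),
    good = c(rnorm(10, 3), rnorm(14, 0)),
    holey = replace(rnorm(n), sample(n, 8), NA),
    label = rep(c("MCI", "CI"), c(10, 14))
  )
  cv <- lopo_cv(feats, cfg = classifier_config(C = 1, penalty = "L2"),
                n_repeats = 5, seed = 3)
  expect_true(is.finite(cv$auc))
  expect_gt(cv$auc, 70)
})
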