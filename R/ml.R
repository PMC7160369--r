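#' Classifier configuration
#'
#' Settings for the linear SVM and its evaluation. The defaults mirror the
#' best-performing published configuration for the combined count + time
#' feature set (`C = 10`, L1 penalty); `tune = TRUE` instead selects `C` and
#' the penalty by inner stratified cross-validated AUC over the grid.
#'
#' @param C Margin softness of the SVM (> 0).
#' @param penalty `"L1"` or `"L2"` coefficient penalty.
#' @param C_grid,penalties Candidate values for tuning.
#' @param inner_cv_folds Folds of the inner stratified CV used for tuning and
#'   feature selection.
#' @param tune Select `C`/penalty by inner CV before cross-validation.
#' @param scaler_center `"q1"` (feature scaling centers on the 25th
#'   percentile, as published) or `"median"` (the conventional robust scaler).
#' @return A list of class `vf_classifier_config`.
#' @export
classifier_config <- function(C = 10, penalty = c("L1", "L2"),
                              C_grid = c(1e-10, 0.1, 1, 10),
                              penalties = c("L1", "L2"),
                              inner_cv_folds = 5L, tune = FALSE,
                              scaler_center = c("q1", "median")) {
  penalty <- match.arg(penalty)
  scaler_center <- match.arg(scaler_center)
  if (C <= 0) stop_vf("C must be positive", class = "validation")
  if (length(C_grid) == 0L) stop_vf("C_grid must be non-empty", class = "validation")
  structure(list(C = C, penalty = penalty, C_grid = C_grid,
                 penalties = penalties, inner_cv_folds = as.integer(inner_cv_folds),
                 tune = tune, scaler_center = scaler_center),
            class = "vf_classifier_config")
}

# ---- robust quantile scaling -------------------------------------------------

scaler_fit <- function(X, center = "q1") {
  q1 <- apply(X, 2L, stats::quantile, probs = 0.25, na.rm = TRUE, names = FALSE)
  q3 <- apply(X, 2L, stats::quantile, probs = 0.75, na.rm = TRUE, names = FALSE)
  ctr <- if (center == "median") {
    apply(X, 2L, stats::median, na.rm = TRUE)
  } else q1
  iqr <- q3 - q1
  constant <- iqr == 0
  iqr[constant] <- 1
  list(center = ctr, iqr = iqr, constant = constant)
}

scaler_apply <- function(scaler, X) {
  sweep(sweep(X, 2L, scaler$center, "-"), 2L, scaler$iqr, "/")
}

#' Robust quantile scaling of a feature table
#'
#' Centers each feature on its 25th percentile and divides by the
#' interquartile range, `f(x) = (x - Q1) / (Q3 - Q1)`, so a value at Q1 maps
#' to 0 and a value at Q3 to 1. Quantiles use linear interpolation between
#' order statistics. When scaling held-out rows, pass the scaler fitted on the
#' training rows. Constant features (zero IQR) are flagged with a warning and
#' scaled to 0.
#'
#' @param features A per-subject feature tibble; non-numeric and label columns
#'   pass through untouched.
#' @param scaler A scaler from a previous call's `"vf_scaler"` attribute
#'   (default: fit on `features` itself).
#' @param center `"q1"` (as published) or `"median"`.
#' @return The scaled tibble, with the fitted scaler in attribute
#'   `"vf_scaler"`.
#' @export
robust_scale <- function(features, scaler = NULL, center = c("q1", "median")) {
  center <- match.arg(center)
  num_cols <- names(features)[vapply(features, is.numeric, TRUE)]
  X <- as.matrix(features[num_cols])
  if (is.null(scaler)) {
    scaler <- scaler_fit(X, center)
    names(scaler$center) <- num_cols
    if (any(scaler$constant)) {
      warning("constant feature(s) scaled to 0: ",
              paste(num_cols[scaler$constant], collapse = ", "), call. = FALSE)
    }
  }
  scaled <- scaler_apply(scaler, X)
  out <- features
  out[num_cols] <- as.data.frame(scaled)
  attr(out, "vf_scaler") <- scaler
  out
}

# ---- metrics -----------------------------------------------------------------

#' Area under the ROC curve
#'
#' The ROC is traced by sweeping the decision threshold from "everything
#' positive" to "everything negative"; the area equals the fraction of
#' (positive, negative) pairs ranked concordantly, ties counted one half.
#'
#' @param scores Numeric decision scores (higher = more positive-like).
#' @param labels Vector of class labels containing both classes.
#' @param positive The positive-class label (default `"MCI"`).
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels, positive = "MCI") {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2L || !positive %in% classes) {
    stop_vf("labels must contain the positive class and exactly one other ",
            "class", class = "undefined_metric")
  }
  negative <- setdiff(classes, positive)
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(negative, positive), direction = "<",
                 quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Sensitivity and specificity
#'
#' Sensitivity is the fraction of positive-class (MCI) subjects correctly
#' identified; specificity the fraction of negative-class (intact) subjects
#' correctly identified.
#'
#' @param predicted Predicted class labels.
#' @param labels True class labels (both classes present).
#' @param positive The positive-class label (default `"MCI"`).
#' @return A one-row tibble with `sensitivity` and `specificity` in `[0, 1]`.
#' @export
sensitivity_specificity <- function(predicted, labels, positive = "MCI") {
  predicted <- as.character(predicted)
  labels <- as.character(labels)
  pos <- labels == positive
  if (!any(pos) || all(pos)) {
    stop_vf("labels must contain both classes", class = "undefined_metric")
  }
  tibble::tibble(
    sensitivity = mean(predicted[pos] == positive),
    specificity = mean(predicted[!pos] != positive)
  )
}

# ---- linear SVM --------------------------------------------------------------

#' Fit a linear support vector machine
#'
#' A maximum-margin linear classifier with hinge loss. The L2-penalized form
#' is fitted with \pkg{e1071} (libsvm); the L1-penalized form minimizes
#' `||w||_1 + C * sum(max(0, 1 - y f(x))^2)` (squared hinge) by proximal
#' gradient, yielding the sparse coefficients that drive feature elimination.
#' Decision scores are oriented so that positive values favour the positive
#' class.
#'
#' @param x Numeric feature matrix (rows = subjects), no missing values.
#' @param y Factor of two class labels.
#' @param C Margin softness (> 0).
#' @param penalty `"L2"` or `"L1"`.
#' @param positive Positive-class label (default: last factor level).
#' @return An object of class `vf_svm` with elements `w`, `b`, `positive`,
#'   `negative`. `predict()` returns decision scores (`type = "score"`) or
#'   labels (`type = "class"`).
#' @export
fit_linear_svm <- function(x, y, C = 1, penalty = c("L2", "L1"),
                           positive = NULL) {
  penalty <- match.arg(penalty)
  y <- factor(y)
  if (nlevels(y) != 2L) {
    stop_vf("y must have exactly 2 classes", class = "degenerate_labels")
  }
  positive <- positive %||% levels(y)[2L]
  negative <- setdiff(levels(y), positive)
  x <- as.matrix(x)

  if (penalty == "L2") {
    model <- e1071::svm(x, y, kernel = "linear", cost = C, scale = FALSE)
    w <- drop(crossprod(model$coefs, model$SV))
    b <- -model$rho
    # libsvm orients the decision value toward whichever class it saw first
    dv <- attr(stats::predict(model, x[1L, , drop = FALSE],
                              decision.values = TRUE), "decision.values")
    dv_pos <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
    if (dv_pos != positive) {
      w <- -w
      b <- -b
    }
  } else {
    yy <- ifelse(as.character(y) == positive, 1, -1)
    fit <- l1_squared_hinge(x, yy, C)
    w <- fit$w
    b <- fit$b
  }
  names(w) <- colnames(x)
  structure(list(w = w, b = b, positive = positive, negative = negative,
                 C = C, penalty = penalty),
            class = "vf_svm")
}

#' @rdname fit_linear_svm
#' @param object A `vf_svm` model.
#' @param newdata Numeric matrix of rows to score.
#' @param type `"score"` or `"class"`.
#' @param ... Unused.
#' @export
predict.vf_svm <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  scores <- drop(as.matrix(newdata) %*% object$w) + object$b
  if (type == "score") return(scores)
  ifelse(scores > 0, object$positive, object$negative)
}

# proximal-gradient (FISTA) solver for ||w||_1 + C * sum squared hinge;
# intercept unpenalized
l1_squared_hinge <- function(X, y, C, max_iter = 300L, tol = 1e-7) {
  n <- nrow(X); p <- ncol(X)
  Xa <- cbind(X, 1)
  L <- 2 * C * norm(Xa, "2")^2
  step <- 1 / max(L, .Machine$double.eps)
  w <- numeric(p); b <- 0
  zw <- w; zb <- b; tmom <- 1
  soft <- function(u, thr) sign(u) * pmax(abs(u) - thr, 0)
  for (it in seq_len(max_iter)) {
    f <- drop(X %*% zw) + zb
    xi <- pmax(0, 1 - y * f)
    gw <- -2 * C * drop(crossprod(X, y * xi))
    gb <- -2 * C * sum(y * xi)
    w_new <- soft(zw - step * gw, step)
    b_new <- zb - step * gb
    t_new <- (1 + sqrt(1 + 4 * tmom^2)) / 2
    zw <- w_new + ((tmom - 1) / t_new) * (w_new - w)
    zb <- b_new + ((tmom - 1) / t_new) * (b_new - b)
    delta <- max(abs(c(w_new - w, b_new - b)))
    w <- w_new; b <- b_new; tmom <- t_new
    if (delta < tol) break
  }
  list(w = w, b = b)
}

# ---- inner CV helpers --------------------------------------------------------

stratified_folds <- function(y, k) {
  y <- as.character(y)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# mean per-fold AUC of a C/penalty setting under stratified k-fold CV
inner_cv_auc <- function(X, y, C, penalty, k, positive) {
  k <- min(k, min(table(y)))
  if (k < 2L) stop_vf("too few subjects per class for inner CV", class = "validation")
  fold <- stratified_folds(y, k)
  aucs <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    model <- fit_linear_svm(X[tr, , drop = FALSE], y[tr], C = C,
                            penalty = penalty, positive = positive)
    auc_roc(predict(model, X[!tr, , drop = FALSE]), y[!tr], positive)
  }, 0)
  mean(aucs)
}

tune_classifier <- function(X, y, cfg, positive) {
  grid <- expand.grid(C = cfg$C_grid, penalty = cfg$penalties,
                      stringsAsFactors = FALSE)
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    inner_cv_auc(X, y, grid$C[i], grid$penalty[i], cfg$inner_cv_folds, positive)
  }, 0)
  best <- which.max(scores)
  list(C = grid$C[best], penalty = grid$penalty[best])
}

# ---- recursive feature elimination -------------------------------------------

#' Recursive feature elimination with cross-validation
#'
#' Iteratively drops the feature with the smallest absolute SVM coefficient,
#' scoring every visited subset by mean inner stratified k-fold AUC, and
#' returns the subset with the best score (ties go to the smaller subset).
#' Features are median-imputed and robust-scaled once before elimination.
#'
#' @param features A feature tibble with a label column, or a numeric matrix
#'   (then supply `y`).
#' @param cfg A [classifier_config()].
#' @param seed Integer seed for the inner fold shuffling.
#' @param y Class factor when `features` is a matrix.
#' @param label_col,id_col Column names used when `features` is a tibble.
#' @param positive Positive-class label.
#' @return Character vector of selected feature names.
#' @export
rfecv_select <- function(features, cfg = classifier_config(), seed = 1L,
                         y = NULL, label_col = "label", id_col = "subject_id",
                         positive = "MCI") {
  if (is.matrix(features)) {
    X <- features
  } else {
    y <- factor(features[[label_col]])
    X <- feature_matrix(features, label_col, id_col)
  }
  if (is.null(y)) stop_vf("y is required with a matrix input", class = "bad_input")
  y <- factor(y)
  if (nlevels(y) != 2L) {
    stop_vf("labels must have exactly 2 classes", class = "degenerate_labels")
  }
  if (ncol(X) < 2L) return(colnames(X))
  withr::with_seed(seed, {
    Xi <- impute_fit_apply(X)$X
    Xs <- scaler_apply(scaler_fit(Xi, cfg$scaler_center), Xi)
    rfe_core(Xs, y, cfg, positive)
  })
}

rfe_core <- function(X, y, cfg, positive) {
  current <- colnames(X)
  best_set <- current
  best_score <- -Inf
  repeat {
    score <- inner_cv_auc(X[, current, drop = FALSE], y, cfg$C, cfg$penalty,
                          cfg$inner_cv_folds, positive)
    if (score >= best_score) {
      best_score <- score
      best_set <- current
    }
    if (length(current) == 1L) break
    model <- fit_linear_svm(X[, current, drop = FALSE], y, C = cfg$C,
                            penalty = cfg$penalty, positive = positive)
    drop_feat <- current[which.min(abs(model$w))]
    current <- setdiff(current, drop_feat)
  }
  best_set
}

# ---- leave-one-pair-out cross-validation -------------------------------------

feature_matrix <- function(features, label_col, id_col) {
  num_cols <- setdiff(names(features)[vapply(features, is.numeric, TRUE)],
                      c(label_col, id_col))
  X <- as.matrix(features[num_cols])
  rownames(X) <- if (id_col %in% names(features)) {
    as.character(features[[id_col]])
  } else as.character(seq_len(nrow(features)))
  all_na <- colSums(!is.na(X)) == 0L
  if (any(all_na)) {
    warning("dropping all-missing feature(s): ",
            paste(num_cols[all_na], collapse = ", "), call. = FALSE)
    X <- X[, !all_na, drop = FALSE]
  }
  X
}

# training-median imputation; medians reused for held-out rows
impute_fit_apply <- function(X, medians = NULL) {
  if (is.null(medians)) {
    medians <- apply(X, 2L, stats::median, na.rm = TRUE)
    medians[is.na(medians)] <- 0
  }
  na_idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(na_idx) > 0L) X[na_idx] <- medians[na_idx[, 2L]]
  list(X = X, medians = medians)
}

# one repeat's pairing plan: shuffled minority members, each assigned a
# distinct majority partner
repeat_plan <- function(small_idx, big_idx) {
  list(small = sample(small_idx),
       partner = sample(big_idx, length(small_idx)))
}

#' Leave-one-pair-out fold structure
#'
#' Materializes the balanced leave-one-pair-out design: per repeat, every
#' minority-class subject is paired with a distinct majority-class subject;
#' each pair in turn is the test fold, and the training fold holds the
#' remaining minority subjects plus an equally sized random subsample of the
#' remaining majority subjects (e.g. with 28 MCI / 42 CI, every training fold
#' has 27 + 27 subjects).
#'
#' @param labels A tibble with columns `subject_id` and `label`.
#' @param n_repeats Number of shuffled repeats.
#' @param seed Integer seed.
#' @return A tibble with columns `repeat_id`, `fold`, `subject_id`, `label`,
#'   `role` (`"test"` / `"train"`).
#' @export
lopo_splits <- function(labels, n_repeats = 1L, seed = 1L) {
  assert_cols(labels, c("subject_id", "label"), "label table")
  lab <- as.character(labels$label)
  counts <- table(lab)
  if (length(counts) != 2L) {
    stop_vf("labels must have exactly 2 classes", class = "validation")
  }
  small_cls <- names(counts)[which.min(counts)]
  small_idx <- which(lab == small_cls)
  big_idx <- which(lab != small_cls)
  withr::with_seed(seed, {
    out <- vector("list", n_repeats)
    for (r in seq_len(n_repeats)) {
      plan <- repeat_plan(small_idx, big_idx)
      folds <- lapply(seq_along(plan$small), function(k) {
        test <- c(plan$small[k], plan$partner[k])
        small_train <- setdiff(plan$small, plan$small[k])
        big_pool <- setdiff(big_idx, plan$partner[k])
        big_train <- sample(big_pool, length(small_train))
        tibble::tibble(
          fold = k,
          subject_id = labels$subject_id[c(test, small_train, big_train)],
          label = lab[c(test, small_train, big_train)],
          role = rep(c("test", "train"),
                     c(2L, length(small_train) + length(big_train)))
        )
      })
      out[[r]] <- dplyr::mutate(dplyr::bind_rows(folds), repeat_id = r,
                                .before = 1L)
    }
  })
  dplyr::bind_rows(out)
}

#' Balanced leave-one-pair-out cross-validation
#'
#' Evaluates a classifier on an imbalanced two-group cohort with the
#' leave-one-pair-out (LOPO) scheme: each test fold holds one subject of each
#' class, and every training fold is subsampled to class balance
#' (minority-count subjects per class). Within each training fold, features
#' are median-imputed and robust-scaled with statistics fitted on that fold
#' only, a linear SVM is trained, and the held-out pair is scored. Fold
#' scores are pooled into per-repeat AUC / sensitivity / specificity, and the
#' report averages over `n_repeats` shuffled repeats.
#'
#' @param features A per-subject feature tibble with `subject_id` and a
#'   two-level label column.
#' @param cfg A [classifier_config()].
#' @param n_repeats Number of shuffled repeats (500 for a publication-grade
#'   run; fewer for exploration).
#' @param seed Integer seed; the whole procedure is reproducible given it.
#' @param classifier `"svm"`, or `"chance"` for the label-independent
#'   random-score baseline.
#' @param rfe Feature selection: `"none"` (default), `"per_repeat"`
#'   (recursive elimination on the full pool once per repeat), or
#'   `"per_fold"` (strictly nested, slow).
#' @param select_features Optional character vector restricting the feature
#'   columns used.
#' @param label_col,id_col,positive Column names and positive-class label.
#' @return An object of class `vf_lopo`; see [tidy()][generics::tidy] /
#'   [glance()][generics::glance] / [autoplot()][ggplot2::autoplot] methods.
#'   Metrics are percentages.
#' @export
lopo_cv <- function(features, cfg = classifier_config(), n_repeats = 500L,
                    seed = 1L, classifier = c("svm", "chance"),
                    rfe = c("none", "per_repeat", "per_fold"),
                    select_features = NULL, label_col = "label",
                    id_col = "subject_id", positive = "MCI") {
  classifier <- match.arg(classifier)
  rfe <- match.arg(rfe)
  if (n_repeats < 1L) stop_vf("n_repeats must be >= 1", class = "validation")
  assert_cols(features, c(label_col), "feature table")
  lab <- as.character(features[[label_col]])
  counts <- table(lab)
  if (length(counts) != 2L || any(counts < 2L)) {
    stop_vf("need two classes with >= 2 subjects each", class = "validation")
  }
  if (!positive %in% names(counts)) {
    stop_vf("positive class '", positive, "' not found in labels",
            class = "validation")
  }
  X <- feature_matrix(features, label_col, id_col)
  if (!is.null(select_features)) {
    X <- X[, intersect(select_features, colnames(X)), drop = FALSE]
  }
  small_cls <- names(counts)[which.min(counts)]
  small_idx <- which(lab == small_cls)
  big_idx <- which(lab != small_cls)

  metrics <- matrix(NA_real_, n_repeats, 3L,
                    dimnames = list(NULL, c("auc", "sensitivity", "specificity")))
  sel_count <- stats::setNames(numeric(ncol(X)), colnames(X))

  withr::with_seed(seed, {
    if (cfg$tune && classifier == "svm") {
      imp <- impute_fit_apply(X)
      Xs <- scaler_apply(scaler_fit(imp$X, cfg$scaler_center), imp$X)
      tuned <- tune_classifier(Xs, factor(lab), cfg, positive)
      cfg$C <- tuned$C
      cfg$penalty <- tuned$penalty
    }
    for (r in seq_len(n_repeats)) {
      plan <- repeat_plan(small_idx, big_idx)
      feats_r <- colnames(X)
      if (classifier == "svm" && rfe == "per_repeat") {
        imp <- impute_fit_apply(X)
        Xs <- scaler_apply(scaler_fit(imp$X, cfg$scaler_center), imp$X)
        feats_r <- rfe_core(Xs, factor(lab), cfg, positive)
        sel_count[feats_r] <- sel_count[feats_r] + 1
      }
      n_fold <- length(plan$small)
      scores <- numeric(2L * n_fold)
      preds <- character(2L * n_fold)
      truth <- character(2L * n_fold)
      for (k in seq_len(n_fold)) {
        test <- c(plan$small[k], plan$partner[k])
        small_train <- setdiff(plan$small, plan$small[k])
        big_train <- sample(setdiff(big_idx, plan$partner[k]),
                            length(small_train))
        train <- c(small_train, big_train)
        stopifnot(length(small_train) == length(big_train),
                  length(intersect(train, test)) == 0L)
        slot <- (2L * k - 1L):(2L * k)
        truth[slot] <- lab[test]
        if (classifier == "chance") {
          scores[slot] <- stats::runif(2L)
          preds[slot] <- ifelse(scores[slot] > 0.5, positive,
                                setdiff(names(counts), positive))
          next
        }
        feats_f <- feats_r
        Xtr <- X[train, feats_f, drop = FALSE]
        Xte <- X[test, feats_f, drop = FALSE]
        imp <- impute_fit_apply(Xtr)
        Xtr <- imp$X
        Xte <- impute_fit_apply(Xte, imp$medians)$X
        if (rfe == "per_fold") {
          sc0 <- scaler_fit(Xtr, cfg$scaler_center)
          feats_f <- rfe_core(scaler_apply(sc0, Xtr), factor(lab[train]),
                              cfg, positive)
          sel_count[feats_f] <- sel_count[feats_f] + 1
          Xtr <- Xtr[, feats_f, drop = FALSE]
          Xte <- Xte[, feats_f, drop = FALSE]
        }
        sc <- scaler_fit(Xtr, cfg$scaler_center)
        model <- fit_linear_svm(scaler_apply(sc, Xtr), factor(lab[train]),
                                C = cfg$C, penalty = cfg$penalty,
                                positive = positive)
        s <- predict(model, scaler_apply(sc, Xte))
        scores[slot] <- s
        preds[slot] <- ifelse(s > 0, positive, setdiff(names(counts), positive))
      }
      ss <- sensitivity_specificity(preds, truth, positive)
      metrics[r, ] <- c(100 * auc_roc(scores, truth, positive),
                        100 * ss$sensitivity, 100 * ss$specificity)
    }
  })

  per_repeat <- tibble::as_tibble(metrics)
  per_repeat$repeat_id <- seq_len(n_repeats)
  structure(
    list(
      metrics = dplyr::relocate(per_repeat, "repeat_id"),
      auc = mean(per_repeat$auc),
      sensitivity = mean(per_repeat$sensitivity),
      specificity = mean(per_repeat$specificity),
      selected_features = if (rfe == "none") colnames(X) else
        names(sel_count)[sel_count > 0],
      selection_count = if (rfe == "none") NULL else
        sort(sel_count, decreasing = TRUE),
      cfg = cfg, n_repeats = n_repeats, seed = seed,
      classifier = classifier, rfe = rfe,
      n_small = length(small_idx), n_big = length(big_idx),
      positive = positive
    ),
    class = "vf_lopo"
  )
}

#' @export
print.vf_lopo <- function(x, ...) {
  cat("<vf_lopo> balanced leave-one-pair-out cross-validation\n")
  cat(sprintf("  cohort: %d / %d subjects; %d repeats (seed %d); classifier: %s\n",
              x$n_small, x$n_big, x$n_repeats, x$seed, x$classifier))
  cat(sprintf("  AUC %.2f%%  sensitivity %.2f%%  specificity %.2f%%\n",
              x$auc, x$sensitivity, x$specificity))
  invisible(x)
}
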