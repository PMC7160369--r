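#' Two-sample Kolmogorov-Smirnov test
#'
#' The screening statistic used to compare a feature's distribution between
#' the MCI and intact groups: the supremum distance between the two empirical
#' CDFs, with a two-sided asymptotic p-value (the cohort sizes put the test in
#' the asymptotic regime). Missing values are dropped per sample.
#'
#' @param x,y Numeric samples (each with >= 2 present values).
#' @return A one-row tibble with `statistic` and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop_vf("both samples need at least 2 present values (got ",
            length(x), " and ", length(y), ")", class = "validation")
  }
  fit <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  tibble::tibble(statistic = unname(fit$statistic),
                 p_value = unname(fit$p.value))
}

#' Screen all features with KS tests between groups
#'
#' Runs [ks_two_sample()] on every numeric feature column, split by the label
#' column, producing the familiar feature / statistic / p-value screening
#' table. Features with fewer than two present values in either group are
#' skipped with a warning.
#'
#' @param features A per-subject feature tibble with a two-level label column
#'   (e.g. from [extract_features()]).
#' @param label_col Name of the label column (default `"label"`).
#' @return A tibble of class `vf_ks_screen` with columns `feature`,
#'   `statistic`, `p_value`, ordered by p-value.
#' @export
ks_screen <- function(features, label_col = "label") {
  assert_cols(features, label_col, "feature table")
  groups <- unique(stats::na.omit(features[[label_col]]))
  if (length(groups) != 2L) {
    stop_vf("label column must have exactly 2 groups (got ",
            length(groups), ")", class = "validation")
  }
  num_cols <- names(features)[vapply(features, is.numeric, TRUE)]
  rows <- lapply(num_cols, function(col) {
    x <- features[[col]][features[[label_col]] == groups[1]]
    y <- features[[col]][features[[label_col]] == groups[2]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) {
      warning("feature '", col, "' skipped: fewer than 2 present values in a group",
              call. = FALSE)
      return(NULL)
    }
    dplyr::mutate(ks_two_sample(x, y), feature = col, .before = 1L)
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$p_value)
  class(out) <- c("vf_ks_screen", class(out))
  out
}
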