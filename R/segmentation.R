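#' Segment a name sequence into semantic clusters and switches
#'
#' A greedy left-to-right scan: token i stays in the current cluster when the
#' same-cluster predicate holds for the adjacent pair (i-1, i); otherwise a
#' switch is recorded at i and a new cluster opens. Under `method = "esa"` the
#' predicate compares the pair's embedding cosine similarity to a threshold
#' (fixed, or subject-adaptive on the min-max normalized scale); under
#' `method = "troyer"` it asks whether the pair shares a subcategory.
#'
#' @param seq A per-subject sequence tibble with columns `subject_id`, `name`
#'   (and typically `onset`), e.g. from [trim_and_renormalize()].
#' @param method `"esa"` or `"troyer"`.
#' @param embeddings Embedding matrix (required for `"esa"`).
#' @param table A [as_category_table()] (required for `"troyer"`).
#' @param threshold A [threshold_config()] (ESA mode only).
#' @param sims Optional precomputed [adjacent_similarities()] tibble for this
#'   subject; computed when missing.
#' @return The sequence tibble with columns `cluster` (1-based id) and
#'   `is_switch` (TRUE where a token opens a new, non-initial cluster),
#'   plus attributes `method` and `threshold_used`. If all adjacent
#'   similarities are identical in adaptive mode, the response degenerates to
#'   a single cluster with a warning.
#' @examples
#' fx <- make_worked_example()
#' seg <- segment_sequence(fx$sequence, method = "esa",
#'                         embeddings = fx$embeddings,
#'                         threshold = threshold_config("fixed", 0.05))
#' cluster_sizes(seg)
#' @export
segment_sequence <- function(seq, method = c("esa", "troyer"),
                             embeddings = NULL, table = NULL,
                             threshold = threshold_config(), sims = NULL) {
  method <- match.arg(method)
  assert_cols(seq, c("subject_id", "name"), "sequence")
  n <- nrow(seq)
  if (n == 0L) stop_vf("cannot segment an empty sequence", class = "validation")
  if (length(unique(seq$subject_id)) > 1L) {
    stop_vf("segment_sequence() takes one subject at a time", class = "bad_input")
  }

  if (n == 1L) {
    links <- logical(0)
    thr_used <- NA_real_
  } else if (method == "esa") {
    if (is.null(sims)) {
      if (is.null(embeddings)) {
        stop_vf("ESA segmentation needs embeddings (or precomputed sims)",
                class = "bad_input")
      }
      sims <- adjacent_similarities(seq, embeddings)
    }
    s <- sims$similarity
    if (threshold$mode == "fixed") {
      thr_used <- threshold$fixed_value
      links <- same_cluster_esa(s, thr_used)
    } else {
      pool <- if (threshold$scope == "all") {
        if (is.null(embeddings)) {
          stop_vf("all-pairs adaptive scope needs embeddings", class = "bad_input")
        }
        all_pair_similarities(seq$name, embeddings)
      } else s
      degenerate <- length(pool) < 2L || max(pool) == min(pool) ||
        max(s) == min(s)
      if (degenerate) {
        warning("degenerate adaptive threshold (identical similarities); ",
                "falling back to a single cluster for subject ",
                seq$subject_id[1], call. = FALSE)
        thr_used <- NA_real_
        links <- rep(TRUE, n - 1L)
      } else {
        thr_used <- adaptive_threshold(pool, threshold$fraction)
        # compare on the same normalized scale the threshold was set on
        s_norm <- (s - min(pool)) / (max(pool) - min(pool))
        links <- same_cluster_esa(s_norm, thr_used)
      }
    }
  } else {
    if (is.null(table)) {
      stop_vf("Troyer segmentation needs a category table", class = "bad_input")
    }
    links <- vapply(seq_len(n - 1L), function(i) {
      same_cluster_troyer(seq$name[i], seq$name[i + 1L], table)
    }, TRUE)
    thr_used <- NA_real_
  }

  cluster <- cumsum(c(TRUE, !links))
  out <- dplyr::mutate(seq, cluster = cluster,
                       is_switch = c(FALSE, !links))
  attr(out, "method") <- method
  attr(out, "threshold_used") <- thr_used
  out
}

#' Cluster sizes of a segmentation
#'
#' @param seg A segmented sequence from [segment_sequence()].
#' @return Integer vector of cluster sizes in order; sums to the number of
#'   tokens.
#' @export
cluster_sizes <- function(seg) {
  assert_cols(seg, "cluster", "segmentation")
  as.integer(table(factor(seg$cluster, levels = unique(seg$cluster))))
}

#' Switch positions of a segmentation
#'
#' @param seg A segmented sequence from [segment_sequence()].
#' @return Integer vector of 1-based token positions that open a new cluster
#'   (the first token of the response is not a switch).
#' @export
switch_positions <- function(seg) {
  which(seg$is_switch)
}
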