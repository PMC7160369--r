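#' Cosine similarity of two vectors
#'
#' @param a,b Numeric vectors of the same dimension, both nonzero.
#' @return `dot(a, b) / (|a| |b|)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) {
    stop_vf("vectors differ in dimension (", length(a), " vs ", length(b), ")",
            class = "validation")
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop_vf("cosine similarity undefined for a zero vector",
            class = "undefined_similarity")
  }
  s <- sum(a * b) / (na * nb)
  min(1, max(-1, s))
}

#' Adjacent-pair semantic similarities of a response
#'
#' For a sequence of n produced names, returns the n-1 cosine similarities
#' between each word and its predecessor - the quantity the embedding-based
#' (ESA-style) segmentation thresholds.
#'
#' @param seq A tibble with columns `subject_id` and `name` in production
#'   order (e.g. from [trim_and_renormalize()]).
#' @param embeddings A word-embedding matrix (rows = words), e.g. from
#'   [read_embeddings()] or [generate_embeddings()].
#' @return A tibble with columns `subject_id`, `from`, `to`, `similarity`
#'   (one row per adjacent pair; zero rows for a single-word sequence).
#' @export
adjacent_similarities <- function(seq, embeddings) {
  assert_cols(seq, c("subject_id", "name"), "sequence")
  missing <- setdiff(unique(seq$name), rownames(embeddings))
  if (length(missing) > 0L) {
    stop_vf("no embedding for word(s): ", paste(missing, collapse = ", "),
            class = "lookup")
  }
  seq |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::reframe(
      from = utils::head(.data$name, -1L),
      to = .data$name[-1L]
    ) |>
    dplyr::mutate(similarity = vapply(seq_len(dplyr::n()), function(i) {
      cosine_similarity(embeddings[.data$from[i], ], embeddings[.data$to[i], ])
    }, 0))
}

#' Semantic threshold configuration
#'
#' @param mode `"adaptive"` (subject-specific, the default) or `"fixed"`.
#' @param fixed_value Threshold on the raw similarity scale, used in fixed
#'   mode.
#' @param fraction Adaptive mode: the threshold is `fraction` times the mean
#'   of the min-max normalized similarities (default 0.75).
#' @param scope Which similarities feed the adaptive normalization:
#'   `"adjacent"` (successive pairs only, the default) or `"all"` (all
#'   unordered word pairs of the response).
#' @return A list of class `vf_threshold_config`.
#' @export
threshold_config <- function(mode = c("adaptive", "fixed"), fixed_value = 0.05,
                             fraction = 0.75, scope = c("adjacent", "all")) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  if (mode == "adaptive" && (fraction <= 0 || fraction > 1)) {
    stop_vf("adaptive fraction must be in (0, 1]", class = "validation")
  }
  structure(list(mode = mode, fixed_value = fixed_value,
                 fraction = fraction, scope = scope),
            class = "vf_threshold_config")
}

# min-max normalization to [0, 1]; degenerate when max == min
normalize_unit <- function(x) (x - min(x)) / (max(x) - min(x))

#' Subject-adaptive semantic threshold
#'
#' Min-max normalizes the response's similarity values to `[0, 1]` and returns
#' `fraction` times their normalized mean. Segmentation then compares the
#' *normalized* similarities against this threshold, so the rule is invariant
#' to affine transforms of the raw similarity scale.
#'
#' @param values Numeric vector of similarity values (>= 2, not all equal).
#' @param fraction Fraction of the normalized mean (default 0.75).
#' @return The threshold on the normalized `[0, 1]` scale.
#' @examples
#' adaptive_threshold(c(0.077, 0.012, 0.053, 0.055, 0.007, 0.067))
#' @export
adaptive_threshold <- function(values, fraction = 0.75) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    stop_vf("adaptive threshold needs at least 2 similarity values",
            class = "degenerate_threshold")
  }
  if (max(values) == min(values)) {
    stop_vf("all similarity values identical; adaptive threshold degenerate",
            class = "degenerate_threshold")
  }
  fraction * mean(normalize_unit(values))
}

#' Same-cluster predicates
#'
#' `same_cluster_esa()` keeps a word pair in one cluster when its similarity
#' is at or above the threshold (a switch happens strictly below it).
#' `same_cluster_troyer()` keeps a pair together when their subcategory sets
#' intersect.
#'
#' @param similarity,threshold Similarity value and threshold on a common
#'   scale (raw for a fixed threshold, normalized for an adaptive one).
#' @return Logical.
#' @export
same_cluster_esa <- function(similarity, threshold) {
  similarity >= threshold
}

#' @rdname same_cluster_esa
#' @param a,b Canonical animal names, both present in `table`.
#' @param table A [as_category_table()] object.
#' @export
same_cluster_troyer <- function(a, b, table) {
  sa <- subcategories_of(a, table)
  sb <- subcategories_of(b, table)
  if (length(sa) == 0L) stop_vf("name not in category table: ", a, class = "lookup")
  if (length(sb) == 0L) stop_vf("name not in category table: ", b, class = "lookup")
  length(intersect(sa, sb)) > 0L
}

# all C(n,2) pairwise cosine similarities of a name sequence
all_pair_similarities <- function(names, embeddings) {
  n <- length(names)
  if (n < 2L) return(numeric())
  vecs <- embeddings[names, , drop = FALSE]
  norms <- sqrt(rowSums(vecs^2))
  cm <- tcrossprod(vecs / norms)
  pmin(1, pmax(-1, cm[upper.tri(cm)]))
}
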