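#' Standard animal-fluency score
#'
#' The conventional test score: the number of distinct canonical animal names
#' produced (duplicates and non-animal speech do not count).
#'
#' @param names Character vector of canonical names in production order.
#' @return Integer count.
#' @export
af_score <- function(names) {
  length(unique(names[!is.na(names)]))
}

#' Single-cluster ratio
#'
#' Fraction of clusters containing exactly one word; responses dominated by
#' singleton clusters reflect a fragmented retrieval pattern.
#'
#' @param seg A segmented sequence from [segment_sequence()].
#' @return A value in `[0, 1]`.
#' @export
single_cluster_ratio <- function(seg) {
  sizes <- cluster_sizes(seg)
  sum(sizes == 1L) / length(sizes)
}

#' Count-based feature set of a response
#'
#' Computes the count-derived block of the feature vector from a segmented
#' sequence: productivity counts (unique words, duplicates), cluster/switch
#' structure (number of switches, average cluster size, singleton-cluster
#' count and ratio), lexical-resource summaries (log word frequency, syllable
#' count, typicality; population sd), and embedding-similarity summaries
#' (mean adjacent similarity MESA, mean all-pairs similarity MAESA, and their
#' ratio).
#'
#' Tokens without an entry in a resource table are excluded from that
#' resource's mean/sd; zero or missing frequencies are excluded from the log
#' features. With fewer than two words, MESA/MAESA are missing.
#'
#' @param seg A segmented sequence from [segment_sequence()].
#' @param sims Optional [adjacent_similarities()] tibble for the subject
#'   (needed for MESA).
#' @param embeddings Optional embedding matrix (needed for MAESA).
#' @param resources Optional word-resource tibble with column `name` and any
#'   of `frequency`, `syllables`, `typicality`.
#' @return A one-row tibble of named features.
#' @export
count_feature_set <- function(seg, sims = NULL, embeddings = NULL,
                              resources = NULL) {
  assert_cols(seg, c("name", "cluster", "is_switch"), "segmentation")
  n <- nrow(seg)
  sizes <- cluster_sizes(seg)
  uniq <- af_score(seg$name)

  mesa <- NA_real_
  maesa <- NA_real_
  if (n >= 2L) {
    if (!is.null(sims)) mesa <- mean(sims$similarity)
    if (!is.null(embeddings) && all(seg$name %in% rownames(embeddings))) {
      maesa <- mean(all_pair_similarities(seg$name, embeddings))
    }
  }
  ratio <- if (!is.na(mesa) && !is.na(maesa) && maesa != 0) mesa / maesa else NA_real_

  res <- resource_block(seg$name, resources)

  dplyr::bind_cols(
    tibble::tibble(
      af_score = uniq,
      n_switches = sum(seg$is_switch),
      anwc = n / length(sizes),
      n_duplicates = n - uniq
    ),
    res,
    tibble::tibble(
      mesa = mesa,
      maesa = maesa,
      mesa_maesa_ratio = ratio,
      n_single_word_clusters = sum(sizes == 1L),
      scr = single_cluster_ratio(seg)
    )
  )
}

# per-token resource summaries; duplicates count once per production
resource_block <- function(names, resources) {
  out <- tibble::tibble(
    freq_log_mean = NA_real_, freq_log_sd = NA_real_,
    syll_mean = NA_real_, syll_sd = NA_real_,
    typ_mean = NA_real_, typ_sd = NA_real_
  )
  if (is.null(resources)) return(out)
  assert_cols(resources, "name", "word resources")
  hit <- match(names, resources$name)
  if ("frequency" %in% names(resources)) {
    f <- resources$frequency[hit]
    usable <- !is.na(f) & f > 0
    if (any(!usable)) {
      warning(sum(!usable), " token(s) without a usable frequency excluded ",
              "from log-frequency features", call. = FALSE)
    }
    lf <- log(f[usable])
    out$freq_log_mean <- agg_or_na(lf, mean)
    out$freq_log_sd <- if (length(lf)) pop_sd(lf) else NA_real_
  }
  if ("syllables" %in% names(resources)) {
    s <- resources$syllables[hit]
    out$syll_mean <- agg_or_na(s, mean)
    out$syll_sd <- if (any(!is.na(s))) pop_sd(s) else NA_real_
  }
  if ("typicality" %in% names(resources)) {
    t_ <- resources$typicality[hit]
    out$typ_mean <- agg_or_na(t_, mean)
    out$typ_sd <- if (any(!is.na(t_))) pop_sd(t_) else NA_real_
  }
  out
}

#' Load word-resource tables
#'
#' Reads and merges per-name resource TSVs: corpus `frequency`, `syllables`
#' count, and `typicality` rating. Each file needs a `name` column plus the
#' resource column.
#'
#' @param frequency,syllables,typicality Paths to the individual TSVs (any
#'   subset may be given).
#' @return A tibble with `name` and the available resource columns.
#' @export
load_word_resources <- function(frequency = NULL, syllables = NULL,
                                typicality = NULL) {
  parts <- list(frequency = frequency, syllables = syllables,
                typicality = typicality)
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (length(parts) == 0L) {
    stop_vf("no resource file given", class = "bad_input")
  }
  tabs <- lapply(names(parts), function(kind) {
    df <- readr::read_tsv(parts[[kind]], show_col_types = FALSE, progress = FALSE)
    assert_cols(df, c("name", kind), paste(kind, "resource file"))
    dplyr::select(dplyr::mutate(df, name = tolower(.data$name)),
                  "name", dplyr::all_of(kind))
  })
  Reduce(function(a, b) dplyr::full_join(a, b, by = "name"), tabs)
}
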