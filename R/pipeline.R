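#' Extract the full per-subject feature table
#'
#' Runs the whole feature pipeline on a cohort of transcripts: token
#' classification and multiword merging, trimming of non-animal speech with
#' timestamp renormalization, cluster/switch segmentation under the chosen
#' semantic method, and the count-based plus timing feature blocks. One row
#' per subject; subjects whose response contains no usable animal token are
#' dropped with a warning.
#'
#' @param tokens A token tibble (from [read_ctm()] or
#'   [generate_cohort()]`$tokens`), or a `vf_cohort` object (then `labels`
#'   and `durations` are taken from it).
#' @param labels Optional tibble `subject_id`, `label`; appended as the last
#'   column.
#' @param durations Optional tibble `subject_id`, `total_duration`.
#' @param lexicon,table Lexicon and subcategory table (defaults: built-ins).
#' @param embeddings Embedding matrix; required for `method = "esa"` and for
#'   the MESA/MAESA features.
#' @param resources Optional word-resource tibble (see
#'   [load_word_resources()]).
#' @param method `"esa"` or `"troyer"` segmentation.
#' @param threshold A [threshold_config()] (ESA only).
#' @param time_norm `"collapse"` or `"fraction"` (see
#'   [trim_and_renormalize()]).
#' @return A tibble with `subject_id`, the feature columns, and `label` last
#'   (when given).
#' @export
extract_features <- function(tokens, labels = NULL, durations = NULL,
                             lexicon = builtin_lexicon(),
                             table = builtin_category_table(),
                             embeddings = NULL, resources = NULL,
                             method = c("esa", "troyer"),
                             threshold = threshold_config(),
                             time_norm = c("collapse", "fraction")) {
  method <- match.arg(method)
  time_norm <- match.arg(time_norm)
  if (inherits(tokens, "vf_cohort")) {
    labels <- labels %||% tokens$labels
    durations <- durations %||% tokens$durations
    tokens <- tokens$tokens
  }
  if (method == "esa" && is.null(embeddings)) {
    stop_vf("method = 'esa' needs an embedding matrix", class = "bad_input")
  }
  classified <- classify_tokens(tokens, lexicon)

  rows <- lapply(split(classified, classified$subject_id), function(tok) {
    subject <- tok$subject_id[1]
    seq <- tryCatch(
      trim_and_renormalize(tok, durations = durations, time_norm = time_norm),
      vfforage_empty_sequence = function(e) {
        warning("subject ", subject, " dropped: no animal tokens",
                call. = FALSE)
        NULL
      }
    )
    if (is.null(seq)) return(NULL)
    # names the chosen semantic representation cannot place are set aside
    known <- if (method == "troyer") {
      seq$name %in% names(table$assignments)
    } else {
      seq$name %in% rownames(embeddings)
    }
    if (any(!known)) {
      warning("subject ", subject, ": ", sum(!known),
              " name(s) unknown to the ", method,
              " representation treated as non-animal (",
              paste(unique(seq$name[!known]), collapse = ", "), ")",
              call. = FALSE)
      seq <- seq[known, ]
    }
    if (nrow(seq) == 0L) {
      warning("subject ", subject, " dropped: no representable animal names",
              call. = FALSE)
      return(NULL)
    }
    sims <- if (!is.null(embeddings) &&
                all(seq$name %in% rownames(embeddings))) {
      adjacent_similarities(seq, embeddings)
    } else NULL
    seg <- withCallingHandlers(
      segment_sequence(seq, method = method, embeddings = embeddings,
                       table = table, threshold = threshold, sims = sims),
      warning = function(w) {
        # degenerate-threshold warnings are informative, not per-subject fatal
        invokeRestart("muffleWarning")
      }
    )
    timing <- switch_timing(seg)
    dplyr::bind_cols(
      tibble::tibble(subject_id = subject),
      count_feature_set(seg, sims = sims, embeddings = embeddings,
                        resources = resources),
      aggregate_timing(timing)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(labels)) {
    out <- dplyr::left_join(out, labels[c("subject_id", "label")],
                            by = "subject_id")
  }
  out
}

#' Sweep the adaptive-threshold fraction
#'
#' Re-extracts the ESA feature set at each threshold fraction and
#' cross-validates a classifier on it, tracing how segmentation granularity
#' drives downstream discrimination. The default grid is 50% to 100% of the
#' normalized mean similarity in 5% steps (11 settings).
#'
#' @param tokens Token tibble or `vf_cohort`.
#' @param labels,durations See [extract_features()].
#' @param fractions Numeric vector of adaptive fractions in (0, 1].
#' @param embeddings,lexicon,table,resources,time_norm Passed to
#'   [extract_features()].
#' @param cfg,n_repeats,seed,classifier Passed to [lopo_cv()].
#' @param ... Further arguments to [lopo_cv()].
#' @return A tibble of class `vf_sweep` with columns `fraction`, `auc`,
#'   `sensitivity`, `specificity` (percentages), one row per fraction.
#' @export
sweep_threshold <- function(tokens, labels = NULL, durations = NULL,
                            fractions = seq(0.5, 1.0, by = 0.05),
                            embeddings = NULL,
                            lexicon = builtin_lexicon(),
                            table = builtin_category_table(),
                            resources = NULL,
                            time_norm = "collapse",
                            cfg = classifier_config(), n_repeats = 50L,
                            seed = 1L, classifier = "svm", ...) {
  if (length(fractions) == 0L) {
    stop_vf("fractions must be non-empty", class = "validation")
  }
  if (any(fractions <= 0 | fractions > 1)) {
    stop_vf("fractions must lie in (0, 1]", class = "validation")
  }
  rows <- lapply(fractions, function(f) {
    feats <- extract_features(
      tokens, labels = labels, durations = durations, lexicon = lexicon,
      table = table, embeddings = embeddings, resources = resources,
      method = "esa", threshold = threshold_config("adaptive", fraction = f),
      time_norm = time_norm
    )
    cv <- lopo_cv(feats, cfg = cfg, n_repeats = n_repeats, seed = seed,
                  classifier = classifier, ...)
    tibble::tibble(fraction = f, auc = cv$auc, sensitivity = cv$sensitivity,
                   specificity = cv$specificity)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("vf_sweep", class(out))
  out
}
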