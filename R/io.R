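#' Read a CTM-style time-aligned transcript
#'
#' Parses whitespace-delimited CTM records, the de-facto transport format for
#' forced-alignment output: one line per spoken word with fields
#' `recording-id channel onset duration word [speaker]`. Onset and duration are
#' seconds. The optional 6th field marks the speaker, `P` (participant, the
#' default) or `E` (examiner). Lines starting with `#` or `;` are comments.
#'
#' @param path Path to a CTM file. One file may hold any number of recordings;
#'   each distinct recording-id becomes one subject.
#' @return A tibble of tokens with columns `subject_id`, `word`, `onset`,
#'   `duration`, `speaker`, ordered by subject and onset (ties keep input
#'   order).
#' @examples
#' ctm <- tempfile(fileext = ".ctm")
#' writeLines(c("S01 1 1.5 0.4 cat", "S01 1 2.2 0.3 falcon"), ctm)
#' read_ctm(ctm)
#' @export
read_ctm <- function(path) {
  if (!file.exists(path)) {
    stop_vf("transcript file not found: ", path, class = "io")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*($|[#;])", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(tibble::tibble(
      subject_id = character(), word = character(),
      onset = double(), duration = double(), speaker = character()
    ))
  }
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  n_fields <- lengths(fields)
  bad <- which(n_fields < 5L)
  if (length(bad) > 0L) {
    stop_vf("malformed CTM line ", idx[bad[1]], " in ", path,
            " (expected >= 5 fields, got ", n_fields[bad[1]], ")",
            class = "parse")
  }
  onset <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  duration <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  nonnum <- which(is.na(onset) | is.na(duration))
  if (length(nonnum) > 0L) {
    stop_vf("malformed CTM line ", idx[nonnum[1]], " in ", path,
            " (non-numeric onset/duration)", class = "parse")
  }
  neg <- which(onset < 0 | duration < 0)
  if (length(neg) > 0L) {
    stop_vf("negative onset or duration on CTM line ", idx[neg[1]],
            " in ", path, class = "validation")
  }
  speaker_raw <- vapply(fields, function(f) {
    if (length(f) >= 6L) f[[6L]] else "P"
  }, "")
  tokens <- tibble::tibble(
    subject_id = vapply(fields, `[[`, "", 1L),
    word = tolower(vapply(fields, `[[`, "", 5L)),
    onset = onset,
    duration = duration,
    speaker = ifelse(toupper(speaker_raw) == "E", "examiner", "participant")
  )
  dplyr::arrange(tokens, .data$subject_id, .data$onset)
}

#' Write and read a per-subject feature table
#'
#' The table is written as TSV with one row per subject, the `label` column
#' (when present) last, and missing cells rendered as `NA`. `read_feature_table()`
#' round-trips what `write_feature_table()` produced.
#'
#' @param features A tibble of per-subject features, e.g. from
#'   [extract_features()].
#' @param path Output (input) TSV path.
#' @return `write_feature_table()` returns `features` invisibly;
#'   `read_feature_table()` returns a tibble.
#' @export
write_feature_table <- function(features, path) {
  if (anyDuplicated(names(features)) > 0L) {
    stop_vf("feature table column names must be unique", class = "validation")
  }
  if ("label" %in% names(features)) {
    features <- dplyr::relocate(features, "label", .after = dplyr::last_col())
  }
  readr::write_tsv(features, path, na = "NA")
  invisible(features)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_tsv(path, na = "NA", show_col_types = FALSE,
                  progress = FALSE)
}

#' Read word embeddings in word2vec text format
#'
#' The format is a header line `N D` followed by `N` lines `word v1 ... vD`.
#' Vectors are returned as a numeric matrix with one row per word.
#'
#' @param path Path to the embedding file.
#' @return A numeric matrix with row names = words and `D` columns.
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) {
    stop_vf("embedding file not found: ", path, class = "io")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(header) != 2L || anyNA(suppressWarnings(as.integer(header)))) {
    stop_vf("bad word2vec header in ", path, " (expected 'N D')",
            class = "parse")
  }
  n <- as.integer(header[1]); d <- as.integer(header[2])
  body <- strsplit(trimws(lines[-1]), "\\s+")
  if (length(body) != n || any(lengths(body) != d + 1L)) {
    stop_vf("embedding body of ", path, " does not match its header (",
            n, " x ", d, ")", class = "parse")
  }
  words <- vapply(body, `[[`, "", 1L)
  # multiword names are stored with underscores in word2vec convention
  words <- gsub("_", " ", words, fixed = TRUE)
  mat <- t(vapply(body, function(f) as.numeric(f[-1]), numeric(d)))
  rownames(mat) <- words
  mat
}

#' @rdname read_embeddings
#' @param embeddings A numeric matrix with row names = words.
#' @export
write_embeddings <- function(embeddings, path) {
  words <- gsub(" ", "_", rownames(embeddings), fixed = TRUE)
  body <- vapply(seq_len(nrow(embeddings)), function(i) {
    paste(c(words[i], format(embeddings[i, ], digits = 8, trim = TRUE)),
          collapse = " ")
  }, "")
  writeLines(c(paste(nrow(embeddings), ncol(embeddings)), body), path)
  invisible(embeddings)
}

#' Read a run configuration file
#'
#' A single YAML (or JSON, a YAML subset) file holding resource paths and the
#' analysis settings: segmentation `method`, threshold mode/fraction,
#' `time_norm`, cross-validation repeats and seed.
#'
#' @param path Path to a YAML/JSON config file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop_vf("config file not found: ", path, class = "io")
  }
  yaml::read_yaml(path)
}
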