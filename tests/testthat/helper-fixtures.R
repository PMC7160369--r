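# shared fixtures, built in code at test time

tiny_lexicon <- function() {
  vf_lexicon(
    c("pig", "ox", "cat", "dog", "moose", "hippopotamus", "mountain lion",
      "great white shark", "pony"),
    c(hippopotami = "hippopotamus", oxen = "ox")
  )
}

tiny_table <- function() {
  as_category_table(tibble::tibble(
    name = c("dog", "cat", "cat", "falcon", "shark", "dolphin", "pig"),
    subcategory = c("domestic", "domestic", "feline", "bird", "sea", "sea",
                    "farm")
  ))
}

# write a token tibble as a CTM file and return the path
write_tmp_ctm <- function(tokens, speaker_col = TRUE) {
  path <- withr::local_tempfile(fileext = ".ctm",
                                .local_envir = parent.frame())
  spk <- if (speaker_col) {
    paste0(" ", ifelse(tokens$speaker == "examiner", "E", "P"))
  } else ""
  writeLines(sprintf("%s 1 %s %s %s%s", tokens$subject_id,
                     format(tokens$onset, trim = TRUE),
                     format(tokens$duration, trim = TRUE),
                     tokens$word, spk), path)
  path
}

# quick participant-only token table from words + onsets
make_tokens <- function(words, onsets, durations = 0.3, id = "S1",
                        speaker = "participant") {
  tibble::tibble(subject_id = id, word = words, onset = onsets,
                 duration = rep_len(durations, length(words)),
                 speaker = rep_len(speaker, length(words)))
}

# brute-force all-pairs cosine enumeration, independent of package internals
all_pairs_oracle <- function(names, emb) {
  out <- numeric()
  n <- length(names)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      a <- emb[names[i], ]; b <- emb[names[j], ]
      out <- c(out, sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
    }
  }
  out
}

worked_example_segmentation <- function() {
  fx <- make_worked_example()
  segment_sequence(fx$sequence, "esa", embeddings = fx$embeddings,
                   threshold = threshold_config("fixed", 0.05))
}
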