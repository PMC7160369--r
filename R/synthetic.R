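#' Built-in demonstration category table and lexicon
#'
#' A small synthetic subcategory table (it is *not* the published 545-name
#' clinical instrument, which is not redistributable): 44 common animal names
#' across 8 subcategories, a handful of names belonging to two subcategories.
#' The matching lexicon adds irregular plurals and multiword names. Both are
#' constructed in code so the whole pipeline runs with no external files.
#'
#' @return `builtin_category_table()` a [as_category_table()] object;
#'   `builtin_lexicon()` a [vf_lexicon()].
#' @export
builtin_category_table <- function() {
  pairs <- list(
    pets = c("dog", "cat", "hamster", "guinea pig", "goldfish", "parrot",
             "rabbit"),
    farm = c("cow", "pig", "horse", "sheep", "goat", "chicken", "ox",
             "rabbit"),
    birds = c("falcon", "eagle", "owl", "sparrow", "penguin", "parrot",
              "chicken", "duck"),
    sea = c("shark", "dolphin", "whale", "octopus", "salmon", "seal",
            "great white shark", "goldfish", "duck", "penguin"),
    african = c("lion", "elephant", "giraffe", "zebra", "hippopotamus",
                "rhinoceros", "cheetah"),
    insects = c("ant", "bee", "butterfly", "spider", "mosquito"),
    rodents = c("mouse", "rat", "squirrel", "hamster", "beaver"),
    wild_north = c("bear", "wolf", "moose", "deer", "fox", "bat",
                   "mountain lion", "lion")
  )
  as_category_table(tibble::tibble(
    name = unlist(pairs, use.names = FALSE),
    subcategory = rep(names(pairs), lengths(pairs))
  ))
}

#' @rdname builtin_category_table
#' @export
builtin_lexicon <- function() {
  table_names <- names(builtin_category_table()$assignments)
  extra <- c("dog", "cat", "falcon", "bat", "elephant", "shark", "dolphin")
  irregular <- c(
    hippopotami = "hippopotamus", oxen = "ox", mice = "mouse",
    geese = "goose", wolves = "wolf", sheep = "sheep", deer = "deer",
    moose = "moose"
  )
  canonical <- unique(c(table_names, extra, unname(irregular)))
  vf_lexicon(canonical, irregular)
}

#' Specification of a synthetic fluency cohort
#'
#' Defines the generative model for seeded two-group cohorts of timestamped
#' animal-name responses. Defaults emulate the study conditions of a 60 s
#' animal fluency test given to 28 MCI and 42 cognitively intact subjects,
#' with the published group word-production statistics (intact 17.3 (4.99),
#' MCI 13.3 (4.12) words) and an MCI switching penalty: intra-cluster gaps
#' are drawn from a shared log-normal, while MCI switch gaps are inflated by
#' `osr_inflation`, so MCI responses show fewer words and a larger
#' |SD - ICRT| mismatch in expectation.
#'
#' @param n_mci,n_ci Group sizes.
#' @param test_duration Test length in seconds.
#' @param mean_words,sd_words Named lists (`mci`, `ci`) of the target
#'   word-production normal distribution per group.
#' @param icrt_meanlog,icrt_sdlog Log-normal parameters of intra-cluster
#'   gaps in seconds (shared across groups).
#' @param sd_meanlog,sd_sdlog Log-normal parameters of the intact group's
#'   switch gaps in seconds.
#' @param osr_inflation Multiplier on MCI switch-gap scale (1 = no group
#'   timing difference).
#' @param interruption_rate Expected number of examiner interruptions per
#'   response (Poisson).
#' @param perseveration_prob Probability that a produced word repeats an
#'   earlier one.
#' @param seed Default seed used by [generate_cohort()].
#' @return A list of class `vf_cohort_spec`.
#' @export
cohort_spec <- function(n_mci = 28L, n_ci = 42L, test_duration = 60,
                        mean_words = list(mci = 13.3, ci = 17.3),
                        sd_words = list(mci = 4.12, ci = 4.99),
                        icrt_meanlog = log(1.2), icrt_sdlog = 0.35,
                        sd_meanlog = log(2.0), sd_sdlog = 0.45,
                        osr_inflation = 1.5,
                        interruption_rate = 1.0,
                        perseveration_prob = 0.05,
                        seed = 1L) {
  if (n_mci < 1L || n_ci < 1L) {
    stop_vf("group sizes must be >= 1", class = "validation")
  }
  if (test_duration <= 0 || osr_inflation <= 0) {
    stop_vf("durations and inflation must be positive", class = "validation")
  }
  structure(
    list(n_mci = as.integer(n_mci), n_ci = as.integer(n_ci),
         test_duration = test_duration,
         mean_words = mean_words, sd_words = sd_words,
         icrt_meanlog = icrt_meanlog, icrt_sdlog = icrt_sdlog,
         sd_meanlog = sd_meanlog, sd_sdlog = sd_sdlog,
         osr_inflation = osr_inflation,
         interruption_rate = interruption_rate,
         perseveration_prob = perseveration_prob,
         seed = as.integer(seed)),
    class = "vf_cohort_spec"
  )
}

#' Generate a synthetic fluency cohort
#'
#' Simulates timestamped responses subject by subject: semantic patches are
#' sampled from the category table (cluster lengths 1-4), words inside a
#' patch arrive after log-normal intra-cluster gaps, patch changes after
#' log-normal switch gaps (inflated for the MCI group), and production stops
#' when the word budget or the test duration runs out. Examiner
#' interruptions ("you still have ten seconds left"-style) are inserted as
#' real-duration tokens that push later speech back, exercising the
#' trim/renormalize path. Fully deterministic given the seed.
#'
#' @param spec A [cohort_spec()].
#' @param table Category table to draw names from.
#' @param seed Integer seed (defaults to `spec$seed`).
#' @return A list of class `vf_cohort`: `tokens` (CTM-shaped tibble with
#'   `speaker`), `labels` (`subject_id`, `label`), `durations`
#'   (`subject_id`, `total_duration`).
#' @export
generate_cohort <- function(spec = cohort_spec(), table = builtin_category_table(),
                            seed = NULL) {
  seed <- seed %||% spec$seed
  subcats <- table$subcategories
  by_subcat <- lapply(subcats, function(sc) {
    names(table$assignments)[vapply(table$assignments,
                                    function(s) sc %in% s, TRUE)]
  })
  names(by_subcat) <- subcats

  ids <- c(sprintf("M%02d", seq_len(spec$n_mci)),
           sprintf("C%02d", seq_len(spec$n_ci)))
  groups <- rep(c("mci", "ci"), c(spec$n_mci, spec$n_ci))

  withr::with_seed(seed, {
    subj <- lapply(seq_along(ids), function(i) {
      generate_response(ids[i], groups[i], spec, by_subcat)
    })
  })
  tokens <- dplyr::bind_rows(lapply(subj, `[[`, "tokens"))
  durations <- dplyr::bind_rows(lapply(subj, `[[`, "duration"))
  structure(
    list(tokens = tokens,
         labels = tibble::tibble(subject_id = ids,
                                 label = ifelse(groups == "mci", "MCI", "CI")),
         durations = durations),
    class = "vf_cohort"
  )
}

#' @export
print.vf_cohort <- function(x, ...) {
  cat("<vf_cohort> ", nrow(x$labels), " subjects (",
      sum(x$labels$label == "MCI"), " MCI / ",
      sum(x$labels$label == "CI"), " CI), ",
      nrow(x$tokens), " tokens\n", sep = "")
  invisible(x)
}

generate_response <- function(id, group, spec, by_subcat) {
  n_target <- max(3L, round(stats::rnorm(1, spec$mean_words[[group]],
                                         spec$sd_words[[group]])))
  sd_meanlog <- spec$sd_meanlog +
    if (group == "mci") log(spec$osr_inflation) else 0

  words <- character(0)
  onsets <- numeric(0)
  t <- stats::runif(1, 0.5, 1.5)
  produced_all <- character(0)
  current_subcat <- sample(names(by_subcat), 1)
  cluster_left <- sample(1:4, 1, prob = c(0.25, 0.35, 0.25, 0.15))
  cluster_used <- character(0)

  while (length(words) < n_target && t <= spec$test_duration - 0.5) {
    pool <- setdiff(by_subcat[[current_subcat]], cluster_used)
    persev <- length(produced_all) > 2 &&
      stats::runif(1) < spec$perseveration_prob
    word <- if (persev) {
      sample(produced_all, 1)
    } else if (length(pool) > 0) {
      if (length(pool) == 1) pool else sample(pool, 1)
    } else NA_character_
    if (is.na(word)) {
      cluster_left <- 0L
    } else {
      words <- c(words, word)
      onsets <- c(onsets, t)
      produced_all <- c(produced_all, word)
      cluster_used <- c(cluster_used, word)
      cluster_left <- cluster_left - 1L
    }
    # retrieval slows as the lexicon patch depletes over the minute
    slow <- 1 + t / spec$test_duration
    if (cluster_left > 0L) {
      gap <- stats::rlnorm(1, spec$icrt_meanlog, spec$icrt_sdlog)
    } else {
      gap <- stats::rlnorm(1, sd_meanlog, spec$sd_sdlog)
      current_subcat <- sample(names(by_subcat), 1)
      cluster_left <- sample(1:4, 1, prob = c(0.25, 0.35, 0.25, 0.15))
      cluster_used <- character(0)
    }
    t <- t + gap * slow
  }
  if (length(words) == 0L) {   # pathological spec; keep the subject valid
    words <- sample(unlist(by_subcat), 1)
    onsets <- 1
  }

  durs <- stats::runif(length(words), 0.35, 0.7)
  # multiword names are spoken word by word; classify_tokens() re-merges them
  parts <- strsplit(words, " ", fixed = TRUE)
  npart <- lengths(parts)
  tok <- tibble::tibble(
    subject_id = id,
    word = unlist(parts),
    onset = unlist(lapply(seq_along(words), function(i) {
      onsets[i] + (seq_len(npart[i]) - 1L) * durs[i] / npart[i]
    })),
    duration = rep(durs / npart, npart),
    speaker = "participant"
  )
  total <- spec$test_duration

  n_inter <- stats::rpois(1, spec$interruption_rate)
  if (n_inter > 0L) {
    phrases <- list(
      c("you", "still", "have", "ten", "seconds", "left"),
      c("good"), c("keep", "going"), c("you", "are", "doing", "fine")
    )
    for (j in seq_len(n_inter)) {
      phrase <- phrases[[sample.int(length(phrases), 1)]]
      pdur <- stats::runif(length(phrase), 0.2, 0.5)
      at <- stats::runif(1, min(tok$onset), max(tok$onset) + 0.1)
      shift <- sum(pdur)
      later <- tok$onset >= at
      tok$onset[later] <- tok$onset[later] + shift
      ins <- tibble::tibble(
        subject_id = id, word = phrase,
        onset = at + cumsum(c(0, pdur[-length(pdur)])),
        duration = pdur, speaker = "examiner"
      )
      tok <- dplyr::bind_rows(tok, ins)
      total <- total + shift
    }
    tok <- dplyr::arrange(tok, .data$onset)
  }
  total <- max(total, max(tok$onset + tok$duration))
  list(tokens = tok,
       duration = tibble::tibble(subject_id = id, total_duration = total))
}

#' Generate fixture word embeddings from a category table
#'
#' Builds a synthetic embedding space in which the subcategory structure is
#' geometrically real: each subcategory gets an orthonormal centroid
#' direction, and a word's vector is the mean of its subcategories' centroids
#' plus isotropic noise. Same-subcategory pairs are therefore more
#' cosine-similar than different-subcategory pairs on average.
#'
#' @param table A [as_category_table()] object.
#' @param dim Embedding dimension (>= number of subcategories for exact
#'   centroid orthogonality).
#' @param seed Integer seed.
#' @param noise Noise scale relative to the unit centroids.
#' @return A numeric matrix, rows = words.
#' @export
generate_embeddings <- function(table = builtin_category_table(), dim = 16L,
                                seed = 1L, noise = 0.15) {
  if (dim < 2L) stop_vf("dim must be >= 2", class = "validation")
  subcats <- table$subcategories
  k <- length(subcats)
  withr::with_seed(seed, {
    raw <- matrix(stats::rnorm(dim * max(k, dim)), nrow = dim)
    basis <- qr.Q(qr(raw))[, seq_len(min(k, dim)), drop = FALSE]
    centroids <- t(basis)
    if (k > dim) {  # more subcategories than dimensions: reuse noisy copies
      extra <- centroids[rep_len(seq_len(dim), k - dim), , drop = FALSE] +
        matrix(stats::rnorm((k - dim) * dim, sd = 0.3), ncol = dim)
      centroids <- rbind(centroids, extra)
    }
    rownames(centroids) <- subcats
    words <- names(table$assignments)
    mat <- t(vapply(words, function(w) {
      subs <- table$assignments[[w]]
      v <- colMeans(centroids[subs, , drop = FALSE]) +
        stats::rnorm(dim, sd = noise)
      while (sqrt(sum(v^2)) < 1e-8) v <- stats::rnorm(dim, sd = noise)
      v
    }, numeric(dim)))
  })
  rownames(mat) <- names(table$assignments)
  mat
}

#' Generate fixture word resources
#'
#' Seeded per-name corpus frequency, syllable count and typicality tables for
#' the lexical features.
#'
#' @param names Canonical animal names.
#' @param seed Integer seed.
#' @return A tibble with columns `name`, `frequency`, `syllables`,
#'   `typicality`.
#' @export
generate_word_resources <- function(names, seed = 1L) {
  names <- unique(tolower(names))
  withr::with_seed(seed, {
    tibble::tibble(
      name = names,
      frequency = pmax(1, round(stats::rlnorm(length(names), log(50), 1.2))),
      syllables = pmax(1L, 1L + stats::rpois(length(names), 1.2)),
      typicality = round(stats::runif(length(names)), 3)
    )
  })
}

#' The worked single-response example
#'
#' A seven-word response (dog, cat, falcon, bat, elephant, shark, dolphin)
#' with onsets {1.0, 1.5, 2.2, 2.4, 2.9, 3.8, 4.2} seconds and adjacent
#' cosine similarities {0.077, 0.012, 0.053, 0.055, 0.007, 0.067}. The
#' bundled 2-D embeddings place the words on the unit circle at cumulative
#' angles `acos(similarity)` apart, so the adjacent cosines reproduce those
#' values to float precision. At a fixed threshold of 0.05 the response
#' segments into three clusters with switches at "falcon" and "shark".
#'
#' @return A list with `tokens` (classified token tibble), `sequence` (the
#'   trimmed animal sequence with onsets), `similarities` (adjacent-pair
#'   tibble), `embeddings` (2-D matrix), and `durations`.
#' @examples
#' fx <- make_worked_example()
#' seg <- segment_sequence(fx$sequence, "esa", embeddings = fx$embeddings,
#'                         threshold = threshold_config("fixed", 0.05))
#' switch_timing(seg)
#' @export
make_worked_example <- function() {
  words <- c("dog", "cat", "falcon", "bat", "elephant", "shark", "dolphin")
  onsets <- c(1.0, 1.5, 2.2, 2.4, 2.9, 3.8, 4.2)
  sims <- c(0.077, 0.012, 0.053, 0.055, 0.007, 0.067)
  angles <- cumsum(c(0, acos(sims)))
  emb <- cbind(cos(angles), sin(angles))
  rownames(emb) <- words
  tokens <- tibble::tibble(
    subject_id = "ex01", word = words, onset = onsets, duration = 0.3,
    speaker = "participant", token_class = "animal", name = words
  )
  sequence <- tibble::tibble(
    subject_id = "ex01", name = words, onset = onsets,
    original_duration = onsets[7] + 0.3, shortened_duration = onsets[7] + 0.3
  )
  list(
    tokens = tokens,
    sequence = sequence,
    similarities = tibble::tibble(
      subject_id = "ex01", from = words[-7], to = words[-1], similarity = sims
    ),
    embeddings = emb,
    durations = tibble::tibble(subject_id = "ex01",
                               total_duration = onsets[7] + 0.3)
  )
}

#' Write a synthetic cohort and its resources to disk
#'
#' Materializes everything a from-files run needs: a CTM transcript file, a
#' labels TSV, the lexicon and category-table TSVs, a word2vec-format
#' embedding file and the word-resource TSVs.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param table,lexicon,embeddings,resources The resources to write
#'   (defaults: the built-ins / seeded fixtures).
#' @param seed Seed for default embedding/resource generation.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, table = builtin_category_table(),
                         lexicon = builtin_lexicon(), embeddings = NULL,
                         resources = NULL, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ctm <- cohort$tokens
  spk <- ifelse(ctm$speaker == "examiner", "E", "P")
  writeLines(
    sprintf("%s 1 %.3f %.3f %s %s", ctm$subject_id, ctm$onset, ctm$duration,
            gsub(" ", "_", ctm$word), spk),
    file.path(dir, "transcripts.ctm")
  )
  readr::write_tsv(cohort$labels, file.path(dir, "labels.tsv"))
  readr::write_tsv(cohort$durations, file.path(dir, "durations.tsv"))
  write_category_table(table, file.path(dir, "category_table.tsv"))
  write_lexicon(lexicon, file.path(dir, "lexicon.tsv"))
  embeddings <- embeddings %||% generate_embeddings(table, seed = seed)
  write_embeddings(embeddings, file.path(dir, "embeddings.txt"))
  resources <- resources %||%
    generate_word_resources(names(table$assignments), seed = seed)
  readr::write_tsv(resources[c("name", "frequency")], file.path(dir, "frequency.tsv"))
  readr::write_tsv(resources[c("name", "syllables")], file.path(dir, "syllables.tsv"))
  readr::write_tsv(resources[c("name", "typicality")], file.path(dir, "typicality.tsv"))
  invisible(dir)
}
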