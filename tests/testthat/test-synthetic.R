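test_that("cohort generation is deterministic given the seed", {
  spec <- cohort_spec(n_mci = 4, n_ci = 5)
  a <- generate_cohort(spec, seed = 99)
  b <- generate_cohort(spec, seed = 99)
  expect_identical(a$tokens, b$tokens)
  expect_identical(a$labels, b$labels)
  c <- generate_cohort(spec, seed = 100)
  expect_false(identical(a$tokens, c$tokens))
})

test_that("cohorts have the requested composition and valid timelines", {
  co <- generate_cohort(cohort_spec(n_mci = 6, n_ci = 9), seed = 2)
  expect_equal(sum(co$labels$label == "MCI"), 6L)
  expect_equal(sum(co$labels$label == "CI"), 9L)
  expect_setequal(unique(co$tokens$subject_id), co$labels$subject_id)
  ok <- dplyr::summarise(
    dplyr::group_by(co$tokens, .data$subject_id),
    sorted = !is.unsorted(onset), nonneg = all(onset >= 0 & duration > 0),
    last = max(onset + duration)
  )
  expect_true(all(ok$sorted))
  expect_true(all(ok$nonneg))
  expect_true(all(ok$last <= co$durations$total_duration[
    match(ok$subject_id, co$durations$subject_id)] + 1e-9))
})

test_that("realized word production recovers the group targets at large n", {
  spec <- cohort_spec(n_mci = 200, n_ci = 200, interruption_rate = 0)
  co <- generate_cohort(spec, seed = 6)
  lex <- builtin_lexicon()
  counts <- classify_tokens(co$tokens, lex) |>
    dplyr::filter(.data$token_class == "animal") |>
    dplyr::count(.data$subject_id)
  counts$label <- co$labels$label[match(counts$subject_id,
                                        co$labels$subject_id)]
  mean_ci <- mean(counts$n[counts$label == "CI"])
  mean_mci <- mean(counts$n[counts$label == "MCI"])
  expect_lt(abs(mean_ci - 17.3), 1.0)
  expect_lt(abs(mean_mci - 13.3), 1.0)
  expect_gt(mean_ci, mean_mci)
})

test_that("injected switch-gap inflation appears in the timing features", {
  emb <- generate_embeddings(seed = 1)
  co <- generate_cohort(cohort_spec(n_mci = 25, n_ci = 25, osr_inflation = 2),
                        seed = 8)
  feats <- suppressWarnings(extract_features(co, embeddings = emb))
  by_grp <- dplyr::summarise(
    dplyr::group_by(feats, .data$label),
    osr = mean(osr_mean, na.rm = TRUE), sd = mean(sd_mean, na.rm = TRUE)
  )
  expect_gt(by_grp$osr[by_grp$label == "MCI"],
            by_grp$osr[by_grp$label == "CI"])
  expect_gt(by_grp$sd[by_grp$label == "MCI"],
            by_grp$sd[by_grp$label == "CI"])
})

test_that("fixture embeddings respect the subcategory geometry", {
  tab <- builtin_category_table()
  emb <- generate_embeddings(tab, dim = 16, seed = 3)
  expect_identical(emb, generate_embeddings(tab, dim = 16, seed = 3))
  set.seed(4)
  same <- c(); diff <- c()
  for (i in 1:100) {
    sc <- sample(tab$subcategories, 2)
    in1 <- names(tab$assignments)[vapply(tab$assignments,
                                         function(s) sc[1] %in% s, TRUE)]
    notin1 <- setdiff(names(tab$assignments), in1)
    p <- sample(in1, 2)
    q <- c(sample(in1, 1), sample(notin1, 1))
    same <- c(same, cosine_similarity(emb[p[1], ], emb[p[2], ]))
    diff <- c(diff, cosine_similarity(emb[q[1], ], emb[q[2], ]))
  }
  expect_gt(mean(same), mean(diff))

  # 2 dimensions, 2 subcategories: orthogonal centroids still separate
  tab2 <- as_category_table(tibble::tibble(
    name = c("cat", "dog", "shark", "whale"),
    subcategory = rep(c("pets", "sea"), each = 2)
  ))
  emb2 <- generate_embeddings(tab2, dim = 2, seed = 5, noise = 0.05)
  expect_gt(cosine_similarity(emb2["cat", ], emb2["dog", ]),
            cosine_similarity(emb2["cat", ], emb2["shark", ]))
})

test_that("the worked-example fixture reproduces the printed values exactly", {
  fx <- make_worked_example()
  expect_equal(fx$sequence$onset, c(1.0, 1.5, 2.2, 2.4, 2.9, 3.8, 4.2))
  expect_equal(fx$similarities$similarity,
               c(0.077, 0.012, 0.053, 0.055, 0.007, 0.067))
  sims <- adjacent_similarities(fx$sequence, fx$embeddings)
  expect_equal(sims$similarity, fx$similarities$similarity,
               tolerance = 1e-12)
  seg <- worked_example_segmentation()
  expect_equal(sum(seg$is_switch), 2L)
})

test_that("a written cohort reloads through the file readers", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_spec(n_mci = 3, n_ci = 4,
                                    interruption_rate = 0.5), seed = 12)
  write_cohort(co, dir, seed = 1)
  tok <- read_ctm(file.path(dir, "transcripts.ctm"))
  expect_setequal(unique(tok$subject_id), co$labels$subject_id)
  lex <- load_lexicon(file.path(dir, "lexicon.tsv"))
  tab <- load_category_table(file.path(dir, "category_table.tsv"))
  emb <- read_embeddings(file.path(dir, "embeddings.txt"))
  res <- load_word_resources(
    frequency = file.path(dir, "frequency.tsv"),
    syllables = file.path(dir, "syllables.tsv"),
    typicality = file.path(dir, "typicality.tsv")
  )
  labels <- readr::read_tsv(file.path(dir, "labels.tsv"),
                            show_col_types = FALSE)
  durations <- readr::read_tsv(file.path(dir, "durations.tsv"),
                               show_col_types = FALSE)
  feats <- suppressWarnings(extract_features(
    tok, labels = labels, durations = durations, lexicon = lex, table = tab,
    embeddings = emb, resources = res
  ))
  expect_equal(nrow(feats), 7L)
  expect_true(all(c("af_score", "osr_mean", "freq_log_mean", "label") %in%
                    names(feats)))
})
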