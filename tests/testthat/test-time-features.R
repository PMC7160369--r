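test_that("interval collapse removes exactly the non-animal speech", {
  lex <- tiny_lexicon()
  # 2.0 s examiner utterance before an animal at 10.0 s -> new onset 8.0 s
  tok <- classify_tokens(dplyr::bind_rows(
    make_tokens("hello", 1.0, durations = 2.0, speaker = "examiner"),
    make_tokens(c("cat", "dog"), c(10.0, 12.5))
  ), lex)
  seq <- trim_and_renormalize(
    tok, durations = tibble::tibble(subject_id = "S1", total_duration = 58)
  )
  expect_equal(seq$onset, c(8.0, 10.5))
  expect_equal(seq$original_duration[1], 58)
  expect_equal(seq$shortened_duration[1], 56)

  # an all-animal response is untouched
  tok2 <- classify_tokens(make_tokens(c("cat", "dog"), c(1, 2)), lex)
  seq2 <- trim_and_renormalize(tok2)
  expect_equal(seq2$onset, c(1, 2))
  expect_equal(seq2$shortened_duration[1], seq2$original_duration[1])

  # no animal tokens at all is an error
  tok3 <- classify_tokens(make_tokens(c("um", "well"), c(1, 2)), lex)
  expect_error(trim_and_renormalize(tok3), class = "vfforage_empty_sequence")
})

test_that("collapse conserves duration and preserves uninterrupted gaps", {
  lex <- tiny_lexicon()
  set.seed(3)
  for (trial in 1:10) {
    n <- sample(4:8, 1)
    words <- sample(c("cat", "dog", "pig", "um", "the", "ox"), n, replace = TRUE)
    onsets <- cumsum(runif(n, 0.5, 2))
    durs <- runif(n, 0.2, 0.6)
    tok <- classify_tokens(make_tokens(words, onsets, durations = durs), lex)
    if (all(tok$token_class != "animal")) next
    total <- max(onsets + durs) + 1
    seq <- trim_and_renormalize(
      tok, durations = tibble::tibble(subject_id = "S1", total_duration = total)
    )
    removed <- sum(tok$duration[tok$token_class != "animal"])
    expect_equal(seq$shortened_duration[1] + removed, total)
    # gaps between adjacent animal words with nothing removed in between
    kept <- which(tok$token_class == "animal")
    adj <- which(diff(kept) == 1)
    for (a in adj) {
      expect_equal(seq$onset[a + 1] - seq$onset[a],
                   tok$onset[kept[a + 1]] - tok$onset[kept[a]])
    }
  }
})

test_that("fraction mode rescales onsets by the shortened duration", {
  lex <- tiny_lexicon()
  tok <- classify_tokens(make_tokens(c("cat", "dog"), c(5, 10),
                                     durations = 0.5), lex)
  dur <- tibble::tibble(subject_id = "S1", total_duration = 50)
  seq <- trim_and_renormalize(tok, durations = dur, time_norm = "fraction")
  expect_equal(seq$onset, c(5, 10) / 50)
})

test_that("SD, ICRT and OSR reproduce the worked example", {
  seg <- worked_example_segmentation()
  timing <- switch_timing(seg)
  expect_equal(timing$sd, c(0.7, 0.9))
  expect_equal(timing$icrt, c(0.2, 0.4))
  expect_equal(timing$osr, abs(timing$sd - timing$icrt))
  expect_equal(switching_durations(seg), c(0.7, 0.9))
  expect_equal(intra_cluster_retrieval_times(seg), c(0.2, 0.4))
  expect_equal(optimal_switch_rates(timing), timing$osr)
})

test_that("switch timing handles no switches, singletons and uniform gaps", {
  # single cluster: no switches, empty timing
  seq1 <- tibble::tibble(subject_id = "s", name = c("a", "b"), onset = c(1, 2))
  sims1 <- tibble::tibble(subject_id = "s", from = "a", to = "b",
                          similarity = 0.9)
  seg1 <- segment_sequence(seq1, "esa", sims = sims1,
                           threshold = threshold_config("fixed", 0.5))
  expect_equal(nrow(switch_timing(seg1)), 0L)
  expect_equal(switching_durations(seg1), numeric())

  # switch into a singleton cluster: ICRT and OSR missing, SD present
  seq2 <- tibble::tibble(subject_id = "s", name = c("a", "b", "c"),
                         onset = c(1, 2, 4))
  sims2 <- tibble::tibble(subject_id = "s", from = c("a", "b"),
                          to = c("b", "c"), similarity = c(0.9, 0.1))
  seg2 <- segment_sequence(seq2, "esa", sims = sims2,
                           threshold = threshold_config("fixed", 0.5))
  t2 <- switch_timing(seg2)
  expect_equal(t2$sd, 2)
  expect_true(is.na(t2$icrt))
  expect_true(is.na(t2$osr))

  # uniform 1 s gaps with switches everywhere: all SD = 1
  n <- 5
  seq3 <- tibble::tibble(subject_id = "s", name = letters[1:n], onset = 1:n)
  sims3 <- tibble::tibble(subject_id = "s", from = letters[1:(n - 1)],
                          to = letters[2:n], similarity = 0)
  seg3 <- segment_sequence(seq3, "esa", sims = sims3,
                           threshold = threshold_config("fixed", 0.5))
  expect_equal(switching_durations(seg3), rep(1, n - 1))
})

test_that("OSR is nonnegative and zero only for perfectly matched switches", {
  set.seed(9)
  for (trial in 1:10) {
    sd <- runif(4, 0.1, 3)
    icrt <- sd
    icrt[2] <- sd[2] + 0.5
    timing <- tibble::tibble(sd = sd, icrt = icrt)
    osr <- optimal_switch_rates(timing)
    expect_true(all(osr >= 0))
    expect_equal(osr == 0, sd == icrt)
  }
})

test_that("timing aggregates summarize present values with population variance", {
  timing <- tibble::tibble(subject_id = "s", switch = 1:2, position = c(3L, 6L),
                           sd = c(0.7, 0.9), icrt = c(0.2, 0.4),
                           osr = c(0.5, 0.6))
  agg <- aggregate_timing(timing)
  expect_equal(agg$osr_mean, 0.55)
  expect_equal(agg$osr_median, 0.55)
  expect_equal(agg$osr_min, 0.5)
  expect_equal(agg$osr_max, 0.6)
  expect_equal(agg$osr_var, 0.0025)
  expect_equal(agg$sd_mean, 0.8)

  # single present value: mean = median = min = max, variance 0
  one <- tibble::tibble(sd = 1.3, icrt = NA_real_, osr = NA_real_)
  agg1 <- aggregate_timing(one)
  expect_equal(agg1$sd_mean, 1.3)
  expect_equal(agg1$sd_var, 0)
  expect_true(is.na(agg1$icrt_mean))
  expect_true(is.na(agg1$osr_max))

  # empty: all aggregates missing
  agg0 <- aggregate_timing(tibble::tibble(sd = double(), icrt = double(),
                                          osr = double()))
  expect_true(all(is.na(unlist(agg0))))
  expect_equal(names(agg0),
               c(paste0("sd_", c("mean", "median", "var", "min", "max")),
                 paste0("icrt_", c("mean", "median", "var", "min", "max")),
                 paste0("osr_", c("mean", "median", "var", "min", "max"))))
})
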