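#' Trim non-animal speech and renormalize timestamps
#'
#' Fluency recordings contain fillers, asides and examiner interruptions.
#' Before timing features are measured, all non-animal tokens are removed and
#' the timeline is collapsed: each removed token's duration is subtracted from
#' the onsets of everything after it, as if the extraneous speech were cut out
#' of the tape. A 58 s recording with 8 s of non-animal speech becomes a 50 s
#' "shortened" response, and gaps between animal words with no interruption
#' between them are preserved exactly.
#'
#' @param tokens A classified token tibble from [classify_tokens()] (one or
#'   many subjects).
#' @param durations Optional tibble `subject_id`, `total_duration` giving the
#'   recording length per subject; defaults to the end of the last token.
#' @param time_norm `"collapse"` (subtract removed durations, the default) or
#'   `"fraction"` (additionally divide collapsed onsets by the shortened
#'   duration, giving unitless relative timestamps).
#' @return A tibble with columns `subject_id`, `name`, `onset` (renormalized),
#'   `original_duration`, `shortened_duration`, in production order. Subjects
#'   with zero animal tokens raise an error (use [extract_features()] for the
#'   warn-and-drop behaviour on cohorts).
#' @export
trim_and_renormalize <- function(tokens, durations = NULL,
                                 time_norm = c("collapse", "fraction")) {
  time_norm <- match.arg(time_norm)
  assert_cols(tokens, c("subject_id", "onset", "duration", "token_class", "name"),
              "classified token table")
  tokens |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(tok, key) {
      total <- NULL
      if (!is.null(durations)) {
        hit <- durations$total_duration[durations$subject_id == key$subject_id]
        if (length(hit) == 1L) total <- hit
      }
      trim_one(tok, total, time_norm)
    }) |>
    dplyr::ungroup()
}

trim_one <- function(tok, total_duration, time_norm) {
  tok <- dplyr::arrange(tok, .data$onset)
  if (is.null(total_duration)) {
    total_duration <- max(tok$onset + tok$duration)
  }
  removed <- tok$token_class != "animal"
  if (all(removed)) {
    stop_vf("response contains no animal tokens", class = "empty_sequence")
  }
  removed_dur <- sum(tok$duration[removed])
  # interval collapse: shift each kept token left by the total duration of
  # removed speech that started before it
  shift <- cumsum(ifelse(removed, tok$duration, 0))
  shift_before <- c(0, shift[-length(shift)])
  kept <- tok[!removed, ]
  new_onset <- kept$onset - shift_before[!removed]
  shortened <- total_duration - removed_dur
  if (time_norm == "fraction") {
    new_onset <- new_onset / shortened
  }
  tibble::tibble(
    name = kept$name,
    onset = new_onset,
    original_duration = total_duration,
    shortened_duration = shortened
  )
}

#' Per-switch timing features: SD, ICRT, OSR
#'
#' For each switch the *switching duration* (SD) is the onset gap between the
#' first word of the new cluster and the last word of the previous one; the
#' *intra-cluster retrieval time* (ICRT) is the onset gap between the first
#' two words of the newly entered cluster (undefined for singleton clusters);
#' and the *optimal switch rate* (OSR) is `|SD - ICRT|` - under the
#' memory-foraging analogy, a well-timed switch pays for itself and the
#' mismatch is small.
#'
#' @param seg A segmented sequence with onsets, from [segment_sequence()] on a
#'   [trim_and_renormalize()] result.
#' @return A tibble with one row per switch: `subject_id`, `switch` (1-based
#'   index), `position` (token position opening the cluster), `sd`, `icrt`
#'   (NA for singleton clusters), `osr` (NA where ICRT is NA).
#' @examples
#' fx <- make_worked_example()
#' seg <- segment_sequence(fx$sequence, "esa", embeddings = fx$embeddings,
#'                         threshold = threshold_config("fixed", 0.05))
#' switch_timing(seg)
#' @export
switch_timing <- function(seg) {
  assert_cols(seg, c("subject_id", "name", "onset", "cluster", "is_switch"),
              "segmentation")
  pos <- which(seg$is_switch)
  if (length(pos) == 0L) {
    return(tibble::tibble(subject_id = character(), switch = integer(),
                          position = integer(), sd = double(),
                          icrt = double(), osr = double()))
  }
  sizes <- cluster_sizes(seg)
  sd <- seg$onset[pos] - seg$onset[pos - 1L]
  # cluster entered at switch k is cluster k+1; ICRT needs its 2nd word
  entered <- seg$cluster[pos]
  icrt <- vapply(seq_along(pos), function(k) {
    if (sizes[entered[k]] >= 2L) seg$onset[pos[k] + 1L] - seg$onset[pos[k]]
    else NA_real_
  }, 0)
  tibble::tibble(
    subject_id = seg$subject_id[1],
    switch = seq_along(pos),
    position = pos,
    sd = sd,
    icrt = icrt,
    osr = abs(sd - icrt)
  )
}

#' @rdname switch_timing
#' @return `switching_durations()`, `intra_cluster_retrieval_times()` and
#'   `optimal_switch_rates()` return plain numeric vectors (with NA where the
#'   quantity is undefined), one value per switch.
#' @export
switching_durations <- function(seg) switch_timing(seg)$sd

#' @rdname switch_timing
#' @export
intra_cluster_retrieval_times <- function(seg) switch_timing(seg)$icrt

#' @rdname switch_timing
#' @param timing A per-switch timing tibble from [switch_timing()].
#' @export
optimal_switch_rates <- function(timing) {
  assert_cols(timing, c("sd", "icrt"), "switch timing")
  abs(timing$sd - timing$icrt)
}

#' Statistical aggregates of the per-switch timing features
#'
#' Summarizes each of SD / ICRT / OSR over the present (non-missing) values
#' with mean, median, population variance, min and max, yielding the
#' fixed-dimension timing block of the feature vector. A response with no
#' present values for a quantity (e.g. zero switches) gets NA aggregates.
#'
#' @param timing A per-switch timing tibble from [switch_timing()].
#' @return A one-row tibble with columns `sd_mean`, `sd_median`, `sd_var`,
#'   `sd_min`, `sd_max`, `icrt_*`, `osr_*` (15 columns).
#' @export
aggregate_timing <- function(timing) {
  block <- function(x, prefix) {
    out <- tibble::tibble(
      mean = agg_or_na(x, mean),
      median = agg_or_na(x, stats::median),
      var = pop_var(x),
      min = agg_or_na(x, min),
      max = agg_or_na(x, max)
    )
    stats::setNames(out, paste0(prefix, "_", names(out)))
  }
  dplyr::bind_cols(
    block(timing$sd, "sd"),
    block(timing$icrt, "icrt"),
    block(timing$osr, "osr")
  )
}
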