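#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for cross-validation reports
#'
#' `tidy()` returns the per-repeat metrics; `glance()` a one-row summary
#' (metrics are percentages, averaged over repeats).
#'
#' @param x A `vf_lopo` object from [lopo_cv()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy vf_lopo
#' @export
tidy.vf_lopo <- function(x, ...) {
  x$metrics
}

#' @rdname tidy.vf_lopo
#' @method glance vf_lopo
#' @export
glance.vf_lopo <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, sensitivity = x$sensitivity, specificity = x$specificity,
    n_repeats = x$n_repeats, n_mci = x$n_small, n_ci = x$n_big,
    classifier = x$classifier, C = x$cfg$C, penalty = x$cfg$penalty,
    seed = x$seed
  )
}

#' Plot methods
#'
#' `autoplot.vf_lopo()` shows the distribution of per-repeat AUCs with the
#' mean marked; `autoplot.vf_ks_screen()` the KS statistic per feature;
#' `autoplot.vf_sweep()` the AUC over the threshold-fraction grid;
#' `plot_segmentation()` the response timeline coloured by cluster with
#' switches marked.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vf_lopo
#' @export
autoplot.vf_lopo <- function(object, ...) {
  ggplot2::ggplot(object$metrics, ggplot2::aes(x = .data$auc)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$auc, linetype = 2) +
    ggplot2::labs(
      x = "per-repeat ROC AUC (%)", y = "repeats",
      title = sprintf("LOPO CV: mean AUC %.1f%% over %d repeats",
                      object$auc, object$n_repeats)
    )
}

#' @rdname autoplot.vf_lopo
#' @method autoplot vf_ks_screen
#' @export
autoplot.vf_ks_screen <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      feature = stats::reorder(.data$feature, .data$statistic),
                      significant = .data$p_value < 0.05)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic, y = .data$feature,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "two-sample KS statistic", y = NULL,
                  fill = "p < 0.05")
}

#' @rdname autoplot.vf_lopo
#' @method autoplot vf_sweep
#' @export
autoplot.vf_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fraction, y = .data$auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "adaptive threshold fraction", y = "mean ROC AUC (%)")
}

#' @rdname autoplot.vf_lopo
#' @param seg A segmented sequence from [segment_sequence()].
#' @export
plot_segmentation <- function(seg, ...) {
  assert_cols(seg, c("name", "onset", "cluster", "is_switch"), "segmentation")
  df <- dplyr::mutate(seg, cluster = factor(.data$cluster))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$onset, y = 0)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$cluster), size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$name), angle = 45,
                       hjust = 0, nudge_y = 0.05, size = 3) +
    ggplot2::geom_vline(data = df[df$is_switch, ],
                        ggplot2::aes(xintercept = .data$onset),
                        linetype = 3, colour = "red") +
    ggplot2::scale_y_continuous(limits = c(-0.2, 0.6), breaks = NULL) +
    ggplot2::labs(x = "renormalized onset (s)", y = NULL, colour = "cluster")
}
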