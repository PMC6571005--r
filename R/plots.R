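#' Plot epoch-averaged waveforms
#'
#' Group-mean waveform per channel and condition, faceted by channel.
#'
#' @param object An `erp_epochs` object.
#' @param channels Channels to show (default: first 6 present).
#' @param conditions Conditions to show (default: `"all"` if present,
#'   otherwise every condition).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot erp_epochs
#' @export
autoplot.erp_epochs <- function(object, channels = NULL, conditions = NULL,
                                ...) {
  channels <- channels %||% head(unique(object$key$channel), 6)
  conditions <- conditions %||%
    (if ("all" %in% object$key$condition) "all"
     else unique(object$key$condition))
  keep <- object$key$channel %in% channels &
    object$key$condition %in% conditions
  d <- as_tibble(new_erp_epochs(object$key[keep, , drop = FALSE],
                                object$amplitude[keep, , drop = FALSE],
                                object$time, object$sampling_rate)) |>
    group_by(.data$group, .data$channel, .data$condition, .data$time_ms) |>
    summarise(amplitude = mean(.data$amplitude), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$time_ms, .data$amplitude,
                                  colour = .data$group,
                                  linetype = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = "Time (ms, 0 = target onset)",
                  y = "Amplitude (µV)",
                  colour = "Group", linetype = "Condition") +
    ggplot2::theme_minimal()
}

#' Plot per-variable importance of a CLV fit
#'
#' Squared normalized loadings (summing to one within each latent), the
#' loading sign mapped to fill.
#'
#' @param object A `clv_fit`.
#' @param top_n Show at most this many variables per latent (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot clv_fit
#' @export
autoplot.clv_fit <- function(object, top_n = 20, ...) {
  d <- tidy(object) |>
    group_by(.data$cluster) |>
    dplyr::slice_max(.data$importance, n = top_n, with_ties = FALSE) |>
    ungroup() |>
    mutate(variable = stats::reorder(.data$variable, .data$importance))
  ggplot2::ggplot(d, ggplot2::aes(.data$importance, .data$variable,
                                  fill = .data$sign)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~cluster, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Squared normalized loading", y = NULL,
                  fill = "Loading sign") +
    ggplot2::theme_minimal()
}

#' Plot the distribution of cross-validated agreement
#'
#' Histograms of per-repetition training and test agreement.
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("train_agreement", "test_agreement"),
                        names_to = "set", values_to = "agreement") |>
    mutate(set = sub("_agreement", "", .data$set))
  ggplot2::ggplot(d, ggplot2::aes(.data$agreement, fill = .data$set)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.6, bins = 15) +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "Agreement with reference labeling", y = "Repetitions",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
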