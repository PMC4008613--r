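#' Plot predicted persistence curves
#'
#' One line per scenario: linetype distinguishes spawning vs non-spawning
#' season, colour the capture river, mirroring the conventional presentation
#' of persistence-probability figures.
#'
#' @param object a `prediction_curve` tibble from [prediction_curve()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.prediction_curve <- function(object, ...) {
  aes_args <- list(x = rlang::sym("value"), y = rlang::sym("probability"))
  if ("capture_murray" %in% names(object)) {
    object$capture <- ifelse(object$capture_murray == 1,
                             "Tagged in Murray", "Tagged in Goulburn")
    aes_args$colour <- rlang::sym("capture")
  }
  if ("spawning" %in% names(object)) {
    object$season <- ifelse(object$spawning == 1, "spawning", "non-spawning")
    aes_args$linetype <- rlang::sym("season")
  }
  ggplot2::ggplot(object, do.call(ggplot2::aes, aes_args)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = unique(object$varying),
                  y = "Predicted persistence probability") +
    ggplot2::theme_minimal()
}

#' Occupancy timeline of tagged fish
#'
#' A tile per fish-week coloured by occupied river, faceted by capture
#' river — the weekly-state analogue of a detection-timeline figure.
#'
#' @param states weekly state tibble.
#' @param tags tag metadata (for capture-river facets).
#' @return a ggplot.
#' @export
plot_occupancy <- function(states, tags) {
  st <- dplyr::inner_join(states,
                          dplyr::select(tags, "fish_id", "capture_river"),
                          by = "fish_id")
  ggplot2::ggplot(st, ggplot2::aes(x = .data$week_index, y = .data$fish_id,
                                   fill = .data$river)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$capture_river),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "Analysis week", y = NULL, fill = "River") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}

#' Coefficient plot of an averaged model
#'
#' Point estimates with 95% unconditional confidence intervals, ordered by
#' relative importance.
#'
#' @param object an `averaged_model`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.averaged_model <- function(object, ...) {
  d <- object$terms
  d$term <- factor(d$term, levels = rev(d$term[order(
    -dplyr::coalesce(d$relative_importance, 101))]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "Averaged coefficient (logit scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
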