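# ggplot2 front-ends for the main result types

#' Plot per-condition transcriptogram profiles
#'
#' @param object output of [class_profiles()].
#' @param ... unused.
#' @return A ggplot object: mean profile per condition with a +/- 1 SE
#'   ribbon over relative list position.
#' @export
plot_class_profiles <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rel_position, y = .data$mean,
                                       colour = .data$condition,
                                       fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "relative position on ordered list",
                  y = "windowed expression (log2)") +
    ggplot2::theme_minimal()
}

#' @method autoplot anneal_fit
#' @export
autoplot.anneal_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$mcs, y = .data$cost)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Monte Carlo step", y = "cost F") +
    ggplot2::theme_minimal()
}

#' @method autoplot xgram_comparison
#' @export
autoplot.xgram_comparison <- function(object, ...) {
  thr <- attr(object, "bonferroni_threshold")
  ggplot2::ggplot(dplyr::filter(object, !is.na(.data$p_value)),
                  ggplot2::aes(x = .data$position, y = .data$p_value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.01, linetype = 2) +
    ggplot2::geom_hline(yintercept = thr, colour = "blue", linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "position on ordered list", y = "Welch P-value") +
    ggplot2::theme_minimal()
}

#' @method autoplot noise_report
#' @export
autoplot.noise_report <- function(object, ...) {
  ggplot2::ggplot(object$positions, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$contrast, colour = "contrast")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sd, colour = "sd")) +
    ggplot2::labs(x = "position", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot gene-set projection profiles
#'
#' @param object output of [project_gene_sets()] (or [project_gene_set()]).
#' @param ... unused.
#' @return A ggplot object of smoothed membership intensity along the list.
#' @export
plot_term_profiles <- function(object, ...) {
  if (!"name" %in% names(object)) object$name <- "set"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rel_position,
                                       y = .data$value,
                                       colour = .data$name)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "relative position on ordered list",
                  y = "membership intensity", colour = "gene set") +
    ggplot2::theme_minimal()
}
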