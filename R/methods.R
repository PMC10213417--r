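#' @export
print.metaspike_fit <- function(x, ...) {
  cat(sprintf("<metaspike_fit> %s task, %s, %d outer steps\n",
              x$kind, if (x$plastic) "plastic" else "non-plastic control",
              if (is.null(x$metrics)) 0L else max(x$metrics$step)))
  cat(sprintf("  DP-SNN: %d -> %d hidden (%s STDP) -> %d readout\n",
              x$n_in, x$n_hid, x$rule, x$n_out))
  cat(sprintf("  NM-SNN: 2 x %d CUBA neurons, per-input LTP/LTD head\n",
              x$n_nm))
  if (!is.null(x$metrics)) {
    last <- x$metrics[nrow(x$metrics), ]
    cat(sprintf("  final outer loss %.4f, batch accuracy %.2f\n",
                last$loss, last$accuracy))
  }
  if (!is.null(x$evals)) {
    last <- x$evals[nrow(x$evals), ]
    cat(sprintf("  held-out accuracy %.3f (n = %d, step %d)\n",
                last$accuracy, last$n, last$step))
  }
  invisible(x)
}

#' @export
print.metaspike_system <- function(x, ...) {
  cat(sprintf("<metaspike_system> %s task (untrained), %s\n", x$kind,
              if (x$plastic) "plastic" else "non-plastic"))
  invisible(x)
}

#' Tidy the per-step training metrics
#'
#' @param x A `metaspike_fit`.
#' @param ... Unused.
#' @return A tibble with one row per outer step: `step`, `loss`,
#'   `accuracy` (batch), `grad_norm`.
#' @export
tidy.metaspike_fit <- function(x, ...) {
  x$metrics
}

#' One-row summary of a fit
#'
#' @param x A `metaspike_fit`.
#' @param ... Unused.
#' @return A one-row tibble: task kind, rule, plasticity flag, steps,
#'   final loss, final batch accuracy, and (if evaluated) held-out accuracy.
#' @export
glance.metaspike_fit <- function(x, ...) {
  last <- x$metrics[nrow(x$metrics), ]
  tibble::tibble(
    kind = x$kind, rule = x$rule, plastic = x$plastic,
    n_outer = max(x$metrics$step),
    final_loss = last$loss, final_batch_accuracy = last$accuracy,
    heldout_accuracy = if (is.null(x$evals)) NA_real_ else
      x$evals$accuracy[nrow(x$evals)])
}

#' Plot the outer-loop learning curve
#'
#' @param object A `metaspike_fit`.
#' @param ... Unused.
#' @return A ggplot: meta-loss per outer step, with held-out accuracy
#'   evaluations overlaid when present.
#' @export
autoplot.metaspike_fit <- function(object, ...) {
  m <- object$metrics
  p <- ggplot2::ggplot(m, ggplot2::aes(x = .data$step, y = .data$loss)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_smooth(se = FALSE, method = "loess", formula = y ~ x,
                         linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::labs(x = "outer step", y = "meta-loss",
                  title = sprintf("%s task: outer-loop optimization",
                                  object$kind)) +
    ggplot2::theme_minimal()
  p
}

#' Plot an evaluation report
#'
#' @param object A `metaspike_eval` (e.g. from [eval_m_sweep()]).
#' @param ... Unused.
#' @return A ggplot of accuracy with exact binomial confidence intervals,
#'   against `M` when the report is a cue-count sweep.
#' @export
autoplot.metaspike_eval <- function(object, ...) {
  if (!is.null(object$M) && length(unique(object$M)) > 1) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$M, y = .data$accuracy)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           fill = "#2c7fb8", alpha = 0.2) +
      ggplot2::geom_line(colour = "#2c7fb8") +
      ggplot2::geom_point() +
      ggplot2::geom_hline(yintercept = 0.5, linetype = 2,
                          colour = "grey50") +
      ggplot2::labs(x = "cues per trial (M)", y = "test accuracy",
                    title = "Generalization over cue count") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object,
                    ggplot2::aes(x = factor(seq_len(nrow(object))),
                                 y = .data$accuracy)) +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                            ymax = .data$ci_high)) +
      ggplot2::labs(x = NULL, y = "accuracy") +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 .data
NULL
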