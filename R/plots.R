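#' Plot one slice of a case with label or prediction overlay
#'
#' Greyscale T2w (or ADC) slice with the in-gland class overlay: indolent in
#' blue, aggressive in red, prostate border implied by the overlay extent.
#'
#' @param case A `study_case` with fused `labels`.
#' @param slice Slice index.
#' @param prob Optional `probability_volume`; when given, the overlay shows
#'   the predicted argmax class instead of the ground truth.
#' @param sequence "t2w" or "adc".
#' @return A ggplot object.
#' @export
plot_case_slice <- function(case, slice, prob = NULL, sequence = c("t2w", "adc")) {
  sequence <- match.arg(sequence)
  img <- case[[sequence]]$data[slice, , ]
  d <- dim(img)
  df <- data.frame(row = rep(seq_len(d[1]), d[2]),
                   col = rep(seq_len(d[2]), each = d[1]),
                   intensity = as.vector(img))
  cls <- if (is.null(prob)) argmax_class(case$labels$y)[slice, , ]
         else argmax_class(prob$p)[slice, , ]
  cls[case$prostate_mask$data[slice, , ] == 0] <- 1L
  df$class <- factor(c("normal", "indolent", "aggressive")[as.vector(cls)],
                     levels = c("normal", "indolent", "aggressive"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::geom_point(data = df[df$class != "normal", ],
                        ggplot2::aes(colour = .data$class), size = 0.1, alpha = 0.4) +
    ggplot2::scale_colour_manual(values = c(indolent = "#3366ff", aggressive = "#ff3333"),
                                 drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL,
                  title = sprintf("%s slice %d (%s)", case$case_id, slice,
                                  if (is.null(prob)) "ground truth" else "prediction"))
}

#' Plot an evaluation report
#'
#' Per-class AUC bars for a pixel- or lesion-level `eval_report`.
#'
#' @param object An `eval_report` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$class, y = .data$auc)) +
    ggplot2::geom_col(fill = "#4477aa") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "ROC AUC",
                  title = paste0(unique(object$level), "-level evaluation")) +
    ggplot2::theme_minimal()
}

#' Plot per-epoch training loss
#'
#' @param histories List of per-fold history tibbles (from [train_crossval()]).
#' @return A ggplot object.
#' @export
plot_training_history <- function(histories) {
  df <- do.call(rbind, Map(function(h, k) cbind(fold = factor(k), h),
                           histories, seq_along(histories)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$fold)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "weighted cross-entropy") +
    ggplot2::theme_minimal()
}
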