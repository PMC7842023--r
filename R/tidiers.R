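# broom-style accessors and ggplot2 autoplot methods for the result objects.

#' Tidy a fitted AF model: its per-epoch training history
#'
#' @param x A `bcg_af_model`.
#' @param ... Unused.
#' @return Tibble with one row per epoch and metric columns.
#' @method tidy bcg_af_model
#' @export
tidy.bcg_af_model <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted AF model
#'
#' @param x A `bcg_af_model`.
#' @param ... Unused.
#' @return Tibble with the configuration and final/best metrics.
#' @method glance bcg_af_model
#' @export
glance.bcg_af_model <- function(x, ...) {
  h <- x$history
  tibble(type = x$spec$type, attention = x$spec$attention,
         mode = x$spec$mode, epochs = nrow(h),
         final_train_acc = h$train_acc[nrow(h)],
         best_val_acc = if (all(is.na(h$val_acc))) NA_real_
                        else max(h$val_acc, na.rm = TRUE),
         best_epoch = x$best_epoch)
}

#' @method tidy bcgaf_roc
#' @export
tidy.bcgaf_roc <- function(x, ...) {
  x$curve
}

#' @method glance bcgaf_roc
#' @export
glance.bcgaf_roc <- function(x, ...) {
  tibble(auc = x$auc, n_points = nrow(x$curve))
}

#' Plot the 2-D phase-space portrait of a segment
#'
#' @param object A `psr_trajectory`.
#' @param ... Unused.
#' @return A ggplot of the `(v, w)` projection.
#' @method autoplot psr_trajectory
#' @export
autoplot.psr_trajectory <- function(object, ...) {
  df <- tibble(v = object$vw[, 1], w = object$vw[, 2])
  ggplot(df, aes(x = .data$v, y = .data$w)) +
    geom_path(alpha = 0.4, linewidth = 0.3) +
    coord_equal() +
    labs(title = sprintf("Phase-space portrait (m = %d, tau = %d samples)",
                         object$m, object$tau),
         x = "v", y = "w") +
    theme_minimal()
}

#' Plot the training history of a fitted model
#'
#' @param object A `bcg_af_model`.
#' @param ... Unused.
#' @return A ggplot of loss and accuracy per epoch.
#' @method autoplot bcg_af_model
#' @export
autoplot.bcg_af_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "series", values_to = "value")
  h <- dplyr::filter(h, !is.na(.data$value))
  ggplot(h, aes(x = .data$epoch, y = .data$value, colour = .data$series)) +
    geom_line() +
    labs(title = "Training history", x = "Epoch", y = NULL, colour = NULL) +
    theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A `bcgaf_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot of the ROC curve with the AUC in the title.
#' @method autoplot bcgaf_roc
#' @export
autoplot.bcgaf_roc <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$fpr, y = .data$tpr)) +
    geom_step() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    coord_equal() +
    labs(title = sprintf("ROC curve (AUC = %.3f)", object$auc),
         x = "False positive rate", y = "True positive rate") +
    theme_minimal()
}

#' Plot a BCG record with its detected or true J-peaks
#'
#' @param object A `bcg_record`.
#' @param from_s,to_s Time window to display, in seconds.
#' @param ... Unused.
#' @return A ggplot of the signal trace.
#' @method autoplot bcg_record
#' @export
autoplot.bcg_record <- function(object, from_s = 0,
                                to_s = min(10, length(object$samples) /
                                             object$fs), ...) {
  n <- length(object$samples)
  t <- (seq_len(n) - 1) / object$fs
  keep <- t >= from_s & t <= to_s
  df <- tibble(time_s = t[keep], amplitude = object$samples[keep])
  p <- ggplot(df, aes(x = .data$time_s, y = .data$amplitude)) +
    geom_line(linewidth = 0.3) +
    labs(title = paste("BCG record", object$subject_id),
         x = "Time (s)", y = "Amplitude") +
    theme_minimal()
  jp <- object$true_j_peaks
  jp <- jp[jp >= from_s & jp <= to_s]
  if (length(jp)) {
    p <- p + geom_vline(xintercept = jp, colour = "red", alpha = 0.3,
                        linewidth = 0.2)
  }
  p
}
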