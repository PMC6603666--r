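#' Plot an evaluation report
#'
#' `"bland_altman"` shows per-minute differences against means with the bias
#' and limits of agreement; `"scatter"` shows predicted against reference
#' index; `"trend"` overlays the two index time courses per subject.
#'
#' @param object A `doa_evaluation` from [loocv()].
#' @param type One of `"bland_altman"`, `"scatter"`, `"trend"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.doa_evaluation <- function(object,
                                    type = c("bland_altman", "scatter", "trend"),
                                    ...) {
  type <- match.arg(type)
  df <- object$pooled
  ba <- object$bland_altman
  if (type == "bland_altman") {
    df$avg <- (df$ref_index + df$pred_index) / 2
    df$diff <- df$pred_index - df$ref_index
    ggplot2::ggplot(df, ggplot2::aes(x = .data$avg, y = .data$diff)) +
      ggplot2::geom_point(alpha = 0.4) +
      ggplot2::geom_hline(yintercept = ba$bias, linetype = 1) +
      ggplot2::geom_hline(yintercept = c(ba$lower, ba$upper), linetype = 2) +
      ggplot2::labs(
        x = "mean of reference and predicted index",
        y = "predicted - reference",
        title = sprintf("Bland-Altman: bias %.2f, limits [%.1f, %.1f]",
                        ba$bias, ba$lower, ba$upper)
      )
  } else if (type == "scatter") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$ref_index, y = .data$pred_index)) +
      ggplot2::geom_point(alpha = 0.4) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::labs(
        x = "reference index", y = "predicted index",
        title = sprintf("Pooled r = %.3f", object$pearson$r)
      )
  } else {
    long <- tidyr::pivot_longer(df, c("ref_index", "pred_index"),
                                names_to = "series", values_to = "index")
    ggplot2::ggplot(long, ggplot2::aes(x = .data$minute, y = .data$index,
                                       colour = .data$series)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~subject) +
      ggplot2::labs(x = "minute", y = "index (0-100)", colour = NULL)
  }
}

#' Plot the training-loss curve of a fitted network
#'
#' @param object A `doa_model` of kind `"ann"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.doa_model <- function(object, ...) {
  if (object$kind != "ann" || !nrow(object$loss_history)) {
    abort("loss-curve plot is available for freshly trained ANN models only.")
  }
  long <- tidyr::pivot_longer(object$loss_history, c("train_mse", "val_mse"),
                              names_to = "split", values_to = "mse")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "MSE (scaled units)", colour = NULL)
}

#' Plot per-minute feature trajectories
#'
#' @param features Feature tibble from [extract_features()] or
#'   [cohort_features()] (one subject).
#' @return A ggplot object with one facet per feature.
#' @export
plot_feature_trends <- function(features) {
  long <- tidyr::pivot_longer(features, dplyr::all_of(doa_features()),
                              names_to = "feature", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$minute, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = "minute", y = NULL)
}
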