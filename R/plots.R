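#' Plot tuning-grid records in the D1-D2 plane
#'
#' One point per model on log-log axes, coloured by loss/augmentation
#' configuration, sized by training-set size, with solid paths for the
#' Otsu-binarized D1 and dashed paths for PKFP (D2 is shared, as it is
#' computed on the predictions, so the two paths differ by a horizontal
#' shift in D1 only).
#'
#' @param object A `"thv_grid"` from [run_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.thv_grid <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::as_tibble(object)[, c("training_size", "augment", "loss",
                                 "d1_otsu_mean", "d1_pkfp_mean",
                                 "d2_mean")],
    c("d1_otsu_mean", "d1_pkfp_mean"),
    names_to = "binarization", values_to = "d1_mean"
  ) |>
    dplyr::mutate(
      binarization = ifelse(.data$binarization == "d1_otsu_mean",
                            "Otsu", "PKFP"),
      configuration = paste0(
        ifelse(.data$loss == "cross_entropy", "CE", "FL"),
        ", DA=", as.integer(.data$augment)
      )
    )
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$d1_mean, .data$d2_mean,
                 colour = .data$configuration,
                 linetype = .data$binarization,
                 group = interaction(.data$configuration,
                                     .data$binarization))
  ) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::geom_point(ggplot2::aes(size = .data$training_size)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "D1 mean [px]", y = "D2 mean [probability mass]",
                  size = "training size", colour = "configuration",
                  linetype = "binarization") +
    ggplot2::theme_minimal()
}

#' Plot a training-loss curve
#'
#' @param object A `"unet_fit"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.unet_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = object$history[object$best_epoch, , drop = FALSE],
      colour = "red"
    ) +
    ggplot2::labs(x = "epoch",
                  y = paste0("training loss (",
                             object$config$loss$name, ")")) +
    ggplot2::theme_minimal()
}

#' Overlay a segmentation on a frame
#'
#' Renders the grayscale frame with the segmentation (and optionally the
#' gold standard) overlaid, for visual inspection of results.
#'
#' @param frame Integer matrix 0-255.
#' @param seg Binary segmentation to overlay.
#' @param gold Optional gold-standard mask overlaid in a second colour.
#' @return A ggplot object.
#' @export
plot_overlay <- function(frame, seg, gold = NULL) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(frame)), times = ncol(frame)),
    col = rep(seq_len(ncol(frame)), each = nrow(frame)),
    intensity = as.vector(frame),
    seg = as.vector(seg) != 0,
    gold = if (is.null(gold)) FALSE else as.vector(gold) != 0
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::geom_point(data = df[df$seg, ], colour = "green",
                        size = 0.1) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (!is.null(gold)) {
    p <- p + ggplot2::geom_point(data = df[df$gold & !df$seg, ],
                                 colour = "red", size = 0.1)
  }
  p
}
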