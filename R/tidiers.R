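#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained U-Net fit
#'
#' `tidy()` returns the per-epoch training-loss curve; `glance()` returns a
#' one-row summary with the best (lowest) loss, its first epoch, and the
#' final loss.
#'
#' @param x A `"unet_fit"` from [train_unet()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.unet_fit <- function(x, ...) {
  x$history
}

#' @rdname tidy.unet_fit
#' @export
glance.unet_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_loss = x$best_loss,
    final_loss = x$history$loss[nrow(x$history)],
    loss = x$config$loss$name,
    augment = x$config$augment
  )
}

#' Tidy a patient-wise split
#'
#' One row per patient with its assigned side.
#'
#' @param x A `"split_spec"` from [patient_split()].
#' @param ... Unused.
#' @return A tibble with columns `patient_id`, `side`.
#' @export
tidy.split_spec <- function(x, ...) {
  tibble::tibble(
    patient_id = c(x$train_patients, x$test_patients),
    side = rep(c("train", "test"),
               c(length(x$train_patients), length(x$test_patients)))
  ) |> dplyr::arrange(.data$patient_id)
}
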