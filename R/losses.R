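#' Training cost functions
#'
#' Binary cross-entropy and the alpha-balanced focal loss for per-pixel
#' foreground probabilities against a binary gold-standard mask.  Writing
#' `q_i = p_i` for foreground pixels and `q_i = 1 - p_i` for background
#' pixels, cross-entropy is `-sum_i log(q_i)` and the focal loss is
#' `-sum_i alpha_i (1 - q_i)^gamma log(q_i)` with `alpha_i = alpha` on
#' foreground and `1 - alpha` on background.  The modulating factor
#' `(1 - q_i)^gamma` down-weights confidently classified (easy) pixels,
#' which in a frame that is >99% background are overwhelmingly easy
#' negatives; `alpha` rebalances the two classes directly.
#'
#' Both functions return the sum over all pixels by default (the natural
#' per-image total); `reduction = "mean"` divides by the pixel count, the
#' convention used when reporting per-epoch training loss values.
#' Probabilities are clipped to `[epsilon, 1 - epsilon]` before taking
#' logarithms.
#'
#' @param pred Numeric matrix of foreground probabilities in `[0, 1]`.
#' @param gold Binary matrix (0/1) of the same shape.
#' @param epsilon Clipping constant for the logarithms, in `(0, 1e-3]`.
#' @param reduction `"sum"` (default) or `"mean"` over pixels.
#' @return A non-negative scalar.
#' @examples
#' p <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2)
#' y <- matrix(c(1, 0, 0, 1), 2, 2)
#' cross_entropy(p, y)
#' focal_loss(p, y, alpha = 0.25, gamma = 2)
#' @export
cross_entropy <- function(pred, gold, epsilon = 1e-7, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  check_loss_inputs(pred, gold, epsilon)
  p <- pmin(pmax(pred, epsilon), 1 - epsilon)
  v <- -sum(gold * log(p) + (1 - gold) * log(1 - p))
  if (reduction == "mean") v / length(pred) else v
}

#' @rdname cross_entropy
#' @param alpha Class-balance weight in `[0, 1]` applied to foreground
#'   pixels (background gets `1 - alpha`); default 0.25.
#' @param gamma Non-negative focusing parameter; `gamma = 0` reduces the
#'   modulating factor to 1.  Default 2.
#' @export
focal_loss <- function(pred, gold, alpha = 0.25, gamma = 2, epsilon = 1e-7,
                       reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  check_loss_inputs(pred, gold, epsilon)
  if (alpha < 0 || alpha > 1) stop_thinseg("alpha must be in [0, 1]")
  if (gamma < 0) stop_thinseg("gamma must be >= 0")
  p <- pmin(pmax(pred, epsilon), 1 - epsilon)
  q <- gold * p + (1 - gold) * (1 - p)
  a <- gold * alpha + (1 - gold) * (1 - alpha)
  v <- -sum(a * (1 - q)^gamma * log(q))
  if (reduction == "mean") v / length(pred) else v
}

check_loss_inputs <- function(pred, gold, epsilon) {
  check_same_shape(pred, gold, "prediction", "gold")
  if (any(pred < 0 | pred > 1)) {
    stop_thinseg("prediction entries must lie in [0, 1]")
  }
  if (!all(gold %in% c(0, 1))) {
    stop_thinseg("gold mask must be binary (0/1)")
  }
  if (epsilon <= 0 || epsilon > 1e-3) {
    stop_thinseg("epsilon must be in (0, 1e-3]")
  }
  invisible(TRUE)
}

#' Loss configuration
#'
#' Bundles the loss choice and its parameters for the training harness.
#'
#' @param name `"cross_entropy"` or `"focal"`.
#' @param alpha,gamma Focal-loss parameters (ignored for cross-entropy);
#'   the defaults `alpha = 0.25`, `gamma = 2` are the values that tune best
#'   for THV segmentation.
#' @param epsilon Log-clipping constant.
#' @return A list of class `"loss_config"`.
#' @export
loss_config <- function(name = c("cross_entropy", "focal"), alpha = 0.25,
                        gamma = 2, epsilon = 1e-7) {
  name <- match.arg(name)
  if (alpha < 0 || alpha > 1) stop_thinseg("alpha must be in [0, 1]")
  if (gamma < 0) stop_thinseg("gamma must be >= 0")
  if (epsilon <= 0 || epsilon > 1e-3) {
    stop_thinseg("epsilon must be in (0, 1e-3]")
  }
  structure(list(name = name, alpha = alpha, gamma = gamma,
                 epsilon = epsilon),
            class = "loss_config")
}
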