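#' U-Net configuration and construction
#'
#' A compact U-Net encoder-decoder with skip connections for per-pixel
#' foreground probability prediction.  Each encoder level applies two 3x3
#' same-padded convolutions (ReLU) followed by 2x2 max-pooling, with the
#' filter count doubling per level from `base_filters`; the symmetric
#' decoder upsamples (nearest neighbour + 2x2 convolution), concatenates
#' the matching encoder features, and applies two further 3x3
#' convolutions.  A final 1x1 convolution with a sigmoid yields a
#' probability map the same size as the input — the *prediction*; its
#' binarized version is a *segmentation*.
#'
#' Same-padding keeps the output size equal to the input size, which the
#' 512-in/512-out contract requires.  The faithful full-scale configuration
#' is `base_filters = 64`, `depth = 4`, `input_size = 512`; tests and
#' examples use much smaller profiles.
#'
#' Weights are He-normal initialized; the output bias starts at the
#' background-prior logit `log(pi / (1 - pi))` with `pi = 0.01`, the
#' standard initialization for heavily imbalanced dense prediction (it
#' stops the first epochs from being dominated by the easy background
#' gradient).
#'
#' @param base_filters Filters in the first convolutional layer.
#' @param depth Number of pooling (and mirrored upsampling) levels.
#' @param input_size Side length of the square input; must be divisible by
#'   `2^depth`.
#' @param seed Integer seed for weight initialization.
#' @return `net_config()` returns a validated list of class
#'   `"net_config"`; `build_unet()` returns an object of class `"unet"`.
#' @export
net_config <- function(base_filters = 64L, depth = 4L, input_size = 512L,
                       seed = 1L) {
  if (base_filters < 1 || depth < 1) {
    stop_thinseg("base_filters and depth must be >= 1")
  }
  if (input_size %% (2^depth) != 0) {
    stop_thinseg("input_size (", input_size,
                 ") must be divisible by 2^depth (", 2^depth, ")")
  }
  structure(list(base_filters = as.integer(base_filters),
                 depth = as.integer(depth),
                 input_size = as.integer(input_size),
                 seed = as.integer(seed)),
            class = "net_config")
}

#' @rdname net_config
#' @param config A [net_config()] object.
#' @export
build_unet <- function(config = net_config()) {
  if (!inherits(config, "net_config")) {
    stop_thinseg("config must be created with net_config()")
  }
  f <- config$base_filters
  d <- config$depth
  he_conv <- function(cin, cout, kh, kw) {
    fan_in <- cin * kh * kw
    matrix(rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), cout, fan_in)
  }
  params <- local_seed(config$seed, {
    p <- list()
    cin <- 1L
    for (i in seq_len(d)) {
      ci <- f * 2^(i - 1)
      p[[sprintf("enc%d_c1_w", i)]] <- he_conv(cin, ci, 3, 3)
      p[[sprintf("enc%d_c1_b", i)]] <- numeric(ci)
      p[[sprintf("enc%d_c2_w", i)]] <- he_conv(ci, ci, 3, 3)
      p[[sprintf("enc%d_c2_b", i)]] <- numeric(ci)
      cin <- ci
    }
    cb <- f * 2^d
    p[["bot_c1_w"]] <- he_conv(cin, cb, 3, 3)
    p[["bot_c1_b"]] <- numeric(cb)
    p[["bot_c2_w"]] <- he_conv(cb, cb, 3, 3)
    p[["bot_c2_b"]] <- numeric(cb)
    for (i in rev(seq_len(d))) {
      ci <- f * 2^(i - 1)
      cabove <- if (i == d) cb else f * 2^i
      p[[sprintf("dec%d_up_w", i)]] <- he_conv(cabove, ci, 2, 2)
      p[[sprintf("dec%d_up_b", i)]] <- numeric(ci)
      p[[sprintf("dec%d_c1_w", i)]] <- he_conv(2 * ci, ci, 3, 3)
      p[[sprintf("dec%d_c1_b", i)]] <- numeric(ci)
      p[[sprintf("dec%d_c2_w", i)]] <- he_conv(ci, ci, 3, 3)
      p[[sprintf("dec%d_c2_b", i)]] <- numeric(ci)
    }
    p[["out_w"]] <- he_conv(f, 1L, 1, 1)
    prior <- 0.01
    p[["out_b"]] <- log(prior / (1 - prior))
    p
  })
  structure(list(params = params, config = config), class = "unet")
}

#' @export
print.unet <- function(x, ...) {
  npar <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(
    "U-Net: depth %d, %d base filters, %dx%d input, %s parameters\n",
    x$config$depth, x$config$base_filters, x$config$input_size,
    x$config$input_size, format(npar, big.mark = ",")
  ))
  invisible(x)
}

#' Predict a probability map
#'
#' @param object A `"unet"` model.
#' @param frame Integer matrix 0-255 matching the model's input size.
#' @param ... Unused.
#' @return Numeric matrix of foreground probabilities in `[0, 1]`, same
#'   shape as `frame`; no thresholding is applied.
#' @export
predict.unet <- function(object, frame, ...) {
  n <- object$config$input_size
  if (nrow(frame) != n || ncol(frame) != n) {
    stop_thinseg("frame is ", nrow(frame), "x", ncol(frame),
                 " but the model expects ", n, "x", n)
  }
  res <- cpp_unet_run(object$params, frame / 255, object$config$depth,
                      FALSE, matrix(0, 1, 1), 0L, 0, 0, 0)
  res$pred
}

#' Jointly augment a frame/mask pair
#'
#' Samples one random geometric transform — translation (uniform within
#' +/-10% of the image size per axis), zoom (uniform in 0.9-1.1), rotation
#' (uniform within +/-15 degrees) and a horizontal flip with probability
#' 0.5 — and applies the *identical* transform to frame and mask.  The
#' frame is bilinearly interpolated with out-of-frame areas filled with its
#' median intensity; the mask uses nearest-neighbour resampling and is
#' re-binarized.  All ranges are configurable; the defaults keep the device
#' inside the frame.
#'
#' @param frame Integer matrix 0-255.
#' @param mask Binary 0/1 matrix of the same shape.
#' @param seed Integer seed for the transform draw.
#' @param max_translate Translation range as a fraction of the image size.
#' @param zoom_range Length-2 zoom factor range.
#' @param max_rotate Rotation range in degrees.
#' @param flip_prob Probability of a horizontal flip.
#' @return A list with transformed `frame` and `mask`.
#' @export
augment_pair <- function(frame, mask, seed = NULL, max_translate = 0.1,
                         zoom_range = c(0.9, 1.1), max_rotate = 15,
                         flip_prob = 0.5) {
  check_same_shape(frame, mask, "frame", "mask")
  draw <- function() {
    list(
      tx = runif(1, -max_translate, max_translate) * ncol(frame),
      ty = runif(1, -max_translate, max_translate) * nrow(frame),
      zoom = runif(1, zoom_range[1], zoom_range[2]),
      rot = runif(1, -max_rotate, max_rotate) * pi / 180,
      flip = runif(1) < flip_prob
    )
  }
  tr <- if (is.null(seed)) draw() else local_seed(seed, draw())
  apply_affine_pair(frame, mask, tr)
}

# Apply one sampled transform to a frame/mask pair.  The identity draw
# returns the pair untouched (exactly), which also documents the transform
# convention: inverse-mapped resampling about the image centre.
apply_affine_pair <- function(frame, mask, tr) {
  if (tr$tx == 0 && tr$ty == 0 && tr$zoom == 1 && tr$rot == 0 && !tr$flip) {
    return(list(frame = frame, mask = mask))
  }
  n_r <- nrow(frame)
  n_c <- ncol(frame)
  cy <- (n_r + 1) / 2
  cx <- (n_c + 1) / 2
  # output pixel grid -> source coordinates (inverse map)
  co <- matrix(rep(seq_len(n_c), each = n_r), n_r, n_c) - cx - tr$tx
  ro <- matrix(rep(seq_len(n_r), times = n_c), n_r, n_c) - cy - tr$ty
  ca <- cos(-tr$rot)
  sa <- sin(-tr$rot)
  sx <- (co * ca - ro * sa) / tr$zoom
  sy <- (co * sa + ro * ca) / tr$zoom
  if (tr$flip) sx <- -sx
  sx <- sx + cx
  sy <- sy + cy
  fill <- stats::median(frame)
  fr <- bilinear_sample(frame, sy, sx, fill)
  mk <- bilinear_sample(mask, round(sy), round(sx), 0)  # nearest neighbour
  list(
    frame = matrix(as.integer(round(pmin(255, pmax(0, fr)))), n_r, n_c),
    mask = matrix(as.integer(mk > 0.5), n_r, n_c)
  )
}

# vectorized bilinear lookup with constant fill outside the image
bilinear_sample <- function(img, sy, sx, fill) {
  n_r <- nrow(img)
  n_c <- ncol(img)
  y0 <- floor(sy)
  x0 <- floor(sx)
  wy <- sy - y0
  wx <- sx - x0
  at <- function(r, c) {
    ok <- r >= 1 & r <= n_r & c >= 1 & c <= n_c
    v <- rep(fill, length(r))
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  v <- (1 - wy) * (1 - wx) * at(y0, x0) +
    (1 - wy) * wx * at(y0, x0 + 1) +
    wy * (1 - wx) * at(y0 + 1, x0) +
    wy * wx * at(y0 + 1, x0 + 1)
  matrix(v, n_r, n_c)
}

#' Training configuration
#'
#' @param epochs Training epochs (30 for tuning-grid models, 50 for the
#'   final model, by convention).
#' @param batch_size Images per optimizer step.
#' @param learning_rate Adam learning rate.
#' @param augment Apply on-the-fly augmentation ([augment_pair()]) so the
#'   network never sees the same image twice across epochs.
#' @param loss A [loss_config()].
#' @param seed Integer seed controlling shuffling and augmentation draws.
#' @param shuffle Reshuffle the presentation order each epoch.
#' @param restore_best Return the weights from the epoch with the lowest
#'   training loss instead of the last epoch (default last epoch).
#' @param loss_reporting `"mean"` (per-pixel average, the convention for
#'   reported per-epoch loss values) or `"sum"`.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(epochs = 30L, batch_size = 2L,
                         learning_rate = 1e-4, augment = FALSE,
                         loss = loss_config("cross_entropy"), seed = 1L,
                         shuffle = TRUE, restore_best = FALSE,
                         loss_reporting = c("mean", "sum")) {
  if (epochs < 1 || batch_size < 1) {
    stop_thinseg("epochs and batch_size must be >= 1")
  }
  if (learning_rate <= 0) stop_thinseg("learning_rate must be > 0")
  if (!inherits(loss, "loss_config")) {
    stop_thinseg("loss must be a loss_config()")
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, augment = augment,
                 loss = loss, seed = as.integer(seed), shuffle = shuffle,
                 restore_best = restore_best,
                 loss_reporting = match.arg(loss_reporting)),
            class = "train_config")
}

#' Train a U-Net
#'
#' Minimizes the configured cost function with Adam (default hyper-
#' parameters beta1 = 0.9, beta2 = 0.999, eps = 1e-8), presenting the
#' training pairs in (optionally shuffled) mini-batches; with augmentation
#' enabled each presentation is a freshly transformed variant.  The
#' per-epoch training loss, the best (lowest) loss and its first epoch are
#' recorded.  Fully deterministic given the seeds.
#'
#' @param model A `"unet"` from [build_unet()].
#' @param frames List of integer matrices (0-255).
#' @param masks List of binary 0/1 matrices, aligned with `frames`.
#' @param config A [train_config()].
#' @param verbose Print `epoch,loss` log lines.
#' @return An object of class `"unet_fit"`: list with the trained `model`,
#'   `history` (tibble `epoch`, `loss`), `best_epoch`, `best_loss`, and
#'   `config`.
#' @export
train_unet <- function(model, frames, masks, config = train_config(),
                       verbose = FALSE) {
  if (!inherits(model, "unet")) stop_thinseg("model must be a unet")
  if (length(frames) == 0) stop_thinseg("empty training set")
  if (length(frames) != length(masks)) {
    stop_thinseg("frames and masks must have the same length")
  }
  if (length(frames) < config$batch_size) {
    stop_thinseg("need at least batch_size (", config$batch_size,
                 ") training pairs")
  }
  loss_type <- if (config$loss$name == "cross_entropy") 1L else 2L
  npix <- length(frames[[1]])

  params <- model$params
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  b1 <- 0.9
  b2 <- 0.999
  adam_eps <- 1e-8
  t_step <- 0
  lr <- config$learning_rate

  history <- numeric(config$epochs)
  best_loss <- Inf
  best_epoch <- NA_integer_
  best_params <- NULL

  local_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- if (config$shuffle) {
        sample(length(frames))
      } else seq_along(frames)
      epoch_loss <- 0
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      for (batch in batches) {
        grads <- NULL
        for (idx in batch) {
          fr <- frames[[idx]]
          mk <- masks[[idx]]
          if (config$augment) {
            aug <- augment_pair(fr, mk)
            fr <- aug$frame
            mk <- aug$mask
          }
          res <- cpp_unet_run(params, fr / 255, model$config$depth, TRUE,
                              matrix(as.numeric(mk), nrow(mk)), loss_type,
                              config$loss$alpha, config$loss$gamma,
                              config$loss$epsilon)
          epoch_loss <- epoch_loss + res$loss
          grads <- if (is.null(grads)) {
            res$grads
          } else {
            Map(`+`, grads, res$grads[names(grads)])
          }
        }
        t_step <- t_step + 1
        corr <- sqrt(1 - b2^t_step) / (1 - b1^t_step)
        for (nm in names(params)) {
          g <- grads[[nm]]
          m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g
          v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g^2
          params[[nm]] <- params[[nm]] -
            lr * corr * m[[nm]] / (sqrt(v[[nm]]) + adam_eps)
        }
      }
      history[epoch] <- if (config$loss_reporting == "mean") {
        epoch_loss / (length(frames) * npix)
      } else {
        epoch_loss / length(frames)
      }
      if (history[epoch] < best_loss) {
        best_loss <- history[epoch]
        best_epoch <- epoch
        if (config$restore_best) best_params <- params
      }
      if (verbose) cat(sprintf("%d,%g\n", epoch, history[epoch]))
    }
  })

  model$params <- if (config$restore_best && !is.null(best_params)) {
    best_params
  } else {
    params
  }
  structure(
    list(model = model,
         history = tibble::tibble(epoch = seq_len(config$epochs),
                                  loss = history),
         best_epoch = best_epoch, best_loss = best_loss, config = config),
    class = "unet_fit"
  )
}

#' @export
print.unet_fit <- function(x, ...) {
  cat(sprintf(
    "unet_fit: %d epochs (%s loss), best %.6g at epoch %d, final %.6g\n",
    nrow(x$history), x$config$loss$name, x$best_loss, x$best_epoch,
    x$history$loss[nrow(x$history)]
  ))
  invisible(x)
}

#' @export
predict.unet_fit <- function(object, frame, ...) {
  predict(object$model, frame, ...)
}
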