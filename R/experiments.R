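#' Hyperparameter-tuning grid specification
#'
#' The tuning design crosses nested training-set sizes, the use of data
#' augmentation, and the cost function; the default
#' `4 sizes x 2 DA x 2 losses` grid yields 16 models, all evaluated on the
#' identical expanded-stage test frames.
#'
#' @param training_sizes Strictly increasing subset sizes.
#' @param augment_options Logical vector of augmentation settings.
#' @param loss_options Character vector among `"cross_entropy"`, `"focal"`.
#' @param epochs,batch_size,learning_rate Shared training parameters.
#' @param alpha,gamma Focal-loss parameters.
#' @param pkfp_k PKFP foreground budget used in evaluation.
#' @param seed Integer master seed.
#' @return A list of class `"grid_spec"`; `grid_cells()` expands it to a
#'   tibble with one row per grid cell.
#' @export
grid_spec <- function(training_sizes = c(75L, 150L, 300L, 600L),
                      augment_options = c(FALSE, TRUE),
                      loss_options = c("cross_entropy", "focal"),
                      epochs = 30L, batch_size = 2L, learning_rate = 1e-4,
                      alpha = 0.25, gamma = 2, pkfp_k = 2500L, seed = 1L) {
  if (any(diff(as.integer(training_sizes)) <= 0)) {
    stop_thinseg("training_sizes must be strictly increasing")
  }
  if (!all(loss_options %in% c("cross_entropy", "focal"))) {
    stop_thinseg("loss_options must be among cross_entropy, focal")
  }
  structure(list(training_sizes = as.integer(training_sizes),
                 augment_options = augment_options,
                 loss_options = loss_options, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, alpha = alpha,
                 gamma = gamma, pkfp_k = as.integer(pkfp_k),
                 seed = as.integer(seed)),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @param grid A `grid_spec`.
#' @export
grid_cells <- function(grid) {
  tidyr::expand_grid(
    training_size = grid$training_sizes,
    augment = grid$augment_options,
    loss = grid$loss_options
  )
}

# load frames/masks for manifest rows; uses in-memory list-columns `frame`
# and `mask` when present, otherwise reads the referenced PNGs
load_pairs <- function(rows) {
  if (all(c("frame", "mask") %in% names(rows))) {
    list(frames = rows$frame, masks = rows$mask)
  } else {
    list(frames = lapply(rows$frame_path, read_frame),
         masks = lapply(rows$mask_path, read_mask))
  }
}

row_key <- function(rows) {
  paste(rows$patient_id, rows$sequence_id, rows$frame_index)
}

#' Run the hyperparameter-tuning grid
#'
#' Trains one model per grid cell — each training-set size drawn as a
#' nested subset of the training side of `split` — and evaluates every
#' model on the *same* expanded-stage test frames, recording the best
#' epoch/loss and the mean +/- sd of D1 (under Otsu and PKFP
#' binarizations) and D2.
#'
#' @param manifest Dataset manifest tibble; may carry in-memory
#'   list-columns `frame`/`mask` instead of file paths.
#' @param split A [patient_split()] result.
#' @param grid A [grid_spec()].
#' @param net A [net_config()] shared by all cells.
#' @param verbose Print one line per completed cell.
#' @return A tibble with one row per cell: `training_size`, `augment`,
#'   `loss`, `best_epoch`, `best_loss`, `d1_otsu_mean/sd`,
#'   `d1_pkfp_mean/sd`, `d2_mean/sd`, plus a list-column `history` of
#'   per-epoch loss tibbles, of class `"thv_grid"`.
#' @export
run_grid <- function(manifest, split, grid, net = net_config(),
                     verbose = FALSE) {
  train_rows <- manifest[manifest$patient_id %in% split$train_patients, ]
  test_rows <- manifest[manifest$patient_id %in% split$test_patients &
                          manifest$stage == "expanded", ]
  if (nrow(test_rows) == 0) {
    stop_thinseg("test side holds no expanded-stage frames")
  }
  subsets <- nested_subsets(train_rows, grid$training_sizes,
                            seed = grid$seed)
  test <- load_pairs(test_rows)
  cells <- grid_cells(grid)

  records <- purrr::pmap(cells, function(training_size, augment, loss) {
    rows <- subsets[[paste0("n", training_size)]]
    pairs <- load_pairs(rows)
    cell_seed <- grid$seed + 7L * training_size +
      1000L * augment + 10000L * (loss == "focal")
    fit <- tryCatch(
      train_unet(
        build_unet(net_config(net$base_filters, net$depth, net$input_size,
                              seed = cell_seed)),
        pairs$frames, pairs$masks,
        train_config(
          epochs = grid$epochs, batch_size = grid$batch_size,
          learning_rate = grid$learning_rate, augment = augment,
          loss = loss_config(loss, alpha = grid$alpha, gamma = grid$gamma),
          seed = cell_seed
        )
      ),
      error = function(e) {
        stop_thinseg(sprintf(
          "training failed for cell (size=%d, augment=%s, loss=%s): %s",
          training_size, augment, loss, conditionMessage(e)
        ))
      }
    )
    ev <- purrr::map2(test$masks, test$frames, function(g, fr) {
      p <- predict(fit$model, fr)
      tibble::tibble(
        d1_otsu = metric_d1(g, binarize_otsu(p)),
        d1_pkfp = metric_d1(g, binarize_pkfp(p, grid$pkfp_k)),
        d2 = metric_d2(g, p)
      )
    }) |> dplyr::bind_rows()
    agg <- aggregate_metrics(ev)
    stat <- function(metric, col) {
      agg[[col]][agg$metric == metric]
    }
    if (verbose) {
      cat(sprintf("cell size=%d augment=%d loss=%s: D1(otsu)=%.3f D2=%.1f\n",
                  training_size, augment, loss,
                  stat("d1_otsu", "mean"), stat("d2", "mean")))
    }
    tibble::tibble(
      training_size = training_size, augment = augment, loss = loss,
      best_epoch = fit$best_epoch, best_loss = fit$best_loss,
      d1_otsu_mean = stat("d1_otsu", "mean"),
      d1_otsu_sd = stat("d1_otsu", "sd"),
      d1_pkfp_mean = stat("d1_pkfp", "mean"),
      d1_pkfp_sd = stat("d1_pkfp", "sd"),
      d2_mean = stat("d2", "mean"), d2_sd = stat("d2", "sd"),
      test_rows = list(row_key(test_rows)),
      history = list(fit$history)
    )
  })
  out <- dplyr::bind_rows(records)
  class(out) <- c("thv_grid", class(out))
  out
}

#' Closest-to-origin model selection
#'
#' Normalizes each configuration's mean D1 and mean D2 by the worst
#' (largest) mean of that metric across the records, then selects the
#' record with the smallest Euclidean norm of the normalized pair — the
#' configuration "closest to the origin" of the normalized D1-D2 plane.
#' Ties are broken by the smaller (unnormalized) D1 mean, then by
#' lexicographic configuration (loss, augment, training size).  Records
#' with undefined means are excluded with a warning.
#'
#' @param records A grid-record tibble from [run_grid()] (or hand-built
#'   with the same columns).
#' @param d1 Which D1 column drives selection: `"otsu"`, `"pkfp"`, or
#'   `"per_loss"` to use the binarization each cost function prefers
#'   (Otsu for cross-entropy, PKFP for focal).
#' @return The winning record (one-row tibble) with the normalized
#'   coordinates and norm attached as columns `d1_norm`, `d2_norm`,
#'   `norm`.
#' @export
select_best <- function(records, d1 = c("otsu", "pkfp", "per_loss")) {
  d1 <- match.arg(d1)
  if (nrow(records) < 1) stop_thinseg("need at least one record")
  d1_mean <- switch(d1,
    otsu = records$d1_otsu_mean,
    pkfp = records$d1_pkfp_mean,
    per_loss = ifelse(records$loss == "focal", records$d1_pkfp_mean,
                      records$d1_otsu_mean)
  )
  ok <- !is.na(d1_mean) & !is.na(records$d2_mean)
  if (any(!ok)) {
    warning(sum(!ok), " record(s) with undefined means excluded from ",
            "selection")
  }
  if (!any(ok)) stop_thinseg("no records with defined means")
  r <- records[ok, ]
  d1v <- d1_mean[ok]
  worst_d1 <- max(d1v)
  worst_d2 <- max(r$d2_mean)
  d1n <- if (worst_d1 > 0) d1v / worst_d1 else d1v
  d2n <- if (worst_d2 > 0) r$d2_mean / worst_d2 else r$d2_mean
  nrm <- sqrt(d1n^2 + d2n^2)
  cfg <- paste(r$loss, r$augment, sprintf("%09d", r$training_size))
  ord <- order(nrm, d1v, cfg)
  win <- r[ord[1], ]
  win$d1_norm <- d1n[ord[1]]
  win$d2_norm <- d2n[ord[1]]
  win$norm <- nrm[ord[1]]
  win
}

#' Frame-type-stratified evaluation
#'
#' Evaluates a trained model separately on each frame type present in the
#' test manifest (expanded, no-device, deploying, contrast), running the
#' prediction, both binarizations, and the full metric suite per stratum.
#' Cells that are undefined for a stratum — D1 and AUROC on frames without
#' the device — are reported as `NA` with their skip counts.
#'
#' @param model A `"unet"` or `"unet_fit"`.
#' @param manifest Test manifest tibble (optionally with in-memory
#'   list-columns `frame`/`mask`).
#' @param pkfp_k PKFP foreground budget.
#' @param auroc_on Passed to [evaluate_frame()].
#' @return A tibble with columns `stage`, `metric`, `mean`, `sd`,
#'   `n_defined`, `n_skipped`, `n_frames`.
#' @export
evaluate_by_frame_type <- function(model, manifest, pkfp_k = 2500L,
                                   auroc_on = c("seg", "pred")) {
  auroc_on <- match.arg(auroc_on)
  if (inherits(model, "unet_fit")) model <- model$model
  stages <- unique(manifest$stage)
  out <- purrr::map(stages, function(st) {
    rows <- manifest[manifest$stage == st, ]
    pairs <- load_pairs(rows)
    evals <- purrr::map2(pairs$masks, pairs$frames, function(g, fr) {
      evaluate_frame(g, predict(model, fr), pkfp_k = pkfp_k,
                     auroc_on = auroc_on)
    }) |> dplyr::bind_rows()
    agg <- aggregate_metrics(evals)
    agg$stage <- st
    agg$n_frames <- nrow(rows)
    agg
  }) |> dplyr::bind_rows()
  dplyr::relocate(out, "stage")
}

#' Train the final model
#'
#' Retrains the winning configuration on the whole training side of the
#' split (not just a nested subset), by convention with the epoch budget
#' raised to 50 for better parameter estimates.
#'
#' @param manifest Dataset manifest.
#' @param split A [patient_split()].
#' @param loss,augment Winning configuration.
#' @param epochs Epoch budget.
#' @param net A [net_config()].
#' @param alpha,gamma,batch_size,learning_rate,seed Training parameters.
#' @return A `"unet_fit"`.
#' @export
final_train <- function(manifest, split, loss = "cross_entropy",
                        augment = FALSE, epochs = 50L, net = net_config(),
                        alpha = 0.25, gamma = 2, batch_size = 2L,
                        learning_rate = 1e-4, seed = 1L) {
  train_rows <- manifest[manifest$patient_id %in% split$train_patients, ]
  pairs <- load_pairs(train_rows)
  train_unet(
    build_unet(net_config(net$base_filters, net$depth, net$input_size,
                          seed = seed)),
    pairs$frames, pairs$masks,
    train_config(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, augment = augment,
                 loss = loss_config(loss, alpha = alpha, gamma = gamma),
                 seed = seed)
  )
}
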