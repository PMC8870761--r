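#' Imbalance-aware distance metrics D1 and D2
#'
#' With the THV occupying under 1% of the pixels, overlap metrics reward a
#' segmentation that predicts almost nothing; the pair D1/D2 was designed
#' for this regime.
#'
#' `metric_d1()` is the mean, over the `K` foreground pixels `g` of the
#' gold standard `G`, of the Euclidean distance (in pixels) to the nearest
#' foreground pixel of the segmentation `S`:
#' `D1(G, S) = (1/K) * sum_g min_s d(g, s)`.  It is 0 for a perfect
#' segmentation — but also for an all-ones segmentation, which is why it is
#' paired with D2.
#'
#' `metric_d2()` aggregates the predicted probability mass sitting outside
#' the gold foreground: `D2(G, P) = sum over background pixels of P`.  It
#' is a soft false-positive measure and is always computed on the
#' probability map, never on a binarization (for a binary map it equals the
#' false-positive count).
#'
#' Undefined cases return `NA`: D1 needs a nonempty gold mask (no pattern
#' to identify otherwise) and a nonempty segmentation (no distances exist).
#'
#' @param gold Binary 0/1 matrix (gold-standard mask).
#' @param seg Binary 0/1 matrix (segmentation).
#' @param pred Numeric probability matrix in `[0, 1]`.
#' @return A scalar; `NA` when undefined.
#' @export
metric_d1 <- function(gold, seg) {
  check_same_shape(gold, seg, "gold", "segmentation")
  if (sum(gold) == 0) return(NA_real_)
  if (sum(seg) == 0) return(NA_real_)
  dt <- edt(seg)
  mean(dt[gold != 0])
}

#' @rdname metric_d1
#' @export
metric_d2 <- function(gold, pred) {
  check_same_shape(gold, pred, "gold", "prediction")
  sum(pred[gold == 0])
}

#' Hausdorff distance between two binary masks
#'
#' The greatest of all distances from a point in one foreground set to the
#' closest point of the other, made symmetric:
#' `HD(G, S) = max(h(G, S), h(S, G))` with
#' `h(A, B) = max_a min_b d(a, b)` the directed distance.  Both directed
#' values are returned as attributes `"directed_gs"` and `"directed_sg"`.
#'
#' @inheritParams metric_d1
#' @return Symmetric Hausdorff distance in pixels (`NA` if either set is
#'   empty), with the two directed distances attached as attributes.
#' @export
metric_hausdorff <- function(gold, seg) {
  check_same_shape(gold, seg, "gold", "segmentation")
  if (sum(gold) == 0 || sum(seg) == 0) return(NA_real_)
  h_gs <- max(edt(seg)[gold != 0])  # gold points -> nearest seg point
  h_sg <- max(edt(gold)[seg != 0])
  structure(max(h_gs, h_sg), directed_gs = h_gs, directed_sg = h_sg)
}

#' Conventional pixel-wise classification metrics
#'
#' Accuracy, precision, recall, Dice coefficient and Jaccard index from the
#' per-pixel confusion counts of a binary segmentation against the gold
#' standard.  When a denominator vanishes with no true-positive overlap
#' (e.g. on frames without the device), precision, recall, Dice and Jaccard
#' are reported as 0.
#'
#' @inheritParams metric_d1
#' @return A one-row tibble with columns `accuracy`, `precision`, `recall`,
#'   `dice`, `jaccard`, `tp`, `fp`, `fn`, `tn`.
#' @export
pixel_metrics <- function(gold, seg) {
  check_same_shape(gold, seg, "gold", "segmentation")
  g <- gold != 0
  s <- seg != 0
  tp <- sum(g & s)
  fp <- sum(!g & s)
  fn <- sum(g & !s)
  tn <- sum(!g & !s)
  safe <- function(num, den) if (den == 0) 0 else num / den
  tibble::tibble(
    accuracy = (tp + tn) / (tp + fp + fn + tn),
    precision = safe(tp, tp + fp),
    recall = safe(tp, tp + fn),
    dice = safe(2 * tp, 2 * tp + fp + fn),
    jaccard = safe(tp, tp + fp + fn),
    tp = tp, fp = fp, fn = fn, tn = tn
  )
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC of per-pixel scores against the gold
#' labels, equivalent to trapezoidal integration of the ROC curve with tied
#' scores handled by mid-ranks.  Scores may be a probability map or a
#' binary segmentation; for a binary input the result degenerates to the
#' single-operating-point value `(TPR + TNR) / 2` and is reported only to
#' mirror the binarization-wise evaluation convention.
#'
#' @param gold Binary 0/1 matrix; must contain both classes, otherwise the
#'   AUROC is undefined and `NA` is returned.
#' @param scores Numeric matrix of scores (probability map or 0/1 mask).
#' @return AUROC in `[0, 1]`, or `NA` for single-class gold.
#' @export
metric_auroc <- function(gold, scores) {
  check_same_shape(gold, scores, "gold", "scores")
  g <- as.integer(gold != 0)
  npos <- sum(g)
  nneg <- length(g) - npos
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(as.numeric(scores))
  (sum(r[g == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Evaluate one frame
#'
#' Runs the full metric suite for a single prediction: D1 under Otsu and
#' PKFP binarizations, D2 on the probability map, Hausdorff distance, and
#' the pixel metrics and AUROC per binarization.
#'
#' @param gold Binary gold mask.
#' @param pred Probability map.
#' @param pkfp_k Foreground pixel budget for the PKFP binarization.
#' @param auroc_on `"pred"` computes AUROC from the probability map,
#'   `"seg"` from each binarized mask (the degenerate two-point AUC).
#' @return A one-row tibble (metrics suffixed `_otsu` / `_pkfp` where the
#'   binarization matters); undefined entries are `NA`.
#' @export
evaluate_frame <- function(gold, pred, pkfp_k = 2500L,
                           auroc_on = c("seg", "pred")) {
  auroc_on <- match.arg(auroc_on)
  segs <- list(
    otsu = tryCatch(binarize_otsu(pred),
                    error = function(e) matrix(0L, nrow(pred), ncol(pred))),
    pkfp = binarize_pkfp(pred, pkfp_k)
  )
  out <- tibble::tibble(d2 = metric_d2(gold, pred))
  for (nm in names(segs)) {
    s <- segs[[nm]]
    pm <- pixel_metrics(gold, s)
    sc <- if (auroc_on == "pred") pred else s
    block <- tibble::tibble(
      d1 = metric_d1(gold, s),
      hausdorff = as.numeric(metric_hausdorff(gold, s)),
      accuracy = pm$accuracy, precision = pm$precision,
      recall = pm$recall, dice = pm$dice, jaccard = pm$jaccard,
      auroc = metric_auroc(gold, sc)
    )
    names(block) <- paste0(names(block), "_", nm)
    out <- dplyr::bind_cols(out, block)
  }
  out
}

#' Aggregate per-frame evaluations
#'
#' Mean and standard deviation per metric over a set of frame evaluations,
#' skipping undefined (`NA`) entries and reporting how many were skipped.
#' The standard deviation is the sample (n-1) version, with 0 reported for
#' a single defined value.
#'
#' @param evals Tibble of per-frame evaluations (rows = frames), e.g. from
#'   [evaluate_frame()].
#' @return A tibble with columns `metric`, `mean`, `sd`, `n_defined`,
#'   `n_skipped`; metrics with no defined entries keep `NA` mean/sd.
#' @export
aggregate_metrics <- function(evals) {
  if (nrow(evals) < 1) stop_thinseg("need at least one evaluation")
  num <- dplyr::select(evals, dplyr::where(is.numeric))
  tidyr::pivot_longer(num, dplyr::everything(),
                      names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = if (any(!is.na(.data$value))) {
        mean(.data$value, na.rm = TRUE)
      } else NA_real_,
      sd = {
        v <- .data$value[!is.na(.data$value)]
        if (length(v) == 0) NA_real_ else if (length(v) == 1) 0 else sd(v)
      },
      n_defined = sum(!is.na(.data$value)),
      n_skipped = sum(is.na(.data$value)),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$metric, names(num)))
}
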