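# Brute-force oracles used to cross-check the metric implementations.
# These deliberately use the naive O(|G| x |S|) / exhaustive formulations.

fg_points <- function(mask) which(mask != 0, arr.ind = TRUE)

bf_d1 <- function(gold, seg) {
  g <- fg_points(gold)
  s <- fg_points(seg)
  if (nrow(g) == 0 || nrow(s) == 0) return(NA_real_)
  mean(vapply(seq_len(nrow(g)), function(i) {
    min(sqrt((s[, 1] - g[i, 1])^2 + (s[, 2] - g[i, 2])^2))
  }, numeric(1)))
}

bf_directed_hausdorff <- function(a, b) {
  pa <- fg_points(a)
  pb <- fg_points(b)
  if (nrow(pa) == 0 || nrow(pb) == 0) return(NA_real_)
  max(vapply(seq_len(nrow(pa)), function(i) {
    min(sqrt((pb[, 1] - pa[i, 1])^2 + (pb[, 2] - pa[i, 2])^2))
  }, numeric(1)))
}

bf_hausdorff <- function(gold, seg) {
  max(bf_directed_hausdorff(gold, seg), bf_directed_hausdorff(seg, gold))
}

bf_d2 <- function(gold, pred) {
  total <- 0
  for (r in seq_len(nrow(gold))) {
    for (c in seq_len(ncol(gold))) {
      if (gold[r, c] == 0) total <- total + pred[r, c]
    }
  }
  total
}

# exhaustive threshold-sweep trapezoidal AUROC
bf_auroc <- function(gold, scores) {
  g <- as.integer(gold != 0)
  npos <- sum(g)
  nneg <- length(g) - npos
  if (npos == 0 || nneg == 0) return(NA_real_)
  th <- sort(unique(as.numeric(scores)), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) sum(scores >= t & g == 1) / npos,
                     numeric(1)))
  fpr <- c(0, vapply(th, function(t) sum(scores >= t & g == 0) / nneg,
                     numeric(1)))
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

bf_confusion <- function(gold, seg) {
  g <- gold != 0
  s <- seg != 0
  c(tp = sum(g & s), fp = sum(!g & s), fn = sum(g & !s), tn = sum(!g & !s))
}

random_mask <- function(nr, nc, p = 0.1) {
  matrix(as.integer(runif(nr * nc) < p), nr, nc)
}
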