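test_that("D1 handles the defining and degenerate cases", {
  g <- random_mask(16, 16, 0.1)
  g[1, 1] <- 1L
  expect_equal(metric_d1(g, g), 0)
  # an all-ones segmentation still scores 0 — the blind spot D2 covers
  expect_equal(metric_d1(g, matrix(1L, 16, 16)), 0)

  # two single points at a 3-4-5 offset
  g1 <- matrix(0L, 8, 8); g1[1, 1] <- 1L
  s1 <- matrix(0L, 8, 8); s1[4, 5] <- 1L
  expect_equal(metric_d1(g1, s1), 5)
  expect_equal(bf_d1(g1, s1), 5)

  empty <- matrix(0L, 8, 8)
  expect_true(is.na(metric_d1(empty, s1)))  # no pattern to identify
  expect_true(is.na(metric_d1(g1, empty)))  # no distances exist
})

test_that("D2 sums the off-gold probability mass", {
  g <- random_mask(10, 10, 0.15)
  expect_equal(metric_d2(g, matrix(0, 10, 10)), 0)
  expect_equal(metric_d2(g, matrix(as.numeric(g), 10, 10)), 0)

  set.seed(21)
  p <- matrix(runif(100), 10, 10)
  expect_equal(metric_d2(g, p), bf_d2(g, p), tolerance = 1e-12)
  # empty gold: D2 is the total mass (the no-device scenario)
  expect_equal(metric_d2(matrix(0L, 10, 10), p), sum(p), tolerance = 1e-12)
  # for a binary map D2 equals the false-positive count
  s <- random_mask(10, 10, 0.2)
  expect_equal(metric_d2(g, s), unname(bf_confusion(g, s)["fp"]))
})

test_that("Hausdorff distance matches brute force and exposes both directions", {
  g1 <- matrix(0L, 8, 8); g1[1, 1] <- 1L
  s1 <- matrix(0L, 8, 8); s1[4, 5] <- 1L
  expect_equal(as.numeric(metric_hausdorff(g1, g1)), 0)
  expect_equal(as.numeric(metric_hausdorff(g1, s1)), 5)

  set.seed(31)
  for (i in 1:10) {
    g <- random_mask(12, 15, 0.12)
    s <- random_mask(12, 15, 0.12)
    if (sum(g) == 0 || sum(s) == 0) next
    h <- metric_hausdorff(g, s)
    expect_equal(as.numeric(h), bf_hausdorff(g, s), tolerance = 1e-9)
    expect_equal(attr(h, "directed_gs"), bf_directed_hausdorff(g, s),
                 tolerance = 1e-9)
    expect_equal(attr(h, "directed_sg"), bf_directed_hausdorff(s, g),
                 tolerance = 1e-9)
    # D1 is a mean of minima, the directed Hausdorff their max
    expect_lte(metric_d1(g, s), as.numeric(h) + 1e-12)
  }
  expect_true(is.na(metric_hausdorff(matrix(0L, 4, 4), s1[1:4, 1:4])))
})

test_that("pixel metrics reproduce explicit confusion counts", {
  g <- random_mask(9, 9, 0.2)
  g[2, 2] <- 1L
  perfect <- pixel_metrics(g, g)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$dice, 1)
  expect_equal(perfect$jaccard, 1)

  # disjoint nonempty masks: all overlap metrics 0
  a <- matrix(0L, 4, 4); a[1, 1] <- 1L
  b <- matrix(0L, 4, 4); b[4, 4] <- 1L
  pm <- pixel_metrics(a, b)
  expect_equal(c(pm$precision, pm$recall, pm$dice, pm$jaccard),
               c(0, 0, 0, 0))

  # 4x4 toy with TP=2, FP=1, FN=1, TN=12
  gold <- matrix(0L, 4, 4); gold[1, 1] <- 1L; gold[1, 2] <- 1L
  gold[2, 1] <- 1L
  seg <- matrix(0L, 4, 4); seg[1, 1] <- 1L; seg[1, 2] <- 1L
  seg[3, 3] <- 1L
  pm <- pixel_metrics(gold, seg)
  expect_identical(c(pm$tp, pm$fp, pm$fn, pm$tn), c(2L, 1L, 1L, 12L))
  expect_equal(pm$precision, 2 / 3)   # TP / (TP + FP)
  expect_equal(pm$recall, 2 / 3)      # TP / (TP + FN)
  expect_equal(pm$dice, 2 / 3)        # 2 TP / (2 TP + FP + FN)
  expect_equal(pm$jaccard, 1 / 2)     # TP / (TP + FP + FN)
  expect_equal(pm$accuracy, 14 / 16)
})

test_that("Dice and Jaccard obey their algebraic identity", {
  set.seed(41)
  for (i in 1:20) {
    g <- random_mask(10, 10, 0.3)
    s <- random_mask(10, 10, 0.3)
    pm <- pixel_metrics(g, s)
    expect_equal(pm$dice, 2 * pm$jaccard / (1 + pm$jaccard),
                 tolerance = 1e-12)
  }
})

test_that("AUROC agrees with the exhaustive ROC sweep and pROC", {
  g <- random_mask(8, 8, 0.3)
  g[1, 1] <- 1L; g[8, 8] <- 0L
  expect_equal(metric_auroc(g, matrix(as.numeric(g), 8, 8)), 1)
  expect_equal(metric_auroc(g, matrix(0.4, 8, 8)), 0.5)
  expect_true(is.na(metric_auroc(matrix(1L, 4, 4), matrix(runif(16), 4, 4))))
  expect_true(is.na(metric_auroc(matrix(0L, 4, 4), matrix(runif(16), 4, 4))))

  set.seed(51)
  for (i in 1:10) {
    g <- random_mask(10, 10, 0.25)
    if (sum(g) == 0 || sum(g) == 100) next
    p <- matrix(runif(100), 10, 10)
    expect_equal(metric_auroc(g, p), bf_auroc(g, p), tolerance = 1e-9)
    # binary scores: the two-operating-point trapezoid (TPR + TNR) / 2
    s <- random_mask(10, 10, 0.25)
    cm <- bf_confusion(g, s)
    expect_equal(metric_auroc(g, s),
                 (cm["tp"] / (cm["tp"] + cm["fn"]) +
                    cm["tn"] / (cm["tn"] + cm["fp"])) / 2,
                 ignore_attr = TRUE, tolerance = 1e-12)
  }

  skip_if_not_installed("pROC")
  set.seed(52)
  g <- random_mask(12, 12, 0.2)
  p <- matrix(runif(144), 12, 12)
  ref <- as.numeric(pROC::auc(pROC::roc(as.vector(g), as.vector(p),
                                        quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(metric_auroc(g, p), ref, tolerance = 1e-9)
})

test_that("distance metrics are invariant under joint translation", {
  set.seed(61)
  g <- matrix(0L, 20, 20)
  s <- matrix(0L, 20, 20)
  g[5:8, 5:8] <- random_mask(4, 4, 0.5)
  s[5:8, 5:8] <- random_mask(4, 4, 0.5)
  if (sum(g[5:8, 5:8]) == 0) g[6, 6] <- 1L
  if (sum(s[5:8, 5:8]) == 0) s[6, 7] <- 1L
  g2 <- matrix(0L, 20, 20); g2[11:14, 9:12] <- g[5:8, 5:8]
  s2 <- matrix(0L, 20, 20); s2[11:14, 9:12] <- s[5:8, 5:8]
  expect_equal(metric_d1(g, s), metric_d1(g2, s2), tolerance = 1e-12)
  expect_equal(as.numeric(metric_hausdorff(g, s)),
               as.numeric(metric_hausdorff(g2, s2)), tolerance = 1e-12)
})

test_that("evaluate_frame and aggregate_metrics wire the suite together", {
  set.seed(71)
  fm <- generate_frame(phantom_params(image_size = 64, seed = 3))
  p <- matrix(runif(64 * 64), 64, 64)
  ev <- evaluate_frame(fm$mask, p, pkfp_k = 150)
  expect_equal(nrow(ev), 1)
  expect_true(all(c("d2", "d1_otsu", "d1_pkfp", "auroc_otsu",
                    "dice_pkfp") %in% names(ev)))

  # aggregation: single frame has sd 0; {0,2} has mean 1; NA entries are
  # skipped and counted
  one <- aggregate_metrics(ev)
  expect_true(all(one$sd[one$n_defined == 1] == 0))
  two <- aggregate_metrics(tibble::tibble(d1 = c(0, 2, NA)))
  expect_equal(two$mean, 1)
  expect_equal(two$n_defined, 2)
  expect_equal(two$n_skipped, 1)
  all_na <- aggregate_metrics(tibble::tibble(d1 = c(NA_real_, NA_real_)))
  expect_true(is.na(all_na$mean))
})
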