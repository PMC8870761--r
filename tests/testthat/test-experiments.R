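test_that("the default tuning grid has 16 cells", {
  cells <- grid_cells(grid_spec())
  expect_equal(nrow(cells), 16)
  expect_equal(nrow(grid_cells(grid_spec(training_sizes = 10,
                                         augment_options = FALSE,
                                         loss_options = "focal"))), 1)
  expect_error(grid_spec(training_sizes = c(100, 50)), "increasing")
  expect_error(grid_spec(loss_options = "hinge"), "loss_options")
})

test_that("run_grid fills one record per cell on a shared test set", {
  man <- memory_manifest(3, 8, size = 64, base_seed = 0)
  split <- patient_split(man, test_fraction = 0.3)
  grid <- grid_spec(training_sizes = c(6L, 12L), augment_options = FALSE,
                    loss_options = c("cross_entropy", "focal"),
                    epochs = 2L, pkfp_k = 60L, seed = 1L)
  rec <- run_grid(man, split, grid, net = net_config(4, 2, 64))
  expect_s3_class(rec, "thv_grid")
  expect_equal(nrow(rec), 4)
  expect_true(all(c("training_size", "augment", "loss", "best_epoch",
                    "best_loss", "d1_otsu_mean", "d1_pkfp_mean", "d2_mean")
                  %in% names(rec)))
  # every cell was evaluated on the identical test rows
  expect_length(unique(rec$test_rows), 1)
  expect_true(all(vapply(rec$history, nrow, numeric(1)) == 2))
  expect_true(all(rec$best_loss >= 0))
  # the grid is seed-reproducible
  rec2 <- run_grid(man, split, grid, net = net_config(4, 2, 64))
  expect_equal(rec$d1_otsu_mean, rec2$d1_otsu_mean)
  expect_equal(rec$d2_mean, rec2$d2_mean)
})

test_that("select_best implements worst-normalized closest-to-origin", {
  base <- tibble::tibble(
    training_size = c(75L, 150L), augment = FALSE,
    loss = "cross_entropy", best_epoch = 1L, best_loss = 0.1,
    d1_otsu_sd = 0, d1_pkfp_mean = c(1, 10), d1_pkfp_sd = 0, d2_sd = 0
  )

  # single record: itself
  one <- base[1, ]
  one$d1_otsu_mean <- 3
  one$d2_mean <- 7
  expect_equal(select_best(one)$training_size, 75L)

  # hand-evaluated tie: (1,10) vs (10,1) normalizes to (0.1,1) vs (1,0.1);
  # equal norms, broken by the smaller D1 -> the (1,10) record
  two <- base
  two$d1_otsu_mean <- c(1, 10)
  two$d2_mean <- c(10, 1)
  win <- select_best(two)
  expect_equal(win$d1_otsu_mean, 1)
  expect_equal(win$norm, sqrt(0.1^2 + 1^2))

  # a record dominating on both metrics always wins
  dom <- base
  dom$d1_otsu_mean <- c(2, 5)
  dom$d2_mean <- c(3, 9)
  expect_equal(select_best(dom)$training_size, 75L)

  # undefined means are excluded with a warning
  nar <- base
  nar$d1_otsu_mean <- c(NA, 5)
  nar$d2_mean <- c(3, 9)
  expect_warning(win <- select_best(nar), "excluded")
  expect_equal(win$training_size, 150L)

  # per-loss pairing picks PKFP D1 for focal cells
  mixed <- base
  mixed$loss <- c("cross_entropy", "focal")
  mixed$d1_otsu_mean <- c(5, 0.1)
  mixed$d1_pkfp_mean <- c(6, 100)
  mixed$d2_mean <- c(5, 5)
  expect_equal(select_best(mixed, d1 = "per_loss")$loss, "cross_entropy")
})

test_that("frame-type stratified evaluation flags undefined cells", {
  man_exp <- memory_manifest(1, 3, size = 64, base_seed = 10)
  man_nod <- memory_manifest(1, 2, size = 64, base_seed = 20,
                             stage = "no_device")
  man_nod$patient_id <- "P09"
  man <- dplyr::bind_rows(man_exp, man_nod)
  model <- build_unet(net_config(4, 2, 64, seed = 1))
  rep <- evaluate_by_frame_type(model, man, pkfp_k = 60)

  expect_setequal(unique(rep$stage), c("expanded", "no_device"))
  nod <- rep[rep$stage == "no_device", ]
  expect_equal(nod$n_skipped[nod$metric == "d1_otsu"], 2)
  expect_true(is.na(nod$mean[nod$metric == "d1_otsu"]))
  expect_equal(nod$n_skipped[nod$metric == "auroc_pkfp"], 2)
  # overlap metrics are defined but 0 without any device
  expect_equal(nod$mean[nod$metric == "precision_pkfp"], 0)
  expect_equal(nod$mean[nod$metric == "recall_pkfp"], 0)
  expect_equal(nod$mean[nod$metric == "dice_pkfp"], 0)
  expect_equal(nod$mean[nod$metric == "jaccard_pkfp"], 0)
  # D2 stays informative on no-device frames
  expect_true(is.finite(nod$mean[nod$metric == "d2"]))

  exp_stratum <- rep[rep$stage == "expanded", ]
  expect_true(all(exp_stratum$mean[exp_stratum$metric == "d2"] >= 0))
})

test_that("final training uses the whole training side and its epoch budget", {
  man <- memory_manifest(3, 4, size = 64, base_seed = 40)
  split <- patient_split(man, test_fraction = 0.3)
  fit <- final_train(man, split, loss = "cross_entropy", epochs = 3L,
                     net = net_config(4, 2, 64), seed = 2)
  expect_equal(nrow(fit$history), 3)
  n_train <- sum(man$patient_id %in% split$train_patients)
  expect_gte(n_train, 8)

  gl <- glance(fit)
  expect_equal(gl$epochs, 3)
  expect_equal(gl$best_loss, min(tidy(fit)$loss))
})

test_that("grid and fit objects plot and tidy cleanly", {
  man <- memory_manifest(2, 4, size = 64, base_seed = 60)
  split <- patient_split(man, test_fraction = 0.4)
  grid <- grid_spec(training_sizes = 4L, augment_options = FALSE,
                    loss_options = "cross_entropy", epochs = 2L,
                    pkfp_k = 60L)
  rec <- run_grid(man, split, grid, net = net_config(4, 2, 64))
  expect_s3_class(autoplot(rec), "ggplot")

  pairs <- phantom_pairs(4, size = 64, base_seed = 70)
  fit <- tiny_fit(pairs, 64, epochs = 2, base_filters = 4)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_overlay(pairs[[1]]$frame, pairs[[1]]$mask),
                  "ggplot")
  expect_equal(nrow(tidy(fit)), 2)
  expect_equal(nrow(tidy(split)), 2)
  expect_setequal(tidy(split)$side[tidy(split)$patient_id %in%
                                     split$test_patients], "test")
})
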