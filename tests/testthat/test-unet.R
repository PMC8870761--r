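test_that("model construction honours the shape and determinism contracts", {
  expect_error(net_config(8, 3, 100), "divisible")
  cfg <- net_config(8, 2, 64, seed = 5)
  net1 <- build_unet(cfg)
  net2 <- build_unet(cfg)
  fm <- generate_frame(phantom_params(image_size = 64, seed = 1))
  p1 <- predict(net1, fm$frame)
  p2 <- predict(net2, fm$frame)
  expect_identical(dim(p1), dim(fm$frame))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_identical(p1, p2)  # same seed, same weights, same output
  net3 <- build_unet(net_config(8, 2, 64, seed = 6))
  expect_false(identical(p1, predict(net3, fm$frame)))
  expect_error(predict(net1, fm$frame[1:32, 1:32]), "expects 64x64")

  tiny <- build_unet(net_config(4, 2, 32))
  expect_true(all(dim(predict(tiny, matrix(0L, 32, 32))) == 32))
})

test_that("network gradients match central finite differences", {
  cfg <- net_config(2, 2, 16, seed = 3)
  net <- build_unet(cfg)
  set.seed(3)
  x <- matrix(runif(256), 16, 16)
  y <- matrix(as.numeric(runif(256) < 0.2), 16, 16)
  eps <- 1e-6
  for (loss_type in 1:2) {
    res <- thinseg:::cpp_unet_run(net$params, x, 2L, TRUE, y, loss_type,
                                  0.25, 2, 1e-7)
    for (nm in c("enc1_c1_w", "bot_c2_w", "dec2_up_w", "dec1_c1_b",
                 "out_w", "out_b")) {
      p <- net$params
      ii <- sample(length(p[[nm]]), 1)
      p[[nm]][ii] <- p[[nm]][ii] + eps
      lp <- thinseg:::cpp_unet_run(p, x, 2L, FALSE, y, loss_type, 0.25, 2,
                                   1e-7)$loss
      p[[nm]][ii] <- p[[nm]][ii] - 2 * eps
      lm <- thinseg:::cpp_unet_run(p, x, 2L, FALSE, y, loss_type, 0.25, 2,
                                   1e-7)$loss
      fd <- (lp - lm) / (2 * eps)
      an <- res$grads[[nm]][ii]
      expect_lt(abs(fd - an) / max(1e-8, abs(fd) + abs(an)), 1e-4)
    }
  }
})

test_that("the compiled training loss equals the R loss functions", {
  net <- build_unet(net_config(4, 2, 64, seed = 2))
  fm <- generate_frame(phantom_params(image_size = 64, seed = 2))
  x <- fm$frame / 255
  y <- matrix(as.numeric(fm$mask), 64, 64)
  res_ce <- thinseg:::cpp_unet_run(net$params, x, 2L, FALSE, y, 1L, 0.25, 2,
                                   1e-7)
  expect_equal(res_ce$loss, cross_entropy(res_ce$pred, fm$mask),
               tolerance = 1e-9)
  res_fl <- thinseg:::cpp_unet_run(net$params, x, 2L, FALSE, y, 2L, 0.25, 2,
                                   1e-7)
  expect_equal(res_fl$loss,
               focal_loss(res_fl$pred, fm$mask, alpha = 0.25, gamma = 2),
               tolerance = 1e-9)
})

test_that("augmentation applies one transform to both members of a pair", {
  fm <- generate_frame(phantom_params(image_size = 64, seed = 7))
  # the identity draw leaves the pair untouched
  id <- augment_pair(fm$frame, fm$mask, seed = 1, max_translate = 0,
                     zoom_range = c(1, 1), max_rotate = 0, flip_prob = 0)
  expect_identical(id$frame, fm$frame)
  expect_identical(id$mask, fm$mask)

  # a pure horizontal flip reverses columns and is an involution
  fl <- augment_pair(fm$frame, fm$mask, seed = 1, max_translate = 0,
                     zoom_range = c(1, 1), max_rotate = 0, flip_prob = 1)
  expect_identical(fl$frame, fm$frame[, ncol(fm$frame):1])
  expect_identical(fl$mask, fm$mask[, ncol(fm$mask):1])
  fl2 <- augment_pair(fl$frame, fl$mask, seed = 1, max_translate = 0,
                      zoom_range = c(1, 1), max_rotate = 0, flip_prob = 1)
  expect_identical(fl2$frame, fm$frame)

  # a general draw keeps shapes, binary masks, and is seed-deterministic
  a1 <- augment_pair(fm$frame, fm$mask, seed = 5)
  a2 <- augment_pair(fm$frame, fm$mask, seed = 5)
  expect_identical(a1, a2)
  expect_identical(dim(a1$frame), dim(fm$frame))
  expect_true(all(a1$mask %in% c(0L, 1L)))
  expect_true(all(a1$frame >= 0 & a1$frame <= 255))
  expect_error(augment_pair(fm$frame, fm$mask[1:10, ]), "shape mismatch")
})

test_that("training records its history and reproduces under a fixed seed", {
  pairs <- phantom_pairs(10, size = 64, base_seed = 100)
  fit <- tiny_fit(pairs, 64, epochs = 3, seed = 9, base_filters = 4)
  expect_equal(nrow(fit$history), 3)
  expect_equal(fit$best_loss, min(fit$history$loss))
  expect_equal(fit$best_epoch, which.min(fit$history$loss))

  fit2 <- tiny_fit(pairs, 64, epochs = 3, seed = 9, base_filters = 4)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$model$params, fit2$model$params)

  expect_error(train_unet(build_unet(net_config(4, 2, 64)), list(), list(),
                          train_config()),
               "empty")
})

test_that("the loss trends downward on phantom data", {
  pairs <- phantom_pairs(12, size = 64, base_seed = 300)
  fit <- tiny_fit(pairs, 64, epochs = 6, seed = 4)
  expect_lt(fit$history$loss[6], fit$history$loss[1])
})

test_that("training with augmentation and restore-best stays well-formed", {
  pairs <- phantom_pairs(6, size = 64, base_seed = 200)
  fit <- train_unet(
    build_unet(net_config(4, 2, 64, seed = 1)),
    frames_of(pairs), masks_of(pairs),
    train_config(epochs = 2, augment = TRUE, seed = 1,
                 restore_best = TRUE)
  )
  expect_equal(nrow(fit$history), 2)
  p <- predict(fit, pairs[[1]]$frame)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("a briefly trained model beats an untrained one on D1", {
  pairs <- phantom_pairs(16, size = 64, base_seed = 400)
  test <- phantom_pairs(6, size = 64, base_seed = 900)
  untrained <- build_unet(net_config(8, 2, 64, seed = 2))
  fit <- tiny_fit(pairs, 64, epochs = 5, seed = 2)
  d1 <- function(model) {
    mean(vapply(test, function(fm) {
      metric_d1(fm$mask, binarize_pkfp(predict(model, fm$frame), 120))
    }, numeric(1)), na.rm = TRUE)
  }
  expect_lt(d1(fit$model), d1(untrained))
})
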