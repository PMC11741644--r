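test_that("the model maps inputs to same-extent probability maps", {
  cfg <- minimal_config()
  m <- build_model(cfg, n_modalities = 2, n_classes = 4, spatial_rank = 3,
                   seed = 1)
  x <- array(rnorm(2 * 32^3), c(2, 32, 32, 32, 1))
  fwd <- laseg:::model_forward(m, x)
  expect_identical(dim(fwd$probs), c(4L, 32L, 32L, 32L, 1L))
  sums <- apply(fwd$probs, c(2, 3, 4, 5), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)

  # extent not divisible by the downsampling factor
  expect_error(laseg:::model_forward(m, array(0, c(2, 30, 30, 30, 1))),
               "downsampling")
  # modality mismatch
  expect_error(laseg:::model_forward(m, array(0, c(3, 32, 32, 32, 1))),
               "modalities")
})

test_that("1x1 kernels on constant input give spatially constant output", {
  m <- build_model(minimal_config(), 2, 4, 3, seed = 2)
  x <- array(1, c(2, 16, 16, 16, 1))
  p <- laseg:::model_forward(m, x)$probs
  per_class_range <- apply(matrix(p, 4), 1, function(r) diff(range(r)))
  expect_lt(max(per_class_range), 1e-9)
})

test_that("parameter count grows when any one layer widens", {
  base_idx <- rep(1L, 19L)
  m0 <- build_model(assemble_configuration(base_idx, c(0L, 0L)), 2, 4, 3)
  for (l in c(1L, 9L, 19L)) {
    idx <- base_idx
    idx[l] <- encode_conv_action(64L, 1L, 1L)
    m1 <- build_model(assemble_configuration(idx, c(0L, 0L)), 2, 4, 3)
    expect_gt(n_parameters(m1), n_parameters(m0))
  }
})

test_that("dense connectivity feeds each layer all previous outputs", {
  set.seed(13)
  idx <- sample.int(375, 19, replace = TRUE)
  cfg <- assemble_configuration(idx, c(0L, 1L))
  m <- build_model(cfg, 2, 4, 3, seed = 1)
  # third internal layer of block 1 sees block input + N1 + N2 channels
  cin3 <- dim(m$params$conv[[3]]$w)[2]
  expect_identical(cin3, 2L + cfg$conv$n_filters[1] + cfg$conv$n_filters[2])
  # and for a decoder block (input channels = previous block's N3)
  cin12 <- dim(m$params$conv[[12]]$w)[2]
  expect_identical(cin12, cfg$conv$n_filters[9] + cfg$conv$n_filters[10] +
                     cfg$conv$n_filters[11])
})

test_that("pooling and upsampling operators are exact adjoint pairs", {
  set.seed(17)
  x <- array(rnorm(3 * 8 * 8 * 4 * 2), c(3, 8, 8, 4, 2))
  for (kind in c("max", "average")) {
    pf <- laseg:::pool_fwd(x, kind, c(2L, 2L, 2L))
    expect_identical(dim(pf$y), c(3L, 4L, 4L, 2L, 2L))
    dy <- array(rnorm(length(pf$y)), dim(pf$y))
    dx <- laseg:::pool_bwd(dy, pf$cache)
    # adjoint identity <pool(x), dy> = <x, pool^T(dy)> holds for the
    # linearised operator; for max pooling compare against the selection
    if (kind == "average") {
      expect_equal(sum(pf$y * dy), sum(x * dx), tolerance = 1e-10)
    } else {
      expect_equal(sum(dx), sum(dy), tolerance = 1e-10)
    }
  }
  up <- laseg:::upsample_fwd(x, c(2L, 2L, 2L))
  expect_identical(dim(up), c(3L, 16L, 16L, 8L, 2L))
  dy <- array(rnorm(length(up)), dim(up))
  dx <- laseg:::upsample_bwd(dy, c(2L, 2L, 2L), dim(x))
  expect_equal(sum(up * dy), sum(x * dx), tolerance = 1e-8)
})

test_that("analytic gradients match finite differences", {
  set.seed(19)
  cfg <- assemble_configuration(rep(2L, 19L), c(0L, 1L))
  m <- build_model(cfg, 2, 3, 2, seed = 4)
  x <- array(rnorm(2 * 8 * 8 * 2), c(2, 8, 8, 1, 2))
  t <- array(sample(0:2, 8 * 8 * 2, TRUE), c(8, 8, 1, 2))
  loss_of <- function(model) {
    f <- laseg:::model_forward(model, x, training = TRUE)
    laseg:::ce_dice_loss(matrix(f$probs, 3), as.integer(t) + 1L, 2:3)$loss
  }
  fwd <- laseg:::model_forward(m, x, training = TRUE)
  ls <- laseg:::ce_dice_loss(matrix(fwd$probs, 3), as.integer(t) + 1L, 2:3)
  gr <- laseg:::model_backward(m, fwd, array(ls$dz, dim(fwd$probs)))
  eps <- 1e-5
  for (l in c(1L, 10L, 19L)) {
    m2 <- m; m2$params$conv[[l]]$w[2] <- m2$params$conv[[l]]$w[2] + eps
    m3 <- m; m3$params$conv[[l]]$w[2] <- m3$params$conv[[l]]$w[2] - eps
    g_num <- (loss_of(m2) - loss_of(m3)) / (2 * eps)
    expect_equal(gr$conv[[l]]$w[2], g_num, tolerance = 1e-4)
  }
  m2 <- m; m2$params$head$b[1] <- m2$params$head$b[1] + eps
  m3 <- m; m3$params$head$b[1] <- m3$params$head$b[1] - eps
  expect_equal(gr$head$b[1], (loss_of(m2) - loss_of(m3)) / (2 * eps),
               tolerance = 1e-4)
})

test_that("training learns a separable toy problem and logs history", {
  ds <- tiny_dataset_2d(n = 2, shape = c(16L, 16L), seed = 3)
  runs_improved <- 0L
  for (s in 1:10) {
    m <- build_model(assemble_configuration(rep(2L, 19L), c(0L, 0L)),
                     2, 4, 2, seed = s)
    fit <- train_candidate(m, ds, training_settings(
      max_epochs = 5, patience_epochs = 5, batch_size = 4,
      patch_shape = c(16L, 16L), seed = s))
    expect_false(fit$failed)
    expect_lte(nrow(fit$history), 5L)
    if (tail(fit$history$loss, 1) <= fit$history$loss[1]) {
      runs_improved <- runs_improved + 1L
    }
  }
  expect_gte(runs_improved, 9L)
})

test_that("early stopping and determinism contracts hold", {
  ds <- tiny_dataset_2d()
  m <- build_model(minimal_config(), 2, 4, 2, seed = 1)
  # learning rate 0: the metric can never improve after epoch 1
  frozen <- train_candidate(m, ds, training_settings(
    max_epochs = 10, patience_epochs = 1, batch_size = 2,
    patch_shape = c(8L, 8L), learning_rate = 0, seed = 5))
  expect_identical(nrow(frozen$history), 2L)
  expect_true(frozen$stopped_early)

  st <- training_settings(max_epochs = 3, patience_epochs = 3,
                          batch_size = 2, patch_shape = c(8L, 8L), seed = 5)
  f1 <- train_candidate(m, ds, st)
  f2 <- train_candidate(m, ds, st)
  expect_identical(f1$history, f2$history)
  expect_equal(f1$model$params, f2$model$params, tolerance = 0)

  expect_error(train_candidate(m, list(), st), "empty")
})

test_that("segmentation predictions are valid label maps and deterministic", {
  ds <- tiny_dataset_2d(n = 1, shape = c(16L, 16L), seed = 4)
  m <- build_model(minimal_config(), 2, 4, 2, seed = 6)
  p1 <- predict_segmentation(m, ds[[1]]$image)
  p2 <- predict_segmentation(m, ds[[1]]$image)
  expect_s3_class(p1, "label_volume")
  expect_true(all(p1$labels %in% 0:3))
  expect_identical(p1$labels, p2$labels)
  expect_identical(dim(p1$labels), c(16L, 16L))
  expect_error(predict_segmentation(m, array(0, c(3, 16, 16))), "modalities|spatial")
})
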