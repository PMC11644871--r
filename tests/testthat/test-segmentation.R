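test_that("the encoder realizes the printed feature-map trace at 256", {
  tr <- encoder_shape_trace(256L)
  expect_equal(tr$side, c(254L, 127L, 127L, 63L, 61L, 30L))
  expect_equal(tr$channels, c(32L, 32L, 64L, 64L, 128L, 128L))
  m <- build_model(seg_model_config(input_side = 256L), seed = 1)
  expect_s3_class(m, "seg_model")
  expect_error(build_model(seg_model_config(input_side = 16L)), "collapses")
})

test_that("a 256-input forward pass produces the printed tensor shapes", {
  m <- build_model(seg_model_config(input_side = 256L), seed = 1)
  X <- array(0.5, c(1L, 256L, 256L, 1L))
  fw <- claheseg:::pixel_forward(m$params, X)
  expect_equal(dim(fw$enc$a1), c(32L, 254L, 254L, 1L))
  expect_equal(dim(fw$enc$p2$Y), c(64L, 63L, 63L, 1L))
  expect_equal(dim(fw$enc$p3$Y), c(128L, 30L, 30L, 1L))
  expect_equal(dim(fw$logits), c(1L, 256L, 256L, 1L))
})

test_that("classifier head emits two probabilities summing to one", {
  m <- build_model(seg_model_config(input_side = 64L, head = "classifier"),
                   seed = 2)
  for (s in 1:3) {
    pr <- predict_classes(m, random_image(64, seed = s))
    expect_length(pr, 2L)
    expect_true(all(pr >= 0))
    expect_lt(abs(sum(pr) - 1), 1e-6)
  }
})

test_that("probability maps are bounded and threshold to masks", {
  m <- build_model(seg_model_config(input_side = 48L), seed = 3)
  img <- random_image(48, seed = 4)
  pm <- predict_probmap(m, img)
  expect_equal(dim(pm), c(48L, 48L))
  expect_true(all(pm >= 0 & pm <= 1))
  expect_warning(mask <- predict_mask(m, img, threshold = 0), "trained")
  expect_true(all(mask))
  suppressWarnings({
    expect_false(any(predict_mask(m, img, threshold = 1) &
                       predict_probmap(m, img) < 1))
  })
})

test_that("backpropagation matches numerical gradients", {
  set.seed(5)
  X <- array(stats::runif(24 * 24 * 2), c(1, 24, 24, 2))
  Y <- array(stats::rbinom(24 * 24 * 2, 1, 0.3), c(1, 24, 24, 2))
  p <- build_model(seg_model_config(input_side = 24L), seed = 6)$params
  fw <- claheseg:::pixel_forward(p, X, keep = TRUE)
  gr <- claheseg:::pixel_backward(
    p, fw, claheseg:::bce_with_logits(fw$logits, Y)$dz)
  loss_at <- function(p) claheseg:::bce_with_logits(
    claheseg:::pixel_forward(p, X)$logits, Y)$loss
  for (nm in c("W1", "s2", "t3", "U1", "su2", "U3", "c3")) {
    set.seed(nm_seed <- 7)
    for (i in sample(length(p[[nm]]), min(2L, length(p[[nm]])))) {
      eps <- 1e-5
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- p; p3[[nm]][i] <- p3[[nm]][i] - eps
      numeric_grad <- (loss_at(p2) - loss_at(p3)) / (2 * eps)
      expect_lt(abs(gr[[nm]][i] - numeric_grad),
                1e-4 + 2e-3 * abs(numeric_grad))
    }
  }
})

test_that("training reduces loss and is seed-reproducible", {
  ds <- generate_dataset(24, phantom_preset("easy", side = 32L), seed = 8)
  cfg <- train_config(epochs = 4L, patience = 3L, seed = 9)
  m1 <- train_model(build_model(seg_model_config(input_side = 32L), seed = 10),
                    ds$images, ds$masks, cfg)
  expect_lt(m1$history$train_loss[4], m1$history$train_loss[1])
  m2 <- train_model(build_model(seg_model_config(input_side = 32L), seed = 10),
                    ds$images, ds$masks, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("early stopping fires patience epochs after the best epoch", {
  # tiny noise-label dataset: validation loss is guaranteed to plateau
  set.seed(11)
  imgs <- lapply(1:8, function(i) random_image(32))
  masks <- lapply(1:8, function(i) random_mask(32, p = 0.5))
  cfg <- train_config(learning_rate = 0.01, epochs = 40L, patience = 3L,
                      seed = 12)
  m <- train_model(build_model(seg_model_config(input_side = 32L), seed = 13),
                   imgs, masks, cfg)
  n <- nrow(m$history)
  expect_lt(n, 40L)
  expect_equal(n - which.min(m$history$val_loss), 3L)
})

test_that("training validates its inputs and head", {
  imgs <- lapply(1:4, function(i) random_image(32, seed = i))
  masks <- lapply(1:4, function(i) random_mask(32, seed = i))
  mc <- build_model(seg_model_config(input_side = 32L, head = "classifier"),
                    seed = 1)
  expect_error(train_model(mc, imgs, masks), "pixel")
  mp <- build_model(seg_model_config(input_side = 32L), seed = 1)
  expect_error(train_model(mp, imgs, masks[1:3]), "pair")
  bad <- masks; bad[[2]] <- random_mask(16)
  expect_error(train_model(mp, imgs, bad), "shape")
})

test_that("checkpoints round-trip weights, stats and config", {
  ds <- generate_dataset(10, phantom_preset("easy", side = 32L), seed = 14)
  m <- train_model(build_model(seg_model_config(input_side = 32L), seed = 15),
                   ds$images, ds$masks,
                   train_config(epochs = 2L, patience = 1L, seed = 16))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_model(path)
  img <- ds$images[[1L]]
  expect_identical(predict_probmap(m, img), predict_probmap(m2, img))
  expect_true(m2$trained)
  hist_csv <- paste0(sub("\\.rds$", "", path), "_history.csv")
  expect_true(file.exists(hist_csv))
  expect_equal(read.csv(hist_csv)$epoch, m$history$epoch)
})

test_that("training configuration validates", {
  expect_error(train_config(patience = 50L, epochs = 50L), "smaller")
  expect_error(train_config(learning_rate = -1), ">= 0")
  expect_error(seg_model_config(threshold = 1.5), "0, 1")
})
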