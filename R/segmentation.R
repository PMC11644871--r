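#' Configure the segmentation CNN
#'
#' The encoder is fixed: conv(32 filters, 3x3, valid), max pool (2x2,
#' stride 2); conv(64, 3x3, same), pool; conv(128, 3x3, valid), pool —
#' each convolution followed by batch normalization and ReLU. On a
#' 256 x 256 x 1 input this realizes the characteristic feature-map trace
#' 254x254x32 -> 127x127x32 -> 127x127x64 -> 63x63x64 -> 61x61x128 ->
#' 30x30x128 (see [encoder_shape_trace()]).
#'
#' Two heads are available. `"pixel"` (the pipeline default) is a decoder
#' of nearest-neighbour upsampling steps mirroring the encoder — upsample
#' + conv(64, 3x3, same), upsample + conv(32, 3x3, same), each with batch
#' norm + ReLU and an additive channel-matched skip connection from the
#' encoder activation at that scale, then upsampling to the input size
#' (fused with upsampled first-stage features) and a 1x1 projection —
#' ending in a per-pixel sigmoid, so the model emits a probability map the
#' size of its input. `"classifier"` is a literal dense head: flatten, 256
#' ReLU neurons, 128 ReLU neurons, 2-way softmax — a per-image (kidney
#' present/absent) classifier that cannot produce masks and is kept as a
#' secondary variant.
#'
#' @param input_side Input side length in pixels (default 256).
#' @param head `"pixel"` or `"classifier"`.
#' @param threshold Probability threshold for [predict_mask()] (default
#'   0.5).
#' @return A list of class `seg_model_config`.
#' @export
seg_model_config <- function(input_side = 256L,
                             head = c("pixel", "classifier"),
                             threshold = 0.5) {
  head <- match.arg(head)
  input_side <- as.integer(input_side)
  if (input_side < 16L) stop("input_side must be at least 16")
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  structure(list(input_side = input_side, head = head,
                 threshold = threshold),
            class = "seg_model_config")
}

#' Encoder feature-map trace
#'
#' Spatial size and channel depth after each encoder stage for a square
#' input. Convolutions are stride-1 3x3 with padding valid/same/valid;
#' pooling is 2x2 stride 2 with floor semantics.
#'
#' @param side Input side length.
#' @return Data frame with columns `stage`, `side`, `channels`.
#' @export
encoder_shape_trace <- function(side) {
  s1 <- side - 2L          # conv1 valid
  p1 <- s1 %/% 2L
  s2 <- p1                 # conv2 same
  p2 <- s2 %/% 2L
  s3 <- p2 - 2L            # conv3 valid
  p3 <- s3 %/% 2L
  data.frame(
    stage = c("conv1", "pool1", "conv2", "pool2", "conv3", "pool3"),
    side = c(s1, p1, s2, p2, s3, p3),
    channels = c(32L, 32L, 64L, 64L, 128L, 128L))
}

#' Build a segmentation model
#'
#' Allocates He-initialized weights for the configured architecture and
#' runs a construction-time self-check of the encoder shape trace: every
#' stage must have positive spatial size, and a 256-input encoder must
#' reproduce the trace 254x254x32, 63x63x64 (after the second pool) and
#' 30x30x128 (after the third pool). A mismatch raises an error naming the
#' stage.
#'
#' @param config A [seg_model_config()].
#' @param seed Integer seed for weight initialization.
#' @return A list of class `seg_model`.
#' @export
build_model <- function(config = seg_model_config(), seed = 1L) {
  stopifnot(inherits(config, "seg_model_config"))
  trace <- encoder_shape_trace(config$input_side)
  if (any(trace$side < 1L))
    stop("input side ", config$input_side,
         " collapses at stage ", trace$stage[which(trace$side < 1L)[1L]])
  if (config$input_side == 256L) {
    expect <- c(conv1 = 254L, pool2 = 63L, pool3 = 30L)
    got <- trace$side[match(names(expect), trace$stage)]
    bad <- which(got != expect)
    if (length(bad))
      stop("encoder self-check failed at ", names(expect)[bad[1L]],
           ": got ", got[bad[1L]], ", expected ", expect[bad[1L]])
  }
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  params <- list(
    W1 = he_init(32L, 9L), s1 = rep(1, 32L), t1 = numeric(32L),
    W2 = he_init(64L, 9L * 32L), s2 = rep(1, 64L), t2 = numeric(64L),
    W3 = he_init(128L, 9L * 64L), s3 = rep(1, 128L), t3 = numeric(128L))
  if (config$head == "pixel") {
    params$U1 <- he_init(64L, 9L * 128L)
    params$su1 <- rep(1, 64L); params$tu1 <- numeric(64L)
    params$U2 <- he_init(32L, 9L * 64L)
    params$su2 <- rep(1, 32L); params$tu2 <- numeric(32L)
    params$U3 <- he_init(1L, 32L); params$c3 <- numeric(1L)
  } else {
    flat <- trace$side[6L]^2 * 128L
    params$F1 <- he_init(256L, flat); params$g1 <- numeric(256L)
    params$F2 <- he_init(128L, 256L); params$g2 <- numeric(128L)
    params$F3 <- he_init(2L, 128L); params$g3 <- numeric(2L)
  }
  structure(list(config = config, params = params, bn_stats = NULL,
                 trained = FALSE),
            class = "seg_model")
}

# Encoder forward shared by both heads. X is (1, H, W, B) in [0, 1]
# (channel-first tensors; see nn.R). Each convolution is followed by batch
# normalization and ReLU; `stats = NULL` uses batch statistics (training),
# otherwise the running statistics collected during training.
encoder_forward <- function(params, X, keep = FALSE, stats = NULL) {
  c1 <- conv_fwd(X, params$W1, NULL, k = 3L, pad = 0L, keep_cols = keep)
  n1 <- bn_fwd(c1$Y, params$s1, params$t1, stats$n1)
  a1 <- relu_fwd(n1$Y)
  p1 <- pool_fwd(a1)
  c2 <- conv_fwd(p1$Y, params$W2, NULL, k = 3L, pad = 1L, keep_cols = keep)
  n2 <- bn_fwd(c2$Y, params$s2, params$t2, stats$n2)
  a2 <- relu_fwd(n2$Y)
  p2 <- pool_fwd(a2)
  c3 <- conv_fwd(p2$Y, params$W3, NULL, k = 3L, pad = 0L, keep_cols = keep)
  n3 <- bn_fwd(c3$Y, params$s3, params$t3, stats$n3)
  a3 <- relu_fwd(n3$Y)
  p3 <- pool_fwd(a3)
  list(c1 = c1, n1 = n1, a1 = a1, p1 = p1, c2 = c2, n2 = n2, a2 = a2,
       p2 = p2, c3 = c3, n3 = n3, a3 = a3, p3 = p3)
}

# Pixel-head forward: returns logits (1, H, W, B) and all caches. The
# decoder mirrors the encoder with nearest-neighbour upsampling and 3x3
# convolutions, and adds (additive, channel-matched) skip connections from
# the encoder activations at each scale so boundary detail survives the
# 3-stage bottleneck; the final stage fuses the upsampled decoder features
# with upsampled first-stage edge features and projects to logits.
pixel_forward <- function(params, X, keep = FALSE, stats = NULL) {
  enc <- encoder_forward(params, X, keep, stats)
  u1 <- upsample_fwd(enc$p3$Y, dim(enc$a3)[2], dim(enc$a3)[3])
  d1 <- conv_fwd(u1$Y + enc$a3, params$U1, NULL, k = 3L, pad = 1L,
                 keep_cols = keep)
  m1 <- bn_fwd(d1$Y, params$su1, params$tu1, stats$nu1)
  r1 <- relu_fwd(m1$Y)
  u2 <- upsample_fwd(r1, dim(enc$a2)[2], dim(enc$a2)[3])
  d2 <- conv_fwd(u2$Y + enc$a2, params$U2, NULL, k = 3L, pad = 1L,
                 keep_cols = keep)
  m2 <- bn_fwd(d2$Y, params$su2, params$tu2, stats$nu2)
  r2 <- relu_fwd(m2$Y)
  u3 <- upsample_fwd(r2, dim(X)[2], dim(X)[3])
  s3 <- upsample_fwd(enc$a1, dim(X)[2], dim(X)[3])
  d3 <- conv_fwd(u3$Y + s3$Y, params$U3, params$c3, k = 1L, pad = 0L,
                 keep_cols = keep)
  list(logits = d3$Y, enc = enc, u1 = u1, d1 = d1, m1 = m1, r1 = r1,
       u2 = u2, d2 = d2, m2 = m2, r2 = r2, u3 = u3, s3 = s3, d3 = d3)
}

# Per-channel running statistics of every batch-norm layer in a forward
# pass, used to accumulate inference-time statistics during training.
pixel_batch_stats <- function(fw) {
  pick <- function(n) list(mean = n$batch_mean, var = n$batch_var)
  list(n1 = pick(fw$enc$n1), n2 = pick(fw$enc$n2), n3 = pick(fw$enc$n3),
       nu1 = pick(fw$m1), nu2 = pick(fw$m2))
}

pixel_backward <- function(params, fw, dlogits) {
  g3 <- conv_bwd(dlogits, params$U3, fw$d3)
  skip_a1 <- upsample_bwd(g3$dX, fw$s3)
  du3 <- upsample_bwd(g3$dX, fw$u3)
  dm2 <- relu_bwd(du3, fw$m2$Y)
  b2 <- bn_bwd(dm2, params$su2, fw$m2)
  g2 <- conv_bwd(b2$dX, params$U2, fw$d2)   # gradient of u2$Y + a2
  du2 <- upsample_bwd(g2$dX, fw$u2)
  dm1 <- relu_bwd(du2, fw$m1$Y)
  b1 <- bn_bwd(dm1, params$su1, fw$m1)
  g1 <- conv_bwd(b1$dX, params$U1, fw$d1)   # gradient of u1$Y + a3
  dp3 <- upsample_bwd(g1$dX, fw$u1)
  enc <- fw$enc
  da3 <- pool_bwd(dp3, enc$p3) + g1$dX
  dn3 <- relu_bwd(da3, enc$n3$Y)
  q3 <- bn_bwd(dn3, params$s3, enc$n3)
  e3 <- conv_bwd(q3$dX, params$W3, enc$c3)
  da2 <- pool_bwd(e3$dX, enc$p2) + g2$dX
  dn2 <- relu_bwd(da2, enc$n2$Y)
  q2 <- bn_bwd(dn2, params$s2, enc$n2)
  e2 <- conv_bwd(q2$dX, params$W2, enc$c2)
  da1 <- pool_bwd(e2$dX, enc$p1) + skip_a1
  dn1 <- relu_bwd(da1, enc$n1$Y)
  q1 <- bn_bwd(dn1, params$s1, enc$n1)
  e1 <- conv_bwd(q1$dX, params$W1, enc$c1)
  list(W1 = e1$dW, s1 = q1$dg, t1 = q1$db,
       W2 = e2$dW, s2 = q2$dg, t2 = q2$db,
       W3 = e3$dW, s3 = q3$dg, t3 = q3$db,
       U1 = g1$dW, su1 = b1$dg, tu1 = b1$db,
       U2 = g2$dW, su2 = b2$dg, tu2 = b2$db,
       U3 = g3$dW, c3 = g3$db)
}

# Classifier-head forward: per-image two-class softmax probabilities.
classifier_forward <- function(params, X, stats = NULL) {
  enc <- encoder_forward(params, X, stats = stats)
  B <- dim(X)[4]
  flat <- matrix(enc$p3$Y, ncol = B)
  h1 <- pmax(params$F1 %*% flat + params$g1, 0)
  h2 <- pmax(params$F2 %*% h1 + params$g2, 0)
  z <- params$F3 %*% h2 + params$g3
  z <- z - rep(apply(z, 2, max), each = 2L)
  ez <- exp(z)
  probs <- ez / rep(colSums(ez), each = 2L)
  t(probs)  # B x 2
}

#' Forward pass: per-pixel probability map
#'
#' @param model A `seg_model` with a pixel head.
#' @param img A [gray_image()] (any size compatible with three pooling
#'   stages; the network is fully convolutional).
#' @return Numeric matrix of probabilities in `[0, 1]`, same shape as the
#'   input.
#' @export
predict_probmap <- function(model, img) {
  stopifnot(inherits(model, "seg_model"))
  if (model$config$head != "pixel")
    stop("probability maps require the pixel head")
  img <- as_gray_image(img)
  X <- array(as.numeric(img) / 255, c(1L, nrow(img), ncol(img), 1L))
  fw <- pixel_forward(model$params, X, stats = model$bn_stats)
  matrix(stats::plogis(fw$logits[1L, , , 1L]), nrow(img), ncol(img))
}

#' Forward pass: two-class probabilities (classifier head)
#'
#' @param model A `seg_model` with a classifier head.
#' @param img A [gray_image()] of the configured input side.
#' @return Numeric vector of 2 probabilities summing to 1.
#' @export
predict_classes <- function(model, img) {
  stopifnot(inherits(model, "seg_model"))
  if (model$config$head != "classifier")
    stop("class probabilities require the classifier head")
  img <- as_gray_image(img)
  X <- array(as.numeric(img) / 255, c(1L, nrow(img), ncol(img), 1L))
  st <- if (!is.null(model$bn_stats))
    model$bn_stats[c("n1", "n2", "n3")] else NULL
  as.numeric(classifier_forward(model$params, X, stats = st))
}

#' Training configuration
#'
#' Defaults: Adam with learning rate 0.001, batch size 32, at most 50
#' epochs, early stopping when validation loss fails to improve for 10
#' consecutive epochs, binary cross-entropy loss, 80/20 train/validation
#' split.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Maximum epochs.
#' @param patience Early-stopping patience (epochs, `< epochs`).
#' @param val_fraction Fraction of the data held out for validation.
#' @param seed Seed controlling initialization-independent randomness
#'   (split and shuffling).
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 32L,
                         epochs = 50L, patience = 10L,
                         val_fraction = 0.2, seed = 1L) {
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  if (batch_size < 1L || epochs < 1L) stop("batch_size and epochs must be >= 1")
  if (patience >= epochs) stop("patience must be smaller than epochs")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Train the pixel-head segmentation model
#'
#' Minimizes per-pixel binary cross-entropy with Adam. An 80/20
#' train/validation split is drawn from the configured seed; training
#' stops at the epoch limit or when validation loss has not improved for
#' `patience` epochs, and the best-validation weights are restored. The
#' loss history (per-epoch train and validation loss) is returned with the
#' model. Fixed seed and data give bit-identical histories.
#'
#' @param model A `seg_model` with a pixel head.
#' @param images List of [gray_image()]s, all of one size.
#' @param masks List of logical matrices paired with `images`.
#' @param cfg A [train_config()].
#' @return The trained `seg_model`, with `history` (data frame of `epoch`,
#'   `train_loss`, `val_loss`) and `trained = TRUE`.
#' @export
train_model <- function(model, images, masks, cfg = train_config()) {
  stopifnot(inherits(model, "seg_model"), inherits(cfg, "train_config"))
  if (model$config$head != "pixel")
    stop("training is supported for the pixel head")
  n <- length(images)
  if (n < 2L) stop("need at least 2 image/mask pairs")
  if (length(masks) != n) stop("images and masks must pair up")
  d1 <- dim(images[[1L]])
  for (i in seq_len(n)) {
    if (!all(dim(images[[i]]) == d1) || !all(dim(masks[[i]]) == d1))
      stop("image/mask ", i, " does not match the common shape")
  }
  H <- d1[1]; W <- d1[2]
  X <- array(0, c(1L, H, W, n)); Y <- array(0, c(1L, H, W, n))
  for (i in seq_len(n)) {
    X[1L, , , i] <- as.numeric(images[[i]]) / 255
    Y[1L, , , i] <- as.numeric(masks[[i]])
  }

  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(cfg$seed)

  n_val <- max(1L, round(cfg$val_fraction * n))
  val_idx <- sort(sample.int(n, n_val))
  tr_idx <- setdiff(seq_len(n), val_idx)
  params <- model$params
  if (!isTRUE(model$trained)) {
    # initialize the output bias at the foreground-prior logit so early
    # epochs are not spent learning the base rate
    prior <- min(max(mean(Y[, , , tr_idx]), 1e-4), 1 - 1e-4)
    params$c3 <- rep(log(prior / (1 - prior)), length(params$c3))
  }
  state <- adam_init(params)
  running <- model$bn_stats
  momentum <- 0.1
  best <- list(loss = Inf, params = params, bn = running)
  wait <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())

  val_loss_of <- function(params, running) {
    vl <- 0
    for (start in seq(1L, length(val_idx), by = cfg$batch_size)) {
      idx <- val_idx[start:min(start + cfg$batch_size - 1L, length(val_idx))]
      fw <- pixel_forward(params, X[, , , idx, drop = FALSE], stats = running)
      vl <- vl + bce_with_logits(fw$logits,
                                 Y[, , , idx, drop = FALSE])$loss * length(idx)
    }
    vl / length(val_idx)
  }

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(tr_idx)
    tl <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      fw <- pixel_forward(params, X[, , , idx, drop = FALSE], keep = TRUE)
      l <- bce_with_logits(fw$logits, Y[, , , idx, drop = FALSE])
      grads <- pixel_backward(params, fw, l$dz)
      upd <- adam_step(params, grads, state, cfg$learning_rate)
      params <- upd$params; state <- upd$state
      bs <- pixel_batch_stats(fw)
      running <- if (is.null(running)) bs else
        mapply(function(r, b) list(
          mean = (1 - momentum) * r$mean + momentum * b$mean,
          var = (1 - momentum) * r$var + momentum * b$var),
          running, bs, SIMPLIFY = FALSE)
      tl <- tl + l$loss * length(idx); nb <- nb + length(idx)
    }
    vl <- val_loss_of(params, running)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tl / nb,
                                   val_loss = vl))
    if (vl < best$loss) {
      best <- list(loss = vl, params = params, bn = running)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  model$params <- best$params
  model$bn_stats <- best$bn
  model$history <- hist
  model$trained <- TRUE
  model$train_config <- cfg
  model
}

#' Predict a binary mask
#'
#' Thresholds the probability map at `threshold` (default: the model
#' config's threshold, 0.5). A warning is emitted for untrained models.
#'
#' @param model A trained `seg_model` (pixel head).
#' @param img A [gray_image()].
#' @param threshold Probability threshold in `[0, 1]`.
#' @return Logical matrix; `TRUE` = kidney.
#' @export
predict_mask <- function(model, img, threshold = model$config$threshold) {
  if (!isTRUE(model$trained))
    warning("model has not been trained; predictions are random")
  predict_probmap(model, img) >= threshold
}

#' Save / load model weights
#'
#' Weights are stored as an RDS checkpoint next to a JSON sidecar
#' recording the model and training configuration; the training history,
#' if any, is written as CSV (`epoch,train_loss,val_loss`).
#'
#' @param model A `seg_model`.
#' @param path Checkpoint path (`.rds`); sidecar files get `.json` /
#'   `_history.csv` suffixes.
#' @return `save_model`: the path, invisibly. `load_model`: the restored
#'   `seg_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "seg_model"))
  saveRDS(list(params = model$params, bn_stats = model$bn_stats), path)
  sidecar <- list(config = unclass(model$config), trained = model$trained)
  if (!is.null(model$train_config))
    sidecar$train_config <- unclass(model$train_config)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  if (!is.null(model$history))
    utils::write.csv(model$history,
                     paste0(sub("\\.rds$", "", path), "_history.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  config <- seg_model_config(input_side = sc$config$input_side,
                             head = sc$config$head,
                             threshold = sc$config$threshold)
  structure(list(config = config, params = ck$params,
                 bn_stats = ck$bn_stats, trained = isTRUE(sc$trained)),
            class = "seg_model")
}
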