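#' EMACNN model configuration
#'
#' Architecture of the attention convolutional network for 4-phase gait
#' classification. The input is a `1 x height x width` feature matrix
#' (channels x MFAREn positions). Three parallel multi-scale input branches
#' (5x5, 3x3, 1x1 kernels, `channels[1]` filters each) are concatenated and
#' feed Layer 1 (three 3x3 conv blocks + attention), then 2x2 pooling,
#' Layer 2 (two conv blocks + attention), pooling, Layer 3 (one conv block
#' + attention), pooling. Every conv block is convolution + batch norm +
#' ReLU with "same" padding, so only pooling shrinks the map. In parallel,
#' an LSTM reads the feature matrix as a length-`width` sequence of
#' `height`-dimensional vectors; its final hidden state is concatenated with
#' the flattened convolutional features before the fully connected softmax
#' head. Dropping the attention modules and the LSTM branch yields the
#' multi-channel CNN (MCNN) ablation baseline.
#'
#' @param n_classes number of output classes (4 gait phases).
#' @param height,width input feature-matrix dimensions (12 channels x F
#'   feature values; F = 91 for 100-sample windows with inner window 10).
#' @param channels filters per layer (layers 1-3).
#' @param ema_groups channel groups of the attention module; must divide
#'   every entry of `channels`.
#' @param lstm_hidden LSTM hidden size.
#' @param use_ema,use_lstm include the attention modules / the LSTM branch
#'   (both `FALSE` gives the MCNN baseline).
#' @param pool `"max"` or `"avg"` pooling.
#' @param dropout dropout rate on the fused feature vector (0 disables).
#' @return list of class `model_config`.
#' @export
model_config <- function(n_classes = 4L, height = 12L, width = 91L,
                         channels = c(16L, 32L, 64L), ema_groups = 4L,
                         lstm_hidden = 64L, use_ema = TRUE, use_lstm = TRUE,
                         pool = c("max", "avg"), dropout = 0) {
  pool <- match.arg(pool)
  channels <- as.integer(channels)
  stopifnot(length(channels) == 3L, all(channels >= 1L), n_classes >= 2L,
            height >= 1L, width >= 1L, lstm_hidden >= 1L,
            dropout >= 0, dropout < 1)
  if (use_ema && any(channels %% ema_groups != 0L))
    stop("every channel count must be divisible by ema_groups")
  structure(list(n_classes = as.integer(n_classes),
                 height = as.integer(height), width = as.integer(width),
                 channels = channels, ema_groups = as.integer(ema_groups),
                 lstm_hidden = as.integer(lstm_hidden),
                 use_ema = isTRUE(use_ema), use_lstm = isTRUE(use_lstm),
                 pool = pool, dropout = dropout),
            class = "model_config")
}

#' Ablation variant of a model configuration
#'
#' @param config a [model_config()].
#' @param variant `"mcnn"` (no attention, no LSTM), `"ema"` (+attention),
#'   `"lstm"` (+LSTM), or `"full"`.
#' @return modified `model_config`.
#' @export
variant_config <- function(config, variant = c("full", "mcnn", "ema", "lstm")) {
  variant <- match.arg(variant)
  config$use_ema <- variant %in% c("ema", "full")
  config$use_lstm <- variant %in% c("lstm", "full")
  config
}

conv_block_init <- function(Cin, Cout, K) {
  list(conv = list(W = array(stats::rnorm(Cout * Cin * K,
                                          sd = sqrt(2 / (Cin * K))),
                             c(Cout, Cin, K)),
                   b = numeric(Cout)),
       bn = list(gamma = rep(1, Cout), beta = numeric(Cout)))
}

bn_state_init <- function(C) list(rmean = numeric(C), rvar = rep(1, C))

block_fwd <- function(X, par, st, plan, train) {
  cf <- conv_fwd(X, par$conv, plan)
  bf <- bn_fwd(cf$out, par$bn, st, train)
  rf <- relu_fwd(bf$out)
  list(out = rf$out, cf = cf, bf = bf, rf = rf, state = bf$state)
}

block_bwd <- function(dY, cache, par, plan) {
  dr <- relu_bwd(dY, cache$rf)
  bb <- bn_bwd(dr, cache$bf, par$bn)
  cb <- conv_bwd(bb$dX, cache$cf, par$conv, plan)
  list(dX = cb$dX,
       grad = list(conv = list(W = cb$dW, b = cb$db),
                   bn = list(gamma = bb$dgamma, beta = bb$dbeta)))
}

#' Build an EMACNN model with freshly initialized weights
#'
#' @param config a [model_config()].
#' @param seed integer seed for the weight initialization.
#' @return list of class `emacnn_model` with elements `params`, `state`
#'   (batch-norm running statistics), `plans` (precomputed index plans),
#'   `config`.
#' @export
build_emacnn <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  H <- config$height; W0 <- config$width
  dims <- list(A = c(H, W0),
               B = c(H %/% 2L, W0 %/% 2L))
  dims$C <- c(dims$B[1] %/% 2L, dims$B[2] %/% 2L)
  dims$out <- c(dims$C[1] %/% 2L, dims$C[2] %/% 2L)
  for (nm in c("A", "B", "C"))
    if (min(dims[[nm]]) < 3L)
      stop("feature map collapses at Layer",
           match(nm, c("A", "B", "C")), " (", dims[[nm]][1], " x ",
           dims[[nm]][2], " < 3x3 kernel)")
  if (min(dims$out) < 1L) stop("feature map collapses after Layer3 pooling")

  plans <- list(
    A5 = conv_plan(dims$A[1], dims$A[2], 5L, 5L),
    A3 = conv_plan(dims$A[1], dims$A[2], 3L, 3L),
    A1 = conv_plan(dims$A[1], dims$A[2], 1L, 1L),
    B3 = conv_plan(dims$B[1], dims$B[2], 3L, 3L),
    C3 = conv_plan(dims$C[1], dims$C[2], 3L, 3L),
    poolA = pool_plan(dims$A[1], dims$A[2]),
    poolB = pool_plan(dims$B[1], dims$B[2]),
    poolC = pool_plan(dims$C[1], dims$C[2])
  )

  ch <- config$channels
  set.seed(seed)
  params <- list(
    br5 = conv_block_init(1L, ch[1], 25L),
    br3 = conv_block_init(1L, ch[1], 9L),
    br1 = conv_block_init(1L, ch[1], 1L),
    l1c1 = conv_block_init(3L * ch[1], ch[1], 9L),
    l1c2 = conv_block_init(ch[1], ch[1], 9L),
    l1c3 = conv_block_init(ch[1], ch[1], 9L),
    l2c1 = conv_block_init(ch[1], ch[2], 9L),
    l2c2 = conv_block_init(ch[2], ch[2], 9L),
    l3c1 = conv_block_init(ch[2], ch[3], 9L)
  )
  if (config$use_ema) {
    g <- config$ema_groups
    params$ema1 <- ema_init(ch[1], g)
    params$ema2 <- ema_init(ch[2], g)
    params$ema3 <- ema_init(ch[3], g)
  }
  if (config$use_lstm)
    params$lstm <- lstm_init(H, config$lstm_hidden)
  flat_dim <- ch[3] * dims$out[1] * dims$out[2]
  fused_dim <- flat_dim + if (config$use_lstm) config$lstm_hidden else 0L
  params$fc <- list(W = matrix(stats::rnorm(config$n_classes * fused_dim,
                                            sd = sqrt(2 / fused_dim)),
                               config$n_classes, fused_dim),
                    b = numeric(config$n_classes))

  state <- list(br5 = bn_state_init(ch[1]), br3 = bn_state_init(ch[1]),
                br1 = bn_state_init(ch[1]), l1c1 = bn_state_init(ch[1]),
                l1c2 = bn_state_init(ch[1]), l1c3 = bn_state_init(ch[1]),
                l2c1 = bn_state_init(ch[2]), l2c2 = bn_state_init(ch[2]),
                l3c1 = bn_state_init(ch[3]))

  structure(list(params = params, state = state, plans = plans,
                 config = config, dims = dims, flat_dim = flat_dim),
            class = "emacnn_model")
}

#' Number of trainable parameters
#'
#' @param x an `emacnn_model` or a [model_config()].
#' @return integer parameter count.
#' @export
n_parameters <- function(x) {
  if (inherits(x, "model_config")) x <- build_emacnn(x, seed = 0L)
  length(par_unlist(x$params))
}

#' @export
print.emacnn_model <- function(x, ...) {
  cfg <- x$config
  cat("<emacnn_model> input 1 x ", cfg$height, " x ", cfg$width,
      ", channels ", paste(cfg$channels, collapse = "/"),
      if (cfg$use_ema) " +EMA" else "",
      if (cfg$use_lstm) " +LSTM" else "",
      ", ", n_parameters(x), " parameters\n", sep = "")
  invisible(x)
}

emacnn_forward <- function(model, X, train = FALSE, dropout_mask = NULL) {
  p <- model$params; st <- model$state
  pl <- model$plans; cfg <- model$config
  d <- dim(X); P <- d[2L]; B <- d[3L]
  c1 <- cfg$channels[1L]

  b5 <- block_fwd(X, p$br5, st$br5, pl$A5, train); st$br5 <- b5$state
  b3 <- block_fwd(X, p$br3, st$br3, pl$A3, train); st$br3 <- b3$state
  b1 <- block_fwd(X, p$br1, st$br1, pl$A1, train); st$br1 <- b1$state
  Y <- array(0, c(3L * c1, P, B))
  Y[seq_len(c1), , ] <- b5$out
  Y[c1 + seq_len(c1), , ] <- b3$out
  Y[2L * c1 + seq_len(c1), , ] <- b1$out

  l1a <- block_fwd(Y, p$l1c1, st$l1c1, pl$A3, train); st$l1c1 <- l1a$state
  l1b <- block_fwd(l1a$out, p$l1c2, st$l1c2, pl$A3, train); st$l1c2 <- l1b$state
  l1c <- block_fwd(l1b$out, p$l1c3, st$l1c3, pl$A3, train); st$l1c3 <- l1c$state
  z1 <- l1c$out
  e1 <- NULL
  if (cfg$use_ema) {
    e1 <- ema_fwd(z1, p$ema1, pl$A3, cfg$ema_groups)
    z1 <- e1$out
  }
  pA <- pool_fwd(z1, pl$poolA, cfg$pool)

  l2a <- block_fwd(pA$out, p$l2c1, st$l2c1, pl$B3, train); st$l2c1 <- l2a$state
  l2b <- block_fwd(l2a$out, p$l2c2, st$l2c2, pl$B3, train); st$l2c2 <- l2b$state
  z2 <- l2b$out
  e2 <- NULL
  if (cfg$use_ema) {
    e2 <- ema_fwd(z2, p$ema2, pl$B3, cfg$ema_groups)
    z2 <- e2$out
  }
  pB <- pool_fwd(z2, pl$poolB, cfg$pool)

  l3a <- block_fwd(pB$out, p$l3c1, st$l3c1, pl$C3, train); st$l3c1 <- l3a$state
  z3 <- l3a$out
  e3 <- NULL
  if (cfg$use_ema) {
    e3 <- ema_fwd(z3, p$ema3, pl$C3, cfg$ema_groups)
    z3 <- e3$out
  }
  pC <- pool_fwd(z3, pl$poolC, cfg$pool)

  feat <- matrix(pC$out, model$flat_dim, B)
  ls <- NULL
  if (cfg$use_lstm) {
    Xseq <- array(X, c(cfg$height, cfg$width, B))
    ls <- lstm_fwd(Xseq, p$lstm, cfg$lstm_hidden)
    feat <- rbind(feat, ls$out)
  }
  drop_mask <- NULL
  if (train && cfg$dropout > 0) {
    if (is.null(dropout_mask))
      dropout_mask <- (matrix(stats::runif(length(feat)), nrow(feat)) >
                         cfg$dropout) / (1 - cfg$dropout)
    drop_mask <- dropout_mask
    feat <- feat * drop_mask
  }
  logits <- p$fc$W %*% feat + p$fc$b

  list(logits = logits, state = st,
       cache = list(b5 = b5, b3 = b3, b1 = b1, l1a = l1a, l1b = l1b,
                    l1c = l1c, e1 = e1, pA = pA, l2a = l2a, l2b = l2b,
                    e2 = e2, pB = pB, l3a = l3a, e3 = e3, pC = pC,
                    feat = feat, ls = ls, drop_mask = drop_mask,
                    dims = c(P = P, B = B)))
}

emacnn_backward <- function(model, dlogits, cache) {
  p <- model$params; pl <- model$plans; cfg <- model$config
  P <- cache$dims[["P"]]; B <- cache$dims[["B"]]
  c1 <- cfg$channels[1L]
  g <- list()

  g$fc <- list(W = dlogits %*% t(cache$feat), b = rowSums(dlogits))
  dfeat <- crossprod(p$fc$W, dlogits)
  if (!is.null(cache$drop_mask)) dfeat <- dfeat * cache$drop_mask
  dflat <- dfeat[seq_len(model$flat_dim), , drop = FALSE]
  dX_lstm <- NULL
  if (cfg$use_lstm) {
    dh <- dfeat[model$flat_dim + seq_len(cfg$lstm_hidden), , drop = FALSE]
    lb <- lstm_bwd(dh, cache$ls$caches, p$lstm, cfg$lstm_hidden)
    g$lstm <- lb$grad
    dX_lstm <- array(lb$dX, c(1L, P, B))
  }

  dpC <- array(dflat, c(cfg$channels[3L], pl$poolC$P, B))
  dz3 <- pool_bwd(dpC, cache$pC, pl$poolC, cfg$channels[3L], pl$C3$P, B)
  if (cfg$use_ema) {
    eb3 <- ema_bwd(dz3, cache$e3, p$ema3, pl$C3)
    g$ema3 <- eb3$grad
    dz3 <- eb3$dX
  }
  l3b <- block_bwd(dz3, cache$l3a, p$l3c1, pl$C3)
  g$l3c1 <- l3b$grad

  dpB <- l3b$dX
  dz2 <- pool_bwd(dpB, cache$pB, pl$poolB, cfg$channels[2L], pl$B3$P, B)
  if (cfg$use_ema) {
    eb2 <- ema_bwd(dz2, cache$e2, p$ema2, pl$B3)
    g$ema2 <- eb2$grad
    dz2 <- eb2$dX
  }
  l2bb <- block_bwd(dz2, cache$l2b, p$l2c2, pl$B3)
  g$l2c2 <- l2bb$grad
  l2ab <- block_bwd(l2bb$dX, cache$l2a, p$l2c1, pl$B3)
  g$l2c1 <- l2ab$grad

  dpA <- l2ab$dX
  dz1 <- pool_bwd(dpA, cache$pA, pl$poolA, cfg$channels[1L], pl$A3$P, B)
  if (cfg$use_ema) {
    eb1 <- ema_bwd(dz1, cache$e1, p$ema1, pl$A3)
    g$ema1 <- eb1$grad
    dz1 <- eb1$dX
  }
  l1cb <- block_bwd(dz1, cache$l1c, p$l1c3, pl$A3)
  g$l1c3 <- l1cb$grad
  l1bb <- block_bwd(l1cb$dX, cache$l1b, p$l1c2, pl$A3)
  g$l1c2 <- l1bb$grad
  l1ab <- block_bwd(l1bb$dX, cache$l1a, p$l1c1, pl$A3)
  g$l1c1 <- l1ab$grad

  dY <- l1ab$dX
  b5b <- block_bwd(dY[seq_len(c1), , , drop = FALSE], cache$b5, p$br5, pl$A5)
  b3b <- block_bwd(dY[c1 + seq_len(c1), , , drop = FALSE], cache$b3, p$br3,
                   pl$A3)
  b1b <- block_bwd(dY[2L * c1 + seq_len(c1), , , drop = FALSE], cache$b1,
                   p$br1, pl$A1)
  g$br5 <- b5b$grad; g$br3 <- b3b$grad; g$br1 <- b1b$grad

  dX <- b5b$dX + b3b$dX + b1b$dX
  if (!is.null(dX_lstm)) dX <- dX + dX_lstm

  list(grads = g[names(p)], dX = dX)
}

#' Categorical cross-entropy loss
#'
#' Mean negative log-probability of the true class. Probability rows must
#' lie on the simplex; probabilities are clamped at `eps` before the log
#' (with a warning) so a zero probability for a true class yields a large
#' finite loss rather than infinity.
#'
#' @param probabilities numeric matrix, one row per sample, columns summing
#'   to 1.
#' @param labels true classes: factor, character or integer column indices.
#' @param eps clamping constant.
#' @return scalar loss (>= 0).
#' @export
cross_entropy <- function(probabilities, labels, eps = 1e-12) {
  probabilities <- as.matrix(probabilities)
  if (is.factor(labels)) labels <- as.integer(labels)
  if (is.character(labels)) labels <- as.integer(phase_factor(labels))
  stopifnot(length(labels) == nrow(probabilities),
            all(labels >= 1L), all(labels <= ncol(probabilities)))
  if (any(abs(rowSums(probabilities) - 1) > 1e-6))
    stop("probability rows must sum to 1")
  ptrue <- probabilities[cbind(seq_along(labels), labels)]
  if (any(ptrue < eps)) {
    warning("true-class probability clamped at ", eps)
    ptrue <- pmax(ptrue, eps)
  }
  mean(-log(ptrue))
}

#' Efficient multi-scale attention on a feature-map batch
#'
#' Applies the grouped attention module to a `B x C x H x W` array. The
#' output has the same shape as the input. See the package vignette for the
#' internals (directional pooled descriptors with a shared 1x1 transform,
#' parallel 3x3 context branch, cross-spatial weighting).
#'
#' @param x numeric array `B x C x H x W`.
#' @param params module weights from [ema_init()]; freshly initialized
#'   (seeded) when `NULL`.
#' @param groups number of channel groups; must divide `C`.
#' @param seed seed used when `params` is `NULL`.
#' @return array of the same shape as `x`.
#' @export
ema_attention <- function(x, params = NULL, groups = 4L, seed = 1L) {
  stopifnot(length(dim(x)) == 4L)
  d <- dim(x)
  B <- d[1L]; C <- d[2L]; H <- d[3L]; W <- d[4L]
  if (C %% groups != 0L)
    stop("channels (", C, ") not divisible by groups (", groups, ")")
  if (is.null(params)) params <- ema_init(C, groups, seed = seed)
  X <- array(aperm(x, c(2, 3, 4, 1)), c(C, H * W, B))
  plan3 <- conv_plan(H, W, 3L, 3L)
  out <- ema_fwd(X, params, plan3, groups)$out
  aperm(array(out, c(C, H, W, B)), c(4, 1, 2, 3))
}

#' Training configuration
#'
#' @param epochs number of epochs.
#' @param batch_size minibatch size.
#' @param lr0 initial Adam learning rate.
#' @param lr_decay multiplicative decay factor.
#' @param decay_every epochs between decays; the learning rate at epoch `e`
#'   (1-based) is `lr0 * lr_decay^floor(e / decay_every)`.
#' @param seed seed fixing initialization and shuffling.
#' @param folds cross-validation folds (used by [kfold_cv()]).
#' @param split training fraction for simple holdout splits.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 64L, lr0 = 0.001,
                         lr_decay = 0.5, decay_every = 20L, seed = 42L,
                         folds = 5L, split = 0.8) {
  stopifnot(epochs >= 1L, batch_size >= 1L, lr0 > 0, lr_decay > 0,
            decay_every >= 1L, folds >= 2L, split > 0, split < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr0 = lr0,
                 lr_decay = lr_decay, decay_every = as.integer(decay_every),
                 seed = as.integer(seed), folds = as.integer(folds),
                 split = split),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' @param epoch 1-based epoch number(s).
#' @param config a [train_config()].
#' @return learning rate(s) `lr0 * lr_decay^floor(epoch / decay_every)`.
#' @export
lr_schedule <- function(epoch, config = train_config()) {
  config$lr0 * config$lr_decay^(epoch %/% config$decay_every)
}

features_to_input <- function(features) {
  if (inherits(features, "feature_set")) features <- features$features
  if (is.matrix(features)) features <- array(features, c(1L, dim(features)))
  stopifnot(length(dim(features)) == 3L)
  dim(features) <- unname(dim(features))
  features
}

apply_scaler <- function(features, scaler) {
  n <- dim(features)[1L]
  for (ch in seq_len(dim(features)[2L]))
    features[, ch, ] <- (features[, ch, ] - scaler$mean[ch]) / scaler$sd[ch]
  # [n, H, F] -> [1, H*F, n]
  X <- aperm(features, c(2, 3, 1))
  array(X, c(1L, dim(X)[1L] * dim(X)[2L], n))
}

#' Train an EMACNN classifier
#'
#' Adam optimization of the softmax cross-entropy with the stepped
#' learning-rate schedule of [train_config()]. Feature matrices are
#' standardized per channel (mean/sd estimated on the training set and
#' stored in the model). Initialization and shuffling are fixed by the
#' seed.
#'
#' @param features a `feature_set` from [mfaren_features()] or an array
#'   `n x height x width`.
#' @param labels factor of gait phases (ignored if `features` is a
#'   `feature_set` carrying labels).
#' @param config a [model_config()]; its `width`/`height` must match the
#'   features.
#' @param train a [train_config()].
#' @param val_features,val_labels optional validation set for the per-epoch
#'   accuracy in the history.
#' @param verbose print per-epoch progress.
#' @return the trained `emacnn_model`, with a `history` data frame
#'   (epoch, lr, loss, val_accuracy) attached.
#' @export
train_emacnn <- function(features, labels = NULL, config = model_config(),
                         train = train_config(), val_features = NULL,
                         val_labels = NULL, verbose = FALSE) {
  if (inherits(features, "feature_set") && is.null(labels))
    labels <- features$labels
  feats <- features_to_input(features)
  labels <- phase_factor(labels)
  stopifnot(dim(feats)[1L] == length(labels))
  if (length(unique(labels[!is.na(labels)])) < 2L)
    stop("training set must contain at least 2 classes")
  if (dim(feats)[2L] != config$height || dim(feats)[3L] != config$width)
    stop("feature dimensions (", dim(feats)[2L], " x ", dim(feats)[3L],
         ") do not match model_config (", config$height, " x ",
         config$width, ")")

  scaler <- list(mean = apply(feats, 2L, mean),
                 sd = pmax(apply(feats, 2L, stats::sd), 1e-8))
  X <- apply_scaler(feats, scaler)
  y <- as.integer(labels)
  n <- length(y)
  nc <- config$n_classes

  model <- build_emacnn(config, seed = train$seed)
  model$scaler <- scaler
  model$classes <- levels(labels)
  skeleton <- model$params
  vec <- par_unlist(skeleton)
  opt <- adam_init(length(vec))

  has_val <- !is.null(val_features)
  if (has_val) {
    vf <- features_to_input(val_features)
    if (inherits(val_features, "feature_set") && is.null(val_labels))
      val_labels <- val_features$labels
    val_labels <- phase_factor(val_labels)
  }

  set.seed(train$seed + 1L)
  hist <- data.frame(epoch = integer(0), lr = numeric(0), loss = numeric(0),
                     val_accuracy = numeric(0))
  for (epoch in seq_len(train$epochs)) {
    lr <- lr_schedule(epoch, train)
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = train$batch_size)) {
      idx <- ord[start:min(start + train$batch_size - 1L, n)]
      Xb <- X[, , idx, drop = FALSE]
      yb <- y[idx]
      fw <- emacnn_forward(model, Xb, train = TRUE)
      model$state <- fw$state
      probs <- softmax_cols(fw$logits)
      losses <- c(losses,
                  mean(-log(pmax(probs[cbind(yb, seq_along(yb))], 1e-12))))
      Y1 <- matrix(0, nc, length(yb))
      Y1[cbind(yb, seq_along(yb))] <- 1
      dlogits <- (probs - Y1) / length(yb)
      bw <- emacnn_backward(model, dlogits, fw$cache)
      step <- adam_step(vec, par_unlist(bw$grads), opt, lr)
      vec <- step$vec
      opt <- step$state
      model$params <- par_relist(vec, skeleton)
    }
    vacc <- NA_real_
    if (has_val) {
      pr <- predict_emacnn(model, vf)
      vacc <- mean(pr$labels == val_labels)
    }
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   loss = mean(losses), val_accuracy = vacc))
    if (verbose)
      message(sprintf("epoch %3d  lr %.5f  loss %.4f  val %.3f",
                      epoch, lr, mean(losses), vacc))
  }
  model$history <- hist
  model
}

#' Predict gait phases with a trained EMACNN
#'
#' @param model a trained `emacnn_model` (from [train_emacnn()]).
#' @param features a `feature_set` or array `n x height x width`.
#' @param batch_size forward-pass batch size.
#' @return list with `labels` (factor), `probs` (matrix `n x n_classes`,
#'   rows summing to 1), `time_per_sample_ms` (mean wall-clock recognition
#'   time per sample) and `times_ms` (per-batch amortized per-sample times).
#' @export
predict_emacnn <- function(model, features, batch_size = 256L) {
  if (is.null(model$scaler)) stop("model has not been trained")
  feats <- features_to_input(features)
  X <- apply_scaler(feats, model$scaler)
  n <- dim(X)[3L]
  nc <- model$config$n_classes
  probs <- matrix(NA_real_, n, nc)
  times <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    t0 <- proc.time()[["elapsed"]]
    fw <- emacnn_forward(model, X[, , idx, drop = FALSE], train = FALSE)
    dt <- proc.time()[["elapsed"]] - t0
    probs[idx, ] <- t(softmax_cols(fw$logits))
    times[idx] <- dt / length(idx) * 1000
  }
  labels <- factor(model$classes[max.col(probs)], levels = model$classes)
  list(labels = labels, probs = probs,
       time_per_sample_ms = mean(times), times_ms = times)
}
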