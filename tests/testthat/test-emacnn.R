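test_that("EMA attention preserves shape and is deterministic", {
  set.seed(10)
  x <- array(rnorm(2 * 16 * 6 * 45), c(2, 16, 6, 45))
  w <- mfaren:::ema_init(16, 4, seed = 1)
  y1 <- ema_attention(x, w, groups = 4)
  y2 <- ema_attention(x, w, groups = 4)
  expect_equal(dim(y1), c(2, 16, 6, 45))
  expect_identical(y1, y2)
  expect_false(identical(y1, x))
  expect_error(ema_attention(x, groups = 5), "divisible")
})

test_that("backward passes agree with finite differences", {
  ns <- asNamespace("mfaren")
  cfg <- model_config(height = 12, width = 17, channels = c(4, 4, 4),
                      ema_groups = 2, lstm_hidden = 5)
  model <- build_emacnn(cfg, seed = 3)
  set.seed(1)
  B <- 3
  X <- array(rnorm(12 * 17 * B), c(1, 12 * 17, B))
  y <- c(1L, 3L, 4L)
  loss_fn <- function(m) {
    fw <- ns$emacnn_forward(m, X, train = TRUE)
    probs <- ns$softmax_cols(fw$logits)
    list(loss = mean(-log(probs[cbind(y, seq_along(y))])), fw = fw)
  }
  l0 <- loss_fn(model)
  probs <- ns$softmax_cols(l0$fw$logits)
  Y1 <- matrix(0, 4, B); Y1[cbind(y, 1:B)] <- 1
  bw <- ns$emacnn_backward(model, (probs - Y1) / B, l0$fw$cache)
  gvec <- ns$par_unlist(bw$grads)
  vec <- ns$par_unlist(model$params)
  skel <- model$params
  set.seed(99)
  idx <- sample(length(vec), 40)
  eps <- 1e-5
  num <- vapply(idx, function(i) {
    v1 <- vec; v1[i] <- v1[i] + eps
    m1 <- model; m1$params <- ns$par_relist(v1, skel)
    v2 <- vec; v2[i] <- v2[i] - eps
    m2 <- model; m2$params <- ns$par_relist(v2, skel)
    (loss_fn(m1)$loss - loss_fn(m2)$loss) / (2 * eps)
  }, numeric(1))
  rel <- abs(num - gvec[idx]) / pmax(1e-6, abs(num) + abs(gvec[idx]))
  expect_lt(max(rel), 1e-4)
})

test_that("the model graph honors its shape and ablation contracts", {
  cfg <- tiny_model_config()
  model <- build_emacnn(cfg, seed = 1)
  ns <- asNamespace("mfaren")
  X <- array(rnorm(12 * 91 * 5), c(1, 12 * 91, 5))
  fw <- ns$emacnn_forward(model, X, train = FALSE)
  expect_equal(dim(fw$logits), c(4L, 5L))
  # parameter-count ordering across ablation variants
  n_full <- n_parameters(variant_config(cfg, "full"))
  n_ema <- n_parameters(variant_config(cfg, "ema"))
  n_lstm <- n_parameters(variant_config(cfg, "lstm"))
  n_mcnn <- n_parameters(variant_config(cfg, "mcnn"))
  expect_gt(n_full, n_ema)
  expect_gt(n_full, n_lstm)
  expect_gt(n_ema, n_mcnn)
  expect_gt(n_lstm, n_mcnn)
  # collapsing spatial dimensions is reported, naming the layer
  expect_error(build_emacnn(model_config(width = 8, channels = c(4, 8, 16),
                                         ema_groups = 2)), "Layer")
})

test_that("cross-entropy matches its analytic values", {
  p_onehot <- matrix(c(1, 0, 0, 0), 1)
  expect_equal(cross_entropy(p_onehot, 1L), 0)
  p_unif <- matrix(1 / 4, 3, 4)
  expect_equal(cross_entropy(p_unif, c(1L, 2L, 4L)), log(4))
  # loss decreases as the true-class probability grows
  ps <- seq(0.3, 0.9, by = 0.1)
  losses <- vapply(ps, function(p) {
    cross_entropy(matrix(c(p, rep((1 - p) / 3, 3)), 1), 1L)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_warning(cross_entropy(matrix(c(0, 1, 0, 0), 1), 1L), "clamped")
  expect_error(cross_entropy(matrix(c(0.5, 0.2, 0.1, 0.1), 1), 1L), "sum to 1")
})

test_that("the learning-rate schedule halves every 20 epochs", {
  tc <- train_config()
  expect_equal(lr_schedule(40, tc), 0.00025)
  expect_equal(lr_schedule(1, tc), 0.001)
  expect_equal(lr_schedule(19, tc), 0.001)
  expect_equal(lr_schedule(200, tc), 0.001 * 0.5^10)
  e <- 1:60
  expect_equal(lr_schedule(e, tc), 0.001 * 0.5^(e %/% 20))
})

test_that("training is seeded, validated and records its history", {
  fs <- small_feature_set()
  n <- dim(fs$features)[1L]
  set.seed(5)
  idx <- sample(n, 120)
  feats <- fs$features[idx, , ]
  labs <- fs$labels[idx]
  cfg <- tiny_model_config()
  tc <- train_config(epochs = 3, batch_size = 64, seed = 9)
  m1 <- train_emacnn(feats, labs, config = cfg, train = tc)
  m2 <- train_emacnn(feats, labs, config = cfg, train = tc)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_equal(m1$history$lr, lr_schedule(1:3, tc))
  expect_equal(nrow(m1$history), 3L)
  # loss starts near ln(4) for 4 balanced classes under random init
  expect_equal(m1$history$loss[1], log(4), tolerance = 0.35)
  expect_error(train_emacnn(feats, factor(rep("SS", 120),
                                          levels = gait_phases()),
                            config = cfg, train = tc),
               "at least 2 classes")
  pred <- predict_emacnn(m1, feats)
  expect_equal(rowSums(pred$probs), rep(1, 120), tolerance = 1e-6)
  expect_length(pred$labels, 120)
  expect_length(pred$times_ms, 120)
  expect_true(pred$time_per_sample_ms >= 0)
})

test_that("a short training run separates the synthetic phases", {
  fs <- small_feature_set()
  n <- dim(fs$features)[1L]
  set.seed(31)
  tr <- sort(sample.int(n, round(0.8 * n)))
  cfg <- tiny_model_config()
  tc <- train_config(epochs = 15, batch_size = 64, seed = 4)
  model <- train_emacnn(fs$features[tr, , ], fs$labels[tr], config = cfg,
                        train = tc)
  pred <- predict_emacnn(model, fs$features[-tr, , ])
  expect_gte(mean(pred$labels == fs$labels[-tr]), 0.9)
})
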