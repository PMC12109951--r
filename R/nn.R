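# Minimal neural-network primitives used by the EMACNN classifier.
#
# Feature maps are stored as arrays [C, P, B] where P = H*W (row index h
# varies fastest) and B is the batch. Convolutions use "same" padding and
# are computed as a sum over kernel offsets of a channel-mixing matrix
# product on shifted copies of the map; a sentinel column (P+1) holds the
# zero padding. Every layer has an explicit backward pass; gradients are
# verified against finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_cols <- function(M) {
  M <- M - rep(apply(M, 2L, max), each = nrow(M))
  E <- exp(M)
  E / rep(colSums(E), each = nrow(M))
}

# ---- convolution ----------------------------------------------------------

conv_plan <- function(H, W, kh, kw) {
  list(K = kh * kw, kh = as.integer(kh), kw = as.integer(kw),
       H = H, W = W, P = H * W)
}

conv_fwd <- function(X, par, plan) {
  out <- cpp_conv_fwd(X, par$W, par$b, plan$kh, plan$kw, plan$H, plan$W)
  list(out = out, X = X)
}

conv_bwd <- function(dY, cache, par, plan) {
  cpp_conv_bwd(dY, cache$X, par$W, plan$kh, plan$kw, plan$H, plan$W)
}

# ---- batch normalization --------------------------------------------------

bn_fwd <- function(X, par, state, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(X); C <- d[1L]; nc <- length(X) %/% C
  if (train) {
    mu <- .rowMeans(X, C, nc)
    v <- .rowMeans(X * X, C, nc) - mu * mu
    v[v < 0] <- 0
    state$rmean <- (1 - momentum) * state$rmean + momentum * mu
    state$rvar <- (1 - momentum) * state$rvar + momentum * v
  } else {
    mu <- state$rmean
    v <- state$rvar
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- (X - mu) * istd  # per-channel recycling (C fastest)
  list(out = xhat * par$gamma + par$beta, xhat = xhat, istd = istd,
       state = state, train = train)
}

bn_bwd <- function(dY, cache, par) {
  C <- dim(dY)[1L]; nc <- length(dY) %/% C
  xhat <- cache$xhat
  dgamma <- .rowSums(dY * xhat, C, nc)
  dbeta <- .rowSums(dY, C, nc)
  dxhat <- dY * par$gamma
  if (cache$train) {
    m1 <- .rowMeans(dxhat, C, nc)
    m2 <- .rowMeans(dxhat * xhat, C, nc)
    dX <- cache$istd * (dxhat - m1 - xhat * m2)
  } else {
    dX <- cache$istd * dxhat
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- relu -----------------------------------------------------------------

relu_fwd <- function(X) {
  M <- X > 0
  list(out = X * M, mask = M)
}

relu_bwd <- function(dY, cache) dY * cache$mask

# ---- 2x2 pooling (stride 2, trailing odd row/column dropped) --------------

pool_plan <- function(H, W) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  if (Ho < 1L || Wo < 1L) stop("feature map too small to pool")
  ho <- rep(seq_len(Ho), times = Wo)
  wo <- rep(seq_len(Wo), each = Ho)
  idx <- vector("list", 4L)
  k <- 0L
  for (dw in 0:1) for (dh in 0:1) {
    k <- k + 1L
    idx[[k]] <- (2L * ho - 1L + dh) + (2L * wo - 2L + dw) * H
  }
  list(idx = idx, H = Ho, W = Wo, P = Ho * Wo)
}

pool_fwd <- function(X, plan, type = "max") {
  s <- lapply(plan$idx, function(ix) X[, ix, , drop = FALSE])
  if (type == "max") {
    Y <- pmax(s[[1L]], s[[2L]], s[[3L]], s[[4L]])
    taken <- array(FALSE, dim(Y))
    masks <- vector("list", 4L)
    for (k in 1:4) {
      m <- (s[[k]] == Y) & !taken
      taken <- taken | m
      masks[[k]] <- m
    }
    list(out = Y, masks = masks, type = type)
  } else {
    Y <- (s[[1L]] + s[[2L]] + s[[3L]] + s[[4L]]) / 4
    list(out = Y, type = type)
  }
}

pool_bwd <- function(dY, cache, plan, C, P_in, B) {
  dX <- array(0, c(C, P_in, B))
  for (k in 1:4) {
    g <- if (cache$type == "max") dY * cache$masks[[k]] else dY / 4
    dX[, plan$idx[[k]], ] <- dX[, plan$idx[[k]], , drop = FALSE] + g
  }
  dX
}

# ---- efficient multi-scale attention (EMA) --------------------------------
#
# Channels are split into `groups` sub-features which are folded into the
# batch dimension and share weights. Per group: directional descriptors
# (mean over width, mean over height) pass through a shared 1x1 transform
# and sigmoid-gate the group; a parallel 3x3 convolution captures local
# context; the two branch outputs are combined by cross-spatial weighting
# (channel-softmax descriptors of each branch weight the spatial map of the
# other) into a spatial sigmoid gate on the input. Output shape equals
# input shape.

ema_init <- function(channels, groups = 4L, seed = NULL) {
  if (channels %% groups != 0L)
    stop("channels (", channels, ") not divisible by groups (", groups, ")")
  Cg <- channels %/% groups
  if (!is.null(seed)) set.seed(seed)
  list(W1 = matrix(stats::rnorm(Cg * Cg, sd = sqrt(2 / Cg)), Cg, Cg),
       b1 = numeric(Cg),
       W3 = array(stats::rnorm(Cg * Cg * 9L, sd = sqrt(2 / (9 * Cg))),
                  c(Cg, Cg, 9L)),
       b3 = numeric(Cg))
}

ema_fwd <- function(X, par, plan3, groups) {
  d <- dim(X); C <- d[1L]; P <- d[2L]; B <- d[3L]
  if (C %% groups != 0L)
    stop("channels (", C, ") not divisible by groups (", groups, ")")
  Cg <- C %/% groups
  H <- plan3$H; W <- plan3$W
  B2 <- groups * B
  Z <- cpp_group_fold(X, groups)
  red <- cpp_dir_reduce(Z, H, W)
  vh <- red$h / W
  vw <- red$w / H
  th <- par$W1 %*% matrix(vh, Cg) + par$b1
  tw <- par$W1 %*% matrix(vw, Cg) + par$b1
  gh <- array(sigmoid(th), c(Cg, H, B2))
  gw <- array(sigmoid(tw), c(Cg, W, B2))
  X1 <- cpp_gate_mul(Z, gh, gw, H, W)
  cf <- conv_fwd(Z, list(W = par$W3, b = par$b3), plan3)
  X2 <- cf$out
  a1 <- softmax_cols(cpp_dir_reduce(X1, H, W)$s / P)
  a2 <- softmax_cols(cpp_dir_reduce(X2, H, W)$s / P)
  m2v <- cpp_chan_weight(X2, a1)
  m1v <- cpp_chan_weight(X1, a2)
  wv <- sigmoid(m1v + m2v)  # [P, B2] spatial gate
  O <- cpp_spatial_gate(Z, wv)
  out <- cpp_group_unfold(O, groups)
  list(out = out, Z = Z, gh = gh, gw = gw, X1 = X1, X2 = X2, vh = vh,
       vw = vw, conv_cache = cf, a1 = a1, a2 = a2, wv = wv,
       dims = c(Cg, P, B2, H, W, groups, B))
}

ema_bwd <- function(dOut, cache, par, plan3) {
  dm <- cache$dims
  Cg <- dm[1L]; P <- dm[2L]; B2 <- dm[3L]; H <- dm[4L]; W <- dm[5L]
  groups <- dm[6L]
  dO <- cpp_group_fold(dOut, groups)
  sg <- cpp_spatial_gate_bwd(dO, cache$Z, cache$wv)
  dsv <- sg$dwv * cache$wv * (1 - cache$wv)
  cw1 <- cpp_chan_weight_bwd(cache$X1, cache$a2, dsv)
  cw2 <- cpp_chan_weight_bwd(cache$X2, cache$a1, dsv)
  da2 <- cw1$da
  da1 <- cw2$da
  dg1 <- cache$a1 * (da1 - rep(colSums(da1 * cache$a1), each = Cg))
  dg2 <- cache$a2 * (da2 - rep(colSums(da2 * cache$a2), each = Cg))
  ones <- matrix(1, P, B2)
  dX1 <- cpp_add_outer(cw1$dX, dg1 / P, ones)
  dX2 <- cpp_add_outer(cw2$dX, dg2 / P, ones)
  cb <- conv_bwd(dX2, cache$conv_cache, list(W = par$W3, b = par$b3), plan3)
  gb <- cpp_gate_bwd(dX1, cache$Z, cache$gh, cache$gw, H, W)
  dth <- matrix(gb$dgh * cache$gh * (1 - cache$gh), Cg)
  dtw <- matrix(gb$dgw * cache$gw * (1 - cache$gw), Cg)
  dW1 <- dth %*% t(matrix(cache$vh, Cg)) + dtw %*% t(matrix(cache$vw, Cg))
  db1 <- rowSums(dth) + rowSums(dtw)
  dvh <- array(crossprod(par$W1, dth), c(Cg, H, B2))
  dvw <- array(crossprod(par$W1, dtw), c(Cg, W, B2))
  dZ <- cpp_add_dir(sg$dZ + cb$dX + gb$dZ, dvh / W, dvw / H, H, W)
  dX <- cpp_group_unfold(dZ, groups)
  list(dX = dX,
       grad = list(W1 = dW1, b1 = db1, W3 = cb$dW, b3 = cb$db))
}

# ---- LSTM (final-state readout) -------------------------------------------

lstm_init <- function(D, Hd, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sdx <- sqrt(1 / D); sdh <- sqrt(1 / Hd)
  b <- numeric(4L * Hd)
  b[Hd + seq_len(Hd)] <- 1  # forget-gate bias
  list(Wx = matrix(stats::rnorm(4L * Hd * D, sd = sdx), 4L * Hd, D),
       Wh = matrix(stats::rnorm(4L * Hd * Hd, sd = sdh), 4L * Hd, Hd),
       b = b)
}

lstm_fwd <- function(Xseq, par, Hd) {
  d <- dim(Xseq); D <- d[1L]; Tn <- d[2L]; B <- d[3L]
  h <- matrix(0, Hd, B)
  cs <- matrix(0, Hd, B)
  caches <- vector("list", Tn)
  i1 <- seq_len(Hd); i2 <- Hd + i1; i3 <- 2L * Hd + i1; i4 <- 3L * Hd + i1
  for (t in seq_len(Tn)) {
    xt <- matrix(Xseq[, t, ], D, B)
    pre <- par$Wx %*% xt + par$Wh %*% h + par$b
    ig <- sigmoid(pre[i1, , drop = FALSE])
    fg <- sigmoid(pre[i2, , drop = FALSE])
    gg <- tanh(pre[i3, , drop = FALSE])
    og <- sigmoid(pre[i4, , drop = FALSE])
    c_prev <- cs
    cs <- fg * c_prev + ig * gg
    tc <- tanh(cs)
    hprev <- h
    h <- og * tc
    caches[[t]] <- list(xt = xt, i = ig, f = fg, g = gg, o = og,
                        c_prev = c_prev, tc = tc, hprev = hprev)
  }
  list(out = h, caches = caches)
}

lstm_bwd <- function(dh_T, caches, par, Hd) {
  Tn <- length(caches)
  B <- ncol(dh_T)
  D <- ncol(par$Wx)
  dWx <- matrix(0, 4L * Hd, D)
  dWh <- matrix(0, 4L * Hd, Hd)
  db <- numeric(4L * Hd)
  dh <- dh_T
  dc <- matrix(0, Hd, B)
  dXseq <- array(0, c(D, Tn, B))
  for (t in rev(seq_len(Tn))) {
    ca <- caches[[t]]
    do_ <- dh * ca$tc
    dc <- dc + dh * ca$o * (1 - ca$tc^2)
    dpre <- rbind(dc * ca$g * ca$i * (1 - ca$i),
                  dc * ca$c_prev * ca$f * (1 - ca$f),
                  dc * ca$i * (1 - ca$g^2),
                  do_ * ca$o * (1 - ca$o))
    dWx <- dWx + dpre %*% t(ca$xt)
    dWh <- dWh + dpre %*% t(ca$hprev)
    db <- db + rowSums(dpre)
    dXseq[, t, ] <- crossprod(par$Wx, dpre)
    dh <- crossprod(par$Wh, dpre)
    dc <- dc * ca$f
  }
  list(dX = dXseq, grad = list(Wx = dWx, Wh = dWh, b = db))
}

# ---- parameter-tree utilities ---------------------------------------------

par_unlist <- function(p) unlist(p, use.names = FALSE)

par_relist <- function(vec, skeleton) {
  pos <- 0L
  walk <- function(node) {
    if (is.list(node)) return(lapply(node, walk))
    n <- length(node)
    out <- vec[pos + seq_len(n)]
    pos <<- pos + n
    attributes(out) <- attributes(node)
    out
  }
  out <- walk(skeleton)
  stopifnot(pos == length(vec))
  out
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(vec, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad * grad
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  list(vec = vec - lr * mhat / (sqrt(vhat) + eps), state = st)
}
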