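# Neural layers with explicit forward/backward passes.
#
# Every *_fw() returns the layer output together with the cache its *_bw()
# needs; backward passes return gradients for inputs and parameters.
# Correctness is pinned down by finite-difference gradient checks in the
# test suite.

relu_fw <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}
relu_bw <- function(x, dy) {
  dy[x <= 0] <- 0
  dy
}

# Inverted dropout; identity when not training.
dropout_fw <- function(x, p, train) {
  if (!train || p <= 0) return(list(y = x, mask = NULL))
  mask <- stats::rbinom(length(x), 1L, 1 - p) / (1 - p)
  if (!is.null(dim(x))) dim(mask) <- dim(x)
  list(y = x * mask, mask = mask)
}
dropout_bw <- function(mask, dy) if (is.null(mask)) dy else dy * mask

softmax_rows <- function(s) {
  s <- s - apply(s, 1, max)
  e <- exp(s)
  e / rowSums(e)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Numerically stable binary cross-entropy on the logit scale.
bce_from_logit <- function(logit, y) {
  pmax(logit, 0) - logit * y + log1p(exp(-abs(logit)))
}

#' Fixed sinusoidal positional-encoding table
#'
#' Classical transformer encoding: `PE[pos, 2i] = sin(pos / 10000^(2i/D))`,
#' `PE[pos, 2i+1] = cos(pos / 10000^(2i/D))` with `pos` starting at 0.
#'
#' @param t_len sequence length (rows).
#' @param d feature dimension (columns).
#' @return A `t_len` x `d` matrix.
#' @export
positional_encoding_table <- function(t_len, d) {
  pos <- 0:(t_len - 1)
  pe <- matrix(0, t_len, d)
  for (j in seq_len(d)) {
    i2 <- if (j %% 2 == 1) j - 1 else j - 2    # the 2i exponent, 0-based
    angle <- pos / 10000^(i2 / d)
    pe[, j] <- if (j %% 2 == 1) sin(angle) else cos(angle)
  }
  pe
}

## ---- single-direction LSTM -------------------------------------------------

lstm_dir_fw <- function(X, Wx, Wh, b) {
  res <- lstm_fw_cpp(X, Wx, Wh, b)
  res$X <- X; res$Wx <- Wx; res$Wh <- Wh
  list(out = res$out, cache = res)
}

lstm_dir_bw <- function(cache, dH) {
  lstm_bw_cpp(cache$X, cache$Wx, cache$Wh, cache$I, cache$F, cache$G,
              cache$O, cache$Tc, cache$Cprev, cache$Hprev, dH)
}

## ---- bidirectional layer ---------------------------------------------------

bilstm_layer_fw <- function(X, p, prefix) {
  T_ <- nrow(X)
  fw <- lstm_dir_fw(X, p[[paste0(prefix, ".fwd.Wx")]],
                    p[[paste0(prefix, ".fwd.Wh")]], p[[paste0(prefix, ".fwd.b")]])
  bw <- lstm_dir_fw(X[T_:1, , drop = FALSE], p[[paste0(prefix, ".bwd.Wx")]],
                    p[[paste0(prefix, ".bwd.Wh")]], p[[paste0(prefix, ".bwd.b")]])
  list(out = cbind(fw$out, bw$out[T_:1, , drop = FALSE]),
       cache = list(fw = fw$cache, bw = bw$cache, T_ = T_))
}

bilstm_layer_bw <- function(cache, dY, prefix) {
  T_ <- cache$T_; H <- ncol(dY) / 2
  gf <- lstm_dir_bw(cache$fw, dY[, 1:H, drop = FALSE])
  gb <- lstm_dir_bw(cache$bw, dY[T_:1, (H + 1):(2 * H), drop = FALSE])
  grads <- list(gf$dWx, gf$dWh, gf$db, gb$dWx, gb$dWh, gb$db)
  names(grads) <- paste0(prefix, c(".fwd.Wx", ".fwd.Wh", ".fwd.b",
                                   ".bwd.Wx", ".bwd.Wh", ".bwd.b"))
  list(dX = gf$dX + gb$dX[T_:1, , drop = FALSE], grads = grads)
}

## ---- multi-head self-attention ---------------------------------------------

attention_fw <- function(X, p, heads, prefix = "attn") {
  D <- ncol(X); dh <- D / heads
  nm <- function(s) p[[paste0(prefix, ".", s)]]
  Q <- X %*% nm("wq.w") + rep(1, nrow(X)) %o% nm("wq.b")
  K <- X %*% nm("wk.w") + rep(1, nrow(X)) %o% nm("wk.b")
  V <- X %*% nm("wv.w") + rep(1, nrow(X)) %o% nm("wv.b")
  A <- array(0, dim = c(heads, nrow(X), nrow(X)))
  O <- matrix(0, nrow(X), D)
  for (h in seq_len(heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dh)
    Ah <- softmax_rows(S)
    A[h, , ] <- Ah
    O[, idx] <- Ah %*% V[, idx, drop = FALSE]
  }
  Y <- O %*% nm("wo.w") + rep(1, nrow(X)) %o% nm("wo.b")
  list(out = Y, weights = A,
       cache = list(X = X, Q = Q, K = K, V = V, A = A, O = O,
                    heads = heads, dh = dh))
}

attention_bw <- function(cache, dY, p, prefix = "attn") {
  X <- cache$X; heads <- cache$heads; dh <- cache$dh
  nm <- function(s) p[[paste0(prefix, ".", s)]]
  dO <- dY %*% t(nm("wo.w"))
  dQ <- dK <- dV <- matrix(0, nrow(X), ncol(X))
  for (h in seq_len(heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    Ah <- cache$A[h, , ]
    dOh <- dO[, idx, drop = FALSE]
    Vh <- cache$V[, idx, drop = FALSE]
    dA <- dOh %*% t(Vh)
    dV[, idx] <- t(Ah) %*% dOh
    dS <- Ah * (dA - rowSums(dA * Ah))
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(dh)
    dK[, idx] <- t(dS) %*% cache$Q[, idx, drop = FALSE] / sqrt(dh)
  }
  grads <- list(crossprod(cache$O, dY), colSums(dY),
                crossprod(X, dQ), colSums(dQ),
                crossprod(X, dK), colSums(dK),
                crossprod(X, dV), colSums(dV))
  names(grads) <- paste0(prefix, ".",
                         c("wo.w", "wo.b", "wq.w", "wq.b",
                           "wk.w", "wk.b", "wv.w", "wv.b"))
  dX <- dQ %*% t(nm("wq.w")) + dK %*% t(nm("wk.w")) + dV %*% t(nm("wv.w"))
  list(dX = dX, grads = grads)
}

## ---- compact CNN backbone --------------------------------------------------

# Input (H, W, 3, N) with H = W divisible by 32. A 4x4 average-pool stem
# is followed by three conv(3x3)/pool(2x2) blocks (8 -> 16 -> 32 channels),
# global average pooling, and a linear map to `d_out` features per image.
small_cnn_fw <- function(x, p, d_out, s0 = NULL) {
  if (is.null(s0)) s0 <- avgpool_fw(x, 4L)
  r1 <- conv2d_fw(s0, p[["cnn.conv1.w"]], p[["cnn.conv1.b"]], relu = TRUE)
  p1 <- avgpool_fw(r1, 2L)
  r2 <- conv2d_fw(p1, p[["cnn.conv2.w"]], p[["cnn.conv2.b"]], relu = TRUE)
  p2 <- avgpool_fw(r2, 2L)
  r3 <- conv2d_fw(p2, p[["cnn.conv3.w"]], p[["cnn.conv3.b"]], relu = TRUE)
  p3 <- avgpool_fw(r3, 2L)
  d <- dim(p3)                                   # (h, w, 32, N)
  gap <- t(matrix(colMeans(matrix(p3, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
  feat <- gap %*% p[["cnn.fc.w"]] + rep(1, d[4]) %o% p[["cnn.fc.b"]]
  list(out = feat,                               # (N, d_out)
       cache = list(s0 = s0, r1 = r1, p1 = p1, r2 = r2, p2 = p2,
                    r3 = r3, p3dim = d, gap = gap))
}

small_cnn_bw <- function(cache, dFeat, p) {
  d <- cache$p3dim
  grads <- list()
  grads[["cnn.fc.w"]] <- crossprod(cache$gap, dFeat)
  grads[["cnn.fc.b"]] <- colSums(dFeat)
  dgap <- dFeat %*% t(p[["cnn.fc.w"]])           # (N, 32)
  dp3 <- array(rep(t(dgap) / (d[1] * d[2]), each = d[1] * d[2]), dim = d)
  dr3 <- avgpool_bw(dp3, 2L, d[1] * 2L, d[2] * 2L)
  g3 <- conv2d_bw(cache$p2, p[["cnn.conv3.w"]], dr3, cache$r3, relu = TRUE)
  grads[["cnn.conv3.w"]] <- g3$dw; grads[["cnn.conv3.b"]] <- g3$db
  d2 <- dim(cache$r2)
  dr2 <- avgpool_bw(g3$dx, 2L, d2[1], d2[2])
  g2 <- conv2d_bw(cache$p1, p[["cnn.conv2.w"]], dr2, cache$r2, relu = TRUE)
  grads[["cnn.conv2.w"]] <- g2$dw; grads[["cnn.conv2.b"]] <- g2$db
  d1 <- dim(cache$r1)
  dr1 <- avgpool_bw(g2$dx, 2L, d1[1], d1[2])
  g1 <- conv2d_bw(cache$s0, p[["cnn.conv1.w"]], dr1, cache$r1, relu = TRUE,
                  need_dx = FALSE)
  grads[["cnn.conv1.w"]] <- g1$dw; grads[["cnn.conv1.b"]] <- g1$db
  list(grads = grads)                            # input gradient not needed
}
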