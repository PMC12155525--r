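# Neural-network primitives for the SegNet-style encoder-decoder.
#
# Feature maps are [H, W, C] arrays; convolutions are im2col + BLAS matmul.
# Every op returns its forward output plus a cache, and has a matching
# backward producing input and parameter gradients, so the whole network
# is trained with plain reverse-mode accumulation. Batch size is 1
# throughout (the training protocol uses single-image steps), so batch
# normalization at train time normalizes each channel over its H x W
# spatial extent and keeps running moments for evaluation.

.im2colIndexCache <- new.env(parent = emptyenv())

# index matrix [H*W, k*k]: padded linear index sampled by each kernel tap
.im2colIndex <- function(H, W, k) {
  key <- paste(H, W, k, sep = "x")
  if (!is.null(.im2colIndexCache[[key]])) return(.im2colIndexCache[[key]])
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p
  h <- rep(seq_len(H), times = W)
  w <- rep(seq_len(W), each = H)
  I <- matrix(0L, H * W, k * k)
  o <- 0L
  for (dx in 0:(k - 1L)) {
    for (dy in 0:(k - 1L)) {
      o <- o + 1L
      I[, o] <- (h + dy) + (w + dx - 1L) * Hp
    }
  }
  .im2colIndexCache[[key]] <- I
  I
}

.pad2 <- function(x, p) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  out
}

# 'same' k x k convolution; W is [k*k*Cin, Cout] (taps major, channels
# minor); patch extraction and gradient scatter run in C++ (cpp_im2col /
# cpp_col2im), the matrix products on BLAS
convForward <- function(x, W, b, k) {
  d <- dim(x)
  Xcol <- cpp_im2col(x, d[1], d[2], d[3], k)
  y <- Xcol %*% W
  y <- y + rep(b, each = nrow(y))
  list(y = array(y, c(d[1], d[2], ncol(W))),
       cache = list(Xcol = Xcol, dim = d, k = k))
}

convBackward <- function(dy, W, cache) {
  d <- cache$dim
  dyM <- matrix(dy, ncol = dim(dy)[3])
  dW <- crossprod(cache$Xcol, dyM)
  db <- colSums(dyM)
  dXcol <- dyM %*% t(W)
  dx <- cpp_col2im(dXcol, d[1], d[2], d[3], cache$k)
  list(dx = array(dx, d), dW = dW, db = db)
}

.bnEps <- 1e-5

bnForward <- function(x, gamma, beta, running, train, momentum = 0.9) {
  d <- dim(x)
  M <- matrix(x, ncol = d[3])
  if (train) {
    mu <- colMeans(M)
    v <- colMeans(sweep(M, 2, mu)^2)
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  n <- nrow(M)
  sd <- sqrt(v + .bnEps)
  xhat <- (M - rep(mu, each = n)) / rep(sd, each = n)
  y <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  list(y = array(y, d), running = running,
       cache = list(xhat = xhat, sd = sd, dim = d))
}

bnBackward <- function(dy, gamma, cache) {
  d <- cache$dim
  n <- d[1] * d[2]
  dyM <- matrix(dy, ncol = d[3])
  dgamma <- colSums(dyM * cache$xhat)
  dbeta <- colSums(dyM)
  dxhat <- dyM * rep(gamma, each = n)
  # standard batch-norm gradient over the n spatial positions per channel
  t1 <- dxhat - rep(colMeans(dxhat), each = n)
  t2 <- cache$xhat * rep(colMeans(dxhat * cache$xhat), each = n)
  dx <- (t1 - t2) / rep(cache$sd, each = n)
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

reluForward <- function(x) {
  y <- pmax(x, 0)
  list(y = y, cache = x > 0)
}

reluBackward <- function(dy, cache) dy * cache

# 2 x 2 max pooling, stride 2 (H, W must be even)
poolForward <- function(x) {
  d <- dim(x)
  h <- seq(1L, d[1], by = 2L)
  w <- seq(1L, d[2], by = 2L)
  c00 <- x[h, w, , drop = FALSE]
  c10 <- x[h + 1L, w, , drop = FALSE]
  c01 <- x[h, w + 1L, , drop = FALSE]
  c11 <- x[h + 1L, w + 1L, , drop = FALSE]
  stack <- cbind(as.vector(c00), as.vector(c10), as.vector(c01), as.vector(c11))
  pick <- max.col(stack, ties.method = "first")
  y <- array(stack[cbind(seq_len(nrow(stack)), pick)],
             c(d[1] %/% 2L, d[2] %/% 2L, d[3]))
  list(y = y, cache = list(pick = pick, dim = d))
}

poolBackward <- function(dy, cache) {
  d <- cache$dim
  dh <- d[1] %/% 2L; dw <- d[2] %/% 2L
  n <- dh * dw * d[3]
  planes <- matrix(0, n, 4L)
  planes[cbind(seq_len(n), cache$pick)] <- as.vector(dy)
  dx <- array(0, d)
  h <- seq(1L, d[1], by = 2L)
  w <- seq(1L, d[2], by = 2L)
  dx[h, w, ] <- array(planes[, 1], c(dh, dw, d[3]))
  dx[h + 1L, w, ] <- array(planes[, 2], c(dh, dw, d[3]))
  dx[h, w + 1L, ] <- array(planes[, 3], c(dh, dw, d[3]))
  dx[h + 1L, w + 1L, ] <- array(planes[, 4], c(dh, dw, d[3]))
  dx
}

# transposed 2 x 2 stride-2 convolution (non-overlapping upsampling);
# W is [Cin, Cout, 4] with one weight slab per output sub-position
upconvForward <- function(x, W, b) {
  d <- dim(x)
  Cout <- dim(W)[2]
  M <- matrix(x, ncol = d[3])
  y <- array(0, c(2L * d[1], 2L * d[2], Cout))
  h <- seq(1L, 2L * d[1], by = 2L)
  w <- seq(1L, 2L * d[2], by = 2L)
  pos <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (p in 1:4) {
    yp <- M %*% W[, , p]
    yp <- yp + rep(b, each = nrow(yp))
    y[h + pos[[p]][1], w + pos[[p]][2], ] <- array(yp, c(d[1], d[2], Cout))
  }
  list(y = y, cache = list(M = M, dim = d))
}

upconvBackward <- function(dy, W, cache) {
  d <- cache$dim
  Cout <- dim(W)[2]
  h <- seq(1L, 2L * d[1], by = 2L)
  w <- seq(1L, 2L * d[2], by = 2L)
  pos <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  dW <- array(0, dim(W))
  dx <- matrix(0, d[1] * d[2], d[3])
  for (p in 1:4) {
    dyp <- matrix(dy[h + pos[[p]][1], w + pos[[p]][2], , drop = FALSE],
                  ncol = Cout)
    dW[, , p] <- crossprod(cache$M, dyp)
    dx <- dx + dyp %*% t(W[, , p])
  }
  db <- colSums(matrix(dy, ncol = Cout))
  list(dx = array(dx, d), dW = dW, db = db)
}

# channel attention: squeeze (global average pool) -> 2-layer MLP ->
# sigmoid gate, one learned weight per channel
channelAttentionForward <- function(x, p) {
  d <- dim(x)
  M <- matrix(x, ncol = d[3])
  s <- colMeans(M)
  h <- pmax(drop(s %*% p$W1), 0)
  a <- drop(h %*% p$W2)
  g <- 1 / (1 + exp(-a))
  y <- sweep(M, 2, g, "*")
  list(y = array(y, d),
       cache = list(M = M, s = s, h = h, g = g, dim = d))
}

channelAttentionBackward <- function(dy, p, cache) {
  d <- cache$dim
  dyM <- matrix(dy, ncol = d[3])
  dg <- colSums(dyM * cache$M)
  da <- dg * cache$g * (1 - cache$g)
  dW2 <- outer(cache$h, da)
  dh <- drop(p$W2 %*% da) * (cache$h > 0)
  dW1 <- outer(cache$s, dh)
  ds <- drop(p$W1 %*% dh)
  dx <- sweep(dyM, 2, cache$g, "*") +
        matrix(rep(ds / (d[1] * d[2]), each = d[1] * d[2]), ncol = d[3])
  list(dx = array(dx, d), dW1 = dW1, dW2 = dW2)
}

# spatial attention: channel mean & max pooled planes -> 7x7 conv ->
# sigmoid gate, one learned weight per position
spatialAttentionForward <- function(x, p) {
  d <- dim(x)
  M <- matrix(x, ncol = d[3])
  mn <- rowMeans(M)
  mxPick <- max.col(M, ties.method = "first")
  mx <- M[cbind(seq_len(nrow(M)), mxPick)]
  pool <- array(c(mn, mx), c(d[1], d[2], 2L))
  cv <- convForward(pool, p$W, p$b, k = 7L)
  a <- as.vector(cv$y)
  g <- 1 / (1 + exp(-a))
  y <- M * g
  list(y = array(y, d),
       cache = list(M = M, g = g, mxPick = mxPick, conv = cv$cache, dim = d))
}

spatialAttentionBackward <- function(dy, p, cache) {
  d <- cache$dim
  dyM <- matrix(dy, ncol = d[3])
  dg <- rowSums(dyM * cache$M)
  da <- dg * cache$g * (1 - cache$g)
  cb <- convBackward(array(da, c(d[1], d[2], 1L)), p$W, cache$conv)
  dpool <- matrix(cb$dx, ncol = 2L)
  dxM <- dyM * cache$g
  dxM <- dxM + dpool[, 1] / d[3]
  dxM[cbind(seq_len(nrow(dxM)), cache$mxPick)] <-
    dxM[cbind(seq_len(nrow(dxM)), cache$mxPick)] + dpool[, 2]
  list(dx = array(dxM, d), dW = cb$dW, db = cb$db)
}

# per-pixel softmax + cross-entropy against integer class targets;
# returns mean loss and the logits gradient
softmaxLoss <- function(logits, target) {
  d <- dim(logits)
  M <- matrix(logits, ncol = d[3])
  M <- M - M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  e <- exp(M)
  probs <- e / rowSums(e)
  n <- nrow(M)
  idx <- cbind(seq_len(n), as.vector(target))
  loss <- -mean(log(pmax(probs[idx], 1e-12)))
  dlog <- probs
  dlog[idx] <- dlog[idx] - 1
  list(loss = loss, probs = array(probs, d),
       dlogits = array(dlog / n, d))
}

softmaxProbs <- function(logits) {
  d <- dim(logits)
  M <- matrix(logits, ncol = d[3])
  M <- M - M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  e <- exp(M)
  array(e / rowSums(e), d)
}
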