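# Host-arithmetic training engine for the desk-scale DnCNN: same-padded 3x3
# convolution as nine shifted matrix multiplies (BLAS), batch norm with batch
# statistics plus running averages, ReLU, and Adam. Batches are N x H x W x C
# arrays. Stride is 1 throughout the network; spatial size is preserved.

conv_fwd_host <- function(x4, W, b) {
  d <- dim(x4); N <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  k <- dim(W)[1]; Cout <- dim(W)[4]; p <- (k - 1) / 2
  xp <- array(0, c(N, H + 2 * p, Wd + 2 * p, C))
  xp[, p + seq_len(H), p + seq_len(Wd), ] <- x4
  om <- matrix(0, N * H * Wd, Cout)
  for (kh in seq_len(k)) for (kw in seq_len(k)) {
    xs <- xp[, kh:(kh + H - 1), kw:(kw + Wd - 1), , drop = FALSE]
    dim(xs) <- c(N * H * Wd, C)
    om <- om + xs %*% matrix(W[kh, kw, , ], C, Cout)
  }
  om <- om + matrix(b, N * H * Wd, Cout, byrow = TRUE)
  out <- om; dim(out) <- c(N, H, Wd, Cout)
  list(out = out, xp = xp)
}

conv_bwd_host <- function(dY, cache, W) {
  xp <- cache$xp
  k <- dim(W)[1]; C <- dim(W)[3]; Cout <- dim(W)[4]; p <- (k - 1) / 2
  d <- dim(dY); N <- d[1]; H <- d[2]; Wd <- d[3]
  dYm <- dY; dim(dYm) <- c(N * H * Wd, Cout)
  dW <- array(0, dim(W)); db <- colSums(dYm)
  dXp <- array(0, dim(xp))
  for (kh in seq_len(k)) for (kw in seq_len(k)) {
    xs <- xp[, kh:(kh + H - 1), kw:(kw + Wd - 1), , drop = FALSE]
    dim(xs) <- c(N * H * Wd, C)
    dW[kh, kw, , ] <- crossprod(xs, dYm)
    dxs <- dYm %*% t(matrix(W[kh, kw, , ], C, Cout))
    dim(dxs) <- c(N, H, Wd, C)
    dXp[, kh:(kh + H - 1), kw:(kw + Wd - 1), ] <-
      dXp[, kh:(kh + H - 1), kw:(kw + Wd - 1), , drop = FALSE] + dxs
  }
  dX <- dXp[, p + seq_len(H), p + seq_len(Wd), , drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

bn_fwd_host <- function(x4, gamma, beta, eps = 1e-5) {
  d <- dim(x4); C <- d[4]; n <- prod(d[1:3])
  xm <- x4; dim(xm) <- c(n, C)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  ym <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  out <- ym; dim(out) <- d
  list(out = out, xhat = xhat, istd = istd, mu = mu, v = v)
}

bn_bwd_host <- function(dY, cache, gamma) {
  d <- dim(dY); C <- d[4]; n <- prod(d[1:3])
  dym <- dY; dim(dym) <- c(n, C)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  m1 <- colMeans(dym)
  m2 <- colMeans(dym * cache$xhat)
  dxm <- sweep(sweep(dym, 2, m1) - sweep(cache$xhat, 2, m2, `*`),
               2, gamma * cache$istd, `*`)
  dX <- dxm; dim(dX) <- d
  dX
}

bn_infer_host <- function(x4, gamma, beta, mean, var, eps = 1e-5) {
  d <- dim(x4); C <- d[4]; n <- prod(d[1:3])
  xm <- x4; dim(xm) <- c(n, C)
  ym <- sweep(sweep(sweep(sweep(xm, 2, mean), 2, 1 / sqrt(var + eps), `*`),
                    2, gamma, `*`), 2, beta, `+`)
  dim(ym) <- d
  ym
}

adam_init <- function(params) {
  lapply(params, function(p) list(m = array(0, dim(p) %||% length(p)),
                                  v = array(0, dim(p) %||% length(p))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(p, g, st, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mh <- st$m / (1 - b1^t)
  vh <- st$v / (1 - b2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), st = st)
}

sigmoid <- function(z) 1 / (1 + exp(-z))
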