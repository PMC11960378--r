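# Low-level neural-network operations with explicit forward caches and
# hand-written gradients. Feature-map tensors are column-major arrays
# (frames, features, channels, batch); convolution kernels are
# (kh, kw, Cin, Cout). Convolution itself (im2col + GEMM) lives in src/.

glorot_uniform <- function(dims, fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -limit, limit), dims)
}

init_conv <- function(kh, kw, cin, cout, bias) {
  w <- glorot_uniform(c(kh, kw, cin, cout), kh * kw * cin, kh * kw * cout)
  if (bias) list(w = w, b = numeric(cout)) else list(w = w)
}

init_bn <- function(c) list(gamma = rep(1, c), beta = rep(0, c))

init_dense <- function(fin, fout, bias = TRUE) {
  list(w = glorot_uniform(c(fin, fout), fin, fout),
       b = if (bias) numeric(fout))
}

init_gru <- function(fin, units) {
  list(w = glorot_uniform(c(fin, 3L * units), fin, units),
       u = glorot_uniform(c(units, 3L * units), units, units),
       b_in = numeric(3L * units), b_rec = numeric(3L * units))
}

conv_fw <- function(x, p) {
  conv2d_fw(x, p$w, if (is.null(p$b)) numeric(0) else p$b)
}

conv_bw <- function(x, p, dy) {
  conv2d_bw(x, p$w, dy, !is.null(p$b))
}

relu_fw <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(y = x, mask = mask)
}

relu_bw <- function(dy, mask) dy * mask

# batch norm over (H, W, B) per channel; tensors (H, W, C, B).
# Per-channel reductions and affine maps are fused C++ passes.
bn_fw <- function(x, p, training, run, eps = 1e-5) {
  d <- dim(x)
  m <- d[1] * d[2] * d[4]
  if (training) {
    s <- chan_dot(x, numeric(0))
    mu <- s$s1 / m
    var <- s$s2 / m - mu^2
    run$k <- run$k + 1L
    run$mean <- run$momentum * run$mean + (1 - run$momentum) * mu
    run$var <- run$momentum * run$var + (1 - run$momentum) * var
  } else {
    corr <- 1 - run$momentum^max(run$k, 1L)
    mu <- run$mean / corr
    var <- run$var / corr
  }
  invstd <- 1 / sqrt(var + eps)
  xhat <- chan_affine(x, invstd, -mu * invstd)
  y <- chan_affine(xhat, p$gamma, p$beta)
  list(y = y, cache = list(xhat = xhat, invstd = invstd, dims = d),
       run = run)
}

bn_bw <- function(dy, p, cache) {
  d <- cache$dims
  m <- d[1] * d[2] * d[4]
  s <- chan_dot(dy, cache$xhat)
  dbeta <- s$s1
  dgamma <- s$s2
  a <- p$gamma * cache$invstd
  dx <- chan_affine2(dy, cache$xhat, a, -a * dgamma / m, -a * dbeta / m)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

bn_new_state <- function(c, momentum = 0.9) {
  list(mean = numeric(c), var = numeric(c), momentum = momentum, k = 0L)
}

# max pool with kernel (1, 2), stride (1, 2): halves the feature axis,
# preserves the frame axis
maxpool12_fw <- function(x) {
  d <- dim(x)
  odd <- x[, seq(1L, d[2], by = 2L), , , drop = FALSE]
  even <- x[, seq(2L, d[2], by = 2L), , , drop = FALSE]
  mask <- odd >= even
  list(y = pmax(odd, even), mask = mask, dims = d)
}

maxpool12_bw <- function(dy, cache) {
  dx <- array(0, cache$dims)
  dx[, seq(1L, cache$dims[2], by = 2L), , ] <- dy * cache$mask
  dx[, seq(2L, cache$dims[2], by = 2L), , ] <- dy * (!cache$mask)
  dx
}

# time-distributed dense on (B, T, F) -> (B, T, U)
tdense_fw <- function(x, p) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1] * d[2], d[3])
  y <- xm %*% p$w
  if (!is.null(p$b)) y <- y + rep(p$b, each = nrow(y))
  dim(y) <- c(d[1], d[2], ncol(p$w))
  y
}

tdense_bw <- function(x, p, dy) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1] * d[2], d[3])
  dym <- dy; dim(dym) <- c(d[1] * d[2], dim(dy)[3])
  dw <- crossprod(xm, dym)
  db <- if (is.null(p$b)) NULL else .colSums(dym, nrow(dym), ncol(dym))
  dx <- tcrossprod(dym, p$w)
  dim(dx) <- d
  list(dx = dx, dw = dw, db = db)
}

dropout_fw <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- (stats::runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(y = x * mask, mask = mask)
}

dropout_bw <- function(dy, mask) if (is.null(mask)) dy else dy * mask

sigmoid <- function(z) 1 / (1 + exp(-z))
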