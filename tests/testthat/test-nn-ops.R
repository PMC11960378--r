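# gradient checks at small shapes for every hand-written operation; the
# builders only fix the canonical (64, 256, 19) input, the ops are generic

test_that("convolution gradients match finite differences", {
  set.seed(101)
  x <- array(rnorm(5 * 6 * 3 * 2), c(5, 6, 3, 2))
  dy4 <- array(rnorm(5 * 6 * 4 * 2), c(5, 6, 4, 2))
  for (ks in c(3L, 1L)) {
    p <- list(w = array(rnorm(ks * ks * 3 * 4) * 0.4, c(ks, ks, 3, 4)),
              b = rnorm(4) * 0.1)
    if (ks == 3L) p_nb <- list(w = p$w)       # bias-free variant
    loss <- function(xx, ww = p$w, bb = p$b) {
      sum(swdnet:::conv2d_fw(array(xx, dim(x)), array(ww, dim(p$w)), bb) *
            dy4)
    }
    g <- swdnet:::conv_bw(x, p, dy4)
    expect_lt(relerr(g$dx, array(num_grad(function(v) loss(v), x), dim(x))),
              1e-6)
    expect_lt(relerr(g$dw, array(num_grad(function(v) loss(x, ww = v),
                                          p$w), dim(p$w))), 1e-6)
    expect_lt(relerr(g$db, num_grad(function(v) loss(x, bb = v), p$b)),
              1e-6)
  }
})

test_that("batch-norm forward/backward are consistent and exact", {
  set.seed(102)
  x <- array(rnorm(4 * 5 * 3 * 2), c(4, 5, 3, 2))
  p <- list(gamma = runif(3, 0.5, 1.5), beta = rnorm(3))
  dy <- array(rnorm(length(x)), dim(x))
  fw <- swdnet:::bn_fw(x, p, TRUE, swdnet:::bn_new_state(3))
  # normalized output: per-channel mean 0, sd 1 (up to eps)
  for (c in 1:3) {
    xh <- fw$cache$xhat[, , c, ]
    expect_lt(abs(mean(xh)), 1e-12)
    expect_equal(sd(as.vector(xh)) * sqrt(39 / 40), 1, tolerance = 1e-4)
  }
  g <- swdnet:::bn_bw(dy, p, fw$cache)
  lossf <- function(xx, gg = p$gamma, be = p$beta) {
    r <- swdnet:::bn_fw(array(xx, dim(x)), list(gamma = gg, beta = be),
                        TRUE, swdnet:::bn_new_state(3))
    sum(r$y * dy)
  }
  expect_lt(relerr(g$dx, array(num_grad(function(v) lossf(v), x), dim(x))),
            1e-5)
  expect_lt(relerr(g$dgamma, num_grad(function(v) lossf(x, gg = v),
                                      p$gamma)), 1e-6)
  expect_lt(relerr(g$dbeta, num_grad(function(v) lossf(x, be = v),
                                     p$beta)), 1e-6)
})

test_that("inference-mode batch norm uses debiased running statistics", {
  set.seed(103)
  p <- list(gamma = rep(1, 2), beta = rep(0, 2))
  run <- swdnet:::bn_new_state(2)
  x <- array(rnorm(6 * 6 * 2 * 4, mean = 3, sd = 2), c(6, 6, 2, 4))
  for (i in 1:20) run <- swdnet:::bn_fw(x, p, TRUE, run)$run
  out <- swdnet:::bn_fw(x, p, FALSE, run)
  expect_lt(abs(mean(out$y)), 0.05)
  expect_equal(sd(as.vector(out$y)), 1, tolerance = 0.05)
})

test_that("max pooling (1,2) halves features, keeps frames, routes
           gradients to the argmax", {
  set.seed(104)
  x <- array(rnorm(3 * 8 * 2 * 2), c(3, 8, 2, 2))
  fw <- swdnet:::maxpool12_fw(x)
  expect_equal(dim(fw$y), c(3L, 4L, 2L, 2L))
  expect_equal(fw$y[2, 3, 1, 1], max(x[2, 5:6, 1, 1]))
  dy <- array(rnorm(3 * 4 * 2 * 2), c(3, 4, 2, 2))
  g <- swdnet:::maxpool12_bw(dy, fw[-1L])
  lf <- function(v) sum(swdnet:::maxpool12_fw(array(v, dim(x)))$y * dy)
  expect_lt(relerr(g, array(num_grad(lf, x), dim(x))), 1e-6)
})

test_that("GRU gradients match finite differences (dual-bias form)", {
  set.seed(105)
  X <- array(rnorm(2 * 5 * 4), c(2, 5, 4))
  p <- swdnet:::init_gru(4, 3)
  dH <- array(rnorm(2 * 5 * 3), c(2, 5, 3))
  fg <- swdnet:::gru_fw(X, p)
  g <- swdnet:::gru_bw(p, fg$cache, dH)
  lossg <- function(pl) sum(swdnet:::gru_fw(X, pl)$h * dH)
  for (nm in c("w", "u", "b_in", "b_rec")) {
    num <- num_grad(function(v) {
      pl <- p; pl[[nm]][] <- v; lossg(pl)
    }, p[[nm]])
    expect_lt(relerr(g[[paste0("d", nm)]], num), 1e-6)
  }
  numx <- num_grad(function(v) sum(swdnet:::gru_fw(array(v, dim(X)),
                                                   p)$h * dH), X)
  expect_lt(relerr(g$dX, array(numx, dim(X))), 1e-6)
})

test_that("GRU parameter count follows 3 u (f + u + 2) per direction", {
  p <- swdnet:::init_gru(1024, 128)
  expect_equal(sum(vapply(p, length, 0L)), 3L * 128L * (1024L + 128L + 2L))
  expect_equal(swdnet:::gru_param_count(1024, 128) * 2L, 886272L)
})

test_that("bidirectional wrapper concatenates directions and back-props", {
  set.seed(106)
  X <- array(rnorm(2 * 4 * 3), c(2, 4, 3))
  pf <- swdnet:::init_gru(3, 2); pb <- swdnet:::init_gru(3, 2)
  fw <- swdnet:::bigru_fw(X, pf, pb)
  expect_equal(dim(fw$h), c(2L, 4L, 4L))
  # forward half equals the unidirectional run
  expect_equal(fw$h[, , 1:2], swdnet:::gru_fw(X, pf)$h)
  dH <- array(rnorm(2 * 4 * 4), c(2, 4, 4))
  g <- swdnet:::bigru_bw(pf, pb, fw$cache, dH)
  numx <- num_grad(function(v) {
    sum(swdnet:::bigru_fw(array(v, dim(X)), pf, pb)$h * dH)
  }, X)
  expect_lt(relerr(g$dX, array(numx, dim(X))), 1e-6)
})

test_that("dense layer gradients match finite differences", {
  set.seed(107)
  x <- array(rnorm(2 * 4 * 5), c(2, 4, 5))
  p <- swdnet:::init_dense(5, 3)
  dy <- array(rnorm(2 * 4 * 3), c(2, 4, 3))
  g <- swdnet:::tdense_bw(x, p, dy)
  lf <- function(xx, ww = p$w, bb = p$b) {
    sum(swdnet:::tdense_fw(array(xx, dim(x)),
                           list(w = array(ww, dim(p$w)), b = bb)) * dy)
  }
  expect_lt(relerr(g$dx, array(num_grad(function(v) lf(v), x), dim(x))),
            1e-6)
  expect_lt(relerr(g$dw, array(num_grad(function(v) lf(x, ww = v), p$w),
                               dim(p$w))), 1e-6)
  expect_lt(relerr(g$db, num_grad(function(v) lf(x, bb = v), p$b)), 1e-6)
})

test_that("focal loss matches hand arithmetic and its stated properties", {
  # hand-computed value: 0.25 * 0.5^2 * (-log 0.5)
  expect_equal(focal_loss(0.5, 1, alpha = 0.25, gamma = 2),
               0.25 * 0.25 * log(2), tolerance = 1e-12)
  # gamma 0, alpha 0.5 -> exactly half the binary cross-entropy
  for (p in c(0.1, 0.5, 0.9)) {
    expect_equal(focal_loss(p, 1, 0.5, 0), -0.5 * log(p))
    expect_equal(focal_loss(p, 0, 0.5, 0), -0.5 * log(1 - p))
  }
  # monotone in confidence
  expect_lt(focal_loss(0.99, 1, 0.25, 2), focal_loss(0.6, 1, 0.25, 2))
  # non-negative, and zero only as prob -> label
  set.seed(108)
  p <- runif(200); y <- rbinom(200, 1, 0.5)
  l <- vapply(seq_along(p), function(i) focal_loss(p[i], y[i]), numeric(1))
  expect_true(all(l >= 0))
  expect_lt(focal_loss(1 - 1e-7, 1), 1e-12)
  # masked frames contribute nothing
  expect_equal(focal_loss(c(0.2, 0.9), c(1, 1), mask = c(1, 0)),
               focal_loss(0.2, 1))
})

test_that("focal gradient matches finite differences through the sigmoid", {
  set.seed(109)
  z <- rnorm(15); y <- rbinom(15, 1, 0.4)
  mask <- c(rep(1, 12), 0, 0, 0)
  p <- swdnet:::sigmoid(z)
  dz <- swdnet:::focal_grad_z(p, z, y, 0.25, 2, mask, "sigmoid")
  num <- num_grad(function(v) {
    focal_loss(swdnet:::sigmoid(v), y, 0.25, 2, mask)
  }, z)
  expect_lt(relerr(dz, num), 1e-6)
  expect_true(all(dz[mask == 0] == 0))
})
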