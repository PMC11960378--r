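# Gated recurrent unit, dual-bias ("reset-after") formulation: the reset
# gate multiplies the recurrent matrix product AFTER its own bias is
# added, so every gate carries two bias vectors:
#   z_t = sigmoid(x_t W_z + b_in_z + h_{t-1} U_z + b_rec_z)
#   r_t = sigmoid(x_t W_r + b_in_r + h_{t-1} U_r + b_rec_r)
#   c_t = tanh(x_t W_c + b_in_c + r_t * (h_{t-1} U_c + b_rec_c))
#   h_t = z_t * h_{t-1} + (1 - z_t) * c_t
# Parameter count per direction: 3 * units * (input + units + 2), which is
# what distinguishes this variant from the single-bias GRU.

gru_param_count <- function(fin, units) 3L * units * (fin + units + 2L)

# forward over (B, T, F) -> hidden sequence (B, T, U) plus caches for BPTT
gru_fw <- function(X, p) {
  d <- dim(X)
  B <- d[1]; T <- d[2]
  U <- nrow(p$u)
  H <- array(0, c(B, T + 1L, U))
  Z <- array(0, c(B, T, U))
  R <- array(0, c(B, T, U))
  Cc <- array(0, c(B, T, U))
  Hr <- array(0, c(B, T, U))     # recurrent candidate term incl. bias
  iz <- 1:U; ir <- (U + 1L):(2L * U); ic <- (2L * U + 1L):(3L * U)
  for (t in seq_len(T)) {
    xt <- matrix(X[, t, ], nrow = B)
    hprev <- matrix(H[, t, ], nrow = B)
    a_in <- xt %*% p$w + rep(p$b_in, each = B)
    a_rec <- hprev %*% p$u + rep(p$b_rec, each = B)
    z <- sigmoid(a_in[, iz, drop = FALSE] + a_rec[, iz, drop = FALSE])
    r <- sigmoid(a_in[, ir, drop = FALSE] + a_rec[, ir, drop = FALSE])
    hr <- a_rec[, ic, drop = FALSE]
    cc <- tanh(a_in[, ic, drop = FALSE] + r * hr)
    H[, t + 1L, ] <- z * hprev + (1 - z) * cc
    Z[, t, ] <- z; R[, t, ] <- r; Cc[, t, ] <- cc; Hr[, t, ] <- hr
  }
  list(h = H[, -1L, , drop = FALSE],
       cache = list(X = X, H = H, Z = Z, R = R, Cc = Cc, Hr = Hr, U = U))
}

gru_bw <- function(p, cache, dH) {
  X <- cache$X
  d <- dim(X)
  B <- d[1]; T <- d[2]; F <- d[3]
  U <- cache$U
  iz <- 1:U; ir <- (U + 1L):(2L * U); ic <- (2L * U + 1L):(3L * U)
  dX <- array(0, d)
  dw <- array(0, dim(p$w)); du <- array(0, dim(p$u))
  db_in <- numeric(3L * U); db_rec <- numeric(3L * U)
  dh_next <- matrix(0, B, U)
  for (t in rev(seq_len(T))) {
    dh <- matrix(dH[, t, ], nrow = B) + dh_next
    z <- matrix(cache$Z[, t, ], nrow = B)
    r <- matrix(cache$R[, t, ], nrow = B)
    cc <- matrix(cache$Cc[, t, ], nrow = B)
    hr <- matrix(cache$Hr[, t, ], nrow = B)
    hprev <- matrix(cache$H[, t, ], nrow = B)
    dz <- dh * (hprev - cc)
    da_z <- dz * z * (1 - z)
    dcc <- dh * (1 - z)
    da_c <- dcc * (1 - cc * cc)
    dhr <- da_c * r
    dr <- da_c * hr
    da_r <- dr * r * (1 - r)
    da_in <- cbind(da_z, da_r, da_c)
    da_rec <- cbind(da_z, da_r, dhr)
    xt <- matrix(X[, t, ], nrow = B)
    dw <- dw + crossprod(xt, da_in)
    db_in <- db_in + .colSums(da_in, B, 3L * U)
    du <- du + crossprod(hprev, da_rec)
    db_rec <- db_rec + .colSums(da_rec, B, 3L * U)
    dX[, t, ] <- tcrossprod(da_in, p$w)
    dh_next <- dh * z + tcrossprod(da_rec, p$u)
  }
  list(dX = dX, dw = dw, du = du, db_in = db_in, db_rec = db_rec)
}

# bidirectional wrapper: forward pass + time-reversed pass, outputs
# concatenated along the feature axis -> (B, T, 2U)
bigru_fw <- function(X, p_fwd, p_bwd) {
  fwd <- gru_fw(X, p_fwd)
  Xr <- X[, rev(seq_len(dim(X)[2])), , drop = FALSE]
  bwd <- gru_fw(Xr, p_bwd)
  hb <- bwd$h[, rev(seq_len(dim(X)[2])), , drop = FALSE]
  U <- dim(fwd$h)[3]
  out <- array(0, c(dim(X)[1], dim(X)[2], 2L * U))
  out[, , 1:U] <- fwd$h
  out[, , (U + 1L):(2L * U)] <- hb
  list(h = out, cache = list(fwd = fwd$cache, bwd = bwd$cache, U = U))
}

bigru_bw <- function(p_fwd, p_bwd, cache, dH) {
  U <- cache$U
  T <- dim(dH)[2]
  gf <- gru_bw(p_fwd, cache$fwd, dH[, , 1:U, drop = FALSE])
  dHb <- dH[, rev(seq_len(T)), (U + 1L):(2L * U), drop = FALSE]
  gb <- gru_bw(p_bwd, cache$bwd, dHb)
  dX <- gf$dX + gb$dX[, rev(seq_len(T)), , drop = FALSE]
  list(dX = dX, fwd = gf, bwd = gb)
}
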