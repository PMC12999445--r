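# Recurrent cells for the temporal/text agent. Sequences are short token
# lists (rule-based descriptors), so cells run one sequence at a time with
# explicit backpropagation through time.
#
# X is a d_in x T matrix of embedded tokens; hidden states are length-H
# vectors. Gate weights are stacked: GRU uses 3H rows (update, reset,
# candidate), LSTM 4H rows (input, forget, output, candidate).

sigmoid <- function(x) 1 / (1 + exp(-x))

rnn_cell <- function(kind, d_in, H) {
  ngate <- if (kind == "gru") 3L else 4L
  list(
    kind = kind, H = H, d_in = d_in,
    W = he_init(ngate * H, d_in, fan_in = d_in),
    U = he_init(ngate * H, H, fan_in = H),
    b = numeric(ngate * H)
  )
}

gru_forward_seq <- function(cell, X) {
  H <- cell$H
  T_len <- ncol(X)
  h <- numeric(H)
  steps <- vector("list", T_len)
  iz <- 1:H
  ir <- (H + 1):(2 * H)
  im <- (2 * H + 1):(3 * H)
  for (t in seq_len(T_len)) {
    x <- X[, t]
    ax <- cell$W %*% x + cell$b
    ah <- cell$U %*% h
    z <- sigmoid(ax[iz] + ah[iz])
    r <- sigmoid(ax[ir] + ah[ir])
    # candidate gate uses U_n (r * h), not U_n h
    n <- as.vector(tanh(ax[im] + cell$U[im, , drop = FALSE] %*% (r * h)))
    steps[[t]] <- list(x = x, h_prev = h, z = as.vector(z),
                       r = as.vector(r), n = n)
    h <- (1 - steps[[t]]$z) * n + steps[[t]]$z * h
  }
  list(h = h, steps = steps)
}

gru_backward_seq <- function(cell, dh, cache) {
  H <- cell$H
  iz <- 1:H
  ir <- (H + 1):(2 * H)
  im <- (2 * H + 1):(3 * H)
  Uz <- cell$U[iz, , drop = FALSE]
  Ur <- cell$U[ir, , drop = FALSE]
  Un <- cell$U[im, , drop = FALSE]
  dW <- array(0, dim(cell$W))
  dU <- array(0, dim(cell$U))
  db <- numeric(length(cell$b))
  T_len <- length(cache$steps)
  dX <- matrix(0, cell$d_in, T_len)
  for (t in rev(seq_len(T_len))) {
    st <- cache$steps[[t]]
    dn <- dh * (1 - st$z)
    dz <- dh * (st$h_prev - st$n)
    dh_prev <- dh * st$z
    da_n <- dn * (1 - st$n^2)
    da_z <- dz * st$z * (1 - st$z)
    dn_h <- as.vector(crossprod(Un, da_n))
    dr <- dn_h * st$h_prev
    dh_prev <- dh_prev + dn_h * st$r
    da_r <- dr * st$r * (1 - st$r)
    dW[iz, ] <- dW[iz, ] + tcrossprod(da_z, st$x)
    dW[ir, ] <- dW[ir, ] + tcrossprod(da_r, st$x)
    dW[im, ] <- dW[im, ] + tcrossprod(da_n, st$x)
    dU[iz, ] <- dU[iz, ] + tcrossprod(da_z, st$h_prev)
    dU[ir, ] <- dU[ir, ] + tcrossprod(da_r, st$h_prev)
    dU[im, ] <- dU[im, ] + tcrossprod(da_n, st$r * st$h_prev)
    db[iz] <- db[iz] + da_z
    db[ir] <- db[ir] + da_r
    db[im] <- db[im] + da_n
    dX[, t] <- crossprod(cell$W[iz, , drop = FALSE], da_z) +
      crossprod(cell$W[ir, , drop = FALSE], da_r) +
      crossprod(cell$W[im, , drop = FALSE], da_n)
    dh <- dh_prev + as.vector(crossprod(Uz, da_z)) +
      as.vector(crossprod(Ur, da_r))
  }
  list(dW = dW, dU = dU, db = db, dX = dX)
}

lstm_forward_seq <- function(cell, X) {
  H <- cell$H
  T_len <- ncol(X)
  h <- numeric(H)
  cst <- numeric(H)
  steps <- vector("list", T_len)
  ii <- 1:H
  i_f <- (H + 1):(2 * H)
  io <- (2 * H + 1):(3 * H)
  ig <- (3 * H + 1):(4 * H)
  for (t in seq_len(T_len)) {
    x <- X[, t]
    a <- as.vector(cell$W %*% x + cell$U %*% h + cell$b)
    gi <- sigmoid(a[ii])
    gf <- sigmoid(a[i_f])
    go <- sigmoid(a[io])
    gg <- tanh(a[ig])
    c_new <- gf * cst + gi * gg
    steps[[t]] <- list(x = x, h_prev = h, c_prev = cst, i = gi, f = gf,
                       o = go, g = gg, c = c_new, tc = tanh(c_new))
    cst <- c_new
    h <- go * steps[[t]]$tc
  }
  list(h = h, steps = steps)
}

lstm_backward_seq <- function(cell, dh, cache) {
  H <- cell$H
  ii <- 1:H
  i_f <- (H + 1):(2 * H)
  io <- (2 * H + 1):(3 * H)
  ig <- (3 * H + 1):(4 * H)
  dW <- array(0, dim(cell$W))
  dU <- array(0, dim(cell$U))
  db <- numeric(length(cell$b))
  T_len <- length(cache$steps)
  dX <- matrix(0, cell$d_in, T_len)
  dc <- numeric(H)
  for (t in rev(seq_len(T_len))) {
    st <- cache$steps[[t]]
    do_ <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    da <- c(di * st$i * (1 - st$i),
            df * st$f * (1 - st$f),
            do_ * st$o * (1 - st$o),
            dg * (1 - st$g^2))
    dW <- dW + tcrossprod(da, st$x)
    dU <- dU + tcrossprod(da, st$h_prev)
    db <- db + da
    dX[, t] <- crossprod(cell$W, da)
    dh <- as.vector(crossprod(cell$U, da))
    dc <- dc * st$f
  }
  list(dW = dW, dU = dU, db = db, dX = dX)
}

rnn_forward_seq <- function(cell, X) {
  if (cell$kind == "gru") gru_forward_seq(cell, X) else lstm_forward_seq(cell, X)
}

rnn_backward_seq <- function(cell, dh, cache) {
  if (cell$kind == "gru") gru_backward_seq(cell, dh, cache) else lstm_backward_seq(cell, dh, cache)
}

# Bidirectional encoder: final forward state concatenated with the final
# state of the reversed pass; d_h = 2 * per-direction hidden size.
bi_forward <- function(cell_f, cell_b, X) {
  fwd <- rnn_forward_seq(cell_f, X)
  bwd <- rnn_forward_seq(cell_b, X[, rev(seq_len(ncol(X))), drop = FALSE])
  list(h = c(fwd$h, bwd$h), fwd = fwd, bwd = bwd)
}

bi_backward <- function(cell_f, cell_b, dh, cache) {
  H <- cell_f$H
  gf <- rnn_backward_seq(cell_f, dh[1:H], cache$fwd)
  gb <- rnn_backward_seq(cell_b, dh[(H + 1):(2 * H)], cache$bwd)
  dX <- gf$dX + gb$dX[, rev(seq_len(ncol(gb$dX))), drop = FALSE]
  list(f = gf, b = gb, dX = dX)
}
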