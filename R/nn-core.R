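# Minimal feed-forward neural-network primitives.
#
# All image tensors use dim c(H, W, C, N) (column-major, batch last); feature
# matrices use dim c(d, N) (features in rows). Convolutions are evaluated as
# im2col gather + one BLAS matmul, which is fast enough at patch scale
# (64x64 inputs, <=64 channels) without compiled code.

# -- initialisation ----------------------------------------------------------

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

# -- im2col convolution ------------------------------------------------------

# memoised geometry: gather indices are pure functions of the layer shapes
.nn_cache <- new.env(parent = emptyenv())

# Precompute the gather index for one image: a P x Q matrix of 1-based flat
# indices into an (H,W,C) array, P = #output positions, Q = k*k*C.
im2col_index <- function(H, W, C, k, stride) {
  key <- paste("ic", H, W, C, k, stride)
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- (H - k) %/% stride + 1L
  Wo <- (W - k) %/% stride + 1L
  di <- rep(0:(k - 1L), times = k * C)
  dj <- rep(rep(0:(k - 1L), each = k), times = C)
  dc <- rep(0:(C - 1L), each = k * k)
  oi <- rep(seq(0L, by = stride, length.out = Ho), times = Wo)
  oj <- rep(seq(0L, by = stride, length.out = Wo), each = Ho)
  P <- Ho * Wo
  Q <- k * k * C
  idx <- outer(oi, di, "+") + outer(oj, dj, "+") * H +
    matrix(dc, P, Q, byrow = TRUE) * (H * W) + 1L
  out <- list(idx = idx, Ho = Ho, Wo = Wo, P = P, Q = Q, H = H, W = W, C = C)
  .nn_cache[[key]] <- out
  out
}

# batched gather index: (P*N) x Q, rows ordered position-fastest per image
im2col_batch_index <- function(ic, N) {
  key <- paste("big", ic$H, ic$W, ic$C, ic$P, ic$Q, N)
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  HWC <- ic$H * ic$W * ic$C
  big <- ic$idx[rep.int(seq_len(ic$P), N), , drop = FALSE] +
    rep((0:(N - 1L)) * HWC, each = ic$P)
  .nn_cache[[key]] <- big
  big
}

# Gather an (H,W,C,N) batch into a (P*N) x Q patch matrix.
im2col_gather <- function(X, ic) {
  big <- im2col_batch_index(ic, dim(X)[4])
  matrix(X[big], nrow = nrow(big))
}

conv_layer <- function(c_in, c_out, k = 3L, stride = 1L) {
  list(
    type = "conv", k = k, stride = stride, c_in = c_in, c_out = c_out,
    W = he_init(k * k * c_in, c_out, fan_in = k * k * c_in),
    b = numeric(c_out)
  )
}

conv_forward <- function(layer, X) {
  d <- dim(X)
  ic <- im2col_index(d[1], d[2], d[3], layer$k, layer$stride)
  M <- im2col_gather(X, ic)
  out <- M %*% layer$W
  out <- out + rep(layer$b, each = nrow(out))
  N <- d[4]
  A <- aperm(array(out, c(ic$P, N, layer$c_out)), c(1, 3, 2))
  dim(A) <- c(ic$Ho, ic$Wo, layer$c_out, N)
  list(out = A, cache = list(M = M, ic = ic, N = N, dimX = d))
}

conv_backward <- function(layer, dOut, cache, need_dx = TRUE) {
  ic <- cache$ic
  N <- cache$N
  dA <- aperm(array(dOut, c(ic$P, layer$c_out, N)), c(1, 3, 2))
  dMatrix <- matrix(dA, ic$P * N, layer$c_out)
  dW <- crossprod(cache$M, dMatrix)
  db <- colSums(dMatrix)
  dX <- NULL
  if (need_dx) {
    dM <- tcrossprod(dMatrix, layer$W)
    big <- im2col_batch_index(ic, N)
    dXf <- numeric(prod(cache$dimX))
    # within one kernel-offset column all gather indices are distinct, so a
    # per-column scatter-add is exact (and cheap: Q is small)
    for (q in seq_len(ic$Q)) {
      ix <- big[, q]
      dXf[ix] <- dXf[ix] + dM[, q]
    }
    dX <- array(dXf, cache$dimX)
  }
  list(dW = dW, db = db, dX = dX)
}

# -- pooling -----------------------------------------------------------------

avgpool_forward <- function(X, k) {
  d <- dim(X)
  Ho <- d[1] %/% k
  Wo <- d[2] %/% k
  A <- array(X[seq_len(Ho * k), seq_len(Wo * k), , , drop = FALSE],
             c(k, Ho, k, Wo, d[3] * d[4]))
  s <- colSums(A)                      # (Ho, k, Wo, C*N)
  s <- colSums(aperm(s, c(2, 1, 3, 4)))  # (Ho, Wo, C*N)
  array(s / (k * k), c(Ho, Wo, d[3], d[4]))
}

gap_forward <- function(X) {
  d <- dim(X)
  matrix(colMeans(matrix(X, d[1] * d[2], d[3] * d[4])), d[3], d[4])
}

gap_backward <- function(dF, dimX) {
  hw <- dimX[1] * dimX[2]
  array(rep(as.vector(dF) / hw, each = hw), dimX)
}

# -- dense / relu ------------------------------------------------------------

dense_layer <- function(d_in, d_out) {
  list(type = "dense", W = he_init(d_out, d_in, fan_in = d_in),
       b = numeric(d_out))
}

dense_forward <- function(layer, X) {
  layer$W %*% X + layer$b
}

dense_backward <- function(layer, dOut, X) {
  list(dW = tcrossprod(dOut, X), db = rowSums(dOut),
       dX = crossprod(layer$W, dOut))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu_backward <- function(dOut, activated) {
  dOut * (activated > 0)
}

# -- Adam optimiser ----------------------------------------------------------

# params/grads are flat named lists of numeric arrays with matching shapes.
adam_new <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  list(
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
    # p * 0 keeps each parameter's exact shape (matrix or plain vector)
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0)
  )
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  b1t <- 1 - state$beta1^state$t
  b2t <- 1 - state$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * g * g
    params[[nm]] <- params[[nm]] - state$lr *
      (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + state$eps)
  }
  list(state = state, params = params)
}
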