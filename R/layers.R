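# Low-level numeric kernels for 1D convolutional networks.
#
# Activations are stored channels-first as C x (L * N) matrices: one row per
# channel, column index (n - 1) * L + l (time fastest within a sample).  Per-
# channel operations (batch norm, scale/shift) then use native column-major
# vector recycling with no broadcast allocation, and every convolution is a
# column gather (im2col) followed by one BLAS GEMM.  Everything here is
# deterministic and single-threaded apart from the BLAS.

conv_out_len <- function(L, k, stride, pad) {
  (L + 2L * pad - k) %/% stride + 1L
}

# Column indices gathering the input positions that feed each output position
# for one kernel offset j (1-based).  Out-of-range (padding) positions map to
# the extra all-zero column L * N + 1 of the padded activation matrix.
.conv_gather_index <- function(L, N, k, stride, pad) {
  Lo <- conv_out_len(L, k, stride, pad)
  base <- rep.int((seq_len(N) - 1L) * L, rep.int(Lo, N))
  zero_col <- L * N + 1L
  idx <- vector("list", k)
  pos0 <- (seq_len(Lo) - 1L) * stride - pad
  for (j in seq_len(k)) {
    pos <- pos0 + j
    full <- rep.int(pos, N) + base
    full[rep.int(pos < 1L | pos > L, N)] <- zero_col
    idx[[j]] <- full
  }
  idx
}

# im2col: (C_in * k) x (Lo * N) matrix, row index c + (j - 1) * C_in -- the
# weight layout below matches.
.im2col <- function(A, L, N, k, stride, pad, idx = NULL) {
  if (is.null(idx)) idx <- .conv_gather_index(L, N, k, stride, pad)
  Apad <- cbind(A, 0)
  big <- Apad[, unlist(idx, use.names = FALSE), drop = FALSE]
  LoN <- length(idx[[1L]])
  C <- nrow(A)
  dim(big) <- c(C, LoN, k)
  big <- aperm(big, c(1L, 3L, 2L))
  dim(big) <- c(C * k, LoN)
  big
}

# Weight tensors are C_out x (C_in * k) matrices, column index
# c_in + (j - 1) * C_in.
conv1d_forward <- function(A, W, L, N, k, stride, pad, idx = NULL) {
  if (k == 1L && stride == 1L && pad == 0L) return(W %*% A)
  Xcol <- .im2col(A, L, N, k, stride, pad, idx)
  W %*% Xcol
}

conv1d_backward <- function(dY, A, W, L, N, k, stride, pad, idx = NULL) {
  if (k == 1L && stride == 1L && pad == 0L) {
    return(list(dW = tcrossprod(dY, A), dA = crossprod(W, dY)))
  }
  if (is.null(idx)) idx <- .conv_gather_index(L, N, k, stride, pad)
  Xcol <- .im2col(A, L, N, k, stride, pad, idx)
  dW <- tcrossprod(dY, Xcol)
  dXcol <- crossprod(W, dY)
  C_in <- nrow(A)
  dApad <- matrix(0, C_in, L * N + 1L)
  for (j in seq_len(k)) {
    jrows <- (j - 1L) * C_in + seq_len(C_in)
    dApad[, idx[[j]]] <- dApad[, idx[[j]], drop = FALSE] +
      dXcol[jrows, , drop = FALSE]
  }
  list(dW = dW, dA = dApad[, -(L * N + 1L), drop = FALSE])
}

new_bn <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C),
       rmean = rep(0, C), rvar = rep(1, C))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1   # update rate for running statistics

bn_forward <- function(A, bn, training) {
  C <- nrow(A)
  m <- ncol(A)
  if (training) {
    mu <- .rowMeans(A, C, m)
    va <- .rowMeans(A * A, C, m) - mu * mu
    va[va < 0] <- 0
    invstd <- 1 / sqrt(va + BN_EPS)
    xhat <- (A - mu) * invstd
    y <- xhat * bn$gamma + bn$beta
    bn$rmean <- (1 - BN_MOMENTUM) * bn$rmean + BN_MOMENTUM * mu
    bn$rvar <- (1 - BN_MOMENTUM) * bn$rvar + BN_MOMENTUM * va * m / max(m - 1, 1)
    list(y = y, xhat = xhat, invstd = invstd, bn = bn)
  } else {
    a <- bn$gamma / sqrt(bn$rvar + BN_EPS)
    list(y = A * a + (bn$beta - a * bn$rmean))
  }
}

bn_backward <- function(dY, cache, bn) {
  C <- nrow(dY)
  m <- ncol(dY)
  xhat <- cache$xhat
  dgamma <- .rowSums(dY * xhat, C, m)
  dbeta <- .rowSums(dY, C, m)
  g <- bn$gamma
  dx <- cache$invstd * (dY * g - dbeta * g / m - xhat * (dgamma * g / m))
  list(dA = dx, dgamma = dgamma, dbeta = dbeta)
}

relu <- function(A) A * (A > 0)
relu_backward <- function(dY, act) dY * (act > 0)

# global average pooling over the temporal axis: C x (L*N) -> C x N
gap_forward <- function(A, L, N) {
  C <- nrow(A)
  B <- A
  dim(B) <- c(C * L, N)
  rowsum(B, group = rep.int(seq_len(C), L), reorder = FALSE) / L
}
gap_backward <- function(dP, L, N) {
  dP[, rep(seq_len(N), each = L), drop = FALSE] / L
}

# logits come N x K (one row per sample) at the interface; gradients flow
# back channels-first (K x N)
softmax_rows <- function(Z) {
  mx <- Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
  E <- exp(Z - mx)
  E / rowSums(E)
}

# mean cross-entropy and its gradient wrt logits; y is 1-based class index;
# Z is N x K, dZ is returned K x N for the backward pass
cross_entropy <- function(Z, y) {
  P <- softmax_rows(Z)
  n <- nrow(Z)
  loss <- -mean(log(P[cbind(seq_len(n), y)] + 1e-12))
  dZ <- P
  dZ[cbind(seq_len(n), y)] <- dZ[cbind(seq_len(n), y)] - 1
  list(loss = loss, dZ = t(dZ) / n)
}

# He fan-in initialisation for a conv weight in the C_out x (C_in*k) layout
he_init <- function(k, C_in, C_out) {
  matrix(stats::rnorm(k * C_in * C_out, sd = sqrt(2 / (k * C_in))),
         nrow = C_out, ncol = k * C_in)
}

# run a block with the RNG state set from `seed` and restored afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
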