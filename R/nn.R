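# A small convolutional network over the L x 5 read encoding, written in
# vectorized base R: 1-D convolution (F filters, width k) -> ReLU ->
# max-pool (2) -> position-preserving flatten -> dense (ReLU) -> sigmoid.
# Sequence-local features come from the convolution; the flatten keeps
# window order so the dense layer aggregates position-aware evidence; the
# sigmoid yields the per-read tumor probability. Training is plain
# minibatch Adam on binary cross-entropy, fully deterministic under the
# spec seed (single R process, base RNG).

#' Classifier hyperparameters
#'
#' @param L Encoding window length in bp (default 66).
#' @param filters Number of convolution filters.
#' @param kernel Convolution width in bp.
#' @param pool Max-pool width (stride equals width).
#' @param dense_units Hidden dense layer width.
#' @param dropout Dropout probability on the dense layer (0 disables).
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param val_fraction Held-out read fraction for the training log.
#' @param seed Seed fixing initialization, the split, and data order.
#' @return A `model_spec` list.
#' @export
model_spec <- function(L = 66L, filters = 32L, kernel = 8L, pool = 2L,
                       dense_units = 16L, dropout = 0, lr = 1e-3,
                       batch_size = 128L, epochs = 15L,
                       val_fraction = 0.2, seed = 1L) {
  spec <- list(L = as.integer(L), filters = as.integer(filters),
               kernel = as.integer(kernel), pool = as.integer(pool),
               dense_units = as.integer(dense_units), dropout = dropout,
               lr = lr, batch_size = as.integer(batch_size),
               epochs = as.integer(epochs), val_fraction = val_fraction,
               seed = as.integer(seed))
  for (k in c("L", "filters", "kernel", "pool", "dense_units",
              "batch_size", "epochs"))
    if (!is_count(spec[[k]]) || spec[[k]] < 1L)
      param_error("%s must be a positive integer", k)
  if (spec$kernel > spec$L) param_error("kernel wider than window L")
  if (!is_prob(spec$dropout) || spec$dropout >= 1)
    param_error("dropout must be in [0,1)")
  if (spec$lr <= 0) param_error("lr must be positive")
  spec
}

nn_dims <- function(spec) {
  P <- spec$L - spec$kernel + 1L
  Pp <- P %/% spec$pool
  list(P = P, Pp = Pp, ks = spec$kernel * 5L, flat = Pp * spec$filters)
}

nn_init <- function(spec) {
  d <- nn_dims(spec)
  set.seed(spec$seed)
  he <- function(nin, nout) matrix(rnorm(nin * nout, 0, sqrt(2 / nin)),
                                   nin, nout)
  list(
    Wc = he(d$ks, spec$filters), bc = rep(0, spec$filters),
    W1 = he(d$flat, spec$dense_units), b1 = rep(0, spec$dense_units),
    W2 = he(spec$dense_units, 1L), b2 = 0
  )
}

# im2col: each convolution window is contiguous in the position-major
# encoding, so a single column gather builds the (B*P) x (k*5) matrix.
nn_im2col <- function(X, spec) {
  d <- nn_dims(spec)
  B <- nrow(X)
  idx <- unlist(lapply(seq_len(d$P) - 1L,
                       function(p) p * 5L + seq_len(d$ks)))
  Xc <- X[, idx, drop = FALSE]                    # B x (P*ks), window-major
  arr <- array(Xc, c(B, d$ks, d$P))               # wait: j fastest? see below
  # idx orders columns window-major with the ks entries of a window
  # consecutive, so linear column index c = (p-1)*ks + j -> array dims
  # must be (B, ks, P)
  matrix(aperm(arr, c(1, 3, 2)), B * d$P, d$ks)   # rows: b fastest, then p
}

nn_forward <- function(params, X, spec, train = FALSE, drop_mask = NULL) {
  d <- nn_dims(spec)
  B <- nrow(X)
  Xc <- nn_im2col(X, spec)
  Zlin <- sweep(Xc %*% params$Wc, 2L, params$bc, "+")
  Z <- pmax(Zlin, 0)
  Zarr <- array(Z, c(B, d$P, spec$filters))
  odd <- seq(1L, by = spec$pool, length.out = d$Pp)
  A1 <- Zarr[, odd, , drop = FALSE]
  mask <- NULL
  if (spec$pool > 1L) {
    mask <- array(1L, c(B, d$Pp, spec$filters))
    for (s in 2:spec$pool) {
      cand <- Zarr[, odd + (s - 1L), , drop = FALSE]
      better <- cand > A1
      A1[better] <- cand[better]
      mask[better] <- s
    }
  }
  Fl <- matrix(A1, B, d$flat)
  H1lin <- sweep(Fl %*% params$W1, 2L, params$b1, "+")
  H1 <- pmax(H1lin, 0)
  if (train && spec$dropout > 0) {
    if (is.null(drop_mask))
      drop_mask <- matrix(runif(length(H1)) >= spec$dropout, nrow(H1))
    H1 <- H1 * drop_mask / (1 - spec$dropout)
  }
  s <- drop(H1 %*% params$W2) + params$b2
  phat <- 1 / (1 + exp(-s))
  list(phat = phat, cache = list(Xc = Xc, Z = Z, mask = mask, odd = odd,
                                 Fl = Fl, H1 = H1, drop_mask = drop_mask,
                                 B = B, d = d))
}

nn_backward <- function(params, cache, phat, y, spec) {
  d <- cache$d
  B <- cache$B
  dout <- matrix((phat - y) / B, B, 1L)
  dW2 <- crossprod(cache$H1, dout)
  db2 <- sum(dout)
  dH1 <- dout %*% t(params$W2)
  if (spec$dropout > 0 && !is.null(cache$drop_mask))
    dH1 <- dH1 * cache$drop_mask / (1 - spec$dropout)
  dH1 <- dH1 * (cache$H1 > 0)
  dW1 <- crossprod(cache$Fl, dH1)
  db1 <- colSums(dH1)
  dFl <- dH1 %*% t(params$W1)
  dA1 <- array(dFl, c(B, d$Pp, spec$filters))
  dZarr <- array(0, c(B, d$P, spec$filters))
  if (spec$pool > 1L) {
    for (s in seq_len(spec$pool)) {
      sel <- cache$mask == s
      tmp <- array(0, dim(dA1))
      tmp[sel] <- dA1[sel]
      dZarr[, cache$odd + (s - 1L), ] <- tmp
    }
  } else {
    dZarr[, cache$odd, ] <- dA1
  }
  dZ <- matrix(dZarr, B * d$P, spec$filters) * (cache$Z > 0)
  dWc <- crossprod(cache$Xc, dZ)
  dbc <- colSums(dZ)
  list(Wc = dWc, bc = dbc, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

nn_adam_step <- function(params, grads, state, lr, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

bce_loss <- function(phat, y) {
  eps <- 1e-12
  -mean(y * log(phat + eps) + (1 - y) * log(1 - phat + eps))
}

nn_predict <- function(params, X, spec, chunk = 2048L) {
  n <- nrow(X)
  out <- numeric(n)
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    out[i0:i1] <- nn_forward(params, X[i0:i1, , drop = FALSE], spec)$phat
  }
  out
}
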