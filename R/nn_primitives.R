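# Neural-network primitives: forward passes with caches and hand-derived
# backward passes, operating on plain R arrays so everything runs through
# BLAS matrix products.
#
# Tensor layout conventions:
#   feature maps  [channels, height, width, batch]   (channel fastest)
#   dense inputs  [features, batch]
#   token blocks  [tokens L, embed E]  per sample
# The channel-fastest layout lets a k x k convolution be computed as k^2
# matrix products of the tap weight [C_out, C_in] with channel-major slices.

## ---- initialisation -------------------------------------------------------

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

glorot_init <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

conv_params <- function(c_in, c_out, k = 3L) {
  list(W = he_init(c(c_out, c_in, k, k), fan_in = c_in * k * k),
       b = rep(0, c_out))
}

linear_params <- function(n_in, n_out) {
  list(W = glorot_init(c(n_out, n_in), n_in, n_out), b = rep(0, n_out))
}

## ---- convolution ----------------------------------------------------------

# "same"-padded cross-correlation with dilation; pad = dilation * (k-1)/2.
conv2d_fw <- function(x, W, b, dilation = 1L) {
  d <- dim(x); Cin <- d[1]; H <- d[2]; Wd <- d[3]; N <- d[4]
  Cout <- dim(W)[1]; k <- dim(W)[3]
  span <- dilation * (k - 1L) + 1L
  if (H < span || Wd < span)
    stop("input ", H, "x", Wd, " smaller than effective kernel span ", span)
  out <- array(b, c(Cout, H, Wd, N))   # channel-fastest recycling = bias
  mid <- (k + 1L) / 2L
  for (ki in seq_len(k)) for (kj in seq_len(k)) {
    oi <- (ki - mid) * dilation; oj <- (kj - mid) * dilation
    hs <- max(1L, 1L + oi):min(H, H + oi)
    ws <- max(1L, 1L + oj):min(Wd, Wd + oj)
    hd <- hs - oi; wd <- ws - oj
    Wt <- matrix(W[, , ki, kj], Cout, Cin)
    m <- Wt %*% matrix(x[, hs, ws, , drop = FALSE], nrow = Cin)
    out[, hd, wd, ] <- out[, hd, wd, , drop = FALSE] +
      array(m, c(Cout, length(hd), length(wd), N))
  }
  list(out = out, cache = list(x = x, dilation = dilation))
}

conv2d_bw <- function(cache, W, dout) {
  x <- cache$x; dilation <- cache$dilation
  d <- dim(x); Cin <- d[1]; H <- d[2]; Wd <- d[3]
  Cout <- dim(W)[1]; k <- dim(W)[3]
  dx <- array(0, dim(x))
  dW <- array(0, dim(W))
  mid <- (k + 1L) / 2L
  for (ki in seq_len(k)) for (kj in seq_len(k)) {
    oi <- (ki - mid) * dilation; oj <- (kj - mid) * dilation
    hs <- max(1L, 1L + oi):min(H, H + oi)
    ws <- max(1L, 1L + oj):min(Wd, Wd + oj)
    hd <- hs - oi; wd <- ws - oj
    Wt <- matrix(W[, , ki, kj], Cout, Cin)
    g <- matrix(dout[, hd, wd, , drop = FALSE], nrow = Cout)
    xs <- matrix(x[, hs, ws, , drop = FALSE], nrow = Cin)
    dW[, , ki, kj] <- g %*% t(xs)
    dx[, hs, ws, ] <- dx[, hs, ws, , drop = FALSE] +
      array(t(Wt) %*% g, c(Cin, length(hs), length(ws), dim(x)[4]))
  }
  list(dx = dx, dW = dW, db = rowSums(matrix(dout, nrow = Cout)))
}

## ---- activations ----------------------------------------------------------

relu_fw <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bw <- function(cache, dout) dout * cache

gelu_fw <- function(x) list(out = x * stats::pnorm(x), cache = x)
gelu_bw <- function(cache, dout)
  dout * (stats::pnorm(cache) + cache * stats::dnorm(cache))

sigmoid_fw <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(out = s, cache = s)
}
sigmoid_bw <- function(cache, dout) dout * cache * (1 - cache)

## ---- pooling --------------------------------------------------------------

# 2x2 max pooling, stride 2 (H, W must be even).
maxpool2_fw <- function(x) {
  d <- dim(x); H <- d[2]; Wd <- d[3]
  stopifnot(H %% 2L == 0L, Wd %% 2L == 0L)
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  j1 <- seq(1L, Wd, 2L); j2 <- seq(2L, Wd, 2L)
  a <- x[, i1, j1, , drop = FALSE]; b <- x[, i2, j1, , drop = FALSE]
  cc <- x[, i1, j2, , drop = FALSE]; dd <- x[, i2, j2, , drop = FALSE]
  ab <- a >= b; cd <- cc >= dd
  m1 <- pmax(a, b); m2 <- pmax(cc, dd)
  s1 <- m1 >= m2
  list(out = pmax(m1, m2),
       cache = list(dim = d, ma = ab & s1, mb = (!ab) & s1,
                    mc = cd & !s1, md = (!cd) & !s1))
}

maxpool2_bw <- function(cache, dout) {
  d <- cache$dim
  dx <- array(0, d)
  i1 <- seq(1L, d[2], 2L); i2 <- seq(2L, d[2], 2L)
  j1 <- seq(1L, d[3], 2L); j2 <- seq(2L, d[3], 2L)
  dx[, i1, j1, ] <- dout * cache$ma
  dx[, i2, j1, ] <- dout * cache$mb
  dx[, i1, j2, ] <- dout * cache$mc
  dx[, i2, j2, ] <- dout * cache$md
  dx
}

## ---- batch normalisation --------------------------------------------------

bn_params <- function(c) list(gamma = rep(1, c), beta = rep(0, c))
bn_state  <- function(c) list(mean = rep(0, c), var = rep(1, c), n = 0)

# Per-channel batch norm over (H, W, N).  In training mode uses batch
# statistics and reports them so the driver can maintain running averages;
# in eval mode uses the supplied running state.
batchnorm_fw <- function(x, gamma, beta, state, training, eps = 1e-5) {
  C <- dim(x)[1]
  M <- matrix(x, nrow = C)
  if (training) {
    mu <- rowMeans(M)
    v <- rowMeans(M * M) - mu * mu
  } else {
    mu <- state$mean; v <- state$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (M - mu) * inv
  out <- array(gamma * xhat + beta, dim(x))
  list(out = out,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, dim = dim(x),
                    training = training),
       stats = list(mean = mu, var = v))
}

batchnorm_bw <- function(cache, dout) {
  C <- cache$dim[1]
  dM <- matrix(dout, nrow = C)
  xhat <- cache$xhat
  dgamma <- rowSums(dM * xhat)
  dbeta <- rowSums(dM)
  if (cache$training) {
    dxh <- dM * cache$gamma
    dx <- cache$inv * (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat))
  } else {
    dx <- dM * cache$gamma * cache$inv
  }
  list(dx = array(dx, cache$dim), dgamma = dgamma, dbeta = dbeta)
}

## ---- dense / dropout / softmax -------------------------------------------

linear_fw <- function(x, W, b) {
  list(out = W %*% x + b, cache = x)
}
linear_bw <- function(cache, W, dout) {
  list(dx = crossprod(W, dout), dW = tcrossprod(dout, cache),
       db = rowSums(dout))
}

dropout_fw <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, cache = NULL))
  mask <- array((stats::runif(length(x)) >= p) / (1 - p), dim(x) %||% length(x))
  list(out = x * mask, cache = mask)
}
dropout_bw <- function(cache, dout) if (is.null(cache)) dout else dout * cache

`%||%` <- function(a, b) if (is.null(a)) b else a

row_softmax <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

# Cross-entropy over logits [D, N] with labels in 1..D.
# Returns mean loss and dlogits.
softmax_ce <- function(logits, labels) {
  D <- nrow(logits); N <- ncol(logits)
  Z <- logits - rep(apply(logits, 2, max), each = D)
  E <- exp(Z)
  P <- E / rep(colSums(E), each = D)
  idx <- cbind(labels, seq_len(N))
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  G <- P
  G[idx] <- G[idx] - 1
  list(loss = loss, probs = P, dlogits = G / N)
}

col_softmax_probs <- function(logits) {
  D <- nrow(logits)
  Z <- logits - rep(apply(logits, 2, max), each = D)
  E <- exp(Z)
  E / rep(colSums(E), each = D)
}

## ---- multi-head self-attention -------------------------------------------

#' Fresh multi-head self-attention projection parameters
#'
#' Glorot-initialised square projection matrices `Wq`, `Wk`, `Wv`, `Wo`;
#' heads correspond to column blocks of the embedding dimension.
#'
#' @param E embedding width.
#' @return Named list of four `E x E` matrices.
#' @seealso [multi_head_self_attention()]
#' @export
mhsa_params <- function(E) {
  list(Wq = glorot_init(c(E, E), E, E), Wk = glorot_init(c(E, E), E, E),
       Wv = glorot_init(c(E, E), E, E), Wo = glorot_init(c(E, E), E, E))
}

# One sample: X [L, E].  Scaled dot-product attention per head over the L
# tokens, heads = column blocks of E, concatenated and projected by Wo.
mhsa_fw <- function(X, p, heads) {
  L <- nrow(X); E <- ncol(X)
  stopifnot(E %% heads == 0L)
  dk <- E %/% heads
  Q <- X %*% p$Wq; K <- X %*% p$Wk; V <- X %*% p$Wv
  O <- matrix(0, L, E)
  A <- vector("list", heads)
  for (h in seq_len(heads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dk)
    A[[h]] <- row_softmax(S)
    O[, idx] <- A[[h]] %*% V[, idx, drop = FALSE]
  }
  list(out = O %*% p$Wo,
       cache = list(X = X, Q = Q, K = K, V = V, A = A, O = O, heads = heads))
}

mhsa_bw <- function(cache, p, dout) {
  X <- cache$X; heads <- cache$heads
  E <- ncol(X); dk <- E %/% heads
  dWo <- crossprod(cache$O, dout)
  dO <- tcrossprod(dout, p$Wo)
  dQ <- matrix(0, nrow(X), E); dK <- dQ; dV <- dQ
  for (h in seq_len(heads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    A <- cache$A[[h]]
    dOh <- dO[, idx, drop = FALSE]
    Vh <- cache$V[, idx, drop = FALSE]
    dA <- tcrossprod(dOh, Vh)
    dV[, idx] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(dA * A))
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(dk)
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) / sqrt(dk)
  }
  list(dx = tcrossprod(dQ, p$Wq) + tcrossprod(dK, p$Wk) + tcrossprod(dV, p$Wv),
       dWq = crossprod(X, dQ), dWk = crossprod(X, dK),
       dWv = crossprod(X, dV), dWo = dWo)
}

# Attention matrices (row-stochastic, one per head) for one sample.
mhsa_attention <- function(X, p, heads) {
  E <- ncol(X); dk <- E %/% heads
  Q <- X %*% p$Wq; K <- X %*% p$Wk
  lapply(seq_len(heads), function(h) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    row_softmax(tcrossprod(Q[, idx, drop = FALSE],
                           K[, idx, drop = FALSE]) / sqrt(dk))
  })
}

## ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  zeros <- rapply(params, function(p) array(0, dim(p) %||% length(p)),
                  how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

# params/grads are (possibly nested) named lists of numeric arrays.
adam_step <- function(params, grads, opt, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t; c2 <- 1 - beta2^opt$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      sel <- function(l) if (is.null(names(p))) l else l[names(p)]
      out <- mapply(walk, p, sel(g), sel(m), sel(v), SIMPLIFY = FALSE)
      return(list(p = lapply(out, `[[`, "p"),
                  m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    upd <- p - lr * (m / c1) / (sqrt(v / c2) + eps)
    if (is.null(dim(p))) upd <- as.vector(upd)   # keep vectors vectors
    list(p = upd, m = m, v = v)
  }
  res <- walk(params, grads, opt$m, opt$v)
  list(params = res$p, opt = list(m = res$m, v = res$v, t = opt$t))
}

# Recursive elementwise sum of two grad lists (for parallel branches).
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) {
    bb <- if (is.null(names(a))) b else b[names(a)]
    return(mapply(grads_add, a, bb, SIMPLIFY = FALSE))
  }
  a + b
}

# Total number of trainable scalars in a (nested) parameter list.
#' Count trainable parameters
#'
#' @param model a fitted or built model object with a `params` element, or a
#'   (nested) list of numeric arrays.
#' @return Integer: total number of trainable scalars.
#' @examples
#' parameter_count(list(W = array(0, c(8, 1, 3, 3)), b = rep(0, 8)))  # 80
#' @export
parameter_count <- function(model) {
  p <- if (!is.null(model$params)) model$params else model
  sum(unlist(rapply(p, length, how = "unlist")))
}
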