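#' Configuration of the EEG classifier
#'
#' The EEG branch consumes (6, 4, 8, 9) differential-entropy tensors
#' (6 time steps, 4 bands, 8 x 9 topographic grid): a band-preserving 3x3
#' convolutional stem, a spectral attention module (the 4 band tokens, each
#' a 72-dim flattened spatial map, through a single-layer 4-head
#' self-attention encoder), a spatial attention module (the 72 grid-cell
#' tokens, their 4-dim band profiles embedded to 72 dims), a temporal
#' weighting over the 6 steps (linear projection + ReLU, normalised to sum
#' one), then a flatten to 1728 with dropout 0.5 and a linear classifier.
#'
#' @param heads attention heads (default 4).
#' @param embed_dim token embedding width (default 72 = 8 x 9); must be
#'   divisible by `heads`.
#' @param head_dropout dropout rate on the flattened 1728-dim representation.
#' @param n_classes output classes (default 2).
#' @param steps,bands,grid_rows,grid_cols input tensor shape.
#' @return A list of class `eeg_config`.
#' @export
eeg_config <- function(heads = 4L, embed_dim = 72L, head_dropout = 0.5,
                       n_classes = 2L, steps = 6L, bands = 4L,
                       grid_rows = 8L, grid_cols = 9L) {
  if (embed_dim %% heads != 0L) stop("embed_dim must be divisible by heads")
  if (embed_dim != grid_rows * grid_cols)
    stop("embed_dim must equal grid_rows * grid_cols")
  structure(list(heads = as.integer(heads), embed_dim = as.integer(embed_dim),
                 head_dropout = head_dropout, n_classes = as.integer(n_classes),
                 steps = as.integer(steps), bands = as.integer(bands),
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols)),
            class = "eeg_config")
}

build_eeg_params <- function(cfg) {
  E <- cfg$embed_dim; nb <- cfg$bands
  flat <- cfg$steps * nb * E
  list(stem = conv_params(nb, nb, 3L),
       spec_att = mhsa_params(E),
       spat_emb = list(W = glorot_init(c(nb, E), nb, E), b = rep(0, E)),
       spat_att = mhsa_params(E),
       spat_back = list(W = glorot_init(c(E, nb), E, nb), b = rep(0, nb)),
       temp = list(v = glorot_init(c(nb * E), nb * E, 1), b = 0),
       fc = linear_params(flat, cfg$n_classes))
}

#' Build an (untrained) EEG classifier
#' @param cfg an [eeg_config()].
#' @return Object of class `eeg_model`.
#' @export
eeg_model <- function(cfg = eeg_config()) {
  structure(list(cfg = cfg, params = build_eeg_params(cfg), state = list(),
                 trained = FALSE, history = numeric(0)),
            class = "eeg_model")
}

# ---- forward/backward -----------------------------------------------------
# Internal tensor flow (batch N):
#   x [steps, bands, R, C, N] -> stem conv on [bands, R, C, steps*N]
#   spectral: per (step, sample) token matrix [bands, E]; MHSA + residual
#   spatial:  per (step, sample) token matrix [E, bands] -> embed E -> MHSA
#             -> project back -> residual
#   temporal: per sample scalar weight per step, ReLU, normalised to sum 1
#   flatten steps*bands*E = 1728 -> dropout -> linear -> softmax

eeg_forward <- function(model, x, training = FALSE) {
  cfg <- model$cfg; p <- model$params
  ds <- dim(x)
  if (length(ds) == 4L) { dim(x) <- c(ds, 1L); ds <- dim(x) }
  if (!all(ds[1:4] == c(cfg$steps, cfg$bands, cfg$grid_rows, cfg$grid_cols)))
    stop("EEG sample shape (", paste(ds[1:4], collapse = ","),
         ") does not match configuration (", cfg$steps, ",", cfg$bands, ",",
         cfg$grid_rows, ",", cfg$grid_cols, ")")
  N <- ds[5]; B <- cfg$steps * N
  nb <- cfg$bands; E <- cfg$embed_dim

  xa <- aperm(x, c(2, 3, 4, 1, 5))            # [bands, R, C, steps, N]
  dim(xa) <- c(nb, cfg$grid_rows, cfg$grid_cols, B)
  stem <- conv2d_fw(xa, p$stem$W, p$stem$b)

  spec_out <- array(0, dim(stem$out))
  spec_caches <- vector("list", B)
  for (b in seq_len(B)) {
    X <- matrix(stem$out[, , , b], nb, E)      # tokens = bands
    mh <- mhsa_fw(X, p$spec_att, cfg$heads)
    spec_caches[[b]] <- mh$cache
    spec_out[, , , b] <- array(X + mh$out, c(nb, cfg$grid_rows, cfg$grid_cols))
  }

  spat_out <- array(0, dim(stem$out))
  spat_caches <- vector("list", B)
  for (b in seq_len(B)) {
    Xp <- t(matrix(spec_out[, , , b], nb, E))  # tokens = grid cells [E, nb]
    Xe <- Xp %*% p$spat_emb$W +
      matrix(p$spat_emb$b, E, E, byrow = TRUE)
    mh <- mhsa_fw(Xe, p$spat_att, cfg$heads)
    Xb <- mh$out %*% p$spat_back$W +
      matrix(p$spat_back$b, E, nb, byrow = TRUE)
    out_p <- Xp + Xb
    spat_caches[[b]] <- list(Xp = Xp, Xe = Xe, mh = mh$cache, A = mh$out)
    spat_out[, , , b] <- array(t(out_p), c(nb, cfg$grid_rows, cfg$grid_cols))
  }

  # temporal weighting
  S <- matrix(spat_out, nb * E)               # [288, steps*N], step fastest? no:
  # spat_out is [nb, R, C, B] with B = steps*N ordered step-fastest from aperm
  a <- as.vector(p$temp$v %*% S) + p$temp$b   # length B
  r <- pmax(a, 0)
  rm_ <- matrix(r, cfg$steps, N)
  R <- colSums(rm_)
  wm <- rm_
  pos <- R > 0
  wm[, pos] <- sweep(rm_[, pos, drop = FALSE], 2, R[pos], "/")
  wm[, !pos] <- 0
  wv <- as.vector(wm)
  Y <- S * rep(wv, each = nb * E)
  flat <- Y
  dim(flat) <- c(nb * E * cfg$steps, N)       # 1728 x N

  dr <- dropout_fw(flat, cfg$head_dropout, training)
  fc <- linear_fw(dr$out, p$fc$W, p$fc$b)
  probs <- col_softmax_probs(fc$out)
  list(probs = probs, logits = fc$out, features = flat,
       caches = list(stem = stem, spec = spec_caches, spat = spat_caches,
                     S = S, a = a, r = r, wv = wv, R = R, N = N, B = B,
                     dr = dr, fc = fc),
       bn_stats = list())
}

eeg_fwbw <- function(model, x, y1, training = TRUE) {
  fw <- eeg_forward(model, x, training)
  ce <- softmax_ce(fw$logits, y1)
  cfg <- model$cfg; p <- model$params; ca <- fw$caches
  nb <- cfg$bands; E <- cfg$embed_dim; N <- ca$N; B <- ca$B

  fcb <- linear_bw(ca$fc$cache, p$fc$W, ce$dlogits)
  dflat <- dropout_bw(ca$dr$cache, fcb$dx)
  dY <- matrix(dflat, nb * E, B)

  # temporal backward
  S <- ca$S; wv <- ca$wv
  dwv <- colSums(dY * S)
  dS <- dY * rep(wv, each = nb * E)
  dwm <- matrix(dwv, cfg$steps, N)
  rm_ <- matrix(ca$r, cfg$steps, N)
  wm <- matrix(wv, cfg$steps, N)
  da <- matrix(0, cfg$steps, N)
  pos <- ca$R > 0
  if (any(pos)) {
    dr_ <- sweep(dwm[, pos, drop = FALSE] -
                   matrix(colSums(dwm[, pos, drop = FALSE] *
                                    wm[, pos, drop = FALSE]),
                          cfg$steps, sum(pos), byrow = TRUE),
                 2, ca$R[pos], "/")
    da[, pos] <- dr_ * (matrix(ca$a, cfg$steps, N)[, pos, drop = FALSE] > 0)
  }
  dav <- as.vector(da)
  dv <- as.vector(S %*% dav)
  db_t <- sum(dav)
  dS <- dS + outer(as.vector(p$temp$v), dav)

  # spatial attention backward
  dspec <- array(0, c(nb, cfg$grid_rows, cfg$grid_cols, B))
  g_emb_W <- array(0, dim(p$spat_emb$W)); g_emb_b <- rep(0, E)
  g_back_W <- array(0, dim(p$spat_back$W)); g_back_b <- rep(0, nb)
  g_spat <- NULL
  for (b in seq_len(B)) {
    cb <- ca$spat[[b]]
    dout_p <- t(matrix(dS[, b], nb, E))        # [E, nb]
    dXb <- dout_p
    g_back_W <- g_back_W + crossprod(cb$A, dXb)
    g_back_b <- g_back_b + colSums(dXb)
    dA <- tcrossprod(dXb, p$spat_back$W)
    mb <- mhsa_bw(cb$mh, p$spat_att, dA)
    g_spat <- grads_add(g_spat, mb[c("dWq", "dWk", "dWv", "dWo")])
    dXe <- mb$dx
    g_emb_W <- g_emb_W + crossprod(cb$Xp, dXe)
    g_emb_b <- g_emb_b + colSums(dXe)
    dXp <- dout_p + tcrossprod(dXe, p$spat_emb$W)
    dspec[, , , b] <- array(t(dXp), c(nb, cfg$grid_rows, cfg$grid_cols))
  }

  # spectral attention backward
  dstem <- array(0, c(nb, cfg$grid_rows, cfg$grid_cols, B))
  g_spec <- NULL
  for (b in seq_len(B)) {
    dout <- matrix(dspec[, , , b], nb, E)
    mb <- mhsa_bw(ca$spec[[b]], p$spec_att, dout)
    g_spec <- grads_add(g_spec, mb[c("dWq", "dWk", "dWv", "dWo")])
    dstem[, , , b] <- array(dout + mb$dx,
                            c(nb, cfg$grid_rows, cfg$grid_cols))
  }

  stb <- conv2d_bw(ca$stem$cache, p$stem$W, dstem)

  names(g_spec) <- names(g_spat) <- c("Wq", "Wk", "Wv", "Wo")
  grads <- list(stem = list(W = stb$dW, b = stb$db),
                spec_att = g_spec,
                spat_emb = list(W = g_emb_W, b = g_emb_b),
                spat_att = g_spat,
                spat_back = list(W = g_back_W, b = g_back_b),
                temp = list(v = dv, b = db_t),
                fc = list(W = fcb$dW, b = fcb$db))
  list(loss = ce$loss, probs = ce$probs, grads = grads[names(p)],
       bn_stats = list())
}

#' Fit the EEG classifier
#'
#' @param x array `(6, 4, 8, 9, n)` of DE samples (see [extract_samples()]
#'   and [stack_samples()]).
#' @param y integer labels in `0 .. n_classes-1`.
#' @param cfg an [eeg_config()].
#' @param run_cfg a [run_config()].
#' @param epochs overrides `run_cfg$branch_epochs` when given.
#' @param verbose print per-epoch loss.
#' @return A trained `eeg_model` with a `history` element.
#' @export
fit_eeg_model <- function(x, y, cfg = eeg_config(), run_cfg = run_config(),
                          epochs = NULL, verbose = FALSE) {
  model <- eeg_model(cfg)
  fit <- train_network(model, x, y,
                       batch_size = run_cfg$batch_eeg,
                       epochs = epochs %||% run_cfg$branch_epochs,
                       lr = run_cfg$learning_rate_branch,
                       fwbw = eeg_fwbw,
                       get_batch = function(m, ids)
                         m[, , , , ids, drop = FALSE],
                       verbose = verbose)
  fit$trained <- TRUE
  fit
}

#' @export
predict.eeg_model <- function(object, newdata,
                              type = c("prob", "class", "features"), ...) {
  type <- match.arg(type)
  fw <- eeg_forward(object, newdata, training = FALSE)
  switch(type,
         prob = t(fw$probs),
         class = max.col(t(fw$probs)) - 1L,
         features = t(fw$features))
}

#' @export
print.eeg_model <- function(x, ...) {
  cat("EEG attention classifier\n")
  cat("  input: (", x$cfg$steps, ",", x$cfg$bands, ",", x$cfg$grid_rows, ",",
      x$cfg$grid_cols, ") -> flatten",
      x$cfg$steps * x$cfg$bands * x$cfg$embed_dim, "->",
      x$cfg$n_classes, "classes\n")
  cat("  parameters:", parameter_count(x), "\n")
  cat("  trained:", if (x$trained) "yes" else "no", "\n")
  invisible(x)
}

## ---- exported functional views -------------------------------------------

#' Spectral attention over one EEG sample
#'
#' Each time step's 4 band tokens (flattened 72-dim spatial maps) pass
#' through a single-layer multi-head self-attention encoder with a residual
#' connection; shape is preserved.
#'
#' @param x array `(steps, bands, 8, 9)`.
#' @param params attention parameters ([mhsa_params] shape) — a model's
#'   `params$spec_att`.
#' @param heads number of attention heads.
#' @return Array of the same shape as `x`.
#' @export
spectral_attention <- function(x, params, heads = 4L) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  E <- d[3] * d[4]
  out <- array(0, d)
  for (s in seq_len(d[1])) {
    X <- matrix(x[s, , , ], d[2], E)
    out[s, , , ] <- array(X + mhsa_fw(X, params, heads)$out,
                          c(d[2], d[3], d[4]))
  }
  out
}

#' Attention matrices of an EEG model on one sample
#'
#' @param model an `eeg_model`.
#' @param sample array `(6, 4, 8, 9)`.
#' @return List with `spectral` and `spatial`: per step, a list of per-head
#'   row-stochastic attention matrices (4 x 4 and 72 x 72 respectively).
#' @export
eeg_attention_maps <- function(model, sample) {
  cfg <- model$cfg; p <- model$params
  d <- dim(sample)
  E <- cfg$embed_dim; nb <- cfg$bands
  spectral <- spatial <- vector("list", d[1])
  for (s in seq_len(d[1])) {
    X <- matrix(sample[s, , , ], nb, E)
    spectral[[s]] <- mhsa_attention(X, p$spec_att, cfg$heads)
    Xp <- t(X)
    Xe <- Xp %*% p$spat_emb$W + matrix(p$spat_emb$b, E, E, byrow = TRUE)
    spatial[[s]] <- mhsa_attention(Xe, p$spat_att, cfg$heads)
  }
  list(spectral = spectral, spatial = spatial)
}

#' Temporal step weighting
#'
#' A linear projection of each step's flattened features followed by ReLU
#' gives one non-negative scalar per step; weights are normalised to sum to
#' one (when any is positive) and applied multiplicatively per step.
#'
#' @param x array `(steps, ...)`; trailing dims are flattened per step.
#' @param v projection vector (length = per-step feature count).
#' @param b projection bias (scalar).
#' @return List with `out` (weighted `x`, same shape) and `weights`.
#' @export
temporal_attention <- function(x, v, b = 0) {
  d <- dim(x)
  S <- t(matrix(x, d[1]))                      # [features, steps]
  a <- as.vector(v %*% S) + b
  r <- pmax(a, 0)
  w <- if (sum(r) > 0) r / sum(r) else r
  out <- x * array(w, d)                       # steps vary fastest
  list(out = out, weights = w)
}
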