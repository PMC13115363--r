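#' A pair of per-sample decision probability matrices
#'
#' Holds the class-probability outputs of the EEG and face branches for the
#' same samples, the raw material of decision-level fusion.
#'
#' @param p_eeg,p_face numeric matrices `[n, n_classes]`; every row must be
#'   non-negative and sum to 1 (within 1e-6).
#' @param labels optional integer labels in `0 .. n_classes-1`.
#' @return Object of class `decision_pair`.
#' @export
decision_pair <- function(p_eeg, p_face, labels = NULL) {
  p_eeg <- as.matrix(p_eeg); p_face <- as.matrix(p_face)
  if (!identical(dim(p_eeg), dim(p_face)))
    stop("p_eeg and p_face must have identical dimensions")
  check_simplex(p_eeg, "p_eeg"); check_simplex(p_face, "p_face")
  if (!is.null(labels) && length(labels) != nrow(p_eeg))
    stop("labels length must match the number of rows")
  structure(list(p_eeg = p_eeg, p_face = p_face, labels = labels),
            class = "decision_pair")
}

check_simplex <- function(m, what, tol = 1e-6) {
  if (any(m < -tol)) stop(what, " has negative entries")
  if (any(abs(rowSums(m) - 1) > tol)) stop(what, " rows must sum to 1")
  invisible(TRUE)
}

#' @export
print.decision_pair <- function(x, ...) {
  cat("Decision pair:", nrow(x$p_eeg), "samples x", ncol(x$p_eeg),
      "classes", if (!is.null(x$labels)) "(labelled)" else "", "\n")
  invisible(x)
}

#' Fixed-weight decision fusion
#'
#' The convex combination `k * p_eeg + (1 - k) * p_face`; rows stay on the
#' probability simplex.
#'
#' @param pair a [decision_pair()].
#' @param k fusion weight in `[0, 1]` (1 = EEG only, 0 = face only).
#' @return Fused probability matrix.
#' @export
fuse_fixed <- function(pair, k) {
  stopifnot(inherits(pair, "decision_pair"))
  if (!is.finite(k) || k < 0 || k > 1) stop("k must lie in [0, 1]")
  k * pair$p_eeg + (1 - k) * pair$p_face
}

#' Pick the fixed fusion weight by grid search
#'
#' Evaluates accuracy of [fuse_fixed()] on a labelled validation pair over
#' a grid of weights and returns the best (ties -> smallest k).
#'
#' @param pair labelled [decision_pair()].
#' @param grid candidate weights.
#' @return List with `k` and `accuracy`.
#' @export
choose_fixed_weight <- function(pair, grid = seq(0, 1, by = 0.1)) {
  stopifnot(!is.null(pair$labels))
  accs <- vapply(grid, function(k) {
    pred <- max.col(fuse_fixed(pair, k)) - 1L
    mean(pred == pair$labels)
  }, numeric(1))
  list(k = grid[which.max(accs)], accuracy = max(accs))
}

#' Concatenate the two decision matrices
#'
#' @param pair a [decision_pair()].
#' @return Matrix `[n, 2 * n_classes]`, EEG columns first.
#' @export
concat_decisions <- function(pair) {
  stopifnot(inherits(pair, "decision_pair"))
  cbind(pair$p_eeg, pair$p_face)
}

#' Fusion model configuration
#'
#' The self-learning weight module: the concatenated decision vector is
#' expanded through four GELU-activated fully connected layers (widths
#' non-decreasing, the last equal to `seq_len * embed_dim`), reshaped into
#' `seq_len` tokens of width `embed_dim`, passed through multi-head
#' self-attention, flattened, and classified by an affine + softmax layer.
#'
#' @param hidden_widths integer quadruple of layer widths.
#' @param seq_len,embed_dim token sequence shape after the expansion.
#' @param heads attention heads; `embed_dim` must be divisible by it.
#' @param n_classes number of classes (default 2).
#' @param modality_dropout_p training-time modality dropout probability.
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(hidden_widths = c(16L, 32L, 64L, 64L),
                          seq_len = 8L, embed_dim = 8L, heads = 4L,
                          n_classes = 2L, modality_dropout_p = 0.1) {
  hidden_widths <- as.integer(hidden_widths)
  if (length(hidden_widths) != 4L || is.unsorted(hidden_widths))
    stop("hidden_widths must be four non-decreasing integers")
  if (hidden_widths[4] != seq_len * embed_dim)
    stop("last hidden width must equal seq_len * embed_dim")
  if (embed_dim %% heads != 0L) stop("embed_dim must be divisible by heads")
  structure(list(hidden_widths = hidden_widths, seq_len = as.integer(seq_len),
                 embed_dim = as.integer(embed_dim), heads = as.integer(heads),
                 n_classes = as.integer(n_classes),
                 modality_dropout_p = modality_dropout_p),
            class = "fusion_config")
}

build_fusion_params <- function(cfg) {
  widths <- c(2L * cfg$n_classes, cfg$hidden_widths)
  layers <- lapply(seq_len(4L), function(i)
    linear_params(widths[i], widths[i + 1L]))
  names(layers) <- paste0("h", 1:4)
  c(layers,
    list(att = mhsa_params(cfg$embed_dim),
         out = linear_params(cfg$seq_len * cfg$embed_dim, cfg$n_classes)))
}

#' Expand a decision matrix through the four GELU layers
#'
#' @param x matrix `[n, 2 * n_classes]` of concatenated decisions.
#' @param params a fusion model's parameters (`model$params`).
#' @return Matrix `[n, seq_len * embed_dim]`.
#' @export
mlp_expand <- function(x, params) {
  h <- t(as.matrix(x))
  for (i in 1:4) {
    li <- params[[paste0("h", i)]]
    h <- gelu_fw(li$W %*% h + li$b)$out
  }
  t(h)
}

#' Multi-head self-attention over a token array
#'
#' Scaled dot-product self-attention: per head, queries/keys/values are
#' learned projections of the tokens, attention weights are the
#' row-softmax of `Q K' / sqrt(d_k)`, and head outputs are concatenated
#' and projected.
#'
#' @param x_seq array `[n, seq_len, embed_dim]`.
#' @param params projection matrices (`Wq`, `Wk`, `Wv`, `Wo`, each
#'   `[embed_dim, embed_dim]`), e.g. [mhsa_params()] output or a fusion
#'   model's `params$att`.
#' @param heads number of heads.
#' @return Array `[n, seq_len, embed_dim]`.
#' @export
multi_head_self_attention <- function(x_seq, params, heads = 4L) {
  d <- dim(x_seq)
  stopifnot(length(d) == 3L)
  out <- array(0, d)
  for (n in seq_len(d[1]))
    out[n, , ] <- mhsa_fw(matrix(x_seq[n, , ], d[2], d[3]), params, heads)$out
  out
}

#' Modality dropout
#'
#' Per sample, each modality's probability row is suppressed with marginal
#' probability `p` — replaced by the uniform distribution, maximally
#' uninformative but still on the simplex — under the constraint that both
#' modalities of one sample are never suppressed together.  A single
#' coupled draw per sample (drop EEG with probability `p`, drop face with
#' probability `p`, keep both otherwise) realises the exact marginal rate
#' while guaranteeing the never-both rule; this requires `p <= 0.5`, and
#' `p = 1` in particular is rejected.
#'
#' @param pair a [decision_pair()].
#' @param p per-modality drop probability in `[0, 0.5]`.
#' @return A `decision_pair` with dropped rows replaced.
#' @export
modality_dropout <- function(pair, p) {
  stopifnot(inherits(pair, "decision_pair"))
  if (!is.finite(p) || p < 0 || p > 0.5)
    stop("p must lie in [0, 0.5]: larger p (and p = 1 in particular) ",
         "cannot satisfy the never-both-modalities rule at marginal rate p")
  n <- nrow(pair$p_eeg); D <- ncol(pair$p_eeg)
  if (p > 0) {
    u <- stats::runif(n)
    pair$p_eeg[u < p, ] <- 1 / D
    pair$p_face[u >= p & u < 2 * p, ] <- 1 / D
  }
  pair
}

## ---- self-learning fusion model ------------------------------------------

fusion_forward <- function(model, pair_mats, training = FALSE) {
  cfg <- model$cfg; p <- model$params
  X <- cbind(pair_mats$p_eeg, pair_mats$p_face)
  h <- t(X)                                   # [2D, n]
  lcaches <- vector("list", 4L)
  for (i in 1:4) {
    li <- p[[paste0("h", i)]]
    lf <- linear_fw(h, li$W, li$b)
    gf <- gelu_fw(lf$out)
    lcaches[[i]] <- list(lf = lf, gf = gf)
    h <- gf$out
  }
  n <- ncol(h); L <- cfg$seq_len; E <- cfg$embed_dim
  att_out <- matrix(0, L * E, n)
  att_caches <- vector("list", n)
  for (j in seq_len(n)) {
    Xs <- matrix(h[, j], L, E)
    mh <- mhsa_fw(Xs, p$att, cfg$heads)
    att_caches[[j]] <- mh$cache
    att_out[, j] <- as.vector(mh$out)
  }
  fc <- linear_fw(att_out, p$out$W, p$out$b)
  probs <- col_softmax_probs(fc$out)
  list(probs = probs, logits = fc$out,
       caches = list(layers = lcaches, att = att_caches, fc = fc,
                     n = n),
       bn_stats = list())
}

fusion_fwbw <- function(model, pair_mats, y1, training = TRUE) {
  if (training && model$cfg$modality_dropout_p > 0) {
    pr <- decision_pair(pair_mats$p_eeg, pair_mats$p_face)
    pr <- modality_dropout(pr, model$cfg$modality_dropout_p)
    pair_mats <- list(p_eeg = pr$p_eeg, p_face = pr$p_face)
  }
  fw <- fusion_forward(model, pair_mats, training)
  ce <- softmax_ce(fw$logits, y1)
  p <- model$params; cfg <- model$cfg; ca <- fw$caches
  L <- cfg$seq_len; E <- cfg$embed_dim

  fcb <- linear_bw(ca$fc$cache, p$out$W, ce$dlogits)
  datt <- fcb$dx
  dh <- matrix(0, L * E, ca$n)
  g_att <- NULL
  for (j in seq_len(ca$n)) {
    mb <- mhsa_bw(ca$att[[j]], p$att, matrix(datt[, j], L, E))
    g_att <- grads_add(g_att, mb[c("dWq", "dWk", "dWv", "dWo")])
    dh[, j] <- as.vector(mb$dx)
  }
  names(g_att) <- c("Wq", "Wk", "Wv", "Wo")

  grads <- list()
  dcur <- dh
  for (i in 4:1) {
    cc <- ca$layers[[i]]
    dg <- gelu_bw(cc$gf$cache, dcur)
    lb <- linear_bw(cc$lf$cache, p[[paste0("h", i)]]$W, dg)
    grads[[paste0("h", i)]] <- list(W = lb$dW, b = lb$db)
    dcur <- lb$dx
  }
  grads$att <- g_att
  grads$out <- list(W = fcb$dW, b = fcb$db)
  list(loss = ce$loss, probs = ce$probs, grads = grads[names(p)],
       bn_stats = list())
}

#' Fit the self-learning decision-fusion model
#'
#' Trains the attention-based fusion module on a labelled
#' [decision_pair()], with modality dropout applied to each training batch.
#'
#' @param pair labelled [decision_pair()].
#' @param cfg a [fusion_config()]; its `modality_dropout_p` is overridden by
#'   `run_cfg$modality_dropout_p`.
#' @param run_cfg a [run_config()]; supplies the fusion learning rate, batch
#'   size, epoch count, and modality-dropout probability.
#' @param epochs overrides `run_cfg$fusion_epochs` when given.
#' @param verbose print per-epoch loss.
#' @return A trained object of class `fusion_model`.
#' @export
fit_fusion_model <- function(pair, cfg = fusion_config(),
                             run_cfg = run_config(), epochs = NULL,
                             verbose = FALSE) {
  stopifnot(inherits(pair, "decision_pair"), !is.null(pair$labels))
  cfg$modality_dropout_p <- run_cfg$modality_dropout_p
  model <- structure(list(cfg = cfg, params = build_fusion_params(cfg),
                          state = list(), trained = FALSE,
                          history = numeric(0)),
                     class = "fusion_model")
  x <- list(p_eeg = pair$p_eeg, p_face = pair$p_face)
  fit <- train_network(model, x, pair$labels,
                       batch_size = run_cfg$batch_fusion,
                       epochs = epochs %||% run_cfg$fusion_epochs,
                       lr = run_cfg$learning_rate_fusion,
                       fwbw = fusion_fwbw,
                       get_batch = function(m, ids)
                         list(p_eeg = m$p_eeg[ids, , drop = FALSE],
                              p_face = m$p_face[ids, , drop = FALSE]),
                       verbose = verbose)
  fit$trained <- TRUE
  fit
}

#' @export
predict.fusion_model <- function(object, newdata,
                                 type = c("prob", "class"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "decision_pair"))
  fw <- fusion_forward(object,
                       list(p_eeg = newdata$p_eeg, p_face = newdata$p_face),
                       training = FALSE)
  if (type == "prob") t(fw$probs) else max.col(t(fw$probs)) - 1L
}

#' @export
print.fusion_model <- function(x, ...) {
  cat("Self-learning decision-fusion model\n")
  cat("  expansion widths:", paste(x$cfg$hidden_widths, collapse = " -> "),
      "; tokens:", x$cfg$seq_len, "x", x$cfg$embed_dim,
      "(", x$cfg$heads, "heads )\n")
  cat("  parameters:", parameter_count(x), "\n")
  invisible(x)
}

## ---- feature-level fusion baseline ---------------------------------------

#' Feature-level fusion baseline
#'
#' Concatenates the penultimate feature representations of the two modality
#' branches and trains a fresh two-layer classifier head on them.
#'
#' @param features_eeg,features_face matrices `[n, d]` of per-sample branch
#'   features (see `predict(..., type = "features")`).
#' @param y integer labels.
#' @param hidden hidden width of the classifier head.
#' @param run_cfg a [run_config()].
#' @param epochs training epochs.
#' @return Object of class `feature_fusion_model`.
#' @export
fit_feature_fusion <- function(features_eeg, features_face, y, hidden = 64L,
                               run_cfg = run_config(), epochs = NULL) {
  x <- cbind(as.matrix(features_eeg), as.matrix(features_face))
  mu <- colMeans(x); sdv <- pmax(apply(x, 2, stats::sd), 1e-8)
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  n_classes <- max(2L, max(as.integer(y)) + 1L)
  params <- list(fc1 = linear_params(ncol(x), hidden),
                 fc2 = linear_params(hidden, n_classes))
  model <- structure(list(params = params, state = list(), mu = mu, sd = sdv,
                          trained = FALSE, history = numeric(0)),
                     class = "feature_fusion_model")
  fwbw <- function(model, xb, y1, training = TRUE) {
    p <- model$params
    l1 <- linear_fw(t(xb), p$fc1$W, p$fc1$b)
    r1 <- relu_fw(l1$out)
    l2 <- linear_fw(r1$out, p$fc2$W, p$fc2$b)
    ce <- softmax_ce(l2$out, y1)
    b2 <- linear_bw(l2$cache, p$fc2$W, ce$dlogits)
    dr <- relu_bw(r1$cache, b2$dx)
    b1 <- linear_bw(l1$cache, p$fc1$W, dr)
    list(loss = ce$loss, probs = ce$probs,
         grads = list(fc1 = list(W = b1$dW, b = b1$db),
                      fc2 = list(W = b2$dW, b = b2$db)),
         bn_stats = list())
  }
  fit <- train_network(model, xs, y,
                       batch_size = run_cfg$batch_fusion,
                       epochs = epochs %||% run_cfg$fusion_epochs,
                       lr = run_cfg$learning_rate_branch,
                       fwbw = fwbw,
                       get_batch = function(m, ids) m[ids, , drop = FALSE])
  fit$trained <- TRUE
  fit
}

#' @export
predict.feature_fusion_model <- function(object, newdata,
                                         type = c("prob", "class"), ...) {
  type <- match.arg(type)
  xs <- sweep(sweep(as.matrix(newdata), 2, object$mu), 2, object$sd, "/")
  p <- object$params
  h <- pmax(p$fc1$W %*% t(xs) + p$fc1$b, 0)
  probs <- col_softmax_probs(p$fc2$W %*% h + p$fc2$b)
  if (type == "prob") t(probs) else max.col(t(probs)) - 1L
}
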