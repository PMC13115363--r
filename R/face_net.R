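#' Configuration of the facial-expression network
#'
#' The MSDAC classifier: a two-block convolutional stem, a multi-scale
#' dilated convolution module (MSDC) whose three parallel 3x3 branches use
#' dilation rates 1, 2 and 3 (effective spans 3, 5, 7), a dual-branch
#' attention block (D-BA) combining channel and spatial attention, a final
#' convolutional block with max-pooling and batch normalisation, and a
#' two-layer classifier head with dropout 0.2 after its first layer.
#'
#' @param stem_channels integer pair: output channels of the two stem blocks.
#' @param branch_channels output channels of each MSDC branch.
#' @param dilations strictly increasing integer triple starting at 1.
#' @param attention_reduction channel-attention bottleneck ratio.
#' @param block3_channels channels of the final convolutional block.
#' @param classifier_hidden width of the first classifier layer.
#' @param classifier_dropout dropout rate after the first classifier layer.
#' @param n_classes number of output classes.
#' @param input_size input image side length (square, divisible by 8).
#' @param dba_fusion how the two attention branches are combined
#'   (`"sum"` or `"average"`).
#' @return A list of class `face_config`.
#' @export
face_config <- function(stem_channels = c(32L, 64L), branch_channels = 64L,
                        dilations = c(1L, 2L, 3L), attention_reduction = 4L,
                        block3_channels = 64L, classifier_hidden = 128L,
                        classifier_dropout = 0.2, n_classes = 2L,
                        input_size = 48L, dba_fusion = c("sum", "average")) {
  dilations <- as.integer(dilations)
  if (is.unsorted(dilations, strictly = TRUE) || dilations[1] != 1L)
    stop("dilations must be strictly increasing and start at 1")
  if (classifier_dropout < 0 || classifier_dropout >= 1)
    stop("classifier_dropout must lie in [0, 1)")
  if (input_size %% 8L != 0L || input_size < 24L)
    stop("input_size must be >= 24 and divisible by 8")
  structure(list(stem_channels = as.integer(stem_channels),
                 branch_channels = as.integer(branch_channels),
                 dilations = dilations,
                 attention_reduction = as.integer(attention_reduction),
                 block3_channels = as.integer(block3_channels),
                 classifier_hidden = as.integer(classifier_hidden),
                 classifier_dropout = classifier_dropout,
                 n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 dba_fusion = match.arg(dba_fusion)),
            class = "face_config")
}

face_variants <- c("MSDAC", "MSAC", "WO_DBA", "WO_DBA_MSDC")

# Per-branch (kernel, dilation) specs for each variant.  MSAC matches the
# dilated receptive fields (3, 5, 7) with standard kernels of those sizes.
branch_spec_for <- function(variant, cfg) {
  switch(variant,
    MSDAC = ,
    WO_DBA = lapply(cfg$dilations, function(d) list(k = 3L, dilation = d)),
    MSAC = lapply(cfg$dilations,
                  function(d) list(k = 2L * d + 1L, dilation = 1L)),
    WO_DBA_MSDC = list(list(k = 3L, dilation = 1L)))
}

## ---- attention sub-modules -----------------------------------------------

#' Channel-attention parameters
#' @param channels feature-map channel count.
#' @param reduction bottleneck ratio; `channels` must be divisible by it.
#' @return Parameter list for [channel_attention()].
#' @export
ca_params <- function(channels, reduction) {
  if (channels %% reduction != 0L)
    stop("channels must be divisible by the attention reduction")
  list(fc1 = linear_params(channels, channels %/% reduction),
       fc2 = linear_params(channels %/% reduction, channels))
}

#' Spatial-attention parameters (a 1x1 convolution on the pooled map)
#' @return Parameter list for [spatial_attention()].
#' @export
sa_params <- function() list(w = 1, b = 0)

# broadcast [C, N] over spatial dims -> [C, H, W, N]
bcast_cn <- function(m, H, W) {
  aperm(array(m, c(nrow(m), ncol(m), H, W)), c(1, 3, 4, 2))
}

channel_attention_fw <- function(x, p) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  y <- array(x, c(C, H * W, N))
  g <- vapply(seq_len(N), function(n) rowMeans(y[, , n, drop = FALSE]),
              numeric(C))
  g <- matrix(g, C, N)
  l1 <- linear_fw(g, p$fc1$W, p$fc1$b); r1 <- relu_fw(l1$out)
  l2 <- linear_fw(r1$out, p$fc2$W, p$fc2$b); gate <- sigmoid_fw(l2$out)
  gf <- bcast_cn(gate$out, H, W)
  list(out = x * gf,
       cache = list(x = x, g = g, l1 = l1, r1 = r1, l2 = l2,
                    gate = gate, gf = gf, dim = d))
}

channel_attention_bw <- function(cache, p, dout) {
  d <- cache$dim; C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  dx <- dout * cache$gf
  dgf <- dout * cache$x
  dgate <- matrix(rowSums(matrix(aperm(dgf, c(1, 4, 2, 3)), C * N)), C, N)
  dz2 <- sigmoid_bw(cache$gate$cache, dgate)
  b2 <- linear_bw(cache$l2$cache, p$fc2$W, dz2)
  dz1 <- relu_bw(cache$r1$cache, b2$dx)
  b1 <- linear_bw(cache$l1$cache, p$fc1$W, dz1)
  dx <- dx + bcast_cn(b1$dx / (H * W), H, W)
  list(dx = dx,
       grads = list(fc1 = list(W = b1$dW, b = b1$db),
                    fc2 = list(W = b2$dW, b = b2$db)))
}

spatial_attention_fw <- function(x, p) {
  d <- dim(x); C <- d[1]
  m <- colMeans(x, dims = 1)                    # [H, W, N]
  z <- p$w * m + p$b
  gate <- sigmoid_fw(z)
  gf <- array(rep(gate$out, each = C), d)
  list(out = x * gf,
       cache = list(x = x, m = m, gate = gate, gf = gf, dim = d))
}

spatial_attention_bw <- function(cache, p, dout) {
  d <- cache$dim; C <- d[1]
  dx <- dout * cache$gf
  dgf <- dout * cache$x
  dgate <- colSums(dgf, dims = 1)               # [H, W, N]
  dz <- sigmoid_bw(cache$gate$cache, dgate)
  dm <- dz * p$w
  dx <- dx + array(rep(dm / C, each = C), d)
  list(dx = dx, grads = list(w = sum(dz * cache$m), b = sum(dz)))
}

#' Channel attention (squeeze-and-excitation gating)
#'
#' Global average pooling gives one descriptor per channel; two fully
#' connected layers (ReLU bottleneck, sigmoid output) learn a gate in
#' (0, 1) per channel which multiplies the feature map channel-wise.
#'
#' @param x feature map, array `[channels, H, W, batch]`.
#' @param params from [ca_params()].
#' @return Gated feature map, same shape.
#' @export
channel_attention <- function(x, params) channel_attention_fw(x, params)$out

#' Spatial attention
#'
#' The feature map is mean-pooled along the channel axis, passed through a
#' 1x1 convolution and a sigmoid, producing one gate per spatial position
#' that is broadcast over channels.
#'
#' @param x feature map, array `[channels, H, W, batch]`.
#' @param params from [sa_params()].
#' @return Gated feature map, same shape.
#' @export
spatial_attention <- function(x, params = sa_params())
  spatial_attention_fw(x, params)$out

#' Dual-branch attention (D-BA)
#'
#' Channel attention and spatial attention are applied in parallel to the
#' same input and their outputs fused element-wise (sum by default, or
#' average).
#'
#' @param x feature map, array `[channels, H, W, batch]`.
#' @param ca from [ca_params()]; `sa` from [sa_params()].
#' @param sa spatial-attention parameters.
#' @param fusion `"sum"` or `"average"`.
#' @return Fused feature map, same shape as `x`.
#' @export
dba <- function(x, ca, sa = sa_params(), fusion = c("sum", "average")) {
  fusion <- match.arg(fusion)
  out <- channel_attention(x, ca) + spatial_attention(x, sa)
  if (fusion == "average") out <- out / 2
  out
}

#' Multi-scale (dilated) convolution module forward pass
#'
#' Runs the parallel convolution branches of a face model on a feature map
#' and concatenates their outputs along the channel axis; spatial size is
#' preserved by same-padding.
#'
#' @param x feature map `[channels, H, W, batch]`.
#' @param branches list of branch parameter lists (each `W`, `b`) as built by
#'   [build_variant()]; stored in `model$params$branches`.
#' @param spec per-branch kernel/dilation spec; stored in
#'   `model$branch_spec`.
#' @return Feature map with `sum(branch channels)` channels.
#' @export
msdc_forward <- function(x, branches, spec) {
  outs <- lapply(seq_along(branches), function(i)
    conv2d_fw(x, branches[[i]]$W, branches[[i]]$b, spec[[i]]$dilation)$out)
  d <- dim(outs[[1]])
  tot <- sum(vapply(outs, function(o) dim(o)[1], integer(1)))
  out <- array(0, c(tot, d[2], d[3], d[4]))
  at <- 0L
  for (o in outs) {
    out[at + seq_len(dim(o)[1]), , , ] <- o
    at <- at + dim(o)[1]
  }
  out
}

## ---- model construction ---------------------------------------------------

#' Build a facial-expression network variant
#'
#' `"MSDAC"` is the full model; `"MSAC"` replaces the dilated 3x3 branches
#' with receptive-field-matched standard 3x3 / 5x5 / 7x7 kernels;
#' `"WO_DBA"` removes the dual-branch attention; `"WO_DBA_MSDC"` also
#' collapses the multi-scale module to a single 3x3 branch.
#'
#' @param variant one of `"MSDAC"`, `"MSAC"`, `"WO_DBA"`, `"WO_DBA_MSDC"`.
#' @param cfg a [face_config()].
#' @return An (untrained) object of class `face_model`.
#' @export
build_variant <- function(variant = "MSDAC", cfg = face_config()) {
  if (!variant %in% face_variants)
    stop("unknown variant '", variant, "'; valid: ",
         paste(face_variants, collapse = ", "))
  spec <- branch_spec_for(variant, cfg)
  s <- cfg$stem_channels
  concat_c <- length(spec) * cfg$branch_channels
  params <- list(
    conv1 = conv_params(1L, s[1]), bn1 = bn_params(s[1]),
    conv2 = conv_params(s[1], s[2]), bn2 = bn_params(s[2]),
    branches = lapply(spec, function(b)
      conv_params(s[2], cfg$branch_channels, b$k)),
    conv3 = conv_params(concat_c, cfg$block3_channels),
    bn3 = bn_params(cfg$block3_channels),
    fc1 = linear_params(cfg$block3_channels * (cfg$input_size %/% 8L)^2,
                        cfg$classifier_hidden),
    fc2 = linear_params(cfg$classifier_hidden, cfg$n_classes))
  if (variant %in% c("MSDAC", "MSAC"))
    params <- c(params, list(ca = ca_params(concat_c, cfg$attention_reduction),
                             sa = sa_params()))
  state <- list(bn1 = bn_state(s[1]), bn2 = bn_state(s[2]),
                bn3 = bn_state(cfg$block3_channels))
  structure(list(variant = variant, cfg = cfg, params = params,
                 state = state, branch_spec = spec, trained = FALSE,
                 history = numeric(0)),
            class = "face_model")
}

# Full forward pass.  Returns class probabilities plus caches (training)
# and the penultimate (post-ReLU fc1) features.
face_forward <- function(model, x, training = FALSE) {
  p <- model$params; st <- model$state; cfg <- model$cfg
  has_dba <- model$variant %in% c("MSDAC", "MSAC")
  cv1 <- conv2d_fw(x, p$conv1$W, p$conv1$b)
  bn1 <- batchnorm_fw(cv1$out, p$bn1$gamma, p$bn1$beta, st$bn1, training)
  r1 <- relu_fw(bn1$out); mp1 <- maxpool2_fw(r1$out)
  cv2 <- conv2d_fw(mp1$out, p$conv2$W, p$conv2$b)
  bn2 <- batchnorm_fw(cv2$out, p$bn2$gamma, p$bn2$beta, st$bn2, training)
  r2 <- relu_fw(bn2$out); mp2 <- maxpool2_fw(r2$out)

  brs <- lapply(seq_along(p$branches), function(i)
    conv2d_fw(mp2$out, p$branches[[i]]$W, p$branches[[i]]$b,
              model$branch_spec[[i]]$dilation))
  d <- dim(brs[[1]]$out); bc <- cfg$branch_channels
  concat <- array(0, c(length(brs) * bc, d[2], d[3], d[4]))
  for (i in seq_along(brs))
    concat[(i - 1L) * bc + seq_len(bc), , , ] <- brs[[i]]$out

  if (has_dba) {
    caf <- channel_attention_fw(concat, p$ca)
    saf <- spatial_attention_fw(concat, p$sa)
    fused <- caf$out + saf$out
    if (cfg$dba_fusion == "average") fused <- fused / 2
  } else {
    caf <- saf <- NULL
    fused <- concat
  }

  cv3 <- conv2d_fw(fused, p$conv3$W, p$conv3$b)
  mp3 <- maxpool2_fw(cv3$out)
  bn3 <- batchnorm_fw(mp3$out, p$bn3$gamma, p$bn3$beta, st$bn3, training)
  r3 <- relu_fw(bn3$out)
  flat <- matrix(r3$out, ncol = dim(x)[4])

  f1 <- linear_fw(flat, p$fc1$W, p$fc1$b); rf <- relu_fw(f1$out)
  dr <- dropout_fw(rf$out, cfg$classifier_dropout, training)
  f2 <- linear_fw(dr$out, p$fc2$W, p$fc2$b)
  probs <- col_softmax_probs(f2$out)
  list(probs = probs, logits = f2$out, features = rf$out,
       caches = list(cv1 = cv1, bn1 = bn1, r1 = r1, mp1 = mp1,
                     cv2 = cv2, bn2 = bn2, r2 = r2, mp2 = mp2,
                     brs = brs, caf = caf, saf = saf,
                     cv3 = cv3, mp3 = mp3, bn3 = bn3, r3 = r3,
                     f1 = f1, rf = rf, dr = dr, f2 = f2,
                     flat_dim = dim(r3$out)),
       bn_stats = list(bn1 = bn1$stats, bn2 = bn2$stats, bn3 = bn3$stats))
}

face_fwbw <- function(model, x, y1, training = TRUE) {
  fw <- face_forward(model, x, training)
  ce <- softmax_ce(fw$logits, y1)
  p <- model$params; cfg <- model$cfg; ca <- fw$caches
  has_dba <- model$variant %in% c("MSDAC", "MSAC")

  b2 <- linear_bw(ca$f2$cache, p$fc2$W, ce$dlogits)
  ddr <- dropout_bw(ca$dr$cache, b2$dx)
  drf <- relu_bw(ca$rf$cache, ddr)
  b1 <- linear_bw(ca$f1$cache, p$fc1$W, drf)
  dflat <- array(b1$dx, ca$flat_dim)
  dr3 <- relu_bw(ca$r3$cache, dflat)
  dbn3 <- batchnorm_bw(ca$bn3$cache, dr3)
  dmp3 <- maxpool2_bw(ca$mp3$cache, dbn3$dx)
  dcv3 <- conv2d_bw(ca$cv3$cache, p$conv3$W, dmp3)

  dfused <- dcv3$dx
  grads <- list()
  if (has_dba) {
    if (cfg$dba_fusion == "average") dfused <- dfused / 2
    cab <- channel_attention_bw(ca$caf$cache, p$ca, dfused)
    sab <- spatial_attention_bw(ca$saf$cache, p$sa, dfused)
    dconcat <- cab$dx + sab$dx
    grads$ca <- cab$grads
    grads$sa <- sab$grads
  } else {
    dconcat <- dfused
  }

  bc <- cfg$branch_channels
  dmp2 <- NULL
  grads$branches <- vector("list", length(ca$brs))
  for (i in seq_along(ca$brs)) {
    dbr <- dconcat[(i - 1L) * bc + seq_len(bc), , , , drop = FALSE]
    bb <- conv2d_bw(ca$brs[[i]]$cache, p$branches[[i]]$W, dbr)
    grads$branches[[i]] <- list(W = bb$dW, b = bb$db)
    dmp2 <- if (is.null(dmp2)) bb$dx else dmp2 + bb$dx
  }

  dr2in <- maxpool2_bw(ca$mp2$cache, dmp2)
  dr2 <- relu_bw(ca$r2$cache, dr2in)
  dbn2 <- batchnorm_bw(ca$bn2$cache, dr2)
  dcv2 <- conv2d_bw(ca$cv2$cache, p$conv2$W, dbn2$dx)
  dr1in <- maxpool2_bw(ca$mp1$cache, dcv2$dx)
  dr1 <- relu_bw(ca$r1$cache, dr1in)
  dbn1 <- batchnorm_bw(ca$bn1$cache, dr1)
  dcv1 <- conv2d_bw(ca$cv1$cache, p$conv1$W, dbn1$dx)

  grads$conv1 <- list(W = dcv1$dW, b = dcv1$db)
  grads$bn1 <- list(gamma = dbn1$dgamma, beta = dbn1$dbeta)
  grads$conv2 <- list(W = dcv2$dW, b = dcv2$db)
  grads$bn2 <- list(gamma = dbn2$dgamma, beta = dbn2$dbeta)
  grads$conv3 <- list(W = dcv3$dW, b = dcv3$db)
  grads$bn3 <- list(gamma = dbn3$dgamma, beta = dbn3$dbeta)
  grads$fc1 <- list(W = b1$dW, b = b1$db)
  grads$fc2 <- list(W = b2$dW, b = b2$db)

  list(loss = ce$loss, probs = ce$probs,
       grads = grads[names(model$params)], bn_stats = fw$bn_stats)
}

# Coerce image input to [1, H, W, N]
as_face_batch <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(1L, dim(x))
  stopifnot(length(dim(x)) == 4L, dim(x)[1] == 1L)
  if (any(!is.finite(x))) stop("non-finite pixel values in input")
  x
}

#' Fit a facial-expression classifier
#'
#' Trains a [build_variant()] network with Adam and cross-entropy loss.
#'
#' @param x grayscale images: array `[H, W, n]` with values in `[0, 1]`.
#' @param y integer class labels in `0 .. n_classes-1`.
#' @param variant model variant, see [build_variant()].
#' @param cfg a [face_config()].
#' @param run_cfg a [run_config()]; supplies learning rate, batch size and
#'   epoch count.
#' @param epochs overrides `run_cfg$branch_epochs` when given.
#' @param verbose print per-epoch loss.
#' @return A trained `face_model` with a `history` element (mean training
#'   loss per epoch).
#' @export
fit_face_model <- function(x, y, variant = "MSDAC", cfg = face_config(),
                           run_cfg = run_config(), epochs = NULL,
                           verbose = FALSE) {
  x <- as_face_batch(x)
  model <- build_variant(variant, cfg)
  fit <- train_network(model, x, y,
                       batch_size = run_cfg$batch_face,
                       epochs = epochs %||% run_cfg$branch_epochs,
                       lr = run_cfg$learning_rate_branch,
                       fwbw = face_fwbw,
                       get_batch = function(m, ids)
                         m[, , , ids, drop = FALSE],
                       verbose = verbose)
  fit$trained <- TRUE
  fit
}

#' @export
predict.face_model <- function(object, newdata,
                               type = c("prob", "class", "features"), ...) {
  type <- match.arg(type)
  x <- as_face_batch(newdata)
  fw <- face_forward(object, x, training = FALSE)
  switch(type,
         prob = t(fw$probs),
         class = max.col(t(fw$probs)) - 1L,
         features = t(fw$features))
}

#' @export
print.face_model <- function(x, ...) {
  cat("Facial-expression network (", x$variant, ")\n", sep = "")
  cat("  parameters:", parameter_count(x), "\n")
  cat("  input:", x$cfg$input_size, "x", x$cfg$input_size,
      "grayscale ->", x$cfg$n_classes, "classes\n")
  cat("  trained:", if (x$trained) paste0("yes (", length(x$history),
                                          " epochs)") else "no", "\n")
  invisible(x)
}

#' @export
summary.face_model <- function(object, ...) {
  print(object)
  if (object$trained)
    cat("  final training loss:",
        format(utils::tail(object$history, 1), digits = 4), "\n")
  invisible(object)
}
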