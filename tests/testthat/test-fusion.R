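test_that("fixed-weight fusion is a convex combination on the simplex", {
  set.seed(31)
  pair <- decision_pair(random_simplex(20), random_simplex(20))
  expect_equal(fuse_fixed(pair, 1), pair$p_eeg)
  expect_equal(fuse_fixed(pair, 0), pair$p_face)
  half <- fuse_fixed(decision_pair(matrix(c(0.8, 0.2), 1),
                                   matrix(c(0.4, 0.6), 1)), 0.5)
  expect_equal(as.vector(half), c(0.6, 0.4))
  expect_error(fuse_fixed(pair, 1.5), "\\[0, 1\\]")
  # rows stay on the simplex and move linearly toward p_eeg as k grows
  ks <- seq(0, 1, 0.25)
  outs <- lapply(ks, fuse_fixed, pair = pair)
  for (o in outs) expect_equal(rowSums(o), rep(1, 20), tolerance = 1e-12)
  d_to_eeg <- vapply(outs, function(o) sum(abs(o - pair$p_eeg)), numeric(1))
  expect_true(all(diff(d_to_eeg) < 0))
  expect_equal(diff(d_to_eeg), rep(diff(d_to_eeg)[1], 4), tolerance = 1e-9)
})

test_that("decision concatenation is invertible and EEG-first", {
  set.seed(32)
  pair <- decision_pair(random_simplex(10), random_simplex(10))
  cc <- concat_decisions(pair)
  expect_equal(dim(cc), c(10L, 4L))
  expect_equal(rowSums(cc), rep(2, 10), tolerance = 1e-12)
  expect_equal(cc[, 1:2], pair$p_eeg)
  expect_equal(cc[, 3:4], pair$p_face)
  # malformed pairs rejected
  expect_error(decision_pair(matrix(c(0.7, 0.2), 1), matrix(c(0.5, 0.5), 1)),
               "sum to 1")
  expect_error(decision_pair(matrix(c(-0.1, 1.1), 1), matrix(c(0.5, 0.5), 1)),
               "negative")
})

test_that("the expansion MLP ends at seq_len x embed_dim and is row-wise", {
  set.seed(33)
  cfg <- fusion_config()
  params <- msdafuse:::build_fusion_params(cfg)
  x <- random_simplex(6) |> cbind(random_simplex(6))
  h <- mlp_expand(x, params)
  expect_equal(dim(h), c(6L, cfg$seq_len * cfg$embed_dim))
  # no cross-sample coupling
  expect_equal(mlp_expand(x[2:3, ], params), h[2:3, ], tolerance = 1e-12)
  # zero input: deterministic stack of GELU'd biases
  h0 <- mlp_expand(matrix(0, 2, 4), params)
  expect_equal(h0[1, ], h0[2, ], tolerance = 1e-14)
  expect_error(fusion_config(hidden_widths = c(16, 32, 64, 72)),
               "seq_len")
  expect_error(fusion_config(hidden_widths = c(16, 32, 64, 60)),
               "non-decreasing")
})

test_that("multi-head self-attention obeys softmax structure and degenerate cases", {
  set.seed(34)
  p <- mhsa_params(8L)
  x <- array(rnorm(3 * 8 * 8), c(3, 8, 8))
  out <- multi_head_self_attention(x, p, heads = 4L)
  expect_equal(dim(out), dim(x))
  # L = 1: attention is [[1]] and the map is linear in the token
  x1 <- array(rnorm(2 * 1 * 8), c(2, 1, 8))
  o1 <- multi_head_self_attention(x1, p, heads = 4L)
  M <- p$Wv %*% p$Wo                   # single token: out = x Wv Wo
  expect_equal(matrix(o1[1, , ], 1), matrix(x1[1, , ], 1) %*% M,
               tolerance = 1e-12)
  expect_equal(matrix(o1[1, , ] + x1[2, , ] %*% M, 1),
               matrix(o1[1, , ] + o1[2, , ], 1), tolerance = 1e-12)
})

test_that("hand-computed two-token single-head attention matches", {
  # fully explicit 2x2 arithmetic with hand-set projections
  p <- list(Wq = diag(2), Wk = diag(2), Wv = diag(2), Wo = diag(2))
  X <- matrix(c(1, 0,
                0, 2), 2, 2, byrow = TRUE)
  # S = X X^T / sqrt(2):  [[1,0],[0,4]] / sqrt(2)
  s11 <- 1 / sqrt(2); s22 <- 4 / sqrt(2)
  A <- rbind(c(exp(s11), exp(0)), c(exp(0), exp(s22)))
  A <- A / rowSums(A)
  expect_equal(msdafuse:::mhsa_fw(X, p, heads = 1L)$out, A %*% X,
               tolerance = 1e-12)
})

test_that("modality dropout respects rate, never-both, and bounds", {
  set.seed(35)
  pair <- decision_pair(random_simplex(10000), random_simplex(10000))
  expect_identical(modality_dropout(pair, 0), pair)
  expect_error(modality_dropout(pair, 1), "never-both")
  dropped <- modality_dropout(pair, 0.1)
  unif <- function(m) abs(m[, 1] - 0.5) < 1e-12 & abs(m[, 2] - 0.5) < 1e-12
  de <- unif(dropped$p_eeg)
  df <- unif(dropped$p_face)
  # empirical per-modality drop rate within 0.10 +/- 0.01 over 10,000 draws
  expect_lt(abs(mean(de) - 0.1), 0.01)
  expect_lt(abs(mean(df) - 0.1), 0.01)
  # both modalities of one sample are never suppressed together
  expect_length(which(de & df), 0L)
})

test_that("self-learning fusion preserves the simplex and sample order", {
  set.seed(36)
  tr <- generate_decisions(200, 0.5, 0.9)
  fit <- fit_fusion_model(tr, run_cfg = run_config(), epochs = 3L)
  te <- generate_decisions(50, 0.5, 0.9)
  pr <- predict(fit, te, type = "prob")
  expect_equal(rowSums(pr), rep(1, 50), tolerance = 1e-6)
  expect_true(all(pr >= 0))
  # permuting samples permutes outputs identically
  perm <- sample(50)
  te_perm <- decision_pair(te$p_eeg[perm, ], te$p_face[perm, ])
  expect_equal(predict(fit, te_perm, type = "prob"), pr[perm, ],
               tolerance = 1e-10)
  # one modality replaced by uniform noise still yields valid probabilities
  te_noisy <- decision_pair(matrix(0.5, 50, 2), te$p_face)
  prn <- predict(fit, te_noisy, type = "prob")
  expect_equal(rowSums(prn), rep(1, 50), tolerance = 1e-6)
})

test_that("fusion trained on complementary decisions beats both single modalities", {
  set.seed(37)
  bench <- fusion_benchmark(n_train = 600, n_test = 300,
                            complementarity = 0.5, acc = 0.85)
  expect_gt(bench$self_learning, bench$eeg)
  expect_gt(bench$self_learning, bench$face)
})
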