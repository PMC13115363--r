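test_that("confusion matrices count, conserve, and reproduce accuracy", {
  preds <- c(0L, 1L, 1L, 0L, 1L)
  labs <- c(0L, 1L, 0L, 0L, 1L)
  cm <- confusion(preds, labs)
  expect_equal(sum(cm), 5L)
  expect_equal(cm["0", "0"], 2L)
  expect_equal(cm["0", "1"], 1L)
  expect_equal(msdafuse:::accuracy_from_confusion(cm), mean(preds == labs))
  perfect <- confusion(labs, labs)
  expect_equal(perfect["0", "1"] + perfect["1", "0"], 0L)
  expect_error(confusion(c(0L, 2L), c(0L, 1L)), "0 or 1")
  expect_error(confusion(0L, c(0L, 1L)), "length")
})

test_that("the paired t-test matches the closed form and its conventions", {
  set.seed(51)
  b <- runif(8, 0.7, 0.9)
  a <- b + 0.05 + rnorm(8, sd = 0.02)
  res <- paired_t_test(a, b)
  # textbook closed form: t = dbar / (s_d / sqrt(n))
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = length(d) - 1)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, p_hand, tolerance = 1e-12)
  # antisymmetry
  swapped <- paired_t_test(b, a)
  expect_equal(swapped$t, -res$t, tolerance = 1e-12)
  expect_equal(swapped$p, res$p, tolerance = 1e-12)
  # zero-variance differences: p = 1 with a warning
  expect_warning(z <- paired_t_test(b, b), "zero-variance")
  expect_equal(z$p, 1)
  expect_true(is.na(z$t))
  expect_error(paired_t_test(1, c(1, 2)), "equal-length")
})

test_that("stratified folds partition every class across k folds", {
  set.seed(52)
  labels <- rep(0:1, c(500, 300))
  fold <- msdafuse:::stratified_folds(labels, 5L)
  expect_setequal(unique(fold), 1:5)
  expect_equal(as.vector(table(fold)), rep(160L, 5))   # 800 / 5
  for (f in 1:5) expect_setequal(unique(labels[fold == f]), 0:1)
})

test_that("cross-validation tests every sample exactly once", {
  set.seed(53)
  n <- 60
  x <- matrix(rnorm(n * 3), n)
  y <- rep(0:1, length.out = n)
  x[y == 1, 1] <- x[y == 1, 1] + 3
  # a deliberately simple threshold model keeps the test about the harness
  fit_fun <- function(xt, yt)
    list(cut = mean(c(mean(xt[yt == 0, 1]), mean(xt[yt == 1, 1]))))
  predict_fun <- function(m, xt) as.integer(xt[, 1] > m$cut)
  res <- cross_validate_subject(x, y, fit_fun, predict_fun,
                                subset_fun = function(x, i) x[i, , drop = FALSE],
                                k = 5L, subject_id = "toy")
  expect_s3_class(res, "subject_result")
  tested <- sort(unlist(lapply(res$folds, `[[`, "test_idx")))
  expect_identical(tested, seq_len(n))                 # partition
  accs <- vapply(res$folds, `[[`, numeric(1), "accuracy")
  expect_equal(res$mean_acc, mean(accs))
  expect_equal(res$std_acc, sd(accs))
  for (f in res$folds) expect_equal(sum(f$confusion), 12L)
  expect_error(cross_validate_subject(x[1:6, ], c(0, 0, 0, 1, 1, 1)[1:6],
                                      fit_fun, predict_fun,
                                      function(x, i) x[i, , drop = FALSE],
                                      k = 5L),
               "at least k")
})

test_that("aggregation is an unweighted, permutation-invariant mean", {
  mk <- function(id, accs) structure(
    list(subject_id = id,
         folds = lapply(seq_along(accs), function(i)
           list(fold_index = i, accuracy = accs[i])),
         mean_acc = mean(accs), std_acc = sd(accs)),
    class = "subject_result")
  r1 <- mk("a", c(0.8, 0.9)); r2 <- mk("b", c(0.6, 0.7))
  single <- aggregate_results(list(r1))
  expect_equal(single$mean_acc, r1$mean_acc)
  expect_equal(single$mean_std, r1$std_acc)
  both <- aggregate_results(list(r1, r2))
  expect_equal(both$mean_acc, mean(c(r1$mean_acc, r2$mean_acc)))
  expect_equal(both$mean_acc, aggregate_results(list(r2, r1))$mean_acc)
  same <- aggregate_results(list(r1, r1, r1))
  expect_equal(sd(same$subjects$mean_acc), 0)
  expect_error(aggregate_results(list()), "no subject")
})

test_that("training is seed-reproducible and overfits a constant-label toy", {
  pair <- within_seed <- NULL
  set.seed(54)
  tr <- generate_decisions(120, 0.5, 0.9)
  set.seed(55)
  f1 <- fit_fusion_model(tr, run_cfg = run_config(), epochs = 4L)
  set.seed(55)
  f2 <- fit_fusion_model(tr, run_cfg = run_config(), epochs = 4L)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  # loss decreases monotonically over the first epochs on a constant-label
  # set (full-batch so each epoch is one clean descent step)
  set.seed(56)
  x <- matrix(rnorm(80 * 4), 80)
  y <- rep(0L, 80)
  ff <- fit_feature_fusion(x[, 1:2], x[, 3:4], y, hidden = 8L,
                           run_cfg = run_config(batch_fusion = 128L),
                           epochs = 5L)
  expect_true(all(diff(ff$history) < 0))
})

test_that("cross-validation on the fusion model reaches high accuracy per fold", {
  set.seed(57)
  pair <- generate_decisions(400, 0.5, 0.9)
  res <- cross_validate_subject(
    pair, pair$labels,
    fit_fun = function(xt, yt)
      fit_fusion_model(decision_pair(xt$p_eeg, xt$p_face, yt),
                       run_cfg = run_config(), epochs = 30L),
    predict_fun = function(m, xt)
      predict(m, decision_pair(xt$p_eeg, xt$p_face), type = "class"),
    subset_fun = function(p, i) list(p_eeg = p$p_eeg[i, , drop = FALSE],
                                     p_face = p$p_face[i, , drop = FALSE]),
    k = 5L, subject_id = "synthetic")
  expect_gt(res$mean_acc, 0.9)
  expect_equal(length(res$folds), 5L)
})
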