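#' Confusion matrix for binary predictions
#'
#' @param preds,labels integer vectors in `{0, 1}`; rows of the result are
#'   the true class, columns the predicted class.
#' @return 2x2 integer matrix with dimnames `true`/`pred`.
#' @export
confusion <- function(preds, labels) {
  if (length(preds) != length(labels)) stop("length mismatch")
  if (!all(c(preds, labels) %in% 0:1)) stop("labels must be 0 or 1")
  m <- matrix(0L, 2, 2, dimnames = list(true = c("0", "1"),
                                        pred = c("0", "1")))
  for (i in seq_along(preds))
    m[labels[i] + 1L, preds[i] + 1L] <- m[labels[i] + 1L, preds[i] + 1L] + 1L
  m
}

accuracy_from_confusion <- function(m) sum(diag(m)) / sum(m)

f1_binary <- function(preds, labels, positive = 1L) {
  tp <- sum(preds == positive & labels == positive)
  fp <- sum(preds == positive & labels != positive)
  fn <- sum(preds != positive & labels == positive)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Paired t-test on per-fold accuracies
#'
#' Two-sided paired t-test on the element-wise differences.  When the
#' differences have zero variance the statistic is undefined; by
#' convention the test then reports `p = 1` with a warning (no evidence of
#' a difference either way).
#'
#' @param acc_a,acc_b equal-length numeric vectors (length >= 2).
#' @return List with `t` and `p`.
#' @export
paired_t_test <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b) || length(acc_a) < 2)
    stop("need two equal-length vectors of length >= 2")
  d <- acc_a - acc_b
  if (stats::sd(d) == 0) {
    warning("zero-variance differences: t undefined, returning p = 1")
    return(list(t = NA_real_, p = 1))
  }
  tt <- stats::t.test(acc_a, acc_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

# Stratified k-fold assignment: within each class, samples are shuffled
# and dealt round-robin so every fold sees every class.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Subject-level stratified k-fold cross-validation
#'
#' Partitions one subject's samples into `k` class-stratified folds, trains
#' a fresh model per fold via `fit_fun`, and evaluates on the held-out
#' fold.  Every sample is tested exactly once.
#'
#' @param x sample container passed to `fit_fun`/`predict_fun` after
#'   subsetting with `subset_fun`.
#' @param y integer 0/1 labels.
#' @param fit_fun `function(x_train, y_train)` returning a fitted model.
#' @param predict_fun `function(model, x_test)` returning 0/1 predictions
#'   (defaults to `predict(model, x_test, type = "class")`).
#' @param subset_fun `function(x, idx)` extracting samples.
#' @param k number of folds (default 5).
#' @param subject_id identifier carried into the result.
#' @return Object of class `subject_result`: per-fold accuracy/F1/confusion
#'   plus `mean_acc` and `std_acc`.
#' @export
cross_validate_subject <- function(x, y, fit_fun, predict_fun = NULL,
                                   subset_fun, k = 5L, subject_id = "S01") {
  y <- as.integer(y)
  if (min(table(y)) < k)
    stop("need at least k samples per class for stratified ", k, "-fold CV")
  if (is.null(predict_fun))
    predict_fun <- function(model, xt) stats::predict(model, xt,
                                                      type = "class")
  fold <- stratified_folds(y, k)
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    te <- which(fold == f); tr <- which(fold != f)
    if (length(unique(y[tr])) < 2L)
      stop("a class is absent from the training split of fold ", f)
    model <- fit_fun(subset_fun(x, tr), y[tr])
    preds <- as.integer(predict_fun(model, subset_fun(x, te)))
    cm <- confusion(preds, y[te])
    folds[[f]] <- list(fold_index = f,
                       accuracy = accuracy_from_confusion(cm),
                       f1 = f1_binary(preds, y[te]),
                       confusion = cm,
                       test_idx = te)
  }
  accs <- vapply(folds, `[[`, numeric(1), "accuracy")
  structure(list(subject_id = subject_id, folds = folds,
                 mean_acc = mean(accs), std_acc = stats::sd(accs)),
            class = "subject_result")
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf("Subject %s: %d-fold CV accuracy %.3f +/- %.3f\n",
              x$subject_id, length(x$folds), x$mean_acc, x$std_acc))
  invisible(x)
}

#' Aggregate subject results
#'
#' Unweighted mean of the per-subject mean accuracies and of the
#' per-subject standard deviations.
#'
#' @param results non-empty list of `subject_result` objects.
#' @return List with `mean_acc`, `mean_std`, `n_subjects`, and the
#'   per-subject table `subjects`.
#' @export
aggregate_results <- function(results) {
  if (length(results) == 0) stop("no subject results to aggregate")
  ma <- vapply(results, `[[`, numeric(1), "mean_acc")
  sa <- vapply(results, `[[`, numeric(1), "std_acc")
  list(mean_acc = mean(ma), mean_std = mean(sa), n_subjects = length(results),
       subjects = data.frame(
         subject_id = vapply(results, `[[`, character(1), "subject_id"),
         mean_acc = ma, std_acc = sa))
}

#' Decision-level fusion benchmark on complementary synthetic decisions
#'
#' Runs the full decision-fusion comparison on a [generate_decisions()]
#' dataset: accuracy of each single modality, of fixed-weight fusion (the
#' weight grid-searched on the training split), and of the trained
#' self-learning fusion model, all evaluated on a held-out split.
#'
#' @param n_train,n_test sample counts.
#' @param complementarity,acc forwarded to [generate_decisions()].
#' @param run_cfg a [run_config()].
#' @param cfg a [fusion_config()].
#' @return List of held-out accuracies: `eeg`, `face`, `fixed` (with the
#'   chosen `k`), `self_learning`.
#' @export
fusion_benchmark <- function(n_train = 600L, n_test = 300L,
                             complementarity = 0.5, acc = 0.85,
                             run_cfg = run_config(),
                             cfg = fusion_config()) {
  tr <- generate_decisions(n_train, complementarity, acc)
  te <- generate_decisions(n_test, complementarity, acc)
  acc_of <- function(probs) mean((max.col(probs) - 1L) == te$labels)
  pick <- choose_fixed_weight(tr)
  model <- fit_fusion_model(tr, cfg, run_cfg)
  list(eeg = acc_of(te$p_eeg),
       face = acc_of(te$p_face),
       fixed = acc_of(fuse_fixed(te, pick$k)),
       fixed_k = pick$k,
       self_learning = mean(stats::predict(model, te,
                                           type = "class") == te$labels))
}
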