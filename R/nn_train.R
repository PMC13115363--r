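# Shared mini-batch Adam driver.  A model is a list with $params (nested
# list of arrays), $state (running batch-norm statistics) and a class; the
# per-model `fwbw(model, xb, y1, training)` returns loss, grads aligned
# with $params, and per-layer batch statistics for the running-state
# update.  Randomness (shuffling, dropout) uses the session RNG, so
# `set.seed()` before fitting makes training fully reproducible.
train_network <- function(model, x, y, batch_size, epochs, lr, fwbw,
                          get_batch, verbose = FALSE, bn_momentum = 0.1) {
  y <- as.integer(y)
  if (any(is.na(y)) || any(y < 0)) stop("labels must be non-negative integers")
  y1 <- y + 1L
  n <- length(y)
  batch_size <- min(batch_size, n)
  opt <- adam_init(model$params)
  history <- numeric(epochs)
  for (e in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = batch_size)) {
      ids <- ord[start:min(start + batch_size - 1L, n)]
      res <- fwbw(model, get_batch(x, ids), y1[ids], training = TRUE)
      if (!is.finite(res$loss))
        stop("training aborted: non-finite loss at epoch ", e,
             " (batch starting at ", start, ")")
      st <- adam_step(model$params, res$grads, opt, lr)
      model$params <- st$params
      opt <- st$opt
      for (nm in names(res$bn_stats)) {
        model$state[[nm]]$mean <- (1 - bn_momentum) * model$state[[nm]]$mean +
          bn_momentum * res$bn_stats[[nm]]$mean
        model$state[[nm]]$var <- (1 - bn_momentum) * model$state[[nm]]$var +
          bn_momentum * res$bn_stats[[nm]]$var
      }
      losses <- c(losses, res$loss)
    }
    history[e] <- mean(losses)
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f", e, epochs, history[e]))
  }
  model$history <- history
  model
}
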