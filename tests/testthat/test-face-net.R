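test_that("parameter counting is exact and additive", {
  # single 3x3 conv, 1 -> 8 channels, bias: 3*3*1*8 + 8 = 80
  set.seed(1)
  p <- conv_params(1L, 8L, 3L)
  expect_equal(parameter_count(p), 80L)
  q <- linear_params(10L, 4L)
  expect_equal(parameter_count(list(a = p, b = q)),
               parameter_count(p) + parameter_count(q))
})

test_that("dilated branches keep parameter count; standard kernels grow as k^2", {
  set.seed(2)
  cfg <- tiny_face_config()
  msdac <- build_variant("MSDAC", cfg)
  msac <- build_variant("MSAC", cfg)
  n_dil <- vapply(msdac$params$branches, parameter_count, numeric(1))
  n_std <- vapply(msac$params$branches, parameter_count, numeric(1))
  # count invariant under dilation
  expect_true(all(n_dil == n_dil[1]))
  # per-branch weight ratio standard-7x7 : dilated-3x3 = 49 : 9
  w_dil <- length(msdac$params$branches[[3]]$W)
  w_std <- length(msac$params$branches[[3]]$W)
  expect_equal(w_std / w_dil, 49 / 9)
  # total: dilated variant strictly lighter at equal widths
  expect_lt(parameter_count(msdac), parameter_count(msac))
})

test_that("MSDC branches preserve spatial size and span multiple scales", {
  set.seed(3)
  model <- build_variant("MSDAC", tiny_face_config())
  spec <- model$branch_spec
  # effective span 2d + 1 for a 3x3 kernel
  expect_equal(vapply(spec, function(s) s$dilation * 2L + 1L, integer(1)),
               c(3L, 5L, 7L))
  for (side in c(8L, 17L, 33L, 64L)) {
    x <- array(rnorm(12 * side * side * 2), c(12, side, side, 2))
    out <- msdc_forward(x, model$params$branches, spec)
    expect_equal(dim(out), c(36L, side, side, 2L))
  }
  # input below the widest span errors
  tiny <- array(0, c(12, 6, 6, 1))
  expect_error(msdc_forward(tiny, model$params$branches, spec), "span")
})

test_that("channel attention pools, gates in (0,1), and can be forced open", {
  set.seed(4)
  C <- 8L
  p <- ca_params(C, 4L)
  x <- array(rnorm(C * 6 * 6 * 3), c(C, 6, 6, 3))
  # pooled descriptor equals the spatial mean (gate forced to 1 via biases)
  fw <- msdafuse:::channel_attention_fw(x, p)
  expect_equal(fw$cache$g[, 2], apply(x[, , , 2], 1, mean))
  # sigmoid gates stay below 1: per-channel magnitude never grows
  out <- channel_attention(x, p)
  mag_in <- apply(abs(x), 1, sum)
  mag_out <- apply(abs(out), 1, sum)
  expect_true(all(mag_out <= mag_in))
  # saturating the output layer bias forces identity gating
  p_open <- p
  p_open$fc2$b <- rep(50, C)
  expect_equal(channel_attention(x, p_open), x, tolerance = 1e-8)
  expect_error(ca_params(10L, 4L), "divisible")
})

test_that("spatial attention gates per position and respects symmetry", {
  set.seed(5)
  x <- array(rnorm(4 * 6 * 6 * 2), c(4, 6, 6, 2))
  p <- sa_params()
  # constant input -> spatially uniform gates
  xc <- array(1, c(4, 6, 6, 1))
  fwc <- msdafuse:::spatial_attention_fw(xc, p)
  expect_equal(max(fwc$cache$gate$out) - min(fwc$cache$gate$out), 0)
  # gate map is one value per spatial position (dim H x W x N)
  fw <- msdafuse:::spatial_attention_fw(x, p)
  expect_equal(dim(fw$cache$gate$out), c(6L, 6L, 2L))
  # multiplicative zero
  expect_equal(spatial_attention(array(0, dim(x)), p), array(0, dim(x)))
})

test_that("dual-branch attention sums its branches", {
  set.seed(6)
  x <- array(rnorm(8 * 6 * 6 * 2), c(8, 6, 6, 2))
  ca <- ca_params(8L, 4L)
  sa <- sa_params()
  # force both branches to identity gating: sum fusion doubles the input
  ca$fc2$b <- rep(50, 8L)
  sa$w <- 0; sa$b <- 50
  expect_equal(dba(x, ca, sa, "sum"), 2 * x, tolerance = 1e-8)
  expect_equal(dba(x, ca, sa, "average"), x, tolerance = 1e-8)
  expect_equal(dim(dba(x, ca_params(8L, 4L), sa_params())), dim(x))
})

test_that("all variants emit probability rows and share the interface", {
  set.seed(7)
  cfg <- tiny_face_config()
  x <- array(runif(48 * 48 * 3), c(48, 48, 3))
  for (v in c("MSDAC", "MSAC", "WO_DBA", "WO_DBA_MSDC")) {
    m <- build_variant(v, cfg)
    pr <- predict(m, x, type = "prob")
    expect_equal(dim(pr), c(3L, 2L))
    expect_equal(rowSums(pr), rep(1, 3), tolerance = 1e-6)
    expect_true(all(pr >= 0))
    # evaluation mode is deterministic
    expect_identical(pr, predict(m, x, type = "prob"))
  }
  expect_error(build_variant("SOMETHING"), "MSDAC, MSAC, WO_DBA")
  expect_error(predict(build_variant("MSDAC", cfg),
                       array(NaN, c(48, 48, 1))), "finite")
})

test_that("one optimisation step moves the weights of every branch", {
  set.seed(8)
  cfg <- tiny_face_config()
  model <- build_variant("MSDAC", cfg)
  x <- array(runif(48 * 48 * 8), c(1, 48, 48, 8))
  y1 <- rep(1:2, 4)
  res <- msdafuse:::face_fwbw(model, x, y1, training = TRUE)
  opt <- msdafuse:::adam_init(model$params)
  st <- msdafuse:::adam_step(model$params, res$grads, opt, 1e-3)
  for (i in 1:3) {
    delta <- st$params$branches[[i]]$W - model$params$branches[[i]]$W
    expect_true(all(abs(delta) > 0),
                label = paste("branch", i, "weights all updated"))
  }
})

test_that("MSDAC separates local-blob from split-blob faces", {
  set.seed(101)
  tr <- generate_faces(240)
  te <- generate_faces(100)
  rc <- run_config(batch_face = 32L)
  fit <- fit_face_model(tr$x, tr$y, "MSDAC", tiny_face_config(), rc,
                        epochs = 5L)
  acc <- mean(predict(fit, te$x, type = "class") == te$y)
  expect_gte(acc, 0.9)
  expect_true(fit$trained)
  expect_length(fit$history, 5L)
})
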