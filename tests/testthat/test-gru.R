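test_that("gru cell reproduces the gate equations in closed form", {
  layer <- list(
    W_z = matrix(0, 3, 2), U_z = matrix(0, 3, 3), b_z = rep(0, 3),
    W_r = matrix(0, 3, 2), U_r = matrix(0, 3, 3), b_r = rep(0, 3),
    W_h = matrix(0, 3, 2), U_h = matrix(0, 3, 3), b_h = rep(0, 3)
  )
  st <- gru_cell_step(c(1, -1), rep(0, 3), layer)
  expect_equal(st$z, rep(0.5, 3))
  expect_equal(st$r, rep(0.5, 3))
  expect_equal(st$h_tilde, rep(0, 3))
  expect_equal(st$h, rep(0, 3))

  # z ~ 0 freezes the hidden state
  layer$b_z <- rep(-1e6, 3)
  h_prev <- c(0.3, -0.2, 0.8)
  st2 <- gru_cell_step(c(1, 2), h_prev, layer)
  expect_equal(st2$h, h_prev, tolerance = 1e-6)

  expect_error(gru_cell_step(c(1, 2, 3), h_prev, layer), "dimension")
})

test_that("gates stay in their ranges over random multi-step runs", {
  set.seed(21)
  p <- gru_init(3, 1, input_size = 2, seed = 5)
  h <- rep(0, 3)
  for (t in 1:5) {
    st <- gru_cell_step(rnorm(2), h, p$layers[[1]])
    expect_true(all(st$z > 0 & st$z < 1))
    expect_true(all(st$r > 0 & st$r < 1))
    expect_true(all(st$h_tilde > -1 & st$h_tilde < 1))
    h <- st$h
  }
})

test_that("the batched forward pass equals the scalar oracle", {
  set.seed(31)
  for (rep_i in 1:10) {
    p <- gru_init(sample(2:3, 1), sample(1:2, 1), input_size = 12,
                  fusion = TRUE, seed = rep_i)
    sig <- matrix(rnorm(12 * 8), 12, 8)
    fv <- rnorm(13)
    expect_equal(unname(gru_forward(sig, p, fv)),
                 oracle_gru_forward(p, sig, fv), tolerance = 1e-6)
  }
})

test_that("forward output is a probability vector and fusion is isolated", {
  p <- gru_init(4, 2, fusion = TRUE, seed = 2)
  sig <- matrix(rnorm(12 * 20), 12, 20)
  pr <- gru_forward(sig, p, rnorm(13))
  expect_true(all(pr >= 0))
  expect_equal(sum(pr), 1, tolerance = 1e-9)

  # zero the feature block of the head: features become irrelevant
  p0 <- p
  p0$head$W[, 5:17] <- 0
  expect_equal(gru_forward(sig, p0, rnorm(13)),
               gru_forward(sig, p0, rnorm(13)), tolerance = 1e-12)

  expect_error(gru_forward(matrix(0, 11, 10), p, rnorm(13)), "channels")
  expect_error(gru_forward(sig, p), "feature vector required")
})

test_that("permuting the head rows permutes the output probabilities", {
  p <- gru_init(4, 1, seed = 3)
  sig <- matrix(rnorm(12 * 15), 12, 15)
  pr <- gru_forward(sig, p)
  perm <- c(3, 1, 4, 2)
  pp <- p
  pp$head$W <- p$head$W[perm, ]
  pp$head$b <- p$head$b[perm]
  expect_equal(unname(gru_forward(sig, pp)), unname(pr[perm]),
               tolerance = 1e-12)
})

test_that("smoothed cross-entropy matches its formula", {
  expect_equal(smoothed_cross_entropy(c(1, 0, 0, 0), 1, smoothing = 0), 0)
  for (s in c(0, 0.1, 0.2, 0.5)) {
    expect_equal(smoothed_cross_entropy(rep(0.25, 4), 2, s), log(4),
                 tolerance = 1e-12)
  }
  p <- c(0.7, 0.1, 0.1, 0.1)
  expect_equal(smoothed_cross_entropy(p, 1, 0.2),
               -(0.85 * log(0.7) + 3 * 0.05 * log(0.1)), tolerance = 1e-12)
  # zero probability with nonzero target weight: finite via the 1e-12 floor
  expect_true(is.finite(smoothed_cross_entropy(c(0, 1, 0, 0), 1, 0.2)))
  expect_error(smoothed_cross_entropy(p, 1, smoothing = 1), "smoothing")
})

test_that("training for zero epochs leaves the parameters untouched", {
  ds <- tiny_dataset(n = 8)
  p <- tiny_params()
  fit <- train_gru(ds, p, gru_train_config(batch_size = 4, stride = 10),
                   epochs = 0, seed = 1)
  expect_identical(fit$params$layers, p$layers)
  expect_identical(fit$params$head, p$head)
  expect_equal(nrow(fit$history), 0)
})

test_that("training is deterministic per seed and loss decreases", {
  ds <- tiny_dataset(n = 16)
  cfg <- gru_train_config(batch_size = 4, stride = 10)
  f1 <- train_gru(ds, tiny_params(), cfg, epochs = 3, seed = 7)
  f2 <- train_gru(ds, tiny_params(), cfg, epochs = 3, seed = 7)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
  f3 <- train_gru(ds, tiny_params(), cfg, epochs = 3, seed = 8)
  expect_false(identical(f3$params, f1$params))
  expect_lte(f1$history$train_loss[3], f1$history$train_loss[1] + 0.05)
})

test_that("tidy, glance and predict work on a fitted model", {
  ds <- tiny_dataset(n = 12)
  fit <- train_gru(ds, tiny_params(),
                   gru_train_config(batch_size = 4, stride = 10),
                   epochs = 2, seed = 1)
  expect_equal(nrow(tidy(fit)), 2)
  g <- glance(fit)
  expect_equal(g$epochs, 2)
  expect_equal(g$hidden_size, 4)
  cls <- predict(fit, ds)
  expect_s3_class(cls, "factor")
  expect_equal(levels(cls), ecg_classes)
  pr <- predict(fit, ds, type = "prob")
  expect_equal(rowSums(as.matrix(pr)), rep(1, 12), tolerance = 1e-9)
})
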