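make_scalar_params <- function(value) {
  # minimal parameter structure for aggregation arithmetic
  list(layers = list(list(W_z = matrix(value, 1, 1))),
       head = list(b = value))
}

test_that("federated averaging is the exact size-weighted mean", {
  p <- tiny_params()
  agg <- fedavg_aggregate(list(p, p, p), c(5, 1, 3))
  expect_equal(flatten_params_for_test(agg), flatten_params_for_test(p),
               tolerance = 1e-15)

  two <- fedavg_aggregate(list(make_scalar_params(0), make_scalar_params(4)),
                          c(1, 3))
  expect_equal(two$head$b, 3.0)
  expect_equal(two$layers[[1]]$W_z[1, 1], 3.0)

  set.seed(41)
  clients <- lapply(1:5, function(i) tiny_params(seed = i))
  sizes <- sample(1:50, 5)
  agg5 <- fedavg_aggregate(clients, sizes)
  w <- sizes / sum(sizes)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  oracle <- Reduce(`+`, Map(function(cl, wi) flatten_params_for_test(cl) * wi,
                            clients, w))
  expect_equal(flatten_params_for_test(agg5), oracle, tolerance = 1e-12)

  expect_error(fedavg_aggregate(list(), integer(0)), "no client")
  expect_error(fedavg_aggregate(list(tiny_params(), tiny_params(hidden = 3)),
                                c(1, 1)), "schemas differ")
})

test_that("aggregation preserves values shared by all clients", {
  clients <- lapply(1:4, function(i) tiny_params(seed = i))
  common <- matrix(0.5, 4, 4)
  for (i in seq_along(clients)) clients[[i]]$layers[[1]]$U_z <- common
  agg <- fedavg_aggregate(clients, c(2, 7, 1, 4))
  expect_equal(agg$layers[[1]]$U_z, common, tolerance = 1e-15)
})

test_that("zero local epochs return the global weights unchanged", {
  ds <- tiny_dataset(n = 6)
  p <- tiny_params()
  out <- local_train(ds, p, local_epochs = 0)
  expect_identical(out$weights, p)
  expect_equal(out$n, 6)
})

test_that("a single client with no DP reduces to centralized training", {
  ds <- tiny_dataset(n = 16)
  sp <- split_ecg(ds, seed = 1)
  part <- partition_clients(sp$train, 1, "iid", seed = 2)
  p <- tiny_params()
  cfg <- gru_train_config(batch_size = 4, stride = 10)
  master <- 99
  fl <- run_federated(sp, part, p, rounds = 1, local_epochs = 2,
                      config = cfg, seed = master)
  cent <- train_gru(sp$train, p, cfg, epochs = 2,
                    seed = derive_seed(master, 1, 1))
  expect_equal(flatten_params_for_test(fl$global_params),
               flatten_params_for_test(cent$params), tolerance = 1e-9)
})

test_that("personalization with zero epochs returns the global model", {
  ds <- tiny_dataset(n = 6)
  p <- tiny_params()
  expect_identical(personalize(ds, p, 0), p)
})

test_that("fine-tuning does not increase the client's local training loss", {
  ds <- tiny_dataset(n = 16, seed = 77)
  cfg <- gru_train_config(learning_rate = 1e-3, batch_size = 4, stride = 10)
  local_loss <- function(params) {
    probs <- fedecg:::gru_predict_probs(params, ds, stride = cfg$stride)
    y <- as.integer(factor(ds$label, levels = ecg_classes))
    mean(vapply(seq_len(nrow(ds)), function(i) {
      smoothed_cross_entropy(probs[i, ], y[i], cfg$label_smoothing)
    }, numeric(1)))
  }
  deltas <- vapply(1:3, function(s) {
    p <- tiny_params(seed = s)
    tuned <- personalize(ds, p, fine_tune_epochs = 2, config = cfg, seed = s)
    local_loss(tuned) - local_loss(p)
  }, numeric(1))
  expect_lte(mean(deltas), 0)
})

test_that("federated runs are deterministic and keep full history", {
  ds <- tiny_dataset(n = 20, seed = 55)
  sp <- split_ecg(ds, seed = 1)
  part <- partition_clients(sp$train, 2, "iid", seed = 2)
  p <- tiny_params()
  cfg <- gru_train_config(batch_size = 4, stride = 10)
  a <- run_federated(sp, part, p, rounds = 2, local_epochs = 1, config = cfg,
                     seed = 5)
  b <- run_federated(sp, part, p, rounds = 2, local_epochs = 1, config = cfg,
                     seed = 5)
  expect_identical(a$global_params, b$global_params)
  expect_equal(nrow(a$history[a$history$scope == "global", ]), 2)
  expect_s3_class(tidy(a), "tbl_df")
  expect_equal(glance(a)$rounds, 2)
})

test_that("only weights and sizes cross the client boundary", {
  ds <- tiny_dataset(n = 8)
  out <- local_train(ds, tiny_params(), local_epochs = 1,
                     config = gru_train_config(batch_size = 4, stride = 10))
  expect_named(out, c("weights", "n", "history"))
  expect_false(any(vapply(out, function(x) {
    is.data.frame(x) && "signal" %in% names(x)
  }, logical(1))))
})
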