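test_that("activation functions match their closed forms", {
  expect_identical(morlet(0), 1)
  expect_equal(morlet(1), exp(-0.5) * cos(5), tolerance = 1e-12)
  expect_lt(abs(morlet(1) - 0.17205), 1e-4)
  u <- seq(-4, 4, by = 0.37)
  expect_equal(morlet(u), morlet(-u))              # even function
  expect_identical(sigmoid(0), 0.5)
  expect_equal(sigmoid(u) + sigmoid(-u), rep(1, length(u)), tolerance = 1e-12)
  expect_gte(sigmoid(-500), 0)
  expect_true(is.finite(sigmoid(-500)) && is.finite(sigmoid(500)))
  expect_equal(sigmoid(500), 1)
})

test_that("forward pass follows the layer equations", {
  set.seed(1)
  model <- init_vgrf_model("morlet", K = 4, m = 1)
  x <- rnorm(101)
  # zero output weights and biases -> zero prediction
  m0 <- model; m0$W_out[] <- 0; m0$b_out[] <- 0
  expect_identical(unique(vgrf_forward(m0, x)), 0)
  # zero hidden weights, b = 0, a = 1 -> all z_k = morlet(0) = 1
  m1 <- model; m1$W_hidden[] <- 0; m1$b_shift[] <- 0; m1$a_scale[] <- 1
  expect_equal(vgrf_forward(m1, x), rowSums(m1$W_out) - m1$b_out,
               tolerance = 1e-12)
  expect_error(vgrf_forward(model, rnorm(50)),
               class = "imugrf_invalid_argument")
})

test_that("forward pass equals the independent scalar-loop oracle", {
  set.seed(2)
  for (act in c("morlet", "sigmoid")) {
    X <- matrix(rnorm(5 * 101, 10, 5), 5, 101)
    model <- init_vgrf_model(act, K = 3, m = 1, x = X)
    for (r in 1:5)
      expect_equal(vgrf_forward(model, X[r, ]), oracle_forward(model, X[r, ]),
                   tolerance = 1e-12)
    # batched forward equals the per-sample loop
    batch <- vgrf_forward(model, X)
    for (r in 1:5)
      expect_equal(batch[r, ], vgrf_forward(model, X[r, ]), tolerance = 1e-12)
  }
})

test_that("the loss combines per-point MSE with a full-parameter penalty", {
  set.seed(3)
  model <- init_vgrf_model("morlet", K = 2, m = 1)
  x <- rnorm(101); y <- vgrf_forward(model, x)
  expect_equal(vgrf_loss(model, x, y, lambda = 0), 0, tolerance = 1e-12)
  # constant 0.1 BW offset at every point -> data term 0.01
  expect_equal(vgrf_loss(model, x, y + 0.1, lambda = 0), 0.01,
               tolerance = 1e-12)
  # lambda * ||w||^2 with zero data error; the clamped a_k contribution is
  # part of the measured norm
  m2 <- model
  m2$W_hidden[] <- 0; m2$b_shift[] <- 0; m2$a_scale[] <- 1
  m2$W_out[] <- 0; m2$b_out[] <- 0; m2$W_out[1, 1] <- 2
  y2 <- vgrf_forward(m2, x)
  expect_equal(vgrf_loss(m2, x, y2, lambda = 0.01),
               0.01 * (4 + sum(m2$a_scale^2)), tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  for (act in c("morlet", "sigmoid")) {
    set.seed(4)
    X <- matrix(rnorm(6 * 101, 10, 5), 6, 101)
    Y <- matrix(runif(6 * 101, 0, 3), 6, 101)
    model <- init_vgrf_model(act, K = 5, m = 1, x = X, y = Y)
    expect_lt(check_gradients(model, X, Y, lambda = 0.01, n_check = 20), 1e-4)
  }
})

test_that("training descends, is seed deterministic, and clamps the scales", {
  set.seed(6)
  tr <- list(x = matrix(rnorm(30 * 101, 10, 5), 30, 101),
             y = matrix(rep(1.8, 30 * 101), 30, 101))
  cfg <- train_config(K = 1, epochs = 100, batch_size = 16, seed = 9)
  fit <- train_vgrf(tr, cfg, "morlet")
  expect_length(fit$history, 100L)
  expect_lt(tail(fit$history, 1), fit$history[1])
  expect_true(all(abs(fit$model$a_scale) >= 1e-3))
  fit2 <- train_vgrf(tr, cfg, "morlet")
  expect_identical(fit$model, fit2$model)
  expect_identical(fit$history, fit2$history)
})

test_that("dataset prediction is a vectorized forward pass", {
  set.seed(7)
  model <- init_vgrf_model("sigmoid", K = 4, m = 3)
  X <- matrix(rnorm(8 * 303, 5, 3), 8, 303)
  pred <- predict_dataset(model, list(x = X))
  expect_identical(dim(pred), c(8L, 101L))
  for (r in 1:8)
    expect_equal(pred[r, ], vgrf_forward(model, X[r, ]), tolerance = 1e-12)
  empty <- predict_dataset(model, list(x = matrix(numeric(0), 0, 303)))
  expect_identical(nrow(empty), 0L)
})

test_that("models round-trip through the JSON format", {
  set.seed(8)
  model <- init_vgrf_model("morlet", K = 3, m = 1)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_vgrf_model(model, tmp)
  back <- read_vgrf_model(tmp)
  x <- rnorm(101)
  expect_equal(vgrf_forward(back, x), vgrf_forward(model, x),
               tolerance = 1e-12)
  expect_identical(back$activation, "morlet")
})
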