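# Sequence classifier: shapes, stochasticity, loss, gradients, decoding,
# capacity and seeded reproducibility.

test_that("forward pass yields row-stochastic per-timestep probabilities", {
  m <- build_model(model_config(32, seed = 4))
  P <- model_forward(m, matrix(0, 50, 32))
  expect_equal(dim(P), c(50, 8))
  expect_equal(rowSums(P), rep(1, 50), tolerance = 1e-6)
  expect_true(all(P >= 0 & P <= 1))

  expect_error(model_forward(m, matrix(0, 10, 6)), "expects")
  expect_error(model_config(0), "positive")
})

test_that("initialization is seed-deterministic and near-uniform at the output", {
  m1 <- build_model(model_config(12, seed = 9))
  m2 <- build_model(model_config(12, seed = 9))
  expect_identical(m1$params, m2$params)
  m3 <- build_model(model_config(12, seed = 10))
  expect_false(identical(m3$params, m1$params))

  withr::with_seed(2, X <- matrix(rnorm(200 * 12), 200, 12))
  P <- model_forward(m1, X)
  expect_lt(abs(mean(apply(P, 1, max)) - 1 / 8), 0.15)
})

test_that("the biLSTM consumes future context: predictions depend on what follows", {
  m <- build_model(model_config(6, seed = 3))
  withr::with_seed(3, X <- matrix(rnorm(40 * 6), 40, 6))
  P1 <- model_forward(m, X)
  P2 <- model_forward(m, rbind(X, 5 + X))
  expect_false(isTRUE(all.equal(P1, P2[1:40, ], tolerance = 1e-6)))
})

test_that("cross-entropy loss matches its analytic anchors", {
  P <- matrix(1 / 8, 30, 8)
  y <- rep(0:7, length.out = 30)
  expect_equal(sequence_loss(P, y), log(8), tolerance = 1e-12)

  onehot <- diag(8)[y + 1, ]
  expect_equal(sequence_loss(pmax(onehot, 1e-12), y), 0, tolerance = 1e-8)

  expect_gt(sequence_loss(matrix(1 / 8, 10, 8), rep(3, 10)), 0)
  expect_error(sequence_loss(P, rep(9, 30)), "labels")
  expect_error(sequence_loss(P, rep(0, 29)), "length")
})

test_that("analytic gradients match finite differences in every layer", {
  set.seed(14)
  cfg <- model_config(3, gru_units = 4, bilstm_units = 5, n_classes = 3,
                      seed = 14)
  params <- sladl:::init_params(cfg)
  T_ <- 7; B <- 2
  X <- array(rnorm(3 * B * T_), c(3, B, T_))
  y <- matrix(sample(0:2, B * T_, TRUE), B, T_)
  mask <- matrix(1, B, T_)
  mask[2, 6:7] <- 0; y[2, 6:7] <- -1L
  res <- sladl:::model_gradient(params, X, y, mask, precise = TRUE)

  eps <- 1e-5
  for (nm in names(params)) {
    idx <- seq_len(min(length(params[[nm]]), 25))
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      lp <- sladl:::model_gradient(pp, X, y, mask, precise = TRUE)$loss
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      lm <- sladl:::model_gradient(pp, X, y, mask, precise = TRUE)$loss
      num <- (lp - lm) / (2 * eps)
      ana <- res$grads[[nm]][i]
      expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-6), 1e-4)
    }
  }
})

test_that("prediction is the per-timestep argmax with ties toward the lowest class", {
  m <- build_model(model_config(4, gru_units = 3, bilstm_units = 3, seed = 2))
  # zero readout -> exactly uniform probabilities -> everything ties to class 1
  m$params$fc_W[] <- 0
  m$params$fc_b[] <- 0
  pred <- predict(m, matrix(rnorm(60 * 4), 60, 4))
  expect_equal(as.character(unique(pred)), "WRL")

  # decoding agrees with an independent argmax of the probabilities
  m2 <- build_model(model_config(4, gru_units = 3, bilstm_units = 3, seed = 7))
  withr::with_seed(1, X <- matrix(rnorm(60 * 4), 60, 4))
  P <- model_forward(m2, X)
  oracle <- apply(P, 1, which.max)
  expect_equal(as.integer(predict(m2, X)), oracle)
})

test_that("the classifier masters a separable two-class sequence task quickly", {
  means <- list(c(2, -2), c(-2, 2))
  labs <- withr::with_seed(30, replicate(3, sample(rep(c(1, 2), 60)),
                                         simplify = FALSE))
  train <- list(toy_features(labs[[1]], means, seed = 1),
                toy_features(labs[[2]], means, seed = 2))
  val <- toy_features(labs[[3]], means, seed = 3)
  cfg <- training_config(grace_iters = 47, patience = 2, repeats = 1,
                         max_iters = 50, base_seed = 1)
  r <- train_fold(train, val, cfg, repeat_seed = 123)
  expect_gte(r$val_accuracy, 0.99)
  expect_lte(length(r$val_acc_trace), 50)
})

test_that("training is reproducible for a fixed repeat seed", {
  feats <- tiny_features(4)
  cfg <- training_config(grace_iters = 2, patience = 1, repeats = 1,
                         max_iters = 5, base_seed = 1)
  r1 <- train_fold(feats[1:2], feats[[3]], cfg, repeat_seed = 77)
  r2 <- train_fold(feats[1:2], feats[[3]], cfg, repeat_seed = 77)
  expect_identical(r1$val_acc_trace, r2$val_acc_trace)
  expect_identical(r1$stopped_at_iter, r2$stopped_at_iter)
  expect_identical(r1$model$params, r2$model$params)
})
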