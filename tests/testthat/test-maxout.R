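test_that("maxout_forward matches a brute-force loop over units and pieces", {
  set.seed(21)
  for (trial in 1:20) {
    d <- sample(2:5, 1); m <- sample(1:4, 1); k <- sample(1:4, 1)
    params <- list(W = array(rnorm(d * m * k), dim = c(d, m, k)),
                   b = matrix(rnorm(m * k), m, k))
    x <- rnorm(d)
    h <- maxout_forward(x, params)
    brute <- vapply(seq_len(m), function(i) {
      max(vapply(seq_len(k), function(j) {
        sum(x * params$W[, i, j]) + params$b[i, j]
      }, numeric(1)))
    }, numeric(1))
    expect_equal(h, brute, tolerance = 1e-12)
  }
})

test_that("maxout with k = 1 is a plain affine map", {
  set.seed(22)
  d <- 4; m <- 3
  params <- list(W = array(rnorm(d * m), dim = c(d, m, 1)),
                 b = matrix(rnorm(m), m, 1))
  x <- rnorm(d)
  expect_equal(maxout_forward(x, params),
               drop(x %*% params$W[, , 1]) + params$b[, 1],
               tolerance = 1e-12)
})

test_that("identical pieces collapse to a single affine map", {
  set.seed(23)
  d <- 3; m <- 2; k <- 4
  W1 <- matrix(rnorm(d * m), d, m); b1 <- rnorm(m)
  params <- list(W = array(rep(W1, k), dim = c(d, m, k)),
                 b = matrix(rep(b1, k), m, k))
  x <- rnorm(d)
  expect_equal(maxout_forward(x, params), drop(x %*% W1) + b1,
               tolerance = 1e-12)
})

test_that("maxout output is convex in the input", {
  set.seed(24)
  d <- 5; m <- 3; k <- 3
  params <- list(W = array(rnorm(d * m * k), dim = c(d, m, k)),
                 b = matrix(rnorm(m * k), m, k))
  for (trial in 1:30) {
    x1 <- rnorm(d); x2 <- rnorm(d)
    mid <- maxout_forward((x1 + x2) / 2, params)
    avg <- (maxout_forward(x1, params) + maxout_forward(x2, params)) / 2
    expect_true(all(mid <= avg + 1e-12))
  }
})

test_that("adding pieces never lowers the activation", {
  set.seed(25)
  d <- 4; m <- 2; k <- 4
  W <- array(rnorm(d * m * k), dim = c(d, m, k))
  b <- matrix(rnorm(m * k), m, k)
  x <- rnorm(d)
  full <- maxout_forward(x, list(W = W, b = b))
  sub <- maxout_forward(x, list(W = W[, , 1:2, drop = FALSE],
                                b = b[, 1:2, drop = FALSE]))
  expect_true(all(full >= sub - 1e-12))
})

test_that("presets carry the published hyperparameters", {
  bac <- preset_bacteria()
  expect_equal(bac$hidden_dims, c(500L, 800L, 800L))
  expect_equal(bac$maxout_units, 3L)
  expect_equal(bac$dropout, 0.2)
  expect_true(bac$batch_norm)
  expect_equal(bac$learning_rate, 0.01)
  expect_equal(bac$batch_size, 16L)
  expect_equal(bac$max_epochs, 100L)
  expect_equal(bac$patience, 30L)
  euk <- preset_eukaryote()
  expect_equal(euk$hidden_dims, c(500L, 800L, 800L))
  expect_equal(euk$maxout_units, 4L)
  expect_equal(euk$batch_size, 32L)
  expect_equal(euk$max_epochs, 300L)
})

test_that("an untrained model with zero-init output scores everything 0.5", {
  cfg <- model_config(hidden_dims = c(8), maxout_units = 2, seed = 1)
  model <- build_model(cfg, input_dim = 6, n_labels = 4)
  p <- predict(model, rep(0, 6))
  expect_equal(unname(drop(p)), rep(0.5, 4))
  # identical rows give identical score vectors
  X <- matrix(rnorm(12), 2, 6, byrow = FALSE)
  X[2, ] <- X[1, ]
  model2 <- train_maxout(model_config(hidden_dims = c(8), maxout_units = 2,
                                      max_epochs = 3, patience = 3,
                                      validation_fraction = 0, seed = 2),
                         matrix(rnorm(60), 10, 6),
                         matrix(rbinom(40, 1, 0.3), 10, 4))
  p2 <- predict(model2, X)
  expect_equal(p2[1, ], p2[2, ])
})

test_that("an empty hidden stack trains as logistic regression", {
  set.seed(26)
  X <- matrix(rnorm(80), 40, 2)
  y <- cbind(as.integer(X[, 1] > 0))
  cfg <- model_config(hidden_dims = integer(0), maxout_units = 1,
                      dropout = 0, batch_norm = FALSE,
                      learning_rate = 0.5, batch_size = 8,
                      max_epochs = 50, patience = 50,
                      validation_fraction = 0, seed = 3)
  model <- train_maxout(cfg, X, y)
  expect_gt(aupr(y, drop(predict(model, X))), 0.95)
})

test_that("training on a separable fixture drives loss down and AUPR to 1", {
  set.seed(27)
  n <- 60
  X <- cbind(rep(c(1, 0), each = n / 2), rep(c(0, 1), each = n / 2)) +
    matrix(rnorm(2 * n, sd = 0.05), n, 2)
  Y <- cbind(rep(c(1, 0), each = n / 2), rep(c(0, 1), each = n / 2))
  cfg <- model_config(hidden_dims = c(8), maxout_units = 2, dropout = 0,
                      batch_norm = FALSE, learning_rate = 0.3,
                      batch_size = 8, max_epochs = 40, patience = 40,
                      seed = 4)
  model <- train_maxout(cfg, X, Y)
  expect_true(all(diff(model$history$loss[1:5]) < 0))
  expect_equal(max(model$history$val_aupr, na.rm = TRUE), 1.0)
})

test_that("patience 0 stops after the first non-improving epoch", {
  set.seed(28)
  X <- matrix(rnorm(40), 20, 2)
  # all-positive validation labels pin the validation AUPR at 1 from epoch
  # one, so no later epoch can improve it: a constructed plateau
  Y <- matrix(1L, 20, 2)
  cfg <- model_config(hidden_dims = c(4), maxout_units = 2, dropout = 0,
                      batch_norm = FALSE, learning_rate = 0.1,
                      batch_size = 8, max_epochs = 50, patience = 0,
                      seed = 5)
  model <- train_maxout(cfg, X, Y)
  expect_equal(nrow(model$history), 2L)  # 1 improving + 1 non-improving
  expect_equal(model$best_epoch, 1L)
})

test_that("early stopping fires after exactly `patience` flat epochs", {
  set.seed(29)
  X <- matrix(rnorm(40), 20, 2)
  Y <- matrix(1L, 20, 2)
  for (pat in c(2L, 5L)) {
    cfg <- model_config(hidden_dims = c(4), maxout_units = 2, dropout = 0,
                        batch_norm = FALSE, learning_rate = 0.1,
                        batch_size = 8, max_epochs = 50, patience = pat,
                        seed = 6)
    model <- train_maxout(cfg, X, Y)
    expect_equal(nrow(model$history), pat + 1L)
  }
})

test_that("training is bit-reproducible under a fixed seed", {
  set.seed(30)
  X <- matrix(rnorm(200), 40, 5)
  Y <- matrix(rbinom(120, 1, 0.3), 40, 3)
  cfg <- model_config(hidden_dims = c(8), maxout_units = 3, dropout = 0.2,
                      batch_norm = TRUE, learning_rate = 0.1,
                      batch_size = 8, max_epochs = 6, patience = 6,
                      seed = 7)
  m1 <- suppressWarnings(train_maxout(cfg, X, Y))
  m2 <- suppressWarnings(train_maxout(cfg, X, Y))
  expect_identical(m1$history, m2$history)
  expect_identical(predict(m1, X), predict(m2, X))
})

test_that("a planted-function fixture is recovered above prevalence", {
  set.seed(31)
  n <- 80; d <- 10
  X <- matrix(rnorm(n * d), n, d)
  Y <- cbind(as.integer(X[, 1] + X[, 2] > 0.5),
             as.integer(X[, 3] > 0.8))
  cfg <- model_config(hidden_dims = c(16), maxout_units = 2, dropout = 0,
                      batch_norm = TRUE, learning_rate = 0.2,
                      batch_size = 16, max_epochs = 60, patience = 60,
                      validation_fraction = 0, seed = 8)
  model <- train_maxout(cfg, X, Y)
  got <- macro_micro_aupr(Y, predict(model, X))$macro
  expect_gt(got, prevalence_macro_aupr(Y) + 0.2)
})

test_that("dimension mismatches are fatal", {
  cfg <- model_config(hidden_dims = c(4), maxout_units = 2, seed = 1)
  model <- build_model(cfg, input_dim = 5, n_labels = 2)
  expect_error(predict(model, matrix(0, 2, 4)), "dimension")
  params <- list(W = array(0, dim = c(3, 2, 2)), b = matrix(0, 2, 2))
  expect_error(maxout_forward(rnorm(4), params), "dimension")
})
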