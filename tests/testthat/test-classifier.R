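toy_model <- function(d = 4, h = 10, seed = 1) {
  mlp_init(input_size = d, hidden_size = h, seed = seed)
}

test_that("initialization is seeded and counts parameters correctly", {
  a <- toy_model(seed = 5); b <- toy_model(seed = 5)
  expect_identical(a$W1, b$W1)
  expect_identical(a$w2, b$w2)
  expect_false(identical(a$W1, toy_model(seed = 6)$W1))
  expect_true(all(a$b1 == 0) && a$b2 == 0 && a$out_bias == 0)

  # stored parameters enumerate to the closed-form count
  expect_equal(length(a$W1) + length(a$b1) + length(a$w2) + 1,
               n_parameters(a))
  big <- mlp_init()  # 1285 x 1285 x 1
  expect_equal(n_parameters(big), (1285 + 1) * 1285 + (1285 + 1))

  zero <- mlp_init(input_size = 4, hidden_size = 3, init_scale = 0)
  expect_equal(predict(zero, matrix(rnorm(8), 2)), c(0.5, 0.5))
})

test_that("forward pass matches a hand computation on a 3-unit network", {
  m <- mlp_init(input_size = 2, hidden_size = 3, seed = 1)
  m$W1 <- matrix(c(0.2, -0.1, 0.4, 0.3, 0.5, -0.6), nrow = 3)
  m$b1 <- c(0.1, 0, -0.2)
  m$w2 <- c(1, -2, 0.5)
  m$b2 <- 0.3
  x <- c(0.7, -1.2)
  h <- 1 / (1 + exp(-(m$W1 %*% x + m$b1)))
  want <- 1 / (1 + exp(-(sum(m$w2 * h) + m$b2 + m$out_bias)))
  expect_equal(predict(m, x), as.numeric(want), tolerance = 1e-12)

  # output bias is monotone in the prediction
  m2 <- m; m2$out_bias <- 1
  expect_gt(predict(m2, x), predict(m, x))
  expect_error(predict(m, c(1, 2, 3)), "feature columns")
})

test_that("backprop gradients match central finite differences", {
  eps <- 1e-6
  for (loss in c("cross_entropy", "squared")) {
    m <- toy_model(d = 6, h = 10, seed = 3)
    withr::with_seed(4, {x <- rnorm(6); y <- 1})
    g <- mlp_gradient(m, x, y, loss)
    loss_at <- function(model) {
      p <- predict(model, x)
      if (loss == "cross_entropy") -(y * log(p) + (1 - y) * log(1 - p)) else {
        0.5 * (p - y)^2
      }
    }
    check <- function(get, set, grad) {
      for (i in seq_len(min(25, length(grad)))) {
        mp <- set(m, i, get(m, i) + eps); mm <- set(m, i, get(m, i) - eps)
        fd <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
        expect_lt(abs(fd - grad[i]) / max(abs(fd), 1e-8), 1e-5)
      }
    }
    check(function(m, i) m$W1[i], function(m, i, v) {m$W1[i] <- v; m},
          as.numeric(g$gW1))
    check(function(m, i) m$b1[i], function(m, i, v) {m$b1[i] <- v; m},
          as.numeric(g$gb1))
    check(function(m, i) m$w2[i], function(m, i, v) {m$w2[i] <- v; m},
          as.numeric(g$gw2))
    check(function(m, i) m$b2, function(m, i, v) {m$b2 <- v; m}, g$gb2)
  }
})

test_that("SGD training separates a linearly separable toy set", {
  withr::with_seed(9, {
    n <- 60
    X <- cbind(runif(n, 0, 1), runif(n, 0, 1))
    y <- as.numeric(X[, 1] + X[, 2] > 1)
  })
  # independent check that the problem is solvable by a convex reference fit
  ref <- suppressWarnings(
    stats::glm(y ~ X, family = stats::binomial()))
  expect_gte(mean((stats::predict(ref, type = "response") > 0.5) == y), 1)

  m <- mlp_init(input_size = 2, hidden_size = 10, seed = 2)
  m <- mlp_train(m, X, y, train_config(epochs = 100, learning_rate = 0.5,
                                       seed = 3))
  acc <- mean((predict(m, X) >= 0.5) == y)
  expect_equal(acc, 1)
  expect_lt(tail(m$loss_trace, 1), m$loss_trace[1])
  expect_length(m$loss_trace, 100)
})

test_that("training is deterministic and counts epochs exactly", {
  withr::with_seed(1, {X <- matrix(rnorm(40), 10); y <- rep(0:1, 5)})
  cfg <- train_config(epochs = 5, seed = 7)
  a <- mlp_train(toy_model(), X, y, cfg)
  b <- mlp_train(toy_model(), X, y, cfg)
  expect_identical(a$W1, b$W1)
  expect_identical(a$loss_trace, b$loss_trace)

  one <- mlp_train(toy_model(), X, y, train_config(epochs = 1, seed = 7))
  expect_length(one$loss_trace, 1)
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(mlp_train(toy_model(), X[0, , drop = FALSE], numeric(0)),
               "empty")
})

test_that("non-finite loss aborts with a diagnostic", {
  X <- matrix(c(NaN, 1, 2, 3, 4, 5, 6, 7), 2)
  expect_error(mlp_train(toy_model(), X, c(0, 1), train_config(epochs = 2)),
               "diverged|non-finite")
})

test_that("classification threshold is inclusive and configurable", {
  m <- toy_model()
  expect_equal(mlp_classify(m, c(0.5, 0.49, 0.51)),
               c("swallow", "non_swallow", "swallow"))
  m$decision_threshold <- 0
  expect_true(all(mlp_classify(m, runif(10)) == "swallow"))
  expect_error(mlp_classify(m, 1.2), "0, 1")
})

test_that("models survive a save/load round trip and tidy/glance work", {
  withr::with_seed(1, {X <- matrix(rnorm(40), 10); y <- rep(0:1, 5)})
  m <- mlp_train(toy_model(), X, y, train_config(epochs = 3, seed = 1))
  path <- withr::local_tempfile(fileext = ".rds")
  save_mlp(m, path)
  back <- load_mlp(path)
  expect_identical(back$W1, m$W1)
  expect_equal(predict(back, X), predict(m, X))

  td <- tidy(m)
  expect_equal(td$epoch, 1:3)
  expect_equal(td$mean_loss, m$loss_trace)
  gl <- glance(m)
  expect_equal(gl$epochs_trained, 3)
  expect_equal(gl$n_parameters, n_parameters(m))
})
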