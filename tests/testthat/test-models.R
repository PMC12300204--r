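test_that("model specs pin the two architectures", {
  spec <- model_spec("lstm", num_labels = 14)
  expect_equal(spec$lstm_units, 64)
  expect_equal(spec$dropout_rate, 0.5)

  dspec <- model_spec("dense", num_labels = 14)
  expect_equal(dspec$dense_hidden, c(100, 75, 50))

  expect_error(model_spec("lstm", num_labels = 1),
               class = "gazeid_validation_error")
  expect_error(train_config(epochs = 0), class = "gazeid_validation_error")
})

test_that("built models have the specified shapes and softmax outputs", {
  spec <- model_spec("lstm", num_labels = 14, lstm_units = 8, timesteps = 20)
  m <- build_model(spec, seed = 1)
  expect_equal(dim(m$params$l1$W), c(7, 32))
  expect_equal(dim(m$params$l2$U), c(8, 32))
  expect_equal(dim(m$params$Wo), c(8, 14))

  X <- array(rnorm(5 * 20 * 7), dim = c(5, 20, 7))
  p <- predict_proba(m, X)
  expect_equal(dim(p), c(5, 14))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-9)
  expect_true(all(p >= 0))

  dspec <- model_spec("dense", num_labels = 14)
  dm <- build_model(dspec, seed = 1)
  # exactly three hidden layers sized 100/75/50 plus the output layer
  expect_length(dm$params$layers, 4)
  expect_equal(vapply(dm$params$layers, function(l) ncol(l$W), numeric(1)),
               c(100, 75, 50, 14))
  pd <- predict_proba(dm, matrix(rnorm(3 * 16), 3, 16))
  expect_equal(rowSums(pd), rep(1, 3), tolerance = 1e-9)

  # zeroed final layer gives the uniform distribution
  dm$params$layers[[4]]$W[] <- 0
  dm$params$layers[[4]]$b[] <- 0
  pu <- predict_proba(dm, matrix(rnorm(2 * 16), 2, 16))
  expect_equal(pu, matrix(1 / 14, 2, 14), tolerance = 1e-12)

  expect_error(predict_proba(m, matrix(0, 2, 16)),
               class = "gazeid_validation_error")
})

test_that("analytic gradients match finite differences (LSTM and dense)", {
  set.seed(4)
  spec <- model_spec("lstm", num_labels = 2, lstm_units = 3, timesteps = 6,
                     input_channels = 2)
  m <- build_model(spec, seed = 7)
  X <- array(rnorm(4 * 6 * 2), dim = c(4, 6, 2))
  Y <- gazeid:::one_hot(c(1, 2, 1, 2), 2)
  loss_fn <- function(p) {
    fw <- gazeid:::lstm_net_forward(p, X)
    -mean(log(pmax(rowSums(fw$probs * Y), 1e-12)))
  }
  g <- gazeid:::lstm_net_gradient(m$params, X, Y)
  eps <- 1e-5
  check <- function(get, set, analytic) {
    for (i in seq_len(min(4, length(get(m$params))))) {
      p1 <- set(m$params, i, eps)
      p2 <- set(m$params, i, -eps)
      num <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
      expect_equal(analytic[i], num, tolerance = 1e-5)
    }
  }
  for (nm in c("Wd", "bd", "Wo", "bo")) {
    check(function(p) p[[nm]],
          function(p, i, e) { p[[nm]][i] <- p[[nm]][i] + e; p },
          g$grads[[nm]])
  }
  for (ly in c("l1", "l2")) {
    for (pn in c("W", "U", "b")) {
      check(function(p) p[[ly]][[pn]],
            function(p, i, e) { p[[ly]][[pn]][i] <- p[[ly]][[pn]][i] + e; p },
            g$grads[[ly]][[paste0("d", pn)]])
    }
  }

  dspec <- model_spec("dense", num_labels = 3, input_dim = 5,
                      dense_hidden = c(6, 4, 3))
  dm <- build_model(dspec, seed = 8)
  Xd <- matrix(rnorm(4 * 5), 4, 5)
  Yd <- gazeid:::one_hot(c(1, 2, 3, 1), 3)
  gd <- gazeid:::mlp_gradient(dm$params, Xd, Yd)
  dloss <- function(p) {
    -mean(log(pmax(rowSums(gazeid:::mlp_forward(p, Xd)$probs * Yd), 1e-12)))
  }
  for (li in 1:4) {
    for (i in 1:3) {
      p1 <- dm$params; p1$layers[[li]]$W[i] <- p1$layers[[li]]$W[i] + eps
      p2 <- dm$params; p2$layers[[li]]$W[i] <- p2$layers[[li]]$W[i] - eps
      num <- (dloss(p1) - dloss(p2)) / (2 * eps)
      expect_equal(gd$grads$layers[[li]]$W[i], num, tolerance = 1e-5)
    }
  }
})

test_that("training validates inputs and runs the exact epoch budget", {
  spec <- model_spec("dense", num_labels = 3, input_dim = 4,
                     dense_hidden = c(5, 4, 3))
  m <- build_model(spec, seed = 1)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- rep(1:3, 10)

  tm <- train_model(m, X, y, train_config(epochs = 7, seed = 2))
  expect_length(tm$loss_trace, 7) # exactly the budget, no early stopping
  expect_true(tm$trained)

  expect_error(train_model(m, X, rep(1:2, 15), train_config(epochs = 1)),
               class = "gazeid_validation_error") # class 3 absent
  expect_error(train_model(m, X, y[1:10], train_config(epochs = 1)),
               class = "gazeid_validation_error")
})

test_that("training is reproducible under a fixed seed", {
  spec <- model_spec("dense", num_labels = 2, input_dim = 3,
                     dense_hidden = c(4, 3, 2))
  X <- matrix(rnorm(20 * 3), 20, 3)
  y <- rep(1:2, 10)
  t1 <- train_model(build_model(spec, seed = 5), X, y,
                    train_config(epochs = 5, seed = 9))
  t2 <- train_model(build_model(spec, seed = 5), X, y,
                    train_config(epochs = 5, seed = 9))
  expect_identical(t1$loss_trace, t2$loss_trace)
  expect_identical(t1$params, t2$params)

  sspec <- model_spec("lstm", num_labels = 2, lstm_units = 4, timesteps = 8,
                      input_channels = 2)
  Xs <- array(rnorm(10 * 8 * 2), dim = c(10, 8, 2))
  ys <- rep(1:2, 5)
  s1 <- train_model(build_model(sspec, seed = 5), Xs, ys,
                    train_config(epochs = 3, seed = 9))
  s2 <- train_model(build_model(sspec, seed = 5), Xs, ys,
                    train_config(epochs = 3, seed = 9))
  expect_identical(s1$loss_trace, s2$loss_trace)
})

test_that("the dense model masters a separable 3-class problem quickly", {
  set.seed(11)
  n <- 60
  y <- rep(1:3, n / 3)
  X <- matrix(rnorm(n * 16, sd = 0.3), n, 16)
  X[, 1] <- X[, 1] + c(0, 3, 6)[y]
  spec <- model_spec("dense", num_labels = 3)
  m <- train_model(build_model(spec, seed = 1), X, y,
                   train_config(epochs = 50, seed = 2))
  acc <- mean(apply(predict_proba(m, X), 1, which.max) == y)
  expect_gte(acc, 0.95)
  expect_lt(tail(m$loss_trace, 1), m$loss_trace[1]) # loss actually decreased
})

test_that("the LSTM learns a separable sequence problem", {
  set.seed(12)
  n <- 45
  y <- rep(1:3, n / 3)
  X <- array(rnorm(n * 20 * 7, sd = 0.1), dim = c(n, 20, 7))
  for (i in seq_len(n)) X[i, , 1] <- X[i, , 1] + c(0.2, 0.5, 0.8)[y[i]]
  spec <- model_spec("lstm", num_labels = 3, timesteps = 20)
  m <- train_model(build_model(spec, seed = 1), X, y,
                   train_config(epochs = 30, seed = 2))
  acc <- mean(apply(predict_proba(m, X), 1, which.max) == y)
  expect_gte(acc, 0.9)
})
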