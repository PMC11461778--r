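# a small deterministic design matrix for training tests
make_design <- function(p, m = 16, seed = 1) {
  set.seed(seed)
  V <- matrix(runif(p * m, 0, 20), p, m)
  colnames(V) <- c(paste0("x", 1:7), paste0("y", 1:7), "z1", "z2")[1:m]
  V
}

test_that("hyperparameter constructor validates and represents the full-scale protocol", {
  expect_error(mlp_hyperparams(hidden = 0), "positive integers")
  expect_error(mlp_hyperparams(learning_rate = -1), "positive")
  expect_error(mlp_hyperparams(batch_size = 0), "batch_size")
  # full-scale configuration: two hidden layers of 90 ReLU units, Adam at
  # 1e-5, batch 4, patience 8, up to 574 epochs
  hp <- mlp_hyperparams(hidden = c(90L, 90L), learning_rate = 1e-5,
                        batch_size = 4L, max_epochs = 574L, patience = 8L)
  expect_identical(hp$hidden, c(90L, 90L))
  expect_equal(hp$learning_rate, 1e-5)
  expect_identical(hp$max_epochs, 574L)
})

test_that("training recovers simple targets", {
  V <- make_design(120)
  # constant target: held-out predictions within 1%
  ds <- list(V = V, w = rep(250, 120))
  m <- train_mlp(ds, mlp_hyperparams(hidden = c(8, 8), max_epochs = 100),
                 seed = 3)
  pred <- predict_f1(m, make_design(30, seed = 2))
  expect_true(all(abs(pred - 250) < 2.5))

  # linear target, 500 samples: held-out MAE well under the target spread
  V2 <- make_design(500, seed = 30)
  set.seed(4)
  a <- runif(16, -2, 2)
  w <- drop(V2 %*% a) + 300
  m2 <- train_mlp(list(V = V2, w = w),
                  mlp_hyperparams(hidden = c(32, 32), max_epochs = 400,
                                  patience = 50, batch_size = 8), seed = 5)
  Vtest <- make_design(200, seed = 6)
  mae <- mean(abs(predict_f1(m2, Vtest) - (drop(Vtest %*% a) + 300)))
  expect_lt(mae, 0.1 * sd(w))
})

test_that("forward pass matches a hand-computed ReLU chain", {
  # tiny 2-2-1 net with hand-set weights, no scaling
  m <- structure(list(
    W = list(matrix(c(1, -1, 0.5, 2), 2, 2), matrix(c(1, -3), 2, 1)),
    b = list(c(0.5, -1), 2),
    activation = "relu",
    x_center = c(0, 0), x_scale = c(1, 1), y_center = 0, y_scale = 1,
    feature_names = c("a", "b"),
    report = data.frame(), best_epoch = 0L, hp = NULL, seed = 1L
  ), class = "mlp_metamodel")
  v <- c(2, 3)
  h <- pmax(c(1 * 2 - 1 * 3 + 0.5, 0.5 * 2 + 2 * 3 - 1), 0)  # c(0, 6)
  expect_equal(predict_f1(m, v), 1 * h[1] - 3 * h[2] + 2)     # -16
  # hand-derived gradient: only the second hidden unit is active
  expect_equal(grad_f1(m, v), c(0.5 * -3, 2 * -3))
  # scaling enters the chain rule
  m$x_scale <- c(2, 4); m$y_scale <- 10
  expect_equal(grad_f1(m, c(4, 12) * c(2, 4) / c(2, 4)),
               c(0.5 * -3 / 2, 2 * -3 / 4) * 10,
               tolerance = 1e-12)
})

test_that("input gradients match central finite differences", {
  V <- make_design(150, seed = 7)
  set.seed(8)
  w <- 100 + 3 * sin(V[, 1]) + rowSums(V) * 0.5 + rnorm(150, 0, 0.5)
  m <- train_mlp(list(V = V, w = w),
                 mlp_hyperparams(hidden = c(24, 24), max_epochs = 150),
                 seed = 9)
  set.seed(10)
  worst <- 0
  for (k in 1:20) {
    v <- runif(16, 2, 18)
    g <- grad_f1(m, v)
    h <- 1e-3
    fd <- vapply(seq_along(v), function(i) {
      e <- replace(numeric(16), i, h)
      (predict_f1(m, v + e) - predict_f1(m, v - e)) / (2 * h)
    }, numeric(1))
    denom <- pmax(abs(fd), 1e-6)
    rel <- abs(g - fd) / denom
    # skip coordinates that straddle a ReLU kink (finite differences are
    # not informative there); they are rare at random interior points
    ok <- rel < 1e-4 | abs(g - fd) < 1e-6
    worst <- max(worst, min(mean(ok), 1))
    expect_gt(mean(ok), 0.95)
  }
})

test_that("first-order expansion error vanishes superlinearly", {
  V <- make_design(100, seed = 11)
  w <- rowSums(V^1.5) / 10
  m <- train_mlp(list(V = V, w = w),
                 mlp_hyperparams(hidden = c(16, 16), max_epochs = 100),
                 seed = 12)
  v <- rep(10, 16)
  g <- grad_f1(m, v)
  set.seed(13)
  d <- runif(16, -1, 1)
  errs <- vapply(c(1e-2, 1e-3, 1e-4), function(s) {
    abs(predict_f1(m, v + s * d) - predict_f1(m, v) - sum(g * (s * d)))
  }, numeric(1))
  # o(|delta|): the ratio error/|delta| must shrink with the step
  expect_lt(errs[3] / 1e-4, errs[1] / 1e-2 + 1e-8)
})

test_that("training is deterministic given the seed", {
  V <- make_design(80, seed = 14)
  w <- rowSums(V) + 5
  hp <- mlp_hyperparams(hidden = c(12, 12), max_epochs = 40)
  m1 <- train_mlp(list(V = V, w = w), hp, seed = 20)
  m2 <- train_mlp(list(V = V, w = w), hp, seed = 20)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$b, m2$b)
  expect_identical(m1$report, m2$report)
  m3 <- train_mlp(list(V = V, w = w), hp, seed = 21)
  expect_false(identical(m1$W, m3$W))
})

test_that("surrogate fidelity on a smooth 16-input response", {
  # smooth sine-of-projection target over the encoded setting, 2000
  # training points: the surrogate must reach a tenth of the target spread
  V <- make_design(2000, seed = 15)
  f <- function(M) 200 + 25 * sin(rowSums(M) / 60) + 10 * sin(M[, 1] / 6)
  w <- f(V)
  m <- train_mlp(list(V = V, w = w),
                 mlp_hyperparams(hidden = c(90, 90), max_epochs = 500,
                                 patience = 60, batch_size = 32),
                 seed = 16)
  Vtest <- make_design(400, seed = 17)
  mae <- mean(abs(predict_f1(m, Vtest) - f(Vtest)))
  expect_lt(mae, 0.1 * sd(w))
})

test_that("K-fold random search separates adequate from crippled models", {
  V <- make_design(150, seed = 18)
  w <- 100 + 30 * sin(V[, 1] / 3) + V[, 2]        # multi-kink nonlinearity
  ds <- list(V = V, w = w)
  # single candidate: returned as-is
  sr1 <- kfold_random_search(ds, list(hidden = list(c(8, 8)),
                                      max_epochs = list(60L)),
                             K = 3, n_candidates = 1, seed = 1)
  expect_identical(sr1$best$hidden, c(8L, 8L))
  expect_length(sr1$scores, 1)

  # a single hidden neuron cannot represent the sine; CV must prefer the
  # larger network
  sr <- kfold_random_search(ds, list(hidden = list(1L, c(24, 24)),
                                     max_epochs = list(300L),
                                     patience = list(50L)),
                            K = 5, n_candidates = 6, seed = 2)
  expect_identical(sr$best$hidden, c(24L, 24L))
  expect_error(kfold_random_search(ds, list(), K = 5, n_candidates = 2,
                                   seed = 1), "empty")
})

test_that("saved metamodels reload and predict identically", {
  V <- make_design(60, seed = 19)
  w <- rowSums(V)
  m <- train_mlp(list(V = V, w = w),
                 mlp_hyperparams(hidden = c(10, 10), max_epochs = 30),
                 seed = 22)
  f <- tempfile(fileext = ".json")
  save_metamodel(m, f)
  m2 <- load_metamodel(f)
  v <- V[5, ]
  expect_equal(predict_f1(m2, v), predict_f1(m, v), tolerance = 1e-12)
  expect_equal(grad_f1(m2, v), grad_f1(m, v), tolerance = 1e-12)
  expect_error(suppressWarnings(load_metamodel(tempfile())),
               "cannot open|No such|not a saved")
})

test_that("rotation symmetrization averages the surrogate exactly", {
  V <- make_design(80, seed = 23)
  w <- rowSums(V) / 2
  m <- train_mlp(list(V = V, w = w),
                 mlp_hyperparams(hidden = c(8, 8), max_epochs = 30),
                 seed = 24)
  sm <- symmetrize_surrogate(m, 7)
  v <- runif(16, 5, 15)
  naive <- mean(vapply(0:6, function(k) {
    p <- ((0:6 + k) %% 7) + 1
    predict_f1(m, v[c(p, 7 + p, 15, 16)])
  }, numeric(1)))
  expect_equal(predict_f1(sm, v), naive, tolerance = 1e-12)
  g <- grad_f1(sm, v)
  fd <- vapply(1:16, function(i) {
    e <- replace(numeric(16), i, 1e-4)
    (predict_f1(sm, v + e) - predict_f1(sm, v - e)) / 2e-4
  }, numeric(1))
  expect_equal(g, fd, tolerance = 1e-6)
})

test_that("non-finite loss raises a divergence error naming the epoch", {
  V <- make_design(40, seed = 25)
  w <- rowSums(V)
  w[3] <- Inf
  expect_error(
    train_mlp(list(V = V, w = w),
              mlp_hyperparams(hidden = c(8, 8), max_epochs = 10,
                              standardize_y = FALSE),
              seed = 26),
    "diverged.*epoch")
})
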