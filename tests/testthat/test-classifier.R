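# A tiny linearly separable image-pair corpus: three class prototypes over
# d binary features with a few bit flips per sample.
separable_fixture <- function(n_per = 150L, d = 500L, flips = 8L,
                              seed = 1L) {
  set.seed(seed)
  proto <- matrix(rbinom(3L * d, 1, 0.15), 3L, d)
  mk <- function(cl) t(vapply(seq_len(n_per), function(i) {
    v <- proto[cl, ]
    fl <- sample.int(d, flips)
    v[fl] <- 1L - v[fl]
    v
  }, numeric(d)))
  X <- rbind(mk(1L), mk(2L), mk(3L))
  list(traj_x = Matrix::Matrix(X, sparse = TRUE),
       speed_x = Matrix::Matrix(X[, sample.int(d)], sparse = TRUE),
       y = rep(COG_CLASSES, each = n_per))
}

test_that("softmax is a stable exponential normalization", {
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  # shift invariance
  expect_equal(softmax(c(5, 5.3, 5)), softmax(c(-2, -1.7, -2)))
  expect_equal(softmax(c(1000, 1001, 1002)), softmax(c(0, 1, 2)))
  # closed form
  z <- c(1, 2, 3)
  expect_equal(softmax(z), exp(z) / sum(exp(z)), tolerance = 1e-12)
  # row-wise on matrices
  m <- rbind(c(1, 2, 3), c(0, 0, 0))
  P <- softmax(m)
  expect_equal(rowSums(P), c(1, 1))
  expect_error(softmax(c(1, NA, 2)), "finite")
})

test_that("the two-branch architecture has the declared shape", {
  spec <- build_two_input_mlp(input_dim = 39000L)
  expect_equal(spec$input_dim, 39000L)
  expect_equal(spec$n_classes, 3L)
  # hand-computed trainable parameter count:
  # per branch: 39000*32+32 (dense) + 64 (bn) + 32*32+32 (dense) + 64 (bn)
  # head: 64*3+3 (dense) + 6 (bn)
  branch <- 39000 * 32 + 32 + 64 + 32 * 32 + 32 + 64
  expect_equal(spec$n_params, 2 * branch + 64 * 3 + 3 + 6)
  spec2 <- build_two_input_mlp(input_dim = 10L, head_norm = FALSE)
  expect_equal(spec2$n_params,
               2 * (10 * 32 + 32 + 64 + 32 * 32 + 32 + 64) + 64 * 3 + 3)
})

test_that("the convolutional baseline halves spatial dims three times", {
  spec <- build_dcnn_baseline(c(64, 64), channels = 1L)
  expect_equal(spec$filters, c(32L, 128L, 256L))
  expect_equal(spec$dense, c(512L, 128L, 64L))
  expect_equal(spec$shapes$pool1[1:2], c(32L, 32L))
  expect_equal(spec$shapes$pool2[1:2], c(16L, 16L))
  expect_equal(spec$shapes$pool3[1:2], c(8L, 8L))
  expect_equal(spec$flat, 8L * 8L * 256L)
  # parameter count arithmetic
  conv <- (25 * 1 + 1) * 32 + (25 * 32 + 1) * 128 + (25 * 128 + 1) * 256
  dense <- (8 * 8 * 256) * 512 + 512 + 512 * 128 + 128 + 128 * 64 + 64 +
    64 * 3 + 3
  expect_equal(spec$n_params, conv + dense)
  expect_error(build_dcnn_baseline(c(6, 64)), "too small")
  # eval-mode forward emits a probability simplex
  model <- init_dcnn(build_dcnn_baseline(c(16, 16), channels = 1L), seed = 2)
  p <- dcnn_forward(model, array(rbinom(256, 1, 0.2), dim = c(16, 16, 1)))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(p >= 0))
  expect_error(dcnn_forward(model, array(0, dim = c(8, 8, 1))), "shape")
})

test_that("training separates a separable fixture within the epoch budget", {
  fx <- separable_fixture()
  spec <- build_two_input_mlp(input_dim = ncol(fx$traj_x))
  m <- train_model(spec, fx$traj_x, fx$speed_x, fx$y, train_config(seed = 3))
  expect_lte(nrow(m$history), 100L)
  pred <- predict_trajectory(m, as.matrix(fx$traj_x), as.matrix(fx$speed_x))
  expect_gte(mean(pred$class == fx$y), 0.9)
  # loss is not flat: it decreases over the run
  expect_lt(m$history$train_loss[nrow(m$history)],
            m$history$train_loss[1L] - 0.05)
})

test_that("training is deterministic under the seed and restores best weights", {
  fx <- separable_fixture(n_per = 30L, d = 120L)
  spec <- build_two_input_mlp(input_dim = 120L)
  cfg <- train_config(seed = 11, max_epochs = 12L, patience = 4L)
  m1 <- train_model(spec, fx$traj_x, fx$speed_x, fx$y, cfg)
  m2 <- train_model(spec, fx$traj_x, fx$speed_x, fx$y, cfg)
  expect_identical(m1$par, m2$par)
  expect_identical(m1$history, m2$history)
  # best-epoch weights are the ones kept
  expect_equal(m1$best_epoch, which.min(m1$history$val_loss))
})

test_that("early stopping halts after patience epochs without improvement", {
  fx <- separable_fixture(n_per = 20L, d = 60L, seed = 2)
  spec <- build_two_input_mlp(input_dim = 60L)
  cfg <- train_config(seed = 1, max_epochs = 100L, patience = 3L)
  m <- train_model(spec, fx$traj_x, fx$speed_x, fx$y, cfg)
  if (nrow(m$history) < 100L)
    expect_equal(nrow(m$history), m$best_epoch + 3L)
})

test_that("training refuses unusable label sets", {
  fx <- separable_fixture(n_per = 10L, d = 40L)
  spec <- build_two_input_mlp(input_dim = 40L)
  y2 <- fx$y; y2[y2 == "PwD"] <- "MCI"
  expect_error(train_model(spec, fx$traj_x, fx$speed_x, y2,
                           train_config(seed = 1)), "absent")
  expect_error(train_model(spec, fx$traj_x, fx$speed_x,
                           rep("X", length(fx$y)), train_config(seed = 1)),
               "labels")
})

test_that("a frozen model predicts deterministically and batch-invariantly", {
  fx <- separable_fixture(n_per = 15L, d = 80L)
  spec <- build_two_input_mlp(input_dim = 80L)
  m <- train_model(spec, fx$traj_x, fx$speed_x, fx$y,
                   train_config(seed = 4, max_epochs = 5L))
  X <- as.matrix(fx$traj_x); S <- as.matrix(fx$speed_x)
  p1 <- predict_trajectory(m, X, S)
  p2 <- predict_trajectory(m, X, S)
  expect_identical(p1, p2)          # dropout is off at inference
  # single-sample prediction equals its row in the batch prediction
  p_one <- predict_trajectory(m, X[7, ], S[7, ])
  expect_equal(unlist(p_one[1, 1:3]), unlist(p1[7, 1:3]), tolerance = 1e-12)
  # probabilities live on the simplex
  expect_equal(rowSums(as.matrix(p1[, 1:3])), rep(1, nrow(p1)),
               tolerance = 1e-6)
  expect_error(predict_trajectory(m, X[, 1:10], S[, 1:10]), "input_dim")
})

test_that("a hand-set head on zero inputs reproduces a manual forward pass", {
  spec <- build_two_input_mlp(input_dim = 2L, head_norm = FALSE)
  set.seed(1)
  model <- trajcog:::init_mlp(spec)
  # zero the branches so only the head bias matters, then hand-set it
  model$par$a$W1[] <- 0; model$par$a$W2[] <- 0
  model$par$b$W1[] <- 0; model$par$b$W2[] <- 0
  model$par$a$bn1$gamma[] <- 0; model$par$a$bn2$gamma[] <- 0
  model$par$b$bn1$gamma[] <- 0; model$par$b$bn2$gamma[] <- 0
  model$par$Wh[] <- 0
  model$par$bh <- c(0.3, -0.2, 1.1)
  p <- predict_trajectory(model, c(1, 0), c(0, 1))
  expect_equal(unname(unlist(p[1, 1:3])),
               unname(softmax(c(0.3, -0.2, 1.1))), tolerance = 1e-12)
  expect_equal(p$class, "PwD")
  # zeroed head: the uniform prediction, tie broken by class order
  model$par$bh <- rep(0, 3)
  p0 <- predict_trajectory(model, c(1, 1), c(1, 1))
  expect_equal(unname(unlist(p0[1, 1:3])), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(p0$class, "healthy")
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(9)
  spec <- build_two_input_mlp(input_dim = 7L, hidden = 4L)
  model <- trajcog:::init_mlp(spec)
  model$spec$dropout <- 0   # deterministic loss surface for the check
  n <- 6L
  Xt <- Matrix::t(matrix(rbinom(n * 7, 1, 0.5), n))
  Xs <- Matrix::t(matrix(rbinom(n * 7, 1, 0.5), n))
  Y <- trajcog:::one_hot(rep(COG_CLASSES, 2), COG_CLASSES)
  cache <- trajcog:::mlp_forward(model, Xt, Xs, training = TRUE)
  grads <- trajcog:::mlp_backward(model, Xt, Xs, Y, cache)
  loss_at <- function(par) {
    m2 <- model; m2$par <- par
    trajcog:::cross_entropy(trajcog:::mlp_forward(m2, Xt, Xs,
                                                  training = TRUE)$P, Y)
  }
  leaves <- list(c("a", "W1"), c("a", "bn1", "gamma"), c("b", "W2"),
                 c("b", "bn2", "beta"), c("Wh"), c("bnh", "gamma"))
  for (path in leaves) {
    g <- grads; p <- model$par
    for (nm in path) { g <- g[[nm]]; p <- p[[nm]] }
    for (i in sample(length(p), 3L)) {
      bump <- function(delta) {
        par <- trajcog:::deep_copy(model$par)
        node <- par
        expr <- sprintf("par%s[%d] <- par%s[%d] + delta",
                        paste0("[['", paste(path, collapse = "']][['"),
                               "']]"), i,
                        paste0("[['", paste(path, collapse = "']][['"),
                               "']]"), i)
        eval(parse(text = expr))
        par
      }
      num <- (loss_at(bump(1e-6)) - loss_at(bump(-1e-6))) / 2e-6
      expect_equal(g[i], num, tolerance = 1e-4,
                   info = paste(paste(path, collapse = "$"), i))
    }
  }
})

test_that("the zero-padded convolution matches a naive sliding-window oracle", {
  set.seed(2)
  x <- array(rnorm(25), dim = c(5, 5, 1))
  W <- matrix(rnorm(25), 25, 1)
  p <- trajcog:::im2col_same(x, 5L)
  got <- matrix(p %*% W, 5, 5)
  xp <- matrix(0, 9, 9)
  xp[3:7, 3:7] <- x[, , 1]
  Wk <- matrix(W, 5, 5)    # patch order: dr fastest, then dc
  want <- matrix(0, 5, 5)
  for (r in 1:5) for (c in 1:5) {
    s <- 0
    for (dr in 1:5) for (dc in 1:5)
      s <- s + xp[r + dr - 1, c + dc - 1] * Wk[dr, dc]
    want[r, c] <- s
  }
  expect_equal(got, want, tolerance = 1e-12)
  # max pooling halves dimensions and takes block maxima
  pooled <- trajcog:::maxpool2(array(1:16, dim = c(4, 4, 1)))
  expect_equal(dim(pooled), c(2L, 2L, 1L))
  expect_equal(as.vector(pooled), c(6, 8, 14, 16))
})
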