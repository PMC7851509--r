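# Two-branch multilayer perceptron for trajectory image-pair classification.
# Each branch ingests one flattened binarized image (path-geometry or
# section-speed); the branches are concatenated into a 3-way softmax head.
# Implemented directly on (sparse) matrix algebra: dense layers, batch
# normalization, inverted dropout, Adam, categorical cross-entropy and
# early stopping with best-weight restoration.

#' The three cognitive-status classes, in tie-break order
#' @export
COG_CLASSES <- c("healthy", "MCI", "PwD")

#' Numerically stable softmax
#'
#' Exponential normalization with max-subtraction, applied row-wise to a
#' matrix of logits (or to a single logit vector).
#'
#' @param logits numeric vector or matrix (rows = samples).
#' @return probabilities of the same shape; each row sums to 1.
#' @export
softmax <- function(logits) {
  if (any(!is.finite(logits))) stop("non-finite logits")
  if (is.null(dim(logits))) {
    z <- exp(logits - max(logits))
    return(z / sum(z))
  }
  z <- exp(logits - apply(logits, 1L, max))
  z / rowSums(z)
}

#' Architecture of the two-branch trajectory classifier
#'
#' Each branch: dense 32 (ReLU) -> batch-norm -> dense 32 (ReLU) ->
#' batch-norm -> dropout 0.5. The branch outputs are concatenated and a
#' dense layer with one neuron per class follows; by default it is itself
#' followed by batch-norm and dropout 0.5 before the softmax
#' (\code{head_norm = FALSE} drops those two head layers).
#'
#' @param input_dim features per branch (39,000 for the default
#'   100 x 130 RGB canvas).
#' @param hidden neurons per dense layer in each branch.
#' @param n_classes output dimension.
#' @param dropout drop fraction.
#' @param head_norm keep batch-norm + dropout after the class layer.
#' @return an \code{mlp_spec} with the layer plan and the trainable
#'   parameter count.
#' @export
build_two_input_mlp <- function(input_dim = 39000L, hidden = 32L,
                                n_classes = 3L, dropout = 0.5,
                                head_norm = TRUE) {
  stopifnot(input_dim > 0, hidden > 0, n_classes > 1)
  d <- as.integer(input_dim); h <- as.integer(hidden)
  k <- as.integer(n_classes)
  branch <- (d * h + h) + 2L * h + (h * h + h) + 2L * h
  head <- (2L * h) * k + k + if (head_norm) 2L * k else 0L
  structure(list(kind = "two_input_mlp", input_dim = d, hidden = h,
                 n_classes = k, dropout = dropout, head_norm = head_norm,
                 n_params = 2L * branch + head),
            class = "mlp_spec")
}

#' @export
print.mlp_spec <- function(x, ...) {
  cat(sprintf("<mlp_spec> %s: 2 x (%d -> %d -> %d) -> concat %d -> %d softmax; %s trainable params\n",
              x$kind, x$input_dim, x$hidden, x$hidden, 2L * x$hidden,
              x$n_classes, format(x$n_params, big.mark = ",")))
  invisible(x)
}

glorot_uniform <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

new_bn <- function(k) list(gamma = rep(1, k), beta = rep(0, k),
                           mean = rep(0, k), var = rep(1, k))

# Fresh parameter set for a spec; caller controls the RNG state.
init_mlp <- function(spec) {
  d <- spec$input_dim; h <- spec$hidden; k <- spec$n_classes
  branch <- function() list(
    W1 = glorot_uniform(d, h), b1 = rep(0, h), bn1 = new_bn(h),
    W2 = glorot_uniform(h, h), b2 = rep(0, h), bn2 = new_bn(h))
  par <- list(a = branch(), b = branch(),
              Wh = glorot_uniform(2L * h, k), bh = rep(0, k))
  if (spec$head_norm) par$bnh <- new_bn(k)
  structure(list(spec = spec, par = par, classes = COG_CLASSES[seq_len(k)]),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  print(x$spec)
  cat("  classes:", paste(x$classes, collapse = ", "),
      if (!is.null(x$history)) sprintf("| trained %d epochs (best %d)",
                                       nrow(x$history), x$best_epoch) else
        "| untrained", "\n")
  invisible(x)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9   # running-statistics decay; small corpora need fast adaptation

bn_forward <- function(x, bn, training) {
  n <- nrow(x)
  if (training) {
    mu <- colMeans(x)
    va <- colMeans(x^2) - mu^2
  } else {
    mu <- bn$mean; va <- bn$var
  }
  inv <- 1 / sqrt(va + BN_EPS)
  xhat <- (x - matrix(mu, n, length(mu), byrow = TRUE)) *
    matrix(inv, n, length(inv), byrow = TRUE)
  out <- xhat * matrix(bn$gamma, n, length(mu), byrow = TRUE) +
    matrix(bn$beta, n, length(mu), byrow = TRUE)
  list(out = out, xhat = xhat, inv = inv, mu = mu, va = va)
}

bn_backward <- function(dout, cache, bn) {
  n <- nrow(dout); k <- ncol(dout)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- dout * matrix(bn$gamma, n, k, byrow = TRUE)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dx <- (dxhat - matrix(s1 / n, n, k, byrow = TRUE) -
           cache$xhat * matrix(s2 / n, n, k, byrow = TRUE)) *
    matrix(cache$inv, n, k, byrow = TRUE)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

add_rowvec <- function(m, v) m + matrix(v, nrow(m), length(v), byrow = TRUE)

# X is carried feature-major (d x n sparse): column slicing of a CsparseMatrix
# is far cheaper than row slicing, crossprod(X, W) is the forward GEMM and
# X %*% dZ the input-weight gradient.
branch_forward <- function(X, br, training) {
  Z1 <- add_rowvec(as.matrix(Matrix::crossprod(X, br$W1)), br$b1)
  A1 <- pmax(Z1, 0)
  B1 <- bn_forward(A1, br$bn1, training)
  Z2 <- add_rowvec(B1$out %*% br$W2, br$b2)
  A2 <- pmax(Z2, 0)
  B2 <- bn_forward(A2, br$bn2, training)
  list(Z1 = Z1, A1 = A1, B1 = B1, Z2 = Z2, A2 = A2, B2 = B2, out = B2$out)
}

dropout_mask <- function(n, k, p) {
  matrix((runif(n * k) >= p) / (1 - p), n, k)
}

# Full forward pass. In training mode dropout masks are drawn from the
# current RNG stream and batch statistics are used (and reported for the
# running-average update); in eval mode dropout is identity and running
# statistics are used, so inference is deterministic and batch-size
# invariant.
mlp_forward <- function(model, Xt, Xs, training = FALSE) {
  p <- model$par; sp <- model$spec
  fa <- branch_forward(Xt, p$a, training)
  fb <- branch_forward(Xs, p$b, training)
  n <- nrow(fa$out)
  ma <- mb <- mh <- NULL
  outa <- fa$out; outb <- fb$out
  if (training) {
    ma <- dropout_mask(n, sp$hidden, sp$dropout)
    mb <- dropout_mask(n, sp$hidden, sp$dropout)
    outa <- outa * ma; outb <- outb * mb
  }
  C <- cbind(outa, outb)
  Zh <- add_rowvec(C %*% p$Wh, p$bh)
  Bh <- NULL
  H <- Zh
  if (sp$head_norm) {
    Bh <- bn_forward(Zh, p$bnh, training)
    H <- Bh$out
  }
  if (training && sp$head_norm) {
    mh <- dropout_mask(n, sp$n_classes, sp$dropout)
    H <- H * mh
  }
  P <- softmax(H)
  list(fa = fa, fb = fb, ma = ma, mb = mb, mh = mh, C = C, Zh = Zh,
       Bh = Bh, H = H, P = P)
}

branch_backward <- function(dout, X, br, cache) {
  g2 <- bn_backward(dout, cache$B2, br$bn2)
  dZ2 <- g2$dx * (cache$Z2 > 0)
  dW2 <- crossprod(cache$B1$out, dZ2)
  db2 <- colSums(dZ2)
  d1 <- dZ2 %*% t(br$W2)
  g1 <- bn_backward(d1, cache$B1, br$bn1)
  dZ1 <- g1$dx * (cache$Z1 > 0)
  dW1 <- as.matrix(X %*% dZ1)
  db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1,
       bn1 = list(gamma = g1$dgamma, beta = g1$dbeta),
       W2 = dW2, b2 = db2,
       bn2 = list(gamma = g2$dgamma, beta = g2$dbeta))
}

# Gradients of mean categorical cross-entropy w.r.t. all trainable
# parameters, given a training-mode forward cache.
mlp_backward <- function(model, Xt, Xs, Y, cache) {
  p <- model$par; sp <- model$spec
  n <- nrow(Y)
  dH <- (cache$P - Y) / n
  grads <- list()
  if (sp$head_norm) {
    if (!is.null(cache$mh)) dH <- dH * cache$mh
    gh <- bn_backward(dH, cache$Bh, p$bnh)
    grads$bnh <- list(gamma = gh$dgamma, beta = gh$dbeta)
    dZh <- gh$dx
  } else {
    dZh <- dH
  }
  grads$Wh <- crossprod(cache$C, dZh)
  grads$bh <- colSums(dZh)
  dC <- dZh %*% t(p$Wh)
  h <- sp$hidden
  da <- dC[, seq_len(h), drop = FALSE]
  db <- dC[, h + seq_len(h), drop = FALSE]
  if (!is.null(cache$ma)) { da <- da * cache$ma; db <- db * cache$mb }
  grads$a <- branch_backward(da, Xt, p$a, cache$fa)
  grads$b <- branch_backward(db, Xs, p$b, cache$fb)
  grads
}

update_running_bn <- function(bn, cache) {
  bn$mean <- BN_MOMENTUM * bn$mean + (1 - BN_MOMENTUM) * cache$mu
  bn$var <- BN_MOMENTUM * bn$var + (1 - BN_MOMENTUM) * cache$va
  bn
}

cross_entropy <- function(P, Y) {
  -mean(log(pmax(rowSums(P * Y), 1e-12)))
}

#' Training configuration for the trajectory classifier
#'
#' The defaults are the training recipe of the method: Adam with a low
#' learning rate of 1e-5, categorical cross-entropy, mini-batches of 64,
#' at most 100 epochs with early stopping on validation loss (best weights
#' restored). Patience defaults to 15 epochs: on desk-scale corpora an
#' epoch is only a handful of mini-batches, so the stopping window must be
#' wide enough for the low learning rate to move the weights at all before
#' validation noise triggers a stop.
#'
#' @param learning_rate Adam step size (> 0).
#' @param batch_size samples per mini-batch (>= 1).
#' @param max_epochs epoch cap.
#' @param patience epochs without validation-loss improvement before
#'   stopping.
#' @param val_fraction fraction of each class held out for validation when
#'   no explicit validation set is supplied.
#' @param seed integer seed controlling initialization, shuffling, dropout
#'   and the validation split.
#' @return a \code{train_config} list.
#' @export
train_config <- function(learning_rate = 1e-5, batch_size = 64L,
                         max_epochs = 100L, patience = 15L,
                         val_fraction = 0.1, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1, val_fraction >= 0, val_fraction < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

# Adam state mirrors the parameter tree; leaves are numeric. The fused
# kernel mutates parameters and moments in place, so the state must be
# deep-copied wherever a snapshot is kept (see deep_copy).
adam_init <- function(par) rapply(par, function(x) x * 0, how = "replace")

deep_copy <- function(par) rapply(par, function(x) x + 0, how = "replace")

adam_step <- function(par, grads, m, v, lr, t, skip = c("mean", "var")) {
  walk <- function(p, g, m, v) {
    for (nm in names(p)) {
      if (nm %in% skip || is.null(g[[nm]])) next
      if (is.list(p[[nm]])) walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
      else adam_update_(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t)
    }
  }
  walk(par, grads, m, v)
  invisible(NULL)
}

one_hot <- function(y, classes) {
  Y <- matrix(0, length(y), length(classes))
  Y[cbind(seq_along(y), match(y, classes))] <- 1
  Y
}

# Stratified hold-out: floor(frac * n_c) of each class (at least 1 when the
# class has > 1 sample and frac > 0), drawn with the current RNG.
stratified_holdout <- function(y, frac) {
  val <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    k <- floor(frac * length(idx))
    if (frac > 0 && k == 0L && length(idx) > 1L) k <- 1L
    if (k > 0L) val <- c(val, sample(idx, k))
  }
  sort(val)
}

#' Train the trajectory image-pair classifier
#'
#' Runs seeded mini-batch Adam on categorical cross-entropy. Unless an
#' explicit validation set is given, 10% of each class is held out for
#' validation and the rest is trained on. Training stops when the
#' validation loss has not improved for \code{patience} epochs and the
#' best-validation-loss weights are restored. The whole run is
#' deterministic given \code{cfg$seed}.
#'
#' @param spec an \code{mlp_spec} from [build_two_input_mlp()].
#' @param traj_x,speed_x feature matrices (rows = trajectories, columns =
#'   binarized pixel features); dense or \code{Matrix} sparse.
#' @param y class labels (values among \code{COG_CLASSES}).
#' @param cfg a [train_config()].
#' @param val optional list \code{(traj_x, speed_x, y)} used as the
#'   validation set instead of the internal split.
#' @return trained \code{mlp_model} with \code{$history} (per-epoch train
#'   and validation loss) and \code{$best_epoch}.
#' @export
train_model <- function(spec, traj_x, speed_x, y, cfg = train_config(),
                        val = NULL) {
  if (!inherits(spec, "mlp_spec") || spec$kind != "two_input_mlp")
    stop("training is implemented for the two-input MLP spec")
  stopifnot(nrow(traj_x) == length(y), nrow(speed_x) == length(y))
  classes <- COG_CLASSES[seq_len(spec$n_classes)]
  if (!all(y %in% classes))
    stop("labels must be among: ", paste(classes, collapse = ", "))
  if (!all(classes %in% y))
    stop("class absent from training data: ",
         paste(setdiff(classes, unique(y)), collapse = ", "))
  set.seed(cfg$seed)
  if (is.null(val) && cfg$val_fraction > 0) {
    vidx <- stratified_holdout(y, cfg$val_fraction)
    val <- list(traj_x = traj_x[vidx, , drop = FALSE],
                speed_x = speed_x[vidx, , drop = FALSE], y = y[vidx])
    traj_x <- traj_x[-vidx, , drop = FALSE]
    speed_x <- speed_x[-vidx, , drop = FALSE]
    y <- y[-vidx]
  }
  model <- init_mlp(spec)
  Y <- one_hot(y, classes)
  Yv <- if (!is.null(val)) one_hot(val$y, classes)
  # feature-major storage for cheap mini-batch slicing
  traj_x <- Matrix::t(traj_x)
  speed_x <- Matrix::t(speed_x)
  if (!is.null(val)) {
    val$traj_x <- Matrix::t(val$traj_x)
    val$speed_x <- Matrix::t(val$speed_x)
  }
  # Features never active in the training corpus have identically zero
  # gradient, so Adam leaves their input weights at initialization for the
  # whole run. Restricting the optimized rows to the ever-active features
  # therefore yields bit-identical results while cutting the optimizer's
  # memory traffic several-fold on sparse trajectory rasters.
  act_a <- which(Matrix::rowSums(traj_x) > 0)
  act_b <- which(Matrix::rowSums(speed_x) > 0)
  W1a_full <- model$par$a$W1; W1b_full <- model$par$b$W1
  model$par$a$W1 <- W1a_full[act_a, , drop = FALSE]
  model$par$b$W1 <- W1b_full[act_b, , drop = FALSE]
  traj_x <- traj_x[act_a, , drop = FALSE]
  speed_x <- speed_x[act_b, , drop = FALSE]
  if (!is.null(val)) {
    val$traj_x <- val$traj_x[act_a, , drop = FALSE]
    val$speed_x <- val$speed_x[act_b, , drop = FALSE]
  }
  m <- adam_init(model$par); v <- adam_init(model$par)
  n <- length(y)
  t_step <- 0L
  best_loss <- Inf; best_par <- model$par; best_epoch <- 0L
  bad <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    batch_loss <- numeric(length(starts))
    for (s in seq_along(starts)) {
      idx <- ord[starts[s]:min(starts[s] + cfg$batch_size - 1L, n)]
      Xt <- traj_x[, idx, drop = FALSE]
      Xs <- speed_x[, idx, drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      cache <- mlp_forward(model, Xt, Xs, training = TRUE)
      batch_loss[s] <- cross_entropy(cache$P, Yb)
      grads <- mlp_backward(model, Xt, Xs, Yb, cache)
      t_step <- t_step + 1L
      adam_step(model$par, grads, m, v, cfg$learning_rate, t_step)
      model$par$a$bn1 <- update_running_bn(model$par$a$bn1, cache$fa$B1)
      model$par$a$bn2 <- update_running_bn(model$par$a$bn2, cache$fa$B2)
      model$par$b$bn1 <- update_running_bn(model$par$b$bn1, cache$fb$B1)
      model$par$b$bn2 <- update_running_bn(model$par$b$bn2, cache$fb$B2)
      if (spec$head_norm)
        model$par$bnh <- update_running_bn(model$par$bnh, cache$Bh)
    }
    # training-mode loss averaged over the epoch's mini-batches (the usual
    # per-epoch training metric); validation in eval mode
    train_loss <- mean(batch_loss)
    val_loss <- if (!is.null(val))
      cross_entropy(
        mlp_forward(model, val$traj_x, val$speed_x, training = FALSE)$P, Yv)
    else train_loss
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = train_loss,
                                   val_loss = val_loss))
    if (val_loss < best_loss - 1e-9) {
      best_loss <- val_loss; best_par <- deep_copy(model$par)
      best_epoch <- epoch; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= cfg$patience) break
    }
  }
  model$par <- best_par
  W1a_full[act_a, ] <- model$par$a$W1
  W1b_full[act_b, ] <- model$par$b$W1
  model$par$a$W1 <- W1a_full
  model$par$b$W1 <- W1b_full
  model$history <- hist
  model$best_epoch <- best_epoch
  model
}

#' Classify one or more trajectory image pairs
#'
#' Eval-mode forward pass: dropout off, batch-norm on running statistics.
#' Ties in the arg-max are broken by class order (healthy < MCI < PwD).
#'
#' @param model a trained \code{mlp_model}.
#' @param traj_img,speed_img binarized feature vectors (or matrices with one
#'   row per trajectory) of length \code{model$spec$input_dim}.
#' @return data.frame with one row per trajectory: class probabilities and
#'   the predicted \code{class}.
#' @export
predict_trajectory <- function(model, traj_img, speed_img) {
  as_mat <- function(x) {
    if (is.null(dim(x))) matrix(x, nrow = 1L) else x
  }
  Xt <- as_mat(traj_img); Xs <- as_mat(speed_img)
  if (ncol(Xt) != model$spec$input_dim || ncol(Xs) != model$spec$input_dim)
    stop("feature vector length ", ncol(Xt), " does not match model input_dim ",
         model$spec$input_dim)
  P <- mlp_forward(model, Matrix::t(Xt), Matrix::t(Xs), training = FALSE)$P
  cls <- model$classes[apply(P, 1L, which.max)]
  out <- as.data.frame(P)
  names(out) <- model$classes
  out$class <- cls
  out
}
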