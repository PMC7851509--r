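# Deep convolutional baseline used for comparison with the two-branch MLP:
# three zero-padded ("same") 5x5 convolution blocks of 32, 128 and 256
# filters, each followed by 2x2 max-pooling that halves the spatial
# dimensions, then dense layers of 512, 128 and 64 neurons into a 3-way
# softmax. Provided as an architecture constructor and an eval-mode forward
# pass; gradient training in this package targets the two-branch MLP.

DCNN_FILTERS <- c(32L, 128L, 256L)
DCNN_DENSE <- c(512L, 128L, 64L)
DCNN_KERNEL <- 5L

#' Build the convolutional baseline classifier
#'
#' @param input_shape integer \code{c(height, width)} of the input images.
#' @param channels image channels (3 for RGB trajectory images, 1 for
#'   binary grids).
#' @param n_classes output dimension.
#' @return a \code{dcnn_spec} with the per-layer output shapes and the
#'   trainable parameter count. Errors when the image is too small to
#'   survive three halvings.
#' @export
build_dcnn_baseline <- function(input_shape, channels = 3L, n_classes = 3L) {
  stopifnot(length(input_shape) == 2L, all(input_shape >= 1))
  h <- as.integer(input_shape[1]); w <- as.integer(input_shape[2])
  if (h < 8L || w < 8L)
    stop("input ", h, "x", w, " too small for three 2x2 poolings")
  shapes <- list()
  n_par <- 0L
  cin <- as.integer(channels)
  for (i in seq_along(DCNN_FILTERS)) {
    cout <- DCNN_FILTERS[i]
    n_par <- n_par + (DCNN_KERNEL^2L * cin + 1L) * cout
    shapes[[paste0("conv", i)]] <- c(h, w, cout)   # 'same' padding
    h <- h %/% 2L; w <- w %/% 2L
    shapes[[paste0("pool", i)]] <- c(h, w, cout)
    cin <- cout
  }
  flat <- h * w * cin
  dims <- c(flat, DCNN_DENSE, as.integer(n_classes))
  for (i in seq_len(length(dims) - 1L))
    n_par <- n_par + dims[i] * dims[i + 1L] + dims[i + 1L]
  structure(list(kind = "dcnn", input_shape = c(input_shape, channels),
                 filters = DCNN_FILTERS, kernel = DCNN_KERNEL,
                 dense = DCNN_DENSE, n_classes = as.integer(n_classes),
                 shapes = shapes, flat = flat, n_params = n_par),
            class = "dcnn_spec")
}

#' @export
print.dcnn_spec <- function(x, ...) {
  cat(sprintf("<dcnn_spec> input %s | conv %s (5x5, same, 2x2 pool) | dense %s -> %d softmax | %s params\n",
              paste(x$input_shape, collapse = "x"),
              paste(x$filters, collapse = "/"),
              paste(x$dense, collapse = "/"), x$n_classes,
              format(x$n_params, big.mark = ",")))
  invisible(x)
}

#' Initialize the convolutional baseline with random weights
#'
#' @param spec a \code{dcnn_spec}.
#' @param seed RNG seed for the variance-scaled uniform initialization.
#' @return a \code{dcnn_model}.
#' @export
init_dcnn <- function(spec, seed = 1L) {
  set.seed(seed)
  par <- list(conv = list(), dense = list())
  cin <- spec$input_shape[3]
  for (i in seq_along(spec$filters)) {
    cout <- spec$filters[i]
    fan_in <- spec$kernel^2 * cin
    par$conv[[i]] <- list(
      W = glorot_uniform(fan_in, cout),  # rows: kernel patch, cols: filter
      b = rep(0, cout))
    cin <- cout
  }
  dims <- c(spec$flat, spec$dense, spec$n_classes)
  for (i in seq_len(length(dims) - 1L))
    par$dense[[i]] <- list(W = glorot_uniform(dims[i], dims[i + 1L]),
                           b = rep(0, dims[i + 1L]))
  structure(list(spec = spec, par = par), class = "dcnn_model")
}

# im2col for 'same' zero padding: each output pixel row collects its
# kh x kw x c patch (zeros outside the image).
im2col_same <- function(x, k) {
  h <- dim(x)[1]; w <- dim(x)[2]; cch <- dim(x)[3]
  pad <- (k - 1L) %/% 2L
  xp <- array(0, dim = c(h + 2L * pad, w + 2L * pad, cch))
  xp[pad + seq_len(h), pad + seq_len(w), ] <- x
  patches <- matrix(0, h * w, k * k * cch)
  col <- 0L
  for (ch in seq_len(cch)) for (dc in seq_len(k)) for (dr in seq_len(k)) {
    col <- col + 1L
    patches[, col] <- as.vector(xp[(dr - 1L) + seq_len(h),
                                   (dc - 1L) + seq_len(w), ch])
  }
  patches
}

maxpool2 <- function(x) {
  h <- dim(x)[1] %/% 2L; w <- dim(x)[2] %/% 2L; cch <- dim(x)[3]
  out <- array(-Inf, dim = c(h, w, cch))
  for (dr in 1:2) for (dc in 1:2)
    out <- pmax(out, x[2L * seq_len(h) - 2L + dr,
                       2L * seq_len(w) - 2L + dc, , drop = FALSE])
  out
}

#' Eval-mode forward pass of the convolutional baseline
#'
#' @param model a \code{dcnn_model}.
#' @param img numeric array \code{height x width x channels} (values on any
#'   scale; trajectory images should be binarized first).
#' @return named probability vector over the classes.
#' @export
dcnn_forward <- function(model, img) {
  sp <- model$spec
  if (!all(dim(img) == sp$input_shape))
    stop("image shape ", paste(dim(img), collapse = "x"),
         " does not match spec input ",
         paste(sp$input_shape, collapse = "x"))
  x <- img
  for (i in seq_along(sp$filters)) {
    p <- im2col_same(x, sp$kernel)
    z <- add_rowvec(p %*% model$par$conv[[i]]$W, model$par$conv[[i]]$b)
    x <- array(pmax(z, 0), dim = c(dim(x)[1], dim(x)[2], sp$filters[i]))
    x <- maxpool2(x)
  }
  v <- as.vector(x)
  nd <- length(model$par$dense)
  for (i in seq_len(nd)) {
    v <- as.vector(v %*% model$par$dense[[i]]$W) + model$par$dense[[i]]$b
    if (i < nd) v <- pmax(v, 0)
  }
  setNames(softmax(v), COG_CLASSES[seq_len(sp$n_classes)])
}
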