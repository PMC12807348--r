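# Miniature float CNN container and forward pass.
#
# Activations are arrays with dimensions (H, W, C, N). Weight layouts:
#   conv2d           W: array(kh, kw, inC, outC), bias: length outC
#   depthwise_conv2d W: array(kh, kw, C),          bias: length C
#   linear           W: matrix(in, out),           bias: length out
# A 1x1 conv2d plays the role of the pointwise convolution in
# depthwise-separable blocks.

#' Float model container
#'
#' @param layers list of layer specifications built with the `layer_*`
#'   constructors.
#' @param input_shape integer vector `c(H, W, C)` of the expected input.
#' @return An object of class `"float_model"`.
#' @export
float_model <- function(layers, input_shape) {
  stopifnot(is.list(layers), length(input_shape) == 3L)
  structure(list(layers = layers, input_shape = as.integer(input_shape)),
            class = "float_model")
}

#' @export
print.float_model <- function(x, ...) {
  cat("<float_model> input ", paste(x$input_shape, collapse = "x"), "\n", sep = "")
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    np <- length(l$W) + length(l$b)
    cat(sprintf("  %2d. %-18s %s\n", i, l$kind,
                if (np > 0) paste0(np, " params") else ""))
  }
  invisible(x)
}

#' Layer constructors
#'
#' Build the layer specifications understood by the float and fixed-point
#' forward passes. Convolutions use `stride` and symmetric zero `pad`;
#' `layer_relu(max_val = 6)` gives ReLU6; `layer_avgpool` averages
#' non-overlapping `size x size` windows; `layer_residual_add(from)` adds
#' the recorded output of layer `from` (0 = the network input) to the
#' current activation.
#'
#' @param W weight array (see layout above).
#' @param b optional bias vector.
#' @param stride,pad convolution stride and zero padding.
#' @return A layer specification list.
#' @export
layer_conv2d <- function(W, b = NULL, stride = 1L, pad = 0L) {
  stopifnot(length(dim(W)) == 4L)
  list(kind = "conv2d", W = W, b = b, stride = as.integer(stride),
       pad = as.integer(pad))
}

#' @rdname layer_conv2d
#' @export
layer_depthwise_conv2d <- function(W, b = NULL, stride = 1L, pad = 0L) {
  stopifnot(length(dim(W)) == 3L)
  list(kind = "depthwise_conv2d", W = W, b = b, stride = as.integer(stride),
       pad = as.integer(pad))
}

#' @rdname layer_conv2d
#' @export
layer_linear <- function(W, b = NULL) {
  stopifnot(is.matrix(W))
  list(kind = "linear", W = W, b = b)
}

#' @rdname layer_conv2d
#' @param gamma,beta,mean,var,eps batch-normalization parameters (per
#'   channel) and stabilizer.
#' @export
layer_batchnorm <- function(gamma, beta, mean, var, eps = 1e-5) {
  list(kind = "batchnorm", gamma = gamma, beta = beta, mean = mean,
       var = var, eps = eps)
}

#' @rdname layer_conv2d
#' @param max_val clamp value; `Inf` for plain ReLU, 6 for ReLU6.
#' @export
layer_relu <- function(max_val = Inf) list(kind = "relu", max_val = max_val)

#' @rdname layer_conv2d
#' @param size pooling window edge (stride equals `size`).
#' @export
layer_avgpool <- function(size = 2L) list(kind = "avgpool", size = as.integer(size))

#' @rdname layer_conv2d
#' @export
layer_flatten <- function() list(kind = "flatten")

#' @rdname layer_conv2d
#' @param from index of the layer whose output is added (0 = model input).
#' @export
layer_residual_add <- function(from) list(kind = "residual_add", from = as.integer(from))

# model-facing input scale: zero-centered 8-bit grayscale
.img_scale <- function(images) images / 255 - 0.5

# ---- im2col machinery -------------------------------------------------------

.pad_hw <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1L] + 2L * pad, d[2L] + 2L * pad, d[3L], d[4L]))
  xp[pad + seq_len(d[1L]), pad + seq_len(d[2L]), , ] <- x
  xp
}

.conv_out_dim <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

# x: (H, W, C, N) -> matrix (outH*outW*N) x (kh*kw*C); column order matches
# the column-major flattening of a (kh, kw, C, ...) weight array.
.im2col <- function(x, kh, kw, stride, pad) {
  xp <- .pad_hw(x, pad)
  d <- dim(xp); C <- d[3L]; N <- d[4L]
  oh <- (dim(x)[1L] + 2L * pad - kh) %/% stride + 1L
  ow <- (dim(x)[2L] + 2L * pad - kw) %/% stride + 1L
  col <- matrix(0, oh * ow * N, kh * kw * C)
  ri <- seq.int(1L, by = stride, length.out = oh)
  ci <- seq.int(1L, by = stride, length.out = ow)
  for (j in seq_len(kw)) {
    for (i in seq_len(kh)) {
      s <- xp[ri + (i - 1L), ci + (j - 1L), , , drop = FALSE]  # (oh, ow, C, N)
      s <- aperm(s, c(1L, 2L, 4L, 3L))                          # (oh, ow, N, C)
      dim(s) <- c(oh * ow * N, C)
      col[, i + (j - 1L) * kh + (seq_len(C) - 1L) * kh * kw] <- s
    }
  }
  attr(col, "out_dim") <- c(oh, ow, N)
  col
}

# inverse scatter-add of .im2col for backprop: dcol -> gradient wrt x
.col2im <- function(dcol, in_dim, kh, kw, stride, pad) {
  H <- in_dim[1L]; W <- in_dim[2L]; C <- in_dim[3L]; N <- in_dim[4L]
  od <- attr(dcol, "out_dim"); oh <- od[1L]; ow <- od[2L]
  dxp <- array(0, c(H + 2L * pad, W + 2L * pad, C, N))
  ri <- seq.int(1L, by = stride, length.out = oh)
  ci <- seq.int(1L, by = stride, length.out = ow)
  for (j in seq_len(kw)) {
    for (i in seq_len(kh)) {
      s <- dcol[, i + (j - 1L) * kh + (seq_len(C) - 1L) * kh * kw, drop = FALSE]
      dim(s) <- c(oh, ow, N, C)
      s <- aperm(s, c(1L, 2L, 4L, 3L))
      dxp[ri + (i - 1L), ci + (j - 1L), , ] <-
        dxp[ri + (i - 1L), ci + (j - 1L), , , drop = FALSE] + s
    }
  }
  if (pad > 0L) dxp[pad + seq_len(H), pad + seq_len(W), , , drop = FALSE]
  else dxp
}

# matrix (oh*ow*N) x outC -> array (oh, ow, outC, N)
.mat_to_act <- function(m, oh, ow, N) {
  dim(m) <- c(oh, ow, N, ncol(m))
  aperm(m, c(1L, 2L, 4L, 3L))
}

.act_to_mat <- function(a) {
  d <- dim(a)
  m <- aperm(a, c(1L, 2L, 4L, 3L))
  dim(m) <- c(d[1L] * d[2L] * d[4L], d[3L])
  m
}

.avgpool_reduce <- function(x, s, op = colMeans) {
  d <- dim(x)
  stopifnot(d[1L] %% s == 0L, d[2L] %% s == 0L)
  m <- x; dim(m) <- c(s, prod(d) / s)
  m <- op(m)                                   # (H/s, W, C, N) flattened
  dim(m) <- c(d[1L] / s, d[2L], d[3L], d[4L])
  m <- aperm(m, c(2L, 1L, 3L, 4L))
  dim(m) <- c(s, prod(dim(m)) / s)
  m <- op(m)
  dim(m) <- c(d[2L] / s, d[1L] / s, d[3L], d[4L])
  aperm(m, c(2L, 1L, 3L, 4L))
}

# flatten (H, W, C, N) -> (N, H*W*C) with column-major feature order
.flatten_act <- function(x) {
  d <- dim(x)
  m <- x; dim(m) <- c(prod(d[1:3]), d[4L])
  t(m)
}

# ---- float forward ----------------------------------------------------------

#' Float forward pass
#'
#' Runs the float model on a batch of images and returns the logits; with
#' `record = TRUE` all intermediate activations are kept (used by the
#' quantization calibration pass and by residual connections).
#'
#' @param model a [float_model].
#' @param x input array `(H, W, C, N)` with values on the model's input
#'   scale (images in `[0, 1]`).
#' @param record keep per-layer activations.
#' @return A matrix of logits `(N, classes)`; with `record = TRUE`, a list
#'   `list(logits, activations)` where `activations[[i]]` is the output of
#'   layer `i` (`activations[["input"]]` is the input).
#' @export
float_forward <- function(model, x, record = FALSE) {
  stopifnot(inherits(model, "float_model"))
  need_cache <- record ||
    any(vapply(model$layers, function(l) l$kind == "residual_add", logical(1)))
  acts <- vector("list", length(model$layers))
  input_act <- x
  cur <- x
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    cur <- switch(
      l$kind,
      conv2d = {
        dw <- dim(l$W)
        col <- .im2col(cur, dw[1L], dw[2L], l$stride, l$pad)
        od <- attr(col, "out_dim")
        Wm <- l$W; dim(Wm) <- c(dw[1L] * dw[2L] * dw[3L], dw[4L])
        m <- col %*% Wm
        if (!is.null(l$b)) m <- sweep(m, 2L, l$b, "+")
        .mat_to_act(m, od[1L], od[2L], od[3L])
      },
      depthwise_conv2d = {
        dw <- dim(l$W); C <- dw[3L]
        out <- NULL
        for (c in seq_len(C)) {
          col <- .im2col(cur[, , c, , drop = FALSE], dw[1L], dw[2L],
                         l$stride, l$pad)
          od <- attr(col, "out_dim")
          m <- col %*% matrix(l$W[, , c], ncol = 1L)
          if (!is.null(l$b)) m <- m + l$b[c]
          a <- .mat_to_act(m, od[1L], od[2L], od[3L])
          if (is.null(out))
            out <- array(0, c(od[1L], od[2L], C, od[3L]))
          out[, , c, ] <- a
        }
        out
      },
      linear = {
        m <- if (is.matrix(cur)) cur else .flatten_act(cur)
        m <- m %*% l$W
        if (!is.null(l$b)) m <- sweep(m, 2L, l$b, "+")
        m
      },
      batchnorm = {
        sc <- l$gamma / sqrt(l$var + l$eps)
        sh <- l$beta - l$mean * sc
        sweep(sweep(cur, 3L, sc, "*"), 3L, sh, "+")
      },
      relu = pmin(pmax(cur, 0), l$max_val),
      avgpool = .avgpool_reduce(cur, l$size),
      flatten = .flatten_act(cur),
      residual_add = {
        ref <- if (l$from == 0L) input_act else acts[[l$from]]
        cur + ref
      },
      stop("unsupported layer kind: ", l$kind))
    if (need_cache) acts[[i]] <- cur
  }
  if (record) list(logits = cur, activations = c(list(input = input_act), acts))
  else cur
}
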