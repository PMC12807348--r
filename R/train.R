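# Minimal gradient-descent training loop for the miniature fixture CNNs.
# Softmax cross-entropy, SGD with momentum, full-batch by default. Supports
# the layer kinds the fixtures instantiate (conv2d, depthwise_conv2d,
# linear, relu, avgpool, flatten); it is intentionally small -- just enough
# to fit the synthetic task so that quantization effects can be studied.

.softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward keeping the caches the backward pass needs
.train_forward <- function(model, x) {
  caches <- vector("list", length(model$layers))
  cur <- x
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    cache <- list(x = cur)
    cur <- switch(
      l$kind,
      conv2d = {
        dw <- dim(l$W)
        col <- .im2col(cur, dw[1L], dw[2L], l$stride, l$pad)
        od <- attr(col, "out_dim")
        Wm <- l$W; dim(Wm) <- c(prod(dw[1:3]), dw[4L])
        m <- col %*% Wm
        if (!is.null(l$b)) m <- sweep(m, 2L, l$b, "+")
        cache$col <- col
        .mat_to_act(m, od[1L], od[2L], od[3L])
      },
      depthwise_conv2d = {
        dw <- dim(l$W); C <- dw[3L]
        cols <- vector("list", C)
        out <- NULL
        for (c in seq_len(C)) {
          col <- .im2col(cur[, , c, , drop = FALSE], dw[1L], dw[2L],
                         l$stride, l$pad)
          od <- attr(col, "out_dim")
          m <- col %*% matrix(l$W[, , c], ncol = 1L)
          if (!is.null(l$b)) m <- m + l$b[c]
          if (is.null(out)) out <- array(0, c(od[1L], od[2L], C, od[3L]))
          out[, , c, ] <- .mat_to_act(m, od[1L], od[2L], od[3L])
          cols[[c]] <- col
        }
        cache$cols <- cols
        out
      },
      linear = {
        m <- cur %*% l$W
        if (!is.null(l$b)) m <- sweep(m, 2L, l$b, "+")
        m
      },
      relu = pmin(pmax(cur, 0), l$max_val),
      avgpool = .avgpool_reduce(cur, l$size),
      flatten = .flatten_act(cur),
      stop("training does not support layer kind: ", l$kind))
    cache$out <- cur
    caches[[i]] <- cache
  }
  list(logits = cur, caches = caches)
}

.train_backward <- function(model, caches, dlogits) {
  grads <- vector("list", length(model$layers))
  d <- dlogits
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    cache <- caches[[i]]
    if (l$kind == "conv2d") {
      dw <- dim(l$W)
      dmat <- .act_to_mat(d)
      gW <- crossprod(cache$col, dmat)
      dim(gW) <- dw
      gb <- if (!is.null(l$b)) colSums(.act_to_mat(d)) else NULL
      Wm <- l$W; dim(Wm) <- c(prod(dw[1:3]), dw[4L])
      dcol <- dmat %*% t(Wm)
      attr(dcol, "out_dim") <- attr(cache$col, "out_dim")
      d <- .col2im(dcol, dim(cache$x), dw[1L], dw[2L], l$stride, l$pad)
      grads[[i]] <- list(W = gW, b = gb)
    } else if (l$kind == "depthwise_conv2d") {
      dw <- dim(l$W); C <- dw[3L]
      gW <- array(0, dw)
      gb <- if (!is.null(l$b)) numeric(C) else NULL
      dx <- array(0, dim(cache$x))
      for (c in seq_len(C)) {
        dc <- d[, , c, , drop = FALSE]
        dmat <- .act_to_mat(dc)
        g <- crossprod(cache$cols[[c]], dmat)
        gW[, , c] <- g
        if (!is.null(gb)) gb[c] <- sum(dmat)
        dcol <- dmat %*% t(matrix(l$W[, , c], ncol = 1L))
        attr(dcol, "out_dim") <- attr(cache$cols[[c]], "out_dim")
        dx[, , c, ] <- .col2im(dcol, dim(cache$x[, , c, , drop = FALSE]),
                               dw[1L], dw[2L], l$stride, l$pad)
      }
      d <- dx
      grads[[i]] <- list(W = gW, b = gb)
    } else if (l$kind == "linear") {
      gW <- crossprod(cache$x, d)
      gb <- if (!is.null(l$b)) colSums(d) else NULL
      d <- d %*% t(l$W)
      grads[[i]] <- list(W = gW, b = gb)
    } else if (l$kind == "relu") {
      d <- d * (cache$x > 0 & cache$x < l$max_val)
    } else if (l$kind == "avgpool") {
      s <- l$size
      din <- dim(cache$x)
      up <- d[rep(seq_len(din[1L] / s), each = s),
              rep(seq_len(din[2L] / s), each = s), , , drop = FALSE] / s^2
      d <- array(up, din)
    } else if (l$kind == "flatten") {
      m <- t(d)
      dim(m) <- dim(cache$x)
      d <- m
    }
  }
  grads
}

#' Train a miniature float model
#'
#' Full-batch adaptive-moment (Adam) gradient descent on the softmax
#' cross-entropy. Adequate for the synthetic fixture task; not a
#' general-purpose trainer.
#'
#' @param model a [float_model] built from trainable layer kinds.
#' @param images input array `(H, W, C, N)` of 8-bit grayscale values in
#'   `0..255` (zero-centered to `[-1/2, 1/2]` internally).
#' @param labels integer class labels in `1..K`.
#' @param epochs number of passes.
#' @param lr learning rate.
#' @param beta1,beta2 Adam moment decay rates.
#' @return The trained [float_model], with the per-epoch mean cross-entropy
#'   in `attr(, "loss_history")`.
#' @export
train_model <- function(model, images, labels, epochs = 60L, lr = 0.01,
                        beta1 = 0.9, beta2 = 0.999) {
  stopifnot(inherits(model, "float_model"))
  x <- .img_scale(images)
  n <- dim(x)[4L]
  K <- max(labels)
  onehot <- matrix(0, n, K)
  onehot[cbind(seq_len(n), labels)] <- 1
  zero_like <- function(l)
    if (!is.null(l$W)) list(W = l$W * 0, b = if (!is.null(l$b)) l$b * 0)
  m1 <- lapply(model$layers, zero_like)
  m2 <- lapply(model$layers, zero_like)
  eps <- 1e-8
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    fw <- .train_forward(model, x)
    pr <- .softmax(fw$logits)
    history[ep] <- -mean(log(pmax(pr[cbind(seq_len(n), labels)], 1e-12)))
    dlogits <- (pr - onehot) / n
    grads <- .train_backward(model, fw$caches, dlogits)
    for (i in seq_along(model$layers)) {
      if (is.null(grads[[i]])) next
      for (f in c("W", "b")) {
        g <- grads[[i]][[f]]
        if (is.null(g)) next
        m1[[i]][[f]] <- beta1 * m1[[i]][[f]] + (1 - beta1) * g
        m2[[i]][[f]] <- beta2 * m2[[i]][[f]] + (1 - beta2) * g^2
        mh <- m1[[i]][[f]] / (1 - beta1^ep)
        vh <- m2[[i]][[f]] / (1 - beta2^ep)
        model$layers[[i]][[f]] <- model$layers[[i]][[f]] -
          lr * mh / (sqrt(vh) + eps)
      }
    }
  }
  attr(model, "loss_history") <- history
  model
}
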