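# Post-training quantization of a float model and the bit-exact fixed-point
# forward pass.
#
# Placement rules follow the hardware design: convolution and fully
# connected layers carry MSD-approximated weights and are computed by the
# shift-and-add MAC model (wide exact accumulation, one rescale with
# round-to-nearest-even, one saturation at read-out); biases and
# normalization parameters stay plain Q-format binary numbers; batch
# normalization, pooling and the residual addition use general-purpose
# arithmetic with round-to-nearest and saturation.

# Q-format with 2^m > maxabs (so an exact power-of-two maximum, e.g. a
# weight of 1.0, remains representable), n = bits - 1 - m, signed.
.auto_qspec <- function(maxabs, bits) {
  m <- if (maxabs <= 0) 0L else max(0L, as.integer(floor(log2(maxabs))) + 1L)
  m <- min(m, bits - 1L)
  qformat(m, bits - 1L - m, signed = TRUE)
}

#' Quantize a float model for MSD shift-and-add inference
#'
#' Converts every convolution and linear weight tensor to packed,
#' p-truncated MSD form (per-tensor Q-format, quantized separately for each
#' approximation level since `W_b = W_M - p`), quantizes biases and folded
#' batch-normalization parameters to plain Q-format, and fixes a 16-bit
#' signed activation format per layer by a max-absolute calibration pass
#' over a batch of images.
#'
#' @param model a [float_model].
#' @param p nonzero-digit budget for conv/linear weights.
#' @param calib_images calibration batch, integer array `(H, W, C, N)` in
#'   `0..255` (a handful of images suffices for max-abs calibration).
#' @param W_M MSD container width (default 16).
#' @param act_bits activation width (default 16, signed).
#' @return An object of class `"quantized_model"`.
#' @export
quantize_model <- function(model, p, calib_images, W_M = 16L, act_bits = 16L) {
  stopifnot(inherits(model, "float_model"))
  fw <- float_forward(model, .img_scale(calib_images), record = TRUE)
  acts <- fw$activations
  in_spec <- .auto_qspec(max(abs(acts[["input"]])), act_bits)
  layers <- vector("list", length(model$layers))
  prev_spec <- in_spec
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    out_spec <- .auto_qspec(max(abs(acts[[i + 1L]])), act_bits)
    ql <- list(kind = l$kind, in_spec = prev_spec, out_spec = out_spec)
    if (l$kind %in% c("conv2d", "depthwise_conv2d", "linear")) {
      mw <- max(abs(l$W))
      W_b <- W_M - p
      m_w <- if (mw <= 0) 0L else max(0L, as.integer(floor(log2(mw))) + 1L)
      m_w <- min(m_w, W_b - 1L)
      cfg <- approx_config(p, W_M, qspec = qformat(m_w, W_b - 1L - m_w))
      raw <- quantize_to_qformat(as.numeric(l$W), cfg$qspec)$raw
      d <- .msd_trunc_mat(.naf_mat(abs(raw), cfg$W_b + 1L) * sign(raw), p)
      ql$cfg <- cfg
      ql$payload <- .pack_vec(d, cfg)
      ql$w_raw <- array(.msd_decode_mat(d), dim(l$W))
      ql$w_dim <- dim(l$W)
      ql$nnz <- sum(.msd_count_mat(d))
      if (!is.null(l$b)) {
        ql$b_raw <- quantize_to_qformat(l$b, out_spec)$raw
        ql$b_spec <- out_spec
      }
      ql$stride <- l$stride; ql$pad <- l$pad
    } else if (l$kind == "batchnorm") {
      sc <- l$gamma / sqrt(l$var + l$eps)
      sh <- l$beta - l$mean * sc
      s_spec <- .auto_qspec(max(abs(sc)), act_bits)
      ql$scale_raw <- quantize_to_qformat(sc, s_spec)$raw
      ql$scale_spec <- s_spec
      ql$shift_raw <- quantize_to_qformat(sh, out_spec)$raw
    } else if (l$kind == "relu") {
      ql$max_val <- l$max_val
    } else if (l$kind == "avgpool") {
      ql$size <- l$size
      ql$out_spec <- prev_spec   # integer mean keeps the incoming format
    } else if (l$kind == "flatten") {
      ql$out_spec <- prev_spec
    } else if (l$kind == "residual_add") {
      ql$from <- l$from
    } else {
      stop("unsupported layer kind: ", l$kind)
    }
    if (l$kind == "relu") ql$out_spec <- prev_spec
    layers[[i]] <- ql
    prev_spec <- layers[[i]]$out_spec
  }
  structure(list(layers = layers, p = as.integer(p), W_M = as.integer(W_M),
                 act_bits = as.integer(act_bits), input_spec = in_spec,
                 input_shape = model$input_shape),
            class = "quantized_model")
}

#' @export
print.quantized_model <- function(x, ...) {
  cat(sprintf("<quantized_model> p = %d, W_M = %d, input %s, activations %d-bit\n",
              x$p, x$W_M, paste(x$input_shape, collapse = "x"), x$act_bits))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    extra <- if (!is.null(l$cfg))
      sprintf("  Q(%d,%d) weights, %d packed, %d nonzero digits",
              l$cfg$qspec$m, l$cfg$qspec$n, length(l$payload), l$nnz) else ""
    cat(sprintf("  %2d. %-18s out Q(%d,%d)%s\n", i, l$kind,
                l$out_spec$m, l$out_spec$n, extra))
  }
  invisible(x)
}

# saturating rescale from an exact accumulator; updates the layer report
.layer_readout <- function(acc, frac_bits, out_spec) {
  r <- .rne_shift(acc, frac_bits - out_spec$n)
  sat <- sum(r < out_spec$min_raw | r > out_spec$max_raw)
  list(raw = .clamp(r, out_spec$min_raw, out_spec$max_raw), sat = sat)
}

#' Bit-exact fixed-point forward pass
#'
#' Runs the quantized model on a batch of 8-bit grayscale images (values
#' `0..255`, mapped to the input format by `x / 255 - 1/2`, zero-centered). Every convolution /
#' linear output element equals a shift-and-add MAC over its receptive
#' field: partial products accumulate exactly, the bias is added as a binary
#' number, and the result is rescaled and saturated once. The pass is
#' deterministic: identical model and batch give bit-identical raw outputs.
#'
#' @param model a [quantized_model].
#' @param images integer array `(H, W, C, N)`, values `0..255`.
#' @return A list of class `"fxp_forward"`: `logits` (dequantized real
#'   matrix, one row per image), `logits_raw`, and `layer_report` (a
#'   data.frame of per-layer shift-and-add partial sums and saturation
#'   events).
#' @export
fxp_forward <- function(model, images) {
  stopifnot(inherits(model, "quantized_model"))
  x <- quantize_to_qformat(.img_scale(images), model$input_spec)$raw
  dim(x) <- dim(images)
  acts <- vector("list", length(model$layers))
  input_act <- x
  report <- data.frame(layer = seq_along(model$layers),
                       kind = vapply(model$layers, `[[`, "", "kind"),
                       partial_sums = 0, saturations = 0)
  cur <- x
  cur_spec <- model$input_spec
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$kind %in% c("conv2d", "depthwise_conv2d")) {
      dw <- l$w_dim
      frac <- l$cfg$qspec$n + cur_spec$n
      if (l$kind == "conv2d") {
        col <- .im2col(cur, dw[1L], dw[2L], l$stride, l$pad)
        od <- attr(col, "out_dim")
        Wm <- l$w_raw; dim(Wm) <- c(prod(dw[-length(dw)]), dw[length(dw)])
        acc <- col %*% Wm
        if (!is.null(l$b_raw))
          acc <- sweep(acc, 2L, l$b_raw * 2^(frac - l$b_spec$n), "+")
        out <- .layer_readout(acc, frac, l$out_spec)
        cur <- .mat_to_act(out$raw, od[1L], od[2L], od[3L])
        n_pos <- od[1L] * od[2L] * od[3L]
      } else {
        C <- dw[3L]
        outarr <- NULL; satn <- 0
        for (c in seq_len(C)) {
          col <- .im2col(cur[, , c, , drop = FALSE], dw[1L], dw[2L],
                         l$stride, l$pad)
          od <- attr(col, "out_dim")
          acc <- col %*% matrix(l$w_raw[, , c], ncol = 1L)
          if (!is.null(l$b_raw))
            acc <- acc + l$b_raw[c] * 2^(frac - l$b_spec$n)
          o <- .layer_readout(acc, frac, l$out_spec)
          satn <- satn + o$sat
          if (is.null(outarr)) outarr <- array(0, c(od[1L], od[2L], C, od[3L]))
          outarr[, , c, ] <- .mat_to_act(o$raw, od[1L], od[2L], od[3L])
        }
        cur <- outarr
        out <- list(sat = satn)
        n_pos <- od[1L] * od[2L] * od[3L]
      }
      report$partial_sums[i] <- n_pos * l$nnz
      report$saturations[i] <- out$sat
    } else if (l$kind == "linear") {
      m <- if (is.matrix(cur)) cur else .flatten_act(cur)
      frac <- l$cfg$qspec$n + cur_spec$n
      Wm <- l$w_raw; dim(Wm) <- l$w_dim
      acc <- m %*% Wm
      if (!is.null(l$b_raw))
        acc <- sweep(acc, 2L, l$b_raw * 2^(frac - l$b_spec$n), "+")
      out <- .layer_readout(acc, frac, l$out_spec)
      cur <- out$raw
      report$partial_sums[i] <- nrow(m) * l$nnz
      report$saturations[i] <- out$sat
    } else if (l$kind == "batchnorm") {
      frac <- l$scale_spec$n + cur_spec$n
      acc <- sweep(cur, 3L, l$scale_raw, "*")
      o <- .layer_readout(acc, frac, l$out_spec)
      r <- sweep(o$raw, 3L, l$shift_raw, "+")
      sat2 <- sum(r < l$out_spec$min_raw | r > l$out_spec$max_raw)
      cur <- .clamp(r, l$out_spec$min_raw, l$out_spec$max_raw)
      report$saturations[i] <- o$sat + sat2
    } else if (l$kind == "relu") {
      clamp_raw <- if (is.finite(l$max_val))
        min(l$max_val * 2^l$out_spec$n, l$out_spec$max_raw) else
        l$out_spec$max_raw
      cur <- pmin(pmax(cur, 0), clamp_raw)
    } else if (l$kind == "avgpool") {
      s <- l$size
      sums <- .avgpool_reduce(cur, s, op = colSums)
      cur <- floor(sums / s^2 + 0.5)       # integer mean, round half up
    } else if (l$kind == "flatten") {
      cur <- .flatten_act(cur)
    } else if (l$kind == "residual_add") {
      ref <- if (l$from == 0L) input_act else acts[[l$from]]
      ref_spec <- if (l$from == 0L) model$input_spec
                  else model$layers[[l$from]]$out_spec
      ref_al <- .rne_shift(ref, ref_spec$n - l$out_spec$n)
      cur_al <- .rne_shift(cur, cur_spec$n - l$out_spec$n)
      r <- cur_al + ref_al
      report$saturations[i] <-
        sum(r < l$out_spec$min_raw | r > l$out_spec$max_raw)
      cur <- .clamp(r, l$out_spec$min_raw, l$out_spec$max_raw)
    } else {
      stop("unsupported layer kind: ", l$kind)
    }
    acts[[i]] <- cur
    cur_spec <- l$out_spec
  }
  structure(list(logits = cur * 2^(-cur_spec$n), logits_raw = cur,
                 out_spec = cur_spec, layer_report = report),
            class = "fxp_forward")
}

#' @export
print.fxp_forward <- function(x, ...) {
  cat(sprintf("<fxp_forward> %d images, output Q(%d,%d), %g partial sums, %g saturations\n",
              nrow(x$logits), x$out_spec$m, x$out_spec$n,
              sum(x$layer_report$partial_sums), sum(x$layer_report$saturations)))
  invisible(x)
}

.metrics_from_logits <- function(logits, labels) {
  n <- nrow(logits); K <- ncol(logits)
  if (n == 0L) stop("empty dataset")
  ord <- t(apply(logits, 1L, order, decreasing = TRUE))
  pred <- ord[, 1L]
  top1 <- mean(pred == labels)
  top2 <- mean(ord[, 1L] == labels | ord[, 2L] == labels)
  pr <- .softmax(logits)
  loss <- -mean(log(pmax(pr[cbind(seq_len(n), labels)], 1e-12)))
  prec <- vapply(seq_len(K), function(k) {
    np <- sum(pred == k)
    if (np == 0L) 0 else sum(pred == k & labels == k) / np
  }, numeric(1))
  confusion <- table(factor(labels, levels = seq_len(K)),
                     factor(pred, levels = seq_len(K)))
  structure(list(top1 = top1, top2 = top2, loss = loss,
                 precision = mean(prec), n = n, confusion = confusion),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("<eval_metrics> n = %d  top1 = %.3f  top2 = %.3f  loss = %.4f  macro precision = %.3f\n",
              x$n, x$top1, x$top2, x$loss, x$precision))
  invisible(x)
}

#' Evaluate a model on a labelled image set
#'
#' Computes top-1 and top-2 accuracy (fraction of samples whose true class
#' is among the 1 or 2 largest logits), mean cross-entropy of the
#' soft-maxed logits, and macro-averaged precision (classes never predicted
#' contribute 0).
#'
#' @param model a [quantized_model] or [float_model].
#' @param images integer array `(H, W, C, N)` in `0..255`, or a dataset
#'   split `list(images, labels)` (then `labels` may be omitted).
#' @param labels integer labels in `1..K`.
#' @return An `"eval_metrics"` object; for quantized models the
#'   [fxp_forward] layer report is attached as `attr(, "layer_report")`.
#' @export
evaluate_model <- function(model, images, labels = NULL) {
  if (is.list(images) && !is.null(images$images)) {
    labels <- images$labels
    images <- images$images
  }
  if (is.null(labels)) stop("labels are required")
  if (inherits(model, "quantized_model")) {
    fw <- fxp_forward(model, images)
    m <- .metrics_from_logits(fw$logits, labels)
    attr(m, "layer_report") <- fw$layer_report
    m
  } else if (inherits(model, "float_model")) {
    .metrics_from_logits(float_forward(model, .img_scale(images)), labels)
  } else {
    stop("model must be a quantized_model or float_model")
  }
}
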