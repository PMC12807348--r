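# Seeded synthetic data and miniature models.
#
# The dataset emulates the shape of a small facial-expression benchmark --
# 48 x 48 8-bit grayscale images in seven classes -- without any faces:
# each class is a fixed oriented-grating-plus-blob template, and samples
# differ by additive Gaussian pixel noise. The templates exercise both
# spatial (depthwise) and cross-channel (pointwise) convolution structure.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Fixture configuration
#'
#' Parameters of the synthetic image generator and model initializer.
#' `noise_sd` is the standard deviation of the additive Gaussian pixel noise
#' on the `[0, 1]` intensity scale; `contrast` scales the class template
#' around mid-gray. Defaults give a task that a miniature CNN learns well
#' beyond chance while remaining sensitive to weight distortion.
#'
#' @param n_classes number of classes (7, matching the emulated benchmark).
#' @param image_size image edge in pixels (48).
#' @param samples_per_class images per class (split into train and test).
#' @param train_frac fraction of each class used for training.
#' @param noise_sd Gaussian pixel-noise standard deviation in `[0, 1]` units.
#' @param contrast template amplitude around mid-gray, in `[0, 1]` units.
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @return A list of class `"fixture_config"`.
#' @export
fixture_config <- function(n_classes = 7L, image_size = 48L,
                           samples_per_class = 36L, train_frac = 2 / 3,
                           noise_sd = 0.45, contrast = 0.3, seed = 1L) {
  structure(list(n_classes = as.integer(n_classes),
                 image_size = as.integer(image_size),
                 samples_per_class = as.integer(samples_per_class),
                 train_frac = train_frac, noise_sd = noise_sd,
                 contrast = contrast, seed = as.integer(seed)),
            class = "fixture_config")
}

# class templates on [-1, 1], dim (S, S, n_classes)
.class_templates <- function(cfg) {
  S <- cfg$image_size
  u <- (seq_len(S) - 0.5) / S
  tpl <- array(0, c(S, S, cfg$n_classes))
  for (k in seq_len(cfg$n_classes)) {
    theta <- (k - 1) * pi / cfg$n_classes
    freq <- 3 + (k - 1) %% 3
    phase <- (k - 1) * pi / 3
    g <- outer(u, u, function(a, b)
      sin(2 * pi * freq * (a * cos(theta) + b * sin(theta)) + phase))
    r2 <- outer((u - 0.5)^2, (u - 0.5)^2, "+")
    sig <- 0.10 + 0.02 * k
    blob <- (if (k %% 2 == 0) 1 else -1) * exp(-r2 / (2 * sig^2))
    t <- 0.7 * g + 0.9 * blob
    tpl[, , k] <- t / max(abs(t))
  }
  tpl
}

#' Generate the synthetic labelled image set
#'
#' Renders each class as its fixed template plus i.i.d. Gaussian pixel
#' noise, quantizes to 8-bit grayscale and splits into train and test.
#' Byte-identical output for identical configurations (the global RNG state
#' is left untouched).
#'
#' @param cfg a [fixture_config] (or arguments passed on to it).
#' @param ... used to build a config when `cfg` is missing.
#' @return A list of class `"msd_dataset"` with elements `train` and `test`
#'   (each `list(images, labels)`, images an integer array
#'   `(S, S, 1, N)` with values `0..255`), `templates`, and `config`.
#' @export
make_dataset <- function(cfg = fixture_config(...), ...) {
  stopifnot(inherits(cfg, "fixture_config"))
  S <- cfg$image_size; K <- cfg$n_classes; M <- cfg$samples_per_class
  tpl <- .class_templates(cfg)
  n_train <- round(M * cfg$train_frac)
  imgs <- .with_seed(cfg$seed, {
    a <- array(0L, c(S, S, 1L, K * M))
    for (k in seq_len(K)) {
      base <- 0.5 + 0.5 * cfg$contrast * tpl[, , k]
      for (j in seq_len(M)) {
        img <- base + matrix(stats::rnorm(S * S, sd = cfg$noise_sd), S, S)
        a[, , 1L, (k - 1L) * M + j] <- as.integer(round(255 * .clamp(img, 0, 1)))
      }
    }
    a
  })
  labels <- rep(seq_len(K), each = M)
  idx_train <- as.vector(vapply(seq_len(K), function(k)
    (k - 1L) * M + seq_len(n_train), integer(n_train)))
  idx_test <- setdiff(seq_len(K * M), idx_train)
  structure(list(
    train = list(images = imgs[, , , idx_train, drop = FALSE],
                 labels = labels[idx_train]),
    test = list(images = imgs[, , , idx_test, drop = FALSE],
                labels = labels[idx_test]),
    templates = tpl, config = cfg), class = "msd_dataset")
}

#' @export
print.msd_dataset <- function(x, ...) {
  cat(sprintf("<msd_dataset> %d classes, %dx%d, %d train / %d test, noise sd %.3g\n",
              x$config$n_classes, x$config$image_size, x$config$image_size,
              length(x$train$labels), length(x$test$labels),
              x$config$noise_sd))
  invisible(x)
}

.he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

#' Create a miniature float CNN
#'
#' A depthwise-separable miniature echoing the inverted-residual motif at
#' desk scale: a 3x3 strided stem convolution followed by two
#' depthwise-plus-pointwise stages with average pooling, then a linear
#' classifier (six weight tensors in total). He-scaled Gaussian
#' initialization (`weight_init = "gaussian"` uses a fixed sd of 0.1
#' instead), deterministic given the seed.
#'
#' @param seed RNG seed for the initialization.
#' @param n_classes output classes.
#' @param image_size input edge (48).
#' @param channels channel widths `c(stem, expanded)` of the two
#'   depthwise-separable stages.
#' @param weight_init `"he_scaled"` (default) or `"gaussian"`.
#' @return An untrained [float_model].
#' @export
make_model <- function(seed = 1L, n_classes = 7L, image_size = 48L,
                       channels = c(8L, 16L),
                       weight_init = c("he_scaled", "gaussian")) {
  weight_init <- match.arg(weight_init)
  c1 <- channels[1L]; c2 <- channels[2L]
  s3 <- image_size %/% 8L          # after stride-2 stem and two 2x2 pools
  init <- function(dims, fan_in) {
    if (weight_init == "he_scaled") .he_init(dims, fan_in)
    else array(stats::rnorm(prod(dims), sd = 0.1), dims)
  }
  .with_seed(seed, {
    float_model(list(
      layer_conv2d(init(c(3L, 3L, 1L, c1), 9), b = numeric(c1),
                   stride = 2L, pad = 1L),
      layer_relu(),
      layer_depthwise_conv2d(init(c(3L, 3L, c1), 9), b = numeric(c1),
                             stride = 1L, pad = 1L),
      layer_relu(),
      layer_conv2d(init(c(1L, 1L, c1, c2), c1), b = numeric(c2)),
      layer_relu(),
      layer_avgpool(2L),
      layer_depthwise_conv2d(init(c(3L, 3L, c2), 9), b = numeric(c2),
                             stride = 1L, pad = 1L),
      layer_relu(),
      layer_conv2d(init(c(1L, 1L, c2, c2), c2), b = numeric(c2)),
      layer_relu(),
      layer_avgpool(2L),
      layer_flatten(),
      layer_linear(init(c(s3 * s3 * c2, n_classes), s3 * s3 * c2),
                   b = numeric(n_classes))
    ), input_shape = c(image_size, image_size, 1L))
  })
}
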