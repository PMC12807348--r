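# Model quantization and the bit-exact fixed-point forward pass.

const_images <- function(val, S = 4L, C = 1L, N = 1L) {
  array(as.integer(val), c(S, S, C, N))
}

test_that("a 1x1 unit-weight conv is the identity on raw activations", {
  m <- float_model(list(layer_conv2d(array(1, c(1, 1, 1, 1)))), c(4, 4, 1))
  set.seed(1)
  imgs <- array(sample(0:255, 32, TRUE), c(4, 4, 1, 2))
  for (p in 1:3) {
    qm <- quantize_model(m, p, imgs)
    l <- qm$layers[[1]]
    # weight 1.0 is a power of two: represented exactly at any budget
    expect_equal(l$w_raw[1] * 2^(-l$cfg$qspec$n), 1.0)
    fw <- fxp_forward(qm, imgs)
    x_raw <- quantize_to_qformat(imgs / 255 - 0.5, qm$input_spec)$raw
    expect_identical(as.vector(fw$logits_raw[, , 1, ] * 1), as.vector(x_raw))
  }
})

test_that("a 2x2 ones kernel sums its receptive field exactly", {
  m <- float_model(list(layer_conv2d(array(1, c(2, 2, 1, 1)))), c(2, 2, 1))
  imgs <- const_images(255, S = 2L)     # maps to +0.5 on the centered scale
  qm <- quantize_model(m, 1, imgs)
  fw <- fxp_forward(qm, imgs)
  xval <- fxp_value(quantize_to_qformat(255 / 255 - 0.5, qm$input_spec))
  expect_equal(as.numeric(fw$logits), 4 * xval)
})

test_that("conv layers equal the exact integer-convolution oracle", {
  set.seed(11)
  m <- float_model(list(
    layer_conv2d(array(rnorm(3 * 3 * 2 * 3, sd = 0.4), c(3, 3, 2, 3)),
                 b = rnorm(3, sd = 0.1), stride = 1L, pad = 1L)), c(4, 4, 2))
  imgs <- array(sample(0:255, 4 * 4 * 2 * 2, TRUE), c(4, 4, 2, 2))
  for (p in c(1L, 2L)) {
    qm <- quantize_model(m, p, imgs)
    l <- qm$layers[[1]]
    x_raw <- quantize_to_qformat(imgs / 255 - 0.5, qm$input_spec)$raw
    dim(x_raw) <- dim(imgs)
    acc <- conv2d_int_oracle(x_raw, l$w_raw, stride = 1, pad = 1)
    frac <- l$cfg$qspec$n + qm$input_spec$n
    acc <- acc + array(rep(l$b_raw * 2^(frac - l$b_spec$n),
                           each = 16), dim(acc))
    expected <- pmin(pmax(round(acc / 2^(frac - l$out_spec$n)),
                          l$out_spec$min_raw), l$out_spec$max_raw)
    got <- fxp_forward(qm, imgs)
    expect_equal(array(aperm(got$logits_raw, c(1, 2, 3, 4)), dim(expected)),
                 expected)
  }
})

test_that("every conv output element is a mac() over its receptive field", {
  set.seed(5)
  m <- float_model(list(
    layer_conv2d(array(rnorm(2 * 2 * 1 * 2, sd = 0.5), c(2, 2, 1, 2)),
                 b = c(0.05, -0.1))), c(3, 3, 1))
  imgs <- array(sample(0:255, 9), c(3, 3, 1, 1))
  qm <- quantize_model(m, 2, imgs)
  l <- qm$layers[[1]]
  x_raw <- quantize_to_qformat(imgs / 255 - 0.5, qm$input_spec)$raw
  dim(x_raw) <- dim(imgs)
  fw <- fxp_forward(qm, imgs)
  for (f in 1:2) for (i in 1:2) for (j in 1:2) {
    idx <- (f - 1L) * 4L + seq_len(4L)
    pws <- lapply(l$payload[idx], function(pl)
      structure(list(payload = pl, config = l$cfg), class = "packed_msd"))
    xs <- fxp(as.vector(x_raw[i + 0:1, j + 0:1, 1, 1]), qm$input_spec)
    bias <- fxp(l$b_raw[f], l$b_spec)
    got <- mac(pws, xs, bias = bias, out_spec = l$out_spec)
    expect_equal(fw$logits_raw[i, j, f, 1], got$raw)
  }
})

test_that("fixed-point batchnorm, relu, avgpool and residual behave exactly", {
  # batchnorm with scale 1, shift 0 is the identity
  m <- float_model(list(layer_batchnorm(gamma = 1, beta = 0, mean = 0,
                                        var = 1 - 1e-5)), c(3, 3, 1))
  imgs <- array(sample(0:255, 9), c(3, 3, 1, 1))
  qm <- quantize_model(m, 3, imgs)
  x_raw <- quantize_to_qformat(imgs / 255 - 0.5, qm$input_spec)$raw
  fw <- fxp_forward(qm, imgs)
  expect_equal(as.vector(fw$logits_raw * 1), as.vector(x_raw))

  # relu zeroes every negative activation (dark image maps below mid-gray)
  m2 <- float_model(list(layer_relu()), c(3, 3, 1))
  qm2 <- quantize_model(m2, 3, const_images(10, 3L))
  fw2 <- fxp_forward(qm2, const_images(10, 3L))
  expect_true(all(fw2$logits_raw == 0))

  # integer-mean pooling: mean of {1,2,3,4} is 2.5, exact in 8 fraction bits
  sums <- msdcnn:::.avgpool_reduce(array(c(256, 512, 768, 1024), c(2, 2, 1, 1)),
                                   2L, op = colSums)
  expect_equal(as.numeric(floor(sums / 4 + 0.5)) / 2^8, 2.5)
  # round-half-up tie: raws {1,2,2,0} -> mean 1.25 -> 1; {1,2,2,1} -> 1.5 -> 2
  s1 <- msdcnn:::.avgpool_reduce(array(c(1, 2, 2, 0), c(2, 2, 1, 1)), 2L, colSums)
  expect_equal(as.numeric(floor(s1 / 4 + 0.5)), 1)
  s2 <- msdcnn:::.avgpool_reduce(array(c(1, 2, 2, 1), c(2, 2, 1, 1)), 2L, colSums)
  expect_equal(as.numeric(floor(s2 / 4 + 0.5)), 2)

  # residual connection: y = conv(x) + x with a unit 1x1 conv doubles x
  m3 <- float_model(list(layer_conv2d(array(1, c(1, 1, 1, 1))),
                         layer_residual_add(0L)), c(3, 3, 1))
  qm3 <- quantize_model(m3, 1, imgs)
  fw3 <- fxp_forward(qm3, imgs)
  x3 <- quantize_to_qformat(imgs / 255 - 0.5, qm3$input_spec)$raw
  got <- as.vector(fw3$logits_raw * 1)
  spec_out <- qm3$layers[[2]]$out_spec
  want <- 2 * msdcnn:::.rne_shift(x3, qm3$input_spec$n - spec_out$n)
  expect_equal(got, want)
})

test_that("an all-zero-weight model emits exactly zero pre-bias activations", {
  m <- float_model(list(layer_conv2d(array(0, c(3, 3, 1, 4)), pad = 1L),
                        layer_flatten(),
                        layer_linear(matrix(0, 9 * 4 * 1, 7))), c(3, 3, 1))
  imgs <- array(sample(0:255, 9), c(3, 3, 1, 1))
  qm <- quantize_model(m, 2, imgs)
  fw <- fxp_forward(qm, imgs)
  expect_true(all(fw$logits_raw == 0))
})

test_that("a constant-prediction head scores the class prevalence", {
  # final linear layer with one all-positive column -> always predicts it
  m <- float_model(list(layer_flatten(),
                        layer_linear(cbind(rep(0.5, 9),
                                           matrix(0, 9, 6)))), c(3, 3, 1))
  set.seed(2)
  imgs <- array(sample(128:255, 9 * 10, TRUE), c(3, 3, 1, 10))
  labels <- rep(1:5, each = 2)
  qm <- quantize_model(m, 3, imgs)
  ev <- evaluate_model(qm, imgs, labels)
  expect_equal(ev$top1, mean(labels == 1))
  expect_gte(ev$top2, ev$top1)
})

test_that("the forward pass is deterministic and the report is consistent", {
  ds <- make_dataset(fixture_config(seed = 3, samples_per_class = 6L))
  model <- make_model(seed = 3)
  qm <- quantize_model(model, 2, ds$train$images)
  a <- fxp_forward(qm, ds$test$images)
  b <- fxp_forward(qm, ds$test$images)
  expect_identical(a$logits_raw, b$logits_raw)
  expect_identical(a$layer_report, b$layer_report)
  # partial sums: positions x total nonzero digits for each MAC layer
  conv1 <- qm$layers[[1]]
  n_img <- dim(ds$test$images)[4]
  expect_equal(a$layer_report$partial_sums[1], 24 * 24 * n_img * conv1$nnz)
  expect_equal(a$layer_report$partial_sums[2], 0)  # relu has no multiplies
})

test_that("model containers round-trip bit-exactly", {
  ds <- make_dataset(fixture_config(seed = 4, samples_per_class = 6L))
  model <- make_model(seed = 4)
  fdir <- tempfile("float_model_")
  write_model(model, fdir)
  m2 <- read_model(fdir)
  expect_equal(m2$layers, model$layers, tolerance = 0)
  qm <- quantize_model(model, 3, ds$train$images)
  qdir <- tempfile("qmodel_")
  write_model(qm, qdir)
  qm2 <- read_model(qdir)
  expect_identical(lapply(qm2$layers, `[[`, "payload"),
                   lapply(qm$layers, `[[`, "payload"))
  expect_equal(qm2$layers, qm$layers, tolerance = 0)
  a <- fxp_forward(qm, ds$test$images)
  b <- fxp_forward(qm2, ds$test$images)
  expect_identical(a$logits_raw, b$logits_raw)
  expect_error(read_model(tempfile("nope_")), "manifest")
})

test_that("dataset containers round-trip byte-identically", {
  ds <- make_dataset(fixture_config(seed = 5, samples_per_class = 3L,
                                    image_size = 16L))
  dir <- tempfile("dataset_")
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_identical(back$train$images, ds$train$images)
  expect_identical(back$test$images, ds$test$images)
  expect_equal(back$train$labels, ds$train$labels)
  expect_error(read_dataset(tempfile("nope_")), "labels.csv")
})
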