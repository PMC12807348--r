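# Canonical signed-digit recoding, truncation, Q-format quantization and the
# packed weight container.

test_that("recoding matches hand-derived examples and decodes exactly", {
  expect_equal(unclass(binary_to_msd(0, 4)), rep(0L, 5L))
  expect_equal(msd_to_int(binary_to_msd(0, 4)), 0)

  d7 <- binary_to_msd(7)                      # 0111 -> +00-
  expect_equal(format_msd(d7), "+00-")
  expect_equal(msd_to_int(d7), 7)

  d26 <- binary_to_msd(c(1, 1, 0, 1, 0))      # 26 -> +0-0+0
  expect_equal(format_msd(d26), "+0-0+0")
  expect_equal(msd_to_int(d26), 26)

  expect_equal(msd_to_int(sdigit(c(1, 0, 0, -1))), 7)
  expect_equal(msd_to_int(sdigit(rep(0, 6))), 0)

  expect_identical(unclass(parse_msd(format_msd(d26))), unclass(d26))
  expect_error(parse_msd("+1x"), "alphabet|only")
  expect_error(sdigit(c(2, 0)), "-1, 0")
})

test_that("recode/decode roundtrip is exact over the full 16-bit range", {
  x <- 0:65535
  d <- msdcnn:::.naf_mat(x, 17L)
  expect_equal(msdcnn:::.msd_decode_mat(d), as.numeric(x))
  # scalar API agrees with the vectorized kernel on a sample
  for (v in c(0, 1, 255, 256, 32767, 65535, sample(x, 25))) {
    expect_equal(msd_to_int(binary_to_msd(v, 16L)), v)
  }
})

test_that("recoder output is non-adjacent, with the known 8-bit digit bound", {
  d <- msdcnn:::.naf_mat(0:65535, 17L)
  adjacent <- abs(d[, -17L]) * abs(d[, -1L])
  expect_true(all(adjacent == 0))
  d8 <- msdcnn:::.naf_mat(0:255, 9L)
  counts8 <- msdcnn:::.msd_count_mat(d8)
  # an eight-digit MSD number carries at most four nonzero digits; recodings
  # that carry into a ninth digit (values near 256, e.g. 171 -> 256 - 85)
  # may use five, the non-adjacency bound for nine digits
  eight_digit <- d8[, 9L] == 0
  expect_equal(max(counts8[eight_digit]), 4)
  expect_equal(max(counts8), 5)
  # spot checks of the counting API
  expect_equal(count_nonzero(binary_to_msd(170, 8L)), 4)  # 10101010
  expect_equal(count_nonzero(sdigit(rep(0, 8))), 0)
})

test_that("nonzero-digit count is minimal over all signed-digit forms (12-bit)", {
  oracle <- min_signed_digit_counts(4095, 13L)
  counts <- msdcnn:::.msd_count_mat(msdcnn:::.naf_mat(0:4095, 13L))
  expect_equal(counts, oracle)
})

test_that("truncation keeps leading digits and obeys the error bound", {
  expect_equal(format_msd(truncate_msd(binary_to_msd(7), 1)), "+000")
  expect_equal(msd_to_int(truncate_msd(binary_to_msd(7), 1)), 8)
  expect_equal(msd_to_int(truncate_msd(binary_to_msd(26), 2)), 24)

  # identity whenever the budget is not binding
  for (v in c(0, 5, 96, 1025)) {
    d <- binary_to_msd(v, 12L)
    expect_identical(unclass(truncate_msd(d, max(1, count_nonzero(d)))),
                     unclass(d))
    expect_identical(unclass(truncate_msd(d, 12L)), unclass(d))
  }
  expect_error(truncate_msd(binary_to_msd(7), 0), "positive")

  # |x - decode(truncate(NAF(x), p))| < 2^(k - p + 1), k = leading position
  x <- 1:4095
  d <- msdcnn:::.naf_mat(x, 13L)
  lead <- apply(d != 0, 1L, function(r) max(which(r))) - 1L
  for (p in 1:3) {
    approx <- msdcnn:::.msd_decode_mat(msdcnn:::.msd_trunc_mat(d, p))
    expect_true(all(abs(x - approx) < 2^(lead - p + 1)))
    expect_true(all(msdcnn:::.msd_count_mat(msdcnn:::.msd_trunc_mat(d, p)) <= p))
  }
})

test_that("Q-format quantization rounds half away from zero and saturates", {
  q <- qformat(1, 6)
  expect_equal(q$width, 8L)
  expect_equal(quantize_to_qformat(0, q)$raw, 0)
  expect_equal(quantize_to_qformat(0.40625, q)$raw, 26)   # exact: 26/64
  expect_equal(fxp_value(quantize_to_qformat(0.40625, q)), 0.40625)
  # ties away from zero
  expect_equal(quantize_to_qformat(26.5 / 64, q)$raw, 27)
  expect_equal(quantize_to_qformat(-26.5 / 64, q)$raw, -27)
  # saturation at both rails
  expect_equal(quantize_to_qformat(100, q)$raw, q$max_raw)
  expect_equal(quantize_to_qformat(-100, q)$raw, q$min_raw)
  expect_error(quantize_to_qformat(NaN, q), "non-finite")
  expect_error(fxp(3.5, q), "integral")
  expect_error(fxp(1000, q), "range")
})

test_that("packed container round-trips losslessly within 16 bits", {
  for (p in 1:3) {
    cfg <- approx_config(p, 16L)
    W_b <- cfg$W_b
    x <- 0:(2^W_b - 1)
    d <- msdcnn:::.msd_trunc_mat(msdcnn:::.naf_mat(x, W_b + 1L), p)
    payload <- msdcnn:::.pack_vec(d, cfg)
    expect_true(all(payload >= 0 & payload < 2^16))
    d2 <- msdcnn:::.unpack_vec(payload, cfg)
    expect_equal(msdcnn:::.msd_decode_mat(d2), msdcnn:::.msd_decode_mat(d))
    expect_identical(d2, d)
    # the zero weight is the unique all-zero payload
    expect_equal(payload[1L], 0)
    expect_equal(sum(payload == 0), 1L)
  }
  # scalar API: negative digit at position 0 survives the roundtrip
  cfg <- make_cfg(p = 2, W_M = 16, m = 12)
  d <- sdigit(c(1, 0, -1))                    # 4 - 1 = 3
  pw <- pack_weight(d, cfg)
  expect_equal(msd_to_int(unpack_weight(pw)), 3)
  expect_equal(decode_weight_raw(pw), 3)
  # contract violation: too many nonzero digits
  expect_error(pack_weight(binary_to_msd(170, 8L), make_cfg(3, 16, m = 12)),
               "more than p")
})

test_that("approximate_weight composes quantize, recode, truncate and pack", {
  cfg0 <- make_cfg(p = 2, W_M = 10, m = 1)    # Q(1,6) quantization
  expect_equal(decode_weight(approximate_weight(0, cfg0)), 0)
  # 0.40625 -> raw 26 -> +0-0+0 -> keep two digits -> 24 -> 0.375
  expect_equal(decode_weight(approximate_weight(0.40625, cfg0)), 0.375)
  # powers of two are exact at any budget
  for (p in 1:3) {
    cfg <- make_cfg(p, 16L, m = 4)
    for (e in -3:3)
      expect_equal(decode_weight(approximate_weight(2^e, cfg)), 2^e)
  }
  # magnitude-negate sign handling is symmetric
  cfg <- make_cfg(p = 2, W_M = 16, m = 1)
  for (w in c(0.1, 0.40625, 0.77, 0.999))
    expect_equal(decode_weight(approximate_weight(-w, cfg)),
                 -decode_weight(approximate_weight(w, cfg)))
  expect_error(approximate_weight(0.5, approx_config(2, 16)), "quantization format")
})
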