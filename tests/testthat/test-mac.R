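# Shift-and-add MAC emulation: oracle equivalence, saturation, counters.

test_that("single multiplications match the worked examples", {
  out20 <- qformat(19, 0)
  # weight 7 = +00- : two partial sums, (5 << 3) - 5 = 35
  cfg7 <- make_cfg(p = 2, W_M = 8, m = 5, n = 0)
  w7 <- approximate_weight(7, cfg7)
  ctr <- mac_counters()
  r <- msd_multiply(w7, fxp(5, qformat(7, 0)), out20, counter = ctr)
  expect_equal(r$raw, 35)
  expect_equal(ctr$partial_sums, 2)
  # weight 6 = +0-0 : 24 - 6 = 18
  w6 <- approximate_weight(6, cfg7)
  expect_equal(msd_multiply(w6, fxp(3, qformat(7, 0)), out20)$raw, 18)
})

test_that("MAC equals the integer-multiplication oracle exhaustively at 8 bits", {
  xspec <- qformat(8, 0, signed = FALSE)
  xs <- fxp(0:255, xspec)
  out <- qformat(24, 0)
  for (p in 1:3) {
    cfg <- make_cfg(p, 16L, m = cfg_m <- 15L - p, n = 0)   # integer weights
    for (w in 0:255) {
      pw <- approximate_weight(w, cfg)
      got <- msd_multiply(pw, xs, out)$raw
      expect_identical(got, decode_weight_raw(pw) * (0:255))
    }
    # negative weights on a sample
    for (w in c(-1, -37, -128, -255)) {
      pw <- approximate_weight(w, cfg)
      expect_identical(msd_multiply(pw, xs, out)$raw,
                       decode_weight_raw(pw) * (0:255))
    }
  }
})

test_that("partial-sum count equals the weight's nonzero digits", {
  cfg <- make_cfg(3, 16L, m = 12, n = 0)
  xs <- fxp(0:15, qformat(8, 0, signed = FALSE))
  for (w in c(0, 1, 3, 170, 4095)) {
    pw <- approximate_weight(w, cfg)
    ctr <- mac_counters()
    msd_multiply(pw, xs, qformat(24, 0), counter = ctr)
    expect_equal(ctr$partial_sums,
                 count_nonzero(unpack_weight(pw)) * length(xs$raw))
  }
})

test_that("mac accumulates, adds bias, and saturates once at read-out", {
  cfg <- make_cfg(2, 16L, m = 13, n = 0)
  xspec <- qformat(8, 0, signed = FALSE)
  out <- qformat(24, 0)
  bias <- fxp(11, out)

  # empty sequence: just the (saturated) bias
  expect_equal(mac(list(), fxp(numeric(0), xspec), bias = bias)$raw, 11)
  narrow <- qformat(2, 0)
  expect_equal(mac(list(), fxp(numeric(0), xspec), bias = fxp(3, narrow),
                   out_spec = narrow)$raw, 3)

  # single pair equals msd_multiply plus bias
  pw <- approximate_weight(6, cfg)
  x1 <- fxp(3, xspec)
  expect_equal(mac(list(pw), x1, bias = bias, out_spec = out)$raw, 18 + 11)

  # dot product of 8 seeded pairs equals exact integer arithmetic
  set.seed(42)
  for (rep in 1:5) {
    w <- sample(-200:200, 8)
    x <- sample(0:255, 8)
    pws <- lapply(w, approximate_weight, cfg = cfg)
    got <- mac(pws, fxp(x, xspec), bias = bias, out_spec = out)$raw
    exact <- sum(vapply(pws, decode_weight_raw, numeric(1)) * x) + 11
    expect_equal(got, exact)
    # order independence
    perm <- sample(8)
    expect_equal(mac(pws[perm], fxp(x[perm], xspec), bias = bias,
                     out_spec = out)$raw, got)
  }
  expect_error(mac(list(pw), fxp(c(1, 2), xspec)), "equal length")
})

test_that("saturation clamps to the format rails and is idempotent", {
  q <- qformat(3, 4)
  expect_equal(saturate(100, q)$raw, 100)
  expect_equal(saturate(q$max_raw + 1, q)$raw, q$max_raw)
  expect_equal(saturate(q$min_raw - 7, q)$raw, q$min_raw)
  v <- c(-5000, -129, -128, 0, 127, 128, 5000)
  once <- saturate(v, q)
  expect_identical(saturate(once$raw, q)$raw, once$raw)
  # msd_multiply saturates its read-out and counts the event
  cfg <- make_cfg(1, 8L, m = 6, n = 0)
  pw <- approximate_weight(64, cfg)
  ctr <- mac_counters()
  r <- msd_multiply(pw, fxp(100, qformat(7, 0)), qformat(7, 0), counter = ctr)
  expect_equal(r$raw, qformat(7, 0)$max_raw)
  expect_equal(ctr$saturations, 1)
})

test_that("read-out rescaling rounds half to even", {
  # weight 0.5 in Q(0,1): product carries one fraction bit
  cfg <- make_cfg(1, 3L, m = 0, n = 1)
  pw <- approximate_weight(0.5, cfg)
  xspec <- qformat(7, 0)
  out <- qformat(7, 0)
  # 3 * 0.5 = 1.5 -> 2 ; 1 * 0.5 = 0.5 -> 0 ; 5 * 0.5 = 2.5 -> 2
  expect_equal(msd_multiply(pw, fxp(3, xspec), out)$raw, 2)
  expect_equal(msd_multiply(pw, fxp(1, xspec), out)$raw, 0)
  expect_equal(msd_multiply(pw, fxp(5, xspec), out)$raw, 2)
})
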