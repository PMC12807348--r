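# Independent oracles used across the suite.

# All signed-digit vectors over the given positions: values and nonzero
# counts, by explicit enumeration (3^length(positions) combinations).
enum_signed_digits <- function(positions) {
  vals <- 0; cnt <- 0
  for (p in positions) {
    vals <- as.vector(outer(vals, c(-2^p, 0, 2^p), "+"))
    cnt <- as.vector(outer(cnt, c(1, 0, 1), "+"))
  }
  list(vals = vals, cnt = cnt)
}

# Brute-force minimal nonzero-digit count for every value 0..maxval over
# signed-digit vectors of width `width` (positions 0..width-1), via a
# meet-in-the-middle split to keep the enumeration tractable.
min_signed_digit_counts <- function(maxval, width) {
  split <- width %/% 2L
  lo <- enum_signed_digits(0:(split - 1L))
  hi <- enum_signed_digits(split:(width - 1L))
  vals <- as.vector(outer(lo$vals, hi$vals, "+"))
  cnt <- as.vector(outer(lo$cnt, hi$cnt, "+"))
  keep <- vals >= 0 & vals <= maxval
  vals <- vals[keep]; cnt <- cnt[keep]
  o <- order(vals, cnt)
  vals <- vals[o]; cnt <- cnt[o]
  first <- !duplicated(vals)
  res <- rep(NA_real_, maxval + 1L)
  res[vals[first] + 1L] <- cnt[first]
  res
}

# Plain integer 2-D convolution oracle (valid for stride/pad), direct loops.
conv2d_int_oracle <- function(x, W, stride, pad) {
  # x: (H, W, C, N) integer raws; W: (kh, kw, C, outC) integer raws
  d <- dim(x); k <- dim(W)
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  oh <- (d[1] + 2 * pad - k[1]) %/% stride + 1
  ow <- (d[2] + 2 * pad - k[2]) %/% stride + 1
  out <- array(0, c(oh, ow, k[4], d[4]))
  for (n in seq_len(d[4])) for (f in seq_len(k[4]))
    for (i in seq_len(oh)) for (j in seq_len(ow)) {
      patch <- xp[(i - 1) * stride + seq_len(k[1]),
                  (j - 1) * stride + seq_len(k[2]), , n]
      out[i, j, f, n] <- sum(patch * W[, , , f])
    }
  out
}

# nearest-template classifier (correlation with class templates)
template_classify <- function(images, templates) {
  n <- dim(images)[4]
  K <- dim(templates)[3]
  x <- matrix(images, ncol = n)
  x <- sweep(x, 2L, colMeans(x))
  tm <- matrix(templates, ncol = K)
  tm <- sweep(tm, 2L, colMeans(tm))
  score <- crossprod(x, tm)
  apply(score, 1L, which.max)
}

make_cfg <- function(p, W_M, m = NULL, n = NULL, signed = TRUE) {
  W_b <- W_M - p
  if (is.null(m) && is.null(n)) return(approx_config(p, W_M))
  if (is.null(n)) n <- W_b - 1L - m
  approx_config(p, W_M, qspec = qformat(m, n, signed))
}
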