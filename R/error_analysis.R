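# Error analysis of the MSD-approximated multiplier: normalized mean error
# distance (NMED) from exhaustive simulation, and nonzero-digit statistics
# over weight tensors.

#' Normalized mean error distance of the MSD-MAC multiplier
#'
#' Simulates the approximate multiplier over all representable operand
#' values: every `width`-bit weight is recoded to minimum-signed-digit form
#' and truncated to `p` nonzero digits, and the error of the approximate
#' product against the exact product is averaged over all (weight, input)
#' pairs, then divided by the maximum exact output of the multiplier. No
#' saturation is applied in this metric.
#'
#' Because the product error is `|w - w_approx| * x` (inputs are
#' nonnegative), the exhaustive mean factorizes as
#' `mean(|w - w_approx|) * mean(x)`, which keeps the full 16-bit sweep at
#' `O(2^width)` cost. The `"pairwise"` method evaluates the raw double sum
#' instead (feasible up to width 12) and serves as an independent oracle for
#' the factorized path.
#'
#' @param p nonzero-digit budget.
#' @param width operand bit-width (16 for the studied multiplier).
#' @param signed_weights if `TRUE` (default) weights range over the signed
#'   two's-complement `width`-bit domain (magnitudes are recoded and digits
#'   negated); if `FALSE`, over the unsigned domain. Inputs are always the
#'   unsigned `width`-bit domain, matching post-ReLU activations.
#' @param weight_domain `"raw"` (default) truncates the MSD form of the
#'   `width`-bit weight itself; `"qformat"` first requantizes the weight to
#'   `W_b = width - p` bits (round half away from zero, saturating) and
#'   rescales, modelling the separate per-level quantization of the weight
#'   pipeline. Both conventions are exposed because the reference
#'   description does not pin one down; at 16 bits they agree to ~4 digits.
#' @param method `"factorized"` (exhaustive, any width up to 16) or
#'   `"pairwise"` (explicit double enumeration, width at most 12).
#' @return An object of class `"nmed_report"`: fields `nmed` (fraction),
#'   `nmed_percent`, `mean_abs_error` (mean absolute product error),
#'   `max_output`, `mean_input`, `mean_abs_weight_error`, `p`, `width`,
#'   `n_weights`, plus the resolved conventions.
#' @examples
#' nmed(p = 1, width = 3, signed_weights = FALSE)  # 2.1875 / 49
#' @export
nmed <- function(p, width = 16L, signed_weights = TRUE,
                 weight_domain = c("raw", "qformat"),
                 method = c("factorized", "pairwise")) {
  weight_domain <- match.arg(weight_domain)
  method <- match.arg(method)
  if (width > 16L) stop("exhaustive simulation supports widths up to 16")
  if (p < 1) stop("p must be at least 1")
  if (method == "pairwise" && width > 12L)
    stop("pairwise enumeration is limited to width <= 12; use the factorized path")

  w <- if (signed_weights) seq.int(-2^(width - 1L), 2^(width - 1L) - 1L)
       else seq.int(0L, 2^width - 1L)
  w_approx <- .approx_weight_int(w, p, width, weight_domain)

  x_max <- 2^width - 1
  x_mean <- x_max / 2
  max_output <- max(abs(w)) * x_max
  if (method == "factorized") {
    mean_abs_werr <- mean(abs(w - w_approx))
    mean_abs_error <- mean_abs_werr * x_mean
  } else {
    x <- 0:x_max
    err <- outer(abs(w - w_approx), x)     # |w - w~| * x over all pairs
    mean_abs_error <- mean(err)
    mean_abs_werr <- mean(abs(w - w_approx))
  }
  val <- mean_abs_error / max_output
  structure(list(nmed = val, nmed_percent = 100 * val,
                 mean_abs_error = mean_abs_error, max_output = max_output,
                 mean_input = x_mean, mean_abs_weight_error = mean_abs_werr,
                 p = as.integer(p), width = as.integer(width),
                 n_weights = length(w), signed_weights = signed_weights,
                 weight_domain = weight_domain, method = method),
            class = "nmed_report")
}

# Truncated-MSD approximation of integer weights (vectorized).
.approx_weight_int <- function(w, p, width, weight_domain = "raw") {
  s <- sign(w)
  mag <- abs(w)
  if (weight_domain == "qformat") {
    W_b <- width - p
    lim <- if (any(w < 0)) 2^(W_b - 1L) else 2^W_b - 1
    q <- .clamp(.round_half_away(mag / 2^p), 0, lim)
    d <- .msd_trunc_mat(.naf_mat(q, W_b + 2L), p)
    s * .msd_decode_mat(d) * 2^p
  } else {
    d <- .msd_trunc_mat(.naf_mat(mag, width + 1L), p)
    s * .msd_decode_mat(d)
  }
}

#' @export
print.nmed_report <- function(x, ...) {
  cat(sprintf("<nmed_report> p = %d, width = %d (%s weights, %s domain)\n",
              x$p, x$width, if (x$signed_weights) "signed" else "unsigned",
              x$weight_domain))
  cat(sprintf("  NMED: %.6g (fraction)  =  %.4g%%\n", x$nmed, x$nmed_percent))
  cat(sprintf("  mean |error|: %.6g   max output: %.6g\n",
              x$mean_abs_error, x$max_output))
  invisible(x)
}

# popcount lookup for one byte
.POP8 <- vapply(0:255, function(v) sum(bitwAnd(v, 2^(0:7)) > 0), numeric(1))

# number of nonzero bits among the 23 explicit mantissa bits of the IEEE-754
# single-precision encoding of each value (the bits that feed a mantissa
# multiplier; the implicit leading 1 and the exponent are excluded).
.f32_mantissa_nzbits <- function(w) {
  b <- writeBin(as.numeric(w), raw(), size = 4L, endian = "little")
  m <- matrix(as.integer(b), nrow = 4L)
  .POP8[m[1L, ] + 1L] + .POP8[m[2L, ] + 1L] + .POP8[(m[3L, ] %% 128L) + 1L]
}

#' Nonzero-digit statistics of a weight tensor
#'
#' Counts, summed over all weights of a tensor, the nonzero digits under
#' several representations: the explicit mantissa bits of the IEEE-754
#' single-precision encoding (the bits that generate partial products in a
#' floating-point mantissa multiplier), the binary Q-format quantization at
#' width `W_M`, the full minimum-signed-digit recoding, and the MSD form
#' truncated at each requested digit budget `p`. Because one container bit
#' is spent per retained sign, the quantization width for the truncated
#' columns is `W_b = W_M - p`, chosen separately per level.
#'
#' @param weights numeric vector/array of float weights.
#' @param p integer vector of digit budgets (default `c(1, 2, 3)`).
#' @param W_M MSD container width (default 16).
#' @param m integer bits of the signed quantization format; default chooses
#'   `max(0, ceiling(log2(max|w|)))` for the tensor.
#' @return An object of class `"digit_stats"` with fields `total_weights`,
#'   `nonzero_digits_fp32`, `nonzero_digits_binary`, `nonzero_digits_msd`
#'   and `nonzero_digits_truncated` (named by `p`).
#' @export
digit_stats <- function(weights, p = c(1L, 2L, 3L), W_M = 16L, m = NULL) {
  w <- as.numeric(weights)
  if (is.null(m)) {
    mx <- max(abs(w), 0)
    m <- if (mx == 0) 0L else max(0L, as.integer(ceiling(log2(mx))))
  }
  fp32 <- sum(.f32_mantissa_nzbits(w))

  q16 <- qformat(m, W_M - 1L - m, signed = TRUE)
  raw16 <- quantize_to_qformat(w, q16)$raw
  mag <- abs(raw16)
  nbin <- 0
  for (k in 0:(W_M - 1L)) nbin <- nbin + sum(floor(mag / 2^k) %% 2)
  d16 <- .naf_mat(mag, W_M + 1L)
  nmsd <- sum(.msd_count_mat(d16))

  ntr <- vapply(p, function(pp) {
    cfg <- approx_config(pp, W_M, m = min(m, W_M - pp - 1L))
    rawp <- quantize_to_qformat(w, cfg$qspec)$raw
    dp <- .msd_trunc_mat(.naf_mat(abs(rawp), cfg$W_b + 1L), pp)
    sum(.msd_count_mat(dp))
  }, numeric(1))
  names(ntr) <- paste0("p", p)

  structure(list(total_weights = length(w), nonzero_digits_fp32 = fp32,
                 nonzero_digits_binary = nbin, nonzero_digits_msd = nmsd,
                 nonzero_digits_truncated = ntr,
                 W_M = as.integer(W_M), m = as.integer(m)),
            class = "digit_stats")
}

#' @export
print.digit_stats <- function(x, ...) {
  cat(sprintf("<digit_stats> %d weights (W_M = %d, m = %d)\n",
              x$total_weights, x$W_M, x$m))
  cat(sprintf("  fp32 mantissa bits : %d\n", x$nonzero_digits_fp32))
  cat(sprintf("  binary (Q-format)  : %d\n", x$nonzero_digits_binary))
  cat(sprintf("  MSD (full)         : %d\n", x$nonzero_digits_msd))
  for (nm in names(x$nonzero_digits_truncated))
    cat(sprintf("  MSD truncated %-4s : %d\n", nm,
                x$nonzero_digits_truncated[[nm]]))
  invisible(x)
}

#' Extract one digit count from a digit_stats object
#'
#' @param stats a [digit_stats] result.
#' @param which one of `"fp32"`, `"binary"`, `"msd"`, or `"p<k>"` for a
#'   truncated column.
#' @return The summed nonzero-digit count.
#' @export
digit_count <- function(stats, which) {
  stopifnot(inherits(stats, "digit_stats"))
  switch(which,
         fp32 = stats$nonzero_digits_fp32,
         binary = stats$nonzero_digits_binary,
         msd = stats$nonzero_digits_msd,
         {
           if (!which %in% names(stats$nonzero_digits_truncated))
             stop("no column '", which, "' in digit_stats")
           stats$nonzero_digits_truncated[[which]]
         })
}

#' Shift-and-add reduction ratio
#'
#' `1 - after / before`: the fraction of shift-and-add partial sums removed
#' by an approximation, comparing nonzero-digit counts of the same tensor
#' under two representations.
#'
#' @param before,after nonzero-digit counts (numbers), e.g. from
#'   [digit_count()].
#' @return The reduction as a fraction in `[0, 1]` (negative if `after`
#'   exceeds `before`).
#' @export
reduction_ratio <- function(before, after) {
  before <- as.numeric(before); after <- as.numeric(after)
  if (any(before == 0)) stop("reduction is undefined for a zero baseline count")
  1 - after / before
}
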