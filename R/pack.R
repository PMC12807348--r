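# Approximation configuration and the compact packed-weight layout.
#
# Packed layout (bit-exact). A truncated MSD weight with budget p is stored
# in a single W_M-bit unsigned container. Let b = ceiling(log2(W_b + 2)) be
# the width of one position field (positions 0..W_b must be encodable, plus
# a reserved "unused" code). Reading the container most-significant bit
# first:
#
#   [ s_1 ... s_p | q_1 ... q_p | zero padding to W_M bits ]
#
# where slot j describes the j-th most-significant nonzero digit: s_j is its
# sign bit (1 = digit -1, 0 = digit +1) and q_j is its position encoded as
# position + 1. A q_j of 0 marks an unused slot (the weight has fewer than p
# nonzero digits); its sign bit is 0. Encoding position + 1 rather than the
# raw position keeps the all-zero container as the unique encoding of the
# zero weight and makes a genuine digit at position 0 unambiguous.
# For W_M = 16 the layout fits for every p in {1, 2, 3}:
# p = 3 uses 3 * (1 + 4) = 15 bits, p = 2 uses 10, p = 1 uses 6.

#' Approximation configuration
#'
#' Bundles the knobs of the weight-approximation scheme: the nonzero-digit
#' budget `p`, the MSD container width `W_M` (16 bits by default), the
#' derived binary quantization width `W_b = W_M - p`, and the Q-format used
#' for the intermediate binary quantization. Because one container bit is
#' spent per retained sign, the binary width shrinks as the digit budget
#' grows; the quantization of the float weights is therefore performed
#' separately for each approximation level.
#'
#' @param p nonzero-digit budget, a positive integer (1, 2 or 3 in the
#'   studied range).
#' @param W_M MSD container bit-width; default 16.
#' @param qspec optional [qformat] of total width `W_b` used to quantize
#'   float weights before recoding. If `NULL`, a per-tensor format is chosen
#'   at model-quantization time (`m = max(0, ceiling(log2(max|w|)))`,
#'   `n = W_b - 1 - m`, signed).
#' @param m convenience: integer bits of a signed default `qspec`
#'   (`n = W_b - 1 - m`); ignored when `qspec` is given.
#' @return An object of class `"approx_config"` with fields `p`, `W_M`,
#'   `W_b`, `pos_bits`, `qspec`.
#' @examples
#' approx_config(p = 2, m = 1)   # Q(1,12) quantization, 2-digit budget
#' @export
approx_config <- function(p, W_M = 16L, qspec = NULL, m = NULL) {
  if (length(p) != 1L || !is.finite(p) || p < 1 || p != floor(p))
    stop("p must be a positive integer")
  p <- as.integer(p); W_M <- as.integer(W_M)
  W_b <- W_M - p
  if (W_b < 1L) stop("W_M must exceed p")
  pos_bits <- ceiling(log2(W_b + 2))
  if (p * (1L + pos_bits) > W_M)
    stop("packed layout does not fit: p * (1 + pos_bits) exceeds W_M")
  if (is.null(qspec) && !is.null(m)) {
    if (m > W_b - 1L) stop("m too large for a signed width-", W_b, " format")
    qspec <- qformat(m, W_b - 1L - m, signed = TRUE)
  }
  if (!is.null(qspec)) {
    if (!inherits(qspec, "qformat")) stop("qspec must be a qformat")
    if (qspec$width != W_b)
      stop("qspec width (", qspec$width, ") must equal W_b = ", W_b)
  }
  structure(list(p = p, W_M = W_M, W_b = W_b,
                 pos_bits = as.integer(pos_bits), qspec = qspec),
            class = "approx_config")
}

#' @export
print.approx_config <- function(x, ...) {
  cat(sprintf("<approx_config> p = %d, W_M = %d, W_b = %d, position field %d bits\n",
              x$p, x$W_M, x$W_b, x$pos_bits))
  if (!is.null(x$qspec))
    cat(sprintf("  quantization: Q(%d,%d) %s\n", x$qspec$m, x$qspec$n,
                if (x$qspec$signed) "signed" else "unsigned"))
  invisible(x)
}

# ---- vectorized pack/unpack kernels ----------------------------------------
# d: LSB-first digit matrix, one weight per row, ncol = W_b + 1.
# Returns numeric payload vector (< 2^W_M).
.pack_vec <- function(d, cfg) {
  p <- cfg$p; b <- cfg$pos_bits; W_M <- cfg$W_M
  nwt <- nrow(d)
  cnt <- integer(nwt)
  pos1 <- matrix(0, nwt, p)  # position + 1 per slot, 0 = unused
  sgn <- matrix(0, nwt, p)
  for (k in rev(seq_len(ncol(d)))) {
    nz <- which(d[, k] != 0)
    if (!length(nz)) next
    cnt[nz] <- cnt[nz] + 1L
    if (any(cnt[nz] > p))
      stop("digit vector has more than p = ", p, " nonzero digits")
    idx <- cbind(nz, cnt[nz])
    pos1[idx] <- k           # column k holds position k - 1, stored as pos+1
    sgn[idx] <- as.numeric(d[nz, k] < 0)
  }
  payload <- numeric(nwt)
  for (j in seq_len(p)) {
    payload <- payload + sgn[, j] * 2^(W_M - j) + pos1[, j] * 2^(W_M - p - j * b)
  }
  payload
}

# Inverse: payload vector -> LSB-first digit matrix (ncol = W_b + 1).
.unpack_vec <- function(payload, cfg) {
  p <- cfg$p; b <- cfg$pos_bits; W_M <- cfg$W_M
  d <- matrix(0, length(payload), cfg$W_b + 1L)
  for (j in seq_len(p)) {
    s <- floor(payload / 2^(W_M - j)) %% 2
    q <- floor(payload / 2^(W_M - p - j * b)) %% 2^b
    used <- which(q > 0)
    if (length(used))
      d[cbind(used, q[used])] <- 1 - 2 * s[used]
  }
  d
}

# ---- public API -------------------------------------------------------------

#' Pack a truncated signed-digit weight into the compact container
#'
#' Stores at most `p` nonzero digits as (sign, position) slots in a single
#' `W_M`-bit unsigned payload; see the package vignette for the bit-exact
#' layout. Packing followed by [unpack_weight()] is the identity on every
#' digit vector with at most `p` nonzero digits.
#'
#' @param d an [sdigit] vector of width at most `W_b + 1` with at most
#'   `cfg$p` nonzero digits (a contract violation otherwise).
#' @param cfg an [approx_config].
#' @return An object of class `"packed_msd"` with fields `payload`
#'   and `config`.
#' @export
pack_weight <- function(d, cfg) {
  stopifnot(inherits(d, "sdigit"), inherits(cfg, "approx_config"))
  w <- cfg$W_b + 1L
  v <- unclass(d)
  if (length(v) > w)
    stop("digit vector wider than W_b + 1 = ", w)
  if (length(v) < w) v <- c(integer(w - length(v)), v)
  payload <- .pack_vec(matrix(rev(v), nrow = 1L), cfg)
  structure(list(payload = payload, config = cfg), class = "packed_msd")
}

#' @rdname pack_weight
#' @param pw a `"packed_msd"` object.
#' @return `unpack_weight` returns the stored [sdigit] vector
#'   (width `W_b + 1`).
#' @export
unpack_weight <- function(pw) {
  stopifnot(inherits(pw, "packed_msd"))
  d <- .unpack_vec(pw$payload[1L], pw$config)
  sdigit(rev(d[1L, ]))
}

#' @export
print.packed_msd <- function(x, ...) {
  d <- unpack_weight(x)
  cat(sprintf("<packed_msd> payload 0x%04X  digits %s  raw %d\n",
              as.integer(x$payload[1L]), format_msd(d), msd_to_int(d)))
  if (!is.null(x$config$qspec))
    cat("  decoded value:", decode_weight(x), "\n")
  invisible(x)
}

#' Decode a packed weight
#'
#' @param pw a `"packed_msd"` object.
#' @return `decode_weight_raw` returns the integer (Q-format raw) value of
#'   the stored digits; `decode_weight` returns the real value
#'   `raw * 2^-n` under the configuration's quantization format.
#' @export
decode_weight_raw <- function(pw) {
  stopifnot(inherits(pw, "packed_msd"))
  .msd_decode_mat(.unpack_vec(pw$payload, pw$config))
}

#' @rdname decode_weight_raw
#' @export
decode_weight <- function(pw) {
  if (is.null(pw$config$qspec))
    stop("configuration carries no quantization format")
  decode_weight_raw(pw) * 2^(-pw$config$qspec$n)
}

#' Approximate a real-valued weight
#'
#' The full approximation pipeline: quantize to the `W_b`-bit Q-format of
#' the configuration, recode the magnitude to minimum-signed-digit form,
#' keep the `p` most-significant nonzero digits, and pack. Negative weights
#' are handled by recoding the magnitude and negating every digit (signed
#' digits make negation closed). Weights that are exact powers of two within
#' range are represented exactly for any `p >= 1`.
#'
#' @param w a finite real number.
#' @param cfg an [approx_config] whose `qspec` is set.
#' @return A `"packed_msd"` weight; `decode_weight()` of the result is the
#'   truncated-MSD dequantization of `w`.
#' @examples
#' cfg <- approx_config(p = 2, W_M = 8, m = 1)   # Q(1,4) quantization
#' decode_weight(approximate_weight(0.40625, cfg))
#' @export
approximate_weight <- function(w, cfg) {
  stopifnot(inherits(cfg, "approx_config"))
  if (is.null(cfg$qspec))
    stop("approximate_weight needs a configuration with a quantization format")
  raw <- quantize_to_qformat(w, cfg$qspec)$raw
  d <- .naf_mat(abs(raw), cfg$W_b + 1L) * sign(raw)
  d <- .msd_trunc_mat(d, cfg$p)
  structure(list(payload = .pack_vec(d, cfg), config = cfg),
            class = "packed_msd")
}
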