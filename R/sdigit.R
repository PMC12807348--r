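# Signed-digit (MSD / non-adjacent form) recoding of binary magnitudes.
#
# A signed-digit vector holds digits in {-1, 0, +1}, most-significant first.
# The canonical recoder produces the non-adjacent form (NAF), which is the
# unique signed-digit representation with no two adjacent nonzero digits and
# provably the minimum number of nonzero digits for the value -- the property
# that bounds the number of shift-and-add partial sums a MAC unit must
# compute per weight.

#' Construct a signed-digit vector
#'
#' @param digits integer vector of digits in \{-1, 0, +1\},
#'   most-significant digit first.
#' @return An object of class `"sdigit"`.
#' @examples
#' sdigit(c(1, 0, 0, -1))  # 8 - 1 = 7
#' @export
sdigit <- function(digits) {
  digits <- as.integer(digits)
  if (length(digits) < 1L || anyNA(digits) || !all(digits %in% c(-1L, 0L, 1L)))
    stop("digits must be a non-empty vector over {-1, 0, +1}")
  structure(digits, class = "sdigit")
}

#' @export
print.sdigit <- function(x, ...) {
  cat("<sdigit> ", format_msd(x), "  value = ", msd_to_int(x),
      "  nonzero = ", count_nonzero(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.sdigit <- function(x, ...) format_msd(x)

# ---- vectorized internal kernels (LSB-first digit matrices) -----------------
#
# Hot paths (exhaustive 16-bit sweeps) operate on a matrix with one row per
# value and one column per digit position, position 0 in column 1.

# NAF digits of nonnegative integers x, ndig columns (LSB first).
# Classic right-to-left recoding: if x is odd emit d = 2 - (x mod 4)
# (so d in {+1,-1} and (x - d) is divisible by 4), else emit 0.
.naf_mat <- function(x, ndig) {
  x <- as.numeric(x)
  if (any(x < 0)) stop("NAF recoding expects nonnegative magnitudes")
  d <- matrix(0, length(x), ndig)
  for (k in seq_len(ndig)) {
    m4 <- x %% 4
    dk <- numeric(length(x))
    dk[m4 == 1] <- 1
    dk[m4 == 3] <- -1
    d[, k] <- dk
    x <- (x - dk) / 2
  }
  if (any(x != 0))
    stop("value does not fit in ", ndig, " signed digits")
  d
}

.msd_decode_mat <- function(d) {
  drop(d %*% 2^(0:(ncol(d) - 1L)))
}

# Keep the p most-significant nonzero digits of each row, zero the rest.
.msd_trunc_mat <- function(d, p) {
  cnt <- numeric(nrow(d))
  for (k in rev(seq_len(ncol(d)))) {
    nz <- d[, k] != 0
    cnt <- cnt + nz
    d[nz & cnt > p, k] <- 0
  }
  d
}

.msd_count_mat <- function(d) rowSums(d != 0)

# ---- public scalar API ------------------------------------------------------

#' Recode an unsigned binary number into minimum-signed-digit form
#'
#' Converts an unsigned binary magnitude to its canonical minimum-signed-digit
#' representation, the non-adjacent form: no two adjacent digits are nonzero
#' and the nonzero-digit count is minimal among all signed-digit
#' representations of the value. The output has one digit more than the input
#' width because the recoding can carry one position past the most-significant
#' bit (e.g. 7 = 0111 becomes +00-, i.e. 8 - 1).
#'
#' @param x a nonnegative integer, or a vector of bits in \{0, 1\}
#'   (most-significant first).
#' @param width bit-width of the input; defaults to `length(x)` for a bit
#'   vector, or the smallest width holding the value for an integer.
#' @return An [sdigit] vector of `width + 1` digits.
#' @examples
#' binary_to_msd(7)                # +00-  (8 - 1)
#' binary_to_msd(c(1, 1, 0, 1, 0)) # 26 -> +0-0+0 (32 - 8 + 2)
#' @export
binary_to_msd <- function(x, width = NULL) {
  if (length(x) > 1L) {
    if (!all(x %in% c(0, 1))) stop("bit vector must contain only 0 and 1")
    if (is.null(width)) width <- length(x)
    if (width != length(x)) stop("width must equal the bit-vector length")
    val <- sum(x * 2^((width - 1L):0))
  } else {
    val <- as.numeric(x)
    if (!is.finite(val) || val < 0 || val != floor(val))
      stop("x must be a nonnegative integer or a bit vector")
    if (is.null(width)) width <- max(1L, ceiling(log2(val + 1)))
    if (val > 2^width - 1) stop("value does not fit in ", width, " bits")
  }
  d <- .naf_mat(val, width + 1L)
  sdigit(rev(d[1L, ]))
}

#' Decode a signed-digit vector to an integer
#'
#' Positional decoding: the least-significant digit has weight 1.
#'
#' @param d an [sdigit] vector.
#' @return The decoded integer value (as numeric, exact for widths below 53).
#' @export
msd_to_int <- function(d) {
  d <- unclass(d)
  sum(d * 2^((length(d) - 1L):0))
}

#' Truncate a signed-digit vector to at most p nonzero digits
#'
#' Keeps the `p` most-significant nonzero digits unchanged and zeroes every
#' less-significant digit; this is the approximation step that caps the
#' number of shift-and-add partial sums per multiplication at `p`.
#'
#' @param d an [sdigit] vector.
#' @param p nonzero-digit budget, a positive integer.
#' @return An [sdigit] vector of the same width with at most `p` nonzero
#'   digits.
#' @examples
#' truncate_msd(binary_to_msd(7), 1)  # +000  -> 8
#' @export
truncate_msd <- function(d, p) {
  if (length(p) != 1L || !is.finite(p) || p < 1 || p != floor(p))
    stop("p must be a positive integer (nonzero-digit budget)")
  v <- unclass(d)
  nz <- which(v != 0L)
  if (length(nz) > p) v[nz[-seq_len(p)]] <- 0L
  sdigit(v)
}

#' Count nonzero digits
#'
#' The nonzero-digit count of a weight equals the number of partial sums a
#' shift-and-add MAC unit computes for it.
#'
#' @param d an [sdigit] vector.
#' @return Integer count of nonzero digits.
#' @export
count_nonzero <- function(d) sum(unclass(d) != 0L)

#' Format / parse the plain-text digit notation
#'
#' Digits are written most-significant first as `+`, `0` and `-`,
#' e.g. `"+00-"` for 8 - 1 = 7.
#'
#' @param d an [sdigit] vector.
#' @return `format_msd` returns a character scalar; `parse_msd` returns an
#'   [sdigit] vector.
#' @export
format_msd <- function(d) {
  paste(c("-", "0", "+")[unclass(d) + 2L], collapse = "")
}

#' @rdname format_msd
#' @param s a string over the alphabet `+`, `0`, `-`.
#' @export
parse_msd <- function(s) {
  ch <- strsplit(s, "")[[1L]]
  m <- match(ch, c("-", "0", "+"))
  if (anyNA(m)) stop("digit string may contain only '+', '0' and '-'")
  sdigit(m - 2L)
}
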