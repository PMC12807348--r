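# Q(m, n) fixed-point formats and saturating quantization.

#' Q(m, n) fixed-point format specification
#'
#' A fixed-point format with `m` integer bits and `n` fraction bits; a stored
#' raw integer `r` represents the real value `r * 2^-n`. Signed formats add
#' one sign bit, so the total width is `m + n + 1`; the representable raw
#' range is `[-2^(m+n), 2^(m+n) - 1]` (two's complement). Unsigned formats
#' cover `[0, 2^(m+n) - 1]`.
#'
#' @param m number of integer bits (nonnegative).
#' @param n number of fraction bits (nonnegative).
#' @param signed logical; two's-complement signed format if `TRUE` (default).
#' @return An object of class `"qformat"` with fields `m`, `n`, `signed`,
#'   `width`, `min_raw`, `max_raw`.
#' @examples
#' qformat(1, 6)           # Q(1,6): 8-bit signed, resolution 1/64
#' @export
qformat <- function(m, n, signed = TRUE) {
  if (m < 0 || n < 0 || m != floor(m) || n != floor(n))
    stop("m and n must be nonnegative integers")
  width <- m + n + as.integer(signed)
  if (width < 1L) stop("format must be at least one bit wide")
  if (width > 52L) stop("formats wider than 52 bits are not supported")
  structure(
    list(m = as.integer(m), n = as.integer(n), signed = isTRUE(signed),
         width = as.integer(width),
         min_raw = if (signed) -2^(m + n) else 0,
         max_raw = 2^(m + n) - 1),
    class = "qformat")
}

#' @export
print.qformat <- function(x, ...) {
  cat(sprintf("<qformat> Q(%d,%d) %s, width %d, raw range [%g, %g], resolution 2^-%d\n",
              x$m, x$n, if (x$signed) "signed" else "unsigned",
              x$width, x$min_raw, x$max_raw, x$n))
  invisible(x)
}

#' Fixed-point value
#'
#' A raw integer (or vector of raw integers) together with its [qformat].
#'
#' @param raw integer raw value(s), within the format's representable range.
#' @param spec a [qformat].
#' @return An object of class `"fxp"`.
#' @export
fxp <- function(raw, spec) {
  if (!inherits(spec, "qformat")) stop("spec must be a qformat")
  raw <- as.numeric(raw)
  if (any(!is.finite(raw)) || any(raw != floor(raw)))
    stop("raw must be integral")
  if (any(raw < spec$min_raw | raw > spec$max_raw))
    stop("raw value outside the representable range of the format")
  structure(list(raw = raw, spec = spec), class = "fxp")
}

#' @rdname fxp
#' @param x an `"fxp"` object.
#' @return `fxp_value` returns the represented real value(s),
#'   `raw * 2^-n`.
#' @export
fxp_value <- function(x) {
  stopifnot(inherits(x, "fxp"))
  x$raw * 2^(-x$spec$n)
}

#' @export
print.fxp <- function(x, ...) {
  v <- fxp_value(x)
  if (length(v) <= 8L) {
    cat(sprintf("<fxp Q(%d,%d)> raw: %s  value: %s\n", x$spec$m, x$spec$n,
                paste(x$raw, collapse = " "), paste(v, collapse = " ")))
  } else {
    cat(sprintf("<fxp Q(%d,%d)> %d values, raw[1:4]: %s ...\n", x$spec$m,
                x$spec$n, length(v), paste(x$raw[1:4], collapse = " ")))
  }
  invisible(x)
}

# round-half-away-from-zero on exact halves, elementwise
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# round-to-nearest-even right shift of integral values by `shift` bits.
# Division by a power of two is exact in doubles, and base round() resolves
# exact .5 ties to even.
.rne_shift <- function(x, shift) {
  if (shift == 0) return(x)
  if (shift < 0) return(x * 2^(-shift))
  round(x / 2^shift)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Quantize real numbers to a Q-format
#'
#' `raw = round(w * 2^n)` with ties rounded half away from zero, then clamped
#' (saturated) to the representable range.
#'
#' @param w real number(s); must be finite.
#' @param spec a [qformat].
#' @return An [fxp] value.
#' @examples
#' quantize_to_qformat(0.40625, qformat(1, 6))  # raw 26
#' @export
quantize_to_qformat <- function(w, spec) {
  if (!inherits(spec, "qformat")) stop("spec must be a qformat")
  if (any(!is.finite(w))) stop("cannot quantize non-finite values")
  raw <- .clamp(.round_half_away(w * 2^spec$n), spec$min_raw, spec$max_raw)
  fxp(raw, spec)
}

#' Saturate a wide integer to a Q-format's range
#'
#' Clamps raw value(s) to `[min_raw, max_raw]` of the format instead of
#' wrapping, emulating the saturating read-out of the hardware MAC unit.
#'
#' @param v integral value(s) of any magnitude.
#' @param spec a [qformat].
#' @return An [fxp] value in range.
#' @export
saturate <- function(v, spec) {
  if (!inherits(spec, "qformat")) stop("spec must be a qformat")
  fxp(.clamp(as.numeric(v), spec$min_raw, spec$max_raw), spec)
}
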