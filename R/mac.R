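# Bit-exact software model of the shift-and-add MAC unit.
#
# The multiplier takes the weight in approximated MSD form and the
# input/activation as a binary Q-format number. Each nonzero weight digit
# contributes one partial sum: the input raw value shifted left by the digit
# position, added or subtracted according to the digit sign. Partial products
# accumulate exactly in a wide accumulator (doubles are exact well past the
# 2 * W_M + log2(fan-in) bits needed); the accumulated value is rescaled to
# the output Q-format with round-to-nearest-even and saturated once at
# read-out, so the result is independent of accumulation order.

#' Instrumentation counters for MAC activity
#'
#' An environment tracking the number of shift-and-add partial sums executed
#' (one per nonzero weight digit per multiplication) and the number of
#' saturation events at read-out. Pass it to [msd_multiply()], [mac()] or the
#' fixed-point layer functions.
#'
#' @return An environment with numeric fields `partial_sums`, `saturations`
#'   and `macs`.
#' @export
mac_counters <- function() {
  e <- new.env(parent = emptyenv())
  e$partial_sums <- 0
  e$saturations <- 0
  e$macs <- 0
  e
}

.count <- function(counter, psums = 0, sats = 0, macs = 0) {
  if (is.null(counter)) return(invisible(NULL))
  counter$partial_sums <- counter$partial_sums + psums
  counter$saturations <- counter$saturations + sats
  counter$macs <- counter$macs + macs
  invisible(NULL)
}

# digit positions/signs of one packed weight: list(pos = integer positions,
# sgn = +1/-1), possibly empty.
.packed_digits <- function(pw) {
  d <- .unpack_vec(pw$payload[1L], pw$config)[1L, ]
  pos <- which(d != 0) - 1L
  list(pos = pos, sgn = d[pos + 1L])
}

# Rescale an exact accumulator (frac_bits fraction bits) to out_spec and
# saturate; returns list(raw, sat_events).
.readout <- function(acc, frac_bits, out_spec) {
  r <- .rne_shift(acc, frac_bits - out_spec$n)
  sat <- sum(r < out_spec$min_raw | r > out_spec$max_raw)
  list(raw = .clamp(r, out_spec$min_raw, out_spec$max_raw), sat = sat)
}

#' Shift-and-add multiplication by an MSD-approximated weight
#'
#' Computes the product of a packed MSD weight and a Q-format input as the
#' hardware would: one shifted add or subtract of the input raw value per
#' nonzero weight digit. Before saturation the result is exactly
#' `decode_weight_raw(pw) * x$raw`; the accumulated product (carrying
#' `n_w + n_x` fraction bits) is rescaled to `out_spec` with
#' round-to-nearest-even and saturated.
#'
#' @param pw a `"packed_msd"` weight whose configuration carries a `qspec`.
#' @param x an [fxp] input (the raw field may be a vector; the same weight
#'   is applied elementwise).
#' @param out_spec output [qformat]; defaults to the input's format.
#' @param counter optional [mac_counters()] environment.
#' @return An [fxp] result in `out_spec`.
#' @examples
#' cfg <- approx_config(p = 2, W_M = 8, m = 3)
#' w <- approximate_weight(7, cfg)               # +00- : two partial sums
#' x <- fxp(5, qformat(7, 0))
#' msd_multiply(w, x, qformat(14, 0))$raw        # 35
#' @export
msd_multiply <- function(pw, x, out_spec = x$spec, counter = NULL) {
  stopifnot(inherits(pw, "packed_msd"), inherits(x, "fxp"))
  cfg <- pw$config
  if (is.null(cfg$qspec)) stop("weight configuration carries no qspec")
  dg <- .packed_digits(pw)
  acc <- numeric(length(x$raw))
  for (i in seq_along(dg$pos))
    acc <- acc + dg$sgn[i] * x$raw * 2^dg$pos[i]
  out <- .readout(acc, cfg$qspec$n + x$spec$n, out_spec)
  .count(counter, psums = length(dg$pos) * length(x$raw), sats = out$sat,
         macs = length(x$raw))
  fxp(out$raw, out_spec)
}

#' Multiply-accumulate over a weight/input sequence
#'
#' Accumulates the shift-and-add partial products of all weight/input pairs
#' in a wide exact accumulator, adds the bias (a plain binary Q-format
#' number, aligned to the accumulator's fraction bits), and saturates once at
#' read-out. Because the accumulator never saturates intermediately the
#' result is independent of the accumulation order.
#'
#' @param pws a list of `"packed_msd"` weights sharing one configuration.
#' @param xs an [fxp] whose raw field has one element per weight (or a list
#'   of scalar [fxp] values in one common format).
#' @param bias optional [fxp] scalar; its fraction bits must not exceed
#'   `n_w + n_x`.
#' @param out_spec output [qformat]; defaults to the input format.
#' @param counter optional [mac_counters()] environment.
#' @return An [fxp] scalar in `out_spec`.
#' @export
mac <- function(pws, xs, bias = NULL, out_spec = NULL, counter = NULL) {
  if (inherits(pws, "packed_msd")) pws <- list(pws)
  if (is.list(xs) && !inherits(xs, "fxp")) {
    spec <- if (length(xs)) xs[[1L]]$spec else NULL
    raw <- vapply(xs, function(z) {
      stopifnot(inherits(z, "fxp"))
      if (!identical(unclass(z$spec), unclass(spec)))
        stop("all inputs must share one Q-format")
      z$raw
    }, numeric(1L))
    xs <- if (is.null(spec)) NULL else fxp(raw, spec)
  }
  n_in <- if (is.null(xs)) 0L else length(xs$raw)
  if (length(pws) != n_in)
    stop("weight and input sequences must have equal length")
  if (n_in == 0L && is.null(bias) && is.null(out_spec))
    stop("empty MAC needs an explicit out_spec or bias")
  cfg <- if (n_in > 0L) pws[[1L]]$config else NULL
  n_w <- if (is.null(cfg)) 0L else cfg$qspec$n
  n_x <- if (is.null(xs)) if (is.null(bias)) 0L else bias$spec$n else xs$spec$n
  frac <- n_w + n_x
  if (is.null(out_spec))
    out_spec <- if (!is.null(xs)) xs$spec else bias$spec
  acc <- 0
  psums <- 0
  for (i in seq_len(n_in)) {
    if (!identical(unclass(pws[[i]]$config$qspec), unclass(cfg$qspec)))
      stop("all weights must share one quantization format")
    dg <- .packed_digits(pws[[i]])
    for (k in seq_along(dg$pos))
      acc <- acc + dg$sgn[k] * xs$raw[i] * 2^dg$pos[k]
    psums <- psums + length(dg$pos)
  }
  if (!is.null(bias)) {
    stopifnot(inherits(bias, "fxp"))
    if (bias$spec$n > frac)
      stop("bias has more fraction bits than the accumulator")
    acc <- acc + bias$raw * 2^(frac - bias$spec$n)
  }
  out <- .readout(acc, frac, out_spec)
  .count(counter, psums = psums, sats = out$sat, macs = 1)
  fxp(out$raw, out_spec)
}
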