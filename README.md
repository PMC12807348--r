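# msdcnn

Minimum-signed-digit (MSD) weight approximation and bit-exact fixed-point
CNN inference, in R.

## The problem

Embedded hardware for always-on image classification — for example
low-power FPGA devices that monitor facial expressions on-device, without
sending images to a server — often cannot afford full combinational
multipliers. A multiply–accumulate (MAC) can instead be built from shifts
and additions: multiplying an activation by a weight costs one
shift-and-add **per nonzero digit** of the weight's representation. The
fewer nonzero digits a weight has, the cheaper every multiplication that
uses it.

The signed-digit (ternary) number system over {−1, 0, +1} makes weights
much sparser in this sense. The canonical minimal form is the
**non-adjacent form (NAF)**: no two adjacent digits are nonzero, and the
nonzero-digit count is provably minimal for the value. Writing the digit
for position *k* as *y<sub>k</sub>*,

```
w = Σ_k  y_k · 2^k ,   y_k ∈ {−1, 0, +1}
```

e.g. `7 = 0111₂` becomes `+00−` (8 − 1, two nonzero digits instead of
three), and `26 = 11010₂` becomes `+0−0+0` (32 − 8 + 2).

This package implements, as a software study of the scheme:

* **Recoding and truncation** — canonical NAF recoding of quantized
  weights, then truncation to the `p` most-significant nonzero digits
  (`p` = 3, 2, 1 are the studied budgets); every multiplication then costs
  at most `p` partial sums.
* **Packed storage** — a 16-bit container (`W_M` = 16) holding `p` sign
  bits plus `p` position fields, with the intermediate binary quantization
  width `W_b = W_M − p`; the Q(m, n) fixed-point format is chosen
  per-tensor and per-budget.
* **A bit-exact MAC model** — shift-and-add partial products, wide exact
  accumulation, binary bias addition, one round-to-nearest-even rescale
  and one saturation at read-out.
* **Error analysis** — normalized mean error distance (NMED: mean absolute
  product error over all operand values divided by the maximum exact
  output) from exhaustive 16-bit simulation, and nonzero-digit statistics
  of weight tensors (including the float32-mantissa counting convention).
* **A fixed-point inference simulator** — conv / depthwise / pointwise /
  linear layers computed by the MAC model with MSD weights; batch-norm,
  pooling and residual additions in plain Q-format arithmetic.
* **Synthetic fixtures** — a seeded 7-class, 48×48 grayscale dataset and
  miniature depthwise-separable CNNs, so the accuracy-vs-`p` trade-off is
  reproducible with no external data.

## A worked example

```r
library(msdcnn)

binary_to_msd(26)
#> <sdigit> +0-0+0  value = 26  nonzero = 3
truncate_msd(binary_to_msd(26), 2)
#> <sdigit> +0-000  value = 24  nonzero = 2

# full pipeline on a real-valued weight: quantize to Q(1,6), recode,
# keep 2 digits, pack into the 16-bit container
cfg <- approx_config(p = 2, W_M = 10, qspec = qformat(1, 6))
pw <- approximate_weight(0.40625, cfg)   # raw 26 -> +0-0+0 -> keep 24
decode_weight(pw)
#> [1] 0.375

# the MAC computes with shifts and adds only
w7 <- approximate_weight(7, approx_config(2, 8, qspec = qformat(5, 0)))
msd_multiply(w7, fxp(5, qformat(7, 0)), qformat(19, 0))$raw  # (5<<3) - 5
#> [1] 35

# exhaustive error of the approximate multiplier
nmed(p = 1, width = 3, signed_weights = FALSE)$nmed
#> [1] 0.04464286          # = 2.1875 / 49, enumeration over all 64 pairs
print(nmed(p = 3, width = 16))
#> <nmed_report> p = 3, width = 16 (signed weights, raw domain)
#>   NMED: 0.00128584 (fraction)  =  0.1286%
#>   mean |error|: 2.76128e+06   max output: 2.14745e+09
```

End-to-end on synthetic data:

```r
ds <- make_dataset(fixture_config(seed = 1))     # 7 classes, 48x48, seeded
model <- train_model(make_model(seed = 1), ds$train$images, ds$train$labels,
                     epochs = 50)
for (p in c(3, 2, 1)) {
  qm <- quantize_model(model, p, ds$train$images)
  print(evaluate_model(qm, ds$test))
}
```

Across five seeds this experiment gives median test top-1 of 0.857 for the
float reference and 0.857 / 0.857 / 0.690 at p = 3 / 2 / 1: three digits
per weight track the float model, a single digit per weight degrades
sharply — the software analogue of the hardware study's accuracy ladder,
at one shift-and-add per weight instead of a full multiply.

A command-line wrapper exposes the same operations
(`exec/msdcnn encode | nmed | weight-stats | quantize | simulate |
fixture`); reports are deterministic JSON given a seed.

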