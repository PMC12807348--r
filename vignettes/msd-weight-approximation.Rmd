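---
title: "Minimum-signed-digit weight approximation: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum-signed-digit weight approximation: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(msdcnn)
```

This vignette is the package's own account of the method it implements:
the number-theoretic model, the fixed-point arithmetic conventions, the
choices made where the design was genuinely open, and what the synthetic
experiments do and do not show.

## 1. Signed digits and why minimality matters

A shift-and-add MAC unit computes `w · x` as a sum of copies of `x`
shifted by the positions of the nonzero digits of `w`. Its cost is
therefore the **nonzero-digit count** of the weight, not the weight's
width. Over the binary digits {0, 1} an n-bit weight averages n/2 nonzero
digits; over the signed digits {−1, 0, +1} far fewer are needed, because a
run of ones collapses into two digits (`0111 → +00−`).

The recoder implemented here produces the **non-adjacent form** (NAF),
computed right-to-left: if the residual value is odd, emit the digit
`d = 2 − (v mod 4)` (so `d ∈ {+1, −1}` and `v − d` is divisible by 4),
else emit 0; halve and repeat. The NAF is the unique signed-digit form
with no two adjacent nonzero digits, and its nonzero count is minimal
among *all* signed-digit representations of the value — the package's test
suite verifies this exhaustively at 12 bits against a brute-force
enumeration of every signed-digit vector. Two consequences used
throughout:

* a width-`n` NAF has at most `⌈n/2⌉` nonzero digits, so an eight-digit
  MSD number carries at most four — equivalently, four partial sums;
* recoding an `n`-bit binary value may carry one position past its MSB
  (7 → 8 − 1), so recoder outputs are `n + 1` digits wide. Values whose
  recoding uses that ninth digit (e.g. 171 = 256 − 85) are nine-digit MSD
  numbers and may carry five nonzero digits; the four-digit bound is a
  statement about eight-digit outputs.

**Truncation.** Keeping only the `p` most-significant nonzero digits and
zeroing the rest caps the per-multiply cost at `p` partial sums. Because
NAF digits at positions below the leading digit alternate sparsely, the
absolute truncation error is bounded by `2^(k−p+1)` where `2^k` is the
leading-digit weight (verified exhaustively at 12 bits). Each discarded
digit shrinks the mean error by roughly a factor of six.

## 2. Quantization and the packed container

Float weights are first quantized to a Q(m, n) fixed-point format: `raw =
round(w · 2^n)`, ties rounded half away from zero, then clamped. The
container width is fixed at `W_M` = 16 bits; since each retained nonzero
digit spends one sign bit, the binary quantization width is `W_b = W_M −
p`, so **each approximation level quantizes the float weights separately**
(p = 3 → 13-bit, p = 2 → 14-bit, p = 1 → 15-bit quantization).

Per tensor, `m` is chosen as the smallest integer with `2^m` strictly
greater than `max |w|` (this keeps an exactly-representable power-of-two
maximum, such as a weight of 1.0, exact) and `n = W_b − 1 − m`, signed.
Negative weights are recoded by magnitude with all digits negated — signed
digits make negation closed, so no separate sign convention is needed
downstream.

**Packed layout (bit-exact).** With `b = ⌈log₂(W_b + 2)⌉` the position
field width, the `W_M`-bit container read MSB-first is

```
[ s_1 … s_p | q_1 … q_p | zero padding ]
```

where slot *j* holds the *j*-th most-significant nonzero digit: sign bit
`s_j` (1 = −1) and position field `q_j` = position + 1, with `q_j = 0`
marking an unused slot. Storing position + 1 rather than the raw position
is deliberate: with raw positions, an unused slot and a genuine
least-significant digit at position 0 would both read (sign 0, position 0)
and a weight such as raw 3 = `+0−` would be irrecoverable. Under the
chosen encoding the all-zero container is the unique encoding of the zero
weight and packing/unpacking is the identity on every truncated digit
vector — tested exhaustively over the full `W_b`-bit range for p ∈ {1, 2,
3}. The layout fits with room to spare: 15 bits at p = 3, 10 at p = 2, 6
at p = 1.

## 3. The MAC model

The emulated multiplier takes the weight in packed MSD form and the
activation as a plain binary Q-format number, and produces a Q-format
activation:

1. one shifted add/subtract of the input raw value per nonzero weight
   digit (the partial sums; an instrumented counter verifies the count
   equals the weight's nonzero digits);
2. exact accumulation in a wide accumulator — partial products carry
   `n_w + n_x` fraction bits, and doubles are exact far beyond the
   `2·W_M + log₂(fan-in)` bits required;
3. binary bias addition, the bias raw value aligned to the accumulator's
   fraction bits;
4. one rescale to the output format with round-to-nearest-even, and one
   saturation at read-out.

Two points were genuinely open in the hardware description and are fixed
here as emulation conventions. *Where to saturate:* saturating once at
read-out (rather than per partial sum) makes the result independent of
accumulation order, which both matches an adder-tree implementation and
makes the arithmetic testable; the property suite checks order
independence and pre-saturation equality with plain integer
multiplication, exhaustively at 8-bit operands. *How to shift back:* the
product of Q(m₁,n₁) and Q(m₂,n₂) carries n₁+n₂ fraction bits; the
shift back to the activation format uses round-to-nearest-even, the
convention that avoids the systematic bias of truncation.

## 4. Error analysis

**NMED** (normalized mean error distance) is the mean absolute difference
between the exact and the approximate product over all operand pairs,
divided by the maximum exact output. Because the inputs are nonnegative
and the error is `|w − ŵ| · x`, the double sum factorizes as
`mean(|w − ŵ|) · mean(x)`, which makes the exhaustive 16-bit computation
O(2¹⁶); the pairwise brute force (feasible to width 12) is kept as an
independent oracle and agrees exactly.

Conventions, both exposed as arguments rather than hard-wired, since the
source description pins down neither: the weight domain is by default the
signed 16-bit range (activations are the unsigned range, matching
post-ReLU values), and the weight may optionally be requantized to `W_b`
bits first (`weight_domain = "qformat"`); at 16 bits the two domains agree
to about four digits. On the percent scale the exhaustive values are
0.1286 / 0.7716 / 4.630 for p = 3 / 2 / 1 — each digit of budget buys
almost a factor six of accuracy. The reporting object carries both the
fraction and the percent value.

**Digit statistics** count, per weight tensor, nonzero digits under four
conventions: explicit IEEE-754 single-precision mantissa bits (the 23
stored bits that feed a mantissa multiplier; exponent and hidden bit
excluded), the binary Q-format quantization, the full NAF, and the NAF
truncated at each requested `p` (each with its own `W_b`). The truncated
counts are bounded by `p ×` (number of weights) by construction, and the
reduction ratio `1 − after/before` quantifies the saved shift-and-add
operations.

## 5. Fixed-point inference

Layer placement follows the hardware design: convolution (regular,
depthwise, pointwise) and fully connected layers use MSD weights and the
MAC model; batch normalization (folded at quantization time into a
Q-format scale and shift, avoiding division at inference), average pooling
(integer mean, round half up) and residual additions use plain saturating
Q-format arithmetic; ReLU/ReLU6 clamp raw values.

Activations are 16-bit signed Q-format numbers whose per-layer formats are
fixed by a max-absolute calibration pass of the float model over one batch
of images. Images enter as 8-bit grayscale and are mapped by `x/255 − ½`
— zero-centered rather than `[0, 1]`, a choice made for the trainability
of the fixture models (below) and absorbed entirely by the input format.

Inside a layer the whole computation is expressible as the MAC contract
(the suite checks random conv outputs element-by-element against `mac()`
over the receptive field, and whole layers against an integer-convolution
oracle), but is executed as an im2col matrix product on the decoded raw
weights, which is mathematically identical because the accumulator never
saturates intermediately.

The on-disk model container stores the manifest (formats, configuration)
as JSON plus raw little-endian tensors; quantized containers store **only
the packed payloads** for conv/linear weights — exactly what the hardware
keeps in on-chip memory — and decoded weights are reconstructed bit-exactly
on load.

## 6. Synthetic fixtures and what they show

The dataset emulates the *shape* of a small facial-expression benchmark —
48×48, 8-bit grayscale, seven classes — with no faces: each class is a
fixed oriented grating (orientation k·π/7, frequency 3–5 cycles) plus a
centered positive or negative Gaussian blob, and samples differ only by
i.i.d. Gaussian pixel noise. Class identity therefore lives in both
spatial structure (exercising depthwise kernels) and cross-channel
combinations after the stem (exercising pointwise kernels). With the noise
switched off the classes are linearly separable and a template matcher is
perfect; the default noise (sd 0.45 on the [0, 1] scale) was chosen once
so that the trained miniature lands in the 0.7–0.9 top-1 regime of the
full-scale reference models, and was not revisited.

The miniature model is a depthwise-separable CNN (3×3 strided stem,
two depthwise + pointwise stages with pooling, linear head; six weight
tensors, He-initialized). Training is full-batch Adam on softmax
cross-entropy, 50 epochs by default. Plain momentum gradient descent was
found to sit at the uniform-logit saddle of this task at every learning
rate tried; Adam's per-parameter scaling escapes it reliably, and a
"minimal trainer" that cannot fit its own fixture task would be useless,
so Adam it is. Training runs on 168 images in a few tens of seconds.

The headline experiment trains five seeded miniatures, quantizes each at
p = 3, 2, 1, and evaluates fixed-point inference on the held-out split.
At the frozen study conditions the median test top-1 is 0.857 (float),
0.857 (p = 3), 0.857 (p = 2) and 0.690 (p = 1): the three- and two-digit
budgets track the float reference while the one-digit budget collapses
the accuracy. Individual seeds vary widely (0.49–0.92 for the float
model), which is why the assertions are on medians.

What this does **not** show: absolute accuracies of full-scale
architectures on real face data. A six-tensor miniature on separable
synthetic textures is far more robust to weight distortion than a deep
network on a hard benchmark — the p = 1 collapse here (≈ 17 points) is
much milder than the collapse reported for full-scale models (≈ 35
points), and the relative robustness of deeper architectures cannot be
studied at this scale at all. The fixture experiment validates the
*machinery* (bit-exact arithmetic, monotone degradation, the cost model)
and the *direction* of the trade-off, not the magnitudes.

## 7. Numerical conventions, sizes, and limitations

Rounding modes, in one place: weight quantization rounds half away from
zero then saturates; MAC read-out and batch-norm rescaling round half to
even then saturate; average pooling rounds half up (toward +∞); all
counters and accumulators are exact.

Problem sizes used by the shipped tests and the acceptance script, chosen
to keep the full run in a few minutes of one CPU: exhaustive sweeps at 16
bits for roundtrip/non-adjacency/NMED, 12 bits for minimality and the
truncation bound (against a 3¹³-vector brute-force enumeration), 8-bit
operands for the MAC oracle; five seeds × 50 epochs for the degradation
experiment.

Known limitations: formats wider than 52 bits are rejected (double
exactness); the trainer supports exactly the layer kinds the fixtures use
(no batch-norm or residual training — both are supported in inference and
folded/aligned at quantization time); `p` must satisfy the packed-layout
inequality `p · (1 + ⌈log₂(W_b+2)⌉) ≤ W_M`, which for the 16-bit container
admits p ≤ 3 — precisely the studied range; and NMED's exhaustive path is
limited to 16-bit operands by design.
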