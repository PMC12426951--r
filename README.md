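# dredct

Block-wise **dynamic-range-enhancing DCT** for leaf-disease image analysis,
with the full classification pipeline around it: image IO, augmentation, a
trainable patch-feature classifier, stratified 5-fold cross-validation with
confusion-matrix metrics and a Welch t-test, a block-size ablation sweep,
and a seeded synthetic leaf-image generator so everything runs offline.

## The problem and the method

Some foliar diseases of bean (angular leaf spot, bean rust) show up as
fine, low-contrast texture that is hard to see — for the eye and for a
classifier. The idea implemented here is a preprocessing transform that
amplifies exactly that texture before classification.

The standard orthonormal 1D DCT pair is

```
y(k) = sqrt(2/N) * a(k) * sum_n x(n) cos((2n+1) k pi / 2N)      (forward)
x(n) = sqrt(2/N) * sum_k a(k) * y(k) cos((2n+1) k pi / 2N)      (inverse)
```

with `a(0) = 1/sqrt(2)`, `a(k) = 1` otherwise. The enhancement variant
re-weights both directions: the forward transform multiplies coefficient
`k` by `N/(N+k)` and the inverse by `N/(N-k)`. Composing forward then
inverse is therefore **not** the identity — each standard-DCT coefficient
is amplified by the closed-form gain

```
g(k) = N^2 / (N^2 - k^2),   k = 0 ... N-1
```

so the block mean is untouched (`g(0) = 1`) and the highest frequency is
boosted most (`g(15) = 256/31 ≈ 8.26` for `N = 16`). Applied separably to
the rows and columns of each `16x16` block of each RGB channel, this
raises the dynamic range of high-frequency detail — lesion texture —
while leaving smooth content alone. The `16x16` block size matches the
`16x16` patch grid of a patch-based transformer backbone on `224x224`
inputs (`N = HW/P^2 = 196` patches).

## Worked example

```r
library(dredct)

x <- c(10, 0, 0, 0)            # an "edge" inside a 4-sample block
round(forward_dct(x), 4)       #  5.0000 6.5328 5.0000 2.7060
round(forward_dre_dct(x), 4)   #  5.0000 5.2263 3.3333 1.5463  (k-th scaled by N/(N+k))
round(enhance_1d(x), 4)        # 12.0593 -2.9883 1.3217 -0.3926 (contrast stretched,
sum(enhance_1d(x))             # 10                              sum/mean preserved)
round(composite_gain(4), 4)    #  1.0000 1.0667 1.3333 2.2857
```

The enhanced signal swings from 12.06 down to −2.99 where the input fell
from 10 to 0: the step is steepened (dynamic range increased) without
moving the mean. On images the same happens per block:

```r
m   <- generate_dataset(60, side = 224, seed = 1, dir = tempfile())
cfg <- train_config(learning_rate = 0.05, seed = 1)   # Adam, batch 16, 10 epochs
cv0 <- run_cross_validation(m, cfg)                               # plain
cv1 <- run_cross_validation(m, cfg, enhancement = enhancement_config())
cv0$mean_accuracy   # 0.9889
cv1$mean_accuracy   # 0.9944
```

On the synthetic three-class dataset (healthy / blotch / speckle texture
analogues) the enhanced pipeline matches or beats the plain one; the gap
is small because the tiny backbone's band-energy features are already
frequency-aware. `ablate_block_size(m, c(8, 14, 15, 16), cfg)` sweeps the
block size on one fold (size 15 exercises reflect-padding of the 224x224
plane to 225x225).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the synthetic dataset from scratch, runs the 5-fold
cross-validation with and without enhancement, compares the two arms with
a Welch t-test, runs the block-size ablation over {8, 14, 15, 16}, prints
all results, and writes the machine-readable report to `--out`
(~1 minute on one CPU).

A thin CLI over the same functions lives at `inst/cli/dredct.R`
(`generate`, `enhance`, `ablate` subcommands).
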