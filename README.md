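# claheseg

Contrast enhancement and CNN segmentation of kidney CT slices, built
around a *modified CLAHE* preprocessing step: instead of fixing the two
CLAHE parameters by hand, the package searches a grid of tile counts and
clip limits, scores every enhanced variant with a no-reference image
quality measure (lower = better), picks the per-image argmin, and
aggregates per-image winners into dataset-level parameters by frequency.
The enhanced images feed a small convolutional encoder–decoder that
labels each pixel as kidney / non-kidney; predicted masks are refined by
binary erosion followed by morphological opening and scored with the
standard overlap metrics.

## The method in brief

**Histogram equalization.** For an image with `L` gray levels, `M×N`
pixels and histogram `h(r_k) = n_k`, the equalization map is

    s_k = (L − 1) · Σ_{j≤k} p(r_j),      p(r_j) = n_j / (M·N)

rounded half-up. CLAHE applies this map per tile of an `NT × NT` grid
after clipping each tile histogram at `T = max(1, ⌈CL · tile_pixels⌉)`
and redistributing the excess uniformly over all bins; pixel values are
bilinearly interpolated between the four nearest tile-center maps. With
`NT = 1, CL = 1` this reduces exactly to global equalization.

**Parameter selection.** Candidates `A_j[i] = (NT_i, CL_i)` are drawn
from the grid NT ∈ {2, 4, …, 24}, CL ∈ {0.01, …, 1.00}. With quality
scores `B(i)`,

    m = argmin_i B(i),    X_j^NL = A_j[m][NL],    X_j^CL = A_j[m][CL]

and the dataset-level parameters are the most frequent `(NL, CL)` pair
over the per-image selections. A raw-image baseline candidate guarantees
selection can never be worse than no enhancement.

**Quality scoring.** The BRISQUE feature pipeline is implemented in
full: MSCN coefficients `(I − μ)/(σ + 1)` with a 7×7 Gaussian window
(σ_w = 7/6), symmetric GGD moment-matching for the MSCN field and
asymmetric GGD fits for four orientations of pairwise products, at two
scales — 36 features. The regressor on top is pluggable: a linear
coefficients file, a packaged fallback (standardized distance to a
reference feature population), or a caller-supplied stub for testing.

**Segmentation.** A three-stage encoder (32/64/128 filters, 3×3
kernels, valid/same/valid padding, 2×2 max pooling, batch norm + ReLU;
on a 256×256 input the feature maps are 254×254×32 → 63×63×64 →
30×30×128) with a mirrored upsampling decoder and per-pixel sigmoid.
Training uses Adam (lr 0.001), batch size 32, binary cross-entropy, up
to 50 epochs with early stopping (patience 10). Masks are refined with
`open(erode(B, S), S)` (default 3×3 square element) and evaluated with
Dice, IoU, accuracy, precision, sensitivity and specificity.

## Worked example

```r
library(claheseg)

# a low-contrast noisy phantom with known ground truth
ph <- generate_phantom(phantom_preset("low_contrast", side = 64))

# grid-search CLAHE parameters under the fallback quality scorer
grid <- param_grid(c(2L, 4L, 8L), c(0.01, 0.05, 0.25, 1))
tab <- evaluate_candidates(ph$image, grid, scorer_spec("fallback"))
sel <- select_best(tab)
c(sel$nt, sel$cl, sel$score)
#> [1] 2.000000 0.010000 1.214599
quality_score(ph$image)   # raw image scores worse (higher)
#> [1] 1.805117

enhanced <- apply_clahe(ph$image, clahe_params(sel$nt, sel$cl))

# train the segmenter on easy phantoms and evaluate held-out Dice
bench <- run_easy_benchmark(n_train = 200, n_test = 50, seed = 42)
bench$mean_dice
#> [1] 0.9696386
```

The selected `(NT = 2, CL = 0.01)` is a mild enhancement — a small clip
limit keeps noise amplification down while stretching the narrow
low-contrast histogram — and lowers the no-reference quality score from
1.81 to 1.21. The benchmark trains the CNN on 200 synthetic
high-contrast phantoms and reaches a mean Dice of 0.97 on 50 held-out
phantoms.

A command-line interface wrapping the same functions is installed at
`system.file("cli", "claheseg", package = "claheseg")` with subcommands
`synth`, `enhance`, `optimize`, `train`, `segment`, `postprocess` and
`evaluate`.

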