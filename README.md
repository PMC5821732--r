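# hicsr — resolution enhancement of Hi-C contact matrices

`hicsr` reconstructs high-sequencing-depth Hi-C contact matrices from
shallow ones. A Hi-C experiment summarizes chromosome folding as an
n × n symmetric matrix of contact counts between fixed-size genomic bins
(10 kb here); at low sequencing depth the fine structure — topologically
associating domains (TADs) and focal chromatin loops — is buried in
sampling noise. Because contact frequencies depend strongly on their
neighbouring matrix entries, a model trained on one deeply sequenced
matrix can restore that structure in a shallow matrix at the same bin
size. The package is aimed at anyone who has a low-depth intra-chromosomal
contact map and wants a denoised, structure-preserving estimate of the
deeply sequenced equivalent.

## The model

The enhancer is a three-layer valid convolutional network applied to
40 × 40 bin windows:

    F1(X) = max(0, w1 * X + b1)      16 filters, 5 × 5
    F2(X) = max(0, w2 * F1(X) + b2)  16 filters, 1 × 1
    F3(X) = w3 * F2(X) + b3          1 filter,  9 × 9

No layer pads its borders, so the 40 × 40 input shrinks to a 28 × 28
output registered at the same centre; each output cell sees a 13 × 13
input neighbourhood. Parameters are Glorot-initialized and trained with
mini-batch SGD (momentum 0.9) on the mean squared error against the
deep-matrix windows. Overlapping windows tile each chromosome (stride
28 = 40 − 12), predictions are merged by averaging overlaps, and
everything outside the 2 Mb diagonal band falls back to the input.
Supporting modules provide dense/triplet text matrix I/O, binomial read
thinning (to simulate shallow libraries and pick enhancement tiers),
classical smoothing and random-forest baselines, distance-stratified
Pearson/Spearman evaluation, virtual-4C track extraction, and a synthetic
chromosome simulator (power-law distance decay, TADs, loops, Poisson
counts) that supplies ground truth for end-to-end testing.

## Worked example

```r
library(hicsr)

spec <- synthetic_spec()                  # 4 Mb chromosome: 8 TADs, 12 loops
pair <- make_pair(spec, fraction = 1/16)  # deep matrix + 1/16-depth copy

geom    <- patch_geometry()               # 40x40 in, 28x28 out, 2 Mb band
patches <- extract_patches(pair$low, pair$high, geom)
fit     <- net_train(patches, train_config(max_epochs = 300, patience = 300,
                                           select = "final", seed = 7))
enh     <- enhance(pair$low, fit$params, geom)

res <- summarize_methods(pair$truth, list(
  downsampled = pair$low,
  enhanced    = enh,
  gaussian    = gaussian_smooth(pair$low)))
res$summary
#>        method mean_pearson mean_spearman n_distances
#> 1 downsampled        0.221         0.199         109
#> 2    enhanced        0.704         0.533         109
#> 3    gaussian        0.562         0.455         109
```

The summary rows are mean per-distance Pearson/Spearman correlations
against the simulator's noise-free contact intensity, over the 109
distances where that intensity varies along the diagonal: thinning to
1/16 depth destroys most per-distance structure (0.22), generic
Gaussian smoothing recovers part of it (0.56), and the trained network
recovers most of it (0.70) — and beats the thinned input at every
individual distance between 30 kb and 1 Mb. (Exact values vary in the
second decimal with the training seed.)

The same pipeline is scriptable from a shell via the bundled `hicsr`
command (`exec/hicsr` after installation): `simulate`, `downsample`,
`train`, `enhance`, `baseline`, `evaluate`, `v4c`. Every command writes a
JSON run manifest (inputs, parameters, seed, version) next to its output.

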