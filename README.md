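# slicmmed

Segmentation of multi-colour ("confetti") muscle fibres in multi-channel
fluorescence microscopy.

Confetti labelling marks clonal lineages with four fluorophores of
distinct subcellular localization — green in nuclei, yellow and red in
the cytosol, cyan on the membrane.  Regenerated muscle imaged this way
shows tightly packed fibres with blurry borders, huge brightness
variation, same-colour neighbours separated only by a thin cyan membrane,
and artifacts such as ice-crystal holes.  `slicmmed` implements a
superpixel-based framework for segmenting the fibres in such images and
for scoring segmentations against ground truth, for microscopists and
image-analysis researchers working with multi-colour lineage-tracing
data.

## The method

**SLIC-MMED** (simple linear iterative clustering on multi-channel
microscopy with edge detection) clusters the pixel feature vectors
[c, y, r, x, y] — cyan/yellow/red intensities plus position; the green
(nuclear) channel is segmented separately — with the edge-augmented
distance

    D' = sqrt( (d'_c / m)^2 + (d_s / S)^2 + alpha * d_e^2 )

where `d'_c` and `d_s` are the colour and spatial Euclidean distances,
`S = sqrt(N/K)` the seeding interval, `m` the compactness (default 20),
`alpha` the edge weight (default 20), and `d_e` the maximum edge
probability along the line joining pixel and centroid.  With a zero edge
map this reduces exactly to plain SLIC.  Superpixels are then merged
into fibres wherever the chi-squared distance between per-channel
intensity histograms

    chi2(P,Q) = 1/2 * sum_k (P_k - Q_k)^2 / (P_k + Q_k)
    D_C(i,j)  = sqrt(chi2_c^2 + chi2_y^2 + chi2_r^2)

is small *and* both directed border edge strengths `E_ij`, `E_ji` are
low, subject to a size cap waived for background regions.  Two
scriptable refinement operations (merge-along-curve, restore
superpixels) replace the original interactive step.  Evaluation follows
the standard superpixel and segmentation scores: boundary recall
(d = 2 px), under-segmentation error, Dice coefficient, median Dice over
ground-truth segments (medDSC) and DSC_X.

A synthetic fixture generator (`generateMosaic`, `generateLateral`)
produces confetti-like images with exact ground truth, so the entire
pipeline is testable without any imaging data.

## Worked example

```r
library(slicmmed)

# a 512x512 four-channel confetti-like mosaic with known ground truth
fx <- generateMosaic(mosaicSpec(seed = 11))
fx$image
#> MultiChannelImage: 512 x 512 px, 8-bit source, channels: cyan, green, yellow, red
#>   declared scale [0, 255]

res <- runPipeline(fx$image, pipelineConfig(K = 800), gt = fx$gt)
print(res$report)
#> EvalReport: boundary recall 0.981 | under-seg error 0.0686 | medDSC 0.945
#>   good segments (DSC > 0.70): 39 / 40
#>   DSC_X: DSC_50=0.97 DSC_60=0.97 DSC_70=0.97 DSC_75=0.93 DSC_80=0.93 DSC_90=0.82
```

`boundary recall` is the fraction of ground-truth boundary pixels within
2 px of a predicted superpixel boundary (1 would be perfect adherence);
`under-seg error` measures how much predicted regions flood across
ground-truth borders (0 is perfect); `medDSC` is the median Dice overlap
between each true fibre and its best-matching segment, and `DSC_75` the
fraction of fibres recovered with Dice >= 0.75.  A fibre with DSC > 0.70
counts as well segmented.  One scripted refinement stroke on the worst
fibre raises medDSC further:

```r
act <- worstRegionAction(res$segments, fx$gt)
refined <- applyRefinement(res$segments, res$superpixels, list(act))
medianDice(refined, fx$gt)$medDSC
#> [1] 0.9465655
```

A command-line interface wrapping the same functions is installed at
`inst/cli/slicmmed` (subcommands `segment`, `evaluate`, `sweep`, `synth`,
`refine`).

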