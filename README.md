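# kinseg — consensus-based kinetic image segmentation

`kinseg` is an R package for unsupervised segmentation of 2D grayscale
images — geometric test images and biomedical slices alike — aimed at
settings where annotated training data are scarce and a clustering-based
method is preferable to a learned one. It treats the pixels of an image as
an interacting particle system: pixel *i* carries a position
*x<sub>i</sub>* ∈ [−1,1]² and a static gray feature *c<sub>i</sub>* ∈ [0,1],
and particles attract each other under a bounded-confidence
(Hegselmann–Krause type) rule gated by two bounds,

P<sub>Δ₁,Δ₂</sub>(x<sub>i</sub>, x<sub>j</sub>, c<sub>i</sub>, c<sub>j</sub>) =
χ(|x<sub>i</sub> − x<sub>j</sub>| ≤ Δ₁) · χ(|c<sub>i</sub> − c<sub>j</sub>| ≤ Δ₂),

plus Gaussian noise of feature-dependent amplitude √(2σ²D(c)) modelling
aleatoric acquisition noise (D(0) = D(1) = 0, maximal mid-gray). The
dynamics are simulated with a Nanbu–Babovsky DSMC scheme (O(N) per step,
with an equilibrium stopping criterion on the L¹ variation of the
reconstructed phase-space density); the emergent spatial clusters are
painted back onto the pixel grid as a multilevel mask, binarized at a
region-of-interest percentile threshold, and cleaned by two-pass
morphological refinement. The three model parameters (Δ₁, Δ₂, σ²) are
calibrated by seeded random search against a choice of binary segmentation
metrics: Volumetric Dice, Surface Dice with boundary tolerance τ, Jaccard,
or F<sub>β</sub>.

See the vignette `vignettes/consensus-kinetic-segmentation.Rmd` for the
model, numerical conventions and design choices.

## Worked example

Segment the synthetic "white square on a blurry background" fixture with a
calibrated parameter triple and score the result:

```r
library(kinseg)

fx <- makeGeometricFixture("square", size = 64, blurScale = 0.1, seed = 2)
fx$image
#> GrayImage 64 x 64, features in [0.000, 1.000]
fx$mask
#> BinaryMask 64 x 64, 1024 foreground pixels

params <- kineticParams(delta1 = 0.606, delta2 = 0.196, sigma2 = 0.007,
                        dt = 0.1, tMax = 200, diffusion = "d1")
res <- segment(fx$image, params, gtMask = fx$mask, seed = 11)
res
#> SegmentationResult 64 x 64: 1024 foreground pixels, 101 clusters, threshold 1

evaluateMask(fx$mask, segmentationMask(res), metric = "surf_dice", tau = 1)
#> MetricReport (loss metric: surf_dice )
#>  vol_dice surf_dice   jaccard     fbeta       ppv       tpr 
#>         1         1         1         1         1         1 
#> loss = 0.0000
```

The 4096 particles aggregate into 101 spatial clusters; the bright square's
pixels all end in clusters of mean gray 1, the 10th-percentile threshold
lands at 1, and the recovered mask matches the ground truth exactly — every
metric is 1 and the loss is 0. Calibration from scratch reaches the same
zero loss:

```r
cal <- calibrate(fx$image, fx$mask,
                 space = geometricSearchSpace(pixelSpacing(particlesFromImage(fx$image)),
                                              nIter = 50L),
                 metric = "surf_dice", tau = 1,
                 params = kineticParams(0, 0, 0, dt = 0.1, tMax = 200,
                                        diffusion = "d1"),
                 seed = 42L)
bestLoss(cal)
#> [1] 0
```

A command-line front end with `fixtures`, `segment`, `evaluate` and
`calibrate` subcommands is installed as `exec/kinseg`.

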