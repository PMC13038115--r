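# ViTSeg3D

A pure-transformer U-shaped encoder–decoder for volumetric brain-tumor
segmentation of BraTS-style multimodal MRI, implemented in R with a
hand-derived reverse-mode training core, an analytic parameter/FLOP
accountant, a seven-metric evaluation suite, NIfTI I/O and preprocessing,
and a synthetic tumor-phantom generator that makes the whole pipeline
testable at desk scale on one CPU.

It is aimed at methods researchers and engineers who want a transparent,
dependency-light reference implementation of this architecture family —
every layer, gradient and metric is inspectable R (plus one compiled
distance transform) — rather than a production training system.

## The model

The input volume (channels T1ce, T2, FLAIR) is split into
(2×4×4)-voxel patches, each linearly embedded into C = 96 channels. Three
encoder stages interleave transformer blocks with patch-merging layers
(every spatial extent halves, channels double), a bottleneck at feature
size 8C = 768 keeps resolution constant, and a mirrored decoder with patch
expansion and skip fusion restores the input resolution, ending in
per-voxel class scores for the four BraTS classes {0, 1, 2, 4}.

Each block applies, with residual connections and pre-norm layout:

1. dynamic position encoding — a depthwise 3×3×3 convolution added back
   to the feature map;
2. **windowed multi-head self-attention** over non-overlapping
   p_D×p_H×p_W windows (default 2×8×8):
   softmax(QKᵀ/√d + B) V per head, with a learned relative-position
   bias B — cost 4ΩC² + 2NΩC for Ω patches and N patches per window,
   linear in Ω;
3. an MLP (expansion 4, GELU);
4. **dilated-window attention**: every r-th patch per axis (default
   r = 2) within an (rp)³-patch block forms a window of the same N
   patches, so the receptive field grows r-fold per axis at unchanged
   cost, and the residue classes tile the grid exactly;
5. a second MLP.

Training minimizes a dice + focal hybrid loss
(λ₁·L_dice + λ₂·L_focal, λ₁ = λ₂ = 1) on label-smoothed targets with
Adam, plateau-scheduled learning rate, gradient clipping and DSC-based
early stopping. Evaluation reports DSC, HD95, sensitivity, specificity,
precision, normalized surface dice and mean absolute surface distance
over the nested WT/TC/ET tumor regions.

## Worked example

```r
library(ViTSeg3D)

cfg <- modelConfig()        # the published full-size configuration
describeModel(cfg, c(128, 128, 128))
#> CostReport
#>   parameters: 50.09 M (50,092,934 scalars)
#>   FLOPs per volume: 114.38 G at input [128x128x128]
#>   FLOPs per slice:  0.8936 G
#>   convention: 1 FLOP = 1 multiply-accumulate; normalization/softmax/activations excluded
```

50.09 M learnable parameters and 114.4 G multiply-accumulates per 128³
volume are the accountant's from-scratch walk over every layer of the
instantiated architecture — within about 1 % of the published 50.56 M /
115.51 G budget for this configuration.

```r
# a synthetic case: nested ellipsoidal tumor in a noisy 4-modality "brain"
case <- generatePhantom(phantomSpec(c(48, 48, 48), tumorFraction = 0.06,
                                    seed = 7), id = "demo")
tumorFraction(case$labels)
#> [1] 0.0597

# corrupt one fifth of the edema voxels and score against the reference
pred <- case$labels
drop <- which(pred == 2L); set.seed(1)
pred[sample(drop, length(drop) %/% 5)] <- 0L
evaluateSegmentation(pred, case$labels)
#>   region  DSC HD95    SE SP Pres   NSD  MASD
#> 1     WT 0.93    3 0.869  1    1 0.722 0.648
#> 2     TC 1.00    0 1.000  1    1 1.000 0.000
#> 3     ET 1.00    0 1.000  1    1 1.000 0.000
```

Only the whole-tumor region is touched by the corruption (edema belongs to
WT but not TC/ET): its overlap drops to DSC 0.93, the worst boundary error
is 3 mm (HD95), and the mean surface error is 0.65 mm (MASD), while TC and
ET stay perfect — exactly the region nesting the metrics are meant to
expose.

Small models train end to end on phantoms: a reduced configuration
(`embedDim = 16`) overfits a single 32³ phantom to whole-tumor DSC ≈ 0.95
within 200 optimization steps on one CPU (see
`tests/testthat/test-acceptance.R`).

A thin command-line wrapper in `inst/scripts/vitseg3d.R` exposes
`describe`, `simulate` (phantom suites as NIfTI), `split`, `train`,
`evaluate`, `predict` and `score` subcommands over the same functions.

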