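# imodmatch

Matched transcriptome–proteome iModulon analysis for bacterial omics
compendia.

Bacterial gene expression is organized into independently modulated gene
sets — **iModulons** — that independent component analysis (ICA) extracts
from a compendium of profiles. `imodmatch` brings the transcriptome and
the proteome into one frame: it estimates absolute protein abundances
from label-free intensities, compiles quality-controlled compendia for
both layers, decomposes each with robust ICA, matches proteome modules
(piModulons) to transcriptome modules (tiModulons), classifies which
layer dominates a matched signal, and infers how much of the proteome a
transcriptome module's genes occupy from that module's activity alone.
It is written for systems biologists who work with matched RNA-seq /
LC–MS/MS condition sets and want the whole chain — quantification to
allocation — reproducible and testable.

## The model

Each compendium is a features × samples matrix **X**, factored as
**X ≈ M·A**: columns of **M** are sparse gene-weight signatures whose
outlying weights (D'Agostino K² thresholding) define module membership;
rows of **A** are condition activities. Robustness comes from consensus
over many FastICA restarts (clustering pooled components at distance
1 − |r|). Upstream, protein amounts come from the UPS2-calibrated top3
model `log10(A) = a + b·log10(top3)` and close to a fixed budget
`C_i = γ·A_i/Σ_j A_j` with γ = 13.94 µmol·gDW⁻¹. Downstream, module
pairs match at gene-weight correlation |r| ≥ 0.25; differential
activities (DiMA) outside a 1.5-sd band classify pairs as
transcriptome-dominant, proteome-dominant, or neutral; and per module,
proteome mass fraction is regressed on activity under linear,
exponential, and broken-line families with leave-one-out
cross-validation choosing among them (strong when adjusted R² ≥ 0.3).
A seeded synthetic-data generator plants all of this structure so every
stage has a recoverable ground truth.

## Worked example

The default synthetic study: 2000 genes, 60 conditions × 2 replicates,
12 planted transcriptome modules, 8 proteome modules (one lumping two
transcriptome modules), one transcriptome-dominant and one
proteome-dominant perturbation.

```r
library(imodmatch)
res <- run_pipeline(list(seed = 1))
print(res)
#> matched-omics modularization pipeline
#>   transcriptome: 2000 features -> 12 robust components
#>   proteome:      667 features -> 8 robust components
#>   matched pairs: 7; dominance: neutral=5, proteome-dominant=2
#>   allocation fits: 12 (strong=9, weak=3)

head(res$recovery$modules, 4)
#>   module best_component     abs_r jaccard
#> 1   mod1           IC11 0.9993740       1
#> 2   mod2            IC7 0.9996184       1
#> 3   mod3            IC8 0.9994053       1
#> 4   mod4           IC10 0.9988732       1
```

Every planted transcriptome module is recovered essentially exactly
(weight correlation > 0.998, membership Jaccard 1). One strong
allocation fit in detail:

```r
summary(res$allocation$IC2)
#> Allocation regression for IC2
#>   selected family: broken_line (LOOCV MAE per family below)
#>      linear exponential broken_line
#>    0.042010    0.102800    0.006554
#>   parameters:
#>  breakpoint   intercept  slope_left slope_right
#> -1.86406000  0.03264360  0.00251382  0.06898510
#>   R^2 = 0.9897, adjusted R^2 = 0.9890 -> strong
#>   median normalized CV error = 0.0832
```

The broken line wins cross-validation by an order of magnitude in MAE —
this module was planted with a thresholded (broken-line) transcript→
protein mapping, and the fit recovers a flat segment below the
breakpoint and a steep response above it. `plot(res$allocation$IC2)`
draws the activity/mass-fraction scatter with the fitted curve.
`res$allocation_summary` gives the sequential proteome allocation
(strong modules first, each gene counted once; shares sum to 1).

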