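---
title: "Matched transcriptome-proteome modularization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched transcriptome-proteome modularization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imodmatch)
```

`imodmatch` decomposes matched bacterial transcriptome and proteome
compendia into independently modulated gene sets (iModulons), matches the
modules across the two omics layers, classifies which layer dominates a
matched signal, and regresses proteome mass allocation on transcriptome
module activities. This vignette is the package's own account of the
models it implements, the tunable parameters and why they default where
they do, what the synthetic-data generator does and does not emulate, and
the design decisions taken where the method left room.

## The model

Both compendia are treated as a features-by-samples matrix $X$. Robust
independent component analysis factors $X \approx M A$: the columns of
$M$ are sparse gene-weight signatures (iModulons, once thresholded) and
the rows of $A$ are their condition-dependent activities. ICA is the
right tool because regulatory signals are independently modulated and
their gene weights are heavy-tailed — a few strongly weighted genes
against a near-Gaussian background — which is exactly the non-Gaussianity
that blind source separation exploits.

### Absolute protein quantification

Label-free intensities enter as the top3 metric (the mean of a protein's
three highest peptide areas). A UPS2 spike-in standard of known amounts
calibrates top3 to absolute loaded amount per sample by ordinary least
squares in log space,

$$\log_{10} A = a + b \log_{10}(\mathrm{top3}),$$

and amounts become dry-weight concentrations by closing each sample to a
fixed total protein budget,

$$C_i = \gamma \frac{A_i}{\sum_j A_j}, \qquad \gamma = 13.94\ \mu\mathrm{mol\,gDW^{-1}}.$$

Calibration is fit per sample because each experimental sample carries
its own spike; a pooled fit is available (`calibrate_proteome(pooled =
TRUE)`). Downstream stages consume mass fractions ($A_i/\sum_j A_j$,
summing to 1 per sample); the $\gamma$-scaled concentrations are kept for
reporting. "Not observed" is distinct from zero throughout this stage —
imputation happens only during compendium compilation.

### Compendium compilation

The fixed pipeline is: drop features observed in strictly less than 50%
of samples; replace remaining missing cells with the global minimum
observed abundance (undetected proteins sit at the detection floor);
renormalize to fractions and transform to $\log_2(\mathrm{PPM}+1)$;
drop replicate groups whose pairwise squared Pearson correlation falls
below $R^2 = 0.9$ (in groups of three or more, single offending samples
are removed instead of the whole group); and center each batch on the
mean profile of a common reference condition, which removes batch
offsets while preserving within-batch contrasts exactly. Replicate
concordance is assessed on log-transformed values, matching the
transcriptome convention; centering is likewise done in log space.

### Robust ICA

FastICA (symmetric decorrelation, logcosh contrast) runs `n_runs` times
with distinct sub-seeds after PCA whitening to `k` dimensions. Pooled
components are clustered with a density-based rule at distance
$1 - |r|$ (neighborhood radius 0.1, minimum cluster size
$\lceil n\_runs/2 \rceil$); every cluster reproduced in at least half
the runs contributes its centrotype — the member most correlated with
the rest of its cluster. Signs are oriented so the largest-magnitude
weight is positive and columns of $M$ get unit norm; $A$ comes from the
pseudo-inverse projection $A = (M^\top M)^{-1} M^\top X$. Explained
variance is reported per component as
$1 - \lVert X - m_j a_j\rVert_F^2 / \lVert X\rVert_F^2$ on the centered
matrix and cumulatively from the full reconstruction; because components
are not exactly orthogonal the per-component values need not sum to the
cumulative one, so both are kept. Dimensionality selection runs the
decomposition over a candidate grid and takes the smallest `k` whose
count of robust multi-gene components is within one of the maximum — a
plateau rule standing in for the external workflow's criterion, which is
not published. Defaults: `n_runs = 10` for simulation-scale work
(increase to ~100 for production compendia), a mandatory master seed.

### Membership thresholds and the K-squared saturation scale

Members of a component are the weights that are outliers against a
normal background. The iterative rule removes the largest-magnitude
weight until the D'Agostino-Pearson $K^2$ statistic drops below a
cutoff, then places the threshold halfway between the last removed
weight and the largest remaining one. The conventional cutoff is 550.
One property matters when working below compendium scale: the two
z-transformations inside $K^2$ saturate, and the saturation plateau
grows with the vector length $n$ (roughly $9A/2$ in the kurtosis
branch, where $A$ grows with $n$). At $n \approx 500$ the plateau for
symmetric outliers sits near 370 — *below* 550 — so no member can ever
be called at the default. The default therefore suits feature sets of
roughly 600 and up (the proteome compendium clears it; full
transcriptomes clear it comfortably), and `k2_cutoff` should be lowered
(we use 100 in small examples) when thresholding shorter weight
vectors. Membership density matters too: modules holding ~10% of all
features depress $K^2$ because the "outliers" dominate the moments.

### Enrichment and categories

Regulator enrichment is a one-sided hypergeometric test of the overlap
between a module's members and each regulon restricted to the measured
background, Benjamini-Hochberg adjusted across regulons, with optional
pairwise regulon unions to capture jointly regulated modules
(combined labels are pairwise in practice, so deeper unions are left to
curation). A component is `regulatory` when its best adjusted p-value
passes $10^{-3}$ (the cutoff is configurable; no published value
exists), `technical/single-gene` at one member or fewer,
`biological`/`genomic` only via a curation table, `uncharacterized`
otherwise.

Invariance statistics use the raw mass-fraction scale: per protein, the
mean fraction and the coefficient of variation across samples; proteins
below CV = 1 are invariant. The compendium-statistics convention is
strict (CV < 1) and the allocation treemap convention is inclusive
(CV <= 1); both are exposed and no protein sits exactly at 1 in
practice.

### Cross-omics matching, DiMM, DiMA, dominance

Module pairs are matched by the Pearson correlation of their gene
weights restricted to the shared feature universe, at $|r| \ge 0.25$ —
deliberately permissive because weight distributions are non-uniform
across omics types; signs are arbitrary, so $|r|$ is compared and sign
alignment applied afterwards. A proteome module may match several
transcriptome modules (a lumped module). For matched analyses the
transcriptome decomposition should be recomputed on the shared features
and condition-matched samples (`matched_subset()`), centered on the
same reference.

DiMA compares replicate-averaged activities per condition. Both series
are standardized robustly (median and scaled MAD) and the differential
signal is the residual of the proteome series from a Huber-robust line
on the transcriptome series; conditions whose residual exceeds
`band = 1.5` standard deviations of the residual series are
differentially activated. Two design choices deserve a note. First,
robust scaling and a robust trend: with plain mean/sd standardization,
a handful of genuinely shifted conditions inflates its own scale
estimate and heavy-tailed activities leave a scale-mismatch term that
throws extreme spurious differences onto the *opposite* side of the
band; the robust versions remove both artifacts while reducing to the
plain standardized difference when the layers agree. Second, dominance
classification adds a one-sided exact sign test (level 0.05) to the
two-thirds majority rule: a 1.5-sd band flags roughly 13% of conditions
under pure noise, and a small symmetric set of such flags would
otherwise be promoted to a dominance call in over a quarter of neutral
pairs. Both the band width, the majority share, and the test level are
config-exposed; the band value itself is a documented stand-in, as no
published definition exists.

### Allocation regression

For each eligible transcriptome module (uncharacterized, genomic and
technical modules are skipped), the summed proteome mass fraction of
its covered genes, replicate-averaged per condition, is regressed on
the module activity under three families: linear; exponential
$y = c + a e^{bx}$ (three parameters, fit by Levenberg-Marquardt from a
log-linear initialization, with a mirrored decreasing-branch start);
and a continuous two-segment broken line whose breakpoint is found by
exhaustive search over interior observed activities with at least two
points on each side. Families compete by leave-one-out MAE. The default
tie rule is the one-standard-error rule: the simplest family whose MAE
is within one standard error of the best is selected. This is the
statistical reading of "ties go to the simpler family" — under a truly
linear signal the flexible families win the literal minimization on
noise alone in roughly 40% of draws, which says nothing about the data.
The literal minimizer remains available (`rule = "min"`). The winner is
refit on all conditions; adjusted $R^2$ uses 2/3/4 parameters for the
three families and `strong` means adjusted $R^2 \ge 0.3$. Normalized
cross-validation errors are $|y_{pred} - y_{test}|/\bar y$. Robustness
is probed by a holdout sweep (test fractions 0.10-0.30 in steps of
0.05, test size rounded half up, per-split seeds derived from the
master seed). No outlier conditions are removed by default.

Sequential allocation assigns each covered gene exactly once: strong
modules in descending adjusted $R^2$ (ties to the larger module), then
weak modules, then the remainder split into invariant (CV <= 1) and
other. Group shares therefore sum to one per sample before averaging.

## The synthetic generator

`generate_ground_truth()` plants: disjoint sparse transcriptome modules
(each 1-3% of genes, weights of mixed sign, unit-norm columns);
heavy-tailed Laplace activities (scale 2), mean-centered per module —
Laplace because ICA identifiability needs non-Gaussian sources; a
lumping map in which a configurable number of proteome modules union
two transcriptome modules; a mapping family per proteome module
(linear, exponential, broken line, round-robin) taking module activity
to module mass fraction; dominance perturbations that act
multiplicatively on the protein layer only (suppression factor 0.15 or
boost factor 3 in five conditions), mirroring post-transcriptional
regulation; and a log-normal baseline abundance spectrum whose top
third defines proteome coverage, with planted proteome-module genes
boosted into the covered tier, emulating detection of the most abundant
proteins. The proteome is generated directly in mass-fraction space
(modules take their mapped mass, background genes share the remainder
proportionally to baseline, samples re-closed to 1), so conservation
holds by construction; planted sector masses are jointly capped at 60%
of the proteome because exponential tails would otherwise outgrow the
budget. Default scale is 2000 genes, 60 conditions with 2 replicates,
12 transcriptome and 8 proteome modules, replicate noise
$\sigma = 0.02$ on the log scale — sized like a matched bacterial
compendium while fitting a single CPU comfortably. Scenario-level
helpers (`simulate_dima_scenario()`, `simulate_allocation_xy()`)
benchmark the dominance classifier (shift 3 activity units against
noise 0.25, a strong post-transcriptional effect well above replicate
noise) and the regression selector (57 conditions, noise 5% of the
response range) without rerunning ICA.

What the generator does **not** emulate: peptide-level
mass-spectrometry noise (spectral counting, missing-not-at-random
beyond top-abundance censoring), correlated module activities, overlap
between module gene sets, regulon databases with errors, or real batch
structure beyond a shared reference condition. Passing the recovery
benchmarks therefore demonstrates that the implementation is correct
and well-conditioned on data that satisfies the model's assumptions —
not that real compendia will reach the same recovery rates.

## A short tour

```{r tour, eval = FALSE}
gt <- generate_ground_truth(seed = 1)
cc <- generate_matched_compendia(gt)
res <- run_pipeline(list(seed = 1))
print(res)
res$recovery

fit <- res$allocation[[1]]
summary(fit)
plot(fit)
```

## Numerical choices and degenerate inputs

- Whitening keeps exactly `k` principal components (no shrinkage) and
  rejects `k` above the numerical rank.
- Non-convergent FastICA restarts are retried with fresh sub-seeds (up
  to 3 times) and then excluded with a warning.
- Exact LOOCV-MAE ties resolve to the simpler family by candidate
  order; exponential fits that fail to converge exclude that family for
  that module with a notice.
- Zero top3 intensities are unquantifiable and stay missing; an
  all-missing sample, an empty coverage filter result, a batch without
  reference samples, and a constant-variance matrix are all rejected
  with named errors.
- Proteins with zero mean fraction are excluded from CV statistics with
  a notice.
- Holdout splits that leave near-constant training activities are
  resampled (capped retries).

## Known limitations

Robust-component clustering assumes restarts land on comparable optima;
highly correlated planted modules can merge at the clustering radius.
The plateau rule for dimensionality is a stand-in and can under-select
when modules explain little variance. End-to-end family recovery on the
full synthetic pipeline is noisier than the regression-level benchmark
(lumped modules regress one constituent's activity against a mass
driven by two, and dominance perturbations add outlier conditions);
this is the expected behavior of the method, not an implementation
artifact. Pairwise regulon unions grow quadratically; enable them only
with modest regulon databases.
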