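---
title: "Multimodal pathomics-transcriptomics survival subtyping: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal pathomics-transcriptomics survival subtyping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `ptmfuse`, the
parameters that matter, the synthetic data the package tests itself on,
and the design decisions taken where the methodology was genuinely open.

# The pipeline

## PTM-restricted differential expression

`differential_expression()` restricts a log2-scale expression matrix to a
user-supplied list of post-translational-modification (PTM) related genes
with category labels, computes per-gene group differences (`log2fc`),
Welch two-sample t-test p-values and Benjamini–Hochberg FDR across the
tested PTM genes, and calls a gene significant when `fdr < 0.05` **and**
`|log2fc| > 1`. Both cutoffs are deliberate: the FDR gate controls the
multiplicity over the PTM panel, and the fold-change gate excludes
statistically crisp but biologically negligible shifts — a gene with
`log2fc = 0.9` is never significant, however small its p-value. We use a
self-contained Welch-t screen rather than an empirical-Bayes moderated
fit: with dozens of samples per group the moderation matters little, and
what downstream stages consume is exactly the stated decision rule, which
the simple screen implements without approximation. Genes with any
missing value are dropped at load time.

## Pathomics

Tiles are cut non-overlapping at `tile_size = 512` px, row-major, edge
remainders dropped (a partial tile would bias pooled statistics toward
padding). The tissue mask is Otsu's threshold on Rec.601 luminance with
tissue = darker side; a constant image has no separable classes and
yields an all-false mask with a warning. A tile is retained iff its
tissue fraction **strictly** exceeds `min_fraction = 0.80`.

Stain estimation follows the Macenko construction: optical density
`OD = -log10((I+1)/256)` (the +1 offset avoids `log 0` at `I = 255`... and
at `I = 0` the offset caps OD at `log10(256) ≈ 2.41`); pixels with any
channel below `beta_od = 0.15` are treated as unstained and discarded
(fewer than 100 qualifying pixels is an error); the stain plane is the
top-2 eigenvector span of the OD covariance; the extreme projection
angles at the 1st/99th percentiles (`alpha_pct = 1`) give the two stain
directions. One subtlety we hit in practice: the eigenvector sign is
arbitrary, and if the projection cone straddles the `atan2` branch cut
the percentile angles are meaningless — we therefore orient the first
plane axis so all projections are positive before taking percentiles.
Hematoxylin is identified as the blue-*appearing* stain, i.e. the column
absorbing more strongly in the red channel (larger red-OD component);
with standard H&E optical-density vectors the "more blue OD" reading
would label the stains backwards. Concentrations use exact two-column
nonnegative least squares (closed-form active set), and normalization
rescales them by the ratio of 99th-percentile reference maxima before
reconstructing through the reference stain matrix.

Deep features standardize each resized 224 x 224 tile with the ImageNet
channel statistics (mean 0.485/0.456/0.406, SD 0.229/0.224/0.225), run a
convolutional backbone mapping to a 7 x 7 x C grid, and max-pool each
channel over the grid. The backbone is a *contract*, not a fixed network:
anything that produces a 7 x 7 grid works, and `tiny_backbone()` provides
a seeded, frozen, He-initialized five-stage residual encoder. Tests use a
32-channel tail for speed; the release configuration
`channels = c(8, 16, 16, 32, 2048)` matches the 2048-channel final stage
of a ResNet-50-style extractor. Random frozen convolutional features are
weaker than pretrained ones but are deterministic, dependency-free, and
exercise every shape and pooling contract; swapping in pretrained weights
changes only the backbone argument. Slide-level aggregation is the
element-wise **mean** over retained tiles — the patch-to-patient reducer
is not standardized in this literature, and the mean is
duplication-invariant (`aggregate({v, v}) = v`), which we treat as the
defining sanity property. Whether the 11 morphometric variables should be
computed per tile or per slide is equally unstandardized; we compute them
per retained tile and report the per-slide mean.

The 11 curated morphometric descriptors (one representative per
measurement family: counts, size, shape, intensity, texture, radial
distribution) are: `nuclei_count`, `mean_nucleus_area`, `sd_nucleus_area`,
`mean_nucleus_perimeter`, `mean_nucleus_eccentricity`,
`mean_nucleus_solidity`, `mean_hematoxylin_intensity_in_nuclei`,
`mean_eosin_intensity_in_cells`, `glcm_contrast_hematoxylin` (8 gray
levels, 1-px offset, mean of 4 directions), `nuclear_density` (nuclei per
10^4 tissue px) and `mean_radial_intensity_cv` (CV of mean intensity over
4 concentric rings). These are reproducible, library-agnostic definitions
of the classic CellProfiler module families. Segmentation uses local-mean
adaptive thresholding (window defaulting to `2*d_max + 1` px so the
window always sees background around a nucleus — a smaller window hollows
out large nuclei), hole filling, watershed on the distance transform to
split touching objects, and an equivalent-diameter gate of 10–50 px.
Cell expansion is purely geometric nearest-seed propagation capped at
`max_expand` px; equidistant ties go to the smaller label,
deterministically. Zero nuclei yield count 0, density 0 and NA object
statistics.

## Fusion and the autoencoder

`assemble()` inner-joins the modalities on sample ID with `expr_`/`path_`
prefixes (collisions are impossible by construction); `split_cohort()`
draws a seeded 7:3 split. The autoencoder is symmetric: encoder
`d -> 128 -> 64 -> 32` with ReLU hidden activations and a **linear**
latent layer, mirrored decoder with linear output — the minimal standard
choice where the activation functions are not otherwise dictated.
Training minimizes mean squared reconstruction error with plain
mini-batch SGD (`batch_size = 64`, full batch when n is smaller;
`learning_rate = 0.001`; `epochs = 150`; inverted dropout 0.1 on hidden
activations during training only). Initialization is seeded
Glorot-uniform; per-epoch shuffling and dropout masks come from the same
seed, so the loss trace is bit-reproducible. Columns are z-scored with
statistics of the *training* table only, stored in the model and reused
verbatim at encode time; the validation path has no fitting method at
all, which enforces leakage-safety by API shape rather than discipline.
The latent space is the innermost 32-unit layer. We train on the training
partition only. Non-finite loss aborts with the epoch index. At the
default learning rate the reconstruction improves slowly by design
(stability over speed); tests that need a tightly converged model (e.g.
representing exact rank-3 data below MSE 0.05) raise the learning rate
and epochs explicitly rather than changing the release defaults.

## Survival modeling

`cox_fit()` maximizes the Breslow-ties partial likelihood for a single
covariate by Newton–Raphson (`|Δβ| < 1e-8`, 50 iterations max); monotone
likelihoods (perfect separation, detected as `|β| > 30` or a
non-positive information) are an error, not a huge coefficient. Screening
standardizes each latent dimension and keeps those with Wald
`p < alpha_screen = 0.05` — the conventional threshold, since no other
value is dictated; if nothing passes, the single smallest-p dimension is
kept with a warning so the risk score always exists. The risk score is
the standard linear predictor `risk = Σ β_j z_j` over selected
standardized dimensions — the natural reading of "Cox-screened latent
risk" — and the high/low cutoff is the training median, with ties going
to low risk. Subtyping fits diagonal-covariance Gaussian mixtures by EM
(10 seeded k-means++ restarts, variance floor 1e-6, empty components
re-initialized up to 3 times) for k = 2..6 and keeps the k maximizing
mean silhouette width (Euclidean, hard labels; ties to the smaller k).
Kaplan–Meier, the two-group log-rank test and the group hazard ratio
(`exp(β ± 1.96 se)` from the Cox fit on the group indicator) are computed
from first principles and cross-checked against `survival` in the tests.

## Interpretation

Feature contributions use permutation importance through the trained
encoder: baseline Harrell C of the risk score, minus the C after
permuting one input column (mean over `n_repeats` seeded permutations).
This is model-agnostic and deterministic given the seed, unlike
surrogate-model "gain" scores, and has the exact property that a feature
the encoder ignores scores 0. Importances do not sum to anything
meaningful; only the ranking is interpreted. Harrell's C counts pairs
where the shorter observed time has an event and times differ; risk ties
count one half. `spearman_map()` is Pearson on average-ties ranks;
constant columns get NA with a warning.

## Single-cell GRN and pseudo-knockout

QC order is fixed and documented: the gene filter (detected in
>= `min_cells = 10` cells) runs first, then cell filters on the filtered
matrix (detected genes in [200, 5000]; mitochondrial fraction <= 0.10,
mito genes recognized by the configurable `MT-` name prefix). Networks
come from principal-component regression: for each target gene, the
other genes' top `n_pcs = 20` PC scores (cells as observations) are the
regressors, and coefficients are back-projected through the loadings to
per-regulator weights; a rank-deficient basis reduces `n_pcs` with a
warning. The consensus stage subsamples `cells_per_net` cells
(`min(500, 70%)`), keeps the top `top_q = 0.05` fraction of entries by
magnitude per network, stacks `n_nets = 10` adjacencies into a tensor,
and denoises with rank-3 CP by ALS (seeded init, 100 iterations or
relative change < 1e-6; an error count of 5 consecutive increases
aborts); the averaged reconstruction is rescaled to `max|w| = 1`. The
retention rule (fraction, not count or absolute threshold) and all of
these constants are exposed configuration.

The knockout zeroes one regulator row. Alignment symmetrizes both
networks (`(|W| + |W^T|)/2`) and couples them through identity
cross-links of strength `mu` in a joint 2G x 2G graph; genes embed as the
`d_embed = 30` smallest nonzero eigenvectors of the joint Laplacian.
Two numerical choices matter here. First, `mu` must dominate the graph
spectrum: we use `mu = max(0.9 * mean(row sums), 1.05 * max(row sums))`,
because `2*mu` then upper-bounds the Laplacian spectrum of either
network, which guarantees that the anti-aligned pair modes (eigenvalue
>= `2*mu`) sit above every shared structural mode. Second, the coupling
band at `>= 2*mu` is excluded from the embedding; with a weak coupling
those pair modes leak into the bottom of the spectrum and assign spurious
displacement `sqrt(2)` to isolated genes even when the two networks are
identical. With both rules, aligning a network with itself is a zero map
to machine precision. Displacements are calibrated as
`delta_i^2 * G / sum(delta^2) ~ chi-squared(1)` (upper tail), BH-adjusted,
significant at FDR < 0.05; the knocked-out gene is excluded from both the
scaling and the ranking (its displacement is structurally the largest and
would deflate everyone else's statistic). A disconnected joint graph
gains a uniform 1e-8 coupling with a warning. Enrichment of the
perturbed set is a one-sided hypergeometric upper tail per gene set with
BH across sets.

# Synthetic data: what it emulates, what it does not

`make_slide()` renders white-background images whose tissue blob
(quantile-thresholded smoothed noise, hence exact area fraction) carries
eosin-rich stroma and hematoxylin-dominant elliptical nuclei, mixed
linearly in OD space through a known unit-column stain matrix. Nuclei
centers always lie in the tissue mask, radii in (3, 30] px,
center-to-center spacing enforced so objects do not touch. Rendered
concentrations are chosen so stained pixels clear the `beta_od` filter.
It does **not** emulate realistic histology texture, scanner artifacts,
pyramidal formats, or touching/overlapping nuclei.

`make_cohort()` draws latent factors `z ~ N(0, I)` that drive both
feature blocks (Gaussian linear mixing, noise SD 0.2 by default) and
survival: event times are exponential with hazard
`h0 * exp(z' beta_true)` at baseline `h0 = 0.01`/day (median ~70 days at
`beta = 0` — a deliberately compressed timescale; only ratios matter to
the Cox machinery), and censoring is exponential with its rate solved
numerically so the expected censoring fraction matches `censor_rate`.
The study conditions used throughout the recovery suites are n = 400,
k = 4 factors, one prognostic factor at `beta = 1.1`, 30% censoring —
chosen as a desk-scale cohort where a real effect should be comfortably
but not trivially detectable. Real cohorts add non-proportional hazards,
informative censoring and non-Gaussian features, none of which are
simulated; a passing suite shows the machinery is correct, not that TCGA
effect sizes will reproduce.

`make_sc()` draws steady-state expression `x = (I - W')^{-1} eps` from a
linear SEM with spectral radius < 1 (checked), shifts by `log 5`,
multiplies by lognormal(0, 0.3) library factors (so CPM scaling is
meaningful), and Poisson-samples counts. Optional mitochondrial genes and
planted QC violators (high-mito, low-complexity cells at recorded
indices) make the QC filters testable exactly. Dropout/zero-inflation
beyond Poisson sampling, cell types, and trajectories are not simulated.

All generators are pure functions of (arguments, seed) via
`withr::with_seed`; regeneration is byte-identical, and ground truth
(mask, nuclei, stain matrix, `beta_true`, the GRN, violator indices) is
always returned with the data.

# Problem sizes in the shipped suites

The test and acceptance runs use: 20 cohorts of n = 400 for end-to-end
recovery; 10-gene/500-cell SEMs with 10 subsample networks for GRN
recovery (10 seeds) and 400-cell SEMs for null-knockout calibration
(20 seeds); 120 x 200 px stain scenes and 300-400 px segmentation
fixtures; a 32-channel backbone everywhere except the single
release-shape check at C = 2048. These sizes keep the full suite in the
low minutes on one core while leaving each recovery bar non-trivial.

# Known limitations

- The frozen random backbone captures texture statistics, not semantic
  histology; it validates contracts and pooling, and is the intended
  slot for a pretrained encoder.
- The autoencoder is plain SGD without momentum or schedules; very
  high-dimensional release-scale inputs will want more epochs.
- `cox_fit` is univariate by design (screening and group contrasts);
  there is no multivariable or regularized Cox, no time-dependent
  covariates, no competing risks.
- The displacement p-value law is a self-normalized chi-squared(1)
  convention; it is calibrated (null knockouts are super-uniform in the
  shipped checks) but is a ranking device, not an exact sampling
  distribution.
- GMM covariances are diagonal; strongly correlated latent clusters
  would need the full-covariance variant.
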