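# ptmfuse

Prognostic stratification of tumor cohorts from the two data types every
hospital already produces: H&E histology slides and RNA-seq. `ptmfuse`
fuses quantitative pathomics features extracted from slide images with the
expression of post-translational-modification (PTM) related genes into one
sample-by-feature matrix, compresses it with an autoencoder, and builds a
survival risk model in the learned latent space. A companion single-cell
stage infers gene regulatory networks (GRNs) and ranks the downstream
consequences of an in-silico ("pseudo") gene knockout. The package is
aimed at computational oncology groups who want a transparent, fully
scriptable reimplementation of this class of multimodal risk pipelines,
with synthetic generators that make every stage testable against known
ground truth.

## The model

**Pathomics.** Slides are partitioned into non-overlapping 512 x 512
tiles; an Otsu threshold on luminance defines the tissue mask and only
tiles with tissue fraction > 0.80 are kept. Staining is harmonized by
Macenko normalization: pixel optical densities `OD = -log10((I+1)/256)`
are projected on the top-2 eigenvector plane, the 1st/99th percentile
projection angles give the hematoxylin/eosin stain vectors, and
concentrations come from exact nonnegative least squares. Each tile is
resized to 224 x 224, standardized with ImageNet channel statistics, and
passed through a convolutional backbone whose final 7 x 7 activation grid
is max-pooled per channel into a C-vector (C = 2048 in the release
configuration); tile vectors are mean-aggregated per slide. In parallel,
nuclei are segmented on the hematoxylin channel (adaptive threshold,
watershed, 10-50 px equivalent-diameter gate), expanded into cells, and
summarized as 11 curated morphometric descriptors.

**Fusion and risk.** Expression of significant PTM differentially
expressed genes (Welch t, Benjamini-Hochberg, `FDR < 0.05` and
`|log2 FC| > 1`) is joined with the pathomics row per sample. After a 7:3
train/validation split, an autoencoder (encoder 128-64-32 with ReLU
hidden layers, mirrored decoder, dropout 0.1, batch 64, learning rate
0.001, 150 epochs of seeded mini-batch SGD) learns a 32-dimensional
latent space. Each latent dimension is screened by univariate Cox
regression (Breslow partial likelihood, Newton-Raphson); the risk score
is the Cox-coefficient-weighted sum of selected dimensions,

```
risk_i = sum_j beta_j * z_ij   (j over selected latent dims)
```

and patients are stratified at the training-median risk. Gaussian-mixture
subtypes with silhouette-selected k, Kaplan-Meier curves, log-rank tests
and group hazard ratios complete the survival report; permutation
importance on Harrell's C and Spearman maps expose which input features
drive the risk axis.

**Single-cell GRN pseudo-knockout.** After QC (genes in >= 10 cells;
cells with 200-5000 detected genes and <= 10% mitochondrial UMIs) and
log-CPM normalization, directed networks are inferred per cell subsample
by principal-component regression, sparsified to the top 5% of edges,
stacked into a tensor and denoised by CP (CANDECOMP/PARAFAC)
decomposition into a consensus GRN. A knockout zeroes the gene's outgoing
edges; WT and KO networks are embedded jointly by a coupled graph
Laplacian, and genes are ranked by the Euclidean displacement between
their two embeddings (chi-squared calibration, BH FDR < 0.05), with
hypergeometric enrichment of the perturbed set against user-supplied
pathways.

## Worked example

```r
library(ptmfuse)

# a synthetic cohort: 400 patients, 4 shared latent factors, one of which
# drives survival (log-hazard 1.1), 30% censoring
co <- make_cohort(n = 400, k = 4, d_expr = 25, d_path = 15,
                  beta_true = c(1.1, 0, 0, 0), noise_sd = 0.2,
                  censor_rate = 0.3, seed = 42)
features <- cbind(co$features_expr, co$features_path)
colnames(features) <- c(paste0("expr_", colnames(co$features_expr)),
                        paste0("path_", colnames(co$features_path)))

res <- run_pipeline(features, co$survival, cfg = ae_config(seed = 1),
                    seed = 42, subtype = TRUE)
```

which prints (via the reporting snippet in `?run_pipeline`):

```
training    HR = 3.31 (95% CI 2.44-4.49), log-rank p = 6.2e-16
validation  HR = 2.00 (95% CI 1.31-3.07), log-rank p = 0.0012
latent dims selected by Cox screen: 20 / 32
silhouette-selected subtypes: k = 2
```

The training hazard ratio of 3.3 between median-split risk groups, and
its independent replication on the held-out 30% (all validation-side
statistics reuse the training median, z-scoring and model weights),
show the pipeline recovering the single planted prognostic factor from
the fused feature matrix. For the imaging side, `make_slide()` renders
stained slides with known tissue masks, nuclei and stain matrix, and
`slide_pathomics()` turns an image into the per-slide feature row.

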