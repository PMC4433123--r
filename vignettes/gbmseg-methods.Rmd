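---
title: "Unsupervised multiparametric glioblastoma segmentation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised multiparametric glioblastoma segmentation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gbmseg segments glioblastoma from co-registered multichannel MR volumes
(T1, post-contrast T1c, T2, FLAIR) without any training labels. This
vignette explains the statistical models, the tunable parameters, the
numerical conventions, and what the synthetic phantom used by the test
suite does and does not establish about real data.

## The segmentation model

### Features

Each study contributes 20 images: the four channels, the derived image
T1d = |T1c − T1| (which isolates gadolinium enhancement), and the local
mean, skewness and plain (non-excess) kurtosis of each of those five bases
over a (2r+1)³ neighbourhood, default r = 2 (5×5×5 voxels). Moments are
computed from the raw neighbourhood intensities restricted to in-mask
voxels, with border clipping rather than padding, so background zeros never
contaminate a moment. A neighbourhood with fewer than two usable voxels, or
zero variance, falls back to (value, 0, 0); with this convention a constant
region has skewness 0 and kurtosis 0 rather than NaN.

The 20 features are standardized (zero mean, unit variance per feature;
zero-variance features are centred only) and reduced by PCA, keeping the
smallest K components whose cumulative explained variance reaches 99%.
Standardization is the default because the raw channels, the local means
and the dimensionless skewness/kurtosis live on incommensurate scales and
the 99% rule is scale-sensitive; `standardize = FALSE` exposes the
raw-covariance alternative. On the synthetic phantom (Gaussian intensities
within each tissue) the skewness and kurtosis images carry almost no
between-tissue signal, so standardized PCA retains more components
(typically K ≈ 13–14 of 20) than it would on real tumour texture; this is
a property of the phantom, not of the decomposition.

### Voxel classifiers

All four classifiers model the in-mask feature vectors x_n ∈ ℝ^D with C
classes:

* **K-means** — Lloyd iterations minimizing Σ‖x_n − μ_{y_n}‖²;
  statistically the hard-EM limit of a Gaussian mixture with shared
  identity covariance and uniform priors, which is how the fitted model
  reports its covariances and priors. An emptied cluster is re-seeded to
  the point farthest from its assigned centroid.
* **Fuzzy K-means** — memberships u_nc = 1/Σ_j (d_nc²/d_nj²)^{1/(m−1)}
  with fuzziness m = 2 by default; a point coincident with a centroid
  takes membership 1 there (the limit of the update). The objective
  Σ u_nc^m d_nc² is non-increasing and memberships are row-stochastic at
  every iteration.
* **GMM** — full-covariance EM for p(x) = Σ_c p_c N(x|μ_c, Σ_c), with
  log-sum-exp stabilized responsibilities. Initial means are the seeds,
  initial covariances the global data covariance, initial priors uniform.
  Every M-step adds a ridge of 1e-6 × trace(Σ_c)/D to the covariance,
  which prevents collapse on quantized intensities while perturbing the
  likelihood far below the stopping tolerance. Convergence is a relative
  NLL change below `tol` (default 1e-6, cap 200 iterations).
* **GHMRF** — the same Gaussian emission model coupled to an Ising prior
  U(Y) = β Σ_{(n,m)∈Q} [y_n ≠ y_m] over the 6-connected in-mask neighbour
  pairs Q. The joint is p(X,Y) ∝ exp(−U(X|Y) − U(Y)) with
  U(X|Y) = Σ_n −log N(x_n|μ_{y_n}, Σ_{y_n}); the partition function is
  never needed for MAP labelling or hard-EM updates and is not computed.
  Fitting is hard EM: the labelling step runs ICM sweeps (deterministic
  voxel order = the flattened column-major in-mask order; ties to the
  lowest label), which never increase the total energy; the parameter step
  is the ML Gaussian update from the hard labels. β defaults to 1.0, the
  unweighted disagreement count. With β = 0 the procedure reduces exactly
  to uniform-prior classification EM, which the test suite exploits as an
  equivalence oracle. ICM is a deliberately simple, dependency-free MAP
  solver: it only guarantees a local energy minimum, unlike graph-cut
  solvers, but it preserves the contract that matters here (deterministic,
  energy-non-increasing) and the solver is pluggable behind `icm_label()`.

### Initialization protocol

Each fit draws 100 K-means++ seedings, keeps the 10 with the lowest mean
squared distance from each point to its nearest seed (mean-per-point is
monotone-equivalent to the total for fixed N), fits the model from each of
the 10, and returns the solution with the lowest distance objective
(K-means, fuzzy) or the lowest mixture NLL (GMM, GHMRF). For GMM/GHMRF the
seeds initialize only the means; covariances start from the global
covariance and priors uniform, a documented choice where the protocol
itself is silent. The whole protocol is deterministic given one integer
seed.

The default class count is C = 14: seven assumed brain tissues (WM, GM,
CSF and the four tumour compartments), each allowed two Gaussian modes to
absorb intra-tissue heterogeneity. C is a configuration value, not an
estimate.

## Tumour class isolation

Unsupervised classes carry no semantics, so the pipeline isolates the
pathological ones in three steps.

**Tissue attribution.** Atlas WM/GM/CSF probability maps (pre-warped to
patient space) are first corrected inside a rough lesion mask: a voxel is
lesion when its intensity exceeds median + sd of the FLAIR or of the T1c
in-mask histogram; holes are filled (6-connectivity background) and the
brain-perimeter shell (mask minus its erosion by radius 2) is removed. All
tissue probabilities inside the lesion are set to ε = 1e-6 — small enough
to remove the lesion's normal-tissue mass, non-zero to avoid divisions by
zero. For each tissue t the share p(c|t,S) = Σ_{v: S(v)=c} p(t|v) / Σ_v
p(t|v) is computed, shares are sorted descending, and the cumulative sum
𝓢_t is thresholded at τ = 0.8: classes past the threshold explain almost
none of tissue t. The pathological set is the intersection over the three
tissues.

Two readings of "past the threshold" are implemented. The *inclusive*
rule takes every class whose cumulative sum strictly exceeds τ — including
the class at which the sum crosses τ, which in a clean segmentation is the
tissue's own dominant class (at rank 1 the cumulative sum already exceeds
0.8, so the rule would flag the WM class itself as "not explaining WM").
The *exclusive* rule starts strictly after the crossing class. The
pipeline defaults to the exclusive rule: it is the reading consistent with
the method's purpose (isolating classes with very low probability of
explaining normal tissue) and the only one that behaves sensibly when one
class per tissue dominates, which is exactly the regime the phantom (and
any well-separated data) produces. The inclusive, literal reading stays
available via `zt_rule = "inclusive"`.

**Outlier removal.** Among the surviving classes, each 26-connected
component with strictly more than half of its voxels inside the dilated
brain-perimeter shell (erosion radius 2, dilation radius 2 — both
unstated upstream and chosen here as the smallest radii that cover the
skull-stripping gradient) is erased; then classes whose occurrence among
the remaining labelled voxels is strictly below 1% are erased, with all
fractions computed once before any deletion.

**Merging.** Each remaining class gets a per-PCA-dimension Gaussian kernel
density (Silverman bandwidth, shared 256-point grid spanning the pooled
range ±5%, renormalized by the trapezoid rule; degenerate classes fall
back to a one-grid-step bandwidth). Distances are base-2 Jensen–Shannon
divergences averaged over dimensions — bounded in [0,1], symmetric, zero
iff equal — and average-link (UPGMA) agglomeration merges classes while
the next merge distance is below 0.1 bits or more than 4 groups remain,
ties to the lowest class-id pair. The feature space for the densities and
the multivariate JSD reduction are choices this package makes explicitly;
nothing upstream prescribes them.

**BRATS coding.** The merged classes are mapped to BRATS codes by contrast
signature: highest mean T1d → enhancing (4); then highest mean FLAIR →
edema (2); then lowest mean T1c → necrosis (1); remainder →
non-enhancing (3); ties to the lower class id. The mapping is logged and
returned. This heuristic is an artifact addition — nothing upstream
specifies how unsupervised classes were matched to challenge codes — and
it is overridable by relabelling the returned volume.

## Evaluation

Compartments follow the BRATS convention: complete = {1,2,3,4}, core =
{1,3,4}, enhancing = {4}. Dice is the standard overlap 2TP/(P+P̂); an
accuracy-style variant 2(TP+TN)/(P+N+P̂+N̂) is implemented behind
`variant = "printed"` for audit but is not a sensible overlap measure (it
rewards true negatives) and is never the default. PPV, sensitivity and
Cohen's kappa follow the printed formulas; kappa is computed on the binary
complete-tumour masks. Both-empty sets score 1 by convention; chance-level
degenerate kappa (P_E = 1) scores 0.

## The phantom: what it emulates and what it does not

The generator builds a 64³ (default) brain as nested ellipsoids: a
cortical GM shell, interior WM, a displaced CSF ventricle, and a tumour of
four nested compartments — necrotic core, enhancing rim, non-enhancing
region, edema halo — embedded in WM. Channel intensities are Gaussian per
tissue with means chosen to reproduce the clinical contrast signatures
(enhancing rim maximal in T1c−T1, edema maximal in FLAIR, necrosis minimal
in T1c) and noise sd 1.5 (low-noise preset; 4 for moderate). Compartment
semi-axes are sized so that each compartment is at least a few voxels
thick relative to the 5×5×5 moment neighbourhood; at 64³ the whole volume
is roughly a 3×-downscaled brain, and a tumour whose compartments were
thinner than the texture operator would conflate generator resolution with
method behaviour. Probability maps are Gaussian-smoothed (σ = 1.5 voxel)
indicators of the *healthy* geometry — the tumour region carries the
enclosing WM's probabilities — so the lesion-mask correction in the
isolation stage is genuinely exercised, and they are renormalized to sum
to 1 inside the brain.

The phantom deliberately omits bias fields, Rician noise, partial-volume
mixing and registration error: the pipeline consumes preprocessed,
pre-aligned data, and the phantom emulates that contract, not a scanner.
Consequently, passing phantom tests demonstrates the correctness and
determinism of the machinery — feature extraction, model fitting, energy
minimization, attribution arithmetic, merging — under the model's own
assumptions. It does not demonstrate accuracy on clinical data, where
tissue non-Gaussianity, registration error in the atlas maps and
partial-volume gradients dominate the error budget.

Two systematic effects are visible even on the phantom, and they bound
what end-to-end accuracy the method can reach on it. First, voxels whose
moment neighbourhood straddles a tissue interface form thin "boundary"
classes in feature space; around the tumour these inflate the predicted
volume by roughly a one-voxel shell relative to the crisp geometric truth
(on expert-annotated data the analogous voxels are usually annotated as
tumour). Second, and dominant: with C = 14 components over a brain whose
normal tissues hold over nine tenths of the voxels, the maximum-likelihood
solution spends most components on WM and GM, and the τ = 0.8
cumulative-attribution rule only protects the components that cover the
first 80% of each tissue's probability mass — any surplus normal-tissue
component lands in the pathological set as false-positive tumour. The
likelihood itself prefers such fragmenting solutions: in the retained
moment-PCA space the class-conditional Gaussian model is misspecified, so
a solution that carves the dominant tissue more finely can have a better
NLL than the one matching the generative modes, and the multistart's NLL
selection keeps it. The practical consequence on the low-noise phantom is
a complete-tumour Dice around 0.6–0.8 (the spatial prior of the GHMRF
consolidates the normal-tissue components and usually scores higher than
the GMM), with the enhancing compartment recovered essentially exactly —
a profile that the test suite asserts and the acceptance script
recomputes, and that sits at the same scale as what attribution-based
isolation achieves on clinical benchmark data.

## Numerical conventions and degenerate inputs

* Voxel order everywhere (feature rows, MRF pairs, ICM visits) is the
  array's native column-major linear order — deterministic and identical
  across modules.
* Masks binarize at > 0 (third-party skull strippers emit floats).
* Covariance ridge 1e-6·trace/D per M-step; a covariance that is still
  not positive definite raises an error naming the class.
* Empty classes: K-means re-seeds to the farthest point; hard-EM
  (GMM-hard and GHMRF share one code path) re-seeds the class mean to the
  worst-fit voxel.
* Convergence: relative objective change below 1e-6 (soft fits) or label
  stability (hard fits), 200-iteration cap, 5 ICM sweeps per labelling
  step.
* Problem sizes in the shipped tests: unit tests run on ≤ 32³ phantoms and
  ≤ a few hundred points; the end-to-end acceptance runs use the 64³
  low-noise preset with the full 100/10 multistart protocol. These sizes
  were chosen so the whole suite completes on one CPU in well under half
  an hour while still exercising every stage at a realistic scale.

## Known limitations

* ICM can stop in local energy minima a graph-cut solver would escape;
  β ≫ 1 amplifies this.
* The attribution step needs atlas maps that are at least roughly aligned;
  it has no mechanism to recover from a grossly wrong warp.
* The BRATS coding heuristic assumes the four compartments' canonical
  contrast ordering; atypical tumours (non-enhancing GBM) can swap codes.
* With fewer than four merged classes the priority order (4, 2, 1, 3)
  decides which codes exist; a single-class tumour is coded enhancing.
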