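# gbmseg

Fully unsupervised segmentation of glioblastoma (GBM) from co-registered
multichannel MR volumes — T1, post-contrast T1 (T1c), T2 and FLAIR — with
automatic identification of the tumour compartments. No training labels
are used at any stage: voxels are clustered by unsupervised models and the
pathological classes are isolated with population-atlas tissue probability
maps.

The package is aimed at neuroimaging researchers who need a reproducible,
scriptable baseline for multiparametric tumour segmentation, and at
methodologists studying unsupervised and Markov-random-field voxel
classification.

## Method

For each study the pipeline:

1. **Features.** Builds 20 images: the four channels, the enhancement
   image T1d = |T1c − T1|, and the local mean μ, skewness γ and kurtosis κ
   of each of those five bases over a 5×5×5 neighbourhood; then reduces
   them with PCA, keeping the smallest K components explaining ≥ 99% of
   the variance.
2. **Unsupervised voxel classification.** Fits one of four models over the
   in-mask feature vectors x_n ∈ ℝ^K with C classes (default C = 14 —
   seven assumed tissues, two Gaussian modes each):
   * K-means: arg min_J Σ_c Σ_{x_n∈J_c} ‖x_n − μ_c‖²;
   * fuzzy K-means with memberships
     u_nc = 1/Σ_j (d²_nc/d²_nj)^{1/(m−1)}, m = 2;
   * Gaussian mixture p(x_n) = Σ_c p_c 𝒩(x_n|μ_c, Σ_c) by EM;
   * Gaussian hidden Markov random field
     p(X,Y) ∝ exp(−Σ_n −log 𝒩(x_n|μ_{y_n},Σ_{y_n}) − β Σ_{(n,m)∈Q}
     δ(y_n ≠ y_m)) with a 6-connected Ising prior, fitted by hard EM with
     iterated conditional modes.

   Every fit uses a multi-start protocol: 100 K-means++ seedings, the 10
   with the lowest mean nearest-seed squared distance are fitted, and the
   best solution is kept (lowest distance objective, or lowest negative
   log-likelihood for GMM/GHMRF).
3. **Tumour class isolation.** WM/GM/CSF probability maps (pre-warped to
   patient space) are corrected to ε inside a rough lesion mask
   (FLAIR/T1c intensities above median + sd, hole-filled, perimeter
   stripped). For each tissue t the share p(c|t,S) = Σ_{v:S(v)=c} p(t|v) /
   Σ_v p(t|v) is sorted, cumulated, and thresholded at τ = 0.8; classes
   past the threshold in *every* tissue form the pathological set 𝒵.
   Perimeter components and sub-1% classes are removed, survivors are
   merged by average-link clustering of Jensen–Shannon divergences between
   class densities (at most 4 groups), and the groups are mapped to BRATS
   codes (1 necrosis, 2 edema, 3 non-enhancing, 4 enhancing) by their
   contrast signatures.
4. **Evaluation.** Dice = 2TP/(P+P̂), PPV, sensitivity and Cohen's kappa
   over the BRATS compartments: complete {1,2,3,4}, core {1,3,4},
   enhancing {4}.

A synthetic phantom module generates complete studies — nested-ellipsoid
brain with a four-compartment tumour, per-tissue two-mode Gaussian
intensities, aligned healthy-atlas probability maps and ground-truth
labels — so the whole pipeline is testable without any data download.

## Worked example

```r
library(gbmseg)

phantom <- generate_phantom(default_specs()$low_noise)   # 64^3 study
cfg <- pipeline_config(study = phantom$study, maps = phantom$maps,
                       reference = phantom$truth,
                       algorithm = "ghmrf", seed = 11)
res <- run_pipeline(cfg)
print(res$report)
cat(res$log[c(4, 6, 8, 10)], sep = "\n")
```

```
 compartment      dice       ppv sensitivity
    complete 0.8188780 0.6935301   0.9995326
        core 0.6271366 0.4570106   0.9990361
   enhancing 1.0000000 1.0000000   1.0000000
complete-tumour kappa: 0.8153
PCA retained K=14 components (cumulative 0.9916)
lesion mask: 4279 voxels
surviving classes after outlier removal: {2, 3, 5, 8, 9, 14}
BRATS mapping: 4->4 1->2 3->1 2->3
```

Reading the output: the GHMRF recovered the enhancing rim exactly
(Dice 1.0) and 99.95% of the complete tumour; the complete-tumour Dice of
0.82 reflects surplus normal-tissue clusters that the τ-threshold
attribution step flagged as pathological (their probability share of every
atlas tissue fell in the post-80% tail) — the characteristic error mode of
attribution-based isolation, discussed in the methods vignette. The
mapping line records which unsupervised classes became which BRATS codes.

The same entry points drive real data: pass NIfTI paths (`t1`, `t1c`,
`t2`, `flair`, `mask`, `wm`, `gm`, `csf`) instead of in-memory objects, or
use the CLI:

```sh
Rscript inst/cli/gbmseg.R phantom --out-dir data/ --preset low_noise
Rscript inst/cli/gbmseg.R segment --t1 data/t1.nii.gz --t1c data/t1c.nii.gz \
    --t2 data/t2.nii.gz --flair data/flair.nii.gz --mask data/mask.nii.gz \
    --wm data/wm.nii.gz --gm data/gm.nii.gz --csf data/csf.nii.gz \
    --algorithm ghmrf --out-dir out/
Rscript inst/cli/gbmseg.R evaluate --segmentation out/segmentation.nii.gz \
    --reference data/truth.nii.gz
```

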