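# connectoscore

Links the topology of weighted structural brain connectomes to a
data-driven **generalized cognitive score**, and extracts
stability-selected connectivity biomarkers of cognitive decline.

The package is aimed at researchers who have, for each subject of a mixed
dementia cohort (normal controls, mild cognitive impairment, Alzheimer's
disease), a streamline-count connectivity matrix over an anatomical
parcellation and a battery of clinical instruments (ADAS-Cog, MMSE,
CDR-SOB, ...), and who want a single quantitative outcome linking the two
data views.

## The method

Given per-subject symmetric weight matrices `W` (entries `w_ij` = fiber
tracts between regions `i` and `j`) and an M x S clinical matrix `Y`:

1. **Features.** Two designs per connectome: `X1`, the strict upper
   triangle of `W` (P = N(N-1)/2); and `X2`, three node metrics per region
   (P = 3N) — strength `s_i = Σ_j w_ij`, eigenvector centrality
   `eig_i = (1/Λ) Σ_j w_ij eig_j` (Perron eigenpair), and weighted local
   efficiency `E(G_i) = 1/(n_i(n_i−1)) Σ_{j≠k∈G_i} 1/d(j,k)` with
   inverse-normalized-weight link lengths.
2. **Score.** Inside each round of a V=10 x k=10 repeated cross-validation
   (T = 100 rounds), the battery is screened for mutual correlation
   (|r| < 0.75), standardized with training-fold parameters, and projected
   on the training correlation matrix's first principal component:
   `Z_TRAIN = Ỹ_TRAIN c1`, `Z_TEST = Ỹ_TEST c1` — leakage-free.
3. **Validation.** Training scores are clustered with a univariate
   Gaussian mixture (EM); cluster-diagnosis agreement is scored by
   normalized mutual information with a label-permutation null.
4. **Association.** A Lasso
   `min_β (1/2M)‖z − β₀ − Xβ‖² + λ‖β‖₁` (coordinate descent, exact
   zeros) maps features to the score; `λ` is tuned on an inner
   diagnosis-stratified validation split per round; performance is the
   held-out Pearson correlation `R`.
5. **Stability.** The T sparse weight vectors form a T x P matrix `B`;
   features whose selection frequency exceeds both the 99th percentile of
   the frequency distribution and a 70% occurrence cut form the signed
   stable-biomarker list.

A synthetic-cohort generator with a planted latent severity factor (one
factor driving both the battery and the connectivity of a few planted
regions) makes the whole pipeline testable end to end without restricted
clinical data.

## Worked example

```r
library(connectoscore)

cohort  <- generateCohort(syntheticConfig(seed = 1))   # 191 subjects, 120 ROIs
dataset <- cohort@dataset
x2      <- buildX2(dataset)                            # 191 x 360

cfg <- experimentConfig(vRepeats = 10, kFolds = 10, seed = 1,
                        variants = "X2", targets = "generalized",
                        nPerm = 1000, nLambda = 20, lambdaRatio = 1e-2)
res <- runExperiment(dataset, cfg, features = list(X2 = x2))

summarizeR(res)
#>      variant            target     meanR        sdR
#> mean      X2 generalized_score 0.9475875 0.02236014

mean(res@scoreSummary$explainedVariance)   # 0.5830 — first-PC variance share
mean(res@scoreSummary$nmi)                 # 0.3002 — cluster/diagnosis overlap
mean(res@scoreSummary$pValue)              # 0      — permutation-tested

subset(stabilityTable(res@stability$X2), selected)
#>          label frequency meanWeight     sign selected
#> 6     S-ROI006      0.98 -0.4178218 negative     TRUE
#> 144 eig-ROI024      1.00 -0.4377376 negative     TRUE
#> 180 eig-ROI060      1.00  0.6673834 positive     TRUE
#> 210 eig-ROI090      1.00  0.5076415 positive     TRUE

recoveryMetrics(cohort, res@stability$X2)[1:3]
#> $precision [1] 1   $recall [1] 1   $signAgreement [1] 1
```

Reading the output: the generalized score of held-out subjects is
predicted from 360 node metrics with mean `r ≈ 0.95` over 100 rounds; the
first component carries ~58% of the battery variance (consistent with the
generator's closed-form value from `theoreticalMoments()`); clustering the
score recovers the diagnostic groups far above chance (permutation
p = 0); and the stable-feature list pinpoints exactly the four planted
regions — ROI006/ROI024 degrading with severity, ROI060/ROI090
strengthening — via their strength or centrality features.

The same pipeline runs from the shell via `inst/cli.R`
(`simulate` / `features` / `run` / `report`).

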