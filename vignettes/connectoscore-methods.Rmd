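---
title: "Linking connectome topology to a generalized cognitive score: methods and design choices"
author: "connectoscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking connectome topology to a generalized cognitive score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectoscore)
```

## The problem

Dementia cohorts are characterized twice over: by structural brain
connectivity (weighted networks whose nodes are atlas regions and whose
edge weights count white-matter streamlines between them) and by batteries
of cognitive instruments (CDR-SOB, ADAS-Cog-13, MMSE, and so on).  The
instruments are partially redundant, live on incomparable scales, and point
in different directions (for MMSE higher is better, for CDR-SOB higher is
worse).  `connectoscore` implements a pipeline that

1. compresses the battery into a single *generalized cognitive score* — the
   first principal component of the training-fold battery, applied
   leakage-free to held-out subjects;
2. validates that score clinically, by clustering it with a univariate
   Gaussian mixture and measuring its overlap with the diagnostic labels
   (NC / MCI / AD) via normalized mutual information, against a
   label-permutation null;
3. regresses connectivity features on the score with the Lasso inside a
   V x k repeated cross-validation (V = 10 repeats of k = 10 folds, so
   T = 100 rounds), tuning the penalty on an inner validation split per
   round; and
4. aggregates the T sparse weight vectors into per-feature selection
   frequencies, from which a stability-selected list of connectivity
   biomarkers is extracted.

Two feature descriptions of each connectome are compared: `X1`, the raw
upper-triangle edge weights (P = N(N-1)/2 = 7140 features for N = 120
regions), and `X2`, three node-level graph metrics per region (P = 3N =
360): strength, eigenvector centrality, and weighted local efficiency.

## Graph metrics

For a symmetric non-negative weight matrix $W$ with entries $w_{ij}$:

* **Strength** $s_i = \sum_j w_{ij}$, the weighted degree.
* **Eigenvector centrality**, the Perron eigenvector of $W$:
  $eig_i = \frac{1}{\Lambda}\sum_j w_{ij}\, eig_j$ with $\Lambda$ the
  largest eigenvalue.  Computed by shifted power iteration ($W + sI$ with
  $s$ the largest row sum), which converges even for bipartite weight
  patterns where the plain iteration oscillates; the result is
  non-negative with unit Euclidean norm, verified against a dense
  eigendecomposition in the tests.  The iteration stops when
  $\max_i |(W\,eig)_i - \Lambda\, eig_i| \le$ `tol` (default `1e-10`,
  at most 1000 iterations).
* **Weighted local efficiency**: for node $i$ with neighbour set $G_i$ of
  size $n_i$,
  $E(G_i) = \frac{1}{n_i(n_i-1)} \sum_{j \neq k \in G_i} 1/d(j,k)$,
  where $d$ is the shortest-path length inside the subgraph induced by
  $G_i$.

Three conventions had to be fixed for local efficiency, and all three are
the ones used by the Brain Connectivity Toolbox, the de-facto standard for
these metrics:

* **Weight-to-length conversion.**  A literal "minimize the sum of the
  weights" reading would make strong connections costly.  We convert
  weights to lengths as $L_{uv} = 1/(w_{uv}/w_{\max})$ with $w_{\max}$ the
  largest weight in the full matrix, so stronger connections are shorter.
  Normalizing by $w_{\max}$ bounds every length below by 1 and hence every
  efficiency within $[0, 1]$, which makes the invariant testable.  The
  literal raw-weight reading remains available via
  `localEfficiency(c, lengths = "raw")`.
* **Path confinement.**  Shortest paths between two neighbours of $i$ are
  confined to the subgraph induced by $G_i$ (they may not detour through
  nodes outside the neighbourhood).  Variants that allow detours exist;
  the confined version is the one that matches the "local subgraph of
  immediate neighbours" definition.
* **Degenerate neighbourhoods.**  Disconnected neighbour pairs contribute
  $1/\infty = 0$, and nodes with fewer than two neighbours get efficiency
  0 (the normalizing factor $n_i(n_i-1)$ is otherwise undefined).

Strength scales linearly under $W \mapsto cW$; centrality and efficiency
are scale-invariant.  All three are permutation-equivariant.  These
symmetries, plus brute-force oracle equality on small random graphs
(hand summation, dense eigensolver, exhaustive shortest paths through an
independent Floyd–Warshall implementation), form the metric test suite.

## The generalized score

Within each round, the training battery $Y_{TRAIN}$ (M subjects x S
indices) is standardized per index with *training* mean and SD, and the
leading eigenvector $c_1$ of the training correlation matrix gives the
score $Z = \tilde{Y} c_1$.  Held-out subjects are projected with the
training parameters (`transformScore`), never refit.  Choices:

* **Correlation-matrix PCA** (standardize first).  The indices range over
  0–30 (MMSE), 0–18 (CDR-SOB), roughly 1–4 (ECog): raw-covariance PCA
  would be dominated by whichever instrument has the widest numeric range.
  Covariance PCA remains available (`standardize = FALSE`).
* **Sign convention.**  Principal directions are arbitrary up to sign; the
  loading on a chosen *anchor* index (default ADAS-Cog-13, a
  higher-is-worse instrument) is forced positive, so larger scores always
  mean greater impairment.  If the upstream correlation filter happens to
  drop the anchor, the experiment re-anchors to the surviving index most
  positively correlated with it.
* **Mixed-direction indices are not pre-flipped**; the loadings absorb
  direction (negative loadings on MMSE-like indices).
* **Explained variance** is $\lambda_1/S$; **contributions** are
  $100\,c_{1s}^2$, which are non-negative and sum to 100%.

The battery is first screened once, before cross-validation, by a greedy
mutual-correlation filter: while any pair of indices has $|r| \ge 0.75$,
the member of the worst pair with the larger mean absolute correlation to
the others is dropped.  Screening once upstream (not per fold) mirrors how
such batteries are fixed before modelling and keeps the feature of the
score constant across rounds.

## Clinical validation of the score

Training-fold scores are clustered with a univariate Gaussian mixture
fitted by EM: seeded k-means++-style initial means, 10 restarts (best
final log-likelihood wins), a variance floor of $10^{-6}\mathrm{var}(z)$
against component collapse, convergence at relative log-likelihood change
below $10^{-8}$ or 500 iterations.  The log-likelihood trace is stored and
must be non-decreasing — a violated trace aborts the fit, since EM
guarantees monotonicity and a violation signals a numerical fault.  The
default component count is 3, one per clinical group; a BIC-based
selection (`selectNComponents`) is provided for a data-driven choice.

Agreement between the cluster labels and the diagnostic labels is scored
by normalized mutual information, $NMI = I(a;b)/\frac{1}{2}(H(a)+H(b))$
with natural logarithms.  The arithmetic-mean normalization is the most
common convention; min, geometric and max normalizations are exposed via
an argument since the literature varies.  Zero-entropy edge cases: NMI is
1 if both partitions are constant and 0 if exactly one is.  Significance
comes from permuting the diagnostic labels (default 10,000 times) and
counting how often the permuted NMI reaches the observed one; the counter
uses $\ge$ rather than $>$ — conservative, and immaterial for a
continuous statistic where ties have measure zero.

## Sparse association and stability selection

Per round, the Lasso
$$\min_\beta \tfrac{1}{2M}\lVert z - \beta_0 - X\beta\rVert_2^2
  + \lambda \lVert\beta\rVert_1$$
is fitted by cyclic coordinate descent with soft-thresholding updates on
columns standardized with the round's *training* part (constant columns
are pinned at zero).  The $1/(2M)$ scaling makes $\lambda$ comparable
across fold sizes; note that reported $\lambda$ values are only meaningful
relative to an objective scaling, so cross-study $\lambda$ comparisons are
not.  The solver works down a descending log-spaced grid (default 100
values from $\lambda_{\max}$, the smallest penalty with an all-zero
solution, to $10^{-3}\lambda_{\max}$) with warm starts and an active-set
strategy; coefficients are exact zeros, and the largest KKT violation at
every returned solution is exposed and asserted below $10^{-6}$ in the
tests.  $\lambda$ is tuned by splitting the round's training data once
more (stratified by diagnosis, default 25% validation), picking the
penalty that maximizes the validation Pearson correlation between
predicted and actual scores (ties break toward the sparser penalty), and
refitting on the full round-training data.  A zero-variance prediction —
an all-zero model — is scored as $r = 0$ by convention, since the
correlation is undefined there.

The T coefficient vectors of the generalized-score models form a T x P
matrix B.  Stability selection keeps features whose selection frequency
$f_p$ (fraction of rounds with a nonzero weight) strictly exceeds **both**
the 99th percentile of the frequency distribution (interpolated quantile
over all P features, zeros included) and an absolute 70% occurrence cut,
partitioned by the sign of the mean weight (mean over all T rounds, zeros
included, which shrinks unstable features).  Applying the two criteria
conjunctively is our reading of a procedure described once as a percentile
rule and once as an occurrence rule; each is independently switchable, as
are the quantile pool (`everSelectedOnly`) and the mean-weight convention.

One objective-sign erratum is worth recording: the printed form of the
penalized objective subtracts the penalty term, which would make the
objective unbounded below; the standard additive penalty is implemented.

## The synthetic cohort generator

No public cohort ships with the package (the motivating data are
restricted-access), so the generator is a first-class module that defines
the study conditions for every test.  It draws, per subject:

* a latent severity $z^*$ from the subject's diagnostic group's normal
  distribution — defaults NC: $\mathcal{N}(-1, 0.6^2)$, MCI:
  $\mathcal{N}(0.3, 0.7^2)$, AD: $\mathcal{N}(1.3, 0.6^2)$, with group
  sizes 48/104/39.  The means are ordered but overlapping, so mixture
  clustering recovers the groups only imperfectly (NMI well below 1), as
  real cohorts behave;
* ten clinical indices $y_s = a_s z^* + \varepsilon_s$,
  $\varepsilon_s \sim \mathcal{N}(0, 0.7^2)$, with signed heterogeneous
  loadings $a_s \in \{\pm 0.7 \ldots \pm 0.95\}$ (negative for MMSE, MoCA
  and the RAVLT learning scores, where higher means better).  The
  magnitudes were chosen once, analytically: a single-factor battery with
  equal loadings large enough to push the first-PC explained variance
  toward 0.8 would force every pairwise correlation above the 0.75
  screening cut — the screen would then randomly amputate the battery.
  The heterogeneous defaults keep all model-implied pairwise $|r|$ safely
  below 0.75 while one factor still dominates; the model-implied
  explained variance (~0.62) and correlation matrix are available in
  closed form from `theoreticalMoments()`, and the score-recovery tests
  compare the empirical PCA against that closed form, not against any
  external figure;
* a connectome: each potential edge is present with probability
  `base_density` (default 0.3) and carries a Poisson streamline count
  (mean `base_weight_scale` = 20) — integer, symmetric, non-negative,
  zero-diagonal, like tract counts.  Edges incident to a small set of
  *planted* regions (defaults: 2 "negative", 2 "positive") have their
  Poisson mean scaled by $\max(0,\, 1 \mp e\, z^*_{norm})$ with effect
  size $e = 0.4$ and $z^*_{norm}$ the cohort-standardized severity —
  connectivity of negative regions degrades with severity, positive
  regions strengthen.

Severity is standardized at cohort level before modulation so the effect
size has the same meaning under any group mix.

**Ground truth and the collinearity caveat.**  The generator's planted
label list contains the *strength* features of the planted regions:
strength is the directly modulated quantity, while the centrality and
(weakly) efficiency of a planted region inherit attenuated, strongly
collinear signal.  In practice the Lasso stably retains one of the
strength/centrality pair per region — which one can differ across regions
— so planted-effect recovery is scored at the *region* level
(`recoveryMetrics(..., level = "roi")`): a selected feature is correct if
its region is planted, and a region is recovered if any of its metric
features is selected.  Exact label-level scoring is also implemented, but
under the percentile rule (which caps the stable list at about 1% of the
360 features) label-level recall is structurally limited by this
representative-picking behaviour, and we consider region identity, with
the association sign, to be the scientifically meaningful claim.

**What the generator does not emulate:** spatial autocorrelation of real
parcellations, hub/rich-club architecture, distance-dependent connection
probabilities, site effects, floor/ceiling effects of real instruments,
and longitudinal conversion.  Passing tests therefore demonstrate that the
pipeline recovers the *kind* of structure it assumes — one dominant
severity factor touching both data views — not that it is robust to every
property of real cohorts.

## Problem sizes used by the tests and the acceptance script

Module tests run on reduced cohorts (tens of subjects, 12–40 regions)
chosen to exercise every code path quickly.  The end-to-end checks run the
full design scale — 191 subjects, 120 regions, T = 100 rounds — with a
20-value penalty grid down to $10^{-2}\lambda_{\max}$ (the tuning curves
at this scale are flat well before that floor), recovery on X2 across 10
generator seeds, and single-repeat (k = 10) runs for the per-target
ordering comparisons.  The acceptance script runs one full X2 experiment
(all targets, 1000 NMI permutations per round) and one X1 experiment
(generalized score) at the same scale.

## Known limitations

* The Lasso grid floor and length trade accuracy of the tuned $\lambda$
  against runtime; with very weak signals a longer grid may shift the
  selected penalty.
* GMM clustering is univariate by design (the score is a scalar); no
  multivariate validation is attempted.
* The stability criterion is purely frequency-based; no error-control
  theory (e.g. complementary-pairs stability selection) is claimed.
* Eigenvector centrality on a disconnected connectome is computed on the
  full matrix with a warning; its mass concentrates on the dominant
  component, and isolated regions get centrality 0.
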