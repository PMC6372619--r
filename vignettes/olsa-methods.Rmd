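---
title: "Orthogonal linear separation of perturbation response profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthogonal linear separation of perturbation response profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olsar)
```

## The model

A perturbagen acting on a cell rarely does one thing. Its transcriptome
footprint mixes several more basic responses — target engagement, stress
programs, cell-cycle arrest — in proportions that vary with compound and
dose. `olsar` treats a response-profile matrix $D$ (genes $\times$ samples,
each entry a differential value versus vehicle control) as approximately a
linear mixture, and factorizes it as

$$D \;\approx\; R^{\top} S\, T,$$

where the rows of $R$ (the *response vectors*) are orthonormal gene-loading
vectors, $S = R\,D'$ holds the *response scores* (each sample's activity on
each factor), and $T = \mathrm{diag}(l_1, \dots, l_N)$ carries each
sample's *total strength* $l_i = \lVert d_i \rVert_2$, the intensity of
stimulation. $D' = D\,T^{-1}$ is the column-normalized matrix of pure
response directions.

The point of the construction is that the **origin of the response space is
biologically meaningful**: it is the untreated state. An ordinary PCA would
re-center the cloud at its empirical mean, which drifts with the library
composition of each data set, so the extracted axes would not be comparable
across studies. Two devices anchor the decomposition at the origin instead:

1. **Mirror augmentation.** For every (non-outlier) normalized profile we
   add its point-symmetric image, $M = -P'$, and decompose the
   concatenation $DM = [\,D' \mid M\,]$. If no sample is excluded the
   centroid of $DM$ is *exactly* zero; biologically, the mirror encodes the
   assumption that elementary responses are reversible (an axis and its
   reverse are the same basic response).
2. **Uncentred extraction.** Components are taken from the singular value
   decomposition of $DM$ *without* re-centering. With no exclusions this is
   identical to centred PCA (the mean is exactly zero — a tested
   equivalence); with exclusions it deliberately keeps the origin fixed
   rather than letting removed samples shift it. The residual centroid is
   then $\sum_{r \in \text{removed}} u_r / (N + m)$, the un-mirrored
   remainder of the excluded profiles.

## Preprocessing: ranks and robust z-scores

Raw expression is first converted, per sample, to within-sample gene ranks
(ascending, mid-ranks for ties). Ranking makes everything downstream
invariant to monotone per-sample distortions — platform scale,
normalization choices, log transforms. For gene $x$ in treated sample $i$,

$$z_i = \frac{x_i - \mathrm{median}(Y)}{\mathrm{NIQR}(Y)},$$

where $Y$ is the vector of the gene's ranks across control samples and
NIQR is the normalized interquartile range, $\mathrm{IQR} \times 0.7413$,
the scaling that makes an IQR estimate a normal standard deviation. The
IQR uses linear interpolation between order statistics (the common default
quantile rule; the convention matters at small control counts and is
therefore fixed and exposed as `niqr_constant`). A gene whose control IQR
is zero cannot be scaled; its z-entries are set to 0 and the gene is
reported, rather than dropped, so gene indexing stays aligned between
training and held-out sets. Precomputed response matrices (log fold
changes, z-scores) enter directly through `as_response_profile()`.

Rank direction (ascending) only flips the global sign of $D$; sign
conventions are restored downstream by the canonical sign rule, so the
choice is inconsequential and documented rather than configurable.

## Outlier screening for the mirror set

A sample with an extreme total strength is interpreted as an irreversible
response (overt toxicity, catastrophic stress): mirroring it would plant a
fictitious "recovery" profile in the data. The L2-norms are therefore
screened by a one-sided (upper-tail) Grubbs test, applied iteratively:
while $G = (\max_i l_i - \bar l)/s_l$ exceeds the critical value

$$G_{\mathrm{crit}} = \frac{n-1}{\sqrt{n}}
  \sqrt{\frac{t^2}{\,n - 2 + t^2\,}}, \qquad
  t = t_{1 - \alpha/n,\; n-2},$$

the max-norm sample is excluded from the mirror set (it still appears,
un-mirrored, in $DM$, and still receives scores). Default $\alpha = 0.05$;
the full audit trail (statistic, critical value, decision per iteration)
is always retained and written with the artifacts. Whether to apply the
test once or repeatedly is genuinely open; we iterate, because a single
gross outlier inflates the variance and can mask a second one, and the
audit trail makes the behaviour inspectable.

## Component retention and varimax rotation

Components are ordered by contribution ratio $\sigma_j^2 / \sum_k
\sigma_k^2$ and retained up to the smallest $k$ whose cumulative
contribution reaches the threshold (default 0.8; ties at the threshold are
broken toward inclusion, and a threshold no nonzero spectrum can reach
retains all nonzero components with a warning).

The retained orthonormal loadings are then rotated to maximize the **raw
varimax criterion** — the summed variance of squared loadings across genes
— which concentrates each factor's mass on few genes while preserving
orthogonality exactly. No Kaiser row-normalization is applied: the rows
here are gene coordinates of orthonormal vectors, not variables with
heterogeneous communalities, so raw weighting is the appropriate variant.
The maximizer uses classical pairwise (Jacobi) planar rotations, sweeping
all factor pairs until the criterion improves by less than `tol` (default
1e-8) in a sweep, up to 1000 sweeps; non-convergence returns the
best-so-far rotation with a warning and a metadata flag. The criterion is
non-decreasing by construction, and for $k = 2$ the implementation is
pinned against an exhaustive 0.001-radian grid search over the rotation
angle (and against an independent varimax implementation); for general $k$
orthogonality, subspace preservation and criterion ascent are the tested
guarantees.

After rotation, factor contributions are recomputed as each rotated
factor's share of the squared mass of $DM$, factors are renamed
P1..Pk in descending contribution order, and each row's sign is
canonicalized so its largest-|loading| gene is positive (an arbitrary but
reproducible resolution of the sign indeterminacy; `sign_flip` overrides
it per factor when the analyst prefers the opposite orientation). A
retained $k = 1$ skips rotation.

## Factor interpretation and validation

* `top_fraction_genes()` — the top 1% of genes by squared loading
  (`floor(0.01 n)`, minimum 1, boundary ties broken by gene id) is the
  query for gene-set over-representation.
* `fisher_enrich()` — one-sided hypergeometric test per gene set, with the
  **universe equal to the genes of the analyzed matrix** (enrichment must
  be relative to what could have been selected, not to the collection's
  vocabulary). `bh_adjust_and_segr()` applies Benjamini–Hochberg across
  all (factor, set) pairs jointly — the most conservative interpretable
  family; `family = "per_factor_min"` adjusts each factor's best p instead
  — and summarizes the fit by the significant-enrichment ratio (SEGR), the
  fraction of factors with any set at $q < \alpha$.
* `extract_signature()` — genes in order of contribution
  ($\text{loading}^2/\text{total}$) until the cumulative contribution
  reaches 0.9; the crossing gene is included, and a cumulative value
  landing exactly on the cutoff (within 1e-9) counts as reached.
* `spearman_validate()` — Spearman's $\rho$ between signature loadings and
  each held-out sample over the gene-id intersection (coverage reported,
  $\geq 3$ shared genes required). Rank correlation makes any monotone
  per-sample scaling of the test data irrelevant, which is why test
  profiles are deliberately *not* re-normalized.

## The synthetic generator

`generate_synthetic()` draws data the decomposition is designed for:
sparse orthonormal loadings $W$ (per factor, 5% of genes on
disjoint-leaning supports — disjoint when they fit, QR-orthonormalized
otherwise — so varimax has a simple structure to find), heavy-tailed
Laplace factor scores whose scales decay geometrically with ratio 0.7
(producing the steep contribution spectra seen in real perturbation
panels), i.i.d. Gaussian gene noise, log-normal per-sample strengths, and
optionally a minority of outlier samples with strength inflated ×10–×20,
emulating irreversible responders. Defaults: 2,000 genes × 150 samples,
6 factors, noise sd 0.1, top Laplace scale 4 — sized so a desk-scale run
finishes in seconds while keeping the planted subspace clearly above the
noise floor.

What it does **not** emulate: correlated gene-gene noise, batch structure,
platform-specific intensity distributions, dose–response within compound,
or non-linear interactions between basic effects. Passing recovery tests
therefore demonstrates that the algorithm does what it claims on data
satisfying its own model — not that real perturbation data satisfy that
model.

Two calibration notes, both visible in the tests:

* With the geometric score spectrum and noise sd 0.1 the six planted
  factors carry a steep spectrum, and the 0.8 cumulative threshold retains
  them *plus* a tail of noise components (around 40 in total). Recovery is
  assessed by greedy |cosine| matching, which simply leaves the noise
  factors unmatched.
* The Monte-Carlo check of the outlier gate uses a calmer spec
  (noise-dominated norms, near-constant strengths), because the gate's own
  false-positive rate is the nominal Grubbs $\alpha \approx 5\%$: under
  heavy-tailed norms no implementation could remove *exactly* the planted
  outliers in ≥96% of runs. With norms concentrated, the planted ×20
  outliers are detected in 50/50 seeds and removed exactly in 48/50.

## Numerical choices and degenerate inputs

* Uncentred SVD via LAPACK (`svd()`); components below
  $10^{-12} \sigma_{\max}$ are never retained, so rank-deficient inputs
  succeed.
* Orthonormality of $R R^\top$ holds to ~1e-14 in practice; the tested
  bound is 1e-8. Subspace preservation is asserted via principal angles at
  1e-6 (the `acos` route has a numerical floor near 1.5e-8).
* All-zero response columns, degenerate (all-flat) control distributions,
  fewer than 2 controls, fewer than 3 Grubbs survivors, gene-id mismatches
  between vectors and profiles, and empty enrichment universes are hard
  errors that name the offending samples/genes/flags.
* Identical profiles collapse to $k = 1$ with equal scores; rotation is
  skipped.
* Ties: mid-ranks in ranking and Spearman; gene-id order in top-gene and
  signature boundaries; sample-id order in score rankings — every ordering
  the package emits is deterministic.

## Problem sizes used by the test and acceptance suites

Unit and property tests run at 30–500 genes and 8–60 samples; the
end-to-end suites use the generator's default 2,000 × 150 condition (a
single decomposition takes ~8 s), 100 random matrices for the varimax grid
oracle, and 100 seeded replicates for the outlier screen. These sizes keep
a full check of every mathematical guarantee within a few minutes while
remaining large enough that spectral concentration, not luck, drives the
results.

## Limitations

The method is linear: responses that combine non-additively are split
across factors or absorbed into low-contribution components, and nothing
in the contribution spectrum distinguishes an uncharacterized biological
factor from structured noise. Factor labels remain the analyst's job —
the package emits the rankings, signatures and enrichment tables that a
labelling effort consumes, not the labels. Inputs must be complete
(no missing values) and share gene identifiers across data sets for
validation.
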