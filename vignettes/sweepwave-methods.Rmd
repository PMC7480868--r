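---
title: "Wavelet-based functional regression for selection scans: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-based functional regression for selection scans: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepwave)
```

## The problem

A selective sweep drags linked variation to high frequency and carves a
trough of diversity around the selected site; adaptive introgression — a
beneficial haplotype arriving by admixture from a diverged donor — leaves a
similar trough flanked by a crest of excess diversity. Both signals live in
the *spatial profile* of summary statistics along the chromosome, not in
any single window. sweepwave treats those profiles as functional data:
curves of windowed statistics are expanded in an orthonormal wavelet basis
and the wavelet coefficients enter penalized regression, either to classify
a region (neutral / sweep / adaptive introgression) or to predict the
parameters of selection.

## Feature curves

Nine statistics are computed in `p = 128` windows of 10 SNPs, each window
overlapping its neighbours by 5 SNPs, so one placement consumes
`10 + 127 * 5 = 645` segregating sites:

* mean pairwise sequence difference (pi-hat), the average Hamming distance
  over all haplotype pairs in the window;
* the haplotype-homozygosity statistics H1, H12 and H2/H1, where
  H1 = sum of squared haplotype frequencies, H12 pools the two most common
  haplotypes, and H2 = H1 minus the top frequency — H12 is sensitive to
  both hard and soft sweeps while H2/H1 separates them;
* the frequencies of the five most common haplotypes (zero-padded when a
  window holds fewer than five).

SNP-delimited windows (rather than fixed physical lengths) make sparse
regions behave conservatively. Sites with minor allele count below 3 are
removed first; this also guarantees every retained window is polymorphic.
The classified SNP of a placement is the middle SNP of the overlap between
the two central windows (0-based index 322 by default), and a genome scan
advances one window (5 SNPs) per iteration.

Optionally, four cross-window linkage-disequilibrium features are added:
the mean, variance, skewness and kurtosis of pairwise `r^2` between all
SNP pairs drawn from the 64 alternating non-overlapping windows —
`64 * 65 / 2 = 2,080` unique window pairs, each a symmetric
`64 x 64` block. A window paired with itself uses its `choose(10, 2) = 45`
distinct SNP pairs, so the printed pair count includes the diagonal.
Moments are population (biased) moments; kurtosis is non-excess
(`m4 / m2^2`); a degenerate, zero-variance pair set reports
`(mean, 0, 0, 0)`. The `r^2` between two sites is the squared Pearson
correlation of their 0/1 allelic states, equal to the classical
`D^2 / (pA (1-pA) pB (1-pB))`.

Every feature cell (statistic, window position) is standardized by its
training mean and population SD before the wavelet step; cells with zero
training variance get SD 1 and a warning. Per-cell (rather than global
per-statistic) standardization matches the functional-covariate convention
of centering each curve coordinate; the population-SD convention makes the
two-observation case come out at z-scores of exactly plus and minus one.
Standardization is estimated inside each cross-validation training fold,
never on held-out data, to avoid leakage.

## The wavelet representation

Each standardized curve of length `p = 2^J` is decomposed by an orthonormal
discrete wavelet transform, truncated at a coarsest level `j0`: `2^j0`
father (scaling) coefficients capture the broad trend and mother (detail)
coefficients at levels `j0 .. J-1` capture progressively finer structure.
Whatever `j0`, the segment has length `p` exactly
(`2^j0 + sum_{j=j0}^{J-1} 2^j = 2^J`), and the map is an isometry, so no
information is lost — `j0` changes the *basis* in which the penalty acts,
hence the smoothness of the fitted coefficient functions. The candidate
grid is `j0 in 0..J-2`, six levels at `p = 128`.

Two filter families are provided: Haar (pairwise sums and differences;
blocky reconstructions) and Daubechies least-asymmetric with 8 vanishing
moments (the `sym8` filter; smooth reconstructions). The filter length for
the least-asymmetric family is a package default, configurable to 4
vanishing moments. Boundary handling is periodic, the only mode that keeps
the `p -> p` map exactly orthonormal; since the transform is applied to
standardized residual-scale curves, wraparound effects are mild and shared
by training and test data. No wavelet package with this periodized
orthonormal construction is assumed; the transform is built here as an
explicit orthonormal matrix (p is at most 128, so this is also fast), which
makes Parseval's identity and exact invertibility structural rather than
approximate. The two-dimensional blocks use the separable row-then-column
transform.

Coefficient segments of all statistics are concatenated into the
observation's coefficient vector (length `9 * 128 = 1152`, plus
`4 * 64^2` when the LD blocks are enabled).

## Classification

Class probabilities follow a symmetric multinomial softmax with linear
scores `alpha_k + xi' zeta_k`. The penalty is the elastic net,
`sum_k [ gamma ||zeta_k||_1 + (1 - gamma) ||zeta_k||_2^2 ]` with weight
`lambda`: `gamma = 1` is the lasso (sparse wavelet coefficients, hence
piecewise-smooth coefficient functions), `gamma = 0` the ridge. Fitting is
delegated to glmnet's coordinate descent with `standardize = FALSE` (the
features are already on a common scale and the wavelet rotation must not
be undone).

Model selection runs seeded, class-stratified 10-fold cross-validation
over the `(gamma, j0)` grid (defaults `gamma in {0, 0.1, ..., 1}` and
`j0 in {0..5}`), with an automatic `lambda` path per combination; the
combination with the highest mean CV classification accuracy wins and is
refitted on all data. Ties prefer smaller `j0` (smoother functions), then
larger `gamma` (sparser models), then larger `lambda` (stronger penalty).
The `lambda` rule is minimum-CV-error rather than one-SE, matching
selection by raw accuracy. The final refit passes the `lambda` sequence
explicitly, because glmnet's automatically generated path stores the null
model at its head while explicitly supplied sequences are solved exactly —
without this the refit can silently degrade when CV selects the path head.

Because the basis is orthonormal, at `gamma = 0` the wavelet step provably
does not change the fit: ridge predictions in the wavelet domain equal
ridge predictions on the raw standardized curves at the same `lambda`
(verified in the test suite against a direct raw-domain fit). With any
lasso weight the equivalence breaks by design — sparsity in the wavelet
domain is the point of the representation.

Scan calls are deliberately conservative: a non-neutral argmax whose
probability does not exceed 0.7 is demoted to neutral, and exact ties go
to neutral. `reliability_curve()` profiles calibration in sliding
probability bins (width 0.05, step 0.001).

## Parameter prediction

The predictor is a multi-response linear model on the same coefficient
vectors, fitted jointly across responses (glmnet `mgaussian`: one `lambda`,
grouped penalty) — a joint fit was chosen over independent per-response
fits so that shared structure in the curves is estimated once; with a
single response the objective reduces to the plain gaussian elastic net
and is fitted as such. The selection coefficient `s` and the initial
beneficial-allele frequency `f` are log10-transformed (they are
scale parameters and must be positive); the onset or split time `T` is
log10-transformed by default but configurable. All transformed responses
are standardized to training mean 0, SD 1, which also makes predictions
exactly equivariant under affine rescaling of a response.
Cross-validation minimizes the mean held-out squared error summed over
responses. Predictions are reported on the standardized-log, log, or
natural scale; RMSE and MAE are available on any of them (MAE never
exceeds RMSE). Inputs whose coefficient-vector norm leaves the training
envelope trigger a warning rather than clipping, since accuracy outside
the training range is known to degrade.

## Synthetic fixtures and what they do (not) show

The generators in this package are *not* population-genetic simulations:
there is no coalescent, no recombination, no demography. Haplotype
fixtures copy a handful of founder lineages and pull a spatially varying
fraction of haplotypes onto one common lineage (a Gaussian bump peaking at
`trough_depth = 0.9` over about 15% of the region), which produces exactly
the windowed signature the statistics respond to — depressed pi-hat and
elevated H1/H12 in the center — with an optional diverged donor band for
the introgression-like crest. Curve-space fixtures add iid Gaussian noise
(`noise_sd = 0.05` by default, small relative to the between-class
template separation) to class templates whose baseline levels
(`pi = 2.5`, `H1 = 0.15`, `H12 = 0.2`, `H2/H1 = 0.6`, top haplotype
frequencies 0.25 down to 0.06) are typical mid-diversity values for
10-SNP windows. For parameter recovery, three latent uniforms deform the
template linearly and the responses are a known affine map of them on the
log10 scale, so out-of-sample R-squared close to 1 is achievable by
construction and chance-level performance is expected under permutation.

Passing these tests demonstrates that the statistical machinery — the
statistics, the isometry, the solvers, the cross-validation plumbing — is
correct. It does not demonstrate power on real genomes: training models
for empirical scans requires forward or coalescent simulations under a
realistic demography, which users must supply as labeled feature tables.
The missing-data generator reproduces the block-removal protocol used to
emulate alignability filters (ten disjoint contiguous blocks of 3% of
SNPs each, 30% in total, placed by seeded rejection sampling with a
10,000-attempt budget before declaring the packing infeasible).

## Numerical choices and edge cases

* Coordinates: bp positions are 1-based; BED mask intervals are 0-based
  half-open and converted internally (position `p` is retained iff
  `start <= p - 1 < end`).
* Fractional ms-style positions are scaled by the stated locus length and
  rounded; rounding ties are bumped by +1 bp to keep positions strictly
  increasing.
* Sites with any missing or unphased VCF genotype are dropped whole, with
  a logged count — the simplest rule consistent with handling block
  missingness upstream of the statistics.
* An even-length central overlap (possible for non-default layouts) takes
  the lower median as the classified SNP; window numbering in messages is
  1-based, all internal indices 0-based.
* A haplotype spectrum must be sorted, non-negative, and sum to 1 (1e-8
  tolerance); a single-haplotype spectrum yields H-statistics (1, 1, 0).
* Double standardization is a contract error, as is computing r-squared on
  a monomorphic site (the MAC filter makes this unreachable in the
  pipeline; it is asserted defensively).
* CV fold assignment is the only randomness in fitting; given the seed,
  selection and coefficients are reproducible bit for bit.

## Problem sizes used in the tests

The test-suite and acceptance fixtures use 50 observations per class for
classifier recovery (25 per class held out), 60/40 train/test observations
for predictor recovery, 600 random vectors for the isometry checks, 200
random windows for the statistic oracles, and 50-observation fixtures at
`p = 32` for the ridge-equivalence check — sizes at which every property
above is sharply testable while the whole suite runs in well under a
minute of fitting time.

## Known limitations

* Cross-population statistics (e.g. XP-EHH) and site-frequency-spectrum
  features beyond pi-hat are not implemented.
* Curve length must be a power of two; non-dyadic `p` via padding is not
  supported.
* The scan assumes phased, biallelic input; no phasing or imputation is
  attempted.
* Model quality on empirical data is entirely determined by the realism of
  the user-supplied training simulations; the built-in generators are test
  instruments, not substitutes for them.
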