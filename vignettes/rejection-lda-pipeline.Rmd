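---
title: "Classifying tissue fingerprints with a rejection-capable PCA-LDA pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tissue fingerprints with a rejection-capable PCA-LDA pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patient-derived xenografts (PDXs) occasionally grow a lymphoproliferative
mass at the engraftment site instead of the intended solid tumour.
Ambient laser-sampling mass spectrometry produces a lipid-range molecular
fingerprint of a tissue surface in about ten seconds, and a two-class
multivariate model on those fingerprints can flag the imposters at the
bench, long before histology. This package implements that analysis as a
reusable, fully tested pipeline: a synthetic scan-stream generator, the
spectral preprocessing, a PCA-LDA classifier with a Mahalanobis rejection
option, a specimen-grouped validation harness, and post-hoc diagnostics.

## The synthetic cohort generator

No public raw data accompany this analysis problem, so the generator is a
first-class module: it emits per-second scan streams with the statistical
structure the downstream stages assume, plus the ground truth needed to
score them.

* **Intensities are log-normal.** A signal peak in specimen $s$, scan $t$
  has intensity $\exp(m_p + u_{sp} + e_{spt})$ with peak mean
  $m_p$, a per-specimen, per-peak random effect
  $u_{sp} \sim N(0, 0.3^2)$ and scan noise
  $e \sim N(0, 0.4^2)$ (log units). Log-normality keeps intensities
  positive and heavy-tailed like real MS peaks; the specimen effect is
  what makes repeated sampling events of one specimen correlated, which
  is precisely why the validation must group by specimen.
* **Peak panels.** Each class carries a disjoint eight-peak panel in the
  lipid range (600–900 Da), on top of twelve shared peaks across
  100–1000 Da and a strong lock-mass peak at m/z 717.5070. The published
  feature list behind the real model is not public, so the defaults are
  lipid-plausible placements, not estimates.
* **Mass drift** is one additive shift per event,
  $N(0, 0.05^2)$ Da, applied uniformly to all of the event's peaks —
  matching the single internal-standard correction applied downstream.
  Chemical baseline noise (40 uniform peaks per scan) is kept out of a
  ±0.3 Da guard band around the lock-mass so that the *absence* of the
  internal standard is a well-defined condition.
* **Bad-data modes** violate exactly one QC criterion each: missing
  lock-mass (peak omitted), short duration (3 scans instead of 13), and
  low TIC (event globally rescaled below the 10³ floor). Default rates
  are the per-attempt rates observed in a published 2,079-attempt blind
  series (11 missing lock-mass, 23 short); low-TIC defaults to zero.
* **Scale defaults** mirror the study design: 20 + 90 training specimens
  at 12 events each (~1,314 data points) and a 30 + 118 specimen blind
  series at 14 events each (~2,079 attempts).

The noise magnitudes are free configuration — the source analysis reports
no noise model — chosen once to give clearly separated but not trivial
classes. What passing tests on this cohort show is that the *pipeline*
recovers structure it was promised; they cannot certify performance on
real tissue, which carries stromal contamination, necrosis, isotope
envelopes and operator variability the generator deliberately does not
model.

## Preprocessing

**Event delimitation.** Two entry points exist. `assemble_events()`
groups scans by a known attempt identifier — the primary path, because
bad attempts (e.g. an event whose total ion count never clears the
trigger) must still be *counted* against the duty cycle, and a
trigger-based recogniser can by construction never see them: an event
rescaled below the 10³ QC floor cannot contain a scan above the 10⁴
recognition trigger. `detect_events()` implements the instrument-style
state machine for undelimited streams (open on the first scan with TIC
> 10⁴, accumulate up to 13 qualifying scans, close on count or at 13 s).

**Quality control** applies the three bad-data criteria in a fixed
order — lock-mass present within ±0.25 Da of 717.5070, duration > 3 s
(≥ 4 scans at 1 scan/s; a 3-scan event fails), combined-spectrum
TIC > 10³ — and the first failing criterion names the status. The 10³
threshold is read as an *event-level* TIC (the per-scan 10⁴ threshold
serves only event recognition); the two thresholds are distinct in the
acquisition settings and conflating them would make the QC vacuous.

**Lock-mass correction** shifts every m/z by (reference − observed),
where the observed lock-mass is the most intense peak in the window.
A uniform additive shift is the simplest model consistent with a single
internal standard; whether the vendor software applies an additive or
ppm-proportional correction is not documented, and at a 300 ppm worst
case across the range the difference is far below the 0.1 Da bin width.
Correction necessarily precedes binning.

**Binning** accumulates peaks into half-open 0.1 Da bins
$[100 + 0.1j, 100 + 0.1(j+1))$, $j = 0, \dots, 8999$; a peak at exactly
1000.0 Da is out of range. Rows are divided by their in-range sum
(TIC normalization); all-zero rows are flagged rather than divided.
`rebin_1da()` sums blocks of ten bins for the 900-feature correlation
analysis; row sums are preserved exactly.

## The classifier

**PCA by the snapshot method.** With $n \approx 10^3$ events and
$p = 9000$ features, the principal components are computed from the
eigendecomposition of the $n \times n$ Gram matrix of the centred data —
algebraically identical to the SVD, an order of magnitude cheaper here.
Eigenvalues are clamped at zero and the retained count $r$ is the
smallest reaching the variance target (default 95%), further limited by
the numerical rank, by $n - k$ (so the within-class scatter stays
invertible for the $k$-class LDA), and by an optional hard cap — the
fixed-cap mode (262 components) mirrors the instrument-software analysis
path, while the variance rule is the default.

**LDA and class statistics.** The retained scores are projected onto the
$k - 1$ discriminant axes (one axis for two classes) with `MASS::lda`.
Per class, the model stores the cluster centre and covariance of the
training discriminant scores, shrunk toward the pooled within-class
covariance, $(1-\lambda)S_c + \lambda S_\text{pooled}$ with
$\lambda = 0.1$: the per-class spread is what the rejection rule needs,
and shrinkage guards the estimate when one class is small.

**Rejection and probabilities.** An event at discriminant score $t$ gets
$d_c = \sqrt{(t-\mu_c)^\top \Sigma_c^{-1} (t-\mu_c)}$ per class
(Cholesky-based; in 1-D simply $|t-\mu_c|/\sigma_c$, the number of
standard deviations from the centre). If $\min_c d_c > 4$ the event is
*unclassifiable* — the operational reading of a 4-SD recognition
boundary, since Mahalanobis distance is exactly "SDs from the cluster
centre". Otherwise the argmin class wins, with Gaussian-likelihood
softmax probabilities $p_c \propto \exp(-d_c^2/2)$ (computed with the
max-shift trick to avoid underflow). The exact probability formula of
the proprietary analysis software is not public; only the decision rule
is matched, not its probability values. Exact distance ties go to the
first declared class (lymphoma), for determinism. Distances are measured
in LDA space, consistent with "cluster centres" of a scores plot.

Specimen-level calls are the majority vote among the specimen's
classified events; the spatial concordance is the fraction agreeing with
the majority, and exact ties are flagged indeterminate.

## Validation harness

**Folds.** `make_folds()` assigns whole specimens to folds (never
splitting a specimen's events across train and test) with a single fold
cycle running across the shuffled class strata, so per-stratum
allocations stay within one specimen of balance and `k = n` degenerates
to leave-one-specimen-out. Leakage is asserted programmatically inside
`cross_validate()` on every fold.

**Accounting.** Correct + misclassified + unclassifiable = total holds
per fold and overall; accuracy is reported per classifiable event and
per all events, and both the pooled accuracy (total correct over total
classifiable) and the across-fold mean are emitted, since published
tables are ambiguous about which of the two an "average" denotes. The
duty cycle is classifiable/attempts × 100.

**The permutation null.** Specimens are reassigned to two pseudo-groups
of (near-)equal specimen count, stratified over the true classes so each
pseudo-group mixes both. Fold plans for the null are stratified on the
pseudo-group × true-class *pair*: stratifying on the pseudo-group alone
leaves a residual true-class imbalance between the training
pseudo-groups that is anti-correlated with the held-out fold's
composition (a finite-population effect), and on strongly separable data
the classifier "anti-learns" the real signal, dragging the null accuracy
systematically below chance (~38–44% in our experiments). With the joint
stratification the null is an unbiased ~50%. The acceptance band around
50% is a binomial 95% interval computed with *n* = specimens, not
events: whole specimens are permuted, so specimens are the independent
units and an event-level interval would understate the true sampling
variability of the permuted accuracy several-fold.

**SMOTE.** For the ~4:1 class imbalance, minority-class training scores
are oversampled in PCA space before the LDA step (classical SMOTE:
point + U(0,1) · (neighbour − point), k = 5 minority neighbours, reduced
with a warning when the class is too small). Test folds are never
augmented, and on a balanced, separable cohort the SMOTE report matches
plain CV.

**ROC.** Threshold-independent performance uses the out-of-fold
lymphoma probability by default (a signed discriminant score works
identically); the AUC is checked in the tests against the
Mann–Whitney identity $\mathrm{AUC} = U/(n_1 n_2)$.

**Blind evaluation** classifies every attempt of a label-sealed set,
then unseals the truth and reports attempts / bad / unclassifiable /
classifiable counts, the 2×2 contingency over classified events only,
per-class sensitivity and specificity (each class in turn as positive;
unclassifiable and bad events are excluded from the denominators because
no decision is made on them), the duty cycle, and the mean prediction
probability and mean spatial concordance. The dispersion convention for
the last two is mean ± 0.5 SD — implemented literally because that is
the convention of the tables this layout mirrors — with
`sd_multiplier = 1` restoring the conventional ± 1 SD.

## Diagnostics

The UMAP embedding (Euclidean metric, 25 neighbours, 2 components, 200
epochs, seed 123) is visualization-only; no classification decision
depends on it. The source settings list both "epochs 200" and
"iterations 250"; the embedding algorithm exposes a single epoch-like
parameter, so epochs drive the optimisation and the iteration count is
recorded as metadata. Single-threaded optimisation keeps the embedding
deterministic for a fixed seed.

Correlation maps are Pearson coefficients between the 900 one-Da
*features* across a subset of events (the stated 900 × 900 dimensionality
forces the feature-wise reading); zero-variance features are masked as
undefined rather than imputed, and at least three events are required.
`map_similarity()` correlates the jointly defined upper triangles of two
maps, so a query specimen's map can be scored against per-class control
maps pooled from specimens whose events were all correctly classified.
`jitter_data()` exports the 1-D discriminant scores with an overlap
statistic — the fraction of events inside the intersection of the two
classes' score ranges — which is ~0 for a separable cohort and ~1 for
identical distributions.

## Numerical choices and problem sizes

Half-open bins with floor arithmetic; Gram eigenvalues clamped at zero
with a $10^{-10}$ relative rank tolerance; Cholesky-based Mahalanobis
distances (a singular covariance raises an error rather than being
silently regularized at classification time); softmax probabilities
max-shifted before exponentiation; all randomness flows through local
seeds that restore the caller's RNG state. The test suite exercises the
full pipeline on small cohorts (6–15 specimens) and the acceptance
properties at the study scale (110 training specimens / ~1,300 events,
148 blind specimens / ~2,070 attempts), which completes in about a
minute; `scripts/acceptance.R` re-runs the study scale end to end.

## Limitations

The generator's separability and noise levels are configuration, not
estimates; real spectra are harder. The probability mapping matches the
decision rule, not the proprietary software's probability values. The
event recogniser cannot, by construction, surface low-TIC attempts from
an undelimited stream (they never trigger), so duty-cycle accounting of
bad data requires operator-delimited attempts. Multiclass (> 2) typing,
feature selection beyond PCA, nested tuning and calibration analysis are
out of scope.
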