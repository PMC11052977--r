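---
title: "Spectral equalization as a fairness preprocessor: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral equalization as a fairness preprocessor: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsfair)
```

## The problem

Clinical prediction models trained on pooled electronic-health-record
cohorts routinely perform worse for under-represented demographic
groups: the pooled optimizer spends its capacity on the patterns of the
majority group, and the features that carry risk information for
minority patients contribute little to training. `gsfair` implements a
*model-agnostic, data-level* mitigation: the patients-by-features score
matrix is carried to the frequency domain, its spectral magnitudes are
equalized to one, and the retrieved phase field is mapped back. The
classifier, its hyperparameters and the data split protocol stay
identical between the untransformed ("benchmark") and transformed
arms, so any difference in the group-fairness profile is attributable
to the transform alone.

## The transform

For an \(N \times M\) real matrix \(x\) the forward transform is the
unnormalized 2-D DFT,
\[
F[u,v] \;=\; \sum_{n=0}^{N-1}\sum_{m=0}^{M-1}
x[n,m]\, e^{-i 2\pi (un/N + vm/M)},
\]
and the inverse carries the \(1/(NM)\) factor, so `idft2(dft2(x))` is
the identity (`stats::fft` supplies both). Parseval's relation under
this convention is \(\sum |F|^2 = NM \sum |x|^2\); both identities are
enforced by tests at tolerances \(10^{-10}\) and \(10^{-9}\).

The Gerchberg–Saxton (GS) iteration retrieves the phase pattern that
connects two magnitude constraints: the image-plane magnitudes \(|x|\)
(the data) and a target spectrum whose magnitudes are all one (the
uniform-information constraint). Starting from i.i.d. random phases
\(\varphi^H_0 \sim U[0, 2\pi)\):

1. form the image-plane field \(|x| e^{i\varphi^H_k}\);
2. transform forward; keep the phase \(\varphi^T_k\), record the mean
   squared mismatch between the achieved magnitudes and the target;
3. impose the unit target magnitudes on that phase;
4. transform back; the phase of the result is \(\varphi^H_{k+1}\).

This is the classical error-reduction scheme, and the recorded
mismatch is non-increasing in \(k\) (asserted to \(10^{-9}\) slack).
After \(K\) cycles the output field is
\(z = \mathrm{idft2}(e^{i\varphi^T_K})\): it satisfies the spectral
constraint *exactly* (\(|\mathrm{dft2}(z)| \equiv 1\), asserted to
\(10^{-9}\)), while its image-plane magnitudes approximate \(|x|\) as
well as the two constraint sets allow. The returned real matrix is
either the elementwise modulus of \(z\) (default) or its real part,
optionally min–max rescaled to \([0,1]\) over the whole matrix.

### What the transform actually does to tabular data

Because phase retrieval drives \(|z|\) toward \(|x|\), the modulus
output is close to a (rescaled) copy of the input wherever the input
has large amplitude and dispersion, while low-amplitude, low-dispersion
columns receive proportionally much larger perturbations — structured
"information leakage" from the rest of the matrix. Two practical
consequences, both visible in the test suite:

* per-feature Shannon entropies are pulled together (near-constant
  columns gain variation, the entropy *spread* across features
  narrows), and
* the locations of smooth extrema are preserved (checked on a 2-D
  Gaussian bump fixture), so the output remains trainable.

The real-part output decorrelates far more aggressively from the input
(the phase rotates every cell); it is exposed as an option, and the
modulus is kept as the default as the conservative choice that
preserves trainability. Whether the image-plane or the
frequency-plane quantity is "the" output is genuinely ambiguous for
this family of methods; we return the image-plane field and expose the
complex `field` itself for diagnostics.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `cycles` | 50 | iterations | standard operating point; the error trace typically flattens within ~20 cycles, and the extra cycles are cheap |
| `output_mode` | `"modulus"` | — | non-negative, structure-preserving; `"real_part"` is the aggressive alternative |
| `rescale` | `"minmax01"` | — | the inverse transform's \(1/(NM)\) factor makes raw moduli tiny; a single global min–max keeps the matrix on a trainable scale without distorting relative column variances |
| `batch_size` | `"all"` | rows | full-matrix transform; batching (largest-remainder, group-balanced batches) exists for cohorts too large to transform at once |
| split fractions | 0.7/0.15/0.15 | — | train/validation/test, group-stratified |
| `threshold` | 0.5 | probability | hard-label threshold on the positive-class softmax output |
| MLP | 35–64–32–16–2 | nodes | reversed-pyramid rectifier stack, softmax head, Adam (`lr` 1e-3), class-weighted cross-entropy, early stopping (patience 10, max 200 epochs, batch 64) |

The classifier maps inputs to \([0,1]\) using one *global* train-set
min/max rather than per-column standardization. This is deliberate:
per-column standardization would equalize every feature's variance by
fiat and erase precisely the property — the relative distribution of
information across features — that the spectral transform manipulates
and the entropy profile measures.

## Fairness metrics

All metrics are computed per protected group \(a\) from the test-set
predictions: positive-prediction rate \(P(\hat Y = 1 \mid A = a)\),
FPR, FNR, accuracy, and Mann–Whitney AUC (rank-based, ties counted
half). Headline gaps are worst-case pairwise absolute differences
(equivalently max − min across groups): the demographic-parity
difference on the positive rates and the error-rate-parity differences
on FPR and FNR. Groups with a degenerate denominator (no negatives, or
no positives) are reported as missing, excluded from the gap, and
flagged with a warning — never silently zeroed. Every metric is
verified against brute-force record counting, and AUC additionally
against explicit pair counting, on randomized instances.

With five groups, "parity difference" could also be read as each group
versus the pooled rate; the per-group vectors are always exposed so any
alternative summary can be derived, and the headline number uses the
worst-case pairwise gap.

## Shapley attribution

Feature contributions are estimated by permutation sampling: for each
explained instance, random feature orderings are drawn, features enter
the coalition in order, and absent features are imputed from a randomly
drawn background row (interventional value function). The marginal
contributions telescope, so per ordering the attribution sum equals
\(f(x) - f(b)\) exactly; averaged estimates satisfy efficiency against
the full-background mean within Monte-Carlo error, and each per-feature
estimate carries its standard error. An exact enumerator over all
\(2^d\) coalitions (\(d \le 10\)) is the oracle: the estimator must
agree within \(3\,\mathrm{SE}\), and for additive models the enumerator
reproduces the closed form \(\phi_j = w_j (x_j - \bar b_j)\) exactly.
Per-class attribution mass is summarized by a uniformity index,
\(1 - \mathrm{Gini}\), so "more equalized feature contribution" is a
single comparable number.

## The synthetic cohort generator

The generator emulates the *structure* of a reference ICU mortality
cohort: 13,980 patients in five self-reported ancestry groups at
proportions 9814 : 1690 : 346 : 641 : 1489 (EA/AA/EAA/HA/OTH), 35
integer severity-score features on \([0, 22]\), a binary
death-within-24-h outcome at a 15% marginal rate, and optional random
missingness removed by complete-case filtering. The default test-scale
cohort is \(n = 2000\) at the same proportions.

Representation bias is built in mechanistically, not assumed:

* the majority group's risk signal sits in broadly dispersed scores
  (sd 3.5) that a raw-scale learner sees easily;
* every minority group's risk signal sits in coarsely quantized,
  near-constant scores (sd 0.3) whose raw-scale variation is too small
  to attract gradient mass — the kind of feature the spectral transform
  re-energizes;
* a dispersion gradient across the background columns spreads the
  per-feature entropies over roughly a one-decade band, matching the
  heterogeneity of real severity panels;
* a few near-constant columns carry small group-mean offsets
  (demographic correlates), and minority groups carry elevated
  baseline risk (logit offsets 0.4–0.8), which a pooled model can only
  express by conditioning on those correlates.

Latent coefficient magnitudes are identical across groups (effect size
1.2 per standardized informative feature): the majority's advantage
comes from representation share and raw-scale feature visibility, not
from a stronger true signal. The logistic intercept is calibrated by
bisection so the expected mortality rate hits the target to \(10^{-6}\)
before the Bernoulli draw. Under these defaults the benchmark
classifier's per-group accuracy spread exceeds 5 percentage points by a
wide margin — the bias the transform is then asked to mitigate.

What the generator does *not* emulate: real marginal score
distributions, inter-feature correlation structure, diagnosis codes,
time series, or any group-specific measurement process beyond the
mechanisms above. A directional result on these cohorts demonstrates
that the pipeline moves the metrics as designed under a controlled bias
mechanism; it is not evidence about any particular real dataset.

## Experiment protocol

Three cohort replicates are built from one patient pool under different
seeded row arrangements; each is split five times (group-stratified
0.7/0.15/0.15), giving 15 repetitions per arm and 30 model runs. The
repetition seed is derived as `master + 100 * cohort + repetition` and
drives the split, the transform's phase initialization, and the model
initialization, so the two arms of a repetition are exactly paired.
The transform is applied to the full feature matrix *before* splitting
(the protocol under evaluation); note that this couples the subsets
through the transform — information flows between training and test
rows inside the transform — which is why an `after_split` mode is also
provided for methodological comparison. The protected attribute is
carried as metadata and never enters the model inputs.

At the default scale the full paired experiment (30 trainings of the
64–32–16 network on 1400 rows, plus per-repetition transforms) runs in
about a minute on one CPU; the test suite uses a further-scaled-down
configuration (400 patients, 20 features, 2 × 2 runs) for its protocol
checks and the full default scale for the directional checks.

## Numerical choices and degenerate inputs

* Phases are stored in \([0, 2\pi)\) (`Arg` output wrapped modulo
  \(2\pi\)).
* A constant matrix min–max rescales to all 0.5 (midpoint) rather than
  dividing by zero.
* \(0 \log 0 = 0\) in entropy sums; integer-valued vectors are tallied
  one bin per value, continuous vectors use 23 equal-width bins by
  default, matching the 0–22 score cardinality, so pre- and
  post-transform entropies share a \(\log_{10} 23\) ceiling.
* A 1×1 transform is an exact fixed point: the unit-magnitude spectrum
  forces output modulus 1 regardless of the drawn phase, and the
  mismatch trace is constant.
* Largest-remainder allocation is used wherever integer counts must
  follow fractions (splits, batches), so every stratum is off by at
  most one row.
* NaN/Inf inputs to the transform raise an error directing the user to
  complete-case filtering; they are never silently imputed.

## Known limitations

* The modulus output preserves most high-amplitude structure, so
  strongly expressed demographic correlates survive the transform;
  mitigation through this channel is partial. The real-part mode
  destroys far more group information at a substantial cost in
  accuracy.
* At the default evaluation scale the smallest group contributes only
  a handful of test rows per repetition, so per-repetition group
  metrics are noisy; `pooled_group_metrics()` aggregates counts across
  repetitions for a stabler per-group view, and directional
  comparisons of per-repetition means inherit that noise.
* Transform-before-split is the protocol under study, but it couples
  the data subsets; results under `after_split` are the
  methodologically cleaner (and typically weaker-looking) variant.
* Training determinism holds under single-threaded BLAS; multi-threaded
  linear algebra may reorder floating-point reductions.
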