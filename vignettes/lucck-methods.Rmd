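---
title: "Classification with concave and convex kernels: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classification with concave and convex kernels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lucck)
```

## The problem this package addresses

Physiological signals from wrist wearables — blood volume pulse,
electrodermal activity, skin temperature, acceleration — are noisy in a
particular way: most samples are fine, but occasionally a feature is
wildly wrong (a motion artifact, a lost beat, a sensor dropout). Feature
tables derived from such signals therefore have *fat-tailed* error
distributions: the chance of a very large single-feature deviation is
small but nowhere near Gaussian-small. Distance-based learners built on
convex notions of similarity (Gaussian kernels, Mahalanobis distance)
punish one bad feature so hard that it can dominate the comparison of two
otherwise similar samples.

LUCCK (Learning Using Concave and Convex Kernels) addresses this with an
instance-based classifier whose per-feature similarity kernels decay
polynomially, so a single large deviation costs only a moderate factor.
It additionally learns, per feature, *how much* that feature should count.

## The model

Training data are feature vectors $x \in \mathbb{R}^n$ in classes
$C_1, \dots, C_d$ with $m_k = |C_k|$ and $m = \sum_k m_k$. Similarity
between two vectors is a product over features,

$$Q(x - y) = \prod_{i=1}^{n} \bigl(1 + \lambda_i (x_i - y_i)^2\bigr)^{-\theta_i},$$

a similarity function in the axiomatic sense: positive, even, and
strictly decreasing along rays from the origin (for $\theta_i > 0$). Each
factor behaves like an unnormalized Cauchy density — the "fat tail". A
test point is scored against each class by summing its similarity to
*every* training sample of that class,

$$R(x, C_k) = \sum_{y \in C_k} Q(x - y),$$

and classified to the class with the largest score (ties to the first
class level, for determinism). Class probabilities are the normalized
scores $p_k = R(x, C_k) / \sum_l R(x, C_l)$. Note that raw sums are used:
larger classes naturally accumulate larger scores. Imbalance is handled
explicitly by reweighting and undersampling (below), not by per-class
normalization.

## Parameter estimation

**Widths.** $\log Q_i$ is most sensitive to differences of size
$\lambda_i^{-1/2}$, so the width is tied to the feature's spread:
$\lambda_i = \Lambda / s_i^2$ with $s_i$ the standard deviation of
feature $i$ and $\Lambda > 0$ a global hyperparameter. A consequence
worth testing (and tested): the whole classifier is invariant to
rescaling any feature by a positive constant.

**Exponents.** Each feature is scored by how much closer samples sit to
their own class than to the pooled data, using the single-feature
proximity $R_i(x, Y) = \sum_{y \in Y} (1 + \lambda_i (x_i - y_i)^2)^{-\Theta}$
at the *global* exponent $\Theta$:

$$\alpha_i = \max\!\left(0,\; \sum_{k=1}^{d} \sum_{x \in C_k}
  \frac{R_i(x, C_k \setminus x)}{m_k - 1} -
  \frac{R_i(x, C \setminus x)}{m - 1}\right).$$

The exponents then keep the ratios of the $\alpha_i$ and sum to
$n\Theta$: $\theta_i = n \alpha_i \Theta / \sum_j \alpha_j$. So $\Theta$
is the *mean* exponent and the data decide how it is distributed:
discriminative features get $\theta_i > \Theta$, useless ones drift to 0
and drop out of the product entirely. The leave-one-out double sum makes
fitting $O(n m^2)$, which the test suite checks empirically as a log-log
slope of fit time against $m$.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| $\Lambda$ | global kernel width multiplier (dimensionless) | 1 | places peak sensitivity at one feature sd; the source method never fixes a value, so 1 is the neutral choice and `lucck_tune()` offers a grid |
| $\Theta$ | mean kernel exponent (dimensionless) | 1 | $\theta_i = 1$ is exactly Cauchy-shaped; same neutrality argument |
| `std` | sd convention for $s_i$ | population | the estimator and its test oracle must simply agree; exposed as a switch |
| `omega_max` | box bound on class weights | 100 | the LP's optimal face contains unbounded scaling rays of objective 0; a box keeps the solver on a finite vertex |
| `min_ratio` | undersampling floor (minority/majority) | 0.3 | extreme self-report scores occupy at most ~30% of a 1–10 scale |

## Class reweighting

With skewed class sizes the raw-sum rule over-predicts the majority. The
remedy is a multiplicative reweighting
$W_\omega(p)_l = \omega_l p_l / \sum_k \omega_k p_k$ with weights
$\omega_k \ge 1$ learned from the training set's leave-one-out table
$\tilde p_k(x) = R(x, C_k \setminus x) / R(x, C \setminus x)$. The exact
total-misclassification objective is nonlinear (it divides by
$\sum_l \omega_l \tilde p_l$), so the package minimizes the standard
linearization

$$\sum_j \max_k \{\omega_k \tilde p_k(x^{(j)})\} -
  \sum_k \omega_k \sum_{x \in C_k} \tilde p_k(x)$$

as a linear program (auxiliary variable $z^{(j)}$ per row for the max,
solved with `boot::simplex`). The exact nonlinear measure is implemented
only as a diagnostic (`misclassification_measure`), mirroring the
method's own linearization step. The surrogate is positively homogeneous
in $\omega$, which has two consequences used in testing: any optimum can
be rescaled so $\min_k \omega_k = 1$, and the grid-search oracle only
needs to search the slices with one coordinate pinned at 1.

## Signal features

`basic_stats`, `spectral_features`, and `range_stats` implement the
generic per-window statistics (5 + 6 + 6 named values) from which feature
tables are assembled with `extract_table`. Conventions are fixed so that
results are bit-reproducible:

* *Power* is the **mean** of squared samples, not the sum — window lengths
  vary between subjects and nights, and a length-dependent feature would
  not be comparable across rows.
* The spectrum is one-sided on the mean-removed window: interior
  amplitudes scaled by $2/N$, the Nyquist bin by $1/N$, DC excluded. An
  on-bin sinusoid of amplitude $A$ then reads exactly $A$, and
  `mean(x^2) == mean(x)^2 + sum(a_interior^2)/2 + a_nyquist^2` — the
  identity the Parseval test asserts.
* *Mean of the FFT frequencies* is the amplitude-weighted mean (spectral
  centroid). An unweighted mean of bin frequencies would depend only on
  $N$ and the sampling rate, i.e., carry no information about the signal.
* Medians over an even count average the two middle order statistics.
* A constant window has an all-zero spectrum; peak frequency and centroid
  are defined as 0 there so every feature is finite on finite input.
* Band splitting is a generic brick-wall FFT band-pass
  (`bandpass_filter`) with caller-supplied cutoffs; no canonical
  low/mid/high cutoffs exist for this feature set, so none are hardcoded.

Upstream denoising (wavelet thresholding, motion-artifact filtering, beat
detection, HRV derivation) is out of scope: the package consumes windows
that are already clean enough to summarize.

## The synthetic generator: what it emulates, and what it does not

`simulate_dataset` produces the regime the classifier is designed for:
a few informative features with class-separated means (separation in
noise-scale units, sign alternating by feature), the rest exchangeable
noise; Gaussian or Student-t noise (`df = 1` is Cauchy; one family covers
the fat-tail motivation); sporadic corruption that replaces exactly one
feature of an affected sample with mean ± `corruption_scale`; and
subject groups assigned round-robin within class, optionally with a
shared per-group offset. Everything is a deterministic function of the
seed.

Where the stated world did not pin a value, the defaults are fixed once:
noise scale 1; class-mean separation 1 noise-sd for the imbalance and
heavy-tail experiments (a moderately hard problem — mid-range AUROC —
which is where method differences are visible at all); corruption scale
10 noise-sd (clearly an artifact, not a tail draw). A green test on this
generator establishes that the estimators recover the structure they
assume; it does *not* establish performance on real wearable data, where
features are correlated, nonstationary within subject, and the label
itself is a noisy self-report.

## Numerical choices

* Products over many features underflow; all kernel products are
  computed as $\exp(\sum -\theta_i \log(1 + \lambda_i d_i^2))$ (with
  `log1p`), and score normalizations use a per-row max shift
  (log-sum-exp). The tests require agreement with naive products to
  1e-10 where those do not underflow.
* In the leave-one-out table the self-similarity is removed by setting
  the diagonal log-kernel to $-\infty$ *before* the shift, so the
  exclusion is exact at any scale.
* $\theta_i = 0$ is legal (feature ignored); the strict monotonicity
  axiom applies to features with $\theta_i > 0$.
* A constant feature has undefined $\lambda_i$; it is flagged, pinned at
  $\theta_i = 0$, excluded from the exponent normalization (the sum
  constraint then holds over the non-constant features), and verified to
  leave predictions identical to a fit without it.
* If every $\alpha_i = 0$ the ratio rule is undefined; the fit falls back
  to uniform $\theta_i = \Theta$, preserving $\sum \theta_i = n\Theta$.
* Ties in `predict` break to the first class level; `max.col(...,
  ties.method = "first")` makes this deterministic.
* Classes with fewer than 2 samples are rejected at fit time (the
  $\alpha$ formula divides by $m_k - 1$), naming the offending class.
* Model JSON stores every double as a 17-significant-digit decimal
  string, which round-trips binary64 exactly.

## Evaluation protocol

`grouped_kfold` partitions *subjects*, not samples: shuffled groups are
assigned greedily to the smallest fold by sample count, so no subject's
data ever straddles a train/test boundary. `undersample` trims only the
majority class, down to the largest count still satisfying the ratio
floor, and `cross_validate` applies it to training splits only — the
wording of the protocol does not localize the undersampling step, but any
placement touching test data leaks. Binary AUROC is the Mann–Whitney
statistic on the positive-class probability; multiclass AUROC is out of
scope. The in-package 7-NN (`knn_scores`) exists solely as the
qualitative comparison point for the heavy-tail claim.

## Known limitations

* Instance-based: the model *is* the training set; memory and prediction
  cost grow with $m$, and fitting is $O(n m^2)$.
* Probabilities are normalized proximity sums, not calibrated posterior
  estimates; with strong imbalance they are biased toward the majority
  unless reweighting or undersampling is used.
* The reweighting LP optimizes a surrogate; the learned $\omega$ is a
  vertex of an optimal face and is not unique — tests assert the
  objective value, never the weights themselves.
* No regression variant, no kernels beyond the polynomial-decay family,
  no approximate nearest-neighbor acceleration.
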