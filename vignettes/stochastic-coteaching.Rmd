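---
title: "Stochastic co-teaching: model, design choices, and what the synthetic experiments show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic co-teaching: model, design choices, and what the synthetic experiments show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stocot)
```

## The problem and the method

Supervised training assumes the recorded labels are correct. When a
fraction *r* of them is wrong, deep models eventually memorize the wrong
labels, and accuracy degrades — most severely for *bias* noise, where a
class is systematically recorded as a specific other class (observer
bias), so the corruption is consistent and learnable. Co-teaching
counteracts this with two models, independently initialized and therefore
carrying different decision boundaries: each model ranks the units of a
mini-batch and the *other* model trains only on the units it endorsed.
The asymmetry matters — a model never filters its own training signal, so
its selection mistakes are not self-reinforcing.

Conventional co-teaching endorses the `1 - forget_rate` fraction of units
with smallest loss, ramping the forget rate linearly over the first
epochs. Its weakness is operational: the forget rate must approximate the
noise rate, which in real tasks is unknown.

Stochastic co-teaching removes that requirement. Selection compares each
unit's *recorded-label posterior* — the probability the model assigns to
the label written in the training set — against a random threshold

$$t \sim \mathrm{Beta}(\alpha, \beta), \qquad
t^\ast = \min(\max(t, 0.01), 0.99)\cdot\eta_n, \qquad
\eta_n = \max\!\big(0, \min(1, (n - n_0)/\delta)\big),$$

keeping units with posterior $\ge t^\ast$. Nothing about $r$ enters the
rule. The number of rejected units is whatever the threshold happens to
reject, so after the models converge, the rejected units are
predominantly the mislabeled ones and the per-epoch **rejection rate
estimates $r$** (`estimate_noise_rate()` averages the last ten epochs).

Two safeguards prevent degenerate selections. Clamping the raw draw into
$[0.01, 0.99]$ guarantees that near-certainly-wrong units (posterior
below 0.01) are always rejected and near-certain units always kept, and
excludes the empty selection at $t = 1$. Independently, if a draw keeps
fewer than 10% of a mini-batch's units, the threshold is redrawn, at most
five times; after five failures the batch is presumed to be dominated by
noise, no update happens, and the caller moves to a fresh mini-batch.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha`, `beta` | 32, 2 | Beta shape; left-tailed ($\alpha \gg \beta$) draws high thresholds with occasional low ones |
| `clamp_lo`, `clamp_hi` | 0.01, 0.99 | clamp bounds on the raw draw (probability units) |
| `n0`, `delta` | 10, 10 | ramp delay and length, in epochs |
| `min_frac` | 0.10 | minimum kept fraction per draw |
| `max_attempts` | 5 | redraws before the mini-batch is skipped |
| `epochs`, `batch_size`, `lr` | 100, 128, 0.001 | training loop (Adam) |

$\alpha = 32, \beta = 2$ (mode $31/32$, mean $\approx 0.94$) is the
default because a high-but-not-extreme threshold rejects mislabeled units
once the models are moderately confident, while the distribution's left
tail still re-admits hard-but-correct examples; shapes with
$\alpha < \beta$ do the opposite and keep noise in. `beta_pdf()` and the
shape sweep `sweep_alpha_beta()` let users inspect and test alternatives;
shapes below 1 warn, since bimodal threshold distributions concentrate on
the degenerate extremes. The ramp ($n_0 = \delta = 10$ epochs) exploits
the memorization effect — networks learn general structure before noise —
so early training sees every unit.

## Design choices the method statement leaves open

* **Clamp before, not after, the ramp scaling.** The effective threshold
  is `clamp(t) * eta_n`, so during warm-up ($\eta_n = 0$) it is exactly 0
  and everything is selected. Clamping after scaling would impose the
  0.01 floor from epoch one and reject units before selection is meant to
  begin, contradicting the gradual introduction.
* **Ties keep.** Selection uses $\ge$, so a threshold of 0 keeps every
  unit and a unit exactly at the threshold survives.
* **One threshold per learner per mini-batch.** The two learners draw
  independent thresholds; sharing one draw would couple their selections
  and erode the decision-boundary diversity the method relies on. For
  pixel tasks each learner draws an independent threshold *field*.
* **Loss normalization.** Kept-unit losses are averaged (not summed), so
  the gradient magnitude does not scale with how many units survived.
* **Skipped batches still count.** A resampled mini-batch contributes all
  its units as presented-and-rejected in the epoch's rejection rate;
  silently dropping them would bias the noise estimate downward exactly
  when noise is worst.
* **Multi-label granularity.** How per-unit selection applies to
  non-exclusive multi-label tasks is underdetermined; `stocot` treats
  each (instance, label) pair as a unit with posterior $p$ for a recorded
  positive and $1-p$ for a recorded negative. This lets a partially
  mislabeled instance contribute its correct labels while its wrong ones
  are rejected. Exact-match subset accuracy is the default multi-label
  summary, as the strictest common choice.
* **Pixel-level 10% rule.** The minimum-kept-fraction safeguard counts
  units, i.e. pixels, in segmentation batches — consistent with pixels
  being the selection unit everywhere else.
* **Threshold-field tiling.** Coarse threshold grids (default style
  16×16) are expanded by nearest-neighbor block replication in row-major
  cell order; with non-divisible shapes the blocks differ by one pixel.
  Any smooth upsampling would blur thresholds across block borders for no
  benefit.
* **Conventional tie-break.** `conventional_select()` keeps the
  $\lceil (1-f)\,n \rceil$ smallest losses with ties broken by original
  position (stable sort), making the baseline reproducible bit-for-bit.
* **Reporting.** Both learners' test accuracies are logged and the
  summary averages them; the package does not silently pick the better
  learner.

## Numerical and reproducibility choices

Learners are one- or two-hidden-layer perceptrons (ReLU, softmax,
log-sum-exp-stabilized) trained with Adam
($\beta_1 = 0.9, \beta_2 = 0.999, \epsilon = 10^{-8}$); their
initialization is He-scaled Gaussian from an explicit seed, so two seeds
give two decision boundaries and one seed is exactly reproducible. The
experiment runner derives learner seeds and one seed per epoch from the
experiment seed; per-epoch reseeding of the data order means the
selector's own threshold draws cannot perturb which mini-batches later
epochs see — a run whose schedule never activates is bit-identical to
standard training, which the test suite asserts. Generators
(`make_ring_task()`, `make_synthetic_seg()`, `corrupt_labels()`) are pure
functions of their seeds. Exact-count corruption flips
$\mathrm{round}(r\,n_c)$ labels per class, so the injected noise rate is
a number, not an expectation. Surface metrics operate on 4-connectivity
boundary pixels with physical pixel spacing; Dice of two empty masks is
`NaN`, and distance metrics on an empty mask are an error rather than a
sentinel value.

## What the synthetic data emulates — and what it does not

`make_ring_task()` places six Gaussian classes evenly on a circle
(radius 1, within-class $\sigma = 0.15$ by default). The geometry is the
point: bias noise flips labels to the *cyclic successor*, and on the ring
the successor really is the nearest class in feature space, so bias noise
is the hardest confusion, as it is meant to be. The default $\sigma$ is
chosen so classes overlap slightly (adjacent centers sit ~6.7 within-class
standard deviations apart): a separable task would be solved perfectly
even by standard training under heavy noise, making noise robustness
trivially indistinguishable, while much larger overlap would confound the
rejection of mislabeled units with the rejection of genuinely ambiguous
ones. `make_synthetic_seg()` draws disc/annulus/blob geometry (blood
pool, myocardium, papillary muscles) with intensity noise, and corrupts
annotations by absorbing papillary pixels into the blood pool in a
configurable fraction of images — the fraction is a parameter rather than
a fixed constant, with 0.4 as the default.

Desk scale here means: 6000 training and ~2000 test samples, MLPs of a
few thousand parameters, 100 epochs — about 20 seconds per run on one
CPU; the package's acceptance script runs the three noise conditions in
about a minute. Passing these experiments shows the *mechanism* works:
cross-selection filters corrupted labels it has never been told about,
the rejection rate tracks the injected rate within a few points (with the
expected slight overshoot from ambiguous-but-correct units), stochastic
selection beats standard training under heavy bias noise, and left-tailed
threshold shapes dominate the shape sweep. It does not show that these
effects transfer to deep convolutional models on natural images, to
real inter-observer variability (which is feature-dependent, unlike the
label-conditional noise simulated here), or to loss functions other than
cross-entropy, whose different calibration would interact differently
with posterior thresholds.

## Known limitations

* Noise models are label-conditional (transition-matrix) only;
  instance-dependent noise is out of scope.
* The reference learners are deliberately small; the co-teaching loop
  accepts any object implementing `predict_posteriors()` /
  `learner_update()`, but no deep-learning backend is bundled.
* The rejection-rate estimator assumes converged, calibrated-enough
  posteriors; on tasks the learner cannot master, the rejection rate
  overshoots the noise rate, and the accompanying accuracy trace — not
  the estimator itself — is what reveals this.
* Training two models costs roughly twice the compute of one.
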