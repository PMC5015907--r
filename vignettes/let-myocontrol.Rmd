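---
title: "Linearly Enhanced Training for simultaneous and proportional myocontrol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linearly Enhanced Training for simultaneous and proportional myocontrol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(letmyo)
```

## The problem

Modern multi-fingered hand prostheses expose more independently drivable
degrees of freedom (DOFs) than a user can calibrate by example. A
regression-based intent detector maps a d-channel surface-EMG (sEMG)
envelope $x \in \mathbb{R}^d$ to a vector of DOF activations
$y \in [0,1]^K$, and is conventionally trained *on-off*: the user holds
full activations ($y_k = 1$) and rest ($y = 0$), and the regressor
interpolates the proportional in-between. The catch is simultaneity: a
machine that has only ever seen single-DOF activations has no evidence
about what, say, a combined index-and-little-finger flexion looks like in
sEMG space, and the number of combinations grows exponentially with $K$ --
recording them all is not an option.

Linearly Enhanced Training (LET) is a data-*augmentation* answer, not a new
learning algorithm. Its structural assumption is that the sample cluster
$X_{ij}$ of a multi-DOF activation lies close to a weighted linear
combination of the single-DOF clusters:

$$X_{ij} \approx F(X_i, X_j),$$

with two model functions: the **single-weight** model
$F_1(X_i, X_j) = \alpha_{ij}\,(X_i + X_j)$ (one scalar per combination) and
the **multi-weight** model
$F_m(X_i, X_j) = \alpha^i_{ij} X_i + \alpha^j_{ij} X_j$ (one weight per
member DOF). Both generalise to triples and quadruples. The weights are
sub-unit: simultaneously flexing several fingers produces *less* signal per
finger than flexing each alone (the familiar force deficit of multi-finger
tasks), so $\alpha$ shrinks as the cardinality grows.

## Estimating the weights

Let $\bar X_i$ denote cluster centroids (channel-wise means). Minimising
the Euclidean distance between the synthetic and the measured multi-DOF
centroid gives both estimators in closed form:

* single-weight: the scalar projection
  $\hat\alpha_{ij} = \dfrac{\bar X_{ij} \cdot s^\top}{s \cdot s^\top}$,
  with $s = \bar X_i + \bar X_j$ (`fit_alpha_single()`);
* multi-weight: the ordinary least-squares coefficients of $\bar X_{ij}$ on
  the stacked single-DOF centroids (`fit_alpha_multi()`), requiring
  $k \le d$. We read the normal-equations form as OLS of the multi centroid
  on the hyperplane spanned by the single-DOF centroids, which is the only
  orientation of the printed transposes consistent with that geometric
  description. A numerically singular Gram matrix (collinear centroids,
  plausible with strongly correlated muscles) falls back to the
  minimum-norm pseudo-inverse solution with a warning rather than failing:
  collinearity is a property of the subject, not a user error.

The single-weight model is nested in the multi-weight one, so the
multi-weight residual can never exceed the single-weight residual -- a
property the test suite asserts on every input it generates. The projection
is also scale-equivariant, so no amplitude normalisation is needed before
fitting.

Weight estimation is offered in two modes (`estimate_alphas()`):
**individual** (each subject's weights from their own data) and **general**
(for each target subject, the average of all *other* subjects' fits -- the
leave-one-subject-out population model a prosthesis would ship with).
Single-weight estimates cluster tightly by cardinality, so `group_alphas()`
reduces the model to one weight per cardinality
($\alpha_\mathrm{DF}, \alpha_\mathrm{TF}, \alpha_\mathrm{QF}$); the
`LET1` training flavor uses the grouped weight by default because that is
the form a population model takes in online use.

Two open choices are resolved as follows, both configurable: repetitions
are **pooled per subject** before taking centroids (the centroid of pooled
samples is the sample-weighted mean of per-repetition centroids, and
pooling uses all data symmetrically); and **no rest-baseline subtraction**
is applied before fitting (`subtract_rest = FALSE` by default). With a
rest envelope an order of magnitude below activation level, the bias this
induces on $\hat\alpha$ is below 0.015 in the bundled generator's
conditions; the option exists for recordings with a larger baseline.

## Training sets

`build_training_set()` assembles the (cluster, target) pairs for one
training flavor over $K$ ordered DOFs, always including the rest cluster at
target $\mathbf 0$ and each single-DOF cluster at its unit vector:

* `SF` -- singles only (the lower bound on what training can achieve for
  multi-DOF test data);
* `MF` -- singles plus the *measured* multi-DOF clusters (the upper bound:
  the machine has seen the real thing);
* `LET1` / `LETm` -- singles plus *synthesized* multi-DOF clusters from
  `combine_single_alpha()` / `combine_multi_alpha()`.

Targets are multi-hot on the member DOFs and strictly binary (on-off
training). When clusters of unequal length are combined row-wise, all
inputs are truncated to the shortest (first rows kept): deterministic and
order-preserving, whereas resampling would manufacture interpolated
samples with temporal structure the recording never had.

## Regression and evaluation

The reference regressor is ridge regression on random Fourier features
(RR-RFF): $z(x) = \sqrt{2/D}\,\cos(\Omega x + \phi)$ with
$\Omega_{lj} \sim \mathcal N(0, 1/\sigma^2)$,
$\phi_l \sim \mathcal U[0, 2\pi)$, approximating the Gaussian kernel
$k(x, y) = \exp(-\lVert x-y\rVert^2 / 2\sigma^2)$. Its model size is set by
$D$, not by the training-set size -- the decisive property here, because
LET-augmented sets grow combinatorially with $K$. Plain linear ridge
(`"rr"`) and exact Gaussian-kernel ridge (`"krr"`, a least-squares SVM)
flank it as baseline and exact-kernel reference; the test suite uses the
exact kernel machine as the independent oracle for the feature
approximation (agreement within 0.02 RMS at $D = 5000$). All fits are
closed-form, multi-output, and intercept-free (rest at target zero anchors
the origin). Base frequencies are drawn once per seed and divided by
$\sigma$, so a bandwidth sweep reuses the same randomness and the error
curve is smooth in $\sigma$.

Prediction error is the range-normalised RMSE,
$\mathrm{nRMSE} = \frac{1}{y_{\max}-y_{\min}}\sqrt{\tfrac1n\sum(\hat y - y)^2}$
with $y_{\max} = 1$, $y_{\min} = 0$; multi-output errors are pooled over
(sample, DOF) cells so one scalar summarises a model (per-DOF breakdowns
can be computed from `predict()` output directly).

Because the envelope filter makes neighbouring samples strongly dependent,
samples are only treated as independent *across repetitions*:
`repetition_cv()` holds out whole repetitions, trains the requested flavor
on the remainder (fitting fold-local "individual" weights for LET flavors
unless a general table is supplied), and always tests against the held-out
repetition's full measured single- *and* multi-DOF data. The bandwidth
$\sigma$ is tuned by `grid_search_sigma()` on a fixed variable-step grid
(0.05 steps on [0.05, 1], 0.1 on (1, 3], 0.2 on (3, 6]; 55 values), with
ties broken towards small $\sigma$ and a reported plateau set (all
$\sigma$ within 0.05 nRMSE of the minimum), since the CV curve is
typically flat around its minimum. $\lambda$ (default 1) and $D$ (default
500) are deliberately excluded from the search: the kernel bandwidth is
the one hyperparameter the method is sensitive to.

## Online target-acquisition metrics

An online attempt presents a target $y^\ast \in \{0, 0.5, 1\}^K$ and gives
the user up to $t_d = 30$ s to hold the prediction inside the box
$\lvert \hat y_k - y^\ast_k \rvert \le 0.25$ *for all $k$ simultaneously*
(the conjunction over DOFs -- including inactive ones at 0 -- is the only
reading that makes an attempt a single success/failure event). Holding for
$t_s = 1.5$ s is a **success**; touching the box without ever holding
$t_s$ is an **overshoot**; never producing a dwell is **unreachable**
(`classify_attempt()`). Dwells are measured between samples whose endpoints
are both in target, so an isolated in-target sample contributes zero dwell.
Task completion time runs from stimulus appearance to the end of the first
qualifying dwell; the longest stable time is capped at $t_s$ and reported
for overshoots (and, capped, for all attempts). `summarize_attempts()`
computes $SR = n_s/n_\mathrm{total}\times 100\%$ and
$UA = n_u/n_\mathrm{total}\times 100\%$; TCT is averaged over successes
only, since it is undefined elsewhere. The advertised "3.125% of the
working space" size of such a target box is reproducible as
$0.5^5 = 3.125\%$ only under a 5-dimensional normalisation we cannot
reconstruct; the package treats the tolerance, not the percentage, as the
defining quantity.

## The synthetic cohort generator

`make_subject()` / `make_cohort()` produce seeded subjects designed to
exercise exactly the structure LET assumes, with ground truth on record in
a sidecar: a nonnegative rest centroid (~0.1 in normalised envelope
units), one unit-norm rectified direction per DOF (optionally mixed
towards their mean by a crosstalk factor, default 0.1), and true
combination weights per cardinality. Multi-DOF plateaus emit
$\mathrm{rest} + \alpha^\ast_{|A|} \sum_{i \in A} \ell_i g_i \mathbf d_i$:
sub-additivity is modelled by the sub-unit scale itself, which *is* the
physiological force-deficit interpretation. Channel noise is generated
white, smoothed by the same 1.5 Hz first-order Butterworth used for real
envelopes (so synthetic data has the temporal correlation that motivates
repetition-wise CV), scaled to `noise_sd` (default 0.1, i.e. 10% of the
direction magnitude), added and clipped at zero. Repetition-to-repetition
variability is a multiplicative per-(repetition, DOF) gain jitter
(default sd 0.05).

Defaults are the study conditions throughout the tests: 10 subjects, 4
analysed repetitions of the 13-activation routine (4 single-DOF, 6 pairs,
2 triples, 1 quadruple), 4 s plateaus at 62 Hz (248 samples per active
cluster), 2 s rest gaps, grouped true weights (0.53, 0.37, 0.29). The
acquisition protocol's additional first repetition is the maximum-force
calibration pass and is not modelled, hence 4 repetitions and 4-fold CV.
The per-subject deviation of the true weights is drawn per *cardinality*
(all pairs of one subject share a weight) with sd 0.04: printed
across-subject spreads of estimated weights (~0.06-0.09) conflate
combo-to-combo and estimation scatter with genuine between-subject
variation, and the phenomenon that makes a population model viable at all
is precisely that subjects agree closely. An additive interaction term
violating linearity is deliberately absent (default 0): the generator
emulates the regime in which LET's assumption holds.

What passing tests on this generator do **not** show: robustness to
nonlinear muscle interactions, electrode shift, fatigue drift, or
non-stationary baselines -- real sEMG phenomena outside the generator's
model. They do show that the estimators, training-set mechanics,
regressors, CV bookkeeping and metrics are correct, and that the
end-to-end ordering of training flavors (measured < LET-augmented <
singles-only, in nRMSE on identical folds) emerges for the modelled
reasons: the general weights mismatch an individual subject only through
between-subject spread, while singles-only training is missing the
multi-DOF geometry entirely. "Separated beyond fold sd" is assessed on the
*paired* per-fold differences, the statistically meaningful yardstick when
methods share folds; raw per-method fold sds are dominated by fold
difficulty common to all methods.

## Numerical choices and degenerate inputs

* Envelope filtering initialises the IIR state at steady state for the
  first sample (filter the deviation from the first sample, add it back;
  exact for unity-DC-gain filters), avoiding startup transients on short
  recordings. A cutoff at or above Nyquist is a configuration error.
* Plateau segmentation trims a configurable guard margin (default 0.5 s)
  from active-plateau edges to drop ramp transients; rest phases, having
  no fixed duration, are kept whole. The generator's ideal step plateaus
  need no guard, so synthetic pipelines use `guard = 0`.
* A zero centroid sum in `fit_alpha_single()` is a degenerate-geometry
  error; a singular Gram matrix in `fit_alpha_multi()` warns and returns
  the minimum-norm solution.
* Grid-search ties go to the smallest bandwidth; the RFF seed is fixed
  across the grid.
* Session summaries with no successes report `NA` completion time rather
  than 0 -- an absent quantity, not a fast one.

## Problem sizes used by the bundled analyses

The test suite runs cohorts of 1-10 subjects with the full 13-activation
routine and feature counts of 100-5000 depending on what the test probes;
the shipped acceptance analysis (`scripts/acceptance.R`) uses the full
10-subject cohort, the ten training-set definitions (each multi-DOF
combination with its singles, plus the three thumb/index/little pairs as a
set), six training modalities, RR-RFF at $D = 200$, and a single bandwidth
selected on one subject -- the package's own choice of desk-scale problem
size, leaning on the finding that the tuned parameters are uniform across
subjects. The simulated online session drives 10 fresh three-DOF subjects
through 3 repetitions of the 18-target sequence on 10 s trajectories with
generator noise. The task is simulated *closed-loop*, as it is performed:
the displayed virtual hand shows the prediction stream smoothed by the
same 1.5 Hz first-order envelope filter used everywhere else in the
pipeline (the one cutoff constant the package has), and the simulated
subject integrates the displayed error into their enacted activation
levels at 1.5/s, never below zero. This exercises the full
train-once-on-singles, control-multi-DOF loop; but an error-integrating
controller is not a human, and the resulting success rates characterise
the synthetic conditions — in particular the generator's envelope noise
amplitude, to which kernel-model prediction jitter is directly
proportional — not human performance.

## Limitations

The linearity assumption is adopted, not tested against alternatives;
weights are time-invariant; incremental LET deployment is realised as a
batch refit on the augmented set; and classification-style or deep intent
detectors, synergy decompositions, and statistical hypothesis testing of
method differences are out of scope.
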