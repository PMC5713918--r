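---
title: "Fuzzy correlation models for surrogate-based tumor tracking: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy correlation models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzytrack)
```

## The correlation problem

During surrogate-guided radiotherapy the treatment machine sees only the
motion of three optical markers on the patient surface — a 9-channel signal
$x(t) \in \mathbb{R}^9$ at roughly 25 Hz — while the quantity that matters,
the 3-D position $y(t) \in \mathbb{R}^3$ of the tumor (localized through
implanted fiducials), is measured only at sparse X-ray imaging instants.
Clinically realistic training sets are tiny: 4–27 synchronized $(x, y)$
pairs gathered over one to ten minutes. A correlation model fitted to those
pairs substitutes for continuous imaging; it is rebuilt whenever new
imaging arrives.

This regime has three defining difficulties that shaped every design
decision below:

1. **n is tiny and p is not.** Even a single first-order Sugeno rule has 10
   free consequent parameters per output; rule bases induced from breathing
   data typically hold close to one rule per training point.
2. **The inputs are strongly collinear.** All nine channels are driven by
   one latent breathing phase, so the training inputs occupy a low
   dimensional, loop-shaped manifold inside $\mathbb{R}^9$.
3. **Patients differ structurally.** Some are well served by an affine
   external-internal map; others show regime switches, saturation,
   hysteresis, or baseline drift. No single model family wins for everyone,
   which motivates per-patient model selectivity.

## The three fuzzy models

All three models share the first-order Takagi–Sugeno skeleton, built
independently per internal coordinate (three single-output rule bases per
model). Rule $i$ has a Gaussian premise per input dimension,
$\mu_{id}(x_d) = \exp(-(x_d - c_{id})^2 / 2\sigma_{id}^2)$, a firing
strength $w_i = \prod_d \mu_{id}(x_d)$ (product conjunction), and an affine
consequent $f_i(x) = p_i \cdot x + r_{0,i}$; the output is the normalized
weighted average $f(x) = \sum_i \bar w_i f_i(x)$ with
$\bar w_i = w_i / \sum_j w_j$. Because Gaussian premises are strictly
positive, $f$ is everywhere a convex combination of the rule outputs.

Model fitting operates on per-dimension min–max normalized data (each input
and output dimension mapped to $[0,1]$ from its training range; constant
dimensions are flagged and given unit scale). The normalization is stored
in the model and inverted at prediction time, so predictions are in mm and
invariant to affine rescaling of raw channels, and so the clustering radius
below is a fraction of the data width uniformly in every dimension.

**SUB-FIS.** The joint (input ⊕ output) normalized space is clustered by
the subtractive procedure: every data point is a candidate center with
potential $D_i = \sum_j \exp(-\|x_i - x_j\|^2/(r/2)^2)$; the
maximum-potential point becomes a center, a squashed Gaussian (radius
$1.25\,r$) is subtracted, and selection continues while the relative
potential exceeds 0.5, stops below 0.15, and applies the standard
distance-based criterion in between. Ties break to the lowest point index,
making the procedure deterministic and order-invariant. Each cluster is one
rule; premise centers are the input block of the cluster center; premise
widths are $\sigma = r \cdot \mathrm{range} / \sqrt 8$, the width at which
the per-dimension Gaussian reproduces the clustering influence range. The
operating radius is $r = 1/3$ of the data width — the clinical operating
point — configurable along with the squash/accept/reject constants, which
are not dictated by the problem and default to the standard 1.25/0.5/0.15.

**FCM-FIS.** The cluster count is inherited from a subtractive pass, then
fuzzy C-means minimizes
$J_m = \sum_i \sum_j u_{ij}^m \|x_i - c_j\|^2$ by alternating the standard
membership update
$u_{ij} = 1/\sum_k (\|x_i - c_j\| / \|x_i - c_k\|)^{2/(m-1)}$ and the
weighted-mean center update, stopping when
$\max |U^{(k+1)} - U^{(k)}| < \varepsilon$. Defaults $m = 2$,
$\varepsilon = 10^{-5}$, 200 iterations: the conventional choices, since
the source procedure specifies none. Premise widths are the
membership-weighted spread around each refined center — typically much
wider than the SUB-FIS widths, which is the main practical difference
between the two models: FCM-FIS rules overlap and blend, SUB-FIS rules are
local.

**ANFIS.** The five-layer network realization of the same Sugeno system,
initialized exactly as SUB-FIS and trained by hybrid learning: each epoch
re-solves all consequents by the same global least squares used everywhere
else, then takes one batch gradient step on every premise $(c, \sigma)$
with a normalized step length. The step length (initial 0.01 in normalized
units) follows the classical heuristic — ×1.1 after four consecutive error
decreases, ×0.9 after an up–down oscillation. The returned model is the
epoch snapshot (including the initialization) with minimum training RMSE,
which guarantees hybrid learning never returns something worse than its
starting point. Defaults of 20 epochs and batch (not sample-wise) gradients
fit the tiny training sets; gradient correctness is property-tested against
central finite differences. A zero step length freezes the premises, which
reduces ANFIS to SUB-FIS exactly.

## Estimating the consequents: the one genuinely open choice

The source procedure never specifies how the consequent parameters are
estimated. The package minimizes the *prediction* objective
$\sum_t (y_t - \sum_i \bar w_i(x_t) f_i(x_t))^2$ jointly over all rule
consequents — a linear least-squares problem in $R(d{+}1)$ unknowns. With
clinical training sizes this system is almost always rank-deficient
(difficulty 1 above), and how it is regularized determines the entire
behavior of the package, so the choice deserves its own section:

- **Shrinkage target.** The rank-deficient solve shrinks toward the *global
  first-order fit* of $y$ on $x$ (every rule's consequent pulled toward the
  same affine map), not toward zero. Shrinking toward zero would make
  out-of-support predictions collapse toward a constant; shrinking toward
  the pooled affine fit makes the degenerate limit of every fuzzy model a
  plain linear regression — the right fallback for this physical problem,
  and the reason noiseless affine couplings are reproduced exactly by all
  three builders (a property the test suite asserts at $10^{-6}$ mm).
- **Penalty level by GCV.** A fixed tiny ridge would interpolate the X-ray
  localization noise through the near-one-rule-per-point bases, pinning the
  tracking error well above the noise floor. Both the global target and the
  per-rule deviations therefore choose their ridge level by generalized
  cross-validation over a log grid (the deviation grid floored at
  $10^{-8}$). Exactly representable data have zero residual at any level,
  so GCV costs nothing in the noiseless limit; with noisy collinear designs
  it damps the noise-dominated singular directions (difficulty 2).
- **Diagnostics.** Whenever the rank-deficient path is taken the fitted
  rule base carries a warning flag, and the achieved training residual is
  stored.

## The adaptive layer

**Selectivity.** The training set is split temporally: the earliest
$\lceil 0.75 n \rceil$ points fit all three candidates, the most recent
quarter checks them by 3-D RMSE, the winner is retrained on 100% of the
points and deployed. The split is temporal, not random, because tracking is
a forecasting task: the premise of selectivity is that the model best at
the end of training stays best during treatment. The winner is retrained on
the full set because discarding a quarter of 4–27 points is wasteful and
the check set's only purpose is ranking. Ties break in the fixed order
FCM-FIS, ANFIS, SUB-FIS (the order of overall clinical preference), and
"tie" means a check-RMSE difference within 1% relative (floored at
$10^{-6}$ mm absolute): check sets hold 1–7 points, the standard error of
an RMSE from $k$ points is of order $1/\sqrt{2k}$, so sub-percent
differences carry no evidence and letting them dictate the choice would be
selection by noise. Candidates that fail to train are excluded with a
logged reason. Fewer than 4 training points is an explicit
"insufficient data for selectivity" error.

**Updating.** New imaging points are appended (timestamps must follow the
accumulated ones) and the model is rebuilt from scratch — same kind, same
hyperparameters — on the accumulated set. Rebuild equivalence (the updated
model predicts identically to a fresh train on the concatenated set) holds
by construction and is asserted in the tests.

**Tracking and scoring.** Inference runs at the external trace's native
timestamps and is stateless, so tracking a concatenation equals
concatenating tracked segments; throughput on one CPU exceeds the 25 Hz
acquisition rate by three orders of magnitude. Errors are scored at imaging
points with the model state in force before each point arrives (the
prequential convention); dense-truth evaluation against the simulator's
noiseless trajectory is additionally available for synthetic data.
Cohort summaries use linear-interpolation quantiles (type 7), stated
explicitly because interquartile ranges depend on the convention.

## The synthetic patient

The simulator stands in for proprietary clinical logs; it is a first-class,
tested module, and its defaults define the package's study conditions.

Latent breathing is a cosine-power waveform: channel $c$ follows
$\mathrm{baseline}_c + \mathrm{drift}_c t + a_k A_c
\cos^{2n}(\phi(t)/2 + \varphi_c)$, where the phase $\phi$ advances $2\pi$
per cycle with the cycle period redrawn each cycle
($\tau \sim N(4\,\mathrm{s}, \mathrm{jitter}^2)$), $a_k$ is a per-cycle
amplitude factor, and $n = 2$ gives the characteristic long end-exhale
dwell. Marker amplitudes default to a few mm (largest in AP/SI), optical
noise to 0.1 mm, X-ray localization noise to 0.5 mm per axis, and the
external–internal lag to 0.2 s. The internal truth is a configurable
coupling applied to the lag-shifted *latent* (noise-free) surface signal:
affine, two-regime piecewise-linear (a hinge on a superior–inferior driver
beyond a quantile threshold), or sigmoidal saturation. Hysteresis adds an
odd-in-phase offset proportional to $\sin^3\phi$ — the cubed form contains
a third harmonic, so the inhale/exhale loop it opens cannot be closed by
any affine function of the nine surface channels (the nine phase-offset
channels span only the first two harmonics). Localization noise enters at
the imaging instants, where it belongs physically; the dense truth
trajectory is noiseless, which also keeps the zero-noise affine case
exactly affine.

Two documented presets operationalize the easy/difficult dichotomy.
`control`: mild jitter, no drift, affine coupling, no hysteresis. `worst`:
per-patient structural draws — coupling family (hinge or sigmoid), hinge
gain 2.5–5 mm/mm, drift scale 0.5–1.5 of a baseline profile up to
1.5 mm/min, hysteresis 0.1–0.4, period jitter 0.4–0.8 s — reflecting that
the difficult group is difficult *heterogeneously*, which is precisely what
makes per-patient selectivity worthwhile. What the simulator does **not**
emulate: tissue deformation (the coupling is a point map), cardiac motion,
imaging-geometry effects, irregular coughing or body shifts, and
non-stationary noise. Passing tests on this generator therefore demonstrate
correctness of the algorithms under controlled quasi-periodic motion, not
clinical performance.

## Validation experiments and problem sizes

The experiment scenarios are frozen as package functions so the test suite
and the acceptance script share one definition:

- `noise_floor_params()` — affine coupling, zero lag and hysteresis (both
  would break affinity, and this experiment isolates noise), 27 training
  points over 603 s, $\sigma_n = 0.5$ mm. Scored against noisy validation
  imaging points, whose irreducible 3-D RMSE is
  $\sigma_n \sqrt 3 \approx 0.87$ mm; the selected model's median over 20
  seeds lands within 20% of that floor.
- `planted_fcm_params()` — hinge coupling, low noise (0.2 mm), 1 mm/min
  drift, 8 training points over 300 s. The drift pushes the check window
  away from the fit support, where FCM-FIS's wide overlapping premises
  generalize and the local SUB-FIS/ANFIS premises do not; FCM-FIS is
  selected in ≥ 90% of 50 replicates.
- `drifting_params()` — strong baseline drift; rebuilding on 4 new imaging
  points roughly halves the next-minute RMSE (median over 20 seeds).
- the cohort contrast — 6 control + 6 worst patients, 360 s each, 8
  training points, validated on the second half of each session: the worst
  median RMSE exceeds the control median several-fold, and the
  selectivity tracker's error fraction beyond the 6 mm clinical threshold
  never exceeds that of the worst fixed candidate.

These sizes (6–27 points, 5–10 minutes, tens of seeds) were chosen to be
clinically representative at desk scale; the full suite runs in about a
minute.

## Numerical choices, degenerate inputs, limitations

- Premise widths are floored at $10^{-4}$ (normalized) so singleton
  clusters cannot produce singular premises; ANFIS re-floors after every
  gradient step and logs any non-finite-gradient event.
- Firing strengths are evaluated in the log domain, so inputs far outside
  the training support still infer (the nearest rules dominate) instead of
  dividing zero by zero.
- FCM handles points coincident with a center by assigning full membership
  there (split equally among coincident centers).
- Synchronization interpolates the external trace linearly at internal
  timestamps and drops points whose bracketing external samples are more
  than 0.2 s apart (about five sample periods); it never fabricates points.
- Model files are versioned JSON at full double precision; a schema
  mismatch or truncated file is an error, never a silent misparse.
- Known limitations: no latency compensation (the models correlate, they
  do not forecast ahead); selection happens once per training set rather
  than continuously; hysteretic patients are fundamentally limited because
  any instantaneous map $x \mapsto y$ must average the inhale and exhale
  branches; and the clustering radius is fixed at its clinical operating
  point rather than optimized per patient.
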