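---
title: "Methods: models, estimators and design choices in photoplast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in photoplast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(photoplast)
```

photoplast implements the computational machinery of a single-neuron optical
BCI learning experiment with interleaved photostimulation mapping: the
closed-loop task itself, trial-epoch tuning quantification, causal
connectivity estimation, tuning-based regression of connectivity and its
learning-related changes, recurrent-network models that discriminate local
from upstream plasticity, and a hand-wired preparatory circuit. This
vignette explains each model, the parameters that matter, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## The closed-loop BCI

The conditioned neuron's (CN) raw fluorescence is mapped to an analog
voltage by a piecewise-linear function anchored at a lower threshold
`FL` (median of a spontaneous period) and an upper threshold `FU`
(maximum of the same period); the voltage times a gain of 7.9 steps/s/V
sets the stepping frequency of a motorized reward port (685 μm per step).
A trial is a hit when cumulative port travel reaches 6 mm (from a 7 mm
start) within 10 s. After a hit the CN must stay below `FL` for 200 ms,
followed by a 2 s delay and a ~300 ms port return, before the next trial.

Numerical choices:

* Port motion integrates the *expected* displacement
  `step_size * f_step * dt` per frame, keeping the loop exactly
  reproducible; a stochastic mode (`stochastic = TRUE` in
  `run_closed_loop()`) samples Poisson step events at `f_step` instead.
* The median of an even-length spontaneous trace is the mean of the central
  pair; `FU == FL` is flagged degenerate because the linear segment of the
  voltage map is then undefined on an empty interval.
* Online motion correction in the real system delays feedback by roughly
  half a second; this is modelled as an optional fixed lag
  (`feedback_lag`, default 0) because no per-frame delay distribution is
  available.
* A miss resets the port logically at once, followed by the port-return
  dead time; partial mid-trial returns are not modelled.

## Task epochs and tuning

Four epochs partition a trial: pretrial (2–1 s before trial start), early
(start to 1 s before reward), late (final 1 s before reward) and reward
(0–3 s after reward). Epoch means use frames with timestamps in the
half-open window `(start, end]`. Availability rules keep the epochs
mutually consistent: pretrial is computed only after hit trials (trial
initiation differs after misses), late and reward exist only on hit trials,
and the early epoch is likewise restricted to hit trials — of duration above
1 s, otherwise the window is empty. All trial-resolved analyses use the
first 40 trials.

Each neuron is summarized by the 4-vector of trial-mean epoch activities
and the 4-vector of per-epoch ordinary-least-squares slopes against trial
index (computed on available trials; a slope needs at least two). The
8-dimensional concatenation feeds the Δconnectivity regression.

* The CN-specificity bootstrap draws one neuron per session and takes the
  median slope across sessions; the p-value is the fraction of null draws
  at or above the CN median. The seed is a required argument — there is no
  default, so library results are always reproducible on purpose.
* Candidate-CN screening ranks neurons by activity-modulation fraction
  (time above one SD of activity) and trial-start tuning; similarity to the
  reference CN is Euclidean distance in rank space, and the closest 5% are
  flagged. Rank space was chosen over raw statistics because the two
  screening statistics live on incommensurate scales.
* The epoch-weighted population average normalizes by the summed absolute
  weights so the output keeps ΔF/F units; signed weights may cancel, which
  is intended (oppositely tuned neurons push the population trace in
  opposite directions).

## Causal connectivity

For every photostimulation repeat, the repeat response is the mean raw
fluorescence in the 300 ms after stimulus offset minus the mean in the
200 ms before onset, normalized by the neuron's repeat-averaged pre-stimulus
baseline; the 100 ms stimulation period is excluded as laser-contaminated.
At 20 Hz these windows hold 6 and 4 frames. The PS response is the repeat
mean divided by the sample (n−1) standard deviation across repeats, defined
only with ≥10 repeats; the across-day ΔPS response divides the difference
of means by the root of the summed variances. Masks: targets within 20 μm
of a site, non-targets 30–100 μm away (distances are 2-D within the imaging
plane); for paired days, a neuron keeps a class only if it qualifies on
both days. Causal connectivity W (and ΔW) is the PS (ΔPS) response
restricted to non-targets.

* Neurons targeted by the immediately preceding application are skipped for
  that application (their activity is often still elevated).
* The baseline is computed over retained repeats only.
* A non-positive baseline (possible in synthetic data) invalidates the
  (neuron, group) entry rather than flipping response signs.
* The entire chain is invariant to rescaling any neuron's raw trace by a
  positive constant — a property test in the suite.

## Tuning regression

Regressors take the form `A[i,g] = Y_i * X_g` with
`X_g = sum_j X_j * W~[j,g]` over the targets of group g weighted by their
PS responses, `Y` ranging over 1 and the non-target's tuning components and
`X` over 1 and the tuning components. The `(Y=1, X=1)` column *is* the
summed target response and is used as the control column, giving 24 tuning
columns for 4-dimensional tuning and 80 for 8-dimensional tuning. For ΔW
fits the control is the change in summed target response, and the target
weighting uses the later (learning-day) session's PS responses.

* Predictors are z-scored before the lasso; coefficients are reported in
  standardized units with a raw-scale back-transform in `coef()`. Tuning
  components are not standardized before forming products — only the final
  columns are — so interaction columns keep their product interpretation.
* The penalty grid is 50 log-spaced values from `lambda_max` (the smallest
  penalty zeroing all slopes) down to `1e-4 * lambda_max`; the penalty
  minimizing mean out-of-fold squared error over 10 folds is selected, and
  out-of-fold predictions cover every row exactly once. Fold assignment can
  be grouped (e.g. by session) to avoid leakage.
* Hypothesis tests are one-sided positive Wald tests on an OLS refit
  containing the intercept, the control column(s) and the focal regressor —
  not on lasso coefficients, whose sampling distribution is ill-defined.
  Collinear focal/control pairs are rejected with the condition number.
* A constant response (e.g. a no-learning control producing ΔW ≡ 0) yields
  the null model directly rather than a degenerate path.

## RNN plasticity-locus models

The cortical circuit is a vanilla rate RNN, `n = 100` hidden neurons
(motor cortex) and `d = 10` inputs (upstream drive), with
`dt = 0.01 s`, `tau = 0.1 s`, tanh nonlinearity and per-step hidden noise
of SD 0.01. Weights initialize as `scale/sqrt(fan_in) * N(0,1)` with
recurrent scale 0.5 (spectral radius ≈ 0.5, avoiding long-lived modes) and
input scale 0.1; the weaker input pathway is needed for correlations to
reflect recurrent connectivity. Each trial is a 1 s pretrial followed by a
1 s late period (durations are a package choice; the model only needs two
distinct periods, and the suite checks that ±50%-scaled periods behave the
same way), with distinct constant inputs drawn once per network and the
hidden state reset to zero between trials.

After a 10-trial stabilization period with frozen weights, the CN is the
neuron with above-median pretrial and late activity whose pretrial/late
difference is smallest (ties to the lowest index); the activity target is
the 95th percentile of the CN's stabilization activity. Training is
supervised BPTT on the late-period MSE, one trial per update, with credit
routed through `w_back = w_bci + w~`, `w~ ~ 0.25 N(0,1)` zeroed at the CN
so `w_back · w_bci = 1` exactly. The misaligned update is deliberately not
the loss gradient; the test suite therefore validates the backward pass by
finite differences with `w_back = w_bci`, for every locus including the
upstream-RNN variant.

* Plasticity loci: `input` (upstream), `recurrent` (local), `both` (the
  input-layer rate is rescaled once, on the first update, so the two loci
  produce comparable update magnitudes), `excitability` (per-neuron gain),
  and `upstream_recurrent` (recurrent weights of a separate 20-unit
  upstream RNN). Weights outside the locus are bit-identical after
  training — an exact test.
* Learning-rate selection: rates on a log grid over four decades are
  scored on calibration seeds; a rate is usable if training is stable
  (loss decreases) and every calibration run reaches 90% of the target
  within the trial budget. Among usable rates with median trials-to-target
  ≤ 30, the slowest-completing one is selected — the training speed closest
  to the animals' tens-of-trials timescale. Runs whose loss never drops
  below its initial value are flagged rejected and excluded, with the
  rejection fraction reported.
* In-silico photostimulation clamps one neuron at a time to `h_pert = 1`
  (comparable to tanh saturation; the experimental analog fixes but does
  not report this value) for 1 s, after a 1 s settle and a 1 s baseline,
  with 5 repeats batched as parallel trajectory columns. The response is
  the during-minus-before activity change. On linear networks this equals
  the analytic propagator column `(I − W₋g,₋g)⁻¹ W₋g,g h_pert`, an oracle
  test at relative tolerance 1e-3 (using a long, transient-skipped clamp).
* Noise is injected through the input layer during photostimulation. Its
  magnitude is unstated in the experimental description; the default
  (`ps_input_noise = 0.02`) was calibrated so that repeat-to-repeat
  variability is dominated by the locus-independent hidden noise. A large
  value (e.g. 0.1) introduces a variance-mediated artifact through the
  tanh curvature that gives the *upstream* model a weak spurious
  correlation-change/connectivity-change association, contrary to the
  qualitative behaviour the models are meant to exhibit; the
  discrimination analysis (pooled positive Wald tests over all ordered
  pairs and seeds) is otherwise insensitive to this parameter.
* The hidden-to-input loop variant (`w_csc_scale > 0`) participates in the
  forward dynamics and photostimulation; training credit through the loop
  path is not propagated (the loop exists to study perturbation routing,
  not gradient routing), and `loop_input_ratio()` quantifies loop drive
  relative to task input.

## Preparatory circuit

A 41-neuron rectified firing-rate network (`h <- h + (dt/tau)(−h + W φ(h) +
U x)`, φ = max(0, ·), no noise): 10 pretrial neurons with recurrent
excitation and an external pretrial drive, 10 trial neurons driven during
the late period and broadly excited by the pretrial population, five
initially untuned 4-neuron modules with internal excitation, and one reward
neuron. The model transitions directly from pretrial to late period (1 s
each), collapsing early and late responses as in short trials. The CN is a
module neuron outside the preparatory-to-trial pathway; weak baseline
pretrial→module and pretrial→reward projections (0.003 per connection)
realize the widespread pretrial excitation motif while keeping modules
essentially untuned before learning. The reward neuron receives trial-
population input and does not project back — its wiring beyond existence is
an assumption.

Learning is applied by hand (no online plasticity): strengthened pretrial
input onto one neuron per module (the Δpretrial population), plus either a
broadcast increase from Δpretrial neurons onto all downstream populations,
or, alternatively, feedback from Δpretrial neurons onto the pretrial
population. Baseline weights and increments are not dictated by any
measurement; they were calibrated once (script in `inst/scripts/`) so the
CN's late activity sits just below the movement threshold (0.13 vs 0.15)
before learning and above it in both variants afterwards, with loop gains
well inside stability. The in-model Δconnectivity regression uses
deterministic single-neuron photostimulation and 2-epoch tuning vectors
(pretrial/late plus their learning changes). The direct motifs appear as
positive lasso coefficients; in the feedback variant the "Δpretrial→All"
pattern is *effective* — routed polysynaptically through the pretrial
population — so the sparse multivariate fit attributes it to collinear
interaction terms while the marginal positive-Wald association is strongly
positive. Both statistics are reported.

## Synthetic-data generator

The generator provides ground truth for every pipeline stage. It emulates:
distance-dependent connectivity (difference-of-Gaussians kernel with its
sign change at a configurable excitation radius, 60 μm by default, with
multiplicative lognormal weight jitter); planted tuning-coupled structure
(stronger output from pretrial-tuned neurons; like-to-like coupling among
reward-tuned neurons — both centered so the distance profile is
unaffected); epoch-tuned drives that tile the trial; within-session CN
amplitude growth via a per-trial gain schedule closed through the actual
BCI state machine; calcium-like dynamics (exponential kernel, 1 s decay,
motivated by a slow indicator); and photostimulation blocks with direct
target drive, one-step propagation through the true weights, and additive
Gaussian repeat noise.

It does **not** emulate: optics (point-spread functions, off-plane
excitation), indicator nonlinearity and saturation, neuropil
contamination, behavioural state changes, non-stationary baselines, or
dynamical network responses to stimulation (one-step propagation is the
default forward model for speed). Passing tests therefore demonstrate that
the estimators recover the structure the generator plants under realistic
noise — not that they are robust to every artifact of real imaging data.
Relatedly, the session generator's pairwise correlations are driven mostly
by shared epoch drives, so the correlation-versus-connectivity association
in the *data* pipeline is directionally positive but underpowered at desk
scale; the RNN models, where the association is a designed property, carry
that analysis.

Default study conditions: 100 groups of 10 sites (< 400 μm pairwise
separation, sampled within a disc of half that radius), 600 ms
inter-stimulus interval, 100 ms stimulation, ~20 repeats, minimum 10
repeats; sessions of 40 trials at 20 Hz with a 2.2-fold gain ramp
(matching the observed within-session CN amplitude growth); 1000 × 1000 μm
field of view. Test and example runs use 80–200 neurons and 30–100 groups
so the full suite runs in minutes on one CPU; these sizes are stated here
as the package's chosen problem sizes for its own validation experiments.

## Group-size experiment

`run_group_size_experiment()` fixes the total number of stimulation events
and varies the number of neurons stimulated per event. Fidelity is defined
as pairwise-weight reconstruction quality: each neuron's incoming weights
are ridge-regressed from its mean per-group responses onto the group
membership matrix (using only groups in which that neuron was not directly
or nearly directly driven), and scored by correlation with the true weights
over all well-separated pairs. Columns never probed at a given budget stay
at the ridge prior of zero, so sparse coverage is penalized — the sense in
which larger groups reconstruct the matrix faster, rising with group size
and saturating around ten neurons per group.

## Known limitations

* Cross-day neuron identity is assumed given; no image registration.
* Distances are 2-D; no z-component or off-plane stimulation model.
* The lasso path and cross-validation are delegated to glmnet; the
  regressor algebra, response statistics, masks, BPTT and circuit models
  are implemented in the package and validated against independent oracles
  (hand arithmetic, enumeration, analytic propagators, finite differences).
* Trace containers are plain R matrices with CSV/JSON serializers; no
  HDF5 container is provided.
* The binned-scatter visualizations used in the experimental figures are
  display conventions and are not reproduced; all statistics are computed
  on unbinned pairs.
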