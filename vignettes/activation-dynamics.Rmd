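---
title: "Muscle activation dynamics: models, numerics and fitting workflows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle activation dynamics: models, numerics and fitting workflows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imadyn)
```

## The problem

Insect skeletal muscle — the locust hind-leg extensor tibiae is the reference
preparation here — is driven by very few motoneurons firing at low rates
(1–50 Hz). Its isometric force shows two features that simple low-pass models
of activation miss: single twitches have a delayed, sigmoid rise with a
rounded peak lasting hundreds of milliseconds, and the peak force of a spike
train grows *supra-linearly* with stimulation frequency, strongest around
10–30 Hz (force potentiation). `imadyn` implements, side by side, five
activation dynamics models that have been used for such muscle — two
non-linear and three linear — together with the spike-train stimulus
machinery, comparison metrics, parameter-fitting workflows and a synthetic
data generator, so the models can be compared under identical conditions.

Activation dynamics here means the transform from motoneuron spike times to
isometric force at fixed muscle length. Contraction dynamics
(force–length–velocity scaling), tendon elasticity, sag and catch effects,
and length-dependent activation are deliberately out of scope.

## Stimulus representation

A `spike_train` holds strictly increasing spike onset times plus the epoch
duration. `constant_train()` and `poisson_train()` generate the standard
protocols; arbitrary trains load from plain text. For simulation, each spike
becomes a pulse of width 1 ms (`pulse_shape()`): a half sine approximating the
depolarised phase of the muscle action potential, or a square pulse. Two
normalisations are used by the models:

* **unit peak** — the calcium-cascade (Hatze-family) models take the endplate
  signal with amplitude 1;
* **unit area** — the Wilson models treat spikes as impulses, so each pulse is
  rescaled *after sampling* so its trapezoidal integral is exactly 1,
  independent of the sampling step.

Spike onsets snap to the nearest sample of the `dt` grid (at the default
5 kHz a 1 ms pulse spans 5 samples) and overlapping pulses sum — linear
superposition of endplate events. The whole stimulus is shifted by a neural
conduction delay, 10 ms by default; the delay shifts the input, never the
output.

## The models

**Hatze-Zakotnik** (`simulate_hatze_zakotnik()`): two cascaded second-order
stages,
$$\ddot\beta + \theta_1\dot\beta + \theta_2\beta = \alpha(t), \qquad
  \ddot\gamma + \theta_3\dot\gamma + c\,\theta_4\gamma = \beta(t),$$
mapping the endplate signal $\alpha$ to T-tubular membrane potential $\beta$
to free calcium $\gamma$, which is read out as force. Potentiation enters
through the factor
$$c(t) = \frac{t^2}{K_1+t^2} - \frac{t^2}{K_2+t^2} + 1,$$
evaluated at the inter-spike interval $t$ preceding each spike and applied to
$\theta_4$ piecewise-constantly from that spike onward. With
$K_1 \ge K_2 \ge 0$, $c \in [0,1]$, $c \to 1$ as $t \to \infty$, and the
minimum sits at $t = (K_1K_2)^{1/4}$ — shortly before the twitch peak, where
summation is strongest. Lowering $\theta_4$ makes twitches larger and
slower-decaying, which is exactly what potentiation looks like in this
muscle.

Two conventions deserve note. First, the *first* spike of any train carries
$c = 1$ (no potentiation for a single twitch), even though $c(1\,\mathrm{s})
\approx 0.986$ for the published constants; the single-twitch convention wins
over the literal formula, and `inter_spike_intervals()` encodes the same
convention by assigning a 1 s interval to the first spike. Second, for
non-constant (e.g. Poisson) trains the instantaneous frequency is taken as
the reciprocal of the preceding inter-spike interval; this reproduces the
constant-frequency case exactly and extends naturally to irregular input.

**Hatze-van-Zandwijk** (`simulate_hatze_van_zandwijk()`): the same cascade
with fixed $\theta_4$, followed by a sigmoid active-state transform
$q(\gamma) = 1/(1+\exp[A(\log\gamma - \log\gamma_0)])$. The calcium state is
floored at $10^{-12}$ before the logarithm so the resting state is defined.

**Non-linear Wilson** (`simulate_wilson_nl()`): first-order calcium kinetics
$\dot C_N = u - C_N/\tau_c$ driven by unit-area pulses, a Hill saturation
$x = C_N^m/(C_N^m + k^m)$, and a force stage
$\dot F = A x - F/(\tau_1 + \tau_2 x)$ whose time constant depends on
saturation. Some fitted parameter sets have $\tau_1 + \tau_2 < 0$ at full
saturation; the constructor accepts them with a warning, since the state may
never visit that range.

**Zajac** (`simulate_zajac()`): the classic bilinear first-order model with
activation time constant $\tau_{act}$ and deactivation
$\tau_{deact} = \tau_{act}/\beta$, $0 < \beta < 1$; excitation $u \in [0,1]$.

**Blümel** (`simulate_blumel()`): a single-pole recursive low-pass filter,
`a[n] = (1-filter)*scaling*u[n] + filter*a[n-1]`, with time constant
$-\Delta t/\log(\mathrm{filter})$.

**Linear Wilson** (`simulate_wilson_linear()`): the third-order model
$\theta_3 a''' + \theta_2 a'' + \theta_1 a' + a = \theta_0 u$, solved as a
companion system; parameter sets whose characteristic roots are not strictly
in the left half-plane are rejected.

## Numerical schemes

All simulators run at a fixed step (default `dt = 0.0002` s, matching the
5 kHz acquisition rate of the recordings these models were developed for).

* The cascade, non-linear Wilson and third-order linear models use classical
  fixed-step fourth-order Runge-Kutta, with mid-step input values taken as
  the average of the bracketing samples.
* The cascade additionally offers an `"iterative"` solver: each linear
  second-order stage is advanced by its *exact first-order-hold
  discretisation* $x_{k+1} = A_d x_k + B_0 u_k + B_1 u_{k+1}$, with the
  matrices precomputed (via a scaling-and-squaring matrix exponential) once
  per distinct potentiation value. This is why the iterative variant is fast:
  the per-sample work is a handful of multiplications. The two solvers agree
  to better than $10^{-3}$ relative on all shipped parameter sets, which the
  test suite checks.
* The Zajac equation is scalar linear within a step, so it is advanced by the
  exact integrating-factor (exponential) update with the excitation held at
  its mid-step value — unconditionally stable for any step.
* The Blümel recursion *is* its own exact scheme.

Halving the step changes every model's output by well under 0.1% relative,
which the suite verifies.

## Published parameter sets

`published_params()` ships the per-animal fits for three slow-motoneuron
(SETi) and three fast-motoneuron (FETi) preparations for both non-linear
models, the published mean sets, and package defaults for the three linear
models. One data-curation note: the printed table these values were
transcribed from typesets large cascade coefficients with dot thousands
separators (e.g. "34.666" for 34666) while other columns are true decimals.
The package adopts the thousands-separator reading for the cascade
coefficients because it is the only one under which every row is
over-critically damped in its calcium stage with twitch times-to-peak of
40–70 ms and twitch/tetanus ratios below ~13 — the documented behaviour of
this muscle — whereas literal readings give multi-second decay constants.
The literal reading of the ambiguous mean row is kept as
`zakotnik2006_mean_seti_printed`, flagged `ambiguous`.

The linear models have no published parameter sets in this transcription, so
the package provides defaults chosen to reproduce the documented *behaviour*
of those models on this muscle: relaxation dominated by a single slow mode
(deactivation 150–300 ms, in the range of slow extensor relaxation),
essentially linear peak-force summation over 5–50 Hz, and
frequency-independent decay time. They are defaults of this
package, not published values, and are labelled as such in the fixture table.

## Fitting workflows

Measured (and synthetic) traces are normalised to the per-animal maximum.
The cascade model has no free output gain — its DC gain is tied to
$\theta_2\theta_4$, which also set the pole positions — so fitting
pole-scale coefficients to amplitude-normalised data requires an explicit
amplitude scale. The staged workflow therefore profiles out a multiplicative
scale analytically (a linear least-squares projection) during the
single-twitch fit and freezes it afterwards, so the per-frequency stage
attributes force changes to potentiation rather than amplitude drift. The
Wilson model needs no such scale: its gain $A$ absorbs normalisation.

The staged Hatze-Zakotnik workflow (`fit_hatze_staged()`):

1. `fit_hatze_single_twitch()` — $\theta_1\ldots\theta_4$ against the single
   twitch only ($c \equiv 1$ there), from 10 random restarts drawn
   log-uniformly inside physiological brackets around the shipped per-animal
   ranges. The two quadratic factors of the cascade commute, so the fit is
   canonicalised with the potentiation-carrying stage as the slower factor,
   and recovery is judged on the reconstructed response, not the raw
   coefficient vector.
2. `fit_theta4_per_frequency()` — with $\theta_1\ldots\theta_3$ and the scale
   frozen, $\theta_4$ is re-optimised per stimulation frequency
   (one-dimensional golden-section search); $c(f) =
   \theta_4(f)/\theta_4(\mathrm{twitch})$, with $c(1) = 1$ by construction.
   Because $\theta_4(\mathrm{twitch})$ lies inside the search interval, the
   refit can never be worse than keeping $\theta_4$ fixed — the nested-model
   direction the suite asserts.
3. `fit_potentiation_curve()` — weighted least squares of the
   Michaelis-Menten-type form over $t = 1/f$, weights proportional to $f$
   (improving the fit at short intervals), parameterised as
   $K_2 = e^{p_2}$, $K_1 = K_2 + e^{p_1}$ so $K_1 \ge K_2 \ge 0$ holds by
   construction.

`fit_wilson_nl()` optimises all six parameters simultaneously against the
concatenated residuals of every trace, from 7 random restarts (the original
workflow's count; configurable), drawn log-uniformly within bounds for the
positive parameters and uniformly for $\tau_2$. `fit_van_zandwijk()` fits
$(A, \gamma_0)$ on top of frozen twitch coefficients and attaches a note when
the fitted midpoint falls outside the calcium range the simulations visit.
`fit_theta3_theta4_joint()` optionally frees $\theta_3$ per frequency as a
nested extension.

Two optimisation algorithms are available behind every workflow:
box-constrained Levenberg-Marquardt and a bounded trust-region quasi-Newton
(the PORT routines); with `algorithm = "both"` each restart runs both and the
lower-error solution wins, mirroring how the original analyses selected
between their two optimisers. Restart seeds derive deterministically from a
master seed, the winning restart and algorithm are recorded in the
`fit_result`, and restarts that tie in error but disagree materially in
parameters raise an `under_determined` flag. Bounds are a documented choice
of this package (the original "constrained" fits did not state theirs);
they bracket the shipped per-animal ranges while excluding unstable regimes.

## Synthetic data

`generate_dataset()` emulates the structure of a per-animal recording
session: one constant-frequency trace per protocol frequency
(SETi: 1, 7, 10, 12.5, 15, 20, 25, 30, 40, 50 Hz; FETi: 1, 10, 20, 30,
50 Hz), 5 kHz sampling, per-animal normalisation to [0, 1], and optional
i.i.d. Gaussian noise scaled to the session maximum. The default protocol
uses 1 s stimulation plus 1 s relaxation per frequency — enough to reach
tetanic plateau and capture the decay while keeping a full closed-loop fit
in seconds; 10 s epochs are available by configuration. The generator is
first-class, tested code: datasets are reproducible bit-for-bit from
(model, parameters, protocol, noise, seed) and round-trip losslessly through
a plain-text directory layout that the reader also accepts for exported real
recordings.

What the generator does *not* emulate — correlated transducer noise, slow
drift, ripple from unfused real twitches beyond what the models produce,
inter-trial variability, or the weak post-twitch contractions of unknown
origin seen under fast-motoneuron stimulation. Passing closed-loop tests
therefore demonstrates correctness of the implementation and identifiability
of the workflows, not that any model is right for a particular real muscle.

## Metrics and conventions

`half_rise_time()` measures from stimulus onset (first spike plus delay, so
the delay setting cancels out of comparisons) to the first linearly
interpolated crossing of half the post-onset peak; `half_decay_time()` from
the post-stimulus peak (the force at which relaxation actually starts) to the
first crossing of half that value. First crossings win when there are
several; traces that never cross return `NA` with a warning rather than
failing silently. Both estimators recover $\tau\ln 2$ on synthetic
exponentials to within one sample across $\tau \in [0.01, 1]$ s.
`frequency_response()` assembles peak force and both times per frequency —
the numeric backbone of the model-comparison figures — with optional
normalisation to the highest-frequency peak. One observed consequence of the
published mean cascade constants is worth recording: the 50 Hz
tetanus-to-twitch peak ratio computes to 10.002 (the test suite measures
it), a hair above the nominal "below ten" expectation for this parameter
set — within the transcription uncertainty of the printed digits.

## Known limitations

* Force is in model units (the calcium state, the filter state, …); absolute
  calibration is deliberately absorbed into normalisation or fitted gains.
* The potentiation factor is defined per preceding interval; alternative
  windowed rate estimates for irregular trains are not implemented.
* No population-level (multi-animal) fitting; each dataset is fitted alone.
* The three linear models are simulation-only; no fitting workflows are
  provided for them.
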