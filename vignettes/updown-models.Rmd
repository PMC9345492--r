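---
title: "Neuron-astrocyte models of Up-Down state switching: methods and design"
author: "astroud"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuron-astrocyte models of Up-Down state switching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astroud)
```

## The scientific problem

Cortical networks spontaneously alternate between epochs of high collective
firing (Up states) and near-silence (Down states).  Classical models
generate this rhythm from an activity-dependent negative feedback intrinsic
to the neurons — here a slow adaptation (after-hyperpolarization, AHP)
current on the excitatory cells — combined with fluctuating external
drive.  Recent experiments implicate astrocytes: raising astrocytic calcium
activity can push a quiet network into the Up-Down regime.  This package
implements a pair of models of that modulation, in which astrocytes form a
third population that integrates neuronal activity slowly and feeds
gliotransmitter release back onto a fraction of the neurons, together with
the analyses used to characterize them.

## The rate model

Three populations — excitatory (E), inhibitory (I), astrocytes (A) — with
rectified-linear transfer \(\phi_X(x) = g_X\,[x - \theta_X]_+\):

\[
\tau_E \dot r_E = -r_E + \phi_E(I_E - a + \sigma\xi_E), \qquad
\tau_I \dot r_I = -r_I + \phi_I(I_I + \sigma\xi_I), \qquad
\tau_A \dot r_A = -r_A + \phi_A(I_A + \sigma\xi_A),
\]
with recurrent inputs \(I_X = \sum_Y J_{XY} r_Y\), adaptation
\(\tau_a \dot a = -a + \beta r_E\) on the excitatory population only, and
independent Ornstein-Uhlenbeck (OU) drives \(\xi_X\).  The astrocyte
threshold is negative (\(\theta_A = -3.5\)), encoding spontaneous calcium
activity: astrocytes release gliotransmitter even when the neurons are
silent, which is the lever by which they move the network's operating
point.

Design notes:

* **Integration.** Forward Euler-Maruyama at `dt = 0.1` ms (guarded by
  `dt <= min(tau)/4`), with the OU states advanced by their *exact*
  conditional update, so the noise process is unbiased at any step size.
  Noise enters inside the transfer argument, exactly as the model is
  written, not as an additive term on \(\dot r\).
* **OU correlation time.** Only the stationary standard deviation
  (\(\sigma = 3.52\)) is fixed by the reference parameter set; the
  correlation time is not.  The default is `tau_ou = 1` ms; it is an
  explicit argument of `simulate_rate()` and results should be checked for
  sensitivity when it matters.
* **Seeding.** One master seed spawns three sub-seeds (via
  `sample.int(2^31 - 2, 3)`), one per OU stream, so trajectories are
  bit-reproducible.
* **Units.** Rates in Hz, couplings in seconds (so \(J r\) is a
  dimensionless input), all times in ms internally.

### The operating point

The reference parameter table fixes every value except the excitatory
threshold \(\theta_E \in [-10, 20]\) and the adaptation strength
\(\beta \in [0, 10]\) s, which span the phase diagram; the specific pair
used for the reference simulations is only marked graphically in the
source study.  The package default is \(\theta_E = 8\), \(\beta = 5\) s,
chosen once so that the two defining properties of the reference
simulation hold: with the astrocyte couplings zeroed the network is
silent (a Down fixed point, robust against the noise), and with
gliotransmission on (\(J_{EA} = 1\), \(J_{IA} = J_{AI} = J_{AE} = 0.5\) s)
the same point exhibits sustained noise-driven Up-Down switching.  A scan
over \(\beta \in [3, 7]\), \(\theta_E \in [6, 10]\) showed this behaviour
is insensitive to \(\beta\) and requires \(\theta_E \gtrsim 8\).

At this operating point the self-consistent Up state has
\(r_E \approx 2.5\) Hz and \(r_I \approx 5\) Hz.  Note a structural fact:
with \(J_{IE} = 10\) s, \(g_I = 4\) and \(\theta_I = 25\), an Up state
with \(r_E = 10\) Hz would force \(r_I\) near 300 Hz, so mean excitatory
rates of order 10 Hz cannot coexist with inhibitory rates of order 5 Hz
at any fixed point of this model; transient excursions at Up onset exceed
the fixed-point level, but the phase-averaged \(r_E\) stays near 2-3 Hz.

## Fixed points and the (\(\beta, \theta_E\)) phase diagram

The model is piecewise linear, so equilibria are solved exactly:

* **Down**: \(r_E = r_I = 0\),
  \(r_{A0} = -g_A\theta_A/(1 - g_A J_{AA})\) (requires
  \(g_A J_{AA} < 1\)).  It exists iff the E and I transfer arguments stay
  subthreshold there, i.e. \(\theta_E \ge J_{EA} r_{A0}\): gliotransmission
  moves this existence line to larger \(\theta_E\), which is the heart of
  the switching mechanism.
* **Up**: all rectifications active; a \(3\times 3\) linear solve with
  \(a_0 = \beta r_{E0}\), accepted only when self-consistent (all rates
  positive).

Stability comes from the Jacobian of the piecewise-linear flow in the
rectification configuration at the point (boundary cases are resolved
towards the inactive side).  `classify_noiseless()` labels each parameter
point U / D / Bist / Osc by which equilibria exist; the labels are
validated against a brute-force oracle that integrates the noiseless
dynamics from Down-like and Up-like initial conditions on a
\(20 \times 20\) grid.  A point worth noting: in parts of the Osc region a
third equilibrium exists with E active and I silent, but its Jacobian
trace \((g_E J_{EE} - 1)/\tau_E + \dots > 0\) makes it always unstable, so
the four-way classification remains dynamically meaningful.

With noise, `noise_frontiers()` provides deliberately coarse first-order
estimates of where switching appears: the Down state is called robust when
its distance-to-threshold exceeds one noise SD
(\(\theta_E \ge J_{EA}r_{A0} + \sigma\)), the Up state when its margin
\(r_{E0}/g_E\) exceeds \(\sigma\).  Both collapse onto the existence lines
at \(\sigma = 0\) and both *underestimate* the extent of the pure-Down
region relative to simulation — the simulated diagram
(`simulate_phase_diagram()`, fraction of time Up per cell, labels U /
U&harr;D / D at 0.95/0.05) is the ground truth.  Full-resolution diagrams
(50×50, 100 s per cell) are reproducible but long; scaled grids
(e.g. 10×10, 10-20 s) give the same picture and are what the test-suite
exercises.

## The spiking network

Leaky integrate-and-fire neurons (4000 E, 1000 I) and integrate-and-release
astrocytes (2000 A, same formalism on a dimensionless release variable G
with its own leak, threshold and reset), coupled through *population*
synaptic variables: every spike or release event, after a per-event
transmission delay, increments a shared \(u_X\) by
\(\bar\tau_X/\tau_r^X\) (the exact integral of the printed delta impulse),
and \(s_X\) low-pass filters \(u_X\).  Neuronal delays are
\(\le 1.5\) ms; astrocyte delays are uniform in \([500, 1500]\) ms,
reflecting calcium-wave propagation — this three-orders-of-magnitude
separation is what keeps the astrocytic drive a stationary background
rather than a phase-locked signal.  Gliotransmission contacts exactly 10%
of the neurons (uniformly drawn; exact counts, not Bernoulli), and 50% of
the astrocytes receive neuronal input.  Excitatory cells carry an AHP
current incremented by \(\beta/\tau_a\) per own spike and scaled by
\(K_a\) in the voltage equation.

Numerical conventions, chosen once and tested:

* Euler step `dt = 0.1` ms; threshold tested after the update; reset the
  same step; spike time = end-of-step time; no refractory period.
* White-noise input realized as \(\sigma_X\sqrt{dt/\tau_X}\,N(0,1)\) per
  step (the stationary free-membrane SD is \(\sigma_X/\sqrt 2\)).
* Delays drawn per event and rounded to the dt grid; the queue is a
  time-bucketed ring buffer, and event conservation (spikes = matured +
  pending) is asserted in the tests.
* The noise generator is a self-contained xoshiro256++ stream with a
  ziggurat normal sampler whose 256 equal-area layers are constructed
  numerically at start-up; it is seeded from the master seed, keeping runs
  bit-reproducible while integrating the full network ~5x faster than
  with the host RNG.

With the reference parameters the network reproduces the study's
phenomenology: silent without astrocytes at \(\sigma_X = 3\) mV, Up-Down
switching with them (Up phases ~1 s, Down ~0.5 s, ~11-13 Up phases per
20 s), Up states ignited within the astrocyte-contacted excitatory subset,
and an astrocytic synaptic variable whose coefficient of variation is far
below the neuronal one.  Pooled Down-phase durations come out somewhat
longer than reported (~550-670 ms across pools of 10-20 runs, vs 459 ms)
and their coefficient of variation is strongly pool-dependent (0.4 to
1.1: occasional runs dwell in the Down state for seconds, fattening the
right tail); the package reports what the equations as printed produce.

## Mean-field analysis of the spiking network

Stationary rates solve a self-consistency problem built from the classical
diffusion-approximation first-passage rate of a leaky integrator (no
refractory period),

\[
\nu^{-1} = \tau\sqrt{\pi}\int_{y_r}^{y_{th}} e^{u^2}(1+\mathrm{erf}\,u)\,du,
\qquad y = \frac{V - V_L - \mu}{\sigma},
\]

evaluated stably as an integral of \(\mathrm{erfcx}\) (series /
asymptotic split for \(\int e^{u^2}\), asymptotic tail beyond \(y = 8\)).
Candidate rates imply stationary drives \(s_X = \bar\tau_X N_X \nu_X\);
because only 10% of neurons feel \(J_{XA}s_A\) and only 50% of astrocytes
feel the neurons, each population is a two-component mixture, and the
solver works on the six subpopulation rates (damped quasi-Newton with
Broyden updates, multi-start, solutions deduplicated at \(10^{-3}\) Hz and
certified by a residual \(< 10^{-6}\)).  The excitatory input includes the
stationary AHP mean \(-K_a\beta\nu\), solved self-consistently within each
subpopulation.  Stability is read off the finite-difference Jacobian of
the relaxation flow \(\dot r_X = (\nu_X(r) - r_X)/\tau_X\).

`sweep_bifurcation()` continues the fixed points along \(\sigma_X\)
(\(\sigma_A\) held fixed), combining warm starts with a fresh multi-start
at every grid point so branches born at folds are picked up.  Without
astrocytes the diagram is the classical fold pair — one low-rate and one
high-rate stable branch coexisting with an unstable middle branch over a
narrow noise window, here \([4.66, 4.88]\) mV (the study's own analysis
places it at \([4.4, 4.5]\); the structure and narrowness agree, the
location differs by a few tenths of a mV, which is within the spread
expected between variant stationary-map conventions).  With astrocytes the
bistable region widens enormously and extends to much lower
\(\sigma_X\) — in particular it contains the reference value 3 mV, which
is the mean-field account of why adding gliotransmission switches the
quiet network into the Up-Down regime — and the two astrocyte branches lie
much closer together than the neuronal ones, matching the observation that
release activity hardly varies between Up and Down phases.  One point of
divergence: under this package's map the silent branch is destabilized by
the glio-depolarized excitatory subset already at \(\sigma_X \approx 4\)
mV, so the with-astro window does not extend beyond the without-astro one
on the high side.

## Up/Down segmentation

From a raster: mean population rate per neuron over a sliding 10-ms
window (E and I spikes only), sampled every 1 ms; then a running median
over \(\pm 50\) points; then threshold crossing at 1.0 Hz (values at or
above the threshold are Up — the tie goes to Up).  The first and last
phases touch the simulation boundaries and are flagged out of the
statistics.  Choices worth stating: the 1-ms sampling step is not fixed by
the source description (only the \(\pm 50\)-point window is), so
\(\pm 50\) points means \(\pm 50\) ms here and the step is configurable
and recorded in outputs; the median window is truncated at the series
edges rather than padded, so no data are fabricated; standard deviations
use the population convention (divisor \(n\)).  The same pipeline applies
to rate-model trajectories with \(r_E\) as the series.  Segmentation is
validated against constructed square waves (100 randomized
period/duty/amplitude configurations, recovered within one sampling step)
and obeys exact tiling, strict alternation and threshold monotonicity.

## What the synthetic fixtures do and do not show

The fixture generator produces square-wave rate traces (known phase
boundaries), homogeneous Poisson rasters (known rate) and single-event
rasters.  They pin down the segmentation pipeline's correctness — window
normalization, median boundary handling, crossing semantics, duration
bookkeeping — under exactly known truth.  They do not emulate the
correlated, bimodal, finite-size structure of real network activity;
claims about the models themselves rest on the simulators and the
analytic/mean-field cross-checks, not on the fixtures.

## Problem sizes used by the shipped checks

The test-suite runs the spiking reference condition at 20 independent
20-s simulations (the study pooled 200), the mean-field sweeps at 0.05 mV
(tests) and 0.01 mV (acceptance script) resolution, the rate model at
100 s for level estimates, and the classification oracle on a 20x20 grid.
These sizes reproduce the reported statistics at the documented
tolerances; enlarging them narrows the confidence intervals but does not
change any conclusion we have observed.

## Known limitations

* No spatial structure, no per-synapse state, no sparse neuron-neuron
  connectivity: population synapse variables are a deliberate modelling
  choice inherited from the model family.
* The OU correlation time of the rate model's drive is not constrained by
  the reference table; conclusions that depend on the noise spectrum
  should be checked against `tau_ou`.
* The mean-field stationary map treats the synaptic drives as
  fluctuation-free (exact only for infinitely many cells); finite-size
  effects shift the simulated transition region relative to the
  mean-field folds.
* The rate model's transfer is non-smooth; stability at rectification
  boundaries is classified by one-sided Jacobians.
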