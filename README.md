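# astroud

Neuron–astrocyte network models of cortical Up-Down state switching.

Cortical circuits spontaneously alternate between epochs of intense
collective firing (Up states) and near-silence (Down states), and recent
experiments show astrocytes can gate the emergence of this regime.
`astroud` implements two complementary models of a three-population
circuit — excitatory neurons (E), inhibitory neurons (I) and astrocytes
(A) coupled by synapses and gliotransmission — together with the analyses
needed to understand them:

* **Rate model** (`simulate_rate()`): rectified-linear populations
  `tau_X dr_X/dt = -r_X + g_X [I_X (- a) + sigma xi_X - theta_X]_+`, slow
  adaptation `tau_a da/dt = -a + beta r_E` on the excitatory population,
  Ornstein–Uhlenbeck external drive, and a *negative* astrocyte threshold
  encoding spontaneous calcium activity.
* **Analytic fixed points** of the rate model (`down_fixed_point()`,
  `up_fixed_point()`, `classify_noiseless()`, `noise_frontiers()`,
  `simulate_phase_diagram()`): the Down state with its astrocyte level
  `r_A0 = -g_A theta_A / (1 - g_A J_AA)`, the fully-active Up state, and
  the U / D / Bist / Osc phase diagram in the adaptation-strength ×
  excitatory-threshold plane.
* **Stochastic spiking network** (`simulate_spiking()`): 4000 + 1000
  leaky integrate-and-fire neurons plus 2000 integrate-and-release
  astrocytes, population synaptic variables with per-event transmission
  delays (milliseconds for neurons, seconds for astrocytes), AHP
  adaptation, and gliotransmission restricted to 10% of the neurons.
* **Mean-field analysis** of the spiking network
  (`find_fixed_points()`, `sweep_bifurcation()`): diffusion-approximation
  first-passage rates, self-consistent fixed points with
  contacted/non-contacted subpopulations, stability, and saddle-node
  (fold) sweeps along the external-noise amplitude `sigma_X`.
* **Up/Down segmentation** (`raster_to_rate()`, `median_smooth()`,
  `segment_phases()`, `phase_statistics()`): sliding-window population
  rate, running-median smoothing, 1-Hz threshold crossing, and duration
  statistics with censored first/last phases.

## Worked example

```r
library(astroud)

## gliotransmission switches the network from silent to Up-Down
p <- spiking_params()                   # reference parameter set
sim <- simulate_spiking(p, duration = 20000, seed = 2)   # 20 s
seg <- segment_phases(median_smooth(spiking_rate_series(sim)))
phase_statistics(seg)
#> Up/Down phase duration statistics (retained phases only)
#>   Up  : n=11  mean=1077 ms  sd=705 ms  CV=0.65
#>   Down: n=11  mean=637 ms  sd=251 ms  CV=0.39

## the same network without astrocytes is silent
sim0 <- simulate_spiking(without_astro(p), 20000, seed = 2)
sum(sim0$raster$t_ms > 1000 & sim0$raster$population != "A")
#> [1] 1

## why: mean-field bistability at sigma_X = 3 mV requires astrocytes
find_fixed_points(3, p, with_astro = TRUE)
#>     r_E0     r_I0  r_A0 stable residual
#> 1 0.0207 1.48e-06 0.120   TRUE 1.77e-12
#> 2 1.2316 2.93e-01 0.142  FALSE 7.26e-12
#> 3 2.5682 4.66e+00 0.205   TRUE 6.68e-12
nrow(find_fixed_points(3, p, with_astro = FALSE))
#> [1] 1
```

A 20-s run alternates between ~1-s Up phases and ~0.5-s Down phases; the
mean-field table shows the silent branch (r_E ≈ 0.02 Hz) and active
branch (r_E ≈ 2.6 Hz) coexisting at the reference noise level once
gliotransmission is on — without it there is a single (silent) fixed
point, which is the mechanistic account of the switch.

The rate-model counterpart, and the analytic phase diagram behind it:

```r
tr <- simulate_rate(rate_params(), duration = 20000, seed = 2)
phase_statistics(segment_trajectory(tr))
#> Up/Down phase duration statistics (retained phases only)
#>   Up  : n=25  mean=238 ms  sd=93 ms  CV=0.39
#>   Down: n=24  mean=565 ms  sd=255 ms  CV=0.45
down_fixed_point(rate_params())$r_A0    # astrocytes fire during Down
#> [1] 3.888889
```

A command-line interface over the same functions ships at
`inst/cli/updown.R` (subcommands `simulate-rate`, `simulate-spiking`,
`segment`, `phase-diagram`, `bifurcation`, `fixtures`).

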