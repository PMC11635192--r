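---
title: "Parameterizing passive compartment chains with a genetic algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parameterizing passive compartment chains with a genetic algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evochain)
```

## The problem

Multi-compartment neuron models replicate the spatial structure of real
neurons — most importantly dendrites — by chaining isopotential RC
compartments.  A classic functional observation on such structures is the
attenuation of an excitatory postsynaptic potential (EPSP) as it spreads
passively away from its input site: peak amplitudes fall off approximately
exponentially with distance, with a characteristic length constant.  Tuning
a substrate (an analog neuromorphic circuit, or any simulator with opaque
low-level knobs) so that it reproduces a *target* attenuation profile is a
parameter-search problem: the knobs — here, integer DAC codes controlling a
leak conductance and an inter-compartment conductance through bias currents
— influence the observables nonlinearly and are not directly derivable from
the observation.

`evochain` packages the whole experimental loop in software: a *virtual
analog substrate* (a noisy, quantized, DAC-controlled passive compartment
chain), the measurement protocol (spike-triggered averaging, amplitude
extraction, exponential fits), a grid search for validating solutions, and
a customized genetic algorithm (GA) that searches the DAC space.  The design
mirrors how the same experiment is run on accelerated analog neuromorphic
systems such as BrainScaleS-2, without requiring any hardware.

## The substrate model

The chain discretizes the passive cable equation with a second-order central
difference in space.  Compartment $i$ obeys

$$C_{m,i}\,\frac{dU_{m,i}}{dt} \;=\; -\,g_{l,i}\,\bigl(U_{m,i}-E_{l,i}\bigr)
\;+\; \sum_{j}\, g_{ic,i\leftrightarrow j}\,\bigl(U_{m,j}-U_{m,i}\bigr)
\;+\; I^{\mathrm{ext}}_i ,$$

with the sum over chain neighbours.  A synaptic event at time $t_0$ injects
a current-based kernel $I(t) = A_{\mathrm{syn}}\,e^{-(t-t_0)/\tau_{\mathrm{syn}}}$.
The model is deliberately linear (no threshold/reset, no adaptation): the
attenuation experiment is sub-threshold, and linearity buys an exact
analytic steady-state oracle (`steady_state()`, a tridiagonal solve) against
which the integrator is validated.

Three "analog" imperfections are emulated at the recording stage:

* **Quantization** — voltages are clipped to the ADC span and rounded to
  $2^{10}$ codes; all amplitudes are reported in *bits* (code differences).
* **Trial-to-trial noise** — Gaussian noise of SD `noise_sigma` is added to
  every recorded sample, independently per trial.  By default it is iid per
  sample; `noise_filter_tau` optionally low-pass filters it (AR(1)) to
  emulate membrane-filtered noise (see *Noise and the averaging law* below).
* **Fixed-pattern mismatch** — optional static per-circuit lognormal factors
  on all conductances (`mismatch_sigma`, default off), distinct from
  temporal noise: it models fabrication variability, frozen per substrate
  instantiation.

Both conductances are set through 10-bit DACs with the shared integer code
range $[0, 1022]$ and a strictly increasing affine code-to-conductance
transfer.  Real bias-current DACs are monotone but not exactly affine; the
affine choice is the simplest monotone map and nothing downstream depends on
its curvature.

### Integration

The full state (voltages, synaptic currents, and a constant-input
coordinate) is linear, so one fixed-step propagator $e^{M\,\Delta t}$ is
computed once per run (`Matrix::expm`) and applied per sample in compiled
code.  This exponential integrator is exact for the model up to two
discretization effects: event times are snapped to the sampling grid, and
peaks are only observed at sample times.  `dt` therefore controls *sampling
resolution*, not stability; the configuration validator still rejects a `dt`
coarser than half the fastest time constant, because an under-sampled peak
biases the amplitude estimate.

### Calibrated default constants

The defaults place the substrate in the operating regime the protocol is
designed for, and are documented constants, chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_compartments` | 5 | chain length of the attenuation experiment |
| `c_m`, `e_l` | 1, 0 | defines the model's capacitance/voltage scale |
| `g_l_range` | (0.5, 2.0) | membrane time constants 0.5–2 at `c_m` = 1 |
| `g_ic_range` | (0.2, 4.2) | mid-code genes (511, 511) give $\lambda_{\mathrm{emp}} \approx 1.06$ compartments |
| `syn_amplitude` | 1.9 | mid-code first-compartment EPSP $\approx$ 146 bits |
| `tau_syn` | 0.5 | synaptic decay of the same order as the membrane time constant, as on accelerated analog substrates |
| `dt` | 0.01 | $\geq$ 10 samples per fastest time constant |
| `adc_range`, `adc_bits` | (−0.2, 1.8), 10 | rest near the lower span, head-room for EPSPs; 1 bit $\approx$ 2 mV-equivalent |
| `noise_sigma` | 0.008 | STA-mode trial-to-trial SDs of $\approx 0.02$ (length constant) and $\approx 0.8$ bits ($h^0$), the regime where averaging pushes the spread below the ADC resolution |

Two constraints shaped the conductance ranges beyond the mid-code operating
point.  First, the whole DAC square must stay in the regime where the
qualitative laws of the experiment hold: larger leak $\Rightarrow$ shorter
length constant, larger coupling $\Rightarrow$ longer length constant, and
either $\Rightarrow$ smaller first-compartment amplitude.  With a leak
conductance far below ~0.4 the chain becomes effectively
charge-conserving on the EPSP timescale; late-time equalization is absorbed
by the offset term of the exponential fit and the fitted length constant
*saturates*, genuinely breaking monotonicity of the maps.  Hardware
bias-current ranges are bounded away from zero for analogous reasons.
Second, mid-code genes should sit well inside the square so both the grid
search and the GA have room on all sides.

## The measurement protocol

One experiment run (`run_attenuation_experiment()`):

1. realize the chain from the genome (2 genes broadcast across the chain, or
   $2n-1$ genes for per-compartment control);
2. inject `n_spikes` (default 10) input spikes into compartment 0, spaced by
   10 slowest time constants so the membrane returns to rest between events
   (residual deflection $< e^{-10}$);
3. record all compartments in one run; cut a window around every spike,
   subtract each window's pre-spike baseline mean, and average: the
   spike-triggered average (STA);
4. take the per-compartment maximum over the post-spike window — the EPSP
   amplitudes $h$ in bits;
5. fit $U_{\max}(x) = a\,e^{-x/\lambda_{\mathrm{emp}}} + c$ over the five
   compartment indices $x = 0\ldots4$ by Levenberg–Marquardt with
   $\lambda > 0$ (offset included because distant compartments sit on the
   quantization floor).

Defaults for the windows: baseline 20 % of the inter-spike interval (ending
one sample before the spike), response window 60 %.  Flat amplitude profiles
(possible at extreme DAC corners) make $\lambda$ unidentifiable; the fit
then raises a typed degenerate-fit condition, which the grid search records
as a failed cell and the GA maps to a worst-case sentinel fitness of $10^6$
so that selection stays total.

### Noise and the averaging law

Because noise enters at the recording stage, averaging $N$ spike windows
reduces the residual noise SD of the *traces* by exactly $1/\sqrt{N}$.  The
amplitude estimator, however, is a **maximum** over the post-spike window,
and the SD of the max of signal-plus-noise grows sublinearly with the noise
scale (extreme-value statistics over the near-peak samples).  With iid
per-sample noise, the measured single-shot/STA SD ratio of $h^0$ is
therefore slightly *below* $\sqrt{10} \approx 3.16$ — about 2.9–3.0 at the
defaults — while the length-constant ratio, which pools five amplitudes
through the fit, sits at $\approx 3$.  With temporally correlated
(membrane-filtered) noise, `noise_filter_tau` $\gtrsim$ the peak width, the
near-peak samples share one noise value, the compression disappears and the
ratio moves to $\sqrt{10}$; this matches the intuition that an analog
substrate's noise is low-pass filtered by the membrane.  The estimator also
acquires a positive bias from the same mechanism — single-shot amplitudes
read a few bits high relative to the STA — which is why averaging, not just
the experimenter's patience, is part of the protocol.

## The genetic algorithm

Genomes are integer DAC vectors (2 or 9 genes).  The loop
(`evolve()`) is a standard generational GA with elitism:

1. evaluate every unevaluated individual on the substrate;
2. copy the `n_elites` fittest unchanged into the next generation;
3. fill the remaining slots by tournament selection (best of `k` uniform
   draws, elites included; without replacement within a tournament);
4. recombine consecutive selected pairs with probability `p_cx` by
   one-point crossover (offspring 1 takes parent 2's leading segment — the
   orientation is fixed and test-locked);
5. mutate each individual with probability `p_mut`, each gene with
   probability `p_gen`, by adding or subtracting $2^x$, $x$ uniform on
   $0\ldots9$, rejection-resampled (both $x$ and sign) until in bounds;
6. stop after a hard limit of `n_generations` generations.

Defaults: 50 individuals, 5 elites, 30 generations, `p_cx` 0.5, `p_mut`
0.1, `p_gen` 0.5, `k` 3.  Note one boundary subtlety of the mutation
operator: no gene admits both $+512$ and $-512$ inside $[0,1022]$, so from
the mid-range code 511 the largest step is unreachable and the nine feasible
magnitudes are equally likely; this is a direct consequence of the stated
operator, not a tuning choice.

Three fitness functions (all minimized) cover the three search problems:

* $f = \lvert \lambda_{\mathrm{emp}} - \hat\lambda_{\mathrm{emp}} \rvert$ —
  single objective;
* $f_2 = \bigl((\hat\lambda-\lambda)/\hat\lambda\bigr)^2 +
  \bigl((\hat h^0-h^0)/\hat h^0\bigr)^2$ — a scalarized two-objective
  fitness that pins both the length constant and the amplitude, collapsing
  the iso-$\lambda$ valley of $f$ to a point;
* $f_3 = \sum_{i,j} (\hat h_{i,j} - h_{i,j})^2$ — the 9-gene problem scores
  the full multi-site amplitude matrix ($h_{i,j}$: response in compartment
  $i$ to an input at compartment $j$, measured site after site).

**Elites and noisy evaluation.**  With a deterministic evaluator, elitism
guarantees a non-increasing best fitness.  On a noisy substrate the
*recorded* best fitness can still fluctuate if elites are re-measured each
generation; whether a lab re-measures elites is a protocol choice, so it is
exposed as `reevaluate_elites` (default off: elites keep their cached
score).  Either way each *new* evaluation uses a fresh noise seed — an
individual's fitness is one noisy measurement, exactly as on hardware, and
the GA is expected to cope with (and mildly exploit) that noise: selected
solutions are biased toward lucky measurements, which is why recovered
solutions are validated with an independent re-measurement.

**Reproducibility.**  All randomness derives from one master seed through
named streams (`derive_seed(master, stream)`: a documented polynomial hash
plus Lehmer mixing, 31-bit): `"ga"` for the loop, `"mismatch"` for
fixed-pattern factors, `"noise"` per recording, `"eval<i>"` per evaluation.
Two runs with equal configuration are identical; the CLI writes every
derived seed into the run manifest.

## Grid search and landscapes

`grid_sweep()` runs the full protocol at every point of a DAC grid
(default 32×32; tests and the worked examples use 5×5), each cell with a
fresh noise seed, exactly as independent hardware runs would be.
`fitness_landscape()` turns the two maps into an $f_2$ surface for
validating GA solutions; `iso_lambda_contour()` traces the locus of a target
length constant (marching squares with linear edge interpolation — the
locus of valid single-objective solutions).

## Problem sizes used in the shipped checks

The package's tests and the results script run: trial-to-trial statistics
with 1000 repeats per recording mode; 10 GA runs of 30 generations for the
two fitness functions on the 2-gene problem (population 50); 3 GA runs of 12
generations on the 9-gene problem; 5×5 noiseless grids; 20 random chains for
the steady-state oracle; $10^5$ mutation draws.  These sizes give Monte-Carlo
standard errors comfortably below the asserted effects while keeping a full
run on a laptop in the minutes range.

## What the synthetic substrate does and does not show

The generator emulates: passive multi-compartment dynamics, monotone
DAC-to-conductance control, 10-bit recording quantization, per-sample
trial-to-trial noise (optionally membrane-filtered), and static fixed-pattern
mismatch.  It does **not** emulate: active/spiking dynamics (AdEx
nonlinearities, thresholds), the true bias-current transfer curves of any
physical chip, crosstalk, temperature drift, or the 1000× accelerated
physical timescale of analog hardware.  Consequently, passing tests show
that the *method* — STA measurement, fits, grid search, and the GA — behaves
as reported under realistic noise, quantization and parameter ranges; they
do not certify parameter values for any specific physical substrate, whose
absolute operating point (e.g. a length constant of exactly 1.07
compartments at mid-range codes, or 147-bit amplitudes) is chip-specific.

## Numerical choices and edge cases

* Exponential fit initialization: $a = h_0 - h_{n-1}$, $\lambda = 1$,
  $c = h_{n-1}$; tight LM tolerances (`ftol = ptol = 1e-14`) so exact model
  data is recovered to $10^{-6}$.
* Ties in elite selection break by stable population order; tournament ties
  by draw order.
* Degenerate inputs raise typed conditions (`evochain_config_error`,
  `evochain_degenerate_fit`, …) rather than generic errors, so callers can
  map them to sentinels.
* Constant-current inputs are carried in the propagator's homogeneous
  coordinate; zero-leak chains (useful as a charge-conservation diagnostic)
  are accepted by `chain_model()` even though they have no unique rest
  state.
* The trial-to-trial driver reuses the noiseless dynamics of a fixed chain
  and stimulus across repeats and redraws only the recording noise — exact,
  because noise enters after integration — which makes 1000-repeat
  histograms cheap.

## Known limitations

* The affine DAC transfer is a stand-in for unspecified hardware bias
  curves; only monotonicity is relied upon.
* Exact monotonicity of noiseless grid maps holds on coarse grids; on fine
  grids (≥ 9 points per axis) quantization-induced jitter of order
  $10^{-2}$ in $\lambda_{\mathrm{emp}}$ can locally perturb the ordering.
* The single-shot amplitude estimator's extreme-value bias and SD
  compression (see above) are properties of the max estimator under iid
  noise; analyses that need the exact $1/\sqrt{N}$ law should enable
  filtered noise or compare trace-level residuals.
* The GA is single-population and sequential; parallel evaluation across
  circuits (natural on real hardware) is out of scope.
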