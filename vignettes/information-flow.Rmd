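---
title: "Information flow through a model klinotaxis circuit"
author: "klinfo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information flow through a model klinotaxis circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(klinfo)
```

## The model

Salt klinotaxis in *C. elegans* is gradual steering toward an attractant:
during sinusoidal crawling the worm modulates the amplitude of its head
swings according to the concentration changes it senses, producing a net
turning bias up the gradient.  `klinfo` implements a minimal model of the
circuit believed to underlie this behavior and asks a single question of
it: how does information about concentration changes flow from the
environment, through the sensory, inter- and motor neurons, into movement?

The circuit has four cell classes wired feedforward with two lateral
(gap-junction) shortcuts:

* **ASE** chemosensors, idealized as ON/OFF cells.  A windowed derivative
  of the recent concentration history,
  `d(t) = mean(newest N samples) - mean(previous M samples)`, drives an ON
  cell (`V_ON = d` when `d > 0`, else 0) and an OFF cell (`V_OFF = -d`
  when `d <= 0`, else 0).  Exactly one of the two is active at any
  instant.
* **AIY** interneurons (left/right), passive isopotential nodes
  `tau dV/dt = -V + w_ON V_ON + w_OFF V_OFF + g_AIY (V_contra - V)`.
  Both AIY cells receive both sensors; the pair is electrically coupled.
* **AIZ** interneurons, each driven by its ipsilateral AIY through a
  chemical synapse `w sigma(V_AIY + theta_AIY)` with
  `sigma(x) = 1 / (1 + exp(-x))`, plus an AIZ-AIZ gap junction.
* **SMB** neck motor neurons (dorsal/ventral x left/right), driven by the
  ipsilateral AIZ, a self-connection (standing in for the voltage
  dependence of inward currents), and an oscillatory pattern-generator
  input `w_PG sin(2 pi t / T)` with period `T = 4.2` s delivered in
  antiphase to ventral (`+sin`) and dorsal (`-sin`) cells.
* The **neck** differences the motor outputs,
  `phi = w_NMJ [(sigma_SMBDL + sigma_SMBDR) - (sigma_SMBVL + sigma_SMBVR)]`,
  and the body is a point moving at constant speed `v = 0.022` cm/s with
  heading `mu` integrating `phi`.

Model parameters are dorsal/ventral symmetric (dorsal and ventral motor
cells share biases and weights) but free to differ left/right — the
asymmetries analysed below are therefore emergent, not imposed.

### Numerical choices

The dynamics are integrated with explicit Euler at `dt = 0.01` s
(`T/420`), the conventional choice for this family of leaky-integrator
circuit models; a convergence test in the suite checks first-order
behavior under `dt` halving, and `dt` is exposed everywhere.  The sensory
history buffer is pre-filled with the initial concentration, so `d = 0` at
`t = 0` and no artificial onset transient occurs.  Simulations start from
`V = 0`, heading 0, pattern-generator phase 0 unless an assay requests an
onset phase.  Left/right cell equations mirror each other exactly; the
gap-junction coupling terms are antisymmetric by construction.  A
blocked gap junction (lesion) zeroes its coupling term and nothing else.

## Synthetic circuits: what the generator emulates

The electrophysiological parameters of the real circuit are unknown; the
package therefore *evolves* them.  `evolve_ensemble()` runs independent
genetic-algorithm searches: real-valued genotypes in [-1, 1] decode
linearly to weights and biases in [-15, 15], gap conductances in
(0.01, 2.5], `tau` in [0.1, 2] s, the neuromuscular weight in [-2, 2], and
integer sensory windows `N, M` in [1, 210] steps (up to half a locomotion
cycle, matching the seconds-long sensory persistence the model family
shows).  Selection is tournament (size 3) with two elites; offspring are
mutated per-gene with probability 0.3 by Gaussian noise of sd 0.5 —
sparse, large mutations explore this landscape better than dense small
ones.  Uniform crossover is available but off by default, where it was
found to disrupt co-adapted weight/bias pairs.

Fitness is the chemotaxis index of embodied closed-loop runs: worms start
2 cm from the peak of a conical gradient (peak concentration 2, length
scale 4.4 cm, i.e. a constant slope of about 0.45 per cm so that perceived
concentration changes stay within about ±0.01 per second), run for 300 s,
and score `1 - mean(distance to peak) / initial distance`, averaged over
three random start poses fixed per run.  A circuit is *successful* when
its index reaches 0.75; a perfect straight-to-peak run from this distance
scores about 0.85, so 0.75 demands genuine gradient climbing.  Each run
uses `pop_size = 60` for `generations = 200` — a desk-scale search that
typically yields successful circuits in a few minutes per seed.

What the generator does **not** emulate: sensory or synaptic noise, body
mechanics and undulation dynamics (the body is a point), pirouettes or
klinokinesis, and any attempt to reproduce the particular evolved
parameter values of prior work.  Passing tests therefore speak to the
information-flow methodology on this model family, not to quantitative
agreement with biological recordings.

The packaged fixture (`load_fixture("best")`) is a frozen product of this
search, committed as plain text for deterministic tests; it was chosen as
the highest-fitness circuit that also displays the ensemble-typical
architecture (see below), the same role the "best circuit" plays in the
analyses this package reconstructs.

## Open-loop assays

Information measures need a stimulus ensemble.  Two open-loop protocols
deliver it, both after the circuit settles onto its unstimulated attractor
(12 locomotion cycles of warm-up):

* `concentration_step_assay()`: an instantaneous jump of size `dc` at a
  configurable pattern-generator phase (default phase 0, phase-locked);
  recorded for two cycles.
* `information_clamp_assay()`: the concentration ramps at a constant rate
  `cdot` so the sensors hold a constant output
  (`d = cdot * dt * (N + M) / 2` in closed form); the sensory transient
  (`N + M` steps) is excluded and one cycle is recorded.  This assay
  isolates the role of the oscillatory drive in gating information through
  the motor neurons.

Stimuli are drawn uniformly from ±0.01 (the range a competent model worm
experiences, and the protocol used experimentally on the chemosensors), or
from the model's own empirical distribution of perceived changes
(`empirical_cdot_distribution()`).  2200 presentations is the full
analysis scale; 220 is a fast mode used widely in the test suite.  The
baseline concentration is arbitrary (the sensor stage is
translation-invariant, which a test asserts) and defaults to 1.

## Information measures and the ASH estimator

All measures are in bits and normalized by the stimulus entropy `H(S)`, so
0 means the stimulus is indistinguishable and 1 means uniquely
determined.  At every recorded time step the trial ensemble defines a
joint distribution `p_t(s, r)` over stimulus and response, estimated on a
fixed grid of 50 stimulus bins x 50 response bins by *average shifted
histograms*: each dimension is binned on 12 grids whose origin shifts left
by `k/12` of one bin width, and the histograms are averaged (equivalently,
each point spreads over two adjacent bins with deterministic weights — a
test checks exact agreement with the brute-force average of shifted
histograms).  From `p_t` the package computes

* mutual information `I(S; R_t)` (`time_resolved(..., "mi")`),
* specific information `I(S = s; R_t)`, the expected reduction in
  surprise about one particular stimulus value — it averages back to the
  mutual information under `p(s)`, an identity the suite verifies to
  1e-9,
* transfer entropy `T(Y -> X) = I(X_t; Y_{t-1} | X_{t-1})`, lag-1 and
  order-1 exactly, appropriate for a deterministic system.

Joint responses (a left-right pair, or the four SMB cells) are binned
jointly with the per-dimension resolution reduced to keep the total cell
count near 50^2 (50 bins/dim for pairs, 7 for quadruples); transfer
entropy uses 20 bins per dimension of its triple for the same reason.
These defaults are exposed everywhere, and a robustness test checks that
the qualitative results (profile extrema locations, orderings) are
preserved from 20 to 200 bins.

Two estimator properties deserve emphasis.  First, tiny negative values
(order -1e-16) arise from floating-point cancellation; they are clipped
only in printed reports, never in tests.  Second, the soft two-bin
assignment gives the estimator a resolution ceiling: a noiseless
*continuous* invertible readout of the stimulus estimates to about 0.85
normalized at 50/50 bins rather than 1.0, because each sample's mass is
deliberately spread.  Exact analytic joints (used for the worked values)
do reach 1 exactly.  Comparisons between layers — the quantity of
interest throughout — are unaffected, since all layers share the ceiling.
For worked-value checks against analytic results the stimulus is taken on
an evenly spaced grid over ±0.01 (the variance-free realization of the
uniform ensemble); with random draws the binomial fluctuation of the
negative-stimulus fraction alone contributes about ±0.03 bits of spread at
n = 2200.

## Derived summaries

* `layer_preservation()` treats the circuit as a channel and tracks
  normalized MI of each layer's joint response under the clamp.
* `symmetry_index()` is the package's left/right diagnostic: the ratio of
  the smaller to the larger time-averaged MI of a cell pair (1 =
  informationally symmetric, 0 = fully asymmetric).
* `gating_curves()` reads a `phase_sweep()` and reports per-SMB-cell MI as
  a function of step-onset phase, at a fixed 50 ms delay (the time the
  interneuron information needs to stabilize) and averaged over all
  delays in a cycle.
* `timing_metrics()` finds the four landmark events of the step response
  (stimulus onset, neck onset, sensor offset, neck offset) by
  threshold-crossings of normalized MI.  The threshold is a package
  choice, default 0.05 and configurable; sensitivity at 0.02/0.10 can be
  probed by re-running with those values.  The "end of sensor response"
  is defined by the same threshold convention.
* `build_architecture()` condenses everything into the information
  architecture: per cell the time-averaged normalized MI and the split of
  time-averaged specific information between positive and negative
  stimuli (normalized to sum to one), per connection the time-averaged
  transfer entropy.  Sensor and interneuron entries use the step assay,
  motor and neck entries the clamp assay, whose phase-dependence they
  require.
* `ensemble_report()` aligns circuits by their dominant AIY cell (highest
  cumulative MI; the AIZ cell downstream of it first) before averaging,
  so left/right labels — which are arbitrary up to relabelling, as an
  equivariance test checks — do not wash out the asymmetry structure.

## Design choices where the design was open

* *Pattern-generator phase convention*: one sinusoid with ventral cells
  receiving `+sin(2 pi t / T)` and dorsal cells the antiphase signal; all
  assay phases are referenced to the ventral drive.
* *Step-onset convention*: phase-locked at phase 0 by default, with the
  phase sweep as the explicit tool for phase dependence; a phase-averaged
  protocol is recoverable by averaging sweep recordings.
* *Stimulus binning*: the stimulus feature is binned like the responses
  (50 bins, same shifts); `H(S)` is computed per time step from the
  stimulus marginal of the estimated joint (constant by construction in
  open loop).
* *Bearing re-parameterization*: in closed loop
  `cdot = v |grad C| cos(bearing)`, so 90 degrees maps to `cdot = 0`;
  `orientation_info_map()` folds bearings into [0, 180] by symmetry.
* *Fitness*: prior work's exact selection criterion is not restated in
  the sources this package follows; the chemotaxis index defined above is
  the package's own documented fitness, and 0.75 its success threshold.

## Problem sizes used by the checks

The acceptance analyses run at deliberately chosen desk scales: worked
values use 2200 presentations and 50 bins (under 1 s); the ensemble
architecture check evolves six seeds at the default population and
generation counts and analyses at least ten successful circuits at 220
presentations with strided time grids; lesion and bin-robustness checks
use the fixture circuit at 220-550 presentations.  These sizes were chosen
so the full suite completes comfortably on a laptop-class single core
while leaving the qualitative conclusions stable under doubling.

## Known limitations

* The estimator ceiling (above) makes absolute preservation percentages
  estimator-dependent; only layer comparisons and time structure are
  interpreted.
* The evolved worms weave far less than real ones: nothing in the
  chemotaxis-index fitness rewards large head sweeps, so the closed-loop
  distribution of perceived concentration changes is positively biased
  but concentrates near its extremes (straight approach, then orbiting
  the peak) instead of peaking at zero as large-amplitude weaving would
  produce.
* Ensemble-level claims split into two groups.  Phase-dependent SMB
  gating with the exact dorsal/ventral half-cycle mirror, the neck
  information dip at the pattern-generator zero crossing, and the
  dominance of the chemical route into the best-informed AIY cell are
  majority properties of the synthetic ensemble.  The full
  AIY-asymmetry-to-AIZ-symmetry cascade (one AIY integrating everything,
  the gap junction re-symmetrizing AIZ) appears in a large minority of
  circuits — roughly 40 percent at the scales the checks run — rather
  than a majority: one-sided AIZ solutions steer just as well under this
  package's fitness, so nothing selects for the cascade.  The packaged
  "best" fixture was chosen to exhibit it, and the corresponding
  ensemble checks are expected to fail honestly at desk scale.
* The point-body model collapses neck angle and heading dynamics into one
  angular velocity; neck-angle information should be read as information
  in the motor command, not in a mechanical joint angle.
* The evolutionary generator is a stand-in ensemble: its parameter
  distributions are its own, and ensemble-level statements are majority
  properties of that synthetic ensemble.
* Closed-loop (self-structured) information analysis is out of scope; all
  information measures here are open-loop.

## A worked tour

```{r tour, eval = FALSE}
params <- load_fixture("best")

# behavior
field <- gradient_field("conical")
traj <- run_closed_loop(params, field, duration = 300, seed = 1)
chemotaxis_index(traj, field)
plot(traj)

# assays
step <- concentration_step_assay(params,
                                 stimulus_ensemble("step", 2200, seed = 1))
clamp <- information_clamp_assay(params,
                                 stimulus_ensemble("clamp", 2200, seed = 2))

# information dynamics
plot(time_resolved(step, "mi", "sigma_AIYL"))
plot(time_resolved(step, "specific", "sigma_AIYL"))
layers <- layer_preservation(clamp, time_stride = 5)
sapply(layers, function(p) mean(p$normalized))

# architecture
arch <- build_architecture(step, clamp, time_stride = 5)
arch
```
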