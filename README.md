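# klinfo

Information flow through a model *C. elegans* klinotaxis circuit.

## What this package is for

Salt klinotaxis is the worm's gradual steering toward an attractant:
during sinusoidal crawling it adjusts its head swings according to the
concentration changes it senses.  `klinfo` is for researchers who want to
ask *information-level* questions of the minimal sensorimotor circuit
believed to drive this behavior — where information about concentration
changes is integrated, which pathways (chemical synapses vs gap
junctions) carry it, how the oscillatory locomotion drive gates it, and
how much of it survives all the way into movement.

The package provides, end to end:

1. a deterministic simulator of the circuit (ASE ON/OFF chemosensors fed
   by a windowed concentration derivative, AIY and AIZ interneuron pairs,
   the four SMB neck motor neurons with antiphase pattern-generator
   drive, and a point-body locomotion model; compiled core, exact pure-R
   reference stepper);
2. a genetic algorithm that evolves ensembles of klinotaxis-competent
   parameter sets under a dorsal/ventral symmetry constraint, scored by a
   chemotaxis index in closed-loop gradient climbing;
3. open-loop *concentration step* and *information clamp* assays that
   turn a circuit into trial x time x variable recordings;
4. a time-resolved information-dynamics engine estimating, via average
   shifted histograms (ASH), the measures

   - mutual information `I(S; R_t)`, normalized by the stimulus entropy
     `H(S)`,
   - specific information
     `I(S = s; R_t) = sum_j p(r_j | s) [log 1/p(s) - log 1/p(s | r_j)]`,
   - transfer entropy `T(Y -> X) = I(X_t; Y_{t-1} | X_{t-1})`;

5. reporting tools that condense these into the circuit's *information
   architecture*: per-cell time-averaged information with its
   positive/negative stimulus split, per-connection transfer entropy,
   left/right symmetry indices, SMB gating curves, and response-timing
   metrics, plus ensemble mean/sd summaries.

## Worked example

```r
library(klinfo)

params <- load_fixture("best")     # packaged evolved circuit
field <- gradient_field("conical")

traj <- run_closed_loop(params, field, duration = 300, seed = 1)
chemotaxis_index(traj, field)
#> [1] 0.8316421

step <- concentration_step_assay(params,
          stimulus_ensemble("step", n_trials = 2200, seed = 1))
aiyl <- time_resolved(step, "mi", "sigma_AIYL", time_stride = 5)
aiyr <- time_resolved(step, "mi", "sigma_AIYR", time_stride = 5)
symmetry_index(aiyl, aiyr)          # left/right information asymmetry in AIY
#> [1] 0.1481543
aizl <- time_resolved(step, "mi", "sigma_AIZL", time_stride = 5)
aizr <- time_resolved(step, "mi", "sigma_AIZR", time_stride = 5)
symmetry_index(aizl, aizr)          # ... but symmetry in AIZ
#> [1] 0.928667
```

A symmetry index near 0 means one cell of the pair dominates the
information about concentration changes; near 1 means the pair shares it.
The fixture reproduces the hallmark pattern: strongly asymmetric AIY,
symmetric AIZ — and transfer entropy shows the AIZ symmetry is carried by
the gap junction, not the chemical synapses:

```r
clamp <- information_clamp_assay(params,
           stimulus_ensemble("clamp", n_trials = 2200, seed = 2))
arch <- build_architecture(step, clamp, time_stride = 5)
arch
#> Information architecture
#>   nodes (time-averaged normalized MI, +/- split):
#>     V_ON         mi = 0.075  (+82% / -18%)  [step assay]
#>     V_OFF        mi = 0.079  (+20% / -80%)  [step assay]
#>     sigma_AIYL   mi = 0.119  (+55% / -45%)  [step assay]
#>     sigma_AIYR   mi = 0.018  (+82% / -18%)  [step assay]
#>     ...
#>   edges (time-averaged transfer entropy, bits):
#>     ...
#>     sigma_AIZL   -> sigma_AIZR   0.0403  (gap)
#>     sigma_AIYL   -> sigma_AIZL   0.0325  (chemical)
#>     V_OFF        -> sigma_AIYL   0.0240  (chemical)
#>     ...
#>     sigma_AIYR   -> sigma_AIZR   0.0025  (chemical)

timing_metrics(step, time_stride = 2)
#> Step-response timing (normalized-MI threshold 0.05):
#>   propagation delay (a-b): 0.16 s
#>   sensor information duration (a-c): 1.46 s
#>   persistence after sensor offset (c-d): 0.54 s
#>   neck response duration (b-d): 1.84 s
```

Reading the architecture: the OFF sensor reports decreases (80% negative
split), information about both signs converges on AIYL through the
chemical synapses, crosses to AIZR mainly through the AIZ gap junction
(0.040 bits vs 0.003 through its chemical synapse), and roughly half of
the sensor-level information survives into the neck command.

See the vignette (`vignettes/information-flow.Rmd`) for the model
equations, estimator details, and every tunable parameter.

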