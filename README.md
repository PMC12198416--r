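# readoutbias

Simulation and analysis tools for dissecting **confirmation bias** in
sequential evidence integration into its two possible neural origins:
selective **encoding** (inconsistent evidence is represented less precisely)
versus selective **readout** (inconsistent evidence is encoded faithfully
but under-used for behavior).

The package is aimed at computational/cognitive neuroscientists who combine
psychophysics with population recordings (e.g., source-level MEG) and want
to quantify, per evidence sample `S`, neural response `R`, and estimation
report `E`:

* the **psychophysical kernel** `I(S;E)` — the weight of each sample on the
  continuous report, as bias-corrected mutual information (or regression
  slopes);
* **encoding** `I(S;R)` and **report information** `I(R;E)` in neural
  component activity, time-resolved or window-averaged;
* **intersection information**
  `II(S;R;E) = min[ SI(E;{S,R}), SI(S;{E,R}) ]`, the stimulus information in
  `R` that also informs `E`. Each shared-information term is the maximum of
  the co-information `I_q(S;R) − I_q(S;R|E)` over joint distributions `q`
  preserving the target-linked pairwise marginals, computed by a concave
  constrained maximization (projected gradient ascent on `H_q(E|S,R)` over
  per-slice transportation polytopes, implemented in C++ and verified
  against exhaustive grid search).

All information measures use equipopulated binning (3 bins by default),
shuffle-based limited-sampling correction, matched trial counts between
compared conditions, and a minimum-trial floor. An inference layer provides
sign-flip and cluster-based permutation tests, FDR control, JZS Bayes
factors, spatial spin-rotation nulls on a sphere, and repeated-measures
ANOVA effect sizes.

A full synthetic-data module generates the sequential estimation task
(twelve angular evidence samples per trial around a hidden generative mean,
with an intermittent categorical choice or a 75%-valid cue), simulates
ideal and biased observers, and simulates neural population activity with a
linear encoding/readout model whose three deficit scenarios — encoding
deficit, decoding noise, weight mismatch — produce *identical* behavioral
consistency effects but distinct neural signatures. See the methods
vignette (`vignettes/encoding-vs-readout.Rmd`) for the model, the
event-aligned analysis frame, and all numerical choices.

## Worked example

Generate the task, simulate an observer and a *weight-mismatch* neural
scenario, and ask the pipeline which mechanism produced the behavioral
consistency effect:

```r
library(readoutbias)

trials <- generate_trials(task_config(rng_seed = 1))
trials
#> Trial table: 1856 trials (Choice: 928, Cue: 928)
#>   12 samples/trial, SD 20 deg, truncation +/- 40 deg, grid |mu| <= 14
#>   estimates present: 0, category events: 928

trials <- simulate_observer(trials, observer_config(decision_noise = 0.1),
                            seed = 2)
scen <- calibrate_scenarios(neural_model_config(rng_seed = 3))
sim <- simulate_neural(trials, scen$weight_mismatch, positions = 7:8)

cts <- lapply(c(ISR = "ISR", IRE = "IRE", II = "II"), function(m)
  consistency_contrast(sim$tensor, sim$trials, measure = m, seed = 4))

cts$ISR
#> Consistency contrast, ISR (positions 7,8, n = 528 matched trials):
#>   consistent   0.1138 bits
#>   inconsistent 0.1122 bits
#>   delta        +0.0016 bits
cts$II
#> Consistency contrast, II (positions 7,8, n = 528 matched trials):
#>   consistent   0.1145 bits
#>   inconsistent 0.0342 bits
#>   delta        +0.0803 bits

classify_mechanism(cts$ISR, cts$IRE, cts$II)$mechanism
#> [1] "weight_mismatch"
```

Reading the numbers: on near-zero-mean trials, pooled over the two samples
following the categorical event and at matched trial counts (n = 528 per
consistency split), the stimulus information in the simulated population
activity is the same for consistent and inconsistent samples
(`I(S;R)`: 0.114 vs 0.112 bits — encoding intact), while the part of that
information that reaches the report collapses for inconsistent samples
(`II`: 0.114 vs 0.034 bits). That combination is the readout signature: the
classifier returns `"weight_mismatch"`. An encoding-deficit simulation
instead drops `I(S;R)` itself, and a decoding-noise simulation drops
`I(R;E)`; the three scenarios are calibrated to the same behavioral effect,
so only the neural measures can tell them apart.

`run_pipeline(run_config(...))` chains the stages (simulate, neural,
behavior, decoding, stats) into a reproducible bundle with TSV/JSON
artifacts and a provenance manifest.

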