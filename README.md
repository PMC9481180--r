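# icephys

Feature extraction and unsupervised phenotyping for whole-cell
current-clamp recordings made with square incremental current steps.

The package is written for electrophysiologists characterizing cellular
excitability — in particular for datasets that mix mature, regularly
spiking neurons with immature cells whose depolarizing responses are
small TTX-sensitive "spikelets" rather than full action potentials, as
seen in developing cortex and in ectopic cell masses of cortical
development mutants. Everything the analysis needs is computable from
sweeps of membrane voltage plus the step protocol; a synthetic-membrane
simulator with known ground truth backs every stage, so the whole
pipeline is testable without any recording hardware or downloads.

## What it computes

**Passive properties**, from the average of repeated hyperpolarizing
steps (−10 or −25 pA, 500 ms):

- resting membrane potential: mean pre-step baseline (flagged when the
  cell was held by a bias current);
- input resistance `R_in = ΔV_ss / I`, with `ΔV_ss` the steady-state
  deflection (mean over the last 100 ms of the step relative to the
  50 ms pre-step baseline);
- membrane time constant `τ` by single-exponential fit
  `V(t) = V_ss + (V_0 − V_ss)·exp(−t/τ)` restricted to the 10–90% band
  of the charging transient;
- capacitance `C = τ / R_in` (ms/MΩ = nF, reported in pF).

**Spike and train features**. AP threshold is the voltage at the first
sample where dV/dt (central difference at the native sampling rate)
exceeds 30 V/s; rheobase is the smallest step amplitude eliciting a
spike. From the single AP at rheobase: amplitude (threshold → peak), AHP
amplitude (threshold → trough), halfwidth (full width at half amplitude
above threshold, interpolated), latency (step onset → first peak). From
the train at double rheobase: spike count and the adaptation ratios
`f₂/f₁` and `f_last/f₁`, with `f_k` the reciprocal of the k-th
inter-spike interval.

**Spikelet analysis and TTX blockade**. Spikelet amplitude is peak
voltage minus steady-state voltage during the step. Responses classify
as mature AP, underdeveloped AP (peak > 30 mV and AHP > 15 mV), spikelet
(peak < 10 mV, amplitude 5–25 mV, little or no AHP), or none. Blockade
in a 60-sweep timed series is quantified as
`100·(1 − mean(last 10)/mean(first 10))` and tested across cells with
the exact Wilcoxon signed-rank test.

**Phenotypic clustering**. Cells × features tables (nine features by
default: AHP amplitude, AP halfwidth, AP threshold, input resistance,
capacitance, spike count at double rheobase, first-spike latency, and
the two adaptation ratios) are z-scored; Euclidean distances feed Ward
agglomeration (merge height = √(2·ΔESS), verified against an exhaustive
within-cluster sum-of-squares oracle); the number of clusters is chosen
by mean silhouette; cluster × group composition is tested with the
Barnard unconditional exact test (sup over the nuisance success
probability of the |Z| tail mass).

Exact Mann–Whitney and Wilcoxon signed-rank tests are implemented by
enumeration/count over (mid)ranks, with normal approximations and tie
corrections for large samples.

## Worked example

Six simulated spikelet-producing cells, sodium transient scaled by 0.1
from sweep 31 of 60 (TTX wash-in), analysed end to end:

```r
library(icephys)

proto <- step_protocol(step_amplitudes = 125)      # 125 pA, 500 ms, 40 kHz
p <- membrane_params(spike_mode = "spikelet", leak_conductance = 5,
                     capacitance_true = 100, ttx_factor = 0.1)
cells <- lapply(1:6, function(i)
  simulate_spikelet_series(p, proto, ttx_onset_sweep = 31,
                           seed = 7000 + i,
                           cell_id = sprintf("ttx%02d", i))$sweeps)

rep <- run_ttx_analysis(cells)
round(rep$per_cell$percent_reduction, 1)
#> [1] 89.5 89.5 89.5 89.5 89.6 89.5
rep$test
#> <test_result> wilcoxon_signed_rank ( exact ) statistic = 21 , p = 0.03125
```

Every cell's spikelet amplitude falls by ~90% after blockade onset, and
with all six paired differences positive the exact two-sided signed-rank
p is 2/2⁶ = 0.03125. The first sweep's response sits inside the spikelet
class bounds:

```r
spl <- spikelet_features(cells[[1]]$sweeps[[1]], proto)
classify_response(spl)
#> [1] "spikelet"      # peak -30 mV, amplitude 15 mV, no AHP
```

Passive properties recover simulator ground truth (here R_in = 200 MΩ,
τ = 20 ms, C = 100 pF, with 0.3 mV noise and 20 averaged sweeps):

```r
s <- simulate_passive_sweeps(
  membrane_params(leak_conductance = 5, capacitance_true = 100),
  step_protocol(step_amplitudes = -25), noise_sd = 0.3,
  n_sweeps = 20, seed = 42)$sweeps
passive_properties(s)
#> RMP -70.0 mV, Rin 200.1 MOhm, tau 20.03 ms, C 100.1 pF
```

## Analysis workflow

Numbered drivers under `analysis/` run a complete synthetic study and
write their tables under `results/` (bulk sweep data goes to
`scratch/`): `01_simulate_cohort.R` (corpus of 20 spiking + 10 immature
cells), `02_passive_recovery.R` (estimator validation grid),
`03_extract_features.R` (per-cell feature table and response classes),
`04_ttx_blockade.R` (paired blockade analysis), `05_clustering.R`
(silhouette-guided Ward clustering and composition test),
`06_full_pipeline.R` (the same corpus through the single `run_pipeline()`
entry point, with provenance).

## Scope and formats

Sweeps are read and written in a long-format CSV dialect
(`sweep_id,time_s,voltage_mV,current_pA` plus a JSON protocol sidecar)
and an equivalent HDF5 layout; both round-trip exactly. Vendor formats
(.csf, ABF, NWB), voltage-clamp analysis, synaptic-event detection, and
liquid-junction/bridge corrections are out of scope. See the methods
vignette (`vignettes/phenotyping-methods.Rmd`) for estimator details,
conventions, and limitations.
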