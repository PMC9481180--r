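---
title: "Current-clamp phenotyping: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Current-clamp phenotyping: models, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icephys)
```

# The measurement model

A recording session delivers a family of 500 ms square current steps
from a holding potential (conventionally −70 mV) while membrane voltage
is sampled, typically at 40 kHz. `step_protocol()` carries the step
timing, the ordered per-sweep amplitudes and the sampling rate;
`sweep_set()` bundles one cell's sweeps with an optional series of
access-resistance readings. Recordings whose access resistance changes
by more than 20% relative to the first reading are discarded
(`qc_access_resistance()`); the change is taken in either direction,
since both degrade series-resistance compensation, and relative to the
first reading rather than a running baseline (the simpler convention;
with drifting electrodes it is also the stricter one).

Time is stored per sweep relative to sweep start; the step begins at
`step_onset` (default 0.1 s) and lasts `step_duration` (default 0.5 s).
The CSV dialect (`sweep_id,time_s,voltage_mV,current_pA` + JSON protocol
sidecar) and the HDF5 layout round-trip all numeric content exactly;
units live in the column/attribute names and are never guessed.

# Passive properties

All passive estimates come from the pointwise average of repeated
hyperpolarizing steps (−10 or −25 pA), which suppresses per-sample noise
by $1/\sqrt{n}$:

- **RMP** — mean voltage over the 50 ms preceding step onset, averaged
  across sweeps. When the amplifier held the cell at a set potential the
  value is a *held baseline*, not a zero-current resting potential; the
  estimate carries a flag so downstream tables stay like-for-like. Both
  cases are supported because recording practice varies and the data
  model cannot distinguish them after the fact.
- **Input resistance** — $R_\mathrm{in} = \Delta V_{ss}/I$ with
  $\Delta V_{ss}$ the mean over the last 100 ms of the step minus the
  pre-step baseline. The 100 ms window exceeds $5\tau$ for any plausible
  $\tau \le 50$ ms, so the window is clear of the charging transient.
  Deflections
  below 0.1 mV (configurable) are refused as unmeasurable.
- **Time constant** — nonlinear least squares of
  $V(t) = V_{ss} + (V_0 - V_{ss})e^{-t/\tau}$ on the onset transient,
  restricted to samples whose deflection is between 10% and 90% of the
  steady-state deflection (the standard charging-curve band; the offset
  transient is unused). $V_{ss}$ is **fixed** at the measured
  steady-state mean rather than fitted: on band-truncated data a free
  asymptote trades off against $\tau$ and biases it upward at low
  signal-to-noise (at $R_\mathrm{in}=50$ MΩ, −25 pA gives only a 1.25 mV
  deflection, and the three-parameter fit overestimated $\tau$ by up to
  30%), while the windowed mean pins $V_{ss}$ to a few µV. $\tau$ is
  initialized from the 63.2% crossing time and bounded to (0.1, 500] ms;
  fewer than 5 samples in the band is an error.
- **Capacitance** — the identity $C = \tau/R_\mathrm{in}$ (ms/MΩ = nF,
  ×1000 → pF), asserted to hold exactly on every emitted row.

# Spike detection and features

Threshold is the voltage at the first sample where the slope exceeds
30 V/s. The slope is the central difference at the native sampling rate
with **no additional smoothing**; acquisition chains apply an online
anti-alias filter, so the raw derivative is meaningful. Crossings within
a 2 ms refractory window of the previous accepted event are ignored;
events outside the current step are discarded. Per event, the peak is
the maximum within 5 ms after the crossing and the AHP trough the
minimum between the peak and the next event's threshold (or step end).
The detector agrees sample-for-sample with a brute-force linear scan
(property-tested on random traces).

Rheobase is the smallest depolarizing amplitude with a detected spike;
single-AP features come from the first spike of that sweep. Halfwidth —
a clustering feature with no universally fixed definition — is the full
width at half amplitude above threshold with linear interpolation at
both crossings. Latency is step onset to first peak.

Train features use the sweep at twice rheobase; when the protocol's step
ladder has no sweep at exactly 2× (coarse 25 pA ladders often do not),
the nearest amplitude is used and recorded with a warning — refusing
would discard legitimate protocols. With peak times $t_1..t_n$
($n \ge 3$), the adaptation ratios are $f_2/f_1$ and $f_\mathrm{last}/f_1$
where $f_k$ is the reciprocal of the $k$-th inter-spike interval. The
"first AP instantaneous frequency" is read as $1/(t_2-t_1)$ — the
reading consistent with measuring intervals between spikes; the
alternative $1/\mathrm{latency}$ reading is available as
`train_features(first_freq = "inverse_latency")` for comparison, without
endorsement. Ratios are undefined (NA) below 3 spikes.

# Spikelets, classification, and TTX

Spikelet amplitude is the peak voltage during the step minus the
steady-state voltage (mean over the last 100 ms of the step — a terminal
window rather than the whole step, so a slow charging ramp does not
inflate the estimate). AHP comes from the dV/dt event trough when a
crossing exists, else 0. The rule table, applied in order:

1. **mature AP**: amplitude ≥ 60 mV and peak overshoots 0 mV — this
   bound is a package convention (immature-response studies classify
   only the immature side) and is configurable and flagged;
2. **underdeveloped AP**: peak > 30 mV and AHP > 15 mV;
3. **spikelet**: peak < 10 mV, amplitude in [5, 25] mV, and AHP ≤ 5 mV
   (the operationalization of "little or no afterhyperpolarization";
   no published number exists, so 5 mV is configurable);
4. otherwise **none**.

The classifier is verified against an independent transcription of the
rule table on an exhaustive value grid.

TTX blockade uses a timed series of identical depolarizing steps (one
per second, 60 s). Because wash-in completes within ~30 sweeps, the mean
spikelet amplitude over sweeps 1–10 is compared with the mean over the
last 10; percent reduction is $100(1 - \bar A_\mathrm{last}/\bar
A_\mathrm{first})$, and the across-cell effect is tested with the exact
Wilcoxon signed-rank test on the paired differences.

# Exact tests

`mann_whitney()` and `wilcoxon_signed_rank()` compute exact two-sided
p-values as twice the smaller tail of the permutation distribution,
capped at 1. The distributions are built by shift-algorithm counts over
doubled midranks, so ties are handled exactly (identical samples give
p = 1); exact mode is automatic up to $nm \le 5000$ (rank-sum) and
$n \le 15$ (signed-rank), beyond which normal approximations with tie
and continuity corrections take over. Both match full enumeration and,
where applicable, `wilcox.test(exact = TRUE)`.

`barnard_test()` implements the unconditional exact 2×2 test: outcomes
at fixed group sizes are ordered by the absolute pooled-score statistic
$|Z|$ (two-sided by $|Z|$ ordering rather than tail doubling — the
standard unconditional practice, stated here so results are
reproducible), the tail mass is the binomial-product probability of all
outcomes at least as extreme, and the p-value is the supremum over the
nuisance success probability, located on a 1000-point grid and refined
by local univariate optimization. The result dominates every pointwise
tail probability and matches a dense-grid brute-force oracle to 1e-6.

# Clustering

Features are z-scored per column (sample SD, moments over observed
values; constant columns are dropped with a warning since their z-score
is undefined). Rows with any missing retained feature — e.g. adaptation
ratios of cells with fewer than 3 spikes — are excluded and listed, not
imputed: imputing kinematic features for cells that cannot express them
would manufacture phenotype. Euclidean distances feed Ward agglomeration
in the `ward.D2` dialect, whose merge heights on Euclidean input equal
$\sqrt{2\,\Delta ESS}$; this makes every height checkable against an
exhaustive within-cluster sum-of-squares computation
(`ess_merge_heights()`), and the 1-D set $\{0, 1, 10\}$ gives the worked
heights $\{1, 10.9697\}$. Tie-breaking among equal merge candidates
follows the agglomeration backend; for distinct distances the result is
exactly permutation-invariant (property-tested). Cut labels are
renumbered by first appearance in leaf order, making the labelling a
deterministic function of the tree.

`select_k()` scans $k = 2..\min(10, n-1)$, computing the mean silhouette
$s(i) = (b_i - a_i)/\max(a_i, b_i)$ (singletons score 0) on the same
scaled-feature distances used for the tree, and takes the argmax
(smallest $k$ on ties). A best mean silhouette below 0.25 — the
customary floor below which partitions are not considered substantial —
raises a `no_structure` flag. Cluster × group composition at $k = 2$ is
tested with the Barnard test.

# The synthetic-membrane simulator

The generators are first-class, tested code, not fixtures; they define
the conditions under which the pipeline is validated.

- **Passive cells** use the exact solution of
  $C\,\dot V = -g_L(V - E_L) + I(t)$ sampled at the protocol rate, plus
  i.i.d. Gaussian noise (default 0.3 mV — a realistic whole-cell noise
  floor). Ground truth: $R_\mathrm{in} = 1/g_L$, $\tau = C/g_L$,
  RMP $= E_L$.
- **Spiking cells** use adaptive exponential integrate-and-fire
  dynamics (Euler, step ≤ 25 µs, compiled), chosen because it yields a
  rheobase, parameterizable AP shape, and spike-frequency adaptation
  with few constants; at cut-off a stereotyped 1 ms waveform (peak
  +35 mV) is inserted and the adaptation current incremented. The
  contract is on observable features (rheobase, monotone spike counts,
  adaptation ratios < 1 for positive increments), not the equations. The
  default noise here is 0.1 mV: the generator adds unfiltered white
  noise per sample, and the raw 40 kHz derivative carries ≈28 V/s of
  noise per mV of per-sample SD, so noise above ~0.15 mV would
  false-trigger the 30 V/s criterion — real rigs avoid this with online
  filtering, which the generator deliberately does not model.
- **Spikelet cells** add a sodium-like alpha-function transient
  (15 mV × `na_scale`, 2 ms rise) to the passive response, 150 ms into
  the step so the charging transient has settled; TTX multiplies
  `na_scale` by `ttx_factor` from the onset sweep. With factor 0.1 the
  measured amplitude reduction is 90% minus a small noise-peak bias
  (≈0.5 percentage points at 0.05 mV noise).
- **Feature tables** plant $k$ spherical Gaussian clusters whose
  centroids sit along random orthonormal directions at a prescribed
  pairwise separation in within-cluster SD units.

All generators are pure functions of (parameters, seed): identical seeds
give bit-identical output, and the caller's RNG stream is untouched.

# Validation scale and known limitations

The validation suite and `scripts/acceptance.R` use: a 5×5 grid of
$R_\mathrm{in} \in [50, 1000]$ MΩ × $\tau \in [5, 50]$ ms at 0.3 mV
noise and 20 averaged sweeps (all passive parameters recovered within
5%, worst ≈3.6%); 100 random spiky traces for detector–oracle identity;
100 random point sets ($n \le 7$) for Ward–ESS agreement; 100 planted
tables for cluster recovery; full enumeration for all exact-test sizes
$n, m \le 7$ and Barnard tables with group sizes ≤ 12; and a six-cell
simulated TTX experiment. These sizes make the whole suite run in well
under a minute per file on one core.

Limitations worth knowing:

- **Perfect-partition recovery is bounded by geometry.** At centroid
  separation 6 within-cluster SD, any classifier misplaces at least one
  of 60 points in ≥ 8% of draws (the midpoint-crossing probability is
  $\Phi(-3)$ per point), and Ward's tree cut does somewhat worse (~70%
  perfect partitions; mean adjusted Rand index ≈ 0.96). Silhouette
  selection of $k$ itself is essentially perfect at this separation.
  Claims of routine *exact* recovery under these conditions should be
  read against that ceiling.
- The simulator's white, stationary noise omits line pickup, 1/f
  drift, seal/access artifacts and electrode filtering; passing tests
  show estimator correctness under the stated model, not robustness to
  every artifact of real rigs.
- Silhouette values on real cortical feature tables depend on the
  exact cell and feature inclusion of the source tables; published
  supplementary tables are not redistributable here, so those
  comparisons require the user to supply the tables (see
  `tests/testthat/test-acceptance.R` for the expected file locations).
- No sag/Ih quantification, no two-exponential or pipette-artifact
  models, no vendor file formats, no voltage-clamp or synaptic
  analysis.
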