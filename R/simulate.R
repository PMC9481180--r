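#' Ground-truth membrane parameters for the synthetic-cell generators
#'
#' The simulator family covers three response modes seen in immature and
#' mature cortical cells: purely passive RC behaviour (`"none"`), repetitive
#' firing with spike-frequency adaptation via adaptive exponential
#' integrate-and-fire dynamics (`"adex"`), and small TTX-sensitive
#' sodium-transient "spikelets" riding on the passive response
#' (`"spikelet"`).
#'
#' Derived ground truth: input resistance `1/leak_conductance` (nS ->
#' GOhm, i.e. `1000/leak_conductance` MOhm) and membrane time constant
#' `capacitance_true/leak_conductance` (pF/nS = ms).
#'
#' @param leak_conductance Leak conductance in nS (> 0).
#' @param capacitance_true Membrane capacitance in pF (> 0).
#' @param leak_reversal Leak reversal potential in mV: the ground-truth
#'   resting membrane potential.
#' @param spike_mode One of `"none"`, `"adex"`, `"spikelet"`.
#' @param adaptation_increment Spike-triggered adaptation-current increment
#'   in pA (AdEx `b`).
#' @param adaptation_tau Adaptation-current time constant in ms (AdEx
#'   `tau_w`).
#' @param spike_threshold Soft spike-initiation threshold in mV (AdEx `V_T`).
#' @param spike_threshold_slope Threshold sharpness in mV (AdEx `Delta_T`).
#' @param reset Post-spike reset potential in mV.
#' @param na_scale Dimensionless scale of the spikelet sodium transient
#'   (1 gives a ~15 mV transient).
#' @param ttx_factor Multiplier applied to `na_scale` after TTX onset,
#'   in (0, 1].
#' @return An object of class `membrane_params`.
#' @export
membrane_params <- function(leak_conductance = 10,
                            capacitance_true = 150,
                            leak_reversal = -70,
                            spike_mode = c("none", "adex", "spikelet"),
                            adaptation_increment = 60,
                            adaptation_tau = 150,
                            spike_threshold = -45,
                            spike_threshold_slope = 2,
                            reset = -58,
                            na_scale = 1,
                            ttx_factor = 1) {
  spike_mode <- match.arg(spike_mode)
  if (leak_conductance <= 0) stop("leak_conductance must be > 0")
  if (capacitance_true <= 0) stop("capacitance_true must be > 0")
  if (ttx_factor <= 0 || ttx_factor > 1) stop("ttx_factor must be in (0, 1]")
  structure(
    list(leak_conductance = leak_conductance,
         capacitance_true = capacitance_true,
         leak_reversal = leak_reversal,
         spike_mode = spike_mode,
         adaptation_increment = adaptation_increment,
         adaptation_tau = adaptation_tau,
         spike_threshold = spike_threshold,
         spike_threshold_slope = spike_threshold_slope,
         reset = reset,
         na_scale = na_scale,
         ttx_factor = ttx_factor,
         rin_true = 1000 / leak_conductance,          # MOhm
         tau_true = capacitance_true / leak_conductance),  # ms
    class = "membrane_params"
  )
}

# Evaluate an expression under a fixed RNG state, restoring the caller's.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Exact passive RC voltage (mV) for one square step, sampled on `tt` (s).
# Baseline is the held potential if the protocol holds the cell, else the
# leak reversal.
passive_trace <- function(p, proto, amplitude_pA, tt) {
  v_base <- if (proto$held) proto$holding_potential else p$leak_reversal
  tau_s <- p$tau_true / 1000
  dv_ss <- amplitude_pA / p$leak_conductance   # pA/nS = mV
  on <- proto$step_onset
  off <- proto$step_onset + proto$step_duration
  v <- rep(v_base, length(tt))
  in_step <- tt >= on & tt < off
  v[in_step] <- v_base + dv_ss * (1 - exp(-(tt[in_step] - on) / tau_s))
  v_off <- v_base + dv_ss * (1 - exp(-proto$step_duration / tau_s))
  after <- tt >= off
  v[after] <- v_base + (v_off - v_base) * exp(-(tt[after] - off) / tau_s)
  v
}

#' Simulate passive hyperpolarizing-step sweeps
#'
#' The exact exponential solution of the RC membrane equation
#' `C dV/dt = -g_L (V - E_L) + I(t)` is sampled at the protocol rate and
#' i.i.d. Gaussian noise is added. The same seed always yields bit-identical
#' output.
#'
#' @param p A [membrane_params()] with `spike_mode = "none"`.
#' @param proto A [step_protocol()]; typically repeated -10 or -25 pA steps.
#' @param noise_sd Per-sample Gaussian noise SD in mV (>= 0).
#' @param n_sweeps Number of sweeps; each uses `proto$step_amplitudes`
#'   recycled if needed (a scalar amplitude repeats).
#' @param seed Integer RNG seed.
#' @param cell_id Cell identifier for the returned set.
#' @return A list with elements `sweeps` (a [sweep_set()]) and `truth`
#'   (ground-truth parameters: `rmp`, `rin_Mohm`, `tau_ms`, `cap_pF`).
#' @export
simulate_passive_sweeps <- function(p, proto, noise_sd = 0.3, n_sweeps = 20,
                                    seed = 1, cell_id = "sim_passive") {
  stopifnot(inherits(p, "membrane_params"), inherits(proto, "step_protocol"))
  if (p$spike_mode != "none") stop("simulate_passive_sweeps requires spike_mode = 'none'")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  amps <- rep_len(proto$step_amplitudes, n_sweeps)
  n_samp <- protocol_span_samples(proto) + round(0.1 * proto$sample_rate)
  tt <- (seq_len(n_samp) - 1) / proto$sample_rate
  sweeps <- with_seed(seed, {
    lapply(seq_len(n_sweeps), function(i) {
      v <- passive_trace(p, proto, amps[i], tt)
      if (noise_sd > 0) v <- v + stats::rnorm(n_samp, 0, noise_sd)
      sweep(sprintf("s%02d", i), v, amps[i])
    })
  })
  proto_out <- proto
  proto_out$step_amplitudes <- amps
  list(
    sweeps = sweep_set(cell_id, proto_out, sweeps),
    truth = list(params = p, rmp = p$leak_reversal, rin_Mohm = p$rin_true,
                 tau_ms = p$tau_true, cap_pF = p$capacitance_true)
  )
}

# AdEx integration for one depolarizing step; returns the voltage trace
# sampled at the protocol rate. Euler steps never exceed 25 us; the inner
# loop is compiled (src/adex.cpp).
adex_trace <- function(p, proto, amplitude_pA) {
  sr <- proto$sample_rate
  nsub <- max(1L, as.integer(ceiling((1 / sr) / 25e-6)))
  dt <- 1000 / (sr * nsub)  # ms
  n_samp <- protocol_span_samples(proto) + round(0.1 * sr)
  v_base <- if (proto$held) proto$holding_potential else p$leak_reversal
  i_hold <- if (proto$held) p$leak_conductance * (v_base - p$leak_reversal) else 0
  .adex_integrate(
    n_samp = as.integer(n_samp), nsub = nsub, dt_ms = dt,
    v_base = v_base, i_hold = i_hold, amplitude = amplitude_pA,
    on_i = as.integer(floor(proto$step_onset * sr) + 1L),
    off_i = as.integer(floor((proto$step_onset + proto$step_duration) * sr) + 1L),
    g_l = p$leak_conductance, e_l = p$leak_reversal,
    delta_t = p$spike_threshold_slope, v_t = p$spike_threshold,
    c = p$capacitance_true, tau_w = p$adaptation_tau,
    b = p$adaptation_increment, v_reset = p$reset,
    ap_len = max(2L, as.integer(round(0.001 * sr))), peak_v = 35
  )
}

#' Simulate a spiking cell (adaptive exponential integrate-and-fire)
#'
#' Depolarizing steps are integrated with AdEx dynamics (Euler, step <= 25
#' microseconds); at cut-off a stereotyped 1 ms action-potential waveform is
#' inserted and the adaptation current incremented, which produces
#' spike-frequency adaptation. Hyperpolarizing and zero steps use the exact
#' passive solution. Spike count is nondecreasing in step amplitude.
#'
#' @param p A [membrane_params()] with `spike_mode = "adex"`.
#' @param proto A [step_protocol()]; one sweep per amplitude.
#' @param seed Integer RNG seed (noise).
#' @param noise_sd Per-sample Gaussian noise SD in mV. The default (0.1) is
#'   deliberately below the passive-sweep default: the noise here is
#'   unfiltered white noise per 40 kHz sample, and spike detection operates
#'   on the raw central-difference derivative, so per-sample noise must stay
#'   well under the 30 V/s criterion (0.1 mV gives ~2.8 V/s derivative
#'   noise). Acquisition systems achieve the same with an online
#'   anti-alias filter, which this generator does not model.
#' @param cell_id Cell identifier.
#' @return A list with `sweeps` (a [sweep_set()]) and `truth`.
#' @export
simulate_spiking_cell <- function(p, proto, seed = 1, noise_sd = 0.1,
                                  cell_id = "sim_adex") {
  stopifnot(inherits(p, "membrane_params"), inherits(proto, "step_protocol"))
  if (p$spike_mode != "adex") stop("simulate_spiking_cell requires spike_mode = 'adex'")
  amps <- proto$step_amplitudes
  sweeps <- with_seed(seed, {
    lapply(seq_along(amps), function(i) {
      v <- if (amps[i] > 0) {
        adex_trace(p, proto, amps[i])
      } else {
        n_samp <- protocol_span_samples(proto) + round(0.1 * proto$sample_rate)
        passive_trace(p, proto, amps[i], (seq_len(n_samp) - 1) / proto$sample_rate)
      }
      if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
      sweep(sprintf("s%02d", i), v, amps[i])
    })
  })
  list(
    sweeps = sweep_set(cell_id, proto, sweeps),
    truth = list(params = p, rmp = p$leak_reversal, rin_Mohm = p$rin_true,
                 tau_ms = p$tau_true, cap_pF = p$capacitance_true)
  )
}

#' Simulate a TTX spikelet series
#'
#' Each sweep is the passive response to the same depolarizing step plus a
#' small sodium-like alpha-function transient whose amplitude is
#' `15 mV * na_scale`. From sweep `ttx_onset_sweep` onward the transient is
#' scaled by `ttx_factor`, emulating tetrodotoxin blockade of the
#' voltage-gated sodium conductance; the passive component is untouched.
#'
#' @param p A [membrane_params()] with `spike_mode = "spikelet"`.
#' @param proto A [step_protocol()] whose first amplitude is the (repeated)
#'   spikelet-inducing depolarizing step.
#' @param n_sweeps Number of sweeps in the series (default 60: one per
#'   second over a minute).
#' @param ttx_onset_sweep First sweep index with TTX in the bath; use
#'   `n_sweeps + 1` for a no-TTX series.
#' @param noise_sd Per-sample Gaussian noise SD in mV.
#' @param seed Integer RNG seed.
#' @param cell_id Cell identifier.
#' @return A list with `sweeps` (a [sweep_set()]; sweeps in series order)
#'   and `truth` (including the transient amplitude per sweep).
#' @export
simulate_spikelet_series <- function(p, proto, n_sweeps = 60,
                                     ttx_onset_sweep = n_sweeps + 1,
                                     noise_sd = 0.05, seed = 1,
                                     cell_id = "sim_spikelet") {
  stopifnot(inherits(p, "membrane_params"), inherits(proto, "step_protocol"))
  if (p$spike_mode != "spikelet") {
    stop("simulate_spikelet_series requires spike_mode = 'spikelet'")
  }
  if (ttx_onset_sweep < 1 || ttx_onset_sweep > n_sweeps + 1) {
    stop("ttx_onset_sweep must be in 1..n_sweeps+1")
  }
  amp <- proto$step_amplitudes[1]
  if (amp <= 0) stop("spikelet series requires a depolarizing step amplitude")
  n_samp <- protocol_span_samples(proto) + round(0.1 * proto$sample_rate)
  tt <- (seq_len(n_samp) - 1) / proto$sample_rate
  base_amp <- 15  # mV transient at na_scale = 1
  delay_s <- 0.15  # transient peak sits well after the charging transient
  tau_r <- 0.002
  t_rel <- tt - (proto$step_onset + delay_s)
  alpha <- ifelse(t_rel > 0, (t_rel / tau_r) * exp(1 - t_rel / tau_r), 0)
  passive <- passive_trace(p, proto, amp, tt)
  scale_by_sweep <- p$na_scale *
    ifelse(seq_len(n_sweeps) >= ttx_onset_sweep, p$ttx_factor, 1)
  sweeps <- with_seed(seed, {
    lapply(seq_len(n_sweeps), function(i) {
      v <- passive + base_amp * scale_by_sweep[i] * alpha
      if (noise_sd > 0) v <- v + stats::rnorm(n_samp, 0, noise_sd)
      sweep(sprintf("s%02d", i), v, amp)
    })
  })
  proto_out <- proto
  proto_out$step_amplitudes <- rep(amp, n_sweeps)
  list(
    sweeps = sweep_set(cell_id, proto_out, sweeps),
    truth = list(params = p, transient_mV = base_amp * scale_by_sweep,
                 ttx_onset_sweep = ttx_onset_sweep)
  )
}

#' Nine feature names used for phenotypic clustering
#'
#' AHP amplitude, AP halfwidth, AP threshold, input resistance, capacitance,
#' spike count at double rheobase, first-spike latency, and the two
#' adaptation ratios.
#' @return Character vector of length 9.
#' @export
clustering_feature_names <- function() {
  c("ahp_amplitude_mV", "ap_halfwidth_ms", "ap_threshold_mV", "rin_Mohm",
    "cap_pF", "n_spikes_2x", "ap_latency_ms", "adapt_1_2", "adapt_1_last")
}

#' Generate a feature table with planted cluster structure
#'
#' Cells are drawn from spherical Gaussian clusters whose centroids are
#' mutually separated by `centroid_separation` within-cluster standard
#' deviations, placed along random orthonormal directions.
#'
#' @param k Number of planted clusters (>= 1).
#' @param n_per_cluster Cells per cluster (>= 2).
#' @param centroid_separation Pairwise centroid distance in units of
#'   `within_sd`.
#' @param within_sd Within-cluster standard deviation per feature.
#' @param n_features Number of features (default 9, named after the
#'   clustering feature set).
#' @param seed Integer RNG seed.
#' @return A list with `table` (a [feature_table()]) and `truth` (planted
#'   labels and centroids).
#' @export
make_feature_table <- function(k, n_per_cluster, centroid_separation = 6,
                               within_sd = 1, n_features = 9, seed = 1) {
  if (k < 1) stop("k must be >= 1")
  if (n_per_cluster < 2) stop("n_per_cluster must be >= 2")
  if (n_features < k) stop("need n_features >= k to place orthogonal centroids")
  with_seed(seed, {
    basis <- qr.Q(qr(matrix(stats::rnorm(n_features * k), n_features, k)))
    centroids <- if (k == 1) {
      matrix(0, 1, n_features)
    } else {
      t(basis) * centroid_separation * within_sd / sqrt(2)
    }
    labels <- rep(seq_len(k), each = n_per_cluster)
    n <- length(labels)
    x <- centroids[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * n_features, 0, within_sd), n, n_features)
    colnames(x) <- if (n_features == 9) clustering_feature_names() else
      paste0("f", seq_len(n_features))
    rownames(x) <- sprintf("cell%03d", seq_len(n))
    list(table = feature_table(x), truth = list(labels = labels, centroids = centroids))
  })
}
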