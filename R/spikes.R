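#' Detect action-potential events by the dV/dt criterion
#'
#' An event starts at the first sample of an upward crossing of the voltage
#' slope (central difference at the native sampling rate) above
#' `dvdt_threshold`. Crossings closer than `refractory` to the previous
#' accepted event are ignored. Per event, the peak is the voltage maximum
#' within `peak_window` after the crossing, and the AHP trough is the
#' voltage minimum between the peak and the next event's threshold (or the
#' step end). Events whose threshold falls outside the current step are
#' discarded.
#'
#' @param sw A [sweep()].
#' @param protocol The [step_protocol()].
#' @param dvdt_threshold Slope threshold in V/s (default 30).
#' @param refractory Minimum event separation in ms (default 2).
#' @param peak_window Peak search window after threshold in ms (default 5).
#' @return A data.frame with one row per event: `threshold_index`,
#'   `threshold_time`, `threshold_voltage`, `peak_time`, `peak_voltage`,
#'   `ahp_trough_voltage`. Zero rows when nothing crosses threshold.
#' @export
detect_spikes <- function(sw, protocol, dvdt_threshold = 30, refractory = 2,
                          peak_window = 5) {
  stopifnot(inherits(sw, "sweep"))
  v <- sw$voltage
  n <- length(v)
  sr <- protocol$sample_rate
  tt <- sweep_times(sw, protocol)
  # central difference; mV/ms numerically equals V/s
  dvdt <- c(NA, (v[3:n] - v[1:(n - 2)]) / 2 * (sr / 1000), NA)
  above <- !is.na(dvdt) & dvdt > dvdt_threshold
  crossings <- which(above & !c(FALSE, above[-n]))
  on <- protocol$step_onset
  off <- on + protocol$step_duration
  crossings <- crossings[tt[crossings] >= on & tt[crossings] < off]
  refr_samp <- refractory / 1000 * sr
  kept <- integer(0)
  last <- -Inf
  for (i in crossings) {
    if (i - last >= refr_samp) {
      kept <- c(kept, i)
      last <- i
    }
  }
  empty <- data.frame(threshold_index = integer(0), threshold_time = numeric(0),
                      threshold_voltage = numeric(0), peak_time = numeric(0),
                      peak_voltage = numeric(0), ahp_trough_voltage = numeric(0))
  if (length(kept) == 0) return(empty)
  pk_samp <- max(1L, round(peak_window / 1000 * sr))
  end_idx <- min(n, which(tt < off)[sum(tt < off)])
  out <- lapply(seq_along(kept), function(j) {
    i <- kept[j]
    prng <- i:min(n, i + pk_samp)
    ipk <- prng[which.max(v[prng])]
    stop_i <- if (j < length(kept)) kept[j + 1] else end_idx
    trng <- ipk:max(ipk, stop_i)
    data.frame(threshold_index = i, threshold_time = tt[i],
               threshold_voltage = v[i], peak_time = tt[ipk],
               peak_voltage = v[ipk], ahp_trough_voltage = min(v[trng]))
  })
  do.call(rbind, out)
}

#' Single-AP features at rheobase
#'
#' Rheobase is the smallest depolarizing step amplitude eliciting at least
#' one detected spike; all single-AP features come from the first spike of
#' that sweep. Amplitude is peak minus threshold; AHP amplitude is
#' threshold minus trough; halfwidth is the full width at half amplitude
#' above threshold with linear interpolation at both crossings; latency is
#' the time from step onset to the first AP peak.
#'
#' @param s A [sweep_set()].
#' @param ... Passed to [detect_spikes()].
#' @return A list of class `single_ap_features`: `rheobase_pA`,
#'   `ap_threshold_mV`, `ap_amplitude_mV`, `ahp_amplitude_mV`,
#'   `ap_halfwidth_ms`, `ap_latency_ms`.
#' @export
ap_features_at_rheobase <- function(s, ...) {
  stopifnot(inherits(s, "sweep_set"))
  amps <- vapply(s$sweeps, `[[`, numeric(1), "injected_current")
  dep <- order(amps)
  dep <- dep[amps[dep] > 0]
  for (i in dep) {
    ev <- detect_spikes(s$sweeps[[i]], s$protocol, ...)
    if (nrow(ev) >= 1) {
      sw <- s$sweeps[[i]]
      e1 <- ev[1, ]
      amp <- e1$peak_voltage - e1$threshold_voltage
      half_v <- e1$threshold_voltage + amp / 2
      structure_out <- list(
        rheobase_pA = amps[i],
        ap_threshold_mV = e1$threshold_voltage,
        ap_amplitude_mV = amp,
        ahp_amplitude_mV = e1$threshold_voltage - e1$ahp_trough_voltage,
        ap_halfwidth_ms = halfwidth_ms(sw, s$protocol, e1, half_v),
        ap_latency_ms = (e1$peak_time - s$protocol$step_onset) * 1000
      )
      return(structure(structure_out, class = "single_ap_features"))
    }
  }
  stop("no rheobase: no depolarizing sweep elicits a spike (dV/dt criterion)")
}

# Full width at `half_v` around the event peak, linear interpolation at
# both crossings.
halfwidth_ms <- function(sw, protocol, event, half_v) {
  v <- sw$voltage
  tt <- sweep_times(sw, protocol)
  ipk <- which.min(abs(tt - event$peak_time))
  # rising crossing: last sample below half_v before the peak
  iup <- ipk
  while (iup > 1 && v[iup - 1] > half_v) iup <- iup - 1
  if (iup == 1) return(NA_real_)
  t_up <- interp_crossing(tt[iup - 1], tt[iup], v[iup - 1], v[iup], half_v)
  idn <- ipk
  n <- length(v)
  while (idn < n && v[idn + 1] > half_v) idn <- idn + 1
  if (idn == n) return(NA_real_)
  t_dn <- interp_crossing(tt[idn], tt[idn + 1], v[idn], v[idn + 1], half_v)
  (t_dn - t_up) * 1000
}

interp_crossing <- function(t1, t2, v1, v2, level) {
  if (v2 == v1) return(t1)
  t1 + (level - v1) / (v2 - v1) * (t2 - t1)
}

#' Spike-train features at double rheobase
#'
#' Spike count and adaptation ratios from the sweep at (or nearest to)
#' twice the rheobase amplitude. With peak times `t_1..t_n` (n >= 3):
#' `f_1 = 1/(t_2 - t_1)`, `f_2 = 1/(t_3 - t_2)`, `f_last = 1/(t_n -
#' t_{n-1})`; the first-second ratio is `f_2/f_1` and the first-last ratio
#' `f_last/f_1`. With fewer than 3 spikes the ratios are `NA`.
#'
#' @param s A [sweep_set()].
#' @param rheobase Rheobase amplitude in pA.
#' @param spike_times Optional numeric vector of spike times in s,
#'   bypassing detection (used for worked examples and external event
#'   streams).
#' @param first_freq `"first_isi"` (default) takes the first AP's
#'   instantaneous frequency as the reciprocal of the first inter-spike
#'   interval, the reading consistent with measuring intervals between
#'   spikes. `"inverse_latency"` instead uses the reciprocal of the first
#'   spike's latency from step onset; provided for comparison only, not
#'   endorsed.
#' @param step_onset Step onset in s, used only by the
#'   `"inverse_latency"` convention with explicit `spike_times`.
#' @param ... Passed to [detect_spikes()].
#' @return A list of class `train_features`: `n_spikes_2x`, `adapt_1_2`,
#'   `adapt_1_last`, `step_amplitude_pA`, `exact_double` (FALSE when the
#'   nearest available amplitude was substituted, with a warning).
#' @export
train_features <- function(s = NULL, rheobase = NULL, spike_times = NULL,
                           first_freq = c("first_isi", "inverse_latency"),
                           step_onset = 0, ...) {
  first_freq <- match.arg(first_freq)
  amp_used <- NA_real_
  exact_double <- NA
  if (is.null(spike_times)) {
    stopifnot(inherits(s, "sweep_set"), is.numeric(rheobase))
    amps <- vapply(s$sweeps, `[[`, numeric(1), "injected_current")
    dep <- which(amps > 0)
    if (length(dep) == 0) stop("no depolarizing sweeps for train analysis")
    target <- 2 * rheobase
    i <- dep[which.min(abs(amps[dep] - target))]
    amp_used <- amps[i]
    exact_double <- abs(amp_used - target) < 1e-9
    if (!exact_double) {
      warning("no sweep at exactly 2x rheobase (", target, " pA); using nearest ",
              amp_used, " pA")
    }
    ev <- detect_spikes(s$sweeps[[i]], s$protocol, ...)
    spike_times <- ev$peak_time
    step_onset <- s$protocol$step_onset
  }
  n <- length(spike_times)
  ratios <- c(NA_real_, NA_real_)
  if (n >= 3) {
    st <- sort(spike_times)
    isi <- diff(st)
    f1 <- if (first_freq == "first_isi") 1 / isi[1] else 1 / (st[1] - step_onset)
    f2 <- if (first_freq == "first_isi") 1 / isi[2] else 1 / isi[1]
    flast <- 1 / isi[length(isi)]
    ratios <- c(f2 / f1, flast / f1)
  }
  structure(
    list(n_spikes_2x = n, adapt_1_2 = ratios[1], adapt_1_last = ratios[2],
         step_amplitude_pA = amp_used, exact_double = exact_double),
    class = "train_features"
  )
}

#' Spikelet features of one depolarizing sweep
#'
#' Peak voltage is the maximum during the step; steady-state voltage is the
#' mean over the last 100 ms of the step; spikelet amplitude is their
#' difference. AHP amplitude comes from the dV/dt event trough when a
#' threshold crossing exists, else 0.
#'
#' @param sw A depolarizing [sweep()].
#' @param protocol The [step_protocol()].
#' @param ss_window Steady-state window length in s (default 0.1).
#' @param ... Passed to [detect_spikes()].
#' @return A list of class `spikelet_features`: `spikelet_peak_mV`,
#'   `spikelet_amp_mV`, `ahp_amplitude_mV`.
#' @export
spikelet_features <- function(sw, protocol, ss_window = 0.1, ...) {
  stopifnot(inherits(sw, "sweep"))
  if (sw$injected_current <= 0) stop("spikelet analysis requires a depolarizing sweep")
  tt <- sweep_times(sw, protocol)
  on <- protocol$step_onset
  off <- on + protocol$step_duration
  in_step <- tt >= on & tt < off
  peak <- max(sw$voltage[in_step])
  ss <- mean(sw$voltage[in_step & tt >= off - ss_window])
  ev <- detect_spikes(sw, protocol, ...)
  ahp <- if (nrow(ev) >= 1) ev$threshold_voltage[1] - ev$ahp_trough_voltage[1] else 0
  structure(
    list(spikelet_peak_mV = peak, spikelet_amp_mV = peak - ss,
         ahp_amplitude_mV = ahp),
    class = "spikelet_features"
  )
}

#' Classify a depolarizing response
#'
#' Rule order: mature AP if amplitude >= `mature_amp_min` and peak
#' overshoots 0 mV; else underdeveloped AP if peak > `underdev_peak_min`
#' and AHP > `underdev_ahp_min`; else spikelet if peak < `spikelet_peak_max`,
#' amplitude within `spikelet_amp_range`, and AHP <= `ahp_small_max`
#' ("little or no afterhyperpolarization"); else none.
#'
#' The immature-response bounds follow the published operational
#' definitions; the mature-AP rule is this package's convention (flagged in
#' reports), since mature cells were not part of the original immature-cell
#' classification.
#'
#' @param sp A [spikelet_features()] result (or any list with
#'   `spikelet_peak_mV`, `spikelet_amp_mV`, `ahp_amplitude_mV`).
#' @param mature_amp_min Minimum amplitude for a mature AP in mV (60).
#' @param mature_peak_min Minimum overshoot for a mature AP in mV (0).
#' @param underdev_peak_min Peak bound for underdeveloped APs in mV (30).
#' @param underdev_ahp_min AHP bound for underdeveloped APs in mV (15).
#' @param spikelet_peak_max Peak bound for spikelets in mV (10).
#' @param spikelet_amp_range Amplitude band for spikelets in mV (c(5, 25)).
#' @param ahp_small_max Largest AHP still counting as "little or none" (5).
#' @return One of `"mature_AP"`, `"underdeveloped_AP"`, `"spikelet"`,
#'   `"none"`.
#' @export
classify_response <- function(sp, mature_amp_min = 60, mature_peak_min = 0,
                              underdev_peak_min = 30, underdev_ahp_min = 15,
                              spikelet_peak_max = 10,
                              spikelet_amp_range = c(5, 25),
                              ahp_small_max = 5) {
  peak <- sp$spikelet_peak_mV
  amp <- sp$spikelet_amp_mV
  ahp <- sp$ahp_amplitude_mV
  if (amp >= mature_amp_min && peak >= mature_peak_min) return("mature_AP")
  if (peak > underdev_peak_min && ahp > underdev_ahp_min) return("underdeveloped_AP")
  if (peak < spikelet_peak_max &&
      amp >= spikelet_amp_range[1] && amp <= spikelet_amp_range[2] &&
      ahp <= ahp_small_max) {
    return("spikelet")
  }
  "none"
}

#' TTX blockade of spikelets in a repeated-step series
#'
#' Spikelet amplitude is measured per sweep; the mean over the first 10
#' sweeps (pre-blockade) is compared with the mean over the last 10
#' (post-blockade), and the percent reduction is
#' `100 * (1 - last10/first10)`.
#'
#' @param series A [sweep_set()] whose sweeps form the timed series (e.g.
#'   60 one-per-second depolarizing steps), or a list of [sweep()]s plus
#'   `protocol`.
#' @param protocol Required when `series` is a bare list of sweeps.
#' @return A list of class `ttx_result`: `mean_amp_first10`,
#'   `mean_amp_last10`, `percent_reduction`, `per_sweep_amp`.
#' @export
ttx_effect <- function(series, protocol = NULL) {
  if (inherits(series, "sweep_set")) {
    protocol <- series$protocol
    sweeps <- series$sweeps
  } else {
    stopifnot(is.list(series), inherits(protocol, "step_protocol"))
    sweeps <- series
  }
  n <- length(sweeps)
  if (n < 20) stop("TTX comparison needs >= 20 sweeps (got ", n, ")")
  amp <- vapply(sweeps, function(sw) {
    spikelet_features(sw, protocol)$spikelet_amp_mV
  }, numeric(1))
  first10 <- mean(amp[1:10])
  last10 <- mean(amp[(n - 9):n])
  structure(
    list(mean_amp_first10 = first10, mean_amp_last10 = last10,
         percent_reduction = if (first10 > 0) 100 * (1 - last10 / first10) else NA_real_,
         per_sweep_amp = amp),
    class = "ttx_result"
  )
}
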