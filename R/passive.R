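#' Resting membrane potential
#'
#' Mean voltage over a pre-step baseline window, averaged across sweeps.
#' When the recording was made under a holding current (protocol `held`),
#' the value is the held baseline, not a true zero-current resting
#' potential; the result carries a `held_baseline` flag so downstream
#' tables can keep the two apart.
#'
#' @param s A [sweep_set()].
#' @param baseline_window Two-element numeric `[start, end]` in seconds,
#'   ending at or before step onset. Default: the 50 ms before onset.
#' @return Numeric RMP in mV with attribute `held_baseline`.
#' @export
measure_rmp <- function(s, baseline_window = NULL) {
  stopifnot(inherits(s, "sweep_set"))
  p <- s$protocol
  if (is.null(baseline_window)) {
    baseline_window <- c(max(0, p$step_onset - 0.05), p$step_onset)
  }
  if (baseline_window[2] > p$step_onset + 1e-12) {
    stop("baseline window [", baseline_window[1], ", ", baseline_window[2],
         "] s extends past step onset (", p$step_onset, " s)")
  }
  means <- vapply(s$sweeps, function(sw) {
    tt <- sweep_times(sw, p)
    idx <- tt >= baseline_window[1] & tt < baseline_window[2]
    if (!any(idx)) {
      stop("baseline window outside recorded span of sweep '", sw$sweep_id, "'")
    }
    mean(sw$voltage[idx])
  }, numeric(1))
  structure(mean(means), held_baseline = isTRUE(p$held))
}

#' Average the responses to one hyperpolarizing step amplitude
#'
#' Pointwise mean across all sweeps acquired at the requested negative
#' amplitude. Averaging across different step sizes is refused.
#'
#' @param s A [sweep_set()].
#' @param target_amplitude Step amplitude in pA (negative). If `NULL`, the
#'   unique negative amplitude present is used; several distinct negative
#'   amplitudes without an explicit choice is an error.
#' @return A [sweep()] holding the averaged trace, with attribute
#'   `n_averaged`.
#' @export
average_hyperpolarizing_response <- function(s, target_amplitude = NULL) {
  stopifnot(inherits(s, "sweep_set"))
  amps <- vapply(s$sweeps, `[[`, numeric(1), "injected_current")
  if (is.null(target_amplitude)) {
    neg <- unique(amps[amps < 0])
    if (length(neg) == 0) stop("no hyperpolarizing sweeps in set ", s$cell_id)
    if (length(neg) > 1) {
      stop("several hyperpolarizing amplitudes present (",
           paste(neg, collapse = ", "),
           " pA); specify target_amplitude (mixed-amplitude averaging refused)")
    }
    target_amplitude <- neg
  }
  if (target_amplitude >= 0) stop("target_amplitude must be negative (pA)")
  sel <- which(abs(amps - target_amplitude) < 1e-9)
  if (length(sel) == 0) {
    stop("no sweeps at ", target_amplitude, " pA in set ", s$cell_id,
         " (available: ", paste(unique(amps), collapse = ", "), ")")
  }
  n_min <- min(vapply(s$sweeps[sel], function(sw) length(sw$voltage), integer(1)))
  vm <- rowMeans(vapply(s$sweeps[sel],
                        function(sw) sw$voltage[seq_len(n_min)],
                        numeric(n_min)))
  out <- sweep(paste0("avg_", target_amplitude, "pA"), vm, target_amplitude,
               t0 = s$sweeps[[sel[1]]]$t0)
  attr(out, "n_averaged") <- length(sel)
  out
}

# Baseline and steady-state deflection of an averaged step response.
# Returns list(v_base, v_ss, dv_ss) using a 50 ms pre-onset baseline and
# the last `ss_window` s of the step as steady state.
step_deflection <- function(avg, protocol, ss_window = 0.1) {
  tt <- sweep_times(avg, protocol)
  on <- protocol$step_onset
  off <- on + protocol$step_duration
  base_idx <- tt >= max(0, on - 0.05) & tt < on
  ss_idx <- tt >= off - ss_window & tt < off
  if (!any(base_idx) || !any(ss_idx)) {
    stop("trace does not cover the baseline/steady-state windows")
  }
  v_base <- mean(avg$voltage[base_idx])
  v_ss <- mean(avg$voltage[ss_idx])
  list(v_base = v_base, v_ss = v_ss, dv_ss = v_ss - v_base)
}

#' Input resistance from an averaged hyperpolarizing response
#'
#' `Rin = dV_ss / I`: the steady-state voltage deflection (mean over the
#' last 100 ms of the step, relative to the 50 ms pre-step baseline)
#' divided by the step current.
#'
#' @param avg Averaged sweep from [average_hyperpolarizing_response()].
#' @param protocol The [step_protocol()].
#' @param ss_window Steady-state window length in s (default 0.1).
#' @param noise_floor Minimum measurable deflection in mV (default 0.1).
#' @return Input resistance in MOhm.
#' @export
estimate_input_resistance <- function(avg, protocol, ss_window = 0.1,
                                      noise_floor = 0.1) {
  stopifnot(inherits(avg, "sweep"))
  i_pa <- avg$injected_current
  if (i_pa == 0) stop("cannot estimate input resistance from a zero-current sweep")
  d <- step_deflection(avg, protocol, ss_window)
  if (abs(d$dv_ss) < noise_floor) {
    stop("no measurable deflection (|dV_ss| = ", signif(abs(d$dv_ss), 3),
         " mV < ", noise_floor, " mV)")
  }
  (d$dv_ss / i_pa) * 1000  # mV/pA = GOhm -> MOhm
}

#' Membrane time constant by single-exponential fit
#'
#' Fits `V(t) = V_ss + (V_0 - V_ss) exp(-(t - t_on)/tau)` by nonlinear
#' least squares to the samples of the step-onset charging transient whose
#' deflection lies between 10% and 90% of the steady-state deflection
#' magnitude. `V_ss` is fixed at the directly measured steady state (mean
#' over the last 100 ms of the step): on band-restricted data a free
#' steady-state parameter trades off against `tau` and biases it upward at
#' low signal-to-noise, whereas the windowed mean determines `V_ss` far
#' more precisely than the fit could. `V_0` and `tau` are free.
#'
#' @inheritParams estimate_input_resistance
#' @param band Fraction band of the deflection used for fitting (default
#'   `c(0.1, 0.9)`).
#' @return List with `tau_ms` (in (0.1, 500]) and `fit_rss` (mV^2).
#' @export
fit_membrane_tau <- function(avg, protocol, ss_window = 0.1,
                             noise_floor = 0.1, band = c(0.1, 0.9)) {
  stopifnot(inherits(avg, "sweep"))
  d <- step_deflection(avg, protocol, ss_window)
  if (abs(d$dv_ss) < noise_floor) {
    stop("no measurable deflection (|dV_ss| = ", signif(abs(d$dv_ss), 3),
         " mV < ", noise_floor, " mV)")
  }
  tt <- sweep_times(avg, protocol)
  on <- protocol$step_onset
  off <- on + protocol$step_duration
  in_step <- which(tt >= on & tt < off)
  frac <- (avg$voltage[in_step] - d$v_base) / d$dv_ss
  # contiguous onset transient: from onset until the deflection first
  # reaches 90%, keeping samples above 10%
  i90 <- which(frac >= band[2])[1]
  if (is.na(i90)) i90 <- length(in_step)
  seg <- in_step[seq_len(i90)]
  seg <- seg[(avg$voltage[seg] - d$v_base) / d$dv_ss >= band[1]]
  if (length(seg) < 5) {
    stop("fewer than 5 samples in the ", band[1] * 100, "-", band[2] * 100,
         "% charging band; cannot fit tau")
  }
  t_ms <- (tt[seg] - on) * 1000
  v <- avg$voltage[seg]
  # tau_0 from the 63.2% crossing time
  i63 <- which(frac >= 1 - exp(-1))[1]
  tau0 <- if (is.na(i63)) protocol$step_duration * 250 else
    max(0.2, (tt[in_step[i63]] - on) * 1000)
  vss <- d$v_ss
  fit <- minpack.lm::nlsLM(
    v ~ vss + (v0 - vss) * exp(-t_ms / tau),
    start = list(v0 = d$v_base, tau = tau0),
    lower = c(v0 = -Inf, tau = 0.1),
    upper = c(v0 = Inf, tau = 500),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  if (!is.finite(cf[["tau"]]) || cf[["tau"]] <= 0) {
    stop("tau fit failed to converge (tau = ", cf[["tau"]], ")")
  }
  list(tau_ms = unname(cf[["tau"]]),
       fit_rss = sum(stats::resid(fit)^2))
}

#' Capacitance from the time constant and input resistance
#'
#' `C = tau / Rin`; ms/MOhm is nF, reported in pF.
#'
#' @param tau_ms Membrane time constant in ms (> 0).
#' @param rin_Mohm Input resistance in MOhm (> 0).
#' @return Capacitance in pF.
#' @export
compute_capacitance <- function(tau_ms, rin_Mohm) {
  if (!is.finite(tau_ms) || tau_ms <= 0) stop("tau must be > 0")
  if (!is.finite(rin_Mohm) || rin_Mohm <= 0) stop("input resistance must be > 0")
  tau_ms / rin_Mohm * 1000
}

#' Passive properties of one cell
#'
#' Convenience wrapper: averages the hyperpolarizing sweeps, then measures
#' RMP, input resistance, the fitted time constant, and the derived
#' capacitance.
#'
#' @param s A [sweep_set()].
#' @param target_amplitude Hyperpolarizing amplitude to average (pA), or
#'   `NULL` for the unique one present.
#' @return A list of class `passive_properties`: `rmp_mV` (with held flag),
#'   `rin_Mohm`, `tau_ms`, `cap_pF`, `n_sweeps_averaged`, `fit_rss`.
#' @export
passive_properties <- function(s, target_amplitude = NULL) {
  avg <- average_hyperpolarizing_response(s, target_amplitude)
  rmp <- measure_rmp(s)
  rin <- estimate_input_resistance(avg, s$protocol)
  tauf <- fit_membrane_tau(avg, s$protocol)
  structure(
    list(rmp_mV = as.numeric(rmp),
         rmp_is_held_baseline = isTRUE(attr(rmp, "held_baseline")),
         rin_Mohm = rin,
         tau_ms = tauf$tau_ms,
         cap_pF = compute_capacitance(tauf$tau_ms, rin),
         n_sweeps_averaged = attr(avg, "n_averaged"),
         fit_rss = tauf$fit_rss),
    class = "passive_properties"
  )
}
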