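#' Current-step stimulation protocol
#'
#' Describes a family of square current steps delivered from a common holding
#' potential: onset time and duration of the step within each sweep, the
#' ordered per-sweep step amplitudes, and the digitization rate.
#'
#' @param step_amplitudes Numeric vector of step amplitudes in pA, one per
#'   sweep, in acquisition order. Depolarizing (positive) amplitudes must be
#'   strictly increasing.
#' @param holding_potential Holding potential in mV (default -70).
#' @param step_onset Step onset relative to sweep start, in seconds.
#' @param step_duration Step duration in seconds (default 0.5).
#' @param increment Nominal step increment in pA; conventionally 10 or 25.
#' @param sample_rate Sampling rate in Hz (default 40000).
#' @param held Logical; was the membrane held at `holding_potential` by a
#'   bias current (affects how resting potential is reported downstream).
#'
#' @return An object of class `step_protocol`.
#' @export
step_protocol <- function(step_amplitudes,
                          holding_potential = -70,
                          step_onset = 0.1,
                          step_duration = 0.5,
                          increment = 25,
                          sample_rate = 40000,
                          held = TRUE) {
  stopifnot(is.numeric(step_amplitudes), length(step_amplitudes) >= 1)
  if (step_duration <= 0) stop("step_duration must be > 0")
  if (sample_rate <= 0) stop("sample_rate must be > 0")
  if (step_onset < 0) stop("step_onset must be >= 0")
  if (increment <= 0) stop("increment must be a positive pA value")
  # incremental families must be ordered; repeats are allowed so that
  # repeated-step series (e.g. timed TTX protocols) share the data model
  dep <- step_amplitudes[step_amplitudes > 0]
  if (length(dep) > 1 && any(diff(dep) < 0)) {
    stop("depolarizing step amplitudes must be nondecreasing")
  }
  structure(
    list(
      holding_potential = holding_potential,
      step_onset = step_onset,
      step_duration = step_duration,
      step_amplitudes = as.numeric(step_amplitudes),
      increment = increment,
      sample_rate = sample_rate,
      held = isTRUE(held)
    ),
    class = "step_protocol"
  )
}

#' A single current-clamp sweep
#'
#' @param sweep_id Identifier (coerced to character).
#' @param voltage Uniformly sampled membrane voltage in mV.
#' @param injected_current Step amplitude for this sweep, in pA.
#' @param t0 Time of the first sample relative to sweep start, in s.
#' @return An object of class `sweep`.
#' @export
sweep <- function(sweep_id, voltage, injected_current, t0 = 0) {
  voltage <- as.numeric(voltage)
  if (anyNA(voltage)) stop("sweep '", sweep_id, "' contains missing samples")
  if (length(voltage) < 2) stop("sweep '", sweep_id, "' has fewer than 2 samples")
  structure(
    list(
      sweep_id = as.character(sweep_id),
      voltage = voltage,
      injected_current = as.numeric(injected_current),
      t0 = as.numeric(t0)
    ),
    class = "sweep"
  )
}

#' One cell's set of sweeps with its protocol
#'
#' @param cell_id Cell identifier.
#' @param protocol A [step_protocol()].
#' @param sweeps List of [sweep()] objects in acquisition order.
#' @param access_resistance Optional numeric vector of access-resistance
#'   readings (MOhm) taken over the course of the recording, first reading
#'   first.
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(cell_id, protocol, sweeps, access_resistance = NULL) {
  stopifnot(inherits(protocol, "step_protocol"), is.list(sweeps))
  if (length(sweeps) == 0) stop("sweep_set requires at least one sweep")
  ok <- vapply(sweeps, inherits, logical(1), what = "sweep")
  if (!all(ok)) stop("all elements of 'sweeps' must be sweep objects")
  # every sweep must cover the protocol span; one trailing sample of slack
  span <- protocol_span_samples(protocol)
  for (sw in sweeps) {
    if (length(sw$voltage) < span - 1) {
      stop("sweep '", sw$sweep_id, "' has ", length(sw$voltage),
           " samples; protocol span requires ", span)
    }
  }
  structure(
    list(
      cell_id = as.character(cell_id),
      protocol = protocol,
      sweeps = sweeps,
      access_resistance = if (is.null(access_resistance)) NULL else as.numeric(access_resistance)
    ),
    class = "sweep_set"
  )
}

# number of samples needed to cover onset + step
protocol_span_samples <- function(protocol) {
  ceiling((protocol$step_onset + protocol$step_duration) * protocol$sample_rate) + 1
}

#' @export
print.sweep_set <- function(x, ...) {
  cat("<sweep_set> cell", x$cell_id, "-", length(x$sweeps), "sweeps @",
      x$protocol$sample_rate / 1000, "kHz\n")
  amps <- vapply(x$sweeps, `[[`, numeric(1), "injected_current")
  cat("  step amplitudes (pA):", paste(amps, collapse = ", "), "\n")
  cat("  step:", x$protocol$step_onset, "s onset,",
      x$protocol$step_duration, "s duration; held at",
      x$protocol$holding_potential, "mV\n")
  invisible(x)
}

#' Time base of a sweep under a protocol
#'
#' @param sw A [sweep()].
#' @param protocol A [step_protocol()].
#' @return Numeric vector of sample times in seconds (relative to sweep start).
#' @export
sweep_times <- function(sw, protocol) {
  sw$t0 + (seq_along(sw$voltage) - 1L) / protocol$sample_rate
}

#' Access-resistance quality control
#'
#' A recording is discarded when the access (series) resistance changes by
#' more than `threshold_frac` relative to the first reading, in either
#' direction: either direction invalidates series-resistance compensation.
#'
#' @param s A [sweep_set()] with a non-empty `access_resistance` series.
#' @param threshold_frac Maximum tolerated fractional change (default 0.20).
#' @return A list of class `qc_result` with `cell_id`, `passed`, and
#'   `max_fractional_change`.
#' @export
qc_access_resistance <- function(s, threshold_frac = 0.20) {
  stopifnot(inherits(s, "sweep_set"))
  ra <- s$access_resistance
  if (is.null(ra) || length(ra) == 0) {
    stop("cell ", s$cell_id, ": no access-resistance series; QC cannot be evaluated")
  }
  if (any(ra <= 0)) stop("cell ", s$cell_id, ": nonpositive access resistance reading")
  change <- max(abs(ra - ra[1]) / ra[1])
  structure(
    list(cell_id = s$cell_id, passed = change <= threshold_frac,
         max_fractional_change = change),
    class = "qc_result"
  )
}

#' Read a cell-metadata table
#'
#' CSV with columns `cell_id,genotype,age_days,region`; `cell_id` must be
#' unique.
#'
#' @param path Path to the CSV file.
#' @return A data.frame.
#' @export
read_cell_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "genotype", "age_days", "region")
  missing <- setdiff(need, names(md))
  if (length(missing)) {
    stop("metadata file ", path, " lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(md$cell_id)) stop("duplicate cell_id in metadata: ", path)
  md
}
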