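# Shared fixture builders and independent brute-force oracles.
# Oracles are written as naive direct computations so they stay
# independent of the package's vectorized implementations.

default_proto <- function(amps = -25, sample_rate = 40000, ...) {
  step_protocol(step_amplitudes = amps, sample_rate = sample_rate, ...)
}

# A sweep holding a constant voltage.
flat_sweep <- function(level = -70, proto = default_proto(), amp = proto$step_amplitudes[1]) {
  n <- ceiling((proto$step_onset + proto$step_duration + 0.1) * proto$sample_rate)
  sweep("flat", rep(level, n), amp)
}

# Ideal square-step response without a charging transient: baseline before
# onset, baseline + dv during the step. Useful for exact Ohm's-law checks.
square_step_sweep <- function(dv, amp, proto = default_proto(amps = amp),
                              baseline = -70) {
  n <- ceiling((proto$step_onset + proto$step_duration + 0.1) * proto$sample_rate)
  tt <- (seq_len(n) - 1) / proto$sample_rate
  v <- rep(baseline, n)
  v[tt >= proto$step_onset & tt < proto$step_onset + proto$step_duration] <-
    baseline + dv
  sweep(paste0("sq", amp), v, amp)
}

# Insert a sharp triangular AP-like deflection into a voltage vector:
# linear rise over rise_ms to peak, linear fall over fall_ms to after_level.
insert_triangle <- function(v, sr, t_start, base_level, peak, rise_ms = 0.5,
                            fall_ms = 0.8, after_level = base_level) {
  i0 <- round(t_start * sr) + 1
  n_up <- max(2, round(rise_ms / 1000 * sr))
  n_dn <- max(2, round(fall_ms / 1000 * sr))
  up <- seq(base_level, peak, length.out = n_up)
  dn <- seq(peak, after_level, length.out = n_dn + 1)[-1]
  idx <- i0 + seq_len(n_up + n_dn) - 1
  keep <- idx <= length(v)
  v[idx[keep]] <- c(up, dn)[keep]
  v
}

# Random spiky trace for detection-oracle tests: quiet baseline with small
# white noise plus triangular events at random times, some deliberately
# close together to exercise the refractory rule.
random_spiky_sweep <- function(seed, proto = default_proto(amps = 100)) {
  set.seed(seed)
  sr <- proto$sample_rate
  n <- ceiling((proto$step_onset + proto$step_duration + 0.1) * sr)
  v <- rep(-70, n) + rnorm(n, 0, 0.05)
  n_ev <- sample(3:12, 1)
  t_ev <- sort(runif(n_ev, proto$step_onset + 0.005,
                     proto$step_onset + proto$step_duration - 0.01))
  if (n_ev >= 2 && runif(1) < 0.7) {
    # force at least one sub-refractory pair
    t_ev[2] <- t_ev[1] + runif(1, 0.0005, 0.0015)
    t_ev <- sort(t_ev)
  }
  for (t0 in t_ev) {
    v <- insert_triangle(v, sr, t0, -55, runif(1, 10, 40), rise_ms = 0.4,
                         fall_ms = 0.8, after_level = -62)
  }
  sweep(paste0("rand", seed), v, 100)
}

# Brute-force spike-threshold scan: per-sample central-difference slope,
# first-crossing rule with refractory, restricted to the current step.
oracle_threshold_indices <- function(sw, proto, dvdt_threshold = 30,
                                     refractory = 2) {
  v <- sw$voltage
  n <- length(v)
  sr <- proto$sample_rate
  tt <- (seq_len(n) - 1) / sr + sw$t0
  on <- proto$step_onset
  off <- on + proto$step_duration
  out <- integer(0)
  last <- -Inf
  prev_above <- FALSE
  for (i in 2:(n - 1)) {
    slope <- (v[i + 1] - v[i - 1]) / 2 * (sr / 1000)  # V/s
    above <- slope > dvdt_threshold
    if (above && !prev_above && tt[i] >= on && tt[i] < off &&
        (i - last) >= refractory / 1000 * sr) {
      out <- c(out, i)
      last <- i
    }
    prev_above <- above
  }
  out
}

# Exhaustive Mann-Whitney oracle: every C(n+m, n) assignment of the pooled
# values to the first group; U by direct pair counting; two-sided p is
# twice the smaller tail, capped at 1.
oracle_mann_whitney_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_of <- function(xx, yy) {
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_of(x, y)
  subsets <- utils::combn(length(pooled), n)
  us <- apply(subsets, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  lo <- mean(us <= u_obs + 1e-9)
  hi <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# Exhaustive Wilcoxon signed-rank oracle over all 2^n sign assignments.
oracle_signed_rank_p <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  lo <- mean(ws <= w_obs + 1e-9)
  hi <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# Brute-force Barnard oracle: outcome enumeration with a dense nuisance
# grid (no refinement step shared with the implementation).
oracle_barnard_p <- function(tab, grid_n = 50001) {
  n1 <- sum(tab[, 1]); n2 <- sum(tab[, 2])
  z_of <- function(y1, y2) {
    pb <- (y1 + y2) / (n1 + n2)
    if (pb == 0 || pb == 1) return(0)
    (y1 / n1 - y2 / n2) / sqrt(pb * (1 - pb) * (1 / n1 + 1 / n2))
  }
  z_obs <- abs(z_of(tab[1, 1], tab[1, 2]))
  zs <- matrix(0, n1 + 1, n2 + 1)
  for (y1 in 0:n1) for (y2 in 0:n2) zs[y1 + 1, y2 + 1] <- abs(z_of(y1, y2))
  mask <- zs >= z_obs - 1e-12
  best <- 0
  for (pi in seq_len(grid_n) / (grid_n + 1)) {
    pr <- outer(dbinom(0:n1, n1, pi), dbinom(0:n2, n2, pi))
    best <- max(best, sum(pr[mask]))
  }
  min(1, best)
}

# Brute-force silhouette: direct a(i)/b(i) computation from a distance
# matrix.
oracle_silhouette <- function(labels, dmat) {
  dmat <- as.matrix(dmat)
  n <- nrow(dmat)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(dmat[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(dmat[i, labels == cl])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# Independent response-class oracle: a direct transcription of the rule
# table, kept deliberately separate from classify_response().
oracle_classify <- function(peak, amp, ahp) {
  if (amp >= 60 && peak >= 0) {
    "mature_AP"
  } else if (peak > 30 && ahp > 15) {
    "underdeveloped_AP"
  } else if (peak < 10 && amp >= 5 && amp <= 25 && ahp <= 5) {
    "spikelet"
  } else {
    "none"
  }
}

# Small simulated spiking cohort for pipeline tests; cheaper protocol
# (10 kHz, short pre/post) to keep runtimes down.
sim_cohort_cell <- function(id, seed, genotype, g = 5, C = 100, e_l = -70) {
  proto <- step_protocol(step_amplitudes = c(-25, -25, -25, seq(25, 300, 25)),
                         sample_rate = 10000)
  p <- membrane_params(spike_mode = "adex", leak_conductance = g,
                       capacitance_true = C, leak_reversal = e_l)
  sim <- simulate_spiking_cell(p, proto, seed = seed, cell_id = id)
  sim$sweeps
}
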