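test_that("generators are pure functions of (params, seed)", {
  p <- membrane_params(leak_conductance = 10, capacitance_true = 150)
  proto <- default_proto(amps = -25)
  a <- simulate_passive_sweeps(p, proto, noise_sd = 0.3, n_sweeps = 3, seed = 5)
  b <- simulate_passive_sweeps(p, proto, noise_sd = 0.3, n_sweeps = 3, seed = 5)
  expect_identical(a$sweeps$sweeps, b$sweeps$sweeps)
  c <- simulate_passive_sweeps(p, proto, noise_sd = 0.3, n_sweeps = 3, seed = 6)
  expect_false(identical(a$sweeps$sweeps, c$sweeps$sweeps))
  pa <- membrane_params(spike_mode = "adex", leak_conductance = 5,
                        capacitance_true = 100)
  proto2 <- default_proto(amps = c(100, 200))
  expect_identical(simulate_spiking_cell(pa, proto2, seed = 3)$sweeps$sweeps,
                   simulate_spiking_cell(pa, proto2, seed = 3)$sweeps$sweeps)
  # the generator does not disturb the caller's RNG stream
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(simulate_passive_sweeps(p, proto, seed = 1))
  expect_identical(runif(1), x1)
})

test_that("passive analytic identities: steady state and 63.2% rise point", {
  p <- membrane_params(leak_conductance = 10, capacitance_true = 150)  # tau 15
  proto <- default_proto(amps = -25)
  s <- simulate_passive_sweeps(p, proto, noise_sd = 0, n_sweeps = 1,
                               seed = 1)$sweeps$sweeps[[1]]
  tt <- sweep_times(s, proto)
  # steady-state deflection exactly I/gL = -2.5 mV at the step end
  i_end <- max(which(tt < proto$step_onset + proto$step_duration))
  expect_equal(s$voltage[i_end] - (-70), -2.5, tolerance = 1e-6)
  # 63.21% of the deflection is reached at tau = 15 ms after onset
  target <- -70 + (1 - exp(-1)) * -2.5
  i_tau <- which(tt >= proto$step_onset & s$voltage <= target)[1]
  expect_equal((tt[i_tau] - proto$step_onset) * 1000, 15,
               tolerance = 0.05)  # within one 40 kHz sample
})

test_that("AdEx spike count is nondecreasing in step amplitude", {
  p <- membrane_params(spike_mode = "adex", leak_conductance = 5,
                       capacitance_true = 100)
  proto <- default_proto(amps = c(seq(25, 300, 25)))
  s <- simulate_spiking_cell(p, proto, seed = 11, noise_sd = 0)$sweeps
  counts <- vapply(s$sweeps, function(sw) {
    nrow(detect_spikes(sw, proto))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[1], 0)  # below rheobase
  expect_gt(max(counts), 0)
})

test_that("adaptation increment controls the first-last ratio", {
  proto <- default_proto(amps = c(-25, seq(25, 300, 25)))
  mk <- function(b, seed) {
    p <- membrane_params(spike_mode = "adex", leak_conductance = 5,
                         capacitance_true = 100, adaptation_increment = b)
    s <- simulate_spiking_cell(p, proto, seed = seed)$sweeps
    ap <- ap_features_at_rheobase(s)
    suppressWarnings(train_features(s, ap$rheobase_pA))
  }
  for (seed in 1:5) {
    tr <- mk(60, seed)
    if (!is.na(tr$adapt_1_last)) expect_lt(tr$adapt_1_last, 1)
  }
  tr0 <- mk(0, 1)
  if (!is.na(tr0$adapt_1_2)) {
    expect_gt(tr0$adapt_1_2, 0.9)
    expect_lt(tr0$adapt_1_2, 1.1)
  }
})

test_that("spikelet series responds to na_scale and ttx_factor as designed", {
  proto <- default_proto(amps = 125)
  base <- membrane_params(spike_mode = "spikelet", leak_conductance = 5,
                          capacitance_true = 100)
  # no TTX: first and last windows agree within noise
  ser <- simulate_spikelet_series(base, proto, ttx_onset_sweep = 61, seed = 2)
  r <- ttx_effect(ser$sweeps)
  expect_lt(abs(r$percent_reduction), 5)
  # na_scale 0: every sweep classifies as none
  p0 <- membrane_params(spike_mode = "spikelet", leak_conductance = 5,
                        capacitance_true = 100, na_scale = 0)
  ser0 <- simulate_spikelet_series(p0, proto, n_sweeps = 20, seed = 3)
  classes <- vapply(ser0$sweeps$sweeps, function(sw) {
    classify_response(spikelet_features(sw, proto))
  }, character(1))
  expect_true(all(classes == "none"))
  # the designed spikelet sits inside the published class bounds
  ser1 <- simulate_spikelet_series(base, proto, n_sweeps = 20, seed = 4)
  cls <- classify_response(spikelet_features(ser1$sweeps$sweeps[[1]], proto))
  expect_equal(cls, "spikelet")
  expect_error(simulate_spikelet_series(base, proto, ttx_onset_sweep = 99),
               "ttx_onset_sweep")
})

test_that("planted feature tables have the requested geometry", {
  sim <- make_feature_table(k = 3, n_per_cluster = 10, centroid_separation = 7,
                            seed = 5)
  expect_equal(dim(sim$table$matrix), c(30, 9))
  expect_equal(sim$table$feature_names, clustering_feature_names())
  cen <- sim$truth$centroids
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(sqrt(sum((cen[i, ] - cen[j, ])^2)), 7, tolerance = 1e-9)
  }
  # separation 0 is unidentifiable: ARI against truth near zero
  sim0 <- make_feature_table(k = 2, n_per_cluster = 20,
                             centroid_separation = 0, seed = 6)
  lab <- cut_dendrogram(ward_linkage(euclidean_distances(sim0$table)), 2)
  expect_lt(abs(adjusted_rand_index(lab, sim0$truth$labels)), 0.3)
  expect_error(make_feature_table(k = 0, n_per_cluster = 5), "k must be")
  expect_error(make_feature_table(k = 2, n_per_cluster = 1), "n_per_cluster")
})

test_that("end-to-end passive recovery across a parameter grid with noise", {
  proto <- default_proto(amps = -25)
  for (rin in c(100, 500)) {
    for (tau in c(10, 40)) {
      g <- 1000 / rin
      p <- membrane_params(leak_conductance = g, capacitance_true = tau * g)
      s <- simulate_passive_sweeps(p, proto, noise_sd = 0.3, n_sweeps = 20,
                                   seed = rin + tau)$sweeps
      pp <- passive_properties(s)
      expect_lt(abs(pp$rin_Mohm - rin) / rin, 0.05)
      expect_lt(abs(pp$tau_ms - tau) / tau, 0.05)
      expect_equal(pp$cap_pF, pp$tau_ms / pp$rin_Mohm * 1000, tolerance = 1e-9)
    }
  }
})
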