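test_that("flat traces yield no events and inserted events match the scan oracle", {
  proto <- default_proto(amps = 100)
  expect_equal(nrow(detect_spikes(flat_sweep(-70, proto, 100), proto)), 0)
  # one synthetic AP at 150 ms
  sr <- proto$sample_rate
  n <- ceiling(0.7 * sr)
  v <- rep(-70, n)
  v <- insert_triangle(v, sr, 0.150, -55, 20)
  sw <- sweep("one", v, 100)
  ev <- detect_spikes(sw, proto)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$threshold_index, oracle_threshold_indices(sw, proto))
  # two crossings 1 ms apart with a 2 ms refractory collapse to one event
  v2 <- rep(-70, n)
  v2 <- insert_triangle(v2, sr, 0.200, -55, 20, rise_ms = 0.3, fall_ms = 0.3)
  v2 <- insert_triangle(v2, sr, 0.201, -55, 20, rise_ms = 0.3, fall_ms = 0.3)
  sw2 <- sweep("two", v2, 100)
  expect_equal(nrow(detect_spikes(sw2, proto, refractory = 2)), 1)
  expect_equal(detect_spikes(sw2, proto, refractory = 2)$threshold_index,
               oracle_threshold_indices(sw2, proto, refractory = 2))
  # events before step onset are discarded
  v3 <- insert_triangle(rep(-70, n), sr, 0.05, -55, 20)
  expect_equal(nrow(detect_spikes(sweep("pre", v3, 100), proto)), 0)
})

test_that("detected thresholds equal the brute-force scan on random spiky traces", {
  proto <- default_proto(amps = 100)
  for (seed in 1:25) {
    sw <- random_spiky_sweep(seed, proto)
    expect_identical(detect_spikes(sw, proto)$threshold_index,
                     oracle_threshold_indices(sw, proto))
  }
})

test_that("event geometry identities hold on detected spikes", {
  proto <- default_proto(amps = c(-25, seq(25, 300, 25)))
  p <- membrane_params(spike_mode = "adex", leak_conductance = 5,
                       capacitance_true = 100)
  s <- simulate_spiking_cell(p, proto, seed = 3)$sweeps
  ap <- ap_features_at_rheobase(s)
  i <- which(vapply(s$sweeps, `[[`, numeric(1), "injected_current") ==
               ap$rheobase_pA)
  ev <- detect_spikes(s$sweeps[[i]], s$protocol)
  expect_equal(ev$peak_voltage, ev$threshold_voltage +
                 (ev$peak_voltage - ev$threshold_voltage))
  expect_true(all(ev$peak_time > ev$threshold_time))
  expect_true(all(ev$peak_voltage >= ev$threshold_voltage))
  # recomposition of the reported amplitudes
  expect_equal(ap$ap_threshold_mV + ap$ap_amplitude_mV,
               ev$peak_voltage[1])
  expect_equal(ap$ap_threshold_mV - ap$ahp_amplitude_mV,
               ev$ahp_trough_voltage[1])
})

test_that("rheobase and the triangular-AP halfwidth match construction", {
  # cell spiking first at +75 pA on a 25 pA ladder
  proto <- default_proto(amps = c(25, 50, 75, 100))
  sr <- proto$sample_rate
  n <- ceiling(0.7 * sr)
  mk <- function(spike) {
    v <- rep(-70, n)
    if (spike) v <- insert_triangle(v, sr, 0.2, -70, 20, rise_ms = 1, fall_ms = 1.5)
    v
  }
  s <- sweep_set("tri", proto, list(
    sweep("a", mk(FALSE), 25), sweep("b", mk(FALSE), 50),
    sweep("c", mk(TRUE), 75), sweep("d", mk(TRUE), 100)))
  ap <- ap_features_at_rheobase(s)
  expect_equal(ap$rheobase_pA, 75)
  expect_equal(ap$ap_amplitude_mV, 20 - ap$ap_threshold_mV)
  # triangle with threshold on the rising limb: closed-form width at half
  # amplitude is the rising time above the half level plus the falling time
  # above it (rise 1 ms over -70..20 mV, fall 1.5 ms over 20..-70 mV)
  thr <- ap$ap_threshold_mV
  half <- thr + (20 - thr) / 2
  width_expected <- (20 - half) / ((20 - (-70)) / 1) +
    (20 - half) / ((20 - (-70)) / 1.5)
  expect_lt(abs(ap$ap_halfwidth_ms - width_expected), 0.06)
  # a never-spiking set has no rheobase
  s0 <- sweep_set("none", proto, list(sweep("a", mk(FALSE), 25)))
  expect_error(ap_features_at_rheobase(s0), "no rheobase")
})

test_that("adaptation-ratio arithmetic matches the worked example", {
  tr <- train_features(spike_times = c(0, 10, 30, 60) / 1000)
  expect_equal(tr$n_spikes_2x, 4)
  expect_equal(tr$adapt_1_2, 0.5)
  expect_equal(tr$adapt_1_last, 1 / 3, tolerance = 1e-12)
  # regular train: both ratios exactly 1
  reg <- train_features(spike_times = seq(0, 0.1, by = 0.02))
  expect_equal(reg$adapt_1_2, 1)
  expect_equal(reg$adapt_1_last, 1)
  # fewer than 3 spikes: count reported, ratios missing
  two <- train_features(spike_times = c(0.01, 0.05))
  expect_equal(two$n_spikes_2x, 2)
  expect_true(is.na(two$adapt_1_2) && is.na(two$adapt_1_last))
})

test_that("the inverse-latency frequency convention is exposed but distinct", {
  # onset at 0, spikes at 10, 20, 40, 70 ms: first-ISI reading gives
  # f1 = 100 Hz; inverse-latency reading gives f1 = 1/10 ms = 100 Hz too,
  # but the second frequency shifts from 1/20 ms to 1/10 ms
  st <- c(10, 20, 40, 70) / 1000
  isi <- train_features(spike_times = st)
  lat <- train_features(spike_times = st, first_freq = "inverse_latency",
                        step_onset = 0)
  expect_equal(isi$adapt_1_2, (1 / 0.020) / (1 / 0.010))
  expect_equal(lat$adapt_1_2, (1 / 0.010) / (1 / 0.010))
  expect_equal(lat$adapt_1_last, (1 / 0.030) / (1 / 0.010))
})

test_that("adaptation ratios are invariant to time shift and dilation", {
  base <- c(0, 0.008, 0.020, 0.045, 0.080)
  r0 <- train_features(spike_times = base)
  r_shift <- train_features(spike_times = base + 0.123)
  r_dilate <- train_features(spike_times = base * 3.7)
  expect_equal(r_shift$adapt_1_2, r0$adapt_1_2)
  expect_equal(r_shift$adapt_1_last, r0$adapt_1_last)
  expect_equal(r_dilate$adapt_1_2, r0$adapt_1_2)
  expect_equal(r_dilate$adapt_1_last, r0$adapt_1_last)
})

test_that("nearest-amplitude substitution at double rheobase warns", {
  proto <- default_proto(amps = c(25, 40))
  sr <- proto$sample_rate
  n <- ceiling(0.7 * sr)
  v <- insert_triangle(rep(-70, n), sr, 0.2, -40, 20)
  s <- sweep_set("coarse", proto,
                 list(sweep("a", v, 25), sweep("b", v, 40)))
  expect_warning(tr <- train_features(s, rheobase = 25), "nearest")
  expect_equal(tr$step_amplitude_pA, 40)
  expect_false(tr$exact_double)
})

test_that("rheobase is monotone under added low-amplitude spikes", {
  proto <- default_proto(amps = c(25, 50, 75))
  sr <- proto$sample_rate
  n <- ceiling(0.7 * sr)
  quiet <- rep(-70, n)
  spiky <- insert_triangle(quiet, sr, 0.2, -40, 20)
  s_hi <- sweep_set("hi", proto, list(
    sweep("a", quiet, 25), sweep("b", quiet, 50), sweep("c", spiky, 75)))
  s_lo <- sweep_set("lo", proto, list(
    sweep("a", quiet, 25), sweep("b", spiky, 50), sweep("c", spiky, 75)))
  expect_gt(ap_features_at_rheobase(s_hi)$rheobase_pA,
            ap_features_at_rheobase(s_lo)$rheobase_pA)
})

test_that("spikelet features and the published class bounds", {
  # worked feature combinations against the rule table
  expect_equal(classify_response(list(spikelet_peak_mV = 5, spikelet_amp_mV = 15,
                                      ahp_amplitude_mV = 1)), "spikelet")
  expect_equal(classify_response(list(spikelet_peak_mV = 40, spikelet_amp_mV = 45,
                                      ahp_amplitude_mV = 20)), "underdeveloped_AP")
  expect_equal(classify_response(list(spikelet_peak_mV = 35, spikelet_amp_mV = 45,
                                      ahp_amplitude_mV = 16)), "underdeveloped_AP")
  expect_equal(classify_response(list(spikelet_peak_mV = 25, spikelet_amp_mV = 80,
                                      ahp_amplitude_mV = 12)), "mature_AP")
  expect_equal(classify_response(list(spikelet_peak_mV = 8, spikelet_amp_mV = 30,
                                      ahp_amplitude_mV = 0)), "none")
  expect_equal(classify_response(list(spikelet_peak_mV = 2, spikelet_amp_mV = 3,
                                      ahp_amplitude_mV = 0)), "none")
  # measured features on an ideal flat depolarizing response
  proto <- default_proto(amps = 50)
  spl <- spikelet_features(square_step_sweep(4, 50), proto)
  expect_equal(spl$spikelet_amp_mV, 0)
  expect_equal(classify_response(spl), "none")
})

test_that("classification matches the rule-table oracle on a value grid", {
  grid <- expand.grid(peak = seq(-10, 100, by = 2),
                      amp = seq(-10, 100, by = 2),
                      ahp = seq(0, 30, by = 3))
  got <- mapply(function(pk, am, ah) {
    classify_response(list(spikelet_peak_mV = pk, spikelet_amp_mV = am,
                           ahp_amplitude_mV = ah))
  }, grid$peak, grid$amp, grid$ahp)
  want <- mapply(oracle_classify, grid$peak, grid$amp, grid$ahp)
  expect_identical(unname(got), unname(want))
})

test_that("TTX amplitude comparison and simulated blockade", {
  proto <- default_proto(amps = 125)
  # constructed series: first 30 sweeps at 20 mV transient, last 30 at 2 mV
  sr <- proto$sample_rate
  n <- ceiling(0.7 * sr)
  mk <- function(amp_mV) {
    v <- rep(-70, n)
    idx <- seq(round(0.3 * sr), round(0.3 * sr) + round(0.002 * sr))
    v[idx] <- v[idx] + amp_mV
    sweep("s", v, 125)
  }
  series <- c(replicate(30, mk(20), simplify = FALSE),
              replicate(30, mk(2), simplify = FALSE))
  r <- ttx_effect(series, proto)
  expect_equal(r$percent_reduction, 90)
  flat_series <- replicate(30, mk(10), simplify = FALSE)
  expect_equal(ttx_effect(flat_series, proto)$percent_reduction, 0)
  expect_error(ttx_effect(flat_series[1:10], proto), ">= 20 sweeps")
  # simulated spikelet cell with blockade factor 0.1 from sweep 31
  p <- membrane_params(spike_mode = "spikelet", leak_conductance = 5,
                       capacitance_true = 100, ttx_factor = 0.1)
  ser <- simulate_spikelet_series(p, proto, ttx_onset_sweep = 31, seed = 9)
  red <- ttx_effect(ser$sweeps)$percent_reduction
  expect_gt(red, 88)
  expect_lt(red, 92)
})
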