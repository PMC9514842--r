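test_that("ground truth validates its parameters and reports the weighted tau", {
  tr <- ground_truth()
  expect_equal(true_weighted_tau(tr), 4) # 0.75 * 2 + 0.25 * 10
  expect_error(ground_truth(rin_mohm = -1), "rin")
  expect_error(ground_truth(p_fail = 1.5), "probability")
  expect_error(ground_truth(swim_freq_hz = c(0, 20)), "frequency")
})

test_that("noiseless step sweeps reproduce the programmed Rin", {
  # exact with single-exponential kinetics...
  sw1 <- generate_step_response_sweeps(
    ground_truth(rin_mohm = 750, tau_b = 0, noise_sd = 0, seed = 1),
    n_sweeps = 3)
  expect_equal(input_resistance(sw1), 750, tolerance = 1e-9)
  # ...and to within the unsettled slow component for bi-exponential kinetics
  sw <- generate_step_response_sweeps(
    ground_truth(rin_mohm = 750, noise_sd = 0, seed = 1), n_sweeps = 3)
  expect_equal(input_resistance(sw), 750, tolerance = 0.005)
  expect_error(generate_step_response_sweeps(ground_truth(), n_sweeps = 2),
               "at least 3")
})

test_that("generation is bit-identical under the same seed", {
  a <- generate_step_response_sweeps(ground_truth(seed = 12), n_sweeps = 4)
  b <- generate_step_response_sweeps(ground_truth(seed = 12), n_sweeps = 4)
  expect_identical(a$sweeps, b$sweeps)
  c1 <- generate_mixed_psp_sweeps(ground_truth(seed = 4), n_sweeps = 15)
  c2 <- generate_mixed_psp_sweeps(ground_truth(seed = 4), n_sweeps = 15)
  expect_identical(c1$sweeps, c2$sweeps)
  s1 <- generate_fictive_swim_trace(ground_truth(seed = 8))
  s2 <- generate_fictive_swim_trace(ground_truth(seed = 8))
  expect_identical(s1$current, s2$current)
  # and the generators do not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_step_response_sweeps(ground_truth(), 3))
  expect_identical(rnorm(1), before)
})

test_that("noisy step sweeps allow Rin and weighted-tau recovery within 5%", {
  truth <- ground_truth(rin_mohm = 500, noise_sd = 0.2, seed = 21)
  sw <- generate_step_response_sweeps(truth, n_sweeps = 5)
  expect_equal(input_resistance(sw), 500, tolerance = 0.05)
  avg <- rowMeans(sw$sweeps)
  off <- attr(sw, "step_window")[2]
  fit <- fit_double_exponential(sw$time[sw$time >= off], avg[sw$time >= off],
                                baseline = mean(avg[sw$time < 5]))
  expect_equal(fit$weighted_tau, true_weighted_tau(truth), tolerance = 0.05)
})

test_that("mixed PSP sweeps honour the programmed failure probability", {
  sw <- generate_mixed_psp_sweeps(ground_truth(p_fail = 0, seed = 2),
                                  n_sweeps = 30)
  expect_true(all(attr(sw, "chem_present")))
  expect_equal(classify_failures(sw)$failure_rate_pct, 0)
  # zero electrical amplitude reduces to pure chemical EPSPs
  pure <- generate_mixed_psp_sweeps(
    ground_truth(elec_amp_mV = 0, p_fail = 0, noise_sd = 0, seed = 2),
    n_sweeps = 10)
  pre <- pure$sweeps[pure$time < pure$spike_time, ]
  expect_true(all(abs(pre + 60) < 1e-12))
  expect_equal(unname(psp_amplitude(pure)[1]), 2, tolerance = 0.01)
  expect_error(generate_mixed_psp_sweeps(ground_truth(p_fail = 0.5,
                                                      noise_sd = -1)),
               "noise")
})

test_that("fictive swim bouts chirp downward and hit the programmed peaks", {
  truth <- ground_truth(seed = 6, noise_sd_pA = 0)
  tr <- generate_fictive_swim_trace(truth)
  expect_equal(nrow(tr$bouts), 5L)
  pk <- peak_swim_current(tr$time, tr$current, tr$bouts)
  expect_equal(pk$per_bout_pA, truth$swim_peaks_pA, tolerance = 1e-9)
  # cycle frequency decays within a bout: neighbouring trough intervals grow
  sel <- tr$time >= tr$bouts$start[1] & tr$time < tr$bouts$end[1]
  cur <- tr$current[sel]
  troughs <- which(diff(sign(diff(cur))) > 0) + 1L
  troughs <- troughs[cur[troughs] < -0.2 * max(-cur)]
  gaps <- diff(tr$time[sel][troughs])
  expect_gt(mean(tail(gaps, 3)), mean(head(gaps, 3)))
  # zero-amplitude bouts give zero peaks
  z <- generate_fictive_swim_trace(ground_truth(swim_peaks_pA = rep(0, 5),
                                                noise_sd_pA = 0, seed = 6))
  expect_equal(peak_swim_current(z$time, z$current, z$bouts)$per_bout_pA,
               rep(0, 5))
})

test_that("ground truth round-trips through its JSON sidecar", {
  truth <- ground_truth(rin_mohm = 321, p_fail = 0.4, seed = 77)
  f <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(truth, f)
  back <- read_ground_truth(f)
  expect_equal(back, truth)
})
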