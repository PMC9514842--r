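noiseless_steps <- function(n = 3, rin = 1000, current = -5) {
  generate_step_response_sweeps(
    ground_truth(rin_mohm = rin, noise_sd = 0, seed = 1),
    n_sweeps = n, current_pA = current)
}

test_that("input resistance is the averaged steady-state deflection over current", {
  # single-exponential kinetics settle fully within the 50 ms pulse
  sw <- generate_step_response_sweeps(
    ground_truth(rin_mohm = 1000, tau_b = 0, noise_sd = 0, seed = 1),
    n_sweeps = 3, current_pA = -5)
  expect_equal(input_resistance(sw), 1000, tolerance = 1e-6)
  expect_error(input_resistance(noiseless_steps(3), current_pA = 0), "nonzero")
})

test_that("fewer than three hyperpolarizing pulses are rejected", {
  sw <- noiseless_steps(3)
  sw$sweeps <- sw$sweeps[, 1:2]
  expect_error(input_resistance(sw), "at least three")
})

test_that("input resistance is recovered within 5% from noisy sweeps", {
  sw <- generate_step_response_sweeps(
    ground_truth(rin_mohm = 500, noise_sd = 0.2, seed = 3), n_sweeps = 5)
  expect_equal(input_resistance(sw), 500, tolerance = 0.05)
})

test_that("double-exponential fits recover programmed kinetics", {
  t <- seq(0, 40, 0.05)
  # worked weighted-tau case: 0.75 * 2 + 0.25 * 10 = 4 ms
  f <- fit_double_exponential(t, 3 * exp(-t / 2) + exp(-t / 10), baseline = 0)
  expect_equal(f$tau1, 2, tolerance = 0.01)
  expect_equal(f$tau2, 10, tolerance = 0.01)
  expect_equal(f$weighted_tau, 4, tolerance = 0.01)
  # noisy recovery
  set.seed(9)
  fn <- fit_double_exponential(t, 3 * exp(-t / 2) + exp(-t / 10) +
                                 rnorm(length(t), 0, 0.05), baseline = 0)
  expect_equal(fn$weighted_tau, 4, tolerance = 0.05)
  # equal weights average the two constants
  fe <- fit_double_exponential(t, 2 * exp(-t / 2) + 2 * exp(-t / 10),
                               baseline = 0)
  expect_equal(fe$weighted_tau, 6, tolerance = 0.01)
})

test_that("single-exponential data collapse to the b = 0 solution", {
  t <- seq(0, 30, 0.05)
  f <- fit_double_exponential(t, 4 * exp(-t / 3), baseline = 0)
  expect_equal(f$weighted_tau, 3, tolerance = 0.02)
  expect_equal(f$b, 0, tolerance = 0.02 * abs(f$a))
  expect_error(fit_double_exponential(1:10, rnorm(10)), "insufficient")
})

test_that("the weighted constant is a convex combination of the two constants", {
  set.seed(31)
  t <- seq(0, 50, 0.1)
  for (i in 1:5) {
    a <- runif(1, 0.5, 5); b <- runif(1, 0.5, 5)
    t1 <- runif(1, 1, 4); t2 <- t1 * runif(1, 2.5, 8)
    f <- fit_double_exponential(t, a * exp(-t / t1) + b * exp(-t / t2) +
                                  rnorm(length(t), 0, 0.02), baseline = 0)
    expect_lte(f$tau1, f$tau2)
    expect_gte(f$weighted_tau, f$tau1 - 1e-9)
    expect_lte(f$weighted_tau, f$tau2 + 1e-9)
  }
})

test_that("PSP amplitude subtracts the 2 ms pre-spike baseline and ignores offsets", {
  time <- seq(0, 30, 0.05)
  v <- -60 + 6 * psp_kernel_for_tests(time - 10)
  sw <- sweep_set(time, cbind(a = v, b = v + 1), spike_time = 10)
  amps <- psp_amplitude(sw)
  expect_equal(unname(amps["a"]), 6, tolerance = 1e-6)
  expect_equal(unname(amps["b"]), unname(amps["a"]), tolerance = 1e-9)
  short <- sweep_set(time[time > 9.5], cbind(v[time > 9.5]), spike_time = 10)
  expect_error(psp_amplitude(short), "baseline")
})

test_that("failure classification counts sweeps without a chemical component", {
  sw <- generate_mixed_psp_sweeps(ground_truth(p_fail = 0.25, seed = 7),
                                  n_sweeps = 100)
  cl <- classify_failures(sw)
  expect_identical(cl$is_failure, !attr(sw, "chem_present"))
  expect_equal(cl$failure_rate_pct, 100 * cl$n_failures / 100)

  none <- generate_mixed_psp_sweeps(ground_truth(p_fail = 0, seed = 2),
                                    n_sweeps = 50)
  expect_equal(classify_failures(none)$failure_rate_pct, 0)

  all_fail <- generate_mixed_psp_sweeps(ground_truth(p_fail = 1, seed = 2),
                                        n_sweeps = 20)
  expect_equal(classify_failures(all_fail)$failure_rate_pct, 100)

  expect_warning(classify_failures(
    generate_mixed_psp_sweeps(ground_truth(seed = 5), n_sweeps = 5)),
    "10-200")
})

test_that("template subtraction isolates the chemical component exactly", {
  sw <- generate_mixed_psp_sweeps(ground_truth(p_fail = 0.25, seed = 8),
                                  n_sweeps = 80)
  cl <- classify_failures(sw)
  iso <- isolate_chemical_component(sw, cl$is_failure)
  # re-adding the template reconstructs the original sweeps exactly
  expect_equal(iso$sweeps + attr(iso, "template"), sw$sweeps)
  # chemical amplitude on the averaged success is recovered within 5%
  avg <- sweep_set(iso$time,
                   rowMeans(iso$sweeps[, !cl$is_failure, drop = FALSE]),
                   spike_time = sw$spike_time)
  expect_equal(unname(psp_amplitude(avg)), 2, tolerance = 0.05)
  # all-failure input leaves only noise
  allf <- isolate_chemical_component(sw, rep(TRUE, 80))
  expect_lt(max(abs(rowMeans(allf$sweeps))), 0.1)
  expect_error(isolate_chemical_component(sw, rep(FALSE, 80)),
               "cannot isolate")
})

test_that("the decay fit between peak and 20% of peak returns the fast constant", {
  time <- seq(0, 40, 0.02)
  base <- -60
  pure <- base + ifelse(time > 10, 5 * exp(-(time - 10) / 3), 0)
  sw <- sweep_set(time, cbind(pure), spike_time = 10)
  expect_equal(as.numeric(psp_decay_tau(sw)), 3, tolerance = 0.05)

  mix <- base + ifelse(time > 10, 4 * exp(-(time - 10) / 2) +
                         1 * exp(-(time - 10) / 15), 0)
  swm <- sweep_set(time, cbind(mix), spike_time = 10)
  expect_equal(as.numeric(psp_decay_tau(swm)), 2, tolerance = 0.25)

  trunc <- sweep_set(time[time <= 11], cbind(pure[time <= 11]), spike_time = 10)
  expect_error(psp_decay_tau(trunc), "truncation")
})

test_that("ohmic current converts mV over MOhm into pA", {
  expect_equal(ohmic_current(5, 50), 100)
  expect_equal(ohmic_current(0, 200), 0)
  expect_equal(ohmic_current(2, 1000), 2)
  expect_error(ohmic_current(1, 0), "resistance")
  # linear in amplitude, inverse in resistance
  expect_equal(ohmic_current(10, 50), 2 * ohmic_current(5, 50))
  expect_equal(ohmic_current(5, 100), ohmic_current(5, 50) / 2)
})

test_that("percent of control sets the control to 100%", {
  expect_equal(percent_control(500, 750), 150)
  expect_equal(percent_control(123, 123), 100)
  expect_equal(percent_control(400, 300), 75)
  expect_error(percent_control(0, 10), "control")
})

test_that("swim peaks are per-bout inward deflections from baseline", {
  swm <- generate_fictive_swim_trace(ground_truth(seed = 3))
  pk <- peak_swim_current(swm$time, swm$current, swm$bouts)
  expect_equal(pk$per_bout_pA, c(100, 110, 120, 130, 140), tolerance = 0.05)
  expect_equal(pk$mean_pA, mean(pk$per_bout_pA))
  # a flat trace yields zero-magnitude peaks
  flat <- peak_swim_current(swm$time, rep(0, length(swm$time)), swm$bouts)
  expect_equal(flat$per_bout_pA, rep(0, 5))
  expect_warning(
    peak_swim_current(swm$time, swm$current, swm$bouts[1:3, ]),
    "five bouts")
  expect_error(peak_swim_current(swm$time, swm$current, swm$bouts[0, ]),
               "no bouts")
})
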