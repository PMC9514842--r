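test_that("sphere surface area follows pi * d^2 with um -> cm conversion", {
  expect_equal(surface_area(10), pi * (10e-4)^2)
  expect_equal(surface_area(10), 3.1416e-6, tolerance = 1e-4)
  expect_equal(surface_area(1), 3.1416e-8, tolerance = 1e-4)
  expect_error(surface_area(0), "invalid geometry")
  expect_error(surface_area(-3), "invalid geometry")
})

test_that("derived passive properties match the closed form", {
  p10 <- derive_passive(neuron_spec("m", "motor", 10))
  expect_equal(p10$capacitance_pF, 3.1416, tolerance = 1e-4)
  expect_equal(p10$conductance_nS, 0.9425, tolerance = 1e-4)
  expect_equal(p10$rin_mohm, 1061, tolerance = 1e-3)
  expect_equal(p10$tau_ms, 10 / 3, tolerance = 1e-12)

  # tau = c_m / g_leak is independent of diameter; R scales as 1/d^2
  p1 <- derive_passive(neuron_spec("m", "motor", 1))
  expect_equal(p1$tau_ms, p10$tau_ms)
  expect_equal(p1$rin_mohm / p10$rin_mohm, 100, tolerance = 1e-12)
})

test_that("parameter constructors enforce their invariants", {
  expect_error(membrane_params(c_m = 0), "c_m")
  expect_error(membrane_params(g_leak = -1), "g_leak")
  expect_error(spike_params(threshold = 20), "threshold")
  expect_error(spike_params(refractory = -1), "refractory")
  expect_error(neuron_spec("m", "motor", -2), "invalid geometry")
  expect_error(chem_synapse("a", "b", decay_tau = 0), "decay_tau")
  expect_error(elec_synapse("a", "b", -1), "conductance")
  expect_error(elec_synapse("a", "a", 1), "itself")
  expect_error(network_spec(list(neuron_spec("a", "motor", 5),
                                 neuron_spec("a", "motor", 6))), "duplicate")
  expect_error(
    network_spec(list(neuron_spec("a", "motor", 5)),
                 elec_synapses = list(elec_synapse("a", "zz", 1))),
    "unknown")
  expect_error(
    stimulus_protocol(data.frame(target = "a", onset = 5, duration = 10,
                                 amplitude = 1), duration = 12),
    "beyond")
})

test_that("an unstimulated neuron rests at the leak equilibrium potential", {
  net <- network_spec(list(neuron_spec("m", "motor", 10)))
  tr <- simulate_network(net, stimulus_protocol(duration = 100))
  expect_true(all(abs(tr$V[, "m"] + 60) < 1e-12))
  expect_equal(nrow(tr$spikes), 0L)
})

test_that("a subthreshold step deflects by I/G and the fitted tau is c_m/g_leak", {
  net <- network_spec(list(neuron_spec("m", "motor", 10)))
  prot <- stimulus_protocol(
    data.frame(target = "m", onset = 5, duration = 50, amplitude = -5),
    duration = 85)
  tr <- simulate_network(net, prot)
  ss <- mean(tr$V[tr$time >= 50 & tr$time < 55, "m"]) + 60
  expect_equal(ss, -5 / 0.9425, tolerance = 0.005) # = I * Rin = -5.305 mV

  # relaxation tau from the step is diameter-independent
  for (d in c(1, 4, 10)) {
    rp <- run_rin_protocol(network_spec(list(neuron_spec("m", "motor", d))), "m")
    expect_equal(rp$tau_ms, 10 / 3, tolerance = 0.02)
  }
})

test_that("a 10 pA 5 ms pulse evokes exactly one spike in an isolated chemical interneuron", {
  net <- network_spec(list(neuron_spec("c", "chem_interneuron", 5)))
  prot <- stimulus_protocol(
    data.frame(target = "c", onset = 10, duration = 5, amplitude = 10),
    duration = 40)
  tr <- simulate_network(net, prot)
  st <- spike_times(tr, "c")
  expect_length(st, 1L)
  expect_gte(st, 10)
  expect_lte(st, 15) # within the pulse
})

test_that("two coupled passive neurons settle on the 2x2 linear-circuit solution", {
  d <- c(10, 7)
  g <- matrix(c(0, 10, 10, 0), 2)
  net <- passive_network(d, g)
  tr <- simulate_network(net, hold_protocol(c("n01", "n02"), c(-5, 0)))
  vss <- tr$V[nrow(tr$V), ]
  oracle <- solve_passive_steady_state(d, g, c(-5, 0))
  expect_equal(unname(vss), oracle, tolerance = 1e-6)
})

test_that("random passive coupled networks match the conductance-matrix solve", {
  set.seed(421)
  for (rep in 1:3) {
    n <- sample(5:12, 1)
    d <- runif(n, 1, 10)
    g <- matrix(0, n, n)
    pairs <- which(upper.tri(g), arr.ind = TRUE)
    on <- pairs[sample(nrow(pairs), max(3, n)), , drop = FALSE]
    g[on] <- runif(nrow(on), 0.01, 2)
    g <- g + t(g)
    I <- numeric(n); I[sample(n, 2)] <- runif(2, -10, 10)
    net <- passive_network(d, g)
    ids <- sprintf("n%02d", seq_len(n))
    tr <- simulate_network(net, hold_protocol(ids, I))
    vss <- unname(tr$V[nrow(tr$V), ])
    oracle <- solve_passive_steady_state(d, g, I)
    expect_equal(vss, oracle, tolerance = 1e-3)
  }
})

test_that("gap-junction currents are antisymmetric along every trace", {
  net <- passive_network(c(10, 3), matrix(c(0, 5, 5, 0), 2))
  tr <- simulate_network(net, hold_protocol(c("n01", "n02"), c(-5, 0),
                                            duration = 20))
  i_ab <- 5 * (tr$V[, "n02"] - tr$V[, "n01"]) # current into n01
  i_ba <- 5 * (tr$V[, "n01"] - tr$V[, "n02"])
  expect_equal(i_ab, -i_ba)
  expect_gt(max(abs(i_ab)), 0)
})

test_that("halving the integration step leaves steady-state voltages unchanged to 0.1%", {
  d <- c(10, 7, 2)
  g <- matrix(0, 3, 3); g[1, 2] <- g[2, 1] <- 10; g[2, 3] <- g[3, 2] <- 0.5
  net <- passive_network(d, g)
  ids <- sprintf("n%02d", 1:3)
  v1 <- simulate_network(net, hold_protocol(ids, c(-5, 0, 0), dt = 0.01))
  v2 <- simulate_network(net, hold_protocol(ids, c(-5, 0, 0), dt = 0.005))
  s1 <- v1$V[nrow(v1$V), ]; s2 <- v2$V[nrow(v2$V), ]
  expect_true(all(abs(s2 - s1) / abs(s1) < 1e-3))
})

test_that("with electrical coupling only, voltages relax monotonically to the leak potential", {
  # start away from equilibrium: resting potential above E_leak
  net <- passive_network(c(5, 8), matrix(c(0, 2, 2, 0), 2),
                         E_leak = -60, V_rest = -50)
  tr <- simulate_network(net, stimulus_protocol(duration = 40))
  for (id in c("n01", "n02")) {
    v <- tr$V[, id]
    expect_true(all(diff(v) <= 1e-12))
    expect_equal(unname(v[length(v)]), -60, tolerance = 1e-3)
  }
})

test_that("unknown protocol targets and unstable steps raise informative errors", {
  net <- network_spec(list(neuron_spec("m", "motor", 10)))
  expect_error(
    simulate_network(net, stimulus_protocol(
      data.frame(target = "ghost", onset = 0, duration = 1, amplitude = 1),
      duration = 10)),
    "unknown neuron id")
})

test_that("network configs round-trip through YAML and JSON", {
  net <- build_size_network(1, "dedicated")
  for (ext in c("yml", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_network_config(net, f)
    back <- read_network_config(f)
    expect_equal(length(back$neurons), length(net$neurons))
    expect_equal(network_summary(back), network_summary(net))
    expect_identical(back$chem_wiring, "dedicated")
  }
})

test_that("simulation traces export to CSV with time and per-neuron columns", {
  net <- network_spec(list(neuron_spec("c", "chem_interneuron", 5)))
  tr <- simulate_network(net, stimulus_protocol(
    data.frame(target = "c", onset = 2, duration = 5, amplitude = 10),
    duration = 20))
  f <- withr::local_tempfile(fileext = ".csv")
  fs <- withr::local_tempfile(fileext = ".csv")
  write_sim_trace(tr, f, spikes_file = fs)
  df <- read.csv(f, check.names = FALSE)
  expect_identical(names(df), c("time_ms", "c"))
  expect_equal(df$c, unname(tr$V[, "c"]))
  expect_equal(read.csv(fs)$time_ms, tr$spikes$time_ms)
})
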