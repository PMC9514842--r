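# Shared fixtures: small networks and an independent linear-circuit oracle.

# passive network with given diameters and an electrical coupling matrix
passive_network <- function(diameters, gmat = NULL, E_leak = -60, V_rest = -60) {
  ids <- sprintf("n%02d", seq_along(diameters))
  neurons <- lapply(seq_along(diameters), function(i)
    neuron_spec(ids[i], "motor", diameters[i],
                membrane = membrane_params(E_leak = E_leak, V_rest = V_rest),
                spiking = NULL))
  esyn <- list()
  if (!is.null(gmat)) {
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (j > i && gmat[i, j] > 0)
        esyn[[length(esyn) + 1L]] <- elec_synapse(ids[i], ids[j], gmat[i, j])
    }
  }
  network_spec(neurons, elec_synapses = esyn)
}

# independent oracle: steady-state voltages of a passive coupled network
# under constant injections, from the conductance-matrix linear system
#   (diag(gL_i + sum_j g_ij) - G) V = gL * E_L + I
solve_passive_steady_state <- function(diameters, gmat, I_pA, E_leak = -60) {
  gl <- 0.3 * pi * (diameters * 1e-4)^2 * 1e6 # nS
  A <- -gmat
  diag(A) <- gl + rowSums(gmat)
  as.vector(solve(A, gl * E_leak + I_pA))
}

# constant-injection protocol long enough to settle
hold_protocol <- function(ids, I_pA, duration = 80, dt = 0.01) {
  keep <- I_pA != 0
  stimulus_protocol(
    data.frame(target = ids[keep], onset = 0, duration = duration,
               amplitude = I_pA[keep]),
    duration = duration, dt = dt)
}

# unit-peak PSP-like waveform built independently of the package generator
psp_kernel_for_tests <- function(t, rise = 0.5, decay = 3) {
  w <- ifelse(t > 0, exp(-t / decay) - exp(-t / rise), 0)
  w / max(w)
}
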