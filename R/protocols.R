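# Virtual current-clamp experiments on built networks: hyperpolarizing
# steps for Rin and tau, single-spike PSPs, dedicated-input coupling maps,
# and the diameter x convergence sweep.

#' Input resistance and time constant from a hyperpolarizing step
#'
#' Injects a hyperpolarizing current pulse (default -5 pA for 50 ms) into
#' `target`, reads the input resistance as the steady-state deflection over
#' the injected current (steady state = mean of the last 5 ms of the
#' pulse, i.e. >= 14 membrane time constants into it), and fits the
#' relaxation after pulse offset with a double exponential to obtain the
#' weighted membrane time constant.
#'
#' @param network A [network_spec()].
#' @param target Neuron id receiving the pulse.
#' @param dt Integration step, ms.
#' @param pulse_pA Pulse amplitude, pA (negative = hyperpolarizing).
#' @param pulse_ms Pulse duration, ms.
#' @param baseline_ms Pre-pulse baseline, ms.
#' @param tail_ms Post-pulse relaxation recorded for the tau fit, ms.
#' @return List with `rin_mohm`, `tau_ms`, `fit` (the [fit_double_exponential()]
#'   result) and `trace` (the `sim_trace`).
#' @export
run_rin_protocol <- function(network, target, dt = 0.01, pulse_pA = -5,
                             pulse_ms = 50, baseline_ms = 5, tail_ms = 30) {
  stopifnot(inherits(network, "network_spec"))
  prot <- stimulus_protocol(
    data.frame(target = target, onset = baseline_ms, duration = pulse_ms,
               amplitude = pulse_pA),
    duration = baseline_ms + pulse_ms + tail_ms, dt = dt)
  tr <- simulate_network(network, prot)
  if (length(spike_times(tr, target)))
    stop("protocol violation: target ", target,
         " spiked during the hyperpolarizing step")
  t <- tr$time
  v <- tr$V[, target]
  off <- baseline_ms + pulse_ms
  base <- mean(v[t < baseline_ms])
  ss <- mean(v[t >= off - 5 & t < off])
  rin <- (ss - base) / pulse_pA * 1000 # mV/pA = GOhm -> MOhm
  seg <- t >= off & t <= off + tail_ms
  fit <- fit_double_exponential(t[seg], v[seg], baseline = base)
  list(rin_mohm = rin, tau_ms = fit$weighted_tau, fit = fit, trace = tr)
}

#' Single-spike PSP protocol
#'
#' Drives exactly one spike in the presynaptic interneuron with the
#' standard pulse (5 ms; 10 pA for chemical, 30 pA for electrical
#' interneurons) and returns the aligned postsynaptic membrane-potential
#' sweeps of all motor neurons as a [sweep_set()] annotated with the
#' presynaptic spike time. A single spike per run is enforced: zero or
#' multiple presynaptic spikes raise a protocol-violation error reporting
#' the count.
#'
#' @param network A [network_spec()].
#' @param pre Id of the presynaptic interneuron.
#' @param dt Integration step, ms.
#' @param pulse_pA Pulse amplitude, pA; default by presynaptic role.
#' @param pulse_ms Pulse duration, ms.
#' @param baseline_ms Pre-pulse baseline, ms.
#' @param post_ms Recording window after the pulse, ms.
#' @param record Ids to record; default all motor neurons.
#' @return A [sweep_set()], one column per recorded neuron.
#' @export
run_psp_protocol <- function(network, pre, dt = 0.01, pulse_pA = NULL,
                             pulse_ms = 5, baseline_ms = 10, post_ms = 25,
                             record = NULL) {
  stopifnot(inherits(network, "network_spec"))
  ids <- vapply(network$neurons, function(x) x$id, character(1))
  ip <- match(pre, ids)
  if (is.na(ip)) stop("unknown presynaptic neuron: ", pre)
  role <- network$neurons[[ip]]$role
  if (role == "motor")
    stop("presynaptic neuron must be an interneuron, got role 'motor'")
  if (is.null(pulse_pA))
    pulse_pA <- if (role == "chem_interneuron") 10 else 30
  prot <- stimulus_protocol(
    data.frame(target = pre, onset = baseline_ms, duration = pulse_ms,
               amplitude = pulse_pA),
    duration = baseline_ms + pulse_ms + post_ms, dt = dt)
  tr <- simulate_network(network, prot)
  st <- spike_times(tr, pre)
  if (length(st) != 1L)
    stop("protocol violation: expected exactly one presynaptic spike, got ",
         length(st))
  if (is.null(record))
    record <- ids[vapply(network$neurons, function(x) x$role, character(1)) == "motor"]
  sweep_set(tr$time, tr$V[, record, drop = FALSE], spike_time = st)
}

#' Coupling map under dedicated chemical wiring
#'
#' At full electrical convergence with dedicated chemical inputs, spikes
#' each motor neuron's own chemical interneuron in turn and records the
#' direct chemical PSP in the target (diagonal) and the coupling potentials
#' spreading into every other motor neuron through shared gap-junction
#' afferents (off-diagonal). The network itself is the low-pass filter: the
#' reported amplitude is the raw peak of the coupling potential, which is
#' both strongly attenuated and slower to peak than the direct PSP.
#'
#' @param network A dedicated-wiring [network_spec()] at duplication 10
#'   (from `build_size_network(10, "dedicated")`).
#' @param dt Integration step, ms.
#' @return List of two 10 x 10 matrices (rows = input/target motor neuron,
#'   columns = recorded motor neuron): `amplitude_mV` and
#'   `time_to_peak_ms`.
#' @export
run_coupling_map <- function(network, dt = 0.01) {
  stopifnot(inherits(network, "network_spec"))
  if (!identical(network$chem_wiring, "dedicated"))
    stop("coupling map requires dedicated chemical wiring")
  if (!identical(as.integer(network$duplication), 10L))
    stop("coupling map is defined at full convergence (duplication 10)")
  mn_ids <- vapply(Filter(function(x) x$role == "motor", network$neurons),
                   function(x) x$id, character(1))
  amp <- tp <- matrix(NA_real_, length(mn_ids), length(mn_ids),
                      dimnames = list(input = mn_ids, recorded = mn_ids))
  for (i in seq_along(mn_ids)) {
    pre <- vapply(Filter(function(s) s$post == mn_ids[i], network$chem_synapses),
                  function(s) s$pre, character(1))
    sw <- run_psp_protocol(network, pre[1], dt = dt)
    amp[i, ] <- psp_amplitude(sw)[mn_ids]
    tp[i, ] <- psp_time_to_peak(sw)[mn_ids]
  }
  list(amplitude_mV = amp, time_to_peak_ms = tp)
}

#' Diameter x convergence sweep
#'
#' Crosses the 10 motor neuron diameters with the requested duplication
#' levels. For every level a shared-wiring size network is built; each
#' motor neuron's Rin and weighted tau come from [run_rin_protocol()], and
#' one single-spike run of the shared chemical interneuron yields every
#' chemical PSP amplitude and decay constant.
#'
#' @param duplications Integer vector of duplication levels (0..10).
#' @param dt Integration step, ms.
#' @return Data frame with one row per diameter x level: `diameter_um`,
#'   `duplication`, `rin_mohm`, `tau_ms`, `cepsp_mV`, `cepsp_decay_ms`.
#' @export
run_convergence_sweep <- function(duplications = c(0, 1, 5, 10), dt = 0.01) {
  rows <- list()
  for (lvl in duplications) {
    net <- build_size_network(lvl, "shared")
    sw <- run_psp_protocol(net, "chem01", dt = dt)
    amps <- psp_amplitude(sw)
    for (d in 1:10) {
      id <- mn_id(d)
      rp <- run_rin_protocol(net, id, dt = dt)
      dec <- psp_decay_tau(sw, which = id)
      rows[[length(rows) + 1L]] <- data.frame(
        diameter_um = d, duplication = lvl,
        rin_mohm = rp$rin_mohm, tau_ms = rp$tau_ms,
        cepsp_mV = unname(amps[id]), cepsp_decay_ms = as.numeric(dec))
    }
  }
  do.call(rbind, rows)
}
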