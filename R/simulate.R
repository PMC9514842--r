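# Fixed-step exponential-Euler integrator for the coupled soma network.
#
# Per neuron i the subthreshold dynamics are
#   C_i dV_i/dt = -g_L,i (V_i - E_L)
#                 - g_chem,i(t) (V_i - E_chem)
#                 - g_AHP,i(t) (V_i - E_AHP)
#                 - sum_j g_e,ij (V_i - V_j)
#                 + I_inj,i(t)
# Each step collects every conductance into g_tot and its weighted reversal
# into a numerator, then relaxes V exactly toward V_inf = num/g_tot over dt.
# Neighbour voltages enter explicitly, so the steady state of the scheme is
# the exact solution of the conductance-matrix linear system (the update is
# a Jacobi iteration on it, convergent because g_tot,i >= sum_j g_e,ij).
# Strong gap-junction coupling makes the system stiff; the exponential
# update stays stable where forward Euler would not.

#' Simulate a network under a stimulus protocol
#'
#' Integrates the coupled membrane-potential dynamics of all somata in
#' `network` with a fixed-step exponential-Euler scheme, applying the square
#' current pulses in `protocol`. Spiking neurons fire a stylized
#' integrate-and-fire spike when the membrane potential crosses the
#' (accommodating) threshold outside the refractory period: the voltage is
#' forced along a triangular waveform to the spike peak and back, the AHP
#' conductance increments and decays exponentially, and every outgoing
#' chemical synapse increments its conductance by `g_norm` scaled by the
#' postsynaptic surface area, decaying with its own time constant. Gap
#' junctions are non-rectifying: the coupling current into one neuron is the
#' exact negative of the current into its partner at every step.
#'
#' @param network A [network_spec()].
#' @param protocol A [stimulus_protocol()].
#' @return A `sim_trace`: list with `time` (ms grid), `V` (matrix, one
#'   column per neuron id, mV), `spikes` (data frame `id`, `time_ms`), and
#'   `dt` (ms).
#' @examples
#' mn <- neuron_spec("mn10", "motor", 10)
#' net <- network_spec(list(mn))
#' prot <- stimulus_protocol(
#'   data.frame(target = "mn10", onset = 5, duration = 50, amplitude = -5),
#'   duration = 85)
#' tr <- simulate_network(net, prot)
#' @export
simulate_network <- function(network, protocol) {
  stopifnot(inherits(network, "network_spec"),
            inherits(protocol, "stimulus_protocol"))
  neurons <- network$neurons
  n <- length(neurons)
  ids <- vapply(neurons, function(x) x$id, character(1))
  dt <- protocol$dt
  nsteps <- as.integer(round(protocol$duration / dt))
  time <- seq(0, by = dt, length.out = nsteps + 1L)

  if (nrow(protocol$pulses)) {
    bad <- setdiff(protocol$pulses$target, ids)
    if (length(bad)) stop("protocol targets unknown neuron id(s): ",
                          paste(bad, collapse = ", "))
  }

  # absolute passive properties (pF, nS)
  A    <- vapply(neurons, function(x) surface_area(x$diameter), numeric(1))
  Cm   <- vapply(neurons, function(x) x$membrane$c_m, numeric(1)) * A * 1e6
  gL   <- vapply(neurons, function(x) x$membrane$g_leak, numeric(1)) * A * 1e6
  EL   <- vapply(neurons, function(x) x$membrane$E_leak, numeric(1))
  Vrest <- vapply(neurons, function(x) x$membrane$V_rest, numeric(1))

  # electrical coupling matrix (nS), symmetric, zero diagonal
  has_elec <- length(network$elec_synapses) > 0L
  ge_row <- numeric(n)
  if (has_elec) {
    Ge <- matrix(0, n, n)
    for (s in network$elec_synapses) {
      ia <- match(s$a, ids); ib <- match(s$b, ids)
      Ge[ia, ib] <- Ge[ia, ib] + s$g
      Ge[ib, ia] <- Ge[ib, ia] + s$g
    }
    ge_row <- rowSums(Ge)
  }

  # chemical synapses grouped by (post, decay_tau, E_rev) so that the state
  # is one decaying conductance per group; per-spike increments are
  # g_norm * A_post in nS
  nsyn <- length(network$chem_synapses)
  has_chem <- nsyn > 0L
  if (has_chem) {
    post_i <- vapply(network$chem_synapses, function(s) match(s$post, ids), integer(1))
    pre_i  <- vapply(network$chem_synapses, function(s) match(s$pre, ids), integer(1))
    dtau   <- vapply(network$chem_synapses, function(s) s$decay_tau, numeric(1))
    Erev   <- vapply(network$chem_synapses, function(s) s$E_rev, numeric(1))
    ginc   <- vapply(network$chem_synapses, function(s) s$g_norm, numeric(1)) *
      A[post_i] * 1e6
    key <- paste(post_i, dtau, Erev)
    grp <- match(key, unique(key))
    ngrp <- max(grp)
    grp_post <- post_i[!duplicated(grp)]
    grp_dec  <- exp(-dt / dtau[!duplicated(grp)])
    grp_E    <- Erev[!duplicated(grp)]
    Cagg <- matrix(0, n, ngrp)
    Cagg[cbind(grp_post, seq_len(ngrp))] <- 1
    # outgoing increments per presynaptic neuron: group index + amount
    out_syn <- lapply(seq_len(n), function(i) {
      sel <- pre_i == i
      list(grp = grp[sel], inc = ginc[sel])
    })
    g_grp <- numeric(ngrp)
  }
  chem_active <- FALSE

  # spiking machinery
  spk <- lapply(neurons, function(x) x$spiking)
  spiking_mask <- !vapply(spk, is.null, logical(1))
  any_spiking <- any(spiking_mask)
  theta0 <- racc <- accfac <- ahp_dec <- ahp_gabs <- ahp_E <- numeric(n)
  theta <- rep(Inf, n)
  refract <- spk_peak <- spk_dur <- numeric(n)
  if (any_spiking) {
    for (i in which(spiking_mask)) {
      p <- spk[[i]]
      theta0[i] <- p$threshold; theta[i] <- p$threshold
      racc[i] <- p$rel_accommodation
      accfac[i] <- exp(-dt / p$accommodation_tau)
      ahp_dec[i] <- exp(-dt / p$ahp_tau)
      ahp_gabs[i] <- p$ahp_g * A[i] * 1e6
      ahp_E[i] <- p$ahp_E
      refract[i] <- p$refractory
      spk_peak[i] <- p$spike_peak
      spk_dur[i] <- p$spike_duration
    }
  }
  g_ahp <- numeric(n)
  ahp_active <- FALSE

  # injected current per neuron per step (pA); pulse active on [onset, onset+dur)
  Imat <- matrix(0, n, nsteps)
  if (nrow(protocol$pulses)) {
    tmid <- time[seq_len(nsteps)]
    for (r in seq_len(nrow(protocol$pulses))) {
      p <- protocol$pulses[r, ]
      i <- match(p$target, ids)
      on <- tmid >= p$onset - 1e-9 & tmid < p$onset + p$duration - 1e-9
      Imat[i, on] <- Imat[i, on] + p$amplitude
    }
  }
  any_inj <- any(Imat != 0)

  g_base <- gL + ge_row
  num_base <- gL * EL
  efac_base <- exp(-dt * g_base / Cm)

  V <- Vrest
  Vout <- matrix(NA_real_, nsteps + 1L, n, dimnames = list(NULL, ids))
  Vout[1L, ] <- V
  spike_id <- character(0); spike_t <- numeric(0)
  next_allowed <- rep(-Inf, n)
  forced_end <- rep(-1L, n)     # last step index of an active forced waveform
  forced_start <- rep(0L, n)
  waveforms <- vector("list", n)
  forced_any <- FALSE

  for (k in seq_len(nsteps)) {
    if (has_chem && chem_active) {
      g_grp <- g_grp * grp_dec
      gchem <- Cagg %*% g_grp
      numchem <- Cagg %*% (g_grp * grp_E)
    }
    if (ahp_active) g_ahp <- g_ahp * ahp_dec

    num <- num_base
    if (has_elec) num <- num + Ge %*% V
    if (any_inj) num <- num + Imat[, k]

    if ((has_chem && chem_active) || ahp_active) {
      gtot <- g_base
      if (has_chem && chem_active) { gtot <- gtot + gchem; num <- num + numchem }
      if (ahp_active) { gtot <- gtot + g_ahp; num <- num + g_ahp * ahp_E }
      Vinf <- num / gtot
      Vnew <- Vinf + (V - Vinf) * exp(-dt * gtot / Cm)
    } else {
      Vinf <- num / g_base
      Vnew <- Vinf + (V - Vinf) * efac_base
    }
    Vnew <- as.vector(Vnew)

    t_now <- k * dt

    if (any_spiking) {
      # accommodation raises the threshold under depolarization only
      tgt <- theta0 + racc * pmax(V - Vrest, 0)
      theta <- tgt + (theta - tgt) * accfac
      theta[!spiking_mask] <- Inf

      if (forced_any) {
        act <- which(forced_end >= 0L)
        for (i in act) {
          j <- k - forced_start[i]
          if (k <= forced_end[i]) {
            Vnew[i] <- waveforms[[i]][j + 1L]
          } else {
            forced_end[i] <- -1L
          }
        }
        forced_any <- any(forced_end >= 0L)
      }

      crossed <- which(spiking_mask & Vnew >= theta & t_now >= next_allowed &
                         forced_end < 0L)
      for (i in crossed) {
        spike_id <- c(spike_id, ids[i]); spike_t <- c(spike_t, t_now)
        next_allowed[i] <- t_now + refract[i]
        nf <- max(2L, as.integer(round(spk_dur[i] / dt)))
        half <- nf %/% 2L
        vd <- Vnew[i]
        up <- vd + (spk_peak[i] - vd) * seq_len(half) / half
        # downstroke ends at rest; the AHP conductance shapes the undershoot
        down <- spk_peak[i] - (spk_peak[i] - Vrest[i]) * seq_len(nf - half) / (nf - half)
        waveforms[[i]] <- c(vd, up, down)
        forced_start[i] <- k
        forced_end[i] <- k + nf
        forced_any <- TRUE
        # spike-triggered threshold accommodation: theta jumps by a fraction
        # of the spike height and relaxes back with accommodation_tau
        theta[i] <- theta[i] + racc[i] * (spk_peak[i] - theta0[i])
        g_ahp[i] <- g_ahp[i] + ahp_gabs[i]
        ahp_active <- TRUE
        if (has_chem && length(out_syn[[i]]$grp)) {
          g_grp[out_syn[[i]]$grp] <- g_grp[out_syn[[i]]$grp] + out_syn[[i]]$inc
          chem_active <- TRUE
        }
      }
    }

    V <- Vnew
    Vout[k + 1L, ] <- V
    if (k %% 500L == 0L && !all(is.finite(V)))
      stop("integration failure: non-finite membrane potential at t = ",
           t_now, " ms with step dt = ", dt,
           " ms; reduce the integration step")
  }
  if (!all(is.finite(V)))
    stop("integration failure: non-finite membrane potential with step dt = ",
         dt, " ms; reduce the integration step")

  structure(list(time = time, V = Vout,
                 spikes = data.frame(id = spike_id, time_ms = spike_t,
                                     stringsAsFactors = FALSE),
                 dt = dt),
            class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  cat("<sim_trace> ", ncol(x$V), " neurons, ",
      length(x$time), " samples (", max(x$time), " ms at dt = ", x$dt,
      " ms), ", nrow(x$spikes), " spikes\n", sep = "")
  invisible(x)
}

#' Spike times of one neuron in a trace
#'
#' @param trace A `sim_trace`.
#' @param id Neuron id.
#' @return Numeric vector of spike times, ms.
#' @export
spike_times <- function(trace, id) {
  stopifnot(inherits(trace, "sim_trace"))
  trace$spikes$time_ms[trace$spikes$id == id]
}
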