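#' @keywords internal
"_PACKAGE"

# Internal unit system: mV, ms, pA, nS, pF (1 pA into 1 pF = 1 mV/ms;
# 1 nS * 1 mV = 1 pA). Per-area parameters (uF/cm2, mS/cm2) are converted
# to absolute values once, at construction, using the sphere surface area.

#' Passive membrane parameters
#'
#' Specific (per-area) passive properties of a spherical soma. Defaults are
#' the standard passive set used throughout the simulated networks:
#' capacitance 1 uF/cm2, leak conductance 0.3 mS/cm2, leak equilibrium and
#' resting potential -60 mV.
#'
#' @param c_m Specific membrane capacitance, uF/cm2. Must be > 0.
#' @param g_leak Specific leak conductance, mS/cm2. Must be > 0.
#' @param E_leak Leak equilibrium potential, mV.
#' @param V_rest Resting potential, mV.
#' @return An object of class `membrane_params`.
#' @examples
#' membrane_params()
#' @export
membrane_params <- function(c_m = 1, g_leak = 0.3, E_leak = -60, V_rest = -60) {
  if (!is.numeric(c_m) || c_m <= 0) stop("c_m must be > 0")
  if (!is.numeric(g_leak) || g_leak <= 0) stop("g_leak must be > 0")
  structure(list(c_m = c_m, g_leak = g_leak, E_leak = E_leak, V_rest = V_rest),
            class = "membrane_params")
}

#' Integrate-and-fire spiking parameters
#'
#' Threshold-and-waveform parameters for the stylized integrate-and-fire
#' spike. The spike itself is a forced triangular waveform (linear rise to
#' `spike_peak`, linear downstroke to the resting potential) of duration
#' `spike_duration`; the undershoot and after-potential are then shaped by
#' the after-hyperpolarization (AHP) conductance. While forced, the
#' membrane potential drives electrical-coupling currents into neighbours,
#' which is what produces gap-junction spikelets postsynaptically.
#'
#' The threshold accommodates: theta relaxes with time constant
#' `accommodation_tau` toward `threshold + rel_accommodation * (V - V_rest)`.
#' `spike_strength` is retained for completeness; each presynaptic spike
#' triggers exactly one unit conductance increment at its chemical synapses.
#'
#' @param threshold Spike threshold, mV.
#' @param spike_peak Peak of the forced spike waveform, mV.
#' @param spike_strength Dimensionless; see Details.
#' @param rel_accommodation Relative threshold accommodation (dimensionless).
#' @param accommodation_tau Accommodation time constant, ms.
#' @param ahp_g Specific AHP conductance increment per spike, mS/cm2.
#' @param ahp_tau AHP decay time constant, ms.
#' @param ahp_E AHP equilibrium potential, mV.
#' @param refractory Absolute refractory period, ms.
#' @param spike_duration Duration of the forced spike waveform, ms.
#' @return An object of class `spike_params`.
#' @export
spike_params <- function(threshold = -40, spike_peak = 10, spike_strength = 10,
                         rel_accommodation = 0.3, accommodation_tau = 10,
                         ahp_g = 0.4, ahp_tau = 3, ahp_E = -70,
                         refractory = 2, spike_duration = 1) {
  if (threshold >= spike_peak) stop("threshold must be below spike_peak")
  if (refractory < 0) stop("refractory must be >= 0")
  if (ahp_g < 0 || ahp_tau <= 0) stop("AHP conductance must be >= 0 and tau > 0")
  if (spike_duration <= 0) stop("spike_duration must be > 0")
  structure(list(threshold = threshold, spike_peak = spike_peak,
                 spike_strength = spike_strength,
                 rel_accommodation = rel_accommodation,
                 accommodation_tau = accommodation_tau,
                 ahp_g = ahp_g, ahp_tau = ahp_tau, ahp_E = ahp_E,
                 refractory = refractory, spike_duration = spike_duration),
            class = "spike_params")
}

#' Neuron specification
#'
#' A spherical soma with a role, diameter, passive membrane parameters and
#' (optionally) integrate-and-fire spiking machinery. Pass `spiking = NULL`
#' for a purely passive neuron.
#'
#' @param id Unique character label.
#' @param role One of `"motor"`, `"chem_interneuron"`, `"elec_interneuron"`.
#' @param diameter Soma diameter, um. Must be > 0.
#' @param membrane A [membrane_params()] object.
#' @param spiking A [spike_params()] object, or `NULL` for a passive soma.
#' @return An object of class `neuron_spec`.
#' @examples
#' neuron_spec("mn10", "motor", diameter = 10)
#' @export
neuron_spec <- function(id, role = c("motor", "chem_interneuron", "elec_interneuron"),
                        diameter, membrane = membrane_params(),
                        spiking = spike_params()) {
  role <- match.arg(role)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("id must be a non-empty string")
  if (!is.numeric(diameter) || diameter <= 0)
    stop("invalid geometry: diameter must be > 0, got ", diameter)
  stopifnot(inherits(membrane, "membrane_params"))
  if (!is.null(spiking)) stopifnot(inherits(spiking, "spike_params"))
  structure(list(id = id, role = role, diameter = diameter,
                 membrane = membrane, spiking = spiking),
            class = "neuron_spec")
}

#' Chemical synapse specification
#'
#' A chemical synapse with a normalized specific conductance that is scaled
#' internally by the surface area of the postsynaptic soma, an excitatory
#' reversal potential, and single-exponential decay kinetics.
#'
#' @param pre,post Neuron ids.
#' @param g_norm Specific conductance, mS/cm2 (default 0.25), scaled by the
#'   postsynaptic surface area at simulation time.
#' @param E_rev Reversal potential, mV (default 0).
#' @param decay_tau Conductance decay time constant, ms (default 1).
#' @return An object of class `chem_synapse`.
#' @export
chem_synapse <- function(pre, post, g_norm = 0.25, E_rev = 0, decay_tau = 1) {
  if (g_norm < 0) stop("g_norm must be >= 0")
  if (decay_tau <= 0) stop("decay_tau must be > 0")
  structure(list(pre = pre, post = post, g_norm = g_norm, E_rev = E_rev,
                 decay_tau = decay_tau), class = "chem_synapse")
}

#' Electrical synapse (gap junction) specification
#'
#' A non-rectifying ohmic coupling conductance, defined as an absolute value
#' in nS: current flows between the two somata whenever their membrane
#' potentials differ, and the current into `a` equals minus the current into
#' `b` at every instant.
#'
#' @param a,b Neuron ids of the two coupled somata.
#' @param g Coupling conductance, nS. Must be >= 0.
#' @return An object of class `elec_synapse`.
#' @export
elec_synapse <- function(a, b, g) {
  if (!is.numeric(g) || g < 0) stop("electrical conductance must be >= 0")
  if (identical(a, b)) stop("an electrical synapse cannot couple a neuron to itself")
  structure(list(a = a, b = b, g = g), class = "elec_synapse")
}

#' Network specification
#'
#' @param neurons List of [neuron_spec()] objects with unique ids.
#' @param chem_synapses List of [chem_synapse()] objects.
#' @param elec_synapses List of [elec_synapse()] objects.
#' @param duplication Optional integer tag recording the convergence level
#'   the network was built at (see [build_size_network()]).
#' @param chem_wiring Optional tag, `"shared"` or `"dedicated"`.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(neurons, chem_synapses = list(), elec_synapses = list(),
                         duplication = NA_integer_, chem_wiring = NA_character_) {
  ids <- vapply(neurons, function(n) n$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate neuron ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  refs <- c(vapply(chem_synapses, function(s) c(s$pre, s$post), character(2)),
            vapply(elec_synapses, function(s) c(s$a, s$b), character(2)))
  bad <- setdiff(unique(refs), ids)
  if (length(bad)) stop("synapses reference unknown neuron ids: ",
                        paste(bad, collapse = ", "))
  structure(list(neurons = neurons, chem_synapses = chem_synapses,
                 elec_synapses = elec_synapses, duplication = duplication,
                 chem_wiring = chem_wiring), class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  roles <- table(vapply(x$neurons, function(n) n$role, character(1)))
  cat("<network_spec> ", length(x$neurons), " neurons (",
      paste(names(roles), roles, sep = ": ", collapse = ", "), "); ",
      length(x$chem_synapses), " chemical, ",
      length(x$elec_synapses), " electrical synapses", sep = "")
  if (!is.na(x$duplication)) cat("; duplication ", x$duplication, sep = "")
  if (!is.na(x$chem_wiring)) cat(" (", x$chem_wiring, " chemical wiring)", sep = "")
  cat("\n")
  invisible(x)
}

#' Stimulus protocol
#'
#' A set of square current pulses delivered to named neurons, plus the total
#' simulated duration and the recording sample step.
#'
#' @param pulses A data frame with columns `target` (neuron id), `onset` (ms),
#'   `duration` (ms), `amplitude` (pA). May have zero rows.
#' @param duration Total simulated duration, ms.
#' @param dt Integration/sampling step, ms (default 0.01).
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(pulses = data.frame(target = character(),
                                                  onset = numeric(),
                                                  duration = numeric(),
                                                  amplitude = numeric()),
                              duration, dt = 0.01) {
  stopifnot(is.data.frame(pulses),
            all(c("target", "onset", "duration", "amplitude") %in% names(pulses)))
  if (dt <= 0) stop("sample step must be > 0")
  if (duration <= 0) stop("duration must be > 0")
  if (nrow(pulses) && any(pulses$onset + pulses$duration > duration + 1e-9))
    stop("pulse extends beyond protocol duration")
  if (nrow(pulses) && any(pulses$onset < 0)) stop("pulse onset must be >= 0")
  structure(list(pulses = pulses, duration = duration, dt = dt),
            class = "stimulus_protocol")
}

#' Sphere surface area
#'
#' Surface area of a spherical soma, `pi * d^2` (equal to `4 * pi * r^2`),
#' with the diameter given in um and the area returned in cm2.
#'
#' @param diameter Soma diameter, um. Must be > 0.
#' @return Surface area in cm2.
#' @examples
#' surface_area(10) # 3.1416e-6 cm2
#' @export
surface_area <- function(diameter) {
  if (!is.numeric(diameter) || any(!is.finite(diameter)) || any(diameter <= 0))
    stop("invalid geometry: diameter must be a positive finite number")
  pi * (diameter * 1e-4)^2
}

#' Analytic passive properties of an isolated soma
#'
#' Converts a neuron's per-area passive parameters into absolute values via
#' its sphere surface area: capacitance C = c_m * A (pF), leak conductance
#' G = g_leak * A (nS), input resistance R = 1/G (MOhm) and membrane time
#' constant tau = C/G = c_m/g_leak (ms). Because both C and G scale with
#' area, tau is independent of diameter.
#'
#' Unit conversions: uF/cm2 * cm2 = uF = 1e6 pF; mS/cm2 * cm2 = mS = 1e6 nS;
#' 1/nS = GOhm = 1e3 MOhm; pF/nS = ms.
#'
#' @param spec A [neuron_spec()].
#' @return A list with `capacitance_pF`, `conductance_nS`, `rin_mohm`,
#'   `tau_ms`.
#' @examples
#' derive_passive(neuron_spec("mn10", "motor", 10))
#' @export
derive_passive <- function(spec) {
  stopifnot(inherits(spec, "neuron_spec"))
  A <- surface_area(spec$diameter)
  C <- spec$membrane$c_m * A * 1e6    # uF -> pF
  G <- spec$membrane$g_leak * A * 1e6 # mS -> nS
  list(capacitance_pF = C, conductance_nS = G,
       rin_mohm = 1000 / G, tau_ms = C / G)
}
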