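# Size-graded convergence networks: 10 motor neurons of 1..10 um diameter,
# a pool of 7 um electrical interneurons wired so that the motor neuron of
# diameter x receives 10*x % of the pool, and either one shared or ten
# dedicated 5 um chemical interneurons.

#' Diameter-weighted electrical synaptic conductance
#'
#' Gap-junction conductance budget of a motor neuron of diameter `x`:
#' `g = 0.01 * x^3` nS, the summed electrical coupling it carries at full
#' convergence. The cubic weighting against a membrane conductance growing
#' only as `x^2` gives larger motor neurons disproportionately more
#' electrical shunt, which is what collapses their input resistance.
#'
#' At full convergence a motor neuron of diameter `x` receives `10 * x`
#' synapses, so each individual synapse carries
#' [per_synapse_conductance()] = `0.01 x^3 / (10 x) = 0.001 x^2` nS; at
#' duplication level n the summed coupling is `(n/10) * 0.01 x^3`.
#' Splitting the budget across the convergent pool (rather than giving
#' every synapse the full `0.01 x^3`) keeps the interneuron pool only
#' moderately loaded — so the stated 30 pA pulse can still spike an
#' embedded electrical interneuron — and keeps coupling potentials orders
#' of magnitude smaller than direct chemical PSPs instead of electrically
#' fusing the motor pool.
#'
#' @param diameter Motor neuron soma diameter, um. Must be > 0.
#' @return Conductance in nS.
#' @examples
#' electrical_conductance(10) # 10 nS total at full convergence
#' per_synapse_conductance(10) # 0.1 nS per synapse
#' @export
electrical_conductance <- function(diameter) {
  if (!is.numeric(diameter) || any(!is.finite(diameter)) || any(diameter <= 0))
    stop("invalid geometry: diameter must be a positive finite number")
  0.01 * diameter^3
}

#' @rdname electrical_conductance
#' @export
per_synapse_conductance <- function(diameter) {
  electrical_conductance(diameter) / (10 * diameter)
}

mn_id <- function(d) sprintf("mn%02d", d)

#' Build a size-graded convergence network
#'
#' Constructs the standard network: 10 motor neurons with integer diameters
#' 1..10 um, `10 * duplication` electrical interneurons (7 um), and chemical
#' interneurons (5 um) in one of two wiring modes. Electrical wiring follows
#' the nested duplication scheme: within each duplicate block of 10
#' interneurons, interneuron k contacts every motor neuron of diameter >= k
#' um, so all 10 contact the 10 um motor neuron, 9 contact the 9 um one, and
#' so forth; the motor neuron of diameter x therefore receives exactly
#' `duplication * x` electrical synapses (10*x % of the pool), each carrying
#' [per_synapse_conductance()] of its own diameter, and the
#' afferents of a smaller motor neuron are a subset of those of every larger
#' one within each block.
#'
#' Chemical wiring: `"shared"` gives one chemical interneuron contacting all
#' 10 motor neurons; `"dedicated"` gives each motor neuron its own chemical
#' interneuron.
#'
#' The builder is deterministic: identical arguments produce identical,
#' stably ordered synapse lists.
#'
#' @param duplication Integer 0..10; number of duplicate blocks of 10
#'   electrical interneurons (0x..100x convergence; the labels 0x, 10x, 50x,
#'   100x correspond to duplication 0, 1, 5, 10).
#' @param chem_wiring `"shared"` (default) or `"dedicated"`.
#' @return A [network_spec()] tagged with `duplication` and `chem_wiring`.
#' @examples
#' net <- build_size_network(duplication = 10)
#' network_summary(net)
#' @export
build_size_network <- function(duplication, chem_wiring = c("shared", "dedicated")) {
  chem_wiring <- match.arg(chem_wiring)
  if (!is.numeric(duplication) || length(duplication) != 1L ||
      duplication != round(duplication) || duplication < 0 || duplication > 10)
    stop("duplication must be an integer in 0..10")
  duplication <- as.integer(duplication)

  mns <- lapply(1:10, function(d) neuron_spec(mn_id(d), "motor", d))

  elecs <- list(); esyn <- list()
  if (duplication > 0L) {
    for (blk in seq_len(duplication)) {
      for (k in 1:10) {
        eid <- sprintf("elec_b%02d_k%02d", blk, k)
        elecs[[length(elecs) + 1L]] <- neuron_spec(eid, "elec_interneuron", 7)
        for (d in k:10)
          esyn[[length(esyn) + 1L]] <-
            elec_synapse(eid, mn_id(d), per_synapse_conductance(d))
      }
    }
  }

  if (chem_wiring == "shared") {
    chems <- list(neuron_spec("chem01", "chem_interneuron", 5))
    csyn <- lapply(1:10, function(d) chem_synapse("chem01", mn_id(d)))
  } else {
    chems <- lapply(1:10, function(d)
      neuron_spec(sprintf("chem%02d", d), "chem_interneuron", 5))
    csyn <- lapply(1:10, function(d)
      chem_synapse(sprintf("chem%02d", d), mn_id(d)))
  }

  network_spec(c(mns, chems, elecs), chem_synapses = csyn, elec_synapses = esyn,
               duplication = duplication, chem_wiring = chem_wiring)
}

#' Build a single interneuron-to-motor-neuron pair
#'
#' A minimal two-neuron network used for the single-PSP demonstrations: one
#' interneuron contacting one motor neuron of the given diameter through
#' either a chemical synapse or a gap junction carrying the single-synapse
#' diameter-weighted conductance [per_synapse_conductance()]. In the pair
#' configuration the stated stimulus pulses (10 pA for the 5 um chemical,
#' 30 pA for the 7 um electrical interneuron) evoke exactly one
#' presynaptic spike.
#'
#' @param diameter Motor neuron diameter, um.
#' @param type `"chemical"` or `"electrical"`.
#' @return A [network_spec()] with neurons `pre` and the motor neuron.
#' @export
build_pair_network <- function(diameter, type = c("chemical", "electrical")) {
  type <- match.arg(type)
  mn <- neuron_spec(mn_id(round(diameter)), "motor", diameter)
  if (type == "chemical") {
    pre <- neuron_spec("pre", "chem_interneuron", 5)
    network_spec(list(pre, mn),
                 chem_synapses = list(chem_synapse("pre", mn$id)))
  } else {
    pre <- neuron_spec("pre", "elec_interneuron", 7)
    network_spec(list(pre, mn),
                 elec_synapses = list(
                   elec_synapse("pre", mn$id, per_synapse_conductance(diameter))))
  }
}

#' Per-neuron synapse counts and total conductances
#'
#' @param network A [network_spec()].
#' @return A data frame with one row per neuron: `id`, `role`, `diameter`,
#'   `n_elec_inputs`, `total_elec_nS` (summed gap-junction conductance),
#'   `n_chem_inputs`.
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "network_spec"))
  ids <- vapply(network$neurons, function(x) x$id, character(1))
  out <- data.frame(
    id = ids,
    role = vapply(network$neurons, function(x) x$role, character(1)),
    diameter = vapply(network$neurons, function(x) x$diameter, numeric(1)),
    n_elec_inputs = 0L, total_elec_nS = 0, n_chem_inputs = 0L,
    stringsAsFactors = FALSE)
  for (s in network$elec_synapses) {
    for (end in c(s$a, s$b)) {
      i <- match(end, ids)
      out$n_elec_inputs[i] <- out$n_elec_inputs[i] + 1L
      out$total_elec_nS[i] <- out$total_elec_nS[i] + s$g
    }
  }
  for (s in network$chem_synapses) {
    i <- match(s$post, ids)
    out$n_chem_inputs[i] <- out$n_chem_inputs[i] + 1L
  }
  out
}

#' Shared electrical afferents between two motor neurons
#'
#' Number of electrical interneurons contacting both neurons. Under the
#' nested duplication scheme this equals `duplication * min(x, y)` for motor
#' neurons of diameters x and y.
#'
#' @param network A [network_spec()].
#' @param id_x,id_y Motor neuron ids.
#' @return Integer count of shared presynaptic partners.
#' @export
shared_afferents <- function(network, id_x, id_y) {
  pre_of <- function(id) {
    unlist(lapply(network$elec_synapses, function(s) {
      if (s$b == id) s$a else if (s$a == id) s$b else NULL
    }))
  }
  length(intersect(pre_of(id_x), pre_of(id_y)))
}
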