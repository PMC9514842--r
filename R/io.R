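# Network/protocol configuration round trip in YAML (or JSON): neuron ids,
# roles, diameters and non-default parameters, synapse lists, and pulses.

network_to_list <- function(network) {
  list(
    duplication = if (is.na(network$duplication)) NULL else network$duplication,
    chem_wiring = if (is.na(network$chem_wiring)) NULL else network$chem_wiring,
    neurons = lapply(network$neurons, function(n) {
      out <- list(id = n$id, role = n$role, diameter = n$diameter,
                  membrane = unclass(n$membrane))
      out$spiking <- if (is.null(n$spiking)) NULL else unclass(n$spiking)
      out$passive <- is.null(n$spiking)
      out
    }),
    chem_synapses = lapply(network$chem_synapses, unclass),
    elec_synapses = lapply(network$elec_synapses, unclass))
}

network_from_list <- function(x) {
  neurons <- lapply(x$neurons, function(n) {
    neuron_spec(n$id, n$role, n$diameter,
                membrane = do.call(membrane_params, n$membrane),
                spiking = if (isTRUE(n$passive)) NULL
                          else do.call(spike_params, n$spiking))
  })
  network_spec(
    neurons,
    chem_synapses = lapply(x$chem_synapses, function(s) do.call(chem_synapse, s)),
    elec_synapses = lapply(x$elec_synapses, function(s) do.call(elec_synapse, s)),
    duplication = if (is.null(x$duplication)) NA_integer_
                  else as.integer(x$duplication),
    chem_wiring = x$chem_wiring %||% NA_character_)
}

#' Write/read a network configuration
#'
#' Serializes a [network_spec()] to YAML (`.yml`/`.yaml`) or JSON (`.json`),
#' chosen by file extension, and reads it back. The round trip preserves all
#' neuron, synapse and tag information.
#'
#' @param network A [network_spec()].
#' @param file Path ending in `.yml`, `.yaml` or `.json`.
#' @return `write_network_config` returns `file` invisibly;
#'   `read_network_config` returns a [network_spec()].
#' @export
write_network_config <- function(network, file) {
  stopifnot(inherits(network, "network_spec"))
  x <- network_to_list(network)
  if (grepl("\\.json$", file)) {
    jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(x, file)
  }
  invisible(file)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(file) {
  x <- if (grepl("\\.json$", file)) {
    jsonlite::read_json(file, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(file)
  }
  network_from_list(x)
}
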