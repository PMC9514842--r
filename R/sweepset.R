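#' A stack of aligned recording sweeps
#'
#' Container for repeated current-clamp sweeps sharing one time base:
#' spike-triggered PSP sweeps, hyperpolarizing step responses, or the
#' per-neuron traces of a simulated PSP protocol. Optionally carries the
#' presynaptic spike time (alignment reference), the injected current, and
#' a ground-truth annotation (see [ground_truth()]) for generated data.
#'
#' @param time Time base, ms (length nt).
#' @param sweeps Numeric matrix, nt rows, one column per sweep; column names
#'   are sweep labels.
#' @param spike_time Presynaptic spike time on the shared time base, ms, or
#'   `NULL`.
#' @param current_pA Injected current for step sweeps, pA, or `NULL`.
#' @param truth A `ground_truth` object or `NULL`.
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(time, sweeps, spike_time = NULL, current_pA = NULL,
                      truth = NULL) {
  sweeps <- as.matrix(sweeps)
  stopifnot(length(time) == nrow(sweeps))
  if (is.null(colnames(sweeps)))
    colnames(sweeps) <- sprintf("sweep%03d", seq_len(ncol(sweeps)))
  structure(list(time = time, sweeps = sweeps, spike_time = spike_time,
                 current_pA = current_pA, truth = truth),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat("<sweep_set> ", ncol(x$sweeps), " sweeps x ", nrow(x$sweeps),
      " samples (", round(diff(range(x$time)), 3), " ms)", sep = "")
  if (!is.null(x$spike_time)) cat("; presynaptic spike at ", x$spike_time, " ms", sep = "")
  if (!is.null(x$truth)) cat("; ground truth attached")
  cat("\n")
  invisible(x)
}

#' @export
length.sweep_set <- function(x) ncol(x$sweeps)

#' Write/read a sweep set as long-format CSV
#'
#' The on-disk dialect is a long table with columns `sweep`, `time_ms`,
#' `value`; the presynaptic spike time and injected current, when present,
#' are stored as `# key: value` comment lines before the header.
#'
#' @param x A [sweep_set()].
#' @param file Path to a CSV file.
#' @return `write_sweep_set` returns `file` invisibly; `read_sweep_set`
#'   returns a [sweep_set()] (without ground truth, which travels in its own
#'   JSON sidecar; see [write_ground_truth()]).
#' @export
write_sweep_set <- function(x, file) {
  stopifnot(inherits(x, "sweep_set"))
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(x$spike_time))
    writeLines(sprintf("# spike_time_ms: %.10g", x$spike_time), con)
  if (!is.null(x$current_pA))
    writeLines(sprintf("# current_pA: %.10g", x$current_pA), con)
  long <- data.frame(
    sweep = rep(colnames(x$sweeps), each = nrow(x$sweeps)),
    time_ms = rep(x$time, ncol(x$sweeps)),
    value = as.vector(x$sweeps))
  utils::write.csv(long, con, row.names = FALSE)
  invisible(file)
}

#' @rdname write_sweep_set
#' @export
read_sweep_set <- function(file) {
  hdr <- readLines(file, n = 10L)
  meta <- hdr[startsWith(hdr, "#")]
  grab <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (length(ln)) as.numeric(sub(".*:", "", ln[1])) else NULL
  }
  long <- utils::read.csv(file, comment.char = "#")
  if (!all(c("sweep", "time_ms", "value") %in% names(long)))
    stop("malformed sweep file ", file,
         ": expected columns sweep, time_ms, value")
  labs <- unique(long$sweep)
  time <- long$time_ms[long$sweep == labs[1]]
  mat <- vapply(labs, function(l) long$value[long$sweep == l],
                numeric(length(time)))
  colnames(mat) <- labs
  sweep_set(time, mat, spike_time = grab("spike_time_ms"),
            current_pA = grab("current_pA"))
}

#' Export a simulation trace as CSV
#'
#' Writes the membrane-potential matrix as a CSV with a `time_ms` column
#' followed by one column per neuron id (mV), and optionally the spike
#' times as a two-column CSV (`id`, `time_ms`).
#'
#' @param trace A `sim_trace` from [simulate_network()].
#' @param file Path for the voltage CSV.
#' @param spikes_file Optional path for the spike-time CSV.
#' @return `file`, invisibly.
#' @export
write_sim_trace <- function(trace, file, spikes_file = NULL) {
  stopifnot(inherits(trace, "sim_trace"))
  df <- data.frame(time_ms = trace$time, trace$V, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  if (!is.null(spikes_file))
    utils::write.csv(trace$spikes, spikes_file, row.names = FALSE)
  invisible(file)
}
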