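# Whole-cell sweep analysis: input resistance from hyperpolarizing steps,
# PSP amplitudes against a 2 ms pre-spike baseline, synaptic failure
# classification, electrical-template subtraction, decay-tau fits, ohmic
# currents, percent-of-control normalization and fictive-swim peak currents.

#' Input resistance from hyperpolarizing step sweeps
#'
#' Computes the per-sweep steady-state voltage deflection divided by the
#' injected current, then averages across sweeps. At least three
#' hyperpolarizing pulses are required. The steady state is read as the
#' mean over the final `ss_window` ms of the pulse, against the mean of the
#' pre-pulse baseline.
#'
#' @param sweeps A [sweep_set()] of step responses sharing one time base.
#' @param current_pA Injected current, pA (nonzero). Defaults to the value
#'   carried by the sweep set.
#' @param step_window `c(onset, offset)` of the pulse on the sweep time
#'   base, ms. Defaults to the annotation carried by generated sweeps, else
#'   `c(5, 55)`.
#' @param ss_window Length of the steady-state averaging window at the end
#'   of the pulse, ms.
#' @return Input resistance, MOhm (positive for a passive membrane).
#' @export
input_resistance <- function(sweeps, current_pA = sweeps$current_pA,
                             step_window = NULL, ss_window = 5) {
  stopifnot(inherits(sweeps, "sweep_set"))
  if (ncol(sweeps$sweeps) < 3L)
    stop("insufficient data: input resistance requires at least three ",
         "hyperpolarizing pulses, got ", ncol(sweeps$sweeps))
  if (is.null(current_pA) || !is.numeric(current_pA) || current_pA == 0)
    stop("injected current must be nonzero")
  if (is.null(step_window))
    step_window <- attr(sweeps, "step_window") %||% c(5, 55)
  t <- sweeps$time
  base_sel <- t < step_window[1]
  ss_sel <- t >= step_window[2] - ss_window & t < step_window[2]
  if (!any(base_sel) || !any(ss_sel))
    stop("step window does not leave a baseline and steady-state region")
  dv <- colMeans(sweeps$sweeps[ss_sel, , drop = FALSE]) -
    colMeans(sweeps$sweeps[base_sel, , drop = FALSE])
  # mV / pA = GOhm; report MOhm
  mean(dv / current_pA) * 1000
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' PSP amplitude against the 2 ms pre-spike baseline
#'
#' Amplitude of a postsynaptic potential: the peak depolarization within
#' `peak_window` ms after the presynaptic spike minus the averaged baseline
#' over the `baseline_ms` window immediately before the spike. Adding a
#' constant offset to the sweep leaves the result unchanged.
#'
#' @param sweeps A [sweep_set()]; amplitudes are computed per sweep/column.
#' @param spike_time Presynaptic spike time, ms. Defaults to the annotation
#'   on the sweep set.
#' @param baseline_ms Baseline window length before the spike, ms.
#' @param peak_window Search window for the peak after the spike, ms.
#' @return Named numeric vector of amplitudes, mV (one per sweep).
#' @export
psp_amplitude <- function(sweeps, spike_time = sweeps$spike_time,
                          baseline_ms = 2, peak_window = 20) {
  stopifnot(inherits(sweeps, "sweep_set"))
  if (is.null(spike_time)) stop("presynaptic spike time is required")
  t <- sweeps$time
  if (t[1] > spike_time - baseline_ms + 1e-9)
    stop("insufficient baseline: need ", baseline_ms,
         " ms of pre-spike record")
  base_sel <- t >= spike_time - baseline_ms & t < spike_time
  post_sel <- t >= spike_time & t <= spike_time + peak_window
  base <- colMeans(sweeps$sweeps[base_sel, , drop = FALSE])
  peak <- apply(sweeps$sweeps[post_sel, , drop = FALSE], 2, max)
  peak - base
}

#' Time to peak of a PSP
#'
#' @inheritParams psp_amplitude
#' @return Named numeric vector, ms from the presynaptic spike to the peak.
#' @export
psp_time_to_peak <- function(sweeps, spike_time = sweeps$spike_time,
                             peak_window = 20) {
  stopifnot(inherits(sweeps, "sweep_set"))
  if (is.null(spike_time)) stop("presynaptic spike time is required")
  t <- sweeps$time
  post_sel <- t >= spike_time & t <= spike_time + peak_window
  tp <- t[post_sel]
  apply(sweeps$sweeps[post_sel, , drop = FALSE], 2,
        function(v) tp[which.max(v)] - spike_time)
}

#' Classify chemical failures in spike-triggered sweeps
#'
#' A sweep is a failure when it shows no chemical-component deflection
#' above criterion inside the chemical window: the mean baseline-subtracted
#' deflection over `window` (ms after the presynaptic spike) must exceed
#' `criterion` times the baseline noise SD for a success. The failure rate
#' is the number of failures divided by the total number of spike-triggered
#' events, as a percentage. 10-200 sweeps are recommended; a warning is
#' issued outside that range.
#'
#' The window mean (rather than the window peak) is used as the detection
#' statistic because the maximum of several hundred noise samples is itself
#' biased well above the noise SD.
#'
#' @param sweeps A [sweep_set()] of spike-triggered events.
#' @param window Chemical window relative to the presynaptic spike, ms;
#'   the early electrical component occupies roughly the first 1.5 ms.
#' @param criterion Detection threshold in baseline-noise SDs.
#' @param baseline_ms Pre-spike baseline window, ms.
#' @return List with `is_failure` (logical per sweep), `failure_rate_pct`,
#'   `n_failures`, `n_total`, `criterion_mV` and `noise_sd`.
#' @export
classify_failures <- function(sweeps, window = c(1.5, 8), criterion = 3,
                              baseline_ms = 2) {
  stopifnot(inherits(sweeps, "sweep_set"))
  n <- ncol(sweeps$sweeps)
  if (n == 0L) stop("empty sweep set")
  if (n < 10L || n > 200L)
    warning("failure rates are recommended on 10-200 spike-triggered sweeps; got ", n)
  st <- sweeps$spike_time
  if (is.null(st)) stop("presynaptic spike time is required")
  t <- sweeps$time
  base_sel <- t >= st - baseline_ms & t < st
  win_sel <- t >= st + window[1] & t <= st + window[2]
  if (!any(win_sel)) stop("chemical window contains no samples")
  base_mat <- sweeps$sweeps[base_sel, , drop = FALSE]
  base <- colMeans(base_mat)
  noise_sd <- stats::sd(sweep_residuals(base_mat))
  defl <- colMeans(sweeps$sweeps[win_sel, , drop = FALSE]) - base
  crit <- criterion * noise_sd
  is_failure <- defl < crit
  list(is_failure = unname(is_failure),
       failure_rate_pct = 100 * sum(is_failure) / n,
       n_failures = sum(is_failure), n_total = n,
       criterion_mV = crit, noise_sd = noise_sd)
}

# per-sweep demeaned baseline samples, pooled
sweep_residuals <- function(base_mat) {
  sweep(base_mat, 2, colMeans(base_mat))
}

#' Isolate the chemical component of mixed synaptic responses
#'
#' Estimates the electrical component as the average of the failure sweeps
#' (where the chemical component was absent) and subtracts this template
#' from every sweep, leaving chemical-only responses. The chemical
#' amplitude is then measured on the success sweeps. The method is
#' undefined without at least one failure.
#'
#' Adding the template back to the returned sweeps reconstructs the
#' originals exactly.
#'
#' @param sweeps A [sweep_set()] of mixed spike-triggered sweeps.
#' @param is_failure Logical flags per sweep, e.g. from
#'   [classify_failures()].
#' @return A [sweep_set()] of chemical-only sweeps with the electrical
#'   template attached as attribute `"template"`.
#' @export
isolate_chemical_component <- function(sweeps, is_failure) {
  stopifnot(inherits(sweeps, "sweep_set"),
            length(is_failure) == ncol(sweeps$sweeps))
  if (!any(is_failure))
    stop("cannot isolate: the electrical template requires at least one ",
         "failure sweep")
  template <- rowMeans(sweeps$sweeps[, is_failure, drop = FALSE])
  out <- sweep_set(sweeps$time, sweeps$sweeps - template,
                   spike_time = sweeps$spike_time, truth = sweeps$truth)
  attr(out, "template") <- template
  out
}

#' Fast decay constant of a PSP
#'
#' Fits a double exponential to the decay of a (typically averaged) PSP
#' between its peak and the first crossing of 20% of the peak amplitude,
#' and reports the fast constant t1 of the fit — the chemical kinetics —
#' rather than the weighted constant, because slow electrical events can
#' contaminate the late decay.
#'
#' @param sweeps A [sweep_set()] with a single sweep (or an average), or a
#'   sweep index via `which`.
#' @param spike_time Presynaptic spike time, ms.
#' @param which Column to analyse if the set has several sweeps.
#' @param frac Fraction of the peak at which the fit window ends (0.2).
#' @param peak_window Search window for the peak after the spike, ms.
#' @return The fast time constant t1, ms, with the full `fit_result` as
#'   attribute `"fit"`.
#' @export
psp_decay_tau <- function(sweeps, spike_time = sweeps$spike_time, which = 1L,
                          frac = 0.2, peak_window = 20) {
  stopifnot(inherits(sweeps, "sweep_set"))
  if (is.null(spike_time)) stop("presynaptic spike time is required")
  t <- sweeps$time
  v <- sweeps$sweeps[, which]
  base_sel <- t >= spike_time - 2 & t < spike_time
  base <- mean(v[base_sel])
  post <- which(t >= spike_time & t <= spike_time + peak_window)
  ipk <- post[which.max(v[post])]
  amp <- v[ipk] - base
  after <- which(t > t[ipk])
  cross <- after[(v[after] - base) <= frac * amp]
  if (!length(cross))
    stop("window truncation: decay does not reach ", 100 * frac,
         "% of peak within the record")
  iend <- cross[1]
  seg_t <- t[ipk:iend]
  seg_v <- v[ipk:iend]
  fit <- fit_double_exponential(seg_t, seg_v, baseline = base)
  structure(fit$tau1, fit = fit)
}

#' Ohmic current from PSP amplitude and input resistance
#'
#' The synaptic current inferred from a PSP amplitude via Ohm's law,
#' I = V / R. With V in mV and R in MOhm the quotient is in nA, so the
#' result is multiplied by 1000 to report pA.
#'
#' @param amplitude_mV PSP amplitude, mV.
#' @param rin_mohm Input resistance, MOhm (> 0).
#' @return Current, pA.
#' @examples
#' ohmic_current(5, 50) # 100 pA
#' @export
ohmic_current <- function(amplitude_mV, rin_mohm) {
  if (any(rin_mohm <= 0)) stop("input resistance must be > 0")
  amplitude_mV / rin_mohm * 1000
}

#' Percent of control
#'
#' Normalizes a post-treatment value to its control, with the control set
#' to 100%.
#'
#' @param pre Control value (> 0).
#' @param post Post-treatment value.
#' @return `100 * post / pre`, percent.
#' @export
percent_control <- function(pre, post) {
  if (any(pre <= 0)) stop("control value must be > 0")
  100 * post / pre
}

#' Peak excitatory current per fictive swim bout
#'
#' Measures, for each annotated bout, the maximum inward (negative)
#' deflection of the current trace from the pre-stimulus baseline, reported
#' as a positive magnitude in pA. At least five bouts are recommended; a
#' warning is issued with fewer. Both the per-bout vector and its mean are
#' returned (the mean is the default summary).
#'
#' @param time Sample times, ms.
#' @param current Current trace, pA (inward negative).
#' @param bouts Data frame with columns `start` and `end` (ms) delimiting
#'   each bout.
#' @param baseline_window `c(from, to)` ms of pre-stimulus baseline.
#' @return List with `per_bout_pA` (positive magnitudes), `mean_pA`,
#'   `max_pA` and `baseline_pA`.
#' @export
peak_swim_current <- function(time, current, bouts,
                              baseline_window = c(0, min(bouts$start))) {
  stopifnot(is.data.frame(bouts), all(c("start", "end") %in% names(bouts)))
  if (nrow(bouts) == 0L) stop("no bouts found")
  if (nrow(bouts) < 5L)
    warning("peak swim currents are recommended on at least five bouts; got ",
            nrow(bouts))
  base_sel <- time >= baseline_window[1] & time < baseline_window[2]
  baseline <- mean(current[base_sel])
  peaks <- vapply(seq_len(nrow(bouts)), function(i) {
    sel <- time >= bouts$start[i] & time <= bouts$end[i]
    d <- baseline - min(current[sel]) # inward deflection magnitude
    max(d, 0)
  }, numeric(1))
  list(per_bout_pA = peaks, mean_pA = mean(peaks), max_pA = max(peaks),
       baseline_pA = baseline)
}
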