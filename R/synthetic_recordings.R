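# Seeded generator of experiment-like sweeps with known ground truth:
# hyperpolarizing step responses with bi-exponential relaxation, mixed
# electrical+chemical spike-triggered PSP sweeps with Bernoulli chemical
# failures, and oscillatory fictive-swim current traces. Every generated
# sweep set carries its ground truth, so recovery tests are self-contained.
# Noise is additive i.i.d. Gaussian and is the only stochastic element; all
# draws flow from the single stored seed, and regeneration from the same
# seed is bit-identical.

#' Ground truth for synthetic recordings
#'
#' The known parameters behind a generated recording. Relaxation kinetics
#' are a double exponential with amplitude weights `tau_a`/`tau_b` (mV) and
#' constants `tau1`/`tau2` (ms), giving a weighted time constant
#' `tau_a/(tau_a+tau_b)*tau1 + tau_b/(tau_a+tau_b)*tau2`.
#'
#' @param rin_mohm True input resistance, MOhm.
#' @param tau_a,tau1,tau_b,tau2 Double-exponential relaxation components:
#'   amplitudes (mV) and time constants (ms), fast component first.
#' @param elec_amp_mV Electrical (gap-junction spikelet) PSP amplitude, mV.
#' @param chem_amp_mV Chemical PSP amplitude, mV.
#' @param p_fail Chemical failure probability per spike-triggered event.
#' @param swim_peaks_pA Programmed per-bout peak inward currents, pA
#'   (positive magnitudes).
#' @param swim_freq_hz Within-bout cycle frequency range `c(high, low)`,
#'   Hz; each bout chirps from the first to the second value.
#' @param noise_sd Voltage noise SD, mV.
#' @param noise_sd_pA Current noise SD for swim traces, pA.
#' @param seed Integer RNG seed stored with the data.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(rin_mohm = 500, tau_a = 3, tau1 = 2, tau_b = 1,
                         tau2 = 10, elec_amp_mV = 1.5, chem_amp_mV = 2,
                         p_fail = 0.25,
                         swim_peaks_pA = c(100, 110, 120, 130, 140),
                         swim_freq_hz = c(75, 20), noise_sd = 0.1,
                         noise_sd_pA = 1, seed = 1L) {
  if (rin_mohm <= 0) stop("rin_mohm must be > 0")
  if (tau1 <= 0 || tau2 <= 0) stop("time constants must be > 0")
  if (p_fail < 0 || p_fail > 1) stop("p_fail must be a probability")
  if (any(swim_freq_hz <= 0)) stop("invalid frequency range")
  if (noise_sd < 0 || noise_sd_pA < 0) stop("noise SDs must be >= 0")
  structure(list(rin_mohm = rin_mohm, tau_a = tau_a, tau1 = tau1,
                 tau_b = tau_b, tau2 = tau2, elec_amp_mV = elec_amp_mV,
                 chem_amp_mV = chem_amp_mV, p_fail = p_fail,
                 swim_peaks_pA = swim_peaks_pA, swim_freq_hz = swim_freq_hz,
                 noise_sd = noise_sd, noise_sd_pA = noise_sd_pA,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  wt <- (x$tau_a * x$tau1 + x$tau_b * x$tau2) / (x$tau_a + x$tau_b)
  cat(sprintf(paste0("<ground_truth> Rin %g MOhm; weighted tau %.3g ms; ",
                     "eEPSP %g mV, cEPSP %g mV, p_fail %g; noise %g mV; seed %d\n"),
              x$rin_mohm, wt, x$elec_amp_mV, x$chem_amp_mV, x$p_fail,
              x$noise_sd, x$seed))
  invisible(x)
}

#' True weighted time constant of a ground truth
#' @param truth A [ground_truth()].
#' @return Weighted tau, ms.
#' @export
true_weighted_tau <- function(truth) {
  (truth$tau_a * truth$tau1 + truth$tau_b * truth$tau2) /
    (truth$tau_a + truth$tau_b)
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate hyperpolarizing step-response sweeps
#'
#' Emulates whole-cell current-clamp sweeps: a square current step whose
#' onset and offset relax bi-exponentially per the ground truth, plus
#' i.i.d. Gaussian noise. The steady-state deflection is
#' `current_pA * rin_mohm / 1000` mV.
#'
#' @param truth A [ground_truth()].
#' @param n_sweeps Number of sweeps (>= 3 for downstream Rin analysis).
#' @param current_pA Step amplitude, pA (default -5).
#' @param dt Sample step, ms.
#' @param baseline_ms,step_ms,tail_ms Segment durations, ms.
#' @param v_rest Resting potential, mV.
#' @return A [sweep_set()] carrying the truth and a `"step_window"`
#'   attribute `c(onset, offset)`.
#' @export
generate_step_response_sweeps <- function(truth, n_sweeps = 5, current_pA = -5,
                                          dt = 0.05, baseline_ms = 5,
                                          step_ms = 50, tail_ms = 40,
                                          v_rest = -60) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_sweeps < 3) stop("generate at least 3 sweeps for Rin analysis")
  total <- baseline_ms + step_ms + tail_ms
  time <- seq(0, total, by = dt)
  dv <- current_pA * truth$rin_mohm / 1000
  wsum <- truth$tau_a + truth$tau_b
  relax <- function(t) (truth$tau_a * exp(-t / truth$tau1) +
                          truth$tau_b * exp(-t / truth$tau2)) / wsum
  v <- rep(v_rest, length(time))
  on <- time >= baseline_ms & time < baseline_ms + step_ms
  v[on] <- v_rest + dv * (1 - relax(time[on] - baseline_ms))
  off <- time >= baseline_ms + step_ms
  v[off] <- v_rest + dv * (1 - relax(step_ms)) *
    relax(time[off] - baseline_ms - step_ms)
  mat <- with_seed(truth$seed, {
    vapply(seq_len(n_sweeps),
           function(i) v + stats::rnorm(length(v), 0, truth$noise_sd),
           numeric(length(v)))
  })
  colnames(mat) <- sprintf("sweep%03d", seq_len(n_sweeps))
  out <- sweep_set(time, mat, current_pA = current_pA, truth = truth)
  attr(out, "step_window") <- c(baseline_ms, baseline_ms + step_ms)
  out
}

# difference-of-exponentials kinetic template, normalized to unit peak
psp_kernel <- function(t, rise, decay) {
  w <- ifelse(t > 0, exp(-t / decay) - exp(-t / rise), 0)
  tpk <- log(decay / rise) / (1 / rise - 1 / decay)
  w / (exp(-tpk / decay) - exp(-tpk / rise))
}

#' Generate mixed electrical-chemical PSP sweeps
#'
#' Spike-triggered sweeps combining a deterministic early electrical
#' component (fast gap-junction spikelet) with a later chemical component
#' present on each sweep with probability `1 - p_fail` (Bernoulli draws),
#' plus Gaussian noise. The presynaptic spike time annotation is included.
#' Setting `elec_amp_mV = 0` in the truth yields pure chemical EPSPs;
#' `p_fail = 1` yields pure electrical responses.
#'
#' @param truth A [ground_truth()].
#' @param n_sweeps Number of spike-triggered events (10-200 recommended).
#' @param dt Sample step, ms.
#' @param spike_time Presynaptic spike time on the sweep, ms.
#' @param total_ms Sweep duration, ms.
#' @param v_rest Resting potential, mV.
#' @param elec_kinetics,chem_kinetics `c(rise, decay)` ms of each component;
#'   the chemical component starts `chem_delay` ms after the spike.
#' @param chem_delay Synaptic delay of the chemical component, ms.
#' @return A [sweep_set()] carrying the truth; the per-sweep success flags
#'   are attached as attribute `"chem_present"`.
#' @export
generate_mixed_psp_sweeps <- function(truth, n_sweeps = 80, dt = 0.05,
                                      spike_time = 10, total_ms = 35,
                                      v_rest = -60,
                                      elec_kinetics = c(0.3, 0.8),
                                      chem_kinetics = c(0.5, 3.5),
                                      chem_delay = 0.8) {
  stopifnot(inherits(truth, "ground_truth"))
  if (truth$p_fail < 0 || truth$p_fail > 1) stop("invalid failure probability")
  time <- seq(0, total_ms, by = dt)
  elec <- truth$elec_amp_mV *
    psp_kernel(time - spike_time, elec_kinetics[1], elec_kinetics[2])
  chem <- truth$chem_amp_mV *
    psp_kernel(time - spike_time - chem_delay, chem_kinetics[1], chem_kinetics[2])
  gen <- with_seed(truth$seed, {
    present <- stats::runif(n_sweeps) >= truth$p_fail
    mat <- vapply(seq_len(n_sweeps), function(i) {
      v_rest + elec + (if (present[i]) chem else 0) +
        stats::rnorm(length(time), 0, truth$noise_sd)
    }, numeric(length(time)))
    list(present = present, mat = mat)
  })
  colnames(gen$mat) <- sprintf("sweep%03d", seq_len(n_sweeps))
  out <- sweep_set(time, gen$mat, spike_time = spike_time, truth = truth)
  attr(out, "chem_present") <- gen$present
  out
}

#' Generate a fictive-swim current trace
#'
#' A voltage-clamp-like current record: flat baseline, a brief stimulus
#' artifact, then bouts of rhythmic inward (negative) current whose cycle
#' frequency chirps linearly from the high to the low end of
#' `swim_freq_hz` within each bout — faster cycles near the beginning —
#' under a smooth envelope scaled so each bout's programmed peak is hit
#' exactly (before noise). Bout annotations are returned alongside.
#'
#' @param truth A [ground_truth()]; one bout per entry of `swim_peaks_pA`.
#' @param dt Sample step, ms.
#' @param bout_ms Duration of each bout, ms.
#' @param gap_ms Quiescent gap between bouts, ms.
#' @param baseline_ms Pre-stimulus baseline, ms.
#' @return List with `time` (ms), `current` (pA), `bouts` (data frame
#'   `start`, `end` in ms) and `truth`.
#' @export
generate_fictive_swim_trace <- function(truth, dt = 0.1, bout_ms = 500,
                                        gap_ms = 300, baseline_ms = 50) {
  stopifnot(inherits(truth, "ground_truth"))
  nb <- length(truth$swim_peaks_pA)
  if (nb < 1L) stop("at least one bout peak must be programmed")
  if (any(truth$swim_freq_hz <= 0)) stop("invalid frequency range")
  total <- baseline_ms + 20 + nb * (bout_ms + gap_ms)
  time <- seq(0, total, by = dt)
  current <- numeric(length(time))
  # stimulus artifact: brief biphasic deflection just after the baseline
  art <- time >= baseline_ms & time < baseline_ms + 1
  current[art] <- 50 * sin(2 * pi * (time[art] - baseline_ms))
  f_hi <- truth$swim_freq_hz[1] / 1000 # cycles per ms
  f_lo <- truth$swim_freq_hz[2] / 1000
  starts <- baseline_ms + 20 + (seq_len(nb) - 1L) * (bout_ms + gap_ms)
  for (i in seq_len(nb)) {
    sel <- time >= starts[i] & time < starts[i] + bout_ms
    s <- (time[sel] - starts[i]) / bout_ms          # 0..1 within bout
    phase <- bout_ms * (f_hi * s + (f_lo - f_hi) * s^2 / 2) # linear chirp
    osc <- 0.5 * (1 - cos(2 * pi * phase))
    env <- sin(pi * s)^2
    w <- env * osc
    if (max(w) > 0) w <- w / max(w)
    current[sel] <- -truth$swim_peaks_pA[i] * w
  }
  current <- with_seed(truth$seed + 1L, {
    current + stats::rnorm(length(current), 0, truth$noise_sd_pA)
  })
  list(time = time, current = current,
       bouts = data.frame(start = starts, end = starts + bout_ms),
       truth = truth)
}

#' Write/read a ground-truth JSON sidecar
#'
#' @param truth A [ground_truth()].
#' @param file Path to a JSON file.
#' @return `write_ground_truth` returns `file` invisibly;
#'   `read_ground_truth` returns a [ground_truth()].
#' @export
write_ground_truth <- function(truth, file) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(unclass(truth), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  do.call(ground_truth, x)
}
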