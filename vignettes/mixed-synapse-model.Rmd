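---
title: "Modelling mixed electrical-chemical synaptic convergence in a spinal motor pool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mixed electrical-chemical synaptic convergence in a spinal motor pool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixedsyn)
```

## The scientific problem

The size principle predicts that motor neurons are recruited in order of
increasing soma size because smaller somata have higher input resistance
(Rin) and are therefore more excitable. In circuits rich in *mixed*
electrical-chemical synapses, however, gap junctions add a resting leak
that scales with synapse density rather than with membrane area. A neuron's
measured Rin then reflects both its size and its electrical-synapse
convergence, which can uncouple size from excitability and make
spike-triggered connectivity measurements ambiguous: current injected into
one neuron spreads through shared gap-junction afferents and reappears in
other neurons as slow, attenuated "coupling potentials" that mimic direct
synaptic connections.

`mixedsyn` provides a compact biophysical model of this situation — a pool
of spherical integrate-and-fire somata coupled by non-rectifying gap
junctions and area-scaled chemical synapses — together with the
electrophysiological measurement procedures used on real whole-cell
recordings, so that the interaction of size, convergence, Rin, time
constant and PSP shape can be explored quantitatively, and so that every
analysis routine can be validated against synthetic recordings with known
ground truth.

## The membrane and synapse model

Each neuron is a sphere of diameter $d$ (µm) with surface area
$A = \pi d^2$ (converted to cm²). Passive parameters are per-area and
converted once to absolute values: capacitance $C = c_m A$ with
$c_m = 1\,\mu F/cm^2$, leak conductance $G = \bar g_L A$ with
$\bar g_L = 0.3\,mS/cm^2$, and $E_L = V_{rest} = -60$ mV. Hence
$R_{in} = 1/G \propto 1/d^2$ while $\tau = C/G = c_m/\bar g_L = 3.33$ ms is
size-independent for an isolated soma.

The subthreshold dynamics of neuron $i$ are

$$C_i \frac{dV_i}{dt} = -g_{L,i}(V_i - E_L) - g_{chem,i}(t)(V_i - E_{chem})
 - g_{AHP,i}(t)(V_i - E_{AHP}) - \sum_j g_{e,ij}(V_i - V_j) + I_{inj,i}(t).$$

Chemical synapses have reversal 0 mV, a normalized conductance of
0.25 mS/cm² scaled by the *postsynaptic* area, and single-exponential decay
with $\tau = 1$ ms; each presynaptic spike adds exactly one quantal
conductance increment. Because the synaptic conductance, the leak and the
capacitance all scale with area, a chemical PSP from a shared source has
identical amplitude and shape in every motor neuron — the model's way of
expressing size-scaled chemical synapses.

Gap junctions are ohmic, non-rectifying absolute conductances in nS:
current flows whenever the two membrane potentials differ, and the current
into one neuron is the exact negative of the current into its partner.

Spikes use integrate-and-fire machinery: threshold $-40$ mV, forced
triangular waveform to $+10$ mV over 1 ms with the downstroke ending at
rest, AHP conductance increment 0.4 mS/cm² (decay 3 ms, reversal $-70$ mV),
absolute refractory period 2 ms, and threshold accommodation (relative
strength 0.3, time constant 10 ms). Three details were genuinely open and
were fixed as follows:

* **Spike waveform.** Only the spike peak is prescribed by the underlying
  parameter set; the waveform *shape* matters here because the forced
  voltage excursion is what drives gap-junction spikelets into coupled
  neurons. We use a linear rise over the first half of the 1 ms spike and a
  linear downstroke ending at the resting potential; the AHP conductance
  then shapes the undershoot. Ending the downstroke at the threshold
  instead leaves the membrane poised so close to threshold that a
  sustained 5 ms stimulus pulse re-fires the cell after the 2 ms
  refractory period, violating the single-spike-per-run design of the PSP
  protocols.
* **Accommodation.** The threshold relaxes toward
  $\theta_0 + 0.3\,\max(V - V_{rest}, 0)$ with a 10 ms time constant, and
  additionally jumps by $0.3\,(V_{peak} - \theta_0)$ = 15 mV at each spike
  (an adaptive-threshold formulation). The spike-triggered jump is what
  guarantees exactly one spike per 5 ms pulse in lightly loaded
  interneurons; the depolarization-only floor prevents large
  hyperpolarizing steps in gigaohm-range model somata from dragging the
  threshold down and registering spurious rebound spikes.
* **"Spike strength".** Treated as internal to the source formulation;
  transmission is one quantal increment per spike.

## Numerical integration

The integrator is fixed-step exponential Euler with default
$\Delta t = 0.01$ ms. Every conductance acting on a neuron is collected
into $g_{tot}$ and a conductance-weighted reversal, and $V$ is relaxed
exactly toward $V_\infty = \mathrm{num}/g_{tot}$ over the step. Neighbour
voltages enter explicitly, which makes the scheme a Jacobi iteration on
the passive conductance-matrix linear system: its fixed point is the exact
steady state regardless of step size, and it is convergent because each
row is diagonally dominant ($g_{tot,i} \ge \sum_j g_{e,ij}$). This matters
because strong gap-junction coupling makes the system stiff — the largest
motor neuron at full convergence has an effective time constant two orders
of magnitude below its isolated value — and a forward-Euler scheme at the
same step would be unstable. The test suite checks the passive steady
state of random coupled networks against a direct linear solve (0.1%
tolerance) and verifies that halving the step changes steady-state
voltages by less than 0.1%.

## The convergence network

The standard network has 10 motor neurons of integer diameters 1–10 µm,
one (or ten dedicated) 5 µm chemical interneurons, and blocks of ten 7 µm
electrical interneurons. Within a block, interneuron $k$ contacts every
motor neuron of diameter $\ge k$ µm, so the pool covers the 10 µm neuron
completely and the 1 µm neuron at 10%; the block is duplicated $n$ times
($n = 0 \ldots 10$), giving the convergence labels 0x–100x and exactly
$n \cdot x$ synapses onto the motor neuron of diameter $x$. Afferent
sharing is nested: two motor neurons of diameters $x < y$ share exactly
$n\,x$ electrical afferents.

The electrical weighting is the cubic rule $y = 0.01 x^3$ nS for the motor
neuron of diameter $x$. We implement this as the neuron's summed coupling
**budget at full convergence**: each of its $10x$ synapses carries
$0.01x^3/(10x) = 0.001 x^2$ nS. The alternative — giving every synapse the
full $0.01x^3$ — was implemented first and rejected on quantitative
grounds: with 100 synapses of 10 nS on a 0.94 nS soma the motor pool is
electrically fused (coupling potentials reach 95% of the direct PSP
instead of being orders of magnitude smaller), and every electrical
interneuron is loaded so heavily that the standard 30 pA pulse cannot
bring it within 20 mV of threshold. Under the budget reading the
electrical interneuron's effective input resistance (~1.3 GΩ) sits about
threefold below the chemical interneuron's (4.2 GΩ), which is exactly the
ratio of the stated stimulus pulses (30 pA vs 10 pA). One consequence is
that single-afferent electrical PSPs are nearly size-independent
(~$0.001x^2$ against a membrane conductance $\propto x^2$) rather than
growing with target size; the size-dependence of the electrical pathway
lives in the *total* shunt ($\propto x^3$) and in convergence, not in the
single spikelet.

## Virtual experiments and analysis procedures

* `run_rin_protocol()`: −5 pA, 50 ms hyperpolarizing step; Rin from the
  steady state read as the mean of the last 5 ms of the pulse (≥ 14
  isolated-membrane time constants after onset); τ from a
  double-exponential fit to the off-relaxation.
* `run_psp_protocol()`: one presynaptic spike evoked by the standard 5 ms
  pulse (10 pA chemical / 30 pA electrical interneurons); zero or multiple
  spikes abort the run. PSP amplitude is measured from the mean of the
  2 ms immediately before the presynaptic spike to the peak within 20 ms.
* `run_coupling_map()`: at 100x convergence with dedicated chemical
  inputs, each motor neuron's own chemical interneuron is spiked in turn;
  the direct PSP (diagonal) and the coupling potentials in all other
  motor neurons (off-diagonal) are tabulated as amplitude and
  time-to-peak matrices. The "low-pass filtered" amplitude is the raw peak
  of the coupling potential — the network itself is the filter; no digital
  filtering is applied. Monotonicity of coupling with shared-afferent
  count holds for the coupling *current* (amplitude over the recorded
  neuron's Rin); raw voltage amplitudes are additionally scaled by each
  neuron's own shunt.
* `fit_double_exponential()`: least squares of
  $a e^{-t/\tau_1} + b e^{-t/\tau_2}$ by variable projection (amplitudes
  solved linearly at fixed time constants; Nelder-Mead over log-τ from a
  multi-start grid spanning 0.5–50 ms, best residual wins). The weighted
  constant is $\tau = \frac{a}{a+b}\tau_1 + \frac{b}{a+b}\tau_2$, always
  inside $[\tau_1, \tau_2]$; degenerate single-exponential segments
  collapse to the $b = 0$ solution. The exponent notation is read as
  $e^{-t/\tau}$, the only dimensionally sensible form.
* `classify_failures()`: a sweep is a failure when its mean
  baseline-subtracted deflection inside the chemical window (default
  1.5–8 ms after the spike; the electrical component occupies the first
  ~1.5 ms) is below 3 baseline-noise SDs. The window *mean* is used
  rather than the window peak because the maximum of several hundred
  noise samples is itself biased ~3.6 SDs above zero, which would
  misclassify failures. The failure rate is failures over total
  spike-triggered events, in percent.
* `isolate_chemical_component()`: the average of the failure sweeps is
  the electrical template; subtracting it from every sweep leaves
  chemical-only responses (and re-adding it reconstructs the originals
  exactly). Undefined without at least one failure.
* `psp_decay_tau()`: double-exponential fit restricted to the window from
  the peak to the first crossing of 20% of the peak; the *fast* constant
  is reported, because slow electrical events contaminate the late decay.
* `peak_swim_current()`: per-bout maximum inward deflection from the
  pre-stimulus baseline; both the per-bout vector and its mean are
  returned (the mean is the default summary; whether a per-fish value
  should be the mean or the maximum across bouts is not prescribed, so
  both are available).
* `spearman_rank()` / `mann_whitney_u()`: midrank tie handling; exact
  permutation p-values by full enumeration for $n \le 8$ (Spearman) or
  pooled $n \le 12$ (U test), t- or normal-approximation with tie and
  continuity correction otherwise. Two-sided p-values throughout (the
  conservative default where sidedness is unstated). Spearman degrees of
  freedom are reported as $n - 2$; for the U test both group sizes are
  reported, the statistic is $\min(U_a, U_b)$.

## Synthetic recordings and what passing tests mean

`generate_step_response_sweeps()`, `generate_mixed_psp_sweeps()` and
`generate_fictive_swim_trace()` emulate the three recording types the
analysis functions consume: square hyperpolarizing steps with
bi-exponential relaxation, spike-triggered mixed PSP sweeps in which the
chemical component fails with a programmed Bernoulli probability, and
voltage-clamp swim episodes — bouts of rhythmic inward current whose cycle
frequency chirps linearly from 75 to 20 Hz within each bout under a
smooth envelope scaled to hit each programmed peak exactly. Default
amplitudes (electrical 1.5 mV, chemical 2 mV, bout peaks 100–140 pA,
noise 0.1 mV / 1 pA) sit in the range of small spinal neurons recorded in
whole cell. Noise is additive i.i.d. Gaussian and is the only stochastic
element; every draw flows from the single stored seed and regeneration is
bit-identical.

These generators deliberately omit electrode artifacts, series-resistance
errors, drift, correlated noise and spike-shape realism. Passing recovery
tests therefore demonstrates that the analysis chain is unbiased and
correctly implemented under its stated assumptions — not that it is robust
to every pathology of real recordings.

## Problem sizes and known limitations

The shipped experiments use the full 10-diameter × {0x, 10x, 50x, 100x}
sweep (40 step protocols on networks of 11–111 somata, ~85 ms each at
dt = 0.01 ms) and the 10-run coupling map; recovery experiments use 5 step
sweeps, 80–100 PSP sweeps and 5 swim bouts. These sizes were chosen to
match the corresponding experimental designs while keeping a full run in
tens of seconds on one core.

Limitations worth keeping in mind: there are no dendritic or axonal
compartments and no interneuron-interneuron synapses, so all filtering is
somatic; gap junctions are linear and non-rectifying; chemical transmission
is deterministic in the simulator (stochastic failures exist only in the
synthetic-recordings generator); and the spike is stylized, so spikelet
waveforms are triangular rather than biophysical. Within the model, the
weighted time constant at 100x convergence is not monotone in diameter —
the largest motor neurons couple so strongly to the interneuron pool that
the interneurons' own membranes dominate the relaxation tail — so τ vs Rin
across the whole sweep is a significant positive rank trend rather than a
strict monotonicity.
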