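---
title: "A conductance-based network model of serotonergic gain control, and its analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A conductance-based network model of serotonergic gain control, and its analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sergain)
```

## The scientific question

Serotonergic 5-HT~2A~ receptors are expressed on both pyramidal neurons and
parvalbumin (PV) interneurons of visual cortex. Activating them in either
cell class alone shifts spontaneous firing (up for pyramidal-targeted
activation, bidirectional for PV-targeted activation), yet activating them
jointly across both classes barely moves spontaneous rates while clearly
reducing the *gain* of visually evoked responses, in a divisive
(slope-scaling) way. `sergain` packages a spiking network model that
explains this dissociation, together with the spike-train and LFP analysis
stack needed to quantify it on simulated, synthetic, or recorded sessions.

## The network model

Each unit is a conductance-based leaky integrate-and-fire neuron,

$$C \frac{dV_m}{dt} = -g_L (V_m - E_L) - G_e(t)\,(V_m - E_e) - G_i(t)\,(V_m - E_i),$$

spiking when $V_m \ge E_T$ and resetting to $V_r$ for an absolute
refractory period $t_\mathrm{ref}$. The total conductances are sums of
alpha-function kernels over presynaptic events,

$$g_x(t) = \frac{J_x}{\tau_x}\, H(t)\, e^{1 - t/\tau_x}\, t, \qquad x \in \{e, i\},$$

which rise from zero and peak at exactly $J_x$ at $t = \tau_x$
(`alpha_kernel()`). Defaults (all overridable in `neuron_params()`):
$C = 120$ pF, $E_e = 0$, $E_i = -75$, $E_L = -70$, $E_T = -50$,
$V_r = -60$ mV, $g_L = 7.14$ nS (membrane time constant $\approx 16.8$ ms),
$t_\mathrm{ref} = 2$ ms, $\tau_e = \tau_i = 1$ ms.

The network (`network_params()`, `build_network()`) has $N_e = 160$
excitatory and $N_i = 40$ inhibitory units. Every potential directed
connection exists independently with probability $CP_e = 0.15$ from
excitatory sources and $CP_i = 1$ from inhibitory sources; weights are
drawn from a Gaussian with mean $J$ ($J_e = 1$ nS, $J_i = 3$ nS) and
standard deviation $J/5$, then clipped at zero so each unit's outgoing
synapses keep a single sign (Dale's law). Every unit receives independent
homogeneous Poisson background input at $\nu_{bkg,e} = 970$ Hz (excitatory)
and $\nu_{bkg,i} = 220$ Hz (inhibitory), each event delivered with the mean
peak conductance. A visual stimulus is a 500-ms excitatory Poisson train at
$\nu_{stim} = 200$ Hz to **all** units.

Receptor activation (`perturbation_spec()`) is extra Poisson drive to an
"activated" subset of units:

| mode | activated units | extra excitatory | extra inhibitory |
|---|---|---|---|
| `selective_e` | fraction of E units | 50 Hz | 0 |
| `selective_i` | fraction of I units | 100 Hz | 0 |
| `systemic` | fraction of E *and* I units | 29.5 kHz | 27 kHz |

The selective-mode rate to inhibitory units is twice the excitatory-unit
rate, reflecting the somatic (PV) versus dendritic (pyramidal) localisation
of the receptor. In systemic mode the same two rates are applied to
activated units of both populations; the "twice as high" rule is read as
describing only the two selective rows, which is how the parameter table
separates them. The activated fraction is a free parameter standing in for
both the PV share of the inhibitory population and variable receptor
expression.

### Numerical scheme

The integrator (C++ core, `simulate_network()`) is exponential Euler on
$V_m$ at `dt = 0.1` ms: within a step, conductances are held and $V_m$
relaxes exactly toward the instantaneous equilibrium. This remains stable
in the systemic condition, where the total conductance exceeds 300 nS and
the effective membrane time constant drops below 0.5 ms — the shunting
regime at the heart of the mechanism. The alpha synapse is propagated as
the exact solution of its two-state linear filter, so kernel shape does not
degrade with `dt`; external Poisson events are drawn as per-step counts
(exact in law for piecewise-constant rates, and efficient at the
multi-kilohertz systemic rates). Choices the underlying experiments do not
constrain, fixed here once:

* **Synaptic delays** are zero; a recurrent spike takes effect on the next
  integration step.
* **Threshold handling**: a spike is registered when $V_m \ge E_T$ at the
  end of a step, with no interpolation.
* **Refractory semantics**: $V_m$ is clamped at $V_r$ while refractory;
  synaptic conductances keep evolving.
* **Initial condition**: $V_m(0) = E_L$ (overridable per unit); protocol
  runs discard a 1-s settling period.
* **External event weights** use the population mean peaks $J_e$/$J_i$;
  only recurrent connections carry per-connection Gaussian weights.

A convergence test (halving `dt` changes the population rate by under 5%),
a closed-form leak-decay check to 0.1 mV, and a 1-µs-step single-event
reference keep these choices honest.

### Why the mechanism works: fluctuation-driven operation

Under the default background drive the mean membrane potential sits near
−55 mV, below threshold: spikes are caused by voltage *fluctuations*, not
by the mean current. Balanced extra excitatory and inhibitory input leaves
the mean potential in place but moves the fluctuation amplitude
non-monotonically: at low conductance added input increases fluctuations
(rate rises), while at high conductance shunting shortens the effective
time constant and each synaptic event deflects the voltage less (rate
falls). The package demonstrates this inverted-U directly on a single
unit receiving balanced drive scaled by a factor $k$ (see
`test-acceptance.R`): the rate rises from ~1 Hz through a ~20-Hz peak and
collapses again by $k \sim 10^3$. Systemic receptor activation parks the
network high on this curve: spontaneous rates are nearly unchanged, but
the driving force and effective gain for an *additional* sensory input are
reduced — gain control without baseline change.

## Protocols

`condition_protocol()` encodes the four condition blocks — spontaneous
(`S`), visual (`V`), and their photostimulated counterparts (`S_ph`,
`V_ph`) — in two stock layouts:

* **experimental**: 21-s trials; six 200-ms stimuli at 3-s intervals
  starting 4 s into the trial; 8-s photostimulation beginning 1.8 s after
  the first stimulus onset. This is the timing the synthetic-session
  generator uses, and the timing all analysis-window defaults assume.
* **model**: compact simulation trials — 1 s settling (discarded), 2 s
  pre-stimulus, one 500-ms stimulus, 1 s post; in `*_ph` runs the
  perturbation is on for the whole analyzed span.

`sweep_activation_fraction()` repeats the model experiment over a grid of
activated fractions with independent connectivity instances and input
realizations, mirroring the 10 × 10 instance/realization aggregation
design at a configurable scale. Two operationalizations are fixed here
because the model figures plot them without formulas: **baseline change**
is the percent change of the pre-stimulus population rate against the
unperturbed run of the same instance and realization (which shares its
input seed, so fraction 0 reproduces the control bit-for-bit), and
**evoked magnitude** is the stimulus-window rate minus the pre-stimulus
rate, expressed as percent change of the control value over the same
units. The seed ledger is two-level: the instance seed fixes connectivity
and the activated-unit draw; the realization seed fixes all Poisson
inputs.

`mean_driven_superposition()` computes the linear (mean-driven) prediction
for systemic activation by summing the selective-E and selective-I percent
changes per fraction — percent-scale superposition, matching how the
selective results are summarised. The headline dissociation is that this
prediction shows no substantial pyramidal gain suppression, while the full
fluctuation-driven systemic simulation
(`compare_systemic_conductance()`) suppresses evoked magnitude strongly at
unchanged baseline.

The default test scale — 3 instances × 3 realizations over fractions
{0, 0.25, 0.5} at $N = 200$ units — was chosen as the smallest design in
which all six directional effects of the selective modes are stable across
seeds; larger designs sharpen, but do not change, the signs.

## The analysis stack

All analyses operate on a `spike_session()`: spikes by unit × trial ×
condition plus protocol timing and per-unit metadata, written/read as
plain CSV (`write_session()`/`read_session()`).

* `classify_units()`: narrow-spiking units (trough-to-peak < 0.5 ms) are
  putative inhibitory, broad-spiking (> 0.5 ms) putative excitatory. The
  boundary itself is unassigned by the rule's strict inequalities; exactly
  0.5 ms is assigned to putative excitatory (configurable).
* `bin_and_average()`: 200-ms spike-count bins, averaged across trials of
  each condition; a trailing partial bin is dropped.
* `exclude_low_rate()`: units with baseline firing below 0.5 Hz are
  excluded to avoid floor effects. "Baseline" is the S-condition mean over
  the first 3 s of the trial — the same window the spontaneous
  normalization uses, which is why exclusion guarantees a positive
  divisor.
* `normalize_spontaneous()` divides each unit's S and S_ph traces by its
  S-condition 3-s baseline; `normalize_evoked()` subtracts the 1-s
  pre-first-stimulus rate and divides by the control (V) first-stimulus
  response amplitude (600-ms window), making the control first response
  exactly 1. Units with non-positive control amplitude cannot be
  normalized and are dropped with a flag.
* `compute_oi()`: the opto-index $OI = (POST - PRE)/(POST + PRE)$, PRE
  over the first 3 s of the trial, POST over the last 3 s of the
  photostimulation window. For protocols whose photostimulation is shorter
  than 6 s, POST is its second half, keeping PRE/POST durations
  comparable. $OI$ is undefined (NA, reported but excluded from
  summaries) when both windows are silent.
* `response_magnitude()`: 600-ms post-onset mean minus 1-s pre-onset
  mean, per stimulus; `gain_observations()` stacks stimulus #1 (before
  photostimulation) as $r_{pre}$ against the mean of stimuli #2–4 (during
  photostimulation) as $r_{post}$, for both V ($ph = 0$) and V_ph
  ($ph = 1$).
* `fit_gain_regression()`: ordinary least squares on
  $r_{post} = \beta_1 + \beta_2 r_{pre} + \beta_3\,ph + \beta_4\,ph\cdot r_{pre}$
  with conventional standard errors ("linear regression" is all the
  definition fixes; OLS is the plain reading). $\beta_3$ is a subtractive
  shift, $\beta_4$ a divisive slope change, and $\beta_4/\beta_2$ the
  fractional gain change. Inputs are pre-normalized to the maximum
  observed magnitude across the pooled (V, V_ph) data — "the unit with the
  highest firing rate" is read as the maximum pooled magnitude, the only
  choice that leaves the two conditions on one scale.

## LFP analysis

`preprocess_lfp()` low-passes at 300 Hz with a zero-phase FIR filter
(Hamming-window design, order 400, forward–backward application, unity DC
gain) and then decimates to 1 kHz. Filtering is done *before* decimation
even though the described order is "downsample, then filter", because the
reverse order would alias; the stop band is −99% by 400 Hz, the pass band
flat to <1% at 10 Hz. `amplitude_spectrum()` returns the single-sided FFT
amplitude averaged over trials/channels and normalized to its peak
(maximum exactly 1). `band_power()` summarises the canonical bands — slow
0–1, delta 1–4, theta 4–8, alpha 8–12, beta 12–30, gamma 30–70 Hz — with
half-open edges $[lo, hi)$ assigning an edge bin to the lower band, and
reports both the mean per-bin power (a PSD summary) and the
band-integrated power, since the verbal definition does not distinguish
them; the all-frequency power sum satisfies Parseval against the
time-domain mean square to numerical precision. `lfp_spectrogram()` is a
Hann-window STFT (1-s window, 50% overlap by default; the source analyses
name no window).

## Connectivity inference

`cross_correlogram()` histograms $t_B - t_A$ in 0.5-ms bins centered on
lag multiples over ±25 ms, so reversing the pair mirrors the correlogram
exactly. `detect_monosynaptic()` looks for a fast transient increase
(excitatory) or decrease (inhibitory) at ~2-ms delay, searching lags
1–4 ms. The significance rule in the source methods is delegated to cited
prior work and not spelled out; the rule implemented here is a documented
stand-in, not a reconstruction: a spike-jitter surrogate (B jittered
uniformly by ±10 ms, 200 surrogates) with the observed max/min bin count
over the detection window compared against the surrogate distribution of
the same statistic — a familywise-calibrated, conservative criterion whose
false-positive rate on independent Poisson pairs stays within the nominal
$\alpha$ (validated by test).

## The synthetic-session generator

`generate_session()` produces sessions with the statistical structure the
analysis assumes, plus ground truth, so every analysis-stage property is
testable end-to-end without the simulator:

* **Baseline rates** are log-normal (median 4 Hz, $\sigma_{\log} = 0.6$) —
  heavy-tailed like cortical rate distributions, with a realistic sliver
  of units under the 0.5-Hz floor so the exclusion filter is exercised.
* **Trough-to-peak** times are a two-Gaussian mixture at 0.25 and 0.85 ms
  (SD 0.05), straddling the 0.5-ms boundary as in real waveform data.
* **Photostimulation modulation** rises as $1 - e^{-t/\tau}$ with
  $\tau = 2$ s to a sustained plateau — the slow, sustained kinetics
  characteristic of GPCR signalling (the exact kinetics are cosmetic for
  testing and configurable). The amplitude is calibrated in closed form so
  the mean rate over the opto-index POST window equals the rate implied by
  the unit's target opto-index; the realized OI therefore equals the
  target in expectation regardless of $\tau$.
* **Visual responses** add a 600-ms boxcar per stimulus; stimuli falling
  inside the photostimulation window in V_ph have amplitude
  $d \cdot a + s$, planting a known divisive factor $d$ and subtractive
  offset $s$ for regression-recovery tests.
* Spikes are sampled as inhomogeneous Poisson by thinning; infeasible
  specs (negative rates after modulation) are rejected.

`generate_lfp()` adds $1/f$-coloured noise with optional gated band
oscillations; `generate_connected_pair()` plants excitatory echoes
(Bernoulli efficacy at fixed lag) or gated suppression for the
correlogram detector.

What the generator deliberately does **not** emulate: spike-sorting
artifacts, electrode drift, waveform time series, bursting/adaptation, or
anesthesia-state dynamics. Passing recovery tests on synthetic sessions
therefore demonstrates the correctness of the analysis arithmetic and its
statistical calibration under the assumed model — not robustness to every
pathology of real recordings.

## Known limitations

* The network is the reduced (200-unit) variant with simple (not
  exponential) integrate-and-fire units and no orientation-tuned
  feedforward structure or explicit lateral-interaction nonlinearities;
  effects of selective activation in local subpopulations may be
  underestimated.
* The absolute spontaneous rate of the default operating point is an
  emergent property (~4–5 Hz here), not a calibrated target; no published
  value pins it.
* In-vivo effect-size percentages depend on the recorded populations and
  are treated as directional context; the package asserts signs and
  dissociations, not those magnitudes.
* Contrast–response (normalization) behaviour is out of scope.
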