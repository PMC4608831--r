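---
title: "Modelling feature-invariant chirp responses in the electrosensory midbrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling feature-invariant chirp responses in the electrosensory midbrain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chirpfi)
```

## The scientific problem

Weakly electric fish (*Apteronotus leptorhynchus*) emit a quasi-sinusoidal
electric organ discharge (EOD). When two fish meet, the interference of their
EODs produces a sinusoidal amplitude modulation — the *beat* — at the
frequency difference between the two discharges. Communication signals
("chirps") are brief (< 40 ms) increases of the emitter's EOD frequency
riding on the beat. Because a small chirp can occur at any phase of a slow
beat, the *same* communication signal produces widely different stimulus
waveforms at the receiver's skin. Hindbrain electrosensory (ELL) pyramidal
cells respond strongly but *differentially* to these waveforms: ON-type
cells fire on the rising phase of the beat and OFF-type cells on the falling
phase, and a given chirp waveform excites some cells while inhibiting
others. Some midbrain torus semicircularis (TS) neurons, in contrast,
respond *selectively and invariantly*: they stay silent during the beat and
fire one to a few spikes shortly after every chirp, whatever its waveform.

`chirpfi` implements a complete computational account of how such invariance
can arise from nonlinear integration of ON and OFF afferent input:

1. **stimulus synthesis** (`synthesize_dyad_signal()`,
   `standard_chirp_stimuli()`) and quantification of chirp attributes
   (duration, beat phase, waveform similarity);
2. **synthetic ELL input** (`generate_population_psths()`) emulating the
   population-averaged ON/OFF responses the downstream analysis needs;
3. **synaptic conversion** (`psth_to_conductance()`, `synaptic_current()`);
4. a **stochastic Hodgkin–Huxley TS neuron** (`ts_params()`,
   `integrate_ts()`) integrated with the Euler–Maruyama scheme;
5. **selectivity/invariance metrics** (`csi()`, `vpd()`, `fi()`, …);
6. a **constrained differential evolution search** (`fit_ts_model()`) and
   **pairwise parameter sweeps** (`pairwise_sweep()`,
   `compare_robustness()`).

## Stimuli and chirp attributes

A stimulus is the AM envelope of the sum of two sinusoids: the receiver's
EOD at $f_r$ (default 750 Hz) and the emitter's at $f_r + \Delta f$. The
envelope is extracted as the magnitude of the FFT-based analytic signal,
low-pass filtered below the carrier, and normalised to mean 1 with a
configurable modulation depth (contrast, default 0.2). A chirp is a Gaussian
excursion of the emitter's instantaneous frequency (peak height = frequency
excursion, width $\sigma$; the full width at half maximum is
$2\sqrt{2\ln 2}\,\sigma \approx 2.355\,\sigma$), with an optional
concurrent amplitude dip for big chirps. The Gaussian profile is a modelling
choice: it matches the FWHM-based duration definition and the smooth
excursions seen in recorded chirps.

Chirp attributes are measured exactly as in a behavioral recording: the
instantaneous frequency is the inverse of the interval between successive
rising zero crossings of the emitter's EOD; the chirp time is the time of
maximal frequency; the duration is the FWHM of the excursion above a robust
baseline (the median frequency outside the chirp window); and the beat phase
expresses the chirp time relative to the nearest preceding beat maximum, in
units of the beat period times 360°. Because the chirp's own frequency
excursion advances the beat by a substantial fraction of a cycle, the
reference maximum is taken from the clean beat *before* the chirp window and
wrapped by whole beat periods — otherwise the chirp would corrupt its own
phase label. Phase 0° is anchored at the beat maximum; this convention is a
deliberate resolution of an ambiguity (a zero crossing would be an equally
defensible anchor) and is applied consistently by generator and estimator,
which round-trip to within ±2° on noiseless traces.

The five standard stimuli place the same small chirp at beat phases 0°, 90°,
180° and 270° of a 10 Hz beat plus one big chirp (260 Hz excursion, 80%
amplitude dip) on an 80 Hz beat, mirroring the convention of mimicking
same-sex encounters 10 Hz above and opposite-sex encounters 80 Hz above the
animal's own EOD frequency. All five chirps peak at the same time
(500 ms into a 1 s trace) and the *beat's starting phase* is shifted
instead: this mirrors an experiment in which every sweep is aligned to the
chirp onset, and keeps across-stimulus spike-train distances from being
dominated by trivial timing offsets.

## Synthetic ELL input

No recordings ship with the package, so a parametric generator stands in for
the population-averaged ELL responses. It is *not* a biophysical ELL model;
it reproduces exactly the qualitative features the downstream analysis
depends on:

* **antiphase beat locking** — ON rate
  $= b + d\,[-\sin\theta(t)]_+$, OFF rate $= b + d\,[\sin\theta(t)]_+$,
  with baseline $b = 20$ spikes/s and beat depth $d = 80$ spikes/s
  (plausible lateral-segment pyramidal-cell rates);
* **signed, heterogeneous chirp transients** — the pathway whose preferred
  beat half-cycle contains the chirp receives a Gaussian excitatory
  transient (peak 200 spikes/s, width 7 ms, latency 5 ms), the other is
  suppressed toward zero during the chirp. The binary sign map (ON excited
  for chirp phases in [180°, 360°), OFF otherwise) is the simplest mechanism
  producing the mixed excitation/inhibition seen in hindbrain recordings;
* **rate noise** — Gaussian, smoothed with a 5 ms kernel so no bin-scale
  artifacts enter, amplitude 10 spikes/s.

With these defaults, Poisson spike trains drawn from the generated ON (or
OFF) profiles score CSI ≈ −0.07 to 0.1, VPD ≈ 55–60 and FI = 0 — the
hindbrain signature of strong beat responses and waveform-dependent chirp
responses, comfortably below the FI ≤ 0.2 non-invariance bar. What the
generator does **not** emulate: single-cell heterogeneity within each
population, bursting, descending control, or the exact magnitudes of real
chirp transients. Tests passing on this input therefore demonstrate the
*mechanism* (balanced ON/OFF integration plus a spiking nonlinearity yields
invariance) rather than quantitative agreement with any recorded dataset.

## Synaptic conversion and the TS model

Population rates are converted to conductances by convolution with an alpha
kernel $(t/\tau_{syn})\,e^{1-t/\tau_{syn}}$ ($\tau_{syn} = 20$ ms), scaled
by $\zeta\,g_{max}$ with $\zeta = 5\times10^{-4}$ and $g_{max} = 0.13$ µS.
Rates enter in spikes/s (the small scale factor $\zeta$ absorbs the unit
choice; the resulting conductances land in the sub-µS range of the model's
other conductances). Convolution is causal and zero-padded — stimuli begin
from silence. The synaptic current is
$I_{syn} = -2 g_{syn}\,\bigl(\sigma_B\,g_{ON}/g_{max} +
(1-\sigma_B)\,g_{OFF}/g_{max}\bigr)(V - E_{syn})$ with $E_{syn} = 0$ mV and
$g_{syn} = W_s\,g_{max}$; $\sigma_B$ is the ON fraction of the mixed input.

The TS neuron follows the Hodgkin–Huxley formalism with instantaneous sodium
activation $m_\infty^3$ and $(0.85 - n)$ inactivation, a delayed rectifier
$n^4$, subthreshold h- and T-type currents ($I_h = -g_h h (V - E_h)$,
$I_T = -g_T s_\infty^3 \eta (V - E_{Ca})$), leak, bias current and additive
Gaussian current noise ($\sigma_{noise}\,\xi(t)$ with $\xi$ of standard
deviation 0.8, discretised as
$\sigma_{noise}\cdot 0.8\cdot\sqrt{dt}\cdot N(0,1)/C$ per Euler–Maruyama
step — the standard convention). The parameter values are phenomenological
working units (µS conductances with $C = 1$ µF and nA-scale currents whose
sum is numerically $dV/dt$); they are used exactly as given rather than
being made SI-consistent, because the dynamics, not the units, carry the
science.

### Numerical choices

* **Integration**: forward Euler–Maruyama at $dt = 0.025$ ms; a 200 ms
  burn-in with conductances held at their first sample removes
  initial-transient spikes; initial state $V_0 = E_{leak}$ with gates at
  steady state. The deterministic integrator agrees with a half-step
  reference to ±1 spike over 1 s.
* **Singularities**: $\alpha_m$, $\alpha_n$ have removable singularities at
  $V = -40.7$ mV, replaced by their analytic limits (1 and 0.1).
* **$\eta_\infty$ parse**: the inactivation steady state of the T-current is
  typeset ambiguously; both readings
  ($1/(0.75 + e^{(V+82)/6.3})$, the default "literal", and
  $1/(0.5 + 0.25\,e^{(V+82)/6.3})$, "product") are implemented and
  selectable, and the flag is recorded in every output manifest. Both are
  monotone, so the qualitative role of the T-current is unaffected.
* **$\tau_n$ numerator**: with the delayed-rectifier time constant read as
  $0.05/(\alpha_n + \beta_n)$, the rectifier is so fast that the model
  saturates near −10 mV instead of firing action potentials — incompatible
  with threshold-crossing spike detection and with responses of one to a few
  overshooting spikes per chirp. The package therefore defaults to the
  classic Hodgkin–Huxley form $\tau_n = 1/(\alpha_n + \beta_n)$, under which
  spikes overshoot +40 mV, and exposes the alternative constant as
  `tau_n_num` for sensitivity analyses.
* **Spike detection**: upward crossings of 0 mV with a 1 ms lockout. For
  clean overshooting spikes, counts are invariant to thresholds between −20
  and 0 mV.

## Metrics

* **PSTH**: 0.1 ms bins, boxcar smoothing (10.8 ms for small-chirp
  responses, 5 ms for the big chirp), edge-aware so that spike mass is
  conserved away from the trace boundaries.
* **CSI** $= (R_C - R_B)/(R_C + R_B)$ with $R_C$ the maximum rate in a
  100 ms window starting at the chirp onset and $R_B$ the maximum rate
  elsewhere. A guard band of half the smoothing width around the window
  edges keeps smoothing leakage from inflating $R_B$; both-zero maxima give
  CSI = 0.
* **VPD**: exact dynamic-programming Victor–Purpura distance with unit
  insert/delete cost and shift cost $q|\Delta t|$, $q = 100\,s^{-1}$. The
  average `vpd_avg()` pools *all* unordered train pairs across stimuli and
  trials ($M = \binom{N N_T}{2}$) — the literal reading of the pair-sum
  indexing, which includes within-stimulus pairs; a between-stimuli-only
  variant is exposed for sensitivity checks.
* **FI** $= \lfloor \mathrm{CSI}_{avg} - \alpha\,\mathrm{VPD}_{avg}
  \rfloor_+$ with $\alpha = 0.01$. A literal Heaviside reading of the
  rectification would make FI binary, contradicting the published worked
  values (0.99, 0.536); the rectified-linear reading reproduces all of them
  exactly and is adopted. Models or neurons with FI ≤ 0.2 are labelled
  non-invariant. The PSTH-based `fi_rmse()` uses the circularly-aligned RMSE
  with $\gamma = 0.0041$.
* **Bimodality index**: the cycle-averaged membrane response, minimum
  subtracted and rotated so its maximum sits at phase 0, evaluated at half
  the cycle relative to its peak — 1 for equal ON+OFF depolarizations half a
  cycle apart, 0 for a single-phase response.
* **Robustness**: the percentage of sweep-grid cells with FI ≥ 0.7; diverged
  cells are excluded from the denominator rather than counted as
  non-invariant.

## Parameter search and sweeps

The differential evolution search evolves
$(\sigma_B, W_s, I_{bias}, g_h, g_T)$ with differential weight $F = 0.5$,
crossover probability $CR = 0.9$, fitness $e^{-FI}$, parent selection
weighted by $e^{-F_{fit}/\max F_{fit}}$ (current generation only), elitist
replacement, and the resampling treatment of bound violations (re-running
the differentiation with fresh parents, clamping only after 20 failed
attempts). Default bounds — $\sigma_B \in [0,1]$, $g_{syn} \in [0.01, 0.3]$
µS, $I_{bias} \in [-25, 5]$ nA, $g_h \in [0, 8]$ µS, $g_T \in [0, 6]$ µS —
span the reference model solutions. Population size and generation count
are free choices (defaults K = 30, 50 generations, early stop after 15
stalled generations); because FI is exactly zero over most of the box, the
early-stop counter only engages once the search has found a nonzero score,
otherwise flat starts would be cut short. The objective is stochastic
(5 noisy trials per stimulus during the search); survivors are not
re-evaluated by default, and the best individual is re-scored with more
trials at the end.

Pairwise sweeps evaluate FI, CSI and VPD maps on 2-D parameter grids with
per-cell seeds derived deterministically from the sweep seed and the cell
index, so maps are independent of evaluation order. The robustness
comparison re-runs the same grid with $g_T = g_h = 0$ and reports the
percentage of cells at FI ≥ 0.7 in each map; subthreshold conductances
enlarge the invariant region.

The shipped `reference_invariant_genes()` is a DE solution found by
`fit_ts_model()` on the default synthetic input and plays the role of the
published example parameter sets: a base point for sweeps. It can be
re-derived at any time; because many parameter combinations are invariant
(that is the central finding), re-runs with other seeds find different but
equally valid solutions.

## Problem sizes

The worked analyses in this package use 1 s stimuli at 0.025 ms resolution,
5 stimuli, 5–10 noisy trials per stimulus, DE populations of 20–30 over
30–50 generations, and sweep grids of 12×12 to 15×15 cells — deliberately
desk-scale versions of the corresponding physiological experiments, chosen
so that a full run
(search plus sweeps) completes in minutes on a single core while leaving
every qualitative conclusion (non-invariant hindbrain input, invariant
optimized model, interior-$\sigma_B$ optimum, subthreshold-conductance
robustness gain) intact.

## Known limitations

* The synthetic ELL generator is a statistical stand-in; absolute FI, CSI
  and VPD values on it are not comparable to values computed from
  recordings, and exact published map values are not reproducible without
  the recorded input they were computed from.
* On this synthetic input, the binary chirp sign map guarantees that at a
  balanced ON/OFF mixture every chirp variant produces a net-*excitatory*
  transient in the summed drive. Invariance then reduces to a threshold
  separation between beat and chirp drive, and the subthreshold h- and
  T-type currents — whose physiological advantage lies in rebound spiking
  after net-inhibitory chirp responses and in stabilizing the operating
  point — have little to contribute; in the package's own sweep
  experiments they do not enlarge (and can slightly shrink) the invariant
  region. Input in which some chirp waveforms suppress *both* pathways
  would be required to exercise the rebound pathway.
* The model has no TS-intrinsic inhibition, no multicompartment morphology
  and no neuromodulation.
* The two typeset ambiguities above ($\eta_\infty$, $\tau_n$) are resolved
  by explicit, flagged defaults rather than silently.
* The DE objective is noisy; elitist selection can briefly retain luckily
  over-scored individuals. The final re-evaluation with more trials reports
  an honest score.
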