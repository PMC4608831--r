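# chirpfi

Feature-invariant midbrain responses to electrocommunication chirps: a
tested, reproducible implementation of the full computational pipeline —
stimulus synthesis, synthetic hindbrain input, a stochastic Hodgkin–Huxley
midbrain neuron, invariance metrics, differential-evolution parameter
search, and parameter-sweep robustness analyses.

## The problem

Weakly electric fish communicate with "chirps": brief (< 40 ms) increases
of the emitter's electric organ discharge (EOD) frequency, superimposed on
the sinusoidal *beat* created by the interference of two fishes' EODs.
Because a small chirp can land on any beat phase, one and the same signal
produces very different stimulus waveforms. Hindbrain (ELL) ON- and
OFF-type pyramidal cells respond strongly to the beat and differentially to
each chirp waveform; some midbrain torus semicircularis (TS) neurons
instead respond *selectively and invariantly* — silent during the beat, one
to a few spikes after every chirp, whatever its waveform.

The package asks, and answers with a model: what does a TS neuron need in
order to turn non-invariant ON/OFF afferent input into an invariant chirp
detector?

## The quantities at its core

For a set of $N$ chirp stimuli with $N_T$ trials each:

* **Chirp selectivity index**
  $\mathrm{CSI} = (R_C - R_B)/(R_C + R_B)$, where $R_C$ and $R_B$ are the
  maximal PSTH rates during the chirp window (100 ms from chirp onset) and
  the beat, respectively; $\mathrm{CSI}_{avg}$ averages over stimuli.
* **Victor–Purpura distance** (VPD): edit-cost metric between spike trains
  (insertions/deletions cost 1, shifts cost $q\,|\Delta t|$ with
  $q = 100\,\mathrm{s^{-1}}$); $\mathrm{VPD}_{avg}$ averages over all
  $\binom{N N_T}{2}$ unordered train pairs pooled across stimuli and
  trials.
* **Feature invariance score**
  $\mathrm{FI} = \left[\mathrm{CSI}_{avg} - \alpha\,\mathrm{VPD}_{avg}\right]_+$
  with $\alpha = 0.01$ — high only for responses that are both selective
  for chirps and similar across chirp waveforms. FI ≤ 0.2 counts as
  non-invariant.

The model TS neuron is a Hodgkin–Huxley point neuron (spiking Na and
delayed-rectifier K currents, subthreshold h- and T-type currents, leak,
bias current, Gaussian current noise) driven by a weighted mixture
($\sigma_B$ : ON, $1-\sigma_B$ : OFF) of population firing rates converted
to conductances through an alpha synapse ($\tau_{syn} = 20$ ms), integrated
with the Euler–Maruyama scheme at $dt = 0.025$ ms. A constrained
differential evolution search ($F = 0.5$, $CR = 0.9$, fitness $e^{-FI}$,
fitness-weighted parent selection, resampling bound handling) looks for
parameter combinations $(\sigma_B, W_s, I_{bias}, g_h, g_T)$ maximizing FI.

## Worked example

```r
library(chirpfi)

# five standard stimuli: one small chirp at beat phases 0/90/180/270 deg
# on a 10 Hz beat, plus a big chirp on an 80 Hz beat
stim  <- standard_chirp_stimuli()
pairs <- generate_population_psths(stim, seed = 42)   # synthetic ELL input

# hindbrain benchmark: Poisson trains from the ON population profile
set.seed(11)
ell <- lapply(pairs, function(p) generate_spike_trains(p$on_rate, p$bin_ms, 10))
kinds <- vapply(pairs, `[[`, character(1), "kind")
onsets <- vapply(pairs, `[[`, numeric(1), "chirp_onset")
res_ell <- evaluate_invariance(ell, onsets, 1000,
                               smooth_ms = ifelse(kinds == "big", 5, 10.8))
round(c(csi = res_ell$csi_avg, vpd = res_ell$vpd_avg, fi = res_ell$fi), 3)
#>    csi    vpd     fi
#> -0.071 59.448  0.000

# model TS neuron at the packaged reference parameter set
g <- reference_invariant_genes()
params <- ts_params(I_bias = g$I_bias, g_h = g$g_h, g_T = g$g_T)
syn <- synaptic_config(sigma_B = g$sigma_B, W_s = g$W_s)
set.seed(1)
ts <- lapply(pairs, simulate_trials, params = params, syn_cfg = syn,
             n_trials = 10)
res_ts <- evaluate_invariance(ts, onsets, 1000,
                              smooth_ms = ifelse(kinds == "big", 5, 10.8))
round(c(csi = res_ts$csi_avg, vpd = res_ts$vpd_avg, fi = res_ts$fi), 3)
#>   csi   vpd    fi
#> 0.800 0.658 0.793
```

The synthetic hindbrain input scores FI = 0 (strong beat responses,
waveform-dependent chirp responses), while the model driven by a balanced
ON/OFF mixture of exactly that input is strongly invariant (FI ≈ 0.8 at
this noise realization; fresh searches with `fit_ts_model()` find
solutions re-evaluating at FI ≈ 0.99): it stays essentially silent during
the beat and fires a short burst after every chirp.
`pairwise_sweep()` / `compare_robustness()` then map where in parameter
space invariance survives — including the roles of the ON/OFF balance
`sigma_B` and of the subthreshold h- and T-type conductances.

See the vignette (`vignettes/feature-invariance-model.Rmd`) for the model
equations, parameter meanings, and every numerical design choice.

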