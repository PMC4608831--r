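#' Synaptic configuration
#'
#' Constants converting ELL population firing rates into the excitatory
#' synaptic drive of the model TS neuron. Rates are convolved with an alpha
#' function `(t/tau_syn) exp(1 - t/tau_syn)` and scaled by `zeta * g_max`;
#' the resulting ON and OFF conductances are mixed with weights `sigma_B`
#' and `1 - sigma_B` and scaled by `W_s`. The effective maximal synaptic
#' conductance reported throughout is `g_syn = W_s * g_max`.
#'
#' @param zeta Dimensionless rate-to-conductance scale factor.
#' @param g_max Maximal synaptic conductance unit (uS).
#' @param tau_syn Synaptic time constant (ms).
#' @param sigma_B Fraction of ON-type input, in `[0, 1]`.
#' @param W_s Dimensionless synaptic weight; `g_syn = W_s * g_max`.
#' @param E_syn Reversal potential of the excitatory synapse (mV).
#' @return A list of class `synaptic_config` (with derived element `g_syn`).
#' @export
synaptic_config <- function(zeta = 5e-4, g_max = 0.13, tau_syn = 20,
                            sigma_B = 0.5, W_s = 1, E_syn = 0) {
  if (zeta <= 0 || g_max <= 0 || tau_syn <= 0)
    stop("zeta, g_max and tau_syn must be positive")
  if (sigma_B < 0 || sigma_B > 1) stop("sigma_B must lie in [0, 1]")
  structure(list(zeta = zeta, g_max = g_max, tau_syn = tau_syn,
                 sigma_B = sigma_B, W_s = W_s, E_syn = E_syn,
                 g_syn = W_s * g_max),
            class = "synaptic_config")
}

#' Convert a firing-rate profile into a synaptic conductance
#'
#' Causal convolution of the rate (spikes/s) with the alpha kernel
#' `alpha(t) = (t/tau_syn) exp(1 - t/tau_syn)` (unit peak at `t = tau_syn`,
#' integral `e * tau_syn` ms), scaled by `zeta * g_max`. The trace is
#' zero-padded at the start (stimuli begin from silence), so a constant rate
#' `r` converges to the steady state `zeta * g_max * r * e * tau_syn`.
#'
#' @param rate Non-negative firing rates (spikes/s), one per bin.
#' @param bin_ms Bin width (ms).
#' @param cfg A [synaptic_config()].
#' @return Numeric conductance series (uS), same length as `rate`.
#' @export
psth_to_conductance <- function(rate, bin_ms, cfg = synaptic_config()) {
  if (any(rate < 0)) stop("rates must be non-negative")
  if (bin_ms <= 0) stop("bin_ms must be positive")
  tk <- seq(0, 10 * cfg$tau_syn, by = bin_ms)
  kern <- (tk / cfg$tau_syn) * exp(1 - tk / cfg$tau_syn)
  n <- length(rate)
  k <- length(kern)
  # exact time-domain causal convolution, zero-padded at the start
  conv <- stats::filter(c(rep(0, k - 1), rate), kern, method = "convolution",
                        sides = 1)
  cfg$zeta * cfg$g_max * bin_ms * as.numeric(conv[(k - 1) + seq_len(n)])
}

#' Instantaneous mixed ON/OFF synaptic current
#'
#' `I_syn = -2 g_syn (sigma_B g_on/g_max + (1 - sigma_B) g_off/g_max)
#' (V - E_syn)` with `g_syn = W_s g_max`. Linear in each conductance, zero at
#' the synaptic reversal potential, and depolarizing (positive in the model's
#' sign convention) whenever `V < E_syn`.
#'
#' @param V Membrane potential (mV); may be a vector.
#' @param g_on,g_off ON and OFF conductances (uS), scalars or vectors
#'   conformable with `V`.
#' @param cfg A [synaptic_config()].
#' @return Synaptic current in the model's internal current unit.
#' @export
synaptic_current <- function(V, g_on, g_off, cfg = synaptic_config()) {
  if (any(g_on < 0) || any(g_off < 0)) stop("conductances must be non-negative")
  -2 * cfg$W_s * (cfg$sigma_B * g_on + (1 - cfg$sigma_B) * g_off) *
    (V - cfg$E_syn)
}
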