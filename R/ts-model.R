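#' Parameters of the stochastic TS neuron model
#'
#' Conductance-based (Hodgkin-Huxley formalism) point-neuron model of a torus
#' semicircularis (TS) neuron with spiking sodium and delayed-rectifier
#' potassium currents, subthreshold h- (HCN) and low-threshold T-type calcium
#' currents, leak, a constant bias current, mixed ON/OFF excitatory synaptic
#' input, and additive Gaussian current noise. The parameter values are the
#' model's phenomenological working units (capacitance 1, currents numerically
#' equal to dV/dt contributions); they are not meant to be SI-consistent.
#'
#' @param C Membrane capacitance (uF).
#' @param g_Na,g_K,g_leak,g_h,g_T Maximal conductances (uS).
#' @param E_Na,E_K,E_leak,E_h,E_Ca Reversal potentials (mV).
#' @param I_bias Constant bias current (nA).
#' @param sigma_noise Noise intensity (nA).
#' @param noise_sd Standard deviation of the white-noise process xi(t).
#' @param Phi Temperature-like factor on the T-current inactivation kinetics.
#' @param tau_eta Time constant of T-current inactivation (ms).
#' @param dt Integration time step (ms).
#' @param eta_parse `"literal"` or `"product"`: two readings of the typeset
#'   steady-state T-current inactivation; `"literal"` uses
#'   `1/(0.5 + 0.25 + exp((V+82)/6.3))`, `"product"` uses
#'   `1/(0.5 + 0.25 exp((V+82)/6.3))`. Both are monotone in V.
#' @param tau_n_num Numerator constant of the delayed-rectifier time constant
#'   `tau_n = tau_n_num / (alpha_n + beta_n)`. The default 1 is the classic
#'   Hodgkin-Huxley form and yields overshooting action potentials; the
#'   alternative reading 0.05 makes the rectifier so fast that the model
#'   saturates below 0 mV instead of spiking.
#' @return A list of class `ts_params`.
#' @export
ts_params <- function(C = 1, g_Na = 30, g_K = 10, g_leak = 0.18, g_h = 7,
                      g_T = 0.32, E_Na = 60, E_K = -85, E_leak = -65,
                      E_h = -30, E_Ca = 120, I_bias = 0, sigma_noise = 1,
                      noise_sd = 0.8, Phi = 2, tau_eta = 30, dt = 0.025,
                      eta_parse = c("literal", "product"),
                      tau_n_num = 1) {
  eta_parse <- match.arg(eta_parse)
  g <- c(g_Na, g_K, g_leak, g_h, g_T)
  if (any(g < 0)) stop("conductances must be non-negative")
  if (dt <= 0) stop("dt must be positive")
  if (C <= 0) stop("C must be positive")
  structure(list(C = C, g_Na = g_Na, g_K = g_K, g_leak = g_leak, g_h = g_h,
                 g_T = g_T, E_Na = E_Na, E_K = E_K, E_leak = E_leak,
                 E_h = E_h, E_Ca = E_Ca, I_bias = I_bias,
                 sigma_noise = sigma_noise, noise_sd = noise_sd, Phi = Phi,
                 tau_eta = tau_eta, dt = dt, eta_parse = eta_parse,
                 tau_n_num = tau_n_num),
            class = "ts_params")
}

param_vector <- function(p) {
  c(p$C, p$g_Na, p$g_K, p$g_leak, p$g_h, p$g_T, p$E_Na, p$E_K, p$E_leak,
    p$E_h, p$E_Ca, p$I_bias, p$sigma_noise, p$noise_sd, p$Phi, p$tau_eta,
    p$dt, if (p$eta_parse == "product") 1 else 0, p$tau_n_num)
}

#' Steady-state gating variables and time constants
#'
#' Evaluates the voltage-dependent steady states of the sodium activation
#' (`m_inf`), T-current activation (`s_inf`) and inactivation (`eta_inf`),
#' delayed-rectifier activation (`n_inf`), and h-current activation
#' (`h_inf`), plus the relaxation time constants `tau_n` and `tau_h` (ms).
#' The removable singularities of the rate functions `alpha_m`, `alpha_n` at
#' V = -40.7 mV are replaced by their analytic limits.
#'
#' @param V Membrane potential (mV); vectorized.
#' @param eta_parse See [ts_params()].
#' @param tau_n_num Numerator constant of `tau_n`; see [ts_params()].
#' @return A list of numeric vectors `m_inf`, `eta_inf`, `s_inf`, `n_inf`,
#'   `h_inf`, `tau_n`, `tau_h`.
#' @export
steady_state_gates <- function(V, eta_parse = c("literal", "product"),
                               tau_n_num = 1) {
  eta_parse <- match.arg(eta_parse)
  x <- V + 40.7
  am <- ifelse(abs(x) < 1e-7, 1, 0.1 * x / (1 - exp(-0.1 * x)))
  bm <- 4 * exp(-0.05 * (V + 49.7))
  an <- ifelse(abs(x) < 1e-7, 0.1, 0.01 * x / (1 - exp(-0.1 * x)))
  bn <- 0.125 * exp(-0.0125 * (V + 50.7))
  e <- exp((V + 82) / 6.3)
  list(m_inf = am / (am + bm),
       eta_inf = if (eta_parse == "product") 1 / (0.5 + 0.25 * e) else 1 / (0.75 + e),
       s_inf = 1 / (1 + exp(-(V + 63) / 7.8)),
       n_inf = an / (an + bn),
       h_inf = 1 / (1 + exp(0.151 * (V + 73))),
       tau_n = tau_n_num / (an + bn),
       tau_h = exp(0.033 * (V + 75)) / (0.011 * (1 + exp(0.083 * (V + 75)))))
}

#' Ionic and synaptic currents at a given state
#'
#' Sodium uses instantaneous activation `m_inf^3` with `(0.85 - n)`
#' inactivation; the T-type calcium current uses instantaneous `s_inf^3` with
#' the dynamic inactivation variable `eta`. Each current is zero at its
#' reversal potential.
#'
#' @param V Membrane potential (mV).
#' @param eta,h,n Gating-variable values.
#' @param params A [ts_params()].
#' @param g_on,g_off Synaptic conductances (uS).
#' @param syn_cfg A [synaptic_config()], or `NULL` for no synaptic input.
#' @return A list `I_Na`, `I_KDR`, `I_h`, `I_T`, `I_leak`, `I_syn` (model
#'   current units).
#' @export
ionic_currents <- function(V, eta, h, n, params = ts_params(), g_on = 0,
                           g_off = 0, syn_cfg = NULL) {
  ss <- steady_state_gates(V, params$eta_parse)
  list(I_Na = -params$g_Na * ss$m_inf^3 * (0.85 - n) * (V - params$E_Na),
       I_KDR = -params$g_K * n^4 * (V - params$E_K),
       I_h = -params$g_h * h * (V - params$E_h),
       I_T = -params$g_T * ss$s_inf^3 * eta * (V - params$E_Ca),
       I_leak = -params$g_leak * (V - params$E_leak),
       I_syn = if (is.null(syn_cfg)) 0 * V
               else synaptic_current(V, g_on, g_off, syn_cfg))
}

#' Integrate the stochastic TS neuron model
#'
#' Euler-Maruyama integration: the voltage is advanced by
#' `dt * sum(I) / C` plus the stochastic increment
#' `sigma_noise * noise_sd * sqrt(dt) * N(0,1) / C` per step; the gating
#' variables `eta`, `h`, `n` relax toward their steady states by forward
#' Euler. The state starts at `V = E_leak` with gates at steady state, and a
#' burn-in period with conductances held at their first sample is discarded
#' before `t = 0`. With a fixed seed the trace is bit-reproducible.
#'
#' @param params A [ts_params()].
#' @param g_on,g_off Synaptic conductance series (uS) sampled every
#'   `g_bin_ms`, or `NULL` for no synaptic input.
#' @param g_bin_ms Sampling step of the conductance series (ms); the
#'   integrator interpolates linearly onto its own grid.
#' @param syn_cfg A [synaptic_config()]; required when conductances are given.
#' @param t_end Simulation length (ms).
#' @param burn_in_ms Settling period before `t = 0` (ms), not recorded.
#' @param seed Optional integer seed for the noise stream.
#' @param threshold,lockout_ms Spike-detection threshold (mV) and lockout.
#' @return A list of class `voltage_trace` with `V` (mV, `t_end/dt + 1`
#'   samples), `dt` (ms) and `spike_times` (ms).
#' @export
integrate_ts <- function(params = ts_params(), g_on = NULL, g_off = NULL,
                         g_bin_ms = 0.5, syn_cfg = NULL, t_end = 1000,
                         burn_in_ms = 200, seed = NULL, threshold = 0,
                         lockout_ms = 1) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(g_on)) {
    g_on <- g_off <- numeric(0)
    syn <- c(0, 0, 1, 0)
  } else {
    if (is.null(syn_cfg)) stop("syn_cfg required when conductances are given")
    if (length(g_on) != length(g_off))
      stop("g_on and g_off must have equal length")
    if (length(g_on) * g_bin_ms < t_end - 1e-9)
      stop("t_end exceeds the conductance support")
    syn <- c(syn_cfg$sigma_B, syn_cfg$W_s, syn_cfg$g_max, syn_cfg$E_syn)
  }
  res <- integrate_ts_cpp(param_vector(params), g_on, g_off, g_bin_ms, syn,
                          t_end, round(burn_in_ms / params$dt), TRUE)
  if (res$diverged_at >= 0)
    stop(sprintf("integration diverged at step %d (t = %.3f ms)",
                 res$diverged_at, res$diverged_at * params$dt))
  spikes <- detect_spikes(res$V, params$dt, threshold, lockout_ms)
  structure(list(V = res$V, dt = params$dt, spike_times = spikes,
                 final_state = res$final_state),
            class = "voltage_trace")
}

#' Detect spikes as upward threshold crossings
#'
#' One spike per upward crossing of `threshold`, with a lockout period
#' suppressing re-crossings within `lockout_ms`.
#'
#' @param V Voltage trace (mV); first sample at `t = 0`.
#' @param dt Sampling step (ms).
#' @param threshold Detection threshold (mV).
#' @param lockout_ms Minimum separation between detected spikes (ms).
#' @return Increasing spike times (ms).
#' @export
detect_spikes <- function(V, dt, threshold = 0, lockout_ms = 1) {
  n <- length(V)
  if (n < 2) return(numeric(0))
  idx <- which(V[-n] < threshold & V[-1] >= threshold)
  if (!length(idx)) return(numeric(0))
  times <- idx * dt
  keep <- times[1]
  for (tt in times[-1]) {
    if (tt - keep[length(keep)] >= lockout_ms) keep <- c(keep, tt)
  }
  keep
}

#' Simulate repeated noisy trials for one stimulus
#'
#' Converts a PSTH pair into ON/OFF conductances once, then integrates the
#' model `n_trials` times with independent noise realizations drawn from a
#' single seeded stream.
#'
#' @param psth_pair A `psth_pair` (see [generate_population_psths()]).
#' @param params A [ts_params()].
#' @param syn_cfg A [synaptic_config()].
#' @param n_trials Number of trials.
#' @param seed Optional integer seed.
#' @param burn_in_ms Settling period (ms).
#' @param threshold Spike threshold (mV).
#' @return A list of `n_trials` spike-time vectors (ms) with attribute
#'   `duration`.
#' @export
simulate_trials <- function(psth_pair, params, syn_cfg, n_trials = 10,
                            seed = NULL, burn_in_ms = 200, threshold = 0) {
  if (!is.null(seed)) set.seed(seed)
  g_on <- psth_to_conductance(psth_pair$on_rate, psth_pair$bin_ms, syn_cfg)
  g_off <- psth_to_conductance(psth_pair$off_rate, psth_pair$bin_ms, syn_cfg)
  syn <- c(syn_cfg$sigma_B, syn_cfg$W_s, syn_cfg$g_max, syn_cfg$E_syn)
  pv <- param_vector(params)
  n_burn <- round(burn_in_ms / params$dt)
  trains <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    res <- integrate_ts_cpp(pv, g_on, g_off, psth_pair$bin_ms, syn,
                            psth_pair$duration, n_burn, TRUE)
    if (res$diverged_at >= 0)
      stop(sprintf("integration diverged at step %d", res$diverged_at))
    trains[[tr]] <- detect_spikes(res$V, params$dt, threshold)
  }
  attr(trains, "duration") <- psth_pair$duration
  trains
}
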