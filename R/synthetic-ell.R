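#' Configuration of the synthetic ELL population generator
#'
#' Parameters of the parametric stand-in for population-averaged ON- and
#' OFF-type ELL pyramidal-cell responses. ON cells fire on the rising phase of
#' the beat, OFF cells on the falling phase (antiphase to ON). During a chirp,
#' the pathway whose preferred beat half-cycle contains the chirp is excited
#' by a transient rate bump while the other pathway is suppressed toward zero
#' -- the simplest mechanism producing the mixed excitation/inhibition that
#' makes single ELL responses non-invariant across chirp waveforms.
#'
#' @param baseline Baseline firing rate (spikes/s).
#' @param beat_depth Peak beat-locked modulation above baseline (spikes/s).
#' @param chirp_gain Peak rate of the excitatory chirp transient (spikes/s).
#' @param chirp_sigma_ms Gaussian width of the chirp transient (ms).
#' @param chirp_latency_ms Latency of the transient peak after the chirp peak
#'   (ms).
#' @param noise_gain Standard deviation of the additive rate noise before
#'   smoothing (spikes/s); 0 for noiseless profiles.
#' @param noise_kernel_ms Gaussian smoothing kernel (standard deviation, ms)
#'   applied to the rate noise.
#' @return A list of class `ell_gain_config`.
#' @export
ell_gain_config <- function(baseline = 20, beat_depth = 80, chirp_gain = 200,
                            chirp_sigma_ms = 7, chirp_latency_ms = 5,
                            noise_gain = 10, noise_kernel_ms = 5) {
  if (baseline < 0 || beat_depth < 0)
    stop("baseline and beat_depth must be non-negative")
  if (chirp_gain < 0 || noise_gain < 0)
    stop("chirp_gain and noise_gain must be non-negative")
  structure(list(baseline = baseline, beat_depth = beat_depth,
                 chirp_gain = chirp_gain, chirp_sigma_ms = chirp_sigma_ms,
                 chirp_latency_ms = chirp_latency_ms, noise_gain = noise_gain,
                 noise_kernel_ms = noise_kernel_ms),
            class = "ell_gain_config")
}

smooth_gaussian <- function(x, sd_bins) {
  if (sd_bins <= 0) return(x)
  half <- max(1L, ceiling(4 * sd_bins))
  k <- stats::dnorm(seq(-half, half), sd = sd_bins)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  stats::convolve(xp, rev(k), type = "filter")
}

#' Generate synthetic ON/OFF population PSTHs for chirp stimuli
#'
#' For each stimulus, builds a pair of population firing-rate profiles that
#' phase-lock to the beat in antiphase (ON on the rising phase, OFF on the
#' falling phase) and respond to each chirp with a signed transient whose
#' direction is set deterministically by the chirp's beat phase: the pathway
#' preferring that half of the beat cycle is excited, the other is suppressed
#' toward zero. Smoothed Gaussian rate noise is added and rates are clipped
#' at zero.
#'
#' @param stimuli A `stimulus_trace` or list thereof (see
#'   [synthesize_dyad_signal()]); names become stimulus ids.
#' @param gain_cfg An [ell_gain_config()].
#' @param bin_ms PSTH bin width (ms).
#' @param seed Optional integer seed for the rate noise.
#' @return A list of `psth_pair` objects with elements `time` (bin centers,
#'   ms), `on_rate`, `off_rate` (spikes/s), `bin_ms`, `stimulus_id`,
#'   `chirp_onset` (ms, first chirp), `kind`, and `duration`.
#' @export
generate_population_psths <- function(stimuli, gain_cfg = ell_gain_config(),
                                      bin_ms = 0.5, seed = NULL) {
  if (inherits(stimuli, "stimulus_trace")) stimuli <- list(stimuli)
  if (!inherits(gain_cfg, "ell_gain_config")) stop("gain_cfg must be an ell_gain_config")
  if (!is.null(seed)) set.seed(seed)
  ids <- names(stimuli)
  if (is.null(ids)) ids <- paste0("stim", seq_along(stimuli))
  out <- vector("list", length(stimuli))
  names(out) <- ids
  for (si in seq_along(stimuli)) {
    st <- stimuli[[si]]
    nb <- floor(st$duration / bin_ms)
    tb <- (seq_len(nb) - 0.5) * bin_ms
    theta <- 2 * pi * st$beat_freq * tb / 1000 + st$beat_phase0 * pi / 180
    on <- gain_cfg$baseline + gain_cfg$beat_depth * pmax(0, -sin(theta))
    off <- gain_cfg$baseline + gain_cfg$beat_depth * pmax(0, sin(theta))
    for (ci in seq_along(st$chirp_onsets)) {
      tc <- st$chirp_onsets[ci]
      sig <- max(st$chirps[[ci]]$duration_sigma, gain_cfg$chirp_sigma_ms)
      bump <- exp(-(tb - tc - gain_cfg$chirp_latency_ms)^2 / (2 * sig^2))
      phase_c <- (st$beat_phase0 + 360 * st$beat_freq * tc / 1000) %% 360
      on_excited <- phase_c >= 180  # chirp in the ON cells' preferred half
      if (on_excited) {
        on <- on + gain_cfg$chirp_gain * bump
        off <- off * (1 - bump)
      } else {
        off <- off + gain_cfg$chirp_gain * bump
        on <- on * (1 - bump)
      }
    }
    if (gain_cfg$noise_gain > 0) {
      on <- on + smooth_gaussian(stats::rnorm(nb, 0, gain_cfg$noise_gain),
                                 gain_cfg$noise_kernel_ms / bin_ms)
      off <- off + smooth_gaussian(stats::rnorm(nb, 0, gain_cfg$noise_gain),
                                   gain_cfg$noise_kernel_ms / bin_ms)
    }
    kind <- if (length(st$chirps)) st$chirps[[1]]$kind else NA_character_
    out[[si]] <- structure(
      list(time = tb, on_rate = pmax(0, on), off_rate = pmax(0, off),
           bin_ms = bin_ms, stimulus_id = ids[si],
           chirp_onset = if (length(st$chirp_onsets)) st$chirp_onsets[1] else NA_real_,
           kind = kind, duration = st$duration),
      class = "psth_pair")
  }
  out
}

#' Sample spike trains from a rate profile (inhomogeneous Poisson)
#'
#' Draws `n_trials` spike trains from an inhomogeneous Poisson process with
#' the given piecewise-constant rate, by thinning a homogeneous process at the
#' maximal rate.
#'
#' @param rate_profile Non-negative rates (spikes/s), one per bin.
#' @param bin_ms Bin width (ms).
#' @param n_trials Number of trials (>= 1).
#' @param seed Optional integer seed.
#' @return A list of `n_trials` numeric vectors of increasing spike times
#'   (ms), with attribute `duration` (ms).
#' @export
generate_spike_trains <- function(rate_profile, bin_ms, n_trials, seed = NULL) {
  if (any(rate_profile < 0)) stop("rates must be non-negative")
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  duration <- length(rate_profile) * bin_ms
  rmax <- max(rate_profile)
  trains <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    if (rmax <= 0) {
      trains[[tr]] <- numeric(0)
      next
    }
    n_cand <- stats::rpois(1, rmax * duration / 1000)
    tc <- sort(stats::runif(n_cand, 0, duration))
    keep <- stats::runif(n_cand) < rate_profile[pmin(length(rate_profile),
                                                     floor(tc / bin_ms) + 1)] / rmax
    trains[[tr]] <- tc[keep]
  }
  attr(trains, "duration") <- duration
  trains
}

#' Synthetic cycle-averaged membrane potential
#'
#' One Gaussian depolarization at phase zero with unit height plus a second at
#' half the cycle with height `peak_ratio`, above a flat floor. Used as a
#' fixture for the bimodality index, which should recover `peak_ratio`.
#'
#' @param peak_ratio Height of the second bump relative to the first, in
#'   `[0, 1]`.
#' @param cycle_ms Cycle length (ms).
#' @param dt Sampling step (ms).
#' @param bump_sigma Bump width (standard deviation, ms).
#' @return Numeric vector covering one cycle.
#' @export
generate_cycle_vm <- function(peak_ratio, cycle_ms = 100, dt = 0.1,
                              bump_sigma = cycle_ms / 16) {
  if (peak_ratio < 0 || peak_ratio > 1) stop("peak_ratio must lie in [0, 1]")
  t <- seq(0, cycle_ms - dt, by = dt)
  d0 <- pmin(t, cycle_ms - t)          # circular distance to phase 0
  d1 <- abs(t - cycle_ms / 2)
  exp(-d0^2 / (2 * bump_sigma^2)) + peak_ratio * exp(-d1^2 / (2 * bump_sigma^2))
}
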