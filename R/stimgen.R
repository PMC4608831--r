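#' Specify a communication chirp
#'
#' A chirp is a brief (<40 ms) transient increase in the emitter fish's
#' electric organ discharge (EOD) frequency riding on top of the beat.
#' "Small" (type II) chirps have frequency excursions between 30 and 150 Hz
#' and no amplitude modulation of the emitter's EOD; "big" (type I) chirps
#' exceed 150 Hz and are accompanied by a transient decrease in the emitter's
#' EOD amplitude.
#'
#' @param kind `"small"` or `"big"`.
#' @param freq_excursion Peak increase of the emitter EOD frequency (Hz).
#' @param duration_sigma Width (standard deviation, ms) of the Gaussian
#'   frequency-excursion profile. The full width at half maximum of the
#'   excursion is `2*sqrt(2*log(2))*duration_sigma`.
#' @param amp_dip_fraction Relative decrease of the emitter EOD amplitude at
#'   the excursion peak, in `[0, 1]`. Must be 0 for small chirps.
#' @param onset_time Time of the excursion peak (ms).
#' @param beat_phase_target Desired beat phase (degrees in `[0, 360)`) at
#'   which the chirp occurs, or `NULL` to leave the beat phase unconstrained.
#'
#' @return An object of class `chirp_spec`.
#' @seealso [synthesize_dyad_signal()], [standard_chirp_stimuli()]
#' @export
chirp_spec <- function(kind = c("small", "big"),
                       freq_excursion = NULL,
                       duration_sigma = 6,
                       amp_dip_fraction = NULL,
                       onset_time = 500,
                       beat_phase_target = NULL) {
  kind <- match.arg(kind)
  if (is.null(freq_excursion)) {
    freq_excursion <- if (kind == "small") 60 else 260
  }
  if (is.null(amp_dip_fraction)) {
    amp_dip_fraction <- if (kind == "small") 0 else 0.8
  }
  if (kind == "small") {
    if (freq_excursion <= 30 || freq_excursion >= 150)
      stop("small chirps require 30 < freq_excursion < 150 Hz")
    if (amp_dip_fraction != 0)
      stop("small chirps have amp_dip_fraction = 0")
  } else {
    if (freq_excursion <= 150)
      stop("big chirps require freq_excursion > 150 Hz")
  }
  if (amp_dip_fraction < 0 || amp_dip_fraction > 1)
    stop("amp_dip_fraction must lie in [0, 1]")
  if (duration_sigma <= 0) stop("duration_sigma must be positive")
  if (!is.null(beat_phase_target)) {
    if (beat_phase_target < 0 || beat_phase_target >= 360)
      stop("beat_phase_target must lie in [0, 360)")
  }
  structure(
    list(kind = kind, freq_excursion = freq_excursion,
         duration_sigma = duration_sigma, amp_dip_fraction = amp_dip_fraction,
         onset_time = onset_time, beat_phase_target = beat_phase_target),
    class = "chirp_spec")
}

# Analytic signal via FFT: zero the negative-frequency half, double the
# positive half. Returns a complex vector whose modulus is the envelope.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Synthesize a two-fish beat/chirp stimulus
#'
#' Builds the compound signal produced by the interference of two
#' quasi-sinusoidal EODs (receiver at `f_receiver`, emitter at
#' `f_receiver + delta_f`), inserts chirps as Gaussian excursions of the
#' emitter's instantaneous frequency (with an optional amplitude dip for big
#' chirps), and extracts the amplitude modulation (AM) envelope, which is the
#' stimulus the electrosensory system actually encodes. The envelope is
#' normalized to mean 1 with modulation depth `contrast`.
#'
#' Chirps with a non-`NULL` `beat_phase_target` are placed at the requested
#' beat phase by adjusting the beat's starting phase (all chirps in one call
#' must then agree); phase 0 is anchored at a beat maximum.
#'
#' @param f_receiver Receiver EOD frequency (Hz), > 0.
#' @param delta_f Emitter minus receiver frequency (Hz); its absolute value is
#'   the beat frequency.
#' @param chirps List of [chirp_spec()] objects (possibly empty).
#' @param duration Trace duration (ms).
#' @param dt Sampling step (ms).
#' @param contrast Modulation depth of the normalized envelope (half
#'   peak-to-peak of the beat, relative to the mean).
#' @param beat_phase0 Beat phase at `t = 0` (degrees); overridden when chirps
#'   carry a `beat_phase_target`.
#'
#' @return An object of class `stimulus_trace` with elements `samples`
#'   (dimensionless AM values), `dt`, `beat_freq`, `chirp_onsets`, `duration`,
#'   `beat_phase0`, `chirps`, `carrier` (the raw compound signal) and
#'   `emitter` (the emitter fish's EOD alone; feed this to
#'   [instantaneous_frequency()] to measure the chirp's frequency
#'   excursion).
#' @export
synthesize_dyad_signal <- function(f_receiver, delta_f, chirps = list(),
                                   duration = 1000, dt = 0.025,
                                   contrast = 0.2, beat_phase0 = 0) {
  if (dt <= 0 || duration <= 0) stop("dt and duration must be positive")
  if (f_receiver <= 0) stop("f_receiver must be positive")
  if (abs(delta_f) <= 0) stop("delta_f must be non-zero")
  if (inherits(chirps, "chirp_spec")) chirps <- list(chirps)
  onsets <- vapply(chirps, `[[`, numeric(1), "onset_time")
  if (length(onsets) && (any(onsets < 0) || any(onsets >= duration)))
    stop("chirp onset outside trace")

  beat_freq <- abs(delta_f)
  targets <- lapply(chirps, `[[`, "beat_phase_target")
  has_target <- !vapply(targets, is.null, logical(1))
  if (any(has_target)) {
    # beat phase at the chirp peak equals phase0 + 360 * f_beat * t (mod 360)
    ph0 <- (unlist(targets[has_target]) -
              360 * beat_freq * onsets[has_target] / 1000) %% 360
    if (max(ph0) - min(ph0) > 1e-6 && (360 - (max(ph0) - min(ph0))) > 1e-6)
      stop("chirps request incompatible beat_phase_target values")
    beat_phase0 <- ph0[1]
  }

  n <- round(duration / dt)
  t <- (seq_len(n) - 1) * dt
  excursion <- numeric(n)   # Hz added to the emitter frequency
  dip <- numeric(n)         # fractional amplitude decrease
  for (ch in chirps) {
    prof <- exp(-(t - ch$onset_time)^2 / (2 * ch$duration_sigma^2))
    excursion <- excursion + ch$freq_excursion * prof
    dip <- dip + ch$amp_dip_fraction * prof
  }
  dip <- pmin(dip, 1)

  phase_r <- 2 * pi * f_receiver * t / 1000
  # sign(delta_f) handled through the emitter frequency itself
  f_emit <- f_receiver + delta_f + excursion
  # trapezoidal phase integral (exact for constant frequency)
  phase_e <- 2 * pi * (cumsum(f_emit) - f_emit / 2 - f_emit[1] / 2) *
    dt / 1000 + beat_phase0 * pi / 180
  emitter <- (1 - dip) * sin(phase_e)
  carrier <- sin(phase_r) + emitter

  env <- Mod(analytic_signal(carrier))
  # low-pass below the carrier to remove residual ripple at 2*f_receiver
  cutoff_hz <- 0.3 * f_receiver
  bf <- signal::butter(4, min(0.95, 2 * cutoff_hz * dt / 1000))
  env <- signal::filtfilt(bf, env)

  dev <- env - mean(env)
  # normalize modulation depth on the chirp-free part of the trace
  free <- rep(TRUE, n)
  for (ch in chirps) {
    free[t >= ch$onset_time - 4 * ch$duration_sigma &
           t <= ch$onset_time + 4 * ch$duration_sigma] <- FALSE
  }
  if (!any(free)) free <- rep(TRUE, n)
  half_ptp <- (max(dev[free]) - min(dev[free])) / 2
  if (half_ptp <= 0) half_ptp <- max(abs(dev), 1e-12)
  samples <- 1 + contrast * dev / half_ptp

  structure(
    list(samples = samples, dt = dt, beat_freq = beat_freq,
         chirp_onsets = onsets, duration = duration,
         beat_phase0 = beat_phase0, chirps = chirps,
         f_receiver = f_receiver, delta_f = delta_f, contrast = contrast,
         carrier = carrier, emitter = emitter),
    class = "stimulus_trace")
}

#' The five standard chirp stimuli
#'
#' Four small-chirp stimuli on a low-frequency beat, identical except for the
#' beat phase at which the chirp occurs (0, 90, 180, 270 degrees) -- the
#' dominant source of waveform heterogeneity for small chirps -- plus one big
#' chirp on a high-frequency beat. All chirps peak at the same `chirp_onset`
#' so that spike-train comparisons across stimuli are aligned to the chirp,
#' as in an experiment where every sweep is triggered on the chirp.
#'
#' @param duration Trace duration (ms).
#' @param dt Sampling step (ms).
#' @param chirp_onset Chirp peak time (ms), common to all five stimuli.
#' @param f_receiver Receiver EOD frequency (Hz).
#' @param small_delta_f,big_delta_f Beat frequencies (Hz) for the small- and
#'   big-chirp stimuli (emitter set above the receiver by these amounts).
#' @param contrast Envelope modulation depth.
#' @param small_excursion,big_excursion Chirp frequency excursions (Hz).
#' @param duration_sigma Gaussian width of the excursion (ms).
#' @param big_dip Amplitude-dip fraction of the big chirp.
#' @return A named list of five `stimulus_trace` objects
#'   (`small_0`, `small_90`, `small_180`, `small_270`, `big_0`). Each trace
#'   also carries the raw compound `carrier` and the `emitter` component
#'   (the chirping fish's own EOD, used to measure frequency excursions).
#' @export
standard_chirp_stimuli <- function(duration = 1000, dt = 0.025,
                                   chirp_onset = 500, f_receiver = 750,
                                   small_delta_f = 10, big_delta_f = 80,
                                   contrast = 0.2, small_excursion = 60,
                                   big_excursion = 260, duration_sigma = 6,
                                   big_dip = 0.8) {
  phases <- c(0, 90, 180, 270)
  out <- list()
  for (ph in phases) {
    ch <- chirp_spec("small", freq_excursion = small_excursion,
                     duration_sigma = duration_sigma,
                     onset_time = chirp_onset, beat_phase_target = ph)
    out[[paste0("small_", ph)]] <-
      synthesize_dyad_signal(f_receiver, small_delta_f, list(ch),
                             duration = duration, dt = dt,
                             contrast = contrast)
  }
  chb <- chirp_spec("big", freq_excursion = big_excursion,
                    duration_sigma = duration_sigma,
                    amp_dip_fraction = big_dip,
                    onset_time = chirp_onset, beat_phase_target = 0)
  out[["big_0"]] <- synthesize_dyad_signal(f_receiver, big_delta_f, list(chb),
                                           duration = duration, dt = dt,
                                           contrast = contrast)
  out
}

#' Instantaneous frequency from zero crossings
#'
#' Estimates the instantaneous frequency of a quasi-sinusoidal signal as the
#' inverse of the time between successive rising zero crossings, placing each
#' estimate at the midpoint of its interval. Crossing times are refined by
#' linear interpolation between samples.
#'
#' @param signal Sampled waveform (numeric vector).
#' @param dt Sampling step (ms).
#' @return A data frame with columns `time` (ms) and `freq` (Hz); zero rows if
#'   the signal has fewer than two rising zero crossings.
#' @export
instantaneous_frequency <- function(signal, dt) {
  if (dt <= 0) stop("dt must be positive")
  n <- length(signal)
  i <- which(signal[-n] < 0 & signal[-1] >= 0)
  if (length(i) < 2)
    return(data.frame(time = numeric(0), freq = numeric(0)))
  tc <- (i - 1) * dt + dt * (-signal[i]) / (signal[i + 1] - signal[i])
  iv <- diff(tc)
  data.frame(time = tc[-length(tc)] + iv / 2, freq = 1000 / iv)
}

#' Measure chirp attributes from a frequency series and a beat envelope
#'
#' The chirp time is the time of maximal instantaneous frequency inside the
#' chirp window; the duration is the full width at half-maximum (FWHM) of the
#' frequency excursion above a baseline (the median frequency outside the
#' window); and the beat phase expresses the chirp time relative to the
#' nearest preceding local maximum of the beat envelope as a fraction of the
#' beat period, times 360 degrees.
#'
#' @param freq_series Data frame with `time` (ms) and `freq` (Hz), e.g. from
#'   [instantaneous_frequency()].
#' @param stimulus A `stimulus_trace` (its envelope supplies the beat maxima
#'   and its `beat_freq` the beat period).
#' @param chirp_window Numeric `c(t0, t1)` (ms) bracketing the chirp.
#' @return A list of class `chirp_attributes` with `duration_fwhm` (ms),
#'   `phase` (degrees in `[0, 360)`), `peak_excursion` (Hz) and `chirp_time`
#'   (ms).
#' @export
chirp_attributes <- function(freq_series, stimulus, chirp_window) {
  stopifnot(length(chirp_window) == 2, chirp_window[1] < chirp_window[2])
  tt <- freq_series$time
  ff <- freq_series$freq
  inw <- tt >= chirp_window[1] & tt <= chirp_window[2]
  if (!any(inw)) stop("freq_series does not cover the chirp window")
  baseline <- stats::median(ff[!inw])
  fw <- ff[inw]; tw <- tt[inw]
  ipk <- which.max(fw)
  peak_excursion <- fw[ipk] - baseline
  chirp_time <- tw[ipk]
  half <- baseline + peak_excursion / 2
  above <- fw >= half
  if (peak_excursion <= 0 || !any(above))
    stop("no frequency excursion above half-maximum in the chirp window")
  # interpolated crossings of the half-max level around the peak
  lo <- ipk; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- ipk; while (hi < length(fw) && above[hi + 1]) hi <- hi + 1
  t_lo <- if (lo > 1) {
    tw[lo - 1] + (half - fw[lo - 1]) / (fw[lo] - fw[lo - 1]) *
      (tw[lo] - tw[lo - 1])
  } else tw[1]
  t_hi <- if (hi < length(fw)) {
    tw[hi] + (fw[hi] - half) / (fw[hi] - fw[hi + 1]) * (tw[hi + 1] - tw[hi])
  } else tw[length(fw)]
  duration_fwhm <- t_hi - t_lo

  # the chirp itself perturbs the envelope, so the reference maximum is the
  # last clean beat maximum before the chirp window, wrapped by beat periods
  env <- stimulus$samples
  te <- (seq_along(env) - 1) * stimulus$dt
  pre <- env[te < chirp_window[1]]
  if (length(pre) < 3) stop("no beat maximum precedes the chirp")
  d <- diff(pre)
  imax <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1
  if (!length(imax)) stop("no beat maximum precedes the chirp")
  t_max <- (imax[length(imax)] - 1) * stimulus$dt
  period <- 1000 / stimulus$beat_freq
  phase <- (360 * (chirp_time - t_max) / period) %% 360
  structure(list(duration_fwhm = duration_fwhm, phase = phase,
                 peak_excursion = peak_excursion, chirp_time = chirp_time),
            class = "chirp_attributes")
}

#' Similarity between two chirp waveforms
#'
#' `SM = 1 - RMSE / sigma`, where RMSE is the root-mean-square error between
#' the two mean-subtracted waveforms over a common window and `sigma` is the
#' maximum error, defined as the larger of the two half peak-to-peak ranges.
#' Identical waveforms (up to a constant offset) score 1; the score has no
#' lower bound but never exceeds 1.
#'
#' @param s_i,s_j Equal-length numeric waveforms (e.g. a 37.5 ms window
#'   centered on the chirp).
#' @return The similarity score (dimensionless, <= 1).
#' @export
similarity_metric <- function(s_i, s_j) {
  if (length(s_i) != length(s_j)) stop("waveform windows must have equal length")
  sigma <- max((max(s_i) - min(s_i)) / 2, (max(s_j) - min(s_j)) / 2)
  if (sigma == 0) stop("similarity undefined for two constant waveforms")
  d <- (s_i - mean(s_i)) - (s_j - mean(s_j))
  1 - sqrt(mean(d^2)) / sigma
}

#' Surrogate-based test of beat-phase uniformity
#'
#' Bins observed chirp phases (14-degree bins), then builds a surrogate
#' distribution of bin counts from `n_surrogate` uniformly drawn phase sets of
#' the same size. The observed distribution is deemed uniform when every bin
#' count lies within mean +/- 3 standard deviations of its surrogate counts.
#'
#' @param phases Observed phases in degrees (values taken modulo 360), at
#'   least 10.
#' @param n_surrogate Number of surrogate phase sets.
#' @param binwidth_deg Bin width in degrees.
#' @param seed Optional integer seed for the surrogate draws.
#' @return A list with `uniform` (logical), `band` (data frame of per-bin
#'   observed counts and lower/upper bounds) and `n_surrogate`.
#' @export
phase_uniformity_test <- function(phases, n_surrogate = 1000,
                                  binwidth_deg = 14, seed = NULL) {
  if (!length(phases)) stop("phases must be non-empty")
  if (length(phases) < 10) stop("need at least 10 phases")
  if (!is.null(seed)) set.seed(seed)
  phases <- phases %% 360
  breaks <- seq(0, 360 + binwidth_deg, by = binwidth_deg)
  breaks <- breaks[breaks - binwidth_deg < 360]
  obs <- table(cut(phases, breaks, right = FALSE, include.lowest = FALSE))
  obs <- as.numeric(obs)
  n <- length(phases)
  counts <- matrix(0L, n_surrogate, length(obs))
  for (s in seq_len(n_surrogate)) {
    counts[s, ] <- as.numeric(table(cut(stats::runif(n, 0, 360), breaks,
                                        right = FALSE)))
  }
  mu <- colMeans(counts)
  sd_ <- apply(counts, 2, stats::sd)
  lo <- mu - 3 * sd_
  hi <- mu + 3 * sd_
  list(uniform = all(obs >= lo & obs <= hi),
       band = data.frame(bin_lo = breaks[-length(breaks)],
                         bin_hi = breaks[-1], observed = obs,
                         lower = lo, upper = hi),
       n_surrogate = n_surrogate)
}
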