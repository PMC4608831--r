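#' Peri-stimulus time histogram (PSTH)
#'
#' Bins spikes across trials into a trial-averaged firing rate (spikes/s) and
#' smooths it with a boxcar filter. Smoothing is mass-preserving away from the
#' edges: the time-integral of the rate equals the mean spike count per trial
#' up to edge effects. Boxcar widths follow the convention of 10.8 ms for
#' small-chirp responses and 5 ms for big-chirp responses.
#'
#' @param trains List of spike-time vectors (ms), one per trial.
#' @param duration Trace duration (ms); defaults to the trains' `duration`
#'   attribute.
#' @param bin_ms Bin width (ms).
#' @param smooth_ms Boxcar length (ms).
#' @return An object of class `psth`: list with `rate` (spikes/s), `bin_ms`,
#'   `smooth_ms`, `duration`, `n_trials`.
#' @export
compute_psth <- function(trains, duration = attr(trains, "duration"),
                         bin_ms = 0.1, smooth_ms = 10.8) {
  if (!length(trains)) stop("need at least one trial")
  if (is.null(duration)) stop("duration must be given")
  nb <- floor(duration / bin_ms)
  counts <- numeric(nb)
  for (tr in trains) {
    if (length(tr)) {
      idx <- pmin(nb, floor(tr / bin_ms) + 1)
      tb <- tabulate(idx, nbins = nb)
      counts <- counts + tb
    }
  }
  rate <- counts / (length(trains) * bin_ms / 1000)
  k <- max(1L, round(smooth_ms / bin_ms))
  if (k > 1) {
    # edge-aware boxcar: each bin averaged over its clipped window
    cs <- cumsum(c(0, rate))
    half_lo <- (k - 1L) %/% 2L
    half_hi <- k %/% 2L
    i <- seq_len(nb)
    lo <- pmax(1L, i - half_lo)
    hi <- pmin(nb, i + half_hi)
    rate <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  structure(list(rate = rate, bin_ms = bin_ms, smooth_ms = smooth_ms,
                 duration = duration, n_trials = length(trains)),
            class = "psth")
}

#' Chirp selectivity index (CSI)
#'
#' `CSI = (R_C - R_B) / (R_C + R_B)` where `R_C` is the maximum PSTH rate in
#' a 100 ms window starting at the chirp onset and `R_B` is the maximum rate
#' elsewhere (the beat). A guard band of half the smoothing width around the
#' window edges is excluded from the beat segment so that smoothing leakage
#' from the chirp response does not inflate `R_B`. CSI is 1 for a purely
#' chirp-selective response, -1 for a purely beat-driven one, and 0 when both
#' maxima are zero.
#'
#' @param psth A [compute_psth()] object.
#' @param chirp_onset Chirp window start (ms).
#' @param window_ms Chirp window length (ms).
#' @param guard_ms Guard band excluded from the beat segment at the window
#'   edges (ms); defaults to half the PSTH smoothing width.
#' @return CSI in `[-1, 1]`.
#' @export
csi <- function(psth, chirp_onset, window_ms = 100,
                guard_ms = psth$smooth_ms / 2) {
  t <- (seq_along(psth$rate) - 0.5) * psth$bin_ms
  if (chirp_onset < 0 || chirp_onset + window_ms > psth$duration + 1e-9)
    stop("chirp window outside PSTH support")
  inw <- t >= chirp_onset & t < chirp_onset + window_ms
  beat <- t < chirp_onset - guard_ms | t >= chirp_onset + window_ms + guard_ms
  if (!any(beat)) stop("beat segment is empty")
  r_c <- max(psth$rate[inw])
  r_b <- max(psth$rate[beat])
  if (r_c == 0 && r_b == 0) return(0)
  (r_c - r_b) / (r_c + r_b)
}

#' Victor-Purpura distance between two spike trains
#'
#' Exact dynamic-programming edit distance with insertion/deletion cost 1 per
#' spike and shift cost `q * |dt|` (with `q` in 1/s and spike times in ms).
#' Symmetric and satisfies the metric axioms; bounded above by the total
#' number of spikes in both trains.
#'
#' @param a,b Sorted spike-time vectors (ms).
#' @param q Shift cost rate (1/s).
#' @return Non-negative transformation cost.
#' @export
vpd <- function(a, b, q = 100) {
  if (is.unsorted(a) || is.unsorted(b)) stop("spike times must be sorted")
  vpd_cpp(as.numeric(a), as.numeric(b), q)
}

#' Average pairwise Victor-Purpura distance
#'
#' Pools all spike trains across stimuli and trials and returns the mean VPD
#' over all unordered distinct pairs (both within- and between-stimulus
#' pairs), i.e. `M = choose(N * N_T, 2)` comparisons for `N` stimuli with
#' `N_T` trials each. Set `between_only = TRUE` to restrict to pairs from
#' different stimuli (sensitivity variant).
#'
#' @param trains Either a flat list of spike-time vectors or a list of
#'   per-stimulus lists of spike-time vectors.
#' @param q Shift cost rate (1/s).
#' @param between_only If `TRUE`, only between-stimulus pairs are averaged
#'   (requires nested input).
#' @return Mean pairwise VPD.
#' @export
vpd_avg <- function(trains, q = 100, between_only = FALSE) {
  nested <- length(trains) > 0 && is.list(trains[[1]])
  if (between_only) {
    if (!nested) stop("between_only requires per-stimulus nested trains")
    total <- 0; m <- 0
    ns <- length(trains)
    for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
      for (a in trains[[i]]) for (b in trains[[j]]) {
        total <- total + vpd_cpp(as.numeric(a), as.numeric(b), q)
        m <- m + 1
      }
    }
    if (m < 1) stop("need at least 2 spike trains")
    return(total / m)
  }
  flat <- if (nested) unlist(trains, recursive = FALSE) else trains
  if (length(flat) < 2) stop("need at least 2 spike trains")
  flat <- lapply(flat, as.numeric)
  vpd_avg_cpp(flat, q)
}

#' Average circularly-aligned RMSE between PSTHs
#'
#' For each unordered pair of equal-length PSTHs, computes the circular
#' cross-correlogram, circularly shifts one PSTH by the lag of its maximum
#' (so small timing offsets do not inflate the error), and takes the RMSE of
#' the aligned pair; returns the mean over all pairs.
#'
#' @param psths List of [compute_psth()] objects or numeric vectors of equal
#'   length (at least 2).
#' @return Mean aligned RMSE (spikes/s).
#' @export
rmse_avg <- function(psths) {
  rates <- lapply(psths, function(p) if (inherits(p, "psth")) p$rate else p)
  if (length(rates) < 2) stop("need at least 2 PSTHs")
  L <- unique(vapply(rates, length, integer(1)))
  if (length(L) != 1) stop("PSTHs must have equal length")
  total <- 0; m <- 0
  for (i in seq_len(length(rates) - 1)) for (j in (i + 1):length(rates)) {
    x <- rates[[i]]; y <- rates[[j]]
    cc <- Re(stats::fft(stats::fft(x) * Conj(stats::fft(y)), inverse = TRUE))
    lag <- which.max(cc) - 1  # shift y forward by `lag` bins
    ys <- if (lag == 0) y else c(y[(L - lag + 1):L], y[1:(L - lag)])
    total <- total + sqrt(mean((x - ys)^2))
    m <- m + 1
  }
  total / m
}

#' Feature-invariance score (FI)
#'
#' `FI = max(0, CSI_avg - alpha * VPD_avg)`: the rectified difference between
#' average chirp selectivity and the penalized average Victor-Purpura
#' distance across chirp waveforms. High FI requires both strong selectivity
#' for the chirp over the beat and similar spiking across heterogeneous chirp
#' waveforms. Neurons or models with FI <= 0.2 are conventionally labelled
#' non-invariant.
#'
#' @param csi_avg Mean chirp selectivity index across stimuli.
#' @param vpd_avg Mean pairwise Victor-Purpura distance.
#' @param alpha Penalty weight on the VPD term.
#' @return FI >= 0.
#' @export
fi <- function(csi_avg, vpd_avg, alpha = 0.01) {
  pmax(0, csi_avg - alpha * vpd_avg)
}

#' RMSE-based feature-invariance score
#'
#' Population-level counterpart of [fi()] for cases where only PSTHs (not
#' single-trial spike trains) are available:
#' `FI_RMSE = max(0, CSI_avg - gamma * RMSE_avg)`.
#'
#' @param csi_avg Mean chirp selectivity index.
#' @param rmse_avg Mean aligned RMSE between PSTHs (spikes/s).
#' @param gamma Penalty weight on the RMSE term.
#' @return FI_RMSE >= 0.
#' @export
fi_rmse <- function(csi_avg, rmse_avg, gamma = 0.0041) {
  pmax(0, csi_avg - gamma * rmse_avg)
}

#' Bimodality index of a cycle-averaged membrane response
#'
#' The trace (one full stimulus cycle) has its minimum subtracted and is then
#' circularly rotated so its maximum sits at index 1; the index is the value
#' at half the stimulus period divided by the value at 0. It is 1 when the
#' cell responds equally at two phases half a cycle apart (mixed ON+OFF
#' input) and 0 when it responds at a single phase.
#'
#' @param vm Numeric vector covering exactly one stimulus cycle.
#' @return Bimodality index (about `[0, 1]`; can slightly exceed 1 with
#'   noise).
#' @export
bimodality_index <- function(vm) {
  if (max(vm) == min(vm)) stop("bimodality undefined for a flat signal")
  v <- vm - min(vm)
  n <- length(v)
  i0 <- which.max(v)
  v <- c(v[i0:n], v[seq_len(i0 - 1)])
  v[1 + round(n / 2) %% n] / v[1]
}

#' Robustness of feature invariance over a parameter grid
#'
#' Percentage of grid cells whose FI meets or exceeds `threshold`. Cells with
#' missing FI (e.g. diverged simulations) are excluded from the denominator.
#'
#' @param fi_grid Numeric matrix (or vector) of FI values.
#' @param threshold FI threshold.
#' @return Percentage in `[0, 100]`.
#' @export
robustness <- function(fi_grid, threshold = 0.7) {
  if (!length(fi_grid)) stop("fi_grid must be non-empty")
  ok <- !is.na(fi_grid)
  if (!any(ok)) stop("fi_grid has no finite cells")
  100 * sum(fi_grid[ok] >= threshold) / sum(ok)
}

#' Full invariance evaluation of a set of spike-train responses
#'
#' Computes per-stimulus PSTHs and CSIs, the pooled average Victor-Purpura
#' distance across all trial pairs, and the resulting FI score.
#'
#' @param trains_by_stim List (one element per stimulus) of lists of
#'   spike-time vectors (ms).
#' @param chirp_onsets Chirp window starts (ms), one per stimulus (recycled
#'   if scalar).
#' @param duration Trace duration (ms).
#' @param smooth_ms Boxcar smoothing widths (ms), one per stimulus (recycled
#'   if scalar).
#' @param bin_ms PSTH bin width (ms).
#' @param window_ms Chirp window length (ms).
#' @param q VPD shift cost rate (1/s).
#' @param alpha FI penalty weight.
#' @return A list of class `invariance_result`: `csi_avg`, `vpd_avg`, `fi`,
#'   `csi` (per stimulus), `alpha`, `q`.
#' @export
evaluate_invariance <- function(trains_by_stim, chirp_onsets, duration,
                                smooth_ms = 10.8, bin_ms = 0.1,
                                window_ms = 100, q = 100, alpha = 0.01) {
  ns <- length(trains_by_stim)
  if (ns < 1) stop("need at least one stimulus")
  chirp_onsets <- rep_len(chirp_onsets, ns)
  smooth_ms <- rep_len(smooth_ms, ns)
  csis <- numeric(ns)
  for (i in seq_len(ns)) {
    p <- compute_psth(trains_by_stim[[i]], duration = duration,
                      bin_ms = bin_ms, smooth_ms = smooth_ms[i])
    csis[i] <- csi(p, chirp_onsets[i], window_ms = window_ms)
  }
  v <- vpd_avg(trains_by_stim, q = q)
  csi_avg <- mean(csis)
  structure(list(csi_avg = csi_avg, vpd_avg = v,
                 fi = fi(csi_avg, v, alpha), csi = csis,
                 alpha = alpha, q = q),
            class = "invariance_result")
}
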