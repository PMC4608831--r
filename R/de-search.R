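#' Differential evolution configuration
#'
#' Settings of the constrained differential evolution (DE) search used to
#' find model parameter combinations maximizing feature invariance. Fitness
#' is `exp(-FI)`, minimized; parents entering the differentiation step are
#' drawn with probabilities preferentially weighted toward fitter (lower
#' fitness) individuals; bound violations are handled by resampling the
#' differentiation with three freshly chosen parents, falling back to
#' clamping after `max_resample` attempts.
#'
#' @param bounds Numeric matrix with one row per gene and columns `lo`, `hi`
#'   (finite, `lo <= hi`; a gene with `lo == hi` is pinned to that value);
#'   row names name the genes.
#' @param K Population size (>= 4).
#' @param generations Maximum number of generations.
#' @param F Differential weight.
#' @param CR Crossover probability in `(0, 1]`.
#' @param seed Optional integer seed; a fixed seed makes the whole run
#'   bit-reproducible.
#' @param max_resample Resampling attempts before clamping to bounds.
#' @param stall_generations Stop early when the best FI has not improved for
#'   this many generations (`Inf` to disable).
#' @return A list of class `de_config`.
#' @export
de_config <- function(bounds, K = 30, generations = 50, F = 0.5, CR = 0.9,
                      seed = NULL, max_resample = 20,
                      stall_generations = 15) {
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2 || any(!is.finite(bounds)) ||
      any(bounds[, 1] > bounds[, 2]))
    stop("bounds must be a finite matrix with lo <= hi per gene")
  if (all(bounds[, 1] == bounds[, 2]))
    stop("at least one gene must have lo < hi")
  if (K < 4) stop("K must be >= 4")
  if (CR <= 0 || CR > 1) stop("CR must lie in (0, 1]")
  structure(list(bounds = bounds, K = K, generations = generations, F = F,
                 CR = CR, seed = seed, max_resample = max_resample,
                 stall_generations = stall_generations),
            class = "de_config")
}

#' Fitness-weighted parent selection
#'
#' Samples three pairwise-distinct indices, all distinct from the target
#' index, without replacement, with probabilities proportional to
#' `exp(-F_fit / max(F_fit))` so that fitter (lower-fitness) individuals are
#' preferentially chosen.
#'
#' @param fitnesses Fitness values `exp(-FI)` of the current population
#'   (length >= 4).
#' @param target Index of the individual being mutated (excluded).
#' @return Integer vector of three indices.
#' @export
select_parents <- function(fitnesses, target) {
  n <- length(fitnesses)
  if (n < 4) stop("need at least 4 individuals")
  w <- exp(-fitnesses / max(fitnesses))
  idx <- setdiff(seq_len(n), target)
  sample(idx, 3, prob = w[idx])
}

#' Differential evolution over a box-constrained objective
#'
#' Maximizes `objective(genes)` (an FI-like score) by evolving `K` gene
#' vectors: differentiation `X_trial = X_r1 + F * (X_r2 - X_r3)` with
#' fitness-weighted parent choice, per-gene recombination with probability
#' `CR`, and elitist selection (an individual is replaced only by a mutant
#' with fitness no worse than its own). Out-of-bounds trial vectors trigger
#' resampling of the differentiation step.
#'
#' @param objective Function mapping a gene vector to a finite score to be
#'   maximized.
#' @param cfg A [de_config()].
#' @return A list with `best` (list `genes`, `score`, `fitness`), `history`
#'   (best score per generation), `population`, `scores`, `n_eval`, and
#'   `n_clamped` (trial vectors that had to be clamped).
#' @export
evolve <- function(objective, cfg) {
  if (!inherits(cfg, "de_config")) stop("cfg must be a de_config")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  D <- nrow(cfg$bounds)
  lo <- cfg$bounds[, 1]; hi <- cfg$bounds[, 2]
  K <- cfg$K
  pop <- matrix(stats::runif(K * D, rep(lo, each = K), rep(hi, each = K)),
                nrow = K)
  colnames(pop) <- rownames(cfg$bounds)
  eval_obj <- function(genes) {
    s <- objective(genes)
    if (!is.finite(s))
      stop(sprintf("objective returned non-finite value at genes: %s",
                   paste(signif(genes, 4), collapse = ", ")))
    s
  }
  scores <- apply(pop, 1, eval_obj)
  n_eval <- K
  fitness <- exp(-scores)
  history <- numeric(0)
  best_score <- max(scores)
  stall <- 0
  n_clamped <- 0L

  for (gen in seq_len(cfg$generations)) {
    for (r in seq_len(K)) {
      trial <- NULL
      for (attempt in seq_len(cfg$max_resample)) {
        p <- select_parents(fitness, r)
        cand <- pop[p[1], ] + cfg$F * (pop[p[2], ] - pop[p[3], ])
        if (all(cand >= lo & cand <= hi)) {
          trial <- cand
          break
        }
      }
      if (is.null(trial)) {
        trial <- pmin(pmax(cand, lo), hi)
        n_clamped <- n_clamped + 1L
      }
      cross <- stats::runif(D) < cfg$CR
      mutant <- pop[r, ]
      mutant[cross] <- trial[cross]
      s <- eval_obj(mutant)
      n_eval <- n_eval + 1
      f <- exp(-s)
      if (f <= fitness[r]) {
        pop[r, ] <- mutant
        scores[r] <- s
        fitness[r] <- f
      }
    }
    gen_best <- max(scores)
    history <- c(history, gen_best)
    if (gen_best > best_score + 1e-12) {
      best_score <- gen_best
      stall <- 0
    } else {
      stall <- stall + 1
    }
    # early stop only once the search has left the flat zero-score region
    if (best_score > 0 && stall >= cfg$stall_generations) break
  }
  ib <- which.max(scores)
  list(best = list(genes = pop[ib, ], score = scores[ib],
                   fitness = fitness[ib]),
       history = history, population = pop, scores = scores,
       n_eval = n_eval, n_clamped = n_clamped)
}

#' Default gene bounds for the TS-model search
#'
#' Physiologically motivated box for the five searched parameters:
#' `sigma_B` in `[0, 1]`, `W_s` such that `g_syn = W_s * g_max` spans
#' `[0.01, 0.3]` uS, `I_bias` in `[-25, 5]` nA, `g_h` in `[0, 8]` uS and
#' `g_T` in `[0, 6]` uS, covering the parameter sets of all reference model
#' solutions.
#'
#' @param g_max Maximal synaptic conductance unit (uS), used to convert the
#'   `g_syn` range into `W_s` bounds.
#' @return A 5 x 2 bounds matrix with row names
#'   `sigma_B, W_s, I_bias, g_h, g_T`.
#' @export
default_ts_bounds <- function(g_max = 0.13) {
  b <- rbind(sigma_B = c(0, 1),
             W_s = c(0.01, 0.3) / g_max,
             I_bias = c(-25, 5),
             g_h = c(0, 8),
             g_T = c(0, 6))
  colnames(b) <- c("lo", "hi")
  b
}

#' Fit the TS model for maximal feature invariance
#'
#' Runs the constrained DE search over `(sigma_B, W_s, I_bias, g_h, g_T)`:
#' each candidate is evaluated by simulating the model on every stimulus with
#' `n_trials` noisy repeats, scoring the responses with
#' [evaluate_invariance()], and maximizing FI (fitness `exp(-FI)`). The best
#' individual is re-evaluated at the end with `n_trials_final` trials.
#'
#' @param stimuli Named list of `stimulus_trace` objects.
#' @param psth_pairs Matching list of `psth_pair` objects (see
#'   [generate_population_psths()]).
#' @param base_params A [ts_params()] providing all non-searched parameters.
#' @param cfg A [de_config()]; defaults to [default_ts_bounds()] with a small
#'   population.
#' @param syn_base A [synaptic_config()] providing `zeta`, `g_max`,
#'   `tau_syn`, `E_syn`.
#' @param n_trials Trials per stimulus during the search.
#' @param n_trials_final Trials for the final re-evaluation of the best
#'   genes.
#' @param smooth_ms Per-stimulus PSTH smoothing widths (ms); default 10.8 for
#'   small chirps, 5 for big, taken from the `psth_pairs` `kind` field.
#' @param ... Further arguments passed to [evaluate_invariance()].
#' @return A list with `best` (genes and search-time score), `result` (an
#'   `invariance_result` for the best genes at `n_trials_final`), `history`,
#'   `n_eval`.
#' @export
fit_ts_model <- function(stimuli, psth_pairs, base_params = ts_params(),
                         cfg = de_config(default_ts_bounds(), K = 20,
                                         generations = 30),
                         syn_base = synaptic_config(), n_trials = 5,
                         n_trials_final = 10, smooth_ms = NULL, ...) {
  stopifnot(length(stimuli) == length(psth_pairs))
  if (is.null(smooth_ms)) {
    kinds <- vapply(psth_pairs, function(p)
      if (is.null(p$kind) || is.na(p$kind)) "small" else p$kind, character(1))
    smooth_ms <- ifelse(kinds == "big", 5, 10.8)
  }
  onsets <- vapply(psth_pairs, `[[`, numeric(1), "chirp_onset")
  duration <- psth_pairs[[1]]$duration
  bin_ms <- psth_pairs[[1]]$bin_ms
  # conductances depend only on zeta, g_max, tau_syn: precompute once
  g_on <- lapply(psth_pairs, function(p)
    psth_to_conductance(p$on_rate, p$bin_ms, syn_base))
  g_off <- lapply(psth_pairs, function(p)
    psth_to_conductance(p$off_rate, p$bin_ms, syn_base))

  simulate_genes <- function(genes, nt) {
    params <- base_params
    params$I_bias <- genes[["I_bias"]]
    params$g_h <- genes[["g_h"]]
    params$g_T <- genes[["g_T"]]
    syn <- c(genes[["sigma_B"]], genes[["W_s"]], syn_base$g_max,
             syn_base$E_syn)
    pv <- param_vector(params)
    n_burn <- round(200 / params$dt)
    lapply(seq_along(psth_pairs), function(i) {
      trains <- vector("list", nt)
      for (tr in seq_len(nt)) {
        res <- integrate_ts_cpp(pv, g_on[[i]], g_off[[i]], bin_ms, syn,
                                duration, n_burn, TRUE)
        if (res$diverged_at >= 0)
          stop(sprintf(
            "integration diverged at step %d for genes: %s",
            res$diverged_at, paste(signif(genes, 4), collapse = ", ")))
        trains[[tr]] <- detect_spikes(res$V, params$dt)
      }
      trains
    })
  }
  objective <- function(genes) {
    tb <- simulate_genes(genes, n_trials)
    evaluate_invariance(tb, onsets, duration, smooth_ms = smooth_ms, ...)$fi
  }
  run <- evolve(objective, cfg)
  tb <- simulate_genes(run$best$genes, n_trials_final)
  final <- evaluate_invariance(tb, onsets, duration, smooth_ms = smooth_ms,
                               ...)
  list(best = run$best, result = final, history = run$history,
       n_eval = run$n_eval, n_clamped = run$n_clamped)
}
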