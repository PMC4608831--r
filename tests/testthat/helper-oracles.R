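# Independent oracles used across the suite.

# Brute-force Victor-Purpura distance: enumerate every monotone matching
# between the two trains recursively (match the first spike of `a` with some
# spike of `b`, or delete it), with unmatched spikes costing 1 and matched
# pairs costing q|dt|. Exponential, only for tiny trains; fully independent
# of the dynamic-programming implementation.
vpd_brute <- function(a, b, q = 100) {
  qms <- q / 1000
  rec <- function(a, b) {
    if (!length(a)) return(length(b))
    if (!length(b)) return(length(a))
    best <- 1 + rec(a[-1], b)            # delete a[1]
    for (j in seq_along(b)) {
      cost <- (j - 1) +                  # delete b[1..j-1]
        qms * abs(a[1] - b[j]) +         # match a[1] <-> b[j]
        rec(a[-1], b[-seq_len(j)])
      if (cost < best) best <- cost
    }
    best
  }
  rec(a, b)
}

random_train <- function(n_max = 6, duration = 1000) {
  n <- sample(0:n_max, 1)
  sort(stats::runif(n, 0, duration))
}

# Small shared fixture: short standard stimuli + noiseless ELL input, cheap
# enough to rebuild per test file.
short_stimuli <- function(duration = 400, chirp_onset = 250) {
  standard_chirp_stimuli(duration = duration, chirp_onset = chirp_onset)
}
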