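test_that("PSTH smoothing conserves spike mass and averages trials", {
  # one spike in one trial: integral of rate over time = 1 spike
  p <- compute_psth(list(100), duration = 400, bin_ms = 0.1,
                    smooth_ms = 10.8)
  expect_equal(sum(p$rate) * p$bin_ms / 1000, 1, tolerance = 1e-9)
  in_window <- p$rate[abs((seq_along(p$rate) - 0.5) * 0.1 - 100) < 5]
  expect_true(all(in_window > 0))

  # twenty identical trains give the same PSTH as one
  tr <- sort(stats::runif(7, 0, 400))
  p1 <- compute_psth(list(tr), duration = 400)
  p20 <- compute_psth(rep(list(tr), 20), duration = 400)
  expect_equal(p1$rate, p20$rate)

  # Poisson rate recovery at 40 spikes/s
  set.seed(21)
  trains <- generate_spike_trains(rep(40, 1000), 1, 50)
  pr <- compute_psth(trains, duration = 1000, bin_ms = 1, smooth_ms = 20)
  se <- sqrt(40 * 1000 / 1000 / 50) / (1000 / 1000)  # rough rate SE
  expect_lt(abs(mean(pr$rate) - 40), 3 * se)
  expect_error(compute_psth(list(), duration = 100), "one trial")
})

test_that("CSI matches its defining ratio and boundary cases", {
  mk <- function(rate) structure(list(rate = rate, bin_ms = 1,
                                      smooth_ms = 2, duration = length(rate)),
                                 class = "psth")
  r <- rep(0, 400); r[210] <- 50
  expect_equal(csi(mk(r), 200), 1)          # response only in the chirp window
  r2 <- rep(0, 400); r2[100] <- 50
  expect_equal(csi(mk(r2), 200), -1)        # response only during the beat
  r3 <- rep(0, 400); r3[210] <- 60; r3[100] <- 20
  expect_equal(csi(mk(r3), 200), 0.5)       # (60 - 20)/(60 + 20)
  expect_equal(csi(mk(rep(0, 400)), 200), 0)
  # invariance to uniform rate scaling
  expect_equal(csi(mk(3.7 * r3), 200), csi(mk(r3), 200))
  expect_error(csi(mk(r), 350), "window")
})

test_that("Victor-Purpura distance matches analytic single-spike cases", {
  expect_equal(vpd(c(100, 200), c(100, 200)), 0)
  expect_equal(vpd(100, numeric(0)), 1)
  expect_equal(vpd(numeric(0), numeric(0)), 0)
  expect_equal(vpd(100, 105), 0.5)    # q|dt| = 100/s * 5 ms
  expect_equal(vpd(100, 130), 2)      # shift cost 3 capped by delete+insert
  expect_error(vpd(c(5, 1), c(1)), "sorted")
})

test_that("DP Victor-Purpura distance equals the brute-force matching oracle", {
  set.seed(99)
  for (i in 1:60) {
    a <- random_train(5)
    b <- random_train(5)
    expect_equal(vpd(a, b), vpd_brute(a, b), tolerance = 1e-10)
  }
})

test_that("Victor-Purpura distance satisfies the metric axioms", {
  set.seed(7)
  trains <- replicate(12, random_train(5), simplify = FALSE)
  for (i in seq_along(trains)) {
    expect_equal(vpd(trains[[i]], trains[[i]]), 0)
    for (j in seq_along(trains)) {
      dij <- vpd(trains[[i]], trains[[j]])
      expect_gte(dij, 0)
      expect_equal(dij, vpd(trains[[j]], trains[[i]]))
      expect_lte(dij, length(trains[[i]]) + length(trains[[j]]))
      for (k in seq_along(trains)) {
        expect_lte(dij, vpd(trains[[i]], trains[[k]]) +
                     vpd(trains[[k]], trains[[j]]) + 1e-12)
      }
    }
  }
})

test_that("vpd_avg pools all unordered pairs across stimuli and trials", {
  # N = 2 stimuli x N_T = 3 trials: M = choose(6, 2) = 15 pairs
  set.seed(1)
  nested <- list(replicate(3, random_train(4), simplify = FALSE),
                 replicate(3, random_train(4), simplify = FALSE))
  flat <- unlist(nested, recursive = FALSE)
  manual <- 0; m <- 0
  for (i in 1:5) for (j in (i + 1):6) {
    manual <- manual + vpd(flat[[i]], flat[[j]]); m <- m + 1
  }
  expect_equal(m, 15)
  expect_equal(vpd_avg(nested), manual / 15)
  expect_equal(vpd_avg(list(numeric(0), 100)), 1)
  expect_true(vpd_avg(rep(list(c(10, 20)), 4)) == 0)
  expect_error(vpd_avg(list(numeric(0))), "at least 2")
  # the between-only variant drops the 2 * choose(3,2) within-stimulus pairs
  manual_btw <- 0
  for (a in nested[[1]]) for (b in nested[[2]])
    manual_btw <- manual_btw + vpd(a, b)
  expect_equal(vpd_avg(nested, between_only = TRUE), manual_btw / 9)
})

test_that("aligned RMSE is zero for circular shifts and matches a toy case", {
  set.seed(12)
  x <- abs(stats::rnorm(200))
  y <- c(x[164:200], x[1:163])  # circular shift by 37 bins
  expect_equal(rmse_avg(list(x, x)), 0)
  expect_equal(rmse_avg(list(x, y)), 0, tolerance = 1e-10)
  # orthogonal unit pulses on 4 bins align perfectly -> RMSE 0;
  # hand toy with unequal mass cannot align: computed by hand
  a <- c(2, 0, 0, 0)
  b <- c(1, 1, 0, 0)
  # best circular shift overlaps the '2' with a '1': residual (1,1,0,0)-like
  expect_equal(rmse_avg(list(a, b)), sqrt(mean(c(1, -1, 0, 0)^2)))
  expect_error(rmse_avg(list(a, c(1, 2, 3))), "equal length")
  expect_error(rmse_avg(list(a)), "at least 2")
})

test_that("FI reproduces the three printed worked examples", {
  expect_equal(round(fi(1, 1.19), 2), 0.99)
  expect_equal(fi(-0.05, 53.3), 0)
  expect_equal(round(fi(0.61, 7.4), 3), 0.536)
})

test_that("FI is monotone in its arguments and rectified at zero", {
  set.seed(8)
  cs <- sort(stats::runif(20, -1, 1))
  vs <- sort(stats::runif(20, 0, 60))
  for (v in c(0, 5, 40)) expect_true(all(diff(fi(cs, v)) >= 0))
  for (cc in c(-0.5, 0.3, 0.9)) expect_true(all(diff(fi(cc, vs)) <= 0))
  expect_true(all(fi(stats::runif(50, -2, 2), stats::runif(50, 0, 100)) >= 0))
  expect_equal(fi_rmse(0.5, 0), 0.5)
  expect_equal(fi_rmse(-0.2, 10), 0)
  expect_equal(fi_rmse(0.61, 18), 0.61 - 0.0041 * 18)
})

test_that("bimodality index recovers generator peak ratios", {
  expect_equal(bimodality_index(generate_cycle_vm(1)), 1, tolerance = 1e-6)
  expect_equal(bimodality_index(sin(2 * pi * seq(0, 0.999, by = 0.001))), 0,
               tolerance = 1e-6)
  for (r in c(0.3, 0.6, 0.8))
    expect_equal(bimodality_index(generate_cycle_vm(r)), r, tolerance = 0.05)
  expect_error(bimodality_index(rep(2, 100)), "flat")
})

test_that("robustness counts the FI >= threshold fraction, ignoring NA cells", {
  expect_equal(robustness(matrix(1, 3, 3)), 100)
  expect_equal(robustness(matrix(0, 3, 3)), 0)
  expect_equal(robustness(matrix(c(0.8, 0.6, 0.7, 0.1), 2, 2)), 50)
  expect_equal(robustness(matrix(c(0.8, NA, 0.1, NA), 2, 2)), 50)
  expect_equal(robustness(matrix(0.7, 2, 2), threshold = 1.01), 0)
  expect_error(robustness(numeric(0)), "non-empty")
})
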