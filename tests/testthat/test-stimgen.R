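test_that("chirp_spec enforces the small/big chirp taxonomy", {
  expect_error(chirp_spec("small", freq_excursion = 200), "small chirps")
  expect_error(chirp_spec("small", amp_dip_fraction = 0.5), "amp_dip")
  expect_error(chirp_spec("big", freq_excursion = 100), "big chirps")
  expect_silent(chirp_spec("big", freq_excursion = 260,
                           amp_dip_fraction = 0.8))
})

test_that("the envelope of a chirp-free dyad oscillates at the beat frequency", {
  st <- synthesize_dyad_signal(750, 10, duration = 1000, dt = 0.025)
  sp <- Mod(stats::fft(st$samples - mean(st$samples)))
  # 1 Hz resolution on a 1 s trace: bin k+1 holds k Hz
  expect_equal(which.max(sp[2:200]), 10)
  expect_true(all(is.finite(st$samples)))
  expect_equal(length(st$samples), 1000 / 0.025)
})

test_that("a big chirp's amplitude dip collapses the beat modulation", {
  ch <- chirp_spec("big", amp_dip_fraction = 0.8, onset_time = 500)
  st <- synthesize_dyad_signal(750, 80, list(ch), duration = 1000, dt = 0.025)
  t <- (seq_along(st$samples) - 1) * st$dt
  core <- t > 497 & t < 503          # around the excursion peak
  beat <- t > 100 & t < 400
  # the emitter's amplitude dip shrinks the interference term, flattening
  # the beat: local modulation range collapses during the chirp
  range_of <- function(x) max(x) - min(x)
  expect_lt(range_of(st$samples[core]), 0.5 * range_of(st$samples[beat]))
  # and the emitter component itself carries the amplitude dip
  env_core <- max(abs(st$emitter[core]))
  env_beat <- max(abs(st$emitter[beat]))
  expect_lt(env_core, 0.4 * env_beat)
})

test_that("invalid stimulus arguments are rejected", {
  expect_error(synthesize_dyad_signal(750, 10, duration = -5), "positive")
  expect_error(synthesize_dyad_signal(750, 10, dt = 0), "positive")
  ch <- chirp_spec("small", onset_time = 1500)
  expect_error(synthesize_dyad_signal(750, 10, list(ch), duration = 1000),
               "onset outside")
})

test_that("instantaneous frequency recovers constant and chirped frequencies", {
  t <- seq(0, 100 - 0.025, by = 0.025)
  x <- sin(2 * pi * 700 * t / 1000)
  fr <- instantaneous_frequency(x, 0.025)
  expect_true(all(abs(fr$freq - 700) < 1))

  # Gaussian excursion peaking at +50 Hz over a 700 Hz carrier
  f_inst <- 700 + 50 * exp(-(t - 50)^2 / (2 * 6^2))
  ph <- 2 * pi * (cumsum(f_inst) - f_inst / 2 - f_inst[1] / 2) * 0.025 / 1000
  fr2 <- instantaneous_frequency(sin(ph), 0.025)
  expect_lt(abs(max(fr2$freq) - 750), 2)

  expect_equal(nrow(instantaneous_frequency(rep(1, 100), 0.025)), 0)
})

test_that("chirp attributes round-trip the generating specification", {
  for (ph in c(0, 90, 180, 270)) {
    ch <- chirp_spec("small", freq_excursion = 60, duration_sigma = 6,
                     onset_time = 500, beat_phase_target = ph)
    st <- synthesize_dyad_signal(750, 10, list(ch), duration = 1000,
                                 dt = 0.025)
    fr <- instantaneous_frequency(st$emitter, st$dt)
    at <- chirp_attributes(fr, st, c(450, 550))
    expect_equal(at$duration_fwhm, 2 * sqrt(2 * log(2)) * 6, tolerance = 0.02)
    err <- min(abs(at$phase - ph), 360 - abs(at$phase - ph))
    expect_lt(err, 5)
    expect_equal(at$peak_excursion, 60, tolerance = 0.02)
  }
})

test_that("chirp duration is the analytic FWHM of the Gaussian excursion", {
  # direct check on an analytic frequency series, no waveform involved
  tt <- seq(0, 1000, by = 0.5)
  ff <- 760 + 60 * exp(-(tt - 500)^2 / (2 * 6^2))
  st <- synthesize_dyad_signal(750, 10, duration = 1000, dt = 0.025)
  at <- chirp_attributes(data.frame(time = tt, freq = ff), st, c(400, 600))
  expect_equal(at$duration_fwhm, 2 * sqrt(2 * log(2)) * 6, tolerance = 1e-3)
  expect_error(
    chirp_attributes(data.frame(time = tt, freq = rep(760, length(tt))),
                     st, c(400, 600)),
    "half-maximum")
})

test_that("similarity metric matches its analytic cases", {
  # sampling grid hits the sine extrema exactly: three whole periods
  t <- seq(0, 37.5 - 0.125, by = 0.125)
  s <- sin(2 * pi * t / 12.5)
  expect_equal(similarity_metric(s, s), 1)
  expect_equal(similarity_metric(s, s + 3.7), 1)
  expect_equal(similarity_metric(3 * s, -3 * s), 1 - sqrt(2), tolerance = 1e-6)
  expect_equal(similarity_metric(s, -s), similarity_metric(-s, s))
  expect_error(similarity_metric(rep(1, 10), rep(2, 10)), "constant")
  expect_error(similarity_metric(s, s[-1]), "equal length")
})

test_that("similarity metric never exceeds 1 on random waveform pairs", {
  set.seed(5)
  for (i in 1:25) {
    a <- stats::rnorm(100)
    b <- stats::rnorm(100)
    sm <- similarity_metric(a, b)
    expect_lte(sm, 1)
    expect_equal(sm, similarity_metric(b, a))
  }
})

test_that("phase uniformity test accepts uniform and rejects clustered phases", {
  set.seed(2)
  accepted <- vapply(1:20, function(i) {
    phase_uniformity_test(stats::runif(500, 0, 360), n_surrogate = 300,
                          seed = 100 + i)$uniform
  }, logical(1))
  expect_gte(mean(accepted), 0.8)

  clustered <- stats::runif(500, 0, 14)
  res <- phase_uniformity_test(clustered, n_surrogate = 300, seed = 1)
  expect_false(res$uniform)
  expect_equal(res$n_surrogate, 300)
  expect_error(phase_uniformity_test(numeric(0)), "non-empty")
  expect_error(phase_uniformity_test(1:5), "at least 10")
})
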