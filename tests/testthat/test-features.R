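# The second layer is exercised both on synthetic log-spectrogram fixtures
# (clean steps and ridges, where exact oracles exist) and end-to-end on
# audio rendered by the stimulus generator.

test_that("onset and offset maps decompose the signed temporal derivative", {
  set.seed(11)
  L <- synthetic_log_spectrogram(matrix(cumsum(rnorm(70 * 25)), 70, 25))
  spec <- rf_spec(tau_a = (0.008)^2, s = 0.5, alpha = 1,
                  family = "time_causal_uniform", K = 4)
  on <- onset_map(L, spec)
  off <- offset_map(L, spec)
  expect_true(all(on$values >= 0) && all(off$values >= 0))
  expect_equal(on$values - off$values, attr(on, "raw"))
  # constant input: both maps vanish
  Lc <- synthetic_log_spectrogram(matrix(4, 50, 20))
  expect_equal(max(abs(onset_map(Lc, spec)$values)), 0)
  expect_error(onset_map(L, rf_spec(1e-4, 1)), "alpha")
})

test_that("onset response to a step peaks at the smoothing-kernel maximum", {
  # ideal dB step in a band: the temporal derivative response is the
  # smoothing kernel itself, so its peak sits at the kernel's t_max
  nt <- 200; nn <- 21; dt <- 0.001
  i_on <- 61
  M <- matrix(0, nt, nn)
  M[i_on:nt, 8:14] <- 30
  L <- synthetic_log_spectrogram(M, dt = dt)
  K <- 4; tau_a <- (0.02)^2
  spec <- rf_spec(tau_a = tau_a, s = 0, alpha = 1,
                  family = "time_causal_uniform", K = K)
  on <- onset_map(L, spec)
  i_peak <- which.max(on$values[, 11])
  # oracle: peak of the discrete cascade impulse response at this scale
  casc <- cascade_for_scale(tau_a / dt^2, K, "uniform")
  imp <- c(rep(0, 30), 1, rep(0, 160))
  delay <- which.max(recursive_smooth(imp, casc)[, K]) - 31L
  expect_lte(abs(i_peak - (i_on + delay)), 1)
  # the discrete delay approximates the continuous (K - 1) mu
  expect_equal(delay * dt, (K - 1) * sqrt(tau_a / K), tolerance = 0.1)
  # offset map is silent around the onset
  off <- offset_map(L, spec)
  expect_equal(max(off$values[1:(i_on + 20), 11]), 0)
})

test_that("onset detection on gated audio is timed by the kernel delay", {
  fs <- 8000
  x <- synth_step_band(600, 0.25, 0.65, 0.9, fs)
  ax <- log_frequency_axis(300, 1200, 24)
  p <- spectrogram_params(fs, ax, window_scale_policy(n = 8, sigma0 = 1e-3))
  L <- to_log_magnitude(compute_spectrogram(x, p), floor_dB = -60)
  spec <- rf_spec(tau_a = (0.02)^2, s = 0.25, alpha = 1,
                  family = "time_causal_uniform", K = 4)
  on <- onset_map(L, spec)
  off <- offset_map(L, spec)
  j <- which.min(abs(ax$frequencies - 600))
  t_on_peak <- L$times[which.max(on$values[, j])]
  t_off_peak <- L$times[which.max(off$values[, j])]
  # peaks fall inside the onset/offset neighbourhoods widened by the
  # first-layer window rise and the second-layer kernel delay
  slack <- 3 * sqrt(window_variance_for_frequency(2 * pi * 600, p$policy)) +
    (4 - 1) * sqrt((0.02)^2 / 4)
  expect_lt(abs(t_on_peak - 0.25), slack)
  expect_lt(abs(t_off_peak - 0.65), slack)
  expect_gt(t_on_peak, 0.25 - 1e-9)    # causal: response cannot precede
})

test_that("band map enhances partials of a harmonic complex at the right places", {
  Lc <- synthetic_log_spectrogram(matrix(1, 40, 20))
  spec <- rf_spec(tau_a = 1e-4, s = 0.25, beta = 2, family = "gaussian")
  expect_equal(max(abs(band_map(Lc, spec)$values)), 0)
  expect_error(band_map(Lc, rf_spec(1e-4, 1)), "beta")

  # single Gaussian band in nu: one positive blob at the band center
  nn <- 61; nu <- 60 + (0:(nn - 1)) * 0.25
  M <- matrix(rep(10 * exp(-(nu - 67.4)^2 / 2), each = 30), 30, nn)
  bm <- band_map(synthetic_log_spectrogram(M, dnu = 0.25), spec)
  mid <- bm$values[15, ]
  expect_equal(nu[which.max(mid)], 67.4, tolerance = 0.25)

  # harmonic stimulus: band-map peaks align with the partial frequencies
  fs <- 16000
  x <- synth_harmonic(harmonic_spec(220, n_partials = 20,
                                    slope_db_per_octave = 6,
                                    duration = 0.4, sample_rate = fs))
  ax <- log_frequency_axis(180, 7500, 36)
  p <- spectrogram_params(fs, ax, window_scale_policy(n = 8, sigma0 = 1e-3),
                          family = "time_causal_uniform", K = 4)
  L <- to_log_magnitude(compute_spectrogram(x, p), floor_dB = -80)
  bmap <- band_map(L, rf_spec(tau_a = (0.005)^2, s = 0.25, beta = 2,
                              family = "time_causal_uniform", K = 4))
  rc <- ridge_curves(bmap, C = 3)
  frame <- rc$curves[abs(rc$curves$time - 0.3) < 1e-9, ]
  partials <- midi_from_frequency(220 * (1:20))
  hits <- vapply(frame$nu,
                 function(nu) min(abs(nu - partials)), 0)
  # every detected ridge lies on a partial, and the strongest partials are
  # all detected
  expect_true(all(hits <= ax$dnu))
  for (j in 1:8)
    expect_true(any(abs(frame$nu - partials[j]) <= ax$dnu))
})

test_that("ridge curves track stationary tones and chirps at sub-grid accuracy", {
  fs <- 8000
  ax <- log_frequency_axis(300, 2000, 24)
  p <- spectrogram_params(fs, ax, window_scale_policy(n = 8, sigma0 = 1e-3))
  spec <- rf_spec(tau_a = (0.01)^2, s = 1, beta = 2, family = "gaussian")

  # stationary tone: a single horizontal curve at the tone's log-frequency
  x <- synth_harmonic(harmonic_spec(600, n_partials = 1, duration = 0.6,
                                    sample_rate = fs))
  L <- to_log_magnitude(compute_spectrogram(x, p))
  rc <- ridge_curves(band_map(L, spec), C = 3)
  cc <- rc$curves[rc$curves$time > 0.1 & rc$curves$time < 0.5, ]
  main_id <- as.integer(names(which.max(table(cc$curve_id))))
  main <- cc[cc$curve_id == main_id, ]
  expect_gt(nrow(main), 300)
  expect_lt(max(abs(main$nu - midi_from_frequency(600))), 0.25)

  # all strengths below threshold: empty set
  rc_hi <- ridge_curves(band_map(L, spec), C = 1e9)
  expect_equal(nrow(rc_hi$curves), 0L)

  # chirp: the curve slope recovers the glissando rate within 5%
  v0 <- 28
  xc <- synth_harmonic(harmonic_spec(600, n_partials = 1, duration = 0.8,
                                     sample_rate = fs, glissando = v0))
  Lc <- to_log_magnitude(compute_spectrogram(xc, p))
  rcc <- ridge_curves(band_map(Lc, spec), C = 3)
  cm <- rcc$curves[rcc$curves$time > 0.15 & rcc$curves$time < 0.65, ]
  main_id <- as.integer(names(which.max(table(cm$curve_id))))
  main <- cm[cm$curve_id == main_id, ]
  slope <- coef(stats::lm(nu ~ time, main))[2]
  expect_equal(unname(slope), v0, tolerance = 0.05)
})

test_that("both glissando estimators recover the chirp rate", {
  fs <- 8000
  v0 <- 28
  ax <- log_frequency_axis(300, 2000, 24)
  p <- spectrogram_params(fs, ax, window_scale_policy(n = 8, sigma0 = 1e-3))
  spec <- rf_spec(tau_a = (0.01)^2, s = 1, beta = 2, family = "gaussian")
  xc <- synth_harmonic(harmonic_spec(600, n_partials = 1, duration = 0.8,
                                     sample_rate = fs, glissando = v0))
  L <- to_log_magnitude(compute_spectrogram(xc, p))
  bm <- band_map(L, spec)
  idx <- which(L$times > 0.15 & L$times < 0.65)
  ridge_j <- vapply(idx, function(i) which.max(bm$values[i, ]), 0L)

  # filter bank over v with parabolic refinement
  fb <- glissando_filterbank(L, spec, c(10, 20, 30, 40, 50))
  v_fb <- stats::median(fb$v_hat[cbind(idx, ridge_j)])
  expect_equal(v_fb, v0, tolerance = 0.1)

  # second-moment (structure-tensor) estimate
  sm <- second_moment_glissando(L, rf_spec(tau_a = (0.01)^2, s = 1,
                                           family = "gaussian"))
  v_sm <- stats::median(sm$v[cbind(idx, ridge_j)], na.rm = TRUE)
  expect_equal(v_sm, v0, tolerance = 0.1)

  # the two estimators agree on rates strictly inside the bank grid
  expect_equal(v_fb, v_sm, tolerance = 0.2)

  # moment-matrix invariants
  mom <- sm$moments
  expect_true(all(mom$Ytt >= -1e-9) && all(mom$Ynn >= -1e-9))
  expect_true(all(mom$Ytn^2 <= mom$Ytt * mom$Ynn + 1e-6 * max(mom$Ytt)))

  # fixed point: after shearing by the estimate the residual rate is small
  Ls <- L
  Ls$values_dB <- shear_warp(L$values_dB, v_sm, L$times, ax$nu_values,
                             "forward")
  sm2 <- second_moment_glissando(Ls, rf_spec(tau_a = (0.01)^2, s = 1,
                                             family = "gaussian"))
  resid <- stats::median(sm2$v[cbind(idx, ridge_j)], na.rm = TRUE)
  expect_lt(abs(resid), 0.1 * v0)
})

test_that("filter bank on a stationary tone estimates zero rate", {
  fs <- 8000
  ax <- log_frequency_axis(300, 2000, 24)
  p <- spectrogram_params(fs, ax, window_scale_policy(n = 8, sigma0 = 1e-3))
  spec <- rf_spec(tau_a = (0.01)^2, s = 1, beta = 2, family = "gaussian")
  x <- synth_harmonic(harmonic_spec(600, n_partials = 1, duration = 0.6,
                                    sample_rate = fs))
  L <- to_log_magnitude(compute_spectrogram(x, p))
  bm <- band_map(L, spec)
  grid <- c(-20, -10, 0, 10, 20)
  fb <- glissando_filterbank(L, spec, grid)
  idx <- which(L$times > 0.15 & L$times < 0.45)
  ridge_j <- vapply(idx, function(i) which.max(bm$values[i, ]), 0L)
  v_hat <- stats::median(fb$v_hat[cbind(idx, ridge_j)])
  expect_lt(abs(v_hat), min(diff(grid)) / 2)
  # single-element grid: the best map is that element's response
  fb1 <- glissando_filterbank(L, spec, 15)
  expect_equal(fb1$best, attr(band_map(L, rf_spec(tau_a = (0.01)^2, s = 1,
                                                  v = 15, beta = 2,
                                                  family = "gaussian")),
                              "raw"))
  expect_true(all(fb1$v_hat == 15))
  expect_error(glissando_filterbank(L, spec, numeric(0)), "non-empty")
})
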