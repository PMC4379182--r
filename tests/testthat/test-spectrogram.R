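test_that("MIDI conversion follows the 69 / 440 Hz convention", {
  expect_equal(midi_from_frequency(440), 69)
  expect_equal(midi_from_frequency(880), 81)
  expect_equal(frequency_from_midi(midi_from_frequency(123.4)), 123.4)
  expect_error(midi_from_frequency(0), "positive")
  ax <- log_frequency_axis(80, 16000, 48)
  expect_equal(ax$dnu, 0.25)
  expect_equal(diff(ax$nu_values), rep(0.25, length(ax$nu_values) - 1))
  expect_equal(ax$frequencies[1], 80)
})

test_that("window scale is wavelength-proportional with soft bounds", {
  pol <- window_scale_policy(n = 8, sigma0 = 0)
  expect_equal(sqrt(window_variance_for_frequency(2 * pi * 440, pol)),
               8 / 440)                          # sigma = n * wavelength
  # high-frequency limit with a lower bound: tau -> tau0
  pol0 <- window_scale_policy(n = 8, sigma0 = 2e-3)
  expect_equal(window_variance_for_frequency(1e9, pol0), 4e-6,
               tolerance = 1e-6)
  # soft upper bound kicks in at low frequencies
  polu <- window_scale_policy(n = 8, sigma0 = 0, tau_inf = 1e-4, p = 2)
  expect_lt(window_variance_for_frequency(2 * pi * 20, polu), 1e-4)
  # frequency where tau = beta^2 tau0 (about 4.6 kHz for the defaults)
  f <- soft_bound_frequency(window_scale_policy(n = 8, sigma0 = 1e-3), beta = 2)
  expect_equal(f, 8 / (1e-3 * sqrt(3)))
  tau_there <- window_variance_for_frequency(2 * pi * f,
                                             window_scale_policy(8, 1e-3))
  expect_equal(tau_there, 4 * 1e-6)
})

test_that("a centered pure tone reaches steady-state magnitude one half", {
  fs <- 4000
  ax <- log_frequency_axis(220, 880, 12)        # includes 440 Hz exactly
  j <- which(abs(ax$nu_values - 69) < 1e-9)
  for (fam in c("gaussian", "time_causal_uniform", "time_causal_log")) {
    p <- spectrogram_params(fs, ax, window_scale_policy(n = 8, sigma0 = 0),
                            family = fam, K = 7, c = sqrt(2))
    prof <- steady_profile(440, p)
    expect_equal(prof[j], 0.5, tolerance = 0.01)
    expect_equal(which.max(prof), j)
  }
  # silent input maps to zero
  p <- spectrogram_params(fs, ax, family = "time_causal_uniform", K = 4)
  S0 <- compute_spectrogram(rep(0, 2000), p)
  expect_equal(max(abs(S0$values)), 0)
  expect_error(compute_spectrogram(numeric(0), p), "empty")
  expect_error(spectrogram_params(2000, log_frequency_axis(220, 1800, 12)),
               "Nyquist")
})

test_that("spectrogram is linear and its magnitude is shift-invariant", {
  fs <- 8000
  ax <- log_frequency_axis(300, 1200, 12)
  p <- spectrogram_params(fs, ax, family = "time_causal_log", K = 4,
                          c = sqrt(2))
  x <- synth_harmonic(harmonic_spec(500, n_partials = 1, duration = 0.5,
                                    sample_rate = fs))
  y <- synth_harmonic(harmonic_spec(800, n_partials = 1, duration = 0.5,
                                    sample_rate = fs))
  Sxy <- compute_spectrogram(2 * x - 3 * y, p)
  ref <- 2 * compute_spectrogram(x, p)$values -
    3 * compute_spectrogram(y, p)$values
  expect_equal(Sxy$values, ref, tolerance = 1e-12)

  # delay by 5 hops shifts the magnitude columns by 5 frames
  xs <- c(rep(0, 5 * p$hop), x)[seq_along(x)]
  S1 <- abs(compute_spectrogram(x, p)$values)
  S2 <- abs(compute_spectrogram(xs, p)$values)
  i <- 150:350
  expect_lt(max(abs(S1[i, ] - S2[i + 5, ])), 1e-10 * max(S1))
})

test_that("pure-tone spectral profiles shift by 12 semitones per octave", {
  fs <- 8000
  ax <- log_frequency_axis(200, 2000, 12)
  p <- spectrogram_params(fs, ax, window_scale_policy(n = 8, sigma0 = 0),
                          family = "time_causal_uniform", K = 7)
  p1 <- steady_profile(400, p)
  p2 <- steady_profile(800, p)
  n <- length(p1)
  expect_lt(max(abs(p1[1:(n - 12)] - p2[13:n])) / max(p1), 0.01)
})

test_that("steady-state -3 dB bandwidth matches the analytical theta", {
  fs <- 8000
  ax <- log_frequency_axis(220, 880, 96)
  width_at <- function(fam, K, cc) {
    p <- spectrogram_params(fs, ax, window_scale_policy(n = 8, sigma0 = 0),
                            family = fam, K = K, c = cc)
    prof <- 20 * log10(steady_profile(440, p))
    prof <- prof - max(prof)
    nu <- ax$nu_values
    above <- which(prof >= -3)
    lo <- above[1]; hi <- above[length(above)]
    f_lo <- nu[lo - 1] + (nu[lo] - nu[lo - 1]) *
      (-3 - prof[lo - 1]) / (prof[lo] - prof[lo - 1])
    f_hi <- nu[hi] + (nu[hi + 1] - nu[hi]) *
      (-3 - prof[hi]) / (prof[hi + 1] - prof[hi])
    f_hi - f_lo
  }
  cases <- list(
    list("gaussian", 7, sqrt(2), theta_gaussian(-3)),
    list("time_causal_uniform", 7, sqrt(2), theta_rec_uniform(-3, 7)),
    list("time_causal_log", 7, sqrt(2), theta_rec_log(-3, 7, sqrt(2))))
  for (cs in cases) {
    predicted <- relative_bandwidth(cs[[4]], 8, "semitones")
    expect_equal(width_at(cs[[1]], cs[[2]], cs[[3]]), predicted,
                 tolerance = 0.05)
  }
})

test_that("dB transform scales and clamps as specified", {
  fs <- 4000
  ax <- log_frequency_axis(300, 900, 12)
  p <- spectrogram_params(fs, ax, family = "time_causal_uniform", K = 4)
  x <- synth_harmonic(harmonic_spec(500, n_partials = 1, duration = 0.3,
                                    sample_rate = fs))
  S <- compute_spectrogram(x, p)
  L <- to_log_magnitude(S, S0 = 1, floor_dB = -1e9)
  keep <- abs(S$values) > 0
  expect_equal(L$values_dB[keep], 20 * log10(abs(S$values)[keep]),
               tolerance = 1e-12)
  # |S| = S0 maps to 0 dB, |S| = 10 S0 to 20 dB
  m <- max(abs(S$values))
  L1 <- to_log_magnitude(S, S0 = m)
  expect_equal(max(L1$values_dB), 0)
  L2 <- to_log_magnitude(S, S0 = m / 10)
  expect_equal(max(L2$values_dB), 20)
  # scaling the input adds 20 log10 a everywhere above the floor
  Sa <- compute_spectrogram(2 * x, p)
  La <- to_log_magnitude(Sa, S0 = 1, floor_dB = -1e6)
  Lb <- to_log_magnitude(S, S0 = 1, floor_dB = -1e6)
  expect_equal(La$values_dB[keep], Lb$values_dB[keep] + 20 * log10(2),
               tolerance = 1e-9)
  # floor clamps
  Lf <- to_log_magnitude(S, S0 = m, floor_dB = -40)
  expect_gte(min(Lf$values_dB), -40)
})

test_that("Gammatone parameters reproduce the composed-window envelope", {
  expect_equal(gammatone_parameters(1 / (2 * pi), 5)$b, 1)
  gp <- gammatone_parameters(1, 1)
  expect_equal(gp$a, 1)
  expect_equal(gp$b, 1 / (2 * pi))
  # a t^{K-1} e^{-2 pi b t} equals the composed kernel envelope
  mu <- 0.013; K <- 4
  gp <- gammatone_parameters(mu, K)
  tt <- seq(0, 0.2, by = 1e-4)
  envelope <- gp$a * tt^(K - 1) * exp(-2 * pi * gp$b * tt)
  expect_equal(envelope,
               sample_composed_uniform_kernel(mu, K, tt)$values,
               tolerance = 1e-10)
})

test_that("window delay is the first inflection point of the window", {
  p <- spectrogram_params(8000, log_frequency_axis(300, 900, 12),
                          window_scale_policy(n = 8, sigma0 = 0),
                          family = "time_causal_uniform", K = 4)
  omega <- 2 * pi * 440
  tau <- window_variance_for_frequency(omega, p$policy)
  expect_equal(window_delay(p, omega), (3 - sqrt(3)) / 2 * sqrt(tau))
  # K = 2: inflection at the origin
  p2 <- spectrogram_params(8000, log_frequency_axis(300, 900, 12),
                           family = "time_causal_uniform", K = 2)
  expect_equal(window_delay(p2, omega), 0)
  # log family, K = 1: pure exponential, inflection at 0
  p3 <- spectrogram_params(8000, log_frequency_axis(300, 900, 12),
                           family = "time_causal_log", K = 1, c = 2)
  expect_equal(window_delay(p3, omega), 0)
  # gaussian family: not applicable
  pg <- spectrogram_params(8000, log_frequency_axis(300, 900, 12))
  expect_error(window_delay(pg, omega), "Gaussian")
  # compensation advances the response of a delayed channel
  fs <- 8000
  x <- synth_step_band(440, 0.25, 0.7, 0.8, fs)
  ax2 <- log_frequency_axis(220, 880, 12)     # contains 440 Hz exactly
  mk <- function(comp) spectrogram_params(
    fs, ax2, window_scale_policy(n = 8, sigma0 = 1e-3),
    family = "time_causal_uniform", K = 7, delay_compensation = comp)
  j <- which(abs(ax2$nu_values - 69) < 1e-9)
  rise <- function(S) S$times[which(abs(S$values[, j]) > 0.25)[1]]
  t_raw <- rise(compute_spectrogram(x, mk(FALSE)))
  t_comp <- rise(compute_spectrogram(x, mk(TRUE)))
  expect_lt(t_comp, t_raw)
  expect_lt(abs((t_raw - t_comp) -
                round(window_delay(mk(TRUE), 2 * pi * 440) * fs) / fs),
            2.5e-3)
})
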