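# Shared fixtures: all synthetic, built in code at test time.

# A log_spectrogram object from a plain matrix (time x channel), for tests
# that exercise the second layer without running audio through the first.
synthetic_log_spectrogram <- function(values, dt = 0.002, dnu = 0.5,
                                      nu0 = 60) {
  nn <- ncol(values)
  structure(list(
    values_dB = values,
    times = (seq_len(nrow(values)) - 1L) * dt,
    axis = list(nu_values = nu0 + (seq_len(nn) - 1L) * dnu, dnu = dnu),
    dt = dt, dnu = dnu, S0 = 1, floor_dB = -120),
    class = "log_spectrogram")
}

# A smooth 2-D Gaussian blob spectrogram.
blob_spectrogram <- function(nt = 160, nn = 48, dt = 0.002, dnu = 0.5,
                             t0 = 0.16, nu_center = 72, var_t = 2e-3^2,
                             var_nu = 3) {
  times <- (seq_len(nt) - 1L) * dt
  nu <- 60 + (seq_len(nn) - 1L) * dnu
  M <- outer(exp(-(times - t0)^2 / (2 * var_t)),
             exp(-(nu - nu_center)^2 / (2 * var_nu)))
  synthetic_log_spectrogram(M, dt, dnu, nu0 = 60)
}

# Steady-state magnitude profile over channels of a pure tone.
steady_profile <- function(f0, params, duration = 0.8, frac = 0.9) {
  fs <- params$sample_rate
  x <- synth_harmonic(harmonic_spec(f0, n_partials = 1,
                                    duration = duration, sample_rate = fs))
  S <- compute_spectrogram(x, params)
  abs(S$values)[round(frac * nrow(S$values)), ]
}

# Piecewise-smooth random test signal for extrema-counting properties.
random_piecewise_signal <- function(n = 256) {
  x <- cumsum(stats::rnorm(n))
  steps <- sort(sample.int(n, 3))
  for (s in steps) x[s:n] <- x[s:n] + stats::runif(1, -5, 5)
  x
}

table1_printed <- function() {
  rbind(
    gauss            = c(0.132, 0.242, 0.342, 0.418),
    rec_uni_K4       = c(0.138, 0.281, 0.468, 0.684),
    rec_log_K4_c1.41 = c(0.140, 0.292, 0.498, 0.736),
    rec_log_K4_c1.68 = c(0.143, 0.312, 0.553, 0.838),
    rec_log_K4_c2    = c(0.146, 0.332, 0.619, 0.971),
    rec_uni_K7       = c(0.136, 0.263, 0.406, 0.546),
    rec_log_K7_c1.41 = c(0.140, 0.289, 0.478, 0.678),
    rec_log_K7_c1.68 = c(0.143, 0.311, 0.547, 0.816),
    rec_log_K7_c2    = c(0.146, 0.332, 0.617, 0.963))
}

table2_printed <- function() {
  cbind(K = 2:8,
        m_uni          = c(1.414, 1.732, 2.000, 2.236, 2.449, 2.646, 2.828),
        m_log_c1.41    = c(1.414, 1.707, 1.914, 2.061, 2.164, 2.237, 2.289),
        m_log_c1.68    = c(1.399, 1.636, 1.777, 1.860, 1.910, 1.940, 1.957),
        m_log_c2       = c(1.366, 1.549, 1.641, 1.686, 1.709, 1.721, 1.732))
}

table3_printed <- function() {
  cbind(K = 2:8,
        t_max_uni       = c(0.707, 1.155, 1.500, 1.789, 2.041, 2.268, 2.475),
        t_max_log_c1.41 = c(0.707, 1.122, 1.385, 1.556, 1.669, 1.745, 1.797),
        t_max_log_c1.68 = c(0.688, 1.027, 1.199, 1.289, 1.340, 1.370, 1.388),
        t_max_log_c2    = c(0.640, 0.909, 1.014, 1.060, 1.083, 1.095, 1.100))
}
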