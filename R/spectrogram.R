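# Multi-scale spectrogram engine: per-channel heterodyne demodulation
# followed by temporal scale-space smoothing, with a frequency-dependent
# window scale, a log-frequency (MIDI) axis and a dB magnitude transform.
#
# Each channel at angular frequency omega projects the signal onto
# cos(omega t) and sin(omega t) and smooths both projections with the
# family's temporal kernel at the channel's window scale tau(omega).  This
# is equivalent (up to phase) to filtering with Gabor functions (Gaussian
# window), Gammatone filters (equal-time-constant cascade) or generalized
# Gammatone filters (logarithmic cascade), while avoiding the blockwise
# windowing artifacts of FFT spectrograms.

#' MIDI log-frequency conversion
#'
#' Converts between frequency in Hz and logarithmic frequency in semitones
#' following the MIDI convention, \eqn{\nu = 69 + 12\log_2(f/440)}, so that
#' 69 corresponds to the tone A4 (440 Hz) and one octave spans 12 semitones.
#'
#' @param f frequency in Hz (positive, vectorized).
#' @param nu logarithmic frequency in semitones (vectorized).
#' @return \code{midi_from_frequency}: semitones; \code{frequency_from_midi}:
#'   Hz.
#' @export
#' @examples
#' midi_from_frequency(440)   # 69
#' frequency_from_midi(81)    # 880
midi_from_frequency <- function(f) {
  if (any(f <= 0)) stop("'f' must be positive", call. = FALSE)
  69 + 12 * log2(f / 440)
}

#' @rdname midi_from_frequency
#' @export
frequency_from_midi <- function(nu) 440 * 2^((nu - 69) / 12)

#' Logarithmic frequency axis
#'
#' A uniform grid of log-frequencies (semitones, MIDI convention) covering
#' \code{[f_min, f_max]} with \code{channels_per_octave} channels per octave,
#' starting at \code{f_min}.
#'
#' @param f_min,f_max frequency range in Hz.
#' @param channels_per_octave integer number of channels per octave.
#' @return An object of class \code{"log_frequency_axis"} with fields
#'   \code{nu_values}, \code{frequencies}, \code{channels_per_octave},
#'   \code{f_min}, \code{f_max} and the grid spacing \code{dnu}.
#' @export
log_frequency_axis <- function(f_min = 80, f_max = 16000,
                               channels_per_octave = 48) {
  check_scalar(f_min, "f_min", lower = 0, strict_lower = TRUE)
  check_scalar(f_max, "f_max", lower = 0, strict_lower = TRUE)
  if (f_min >= f_max) stop("'f_min' must be < 'f_max'", call. = FALSE)
  check_scalar(channels_per_octave, "channels_per_octave", lower = 1,
               integer = TRUE)
  dnu <- 12 / channels_per_octave
  nu <- seq(midi_from_frequency(f_min), midi_from_frequency(f_max), by = dnu)
  structure(list(nu_values = nu, frequencies = frequency_from_midi(nu),
                 channels_per_octave = as.integer(channels_per_octave),
                 f_min = f_min, f_max = f_max, dnu = dnu),
            class = "log_frequency_axis")
}

#' @export
print.log_frequency_axis <- function(x, ...) {
  cat(sprintf(
    "Log-frequency axis: %d channels, %g-%g Hz, %d per octave\n",
    length(x$nu_values), x$f_min, x$f_max, x$channels_per_octave))
  invisible(x)
}

#' Frequency-dependent window-scale policy
#'
#' The temporal window scale of each spectrogram channel is chosen
#' proportional to the channel's wavelength, \eqn{\tau = (2\pi n/\omega)^2}
#' in variance units, which makes the spectral selectivity independent of
#' frequency (frequency covariance on a log-frequency axis). Two departures
#' from strict proportionality are supported: a \emph{soft lower bound}
#' \eqn{\tau = \tau_0 + (2\pi n/\omega)^2} preventing vanishing windows at
#' high frequencies, and a \emph{soft upper bound}
#' \eqn{\tau' = \tau / (1 + (\tau/\tau_\infty)^p)^{1/p}} limiting the
#' temporal delay at low frequencies.
#'
#' @param n window-length-to-wavelength factor (dimensionless; default 8).
#' @param sigma0 lower bound on the window standard deviation in seconds
#'   (default 1 ms); \code{tau0 = sigma0^2}.
#' @param tau_inf upper-bound variance in seconds squared (default
#'   \code{Inf}, i.e. off).
#' @param p softness exponent of the upper bound (default 2).
#' @return An object of class \code{"window_scale_policy"}.
#' @export
window_scale_policy <- function(n = 8, sigma0 = 1e-3, tau_inf = Inf, p = 2) {
  check_scalar(n, "n", lower = 0, strict_lower = TRUE)
  check_scalar(sigma0, "sigma0", lower = 0)
  if (!identical(tau_inf, Inf))
    check_scalar(tau_inf, "tau_inf", lower = 0, strict_lower = TRUE)
  check_scalar(p, "p", lower = 0, strict_lower = TRUE)
  structure(list(n = n, tau0 = sigma0^2, sigma0 = sigma0,
                 tau_inf = tau_inf, p = p),
            class = "window_scale_policy")
}

#' Window variance for a channel frequency
#'
#' Evaluates the window-scale policy at angular frequency \code{omega}
#' (rad/s): \eqn{\tau = \tau_0 + (2\pi n/\omega)^2}, followed by the soft
#' upper bound when \code{tau_inf} is finite.
#'
#' @param omega angular frequency in rad/s (positive, vectorized).
#' @param policy a [window_scale_policy()].
#' @return Window variance in seconds squared.
#' @export
window_variance_for_frequency <- function(omega, policy) {
  stopifnot(inherits(policy, "window_scale_policy"))
  if (any(omega <= 0)) stop("'omega' must be positive", call. = FALSE)
  tau <- policy$tau0 + (2 * pi * policy$n / omega)^2
  if (is.finite(policy$tau_inf))
    tau <- tau / (1 + (tau / policy$tau_inf)^policy$p)^(1 / policy$p)
  tau
}

#' Frequency where the soft lower bound takes over
#'
#' The lower-bounded window scale \eqn{\tau = \tau_0 + (2\pi n/\omega)^2}
#' deviates from wavelength proportionality at high frequencies. Quantifying
#' "high" as the frequency where \eqn{\tau = \beta^2 \tau_0}, this function
#' returns \eqn{f = n / (\sigma_0\sqrt{\beta^2 - 1})} in Hz: with the
#' defaults (\eqn{\sigma_0} = 1 ms, n = 8, \eqn{\beta} = 2) about 4.6 kHz.
#'
#' @param policy a [window_scale_policy()] with \code{sigma0 > 0}.
#' @param beta tolerance factor (> 1).
#' @return Frequency in Hz.
#' @export
soft_bound_frequency <- function(policy = window_scale_policy(), beta = 2) {
  stopifnot(inherits(policy, "window_scale_policy"))
  check_scalar(beta, "beta", lower = 1, strict_lower = TRUE)
  if (policy$sigma0 <= 0) stop("policy has no lower bound (sigma0 = 0)",
                               call. = FALSE)
  policy$n / (policy$sigma0 * sqrt(beta^2 - 1))
}

#' Spectrogram parameters
#'
#' Bundles the configuration of [compute_spectrogram()]: sample rate,
#' log-frequency axis, window-scale policy, temporal window family
#' (non-causal Gaussian, or a time-causal cascade with uniform or
#' logarithmic scale distribution), output decimation and optional delay
#' compensation for the time-causal families.
#'
#' @param sample_rate sampling frequency in Hz.
#' @param axis a [log_frequency_axis()].
#' @param policy a [window_scale_policy()].
#' @param family \code{"gaussian"}, \code{"time_causal_uniform"} or
#'   \code{"time_causal_log"}.
#' @param K number of cascade stages (time-causal families; default 7).
#' @param c distribution ratio (> 1, logarithmic family; default sqrt(2)).
#' @param hop output decimation in samples; defaults to 1 ms worth of
#'   samples (at least 1).
#' @param delay_compensation logical; shift each time-causal channel earlier
#'   by the delay of the window's first inflection point (whole samples).
#' @return An object of class \code{"spectrogram_params"}.
#' @export
spectrogram_params <- function(sample_rate,
                               axis = log_frequency_axis(),
                               policy = window_scale_policy(),
                               family = c("gaussian", "time_causal_uniform",
                                          "time_causal_log"),
                               K = 7, c = sqrt(2), hop = NULL,
                               delay_compensation = FALSE) {
  family <- match.arg(family)
  check_scalar(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  stopifnot(inherits(axis, "log_frequency_axis"),
            inherits(policy, "window_scale_policy"))
  if (family != "gaussian") check_scalar(K, "K", lower = 1, integer = TRUE)
  if (family == "time_causal_log")
    check_scalar(c, "c", lower = 1, strict_lower = TRUE)
  if (is.null(hop)) hop <- max(1L, round(sample_rate * 1e-3))
  check_scalar(hop, "hop", lower = 1, integer = TRUE)
  if (max(axis$frequencies) >= sample_rate / 2)
    stop("channel frequencies must lie below the Nyquist frequency ",
         sample_rate / 2, " Hz", call. = FALSE)
  structure(list(sample_rate = sample_rate, axis = axis, policy = policy,
                 family = family, K = as.integer(K), c = c,
                 hop = as.integer(hop),
                 delay_compensation = isTRUE(delay_compensation)),
            class = "spectrogram_params")
}

#' Delay of a time-causal window at a given frequency
#'
#' Returns the temporal delay used for delay compensation: the time of the
#' first inflection point of the zero-order time-causal window at the
#' channel's window scale. For the uniform family this is the closed form
#' \eqn{(K - 1 - \sqrt{K - 1})\,\mu}; for the logarithmic family it is
#' located numerically on the cascade impulse response (computed once per
#' \code{(K, c)} in units of \eqn{\sqrt{\tau}} — the kernel family is
#' self-similar in \eqn{\sqrt{\tau}} — and rescaled per channel). A
#' single-stage cascade is a pure decaying exponential whose first
#' inflection sits at the origin.
#'
#' @param params a [spectrogram_params()] with a time-causal family.
#' @param omega angular frequency in rad/s.
#' @return Delay in seconds.
#' @export
window_delay <- function(params, omega) {
  stopifnot(inherits(params, "spectrogram_params"))
  if (params$family == "gaussian")
    stop("delay compensation does not apply to the Gaussian family ",
         "(its delay is the explicit parameter delta)", call. = FALSE)
  tau <- window_variance_for_frequency(omega, params$policy)
  unit_window_delay(params$family, params$K, params$c) * sqrt(tau)
}

# First-inflection delay in units of sqrt(tau); memoized per (family, K, c).
unit_window_delay <- local({
  cache <- new.env(parent = emptyenv())
  function(family, K, c) {
    key <- paste(family, K, signif(c, 12), sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- if (K == 1L) 0
      else if (family == "time_causal_uniform")
        max(0, (K - 1 - sqrt(K - 1)) / sqrt(K))
      else {
        dm <- delay_metrics(log_discretization(1, K, c))
        if (is.na(dm$t_infl1)) 0 else dm$t_infl1
      }
    cache[[key]] <- val
    val
  }
})

#' Compute a multi-scale spectrogram
#'
#' For each channel of the log-frequency axis, the signal is multiplied by
#' \eqn{\cos(\omega t)} and \eqn{\sin(\omega t)} (heterodyne demodulation
#' with absolute sample time), both projections are smoothed with the
#' family's temporal kernel at the channel's window scale
#' \eqn{\tau(\omega)}, and the two outputs are combined into the complex
#' channel response. The Gaussian family uses the discrete analogue of the
#' Gaussian kernel with mirrored boundaries (zero delay, for off-line use);
#' the time-causal families use a cascade of first-order recursive filters
#' whose variance bookkeeping is exact. The output is decimated by
#' \code{params$hop}. With \code{delay_compensation} each time-causal
#' channel is advanced by the whole-sample rounding of [window_delay()]
#' (edge-replicated at the tail).
#'
#' @param signal numeric vector, a mono waveform.
#' @param params a [spectrogram_params()].
#' @return An object of class \code{"complex_spectrogram"}: list with
#'   \code{times} (seconds), \code{axis}, complex matrix \code{values}
#'   (time x channel) and \code{params}.
#' @export
#' @examples
#' fs <- 4000
#' t <- seq(0, 0.5, by = 1 / fs)
#' x <- sin(2 * pi * 440 * t)
#' p <- spectrogram_params(fs, log_frequency_axis(220, 880, 12),
#'                         family = "time_causal_uniform", K = 4)
#' S <- compute_spectrogram(x, p)
#' max(abs(S$values))   # about 0.5 in steady state
compute_spectrogram <- function(signal, params) {
  stopifnot(inherits(params, "spectrogram_params"))
  if (length(signal) == 0L) stop("empty signal", call. = FALSE)
  signal <- as.numeric(signal)
  fs <- params$sample_rate
  n <- length(signal)
  tt <- (seq_len(n) - 1L) / fs
  idx <- seq(1L, n, by = params$hop)
  freqs <- params$axis$frequencies
  vals <- matrix(0i, nrow = length(idx), ncol = length(freqs))
  for (j in seq_along(freqs)) {
    omega <- 2 * pi * freqs[j]
    tau <- window_variance_for_frequency(omega, params$policy)
    tau_sampl <- fs^2 * tau
    fc <- signal * cos(omega * tt)
    fsn <- signal * sin(omega * tt)
    if (params$family == "gaussian") {
      re <- smooth_1d(fc, tau_sampl)
      im <- -smooth_1d(fsn, tau_sampl)
    } else {
      casc <- cascade_for_scale(
        tau_sampl, params$K,
        if (params$family == "time_causal_uniform") "uniform" else
          "logarithmic",
        params$c)
      re <- recursive_smooth(fc, casc)[, params$K]
      im <- -recursive_smooth(fsn, casc)[, params$K]
      if (params$delay_compensation) {
        shift <- round(window_delay(params, omega) * fs)
        if (shift > 0) {
          keep <- pmin(seq_len(n) + shift, n)
          re <- re[keep]; im <- im[keep]
        }
      }
    }
    vals[, j] <- complex(real = re[idx], imaginary = im[idx])
  }
  structure(list(times = tt[idx], axis = params$axis, values = vals,
                 params = params),
            class = "complex_spectrogram")
}

#' @export
print.complex_spectrogram <- function(x, ...) {
  cat(sprintf(
    "Complex spectrogram: %d frames x %d channels (%s family), %.3g s\n",
    nrow(x$values), ncol(x$values), x$params$family, max(x$times)))
  invisible(x)
}

#' Logarithmic (dB) magnitude of a spectrogram
#'
#' \eqn{S_{dB} = 20\log_{10}(|S| / S_0)}, clamped below at \code{floor_dB}.
#' The reference \code{S0} defaults to the global magnitude maximum so that
#' 0 dB marks the spectrogram peak. A multiplicative change of the sound
#' pressure shifts every dB value by a constant, which is what makes
#' derivative features on this representation invariant to sound level.
#'
#' @param S a \code{"complex_spectrogram"}.
#' @param S0 reference magnitude; \code{NULL} (default) uses
#'   \code{max(abs(S$values))}.
#' @param floor_dB clamp level in dB (default -120).
#' @return An object of class \code{"log_spectrogram"}: \code{times},
#'   \code{axis}, matrix \code{values_dB}, \code{S0}, \code{floor_dB} and
#'   the grid steps \code{dt} (s) and \code{dnu} (semitones).
#' @export
to_log_magnitude <- function(S, S0 = NULL, floor_dB = -120) {
  stopifnot(inherits(S, "complex_spectrogram"))
  mag <- abs(S$values)
  if (is.null(S0)) S0 <- max(mag)
  if (!is.finite(S0) || S0 <= 0) S0 <- 1
  db <- 20 * log10(pmax(mag, .Machine$double.xmin) / S0)
  db[db < floor_dB] <- floor_dB
  dt <- if (length(S$times) > 1L) S$times[2L] - S$times[1L] else
    S$params$hop / S$params$sample_rate
  structure(list(times = S$times, axis = S$axis, values_dB = db, S0 = S0,
                 floor_dB = floor_dB, dt = dt, dnu = S$axis$dnu),
            class = "log_spectrogram")
}

#' @export
print.log_spectrogram <- function(x, ...) {
  cat(sprintf("Log spectrogram: %d frames x %d channels, range [%.1f, %.1f] dB\n",
              nrow(x$values_dB), ncol(x$values_dB), min(x$values_dB),
              max(x$values_dB)))
  invisible(x)
}

#' Gammatone parameters of the equal-time-constant window
#'
#' The cascade of \code{K} truncated exponentials with equal time constant
#' \code{mu}, modulated by a sinusoid, is exactly a Gammatone filter
#' \eqn{a\,t^{K-1} e^{-2\pi b t}\cos(2\pi\phi t + \alpha)} with
#' \eqn{a = 1/(\mu^K\,\Gamma(K))} and \eqn{b = 1/(2\pi\mu)}.
#'
#' @param mu stage time constant in seconds (positive).
#' @param K number of stages.
#' @return Named list with elements \code{a} and \code{b}.
#' @export
gammatone_parameters <- function(mu, K) {
  check_scalar(mu, "mu", lower = 0, strict_lower = TRUE)
  check_scalar(K, "K", lower = 1, integer = TRUE)
  list(a = 1 / (mu^K * gamma(K)), b = 1 / (2 * pi * mu))
}

#' Export a spectrogram to a data frame / CSV
#'
#' Long-format export with columns \code{time}, \code{nu}, \code{frequency}
#' and either the complex parts or the dB value.
#'
#' @param x a \code{"complex_spectrogram"} or \code{"log_spectrogram"}.
#' @param file optional path; when given the data frame is also written as
#'   CSV.
#' @return The data frame, invisibly when \code{file} is given.
#' @export
spectrogram_to_frame <- function(x, file = NULL) {
  if (inherits(x, "complex_spectrogram")) {
    df <- data.frame(
      time = rep(x$times, times = ncol(x$values)),
      nu = rep(x$axis$nu_values, each = nrow(x$values)),
      frequency = rep(x$axis$frequencies, each = nrow(x$values)),
      re = as.vector(Re(x$values)), im = as.vector(Im(x$values)))
  } else if (inherits(x, "log_spectrogram")) {
    df <- data.frame(
      time = rep(x$times, times = ncol(x$values_dB)),
      nu = rep(x$axis$nu_values, each = nrow(x$values_dB)),
      frequency = rep(x$axis$frequencies, each = nrow(x$values_dB)),
      dB = as.vector(x$values_dB))
  } else stop("unsupported object", call. = FALSE)
  if (!is.null(file)) {
    utils::write.csv(df, file, row.names = FALSE)
    return(invisible(df))
  }
  df
}
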