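# Synthetic stimulus generation: harmonic complexes with a dB/octave
# spectral slope, optional exponential glissando, and gated tones for
# onset/offset experiments.

#' Harmonic stimulus specification
#'
#' Describes a deterministic harmonic complex: fundamental \code{f0} (Hz),
#' \code{n_partials} harmonics whose amplitudes fall off by
#' \code{slope_db_per_octave} dB per octave relative to the fundamental, an
#' optional glissando (common exponential drift of all partials, linear in
#' log-frequency at \code{glissando} semitones/second) and a raised-cosine
#' onset ramp. Partials that would exceed the Nyquist frequency at any time
#' during the sweep are dropped with a warning.
#'
#' @param f0 fundamental frequency in Hz (positive).
#' @param n_partials number of partials (integer >= 1; default 20).
#' @param slope_db_per_octave spectral slope in dB per octave (default 6,
#'   i.e. partial amplitudes fall by 6 dB per octave).
#' @param duration duration in seconds.
#' @param amplitude peak amplitude of partial 1 (default 1).
#' @param sample_rate sampling frequency in Hz (default 44100).
#' @param glissando drift rate in semitones per second (0 = stationary).
#' @param onset_ramp raised-cosine ramp length in seconds (default 0).
#' @return An object of class \code{"harmonic_spec"}.
#' @export
harmonic_spec <- function(f0, n_partials = 20, slope_db_per_octave = 6,
                          duration = 1, amplitude = 1, sample_rate = 44100,
                          glissando = 0, onset_ramp = 0) {
  check_scalar(f0, "f0", lower = 0, strict_lower = TRUE)
  check_scalar(n_partials, "n_partials", lower = 1, integer = TRUE)
  check_scalar(slope_db_per_octave, "slope_db_per_octave")
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  check_scalar(amplitude, "amplitude", lower = 0)
  check_scalar(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  check_scalar(glissando, "glissando")
  check_scalar(onset_ramp, "onset_ramp", lower = 0)
  structure(list(f0 = f0, n_partials = as.integer(n_partials),
                 slope_db_per_octave = slope_db_per_octave,
                 duration = duration, amplitude = amplitude,
                 sample_rate = sample_rate, glissando = glissando,
                 onset_ramp = onset_ramp),
            class = "harmonic_spec")
}

#' Synthesize a harmonic complex
#'
#' Renders the stimulus described by a [harmonic_spec()]. Partial \code{j}
#' has amplitude \eqn{A \cdot 10^{-m \log_2 j / 20}} (slope \code{m} in
#' dB/octave) and instantaneous frequency
#' \eqn{f_j(t) = j f_0\, 2^{v t / 12}}; the phase is the exact integral of
#' the exponential sweep,
#' \eqn{\phi_j(t) = 2\pi j f_0\, 12 (2^{v t/12} - 1)/(v \ln 2)}.
#'
#' @param spec a [harmonic_spec()].
#' @return Numeric vector of samples.
#' @export
#' @examples
#' x <- synth_harmonic(harmonic_spec(440, n_partials = 1, duration = 0.1,
#'                                   sample_rate = 8000))
#' sqrt(mean(x^2))    # RMS of a unit sine: 1/sqrt(2)
synth_harmonic <- function(spec) {
  stopifnot(inherits(spec, "harmonic_spec"))
  fs <- spec$sample_rate
  t <- seq(0, spec$duration - 1 / fs, by = 1 / fs)
  v <- spec$glissando
  fmax_factor <- if (v > 0) 2^(v * spec$duration / 12) else 1
  j_all <- seq_len(spec$n_partials)
  keep <- j_all * spec$f0 * fmax_factor < fs / 2
  if (!all(keep))
    warning(sum(!keep), " partial(s) above the Nyquist frequency dropped")
  j_all <- j_all[keep]
  if (!length(j_all)) return(numeric(length(t)))
  phase_base <- if (v == 0) 2 * pi * spec$f0 * t else
    2 * pi * spec$f0 * 12 * (2^(v * t / 12) - 1) / (v * log(2))
  x <- numeric(length(t))
  for (j in j_all) {
    a <- spec$amplitude * 10^(-spec$slope_db_per_octave * log2(j) / 20)
    x <- x + a * sin(j * phase_base)
  }
  if (spec$onset_ramp > 0) {
    nr <- min(length(t), round(spec$onset_ramp * fs))
    if (nr > 0)
      x[seq_len(nr)] <- x[seq_len(nr)] *
        (1 - cos(pi * seq_len(nr) / nr)) / 2
  }
  x
}

#' Gated tone for onset/offset experiments
#'
#' A pure tone at \code{frequency}, switched on at \code{t_on} and off at
#' \code{t_off} with raised-cosine ramps of length \code{ramp} seconds
#' (\code{ramp = 0} gives ideal steps).
#'
#' @param frequency tone frequency in Hz.
#' @param t_on,t_off gate times in seconds, \code{t_on < t_off}.
#' @param duration total duration in seconds.
#' @param sample_rate sampling frequency in Hz.
#' @param amplitude tone amplitude (default 1).
#' @param ramp ramp length in seconds (default 0).
#' @return Numeric vector of samples.
#' @export
synth_step_band <- function(frequency, t_on, t_off, duration, sample_rate,
                            amplitude = 1, ramp = 0) {
  check_scalar(frequency, "frequency", lower = 0, strict_lower = TRUE)
  check_scalar(t_on, "t_on", lower = 0)
  check_scalar(t_off, "t_off", lower = 0)
  if (t_off <= t_on) stop("'t_off' must be > 't_on'", call. = FALSE)
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  check_scalar(ramp, "ramp", lower = 0)
  fs <- sample_rate
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  gate <- as.numeric(t >= t_on & t < t_off)
  if (ramp > 0) {
    up <- t >= t_on & t < t_on + ramp
    gate[up] <- (1 - cos(pi * (t[up] - t_on) / ramp)) / 2
    down <- t >= t_off - ramp & t < t_off
    gate[down] <- (1 + cos(pi * (t[down] - (t_off - ramp)) / ramp)) / 2
  }
  amplitude * gate * sin(2 * pi * frequency * t)
}
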