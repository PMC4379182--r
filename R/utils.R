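# Internal numeric helpers shared across modules.

# Linear convolution of two real vectors via zero-padded FFT.
# Returns the full convolution of length length(x) + length(y) - 1.
fft_convolve <- function(x, y) {
  n <- length(x) + length(y) - 1L
  nf <- stats::nextn(n)
  X <- stats::fft(c(x, rep(0, nf - length(x))))
  Y <- stats::fft(c(y, rep(0, nf - length(y))))
  Re(stats::fft(X * Y, inverse = TRUE))[seq_len(n)] / nf
}

# Index vector implementing whole-sample mirror extension of 1..n
# (reflection without repeating the boundary sample), valid for any
# out-of-range offset.
mirror_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * (n - 1L)
  j <- (idx - 1L) %% period
  j <- ifelse(j >= n, period - j, j)
  j + 1L
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  if (x > upper)
    stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  invisible(x)
}

# Trapezoid integral on a (possibly non-uniform) grid.
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# Parabolic (three-point) refinement of a maximum on a uniform grid.
# Returns the refined position given grid values y at x[i-1], x[i], x[i+1].
parabolic_peak <- function(x, y, i) {
  if (i <= 1L || i >= length(y)) return(x[i])
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (denom == 0) return(x[i])
  x[i] + (x[2L] - x[1L]) * 0.5 * (y[i - 1L] - y[i + 1L]) / denom
}

count_local_extrema <- function(x) {
  d <- diff(x)
  d <- d[d != 0]
  if (length(d) < 2L) return(0L)
  sum(diff(sign(d)) != 0)
}
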