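# Second-layer spectro-temporal receptive fields over the log spectrogram:
# the idealized family A(t, nu) = d_t^alpha d_nu^beta g(nu - v t; s) T(t; tau_a)
# combining a temporal scale-space kernel T (Gaussian or time-causal
# cascade), a Gaussian over log-frequency, a glissando shear v and
# scale-normalized derivatives.

#' Receptive-field specification
#'
#' Parameters of a second-layer spectro-temporal receptive field:
#' second-layer temporal variance \code{tau_a} (s^2), logspectral variance
#' \code{s} (semitones^2), glissando rate \code{v} (semitones/second),
#' derivative orders \code{alpha} (time) and \code{beta} (log-frequency),
#' and the temporal kernel family. With \code{v = 0} the kernel is
#' separable; \code{v != 0} shears it along the frequency axis, adapting it
#' to sounds whose log-frequencies drift linearly over time. For the
#' time-causal families the composed kernel is only \eqn{K - 1} times
#' differentiable, so \code{alpha < K} is required.
#'
#' @param tau_a temporal variance in seconds squared (non-negative).
#' @param s logspectral variance in semitones squared (non-negative).
#' @param v glissando rate in semitones per second.
#' @param alpha temporal derivative order (0, 1 or 2).
#' @param beta logspectral derivative order (0, 1 or 2).
#' @param family \code{"gaussian"}, \code{"time_causal_uniform"} or
#'   \code{"time_causal_log"}.
#' @param K,c cascade stages and distribution ratio (time-causal families;
#'   defaults K = 4, c = sqrt(2)).
#' @param delta temporal delay in seconds (Gaussian family only).
#' @return An object of class \code{"rf_spec"}.
#' @export
#' @examples
#' rf_spec(tau_a = (0.01)^2, s = 0.25, alpha = 1)   # an onset detector
rf_spec <- function(tau_a, s, v = 0, alpha = 0, beta = 0,
                    family = c("gaussian", "time_causal_uniform",
                               "time_causal_log"),
                    K = 4, c = sqrt(2), delta = 0) {
  family <- match.arg(family)
  check_scalar(tau_a, "tau_a", lower = 0)
  check_scalar(s, "s", lower = 0)
  check_scalar(v, "v")
  check_scalar(alpha, "alpha", lower = 0, upper = 2, integer = TRUE)
  check_scalar(beta, "beta", lower = 0, upper = 2, integer = TRUE)
  check_scalar(delta, "delta", lower = 0)
  if (family != "gaussian") {
    check_scalar(K, "K", lower = 1, integer = TRUE)
    if (alpha >= K)
      stop("'alpha' must be < K for the time-causal families", call. = FALSE)
    if (family == "time_causal_log")
      check_scalar(c, "c", lower = 1, strict_lower = TRUE)
  }
  structure(list(tau_a = tau_a, s = s, v = v, alpha = as.integer(alpha),
                 beta = as.integer(beta), family = family, K = as.integer(K),
                 c = c, delta = delta),
            class = "rf_spec")
}

#' @export
print.rf_spec <- function(x, ...) {
  cat(sprintf(
    "RF spec: tau_a = %g s^2, s = %g st^2, v = %g st/s, d_t^%d d_nu^%d, %s\n",
    x$tau_a, x$s, x$v, x$alpha, x$beta, x$family))
  invisible(x)
}

# Derivatives of the 1-D Gaussian up to order 4 (probabilists' Hermite).
gaussian_derivative <- function(x, s, order = 0) {
  if (s <= 0) stop("Gaussian derivatives need s > 0", call. = FALSE)
  sg <- sqrt(s)
  u <- x / sg
  g <- stats::dnorm(x, sd = sg)
  he <- switch(as.character(order),
               "0" = 1, "1" = u, "2" = u^2 - 1, "3" = u^3 - 3 * u,
               "4" = u^4 - 6 * u^2 + 3,
               stop("order must be <= 4", call. = FALSE))
  (-1)^order * he * g / sg^order
}

# Temporal factor T^(m)(t) of an RF spec on a grid.
rf_temporal_factor <- function(spec, t_grid, order) {
  switch(spec$family,
    gaussian = sample_gaussian_kernel(
      gaussian_window(spec$tau_a, spec$delta), t_grid, order)$values,
    time_causal_uniform = sample_composed_uniform_kernel(
      sqrt(spec$tau_a / spec$K), spec$K, t_grid, order)$values,
    time_causal_log = sample_composed_kernel(
      log_discretization(spec$tau_a, spec$K, spec$c), t_grid, order)$values)
}

#' Render a spectro-temporal receptive-field kernel
#'
#' Samples the idealized receptive field
#' \eqn{A(t, \nu) = \partial_t^\alpha \partial_\nu^\beta
#'   [\,g(\nu - v t;\, s)\, T(t;\, \tau_a)\,]}
#' on the requested grids, for visualization or direct 2-D convolution.
#' Two temporal-derivative conventions are supported: \code{"plain"}
#' applies \eqn{\partial_t} at fixed \eqn{\nu} (expanding
#' \eqn{\partial_t g(\nu - vt) = -v\,g'}), while \code{"adapted"} uses the
#' glissando-following derivative \eqn{\partial_{\bar t} = \partial_t +
#' v\partial_\nu}, under which the kernel is exactly the sheared copy of
#' the separable \eqn{v = 0} kernel. The two coincide for \eqn{v = 0}.
#'
#' @param spec an [rf_spec()].
#' @param t_grid,nu_grid numeric grids (seconds; semitones, centered at the
#'   channel of interest).
#' @param derivative \code{"plain"} or \code{"adapted"}.
#' @return Matrix of size \code{length(t_grid)} x \code{length(nu_grid)}.
#' @export
render_rf_kernel <- function(spec, t_grid, nu_grid,
                             derivative = c("plain", "adapted")) {
  stopifnot(inherits(spec, "rf_spec"))
  derivative <- match.arg(derivative)
  A <- matrix(0, nrow = length(t_grid), ncol = length(nu_grid))
  if (derivative == "adapted" || spec$v == 0) {
    Tt <- rf_temporal_factor(spec, t_grid, spec$alpha)
    for (i in seq_along(t_grid))
      A[i, ] <- Tt[i] *
        gaussian_derivative(nu_grid - spec$v * t_grid[i], spec$s, spec$beta)
  } else {
    # plain d_t: A = sum_j C(alpha, j) (-v)^j g^(beta + j) T^(alpha - j)
    for (j in 0:spec$alpha) {
      Tt <- rf_temporal_factor(spec, t_grid, spec$alpha - j)
      w <- choose(spec$alpha, j) * (-spec$v)^j
      for (i in seq_along(t_grid))
        A[i, ] <- A[i, ] + w * Tt[i] *
          gaussian_derivative(nu_grid - spec$v * t_grid[i], spec$s,
                              spec$beta + j)
    }
  }
  A
}

#' Shear-warp a time-frequency matrix along the glissando direction
#'
#' Resamples every time frame along the frequency axis by the time-dependent
#' shift \eqn{v\,t} using cubic spline interpolation, with edge replication
#' outside the covered range. \code{"forward"} maps into the sheared frame
#' \eqn{\nu' = \nu - v t} (a ridge drifting at rate \code{v} becomes
#' horizontal); \code{"inverse"} maps back. Forward followed by inverse
#' reproduces the interior up to interpolation error.
#'
#' @param M numeric matrix, time x frequency.
#' @param v glissando rate in semitones per second.
#' @param times frame times in seconds.
#' @param nu_values channel log-frequencies in semitones.
#' @param direction \code{"forward"} or \code{"inverse"}.
#' @return Matrix of the same shape.
#' @export
shear_warp <- function(M, v, times, nu_values,
                       direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  if (v == 0) return(M)
  sgn <- if (direction == "forward") 1 else -1
  lo <- min(nu_values); hi <- max(nu_values)
  out <- M
  for (i in seq_len(nrow(M))) {
    f <- stats::splinefun(nu_values, M[i, ], method = "natural")
    q <- pmin(pmax(nu_values + sgn * v * times[i], lo), hi)
    out[i, ] <- f(q)
  }
  out
}

# Temporal smoothing of the columns of a time x frequency matrix at grid
# variance tau_grid, using the spec's kernel family.
rf_temporal_smooth <- function(M, spec, tau_grid) {
  if (tau_grid <= 0) return(M)
  if (spec$family == "gaussian")
    return(apply(M, 2L, smooth_1d, s = tau_grid))
  casc <- cascade_for_scale(
    tau_grid, spec$K,
    if (spec$family == "time_causal_uniform") "uniform" else "logarithmic",
    spec$c)
  apply(M, 2L, function(col) recursive_smooth(col, casc)[, spec$K])
}

#' Apply a receptive field to a log spectrogram
#'
#' Computes the second-layer receptive-field response as a separable
#' discrete pipeline: optional forward shear-warp by the glissando rate,
#' temporal smoothing at \code{tau_a} (recursive cascade or discrete
#' Gaussian), logspectral discrete-Gaussian smoothing at \code{s},
#' small-support difference operators of orders \code{alpha} and
#' \code{beta} (converted from grid units to per-second and per-semitone),
#' scale normalization by \eqn{\tau_a^{\alpha/2} s^{\beta/2}}, and the
#' inverse warp. With \code{derivative = "plain"} (default) and a nonzero
#' glissando the difference operators are applied after unwarping, so
#' \eqn{\partial_t} is taken at fixed \eqn{\nu}; \code{"adapted"}
#' differentiates inside the sheared frame (the glissando-following
#' derivative).
#'
#' @param SdB a \code{"log_spectrogram"} (or any list with fields
#'   \code{values_dB}, \code{times}, \code{axis}, \code{dt}, \code{dnu}).
#' @param spec an [rf_spec()].
#' @param derivative \code{"plain"} or \code{"adapted"}.
#' @return An object of class \code{"feature_map"}: \code{times},
#'   \code{axis}, matrix \code{values} and the \code{spec}; the applied
#'   scale-normalization factor is recorded in \code{normalization}.
#' @export
apply_rf <- function(SdB, spec, derivative = c("plain", "adapted")) {
  stopifnot(inherits(spec, "rf_spec"))
  derivative <- match.arg(derivative)
  M <- SdB$values_dB
  if (is.null(M)) stop("'SdB' must carry a values_dB matrix", call. = FALSE)
  dt <- SdB$dt
  dnu <- SdB$dnu
  nu <- SdB$axis$nu_values
  warped <- spec$v != 0
  diff_ops <- function(M) {
    if (spec$alpha == 1L) M <- difference_operator(M, "dt") / dt
    if (spec$alpha == 2L) M <- difference_operator(M, "dtt") / dt^2
    if (spec$beta == 1L) M <- difference_operator(M, "dnu") / dnu
    if (spec$beta == 2L) M <- difference_operator(M, "dnunu") / dnu^2
    M
  }
  smooth_ops <- function(M) {
    M <- rf_temporal_smooth(M, spec, spec$tau_a / dt^2)
    if (spec$s > 0) M <- t(apply(M, 1L, smooth_1d, s = spec$s / dnu^2))
    M
  }
  # the difference operators are applied before the smoothing they commute
  # with: any constant baseline in SdB then cancels exactly (to the last
  # bit) instead of surviving as rounding noise through the smoothing stages
  if (derivative == "plain" || !warped) {
    M <- diff_ops(M)
    if (warped) {
      M <- shear_warp(M, spec$v, SdB$times, nu, "forward")
      M <- smooth_ops(M)
      M <- shear_warp(M, spec$v, SdB$times, nu, "inverse")
    } else M <- smooth_ops(M)
  } else {
    M <- shear_warp(M, spec$v, SdB$times, nu, "forward")
    M <- diff_ops(M)
    M <- smooth_ops(M)
    M <- shear_warp(M, spec$v, SdB$times, nu, "inverse")
  }
  norm <- spec$tau_a^(spec$alpha / 2) * spec$s^(spec$beta / 2)
  structure(list(times = SdB$times, axis = SdB$axis, values = M * norm,
                 spec = spec, normalization = norm),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf(
    "Feature map: %d frames x %d channels, d_t^%d d_nu^%d, range [%.3g, %.3g]\n",
    nrow(x$values), ncol(x$values), x$spec$alpha, x$spec$beta,
    min(x$values), max(x$values)))
  invisible(x)
}
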