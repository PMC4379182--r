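# Continuous-domain temporal scale-space kernels: the (time-shifted) Gaussian
# and cascades of truncated exponential (first-order integrator) kernels,
# together with the discretizations of the temporal scale axis that define
# the time-causal kernels.

#' Time-shifted Gaussian temporal window
#'
#' Defines a Gaussian temporal smoothing kernel
#' \eqn{g(t; \tau, \delta) = \exp(-(t-\delta)^2 / 2\tau) / \sqrt{2\pi\tau}}
#' with temporal variance \code{tau} (seconds squared) and temporal delay
#' \code{delta} (seconds). The Gaussian is the canonical non-causal temporal
#' scale-space kernel: it is the unique family (up to the free delay) whose
#' smoothing never enhances local extrema. The delay is a free parameter and
#' defaults to 0, appropriate for off-line analysis.
#'
#' @param tau temporal variance in seconds squared; must be positive.
#' @param delta temporal delay in seconds; must be non-negative.
#' @return An object of class \code{"gaussian_window"}.
#' @seealso [sample_gaussian_kernel()]
#' @export
#' @examples
#' w <- gaussian_window(tau = 1, delta = 4)
#' ks <- sample_gaussian_kernel(w, seq(0, 8, by = 0.01))
#' sum(diff(ks$times) * (head(ks$values, -1) + tail(ks$values, -1)) / 2)
gaussian_window <- function(tau, delta = 0) {
  check_scalar(tau, "tau", lower = 0, strict_lower = TRUE)
  check_scalar(delta, "delta", lower = 0)
  structure(list(tau = tau, delta = delta), class = "gaussian_window")
}

#' Discretization of the temporal scale axis for a time-causal kernel
#'
#' A time-causal temporal scale-space kernel is a cascade of \code{K}
#' first-order integrators (truncated exponentials) with time constants
#' \code{mu[k]}. The intermediate variances \code{tau_levels[k]} accumulate as
#' \eqn{\tau_k = \sum_{j \le k} \mu_j^2} and the composed variance equals
#' \code{tau_max}. Two level distributions are supported: \emph{uniform},
#' \eqn{\tau_k = (k/K)\,\tau_{max}} so that all \eqn{\mu_k =
#' \sqrt{\tau_{max}/K}} are equal (the Gammatone case), and
#' \emph{logarithmic} (self-similar), \eqn{\tau_k = c^{2(k-K)}\tau_{max}}
#' for a distribution ratio \eqn{c > 1} (the generalized-Gammatone case),
#' giving \eqn{\mu_1 = c^{1-K}\sqrt{\tau_{max}}} and
#' \eqn{\mu_k = c^{k-K-1}\sqrt{c^2-1}\,\sqrt{\tau_{max}}} for \eqn{k \ge 2}.
#'
#' @param tau_max composed temporal variance (seconds squared), positive.
#' @param K number of first-order integrators, integer \eqn{\ge 1}.
#' @param c distribution ratio (> 1), logarithmic distribution only.
#' @return An object of class \code{"scale_discretization"} with fields
#'   \code{tau_max}, \code{K}, \code{distribution}, \code{c},
#'   \code{tau_levels} and \code{mu}.
#' @export
#' @examples
#' d <- uniform_discretization(1, 4)
#' sum(d$mu)            # temporal mean, 2 for K = 4
#' sum(d$mu^2)          # variance additivity: equals tau_max
uniform_discretization <- function(tau_max, K) {
  check_scalar(tau_max, "tau_max", lower = 0, strict_lower = TRUE)
  check_scalar(K, "K", lower = 1, integer = TRUE)
  K <- as.integer(K)
  tau_levels <- (1:K) / K * tau_max
  mu <- rep(sqrt(tau_max / K), K)
  structure(list(tau_max = tau_max, K = K, distribution = "uniform",
                 c = NA_real_, tau_levels = tau_levels, mu = mu),
            class = "scale_discretization")
}

#' @rdname uniform_discretization
#' @export
#' @examples
#' dl <- log_discretization(1, 7, sqrt(2))
#' sum(dl$mu)           # 2.237: faster than the uniform 2.646
log_discretization <- function(tau_max, K, c) {
  check_scalar(tau_max, "tau_max", lower = 0, strict_lower = TRUE)
  check_scalar(K, "K", lower = 1, integer = TRUE)
  check_scalar(c, "c", lower = 1, strict_lower = TRUE)
  K <- as.integer(K)
  tau_levels <- c^(2 * ((1:K) - K)) * tau_max
  mu <- c(c^(1 - K) * sqrt(tau_max),
          if (K >= 2) sqrt(diff(tau_levels)))
  structure(list(tau_max = tau_max, K = K, distribution = "logarithmic",
                 c = c, tau_levels = tau_levels, mu = mu),
            class = "scale_discretization")
}

#' @export
print.scale_discretization <- function(x, ...) {
  cat(sprintf("Temporal scale discretization (%s), K = %d, tau_max = %g\n",
              x$distribution, x$K, x$tau_max))
  if (x$distribution == "logarithmic") cat(sprintf("  c = %g\n", x$c))
  cat("  time constants mu_k:", signif(x$mu, 4), "\n")
  invisible(x)
}

#' Distribution ratio from temporal scale bounds
#'
#' Inverts the logarithmic level recursion: given the finest and coarsest
#' temporal variances and the number of levels, returns the ratio \code{c}
#' such that \code{tau_levels[1] == tau_min} and
#' \code{tau_levels[K] == tau_max}, i.e.
#' \eqn{c = (\tau_{max}/\tau_{min})^{1/(2(K-1))}}.
#'
#' @param tau_min,tau_max finest and coarsest temporal variances
#'   (seconds squared), \code{0 < tau_min < tau_max}.
#' @param K number of levels, integer \eqn{\ge 2}.
#' @return The distribution ratio, a scalar > 1.
#' @export
c_from_tau_bounds <- function(tau_min, tau_max, K) {
  check_scalar(tau_min, "tau_min", lower = 0, strict_lower = TRUE)
  check_scalar(tau_max, "tau_max", lower = 0, strict_lower = TRUE)
  if (tau_min >= tau_max) stop("'tau_min' must be < 'tau_max'", call. = FALSE)
  check_scalar(K, "K", lower = 2, integer = TRUE)
  (tau_max / tau_min)^(1 / (2 * (K - 1)))
}

kernel_samples <- function(times, values, derivative_order) {
  structure(list(times = times, values = values,
                 derivative_order = as.integer(derivative_order)),
            class = "kernel_samples")
}

#' @export
print.kernel_samples <- function(x, ...) {
  cat(sprintf("Kernel samples: %d points on [%g, %g], derivative order %d\n",
              length(x$times), min(x$times), max(x$times), x$derivative_order))
  invisible(x)
}

#' Sample the Gaussian temporal kernel and its derivatives
#'
#' Evaluates \eqn{\partial_t^\alpha g(t - \delta; \tau)} for derivative
#' orders 0, 1 or 2 at the requested sample instants.
#'
#' @param w a [gaussian_window()].
#' @param times numeric vector of sample instants (seconds).
#' @param derivative_order 0, 1 or 2.
#' @return A \code{"kernel_samples"} object with fields \code{times},
#'   \code{values}, \code{derivative_order}.
#' @export
sample_gaussian_kernel <- function(w, times, derivative_order = 0) {
  stopifnot(inherits(w, "gaussian_window"))
  check_scalar(derivative_order, "derivative_order", lower = 0, upper = 2,
               integer = TRUE)
  u <- times - w$delta
  g <- stats::dnorm(u, sd = sqrt(w$tau))
  v <- switch(as.character(derivative_order),
              "0" = g,
              "1" = -u / w$tau * g,
              "2" = (u^2 / w$tau^2 - 1 / w$tau) * g)
  kernel_samples(times, v, derivative_order)
}

#' Sample the equal-time-constant composed kernel (closed form)
#'
#' The cascade of \code{K} truncated exponentials with equal time constant
#' \code{mu} has the closed-form impulse response
#' \eqn{h(t) = t^{K-1} e^{-t/\mu} / (\mu^K \Gamma(K))} for \eqn{t \ge 0}
#' (the Gammatone envelope). The composed kernel is continuous of order
#' \eqn{K - 1}, so derivative orders \eqn{\alpha \ge K} are rejected.
#'
#' @param mu time constant of each stage (seconds), positive.
#' @param K number of stages, integer \eqn{\ge 1}.
#' @param times numeric vector of sample instants (seconds).
#' @param derivative_order 0, 1 or 2 (and < \code{K}).
#' @return A \code{"kernel_samples"} object.
#' @export
#' @examples
#' ks <- sample_composed_uniform_kernel(0.25, 4, seq(0, 3, by = 0.001))
#' ks$times[which.max(ks$values)]   # peak at (K - 1) mu = 0.75
sample_composed_uniform_kernel <- function(mu, K, times, derivative_order = 0) {
  check_scalar(mu, "mu", lower = 0, strict_lower = TRUE)
  check_scalar(K, "K", lower = 1, integer = TRUE)
  check_scalar(derivative_order, "derivative_order", lower = 0, upper = 2,
               integer = TRUE)
  if (derivative_order >= K)
    stop("derivative order must be smaller than K: the composed kernel is ",
         "only continuous of order K - 1", call. = FALSE)
  tp <- pmax(times, 0)
  e <- ifelse(times < 0, 0, exp(-tp / mu))
  gK <- gamma(K)
  pow <- function(p) ifelse(times < 0, 0, ifelse(tp == 0 & p == 0, 1, tp^p))
  v <- switch(as.character(derivative_order),
    "0" = pow(K - 1) * e / (mu^K * gK),
    "1" = mu^(-K - 1) * pow(K - 2) * ((K - 1) * mu - tp) * e / gK,
    "2" = mu^(-K - 2) * pow(K - 3) *
          ((K^2 - 3 * K + 2) * mu^2 - 2 * (K - 1) * tp * mu + tp^2) * e / gK)
  kernel_samples(times, v, derivative_order)
}

# Impulse response of a cascade of truncated exponentials with (possibly
# distinct) time constants mu, computed by sequential numeric convolution of
# analytically sampled primitives on a uniform grid tt (starting at 0).
# Endpoint samples are half-weighted so each convolution is a trapezoid
# approximation of the continuous convolution integral.
cascade_impulse_response <- function(mu, tt) {
  dt <- tt[2L] - tt[1L]
  half0 <- function(x) { x[1L] <- x[1L] / 2; x }
  h <- exp(-tt / mu[1L]) / mu[1L]
  for (m in mu[-1L]) {
    g <- exp(-tt / m) / m
    h <- fft_convolve(half0(h), half0(g))[seq_along(tt)] * dt
  }
  h
}

# Default sampling grid for a time-causal kernel: step sqrt(tau_max)/1000,
# support [0, m + 10 sqrt(tau_max)] with m the temporal mean.
default_kernel_grid <- function(d, step_div = 1000) {
  s <- sqrt(d$tau_max)
  seq(0, sum(d$mu) + 10 * s, by = s / step_div)
}

#' Sample a composed time-causal kernel with arbitrary time constants
#'
#' For a cascade with distinct time constants (the logarithmic distribution)
#' there is no compact closed form, so the impulse response is computed by
#' sequential numeric convolution of the analytically sampled truncated
#' exponentials on a fine internal grid (step \eqn{\sqrt{\tau_{max}}/1000})
#' and interpolated to the requested instants. Derivatives are obtained by
#' central differences on the fine grid. For a uniform discretization the
#' closed form of [sample_composed_uniform_kernel()] is used instead.
#'
#' @param d a \code{"scale_discretization"}.
#' @param times numeric vector of sample instants (seconds); defaults to the
#'   internal fine grid.
#' @param derivative_order non-negative integer < \code{K}.
#' @return A \code{"kernel_samples"} object.
#' @export
sample_composed_kernel <- function(d, times = NULL, derivative_order = 0) {
  stopifnot(inherits(d, "scale_discretization"))
  check_scalar(derivative_order, "derivative_order", lower = 0, integer = TRUE)
  if (derivative_order >= d$K)
    stop("derivative order must be smaller than K: the composed kernel is ",
         "only continuous of order K - 1", call. = FALSE)
  if (d$distribution == "uniform") {
    if (is.null(times)) times <- default_kernel_grid(d)
    return(sample_composed_uniform_kernel(d$mu[1L], d$K, times,
                                          derivative_order))
  }
  grid <- default_kernel_grid(d)
  h <- cascade_impulse_response(d$mu, grid)
  dt <- grid[2L] - grid[1L]
  v <- h
  r <- derivative_order
  while (r > 0) {                       # central differences on the fine grid
    v <- c(0, (v[-(1:2)] - v[1:(length(v) - 2L)]) / (2 * dt), 0)
    r <- r - 1L
  }
  if (is.null(times)) return(kernel_samples(grid, v, derivative_order))
  vi <- stats::approx(grid, v, xout = times, yleft = 0, yright = 0)$y
  kernel_samples(times, vi, derivative_order)
}
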