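# Discrete-domain scale-space primitives: first-order recursive filters and
# their cascades, the discrete analogue of the Gaussian kernel, mirrored
# boundary smoothing, and small-support difference operators.

#' Discrete time constant from a variance increment
#'
#' A first-order recursive filter
#' \eqn{f_{out}(t) - f_{out}(t-1) = (f_{in}(t) - f_{out}(t-1)) / (1 + \mu)}
#' has temporal mean \eqn{\mu} and temporal variance
#' \eqn{\Delta\tau = \mu^2 + \mu} (in grid units). Inverting gives
#' \eqn{\mu = (\sqrt{1 + 4\Delta\tau} - 1) / 2}, so the discrete variance
#' bookkeeping of a cascade is exact by construction.
#'
#' @param delta_tau variance increment in grid units squared (vectorized),
#'   non-negative.
#' @return The per-stage time constant(s) in grid units.
#' @export
#' @examples
#' mu_from_delta_tau(c(0, 2, 6))   # 0, 1, 2
mu_from_delta_tau <- function(delta_tau) {
  if (any(!is.finite(delta_tau)) || any(delta_tau < 0))
    stop("'delta_tau' must be non-negative", call. = FALSE)
  (sqrt(1 + 4 * delta_tau) - 1) / 2
}

#' First-order recursive filter cascade
#'
#' Builds a cascade of discrete first-order recursive filters realizing a set
#' of intermediate temporal scale levels \code{tau_levels} (grid units
#' squared). The per-stage variance increments are
#' \code{diff(c(0, tau_levels))} and each stage's time constant satisfies
#' \eqn{\mu^2 + \mu = \Delta\tau} exactly, so the variance of the composed
#' impulse response equals \code{tau_levels[K]} to machine precision.
#'
#' @param tau_levels increasing vector of cumulative variances (grid units
#'   squared).
#' @return An object of class \code{"recursive_cascade"} with fields
#'   \code{mu}, \code{delta_tau} and \code{tau_levels}.
#' @seealso [cascade_for_scale()] for the uniform/logarithmic distributions,
#'   [recursive_smooth()].
#' @export
recursive_cascade <- function(tau_levels) {
  if (length(tau_levels) < 1L || any(!is.finite(tau_levels)))
    stop("'tau_levels' must be a non-empty finite vector", call. = FALSE)
  delta_tau <- diff(c(0, tau_levels))
  if (any(delta_tau < 0))
    stop("'tau_levels' must be non-decreasing", call. = FALSE)
  structure(list(mu = mu_from_delta_tau(delta_tau), delta_tau = delta_tau,
                 tau_levels = tau_levels),
            class = "recursive_cascade")
}

#' @describeIn recursive_cascade Cascade realizing composed grid-unit
#'   variance \code{tau_sampl} with \code{K} stages under a uniform or
#'   logarithmic distribution of the intermediate scale levels.
#' @param tau_sampl composed variance in grid units squared.
#' @param K number of stages.
#' @param distribution \code{"uniform"} or \code{"logarithmic"}.
#' @param c distribution ratio (> 1) for the logarithmic case.
#' @export
cascade_for_scale <- function(tau_sampl, K,
                              distribution = c("uniform", "logarithmic"),
                              c = sqrt(2)) {
  distribution <- match.arg(distribution)
  check_scalar(tau_sampl, "tau_sampl", lower = 0)
  check_scalar(K, "K", lower = 1, integer = TRUE)
  levels <- if (distribution == "uniform") (1:K) / K * tau_sampl
            else {
              check_scalar(c, "c", lower = 1, strict_lower = TRUE)
              c^(2 * ((1:K) - K)) * tau_sampl
            }
  recursive_cascade(levels)
}

#' Smooth a signal with a recursive filter cascade
#'
#' Runs the signal through every stage of the cascade and returns all
#' intermediate outputs: the columns are the temporal scale-space
#' representations at the scales \code{cascade$tau_levels}, i.e. the compact
#' temporal buffer from which temporal derivatives can be computed by
#' channel differences. Each stage has unit DC gain. The internal filter
#' state is seeded with the first input sample so a constant signal passes
#' through unchanged.
#'
#' @param x numeric signal.
#' @param cascade a \code{"recursive_cascade"}.
#' @return A matrix with \code{length(x)} rows and one column per stage,
#'   with the input attached as attribute \code{"input"}.
#' @export
recursive_smooth <- function(x, cascade) {
  stopifnot(inherits(cascade, "recursive_cascade"))
  if (length(x) == 0L) stop("empty signal", call. = FALSE)
  K <- length(cascade$mu)
  out <- matrix(0, nrow = length(x), ncol = K)
  cur <- as.numeric(x)
  for (k in seq_len(K)) {
    mu <- cascade$mu[k]
    if (mu == 0) {
      out[, k] <- cur
    } else {
      a <- 1 / (1 + mu)
      out[, k] <- as.numeric(
        stats::filter(a * cur, mu / (1 + mu), method = "recursive",
                      init = cur[1L]))
    }
    cur <- out[, k]
  }
  attr(out, "input") <- as.numeric(x)
  attr(out, "cascade") <- cascade
  out
}

#' Temporal derivatives from differences between scale channels
#'
#' Computes the order-\code{r} temporal derivative approximation at the final
#' stage of a recursive cascade from the recurrence
#' \eqn{L^{(r)}_k = (L^{(r-1)}_{k-1} - L^{(r-1)}_k) / \mu_k},
#' where \eqn{L^{(0)}_k} are the stage outputs and \eqn{L^{(0)}_0} is the
#' input signal. The temporal scale-space representations at the different
#' scales thus serve as a sufficient buffer for derivative computation; no
#' explicit difference filters over time are needed. The total order of
#' differentiation must be smaller than the number of integration stages.
#'
#' @param stages matrix returned by [recursive_smooth()].
#' @param order derivative order \code{r}, with \code{0 <= r < K}.
#' @return Numeric vector: the order-\code{r} derivative (per grid unit) at
#'   the coarsest scale.
#' @export
temporal_derivative_from_channels <- function(stages, order) {
  cascade <- attr(stages, "cascade")
  if (is.null(cascade)) stop("'stages' must come from recursive_smooth()",
                             call. = FALSE)
  K <- length(cascade$mu)
  check_scalar(order, "order", lower = 0, integer = TRUE)
  if (order >= K)
    stop("derivative order must be smaller than the number of stages K",
         call. = FALSE)
  L <- cbind(attr(stages, "input"), stages)    # column k + 1 is stage k
  for (r in seq_len(order)) {
    # after this loop iteration, column k + 1 holds the order-r derivative
    # at stage k, defined for k >= r
    for (k in K:r) {
      mu <- cascade$mu[k]
      L[, k + 1L] <- if (mu == 0) 0 else (L[, k] - L[, k + 1L]) / mu
    }
  }
  L[, K + 1L]
}

#' Discrete analogue of the Gaussian kernel
#'
#' The kernel \eqn{T(n; s) = e^{-s} I_n(s)}, with \eqn{I_n} the modified
#' Bessel function of integer order, is the discrete counterpart of Gaussian
#' smoothing: it is the solution of the semi-discrete diffusion equation,
#' satisfies an exact semigroup \eqn{T(\cdot;s_1) * T(\cdot;s_2) =
#' T(\cdot;s_1+s_2)} and never creates new local extrema. The infinite
#' kernel is truncated at the smallest halfwidth \code{N} for which the
#' retained mass exceeds \eqn{1 - \epsilon}, starting from the
#' continuous-Gaussian tail estimate and incrementing until the discrete
#' mass condition holds. For very large \code{s} (> 1e4) the exponentially
#' scaled Bessel recursion becomes both slow and unnecessary, and a sampled
#' continuous Gaussian is used; at those scales the two agree to well below
#' the truncation tolerance.
#'
#' @param s variance in grid units squared, non-negative.
#' @param epsilon truncation mass tolerance, positive (default 1e-6).
#' @return An object of class \code{"discrete_gaussian"} with fields
#'   \code{s}, \code{N} and \code{values} (indices \code{-N:N}).
#' @export
#' @examples
#' k <- discrete_gaussian(1)
#' k$values[k$N + 1]          # central weight e^{-1} I_0(1)
discrete_gaussian <- function(s, epsilon = 1e-6) {
  check_scalar(s, "s", lower = 0)
  check_scalar(epsilon, "epsilon", lower = 0, strict_lower = TRUE)
  if (s == 0)
    return(structure(list(s = 0, N = 0L, values = 1),
                     class = "discrete_gaussian"))
  if (s > 1e4) {
    N <- as.integer(ceiling(stats::qnorm(1 - epsilon / 2) * sqrt(s))) + 1L
    v <- stats::dnorm(-N:N, sd = sqrt(s))
    v <- v / sum(v)
    return(structure(list(s = s, N = N, values = v),
                     class = "discrete_gaussian"))
  }
  N <- as.integer(ceiling(stats::qnorm(1 - epsilon / 2) * sqrt(s)))
  repeat {
    half <- besselI(s, 1:max(N, 1L), expon.scaled = TRUE)
    mass <- besselI(s, 0, expon.scaled = TRUE) + 2 * sum(half[seq_len(N)])
    if (mass > 1 - epsilon) break
    N <- N + 1L
  }
  v <- besselI(s, abs(-N:N), expon.scaled = TRUE)
  structure(list(s = s, N = N, values = v), class = "discrete_gaussian")
}

#' Smooth a sequence with the discrete Gaussian under mirrored boundaries
#'
#' Convolves \code{x} with [discrete_gaussian()] at scale \code{s}, with the
#' data mirrored at the boundaries (equivalent to adiabatic boundary
#' conditions for the underlying diffusion equation), so a constant sequence
#' maps to itself exactly.
#'
#' @param x numeric sequence.
#' @param s variance in grid units squared.
#' @param epsilon truncation tolerance passed to [discrete_gaussian()].
#' @return Smoothed sequence of the same length.
#' @export
smooth_1d <- function(x, s, epsilon = 1e-6) {
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  k <- discrete_gaussian(s, epsilon)
  if (k$N == 0L) return(as.numeric(x))
  n <- length(x)
  xp <- x[mirror_index(seq(1L - k$N, n + k$N), n)]
  # renormalize the truncated kernel so a constant maps exactly to itself
  y <- fft_convolve(xp, k$values / sum(k$values))
  y[(2L * k$N + 1L):(2L * k$N + n)]
}

#' Small-support difference operators on a time-frequency matrix
#'
#' Applies one of the separable derivative stencils to a matrix with time
#' along rows and (log-)frequency along columns, with mirrored boundary
#' handling: \code{"dt"} is the two-tap causal difference \code{(-1, +1)}
#' aligned to the later sample (preserving time causality of the chain, at
#' the price of an uncompensated half-sample shift), \code{"dtt"} the
#' three-tap second difference along time, \code{"dnu"} the centered
#' difference \code{(-1/2, 0, +1/2)} along frequency and \code{"dnunu"} the
#' second difference along frequency. Results are in grid units (per sample
#' and per channel step).
#'
#' @param M numeric matrix, time x frequency.
#' @param which one of \code{"dt"}, \code{"dtt"}, \code{"dnu"},
#'   \code{"dnunu"}.
#' @return Matrix of the same shape.
#' @export
difference_operator <- function(M, which = c("dt", "dtt", "dnu", "dnunu")) {
  which <- match.arg(which)
  if (!is.matrix(M)) M <- as.matrix(M)
  along_time <- which %in% c("dt", "dtt")
  if ((along_time && nrow(M) < 3L) || (!along_time && ncol(M) < 3L))
    stop("differentiated axis needs at least 3 samples", call. = FALSE)
  n <- nrow(M); m <- ncol(M)
  switch(which,
    dt = {
      D <- M - M[mirror_index(0:(n - 1L), n), , drop = FALSE]
      D
    },
    dtt = M[mirror_index(2:(n + 1L), n), , drop = FALSE] - 2 * M +
          M[mirror_index(0:(n - 1L), n), , drop = FALSE],
    dnu = (M[, mirror_index(2:(m + 1L), m), drop = FALSE] -
           M[, mirror_index(0:(m - 1L), m), drop = FALSE]) / 2,
    dnunu = M[, mirror_index(2:(m + 1L), m), drop = FALSE] - 2 * M +
            M[, mirror_index(0:(m - 1L), m), drop = FALSE])
}
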