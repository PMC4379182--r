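# Analytical characterization of the temporal window families: frequency
# selectivity (relative-bandwidth parameter theta), and temporal dynamics
# (mean delay, kernel-peak delay, inflection points).

# dB attenuation of each family expressed as a function of
# theta = n (omega - omega0) / omega.
rdb_gaussian_theta <- function(theta) -40 * pi^2 * theta^2 / log(10)

rdb_rec_uniform_theta <- function(theta, K)
  -10 * K * log10(1 + 4 * pi^2 * theta^2 / K)

rdb_rec_log_theta <- function(theta, K, c) {
  v <- -10 * log10(1 + 4 * pi^2 * theta^2 * c^(2 - 2 * K))
  if (K >= 2)
    for (k in 2:K)
      v <- v - 10 * log10(1 + 4 * pi^2 * (c^2 - 1) * theta^2 *
                            c^(2 * (k - K - 1)))
  v
}

#' Frequency-selectivity curve of a temporal window family
#'
#' For a window whose temporal extent is proportional to the wavelength
#' (\eqn{\sqrt{\tau}\,\omega = 2\pi n}), the normalized magnitude response of
#' a spectrogram channel at center frequency \eqn{\omega_0} to a pure tone at
#' \eqn{\omega} depends only on \eqn{\theta = n(\omega - \omega_0)/\omega}.
#' This function evaluates the attenuation in dB on a grid of frequencies
#' expressed in units of \eqn{\omega_0}: 0 dB at the channel center,
#' monotonically decreasing away from it.
#'
#' @param omega_grid frequencies in units of \eqn{\omega_0} (positive).
#' @param family \code{"gaussian"}, \code{"rec_uniform"} or \code{"rec_log"}.
#' @param K number of cascade stages (time-causal families).
#' @param c distribution ratio (> 1, \code{"rec_log"} only).
#' @param n window-length-to-wavelength factor.
#' @return Numeric vector of dB values (\eqn{\le 0}).
#' @export
#' @examples
#' w <- seq(0.8, 1.25, by = 0.01)
#' selectivity_curve(w, "gaussian", n = 8)
selectivity_curve <- function(omega_grid,
                              family = c("gaussian", "rec_uniform", "rec_log"),
                              K = 4, c = sqrt(2), n = 8) {
  family <- match.arg(family)
  if (any(omega_grid <= 0)) stop("'omega_grid' must be positive", call. = FALSE)
  theta <- n * (omega_grid - 1) / omega_grid
  switch(family,
         gaussian = rdb_gaussian_theta(theta),
         rec_uniform = rdb_rec_uniform_theta(theta, K),
         rec_log = vapply(theta, rdb_rec_log_theta, 0, K = K, c = c))
}

#' Relative-bandwidth parameter theta of the window families
#'
#' \code{theta_gaussian} and \code{theta_rec_uniform} give the closed-form
#' value of \eqn{\theta} at which the channel response has dropped to the
#' level \code{R_dB} (< 0):
#' \eqn{\theta_{gauss} = \sqrt{-R_{dB}\ln 10 / 10} / (2\pi)} and
#' \eqn{\theta_{rec-uni} = \sqrt{K}\sqrt{10^{-R_{dB}/(10K)} - 1} / (2\pi)}.
#' \code{theta_rec_log} solves the logarithmic-family dB equation by
#' bracketed bisection on \eqn{\theta \in (0, 4]} to an interval of 1e-9
#' (the attenuation is strictly decreasing in \eqn{\theta}); for
#' \code{K = 1} it reduces to the single-stage closed form. The relative
#' bandwidth of the spectrogram at that level is then \eqn{2\theta/n} to
#' leading order, see [relative_bandwidth()].
#'
#' @param R_dB attenuation level in dB, strictly negative.
#' @param K number of cascade stages.
#' @param c distribution ratio (> 1).
#' @return The scalar \eqn{\theta > 0}.
#' @export
#' @examples
#' theta_gaussian(-3)              # 0.132
#' theta_rec_uniform(-10, 4)       # 0.281
#' theta_rec_log(-30, 7, 2)        # 0.964
theta_gaussian <- function(R_dB) {
  check_scalar(R_dB, "R_dB")
  if (R_dB >= 0) stop("'R_dB' must be negative", call. = FALSE)
  sqrt(-R_dB * log(10) / 10) / (2 * pi)
}

#' @rdname theta_gaussian
#' @export
theta_rec_uniform <- function(R_dB, K) {
  if (R_dB >= 0) stop("'R_dB' must be negative", call. = FALSE)
  check_scalar(K, "K", lower = 1, integer = TRUE)
  sqrt(K) / (2 * pi) * sqrt(10^(-R_dB / (10 * K)) - 1)
}

#' @rdname theta_gaussian
#' @export
theta_rec_log <- function(R_dB, K, c) {
  if (R_dB >= 0) stop("'R_dB' must be negative", call. = FALSE)
  check_scalar(K, "K", lower = 1, integer = TRUE)
  check_scalar(c, "c", lower = 1, strict_lower = TRUE)
  if (K == 1L) return(theta_rec_uniform(R_dB, 1L))
  f <- function(th) rdb_rec_log_theta(th, K, c) - R_dB
  lo <- 1e-12; hi <- 4
  if (f(lo) < 0 || f(hi) > 0)
    stop("no sign change on the bisection bracket (0, 4]", call. = FALSE)
  while (hi - lo > 1e-9) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Relative bandwidth from theta
#'
#' Converts the selectivity parameter \eqn{\theta} into the two-sided
#' relative bandwidth of a spectrogram channel:
#' as a fraction of the center frequency,
#' \eqn{1/(1 - \theta/n) - 1/(1 + \theta/n) \approx 2\theta/n}, or in
#' logarithmic (semitone) units,
#' \eqn{12 \log_2((1 + \theta/n) / (1 - \theta/n))}.
#'
#' @param theta selectivity parameter, with \code{theta / n < 1}.
#' @param n window-length-to-wavelength factor.
#' @param units \code{"fraction"} or \code{"semitones"}.
#' @return Bandwidth in the requested units.
#' @export
relative_bandwidth <- function(theta, n, units = c("fraction", "semitones")) {
  units <- match.arg(units)
  check_scalar(theta, "theta", lower = 0)
  check_scalar(n, "n", lower = 0, strict_lower = TRUE)
  r <- theta / n
  if (r >= 1) stop("'theta'/'n' must be < 1", call. = FALSE)
  switch(units,
         fraction = 1 / (1 - r) - 1 / (1 + r),
         semitones = 12 * log2((1 + r) / (1 - r)))
}

#' Temporal mean (delay) of a time-causal cascade
#'
#' The temporal mean of the composed kernel is the sum of the stage time
#' constants, \eqn{m = \sum_k \mu_k} (means add under convolution), reported
#' in units of \eqn{\sqrt{\tau_{max}}}. For the uniform distribution this is
#' \eqn{\sqrt{K}}; for the logarithmic distribution it converges to
#' \eqn{\sqrt{c^2 - 1}/(c - 1)} as \eqn{K \to \infty}
#' (see [temporal_mean_log_limit()]).
#'
#' @param d a \code{"scale_discretization"}.
#' @return Temporal mean in units of \eqn{\sqrt{\tau_{max}}}.
#' @export
#' @examples
#' temporal_mean(uniform_discretization(1, 4))       # 2
#' temporal_mean(log_discretization(1, 7, sqrt(2)))  # 2.237
temporal_mean <- function(d) {
  stopifnot(inherits(d, "scale_discretization"))
  sum(d$mu) / sqrt(d$tau_max)
}

#' @rdname temporal_mean
#' @param c distribution ratio (> 1).
#' @export
temporal_mean_log_limit <- function(c) {
  check_scalar(c, "c", lower = 1, strict_lower = TRUE)
  sqrt(c^2 - 1) / (c - 1)
}

#' Delay metrics of a time-causal kernel
#'
#' Positions, in units of \eqn{\sqrt{\tau_{max}}}, of the kernel maximum and
#' inflection points, together with the temporal mean. For the uniform
#' distribution closed forms exist:
#' \eqn{t_{max} = (K-1)\mu}, \eqn{t_{infl} = (K - 1 \mp \sqrt{K-1})\,\mu}.
#' For the logarithmic distribution the kernel maximum is located numerically
#' on the sampled cascade impulse response (1e5 grid points on
#' \eqn{[0, m + 6\sqrt{\tau}]}) with parabolic refinement, and the inflection
#' points from the sign changes of the second difference. For \code{K = 1}
#' the kernel is a monotonically decaying exponential: the maximum sits at
#' the origin and no inflection points exist (flagged with \code{NA}).
#'
#' @param d a \code{"scale_discretization"}.
#' @return An object of class \code{"delay_metrics"}: a list with fields
#'   \code{m}, \code{t_max}, \code{t_infl1}, \code{t_infl2}, all in units of
#'   \eqn{\sqrt{\tau_{max}}}.
#' @export
#' @examples
#' delay_metrics(uniform_discretization(1, 5))$t_max   # 1.789
delay_metrics <- function(d) {
  stopifnot(inherits(d, "scale_discretization"))
  s <- sqrt(d$tau_max)
  m <- sum(d$mu) / s
  K <- d$K
  if (d$distribution == "uniform") {
    mu <- d$mu[1L] / s
    t_max <- (K - 1) * mu
    if (K >= 2) {
      t_infl1 <- (K - 1 - sqrt(K - 1)) * mu
      t_infl2 <- (K - 1 + sqrt(K - 1)) * mu
    } else t_infl1 <- t_infl2 <- NA_real_
  } else {
    if (K == 1L) {
      t_max <- 0; t_infl1 <- t_infl2 <- NA_real_
    } else {
      tt <- seq(0, (m + 6) * s, length.out = 1e5)
      h <- cascade_impulse_response(d$mu, tt)
      ipk <- which.max(h)
      t_max <- parabolic_peak(tt, h, ipk) / s
      d2 <- diff(h, differences = 2)
      # ignore sign flips caused by convolution rounding noise
      thr <- 1e-8 * max(abs(d2))
      sc <- which(d2[-length(d2)] * d2[-1L] < 0 &
                    pmax(abs(d2[-length(d2)]), abs(d2[-1L])) > thr)
      at <- function(i) (tt[i + 1L] +
                           (tt[2L] - tt[1L]) * d2[i] / (d2[i] - d2[i + 1L])) / s
      down <- sc[d2[sc] > 0 & sc < ipk]      # convex -> concave, before peak
      up <- sc[d2[sc] < 0 & sc >= ipk]       # concave -> convex, after peak
      t_infl1 <- if (length(down)) at(down[length(down)]) else NA_real_
      t_infl2 <- if (length(up)) at(up[1L]) else NA_real_
    }
  }
  structure(list(m = m, t_max = t_max, t_infl1 = t_infl1, t_infl2 = t_infl2),
            class = "delay_metrics")
}

#' @export
print.delay_metrics <- function(x, ...) {
  cat(sprintf("Delay metrics (units of sqrt(tau)): m = %.3f, t_max = %.3f,",
              x$m, x$t_max))
  cat(sprintf(" inflections = (%.3f, %.3f)\n", x$t_infl1, x$t_infl2))
  invisible(x)
}

#' Characterization tables of the window families
#'
#' Recomputes the three summary tables characterizing the temporal window
#' families, each rounded to 3 decimals:
#' \describe{
#'   \item{theta}{the relative-bandwidth parameter \eqn{\theta} at the
#'     -3, -10, -20 and -30 dB levels for the Gaussian window, the uniform
#'     cascades with K = 4 and K = 7, and the logarithmic cascades with
#'     K in \{4, 7\} and c in \{sqrt(2), 2^(3/4), 2\}.}
#'   \item{temporal_mean}{the mean delay \eqn{m = \sum_k \mu_k} in units of
#'     \eqn{\sqrt{\tau}} for K = 2..8, uniform and logarithmic
#'     distributions.}
#'   \item{t_max}{the kernel-peak delay in units of \eqn{\sqrt{\tau}} for
#'     the same configurations; the uniform column is the closed form
#'     \eqn{(K-1)/\sqrt{K}}, the logarithmic columns are located numerically
#'     on the cascade impulse response.}
#' }
#'
#' @param digits rounding applied to the table entries (default 3).
#' @return A named list of three data frames.
#' @export
characterization_tables <- function(digits = 3) {
  levels_db <- c(-3, -10, -20, -30)
  cs <- c(sqrt(2), 2^(3 / 4), 2)
  th <- rbind(
    gauss = vapply(levels_db, theta_gaussian, 0),
    rec_uni_K4 = vapply(levels_db, theta_rec_uniform, 0, K = 4),
    rec_log_K4_c1.41 = vapply(levels_db, theta_rec_log, 0, K = 4, c = cs[1]),
    rec_log_K4_c1.68 = vapply(levels_db, theta_rec_log, 0, K = 4, c = cs[2]),
    rec_log_K4_c2 = vapply(levels_db, theta_rec_log, 0, K = 4, c = cs[3]),
    rec_uni_K7 = vapply(levels_db, theta_rec_uniform, 0, K = 7),
    rec_log_K7_c1.41 = vapply(levels_db, theta_rec_log, 0, K = 7, c = cs[1]),
    rec_log_K7_c1.68 = vapply(levels_db, theta_rec_log, 0, K = 7, c = cs[2]),
    rec_log_K7_c2 = vapply(levels_db, theta_rec_log, 0, K = 7, c = cs[3]))
  theta_tab <- data.frame(family = rownames(th), round(th, digits),
                          row.names = NULL, check.names = FALSE)
  names(theta_tab)[-1] <- paste0(levels_db, "_dB")

  Ks <- 2:8
  mean_tab <- data.frame(
    K = Ks,
    m_uni = round(sqrt(Ks), digits),
    m_log_c1.41 = round(vapply(Ks, function(K)
      temporal_mean(log_discretization(1, K, cs[1])), 0), digits),
    m_log_c1.68 = round(vapply(Ks, function(K)
      temporal_mean(log_discretization(1, K, cs[2])), 0), digits),
    m_log_c2 = round(vapply(Ks, function(K)
      temporal_mean(log_discretization(1, K, cs[3])), 0), digits))

  tmax_log <- function(K, c) delay_metrics(log_discretization(1, K, c))$t_max
  tmax_tab <- data.frame(
    K = Ks,
    t_max_uni = round((Ks - 1) / sqrt(Ks), digits),
    t_max_log_c1.41 = round(vapply(Ks, tmax_log, 0, c = cs[1]), digits),
    t_max_log_c1.68 = round(vapply(Ks, tmax_log, 0, c = cs[2]), digits),
    t_max_log_c2 = round(vapply(Ks, tmax_log, 0, c = cs[3]), digits))

  list(theta = theta_tab, temporal_mean = mean_tab, t_max = tmax_tab)
}
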