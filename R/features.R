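# Auditory feature operators built on second-layer receptive-field
# responses: onset/offset maps, spectral-band enhancement, partial-tone
# ridge curves, and two glissando estimators (filter bank over the shear
# parameter, and the spectro-temporal second-moment matrix).

clamp_pos <- function(x) pmax(x, 0)

#' Onset and offset maps
#'
#' The scale-normalized first-order temporal derivative of the log
#' spectrogram responds positively to energy onsets and negatively to
#' offsets. \code{onset_map} keeps the positive part (negatives clamped to
#' zero), \code{offset_map} the positive part of the negated response, so
#' that \code{onset - offset} reconstructs the raw signed derivative
#' exactly. The supplied spec must have \code{alpha = 1}.
#'
#' @param SdB a \code{"log_spectrogram"}.
#' @param spec an [rf_spec()] with \code{alpha = 1}.
#' @return A \code{"feature_map"}; the raw signed derivative is attached as
#'   attribute \code{"raw"}.
#' @export
onset_map <- function(SdB, spec) {
  if (spec$alpha != 1L) stop("onset detection needs alpha = 1", call. = FALSE)
  fm <- apply_rf(SdB, spec)
  raw <- fm$values
  fm$values <- clamp_pos(raw)
  attr(fm, "raw") <- raw
  fm
}

#' @rdname onset_map
#' @export
offset_map <- function(SdB, spec) {
  if (spec$alpha != 1L) stop("offset detection needs alpha = 1", call. = FALSE)
  fm <- apply_rf(SdB, spec)
  raw <- fm$values
  fm$values <- clamp_pos(-raw)
  attr(fm, "raw") <- raw
  fm
}

#' Spectral-band enhancement
#'
#' The negated scale-normalized second logspectral derivative,
#' \eqn{-\mathcal{D}_{\nu\nu}}, is positive at local maxima over frequency.
#' Keeping its positive part enhances spectral bands: at a fine logspectral
#' scale (about half a semitone) the partial tones of a harmonic sound, at
#' a coarse scale (about 4 semitones) the formants of vowels. The spec must
#' have \code{beta = 2} (and typically \code{alpha = 0}).
#'
#' @param SdB a \code{"log_spectrogram"}.
#' @param spec an [rf_spec()] with \code{beta = 2}.
#' @return A \code{"feature_map"} whose values are
#'   \eqn{\max(-\mathcal{D}_{\nu\nu}, 0)}; the signed
#'   \eqn{-\mathcal{D}_{\nu\nu}} is attached as attribute \code{"raw"}.
#' @export
band_map <- function(SdB, spec) {
  if (spec$beta != 2L) stop("band enhancement needs beta = 2", call. = FALSE)
  fm <- apply_rf(SdB, spec)
  raw <- -fm$values
  fm$values <- clamp_pos(raw)
  attr(fm, "raw") <- raw
  fm
}

#' Partial-tone ridge curves
#'
#' Extracts sub-grid curves of how the frequencies of partial tones vary
#' over time from a band-enhancement map: within each time frame, points
#' where the first logspectral difference of \eqn{-\mathcal{D}_{\nu\nu}}
#' changes sign from positive to negative (a local maximum over frequency)
#' are located by linear interpolation, kept when their interpolated
#' strength reaches the threshold \code{C}, and linked across adjacent
#' frames into polylines by nearest-frequency association within a gate.
#'
#' @param band a \code{"feature_map"} from [band_map()].
#' @param C strength threshold (default 3, in dB-derived units).
#' @param gate maximum frequency jump between consecutive frames when
#'   linking, in semitones (default 1).
#' @return An object of class \code{"ridge_curve_set"}: a list with
#'   \code{curves}, a data frame with columns \code{curve_id}, \code{time},
#'   \code{nu} and \code{strength}, and the threshold \code{C}.
#' @export
ridge_curves <- function(band, C = 3, gate = 1) {
  stopifnot(inherits(band, "feature_map"))
  y <- attr(band, "raw")
  if (is.null(y)) y <- band$values
  nu <- band$axis$nu_values
  m <- length(nu)
  dnu <- band$axis$dnu
  verts <- vector("list", nrow(y))
  for (i in seq_len(nrow(y))) {
    row <- y[i, ]
    d <- (row[c(2:m, m - 1L)] - row[c(2L, 1:(m - 1L))]) / 2  # mirrored ends
    j <- which(d[-m] > 0 & d[-1L] <= 0)
    if (!length(j)) next
    frac <- d[j] / (d[j] - d[j + 1L])
    frac[!is.finite(frac)] <- 0
    nu_hat <- nu[j] + frac * dnu
    strength <- row[j] + frac * (row[j + 1L] - row[j])
    keep <- strength >= C
    if (!any(keep)) next
    verts[[i]] <- data.frame(time = band$times[i], nu = nu_hat[keep],
                             strength = strength[keep])
  }
  # link greedily by nearest frequency within the gate
  curves <- list(); open <- list()  # open: list of (id, nu_last, frame_last)
  next_id <- 1L
  rows <- list()
  for (i in seq_len(nrow(y))) {
    vi <- verts[[i]]
    n_open0 <- length(open)          # curves opened this frame are not
    matched <- logical(n_open0)      # candidates for matching in it
    if (!is.null(vi)) {
      assigned <- integer(nrow(vi))
      for (r in seq_len(nrow(vi))) {
        best <- 0L; bestd <- gate
        for (oi in seq_len(n_open0)) {
          if (matched[oi] || open[[oi]]$frame < i - 1L) next
          dd <- abs(open[[oi]]$nu - vi$nu[r])
          if (dd <= bestd) { best <- oi; bestd <- dd }
        }
        if (best > 0L) {
          matched[best] <- TRUE
          assigned[r] <- open[[best]]$id
          open[[best]]$nu <- vi$nu[r]; open[[best]]$frame <- i
        } else {
          assigned[r] <- next_id
          open[[length(open) + 1L]] <- list(id = next_id, nu = vi$nu[r],
                                            frame = i)
          next_id <- next_id + 1L
        }
      }
      rows[[length(rows) + 1L]] <- cbind(curve_id = assigned, vi)
    }
    open <- Filter(function(o) o$frame >= i - 1L, open)
  }
  curves <- if (length(rows)) do.call(rbind, rows) else
    data.frame(curve_id = integer(), time = numeric(), nu = numeric(),
               strength = numeric())
  curves <- curves[order(curves$curve_id, curves$time), , drop = FALSE]
  rownames(curves) <- NULL
  structure(list(curves = curves, C = C), class = "ridge_curve_set")
}

#' @export
print.ridge_curve_set <- function(x, ...) {
  cat(sprintf("Ridge curves: %d curves, %d vertices, threshold C = %g\n",
              length(unique(x$curves$curve_id)), nrow(x$curves), x$C))
  invisible(x)
}

#' Glissando estimation by a filter bank over the shear parameter
#'
#' Computes the band-enhancement response for every glissando rate in
#' \code{v_grid}, takes the pointwise maximum over the bank as the combined
#' response, and estimates the local glissando rate as the argmax over
#' \code{v}, refined by three-point parabolic interpolation where the
#' maximum is interior to the grid. Responses are the raw (signed)
#' \eqn{-\mathcal{D}_{\nu\nu}} values; no per-rate normalization is
#' applied.
#'
#' @param SdB a \code{"log_spectrogram"}.
#' @param spec an [rf_spec()] with \code{beta = 2}; its \code{v} is ignored.
#' @param v_grid glissando rates in semitones/second (non-empty).
#' @return List with \code{best} (matrix of maxima), \code{v_hat} (matrix
#'   of estimated rates) and \code{v_grid}.
#' @export
glissando_filterbank <- function(SdB, spec, v_grid) {
  if (!length(v_grid)) stop("'v_grid' must be non-empty", call. = FALSE)
  resp <- lapply(v_grid, function(v) {
    s <- spec; s$v <- v
    attr(band_map(SdB, s), "raw")
  })
  stack <- simplify2array(resp)            # time x channel x v
  if (length(v_grid) == 1L)
    return(list(best = resp[[1L]], v_hat = array(v_grid, dim(resp[[1L]])),
                v_grid = v_grid))
  imax <- apply(stack, c(1, 2), which.max)
  best <- apply(stack, c(1, 2), max)
  v_hat <- matrix(v_grid[imax], nrow = nrow(imax))
  interior <- imax > 1L & imax < length(v_grid)
  if (any(interior)) {
    idx <- which(interior)
    for (q in idx) {
      i <- ((q - 1L) %% nrow(imax)) + 1L
      j <- ((q - 1L) %/% nrow(imax)) + 1L
      k <- imax[i, j]
      y0 <- stack[i, j, k - 1L]; y1 <- stack[i, j, k]; y2 <- stack[i, j, k + 1L]
      # quadratic through three (possibly non-uniform) grid points
      x0 <- v_grid[k - 1L]; x1 <- v_grid[k]; x2 <- v_grid[k + 1L]
      d1 <- (y1 - y0) / (x1 - x0); d2 <- (y2 - y1) / (x2 - x1)
      a2 <- (d2 - d1) / (x2 - x0)
      if (a2 < 0) {
        # vertex of the quadratic through the three bank responses
        v_hat[i, j] <- (x1 + x0) / 2 - d1 / (2 * a2)
      }
    }
  }
  list(best = best, v_hat = v_hat, v_grid = v_grid)
}

#' Glissando estimation from the spectro-temporal second-moment matrix
#'
#' Forms the scale-normalized first derivatives \eqn{L_t} and \eqn{L_\nu}
#' of the smoothed log spectrogram, smooths their products with a third
#' layer of spectro-temporal smoothing at the integration scales, and
#' estimates the glissando rate as \eqn{v = -\Upsilon_{t\nu} /
#' \Upsilon_{\nu\nu}} — the shear that diagonalizes the second-moment
#' matrix. The estimate is reported only where \eqn{\Upsilon_{\nu\nu}}
#' exceeds a small fraction of its maximum (elsewhere \code{NA}).
#'
#' @param SdB a \code{"log_spectrogram"}.
#' @param spec an [rf_spec()] carrying the derivative scales \code{tau_a}
#'   and \code{s} (its \code{alpha}, \code{beta}, \code{v} are ignored).
#' @param tau_int,s_int integration scales; default 4x the derivative
#'   scales.
#' @param threshold fraction of \code{max(Ynn)} below which the estimate is
#'   masked (default 1e-3).
#' @return List with \code{moments} (list \code{Ytt}, \code{Ytn},
#'   \code{Ynn}, \code{tau_int}, \code{s_int}) and \code{v} (matrix,
#'   semitones/second, \code{NA} where undefined).
#' @export
second_moment_glissando <- function(SdB, spec, tau_int = 4 * spec$tau_a,
                                    s_int = 4 * spec$s, threshold = 1e-3) {
  # physical-unit derivatives (dB/s and dB/semitone): the scale
  # normalization must not enter the moment ratio, or it would bias v by
  # sqrt(tau_a / s)
  st <- spec; st$v <- 0
  st$alpha <- 1L; st$beta <- 0L
  ft <- apply_rf(SdB, st)
  Lt <- ft$values / ft$normalization
  sn <- spec; sn$v <- 0
  sn$alpha <- 0L; sn$beta <- 1L
  fn <- apply_rf(SdB, sn)
  Lnu <- fn$values / fn$normalization
  smooth2 <- function(M) {
    M <- rf_temporal_smooth(M, spec, tau_int / SdB$dt^2)
    if (s_int > 0) M <- t(apply(M, 1L, smooth_1d, s = s_int / SdB$dnu^2))
    M
  }
  Ytt <- smooth2(Lt * Lt)
  Ytn <- smooth2(Lt * Lnu)
  Ynn <- smooth2(Lnu * Lnu)
  v <- -Ytn / Ynn
  v[Ynn <= threshold * max(Ynn)] <- NA_real_
  list(moments = list(Ytt = Ytt, Ytn = Ytn, Ynn = Ynn,
                      tau_int = tau_int, s_int = s_int),
       v = v)
}
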