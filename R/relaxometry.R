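# T1 estimation from saturation-recovery (multi-TR spin echo) and
# Look-Locker inversion-recovery (MOLLI) series.
#
# Both signal models are linear in their amplitude parameters once the time
# constant is fixed, so fitting is done by variable projection: the profiled
# residual sum of squares is evaluated on a log-spaced grid of time constants
# and the bracketed minimum refined by Brent's method. This is an exact
# nonlinear least-squares solution of the separable problem and is fast
# enough for pixelwise maps.

DEFAULT_T1_BOUNDS <- c(1, 10000) # ms

#' Default repetition-time grid for the in-vitro spin-echo protocol
#'
#' Seventeen repetition times (ms) spanning 20 ms to 4 s, as used for
#' multi-TR saturation-recovery T1 measurement of phantom vials.
#' @return numeric vector of TRs in ms.
#' @export
default_tr_list <- function() {
  c(20, 25, 30, 40, 50, 75, 100, 150, 200, 250, 300, 400, 500,
    1000, 1500, 2000, 4000)
}

#' Default inversion-time grid for the MOLLI protocol
#'
#' Eleven inversion times: initial TI 100 ms, increment 80 ms.
#' @return numeric vector of TIs in ms.
#' @export
default_ti_list <- function() 100 + 80 * (0:10)

t1_grid <- function(bounds, n = 120L) {
  exp(seq(log(bounds[1]), log(bounds[2]), length.out = n))
}

# profiled RSS of S = S0 * (1 - exp(-tr/t1)) at fixed t1 (S0 solved exactly)
sr_profile_rss <- function(t1, tr, s, ss) {
  f <- 1 - exp(-tr / t1)
  ff <- sum(f * f)
  if (ff <= 0) return(ss)
  max(ss - sum(s * f)^2 / ff, 0)
}

sr_s0_hat <- function(t1, tr, s) {
  f <- 1 - exp(-tr / t1)
  sum(s * f) / sum(f * f)
}

#' Fit the saturation-recovery signal model
#'
#' Nonlinear least-squares estimate of `(S0, T1)` under
#' `S(TR) = S0 * (1 - exp(-TR/T1))` from mean signal intensities acquired at
#' multiple repetition times. The amplitude is profiled out analytically and
#' T1 located by a grid-bracketed Brent search, which cannot do worse than a
#' dense grid search over the same bounds.
#'
#' @param tr numeric vector of repetition times, strictly increasing. Units
#'   are arbitrary but must match `t1_bounds`; the package convention is ms.
#' @param signal numeric vector of signal intensities, one per TR.
#' @param t1_bounds length-2 numeric, search bounds for T1 (same units as
#'   `tr`; default 1 ms to 10 s).
#' @return object of class `se_fit`: list with `t1`, `s0`, `residual_norm`
#'   (root mean squared residual divided by the largest absolute signal) and
#'   `converged`. A fit is flagged not converged when the amplitude is
#'   non-positive or T1 sticks to a search bound.
#' @examples
#' tr <- default_tr_list()
#' s <- 1000 * (1 - exp(-tr / 300))
#' fit_saturation_recovery(tr, s)$t1
#' @export
fit_saturation_recovery <- function(tr, signal, t1_bounds = DEFAULT_T1_BOUNDS) {
  stopifnot(length(tr) == length(signal), length(tr) >= 3L)
  if (any(diff(tr) <= 0)) {
    stop("`tr` must be strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(signal)) || !all(is.finite(tr)) || any(tr <= 0)) {
    stop("non-finite values in series", call. = FALSE)
  }
  if (max(signal) - min(signal) <= 0) {
    stop("signal is constant: saturation-recovery fit cannot converge",
         call. = FALSE)
  }
  ss <- sum(signal^2)
  grid <- t1_grid(t1_bounds)
  rss_grid <- vapply(grid, sr_profile_rss, numeric(1), tr = tr, s = signal,
                     ss = ss)
  i <- which.min(rss_grid)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- optimize(sr_profile_rss, c(lo, hi), tr = tr, s = signal, ss = ss,
                  tol = 1e-7 * grid[i])
  t1 <- opt$minimum
  s0 <- sr_s0_hat(t1, tr, signal)
  rss <- max(opt$objective, 0)
  interior <- t1 > t1_bounds[1] * 1.001 && t1 < t1_bounds[2] * 0.999
  structure(list(
    t1 = t1,
    s0 = s0,
    residual_norm = sqrt(rss / length(signal)) / max(abs(signal)),
    converged = is.finite(t1) && is.finite(s0) && s0 > 0 && interior
  ), class = "se_fit")
}

# ---- MOLLI / inversion recovery ------------------------------------------

# closed-form LS solve of y = A - B*e for fixed e = exp(-ti/t1_star);
# returns c(A, B, rss)
ir_solve <- function(y, e) {
  n <- length(y)
  se <- sum(e); see <- sum(e * e)
  sy <- sum(y); sye <- sum(y * e)
  den <- see - se * se / n
  if (!is.finite(den) || den < 1e-12 * max(see, 1)) {
    # e is numerically constant: only the mean is identifiable (B -> 0 limit)
    return(c(mean(y), 0, sum((y - mean(y))^2)))
  }
  b <- (se * sy / n - sye) / den
  a <- (sy + b * se) / n
  r <- y - a + b * e
  c(a, b, sum(r * r))
}

ir_profile_rss <- function(t1s, ti, y) ir_solve(y, exp(-ti / t1s))[3]

# grid-stage profiled RSS for all candidate T1* at once.
# E: length(ti) x G matrix of exp(-ti/t1s); returns RSS vector length G.
ir_grid_rss <- function(y, E, se, see) {
  n <- length(y)
  sy <- sum(y)
  syy <- sum(y * y)
  sye <- drop(y %*% E)
  den <- see - se * se / n
  b <- (se * sy / n - sye) / den
  a <- (sy + b * se) / n
  rss <- syy - 2 * a * sy + 2 * b * sye + a * a * n - 2 * a * b * se +
    b * b * see
  rss[!is.finite(rss) | den < 1e-12 * pmax(see, 1)] <- Inf
  pmax(rss, 0)
}

#' Fit the three-parameter Look-Locker inversion-recovery model
#'
#' Fits `S(TI) = A - B * exp(-TI/T1*)` to a MOLLI series and applies the
#' Look-Locker correction `T1 = T1* (B/A - 1)`. For magnitude data
#' (`polarity_known = FALSE`) the sign of the early, inverted part of the
#' curve is lost; polarity is restored by exhaustively refitting with the
#' first k samples negated for every k in 0..n and keeping the lowest
#' residual, ties broken toward fewer flipped points.
#'
#' @param ti numeric vector of inversion times (ms by convention).
#' @param signal numeric vector of intensities per TI. Interpreted as
#'   magnitude data unless `polarity_known = TRUE`, in which case it is used
#'   as signed data with no flip search.
#' @param polarity_known logical; `TRUE` for signed (real-valued) data.
#' @param t1_bounds search bounds for the apparent time constant T1*.
#' @return object of class `molli_fit`: list with `a`, `b`, `t1_star`, `t1`
#'   (Look-Locker corrected), `polarity_flip_index` (number of negated
#'   leading samples; 0 for signed fits), `residual_norm`, and `converged`.
#'   Fits with `b/a <= 1` or `a <= 0` are physically invalid and flagged
#'   not converged; `t1` is `NA` in that case.
#' @examples
#' ti <- default_ti_list()
#' s <- 1000 - 2000 * exp(-ti / 250)
#' fit_molli(ti, s, polarity_known = TRUE)$t1
#' @export
fit_molli <- function(ti, signal, polarity_known = FALSE,
                      t1_bounds = DEFAULT_T1_BOUNDS) {
  stopifnot(length(ti) == length(signal), length(ti) >= 4L)
  if (any(diff(ti) <= 0)) stop("`ti` must be strictly increasing", call. = FALSE)
  if (!all(is.finite(signal))) stop("non-finite signal", call. = FALSE)
  if (max(signal) - min(signal) <= 0) {
    stop("signal is constant: inversion-recovery fit is degenerate",
         call. = FALSE)
  }
  grid <- t1_grid(t1_bounds)
  E <- exp(-outer(ti, grid, function(t, g) t / g))
  se <- colSums(E)
  see <- colSums(E * E)

  n <- length(ti)
  if (polarity_known) {
    candidates <- list(signal)
    flips <- 0L
  } else {
    mag <- abs(signal)
    flips <- 0:n
    candidates <- lapply(flips, function(k) {
      y <- mag
      if (k > 0) y[seq_len(k)] <- -y[seq_len(k)]
      y
    })
  }

  # every flip candidate is refined before selection: physically valid
  # fits (A > 0, B/A > 1) beat invalid ones, then lowest residual wins,
  # with strict improvement required so ties keep the fewest flipped points
  best <- NULL
  for (ci in seq_along(candidates)) {
    y <- candidates[[ci]]
    rss_grid <- ir_grid_rss(y, E, se, see)
    i <- which.min(rss_grid)
    opt <- optimize(ir_profile_rss,
                    c(grid[max(i - 1L, 1L)], grid[min(i + 1L, length(grid))]),
                    ti = ti, y = y, tol = 1e-7 * grid[i])
    ab <- ir_solve(y, exp(-ti / opt$minimum))
    valid <- is.finite(ab[1]) && ab[1] > 0 && ab[2] / ab[1] > 1
    better <- is.null(best) ||
      (valid && !best$valid) ||
      (valid == best$valid &&
         opt$objective < best$rss * (1 - 1e-12) - 1e-300)
    if (better) {
      best <- list(y = y, t1s = opt$minimum, rss = opt$objective,
                   flip = flips[ci], valid = valid)
    }
  }

  ab <- ir_solve(best$y, exp(-ti / best$t1s))
  a <- ab[1]; b <- ab[2]
  valid <- is.finite(a) && is.finite(b) && a > 0 && b / a > 1
  interior <- best$t1s > t1_bounds[1] * 1.001 && best$t1s < t1_bounds[2] * 0.999
  structure(list(
    a = a,
    b = b,
    t1_star = best$t1s,
    t1 = if (valid) best$t1s * (b / a - 1) else NA_real_,
    polarity_flip_index = best$flip,
    residual_norm = sqrt(max(best$rss, 0) / n) / max(abs(signal)),
    converged = valid && interior
  ), class = "molli_fit")
}

#' Pixelwise T1 map from an image stack
#'
#' Fits every pixel inside `mask` with the saturation-recovery or MOLLI
#' model and returns a T1 map with per-pixel fit quality. Pixels whose fit
#' fails to converge are retained in the map but flagged, and region
#' statistics ([roi_mean_t1()]) exclude them.
#'
#' @param stack 3-D numeric array `x` by `y` by time, one slice per TR or TI.
#' @param grid numeric vector of TRs (saturation recovery) or TIs (MOLLI),
#'   length `dim(stack)[3]`.
#' @param mode `"saturation_recovery"` or `"molli"`.
#' @param mask logical matrix selecting pixels to fit; default all pixels.
#' @param polarity_known for MOLLI mode, whether the stack holds signed data.
#' @param t1_bounds T1 search bounds passed to the fitters.
#' @return object of class `t1_map`: list with matrices `t1` (NA outside the
#'   mask), `residual`, `converged`, plus `mask` and `mode`.
#' @export
fit_t1_map <- function(stack, grid, mode = c("saturation_recovery", "molli"),
                       mask = NULL, polarity_known = FALSE,
                       t1_bounds = DEFAULT_T1_BOUNDS) {
  mode <- match.arg(mode)
  stopifnot(length(dim(stack)) == 3L, dim(stack)[3] == length(grid))
  nx <- dim(stack)[1]; ny <- dim(stack)[2]
  if (is.null(mask)) mask <- matrix(TRUE, nx, ny)
  stopifnot(is.logical(mask), all(dim(mask) == c(nx, ny)))
  idx <- which(mask)
  if (length(idx) == 0L) stop("mask is empty", call. = FALSE)

  t1 <- matrix(NA_real_, nx, ny)
  residual <- matrix(NA_real_, nx, ny)
  converged <- matrix(FALSE, nx, ny)

  sig <- matrix(stack, nx * ny, length(grid))[idx, , drop = FALSE]

  if (mode == "saturation_recovery") {
    # vectorised grid stage across pixels, then per-pixel Brent refinement
    tg <- t1_grid(t1_bounds)
    Fm <- 1 - exp(-outer(grid, tg, function(t, g) t / g))
    ff <- colSums(Fm * Fm)
    gain <- (sig %*% Fm)^2 / rep(ff, each = nrow(sig))
    ibest <- max.col(gain, ties.method = "first")
    for (p in seq_along(idx)) {
      s <- sig[p, ]
      if (max(s) - min(s) <= 0) next
      ss <- sum(s^2)
      i <- ibest[p]
      opt <- optimize(sr_profile_rss, c(tg[max(i - 1L, 1L)],
                                        tg[min(i + 1L, length(tg))]),
                      tr = grid, s = s, ss = ss, tol = 1e-7 * tg[i])
      s0 <- sr_s0_hat(opt$minimum, grid, s)
      t1[idx[p]] <- opt$minimum
      residual[idx[p]] <- sqrt(max(opt$objective, 0) / length(s)) / max(abs(s))
      converged[idx[p]] <- is.finite(s0) && s0 > 0 &&
        opt$minimum > t1_bounds[1] * 1.001 && opt$minimum < t1_bounds[2] * 0.999
    }
  } else {
    for (p in seq_along(idx)) {
      s <- sig[p, ]
      if (max(s) - min(s) <= 0) next
      fit <- fit_molli(grid, s, polarity_known = polarity_known,
                       t1_bounds = t1_bounds)
      t1[idx[p]] <- if (is.na(fit$t1)) fit$t1_star else fit$t1
      residual[idx[p]] <- fit$residual_norm
      converged[idx[p]] <- fit$converged
    }
  }

  structure(list(t1 = t1, residual = residual, converged = converged,
                 mask = mask, mode = mode, grid = grid),
            class = "t1_map")
}

#' Mean T1 over a region of interest
#'
#' Averages map pixels over the ROI, using only pixels that are inside the
#' map mask and whose fit converged.
#'
#' @param map a [fit_t1_map()] result.
#' @param roi logical matrix the same size as the map, or integer pixel
#'   indices.
#' @return object of class `t1_estimate`: list with `mean` (ms), `sd`,
#'   `n_pixels`.
#' @export
roi_mean_t1 <- function(map, roi) {
  stopifnot(inherits(map, "t1_map"))
  if (is.matrix(roi)) {
    stopifnot(all(dim(roi) == dim(map$t1)))
    roi <- which(roi)
  }
  valid <- roi[map$mask[roi] & map$converged[roi] & is.finite(map$t1[roi])]
  if (length(valid) == 0L) {
    stop("no valid (converged) pixels in ROI", call. = FALSE)
  }
  v <- map$t1[valid]
  structure(list(mean = mean(v), sd = if (length(v) > 1L) sd(v) else 0,
                 n_pixels = length(v)),
            class = "t1_estimate")
}

#' @export
print.se_fit <- function(x, ...) {
  cat(sprintf("Saturation-recovery fit: T1 = %.2f ms, S0 = %.3g (%s)\n",
              x$t1, x$s0,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
print.molli_fit <- function(x, ...) {
  cat(sprintf(
    "MOLLI fit: T1* = %.2f ms, T1 = %.2f ms, B/A = %.3f, flip index %d (%s)\n",
    x$t1_star, x$t1, x$b / x$a, x$polarity_flip_index,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
print.t1_map <- function(x, ...) {
  n <- sum(x$mask)
  cat(sprintf("T1 map (%s): %d x %d, %d fitted pixels, %d converged\n",
              x$mode, nrow(x$t1), ncol(x$t1), n, sum(x$converged)))
  invisible(x)
}
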