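# Relaxivity estimation from dilution series and the in-vitro hypothesis
# tests: albumin effect (paired t) and ibuprofen correlation (Pearson).

#' Relaxivity from a gadolinium dilution series
#'
#' Ordinary least-squares regression of the longitudinal relaxation rate
#' `R1 = 1/T1` (s^-1) on gadolinium concentration (mmol/l). The slope is
#' the relaxivity r1 in mmol^-1 s^-1 l; T1 input is in ms and converted
#' internally.
#'
#' @param gd_conc gadolinium concentrations, mmol/l (>= 2 distinct values).
#' @param t1_ms measured T1 per concentration, ms (all positive).
#' @return object of class `relaxivity_fit`: list with `r1` (slope),
#'   `intercept` (s^-1), `r_squared`, `n_points`.
#' @examples
#' c_gd <- c(0, 2, 4, 8, 16)
#' fit_relaxivity(c_gd, 1000 / (0.5 + 7.22 * c_gd))$r1
#' @export
fit_relaxivity <- function(gd_conc, t1_ms) {
  stopifnot(length(gd_conc) == length(t1_ms))
  if (length(unique(gd_conc)) < 2L) {
    stop("need at least 2 distinct gadolinium concentrations", call. = FALSE)
  }
  if (any(!is.finite(t1_ms)) || any(t1_ms <= 0)) {
    stop("all T1 values must be positive and finite", call. = FALSE)
  }
  r1_rate <- 1000 / t1_ms # s^-1
  fit <- lm(r1_rate ~ gd_conc)
  # direct R^2 (summary.lm warns on numerically perfect fits)
  rss <- sum(residuals(fit)^2)
  tss <- sum((r1_rate - mean(r1_rate))^2)
  rsq <- if (tss == 0) 1 else 1 - rss / tss
  structure(list(r1 = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = rsq,
                 n_points = length(gd_conc)),
            class = "relaxivity_fit")
}

#' Relaxivity table for the full factorial phantom
#'
#' Splits per-vial T1 estimates into one gadolinium dilution series per
#' (ibuprofen concentration, albumin) cell and fits each series, yielding
#' the 10 relaxivity values of the full design.
#'
#' @param vial_t1 data frame with columns `vial_id` and `t1` (ms), one row
#'   per vial.
#' @param manifest vial manifest (default the full factorial
#'   [vial_manifest()]).
#' @return data frame with one row per (ibuprofen_conc, albumin_conc) cell:
#'   `ibuprofen_conc`, `albumin_conc`, `albumin_present`, `r1`, `intercept`,
#'   `r_squared`, `n_points`.
#' @export
relaxivity_table <- function(vial_t1, manifest = vial_manifest()) {
  stopifnot(is.data.frame(vial_t1), all(c("vial_id", "t1") %in% names(vial_t1)))
  missing_v <- setdiff(manifest$vial_id, vial_t1$vial_id)
  if (length(missing_v) > 0) {
    mm <- manifest[manifest$vial_id %in% missing_v, ]
    stop(sprintf(
      "missing T1 for vial(s) %s (cells: %s)",
      paste(missing_v, collapse = ", "),
      paste(unique(sprintf("ibuprofen %g / albumin %g",
                           mm$ibuprofen_conc, mm$albumin_conc)),
            collapse = "; ")), call. = FALSE)
  }
  d <- merge(manifest, vial_t1[, c("vial_id", "t1")], by = "vial_id")
  cells <- unique(d[, c("ibuprofen_conc", "albumin_conc")])
  cells <- cells[order(cells$albumin_conc, cells$ibuprofen_conc), ]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- d[d$ibuprofen_conc == cells$ibuprofen_conc[i] &
               d$albumin_conc == cells$albumin_conc[i], ]
    fit <- fit_relaxivity(sub$gd_conc, sub$t1)
    data.frame(ibuprofen_conc = cells$ibuprofen_conc[i],
               albumin_conc = cells$albumin_conc[i],
               albumin_present = cells$albumin_conc[i] > 0,
               r1 = fit$r1, intercept = fit$intercept,
               r_squared = fit$r_squared, n_points = fit$n_points)
  }))
  rownames(out) <- NULL
  out
}

#' End-to-end relaxivity analysis of a phantom series
#'
#' Convenience chain for a simulated (or compatible) phantom: pixelwise
#' saturation-recovery T1 map over the vial masks, per-vial ROI mean T1,
#' and the per-cell relaxivity table.
#'
#' @param phantom a [make_phantom()] result.
#' @return list with `vial_t1` (data frame: vial_id, t1, t1_sd, n_pixels),
#'   `table` (the [relaxivity_table()]), and `map` (the fitted [fit_t1_map()]
#'   object).
#' @export
phantom_relaxivity <- function(phantom) {
  stopifnot(inherits(phantom, "phantom_series"))
  mask <- matrix(FALSE, dim(phantom$images)[1], dim(phantom$images)[2])
  for (v in phantom$vial_masks) mask[v] <- TRUE
  map <- fit_t1_map(phantom$images, phantom$tr_list,
                    mode = "saturation_recovery", mask = mask)
  vial_t1 <- do.call(rbind, lapply(seq_along(phantom$vial_masks), function(v) {
    est <- roi_mean_t1(map, phantom$vial_masks[[v]])
    data.frame(vial_id = phantom$manifest$vial_id[v], t1 = est$mean,
               t1_sd = est$sd, n_pixels = est$n_pixels)
  }))
  list(vial_t1 = vial_t1, table = relaxivity_table(vial_t1, phantom$manifest),
       map = map)
}

#' Albumin effect on relaxivity (paired t-test)
#'
#' Pairs the with-albumin and without-albumin relaxivities by ibuprofen
#' concentration and applies a two-sided paired t-test.
#'
#' @param rtab a [relaxivity_table()] result.
#' @return list with `t`, `df`, `p`, `mean_diff`
#'   (albumin minus no-albumin), `mean_albumin`, `mean_no_albumin`, `n`,
#'   `degenerate` (see [paired_t()]).
#' @export
albumin_effect_test <- function(rtab) {
  a1 <- rtab[rtab$albumin_present, ]
  a0 <- rtab[!rtab$albumin_present, ]
  a1 <- a1[order(a1$ibuprofen_conc), ]
  a0 <- a0[order(a0$ibuprofen_conc), ]
  if (nrow(a1) == 0 || nrow(a0) == 0 ||
      !identical(a1$ibuprofen_conc, a0$ibuprofen_conc)) {
    stop("arms are not paired by ibuprofen concentration", call. = FALSE)
  }
  res <- paired_t(a1$r1, a0$r1)
  res$mean_albumin <- mean(a1$r1)
  res$mean_no_albumin <- mean(a0$r1)
  res
}

#' Correlation of relaxivity with ibuprofen concentration
#'
#' Pearson correlation of r1 against ibuprofen concentration, separately in
#' the presence and absence of albumin, with two-sided p-values from the
#' exact t transform `t = r sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom
#' (approximate at the small n of a single design).
#'
#' @param rtab a [relaxivity_table()] result.
#' @return data frame with one row per arm: `albumin_present`, `r`, `p`,
#'   `n`.
#' @export
ibuprofen_correlation <- function(rtab) {
  do.call(rbind, lapply(c(FALSE, TRUE), function(arm) {
    sub <- rtab[rtab$albumin_present == arm, ]
    if (nrow(sub) < 3L) stop("need >= 3 points per arm", call. = FALSE)
    if (var(sub$r1) == 0 || var(sub$ibuprofen_conc) == 0) {
      stop("zero variance in correlation input", call. = FALSE)
    }
    r <- cor(sub$ibuprofen_conc, sub$r1)
    n <- nrow(sub)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    data.frame(albumin_present = arm, r = r,
               p = 2 * pt(-abs(tt), df = n - 2), n = n)
  }))
}

#' @export
print.relaxivity_fit <- function(x, ...) {
  cat(sprintf("Relaxivity fit: r1 = %.3f mmol^-1 s^-1 l, intercept = %.4f s^-1, R^2 = %.4f (n = %d)\n",
              x$r1, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}
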