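# Synthetic in-vitro relaxivity phantom: a 50-vial factorial design of
# gadolinium contrast agent x ibuprofen x albumin, imaged as a multi-TR
# saturation-recovery spin-echo series.

GD_LEVELS <- c(0, 2, 4, 8, 16)              # mmol/l
IBUPROFEN_LEVELS <- c(0, 0.48, 0.97, 1.94, 4.85)  # mmol/l
ALBUMIN_LEVELS <- c(0, 4)                   # g/dl

#' Factorial vial manifest for the relaxivity phantom
#'
#' Full factorial of gadolinium concentration (0, 2, 4, 8, 16 mmol/l),
#' ibuprofen concentration (0, 0.48, 0.97, 1.94, 4.85 mmol/l) and albumin
#' (0 or 4 g/dl): 50 vials.
#'
#' @return data frame with columns `vial_id`, `gd_conc` (mmol/l),
#'   `ibuprofen_conc` (mmol/l), `albumin_conc` (g/dl).
#' @export
vial_manifest <- function() {
  m <- expand.grid(gd_conc = GD_LEVELS,
                   ibuprofen_conc = IBUPROFEN_LEVELS,
                   albumin_conc = ALBUMIN_LEVELS,
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(vial_id = seq_len(nrow(m)), m)
}

#' Ground-truth parameters for the synthetic phantom
#'
#' The generating model for each vial is
#' `1/T1 = 1/t1_solvent + r1(albumin, ibuprofen) * gd_conc` with
#' `r1 = (r1_albumin or r1_no_albumin) + ibuprofen_effect_slope * ibuprofen_conc`
#' (rates in s^-1, concentrations in mmol/l). The default relaxivities are
#' the literature values for gadobenate dimeglumine at 1.5 T with and
#' without physiological albumin; `ibuprofen_effect_slope = 0` encodes the
#' null hypothesis of no ibuprofen interference and can be set negative to
#' simulate competitive displacement.
#'
#' @param r1_no_albumin,r1_albumin relaxivity in mmol^-1 s^-1 l.
#' @param t1_solvent T1 of the gadolinium-free solvent, ms.
#' @param noise_sd image noise standard deviation as a fraction of the
#'   fully-recovered signal.
#' @param ibuprofen_effect_slope change in relaxivity per mmol/l ibuprofen.
#' @param s0 fully-recovered signal amplitude (arbitrary units).
#' @return validated list of class `phantom_truth`.
#' @export
phantom_truth <- function(r1_no_albumin = 7.22, r1_albumin = 9.24,
                          t1_solvent = 3000, noise_sd = 0.01,
                          ibuprofen_effect_slope = 0, s0 = 1000) {
  assert_number(r1_no_albumin, "r1_no_albumin", lower = 0, strict_lower = TRUE)
  assert_number(r1_albumin, "r1_albumin", lower = 0, strict_lower = TRUE)
  assert_number(t1_solvent, "t1_solvent", lower = 0, strict_lower = TRUE)
  assert_number(noise_sd, "noise_sd", lower = 0)
  assert_number(ibuprofen_effect_slope, "ibuprofen_effect_slope")
  assert_number(s0, "s0", lower = 0, strict_lower = TRUE)
  structure(list(r1_no_albumin = r1_no_albumin, r1_albumin = r1_albumin,
                 t1_solvent = t1_solvent, noise_sd = noise_sd,
                 ibuprofen_effect_slope = ibuprofen_effect_slope, s0 = s0),
            class = "phantom_truth")
}

#' Grid layout of phantom vials in the image
#'
#' @param vial_radius vial radius in pixels.
#' @param margin blank pixels around each vial within its grid cell.
#' @param nrow,ncol grid dimensions (`nrow * ncol` must cover 50 vials).
#' @return list of class `phantom_layout`.
#' @export
phantom_layout <- function(vial_radius = 3, margin = 2, nrow = 5, ncol = 10) {
  stopifnot(vial_radius >= 1, nrow * ncol >= 50)
  cell <- 2 * (vial_radius + margin) + 1
  structure(list(vial_radius = vial_radius, cell = cell,
                 nrow = nrow, ncol = ncol,
                 dim = c(nrow * cell, ncol * cell)),
            class = "phantom_layout")
}

#' True vial T1 values implied by phantom truth parameters
#'
#' @param truth a [phantom_truth()].
#' @param manifest a [vial_manifest()] (or subset with the same columns).
#' @return the manifest with an extra column `t1_true` (ms).
#' @export
vial_true_t1 <- function(truth, manifest = vial_manifest()) {
  stopifnot(inherits(truth, "phantom_truth"))
  r1_eff <- ifelse(manifest$albumin_conc > 0, truth$r1_albumin,
                   truth$r1_no_albumin) +
    truth$ibuprofen_effect_slope * manifest$ibuprofen_conc
  r1_total <- 1000 / truth$t1_solvent + r1_eff * manifest$gd_conc # s^-1
  bad <- which(r1_total <= 0)
  if (length(bad) > 0) {
    stop(sprintf(
      "non-positive relaxation rate for vial(s) %s: check relaxivity and ibuprofen_effect_slope",
      paste(manifest$vial_id[bad], collapse = ", ")), call. = FALSE)
  }
  manifest$t1_true <- 1000 / r1_total # ms
  manifest
}

#' Simulate the multi-TR phantom image series
#'
#' Lays the 50 vials out on a grid, assigns each its ground-truth T1 from
#' the relaxivity model, and simulates a saturation-recovery spin-echo image
#' at every TR: `S(TR) = S0 * (1 - exp(-TR/T1))` plus noise. The default
#' noise model adds Gaussian noise to the signed signal; `"rician"` takes
#' the magnitude of a complex Gaussian perturbation, as for magnitude MR
#' reconstructions.
#'
#' @param truth a [phantom_truth()].
#' @param layout a [phantom_layout()].
#' @param seed integer seed; required, every run is fully reproducible.
#' @param tr_list repetition times in ms (default the 17-TR protocol).
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @return object of class `phantom_series`: list with `tr_list`, `images`
#'   (3-D array, last dimension TR), `vial_masks` (list of pixel index
#'   vectors keyed by vial id), `manifest` (including `t1_true`), `truth`,
#'   `layout`, `noise_model`.
#' @examples
#' ph <- make_phantom(phantom_truth(noise_sd = 0), seed = 1)
#' nrow(ph$manifest)
#' @export
make_phantom <- function(truth = phantom_truth(), layout = phantom_layout(),
                         seed, tr_list = default_tr_list(),
                         noise_model = c("gaussian", "rician")) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(layout, "phantom_layout"))
  noise_model <- match.arg(noise_model)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (any(diff(tr_list) <= 0)) {
    stop("`tr_list` must be strictly increasing", call. = FALSE)
  }
  manifest <- vial_true_t1(truth, vial_manifest())

  nx <- layout$dim[1]; ny <- layout$dim[2]
  half <- (layout$cell - 1) / 2
  masks <- vector("list", nrow(manifest))
  names(masks) <- manifest$vial_id
  px <- matrix(seq_len(nx), nx, ny)
  py <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  for (v in seq_len(nrow(manifest))) {
    r <- (v - 1) %/% layout$ncol
    c <- (v - 1) %% layout$ncol
    cx <- r * layout$cell + half + 1
    cy <- c * layout$cell + half + 1
    masks[[v]] <- which((px - cx)^2 + (py - cy)^2 <= layout$vial_radius^2)
  }

  clean <- array(0, dim = c(nx, ny, length(tr_list)))
  plane <- nx * ny
  for (v in seq_len(nrow(manifest))) {
    s <- truth$s0 * (1 - exp(-tr_list / manifest$t1_true[v]))
    for (k in seq_along(tr_list)) {
      clean[masks[[v]] + (k - 1L) * plane] <- s[k]
    }
  }

  images <- withr::with_seed(seed, {
    if (truth$noise_sd == 0) {
      clean
    } else {
      sdn <- truth$noise_sd * truth$s0
      if (noise_model == "gaussian") {
        clean + array(rnorm(length(clean), sd = sdn), dim = dim(clean))
      } else {
        n1 <- array(rnorm(length(clean), sd = sdn), dim = dim(clean))
        n2 <- array(rnorm(length(clean), sd = sdn), dim = dim(clean))
        sqrt((clean + n1)^2 + n2^2)
      }
    }
  })

  structure(list(tr_list = tr_list, images = images, vial_masks = masks,
                 manifest = manifest, truth = truth, layout = layout,
                 noise_model = noise_model, seed = seed),
            class = "phantom_series")
}

#' @export
print.phantom_series <- function(x, ...) {
  cat(sprintf(
    "Synthetic relaxivity phantom: %d vials, %d TRs, %d x %d pixels (%s noise, sd %.3g)\n",
    nrow(x$manifest), length(x$tr_list), dim(x$images)[1], dim(x$images)[2],
    x$noise_model, x$truth$noise_sd))
  invisible(x)
}
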