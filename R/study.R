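# Synthetic two-exam in-vivo MOLLI study: mid-ventricular short-axis slice,
# pre-contrast plus every 5 minutes from 5 to 60 minutes after bolus
# contrast injection, two exams per subject generated from identical truth
# (the null hypothesis of no between-exam effect) with independent noise.

#' Bi-exponential blood contrast washout curve
#'
#' Returns `C(t) = a1 * exp(-t/tau1) + a2 * exp(-t/tau2)` (mmol/l as a
#' function of minutes). The defaults were calibrated so that, combined with
#' the default blood relaxivity, the simulated blood T1 rises from roughly
#' 148 ms at 5 minutes to 373 ms at 60 minutes after a 0.15 mmol/kg bolus.
#'
#' @param a1,a2 amplitudes in mmol/l.
#' @param tau1,tau2 decay times in minutes.
#' @return function of time (minutes) returning concentration (mmol/l).
#' @export
gd_washout_curve <- function(a1 = 1.307, tau1 = 3.935, a2 = 0.640,
                             tau2 = 86.75) {
  force(a1); force(tau1); force(a2); force(tau2)
  function(t) a1 * exp(-t / tau1) + a2 * exp(-t / tau2)
}

#' Ground-truth parameters for the synthetic in-vivo study
#'
#' Generating model per subject and time point `t` (minutes after
#' injection): blood `1/T1 = 1/t1_blood_pre + r1_blood * C(t)` with `C` the
#' washout curve; myocardial `dR1(t) = lambda(t) * dR1_blood(t)` with
#' `lambda(t) = lambda_start + lambda_drift_per_min * t`. Both exams share
#' the same truth; only the noise differs. Defaults reproduce typical 1.5 T
#' healthy-volunteer values: pre-contrast myocardium 1011 ms, blood 1526 ms,
#' and a partition coefficient rising from 0.382 at 5 min to 0.454 at
#' 60 min.
#'
#' @param n_subjects number of subjects.
#' @param t1_myo_pre,t1_blood_pre population mean pre-contrast T1, ms.
#' @param lambda_start partition coefficient extrapolated to t = 0.
#' @param lambda_drift_per_min linear drift of lambda per minute.
#' @param blood_gd_conc_curve function of minutes returning blood
#'   gadolinium concentration in mmol/l; default [gd_washout_curve()].
#' @param r1_blood blood relaxivity of the agent, mmol^-1 s^-1 l.
#' @param between_subject_sd SD of subject pre-contrast myocardial T1 (ms);
#'   blood T1 is scattered proportionally to its larger mean.
#' @param noise_sd signal noise SD as a fraction of the amplitude `A`.
#' @param seed integer seed.
#' @return validated list of class `study_truth`.
#' @export
study_truth <- function(n_subjects = 10, t1_myo_pre = 1011,
                        t1_blood_pre = 1526, lambda_start = 0.3755,
                        lambda_drift_per_min = 0.0013091,
                        blood_gd_conc_curve = gd_washout_curve(),
                        r1_blood = 6.3, between_subject_sd = 32,
                        noise_sd = 0.01, seed = 1L) {
  assert_number(n_subjects, "n_subjects", lower = 1)
  assert_number(t1_myo_pre, "t1_myo_pre", lower = 0, strict_lower = TRUE)
  assert_number(t1_blood_pre, "t1_blood_pre", lower = 0, strict_lower = TRUE)
  assert_number(lambda_start, "lambda_start", lower = 0, upper = 1,
                strict_lower = TRUE)
  assert_number(lambda_drift_per_min, "lambda_drift_per_min")
  assert_number(r1_blood, "r1_blood", lower = 0, strict_lower = TRUE)
  assert_number(between_subject_sd, "between_subject_sd", lower = 0)
  assert_number(noise_sd, "noise_sd", lower = 0)
  stopifnot(is.function(blood_gd_conc_curve))
  structure(list(n_subjects = as.integer(n_subjects),
                 t1_myo_pre = t1_myo_pre, t1_blood_pre = t1_blood_pre,
                 lambda_start = lambda_start,
                 lambda_drift_per_min = lambda_drift_per_min,
                 blood_gd_conc_curve = blood_gd_conc_curve,
                 r1_blood = r1_blood,
                 between_subject_sd = between_subject_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "study_truth")
}

#' Slice geometry for the synthetic heart
#'
#' Concentric-circle model of the mid-ventricular short-axis slice: the
#' myocardium is the annulus between the endocardial and epicardial
#' contours, the blood pool the endocardial disc, and the blood ROI a
#' smaller concentric disc eroded inward from the endocardium so papillary
#' muscle territory near the endocardial border is avoided.
#'
#' @param dim image size in pixels (square).
#' @param pixel_mm pixel spacing, mm.
#' @param endo_r,epi_r endo- and epicardial radii in pixels.
#' @param blood_erosion_px inward erosion from the endocardial contour used
#'   to place the blood ROI.
#' @param blood_area_range admissible blood-ROI area in cm^2; an error is
#'   raised if the implied ROI falls outside it.
#' @return list of class `study_geometry` with the three contour polygons.
#' @export
study_geometry <- function(dim = 48L, pixel_mm = 2.5, endo_r = 8, epi_r = 12,
                           blood_erosion_px = 3.8,
                           blood_area_range = c(3, 4)) {
  stopifnot(endo_r < epi_r, blood_erosion_px < endo_r)
  ctr <- (dim + 1) / 2
  blood_r <- endo_r - blood_erosion_px
  blood_area_cm2 <- pi * (blood_r * pixel_mm / 10)^2
  if (blood_area_cm2 < blood_area_range[1] ||
      blood_area_cm2 > blood_area_range[2]) {
    stop(sprintf("blood ROI area %.2f cm^2 outside [%g, %g]",
                 blood_area_cm2, blood_area_range[1], blood_area_range[2]),
         call. = FALSE)
  }
  structure(list(
    dim = as.integer(dim), pixel_mm = pixel_mm, center = c(ctr, ctr),
    endo_r = endo_r, epi_r = epi_r, blood_r = blood_r,
    endo = circle_polygon(ctr, ctr, endo_r),
    epi = circle_polygon(ctr, ctr, epi_r),
    blood_roi = circle_polygon(ctr, ctr, blood_r),
    blood_area_cm2 = blood_area_cm2
  ), class = "study_geometry")
}

molli_signal <- function(ti, t1, a = 1000, b_over_a = 2) {
  t1_star <- t1 / (b_over_a - 1)
  a - b_over_a * a * exp(-ti / t1_star)
}

#' Simulate a two-exam in-vivo MOLLI study
#'
#' For every subject, exam and time point a MOLLI inversion-recovery series
#' is generated from the three-parameter model `S(TI) = A - B exp(-TI/T1*)`
#' with `B = 2A` (so the apparent and corrected T1 coincide) at the 11
#' nominal inversion times. Exam 2 is generated from the same truth as exam
#' 1 with independent noise.
#'
#' At `resolution = "image"` each time point is a raster stack with blood
#' pool, myocardial annulus and empty background, and the contours are
#' returned for segmentation; at `resolution = "roi"` the generator emits
#' per-segment and blood mean-signal series directly, which is much faster
#' and appropriate for large simulation studies.
#'
#' @param truth a [study_truth()].
#' @param geometry a [study_geometry()].
#' @param resolution `"image"` or `"roi"`.
#' @param minutes time points in minutes, 0 meaning pre-contrast; default
#'   pre plus every 5 minutes from 5 to 60 (13 time points).
#' @param ti_list inversion times, ms.
#' @param magnitude if `TRUE` (default) the stored signal is the magnitude
#'   of the noisy signed signal, as reconstructed MR data would be.
#' @param noise_model `"gaussian"` on the signed signal (default) or
#'   `"rician"`.
#' @param n_segments myocardial segments per slice.
#' @return object of class `synthetic_study`: list with `truth`,
#'   `geometry`, `subject_truth` (per-subject pre-contrast T1 draws),
#'   `truth_records` (per subject and time point: true tissue T1 and
#'   lambda), and `subjects`, a nested list
#'   `subjects[[s]]$exams[[e]]$timepoints[[k]]` holding `minutes`,
#'   `ti_list` and either `stack` (image mode) or `segment_series` +
#'   `blood_series` (roi mode).
#' @examples
#' st <- make_invivo_study(study_truth(n_subjects = 2, noise_sd = 0),
#'                         resolution = "roi")
#' length(st$subjects[[1]]$exams[[1]]$timepoints)
#' @export
make_invivo_study <- function(truth = study_truth(),
                              geometry = study_geometry(),
                              resolution = c("image", "roi"),
                              minutes = c(0, seq(5, 60, by = 5)),
                              ti_list = default_ti_list(),
                              magnitude = TRUE,
                              noise_model = c("gaussian", "rician"),
                              n_segments = 6L) {
  stopifnot(inherits(truth, "study_truth"), inherits(geometry, "study_geometry"))
  resolution <- match.arg(resolution)
  noise_model <- match.arg(noise_model)
  stopifnot(minutes[1] == 0, all(diff(minutes) > 0))

  post <- minutes[minutes > 0]
  lambda_t <- truth$lambda_start + truth$lambda_drift_per_min * post
  if (any(lambda_t <= 0 | lambda_t >= 1)) {
    stop("lambda(t) leaves (0, 1) over the requested time points",
         call. = FALSE)
  }

  a_amp <- 1000
  sd_noise <- truth$noise_sd * a_amp
  sd_blood <- truth$between_subject_sd * truth$t1_blood_pre / truth$t1_myo_pre

  # precompute pixel region indices for image mode
  if (resolution == "image") {
    d <- geometry$dim
    px <- matrix(seq_len(d), d, d)
    py <- matrix(rep(seq_len(d), each = d), d, d)
    rr <- sqrt((px - geometry$center[1])^2 + (py - geometry$center[2])^2)
    idx_blood_pool <- which(rr <= geometry$endo_r)
    idx_myo <- which(rr > geometry$endo_r & rr <= geometry$epi_r)
  }

  add_noise <- function(clean) {
    if (truth$noise_sd == 0) {
      out <- clean
    } else if (noise_model == "gaussian") {
      out <- clean + rnorm(length(clean), sd = sd_noise)
    } else {
      out <- sqrt((clean + rnorm(length(clean), sd = sd_noise))^2 +
                    rnorm(length(clean), sd = sd_noise)^2)
    }
    if (magnitude) abs(out) else out
  }

  withr::with_seed(truth$seed, {
    subj_myo_pre <- rnorm(truth$n_subjects, truth$t1_myo_pre,
                          truth$between_subject_sd)
    subj_blood_pre <- rnorm(truth$n_subjects, truth$t1_blood_pre, sd_blood)
    if (any(subj_myo_pre <= 0) || any(subj_blood_pre <= 0)) {
      stop("between_subject_sd too large: non-positive pre-contrast T1",
           call. = FALSE)
    }

    truth_records <- do.call(rbind, lapply(seq_len(truth$n_subjects), function(s) {
      cb <- ifelse(minutes > 0, truth$blood_gd_conc_curve(minutes), 0)
      dr1_blood <- truth$r1_blood * cb                       # s^-1
      lam <- ifelse(minutes > 0,
                    truth$lambda_start + truth$lambda_drift_per_min * minutes,
                    NA_real_)
      dr1_myo <- ifelse(minutes > 0, lam * dr1_blood, 0)
      data.frame(
        subject = s, minutes = minutes,
        t1_myo_true = 1000 / (1000 / subj_myo_pre[s] + dr1_myo),
        t1_blood_true = 1000 / (1000 / subj_blood_pre[s] + dr1_blood),
        lambda_true = lam
      )
    }))

    subjects <- lapply(seq_len(truth$n_subjects), function(s) {
      tr_s <- truth_records[truth_records$subject == s, ]
      exams <- lapply(1:2, function(e) {
        tps <- lapply(seq_along(minutes), function(k) {
          t1m <- tr_s$t1_myo_true[k]
          t1b <- tr_s$t1_blood_true[k]
          tp <- list(minutes = minutes[k], ti_list = ti_list)
          if (resolution == "image") {
            clean <- array(0, dim = c(d, d, length(ti_list)))
            plane <- d * d
            sm <- molli_signal(ti_list, t1m, a_amp)
            sb <- molli_signal(ti_list, t1b, a_amp)
            for (j in seq_along(ti_list)) {
              off <- (j - 1L) * plane
              clean[idx_myo + off] <- sm[j]
              clean[idx_blood_pool + off] <- sb[j]
            }
            tp$stack <- add_noise(clean)
          } else {
            tp$segment_series <- lapply(seq_len(n_segments), function(g) {
              add_noise(molli_signal(ti_list, t1m, a_amp))
            })
            tp$blood_series <- add_noise(molli_signal(ti_list, t1b, a_amp))
          }
          tp
        })
        list(exam = e, timepoints = tps)
      })
      list(subject = s, exams = exams)
    })

    structure(list(
      truth = truth, geometry = geometry, resolution = resolution,
      minutes = minutes, ti_list = ti_list, magnitude = magnitude,
      noise_model = noise_model, n_segments = as.integer(n_segments),
      subject_truth = data.frame(subject = seq_len(truth$n_subjects),
                                 t1_myo_pre = subj_myo_pre,
                                 t1_blood_pre = subj_blood_pre),
      truth_records = truth_records,
      subjects = subjects
    ), class = "synthetic_study")
  })
}

#' Number of MOLLI series in a synthetic study
#'
#' One series per subject, exam and time point.
#' @param study a [make_invivo_study()] result.
#' @return integer count.
#' @export
n_molli_series <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  sum(vapply(study$subjects, function(s) {
    sum(vapply(s$exams, function(e) length(e$timepoints), integer(1)))
  }, integer(1)))
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic MOLLI study: %d subjects x 2 exams x %d time points (%s resolution, noise sd %.3g)\n",
    x$truth$n_subjects, length(x$minutes), x$resolution, x$truth$noise_sd))
  invisible(x)
}
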