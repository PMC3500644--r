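# Myocardial segmentation, per-time-point T1 extraction, and partition
# coefficient / ECV computation.

#' Build the six mid-cavity myocardial segments
#'
#' Labels every pixel between the endocardial and epicardial contours with
#' one of the six mid-cavity segments of the AHA 17-segment left-ventricular
#' model (labels 7-12). Sectors are equal 60-degree wedges counted
#' anticlockwise from `reference_angle`; segment 7 starts at the reference
#' (anterior by convention).
#'
#' @param endo,epi contour polygons (data frames with `x`, `y` in pixel
#'   coordinates); `endo` must lie strictly inside `epi`.
#' @param dim image dimensions, length-2 integer (rows, columns).
#' @param reference_angle angle in degrees (mathematical convention:
#'   anticlockwise from the +x axis) at which segment 7 begins.
#' @param labels segment labels, length 6.
#' @return object of class `segment_model`: list with `label` (integer
#'   matrix, NA outside the myocardium), `labels`, `reference_angle`,
#'   `center`, `endo`, `epi`.
#' @export
build_segments <- function(endo, epi, dim, reference_angle = 90,
                           labels = 7:12) {
  stopifnot(length(labels) == 6L, length(dim) == 2L)
  if (!all(point_in_polygon(endo$x, endo$y, epi))) {
    stop("contours cross: endocardial contour is not strictly inside the epicardial contour",
         call. = FALSE)
  }
  ctr <- polygon_centroid(endo)
  px <- matrix(seq_len(dim[1]), dim[1], dim[2])
  py <- matrix(rep(seq_len(dim[2]), each = dim[1]), dim[1], dim[2])
  in_epi <- point_in_polygon(as.vector(px), as.vector(py), epi)
  in_endo <- point_in_polygon(as.vector(px), as.vector(py), endo)
  myo <- in_epi & !in_endo

  theta <- atan2(as.vector(py) - ctr[2], as.vector(px) - ctr[1]) * 180 / pi
  sector <- floor(((theta - reference_angle) %% 360) / 60) + 1L
  lab <- rep(NA_integer_, dim[1] * dim[2])
  lab[myo] <- labels[sector[myo]]

  structure(list(label = matrix(lab, dim[1], dim[2]), labels = labels,
                 reference_angle = reference_angle, center = ctr,
                 endo = endo, epi = epi),
            class = "segment_model")
}

#' Extract per-segment, slice and blood T1 at one time point
#'
#' Averages a T1 map over each myocardial segment and over the blood ROI.
#' A segment is excluded automatically when the fraction of its pixels with
#' failed fits exceeds `quality_threshold` (the operational criterion for
#' severely impaired image quality), or when listed in `exclusions`. The
#' slice mean is the unweighted mean of the included segment means.
#'
#' @param map a [fit_t1_map()] result.
#' @param segments a [build_segments()] model on the same pixel grid.
#' @param blood_roi polygon (data frame `x`, `y`) or logical matrix for the
#'   blood pool ROI.
#' @param exclusions integer vector of segment labels to exclude a priori.
#' @param quality_threshold maximum tolerated fraction of non-converged
#'   pixels per segment.
#' @return object of class `timepoint_record`: list with `t1_segments`
#'   (named numeric, NA for excluded), `slice_t1_myo`, `t1_blood`,
#'   `excluded_segments`, `n_pixels_blood`.
#' @export
extract_timepoint <- function(map, segments, blood_roi,
                              exclusions = integer(0),
                              quality_threshold = 0.3) {
  stopifnot(inherits(map, "t1_map"), inherits(segments, "segment_model"),
            all(dim(segments$label) == dim(map$t1)))
  seg_means <- rep(NA_real_, length(segments$labels))
  names(seg_means) <- segments$labels
  excluded <- intersect(as.integer(exclusions), segments$labels)
  for (g in setdiff(segments$labels, excluded)) {
    pix <- which(segments$label == g & map$mask)
    if (length(pix) == 0L) {
      excluded <- union(excluded, g)
      next
    }
    ok <- pix[map$converged[pix] & is.finite(map$t1[pix])]
    if (1 - length(ok) / length(pix) > quality_threshold) {
      excluded <- union(excluded, g)
      next
    }
    seg_means[as.character(g)] <- mean(map$t1[ok])
  }
  included <- setdiff(segments$labels, excluded)
  if (length(included) == 0L) {
    stop("all segments excluded at this time point", call. = FALSE)
  }
  slice_mean <- mean(seg_means[as.character(included)])

  if (is.data.frame(blood_roi)) {
    px <- matrix(seq_len(nrow(map$t1)), nrow(map$t1), ncol(map$t1))
    py <- matrix(rep(seq_len(ncol(map$t1)), each = nrow(map$t1)),
                 nrow(map$t1), ncol(map$t1))
    inside <- point_in_polygon(as.vector(px), as.vector(py), blood_roi)
    blood_roi <- matrix(inside, nrow(map$t1), ncol(map$t1))
  }
  blood <- roi_mean_t1(map, blood_roi)

  structure(list(t1_segments = seg_means, slice_t1_myo = slice_mean,
                 t1_blood = blood$mean, excluded_segments = sort(excluded),
                 n_pixels_blood = blood$n_pixels),
            class = "timepoint_record")
}

#' Partition coefficient from pre/post contrast T1
#'
#' `lambda = dR1_myocardium / dR1_blood` with `dR1 = 1/T1_post - 1/T1_pre`.
#' The ratio is invariant to the common time unit of the four inputs.
#'
#' @param t1_myo_pre,t1_myo_post,t1_blood_pre,t1_blood_post T1 values
#'   (same unit each), all positive. Vectorised.
#' @return numeric lambda.
#' @examples
#' partition_coefficient(1011, 301, 1526, 148) # ~0.382
#' @export
partition_coefficient <- function(t1_myo_pre, t1_myo_post,
                                  t1_blood_pre, t1_blood_post) {
  vals <- c(t1_myo_pre, t1_myo_post, t1_blood_pre, t1_blood_post)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all T1 inputs must be positive", call. = FALSE)
  }
  dr1_blood <- 1 / t1_blood_post - 1 / t1_blood_pre
  if (any(dr1_blood == 0)) {
    stop("dR1_blood = 0: partition coefficient undefined", call. = FALSE)
  }
  if (any(dr1_blood < 0)) {
    stop("dR1_blood < 0: post-contrast blood T1 exceeds pre-contrast (no contrast arrived)",
         call. = FALSE)
  }
  (1 / t1_myo_post - 1 / t1_myo_pre) / dr1_blood
}

#' Extracellular volume fraction
#'
#' `ECV = lambda * (1 - hematocrit)`.
#'
#' @param lambda partition coefficient.
#' @param hematocrit fraction in `[0, 1)`.
#' @return numeric ECV.
#' @export
ecv <- function(lambda, hematocrit) {
  if (any(!is.finite(hematocrit)) || any(hematocrit < 0) ||
      any(hematocrit >= 1)) {
    stop("hematocrit must lie in [0, 1)", call. = FALSE)
  }
  lambda * (1 - hematocrit)
}

#' Partition-coefficient time course and summary
#'
#' Computes per-subject lambda at every post-contrast time point from a
#' long table of slice-mean myocardial and blood T1, then summarises by
#' exam and time. The exam-level lambda can be formed either as the ratio
#' of mean dR1 values across subjects (`"ratio_of_means"`, default) or as
#' the mean of per-subject lambdas (`"mean_of_ratios"`); with group-mean
#' input the two coincide. The relative increase per exam is
#' `(lambda_last - lambda_first)/lambda_first` over the first and last
#' post-contrast times present.
#'
#' @param records data frame with columns `subject`, `exam`, `minutes`
#'   (0 = pre-contrast), `t1_myo`, `t1_blood` (ms).
#' @param mode `"ratio_of_means"` or `"mean_of_ratios"`.
#' @param hematocrit optional fraction; when given, per-record ECV is added.
#' @return object of class `partition_timecourse`: list with `records`
#'   (per subject/exam/time lambda and dR1, s^-1), `summary` (per
#'   exam/time: `lambda`, `lambda_sd`, `n`), `relative_increase` (named by
#'   exam), `mode`.
#' @export
partition_timecourse <- function(records,
                                 mode = c("ratio_of_means", "mean_of_ratios"),
                                 hematocrit = NULL) {
  mode <- match.arg(mode)
  need <- c("subject", "exam", "minutes", "t1_myo", "t1_blood")
  stopifnot(is.data.frame(records), all(need %in% names(records)))

  out <- do.call(rbind, lapply(split(records, records[c("subject", "exam")],
                                     drop = TRUE), function(d) {
    pre <- d[d$minutes == 0, ]
    if (nrow(pre) != 1L) {
      stop(sprintf("subject %s exam %s: missing pre-contrast record",
                   d$subject[1], d$exam[1]), call. = FALSE)
    }
    post <- d[d$minutes > 0, ]
    post <- post[order(post$minutes), ]
    data.frame(
      subject = post$subject, exam = post$exam, minutes = post$minutes,
      dr1_myo = 1000 / post$t1_myo - 1000 / pre$t1_myo,      # s^-1
      dr1_blood = 1000 / post$t1_blood - 1000 / pre$t1_blood, # s^-1
      lambda = partition_coefficient(pre$t1_myo, post$t1_myo,
                                     pre$t1_blood, post$t1_blood)
    )
  }))
  rownames(out) <- NULL
  if (!is.null(hematocrit)) out$ecv <- ecv(out$lambda, hematocrit)

  summ <- do.call(rbind, lapply(split(out, out[c("minutes", "exam")],
                                      drop = TRUE), function(d) {
    lam <- if (mode == "ratio_of_means") {
      mean(d$dr1_myo) / mean(d$dr1_blood)
    } else {
      mean(d$lambda)
    }
    data.frame(exam = d$exam[1], minutes = d$minutes[1], lambda = lam,
               lambda_sd = if (nrow(d) > 1L) sd(d$lambda) else NA_real_,
               n = nrow(d))
  }))
  summ <- summ[order(summ$exam, summ$minutes), ]
  rownames(summ) <- NULL

  rel <- vapply(split(summ, summ$exam), function(d) {
    (d$lambda[nrow(d)] - d$lambda[1]) / d$lambda[1]
  }, numeric(1))

  structure(list(records = out, summary = summ, relative_increase = rel,
                 mode = mode),
            class = "partition_timecourse")
}

#' Segment evaluation and exclusion bookkeeping
#'
#' Either pass a segment-level data frame with a logical `excluded` column,
#' or the study dimensions plus the number of excluded segments.
#'
#' @param records optional data frame with one row per evaluated segment and
#'   a logical column `excluded`.
#' @param n_subjects,n_exams,n_timepoints,n_segments study dimensions (used
#'   when `records` is not given).
#' @param n_excluded number of excluded segments (when `records` not given).
#' @return list with `evaluated`, `excluded`, `fraction`, and
#'   `percent` (fraction rounded to one decimal, in percent).
#' @export
exclusion_bookkeeping <- function(records = NULL, n_subjects = 10,
                                  n_exams = 2, n_timepoints = 13,
                                  n_segments = 6, n_excluded = 0) {
  if (!is.null(records)) {
    stopifnot(is.data.frame(records), "excluded" %in% names(records))
    evaluated <- nrow(records)
    excluded <- sum(records$excluded)
  } else {
    evaluated <- n_subjects * n_exams * n_timepoints * n_segments
    excluded <- n_excluded
  }
  list(evaluated = evaluated, excluded = excluded,
       fraction = excluded / evaluated,
       percent = round(100 * excluded / evaluated, 1))
}

#' Fit and extract a whole synthetic study
#'
#' Runs the T1-mapping and extraction chain over every subject, exam and
#' time point of a [make_invivo_study()] result: image-resolution studies
#' go through pixelwise MOLLI mapping, segmentation and ROI extraction;
#' roi-resolution studies fit each per-segment and blood series directly.
#'
#' @param study a [make_invivo_study()] result.
#' @param quality_threshold passed to [extract_timepoint()] (image mode).
#' @return list with `records` (data frame: subject, exam, minutes, t1_myo
#'   = slice mean, t1_blood, n_excluded) and `segment_records` (one row per
#'   segment with its T1 and exclusion flag).
#' @export
study_timecourse <- function(study, quality_threshold = 0.3) {
  stopifnot(inherits(study, "synthetic_study"))
  polarity_known <- !study$magnitude
  seg_labels <- 7:12

  if (study$resolution == "image") {
    g <- study$geometry
    segments <- build_segments(g$endo, g$epi, dim = c(g$dim, g$dim))
    px <- matrix(seq_len(g$dim), g$dim, g$dim)
    py <- matrix(rep(seq_len(g$dim), each = g$dim), g$dim, g$dim)
    rr <- sqrt((px - g$center[1])^2 + (py - g$center[2])^2)
    blood_mask <- rr <= g$blood_r
    fit_mask <- (rr <= g$epi_r & rr > g$endo_r) | blood_mask
  }

  rec <- list(); seg_rec <- list()
  for (s in study$subjects) {
    for (e in s$exams) {
      for (tp in e$timepoints) {
        if (study$resolution == "image") {
          map <- fit_t1_map(tp$stack, tp$ti_list, mode = "molli",
                            mask = fit_mask, polarity_known = polarity_known)
          x <- extract_timepoint(map, segments, blood_mask,
                                 quality_threshold = quality_threshold)
          seg_t1 <- x$t1_segments
          excluded <- x$excluded_segments
          slice <- x$slice_t1_myo
          blood <- x$t1_blood
        } else {
          seg_t1 <- vapply(tp$segment_series, function(y) {
            f <- fit_molli(tp$ti_list, y, polarity_known = polarity_known)
            if (f$converged) f$t1 else NA_real_
          }, numeric(1))
          names(seg_t1) <- seg_labels
          excluded <- seg_labels[is.na(seg_t1)]
          if (length(excluded) == 6L) {
            stop("all segments excluded at this time point", call. = FALSE)
          }
          slice <- mean(seg_t1, na.rm = TRUE)
          fb <- fit_molli(tp$ti_list, tp$blood_series,
                          polarity_known = polarity_known)
          if (!fb$converged) stop("blood fit failed", call. = FALSE)
          blood <- fb$t1
        }
        rec[[length(rec) + 1L]] <- data.frame(
          subject = s$subject, exam = e$exam, minutes = tp$minutes,
          t1_myo = slice, t1_blood = blood, n_excluded = length(excluded))
        seg_rec[[length(seg_rec) + 1L]] <- data.frame(
          subject = s$subject, exam = e$exam, minutes = tp$minutes,
          segment = seg_labels, t1 = unname(seg_t1),
          excluded = seg_labels %in% excluded)
      }
    }
  }
  list(records = do.call(rbind, rec),
       segment_records = do.call(rbind, seg_rec))
}

#' Reference two-exam in-vivo T1 summary
#'
#' Literature-derived mean T1 times of myocardium and blood and the
#' partition coefficient for a two-exam healthy-volunteer reproducibility
#' study at 1.5 T (13 time points: pre-contrast and every 5 minutes from 5
#' to 60 minutes after 0.15 mmol/kg gadobenate dimeglumine). Used as the
#' package's default in-vivo operating point and in worked examples.
#'
#' @return data frame with columns `minutes` (0 = pre-contrast), `exam`,
#'   `t1_myo` (ms), `t1_blood` (ms), `lambda` (NA pre-contrast).
#' @export
reference_exam_summary <- function() {
  path <- system.file("extdata", "invivo_exam_summary.csv", package = "cmrt1",
                      mustWork = TRUE)
  read.csv(path)
}

#' @export
print.partition_timecourse <- function(x, ...) {
  cat(sprintf("Partition-coefficient time course (%s):\n", x$mode))
  print(x$summary, row.names = FALSE)
  cat("Relative increase first->last post-contrast time:\n")
  print(round(x$relative_increase, 4))
  invisible(x)
}
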