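# End-to-end orchestration: validated run configuration, simulation to
# disk (NIfTI stacks + CSV sidecars + JSON truth), and analysis from disk
# back to results tables and a stats report. Column names of all output
# tables carry their units.

PHANTOM_CONFIG_KEYS <- c("mode", "seed", "out_dir", "truth", "layout",
                         "noise_model", "tr_list")
STUDY_CONFIG_KEYS <- c("mode", "seed", "out_dir", "truth", "geometry",
                       "resolution", "minutes", "magnitude", "noise_model",
                       "fit", "hematocrit")

#' Read a run configuration file
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON (`.json`) file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml/.yml or .json", call. = FALSE)
  }
}

#' Validate a run configuration
#'
#' Checks the mode, required keys and rejects unknown keys, naming the
#' offenders.
#'
#' @param config configuration list.
#' @return the config, invisibly, with defaults filled in.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  if (is.null(config$mode) || !config$mode %in% c("phantom", "study")) {
    stop("config$mode must be \"phantom\" or \"study\"", call. = FALSE)
  }
  known <- if (config$mode == "phantom") PHANTOM_CONFIG_KEYS else STUDY_CONFIG_KEYS
  bad <- setdiff(names(config), known)
  if (length(bad) > 0) {
    stop(sprintf("unknown config key(s) for mode %s: %s", config$mode,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  for (key in c("seed", "out_dir")) {
    if (is.null(config[[key]])) {
      stop(sprintf("config$%s is required", key), call. = FALSE)
    }
  }
  config$truth <- config$truth %||% list()
  invisible(config)
}

resolve_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
}

check_overwrite <- function(path, force) {
  if (file.exists(path) && !force) {
    stop(sprintf("output %s exists; rerun with force = TRUE to overwrite",
                 path), call. = FALSE)
  }
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

#' Simulate phantom or study data to disk
#'
#' Writes image stacks as NIfTI, acquisition-time grids and manifests as
#' CSV, and the generating truth plus the resolved configuration as JSON,
#' all reproducible from the configured seed.
#'
#' @param config configuration list or path to a YAML/JSON file. Required
#'   keys: `mode` ("phantom" or "study"), `seed`, `out_dir`; optional
#'   `truth` (arguments of [phantom_truth()] / [study_truth()]), `layout`
#'   or `geometry`, `noise_model`, and for studies `resolution`, `minutes`,
#'   `magnitude`.
#' @param force overwrite existing outputs.
#' @return invisibly, the output directory.
#' @export
cmd_simulate <- function(config, force = FALSE) {
  config <- resolve_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  if (config$mode == "phantom") {
    check_overwrite(file.path(out, "manifest.csv"), force)
    truth <- do.call(phantom_truth, config$truth)
    layout <- do.call(phantom_layout, config$layout %||% list())
    ph <- make_phantom(truth, layout, seed = config$seed,
                       tr_list = config$tr_list %||% default_tr_list(),
                       noise_model = config$noise_model %||% "gaussian")
    RNifti::writeNifti(ph$images, file.path(out, "phantom_images.nii.gz"))
    labels <- matrix(0L, dim(ph$images)[1], dim(ph$images)[2])
    for (v in seq_along(ph$vial_masks)) labels[ph$vial_masks[[v]]] <- v
    RNifti::writeNifti(labels, file.path(out, "vial_labels.nii.gz"))
    write.csv(data.frame(volume = seq_along(ph$tr_list),
                         tr_ms = ph$tr_list),
              file.path(out, "tr_table.csv"), row.names = FALSE)
    m <- ph$manifest
    names(m) <- c("vial_id", "gd_conc_mmol_l", "ibuprofen_conc_mmol_l",
                  "albumin_conc_g_dl", "t1_true_ms")
    write.csv(m, file.path(out, "manifest.csv"), row.names = FALSE)
    write_json_report(unclass(ph$truth), file.path(out, "truth.json"))
    message(sprintf("simulated phantom: %d vials, %d TRs -> %s",
                    nrow(m), length(ph$tr_list), out))
  } else {
    check_overwrite(file.path(out, "study_index.csv"), force)
    truth_args <- config$truth
    truth_args$seed <- config$seed
    truth <- do.call(study_truth, truth_args)
    geometry <- do.call(study_geometry, config$geometry %||% list())
    st <- make_invivo_study(
      truth, geometry,
      resolution = config$resolution %||% "image",
      minutes = config$minutes %||% c(0, seq(5, 60, by = 5)),
      magnitude = if (is.null(config$magnitude)) TRUE else config$magnitude,
      noise_model = config$noise_model %||% "gaussian")

    write.csv(data.frame(volume = seq_along(st$ti_list),
                         ti_ms = st$ti_list),
              file.path(out, "ti_table.csv"), row.names = FALSE)
    contours <- rbind(
      data.frame(kind = "endo", x_px = st$geometry$endo$x,
                 y_px = st$geometry$endo$y),
      data.frame(kind = "epi", x_px = st$geometry$epi$x,
                 y_px = st$geometry$epi$y),
      data.frame(kind = "blood_roi", x_px = st$geometry$blood_roi$x,
                 y_px = st$geometry$blood_roi$y))
    write.csv(contours, file.path(out, "contours.csv"), row.names = FALSE)

    idx <- list()
    if (st$resolution == "image") {
      for (s in st$subjects) for (e in s$exams) for (tp in e$timepoints) {
        f <- sprintf("sub%02d_exam%d_t%02d.nii.gz", s$subject, e$exam,
                     tp$minutes)
        RNifti::writeNifti(tp$stack, file.path(out, f))
        idx[[length(idx) + 1L]] <- data.frame(
          subject = s$subject, exam = e$exam, minutes = tp$minutes, file = f)
      }
    } else {
      series <- list()
      for (s in st$subjects) for (e in s$exams) for (tp in e$timepoints) {
        rois <- c(lapply(tp$segment_series, identity),
                  list(tp$blood_series))
        roi_names <- c(paste0("segment_", 7:12), "blood")
        for (j in seq_along(rois)) {
          series[[length(series) + 1L]] <- data.frame(
            subject = s$subject, exam = e$exam, minutes = tp$minutes,
            roi = roi_names[j], ti_ms = tp$ti_list, signal = rois[[j]])
        }
        idx[[length(idx) + 1L]] <- data.frame(
          subject = s$subject, exam = e$exam, minutes = tp$minutes,
          file = "roi_series.csv")
      }
      write.csv(do.call(rbind, series), file.path(out, "roi_series.csv"),
                row.names = FALSE)
    }
    write.csv(do.call(rbind, idx), file.path(out, "study_index.csv"),
              row.names = FALSE)
    stt <- st$subject_truth
    names(stt) <- c("subject", "t1_myo_pre_ms", "t1_blood_pre_ms")
    write.csv(stt, file.path(out, "subject_truth.csv"), row.names = FALSE)
    trr <- st$truth_records
    names(trr) <- c("subject", "minutes", "t1_myo_true_ms",
                    "t1_blood_true_ms", "lambda_true")
    write.csv(trr, file.path(out, "truth_records.csv"), row.names = FALSE)
    tj <- unclass(truth)
    tj$blood_gd_conc_curve <- NULL # functions are not serialisable
    write_json_report(tj, file.path(out, "truth.json"))
    meta <- list(resolution = st$resolution, magnitude = st$magnitude,
                 noise_model = st$noise_model,
                 geometry = unclass(geometry)[c("dim", "pixel_mm", "endo_r",
                                                "epi_r", "blood_r")])
    write_json_report(meta, file.path(out, "study_meta.json"))
    message(sprintf("simulated study: %d subjects x 2 exams x %d time points -> %s",
                    truth$n_subjects, length(st$minutes), out))
  }
  cfg <- config
  cfg$truth <- config$truth
  write_json_report(cfg, file.path(out, "config_resolved.json"))
  invisible(out)
}

analyze_phantom_dir <- function(dir, out) {
  images <- as.array(RNifti::readNifti(file.path(dir, "phantom_images.nii.gz")))
  labels <- as.array(RNifti::readNifti(file.path(dir, "vial_labels.nii.gz")))
  labels <- matrix(as.integer(round(labels)), dim(images)[1], dim(images)[2])
  tr <- read.csv(file.path(dir, "tr_table.csv"))$tr_ms
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  names(manifest)[1:4] <- c("vial_id", "gd_conc", "ibuprofen_conc",
                            "albumin_conc")

  map <- fit_t1_map(images, tr, mode = "saturation_recovery",
                    mask = labels > 0)
  vial_t1 <- do.call(rbind, lapply(sort(unique(labels[labels > 0])),
                                   function(v) {
    est <- roi_mean_t1(map, labels == v)
    data.frame(vial_id = v, t1 = est$mean, t1_sd = est$sd,
               n_pixels = est$n_pixels)
  }))
  message(sprintf("fitted %d vials (%d converged pixels)",
                  nrow(vial_t1), sum(map$converged)))

  rtab <- relaxivity_table(vial_t1, manifest)
  alb <- withCallingHandlers(
    albumin_effect_test(rtab),
    warning = function(w) {
      message("albumin effect test: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  # degenerate (noise-free) phantoms have zero variance across ibuprofen
  # levels; report the correlation as unavailable rather than failing
  corr <- tryCatch(ibuprofen_correlation(rtab), error = function(e) {
    message("ibuprofen correlation unavailable: ", conditionMessage(e))
    data.frame(albumin_present = c(FALSE, TRUE), r = NA_real_,
               p = NA_real_, n = 5L)
  })

  vt <- vial_t1
  names(vt) <- c("vial_id", "t1_ms", "t1_sd_ms", "n_pixels")
  write.csv(vt, file.path(out, "vial_t1.csv"), row.names = FALSE)
  rt <- rtab
  names(rt) <- c("ibuprofen_conc_mmol_l", "albumin_conc_g_dl",
                 "albumin_present", "r1_per_mmol_s",
                 "intercept_per_s", "r_squared", "n_points")
  write.csv(rt, file.path(out, "relaxivity.csv"), row.names = FALSE)
  report <- list(
    n_vials = nrow(vial_t1),
    albumin_effect = alb,
    ibuprofen_correlation = list(
      no_albumin = as.list(corr[!corr$albumin_present, ]),
      albumin = as.list(corr[corr$albumin_present, ]))
  )
  write_json_report(report, file.path(out, "stats.json"))
  invisible(report)
}

# a fully degenerate response (e.g. a noise-free simulation) breaks the
# mixed-model machinery; the pipeline reports it as unavailable instead
safe_mixed_model <- function(data, response) {
  tryCatch(
    unclass(mixed_model_compare(data, response = response))[
      c("group_p", "group_estimate", "random_intercept_var", "n_obs")],
    error = function(e) {
      message(sprintf("mixed model for %s unavailable: %s", response,
                      conditionMessage(e)))
      list(group_p = NA_real_, group_estimate = NA_real_,
           random_intercept_var = NA_real_, n_obs = nrow(data))
    })
}

analyze_study_dir <- function(dir, out, quality_threshold = 0.3,
                              hematocrit = NULL) {
  idx <- read.csv(file.path(dir, "study_index.csv"))
  ti <- read.csv(file.path(dir, "ti_table.csv"))$ti_ms
  meta <- jsonlite::fromJSON(file.path(dir, "study_meta.json"))
  polarity_known <- !isTRUE(meta$magnitude)

  if (meta$resolution == "image") {
    contours <- read.csv(file.path(dir, "contours.csv"))
    poly <- function(kind) {
      d <- contours[contours$kind == kind, ]
      data.frame(x = d$x_px, y = d$y_px)
    }
    dimg <- as.integer(meta$geometry$dim)
    segments <- build_segments(poly("endo"), poly("epi"), dim = c(dimg, dimg))
    blood_poly <- poly("blood_roi")
    epi_poly <- poly("epi"); endo_poly <- poly("endo")
    px <- matrix(seq_len(dimg), dimg, dimg)
    py <- matrix(rep(seq_len(dimg), each = dimg), dimg, dimg)
    in_epi <- matrix(point_in_polygon(as.vector(px), as.vector(py), epi_poly),
                     dimg, dimg)
    in_endo <- matrix(point_in_polygon(as.vector(px), as.vector(py), endo_poly),
                      dimg, dimg)
    in_blood <- matrix(point_in_polygon(as.vector(px), as.vector(py), blood_poly),
                       dimg, dimg)
    fit_mask <- (in_epi & !in_endo) | in_blood

    rec <- list(); seg_rec <- list()
    for (i in seq_len(nrow(idx))) {
      stack <- as.array(RNifti::readNifti(file.path(dir, idx$file[i])))
      map <- fit_t1_map(stack, ti, mode = "molli", mask = fit_mask,
                        polarity_known = polarity_known)
      x <- extract_timepoint(map, segments, in_blood,
                             quality_threshold = quality_threshold)
      rec[[i]] <- data.frame(subject = idx$subject[i], exam = idx$exam[i],
                             minutes = idx$minutes[i],
                             t1_myo = x$slice_t1_myo, t1_blood = x$t1_blood,
                             n_excluded = length(x$excluded_segments))
      seg_rec[[i]] <- data.frame(
        subject = idx$subject[i], exam = idx$exam[i], minutes = idx$minutes[i],
        segment = segments$labels, t1 = unname(x$t1_segments),
        excluded = segments$labels %in% x$excluded_segments)
    }
    records <- do.call(rbind, rec)
    segment_records <- do.call(rbind, seg_rec)
  } else {
    series <- read.csv(file.path(dir, "roi_series.csv"))
    keys <- unique(series[, c("subject", "exam", "minutes")])
    rec <- list(); seg_rec <- list()
    for (i in seq_len(nrow(keys))) {
      d <- series[series$subject == keys$subject[i] &
                    series$exam == keys$exam[i] &
                    series$minutes == keys$minutes[i], ]
      seg_t1 <- vapply(paste0("segment_", 7:12), function(rn) {
        y <- d$signal[d$roi == rn]
        f <- fit_molli(d$ti_ms[d$roi == rn], y,
                       polarity_known = polarity_known)
        if (f$converged) f$t1 else NA_real_
      }, numeric(1))
      fb <- fit_molli(d$ti_ms[d$roi == "blood"], d$signal[d$roi == "blood"],
                      polarity_known = polarity_known)
      rec[[i]] <- data.frame(subject = keys$subject[i], exam = keys$exam[i],
                             minutes = keys$minutes[i],
                             t1_myo = mean(seg_t1, na.rm = TRUE),
                             t1_blood = fb$t1,
                             n_excluded = sum(is.na(seg_t1)))
      seg_rec[[i]] <- data.frame(
        subject = keys$subject[i], exam = keys$exam[i],
        minutes = keys$minutes[i], segment = 7:12, t1 = unname(seg_t1),
        excluded = is.na(seg_t1))
    }
    records <- do.call(rbind, rec)
    segment_records <- do.call(rbind, seg_rec)
  }

  book <- exclusion_bookkeeping(segment_records)
  message(sprintf("%d segments evaluated, %d excluded (%.1f%%)",
                  book$evaluated, book$excluded, 100 * book$fraction))

  tc <- partition_timecourse(records, hematocrit = hematocrit)

  # reproducibility between exams
  pre <- records[records$minutes == 0, ]
  pre1 <- pre[pre$exam == 1, ][order(pre$subject[pre$exam == 1]), ]
  pre2 <- pre[pre$exam == 2, ][order(pre$subject[pre$exam == 2]), ]
  lam <- tc$records
  key <- paste(lam$subject, lam$minutes)
  l1 <- lam[lam$exam == 1, ]; l2 <- lam[lam$exam == 2, ]
  l2 <- l2[match(paste(l1$subject, l1$minutes), paste(l2$subject, l2$minutes)), ]
  post <- records[records$minutes > 0, ]

  stats <- list(
    bookkeeping = book,
    pre_contrast_paired_t = list(
      myocardium = paired_t(pre1$t1_myo, pre2$t1_myo),
      blood = paired_t(pre1$t1_blood, pre2$t1_blood)),
    lambda_agreement = unclass(agreement(l1$lambda, l2$lambda)),
    mixed_models = list(
      t1_myocardium = safe_mixed_model(post, "t1_myo"),
      t1_blood = safe_mixed_model(post, "t1_blood"),
      lambda = safe_mixed_model(tc$records, "lambda")),
    relative_lambda_increase = as.list(tc$relative_increase)
  )
  message(sprintf("compared %d lambda pairs between exams", nrow(l1)))

  r <- records
  names(r) <- c("subject", "exam", "minutes", "t1_myo_ms", "t1_blood_ms",
                "n_excluded_segments")
  write.csv(r, file.path(out, "timepoint_records.csv"), row.names = FALSE)
  sr <- segment_records
  names(sr) <- c("subject", "exam", "minutes", "segment", "t1_ms", "excluded")
  write.csv(sr, file.path(out, "segment_records.csv"), row.names = FALSE)
  lr <- tc$records
  names(lr)[names(lr) == "dr1_myo"] <- "dr1_myo_per_s"
  names(lr)[names(lr) == "dr1_blood"] <- "dr1_blood_per_s"
  write.csv(lr, file.path(out, "lambda_records.csv"), row.names = FALSE)
  write.csv(tc$summary, file.path(out, "lambda_summary.csv"),
            row.names = FALSE)
  ba <- bland_altman(l1$lambda, l2$lambda)
  write.csv(ba$data, file.path(out, "bland_altman_lambda.csv"),
            row.names = FALSE)
  write_json_report(stats, file.path(out, "stats.json"))
  invisible(stats)
}

#' Analyse simulated (or compatible) data from disk
#'
#' Runs the full analysis chain on a directory produced by
#' [cmd_simulate()]: T1 mapping, ROI extraction, relaxivity or partition
#' coefficient computation, and the statistics report. Results tables
#' (CSV, units in column names) and `stats.json` are written to
#' `config$out_dir`.
#'
#' @param config configuration list or file; `out_dir` here names the
#'   directory holding the simulated inputs, and results are written next
#'   to them.
#' @param force overwrite existing results.
#' @return invisibly, the stats report list.
#' @export
cmd_analyze <- function(config, force = FALSE) {
  config <- resolve_config(config)
  dir <- config$out_dir
  check_overwrite(file.path(dir, "stats.json"), force)
  if (config$mode == "phantom") {
    if (!file.exists(file.path(dir, "phantom_images.nii.gz"))) {
      stop(sprintf("no phantom inputs found in %s: run cmd_simulate() first",
                   dir), call. = FALSE)
    }
    analyze_phantom_dir(dir, dir)
  } else {
    if (!file.exists(file.path(dir, "study_index.csv"))) {
      stop(sprintf("no study inputs found in %s: run cmd_simulate() first",
                   dir), call. = FALSE)
    }
    fitcfg <- config$fit %||% list()
    analyze_study_dir(dir, dir,
                      quality_threshold = fitcfg$quality_threshold %||% 0.3,
                      hematocrit = config$hematocrit)
  }
}
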