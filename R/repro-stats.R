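# Test-retest reproducibility statistics between two exams: paired t-test,
# ICC(2,1), Bland-Altman limits of agreement, and a linear mixed model on
# log-transformed responses.

#' Two-sided paired t-test
#'
#' Thin wrapper around [stats::t.test()] with explicit handling of the
#' zero-variance degenerate case: identical pairs give `t = 0, p = 1`;
#' a constant nonzero difference is reported with `p = 0` and a
#' `degenerate` flag (plus a warning) rather than an error, so that
#' pipelines complete.
#'
#' @param x,y paired measurement vectors of equal length (>= 2).
#' @return list with `t`, `df`, `p`, `mean_diff` (`mean(x - y)`), `n`,
#'   `degenerate`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L,
            all(is.finite(x)), all(is.finite(y)))
  d <- x - y
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, df = length(d) - 1L, p = 1, mean_diff = 0,
                  n = length(d), degenerate = FALSE))
    }
    warning("zero variance of paired differences with nonzero mean; reporting p = 0")
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1L, p = 0,
                mean_diff = mean(d), n = length(d), degenerate = TRUE))
  }
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate), n = length(d),
       degenerate = FALSE)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measures intraclass
#' correlation (Shrout-Fleiss ICC(2,1)) between two raters/exams, computed
#' from the two-way ANOVA decomposition:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param x,y paired measurements (one column per exam), length n >= 3.
#' @return object of class `icc_result`: list with `icc`, `msr`, `msc`,
#'   `mse`, `n`, `k`.
#' @export
icc_two_way_random <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 units for the ICC", call. = FALSE)
  m <- cbind(x, y)
  k <- 2L
  g <- mean(m)
  rowm <- rowMeans(m)
  colm <- colMeans(m)
  msr <- k * sum((rowm - g)^2) / (n - 1)
  msc <- n * sum((colm - g)^2) / (k - 1)
  sse <- sum((m - g)^2) - k * sum((rowm - g)^2) - n * sum((colm - g)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  structure(list(icc = icc, msr = msr, msc = msc, mse = mse, n = n, k = k),
            class = "icc_result")
}

#' Bland-Altman agreement analysis
#'
#' Bias (`mean(x - y)`) and 95% limits of agreement
#' (`bias +/- 1.96 sd(x - y)`), with the per-pair (mean, difference) data
#' used for plotting.
#'
#' @param x,y paired measurements (>= 2 pairs).
#' @return object of class `bland_altman`: list with `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n_pairs`, and `data` (data frame `mean`,
#'   `difference`).
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n_pairs = length(d),
                 data = data.frame(mean = (x + y) / 2, difference = d)),
            class = "bland_altman")
}

#' @export
plot.bland_altman <- function(x, ...,
                              xlab = "mean of exams",
                              ylab = "difference (exam 1 - exam 2)") {
  graphics::plot(x$data$mean, x$data$difference, xlab = xlab, ylab = ylab,
                 ylim = range(c(x$data$difference, x$loa_low, x$loa_high)),
                 ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Combined agreement summary (ICC + Bland-Altman)
#'
#' @param x,y paired measurements (>= 3 pairs).
#' @return object of class `agreement_result`: list with `icc`, `bias`,
#'   `loa_low`, `loa_high`, `n_pairs`.
#' @export
agreement <- function(x, y) {
  icc <- icc_two_way_random(x, y)
  ba <- bland_altman(x, y)
  structure(list(icc = icc$icc, bias = ba$bias, loa_low = ba$loa_low,
                 loa_high = ba$loa_high, n_pairs = ba$n_pairs),
            class = "agreement_result")
}

#' Linear mixed model comparing two exams over time
#'
#' Mixed model on the (by default log-transformed) response:
#' `log(response) ~ exam * factor(time) + (1 | subject) + (1 | subject:time)`,
#' fitted with [lmerTest::lmer()]; the exam (group) effect is tested with
#' Satterthwaite degrees of freedom. The subject-by-time random interaction
#' reflects the paired design — both exams measure the same subject at the
#' same time point — so the exam comparison is a within-cell contrast and
#' subject-specific washout curves do not inflate the error term.
#' Multiplying the response by a constant in both groups shifts only the
#' intercept on the log scale, so the group test is scale-invariant.
#'
#' @param data long-format data frame.
#' @param response,group,time,subject column names.
#' @param log_transform fit on `log(response)` (default `TRUE`).
#' @return object of class `mixed_model_result`: list with `fixed`
#'   (coefficient table), `anova` (Satterthwaite F table), `group_p`,
#'   `group_estimate` (group main-effect coefficient at the reference time),
#'   `random_intercept_var`, `n_obs`, `log_transform`.
#' @export
mixed_model_compare <- function(data, response = "t1", group = "exam",
                                time = "minutes", subject = "subject",
                                log_transform = TRUE) {
  stopifnot(is.data.frame(data),
            all(c(response, group, time, subject) %in% names(data)))
  d <- data.frame(resp = data[[response]],
                  g = factor(data[[group]]),
                  tm = factor(data[[time]]),
                  subj = factor(data[[subject]]))
  if (nlevels(d$g) != 2L) stop("exactly 2 groups required", call. = FALSE)
  if (nlevels(d$tm) < 2L) stop("need >= 2 time points", call. = FALSE)
  if (nlevels(d$subj) < 2L) stop("need >= 2 subjects", call. = FALSE)
  if (log_transform) {
    if (any(d$resp <= 0)) stop("log transform requires positive response",
                               call. = FALSE)
    d$resp <- log(d$resp)
  }
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(resp ~ g * tm + (1 | subj) + (1 | subj:tm), data = d)
  ))
  an <- suppressMessages(suppressWarnings(anova(fit)))
  co <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    fixed = co,
    anova = an,
    group_p = an["g", "Pr(>F)"],
    group_estimate = co[grep("^g", rownames(co))[1], "Estimate"],
    random_intercept_var = vc$vcov[vc$grp == "subj"],
    n_obs = nrow(d),
    log_transform = log_transform
  ), class = "mixed_model_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.4f (n = %d units, k = %d raters)\n",
              x$icc, x$n, x$k))
  invisible(x)
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias = %.4g, 95%% limits [%.4g, %.4g] (n = %d)\n",
              x$bias, x$loa_low, x$loa_high, x$n_pairs))
  invisible(x)
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Agreement: ICC(2,1) = %.4f, bias = %.4g, LoA [%.4g, %.4g] (n = %d)\n",
              x$icc, x$bias, x$loa_low, x$loa_high, x$n_pairs))
  invisible(x)
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("Mixed model on %s response (%d obs): group p = %.4g\n",
              if (x$log_transform) "log" else "raw", x$n_obs, x$group_p))
  invisible(x)
}
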