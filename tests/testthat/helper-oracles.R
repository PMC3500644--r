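# Independent oracles used across the test suite. These deliberately avoid
# the package's profiled (variable-projection) fitting path: brute-force
# parameter grids, direct textbook formulas, and reference optimisers.

# dense brute-force grid search over (S0, T1) for the saturation-recovery
# model; returns the minimum RSS and its parameters
oracle_sr_grid <- function(tr, s, t1_range = c(1, 10000), n_t1 = 600,
                           s0_range = NULL, n_s0 = 300) {
  if (is.null(s0_range)) s0_range <- c(0.5, 1.5) * max(abs(s))
  t1s <- exp(seq(log(t1_range[1]), log(t1_range[2]), length.out = n_t1))
  s0s <- seq(s0_range[1], s0_range[2], length.out = n_s0)
  best <- list(rss = Inf)
  for (t1 in t1s) {
    f <- 1 - exp(-tr / t1)
    # rss over all S0 at once
    rss <- vapply(s0s, function(a) sum((s - a * f)^2), numeric(1))
    i <- which.min(rss)
    if (rss[i] < best$rss) best <- list(rss = rss[i], t1 = t1, s0 = s0s[i])
  }
  best
}

# brute-force grid over (A, B, T1*) for the inversion-recovery model
oracle_ir_grid <- function(ti, y, t1_range = c(1, 10000), n_t1 = 300,
                           n_ab = 80) {
  amax <- max(abs(y))
  as <- seq(-1.5 * amax, 1.5 * amax, length.out = n_ab)
  bs <- seq(0, 3 * amax, length.out = n_ab)
  t1s <- exp(seq(log(t1_range[1]), log(t1_range[2]), length.out = n_t1))
  best <- list(rss = Inf)
  for (t1 in t1s) {
    e <- exp(-ti / t1)
    for (a in as) {
      rss <- vapply(bs, function(b) sum((y - a + b * e)^2), numeric(1))
      i <- which.min(rss)
      if (rss[i] < best$rss) {
        best <- list(rss = rss[i], t1_star = t1, a = a, b = bs[i])
      }
    }
  }
  best
}

# reference nonlinear LS fit of the SR model via minpack.lm (independent
# optimiser and parameterisation)
oracle_sr_nlsLM <- function(tr, s) {
  d <- data.frame(tr = tr, s = s)
  fit <- minpack.lm::nlsLM(
    s ~ s0 * (1 - exp(-tr / t1)), data = d,
    start = list(s0 = max(s), t1 = tr[which.min(abs(s - 0.63 * max(s)))]),
    lower = c(1e-6, 1), upper = c(Inf, 1e4),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  coef(fit)
}

# exhaustive signed-fit polarity oracle for magnitude MOLLI data: for every
# flip index fit the signed 3-parameter model with nlsLM, keep lowest RSS
oracle_molli_polarity <- function(ti, mag) {
  n <- length(mag)
  best <- NULL
  for (k in 0:n) {
    y <- mag
    if (k > 0) y[seq_len(k)] <- -y[seq_len(k)]
    d <- data.frame(ti = ti, y = y)
    fit <- try(minpack.lm::nlsLM(
      y ~ a - b * exp(-ti / t1s), data = d,
      start = list(a = max(y), b = max(y) - min(y), t1s = 300),
      lower = c(-Inf, 0, 1), upper = c(Inf, Inf, 1e4),
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      cf <- coef(fit)
      best <- list(rss = rss, a = cf["a"], b = cf["b"], t1_star = cf["t1s"],
                   t1 = cf["t1s"] * (cf["b"] / cf["a"] - 1), flip = k)
    }
  }
  best
}

# textbook paired t statistic
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  list(t = tstat, p = 2 * pt(-abs(tstat), df = n - 1))
}

# ICC(2,1) from stats::aov mean squares (independent ANOVA decomposition)
oracle_icc_aov <- function(x, y) {
  n <- length(x)
  d <- data.frame(value = c(x, y),
                  unit = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(aov(value ~ unit + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# direct-sum Pearson correlation (no stats::cor)
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
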