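test_that("noise-free saturation-recovery series invert exactly", {
  tr <- default_tr_list()
  for (t1_true in c(53.15, 300, 1011, 3000)) {
    s <- 1000 * (1 - exp(-tr / t1_true))
    fit <- fit_saturation_recovery(tr, s)
    expect_true(fit$converged)
    expect_equal(fit$t1, t1_true, tolerance = 1e-3)
    expect_equal(fit$s0, 1000, tolerance = 1e-3)
  }
})

test_that("saturation-recovery fit rejects degenerate input", {
  tr <- default_tr_list()
  expect_error(fit_saturation_recovery(tr, rep(0, 17)), "constant")
  expect_error(fit_saturation_recovery(tr, rep(5, 17)), "constant")
  expect_error(fit_saturation_recovery(rev(tr), 1:17), "increasing")
  expect_error(fit_saturation_recovery(tr[1:2], 1:2))
})

test_that("noisy saturation-recovery T1 is recovered and matches reference fits", {
  tr <- default_tr_list()
  t1s <- withr::with_seed(42, {
    replicate(200, {
      s <- 1000 * (1 - exp(-tr / 300)) + rnorm(17, sd = 10)
      fit_saturation_recovery(tr, s)$t1
    })
  })
  expect_lt(abs(mean(t1s) - 300) / 300, 0.02)

  # dual route: profiled fit agrees with the independent Levenberg-Marquardt
  # optimiser on individual noisy series
  withr::with_seed(7, {
    for (i in 1:5) {
      s <- 1000 * (1 - exp(-tr / 300)) + rnorm(17, sd = 10)
      fit <- fit_saturation_recovery(tr, s)
      ref <- oracle_sr_nlsLM(tr, s)
      expect_equal(fit$t1, unname(ref["t1"]), tolerance = 1e-4)
    }
  })
})

test_that("nonlinear fits never exceed the brute-force grid-search residual", {
  tr <- default_tr_list()
  ti <- default_ti_list()
  withr::with_seed(11, {
    for (i in 1:6) {
      t1_true <- exp(runif(1, log(30), log(3000)))
      s <- 800 * (1 - exp(-tr / t1_true)) + rnorm(17, sd = 15)
      fit <- fit_saturation_recovery(tr, s)
      rss_fit <- (fit$residual_norm * max(abs(s)))^2 * length(s)
      rss_grid <- oracle_sr_grid(tr, s)$rss
      expect_lte(rss_fit, rss_grid * (1 + 1e-6))

      y <- 1000 - 1900 * exp(-ti / t1_true) + rnorm(11, sd = 15)
      mfit <- fit_molli(ti, y, polarity_known = TRUE)
      rss_m <- (mfit$residual_norm * max(abs(y)))^2 * length(y)
      rss_mg <- oracle_ir_grid(ti, y)$rss
      expect_lte(rss_m, rss_mg * (1 + 1e-6))
    }
  })
})

test_that("fits are scale-equivariant and unit-consistent", {
  tr <- default_tr_list()
  s <- 1000 * (1 - exp(-tr / 450))
  f1 <- fit_saturation_recovery(tr, s)
  f2 <- fit_saturation_recovery(tr, 3.7 * s)
  expect_equal(f2$t1, f1$t1, tolerance = 1e-8)
  expect_equal(f2$s0, 3.7 * f1$s0, tolerance = 1e-8)

  # ms -> s inputs with matching bounds scale T1 by exactly 1/1000
  f3 <- fit_saturation_recovery(tr / 1000, s, t1_bounds = c(0.001, 10))
  expect_equal(f3$t1 * 1000, f1$t1, tolerance = 1e-6)

  ti <- default_ti_list()
  y <- 1000 - 2000 * exp(-ti / 250)
  m1 <- fit_molli(ti, y, polarity_known = TRUE)
  m2 <- fit_molli(ti, 2.5 * y, polarity_known = TRUE)
  expect_equal(m2$t1, m1$t1, tolerance = 1e-8)
  expect_equal(m2$a, 2.5 * m1$a, tolerance = 1e-8)
  expect_equal(m2$b, 2.5 * m1$b, tolerance = 1e-8)
})

test_that("MOLLI fit applies the Look-Locker correction", {
  ti <- default_ti_list()
  # B = 2A: corrected T1 equals T1*
  m <- fit_molli(ti, 1000 - 2000 * exp(-ti / 250), polarity_known = TRUE)
  expect_equal(m$t1_star, 250, tolerance = 1e-4)
  expect_equal(m$t1, 250, tolerance = 1e-4)
  # B/A = 1.8: T1 = 250 * 0.8 = 200
  m2 <- fit_molli(ti, 1000 - 1800 * exp(-ti / 250), polarity_known = TRUE)
  expect_equal(m2$t1, 200, tolerance = 1e-4)
  expect_equal(m2$b / m2$a, 1.8, tolerance = 1e-4)
  # B/A <= 1 is physically invalid
  m3 <- fit_molli(ti, 1000 - 800 * exp(-ti / 250), polarity_known = TRUE)
  expect_false(m3$converged)
  expect_true(is.na(m3$t1))
  expect_error(fit_molli(ti, rep(3, 11)), "degenerate")
})

test_that("magnitude polarity restoration agrees with the exhaustive signed oracle", {
  ti <- default_ti_list()
  for (t1_true in c(148, 250, 524, 900, 1526)) {
    mag <- abs(1000 - 2000 * exp(-ti / t1_true))
    fit <- fit_molli(ti, mag)
    expect_true(fit$converged)
    expect_equal(fit$t1, t1_true, tolerance = 1e-3)
    oracle <- oracle_molli_polarity(ti, mag)
    expect_equal(fit$t1, unname(oracle$t1), tolerance = 1e-3)
    expect_equal(fit$polarity_flip_index, oracle$flip)
  }
  # with noise the two routes still pick the same flip and similar T1
  withr::with_seed(5, {
    mag <- abs(1000 - 2000 * exp(-ti / 300) + rnorm(11, sd = 10))
    fit <- fit_molli(ti, mag)
    oracle <- oracle_molli_polarity(ti, mag)
    expect_equal(fit$polarity_flip_index, oracle$flip)
    expect_equal(fit$t1, unname(oracle$t1), tolerance = 1e-3)
  })
})

test_that("pixelwise maps round-trip the phantom and respect the mask", {
  ph <- make_phantom(phantom_truth(noise_sd = 0), seed = 1)
  res <- phantom_relaxivity(ph)
  expect_equal(res$vial_t1$t1, ph$manifest$t1_true, tolerance = 1e-3)

  # single-pixel mask
  mask1 <- matrix(FALSE, dim(ph$images)[1], dim(ph$images)[2])
  mask1[ph$vial_masks[[1]][1]] <- TRUE
  map1 <- fit_t1_map(ph$images, ph$tr_list, mask = mask1)
  expect_equal(sum(!is.na(map1$t1)), 1L)
  expect_error(fit_t1_map(ph$images, ph$tr_list,
                          mask = mask1 & !mask1), "empty")
})

test_that("map error shrinks when noise halves", {
  err <- vapply(c(0.04, 0.02), function(ns) {
    ph <- make_phantom(phantom_truth(noise_sd = ns), seed = 31)
    res <- phantom_relaxivity(ph)
    median(abs(res$vial_t1$t1 - ph$manifest$t1_true) / ph$manifest$t1_true)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("ROI means use only valid pixels", {
  t1 <- matrix(1011, 4, 4)
  conv <- matrix(TRUE, 4, 4)
  map <- structure(list(t1 = t1, residual = matrix(0, 4, 4),
                        converged = conv, mask = matrix(TRUE, 4, 4),
                        mode = "molli"), class = "t1_map")
  roi <- matrix(TRUE, 4, 4)
  expect_equal(roi_mean_t1(map, roi)$mean, 1011)

  map$t1[1:8] <- 99
  map$converged[1:8] <- FALSE
  est <- roi_mean_t1(map, roi)
  expect_equal(est$mean, 1011)
  expect_equal(est$n_pixels, 8L)

  map$converged[] <- FALSE
  expect_error(roi_mean_t1(map, roi), "valid")
})
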