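test_that("the bolus model honours its boundary and peak identities", {
  expect_equal(gammaVariate(1, t0 = 1, alpha = 3, beta = 1), 0)
  expect_equal(gammaVariate(0.5, t0 = 1, alpha = 3, beta = 1), 0)
  # continuity at t0
  expect_lt(gammaVariate(1 + 1e-9, t0 = 1, alpha = 2, beta = 1), 1e-12)
  # peak at t0 + alpha*beta with the closed-form value
  expect_equal(gammaVariate(3, 0, 3, 1), 27 * exp(-3), tolerance = 1e-12)
  expect_equal(gammaVariate(3, 0, 3, 1), 1.3443, tolerance = 1e-4)
  tgrid <- seq(0, 12, by = 1e-3)
  expect_equal(tgrid[which.max(gammaVariate(tgrid, 1, 2.5, 0.9, K = 2))],
               1 + 2.5 * 0.9, tolerance = 1e-3)
  expect_error(gammaVariate(1, 0, -1, 1), "alpha")
  expect_error(gammaVariate(1, 0, 2, 0), "beta")
})

test_that("FWHM matches the dense-grid oracle and obeys the scale law", {
  expect_equal(computeFWHM(alpha = 3, beta = 1), fwhmNumericOracle(3, 1),
               tolerance = 1e-6)
  expect_equal(computeFWHM(alpha = 3, beta = 1), 4.13, tolerance = 1e-2)
  expect_equal(computeFWHM(alpha = 1.5, beta = 2),
               fwhmNumericOracle(1.5, 2), tolerance = 1e-6)
  f1 <- computeFWHM(alpha = 2.7, beta = 1.3)
  for (c in c(0.5, 2, 10))
    expect_equal(computeFWHM(alpha = 2.7, beta = c * 1.3) / (c * f1), 1,
                 tolerance = 1e-9)
})

test_that("FWHM is invariant to amplitude and baseline", {
  ts <- buildTimeGrid(defaultSchedule())
  base <- new("TDC", timestamps = ts,
              density = gammaVariate(ts, 1, 3, 0.8, K = 2),
              label = "x", nPixels = 1L)
  shifted <- new("TDC", timestamps = ts,
                 density = gammaVariate(ts, 1, 3, 0.8, K = 9, baseline = 4),
                 label = "x", nPixels = 1L)
  expect_equal(fitGammaVariate(base)@fwhm, fitGammaVariate(shifted)@fwhm,
               tolerance = 1e-6)
})

test_that("exact curves on the clinical grid are recovered within 1%", {
  ts <- buildTimeGrid(defaultSchedule())
  truth <- list(t0 = 1, alpha = 3, beta = 0.8, K = 2)
  tdc <- new("TDC", timestamps = ts,
             density = gammaVariate(ts, truth$t0, truth$alpha, truth$beta,
                                    truth$K),
             label = "capillary", nPixels = 100L)
  fit <- fitGammaVariate(tdc)
  expect_equal(fit@t0, truth$t0, tolerance = 0.01)
  expect_equal(fit@alpha, truth$alpha, tolerance = 0.01)
  expect_equal(fit@beta, truth$beta, tolerance = 0.01)
  expect_equal(fit@K, truth$K, tolerance = 0.01)
  expect_gt(fit@rSquared, 0.9999)
  # analytic TTP identity of the returned object
  expect_lt(abs(fit@ttp - (fit@t0 + fit@alpha * fit@beta)), 1e-9)
})

test_that("noisy fits keep the median FWHM error within 5%", {
  ts <- buildTimeGrid(defaultSchedule())
  clean <- gammaVariate(ts, 1, 3, 0.8, K = 2)
  trueF <- computeFWHM(alpha = 3, beta = 0.8)
  errs <- vapply(1:100, function(s) {
    y <- clean + withr::with_seed(4000 + s,
                                  rnorm(length(ts), 0, 0.05 * max(clean)))
    fit <- tryCatch(suppressWarnings(
      fitGammaVariate(new("TDC", timestamps = ts, density = y,
                          label = "x", nPixels = 1L))),
      error = function(e) NULL)
    if (is.null(fit)) NA_real_ else abs(fit@fwhm - trueF) / trueF
  }, 0)
  expect_lt(mean(is.na(errs)), 0.05)
  expect_lte(median(errs, na.rm = TRUE), 0.05)
})

test_that("flat, all-zero or monotone curves fail loudly", {
  ts <- buildTimeGrid(defaultSchedule())
  zero <- new("TDC", timestamps = ts, density = numeric(length(ts)),
              label = "x", nPixels = 1L)
  expect_error(fitGammaVariate(zero), "fit")
  rising <- new("TDC", timestamps = ts, density = ts^2, label = "x",
                nPixels = 1L)
  expect_error(fitGammaVariate(rising), "rising")
  short <- new("TDC", timestamps = 0:3 / 2, density = c(0, 1, 2, 1),
               label = "x", nPixels = 1L)
  expect_error(fitGammaVariate(short), "at least 8")
})

test_that("TTP follows the argmax/fitted contract with tie handling", {
  tdc <- new("TDC", timestamps = c(0, 0.5, 1.0, 1.5),
             density = c(0, 1, 5, 2), label = "x", nPixels = 1L)
  expect_equal(computeTTP(tdc), 1.0)
  tie <- new("TDC", timestamps = c(0, 0.5, 1.0, 1.5),
             density = c(0, 5, 5, 2), label = "x", nPixels = 1L)
  expect_warning(tp <- computeTTP(tie), "earliest")
  expect_equal(tp, 0.5)
  ts <- buildTimeGrid(defaultSchedule())
  exact <- new("TDC", timestamps = ts,
               density = gammaVariate(ts, 1, 3, 0.8, K = 2),
               label = "x", nPixels = 1L)
  expect_equal(computeTTP(exact, method = "fitted"), 1 + 3 * 0.8,
               tolerance = 1e-4)
  flat <- new("TDC", timestamps = ts, density = rep(2, length(ts)),
              label = "x", nPixels = 1L)
  expect_error(computeTTP(flat), "constant")
})

test_that("two distinguishable peaks are detected, single peaks are not", {
  ts <- seq(0, 12, by = 0.2)
  single <- gammaVariate(ts, 1, 3, 1.2)
  expect_false(dsaflow:::hasTwoPeaks(single))
  mixed <- gammaVariate(ts, 0.5, 3, 0.35, K = 8) +
    gammaVariate(ts, 3.5, 3, 1.0, K = 0.4)
  expect_true(dsaflow:::hasTwoPeaks(mixed))
})
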