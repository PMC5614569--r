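test_that("aMTT on the easy phantom recovers the 5 s capillary FWHM", {
  ph <- generatePhantom(standardPhantom("easy", seed = 42))
  expect_equal(unname(ph$truth$fwhm["capillary"]), 5, tolerance = 1e-9)
  entry <- computeAMTT(ph$series, seed = 1)
  expect_true(entry$valid)
  expect_gte(entry$aMTT_s, 4.75)
  expect_lte(entry$aMTT_s, 5.25)
  expect_equal(entry$view, "LAT")
  # intermediates are all retrievable for audit
  expect_s4_class(entry$components, "ComponentSet")
  expect_s4_class(entry$masks$capillary, "VesselMask")
  expect_s4_class(entry$tdcs$capillary, "TDC")
  expect_s4_class(entry$fit, "GammaVariateFit")
})

test_that("aMTT is deterministic for a fixed seed", {
  ph <- generatePhantom(standardPhantom("easy", seed = 9, shape = c(64, 64),
                                        noiseSigma = 0.05))
  a <- suppressWarnings(computeAMTT(ph$series, seed = 11))
  b <- suppressWarnings(computeAMTT(ph$series, seed = 11))
  expect_identical(a$aMTT_s, b$aMTT_s)
  expect_identical(timeCourses(a$components), timeCourses(b$components))
})

test_that("a series without a capillary blush is flagged invalid, not fatal", {
  art <- CompartmentSpec("arterial",
                         list(polylineGeom(rbind(c(0.2, 0.8), c(0.4, 0.3),
                                                 c(0.7, 0.2)), 0.04)),
                         dsaflow:::kineticsFor(2, 3, 0.45, 1))
  spec <- PhantomSpec(shape = c(64L, 64L), compartments = list(art),
                      seed = 3L)
  ph <- generatePhantom(spec)
  entry <- suppressWarnings(computeAMTT(ph$series, seed = 2,
                                        register = FALSE))
  expect_false(isTRUE(entry$valid) && length(entry$warnings) == 0)
  expect_true(is.list(entry))
})

test_that("the stenosis-like stress phantom completes with a usable outcome", {
  ph <- generatePhantom(standardPhantom("severe_stenosis_like", seed = 1))
  # the stress condition: arterial and capillary courses strongly correlated
  expect_gte(cor(ph$truth$courses[, "arterial"],
                 ph$truth$courses[, "capillary"]), 0.7)
  entry <- suppressWarnings(computeAMTT(ph$series, seed = 2))
  flagged <- length(entry$warnings) > 0 || !entry$valid ||
    (!is.null(entry$fit) && entry$fit@rSquared < 0.8)
  accurate <- entry$valid && abs(entry$aMTT_s - 5) <= 0.25
  expect_true(flagged || accurate)
})

test_that("CCT is the venous-minus-arterial TTP difference on ROIs", {
  ph <- generatePhantom(cctPhantomSpec())
  res <- computeCCT(ph$series, latCCTROIs())
  truthDiff <- unname(ph$truth$ttp["venous"] - ph$truth$ttp["arterial"])
  expect_equal(truthDiff, 4.87, tolerance = 1e-9)
  # within one local frame interval of the truth
  ts <- timePoints(ph$series)
  localDt <- max(diff(ts)[findInterval(c(res@ttpArtery, res@ttpVein), ts)])
  expect_lte(abs(res@cct - truthDiff), localDt + 1e-9)
  expect_equal(res@cct, res@ttpVein - res@ttpArtery)
  # the fitted variant lands even closer
  resF <- computeCCT(ph$series, latCCTROIs(), method = "fitted")
  expect_lte(abs(resF@cct - truthDiff), 0.1)
})

test_that("identical ROIs give zero CCT; contract violations raise", {
  ph <- generatePhantom(cctPhantomSpec())
  same <- new("ROISet", regions = list(
    cavernous_ICA = latCCTROIs()@regions$cavernous_ICA,
    parietal_vein = latCCTROIs()@regions$cavernous_ICA))
  expect_equal(computeCCT(ph$series, same)@cct, 0)
  expect_error(computeCCT(ph$series,
                          new("ROISet", regions = latCCTROIs()@regions[1])),
               "parietal_vein")
  oob <- new("ROISet", regions = list(
    cavernous_ICA = list(type = "polygon",
                         xy = cbind(c(100, 200, 200), c(10, 10, 40))),
    parietal_vein = latCCTROIs()@regions$parietal_vein))
  expect_error(computeCCT(ph$series, oob), "outside")
  ap <- ph$series; ap@view <- "AP"
  expect_warning(computeCCT(ap, latCCTROIs()), "lateral")
})

test_that("marker correlations match known structure", {
  x <- 1:10
  out <- correlateMarkers(data.frame(a = x, b = 2 * x + 1))
  expect_equal(out$r["a", "b"], 1, tolerance = 1e-12)
  expect_true(out$pairs$significant[1])
  withr::with_seed(77, {
    big <- data.frame(x = rnorm(1000), y = rnorm(1000))
    expect_lt(abs(correlateMarkers(big)$r["x", "y"]), 0.1)
  })
  const <- correlateMarkers(data.frame(a = x, b = rep(3, 10), c = rev(x)))
  expect_true(is.na(const$r["a", "b"]))
  expect_equal(const$r["a", "c"], -1, tolerance = 1e-12)
  expect_error(correlateMarkers(data.frame(a = x)), "two numeric")
})

test_that("identical runs produce byte-identical reports", {
  ph <- generatePhantom(standardPhantom("easy", seed = 5, shape = c(64, 64)))
  paths <- vapply(1:2, function(i) {
    entry <- computeAMTT(ph$series, seed = 3)
    rep <- makeReport(list(LAT = entry), seed = 3L, inputs = "phantom",
                      parameters = list(max_iter = 500L, tol = 1e-4))
    f <- file.path(withr::local_tempdir(.local_envir = parent.frame(2)),
                   paste0("rep", i, ".json"))
    writeReport(rep, f)
    f
  }, "")
  expect_identical(readLines(paths[1]), readLines(paths[2]))
})
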