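test_that("a jitter-free compartment reproduces its analytic curve exactly", {
  cap <- CompartmentSpec("capillary", list(ellipseGeom(0.5, 0.5, 0.25, 0.3)),
                         dsaflow:::kineticsFor(4.5, 3, 1.2, 0.5))
  spec <- PhantomSpec(shape = c(64L, 64L), compartments = list(cap),
                      seed = 1L)
  ph <- generatePhantom(spec)
  tdc <- extractTDC(ph$series, ph$truth$regions$capillary, label = "cap")
  k <- ph$truth$kinetics$capillary
  expected <- gammaVariate(timePoints(ph$series), k$t0, k$alpha, k$beta, k$K)
  expect_equal(tdc@density, expected, tolerance = 1e-9)
})

test_that("phantom generation is bit-identical for a fixed seed", {
  a <- generatePhantom(standardPhantom("easy", seed = 42, noiseSigma = 0.05))
  b <- generatePhantom(standardPhantom("easy", seed = 42, noiseSigma = 0.05))
  expect_identical(frames(a$series), frames(b$series))
  c <- generatePhantom(standardPhantom("easy", seed = 43, noiseSigma = 0.05))
  expect_false(identical(frames(a$series), frames(c$series)))
})

test_that("the standard capillary kinetics put the FWHM at exactly 5 s", {
  spec <- standardPhantom("easy", seed = 1)
  kin <- spec@compartments[[2]]@kinetics
  expect_equal(kin$alpha, 3)
  expect_equal(kin$beta, 5 / 4.131213, tolerance = 1e-4)
  expect_equal(computeFWHM(alpha = kin$alpha, beta = kin$beta), 5,
               tolerance = 1e-9)
  tt <- generatePhantom(spec)$truth
  expect_equal(unname(tt$ttp), c(2, 4.5, 7))
})

test_that("noise in a contrast-free corner matches the requested sigma", {
  ph <- generatePhantom(standardPhantom("easy", seed = 11,
                                        noiseSigma = 0.05))
  corner <- frames(ph$series)[, 113:128, 113:128]   # > 15000 samples
  expect_false(any(ph$truth$regions$arterial[113:128, 113:128] |
                     ph$truth$regions$capillary[113:128, 113:128] |
                     ph$truth$regions$venous[113:128, 113:128]))
  expect_equal(sd(corner), 0.05 * ph$truth$peak, tolerance = 0.1)
})

test_that("every standard phantom carries one compartment per phase", {
  for (nm in c("easy", "overlap", "severe_stenosis_like", "motion")) {
    spec <- standardPhantom(nm, seed = 2)
    expect_setequal(vapply(spec@compartments, function(x) x@phase, ""),
                    c("arterial", "capillary", "venous"))
    ph <- generatePhantom(spec)
    expect_equal(nFrames(ph$series), 60L)
  }
  expect_error(standardPhantom("nope", seed = 1))
})

test_that("motion phantoms move and motionless phantoms do not", {
  pm <- generatePhantom(standardPhantom("motion", seed = 3))
  disp <- vapply(pm$truth$motion, meanDisplacement, 0)
  expect_gt(max(disp), 2)
  expect_lte(max(vapply(pm$truth$motion, function(x) abs(x@dx), 0)), 5)
  expect_lte(max(vapply(pm$truth$motion, function(x) abs(x@rotation), 0)), 2)
  expect_length(generatePhantom(standardPhantom("easy", seed = 3))$truth$motion,
                0L)
})

test_that("registration improves aMTT on the motion phantom (ablation)", {
  ph <- generatePhantom(standardPhantom("motion", seed = 3))
  withReg <- computeAMTT(ph$series, seed = 1)
  withoutReg <- computeAMTT(ph$series, seed = 1, register = FALSE)
  errWith <- abs(withReg$aMTT_s - 5)
  errWithout <- abs(withoutReg$aMTT_s - 5)
  expect_lte(errWith, errWithout)
  expect_lte(errWith, 0.25)
})

test_that("out-of-bounds compartments are rejected", {
  bad <- CompartmentSpec("arterial",
                         list(ellipseGeom(1.8, 1.8, 0.05, 0.05)),
                         dsaflow:::kineticsFor(2, 3, 0.45, 1))
  spec <- PhantomSpec(shape = c(64L, 64L), compartments = list(bad),
                      seed = 1L)
  expect_error(generatePhantom(spec), "empty region")
})

test_that("phantom specs round-trip through YAML", {
  y <- list(
    shape = c(48L, 48L),
    schedule = list(rates = c(4, 2), durations = c(2, 2)),
    noise_sigma = 0.02,
    view = "AP",
    seed = 6L,
    compartments = list(
      list(phase = "arterial", jitter = 0.1,
           kinetics = list(t0 = 0.6, alpha = 3, beta = 0.45, K = 10),
           geometry = list(list(type = "polyline", width = 0.05,
                                points = list(c(0.2, 0.8), c(0.5, 0.3))))),
      list(phase = "capillary",
           kinetics = list(t0 = 0.9, alpha = 3, beta = 1.2, K = 0.3),
           geometry = list(list(type = "ellipse", cx = 0.6, cy = 0.6,
                                rx = 0.2, ry = 0.25)))))
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(y, f)
  spec <- phantomSpecFromYAML(f)
  expect_equal(spec@shape, c(48L, 48L))
  expect_equal(spec@noiseSigma, 0.02)
  expect_equal(spec@view, "AP")
  expect_length(spec@compartments, 2L)
  expect_equal(spec@compartments[[2]]@kinetics$beta, 1.2)
  ph <- generatePhantom(spec)
  expect_equal(dim(ph$series), c(12L, 48L, 48L))
  # seed override
  expect_equal(phantomSpecFromYAML(f, seed = 99L)@seed, 99L)
  yaml::write_yaml(list(standard = "easy", seed = 2L), f)
  expect_length(phantomSpecFromYAML(f)@compartments, 3L)
  yaml::write_yaml(list(shape = c(32L, 32L)), f)
  expect_error(phantomSpecFromYAML(f), "compartment")
})
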