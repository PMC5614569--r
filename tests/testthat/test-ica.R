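test_that("flattening uses row-major pixel order and inverts exactly", {
  arr <- array(seq_len(3 * 2 * 2), c(3, 2, 2))
  s <- DSASeries(array(rnorm(3 * 16 * 16), c(3, 16, 16)), c(0, 0.5, 1))
  m <- flattenSeries(s)
  expect_equal(dim(m), c(3L, 256L))
  # 0-based entry (1, 2) is pixel (row 1, col 0) of frame 1
  expect_equal(m[2, 17], frames(s)[2, 2, 1])
  expect_equal(m[1, 2], frames(s)[1, 1, 2])
  H <- 16; W <- 16
  for (t in 1:3)
    expect_identical(unflattenMap(m[t, ], H, W), frames(s)[t, , ])
  # constant frame -> constant row
  s2 <- DSASeries(array(rep(c(0, 7, 1), 256), c(3, 16, 16)), c(0, 0.5, 1))
  expect_equal(unique(flattenSeries(s2)[2, ]), 7)
})

test_that("noiseless rank-3 mixtures are recovered almost exactly", {
  mix <- rank3Mixture()
  cs <- fixSigns(decomposeSeries(mix$x, seed = 3, frameDim = mix$dim))
  rec <- timeCourses(cs)
  for (k in 1:3) {
    rbest <- max(abs(cor(mix$courses[, k], rec)))
    expect_gte(rbest, 0.99)
  }
  # reconstruction: courses x maps explain the row-centred data
  Xr <- mix$x - rowMeans(mix$x)
  mapsFlat <- t(apply(spatialMaps(cs), 1, t))  # back to row-major vectors
  mapsFlat <- vapply(1:3, function(k)
    as.vector(t(spatialMaps(cs)[k, , ])), numeric(ncol(mix$x)))
  recon <- rec %*% t(mapsFlat)
  expect_lt(norm(Xr - recon, "F") / norm(Xr, "F"), 0.05)
})

test_that("decomposition is bit-reproducible for a fixed seed", {
  mix <- rank3Mixture()
  a <- decomposeSeries(mix$x, seed = 42, frameDim = mix$dim)
  b <- decomposeSeries(mix$x, seed = 42, frameDim = mix$dim)
  expect_identical(timeCourses(a), timeCourses(b))
  expect_identical(spatialMaps(a), spatialMaps(b))
})

test_that("rank-deficient data is flagged, not fatal", {
  course <- gammaVariate(seq(0, 10, length.out = 30), 1, 3, 1)
  x <- course %*% t(runif(16 * 16))
  expect_warning(cs <- decomposeSeries(x, seed = 1, frameDim = c(16, 16)),
                 "rank")
  expect_false(cs@converged)
  expect_equal(ncol(timeCourses(cs)), 3L)
})

test_that("input contracts are enforced", {
  expect_error(decomposeSeries(matrix(rnorm(4), 2, 2), seed = 1,
                               frameDim = c(1, 2)), "at least as many")
  expect_error(decomposeSeries(matrix(c(1, NA, 2, 3, 1, 0), 3), seed = 1,
                               frameDim = c(1, 2)), "finite")
  expect_error(decomposeSeries(matrix(rnorm(20), 4), seed = 1), "frameDim")
})

test_that("sign fixing enforces positive peaks and preserves reconstruction", {
  courses <- cbind(c(0, -5, -1), c(0, 5, 1), c(1, -2, 3))
  maps <- array(rnorm(3 * 16 * 16), c(3, 16, 16))
  cs <- new("ComponentSet", timeCourses = courses, spatialMaps = maps,
            phaseLabels = rep("unassigned", 3), timestamps = c(0, 1, 2),
            converged = TRUE, iterations = 1L, tol = 1e-4, seed = 1L)
  fixed <- fixSigns(cs)
  expect_equal(timeCourses(fixed)[, 1], c(0, 5, 1))
  expect_equal(spatialMaps(fixed)[1, , ], -maps[1, , ])
  expect_equal(timeCourses(fixed)[, 2], c(0, 5, 1))      # untouched
  expect_identical(spatialMaps(fixed)[2, , ], maps[2, , ])
  for (k in 1:3) {
    before <- courses[, k] %o% as.vector(maps[k, , ])
    after <- timeCourses(fixed)[, k] %o% as.vector(spatialMaps(fixed)[k, , ])
    expect_identical(before, after)
  }
})

test_that("phases are assigned by TTP order with energy tie-breaks", {
  ts <- seq(0, 10, length.out = 21)
  mkcs <- function(ttps, energies) {
    courses <- vapply(ttps, function(tp) exp(-(ts - tp)^2), numeric(21))
    maps <- array(0, c(3, 16, 16))
    for (k in 1:3) maps[k, k, ] <- sqrt(energies[k] / 16)
    new("ComponentSet", timeCourses = courses, spatialMaps = maps,
        phaseLabels = rep("unassigned", 3), timestamps = ts,
        converged = TRUE, iterations = 1L, tol = 1e-4, seed = 1L)
  }
  lab <- assignPhases(mkcs(c(7.0, 2.0, 4.5), c(1, 1, 1)))
  expect_equal(phaseLabels(lab), c("arterial", "capillary", "venous"))
  expect_equal(ts[apply(timeCourses(lab), 2, which.max)], c(2.0, 4.5, 7.0))
  # tie on TTP: larger map energy takes the earlier phase
  tie <- assignPhases(mkcs(c(3.0, 3.0, 6.0), c(5, 10, 1)))
  expect_equal(which.max(spatialMaps(tie)[1, , 1] != 0), 2L)
  expect_warning(assignPhases(mkcs(c(3, 3, 6), c(2, 2, 1))), "tie")
})

test_that("easy-phantom compartments are recovered and labelled correctly", {
  ph <- generatePhantom(standardPhantom("easy", seed = 42))
  cs <- assignPhases(fixSigns(decomposeSeries(ph$series, seed = 1)))
  for (phase in c("arterial", "capillary", "venous")) {
    r <- cor(getComponent(cs, phase)$course, ph$truth$courses[, phase])
    expect_gte(abs(r), 0.99)
  }
})

test_that("overlapping compartments (about 20%) still separate", {
  ph <- generatePhantom(standardPhantom("overlap", seed = 8))
  ra <- ph$truth$regions$arterial; rc <- ph$truth$regions$capillary
  frac <- sum(ra & rc) / sum(ra)
  expect_gt(frac, 0.1); expect_lt(frac, 0.25)
  cs <- assignPhases(fixSigns(decomposeSeries(ph$series, seed = 2)))
  for (phase in c("arterial", "capillary", "venous"))
    expect_gte(abs(cor(getComponent(cs, phase)$course,
                       ph$truth$courses[, phase])), 0.99)
})

test_that("time-course CSV export is labelled by phase", {
  ph <- generatePhantom(standardPhantom("easy", seed = 2, shape = c(32, 32)))
  cs <- assignPhases(fixSigns(decomposeSeries(ph$series, seed = 1)))
  f <- withr::local_tempfile(fileext = ".csv")
  writeTimeCourses(cs, f)
  d <- read.csv(f)
  expect_equal(names(d), c("t_s", "arterial", "capillary", "venous"))
  expect_equal(nrow(d), nFrames(ph$series))
})
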