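# Shared fixtures: all built in code at test time.

# Easy-phantom ROIs for CCT: a box on the arterial trunk and one on the
# venous channel of the LAT layout (0-based pixel coordinates).
latCCTROIs <- function() {
  new("ROISet", regions = list(
    cavernous_ICA = list(type = "polygon",
                         xy = cbind(c(12, 26, 26, 12), c(55, 55, 75, 75))),
    parietal_vein = list(type = "polygon",
                         xy = cbind(c(70, 82, 82, 70), c(8, 8, 18, 18)))))
}

# Easy phantom whose venous TTP is moved to 6.87 s so the ground-truth
# venous-minus-arterial TTP difference equals the cohort-average CCT.
cctPhantomSpec <- function(seed = 5L) {
  sp <- standardPhantom("easy", seed = seed)
  sp@compartments[[3]]@kinetics <-
    dsaflow:::kineticsFor(6.87, alpha = 3, beta = 0.8, amp = 0.8)
  sp
}

# Noiseless rank-3 mixture with known smooth courses and sparse disjoint
# maps (each source occupies ~5% of the pixels, like vessels in a frame),
# for direct decomposition tests.
rank3Mixture <- function(T = 40, H = 48, W = 48, seed = 99) {
  withr::with_seed(seed, {
    ts <- seq(0, 10, length.out = T)
    kin <- list(dsaflow:::kineticsFor(1.7, 3, 0.4, 1.0),
                dsaflow:::kineticsFor(4.3, 3, 1.1, 0.6),
                dsaflow:::kineticsFor(6.1, 3, 0.7, 0.8))
    courses <- vapply(kin, function(k)
      gammaVariate(ts, k$t0, k$alpha, k$beta, k$K), numeric(T))
    P <- H * W
    maps <- matrix(0, 3, P)
    blocks <- list(1:120, 301:420, 601:720)
    for (k in 1:3) maps[k, blocks[[k]]] <- runif(length(blocks[[k]]), 0.5, 1.5)
    x <- courses %*% maps
    list(x = x, ts = ts, courses = courses, maps = maps, dim = c(H, W))
  })
}

# A minimal valid series wrapping given frames on a uniform grid.
seriesFromFrames <- function(arr, dt = 0.25, view = "LAT") {
  DSASeries(arr, seq(0, by = dt, length.out = dim(arr)[1]), view = view)
}

# Exhaustive-search Otsu oracle: tries every candidate bin edge and
# maximizes between-class variance computed from the raw values.
otsuBruteForce <- function(values, nBins = 256L) {
  lo <- min(values); hi <- max(values)
  width <- (hi - lo) / nBins
  edges <- lo + seq_len(nBins - 1L) * width
  n <- length(values)
  bc <- vapply(edges, function(e) {
    a <- values[values < e]; b <- values[values >= e]
    if (!length(a) || !length(b)) return(-Inf)
    (length(a) / n) * (length(b) / n) * (mean(a) - mean(b))^2
  }, 0)
  edges[which.max(bc)]
}

meanDisplacement <- function(tf, H = 128, W = 128) {
  g <- expand.grid(x = seq(0, W - 1, by = 8), y = seq(0, H - 1, by = 8))
  p <- dsaflow:::applyTransform(tf, g$x, g$y, H, W)
  mean(sqrt((p$x - g$x)^2 + (p$y - g$y)^2))
}

# Residual displacement of estimated-then-true motion per frame.
registrationResiduals <- function(regResult, truth) {
  vapply(seq_along(regResult$transforms), function(i) {
    comp <- dsaflow:::composeTransforms(regResult$transforms[[i]],
                                        truth$motion[[i + 1L]])
    meanDisplacement(comp)
  }, 0)
}

# Dense-grid numeric FWHM oracle: sample the curve finely and interpolate
# the half-maximum crossings linearly. Independent of the bisection path.
fwhmNumericOracle <- function(alpha, beta, n = 2e6) {
  t <- seq(0, 40 * beta * max(alpha, 1), length.out = n)
  y <- gammaVariate(t, 0, alpha, beta)
  half <- max(y) / 2
  above <- y >= half
  i1 <- which(above)[1]
  i2 <- tail(which(above), 1)
  crossAt <- function(i) {
    t[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
  }
  crossAt(i2 + 1) - crossAt(i1)
}

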