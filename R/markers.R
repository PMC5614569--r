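# End-to-end hemodynamic markers: the angiographic mean transit time (aMTT,
# the FWHM of the automatically extracted capillary-phase TDC) and the
# cerebral circulation time (CCT, the TTP difference between a parietal-vein
# ROI and a cavernous carotid ROI on a lateral view).

#' Angiographic mean transit time of one view
#'
#' Runs the full automatic pipeline on a series: motion correction,
#' temporal FastICA into three phases, sign fixing and TTP-ordered phase
#' labelling, Otsu vessel masking of the capillary map, capillary TDC
#' extraction from the registered series, gamma-variate fitting, and the
#' FWHM of the fitted curve. All intermediates are returned for audit.
#'
#' A warning is raised (and recorded) when the capillary TDC shows two
#' distinguishable peaks -- the signature of stagnant arterial flow leaking
#' into the capillary component at severe stenosis. A capillary fit failure
#' flags the entry invalid instead of raising.
#'
#' @param series a [DSASeries-class].
#' @param seed integer seed for the ICA start (required; the only stochastic
#'   stage).
#' @param register run keypoint motion correction first (default TRUE; the
#'   decomposition always consumes the registered series).
#' @param maxIter,tol FastICA iteration cap and tolerance.
#' @param otsuBins histogram bins for the Otsu cuts.
#' @param minMatches keypoint matches required per frame during registration.
#' @return A list ("aMTT entry"): \code{view}, \code{aMTT_s}, \code{valid},
#'   \code{fit} ([GammaVariateFit-class] or NULL), \code{components}
#'   ([ComponentSet-class]), \code{masks} (list of [VesselMask-class] per
#'   phase), \code{tdcs} (list of [TDC-class] per phase), \code{transforms},
#'   \code{warnings} (character).
#' @export
computeAMTT <- function(series, seed, register = TRUE, maxIter = 500L,
                        tol = 1e-4, otsuBins = 256L, minMatches = 8L) {
  stopifnot(is(series, "DSASeries"))
  if (missing(seed)) stop("an explicit seed is required (ICA initialization)")
  notes <- character()
  note <- function(w) {
    notes <<- c(notes, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  transforms <- list()
  reg <- series
  if (register) {
    r <- withCallingHandlers(registerSeries(series, minMatches = minMatches),
                             warning = note)
    reg <- r$series
    transforms <- r$transforms
  }

  comp <- withCallingHandlers(
    assignPhases(fixSigns(decomposeSeries(reg, seed = seed,
                                          maxIter = maxIter, tol = tol))),
    warning = note)

  phases <- c("arterial", "capillary", "venous")
  masks <- list(); tdcs <- list()
  for (ph in phases) {
    mk <- withCallingHandlers(
      makeMask(getComponent(comp, ph)$map, ph, nBins = otsuBins),
      warning = note)
    masks[[ph]] <- mk
    if (!mk@degenerate) tdcs[[ph]] <- extractTDC(reg, mk)
  }

  out <- list(view = series@view, aMTT_s = NA_real_, valid = FALSE,
              fit = NULL, components = comp, masks = masks, tdcs = tdcs,
              transforms = transforms, warnings = notes)
  capTDC <- tdcs[["capillary"]]
  if (is.null(capTDC)) {
    out$warnings <- c(out$warnings,
                      "capillary mask degenerate; aMTT flagged invalid")
    return(out)
  }
  if (hasTwoPeaks(capTDC@density)) {
    msg <- paste("capillary TDC shows two distinguishable peaks;",
                 "possible arterial admixture (severe stenosis pattern)")
    warning(msg, call. = FALSE)
    out$warnings <- c(out$warnings, msg)
  }
  fit <- withCallingHandlers(
    tryCatch(fitGammaVariate(capTDC), error = function(e) e),
    warning = note)
  if (inherits(fit, "error")) {
    out$warnings <- c(out$warnings,
                      paste("capillary fit failure:", conditionMessage(fit)))
    return(out)
  }
  out$fit <- fit
  out$aMTT_s <- fit@fwhm
  out$valid <- TRUE
  out$warnings <- notes
  out
}

#' Cerebral circulation time from manual ROIs
#'
#' Extracts a TDC per ROI and returns
#' \code{CCT = TTP(parietal_vein) - TTP(cavernous_ICA)}. The ROI set must
#' contain regions labelled \code{"cavernous_ICA"} and
#' \code{"parietal_vein"}; the measurement is defined on a lateral view (an
#' AP series is processed with a warning). A negative CCT warns.
#'
#' @param series a [DSASeries-class] (lateral view).
#' @param rois an [ROISet-class].
#' @param method TTP method: "argmax" (manual-workflow default) or "fitted".
#' @return A [CCTResult-class].
#' @export
computeCCT <- function(series, rois, method = c("argmax", "fitted")) {
  method <- match.arg(method)
  stopifnot(is(series, "DSASeries"), is(rois, "ROISet"))
  need <- c("cavernous_ICA", "parietal_vein")
  missing <- setdiff(need, names(rois@regions))
  if (length(missing))
    stop("ROI set lacks required label(s): ", paste(missing, collapse = ", "))
  if (series@view == "AP")
    warning("CCT is defined on a lateral angiogram; computing on an AP view",
            call. = FALSE)
  d <- dim(series@frames)
  tdcA <- extractTDC(series, roiMask(rois, "cavernous_ICA", d[2], d[3]),
                     label = "cavernous_ICA")
  tdcV <- extractTDC(series, roiMask(rois, "parietal_vein", d[2], d[3]),
                     label = "parietal_vein")
  ttpA <- computeTTP(tdcA, method = method)
  ttpV <- computeTTP(tdcV, method = method)
  cct <- ttpV - ttpA
  if (cct < 0)
    warning("negative CCT (venous peak before arterial peak)", call. = FALSE)
  res <- new("CCTResult", ttpArtery = ttpA, ttpVein = ttpV, cct = cct,
             method = method)
  attr(res, "tdcs") <- list(cavernous_ICA = tdcA, parietal_vein = tdcV)
  res
}

setMethod("show", "CCTResult", function(object) {
  cat(sprintf("CCT: %.3f s (TTP vein %.3f s - TTP artery %.3f s, %s)\n",
              object@cct, object@ttpVein, object@ttpArtery, object@method))
})

#' Pairwise Pearson correlations among cohort markers
#'
#' For each pair of numeric columns with at least 3 complete cases, Pearson
#' r and its two-sided p-value; pairs are flagged significant at p < 0.05
#' (raw p-values, no multiplicity correction). Zero-variance columns yield
#' missing entries for their pairs.
#'
#' @param table data.frame of per-case marker values (e.g. stenosis
#'   percentage, CCT, aMTT per view, perfusion parameters).
#' @return list with matrices \code{r}, \code{p}, \code{n} and a long-format
#'   data.frame \code{pairs} (var1, var2, r, p, n, significant).
#' @export
correlateMarkers <- function(table) {
  table <- as.data.frame(table)
  num <- vapply(table, is.numeric, TRUE)
  table <- table[num]
  v <- names(table)
  k <- length(v)
  if (k < 2L) stop("need at least two numeric marker columns")
  r <- p <- matrix(NA_real_, k, k, dimnames = list(v, v))
  n <- matrix(0L, k, k, dimnames = list(v, v))
  diag(r) <- 1
  pairs <- NULL
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    ok <- stats::complete.cases(table[[i]], table[[j]])
    n[i, j] <- n[j, i] <- sum(ok)
    rij <- pij <- NA_real_
    if (sum(ok) >= 3L &&
        stats::sd(table[[i]][ok]) > 0 && stats::sd(table[[j]][ok]) > 0) {
      ct <- stats::cor.test(table[[i]][ok], table[[j]][ok],
                            method = "pearson")
      rij <- unname(ct$estimate); pij <- ct$p.value
    }
    r[i, j] <- r[j, i] <- rij
    p[i, j] <- p[j, i] <- pij
    pairs <- rbind(pairs, data.frame(
      var1 = v[i], var2 = v[j], r = rij, p = pij, n = sum(ok),
      significant = !is.na(pij) & pij < 0.05))
  }
  list(r = r, p = p, n = n, pairs = pairs)
}

#' Assemble a marker report
#'
#' @param views named list of aMTT entries from [computeAMTT()], keyed
#'   "AP"/"LAT".
#' @param cct optional [CCTResult-class].
#' @param correlations optional pairs data.frame from [correlateMarkers()].
#' @param seed seed used for the run.
#' @param inputs character vector of input identifiers.
#' @param parameters list of run parameters echoed for reproducibility.
#' @return A [MarkerReport-class].
#' @export
makeReport <- function(views, cct = NULL, correlations = NULL,
                       seed = NA_integer_, inputs = character(),
                       parameters = list()) {
  for (v in names(views)) {
    e <- views[[v]]
    if (!is.na(e$aMTT_s) && (!is.finite(e$aMTT_s) || e$aMTT_s < 0))
      stop("reported aMTT must be finite and >= 0")
  }
  new("MarkerReport", views = views, cct = cct, correlations = correlations,
      provenance = list(
        software = "dsaflow",
        version = as.character(utils::packageVersion("dsaflow")),
        seed = seed, inputs = as.list(inputs), parameters = parameters))
}

setMethod("show", "MarkerReport", function(object) {
  cat("MarkerReport\n")
  for (v in names(object@views)) {
    e <- object@views[[v]]
    cat(sprintf("  aMTT_%s: %s\n", ifelse(v == "LAT", "Lat", v),
                if (isTRUE(e$valid)) sprintf("%.3f s", e$aMTT_s)
                else "invalid"))
  }
  if (!is.null(object@cct)) cat(sprintf("  CCT: %.3f s\n", object@cct@cct))
  cat(sprintf("  seed: %s\n", object@provenance$seed))
})
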