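#' Matching tolerances for cross-sample peptide matching
#'
#' @param massRel relative mass tolerance (default 1e-4, i.e. +/- 100
#'   ppm).
#' @param timeAbs absolute migration-time tolerance in min (default 0.5).
#' @return list with components `massRel`, `timeAbs`.
#' @export
matchTolerances <- function(massRel = 1e-4, timeAbs = 0.5) {
  if (massRel <= 0 || timeAbs <= 0)
    stopf("tolerances must be > 0")
  list(massRel = massRel, timeAbs = timeAbs)
}

## Match reference standards into one sample's raw peaks by mass
## (nearest within massRel); returns row indices into `peaks` (NA = no
## match).
.matchStandards <- function(peaks, standards, massRel) {
  vapply(seq_len(nrow(standards)), function(k) {
    m <- standards$mass[k]
    d <- abs(peaks$mass - m) / m
    j <- which.min(d)
    if (length(j) && d[j] <= massRel) j else NA_integer_
  }, integer(1))
}

#' Normalize migration time and intensity against internal standards
#'
#' For every sample, reference standards are located in the raw peaks by
#' mass (nearest match within `massRel`). The migration-time map
#' `t_norm = a * t_raw + b` is the least-squares line from observed to
#' reference standard times, and the intensity factor `s` is the median of
#' reference/observed intensity ratios over matched standards. All of the
#' sample's peaks are then transformed. Samples matching fewer than
#' `minStandards` standards are excluded and reported in the calibration
#' record with `calibrated = FALSE`.
#'
#' @param object a [PeakSet-class] of raw samples.
#' @param standards reference standard table (`mass`, `time`,
#'   `intensity`), e.g. [referenceStandards()].
#' @param massRel relative mass tolerance for standard matching.
#' @param minStandards minimum matched standards per sample (>= 2;
#'   default 3).
#' @return list with `peaks` (calibrated [PeakSet-class], failed samples
#'   dropped) and `records` (data.frame: `sampleId`, `a`, `b`, `s`,
#'   `nStandards`, `residualRmse`, `calibrated`).
#' @export
calibrateSamples <- function(object, standards = referenceStandards(),
                             massRel = 1e-4, minStandards = 3) {
  stopifnot(is(object, "PeakSet"))
  if (minStandards < 2) stopf("minStandards must be >= 2")
  assertColumns(standards, c("mass", "time", "intensity"),
                "standards table")
  ids <- sampleIds(object)
  allPeaks <- peakTable(object)
  recs <- vector("list", length(ids))
  outPeaks <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    p <- allPeaks[allPeaks$sampleId == ids[i], , drop = FALSE]
    hit <- .matchStandards(p, standards, massRel)
    ok <- !is.na(hit)
    if (sum(ok) < minStandards) {
      warnf("sample '%s': only %d of %d standards matched; excluded",
            ids[i], sum(ok), nrow(standards))
      recs[[i]] <- data.frame(sampleId = ids[i], a = NA_real_,
                              b = NA_real_, s = NA_real_,
                              nStandards = sum(ok),
                              residualRmse = NA_real_, calibrated = FALSE)
      next
    }
    obsT <- p$time[hit[ok]]
    refT <- standards$time[ok]
    fit <- lm(refT ~ obsT)
    a <- unname(coef(fit)[2]); b <- unname(coef(fit)[1])
    if (!is.finite(a) || a <= 0) {
      warnf("sample '%s': degenerate time calibration; excluded", ids[i])
      recs[[i]] <- data.frame(sampleId = ids[i], a = NA_real_,
                              b = NA_real_, s = NA_real_,
                              nStandards = sum(ok),
                              residualRmse = NA_real_, calibrated = FALSE)
      next
    }
    s <- median(standards$intensity[ok] / p$intensity[hit[ok]])
    rmse <- sqrt(mean((a * obsT + b - refT)^2))
    p$time <- a * p$time + b
    p$intensity <- s * p$intensity
    recs[[i]] <- data.frame(sampleId = ids[i], a = a, b = b, s = s,
                            nStandards = sum(ok), residualRmse = rmse,
                            calibrated = TRUE)
    outPeaks[[i]] <- p
  }
  records <- do.call(rbind, recs)
  keep <- records$sampleId[records$calibrated]
  peaks <- do.call(rbind, outPeaks[!vapply(outPeaks, is.null, logical(1))])
  if (is.null(peaks)) peaks <- allPeaks[0, , drop = FALSE]
  samp <- sampleData(object)
  ps <- PeakSet(peaks, samp[samp$sampleId %in% keep, , drop = FALSE],
                tkvSeries(object)[tkvSeries(object)$sampleId %in% keep, ,
                                  drop = FALSE])
  list(peaks = ps, records = records)
}

#' Match calibrated peaks across samples into a consensus peptide catalog
#'
#' Pools all peaks, sorts them by mass and clusters them in a single
#' greedy pass: a peak joins the open cluster whose intensity-weighted
#' centroid is nearest in mass among those within `massRel` (relative
#' mass) and `timeAbs` (absolute migration time); otherwise it opens a
#' new cluster. At most one peak per sample enters a cluster (the most
#' intense wins; conflicts are counted in the result metadata). Consensus
#' mass/time per peptide are intensity-weighted means of the retained
#' members; matrix entries are the matched peak intensities, with 0
#' encoding "not detected".
#'
#' @param object a calibrated [PeakSet-class].
#' @param tolerances a [matchTolerances()] list.
#' @return A [PeptideExperiment-class]; peptide ids are assigned in
#'   consensus-mass order.
#' @export
matchPeptides <- function(object, tolerances = matchTolerances()) {
  stopifnot(is(object, "PeakSet"))
  p <- peakTable(object)
  ids <- sampleIds(object)
  if (!nrow(p)) {
    m <- matrix(numeric(), 0, length(ids),
                dimnames = list(character(), ids))
    return(PeptideExperiment(m, data.frame(peptideId = character(),
                                           mass = numeric(),
                                           time = numeric()),
                             sampleData(object), tolerances))
  }
  o <- order(p$mass, p$time, p$intensity, p$sampleId)
  p <- p[o, , drop = FALSE]
  sampCode <- match(p$sampleId, ids)
  cl <- .greedyCluster(p$mass, p$time, p$intensity, sampCode,
                       tolerances$massRel, tolerances$timeAbs)
  keep <- cl$kept
  kid <- cl$clusterId[keep]
  kp <- p[keep, , drop = FALSE]
  sumI <- rowsum(kp$intensity, kid)
  consMass <- rowsum(kp$intensity * kp$mass, kid) / sumI
  consTime <- rowsum(kp$intensity * kp$time, kid) / sumI
  count <- as.integer(rowsum(rep(1L, nrow(kp)), kid))
  ## stable peptide ids in consensus-mass (then time) order
  ord <- order(consMass, consTime)
  pid <- sprintf("C%05d", seq_along(ord))
  rank <- integer(length(ord)); rank[ord] <- seq_along(ord)
  catalog <- data.frame(peptideId = pid,
                        mass = as.numeric(consMass)[ord],
                        time = as.numeric(consTime)[ord],
                        detectionCount = count[ord],
                        stringsAsFactors = FALSE)
  m <- matrix(0, nrow(catalog), length(ids),
              dimnames = list(pid, ids))
  rowIdx <- rank[match(kid, sort(unique(kid)))]
  m[cbind(rowIdx, match(kp$sampleId, ids))] <- kp$intensity
  PeptideExperiment(m, catalog, sampleData(object),
                    c(tolerances, conflicts = cl$conflicts))
}
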