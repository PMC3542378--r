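#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the inputs and applies the step-up false-discovery-rate
#' adjustment: for the i-th smallest of m p-values,
#' `adj(i) = min over j >= i of min(1, (m/j) * p(j))`, with the result
#' returned in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order as `p`.
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(!is.finite(p) | p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

## Midrank Mann-Whitney AUC of `x[case]` vs `x[!case]`, all samples.
.mwAuc <- function(x, case) {
  r <- rank(x)
  n1 <- sum(case); n0 <- sum(!case)
  (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-peptide differential excretion statistics
#'
#' For each catalog peptide, compares the two diagnosis groups:
#' detection frequency per group; fold change = mean case intensity /
#' mean control intensity over *all* samples (zeros included, the
#' regulation-factor convention); a two-sample Welch statistic on the
#' natural-log intensities of *detected* samples referred to the standard
#' normal for the p-value; Benjamini-Hochberg adjusted p; and the
#' midrank Mann-Whitney AUC over all samples. Only peptides detected in
#' at least `minFreq` of one group, with at least 2 detected values per
#' group, are testable; the rest carry `p = 1` and `testable = FALSE`.
#'
#' @param object a [PeptideExperiment-class].
#' @param labels per-sample group labels (defaults to the diagnosis
#'   column); exactly two groups.
#' @param caseLabel which label is the case group (default `"ADPKD"` when
#'   present, else the rarer label).
#' @param minFreq candidacy detection-frequency threshold (default 0.3).
#' @param auc compute the per-peptide Mann-Whitney AUC (default TRUE;
#'   disable for large screening sweeps where only p-values matter).
#' @return data.frame, one row per peptide: `peptideId`, `freqCase`,
#'   `freqControl`, `foldChange`, `pRaw`, `pBh`, `auc`, `direction`,
#'   `testable`.
#' @export
differentialStats <- function(object, labels = diagnosisLabels(object),
                              caseLabel = NULL, minFreq = 0.3,
                              auc = TRUE) {
  M <- intensityMatrix(object)
  labels <- as.character(labels)
  grp <- unique(labels)
  if (length(grp) != 2L)
    stopf("exactly two groups are required (got: %s)",
          paste(grp, collapse = ", "))
  if (is.null(caseLabel))
    caseLabel <- if ("ADPKD" %in% grp) "ADPKD" else
      grp[which.min(tabulate(match(labels, grp)))]
  case <- labels == caseLabel
  n1 <- sum(case); n0 <- sum(!case)
  if (n1 < 2L || n0 < 2L) stopf("each group needs n >= 2")

  det <- M > 0
  d1 <- rowSums(det[, case, drop = FALSE])
  d0 <- rowSums(det[, !case, drop = FALSE])
  freq1 <- d1 / n1
  freq0 <- d0 / n0

  mean1 <- rowMeans(M[, case, drop = FALSE])
  mean0 <- rowMeans(M[, !case, drop = FALSE])
  fold <- ifelse(mean0 > 0, mean1 / mean0, NA_real_)

  ## Welch z on ln intensities of detected samples only
  lnM <- suppressWarnings(log(M))
  lnM[!det] <- NA
  ln1 <- lnM[, case, drop = FALSE]; ln0 <- lnM[, !case, drop = FALSE]
  m1 <- rowMeans(ln1, na.rm = TRUE); m0 <- rowMeans(ln0, na.rm = TRUE)
  v1 <- rowSums((ln1 - m1)^2, na.rm = TRUE) / pmax(d1 - 1, 1)
  v0 <- rowSums((ln0 - m0)^2, na.rm = TRUE) / pmax(d0 - 1, 1)
  se <- sqrt(v1 / pmax(d1, 1) + v0 / pmax(d0, 1))
  z <- (m1 - m0) / se

  testable <- (pmax(freq1, freq0) >= minFreq) & d1 >= 2 & d0 >= 2 &
    is.finite(z)
  pRaw <- rep(1, nrow(M))
  pRaw[testable] <- 2 * pnorm(-abs(z[testable]))

  aucVal <- rep(NA_real_, nrow(M))
  if (auc)
    for (j in which(testable)) aucVal[j] <- .mwAuc(M[j, ], case)

  pBh <- rep(1, nrow(M))
  if (any(testable)) pBh[testable] <- bhAdjust(pRaw[testable])

  data.frame(peptideId = rownames(M), freqCase = freq1,
             freqControl = freq0, foldChange = fold, pRaw = pRaw,
             pBh = pBh, auc = aucVal,
             direction = ifelse(is.na(fold) | fold >= 1, "up", "down"),
             testable = testable, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Select significant markers
#'
#' @param stats result of [differentialStats()].
#' @param qThreshold adjusted-significance threshold (default 0.05).
#' @return character vector of peptide ids with `pBh < qThreshold` among
#'   testable peptides, ordered by ascending adjusted p.
#' @export
selectMarkers <- function(stats, qThreshold = 0.05) {
  assertColumns(stats, c("peptideId", "pBh", "testable"), "marker stats")
  ## qThreshold >= 1 is the "no filter" boundary: every testable peptide
  sel <- stats$testable & (stats$pBh < qThreshold | qThreshold >= 1)
  hit <- stats[sel, , drop = FALSE]
  hit$peptideId[order(hit$pBh, hit$peptideId)]
}
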