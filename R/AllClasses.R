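#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## Analyzed mass window of the CE-MS peptidome (Da). Peaks outside are
## instrument artefacts and are rejected at the container boundary.
.MASS_WINDOW <- c(800, 20000)

#' PeakSet: deconvolved CE-MS peak lists for a cohort of urine samples
#'
#' A `PeakSet` holds one cohort of deconvolved peak lists — one record per
#' detected peptide ion with monoisotopic mass (Da), CE migration time
#' (min, on the normalized 18-45 scale) and signal intensity (arbitrary
#' units, strictly positive) — together with per-sample clinical metadata
#' and an optional long-format table of serial total-kidney-volume (TKV)
#' measurements.
#'
#' Peaks are kept in canonical order (sample, then mass, then time) so that
#' equal cohorts compare identical regardless of input file ordering.
#'
#' @slot peaks data.frame with columns `sampleId`, `mass`, `time`,
#'   `intensity`.
#' @slot samples data.frame of per-sample metadata; must contain `sampleId`
#'   (unique) and `diagnosis`, and may carry `age`, `sex`, `genotype`,
#'   `height`, `egfr`.
#' @slot tkv data.frame with columns `sampleId`, `timeYears`, `tkvMl`
#'   (possibly empty).
#' @export
setClass("PeakSet",
  representation(peaks = "data.frame", samples = "data.frame",
                 tkv = "data.frame"))

setValidity("PeakSet", function(object) {
  p <- object@peaks
  msg <- character()
  need <- c("sampleId", "mass", "time", "intensity")
  if (!all(need %in% names(p)))
    return(paste("peaks must have columns", paste(need, collapse = ", ")))
  if (nrow(p)) {
    if (any(p$mass <= .MASS_WINDOW[1] | p$mass >= .MASS_WINDOW[2]))
      msg <- c(msg, sprintf("all masses must lie in (%g, %g) Da",
                            .MASS_WINDOW[1], .MASS_WINDOW[2]))
    if (any(p$intensity <= 0))
      msg <- c(msg, "all intensities must be > 0")
  }
  s <- object@samples
  if (!all(c("sampleId", "diagnosis") %in% names(s)))
    msg <- c(msg, "samples must have columns sampleId, diagnosis")
  else if (anyDuplicated(s$sampleId))
    msg <- c(msg, "sample ids must be unique within a cohort")
  if (nrow(object@tkv) &&
      !all(c("sampleId", "timeYears", "tkvMl") %in% names(object@tkv)))
    msg <- c(msg, "tkv must have columns sampleId, timeYears, tkvMl")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' CohortConfig: parameters of the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated CE-MS case/control
#' cohort: catalog size, planted diagnostic markers (signed fold changes,
#' mostly down-regulated as observed for urinary collagen fragments),
#' planted peptides tied to a latent disease-severity axis correlated with
#' ln height-adjusted TKV, per-peptide detection frequencies, log-scale
#' intensity noise, a fixed internal-standard panel, and per-sample
#' migration-time/intensity drift.
#'
#' @slot nCases,nControls cohort sizes (defaults 41 and 189, the training
#'   design emulated throughout).
#' @slot nPeptides catalog size (default 5000).
#' @slot nStandards number of internal-standard peptides (default 29).
#' @slot fracMarkers fraction of peptides with a planted case/control
#'   effect (default 0.12).
#' @slot fracDown fraction of planted markers that are down-regulated
#'   (default 0.8).
#' @slot foldRange multiplicative effect range, low > 1 (default 1.5-6;
#'   folds drawn log-uniformly).
#' @slot detectFreqShape Beta(shape1, shape2) parameters of the per-peptide
#'   detection frequency (default c(3, 1.5)).
#' @slot logIntensitySd dispersion of ln intensity (default 0.5).
#' @slot nSeverityPeptides peptides tied to the severity axis (default 99).
#' @slot severityRTarget correlation magnitude between the latent severity
#'   axis and ln htTKV (default 0.6).
#' @slot loadingRange per-peptide loading range on the severity axis, in
#'   units of `logIntensitySd` (default 2-4, calibrated so that
#'   observed per-peptide screening correlations fall in the 0.25-0.45
#'   range reported for real htTKV-associated peptides).
#' @slot fracSeverityNegative fraction of severity loadings that are
#'   negative (default 0.7, the collagen-dominated direction).
#' @slot tkvLognormal c(meanlog, sdlog) of the TKV (ml) distribution;
#'   defaults target mean 1078, sd 647 ml.
#' @slot heightRange body height range in m (default 1.5-2.0).
#' @slot drift list with ranges `timeShift` (min), `timeScale`,
#'   `intensityScale`; each sample draws one value per component.
#' @slot massJitterPpm per-peak mass measurement noise, ppm sd (default 10).
#' @slot timeJitterSd per-peak migration-time noise, min sd (default 0.05).
#' @slot seed master RNG seed.
#' @export
setClass("CohortConfig",
  representation(nCases = "integer", nControls = "integer",
                 nPeptides = "integer", nStandards = "integer",
                 fracMarkers = "numeric", fracDown = "numeric",
                 foldRange = "numeric", detectFreqShape = "numeric",
                 logIntensitySd = "numeric",
                 nSeverityPeptides = "integer", severityRTarget = "numeric",
                 loadingRange = "numeric", fracSeverityNegative = "numeric",
                 tkvLognormal = "numeric", heightRange = "numeric",
                 drift = "list", massJitterPpm = "numeric",
                 timeJitterSd = "numeric", seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  fr <- c(object@fracMarkers, object@fracDown, object@fracSeverityNegative)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
  if (object@nCases < 0L || object@nControls < 0L ||
      object@nPeptides <= 0L || object@nStandards <= 0L)
    msg <- c(msg, "counts must be positive")
  if (length(object@foldRange) != 2L || object@foldRange[1] <= 1)
    msg <- c(msg, "foldRange must be c(low, high) with low > 1")
  if (object@foldRange[2] < object@foldRange[1])
    msg <- c(msg, "foldRange must be non-decreasing")
  if (object@nSeverityPeptides > object@nPeptides)
    msg <- c(msg, "nSeverityPeptides cannot exceed nPeptides")
  if (object@logIntensitySd <= 0) msg <- c(msg, "logIntensitySd must be > 0")
  if (abs(object@severityRTarget) > 1)
    msg <- c(msg, "severityRTarget must lie in [-1, 1]")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' CohortTruth: planted ground truth of a synthetic cohort
#'
#' Records everything the generator planted so that downstream stages can
#' be scored against truth: signed fold change per diagnostic marker,
#' severity-axis loading per severity peptide, per-sample drift parameters,
#' the internal-standard reference panel, per-case htTKV, and the
#' drift-free normalized intensity matrix (peptides x samples, 0 = not
#' detected).
#'
#' @slot peptides data.frame: `peptideId`, `mass`, `time`, `baseline`
#'   (ln-intensity), `detectProb`.
#' @slot markers data.frame: `peptideId`, `fold`, `direction`.
#' @slot severity data.frame: `peptideId`, `loading`.
#' @slot drift data.frame: `sampleId`, `timeShift`, `timeScale`,
#'   `intensityScale`.
#' @slot standards data.frame: `standardId`, `mass`, `time`, `intensity`.
#' @slot httkv named numeric, htTKV (ml/m) per case sample.
#' @slot matrix numeric matrix, peptides x samples, pre-drift intensities.
#' @slot config the generating [CohortConfig-class].
#' @export
setClass("CohortTruth",
  representation(peptides = "data.frame", markers = "data.frame",
                 severity = "data.frame", drift = "data.frame",
                 standards = "data.frame", httkv = "numeric",
                 matrix = "matrix", config = "CohortConfig"))

#' PeptideExperiment: consensus peptide catalog with per-sample intensities
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] derivative holding
#' the cross-sample consensus peptide catalog. Rows are consensus peptides
#' (rowData: `mass`, `time`, `detectionCount`), columns are samples
#' (colData: diagnosis and clinical covariates), and the single
#' `"intensity"` assay stores normalized signal intensities with 0 encoding
#' "peptide not detected in that sample". Matching tolerances are kept in
#' `metadata()` for provenance.
#'
#' @export
setClass("PeptideExperiment", contains = "SummarizedExperiment")

setValidity("PeptideExperiment", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    return("assay 'intensity' is required")
  a <- SummarizedExperiment::assay(object, "intensity")
  if (nrow(a) && any(a < 0)) msg <- c(msg, "intensities must be >= 0")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("mass", "time") %in% names(rd)))
    msg <- c(msg, "rowData must contain 'mass' and 'time'")
  if (nrow(object) &&
      (is.null(rownames(object)) || anyDuplicated(rownames(object))))
    msg <- c(msg, "peptide ids (rownames) must be present and unique")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' DiagnosticModel: RBF-SVM diagnostic score over a peptide marker panel
#'
#' The fitted diagnostic classifier: the marker panel, the per-feature
#' transform (ln(1+x), then min-max constants learned on training samples
#' only), the RBF-kernel support-vector machine (cost C, kernel width
#' gamma, support set), the kernel-space norm of the separating direction
#' used to convert decision values into margin distances, the
#' cross-validated scores the operating cutoff was chosen on, and the
#' cutoff itself.
#'
#' @slot markerIds character, the feature panel.
#' @slot featureMin,featureMax named numeric, min-max scaling constants on
#'   the ln(1+x) scale (training samples only).
#' @slot fit the underlying support-vector machine fit.
#' @slot flip logical; TRUE when the raw decision value must be negated so
#'   that cases score high.
#' @slot wNorm kernel-space norm of the separating direction (> 0).
#' @slot cost,gamma selected RBF-SVM hyperparameters.
#' @slot cvAuc cross-validated AUC at the selected hyperparameters.
#' @slot cvScores named numeric, cross-validated margin scores per training
#'   sample (the basis for cutoff selection).
#' @slot cutoff operating score threshold (NA until chosen).
#' @slot caseLabel,controlLabel the two class labels.
#' @export
setClass("DiagnosticModel",
  representation(markerIds = "character", featureMin = "numeric",
                 featureMax = "numeric", fit = "ANY", flip = "logical",
                 wNorm = "numeric", cost = "numeric", gamma = "numeric",
                 cvAuc = "numeric", cvScores = "numeric", cutoff = "numeric",
                 caseLabel = "character", controlLabel = "character"))

setValidity("DiagnosticModel", function(object) {
  msg <- character()
  if (length(object@wNorm) && !is.na(object@wNorm) && object@wNorm <= 0)
    msg <- c(msg, "wNorm must be > 0")
  if (length(object@featureMin) != length(object@markerIds) ||
      length(object@featureMax) != length(object@markerIds))
    msg <- c(msg, "scaling constants must match the marker panel")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' SeverityModel: rank-screened linear predictor of htTKV
#'
#' Peptides surviving the Spearman screen against height-adjusted total
#' kidney volume, their screening correlations, and the coefficients of the
#' linear model (on standardized ln(1+intensity)) that combines them into a
#' severity score. When the design is ill-conditioned or wide, the fit is
#' ridge-penalized with the penalty chosen by generalized cross-validation;
#' `lambda = 0` marks a plain least-squares fit.
#'
#' @slot peptideIds character, screened peptide panel.
#' @slot screeningR named numeric, Spearman r per panel peptide.
#' @slot center,scale named numeric, standardization constants (ln(1+x)
#'   scale, training samples only).
#' @slot intercept,weights the affine combination.
#' @slot lambda ridge penalty used (0 = ordinary least squares).
#' @slot method "ridge", "ols" or "signed-sum".
#' @slot trainingCor named numeric: Pearson and Spearman correlation of
#'   fitted vs observed htTKV on the training samples.
#' @export
setClass("SeverityModel",
  representation(peptideIds = "character", screeningR = "numeric",
                 center = "numeric", scale = "numeric",
                 intercept = "numeric", weights = "numeric",
                 lambda = "numeric", method = "character",
                 trainingCor = "numeric"))

setValidity("SeverityModel", function(object) {
  msg <- character()
  if (length(object@weights) != length(object@peptideIds))
    msg <- c(msg, "one weight per screened peptide is required")
  if (length(object@lambda) && object@lambda < 0)
    msg <- c(msg, "lambda must be >= 0")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
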