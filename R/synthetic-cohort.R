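#' Configure a synthetic CE-MS cohort
#'
#' Builds a [CohortConfig-class] with defaults emulating the statistical
#' structure of a urinary-peptidome case/control study: a 41-case /
#' 189-control training design, a catalog of 5000 detectable peptides with
#' Beta-distributed per-peptide detection frequencies, ~12% planted
#' diagnostic markers of which 80% are down-regulated (the
#' collagen-fragment-dominated direction), 99 peptides loading on a latent
#' severity axis correlated with ln htTKV, a 29-peptide internal-standard
#' panel, log-normal total kidney volume targeting mean 1078 / sd 647 ml,
#' and per-sample migration-time and intensity drift.
#'
#' @param nCases,nControls cohort sizes.
#' @param nPeptides,nStandards catalog and internal-standard panel sizes.
#' @param fracMarkers,fracDown,foldRange planted diagnostic effect:
#'   fraction of peptides affected, fraction down-regulated, and the
#'   multiplicative fold range (log-uniform draw).
#' @param detectFreqShape Beta(shape1, shape2) of detection frequency.
#' @param logIntensitySd sd of ln intensity around the peptide baseline.
#' @param nSeverityPeptides,severityRTarget,loadingRange,fracSeverityNegative
#'   planted severity structure; see [CohortConfig-class].
#' @param tkvLognormal c(meanlog, sdlog) for TKV in ml.
#' @param heightRange body height range (m).
#' @param drift list of per-sample drift ranges: `timeShift` (min),
#'   `timeScale`, `intensityScale`; use [noDrift()] to disable.
#' @param massJitterPpm,timeJitterSd per-peak measurement noise.
#' @param seed master RNG seed; identical (config, seed) yields identical
#'   cohorts.
#' @return A validated [CohortConfig-class].
#' @export
#' @examples
#' cfg <- cohortConfig(nCases = 10, nControls = 20, nPeptides = 200,
#'                     seed = 1)
#' cohort <- generateCohort(cfg)
cohortConfig <- function(nCases = 41, nControls = 189, nPeptides = 5000,
                         nStandards = 29, fracMarkers = 0.12,
                         fracDown = 0.8, foldRange = c(1.5, 6),
                         detectFreqShape = c(3, 1.5),
                         logIntensitySd = 0.5, nSeverityPeptides = 99,
                         severityRTarget = 0.6, loadingRange = c(2, 4),
                         fracSeverityNegative = 0.7,
                         tkvLognormal = c(meanlog = 6.829, sdlog = 0.5545),
                         heightRange = c(1.5, 2.0),
                         drift = list(timeShift = c(-2, 2),
                                      timeScale = c(0.97, 1.03),
                                      intensityScale = c(0.7, 1.4)),
                         massJitterPpm = 10, timeJitterSd = 0.05,
                         seed = 1L) {
  new("CohortConfig", nCases = as.integer(nCases),
      nControls = as.integer(nControls), nPeptides = as.integer(nPeptides),
      nStandards = as.integer(nStandards), fracMarkers = fracMarkers,
      fracDown = fracDown, foldRange = as.numeric(foldRange),
      detectFreqShape = as.numeric(detectFreqShape),
      logIntensitySd = logIntensitySd,
      nSeverityPeptides = as.integer(nSeverityPeptides),
      severityRTarget = severityRTarget,
      loadingRange = as.numeric(loadingRange),
      fracSeverityNegative = fracSeverityNegative,
      tkvLognormal = as.numeric(tkvLognormal),
      heightRange = as.numeric(heightRange), drift = drift,
      massJitterPpm = massJitterPpm, timeJitterSd = timeJitterSd,
      seed = as.integer(seed))
}

#' Drift ranges that disable per-sample distortion
#' @return a list usable as the `drift` argument of [cohortConfig()].
#' @export
noDrift <- function() list(timeShift = c(0, 0), timeScale = c(1, 1),
                           intensityScale = c(1, 1))

#' Reference internal-standard panel
#'
#' A deterministic panel of "housekeeping" peptides spread over the
#' analyzed mass and migration-time window, used both by the generator
#' (standards are spiked into every sample at reference intensity) and by
#' the calibration stage as the reference list.
#'
#' @param n panel size.
#' @return data.frame with `standardId`, `mass`, `time`, `intensity`.
#' @export
referenceStandards <- function(n = 29) {
  k <- seq_len(n)
  phi <- (sqrt(5) - 1) / 2
  data.frame(standardId = sprintf("IS%02d", k),
             mass = round(exp(seq(log(900), log(15000), length.out = n)), 4),
             time = round(19 + 25 * ((k * phi) %% 1), 3),
             intensity = 800 + 150 * (k %% 7),
             stringsAsFactors = FALSE)
}

.drawUnif <- function(n, range) if (diff(range) == 0) rep(range[1], n) else
  runif(n, range[1], range[2])

## Core simulation shared by matrix- and peak-level representations.
## Draw order is fixed so that truth is reproducible from (config, seed).
.simulateTruth <- function(config) {
  P <- config@nPeptides
  n <- config@nCases + config@nControls
  sid <- c(sprintf("ADPKD%03d", seq_len(config@nCases)),
           sprintf("CTRL%03d", seq_len(config@nControls)))
  caseIdx <- seq_len(config@nCases)
  pid <- sprintf("P%05d", seq_len(P))

  peptides <- data.frame(
    peptideId = pid,
    mass = exp(runif(P, log(850), log(19000))),
    time = runif(P, 18.5, 44.5),
    baseline = rnorm(P, mean = 6, sd = 1),
    detectProb = rbeta(P, config@detectFreqShape[1],
                       config@detectFreqShape[2]),
    stringsAsFactors = FALSE)

  nMark <- round(config@fracMarkers * P)
  markIds <- sort(sample.int(P, nMark))
  fold <- exp(runif(nMark, log(config@foldRange[1]),
                    log(config@foldRange[2])))
  down <- runif(nMark) < config@fracDown
  markers <- data.frame(peptideId = pid[markIds], fold = fold,
                        direction = ifelse(down, "down", "up"),
                        stringsAsFactors = FALSE)

  sevPool <- setdiff(seq_len(P), markIds)
  nSev <- min(config@nSeverityPeptides, length(sevPool))
  sevIds <- sort(sample(sevPool, nSev))
  loadMag <- runif(nSev, config@loadingRange[1], config@loadingRange[2]) *
    config@logIntensitySd
  neg <- runif(nSev) < config@fracSeverityNegative
  severity <- data.frame(peptideId = pid[sevIds],
                         loading = ifelse(neg, -loadMag, loadMag),
                         stringsAsFactors = FALSE)
  ## severity peptides are consistently detected: rank screening of
  ## sparsely detected peptides is dominated by zero ties, and real
  ## htTKV-associated panels come from frequently observed peptides
  peptides$detectProb[sevIds] <- pmax(peptides$detectProb[sevIds], 0.8)

  ## clinical metadata
  height <- .drawUnif(n, config@heightRange)
  age <- pmin(80, pmax(16, c(rnorm(config@nCases, 32.4, 8.7),
                             rnorm(config@nControls, 37, 15))))
  sex <- ifelse(runif(n) < 0.5, "F", "M")
  genotype <- c(sample(c("PKD1", "PKD2", "none"), config@nCases,
                       replace = TRUE, prob = c(0.781, 0.138, 0.071)),
                rep("none", config@nControls))
  egfr <- c(rnorm(config@nCases, 89.1, 27.8),
            rnorm(config@nControls, 105, 15))

  ## kidney volume: log-normal TKV, htTKV = TKV / height; annual series
  tkv0 <- rlnorm(config@nCases, config@tkvLognormal[1],
                 config@tkvLognormal[2])
  httkv <- setNames(tkv0 / height[caseIdx], sid[caseIdx])
  growth <- rnorm(config@nCases, 0.05, 0.025)
  tkvNoise <- matrix(rnorm(config@nCases * 3, 0, 0.02), config@nCases, 3)
  tkv <- do.call(rbind, lapply(seq_len(config@nCases), function(i) {
    yrs <- 0:3
    vol <- tkv0[i] * (1 + growth[i])^yrs *
      exp(c(0, tkvNoise[i, ]))
    data.frame(sampleId = sid[i], timeYears = yrs, tkvMl = vol,
               stringsAsFactors = FALSE)
  }))

  ## latent severity axis: correlated severityRTarget with ln htTKV in
  ## cases; the per-peptide loadings then cap the achievable model
  ## correlation at that target
  rho <- config@severityRTarget
  u <- numeric(n)
  if (config@nCases > 1) {
    z <- as.numeric(scale(log(httkv)))
    u[caseIdx] <- rho * z + sqrt(max(0, 1 - rho^2)) *
      rnorm(config@nCases)
  }

  ## ln-intensity model: peptide baseline + case effect + severity axis +
  ## Gaussian noise; detection independent Bernoulli per (peptide, sample)
  ci <- as.numeric(seq_len(n) %in% caseIdx)
  eff <- numeric(P)
  eff[markIds] <- ifelse(down, -log(fold), log(fold))
  lv <- numeric(P)
  lv[sevIds] <- severity$loading
  L <- matrix(rnorm(P * n, 0, config@logIntensitySd), P, n)
  L <- L + peptides$baseline + eff %o% ci + lv %o% u
  D <- matrix(runif(P * n), P, n) < peptides$detectProb
  M <- exp(L)
  M[!D] <- 0
  dimnames(M) <- list(pid, sid)

  drift <- data.frame(
    sampleId = sid,
    timeShift = .drawUnif(n, config@drift$timeShift),
    timeScale = .drawUnif(n, config@drift$timeScale),
    intensityScale = exp(.drawUnif(n, log(config@drift$intensityScale))),
    stringsAsFactors = FALSE)

  samples <- data.frame(
    sampleId = sid,
    diagnosis = c(rep("ADPKD", config@nCases),
                  rep("healthy", config@nControls)),
    age = age, sex = sex, genotype = genotype,
    height = height, egfr = egfr, stringsAsFactors = FALSE)

  truth <- new("CohortTruth", peptides = peptides, markers = markers,
               severity = severity, drift = drift,
               standards = referenceStandards(config@nStandards),
               httkv = httkv, matrix = M, config = config)
  list(truth = truth, samples = samples, tkv = tkv)
}

#' Generate a synthetic cohort of CE-MS peak lists with ground truth
#'
#' Simulates per-sample deconvolved peak lists under the generator model
#' described in [cohortConfig()]: each catalog peptide is present in a
#' sample with its detection probability; ln intensity is Gaussian around
#' a peptide baseline, shifted by the planted ln fold in cases for marker
#' peptides and by the latent severity axis for severity peptides;
#' internal standards are present in every sample at reference intensity;
#' finally each sample's peaks are distorted by its drawn drift
#' (time shift/scale, intensity scale) plus small per-peak mass/time
#' measurement noise (standards drift but are not jittered, as befits
#' high-abundance calibrants).
#'
#' @param config a [CohortConfig-class].
#' @param representation `"peaks"` (full peak lists; default) or
#'   `"matrix"` (skip peak assembly when only the drift-free intensity
#'   matrix is needed — identical truth, much faster).
#' @return list with elements `peaks` (a [PeakSet-class]; NULL under
#'   `"matrix"`) and `truth` (a [CohortTruth-class]).
#' @export
generateCohort <- function(config,
                           representation = c("peaks", "matrix")) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  representation <- match.arg(representation)
  sim <- withSeed(config@seed, .simulateTruth(config))
  truth <- sim$truth
  if (representation == "matrix")
    return(list(peaks = NULL, truth = truth, samples = sim$samples,
                tkv = sim$tkv))

  peaks <- withSeed(childSeed(config@seed, 2L), {
    M <- truth@matrix
    det <- which(M > 0, arr.ind = TRUE)
    pepRow <- det[, 1]; sampCol <- det[, 2]
    dr <- truth@drift
    massObs <- truth@peptides$mass[pepRow] *
      (1 + rnorm(nrow(det), 0, config@massJitterPpm * 1e-6))
    timeObs <- dr$timeScale[sampCol] *
      (truth@peptides$time[pepRow] +
         rnorm(nrow(det), 0, config@timeJitterSd)) +
      dr$timeShift[sampCol]
    intObs <- dr$intensityScale[sampCol] * M[det]
    reg <- data.frame(sampleId = colnames(M)[sampCol], mass = massObs,
                      time = timeObs, intensity = intObs,
                      stringsAsFactors = FALSE)
    ## internal standards: every sample, reference values under drift
    ns <- nrow(truth@standards)
    n <- ncol(M)
    std <- data.frame(
      sampleId = rep(colnames(M), each = ns),
      mass = rep(truth@standards$mass, n),
      time = rep(dr$timeScale, each = ns) * rep(truth@standards$time, n) +
        rep(dr$timeShift, each = ns),
      intensity = rep(dr$intensityScale, each = ns) *
        rep(truth@standards$intensity, n),
      stringsAsFactors = FALSE)
    rbind(reg, std)
  })
  ps <- PeakSet(peaks, sim$samples, sim$tkv)
  list(peaks = ps, truth = truth, samples = sim$samples, tkv = sim$tkv)
}

#' Assemble the drift-free ground-truth intensity matrix
#'
#' Returns the generator's pre-drift normalized intensities as a
#' [PeptideExperiment-class] keyed by the true peptide identities —
#' the matrix the calibration + matching stages aim to recover.
#'
#' @param cohort result of [generateCohort()].
#' @return A [PeptideExperiment-class].
#' @export
cohortMatrix <- function(cohort) {
  truth <- cohort$truth
  catalog <- data.frame(peptideId = truth@peptides$peptideId,
                        mass = truth@peptides$mass,
                        time = truth@peptides$time,
                        stringsAsFactors = FALSE)
  PeptideExperiment(truth@matrix, catalog, cohort$samples)
}

#' Generate height-adjusted total kidney volume for a set of cases
#'
#' Draws TKV from the configured log-normal, heights uniformly from the
#' configured range, and returns htTKV = TKV / height (ml/m) per sample,
#' reproducibly under the config seed.
#'
#' @param config a [CohortConfig-class].
#' @param sampleIds character vector of case sample ids.
#' @return named numeric vector of htTKV (ml/m); empty input gives an
#'   empty mapping.
#' @export
generateHtTKV <- function(config, sampleIds) {
  stopifnot(is(config, "CohortConfig"))
  if (!length(sampleIds)) return(setNames(numeric(), character()))
  withSeed(childSeed(config@seed, 7L), {
    tkv <- rlnorm(length(sampleIds), config@tkvLognormal[1],
                  config@tkvLognormal[2])
    height <- .drawUnif(length(sampleIds), config@heightRange)
    setNames(tkv / height, sampleIds)
  })
}

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf("CohortConfig: %d cases / %d controls, %d peptides\n",
              object@nCases, object@nControls, object@nPeptides))
  cat(sprintf("  markers: %.0f%% of peptides, %.0f%% down, fold %.2g-%.2g\n",
              100 * object@fracMarkers, 100 * object@fracDown,
              object@foldRange[1], object@foldRange[2]))
  cat(sprintf("  severity: %d peptides, target |r| = %.2f; seed %d\n",
              object@nSeverityPeptides, object@severityRTarget,
              object@seed))
})

setMethod("show", "CohortTruth", function(object) {
  cat(sprintf(paste0("CohortTruth: %d peptides x %d samples; %d markers, ",
                     "%d severity peptides, %d standards\n"),
              nrow(object@matrix), ncol(object@matrix),
              nrow(object@markers), nrow(object@severity),
              nrow(object@standards)))
})

#' Accessors for CohortTruth
#'
#' `plantedMarkers()` returns the planted diagnostic markers (peptide id,
#' fold, direction); `plantedSeverity()` the severity peptides and their
#' loadings; `plantedDrift()` the per-sample drift parameters;
#' `trueHtTKV()` the per-case htTKV.
#'
#' @param object a [CohortTruth-class]
#' @export
setGeneric("plantedMarkers",
           function(object) standardGeneric("plantedMarkers"))

#' @rdname plantedMarkers
#' @export
setMethod("plantedMarkers", "CohortTruth", function(object) object@markers)

#' @rdname plantedMarkers
#' @export
setGeneric("plantedSeverity",
           function(object) standardGeneric("plantedSeverity"))

#' @rdname plantedMarkers
#' @export
setMethod("plantedSeverity", "CohortTruth",
          function(object) object@severity)

#' @rdname plantedMarkers
#' @export
setGeneric("plantedDrift", function(object) standardGeneric("plantedDrift"))

#' @rdname plantedMarkers
#' @export
setMethod("plantedDrift", "CohortTruth", function(object) object@drift)

#' @rdname plantedMarkers
#' @export
setGeneric("trueHtTKV", function(object) standardGeneric("trueHtTKV"))

#' @rdname plantedMarkers
#' @export
setMethod("trueHtTKV", "CohortTruth", function(object) object@httkv)
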