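## One sample whose peaks include the reference standards, under a known
## affine distortion of time and scaling of intensity.
distortedSample <- function(shift = 0, scale = 1, iScale = 1,
                            id = "S1", n = 25) {
  std <- referenceStandards(10)
  set.seed(4)
  extra <- data.frame(sampleId = id,
                      mass = exp(runif(n, log(900), log(15000))),
                      time = runif(n, 19, 44),
                      intensity = exp(rnorm(n, 6, 1)))
  peaks <- rbind(extra,
                 data.frame(sampleId = id, mass = std$mass,
                            time = std$time, intensity = std$intensity))
  peaks$time <- scale * peaks$time + shift
  peaks$intensity <- iScale * peaks$intensity
  PeakSet(peaks)
}

test_that("standards at reference give the identity calibration", {
  ps <- distortedSample()
  out <- calibrateSamples(ps, referenceStandards(10))
  r <- out$records
  expect_true(r$calibrated)
  expect_equal(r$a, 1, tolerance = 1e-9)
  expect_equal(r$b, 0, tolerance = 1e-9)
  expect_equal(r$s, 1, tolerance = 1e-9)
  expect_equal(peakTable(out$peaks)$time, peakTable(ps)$time,
               tolerance = 1e-9)
})

test_that("a uniform time shift is inverted exactly", {
  out <- calibrateSamples(distortedSample(shift = 2),
                          referenceStandards(10))
  expect_equal(out$records$a, 1, tolerance = 1e-6)
  expect_equal(out$records$b, -2, tolerance = 1e-6)
})

test_that("doubled intensities give a median ratio factor of one half", {
  out <- calibrateSamples(distortedSample(iScale = 2),
                          referenceStandards(10))
  expect_equal(out$records$s, 0.5, tolerance = 1e-9)
})

test_that("normalization is idempotent", {
  once <- calibrateSamples(distortedSample(shift = 1.2, scale = 1.04,
                                           iScale = 1.6),
                           referenceStandards(10))
  twice <- calibrateSamples(once$peaks, referenceStandards(10))
  expect_equal(twice$records$a, 1, tolerance = 1e-9)
  expect_equal(twice$records$b, 0, tolerance = 1e-9)
  expect_equal(twice$records$s, 1, tolerance = 1e-9)
})

test_that("samples with too few matchable standards are excluded", {
  ## standards far outside the sample's peaks
  ps <- PeakSet(data.frame(sampleId = "S1", mass = c(1000, 1100, 1200),
                           time = c(20, 21, 22), intensity = c(1, 2, 3)))
  fake <- data.frame(mass = c(5000, 6000, 7000, 8000),
                     time = c(25, 30, 35, 40),
                     intensity = c(1, 1, 1, 1))
  expect_warning(out <- calibrateSamples(ps, fake), "excluded")
  expect_false(out$records$calibrated)
  expect_equal(length(out$peaks), 0L)
})

test_that("planted drift is recovered within 1% on synthetic data", {
  co <- generateCohort(cohortConfig(nCases = 8, nControls = 12,
                                    nPeptides = 400, seed = 13))
  cal <- calibrateSamples(co$peaks, co$truth@standards)
  m <- merge(cal$records, plantedDrift(co$truth), by = "sampleId")
  expect_true(all(m$calibrated))
  ## t_norm = a t_obs + b must invert t_obs = scale * t + shift
  expect_lt(max(abs(m$a * m$timeScale - 1)), 0.01)
  expect_lt(max(abs(m$b + m$a * m$timeShift)), 0.01)
  expect_lt(max(abs(m$s * m$intensityScale - 1)), 0.01)
})

test_that("identical peaks across samples match into one consensus peptide", {
  peaks <- data.frame(sampleId = c("S1", "S2"), mass = 1000, time = 25,
                      intensity = c(50, 60))
  pe <- matchPeptides(PeakSet(peaks))
  expect_equal(nrow(pe), 1L)
  expect_equal(sum(intensityMatrix(pe) > 0), 2L)
})

test_that("peaks 300 ppm apart stay distinct under the default tolerance", {
  peaks <- data.frame(sampleId = c("S1", "S2"),
                      mass = c(1000.00, 1000.30), time = 25,
                      intensity = c(50, 60))
  pe <- matchPeptides(PeakSet(peaks))
  expect_equal(nrow(pe), 2L)
  ## at 50 ppm apart they merge
  peaks2 <- peaks; peaks2$mass <- c(1000.00, 1000.05)
  expect_equal(nrow(matchPeptides(PeakSet(peaks2))), 1L)
})

test_that("matching is invariant to sample input order", {
  co <- generateCohort(cohortConfig(nCases = 5, nControls = 5,
                                    nPeptides = 150, drift = noDrift(),
                                    seed = 2))
  ps <- co$peaks
  ids <- rev(sampleIds(ps))
  flipped <- ps[ids]
  a <- matchPeptides(ps)
  b <- matchPeptides(flipped)
  expect_equal(peptideCatalog(a), peptideCatalog(b))
  expect_equal(intensityMatrix(a),
               intensityMatrix(b)[, colnames(intensityMatrix(a))])
})

test_that("every consensus member lies within tolerance of its centroid", {
  co <- generateCohort(cohortConfig(nCases = 6, nControls = 6,
                                    nPeptides = 300, seed = 9))
  cal <- calibrateSamples(co$peaks, co$truth@standards)
  tol <- matchTolerances()
  pe <- matchPeptides(cal$peaks, tol)
  cat <- peptideCatalog(pe)
  M <- intensityMatrix(pe)
  p <- peakTable(cal$peaks)
  ## reconstruct membership: each nonzero entry is a member peak,
  ## identified by its (sample, intensity) pair where that is unambiguous
  idx <- which(M > 0, arr.ind = TRUE)
  key <- paste(colnames(M)[idx[, 2]], round(M[idx], 6))
  peakKey <- paste(p$sampleId, round(p$intensity, 6))
  unambiguous <- !(key %in% peakKey[duplicated(peakKey)])
  mm <- match(key[unambiguous], peakKey)
  mass <- cat$mass[idx[unambiguous, 1]]
  time <- cat$time[idx[unambiguous, 1]]
  expect_gt(sum(unambiguous), 1000)
  expect_true(all(abs(p$mass[mm] - mass) / mass <= tol$massRel + 1e-12))
  expect_true(all(abs(p$time[mm] - time) <= tol$timeAbs + 1e-12))
})

test_that("an empty peak set matches into an empty catalog", {
  ps <- PeakSet(tinyPeakDf()[0, ])
  pe <- matchPeptides(ps)
  expect_equal(nrow(pe), 0L)
})
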