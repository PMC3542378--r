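#' Assemble a pipeline configuration
#'
#' Collects every knob of the end-to-end run: the synthetic cohort (or
#' input file paths), matching tolerances, discovery thresholds, SVM grid
#' and cross-validation mode, panel size, severity screening threshold
#' and train fraction, and the output directory. The effective
#' configuration is echoed into the run directory as YAML.
#'
#' @param outDir run directory (created if needed).
#' @param cohort a [CohortConfig-class] to simulate, or NULL when
#'   `peakFile` inputs are given.
#' @param peakFile,metadataFile,tkvFile input files consumed instead of
#'   simulation.
#' @param tolerances [matchTolerances()] list.
#' @param qThreshold,minFreq discovery thresholds.
#' @param grid SVM hyperparameter grid (list of `cost`, `gamma`).
#' @param cv,k cross-validation mode for training.
#' @param panelSize markers fed to the SVM (top of the discovery
#'   ranking; default 142).
#' @param rThreshold severity screening threshold.
#' @param severityTrainFrac fraction of cases used to fit the severity
#'   model (rest validates it).
#' @param seed master seed for all pipeline randomness.
#' @return a named list (class `pipelineConfig`).
#' @export
pipelineConfig <- function(outDir, cohort = cohortConfig(),
                           peakFile = NULL, metadataFile = NULL,
                           tkvFile = NULL,
                           tolerances = matchTolerances(),
                           qThreshold = 0.05, minFreq = 0.3,
                           grid = list(cost = c(1, 10, 100, 1000),
                                       gamma = c(1e-4, 1e-3, 1e-2)),
                           cv = "kfold", k = 10, panelSize = 142,
                           rThreshold = 0.25, severityTrainFrac = 0.46,
                           seed = 1L) {
  structure(list(outDir = outDir, cohort = cohort, peakFile = peakFile,
                 metadataFile = metadataFile, tkvFile = tkvFile,
                 tolerances = tolerances, qThreshold = qThreshold,
                 minFreq = minFreq, grid = grid, cv = cv, k = k,
                 panelSize = panelSize, rThreshold = rThreshold,
                 severityTrainFrac = severityTrainFrac,
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

.stage <- function(name, expr) {
  message(sprintf("[%s] %s ...", format(Sys.time(), "%H:%M:%S"), name))
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
}

.writeTsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or read) -> calibrate -> match -> discover ->
#' train -> score -> severity -> report, writing every stage's artifacts
#' into the run directory. Identical configuration and seed yield
#' identical artifacts.
#'
#' @param config a [pipelineConfig()] list.
#' @return invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(list(
    qThreshold = config$qThreshold, minFreq = config$minFreq,
    panelSize = config$panelSize, rThreshold = config$rThreshold,
    severityTrainFrac = config$severityTrainFrac, cv = config$cv,
    k = config$k, seed = config$seed,
    tolerances = config$tolerances),
    file.path(config$outDir, "config.yaml"))

  withSeed(config$seed, {
    cohort <- NULL
    ps <- .stage("simulate/read", {
      if (!is.null(config$peakFile)) {
        readPeakTable(config$peakFile, config$metadataFile,
                      config$tkvFile)
      } else {
        cohort <- generateCohort(config$cohort)
        writePeakTable(cohort$peaks, file.path(config$outDir, "peaks.tsv"),
                       file.path(config$outDir, "metadata.tsv"),
                       file.path(config$outDir, "tkv.tsv"),
                       overwrite = TRUE)
        .writeTsv(plantedMarkers(cohort$truth), config$outDir,
                  "truth_markers.tsv")
        .writeTsv(plantedSeverity(cohort$truth), config$outDir,
                  "truth_severity.tsv")
        cohort$peaks
      }
    })

    cal <- .stage("calibrate", {
      out <- calibrateSamples(ps)
      .writeTsv(out$records, config$outDir, "calibration.tsv")
      out
    })

    pe <- .stage("match", {
      pe <- matchPeptides(cal$peaks, config$tolerances)
      writeMatrix(pe, file.path(config$outDir, "matrix.tsv"),
                  overwrite = TRUE)
      pe
    })

    disc <- .stage("discover", {
      st <- differentialStats(pe, minFreq = config$minFreq)
      .writeTsv(st, config$outDir, "marker_stats.tsv")
      markers <- selectMarkers(st, config$qThreshold)
      list(stats = st, markers = markers)
    })

    model <- .stage("train", {
      if (!length(disc$markers))
        stopf("no significant markers at q < %g; cannot train",
              config$qThreshold)
      st <- disc$stats
      panel <- head(disc$markers, config$panelSize)
      m <- trainSvm(pe, markerIds = panel, grid = config$grid,
                    cv = config$cv, k = config$k)
      setCutoff(m, labels = diagnosisLabels(pe))
    })

    scores <- .stage("score", {
      s <- scoreSamples(model, pe)
      .writeTsv(data.frame(sample_id = names(s), score = s,
                           call = ifelse(s >= modelCutoff(model),
                                         model@caseLabel,
                                         model@controlLabel)),
                config$outDir, "scores.tsv")
      s
    })

    sev <- .stage("severity", {
      labs <- diagnosisLabels(pe)
      caseIds <- names(labs)[labs == model@caseLabel]
      htt <- .pipelineHtTKV(ps, caseIds)
      if (length(htt) < 20) {
        message("  too few cases with htTKV; severity stage skipped")
        NULL
      } else {
        ids <- names(htt)
        nTrain <- max(10L, round(config$severityTrainFrac * length(ids)))
        trainIds <- sort(sample(ids, nTrain))
        testIds <- setdiff(ids, trainIds)
        Mcase <- intensityMatrix(pe)
        scr <- screenSpearman(Mcase[, trainIds, drop = FALSE],
                              htt[trainIds], config$rThreshold)
        if (!nrow(scr)) {
          message("  no peptides passed the severity screen")
          NULL
        } else {
          fit <- fitSeverity(Mcase[, trainIds, drop = FALSE],
                             htt[trainIds], scr)
          val <- predictSeverity(fit, Mcase[, testIds, drop = FALSE],
                                 htt[testIds])
          .writeTsv(data.frame(sample_id = testIds,
                               predicted = val$predicted,
                               observed = htt[testIds]),
                    config$outDir, "severity_predictions.tsv")
          list(model = fit, validation = val, trainIds = trainIds,
               testIds = testIds)
        }
      }
    })

    report <- .stage("report", {
      labs <- diagnosisLabels(pe)
      roc <- rocAuc(scores, labs, model@caseLabel)
      .writeTsv(roc$curve, config$outDir, "roc.tsv")
      op <- operatingPoint(scores, labs, modelCutoff(model),
                           model@caseLabel)
      md <- sampleData(ps)
      sub <- if (all(c("age", "genotype") %in% names(md)))
        subgroupReport(scores, labs, md, cutoffs = modelCutoff(model),
                       caseLabel = model@caseLabel) else NULL
      if (!is.null(sub)) .writeTsv(sub, config$outDir, "subgroups.tsv")
      lines <- c(
        "# Pipeline report", "",
        sprintf("- samples: %d (%d %s)", length(labs),
                sum(labs == model@caseLabel), model@caseLabel),
        sprintf("- consensus peptides: %d", nrow(pe)),
        sprintf("- significant markers (q < %g): %d", config$qThreshold,
                length(disc$markers)),
        sprintf("- SVM panel: %d peptides, C = %g, gamma = %g",
                length(markerPanel(model)), model@cost, model@gamma),
        sprintf("- cross-validated AUC: %.3f", cvAuc(model)),
        sprintf("- full-cohort AUC: %.3f (95%% CI %.3f-%.3f)", roc$auc,
                roc$ci[1], roc$ci[2]),
        sprintf("- at cutoff %.3f: sensitivity %.1f%%, specificity %.1f%%",
                modelCutoff(model), 100 * op$sensitivity$estimate,
                100 * op$specificity$estimate),
        if (!is.null(sev))
          sprintf("- severity: %d peptides, training r %.3f, held-out r %.3f",
                  length(sev$model@peptideIds),
                  sev$model@trainingCor["spearman"],
                  sev$validation$spearman$r))
      writeLines(lines, file.path(config$outDir, "report.md"))
      list(roc = roc, operatingPoint = op, subgroups = sub)
    })

    invisible(list(peaks = ps, calibration = cal$records, experiment = pe,
                   discovery = disc, model = model, scores = scores,
                   severity = sev, report = report))
  })
}

## htTKV per case from the PeakSet's metadata + TKV series
.pipelineHtTKV <- function(ps, caseIds) {
  md <- sampleData(ps)
  tkv <- tkvSeries(ps)
  out <- numeric(0)
  for (id in caseIds) {
    h <- md$height[md$sampleId == id]
    s <- tkv[tkv$sampleId == id, , drop = FALSE]
    if (length(h) == 1 && is.finite(h) && h > 0 && nrow(s))
      out[id] <- tkvGrowth(s, h)$httkv
  }
  out
}
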