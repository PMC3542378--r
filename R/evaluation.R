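#' ROC curve and AUC with DeLong confidence interval
#'
#' AUC is the midrank Mann-Whitney statistic (trapezoidal area under the
#' empirical ROC curve with tied scores handled by midranks); the 95%
#' confidence interval uses the DeLong placement-variance estimator,
#' truncated to \[0, 1\].
#'
#' @param scores numeric classifier scores (higher = more case-like).
#' @param labels class labels aligned with `scores`.
#' @param caseLabel the positive class (default `"ADPKD"` when present,
#'   else the rarer label).
#' @param conf confidence level (default 0.95).
#' @return list with `auc`, `ci` (length-2), `se`, and `curve` (data.frame
#'   of `fpr`, `tpr`, `cutoff`).
#' @export
rocAuc <- function(scores, labels, caseLabel = NULL, conf = 0.95) {
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) != 2L) stopf("both classes must be present")
  if (is.null(caseLabel))
    caseLabel <- if ("ADPKD" %in% cls) "ADPKD" else
      cls[which.min(tabulate(match(labels, cls)))]
  case <- labels == caseLabel
  x <- scores[case]; y <- scores[!case]
  m <- length(x); n <- length(y)
  auc <- .mwAuc(scores, case)

  ## DeLong placements
  vx <- vapply(x, function(xi) (sum(xi > y) + 0.5 * sum(xi == y)) / n,
               numeric(1))
  vy <- vapply(y, function(yi) (sum(x > yi) + 0.5 * sum(x == yi)) / m,
               numeric(1))
  se <- sqrt(var(vx) / m + var(vy) / n)
  zq <- qnorm(1 - (1 - conf) / 2)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * zq * se))

  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    cutoff = cuts,
    tpr = vapply(cuts, function(ct) mean(x >= ct), numeric(1)),
    fpr = vapply(cuts, function(ct) mean(y >= ct), numeric(1)))
  list(auc = auc, ci = ci, se = se, curve = curve)
}

## Exact (Clopper-Pearson) binomial interval, vectorized.
.clopperPearson <- function(x, n, conf = 0.95) {
  a <- 1 - conf
  lo <- ifelse(x == 0, 0, qbeta(a / 2, x, n - x + 1))
  hi <- ifelse(x == n, 1, qbeta(1 - a / 2, x + 1, n - x))
  cbind(lower = lo, upper = hi)
}

#' Operating point with exact binomial confidence intervals
#'
#' Calls are `score >= cutoff` = case. Sensitivity and specificity are
#' reported with exact (Clopper-Pearson) 95% confidence intervals.
#'
#' @inheritParams rocAuc
#' @param cutoff decision threshold.
#' @return list with `cutoff`, `counts` (TP, FP, TN, FN), `sensitivity`
#'   and `specificity` (each: `estimate`, `lower`, `upper`).
#' @export
operatingPoint <- function(scores, labels, cutoff, caseLabel = NULL,
                           conf = 0.95) {
  labels <- as.character(labels)
  cls <- unique(labels)
  if (is.null(caseLabel))
    caseLabel <- if ("ADPKD" %in% cls) "ADPKD" else
      cls[which.min(tabulate(match(labels, cls)))]
  case <- labels == caseLabel
  pos <- scores >= cutoff
  counts <- c(TP = sum(case & pos), FP = sum(!case & pos),
              TN = sum(!case & !pos), FN = sum(case & !pos))
  .opFromCounts(counts, cutoff, conf)
}

.opFromCounts <- function(counts, cutoff, conf = 0.95) {
  nCase <- counts["TP"] + counts["FN"]
  nCtrl <- counts["TN"] + counts["FP"]
  sens <- if (nCase > 0) {
    ci <- .clopperPearson(counts["TP"], nCase, conf)
    list(estimate = unname(counts["TP"] / nCase),
         lower = unname(ci[, 1]), upper = unname(ci[, 2]))
  } else list(estimate = NA_real_, lower = NA_real_, upper = NA_real_)
  spec <- if (nCtrl > 0) {
    ci <- .clopperPearson(counts["TN"], nCtrl, conf)
    list(estimate = unname(counts["TN"] / nCtrl),
         lower = unname(ci[, 1]), upper = unname(ci[, 2]))
  } else list(estimate = NA_real_, lower = NA_real_, upper = NA_real_)
  list(cutoff = cutoff, counts = counts, sensitivity = sens,
       specificity = spec)
}

#' Build an operating point directly from confusion counts
#'
#' Convenience for cohorts known only through printed counts (e.g. a
#' published specificity panel): supply TP/FP/TN/FN and get the same
#' structure [operatingPoint()] returns.
#'
#' @param TP,FP,TN,FN confusion counts.
#' @param cutoff the shared decision threshold the counts were taken at.
#' @param conf confidence level.
#' @export
countsOperatingPoint <- function(TP = 0, FP = 0, TN = 0, FN = 0,
                                 cutoff = NA_real_, conf = 0.95) {
  .opFromCounts(c(TP = TP, FP = FP, TN = TN, FN = FN), cutoff, conf)
}

#' Pool operating points across disjoint cohorts
#'
#' Confusion counts are summed and the proportions recomputed with fresh
#' exact intervals; all cohorts must share the same cutoff.
#'
#' @param results list of operating points (from [operatingPoint()] or
#'   [countsOperatingPoint()]).
#' @return a pooled operating point.
#' @export
poolCohorts <- function(results) {
  if (!length(results)) stopf("nothing to pool")
  cuts <- vapply(results, function(r) r$cutoff, numeric(1))
  known <- cuts[!is.na(cuts)]
  if (length(unique(known)) > 1L)
    stopf("cohorts were evaluated at different cutoffs: %s",
          paste(unique(known), collapse = ", "))
  counts <- Reduce(`+`, lapply(results, `[[`, "counts"))
  .opFromCounts(counts, if (length(known)) known[1] else NA_real_)
}

#' Sensitivity/specificity by age and genotype subgroup
#'
#' One row per cutoff; sensitivity columns for all cases, age < 30,
#' age >= 30, PKD1 and PKD2 subgroups, and a single specificity column
#' per cutoff computed on the full control set (age-subgroup
#' specificities are additionally reported from the controls' ages).
#' Cases with other genotype categories count toward "all" only.
#'
#' @param scores named numeric scores.
#' @param labels class labels aligned with `scores`.
#' @param metadata data.frame with `sampleId`, `age`, `genotype` covering
#'   the scored samples.
#' @param cutoffs decision thresholds (defaults are the three published
#'   presets).
#' @param caseLabel the positive class.
#' @return data.frame, one row per cutoff.
#' @export
subgroupReport <- function(scores, labels, metadata,
                           cutoffs = c(-0.169, -0.250, -0.400),
                           caseLabel = NULL) {
  if (!length(cutoffs)) stopf("at least one cutoff is required")
  assertColumns(metadata, c("sampleId", "age", "genotype"), "metadata")
  labels <- as.character(labels)
  cls <- unique(labels)
  if (is.null(caseLabel))
    caseLabel <- if ("ADPKD" %in% cls) "ADPKD" else
      cls[which.min(tabulate(match(labels, cls)))]
  md <- metadata[match(names(scores), metadata$sampleId), , drop = FALSE]
  case <- labels == caseLabel
  young <- md$age < 30
  sensOf <- function(sel, ct) if (any(sel)) mean(scores[sel] >= ct) else
    NA_real_
  rows <- lapply(cutoffs, function(ct) {
    data.frame(
      cutoff = ct,
      sensAll = sensOf(case, ct),
      sensAgeUnder30 = sensOf(case & young, ct),
      sensAge30Plus = sensOf(case & !young, ct),
      sensPKD1 = sensOf(case & md$genotype == "PKD1", ct),
      sensPKD2 = sensOf(case & md$genotype == "PKD2", ct),
      specAll = if (any(!case)) mean(scores[!case] < ct) else NA_real_,
      specAgeUnder30 = if (any(!case & young))
        mean(scores[!case & young] < ct) else NA_real_,
      specAge30Plus = if (any(!case & !young))
        mean(scores[!case & !young] < ct) else NA_real_)
  })
  out <- do.call(rbind, rows)
  empty <- names(out)[vapply(out, function(x) all(is.na(x)), logical(1))]
  if (length(empty))
    warnf("empty subgroup column(s): %s", paste(empty, collapse = ", "))
  out
}

#' Correlate a biomarker score with clinical severity markers
#'
#' Spearman rank correlation (with asymptotic p-value) of the score
#' against each clinical variable; variables with fewer than `minPairs`
#' paired observations are skipped with a note.
#'
#' @param scores named numeric scores.
#' @param clinical data.frame with `sampleId` and clinical columns (e.g.
#'   `tkv`, `httkv`, `tkvChangeMlYr`, `tkvChangePctYr`, `egfr`).
#' @param minPairs minimum paired observations (default 10).
#' @return data.frame `variable`, `n`, `rho`, `p`.
#' @export
correlateClinical <- function(scores, clinical, minPairs = 10) {
  assertColumns(clinical, "sampleId", "clinical table")
  cl <- clinical[match(names(scores), clinical$sampleId), , drop = FALSE]
  vars <- setdiff(names(cl), "sampleId")
  rows <- lapply(vars, function(v) {
    x <- cl[[v]]
    if (!is.numeric(x)) return(NULL)
    ok <- is.finite(x) & is.finite(scores)
    if (sum(ok) < minPairs) {
      message("skipping '", v, "': only ", sum(ok), " paired observations")
      return(NULL)
    }
    ct <- suppressWarnings(cor.test(scores[ok], x[ok],
                                    method = "spearman", exact = FALSE))
    data.frame(variable = v, n = sum(ok), rho = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(variable = character(), n = integer(),
                      rho = numeric(), p = numeric())
  out
}

#' Kidney-volume severity and growth rates from a TKV series
#'
#' htTKV is the first TKV measurement divided by body height (ml/m). The
#' absolute growth rate is the least-squares slope of TKV over time
#' (ml/yr); the relative rate is `(exp(slope of ln TKV) - 1) * 100`
#' (%/yr). Rates require at least `minPoints` time points (default 2;
#' progression analyses customarily demand 4 serial measurements).
#'
#' @param tkvSeries data.frame with `timeYears`, `tkvMl` for one patient.
#' @param height body height in m.
#' @param minPoints minimum measurements for rate estimation.
#' @return list with `httkv`, `absRate`, `relRate` (rates NA when the
#'   series is too short).
#' @export
tkvGrowth <- function(tkvSeries, height, minPoints = 2) {
  assertColumns(tkvSeries, c("timeYears", "tkvMl"), "TKV series")
  if (!nrow(tkvSeries)) stopf("empty TKV series")
  if (!is.finite(height) || height <= 0) stopf("height must be > 0")
  s <- tkvSeries[order(tkvSeries$timeYears), , drop = FALSE]
  httkv <- s$tkvMl[1] / height
  if (nrow(s) < max(2, minPoints))
    return(list(httkv = httkv, absRate = NA_real_, relRate = NA_real_))
  absRate <- unname(coef(lm(tkvMl ~ timeYears, data = s))[2])
  relRate <- (exp(unname(coef(lm(log(tkvMl) ~ timeYears,
                                 data = s))[2])) - 1) * 100
  list(httkv = httkv, absRate = absRate, relRate = relRate)
}
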