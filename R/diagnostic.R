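## ---- feature pipeline -----------------------------------------------

## ln(1+x) features (samples x markers) from a PeptideExperiment or
## peptide x sample matrix; absent peptide columns are an error.
.featureMatrix <- function(object, markerIds) {
  M <- if (is(object, "PeptideExperiment")) intensityMatrix(object) else
    as.matrix(object)
  miss <- setdiff(markerIds, rownames(M))
  if (length(miss))
    stopf("matrix is missing marker peptide(s): %s",
          paste(miss, collapse = ", "))
  t(log1p(M[markerIds, , drop = FALSE]))
}

.fitMinMax <- function(X) {
  mins <- apply(X, 2, min)
  maxs <- apply(X, 2, max)
  keep <- maxs > mins
  if (!all(keep))
    warnf("dropping %d constant feature(s): %s", sum(!keep),
          paste(colnames(X)[!keep], collapse = ", "))
  list(min = mins[keep], max = maxs[keep], keep = colnames(X)[keep])
}

.applyMinMax <- function(X, mins, maxs) {
  X <- X[, names(mins), drop = FALSE]
  sweep(sweep(X, 2, mins, "-"), 2, maxs - mins, "/")
}

.rbfKernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

## ---- SVM core --------------------------------------------------------

.classWeights <- function(y, balanced) {
  if (!balanced) return(NULL)
  tab <- table(y)
  w <- length(y) / (length(tab) * tab)
  setNames(as.numeric(w), names(tab))
}

.svmFit <- function(X, y, cost, gamma, weights) {
  e1071::svm(x = X, y = y, type = "C-classification", kernel = "radial",
             cost = cost, gamma = gamma, scale = FALSE,
             class.weights = weights)
}

## raw libsvm decision values, oriented so that `caseLabel` scores high
.decision <- function(fit, X, caseLabel) {
  dv <- attr(predict(fit, X, decision.values = TRUE), "decision.values")
  flip <- !startsWith(colnames(dv)[1], paste0(caseLabel, "/"))
  list(values = if (flip) -dv[, 1] else dv[, 1], flip = flip)
}

## kernel-space norm of the separating direction:
## w_norm^2 = sum_ij alpha_i alpha_j y_i y_j K(x_i, x_j)
.wNorm <- function(fit, gamma) {
  co <- as.numeric(fit$coefs)
  K <- .rbfKernel(fit$SV, fit$SV, gamma)
  sqrt(max(as.numeric(t(co) %*% K %*% co), .Machine$double.eps))
}

## cross-validation folds: stratified k-fold or leave-one-out
.cvFolds <- function(y, cv, k) {
  n <- length(y)
  if (cv == "loo") return(as.list(seq_len(n)))
  idx <- unlist(lapply(split(seq_len(n), y), function(g)
    split(sample(g), rep_len(seq_len(k), length(g)))), recursive = FALSE)
  ## merge the per-class splits fold-wise
  folds <- vector("list", k)
  for (i in seq_along(idx)) {
    f <- (i - 1L) %% k + 1L
    folds[[f]] <- c(folds[[f]], idx[[i]])
  }
  folds[lengths(folds) > 0]
}

#' Cross-validated margin scores at fixed SVM hyperparameters
#'
#' Every sample is scored by a model trained on the samples outside its
#' fold ("total cross-validation" when folds are leave-one-out); scores
#' are margin distances (decision value divided by the kernel-space norm
#' of the separating direction).
#'
#' @param X transformed feature matrix (samples x features).
#' @param y factor of class labels.
#' @param cost,gamma RBF-SVM hyperparameters.
#' @param folds list of held-out index vectors covering all samples.
#' @param caseLabel label that should score high.
#' @param weights class weights (see [trainSvm()]).
#' @return named numeric vector of cross-validated scores.
#' @keywords internal
.cvScores <- function(X, y, cost, gamma, folds, caseLabel, weights) {
  out <- numeric(nrow(X))
  for (f in folds) {
    fit <- .svmFit(X[-f, , drop = FALSE], droplevels(y[-f]), cost, gamma,
                   weights)
    d <- .decision(fit, X[f, , drop = FALSE], caseLabel)
    out[f] <- d$values / .wNorm(fit, gamma)
  }
  names(out) <- rownames(X)
  out
}

#' The published-model hyperparameter preset
#'
#' Cost and kernel width of the reported 142-peptide diagnostic model
#' (C = 640, gamma = 3e-06) plus its panel size, usable as a one-point
#' grid for [trainSvm()] and as `targetSize` for [takeOneOutPrune()].
#'
#' @return list with `cost`, `gamma`, `targetSize`.
#' @export
adpkd142Preset <- function() list(cost = 640, gamma = 3e-06,
                                  targetSize = 142L)

#' Train the RBF-SVM diagnostic score over a marker panel
#'
#' Features are the ln(1+x) intensities of the marker panel, min-max
#' scaled to \[0, 1\] with constants learned on the training samples.
#' Hyperparameters (C, gamma) are chosen to maximize cross-validated AUC
#' over the grid (ties: smallest cost, then largest gamma), optionally
#' refined one half-step around the optimum, and the final machine is
#' refit on all training data. Scores are kernel-space margin distances:
#' decision value divided by the norm of the separating direction, so a
#' score of 0 is the hyperplane itself.
#'
#' @param object a [PeptideExperiment-class] (or peptides x samples
#'   matrix) of training data.
#' @param labels per-sample class labels (two classes; default the
#'   diagnosis column).
#' @param markerIds candidate marker panel from [selectMarkers()].
#' @param grid list with numeric `cost` and `gamma` vectors.
#' @param cv `"loo"` (total leave-one-out, default) or `"kfold"`.
#' @param k folds when `cv = "kfold"`.
#' @param caseLabel label to score high (default `"ADPKD"` when present,
#'   else the rarer label).
#' @param balanced use inverse-prevalence class weights (default TRUE).
#' @param refine evaluate half-step neighbours of the grid optimum
#'   (default FALSE).
#' @return A [DiagnosticModel-class] (cutoff unset; see
#'   [chooseCutoff()]).
#' @export
trainSvm <- function(object, labels = diagnosisLabels(object), markerIds,
                     grid = list(cost = 2^seq(-5, 13, by = 2),
                                 gamma = 10^seq(-7, 1)),
                     cv = c("loo", "kfold"), k = 10, caseLabel = NULL,
                     balanced = TRUE, refine = FALSE) {
  cv <- match.arg(cv)
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) != 2L) stopf("exactly two classes are required")
  if (length(labels) < 10L) stopf("need n >= 10 training samples")
  if (is.null(caseLabel))
    caseLabel <- if ("ADPKD" %in% cls) "ADPKD" else
      cls[which.min(tabulate(match(labels, cls)))]
  controlLabel <- setdiff(cls, caseLabel)
  if (length(markerIds) < 1L) stopf("empty marker panel")

  X0 <- .featureMatrix(object, markerIds)
  sc <- .fitMinMax(X0)
  if (!length(sc$keep)) stopf("all features are constant")
  X <- .applyMinMax(X0, sc$min, sc$max)
  y <- factor(labels, levels = c(controlLabel, caseLabel))
  w <- .classWeights(y, balanced)
  case <- labels == caseLabel
  folds <- .cvFolds(y, cv, k)

  evalPoint <- function(cost, gamma) {
    s <- .cvScores(X, y, cost, gamma, folds, caseLabel, w)
    list(auc = .mwAuc(s, case), scores = s)
  }
  pts <- expand.grid(cost = grid$cost, gamma = grid$gamma)
  evals <- mapply(function(co, ga) evalPoint(co, ga), pts$cost, pts$gamma,
                  SIMPLIFY = FALSE)
  res <- vapply(evals, `[[`, numeric(1), "auc")
  ## ties: smallest cost, then largest gamma
  best <- order(-res, pts$cost, -pts$gamma)[1]
  bestCost <- pts$cost[best]; bestGamma <- pts$gamma[best]
  final <- evals[[best]]
  if (refine) {
    cand <- expand.grid(cost = bestCost * c(1 / sqrt(2), 1, sqrt(2)),
                        gamma = bestGamma * c(1 / sqrt(10), 1, sqrt(10)))
    cEvals <- mapply(function(co, ga) evalPoint(co, ga), cand$cost,
                     cand$gamma, SIMPLIFY = FALSE)
    aucs <- vapply(cEvals, `[[`, numeric(1), "auc")
    b2 <- order(-aucs, cand$cost, -cand$gamma)[1]
    if (aucs[b2] > final$auc) {
      bestCost <- cand$cost[b2]; bestGamma <- cand$gamma[b2]
      final <- cEvals[[b2]]
    }
  }
  fit <- .svmFit(X, y, bestCost, bestGamma, w)
  d <- .decision(fit, X, caseLabel)
  new("DiagnosticModel", markerIds = sc$keep, featureMin = sc$min,
      featureMax = sc$max, fit = fit, flip = d$flip,
      wNorm = .wNorm(fit, bestGamma), cost = bestCost, gamma = bestGamma,
      cvAuc = final$auc, cvScores = final$scores, cutoff = NA_real_,
      caseLabel = caseLabel, controlLabel = controlLabel)
}

#' Margin scores for new samples under a diagnostic model
#'
#' Applies the stored feature transform (ln(1+x), training min-max) and
#' returns the kernel-space margin distance per sample; positive scores
#' lie on the case side of the hyperplane. Columns beyond the marker
#' panel are ignored; all panel peptides must be present (a peptide not
#' detected in a sample is an intensity of 0, not a missing column).
#'
#' @param model a [DiagnosticModel-class].
#' @param object a [PeptideExperiment-class] or peptides x samples
#'   matrix.
#' @return named numeric vector of scores.
#' @export
setGeneric("scoreSamples",
           function(model, object) standardGeneric("scoreSamples"))

#' @rdname scoreSamples
#' @export
setMethod("scoreSamples", "DiagnosticModel", function(model, object) {
  X <- .featureMatrix(object, model@markerIds)
  X <- .applyMinMax(X, model@featureMin, model@featureMax)
  dv <- attr(predict(model@fit, X, decision.values = TRUE),
             "decision.values")[, 1]
  s <- (if (model@flip) -dv else dv) / model@wNorm
  names(s) <- rownames(X)
  s
})

#' Greedy take-one-out backward marker pruning
#'
#' At each step, removes the marker whose removal yields the highest
#' cross-validated AUC, as long as that removal does not degrade the AUC
#' by more than `improveTol` (redundant or noisy markers therefore keep
#' being shed while the panel's consistency is preserved); pruning stops
#' when every removal hurts, or when `targetSize` markers remain (when
#' `targetSize` is given, removal continues to that size regardless,
#' mirroring a fixed published panel size).
#'
#' @inheritParams trainSvm
#' @param cost,gamma fixed SVM hyperparameters used throughout pruning.
#' @param targetSize optional panel size to prune down to.
#' @param improveTol largest tolerated AUC degradation per removal when
#'   no `targetSize` is given (default 1e-4).
#' @return list with `markers` (surviving ids), `trajectory` (data.frame
#'   of step, removed id, cross-validated AUC) and `auc` (final AUC).
#' @export
takeOneOutPrune <- function(object, labels = diagnosisLabels(object),
                            markerIds, cost, gamma, targetSize = NULL,
                            improveTol = 1e-4, cv = c("loo", "kfold"),
                            k = 10, caseLabel = NULL, balanced = TRUE) {
  cv <- match.arg(cv)
  if (length(markerIds) < 2L) stopf("need at least 2 markers to prune")
  if (!is.null(targetSize)) {
    if (targetSize > length(markerIds))
      stopf("targetSize (%d) exceeds panel size (%d)", targetSize,
            length(markerIds))
    if (targetSize < 1L) stopf("targetSize must be >= 1")
  }
  labels <- as.character(labels)
  cls <- unique(labels)
  if (is.null(caseLabel))
    caseLabel <- if ("ADPKD" %in% cls) "ADPKD" else
      cls[which.min(tabulate(match(labels, cls)))]
  controlLabel <- setdiff(cls, caseLabel)
  X0 <- .featureMatrix(object, markerIds)
  sc <- .fitMinMax(X0)
  Xall <- .applyMinMax(X0, sc$min, sc$max)
  y <- factor(labels, levels = c(controlLabel, caseLabel))
  w <- .classWeights(y, balanced)
  case <- labels == caseLabel
  folds <- .cvFolds(y, cv, k)

  aucOf <- function(cols) {
    s <- .cvScores(Xall[, cols, drop = FALSE], y, cost, gamma, folds,
                   caseLabel, w)
    .mwAuc(s, case)
  }
  current <- sc$keep
  baseAuc <- aucOf(current)
  traj <- data.frame(step = 0L, removed = NA_character_, auc = baseAuc,
                     stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (length(current) <= 2L) break
    if (!is.null(targetSize) && length(current) <= targetSize) break
    cand <- vapply(seq_along(current), function(i)
      aucOf(current[-i]), numeric(1))
    best <- which.max(cand)
    if (is.null(targetSize) && cand[best] < baseAuc - improveTol) break
    step <- step + 1L
    traj <- rbind(traj, data.frame(step = step, removed = current[best],
                                   auc = cand[best]))
    current <- current[-best]
    baseAuc <- cand[best]
  }
  list(markers = current, trajectory = traj, auc = baseAuc)
}

#' Choose the operating cutoff on cross-validated scores
#'
#' Scans the midpoints between adjacent sorted distinct scores and
#' returns the cutoff maximizing the Youden index J = sensitivity +
#' specificity - 1 (call convention: score >= cutoff is a case call);
#' ties are broken toward higher specificity.
#'
#' @param scores numeric scores (cross-validated training scores, not
#'   resubstitution).
#' @param labels class labels aligned with `scores`.
#' @param caseLabel the positive class (default `"ADPKD"` when present,
#'   else the rarer label).
#' @return the cutoff value.
#' @export
chooseCutoff <- function(scores, labels, caseLabel = NULL) {
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) != 2L) stopf("exactly two classes are required")
  if (is.null(caseLabel))
    caseLabel <- if ("ADPKD" %in% cls) "ADPKD" else
      cls[which.min(tabulate(match(labels, cls)))]
  case <- labels == caseLabel
  s <- sort(unique(scores))
  if (length(s) < 2L) stopf("scores are constant; no cutoff exists")
  cand <- (s[-length(s)] + s[-1]) / 2
  sens <- vapply(cand, function(ct) mean(scores[case] >= ct), numeric(1))
  spec <- vapply(cand, function(ct) mean(scores[!case] < ct), numeric(1))
  j <- sens + spec - 1
  best <- order(-j, -spec, -cand)[1]
  cand[best]
}

#' Store an operating cutoff in a diagnostic model
#'
#' @param model a [DiagnosticModel-class].
#' @param cutoff score threshold (score >= cutoff calls a case); by
#'   default chosen from the model's cross-validated scores via
#'   [chooseCutoff()].
#' @param labels training labels for the default cutoff choice.
#' @return the updated model.
#' @export
setCutoff <- function(model, cutoff = NULL, labels = NULL) {
  stopifnot(is(model, "DiagnosticModel"))
  if (is.null(cutoff)) {
    if (is.null(labels))
      stopf("either an explicit cutoff or training labels are required")
    cutoff <- chooseCutoff(model@cvScores, labels, model@caseLabel)
  }
  model@cutoff <- cutoff
  model
}

setMethod("show", "DiagnosticModel", function(object) {
  cat(sprintf(paste0("DiagnosticModel: %d-peptide RBF-SVM panel ",
                     "(C = %g, gamma = %g)\n"),
              length(object@markerIds), object@cost, object@gamma))
  cat(sprintf("  cross-validated AUC %.3f; cutoff %s; %d support vectors\n",
              object@cvAuc,
              if (is.na(object@cutoff)) "unset" else
                sprintf("%.3f", object@cutoff),
              nrow(object@fit$SV)))
})

#' Accessors for DiagnosticModel
#'
#' @param object a [DiagnosticModel-class]
#' @export
setGeneric("markerPanel", function(object) standardGeneric("markerPanel"))

#' @rdname markerPanel
#' @export
setMethod("markerPanel", "DiagnosticModel",
          function(object) object@markerIds)

#' @rdname markerPanel
#' @export
setGeneric("cvAuc", function(object) standardGeneric("cvAuc"))

#' @rdname markerPanel
#' @export
setMethod("cvAuc", "DiagnosticModel", function(object) object@cvAuc)

#' @rdname markerPanel
#' @export
setGeneric("modelCutoff", function(object) standardGeneric("modelCutoff"))

#' @rdname markerPanel
#' @export
setMethod("modelCutoff", "DiagnosticModel", function(object) object@cutoff)
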