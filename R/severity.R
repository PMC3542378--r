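#' Screen peptides by Spearman correlation with htTKV
#'
#' Computes the Spearman rank correlation of each peptide's
#' ln(1+intensity) with the response; samples where a peptide is not
#' detected enter as intensity 0, i.e. the lowest midrank tie (absence is
#' informative). Peptides with `|r|` above the threshold are returned,
#' strongest first.
#'
#' @param object a [PeptideExperiment-class] or peptides x samples
#'   matrix.
#' @param response named numeric (htTKV, ml/m) covering every sample.
#' @param rThreshold absolute correlation threshold (default 0.25).
#' @return data.frame `peptideId`, `r`, ordered by decreasing `|r|`.
#' @export
screenSpearman <- function(object, response, rThreshold = 0.25) {
  M <- if (is(object, "PeptideExperiment")) intensityMatrix(object) else
    as.matrix(object)
  if (!is.null(names(response))) {
    miss <- setdiff(colnames(M), names(response))
    if (length(miss))
      stopf("response missing for sample(s): %s",
            paste(head(miss, 5), collapse = ", "))
    response <- response[colnames(M)]
  } else if (length(response) != ncol(M))
    stopf("response must cover every sample")
  if (ncol(M) < 3L) stopf("need n >= 3 samples for screening")
  if (ncol(M) < 10L)
    warnf("screening on n = %d samples; correlations are unstable below n = 10",
          ncol(M))
  if (sd(response) == 0) stopf("response is constant")
  ## Spearman = Pearson on midranks; log1p preserves ranks but is applied
  ## for consistency with the modelling scale
  ry <- rank(response)
  rx <- apply(log1p(M), 1, rank)        # samples x peptides
  sds <- apply(rx, 2, sd)
  const <- sds == 0
  if (any(const))
    warnf("%d constant peptide column(s) excluded from screening",
          sum(const))
  r <- rep(NA_real_, nrow(M))
  r[!const] <- suppressWarnings(as.numeric(cor(rx[, !const, drop = FALSE],
                                               ry)))
  keep <- !is.na(r) & abs(r) > rThreshold
  out <- data.frame(peptideId = rownames(M)[keep], r = r[keep],
                    stringsAsFactors = FALSE)
  out[order(-abs(out$r), out$peptideId), , drop = FALSE]
}

## Ridge fit with lambda chosen by generalized cross-validation, via SVD.
.ridgeGcv <- function(X, y, lambdas = 10^seq(-3, 5, length.out = 50)) {
  sv <- svd(X)
  d <- sv$d
  uy <- crossprod(sv$u, y)
  n <- length(y)
  gcv <- vapply(lambdas, function(l) {
    shrink <- d^2 / (d^2 + l)
    fitted <- sv$u %*% (shrink * uy)
    df <- sum(shrink)
    rss <- sum((y - fitted)^2)
    n * rss / (n - df)^2
  }, numeric(1))
  l <- lambdas[which.min(gcv)]
  beta <- sv$v %*% ((d / (d^2 + l)) * uy)
  list(lambda = l, beta = as.numeric(beta))
}

#' Fit the linear severity model on screened peptides
#'
#' Regresses htTKV on the standardized ln(1+intensity) of the screened
#' peptides. A plain least-squares fit is used when the design is
#' well-conditioned and `p < n/4`; otherwise the fit is ridge-penalized
#' with the penalty chosen by generalized cross-validation (the
#' rotation-invariant form of leave-one-out), since a ~100-peptide panel
#' against ~134 patients leaves ordinary least squares fragile. A
#' signed-sum variant (mean of sign(r) * standardized intensity, scaled
#' to the response) is available for sensitivity analysis.
#'
#' @param object training data ([PeptideExperiment-class] or peptides x
#'   samples matrix).
#' @param response named numeric htTKV per training sample.
#' @param screened result of [screenSpearman()] (or a character vector of
#'   peptide ids, in which case screening correlations are recomputed).
#' @param method `"auto"` (OLS or GCV-ridge by the rule above),
#'   `"ridge"`, `"ols"`, or `"signed-sum"`.
#' @return A [SeverityModel-class]; its `trainingCor` slot reports
#'   Pearson and Spearman correlation of fitted vs observed htTKV.
#' @export
fitSeverity <- function(object, response,
                        screened = screenSpearman(object, response),
                        method = c("auto", "ridge", "ols", "signed-sum")) {
  method <- match.arg(method)
  M <- if (is(object, "PeptideExperiment")) intensityMatrix(object) else
    as.matrix(object)
  if (is.character(screened))
    screened <- data.frame(peptideId = screened,
                           r = suppressWarnings(as.numeric(
                             cor(t(apply(log1p(M[screened, , drop = FALSE]),
                                         1, rank)),
                                 rank(response[colnames(M)]))[, 1])))
  if (!nrow(screened)) stopf("no screened peptides to fit")
  if (!is.null(names(response))) response <- response[colnames(M)]
  n <- length(response)
  if (n <= 2L) stopf("need n > 2 training samples")
  ids <- screened$peptideId
  X0 <- t(log1p(M[ids, , drop = FALSE]))
  center <- colMeans(X0)
  scale <- apply(X0, 2, sd)
  scale[scale == 0] <- 1
  X <- sweep(sweep(X0, 2, center), 2, scale, "/")
  p <- ncol(X)

  if (method == "signed-sum") {
    w <- sign(screened$r) / p
    raw <- as.numeric(X %*% w)
    fit <- lm(response ~ raw)
    weights <- w * unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    lambda <- 0
  } else {
    yc <- response - mean(response)
    useRidge <- method == "ridge" ||
      (method == "auto" && (p >= n / 4 || kappa(X) > 1e8))
    if (method == "ols" && p >= n)
      stopf(paste("p >= n with an unpenalized fit requested; use",
                  "method = 'ridge' (or 'auto')"))
    if (useRidge) {
      rf <- .ridgeGcv(X, yc)
      weights <- rf$beta
      lambda <- rf$lambda
    } else {
      weights <- as.numeric(coef(lm(yc ~ X - 1)))
      lambda <- 0
    }
    intercept <- mean(response) - sum(colMeans(X) * weights)
  }
  fitted <- intercept + as.numeric(X %*% weights)
  trainingCor <- c(pearson = cor(fitted, response),
                   spearman = cor(fitted, response, method = "spearman"))
  new("SeverityModel", peptideIds = ids,
      screeningR = setNames(screened$r, ids),
      center = setNames(center, ids), scale = setNames(scale, ids),
      intercept = intercept, weights = setNames(weights, ids),
      lambda = lambda,
      method = if (method == "auto") (if (lambda > 0) "ridge" else "ols")
               else method,
      trainingCor = trainingCor)
}

#' Predict the severity score (htTKV scale) for samples
#'
#' Applies the stored standardization and affine combination; peptides
#' absent from a sample contribute intensity 0. When observed htTKV is
#' supplied, Pearson and Spearman correlations (with p-values) of
#' predicted vs observed are reported alongside.
#'
#' @param model a [SeverityModel-class].
#' @param object a [PeptideExperiment-class] or peptides x samples
#'   matrix containing all model peptides.
#' @param observed optional named numeric of observed htTKV.
#' @return named numeric of predictions; when `observed` is given, a
#'   list with `predicted`, `pearson`, `spearman` (each a list with `r`
#'   and `p`).
#' @export
setGeneric("predictSeverity", function(model, object, observed = NULL)
  standardGeneric("predictSeverity"))

#' @rdname predictSeverity
#' @export
setMethod("predictSeverity", "SeverityModel",
          function(model, object, observed = NULL) {
  M <- if (is(object, "PeptideExperiment")) intensityMatrix(object) else
    as.matrix(object)
  miss <- setdiff(model@peptideIds, rownames(M))
  if (length(miss))
    stopf("matrix is missing model peptide(s): %s",
          paste(miss, collapse = ", "))
  X <- t(log1p(M[model@peptideIds, , drop = FALSE]))
  X <- sweep(sweep(X, 2, model@center), 2, model@scale, "/")
  pred <- setNames(model@intercept + as.numeric(X %*% model@weights),
                   colnames(M))
  if (is.null(observed)) return(pred)
  observed <- observed[names(pred)]
  pe <- cor.test(pred, observed)
  sp <- suppressWarnings(cor.test(pred, observed, method = "spearman",
                                  exact = FALSE))
  list(predicted = pred,
       pearson = list(r = unname(pe$estimate), p = pe$p.value),
       spearman = list(r = unname(sp$estimate), p = sp$p.value))
})

setMethod("show", "SeverityModel", function(object) {
  cat(sprintf("SeverityModel: %d screened peptides (%s, lambda = %.3g)\n",
              length(object@peptideIds), object@method, object@lambda))
  cat(sprintf("  training r: Pearson %.3f, Spearman %.3f\n",
              object@trainingCor["pearson"],
              object@trainingCor["spearman"]))
})
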