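## Small in-code fixtures shared across test files.

## A tiny peak table with two samples of three peaks each.
tinyPeakDf <- function() {
  data.frame(
    sampleId = rep(c("S1", "S2"), each = 3),
    mass = c(1000.5, 2000.25, 8000.125, 1000.5, 2000.25, 8000.125),
    time = c(20, 25, 30, 20.1, 25.1, 30.1),
    intensity = c(100, 200, 300, 110, 190, 310),
    stringsAsFactors = FALSE)
}

## Build a PeptideExperiment directly from an intensity matrix.
peFromMatrix <- function(M, diagnosis = NULL) {
  if (is.null(rownames(M)) && nrow(M))
    rownames(M) <- sprintf("P%03d", seq_len(nrow(M)))
  if (is.null(colnames(M))) colnames(M) <- sprintf("S%03d", seq_len(ncol(M)))
  catalog <- data.frame(peptideId = rownames(M) %||% character(0),
                        mass = 1000 + seq_len(nrow(M)),
                        time = 20 + seq_len(nrow(M)) %% 20)
  samples <- data.frame(sampleId = colnames(M),
                        diagnosis = diagnosis %||%
                          rep("unknown", ncol(M)))
  PeptideExperiment(M, catalog, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Separable two-class feature matrix for SVM tests: peptides x samples.
separableMatrix <- function(nCase = 10, nCtrl = 10, p = 2, gap = 3,
                            seed = 1) {
  set.seed(seed)
  X <- cbind(matrix(exp(rnorm(p * nCase, 2 + gap, 0.3)), p, nCase),
             matrix(exp(rnorm(p * nCtrl, 2, 0.3)), p, nCtrl))
  rownames(X) <- sprintf("P%03d", seq_len(p))
  colnames(X) <- c(sprintf("A%02d", seq_len(nCase)),
                   sprintf("C%02d", seq_len(nCtrl)))
  list(M = X, labels = setNames(rep(c("ADPKD", "healthy"),
                                    c(nCase, nCtrl)), colnames(X)))
}

## Brute-force BH: min over tails of (m/j) p_(j), capped at 1.
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i)
    min(1, min((m / seq(i, m)) * ps[seq(i, m)])), numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

## Exhaustive concordant-pair AUC with half-credit ties.
pairCountAuc <- function(scores, case) {
  x <- scores[case]; y <- scores[!case]
  comp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(comp)
}
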