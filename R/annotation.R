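## Sequence alphabet: the 20 residues (upper case) plus lower-case
## modification letters p (hydroxyproline), k (hydroxylysine) and
## m (oxidized methionine).
.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.MODS <- c("p", "k", "m")

#' Net peptide charge at pH 2
#'
#' At pH 2 the carboxyl groups are protonated (neutral) while the
#' N-terminal amine and the basic side chains carry a positive charge, so
#' the net charge is 1 (N-terminus) + #R + #K + #H. Hydroxylysine
#' (written `k`) counts as lysine; hydroxyproline (`p`) and oxidized
#' methionine (`m`) are uncharged. Histidine is counted fully charged
#' (side-chain pKa ~ 6, far above pH 2).
#'
#' @param sequence amino-acid string (may contain `p`, `k`, `m`).
#' @return integer net charge.
#' @export
#' @examples
#' chargeAtPh2("IDQSRVLNLGPITR")  # 3: N-terminus + two arginines
chargeAtPh2 <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% c(.AA, .MODS))
  if (length(bad))
    stopf("unknown residue '%s' at position %d", chars[bad[1]], bad[1])
  1L + sum(chars %in% c("R", "K", "k", "H"))
}

#' Cleavage-site overlap between two annotated peptide sets
#'
#' Two peptides overlap when they derive from the same parent protein and
#' their position intervals intersect; they share a terminus when, in
#' addition, their start positions are equal (common N-terminal cleavage
#' site) or their stop positions are equal (common C-terminal site).
#' Peptides lacking parent or position annotation are skipped and
#' counted.
#'
#' @param setA,setB data.frames with columns `sequence` (optional),
#'   `parentProtein`, `start`, `stop`.
#' @return list with `nOverlap` (overlapping pairs), `nSharedTerminus`
#'   (overlapping pairs sharing an N- or C-terminal cleavage site),
#'   `pairs` (data.frame of the overlapping pairs), `nSkippedA`,
#'   `nSkippedB`.
#' @export
cleavageOverlap <- function(setA, setB) {
  need <- c("parentProtein", "start", "stop")
  assertColumns(setA, need, "setA"); assertColumns(setB, need, "setB")
  okA <- !is.na(setA$parentProtein) & is.finite(setA$start) &
    is.finite(setA$stop)
  okB <- !is.na(setB$parentProtein) & is.finite(setB$start) &
    is.finite(setB$stop)
  a <- setA[okA, , drop = FALSE]; b <- setB[okB, , drop = FALSE]
  pairs <- list()
  for (i in seq_len(nrow(a))) {
    hit <- which(b$parentProtein == a$parentProtein[i] &
                   b$start <= a$stop[i] & b$stop >= a$start[i])
    for (j in hit) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        indexA = which(okA)[i], indexB = which(okB)[j],
        parentProtein = a$parentProtein[i],
        sharedN = a$start[i] == b$start[j],
        sharedC = a$stop[i] == b$stop[j], stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(indexA = integer(), indexB = integer(),
               parentProtein = character(), sharedN = logical(),
               sharedC = logical())
  list(nOverlap = nrow(pairs),
       nSharedTerminus = sum(pairs$sharedN | pairs$sharedC),
       pairs = pairs, nSkippedA = sum(!okA), nSkippedB = sum(!okB))
}

#' Fit the charge/mass to migration-time calibration
#'
#' CE migration time correlates strictly with peptide charge at pH 2 and
#' with mass; the calibration is a least-squares fit of
#' `ln(time) = b0 + b1 ln(mass) + b2 ln(charge)` on at least 10 calibrant
#' peptides of known sequence.
#'
#' @param calibrants data.frame with `mass`, `charge`, `time`.
#' @return list with `coefficients` (b0, b1, b2) and `residualSd`.
#' @seealso [predictMigrationTime()]
#' @export
fitMigrationModel <- function(calibrants) {
  assertColumns(calibrants, c("mass", "charge", "time"), "calibrants")
  if (nrow(calibrants) < 10L) stopf("need >= 10 calibrant peptides")
  if (any(calibrants$charge < 1)) stopf("charge must be >= 1")
  fit <- lm(log(time) ~ log(mass) + log(charge), data = calibrants)
  list(coefficients = setNames(coef(fit), c("b0", "b1", "b2")),
       residualSd = sqrt(mean(fit$residuals^2)))
}

#' Predict CE migration time and flag implausible sequence assignments
#'
#' Predicts migration time from mass and charge under a fitted
#' calibration; a (peptide, observed time) pair is implausible when the
#' deviation exceeds `maxDeviation` (the +/- 1 min acceptance rule).
#'
#' @param mass monoisotopic mass (Da).
#' @param charge net charge at pH 2 (>= 1).
#' @param calibration result of [fitMigrationModel()].
#' @param observed optional observed times; when given, the result also
#'   carries `deviation` and `plausible`.
#' @param maxDeviation acceptance threshold in min (default 1).
#' @return data.frame with `predicted` (and `observed`, `deviation`,
#'   `plausible` when observed times are given).
#' @export
predictMigrationTime <- function(mass, charge, calibration,
                                 observed = NULL, maxDeviation = 1) {
  if (any(charge < 1)) stopf("charge must be >= 1")
  b <- calibration$coefficients
  pred <- exp(b["b0"] + b["b1"] * log(mass) + b["b2"] * log(charge))
  out <- data.frame(predicted = unname(pred))
  if (!is.null(observed)) {
    out$observed <- observed
    out$deviation <- observed - out$predicted
    out$plausible <- abs(out$deviation) <= maxDeviation
  }
  out
}

#' Read a peptide annotation table
#'
#' @param path TSV with columns `peptide_id`, `sequence`,
#'   `parent_protein`, `start`, `stop`.
#' @return data.frame with camelCase columns as used by
#'   [cleavageOverlap()].
#' @export
readAnnotationTable <- function(path) {
  df <- .readDelim(path)
  assertColumns(df, c("peptide_id", "sequence", "parent_protein",
                      "start", "stop"), "annotation table")
  data.frame(peptideId = as.character(df$peptide_id),
             sequence = df$sequence, parentProtein = df$parent_protein,
             start = df$start, stop = df$stop, stringsAsFactors = FALSE)
}
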