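#' Construct a PeptideExperiment
#'
#' @param intensity numeric matrix, peptides x samples (0 = not detected);
#'   rownames are peptide ids, colnames sample ids.
#' @param catalog data.frame with one row per peptide: `peptideId`, `mass`
#'   (Da), `time` (min) and optionally `detectionCount`.
#' @param samples optional per-sample metadata (`sampleId`, `diagnosis`,
#'   ...); matched to `colnames(intensity)`.
#' @param tolerances optional list of matching tolerances, recorded as
#'   provenance metadata.
#' @return A [PeptideExperiment-class].
#' @export
PeptideExperiment <- function(intensity, catalog, samples = NULL,
                              tolerances = NULL) {
  assertColumns(catalog, c("peptideId", "mass", "time"), "catalog")
  catalog$peptideId <- as.character(catalog$peptideId)
  if (is.null(rownames(intensity))) rownames(intensity) <- catalog$peptideId
  if (!identical(rownames(intensity), catalog$peptideId)) {
    idx <- match(rownames(intensity), catalog$peptideId)
    if (anyNA(idx)) stopf("catalog does not cover all matrix rows")
    catalog <- catalog[idx, , drop = FALSE]
  }
  if (!"detectionCount" %in% names(catalog))
    catalog$detectionCount <- as.integer(rowSums(intensity > 0))
  rd <- S4Vectors::DataFrame(catalog[setdiff(names(catalog), "peptideId")],
                             row.names = catalog$peptideId)
  if (is.null(samples)) {
    cd <- S4Vectors::DataFrame(diagnosis = rep("unknown", ncol(intensity)),
                               row.names = colnames(intensity))
  } else {
    samples$sampleId <- as.character(samples$sampleId)
    idx <- match(colnames(intensity), samples$sampleId)
    if (anyNA(idx)) stopf("metadata missing for sample(s): %s",
                          paste(colnames(intensity)[is.na(idx)],
                                collapse = ", "))
    sm <- samples[idx, setdiff(names(samples), "sampleId"), drop = FALSE]
    cd <- S4Vectors::DataFrame(sm, row.names = colnames(intensity))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity), rowData = rd, colData = cd,
    metadata = list(tolerances = tolerances))
  new("PeptideExperiment", se)
}

#' Accessors for PeptideExperiment
#'
#' `intensityMatrix()` returns the normalized intensity assay (peptides x
#' samples, 0 = not detected); `peptideCatalog()` the consensus catalog as
#' a data.frame (`peptideId`, `mass`, `time`, `detectionCount`);
#' `diagnosisLabels()` the per-sample diagnosis factor.
#'
#' @param object a [PeptideExperiment-class]
#' @export
setGeneric("intensityMatrix",
           function(object) standardGeneric("intensityMatrix"))

#' @rdname intensityMatrix
#' @export
setMethod("intensityMatrix", "PeptideExperiment", function(object)
  SummarizedExperiment::assay(object, "intensity"))

#' @rdname intensityMatrix
#' @export
setGeneric("peptideCatalog",
           function(object) standardGeneric("peptideCatalog"))

#' @rdname intensityMatrix
#' @export
setMethod("peptideCatalog", "PeptideExperiment", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  data.frame(peptideId = rownames(object), as.data.frame(rd),
             stringsAsFactors = FALSE, row.names = NULL)
})

#' @rdname intensityMatrix
#' @export
setGeneric("diagnosisLabels",
           function(object) standardGeneric("diagnosisLabels"))

#' @rdname intensityMatrix
#' @export
setMethod("diagnosisLabels", "PeptideExperiment", function(object)
  setNames(as.character(SummarizedExperiment::colData(object)$diagnosis),
           colnames(object)))

setMethod("show", "PeptideExperiment", function(object) {
  callNextMethod()
  a <- intensityMatrix(object)
  if (length(a))
    cat(sprintf("detection: %.1f%% of entries nonzero\n",
                100 * mean(a > 0)))
})

#' Write a PeptideExperiment as wide TSV plus sidecar catalog
#'
#' The intensity matrix is written samples-by-peptides (one row per
#' sample, first column `sample_id`), the catalog as a sidecar TSV
#' (`peptide_id`, `mass`, `time`, `detection_count`). [readMatrix()]
#' reproduces the object exactly to the written precision.
#'
#' @param object a [PeptideExperiment-class]
#' @param path output matrix TSV.
#' @param catalogPath sidecar catalog TSV (default: `path` with a
#'   `.catalog.tsv` suffix).
#' @param overwrite refuse to clobber existing files unless TRUE.
#' @return `path`, invisibly.
#' @export
writeMatrix <- function(object, path,
                        catalogPath = sub("(\\.[^.]+)?$", ".catalog.tsv",
                                          path),
                        overwrite = FALSE) {
  stopifnot(is(object, "PeptideExperiment"))
  hit <- c(path, catalogPath)[file.exists(c(path, catalogPath))]
  if (!overwrite && length(hit))
    stopf("refusing to overwrite existing file(s): %s (set overwrite = TRUE)",
          paste(hit, collapse = ", "))
  m <- t(intensityMatrix(object))
  wide <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat <- peptideCatalog(object)
  out <- data.frame(peptide_id = cat$peptideId, mass = cat$mass,
                    time = cat$time,
                    detection_count = cat$detectionCount)
  write.table(out, catalogPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a PeptideExperiment written by writeMatrix
#'
#' @param path matrix TSV (samples x peptides).
#' @param catalogPath sidecar catalog TSV.
#' @param metadataPath optional per-sample metadata TSV (`sample_id`,
#'   `diagnosis`, ...).
#' @return A [PeptideExperiment-class].
#' @export
readMatrix <- function(path,
                       catalogPath = sub("(\\.[^.]+)?$", ".catalog.tsv",
                                         path),
                       metadataPath = NULL) {
  wide <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  assertColumns(wide, "sample_id", "matrix file")
  cat <- read.delim(catalogPath, stringsAsFactors = FALSE)
  assertColumns(cat, c("peptide_id", "mass", "time"), "catalog file")
  ids <- as.character(wide$sample_id)
  m <- as.matrix(wide[setdiff(names(wide), "sample_id")])
  if (!nrow(m)) m <- matrix(numeric(), 0, ncol(m),
                            dimnames = list(NULL, colnames(m)))
  rownames(m) <- ids
  catalog <- data.frame(peptideId = as.character(cat$peptide_id),
                        mass = cat$mass, time = cat$time,
                        stringsAsFactors = FALSE)
  if ("detection_count" %in% names(cat))
    catalog$detectionCount <- as.integer(cat$detection_count)
  m <- t(m)[catalog$peptideId, , drop = FALSE]
  samples <- NULL
  if (!is.null(metadataPath)) {
    md <- .readDelim(metadataPath)
    assertColumns(md, c("sample_id", "diagnosis"), "metadata table")
    names(md)[names(md) == "sample_id"] <- "sampleId"
    samples <- md
  }
  PeptideExperiment(m, catalog, samples)
}
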