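## Canonical peak ordering: sample, then mass, then time, then intensity.
.canonicalPeaks <- function(peaks) {
  if (!nrow(peaks)) return(peaks)
  o <- order(peaks$sampleId, peaks$mass, peaks$time, peaks$intensity)
  p <- peaks[o, c("sampleId", "mass", "time", "intensity"), drop = FALSE]
  rownames(p) <- NULL
  p
}

.emptyTkv <- function() {
  data.frame(sampleId = character(), timeYears = numeric(),
             tkvMl = numeric(), stringsAsFactors = FALSE)
}

#' Construct a PeakSet
#'
#' @param peaks data.frame with columns `sampleId`, `mass` (Da), `time`
#'   (min), `intensity` (> 0).
#' @param samples per-sample metadata data.frame (`sampleId`, `diagnosis`,
#'   optionally `age`, `sex`, `genotype`, `height`, `egfr`). If omitted, a
#'   minimal table with diagnosis `"unknown"` is derived from the peaks.
#' @param tkv optional long-format TKV table (`sampleId`, `timeYears`,
#'   `tkvMl`).
#' @return A [PeakSet-class] with peaks in canonical order.
#' @export
PeakSet <- function(peaks, samples = NULL, tkv = NULL) {
  assertColumns(peaks, c("sampleId", "mass", "time", "intensity"),
                "peak table")
  peaks$sampleId <- as.character(peaks$sampleId)
  if (is.null(samples)) {
    ids <- unique(peaks$sampleId)
    samples <- data.frame(sampleId = ids,
                          diagnosis = rep("unknown", length(ids)),
                          stringsAsFactors = FALSE)
  }
  samples$sampleId <- as.character(samples$sampleId)
  if (is.null(tkv)) tkv <- .emptyTkv() else
    tkv$sampleId <- as.character(tkv$sampleId)
  new("PeakSet", peaks = .canonicalPeaks(peaks), samples = samples,
      tkv = tkv)
}

#' @describeIn PeakSet number of samples in the cohort
#' @param x,object a `PeakSet`
#' @export
setMethod("length", "PeakSet", function(x) nrow(x@samples))

#' Accessors for PeakSet components
#'
#' `peakTable()` returns the peak records, `sampleData()` the per-sample
#' metadata, `tkvSeries()` the long-format TKV measurements, and
#' `sampleIds()` the sample identifiers.
#'
#' @param object a [PeakSet-class]
#' @return the corresponding data.frame (or character vector of ids).
#' @export
setGeneric("peakTable", function(object) standardGeneric("peakTable"))

#' @rdname peakTable
#' @export
setMethod("peakTable", "PeakSet", function(object) object@peaks)

#' @rdname peakTable
#' @export
setGeneric("sampleData", function(object) standardGeneric("sampleData"))

#' @rdname peakTable
#' @export
setMethod("sampleData", "PeakSet", function(object) object@samples)

#' @rdname peakTable
#' @export
setGeneric("tkvSeries", function(object) standardGeneric("tkvSeries"))

#' @rdname peakTable
#' @export
setMethod("tkvSeries", "PeakSet", function(object) object@tkv)

#' @rdname peakTable
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname peakTable
#' @export
setMethod("sampleIds", "PeakSet", function(object) object@samples$sampleId)

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet with", nrow(object@samples), "samples and",
      nrow(object@peaks), "peaks\n")
  if (nrow(object@peaks)) {
    cat(sprintf("  mass range: %.1f-%.1f Da; time range: %.1f-%.1f min\n",
                min(object@peaks$mass), max(object@peaks$mass),
                min(object@peaks$time), max(object@peaks$time)))
  }
  dx <- table(object@samples$diagnosis)
  cat("  diagnosis:", paste(sprintf("%s (%d)", names(dx), dx),
                            collapse = ", "), "\n")
})

#' Subset a PeakSet to a set of samples
#'
#' @param x a [PeakSet-class]
#' @param i character vector of sample ids (or logical/integer index into
#'   `sampleIds(x)`).
#' @param j,...,drop ignored.
#' @export
setMethod("[", "PeakSet", function(x, i, j, ..., drop = FALSE) {
  ids <- if (is.character(i)) i else sampleIds(x)[i]
  miss <- setdiff(ids, sampleIds(x))
  if (length(miss))
    stopf("unknown sample id(s): %s", paste(miss, collapse = ", "))
  PeakSet(x@peaks[x@peaks$sampleId %in% ids, , drop = FALSE],
          x@samples[match(ids, x@samples$sampleId), , drop = FALSE],
          x@tkv[x@tkv$sampleId %in% ids, , drop = FALSE])
})

.readDelim <- function(path) {
  ## sniff the delimiter from the header line (tab or comma)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read deconvolved peak lists from a delimited file
#'
#' Parses a tab- or comma-separated peak table (header required; columns
#' `sample_id`, `mass`, `time`, `intensity`) into a [PeakSet-class], one
#' peak list per distinct sample, with peaks in ascending mass order.
#' Metadata and TKV side files, when given, are joined by sample id.
#'
#' @param path peak table file.
#' @param metadataPath optional per-sample metadata file (`sample_id`,
#'   `diagnosis`, `age`, `sex`, `genotype`, `height`, `egfr`).
#' @param tkvPath optional long-format TKV file (`sample_id`, `time_years`,
#'   `tkv_ml`).
#' @return A [PeakSet-class].
#' @seealso [writePeakTable()]
#' @export
readPeakTable <- function(path, metadataPath = NULL, tkvPath = NULL) {
  df <- .readDelim(path)
  need <- c("sample_id", "mass", "time", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("peak table '%s' is missing column(s): %s", path,
          paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$intensity) | df$intensity <= 0)
  if (length(bad))
    stopf("non-positive intensity at line %d of '%s'", bad[1] + 1L, path)
  peaks <- data.frame(sampleId = as.character(df$sample_id), mass = df$mass,
                      time = df$time, intensity = df$intensity,
                      stringsAsFactors = FALSE)
  samples <- NULL
  if (!is.null(metadataPath)) {
    md <- .readDelim(metadataPath)
    assertColumns(md, c("sample_id", "diagnosis"), "metadata table")
    names(md)[names(md) == "sample_id"] <- "sampleId"
    samples <- md
  }
  tkv <- NULL
  if (!is.null(tkvPath)) {
    tv <- .readDelim(tkvPath)
    assertColumns(tv, c("sample_id", "time_years", "tkv_ml"), "TKV table")
    tkv <- data.frame(sampleId = as.character(tv$sample_id),
                      timeYears = tv$time_years, tkvMl = tv$tkv_ml,
                      stringsAsFactors = FALSE)
  }
  PeakSet(peaks, samples, tkv)
}

#' Write a PeakSet to delimited files
#'
#' Writes the canonical peak table (`sample_id`, `mass`, `time`,
#' `intensity`) as TSV; round-trips through [readPeakTable()] to the
#' written precision.
#'
#' @param object a [PeakSet-class]
#' @param path output peak table path.
#' @param metadataPath,tkvPath optional side-file paths for the metadata
#'   and TKV tables.
#' @param overwrite refuse to clobber existing files unless TRUE.
#' @return `path`, invisibly.
#' @export
writePeakTable <- function(object, path, metadataPath = NULL,
                           tkvPath = NULL, overwrite = FALSE) {
  stopifnot(is(object, "PeakSet"))
  targets <- c(path, metadataPath, tkvPath)
  hit <- targets[file.exists(targets)]
  if (!overwrite && length(hit))
    stopf("refusing to overwrite existing file(s): %s (set overwrite = TRUE)",
          paste(hit, collapse = ", "))
  p <- object@peaks
  out <- data.frame(sample_id = p$sampleId,
                    mass = sprintf("%.6f", p$mass),
                    time = sprintf("%.6f", p$time),
                    intensity = sprintf("%.6f", p$intensity))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadataPath)) {
    md <- object@samples
    names(md)[names(md) == "sampleId"] <- "sample_id"
    write.table(md, metadataPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(tkvPath)) {
    tv <- object@tkv
    out <- data.frame(sample_id = tv$sampleId, time_years = tv$timeYears,
                      tkv_ml = tv$tkvMl)
    write.table(out, tkvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
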