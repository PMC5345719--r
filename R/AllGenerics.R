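#' Number of markers
#' @param x a SiteMatrix or ABHMatrix
#' @return integer marker count
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' Number of samples / individuals
#' @param x a SiteMatrix or ABHMatrix
#' @return integer sample count
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Marker table
#' @param x a SiteMatrix, ABHMatrix or GeneticMap
#' @return data.frame of marker metadata
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname nMarkers
#' @export
setMethod("nMarkers", "SiteMatrix", function(x) nrow(x@markers))
#' @rdname nMarkers
#' @export
setMethod("nMarkers", "ABHMatrix", function(x) nrow(x@markers))

#' @rdname nSamples
#' @export
setMethod("nSamples", "SiteMatrix", function(x) nrow(x@samples))
#' @rdname nSamples
#' @export
setMethod("nSamples", "ABHMatrix", function(x) nrow(x@codes))

#' @rdname markerInfo
#' @export
setMethod("markerInfo", "SiteMatrix", function(x) x@markers)
#' @rdname markerInfo
#' @export
setMethod("markerInfo", "ABHMatrix", function(x) x@markers)
#' @rdname markerInfo
#' @export
setMethod("markerInfo", "GeneticMap", function(x) x@table)

#' Sample table of a SiteMatrix
#' @param x a SiteMatrix
#' @return data.frame with columns id, role
#' @export
sampleInfo <- function(x) {
  stopifnot(is(x, "SiteMatrix"))
  x@samples
}

#' ABH code matrix (individuals x markers)
#' @param x an ABHMatrix
#' @return character matrix with entries A/B/H/N
#' @export
abhCodes <- function(x) {
  stopifnot(is(x, "ABHMatrix"))
  x@codes
}

#' Map table of a GeneticMap
#' @param x a GeneticMap
#' @return data.frame with columns marker, chrom, cM
#' @export
mapTable <- function(x) {
  stopifnot(is(x, "GeneticMap"))
  x@table
}

#' Per-chromosome and total genetic map length
#' @param x a GeneticMap
#' @return named numeric vector of chromosome lengths in cM
#' @export
chromLengths <- function(x) {
  stopifnot(is(x, "GeneticMap"))
  vapply(split(x@table$cM, x@table$chrom), max, numeric(1))
}

#' @rdname chromLengths
#' @export
totalMapLength <- function(x) sum(chromLengths(x))

#' LOD profile of a scan
#' @param x a QTLScanResult
#' @return data.frame with columns chrom, pos, lod
#' @export
lodProfile <- function(x) {
  stopifnot(is(x, "QTLScanResult"))
  x@profile
}

#' Significant peaks of a scan
#' @param x a QTLScanResult
#' @return data.frame of peaks (possibly empty)
#' @export
scanPeaks <- function(x) {
  stopifnot(is(x, "QTLScanResult"))
  x@peaks
}

setMethod("show", "SiteMatrix", function(object) {
  roles <- table(object@samples$role)
  cat("SiteMatrix:", nrow(object@markers), "sites x",
      nrow(object@samples), "samples\n")
  cat("  roles:", paste(names(roles), roles, sep = "=", collapse = ", "), "\n")
  cat("  chromosomes:", length(unique(object@markers$chrom)), "\n")
  if (nrow(object@filterLog))
    cat("  filter stages applied:",
        paste(object@filterLog$stage, collapse = " -> "), "\n")
})

setMethod("show", "ABHMatrix", function(object) {
  comp <- table(factor(object@codes, levels = ABH_CODES))
  frac <- round(100 * comp / sum(comp), 2)
  cat("ABHMatrix:", nrow(object@codes), "individuals x",
      ncol(object@codes), "markers (positions in", object@units, ")\n")
  cat("  composition:",
      paste(names(frac), paste0(frac, "%"), sep = "=", collapse = ", "), "\n")
})

setMethod("show", "GeneticMap", function(object) {
  len <- chromLengths(object)
  cat("GeneticMap:", nrow(object@table), "markers on", length(len),
      "chromosomes, total", round(sum(len), 1), "cM\n")
})

setMethod("show", "QTLScanResult", function(object) {
  cat("QTLScanResult:", nrow(object@profile), "positions, max LOD",
      round(max(object@profile$lod), 2), "\n")
  if (!is.na(object@threshold))
    cat("  genome-wide threshold (alpha=", object@alpha, "): ",
        round(object@threshold, 2), "\n", sep = "")
  if (nrow(object@peaks)) {
    cat("  peaks:\n")
    print(object@peaks)
  }
})
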