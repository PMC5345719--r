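#' @import methods
NULL

ABH_CODES <- c("A", "B", "H", "N")

#' SiteMatrix: variant sites by samples with per-allele read depths
#'
#' Container for post-SNP-calling genotype tables from a biparental GBS
#' experiment. Rows are variant sites (markers), columns are samples. Each
#' sample carries a role: a replicate of parent 1 (\code{parent1_rep}), a
#' replicate of parent 2 (\code{parent2_rep}), or an F2 individual
#' (\code{f2}). Genotypes are stored as two unordered allele matrices; read
#' depths are stored per REF/ALT allele as reported by the caller.
#'
#' Coordinates are 1-based inclusive. Markers are kept sorted by
#' (chromosome, position) and (chromosome, position) pairs are unique.
#'
#' @slot markers data.frame with columns \code{id}, \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, and (after parental-consistency filtering)
#'   \code{parentA}, \code{parentB} consensus alleles.
#' @slot samples data.frame with columns \code{id}, \code{role}.
#' @slot geno1,geno2 character matrices (sites x samples) holding the two
#'   alleles of each call; \code{NA} in both marks a missing call. The pair
#'   is unordered (G/T and T/G are the same call).
#' @slot depthRef,depthAlt integer matrices of reads supporting the REF and
#'   ALT allele (zero when the source format carries no depths).
#' @slot filterLog data.frame audit trail: one row per filter stage, in
#'   execution order, with sites in/out, calls masked and parameters.
#' @export
setClass("SiteMatrix",
  slots = c(
    markers = "data.frame",
    samples = "data.frame",
    geno1 = "matrix",
    geno2 = "matrix",
    depthRef = "matrix",
    depthAlt = "matrix",
    filterLog = "data.frame"
  )
)

setValidity("SiteMatrix", function(object) {
  mk <- object@markers
  sm <- object@samples
  msgs <- character(0)
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(mk)))
    msgs <- c(msgs, paste("markers must have columns:", paste(need, collapse = ", ")))
  if (!all(c("id", "role") %in% names(sm)))
    msgs <- c(msgs, "samples must have columns id, role")
  if (length(msgs) == 0) {
    if (any(!sm$role %in% c("parent1_rep", "parent2_rep", "f2")))
      msgs <- c(msgs, "sample roles must be parent1_rep, parent2_rep or f2")
    if (any(mk$pos < 1)) msgs <- c(msgs, "positions must be >= 1")
    if (anyDuplicated(paste(mk$chrom, mk$pos)))
      msgs <- c(msgs, "duplicated (chromosome, position) pairs")
    if (any(!is.na(mk$ref) & !is.na(mk$alt) & mk$ref == mk$alt))
      msgs <- c(msgs, "ref and alt alleles must differ")
    dims <- vapply(list(object@geno1, object@geno2, object@depthRef,
                        object@depthAlt),
                   function(m) identical(dim(m), c(nrow(mk), nrow(sm))),
                   logical(1))
    if (!all(dims)) msgs <- c(msgs, "matrix dimensions inconsistent with markers/samples")
    if (!identical(order(mk$chrom, mk$pos), seq_len(nrow(mk))))
      msgs <- c(msgs, "markers must be sorted by (chromosome, position)")
    miss1 <- is.na(object@geno1)
    miss2 <- is.na(object@geno2)
    if (any(miss1 != miss2))
      msgs <- c(msgs, "a call is missing iff both alleles are missing")
    if (any(object@depthRef < 0, na.rm = TRUE) ||
        any(object@depthAlt < 0, na.rm = TRUE))
      msgs <- c(msgs, "read depths must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' ABHMatrix: individuals by ordered markers coded A/B/H/N
#'
#' The substrate of imputation, error correction and mapping. A codes a
#' parent-1 homozygote, B a parent-2 homozygote, H a heterozygote, N a
#' missing genotype. Markers are grouped by chromosome and sorted by
#' position; positions may be physical (bp) or genetic (cM), recorded in
#' \code{units}.
#'
#' @slot codes character matrix (individuals x markers), entries in
#'   \{A,B,H,N\}; dimnames carry individual and marker ids.
#' @slot markers data.frame with columns \code{id}, \code{chrom}, \code{pos}.
#' @slot units "bp" or "cM".
#' @export
setClass("ABHMatrix",
  slots = c(codes = "matrix", markers = "data.frame", units = "character")
)

setValidity("ABHMatrix", function(object) {
  mk <- object@markers
  msgs <- character(0)
  if (!all(c("id", "chrom", "pos") %in% names(mk)))
    msgs <- c(msgs, "markers must have columns id, chrom, pos")
  if (ncol(object@codes) != nrow(mk))
    msgs <- c(msgs, "codes columns must match marker count")
  if (length(msgs) == 0) {
    if (!all(object@codes %in% ABH_CODES))
      msgs <- c(msgs, "codes must be A, B, H or N")
    if (!identical(order(mk$chrom, mk$pos), seq_len(nrow(mk))))
      msgs <- c(msgs, "markers must be grouped by chromosome and sorted by position")
    if (!object@units %in% c("bp", "cM"))
      msgs <- c(msgs, "units must be 'bp' or 'cM'")
  }
  if (length(msgs)) msgs else TRUE
})

#' GeneticMap: per-chromosome marker positions in centiMorgans
#'
#' @slot table data.frame with columns \code{marker}, \code{chrom},
#'   \code{cM}; within each chromosome positions are non-decreasing and the
#'   first marker sits at 0 cM.
#' @export
setClass("GeneticMap", slots = c(table = "data.frame"))

setValidity("GeneticMap", function(object) {
  tb <- object@table
  if (!all(c("marker", "chrom", "cM") %in% names(tb)))
    return("table must have columns marker, chrom, cM")
  bad <- vapply(split(tb$cM, tb$chrom), function(p) {
    length(p) > 0 && (is.unsorted(p) || abs(p[1]) > 1e-9)
  }, logical(1))
  if (any(bad))
    return("cM positions must be non-decreasing and start at 0 per chromosome")
  TRUE
})

#' QTLScanResult: LOD profile on a cM grid with threshold and peaks
#'
#' @slot profile data.frame with columns \code{chrom}, \code{pos} (cM),
#'   \code{lod}.
#' @slot threshold genome-wide LOD significance threshold (NA until
#'   permutations are run).
#' @slot alpha significance level the threshold corresponds to.
#' @slot peaks data.frame of significant peaks: chromosome, peak position,
#'   LOD, credible-interval bounds, percent variance, additive and dominance
#'   effects.
#' @export
setClass("QTLScanResult",
  slots = c(profile = "data.frame", threshold = "numeric",
            alpha = "numeric", peaks = "data.frame"),
  prototype = list(threshold = NA_real_, alpha = NA_real_,
                   peaks = data.frame())
)

setValidity("QTLScanResult", function(object) {
  pf <- object@profile
  if (!all(c("chrom", "pos", "lod") %in% names(pf)))
    return("profile must have columns chrom, pos, lod")
  if (any(pf$lod < -1e-9, na.rm = TRUE)) return("LOD must be non-negative")
  TRUE
})

#' CorrectionParams: thresholds of the two error-correction passes
#'
#' \code{hetRunMax} is the longest homozygous-or-missing run flanked by
#' heterozygous calls that is rewritten to H (the heterozygote-undercall
#' pass). \code{stretchRunMax} is the longest single-genotype run flanked by
#' matching neighbours that is rewritten to the flanking genotype. The
#' application order is fixed: impute, then het-correct, then
#' stretch-correct.
#'
#' @slot hetRunMax integer >= 1, default 4.
#' @slot stretchRunMax integer >= 1, default 1.
#' @export
setClass("CorrectionParams",
  slots = c(hetRunMax = "numeric", stretchRunMax = "numeric"),
  prototype = list(hetRunMax = 4, stretchRunMax = 1)
)

setValidity("CorrectionParams", function(object) {
  if (object@hetRunMax < 1 || object@stretchRunMax < 1)
    return("run-length thresholds must be >= 1")
  TRUE
})

#' F2SimConfig: configuration of the F2 cross simulator
#'
#' Defaults encode the simulation design used throughout: twelve chromosomes
#' of 140, 115, 130, 110, 100, 105, 110, 100, 75, 80, 100 and 105 cM
#' (a rice F2 microsatellite map), additive QTL effects of 0.5 and residual
#' phenotype standard deviation 1.
#'
#' @slot chrLengths chromosome lengths in cM.
#' @slot nMarkers total marker count, allocated to chromosomes in proportion
#'   to length.
#' @slot spacing "equal" (both chromosome ends included) or "random".
#' @slot nIndividuals F2 population size.
#' @slot qtl data.frame with columns \code{chrom}, \code{pos} (cM),
#'   \code{add}, \code{dom}; may have zero rows.
#' @slot residualSD residual phenotype standard deviation.
#' @slot seed integer seed.
#' @export
setClass("F2SimConfig",
  slots = c(chrLengths = "numeric", nMarkers = "numeric",
            spacing = "character", nIndividuals = "numeric",
            qtl = "data.frame", residualSD = "numeric", seed = "numeric"),
  prototype = list(
    chrLengths = c(140, 115, 130, 110, 100, 105, 110, 100, 75, 80, 100, 105),
    nMarkers = 200, spacing = "equal", nIndividuals = 200,
    qtl = data.frame(chrom = integer(0), pos = numeric(0),
                     add = numeric(0), dom = numeric(0)),
    residualSD = 1, seed = 1
  )
)

setValidity("F2SimConfig", function(object) {
  msgs <- character(0)
  if (any(object@chrLengths <= 0)) msgs <- c(msgs, "chromosome lengths must be > 0")
  if (object@nIndividuals < 1) msgs <- c(msgs, "nIndividuals must be >= 1")
  if (!object@spacing %in% c("equal", "random"))
    msgs <- c(msgs, "spacing must be 'equal' or 'random'")
  q <- object@qtl
  if (nrow(q)) {
    if (any(q$chrom < 1 | q$chrom > length(object@chrLengths)))
      msgs <- c(msgs, "QTL chromosome out of range")
    else if (any(q$pos < 0 | q$pos > object@chrLengths[q$chrom]))
      msgs <- c(msgs, "QTL position outside its chromosome")
  }
  if (length(msgs)) msgs else TRUE
})

#' GBSNoiseConfig: the GBS error model applied to clean genotypes
#'
#' Three independent mechanisms, in this order per cell: random missingness;
#' depth-dependent heterozygote undercalling (an H cell with simulated read
#' depth d is rewritten to A or B, equal odds, with probability
#' 2*(1/2)^d, the chance that all d reads sample one allele); and
#' systematically error-prone markers, which flip H to B and A to H at the
#' given per-cell rates (the co-occurring HBH/AHA error signature).
#'
#' @slot missingRate per-cell probability of N.
#' @slot depths integer read depths sampled uniformly per heterozygous call;
#'   a length-1 vector fixes the depth; empty disables undercalling.
#' @slot errorMarkerFraction fraction of markers designated error-prone.
#' @slot flipHtoB,flipAtoH per-cell flip rates at error-prone markers.
#' @export
setClass("GBSNoiseConfig",
  slots = c(missingRate = "numeric", depths = "numeric",
            errorMarkerFraction = "numeric", flipHtoB = "numeric",
            flipAtoH = "numeric"),
  prototype = list(missingRate = 0, depths = numeric(0),
                   errorMarkerFraction = 0, flipHtoB = 0.2, flipAtoH = 0.2)
)

setValidity("GBSNoiseConfig", function(object) {
  rates <- c(object@missingRate, object@errorMarkerFraction,
             object@flipHtoB, object@flipAtoH)
  if (any(rates < 0 | rates > 1)) return("rates must lie in [0, 1]")
  if (length(object@depths) && any(object@depths < 1))
    return("read depths must be >= 1")
  TRUE
})

#' EnzymeSpec: a restriction enzyme recognition sequence
#'
#' @slot name enzyme name.
#' @slot site recognition sequence, IUPAC codes.
#' @export
setClass("EnzymeSpec", slots = c(name = "character", site = "character"))

setValidity("EnzymeSpec", function(object) {
  if (!nzchar(object@site)) return("recognition sequence must be non-empty")
  ok <- strsplit(toupper(object@site), "")[[1]] %in%
    strsplit("ACGTRYSWKMBDHVN", "")[[1]]
  if (!all(ok)) return("recognition sequence must use IUPAC codes")
  TRUE
})

#' ErrorMotifCounts: the six-motif error census
#'
#' Counts of the window motifs HAH, HBH, AHA, BHB, ABA and BAB (a genotype
#' flanked on both sides by a different, equal genotype) per marker and per
#' individual.
#'
#' @slot perMarker integer matrix markers x 6 motifs.
#' @slot perIndividual integer matrix individuals x 6 motifs.
#' @export
setClass("ErrorMotifCounts",
  slots = c(perMarker = "matrix", perIndividual = "matrix")
)

MOTIFS <- c("HAH", "HBH", "AHA", "BHB", "ABA", "BAB")

setValidity("ErrorMotifCounts", function(object) {
  if (!identical(colnames(object@perMarker), MOTIFS) ||
      !identical(colnames(object@perIndividual), MOTIFS))
    return("motif columns must be HAH, HBH, AHA, BHB, ABA, BAB")
  if (any(object@perMarker < 0) || any(object@perIndividual < 0))
    return("counts must be non-negative")
  TRUE
})
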