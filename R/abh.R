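# ABH encoding and the haplotype-based imputation / error-correction core.
#
# The three passes exploit the long uniparental haplotype blocks of an F2
# population: genuine genotype changes come from crossovers, so very short
# runs interrupting a uniform block are far more likely to be errors than
# double recombination events. Each pass operates on the maximal runs of the
# *input* string (not the partially rewritten one), so results do not depend
# on scan direction, and chromosomes are processed independently.

#' Encode a filtered SiteMatrix as ABH genotypes
#'
#' Per F2 call: homozygous for the parent-1 consensus allele -> A,
#' homozygous for the parent-2 allele -> B, one of each -> H. Missing calls,
#' and calls carrying any allele that matches neither parent (attributable
#' to structural divergence between the parental genomes), become N.
#'
#' @param m a SiteMatrix after \code{\link{filterParentalConsistency}}
#' @return an \linkS4class{ABHMatrix} over the F2 individuals
#' @export
encodeABH <- function(m) {
  stopifnot(is(m, "SiteMatrix"))
  if (any(is.na(m@markers$parentA)))
    stop("site(s) lacking parental consensus: ",
         paste(utils::head(m@markers$id[is.na(m@markers$parentA)], 3),
               collapse = ", "))
  f2 <- which(m@samples$role == "f2")
  codes <- matrix("N", length(f2), nrow(m@markers),
                  dimnames = list(m@samples$id[f2], m@markers$id))
  for (i in seq_len(nrow(m@markers))) {
    a <- m@markers$parentA[i]; b <- m@markers$parentB[i]
    g1 <- m@geno1[i, f2]; g2 <- m@geno2[i, f2]
    codes[, i] <- ifelse(is.na(g1), "N",
                  ifelse(g1 == a & g2 == a, "A",
                  ifelse(g1 == b & g2 == b, "B",
                  ifelse((g1 == a & g2 == b) | (g1 == b & g2 == a), "H",
                         "N"))))
  }
  ABHMatrix(codes, m@markers[, c("id", "chrom", "pos")], units = "bp")
}

# apply a per-chromosome string transform f(character vector) to every
# individual x chromosome slice
.perChromApply <- function(g, f) {
  codes <- g@codes
  for (idx in split(seq_len(ncol(codes)), g@markers$chrom)) {
    if (length(idx) < 2) next
    block <- codes[, idx, drop = FALSE]
    codes[, idx] <- t(apply(block, 1, f))
  }
  g@codes <- codes
  g
}

.imputeRow <- function(x) {
  r <- rle(x)
  v <- r$values
  k <- length(v)
  if (k >= 3) {
    fill <- which(v == "N")
    fill <- fill[fill > 1 & fill < k]
    fill <- fill[v[fill - 1] == v[fill + 1]]
    if (length(fill)) {
      r$values[fill] <- v[fill - 1]
      x <- inverse.rle(r)
    }
  }
  x
}

#' Impute flanked missing genotypes
#'
#' Per individual and chromosome, every maximal run of N whose nearest
#' non-missing genotypes on both sides exist and are equal is replaced by
#' that genotype, regardless of run length. Runs with conflicting or absent
#' flanks (chromosome ends) are left unchanged. Never alters a non-missing
#' genotype.
#'
#' @param g an ABHMatrix (markers ordered by chromosome and position)
#' @return imputed ABHMatrix
#' @export
imputeFlankedMissing <- function(g) {
  stopifnot(is(g, "ABHMatrix"))
  .perChromApply(g, .imputeRow)
}

.hetCorrectRow <- function(x, hetRunMax) {
  isH <- x == "H"
  r <- rle(isH)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  for (j in seq_len(k)) {
    if (!r$values[j] && j > 1 && j < k && r$lengths[j] <= hetRunMax)
      x[starts[j]:ends[j]] <- "H"
  }
  x
}

#' Correct undercalled heterozygotes
#'
#' Per individual and chromosome, every maximal run consisting only of
#' homozygous or missing genotypes (A, B or N in any mixture), of length at
#' most \code{hetRunMax}, with an H immediately on both sides, is rewritten
#' to H. Such runs are the signature of heterozygote undercalling: at low
#' read depth all reads of a true heterozygote may sample one allele.
#'
#' @param g an ABHMatrix (conventionally after
#'   \code{\link{imputeFlankedMissing}})
#' @param hetRunMax longest run rewritten, default 4
#' @return corrected ABHMatrix
#' @export
correctUndercalledHet <- function(g, hetRunMax = 4) {
  stopifnot(is(g, "ABHMatrix"), hetRunMax >= 1)
  .perChromApply(g, function(x) .hetCorrectRow(x, hetRunMax))
}

.stretchCorrectRow <- function(x, stretchRunMax) {
  r <- rle(x)
  v <- r$values
  k <- length(v)
  if (k >= 3) {
    fix <- which(r$lengths <= stretchRunMax)
    fix <- fix[fix > 1 & fix < k]
    # flanks must agree AND carry an actual genotype: a correction pass must
    # never overwrite a call with missingness
    fix <- fix[v[fix - 1] == v[fix + 1] & v[fix - 1] != "N"]
    if (length(fix)) {
      r$values[fix] <- v[fix - 1]
      x <- inverse.rle(r)
    }
  }
  x
}

#' Correct short interspersed stretches
#'
#' Per individual and chromosome, every maximal run of a single genotype
#' value (any of A, B, H or N), of length at most \code{stretchRunMax},
#' whose immediate left and right neighbours are equal to each other (and,
#' being neighbours of a maximal run, necessarily different from the run
#' value), is replaced by the flanking value. Runs flanked by N are left
#' alone: a correction never replaces a call with missingness. With the
#' default threshold of one this removes single erroneous genotypes inside
#' longer uniform haplotypes, e.g. the A-H-A motif.
#'
#' @param g an ABHMatrix (conventionally after
#'   \code{\link{correctUndercalledHet}})
#' @param stretchRunMax longest run rewritten, default 1
#' @return corrected ABHMatrix
#' @export
correctShortStretches <- function(g, stretchRunMax = 1) {
  stopifnot(is(g, "ABHMatrix"), stretchRunMax >= 1)
  .perChromApply(g, function(x) .stretchCorrectRow(x, stretchRunMax))
}

#' Merge two populations genotyped at different marker sets
#'
#' Marker set = position-sorted union; individuals = union (the two sets
#' must be disjoint); cells at markers not assayed in an individual's source
#' population are N; missing data are then re-imputed with
#' \code{\link{imputeFlankedMissing}}. Typical use: two populations prepared
#' with different restriction enzymes, hence non-overlapping marker sets on
#' the same physical reference.
#'
#' @param g1,g2 ABHMatrix objects with bp positions on the same reference
#' @return merged, re-imputed ABHMatrix
#' @export
mergePopulations <- function(g1, g2) {
  stopifnot(is(g1, "ABHMatrix"), is(g2, "ABHMatrix"))
  if (g1@units != g2@units) stop("position units differ between populations")
  if (length(intersect(rownames(g1@codes), rownames(g2@codes))))
    stop("individual sets must be disjoint")
  k1 <- paste(g1@markers$chrom, g1@markers$pos)
  k2 <- paste(g2@markers$chrom, g2@markers$pos)
  shared <- intersect(k1, k2)
  if (length(shared)) {
    i1 <- match(shared, k1); i2 <- match(shared, k2)
    if (any(g1@markers$id[i1] != g2@markers$id[i2]))
      stop("shared positions with conflicting marker identities: ",
           paste(utils::head(shared, 3), collapse = "; "))
  }
  mk <- rbind(g1@markers[, c("id", "chrom", "pos")],
              g2@markers[!k2 %in% k1, c("id", "chrom", "pos")])
  o <- order(mk$chrom, mk$pos)
  mk <- mk[o, , drop = FALSE]
  rownames(mk) <- NULL
  inds <- c(rownames(g1@codes), rownames(g2@codes))
  codes <- matrix("N", length(inds), nrow(mk),
                  dimnames = list(inds, mk$id))
  key <- paste(mk$chrom, mk$pos)
  codes[rownames(g1@codes), match(k1, key)] <- g1@codes
  codes[rownames(g2@codes), match(k2, key)] <- g2@codes
  merged <- new("ABHMatrix", codes = codes, markers = mk, units = g1@units)
  imputeFlankedMissing(merged)
}

#' Run the full imputation and error-correction pipeline
#'
#' Applies, in this fixed order: flank-based imputation of missing
#' genotypes, heterozygote-undercall correction, and short-stretch
#' correction, and reports before/after genotype composition, the number of
#' cells changed by each pass, and the run-length distribution of imputed
#' stretches.
#'
#' @param g an ABHMatrix
#' @param params a \linkS4class{CorrectionParams} (defaults: het run max 4,
#'   stretch run max 1)
#' @return list with elements \code{abh} (the post-processed matrix) and
#'   \code{stats}
#' @export
postprocessABH <- function(g, params = new("CorrectionParams")) {
  stopifnot(is(g, "ABHMatrix"), is(params, "CorrectionParams"))
  comp <- function(x) {
    tb <- table(factor(x@codes, levels = ABH_CODES))
    as.list(tb / sum(tb))
  }
  before <- comp(g)
  g1 <- imputeFlankedMissing(g)
  # run lengths of stretches the imputation filled
  filled <- g1@codes != g@codes
  runlens <- integer(0)
  if (any(filled)) {
    for (i in which(rowSums(filled) > 0)) {
      r <- rle(filled[i, ])
      runlens <- c(runlens, r$lengths[r$values])
    }
  }
  g2 <- correctUndercalledHet(g1, params@hetRunMax)
  g3 <- correctShortStretches(g2, params@stretchRunMax)
  stats <- list(
    composition_before = before,
    composition_after = comp(g3),
    cells_imputed = sum(filled),
    cells_het_corrected = sum(g2@codes != g1@codes),
    cells_stretch_corrected = sum(g3@codes != g2@codes),
    imputed_run_lengths = if (length(runlens)) table(runlens) else table(integer(0)),
    params = list(het_run_max = params@hetRunMax,
                  stretch_run_max = params@stretchRunMax)
  )
  list(abh = g3, stats = stats)
}
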