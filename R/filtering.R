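# Site- and call-level filters applied between SNP calling and ABH
# encoding. The pipeline order is fixed: parental consistency -> MAF ->
# depth mask -> thinning -> missingness; every stage appends to the
# SiteMatrix filter log so the order is auditable.

.logStage <- function(m, stage, sites_in, sites_out, calls_masked, params) {
  m@filterLog <- rbind(m@filterLog, data.frame(
    stage = stage, sites_in = sites_in, sites_out = sites_out,
    calls_masked = calls_masked, params = params, stringsAsFactors = FALSE))
  m
}

.subsetSites <- function(m, keep) {
  m@markers <- m@markers[keep, , drop = FALSE]
  rownames(m@markers) <- NULL
  m@geno1 <- m@geno1[keep, , drop = FALSE]
  m@geno2 <- m@geno2[keep, , drop = FALSE]
  m@depthRef <- m@depthRef[keep, , drop = FALSE]
  m@depthAlt <- m@depthAlt[keep, , drop = FALSE]
  m
}

.roleCols <- function(m, role) which(m@samples$role == role)

#' Filter sites on triplicate-parent consistency
#'
#' Retains exactly the sites where (1) all non-missing parent-1 replicate
#' calls agree and all parent-2 replicate calls agree, (2) both parental
#' consensus calls are homozygous, and (3) the two consensus alleles differ.
#' Sites where either parent has no non-missing call are dropped (and
#' counted), not guessed. Consensus alleles are recorded in the marker table
#' as \code{parentA} (parent 1) and \code{parentB} (parent 2).
#'
#' @param m a SiteMatrix with at least one sample per parent role
#' @return filtered SiteMatrix with consensus alleles recorded
#' @export
filterParentalConsistency <- function(m) {
  stopifnot(is(m, "SiteMatrix"))
  p1 <- .roleCols(m, "parent1_rep")
  p2 <- .roleCols(m, "parent2_rep")
  if (!length(p1) || !length(p2))
    stop("parental filtering needs at least one sample per parent role")
  n <- nrow(m@markers)
  keep <- logical(n)
  pa <- rep(NA_character_, n)
  pb <- rep(NA_character_, n)
  consensus <- function(i, cols) {
    a1 <- m@geno1[i, cols]; a2 <- m@geno2[i, cols]
    ok <- !is.na(a1)
    if (!any(ok)) return(NA_character_)
    gt <- paste(a1[ok], a2[ok])
    if (length(unique(gt)) != 1) return(NA_character_)   # replicates disagree
    if (a1[ok][1] != a2[ok][1]) return(NA_character_)    # heterozygous parent
    a1[ok][1]
  }
  for (i in seq_len(n)) {
    ca <- consensus(i, p1)
    cb <- consensus(i, p2)
    if (!is.na(ca) && !is.na(cb) && ca != cb) {
      keep[i] <- TRUE
      pa[i] <- ca; pb[i] <- cb
    }
  }
  out <- .subsetSites(m, keep)
  out@markers$parentA <- pa[keep]
  out@markers$parentB <- pb[keep]
  .logStage(out, "parental_consistency", n, sum(keep), 0L, "")
}

#' Filter sites on minor allele frequency
#'
#' MAF is computed over F2 samples only, counting each homozygote as two
#' copies and each heterozygote as one copy of each parental allele; sites
#' with MAF strictly below the threshold are removed (a site at exactly the
#' threshold is retained). Sites with all F2 calls missing are removed.
#'
#' @param m a SiteMatrix with parental consensus recorded
#' @param threshold removal boundary, default 0.25
#' @return filtered SiteMatrix
#' @export
filterMAF <- function(m, threshold = 0.25) {
  stopifnot(is(m, "SiteMatrix"))
  if (all(is.na(m@markers$parentA)))
    stop("filterMAF needs parental consensus alleles (run filterParentalConsistency)")
  f2 <- .roleCols(m, "f2")
  n <- nrow(m@markers)
  maf <- vapply(seq_len(n), function(i) {
    a1 <- m@geno1[i, f2]; a2 <- m@geno2[i, f2]
    al <- c(a1, a2)
    cA <- sum(al == m@markers$parentA[i], na.rm = TRUE)
    cB <- sum(al == m@markers$parentB[i], na.rm = TRUE)
    if (cA + cB == 0) return(-1)  # all missing -> removed
    min(cA, cB) / (cA + cB)
  }, numeric(1))
  keep <- maf >= threshold
  out <- .subsetSites(m, keep)
  .logStage(out, "maf", n, sum(keep), 0L, paste0("threshold=", threshold))
}

#' Mask low-depth F2 calls as missing
#'
#' Any F2 call whose total read depth (REF + ALT supporting reads) is below
#' \code{minDepth} is set to missing. Parental replicate calls are left
#' untouched: their reliability is already enforced by the
#' triplicate-consistency rule.
#'
#' @param m a SiteMatrix with depths populated
#' @param minDepth minimum total reads per call, default 7
#' @return SiteMatrix with low-depth calls masked
#' @export
maskLowDepth <- function(m, minDepth = 7) {
  stopifnot(is(m, "SiteMatrix"))
  f2 <- .roleCols(m, "f2")
  tot <- m@depthRef[, f2, drop = FALSE] + m@depthAlt[, f2, drop = FALSE]
  mask <- tot < minDepth & !is.na(m@geno1[, f2, drop = FALSE])
  g1 <- m@geno1; g2 <- m@geno2
  g1[, f2][mask] <- NA_character_
  g2[, f2][mask] <- NA_character_
  m@geno1 <- g1; m@geno2 <- g2
  .logStage(m, "depth_mask", nrow(m@markers), nrow(m@markers),
            sum(mask), paste0("min_depth=", minDepth))
}

#' Probability of undercalling a heterozygote at a given read depth
#'
#' At a true heterozygous site covered by \code{depth} reads, each read
#' samples one of the two alleles with equal probability; the call is
#' wrongly homozygous exactly when all reads come from one allele, which has
#' probability 2 * (1/2)^depth. At the pipeline's 7-read minimum this bound
#' is 0.015625 (about 1.6%).
#'
#' @param depth integer read depth >= 1 (vectorized)
#' @return probability that all reads sample the same allele
#' @export
undercallProbability <- function(depth) {
  if (any(depth < 1) || any(depth != floor(depth)))
    stop("depth must be an integer >= 1")
  2 * 0.5^depth
}

#' Thin sites to a minimum physical distance
#'
#' Greedy left-to-right scan per chromosome: the first site is always kept;
#' each later site is kept iff its position is at least \code{minBp} greater
#' than the last kept site's position (a distance of exactly \code{minBp}
#' qualifies). Removes redundant SNPs called from the same sequencing tag.
#'
#' @param m a SiteMatrix (sorted by chromosome, position)
#' @param minBp minimum distance in bp, default 64
#' @return thinned SiteMatrix
#' @export
thinSites <- function(m, minBp = 64) {
  stopifnot(is(m, "SiteMatrix"))
  n <- nrow(m@markers)
  keep <- logical(n)
  for (idx in split(seq_len(n), m@markers$chrom)) {
    last <- -Inf
    for (i in idx) {
      if (m@markers$pos[i] - last >= minBp) {
        keep[i] <- TRUE
        last <- m@markers$pos[i]
      }
    }
  }
  out <- .subsetSites(m, keep)
  .logStage(out, "thin", n, sum(keep), 0L, paste0("min_bp=", minBp))
}

#' Filter sites on per-site missing-data fraction
#'
#' Removes sites whose fraction of missing F2 calls exceeds
#' \code{maxMissing} (strictly greater than).
#'
#' @param m a SiteMatrix
#' @param maxMissing maximum tolerated missing fraction among F2 calls
#' @return filtered SiteMatrix
#' @export
filterSiteMissingness <- function(m, maxMissing = 0.75) {
  stopifnot(is(m, "SiteMatrix"))
  f2 <- .roleCols(m, "f2")
  n <- nrow(m@markers)
  frac <- rowMeans(is.na(m@geno1[, f2, drop = FALSE]))
  keep <- frac <= maxMissing
  out <- .subsetSites(m, keep)
  .logStage(out, "missingness", n, sum(keep), 0L,
            paste0("max_missing=", maxMissing))
}

#' Relative allelic depth of heterozygous calls
#'
#' For every heterozygous F2 call with both parental-allele depths positive,
#' computes the ratio parent-1 reads / parent-2 reads and reports the
#' fraction of calls whose ratio lies strictly inside the two-fold band
#' (0.5, 2.0), plus a histogram of log2 ratios. Calls with a zero
#' denominator are excluded from ratios and counted separately. A fraction
#' near one indicates no parent-of-origin read bias.
#'
#' @param m a SiteMatrix with parental consensus and depths
#' @return list: n_het, n_zero_denominator, fraction_within_2fold, ratios,
#'   histogram (log2 scale)
#' @export
allelicDepthRatioStats <- function(m) {
  stopifnot(is(m, "SiteMatrix"))
  if (all(is.na(m@markers$parentA)))
    stop("needs parental consensus alleles (run filterParentalConsistency)")
  f2 <- .roleCols(m, "f2")
  ratios <- numeric(0)
  n_zero <- 0L
  for (i in seq_len(nrow(m@markers))) {
    a1 <- m@geno1[i, f2]; a2 <- m@geno2[i, f2]
    het <- which(!is.na(a1) & a1 != a2)
    if (!length(het)) next
    refIsA <- m@markers$ref[i] == m@markers$parentA[i]
    dA <- if (isTRUE(refIsA)) m@depthRef[i, f2][het] else m@depthAlt[i, f2][het]
    dB <- if (isTRUE(refIsA)) m@depthAlt[i, f2][het] else m@depthRef[i, f2][het]
    zero <- dB == 0
    n_zero <- n_zero + sum(zero)
    ratios <- c(ratios, dA[!zero] / dB[!zero])
  }
  inside <- ratios > 0.5 & ratios < 2.0
  list(n_het = length(ratios) + n_zero,
       n_zero_denominator = n_zero,
       fraction_within_2fold = if (length(ratios)) mean(inside) else NA_real_,
       ratios = ratios,
       histogram = if (length(ratios)) graphics::hist(log2(ratios),
                                                      plot = FALSE) else NULL)
}

#' Filter audit trail of a SiteMatrix
#' @param m a SiteMatrix
#' @return data.frame with one row per applied stage, in execution order
#' @export
filterReport <- function(m) {
  stopifnot(is(m, "SiteMatrix"))
  m@filterLog
}

#' Write the filter report as JSON
#' @param m a SiteMatrix
#' @param path output file
#' @return invisibly, the path
#' @export
writeFilterReport <- function(m, path) {
  jsonlite::write_json(filterReport(m), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
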