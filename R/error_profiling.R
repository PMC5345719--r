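# Error-motif census and genotype summary statistics. Run on imputed but
# NOT error-corrected data: the motifs are exactly the patterns the
# correction passes rewrite, so counting after correction would find none.

#' Count the six error motifs
#'
#' Slides a window of width 3 along each individual x chromosome. A window
#' x-y-x with x != y and both in \{A, B, H\} increments motif "xyx" for the
#' centre marker and for the individual. Windows containing N do not count
#' (absence of evidence is not a genotype). Overlapping windows are all
#' counted. The six motifs are HAH, HBH, AHA, BHB, ABA and BAB; HBH
#' (undercalled parent-2 allele) and AHA (overcalled heterozygote in a
#' parent-1 background) are the two classes that dominate systematically
#' error-prone markers.
#'
#' @param g an ABHMatrix, imputed but not error-corrected
#' @return an \linkS4class{ErrorMotifCounts}
#' @export
countMotifs <- function(g) {
  stopifnot(is(g, "ABHMatrix"))
  codes <- g@codes
  nm <- ncol(codes); ni <- nrow(codes)
  perMarker <- matrix(0L, nm, length(MOTIFS),
                      dimnames = list(colnames(codes), MOTIFS))
  perInd <- matrix(0L, ni, length(MOTIFS),
                   dimnames = list(rownames(codes), MOTIFS))
  for (idx in split(seq_len(nm), g@markers$chrom)) {
    if (length(idx) < 3) next
    left <- codes[, idx[-c(length(idx) - 1, length(idx))], drop = FALSE]
    mid <- codes[, idx[-c(1, length(idx))], drop = FALSE]
    right <- codes[, idx[-c(1, 2)], drop = FALSE]
    hit <- left == right & left != mid & left != "N" & mid != "N"
    if (!any(hit)) next
    motif <- paste0(left[hit], mid[hit], left[hit])
    centre <- idx[-c(1, length(idx))][col(mid)[hit]]
    ind <- row(mid)[hit]
    for (k in seq_along(motif)) {
      mcol <- match(motif[k], MOTIFS)
      perMarker[centre[k], mcol] <- perMarker[centre[k], mcol] + 1L
      perInd[ind[k], mcol] <- perInd[ind[k], mcol] + 1L
    }
  }
  new("ErrorMotifCounts", perMarker = perMarker, perIndividual = perInd)
}

#' Global and per-marker genotype composition
#'
#' @param g an ABHMatrix
#' @return list: \code{global}, named fractions of A/B/H/N summing to 1;
#'   \code{perMarker}, markers x 4 matrix of fractions
#' @export
genotypeComposition <- function(g) {
  stopifnot(is(g, "ABHMatrix"))
  lv <- ABH_CODES
  global <- table(factor(g@codes, levels = lv))
  global <- as.numeric(global) / sum(global)
  names(global) <- lv
  pm <- t(apply(g@codes, 2, function(x) {
    tb <- table(factor(x, levels = lv))
    as.numeric(tb) / sum(tb)
  }))
  colnames(pm) <- lv
  list(global = global, perMarker = pm)
}

#' Per-marker parental allele frequencies and segregation distortion
#'
#' For each marker, the observed frequencies of A, H and B among non-missing
#' genotypes, and a 2-df chi-square statistic against the Mendelian 1:2:1
#' F2 expectation (a convenience extension; large values flag segregation
#' distortion, e.g. from reproductive incompatibility). Markers with all
#' calls missing get NA frequencies and statistic.
#'
#' @param g an ABHMatrix
#' @return data.frame: marker, chrom, pos, n, freqA, freqH, freqB, chisq
#' @export
alleleFrequencyProfile <- function(g) {
  stopifnot(is(g, "ABHMatrix"))
  res <- t(apply(g@codes, 2, function(x) {
    nA <- sum(x == "A"); nH <- sum(x == "H"); nB <- sum(x == "B")
    n <- nA + nH + nB
    if (n == 0) return(c(0, NA, NA, NA, NA))
    expd <- n * c(0.25, 0.5, 0.25)
    chisq <- sum((c(nA, nH, nB) - expd)^2 / expd)
    c(n, nA / n, nH / n, nB / n, chisq)
  }))
  data.frame(marker = g@markers$id, chrom = g@markers$chrom,
             pos = g@markers$pos, n = res[, 1], freqA = res[, 2],
             freqH = res[, 3], freqB = res[, 4], chisq = res[, 5],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Marker density in physical bins
#'
#' Counts markers per chromosome in half-open bins [k*bin, (k+1)*bin) of
#' physical position; bin counts sum to the total marker count.
#'
#' @param markers data.frame with columns chrom, pos (bp), or an ABHMatrix /
#'   SiteMatrix
#' @param binBp bin width in bp, default 1e6
#' @return data.frame: chrom, bin_start, bin_end, n_markers
#' @export
markerDensity <- function(markers, binBp = 1e6) {
  if (is(markers, "ABHMatrix") || is(markers, "SiteMatrix"))
    markers <- markerInfo(markers)
  out <- lapply(split(markers$pos, markers$chrom), function(p) {
    if (!length(p)) return(data.frame(bin_start = numeric(0),
                                      bin_end = numeric(0),
                                      n_markers = integer(0)))
    bins <- 0:floor(max(p) / binBp)
    cnt <- tabulate(floor(p / binBp) + 1, nbins = length(bins))
    data.frame(bin_start = bins * binBp, bin_end = (bins + 1) * binBp,
               n_markers = cnt)
  })
  res <- do.call(rbind, Map(function(ch, df) {
    if (nrow(df)) cbind(chrom = ch, df)
    else cbind(chrom = character(0), df)
  }, names(out), out))
  rownames(res) <- NULL
  res
}
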