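# Recombination-fraction estimation and genetic-map construction for an F2
# intercross. Adjacent markers are estimated pairwise by maximum likelihood
# (EM over the 3x3 genotype table, with the double-heterozygote class
# treated as a mixture of zero- and two-recombinant phase configurations)
# and chained into cumulative cM via Haldane or Kosambi map functions.

#' Haldane and Kosambi map functions
#'
#' Haldane (no crossover interference): cM = -50 * ln(1 - 2r). Kosambi:
#' cM = 25 * ln((1 + 2r) / (1 - 2r)). Inverses are exact. Recombination
#' fractions at or above 0.5 are capped at 0.4999 before transformation to
#' avoid infinite distances.
#'
#' @param r recombination fraction(s) in [0, 0.5)
#' @param cm map distance(s) in cM, >= 0
#' @return transformed values
#' @export
haldaneCM <- function(r) {
  r <- pmin(pmax(r, 0), 0.4999)
  -50 * log(1 - 2 * r)
}

#' @rdname haldaneCM
#' @export
inverseHaldane <- function(cm) {
  stopifnot(all(cm >= 0))
  0.5 * (1 - exp(-cm / 50))
}

#' @rdname haldaneCM
#' @export
kosambiCM <- function(r) {
  r <- pmin(pmax(r, 0), 0.4999)
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname haldaneCM
#' @export
inverseKosambi <- function(cm) {
  stopifnot(all(cm >= 0))
  0.5 * tanh(cm / 50)
}

#' Recombination density and double-crossover risk
#'
#' \code{recombinationDensity} is total genetic length over total physical
#' length (cM/Mb). \code{doubleCrossoverRisk} converts that density into the
#' probability of two crossover events inside a physical window: with d
#' cM/Mb, a window of w Mb spans d*w/100 Morgans, so the chance of a
#' crossover there is ~d*w/100 and the chance of two independent ones is its
#' square. This bounds how often flank-based imputation misses a genuine
#' double crossover between two informative markers.
#'
#' @param map_cM total genetic map length in cM
#' @param genome_Mb total physical genome length in Mb
#' @param window_Mb physical window of interest in Mb, default 1
#' @return density in cM/Mb, or a probability
#' @export
recombinationDensity <- function(map_cM, genome_Mb) map_cM / genome_Mb

#' @rdname recombinationDensity
#' @export
doubleCrossoverRisk <- function(map_cM, genome_Mb, window_Mb = 1) {
  (recombinationDensity(map_cM, genome_Mb) * window_Mb / 100)^2
}

# 3x3 genotype table (A/H/B x A/H/B) from two ABH columns, N pairs dropped
.pairTable <- function(x, y) {
  ok <- x != "N" & y != "N"
  table(factor(x[ok], levels = c("A", "H", "B")),
        factor(y[ok], levels = c("A", "H", "B")))
}

# F2 two-locus genotype class probabilities at recombination fraction r,
# in the 3x3 layout of .pairTable
.f2PairProbs <- function(r) {
  s <- 1 - r
  matrix(c(s^2 / 4,     r * s / 2,        r^2 / 4,
           r * s / 2,   (s^2 + r^2) / 2,  r * s / 2,
           r^2 / 4,     r * s / 2,        s^2 / 4),
         3, 3, byrow = TRUE)
}

# number of recombinant gametes per class (double-het handled in E-step)
.recGametes <- matrix(c(0, 1, 2,
                        1, NA, 1,
                        2, 1, 0), 3, 3, byrow = TRUE)

#' Two-point recombination fraction for an F2 intercross, by EM
#'
#' Maximizes the F2 likelihood over the 3x3 observed genotype table of two
#' markers. The double-heterozygote class is a phase mixture (zero or two
#' recombinant gametes); the E-step assigns it expected recombinant count
#' 2 r^2 / (r^2 + (1-r)^2). Iterated until |delta r| < 1e-8 or 1000
#' iterations; the estimate is clipped to [0, 0.5].
#'
#' @param x,y character vectors of ABH codes for the two markers (same
#'   individuals); pairs with an N are dropped
#' @return list: \code{r_hat}, \code{n_informative} (non-missing pairs),
#'   \code{log_likelihood} at the estimate
#' @export
estimateRF <- function(x, y) {
  tb <- .pairTable(x, y)
  n <- sum(tb)
  if (n < 2) stop("need at least 2 individuals with both genotypes non-missing")
  fixedRec <- sum(tb * .recGametes, na.rm = TRUE)
  nHH <- tb[2, 2]
  r <- 0.25
  for (it in seq_len(1000)) {
    expHH <- if (nHH > 0) nHH * 2 * r^2 / (r^2 + (1 - r)^2) else 0
    rNew <- (fixedRec + expHH) / (2 * n)
    rNew <- min(max(rNew, 0), 0.5)
    if (abs(rNew - r) < 1e-8) { r <- rNew; break }
    r <- rNew
  }
  list(r_hat = r, n_informative = n, log_likelihood = .pairLogLik(tb, r))
}

.pairLogLik <- function(tb, r) {
  p <- .f2PairProbs(max(min(r, 0.499999), 1e-9))
  sum(tb[tb > 0] * log(p[tb > 0]))
}

#' Estimate a genetic map from an ABH matrix
#'
#' Chains two-point EM estimates (\code{\link{estimateRF}}) along adjacent
#' markers within each chromosome, in the given physical order, and
#' accumulates cM from 0 via the chosen map function. Recombination
#' fractions are capped at 0.4999 before transformation. Chromosomes with a
#' single marker yield a zero-length map with a warning.
#'
#' @param g an ABHMatrix, markers ordered by physical position
#' @param mapFunction "haldane" (default) or "kosambi"
#' @return a \linkS4class{GeneticMap}
#' @export
estimateMap <- function(g, mapFunction = c("haldane", "kosambi")) {
  stopifnot(is(g, "ABHMatrix"))
  mapFunction <- match.arg(mapFunction)
  mf <- if (mapFunction == "haldane") haldaneCM else kosambiCM
  codes <- g@codes
  pieces <- lapply(split(seq_len(ncol(codes)), g@markers$chrom), function(idx) {
    if (length(idx) < 2) {
      warning("chromosome with fewer than 2 markers: zero-length map")
      return(data.frame(marker = g@markers$id[idx],
                        chrom = g@markers$chrom[idx],
                        cM = rep(0, length(idx)),
                        stringsAsFactors = FALSE))
    }
    d <- vapply(seq_len(length(idx) - 1), function(j) {
      est <- estimateRF(codes[, idx[j]], codes[, idx[j + 1]])
      mf(min(est$r_hat, 0.4999))
    }, numeric(1))
    data.frame(marker = g@markers$id[idx], chrom = g@markers$chrom[idx],
               cM = c(0, cumsum(d)), stringsAsFactors = FALSE)
  })
  tb <- do.call(rbind, pieces)
  rownames(tb) <- NULL
  new("GeneticMap", table = tb)
}
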