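# Single-QTL genome scan by multiple imputation. Genotypes on a cM step
# grid are drawn from their conditional distribution given the nearest
# non-missing flanking markers under a no-interference Markov model with
# Haldane recombination probabilities; each draw is scanned by least-squares
# regression on an additive contrast and a dominance indicator, and evidence
# is combined across draws on the 10^LOD scale.

#' GenotypeDraws: multiply imputed genotypes on a cM grid
#'
#' @slot grid data.frame with columns chrom, pos (cM); covers every marker
#'   position plus a regular step grid.
#' @slot draws integer array individuals x grid positions x draws with
#'   values 1 (A), 2 (H), 3 (B).
#' @export
setClass("GenotypeDraws", slots = c(grid = "data.frame", draws = "array"))

# genotype transition matrix over recombination fraction r: two independent
# gametes, each switching parent with probability r
.genoTransition <- function(r) {
  s <- 1 - r
  matrix(c(s^2,     2 * r * s, r^2,
           r * s,   s^2 + r^2, r * s,
           r^2,     2 * r * s, s^2), 3, 3, byrow = TRUE)
}

.F2_PRIOR <- c(0.25, 0.5, 0.25)

# conditional genotype distribution at distance dL right of genotype gL and
# dR left of genotype gR (codes 1..3; NA = no flank on that side)
.bridgeProbs <- function(gL, dL, gR, dR) {
  if (!is.na(gL) && !is.na(gR)) {
    p <- .genoTransition(inverseHaldane(dL))[gL, ] *
      .genoTransition(inverseHaldane(dR))[, gR]
  } else if (!is.na(gL)) {
    p <- .genoTransition(inverseHaldane(dL))[gL, ]
  } else if (!is.na(gR)) {
    p <- .F2_PRIOR * .genoTransition(inverseHaldane(dR))[, gR]
  } else {
    p <- .F2_PRIOR
  }
  p / sum(p)
}

#' Draw grid genotypes conditional on flanking markers
#'
#' Builds, per chromosome, a position grid of step \code{stepCM} (grid
#' points outside the chromosome span are clamped to the span) joined with
#' every marker position, and draws \code{nDraws} independent genotypes per
#' individual and grid point from the Markov conditional given the nearest
#' non-missing flanking markers (Haldane recombination probabilities, no
#' interference). A grid point on a non-missing marker reproduces the
#' observed genotype in every draw.
#'
#' @param g an ABHMatrix
#' @param map a \linkS4class{GeneticMap} sharing markers with \code{g}
#' @param stepCM grid step in cM, default 1
#' @param nDraws number of imputations, default 16
#' @param seed integer seed for reproducible draws
#' @return a \linkS4class{GenotypeDraws}
#' @export
conditionalGenotypeDraws <- function(g, map, stepCM = 1, nDraws = 16,
                                     seed = NULL) {
  stopifnot(is(g, "ABHMatrix"), is(map, "GeneticMap"))
  if (!is.null(seed)) set.seed(seed)
  mt <- mapTable(map)
  if (!all(mt$marker %in% g@markers$id))
    stop("map contains markers absent from the genotype matrix")
  nInd <- nrow(g@codes)
  gridL <- list(); drawL <- list()
  for (ch in unique(mt$chrom)) {
    sub <- mt[mt$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$cM), , drop = FALSE]
    pos <- sub$cM
    span <- range(pos)
    pts <- unique(pmin(pmax(seq(span[1], span[2] + stepCM * 0.999,
                                by = stepCM), span[1]), span[2]))
    pts <- sort(unique(c(pts, pos)))
    obs <- g@codes[, sub$marker, drop = FALSE]
    nMk <- length(pos)
    code <- matrix(match(obs, c("A", "H", "B")), nInd, nMk)
    arr <- array(NA_integer_, c(nInd, length(pts), nDraws))
    # per individual: index of the nearest non-missing marker at or left of
    # (resp. at or right of) each marker slot
    leftNon <- matrix(NA_integer_, nInd, nMk)
    rightNon <- matrix(NA_integer_, nInd, nMk)
    for (ind in seq_len(nInd)) {
      nz <- which(!is.na(code[ind, ]))
      if (!length(nz)) next
      li <- findInterval(seq_len(nMk), nz)
      leftNon[ind, li > 0] <- nz[li[li > 0]]
      ri <- findInterval(seq_len(nMk) - 0.5, nz) + 1L
      rightNon[ind, ri <= length(nz)] <- nz[ri[ri <= length(nz)]]
    }
    rows_all <- seq_len(nInd)
    for (k in seq_along(pts)) {
      p <- pts[k]
      j <- findInterval(p, pos)
      Lm <- if (j >= 1) leftNon[, j] else rep(NA_integer_, nInd)
      Rm <- if (j < nMk) rightNon[, j + 1] else rep(NA_integer_, nInd)
      # a grid point sitting on a non-missing marker has dL = 0, so the
      # bridge distribution degenerates to the observed genotype
      onMk <- !is.na(Lm) & pos[pmax(Lm, 1)] == p
      Rm[onMk] <- NA_integer_
      gL <- ifelse(is.na(Lm), NA_integer_, code[cbind(rows_all, pmax(Lm, 1))])
      gR <- ifelse(is.na(Rm), NA_integer_, code[cbind(rows_all, pmax(Rm, 1))])
      key <- paste(Lm, gL, Rm, gR)
      for (u in unique(key)) {
        rows <- which(key == u)
        i1 <- rows[1]
        pr <- .bridgeProbs(gL[i1],
                           if (is.na(Lm[i1])) NA else p - pos[Lm[i1]],
                           gR[i1],
                           if (is.na(Rm[i1])) NA else pos[Rm[i1]] - p)
        if (max(pr) > 1 - 1e-12) {
          arr[rows, k, ] <- which.max(pr)
        } else {
          arr[rows, k, ] <- sample.int(3, length(rows) * nDraws,
                                       replace = TRUE, prob = pr)
        }
      }
    }
    gridL[[length(gridL) + 1]] <- data.frame(chrom = ch, pos = pts,
                                             stringsAsFactors = FALSE)
    drawL[[length(drawL) + 1]] <- arr
  }
  grid <- do.call(rbind, gridL)
  draws <- array(NA_integer_, c(nInd, nrow(grid), nDraws))
  at <- 0
  for (a in drawL) {
    draws[, at + seq_len(dim(a)[2]), ] <- a
    at <- at + dim(a)[2]
  }
  dimnames(draws) <- list(rownames(g@codes), NULL, NULL)
  new("GenotypeDraws", grid = grid, draws = draws)
}

# LOD profile(s): positions x phenotype-columns, combined over draws as
# log10 of the mean of 10^LOD (log-sum-exp for stability)
.scanLOD <- function(draws, Y) {
  arr <- draws@draws
  nInd <- dim(arr)[1]; nPos <- dim(arr)[2]; nDraws <- dim(arr)[3]
  Y <- as.matrix(Y)
  yc <- sweep(Y, 2, colMeans(Y))
  rss0 <- colSums(yc^2)
  if (any(rss0 <= 0))
    stop("constant phenotype: zero residual variance under the null model")
  sumY2 <- colSums(Y^2)
  lod <- matrix(NA_real_, nPos, ncol(Y))
  ln10 <- log(10)
  for (i in seq_len(nPos)) {
    ld <- matrix(NA_real_, nDraws, ncol(Y))
    for (d in seq_len(nDraws)) {
      xg <- arr[, i, d]
      X <- cbind(1, xg - 2L, as.numeric(xg == 2L))
      dc <- qr(X)
      Q <- qr.Q(dc)[, seq_len(dc$rank), drop = FALSE]
      rss1 <- pmax(sumY2 - colSums(crossprod(Q, Y)^2), 1e-12)
      ld[d, ] <- (nInd / 2) * log10(rss0 / rss1)
    }
    if (nDraws == 1) {
      lod[i, ] <- ld[1, ]
    } else {
      M <- apply(ld, 2, max)
      lod[i, ] <- M + log10(colMeans(10^sweep(ld, 2, M)))
    }
  }
  pmax(lod, 0)
}

#' Single-QTL LOD profile
#'
#' Per grid position and imputation draw, fits trait ~ additive contrast
#' (-1, 0, +1 for A, H, B) + dominance indicator by least squares;
#' LOD = (n/2) log10(RSS0 / RSS1). Evidence is combined across draws as
#' log10 of the mean of 10^LOD.
#'
#' @param phenotype numeric vector, one value per individual, aligned with
#'   (or named by) the individuals of \code{draws}
#' @param draws a \linkS4class{GenotypeDraws}
#' @return a \linkS4class{QTLScanResult} (threshold and peaks unset)
#' @export
scanSingleQTL <- function(phenotype, draws) {
  stopifnot(is(draws, "GenotypeDraws"))
  phenotype <- .alignPhenotype(phenotype, draws)
  lod <- .scanLOD(draws, matrix(phenotype, ncol = 1))[, 1]
  new("QTLScanResult",
      profile = data.frame(chrom = draws@grid$chrom, pos = draws@grid$pos,
                           lod = lod, stringsAsFactors = FALSE))
}

.alignPhenotype <- function(phenotype, draws) {
  inds <- dimnames(draws@draws)[[1]]
  if (!is.null(names(phenotype)) && !is.null(inds)) {
    if (!all(inds %in% names(phenotype)))
      stop("phenotype is missing individuals present in the genotype draws")
    phenotype <- phenotype[inds]
  }
  if (length(phenotype) != dim(draws@draws)[1])
    stop("phenotype length does not match the number of individuals")
  if (any(is.na(phenotype))) stop("phenotype contains missing values")
  as.numeric(phenotype)
}

#' Genome-wide LOD threshold by phenotype permutation
#'
#' Permutes the phenotype vector across individuals (preserving the
#' genotype LD structure), rescans, and records the genome-wide maximum LOD
#' per permutation; the threshold is the empirical (1 - alpha) quantile of
#' that null distribution.
#'
#' @param phenotype numeric vector as in \code{\link{scanSingleQTL}}
#' @param draws a \linkS4class{GenotypeDraws}
#' @param nPerm number of permutations, default 1000
#' @param alpha significance level, default 0.05
#' @param seed integer seed
#' @return list: \code{threshold}, \code{alpha}, \code{max_lods} (the null
#'   distribution)
#' @export
permutationThreshold <- function(phenotype, draws, nPerm = 1000,
                                 alpha = 0.05, seed = NULL) {
  stopifnot(is(draws, "GenotypeDraws"), nPerm >= 1)
  phenotype <- .alignPhenotype(phenotype, draws)
  if (!is.null(seed)) set.seed(seed)
  n <- length(phenotype)
  Y <- vapply(seq_len(nPerm), function(i) phenotype[sample.int(n)],
              numeric(n))
  maxLod <- apply(.scanLOD(draws, Y), 2, max)
  list(threshold = stats::quantile(maxLod, 1 - alpha, names = FALSE),
       alpha = alpha, max_lods = maxLod)
}

#' Bayes credible interval of a LOD profile
#'
#' Rescales 10^LOD on one chromosome to unit area (trapezoid rule,
#' tolerating an uneven grid) and expands a connected interval outward from
#' the peak, greedily adding the heavier neighbouring grid point, until the
#' covered area reaches \code{prob}. Endpoints are grid points (snapped
#' outward by construction), so realized coverage is >= \code{prob}. A flat
#' profile (e.g. all zero LOD) yields a central interval of ~\code{prob} of
#' the chromosome.
#'
#' @param profile data.frame with columns pos (cM) and lod for ONE
#'   chromosome
#' @param prob target coverage, default 0.95
#' @return list: \code{left}, \code{right} (cM), \code{coverage} achieved
#' @export
bayesCredibleInterval <- function(profile, prob = 0.95) {
  pos <- profile$pos
  lod <- profile$lod
  stopifnot(length(pos) >= 1, !is.unsorted(pos))
  if (length(pos) == 1)
    return(list(left = pos, right = pos, coverage = 1))
  w <- 10^(lod - max(lod))  # rescale before exponentiating
  gaps <- diff(pos)
  mass <- w * (c(0, gaps) + c(gaps, 0)) / 2
  mass <- mass / sum(mass)
  peaks <- which(lod == max(lod))
  peak <- peaks[ceiling(length(peaks) / 2)]
  l <- r <- peak
  cov <- mass[peak]
  while (cov < prob && (l > 1 || r < length(pos))) {
    mL <- if (l > 1) mass[l - 1] else -Inf
    mR <- if (r < length(pos)) mass[r + 1] else -Inf
    goLeft <- if (mL != mR) mL > mR else (peak - l) <= (r - peak)
    if (goLeft && is.finite(mL)) { l <- l - 1; cov <- cov + mass[l] }
    else { r <- r + 1; cov <- cov + mass[r] }
  }
  list(left = pos[l], right = pos[r], coverage = cov)
}

.designFromCodes <- function(codes) {
  keep <- codes %in% c("A", "H", "B")
  x <- match(codes[keep], c("A", "H", "B"))
  list(keep = keep, add = x - 2, dom = as.numeric(x == 2))
}

#' Percent phenotypic variance explained by the single-QTL model
#'
#' 100 * R-squared of the regression trait ~ additive contrast + dominance
#' indicator at the peak genotypes (individuals with missing genotype are
#' dropped).
#'
#' @param phenotype numeric vector
#' @param genotype character vector of ABH codes at the peak marker
#' @return percent of variance, in [0, 100]
#' @export
varianceExplained <- function(phenotype, genotype) {
  stopifnot(length(phenotype) == length(genotype))
  d <- .designFromCodes(genotype)
  y <- phenotype[d$keep]
  fit <- stats::lm(y ~ d$add + d$dom)
  100 * (1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2))
}

#' Additive and dominance effects at a QTL
#'
#' From the mean phenotype per genotype class: additive = (meanB - meanA)/2
#' (positive when parent-2 homozygotes increase the trait), dominance =
#' meanH - (meanA + meanB)/2. All three classes must be present.
#'
#' @param phenotype numeric vector
#' @param genotype character vector of ABH codes at the QTL marker
#' @return list: \code{additive}, \code{dominance}
#' @export
qtlEffects <- function(phenotype, genotype) {
  stopifnot(length(phenotype) == length(genotype))
  mA <- mean(phenotype[genotype == "A"])
  mH <- mean(phenotype[genotype == "H"])
  mB <- mean(phenotype[genotype == "B"])
  if (any(is.nan(c(mA, mH, mB))))
    stop("all three genotype classes must be present at the QTL")
  list(additive = (mB - mA) / 2, dominance = mH - (mA + mB) / 2)
}

#' Full single-QTL scan with threshold, intervals and effects
#'
#' Orchestrates \code{\link{conditionalGenotypeDraws}},
#' \code{\link{scanSingleQTL}}, \code{\link{permutationThreshold}} and, per
#' chromosome whose maximum LOD reaches the threshold, a
#' \code{\link{bayesCredibleInterval}}, \code{\link{varianceExplained}} and
#' \code{\link{qtlEffects}} at the marker nearest the peak (observed
#' genotypes, not draws).
#'
#' @param g an ABHMatrix
#' @param map a \linkS4class{GeneticMap}
#' @param phenotype numeric vector, named by individual
#' @param stepCM grid step, default 1
#' @param nDraws imputation draws, default 16
#' @param nPerm permutations, default 1000
#' @param alpha significance level, default 0.05
#' @param prob credible-interval coverage, default 0.95
#' @param seed integer seed
#' @return a \linkS4class{QTLScanResult} with threshold and peaks populated
#' @export
qtlScan <- function(g, map, phenotype, stepCM = 1, nDraws = 16, nPerm = 1000,
                    alpha = 0.05, prob = 0.95, seed = NULL) {
  draws <- conditionalGenotypeDraws(g, map, stepCM = stepCM, nDraws = nDraws,
                                    seed = seed)
  phen <- .alignPhenotype(phenotype, draws)
  scan <- scanSingleQTL(phen, draws)
  perm <- permutationThreshold(phen, draws, nPerm = nPerm, alpha = alpha,
                               seed = if (is.null(seed)) NULL else seed + 1)
  pf <- lodProfile(scan)
  mt <- mapTable(map)
  peaks <- list()
  for (ch in unique(pf$chrom)) {
    sub <- pf[pf$chrom == ch, , drop = FALSE]
    if (max(sub$lod) < perm$threshold) next
    pk <- which.max(sub$lod)
    ci <- bayesCredibleInterval(sub, prob = prob)
    mch <- mt[mt$chrom == ch, , drop = FALSE]
    nearest <- mch$marker[which.min(abs(mch$cM - sub$pos[pk]))]
    geno <- g@codes[, nearest]
    eff <- tryCatch(qtlEffects(phen, geno),
                    error = function(e) list(additive = NA_real_,
                                             dominance = NA_real_))
    pv <- tryCatch(varianceExplained(phen, geno),
                   error = function(e) NA_real_)
    peaks[[length(peaks) + 1]] <- data.frame(
      chrom = ch, peak_cM = sub$pos[pk], lod = sub$lod[pk],
      ci_left_cM = ci$left, ci_right_cM = ci$right,
      percent_variance = pv, additive_effect = eff$additive,
      dominance_effect = eff$dominance, marker = nearest,
      stringsAsFactors = FALSE)
  }
  new("QTLScanResult", profile = pf, threshold = perm$threshold,
      alpha = alpha,
      peaks = if (length(peaks)) do.call(rbind, peaks) else data.frame())
}
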