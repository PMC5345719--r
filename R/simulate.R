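# F2 cross simulator and GBS noise model: the fixture generator for tests
# and the engine of QTL-detection power studies. Crossovers follow a
# no-interference model (counts Poisson with mean length/100 per gamete,
# positions uniform), consistent with the Haldane map function used in
# estimation.

#' Simulate a marker map
#'
#' Markers are allocated to chromosomes proportionally to length (largest
#' remainder, at least two per chromosome) and placed either equally spaced
#' including both chromosome ends, or uniformly at random in the interior
#' with both ends anchored. Deterministic given the config seed.
#'
#' @param config an \linkS4class{F2SimConfig}
#' @return a \linkS4class{GeneticMap}
#' @export
simMap <- function(config) {
  stopifnot(is(config, "F2SimConfig"))
  len <- config@chrLengths
  nChr <- length(len)
  nM <- config@nMarkers
  if (nM < 2 * nChr)
    stop("need at least 2 markers per chromosome (", 2 * nChr, " total)")
  raw <- nM * len / sum(len)
  alloc <- pmax(floor(raw), 2)
  rem <- nM - sum(alloc)
  if (rem > 0) {
    extra <- order(raw - floor(raw), decreasing = TRUE)
    alloc[extra[seq_len(rem)]] <- alloc[extra[seq_len(rem)]] + 1
  } else if (rem < 0) {
    for (k in order(alloc, decreasing = TRUE)) {
      if (rem == 0) break
      give <- min(alloc[k] - 2, -rem)
      alloc[k] <- alloc[k] - give
      rem <- rem + give
    }
    if (rem != 0) stop("cannot allocate markers with 2 per chromosome")
  }
  set.seed(config@seed)
  tb <- do.call(rbind, lapply(seq_len(nChr), function(ch) {
    k <- alloc[ch]
    pos <- if (config@spacing == "equal") {
      seq(0, len[ch], length.out = k)
    } else {
      sort(c(0, stats::runif(k - 2, 0, len[ch]), len[ch]))
    }
    data.frame(marker = sprintf("c%02dm%03d", ch, seq_len(k)),
               chrom = ch, cM = pos, stringsAsFactors = FALSE)
  }))
  rownames(tb) <- NULL
  new("GeneticMap", table = tb)
}

# one chromosome of gametes: matrix (nGametes x loci) of 0/1 parent alleles
.simGametes <- function(nGametes, lociCM, lengthCM) {
  start <- stats::rbinom(nGametes, 1, 0.5)
  ncx <- stats::rpois(nGametes, lengthCM / 100)
  out <- matrix(0L, nGametes, length(lociCM))
  for (i in seq_len(nGametes)) {
    if (ncx[i] == 0) {
      out[i, ] <- start[i]
    } else {
      cx <- sort(stats::runif(ncx[i], 0, lengthCM))
      out[i, ] <- (start[i] + findInterval(lociCM, cx)) %% 2L
    }
  }
  out
}

#' Simulate an F2 cross
#'
#' Per individual and chromosome, two independent gametes are generated
#' (crossover count Poisson with mean chromosome-length/100, positions
#' uniform, no interference) and read at every marker and QTL position.
#' Phenotype = sum over QTL of additive * x + dominance * 1(het) + residual
#' noise, with x in \{-1, 0, +1\} for A/H/B (positive additive effects mean
#' the parent-2 homozygote increases the trait). Reproducible given the
#' config seed.
#'
#' @param map a \linkS4class{GeneticMap} (e.g. from \code{\link{simMap}})
#' @param config an \linkS4class{F2SimConfig}
#' @return list: \code{abh} (ABHMatrix, cM positions, no missing data),
#'   \code{phenotype} (named numeric), \code{qtlGeno} (individuals x QTL
#'   character matrix), \code{config}
#' @export
simF2 <- function(map, config) {
  stopifnot(is(map, "GeneticMap"), is(config, "F2SimConfig"))
  set.seed(config@seed)
  mt <- mapTable(map)
  n <- config@nIndividuals
  qtl <- config@qtl
  chroms <- unique(mt$chrom)
  inds <- sprintf("F2_%04d", seq_len(n))
  genoCols <- list()
  qtlGeno <- matrix(NA_character_, n, nrow(qtl))
  for (ch in chroms) {
    sub <- mt[mt$chrom == ch, , drop = FALSE]
    qhere <- which(qtl$chrom == ch)
    loci <- sort(unique(c(sub$cM, qtl$pos[qhere])))
    L <- max(loci)
    g1 <- .simGametes(n, loci, L)
    g2 <- .simGametes(n, loci, L)
    geno <- g1 + g2  # 0/1/2 copies of the parent-2 allele
    codes <- matrix(c("A", "H", "B")[geno + 1L], n, length(loci))
    mi <- match(sub$cM, loci)
    genoCols[[length(genoCols) + 1]] <- codes[, mi, drop = FALSE]
    for (q in qhere)
      qtlGeno[, q] <- codes[, match(qtl$pos[q], loci)]
  }
  codes <- do.call(cbind, genoCols)
  rownames(codes) <- inds
  markers <- data.frame(id = mt$marker, chrom = mt$chrom, pos = mt$cM,
                        stringsAsFactors = FALSE)
  abh <- ABHMatrix(codes, markers, units = "cM")
  phen <- stats::rnorm(n, 0, config@residualSD)
  if (nrow(qtl)) {
    for (q in seq_len(nrow(qtl))) {
      x <- match(qtlGeno[, q], c("A", "H", "B")) - 2
      phen <- phen + qtl$add[q] * x + qtl$dom[q] * (x == 0)
    }
  }
  names(phen) <- inds
  rownames(qtlGeno) <- inds
  list(abh = abh, phenotype = phen, qtlGeno = qtlGeno, config = config)
}

#' Apply the GBS noise model to a clean genotype matrix
#'
#' Independently per cell: set to N with the missing rate; for remaining H
#' cells, draw a read depth from the configured depth distribution and
#' rewrite the call to A or B (equal odds) with probability 2 * (1/2)^depth
#' (heterozygote undercalling); finally, at a designated fraction of
#' error-prone markers, flip H to B and A to H at the configured per-cell
#' rates, emulating markers with a systematic cause of error (the
#' co-occurring HBH/AHA signature).
#'
#' @param g an ABHMatrix
#' @param noise a \linkS4class{GBSNoiseConfig}
#' @param seed integer seed
#' @return list: \code{abh} (noisy matrix), \code{errorMarkers} (ids of the
#'   designated error-prone markers)
#' @export
applyGBSNoise <- function(g, noise, seed = NULL) {
  stopifnot(is(g, "ABHMatrix"), is(noise, "GBSNoiseConfig"))
  if (!is.null(seed)) set.seed(seed)
  codes <- g@codes
  nc <- length(codes)
  if (noise@missingRate > 0)
    codes[stats::runif(nc) < noise@missingRate] <- "N"
  if (length(noise@depths)) {
    het <- which(codes == "H")
    if (length(het)) {
      d <- noise@depths[sample.int(length(noise@depths), length(het),
                                   replace = TRUE)]
      hit <- stats::runif(length(het)) < undercallProbability(d)
      codes[het[hit]] <- sample(c("A", "B"), sum(hit), replace = TRUE)
    }
  }
  errMk <- character(0)
  nErr <- round(noise@errorMarkerFraction * ncol(codes))
  if (nErr > 0) {
    cols <- sample.int(ncol(codes), nErr)
    errMk <- colnames(codes)[cols]
    for (j in cols) {
      hb <- codes[, j] == "H" & stats::runif(nrow(codes)) < noise@flipHtoB
      ah <- codes[, j] == "A" & stats::runif(nrow(codes)) < noise@flipAtoH
      codes[hb, j] <- "B"
      codes[ah, j] <- "H"
    }
  }
  g@codes <- codes
  list(abh = g, errorMarkers = errMk)
}

#' QTL-detection power over population-size and marker grids
#'
#' For each (individuals, markers) combination: simulate a map and an F2
#' cross, scan for QTL with the multiple-imputation method, and count a QTL
#' as correctly detected iff some grid position within +/- windowCM of its
#' true location has LOD at or above the genome-wide permutation threshold.
#' Reports per-QTL power and the probability of detecting all QTL.
#'
#' @param config an \linkS4class{F2SimConfig}; its \code{nIndividuals} and
#'   \code{nMarkers} are overridden by the grids
#' @param nGrid vector of population sizes
#' @param markerGrid vector of total marker counts
#' @param reps simulations per grid cell, default 100
#' @param windowCM detection window, default 10
#' @param alpha significance level, default 0.05
#' @param nPerm permutations per scan (default 200, desk-scale; raise to
#'   1000 for final runs)
#' @param stepCM,nDraws scan resolution and imputation draws
#' @param seed integer seed; per-replicate seeds are derived from it
#' @return list: \code{perQTL} data.frame (n, markers, qtl, power) and
#'   \code{allQTL} data.frame (n, markers, power_all)
#' @export
powerExperiment <- function(config, nGrid, markerGrid, reps = 100,
                            windowCM = 10, alpha = 0.05, nPerm = 200,
                            stepCM = 2, nDraws = 4, seed = 1) {
  stopifnot(is(config, "F2SimConfig"), length(nGrid) >= 1,
            length(markerGrid) >= 1)
  set.seed(seed)
  subSeeds <- sample.int(2^30, length(nGrid) * length(markerGrid) * reps)
  qtl <- config@qtl
  perQTL <- list(); allQTL <- list(); cell <- 0
  for (n in nGrid) for (m in markerGrid) {
    det <- matrix(FALSE, reps, nrow(qtl))
    for (rep in seq_len(reps)) {
      cell <- cell + 1
      cfg <- config
      cfg@nIndividuals <- n
      cfg@nMarkers <- m
      cfg@seed <- subSeeds[cell]
      mp <- simMap(cfg)
      sim <- simF2(mp, cfg)
      draws <- conditionalGenotypeDraws(sim$abh, mp, stepCM = stepCM,
                                        nDraws = nDraws,
                                        seed = subSeeds[cell] + 1)
      scan <- scanSingleQTL(sim$phenotype, draws)
      thr <- permutationThreshold(sim$phenotype, draws, nPerm = nPerm,
                                  alpha = alpha,
                                  seed = subSeeds[cell] + 2)$threshold
      pf <- lodProfile(scan)
      for (q in seq_len(nrow(qtl))) {
        win <- pf$chrom == qtl$chrom[q] & abs(pf$pos - qtl$pos[q]) <= windowCM
        det[rep, q] <- any(pf$lod[win] >= thr)
      }
    }
    for (q in seq_len(nrow(qtl)))
      perQTL[[length(perQTL) + 1]] <- data.frame(
        n = n, markers = m, qtl = q, power = mean(det[, q]))
    allQTL[[length(allQTL) + 1]] <- data.frame(
      n = n, markers = m, power_all = mean(apply(det, 1, all)))
  }
  list(perQTL = do.call(rbind, perQTL), allQTL = do.call(rbind, allQTL))
}
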