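two_marker_draws <- function(codes1, codes2, dCM, nDraws, seed = 1) {
  n <- length(codes1)
  g <- ABHMatrix(cbind(codes1, codes2),
                 data.frame(id = c("m1", "m2"), chrom = "1", pos = c(0, dCM)))
  rownames(g@codes) <- paste0("i", seq_len(n))
  map <- new("GeneticMap", table = data.frame(marker = c("m1", "m2"),
                                              chrom = "1", cM = c(0, dCM)))
  conditionalGenotypeDraws(g, map, stepCM = dCM / 2, nDraws = nDraws,
                           seed = seed)
}

test_that("conditional draws reproduce observed markers and exact bridge probabilities", {
  # grid point on a non-missing marker: observed genotype in every draw
  d <- two_marker_draws("A", "B", 10, nDraws = 50)
  expect_true(all(d@draws[1, 1, ] == 1))
  expect_true(all(d@draws[1, 3, ] == 3))
  # midpoint between two A markers 2 cM apart: P(A) > 0.96 (the exact
  # Markov conditional is (1-r)^4 / ((1-r)^4 + 2r^2(1-r)^2 + r^4), r = r(1 cM))
  d2 <- two_marker_draws("A", "A", 2, nDraws = 4000, seed = 2)
  r <- inverseHaldane(1)
  pA <- (1 - r)^4 / ((1 - r)^4 + 2 * r^2 * (1 - r)^2 + r^4)
  frac <- mean(d2@draws[1, 2, ] == 1)
  expect_gt(frac, 0.96)
  expect_lt(abs(frac - pA), 3 * sqrt(pA * (1 - pA) / 4000) + 1e-3)
  # A and B flanks: H is the modal state at the midpoint
  d3 <- two_marker_draws("A", "B", 20, nDraws = 4000, seed = 3)
  tab <- tabulate(d3@draws[1, 2, ], 3)
  expect_equal(which.max(tab), 2)
  # missing at a marker: draws fall back on the remaining flank
  d4 <- two_marker_draws(c("A", "A"), c("N", "B"), 2, nDraws = 200, seed = 4)
  expect_gt(mean(d4@draws[1, 3, ] == 1), 0.9)  # N end imputed from the A flank
  expect_true(all(d4@draws[2, 3, ] == 3))
})

test_that("single-draw LOD equals the hand-computed regression LOD", {
  y <- c(1.2, 0.8, 2.1, 1.9, 3.2, 2.7)
  xg <- match(c("A", "A", "H", "H", "B", "B"), c("A", "H", "B"))
  draws <- new("GenotypeDraws",
               grid = data.frame(chrom = "1", pos = 0),
               draws = array(xg, c(6, 1, 1)))
  scan <- scanSingleQTL(y, draws)
  fit <- stats::lm(y ~ I(xg - 2) + I(as.numeric(xg == 2)))
  lod_hand <- (6 / 2) * log10(sum((y - mean(y))^2) / sum(stats::resid(fit)^2))
  expect_equal(lodProfile(scan)$lod, lod_hand, tolerance = 1e-10)
  # constant phenotype is rejected
  expect_error(scanSingleQTL(rep(1, 6), draws), "constant phenotype")
})

test_that("LOD is invariant to affine phenotype transformation and collapses for identical draws", {
  set.seed(71)
  cfg <- new("F2SimConfig", chrLengths = 60, nMarkers = 10,
             nIndividuals = 80, seed = 71,
             qtl = data.frame(chrom = 1L, pos = 30, add = 1, dom = 0))
  mp <- simMap(cfg)
  sim <- simF2(mp, cfg)
  d <- conditionalGenotypeDraws(sim$abh, mp, stepCM = 5, nDraws = 3, seed = 72)
  l1 <- lodProfile(scanSingleQTL(sim$phenotype, d))$lod
  l2 <- lodProfile(scanSingleQTL(3 * sim$phenotype + 5, d))$lod
  expect_equal(l1, l2, tolerance = 1e-8)
  # stacking one draw four times equals the single draw profile
  d1 <- d; d1@draws <- d@draws[, , 1, drop = FALSE]
  d4 <- d; d4@draws <- array(d@draws[, , c(1, 1, 1, 1)],
                             c(dim(d@draws)[1:2], 4))
  expect_equal(lodProfile(scanSingleQTL(sim$phenotype, d4))$lod,
               lodProfile(scanSingleQTL(sim$phenotype, d1))$lod,
               tolerance = 1e-10)
})

test_that("permutation thresholds follow the empirical quantile definition", {
  set.seed(73)
  cfg <- new("F2SimConfig", chrLengths = 60, nMarkers = 8,
             nIndividuals = 60, seed = 73)
  mp <- simMap(cfg)
  sim <- simF2(mp, cfg)
  d <- conditionalGenotypeDraws(sim$abh, mp, stepCM = 10, nDraws = 2, seed = 74)
  p1 <- permutationThreshold(sim$phenotype, d, nPerm = 60, alpha = 0.05,
                             seed = 75)
  # alpha = 1 gives the minimum of the max-LOD null distribution
  p2 <- permutationThreshold(sim$phenotype, d, nPerm = 60, alpha = 1,
                             seed = 75)
  expect_equal(p2$threshold, min(p2$max_lods))
  expect_equal(p1$max_lods, p2$max_lods)  # same seed, same null draws
  expect_gte(p1$threshold, p2$threshold)
})

test_that("credible intervals cover the peak with the requested mass", {
  # single-point spike: the interval is that point
  spike <- data.frame(pos = 0:10, lod = c(rep(0, 5), 50, rep(0, 5)))
  ci <- bayesCredibleInterval(spike)
  expect_equal(c(ci$left, ci$right), c(5, 5))
  # flat profile on [0, 100]: central interval of about 95 cM
  flat <- data.frame(pos = 0:100, lod = rep(1.3, 101))
  cif <- bayesCredibleInterval(flat)
  expect_lt(abs((cif$right - cif$left) - 95), 2.5)
  expect_lt(abs((cif$right + cif$left) / 2 - 50), 2)
  # discretized Gaussian bump: matches an exhaustive smallest-interval oracle
  pos <- seq(0, 80, by = 1)
  lod <- 3 * exp(-(pos - 40)^2 / (2 * 36))
  ci2 <- bayesCredibleInterval(data.frame(pos = pos, lod = lod))
  w <- 10^lod
  seg <- (w[-1] + w[-length(w)]) / 2  # trapezoid areas per unit segment
  total <- sum(seg)
  best <- c(-Inf, Inf)
  peak <- which.max(lod)
  for (l in 1:peak) for (r in peak:length(pos)) {
    if (l == r) next
    if (sum(seg[l:(r - 1)]) / total >= 0.95 &&
        (pos[r] - pos[l]) < (best[2] - best[1])) best <- c(pos[l], pos[r])
  }
  expect_lte(abs(ci2$left - best[1]), 1)
  expect_lte(abs(ci2$right - best[2]), 1)
  expect_gte(ci2$coverage, 0.95)
  # coverage >= prob holds on random profiles
  set.seed(76)
  for (i in 1:20) {
    prof <- data.frame(pos = 0:50, lod = cumsum(rnorm(51, 0, 0.3))^2 / 10)
    expect_gte(bayesCredibleInterval(prof, prob = 0.9)$coverage, 0.9)
  }
})

test_that("variance explained and effects match their definitions", {
  geno <- rep(c("A", "H", "B"), times = c(30, 60, 30))
  y_det <- c(A = -1, H = 0.5, B = 1)[geno]
  expect_equal(varianceExplained(y_det, geno), 100)
  set.seed(77)
  y_ind <- rnorm(500)
  g_ind <- sample(c("A", "H", "B"), 500, TRUE)
  expect_lt(varianceExplained(y_ind, g_ind), 3)
  # effects from class means: mu = (10, 12, 8) -> additive -1, dominance 3
  y <- c(rep(10, 20), rep(12, 20), rep(8, 20))
  g <- rep(c("A", "H", "B"), each = 20)
  eff <- qtlEffects(y, g)
  expect_equal(eff$additive, -1)
  expect_equal(eff$dominance, 3)
  expect_equal(unlist(qtlEffects(rep(1, 60), g)), c(additive = 0, dominance = 0))
  expect_error(qtlEffects(y[1:40], g[1:40]), "all three genotype classes")
})

test_that("the orchestrated scan finds a strong simulated QTL with a sane summary", {
  cfg <- new("F2SimConfig", chrLengths = c(80, 80), nMarkers = 24,
             nIndividuals = 250, seed = 78,
             qtl = data.frame(chrom = 1L, pos = 40, add = 1, dom = 0))
  mp <- simMap(cfg)
  sim <- simF2(mp, cfg)
  scan <- qtlScan(sim$abh, mp, sim$phenotype, stepCM = 2, nDraws = 4,
                  nPerm = 100, seed = 79)
  pk <- scanPeaks(scan)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$chrom, 1)
  expect_lt(abs(pk$peak_cM - 40), 10)
  expect_true(pk$ci_left_cM <= pk$peak_cM && pk$peak_cM <= pk$ci_right_cM)
  expect_gt(pk$lod, scan@threshold)
  expect_gt(pk$percent_variance, 5)
  expect_lt(abs(pk$additive_effect - 1), 0.35)
})
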