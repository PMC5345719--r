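roles6 <- c(rep("parent1_rep", 3), rep("parent2_rep", 3))

test_that("parental consistency keeps only fixed, alternate, homozygous sites", {
  calls <- rbind(
    c("GG", "GG", "GG", "TT", "TT", "TT"),  # consistent, alternate -> keep
    c("GG", "GG", "TT", "TT", "TT", "TT"),  # parent1 replicates disagree
    c("GG", "GG", "GG", "GG", "GG", "GG"),  # identical consensus alleles
    c("GT", "GT", "GT", "TT", "TT", "TT"),  # heterozygous parent
    c(NA,   NA,   NA,   "TT", "TT", "TT"),  # parent1 all missing
    c("GG", NA,   "GG", "TT", NA,   "TT"))  # missing replicates tolerated
  m <- site_fixture(calls, roles = roles6)
  out <- filterParentalConsistency(m)
  expect_equal(markerInfo(out)$id, c("s1", "s6"))
  expect_equal(markerInfo(out)$parentA, c("G", "G"))
  expect_equal(markerInfo(out)$parentB, c("T", "T"))
  rep <- filterReport(out)
  expect_equal(rep$stage, "parental_consistency")
  expect_equal(rep$sites_in, 6)
  expect_equal(rep$sites_out, 2)
})

make_maf_fixture <- function(nAA, nHet, nBB, nMiss = 0) {
  f2 <- c(rep("GG", nAA), rep("GT", nHet), rep("TT", nBB),
          rep(NA, nMiss))
  calls <- rbind(c("GG", "TT", f2))
  m <- site_fixture(calls, roles = c("parent1_rep", "parent2_rep",
                                     rep("f2", length(f2))))
  filterParentalConsistency(m)
}

test_that("MAF is computed on F2 allele copies with strict removal below threshold", {
  # 2 BB + 4 het + 4 AA -> allele counts 12:8, MAF 0.4 -> retained
  expect_equal(nMarkers(filterMAF(make_maf_fixture(4, 4, 2))), 1)
  # 9 AA + 2 het + 0 BB over 11 F2 -> counts 20:2, MAF 1/11 < 0.25 -> removed
  expect_equal(nMarkers(filterMAF(make_maf_fixture(9, 2, 0))), 0)
  # exactly at the boundary: 3 AA + 2 het + 1 BB -> counts 8:4, MAF 1/3;
  # 2 AA + 4 het + 0 BB -> 8:4... use counts 6:2 -> MAF 0.25 -> retained
  expect_equal(nMarkers(filterMAF(make_maf_fixture(2, 2, 0), threshold = 0.25)), 1)
  # all F2 missing -> removed, not an error
  expect_equal(nMarkers(filterMAF(make_maf_fixture(0, 0, 0, nMiss = 3))), 0)
})

test_that("depth masking hits F2 calls below the total-read threshold only", {
  calls <- rbind(c("GG", "TT", "GT", "GT", "GT"))
  dref <- rbind(c(2L, 0L, 3L, 7L, 4L))
  dalt <- rbind(c(0L, 2L, 3L, 0L, 3L))
  m <- site_fixture(calls, roles = c("parent1_rep", "parent2_rep",
                                     rep("f2", 3)),
                    dref = dref, dalt = dalt)
  out <- maskLowDepth(m, minDepth = 7)
  expect_true(is.na(out@geno1[1, 3]))        # 3+3 = 6 < 7 -> masked
  expect_equal(unname(out@geno1[1, 4]), "G") # 7+0 = 7 -> kept
  expect_equal(unname(out@geno1[1, 5]), "G") # 4+3 = 7 -> kept
  expect_equal(unname(out@geno1[1, 1]), "G") # low-depth parent untouched
  expect_equal(filterReport(out)$calls_masked, 1)
  # minDepth = 1 masks nothing that has any read
  out1 <- maskLowDepth(m, minDepth = 1)
  expect_equal(out1@geno1, m@geno1)
  # masking never changes a genotype to anything but missing
  changed <- which(!is.na(m@geno1) & is.na(out@geno1))
  expect_true(all(is.na(out@geno1[changed])))
})

test_that("undercall probability matches the closed form and exhaustive enumeration", {
  expect_identical(undercallProbability(7), 0.015625)
  expect_identical(undercallProbability(1), 1)
  expect_identical(undercallProbability(10), 0.001953125)
  expect_error(undercallProbability(0), "integer >= 1")
  # enumeration oracle: all 2^d equiprobable read-origin vectors, counting
  # the all-one-parent outcomes
  for (d in 1:12) {
    vecs <- as.matrix(expand.grid(rep(list(0:1), d)))
    frac <- mean(rowSums(vecs) %in% c(0, d))
    expect_equal(undercallProbability(d), frac)
  }
})

test_that("thinning keeps the greedy maximal set from the left, per chromosome", {
  m <- site_fixture(matrix("GT", 4, 1), roles = "f2",
                    pos = c(100, 150, 170, 300))
  out <- thinSites(m, minBp = 64)
  expect_equal(markerInfo(out)$pos, c(100, 170, 300))
  # a distance of exactly the threshold qualifies
  m2 <- site_fixture(matrix("GT", 2, 1), roles = "f2", pos = c(100, 164))
  expect_equal(nMarkers(thinSites(m2, 64)), 2)
  # single site is kept; chromosomes are independent
  m3 <- site_fixture(matrix("GT", 3, 1), roles = "f2",
                     chrom = c("1", "2", "2"), pos = c(100, 110, 120))
  expect_equal(markerInfo(thinSites(m3, 64))$pos, c(100, 110))
})

test_that("site missingness removal uses a strict 'exceeds' boundary", {
  build <- function(nMiss) {
    f2 <- c(rep("GT", 813 - nMiss), rep(NA, nMiss))
    site_fixture(rbind(f2), roles = rep("f2", 813))
  }
  expect_equal(nMarkers(filterSiteMissingness(build(40), 0.05)), 1)  # 4.92%
  expect_equal(nMarkers(filterSiteMissingness(build(41), 0.05)), 0)  # 5.04%
  expect_equal(nMarkers(filterSiteMissingness(build(500), 1.0)), 1)  # identity
})

test_that("allelic depth ratios flag calls outside the two-fold band", {
  calls <- rbind(c("GG", "TT", "GT", "GT", "GT", "GT"))
  dref <- rbind(c(9L, 0L, 6L, 10L, 5L, 4L))
  dalt <- rbind(c(0L, 9L, 5L, 4L, 5L, 0L))
  m <- filterParentalConsistency(
    site_fixture(calls, roles = c("parent1_rep", "parent2_rep", rep("f2", 4)),
                 dref = dref, dalt = dalt))
  st <- allelicDepthRatioStats(m)
  expect_equal(st$n_het, 4)
  expect_equal(st$n_zero_denominator, 1)
  # ratios 6/5 = 1.2 (in), 10/4 = 2.5 (out), 5/5 = 1 (in)
  expect_equal(st$fraction_within_2fold, 2 / 3)
  # equal depths everywhere -> everything inside the band
  m2 <- filterParentalConsistency(
    site_fixture(rbind(c("GG", "TT", "GT", "GT")),
                 roles = c("parent1_rep", "parent2_rep", "f2", "f2"),
                 dref = rbind(c(9L, 0L, 7L, 4L)),
                 dalt = rbind(c(0L, 9L, 7L, 4L))))
  expect_equal(allelicDepthRatioStats(m2)$fraction_within_2fold, 1)
})

test_that("the filter pipeline records stages in the fixed order and only shrinks", {
  set.seed(21)
  nF2 <- 40
  calls <- rbind(
    cbind(matrix("GG", 8, 3), matrix("TT", 8, 3),
          matrix(sample(c("GG", "GT", "TT", NA), 8 * nF2, replace = TRUE,
                        prob = c(0.24, 0.5, 0.24, 0.02)), 8, nF2)))
  dref <- matrix(9L, 8, 6 + nF2); dalt <- matrix(9L, 8, 6 + nF2)
  m <- site_fixture(calls, roles = c(roles6, rep("f2", nF2)),
                    pos = c(100, 120, 200, 300, 310, 400, 500, 600),
                    dref = dref, dalt = dalt)
  out <- filterSiteMissingness(
    thinSites(maskLowDepth(filterMAF(filterParentalConsistency(m)), 7), 64),
    0.75)
  rep <- filterReport(out)
  expect_equal(rep$stage, c("parental_consistency", "maf", "depth_mask",
                            "thin", "missingness"))
  expect_true(all(rep$sites_out <= rep$sites_in))
  expect_true(all(markerInfo(out)$id %in% markerInfo(m)$id))
})
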