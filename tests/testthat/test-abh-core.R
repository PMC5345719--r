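test_that("ABH encoding maps parental-consensus genotypes and everything else to N", {
  calls <- rbind(c("GG", "TT", "GG", "GT", "TT", NA, "GC"))
  m <- filterParentalConsistency(
    site_fixture(calls, roles = c("parent1_rep", "parent2_rep", rep("f2", 5))))
  g <- encodeABH(m)
  expect_equal(unname(abhCodes(g)[, 1]), c("A", "H", "B", "N", "N"))
  # an all-parental-allele matrix introduces no N
  calls2 <- rbind(c("GG", "TT", "GG", "GT", "TT"))
  g2 <- encodeABH(filterParentalConsistency(
    site_fixture(calls2, roles = c("parent1_rep", "parent2_rep", rep("f2", 3)))))
  expect_false(any(abhCodes(g2) == "N"))
  # a site without consensus is an error
  m3 <- site_fixture(calls, roles = c("parent1_rep", "parent2_rep",
                                      rep("f2", 5)))
  expect_error(encodeABH(m3), "consensus")
})

pass_str <- function(fn, s, ...) abh_string(fn(abh_from_strings(s), ...))

test_that("imputation fills N runs with matching flanks and nothing else", {
  expect_equal(pass_str(imputeFlankedMissing, "ANNNA"), "AAAAA")
  expect_equal(pass_str(imputeFlankedMissing, "ANNB"), "ANNB")
  expect_equal(pass_str(imputeFlankedMissing, "NNAHB"), "NNAHB")
  expect_equal(pass_str(imputeFlankedMissing, "BHNNN"), "BHNNN")
  # no length limit on imputed stretches
  expect_equal(pass_str(imputeFlankedMissing,
                        paste0("H", strrep("N", 12), "H")),
               strrep("H", 14))
})

test_that("heterozygote-undercall correction rewrites short flanked non-H runs", {
  expect_equal(pass_str(correctUndercalledHet, "HAAAAH"), "HHHHHH")
  expect_equal(pass_str(correctUndercalledHet, "HAAAAAH"), "HAAAAAH")
  expect_equal(pass_str(correctUndercalledHet, "HANBH"), "HHHHH")
  expect_equal(pass_str(correctUndercalledHet, "AAHBBH"), "AAHHHH")
  expect_equal(pass_str(correctUndercalledHet, "HAAH", hetRunMax = 1), "HAAH")
})

test_that("short-stretch correction replaces flanked single-value runs", {
  expect_equal(pass_str(correctShortStretches, "ABA"), "AAA")
  expect_equal(pass_str(correctShortStretches, "AHA"), "AAA")
  expect_equal(pass_str(correctShortStretches, "ABBA"), "ABBA")
  expect_equal(pass_str(correctShortStretches, "ABBA", stretchRunMax = 2),
               "AAAA")
  expect_equal(pass_str(correctShortStretches, "HNH"), "HHH")
})

test_that("the full postprocess reproduces the worked single-individual trace", {
  g <- abh_from_strings("AANAHAHHBNB")
  res <- postprocessABH(g)
  expect_equal(abh_string(res$abh), "AAAAHHHHBBB")
  expect_equal(res$stats$cells_imputed, 2)
  # a noise-free F2 simulation passes through unchanged
  cfg <- new("F2SimConfig", chrLengths = c(120, 90), nMarkers = 30,
             nIndividuals = 40, seed = 2)
  sim <- simF2(simMap(cfg), cfg)
  res2 <- postprocessABH(sim$abh)
  expect_equal(res2$stats$cells_imputed, 0)
  # with no missing data the imputation pass is the identity; the correction
  # passes may still rewrite genuine short double-recombinant runs, but they
  # must never introduce missingness
  expect_false(any(abhCodes(res2$abh) == "N"))
})

test_that("each pass matches its naive explicit-scan oracle exhaustively to length 5", {
  for (L in 3:5) {
    rows <- all_abh_strings(L)
    g <- ABHMatrix(rows, data.frame(id = paste0("m", seq_len(L)), chrom = "1",
                                    pos = seq_len(L)))
    expect_identical(unname(abhCodes(imputeFlankedMissing(g))),
                     unname(oracle_rows(rows, oracle_impute)))
    expect_identical(unname(abhCodes(correctUndercalledHet(g))),
                     unname(oracle_rows(rows, oracle_het)))
    expect_identical(unname(abhCodes(correctShortStretches(g))),
                     unname(oracle_rows(rows, oracle_stretch)))
  }
})

test_that("imputation and correction respect their structural invariants", {
  set.seed(31)
  for (rep in 1:25) {
    L <- sample(10:40, 1)
    s <- matrix(sample(c("A", "B", "H", "N"), 3 * L, replace = TRUE,
                       prob = c(0.3, 0.3, 0.3, 0.1)), 3, L)
    g <- ABHMatrix(s, data.frame(id = paste0("m", 1:L), chrom = "1",
                                 pos = 1:L))
    gi <- imputeFlankedMissing(g)
    nonN <- abhCodes(g) != "N"
    # imputation never alters a non-missing genotype
    expect_identical(abhCodes(gi)[nonN], abhCodes(g)[nonN])
    # correction passes never produce N
    gh <- correctUndercalledHet(gi)
    gs <- correctShortStretches(gh)
    expect_false(any(abhCodes(gh) == "N" & abhCodes(gi) != "N"))
    expect_false(any(abhCodes(gs) == "N" & abhCodes(gh) != "N"))
    # N count is non-increasing across the full postprocess
    res <- postprocessABH(g)
    expect_lte(sum(abhCodes(res$abh) == "N"), sum(abhCodes(g) == "N"))
    # imputation and het-correction are idempotent on their own output; the
    # stretch pass works on runs of its input, so alternating patterns like
    # ABABA may need a second application -- it must converge, not oscillate
    expect_identical(abhCodes(imputeFlankedMissing(gi)), abhCodes(gi))
    expect_identical(abhCodes(correctUndercalledHet(gh)), abhCodes(gh))
    gs2 <- correctShortStretches(gs)
    expect_lte(sum(abhCodes(gs2) != abhCodes(gs)),
               sum(abhCodes(gs) != abhCodes(gh)))
    # a second full postprocess changes no more cells than the first
    res2 <- postprocessABH(res$abh)
    expect_lte(sum(abhCodes(res2$abh) != abhCodes(res$abh)),
               sum(abhCodes(res$abh) != abhCodes(g)))
  }
})

test_that("chromosomes are processed in isolation", {
  # the A run straddling the chromosome boundary must not be treated as
  # H-flanked, and N at a chromosome edge must not be imputed across it
  g <- abh_from_strings("HAAAHANA", chrom = c(rep("1", 4), rep("2", 4)))
  out <- postprocessABH(g)$abh
  expect_equal(abh_string(out), paste0("HAAA", "HAAA"))
  g2 <- abh_from_strings("AANBBN", chrom = c(rep("1", 3), rep("2", 3)))
  expect_equal(pass_str(imputeFlankedMissing, "AAN"), "AAN")
  expect_equal(abh_string(imputeFlankedMissing(g2)), "AANBBN")
})

test_that("merging unions markers and individuals, then re-imputes", {
  g1 <- ABHMatrix(matrix(c("A", "A", "A", "B"), 2, 2,
                         dimnames = list(c("i1", "i2"), NULL)),
                  data.frame(id = c("a", "b"), chrom = "1",
                             pos = c(100e3, 300e3)))
  g2 <- ABHMatrix(matrix(c("H", "H"), 2, 1,
                         dimnames = list(c("i3", "i4"), NULL)),
                  data.frame(id = "c", chrom = "1", pos = 200e3))
  mg <- mergePopulations(g1, g2)
  expect_equal(nMarkers(mg), 3)
  expect_equal(nSamples(mg), 4)
  expect_equal(markerInfo(mg)$pos, c(100e3, 200e3, 300e3))
  # i1 has A at both flanks -> imputed A at the unassayed middle marker
  expect_equal(unname(abhCodes(mg)["i1", ]), c("A", "A", "A"))
  # i2 has conflicting flanks -> middle stays N
  expect_equal(unname(abhCodes(mg)["i2", ]), c("A", "N", "B"))
  # population-2 individuals keep N at edge markers (no flank on one side)
  expect_equal(unname(abhCodes(mg)["i3", ]), c("N", "H", "N"))
  # overlapping individual sets are rejected
  expect_error(mergePopulations(g1, g1), "disjoint")
  # shared position with a different marker identity is rejected
  g3 <- ABHMatrix(matrix("B", 1, 1, dimnames = list("i9", NULL)),
                  data.frame(id = "zzz", chrom = "1", pos = 100e3))
  expect_error(mergePopulations(g1, g3), "conflicting")
})

test_that("postprocess on noisy simulations strictly reduces missingness", {
  set.seed(41)
  cfg <- new("F2SimConfig", chrLengths = 100, nMarkers = 50,
             nIndividuals = 30, seed = 41)
  sim <- simF2(simMap(cfg), cfg)
  noisy <- applyGBSNoise(sim$abh,
                         new("GBSNoiseConfig", missingRate = 0.05),
                         seed = 42)$abh
  res <- postprocessABH(noisy)
  expect_lt(sum(abhCodes(res$abh) == "N"), sum(abhCodes(noisy) == "N"))
})
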