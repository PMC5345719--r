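---
title: "Methods: GBS post-processing, map estimation and QTL scanning in gbsf2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GBS post-processing, map estimation and QTL scanning in gbsf2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbsf2)
```

# The problem

An F2 intercross between two inbred (or effectively fixed) parents is the
cheapest population in which to map quantitative trait loci, and the most
awkward one to genotype by sequencing. Each locus segregates 1:2:1
(parent-1 homozygote : heterozygote : parent-2 homozygote), so about half of
all true genotypes are heterozygous, and a heterozygote is only called
correctly when reads from *both* alleles are observed. At read depth $d$ the
probability that all reads sample a single allele is

$$P_{\text{undercall}}(d) = 2 \cdot (1/2)^d,$$

which `undercallProbability()` implements: 50% at $d=2$, 12.5% at $d=4$, and
1.5625% at the $d \ge 7$ floor the filtering stage enforces. Undercalled
heterozygotes, plus a smaller class of systematic miscalls at markers where
the two parental genomes differ structurally, are the error budget the whole
pipeline is designed around.

# Filtering

`SiteMatrix` holds post-calling genotypes (sites × samples) with per-allele
read depths; sample roles (`parent1_rep`, `parent2_rep`, `f2`) come from a
sidecar table because parental replicates are rarely named systematically.
The filters run in a fixed order, each appending to an audit log:

1. **Parental consistency** (`filterParentalConsistency`): keep a site only
   if all non-missing parent-1 replicate calls agree, all parent-2 calls
   agree, both consensus calls are homozygous, and the consensus alleles
   differ. Sites where a parent has no call are dropped, not guessed.
2. **MAF** (`filterMAF`): minor allele frequency over F2 allele *copies*
   (homozygote = 2, heterozygote = 1 + 1); sites strictly below 0.25 are
   removed. Computed over F2 samples only — the parents contribute exactly
   one copy of each allele by construction and would drag every site toward
   0.5.
3. **Depth mask** (`maskLowDepth`): F2 calls with total depth < 7 become
   missing. Parental calls are exempt; their reliability is already enforced
   by rule 1, and masking them would discard sites rather than calls.
4. **Thinning** (`thinSites`): greedy left-to-right per chromosome with a
   64 bp minimum gap, keeping the first site of each crowded cluster. SNPs
   within one 64 bp sequencing tag are almost always redundant copies of the
   same segregation signal.
5. **Missingness** (`filterSiteMissingness`): drop sites whose missing
   fraction among F2 calls exceeds the chosen tier (0.05 / 0.50 / 0.75).

MAF is evaluated before the depth mask (the order used by upstream callers);
both the order and every threshold are arguments, so the alternative is one
call away.

# ABH encoding, imputation and error correction

`encodeABH` maps each F2 call to A (parent-1 homozygote), B (parent-2
homozygote), H (heterozygote) or N (missing *or* carrying a non-parental
allele — such calls are treated as evidence of structural divergence and
handled by the run-length rules downstream rather than raised as errors).

The corrections exploit one fact about F2 genomes: true haplotype blocks are
long (crossovers arrive at roughly one per Morgan per gamete), so very short
runs interrupting a uniform block are overwhelmingly likely to be errors.
Three passes run in a fixed order on each individual × chromosome string:

1. **Imputation** (`imputeFlankedMissing`): every maximal run of N whose
   nearest non-missing neighbours on both sides are equal becomes that
   genotype, with no length limit. Conflicting or absent flanks leave the
   run untouched.
2. **Heterozygote-undercall correction** (`correctUndercalledHet`): every
   maximal run of homozygous-or-missing calls of length ≤ 4 flanked
   immediately by H on both sides becomes H. The threshold (default 4) is
   the empirical "minimum believable haplotype length" for the marker
   densities this method targets.
3. **Short-stretch correction** (`correctShortStretches`): every maximal
   single-genotype run of length ≤ 1 whose two neighbours are equal, and
   carry an actual genotype, is rewritten to the neighbour value. This
   removes the `AHA`/`ABA`-type singletons.

Each pass computes its maximal runs from the *input* string, not the
partially rewritten one, so results are independent of scan direction. Two
consequences are deliberate and tested: the stretch pass on pathological
alternating input (`ABABA`) needs a second application to reach its fixed
point (it converges, never oscillates), and a run flanked by N is never
"corrected" into missingness — a correction pass must not destroy calls, so
N flanks disqualify replacement while N *runs* (e.g. `H N H` or the mixed
`H A N B H`) are still rewritten.

Why flank-based imputation is safe here: with a map of density
$\delta$ cM/Mb, the chance of a *double* crossover inside a window of $w$ Mb
is approximately $(\delta w / 100)^2$ (`doubleCrossoverRisk`). At
3.84 cM/Mb and 1 Mb windows that is $0.0384^2 \approx 1.5 \times 10^{-3}$ —
about one missed double crossover per ~1500 imputation events.

`mergePopulations` combines two populations assayed with different enzymes
(disjoint individuals, largely disjoint markers) on physical position, fills
the unassayed cells with N, and re-runs imputation. Merging happens after
each population's own postprocess.

# Error profiling

`countMotifs` counts the six width-3 motifs `HAH, HBH, AHA, BHB, ABA, BAB`
(a genotype flanked by two equal, different genotypes) per marker and per
individual on imputed but *not* corrected data — after correction the motifs
are gone by construction. Windows containing N are skipped (absence of
evidence), and overlapping windows all count; both choices are assertions in
the test suite. `alleleFrequencyProfile` adds per-marker A/H/B frequencies
and a 2-df chi-square statistic against 1:2:1 as a segregation-distortion
flag (an extension beyond plotting frequencies; distorted regions in wide
crosses often mark incompatibility loci). `markerDensity` bins markers into
half-open 1 Mb windows.

# Genetic maps

`estimateRF` maximizes the F2 two-point likelihood on the 3×3 genotype
table by EM. All classes except the double heterozygote determine their
recombinant-gamete count (0, 1 or 2); the double-het class is a phase
mixture with expected count $2r^2/(r^2 + (1-r)^2)$. The update is the
expected recombinant fraction over $2n$ gametes, iterated to
$|\Delta r| < 10^{-8}$ (≤ 1000 iterations), clipped to $[0, 0.5]$. A
0.0001-step grid search over the same likelihood serves as the independent
oracle in tests (agreement to $10^{-3}$).

`estimateMap` chains adjacent-pair estimates along the physical marker
order — a deliberate simplification versus a multipoint HMM. After
imputation the data are nearly complete, in which case adjacent two-point
MLEs carry essentially all the linkage information, are orders of magnitude
cheaper, and are testable against a closed-form oracle. Pairs with an N are
dropped from the pair likelihood rather than re-imputed inside the
estimator. $r$ is capped at 0.4999 before the map function (Haldane default,
Kosambi by flag) to keep distances finite. De novo marker ordering is out of
scope: physical order is trusted.

# Single-QTL scanning

`conditionalGenotypeDraws` builds, per chromosome, a grid of step 1 cM
joined with every marker position, and draws genotypes per individual and
grid point from the exact conditional given the nearest non-missing flanking
markers under a no-interference Markov model: gametes switch parental origin
with probability $r(d)$ = inverse Haldane of the flank distance, so the
genotype chain has the 3×3 transition kernel built from two independent
gamete chains. A point on an observed marker reproduces the observation in
every draw; missing flanks degrade gracefully to one-sided or prior
(1:2:1) draws. Draws at different grid points are sampled independently
given the flanks — sufficient for pointwise regression scanning, and much
simpler than joint path sampling; this is documented as a deviation from
joint-chain imputation.

`scanSingleQTL` fits, per grid point and draw, least squares of the trait on
an additive contrast ($-1, 0, +1$ for A/H/B) plus a dominance indicator;
$\mathrm{LOD} = (n/2)\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$, combined
over the default 16 draws as $\log_{10}$ of the mean of $10^{\mathrm{LOD}}$
(computed with a log-sum-exp guard). With one draw the combination is the
identity; rank-deficient designs (a genotype class absent at a grid point)
are handled by projecting on the realized column space. Phenotypes are
assumed numeric and untransformed.

`permutationThreshold` permutes the phenotype vector only — preserving
genotype LD — and takes the empirical $(1-\alpha)$ quantile of the
genome-wide maximum LOD over 1000 permutations (α = 0.05 default). The
permutation scan shares the per-position orthonormal basis with the real
scan, so 1000 permutations cost one matrix product per position × draw.

`bayesCredibleInterval` rescales $10^{\mathrm{LOD}}$ on one chromosome to
unit area using trapezoid point masses (tolerating the uneven marker+grid
spacing), then expands outward from the peak, greedily adding the heavier
neighbour (ties balance the interval), until coverage reaches 95%. Endpoints
are grid points, so realized coverage is ≥ the target; on a flat profile the
interval is the central 95% of the chromosome, and a single dominant point
can be an interval of width zero on a coarse grid. Peak effects and percent
variance come from *observed* genotypes at the marker nearest the peak
($a = (\mu_B - \mu_A)/2$, positive when the parent-2 homozygote raises the
trait; $d = \mu_H - (\mu_A+\mu_B)/2$; $100 R^2$ of the two-term model) —
deterministic, and faithful to "effects from class means".

# The simulator

`simMap`/`simF2`/`applyGBSNoise` generate the study conditions the rest of
the package is tested against. Defaults: twelve chromosomes of
140, 115, 130, 110, 100, 105, 110, 100, 75, 80, 100, 105 cM (a rice F2
microsatellite map; total 1270 cM), markers allocated proportionally to
length and equally spaced including both ends, additive QTL effect 0.5,
dominance 0, residual SD 1. Gametes receive Poisson(length/100) crossovers
at uniform positions — no interference, consistent with the Haldane map
function used in estimation. Phenotype = $\sum_q a_q x_q + d_q \mathbf{1}(H_q)$
+ Gaussian noise, $x \in \{-1, 0, 1\}$. Under this parameterization one
QTL with $a = 0.5$ contributes $a^2/2 = 0.125$ genetic variance, i.e. 11.1%
of a total variance of 1.125 — the parameterization is stated precisely
because alternative per-QTL variance-share figures quoted for similar
designs are not derivable from these parameters, and no such figure is
treated as a target here.

GBS noise is applied independently per cell in three mechanisms: missingness
at a flat rate; heterozygote undercalling, where an H cell with a depth
drawn from the configured distribution flips to A or B (equal odds) with
probability $2(1/2)^d$; and designated error-prone markers that flip H→B and
A→H at configured rates, reproducing the empirically co-occurring HBH/AHA
error signature. What the simulator does **not** emulate: crossover
interference, segregation distortion (a per-marker viability hook is out of
scope), read-level artifacts, linked error processes along a tag, and
non-random missingness. Tests passing on this generator therefore validate
the algorithms under clean Mendelian assumptions, not the full messiness of
real libraries.

`powerExperiment` wraps simulate → scan → threshold over an
individuals × markers grid, counting a QTL as detected when any grid point
within ±10 cM of its true position reaches the genome-wide threshold, with
200 permutations by default at desk scale (a flag restores 1000).

# In-silico digests

`countSites` counts recognition-site occurrences (PstI `CTGCAG`, KpnI
`GGTACC`, MspI `CCGG` built in) by exact pattern matching on the uppercased
sequence, overlapping matches allowed; palindromic sites are counted once
per location, non-palindromic patterns are additionally scanned on the
reverse complement, and `N` never matches. Soft-masked (lowercase) bases
count by default — mask provenance varies between assemblies — with
`respectMask = TRUE` to exclude them; case is preserved by reading FASTA
through a byte-exact container. `predictGBSFragments` enumerates intervals
bounded by one rare- and one common-cutter site with no internal site of
either enzyme, using site start coordinates (cut offsets within the site are
ignored, since enzyme choice needs site counts, not exact fragment ends).

# Numerical and testing choices

* Exhaustive oracle equivalence for the three ABH passes is run over **all
  strings up to length 7** plus 10⁴ random strings of lengths 12–40: every
  rewritable pattern (run of ≤ 4 plus two flanks) fits within a length-7
  window, and the naive per-character scan oracle stays affordable at that
  size.
* Null calibration of the scan uses a 30 cM single-chromosome genome so the
  ±10 cM detection window spans most of the genome and the windowed false
  positive rate tracks α; 100 replicates give a 3σ binomial band.
* Parameter recovery (a = 0.5, d = 0.25, n = 600) uses a four-chromosome
  495 cM genome with 100 markers, 2 cM grid, 8 draws and 200 permutations
  over 20 seeds — sizes chosen so the full suite runs in minutes on one CPU
  while keeping the genetic parameters at their stated values.
* EM tolerance $10^{-8}$, map-function cap $r \le 0.4999$, LOD floored at 0,
  RSS floored at $10^{-12}$ to guard exact fits, credible-interval ties
  resolved toward the balanced interval, thinning ties impossible by the
  position-uniqueness invariant.

# Known limitations

* **The correction rules over-correct genuine double crossovers at moderate
  marker density.** A true homozygous run flanked by H spans ≤ 4 markers
  with probability ≈ $1 - (1-2r)^4$ per run ($r$ = adjacent-marker
  recombination fraction). Under the no-interference simulator at 400
  markers / 1270 cM this erases enough genuine recombination that the
  corrected map sits 10–20% *below* the simulated truth even though the
  uncorrected, error-injected map is inflated ~80% above it and the
  estimator itself is unbiased on clean data (tests measure all three). Real
  meioses show strong positive interference, which makes tight genuine
  double crossovers far rarer than Poisson placement predicts, so on real
  data the bias is much smaller — but users mapping at coarse density should
  expect conservatively short maps, and the deflation shrinks as marker
  density grows.
* Single-marker effect estimates at the peak are attenuated (and dominance
  inflated) by residual genotyping error at that marker; the scan's LOD and
  localization are much more robust than the effect sizes.
* Two-point map chaining ignores information in non-adjacent pairs when
  missingness is high; run imputation first.
* The stretch-correction pass is order-independent but not single-pass
  idempotent on alternating pathological input; it converges on a second
  application.
* No multiple-QTL models, covariates, interference-aware map functions
  during estimation, or nonparametric scans.
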