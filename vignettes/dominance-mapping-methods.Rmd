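---
title: "Estimating dominance variance and mapping dominance QTL in low-heritability fertility traits"
author: "domvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dominance variance and mapping dominance QTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domvar)
```

## The problem

Female fertility traits in dairy cattle — the number of inseminations
(NINS), the interval from calving to first insemination (ICF), and the
interval from first to last insemination (IFL) — have heritabilities of a
few percent. Because recessive deleterious alleles and inbreeding depression
plausibly act on fertility, a substantial share of their genetic variation
may be non-additive. `domvar` implements a complete pipeline for asking two
questions on SNP-chip data from genotyped females: how much dominance
genetic variance do these traits carry, and can individual loci with
dominance effects be mapped at realistic sample sizes?

The pipeline has five stages, each exposed as ordinary functions around S4
data containers (`GenotypeData`, `Pedigree`, `RelMatrix`,
`VarianceComponents`, `NullModelFit`):

1. **Data and QC** — PLINK text genotype I/O and marker quality control
   (MAF < 0.05, call rate < 0.90, Hardy-Weinberg p < 1e-5 as strict
   removal rules, attributed in that order).
2. **Phenotype preparation** — record editing, censoring penalties (+21 d
   IFL, +1 NINS), and pre-correction of fixed effects through a
   pedigree-based sire model, so that the genotyped subset carries
   phenotypes adjusted with the full recorded population's information.
3. **Variance components** — additive (VanRaden) and dominance
   (heterozygosity-deviation) genomic relationship matrices and an
   average-information REML engine for `y = 1mu + a + d + e`.
4. **Association** — a mixed-model scan fitting the three genotype classes
   of each marker as fixed effects on top of a pedigree polygenic term,
   with a two-step additive/dominance significance procedure under FDR
   control.
5. **Power study** — a gene-drop simulation framework measuring the power
   and precision of dominance-QTL detection for a given study design.

## Models

### Sire model for pre-correction

For heifers, records follow `y = Xb + Z_s s + e`; for cows
`y = Xb + Z_s s + Z pe + e`, with `s ~ N(0, sigma_s^2 A_s)` over the sire
pedigree, iid permanent-environment effects `pe` for repeated cow parities,
and iid residuals. Fixed effects are herd, year-month of first insemination,
a linear age covariate (age at first insemination for heifers, at first
calving for cows) and parity for cows. Whether ages should enter as classes
or covariates is a genuinely open choice; `domvar` uses linear covariates,
which is parsimonious at desk scale and is absorbed exactly by the
pre-correction either way.

Pre-corrected phenotypes are `y_hc = Z_s s + e` for heifers and
`y_cc = Z_s s + mean_k(e_k)` for cows (permanent-environment effects are
deliberately excluded: they are environmental, not genetic). Cow
reliabilities follow `r^2 = n h^2 / ((n-1) h^2 + 1)` over `n` parities and
become residual weights `w = r^2/(1-r^2)`, standardized to mean 1 so that
the residual variance keeps its original scale — the standardization
convention is otherwise arbitrary. The heritabilities used in the
reliability formula are configuration inputs (defaults 0.02 for IFL, 0.03
for NINS, 0.04 for ICF, typical for these traits); heifer phenotypes carry
unit weights.

### Genomic relationship matrices

`genomicG()` builds VanRaden method-1 `G = ZZ'/sum 2 p q` with codes
centered at `2p` and observed sample frequencies (base-population
frequencies are unknowable here; the sample convention is standard).
`genomicD()` builds the dominance matrix from heterozygosity deviations:
`H[i,j] = 1 - 2 p_j q_j` for a heterozygote and `-2 p_j q_j` otherwise,
`D = HH'/sum 2 p_j q_j (1 - 2 p_j q_j)`. Under Hardy-Weinberg proportions
both diagonals average 1, which the test suite verifies on simulated panels.
Missing calls contribute their expectation (zero after centering) — unbiased
and cheap; X-linked markers are excluded from both matrices but are kept by
QC so they remain available for other analyses.

### AI-REML

`aiReml()` maximizes the restricted likelihood of
`y = Xb + sum_k u_k + e`, `u_k ~ N(0, sigma_k^2 K_k)`,
`e ~ N(0, sigma_e^2 diag(1/w*))` by average-information updates with
step-halving, an EM fallback whenever the AI step would leave the parameter
space or reduce the likelihood, and boundary clamping at `1e-8` times the
phenotypic variance. Accepted iterations therefore never decrease the
likelihood; convergence is a relative log-likelihood change below `1e-8`
(default, `maxIter = 200`). Asymptotic standard errors come from the
inverse AI matrix at the optimum and proportion (heritability) standard
errors from a first-order Taylor expansion. Non-convergence is reported as
a flag, not an error — models with weighted cow phenotypes can legitimately
fail and downstream code refuses to continue on such fits.

Two implementation paths produce identical estimates: a dense path for any
number of covariance structures (Cholesky of the assembled `V`; adequate
for the 3-5k-individual models this package targets) and a spectral
shortcut when a single structure is present — after scaling by the square
roots of the weights, one eigendecomposition diagonalizes every iteration,
making the per-iteration cost linear in `n`. The shortcut is what makes
100-replicate power studies affordable on one CPU.

### Association scan

The scan model is `y_c = M g + Z u + e` with the three genotype classes
(AA, Aa, aa) as fixed effects, a polygenic term `u ~ N(0, sigma_g^2 A)`
over the pedigree relationship matrix, and weighted residuals. Variance
components are estimated once under the no-marker null and held fixed for
all marker tests (the EMMAX-style approximation); the cached spectral
decomposition then gives each marker's generalized least squares in O(n).
An exact mode that re-estimates the variance components for every marker
(`refitPerSnp = TRUE`) exists for spot checks; on test panels the two agree
to within a few percent on the test statistic.

Step 1 tests `mu_AA = mu_Aa = mu_aa` with a 2-df Wald chi-square (1 df,
flagged, when only two classes are observed) and converts p-values to
q-values; step 2 decomposes significant markers into `a = (mu_aa -
mu_AA)/2` and `d = mu_Aa - (mu_AA + mu_aa)/2` with t-tests from the GLS
covariance of the class means (df `n - 3`), plus the variance explained
`2p(1-p)[a + (1-2p)d]^2` and `[2p(1-p)d]^2` as fractions of a configurable
phenotypic variance (default: sample variance of the pre-corrected
phenotype — reported per-SNP variance fractions in the literature rarely
print their denominator, so it is left explicit here).

q-values use Storey's method with the smoother pi0 estimate (natural-spline
smoothing of `pi0(lambda)` over `lambda = 0.05, ..., 0.95`), implemented
in-package and falling back to `pi0 = 1` (Benjamini-Hochberg) for short
p-value vectors; `method = "BH"` is available directly.

## The synthetic-data generator

Real insemination records and SNP genotypes of commercial dairy populations
are not redistributable, so every stage is exercised against a generator
that emulates their structure:

* **Pedigree** (`simulatePedigree()`): a half-sib-heavy design — few sires,
  many dams, `offspringPerDam` full sibs per mating — with defaults (415
  founders, 20 sires per generation, 3 generations) chosen to yield 3,040
  terminal genotyped females, a realistic genotyped-heifer cohort.
* **Genotypes** (`geneDropGenotypes()`): founder alleles drawn at given
  frequencies, then Mendelian gene drop; loci segregate independently by
  default, with an optional Haldane recombination model (1 cM per Mb when
  no genetic map is given). The default panel emulates one 43-Mb chromosome
  of a 50k bovine chip: about 1,200 evenly spaced markers with founder
  frequencies uniform on [0.05, 0.5] (a post-QC spectrum).
* **Polygenic values** (`simulatePolygenic()`): sampled oldest to youngest;
  founders `N(0, sigma_u^2)`, one known parent `N(a/2, (3/4 - F/4)
  sigma_u^2)`, two known parents `N((a_s + a_d)/2, (1/4(1-F_s) +
  1/4(1-F_d)) sigma_u^2)` with pedigree inbreeding coefficients `F`.
* **QTN phenotypes** (`simulateQtnPhenotypes()`): three QTN at high /
  medium / low minor-allele frequency (0.43 / 0.19 / 0.09), each with
  additive effect solving `2p(1-p)a^2 = f sigma_u^2` (`f` = 0.05 or 0.10;
  the `(1-2p)d` cross-term is deliberately not part of the scaling — the
  simpler convention, and the one consistent with the reported power
  values), dominance `d = h a` for `h` in {-1, -0.5, 0.5, 1}, genotypic
  values coded `-a / d / +a` (shift-invariant for all tests), polygenic
  variance 1 and residual `N(0, 19)` — a trait heritability near 0.05.
* **Fertility records** (`simulateFertilityRecords()`): herd/year-month
  contemporary groups, age covariates, a sire genetic component, zero-
  truncated latent-Gaussian IFL calibrated so the realized heifer mean sits
  near 30 d (cow ICF near 50 d), NINS derived from IFL, and a 15% censoring
  rate.

Because allele frequencies drift through the short, small-`Ne` synthetic
pedigree, each QTN target is planted as a cluster of candidate markers and
the candidate whose realized minor-allele frequency is closest to target is
designated the QTN after the drop (`setupPowerStudy()`) — mirroring a study
that picks QTN among its genotyped markers to represent frequency classes.

What the generator does **not** emulate: linkage disequilibrium of real
cattle chromosomes (founders are in linkage equilibrium and three
generations build almost none), selection history, genotyping error, and
the paperwork quirks of real insemination records. Consequences: mapping
*precision* here reflects an LD-free panel, where the top associated marker
is essentially always the QTN itself or an unlinked false positive, so
precision values are optimistic near zero and occasionally jump by
megabases; power *at the QTN* is unaffected. Passing tests therefore
validate the estimators and the detection machinery, not the fine-scale
localization behaviour expected on real LD structure.

## The power study

`runScenarioGrid()` crosses QTN variance fractions {0.05, 0.10} with
dominance ratios {-1, -0.5, 0.5, 1} (optionally `h = 0`), runs 100
replicates per scenario against a fixed study population, and reports
power — detected QTN over the 300 simulated (3 QTN x 100 replicates) — and
precision — the mean distance in Mb between the most significant marker
within +-5 Mb of the QTN and the QTN itself. The +-5 Mb matching window is
the Voronoi choice for QTN spaced ~10 Mb apart; window 0 restricts
detection to the QTN marker.

Two detection rules are implemented, and the choice matters:

* `"two-step"` declares a QTN detected when some window marker passes the
  genome-scan FDR screen (q <= 0.10) *and* has dominance t-test p < 0.01 —
  the literal real-data procedure applied per replicate.
* `"qtn-dominance"` (default) declares detection from the dominance t-test
  at the QTN marker alone (p < 0.01).

An a-priori calculation shows why the default is the rule that reproduces
reported power values for this design: with ~1,245 markers, q <= 0.10
requires a 2-df p around 1e-4, i.e. a chi-square beyond ~18, while the
per-QTN noncentrality under the stated conditions (n = 3,040, per-QTN
variance 0.05-0.10 on a phenotypic variance of ~20) is at most ~19 — the
screen fails more often than not even for the strongest QTN, capping
two-step power far below values like 0.46 that are attainable, and
predicted almost exactly, by the ungated dominance t-test. The package's
dominance estimator is verifiably calibrated (the empirical spread of
`d_hat` across replicates matches its reported standard error to three
decimals), so the difference between rules is a property of the detection
bookkeeping, not of the test statistics.

## Numerical choices and problem sizes

* Dense REML path: intended for n up to ~3,000-5,000; the spectral path
  handles the same sizes per iteration in O(n) after one
  eigendecomposition (a 3,040 x 3,040 symmetric eigendecomposition takes a
  few seconds on one core).
* A ridge of 1e-6 may be added to near-singular genomic matrices before
  factorization (`ridge =` argument; Cholesky-based simulation of GBLUP
  phenotypes in the test suite does the same).
* Variance components are clamped at `1e-8 * Vp`; zero-variance responses
  return boundary estimates with a converged flag rather than erroring.
* Ties and degenerate markers: monomorphic markers are excluded from scans
  (nothing to test) and dropped from D with a warning (they contribute
  zero to numerator and denominator); two-class markers get a 1-df test
  and no a/d decomposition.
* The test suite runs its heavy checks at reduced but honest sizes: the
  power reproduction uses the full 3,040-female population with 100
  replicates per scenario; GBLUP parameter recovery uses a 640-female
  population with a 700-marker panel and 20 replicates, sizes at which the
  asymptotic standard errors are still informative.

## Known limitations

* No linkage disequilibrium in the default generator (see above); the
  optional recombination model creates Mendelian linkage within families
  but not population LD.
* The scan's default EMMAX-style approximation slightly misstates per-SNP
  test statistics when a marker explains a non-trivial variance share; the
  exact refit mode exists for such markers.
* Permanent-environment and maternal effects beyond the cow `pe` term,
  multi-lactation random regressions, and single-step (pedigree + genomic)
  evaluations are out of scope.
* The two-class (1-df) marker tests are reported but never enter the
  dominance decomposition, so loci with absent heterozygotes cannot be
  declared dominant — a structural limit of genotype-class testing.
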