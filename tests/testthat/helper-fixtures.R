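# Shared fixtures built in code.

# tiny genotype object: codes given as individuals x markers
makeGeno <- function(codes, chrom = "1", bp = NULL, allele1 = "A",
                     allele2 = "G") {
  codes <- as.matrix(codes)
  m <- ncol(codes)
  if (is.null(bp)) bp <- seq_len(m) * 1000
  map <- data.frame(snp = paste0("s", seq_len(m)), chrom = chrom, bp = bp,
                    allele1 = allele1, allele2 = allele2,
                    stringsAsFactors = FALSE)
  GenotypeData(codes, map)
}

# HWE genotypes for n individuals at supplied allele frequencies
hweGeno <- function(n, freqs, seed = 1, chrom = "1") {
  set.seed(seed)
  codes <- vapply(freqs, function(p) rbinom(n, 2, p), numeric(n))
  makeGeno(codes, chrom = chrom)
}

# classic 3-generation pedigree: two founder couples, full sibs B1/B2 from
# one couple, and an offspring of the full-sib mating (F = 0.25)
fullSibPed <- function() {
  Pedigree(id   = c("A1", "A2", "B1", "B2", "C1"),
           sire = c(NA,   NA,   "A1", "A1", "B1"),
           dam  = c(NA,   NA,   "A2", "A2", "B2"))
}

# phenotype with polygenic covariance A and iid residual, no marker effects
nullPheno <- function(st, seed, sigmaG2 = 1, sigmaE2 = 19) {
  set.seed(seed)
  n <- nrow(st$A)
  ch <- chol(st$A + diag(1e-8, n))
  y <- drop(crossprod(ch, rnorm(n)) * sqrt(sigmaG2)) +
    rnorm(n, 0, sqrt(sigmaE2))
  setNames(y, rownames(st$A))
}

# small half-sib study population shared by the heavier association tests;
# built once per test session
smallStudy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ped <- simulatePedigree(nFounders = 90, nGenerations = 2,
                              siresPerGeneration = 8, offspringPerDam = 2,
                              seed = 402)
      # low-MAF targets are fragile at ~300 individuals; keep all three QTN
      # comfortably polymorphic
      sc <- SimulationScenario(0.10, -1, qtnPositions = c(2e6, 5e6, 8e6),
                               qtnMafs = c(0.45, 0.3, 0.2))
      panel <- defaultMarkerPanel(sc, nSnps = 120, lengthMb = 10,
                                  chrom = "25", seed = 402,
                                  qtnCandidates = 5)
      g <- geneDropGenotypes(ped, panel$freqs, panel$map, seed = 403)
      A <- relMat(pedigreeA(ped, subset = genotypedIds(ped)))
      F <- setNames(inbreedingCoefficients(ped), pedIds(ped))
      # pick the candidate marker with realized MAF closest to each target
      map <- markerMap(g)
      maf <- pmin(alleleFreqs(g), 1 - alleleFreqs(g))
      qtnBp <- vapply(seq_along(sc@qtnPositions), function(k) {
        cand <- which(map$qtnTarget %in% k)
        map$bp[cand[which.min(abs(maf[cand] - sc@qtnMafs[k]))]]
      }, numeric(1))
      sc@qtnPositions <- qtnBp
      cache <<- list(ped = ped, g = g, A = A, F = F,
                     cache = buildScanCache(A, g), scenario = sc,
                     qtnBp = qtnBp)
    }
    cache
  }
})
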