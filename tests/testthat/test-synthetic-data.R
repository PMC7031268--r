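test_that("simulated pedigree has the requested structure", {
  ped0 <- simulatePedigree(nFounders = 12, nGenerations = 0, seed = 1)
  expect_equal(nIndividuals(ped0), 12L)
  expect_true(all(is.na(pedSires(ped0))))

  ped <- simulatePedigree(nFounders = 60, nGenerations = 3,
                          siresPerGeneration = 5, offspringPerDam = 2,
                          seed = 2)
  info <- pedInfo(ped)
  nonFounder <- info$generation > 0
  expect_true(all(!is.na(pedSires(ped)[nonFounder])))
  expect_true(all(!is.na(pedDams(ped)[nonFounder])))
  # half-sib family sizes: mean paternal family size ~ offspring / sires
  g1 <- which(info$generation == 1)
  fam <- table(pedSires(ped)[g1])
  expect_equal(mean(fam), length(g1) / length(fam))
  expect_lte(length(fam), 5)
  # genotyped subset = terminal females
  expect_true(all(info$sex[match(genotypedIds(ped), pedIds(ped))] == "F"))
  expect_error(simulatePedigree(nFounders = 4, nGenerations = 1,
                                siresPerGeneration = 5),
               "impossible mating design")
})

test_that("gene drop is Mendelian-consistent and respects fixed loci", {
  ped <- simulatePedigree(nFounders = 16, nGenerations = 2,
                          siresPerGeneration = 3, offspringPerDam = 2,
                          seed = 3)
  map <- data.frame(snp = paste0("m", 1:5), chrom = "1",
                    bp = 1:5 * 1e5, allele1 = "A", allele2 = "B")
  g <- geneDropGenotypes(ped, c(1, 0.5, 0.5, 0.2, 0.8), map, seed = 4,
                         subset = pedIds(ped))
  codes <- genoCodes(g)
  expect_true(all(codes[, 1] == 2L))  # fixed locus
  sp <- match(pedSires(ped), pedIds(ped))
  dp <- match(pedDams(ped), pedIds(ped))
  for (i in which(!is.na(sp))) {
    for (j in seq_len(ncol(codes))) {
      cs <- codes[sp[i], j]; cd <- codes[dp[i], j]; co <- codes[i, j]
      lo <- (cs >= 2) + (cd >= 2)        # forced alt contributions
      hi <- 2 - ((cs <= 0) + (cd <= 0))
      expect_gte(co, lo)
      expect_lte(co, hi)
    }
  }
})

test_that("offspring of 0 x 2 parents are always heterozygous", {
  ped <- Pedigree(id = c("S", "D", paste0("O", 1:50)),
                  sire = c(NA, NA, rep("S", 50)),
                  dam = c(NA, NA, rep("D", 50)))
  map <- data.frame(snp = "m1", chrom = "1", bp = 100,
                    allele1 = "A", allele2 = "B")
  # founder frequency ~ 0.5 keeps redrawing until parents are (0,2)
  found <- FALSE
  for (s in 1:50) {
    g <- geneDropGenotypes(ped, 0.5, map, seed = s, subset = pedIds(ped))
    cs <- genoCodes(g)["S", 1]; cd <- genoCodes(g)["D", 1]
    if (cs + cd == 2 && cs != 1) {
      expect_true(all(genoCodes(g)[-(1:2), 1] == 1L))
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("realized allele frequency tracks the founder frequency", {
  ped <- simulatePedigree(nFounders = 400, nGenerations = 1,
                          siresPerGeneration = 20, offspringPerDam = 4,
                          seed = 5)
  map <- data.frame(snp = paste0("m", 1:3), chrom = "1", bp = 1:3 * 1e5,
                    allele1 = "A", allele2 = "B")
  g <- geneDropGenotypes(ped, c(0.3, 0.5, 0.1), map, seed = 6)
  freq <- alleleFreqs(g)
  n2 <- 2 * nIndividuals(g)
  for (k in 1:3) {
    p0 <- c(0.3, 0.5, 0.1)[k]
    # drift through 20 sires widens the binomial SE; allow 3x the
    # founder-sampling bound plus the sire bottleneck term
    se <- sqrt(p0 * (1 - p0) * (1 / n2 + 1 / (8 * 20)))
    expect_lt(abs(freq[k] - p0), 3.5 * se)
  }
})

test_that("polygenic simulation follows the pedigree sampling rules", {
  ped <- fullSibPed()
  pg0 <- simulatePolygenic(ped, sigmaU2 = 0, seed = 1)
  expect_true(all(pg0$a == 0))

  # conditional variance of full sibs from non-inbred parents: sigma_u2/2;
  # sib covariance 0.5 sigma_u2 over replicate pairs
  n <- 5000
  ped2 <- Pedigree(id = c("S", "D", paste0("K", 1:(2 * n))),
                   sire = c(NA, NA, rep("S", 2 * n)),
                   dam = c(NA, NA, rep("D", 2 * n)))
  pg <- simulatePolygenic(ped2, sigmaU2 = 1, seed = 2)
  kids <- pg$a[-(1:2)]
  parentMean <- mean(pg$a[1:2])
  expect_equal(var(kids), 0.5, tolerance = 0.05)
  expect_lt(abs(mean(kids) - parentMean), 3 * sqrt(0.5 / (2 * n)))
  # independent full-sib pairs across many parent draws
  set.seed(3)
  sib1 <- sib2 <- numeric(600)
  for (r in 1:600) {
    pp <- rnorm(2)
    sib <- rnorm(2, mean(pp), sqrt(0.5))
    sib1[r] <- sib[1]; sib2[r] <- sib[2]
  }
  pedF <- Pedigree(id = c(paste0("s", 1:600), paste0("d", 1:600),
                          paste0("x", 1:600), paste0("y", 1:600)),
                   sire = c(rep(NA, 1200), paste0("s", 1:600),
                            paste0("s", 1:600)),
                   dam = c(rep(NA, 1200), paste0("d", 1:600),
                           paste0("d", 1:600)))
  pgF <- simulatePolygenic(pedF, sigmaU2 = 1, seed = 4)
  x <- pgF$a[match(paste0("x", 1:600), pgF$id)]
  y <- pgF$a[match(paste0("y", 1:600), pgF$id)]
  expect_equal(cov(x, y), 0.5, tolerance = 0.1)
})

test_that("parental inbreeding shrinks Mendelian sampling variance", {
  # both parents fully inbred: offspring conditional variance is 0
  ped <- Pedigree(id = c("A", "B", "C", "D", "E"),
                  sire = c(NA, NA, "A", "A", "C"),
                  dam = c(NA, NA, "B", "B", "D"))
  F <- c(0, 0, 0, 0, 0.25)
  reps <- vapply(1:400, function(s) {
    pg <- simulatePolygenic(ped, sigmaU2 = 1, seed = 1000 + s, F = F)
    pg$a[5] - mean(pg$a[3:4])
  }, numeric(1))
  # E's parents C,D have F = 0 (E itself is inbred); variance (1/4+1/4)
  expect_equal(var(reps), 0.5, tolerance = 0.08)
})

test_that("QTN effects satisfy the variance-scaling algebra", {
  e <- qtnEffects(0.5, 0.10, -1, 1)
  expect_equal(e$a, sqrt(0.2))
  expect_equal(e$d, -sqrt(0.2))
  expect_equal(qtnEffects(0.3, 0.05, 0, 1)$d, 0)
  e2 <- qtnEffects(0.19, 0.05, 1, 1)
  expect_equal(2 * 0.19 * 0.81 * e2$a^2, 0.05)
  expect_equal(e2$a, 0.4030, tolerance = 1e-3)
  expect_error(qtnEffects(0, 0.05, 1), "frequency")
  expect_error(qtnEffects(0.5, 0, 1), "positive")
})

test_that("phenotype variance decomposes into its simulated components", {
  st <- smallStudy()
  sc <- SimulationScenario(0.10, 1, qtnPositions = st$scenario@qtnPositions,
                           qtnMafs = st$scenario@qtnMafs)
  set.seed(99)
  vs <- replicate(60, {
    s <- sample.int(1e7, 1)
    sim <- simulateQtnPhenotypes(st$g, st$ped, sc, seed = s, F = st$F)
    var(sim$y)
  })
  qt <- attr(simulateQtnPhenotypes(st$g, st$ped, sc, seed = 1, F = st$F),
             "qtn")
  vqtn <- sum(2 * qt$p * (1 - qt$p) * (qt$a + (1 - 2 * qt$p) * qt$d)^2 +
                (2 * qt$p * (1 - qt$p) * qt$d)^2)
  expected <- 1 + vqtn + 19
  expect_equal(mean(vs), expected, tolerance = 0.08 * expected)
})

test_that("zero-QTN noise-free phenotypes equal the polygenic values", {
  st <- smallStudy()
  sc <- SimulationScenario(0.05, -1, qtnPositions = numeric(0),
                           qtnMafs = numeric(0), sigmaE2 = 1e-12)
  sim <- simulateQtnPhenotypes(st$g, st$ped, sc, seed = 9, F = st$F)
  expect_equal(sim$y, sim$polygenic, tolerance = 1e-4)
})

test_that("heterozygote class mean reflects the dominance deviation", {
  st <- smallStudy()
  qbp <- st$scenario@qtnPositions[1]
  sc <- SimulationScenario(0.10, 1, qtnPositions = qbp, qtnMafs = 0.43,
                           sigmaE2 = 0.01)
  j <- which(markerMap(st$g)$bp == qbp)
  codes <- genoCodes(st$g)[, j]
  set.seed(98)
  devs <- replicate(200, {
    s <- sample.int(1e7, 1)
    sim <- simulateQtnPhenotypes(st$g, st$ped, sc, seed = s, F = st$F)
    mean(sim$y[codes == 1]) -
      (mean(sim$y[codes == 0]) + mean(sim$y[codes == 2])) / 2
  })
  d <- attr(simulateQtnPhenotypes(st$g, st$ped, sc, seed = 1, F = st$F),
            "qtn")$d[1]
  expect_equal(mean(devs), d, tolerance = 0.15 * abs(d) + 0.05)
})

test_that("fixed seeds reproduce every simulation output bit-for-bit", {
  ped1 <- simulatePedigree(nFounders = 30, nGenerations = 2,
                           siresPerGeneration = 4, seed = 77)
  ped2 <- simulatePedigree(nFounders = 30, nGenerations = 2,
                           siresPerGeneration = 4, seed = 77)
  expect_identical(pedIds(ped1), pedIds(ped2))
  expect_identical(pedSires(ped1), pedSires(ped2))
  map <- data.frame(snp = paste0("m", 1:10), chrom = "1", bp = 1:10 * 1e5,
                    allele1 = "A", allele2 = "B")
  freqs <- seq(0.2, 0.8, length.out = 10)
  g1 <- geneDropGenotypes(ped1, freqs, map, seed = 5)
  g2 <- geneDropGenotypes(ped2, freqs, map, seed = 5)
  expect_identical(genoCodes(g1), genoCodes(g2))
  p1 <- simulatePolygenic(ped1, 1, seed = 6)
  p2 <- simulatePolygenic(ped2, 1, seed = 6)
  expect_identical(p1$a, p2$a)
})

test_that("scenario files round-trip through the key:value reader", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# large-variance complete dominance",
               "varFraction: 0.10",
               "dominanceRatio: -1",
               "qtnPositions: 10109903, 20058762, 30039582",
               "qtnMafs: 0.43, 0.19, 0.09",
               "qtnChrom: 25",
               "sigmaE2: 19",
               "nReps: 100"), f)
  sc <- readScenario(f)
  expect_equal(sc@varFraction, 0.10)
  expect_equal(sc@dominanceRatio, -1)
  expect_equal(sc@qtnMafs, c(0.43, 0.19, 0.09))
  expect_equal(sc@sigmaE2, 19)
  expect_equal(sc@nReps, 100L)
  writeLines("varFraction: 0.1\nbogus: 3", f)
  expect_error(readScenario(f), "unknown scenario keys")
})

test_that("gene drop with recombination stays Mendelian and reproducible", {
  ped <- simulatePedigree(nFounders = 20, nGenerations = 2,
                          siresPerGeneration = 3, offspringPerDam = 2,
                          seed = 19)
  map <- data.frame(snp = paste0("m", 1:30), chrom = "1",
                    bp = seq(1e5, 3e6, length.out = 30),
                    allele1 = "A", allele2 = "B")
  freqs <- rep(0.5, 30)
  g1 <- geneDropGenotypes(ped, freqs, map, seed = 20, linkage = TRUE,
                          subset = pedIds(ped))
  g2 <- geneDropGenotypes(ped, freqs, map, seed = 20, linkage = TRUE,
                          subset = pedIds(ped))
  expect_identical(genoCodes(g1), genoCodes(g2))
  codes <- genoCodes(g1)
  expect_true(all(codes %in% 0:2))
  sp <- match(pedSires(ped), pedIds(ped))
  dp <- match(pedDams(ped), pedIds(ped))
  for (i in which(!is.na(sp))) {
    lo <- (codes[sp[i], ] >= 2) + (codes[dp[i], ] >= 2)
    hi <- 2 - ((codes[sp[i], ] <= 0) + (codes[dp[i], ] <= 0))
    expect_true(all(codes[i, ] >= lo & codes[i, ] <= hi))
  }
})

test_that("fertility record generator matches its configured targets", {
  ped <- simulatePedigree(nFounders = 200, nGenerations = 2,
                          siresPerGeneration = 10, offspringPerDam = 3,
                          seed = 12)
  rec0 <- simulateFertilityRecords(ped, censorRate = 0, seed = 1)
  expect_false(any(rec0$censored))
  rec <- simulateFertilityRecords(ped, censorRate = 0.15, seed = 2)
  n <- nrow(rec)
  expect_lt(abs(mean(rec$censored) - 0.15), 3 * sqrt(0.15 * 0.85 / n))
  # heifer IFL near 30 days (emulation target)
  expect_equal(mean(rec$IFL), 30, tolerance = 6)
  recC <- simulateFertilityRecords(ped, stage = "cow", seed = 3)
  expect_equal(mean(recC$ICF), 50, tolerance = 6)
  expect_true(all(recC$parity %in% 1:3))
})
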