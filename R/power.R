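#' Default scenario grid for the dominance power study
#'
#' The grid crosses the per-QTN additive variance fractions (0.05 small,
#' 0.10 large) with the dominance ratios -1, -0.5, 0.5 and 1; with
#' `includeNullRatio = TRUE` the purely additive ratio `h = 0` is added to
#' each variance level, giving 10 scenarios.
#'
#' @param varFractions QTN additive variance fractions of the polygenic
#'   variance.
#' @param ratios dominance ratios `h = d/a`.
#' @param includeNullRatio add `h = 0` scenarios.
#' @param nReps replicates per scenario.
#' @param ... passed to [SimulationScenario()] (QTN positions, variances).
#' @return named list of [SimulationScenario-class] objects.
#' @export
defaultScenarioGrid <- function(varFractions = c(0.05, 0.10),
                                ratios = c(-1, -0.5, 0.5, 1),
                                includeNullRatio = FALSE, nReps = 100L, ...) {
  if (includeNullRatio) ratios <- c(ratios, 0)
  grid <- expand.grid(f = varFractions, h = ratios)
  out <- lapply(seq_len(nrow(grid)), function(i)
    SimulationScenario(varFraction = grid$f[i], dominanceRatio = grid$h[i],
                       nReps = nReps, ...))
  names(out) <- sprintf("f%.2f_h%+.1f", grid$f, grid$h)
  out
}

#' Assemble the default synthetic study population
#'
#' Builds the fixed ingredients shared by all power-study scenarios: a
#' half-sib-heavy pedigree with 3,040 terminal genotyped females, a
#' gene-dropped marker panel emulating a 50k-chip chromosome (about 1,200
#' markers over 43 Mb) carrying the three QTN at their target minor-allele
#' frequencies, the pedigree relationship matrix among the genotyped
#' females (computed through all ancestors), per-individual inbreeding
#' coefficients, and the association-scan cache.
#'
#' Allele frequencies drift down the pedigree, so each QTN target is planted
#' as a cluster of candidate markers ([defaultMarkerPanel()]); the candidate
#' whose realized minor-allele frequency in the genotyped females is closest
#' to the target becomes the QTN marker, and its position is recorded in the
#' returned `qtnBp` (used by [runReplicate()] in place of the nominal
#' positions).
#'
#' @param seed RNG seed for pedigree and gene drop.
#' @param scenario a [SimulationScenario-class] supplying QTN positions and
#'   frequencies (only these fields are used; default scenario settings).
#' @param nSnps approximate panel size.
#' @param pedArgs list of overrides for [simulatePedigree()].
#' @return list with `ped`, `g`, `A` (matrix over the genotyped subset),
#'   `F` (named, pedigree order), `cache` (see [buildScanCache()]),
#'   `qtnBp` (selected QTN positions) and `qtnMaf` (their realized
#'   minor-allele frequencies).
#' @export
setupPowerStudy <- function(seed = 1, scenario = SimulationScenario(0.05, -1),
                            nSnps = 1200, pedArgs = list()) {
  ped <- do.call(simulatePedigree,
                 c(list(seed = seed), pedArgs))
  panel <- defaultMarkerPanel(scenario, nSnps = nSnps,
                              chrom = scenario@qtnChrom, seed = seed)
  g <- geneDropGenotypes(ped, panel$freqs, panel$map, seed = seed + 1L)
  Afull <- .tabularA(ped)
  F <- setNames(diag(Afull) - 1, pedIds(ped))
  ids <- sampleIds(g)
  A <- Afull[ids, ids]
  rm(Afull)
  # designate one candidate marker per QTN target: realized MAF closest to
  # the target frequency
  map <- markerMap(g)
  maf <- pmin(alleleFreqs(g), 1 - alleleFreqs(g))
  nq <- length(scenario@qtnPositions)
  qtnBp <- numeric(nq)
  qtnMaf <- numeric(nq)
  for (k in seq_len(nq)) {
    cand <- which(map$qtnTarget %in% k)
    best <- cand[which.min(abs(maf[cand] - scenario@qtnMafs[k]))]
    qtnBp[k] <- map$bp[best]
    qtnMaf[k] <- maf[best]
  }
  cache <- buildScanCache(A, g)
  list(ped = ped, g = g, A = A, F = F, cache = cache,
       qtnBp = qtnBp, qtnMaf = qtnMaf)
}

#' Run one power-study replicate
#'
#' Simulates a phenotype for the genotyped females under the scenario
#' (polygenic gene flow, QTN genotypic values, residual noise), runs the
#' mixed-model association scan over the panel, and records for each QTN
#' whether it was detected. Two detection rules are available:
#'
#' * `"qtn-dominance"` (default): the QTN marker's dominance t-test is
#'   significant (`p_d < pdAlpha`). When the reported power values of the design
#'   this emulates are back-calculated from the stated sample size, allele
#'   frequencies and variances, they agree with this ungated rule; the
#'   genome-scan FDR screen, applied per replicate over a single-chromosome
#'   panel, analytically cannot reach them (see the methods vignette).
#' * `"two-step"`: at least one marker within `windowBp` of the QTN passes
#'   step 1 (q-value at or below `fdrLevel`) and has a significant dominance
#'   effect — the two-step procedure exactly as used for real-data scans.
#'   `windowBp = 0` restricts detection to the QTN marker itself.
#'
#' Under either rule the detected position (for precision) is the most
#' significant qualifying marker within the window.
#'
#' @param scenario a [SimulationScenario-class].
#' @param setup study population from [setupPowerStudy()] (or a compatible
#'   list with `ped`, `g`, `F`, `cache`).
#' @param repSeed RNG seed for this replicate.
#' @param windowBp QTN-matching window in bp (default 5 Mb, giving disjoint
#'   windows for QTN spaced about 10 Mb apart).
#' @param fdrLevel step-1 FDR threshold (default 0.10).
#' @param pdAlpha dominance-test significance level (default 0.01).
#' @param fdrMethod passed to [runScan()].
#' @param detection detection rule, see above.
#' @return `data.frame` with one row per QTN: `qtnBp`, `detected`, `topBp`,
#'   `topP`, `distMb`.
#' @export
runReplicate <- function(scenario, setup, repSeed, windowBp = 5e6,
                         fdrLevel = 0.10, pdAlpha = 0.01,
                         fdrMethod = "storey",
                         detection = c("qtn-dominance", "two-step")) {
  detection <- match.arg(detection)
  if (!is.null(setup$qtnBp)) scenario@qtnPositions <- setup$qtnBp
  sim <- simulateQtnPhenotypes(setup$g, setup$ped, scenario, seed = repSeed,
                               F = setup$F)
  yc <- setNames(sim$y, sim$id)
  map <- markerMap(setup$g)
  qpos <- scenario@qtnPositions
  qtnSnps <- map$snp[match(paste(scenario@qtnChrom, qpos),
                           paste(map$chrom, map$bp))]
  res <- runScan(yc, cache = setup$cache, fdrLevel = fdrLevel,
                 fdrMethod = fdrMethod, step2Extra = qtnSnps)
  out <- data.frame(qtnBp = qpos, detected = FALSE, topBp = NA_real_,
                    topP = NA_real_, distMb = NA_real_)
  onChr <- res$chrom == scenario@qtnChrom
  for (k in seq_along(qpos)) {
    if (detection == "qtn-dominance") {
      qrow <- which(onChr & res$bp == qpos[k])
      det <- length(qrow) == 1L && !is.na(res$pD[qrow]) &&
        res$pD[qrow] < pdAlpha
      if (det) {
        inWin <- which(onChr & abs(res$bp - qpos[k]) <= windowBp)
        top <- inWin[which.min(res$p[inWin])]
        out$detected[k] <- TRUE
        out$topBp[k] <- res$bp[top]
        out$topP[k] <- res$p[top]
        out$distMb[k] <- abs(res$bp[top] - qpos[k]) / 1e6
      }
    } else {
      hits <- onChr & res$sig & !is.na(res$pD) & res$pD < pdAlpha
      inWin <- hits & abs(res$bp - qpos[k]) <= windowBp
      if (any(inWin)) {
        top <- which(inWin)[which.min(res$p[inWin])]
        out$detected[k] <- TRUE
        out$topBp[k] <- res$bp[top]
        out$topP[k] <- res$p[top]
        out$distMb[k] <- abs(res$bp[top] - qpos[k]) / 1e6
      }
    }
  }
  out
}

#' Run a scenario grid and summarize power and precision
#'
#' Runs `nReps` replicates of every scenario against a fixed study
#' population (pedigree, genotypes and scan cache are shared, as when
#' simulation re-uses a real genotype panel) and reports, per scenario, the
#' power — detected QTN over total simulated QTN (3 x nReps) — and the
#' precision — mean absolute distance in Mb between the top significant
#' marker and the QTN over detected QTN.
#'
#' @param scenarios list of [SimulationScenario-class] objects (e.g. from
#'   [defaultScenarioGrid()]).
#' @param setup study population from [setupPowerStudy()].
#' @param seed master seed; per-replicate seeds are drawn from it
#'   reproducibly.
#' @param nReps replicate count override (default: each scenario's `nReps`).
#' @param ... passed to [runReplicate()] (window, thresholds).
#' @param verbose print a progress line per scenario.
#' @return `data.frame` with one row per scenario: `scenario`, `f`, `h`,
#'   `nReps`, `nDetected`, `power`, `precisionMb`; the per-replicate QTN
#'   records are attached as attribute `"detail"`.
#' @export
runScenarioGrid <- function(scenarios, setup, seed = 1, nReps = NULL, ...,
                            verbose = FALSE) {
  if (is.null(names(scenarios)))
    names(scenarios) <- paste0("scenario", seq_along(scenarios))
  set.seed(seed)
  maxReps <- max(vapply(scenarios, function(s) s@nReps, integer(1)),
                 if (is.null(nReps)) 0L else nReps)
  seedMat <- matrix(sample.int(.Machine$integer.max - 1L,
                               length(scenarios) * maxReps),
                    nrow = maxReps)
  rows <- list()
  details <- list()
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    reps <- if (is.null(nReps)) sc@nReps else nReps
    det <- vector("list", reps)
    for (r in seq_len(reps)) {
      det[[r]] <- cbind(scenario = names(scenarios)[i], rep = r,
                        runReplicate(sc, setup, repSeed = seedMat[r, i], ...))
    }
    det <- do.call(rbind, det)
    nDet <- sum(det$detected)
    nTot <- length(sc@qtnPositions) * reps
    rows[[i]] <- data.frame(scenario = names(scenarios)[i],
                            f = sc@varFraction, h = sc@dominanceRatio,
                            nReps = reps, nDetected = nDet,
                            power = nDet / nTot,
                            precisionMb = if (nDet > 0)
                              mean(det$distMb[det$detected]) else NA_real_,
                            stringsAsFactors = FALSE)
    details[[i]] <- det
    if (verbose)
      message(sprintf("%s: power %.3f (%d/%d)", names(scenarios)[i],
                      nDet / nTot, nDet, nTot))
  }
  out <- do.call(rbind, rows)
  attr(out, "detail") <- do.call(rbind, details)
  out
}
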