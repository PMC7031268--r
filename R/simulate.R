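#' Construct a simulation scenario
#'
#' Study conditions for a dominance-QTL power study: three (by default) QTN
#' on one chromosome at high/medium/low minor-allele frequency, each with
#' additive variance equal to a fraction `varFraction` of the polygenic
#' variance, dominance ratio `h = d/a`, polygenic variance 1 and residual
#' variance 19 (a heritability of about 0.05, typical of fertility traits).
#'
#' @param varFraction per-QTN additive variance as a fraction of `sigmaU2`
#'   (0.05 = small, 0.10 = large QTL variance).
#' @param dominanceRatio dominance ratio `h = d/a`.
#' @param qtnPositions bp positions of the QTN markers.
#' @param qtnMafs target minor-allele frequencies, same length.
#' @param qtnChrom chromosome label carrying the QTN.
#' @param sigmaU2 polygenic variance.
#' @param sigmaE2 residual variance.
#' @param nReps number of replicates when used in a power study.
#' @return a [SimulationScenario-class] object.
#' @export
SimulationScenario <- function(varFraction, dominanceRatio,
                               qtnPositions = c(10109903, 20058762, 30039582),
                               qtnMafs = c(0.43, 0.19, 0.09),
                               qtnChrom = "25",
                               sigmaU2 = 1, sigmaE2 = 19, nReps = 100L) {
  new("SimulationScenario", qtnChrom = as.character(qtnChrom),
      qtnPositions = as.numeric(qtnPositions), qtnMafs = as.numeric(qtnMafs),
      varFraction = as.numeric(varFraction),
      dominanceRatio = as.numeric(dominanceRatio),
      sigmaU2 = as.numeric(sigmaU2), sigmaE2 = as.numeric(sigmaE2),
      nReps = as.integer(nReps))
}

#' Read a simulation scenario from a key:value file
#'
#' Plain-text scenario configuration: one `key: value` pair per line
#' (`#` comments allowed), with comma-separated lists for the vector fields.
#' Recognized keys mirror the [SimulationScenario()] arguments:
#' `varFraction`, `dominanceRatio`, `qtnPositions`, `qtnMafs`, `qtnChrom`,
#' `sigmaU2`, `sigmaE2`, `nReps`.
#'
#' @param path configuration file path.
#' @return a [SimulationScenario-class] object.
#' @export
readScenario <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl(":", lines)])
  kv <- regmatches(lines, regexpr(":", lines), invert = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  known <- c("varFraction", "dominanceRatio", "qtnPositions", "qtnMafs",
             "qtnChrom", "sigmaU2", "sigmaE2", "nReps")
  bad <- setdiff(keys, known)
  if (length(bad)) stop("unknown scenario keys: ", paste(bad, collapse = ", "))
  args <- list()
  for (i in seq_along(keys)) {
    v <- strsplit(vals[i], ",")[[1]]
    args[[keys[i]]] <- if (keys[i] == "qtnChrom") trimws(v) else
      as.numeric(trimws(v))
  }
  if (!all(c("varFraction", "dominanceRatio") %in% names(args)))
    stop("scenario file must set varFraction and dominanceRatio")
  do.call(SimulationScenario, args)
}

#' Simulate a half-sib-heavy livestock pedigree
#'
#' Generates a dairy-cattle-like multi-generation pedigree: few sires and
#' many dams per generation, so paternal half-sib families are large. The
#' founder generation holds `siresPerGeneration` males and the remaining
#' founders as females; in each later generation every female of the previous
#' generation is mated to one randomly chosen male of the previous generation
#' and produces `offspringPerDam` offspring, of which `siresPerGeneration`
#' are male. Females of the terminal generation are marked as the genotyped
#' subset.
#'
#' @param nFounders number of founders (must exceed `siresPerGeneration`).
#' @param nGenerations number of descendant generations (0 = founders only).
#' @param siresPerGeneration number of breeding males per generation.
#' @param offspringPerDam offspring per mated female.
#' @param seed RNG seed.
#' @return a [Pedigree-class] with `sex` and `generation` metadata.
#' @export
simulatePedigree <- function(nFounders = 415, nGenerations = 3,
                             siresPerGeneration = 20, offspringPerDam = 2,
                             seed = 1) {
  if (nFounders < 2) stop("need at least 2 founders")
  if (nGenerations > 0 && nFounders <= siresPerGeneration)
    stop("impossible mating design: no founder dams available")
  set.seed(seed)
  id <- sprintf("G0_%04d", seq_len(nFounders))
  sex <- c(rep("M", min(siresPerGeneration, nFounders)),
           rep("F", max(0, nFounders - siresPerGeneration)))
  gen <- rep(0L, nFounders)
  sire <- rep(NA_character_, nFounders)
  dam <- rep(NA_character_, nFounders)
  prevMales <- id[sex == "M"]
  prevFemales <- id[sex == "F"]
  for (g in seq_len(nGenerations)) {
    if (!length(prevMales) || !length(prevFemales))
      stop("impossible mating design: no candidates in generation ", g)
    nOff <- length(prevFemales) * offspringPerDam
    offDam <- rep(prevFemales, each = offspringPerDam)
    mateSire <- sample(prevMales, length(prevFemales), replace = TRUE)
    offSire <- rep(mateSire, each = offspringPerDam)
    offId <- sprintf("G%d_%04d", g, seq_len(nOff))
    offSex <- rep("F", nOff)
    # no males needed in the terminal generation (all females are phenotyped)
    if (g < nGenerations && nOff > siresPerGeneration)
      offSex[sample.int(nOff, siresPerGeneration)] <- "M"
    id <- c(id, offId); sire <- c(sire, offSire); dam <- c(dam, offDam)
    sex <- c(sex, offSex); gen <- c(gen, rep(g, nOff))
    prevMales <- offId[offSex == "M"]
    prevFemales <- offId[offSex == "F"]
  }
  genotyped <- id[gen == nGenerations & sex == "F"]
  Pedigree(id, sire, dam,
           info = data.frame(sex = sex, generation = gen,
                             stringsAsFactors = FALSE),
           genotyped = genotyped)
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder alleles are drawn independently at the supplied frequencies; each
#' offspring receives one gamete from each parent. By default loci segregate
#' independently (no linkage); with `linkage = TRUE` gametes follow a Haldane
#' crossover process along each chromosome using `cM` distances from the map
#' (1 cM per Mb when the map has no `cM` column). An individual with an
#' unknown parent receives a population gamete drawn at the founder
#' frequencies from that side.
#'
#' @param ped a [Pedigree-class] object.
#' @param founderFreqs per-marker alternate-allele frequencies in (0, 1];
#'   frequency 1 yields a fixed locus.
#' @param map marker map `data.frame` (columns `snp`, `chrom`, `bp`, and
#'   optionally `cM`, `allele1`, `allele2`).
#' @param seed RNG seed.
#' @param subset ids to return genotypes for (default: the pedigree's
#'   genotyped subset, or everyone when none is set).
#' @param linkage logical; simulate recombination along chromosomes.
#' @return a [GenotypeData-class] object.
#' @export
geneDropGenotypes <- function(ped, founderFreqs, map, seed = 1,
                              subset = NULL, linkage = FALSE) {
  if (any(founderFreqs <= 0 | founderFreqs > 1))
    stop("founder frequencies must lie in (0, 1]")
  m <- length(founderFreqs)
  if (nrow(map) != m) stop("map and founderFreqs lengths differ")
  set.seed(seed)
  n <- length(ped@id)
  sp <- match(ped@sire, ped@id)
  dp <- match(ped@dam, ped@id)
  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)

  if (linkage) {
    cm <- if ("cM" %in% names(map)) map$cM else map$bp / 1e6
    newChrom <- c(TRUE, map$chrom[-1] != map$chrom[-m])
    dcm <- c(0, pmax(0, diff(cm)))
    dcm[newChrom] <- 0
    rfrac <- 0.5 * (1 - exp(-2 * dcm / 100))  # Haldane map function
    rfrac[newChrom] <- 0.5                    # independent chromosomes
    gamete <- function(h1, h2) {
      sw <- runif(m) < rfrac
      phase <- (cumsum(sw) + (runif(1) < 0.5)) %% 2L
      ifelse(phase == 0L, h1, h2)
    }
  } else {
    gamete <- function(h1, h2) {
      pick <- runif(m) < 0.5
      ifelse(pick, h1, h2)
    }
  }
  popGamete <- function() as.integer(runif(m) < founderFreqs)

  for (i in seq_len(n)) {
    s <- sp[i]; d <- dp[i]
    H1[i, ] <- if (is.na(s)) popGamete() else gamete(H1[s, ], H2[s, ])
    H2[i, ] <- if (is.na(d)) popGamete() else gamete(H1[d, ], H2[d, ])
  }
  codes <- H1 + H2
  rownames(codes) <- ped@id
  if (is.null(subset)) {
    subset <- if (length(ped@genotyped)) ped@genotyped else ped@id
  }
  GenotypeData(codes[subset, , drop = FALSE], map, ids = subset)
}

#' Simulate polygenic values down a pedigree
#'
#' Breeding values are sampled from the oldest to the youngest individual.
#' Founders are drawn from `N(0, sigmaU2)`; an individual with one known
#' parent from `N(a_p / 2, (3/4 - F_p/4) sigmaU2)`; an individual with both
#' parents known from
#' `N((a_s + a_d)/2, (1/4 (1 - F_s) + 1/4 (1 - F_d)) sigmaU2)`, where `F` is
#' the parent's inbreeding coefficient, so Mendelian-sampling variance
#' shrinks with parental inbreeding.
#'
#' @param ped a [Pedigree-class] object (topologically sorted by
#'   construction).
#' @param sigmaU2 polygenic variance.
#' @param seed RNG seed.
#' @param F optional precomputed inbreeding coefficients in pedigree order
#'   (computed via [inbreedingCoefficients()] when missing).
#' @return `data.frame` with columns `id`, `a` (polygenic value) and `F`.
#' @export
simulatePolygenic <- function(ped, sigmaU2 = 1, seed = 1, F = NULL) {
  n <- length(ped@id)
  if (is.null(F)) F <- inbreedingCoefficients(ped)
  if (length(F) != n) stop("F must have one entry per pedigree member")
  set.seed(seed)
  sp <- match(ped@sire, ped@id)
  dp <- match(ped@dam, ped@id)
  a <- numeric(n)
  # process in waves: all individuals whose parents are done are sampled
  # together with vectorized draws (pedigree order guarantees progress)
  done <- logical(n)
  remaining <- seq_len(n)
  while (length(remaining)) {
    ready <- remaining[(is.na(sp[remaining]) | done[sp[remaining]]) &
                       (is.na(dp[remaining]) | done[dp[remaining]])]
    s <- sp[ready]; d <- dp[ready]
    mu <- numeric(length(ready))
    v <- numeric(length(ready))
    both <- !is.na(s) & !is.na(d)
    one <- xor(is.na(s), is.na(d))
    none <- is.na(s) & is.na(d)
    mu[none] <- 0; v[none] <- sigmaU2
    if (any(one)) {
      par1 <- ifelse(is.na(s[one]), d[one], s[one])
      mu[one] <- a[par1] / 2
      v[one] <- (3 / 4 - F[par1] / 4) * sigmaU2
    }
    if (any(both)) {
      mu[both] <- (a[s[both]] + a[d[both]]) / 2
      v[both] <- (0.25 * (1 - F[s[both]]) + 0.25 * (1 - F[d[both]])) * sigmaU2
    }
    a[ready] <- rnorm(length(ready), mu, sqrt(pmax(v, 0)))
    done[ready] <- TRUE
    remaining <- setdiff(remaining, ready)
  }
  data.frame(id = ped@id, a = a, F = F, stringsAsFactors = FALSE)
}

#' QTN additive and dominance effects from target variance
#'
#' Solves `2 p (1 - p) a^2 = f * sigmaU2` for the additive effect `a`
#' (positive by convention) and sets the dominance effect `d = h * a`.
#'
#' @param p allele frequency in (0, 1).
#' @param f QTN additive variance as a fraction of the polygenic variance.
#' @param h dominance ratio `d / a`.
#' @param sigmaU2 polygenic variance.
#' @return list with elements `a` and `d`.
#' @export
qtnEffects <- function(p, f, h, sigmaU2 = 1) {
  if (any(p <= 0 | p >= 1)) stop("allele frequency must lie strictly in (0, 1)")
  if (any(f <= 0)) stop("variance fraction must be positive")
  a <- sqrt(f * sigmaU2 / (2 * p * (1 - p)))
  list(a = a, d = h * a)
}

#' Simulate phenotypes with polygenic, QTN and residual components
#'
#' For each genotyped individual, `y = a_poly + sum_q v_q + e`, where the QTN
#' genotypic value `v_q` is `-a` for the reference homozygote, `d` for the
#' heterozygote and `+a` for the alternate homozygote, and
#' `e ~ N(0, sigmaE2)`. QTN effects are derived with [qtnEffects()] from the
#' observed allele frequency of each QTN marker in the genotyped sample.
#'
#' @param g a [GenotypeData-class] holding the genotyped individuals.
#' @param ped the [Pedigree-class] the individuals belong to.
#' @param scenario a [SimulationScenario-class].
#' @param seed RNG seed.
#' @param F optional precomputed inbreeding coefficients in pedigree order.
#' @return `data.frame` with `id`, `y`, `polygenic`, `qtn` (summed genotypic
#'   value), `e`; QTN effect sizes attached as attribute `"qtn"`.
#' @export
simulateQtnPhenotypes <- function(g, ped, scenario, seed = 1, F = NULL) {
  map <- markerMap(g)
  qpos <- scenario@qtnPositions
  qidx <- if (length(qpos))
    match(paste(scenario@qtnChrom, qpos), paste(map$chrom, map$bp))
  else integer(0)
  if (anyNA(qidx))
    stop("QTN positions not present in the genotype map")
  poly <- simulatePolygenic(ped, scenario@sigmaU2, seed = seed, F = F)
  ids <- sampleIds(g)
  aPoly <- poly$a[match(ids, poly$id)]
  set.seed(seed + 1L)
  qval <- numeric(length(ids))
  qtab <- data.frame(snp = character(), p = numeric(), a = numeric(),
                     d = numeric())
  if (length(qidx)) {
    codes <- genoCodes(g)[, qidx, drop = FALSE]
    p <- colMeans(codes, na.rm = TRUE) / 2
    for (k in seq_along(qidx)) {
      if (scenario@varFraction == 0) {
        qtab <- rbind(qtab, data.frame(snp = map$snp[qidx[k]], p = p[k],
                                       a = 0, d = 0))
        next
      }
      if (p[k] <= 0 || p[k] >= 1) {
        warning("QTN ", map$snp[qidx[k]],
                " is monomorphic in the sample; no segregating effect")
        qtab <- rbind(qtab, data.frame(snp = map$snp[qidx[k]], p = p[k],
                                       a = 0, d = 0))
        next
      }
      eff <- qtnEffects(p[k], scenario@varFraction, scenario@dominanceRatio,
                        scenario@sigmaU2)
      v <- c(-eff$a, eff$d, eff$a)[codes[, k] + 1L]
      v[is.na(v)] <- 0
      qval <- qval + v
      qtab <- rbind(qtab, data.frame(snp = map$snp[qidx[k]], p = p[k],
                                     a = eff$a, d = eff$d))
    }
  }
  e <- rnorm(length(ids), 0, sqrt(scenario@sigmaE2))
  out <- data.frame(id = ids, y = aPoly + qval + e, polygenic = aPoly,
                    qtn = qval, e = e, stringsAsFactors = FALSE)
  attr(out, "qtn") <- qtab
  out
}

#' Simulate raw fertility records
#'
#' Emulates insemination/calving record tables for heifers and cows: herd and
#' year-month contemporary groups, age covariates, the interval from first to
#' last insemination (IFL), the number of inseminations (NINS), the interval
#' from calving to first insemination (ICF, cows), and a right-censoring flag
#' for females without a confirmed successful insemination (default rate
#' 0.15). Trait values carry herd, year-month and age fixed effects plus a
#' sire genetic component (half the sire's simulated breeding value) so that
#' the full pre-correction pipeline can be exercised on the output. Defaults
#' target a heifer IFL mean near 30 days and a cow ICF mean near 50 days.
#'
#' @param ped a [Pedigree-class]; terminal females (the genotyped subset when
#'   set) become record holders.
#' @param nHerds number of herds.
#' @param traitParams list of generator settings; see Details. Any entry may
#'   be overridden.
#' @param stage `"heifer"` or `"cow"`.
#' @param censorRate fraction of females whose last insemination is
#'   unsuccessful (censored records).
#' @param seed RNG seed.
#'
#' @details `traitParams` entries (days unless noted): `iflMu` latent IFL
#'   mean (heifers 24, cows 70), `iflSd` residual SD (45), `icfMu` latent ICF
#'   mean (50), `icfSd` (15), `herdSd` herd-effect SD (6), `ymSd` year-month
#'   SD (4), `ageBeta` slope of IFL on age (0.02), `nYm` number of year-month
#'   classes (24), `sireVar` sire-effect variance on the IFL scale (9),
#'   `nParities` maximum cow parity (3).
#' @return `data.frame` of records with columns `id`, `stage`, `parity`,
#'   `herd`, `ym`, `ageIns`, `ageCalv`, `IFL`, `NINS`, `ICF`, `censored`.
#' @export
simulateFertilityRecords <- function(ped, nHerds = 20,
                                     traitParams = list(),
                                     stage = c("heifer", "cow"),
                                     censorRate = 0.15, seed = 1) {
  stage <- match.arg(stage)
  # latent IFL means are set so the realized mean after zero-truncation lands
  # near the field-typical 30 d (heifers) / 78 d (cows)
  tp <- list(iflMu = if (stage == "heifer") 19 else 74, iflSd = 45,
             icfMu = 50, icfSd = 15, herdSd = 6, ymSd = 4, ageBeta = 0.02,
             nYm = 24, sireVar = 9, nParities = 3)
  tp[names(traitParams)] <- traitParams
  if (tp$iflSd <= 0 || tp$icfSd <= 0) stop("trait SDs must be positive")
  set.seed(seed)
  females <- if (length(ped@genotyped)) ped@genotyped else ped@id
  nf <- length(females)
  sires <- ped@sire[match(females, ped@id)]
  sireIds <- unique(stats::na.omit(sires))
  sireEff <- setNames(rnorm(length(sireIds), 0, sqrt(tp$sireVar)), sireIds)
  sEff <- ifelse(is.na(sires), 0, sireEff[sires])
  herdEff <- rnorm(nHerds, 0, tp$herdSd)
  ymEff <- rnorm(tp$nYm, 0, tp$ymSd)

  nPar <- if (stage == "heifer") rep(1L, nf) else
    sample.int(tp$nParities, nf, replace = TRUE)
  idx <- rep(seq_len(nf), nPar)
  parity <- unlist(lapply(nPar, seq_len))
  herd <- sample.int(nHerds, nf, replace = TRUE)[idx]
  ym <- sample.int(tp$nYm, length(idx), replace = TRUE)
  ageIns <- if (stage == "heifer")
    round(rnorm(length(idx), 440, 70)) else rep(NA_real_, length(idx))
  ageCalv <- if (stage == "cow")
    round(rnorm(length(idx), 780, 80) + (parity - 1) * 390) else
    rep(NA_real_, length(idx))
  age <- if (stage == "heifer") ageIns else ageCalv
  eta <- tp$iflMu + herdEff[herd] + ymEff[ym] +
    tp$ageBeta * (age - mean(age)) + sEff[idx] +
    rnorm(length(idx), 0, tp$iflSd)
  IFL <- pmax(0, round(eta))
  NINS <- pmin(1L + rpois(length(idx), IFL / 40), 12L)
  ICF <- if (stage == "cow")
    pmax(20, round(tp$icfMu + 0.5 * herdEff[herd] + 0.5 * sEff[idx] +
                   rnorm(length(idx), 0, tp$icfSd)))
  else rep(NA_real_, length(idx))
  censored <- runif(length(idx)) < censorRate
  data.frame(id = females[idx], stage = stage, parity = parity, herd = herd,
             ym = ym, ageIns = ageIns, ageCalv = ageCalv, IFL = IFL,
             NINS = NINS, ICF = ICF, censored = censored,
             stringsAsFactors = FALSE)
}

#' Default marker panel emulating a 50k-chip chromosome
#'
#' An evenly spaced panel of about `nSnps` markers over `lengthMb` megabases
#' on one chromosome (BovineSNP50 density on a mid-sized autosome), with the
#' scenario's QTN positions inserted as panel markers. Founder frequencies
#' for non-QTN markers are drawn uniformly on `[0.05, 0.5]` (a post-QC
#' spectrum); QTN markers get their target minor-allele frequencies.
#'
#' Because allele frequencies drift while genotypes descend the pedigree,
#' each QTN target is represented by `qtnCandidates` markers planted at and
#' around the nominal position, all with the target founder frequency; after
#' the gene drop the candidate whose realized minor-allele frequency is
#' closest to the target is designated the QTN (mirroring a study that picks
#' QTN among genotyped markers to represent high/medium/low MAF). The
#' selection is done by [setupPowerStudy()].
#'
#' @param scenario a [SimulationScenario-class] supplying QTN positions and
#'   frequencies (optional; `NULL` gives a QTN-free panel).
#' @param nSnps approximate panel size.
#' @param lengthMb chromosome length in Mb.
#' @param chrom chromosome label.
#' @param seed RNG seed for the background frequencies.
#' @param qtnCandidates candidate markers per QTN target (odd; 1 plants the
#'   QTN at the nominal position only).
#' @param candidateSpacingBp spacing between candidate markers.
#' @return list with `map` (marker map `data.frame`, with a `qtnTarget`
#'   column indexing candidate markers) and `freqs` (founder
#'   alternate-allele frequencies; the minor-allele targets at candidates).
#' @export
defaultMarkerPanel <- function(scenario = NULL, nSnps = 1200, lengthMb = 43,
                               chrom = "25", seed = 1, qtnCandidates = 15,
                               candidateSpacingBp = 2e4) {
  set.seed(seed)
  bp <- round(seq(50000, lengthMb * 1e6, length.out = nSnps))
  qtnTarget <- rep(NA_integer_, length(bp))
  freqs <- runif(length(bp), 0.05, 0.5)
  if (!is.null(scenario)) {
    off <- (seq_len(qtnCandidates) - (qtnCandidates + 1) / 2) *
      candidateSpacingBp
    for (k in seq_along(scenario@qtnPositions)) {
      cand <- round(scenario@qtnPositions[k] + off)
      bp <- c(bp, cand)
      freqs <- c(freqs, rep(scenario@qtnMafs[k], length(cand)))
      qtnTarget <- c(qtnTarget, rep(k, length(cand)))
    }
    o <- order(bp)
    dup <- duplicated(bp[o])
    o <- o[!dup]
    bp <- bp[o]; freqs <- freqs[o]; qtnTarget <- qtnTarget[o]
  }
  m <- length(bp)
  map <- data.frame(snp = sprintf("snp%s_%08d", chrom, bp),
                    chrom = chrom, bp = bp, allele1 = "A", allele2 = "B",
                    qtnTarget = qtnTarget, stringsAsFactors = FALSE)
  list(map = map, freqs = freqs)
}
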