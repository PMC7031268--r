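#' Hardy-Weinberg chi-square test from genotype counts
#'
#' Pearson chi-square (1 df) of observed genotype counts against
#' Hardy-Weinberg expectations at the sample allele frequency. Monomorphic
#' markers return `chi2 = 0`, `p = 1`. All arguments are vectorized.
#'
#' @param nAA,nAa,naa genotype class counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return `data.frame` with columns `chi2` and `p`.
#' @export
hweChi2 <- function(nAA, nAa, naa) {
  if (any(c(nAA, nAa, naa) < 0)) stop("genotype counts must be non-negative")
  n <- nAA + nAa + naa
  if (any(n < 1)) stop("at least one genotype call is required")
  p <- (2 * nAA + nAa) / (2 * n)
  q <- 1 - p
  eAA <- n * p^2
  eAa <- n * 2 * p * q
  eaa <- n * q^2
  term <- function(o, e) ifelse(e > 0, (o - e)^2 / e, 0)
  chi2 <- term(nAA, eAA) + term(nAa, eAa) + term(naa, eaa)
  mono <- p == 0 | p == 1
  chi2[mono] <- 0
  pval <- pchisq(chi2, df = 1, lower.tail = FALSE)
  pval[mono] <- 1
  data.frame(chi2 = chi2, p = pval)
}

# Per-marker summary stats on non-missing calls.
.markerStats <- function(codes) {
  nCall <- colSums(!is.na(codes))
  n0 <- colSums(codes == 0L, na.rm = TRUE)
  n1 <- colSums(codes == 1L, na.rm = TRUE)
  n2 <- colSums(codes == 2L, na.rm = TRUE)
  p2 <- ifelse(nCall > 0, (2 * n2 + n1) / (2 * nCall), NA_real_)
  maf <- pmin(p2, 1 - p2)
  callrate <- nCall / nrow(codes)
  ok <- nCall > 0
  chi2 <- rep(0, ncol(codes)); hp <- rep(1, ncol(codes))
  if (any(ok)) {
    hw <- hweChi2(n0[ok], n1[ok], n2[ok])
    chi2[ok] <- hw$chi2; hp[ok] <- hw$p
  }
  data.frame(n0 = n0, n1 = n1, n2 = n2, nCall = nCall, pAlt = p2,
             maf = maf, callrate = callrate, hweChi2 = chi2, hweP = hp)
}

#' Marker quality control
#'
#' Removes markers with minor allele frequency, call rate or Hardy-Weinberg
#' test p-value below the thresholds (strict inequalities: a marker with
#' MAF exactly `mafMin` is retained). Each removed marker is counted under
#' the first criterion it fails, in the order MAF, call rate, HWE. MAF and
#' the HWE test use non-missing calls only. X-chromosome markers are
#' retained (and can be excluded later when building genomic relationship
#' matrices); markers with no calls at all are removed under call rate.
#'
#' @param g a [GenotypeData-class] object.
#' @param mafMin minimum minor allele frequency (default 0.05).
#' @param callrateMin minimum call rate (default 0.90).
#' @param hweAlpha HWE test significance threshold (default 1e-5).
#' @return list with elements `genotypes` (filtered [GenotypeData-class]) and
#'   `report` (a [QCReport-class]).
#' @export
qcFilter <- function(g, mafMin = 0.05, callrateMin = 0.90, hweAlpha = 1e-5) {
  codes <- genoCodes(g)
  if (ncol(codes) == 0L) stop("no markers to filter")
  st <- .markerStats(codes)
  failMaf <- !is.na(st$maf) & st$maf < mafMin
  failCall <- st$callrate < callrateMin
  failHwe <- st$hweP < hweAlpha
  reason <- rep(NA_character_, ncol(codes))
  reason[failHwe] <- "hwe"
  reason[failCall] <- "callrate"
  reason[failMaf] <- "maf"
  reason[st$nCall == 0L] <- "callrate"
  removed <- !is.na(reason)
  stats <- data.frame(snp = markerMap(g)$snp, maf = st$maf,
                      callrate = st$callrate, hweChi2 = st$hweChi2,
                      hweP = st$hweP, removed = removed, reason = reason,
                      stringsAsFactors = FALSE)
  report <- new("QCReport",
                nInput = ncol(codes),
                nRemovedMaf = sum(reason == "maf", na.rm = TRUE),
                nRemovedCallrate = sum(reason == "callrate", na.rm = TRUE),
                nRemovedHwe = sum(reason == "hwe", na.rm = TRUE),
                nRetained = sum(!removed),
                stats = stats)
  keep <- which(!removed)
  gOut <- GenotypeData(codes[, keep, drop = FALSE],
                       markerMap(g)[keep, , drop = FALSE],
                       ids = sampleIds(g))
  list(genotypes = gOut, report = report)
}

#' Observed alternate-allele frequencies
#'
#' @param g a [GenotypeData-class] object.
#' @return numeric vector of alternate-allele (allele2) frequencies computed
#'   on non-missing calls.
#' @export
alleleFreqs <- function(g) {
  codes <- genoCodes(g)
  colMeans(codes, na.rm = TRUE) / 2
}
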