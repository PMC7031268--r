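#' @import methods
#' @importFrom stats rnorm runif rbinom rpois var sd pchisq pt pnorm qnorm
#'   optimize smooth.spline predict p.adjust complete.cases setNames aggregate
#' @importFrom utils read.table write.table head
NULL

#' Genotype matrix with marker map
#'
#' Container for SNP-chip style genotypes: an individuals-by-markers integer
#' matrix counting copies of the second (alternate) allele, together with a
#' per-marker map. Missing calls are stored as `NA`.
#'
#' @slot codes integer matrix, individuals in rows, markers in columns, values
#'   in `{0, 1, 2, NA}`; rownames are individual ids, colnames marker ids.
#' @slot map `data.frame` with one row per marker and columns `snp`, `chrom`
#'   (character), `bp` (1-based position), `allele1`, `allele2`. Codes count
#'   copies of `allele2`.
#'
#' @seealso [readPlinkText()], [qcFilter()], [genomicG()], [genomicD()]
#' @export
setClass("GenotypeData",
         representation(codes = "matrix", map = "data.frame"))

setValidity("GenotypeData", function(object) {
  msg <- character()
  v <- object@codes[!is.na(object@codes)]
  if (length(v) && !all(v %in% c(0L, 1L, 2L)))
    msg <- c(msg, "non-missing genotype codes must be 0, 1 or 2")
  if (nrow(object@map) != ncol(object@codes))
    msg <- c(msg, "map must have one row per genotype column")
  need <- c("snp", "chrom", "bp", "allele1", "allele2")
  if (!all(need %in% names(object@map)))
    msg <- c(msg, paste("map must contain columns:", paste(need, collapse = ", ")))
  else if (any(object@map$bp <= 0))
    msg <- c(msg, "map positions must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' Pedigree
#'
#' Topologically ordered pedigree: every parent precedes its offspring.
#' Unknown parents are `NA`. Individuals referenced only as parents are
#' promoted to founders by the constructor.
#'
#' @slot id character vector of individual ids in topological order.
#' @slot sire,dam character vectors of parent ids (`NA` when unknown).
#' @slot info `data.frame` of optional per-individual metadata (e.g. `sex`,
#'   `generation`), row-aligned with `id`.
#' @slot genotyped character vector of ids designating the genotyped subset
#'   (may be empty).
#'
#' @seealso [Pedigree()], [readPedigree()], [simulatePedigree()],
#'   [inbreedingCoefficients()], [pedigreeA()]
#' @export
setClass("Pedigree",
         representation(id = "character", sire = "character", dam = "character",
                        info = "data.frame", genotyped = "character"))

setValidity("Pedigree", function(object) {
  msg <- character()
  n <- length(object@id)
  if (length(object@sire) != n || length(object@dam) != n)
    msg <- c(msg, "id, sire and dam must have equal length")
  if (anyDuplicated(object@id))
    msg <- c(msg, "duplicated individual ids")
  pos <- match(object@id, object@id)
  sp <- match(object@sire, object@id)
  dp <- match(object@dam, object@id)
  if (any(!is.na(sp) & sp >= seq_len(n)) || any(!is.na(dp) & dp >= seq_len(n)))
    msg <- c(msg, "pedigree not topologically sorted: a parent follows its offspring")
  if (length(msg)) msg else TRUE
})

#' Marker quality-control report
#'
#' Per-marker statistics and removal counts from [qcFilter()]. Each removed
#' marker is attributed to the first criterion it fails, in the order
#' MAF, call rate, Hardy-Weinberg.
#'
#' @slot nInput,nRemovedMaf,nRemovedCallrate,nRemovedHwe,nRetained integer counts.
#' @slot stats `data.frame` with per-marker `snp`, `maf`, `callrate`,
#'   `hweChi2`, `hweP`, `removed`, `reason`.
#' @export
setClass("QCReport",
         representation(nInput = "integer", nRemovedMaf = "integer",
                        nRemovedCallrate = "integer", nRemovedHwe = "integer",
                        nRetained = "integer", stats = "data.frame"))

setValidity("QCReport", function(object) {
  tot <- object@nRemovedMaf + object@nRemovedCallrate + object@nRemovedHwe
  if (object@nRetained + tot != object@nInput)
    return("retained + removed counts must equal input count")
  TRUE
})

#' Relationship matrix
#'
#' Symmetric relationship matrix among individuals, of pedigree-additive,
#' genomic-additive (VanRaden) or genomic-dominance kind, with the scaling
#' denominator recorded for the genomic kinds.
#'
#' @slot mat symmetric numeric matrix with individual ids as dimnames.
#' @slot kind one of `"pedigree-additive"`, `"genomic-additive"`,
#'   `"genomic-dominance"`.
#' @slot denom scaling denominator used (NA for pedigree kind).
#' @export
setClass("RelMatrix",
         representation(mat = "matrix", kind = "character", denom = "numeric"))

setValidity("RelMatrix", function(object) {
  msg <- character()
  m <- object@mat
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  else if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    msg <- c(msg, "matrix must be symmetric")
  if (!object@kind %in% c("pedigree-additive", "genomic-additive", "genomic-dominance"))
    msg <- c(msg, "unknown relationship kind")
  if (!any(is.na(object@denom)) && length(object@denom) && object@denom <= 0)
    msg <- c(msg, "denominator must be positive")
  if (length(msg)) msg else TRUE
})

#' Variance-component estimates from AI-REML
#'
#' @slot estimates named numeric vector of variance components (residual last,
#'   named `"residual"`).
#' @slot se asymptotic standard errors (square roots of the diagonal of the
#'   inverse average-information matrix).
#' @slot vcov inverse average-information matrix (asymptotic covariance of the
#'   estimates).
#' @slot proportions each component's share of the summed variance, with
#'   first-order (delta-method) standard errors in `proportionsSE`.
#' @slot proportionsSE numeric.
#' @slot loglik restricted log-likelihood at the optimum.
#' @slot converged logical.
#' @slot trace per-iteration `data.frame` (step kind, log-likelihood, estimates).
#' @slot gradNorm final gradient norm.
#' @export
setClass("VarianceComponents",
         representation(estimates = "numeric", se = "numeric", vcov = "matrix",
                        proportions = "numeric", proportionsSE = "numeric",
                        loglik = "numeric", converged = "logical",
                        trace = "data.frame", gradNorm = "numeric"))

#' Fitted pedigree sire model
#'
#' REML fit of a sire model used to pre-correct fertility phenotypes for
#' fixed effects: `y = Xb + Z_s s + (Z pe) + e` with `s ~ N(0, sigma_s^2 A_s)`,
#' optional permanent-environment effects for cows, and iid residuals.
#'
#' @slot stage `"heifer"` or `"cow"`.
#' @slot fixef named fixed-effect estimates.
#' @slot sireBlup named BLUPs of sire effects.
#' @slot peBlup named BLUPs of permanent-environment effects (cows; empty for
#'   heifers).
#' @slot residuals per-record residual BLUPs (`y - Xb - Z_s s - Z pe`).
#' @slot records the record table the model was fitted to.
#' @slot vc [VarianceComponents-class] of the fit.
#' @slot trait name of the response column.
#' @export
setClass("SireModelFit",
         representation(stage = "character", fixef = "numeric",
                        sireBlup = "numeric", peBlup = "numeric",
                        residuals = "numeric", records = "data.frame",
                        vc = "VarianceComponents", trait = "character"))

#' Null polygenic model for the association scan
#'
#' REML fit of `y = 1 mu + u + e`, `u ~ N(0, sigma_g^2 A)`,
#' `e ~ N(0, sigma_e^2 W)` with `W = diag(1/w*)`, plus the cached spectral
#' decomposition that makes per-marker generalized least squares O(n).
#'
#' @slot sigmaG2,sigmaE2 variance-component estimates.
#' @slot ids individual ids, aligned with the decomposition.
#' @slot evectors,evalues eigenvectors/eigenvalues of the (weight-scaled)
#'   relationship matrix.
#' @slot sqrtw square roots of the standardized residual weights (all 1 for
#'   unweighted traits).
#' @slot ytilde rotated (weight-scaled) phenotype vector.
#' @slot loglik restricted log-likelihood.
#' @slot converged logical.
#' @export
setClass("NullModelFit",
         representation(sigmaG2 = "numeric", sigmaE2 = "numeric",
                        ids = "character", evectors = "matrix",
                        evalues = "numeric", sqrtw = "numeric",
                        ytilde = "numeric", loglik = "numeric",
                        converged = "logical"))

#' Simulation scenario for QTN phenotypes
#'
#' Study conditions for one power-study scenario: QTN positions and target
#' minor-allele frequencies, the per-QTN additive variance expressed as a
#' fraction of the polygenic variance, the dominance ratio `h = d/a`, and the
#' polygenic and residual variances.
#'
#' @slot qtnChrom chromosome label of the QTN.
#' @slot qtnPositions bp positions of the QTN markers.
#' @slot qtnMafs target minor-allele frequencies (same length).
#' @slot varFraction per-QTN additive variance as a fraction of `sigmaU2`.
#' @slot dominanceRatio dominance ratio `h = d/a`.
#' @slot sigmaU2 polygenic variance (default 1).
#' @slot sigmaE2 residual variance (default 19).
#' @slot nReps replicate count for the power study.
#' @seealso [SimulationScenario()], [simulateQtnPhenotypes()], [runReplicate()]
#' @export
setClass("SimulationScenario",
         representation(qtnChrom = "character", qtnPositions = "numeric",
                        qtnMafs = "numeric", varFraction = "numeric",
                        dominanceRatio = "numeric", sigmaU2 = "numeric",
                        sigmaE2 = "numeric", nReps = "integer"))

setValidity("SimulationScenario", function(object) {
  msg <- character()
  if (length(object@qtnPositions) != length(object@qtnMafs))
    msg <- c(msg, "qtnPositions and qtnMafs must have the same length")
  if (object@varFraction < 0)
    msg <- c(msg, "varFraction must be non-negative (0 = no QTN effect)")
  if (object@nReps < 1L) msg <- c(msg, "nReps must be >= 1")
  if (any(object@qtnMafs <= 0 | object@qtnMafs >= 1))
    msg <- c(msg, "qtnMafs must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})
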