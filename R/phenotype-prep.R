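#' Edit raw fertility records
#'
#' Applies standard record-editing bounds. Heifers are kept when age at first
#' insemination is strictly between 270 and 900 days, NINS < 8 and
#' IFL < 365 days. Cows are kept when age at first calving is strictly
#' between 550 and 1100 days, NINS < 8, ICF < 230 days and IFL < 365 days.
#' Records missing a required field are rejected with reason `"incomplete"`.
#' Each removed record is attributed to the first rule it violates, in the
#' order listed above. Editing is idempotent.
#'
#' @param records fertility record `data.frame` as produced by
#'   [simulateFertilityRecords()] (columns `id`, `stage`, `ageIns`,
#'   `ageCalv`, `IFL`, `NINS`, `ICF`, `censored`, ...).
#' @return list with `records` (retained rows) and `report` (removal counts
#'   per rule).
#' @export
editRecords <- function(records) {
  reason <- rep(NA_character_, nrow(records))
  isHeifer <- records$stage == "heifer"
  isCow <- records$stage == "cow"

  need <- ifelse(isHeifer,
                 is.na(records$ageIns) | is.na(records$NINS) | is.na(records$IFL),
                 is.na(records$ageCalv) | is.na(records$NINS) |
                   is.na(records$ICF) | is.na(records$IFL))
  reason[need] <- "incomplete"

  chk <- function(cond, label) {
    hit <- is.na(reason) & !need & cond & !is.na(cond)
    reason[hit] <<- label
  }
  chk(isHeifer & !(records$ageIns > 270 & records$ageIns < 900), "ageIns")
  chk(isHeifer & !(records$NINS < 8), "nins")
  chk(isHeifer & !(records$IFL < 365), "ifl")
  chk(isCow & !(records$ageCalv > 550 & records$ageCalv < 1100), "ageCalv")
  chk(isCow & !(records$NINS < 8), "nins")
  chk(isCow & !(records$ICF < 230), "icf")
  chk(isCow & !(records$IFL < 365), "ifl")

  keep <- is.na(reason)
  report <- table(factor(reason[!keep],
                         levels = c("incomplete", "ageIns", "ageCalv",
                                    "nins", "icf", "ifl")))
  list(records = records[keep, , drop = FALSE],
       report = as.data.frame(report, responseName = "removed",
                              stringsAsFactors = FALSE))
}

#' Apply censoring penalties
#'
#' Records flagged as censored (no confirmed successful insemination) get a
#' penalty of 21 days added to IFL and 1 count added to NINS; uncensored
#' records are unchanged. Apply after [editRecords()].
#'
#' @param records fertility record `data.frame` with a logical `censored`
#'   column.
#' @return the records with penalties applied.
#' @export
applyCensoringPenalty <- function(records) {
  if (!"censored" %in% names(records)) stop("records lack a censored flag")
  cz <- records$censored %in% TRUE
  records$IFL[cz] <- records$IFL[cz] + 21
  records$NINS[cz] <- records$NINS[cz] + 1
  records
}

#' Fit a pedigree sire model to fertility records
#'
#' REML fit (via [aiReml()]) of `y = Xb + Z_s s + e` for heifers or
#' `y = Xb + Z_s s + Z pe + e` for cows, with `s ~ N(0, sigma_s^2 A_s)` over
#' the sire pedigree relationship matrix, iid permanent-environment effects
#' for cows, and iid residuals. Fixed effects: herd, year-month of first
#' insemination (categorical), a linear age covariate (age at first
#' insemination for heifers, at first calving for cows) and parity (cows).
#' Factors with a single observed level are absorbed into the intercept.
#'
#' @param records edited (and penalty-adjusted) record `data.frame`.
#' @param sirePedigree a [Pedigree-class] containing the sires of the record
#'   holders (records whose animal has no known sire carry no sire effect).
#' @param ped a [Pedigree-class] linking animals to sires (used to look up
#'   each record animal's sire); may be the same object as `sirePedigree`.
#' @param stage `"heifer"` or `"cow"`.
#' @param trait response column name (default `"IFL"`).
#' @param ... passed to [aiReml()].
#' @return a [SireModelFit-class] object.
#' @export
fitSireModel <- function(records, sirePedigree, ped = sirePedigree,
                         stage = c("heifer", "cow"), trait = "IFL", ...) {
  stage <- match.arg(stage)
  records <- records[records$stage == stage, , drop = FALSE]
  y <- records[[trait]]
  if (is.null(y)) stop("trait column not found: ", trait)
  n <- length(y)
  if (length(unique(records$herd)) < 2)
    message("single herd: herd effect absorbed into the intercept")

  addFactor <- function(terms, col) {
    if (col %in% names(records) && length(unique(records[[col]])) > 1)
      c(terms, sprintf("factor(%s)", col)) else terms
  }
  terms <- character()
  terms <- addFactor(terms, "herd")
  terms <- addFactor(terms, "ym")
  age <- if (stage == "heifer") "ageIns" else "ageCalv"
  if (age %in% names(records) && stats::sd(records[[age]]) > 0)
    terms <- c(terms, age)
  if (stage == "cow") terms <- addFactor(terms, "parity")
  form <- if (length(terms))
    stats::as.formula(paste("~", paste(terms, collapse = " + "))) else ~1
  X <- stats::model.matrix(form, data = records)

  sires <- pedSires(ped)[match(records$id, pedIds(ped))]
  sireIds <- sort(unique(stats::na.omit(sires)))
  if (!length(sireIds)) stop("no record animal has a known sire")
  As <- relMat(pedigreeA(sirePedigree, subset = sireIds))
  si <- match(sires, sireIds)
  Zs <- matrix(0, n, length(sireIds))
  Zs[cbind(which(!is.na(si)), si[!is.na(si)])] <- 1
  Ksire <- Zs %*% As %*% t(Zs)

  random <- list(sire = Ksire)
  if (stage == "cow") {
    animals <- factor(records$id)
    Zpe <- stats::model.matrix(~ animals - 1)
    random$pe <- tcrossprod(Zpe)
  }
  vc <- aiReml(y, X, random, ...)
  est <- vcEstimates(vc)

  # BLUPs at the estimated variances
  V <- est["sire"] * Ksire + diag(est["residual"], n)
  if (stage == "cow") V <- V + est["pe"] * random$pe
  Vinv <- chol2inv(chol(V))
  XVX <- crossprod(X, Vinv %*% X)
  b <- drop(solve(XVX, crossprod(X, Vinv %*% y)))
  names(b) <- colnames(X)
  resid0 <- y - drop(X %*% b)
  Vr <- drop(Vinv %*% resid0)
  sHat <- drop(est["sire"] * As %*% crossprod(Zs, Vr))
  names(sHat) <- sireIds
  peHat <- numeric(0)
  fitted <- drop(Zs %*% sHat)
  if (stage == "cow") {
    peHat <- drop(est["pe"] * crossprod(Zpe, Vr))
    names(peHat) <- levels(animals)
    fitted <- fitted + drop(Zpe %*% peHat)
  }
  eHat <- resid0 - fitted
  records$.sire <- sires  # sire used for each record (NA when unknown)
  new("SireModelFit", stage = stage, fixef = b, sireBlup = sHat,
      peBlup = peHat, residuals = eHat, records = records, vc = vc,
      trait = trait)
}

#' Pre-correct phenotypes from a fitted sire model
#'
#' Removes estimated fixed effects and, for cows, averages residuals over
#' parities: heifers get `y_hc = Z_s s + e` (one record each); cows get
#' `y_cc = Z_s s + mean_k(e_k)` over their `n` usable parities, with the
#' permanent-environment effect excluded. Cow reliabilities follow
#' [reliability()] with the supplied heritability, and residual weights
#' [residualWeights()]; heifer phenotypes carry unit weights.
#'
#' @param fit a converged [SireModelFit-class].
#' @param h2 heritability used in the cow reliability formula (defaults:
#'   0.02 for IFL, 0.03 for NINS, 0.04 for ICF; ignored for heifers).
#' @return `data.frame` with `id`, `yc`, `n`, `r2`, `w`, `wstar`.
#' @export
precorrect <- function(fit, h2 = NULL) {
  if (!isConverged(fit@vc))
    stop("sire model did not converge; refusing to pre-correct")
  records <- fit@records
  # y - Xb = Zs s + (Z pe) + e; keep the s-part plus residual, pe excluded
  sVals <- records$.sire
  sPart <- ifelse(is.na(sVals), 0, fit@sireBlup[sVals])
  yPart <- sPart + fit@residuals
  if (fit@stage == "heifer") {
    out <- data.frame(id = records$id, yc = yPart, n = 1L, r2 = NA_real_,
                      w = 1, wstar = 1, stringsAsFactors = FALSE)
    return(out)
  }
  if (is.null(h2)) {
    h2 <- switch(fit@trait, IFL = 0.02, NINS = 0.03, ICF = 0.04, 0.02)
  }
  # the sire part is constant within animal, so averaging yPart over
  # parities gives s + mean(e) directly
  agg <- aggregate(yPart, by = list(id = records$id), FUN = mean)
  cnt <- aggregate(rep(1L, nrow(records)), by = list(id = records$id),
                   FUN = sum)
  yc <- agg$x
  n <- cnt$x
  r2 <- reliability(h2, n)
  wts <- residualWeights(r2)
  data.frame(id = agg$id, yc = yc, n = n, r2 = r2, w = wts$w,
             wstar = wts$wstar, stringsAsFactors = FALSE)
}

#' Reliability of a parity-averaged phenotype
#'
#' `r^2 = n h^2 / ((n - 1) h^2 + 1)` for an average over `n` repeated
#' records of a trait with heritability `h^2`; reduces to `h^2` at `n = 1`.
#'
#' @param h2 heritability in (0, 1).
#' @param n number of parities (>= 1). Vectorized.
#' @return reliability values in `[0, 1)`.
#' @export
reliability <- function(h2, n) {
  if (any(h2 <= 0 | h2 >= 1)) stop("h2 must lie strictly in (0, 1)")
  if (any(n < 1)) stop("n must be at least 1")
  n * h2 / ((n - 1) * h2 + 1)
}

#' Residual weights from reliabilities
#'
#' Raw weights `w = r^2 / (1 - r^2)`, standardized to mean 1
#' (`w* = w / mean(w)`); the residual covariance downstream is
#' `sigma_e^2 diag(1/w*)`.
#'
#' @param r2 reliabilities in `[0, 1)`.
#' @return list with `w` and `wstar`.
#' @export
residualWeights <- function(r2) {
  if (any(r2 < 0 | r2 >= 1)) stop("reliabilities must lie in [0, 1)")
  w <- r2 / (1 - r2)
  list(w = w, wstar = w / mean(w))
}
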