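#' Fit the null polygenic model for an association scan
#'
#' REML fit of `y = 1 mu + u + e` with `u ~ N(0, sigma_g^2 A)` and
#' `e ~ N(0, sigma_e^2 diag(1/w*))` using the spectral AI-REML path, and
#' caches the decomposition so that per-marker generalized least squares
#' costs O(n) afterwards. Raises an error on non-convergence (a scan must
#' not run on a broken null).
#'
#' @param yc named numeric vector of (pre-corrected) phenotypes.
#' @param A relationship matrix among the phenotyped individuals
#'   ([RelMatrix-class] or matrix), usually the pedigree relationship matrix.
#' @param weights standardized residual weights `w*` (default 1).
#' @param eig optional precomputed `eigen()` of the weight-scaled `A`
#'   (see [buildScanCache()]).
#' @param ... passed to [aiReml()]'s iteration controls.
#' @return a [NullModelFit-class] object.
#' @export
fitNull <- function(yc, A = NULL, weights = NULL, eig = NULL, ...) {
  if (is(A, "RelMatrix")) A <- relMat(A)
  if (is.null(A) && is.null(eig))
    stop("supply A or a precomputed eigendecomposition")
  n <- length(yc)
  ids <- names(yc)
  if (is.null(ids) && !is.null(A)) ids <- rownames(A)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (is.null(weights)) weights <- rep(1, n)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  engine <- .spectralEngine(yc, X, A, weights, eig = eig)
  vy <- var(yc)
  vc <- .airemlIterate(engine,
                       setNames(c(vy / 2, vy / 2), c("polygenic", "residual")),
                       lb = 1e-8 * vy, maxIter = 200, tol = 1e-8)
  if (!isConverged(vc))
    stop("null polygenic model failed to converge")
  new("NullModelFit",
      sigmaG2 = unname(vcEstimates(vc)["polygenic"]),
      sigmaE2 = unname(vcEstimates(vc)["residual"]),
      ids = ids, evectors = engine$eig$vectors,
      evalues = pmax(engine$eig$values, 0), sqrtw = engine$sw,
      ytilde = drop(engine$yt), loglik = vc@loglik, converged = TRUE)
}

#' Test one marker against a fitted null model
#'
#' Generalized least squares fit of the genotype-class means under the null
#' model's covariance, with a Wald chi-square test of class-mean equality
#' (2 df with three observed classes; 1 df, flagged, with two). Individuals
#' with a missing call at the marker are dropped from the test.
#'
#' @param fit a [NullModelFit-class].
#' @param codes integer vector of genotype codes (0/1/2, `NA` allowed) in the
#'   same individual order as the fit.
#' @return list with `counts`, `means`, `cov` (covariance of the class
#'   means), `chi2`, `df`, `p`, `twoClass`.
#' @export
scanSnp <- function(fit, codes) {
  n <- length(fit@ytilde)
  if (length(codes) != n) stop("codes length does not match the fitted model")
  present <- sort(unique(codes[!is.na(codes)]))
  if (length(present) < 2) stop("monomorphic marker: nothing to test")
  d <- fit@sigmaG2 * fit@evalues + fit@sigmaE2
  if (anyNA(codes)) {
    # exact GLS on the complete-case subset with the dense covariance
    U <- fit@evectors
    keep <- which(!is.na(codes))
    Vs <- U %*% (d * t(U))           # covariance of the weight-scaled data
    Vcc <- Vs[keep, keep]
    sw <- fit@sqrtw[keep]
    ysc <- drop(U %*% fit@ytilde)[keep]
    Xcc <- sapply(present, function(cl) as.numeric(codes[keep] == cl)) * sw
    Vinv <- chol2inv(chol(Vcc))
    S <- crossprod(Xcc, Vinv %*% Xcc)
    t0 <- crossprod(Xcc, Vinv %*% ysc)
  } else {
    U <- fit@evectors
    dinv <- 1 / d
    Xr <- crossprod(U, fit@sqrtw *
                      sapply(present, function(cl) as.numeric(codes == cl)))
    S <- crossprod(Xr, dinv * Xr)
    t0 <- crossprod(Xr, dinv * fit@ytilde)
  }
  C <- solve(S)
  mu <- drop(C %*% t0)
  k <- length(present)
  chi2 <- drop(crossprod(mu, t0)) - sum(t0)^2 / sum(S)
  df <- k - 1L
  counts <- table(factor(codes, levels = 0:2))
  means <- setNames(rep(NA_real_, 3), c("mu0", "mu1", "mu2"))
  means[present + 1L] <- mu
  covM <- matrix(NA_real_, 3, 3)
  covM[present + 1L, present + 1L] <- C
  list(counts = as.integer(counts), means = means, cov = covM,
       chi2 = max(chi2, 0), df = df,
       p = pchisq(max(chi2, 0), df, lower.tail = FALSE),
       twoClass = k == 2L)
}

#' False-discovery-rate q-values
#'
#' Storey q-values with the smoother estimate of the null proportion `pi0`
#' (natural-spline smoothing of `pi0(lambda)` over a lambda grid, evaluated
#' at the largest lambda) by default; `method = "BH"` gives
#' Benjamini-Hochberg adjusted p-values (equivalent to `pi0 = 1`). When the
#' smoother cannot be estimated (few p-values, degenerate distributions),
#' `pi0` falls back to 1.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param method `"storey"` (default) or `"BH"`.
#' @param lambda grid for the `pi0` smoother.
#' @return numeric q-values, same length and order as `pvals`.
#' @export
fdrQvalues <- function(pvals, method = c("storey", "BH"),
                       lambda = seq(0.05, 0.95, 0.05)) {
  method <- match.arg(method)
  m <- length(pvals)
  if (m == 0) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (method == "BH") return(p.adjust(pvals, method = "BH"))
  pi0 <- .estimatePi0(pvals, lambda)
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * m * pvals[o] / rank(pvals, ties.method = "max")[o]
  q <- pmin(1, cummin(q))
  q[ro]
}

.estimatePi0 <- function(pvals, lambda) {
  m <- length(pvals)
  if (m < 100 || length(lambda) < 4) return(1)
  pi0l <- vapply(lambda, function(l) mean(pvals > l) / (1 - l), numeric(1))
  pi0 <- tryCatch({
    fit <- smooth.spline(lambda, pi0l, df = 3)
    predict(fit, x = max(lambda))$y
  }, error = function(e) 1)
  if (!is.finite(pi0) || pi0 <= 0) pi0 <- 1
  min(pi0, 1)
}

#' Additive/dominance decomposition of genotype-class means
#'
#' `a = (mu_aa - mu_AA) / 2` and `d = mu_Aa - (mu_aa + mu_AA) / 2`, with
#' t-tests of each effect against zero using the GLS covariance of the class
#' means. Requires all three classes; with a missing class the effects are
#' returned as `NA` with `defined = FALSE`.
#'
#' @param means length-3 numeric: reference-homozygote, heterozygote and
#'   alternate-homozygote means (`mu_AA`, `mu_Aa`, `mu_aa`).
#' @param covMeans 3x3 covariance matrix of the class means.
#' @param df residual degrees of freedom for the t-tests.
#' @return list with `a`, `d`, `seA`, `seD`, `tA`, `pA`, `tD`, `pD`,
#'   `h` (= `d/a`) and `defined`.
#' @export
adDecompose <- function(means, covMeans, df) {
  if (anyNA(means)) {
    return(list(a = NA_real_, d = NA_real_, seA = NA_real_, seD = NA_real_,
                tA = NA_real_, pA = NA_real_, tD = NA_real_, pD = NA_real_,
                h = NA_real_, defined = FALSE))
  }
  la <- c(-0.5, 0, 0.5)
  ld <- c(-0.5, 1, -0.5)
  a <- sum(la * means)
  d <- sum(ld * means)
  seA <- sqrt(drop(t(la) %*% covMeans %*% la))
  seD <- sqrt(drop(t(ld) %*% covMeans %*% ld))
  tA <- a / seA
  tD <- d / seD
  list(a = a, d = d, seA = seA, seD = seD,
       tA = tA, pA = 2 * pt(-abs(tA), df),
       tD = tD, pD = 2 * pt(-abs(tD), df),
       h = d / a, defined = TRUE)
}

#' Per-marker variance explained under Hardy-Weinberg equilibrium
#'
#' Additive variance `2 p (1 - p) [a + (1 - 2p) d]^2` and dominance variance
#' `[2 p (1 - p) d]^2`, divided by the phenotypic variance `Vp`, with `p` the
#' frequency of the `a` allele (the alternate allele whose homozygote mean is
#' `mu_aa`).
#'
#' @param p allele frequency in (0, 1).
#' @param a,d additive and dominance effects.
#' @param Vp phenotypic variance (> 0).
#' @return list with `vA` and `vD` (proportions of `Vp`).
#' @export
snpVarianceExplained <- function(p, a, d, Vp) {
  if (any(Vp <= 0)) stop("phenotypic variance must be positive")
  if (any(p <= 0 | p >= 1)) stop("allele frequency must lie in (0, 1)")
  vA <- 2 * p * (1 - p) * (a + (1 - 2 * p) * d)^2
  vD <- (2 * p * (1 - p) * d)^2
  list(vA = vA / Vp, vD = vD / Vp)
}

#' Precompute the association-scan cache
#'
#' Eigendecomposes the (weight-scaled) relationship matrix and rotates the
#' genotype-class indicators of every marker, so repeated scans over the same
#' individuals and panel (e.g. power-study replicates) reuse all O(n^2 m)
#' work.
#'
#' @param A relationship matrix among the scanned individuals.
#' @param g [GenotypeData-class] aligned with `A` (same individual order).
#' @param weights standardized residual weights `w*` (default 1).
#' @return an opaque cache list consumed by [runScan()].
#' @export
buildScanCache <- function(A, g, weights = NULL) {
  if (is(A, "RelMatrix")) A <- relMat(A)
  codes <- genoCodes(g)
  n <- nrow(codes)
  if (nrow(A) != n) stop("A and genotypes have different individual counts")
  if (is.null(weights)) weights <- rep(1, n)
  sw <- sqrt(weights)
  eig <- eigen(A * tcrossprod(sw), symmetric = TRUE)
  U <- eig$vectors
  n0 <- colSums(codes == 0L, na.rm = TRUE)
  n1 <- colSums(codes == 1L, na.rm = TRUE)
  n2 <- colSums(codes == 2L, na.rm = TRUE)
  anyMissing <- colSums(is.na(codes)) > 0L
  R0 <- crossprod(U, sw * (!is.na(codes) & codes == 0L))
  R1 <- crossprod(U, sw * (!is.na(codes) & codes == 1L))
  Rs <- drop(crossprod(U, sw))
  list(eig = eig, sw = sw, R0 = R0, R1 = R1, Rs = Rs,
       n0 = n0, n1 = n1, n2 = n2, anyMissing = anyMissing,
       map = markerMap(g), n = n, codes = codes)
}

#' Two-step mixed-model association scan
#'
#' Step 1 tests every polymorphic marker with genotype-class fixed effects
#' against the null `mu_AA = mu_Aa = mu_aa` (Wald chi-square, 2 df with three
#' observed classes, 1 df with two) under the polygenic covariance estimated
#' once by [fitNull()], and converts p-values to q-values with
#' [fdrQvalues()]. Step 2 decomposes markers passing the FDR threshold into
#' additive and dominance effects with t-tests ([adDecompose()]) and
#' computes the variance explained ([snpVarianceExplained()]). Two-class
#' markers are excluded from step 2 (the dominance contrast is undefined);
#' monomorphic markers are not scanned.
#'
#' Variance components are estimated once under the null and held fixed
#' across markers; `refitPerSnp = TRUE` re-estimates them for every marker
#' (slow, for spot checks).
#'
#' @param yc named numeric phenotype vector, aligned with `g`.
#' @param A relationship matrix (ignored when `cache` is supplied).
#' @param g [GenotypeData-class] (ignored when `cache` is supplied).
#' @param fdrLevel FDR significance threshold for step 1 (default 0.10).
#' @param fdrMethod `"storey"` or `"BH"`.
#' @param weights standardized residual weights `w*`.
#' @param cache precomputed [buildScanCache()] result.
#' @param Vp phenotypic variance used as the variance-explained denominator
#'   (default: sample variance of `yc`).
#' @param refitPerSnp logical; re-estimate variance components per marker.
#' @param step2Extra marker ids (snp names) to decompose in step 2 regardless
#'   of step-1 significance (e.g. designated QTN markers in a simulation
#'   study).
#' @return `data.frame` with one row per polymorphic marker: map columns,
#'   MAF, class counts and means, `chi2`, `df`, `p`, `q`, `sig`, and for
#'   step-2 markers `a`, `d`, their SEs, t- and p-values, `h = d/a`, and
#'   `varA`/`varD` (proportions of `Vp`). The [NullModelFit-class] is
#'   attached as attribute `"null"`.
#' @export
runScan <- function(yc, A = NULL, g = NULL, fdrLevel = 0.10,
                    fdrMethod = c("storey", "BH"), weights = NULL,
                    cache = NULL, Vp = NULL, refitPerSnp = FALSE,
                    step2Extra = character()) {
  fdrMethod <- match.arg(fdrMethod)
  if (is.null(cache)) {
    if (is.null(A) || is.null(g)) stop("supply either cache or A and g")
    cache <- buildScanCache(A, g, weights)
  }
  n <- cache$n
  if (length(yc) != n) stop("phenotype length does not match the scan cache")
  weights <- cache$sw^2
  fit <- fitNull(yc, weights = weights, eig = cache$eig)
  if (is.null(Vp)) Vp <- var(yc)

  map <- cache$map
  m <- nrow(map)
  nCall <- cache$n0 + cache$n1 + cache$n2
  pAlt <- ifelse(nCall > 0, (2 * cache$n2 + cache$n1) / (2 * nCall), NA)
  nClass <- (cache$n0 > 0) + (cache$n1 > 0) + (cache$n2 > 0)
  poly <- nClass >= 2L
  fast3 <- poly & nClass == 3L & !cache$anyMissing
  slow <- poly & !fast3

  mu0 <- mu1 <- mu2 <- chi2 <- rep(NA_real_, m)
  df <- rep(NA_integer_, m)
  covList <- vector("list", m)

  if (any(fast3)) {
    d <- fit@sigmaG2 * fit@evalues + fit@sigmaE2
    dinv <- 1 / d
    yt <- fit@ytilde
    R0 <- cache$R0[, fast3, drop = FALSE]
    R1 <- cache$R1[, fast3, drop = FALSE]
    Rs <- cache$Rs
    z <- dinv * yt
    t0 <- drop(crossprod(R0, z))
    t1 <- drop(crossprod(R1, z))
    ts <- sum(Rs * z)
    t2 <- ts - t0 - t1
    W0 <- dinv * R0
    S00 <- colSums(W0 * R0)
    S01 <- colSums(W0 * R1)
    S0s <- drop(crossprod(W0, Rs))
    W1 <- dinv * R1
    S11 <- colSums(W1 * R1)
    S1s <- drop(crossprod(W1, Rs))
    Sss <- sum(dinv * Rs^2)
    # indicator columns sum to one, so the third class is the complement:
    # R2 = Rs - R0 - R1 and its cross-terms follow by expansion
    S02 <- S0s - S00 - S01
    S12 <- S1s - S01 - S11
    S22 <- Sss - 2 * S0s - 2 * S1s + S00 + 2 * S01 + S11
    # closed-form 3x3 solve via cofactors, vectorized over markers
    c00 <- S11 * S22 - S12^2
    c01 <- S02 * S12 - S01 * S22
    c02 <- S01 * S12 - S02 * S11
    c11 <- S00 * S22 - S02^2
    c12 <- S01 * S02 - S00 * S12
    c22 <- S00 * S11 - S01^2
    det <- S00 * c00 + S01 * c01 + S02 * c02
    m0 <- (c00 * t0 + c01 * t1 + c02 * t2) / det
    m1 <- (c01 * t0 + c11 * t1 + c12 * t2) / det
    m2 <- (c02 * t0 + c12 * t1 + c22 * t2) / det
    quad <- m0 * t0 + m1 * t1 + m2 * t2
    sumS <- S00 + S11 + S22 + 2 * (S01 + S02 + S12)
    x2 <- pmax(quad - (t0 + t1 + t2)^2 / sumS, 0)
    idx <- which(fast3)
    mu0[idx] <- m0; mu1[idx] <- m1; mu2[idx] <- m2
    chi2[idx] <- x2
    df[idx] <- 2L
    # covariance matrices stored lazily: rebuild from cofactors on demand
    covFast <- function(j) {
      k <- match(j, idx)
      matrix(c(c00[k], c01[k], c02[k],
               c01[k], c11[k], c12[k],
               c02[k], c12[k], c22[k]), 3, 3) / det[k]
    }
  } else {
    covFast <- function(j) stop("no fast-path marker")
    idx <- integer(0)
  }
  for (j in which(slow)) {
    res <- scanSnp(fit, .cacheCodes(cache, j))
    mu0[j] <- res$means[1]; mu1[j] <- res$means[2]; mu2[j] <- res$means[3]
    chi2[j] <- res$chi2
    df[j] <- res$df
    covList[[j]] <- res$cov
  }
  if (refitPerSnp) {
    for (j in which(fast3)) {
      res <- .refitSnp(yc, cache, j, weights)
      mu0[j] <- res$means[1]; mu1[j] <- res$means[2]; mu2[j] <- res$means[3]
      chi2[j] <- res$chi2
      df[j] <- res$df
      covList[[j]] <- res$cov
    }
  }

  keep <- which(poly)
  p <- pchisq(chi2[keep], df[keep], lower.tail = FALSE)
  q <- fdrQvalues(p, method = fdrMethod)
  out <- data.frame(snp = map$snp[keep], chrom = map$chrom[keep],
                    bp = map$bp[keep],
                    maf = pmin(pAlt[keep], 1 - pAlt[keep]),
                    pAlt = pAlt[keep],
                    n0 = cache$n0[keep], n1 = cache$n1[keep],
                    n2 = cache$n2[keep],
                    mu0 = mu0[keep], mu1 = mu1[keep], mu2 = mu2[keep],
                    chi2 = chi2[keep], df = df[keep], p = p, q = q,
                    sig = q <= fdrLevel,
                    a = NA_real_, d = NA_real_, seA = NA_real_,
                    seD = NA_real_, tA = NA_real_, pA = NA_real_,
                    tD = NA_real_, pD = NA_real_, h = NA_real_,
                    varA = NA_real_, varD = NA_real_,
                    stringsAsFactors = FALSE)
  step2 <- which((out$sig | out$snp %in% step2Extra) & out$df == 2L)
  for (r in step2) {
    j <- keep[r]
    cv <- if (!is.null(covList[[j]])) covList[[j]] else covFast(j)
    dec <- adDecompose(c(out$mu0[r], out$mu1[r], out$mu2[r]), cv,
                       df = n - 3L)
    ve <- snpVarianceExplained(out$pAlt[r], dec$a, dec$d, Vp)
    out$a[r] <- dec$a; out$d[r] <- dec$d
    out$seA[r] <- dec$seA; out$seD[r] <- dec$seD
    out$tA[r] <- dec$tA; out$pA[r] <- dec$pA
    out$tD[r] <- dec$tD; out$pD[r] <- dec$pD
    out$h[r] <- dec$h
    out$varA[r] <- ve$vA; out$varD[r] <- ve$vD
  }
  attr(out, "null") <- fit
  out
}

# the cache keeps the raw codes for the slow (missing-call / two-class /
# per-marker refit) paths
.cacheCodes <- function(cache, j) cache$codes[, j]

# exact per-marker REML refit (slow path): re-estimates both variance
# components with the genotype classes as fixed effects, reusing the cached
# eigendecomposition
.refitSnp <- function(yc, cache, j, weights) {
  codes <- .cacheCodes(cache, j)
  present <- sort(unique(codes[!is.na(codes)]))
  X <- sapply(present, function(cl) as.numeric(codes == cl))
  engine <- .spectralEngine(yc, X, K = NULL, weights, eig = cache$eig)
  vy <- var(yc)
  vc <- .airemlIterate(engine, setNames(c(vy / 2, vy / 2),
                                        c("polygenic", "residual")),
                       lb = 1e-8 * vy, maxIter = 200, tol = 1e-8)
  est <- vcEstimates(vc)
  d <- est["polygenic"] * pmax(cache$eig$values, 0) + est["residual"]
  dinv <- 1 / d
  Xr <- crossprod(cache$eig$vectors, cache$sw * X)
  yt <- drop(crossprod(cache$eig$vectors, cache$sw * yc))
  S <- crossprod(Xr, dinv * Xr)
  t0 <- crossprod(Xr, dinv * yt)
  C <- solve(S)
  mu <- drop(C %*% t0)
  chi2 <- max(drop(crossprod(mu, t0)) - sum(t0)^2 / sum(S), 0)
  means <- setNames(rep(NA_real_, 3), c("mu0", "mu1", "mu2"))
  means[present + 1L] <- mu
  covM <- matrix(NA_real_, 3, 3)
  covM[present + 1L, present + 1L] <- C
  list(means = means, cov = covM, chi2 = chi2, df = length(present) - 1L)
}
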