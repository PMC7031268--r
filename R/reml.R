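#' Average-information REML for variance-component models
#'
#' Fits `y = X b + sum_k u_k + e` with `u_k ~ N(0, sigma_k^2 K_k)` and
#' `e ~ N(0, sigma_e^2 W)`, `W = diag(1/w*)`, by average-information (AI)
#' REML. AI (quasi-Newton) updates are taken whenever they increase the
#' restricted likelihood and stay inside the parameter space; otherwise an
#' expectation-maximization step with step-halving is used, so accepted
#' iterations never decrease the likelihood. Estimates are clamped at a small
#' positive boundary (`1e-8` times the phenotypic variance), which lets
#' near-zero components be reported rather than crashing; models that exhaust
#' `maxIter` are returned with `converged = FALSE` and partial results.
#' Asymptotic standard errors are square roots of the diagonal of the inverse
#' AI matrix at the optimum.
#'
#' Models with a single covariance structure use an exact spectral shortcut
#' (one eigendecomposition of the weight-scaled structure, then O(n) algebra
#' per iteration); the reported log-likelihood is then relative to the
#' weight-scaled data, a constant offset that does not affect estimates,
#' standard errors or convergence.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (default: intercept only). Must have
#'   full column rank.
#' @param random named list of covariance structures: [RelMatrix-class]
#'   objects, symmetric matrices, or the string `"identity"`.
#' @param weights standardized residual weights `w*` (residual covariance is
#'   `sigma_e^2 diag(1/w*)`); default all 1.
#' @param maxIter maximum number of iterations (default 200).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param init optional named starting values (one per random term plus
#'   `"residual"`); default splits the sample variance equally.
#' @return a [VarianceComponents-class] object.
#' @seealso [heritabilitySE()], [fitNull()]
#' @export
aiReml <- function(y, X = NULL, random, weights = NULL, maxIter = 200,
                   tol = 1e-8, init = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X and y dimensions differ")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  if (n <= qrX$rank) stop("more fixed-effect parameters than observations")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights <= 0))
    stop("weights must be positive and match y")
  if (is.null(names(random)) || any(!nzchar(names(random))))
    names(random) <- paste0("vc", seq_along(random))
  Ks <- lapply(random, function(k) {
    if (is(k, "RelMatrix")) k <- relMat(k)
    if (identical(k, "identity")) return("identity")
    k <- as.matrix(k)
    if (nrow(k) != n || ncol(k) != n)
      stop("covariance structure dimension does not match y")
    k
  })

  vy <- var(y)
  if (!is.finite(vy) || vy <= 0) {
    # degenerate response: all components at the boundary
    r <- length(Ks) + 1L
    lb <- 1e-8
    est <- setNames(rep(lb, r), c(names(Ks), "residual"))
    return(new("VarianceComponents", estimates = est,
               se = setNames(rep(NA_real_, r), names(est)),
               vcov = matrix(NA_real_, r, r), proportions = est / sum(est),
               proportionsSE = setNames(rep(NA_real_, r), names(est)),
               loglik = NA_real_, converged = TRUE,
               trace = data.frame(), gradNorm = NA_real_))
  }
  lb <- 1e-8 * vy
  r <- length(Ks) + 1L
  theta <- if (is.null(init)) rep(vy / r, r) else {
    stopifnot(length(init) == r)
    as.numeric(init)
  }
  names(theta) <- c(names(Ks), "residual")

  single <- length(Ks) == 1L && is.matrix(Ks[[1]])
  engine <- if (single) {
    .spectralEngine(y, X, Ks[[1]], weights)
  } else {
    .denseEngine(y, X, Ks, weights)
  }
  .airemlIterate(engine, theta, lb, maxIter, tol)
}

# ---- shared iteration driver -------------------------------------------------
# engine: list(eval = function(theta) -> list(ll, grad, AI))
.airemlIterate <- function(engine, theta, lb, maxIter, tol) {
  r <- length(theta)
  theta <- pmax(theta, lb)
  cur <- engine$eval(theta)
  trace <- data.frame(iter = 0L, step = "init", loglik = cur$ll,
                      t(theta), check.names = FALSE)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    # floating-noise scale for accepting (near-)equal likelihoods
    eps <- 1e-9 * (abs(cur$ll) + 1)
    step <- "AI"
    delta <- tryCatch(solve(cur$AI, cur$grad), error = function(e) NULL)
    cand <- NULL
    if (!is.null(delta) && it > 1L) {
      # AI update with step halving: full Newton-type steps can overshoot
      # early on
      for (fac in c(1, 0.5, 0.25, 0.125)) {
        prop <- pmax(theta + fac * delta, lb)
        candEval <- tryCatch(engine$eval(prop), error = function(e) NULL)
        if (!is.null(candEval) && is.finite(candEval$ll) &&
            candEval$ll >= cur$ll - eps) {
          cand <- list(theta = prop, eval = candEval)
          break
        }
      }
    }
    emDelta <- (theta^2 / engine$n) * (cur$yPKPy - cur$trPK)
    if (is.null(cand)) {
      # EM step (guaranteed uphill direction), with step halving
      step <- "EM"
      fac <- 1
      for (half in 1:12) {
        prop <- pmax(theta + fac * emDelta, lb)
        candEval <- tryCatch(engine$eval(prop), error = function(e) NULL)
        if (!is.null(candEval) && is.finite(candEval$ll) &&
            candEval$ll >= cur$ll - eps) {
          cand <- list(theta = prop, eval = candEval)
          break
        }
        fac <- fac / 2
      }
    }
    if (is.null(cand)) {
      # no step improves the likelihood; if the EM update itself is
      # negligible we are at a stationary point
      converged <- max(abs(emDelta) / pmax(theta, lb)) < 1e-4
      break
    }
    dll <- cand$eval$ll - cur$ll
    theta <- cand$theta
    cur <- cand$eval
    trace <- rbind(trace, data.frame(iter = it, step = step, loglik = cur$ll,
                                     t(theta), check.names = FALSE))
    if (abs(dll) < tol * (abs(cur$ll) + 1)) {
      converged <- TRUE
      break
    }
  }
  vcov <- tryCatch(solve(cur$AI), error = function(e)
    matrix(NA_real_, r, r))
  se <- sqrt(pmax(diag(vcov), 0))
  names(se) <- names(theta)
  dimnames(vcov) <- list(names(theta), names(theta))
  tot <- sum(theta)
  props <- theta / tot
  propSE <- vapply(seq_len(r), function(i) {
    grad <- -theta[i] / tot^2 * rep(1, r)
    grad[i] <- grad[i] + 1 / tot
    v <- drop(t(grad) %*% vcov %*% grad)
    if (is.finite(v) && v >= 0) sqrt(v) else NA_real_
  }, numeric(1))
  names(propSE) <- names(theta)
  new("VarianceComponents", estimates = theta, se = se, vcov = vcov,
      proportions = props, proportionsSE = propSE, loglik = cur$ll,
      converged = converged, trace = trace,
      gradNorm = sqrt(sum(cur$grad^2)))
}

# ---- dense engine (any number of structures) --------------------------------
.denseEngine <- function(y, X, Ks, weights) {
  n <- length(y)
  rinv <- 1 / weights  # residual structure diag(1/w*)
  Kmats <- lapply(Ks, function(k) if (identical(k, "identity")) diag(n) else k)
  evalFn <- function(theta) {
    r <- length(theta)
    V <- diag(theta[r] * rinv, n)
    for (k in seq_len(r - 1L)) V <- V + theta[k] * Kmats[[k]]
    ch <- chol(V)
    Vinv <- chol2inv(ch)
    logdetV <- 2 * sum(log(diag(ch)))
    VX <- Vinv %*% X
    XVX <- crossprod(X, VX)
    chX <- chol(XVX)
    XVXinv <- chol2inv(chX)
    logdetXVX <- 2 * sum(log(diag(chX)))
    Vy <- Vinv %*% y
    Py <- Vy - VX %*% (XVXinv %*% crossprod(VX, y))
    ll <- -0.5 * (logdetV + logdetXVX + sum(y * Py))
    P <- Vinv - VX %*% XVXinv %*% t(VX)
    q <- matrix(0, n, r)
    trPK <- numeric(r)
    for (k in seq_len(r - 1L)) {
      q[, k] <- Kmats[[k]] %*% Py
      trPK[k] <- sum(P * Kmats[[k]])
    }
    q[, r] <- rinv * Py
    trPK[r] <- sum(diag(P) * rinv)
    yPKPy <- colSums(q * as.vector(Py))
    Pq <- P %*% q
    AI <- 0.5 * crossprod(q, Pq)
    grad <- -0.5 * (trPK - yPKPy)
    list(ll = ll, grad = grad, AI = AI, trPK = trPK, yPKPy = yPKPy)
  }
  list(eval = evalFn, n = n)
}

# ---- spectral engine (one structure + weighted iid residual) ----------------
# Transform y* = sqrt(w) y so the residual is iid, then rotate by the
# eigenvectors of the scaled structure; everything becomes diagonal.
.spectralEngine <- function(y, X, K, weights, eig = NULL) {
  n <- length(y)
  sw <- sqrt(weights)
  if (is.null(eig)) {
    Ks <- K * tcrossprod(sw)
    eig <- eigen(Ks, symmetric = TRUE)
  }
  U <- eig$vectors
  lam <- pmax(eig$values, 0)
  yt <- crossprod(U, sw * y)
  Xt <- crossprod(U, sw * X)
  p <- ncol(Xt)
  evalFn <- function(theta) {
    d <- theta[1] * lam + theta[2]
    if (any(d <= 0)) stop("non-positive-definite V")
    dinv <- 1 / d
    B <- Xt * dinv
    XVX <- crossprod(Xt, B)
    chX <- chol(XVX)
    XVXinv <- chol2inv(chX)
    Bty <- crossprod(B, yt)
    Py <- dinv * yt - B %*% (XVXinv %*% Bty)
    ll <- -0.5 * (sum(log(d)) + 2 * sum(log(diag(chX))) + sum(yt * Py))
    BC <- B %*% XVXinv
    trPK <- c(sum(lam * dinv) - sum(BC * (B * lam)),
              sum(dinv) - sum(BC * B))
    q <- cbind(lam * Py, Py)
    yPKPy <- colSums(q * as.vector(Py))
    Pq <- dinv * q - B %*% (XVXinv %*% crossprod(B, q))
    AI <- 0.5 * crossprod(q, Pq)
    grad <- -0.5 * (trPK - yPKPy)
    list(ll = ll, grad = grad, AI = AI, trPK = trPK, yPKPy = yPKPy)
  }
  list(eval = evalFn, n = n, eig = eig, yt = yt, sw = sw)
}

#' Proportion of variance and its delta-method standard error
#'
#' Computes `sigma_c^2 / sum(sigma^2)` for a named component and its
#' standard error by a first-order Taylor expansion using the asymptotic
#' covariance of all variance components (the inverse AI matrix).
#'
#' @param vc a [VarianceComponents-class] object.
#' @param component name of the component (e.g. `"additive"`).
#' @return list with `proportion` and `se`.
#' @export
heritabilitySE <- function(vc, component) {
  est <- vc@estimates
  if (!component %in% names(est)) stop("unknown component: ", component)
  tot <- sum(est)
  if (tot <= 0) stop("total variance is zero")
  i <- match(component, names(est))
  grad <- -est[i] / tot^2 * rep(1, length(est))
  grad[i] <- grad[i] + 1 / tot
  v <- drop(t(grad) %*% vc@vcov %*% grad)
  list(proportion = unname(est[i] / tot),
       se = if (is.finite(v) && v >= 0) sqrt(v) else NA_real_)
}
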