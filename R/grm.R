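#' Additive genomic relationship matrix (VanRaden method 1)
#'
#' Centers the allele-count codes by twice the observed allele frequency and
#' scales by the summed heterozygosity: `G = ZZ' / sum_j 2 p_j q_j`. Missing
#' codes are mean-imputed (centered to zero) before the cross-product.
#' X-chromosome markers are excluded; monomorphic markers contribute nothing
#' to numerator or denominator.
#'
#' @param g a [GenotypeData-class] object.
#' @param excludeChrom chromosome labels dropped before construction
#'   (default the X chromosome).
#' @param ridge small value added to the diagonal for numerical safety before
#'   downstream factorization (default 0; recorded in the object if used).
#' @return a [RelMatrix-class] of kind `"genomic-additive"`.
#' @export
genomicG <- function(g, excludeChrom = c("X", "x"), ridge = 0) {
  codes <- .autosomalCodes(g, excludeChrom)
  p <- colMeans(codes, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all markers are monomorphic: zero denominator for G")
  codes <- codes[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(codes, 2, 2 * p)
  Z[is.na(Z)] <- 0  # mean imputation: centered value 0
  denom <- sum(2 * p * (1 - p))
  G <- tcrossprod(Z) / denom
  if (ridge > 0) diag(G) <- diag(G) + ridge
  dimnames(G) <- list(rownames(codes), rownames(codes))
  new("RelMatrix", mat = G, kind = "genomic-additive", denom = denom)
}

#' Dominance genomic relationship matrix
#'
#' Built from heterozygosity deviations: entry `(i, j)` of `H` is
#' `1 - 2 p_j q_j` if individual `i` is heterozygous at marker `j` and
#' `-2 p_j q_j` otherwise, and `D = HH' / sum_j 2 p_j q_j (1 - 2 p_j q_j)`.
#' Missing calls contribute the neutral value 0. Monomorphic markers are
#' dropped with a warning; X-chromosome markers are excluded.
#'
#' @inheritParams genomicG
#' @return a [RelMatrix-class] of kind `"genomic-dominance"`.
#' @export
genomicD <- function(g, excludeChrom = c("X", "x"), ridge = 0) {
  codes <- .autosomalCodes(g, excludeChrom)
  p <- colMeans(codes, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all markers are monomorphic: zero denominator for D")
  if (any(!poly))
    warning(sum(!poly), " monomorphic marker(s) dropped from D construction")
  codes <- codes[, poly, drop = FALSE]
  p <- p[poly]
  tpq <- 2 * p * (1 - p)
  het <- codes == 1L
  H <- sweep(ifelse(het, 1, 0), 2, tpq)
  H[is.na(H)] <- 0  # neutral contribution for missing calls
  denom <- sum(tpq * (1 - tpq))
  D <- tcrossprod(H) / denom
  if (ridge > 0) diag(D) <- diag(D) + ridge
  dimnames(D) <- list(rownames(codes), rownames(codes))
  new("RelMatrix", mat = D, kind = "genomic-dominance", denom = denom)
}

.autosomalCodes <- function(g, excludeChrom) {
  map <- markerMap(g)
  keep <- !(map$chrom %in% excludeChrom)
  if (!any(keep)) stop("no autosomal markers available")
  genoCodes(g)[, keep, drop = FALSE]
}
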