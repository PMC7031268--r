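#' Construct a Pedigree
#'
#' Builds a topologically sorted pedigree from id/sire/dam triples. Unknown
#' parents may be given as `NA`, `""` or `"0"`. Individuals that appear only
#' as parents are added as founders. A cycle (an individual among its own
#' ancestors) is an error naming one individual on the cycle.
#'
#' @param id,sire,dam vectors of individual and parent identifiers.
#' @param info optional `data.frame` of per-individual metadata aligned with
#'   `id` (it is reordered along with the ids).
#' @param genotyped optional character vector marking the genotyped subset.
#' @return a [Pedigree-class] object.
#' @export
Pedigree <- function(id, sire, dam, info = NULL, genotyped = character()) {
  id <- as.character(id)
  clean <- function(x) {
    x <- as.character(x)
    x[x %in% c("0", "", "NA") | is.na(x)] <- NA_character_
    x
  }
  sire <- clean(sire)
  dam <- clean(dam)
  if (anyDuplicated(id))
    stop("duplicated individual ids in pedigree")
  parents <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(parents)) {
    id <- c(id, parents)
    sire <- c(sire, rep(NA_character_, length(parents)))
    dam <- c(dam, rep(NA_character_, length(parents)))
    if (!is.null(info)) {
      pad <- info[rep(NA_integer_, length(parents)), , drop = FALSE]
      info <- rbind(info, pad)
    }
  }
  n <- length(id)
  sp <- match(sire, id)
  dp <- match(dam, id)

  # Kahn topological sort over the parent -> offspring DAG
  indeg <- (!is.na(sp)) + (!is.na(dp))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(sp[i])) children[[sp[i]]] <- c(children[[sp[i]]], i)
    if (!is.na(dp[i])) children[[dp[i]]] <- c(children[[dp[i]]], i)
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    onCycle <- setdiff(seq_len(n), ord)
    stop(sprintf("pedigree cycle detected involving individual '%s'",
                 id[onCycle[1]]))
  }
  if (is.null(info)) info <- data.frame(row.names = seq_len(n))
  new("Pedigree", id = id[ord], sire = sire[ord], dam = dam[ord],
      info = info[ord, , drop = FALSE], genotyped = as.character(genotyped))
}

#' Pedigree accessors
#'
#' @param ped a [Pedigree-class] object.
#' @return `pedIds`, `pedSires`, `pedDams` return character vectors in
#'   topological order; `pedInfo` the metadata table; `genotypedIds` the
#'   designated genotyped subset.
#' @name pedigree-accessors
#' @export
pedIds <- function(ped) ped@id

#' @rdname pedigree-accessors
#' @export
pedSires <- function(ped) ped@sire

#' @rdname pedigree-accessors
#' @export
pedDams <- function(ped) ped@dam

#' @rdname pedigree-accessors
#' @export
pedInfo <- function(ped) ped@info

#' @rdname pedigree-accessors
#' @export
genotypedIds <- function(ped) ped@genotyped

# Tabular-method numerator relationship matrix over the whole pedigree.
# Returns the dense N x N matrix in topological order. O(N^2) time/memory;
# fine for desk-scale pedigrees (N up to ~10k).
.tabularA <- function(ped) {
  n <- length(ped@id)
  sp <- match(ped@sire, ped@id)
  dp <- match(ped@dam, ped@id)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sp[i]; d <- dp[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[j, s]
      if (!is.na(d)) row <- row + 0.5 * A[j, d]
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(ped@id, ped@id)
  A
}

#' Inbreeding coefficients from a pedigree
#'
#' Computes per-individual inbreeding coefficients `F` via the tabular
#' numerator-relationship recursion (`F = diag(A) - 1`). Founders have
#' `F = 0`.
#'
#' @param ped a [Pedigree-class] object.
#' @param A optional precomputed full numerator relationship matrix in
#'   pedigree order (as returned internally by [pedigreeA()] with
#'   `subset = NULL`), to avoid recomputation.
#' @return named numeric vector of inbreeding coefficients in pedigree order.
#' @export
inbreedingCoefficients <- function(ped, A = NULL) {
  if (is.null(A)) A <- .tabularA(ped)
  diag(A) - 1
}

#' Pedigree numerator relationship matrix
#'
#' Tabular-method additive relationship matrix, computed through all
#' ancestors and returned restricted to `subset` (default: all individuals).
#' The diagonal equals `1 + F`.
#'
#' @param ped a [Pedigree-class] object.
#' @param subset ids to restrict the returned matrix to.
#' @return a [RelMatrix-class] of kind `"pedigree-additive"`.
#' @export
pedigreeA <- function(ped, subset = NULL) {
  A <- .tabularA(ped)
  if (!is.null(subset)) {
    subset <- as.character(subset)
    missing <- setdiff(subset, ped@id)
    if (length(missing))
      stop("subset ids not in pedigree: ", paste(head(missing, 5), collapse = ", "))
    A <- A[subset, subset, drop = FALSE]
  }
  new("RelMatrix", mat = A, kind = "pedigree-additive", denom = NA_real_)
}
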