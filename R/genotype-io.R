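#' Construct a GenotypeData object
#'
#' @param codes integer matrix (individuals x markers) of alternate-allele
#'   counts in `{0,1,2,NA}`.
#' @param map `data.frame` with columns `snp`, `chrom`, `bp`, `allele1`,
#'   `allele2` (codes count copies of `allele2`).
#' @param ids optional individual ids (defaults to `rownames(codes)`).
#' @return a [GenotypeData-class] object.
#' @export
GenotypeData <- function(codes, map, ids = rownames(codes)) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(codes)))
  rownames(codes) <- as.character(ids)
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  map$snp <- as.character(map$snp)
  map$chrom <- as.character(map$chrom)
  colnames(codes) <- map$snp
  new("GenotypeData", codes = codes, map = map)
}

.validAlleles <- c("A", "C", "G", "T", "1", "2", "0")

#' Read PLINK text genotypes
#'
#' Reads a `.ped`/`.map` pair into a [GenotypeData-class] object. Allele pairs
#' are recoded to counts of the second allele; `0 0` becomes a missing call.
#' With a standard 4-column map (`chrom snp cM bp`), per-marker alleles are
#' assigned by order of first appearance down the file (first distinct allele
#' is `allele1`, second is `allele2`). A 6-column map (`chrom snp cM bp
#' allele1 allele2`, as written by [writePlinkText()]) fixes the assignment
#' explicitly, making write/read round trips exact.
#'
#' @param pedPath path to the `.ped` file (6 leading columns, then two allele
#'   columns per marker).
#' @param mapPath path to the `.map` file.
#' @return a [GenotypeData-class] object.
#' @export
readPlinkText <- function(pedPath, mapPath) {
  mapLines <- readLines(mapPath)
  mapLines <- mapLines[nzchar(trimws(mapLines))]
  mp <- strsplit(trimws(mapLines), "[ \t]+")
  nf <- lengths(mp)
  if (!all(nf %in% c(4L, 6L)) || length(unique(nf)) != 1L)
    stop("map parse error: expected 4 or 6 whitespace-separated columns on every line")
  mp <- do.call(rbind, mp)
  map <- data.frame(snp = mp[, 2], chrom = mp[, 1],
                    bp = as.numeric(mp[, 4]), stringsAsFactors = FALSE)
  hasAlleles <- ncol(mp) == 6L
  if (hasAlleles) {
    map$allele1 <- mp[, 5]
    map$allele2 <- mp[, 6]
  }
  m <- nrow(map)

  pedLines <- readLines(pedPath)
  pedLines <- pedLines[nzchar(trimws(pedLines))]
  fields <- strsplit(trimws(pedLines), "[ \t]+")
  nf <- lengths(fields)
  expected <- 6L + 2L * m
  bad <- which(nf != expected)
  if (length(bad))
    stop(sprintf("ped parse error at line %d: expected %d fields, found %d",
                 bad[1], expected, nf[bad[1]]))
  ped <- do.call(rbind, fields)
  ids <- ped[, 2]
  al <- ped[, -(1:6), drop = FALSE]
  badAl <- which(!(al %in% .validAlleles))
  if (length(badAl)) {
    ln <- ((badAl[1] - 1L) %% nrow(al)) + 1L
    stop(sprintf("ped parse error at line %d: invalid allele '%s'",
                 ln, al[badAl[1]]))
  }
  n <- nrow(al)
  a1 <- al[, seq(1L, 2L * m, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * m, by = 2L), drop = FALSE]
  if (any((a1 == "0") != (a2 == "0")))
    stop("ped parse error: half-missing genotype (one allele '0')")

  codes <- matrix(NA_integer_, n, m)
  if (!hasAlleles) {
    map$allele1 <- NA_character_
    map$allele2 <- NA_character_
  }
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    obs <- x1 != "0"
    if (!hasAlleles || is.na(map$allele1[j])) {
      # order of first appearance down the file, reading allele pairs in order
      inter <- as.vector(rbind(x1[obs], x2[obs]))
      seen <- unique(inter)
      map$allele1[j] <- if (length(seen) >= 1) seen[1] else NA_character_
      map$allele2[j] <- if (length(seen) >= 2) seen[2] else NA_character_
      if (length(seen) > 2)
        stop(sprintf("ped parse error: marker %s has more than two alleles",
                     map$snp[j]))
    }
    ref2 <- map$allele2[j]
    if (is.na(ref2) || ref2 == "0") {
      codes[obs, j] <- 0L
    } else {
      known <- c(map$allele1[j], ref2)
      if (any(obs & !(x1 %in% c(known, "0") & x2 %in% c(known, "0"))))
        stop(sprintf("ped parse error: marker %s carries an allele not in its map entry",
                     map$snp[j]))
      codes[obs, j] <- (x1[obs] == ref2) + (x2[obs] == ref2)
    }
  }
  map$allele2[is.na(map$allele2)] <- "0"
  GenotypeData(codes, map, ids = ids)
}

#' Write PLINK text genotypes
#'
#' Writes a `.ped` file and a 6-column `.map` file (`chrom snp cM bp allele1
#' allele2`) so that [readPlinkText()] reproduces codes and map exactly.
#'
#' @param g a [GenotypeData-class] object.
#' @param prefix output path prefix; files `<prefix>.ped` and `<prefix>.map`
#'   are created.
#' @return the prefix, invisibly.
#' @export
writePlinkText <- function(g, prefix) {
  map <- markerMap(g)
  a1 <- map$allele1
  a2 <- map$allele2
  a1[is.na(a1)] <- "A"
  a2[is.na(a2) | a2 == "0"] <- a1[is.na(a2) | a2 == "0"]
  codes <- genoCodes(g)
  n <- nrow(codes); m <- ncol(codes)
  first <- matrix(rep(a1, each = n), n, m)
  second <- matrix(rep(a2, each = n), n, m)
  h1 <- ifelse(is.na(codes), "0", ifelse(codes >= 1, second, first))
  h2 <- ifelse(is.na(codes), "0", ifelse(codes == 2, second, first))
  inter <- matrix("", n, 2L * m)
  inter[, seq(1L, 2L * m, 2L)] <- h1
  inter[, seq(2L, 2L * m, 2L)] <- h2
  ids <- sampleIds(g)
  lead <- cbind("FAM", ids, "0", "0", "0", "-9")
  writeLines(apply(cbind(lead, inter), 1, paste, collapse = " "),
             paste0(prefix, ".ped"))
  mp <- cbind(map$chrom, map$snp, "0", format(map$bp, scientific = FALSE,
                                              trim = TRUE),
              ifelse(is.na(map$allele1), "0", map$allele1),
              ifelse(is.na(map$allele2), "0", map$allele2))
  writeLines(apply(mp, 1, paste, collapse = " "), paste0(prefix, ".map"))
  invisible(prefix)
}

#' Read a pedigree from CSV
#'
#' Expects a header row and columns `id`, `sire`, `dam`; unknown parents may
#' be coded `0`, empty or `NA`. The result is topologically sorted and
#' individuals referenced only as parents are added as founders.
#'
#' @param path CSV file path.
#' @return a [Pedigree-class] object.
#' @export
readPedigree <- function(path) {
  tab <- read.table(path, header = TRUE, sep = ",", colClasses = "character",
                    stringsAsFactors = FALSE)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(tab)))
    stop("pedigree file must have columns id, sire, dam")
  Pedigree(tab$id, tab$sire, tab$dam)
}

#' Write a pedigree to CSV
#'
#' @param ped a [Pedigree-class] object.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writePedigree <- function(ped, path) {
  out <- data.frame(id = ped@id,
                    sire = ifelse(is.na(ped@sire), "0", ped@sire),
                    dam = ifelse(is.na(ped@dam), "0", ped@dam),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a QC report as TSV
#'
#' @param report a [QCReport-class] object.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeQCReport <- function(report, path) {
  write.table(report@stats, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
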