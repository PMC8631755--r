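# Containers for diploid microsatellite genotypes and aligned haplotype
# sequences, plus GenAlEx-style CSV and FASTA interchange.

#' Diploid SSR genotype table
#'
#' Individuals by loci, two integer allele calls per cell. Missing genotypes
#' are `NA` in both allele slices (a genotype is either fully observed or
#' fully missing).
#'
#' @slot ids character, individual identifiers.
#' @slot pops character, population label per individual.
#' @slot coords numeric matrix (`lon`, `lat`) per individual, or 0-row.
#' @slot alleles integer array `n x loci x 2` of allele sizes.
#' @exportClass GenotypeTable
setClass("GenotypeTable",
  representation(ids = "character", pops = "character", coords = "matrix",
                 alleles = "array"))

setValidity("GenotypeTable", function(object) {
  n <- length(object@ids)
  if (length(object@pops) != n) return("one population label per individual")
  d <- dim(object@alleles)
  if (length(d) != 3L || d[1] != n || d[3] != 2L)
    return("alleles must be an n x loci x 2 array")
  half <- is.na(object@alleles[, , 1, drop = FALSE]) !=
    is.na(object@alleles[, , 2, drop = FALSE])
  if (any(half)) return("genotypes must be fully observed or fully missing")
  if (nrow(object@coords) && nrow(object@coords) != n)
    return("coords must have one row per individual")
  TRUE
})

#' Construct a GenotypeTable
#' @param ids,pops individual ids and population labels.
#' @param alleles integer array `n x loci x 2` (dimnames on dim 2 = loci).
#' @param coords optional per-individual lon/lat matrix.
#' @export
genotypeTable <- function(ids, pops, alleles, coords = NULL) {
  if (is.null(coords)) coords <- matrix(numeric(0), 0, 2,
                                        dimnames = list(NULL, c("lon", "lat")))
  new("GenotypeTable", ids = as.character(ids), pops = as.character(pops),
      coords = coords, alleles = alleles)
}

#' Aligned haplotype sequences with population labels
#'
#' A rectangular alignment (one sequence per individual) with a haplotype id
#' per sequence; identical sequences (gaps significant) share one id.
#'
#' @slot seqs a [Biostrings::DNAStringSet] of equal-length sequences.
#' @slot pops character, population per individual.
#' @slot haplotype character haplotype id per individual.
#' @exportClass HaplotypeSet
setClass("HaplotypeSet",
  representation(seqs = "ANY", pops = "character", haplotype = "character"))

setValidity("HaplotypeSet", function(object) {
  n <- length(object@seqs)
  if (length(object@pops) != n || length(object@haplotype) != n)
    return("pops and haplotype must have one entry per sequence")
  if (n && length(unique(Biostrings::width(object@seqs))) != 1L)
    return("alignment must be rectangular")
  sq <- as.character(object@seqs)
  if (anyDuplicated(sq)) {
    tab <- split(object@haplotype, sq)
    if (any(vapply(tab, function(h) length(unique(h)), 1L) != 1L))
      return("identical sequences must share one haplotype id")
  }
  TRUE
})

#' Construct a HaplotypeSet, collapsing identical sequences to haplotype ids
#'
#' @param seqs a `DNAStringSet` (or named character vector) of aligned
#'   sequences, one per individual.
#' @param pops population label per individual.
#' @return a [HaplotypeSet-class]; haplotype ids are `H1`, `H2`, ... in
#'   order of first appearance.
#' @export
haplotypeSet <- function(seqs, pops) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  sq <- as.character(seqs)
  hid <- paste0("H", as.integer(factor(sq, levels = unique(sq))))
  new("HaplotypeSet", seqs = seqs, pops = as.character(pops), haplotype = hid)
}

#' @rdname rasterStack
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))
#' Population labels of a genetic container
#' @param x a [GenotypeTable-class] or [HaplotypeSet-class].
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))
#' Locus names of a genotype table
#' @param x a [GenotypeTable-class].
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))
#' Haplotype id per individual
#' @param x a [HaplotypeSet-class].
#' @export
setGeneric("haplotypeIds", function(x) standardGeneric("haplotypeIds"))

setMethod("nIndividuals", "GenotypeTable", function(x) length(x@ids))
setMethod("nIndividuals", "HaplotypeSet", function(x) length(x@seqs))
setMethod("populations", "GenotypeTable", function(x) x@pops)
setMethod("populations", "HaplotypeSet", function(x) x@pops)
setMethod("lociNames", "GenotypeTable", function(x) {
  nm <- dimnames(x@alleles)[[2]]
  if (is.null(nm)) paste0("L", seq_len(dim(x@alleles)[2])) else nm
})
setMethod("haplotypeIds", "HaplotypeSet", function(x) x@haplotype)

setMethod("show", "GenotypeTable", function(object) {
  cat(sprintf("GenotypeTable: %d individuals, %d loci, %d populations\n",
              nIndividuals(object), dim(object@alleles)[2],
              length(unique(object@pops))))
})

setMethod("show", "HaplotypeSet", function(object) {
  cat(sprintf(
    "HaplotypeSet: %d sequences (%d bp), %d haplotypes, %d populations\n",
    nIndividuals(object),
    if (nIndividuals(object)) Biostrings::width(object@seqs)[1] else 0L,
    length(unique(object@haplotype)), length(unique(object@pops))))
})

#' Subset a genotype table by individuals
#' @param x a [GenotypeTable-class].
#' @param i logical or integer index over individuals.
#' @export
subsetIndividuals <- function(x, i) {
  coords <- if (nrow(x@coords)) x@coords[i, , drop = FALSE] else x@coords
  genotypeTable(x@ids[i], x@pops[i],
                x@alleles[i, , , drop = FALSE], coords)
}

#' Subset a haplotype set by individuals
#' @param x a [HaplotypeSet-class].
#' @param i logical or integer index over individuals.
#' @export
subsetHaplotypes <- function(x, i) {
  new("HaplotypeSet", seqs = x@seqs[i], pops = x@pops[i],
      haplotype = x@haplotype[i])
}

## ---- GenAlEx-style CSV ----------------------------------------------------

#' Read / write GenAlEx-style genotype CSV
#'
#' The layout: row 1 holds `n_loci, n_samples, n_pops`, row 2 a title and the
#' population names, row 3 the column header (`sample, pop`, then two columns
#' per locus), and data rows follow with integer allele sizes (0 or blank =
#' missing).
#'
#' @param path CSV file path.
#' @return `readGenAlEx`: a [GenotypeTable-class].
#' @export
readGenAlEx <- function(path) {
  raw <- read.csv(path, header = FALSE, colClasses = "character",
                  blank.lines.skip = FALSE)
  header <- as.character(unlist(raw[3, ]))
  loci <- header[seq(3, length(header), by = 2)]
  loci <- loci[nzchar(loci)]
  dat <- raw[-(1:3), , drop = FALSE]
  dat <- dat[nzchar(dat[[1]]), , drop = FALSE]
  n <- nrow(dat); L <- length(loci)
  al <- array(NA_integer_, c(n, L, 2), dimnames = list(NULL, loci, NULL))
  for (l in seq_len(L)) {
    a1 <- suppressWarnings(as.integer(dat[[2 * l + 1]]))
    a2 <- suppressWarnings(as.integer(dat[[2 * l + 2]]))
    a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
    miss <- is.na(a1) | is.na(a2)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    al[, l, 1] <- a1; al[, l, 2] <- a2
  }
  genotypeTable(dat[[1]], dat[[2]], al)
}

#' @rdname readGenAlEx
#' @param gt a [GenotypeTable-class].
#' @export
writeGenAlEx <- function(gt, path) {
  loci <- lociNames(gt)
  pops <- unique(gt@pops)
  L <- length(loci); n <- nIndividuals(gt)
  width <- max(2L + 2L * L, 2L + length(pops))
  pad <- function(v) c(v, rep("", width - length(v)))
  lines <- rbind(pad(c(L, n, length(pops))),
                 pad(c("clgc genotypes", "", pops)),
                 pad(c("sample", "pop",
                       as.vector(rbind(loci, rep("", L))))))
  body <- matrix("", n, width)
  body[, 1] <- gt@ids; body[, 2] <- gt@pops
  for (l in seq_len(L)) {
    a1 <- gt@alleles[, l, 1]; a2 <- gt@alleles[, l, 2]
    a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
    body[, 2 * l + 1] <- a1; body[, 2 * l + 2] <- a2
  }
  write.table(rbind(lines, body), path, sep = ",", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- FASTA ----------------------------------------------------------------

#' Read / write aligned haplotype FASTA
#'
#' Sequence ids follow the convention `<population>_<individual>`; the
#' population is everything before the last underscore.
#'
#' @param path FASTA file path.
#' @return `readHaplotypes`: a [HaplotypeSet-class].
#' @export
readHaplotypes <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- names(seqs)
  pops <- sub("_[^_]*$", "", ids)
  haplotypeSet(seqs, pops)
}

#' @rdname readHaplotypes
#' @param haps a [HaplotypeSet-class].
#' @export
writeHaplotypes <- function(haps, path) {
  seqs <- haps@seqs
  if (is.null(names(seqs)) || !all(nzchar(names(seqs))))
    names(seqs) <- paste0(haps@pops, "_", seq_along(seqs))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

## ---- labelled square matrices ---------------------------------------------

#' Read / write a labelled square distance matrix CSV
#' @param path CSV path; row and column names are population labels.
#' @export
readDistanceMatrixCsv <- function(path) {
  m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  storage.mode(m) <- "double"
  m
}

#' @rdname readDistanceMatrixCsv
#' @param m square matrix with dimnames.
#' @export
writeDistanceMatrixCsv <- function(m, path) {
  write.csv(m, path, quote = FALSE)
  invisible(path)
}
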