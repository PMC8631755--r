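# Microsatellite and chloroplast-sequence diversity statistics, pairwise
# Weir-Cockerham Fst, and the persistence-based projection of future
# diversity under a habitat-suitability threshold.

#' Allele frequencies for one population x locus
#'
#' @param gt a [GenotypeTable-class].
#' @param population population label.
#' @param locus locus name or index.
#' @return named numeric vector of frequencies over observed alleles,
#'   summing to 1.
#' @export
alleleFrequencies <- function(gt, population, locus) {
  sel <- populations(gt) == population
  a <- c(gt@alleles[sel, locus, 1], gt@alleles[sel, locus, 2])
  a <- a[!is.na(a)]
  if (!length(a)) stop("no non-missing genotypes for ", population,
                       " at locus ", locus)
  tab <- table(a)
  setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Per-locus diversity from an allele-frequency vector
#'
#' `expectedHeterozygosity` is Nei's He = 1 - sum(p^2) (no small-sample
#' correction); `unbiasedHeterozygosity` applies the 2n/(2n-1) correction;
#' `effectiveAlleles` is Ne = 1 / sum(p^2); `shannonIndex` is
#' I = -sum(p log p).
#'
#' @param p frequency vector (sums to 1).
#' @export
expectedHeterozygosity <- function(p) {
  checkFreq(p)
  1 - sum(p^2)
}

#' @rdname expectedHeterozygosity
#' @export
effectiveAlleles <- function(p) {
  checkFreq(p)
  1 / sum(p^2)
}

#' @rdname expectedHeterozygosity
#' @export
shannonIndex <- function(p) {
  checkFreq(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' @rdname expectedHeterozygosity
#' @param n_gene_copies number of gene copies behind `p`.
#' @export
unbiasedHeterozygosity <- function(p, n_gene_copies) {
  he <- expectedHeterozygosity(p)
  if (n_gene_copies < 2) return(NA_real_)
  n_gene_copies / (n_gene_copies - 1) * he
}

checkFreq <- function(p) {
  if (!length(p)) stop("empty frequency vector")
  if (abs(sum(p) - 1) > 1e-8) stop("frequencies must sum to 1")
  invisible(TRUE)
}

## ---- sequence statistics --------------------------------------------------

seqMatrix <- function(seqs) {
  if (is(seqs, "HaplotypeSet")) seqs <- as.character(seqs@seqs)
  if (!is.character(seqs)) seqs <- as.character(seqs)
  do.call(rbind, strsplit(toupper(seqs), ""))
}

#' Sequence diversity statistics
#'
#' `nucleotideDiversity` is the mean pairwise proportion of differing
#' compared sites (sites with a gap or N in either sequence of a pair are
#' excluded pairwise); `geneDiversity` is Nei's unbiased
#' h = n (1 - sum(q^2)) / (n - 1) over haplotype frequencies q;
#' `haplotypeCount` counts distinct sequences with gaps significant.
#'
#' @param seqs a [HaplotypeSet-class], `DNAStringSet`, or character vector
#'   of aligned sequences.
#' @export
nucleotideDiversity <- function(seqs) {
  m <- seqMatrix(seqs)
  n <- nrow(m)
  if (n < 2L) return(NA_real_)
  tot <- 0; cnt <- 0L
  valid <- m %in% c("A", "C", "G", "T")
  dim(valid) <- dim(m)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- valid[i, ] & valid[j, ]
    L <- sum(comp)
    if (L == 0L) next
    tot <- tot + sum(m[i, comp] != m[j, comp]) / L
    cnt <- cnt + 1L
  }
  if (cnt == 0L) NA_real_ else tot / cnt
}

#' @rdname nucleotideDiversity
#' @export
geneDiversity <- function(seqs) {
  m <- if (is(seqs, "HaplotypeSet")) as.character(seqs@seqs) else
    as.character(seqs)
  n <- length(m)
  if (n < 2L) return(NA_real_)
  q <- as.numeric(table(m)) / n
  n * (1 - sum(q^2)) / (n - 1)
}

#' @rdname nucleotideDiversity
#' @export
haplotypeCount <- function(seqs) {
  m <- if (is(seqs, "HaplotypeSet")) as.character(seqs@seqs) else
    as.character(seqs)
  length(unique(m))
}

## ---- Weir-Cockerham Fst ---------------------------------------------------

# Variance components a (among populations), b (among individuals within
# populations), c (within individuals) for one allele at one locus,
# following Weir & Cockerham's theta estimator.
wcComponents <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                              hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# multilocus theta between two populations: ratio of sums over all alleles
# and loci
thetaPair <- function(gt, popA, popB) {
  selA <- populations(gt) == popA
  selB <- populations(gt) == popB
  num <- 0; den <- 0
  for (l in seq_len(dim(gt@alleles)[2])) {
    gA <- cbind(gt@alleles[selA, l, 1], gt@alleles[selA, l, 2])
    gB <- cbind(gt@alleles[selB, l, 1], gt@alleles[selB, l, 2])
    gA <- gA[!is.na(gA[, 1]), , drop = FALSE]
    gB <- gB[!is.na(gB[, 1]), , drop = FALSE]
    n_i <- c(nrow(gA), nrow(gB))
    if (any(n_i < 2L)) next
    alleles <- sort(unique(c(gA, gB)))
    if (length(alleles) < 2L) next
    for (al in alleles) {
      p_i <- c(mean(gA == al), mean(gB == al))
      h_i <- c(mean(xor(gA[, 1] == al, gA[, 2] == al)),
               mean(xor(gB[, 1] == al, gB[, 2] == al)))
      comp <- wcComponents(n_i, p_i, h_i)
      num <- num + comp["a"]
      den <- den + sum(comp)
    }
  }
  if (den == 0) return(NA_real_)
  as.numeric(num / den)
}

#' Pairwise Weir-Cockerham Fst and its linearization
#'
#' Multilocus theta (ratio of sums over alleles and loci) for every
#' population pair. `linearizeFst` maps F to F / (1 - F), flooring negative
#' estimates at zero first; F = 1 maps to `Inf` (flagged with a warning).
#'
#' @param gt a [GenotypeTable-class] with >= 2 populations of >= 2
#'   individuals.
#' @return symmetric labelled matrix of theta estimates.
#' @export
pairwiseFst <- function(gt) {
  pops <- sort(unique(populations(gt)))
  sizes <- table(populations(gt))
  if (length(pops) < 2L || any(sizes < 2L))
    stop("need >= 2 populations with >= 2 individuals each")
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_len(length(pops) - 1L)) for (j in (i + 1L):length(pops)) {
    th <- thetaPair(gt, pops[i], pops[j])
    m[i, j] <- m[j, i] <- th
  }
  m
}

#' @rdname pairwiseFst
#' @param F Fst value or matrix.
#' @export
linearizeFst <- function(F) {
  F <- pmax(F, 0)
  if (any(F >= 1, na.rm = TRUE))
    warning("Fst of 1 linearizes to Inf")
  F / (1 - F)
}

## ---- diversity tables -----------------------------------------------------

#' Per-population diversity statistics
#'
#' Computes, per population, the SSR statistics N, I, Ne, He, uHe (per-locus
#' values averaged over loci) and the sequence statistics n, h, pi, Nh.
#'
#' @param gt a [GenotypeTable-class] (or `NULL`).
#' @param haps a [HaplotypeSet-class] (or `NULL`).
#' @return data.frame, one row per population.
#' @export
diversityStats <- function(gt = NULL, haps = NULL) {
  pops <- sort(unique(c(if (!is.null(gt)) populations(gt),
                        if (!is.null(haps)) populations(haps))))
  np <- length(pops)
  out <- data.frame(pop = pops, N = rep(NA_integer_, np),
                    I = rep(NA_real_, np), Ne = rep(NA_real_, np),
                    He = rep(NA_real_, np), uHe = rep(NA_real_, np),
                    n = rep(NA_integer_, np), h = rep(NA_real_, np),
                    pi = rep(NA_real_, np), Nh = rep(NA_integer_, np))
  for (i in seq_along(pops)) {
    p <- pops[i]
    if (!is.null(gt) && any(populations(gt) == p)) {
      sel <- populations(gt) == p
      out$N[i] <- sum(sel)
      L <- dim(gt@alleles)[2]
      vals <- vapply(seq_len(L), function(l) {
        fr <- tryCatch(alleleFrequencies(gt, p, l), error = function(e) NULL)
        if (is.null(fr)) return(c(NA, NA, NA, NA))
        ncop <- 2 * sum(sel & !is.na(gt@alleles[, l, 1]))
        c(shannonIndex(fr), effectiveAlleles(fr),
          expectedHeterozygosity(fr), unbiasedHeterozygosity(fr, ncop))
      }, numeric(4))
      out$I[i] <- mean(vals[1, ], na.rm = TRUE)
      out$Ne[i] <- mean(vals[2, ], na.rm = TRUE)
      out$He[i] <- mean(vals[3, ], na.rm = TRUE)
      out$uHe[i] <- mean(vals[4, ], na.rm = TRUE)
    }
    if (!is.null(haps) && any(populations(haps) == p)) {
      sub <- subsetHaplotypes(haps, populations(haps) == p)
      out$n[i] <- nIndividuals(sub)
      out$Nh[i] <- haplotypeCount(sub)
      out$h[i] <- geneDiversity(sub)
      out$pi[i] <- nucleotideDiversity(sub)
    }
  }
  out
}

#' Pooled species-level diversity
#'
#' All individuals pooled into one population.
#'
#' @param gt,haps as in [diversityStats()].
#' @return one-row data.frame with the same columns.
#' @export
pooledDiversity <- function(gt = NULL, haps = NULL) {
  if (!is.null(gt)) gt <- genotypeTable(gt@ids, rep("ALL", nIndividuals(gt)),
                                        gt@alleles)
  if (!is.null(haps)) haps <- haplotypeSet(haps@seqs,
                                           rep("ALL", nIndividuals(haps)))
  diversityStats(gt, haps)
}

#' Drop populations below a minimum SSR sample size
#'
#' Populations with fewer than `n_min` genotyped individuals are excluded
#' (to avoid underestimating Ne); exclusions are recorded in the
#' `excluded` attribute.
#'
#' @param stats data.frame from [diversityStats()].
#' @param n_min minimum sample size (default 5).
#' @export
filterMinN <- function(stats, n_min = 5L) {
  drop <- !is.na(stats$N) & stats$N < n_min
  out <- stats[!drop, , drop = FALSE]
  attr(out, "excluded") <- stats$pop[drop]
  out
}

#' Project genetic diversity after climate-driven population loss
#'
#' Assumes only populations sitting in cells whose future suitability is at
#' least the lowest presence threshold persist and contribute to the next
#' generation's gene pool; diversity statistics are recomputed on the
#' survivors.
#'
#' @param gt a [GenotypeTable-class] (or `NULL`).
#' @param haps a [HaplotypeSet-class] (or `NULL`).
#' @param pops data.frame `id`, `lon`, `lat`.
#' @param future_suit future-scenario [SuitabilityMap-class].
#' @param lpt persistence threshold (suitability >= lpt persists).
#' @return list with `survivors` (population ids), `suitability` (named
#'   per-population values), `stats` (per-population table on survivors),
#'   `pooled` and `averaged` species-level rows.
#' @export
projectFutureDiversity <- function(gt, haps, pops, future_suit, lpt) {
  rc <- cellFromXY(future_suit, pops$lon, pops$lat)
  suit <- gridValues(future_suit)[rc]
  names(suit) <- pops$id
  survivors <- pops$id[!is.na(suit) & suit >= lpt]
  if (!length(survivors)) {
    return(list(survivors = character(0), suitability = suit,
                stats = diversityStats(NULL, NULL)[0, ],
                pooled = NULL, averaged = NULL,
                note = "no population persists at this threshold"))
  }
  gts <- if (!is.null(gt)) subsetIndividuals(gt, populations(gt) %in%
                                               survivors) else NULL
  hps <- if (!is.null(haps)) subsetHaplotypes(haps, populations(haps) %in%
                                                survivors) else NULL
  st <- diversityStats(gts, hps)
  pooled <- pooledDiversity(gts, hps)
  averaged <- colMeans(st[, c("I", "Ne", "He", "h", "pi")], na.rm = TRUE)
  list(survivors = survivors, suitability = suit, stats = st,
       pooled = pooled, averaged = averaged)
}
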