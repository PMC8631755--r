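# Synthetic landscapes and genotypes with the statistical structure the
# downstream analysis assumes: spatially autocorrelated climate surfaces,
# occurrences from a known logistic suitability, climate-driven ancestral
# clusters emitting SSR genotypes and chloroplast haplotypes, and an
# optional isolation-by-resistance drift component.

#' Parameters of a synthetic landscape-genetics study
#'
#' Defaults emulate the study design the pipeline targets: 19 climate
#' layers, 24 populations of ~9 genotyped individuals, 8 SSR loci, 7
#' chloroplast haplotypes, and climate-driven ancestral clusters.
#'
#' @slot seed integer master seed.
#' @slot extent numeric `(xmin, ymin, xmax, ymax)` in degrees.
#' @slot nCells integer `(rows, cols)`.
#' @slot nVars number of climate layers.
#' @slot autocorrRange Gaussian-field correlation length, in cells.
#' @slot futureShift additive per-variable trend (length `nVars`, recycled).
#' @slot futureNoise sd of small-scale future noise (0 = none).
#' @slot nPops,nIndPerPop population count and individuals per population.
#' @slot kTrue true cluster count.
#' @slot betaTrue `kTrue x (nCovariates + 1)` cluster-by-covariate logit
#'   coefficients (column 1 = intercept).
#' @slot nCovariates number of leading climate layers driving ancestry.
#' @slot qNoiseSd sd of spatial noise added to ancestry logits.
#' @slot nSsrLoci,nAllelesPerLocus SSR panel shape.
#' @slot nHaplotypes number of distinct chloroplast haplotypes.
#' @slot seqLength haplotype alignment length (bp).
#' @slot dirichletConc concentration of cluster allele-frequency draws.
#' @slot ibr logical; add isolation-by-resistance drift to population
#'   allele frequencies.
#' @slot ibrSigma drift magnitude on the frequency logit scale.
#' @exportClass SyntheticScenario
setClass("SyntheticScenario",
  representation(seed = "integer", extent = "numeric", nCells = "integer",
                 nVars = "integer", autocorrRange = "numeric",
                 futureShift = "numeric", futureNoise = "numeric",
                 nPops = "integer", nIndPerPop = "integer",
                 kTrue = "integer", betaTrue = "matrix",
                 nCovariates = "integer", qNoiseSd = "numeric",
                 nSsrLoci = "integer", nAllelesPerLocus = "integer",
                 nHaplotypes = "integer", seqLength = "integer",
                 dirichletConc = "numeric", ibr = "logical",
                 ibrSigma = "numeric"))

setValidity("SyntheticScenario", function(object) {
  if (any(object@nCells < 8L)) return("nCells must both be >= 8")
  if (object@kTrue < 1L) return("kTrue must be >= 1")
  if (object@nPops < 2L) return("nPops must be >= 2")
  if (object@autocorrRange <= 0) return("autocorrRange must be positive")
  if (object@kTrue > object@nHaplotypes)
    return("kTrue may not exceed the number of distinct haplotypes")
  if (!identical(dim(object@betaTrue),
                 c(object@kTrue, object@nCovariates + 1L)))
    return("betaTrue must be kTrue x (nCovariates + 1)")
  if (diff(object@extent[c(1, 3)]) <= 0 || diff(object@extent[c(2, 4)]) <= 0)
    return("extent must have positive width and height")
  TRUE
})

#' Default cluster-by-covariate coefficients
#'
#' Deterministic logit coefficients spreading `K` clusters along the leading
#' climate gradient (slopes evenly spaced around zero) with an alternating
#' secondary preference, so clusters occupy distinct climatic bands.
#'
#' @param K cluster count.
#' @param m covariate count.
#' @param scale slope magnitude (logit units per sd of covariate).
#' @export
defaultBetaTrue <- function(K, m, scale = 4) {
  b <- matrix(0, K, m + 1L)
  if (K > 1L) {
    b[, 2] <- scale * (seq_len(K) - (K + 1) / 2)
    if (m >= 2L) b[, 3] <- (scale / 2) * rep_len(c(-1, 1), K)
  }
  b
}

#' @rdname defaultBetaTrue
#' @param seed master seed; every generator in this module is a pure
#'   function of it.
#' @param extent,nCells,nVars,autocorrRange,futureShift,futureNoise,nPops,nIndPerPop,kTrue,betaTrue,nCovariates,qNoiseSd,nSsrLoci,nAllelesPerLocus,nHaplotypes,seqLength,dirichletConc,ibr,ibrSigma
#'   see [SyntheticScenario-class].
#' @return a validated [SyntheticScenario-class].
#' @export
syntheticScenario <- function(seed = 1L,
                              extent = c(100, 25, 110, 35),
                              nCells = c(60L, 60L),
                              nVars = 19L,
                              autocorrRange = 10,
                              futureShift = 0.8,
                              futureNoise = 0.1,
                              nPops = 24L,
                              nIndPerPop = 9L,
                              kTrue = 3L,
                              nCovariates = 3L,
                              betaTrue = defaultBetaTrue(kTrue, nCovariates),
                              qNoiseSd = 0.5,
                              nSsrLoci = 8L,
                              nAllelesPerLocus = 6L,
                              nHaplotypes = 7L,
                              seqLength = 1000L,
                              dirichletConc = 0.5,
                              ibr = FALSE,
                              ibrSigma = 1.5) {
  new("SyntheticScenario", seed = as.integer(seed), extent = extent,
      nCells = as.integer(nCells), nVars = as.integer(nVars),
      autocorrRange = autocorrRange,
      futureShift = rep_len(futureShift, nVars), futureNoise = futureNoise,
      nPops = as.integer(nPops), nIndPerPop = as.integer(nIndPerPop),
      kTrue = as.integer(kTrue), betaTrue = betaTrue,
      nCovariates = as.integer(nCovariates), qNoiseSd = qNoiseSd,
      nSsrLoci = as.integer(nSsrLoci),
      nAllelesPerLocus = as.integer(nAllelesPerLocus),
      nHaplotypes = as.integer(nHaplotypes), seqLength = as.integer(seqLength),
      dirichletConc = dirichletConc, ibr = ibr, ibrSigma = ibrSigma)
}

setMethod("show", "SyntheticScenario", function(object) {
  cat(sprintf(paste0("SyntheticScenario: %dx%d grid, %d layers, %d pops x %d",
                     " ind, K=%d, %d SSR loci, %d haplotypes (seed %d)\n"),
              object@nCells[1], object@nCells[2], object@nVars, object@nPops,
              object@nIndPerPop, object@kTrue, object@nSsrLoci,
              object@nHaplotypes, object@seed))
})

## ---- Gaussian random fields ----------------------------------------------

# Stationary Gaussian random field by FFT spectral synthesis: white noise
# filtered with a Gaussian spectral envelope whose width is 1/range, then
# standardized to zero mean / unit sd.
gaussianRandomField <- function(nr, nc, range) {
  if (range <= 0) stop("autocorrelation range must be positive")
  wr <- 2 * pi * (seq_len(nr) - 1) / nr
  wc <- 2 * pi * (seq_len(nc) - 1) / nc
  wr <- pmin(wr, 2 * pi - wr)   # fold to [-pi, pi]
  wc <- pmin(wc, 2 * pi - wc)
  spec <- exp(-(range^2 / 4) * (outer(wr^2, wc^2, `+`)))
  noise <- matrix(rnorm(nr * nc), nr, nc)
  f <- Re(fft(fft(noise) * sqrt(spec), inverse = TRUE)) / (nr * nc)
  (f - mean(f)) / sd(f)
}

#' Generate current and future climate stacks
#'
#' Each layer is a smoothed Gaussian random field (FFT spectral synthesis,
#' exact stationarity) standardized to zero mean and unit variance; the
#' future stack adds the per-variable `futureShift` trend plus small-scale
#' Gaussian noise of sd `futureNoise`. Pure function of `scenario@seed`.
#'
#' @param scenario a [SyntheticScenario-class].
#' @return list with elements `current` and `future`, both
#'   [RasterStack-class] objects sharing geotransform and mask.
#' @export
generateClimateStack <- function(scenario) {
  validObject(scenario)
  nr <- scenario@nCells[1]; nc <- scenario@nCells[2]
  cellsize <- (scenario@extent[3] - scenario@extent[1]) / nc
  withSeed(scenario@seed, {
    cur <- lapply(seq_len(scenario@nVars), function(i)
      gaussianRandomField(nr, nc, scenario@autocorrRange))
    fut <- lapply(seq_len(scenario@nVars), function(i) {
      noise <- if (scenario@futureNoise > 0)
        scenario@futureNoise * gaussianRandomField(nr, nc,
                                                   scenario@autocorrRange / 2)
      else 0
      cur[[i]] + scenario@futureShift[i] + noise
    })
    names(cur) <- names(fut) <- sprintf("bio%02d", seq_len(scenario@nVars))
    list(current = rasterStack(cur, scenario@extent[1], scenario@extent[2],
                               cellsize),
         future = rasterStack(fut, scenario@extent[1], scenario@extent[2],
                              cellsize))
  })
}

# Evaluate the scenario's seed-scoped RNG without disturbing the caller's.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## ---- occurrences ----------------------------------------------------------

#' True logistic suitability of a stack
#'
#' @param stack a [RasterStack-class].
#' @param trueBeta coefficients, length `nLayers + 1` (intercept first).
#' @return a [SuitabilityMap-class] with scenario label `"true"`.
#' @export
trueSuitability <- function(stack, trueBeta) {
  if (length(trueBeta) != nLayers(stack) + 1L)
    stop("trueBeta must have length nLayers + 1 (intercept first)")
  v <- stackValues(stack)
  eta <- drop(cbind(1, v) %*% trueBeta)
  g <- stack@layers[[1]]
  g[!is.na(g)] <- plogis(eta)
  suitabilityMap(g, "true", stack@xmin, stack@ymin, stack@cellsize)
}

#' Sample occurrence points from a known suitability function
#'
#' Cells are drawn without replacement with probability proportional to
#' `plogis(trueBeta . x_cell)`; points sit at cell centres. The true
#' suitability surface is attached for recovery tests.
#'
#' @param stack a [RasterStack-class].
#' @param trueBeta logistic coefficients (intercept first).
#' @param n requested number of points.
#' @param seed integer seed.
#' @return data.frame with columns `lon`, `lat`; attributes
#'   `true_suitability` ([SuitabilityMap-class]) and `provenance`.
#' @export
generateOccurrences <- function(stack, trueBeta, n, seed = 1L) {
  suit <- trueSuitability(stack, trueBeta)
  p <- gridValues(suit)
  keep <- which(!is.na(p) & p > 1e-12)
  if (length(keep) < n) {
    warning("only ", length(keep),
            " cells carry presence mass; returning fewer points")
    n <- length(keep)
  }
  idx <- withSeed(seed, {
    if (n == 0L) integer(0)
    else keep[sample.int(length(keep), n, prob = p[keep])]
  })
  d <- gridDim(stack)
  cells <- cbind(row = ((idx - 1L) %% d[1]) + 1L,
                 col = ((idx - 1L) %/% d[1]) + 1L)
  xy <- xyFromCell(stack, cells)
  occ <- data.frame(lon = xy[, "lon"], lat = xy[, "lat"])
  attr(occ, "true_suitability") <- suit
  attr(occ, "provenance") <- "synthetic"
  occ
}

## ---- populations, genotypes, haplotypes -----------------------------------

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

softmaxRows <- function(m) {
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}

#' Generate populations, SSR genotypes, haplotypes and true ancestry
#'
#' Populations are placed on distinct unmasked cells. Individual ancestry is
#' `Q_true = softmax(betaTrue . climate + spatial noise)` using the leading
#' `nCovariates` standardized layers at the population cell; each gene copy
#' picks a cluster from `Q_true` and an allele from that cluster's
#' Dirichlet-drawn frequencies, and each individual draws one chloroplast
#' haplotype the same way. Haplotype `h`'s sequence is a fixed base sequence
#' with one diagnostic substitution, so \eqn{\pi} and gene diversity are
#' hand-computable. With `scenario@ibr`, population allele frequencies
#' additionally drift with covariance decaying in least-cost resistance
#' distance, producing isolation by resistance.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param stack the current-climate [RasterStack-class] for the scenario.
#' @param ibr_suitability optional [SuitabilityMap-class] whose inversion
#'   defines the resistance driving the drift covariance (default: a
#'   logistic transform of the first, standardized layer).
#' @return list with `pops` (data.frame id, lon, lat), `genotypes`
#'   ([GenotypeTable-class]), `haplotypes` ([HaplotypeSet-class]), `Q_true`
#'   (individuals x kTrue), plus `covariates` (per-individual matrix) and
#'   `cluster_freqs`.
#' @export
generatePopulationsAndGenotypes <- function(scenario, stack,
                                            ibr_suitability = NULL) {
  validObject(scenario)
  K <- scenario@kTrue
  nP <- scenario@nPops; nI <- scenario@nIndPerPop
  L <- scenario@nSsrLoci; A <- scenario@nAllelesPerLocus
  m <- scenario@nCovariates
  withSeed(scenario@seed + 1L, {
    v <- stackValues(stack)
    cells <- attr(v, "cells")
    pick <- sample.int(nrow(v), nP)
    xy <- xyFromCell(stack, cells[pick, , drop = FALSE])
    pops <- data.frame(id = sprintf("P%02d", seq_len(nP)),
                       lon = xy[, "lon"], lat = xy[, "lat"])
    # standardized covariates at population cells
    X <- scale(v[, seq_len(m), drop = FALSE])[pick, , drop = FALSE]
    ind_pop <- rep(seq_len(nP), each = nI)
    Xi <- X[ind_pop, , drop = FALSE]
    eta <- cbind(1, Xi) %*% t(scenario@betaTrue)
    if (scenario@qNoiseSd > 0)
      eta <- eta + matrix(rnorm(length(eta), sd = scenario@qNoiseSd),
                          nrow(eta))
    Q <- if (K == 1L) matrix(1, nrow(eta), 1L) else softmaxRows(eta)

    # cluster allele and haplotype frequencies
    f <- array(NA_real_, c(K, L, A))
    for (k in seq_len(K)) for (l in seq_len(L))
      f[k, l, ] <- rdirichlet1(rep(scenario@dirichletConc, A))
    g <- t(vapply(seq_len(K), function(k)
      rdirichlet1(rep(1, scenario@nHaplotypes)),
      numeric(scenario@nHaplotypes)))

    n <- nP * nI
    allele_sizes <- 150L + 2L * seq_len(A)
    al <- array(NA_integer_, c(n, L, 2),
                dimnames = list(NULL, sprintf("SSR%02d", seq_len(L)), NULL))

    if (scenario@ibr) {
      # population-level drift correlated through landscape resistance
      suitMap <- ibr_suitability
      if (is.null(suitMap)) {
        suit1 <- plogis(scale(v[, 1])[, 1])
        gmat <- stack@layers[[1]]
        gmat[!is.na(gmat)] <- suit1
        suitMap <- suitabilityMap(gmat, "true", stack@xmin, stack@ymin,
                                  stack@cellsize)
      }
      fric <- frictionFromSuitability(suitMap)
      D <- resistanceMatrix(pops, fric)
      phi <- stats::median(D[upper.tri(D)])
      Sig <- scenario@ibrSigma^2 * exp(-D / phi)
      cf <- chol(Sig + diag(1e-8, nP))
      Qbar <- rowsum(Q, ind_pop) / nI
      p_pop <- array(NA_real_, c(nP, L, A))
      for (l in seq_len(L)) {
        base <- Qbar %*% f[, l, ]               # nP x A mixture frequencies
        eta_d <- t(cf) %*% matrix(rnorm(nP * A), nP, A)
        lp <- log(pmax(base, 1e-12)) + eta_d
        p_pop[, l, ] <- softmaxRows(lp)
      }
      for (l in seq_len(L)) {
        pr <- p_pop[ind_pop, l, ]
        al[, l, 1] <- allele_sizes[sampleRowCat(pr)]
        al[, l, 2] <- allele_sizes[sampleRowCat(pr)]
      }
    } else {
      for (l in seq_len(L)) for (copy in 1:2) {
        z <- sampleRowCat(Q)
        fl <- matrix(f[, l, ], nrow = K)
        al[, l, copy] <- allele_sizes[sampleRowCat(fl[z, , drop = FALSE])]
      }
    }

    # chloroplast haplotype per individual
    zh <- sampleRowCat(Q)
    hap <- sampleRowCat(g[zh, , drop = FALSE])
    # guarantee every requested haplotype is observed
    missing_h <- setdiff(seq_len(scenario@nHaplotypes), unique(hap))
    if (length(missing_h))
      hap[sample.int(n, length(missing_h))] <- missing_h
    seqs <- haplotypeReferenceSequences(scenario)[hap]
    ids <- paste0(pops$id[ind_pop], "_", sequence(rep(nI, nP)))
    names(seqs) <- ids
    haps <- haplotypeSet(seqs, pops$id[ind_pop])

    coords <- cbind(lon = pops$lon[ind_pop], lat = pops$lat[ind_pop])
    gt <- genotypeTable(ids, pops$id[ind_pop], al, coords)
    list(pops = pops, genotypes = gt, haplotypes = haps, Q_true = Q,
         covariates = Xi, cluster_freqs = list(ssr = f, hap = g))
  })
}

# one categorical draw per row of a probability matrix
sampleRowCat <- function(pr) {
  u <- runif(nrow(pr))
  cum <- pr %*% upper.tri(diag(ncol(pr)), diag = TRUE)
  as.integer(rowSums(u > cum) + 1L)
}

#' Reference sequence of each synthetic haplotype
#'
#' Haplotype `h` is the fixed 4-periodic base sequence with one diagnostic
#' substitution at position `10 * h`.
#'
#' @param scenario a [SyntheticScenario-class].
#' @return character vector of `nHaplotypes` distinct sequences.
#' @export
haplotypeReferenceSequences <- function(scenario) {
  base <- strsplit(paste(rep_len(c("A", "C", "G", "T"),
                                 scenario@seqLength), collapse = ""),
                   "")[[1]]
  vapply(seq_len(scenario@nHaplotypes), function(h) {
    s <- base
    pos <- 10L * h
    s[pos] <- setdiff(c("A", "C", "G", "T"), s[pos])[1]
    paste(s, collapse = "")
  }, character(1))
}
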