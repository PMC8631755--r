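# Spatial Bayesian admixture with climate covariates. The model is a
# logistic-normal ancestry regression: for individual i and cluster
# k < K, z_ik = beta_k . x_i + gamma_k . s_i + eps_ik with
# eps ~ N(0, sigma^2) and z_iK = 0; ancestry Q_i = softmax(z_i). Gene
# copies are assigned to clusters by data augmentation (Gibbs, probability
# proportional to Q_ik f_kla), cluster allele/haplotype frequencies are
# updated by Dirichlet conjugacy, the regression coefficients by their
# normal conjugate update, sigma^2 by inverse-gamma conjugacy, and the
# latent z by an adaptive random-walk Metropolis step. Cluster number is
# chosen by refitting over a ladder of K and minimizing DIC.

#' Fitted climate-covariate admixture model
#'
#' @slot Q posterior-mean ancestry (individuals x K; rows sum to 1).
#' @slot Q_reg regression-component ancestry softmax(W beta-hat) (no
#'   individual noise), what [projectAdmixture()] reproduces under
#'   unchanged covariates.
#' @slot beta posterior-mean coefficients, (K - 1) x p over the design
#'   `(intercept, covariates, lon, lat)`; the reference cluster K is fixed
#'   at zero.
#' @slot freqs list of posterior-mean per-cluster category frequencies, one
#'   `K x n_alleles` matrix per locus.
#' @slot sigma posterior-mean logistic-normal noise sd.
#' @slot trace data.frame `sweep`, `deviance` (thinned, post- and
#'   pre-burn-in).
#' @slot DIC deviance information criterion (pD form).
#' @slot K,sweeps,burn_in,seed run bookkeeping.
#' @slot covariates standardized covariate matrix used (with centre/scale
#'   attributes), `coords` the standardized lon/lat.
#' @exportClass AdmixtureFit
setClass("AdmixtureFit",
  representation(Q = "matrix", Q_reg = "matrix", beta = "matrix",
                 freqs = "list", sigma = "numeric", trace = "data.frame",
                 DIC = "numeric", K = "integer", sweeps = "integer",
                 burn_in = "integer", seed = "integer",
                 covariates = "matrix", coords = "matrix",
                 scaling = "list"))

setValidity("AdmixtureFit", function(object) {
  if (nrow(object@Q) &&
      max(abs(rowSums(object@Q) - 1)) > 1e-9)
    return("rows of Q must sum to 1")
  if (!is.finite(object@DIC)) return("DIC must be finite")
  TRUE
})

setMethod("show", "AdmixtureFit", function(object) {
  cat(sprintf(
    "AdmixtureFit: %d individuals, K = %d, %d sweeps (burn-in %d), DIC %.1f\n",
    nrow(object@Q), object@K, object@sweeps, object@burn_in, object@DIC))
})

#' Posterior-mean ancestry matrix
#' @param x an [AdmixtureFit-class].
#' @export
setGeneric("ancestryQ", function(x) standardGeneric("ancestryQ"))
setMethod("ancestryQ", "AdmixtureFit", function(x) x@Q)
#' @rdname ancestryQ
#' @export
setGeneric("dic", function(x) standardGeneric("dic"))
setMethod("dic", "AdmixtureFit", function(x) x@DIC)
#' @rdname ancestryQ
#' @export
setGeneric("devianceTrace", function(x) standardGeneric("devianceTrace"))
setMethod("devianceTrace", "AdmixtureFit", function(x) x@trace)

# Convert genetic input into a list of categorical "loci": per locus an
# n x copies integer matrix of category codes (NA = missing) plus the
# category count.
asCategorical <- function(data) {
  if (is(data, "GenotypeTable")) {
    L <- dim(data@alleles)[2]
    lapply(seq_len(L), function(l) {
      codes <- sort(unique(na.omit(c(data@alleles[, l, ]))))
      m <- cbind(match(data@alleles[, l, 1], codes),
                 match(data@alleles[, l, 2], codes))
      list(calls = m, n_cat = length(codes), codes = codes)
    })
  } else if (is(data, "HaplotypeSet")) {
    codes <- unique(haplotypeIds(data))
    list(list(calls = matrix(match(haplotypeIds(data), codes), ncol = 1),
              n_cat = length(codes), codes = codes))
  } else stop("data must be a GenotypeTable or HaplotypeSet")
}

#' Select climate covariates by among-population variance
#'
#' Standardizes each layer over unmasked cells, reads it at the population
#' coordinates, and returns the names of the `m` layers with the highest
#' among-population variance (the screening used to pick e.g. annual mean
#' temperature, driest-month precipitation and annual precipitation).
#'
#' @param stack a [RasterStack-class].
#' @param pops data.frame `id`, `lon`, `lat`.
#' @param m number of covariates (default 3).
#' @return character vector of layer names.
#' @export
selectClimateCovariates <- function(stack, pops, m = 3L) {
  v <- stackValues(stack)
  mu <- colMeans(v); sdv <- apply(v, 2L, sd)
  at <- extractValues(stack, pops$lon, pops$lat)
  z <- sweep(sweep(at, 2L, mu), 2L, pmax(sdv, 1e-12), "/")
  vr <- apply(z, 2L, var)
  names(sort(vr, decreasing = TRUE))[seq_len(min(m, length(vr)))]
}

logSoftmaxRows <- function(z) z - log(rowSums(exp(z - apply(z, 1, max)))) -
  apply(z, 1, max)

modelDeviance <- function(loci, Q, freqs) {
  ll <- 0
  for (l in seq_along(loci)) {
    f <- freqs[[l]]                       # K x n_cat
    for (copy in seq_len(ncol(loci[[l]]$calls))) {
      a <- loci[[l]]$calls[, copy]
      ok <- !is.na(a)
      p <- rowSums(Q[ok, , drop = FALSE] *
                     t(f)[a[ok], , drop = FALSE])
      ll <- ll + sum(log(pmax(p, 1e-300)))
    }
  }
  -2 * ll
}

#' Fit the climate-covariate admixture model by MCMC
#'
#' @param data a [GenotypeTable-class] (diploid SSR) or
#'   [HaplotypeSet-class] (haploid chloroplast haplotypes).
#' @param coords n x 2 matrix of lon/lat (defaults to the coordinates
#'   stored on a genotype table).
#' @param covariates n x m numeric matrix of climate covariates per
#'   individual (standardized internally; the scaling is stored for
#'   projection).
#' @param K_max cluster bound K.
#' @param sweeps,burn_in MCMC sweeps and burn-in (headline runs use
#'   20000/2000; reduced sizes are adequate for the synthetic fixtures).
#' @param thin trace thinning interval.
#' @param seed integer seed; fits are deterministic given it.
#' @return an [AdmixtureFit-class].
#' @export
fitAdmixture <- function(data, coords = NULL, covariates, K_max,
                         sweeps = 20000L, burn_in = 2000L, thin = 10L,
                         seed = 1L) {
  if (is.null(coords)) {
    if (is(data, "GenotypeTable") && nrow(data@coords)) coords <- data@coords
    else stop("coords are required")
  }
  covariates <- as.matrix(covariates)
  if (any(!is.finite(covariates))) stop("non-finite covariates")
  if (K_max < 1L) stop("K_max must be >= 1")
  loci <- asCategorical(data)
  n <- nrow(loci[[1]]$calls)
  X <- scale(covariates)
  S <- scale(coords)
  scaling <- list(x_center = attr(X, "scaled:center"),
                  x_scale = attr(X, "scaled:scale"),
                  s_center = attr(S, "scaled:center"),
                  s_scale = attr(S, "scaled:scale"))
  W <- cbind(intercept = 1, X, lon = S[, 1], lat = S[, 2])
  p <- ncol(W)
  K <- as.integer(K_max)

  withSeed(seed, {
    # initial state
    freqs <- lapply(loci, function(l)
      matrix(1 / l$n_cat, K, l$n_cat))
    z <- matrix(rnorm(n * max(K - 1L, 1L), sd = 0.5), n)
    if (K == 1L) z <- matrix(0, n, 0)
    theta <- matrix(0, max(K - 1L, 0L), p)
    sigma2 <- 1
    step <- 0.5
    acc <- 0; tries <- 0
    prior_prec <- 1 / 100      # N(0, 100) coefficient prior
    WtW <- crossprod(W)

    Qfun <- function(z) {
      if (K == 1L) return(matrix(1, n, 1))
      softmaxRows(cbind(z, 0))
    }
    Q <- Qfun(z)

    Qsum <- matrix(0, n, K)
    fsum <- lapply(loci, function(l) matrix(0, K, l$n_cat))
    thetasum <- matrix(0, max(K - 1L, 0L), p)
    sig_sum <- 0; kept <- 0L
    dev_trace <- numeric(0); dev_sweep <- integer(0)
    dev_kept <- numeric(0)

    for (sw in seq_len(sweeps)) {
      # -- assignment counts and frequency updates
      m_ik <- matrix(0, n, K)
      for (l in seq_along(loci)) {
        f <- freqs[[l]]
        counts <- matrix(0, K, loci[[l]]$n_cat)
        for (copy in seq_len(ncol(loci[[l]]$calls))) {
          a <- loci[[l]]$calls[, copy]
          ok <- which(!is.na(a))
          wgt <- Q[ok, , drop = FALSE] * t(f)[a[ok], , drop = FALSE]
          wgt <- wgt / pmax(rowSums(wgt), 1e-300)
          u <- sampleRowCat(wgt)
          m_ik[cbind(ok, u)] <- m_ik[cbind(ok, u)] + 1
          counts <- counts + matrix(tabulate((a[ok] - 1L) * K + u,
                                             K * loci[[l]]$n_cat),
                                    K, loci[[l]]$n_cat)
        }
        for (k in seq_len(K))
          freqs[[l]][k, ] <- rdirichlet1(1 + counts[k, ])
      }

      if (K > 1L) {
        # -- latent logits: random-walk Metropolis, independent across i
        mu <- W %*% t(theta)
        zprop <- z + matrix(rnorm(n * (K - 1L), sd = step), n)
        logpost <- function(zz) {
          lq <- logSoftmaxRows(cbind(zz, 0))
          rowSums(m_ik * lq) - rowSums((zz - mu)^2) / (2 * sigma2)
        }
        lr <- logpost(zprop) - logpost(z)
        accept <- log(runif(n)) < lr
        z[accept, ] <- zprop[accept, ]
        acc <- acc + sum(accept); tries <- tries + n
        if (sw <= burn_in && sw %% 50L == 0L) {
          rate <- acc / tries
          step <- step * exp(rate - 0.25)   # adapt toward 0.25 acceptance
          acc <- 0; tries <- 0
        }
        Q <- Qfun(z)

        # -- regression coefficients (normal conjugate per cluster)
        prec <- WtW / sigma2 + diag(prior_prec, p)
        ch <- chol(prec)
        for (k in seq_len(K - 1L)) {
          mean_k <- backsolve(ch, forwardsolve(t(ch), crossprod(W, z[, k]) /
                                                 sigma2))
          theta[k, ] <- mean_k + backsolve(ch, rnorm(p))
        }

        # -- noise variance (inverse-gamma conjugate)
        resid <- z - W %*% t(theta)
        sh <- 2 + n * (K - 1L) / 2
        rt <- 1 + sum(resid^2) / 2
        sigma2 <- rt / rgamma(1, shape = sh)
      }

      if (sw %% thin == 0L) {
        dev <- modelDeviance(loci, Q, freqs)
        if (!is.finite(dev)) stop("chain divergence: deviance is not finite")
        dev_trace <- c(dev_trace, dev); dev_sweep <- c(dev_sweep, sw)
        if (sw > burn_in) {
          kept <- kept + 1L
          Qsum <- Qsum + Q
          for (l in seq_along(loci)) fsum[[l]] <- fsum[[l]] + freqs[[l]]
          if (K > 1L) thetasum <- thetasum + theta
          sig_sum <- sig_sum + sqrt(sigma2)
          dev_kept <- c(dev_kept, dev)
        }
      }
    }

    Qbar <- Qsum / kept
    Qbar <- Qbar / rowSums(Qbar)
    fbar <- lapply(fsum, function(f) f / kept)
    fbar <- lapply(fbar, function(f) f / rowSums(f))
    thetabar <- if (K > 1L) thetasum / kept else matrix(0, 0, p)
    dbar <- mean(dev_kept)
    dhat <- modelDeviance(loci, Qbar, fbar)
    pD <- dbar - dhat
    DIC <- dbar + pD
    Qreg <- if (K == 1L) matrix(1, n, 1) else
      softmaxRows(cbind(W %*% t(thetabar), 0))
    colnames(thetabar) <- colnames(W)
    new("AdmixtureFit", Q = Qbar, Q_reg = Qreg, beta = thetabar,
        freqs = fbar, sigma = sig_sum / max(kept, 1L),
        trace = data.frame(sweep = dev_sweep, deviance = dev_trace),
        DIC = DIC, K = K, sweeps = as.integer(sweeps),
        burn_in = as.integer(burn_in), seed = as.integer(seed),
        covariates = cbind(X), coords = cbind(S), scaling = scaling)
  })
}

#' Pick the run minimizing DIC
#'
#' @param fits list of [AdmixtureFit-class] objects (e.g. several runs over
#'   a ladder of K).
#' @return the fit with lowest DIC; attribute `dic_table` holds the full
#'   K/DIC table.
#' @export
selectRuns <- function(fits) {
  if (!length(fits)) stop("no fits to select from")
  tab <- data.frame(K = vapply(fits, function(f) f@K, 1L),
                    seed = vapply(fits, function(f) f@seed, 1L),
                    DIC = vapply(fits, dic, 1))
  best <- fits[[which.min(tab$DIC)]]
  attr(best, "dic_table") <- tab
  best
}

standardizeNew <- function(fit, covariates, coords) {
  X <- sweep(sweep(as.matrix(covariates), 2L, fit@scaling$x_center),
             2L, fit@scaling$x_scale, "/")
  S <- sweep(sweep(as.matrix(coords), 2L, fit@scaling$s_center),
             2L, fit@scaling$s_scale, "/")
  cbind(1, X, S)
}

#' Project ancestry under new (future) climate covariates
#'
#' `Q'_ik = softmax(beta-hat . x'_i + gamma-hat . s_i)` with the posterior
#' means; the genetic data are unchanged. With the fitting covariates this
#' reproduces the fit's regression-component ancestry exactly.
#'
#' @param fit an [AdmixtureFit-class].
#' @param covariates future covariate matrix (same columns/order and
#'   original units as passed to [fitAdmixture()]).
#' @param coords lon/lat matrix (defaults to the fit's, back-transformed).
#' @return projected ancestry matrix (individuals x K).
#' @export
projectAdmixture <- function(fit, covariates, coords = NULL) {
  if (ncol(as.matrix(covariates)) != length(fit@scaling$x_center))
    stop("covariate mismatch: expected ",
         length(fit@scaling$x_center), " columns")
  if (is.null(coords))
    coords <- sweep(sweep(fit@coords, 2L, fit@scaling$s_scale, "*"),
                    2L, fit@scaling$s_center, "+")
  W <- standardizeNew(fit, covariates, coords)
  if (fit@K == 1L) return(matrix(1, nrow(W), 1))
  softmaxRows(cbind(W %*% t(fit@beta), 0))
}

#' Correlation between current and projected ancestry, and turnover
#'
#' `ancestryCorrelation` is the Pearson correlation of the flattened
#' matrices. `turnoverReport` adds per-cluster correlations and flags a
#' cluster lost when its maximum projected ancestry falls below
#' `lost_threshold`.
#'
#' @param Q,Qp current and projected ancestry matrices (same shape,
#'   clusters aligned).
#' @export
ancestryCorrelation <- function(Q, Qp) {
  if (!identical(dim(Q), dim(Qp))) stop("ancestry matrices differ in shape")
  cor(as.vector(Q), as.vector(Qp))
}

#' @rdname ancestryCorrelation
#' @param lost_threshold max-ancestry threshold below which a cluster is
#'   flagged lost (default 0.5).
#' @return `turnoverReport`: list with `overall_r`, `per_cluster_r`,
#'   `lost`, `max_projected`.
#' @export
turnoverReport <- function(Q, Qp, lost_threshold = 0.5) {
  if (!identical(dim(Q), dim(Qp))) stop("ancestry matrices differ in shape")
  per <- vapply(seq_len(ncol(Q)), function(k) {
    if (sd(Q[, k]) == 0 || sd(Qp[, k]) == 0) return(NA_real_)
    cor(Q[, k], Qp[, k])
  }, numeric(1))
  mx <- apply(Qp, 2L, max)
  list(overall_r = ancestryCorrelation(Q, Qp), per_cluster_r = per,
       lost = mx < lost_threshold, max_projected = mx)
}

#' Align cluster labels to a reference ancestry matrix
#'
#' Resolves MCMC label switching: finds the column permutation of `Q`
#' maximizing the summed per-cluster correlation with `ref` (exact search
#' over permutations for K <= 7, greedy assignment above).
#'
#' @param Q ancestry matrix to relabel.
#' @param ref reference ancestry matrix (e.g. the simulation truth), same
#'   shape.
#' @return `Q` with columns permuted; attribute `perm` gives the
#'   permutation used (`ref` column k matches `Q` column `perm[k]`).
#' @export
alignClusters <- function(Q, ref) {
  K <- ncol(Q)
  if (!identical(dim(Q), dim(ref))) stop("shape mismatch")
  score <- matrix(0, K, K)    # score[i, j] = cor(ref_i, Q_j)
  for (i in seq_len(K)) for (j in seq_len(K))
    score[i, j] <- if (sd(ref[, i]) == 0 || sd(Q[, j]) == 0) 0 else
      cor(ref[, i], Q[, j])
  if (K <= 7L) {
    perms <- permutationsOf(K)
    vals <- apply(perms, 1L, function(pp) sum(score[cbind(seq_len(K), pp)]))
    perm <- perms[which.max(vals), ]
  } else {
    perm <- integer(K); used <- logical(K)
    for (i in order(-apply(score, 1L, max))) {
      j <- which.max(ifelse(used, -Inf, score[i, ]))
      perm[i] <- j; used[j] <- TRUE
    }
  }
  out <- Q[, perm, drop = FALSE]
  attr(out, "perm") <- perm
  out
}

#' Mean per-individual correlation between two ancestry matrices
#'
#' Aligns clusters to `truth` first; rows with zero variance (e.g. K = 1)
#' count as perfectly recovered when both rows are constant and equal.
#'
#' @param Q estimated ancestry; `truth` reference ancestry.
#' @param truth reference matrix.
#' @export
ancestryRecovery <- function(Q, truth) {
  Qa <- alignClusters(Q, truth)
  per <- vapply(seq_len(nrow(Q)), function(i) {
    a <- truth[i, ]; b <- Qa[i, ]
    if (sd(a) == 0 || sd(b) == 0)
      return(as.numeric(max(abs(a - b)) < 0.05))
    cor(a, b)
  }, numeric(1))
  mean(per)
}

#' Render ancestry cluster maps over covariate rasters
#'
#' Evaluates the regression component per unmasked cell using the named
#' covariate layers and the cell-centre coordinates, returning per-cluster
#' ancestry grids and the argmax categorical map.
#'
#' @param fit an [AdmixtureFit-class].
#' @param stack a [RasterStack-class] supplying all covariate layers (named
#'   as the covariates passed to [fitAdmixture()]).
#' @param covariate_names layer names in the fit's covariate order.
#' @return list with `ancestry` ([RasterStack-class], one layer per
#'   cluster) and `category` (integer matrix of argmax clusters).
#' @export
renderClusterMap <- function(fit, stack, covariate_names) {
  miss <- setdiff(covariate_names, layerNames(stack))
  if (length(miss)) stop("missing covariate layer(s): ",
                         paste(miss, collapse = ", "))
  v <- stackValues(stack)[, covariate_names, drop = FALSE]
  xy <- xyFromCell(stack, attr(stackValues(stack), "cells"))
  W <- standardizeNew(fit, v, xy)
  Qc <- if (fit@K == 1L) matrix(1, nrow(W), 1) else
    softmaxRows(cbind(W %*% t(fit@beta), 0))
  layers <- lapply(seq_len(fit@K), function(k) {
    g <- stack@layers[[1]]
    g[!is.na(g)] <- Qc[, k]
    g
  })
  names(layers) <- paste0("cluster", seq_len(fit@K))
  cat_g <- stack@layers[[1]]
  cat_g[!is.na(cat_g)] <- max.col(Qc)
  list(ancestry = rasterStack(layers, stack@xmin, stack@ymin,
                              stack@cellsize),
       category = cat_g)
}

#' Geweke-style stationarity z-score of a trace
#'
#' Compares the means of the first `frac1` and last `frac2` segments using
#' batch-means standard errors; |z| < 3 indicates no trend worth worrying
#' about at fixture scale.
#'
#' @param x numeric trace (post-burn-in).
#' @param frac1,frac2 leading and trailing fractions compared.
#' @export
gewekeZ <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(max(2L, floor(frac1 * n)))]
  b <- x[seq.int(n - max(2L, floor(frac2 * n)) + 1L, n)]
  bmVar <- function(v) {
    nb <- max(2L, floor(sqrt(length(v))))
    bs <- floor(length(v) / nb)
    mns <- vapply(seq_len(nb), function(i)
      mean(v[((i - 1) * bs + 1):(i * bs)]), numeric(1))
    var(mns) / nb
  }
  (mean(a) - mean(b)) / sqrt(bmVar(a) + bmVar(b))
}
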