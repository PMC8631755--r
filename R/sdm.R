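# Ensemble species distribution modelling: variable pruning, occurrence
# rarefaction, pseudo-absence sampling, a multi-algorithm ensemble gated on
# held-out TSS and AUC, lowest-presence-threshold binarization and
# range-shift accounting.

#' Drop highly correlated climate layers
#'
#' Greedy elimination on the Pearson correlation matrix over unmasked cells:
#' while any pair exceeds `r_max` in absolute value, the layer with the
#' highest mean absolute correlation among offending pairs is removed (ties
#' broken by layer-name order).
#'
#' @param stack a [RasterStack-class].
#' @param r_max correlation cut (default 0.75).
#' @return the pruned [RasterStack-class]; attribute `retained` lists the
#'   surviving layer names.
#' @export
pruneCorrelatedVariables <- function(stack, r_max = 0.75) {
  if (nLayers(stack) < 2L) {
    warning("single layer: nothing to prune")
    attr(stack, "retained") <- layerNames(stack)
    return(stack)
  }
  v <- stackValues(stack)
  keep <- colnames(v)
  repeat {
    r <- abs(cor(v[, keep, drop = FALSE]))
    diag(r) <- 0
    if (all(r <= r_max, na.rm = TRUE) || length(keep) == 1L) break
    offending <- r > r_max
    score <- rowSums(r * offending)
    m <- rowSums(offending)
    cand <- which(m > 0)
    worst <- cand[order(-score[cand] / m[cand], keep[cand])][1]
    keep <- keep[-match(names(worst), keep)]
  }
  out <- rasterStack(stack@layers[keep], stack@xmin, stack@ymin,
                     stack@cellsize)
  attr(out, "retained") <- keep
  out
}

#' Climatic-heterogeneity surface
#'
#' Standardizes the layers, takes PC1 scores per cell, and returns the
#' moving-window (default 5 x 5) standard deviation of PC1 as a per-cell
#' heterogeneity estimate, used to set the rarefaction distance by zone.
#'
#' @param stack a [RasterStack-class].
#' @param window odd window edge length in cells.
#' @return numeric matrix, same shape as the grid.
#' @export
heterogeneitySurface <- function(stack, window = 5L) {
  v <- stackValues(stack)
  sds <- apply(v, 2L, sd)
  if (all(sds < 1e-12)) {
    warning("all layers constant: heterogeneity is zero everywhere")
    g <- stack@layers[[1]]; g[!is.na(g)] <- 0
    return(g)
  }
  vs <- scale(v[, sds > 1e-12, drop = FALSE])
  pc1 <- prcomp(vs, center = FALSE, scale. = FALSE)$x[, 1]
  g <- stack@layers[[1]]
  g[!is.na(g)] <- pc1
  d <- dim(g); h <- (window - 1L) %/% 2L
  out <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (is.na(g[i, j])) next
    w <- g[max(1L, i - h):min(d[1], i + h), max(1L, j - h):min(d[2], j + h)]
    w <- w[!is.na(w)]
    out[i, j] <- if (length(w) > 1L) sd(w) else 0
  }
  out
}

#' Spatially rarefy occurrence points
#'
#' Greedy first-come retention in input order: a point is kept iff its
#' great-circle distance to every already-kept point is at least
#' `min_dist_km`. Deterministic.
#'
#' @param points data.frame with `lon`, `lat`.
#' @param min_dist_km minimum pairwise distance, km.
#' @return the retained subset (same columns, original order).
#' @export
rarefyOccurrences <- function(points, min_dist_km) {
  if (min_dist_km <= 0) stop("min_dist_km must be positive")
  n <- nrow(points)
  if (n == 0L) return(points)
  keep <- logical(n); keep[1] <- TRUE
  for (i in seq_len(n)[-1]) {
    kept <- which(keep)
    d <- geosphere::distHaversine(as.matrix(points[i, c("lon", "lat")]),
                                  as.matrix(points[kept, c("lon", "lat")])) /
      1000
    keep[i] <- all(d >= min_dist_km)
  }
  points[keep, , drop = FALSE]
}

#' Sample pseudo-absence points
#'
#' Draws `n_pa` distinct unmasked cells excluding presence cells and an
#' optional exclusion buffer around them, at cell centres.
#'
#' @param stack a [RasterStack-class].
#' @param presences data.frame with `lon`, `lat`.
#' @param n_pa number of pseudo-absences.
#' @param seed integer seed.
#' @param buffer_cells Chebyshev radius (cells) excluded around presences.
#' @return data.frame with `lon`, `lat`.
#' @export
samplePseudoAbsences <- function(stack, presences, n_pa, seed = 1L,
                                 buffer_cells = 0L) {
  stopifnot(n_pa >= 1)
  d <- gridDim(stack)
  msk <- !is.na(stack@layers[[1]])
  rc <- cellFromXY(stack, presences$lon, presences$lat)
  excl <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(nrow(rc))) {
    if (is.na(rc[i, 1])) next
    rows <- max(1L, rc[i, 1] - buffer_cells):min(d[1], rc[i, 1] + buffer_cells)
    cols <- max(1L, rc[i, 2] - buffer_cells):min(d[2], rc[i, 2] + buffer_cells)
    excl[rows, cols] <- TRUE
  }
  eligible <- which(as.vector(msk & !excl))
  if (length(eligible) < n_pa)
    stop("only ", length(eligible), " eligible cells for ", n_pa,
         " pseudo-absences")
  idx <- withSeed(seed, eligible[sample.int(length(eligible), n_pa)])
  cells <- cbind(row = ((idx - 1L) %% d[1]) + 1L,
                 col = ((idx - 1L) %/% d[1]) + 1L)
  xy <- xyFromCell(stack, cells)
  data.frame(lon = xy[, "lon"], lat = xy[, "lat"])
}

#' True skill statistic from a 2 x 2 confusion matrix
#'
#' TSS = sensitivity + specificity - 1.
#'
#' @param tp,fn,tn,fp confusion counts.
#' @return numeric in \[-1, 1\].
#' @export
tss <- function(tp, fn, tn, fp) {
  if (tp + fn == 0 || tn + fp == 0)
    stop("TSS undefined: a confusion-matrix margin is zero")
  tp / (tp + fn) + tn / (tn + fp) - 1
}

# threshold-maximized TSS over candidate cutoffs (the usual presence/absence
# evaluation convention)
maxTss <- function(obs, prob) {
  cuts <- sort(unique(c(0, prob, 1)))
  best <- -1
  for (ct in cuts) {
    pred <- as.integer(prob >= ct)
    tp <- sum(pred == 1 & obs == 1); fn <- sum(pred == 0 & obs == 1)
    tn <- sum(pred == 0 & obs == 0); fp <- sum(pred == 1 & obs == 0)
    if (tp + fn == 0 || tn + fp == 0) next
    best <- max(best, tp / (tp + fn) + tn / (tn + fp) - 1)
  }
  best
}

aucScore <- function(obs, prob) {
  as.numeric(pROC::auc(pROC::roc(obs, prob, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

## ---- per-algorithm fitting ------------------------------------------------

sdmAlgorithms <- function() c("glm", "gam", "rf", "cta", "fda", "ann", "sre")

fitOneSdm <- function(alg, X, y) {
  df <- data.frame(y = y, X)
  vars <- colnames(X)
  switch(alg,
    glm = {
      fit <- suppressWarnings(glm(y ~ ., binomial(), df))
      list(fit = fit, predict = function(nd)
        as.numeric(predict(fit, as.data.frame(nd), type = "response")))
    },
    gam = {
      k <- max(3L, min(6L, floor(nrow(df) / (2 * length(vars))) ))
      form <- stats::as.formula(paste("y ~",
        paste(sprintf("s(%s, k = %d)", vars, k), collapse = " + ")))
      fit <- mgcv::gam(form, family = binomial(), data = df,
                       method = "REML")
      list(fit = fit, predict = function(nd)
        as.numeric(predict(fit, as.data.frame(nd), type = "response")))
    },
    rf = {
      fit <- randomForest::randomForest(x = X, y = factor(y, levels = 0:1),
                                        ntree = 250)
      list(fit = fit, predict = function(nd)
        as.numeric(predict(fit, nd, type = "prob")[, "1"]))
    },
    cta = {
      fit <- rpart::rpart(y ~ ., df, method = "class",
                          control = rpart::rpart.control(cp = 0.005,
                                                         minsplit = 5))
      list(fit = fit, predict = function(nd)
        as.numeric(predict(fit, as.data.frame(nd))[, "1"]))
    },
    fda = {
      fit <- MASS::lda(y ~ ., df)
      list(fit = fit, predict = function(nd)
        as.numeric(predict(fit, as.data.frame(nd))$posterior[, "1"]))
    },
    ann = {
      fit <- nnet::nnet(y ~ ., df, size = 4, decay = 0.01, maxit = 300,
                        trace = FALSE)
      list(fit = fit, predict = function(nd)
        as.numeric(predict(fit, as.data.frame(nd))))
    },
    sre = {
      # surface range envelope: inner quantile box of the presence cloud
      q <- apply(X[y == 1, , drop = FALSE], 2L, quantile,
                 probs = c(0.025, 0.975))
      list(fit = q, predict = function(nd) {
        nd <- as.matrix(nd)
        inside <- rep(TRUE, nrow(nd))
        for (j in seq_len(ncol(nd)))
          inside <- inside & nd[, j] >= q[1, j] & nd[, j] <= q[2, j]
        as.numeric(inside)
      })
    },
    stop("unknown SDM algorithm: ", alg))
}

#' Fit a gated multi-algorithm SDM ensemble
#'
#' Each algorithm x repeat is trained on a fresh stratified 75/25 split;
#' AUC and threshold-maximized TSS are computed on the held-out 25%, and a
#' model is retained iff both exceed `gate`. Degenerate single-class splits
#' are redrawn with the next seed (logged via message).
#'
#' @param presences,absences data.frames with `lon`, `lat`.
#' @param stack predictor [RasterStack-class].
#' @param algorithms subset of `r paste(sdmAlgorithms(), collapse = ", ")`.
#' @param n_repeats repeats per algorithm (default 10).
#' @param split training fraction (default 0.75).
#' @param gate retention threshold on both AUC and TSS (default 0.6).
#' @param seed integer seed.
#' @return list with `models` (retained fit objects with predictors) and
#'   `evaluations` (data.frame algorithm, repeat, auc, tss, retained).
#' @export
fitEnsemble <- function(presences, absences, stack,
                        algorithms = c("glm", "gam", "rf", "cta", "fda"),
                        n_repeats = 10L, split = 0.75, gate = 0.6,
                        seed = 1L) {
  if (nrow(presences) < 10L) stop("need at least 10 presences")
  algorithms <- match.arg(algorithms, sdmAlgorithms(), several.ok = TRUE)
  Xp <- extractValues(stack, presences$lon, presences$lat)
  Xa <- extractValues(stack, absences$lon, absences$lat)
  X <- rbind(Xp, Xa)
  y <- c(rep(1L, nrow(Xp)), rep(0L, nrow(Xa)))
  ok <- complete.cases(X)
  X <- X[ok, , drop = FALSE]; y <- y[ok]

  models <- list(); evals <- NULL
  withSeed(seed, {
    for (rep_i in seq_len(n_repeats)) {
      # stratified split, redrawn if a class is absent from either side
      repeat {
        tr <- c(sample(which(y == 1), floor(split * sum(y == 1))),
                sample(which(y == 0), floor(split * sum(y == 0))))
        te <- setdiff(seq_along(y), tr)
        if (length(unique(y[tr])) == 2L && length(unique(y[te])) == 2L) break
        message("degenerate split; redrawing")
      }
      for (alg in algorithms) {
        model <- fitOneSdm(alg, X[tr, , drop = FALSE], y[tr])
        prob <- model$predict(X[te, , drop = FALSE])
        auc_i <- aucScore(y[te], prob)
        tss_i <- maxTss(y[te], prob)
        retained <- auc_i > gate && tss_i > gate
        evals <- rbind(evals, data.frame(algorithm = alg, rep = rep_i,
                                         auc = auc_i, tss = tss_i,
                                         retained = retained))
        if (retained) {
          model$algorithm <- alg; model$rep <- rep_i; model$tss <- tss_i
          models[[length(models) + 1L]] <- model
        }
      }
    }
  })
  list(models = models, evaluations = evals)
}

#' Ensemble suitability prediction
#'
#' Per-cell mean (optionally TSS-weighted) of the retained models'
#' probabilities over a scenario stack. For multi-GCM futures, average the
#' stacks first with [averageGcmStacks()].
#'
#' @param ensemble result of [fitEnsemble()].
#' @param stack scenario [RasterStack-class] (same layers as used to fit).
#' @param scenario label stored on the output.
#' @param weighted use TSS weights instead of the unweighted mean.
#' @return a [SuitabilityMap-class].
#' @export
ensemblePredict <- function(ensemble, stack, scenario = "current",
                            weighted = FALSE) {
  models <- ensemble$models
  if (!length(models))
    stop("no models were retained by the TSS/AUC gate; cannot predict")
  v <- stackValues(stack)
  preds <- vapply(models, function(m) m$predict(v), numeric(nrow(v)))
  preds <- matrix(preds, nrow = nrow(v))
  w <- if (weighted) vapply(models, `[[`, 1, "tss") else
    rep(1, length(models))
  p <- drop(preds %*% (w / sum(w)))
  g <- stack@layers[[1]]
  g[!is.na(g)] <- pmin(pmax(p, 0), 1)
  suitabilityMap(g, scenario, stack@xmin, stack@ymin, stack@cellsize)
}

#' Lowest presence threshold
#'
#' Minimum predicted suitability over the (training) presence cells, so
#' binarizing at it keeps every training presence.
#'
#' @param suit a [SuitabilityMap-class].
#' @param presences data.frame with `lon`, `lat`.
#' @return numeric threshold.
#' @export
lptThreshold <- function(suit, presences) {
  if (nrow(presences) == 0L) stop("empty presence set")
  rc <- cellFromXY(suit, presences$lon, presences$lat)
  vals <- gridValues(suit)[rc]
  if (all(is.na(vals))) stop("no presence falls on an unmasked cell")
  min(vals, na.rm = TRUE)
}

#' Binarize a suitability map
#'
#' A cell is present iff suitability >= `threshold` (closed at the
#' threshold, so LPT binarization keeps all training presences).
#'
#' @param suit a [SuitabilityMap-class].
#' @param threshold numeric in \[0, 1\].
#' @return the map with its `binary` grid and `lpt` slot filled.
#' @export
binarize <- function(suit, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  b <- gridValues(suit)
  b[!is.na(b)] <- as.numeric(b[!is.na(b)] >= threshold)
  suitabilityMap(gridValues(suit), scenarioLabel(suit), suit@xmin,
                 suit@ymin, suit@cellsize, binary = b, lpt = threshold)
}

#' Range shift between two binary suitability maps
#'
#' Classifies every unmasked cell as expansion (absent now, present in the
#' future), contraction, stable or absent, and totals spherically weighted
#' areas in km^2. Percent change = (future - current area) / current area.
#'
#' @param current,future binarized [SuitabilityMap-class] objects on the
#'   same grid.
#' @return list with `categories` (character matrix), `areas_km2` (named
#'   totals incl. current/future presence), and `percent_change`.
#' @export
rangeShift <- function(current, future) {
  if (!identical(dim(gridValues(current)), dim(gridValues(future))) ||
      current@xmin != future@xmin || current@ymin != future@ymin ||
      current@cellsize != future@cellsize)
    stop("current and future grids do not share a geotransform")
  bc <- binaryGrid(current); bf <- binaryGrid(future)
  if (is.null(bc) || is.null(bf)) stop("both maps must be binarized first")
  cat_m <- matrix(NA_character_, nrow(bc), ncol(bc))
  cat_m[bc == 0 & bf == 1] <- "expansion"
  cat_m[bc == 1 & bf == 0] <- "contraction"
  cat_m[bc == 1 & bf == 1] <- "stable"
  cat_m[bc == 0 & bf == 0] <- "absent"
  area <- cellAreaKm2(current)
  tot <- function(cl) sum(area[which(cat_m == cl)])
  areas <- c(expansion = tot("expansion"), contraction = tot("contraction"),
             stable = tot("stable"), absent = tot("absent"))
  areas["current_presence"] <- areas["contraction"] + areas["stable"]
  areas["future_presence"] <- areas["expansion"] + areas["stable"]
  pc <- if (areas["current_presence"] > 0)
    100 * (areas[["future_presence"]] - areas[["current_presence"]]) /
      areas[["current_presence"]]
  else NA_real_
  list(categories = cat_m, areas_km2 = areas, percent_change = pc)
}

#' Permutation importance of each climate layer
#'
#' Importance of layer v = 1 - Pearson r between a model's predictions on
#' the intact stack and on a stack with layer v's unmasked cells permuted,
#' averaged over `n_shuffles` permutations.
#'
#' @param model one element of `fitEnsemble()$models` (or any list with a
#'   `$predict(matrix)` function).
#' @param stack a [RasterStack-class].
#' @param seed integer seed.
#' @param n_shuffles permutations per layer (default 3).
#' @return named numeric vector of importances in \[0, 2\].
#' @export
variableImportance <- function(model, stack, seed = 1L, n_shuffles = 3L) {
  v <- stackValues(stack)
  base <- model$predict(v)
  if (sd(base) < 1e-12) {
    warning("constant predictions: all importances zero")
    return(setNames(rep(0, ncol(v)), colnames(v)))
  }
  withSeed(seed, {
    imp <- vapply(seq_len(ncol(v)), function(j) {
      mean(vapply(seq_len(n_shuffles), function(s) {
        vp <- v
        vp[, j] <- vp[sample.int(nrow(vp)), j]
        pred <- model$predict(vp)
        if (sd(pred) < 1e-12) return(1)
        1 - cor(base, pred)
      }, numeric(1)))
    }, numeric(1))
    setNames(imp, colnames(v))
  })
}
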