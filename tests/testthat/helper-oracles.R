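# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results with different algorithms/code paths
# than the package implementation.

# Naive O(V^2) Dijkstra on an explicitly built 8-connected graph of a cost
# matrix (NA = impassable). Edge weight = mean endpoint cost * cellsize
# (* sqrt(2) for diagonals). Returns the full accumulated-cost matrix.
dijkstraOracle <- function(cost, src_row, src_col, cellsize = 1) {
  nr <- nrow(cost); nc <- ncol(cost)
  id <- function(r, c) (c - 1L) * nr + r
  nV <- nr * nc
  adj <- vector("list", nV)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(cost[r, c])) next
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (is.na(cost[r2, c2])) next
      w <- (cost[r, c] + cost[r2, c2]) / 2 * cellsize *
        if (dr != 0 && dc != 0) sqrt(2) else 1
      adj[[id(r, c)]] <- rbind(adj[[id(r, c)]], c(id(r2, c2), w))
    }
  }
  dist <- rep(Inf, nV)
  done <- rep(FALSE, nV)
  dist[id(src_row, src_col)] <- 0
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u]) || all(done)) break
    done[u] <- TRUE
    for (e in seq_len(NROW(adj[[u]]))) {
      if (is.null(adj[[u]])) break
      v <- adj[[u]][e, 1]; w <- adj[[u]][e, 2]
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
    if (all(done | !is.finite(dist))) break
  }
  out <- matrix(dist, nr, nc)
  out[is.na(cost)] <- NA_real_
  out
}

# Recursive permutation enumeration (independent of the package's).
permsOracle <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in permsOracle(n - 1L)) for (pos in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  }
  out
}

# Brute-force Mantel over all n! relabelings of B, lower-triangle Pearson.
mantelOracle <- function(A, B) {
  lt <- function(m) m[lower.tri(m)]
  r_obs <- cor(lt(A), lt(B))
  rs <- vapply(permsOracle(nrow(A)), function(p)
    cor(lt(A), lt(B[p, p])), numeric(1))
  list(r = r_obs, p = sum(rs >= r_obs - 1e-12) / length(rs))
}

# Direct-sum IDW at query points (full loops, no shortcuts).
idwOracle <- function(qx, qy, sx, sy, sv, power, k) {
  out <- numeric(length(qx))
  for (i in seq_along(qx)) {
    d <- numeric(length(sx))
    for (j in seq_along(sx))
      d[j] <- sqrt((qx[i] - sx[j])^2 + (qy[i] - sy[j])^2)
    if (min(d) < 1e-12) { out[i] <- sv[which.min(d)]; next }
    nb <- order(d)[seq_len(min(k, length(d)))]
    num <- 0; den <- 0
    for (j in nb) { num <- num + sv[j] / d[j]^power; den <- den + 1 / d[j]^power }
    out[i] <- num / den
  }
  out
}

# Brute-force mean pairwise nucleotide diversity with pairwise deletion.
piOracle <- function(seqs) {
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  n <- nrow(m)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] %in% c("A", "C", "G", "T") & m[j, ] %in% c("A", "C", "G", "T")
    if (!any(ok)) next
    vals <- c(vals, mean(m[i, ok] != m[j, ok]))
  }
  mean(vals)
}

# Global Moran's I with rook contiguity.
moranI <- function(m) {
  x <- as.vector(m) - mean(m)
  nr <- nrow(m); nc <- ncol(m)
  num <- 0; S0 <- 0
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    i <- (c - 1) * nr + r
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      j <- (c2 - 1) * nr + r2
      num <- num + x[i] * x[j]; S0 <- S0 + 1
    }
  }
  (length(x) / S0) * num / sum(x^2)
}

# fixture builders ----------------------------------------------------------

mkStack <- function(layers, xmin = 0, ymin = 0, cellsize = 1) {
  if (is.null(names(layers)))
    names(layers) <- paste0("v", seq_along(layers))
  rasterStack(layers, xmin, ymin, cellsize)
}

mkSuit <- function(grid, scenario = "current", xmin = 0, ymin = 0,
                   cellsize = 1) {
  new("SuitabilityMap", grid = grid, scenario = scenario,
      binary = matrix(numeric(0), 0, 0), lpt = NA_real_,
      xmin = xmin, ymin = ymin, cellsize = cellsize)
}

mkFriction <- function(grid, cellsize = 1) {
  new("FrictionSurface", grid = grid, source = "test", xmin = 0, ymin = 0,
      cellsize = cellsize)
}

# small genotype table from a list: pops[[p]] = matrix n x (2L) of alleles
mkGenotypes <- function(poplist, loci = NULL) {
  alle <- NULL; pops <- c()
  for (p in names(poplist)) {
    g <- poplist[[p]]
    L <- ncol(g) / 2
    arr <- array(NA_integer_, c(nrow(g), L, 2))
    for (l in seq_len(L)) {
      arr[, l, 1] <- g[, 2 * l - 1]; arr[, l, 2] <- g[, 2 * l]
    }
    alle <- if (is.null(alle)) arr else {
      out <- array(NA_integer_, c(dim(alle)[1] + nrow(g), L, 2))
      out[seq_len(dim(alle)[1]), , ] <- alle
      out[dim(alle)[1] + seq_len(nrow(g)), , ] <- arr
      out
    }
    pops <- c(pops, rep(p, nrow(g)))
  }
  if (!is.null(loci)) dimnames(alle)[[2]] <- loci
  genotypeTable(paste0("i", seq_along(pops)), pops, alle)
}

# diploid population sample drawn from given allele frequencies
drawPop <- function(n, freqs_per_locus, alleles = NULL) {
  L <- length(freqs_per_locus)
  g <- matrix(NA_integer_, n, 2 * L)
  for (l in seq_len(L)) {
    p <- freqs_per_locus[[l]]
    a <- if (is.null(alleles)) seq_along(p) else alleles
    g[, 2 * l - 1] <- sample(a, n, TRUE, p)
    g[, 2 * l] <- sample(a, n, TRUE, p)
  }
  g
}
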