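# Friction-based connectivity: continuous suitability inverted to a
# dispersal-cost surface, accumulated-cost distances and least-cost paths on
# the 8-connected raster graph (endpoint-mean edge costs, sqrt(2) diagonal
# scaling), and population / shared-haplotype networks.

#' Invert suitability into a friction (dispersal-cost) surface
#'
#' Cost = (1 - suitability) + `epsilon`; high suitability means low
#' dispersal cost. The continuous map is inverted (not the binary one), and
#' the `epsilon` floor keeps perfectly suitable terrain from being free to
#' cross. Masked cells are impassable.
#'
#' @param suit a [SuitabilityMap-class].
#' @param epsilon positive cost floor (default 0.001).
#' @return a [FrictionSurface-class].
#' @export
frictionFromSuitability <- function(suit, epsilon = 0.001) {
  if (epsilon <= 0) stop("epsilon must be positive")
  g <- (1 - gridValues(suit)) + epsilon
  new("FrictionSurface", grid = g, source = scenarioLabel(suit),
      xmin = suit@xmin, ymin = suit@ymin, cellsize = suit@cellsize)
}

# Build the 8-connected weighted graph of a friction surface once; edge
# weight = mean of the two endpoint cell costs x centre distance (cellsize,
# diagonals x sqrt(2)).
frictionGraph <- function(friction) {
  g <- friction@grid
  d <- dim(g)
  nr <- d[1]; nc <- d[2]
  idx <- matrix(seq_len(nr * nc), nr, nc)
  edges <- list(); wts <- list(); e <- 0L
  add <- function(from, to, mult) {
    ok <- !is.na(g[from]) & !is.na(g[to])
    e <<- e + 1L
    edges[[e]] <<- rbind(from[ok], to[ok])
    wts[[e]] <<- (g[from[ok]] + g[to[ok]]) / 2 * friction@cellsize * mult
  }
  # horizontal, vertical, two diagonals
  add(as.vector(idx[, -nc]), as.vector(idx[, -1]), 1)
  add(as.vector(idx[-nr, ]), as.vector(idx[-1, ]), 1)
  add(as.vector(idx[-nr, -nc]), as.vector(idx[-1, -1]), sqrt(2))
  add(as.vector(idx[-1, -nc]), as.vector(idx[-nr, -1]), sqrt(2))
  graph <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  graph <- igraph::add_edges(graph, as.vector(do.call(cbind, edges)))
  igraph::E(graph)$weight <- unlist(wts)
  graph
}

cellIndex <- function(friction, cell) {
  d <- dim(friction@grid)
  (cell[2] - 1L) * d[1] + cell[1]
}

#' Accumulated-cost surface from one source cell
#'
#' Single-source shortest accumulated cost over the 8-connected raster
#' graph.
#'
#' @param friction a [FrictionSurface-class].
#' @param source integer `(row, col)` of the source cell.
#' @param graph optional prebuilt graph (from repeated calls).
#' @return numeric matrix of accumulated costs (`Inf` = unreachable,
#'   `NA` = masked); the source cell is 0.
#' @export
costDistance <- function(friction, source, graph = NULL) {
  g <- friction@grid
  if (is.na(g[source[1], source[2]])) stop("source cell is masked")
  if (is.null(graph)) graph <- frictionGraph(friction)
  dvec <- as.numeric(igraph::distances(graph, v = cellIndex(friction, source),
                                       algorithm = "dijkstra"))
  out <- matrix(dvec, nrow(g), ncol(g))
  out[is.na(g)] <- NA_real_
  out
}

#' Least-cost path between two cells
#'
#' @param friction a [FrictionSurface-class].
#' @param a,b integer `(row, col)` cells, unmasked.
#' @param graph optional prebuilt graph.
#' @return list with `path` (matrix of row/col cells along the path) and
#'   `cost` (total accumulated cost, symmetric in a and b).
#' @export
leastCostPath <- function(friction, a, b, graph = NULL) {
  g <- friction@grid
  if (is.na(g[a[1], a[2]]) || is.na(g[b[1], b[2]]))
    stop("path endpoints must be unmasked")
  if (all(a == b))
    return(list(path = matrix(a, 1, 2,
                              dimnames = list(NULL, c("row", "col"))),
                cost = 0))
  if (is.null(graph)) graph <- frictionGraph(friction)
  ia <- cellIndex(friction, a); ib <- cellIndex(friction, b)
  sp <- suppressWarnings(igraph::shortest_paths(graph, from = ia, to = ib,
                                                output = "both"))
  if (!length(sp$vpath[[1]]))
    stop(sprintf("cells (%d,%d) and (%d,%d) are disconnected",
                 a[1], a[2], b[1], b[2]))
  v <- as.integer(sp$vpath[[1]])
  d <- dim(g)
  path <- cbind(row = ((v - 1L) %% d[1]) + 1L, col = ((v - 1L) %/% d[1]) + 1L)
  cost <- sum(igraph::E(graph)$weight[as.integer(sp$epath[[1]])])
  list(path = path, cost = cost)
}

#' Population pairs sharing at least one haplotype
#'
#' @param haps a [HaplotypeSet-class].
#' @return data.frame `pop_a`, `pop_b` (sorted labels), one row per
#'   unordered pair whose haplotype sets intersect.
#' @export
sharedHaplotypeLinks <- function(haps) {
  sets <- split(haplotypeIds(haps), populations(haps))
  empty <- names(sets)[vapply(sets, length, 1L) == 0L]
  if (length(empty)) {
    warning("populations without sequenced individuals excluded: ",
            paste(empty, collapse = ", "))
    sets <- sets[setdiff(names(sets), empty)]
  }
  pops <- sort(names(sets))
  if (length(pops) < 2L)
    return(data.frame(pop_a = character(0), pop_b = character(0)))
  prs <- combn(pops, 2L)
  share <- apply(prs, 2L, function(p)
    length(intersect(sets[[p[1]]], sets[[p[2]]])) > 0L)
  data.frame(pop_a = prs[1, share], pop_b = prs[2, share])
}

#' Population connectivity network
#'
#' One least-cost-path edge per requested population pair: all pairs
#' ("population connectivity") or only pairs sharing a chloroplast
#' haplotype ("genetic connectivity"). Population coordinates are snapped
#' to the nearest unmasked cell centre (snap distance recorded).
#'
#' @slot nodes data.frame id, lon, lat, row, col, snap_km.
#' @slot edges data.frame pop_a, pop_b, cost, n_cells, type; unreachable
#'   pairs keep an `Inf` cost.
#' @slot paths list of path cell matrices, named `"a|b"`.
#' @slot type `"all-pairs"` or `"shared-haplotype"`.
#' @exportClass ConnectivityNetwork
setClass("ConnectivityNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 paths = "list", type = "character"))

setValidity("ConnectivityNetwork", function(object) {
  if (!object@type %in% c("all-pairs", "shared-haplotype"))
    return("type must be 'all-pairs' or 'shared-haplotype'")
  TRUE
})

setMethod("show", "ConnectivityNetwork", function(object) {
  cat(sprintf("ConnectivityNetwork (%s): %d nodes, %d edges (%d finite)\n",
              object@type, nrow(object@nodes), nrow(object@edges),
              sum(is.finite(object@edges$cost))))
})

#' Network edges as a data.frame
#' @param x a [ConnectivityNetwork-class].
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
setMethod("networkEdges", "ConnectivityNetwork", function(x) x@edges)

snapPopulations <- function(pops, friction) {
  g <- friction@grid
  msk_cells <- which(!is.na(g), arr.ind = TRUE)
  msk_xy <- xyFromCell(friction, msk_cells)
  out <- pops
  out$row <- NA_integer_; out$col <- NA_integer_; out$snap_km <- NA_real_
  for (i in seq_len(nrow(pops))) {
    rc <- cellFromXY(friction, pops$lon[i], pops$lat[i])
    if (!is.na(rc[1, 1]) && !is.na(g[rc])) {
      out$row[i] <- rc[1, 1]; out$col[i] <- rc[1, 2]; out$snap_km[i] <- 0
    } else {
      d <- geosphere::distHaversine(c(pops$lon[i], pops$lat[i]), msk_xy) / 1000
      j <- which.min(d)
      out$row[i] <- msk_cells[j, 1]; out$col[i] <- msk_cells[j, 2]
      out$snap_km[i] <- d[j]
    }
  }
  out
}

#' @rdname sharedHaplotypeLinks
#' @param pops data.frame `id`, `lon`, `lat`.
#' @param friction a [FrictionSurface-class].
#' @param links optional data.frame `pop_a`, `pop_b` restricting the edge
#'   set (e.g. from `sharedHaplotypeLinks`); `NULL` = all pairs.
#' @return `buildNetwork`: a [ConnectivityNetwork-class].
#' @export
buildNetwork <- function(pops, friction, links = NULL) {
  nodes <- snapPopulations(pops, friction)
  type <- if (is.null(links)) "all-pairs" else "shared-haplotype"
  if (is.null(links)) {
    prs <- combn(sort(nodes$id), 2L)
    links <- data.frame(pop_a = prs[1, ], pop_b = prs[2, ])
  }
  graph <- frictionGraph(friction)
  edges <- links
  edges$cost <- NA_real_; edges$n_cells <- NA_integer_
  paths <- vector("list", nrow(links))
  names(paths) <- paste(links$pop_a, links$pop_b, sep = "|")
  for (i in seq_len(nrow(links))) {
    a <- unlist(nodes[nodes$id == links$pop_a[i], c("row", "col")])
    b <- unlist(nodes[nodes$id == links$pop_b[i], c("row", "col")])
    lcp <- tryCatch(leastCostPath(friction, a, b, graph = graph),
                    error = function(e) NULL)
    if (is.null(lcp)) {
      edges$cost[i] <- Inf; edges$n_cells[i] <- 0L
    } else {
      edges$cost[i] <- lcp$cost; edges$n_cells[i] <- nrow(lcp$path)
      paths[[i]] <- lcp$path
    }
  }
  edges$type <- type
  new("ConnectivityNetwork", nodes = nodes, edges = edges, paths = paths,
      type = type)
}

#' Pairwise landscape-resistance matrix
#'
#' Accumulated least-cost distances between every pair of populations on a
#' friction surface; zero diagonal, symmetric.
#'
#' @param pops data.frame `id`, `lon`, `lat`.
#' @param friction a [FrictionSurface-class].
#' @return labelled symmetric matrix.
#' @export
resistanceMatrix <- function(pops, friction) {
  nodes <- snapPopulations(pops, friction)
  graph <- frictionGraph(friction)
  vids <- (nodes$col - 1L) * nrow(friction@grid) + nodes$row
  m <- igraph::distances(graph, v = vids, to = vids, algorithm = "dijkstra")
  dimnames(m) <- list(nodes$id, nodes$id)
  diag(m) <- 0
  m
}
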