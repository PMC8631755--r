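# Genetic-divergence landscapes: pairwise genetic distances placed at
# spherical midpoints, interpolated with k-nearest-neighbour inverse
# distance weighting, clipped to the sample extent, and regressed on
# climatic-suitability change with a penalized-spline GAM.

#' Pairwise distances at population midpoints
#'
#' One sample per unordered population pair, located at the spherical
#' midpoint of the two collection locations.
#'
#' @param pops data.frame `id`, `lon`, `lat`.
#' @param D labelled symmetric genetic-distance matrix over `pops$id`.
#' @return data.frame `lon`, `lat`, `value`, `pop_a`, `pop_b`.
#' @export
midpointDistances <- function(pops, D) {
  if (!all(pops$id %in% rownames(D)))
    stop("distance matrix labels do not cover all populations")
  prs <- combn(nrow(pops), 2L)
  xy <- as.matrix(pops[, c("lon", "lat")])
  out <- data.frame(lon = numeric(ncol(prs)), lat = numeric(ncol(prs)),
                    value = numeric(ncol(prs)),
                    pop_a = pops$id[prs[1, ]], pop_b = pops$id[prs[2, ]])
  for (j in seq_len(ncol(prs))) {
    a <- prs[1, j]; b <- prs[2, j]
    if (abs(pops$lon[a] - pops$lon[b]) %% 360 == 180 &&
        pops$lat[a] == -pops$lat[b])
      stop("antipodal pair: midpoint undefined")
    mp <- geosphere::midPoint(xy[a, ], xy[b, ], a = 6371008.8, f = 0)
    out$lon[j] <- mp[1]; out$lat[j] <- mp[2]
    out$value[j] <- D[pops$id[a], pops$id[b]]
  }
  out
}

#' k-nearest-neighbour inverse distance weighted interpolation
#'
#' Cell value = sum(w_j v_j) / sum(w_j) over the `k_neighbors` nearest
#' samples with w_j = d_j^-power ("variable search radius with k points"
#' semantics). A cell whose centre coincides with a sample takes that
#' sample's value exactly. The raster is clipped to the convex hull of the
#' sample locations (a degenerate hull is buffered by one cell).
#'
#' @param samples data.frame `lon`, `lat`, `value`.
#' @param cellsize cell edge in degrees.
#' @param power IDW power (default 2).
#' @param k_neighbors neighbours per cell (default 12).
#' @param extent optional `(xmin, ymin, xmax, ymax)`; default the sample
#'   bounding box padded by one cell.
#' @param clip clip to the convex hull of samples (default TRUE).
#' @return list: `grid` matrix (NA outside the hull), `xmin`, `ymin`,
#'   `cellsize`.
#' @export
idwInterpolate <- function(samples, cellsize, power = 2, k_neighbors = 12L,
                           extent = NULL, clip = TRUE) {
  if (nrow(samples) == 0L) stop("no samples to interpolate")
  if (is.null(extent))
    extent <- c(min(samples$lon) - cellsize, min(samples$lat) - cellsize,
                max(samples$lon) + cellsize, max(samples$lat) + cellsize)
  nc <- max(1L, ceiling((extent[3] - extent[1]) / cellsize))
  nr <- max(1L, ceiling((extent[4] - extent[2]) / cellsize))
  ymax <- extent[2] + nr * cellsize
  lon <- extent[1] + (seq_len(nc) - 0.5) * cellsize
  lat <- ymax - (seq_len(nr) - 0.5) * cellsize
  pts <- cbind(lon = rep(lon, each = nr), lat = rep(lat, nc))
  g <- matrix(idwAt(pts, samples, power, k_neighbors), nr, nc)
  if (clip) {
    inside <- hullMask(pts, samples, cellsize)
    g[!matrix(inside, nr, nc)] <- NA_real_
  }
  list(grid = g, xmin = extent[1], ymin = extent[2], cellsize = cellsize)
}

# direct IDW evaluation at arbitrary points (planar degrees metric, the
# grid-native distance of the interpolation tool being emulated)
idwAt <- function(pts, samples, power, k_neighbors) {
  k <- min(k_neighbors, nrow(samples))
  vapply(seq_len(nrow(pts)), function(i) {
    d <- sqrt((pts[i, 1] - samples$lon)^2 + (pts[i, 2] - samples$lat)^2)
    if (any(d < 1e-12)) return(samples$value[which.min(d)])
    nb <- order(d)[seq_len(k)]
    w <- d[nb]^(-power)
    sum(w * samples$value[nb]) / sum(w)
  }, numeric(1))
}

hullMask <- function(pts, samples, cellsize) {
  xy <- unique(cbind(samples$lon, samples$lat))
  if (nrow(xy) < 3L) {
    # degenerate hull: buffer each sample by one cell
    keep <- rep(FALSE, nrow(pts))
    for (i in seq_len(nrow(xy)))
      keep <- keep | (abs(pts[, 1] - xy[i, 1]) <= cellsize &
                        abs(pts[, 2] - xy[i, 2]) <= cellsize)
    return(keep)
  }
  h <- chull(xy)
  mgcv::in.out(rbind(xy[h, , drop = FALSE], xy[h[1], , drop = FALSE]),
               pts)
}

#' Signed suitability change between scenarios
#'
#' Per-cell `future - current` (positive = suitability gain); the sign
#' convention is recorded in the `sign_convention` attribute.
#'
#' @param current,future [SuitabilityMap-class] objects on the same grid.
#' @return numeric matrix of differences.
#' @export
suitabilityChange <- function(current, future) {
  if (!identical(dim(gridValues(current)), dim(gridValues(future))) ||
      current@xmin != future@xmin || current@ymin != future@ymin ||
      current@cellsize != future@cellsize)
    stop("grids do not match")
  out <- gridValues(future) - gridValues(current)
  attr(out, "sign_convention") <- "future - current (positive = gain)"
  out
}

#' GAM of interpolated genetic distance on suitability change
#'
#' Fits a univariate penalized cubic regression spline (basis dimension
#' `k`) of the interpolated genetic-divergence landscape on the climatic
#' suitability change at the same cells, reporting adjusted R^2 and the
#' smooth-term p-value. Evaluation cells are those where both surfaces are
#' defined, subsampled to `max_cells` with the given seed.
#'
#' @param landscape list from [idwInterpolate()].
#' @param change suitability-change matrix on the same grid (or a function
#'   of lon/lat evaluated at cell centres).
#' @param k spline basis dimension (default 10).
#' @param max_cells evaluation-cell cap (default 5000).
#' @param seed subsampling seed.
#' @return list with `r_squared`, `p_value`, `n`, `model` (the mgcv fit),
#'   and `data` (the evaluation data.frame).
#' @export
stabilityGam <- function(landscape, change, k = 10L, max_cells = 5000L,
                         seed = 1L) {
  g <- landscape$grid
  if (is.function(change)) {
    nr <- nrow(g); nc <- ncol(g)
    ymax <- landscape$ymin + nr * landscape$cellsize
    lon <- landscape$xmin + (rep(seq_len(nc), each = nr) - 0.5) *
      landscape$cellsize
    lat <- ymax - (rep(seq_len(nr), nc) - 0.5) * landscape$cellsize
    ch <- matrix(change(lon, lat), nr, nc)
  } else {
    if (!identical(dim(change), dim(g)))
      stop("change raster does not match the landscape grid")
    ch <- change
  }
  ok <- which(!is.na(g) & !is.na(ch))
  if (length(ok) < 30L) stop("fewer than 30 evaluation cells")
  if (length(ok) > max_cells)
    ok <- withSeed(seed, sort(sample(ok, max_cells)))
  df <- data.frame(y = g[ok], x = ch[ok])
  if (sd(df$x) < 1e-12) stop("constant predictor")
  kk <- min(k, length(unique(df$x)) - 1L)
  fit <- mgcv::gam(y ~ s(x, bs = "cr", k = kk), data = df, method = "REML")
  sm <- summary(fit)
  list(r_squared = max(0, sm$r.sq), p_value = sm$s.table[1, "p-value"],
       n = nrow(df), model = fit, data = df)
}
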