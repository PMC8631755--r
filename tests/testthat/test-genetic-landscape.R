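test_that("midpoint samples cover each unordered pair once, on the sphere", {
  pops <- data.frame(id = c("a", "b"), lon = c(0, 0), lat = c(0, 10))
  D <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  mp <- midpointDistances(pops, D)
  expect_equal(nrow(mp), 1L)
  expect_equal(mp$lon, 0, tolerance = 1e-9)
  expect_equal(mp$lat, 5, tolerance = 1e-9)
  expect_equal(mp$value, 0.4)
  # longitude midpoint along the equator
  pops2 <- data.frame(id = c("a", "b"), lon = c(0, 10), lat = c(0, 0))
  D2 <- D
  mp2 <- midpointDistances(pops2, D2)
  expect_equal(mp2$lon, 5, tolerance = 1e-9)
  expect_equal(mp2$lat, 0, tolerance = 1e-9)
  # n(n-1)/2 combinatorics
  pops4 <- data.frame(id = letters[1:4], lon = c(0, 1, 2, 3),
                      lat = c(0, 1, 0, 1))
  D4 <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D4) <- 0
  expect_equal(nrow(midpointDistances(pops4, D4)), 6L)
  expect_error(midpointDistances(data.frame(id = "z", lon = 0, lat = 0),
                                 D), "labels")
})

test_that("IDW interpolation is exact, bounded and oracle-identical", {
  # single sample: constant surface inside its (degenerate) hull
  one <- data.frame(lon = 2, lat = 2, value = 7)
  r1 <- idwInterpolate(one, cellsize = 1)
  expect_true(all(r1$grid[!is.na(r1$grid)] == 7))
  # query equidistant from two samples with values 2 and 4 -> 3
  two <- data.frame(lon = c(0, 2), lat = c(0, 0), value = c(2, 4))
  mid <- clgc:::idwAt(cbind(1, 0), two, power = 2, k_neighbors = 2)
  expect_equal(mid, 3, tolerance = 1e-12)
  # sample-coincident cells take the sample value exactly
  at <- clgc:::idwAt(cbind(0, 0), two, power = 2, k_neighbors = 2)
  expect_equal(at, 2)
  # random configuration against the direct-sum oracle
  set.seed(14)
  smp <- data.frame(lon = runif(10, 0, 5), lat = runif(10, 0, 5),
                    value = rnorm(10))
  q <- cbind(runif(20, 0, 5), runif(20, 0, 5))
  got <- clgc:::idwAt(q, smp, power = 2, k_neighbors = 12)
  want <- idwOracle(q[, 1], q[, 2], smp$lon, smp$lat, smp$value, 2, 12)
  expect_equal(got, want, tolerance = 1e-10)
  # surface bounded by the sample range (weights are convex)
  r <- idwInterpolate(smp, cellsize = 0.25)
  v <- r$grid[!is.na(r$grid)]
  expect_gte(min(v), min(smp$value))
  expect_lte(max(v), max(smp$value))
  expect_error(idwInterpolate(smp[0, ], 1), "no samples")
})

test_that("hull clipping keeps interpolation inside the sampled extent", {
  smp <- data.frame(lon = c(0, 4, 0, 4), lat = c(0, 0, 4, 4),
                    value = 1:4)
  r <- idwInterpolate(smp, cellsize = 0.5)
  # corner cells outside the hull-but-inside-extent padding are NA
  expect_true(any(is.na(r$grid)))
  # unclipped surface has no NA
  r2 <- idwInterpolate(smp, cellsize = 0.5, clip = FALSE)
  expect_false(any(is.na(r2$grid)))
})

test_that("suitability change is the signed future-minus-current field", {
  a <- mkSuit(matrix(runif(16), 4))
  b <- mkSuit(matrix(runif(16), 4), scenario = "future")
  expect_true(all(suitabilityChange(a, a) == 0))
  shifted <- mkSuit(pmin(gridValues(a) + 0.2, 1), scenario = "future")
  ch <- suitabilityChange(a, shifted)
  expect_equal(unclass(ch)[gridValues(a) <= 0.8],
               rep(0.2, sum(gridValues(a) <= 0.8)), tolerance = 1e-12)
  expect_equal(unname(suitabilityChange(a, b) + suitabilityChange(b, a)),
               matrix(0, 4, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  bad <- mkSuit(matrix(runif(9), 3))
  expect_error(suitabilityChange(a, bad), "match")
})

test_that("the stability GAM recovers signal and rejects noise", {
  # noiseless quadratic relation: essentially perfect fit
  set.seed(5)
  n <- 30
  x <- matrix(rnorm(n * n), n)
  land <- list(grid = 2 * x^2 - x + 1, xmin = 0, ymin = 0, cellsize = 1)
  g <- stabilityGam(land, x, max_cells = 500, seed = 1)
  expect_gte(g$r_squared, 0.99)
  expect_lt(g$p_value, 1e-6)
  expect_lte(g$n, 500)
  # independent noise: no explanatory power
  land_noise <- list(grid = matrix(rnorm(n * n), n), xmin = 0, ymin = 0,
                     cellsize = 1)
  g0 <- stabilityGam(land_noise, x, max_cells = 500, seed = 1)
  expect_lt(g0$r_squared, 0.1)
  # R^2 invariant to linear rescaling of the predictor
  g2 <- stabilityGam(land, 10 * x + 3, max_cells = 500, seed = 1)
  expect_equal(g2$r_squared, g$r_squared, tolerance = 1e-6)
  expect_error(stabilityGam(land, matrix(1, n, n)), "constant")
  expect_error(stabilityGam(list(grid = matrix(1, 4, 4), xmin = 0,
                                 ymin = 0, cellsize = 1),
                            matrix(rnorm(16), 4)), "30")
})

test_that("divergence built on climatic stability is recovered end to end", {
  # construct a landscape where genetic distance between populations is
  # high exactly where suitability stays stable, then check the fitted
  # association
  set.seed(9)
  sc <- syntheticScenario(seed = 19, nCells = c(25, 25), nVars = 2,
                          nPops = 12, nIndPerPop = 4, kTrue = 2L,
                          nCovariates = 2, betaTrue = defaultBetaTrue(2, 2),
                          autocorrRange = 6)
  stk <- generateClimateStack(sc)
  cur <- trueSuitability(stk$current, c(0, 2, -1))
  fut <- trueSuitability(stk$future, c(0, 2, -1))
  chg <- suitabilityChange(cur, fut)
  gen <- generatePopulationsAndGenotypes(sc, stk$current)
  pops <- gen$pops
  # synthetic divergence: a pair's genetic distance is the climatic
  # stability at the pair's midpoint (high where change is small)
  n <- nrow(pops)
  D0 <- matrix(1, n, n, dimnames = list(pops$id, pops$id)); diag(D0) <- 0
  mp0 <- midpointDistances(pops, D0)
  rc_mp <- cellFromXY(cur, mp0$lon, mp0$lat)
  D <- matrix(0, n, n, dimnames = list(pops$id, pops$id))
  for (j in seq_len(nrow(mp0))) {
    val <- 3 - abs(chg[rc_mp[j, , drop = FALSE]])
    D[mp0$pop_a[j], mp0$pop_b[j]] <- val
    D[mp0$pop_b[j], mp0$pop_a[j]] <- val
  }
  smp <- midpointDistances(pops, D)
  land <- idwInterpolate(smp, cellsize = stk$current@cellsize,
                         extent = c(stk$current@xmin, stk$current@ymin,
                                    stk$current@xmin + 10,
                                    stk$current@ymin + 10))
  pred <- -abs(chg)
  attributes(pred) <- attributes(pred)["dim"]
  g <- stabilityGam(land, pred, seed = 2)
  expect_gte(g$r_squared, 0.3)
})
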