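gradStack <- function(nr = 10, nc = 10, seed = 1) {
  set.seed(seed)
  mkStack(list(a = matrix(rep(seq_len(nc), each = nr), nr),
               b = matrix(rnorm(nr * nc), nr)))
}

test_that("correlated-variable pruning applies the greedy |r| rule", {
  set.seed(2)
  A <- matrix(rnorm(100), 10)
  C <- matrix(rnorm(100), 10)
  # identical twin layers: exactly one survives
  st <- mkStack(list(x = A, y = A))
  pruned <- suppressWarnings(pruneCorrelatedVariables(st))
  expect_equal(nLayers(pruned), 1L)
  # trio: A, B = A + tiny noise, C independent -> one of A/B plus C
  B <- A + matrix(rnorm(100, sd = 0.01), 10)
  p3 <- pruneCorrelatedVariables(mkStack(list(A = A, B = B, C = C)))
  expect_true("C" %in% layerNames(p3))
  expect_equal(nLayers(p3), 2L)
  expect_length(intersect(c("A", "B"), layerNames(p3)), 1L)
  # already weakly correlated stacks are untouched
  set.seed(3)
  weak <- mkStack(list(u = matrix(rnorm(400), 20),
                       v = matrix(rnorm(400), 20)))
  expect_equal(layerNames(pruneCorrelatedVariables(weak)), c("u", "v"))
  expect_warning(pruneCorrelatedVariables(mkStack(list(a = A))), "single")
})

test_that("heterogeneity surface is the windowed SD of PC1", {
  # spatially constant layers -> zero surface with a warning
  flat <- mkStack(list(a = matrix(1, 8, 8), b = matrix(2, 8, 8)))
  expect_warning(h0 <- heterogeneitySurface(flat), "constant")
  expect_true(all(h0 == 0))
  # single linear gradient: PC1 is the gradient, interior window SD is the
  # closed-form SD of an arithmetic progression of the standardized step
  nr <- 9; nc <- 9
  g <- matrix(rep(seq_len(nc), each = nr), nr)
  st <- mkStack(list(a = g))
  h <- heterogeneitySurface(st, window = 5L)
  step <- 1 / sd(as.vector(g))               # standardized column step
  expected_sd <- sd(rep((-2:2) * step, each = 5))
  expect_equal(h[5, 5], expected_sd, tolerance = 1e-10)
  # invariance to layer rescaling
  st2 <- mkStack(list(a = 100 + 42 * g))
  expect_equal(heterogeneitySurface(st2), h, tolerance = 1e-10)
})

test_that("rarefaction keeps a greedy minimum-distance subset", {
  pts <- data.frame(lon = c(0, 0, 1), lat = c(0, 0, 0))
  out <- rarefyOccurrences(pts, 10)
  expect_equal(nrow(out), 2L)                 # coincident pair collapsed
  # all pairs already far apart: unchanged
  far <- data.frame(lon = c(0, 5, 10), lat = c(0, 0, 0))
  expect_equal(rarefyOccurrences(far, 100), far)
  # 5 collinear points spaced d apart, threshold 1.5 d: brute-force greedy
  d_deg <- 0.2
  coll <- data.frame(lon = (0:4) * d_deg, lat = 0)
  d_km <- geosphere::distHaversine(c(0, 0), c(d_deg, 0)) / 1000
  out5 <- rarefyOccurrences(coll, 1.5 * d_km)
  # greedy in input order keeps 1, skips 2, keeps 3 (2d away), skips 4, keeps 5
  expect_equal(out5$lon, c(0, 2, 4) * d_deg)
  expect_equal(nrow(rarefyOccurrences(coll[0, ], 1)), 0L)
})

test_that("pseudo-absences avoid presences and are seeded", {
  st <- gradStack()
  pres <- data.frame(lon = c(0.5, 1.5), lat = c(0.5, 1.5))
  pa1 <- samplePseudoAbsences(st, pres, 20, seed = 7)
  pa2 <- samplePseudoAbsences(st, pres, 20, seed = 7)
  expect_identical(pa1, pa2)
  rc_pa <- cellFromXY(st, pa1$lon, pa1$lat)
  rc_pr <- cellFromXY(st, pres$lon, pres$lat)
  expect_equal(nrow(merge(as.data.frame(rc_pa), as.data.frame(rc_pr))), 0L)
  # mask leaving exactly n free cells returns those cells
  g <- matrix(NA_real_, 10, 10); g[1, 1:3] <- 1
  tiny <- mkStack(list(a = g))
  pa3 <- samplePseudoAbsences(tiny, data.frame(lon = 0.5, lat = 9.5), 2,
                              seed = 1)
  expect_setequal(pa3$lon, c(1.5, 2.5))
  expect_error(samplePseudoAbsences(tiny, data.frame(lon = 0.5, lat = 9.5),
                                    5, seed = 1), "eligible")
})

test_that("TSS is sensitivity + specificity - 1", {
  expect_equal(tss(tp = 40, fn = 10, tn = 30, fp = 20), 0.4)
  expect_equal(tss(50, 0, 50, 0), 1)          # perfect classifier
  expect_equal(tss(50, 0, 0, 50), 0)          # constant 'present' classifier
  expect_error(tss(0, 0, 10, 10), "margin")
})

test_that("ensemble gating retains exactly the above-threshold models", {
  # perfectly separable single-gradient problem
  st <- gradStack(20, 20)
  pres <- data.frame(lon = rep(15:19 + 0.5, each = 4),
                     lat = rep(1:4 + 0.5, 5))
  abs_ <- data.frame(lon = rep(0:4 + 0.5, each = 4),
                     lat = rep(1:4 + 0.5, 5))
  ens <- fitEnsemble(pres, abs_, st, algorithms = c("glm", "rf", "cta"),
                     n_repeats = 2, seed = 11)
  expect_true(all(ens$evaluations$auc == 1))
  expect_true(all(ens$evaluations$tss == 1))
  expect_true(all(ens$evaluations$retained))
  expect_equal(ens$evaluations$retained,
               ens$evaluations$auc > 0.6 & ens$evaluations$tss > 0.6)
  expect_error(fitEnsemble(pres[1:5, ], abs_, st), "10 presences")
})

test_that("random labels give chance-level AUC", {
  set.seed(21)
  st <- mkStack(list(a = matrix(rnorm(900), 30), b = matrix(rnorm(900), 30)))
  cells <- sample(900, 400)
  xy <- xyFromCell(st, cbind(((cells - 1) %% 30) + 1,
                             ((cells - 1) %/% 30) + 1))
  pts <- data.frame(lon = xy[, 1], lat = xy[, 2])
  lab <- rep(0:1, 200)                       # labels independent of climate
  ens <- fitEnsemble(pts[lab == 1, ], pts[lab == 0, ], st,
                     algorithms = c("glm", "cta"), n_repeats = 3, seed = 2)
  expect_lt(abs(mean(ens$evaluations$auc) - 0.5), 0.1)
})

test_that("ensemble prediction averages the retained models", {
  st <- gradStack(6, 6)
  const_model <- function(v) list(predict = function(nd)
    rep(v, nrow(nd)), tss = 1, algorithm = "const", rep = 1L)
  ens <- list(models = list(const_model(0.2), const_model(0.8)))
  suit <- ensemblePredict(ens, st)
  expect_true(all(abs(gridValues(suit) - 0.5) < 1e-12))
  one <- ensemblePredict(list(models = list(const_model(0.8))), st)
  expect_true(all(gridValues(one) == 0.8))
  expect_error(ensemblePredict(list(models = list()), st), "gate")
})

test_that("LPT binarization keeps every training presence", {
  g <- matrix(seq(0, 1, length.out = 25), 5, 5)
  suit <- mkSuit(g)
  pres <- data.frame(lon = c(0.5, 2.5, 4.5), lat = c(0.5, 2.5, 4.5))
  lpt <- lptThreshold(suit, pres)
  vals <- g[cellFromXY(suit, pres$lon, pres$lat)]
  expect_equal(lpt, min(vals))
  b <- binarize(suit, lpt)
  expect_true(all(binaryGrid(b)[cellFromXY(b, pres$lon, pres$lat)] == 1))
  # threshold extremes and monotonicity
  expect_true(all(binaryGrid(binarize(suit, 0))[!is.na(g)] == 1))
  b_lo <- binaryGrid(binarize(suit, 0.3)); b_hi <- binaryGrid(binarize(suit, 0.7))
  expect_true(all(b_hi <= b_lo))
  expect_error(lptThreshold(suit, pres[0, ]), "empty")
  # constant suitability: LPT equals the constant
  expect_equal(lptThreshold(mkSuit(matrix(0.42, 4, 4)),
                            data.frame(lon = 1.5, lat = 1.5)), 0.42)
})

test_that("range shift accounting conserves area", {
  # near-equator grid with effectively equal cell areas
  mk <- function(bin) {
    s <- mkSuit(matrix(0.5, 3, 3), xmin = 0, ymin = -1.5e-4,
                cellsize = 1e-4)
    s@binary <- bin; s@lpt <- 0.5
    s
  }
  cur <- matrix(c(1, 1, 1, 1, 1, 1, 0, 0, 0), 3, byrow = TRUE)
  fut <- matrix(c(1, 1, 1, 1, 0, 0, 1, 0, 0), 3, byrow = TRUE)
  rs <- rangeShift(mk(cur), mk(fut))
  # 4 stable, 2 lost, 1 gained: percent change = (5 - 6)/6
  expect_equal(rs$percent_change, 100 * (5 - 6) / 6, tolerance = 1e-6)
  a <- rs$areas_km2
  expect_equal(a[["expansion"]] + a[["stable"]], a[["future_presence"]])
  expect_equal(a[["contraction"]] + a[["stable"]], a[["current_presence"]])
  # identical grids: nothing moves
  rs0 <- rangeShift(mk(cur), mk(cur))
  expect_equal(rs0$areas_km2[["expansion"]], 0)
  expect_equal(rs0$areas_km2[["contraction"]], 0)
  expect_equal(rs0$percent_change, 0)
  # disjoint grids: no stable area, contraction equals the current range
  rs_d <- rangeShift(mk(cur), mk(1 - cur))
  expect_equal(rs_d$areas_km2[["stable"]], 0)
  expect_equal(rs_d$areas_km2[["contraction"]],
               rs_d$areas_km2[["current_presence"]])
  bad <- mk(fut); bad@xmin <- 99
  expect_error(rangeShift(mk(cur), bad), "geotransform")
})

test_that("permutation importance isolates the active variable", {
  set.seed(4)
  st <- mkStack(list(u = matrix(rnorm(1600), 40),
                     v = matrix(rnorm(1600), 40)))
  only_u <- list(predict = function(nd) plogis(2 * nd[, "u"]))
  imp <- variableImportance(only_u, st, seed = 3, n_shuffles = 3)
  expect_lt(imp[["v"]], 0.02)                 # ignored variable
  expect_gt(imp[["u"]], imp[["v"]])           # active variable dominates
  expect_true(all(imp >= 0 & imp <= 2))
  const <- list(predict = function(nd) rep(0.5, nrow(nd)))
  expect_warning(imp0 <- variableImportance(const, st), "constant")
  expect_true(all(imp0 == 0))
})
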