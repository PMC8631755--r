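test_that("friction inversion maps suitability to dispersal cost", {
  suit <- mkSuit(matrix(c(0, 0.5, 1, NA), 2, 2))
  fr <- frictionFromSuitability(suit, epsilon = 0.001)
  expect_equal(gridValues(fr)[1, 1], 1.001)      # suitability 0
  expect_equal(gridValues(fr)[1, 2], 0.001)      # suitability 1
  expect_true(is.na(gridValues(fr)[2, 2]))       # masked stays impassable
  expect_error(frictionFromSuitability(suit, epsilon = 0), "positive")
  # strictly decreasing in suitability
  s <- seq(0, 1, 0.1)
  costs <- 1 - s + 0.001
  expect_true(all(diff(costs) < 0))
})

test_that("cost distance matches the hand Dijkstra oracle exactly", {
  set.seed(5)
  for (i in 1:8) {
    g <- matrix(runif(100, 0.1, 2), 10, 10)
    if (i > 4) g[sample(100, 10)] <- NA          # some impassable cells
    fr <- mkFriction(g)
    src <- which(!is.na(g), arr.ind = TRUE)[1, ]
    got <- costDistance(fr, src)
    want <- dijkstraOracle(g, src[1], src[2])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("uniform-cost distances follow the 8-connected closed form", {
  fr <- mkFriction(matrix(2, 6, 6), cellsize = 0.5)
  cd <- costDistance(fr, c(3, 3))
  expect_equal(cd[3, 3], 0)
  expect_equal(cd[3, 4], 2 * 0.5)                # rook neighbour
  expect_equal(cd[4, 4], 2 * 0.5 * sqrt(2))      # diagonal neighbour
  # general cell: chebyshev decomposition into diagonal + straight steps
  dr <- 2; dc <- 1
  expect_equal(cd[3 + dr, 3 + dc],
               2 * 0.5 * (min(dr, dc) * sqrt(2) + abs(dr - dc)))
})

test_that("least-cost paths are minimal, symmetric and corridor-following", {
  # trivial identity
  fr <- mkFriction(matrix(1, 5, 5))
  same <- leastCostPath(fr, c(2, 2), c(2, 2))
  expect_equal(same$cost, 0)
  expect_equal(nrow(same$path), 1L)
  # uniform friction along a row: straight path with closed-form cost
  row_lcp <- leastCostPath(fr, c(3, 1), c(3, 5))
  expect_equal(row_lcp$cost, 1 * 1 * 4)
  expect_true(all(row_lcp$path[, "row"] == 3))
  # corridor around a high-cost block
  g <- matrix(1, 6, 6)
  g[2:5, 3:4] <- 100                              # block in the middle
  g[1, ] <- 0.1                                   # cheap corridor along top
  frc <- mkFriction(g)
  lcp <- leastCostPath(frc, c(4, 1), c(4, 6))
  expect_true(any(lcp$path[, "row"] == 1))        # goes through the corridor
  expect_false(any(g[lcp$path] == 100))           # never enters the block
  oracle <- dijkstraOracle(g, 4, 1)
  expect_equal(lcp$cost, oracle[4, 6], tolerance = 1e-12)
  # symmetry
  back <- leastCostPath(frc, c(4, 6), c(4, 1))
  expect_equal(back$cost, lcp$cost, tolerance = 1e-12)
  # disconnected components are reported by cell
  g2 <- matrix(1, 4, 4); g2[, 2] <- NA
  expect_error(leastCostPath(mkFriction(g2), c(1, 1), c(1, 4)),
               "disconnected")
})

test_that("raising any cell cost never shortens a cost distance", {
  set.seed(9)
  g <- matrix(runif(64, 0.5, 1.5), 8, 8)
  fr <- mkFriction(g)
  base <- costDistance(fr, c(1, 1))
  for (i in 1:5) {
    g2 <- g
    cell <- sample(64, 1)
    g2[cell] <- g2[cell] + runif(1, 0.5, 3)
    up <- costDistance(mkFriction(g2), c(1, 1))
    expect_true(all(up - base >= -1e-12, na.rm = TRUE))
  }
})

test_that("shared-haplotype links are exactly the intersecting pairs", {
  seqs <- c("AAAA", "AAAT", "AAAA", "AAAT", "AATT", "AAAT")
  pops <- c("p1", "p1", "p2", "p2", "p3", "p3")
  haps <- haplotypeSet(seqs, pops)
  # p1 = {H1,H2}, p2 = {H1,H2}, p3 = {H3,H2}: all pairs share something
  links <- sharedHaplotypeLinks(haps)
  expect_equal(nrow(links), 3L)
  # textbook case: {H1}, {H1,H2}, {H2} -> links (1,2) and (2,3) only
  h2 <- haplotypeSet(c("AAAA", "AAAA", "CCCC", "CCCC"),
                     c("a", "b", "b", "c"))
  l2 <- sharedHaplotypeLinks(h2)
  expect_equal(nrow(l2), 2L)
  expect_setequal(paste(l2$pop_a, l2$pop_b), c("a b", "b c"))
  # private haplotypes everywhere: no links
  h3 <- haplotypeSet(c("AAAA", "CCCC", "GGGG"), c("a", "b", "c"))
  expect_equal(nrow(sharedHaplotypeLinks(h3)), 0L)
})

test_that("networks carry one least-cost edge per requested pair", {
  g <- matrix(1, 8, 8)
  fr <- mkFriction(g)
  pops <- data.frame(id = c("A", "B", "C", "D"),
                     lon = c(0.5, 6.5, 0.5, 6.5),
                     lat = c(0.5, 0.5, 6.5, 6.5))
  net <- buildNetwork(pops, fr)
  expect_s4_class(net, "ConnectivityNetwork")
  expect_equal(nrow(networkEdges(net)), 6L)          # n(n-1)/2
  # two-population network reproduces leastCostPath
  net2 <- buildNetwork(pops[1:2, ], fr)
  e <- networkEdges(net2)
  lcp <- leastCostPath(fr, c(8, 1), c(8, 7))
  expect_equal(e$cost, lcp$cost, tolerance = 1e-12)
  # node order invariance of costs
  net_r <- buildNetwork(pops[4:1, ], fr)
  key <- function(n) {
    ed <- networkEdges(n)
    setNames(ed$cost, paste(pmin(ed$pop_a, ed$pop_b),
                            pmax(ed$pop_a, ed$pop_b)))
  }
  expect_equal(key(net_r)[names(key(net))], key(net), tolerance = 1e-12)
  # shared-haplotype edge set is a subset of all pairs
  links <- data.frame(pop_a = "A", pop_b = "D")
  net_s <- buildNetwork(pops, fr, links)
  expect_equal(net_s@type, "shared-haplotype")
  expect_equal(nrow(networkEdges(net_s)), 1L)
})

test_that("resistance matrices behave like shortest-path metrics", {
  pops <- data.frame(id = c("A", "B", "C"),
                     lon = c(0.5, 4.5, 2.5), lat = c(0.5, 0.5, 4.5))
  fr1 <- mkFriction(matrix(1, 6, 6))
  fr3 <- mkFriction(matrix(3, 6, 6))
  m1 <- resistanceMatrix(pops, fr1)
  m3 <- resistanceMatrix(pops, fr3)
  expect_equal(m3, 3 * m1, tolerance = 1e-12)     # linear in uniform cost
  expect_true(all(diag(m1) == 0))
  expect_equal(m1, t(m1))
  # uniform friction: proportional to the 8-connected geometric distance
  cheb <- function(a, b) {
    dr <- abs(a[1] - b[1]); dc <- abs(a[2] - b[2])
    min(dr, dc) * sqrt(2) + abs(dr - dc)
  }
  cells <- list(A = c(6, 1), B = c(6, 5), C = c(2, 3))
  expect_equal(m1["A", "B"], cheb(cells$A, cells$B), tolerance = 1e-12)
  expect_equal(m1["A", "C"], cheb(cells$A, cells$C), tolerance = 1e-12)
  # triangle inequality on a random friction
  set.seed(3)
  frr <- mkFriction(matrix(runif(36, 0.2, 2), 6, 6))
  mr <- resistanceMatrix(pops, frr)
  expect_lte(mr["A", "B"], mr["A", "C"] + mr["C", "B"] + 1e-12)
  expect_lte(mr["A", "C"], mr["A", "B"] + mr["B", "C"] + 1e-12)
})
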