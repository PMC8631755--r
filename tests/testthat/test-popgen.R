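test_that("allele frequencies are simple counts over observed alleles", {
  gt <- mkGenotypes(list(p1 = rbind(c(1, 1), c(1, 2))))
  p <- alleleFrequencies(gt, "p1", 1)
  expect_equal(unname(p), c(0.75, 0.25))
  expect_equal(names(p), c("1", "2"))
  mono <- mkGenotypes(list(p1 = rbind(c(5, 5), c(5, 5))))
  expect_equal(unname(alleleFrequencies(mono, "p1", 1)), 1)
  # missing-only input errors
  gm <- genotypeTable("i1", "p1", array(NA_integer_, c(1, 1, 2)))
  expect_error(alleleFrequencies(gm, "p1", 1), "non-missing")
  # frequencies sum to 1 over random tables
  set.seed(11)
  for (i in 1:20) {
    w <- runif(4) / 2 + 0.1
    g <- mkGenotypes(list(p = drawPop(10, list(w / sum(w)))))
    expect_equal(sum(alleleFrequencies(g, "p", 1)), 1, tolerance = 1e-12)
  }
})

test_that("He, Ne and I match their closed forms", {
  p <- c(0.5, 0.5)
  expect_equal(expectedHeterozygosity(p), 0.5, tolerance = 1e-13)
  expect_equal(effectiveAlleles(p), 2, tolerance = 1e-13)
  expect_equal(shannonIndex(p), log(2), tolerance = 1e-13)
  q <- c(0.75, 0.25)
  expect_equal(expectedHeterozygosity(q), 0.375, tolerance = 1e-13)
  expect_equal(effectiveAlleles(q), 1.6, tolerance = 1e-13)
  expect_equal(shannonIndex(q), -(0.75 * log(0.75) + 0.25 * log(0.25)),
               tolerance = 1e-13)
  expect_equal(expectedHeterozygosity(1), 0)
  expect_equal(effectiveAlleles(1), 1)
  expect_equal(shannonIndex(1), 0)
  expect_error(expectedHeterozygosity(numeric(0)), "empty")
  # Ne = 1/(1 - He) identity on random frequency vectors
  set.seed(2)
  for (i in 1:25) {
    w <- runif(sample(2:6, 1)); w <- w / sum(w)
    expect_equal(effectiveAlleles(w), 1 / (1 - expectedHeterozygosity(w)),
                 tolerance = 1e-12)
  }
})

test_that("sequence diversity matches closed forms and the brute-force oracle", {
  same <- c("ACGTACGT", "ACGTACGT")
  expect_equal(nucleotideDiversity(same), 0)
  expect_equal(geneDiversity(same), 0)
  expect_equal(haplotypeCount(same), 1L)
  # two 100-bp sequences, one difference
  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("A", 99), "T"), collapse = "")
  expect_equal(nucleotideDiversity(c(s1, s2)), 0.01, tolerance = 1e-13)
  expect_equal(geneDiversity(c(s1, s2)), 1, tolerance = 1e-13)
  expect_equal(haplotypeCount(c(s1, s2)), 2L)
  # n < 2: pi and h undefined, Nh still reported
  expect_true(is.na(nucleotideDiversity(s1)))
  expect_true(is.na(geneDiversity(s1)))
  expect_equal(haplotypeCount(s1), 1L)
  # gaps: excluded pairwise for pi, significant for haplotype identity
  g1 <- "AC-T"; g2 <- "ACTT"
  expect_equal(nucleotideDiversity(c(g1, g2)), 0)   # only 3 comparable sites
  expect_equal(haplotypeCount(c(g1, g2)), 2L)
  # random alignments against the brute-force pairwise oracle, exactly
  set.seed(7)
  bases <- c("A", "C", "G", "T", "-")
  for (i in 1:50) {
    n <- sample(3:6, 1); L <- sample(10:30, 1)
    seqs <- vapply(seq_len(n), function(j)
      paste(sample(bases, L, TRUE, prob = c(.3, .3, .2, .15, .05)),
            collapse = ""), "")
    expect_equal(nucleotideDiversity(seqs), piOracle(seqs),
                 tolerance = 1e-14)
  }
})

test_that("Weir-Cockerham theta is exact on fixed populations and null on clones", {
  # two populations fixed for different alleles: theta = 1
  gt <- mkGenotypes(list(a = matrix(1L, 10, 2), b = matrix(2L, 10, 2)))
  th <- pairwiseFst(gt)
  expect_equal(th["a", "b"], 1, tolerance = 1e-12)
  # two samples from one panmictic pool: theta ~ 0 (2 x 50, 8 loci)
  set.seed(13)
  freqs <- lapply(1:8, function(l) { w <- runif(5) + 0.2; w / sum(w) })
  gt0 <- mkGenotypes(list(a = drawPop(50, freqs), b = drawPop(50, freqs)))
  expect_lt(abs(pairwiseFst(gt0)["a", "b"]), 0.02)
  expect_error(pairwiseFst(mkGenotypes(list(a = matrix(1L, 1, 2),
                                            b = matrix(2L, 2, 2)))),
               ">= 2")
})

test_that("Fst linearization is F/(1-F) with flooring and Inf flag", {
  expect_equal(linearizeFst(0), 0)
  expect_equal(linearizeFst(0.5), 1)
  expect_equal(linearizeFst(-0.03), 0)             # floored before transform
  expect_warning(li <- linearizeFst(1), "Inf")
  expect_true(is.infinite(li))
  m <- matrix(c(0, 0.2, 0.2, 0), 2)
  expect_equal(linearizeFst(m), m / (1 - m))
})

test_that("small populations are dropped from SSR reporting", {
  st <- data.frame(pop = c("a", "b", "c"), N = c(6, 4, 5))
  f <- filterMinN(st, 5)
  expect_equal(f$pop, c("a", "c"))
  expect_equal(attr(f, "excluded"), "b")
  expect_equal(filterMinN(st, 0)$pop, st$pop)       # identity at n_min = 0
})

test_that("diversity tables agree with per-component statistics", {
  set.seed(5)
  freqs <- list(c(0.5, 0.5), c(0.75, 0.25))
  gt <- mkGenotypes(list(p1 = drawPop(30, freqs[1]),
                         p2 = drawPop(30, freqs[2])))
  haps <- haplotypeSet(c("AAAA", "AAAT", "AAAA", "CCCC"),
                       c("p1", "p1", "p2", "p2"))
  ds <- diversityStats(gt, haps)
  expect_equal(ds$pop, c("p1", "p2"))
  expect_equal(ds$N, c(30L, 30L))
  expect_equal(ds$Nh, c(2L, 2L))
  expect_equal(ds$h, c(1, 1))
  p1 <- alleleFrequencies(gt, "p1", 1)
  expect_equal(ds$He[1], expectedHeterozygosity(p1), tolerance = 1e-12)
  # pooled table merges everything into one population
  pooled <- pooledDiversity(gt, haps)
  expect_equal(pooled$N, 60L)
  expect_equal(pooled$Nh, 3L)
})

test_that("persistence projection filters by suitability and recomputes", {
  haps <- haplotypeSet(c("AAAA", "AAAT", "AAAT", "CCCC", "CCCC", "GGGG"),
                       c("a", "a", "b", "b", "c", "c"))
  set.seed(8)
  freqs <- list(c(0.6, 0.4))
  gt <- mkGenotypes(list(a = drawPop(4, freqs), b = drawPop(4, freqs),
                         c = drawPop(4, freqs)))
  pops <- data.frame(id = c("a", "b", "c"),
                     lon = c(0.5, 1.5, 2.5), lat = c(0.5, 0.5, 0.5))
  suit <- mkSuit(matrix(c(0.2, 0.5, 0.9), 1, 3))
  # lpt = 0: everything persists, statistics unchanged
  all_in <- projectFutureDiversity(gt, haps, pops, suit, 0)
  expect_setequal(all_in$survivors, c("a", "b", "c"))
  expect_equal(all_in$stats, diversityStats(gt, haps))
  # lpt = 0.3: populations b and c persist; pooled Nh is their union
  some <- projectFutureDiversity(gt, haps, pops, suit, 0.3)
  expect_setequal(some$survivors, c("b", "c"))
  expect_equal(some$pooled$Nh, 3L)   # {AAAT, CCCC} U {CCCC, GGGG}
  # single survivor: species level equals that population
  one <- projectFutureDiversity(gt, haps, pops, suit, 0.85)
  expect_equal(one$survivors, "c")
  expect_equal(one$pooled$Nh, one$stats$Nh)
  expect_equal(one$pooled$h, one$stats$h)
  # zero survivors: explicit empty report
  none <- projectFutureDiversity(gt, haps, pops, suit, 0.99)
  expect_length(none$survivors, 0L)
  expect_match(none$note, "no population")
})

test_that("pooled richness never rises as the persistence threshold rises", {
  set.seed(21)
  sc <- syntheticScenario(seed = 17, nCells = c(16, 16), nVars = 2,
                          nPops = 6, nIndPerPop = 5, kTrue = 2L,
                          nCovariates = 2, betaTrue = defaultBetaTrue(2, 2),
                          autocorrRange = 4)
  st <- generateClimateStack(sc)$current
  gen <- generatePopulationsAndGenotypes(sc, st)
  suit <- mkSuit(matrix(runif(256), 16, 16), xmin = st@xmin,
                 ymin = st@ymin, cellsize = st@cellsize)
  prev_nh <- Inf; prev_alleles <- Inf
  for (lpt in c(0, 0.25, 0.5, 0.75, 0.95)) {
    pr <- projectFutureDiversity(gen$genotypes, gen$haplotypes, gen$pops,
                                 suit, lpt)
    if (!length(pr$survivors)) break
    nh <- pr$pooled$Nh
    keep <- populations(gen$genotypes) %in% pr$survivors
    n_alleles <- length(unique(na.omit(c(
      gen$genotypes@alleles[keep, , ]))))
    expect_lte(nh, prev_nh)
    expect_lte(n_alleles, prev_alleles)
    prev_nh <- nh; prev_alleles <- n_alleles
  }
})
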