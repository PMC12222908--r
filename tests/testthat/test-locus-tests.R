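test_that("heterozygosity matches the unbiased gene-diversity formula", {
  tab <- makeCohort(A = rbind(c("A*01:01", "A*02:01"), c("A*01:01", "A*02:01")))
  h <- heterozygosity(tab, "A")
  expect_equal(h$obsHet, 1.0)
  expect_equal(h$expHet, (4 / 3) * 0.5, tolerance = 1e-12)

  mono <- makeCohort(A = rbind(c("A*01:01", "A*01:01"), c("A*01:01", "A*01:01")))
  h <- heterozygosity(mono, "A")
  expect_equal(h$obsHet, 0)
  expect_equal(h$expHet, 0)

  expect_error(heterozygosity(makeCohort(A = rbind(c("A*01:01", "A*01:01"))), "A"),
               "at least 2")
})

test_that("observed heterozygosity tracks expectation under HWE simulation", {
  hp <- data.frame(A = sprintf("A*%02d:01", 1:5), freq = c(.35, .25, .2, .15, .05))
  hp$B <- "B*01:01"; hp$C <- "C*01:01"
  tab <- simulatePopulation(simulationConfig("H", 2000, hp), seed = 8)
  h <- heterozygosity(tab, "A")
  expect_equal(h$obsHet, h$expHet, tolerance = 0.03)
})

test_that("Markov-chain HWE p matches exact enumeration on the minimal fixture", {
  # 2 subjects {AA, aa}: tables {Aa,Aa} w.p. 2/3 and {AA,aa} w.p. 1/3 => p = 1/3
  calls <- rbind(c("A*01:01", "A*01:01"), c("A*02:01", "A*02:01"))
  expect_equal(hweExactOracle(calls), 1 / 3, tolerance = 1e-12)
  res <- hweExactTest(calls, dememorization = 5000, batches = 20,
                      stepsPerBatch = 2000, seed = 42)
  expect_lt(abs(res$p - 1 / 3), 3 * res$se)

  # observed = the most probable table => p includes all tables = 1
  calls <- rbind(c("A*01:01", "A*02:01"), c("A*01:01", "A*02:01"))
  expect_equal(hweExactOracle(calls), 1, tolerance = 1e-12)
  res <- hweExactTest(calls, dememorization = 2000, batches = 5,
                      stepsPerBatch = 500, seed = 1)
  expect_equal(res$p, 1)
})

test_that("HWE p is invariant to allele relabelling (within MC error)", {
  set.seed(14)
  pool <- sprintf("A*%02d:01", 1:4)
  g <- cbind(sample(pool, 30, TRUE), sample(pool, 30, TRUE))
  r1 <- hweExactTest(g, dememorization = 20000, batches = 20,
                     stepsPerBatch = 3000, seed = 7)
  relab <- setNames(rev(pool), pool)
  g2 <- cbind(relab[g[, 1]], relab[g[, 2]])
  r2 <- hweExactTest(g2, dememorization = 20000, batches = 20,
                     stepsPerBatch = 3000, seed = 8)
  expect_lt(abs(r1$p - r2$p), 3 * sqrt(r1$se^2 + r2$se^2) + 1e-6)
})

test_that("HWE test rejects degenerate inputs", {
  mono <- rbind(c("A*01:01", "A*01:01"), c("A*01:01", "A*01:01"))
  expect_error(hweExactTest(mono), "monomorphic")
  expect_error(hweExactTest(rbind(c("A*01:01", "A*02:01"))), "at least 2")
})

test_that("Ewens-Watterson null reproduces the exact worked partition case", {
  # 2n = 4 copies, k = 2: partitions (3,1) w.p. 8/11 and (2,2) w.p. 3/11
  res <- ewTest(c(2L, 2L), method = "enumeration")
  expect_equal(res$Fexp, 6.5 / 11, tolerance = 1e-12)
  expect_equal(res$p, 3 / 11, tolerance = 1e-12)
  expect_equal(res$Fobs, 0.5)
  expect_equal(res$Fnd, (0.5 - 6.5 / 11) / res$sdF)
})

test_that("all-singleton configuration sits at the lower boundary", {
  n <- 5L
  res <- ewTest(rep(1L, 2 * n), method = "enumeration")
  expect_equal(res$Fobs, 1 / (2 * n))
  # the all-singleton partition is the only one with F <= 1/(2n)
  nul <- ewNullOracle(2 * n, 2 * n)
  expect_equal(res$p, nul$pLower(res$Fobs), tolerance = 1e-12)
  expect_equal(length(nul$F), 1L)
})

test_that("Monte-Carlo EW null agrees with enumeration for 2n = 40, k = 10", {
  res <- ewTest(c(rep(6L, 5), rep(2L, 5)), method = "montecarlo",
                nSim = 40000, seed = 9)
  oracle <- ewNullOracle(40, 10)
  expect_lt(abs(res$Fexp - oracle$Fexp), 3 * oracle$sdF / sqrt(40000) + 2e-3)
  expect_equal(res$sdF, oracle$sdF, tolerance = 0.15)
  exact <- ewTest(c(rep(6L, 5), rep(2L, 5)), method = "enumeration")
  expect_lt(abs(res$p - exact$p), 3 * sqrt(exact$p * (1 - exact$p) / 40000) + 0.01)
})

test_that("EW errors on monomorphic input and supports the two-sided flag", {
  expect_error(ewTest(c(10L)), "monomorphic")
  one <- ewTest(c(2L, 2L), method = "enumeration", tail = "lower")
  two <- ewTest(c(2L, 2L), method = "enumeration", tail = "two")
  expect_lte(one$p, two$p)
  expect_lte(two$p, 1)
})

test_that("BH adjustment reproduces the hand-computed step-up values", {
  expect_equal(bhAdjust(c(0.005, 0.01, 0.03, 0.04)), c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(0.07, 5)), rep(0.07, 5))
  p <- runif(20)
  expect_true(all(bhAdjust(p) >= p) && all(bhAdjust(p) <= 1))
  expect_error(bhAdjust(c(0.5, 1.2)), "lie in")
})

test_that("locusTests assembles per-locus tables with BH within locus", {
  panel <- selectPopulation(referencePanel(seed = 2), c("Kenya", "Rwanda"))
  res <- locusTests(panel, loci = c("A", "B"), seed = 3,
                    dememorization = 3000, batches = 5, stepsPerBatch = 500,
                    nSim = 3000)
  expect_equal(nrow(res$hwe), 4L)
  expect_equal(nrow(res$ew), 4L)
  for (l in c("A", "B")) {
    sel <- res$hwe$locus == l
    expect_equal(res$hwe$p_adj[sel], bhAdjust(res$hwe$p[sel]))
  }
  expect_true(all(res$ew$p >= 0 & res$ew$p <= 1))
  expect_true(all(res$hwe$obs_het >= 0 & res$hwe$obs_het <= 1))
})
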