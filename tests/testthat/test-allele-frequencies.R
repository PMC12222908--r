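test_that("direct counting matches a brute-force copy tally", {
  g <- rbind(c("A*01:01", "A*01:01"), c("A*01:01", "A*02:01"))
  tab <- makeCohort(A = g)
  fs <- alleleFreqs(countAlleles(tab, "A"))
  expect_equal(fs$frequency[fs$allele == "A*01:01"], 0.75)
  expect_equal(fs$frequency[fs$allele == "A*02:01"], 0.25)

  # single homozygote
  tab1 <- makeCohort(A = rbind(c("A*03:01", "A*03:01")))
  fs1 <- alleleFreqs(countAlleles(tab1, "A"))
  expect_equal(nrow(fs1), 1L)
  expect_equal(fs1$frequency, 1.0)

  # 10 simulated subjects vs independent tally of all 20 gene copies
  set.seed(11)
  pool <- sprintf("A*%02d:01", 1:6)
  g <- cbind(sample(pool, 10, TRUE), sample(pool, 10, TRUE))
  g <- cbind(pmin(g[, 1], g[, 2]), pmax(g[, 1], g[, 2]))
  tab <- makeCohort(A = g)
  fs <- alleleFreqs(countAlleles(tab, "A"))
  tally <- table(c(g))
  expect_equal(setNames(fs$count, fs$allele)[names(tally)],
               setNames(as.integer(tally), names(tally)))
  expect_equal(sum(fs$frequency), 1, tolerance = 1e-12)
  expect_equal(sum(fs$count), 2L * nSubjects(countAlleles(tab, "A")))
})

test_that("counting excludes partially typed subjects and errors on empty", {
  d <- data.frame(PID = c("s1", "s2"), country = "P",
                  A_1 = c("A*01:01", NA), A_2 = c("A*02:01", "A*01:01"),
                  stringsAsFactors = FALSE)
  tab <- genotypeTable(d, loci = "A")
  expect_equal(nSubjects(countAlleles(tab, "A")), 1L)
  expect_error(countAlleles(tab, "A", population = "Q"), "no fully typed")
})

test_that("merging two disjoint groups sums the counts", {
  set.seed(21)
  pool <- sprintf("A*%02d:01", 1:5)
  mk <- function(n, country) {
    g <- cbind(sample(pool, n, TRUE), sample(pool, n, TRUE))
    makeCohort(A = cbind(pmin(g[, 1], g[, 2]), pmax(g[, 1], g[, 2])),
               country = country)
  }
  t1 <- mk(8, "P1"); t2 <- mk(12, "P2")
  both <- new("HLAGenotypeTable",
              data = rbind(t1@data, transform(t2@data, PID = paste0("x", PID))),
              loci = "A", cleaned = FALSE)
  f1 <- alleleFreqs(countAlleles(both, "A", "P1"))
  f2 <- alleleFreqs(countAlleles(both, "A", "P2"))
  fb <- alleleFreqs(countAlleles(both, "A"))
  merged <- tapply(c(f1$count, f2$count), c(f1$allele, f2$allele), sum)
  expect_equal(setNames(fb$count, fb$allele)[names(merged)],
               setNames(as.integer(merged), names(merged)))
})

test_that("frequency bins follow the printed 5%/1% boundaries", {
  expect_equal(classifyFrequency(c(0.051, 0.05, 0.01, 0.0099, 0.049)),
               c("high", "high", "intermediate", "low", "intermediate"))
  expect_error(classifyFrequency(0), "lie in")
  expect_error(classifyFrequency(1.2), "lie in")
})

test_that("topAlleles sorts by frequency with lexicographic ties", {
  fs <- new("AlleleFrequencySet", locus = "A", population = "P", nSubjects = 50L,
            table = data.frame(allele = c("A*03:01", "A*01:01", "A*02:01"),
                               count = c(25L, 6L, 69L),
                               frequency = c(0.25, 0.06, 0.69),
                               stringsAsFactors = FALSE))
  top <- topAlleles(fs, 0.05)
  expect_equal(top$allele, c("A*02:01", "A*03:01", "A*01:01"))
  expect_equal(nrow(topAlleles(fs, 0.9)), 0L)
  tie <- new("AlleleFrequencySet", locus = "A", population = "P", nSubjects = 50L,
             table = data.frame(allele = c("A*30:01", "A*02:01", "A*11:01"),
                                count = c(6L, 6L, 88L),
                                frequency = c(0.06, 0.06, 0.88),
                                stringsAsFactors = FALSE))
  expect_equal(topAlleles(tie)$allele, c("A*11:01", "A*02:01", "A*30:01"))
})

test_that("population-unique alleles match a set-algebra oracle", {
  set.seed(31)
  pool <- sprintf("B*%02d:01", 1:12)
  mk <- function(n, country, sub) {
    g <- cbind(sample(sub, n, TRUE), sample(sub, n, TRUE))
    makeCohort(B = cbind(pmin(g[, 1], g[, 2]), pmax(g[, 1], g[, 2])),
               country = country)
  }
  tabs <- list(mk(15, "P1", pool[1:8]), mk(15, "P2", pool[4:10]),
               mk(15, "P3", pool[7:12]))
  fsets <- lapply(tabs, function(t) countAlleles(t, "B", populations(t)))
  ut <- uniqueAlleleTable(fsets)

  observed <- lapply(fsets, function(f) alleleFreqs(f)$allele)
  for (i in 1:3) {
    oracle <- setdiff(observed[[i]], unlist(observed[-i]))
    expect_equal(ut$n_unique[i], length(oracle))
    f <- alleleFreqs(fsets[[i]])
    expect_equal(ut$unique_freq_pct[i], 100 * sum(f$frequency[f$allele %in% oracle]))
  }
  # unique counts sum to the number of alleles observed in exactly one population
  presence <- table(unlist(observed))
  expect_equal(sum(ut$n_unique), sum(presence == 1))
})

test_that("an allele shared by two populations is unique to neither", {
  f1 <- new("AlleleFrequencySet", locus = "A", population = "P1", nSubjects = 2L,
            table = data.frame(allele = c("A*01:01", "A*02:01"), count = c(2L, 2L),
                               frequency = c(0.5, 0.5), stringsAsFactors = FALSE))
  f2 <- new("AlleleFrequencySet", locus = "A", population = "P2", nSubjects = 2L,
            table = data.frame(allele = c("A*01:01", "A*03:01"), count = c(2L, 2L),
                               frequency = c(0.5, 0.5), stringsAsFactors = FALSE))
  ut <- uniqueAlleleTable(list(f1, f2))
  expect_equal(ut$n_unique, c(1L, 1L))
  expect_equal(ut$unique_freq_pct, c(50, 50))
})
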