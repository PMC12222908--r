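test_that("configuration validation", {
  hp <- data.frame(A = "A*01:01", B = "B*01:01", C = "C*01:01", freq = 0.9)
  expect_error(simulationConfig("P", 10, hp), "sum to 1")
  hp$freq <- 1
  expect_error(simulationConfig("P", 10, hp, f = 1.5), "inbreeding")
  expect_error(simulationConfig("P", 10, hp, errorRate = -1), "error rate")
  expect_error(simulationConfig("P", 10, hp, tribes = c(T1 = 20L)), "exceed")
})

test_that("full inbreeding makes every subject homozygous at every locus", {
  hp <- expand.grid(A = sprintf("A*%02d:01", 1:3), B = sprintf("B*%02d:01", 1:3),
                    stringsAsFactors = FALSE)
  hp$C <- "C*01:01"
  hp$freq <- rep(1 / 9, 9)
  tab <- simulatePopulation(simulationConfig("F1", 100, hp, f = 1), seed = 2)
  for (l in c("A", "B", "C")) {
    calls <- alleleCalls(tab, l)
    expect_true(all(calls[, 1] == calls[, 2]))
  }
})

test_that("observed heterozygosity decreases in the inbreeding coefficient", {
  hp <- expand.grid(A = sprintf("A*%02d:01", 1:4), B = "B*01:01",
                    C = "C*01:01", stringsAsFactors = FALSE)
  hp$freq <- c(0.4, 0.3, 0.2, 0.1)
  het <- vapply(c(0, 0.25, 0.5, 1), function(f) {
    tab <- simulatePopulation(simulationConfig(paste0("f", f), 800, hp, f = f),
                              seed = 20)
    heterozygosity(tab, "A")$obsHet
  }, numeric(1))
  expect_true(all(diff(het) < 0))
})

test_that("f = 0 draws match HWE genotype proportions (chi-square)", {
  hp <- expand.grid(A = sprintf("A*%02d:01", 1:3), B = "B*01:01", C = "C*01:01",
                    stringsAsFactors = FALSE)
  p <- c(0.5, 0.3, 0.2)
  hp$freq <- p
  tab <- simulatePopulation(simulationConfig("HWE", 3000, hp), seed = 31)
  calls <- alleleCalls(tab, "A")
  key <- paste(calls[, 1], calls[, 2])
  als <- sprintf("A*%02d:01", 1:3)
  expProb <- c()
  obs <- c()
  for (i in 1:3) for (j in i:3) {
    expProb <- c(expProb, if (i == j) p[i]^2 else 2 * p[i] * p[j])
    obs <- c(obs, sum(key == paste(als[i], als[j])))
  }
  chi <- suppressWarnings(stats::chisq.test(obs, p = expProb))
  expect_gt(chi$p.value, 0.001)
})

test_that("genotyping error perturbs calls at the configured rate", {
  hp <- expand.grid(A = sprintf("A*%02d:01", 1:2), B = "B*01:01", C = "C*01:01",
                    stringsAsFactors = FALSE)
  hp$freq <- c(1, 0)  # truth is always allele 1
  tab <- simulatePopulation(simulationConfig("E", 2000, hp, errorRate = 0.05),
                            seed = 13)
  calls <- alleleCalls(tab, "A")
  errRate <- mean(c(calls) != "A*01:01")
  expect_equal(errRate, 0.05, tolerance = 0.02)
})

test_that("empirical allele frequencies converge to the configured spectrum", {
  set.seed(55)
  fa <- c(0.45, 0.3, 0.15, 0.1)
  hp <- expand.grid(A = sprintf("A*%02d:01", 1:4), B = "B*01:01", C = "C*01:01",
                    stringsAsFactors = FALSE)
  hp$freq <- fa
  tab <- simulatePopulation(simulationConfig("Rec", 1500, hp), seed = 41)
  fs <- alleleFreqs(countAlleles(tab, "A"))
  got <- setNames(fs$frequency, fs$allele)[hp$A]
  n2 <- 2 * 1500
  expect_true(all(abs(got - fa) < 3 * sqrt(fa * (1 - fa) / n2)))
})

test_that("independent-loci haplotypes give near-zero ALD", {
  hp <- expand.grid(A = sprintf("A*%02d:01", 1:3), B = sprintf("B*%02d:01", 1:4),
                    stringsAsFactors = FALSE)
  fa <- c(0.5, 0.3, 0.2); fb <- c(0.4, 0.3, 0.2, 0.1)
  hp$C <- "C*01:01"
  hp$freq <- fa[match(hp$A, unique(hp$A))] * fb[match(hp$B, unique(hp$B))]
  tab <- simulatePopulation(simulationConfig("Ind", 1200, hp), seed = 61)
  r <- ald(emHaplotypes(tab, c("A", "B")))
  expect_lt(r$W_A_given_B, 0.12)
  expect_lt(r$W_B_given_A, 0.12)
})

test_that("seed streams are stable: adding a population leaves others unchanged", {
  hp <- expand.grid(A = sprintf("A*%02d:01", 1:3), B = sprintf("B*%02d:01", 1:3),
                    stringsAsFactors = FALSE)
  hp$C <- "C*01:01"
  hp$freq <- randomDistribution(9)
  hp$freq <- hp$freq / sum(hp$freq)
  c1 <- simulationConfig("P1", 50, hp)
  c2 <- simulationConfig("P2", 50, hp)
  solo <- simulatePopulation(list(c1), seed = 3)
  both <- simulatePopulation(list(c1, c2), seed = 3)
  expect_identical(solo@data, both@data[both@data$country == "P1", ])
})

test_that("reference panel reproduces the configured cohort structure", {
  panel <- referencePanel(seed = 1)
  sizes <- table(panel@data$country)
  expect_equal(as.integer(sizes[c("Kenya", "Rwanda", "SouthAfrica", "Uganda",
                                  "Zambia", "EUAM", "AFAM")]),
               c(109L, 173L, 1640L, 231L, 565L, 1765L, 661L))
  expect_true(all(c("Kikuyu", "Zulu", "Muganda", "Bemba") %in% tribes(panel)))
  # locus B richer than locus C at equal n
  for (pop in c("Kenya", "Uganda")) {
    rB <- nrow(alleleFreqs(countAlleles(panel, "B", pop)))
    rC <- nrow(alleleFreqs(countAlleles(panel, "C", pop)))
    expect_gt(rB, rC)
  }
  # determinism
  p2 <- referencePanel(seed = 1)
  expect_identical(panel@data, p2@data)
  p3 <- referencePanel(seed = 2)
  expect_false(identical(panel@data, p3@data))
})
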