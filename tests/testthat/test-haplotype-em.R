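test_that("EM reaches the hand-computed fixed point on the two-subject fixture", {
  tab <- makeCohort(A = rbind(c("A*01:01", "A*01:01"), c("A*01:01", "A*02:01")),
                    B = rbind(c("B*01:01", "B*01:01"), c("B*01:01", "B*02:01")))
  hf <- emHaplotypes(tab, c("A", "B"), tol = 1e-12, maxIter = 20000)
  f <- setNames(haplotypes(hf)$frequency, haplotypes(hf)$haplotype)
  expect_equal(unname(f["A*01:01~B*01:01"]), 0.75, tolerance = 1e-3)
  expect_equal(unname(f["A*02:01~B*02:01"]), 0.25, tolerance = 1e-3)
  expect_lt(sum(f) - f["A*01:01~B*01:01"] - f["A*02:01~B*02:01"], 1e-3)
})

test_that("a single double heterozygote stays on the symmetric ridge", {
  tab <- makeCohort(A = rbind(c("A*01:01", "A*02:01")),
                    B = rbind(c("B*01:01", "B*02:01")))
  hf <- emHaplotypes(tab, c("A", "B"))
  f <- haplotypes(hf)$frequency
  expect_equal(length(f), 4L)
  expect_equal(f, rep(0.25, 4))
})

test_that("phase-unambiguous cohorts reduce to direct gamete counting", {
  # every subject homozygous at >= 1 locus: phase is known
  tab <- makeCohort(
    A = rbind(c("A*01:01", "A*01:01"), c("A*01:01", "A*02:01"),
              c("A*02:01", "A*02:01"), c("A*01:01", "A*01:01")),
    B = rbind(c("B*01:01", "B*02:01"), c("B*02:01", "B*02:01"),
              c("B*01:01", "B*02:01"), c("B*01:01", "B*01:01")))
  hf <- emHaplotypes(tab, c("A", "B"), tol = 1e-12)
  # direct gamete counts: s1 -> A1B1, A1B2; s2 -> A1B2, A2B2;
  # s3 -> A2B1, A2B2; s4 -> A1B1 x2
  direct <- c("A*01:01~B*01:01" = 3, "A*01:01~B*02:01" = 2,
              "A*02:01~B*01:01" = 1, "A*02:01~B*02:01" = 2) / 8
  f <- setNames(haplotypes(hf)$frequency, haplotypes(hf)$haplotype)
  expect_equal(f[names(direct)], direct, tolerance = 1e-6)
})

test_that("log-likelihood is monotone non-decreasing in every run", {
  set.seed(5)
  for (rep in 1:5) {
    pool <- list(A = sprintf("A*%02d:01", 1:3), B = sprintf("B*%02d:01", 1:3),
                 C = sprintf("C*%02d:01", 1:2))
    hp <- expand.grid(A = pool$A, B = pool$B, C = pool$C, stringsAsFactors = FALSE)
    hp$freq <- randomDistribution(nrow(hp))
    tab <- simulatePopulation(simulationConfig(paste0("P", rep), 60, hp), seed = rep)
    hf <- emHaplotypes(tab, c("A", "B", "C"))
    tr <- emDiagnostics(hf)$llTrace
    expect_true(all(diff(tr) >= -1e-8))
  }
})

test_that("progressive-insertion EM agrees with full-space brute-force EM", {
  set.seed(17)
  for (rep in 1:4) {
    kA <- sample(2:4, 1); kB <- sample(2:4, 1); kC <- sample(2:3, 1)
    hp <- expand.grid(A = sprintf("A*%02d:01", 1:kA),
                      B = sprintf("B*%02d:01", 1:kB),
                      C = sprintf("C*%02d:01", 1:kC), stringsAsFactors = FALSE)
    hp$freq <- randomDistribution(nrow(hp))
    tab <- simulatePopulation(simulationConfig(paste0("O", rep), 40, hp), seed = 100 + rep)
    hf <- emHaplotypes(tab, c("A", "B", "C"), tol = 1e-12, maxIter = 20000,
                       progressive = FALSE)

    sel <- tab@data
    genotypes <- lapply(c("A", "B", "C"), function(l)
      cbind(sel[[paste0(l, "_1")]], sel[[paste0(l, "_2")]]))
    oracle <- emBruteForce(genotypes, tol = 1e-12)

    expect_equal(emDiagnostics(hf)$logLik, oracle$logLik, tolerance = 1e-6)
    f <- setNames(haplotypes(hf)$frequency, haplotypes(hf)$haplotype)
    of <- oracle$freq[oracle$freq > 1e-6]
    expect_lt(max(abs(f[names(of)] - of), na.rm = TRUE), 1e-4)
  }
})

test_that("three-locus frequencies are recovered from n = 500 subjects", {
  set.seed(23)
  hp <- expand.grid(A = sprintf("A*%02d:01", 1:4), B = sprintf("B*%02d:01", 1:4),
                    C = sprintf("C*%02d:01", 1:3), stringsAsFactors = FALSE)
  hp$freq <- randomDistribution(nrow(hp))^2
  hp$freq <- hp$freq / sum(hp$freq)
  tab <- simulatePopulation(simulationConfig("R", 500, hp), seed = 99)
  hf <- emHaplotypes(tab, c("A", "B", "C"))
  est <- setNames(haplotypes(hf)$frequency, haplotypes(hf)$haplotype)
  truth <- setNames(hp$freq, paste(hp$A, hp$B, hp$C, sep = "~"))
  truth <- truth[truth >= 0.01]
  got <- est[names(truth)]
  got[is.na(got)] <- 0
  expect_lt(mean(abs(got - truth)), 0.02)
})

test_that("phase posteriors follow the product rule", {
  # homozygous subject: single phase with posterior 1
  tab <- makeCohort(A = rbind(c("A*01:01", "A*01:01"), c("A*01:01", "A*02:01")),
                    B = rbind(c("B*01:01", "B*01:01"), c("B*01:01", "B*02:01")))
  hf <- emHaplotypes(tab, c("A", "B"), tol = 1e-14, maxIter = 50000)
  pp <- phasePosteriors(list(A = c("A*01:01", "A*01:01"),
                             B = c("B*01:01", "B*01:01")), hf)
  expect_equal(nrow(pp), 1L)
  expect_equal(pp$posterior, 1)

  # double heterozygote under near-(0.75, 0.25, 0, 0) frequencies:
  # posterior concentrates on the (A1B1, A2B2) phasing
  pp <- phasePosteriors(list(A = c("A*01:01", "A*02:01"),
                             B = c("B*01:01", "B*02:01")), hf)
  idx <- which(pp$hap1 == "A*01:01~B*01:01")
  expect_gt(pp$posterior[idx], 0.99)
  expect_equal(sum(pp$posterior), 1)

  # uniform frequencies: symmetric 0.5/0.5
  uni <- new("HaplotypeFrequencySet", loci = c("A", "B"),
             table = data.frame(A = rep(c("A*01:01", "A*02:01"), 2),
                                B = rep(c("B*01:01", "B*02:01"), each = 2),
                                haplotype = c("A*01:01~B*01:01", "A*02:01~B*01:01",
                                              "A*01:01~B*02:01", "A*02:01~B*02:01"),
                                frequency = rep(0.25, 4), stringsAsFactors = FALSE),
             diagnostics = list())
  pp <- phasePosteriors(list(A = c("A*01:01", "A*02:01"),
                             B = c("B*01:01", "B*02:01")), uni)
  expect_equal(pp$posterior, c(0.5, 0.5))

  expect_error(phasePosteriors(list(A = c("A*09:09", "A*01:01"),
                                    B = c("B*01:01", "B*01:01")), hf), "absent")
})
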