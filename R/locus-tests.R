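#' Observed and expected heterozygosity at one locus
#'
#' Observed heterozygosity is the fraction of heterozygous subjects among
#' fully typed subjects. Expected heterozygosity is the unbiased gene
#' diversity \eqn{(2n/(2n-1)) (1 - \sum p_i^2)}.
#'
#' @param x an \code{HLAGenotypeTable} or a two-column matrix of allele calls.
#' @param locus locus code (table input only).
#' @param population,tribe optional subject selection (table input only).
#' @return list with \code{obsHet}, \code{expHet} and \code{nSubjects}.
#' @export
heterozygosity <- function(x, locus = NULL, population = NULL, tribe = NULL) {
  calls <- .resolveCalls(x, locus, population, tribe)
  n <- nrow(calls)
  if (n < 2L) stop("heterozygosity requires at least 2 fully typed subjects")
  obs <- mean(calls[, 1] != calls[, 2])
  p <- table(c(calls[, 1], calls[, 2])) / (2 * n)
  exp <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
  list(obsHet = obs, expHet = exp, nSubjects = n)
}

.resolveCalls <- function(x, locus, population, tribe) {
  if (is(x, "HLAGenotypeTable")) {
    stopifnot(!is.null(locus))
    calls <- alleleCalls(selectPopulation(x, population, tribe), locus)
  } else {
    calls <- as.matrix(x)
    stopifnot(ncol(calls) == 2L)
  }
  calls[!is.na(calls[, 1]) & !is.na(calls[, 2]), , drop = FALSE]
}

#' Exact Hardy-Weinberg test by Markov chain Monte Carlo
#'
#' Tests the observed genotype table against the null distribution of
#' genotype tables conditional on the allele counts (Levene's conditional
#' distribution) with a Markov random-walk chain: gene copies are swapped
#' between individuals so that the chain is uniform over labelled pairings
#' of the 2n copies, which induces exactly the conditional null on tables.
#' The p-value is the chain probability of tables no more probable than the
#' observed one; its Monte Carlo standard error comes from batch means.
#'
#' @param x an \code{HLAGenotypeTable} or a two-column matrix of allele calls.
#' @param locus,population,tribe subject selection (table input only).
#' @param dememorization burn-in steps before recording.
#' @param batches,stepsPerBatch batch-means layout of the recorded chain.
#' @param seed optional integer seed applied via \code{set.seed}.
#' @return list with \code{p}, \code{se}, \code{nSubjects}, \code{k} (number
#'   of distinct alleles) and \code{batchMeans}.
#' @export
hweExactTest <- function(x, locus = NULL, population = NULL, tribe = NULL,
                         dememorization = 100000L, batches = 20L,
                         stepsPerBatch = 5000L, seed = NULL) {
  calls <- .resolveCalls(x, locus, population, tribe)
  n <- nrow(calls)
  if (n < 2L) stop("HWE test requires at least 2 fully typed subjects")
  alleles <- sort(unique(c(calls[, 1], calls[, 2])))
  k <- length(alleles)
  if (k < 2L) stop("HWE test undefined for a monomorphic locus")
  if (!is.null(seed)) set.seed(seed)
  res <- hwe_chain_cpp(match(calls[, 1], alleles) - 1L,
                       match(calls[, 2], alleles) - 1L, k,
                       as.integer(dememorization), as.integer(batches),
                       as.integer(stepsPerBatch))
  list(p = res$p, se = res$se, nSubjects = n, k = k, batchMeans = res$batchMeans)
}

.partitions <- function(g, k, maxPart = g - k + 1L) {
  ## all partitions of g into exactly k non-increasing positive parts
  if (k == 1L) {
    if (g <= maxPart) return(list(g)) else return(list())
  }
  out <- list()
  hi <- min(maxPart, g - k + 1L)
  lo <- as.integer(ceiling(g / k))
  if (hi < lo) return(out)
  for (first in seq(hi, lo)) {
    rest <- .partitions(g - first, k - 1L, first)
    out <- c(out, lapply(rest, function(r) c(first, r)))
  }
  out
}

.ewEnumerate <- function(g, k) {
  parts <- .partitions(g, k)
  ## P(partition | g, k) proportional to 1 / (prod_j j^{a_j} a_j!) where a_j
  ## is the number of parts of size j
  logw <- vapply(parts, function(p) {
    a <- table(p)
    sizes <- as.numeric(names(a)); mult <- as.integer(a)
    -sum(mult * log(sizes)) - sum(lgamma(mult + 1))
  }, numeric(1))
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  Fv <- vapply(parts, function(p) sum((p / g)^2), numeric(1))
  list(partitions = parts, prob = w, F = Fv)
}

#' Ewens-Watterson homozygosity test of neutrality
#'
#' Compares the observed homozygosity \eqn{F = \sum p_i^2} with its null
#' distribution under the Ewens sampling formula conditional on the number
#' of gene copies (2n) and the number of distinct alleles (k), following
#' Slatkin's implementation: the conditional null is enumerated exactly over
#' allele-count partitions when the partition count is small and otherwise
#' sampled by a Metropolis Monte Carlo on the ordered count vector, whose
#' stationary law satisfies \eqn{P(n_1..n_k) \propto \prod_i 1/n_i}.
#'
#' The default p-value is the lower tail \eqn{P(F_{null} \le F_{obs})}:
#' small values indicate excess evenness relative to neutrality, the
#' signature of balancing selection, reported together with a negative
#' normalized deviate \code{Fnd}.
#'
#' @param x named integer vector of allele counts, or an
#'   \code{HLAGenotypeTable} (with \code{locus}/\code{population}).
#' @param locus,population,tribe subject selection (table input only).
#' @param nSim Monte Carlo sample size when sampling is used.
#' @param seed optional integer seed.
#' @param method \code{"auto"} (enumerate when the partition count is below
#'   \code{enumLimit}), \code{"enumeration"} or \code{"montecarlo"}.
#' @param tail \code{"lower"} (default, matching the balancing-selection
#'   reading) or \code{"two"} for a two-sided p-value.
#' @param enumLimit largest partition count enumerated under
#'   \code{method = "auto"}.
#' @return list with \code{Fobs}, \code{Fexp}, \code{sdF}, \code{Fnd},
#'   \code{p}, \code{k}, \code{g} (gene copies), \code{method} and, for
#'   Monte Carlo, \code{se} of the p estimate.
#' @export
ewTest <- function(x, locus = NULL, population = NULL, tribe = NULL,
                   nSim = 100000L, seed = NULL,
                   method = c("auto", "enumeration", "montecarlo"),
                   tail = c("lower", "two"), enumLimit = 20000) {
  method <- match.arg(method)
  tail <- match.arg(tail)
  if (is(x, "HLAGenotypeTable") || (is.matrix(x) && ncol(x) == 2L)) {
    calls <- .resolveCalls(x, locus, population, tribe)
    counts <- as.integer(table(c(calls[, 1], calls[, 2])))
  } else {
    counts <- as.integer(x)
  }
  counts <- counts[counts > 0]
  g <- sum(counts)
  k <- length(counts)
  if (k < 2L) stop("Ewens-Watterson test undefined for a monomorphic locus")
  Fobs <- sum((counts / g)^2)
  eps <- 1e-12

  if (method == "auto")
    method <- if (.partitionCountSimple(g, k) <= enumLimit) "enumeration" else "montecarlo"

  if (method == "enumeration") {
    nul <- .ewEnumerate(g, k)
    Fexp <- sum(nul$prob * nul$F)
    sdF <- sqrt(max(0, sum(nul$prob * nul$F^2) - Fexp^2))
    lower <- sum(nul$prob[nul$F <= Fobs + eps])
    upper <- sum(nul$prob[nul$F >= Fobs - eps])
    se <- 0
  } else {
    if (!is.null(seed)) set.seed(seed)
    thin <- max(1L, as.integer(ceiling(g / 10)))
    burn <- as.integer(50L * g)
    Fs <- ew_chain_cpp(g, k, as.integer(nSim), thin, burn)
    Fexp <- mean(Fs)
    sdF <- sd(Fs)
    lower <- mean(Fs <= Fobs + eps)
    upper <- mean(Fs >= Fobs - eps)
    se <- sqrt(lower * (1 - lower) / length(Fs))
  }
  p <- if (tail == "lower") lower else min(1, 2 * min(lower, upper))
  Fnd <- (Fobs - Fexp) / sdF
  list(Fobs = Fobs, Fexp = Fexp, sdF = sdF, Fnd = Fnd, p = p,
       k = k, g = g, method = method, se = se)
}

.partitionCountSimple <- function(g, k) {
  ## p(g, k): partitions of g into exactly k parts, p(g,k) = p(g-1,k-1) + p(g-k,k)
  P <- matrix(0, g + 1L, k + 1L)
  P[, 1L] <- 0; P[1L, 1L] <- 1
  for (n in seq_len(g)) for (j in seq_len(min(n, k))) {
    P[n + 1L, j + 1L] <- P[n, j] + if (n > j) P[n - j + 1L, j + 1L] else 0
  }
  P[g + 1L, k + 1L]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment (wrapper around
#' \code{stats::p.adjust(method = "BH")}); adjusted values are capped at 1
#' and monotone in rank.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values in the input order.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-locus test tables across populations
#'
#' Runs heterozygosity + exact HWE and the Ewens-Watterson test for every
#' (population, locus) combination and applies the Benjamini-Hochberg
#' adjustment per test type across populations within each locus.
#'
#' @param x a cleaned \code{HLAGenotypeTable}.
#' @param loci loci to test.
#' @param populationSet populations; default all in \code{x}.
#' @param seed integer seed; per-test seeds are derived deterministically.
#' @param dememorization,batches,stepsPerBatch HWE chain layout.
#' @param nSim Ewens-Watterson Monte Carlo sample size.
#' @return list with data.frames \code{hwe} (population, locus, n, obs_het,
#'   exp_het, p, p_adj, se) and \code{ew} (population, locus, Fobs, Fexp,
#'   Fnd, p, p_adj).
#' @export
locusTests <- function(x, loci = hlaLoci(x), populationSet = populations(x),
                       seed = 1L, dememorization = 100000L, batches = 20L,
                       stepsPerBatch = 5000L, nSim = 100000L) {
  hweRows <- list(); ewRows <- list()
  idx <- 0L
  for (l in loci) {
    for (pop in populationSet) {
      idx <- idx + 1L
      het <- heterozygosity(x, l, pop)
      hw <- hweExactTest(x, l, pop, dememorization = dememorization,
                         batches = batches, stepsPerBatch = stepsPerBatch,
                         seed = seed + 1000L * idx)
      ew <- ewTest(x, locus = l, population = pop, nSim = nSim,
                   seed = seed + 1000L * idx + 500L)
      hweRows[[idx]] <- data.frame(population = pop, locus = l,
                                   n = het$nSubjects, obs_het = het$obsHet,
                                   exp_het = het$expHet, p = hw$p, se = hw$se,
                                   stringsAsFactors = FALSE)
      ewRows[[idx]] <- data.frame(population = pop, locus = l, n = ew$g / 2,
                                  Fobs = ew$Fobs, Fexp = ew$Fexp, Fnd = ew$Fnd,
                                  p = ew$p, method = ew$method,
                                  stringsAsFactors = FALSE)
    }
  }
  hwe <- do.call(rbind, hweRows)
  ew <- do.call(rbind, ewRows)
  hwe$p_adj <- NA_real_; ew$p_adj <- NA_real_
  for (l in loci) {
    sel <- hwe$locus == l
    hwe$p_adj[sel] <- bhAdjust(hwe$p[sel])
    sel <- ew$locus == l
    ew$p_adj[sel] <- bhAdjust(ew$p[sel])
  }
  list(hwe = hwe, ew = ew)
}
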