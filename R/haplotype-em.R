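## Haplotype frequency estimation from unphased genotypes.
##
## Phase configurations of a subject are the unordered haplotype pairs
## compatible with its genotype: with h heterozygous loci there are
## 2^(h-1) configurations (the assignment at the first heterozygous locus is
## anchored to remove the pair-order symmetry). The EM treats the
## configuration as the latent variable; for three or more loci the
## haplotype space is grown by progressive locus insertion with trimming of
## low-posterior partial expansions, the scheme used by the standard
## haplotype-frequency estimators for unphased multiallelic data.

.hapSep <- "~"

.hapString <- function(m) {
  if (ncol(m) == 1L) return(m[, 1])
  do.call(paste, c(lapply(seq_len(ncol(m)), function(k) m[, k]), sep = .hapSep))
}

## configurations for one genotype: gRow = list of length-2 allele vectors
## (one per locus); anchorHet = index of first heterozygous locus overall.
.expandConfigs <- function(gRow) {
  het <- vapply(gRow, function(p) p[1] != p[2], logical(1))
  L <- length(gRow)
  if (!any(het)) {
    hap <- vapply(gRow, `[`, character(1), 1)
    return(list(h1 = matrix(hap, 1L, L), h2 = matrix(hap, 1L, L)))
  }
  hIdx <- which(het)
  free <- hIdx[-1]
  combos <- if (length(free))
    as.matrix(expand.grid(rep(list(0:1), length(free)), KEEP.OUT.ATTRS = FALSE))
  else matrix(0L, 1L, 0L)
  ncfg <- nrow(combos)
  h1 <- matrix("", ncfg, L); h2 <- matrix("", ncfg, L)
  for (l in seq_len(L)) {
    p <- gRow[[l]]
    if (!het[l]) { h1[, l] <- p[1]; h2[, l] <- p[1] }
    else if (l == hIdx[1]) { h1[, l] <- p[1]; h2[, l] <- p[2] }
    else {
      k <- combos[, match(l, free)]
      h1[, l] <- p[1 + k]; h2[, l] <- p[2 - k]
    }
  }
  list(h1 = h1, h2 = h2)
}

## EM on a fixed configuration list.
## s: genotype index per configuration; i, j: haplotype dictionary indices;
## wg: subject count per unique genotype; f0: start frequencies.
.emCore <- function(s, i, j, wg, nHap, n, f0, tol, maxIter) {
  f <- f0
  mult <- 1 + (i != j)
  llOld <- -Inf
  llTrace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    p <- mult * f[i] * f[j]
    S <- rowsum(p, s)[, 1]
    if (any(S <= 0))
      stop("a genotype has zero likelihood under the current haplotype set")
    ll <- sum(wg * log(S))
    llTrace <- c(llTrace, ll)
    wcfg <- p / S[s] * wg[s]
    cnt <- rowsum(c(wcfg, wcfg), factor(c(i, j), levels = seq_len(nHap)))[, 1]
    cnt[is.na(cnt)] <- 0
    f <- cnt / (2 * n)
    if (is.finite(llOld) && abs(ll - llOld) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    if (iter >= maxIter) break
    llOld <- ll
  }
  list(f = f, logLik = ll, iterations = iter, converged = converged,
       llTrace = llTrace)
}

## marginal allele frequencies per locus from grouped genotypes
.marginals <- function(Gu, wg) {
  lapply(Gu, function(m) {
    cnt <- rowsum(c(wg, wg), c(m[, 1], m[, 2]))[, 1]
    cnt / sum(cnt)
  })
}

#' Haplotype frequencies by EM with progressive locus insertion
#'
#' Estimates multi-locus haplotype frequencies from unphased genotypes. For
#' two loci a plain EM is run over all phase configurations from a
#' deterministic product-of-marginal-allele-frequencies start. For three (or
#' more) loci, EM is first run on the first two loci; each further locus is
#' then inserted: every retained partial phase configuration is expanded
#' with the new locus' allele assignments, expansions whose posterior
#' probability falls below \code{posteriorThreshold} are trimmed, and EM is
#' re-run on the retained space. The log-likelihood is non-decreasing across
#' iterations; haplotypes with final frequency below 1e-6 are dropped as
#' numerical dust and the distribution renormalised.
#'
#' @param x an \code{HLAGenotypeTable}.
#' @param loci ordered locus tuple (insertion order; default A, B then C).
#' @param population,tribe optional subject selection.
#' @param tol relative log-likelihood change declaring convergence.
#' @param maxIter maximum EM iterations per stage.
#' @param posteriorThreshold trimming threshold for partial-phase posteriors
#'   at insertion time.
#' @param progressive set \code{FALSE} to run plain EM over the full
#'   phase-configuration space regardless of the number of loci.
#' @return a \code{\linkS4class{HaplotypeFrequencySet}}; diagnostics carry
#'   the final log-likelihood, iteration count, convergence flag, trim
#'   threshold and the log-likelihood trace of the final EM stage.
#' @examples
#' tab <- genotypeTable(data.frame(
#'   PID = c("s1", "s2"), country = "P",
#'   A_1 = c("A*01:01", "A*01:01"), A_2 = c("A*01:01", "A*02:01"),
#'   B_1 = c("B*07:02", "B*07:02"), B_2 = c("B*07:02", "B*15:03")),
#'   loci = c("A", "B"))
#' haplotypes(emHaplotypes(tab, c("A", "B")))
#' @export
emHaplotypes <- function(x, loci = c("A", "B", "C"), population = NULL,
                         tribe = NULL, tol = 1e-8, maxIter = 5000L,
                         posteriorThreshold = 1e-4, progressive = TRUE) {
  stopifnot(is(x, "HLAGenotypeTable"), length(loci) >= 2L,
            all(loci %in% hlaLoci(x)))
  sel <- selectPopulation(x, population, tribe)
  callsL <- lapply(loci, function(l) alleleCalls(sel, l))
  full <- Reduce(`&`, lapply(callsL, function(m) !is.na(m[, 1]) & !is.na(m[, 2])))
  if (!any(full))
    stop("no subjects fully typed at loci ", paste(loci, collapse = ", "))
  n <- sum(full)
  G <- lapply(callsL, function(m) {
    m <- m[full, , drop = FALSE]
    flip <- m[, 1] > m[, 2]
    tmp <- m[flip, 1]; m[flip, 1] <- m[flip, 2]; m[flip, 2] <- tmp
    m
  })
  key <- do.call(paste, c(lapply(G, function(m) paste(m[, 1], m[, 2], sep = "/")),
                          sep = "|"))
  grp <- match(key, unique(key))
  wg <- as.numeric(tabulate(grp))
  uniq <- !duplicated(key)
  Gu <- lapply(G, function(m) m[uniq, , drop = FALSE])
  nGen <- sum(uniq)
  marg <- .marginals(Gu, wg)

  ## start with the first two loci over the full configuration space
  nStart <- if (progressive) 2L else length(loci)
  cfg <- .buildConfigs(Gu, seq_len(nStart))
  dict <- .hapDict(cfg)
  f0 <- .productStart(dict$haps, seq_len(nStart), marg)
  fit <- .emCore(dict$s, dict$i, dict$j, wg, nrow(dict$haps), n, f0, tol, maxIter)

  if (progressive && length(loci) > 2L) {
    for (lNew in seq.int(3L, length(loci))) {
      ins <- .insertLocus(cfg, dict, fit$f, Gu, lNew, marg, wg,
                          posteriorThreshold)
      cfg <- ins$cfg
      dict <- ins$dict
      fit <- .emCore(dict$s, dict$i, dict$j, wg, nrow(dict$haps), n, ins$f0,
                     tol, maxIter)
    }
  }

  if (!fit$converged)
    warning("EM did not converge within ", maxIter, " iterations")

  f <- fit$f
  keep <- f >= 1e-6
  haps <- dict$haps[keep, , drop = FALSE]
  f <- f[keep] / sum(f[keep])
  tab <- as.data.frame(haps, stringsAsFactors = FALSE)
  names(tab) <- loci
  tab$haplotype <- .hapString(haps)
  tab$frequency <- f
  tab <- tab[order(-tab$frequency, tab$haplotype), , drop = FALSE]
  rownames(tab) <- NULL
  new("HaplotypeFrequencySet", loci = loci, table = tab,
      diagnostics = list(logLik = fit$logLik, iterations = fit$iterations,
                         converged = fit$converged,
                         trimThreshold = posteriorThreshold, nSubjects = n,
                         llTrace = fit$llTrace))
}

## build configurations for the given locus indices; returns per-genotype
## flat arrays (s = genotype index per configuration row)
.buildConfigs <- function(Gu, lociIdx) {
  nGen <- nrow(Gu[[1]])
  h1l <- list(); h2l <- list(); sl <- list()
  for (g in seq_len(nGen)) {
    gRow <- lapply(lociIdx, function(l) Gu[[l]][g, ])
    e <- .expandConfigs(gRow)
    h1l[[g]] <- e$h1; h2l[[g]] <- e$h2
    sl[[g]] <- rep.int(g, nrow(e$h1))
  }
  list(h1 = do.call(rbind, h1l), h2 = do.call(rbind, h2l),
       s = unlist(sl, use.names = FALSE))
}

.hapDict <- function(cfg) {
  k1 <- .hapString(cfg$h1); k2 <- .hapString(cfg$h2)
  all <- unique(c(k1, k2))
  haps <- do.call(rbind, strsplit(all, .hapSep, fixed = TRUE))
  list(haps = haps, i = match(k1, all), j = match(k2, all), s = cfg$s)
}

.productStart <- function(haps, lociIdx, marg) {
  f0 <- rep(1, nrow(haps))
  for (k in seq_along(lociIdx))
    f0 <- f0 * marg[[lociIdx[k]]][haps[, k]]
  f0 / sum(f0)
}

## expand configurations with one further locus, trimming partial-phase
## expansions whose posterior falls below the threshold
.insertLocus <- function(cfg, dict, f, Gu, lNew, marg, wg, threshold) {
  p <- (1 + (dict$i != dict$j)) * f[dict$i] * f[dict$j]
  S <- rowsum(p, dict$s)[, 1]
  post <- p / S[dict$s]

  m <- Gu[[lNew]]
  ## a heterozygous new locus yields two expansions only when the pair order
  ## is already anchored by heterozygosity at an earlier locus; genotypes
  ## homozygous at all earlier loci anchor at the new locus instead
  hetEarlier <- rowSums(do.call(cbind, lapply(seq_len(lNew - 1L), function(l)
    Gu[[l]][, 1] != Gu[[l]][, 2]))) > 0
  hetNew <- m[, 1] != m[, 2]
  nExt <- ifelse(hetNew[dict$s] & hetEarlier[dict$s], 2L, 1L)
  baseRow <- rep(seq_along(dict$s), nExt)
  ext2 <- sequence(nExt) == 2L             # second (swapped) expansion?
  g2 <- dict$s[baseRow]
  n1 <- ifelse(ext2, m[g2, 2], m[g2, 1])
  n2 <- ifelse(ext2, m[g2, 1], m[g2, 2])
  postNew <- post[baseRow] / nExt[baseRow]
  keep <- postNew >= threshold
  ## never leave a genotype without configurations
  for (g in unique(dict$s)) {
    rows <- which(dict$s[baseRow] == g)
    if (!any(keep[rows])) keep[rows[which.max(postNew[rows])]] <- TRUE
  }
  baseRow <- baseRow[keep]; n1 <- n1[keep]; n2 <- n2[keep]
  cfgNew <- list(h1 = cbind(cfg$h1[baseRow, , drop = FALSE], n1),
                 h2 = cbind(cfg$h2[baseRow, , drop = FALSE], n2),
                 s = dict$s[baseRow])
  dictNew <- .hapDict(cfgNew)
  L <- ncol(dictNew$haps)
  prev <- .hapString(dictNew$haps[, -L, drop = FALSE])
  f0 <- f[match(prev, .hapString(dict$haps))] * marg[[lNew]][dictNew$haps[, L]]
  f0[is.na(f0) | f0 <= 0] <- 1e-12
  list(cfg = cfgNew, dict = dictNew, f0 = f0 / sum(f0))
}

#' Phase posteriors of a subject under estimated haplotype frequencies
#'
#' Enumerates the phase configurations compatible with a subject's genotype
#' and returns their posterior probabilities, proportional to the product of
#' the two haplotype frequencies (doubled for heterotypic pairs).
#'
#' @param genotype named list, one unordered allele pair per locus of
#'   \code{freqSet} (e.g. \code{list(A = c("A*01:01","A*02:01"), ...)}).
#' @param freqSet a \code{HaplotypeFrequencySet}.
#' @return data.frame (hap1, hap2, posterior), posteriors summing to 1.
#' @export
phasePosteriors <- function(genotype, freqSet) {
  stopifnot(is(freqSet, "HaplotypeFrequencySet"))
  loci <- freqSet@loci
  if (!all(loci %in% names(genotype)))
    stop("genotype must supply an allele pair for each of: ",
         paste(loci, collapse = ", "))
  tab <- freqSet@table
  for (l in seq_along(loci)) {
    seen <- unique(tab[[loci[l]]])
    miss <- setdiff(genotype[[loci[l]]], seen)
    if (length(miss))
      stop("allele(s) absent from the haplotype frequency set: ",
           paste(miss, collapse = ", "))
  }
  e <- .expandConfigs(lapply(loci, function(l) as.character(genotype[[l]])))
  k1 <- .hapString(e$h1); k2 <- .hapString(e$h2)
  f <- setNames(tab$frequency, tab$haplotype)
  f1 <- f[k1]; f2 <- f[k2]
  f1[is.na(f1)] <- 0; f2[is.na(f2)] <- 0
  p <- (1 + (k1 != k2)) * f1 * f2
  if (sum(p) <= 0)
    stop("genotype has zero probability under the haplotype frequency set")
  data.frame(hap1 = k1, hap2 = k2, posterior = p / sum(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname HaplotypeFrequencySet-class
#' @export
setMethod("haplotypes", "HaplotypeFrequencySet", function(x) x@table)

#' @rdname HaplotypeFrequencySet-class
#' @export
setMethod("emDiagnostics", "HaplotypeFrequencySet", function(x) x@diagnostics)

#' @rdname HaplotypeFrequencySet-class
#' @export
setMethod("hlaLoci", "HaplotypeFrequencySet", function(x) x@loci)

#' @export
#' @describeIn HaplotypeFrequencySet-class summary with top haplotypes.
setMethod("show", "HaplotypeFrequencySet", function(object) {
  d <- object@diagnostics
  cat("HaplotypeFrequencySet over", paste(object@loci, collapse = "~"),
      "|", nrow(object@table), "haplotypes |", d$nSubjects, "subjects\n")
  cat(sprintf("  logLik %.4f after %d iterations (%s)\n", d$logLik, d$iterations,
              if (isTRUE(d$converged)) "converged" else "NOT converged"))
  print(head(object@table[, c("haplotype", "frequency")], 5))
  if (nrow(object@table) > 5) cat("  ...\n")
})
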