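#' Shannon entropy of an allele frequency distribution
#'
#' \eqn{H = -\sum_i p_i \ln p_i} in nats, with \eqn{0 \ln 0 = 0}. Maximal
#' (\eqn{\ln k}) for a uniform distribution over k alleles, zero for a
#' degenerate one.
#'
#' @param freqs numeric vector of proportions summing to 1, or an
#'   \code{AlleleFrequencySet}.
#' @return entropy in nats.
#' @export
shannonIndex <- function(freqs) {
  p <- .asDistribution(freqs)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Gini-Simpson index
#'
#' \eqn{1 - \sum_i p_i^2}: the probability that two gene copies drawn at
#' random are different alleles.
#'
#' @inheritParams shannonIndex
#' @return probability in [0, 1 - 1/k].
#' @export
giniSimpson <- function(freqs) {
  p <- .asDistribution(freqs)
  1 - sum(p^2)
}

.asDistribution <- function(freqs) {
  if (is(freqs, "AlleleFrequencySet")) freqs <- freqs@table$frequency
  p <- as.numeric(freqs)
  if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("frequencies must be non-negative and sum to 1")
  p
}

#' Hellinger distance between two allele frequency distributions
#'
#' \deqn{HD(P, Q) = \sqrt{1 - \sum_i \sqrt{p_i q_i}}}
#' equivalently \eqn{\|\sqrt P - \sqrt Q\|_2 / \sqrt 2}; a metric with range
#' [0, 1], 0 for identical distributions and 1 for disjoint supports.
#' Frequency sets are aligned on the union of their alleles, absent alleles
#' counting as 0.
#'
#' @param P,Q \code{AlleleFrequencySet} objects for the same locus, or plain
#'   named (or equal-length unnamed) frequency vectors.
#' @return distance in [0, 1].
#' @export
hellinger <- function(P, Q) {
  if (is(P, "AlleleFrequencySet") && is(Q, "AlleleFrequencySet")) {
    if (P@locus != Q@locus)
      stop("Hellinger distance requires frequency sets for the same locus")
    alleles <- union(P@table$allele, Q@table$allele)
    p <- setNames(numeric(length(alleles)), alleles)
    q <- p
    p[P@table$allele] <- P@table$frequency
    q[Q@table$allele] <- Q@table$frequency
  } else if (!is.null(names(P)) && !is.null(names(Q))) {
    alleles <- union(names(P), names(Q))
    p <- setNames(numeric(length(alleles)), alleles); p[names(P)] <- P
    q <- setNames(numeric(length(alleles)), alleles); q[names(Q)] <- Q
  } else {
    if (length(P) != length(Q)) stop("unnamed frequency vectors must align")
    p <- as.numeric(P); q <- as.numeric(Q)
  }
  .asDistribution(p); .asDistribution(q)
  bc <- sum(sqrt(p * q))
  h2 <- max(0, 1 - min(1, bc))
  if (h2 < 1e-12) h2 <- 0   # guard floating noise at identical inputs
  sqrt(h2)
}

#' Hellinger similarity matrix across populations
#'
#' Pairwise similarity percentages \eqn{(1 - HD) \times 100} between
#' population allele frequency distributions at one locus. The matrix is
#' symmetric with 100 on the diagonal; values are stored at full precision
#' (round only for display).
#'
#' @param freqSets list of \code{AlleleFrequencySet} objects for one locus,
#'   one per population (at least two).
#' @return numeric matrix of similarity percentages with population labels,
#'   attribute \code{"locus"} set.
#' @export
similarityMatrix <- function(freqSets) {
  stopifnot(length(freqSets) >= 2L)
  pops <- vapply(freqSets, function(f) f@population, character(1))
  locus <- unique(vapply(freqSets, function(f) f@locus, character(1)))
  if (length(locus) != 1L) stop("all frequency sets must share one locus")
  m <- length(pops)
  S <- matrix(100, m, m, dimnames = list(pops, pops))
  for (i in seq_len(m - 1)) for (j in seq.int(i + 1, m)) {
    s <- (1 - hellinger(freqSets[[i]], freqSets[[j]])) * 100
    S[i, j] <- s; S[j, i] <- s
  }
  attr(S, "locus") <- locus
  S
}

#' Average genetic diversity of a population against partners
#'
#' The mean of \eqn{100 - similarity\%} over all supplied loci and partner
#' populations: the percentage used to summarise how diverse one population
#' is with respect to a reference set.
#'
#' @param simList list of similarity matrices (one per locus), as returned
#'   by \code{\link{similarityMatrix}}.
#' @param focal focal population label.
#' @param partners partner population labels (non-empty, excluding focal).
#' @return average diversity percentage.
#' @export
averageDiversity <- function(simList, focal, partners) {
  if (is.matrix(simList)) simList <- list(simList)
  partners <- setdiff(partners, focal)
  if (!length(partners)) stop("partner set must be non-empty")
  vals <- unlist(lapply(simList, function(S) {
    stopifnot(focal %in% rownames(S), all(partners %in% colnames(S)))
    100 - S[focal, partners]
  }))
  mean(vals)
}

#' Alpha diversity table across populations and loci
#'
#' @param x an \code{HLAGenotypeTable}.
#' @param loci loci to include.
#' @param populationSet populations; default all.
#' @return data.frame (population, locus, n_subjects, richness, shannon,
#'   gini_simpson).
#' @export
alphaDiversityTable <- function(x, loci = hlaLoci(x),
                                populationSet = populations(x)) {
  rows <- list()
  for (pop in populationSet) for (l in loci) {
    fs <- countAlleles(x, l, pop)
    rows[[length(rows) + 1L]] <- data.frame(
      population = pop, locus = l, n_subjects = fs@nSubjects,
      richness = nrow(fs@table), shannon = shannonIndex(fs),
      gini_simpson = giniSimpson(fs), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
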