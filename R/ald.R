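#' Asymmetric linkage disequilibrium between two loci
#'
#' Computes the conditional-homozygosity ALD measure from two-locus
#' haplotype frequencies. With haplotype frequencies \eqn{h_{ab}}, marginals
#' \eqn{f_a, f_b}, \eqn{F(A) = \sum_a f_a^2} and
#' \eqn{F(A/B) = \sum_b \sum_a h_{ab}^2 / f_b}, the ALD of locus A
#' conditioned on locus B is
#' \deqn{W_{A|B} = \sqrt{ (F(A/B) - F(A)) / (1 - F(A)) }.}
#' Both directions are returned; for two bi-allelic loci they coincide with
#' \eqn{|r|}. A monomorphic conditioned locus yields \code{W = 0} with a
#' warning.
#'
#' @param haplotypes a two-locus \code{HaplotypeFrequencySet}, or a numeric
#'   matrix of haplotype frequencies (rows = alleles of the first locus,
#'   columns = alleles of the second) summing to 1.
#' @return list with \code{W_A_given_B} (first locus conditioned on second),
#'   \code{W_B_given_A} and the locus pair.
#' @export
ald <- function(haplotypes) {
  if (is(haplotypes, "HaplotypeFrequencySet")) {
    if (length(haplotypes@loci) != 2L)
      stop("ALD is defined for a two-locus haplotype frequency set")
    tab <- haplotypes@table
    h <- .hapMatrix(tab, haplotypes@loci)
    pair <- haplotypes@loci
  } else {
    h <- as.matrix(haplotypes)
    pair <- c("A", "B")
  }
  if (any(h < 0) || abs(sum(h) - 1) > 1e-8)
    stop("haplotype frequencies must be non-negative and sum to 1")
  list(W_A_given_B = .aldDir(h, pair[1]),
       W_B_given_A = .aldDir(t(h), pair[2]),
       loci = pair)
}

.hapMatrix <- function(tab, loci) {
  a <- sort(unique(tab[[loci[1]]]))
  b <- sort(unique(tab[[loci[2]]]))
  h <- matrix(0, length(a), length(b), dimnames = list(a, b))
  h[cbind(match(tab[[loci[1]]], a), match(tab[[loci[2]]], b))] <- tab$frequency
  h
}

## W of the row locus conditioned on the column locus
.aldDir <- function(h, focal) {
  fa <- rowSums(h)
  fb <- colSums(h)
  FA <- sum(fa^2)
  if (1 - FA < 1e-12) {
    warning("focal locus ", focal, " is monomorphic; ALD set to 0")
    return(0)
  }
  keep <- fb > 1e-12
  FAB <- sum(colSums(h[, keep, drop = FALSE]^2) / fb[keep])
  W2 <- (FAB - FA) / (1 - FA)
  sqrt(min(1, max(0, W2)))
}

#' Pairwise directed ALD matrix over loci
#'
#' Estimates two-locus haplotype frequencies by EM for every locus pair and
#' computes the directed ALD values. Entry [i, j] is the ALD of locus i
#' conditioned on locus j.
#'
#' @param x an \code{HLAGenotypeTable}.
#' @param loci loci to include.
#' @param population,tribe optional subject selection.
#' @param ... passed to \code{\link{emHaplotypes}}.
#' @return numeric matrix with \code{NA} on the diagonal and attribute
#'   \code{"long"}: a data.frame (focal, conditioning, W).
#' @export
aldMatrix <- function(x, loci = hlaLoci(x), population = NULL, tribe = NULL, ...) {
  L <- length(loci)
  W <- matrix(NA_real_, L, L, dimnames = list(loci, loci))
  for (i in seq_len(L - 1)) for (j in seq.int(i + 1, L)) {
    hf <- emHaplotypes(x, loci = c(loci[i], loci[j]), population = population,
                       tribe = tribe, ...)
    r <- ald(hf)
    W[i, j] <- r$W_A_given_B
    W[j, i] <- r$W_B_given_A
  }
  long <- expand.grid(focal = loci, conditioning = loci, stringsAsFactors = FALSE)
  long <- long[long$focal != long$conditioning, ]
  long$W <- W[cbind(match(long$focal, loci), match(long$conditioning, loci))]
  rownames(long) <- NULL
  attr(W, "long") <- long
  W
}
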