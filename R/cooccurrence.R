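#' Within-locus allele co-occurrence ("inheritance pattern") table
#'
#' Tabulates, for one locus and population, the unordered pair of alleles
#' each subject carries — the observable co-inheritance pattern behind
#' alluvial-style plots. Each fully typed subject contributes exactly one
#' pair (homozygotes contribute a self-pair); relative frequency =
#' count / n.
#'
#' Marginalising the pair counts (heterozygous pairs contributing one copy
#' to each allele, homozygous pairs two) reproduces the gene-copy counts of
#' \code{\link{countAlleles}} exactly.
#'
#' @param x an \code{HLAGenotypeTable}.
#' @param locus locus code.
#' @param population,tribe optional subject selection.
#' @return data.frame (population, locus, allele_1, allele_2, count,
#'   frequency) with \code{allele_1 <= allele_2} lexicographically.
#' @export
pairFrequencies <- function(x, locus, population = NULL, tribe = NULL) {
  calls <- alleleCalls(selectPopulation(x, population, tribe), locus)
  full <- !is.na(calls[, 1]) & !is.na(calls[, 2])
  if (!any(full)) stop("no fully typed subjects at locus ", locus)
  calls <- calls[full, , drop = FALSE]
  a1 <- pmin(calls[, 1], calls[, 2])
  a2 <- pmax(calls[, 1], calls[, 2])
  key <- paste(a1, a2, sep = "|")
  cnt <- table(key)
  parts <- do.call(rbind, strsplit(names(cnt), "|", fixed = TRUE))
  out <- data.frame(
    population = if (is.null(population)) "all" else paste(population, collapse = "/"),
    locus = locus, allele_1 = parts[, 1], allele_2 = parts[, 2],
    count = as.integer(cnt), stringsAsFactors = FALSE)
  out$frequency <- out$count / sum(out$count)
  out <- out[order(-out$count, out$allele_1, out$allele_2), , drop = FALSE]
  rownames(out) <- NULL
  out
}
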