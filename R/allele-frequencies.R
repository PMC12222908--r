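#' Allele frequencies by direct counting
#'
#' Counts gene copies at one locus within a population: every subject with
#' both calls present contributes two copies (homozygotes contribute two to
#' one allele); frequency = count / (2 n). Subjects with a missing call at
#' the locus are excluded from this locus only.
#'
#' @param x an \code{HLAGenotypeTable}.
#' @param locus single locus code.
#' @param population country label(s) to select; \code{NULL} = all subjects.
#' @param tribe optional tribe label(s).
#' @return an \code{\linkS4class{AlleleFrequencySet}}.
#' @examples
#' tab <- genotypeTable(data.frame(
#'   PID = c("s1", "s2"), country = "P",
#'   A_1 = c("A*01:01", "A*01:01"), A_2 = c("A*01:01", "A*02:01")), loci = "A")
#' alleleFreqs(countAlleles(tab, "A"))
#' @export
countAlleles <- function(x, locus, population = NULL, tribe = NULL) {
  stopifnot(is(x, "HLAGenotypeTable"))
  sel <- selectPopulation(x, population, tribe)
  calls <- alleleCalls(sel, locus)
  full <- !is.na(calls[, 1]) & !is.na(calls[, 2])
  if (!any(full))
    stop("no fully typed subjects at locus ", locus,
         if (!is.null(population)) paste0(" in population ", paste(population, collapse = "/")))
  copies <- c(calls[full, 1], calls[full, 2])
  cnt <- table(copies)
  tab <- data.frame(allele = names(cnt), count = as.integer(cnt),
                    stringsAsFactors = FALSE)
  tab$frequency <- tab$count / sum(tab$count)
  tab <- tab[order(-tab$frequency, tab$allele), , drop = FALSE]
  rownames(tab) <- NULL
  new("AlleleFrequencySet", locus = locus,
      population = if (is.null(population)) "all" else paste(population, collapse = "/"),
      nSubjects = sum(full), table = tab)
}

#' @rdname AlleleFrequencySet-class
#' @export
setMethod("alleleFreqs", "AlleleFrequencySet", function(x) x@table)

#' @rdname AlleleFrequencySet-class
#' @export
setMethod("nSubjects", "AlleleFrequencySet", function(x) x@nSubjects)

#' @rdname AlleleFrequencySet-class
#' @export
setMethod("hlaLoci", "AlleleFrequencySet", function(x) x@locus)

#' @rdname AlleleFrequencySet-class
#' @export
setMethod("populations", "AlleleFrequencySet", function(x) x@population)

#' @export
#' @describeIn AlleleFrequencySet-class summary of the frequency spectrum.
setMethod("show", "AlleleFrequencySet", function(object) {
  cat("AlleleFrequencySet: locus", object@locus, "| population", object@population,
      "|", object@nSubjects, "subjects |", nrow(object@table), "alleles\n")
  print(head(object@table, 5))
  if (nrow(object@table) > 5) cat("  ...\n")
})

#' Bin an allele frequency
#'
#' Frequencies are classed as \code{high} (>= 5\%), \code{low} (< 1\%) or
#' \code{intermediate} (1\% to under 5\%), the conventional presentation for
#' HLA frequency spectra.
#'
#' @param freq numeric vector of proportions in (0, 1].
#' @return character vector of bins.
#' @export
classifyFrequency <- function(freq) {
  if (any(!is.finite(freq)) || any(freq <= 0) || any(freq > 1))
    stop("frequencies must lie in (0, 1]")
  ifelse(freq >= 0.05, "high", ifelse(freq < 0.01, "low", "intermediate"))
}

#' Most frequent alleles of a population
#'
#' @param freqSet an \code{AlleleFrequencySet}.
#' @param threshold minimum frequency retained (default the 5\% high-frequency
#'   convention).
#' @return data.frame (allele, count, frequency) sorted by decreasing
#'   frequency, ties broken lexicographically; possibly empty.
#' @export
topAlleles <- function(freqSet, threshold = 0.05) {
  stopifnot(is(freqSet, "AlleleFrequencySet"))
  tab <- freqSet@table
  tab <- tab[tab$frequency >= threshold, , drop = FALSE]
  tab <- tab[order(-tab$frequency, tab$allele), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Population-unique alleles at one locus
#'
#' An allele is population-unique when its count is non-zero in exactly one
#' of the supplied populations. For each population the number of such
#' alleles and the percentage of that population's frequency mass they carry
#' are tabulated.
#'
#' @param freqSets list of \code{AlleleFrequencySet} objects for the same
#'   locus, one per population (at least two).
#' @return data.frame (population, locus, n_subjects, n_unique,
#'   unique_freq_pct). The percentage is the summed relative frequency of
#'   the population's unique alleles times 100.
#' @export
uniqueAlleleTable <- function(freqSets) {
  stopifnot(length(freqSets) >= 2L,
            all(vapply(freqSets, is, logical(1), "AlleleFrequencySet")))
  locus <- unique(vapply(freqSets, function(f) f@locus, character(1)))
  if (length(locus) != 1L) stop("all frequency sets must share one locus")
  pops <- vapply(freqSets, function(f) f@population, character(1))
  if (anyDuplicated(pops)) stop("duplicate population labels")
  alleleLists <- lapply(freqSets, function(f) f@table$allele)
  presence <- table(unlist(alleleLists))
  uniqueAlleles <- names(presence)[presence == 1L]
  out <- data.frame(population = pops, locus = locus,
                    n_subjects = vapply(freqSets, function(f) f@nSubjects, integer(1)),
                    n_unique = 0L, unique_freq_pct = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_along(freqSets)) {
    tab <- freqSets[[i]]@table
    u <- tab$allele %in% uniqueAlleles
    out$n_unique[i] <- sum(u)
    out$unique_freq_pct[i] <- 100 * sum(tab$frequency[u])
  }
  rownames(out) <- NULL
  out
}

#' Construct an allele frequency set from explicit frequencies
#'
#' For frequency tables obtained outside the package (published per-locus
#' allele frequency listings, external estimators). Counts are optional;
#' when absent the set carries frequencies only, which is sufficient for
#' the diversity, similarity and cartography machinery.
#'
#' @param locus locus code.
#' @param population population label.
#' @param alleles character vector of canonical allele names.
#' @param frequencies relative frequencies summing to 1 (within 1e-6; they
#'   are renormalised).
#' @param counts optional integer gene-copy counts.
#' @param nSubjects optional subject count.
#' @return an \code{AlleleFrequencySet}.
#' @export
alleleFrequencySet <- function(locus, population, alleles, frequencies,
                               counts = NULL, nSubjects = NA_integer_) {
  stopifnot(length(alleles) == length(frequencies))
  if (abs(sum(frequencies) - 1) > 1e-6)
    stop("frequencies must sum to 1")
  ord <- order(-frequencies, alleles)
  tab <- data.frame(allele = alleles[ord],
                    count = if (is.null(counts)) NA_integer_ else counts[ord],
                    frequency = frequencies[ord] / sum(frequencies),
                    stringsAsFactors = FALSE)
  new("AlleleFrequencySet", locus = locus, population = population,
      nSubjects = as.integer(nSubjects), table = tab)
}

#' Read per-population allele frequency tables
#'
#' Reads a long-format TSV/CSV with columns \code{population}, \code{locus},
#' \code{allele}, \code{frequency} (and optionally \code{count}) into a
#' nested list of \code{AlleleFrequencySet} objects, indexed first by locus
#' then by population — the input shape used when similarity and diversity
#' summaries are computed from published frequency tables rather than raw
#' genotypes.
#'
#' @param file path to the table.
#' @return list: \code{result[[locus]][[population]]} is an
#'   \code{AlleleFrequencySet}.
#' @export
readAlleleFrequencyTable <- function(file) {
  sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  d <- read.delim(file, sep = sep, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("population", "locus", "allele", "frequency")
  if (!all(need %in% names(d)))
    stop("frequency table must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (l in unique(d$locus)) {
    out[[l]] <- list()
    for (pop in unique(d$population[d$locus == l])) {
      sub <- d[d$locus == l & d$population == pop, ]
      if (abs(sum(sub$frequency) - 1) > 0.02)
        stop("frequencies for ", pop, "/", l, " do not sum to 1")
      out[[l]][[pop]] <- alleleFrequencySet(
        locus = l, population = pop, alleles = sub$allele,
        frequencies = sub$frequency / sum(sub$frequency),
        counts = if ("count" %in% names(sub)) sub$count else NULL)
    }
  }
  out
}

#' Long-format allele frequency table across populations
#'
#' @param freqSets list of \code{AlleleFrequencySet} objects.
#' @return data.frame (population, locus, allele, count, frequency, bin).
#' @export
alleleFrequencyTable <- function(freqSets) {
  do.call(rbind, lapply(freqSets, function(f) {
    tab <- f@table
    data.frame(population = f@population, locus = f@locus,
               allele = tab$allele, count = tab$count, frequency = tab$frequency,
               bin = classifyFrequency(tab$frequency), stringsAsFactors = FALSE)
  }))
}
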