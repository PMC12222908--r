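#' @import methods
#' @importFrom stats p.adjust cmdscale quantile runif rnorm sd setNames
#' @importFrom utils read.delim write.table head modifyList packageVersion
#' @useDynLib hlaDiversity, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Multi-locus HLA genotype table
#'
#' Container for a cohort of unrelated subjects typed at one or more class I
#' HLA loci at two-field resolution. Each subject carries an unordered allele
#' pair per typed locus; either or both calls may be missing (\code{NA}).
#' Population (country) labels are mandatory, tribe labels optional.
#'
#' The underlying \code{data} slot holds one row per subject with columns
#' \code{PID}, \code{country}, \code{tribe} and, for every locus \code{L} in
#' \code{loci}, the columns \code{L_1} and \code{L_2} containing canonical
#' two-field allele names (e.g. \code{"A*02:01"}).
#'
#' @slot data data.frame as described above.
#' @slot loci character vector of locus codes, a subset of \code{c("A","B","C")}.
#' @slot cleaned logical; \code{TRUE} once \code{\link{cleanGenotypes}} has run,
#'   at which point subject identifiers are guaranteed unique.
#'
#' @seealso \code{\link{genotypeTable}}, \code{\link{readGenotypeTable}},
#'   \code{\link{cleanGenotypes}}
#' @export
setClass("HLAGenotypeTable",
  representation(data = "data.frame", loci = "character", cleaned = "logical"),
  prototype(data = data.frame(), loci = character(), cleaned = FALSE)
)

setValidity("HLAGenotypeTable", function(object) {
  msg <- character()
  d <- object@data
  need <- c("PID", "country", "tribe",
            as.vector(rbind(paste0(object@loci, "_1"), paste0(object@loci, "_2"))))
  if (!all(need %in% names(d)))
    msg <- c(msg, paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  if (length(object@loci) && !all(object@loci %in% c("A", "B", "C")))
    msg <- c(msg, "loci must be a subset of A, B, C")
  if (nrow(d)) {
    if (any(is.na(d$country) | !nzchar(d$country)))
      msg <- c(msg, "population (country) labels must be non-empty")
    if (isTRUE(object@cleaned) && anyDuplicated(d$PID))
      msg <- c(msg, "subject IDs must be unique in a cleaned table")
  }
  if (length(msg)) msg else TRUE
})

#' Per-population allele frequency set for one locus
#'
#' Relative allele frequencies estimated by direct counting of gene copies:
#' every fully typed subject contributes two copies, homozygotes contribute
#' two copies of one allele, and frequency = count / (2 n). Unobserved
#' alleles are absent rather than listed with zero frequency.
#'
#' @slot locus single locus code.
#' @slot population population label the frequencies refer to.
#' @slot nSubjects number of fully typed subjects counted.
#' @slot table data.frame with columns \code{allele}, \code{count},
#'   \code{frequency}, sorted by decreasing frequency then allele name.
#'
#' @seealso \code{\link{countAlleles}}
#' @export
setClass("AlleleFrequencySet",
  representation(locus = "character", population = "character",
                 nSubjects = "integer", table = "data.frame")
)

setValidity("AlleleFrequencySet", function(object) {
  msg <- character()
  tab <- object@table
  if (!all(c("allele", "count", "frequency") %in% names(tab)))
    return("table must have columns allele, count, frequency")
  if (nrow(tab)) {
    if (!anyNA(tab$count) && !is.na(object@nSubjects) &&
        sum(tab$count) != 2L * object@nSubjects)
      msg <- c(msg, "allele counts must sum to 2 * nSubjects")
    if (abs(sum(tab$frequency) - 1) > 1e-12)
      msg <- c(msg, "frequencies must sum to 1")
    if (any(tab$frequency <= 0))
      msg <- c(msg, "unobserved alleles must be absent, not zero")
    if (anyDuplicated(tab$allele))
      msg <- c(msg, "duplicate allele entries")
  }
  if (length(msg)) msg else TRUE
})

#' Multi-locus haplotype frequency set
#'
#' Haplotype frequencies for an ordered tuple of loci, usually estimated from
#' unphased genotypes by \code{\link{emHaplotypes}}. Haplotypes are rendered
#' in tilde notation, e.g. \code{"A*30:01~B*42:01~C*17:01"}.
#'
#' @slot loci ordered locus codes the haplotypes span.
#' @slot table data.frame with one allele column per locus plus
#'   \code{haplotype} (tilde rendering) and \code{frequency}.
#' @slot diagnostics list with elements \code{logLik}, \code{iterations},
#'   \code{converged}, \code{trimThreshold}, \code{nSubjects}.
#'
#' @export
setClass("HaplotypeFrequencySet",
  representation(loci = "character", table = "data.frame", diagnostics = "list")
)

setValidity("HaplotypeFrequencySet", function(object) {
  msg <- character()
  tab <- object@table
  if (!all(c(object@loci, "haplotype", "frequency") %in% names(tab)))
    return("table must carry one column per locus plus haplotype and frequency")
  if (nrow(tab)) {
    if (any(tab$frequency < 0)) msg <- c(msg, "negative haplotype frequency")
    if (abs(sum(tab$frequency) - 1) > 1e-9)
      msg <- c(msg, "haplotype frequencies must sum to 1")
  }
  if (length(msg)) msg else TRUE
})
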