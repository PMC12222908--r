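#' @rdname HLAGenotypeTable-class
#' @param x,object an object.
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname HLAGenotypeTable-class
#' @export
setGeneric("hlaLoci", function(x) standardGeneric("hlaLoci"))

#' @rdname HLAGenotypeTable-class
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname HLAGenotypeTable-class
#' @export
setGeneric("tribes", function(x) standardGeneric("tribes"))

#' @rdname HLAGenotypeTable-class
#' @param locus single locus code ("A", "B" or "C").
#' @export
setGeneric("alleleCalls", function(x, locus) standardGeneric("alleleCalls"))

#' @rdname AlleleFrequencySet-class
#' @param x an object.
#' @export
setGeneric("alleleFreqs", function(x) standardGeneric("alleleFreqs"))

#' @rdname HaplotypeFrequencySet-class
#' @param x an object.
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @rdname HaplotypeFrequencySet-class
#' @export
setGeneric("emDiagnostics", function(x) standardGeneric("emDiagnostics"))
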