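#' Parse class I HLA allele names at two-field resolution
#'
#' Accepts names in IMGT-style nomenclature, optionally prefixed with
#' \code{"HLA-"} and optionally carrying an expression suffix (\code{N},
#' \code{L}, \code{S}, \code{C}, \code{A}, \code{Q}), and returns the
#' canonical two-field rendering \code{"<locus>*<group>:<protein>"}. Names
#' typed at higher resolution (three or four fields) are truncated to two
#' fields. Parsing a canonical name and rendering it back is the identity.
#'
#' @param text character vector of allele names.
#' @param loci loci accepted; anything else is a parse error.
#' @param onError \code{"stop"} to raise an error naming the offending token,
#'   \code{"NA"} to return \code{NA} for malformed entries.
#' @return character vector of canonical two-field names (\code{NA} passed
#'   through unchanged).
#' @examples
#' parseAllele(c("A*02:01", "B*57:01:01:02", "HLA-C*04:09N"))
#' @export
parseAllele <- function(text, loci = c("A", "B", "C"), onError = c("stop", "NA")) {
  onError <- match.arg(onError)
  out <- rep(NA_character_, length(text))
  fail <- function(tok, why) {
    if (onError == "stop")
      stop("malformed allele name '", tok, "': ", why, call. = FALSE)
    NA_character_
  }
  for (i in seq_along(text)) {
    tok <- text[i]
    if (is.na(tok) || !nzchar(trimws(tok))) next
    s <- trimws(tok)
    s <- sub("^HLA-", "", s, ignore.case = TRUE)
    if (!grepl("*", s, fixed = TRUE)) { out[i] <- fail(tok, "missing '*'"); next }
    parts <- strsplit(s, "*", fixed = TRUE)[[1]]
    if (length(parts) != 2L) { out[i] <- fail(tok, "expected one '*'"); next }
    locus <- toupper(parts[1])
    if (!locus %in% loci) { out[i] <- fail(tok, paste0("locus '", locus, "' not one of ", paste(loci, collapse = ", "))); next }
    fieldstr <- sub("[A-Za-z]$", "", parts[2])   # expression suffix
    if (!grepl(":", fieldstr, fixed = TRUE)) { out[i] <- fail(tok, "missing ':' (two-field resolution required)"); next }
    fields <- strsplit(fieldstr, ":", fixed = TRUE)[[1]]
    if (length(fields) < 2L || !all(grepl("^[0-9]+$", fields[1:2]))) {
      out[i] <- fail(tok, "fields must be numeric"); next
    }
    f <- vapply(fields[1:2], function(z) formatC(as.integer(z), width = 2, flag = "0"),
                character(1))
    out[i] <- paste0(locus, "*", f[1], ":", f[2])
  }
  out
}

.alleleCols <- function(loci) as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2")))

#' Construct an HLA genotype table
#'
#' Builds an \code{\linkS4class{HLAGenotypeTable}} from a data.frame with one
#' row per subject. Allele columns are parsed to canonical two-field names.
#'
#' @param data data.frame with columns \code{PID}, \code{country}, optionally
#'   \code{tribe}, and \code{<locus>_1}/\code{<locus>_2} per locus.
#' @param loci loci present in \code{data}.
#' @param cleaned mark the table as already cleaned (unique PIDs enforced).
#' @return an \code{HLAGenotypeTable}.
#' @export
genotypeTable <- function(data, loci = c("A", "B", "C"), cleaned = FALSE) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!"tribe" %in% names(data)) data$tribe <- NA_character_
  cols <- .alleleCols(loci)
  miss <- setdiff(c("PID", "country", cols), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  data$PID <- as.character(data$PID)
  data$country <- as.character(data$country)
  data$tribe <- as.character(data$tribe)
  for (cl in cols) data[[cl]] <- parseAllele(as.character(data[[cl]]), loci = loci)
  new("HLAGenotypeTable",
      data = data[, c("PID", "country", "tribe", cols), drop = FALSE],
      loci = loci, cleaned = cleaned)
}

#' Read a genotype table from CSV/TSV
#'
#' Reads a delimited file with a header row, maps columns through
#' \code{schema}, and parses allele names. Rows with a malformed (non-empty,
#' unparseable) allele cell are rejected and logged with their line numbers;
#' empty cells become missing calls and are handled downstream per locus.
#'
#' @param file path to a CSV (comma) or TSV (tab) file; the delimiter is
#'   taken from the extension unless \code{sep} is given.
#' @param schema named character vector mapping the standard column names
#'   (\code{PID}, \code{country}, \code{tribe}, \code{A_1}, ..., \code{C_2})
#'   to the file's column names.
#' @param loci loci to read.
#' @param sep field delimiter override.
#' @return an \code{HLAGenotypeTable}; rejected rows are recorded in
#'   \code{attr(, "rejections")} as a data.frame (line, PID, reason).
#' @export
readGenotypeTable <- function(file, schema = NULL, loci = c("A", "B", "C"), sep = NULL) {
  if (!file.exists(file)) stop("cannot read file: ", file)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(file, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty genotype table: ", file)
  std <- c("PID", "country", "tribe", .alleleCols(loci))
  if (is.null(schema)) schema <- setNames(std, std)
  have <- intersect(std, names(schema))
  if (!all(c("PID", "country", .alleleCols(loci)) %in% have))
    stop("schema must map PID, country and all allele columns")
  missingCols <- setdiff(schema[have], names(raw))
  if (length(missingCols))
    stop("mapped columns absent from file: ", paste(missingCols, collapse = ", "))
  d <- raw[, unname(schema[have]), drop = FALSE]
  names(d) <- have
  if (!"tribe" %in% names(d)) d$tribe <- NA_character_
  d$tribe[!nzchar(trimws(ifelse(is.na(d$tribe), "", d$tribe)))] <- NA_character_

  cols <- .alleleCols(loci)
  bad <- matrix(FALSE, nrow(d), length(cols))
  for (j in seq_along(cols)) {
    v <- d[[cols[j]]]
    blank <- is.na(v) | !nzchar(trimws(v))
    parsed <- parseAllele(v, loci = loci, onError = "NA")
    bad[, j] <- !blank & is.na(parsed)
    parsed[blank] <- NA_character_
    d[[cols[j]]] <- parsed
  }
  rowBad <- rowSums(bad) > 0
  if (mean(rowBad) > 0.5)
    stop("more than 50% of rows are malformed (", sum(rowBad), "/", nrow(d), ")")
  rejections <- data.frame(
    line = which(rowBad) + 1L,  # header is line 1
    PID = d$PID[rowBad],
    reason = vapply(which(rowBad), function(i)
      paste("unparseable allele in", paste(cols[bad[i, ]], collapse = ",")), character(1)),
    stringsAsFactors = FALSE)
  d <- d[!rowBad, , drop = FALSE]
  if (nrow(d) == 0L) stop("no parseable rows in ", file)
  tab <- new("HLAGenotypeTable",
             data = d[, c("PID", "country", "tribe", cols), drop = FALSE],
             loci = loci, cleaned = FALSE)
  attr(tab, "rejections") <- rejections
  tab
}

#' Clean a genotype table
#'
#' Resolves duplicated subject identifiers by keeping, for each PID, the row
#' with the greater number of non-missing allele cells (ties keep the first
#' occurrence; both are logged). Subjects with a missing call at a locus are
#' retained — they are excluded per locus by the counting functions — and the
#' per-locus exclusion counts are reported.
#'
#' Cleaning is idempotent and never alters a retained allele call.
#'
#' @param x an \code{HLAGenotypeTable}.
#' @return the cleaned table (\code{cleaned = TRUE}); the report is attached
#'   as \code{attr(, "cleaningReport")}, a data.frame (PID, action, reason),
#'   and per-locus exclusion counts as \code{attr(, "locusExclusions")}.
#' @export
cleanGenotypes <- function(x) {
  stopifnot(is(x, "HLAGenotypeTable"))
  d <- x@data
  cols <- .alleleCols(x@loci)
  report <- data.frame(PID = character(), action = character(), reason = character(),
                       stringsAsFactors = FALSE)
  if (nrow(d) && anyDuplicated(d$PID)) {
    completeness <- rowSums(!is.na(d[, cols, drop = FALSE]))
    keep <- rep(TRUE, nrow(d))
    for (pid in unique(d$PID[duplicated(d$PID)])) {
      idx <- which(d$PID == pid)
      best <- idx[which.max(completeness[idx])]  # ties -> first occurrence
      drop <- setdiff(idx, best)
      keep[drop] <- FALSE
      tie <- sum(completeness[idx] == completeness[best]) > 1L
      report <- rbind(report, data.frame(
        PID = pid, action = "kept",
        reason = paste0(if (tie) "duplicate PID, tie on completeness, first occurrence kept"
                        else "duplicate PID, most complete row kept",
                        " (", completeness[best], " allele cells)"),
        stringsAsFactors = FALSE))
      report <- rbind(report, data.frame(
        PID = rep(pid, length(drop)), action = "dropped",
        reason = paste0("duplicate of retained row (", completeness[drop], " allele cells)"),
        stringsAsFactors = FALSE))
    }
    d <- d[keep, , drop = FALSE]
    rownames(d) <- NULL
  }
  exclusions <- vapply(x@loci, function(l) {
    sum(is.na(d[[paste0(l, "_1")]]) | is.na(d[[paste0(l, "_2")]]))
  }, integer(1))
  out <- new("HLAGenotypeTable", data = d, loci = x@loci, cleaned = TRUE)
  attr(out, "cleaningReport") <- report
  attr(out, "locusExclusions") <- exclusions
  out
}

#' Write a genotype table
#'
#' @param x an \code{HLAGenotypeTable}.
#' @param file output path; extension picks the delimiter (.csv comma,
#'   otherwise tab).
#' @return invisibly, the path written.
#' @export
writeGenotypeTable <- function(x, file) {
  stopifnot(is(x, "HLAGenotypeTable"))
  sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  write.table(x@data, file, sep = sep, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' Subset a genotype table by population and tribe
#'
#' @param x an \code{HLAGenotypeTable}.
#' @param population country label(s) to keep; \code{NULL} keeps all.
#' @param tribe tribe label(s) to keep; \code{NULL} keeps all.
#' @return an \code{HLAGenotypeTable} with the selected subjects.
#' @export
selectPopulation <- function(x, population = NULL, tribe = NULL) {
  stopifnot(is(x, "HLAGenotypeTable"))
  d <- x@data
  if (!is.null(population)) d <- d[d$country %in% population, , drop = FALSE]
  if (!is.null(tribe)) d <- d[!is.na(d$tribe) & d$tribe %in% tribe, , drop = FALSE]
  rownames(d) <- NULL
  new("HLAGenotypeTable", data = d, loci = x@loci, cleaned = x@cleaned)
}

#' @rdname HLAGenotypeTable-class
#' @export
setMethod("nSubjects", "HLAGenotypeTable", function(x) nrow(x@data))

#' @rdname HLAGenotypeTable-class
#' @export
setMethod("hlaLoci", "HLAGenotypeTable", function(x) x@loci)

#' @rdname HLAGenotypeTable-class
#' @export
setMethod("populations", "HLAGenotypeTable", function(x) unique(x@data$country))

#' @rdname HLAGenotypeTable-class
#' @export
setMethod("tribes", "HLAGenotypeTable", function(x) {
  tr <- unique(x@data$tribe)
  tr[!is.na(tr)]
})

#' @rdname HLAGenotypeTable-class
#' @details \code{alleleCalls} returns the two-column character matrix of
#'   allele calls at one locus (one row per subject, \code{NA} = missing).
#' @export
setMethod("alleleCalls", "HLAGenotypeTable", function(x, locus) {
  stopifnot(length(locus) == 1L, locus %in% x@loci)
  m <- as.matrix(x@data[, paste0(locus, c("_1", "_2")), drop = FALSE])
  dimnames(m) <- list(x@data$PID, c("allele1", "allele2"))
  m
})

#' @export
#' @describeIn HLAGenotypeTable-class compact summary of the cohort.
setMethod("show", "HLAGenotypeTable", function(object) {
  cat("HLAGenotypeTable with", nrow(object@data), "subjects,",
      length(unique(object@data$country)), "population(s)\n")
  cat("  loci:", paste(object@loci, collapse = ", "),
      if (object@cleaned) " (cleaned)" else " (raw)", "\n")
  pops <- table(object@data$country)
  cat("  ", paste(sprintf("%s: %d", names(pops), as.integer(pops)), collapse = ", "), "\n")
})
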