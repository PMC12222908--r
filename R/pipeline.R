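## End-to-end orchestration: one call reproduces every report table of the
## analysis (frequency spectra and bins, alpha diversity, similarity
## heatmap tables, MDS cartography, ALD, co-occurrence, unique-allele
## summary, HWE and Ewens-Watterson tables, haplotype tables, rarefaction
## curves) from a genotype table, with every stochastic stage seeded.

.writeTable <- function(df, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), con)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE, na = "")
  path
}

.writeMatrix <- function(m, path, meta = list()) {
  df <- data.frame(population = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .writeTable(df, path, meta)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full diversity analysis pipeline
#'
#' Executes every analysis stage on a genotype table and writes the report
#' bundle to \code{outputDir}: per-population allele frequencies and bins,
#' alpha diversity, Hellinger similarity matrices and a diversity summary,
#' MDS coordinates for every locus combination, directed ALD tables,
#' within-locus pair frequencies, the unique-allele summary, HWE and
#' Ewens-Watterson test tables (BH-adjusted per locus), haplotype frequency
#' tables in tilde notation, rarefaction-extrapolation curves, and a JSON
#' run manifest echoing all parameters and seeds. Identical input,
#' parameters and seed produce byte-identical outputs.
#'
#' @param x an \code{HLAGenotypeTable} or a path to a genotype CSV/TSV.
#' @param outputDir directory for the report bundle (created if needed).
#' @param loci loci analysed.
#' @param populationSet populations analysed; default all in the table.
#' @param diversityGroup population labels forming the reference group for
#'   the average-diversity summary (each member is summarised against the
#'   others); default all of \code{populationSet}.
#' @param seed integer master seed; per-stage seeds are derived from it.
#' @param params named list overriding stage parameters:
#'   \code{topThreshold} (0.05), \code{hfThreshold} (0.01), \code{emTol}
#'   (1e-8), \code{posteriorThreshold} (1e-4), \code{dememorization}
#'   (100000), \code{batches} (20), \code{stepsPerBatch} (5000),
#'   \code{ewNSim} (100000), \code{bootstrap} (50), \code{nDepths} (20).
#' @return invisibly, a list with the in-memory results and the file paths
#'   written.
#' @export
runPipeline <- function(x, outputDir, loci = c("A", "B", "C"),
                        populationSet = NULL, diversityGroup = NULL,
                        seed = 1L, params = list()) {
  p <- modifyList(list(topThreshold = 0.05, hfThreshold = 0.01, emTol = 1e-8,
                       posteriorThreshold = 1e-4, dememorization = 100000L,
                       batches = 20L, stepsPerBatch = 5000L, ewNSim = 100000L,
                       bootstrap = 50L, nDepths = 20L), params)
  if (is.character(x)) x <- cleanGenotypes(readGenotypeTable(x, loci = loci))
  stopifnot(is(x, "HLAGenotypeTable"))
  if (is.null(populationSet)) populationSet <- populations(x)
  if (is.null(diversityGroup)) diversityGroup <- populationSet
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  results <- list()
  meta0 <- list(seed = seed, loci = paste(loci, collapse = ","),
                populations = paste(populationSet, collapse = ","))

  ## allele frequencies, bins, top alleles, unique-allele summary
  freqSets <- .stage("allele_frequencies", {
    out <- list()
    for (l in loci) out[[l]] <- lapply(populationSet, function(pop)
      countAlleles(x, l, pop))
    out
  })
  freqLong <- do.call(rbind, lapply(loci, function(l)
    alleleFrequencyTable(freqSets[[l]])))
  paths["allele_frequencies"] <- .writeTable(freqLong,
    file.path(outputDir, "allele_frequencies.tsv"), meta0)
  topLong <- do.call(rbind, lapply(loci, function(l)
    do.call(rbind, lapply(freqSets[[l]], function(fs) {
      t <- topAlleles(fs, p$topThreshold)
      if (!nrow(t)) return(NULL)
      data.frame(population = fs@population, locus = l, t, stringsAsFactors = FALSE)
    }))))
  paths["top_alleles"] <- .writeTable(topLong,
    file.path(outputDir, "top_alleles.tsv"),
    c(meta0, threshold = p$topThreshold))
  if (length(populationSet) >= 2L) {
    uniq <- .stage("unique_alleles",
      do.call(rbind, lapply(loci, function(l) uniqueAlleleTable(freqSets[[l]]))))
    paths["unique_alleles"] <- .writeTable(uniq,
      file.path(outputDir, "unique_alleles.tsv"),
      c(meta0, note = "unique_freq_pct = summed relative frequency of population-unique alleles x 100"))
  }
  results$freqSets <- freqSets

  ## alpha diversity
  alpha <- .stage("alpha_diversity", alphaDiversityTable(x, loci, populationSet))
  paths["alpha_diversity"] <- .writeTable(alpha,
    file.path(outputDir, "alpha_diversity.tsv"), meta0)
  results$alpha <- alpha

  ## similarity matrices + diversity summary
  if (length(populationSet) >= 2L) {
  simList <- .stage("similarity", {
    sl <- lapply(loci, function(l) similarityMatrix(freqSets[[l]]))
    names(sl) <- loci
    sl
  })
  for (l in loci)
    paths[paste0("similarity_", l)] <- .writeMatrix(simList[[l]],
      file.path(outputDir, paste0("similarity_", l, ".csv")),
      c(meta0, note = "similarity percent = (1 - Hellinger distance) x 100"))
  divSummary <- do.call(rbind, lapply(intersect(diversityGroup, populationSet),
    function(pop) data.frame(
      population = pop,
      partners = paste(setdiff(diversityGroup, pop), collapse = ","),
      avg_diversity_pct = averageDiversity(simList, pop,
                                           setdiff(diversityGroup, pop)),
      stringsAsFactors = FALSE)))
  paths["diversity_summary"] <- .writeTable(divSummary,
    file.path(outputDir, "diversity_summary.tsv"),
    c(meta0, note = "mean over loci and partners of (100 - similarity percent)"))
  results$similarity <- simList
  results$diversitySummary <- divSummary
  }

  ## locus tests (HWE + Ewens-Watterson, BH-adjusted per locus)
  tests <- .stage("locus_tests",
    locusTests(x, loci, populationSet, seed = seed + 101L,
               dememorization = p$dememorization, batches = p$batches,
               stepsPerBatch = p$stepsPerBatch, nSim = p$ewNSim))
  paths["hwe"] <- .writeTable(tests$hwe, file.path(outputDir, "hwe.tsv"),
    c(meta0, dememorization = p$dememorization, batches = p$batches,
      steps_per_batch = p$stepsPerBatch,
      note = "exp_het uses the 2n/(2n-1) unbiased correction; p_adj = BH across populations within locus"))
  paths["ew"] <- .writeTable(tests$ew, file.path(outputDir, "ew.tsv"),
    c(meta0, n_sim = p$ewNSim,
      note = "lower-tail p under Ewens sampling formula conditional on (2n, k); p_adj = BH across populations within locus"))
  results$tests <- tests

  ## haplotypes, cartography, ALD
  combos <- list(c("A", "B"), c("A", "C"), c("B", "C"), c("A", "B", "C"))
  combos <- Filter(function(cb) all(cb %in% loci), combos)
  hapSetsByCombo <- .stage("haplotypes", {
    out <- list()
    for (cb in combos) {
      key <- paste(cb, collapse = "")
      out[[key]] <- lapply(populationSet, function(pop)
        emHaplotypes(x, loci = cb, population = pop, tol = p$emTol,
                     posteriorThreshold = p$posteriorThreshold))
      names(out[[key]]) <- populationSet
    }
    out
  })
  for (key in names(hapSetsByCombo)) {
    hl <- do.call(rbind, lapply(populationSet, function(pop) {
      hs <- hapSetsByCombo[[key]][[pop]]
      tab <- haplotypes(hs)
      data.frame(population = pop, loci = paste(hs@loci, collapse = ":"),
                 haplotype = tab$haplotype, frequency = tab$frequency,
                 rank = seq_len(nrow(tab)), stringsAsFactors = FALSE)
    }))
    paths[paste0("haplotypes_", key)] <- .writeTable(hl,
      file.path(outputDir, paste0("haplotypes_", key, ".tsv")),
      c(meta0, em_tol = p$emTol, posterior_threshold = p$posteriorThreshold))
  }
  results$haplotypes <- hapSetsByCombo

  mds <- .stage("cartography", {
    out <- list()
    for (key in names(hapSetsByCombo)) {
      if (length(populationSet) < 2L) break
      prof <- profileMatrix(hapSetsByCombo[[key]], threshold = p$hfThreshold)
      D <- populationDistances(prof)
      fit <- classicalMDS(D, dims = 2L)
      share <- round(100 * fit$varianceExplained, 2)
      out[[key]] <- data.frame(population = rownames(fit$points),
                               dim1 = fit$points[, 1], dim2 = fit$points[, 2],
                               stringsAsFactors = FALSE)
      paths[paste0("mds_", key)] <- .writeTable(out[[key]],
        file.path(outputDir, paste0("mds_", key, ".csv")),
        c(meta0, hf_threshold = p$hfThreshold,
          variance_explained_pct = paste(share, collapse = " ")))
    }
    out
  })
  results$mds <- mds

  aldLong <- .stage("ald", {
    do.call(rbind, lapply(populationSet, function(pop) {
      pairs <- Filter(function(cb) length(cb) == 2L, combos)
      do.call(rbind, lapply(pairs, function(cb) {
        key <- paste(cb, collapse = "")
        r <- ald(hapSetsByCombo[[key]][[pop]])
        data.frame(population = pop,
                   focal = c(cb[1], cb[2]), conditioning = c(cb[2], cb[1]),
                   W = c(r$W_A_given_B, r$W_B_given_A),
                   stringsAsFactors = FALSE)
      }))
    }))
  })
  paths["ald"] <- .writeTable(aldLong, file.path(outputDir, "ald.tsv"),
    c(meta0, note = "W = ALD of focal locus conditioned on conditioning locus"))
  results$ald <- aldLong

  ## co-occurrence and rarefaction
  pairsLong <- .stage("pair_frequencies",
    do.call(rbind, lapply(populationSet, function(pop)
      do.call(rbind, lapply(loci, function(l) pairFrequencies(x, l, pop))))))
  paths["pair_frequencies"] <- .writeTable(pairsLong,
    file.path(outputDir, "pair_frequencies.tsv"), meta0)
  results$pairs <- pairsLong

  rare <- .stage("rarefaction",
    do.call(rbind, lapply(populationSet, function(pop)
      do.call(rbind, lapply(loci, function(l)
        rarefactionCurve(x, l, pop, nDepths = p$nDepths,
                         bootstrap = p$bootstrap, seed = seed + 757L))))))
  paths["rarefaction"] <- .writeTable(rare,
    file.path(outputDir, "rarefaction.tsv"),
    c(meta0, bootstrap = p$bootstrap,
      note = "interpolation is the exact hypergeometric expectation; extrapolation Chao1-type with percentile bootstrap CI"))
  results$rarefaction <- rare

  manifest <- list(package = "hlaDiversity",
                   version = as.character(utils::packageVersion("hlaDiversity")),
                   seed = seed, loci = loci, populations = populationSet,
                   diversity_group = diversityGroup, parameters = p,
                   n_subjects = nSubjects(x),
                   artifacts = as.list(basename(paths)))
  manifestPath <- file.path(outputDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, pretty = TRUE)
  paths["manifest"] <- manifestPath

  results$paths <- paths
  invisible(results)
}
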