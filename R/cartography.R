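#' Thresholded haplotype-frequency profile matrix
#'
#' Builds the populations x haplotypes matrix of relative haplotype
#' frequencies used for genetic cartography. A haplotype is retained when
#' its frequency reaches \code{threshold} in at least one population (the
#' conventional 1\% rule); a haplotype missing from a population scores 0.
#'
#' @param hapSets named list of \code{HaplotypeFrequencySet} objects (one
#'   per population) for the same locus combination.
#' @param threshold minimum relative haplotype frequency.
#' @return numeric matrix (populations x haplotypes) with attribute
#'   \code{"loci"}.
#' @export
profileMatrix <- function(hapSets, threshold = 0.01) {
  stopifnot(length(hapSets) >= 2L, !is.null(names(hapSets)))
  loci <- unique(lapply(hapSets, function(h) h@loci))
  if (length(loci) != 1L) stop("all haplotype sets must share one locus combination")
  freqs <- lapply(hapSets, function(h) setNames(h@table$frequency, h@table$haplotype))
  keep <- sort(unique(unlist(lapply(freqs, function(f) names(f)[f >= threshold]))))
  if (!length(keep)) stop("no haplotype reaches the threshold in any population")
  M <- matrix(0, length(hapSets), length(keep),
              dimnames = list(names(hapSets), keep))
  for (i in seq_along(freqs)) {
    f <- freqs[[i]][intersect(names(freqs[[i]]), keep)]
    M[i, names(f)] <- f
  }
  attr(M, "loci") <- loci[[1]]
  M
}

#' Distances between population haplotype profiles
#'
#' @param profiles matrix from \code{\link{profileMatrix}}.
#' @param metric \code{"euclidean"} (default) on the relative-frequency
#'   rows, or \code{"hellinger"} on the row-renormalised profiles.
#' @return symmetric distance matrix with zero diagonal.
#' @export
populationDistances <- function(profiles, metric = c("euclidean", "hellinger")) {
  metric <- match.arg(metric)
  m <- nrow(profiles)
  D <- matrix(0, m, m, dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(m - 1)) for (j in seq.int(i + 1, m)) {
    if (metric == "euclidean") {
      d <- sqrt(sum((profiles[i, ] - profiles[j, ])^2))
    } else {
      p <- profiles[i, ] / sum(profiles[i, ])
      q <- profiles[j, ] / sum(profiles[j, ])
      d <- sqrt(max(0, 1 - sum(sqrt(p * q))))
    }
    D[i, j] <- d; D[j, i] <- d
  }
  D
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Torgerson scaling: double-centering of squared distances and
#' eigendecomposition (via \code{stats::cmdscale}), retaining the top
#' \code{dims} axes scaled by the square roots of their eigenvalues.
#' Negative eigenvalues (non-Euclidean input) are truncated with a warning.
#' The embedding is canonicalised so the first row has non-negative
#' coordinates on every axis, fixing the rotation/reflection freedom.
#'
#' @param D square symmetric non-negative matrix with zero diagonal.
#' @param dims number of output dimensions.
#' @return list with \code{points} (rows = objects), \code{eig}
#'   (eigenvalues), \code{varianceExplained} (share of the positive
#'   eigenvalue mass on the retained axes).
#' @export
classicalMDS <- function(D, dims = 2L) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(D < 0) || any(abs(diag(D)) > 1e-12))
    stop("distances must be non-negative with zero diagonal")
  n <- nrow(D)
  k <- min(dims, n - 1L)
  fit <- cmdscale(D, k = k, eig = TRUE)
  if (any(fit$eig < -1e-8 * max(abs(fit$eig))))
    warning("negative eigenvalues truncated (non-Euclidean distances)")
  pts <- fit$points
  if (ncol(pts) < dims)
    pts <- cbind(pts, matrix(0, n, dims - ncol(pts)))
  ## canonical orientation: first object non-negative on each axis
  for (a in seq_len(ncol(pts)))
    if (pts[1, a] < 0) pts[, a] <- -pts[, a]
  rownames(pts) <- rownames(D)
  colnames(pts) <- paste0("dim", seq_len(ncol(pts)))
  posMass <- sum(pmax(fit$eig, 0))
  ve <- if (posMass > 0) pmax(fit$eig[seq_len(min(dims, length(fit$eig)))], 0) / posMass
        else rep(0, dims)
  list(points = pts, eig = fit$eig, varianceExplained = ve)
}

#' Two-dimensional genetic cartography of populations
#'
#' Convenience wrapper: per-population EM haplotype frequencies for the
#' requested locus combination, thresholded profile matrix, distances and
#' classical MDS.
#'
#' @param x an \code{HLAGenotypeTable}.
#' @param loci locus combination (2 or 3 loci).
#' @param populationSet populations; default all.
#' @param threshold haplotype frequency threshold for the profile matrix.
#' @param metric distance metric, see \code{\link{populationDistances}}.
#' @param ... passed to \code{\link{emHaplotypes}}.
#' @return list with \code{embedding} (data.frame population, dim1, dim2),
#'   \code{distances}, \code{profiles}, \code{mds}.
#' @export
haplotypeCartography <- function(x, loci, populationSet = populations(x),
                                 threshold = 0.01, metric = "euclidean", ...) {
  hapSets <- lapply(populationSet, function(p)
    emHaplotypes(x, loci = loci, population = p, ...))
  names(hapSets) <- populationSet
  prof <- profileMatrix(hapSets, threshold = threshold)
  D <- populationDistances(prof, metric = metric)
  mds <- classicalMDS(D, dims = 2L)
  emb <- data.frame(population = rownames(mds$points),
                    dim1 = mds$points[, 1], dim2 = mds$points[, 2],
                    stringsAsFactors = FALSE, row.names = NULL)
  list(embedding = emb, distances = D, profiles = prof, mds = mds)
}
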