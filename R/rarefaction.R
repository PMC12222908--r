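## Rarefaction and extrapolation of allelic richness versus participants.
##
## The subsampling unit is the participant (two gene copies). Interpolation
## has an exact hypergeometric form: with N participants of whom m_a carry
## allele a, the expected richness in a random subsample of n participants is
##   E[S(n)] = sum_a [ 1 - C(N - m_a, n) / C(N, n) ].
## Extrapolation uses the Chao1 asymptote on gene-copy abundances (f1
## singletons, f2 doubletons) with the standard abundance-based completion
## curve; 95% CIs come from a percentile bootstrap over participants.

.lchooseSafe <- function(n, k) ifelse(k > n, -Inf, lchoose(n, k))

.richnessInterp <- function(carriers, N, depths) {
  vapply(depths, function(n) {
    sum(1 - exp(.lchooseSafe(N - carriers, n) - lchoose(N, n)))
  }, numeric(1))
}

.chaoF0 <- function(f1, f2) {
  if (f1 == 0) return(0)
  if (f2 > 0) f1^2 / (2 * f2) else f1 * (f1 - 1) / 2
}

.richnessExtrap <- function(copyCounts, N, depths) {
  Sobs <- length(copyCounts)
  g <- sum(copyCounts)          # gene copies = 2N
  f1 <- sum(copyCounts == 1L)
  f2 <- sum(copyCounts == 2L)
  f0 <- .chaoF0(f1, f2)
  vapply(depths, function(n) {
    mstar <- 2 * (n - N)        # additional gene copies
    if (f0 == 0 || f1 == 0) return(Sobs)
    Sobs + f0 * (1 - (1 - f1 / (g * f0 + f1))^mstar)
  }, numeric(1))
}

.carriersAndCopies <- function(calls) {
  full <- !is.na(calls[, 1]) & !is.na(calls[, 2])
  calls <- calls[full, , drop = FALSE]
  alleles <- unique(c(calls[, 1], calls[, 2]))
  carriers <- vapply(alleles, function(a)
    sum(calls[, 1] == a | calls[, 2] == a), integer(1))
  copies <- table(c(calls[, 1], calls[, 2]))
  list(calls = calls, N = nrow(calls), carriers = carriers,
       copies = as.integer(copies))
}

#' Rarefy allelic richness by participant subsampling
#'
#' Expected number of distinct alleles in random subsamples of participants
#' drawn without replacement. \code{reps = 0} returns the exact
#' hypergeometric expectation; otherwise the Monte Carlo mean over
#' \code{reps} subsamples is returned together with its standard error.
#' At depth \eqn{N_p} (all participants) the observed richness is returned
#' exactly.
#'
#' @param x an \code{HLAGenotypeTable}.
#' @param locus locus code.
#' @param population,tribe optional subject selection.
#' @param depths participant counts between 1 and \eqn{N_p}.
#' @param reps Monte Carlo subsamples per depth (0 = analytic).
#' @param seed optional integer seed for the Monte Carlo path.
#' @return data.frame (depth, estimate, se, mode = "interpolated").
#' @export
rarefyRichness <- function(x, locus, population = NULL, tribe = NULL,
                           depths = NULL, reps = 0L, seed = NULL) {
  calls <- alleleCalls(selectPopulation(x, population, tribe), locus)
  info <- .carriersAndCopies(calls)
  if (info$N == 0L) stop("no fully typed subjects")
  if (is.null(depths)) depths <- unique(round(seq(1, info$N, length.out = min(info$N, 25))))
  if (any(depths < 1 | depths > info$N)) stop("depths must lie in 1..N_p")
  if (reps > 0L) {
    if (!is.null(seed)) set.seed(seed)
    est <- se <- numeric(length(depths))
    for (d in seq_along(depths)) {
      richness <- vapply(seq_len(reps), function(r) {
        idx <- sample.int(info$N, depths[d])
        length(unique(c(info$calls[idx, 1], info$calls[idx, 2])))
      }, numeric(1))
      est[d] <- mean(richness)
      se[d] <- sd(richness) / sqrt(reps)
    }
  } else {
    est <- .richnessInterp(info$carriers, info$N, depths)
    se <- rep(0, length(depths))
  }
  data.frame(depth = depths, estimate = est, se = se, mode = "interpolated",
             stringsAsFactors = FALSE)
}

#' Extrapolate allelic richness beyond the sample size
#'
#' Chao1-type extrapolation on gene-copy abundances with a percentile
#' bootstrap confidence interval from resampled participants. With no
#' singletons the asymptote equals the observed richness and the curve is
#' flat (degenerate CI, warning).
#'
#' @inheritParams rarefyRichness
#' @param depths participant counts greater than \eqn{N_p}.
#' @param bootstrap number of bootstrap resamples for the 95\% CI.
#' @param seed optional integer seed.
#' @return data.frame (depth, estimate, ci_low, ci_high, mode =
#'   "extrapolated").
#' @export
extrapolateRichness <- function(x, locus, population = NULL, tribe = NULL,
                                depths, bootstrap = 50L, seed = NULL) {
  calls <- alleleCalls(selectPopulation(x, population, tribe), locus)
  info <- .carriersAndCopies(calls)
  if (any(depths <= info$N)) stop("extrapolation depths must exceed N_p")
  est <- .richnessExtrap(info$copies, info$N, depths)
  f1 <- sum(info$copies == 1L)
  if (f1 == 0)
    warning("no singleton alleles: asymptote equals observed richness, CI degenerate")
  if (!is.null(seed)) set.seed(seed)
  boot <- matrix(NA_real_, bootstrap, length(depths))
  for (b in seq_len(bootstrap)) {
    idx <- sample.int(info$N, info$N, replace = TRUE)
    cc <- table(c(info$calls[idx, 1], info$calls[idx, 2]))
    boot[b, ] <- .richnessExtrap(as.integer(cc), info$N, depths)
  }
  ## percentile bootstrap recentred on the point estimate (the bootstrap
  ## understates singletons, so raw percentiles can sit below the estimate)
  ci <- apply(boot, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  shift <- est - colMeans(boot)
  ciLow <- pmin(est, ci[1, ] + shift)
  ciHigh <- pmax(est, ci[2, ] + shift)
  data.frame(depth = depths, estimate = est, ci_low = ciLow,
             ci_high = ciHigh, mode = "extrapolated", stringsAsFactors = FALSE)
}

#' Combined rarefaction-extrapolation curve
#'
#' Interpolated expected richness up to the observed number of participants
#' and Chao1-type extrapolation beyond it, with bootstrap 95\% CIs on the
#' extrapolated part.
#'
#' @inheritParams rarefyRichness
#' @param extrapolateTo largest participant depth (default twice \eqn{N_p}).
#' @param nDepths approximate number of grid depths on each branch.
#' @param bootstrap bootstrap resamples for the extrapolation CI.
#' @return data.frame (population, locus, depth, mode, estimate, ci_low,
#'   ci_high); on the interpolated branch the CI equals the estimate (the
#'   hypergeometric form is exact).
#' @export
rarefactionCurve <- function(x, locus, population = NULL, tribe = NULL,
                             extrapolateTo = NULL, nDepths = 20L,
                             bootstrap = 50L, seed = NULL) {
  calls <- alleleCalls(selectPopulation(x, population, tribe), locus)
  info <- .carriersAndCopies(calls)
  N <- info$N
  if (is.null(extrapolateTo)) extrapolateTo <- 2L * N
  dIn <- unique(round(seq(1, N, length.out = min(N, nDepths))))
  ri <- rarefyRichness(x, locus, population, tribe, depths = dIn)
  ri$ci_low <- ri$estimate; ri$ci_high <- ri$estimate
  ri$se <- NULL
  out <- ri
  if (extrapolateTo > N) {
    dEx <- unique(round(seq(N + 1, extrapolateTo,
                            length.out = min(extrapolateTo - N, nDepths))))
    ex <- suppressWarnings(
      extrapolateRichness(x, locus, population, tribe, depths = dEx,
                          bootstrap = bootstrap, seed = seed))
    out <- rbind(ri[, c("depth", "estimate", "ci_low", "ci_high", "mode")],
                 ex[, c("depth", "estimate", "ci_low", "ci_high", "mode")])
  }
  out$population <- if (is.null(population)) "all" else paste(population, collapse = "/")
  out$locus <- locus
  rownames(out) <- NULL
  out[, c("population", "locus", "depth", "mode", "estimate", "ci_low", "ci_high")]
}
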