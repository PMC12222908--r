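# Independent oracles used to check the package's estimators on small
# fixtures: full enumeration of genotype tables under Levene's conditional
# distribution, full-space EM without progressive insertion or trimming,
# and partition enumeration for the conditional Ewens null.

# --- genotype-table enumeration for the exact HWE test ---------------------

# all genotype tables (counts n_ij, i <= j) compatible with allele counts m;
# returns list of k x k upper-triangular count matrices
enumerateTables <- function(m) {
  k <- length(m)
  cells <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  out <- list()
  recur <- function(idx, rem, acc) {
    if (idx > nrow(cells)) {
      if (all(rem == 0)) out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    i <- cells[idx, 1]; j <- cells[idx, 2]
    maxN <- if (i == j) rem[i] %/% 2 else min(rem[i], rem[j])
    for (n in 0:maxN) {
      rem2 <- rem
      if (i == j) rem2[i] <- rem2[i] - 2 * n
      else { rem2[i] <- rem2[i] - n; rem2[j] <- rem2[j] - n }
      acc2 <- acc; acc2[i, j] <- n
      recur(idx + 1L, rem2, acc2)
    }
  }
  recur(1L, m, matrix(0L, k, k))
  out
}

# Levene conditional log-probability of a genotype table
leveneLogProb <- function(tab, m) {
  n <- sum(tab)
  het <- sum(tab[upper.tri(tab)])
  lgamma(n + 1) + het * log(2) + sum(lgamma(m + 1)) -
    lgamma(2 * n + 1) - sum(lgamma(tab[upper.tri(tab, diag = TRUE)] + 1))
}

# exact conditional p: mass of tables no more probable than the observed
hweExactOracle <- function(calls) {
  alleles <- sort(unique(c(calls[, 1], calls[, 2])))
  k <- length(alleles)
  m <- as.integer(table(factor(c(calls[, 1], calls[, 2]), levels = alleles)))
  obs <- matrix(0L, k, k)
  for (r in seq_len(nrow(calls))) {
    i <- match(calls[r, 1], alleles); j <- match(calls[r, 2], alleles)
    if (i > j) { t <- i; i <- j; j <- t }
    obs[i, j] <- obs[i, j] + 1L
  }
  tabs <- enumerateTables(m)
  lp <- vapply(tabs, leveneLogProb, numeric(1), m = m)
  lpObs <- leveneLogProb(obs, m)
  stopifnot(abs(sum(exp(lp)) - 1) < 1e-9)
  sum(exp(lp[lp <= lpObs + 1e-9]))
}

# --- brute-force EM over the full haplotype space --------------------------

# genotypes: list per locus of 2-column allele matrices (same subjects);
# plain EM over every combination of observed alleles, product start
emBruteForce <- function(genotypes, tol = 1e-10, maxIter = 20000) {
  L <- length(genotypes)
  n <- nrow(genotypes[[1]])
  alleles <- lapply(genotypes, function(g) sort(unique(c(g))))
  space <- expand.grid(rev(alleles), stringsAsFactors = FALSE)[, L:1, drop = FALSE]
  H <- nrow(space)
  hapKey <- apply(space, 1, paste, collapse = "~")
  marg <- lapply(seq_len(L), function(l) {
    tab <- table(c(genotypes[[l]]))
    tab / sum(tab)
  })
  f <- rep(1, H)
  for (l in seq_len(L)) f <- f * as.numeric(marg[[l]][space[, l]])
  f <- f / sum(f)
  # compatibility: unordered pair (h1, h2) explains subject s?
  compat <- vector("list", n)
  for (s in seq_len(n)) {
    pairs <- list()
    for (h1 in seq_len(H)) for (h2 in h1:H) {
      ok <- TRUE
      for (l in seq_len(L)) {
        g <- sort(c(genotypes[[l]][s, 1], genotypes[[l]][s, 2]))
        hap <- sort(c(space[h1, l], space[h2, l]))
        if (!identical(g, hap)) { ok <- FALSE; break }
      }
      if (ok) pairs[[length(pairs) + 1L]] <- c(h1, h2)
    }
    compat[[s]] <- do.call(rbind, pairs)
  }
  ll_old <- -Inf
  for (iter in seq_len(maxIter)) {
    ll <- 0
    cnt <- numeric(H)
    for (s in seq_len(n)) {
      pr <- compat[[s]]
      w <- ifelse(pr[, 1] == pr[, 2], 1, 2) * f[pr[, 1]] * f[pr[, 2]]
      S <- sum(w)
      ll <- ll + log(S)
      w <- w / S
      for (r in seq_len(nrow(pr))) {
        cnt[pr[r, 1]] <- cnt[pr[r, 1]] + w[r]
        cnt[pr[r, 2]] <- cnt[pr[r, 2]] + w[r]
      }
    }
    f <- cnt / (2 * n)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(freq = setNames(f, hapKey), logLik = ll, iterations = iter)
}

# --- conditional Ewens null by partition enumeration -----------------------

# partitions of g into exactly k positive non-increasing parts
partitionsOracle <- function(g, k, cap = g) {
  if (k == 0L) return(if (g == 0L) list(integer()) else list())
  out <- list()
  for (first in seq_len(min(cap, g - k + 1L))) {
    if (first * k < g) next
    for (rest in partitionsOracle(g - first, k - 1L, first))
      out[[length(out) + 1L]] <- c(first, rest)
  }
  out
}

ewNullOracle <- function(g, k) {
  parts <- partitionsOracle(g, k)
  w <- vapply(parts, function(p) {
    a <- tabulate(p)
    js <- which(a > 0)
    exp(-sum(a[js] * log(js)) - sum(lgamma(a[js] + 1)))
  }, numeric(1))
  w <- w / sum(w)
  Fv <- vapply(parts, function(p) sum((p / g)^2), numeric(1))
  list(prob = w, F = Fv,
       Fexp = sum(w * Fv),
       sdF = sqrt(max(0, sum(w * Fv^2) - sum(w * Fv)^2)),
       pLower = function(Fobs) sum(w[Fv <= Fobs + 1e-12]))
}

# --- small-cohort construction ---------------------------------------------

# build an HLAGenotypeTable from per-locus genotype string pairs
makeCohort <- function(..., country = "P") {
  loci <- names(list(...))
  g <- list(...)
  n <- nrow(g[[1]])
  d <- data.frame(PID = paste0("s", seq_len(n)), country = country,
                  stringsAsFactors = FALSE)
  for (l in loci) {
    d[[paste0(l, "_1")]] <- g[[l]][, 1]
    d[[paste0(l, "_2")]] <- g[[l]][, 2]
  }
  genotypeTable(d, loci = loci)
}

# random discrete distribution for property tests
randomDistribution <- function(k) {
  w <- rexp(k)
  w / sum(w)
}
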