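#' Simulation configuration for a synthetic genotype cohort
#'
#' Describes one population: its label, size, optional tribe composition,
#' an explicit three-locus haplotype frequency table (linkage
#' disequilibrium is encoded directly in the haplotype frequencies, which
#' makes the generator exact and directly comparable with the EM and ALD
#' estimators), an inbreeding coefficient and a genotyping error rate.
#'
#' @param label population (country) label.
#' @param n number of subjects.
#' @param haplotypes data.frame with one allele column per locus (named by
#'   locus) and a \code{freq} column summing to 1.
#' @param loci locus codes, matching the haplotype column names.
#' @param tribes optional named integer vector of tribe sizes (must not
#'   exceed \code{n}; remaining subjects carry no tribe label).
#' @param f inbreeding coefficient in [0, 1]: probability a subject is
#'   autozygous (one haplotype duplicated).
#' @param errorRate per-allele-call genotyping error rate: with this
#'   probability a call is replaced by a different random allele from the
#'   population's pool at that locus.
#' @return a \code{simulationConfig} object (list).
#' @export
simulationConfig <- function(label, n, haplotypes, loci = c("A", "B", "C"),
                             tribes = NULL, f = 0, errorRate = 0) {
  stopifnot(is.data.frame(haplotypes), all(loci %in% names(haplotypes)),
            "freq" %in% names(haplotypes))
  if (abs(sum(haplotypes$freq) - 1) > 1e-8)
    stop("haplotype frequencies must sum to 1")
  if (any(haplotypes$freq < 0)) stop("negative haplotype frequency")
  if (f < 0 || f > 1) stop("inbreeding coefficient must lie in [0, 1]")
  if (errorRate < 0 || errorRate > 1) stop("error rate must lie in [0, 1]")
  if (!is.null(tribes) && sum(tribes) > n)
    stop("tribe sizes exceed the population size")
  structure(list(label = label, n = as.integer(n), haplotypes = haplotypes,
                 loci = loci, tribes = tribes, f = f, errorRate = errorRate),
            class = "simulationConfig")
}

## deterministic per-population seed stream derived from one global seed, so
## adding a population does not perturb earlier populations' draws
.streamSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 131) %% 2147483647)
}

#' Simulate a genotype cohort from a configuration
#'
#' Subjects are drawn as two haplotypes from the configured three-locus
#' haplotype distribution; with inbreeding coefficient \code{f} a subject is
#' autozygous (its first haplotype is duplicated) with probability \code{f};
#' genotyping error then replaces allele calls independently at the stated
#' rate. Deterministic under a fixed seed.
#'
#' @param config a \code{\link{simulationConfig}}, or a list of them (the
#'   per-population draws come from independent seed streams derived from
#'   \code{seed}).
#' @param seed integer seed.
#' @return an \code{HLAGenotypeTable} (cleaned: PIDs unique by construction).
#' @export
simulatePopulation <- function(config, seed) {
  if (is.list(config) && !inherits(config, "simulationConfig")) {
    tabs <- lapply(config, simulatePopulation, seed = seed)
    d <- do.call(rbind, lapply(tabs, function(t) t@data))
    rownames(d) <- NULL
    return(new("HLAGenotypeTable", data = d, loci = tabs[[1]]@loci, cleaned = TRUE))
  }
  stopifnot(inherits(config, "simulationConfig"))
  set.seed(.streamSeed(seed, config$label))
  n <- config$n
  hp <- config$haplotypes
  loci <- config$loci

  i1 <- sample.int(nrow(hp), n, replace = TRUE, prob = hp$freq)
  i2 <- sample.int(nrow(hp), n, replace = TRUE, prob = hp$freq)
  auto <- runif(n) < config$f
  i2[auto] <- i1[auto]

  d <- data.frame(PID = sprintf("%s_%05d", config$label, seq_len(n)),
                  country = config$label, tribe = NA_character_,
                  stringsAsFactors = FALSE)
  if (!is.null(config$tribes)) {
    lab <- rep(names(config$tribes), config$tribes)
    d$tribe[seq_along(lab)] <- lab
  }
  for (l in loci) {
    a1 <- hp[[l]][i1]
    a2 <- hp[[l]][i2]
    if (config$errorRate > 0) {
      pool <- unique(hp[[l]])
      if (length(pool) > 1L) {
        for (v in c("a1", "a2")) {
          x <- get(v)
          hit <- which(runif(n) < config$errorRate)
          for (s in hit) x[s] <- sample(setdiff(pool, x[s]), 1L)
          assign(v, x)
        }
      }
    }
    d[[paste0(l, "_1")]] <- pmin(a1, a2)
    d[[paste0(l, "_2")]] <- pmax(a1, a2)
  }
  new("HLAGenotypeTable",
      data = d[, c("PID", "country", "tribe", .alleleCols(loci))],
      loci = loci, cleaned = TRUE)
}

## skewed (geometric-tail) allele frequency spectrum over a population's
## allele pool, with a per-population shuffle so top alleles overlap across
## populations without being identical
.skewedSpectrum <- function(alleles, decay = 0.85, jitterSD = 3) {
  k <- length(alleles)
  rank <- order(seq_len(k) + rnorm(k, sd = jitterSD))
  w <- decay^(order(rank) - 1)
  setNames(w / sum(w), alleles)
}

## mixture haplotype table: locus B drives both partners; coupling is the
## probability that the partner allele is the B allele's preferred partner
## rather than an independent draw from the partner marginal
.mixtureHaplotypes <- function(fA, fB, fC, couplingAB, couplingBC) {
  rows <- list()
  aAll <- names(fA); cAll <- names(fC)
  prefA <- sample(aAll, length(fB), replace = TRUE, prob = fA)
  prefC <- sample(cAll, length(fB), replace = TRUE, prob = fC)
  for (bi in seq_along(fB)) {
    pa <- (1 - couplingAB) * fA
    pa[prefA[bi]] <- pa[prefA[bi]] + couplingAB
    pc <- (1 - couplingBC) * fC
    pc[prefC[bi]] <- pc[prefC[bi]] + couplingBC
    ## drop negligible cells to keep the table sparse
    pa <- pa[pa > 1e-7]; pc <- pc[pc > 1e-7]
    grid <- expand.grid(A = names(pa), C = names(pc), stringsAsFactors = FALSE)
    rows[[bi]] <- data.frame(A = grid$A, B = names(fB)[bi], C = grid$C,
                             freq = fB[bi] * as.numeric(pa[grid$A]) *
                               as.numeric(pc[grid$C]),
                             stringsAsFactors = FALSE)
  }
  hp <- do.call(rbind, rows)
  hp$freq <- hp$freq / sum(hp$freq)
  rownames(hp) <- NULL
  hp
}

#' Reference seven-population synthetic panel
#'
#' Generates a panel emulating the structure of a multi-country class I HLA
#' survey: seven cohorts (Kenya, Rwanda, South Africa, Uganda, Zambia,
#' EUAM, AFAM) with sizes 109, 173, 1640, 231, 565, 1765 and 661; skewed
#' allele frequency spectra with more alleles at HLA-B than HLA-A than
#' HLA-C; stronger haplotype coupling between HLA-B and HLA-C than for
#' pairs involving HLA-A; and nested tribe labels for Kenya, Uganda, Zambia
#' and South Africa. African populations share most of their allele pools;
#' the US cohorts overlap partially and carry private alleles, giving the
#' panel its between-continent contrast.
#'
#' @param seed integer seed; the panel is deterministic given the seed.
#' @return an \code{HLAGenotypeTable} with attribute \code{"configs"}: the
#'   list of \code{\link{simulationConfig}} objects used (true parameters,
#'   for recovery checks).
#' @export
referencePanel <- function(seed = 1L) {
  sizes <- c(Kenya = 109L, Rwanda = 173L, SouthAfrica = 1640L, Uganda = 231L,
             Zambia = 565L, EUAM = 1765L, AFAM = 661L)
  tribes <- list(
    Kenya = c(Kikuyu = 25L, Luhya = 21L),
    Uganda = c(Muganda = 134L, Munyankole = 25L, Munyarwanda = 26L),
    Zambia = c(Bemba = 142L, Chewa = 63L, Lozi = 23L, Ngoni = 44L,
               Nsenga = 70L, Tonga = 29L, Tumbuka = 29L),
    SouthAfrica = c(Zulu = 1624L))
  pool <- list(A = sprintf("A*%02d:01", 1:60),
               B = sprintf("B*%02d:01", 1:90),
               C = sprintf("C*%02d:01", 1:45))
  ## per-population pool sizes: B richest, C poorest (survey-like magnitudes)
  kA <- c(Kenya = 30, Rwanda = 32, SouthAfrica = 45, Uganda = 33, Zambia = 38,
          EUAM = 45, AFAM = 42)
  share <- c(A = 18, B = 26, C = 14)   # alleles common to every population

  configs <- list()
  for (p in names(sizes)) {
    set.seed(.streamSeed(seed, paste0("pool:", p)))
    african <- !(p %in% c("EUAM", "AFAM"))
    freqs <- list()
    for (l in c("A", "B", "C")) {
      k <- round(kA[[p]] * c(A = 1, B = 1.45, C = 0.75)[[l]])
      common <- pool[[l]][seq_len(share[[l]])]
      ## African cohorts draw their tails from the front half of the global
      ## pool, US cohorts from the back half plus some overlap
      tailPool <- if (african) setdiff(pool[[l]][seq_len(ceiling(length(pool[[l]]) * 0.8))], common)
                  else setdiff(pool[[l]], common)
      extra <- sample(tailPool, k - length(common))
      ## HLA-B spectra are flatter (lower top-allele frequencies, longer
      ## observable tail) than A; C is the most concentrated
      decay <- c(A = 0.82, B = 0.9, C = 0.8)[[l]]
      ## US cohorts rank the shared alleles very differently, mirroring the
      ## between-continent frequency contrast
      freqs[[l]] <- .skewedSpectrum(c(common, extra), decay = decay,
                                    jitterSD = if (african) 3 else 9)
    }
    hp <- .mixtureHaplotypes(freqs$A, freqs$B, freqs$C,
                             couplingAB = 0.35, couplingBC = 0.75)
    configs[[p]] <- simulationConfig(p, sizes[[p]], hp,
                                     tribes = tribes[[p]])
  }
  panel <- simulatePopulation(configs, seed = seed)
  attr(panel, "configs") <- configs
  panel
}
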