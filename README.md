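# hlaDiversity

Population-genetic analysis of class I HLA (HLA-A, -B, -C) genotype cohorts
typed at two-field resolution, for immunogenetics groups characterising
allele and haplotype diversity within and between populations — the kind of
multi-country survey used to argue that T-cell vaccine design needs
population-specific HLA data.

From a plain genotype table (one row per subject: ID, country, optional
tribe, two alleles per locus) the package computes:

* **Allele frequencies** by direct counting (each fully typed subject
  contributes two gene copies; `p̂_a = n_a / 2n`), with the conventional
  high (≥ 5%) / intermediate / low (< 1%) binning, top-allele lists and
  population-unique allele summaries.
* **Haplotype frequencies** from unphased genotypes by
  expectation–maximisation with progressive locus insertion: EM on the
  first two loci, insertion of each further locus with trimming of partial
  phase expansions whose posterior falls below 10⁻⁴, then EM to
  convergence (|Δ log L| < 10⁻⁸ relative). Output in tilde notation, e.g.
  `A*30:01~B*42:01~C*17:01`.
* **Exact Hardy–Weinberg tests** by Markov chain Monte Carlo on the
  conditional (Levene) distribution of genotype tables given allele
  counts — gene-copy swaps between individuals with 100,000 dememorisation
  steps, p-value = chain mass of tables no more probable than the observed
  one, batch-means standard errors — plus observed and unbiased expected
  heterozygosity `(2n/(2n−1))(1 − Σp²)`.
* **Ewens–Watterson homozygosity tests of neutrality** (Slatkin-style):
  `F = Σp²` against its null under the Ewens sampling formula conditional
  on (2n, k) — exact partition enumeration when feasible, otherwise a
  Metropolis sampler on allele-count configurations (`P ∝ Π 1/nᵢ`) — with
  the normalised deviate `Fnd = (F_obs − F_exp)/sd(F)` and a lower-tail
  p-value (small p ⇒ excess evenness ⇒ balancing selection).
* **Asymmetric linkage disequilibrium**:
  `W_{A|B} = sqrt((F(A/B) − F(A)) / (1 − F(A)))` with
  `F(A/B) = Σ_b Σ_a h²_ab / f_b`, computed in both directions for every
  locus pair from EM haplotype frequencies; equals |r| for bi-allelic loci.
* **Diversity indices**: Shannon entropy and Gini–Simpson within
  populations; Hellinger distance `HD = sqrt(1 − Σ√(p·q))` between
  populations, reported as similarity percentages `(1 − HD) × 100` and as
  average-diversity summaries (mean of `100 − similarity` over loci and
  partner populations).
* **Rarefaction and extrapolation** of allelic richness versus number of
  participants: exact hypergeometric interpolation, Chao1-type asymptote on
  gene-copy abundances, 95% CIs from 50 bootstrap resamples.
* **Genetic cartography**: classical MDS of per-population haplotype
  frequency profiles (haplotypes with frequency ≥ 1% in at least one
  population), with a canonical orientation.
* **Co-occurrence tables** of within-locus allele pairs (the observable
  "inheritance pattern" behind alluvial plots).
* A **synthetic cohort generator** with explicit haplotype-frequency
  control, inbreeding and genotyping-error knobs, and a seven-population
  reference panel mirroring the structure of a multi-country survey.

Benjamini–Hochberg adjustment is applied per test type across populations
within each locus. `runPipeline()` executes everything and writes a
seeded, byte-reproducible report bundle of TSV/CSV tables plus a JSON
manifest.

## Worked example

```r
library(hlaDiversity)

panel <- referencePanel(seed = 7)   # synthetic 7-population cohort, n = 5144

countAlleles(panel, "B", "SouthAfrica")
#> AlleleFrequencySet: locus B | population SouthAfrica | 1640 subjects | 56 alleles
#>    allele count  frequency
#> 1 B*01:01   329 0.10030488
#> 2 B*02:01   285 0.08689024
#> ...

emHaplotypes(panel, c("A", "B", "C"), population = "SouthAfrica")
#> HaplotypeFrequencySet over A~B~C | 933 haplotypes | 1640 subjects
#>   logLik -17612.8028 after 99 iterations (converged)
#>                 haplotype  frequency
#> 1 A*02:01~B*02:01~C*07:01 0.03455390
#> ...

round(aldMatrix(panel, population = "SouthAfrica"), 2)
#>      A    B    C
#> A   NA 0.37 0.20
#> B 0.27   NA 0.52
#> C 0.22 0.76   NA
```

The allele table shows a skewed spectrum (top allele at 10%, a long tail
below 1%) over 56 HLA-B alleles; the EM output lists the estimated
three-locus haplotypes with their frequencies and convergence diagnostics;
the ALD matrix (entry [i, j] = W of locus i conditioned on locus j) shows
the strong, asymmetric B–C association (W of C given B = 0.76, W of B
given C = 0.52, versus ≈ 0.2–0.4 for every pair involving HLA-A) that the
panel encodes.

Locus tests:

```r
locusTests(panel, loci = "C", populationSet = c("SouthAfrica", "Zambia"),
           seed = 2)$ew
#>    population locus    n      Fobs      Fexp        Fnd       p     method  p_adj
#> 1 SouthAfrica     C 1640 0.1405259 0.1573502 -0.4251257 0.32985 montecarlo 0.3369
#> 2      Zambia     C  565 0.1591213 0.2214409 -0.6843434 0.33690 montecarlo 0.3369
```

Observed homozygosity sits below its neutral expectation (negative `Fnd`),
the signature direction of balancing selection, but not significantly so
in this synthetic panel.

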