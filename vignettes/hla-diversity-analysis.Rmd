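---
title: "Models and methods behind hlaDiversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hlaDiversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlaDiversity)
```

hlaDiversity analyses class I HLA genotype cohorts — unrelated subjects
typed at HLA-A, -B and -C at two-field resolution, grouped by country and
optionally by tribe — with the standard population-genetic toolkit for
highly multiallelic loci. This vignette documents the statistical models,
the tunable parameters and their defaults, the numerical choices, and what
the synthetic cohort generator does and does not emulate.

## Data model and cleaning

A cohort is an `HLAGenotypeTable`: one row per subject carrying an
unordered allele pair per locus. Names are canonicalised to the two-field
form `<locus>*<group>:<protein>`; higher-resolution names are truncated,
an optional `HLA-` prefix and expression suffixes (`N`, `L`, ...) are
stripped, and anything else is a parse error naming the offending token.
Truncation to two fields is the usual resolution for population-level
summaries: it aggregates synonymous and non-coding variation while keeping
the protein-level distinction that drives antigen presentation.

Cleaning applies two rules. Among rows that share a subject identifier the
row with the most non-missing allele cells is retained (ties keep the
first occurrence; both rows are logged in the cleaning report). Subjects
missing a call at a locus are excluded from analyses *of that locus only*,
so the per-locus denominators differ; this per-locus treatment maximises
usable data compared with whole-subject deletion. Cleaning is idempotent
and never modifies a retained call. No nomenclature-release conversion is
attempted: input is assumed current, and resolving typing ambiguities is a
typing-pipeline concern upstream of this package.

## Allele frequencies

Frequencies are estimated by direct counting: each fully typed subject
contributes two gene copies, so `p̂_a = n_a / (2n)`. Counts are kept as
integers alongside proportions to avoid round-trip drift. The 5% / 1%
binning (high ≥ 5%, low < 1%, intermediate between) follows the
conventional presentation of HLA spectra; the boundaries are applied
exactly as printed (0.05 is high, 0.01 is intermediate).

A population-unique allele is one whose count is non-zero in exactly one
of the populations under comparison. The "frequency of unique alleles"
summary is implemented as the summed relative frequency of a population's
unique alleles × 100 — the most natural reading of that summary — and the
definition is recorded in the output metadata since other readings exist.

## Haplotype frequencies by EM with progressive insertion

Phase is latent: a subject heterozygous at *h* of the requested loci is
compatible with 2^(h−1) unordered haplotype pairs. The EM treats the pair
as the missing datum. The E step weights each configuration by
`(2 − δ_{ij}) h_i h_j` normalised within subject; the M step sets each
haplotype frequency to its expected gamete count over 2n. The
log-likelihood is non-decreasing by construction and is asserted at every
iteration.

* **Initialisation** is the product of marginal allele frequencies,
  restricted to phase-compatible haplotypes and renormalised — a
  deterministic start, so ridge cases (e.g. a lone double heterozygote,
  whose likelihood is flat between its two phasings) resolve to the
  symmetric answer reproducibly.
* **Convergence**: relative log-likelihood change below `tol = 1e-8`, with
  `maxIter = 5000`; non-convergence returns a flagged result with a
  warning rather than an error.
* **Progressive insertion** (three or more loci): EM is run on the first
  two loci (caller-supplied order, default A, B then C); each further
  locus is inserted by expanding every retained configuration with the new
  locus' allele assignments, splitting the configuration's posterior
  uniformly over the 1–2 expansions, and trimming expansions whose
  posterior falls below `posteriorThreshold = 1e-4` before the next EM.
  The threshold is applied to insertion-time phase posteriors, the reading
  consistent with the progressive-insertion estimators used for unphased
  multiallelic data. A genotype is never left without configurations.
* **Output hygiene**: final frequencies below 1e-6 are numerical dust and
  are dropped, the rest renormalised.

With `progressive = FALSE` the EM runs over the full configuration space
from the product start for any number of loci. That mode matches a
brute-force full-haplotype-space EM to machine precision and is the
reference in the test suite; the progressive path is the production
estimator and, on small cohorts, can settle within a fraction of a
log-likelihood unit of the full optimum because its final stage starts
from the post-insertion state. Estimated frequencies at realistic sample
sizes are indistinguishable between the two modes for haplotypes above
~1% frequency.

## Exact Hardy–Weinberg testing

Conditional on the allele counts, the null distribution of the genotype
table is Levene's, and it is exactly the distribution induced by pairing
the 2n gene copies uniformly at random. The Markov chain exploits this
directly: each step picks two subjects and one gene copy from each and
swaps them — a symmetric proposal on labelled pairings, so every move is
accepted and the induced table distribution is the conditional null. The
p-value is the chain fraction of tables whose conditional probability
(`∝ 2^h / Π n_g!` on the log scale) does not exceed the observed table's.

Defaults: 100,000 dememorisation steps, then 20 batches × 5,000 recorded
steps; the batch means give the Monte Carlo standard error. A seed is
required at the pipeline level so that every table in a report is
reproducible. Monomorphic loci are a hard error (the test is undefined),
as are cohorts of fewer than two subjects. Expected heterozygosity is
reported with the `2n/(2n−1)` unbiased correction, the convention of the
population-genetics software family this analysis descends from; the
choice is recorded in the output metadata.

## Ewens–Watterson neutrality test

Observed homozygosity is `F = Σ p̂²`. The null is the Ewens sampling
formula conditional on the number of gene copies `g = 2n` and distinct
alleles `k`; in the ordered allele-count representation the conditional
law is `P(n_1..n_k) ∝ Π 1/n_i`, which the sampler exploits with
single-copy Metropolis moves (acceptance
`min(1, n_i n_j / ((n_i−1)(n_j+1)))`, burn-in 50·g steps, thinning ~g/10).
When the number of partitions of g into k parts is at most 20,000 the null
is enumerated exactly instead (`method = "auto"`). `F_exp` and `sd(F)`
come from the null, `Fnd = (F_obs − F_exp)/sd(F)`, and the default
p-value is the lower tail `P(F_null ≤ F_obs)`: observed homozygosity
below expectation (negative `Fnd`) is the balancing-selection signature of
interest at HLA loci. A two-sided variant is available behind the `tail`
flag. Sample size enters as gene copies (2n), not subjects.

Benjamini–Hochberg adjustment (via `stats::p.adjust`) is applied per test
type across populations within a locus — the family that matches a
column-wise reading of per-locus result tables; since other families are
defensible, the choice is stated in the output metadata.

## Asymmetric linkage disequilibrium

For loci A and B with haplotype frequencies `h_ab` and marginals `f_a`,
`f_b`, with `F(A) = Σ f_a²` and `F(A/B) = Σ_b Σ_a h_ab²/f_b`,

W(A|B) = sqrt( (F(A/B) − F(A)) / (1 − F(A)) ).

W lies in [0, 1], is invariant to allele relabelling, equals |r| when both
loci are bi-allelic, and is genuinely asymmetric for multiallelic loci —
the property that makes it informative for HLA, where a less polymorphic
locus can be nearly determined by a more polymorphic neighbour without the
converse holding. Haplotype frequencies come from the two-locus EM (phase
is unknown in this data situation); conditioning alleles with marginal
frequency below 1e-12 are dropped to avoid 0/0; a monomorphic focal locus
returns W = 0 with a warning. Both directions are always reported, with
explicit "focal conditioned on conditioning" naming to avoid the ambiguity
of compact row/column conventions.

## Diversity indices and similarity

Shannon entropy `−Σ p ln p` (nats) and Gini–Simpson `1 − Σ p²` summarise
within-population richness-and-evenness. Between populations the Hellinger
distance `HD = sqrt(1 − Σ √(p_i q_i))`, computed on the union of alleles
(absent ⇒ 0), is a bounded [0, 1] metric on relative frequencies — a
natural choice for compositional allele data. Similarity is reported as
`(1 − HD) × 100`, stored at full precision and rounded only for display;
the average-diversity summary for a focal population is the uniform mean
of `100 − similarity` over the loci and partner populations supplied.
Both conversions are linear and monotone, so orderings are unaffected by
the specific choice, which is recorded in output metadata.

## Rarefaction and extrapolation

The subsampling unit is the participant (two gene copies). Interpolated
richness has the exact hypergeometric form
`E[S(n)] = Σ_a [1 − C(N−m_a, n)/C(N, n)]` with `m_a` carriers of allele a
among N participants; Monte Carlo subsampling (`reps > 0`) is available
and converges to the closed form. Extrapolation uses the Chao1 asymptote
on gene-copy abundances — `f0 = f1²/(2 f2)`, falling back to
`f1(f1−1)/2` when `f2 = 0` — with the standard abundance-based completion
curve; with no singletons the curve is flat at the observed richness
(degenerate CI, warning). This participant-subsampling /
copy-abundance-asymptote hybrid is recorded in metadata since no single
canonical estimator is mandated for gene-copy data. The 95% CI comes from
50 bootstrap resamples of participants; the percentile interval is
recentred on the point estimate because bootstrap resamples systematically
understate singletons, which would otherwise place the whole interval
below the estimate. Defaults: 200 Monte Carlo reps when sampling, 50
bootstrap resamples, extrapolation to twice the observed sample size.

## Genetic cartography

Per-population haplotype profiles keep haplotypes whose estimated
frequency reaches 1% in at least one population — thresholding happens
before distance computation — with absent haplotypes scored 0. Distances
default to Euclidean on the relative-frequency rows (Hellinger available);
classical (Torgerson) MDS double-centres the squared distances and keeps
the top two eigenpairs, delegating the eigendecomposition to
`stats::cmdscale` and truncating negative eigenvalues with a warning.
Because the embedding is only defined up to rotation and reflection, a
canonical orientation is fixed by making the first population's
coordinates non-negative on both axes; embeddings of exactly planar
configurations reproduce the input distances to 1e-9.

## Synthetic cohorts: what they emulate and what they do not

`simulationConfig()` specifies a population by an explicit three-locus
haplotype frequency table — LD is encoded directly in the haplotype
frequencies, which makes the generator exact and directly comparable with
the EM and ALD estimators — plus an inbreeding coefficient f (probability
of autozygosity, i.e. a duplicated haplotype) and a per-call genotyping
error rate. A single global seed expands into per-population streams, so
adding a population never perturbs another population's draws.

`referencePanel()` instantiates the study conditions the package is
exercised under: seven cohorts with sizes 109, 173, 1640, 231, 565, 1765
and 661 (five African countries plus two US groups); nested tribe labels
for four of the countries at their reported sizes; skewed geometric-tail
allele spectra with per-locus decay 0.82 / 0.90 / 0.80 so that HLA-B is
the richest locus and HLA-C the poorest (pool magnitudes of tens of
alleles per locus, as such surveys report); and a mixture construction of
the haplotype table in which each HLA-B allele has a preferred HLA-C
partner with coupling 0.75 and a preferred HLA-A partner with coupling
0.35. Those couplings were fixed once, from the magnitude ordering such
surveys report for the directed B–C versus A-involving associations
(strong, asymmetric B–C LD; moderate A-involving LD), and are not
calibrated against any test outcome. African cohorts draw their allele
tails from an overlapping pool; US cohorts carry private alleles and
re-rank the shared alleles strongly, producing the between-continent
frequency contrast.

The generator does **not** emulate: real allele identities or their
published frequencies; typing ambiguity and nomenclature history;
admixture, drift or any demographic process (haplotype draws are i.i.d.);
locus-specific mutation or recombination. Passing tests on these cohorts
therefore demonstrate correctness of the estimators under the declared
sampling model — not agreement with any published cohort's values.

## Problem sizes and numerical choices in the test suite

Oracle comparisons run at desk scale by design: HWE enumeration fixtures
use up to 3 alleles and 12 subjects; the Ewens–Watterson null is
enumerated for every (2n ≤ 30, k); brute-force EM fixtures use ≤ 3 loci
and ≤ 4 alleles per locus; type-I error uses 500 cohorts of 100 subjects
with 5 alleles; parameter recovery uses 500 subjects. Pipeline smoke tests
run on a 180-subject, three-population slice with reduced chain sizes;
the acceptance script runs the full 5,144-subject panel at production
chain sizes. Ties in sorted outputs are broken lexicographically
throughout so that equal-frequency outputs are deterministic.

## Known limitations

* Haplotype estimation assumes Hardy–Weinberg proportions between
  haplotypes (random union of gametes); strong inbreeding biases the EM.
* The progressive-insertion trimming threshold trades a slightly
  restricted phase space for speed; extremely rare haplotypes (below the
  trim threshold's reach, or below 1e-6 finally) are not recoverable.
* The Ewens–Watterson Monte Carlo standard error is reported for the
  p-value only; `F_exp`/`sd(F)` sampling error is controlled by `nSim`.
* Average-diversity percentages depend on the declared partner set; they
  are summaries of the similarity matrices, not standalone estimands.
* Tribe-level analyses inherit small-sample instability; the package
  reports them like any population but leaves power considerations to the
  analyst.
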