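---
title: "Diversity analysis of pepper germplasm panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity analysis of pepper germplasm panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepperdiv)
```

`pepperdiv` implements the complete statistical pipeline used to compare
the diversity of two pepper (*Capsicum annuum*) germplasm panels — 94
local landraces (LLR) collected before 1985 and 85 current breeding lines
(CBL) — from scored phenotypes and codominant SSR/InDel genotypes. This
vignette is the package's own account of the models, the parameters that
matter, the numerical conventions, and what the synthetic-data tests do
and do not demonstrate.

## Phenotypic diversity

Qualitative traits are category codes per accession. For each trait and
population we form the frequencies $P_i$ of the observed categories
(missing values are dropped and the frequencies renormalised; dropped
counts are available from the validation report) and compute the Shannon
diversity index in natural logarithms,

$$H' = -\sum_i P_i \ln P_i, \qquad 0 \ln 0 := 0,$$

reported at 2 decimal places. $H'$ is 0 exactly when one category has
frequency 1 and is maximal at $\ln k$ for $k$ equiprobable categories;
both facts are property-tested.

Quantitative traits are first mapped to a 1–10 score using the mean $M$
and sample standard deviation $S$ of the trait **pooled over both
populations**, so the two panels share one scale: score 1 below $M - 2S$,
score 10 at or above $M + 2S$, and eight half-$S$ bins in between. Bins
are left-closed/right-open, which places $x = M$ in the score-6 bin and
honours the convention that the upper boundary belongs to score 10. $H'$
is then the Shannon index of the score frequencies, while Max, Min,
Range, Mean, SD and $CV = SD/M \times 100\%$ come from the raw values.
The pooled-scale choice follows the aggregate-data wording of the source
protocol; it is not fully explicit there whether per-population scales
were used for the published quantitative $H'$ values, so the pooled
reading is adopted and flagged here. Sample SD ($n-1$ denominator) is
used throughout; the protocol does not state the denominator, and the
sample form is the standard choice in germplasm characterisation.

## Marker diversity

For each locus, allele frequencies $p_a$ are proportions over the
$2\,n_\mathrm{obs}$ allele copies of genotyped accessions, computed within
the selected population (the two panels are summarised separately). The
per-locus statistics are

* major allele frequency $\max_a p_a$ (ties broken toward the smallest
  allele code, for deterministic reporting),
* allele and distinct-genotype counts (unordered pairs, missing excluded),
* gene diversity $D = 1 - \sum_a p_a^2$, uncorrected — the form the
  reference software reports by default; an optional
  $2n/(2n-1)$ correction can be switched on in `gene_diversity()`,
* observed heterozygosity, the fraction of heterozygous calls among
  non-missing calls, and
* $\mathrm{PIC} = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$
  (Botstein's index), computed through the algebraic identity
  $\sum_{i<j} 2 p_i^2 p_j^2 = (\sum_i p_i^2)^2 - \sum_i p_i^4$ and
  cross-checked in the tests against an explicit double loop.

$\mathrm{PIC} \le D < 1$ holds algebraically and is property-tested on
random frequency vectors; on Hardy–Weinberg data observed heterozygosity
tracks $D$ within binomial error.

## Chord distances and trees

Between two individuals, each locus contributes a Cavalli-Sforza–Edwards
chord term computed from within-individual allele frequencies
$x_a \in \{0, \tfrac12, 1\}$:

$$d_\ell = \frac{2}{\pi}\sqrt{2\Big(1 - \sum_a \sqrt{x_a y_a}\Big)},$$

and the overall distance is the arithmetic mean of $d_\ell$ over the loci
where both individuals are genotyped (pairwise deletion, no imputation;
shared-locus counts are recorded per pair). The theoretical maximum is
$2\sqrt{2}/\pi \approx 0.9003$, which matches the upper end of the
distance range published for the 179-accession panel (0.04–0.90) and is
the reason this scaling is the default. Because the exact normalisation
used by the original distance software is not documented, the scaling is
isolated behind the `variant` argument (`"angular"` drops the $2/\pi$
prefactor), so the alternative convention can be compared directly.

Trees are built from the distance matrix by Saitou–Nei neighbour joining
(the method used for the published clustering) or UPGMA
(average-linkage, rooted and ultrametric). Both are standard algorithms
and are delegated to `ape`/`stats`; the package wrapper clamps the
occasional negative NJ branch length to zero and records the clamped
total. NJ consistency (exact recovery of random additive trees with up to
12 leaves) and UPGMA ultrametricity are tested properties. Trees are
serialised as Newick, distance matrices as square PHYLIP.

## Admixture model and choice of K

The population-structure model is the standard Bayesian admixture model:
each individual $i$ has proportions $q_i$ over $K$ clusters, each cluster
$k$ has allele frequencies $p_{k\ell}$ per locus, and each allele copy is
drawn by first choosing a cluster from $q_i$ and then an allele from
$p_{k\ell}$, assuming Hardy–Weinberg equilibrium within clusters and
independent loci. The Gibbs sampler sweeps over (i) allele-copy origins,
(ii) $p_{k\ell} \mid$ counts $\sim$ Dirichlet($\lambda$ + counts),
(iii) $q_i \mid$ counts $\sim$ Dirichlet($\alpha$ + copy counts), and
(iv) a reflected random-walk Metropolis update of $\alpha$ (step 0.05,
uniform prior on $(0, 10]$). Missing copies are skipped everywhere. The
sweep kernel is written in C++ for speed; all randomness flows through
R's RNG, so runs are exactly reproducible — chain $r$ at a given $K$ uses
seed $\texttt{seed} + 1000K + r$.

Two deliberate simplifications relative to the original tool: the
allele-frequency prior is the **independent** Dirichlet($\lambda = 1$)
model rather than the correlated-frequencies F-model, and no linkage or
prior-population information is used. For strongly diverged panels the
independent model suffices for $\Delta K$-based model choice, which is
what the pipeline needs; the published group sizes at $K = 2$ (70 and
109) depend on the raw genotypes and the correlated model and are
therefore treated as a qualitative, not numeric, benchmark.

$\ln \Pr(X \mid K)$ is estimated per chain as
$\overline{\ln L} - \mathrm{var}(\ln L)/2$ over the post-burn-in trace
(thinned every 10 sweeps), and $K$ is chosen by the Evanno method:
$\Delta K = |L''(K)| / s[L(K)]$ with $L'(K) = L(K) - L(K-1)$ and
$|L''(K)| = |L'(K+1) - L'(K)|$, means and standard deviations taken over
chains. $\Delta K$ is undefined at the end points and wherever the
run-to-run SD is zero; such entries are reported as `NA`, never
fabricated. (The formula is implemented as in Evanno's original
definition; the source protocol's printed formula contains an obvious
typographical garble.) Accessions are assigned to their argmax cluster
and flagged admixed when their largest $Q$ does not exceed the 0.6
clear-membership threshold used in the reference analysis. Label
switching between chains is undone by greedy correlation matching, which
the tests verify against exhaustive permutation search at small $K$.

Default MCMC settings are desk-scale — 5,000 sweeps, 1,000 burn-in, 4
chains — chosen so a full $K = 1..5$ scan of a 100-accession panel runs
in about a minute while leaving the study-scale settings (100,000
iterations, 30,000 burn-in, 8 chains) one argument away.

## Principal coordinates

PCoA applies Gower double-centering to $-d^2/2$ and takes the
eigenvectors scaled by $\sqrt{\lambda}$. Chord-mean matrices are usually
not exactly Euclidean; axes with negative eigenvalues carry no
coordinates and their total magnitude is reported rather than corrected
(no Lingoes/Cailliez adjustment — the simplest convention, made visible).
Axis signs are fixed by making the largest-magnitude loading positive, so
exports are reproducible. On Euclidean-embeddable input the
configuration reproduces the distances to $10^{-9}$, which is tested.

## Synthetic data: what it emulates and what it does not

The generator mirrors the structure of the target dataset: 179 diploid
accessions — two source populations (85 + 80) plus 14 admixed
individuals, matching the scale of below-threshold accessions in the
published membership — 27 loci with 2–20 alleles, allele codes emitted as
fragment-like sizes ($150 + 2i$ bp) so the same parsers run on synthetic
and real files, 22 categorical and 13 numeric traits, and 2% missing
data. Divergence is controlled by the Balding–Nichols construction:
ancestral frequencies $p \sim$ Dirichlet(1), population frequencies
$\sim$ Dirichlet$(p\,(1-F)/F)$, so the variance-standardised divergence
is approximately $F$. The default $F = 0.25$ produces clearly separated
pools; note that the realised multi-allelic $G_{ST}$-style estimate
reported by `fst_estimate()` is lower than $F$ (heterozygosity caps
$G_{ST}$ when within-population diversity is high), around 0.13 at the
default settings. Admixed ancestry rows are Dirichlet(1). The acceptance
experiments use the stronger, explicitly stated condition $F = 0.3$ with
two populations of 50 and 20 loci.

Two features of the real panels are deliberately **not** emulated.
First, inbreeding: the generator draws Hardy–Weinberg genotypes, so
synthetic observed heterozygosity is close to gene diversity (~0.5),
whereas the real landraces and especially the 8–10-generation inbred
breeding lines are largely homozygous (published panel means 0.16 and
0.07). Second, SSR mutation dynamics (stepwise sizes, null alleles) and
linkage are absent. Passing tests therefore demonstrate the correctness
and recovery behaviour of the statistics and samplers, not that the
synthetic data are a facsimile of pepper germplasm.

## Numerical conventions and edge cases

* Missing genotype sentinel: `-9` in STRUCTURE files, empty/`NA` in
  delimited files, `NA` internally; 0 is never a valid allele code.
  Allele pairs are stored order-normalised, so `155/161` equals
  `161/155`.
* A trait with $S = 0$ cannot be scored (degenerate-trait error); a trait
  with mean 0 has no CV; an all-missing locus or trait is an error where
  a statistic is requested and a flagged issue in the validation report.
* Report tables round $H'$ and marker statistics to 2 dp and percentages
  and CV to 1 dp, mirroring the published tables; full-precision twins
  are written alongside (`*_precise.csv`).
* NJ Q-criterion ties resolve by lowest index pair (inherited from the
  `ape` implementation's deterministic scan order); major-allele ties by
  smallest allele code; merge order in UPGMA is permutation-invariant up
  to relabelling, which is tested.
* Problem sizes in the test-suite and the analysis scripts (panels of
  20–100 accessions, 5–27 loci, $K \le 5$, a few thousand sweeps) were
  chosen as the smallest sizes at which the recovery properties are
  stable and routinely reproduce; the full pipeline on the 179 × 27
  synthetic preset runs in a few minutes on one core.

## Known limitations

* The correlated-allele-frequencies prior, linkage model and
  USEPOPINFO-style supervision are out of scope; `align_runs()` is a
  greedy CLUMPP-like matcher, not the full algorithm.
* Published per-accession results that require the raw supplementary
  genotype table (exact group sizes at $K = 2$, the 0.50 mean chord
  distance, the published tree) cannot be recomputed from the summary
  tables shipped here; the pipeline accepts that table directly once a
  user obtains it.
* No significance tests accompany $H'$ differences — the reference
  analysis reports none, so the difference tables are descriptive.
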