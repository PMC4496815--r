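---
title: "Selection scans for small population samples: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection scans for small population samples: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apisweep)
```

This vignette is the package's account of the statistics it implements,
the defaults it ships with and the choices made where the methods
literature leaves room. It is written for a reader planning to run the
suite on a real resequencing panel: a VCF of biallelic SNPs for a
handful of diploid individuals, gene models, a reference genome, a
population assignment and (for polarized statistics) per-site outgroup
alleles.

## Data model and coordinates

All coordinates are 0-based and half-open internally; conversion to and
from 1-based coordinates happens only at format boundaries (VCF and the
outgroup TSV are 1-based, BED output is 0-based half-open). This removes
every off-by-one from windowing and interval intersection at the cost of
one conversion per reader/writer, and it is asserted by round-trip
tests.

Genotypes are unphased counts of the alternate allele (0/1/2, `NA` for
missing); phased and unphased VCF separators are treated identically,
and half-called genotypes such as `./1` become missing. The default
quality filter is QUAL ≥ 100 (inclusive), the customary threshold for
SAMtools-called variants in low-coverage panels; coverage and mapping
quality filtering are considered upstream concerns of the variant
caller, not re-implemented here.

Gene models are chains of CDS intervals stored in transcription order.
When a spliced CDS length is not a multiple of 3 the trailing partial
codon (3'-most in transcription order) is dropped and the event logged —
annotation errors should be visible, not fatal.

## Codon-level tests

**Effective sites.** For each codon, the synonymous site count
\(s\) is the number of its nine single-base mutants that preserve the
encoded amino acid, divided by 3; the nonsynonymous count is
\(n = 3 - s\). Mutations that create or destroy a stop codon are counted
as nonsynonymous (they certainly change the protein), which keeps
\(n + s = 3\) for every counted codon and \( \sum (n+s) = 183\) over the
61 sense codons. Stop codons and codons containing non-ACGT letters are
skipped and tallied. Effective sites are computed from the reference
CDS, not a sample consensus — the pipeline is annotation-driven
throughout. No multiple-hit correction is applied: at within-species
divergence levels the raw counting estimate is the appropriate one, and
the three tests below consume raw counts.

**SNP classification.** Each CDS SNP is classified by substituting the
alternate allele into the reference codon in transcription orientation
(reverse-complemented on minus-strand genes) and translating. Codons
carrying more than one SNP are classified one SNP at a time with the
other positions held at the reference base, which avoids any dependence
on haplotype phase that the genotype data cannot support.

**The three tests.** With \(P_N, P_S\) the nonsynonymous/synonymous
polymorphism counts among the selected samples, \(E_N, E_S\) the fixed
differences from the reference genome (every called genotype homozygous
alternate), and \(D_N, D_S\) the fixed differences from the outgroup
allele:

- \(pN/pS = (P_N/N) / (P_S/S)\), reported only for genes with
  \(P_S \ge 1\);
- the fixed-difference ranking uses \(E_N / (P_N + 1)\), the +1 keeping
  genes with no amino-acid polymorphism in the ranking;
- the McDonald-Kreitman Fixation Index is
  \(FI = (D_N/D_S)/(P_N/P_S)\), undefined (with a flag naming the zero
  cell) when \(D_S\), \(P_N\) or \(P_S\) is zero. An optional
  pseudocount adds 1 to all four cells for exploratory ranking only —
  the default refuses to manufacture a number from a degenerate table.

A site that is polymorphic in-group *and* different from the outgroup
counts as polymorphism, not divergence: polymorphism is observed
directly, divergence is inferred, and this rule makes the two
categories partition the informative sites. Outgroup alleles matching
neither the reference nor the alternate allele exclude the site and are
tallied per gene.

## Allele-frequency statistics

**Homozygosity.** The per-site score is \((p_{alt} - p_{ref})^2\): 1.0
exactly when a group is monomorphic, 0 at frequency one-half. A run of
1.0 scores is a run of homozygosity, the footprint of a recent sweep.

**Reich-Patterson FST.** With alternate counts \(a_k\) of \(n_k\)
called chromosomes and
\(h_k = a_k (n_k - a_k) / (n_k (n_k - 1))\):

\[N = \left(\frac{a_1}{n_1} - \frac{a_2}{n_2}\right)^2
      - \frac{h_1}{n_1} - \frac{h_2}{n_2},
  \qquad D = N + h_1 + h_2.\]

The per-site estimate is \(N/D\) (negative values are legitimate and
indicate more variation within groups than between), and the overall
estimate is the ratio of sums \(\sum N / \sum D\) — the standard form
for this estimator and the only one that yields a single genome-wide
scalar with small-sample bias cancellation. Parameter-recovery tests
against a Balding-Nichols simulation confirm the estimator returns the
generating \(F\) to ±0.01 at 5×10⁴ SNPs with groups as small as 3 and 5
diploids. Significance of an observed grouping is assessed by comparing
against random disjoint groupings of the same sizes; p-values use the
+1 rule \((1 + \#\{F_{rep} \ge F_{obs}\})/(1 + reps)\) and so are never
zero. Note that with few samples some randomized groupings reproduce
the observed partition exactly, so the smallest attainable p is bounded
by the partition-recovery probability, not just by the replicate count.

**Tajima's D and Fay-Wu's H.** D follows the original 1989 definition:
\(D = (\pi - S/a_1) / \sqrt{e_1 S + e_2 S (S-1)}\) with the standard
n-indexed constants (implemented in `tajima_constants()` and verified
against an independently computed table for n = 4, 10, 22). π uses the
unbiased per-site estimator \(2a(n-a)/(n(n-1))\). Windows are
non-overlapping, 5 kb by default, and D is undefined (`NA`) where
\(S = 0\); `tajima_d_for_sites()` applies the same formula to arbitrary
site classes (noncoding / synonymous / nonsynonymous masks from the
codon module). The normalized H contrasts π with
\(\theta_L = \sum i S_i / (n - 1)\) and divides by the Zeng et al.
(2006) variance with θ and θ² estimated from S; derived states come
from the outgroup allele, and a site whose outgroup allele equals the
alternate allele is polarized with the reference allele as derived
(count \(n - a\)).

**Missing data.** The run-level chromosome count \(n\) is fixed at
twice the group size, and by default only sites with complete genotypes
in the group enter S and π — the variance constants assume a constant
n, and silently mixing per-site sample sizes into them biases D. An
`allow_missing` option keeps incomplete sites (with their observed
allele counts) for exploratory use.

## Remarkable intervals

Scores (homozygosity, per-SNP FST, or any custom track) are reduced by
a cutoff and scanned for **all** locally optimal maximal-scoring
segments in the Ruzzo-Tompa sense: every reported segment has positive
total, cannot be improved by moving either endpoint, and the set is
disjoint and exhaustive. The cutoff is either explicit (0.9 for ROH
scans — a cutoff of 1.0 would leave no positive scores to extend) or a
nearest-rank percentile of the genome-wide score distribution (top 10%
for FST scans). Zero-sum extensions are not absorbed: a segment ends at
its last strictly positive suffix, which keeps ties from smearing
interval boundaries. The linear-time scanner is verified against
quadratic brute-force enumeration on a thousand random tracks per test
run.

Two deliberate conventions: optimality is computed over member SNP
scores only, with no penalty for SNP-free gaps (intervals are reported
as the genomic span from first to last member SNP); and the permutation
null shuffles the score-to-position assignment within each chromosome,
preserving both the per-chromosome score distribution and the site
density. The null summary is each replicate's **maximum** segment
score, so the resulting p-value is family-wise across the scan: with
1000 permutations, a reported interval at p = 1/1001 < 0.001 scored
higher than every segment in every permuted genome. One numerical
subtlety: segment scores are taken from `cumsum()` prefix sums so that
observed scores and permutation maxima share the same floating-point
accumulation; without this, exact ties (e.g. constant tracks, where the
correct p is 1) split on the last bit.

## Neutral calibration

The calibrator simulates standard neutral coalescent windows without
recombination under the infinite-sites model: exponential coalescence
times at rate \(k(k-1)/2\), Poisson\((\theta T_{total}/2)\) mutations
placed uniformly on branches. Closed-form checks
(\(E[S] = \theta a_1(n)\), \(E[\pi] = \theta\)) and neutrality checks
(mean D and mean normalized H within ±0.15 of zero at n = 22, θ = 5)
are part of the test suite, as is the self-consistency of the α = 0.05
cutoff (type-I error inside its binomial confidence interval).

θ̂ should be supplied as the observed mean number of segregating sites
per window divided by \(a_1(n)\). The default mode returns the
per-window lower-tail α quantile of the null; an experiment-wide mode
instead simulates replicates of \(m\) windows and takes the quantile of
per-replicate minima, for a multiple-testing-corrected cutoff. Both are
offered because genome-wide studies have used both readings of
simulation-based correction; the per-window default is the conservative
interpretation for filtering individual windows, and the choice is
explicit in the result object. No recombination, migration or
demography is modelled — cutoffs calibrated this way are conservative
for statistics computed in short windows but do not capture demographic
confounding, which a real study must address separately.

Default n is 22 chromosomes (11 diploids), the sample scale this
package targets; it is a parameter everywhere.

## Synthetic fixtures: what they do and do not emulate

- `island_fixture()` draws per-SNP ancestral frequencies from
  U(0.05, 0.95) and deme frequencies from the Balding-Nichols beta
  distribution at the target F, with binomial diploid sampling; group
  sizes default to 3 + 5 diploids. It emulates allele-frequency
  structure only — sites are unlinked, so it cannot exercise
  linkage-sensitive behaviour.
- `sweep_fixture()` guarantees background sites polymorphic within both
  groups (frequencies U(0.25, 0.75), resampled until polymorphic) and
  plants a tract monomorphic in group A only, at 50 bp SNP spacing. It
  produces an idealized, maximally clean ROH signal: passing the
  end-to-end detection test shows the scanner and p-value machinery
  work, not that real sweeps of a given age are detectable.
- `coding_gene_fixture()` builds a mini reference, a single-gene
  annotation (either strand) and a variant table realizing a planned
  list of SNPs with verified coding effects, plus outgroup alleles for
  MK-style divergence sites. Plans that contradict the sequence are
  errors, never silently reinterpreted.

All generators are bit-reproducible under a fixed seed. Test problem
sizes were chosen to make sampling error small relative to the asserted
tolerances: 10⁴ coalescent replicates for closed-form means, 2000
windows for neutrality and type-I checks, 5×10⁴ SNPs for FST recovery,
1000 random tracks for the scanner oracle.

## Known limitations

- No haplotype-based statistics (iHS, XP-EHH), no LD-aware methods, no
  Weir-Cockerham FST variant.
- No maximum-likelihood dN/dS; the codon tests are counting-based by
  design and inherit the known conservatism of raw counts at higher
  divergence.
- The MK framework assumes the outgroup allele is correctly aligned and
  orthologous; misalignment inflates D_N, and the per-gene
  `sites_skipped` counter is the only internal diagnostic.
- Windowed statistics assume a fixed per-run n; panels with pervasive
  missingness will lose sites under the default complete-genotype rule.
- The coalescent null ignores recombination and demography; its cutoffs
  correct for window-level multiple testing, not for population history.
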