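---
title: "Localizing a ZW sex-determining region and building a W-linked marker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing a ZW sex-determining region and building a W-linked marker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zwseeker)
```

## The problem and the model

In a female-heterogametic (ZW) species, every female carries one W
chromosome. Any variant fixed on the W is therefore heterozygous in all
females and absent from all males, which makes phenotypic sex behave like a
perfectly penetrant Mendelian trait mapped by a case–control scan. The
catch in practice is coverage: a resequencing design of 90 wild fish at
roughly 2× per sample leaves most individual genotypes miscalled or
missing, so every statistic in this package is chosen to survive that
regime. The package follows the design used for California yellowtail
(*Seriola dorsalis*): three sampling populations of 15 females + 15 males
each, a fully sex-linked region on one scaffold, and a 61-bp W-specific
deletion in the promoter of the estradiol 17-beta-dehydrogenase gene
(*hsd17b1*), 954 bp upstream of its start.

The pipeline is: (1) simulate or load a GT:AD cohort; (2) localize the SDR
by single-marker association; (3) classify ZW vs XY from heterozygosity
ratios; (4) screen the SDR for a long sex-patterned indel and validate a
PCR assay in silico; (5) footprint conserved promoter motifs against the
deletion.

## Association scan

Sex (F = 1, M = 0) is regressed on alt-allele dosage per site; the p-value
comes from the F statistic on (1, n − 2) degrees of freedom. This is the
classic fixed-effects single-marker GLM; kinship (centered identity by
state with VanRaden scaling, `centered_ibs()`) is computed and reported but
deliberately not included in the model, matching the fixed-effects
semantics of the standard GWAS tool this emulates. With a perfectly
W-linked site the residual is zero and the F statistic diverges; p-values
are clamped at 1e−300 so downstream code sees a valid probability. The
normal-theory F tail is much lighter than an exact (hypergeometric) tail in
this extreme regime, so F-test p-values should be read as ranking scores
near separation, not as calibrated tail probabilities; rank agreement with
exact enumeration is what the test suite asserts.

Missing dosages are imputed before testing: Euclidean distance between
samples over sites observed in both, mean dosage of the five nearest
neighbours observed at the site, rounded to the nearest integer dosage.
Rounding keeps dosages in {0, 1, 2}, which keeps count-based cross-checks
(e.g. allele-count enumeration) applicable downstream.

Two numerical scan choices are operationalized here because the procedure
they come from is qualitative:

- *Thinning*: one uniformly chosen SNP per 5000-bp window per scaffold
  (seeded), emulating the subset a memory-bound association tool would use
  for the genome-wide pass.
- *Follow-up*: a scaffold is rescanned at full density when it shows at
  least 3 significant sites (p ≤ 1e−3) within 100 kb. "Several co-linear
  significant SNPs" needed a number; 3-in-100 kb is conservative for the
  simulated SNP densities and makes the promotion rule testable.

The SDR is bounded by the first and last site with p ≤ 1e−7 on the
best scaffold (a p exactly at the cutoff counts). The experiment-wise
threshold is the empirical 0.05 quantile of minimum p over 1000 sex-label
permutations; calibration (fraction of true-label null minima below the
threshold ≈ 0.05) is verified in the test suite by repeat simulation.

## Heterozygosity ratios and the ZW/XY call

A SNP is counted heterozygous for a population × sex group when the
group-pooled alt read fraction lies in [0.4, 0.6] (inclusive at both ends)
with pooled depth ≥ 10. Pooling is a deliberate reading of the
heterozygosity rule: at 2× coverage a single individual contributes 0–3
reads, so per-individual allelic ratios are 0, ½ or 1 and carry almost no
information, whereas 15 individuals pool to ~30 reads where a true
heterozygous site shows a fraction near ½. A strict per-individual variant
is available (`per_individual = TRUE`) but is not the default. The pooled
depth floor of 10 avoids ratio noise at nearly empty sites and is
configurable.

Exact computation under this model (depth ~ Poisson(30), alt ~
Binomial(depth, ½)) gives a per-site counting probability of 0.74 for a
W-linked site in a 15-female group — the count tables are not a census of
W-linked sites, and do not need to be: the inference rides on the
female/male *contrast*, which is large (observed SDR ratios 4–7 against
controls near 1 on default simulations).

The system call uses thresholds not fixed by the original analysis: ZW
requires every population's SDR ratio ≥ 2.0 while all control ratios stay
strictly inside (0.5, 2.0); XY is the mirror image. The 2.0/0.5 pair is
symmetric and conservative relative to the separation actually observed
(SDR 3.9–6.2 vs controls 0.8–1.3 in the motivating data); an SDR ratio
that is undefined because the male count is zero is treated as
infinitely female-skewed.

## Marker discovery and the in-silico assay

Candidate markers are indels of length ≥ 41 bp (the "> 40" rule read
strictly) inside the SDR whose carriers follow the W pattern. Two evidence
modes are provided because the natural per-genotype rule breaks down at
low coverage: with depth ~ Poisson(2) per sample, a true heterozygous
deletion is *called* heterozygous in only ~40% of females, so a rule of
the form "≥ 90% of females are het" can never fire at 2×. The default
`mode = "pooled"` therefore applies the same pooled-depth logic as the
heterozygosity table: the female pooled alt fraction must fall in
[0.3, 0.7] at pooled depth ≥ 10 (slightly wider than the SNP band, since a
single indel site pools ~90 reads over 45 females and the decision is per
marker, not per thousands of sites) and the male pooled alt fraction must
not exceed 0.05. `mode = "genotype"` implements the per-call rule (≥ 90%
of non-missing females het, ≤ 5% of non-missing males carrying the
allele) and is the right choice at deep coverage; the tests exercise it in
the simulator's noise-free limit.

Melting temperatures use nearest-neighbour thermodynamics. The default
parameterization is Breslauer-1986 stacking parameters with the
Schildkraut–Lifson salt term (16.6·log10[Na+], 50 mM) and an
excess-primer duplex term R·ln(C) at C = 250 nM — the classic
primer-design configuration, whose 250 nM matches the 0.15–0.3 µM primer
concentrations of the wet assay this package models; it reproduces the
assay's published Tm values (59.8–60.1 °C) to within 0.1 °C. The
SantaLucia-1998 unified parameters (terminal initiation penalties,
entropic salt correction, CT/4 convention) are available as
`method = "santalucia"`; they sit ~8 °C lower for these primers at
50 mM Na+, which is expected behaviour of that parameter set, not an
error — the two scales should not be mixed.

In-silico PCR matches the forward primer on either strand and the reverse
primer as its reverse complement downstream, emitting every properly
oriented pair within 3000 bp; product length includes both primer
footprints. Mismatch tolerance defaults to zero; when enabled, mismatches
are still forbidden in the 3'-terminal 3 bases (polymerase extension is
intolerant there). Sex calls from band patterns: both allele products ⇒
female, single intact-allele product ⇒ male, anything else anomalous —
a deletion-homozygote is not expected under ZW and is flagged rather than
called.

`design_primers()` is an intentionally simple enumerator (18–22-mers
scored by |Tm − 60| with a 3'-G/C bonus and homopolymer exclusion), a
stand-in for a full design tool; it exists so the assay-construction path
is closed and testable, not to compete with dedicated designers.

## Promoter footprinting

Upstream regions (3000 bp, strand-aware, truncated at scaffold edges) of
orthologous genes are scanned for shared words: every 15-mer of the first
sequence is matched against all sequences on both strands within 2
mismatches, and words present in ≥ `min_seqs` sequences are ranked by
(number of sequences, exact-match support, total matches). Exact-match
support is in the key because a conserved word's one-off shifted variants
also clear the mismatch budget in the same sequences; without it the
reported representative could be an arbitrary shift. Overlapping reported
words are merged to the best-ranked representative. This enumeration is a
declared simplification of EM-based motif discovery: it recovers planted
or genuinely conserved words exactly, but cannot find degenerate motifs
with no dominant word.

PWM scoring follows the JASPAR convention: a total pseudocount of 0.8
split by the background frequencies, log2 odds against the background, and
a relative score (S − Smin)/(Smax − Smin) so 1.0 is the best attainable
window. `deletion_overlap()` reports the longest contiguous match between
the strand-oriented motif and any substring of the deletion; boundary
overlaps count, which matters because the motivating motif straddles the
deletion edge (12 of its 15 bases fall inside). Only a synthetic PWM
fixture ships with the package; real JASPAR matrices are version-dependent
external data, so database-derived relative scores are discussed in
documentation but never asserted by tests.

## The simulator: what it emulates, and what it does not

`simulate_cohort()` generates, under one seed: a multi-scaffold reference;
background SNPs at Hardy–Weinberg with alt frequency ~ U(0.05, 0.5),
independent of sex; W-linked SNPs heterozygous in every true female;
the 61-bp deletion on all W haplotypes, left-anchored in the VCF, with the
primer cassette embedded in the reference so the published assays amplify
from the simulated genome; and observed GT:AD produced by depth ~
Poisson(coverage), allele reads ~ Binomial(depth, dosage/2), genotypes
called het when both alleles are seen, hom for the single seen allele,
missing at zero depth. `coverage = Inf` switches to a deterministic
depth-30 noise-free limit used by exactness tests. An XY toggle swaps the
panel's sex labels, turning the cohort into a negative control for the
classifier.

Desk-scale defaults are the package's own choices and are stated here
once: six scaffolds totalling ~1 Mb (the SDR scaffold is 400 kb with the
sex-linked interval at 231–320 kb and the deletion at 246,495), background
SNP density 0.01/bp, 120 W-linked SNPs, and background heterozygosity
inside the SDR reduced to 0.12 of the genome-wide level. The reduction
factor was derived from the motivating study's count table (male SDR
counts ~22 against same-size control counts ~130 imply ~0.12 residual
background diversity — the expected signature of a degenerating,
non-recombining sex-linked region); with it, simulated SDR rows show
female counts ~90–125 against male counts ~20–30, matching the observed
table. Two sex-independent decoy indels (45 and 50 bp) are planted so the
marker scan's sex-pattern filter has something to reject.

What the simulator does not model: read-level errors and mapping
artefacts, linkage between background sites, population structure and
migration, recombination inside the SDR, and genotype-quality fields
beyond GT/AD. Passing tests therefore demonstrate that the statistics
behave correctly under the idealized noise model the methods assume, not
that they are robust to alignment pathology in real data.

## Numerical choices and degenerate inputs

- Coordinates are 1-based inclusive everywhere; any half-open arithmetic
  is internal.
- Ratio rounding is half-away-from-zero (so 123/20 → 6.2), with a small
  epsilon guard and scale-before-divide so exact halves survive binary
  floating point.
- Monomorphic sites carry an untested sentinel (`NA` statistic and p) and
  are excluded from thresholds and minima.
- KNN distance ties are broken by stable ordering, so imputation is
  deterministic; all-missing sites are left missing with a warning and
  excluded downstream.
- Scaffold containment uses canonical 21-mers (lexicographic minimum of a
  k-mer and its reverse complement). The containment detection method was
  unspecified in the motivating analysis; k-mer membership was chosen
  because it is alignment-free and exactly checkable against a brute-force
  oracle. Whether mismatches were allowed there is unknown; the k-mer
  proxy is declared, not inferred.
- Boundary semantics of the curation filter: length exactly 800 is kept
  ("fewer than 800" removed); a gene-less scaffold of exactly 10,000 is
  removed ("larger than 10,000" required).
- VCF round-trips are exact for sites with up to two ALT alleles; depth
  beyond the second ALT collapses into an "other" column with a warning.
  Multi-allelic records are kept at parse time and removed only by
  `keep_biallelic()`, so that filter is observable.

## Problem sizes used by the tests

Unit tests run on reduced cohorts (three scaffolds, ~140 kb, 40 W-linked
SNPs) chosen to exercise every code path in seconds; the acceptance-level
checks run the full default configuration (~1 Mb, 90 samples) and a
20-replicate parameter-recovery study, with permutation calibration at 100
null datasets × 500 permutations. These sizes were picked so the complete
suite documents the method's behaviour at interactive timescales; the
algorithms themselves are vectorized and scale linearly in sites ×
samples.

## Known limitations

The GLM is fixed-effects only — cohorts with real structure or relatedness
need a mixed model, which is out of scope. The motif finder cannot
discover degenerate motifs. The Tm model ignores divalent-cation and
secondary-structure effects. The sexing assay's in-silico validation
presumes the deletion is the only length difference between alleles within
the amplicon. And the scaffold-curation containment proxy measures k-mer
sharing, which slightly overestimates containment for repetitive
sequence.
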