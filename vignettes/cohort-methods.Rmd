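---
title: "Models and methods behind sgcohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sgcohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgcohort)
```

sgcohort implements the bespoke downstream stages of a tumour/normal
exome cohort study of salivary gland basal cell adenoma (benign) and
adenocarcinoma (malignant): somatic variant refinement, tumour mutation
burden, copy-number analytics including chromothripsis scoring and
two-hit calling, a minimizer-based taxon presence test, and cohort-level
hotspot and mutual-exclusivity summaries. This vignette explains the
models, the tunable parameters, the numerical choices, and what the
synthetic cohort does and does not establish about real data.

## The refinement cascade

Calls arriving from somatic callers on FFPE exomes carry germline
leakage, alignment artefacts and low-support noise. The refinery
applies, in order:

1. **Common-SNP exclusion.** A call with population allele frequency at
   or above `common_af_threshold` (default 0.01) in the configured
   population resource is treated as germline and removed. A missing
   frequency never removes a call — absence of evidence is not treated
   as commonness.
2. **MNV merging.** Maximal runs of SNVs at consecutive positions that
   share a sample, chromosome and phase set are merged into one MNV.
   Runs longer than `max_mnv_len` (default 3 bp) are left unmerged, and
   MNVs longer than that are removed outright. The merged record's
   read support is the minimum over constituents: the joint event is
   only as well supported as its weakest site. Phasing itself is out of
   scope; the `phase_set` field stands in for a read-backed phasing
   tool, and the synthetic generator populates it.
3. **VAF and allele-length retention.** Tumour VAF is `t_alt/t_depth`,
   defined as 0 when depth is 0 (such records are removed as
   `malformed` rather than risking division by zero). Calls below
   `min_vaf` (default 0.1) are removed. An allele pair is *simple* when
   both alleles are at most 25 bp long and they are not both longer
   than 10 bp; simple pairs are retained. Everything else is *complex*
   and is retained only with VAF strictly above 0.25 and at least 20×
   depth in both tumour and matched normal. The published description
   of this rule is ambiguous; the reading above is isolated in a single
   predicate (`is_simple_allele`) so an alternative reading is a
   one-line change.
4. **Target proximity.** The assayable territory is the exome target
   set, each interval extended by a 2 bp splice flank and merged.
   Calls whose reference span is more than `target_proximity_bp`
   (default 100, inclusive at the boundary) from any flanked interval
   are removed.
5. **Hotspot rescue.** Low tumour purity or tumour-in-normal
   contamination can push a true recurrent hotspot below the VAF or
   depth filters. A removed raw call at a configured hotspot site is
   reinstated when it has at least `rescue_min_t_alt` (default 3)
   tumour alt reads and a normal VAF of at most `rescue_max_n_vaf`
   (default 0.01). The study this models performed that step by manual
   alignment inspection; automating it requires explicit thresholds,
   and the defaults encode "unambiguous tumour support, clean normal".
   Rescued records are flagged with the rule they overrode.

The pipeline is idempotent, order-invariant, and monotone in
`min_vaf`; every removal appears exactly once in the audit log with
the first rule that fired. These contracts are asserted in the test
suite.

## Tumour mutation burden

TMB counts refined SNVs, MNVs (one mutation each) and indels whose
reference span overlaps the flanked territory, divided by the territory
size in Mb. A variant overlapping only the 2 bp flank is a splice-site
mutation and counts; this is a documented choice the published
definition leaves open. With the study's territory of 48.225157 Mb,
362 mutations give 7.5 mutations/Mb at one decimal.

Cohorts are compared with the unpaired Wilcoxon rank-sum test in its
normal-approximation form: mid-ranks for ties, tie-corrected variance,
and a 0.5 continuity correction toward the mean. The approximation is
the published procedure, so it is used at all sizes, but its accuracy
is size-dependent: enumerating every achievable statistic exactly, the
worst-case deviation of the approximate two-sided p from the exact
permutation p is 0.016 at groups of six, 0.021 at 4 vs 5, 0.038 at
3 vs 3 and 0.088 at 2 vs 2. The test suite asserts agreement within
0.02 exhaustively at groups of five and six, and the computed looser
bounds below that. At the study's cohort sizes (32 vs 11) the
approximation error is negligible.

## Copy-number analytics

**Altered-genome fraction** is the length fraction of autosomal
segments with total copy number different from 2. The baseline is the
diploid state rather than sample ploidy because the modelled study
reports genome fractions "amplified or deleted" without a ploidy
adjustment; a ploidy-relative mode is available behind a flag. Sex
chromosomes are excluded; the synthetic genome model is entirely
autosomal.

**Broad events** require at least half a chromosome arm below (loss)
or above (gain) total CN 2. Both cannot win simultaneously except in an
exact tie of lost and gained halves, where loss takes precedence
(documented tie-break).

**Chromothripsis scoring.** A *CN state switch* is a breakpoint between
adjacent segments with different total CN. The score of a chromosome is
the maximum number of switches inside any 50 Mb window. Windows are
anchored at segment breakpoints rather than slid on a fixed grid: any
window can be translated until its left edge meets a breakpoint without
losing a switch, so the breakpoint-anchored maximum is exact, and the
test suite checks it against a brute-force scan on random profiles.
Confidence tiers are 10+/8–9/6–7 switches for high/intermediate/low.
For chromosomes shorter than the window the thresholds scale by
`length/50 Mb`, rounded to the nearest whole number with halves rounded
away from zero (base R's banker's rounding would turn 8.5 into 8);
at 46.709 Mb the factor is 0.934 and the tiers become 9/7–8/6.
Canonical events oscillate among 2–3 distinct CN states; more states is
non-canonical. Copy-number oscillation alone cannot confirm
chromothripsis — that requires structural evidence beyond exome data —
so the output is labelled by confidence tier, never as a verified
event.

**Focal-event post-filters** remove, in order: events of at most
100 kb (size is `end − start` on half-open coordinates, boundary
inclusive), events overlapping difficult sequencing/mapping regions by
more than 40%, and events where fewer than 75% of supporting samples
concur (a sample concurs when at least half the event length in its
own segment profile carries CN in the event direction). The statuses
partition the input and re-filtering kept events is a no-op. The
upstream focal-event discovery tool is not re-implemented; the filter
consumes its table shape.

**Two-hit calling.** A gene is biallelically inactivated through two
distinct damaging variants, or one damaging variant plus loss of
heterozygosity. Damaging defaults to truncating and splice-disrupting
consequence classes. LOH is minor CN 0 over at least half the gene
interval — the published narratives do not quantify the span, and half
the gene body is a conservative, documented choice.

## The taxon presence test

A taxonomic classifier reports, per taxon, `m` distinct clade-level
minimizers observed out of `M` in its database, from `n` reads assigned
to the taxon of `N` evaluated in the sample. The null model is
`m ~ Binomial(M, p0)` with `p0 = n/N`: under background, a taxon's
chance of revealing any one of its database minimizers is taken
proportional to its share of the sample's reads. The published
description does not state the null success probability; `p0 = n/N` is
the package's documented interpretation and the parameter is
injectable. The test is one-sided for enrichment, because the screen
asks about presence, not depletion.

The upper tail `P(X ≥ m)` uses the continuity-corrected normal
approximation `z = (m − M·p0 − 0.5)/√(M·p0(1−p0))` when
`M·p0(1−p0) ≥ approx_validity_min`, and the exact binomial tail
otherwise. The validity floor defaults to 25: computing the gap
between the corrected normal and exact tails over a full grid, the
worst case is 0.020 at variance 5, 0.014 at 10, and first drops below
0.01 around 25. Since the exact tail is cheap precisely when expected
counts are small, the floor is set where the approximation genuinely
achieves 0.01 absolute accuracy; in the classifier regime this test
targets (tens of thousands of minimizers), the normal branch is
essentially always in use. Benjamini–Hochberg correction is applied
within each sample — the taxa screened in one sample form the natural
family — and significance is adjusted p strictly below 0.05. Type-I
error measured on 10,000 null taxa at the generator's scales is 0.047.

## Cohort summaries and the exclusivity screen

The alteration matrix is binary over samples × genes, a cell set when
the sample has any non-silent call in the gene, with genes mutated in
fewer than 2 samples dropped. Hotspot frequencies report both
nearest-integer and one-decimal percentages (both roundings appear in
cohort reporting); a `truncate` display mode reproduces the convention
of truncating 93.75 to 93.7 where needed.

The mutual-exclusivity screen is a margin-preserving permutation test:
null matrices are generated by checkerboard swaps (two rows, two
columns, flip a 2×2 checkerboard) that conserve every row and column
sum, with 10 × (number of 1-cells) swap attempts per permutation after
an equal burn-in. The exclusivity p-value for a gene pair is
`(1 + #{null co-occurrence ≤ observed})/(B + 1)`, with BH across pairs
at FDR 0.1. This is a deliberate stand-in for dedicated exclusivity
software with a per-sample background model, and the two do not agree
numerically. Two measured properties matter for interpretation:

* *Discreteness.* Co-occurrence counts take few values, so permutation
  p-values are super-uniform (conservative); type-I error at nominal
  0.05 measured on independent columns is 0.045, and uniformity holds
  for the standard randomized p (the output's `p_exclusivity_strict`
  column supports that construction).
* *Margin conditioning.* Fixing both margins conditions away part of
  the exclusivity signal when the matrix is sparse (most row sums 1).
  For the planted 25-vs-5-of-32 disjoint pattern, the stationary null
  probability of zero co-occurrence is of order 10⁻²–10⁻³ depending on
  the rest of the matrix, so the pair's raw exclusivity p is robustly
  small but its BH-adjusted q clears 0.1 only for most, not all,
  generator seeds. This conservatism is inherent to margin-preserving
  nulls on sparse cohorts and is the reason dedicated tools model
  per-sample rates instead.

The two-proportion comparison is the Pearson chi-square on the 2×2
carrier table with optional Yates correction (each `|O − E|` reduced by
0.5, clamped at zero). A published statistic for the cross-cohort
hotspot comparison is not reproduced by either the corrected or the
uncorrected form; that number is therefore not a package target and the
exact procedure behind it is unknown.

## The synthetic cohort

The generator emulates the study's structure on a small synthetic
genome — three autosomes of 60, 50 and 47 Mb with a regular exon grid
(2 kb exons every 10 kb, ≈ 31.5 Mb of targets with the 2 bp flank) —
so chromosome-scaling logic is exercised without human reference files.
Defaults are the study conditions: 32 benign and 11 malignant samples;
25 benign *CTNNB1*-hotspot and 5 *FBXW11*-hotspot carriers (disjoint),
plus one malignant *FBXW11* carrier; two low-purity carriers emitted at
VAF ≈ 0.07 to exercise hotspot rescue; background mutation counts
Poisson with per-sample lognormal rates (benign median 0.32/Mb,
sdlog 0.3, spanning ≈ 0.15–0.7; malignant median 0.56/Mb, sdlog 0.5,
spanning ≈ 0.2–2.5); one hypermutator fixed at 7.5/Mb with indel:SNV
1:3 against the background 1:9, echoing mismatch-repair-deficient
indel spectra; q-arm losses planted in 4/11 and 2/11 malignant samples
(the synthetic counterparts of the study's 16q and 5q losses); one
10-switch 2-state chromothripsis plant; two-hit narratives for *MLH1*
(splice + LOH), *CYLD* (variant + arm-loss LOH), *KMT2D* and *DICER1*
(double mutants); and a minimizer report of 150 taxa at
database/read scales typical of capped classifier databases
(`M` ~ 10⁴–10⁵, `n` ~ 10²–10⁴ of `N` = 10⁶ reads), with one taxon
enriched tenfold over its null expectation.

Background mutations avoid the six anchor genes so planted carrier
counts are exact. Per-sample random streams are forked by a stable hash
of the sample id: adding a sample never perturbs another sample's data.
Everything is deterministic given (config, seed), down to byte-identical
output bundles.

What passing the planted-truth tests shows is that the pipeline's
logic recovers known structure of the configured magnitudes; it does
not show robustness to the things the generator deliberately omits:
caller error models, trinucleotide-context mutation spectra, FFPE
artefact modes, subclonality, segmentation noise in copy-number
profiles, or classifier misassignment. Real-data thresholds (VAF
floors, difficult-region masks, fit-quality cut-offs) exist precisely
for failure modes the synthetic cohort does not simulate.

## Numerical conventions

* Variants are 1-based inclusive (VCF); interval files are 0-based
  half-open (BED); conversions happen only at the I/O boundary.
  Mixed chromosome naming styles in one file are an error.
* Copy-number profiles with goodness of fit below 0.9 are flagged
  `low_fit` and refused by downstream copy-number stages.
* Threshold scaling rounds halves away from zero; percentage reporting
  offers nearest-integer, one-decimal, and truncating display modes.
* VAF at zero depth is 0 and the record is removed as malformed.
* The exclusivity permutation chain, the generator, and every test
  are seeded; the acceptance script threads one seed through all of
  them.

## Problem sizes used in the tests

The suite runs the full default cohort (43 samples, ≈ 1000 raw calls)
through every stage; oracle comparisons use 200 random segment
profiles, exhaustive rank-sum enumeration at groups ≤ 6, a full
binomial-tail grid, 10,000 null taxa for calibration, 400–2000
permutations for the exclusivity screen, and 100 generator seeds for
planted-truth recovery. These sizes make every statistical property
measurable at desk scale while keeping the whole suite under a few
minutes on one core.
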