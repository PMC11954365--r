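---
title: "Tri-omic direct-target calling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tri-omic direct-target calling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromtriad)
```

# The question the pipeline answers

A chromatin remodeler can change a gene's expression in two ways: directly,
by binding at the locus and opening or closing chromatin there, or
indirectly, through downstream regulators. Given three assays on wild-type
(WT) and knockout (KO) cells — ChIP-seq for where the remodeler binds,
ATAC-seq for where accessibility changes, and RNA-seq for which genes change
expression — `chromtriad` identifies *direct targets* (genes both bound and
differentially expressed) and classifies each by mechanism: whether binding
represses or activates the gene, and whether it does so by closing or
opening the locus.

# The procedure, stage by stage

## Replicate-consensus peaks

Peak callers produce per-replicate calls with replicate-private noise. Peaks
are clustered transitively whenever two of them overlap by at least 50% *of
the shorter peak* (a symmetric criterion; the threshold `consensus_min` is
configurable), each cluster is replaced by its convex hull, and clusters
supported by fewer than two distinct replicates are discarded. Transitive
clustering mirrors the merge semantics of standard interval tools: if A
matches B and B matches C, all three merge even if A and C alone would not.
Since hulls of distinct clusters can themselves overlap, a final any-overlap
merge guarantees a pairwise-disjoint consensus set.

The *master list* for counting is the any-overlap (≥ 1 bp) union of the
per-sample consensus sets. The 50% rule is applied only within replicate
aggregation; cross-assay overlap (ATAC × ChIP) uses ≥ 1 bp
(`binding_min_bp`), because a binding site and an accessibility peak need
not have similar extents.

## Counting, normalization, and the three-class call

A fragment is assigned to the unique master peak containing its *midpoint*.
Any-overlap counting would double-count fragments spanning peak edges;
the midpoint rule assigns each fragment at most once, so column totals never
exceed fragment totals. Counts are normalized as TPM (dividing by peak
width, then scaling each sample to one million) or CPM; TPM columns sum to
1e6 by construction, which the tests assert to 1e-6 relative error.

Features are split into three classes by the log2 fold change of group
means on normalized values, with a pseudocount of 1 as a stabilizer:

* `up` if log2FC ≥ cutoff, `down` if ≤ −cutoff, `same` otherwise
  (inclusive boundary, documented rather than inferred);
* defaults: 0.4 for accessibility, 1.0 for the headline expression list,
  0.7 for the integration step — three different cutoffs because the three
  questions tolerate different effect sizes, all exposed in
  `pipeline_config()` and never hard-coded.

An optional FDR filter (Welch t on log2(normalized + 1), Benjamini–Hochberg
adjusted, `q_max` 0.05) is available for replicated designs. It is off by
default: with two replicates per group the t-test has almost no power, so
the filter would silence true planted effects without protecting much
against false ones; it is an approximation and documented as such.

## Fragment-size quality control

ATAC libraries have a characteristic fragment-size fingerprint: a large
sub-nucleosomal fraction (< 100 bp, cut in open chromatin) and a
mono-nucleosome mode near 200 bp. `fragment_size_qc()` histograms sizes in
10-bp bins and reports the fraction strictly below 100 bp, the modal size
among bins with centers ≥ 120 bp, and a periodicity flag: a strict local
maximum with bin center in [160, 260] bp.

## Feature annotation and region-normalized enrichment

Every base is labeled with exactly one class under the precedence
TSS > 5'UTR > exon > intron > intergenic; the TSS window is ±500 bp
(`tss_halfwidth`). A single-label partition is required because the output
is a proportion per class; TSS priority reflects that promoter-proximal
binding is the signal of interest. A peak's class is the class of its
midpoint base. The region-normalized proportion for class *c* is
(peaks in *c* / all peaks) ÷ (bp of *c* / genome bp), so 1 means "exactly
its genomic share": uniformly placed peaks converge to 1 in every class,
which is both a unit test and an acceptance property.

Peaks map to genes by nearest TSS within 5 kb of the peak midpoint
(`max_tss_distance`), with lexicographic gene-id tie-breaks; failing that,
to a gene whose span contains the midpoint; otherwise unassigned. Real
annotation pipelines differ in this rule and published work rarely states
it; ours is a documented choice, not an inference, and both radii are
configuration.

## Binding stratification and paired coverage

Differential ATAC peaks are partitioned into {bound, unbound} × {up, down,
same} by ≥ 1 bp overlap with consensus ChIP peaks. For each cell, fixed
1.5-kb flanks around peak centers (3 kb regions, 50-bp bins by default; the
flank must be divisible by the bin) yield a coverage matrix per genotype
over the *same* region list, so WT and KO rows are directly comparable.
Regions that would run past a chromosome end are dropped, not clipped, so
all matrix rows stay commensurate; the count of dropped regions is
reported in a warning. Profiles are column means; with planted KO-specific
gains at bound sites the KO profile exceeds WT at the central bins for the
bound-up class, and the mirror holds for bound-down.

## The mechanism taxonomy

With `up` meaning higher in KO, a bound gene whose RNA goes up while its
chromatin opens was, in the wild type, *repressed by binding-mediated
closing*; the four combinations are:

| RNA class | ATAC class | mechanism              |
|-----------|-----------|------------------------|
| up        | up        | repressed_via_closing  |
| up        | down      | repressed_via_opening  |
| down      | up        | activated_via_closing  |
| down      | down      | activated_via_opening  |

A gene's ATAC class is the class of its assigned peak with the largest
|log2FC| — deterministic and sensitive to the strongest remodeling event
when a gene owns several peaks. Direct targets without an up/down ATAC call
stay `unresolved`.

## Gene-set statistics

Two statistics are implemented in the package itself so they can be tested
against brute force:

* **Over-representation**: the exact hypergeometric upper tail
  (`stats::phyper`) for the overlap between a query and a set within a
  universe, with a Haldane 0.5 correction on the 2×2 odds ratio when a cell
  is zero. Tests compare against full enumeration for universes ≤ 12.
* **Preranked enrichment**: the weighted Kolmogorov–Smirnov running sum —
  hits increment by |score|^p / Σ|score|^p (p = 1 by default), misses
  decrement by 1/(N−Nh); the enrichment score (ES) is the extremum of
  largest magnitude. When the positive and negative extrema tie in
  magnitude (exact rational ties can arise from the miss decrement), the
  positive one wins, compared with a 1e-12 tolerance so the choice cannot
  depend on floating-point summation order.

Significance uses a gene-label permutation null (random same-size sets),
the only option without sample-level data. NES divides ES by the mean
|null ES| of the same sign. The p-value is (1 + #{|null ES| ≥ |ES|}) /
(1 + n_perm): extremeness is defined on magnitudes because the sign of the
observed ES is data-chosen — conditioning the tail on that sign doubles the
type-I rate (measured ≈ 0.10 at α = 0.05), while the magnitude definition
is calibrated (measured ≈ 0.04–0.05). FDR across sets is Benjamini–Hochberg
on the permutation p-values, simpler and more testable than NES-pooling.

# The synthetic study and what it does (not) show

`sim_config()` encodes the study design: two genotypes × two replicates for
ATAC and RNA, one ChIP experiment (antibody vs IgG background) × two
replicates, and a planted gene taxonomy of 20 genes per mechanism category,
40 bound-but-unchanged genes, 40 unbound genes with indirect changes (half
up, half down, populating the unbound stratification cells), and a null
remainder.

Key parameters, units and rationale:

* `lfc_rna = 2.0`, `lfc_atac = 1.5` (log2): comfortably above the 0.7/0.4
  class cutoffs, so default recovery tests isolate pipeline correctness
  from statistical power. A "hard mode" with effects at 1.1× the cutoffs is
  run and reported (not asserted) to show graceful degradation.
* `nb_dispersion = 0.2`: the coefficient of variation of the mean-1 Gamma
  intensity in the Poisson-Gamma noise, i.e. counts are negative-binomial-
  like with variance µ + (0.2²)µ². One sampler serves RNA counts and ATAC
  fragment intensities. Under this parameterisation a 2-vs-2 design has
  sd(log2FC) ≈ 0.3 for well-expressed features, which makes the generator's
  own calibration contracts hold (planted "same" genes stay under the 0.7
  cutoff ≥ 95% of the time; planted effects are recovered ≥ 95%).
* `n_genes = 1000` with 160 planted: differential features are kept a small
  fraction of the universe, as in real datasets where a few hundred genes
  change among tens of thousands. This matters because TPM is compositional:
  planting large effects in a large fraction of features shifts every
  log2FC by the library-size ratio. At 12% planted the shift is ≈ −0.2
  log2 units — visible, realistic and tolerable; at 40% it would push null
  genes across the cutoffs wholesale.
* `reads_per_sample = 3e5` ATAC fragments, ~200 fragments per peak,
  RNA baseline means log-normal around 300 (floored at 30 — planted targets
  are expressed genes): large enough that Poisson noise is secondary to the
  dispersion, small enough that the full pipeline runs in ~20 s. These are
  the problem sizes used throughout the tests and the acceptance script.
* `replicate_jitter = 50` bp on ~400 bp peaks: replicate copies of a planted
  peak always satisfy the 50% rule (worst case 300/400 = 0.75; the
  constructor rejects jitter that could break the guarantee), while
  replicate-private decoys (`singleton_rate = 0.2`) are placed with ≥ 1 kb
  clearance from all real peaks and from each other, so consensus must
  remove 100% of them.
* Fragment sizes: 55% sub-nucleosomal (Normal(60, 15), ≥ 20 bp) and 45%
  mono-nucleosomal (Normal(200, 20)), reproducing the short-fragment
  fraction and ~200 bp mode that the QC operation checks.

Every stage derives its own sub-seed from the master seed, so the whole
generator is deterministic and stages remain deterministic when called
standalone.

What the generator does *not* emulate: sequence composition and mappability
bias, peak-width/signal correlations, overdispersion that varies with mean
(a single dispersion is used), chained or nested gene structures,
enhancer–gene skipping, or any cross-build coordinate mismatch (one
annotation serves all three assays). Passing the recovery tests therefore
shows the *logic* of the integration is correct under known noise — it does
not certify performance on real libraries, where peak calling, alignment
artifacts and annotation ambiguity dominate.

# Numerical and degenerate-input policy

* Coordinates are 0-based half-open (BED convention) everywhere on disk;
  the GRanges conversion (+1 on start) is confined to one internal helper.
  Chromosome names are matched strictly — "chr1" and "1" never coerce —
  because silent coercion hides fixture bugs.
* Empty inputs are either identities (union with an empty set) or errors
  with named causes (consensus with < 2 replicates, empty RNA universe,
  empty matrix profiles); inverted or negative coordinates error at read
  time with the offending line number.
* Ties: equal TSS distances resolve to the lexicographically smaller gene
  id; equal |log2FC| peaks resolve by table order then peak name; equal
  enrichment p-values order by |NES| (or odds ratio) then set name.
* A zero-sum normalization column, a missing feature length for TPM, or a
  bin size that does not divide the region width are errors, not warnings.

# Limitations

The FDR filter is a deliberately simple approximation (per-feature Welch t),
not a shrinkage-based count model; for real data a dedicated differential
framework is preferable, and the tri-class call by fold change alone is the
primary, tested path. The peak→gene rule ignores three-dimensional contacts.
The permutation null treats genes as exchangeable, ignoring gene-gene
correlation. Mechanism categories are overlap-defined labels: they assert
co-occurrence of binding, accessibility change and expression change at a
gene, not causation.
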