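---
title: "Methods: replicated amplicon genotyping and expression classification of MHC-I alleles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replicated amplicon genotyping and expression classification of MHC-I alleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Passerine birds carry many duplicated MHC class I genes.  Amplicon
sequencing of the hypervariable exon 3 yields, per individual, a set of
allele sequences without locus assignment; sequencing the same amplicon
from genomic DNA (gDNA) and from reverse-transcribed mRNA (cDNA) makes the
*relative read depth* of each allele in cDNA a proxy for its transcription
level.  `mhcpipe` implements the analysis chain that turns denoised
per-amplicon variant counts into:

1. **verified alleles** (filtering out residual PCR/sequencing noise),
2. a **high/low expression call** per allele,
3. a split into putatively **classical** and **non-classical** alleles, and
4. **divergence statistics** per allele class.

The package consumes DADA2-style output: a long-form table of read counts
keyed by (individual, primer combination, DNA type, replicate, variant).
Demultiplexing, primer trimming and denoising are out of scope.

## Allele verification

Within each amplicon group (one individual x primer combination x DNA type
x replicate) every variant gets a frequency `count / group total`.
Filtering proceeds in three steps.

**Length/frame filter.**  Variants whose length deviates from the primer
combination's expected amplicon length by anything other than a multiple
of three are discarded: in-frame 3-bp indels are genuine allelic variation,
frame shifts are artefacts.  An optional screen additionally removes
variants whose translation contains a stop codon; it is off by default
because open-reading-frame status is a biological observation one may want
to keep, and on in a recommended profile for expression work.

**Duplicate-repeatability threshold.**  A subset of samples is amplified
and sequenced twice.  For each primer combination the minimum per-amplicon
frequency threshold is chosen by grid search (default grid 0 to 0.05 in
steps of 1e-4): candidate threshold `t` keeps the variants with frequency
`>= t`, and the selected `t` is the smallest grid value maximising the mean
Jaccard index between the kept sets of each duplicate pair.  The grid makes
the procedure exactly reproducible; taking the *smallest* maximiser keeps
the threshold as permissive as the duplicates allow.  A variant passing the
threshold in at least one gDNA group of an individual is a verified allele.

**Expressed-allele calling.**  A cDNA variant that matches a verified gDNA
allele of the same individual is expressed at any read count.  A cDNA-only
variant must have at least 100 reads *and* reach the mean per-variant
frequency of its primer combination's cDNA groups.  The source data's
filtering rule conditions on "average read depth"; whether that meant mean
frequency or mean raw depth is ambiguous, so both operationalisations are
exposed (`cdna_only_rule = "frequency"` (default) or `"depth"`).
Individuals whose cDNA sequencing failed are flagged and excluded from all
expression analyses.

## Expression classification

Relative depths are computed per (individual, primer combination, DNA
type) after pooling technical replicates by summed counts — duplicates
show very similar relative depths, and pooling is deterministic and
variance-reducing (replicate averaging would differ only at the third
decimal on typical depths).

**Equal-expression threshold.**  With `n` expressed alleles amplified for
an individual by a combination, equal transcription would give each a
relative depth of `1/n`.  An allele is *high* iff its relative depth is
strictly above `1/n`; ties go to *low* (ties are measure-zero on real
counts, and "higher than expected" reads naturally as strict).

**Between-combination reconciliation.**  Two primer combinations amplify
cDNA (PC2 within exon 3, PC3 spanning exon 2-3).  Agreeing calls stand;
alleles seen by one combination keep that combination's call; conflicts go
through two rules that exploit PC2 being run on both DNA types:

* *Ratio rule:* the allele is high if its PC2 cDNA relative depth is at
  least `1 + margin` times its PC2 gDNA relative depth, with
  `margin = 0.25` ("one fourth higher").  The margin is multiplicative: an
  additive margin of 0.25 in relative-depth units would exceed nearly all
  observed depths (thresholds sit near 1/11 ≈ 0.09) and could never fire.
* *Cleaning rule:* an allele barely amplified in **both** DNA types —
  relative depth below `barely_amplified_fraction` (default 0.5) of the
  equal-expression threshold in each — is treated as an amplification
  error and removed.  The source analysis states "barely"/"not
  satisfactory" qualitatively; half the equal-expression threshold is a
  declared, config-overridable quantification, not an inferred one.

The ratio rule is checked first, matching the order in which the rules
were applied; remaining conflicts are *undetermined* pending the
cross-individual step.  As a QC statistic, `validate_ratio_rule()` reports
the fraction of PC2-high alleles that also satisfy the ratio rule.

**Cross-individual consolidation.**  Alleles shared by several individuals
should have the same expression class (same gene copy).  Unanimous calls
stand.  In a conflict, if exactly one side lies entirely within the
near-threshold band (relative depth within ±10% of `1/n`,
`near_threshold_band`), the other side wins — this encodes "clearly high
in one individual, just barely under the limit in the other" without
per-case judgement.  Conflicts that remain are undetermined; balanced ones
(|#high − #low| ≤ 1 with both sides occupied and far from threshold) are
flagged `locus_conflict`, the signature of one sequence occurring at two
gene copies with different expression.

Every expressed allele therefore ends in exactly one of
{high, low, undetermined}; the partition is checked in the tests.

## Tree building and the classical/non-classical split

Putatively non-classical alleles are defined by three joint criteria:
membership in a highly supported phylogenetic cluster, no highly expressed
member, and low within-cluster divergence.

The tree is neighbor joining over Kimura two-parameter (K80) distances,
with clade support from bootstrap resampling of alignment columns
(default 1000 replicates).  Distance-based NJ replaces maximum-likelihood
inference deliberately: the classification consumes only the "highly
supported cluster" structure, not branch lengths, NJ is deterministic and
fast enough to bootstrap thousands of times, and an import hook
(`read_support_tree()`) accepts an externally built ML tree with supports
for users who want likelihood inference.  Gamma rate heterogeneity is
omitted from the distance (plain K80): at the divergence levels involved
(mean amino-acid P-distance ≤ 0.17) cluster structure is insensitive to
it, and the shape parameter is not available.  NJ tie-breaking follows the
underlying implementation's fixed ordering, so results are reproducible.

Alleles differing by the in-frame 3-bp insertion are aligned by inserting
a gap triplet into the non-insertion alleles at the annotated codon
boundary (`insertion_codon`); gapped columns are excluded pairwise from
all distances.

The tree is rooted on an outgroup MHC-I sequence (midpoint rooting is the
fallback).  `find_supported_clusters()` reports maximal clades whose
subtending edge support reaches `cluster_support_min` (default 950/1000).
The figure-style display cutoff (700) and the classification cutoff are
distinct configurables: the displayed-support convention is more
permissive than what should count as decisive evidence for a gene-class
claim, and the observed non-classical cluster support (987) sits
comfortably above 950.  A cluster is non-classical iff, additionally, no
member has a high cohort expression call and the mean within-cluster
amino-acid P-distance is at most `cluster_pdist_max` (default 0.05).  The
divergence criterion is applied as a post-hoc filter on discovered
clusters (whether it was originally assessed before or after cluster
discovery is unstated; filtering afterwards is the order that needs no
extra tuning).

## Divergence statistics

All divergence analyses run on alleles trimmed to a common region
(`trim_codons`, default codons 16-72, i.e. 57 codons — the exact published
trimming coordinates are not printed, so the region is a configuration
input) and collapsed to unique nucleotide sequences.  Reported per class:

* `NA` (unique nucleotide alleles), the total at original lengths, and
  `AA` (unique proteins); **haplotype degeneracy** = AA/NA.
* **Amino-acid P-distance**: mean over all pairs of the proportion of
  differing sites, gaps excluded pairwise; the standard error is the SD of
  the mean across 500 site-bootstrap replicates (the usual convention;
  the replicate count is not stated in the source and is configurable).
* **Nei-Gojobori dN/dS** (pathway counting): per-codon synonymous site
  fractions averaged over the pair (changes to stop codons counted as
  non-synonymous, so S + N equals the nucleotide length); codons with
  multiple differences averaged over all shortest substitution pathways
  with equal weight, pathways through stop codons excluded; pairwise
  proportions Jukes-Cantor corrected by default (`dnds_correction =
  "none"` gives raw pN/pS — whether the published values were corrected is
  not stated, so both are exposed); the class value is the mean over all
  pairs.  Pairs with proportions ≥ 3/4 are excluded with a warning.

Positive-selection site inference (CODEML) is out of scope; the report
carries no stand-in for it.

## The synthetic cohort generator

Every stage is testable without external data via `simulate_cohort()`,
which plants a known truth:

* **Pool** (default 70 classical + 18 non-classical = 88 alleles, 258-nt
  amplicons): classical alleles take 8 non-synonymous and 4 synonymous
  single-nucleotide codon changes from a common ancestor (mean amino-acid
  P-distance ≈ 0.16, dN ≈ 0.08, dS ≈ 0.12-0.14); the non-classical
  ancestor sits 24 substitutions away and its 18 descendants differ by 1-2
  mostly synonymous changes (a third carry one non-synonymous change),
  giving mean amino-acid P-distance ≈ 0.01 and degeneracy well below one.
  Eight alleles carry an in-frame 3-nt insertion.  Two alleles per class
  are never expressed.
* **Individuals** (default 18): 6-16 alleles each (mean 11, SD 3), with
  2-5 high-tier classical alleles, 2-6 non-classical alleles and the rest
  low/none-tier classical.  The high-tier count scales with the total
  allele count (≈ 0.3k, clamped), matching the observed joint pattern of
  ~11 alleles with ~3 high and ~6 low per individual and keeping the gDNA
  depth distributions of the high and low groups comparable.
* **Counts** (default 50,000 reads/group): gDNA groups draw multinomially
  from equal expected depths, cDNA groups from tier-scaled weights — high
  2.5/n, low 0.4/n.  These sit clearly on either side of the 1/n threshold
  for *any* mixture of tiers (2.5·n > 2.5h + 0.4l > 0.4·n always), while
  small n still produces near-threshold cases.  A lognormal amplification
  bias (SD 0.15) per allele x individual x combination is shared across
  technical replicates, reflecting that duplicates reproduce relative
  depths.  Each group receives Poisson(2) error variants, 1-2 substitutions
  off a carried allele; the most abundant error sits at a 0.5% frequency
  ceiling and the rest decay below it, emulating the stable residual-error
  ceiling left after denoising — and guaranteeing, by construction, that
  the duplicate-derived threshold separates noise from the sparsest true
  allele (1/16 ≈ 6%).  A quarter of pool alleles are invisible to one
  primer combination (mimicking primer mismatch), which exercises the
  single-combination and reconciliation code paths.

What the generator does **not** emulate: read-level errors and quality
(denoising is upstream), chimeras, contamination, allele-specific
amplification efficiencies correlated with sequence, copy-number variation
between haplotypes, and any relationship between expression tier and
sequence.  Passing recovery tests therefore demonstrates that the
implemented rules invert the generator's noise model, not that the rules
are optimal on arbitrary real data.

## Problem sizes and determinism

The test-suite recovery checks run ten cohorts of 18 individuals at
default settings (50,000 reads per group, 1000 bootstrap replicates),
chosen to mirror the study's cohort size while keeping a full 10-seed
sweep at a few minutes on one core.  All stochastic stages (simulation,
bootstraps, P-distance SE) take explicit seeds; identical seeds give
byte-identical results.  Degenerate inputs are handled explicitly: empty
groups are rejected at validation, saturated K80 pairs return `Inf`,
undefined Jukes-Cantor corrections exclude the pair with a warning, groups
of fewer than two alleles report `NA` divergence, and cohorts without
duplicates require a manual threshold.

## Worked example

```{r example}
library(mhcpipe)

cfg <- mhc_config()
sim <- simulate_cohort(n_individuals = 18, seed = 1, config = cfg)
run <- run_mhc_pipeline(sim$counts, cfg, outgroup = sim$outgroup)

print(run$report)       # cohort tallies, QC, tests
run$divergence          # per-class divergence table
evaluate_recovery(run, sim)
```

## Known limitations

* Alleles cannot be assigned to loci; `n` alleles only bounds the copy
  number from below, and a shared sequence at two differently expressed
  copies surfaces only as a `locus_conflict`.
* Relative read depth is a transcription proxy; nothing here speaks to
  protein or cell-surface expression.
* The in-repo aligner only handles the single annotated 3-nt insertion;
  arbitrary indel structure requires aligning upstream and importing the
  alignment.
* The cDNA-only expression rule and the "barely amplified" cut-offs are
  declared operationalisations of qualitatively described rules; both are
  configuration-exposed so sensitivity can be checked.
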