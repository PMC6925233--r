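# mhcpipe

Verification, expression classification and divergence analysis of MHC
class I alleles from replicated amplicon sequencing.

## What it is for

Passerine birds carry many duplicated MHC-I genes.  Sequencing the
hypervariable exon 3 amplicon from both genomic DNA (gDNA) and
reverse-transcribed mRNA (cDNA), in several individuals with technical
replicates, makes it possible to (i) verify which amplicon variants are
true alleles, (ii) score each allele's transcription level from its
*relative read depth* — its count divided by the amplicon total — and
(iii) separate putatively *classical* from *non-classical* alleles.
`mhcpipe` implements that pipeline for researchers doing MHC genotyping
and expression work on denoised (DADA2-style) variant-count tables, plus a
synthetic cohort generator with planted truth so every stage can be
validated end to end.

The core statistics, in the field's usual notation:

* **Equal-expression threshold**: with `n` expressed alleles in an
  individual, an allele is highly expressed iff its relative cDNA depth
  exceeds `1/n`.  Discrepancies between the two cDNA primer combinations
  are resolved by a ratio rule (cDNA relative depth ≥ 1.25 × gDNA relative
  depth ⇒ high) and a cleaning rule for barely amplified variants, then
  consolidated across individuals.
* **Duplicate-repeatability threshold**: the per-primer minimum amplicon
  frequency is the smallest grid value maximising the mean Jaccard index
  between the above-threshold variant sets of duplicated samples.
* **Classical/non-classical split**: a bootstrap-supported
  neighbor-joining cluster (K80 distances, support ≥ 950/1000) whose
  members all lack high expression and whose mean within-cluster
  amino-acid P-distance is ≤ 0.05 is called non-classical.
* **Divergence per class**: haplotype degeneracy AA/NA, amino-acid
  P-distance ± site-bootstrap SE, and Nei–Gojobori pathway-counting
  dN/dS (Jukes–Cantor corrected).

## Worked example

```r
library(mhcpipe)

cfg <- mhc_config()                                   # study defaults
sim <- simulate_cohort(n_individuals = 18, seed = 1)  # planted truth
run <- run_mhc_pipeline(sim$counts, cfg, outgroup = sim$outgroup)
print(run$report)
```

```
MHC-I cohort report
  individuals: 18; alleles: 79 (76 expressed, 96%)
  n_gdna          11.1 +/- 2.7  (min 8, max 16)
  n_cdna          10.4 +/- 2.4  (min 7, max 15)
  n_classical      8.2 +/- 2.1  (min 5, max 13)
  n_nonclassical   2.8 +/- 1.0  (min 2, max 5)
  n_high           3.5 +/- 0.7  (min 2, max 5)
  n_low            6.9 +/- 2.0  (min 4, max 10)
  expression partition: 28 high / 48 low / 0 undetermined
  primer-combination agreement: 100% (152 of 152)
  Mann-Whitney cDNA high vs low: W = 6993, p = 6.84e-28
  Mann-Whitney gDNA high vs low: W = 3620, p = 0.701
  Fligner-Killeen classical vs non-classical: chi2(1) = 58.17, p = 2.41e-14
```

Each individual carries 8–16 verified alleles, almost all expressed, with
2–5 highly expressed ones.  The high/low contrast is strong in cDNA but
absent in gDNA — amplification bias is not driving the calls — and
classical alleles show far more expression variance than the non-classical
cluster.  The per-class divergence table:

```r
run$divergence
```

```
           group n_nt n_full n_aa degeneracy      pdist    pdist_se          dN         dS
1   nonclassical   14     16    5  0.3571429 0.01020408 0.004717073 0.004510272 0.05660556
2  classical_all   63     63   63  1.0000000 0.16426563 0.009683809 0.078023372 0.13847785
3 classical_high   28     28   28  1.0000000 0.16118670 0.013706610 0.077829107 0.12787850
4  classical_low   33     33   33  1.0000000 0.16668269 0.014108604 0.078429440 0.14593697
```

The planted non-classical clade is an order of magnitude less divergent
than the classical pool, with dN another order below that, and
`evaluate_recovery(run, sim)` confirms the pipeline recovered every
planted allele with no false positives and correct tiers and classes.

A thin command-line wrapper over the same functions is at
`inst/cli/mhcpipe.R` (`simulate`, `verify`, `express`, `pipeline`
subcommands).

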