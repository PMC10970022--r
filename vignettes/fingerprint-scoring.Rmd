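---
title: "Fingerprint scoring of genomic sites: model, thresholding and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprint scoring of genomic sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpfinder)
```

## The model

`fpfinder` identifies genomic sites that are simultaneously *frequent* in a
target sub-population and *rare* in a background cohort. The analogy is
text retrieval: samples are documents, variant sites are terms, and a
sub-population's characteristic sites are the terms with high term
frequency (TF) inside it and high inverse document frequency (IDF) in the
corpus.

A multi-sample VCF is first reduced to a boolean presence/absence matrix: a
site is *present* in a sample iff the genotype carries at least one ALT
allele. For a site carried by $k$ of $n_t$ target samples and $m$ of $n_b$
background samples, the default score is

$$\mathrm{score} = \underbrace{\frac{k}{n_t}}_{\mathrm{tf}}
  \times \underbrace{\log_{10}\frac{n_b + 1}{m + 1}}_{\mathrm{idf}}.$$

TF is a plain presence fraction in $[0,1]$; IDF is non-negative, zero when
the site is ubiquitous in the background, and at most $\log_{10}(n_b + 1)$
when it is absent from it. The score is therefore bounded by
$\log_{10}(n_b+1)$ — about 2.61 for a 410-sample background — monotonically
increasing in $k$ and decreasing in $m$, and exactly zero whenever the site
is absent from the target.

### Formula variants

The TF-IDF family admits several log bases and smoothing schemes, and the
method's description does not pin one down. `scoring_config()` makes the
choice explicit:

* `log_base`: 10 (default) or $e$. Base 10 keeps the permutation threshold
  for the 20-vs-410 design in the 0.7–0.9 range where the published
  realization (0.817) lies; natural log scales everything by $\ln 10$.
* `smoothing`: `add-one-both` (default, $\log((n_b+1)/(m+1))$),
  `add-one-denominator` ($\log(n_b/(m+1))$), or `none`
  ($\log(n_b/m)$, infinite at $m = 0$). Add-one-both is the standard
  smoothed IDF: finite everywhere, zero for ubiquitous sites.
* `background_mode`: `disjoint` (the background is only the samples labelled
  `background`; used for a pedigree scored against an external cohort) or
  `full-cohort` (every sample counts toward the background; used when a
  region's members are themselves part of the cohort). The two modes are
  explicit because silently inferring nesting from sample labels would make
  $m$ ambiguous — in full-cohort mode a target-exclusive site necessarily
  has $m = k$.

## The permutation threshold

Rather than a fixed cutoff, the selection threshold is the top-5% boundary
of a simulated null: draw $k$ uniformly from the integers
$\{0,\dots,n_t\}$ and $m$ uniformly from $\{0,\dots,n_b\}$, independently,
1000 times; score each pair; take the smallest score $s$ such that at least
$\lceil 0.05 \times 1000 \rceil = 50$ scores are $\ge s$ (the
nearest-rank-from-above rule, so "top 5%" means exactly the 50 largest
scores sit at or above the boundary). The draws are integer presence
*counts*, not real-valued frequencies — frequencies in finite cohorts are
integers over the sample size.

This null assumes no association between target and background presence and
uniform marginal counts; it is deliberately conservative in the upper tail,
where real cohorts concentrate far fewer high-TF/low-DF sites than the
uniform null does.

Because the null is a finite discrete distribution — $(n_t+1)(n_b+1)$
equiprobable $(k, m)$ pairs — its quantiles are exactly computable.
`exact_null_quantile()` enumerates all pairs (8,631 for the 20-vs-410
design) and returns the stable reference that Monte-Carlo thresholds
converge to as the number of simulations grows:

```{r}
exact_null_quantile(n_target = 20, n_background = 410, top_fraction = 0.05)
```

A single 1000-draw realization scatters around this value with a spread of
roughly $\pm 0.1$; the test suite verifies that the across-seed
distribution brackets both the exact quantile and the published single
realization (0.817). Seeds are mandatory everywhere randomness exists — no
wall-clock defaults — so every threshold is reproducible.

## Region-specific scanning

For geographic analysis, each site is scored once per region: TF over the
region's samples, IDF over the whole cohort (full-cohort mode). The region
with the highest score is the site's *enriched region*; exact ties are
broken lexicographically by region label and flagged rather than hidden.
Two selection rules follow the pedigree analysis's spirit:

* `trim_low_specificity()` drops sites whose maximum score across regions
  is below 0.1 (boundary inclusive) — sites with no meaningful geographic
  signal anywhere.
* `select_region_specific()` takes, *per region column independently*, the
  sites at or above the nearest-rank top-0.1% quantile of that column. The
  per-region reading (rather than pooling all columns) is the design
  choice here: a "region-specific site" is defined relative to its own
  region's score distribution, and the per-region counts plus their union
  are both reported so either convention can be recovered.

`compare_enriched_groups()` resolves an externally supplied functional-site
list (e.g. GWAS hits with signed effects) against the score table,
partitions by enriched region, and compares any two groups with a Welch
t-test (or Wilcoxon). The positive-effect subset is an explicit filter
flag, never inferred. Unresolvable site keys are reported, not dropped.

## Genic-context annotation

Sites are classified against GFF3 gene models with a transparent rule set
instead of an external annotator, so the category of every site is exactly
auditable:

* Categories and precedence: splicing > UTR5 > UTR3 > exonic > intronic >
  upstream 1 kb > downstream 1 kb > intergenic. Precedence resolves
  multi-feature and multi-gene overlaps to the single reported category;
  all per-gene overlaps are retained in an `all_overlaps` column.
* *Splicing* is within 2 bp of an exon–intron junction on the intron side —
  the common annotator default, chosen because the category is standard but
  its width is rarely stated.
* A site inside an exon that lies in a UTR span is labelled UTR5/UTR3, not
  exonic, since the UTR categories are reported separately.
* Flanks are strand-aware 1 kb: upstream of a minus-strand gene is past its
  highest coordinate.
* Only the first mRNA per gene is used (warning on multi-isoform genes);
  models are validated at load time (exons within the gene span and
  non-overlapping, UTRs within the exon union), so classification itself
  never fails.

The 12-type SNP spectrum counts ordered ref→alt pairs over {A,C,G,T}
without collapsing complementary strands — G→A and C→T are biologically
distinct signals in this context. `gene_related_downsample_test()`
implements the enrichment comparison for unequal set sizes: draw `n_sets`
random subsets of the non-fingerprint pool at the fingerprint set's size,
count gene-related sites per subset, and report the one-sided empirical
p-value $(1 + \#\{\text{counts} \le \text{observed}\})/(n_\text{sets}+1)$.
On small pools the per-set counts follow the hypergeometric law exactly,
which the tests verify against `dhyper`.

## The synthetic cohort

`simulate_cohort()` generates the full input bundle — VCF 4.2, sample
manifest, GFF3 gene models, truth table — for a target sub-population
nested alongside a multi-region background:

* Defaults mirror the pedigree design: 20 target samples, 410 background
  samples over six region labels (USA, YZ, YR, S, N, NW; split near-evenly,
  69/69/68/68/68/68, since no finer breakdown is given), 10,000 sites.
* Unplanted sites draw a per-site presence probability uniformly on
  (0.01, 0.99) and apply it to *every* sample. Target and background
  frequencies are then coupled only through that shared probability, which
  is what keeps false positives rare: a high score needs high TF *and* low
  background frequency simultaneously.
* Planted pedigree sites are present with probability 0.95 per target
  sample and 0.002 per background sample; planted region-specific sites use
  the same pair within/outside one region.
* 5% of records are low-QUAL decoys (QUAL < 30) so the ingestion filter is
  exercised end-to-end; genotypes are emitted as 0/0 vs 0/1.

Presence is simulated directly as site-level Bernoulli draws because the
scoring model consumes only presence. The simulator therefore does **not**
emulate linkage disequilibrium, diploid dosage, missing genotypes, shared
ancestry between target and background, or realistic site-frequency
spectra. Passing recovery tests show the scoring and thresholding machinery
is correct, not that real cohorts separate as cleanly: in real data,
relatedness between the target and background inflates background
frequencies of genuinely target-characteristic sites and pushes scores
down.

## Numerical choices and degenerate inputs

* Missing genotypes (`./.`) count as absent — conservative for both TF and
  IDF — with per-site missingness recorded and an optional
  `max_missing_frac` filter. Multi-allelic records are dropped (not split)
  and counted; so are non-SNP and sub-threshold-QUAL records.
* Monomorphic matrix rows are retained: they score 0 (all-absent) or
  minimal IDF (all-present) and keeping them makes site counts auditable.
* Ranked outputs break score ties by (chrom, pos); selection boundaries are
  inclusive everywhere (`score >= threshold`, `max_score >= cutoff`).
* Empty target or background sets, regions with zero samples, manifest
  samples missing from the VCF, and truth/result universe mismatches are
  hard errors naming the offender; an all-filtered VCF warns explicitly
  rather than succeeding silently.

## Problem sizes in the test suite

The tests run the oracle comparison on 200 random matrices up to 50 × 30,
the recovery study on 20 seeds of the default 10,000-site cohort, the
region-assignment check on five 3,000-site cohorts with clean (1/0)
planting, the null-convergence check at 2 × 10^5 draws, and the
hypergeometric check at 10^5 down-sampled sets — sizes at which every
stochastic assertion has at least a 3-standard-error margin while the whole
suite stays fast on one CPU.

## Known limitations

* The TF-IDF variant actually used by the original tool is not documented;
  the default here is the standard smoothed form whose null quantile is
  consistent with the published threshold realization, and the alternatives
  remain selectable for sensitivity analysis.
* The permutation null ignores the empirical site-frequency spectrum; on
  real data the top-5% rule is conservative (few real sites reach the
  uniform null's upper tail).
* Annotation reproduces a transparent precedence rule set, not any specific
  annotator's output; category counts on real data will differ from
  annotator-based reports at the margins (isoform choice, splice-window
  width).
* Scores are presence-based: allele dosage, phasing and imputation
  uncertainty are out of scope.
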