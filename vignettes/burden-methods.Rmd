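---
title: "Rare-variant burden, etiological fractions and mutation clustering: methods"
author: "geneburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant burden, etiological fractions and mutation clustering: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneburden)
```

## The model

`geneburden` quantifies how interpretable rare variation is, gene by
gene and variant class by variant class, in a multigenic dominant
Mendelian disease. The data are summary-level: per-variant carrier
counts from disease cohorts sequenced on clinical gene panels, and
per-site allele counts (AC) and allele numbers (AN) from a large
reference population. The model rests on two assumptions:

1. **Symmetric benign background.** Rare benign protein-altering
   variants arise at the same per-individual rate in cases and in the
   reference population. Any excess carrier frequency in cases is then
   attributable to disease-causing variants.
2. **Negligible pathogenic contamination of the reference.** For a
   penetrant dominant disease, pathogenic alleles in the reference
   population are too rare to affect the comparison.

Under these assumptions, for a gene with case carrier frequency
$p_\text{case}$ and reference carrier frequency $p_\text{ref}$:

* the **case excess** $p_\text{case} - p_\text{ref}$ estimates the
  proportion of cases whose disease is caused by a variant in the gene
  (multiplied by the cohort size, it predicts the number of true
  pathogenic-variant carriers — the yardstick against which variant
  counts reported by research studies can be compared);
* the **odds ratio** from the carrier 2×2 table measures enrichment;
* the **etiological fraction** $\mathrm{EF} = (\mathrm{OR}-1)/\mathrm{OR}$
  estimates the probability that a qualifying variant observed in an
  affected carrier is causal — the attributable fraction among the
  exposed, and the single most useful number for a diagnostic
  laboratory deciding whether a novel variant in this gene is
  reportable. EF pools all variants of a class, so it is an average
  over a mixture of pathogenic and benign alleles; a high EF means few
  false positives, not that every variant is pathogenic.

Both measures condition on carrying a *qualifying* variant, which is
where the filter matters.

## The rare-variant filter

Only likely protein-altering consequences on the designated canonical
transcript enter the comparison, split into **truncating**
(frameshift, nonsense, splice donor/acceptor — the first and last two
intron bases) and **nontruncating** (missense, in-frame indels)
classes, plus their union. The two classes behave very differently by
disease mechanism (dominant-negative missense vs haploinsufficiency
truncations), so they are always tested separately as well as jointly.

Variants with reference MAF ≥ `rare_maf_threshold` (default 10⁻⁴) are
removed **from both sides**: more frequent alleles are implausible as
highly penetrant dominant mutations, and removing them symmetrically
preserves assumption 1. The default is a conservative upper bound
calibrated against the most common confirmed pathogenic variants in
this disease family, which sit near MAF 2.5 × 10⁻⁵ in reference data.
Case variants absent from the reference are assigned frequency 0 and
always pass — absence among tens of thousands of reference samples is
evidence of rarity, not grounds for exclusion. Frequencies are global
(not per-ancestry); ancestry robustness is handled by re-running the
pipeline on cohort subsets, not by stratified filtering. A second
threshold, `polymorphism_threshold` (default 10⁻²), marks outright
polymorphisms and is used by the reported-variant audit.

## Coverage-adjusted denominators

Reference cohorts do not genotype every sample at every site. The
reference carrier frequency for a gene/class is
$\sum_i \mathrm{AC}_i / \overline{\mathrm{AN}}$ over the retained
sites, and the effective number of reference individuals is
$\overline{\mathrm{AN}}/2$. With complete genotyping
($\mathrm{AN} = 2N$ everywhere) this recovers the nominal cohort size
$N$; with incomplete coverage it shrinks, so carrier proportions are
never deflated by unsequenced samples. Each allele is counted as one
carrier (`assume_het`): below MAF 10⁻⁴ homozygotes are vanishingly
rare. When a gene/class has no retained reference site, the gene-level
median AN over all sites of the gene supplies the denominator; the
result row is flagged (`ref_fallback_an`), and a gene with no
reference sites at all is an error rather than a silent guess.

## Test statistics and intervals

* **Fisher's exact test**, two-sided by summation of hypergeometric
  probabilities no larger than the observed table's (with the standard
  1 + 10⁻⁷ relative tolerance for ties). It is implemented by direct
  vectorised summation, which the test suite verifies exactly against
  both `stats::fisher.test` and an independent log-binomial
  enumeration over every table with margins ≤ 50. Coverage-adjusted
  (non-integer) reference carrier totals are rounded only for the
  exact test; effect estimates keep full precision.
* **Multiple testing**: Bonferroni over the $m$ genes of the disease
  panel (not genes × classes): significant iff $p \le \alpha/m$. For a
  20-gene panel at $\alpha = 0.05$ that is $p \le 0.0025$; for an
  8-gene panel, $p \le 0.00625$.
* **OR interval**: Woolf log-normal,
  $\exp(\ln \mathrm{OR} \pm z\sqrt{1/a+1/b+1/c+1/d})$, with the
  Haldane–Anscombe 0.5 correction applied to all four cells whenever
  any cell is zero. This is the standard epidemiological default and
  handles zero-carrier genes gracefully. EF bounds are the monotone
  transform of the OR bounds, floored at 0; EF is always computed from
  the unrounded OR, so round-tripping printed (rounded) ORs can differ
  in the second decimal.
* **Case-proportion interval**: Wilson score, which is stable at the
  small proportions typical of per-gene carrier frequencies (Wald and
  Clopper–Pearson agree at one-decimal reporting precision; the choice
  is not distinguishable there).

Carrier counting from summary tables sums per-variant carrier counts;
a case carrying two qualifying variants in one gene is counted twice.
The sum is capped at the cohort size with a warning when the cap
binds; at observed frequencies (a few percent per gene) the bias is
negligible.

## Nonrandom mutation clustering

Pathogenic missense variants often concentrate in functional domains.
The scan works on the **distinct** residue positions of rare missense
variants, scaled by protein length to $x_{(1)} < \dots < x_{(n)}$ in
$(0,1]$. Under positional uniformity, the spacing
$x_{(j)} - x_{(i)}$ follows $\mathrm{Beta}(j-i,\; n-j+i+1)$, so its
CDF at the observed gap is an exact p-value for "closer than chance".
All $n(n-1)/2$ pairs are tested; Benjamini–Hochberg FDR is applied
across pairs; pairs with $q \le$ `fdr_threshold` (default 0.05) are
mapped back to residue intervals and overlapping intervals are merged
into maximal clusters, each reporting its minimum pair p and that
pair's q. Design choices made here:

* **Duplicate residues are collapsed** before the scan: the
  continuous order-statistic model degenerates at zero gaps. The
  alternative — a one-residue resolution floor with carrier-weighted
  positions — would gain power at recurrent hotspots at the cost of a
  calibration that depends on carrier counts; collapsed positions are
  the conservative, deterministic choice.
* **Cluster boundaries** span from the smallest to the largest residue
  among significant pairs after merging. When the true hotspot is wide
  and dense, merging can stretch boundaries toward flanking background
  positions; boundaries should be read as "contains the cluster", and
  the cluster-restricted EF, not the boundary itself, carries the
  interpretive weight.
* `cluster_ef()` keeps the **gene-level denominators** (same
  $n_\text{cases}$, same $\overline{\mathrm{AN}}/2$) and restricts
  only the carrier counts to the interval, so an interval covering the
  whole protein reproduces the unrestricted nontruncating result
  exactly.

## The synthetic-data generator

`simulate_cohorts()` emulates the structure of the real inputs so that
every stage is testable with known truth:

* benign carriers are Bernoulli(`background_rate`) per individual on
  both sides (default 0.01 per gene, typical of large sarcomeric
  genes); each carrier draws an allele from a Zipf-like spectrum
  (exponent 0.5 over a pool that scales with the expected carrier
  count), producing a few recurrent alleles and many singletons with
  the top allele's expected MAF safely below the 10⁻⁴ filter — the
  generator warns if a parameter choice would push recurrent benign
  alleles into self-filtering territory;
* pathogenic carriers occur only in cases, with probability
  `pathogenic_fraction`, one causal variant each, class mix
  configurable, missense positions uniform inside `cluster_interval`
  when given;
* per-site AN comes from a coverage model (`coverage_model_uniform`):
  a fraction of $2 n_\text{ref}$ drawn around `depth_fraction`;
* the implied truth is recorded: with
  $p_\text{case} = 1-(1-\pi)(1-\beta)$ for pathogenic fraction $\pi$
  and background $\beta$, the true OR is the odds ratio of
  $p_\text{case}$ against $\beta$ and the true EF its
  $(\mathrm{OR}-1)/\mathrm{OR}$ transform;
  `pathogenic_fraction_for_ef()` inverts this map.

What the generator does **not** emulate: population structure and
ancestry-specific alleles, genotyping-platform differences between
case and reference cohorts, compound heterozygosity and per-sample
genotypes, and sequencing error. Passing calibration and recovery
tests therefore demonstrates correctness of the statistical machinery
under the model's own assumptions, not robustness to those real-data
complications — the same caveat that applies to the analytical
framework itself.

## Numerical choices and degenerate inputs

* Fisher p-values use the 1 + 10⁻⁷ relative tie tolerance; all-zero
  margins return p = 1 with a warning.
* Degenerate 2×2 tables (an empty study arm) raise errors; zero cells
  are handled by the Haldane–Anscombe correction.
* Unknown consequence terms classify as EXCLUDED with a mandatory
  warning — they can never silently enter a burden class; legacy
  spellings ("nonsense", "stop gained") are handled by an alias table
  over canonical Sequence Ontology terms.
* Scans with fewer than two distinct positions warn and return no
  clusters. Scan output is invariant to position input order.
* All simulation entry points require an explicit seed; identical
  seeds give byte-identical outputs.

## Problem sizes used by the test and acceptance suites

Calibration and recovery experiments in the package's own checks use:
50 null panels of 20 genes at 500 cases / 10,000 reference samples for
family-wise error; 200 uniform-position replicates (n = 30 positions,
L = 1935) for the NMC false-cluster rate; 200 seeds per level at 2,000
cases / 60,000 reference samples for EF recovery at true EF 0.2 / 0.5
/ 0.9 and for hotspot detection (interval 180–940 of a 1,935-residue
protein). These sizes give binomial tolerances comfortably tighter
than the effects being checked while keeping the suites quick to run.

## Known limitations

* Summary-level inputs cannot resolve individuals carrying multiple
  qualifying variants (in one gene or across a reported-variant list);
  carrier sums are capped and the approximation is logged when it
  binds.
* EF is an average over a variant class; it does not classify
  individual variants, and it applies to probands ascertained for the
  phenotype — for incidental findings the prior, and hence the
  posterior probability of pathogenicity, is far lower.
* Bonferroni control treats the panel's genes as the family; variant
  classes within a gene are not separately corrected.
* The clustering scan is one-dimensional in sequence; it cannot see
  3D-structural clustering.
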