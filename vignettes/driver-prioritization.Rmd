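---
title: "Consensus driver prioritization: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus driver prioritization: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

driverscape prioritizes oncogenic driver events in a somatic mutation
cohort at three levels — mutations, genes, and pathways — by combining
statistical evidence of positive selection with prior knowledge from
curated driver catalogs. This vignette describes the model at each
stage, the tunable parameters and their defaults, the synthetic data
generator used for validation, and the design decisions taken where the
procedure was genuinely open.

## Mutation level: extreme and driver mutations

Two mutation classes are called from an annotated MAF cohort.

**Extreme mutations** are changes expected to damage the protein
outright: loss-of-function classes (stop-gain, stop-loss, splice site,
frameshift indels) plus missense mutations whose ReVe pathogenicity
score — a combined in-silico deleteriousness score on [0, 1] — reaches
0.5. The boundary is inclusive, and the raw score is used; the
percentile transform below is presentation only. A missense record with
no ReVe score is never extreme (absence of evidence is treated as
benign, the conservative choice for a damage call).

**Driver mutations** are recurrent, high-confidence oncogenic missense
changes: the exact genomic change (chromosome, position, ref, alt) must
occur in at least `min_recurrence = 2` distinct tumor samples and reach
a maximum AI-Driver machine-learning score of `score_threshold = 0.95`.
Recurrence is counted at mutation level, not gene or codon level, so a
hotspot shared across patients is the unit of evidence. Both thresholds
are exposed; lowering either can only grow the driver set
(monotonicity, asserted by tests).

ReVe scores are reported as rank percentiles (`reve_percentile()`):
average rank divided by n, so ties share a value, the transform is
order-preserving and the top score maps to 1. Average rank was chosen
over min- or max-rank because it is the unbiased convention
(`rank(ties = "average")`) and keeps the mean percentile at (n+1)/2n
regardless of ties.

Hypermutated samples — whose high background rate destabilizes
frequency-based gene tests — are removed before analysis when their
total mutation count strictly exceeds `max_per_sample = 1000`. No
standard rule exists for this cut; 1000 mutations per exome (roughly
>30 mutations/Mb) is a common operational definition of a
hypermutator, and the threshold is configurable.

## Gene level: combined significance and the weighted consensus

Per-gene significance enters as two p-value streams from
recurrence-based driver tests (MutSigCV-like and MutPanning-like tools;
their internals are out of scope and their outputs are inputs here).
The streams are combined with Fisher's method:
$X = -2(\ln p_1 + \ln p_2)$ referred to $\chi^2_4$, which for two
p-values has the closed form $e^{-X/2}(1 + X/2)$. p-values are floored
at $10^{-300}$ before the logarithm so underflowed zeros cannot produce
infinities. A gene covered by only one method keeps that p-value as its
combined p (the missing stream is treated as 1) and is flagged
`single_method`. Combined p-values are corrected with Benjamini–
Hochberg within the cohort, and genes at q ≤ 0.05 (inclusive) form the
**AI-DriverGene** set.

Prior knowledge enters through a catalog of driver-gene sets
partitioned into Group1 (gold standard: CGC, OncoKB, the computed
AI-DriverGene set, and MutPanning) and Group2 (supplementary sources).
Each gene receives a weighted Borda consensus score — the sum of 10 per
Group1 set and 1 per Group2 set containing it — and a five-tier level:

| Level | score | interpretation |
|---|---|---|
| 0 | 0 | non-pathogenic |
| 1 | 1 | possible pathogenic |
| 2 | 1 < s ≤ 10 | likely pathogenic |
| 3 | 10 < s < 20 | probable pathogenic |
| 4 | s ≥ 20 | pathogenic |

With weights {10, 1} the score is an integer, so the tier boundaries
are exact. A score of 20 requires either two Group1 memberships or one
Group1 plus ten Group2 memberships — pure Group2 support (max 12 with a
16-set catalog) can never make a driver. **Final driver genes** are the
Level-4 genes that also harbor at least one driver or extreme mutation;
catalog membership alone, without mutational evidence in the cohort at
hand, is not sufficient.

The AI-DriverGene set is computed first and injected into the catalog
before scoring, so the pipeline's own statistical evidence competes on
equal footing with the literature catalogs.

## The Gaussian driverness score

To compare entities on a common 0–1 scale, each FDR-bearing entity
class (all tested genes of a cohort, or all tested pathways) is scored
by a Gaussian model on $x = -\log_2(\mathrm{FDR})$: with class mean
$\mu$ and standard deviation $\sigma$, the score is
$\Phi\!\left((x - \mu)/\sigma\right)$. The score is a strictly
increasing function of significance, equals 0.5 at the class mean, and
ranks identically to the FDR — its value is interpretability, not new
information. Design choices: the population standard deviation (divide
by n) is used for determinism on small sets, with the sample convention
available via `sd_type = "sample"`; classes are never mixed (genes and
pathways are scored against their own populations, per cohort); FDR = 1
is a valid minimum ($x = 0$), while FDR = 0 is floored to $10^{-300}$
with a warning. When all FDRs coincide, $\sigma = 0$ and every score is
reported as 0.5 with a warning. Mutation-level FDRs are not produced by
any in-scope stage (the driver-mutation call is a threshold rule, not a
test), so `run_pipeline()` scores the gene and pathway classes;
`driverness_score()` itself accepts any FDR-bearing entity set.

## Pathway level: hypergeometric enrichment

Final driver genes are tested for over-representation in each set of a
flat GO/KEGG-style collection with the upper-tail hypergeometric test
against a background universe, defaulting to all genes present in the
(filtered) MAF — an operational stand-in for "genes sequenced at
sufficient depth". Sets are intersected with the background first; sets
with fewer than 3 or more than 5000 background members are excluded
(conventional enrichment hygiene, configurable). BH correction is
applied jointly across all tested sets of the supplied collection;
significance is q ≤ 0.05. GO graph structure is not modeled — sets are
flat, with no parent propagation.

## Mutual exclusivity and co-occurrence

Among the top 50 ranked driver genes (consensus score, then q-value),
every unordered pair is tested on the 2×2 table of per-sample nonsilent
mutation status with the two-sided Fisher exact test, using the
conventional point-probability rule (sum of hypergeometric
probabilities no larger than the observed table's). Direction comes
from the unconditioned sample odds ratio $(n_{11}n_{00})/(n_{10}n_{01})$
with 0 and ∞ permitted: co-occurrence above 1, mutual exclusivity
otherwise; a gene mutated in no sample yields p = 1 and direction "ns".
Pairs are labeled at raw p < 0.05 and p < 0.01 — the field's
convention for this display — and a BH-corrected column is emitted
alongside for users who want FDR control over the C(50, 2) tests.

## The binomial stand-in for gene significance

So synthetic cohorts can run end to end without external tools,
`frequency_pvalue_standin()` supplies a deliberately simple per-gene
test: the observed nonsilent count against the upper tail of
Binomial(length × n_samples, rate), with rate the cohort-wide per-bp
nonsilent rate. It conditions on nothing a real background-mutation
model conditions on (expression, replication timing, nucleotide
context) and must not be read as a MutSigCV or MutPanning replacement.

The classic upper tail is exactly 1 at zero counts but, like any
discrete tail at low expected counts, is conservative: its null
distribution is super-uniform. The `midp = TRUE` option subtracts half
the point probability (the standard mid-p correction), which restores
approximate null uniformity. The package's null-calibration check runs
the mid-p variant on a cohort large enough for the binomial to be
smooth (2000 samples × 400 genes, no planted drivers) and verifies
Kolmogorov–Smirnov uniformity; the default remains the classic tail.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the mutation
rules assume: a passenger background plus recurrent high-score missense
hotspots concentrated in designated driver genes. Defaults are the
package's standard study conditions:

* 200 samples, 500 genes with lengths uniform on 500–5000 bp, laid out
  as disjoint blocks on one synthetic contig (no reference genome);
* background rate 2 × 10⁻⁶ per bp per sample (≈2 mutations/Mb, typical
  of non-hypermutated TCGA cohorts), 30% silent by a per-mutation
  Bernoulli draw, the nonsilent remainder split ~80% missense with
  small LoF classes;
* 20 planted driver genes, each with one hotspot shared by 6 samples
  (a 3% hotspot frequency) plus extra driver missense at rate 0.01 per
  sample per gene;
* AI-Driver scores Beta(30, 1) for driver mutations vs Beta(1.2, 8)
  for passengers; ReVe Beta(8, 2) vs Beta(1.5, 3.5).

`simulate_driver_catalog()` gives each synthetic catalog every planted
driver with probability `coverage` (0.9 in the standard recovery
scenario) plus random decoys — 5 per Group1 set, 20 per Group2 set,
mirroring the higher curation stringency of gold-standard catalogs.
`simulate_gene_sets()` writes a GMT with one "TRUE_PATHWAY" holding the
planted drivers among random background sets.

What the generator does **not** emulate: trinucleotide mutational
signatures, codon-accurate silent/nonsilent assignment, copy-number or
rearrangement events, correlated gene lengths and expression, and
patient-level structure (each barcode is an independent patient).
Passing recovery tests on this generator therefore demonstrates that
the pipeline's logic is correct under its stated assumptions, not that
it matches real-cohort operating characteristics.

## Numerical choices and degenerate inputs

* p-value floor $10^{-300}$ before any logarithm; Fisher's method
  rejects p ≤ 0 outright so callers must floor first.
* Gene symbols are matched case-insensitively across all inputs (MAFs
  and curated lists mix cases in the wild) with display case preserved
  from first sight.
* Only `Tumor_Seq_Allele2` is the alternate allele; coordinates are
  1-based inclusive, MAF convention, with no liftover.
* Ti/Tv classification collapses purine-reference changes onto the
  pyrimidine strand, yielding the six standard conversion classes.
* Fisher-exact p-values are clamped at 1 (tail summation can overshoot
  by a few ulps).
* Enrichment output is sorted by (q, p, set_id) so ties break
  deterministically; reruns of the pipeline on identical inputs are
  byte-identical.

## Problem sizes used by the test suite

The suite validates the primitives against independent oracles (literal
step-up BH on 1000 random vectors; exhaustive hypergeometric and
Fisher-exact enumeration for universes/cohorts ≤ 30) and runs the full
pipeline on the standard 200 × 500 scenario over 5 seeds for recovery
(sensitivity ≥ 0.9, precision ≥ 0.8, planted pathway the top
enrichment hit), plus a 2000 × 400 null cohort for calibration. These
sizes keep a full run around half a minute while leaving each check
well-powered.

## Known limitations

* The stand-in significance test is not a background-mutation-rate
  model; real analyses should supply MutSigCV/MutPanning-style tables.
* Catalog quality drives the consensus: a gene absent from Group1
  catalogs can only become a driver through the computed AI-DriverGene
  set plus ten Group2 memberships.
* Pair-interaction labels are raw-p by convention; with many drivers
  the emitted q-values are the better guide.
* Splice-site detection trusts the MAF `Variant_Classification` term;
  distance-to-junction is not inspected.
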