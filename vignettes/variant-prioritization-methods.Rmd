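---
title: "Methods: prioritizing a causal regulatory SNP at a GWAS locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prioritizing a causal regulatory SNP at a GWAS locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snp2enhancer)
```

## The problem

A genome-wide association signal in a non-coding region names a *locus*,
not a variant: the lead (index) SNP tags a block of correlated variants,
any of which could be the functional one. `snp2enhancer` implements the
standard post-GWAS triage for a candidate *enhancer* variant — here
modeled on an X-linked locus upstream of a target gene expressed in
uterine tissue — as a reproducible cascade:

1. **LD expansion** — find all proxies of the index SNP with haplotype
   r² above a threshold (default strict `> 0.8`);
2. **eQTL annotation** — which proxies associate with the target gene's
   expression in the relevant tissue, and in which allelic direction;
3. **epigenomic overlap** — which proxies sit in regulatory chromatin
   (histone marks, open chromatin) and in TF ChIP-seq peaks;
4. **allele-dependent motif scoring** — for which proxies does the risk
   allele measurably weaken a binding motif of a TF that is actually
   bound there;
5. corroboration by **chromatin contact** (observed/expected Hi-C from
   the candidate bin to the promoter), **single-cell expression
   enrichment** of the target gene, and **dual-luciferase reporter
   statistics** for the allelic constructs.

Every step is driven by files in ordinary formats (VCF, BED + manifest,
Cis-BP/MEME motifs, GTEx-style eQTL TSV, binned contact TSV, MTX counts,
plate TSV), so the same code runs on real downloads or on this package's
synthetic studies.

## Linkage disequilibrium

With alt-allele frequencies $p_A$, $p_B$ and joint alt–alt haplotype
frequency $p_{AB}$,

$$D = p_{AB} - p_A p_B,\qquad
r^2 = \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)},\qquad
D' = \frac{|D|}{D_{\max}},$$

where $D_{\max}$ is the classical bound given the margins. The estimator
requires *phase*: unphased diploid genotypes are rejected rather than
EM-phased, which keeps $r^2$ exact and identical to the squared Pearson
correlation of the 0/1 haplotype columns (a property the tests assert to
1e-12). On chromosome X, males contribute one haplotype row and females
two, pooled as PLINK does. Monomorphic columns have no defined LD and
raise an error naming the column.

The proxy threshold is applied strictly (`r2 > threshold`); at a
threshold of 1.0 the set is therefore empty — even the index SNP's
self-r² of 1 does not pass. This edge is deliberate and documented: the
selection criterion is an inequality, not an inclusion rule for the
index, which is reported (flagged `is_index`) whenever it passes.

## Allele-dependent binding

A motif is a position frequency matrix (PFM). Frequencies are smoothed
with a total pseudocount $c$ (default 0.1, a Cis-BP-conventional value)
as $f' = (f + c/4)/(1 + c)$ and scored two ways:

* **log-odds**: $w(i,b) = \log_2 f'(i,b)/q_b$ against the background
  $q$ (default uniform), in bits;
* **relative binding free energy**: $e(i,b) = -(\ln f'(i,b) -
  \overline{\ln f'(i,\cdot)})$, mean-centered per position, in RT units
  (dimensionless multiples of gas constant × temperature). Preferred
  bases have negative (favorable) energies and plot above the axis in an
  energy logo; `energy_logo_table()` emits the per-position heights.

With uniform background the two parameterizations are affinely related
at any fixed placement, so they agree in rank — asserted numerically in
the tests rather than assumed.

`score_alleles()` substitutes each allele at the SNP, evaluates the
log-odds sum at every placement of the motif window that covers the SNP
(L placements) on both strands, and keeps the maximum; `delta` is
`score_alt - score_ref`. Ties are broken deterministically (smaller
offset, then + strand). Best-placement scoring, rather than a
sum-over-placements occupancy, matches the single-site logic of an
energy-logo figure; occupancy models are out of scope.

Two design points deserve emphasis:

* The **ChIP gate**: a predicted differential pair (|delta| ≥ 2 bits by
  default) is only *flagged* if the candidate overlaps a TF ChIP-seq
  peak whose factor matches the motif name. Prediction without observed
  binding is treated as noise. The 2-bit default is exposed and recorded
  in the output; no published cutoff exists for this step.
* Because the scan maximizes over placements and strands, a motif with
  uninformative flanking columns can let the disfavored allele recover
  its score at a shifted placement. The direction guarantee "risk allele
  scores lower" holds for motifs that match the site — which is exactly
  the situation the gate selects for.

## The tier cascade and ranking

Evidence layers combine as a monotone cascade: tier 1 = in the LD set;
tier 2 = tier 1 **and** significant eQTL for the target gene/tissue;
tier 3 = tier 2 **and** at least one regulatory peak **and** one TF
ChIP-seq peak; tier 4 = tier 3 **and** at least one gated motif flag.
Removing any layer can only lower a tier (tested as a property).
Candidates are then ordered by the fully keyed sort
(tier desc, max |delta| desc, n_tf desc, r² desc, position asc), which
makes the "cross-referencing" of evidence layers explicit, auditable and
permutation-invariant. A composite score, tier + 0.5·tanh(|delta|/4), is
reported for readability only; the sort key is authoritative.

eQTL slopes are harmonized to the alternate allele
(`slope_alt = slope` if the record's effect allele is alt, else
`-slope`), an involution under effect-allele flips. Significance is
taken from the table as supplied (these tables are usually pre-filtered
by the source); a `pvalue_max` filter is exposed for synthetic use.

## Chromatin contact (observed/expected)

The expected count at bin separation $d$ is the mean over all bin pairs
of the table's range at that separation, with separations holding fewer
than `min_pairs` (default 10) pair slots pooled with their neighbors so
the far tail is not estimated from a handful of pairs. The bait profile
is `observed(bait, j) / expected(|bait - j|)`; bins at or above the
threshold (default 2.00, the conventional looping cutoff) are reported,
and genes whose promoter (TSS ± 2 kb) falls in a reported bin are
listed. O/E is scale-invariant (multiplying every count by k changes
nothing — tested to 1e-12) and never alters observed counts. The
expected model is estimated from the supplied table itself; no claim of
bit-exact equivalence with any particular browser's normalization is
made, since those estimators (spline vs binned mean) are not published
in detail.

## Single-cell enrichment

For one gene, a cell is "expressing" iff its raw count ≥ 1 (presence,
not level; normalization is out of scope, and clustering is an input,
not computed). Per cluster: frequency = expressing/size, fold =
frequency / overall frequency, and an upper-tail hypergeometric p-value
(population = all cells, successes = expressing cells, draws = cluster).
The hypergeometric is the simplest exchangeable null consistent with a
reported (frequency, fold, p) triple; the tests verify it against
exhaustive enumeration for all configurations with N ≤ 12. No claim is
made that any published figure used this exact test.

## Reporter statistics

Per well, nano/firefly controls transfection efficiency and cell
number; dividing by the mean backbone ratio of the same condition
controls vector baseline, so backbone wells normalize to mean 1.
"Student's t-test" is read literally: pooled variance, two-sided
(Welch available behind a flag). Replicates across independent
experiments are modeled as a flat well table — a documented limitation;
no mixed-effects structure is fitted.

## What the synthetic studies emulate

The generators are pure functions of one seeded `sim_config()` (same
seed, byte-identical outputs) and plant a known truth record, so every
downstream stage can be scored:

* **Haplotypes**: mosaics of `founder_count` (8) founder haplotypes with
  per-site founder switching (0.1) and allele flips (0.01) — a
  three-parameter stand-in for a reference panel with tunable LD, not a
  coalescent simulation. The causal column is rebuilt from the index
  column with the flip probability solved (by `uniroot` on the closed
  form) so expected r² equals `target_r2` (0.9); the realized r² is
  stochastic and recorded. Defaults: 2000 haplotypes (1000 diploid
  females), 60 SNPs 2 kb apart on chrX.
* **Annotations**: the causal SNP lies in one histone and two TF
  ChIP-seq peaks (500 bp wide); 10% of decoy SNPs get decoy histone
  peaks, so ≥ 80% of decoys are peak-free. Every SNP's alt-oriented eQTL
  slope is −0.5 · r²(SNP, causal) with p decreasing in r² — the risk
  (alt) allele lowers expression, hardest at the causal SNP. The planted
  motif's highest-information column (ref base 0.85) sits on the causal
  SNP with flanking columns matching the genomic sequence (0.7), so the
  risk allele loses ≈ 3.5 bits at the best placement.
* **Contacts**: counts follow `scale · exp(-d/tau)` (tau = 5 bins of
  40 kb) with multiplicative lognormal noise (sdlog 0.1); the bait ×
  promoter entry is multiplied by `loop_strength` (3). The promoter sits
  360 kb from the region start — several bins from the bait, like a
  distal enhancer–promoter pair.
* **Counts**: 23,110 cells in 8 clusters; the planted stromal cluster
  (15% of cells) detects the target gene at 5.2% and the rest at 0.94%,
  so the expected all-cell frequency is 1.58% and the expected
  enrichment fold is 0.052/0.0158 = 3.3. The out-of-cluster rate is
  derived from the (frequency, fold) pair rather than set equal to the
  all-cell rate, which would make the target fold unreachable for any
  non-vanishing cluster. Nonzero counts are 1 + NB(mu = 1, dispersion
  0.5); only presence matters downstream.
* **Reporter**: firefly ~ lognormal; nano = firefly × construct mean ×
  lognormal noise (CV 0.15); the risk construct's mean is
  `reporter_effect` (0.5) times the non-risk mean; 3 experiments × 3
  replicates, two conditions.

What passing on these studies does **not** show: robustness to
genotyping error or missing data (panels are complete by design), to
eQTL tables with allele-frequency–correlated errors, to unbalanced or
ICE-normalized contact matrices, to ambient-RNA or doublet artifacts in
the counts, or to plate-position effects in the reporter. The
generators plant one causal variant; multi-causal loci are untested.

## Numerical choices and degenerate inputs

* LD: r² and D′ are clamped at 1 (floating division can exceed the
  bound by ~1e-16); D′ at D = 0 is defined as 0; monomorphic columns
  error.
* Motifs: PFM rows renormalized to sum 1, but a pre-normalization row
  sum outside [0.9, 1.1] is rejected as likely raw counts rather than
  silently rescaled. Pseudocount smoothing guarantees finite scores.
  Placements containing N are skipped; if all are skipped, the scan
  errors.
* O/E: an empty contact table errors; a bait bin with zero marginal
  contacts warns and returns an empty profile.
* Enrichment: empty clusters error; a gene absent from the matrix
  errors listing near-matches.
* Reporter: non-positive readings, missing backbone wells, or zero
  pooled variance error.
* Problem sizes in the test suite and acceptance script (100 pipeline
  replicates, 50 contact/count replicates, 1000 null reporter
  replicates) were chosen to put Monte-Carlo error well inside the
  asserted bands while keeping a full run around two minutes on one
  core.

## Known limitations

Genome-build consistency between inputs is the caller's responsibility
(no liftover). eQTLs are annotated, not colocalized — no coloc/SMR, no
fine-mapped posterior probabilities. TF ChIP evidence is counted by
dataset presence, not signal height or replicate weighting. The LD
window default (1 Mb) is configurable; published proxy lists rarely
state one. None of the single-cell upstream processing (QC,
normalization, embedding, clustering) is reimplemented — labels are an
input by design.
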