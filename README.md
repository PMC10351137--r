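# snp2enhancer

Post-GWAS prioritization of a causal regulatory variant at an enhancer
locus, as a tested R package plus a numbered analysis workflow.

A GWAS association in non-coding sequence tags a linkage-disequilibrium
(LD) block, not a variant. This package implements the standard triage
that narrows such a block to a single candidate enhancer SNP and a set
of transcription factors whose binding it disrupts:

1. **LD expansion** — all proxies of the index SNP with haplotype
   r² > 0.8 (strict), where
   r² = D²/(p_A(1−p_A) p_B(1−p_B)) and D = p_AB − p_A·p_B from phased
   haplotypes (chrX-aware: male hemizygotes contribute one haplotype);
2. **eQTL annotation** — slopes harmonized to the alternate allele for a
   target gene and tissue, with direction labels;
3. **epigenomic overlap** — TF ChIP-seq and regulatory-region (histone /
   open-chromatin) peak hits, half-open BED semantics throughout;
4. **allele-dependent motif scoring** — both alleles scanned over every
   motif placement covering the SNP, both strands, in log-odds (bits)
   and relative binding free-energy (ΔΔG, RT units) parameterizations,
   gated on ChIP evidence for the matching factor;
5. a monotone **tier cascade** (LD → eQTL → peaks → motif) with a fully
   keyed deterministic ranking;
6. corroboration modules: distance-normalized **Hi-C O/E** bait
   profiles with promoter lookup, **single-cell expression enrichment**
   (frequency, fold, upper-tail hypergeometric p), and
   **dual-luciferase reporter statistics** (backbone normalization,
   pooled-variance Student's t).

Seeded synthetic-data generators plant a known causal SNP through every
layer (LD block, peaks, eQTL table, motif, chromatin loop, enriched
cell cluster, allelic reporter effect), so the full cascade is testable
end to end without external downloads. All I/O uses ordinary text
formats: VCF, BED + TSV manifest, Cis-BP PWM / minimal MEME, GTEx-style
eQTL TSV, binned contact TSV, MatrixMarket counts, plate TSV.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Run
the scripts in order from the repository root:

```sh
Rscript analysis/01_simulate.R      # write the synthetic study
Rscript analysis/02_ld_expansion.R  # LD proxies of the index SNP
Rscript analysis/03_annotate.R      # eQTL + peak annotation
Rscript analysis/04_motif_scan.R    # allele-dependent binding
Rscript analysis/05_prioritize.R    # tier cascade + ranking
Rscript analysis/06_chromatin.R     # O/E bait profile
Rscript analysis/07_single_cell.R   # cluster enrichment
Rscript analysis/08_reporter.R      # reporter statistics
```

Output of the run at seed 1 (tables land under `results/`):

```
wrote synthetic study to results/study
  haplotypes: 2000  SNPs: 60
  planted causal SNP: rs000032  index SNP: rs000030
  realized index-causal r2: 0.902 (target 0.90)
LD expansion around rs000030: 2 candidate SNP(s) at r2 > 0.8
2 of 2 candidates are uterus eQTLs for AGTR2
1 (candidate, motif) pair(s) flagged as differential
  rs000032 x CEBPB (delta -3.54 bits)
top-ranked candidate: rs000032 (tier 4, |delta| 3.54 bits, r2 0.902)
planted causal SNP: rs000032  -- recovered
bait bin 2876: 1 bin(s) at O/E >= 2.00
  promoter contact: AGTR2 in bin 2883 (O/E 3.12)
AGTR2 most enriched in Stromal-2: frequency 5.8%, fold 3.4, p = 5.5e-64
normalized activity: T 5.71, C 2.62 (ratio C/T 0.46)
pooled t = 10.631 (df 16), two-sided p = 1.16e-08
```

Reading: of the 60 simulated SNPs, two exceed r² 0.8 with the index;
only the planted causal SNP carries the full evidence stack — strongest
negative alt-allele eQTL slope, histone + TF ChIP peaks, and a 3.5-bit
loss of the CEBPB motif score for the risk allele inside a CEBPB peak —
so it alone reaches tier 4 and ranks first. Its bin contacts the target
promoter at 3× the distance-expected frequency, the target gene is
enriched ~3.3-fold in the planted stromal cluster, and the risk-allele
reporter construct shows about half the non-risk activity.

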