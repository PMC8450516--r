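# snpfunnel

Most GWAS hits for complex diseases such as non-small cell lung cancer
(NSCLC) are non-coding, so the sentinel ("tag") SNP is rarely the causal
variant. A standard post-GWAS strategy is to *funnel* each associated locus
through functional-genomics evidence: take the tag SNPs in two significance
tiers (genome-wide, p < 5×10⁻⁸, and subthreshold, 5×10⁻⁸ ≤ p < 10⁻⁵), expand
each into the variants in linkage disequilibrium with it (r² > 0.2 against a
reference panel), keep those falling inside open-chromatin regions mapped by
ATAC-seq, and finally those also under the active-enhancer histone mark
H3K27ac from ChIP-seq. The surviving candidates are then genotyped in a
two-stage case–control study: a lenient discovery screen (p < 0.1, additive
model, adjusted for age, sex and smoking), independent validation of the
promoted SNPs under five genetic models, and a pooled combined analysis.

`snpfunnel` implements this whole pipeline as reusable, tested R components:

* **core I/O** — BED3+/narrowPeak peaks, a genotype TSV dialect, VCF intake
  (GT field), tag-SNP catalogs, phenotype tables;
* **intervals** — indexed variant-in-peak queries (1-based SNP positions
  against 0-based half-open BED intervals: position *p* is in `(s, e]` iff
  `s < p ≤ e`);
* **ld** — two-locus haplotype frequencies by the classic EM algorithm for
  unphased genotypes, D, D′ and r², LD expansion around tags, proxy search;
* **casecontrol** — Hardy–Weinberg goodness-of-fit χ² on controls,
  call-rate/HWE QC, Pearson χ², crude odds ratios (OR = ad/bc with 95% Wald
  CI, Haldane–Anscombe corrected when a cell is zero), covariate-adjusted
  ORs from an in-house IRLS logistic regression, under the homozygous,
  heterozygous, dominant, recessive and additive models;
* **two-stage and stratified analyses** — screen/validate/combine, and
  subgroup estimates by histology, smoking and sex;
* **synthdata** — generators for haplotype blocks with controlled r²/D′,
  retrospectively sampled case–control cohorts with planted ORs, and peak
  sets with planted variant overlaps, all byte-deterministic under a seed;
* **cli** — `simulate` / `prioritize` / `assoc` / `report` subcommands
  driven by a DCF key-value config (see `inst/scripts/snpfunnel`).

## Worked example

Re-analyze a published genotype-count table (combined population, counts
cases 632/839/303 and controls 770/931/261 for GG/GA/AA) without
individual-level data, then run the funnel end-to-end on synthetic data
with known ground truth:

```r
library(snpfunnel)

counts <- genotype_counts(case = c(632, 839, 303),
                          control = c(770, 931, 261))
for (m in c("dominant", "recessive", "additive"))
  print(crude_or(m, counts))
#> <crude dominant OR 1.17 (1.02-1.33) p=0.0225>
#> <crude recessive OR 1.34 (1.12-1.61) p=0.00128>
#> <crude additive OR 1.17 (1.06-1.28) p=0.00105>

hwe_test(c(583, 707, 197))     # control genotypes, stage 2
#> <test: stat=0.5720 df=1 p=0.4495>

world  <- simulate_funnel_world(seed = 1)
report <- run_funnel(world$catalog, world$panel,
                     world$atac, world$h3k27ac)
report
#> Variant prioritization funnel
#> =============================
#> tag SNPs:            28 (21 genome-wide, 7 subthreshold)
#> tags absent from panel: 0
#> after LD expansion (r2 > 0.2, +/-500000 bp): 84 variants
#> within open chromatin:  40
#> also under H3K27ac:     20 candidates

identical(sort(report$candidates$rsid), world$planted_candidates)
#> [1] TRUE
```

The crude odds ratios here reproduce, at the printed two-decimal
precision, the published covariate-adjusted estimates for the recessive
(1.34, CI 1.12–1.61), dominant (1.17) and additive (1.17) models — the
adjustment happens to be nearly neutral in that cohort. The HWE p-value
of 0.45 is the control-genotype QC check (exclusion threshold p < 0.05).
The funnel counts are fixture properties (28 tags expand to 84 retained
LD variants, 40 in open chromatin, 20 under H3K27ac); the last line
confirms the candidates are exactly the planted ground truth.

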