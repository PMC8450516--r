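---
title: "Methods: the prioritization funnel and its statistics"
author: "snpfunnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the prioritization funnel and its statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpfunnel)
```

## The problem

Genome-wide association studies report sentinel ("tag") SNPs, but in
non-coding loci the causal variant is usually a linked neighbour that
perturbs a regulatory element. `snpfunnel` implements the standard
integrative prioritization for this situation — tag SNPs, tiered by
significance, are expanded through linkage disequilibrium (LD) and
intersected successively with open-chromatin (ATAC-seq) and
active-enhancer (H3K27ac ChIP-seq) peak intervals — together with the
two-stage case–control machinery used to test the surviving candidates.
This vignette records the models, the tunable parameters with their
defaults, and the design decisions taken where the procedure is
underdetermined.

## Coordinates and funnel conventions

SNP positions are 1-based (dbSNP convention); peak intervals are 0-based
half-open (BED convention). The single conversion point is
`build_index()`: a SNP at position $p$ overlaps a BED interval $(s, e]$
iff $s < p \le e$. Chromosome labels are compared after stripping an
optional `chr` prefix, because public ATAC/ChIP resources mix the two
styles. Peak indexing restricts to autosomes by default
(`autosomes_only = TRUE`), mirroring how accessibility segment counts
are conventionally reported; the toggle exists for completeness.

Funnel stage order is: significance tiering (genome-wide $p < 5\times
10^{-8}$; subthreshold $5\times 10^{-8} \le p < 10^{-5}$; catalog rows at
or above $10^{-5}$ are dropped with a logged count), LD expansion, ATAC
intersection, then H3K27ac intersection. Decisions taken where the
procedure is commonly left unstated:

* the boundary $p = 5\times 10^{-8}$ falls in the subthreshold tier
  (tiers partition the p-axis; the strict genome-wide convention is
  `<`);
* the two peak sets are applied *in succession* — a candidate must lie
  in some ATAC peak and in some H3K27ac peak, not necessarily in a
  single interval carrying both marks;
* strict containment is required (no flanking slack around peaks);
* a variant in LD with several tags is counted once, annotated with all
  tags and its maximal r²; tags pass through the funnel as their own
  proxies with r² = 1;
* output ordering is deterministic (chromosome, position, rsid), so
  reports are invariant to catalog row order.

## Two-locus LD by EM

Unphased genotypes leave only the double heterozygote phase-ambiguous.
With alternate-allele dosages at two loci, every other genotype class
determines its two haplotypes; the EM algorithm
(`em_haplotype_freqs()`) splits the double-heterozygote class between
the $AB/ab$ and $Ab/aB$ resolutions in proportion to
$f_{AB}f_{ab}$ vs $f_{Ab}f_{aB}$ (E-step) and re-tallies haplotype
frequencies (M-step). Numerical choices: initialization at linkage
equilibrium (products of the observed allele frequencies), convergence
when the largest frequency change is below $10^{-10}$, at most 1,000
iterations, and a degenerate E-step weight of 0.5 when
$f_{AB}f_{ab} + f_{Ab}f_{aB} = 0$. The multinomial log-likelihood is
recorded per iteration; the suite asserts it never decreases, that the
estimates match a grid-search likelihood oracle, and that closed-form
counting is recovered exactly when no double heterozygotes exist.

From the fitted frequencies, $D = f_{AB} - p_A p_B$;
$D' = D / D_{\max}$ with
$D_{\max} = \min(p_A(1-p_B), (1-p_A)p_B)$ for $D>0$ and
$\min(p_A p_B, (1-p_A)(1-p_B))$ for $D<0$ ($D'=0$ when $D=0$); and
$r^2 = D^2 / (p_A(1-p_A)\,p_B(1-p_B))$. Monomorphic loci and boundary
allele frequencies raise classed errors rather than returning NaN. LD
statistics are computed on alt-allele dosage as coded; r² is
orientation-invariant and thresholding uses |D′| and r² only, so allele
relabelling cannot change funnel membership.

`ld_expand()` searches ±500,000 bp around the tag (a conventional
maximum pairwise-comparison distance; the window is a parameter) and
retains variants with r² strictly greater than `r2_min = 0.2`, matching
the usual "r² > 0.2" screen wording. `find_proxy()` returns the
highest-r² substitute at or above its own threshold, breaking ties by
physical distance and then rsid — the use case is a tag that fails assay
design and is replaced by a perfect proxy (r² = 1).

## Case–control statistics

**QC.** Controls are tested for Hardy–Weinberg equilibrium with the
1-df goodness-of-fit χ² at the observed allele frequency; a SNP is
excluded when the control HWE p-value is below `hwe_alpha = 0.05` or
when its call rate (typed / (typed + missing), both arms) is below
`call_rate_min = 0.90`. Missing genotypes are a distinct `NA` sentinel,
never conflated with dosage 0, precisely because call-rate QC counts
them. Both failure reasons are recorded when both apply.

**Genetic models.** Five codings of the genotype: homozygous (HV vs HW,
heterozygotes excluded), heterozygous (HT vs HW), dominant (HT+HV vs
HW), recessive (HV vs HW+HT), additive (dosage 0/1/2). The risk allele
is fixed to the variant (alt) allele even when its frequency exceeds
0.5, matching the convention of reporting ORs "under the assumption that
variant alleles are risk alleles".

**Crude estimates.** Each model collapses the counts to 2×2 (the
additive model by allele counting: $2\,\mathrm{HV} + \mathrm{HT}$ vs
$2\,\mathrm{HW} + \mathrm{HT}$); OR = ad/bc with a 95% Wald CI
($z = 1.959964$) and a p-value from the uncorrected 2×2 Pearson χ².
When any cell is zero the Haldane–Anscombe correction (+0.5 everywhere)
is applied to the OR and CI and flagged in the output.

**Adjusted estimates.** An in-house IRLS logistic regression
(`fit_logistic()`): deviance-change tolerance $10^{-8}$, at most 25
iterations, convergence additionally requires the score vector below
$10^{-6}$ in absolute value; separation (diverging coefficients with
fitted probabilities pinned at 0/1) is flagged, never silently
reported. Covariates enter untransformed: age in years, sex coded
female = 0 / male = 1, smoking nonsmoker = 0 / smoker = 1. Samples with
unknown smoking status are excluded from adjusted models (and from
smoking strata) but retained in crude counts and in the 3-category
demographic χ² — published cohort tables include an "Unknown" row while
regression handling is typically unstated, and complete-case exclusion
is the least-assuming choice. Constant covariate columns are dropped
(they carry no information and would make the design singular), which
also makes the "adjusted equals crude under constant covariates"
property hold exactly.

**Demographics.** Pearson's χ² (no continuity correction) compares
distributions; the genotype-distribution test in scans uses the full
3×2 table (2 df) — "distribution of genotypes" rather than a 1-df
allelic test, which is the more literal reading. Age comparisons from
published mean ± SD summaries use the pooled-variance two-sample t-test
(the test type behind such tables is rarely stated; pooled-variance is
the SPSS default line).

**Two-stage design.** Stage-1 SNPs with adjusted additive p below
`screen_alpha = 0.1` are promoted; promoted SNPs are re-tested in stage
2 under all five models; the combined analysis pools individual-level
data (not a meta-analysis), and pooled genotype counts are checked to
equal the element-wise stage sums. No multiple-testing adjustment is
applied, mirroring the two-tailed p < 0.05 convention of the design
being reproduced; reports state the number of tests instead.

**Stratified analyses.** Histology strata pair the cases of one tumour
subtype with *all* controls (subtypes are case-only attributes); smoking
strata drop unknowns; the stratifying factor is removed from the
adjustment set. Strata lacking cases or controls are skipped with a log
entry.

## The synthetic world

The generators produce every input the pipeline consumes, with ground
truth, and are byte-deterministic under a seed.

* **Haplotype blocks** (`block_spec()` / `simulate_haplotypes()`): an
  anchor variant plus companions at target pairwise r² or D′. Targets
  are converted to the raw $D$ and checked against the
  $D_{\max}$ feasibility bound (an infeasible request errors, naming the
  bound). Haplotypes are drawn independently per individual: anchor
  allele Bernoulli, companions conditional on the anchor, independent
  of each other given the anchor. `solve_pair_freq()` finds the
  companion frequency at which a stated (r², D′) pair — such as
  (0.6, 0.92) at anchor frequency 0.37 — is simultaneously satisfiable.
* **Cohorts** (`cohort_spec()` / `simulate_cohort()`): genotypes drawn
  under HWE at the stated control MAF (default 0.37) in a virtual
  population (default 4× the requested cohort), disease assigned by a
  logistic model with the planted per-SNP ORs (default additive 1.17)
  and covariate effects, the intercept tuned by bisection to a ~50%
  population case fraction, then `n_case` cases and `n_control`
  controls sampled retrospectively. Under outcome-dependent sampling
  the odds ratio is invariant, so the planted OR is exactly the
  estimand of the logistic analysis — this is why retrospective
  sampling was chosen over prospective cohort thinning. Defaults mirror
  the reproduced study's demographics: age normal(55, 8.5) truncated to
  [30, 80], 64% male, population smoking prevalence 0.40 with smoking
  OR 1.45 (these two jointly *induce* case/control smoker fractions of
  roughly 44%/36%; the published 48%/39% cannot be forced directly
  without over-determining the logistic model, so the emergent values
  are accepted), 0.8% unknown smoking, case histology shares
  65/27/8% adenocarcinoma/squamous/other.
* **Peaks** (`simulate_peaks()`): `floor(fraction × n)` variants are
  designated in-ATAC, a nested fraction of those also in-H3K27ac; each
  peak is placed to contain exactly its designated variant (clipped
  against neighbouring variants) and decoy peaks containing no variant
  are added. `simulate_funnel_world()` assembles a complete fixture —
  default 21 + 7 tags, each anchoring a block with two clearly-high
  (r² ≈ 0.8) and two clearly-low (r² ≈ 0.02) companions at n = 600 —
  whose planted candidate set the funnel must recover exactly.

What the generators deliberately do **not** emulate: genome-wide LD
maps, population structure or relatedness, genotyping batch effects,
imputation uncertainty, peak-calling noise, or correlated covariates.
A green end-to-end test therefore establishes that the pipeline's
logic, thresholds and estimators behave as specified under a clean
stated world — not that the original study's external datasets would
reproduce its exact funnel counts (28 → 4,069 → 232 → 16), which
depend on third-party catalog, panel and peak downloads that are out of
scope. The high/low construction targets sit far from the 0.2 retention
threshold precisely so that sampling noise at n = 600 cannot flip
membership; the spec-level example targets {0.9, 0.5, 0.15, 0} are
exercised separately in the LD unit tests under a fixed seed.

## Degenerate inputs and error taxonomy

All validation failures raise classed conditions
(`snpfunnel_parse_error`, `snpfunnel_validation_error`,
`snpfunnel_monomorphic_error`, `snpfunnel_insufficient_data`,
`snpfunnel_lookup_error`, `snpfunnel_spec_error`,
`snpfunnel_sampling_error`, `snpfunnel_config_error`,
`snpfunnel_io_error`), so pipelines can distinguish a malformed file
(parse error with line number) from an undefined statistic (monomorphic
locus) from a missing input. Per-SNP failures inside `assoc_scan()`
become flagged rows — a scan never aborts on one bad SNP; absent tags
are logged and counted, never fatal to the funnel.

## Known limitations

* Only biallelic SNPs: no indels, no multi-allelic records, and the VCF
  reader uses the GT field alone.
* No exact (Fisher / mid-p) HWE test; rare-variant SNPs are better
  served by exact tests than the χ² used here.
* No haplotype-block detection or multi-locus phasing; LD is strictly
  pairwise to a tag.
* The combined analysis pools individual-level data; there is no
  meta-analytic combination for when raw data cannot be shared.
* One published χ² value (combined smoking distribution, printed 30.96)
  is not exactly reproducible from its own printed counts, which give
  30.95 — the acceptance test asserts the recomputed value and its
  agreement with the print to within one unit in the last digit.
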