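---
title: "ROH, inbreeding and selection-signature scans with rohscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ROH, inbreeding and selection-signature scans with rohscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
```

## The analysis

`rohscan` implements the standard breed-level workflow for medium-density
SNP-array genotypes in livestock: quality control, runs of homozygosity
(ROH), genomic inbreeding, ROH islands, per-locus FST selection scans,
observed heterozygosity, and candidate-gene annotation. It is built around
closed local populations — the motivating setting is sets of related pig
breeds genotyped on a ~60K porcine chip — where inbreeding is substantial,
ROH are long, and within-breed selection leaves breed-private islands of
shared autozygosity.

A run of homozygosity is a contiguous stretch of homozygous genotypes in
one individual; long ROH indicate recent inbreeding (autozygosity). The
genomic inbreeding coefficient `F_ROH` is the summed ROH length divided by
the SNP-covered autosomal genome length, reported overall and in the
length classes 1–2, 2–4, 4–8, 8–16 and >16 Mb (half-open intervals, so no
segment is counted twice). An *ROH island* is a locus where an unusually
large fraction of a breed's individuals are autozygous — a candidate
selection signature. Divergence between breeds is measured per SNP by the
Weir–Cockerham (1984) FST estimator, with genome-wide means taken as the
ratio of summed variance components (the weighted mean).

## ROH calling model

Calling is window-based. The window length `L` (in SNPs) is set so that a
chance run of homozygous calls anywhere in the dataset has probability
about `alpha`:

    L = ceil( ln(alpha / (n_snps * n_samples)) / ln(1 - mean_het) )

with `alpha = 0.05`, `mean_het` the dataset's mean per-SNP heterozygosity,
and a floor of 20 SNPs. A length-`L` window is *homozygous* if it contains
no heterozygote and at most one missing call. A SNP is in-run if at least
5% of the windows covering it are homozygous (the PLINK default hit
ratio). Maximal runs of in-run SNPs are split at inter-SNP gaps above
1,000 kb and kept only if they hold at least `L` SNPs at an average
density of one SNP per 150 kb or better. Segment length is `end - start`
of the first and last SNP. On a ~36K chip-density map these rules give
`L` around 45–52 and a minimum detectable segment of roughly 3 Mb, which
is why the 1–2 Mb class is empty on such data — a property the test suite
asserts rather than assumes.

`F_ROH` uses the SNP-covered genome (per chromosome, last minus first SNP
position) as denominator, so it is comparable across the slightly
different per-breed marker panels that breed-wise QC produces.

## Island calling

Within a breed, the *incidence* of a SNP is the percentage of individuals
whose ROH cover it. Incidences are z-scored against the breed's own
genome-wide distribution and mapped through the standard normal CDF;
island members must have `p > 0.999` (the top 0.1% of a normal incidence
distribution) *and* incidence of at least 30% of the breed. Adjacent
members within 1 Mb merge into one island. Two deliberate choices:

* The normal approximation to a bounded, discrete incidence distribution
  is kept because it is the field's convention; it is a genuine
  limitation. In a cohort where individual ROH burden is high (`F_ROH`
  above ~0.15), random co-occurrence of long ROH already produces loci in
  the top normal tail, so island calls at high burden should be read as
  descriptive top-of-distribution summaries rather than significance
  statements. The 30% incidence floor is what keeps island calls
  meaningful at low burden.
* Very inbred breeds can have such a flat, elevated incidence
  distribution that no SNP reaches `p > 0.999`; the configurable fallback
  (`p >= 0.998` with an absolute 55% incidence threshold) reproduces the
  standard relaxation for that case and is flagged in the output.
* The reported peak SNP is the central member of the maximal-incidence
  plateau. Shared ROH cores produce flat-topped incidence profiles, so
  the plateau centre is the stable representative; the first or last tied
  SNP would wander with single-individual noise at the plateau edges.

## FST scan

Per SNP, the Weir–Cockerham variance components `a` (among populations),
`b` (among individuals within) and `c` (within individuals) are computed
from per-population sample sizes, allele frequencies and observed
heterozygote frequencies; `FST = a/(a+b+c)`. Negative finite-sample
estimates are kept for the weighted genome-wide mean `sum(a)/sum(a+b+c)`
and floored at zero only in the Manhattan export. Outliers are the
`ceiling(0.001 * n)` top SNPs whose empirical normal-tail p (z-scored
against the genome-wide FST distribution) exceeds 0.999 — the top-0.1%
convention, applied per comparison.

## Quality control

Three named profiles mirror how such studies split their QC by analysis
branch:

| profile     | marker call rate | sample call rate | MAF  | HWE   | LD prune |
|-------------|------------------|------------------|------|-------|----------|
| `structure` | 0.90             | 0.90             | 0.05 | 1e-6  | 50/25/0.5 |
| `roh`       | 0.95             | 0.90             | —    | —     | — |
| `fst`       | 0.90             | 0.90             | —    | 1e-6  | — |

The ROH branch runs per breed. The HWE test is the exact (non-mid-p)
conditional test; note that with 20 or fewer diploids even a total
heterozygote deficit cannot reach p < 1e-6 (the most extreme attainable
table, (10,0,10), has p = 1.34e-6), so that filter only bites in larger
panels. Relatedness uses the VanRaden method-1 genomic relationship
matrix with pairwise-complete missing handling; for each pair above the
threshold (0.95 flags genotyping duplicates) the lower-call-rate member
is removed, highest coefficient first. LD pruning follows the
`--indep-pairwise` scheme (50-SNP windows, step 25, r² > 0.5), resolving
the highest-r² pair first and dropping its lower-MAF member (ties: the
later position) — the tie-break is not specified by the original tool and
is fixed here for determinism.

## The synthetic cohort generator

`simulate_cohort()` produces multi-breed cohorts with known truth; its
defaults emulate a three-breed Mangalitsa-scale cohort:

* 23/24/30 individuals in breeds labelled BM/RM/SM; 18 autosomes of
  126 Mb (≈2.27 Gb genome; a real pig genome has unequal chromosomes —
  a simplification that does not affect any per-locus rule); 36,000 SNPs
  on a jittered grid (spacing ±30%), ancestral MAF uniform on
  [0.05, 0.5].
* Balding–Nichols divergence: each breed's allele frequency is Beta
  distributed around the ancestral frequency with parameter `F` per
  breed; defaults `F = (0.033, 0.025, 0.157)` were solved from the
  pairwise divergence targets 0.029/0.091/0.095 under
  `theta_ij = (F_i + F_j)/2`.
* Autozygosity is planted haplotype-free: a tract is overwritten with one
  doubled haplotype sampled from the breed's frequencies. This gives
  exact per-individual truth (`F_ROH` = merged tract fraction) at trivial
  runtime; what it does *not* model is background LD, allele-sharing
  between relatives, or mutation/genotype error inside real IBD tracts —
  so passing recovery tests shows the caller implements its rules
  correctly, not that chip data are this clean. Per-breed `F_ROH` targets
  default to 24.1/16.3/20.8% with tract lengths uniform on 2–24 Mb, which
  also reproduces a realistic per-individual ROH count (~35) and summed
  length (~460 Mb).
* Island loci: the first `ceiling(carrier_fraction * n)` individuals of a
  seeded permutation receive the island core plus a per-carrier uniform
  flanking extension (default 0–3 Mb per side). An island is therefore
  the shared core of individually longer runs — the way sweep islands
  appear in data. Planting only the bare core would be undetectable by
  construction whenever the core holds fewer than `L` SNPs.
* Outlier loci: planted high-divergence SNPs get deterministic
  contrasting frequencies `0.5 ± delta` with `delta` solved so the
  parametric Weir–Cockerham theta equals the requested value. A
  Balding–Nichols draw at high `F` is strongly bimodal — both populations
  often drift to the same boundary, leaving no realized divergence — so
  it cannot serve as a per-locus planted truth; the deterministic
  contrast can, and the background stays Balding–Nichols.
* Genotype errors (default 0, i.e. clean post-QC calls) reassign a call
  to one of the other two codes; missingness (default 1%) masks calls
  last. Everything, including written file bytes, is a deterministic
  function of the seed.

## Validation experiments and problem sizes

The test suite validates each stage against an independent oracle or
planted truth, at sizes chosen to keep the full suite comfortably inside
a coffee break:

* ROH calling equals a brute-force window/run enumerator on 200 random
  instances of up to 500 SNPs × 10 samples with randomized gap/density
  parameters.
* Planted autozygous fractions 0.05/0.15/0.25 (tracts 4–16 Mb, 30,000
  SNPs, 2% missingness) are recovered with mean absolute error below
  0.02 over 20 seeds.
* A 2-Mb island carried by 24 of 30 individuals over a background burden
  of 0.05 is recovered with its peak inside the planted core in ≥95 of
  100 seeds, and null cohorts with no planted autozygosity (chance
  homozygosity only) produce no island in ≥95 of 100. Both choices are
  deliberate: a cohort with random individual tracts genuinely shares
  loci by drift — in such cohorts the caller *should* report those loci
  (they are real shared autozygosity, indistinguishable from selection
  without an outgroup), so detector specificity has to be measured
  against a null with no autozygosity at all, and the modest background
  in the planted arm keeps the recovery measurement about locus-sharing
  rather than burden coincidence.
* The weighted mean FST is within 0.02 of the Balding–Nichols truth at
  F = 0.03 and 0.10 (2×50 diploids, 5,000 SNPs, 20 seeds), and the
  per-SNP estimator matches an independent transcription of the 1984
  formulas to 1e-12 on random count tables.
* 30 planted theta = 0.5 loci on a 30,000-SNP F = 0.02 background are
  ≥90% recovered in the top-0.1% call set over 100 seeds.
* The exact HWE p equals closed-form enumeration to 1e-12 on a 500-table
  grid with 2N ≤ 200.
* A planted inbreeding gradient (burden ~0 to 0.4) forces
  r(Ho, F_ROH) < −0.8 in every one of 50 seeds.
* A constructed 20-sample QC toy yields exactly the planted removal
  counts at the standard thresholds, and the ±100 kb gene flank is
  closed at exactly 100,000 bp.

`scripts/acceptance.R` re-runs a condensed version of these experiments
plus a full default cohort and writes the resulting quantities as JSON.

## Numerical and degenerate-input choices

* HWE: the exact-test sum includes configurations whose probability is
  within a 1e-10 relative factor of the observed one, so symmetric ties
  are included regardless of floating-point evaluation order.
* Zero-variance markers have LD r² defined as 0; monomorphic-across-pops
  SNPs are skipped in FST (denominator 0); a constant incidence track
  (sd = 0) yields no islands, with a warning.
* Chromosomes with fewer than `L` SNPs produce no ROH; `coverage_bp = 0`
  or an all-missing individual is an error rather than a silent 0/0.
* PED input carries no allele registry, so the text reader assigns
  allele codes alphabetically; binary round trips are exact because BIM
  stores both alleles.

## Known limitations

Single-size chromosomes and LD-free background in the simulator; normal
approximation in both the island and FST outlier thresholds (inherited
from the method being implemented); no phasing, no sex chromosomes, no
pedigree inbreeding, no permutation nulls. The batch-intersection step of
two-chip designs is modelled only as an optional marker-ID whitelist.

## Pipeline configuration

`run_pipeline()` takes a YAML file or list: `input` (PLINK prefix and
`format: binary|text`) *or* `simulate` (arguments to `sim_config()`),
optional `population_file` and `annotation` (`path` + `format:
bed|gff3`), `branches` (`structure`/`roh`/`fst` switches), `roh`
(`roh_params()` overrides), `islands` (`p_min`, `incidence_floor_pct`,
`fallback`), `fst` (`top_fraction`), `flank_bp`, `seed` and `output_dir`.
Outputs are TSVs (QC reports, per-breed segments, F_ROH, incidence and
island tables, per-comparison Manhattan and significant-SNP tables,
diversity, gene-annotated reports) plus a manifest with a config hash;
identical config + seed reproduces the TSVs byte for byte. A thin CLI
wrapper ships in `inst/cli/rohscan`.
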