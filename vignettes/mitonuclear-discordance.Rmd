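---
title: "Quantifying mitonuclear discordance in admixed cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitonuclear discordance in admixed cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mndkit)
```

## The statistic and its assumptions

Mitochondria are jointly encoded by the mtDNA and by nuclear genes whose
products are imported into the organelle. In admixed individuals the two
genomes can carry different continental ancestries; **mitonuclear
discordance (MND)** measures how much. The package computes MND at three
resolutions:

* **Gene-wise MND** — for a gene represented by SNPs with per-haplotype
  local-ancestry calls, the proportion of calls not matching the mtDNA
  ancestry. Each diploid SNP contributes two calls, so a site
  heterozygous for ancestry contributes 0.5. This per-call convention is
  a deliberate choice: local-ancestry tools emit haplotype-level calls,
  and any per-SNP collapse discards the heterozygous information and
  creates ties. A per-SNP majority mode (`collapse = "per_snp"`, ties
  0.5) is provided for sensitivity analysis; the two agree except at
  sites with exactly one missing haplotype call.
* **Per-sample, per-gene-set MND** — the unweighted arithmetic mean of
  gene-wise MND over all genes of a set (each gene one vote, regardless
  of its SNP count, because the averaging is defined over genes).
  Genes with zero usable calls are dropped from the mean, not imputed.
* **Global MND** — `1 − θ_a`, where `θ` is the genome-wide ancestry
  proportion vector (estimated here by averaging local-ancestry calls)
  and `a` is the mtDNA ancestry.

The intergenerational change for a mother–offspring pair is the relative
change `ΔMND = (MND_offspring − MND_mother) / MND_mother`; it is
undefined when the mother's MND is zero, and such pairs are excluded with
a logged reason rather than patched.

The statistic assumes (i) local-ancestry calls are correct (the package
consumes FLARE-style output; it does not infer ancestry), (ii) the mtDNA
haplogroup's macro branch determines a single continental ancestry, and
(iii) missingness is uninformative — missing calls leave both numerator
and denominator.

## Haplogroup handling

Full haplogroup strings collapse to single-token macrohaplogroups by
longest-prefix matching with a leading-letter fallback; all L0–L6
lineages collapse to `L`. Longest-prefix matters because a pure
first-letter rule would file `HV0a` under `H` — harmless for ancestry
(both European) but wrong as a macro token. The default ancestry map
assigns A–D to NAT, L to AFR, and the common West-Eurasian macros (H, HV,
V, J, T, U, K, N, R, W, I, X) to EUR. Haplogroup X is geographically
ambiguous (European X and Native American X2a); the default maps it to
EUR — a documented default, not an inference, and overridable through a
JSON config (`haplogroup_map_from_config()`). Macros outside the map
resolve to `UNMAPPED`, a value, not an error: those samples are excluded
from MND with a logged reason, so no silent label guessing occurs.

## Statistical layer

* **Omnibus**: one-way ANOVA where normality or the central limit
  theorem applies, otherwise Kruskal–Wallis (tie-corrected). The informal
  rule is concretized as: ANOVA if every group has n ≥ 30; otherwise
  ANOVA if Shapiro–Wilk on within-group-centered residuals gives
  p > 0.05; otherwise Kruskal–Wallis.
* **Pairwise**: all unordered pairs, two-sided, Welch t or Mann–Whitney
  U by the same rule; Bonferroni adjustment `min(1, p × family size)`;
  alpha fixed at 0.05.
* **Effect size**: Cohen's d with the root-mean-square of the two sds as
  denominator, `d = (m_a − m_b) / sqrt((s_a² + s_b²)/2)`. The RMS form is
  the default because published all-mitonuclear effect sizes recompute
  from their printed group moments under RMS and not under n-weighted
  pooling; the pooled variant is available (`method = "pooled"`).
* **Variance comparison**: two-sided F test with the larger variance in
  the numerator (reported ratio ≥ 1). The F test is exact under
  normality but sensitive to heavy tails, so a Brown–Forsythe Levene
  test (absolute deviations from group medians, one-way ANOVA) is
  available by configuration.
* **Correlation**: Spearman's rho with midrank ties and an asymptotic
  two-sided p, appropriate at cohort sample sizes.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates the stated world used for validation:

* Individual ancestry proportions `θ ~ Dirichlet(α)`, default
  `α = (NAT 4.5, EUR 5.0, AFR 0.5)` — a spread centered near a
  half-Native-American, half-European, low-African profile typical of
  Chilean admixed cohorts. The concentration was chosen once as a
  realistic desk-scale default and not revisited.
* Haplotypes follow the standard Poisson admixture-tract approximation:
  breakpoints at rate `g` per Morgan (default `g = 12`, roughly the
  post-Columbian number of generations) and tract ancestries drawn
  independently from `θ`. Two chromosomes of 1 Morgan map to 100 Mb
  each; 200 genes × 10 sites by default, so a cohort builds in seconds.
* mtDNA ancestry is a categorical draw from the individual's own `θ`
  (`maternal_draw`): the maternal lineage is one random lineage out of
  the ancestry makeup. A haplogroup string consistent with the drawn
  ancestry (e.g. NAT → one of A2/B2b/C1b/D1a) is attached so the
  classifier is exercised end to end.
* Offspring receive one haplotype by meiosis over the mother's two
  haplotypes (crossovers Poisson, rate 1/Morgan) and one from a freshly
  simulated father; mtDNA ancestry and haplogroup are copied from the
  mother. `father_theta = "match"` equates the father's `θ` with the
  mother's, giving the null expectation E[ΔMND] ≈ 0 used in testing.

The simulator does **not** emulate: genotypes or alleles (the VCF GT is
a placeholder), linkage between ancestry and gene location, local-
ancestry inference error, imputation-quality structure, population
phylogeography of haplogroups beyond the macro label, or selection. A
green test therefore establishes that the estimator recovers the truth
of this generative model — e.g. mean sample MND converges to
`mean(1 − θ_mt)` — not that inference error on real data is negligible.

## Numerical and degenerate-input choices

* Coordinates follow format standards: VCF positions 1-based, BED
  0-based half-open; a site belongs to a gene iff
  `start ≤ pos − 1 < end`. Nested or overlapping genes each receive the
  shared site (the statistic is per-gene, so there is no double count
  within a gene).
* Ancestry proportions must sum to 1 within 1e-9; `sd` is reported `NA`
  for n = 1; constant data make omnibus, variance-ratio and correlation
  statistics errors rather than silently degenerate values.
* No default per-site QC is applied; `read_flare_vcf(site_filter=)`
  exposes a mask hook for upstream imputation-quality filters.
* All runs are deterministic given a seed; pipeline manifests omit
  timestamps so reruns with identical inputs are byte-identical.

## Known limitations

* The haplogroup→ancestry map for non-A–D, non-L macros is a curated
  default; analyses of cohorts rich in Eurasian back-migration lineages
  (notably X, M, N subtrees) should review it.
* MND treats all mismatching ancestry equally; it does not weight genes
  by mitochondrial importance beyond set membership.
* ΔMND is a ratio statistic: it is undefined at maternal MND 0 and
  right-skewed when maternal MND is small, which is why cohort contrasts
  of ΔMND use rank-based and variance tests rather than means.
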