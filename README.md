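# mndkit

Mitonuclear discordance analysis for admixed cohorts.

## The problem

Mitochondrial function is under dual genetic control: the mtDNA and more
than a thousand nuclear-encoded mitochondrial genes coevolved within
populations. Admixture — such as the post-Columbian mixing of Native
American (NAT), European (EUR) and African (AFR) ancestries in Latin
America — combines mtDNA from one lineage with nuclear alleles from
others. **Mitonuclear discordance (MND)** quantifies that mismatch for an
individual: the fraction of nuclear local-ancestry calls, at
nuclear-encoded mitochondrial genes, that do not match the continental
ancestry of the individual's mtDNA haplogroup.

For a gene *g* represented by a set of SNPs with per-haplotype local
ancestry calls, and an individual whose mtDNA macrohaplogroup maps to
ancestry *a*:

    MND_g = (# haplotype calls in g with ancestry != a) / (# usable calls in g)

The per-sample statistic is the unweighted mean of `MND_g` over a gene set
(all mitonuclear, OXPHOS, high-mt or low-mt). The global analogue is
`1 − θ_a` where `θ` is the genome-wide ancestry proportion vector: an
individual with 55% EUR / 40% NAT / 5% AFR nuclear ancestry and a Native
American haplogroup-B mtDNA has global MND = 0.60. The intergenerational
change for a mother–offspring pair is

    ΔMND = (MND_offspring − MND_mother) / MND_mother

`mndkit` implements the full pipeline for researchers in population and
medical genetics: I/O for FLARE-style local-ancestry VCFs (FORMAT
`AN1`/`AN2`), gene BED intervals, gene-set tables, Haplogrep-style
haplogroup calls and pair lists; macrohaplogroup collapsing and
haplogroup→ancestry mapping; gene-wise/set-averaged MND, global ancestry,
global MND and ΔMND; a cohort-comparison layer (ANOVA or Kruskal–Wallis
omnibus, Bonferroni-corrected pairwise t / Mann–Whitney U tests, Cohen's
d with an RMS-of-sds denominator, variance F / Levene tests, Spearman
correlation); and a synthetic admixed-cohort simulator with known ground
truth that stands in for restricted genomic data.

## Worked example

```r
library(mndkit)

cfg    <- sim_config(n_individuals = 60, n_pairs = 20, seed = 2026)
cohort <- simulate_cohort(cfg)
write_cohort(cohort, "sim")            # FLARE VCF, BED, TSVs + ground truth

inp    <- read_cohort("sim")
assign <- assign_mt_ancestry(inp$haplogroups, panel = inp$la$panel)
tab    <- mnd_table(inp$la, inp$gene_index, assign, sets = "all_mitonuclear")
head(tab, 4)
#>   sample_id        gene_set mean_mnd n_genes_used mt_ancestry
#> 1      F001 all_mitonuclear   0.3725          200         NAT
#> 2      F002 all_mitonuclear   0.6625          200         NAT
#> 3      F003 all_mitonuclear   0.9025          200         AFR
#> 4      F004 all_mitonuclear   0.4750          200         NAT

summarize_groups(tab$mean_mnd, tab$mt_ancestry)
#>   group  n      mean         sd    variance  median    min    max
#> 1   NAT 38 0.5143421 0.15970590 0.025505974 0.47875 0.2250 0.8750
#> 2   AFR  6 0.9070833 0.05712742 0.003263542 0.91625 0.8250 0.9725
#> 3   EUR 36 0.4625694 0.18614653 0.034650531 0.43625 0.1175 0.9150

compare_groups(tab$mean_mnd, tab$mt_ancestry, reference = "NAT")
#> <comparison_report>
#>   omnibus: ANOVA statistic=18.05 p=3.72e-07
#>   NAT: n=38, 0.514 +/- 0.160
#>   AFR: n=6, 0.907 +/- 0.057
#>   EUR: n=36, 0.463 +/- 0.186
#>   pairwise tests: 3 (Bonferroni family 3, alpha 0.05)

dd <- delta_mnd(tab, inp$pairs, "all_mitonuclear")
median(dd$delta)     # 0.108 over 20 pairs
```

Each `mean_mnd` is the fraction of that sample's ancestry calls at
mitonuclear genes that disagree with its mtDNA ancestry: the AFR-mtDNA
samples are highly discordant (0.91) because their nuclear genomes are
mostly NAT/EUR, and the omnibus test flags the haplogroup-group
differences. Every number above was produced by the code shown.

The worked textbook case:

```r
global_mnd(c(EUR = 0.55, NAT = 0.40, AFR = 0.05), "NAT")   # 0.6
cohens_d(0.60, 0.09, 63, 0.43, 0.24, 26)                   # 0.9379533
```

## Command line

```sh
Rscript inst/scripts/mnd-pipeline.R simulate --config sim.json --seed 99
Rscript inst/scripts/mnd-pipeline.R compute  --config run.json
Rscript inst/scripts/mnd-pipeline.R delta    --config run.json
Rscript inst/scripts/mnd-pipeline.R compare  --config cmp.json
```

Configs are JSON (see `?run_config`); exit codes are 0 (ok),
1 (validation error), 2 (runtime error). Each stage writes a
`run_manifest.json` recording inputs, package version and a config hash.

## Vignette

`vignettes/mitonuclear-discordance.Rmd` documents the model, the
statistical choices, what the simulator does and does not emulate, and
known limitations.
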