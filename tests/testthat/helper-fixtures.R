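# Fixtures are built in code; nothing is stored on disk.

default_panel <- function() ancestry_panel(c("NAT", "EUR", "AFR"))

# tiny hand-built local-ancestry matrix: calls[sample, site, haplotype]
tiny_la <- function(calls, chrom = "chr1", pos = NULL, samples = NULL,
                    panel = default_panel()) {
  stopifnot(length(dim(calls)) == 3)
  ns <- dim(calls)[1]; np <- dim(calls)[2]
  if (is.null(pos)) pos <- seq(101L, by = 100L, length.out = np)
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(ns))
  sites <- data.frame(chrom = chrom, pos = pos,
                      id = paste0(chrom, "_", pos))
  local_ancestry(samples, sites, calls, panel)
}

# gene index over a tiny matrix: genes as list(gene_id = c(start, end))
tiny_gene_index <- function(la, genes, sets = NULL) {
  gdf <- data.frame(gene_id = names(genes),
                    chrom = la$sites$chrom[1],
                    start = vapply(genes, `[`, 0, 1),
                    end = vapply(genes, `[`, 0, 2))
  if (is.null(sets))
    sets <- list(all_mitonuclear = names(genes), oxphos = character(0),
                 high_mt = character(0), low_mt = character(0))
  gene_index(gdf, sets, la)
}

# independent brute-force oracle for gene-wise MND: explicit loops over
# samples x genes x sites x haplotypes, never touching gene_mnd_matrix
naive_gene_mnd <- function(la, gene_index, mt_ancestry) {
  samples <- names(mt_ancestry)
  genes <- gene_index$genes$gene_id
  out <- matrix(NA_real_, length(samples), length(genes),
                dimnames = list(samples, genes))
  for (s in samples) {
    si <- match(s, la$samples)
    code <- panel_code(la$panel, mt_ancestry[[s]])
    for (g in genes) {
      mism <- 0L; tot <- 0L
      for (j in gene_index$site_map[[g]]) {
        for (h in 1:2) {
          call <- la$calls[si, j, h]
          if (!is.na(call)) {
            tot <- tot + 1L
            if (call != code) mism <- mism + 1L
          }
        }
      }
      if (tot > 0) out[s, g] <- mism / tot
    }
  }
  out
}

# small simulated cohort for cross-module tests
small_cohort <- function(seed = 101, n = 20, n_pairs = 0, n_genes = 30,
                         sites_per_gene = 5, ...) {
  simulate_cohort(sim_config(n_individuals = n, n_pairs = n_pairs,
                             n_genes = n_genes,
                             sites_per_gene = sites_per_gene,
                             seed = seed, ...))
}

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
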