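#' Gene-wise mitonuclear discordance
#'
#' For one sample and one gene, the proportion of local-ancestry calls at
#' the gene's sites that do not match the sample's mtDNA ancestry. Each
#' diploid SNP contributes two calls (one per haplotype), so a site
#' heterozygous for ancestry contributes 0.5; missing calls are excluded
#' from numerator and denominator.
#'
#' @param la A [local_ancestry()] object.
#' @param sample Sample id.
#' @param gene Gene id present in `gene_index`.
#' @param gene_index A [gene_index()].
#' @param mt_ancestry The sample's mtDNA ancestry label (panel member).
#' @param collapse `"per_call"` (default: proportion over SNP x haplotype
#'   calls) or `"per_snp"` (each SNP collapsed to one value by majority,
#'   ancestry-heterozygous sites counting 0.5 -- a sensitivity-analysis
#'   mode; the two agree except at sites with exactly one missing call).
#' @return Proportion in \[0, 1\], or `NA` when the gene has no usable call
#'   for this sample (the gene is then skipped, not an error).
#' @export
gene_wise_mnd <- function(la, sample, gene, gene_index, mt_ancestry,
                          collapse = c("per_call", "per_snp")) {
  collapse <- match.arg(collapse)
  si <- match(sample, la$samples)
  if (is.na(si)) abort_validation(sprintf("unknown sample: %s", sample))
  m <- gene_mnd_matrix(la, gene_index,
                       stats::setNames(mt_ancestry, sample),
                       genes = gene, collapse = collapse)
  m[sample, gene]
}

#' Per-gene MND matrix
#'
#' Vectorized computation of gene-wise MND for many samples and genes at
#' once; the workhorse behind [mnd_table()].
#'
#' @inheritParams gene_wise_mnd
#' @param mt_ancestry Named character vector, sample id -> mtDNA ancestry
#'   label. Only the named samples are computed.
#' @param genes Gene ids to compute (default: all genes in the index).
#' @return Numeric matrix (samples x genes) of gene-wise MND; `NA` where a
#'   gene has zero usable calls for a sample.
#' @export
gene_mnd_matrix <- function(la, gene_index, mt_ancestry,
                            genes = gene_index$genes$gene_id,
                            collapse = c("per_call", "per_snp")) {
  collapse <- match.arg(collapse)
  samples <- names(mt_ancestry)
  si <- match(samples, la$samples)
  if (anyNA(si))
    abort_validation(sprintf("unknown sample(s): %s",
                             paste(samples[is.na(si)], collapse = ", ")))
  mt_code <- panel_code(la$panel, unname(mt_ancestry))
  a1 <- la$calls[si, , 1, drop = FALSE]; dim(a1) <- c(length(si), nrow(la$sites))
  a2 <- la$calls[si, , 2, drop = FALSE]; dim(a2) <- c(length(si), nrow(la$sites))
  m1 <- a1 != mt_code  # recycles mt_code down rows (samples)
  m2 <- a2 != mt_code
  u1 <- !is.na(m1); u2 <- !is.na(m2)
  m1[!u1] <- FALSE; m2[!u2] <- FALSE
  mis <- m1 + m2          # mismatching calls per sample x site
  use <- u1 + u2          # usable calls per sample x site
  out <- matrix(NA_real_, length(si), length(genes),
                dimnames = list(samples, genes))
  for (k in seq_along(genes)) {
    idx <- gene_index$site_map[[genes[k]]]
    if (is.null(idx))
      abort_validation(sprintf("unknown gene: %s", genes[k]))
    if (length(idx) == 0) next
    if (collapse == "per_call") {
      num <- rowSums(mis[, idx, drop = FALSE])
      den <- rowSums(use[, idx, drop = FALSE])
      out[, k] <- ifelse(den > 0, num / den, NA_real_)
    } else {
      v <- mis[, idx, drop = FALSE] / use[, idx, drop = FALSE]  # NaN if 0 calls
      out[, k] <- rowMeans(v, na.rm = TRUE)
      out[, k][!is.finite(out[, k])] <- NA_real_
    }
  }
  out
}

#' Per-sample gene-set-averaged MND
#'
#' Averages gene-wise MND over all genes of each requested gene set
#' (unweighted: each gene one vote, regardless of its SNP count). Genes
#' with zero usable calls are dropped from a sample's mean; samples with an
#' unmapped mtDNA ancestry, or with no usable gene in a set, are excluded
#' and reported in the `exclusions` attribute.
#'
#' @inheritParams gene_wise_mnd
#' @param assignments `data.frame` from [assign_mt_ancestry()].
#' @param sets Character vector of gene-set names to evaluate (default: all
#'   sets in the index).
#' @param detail If `TRUE`, attach the per-gene MND matrix as attribute
#'   `"gene_detail"`.
#' @return `data.frame` of class `mnd_table` with columns `sample_id`,
#'   `gene_set`, `mean_mnd`, `n_genes_used`, `mt_ancestry`; attribute
#'   `exclusions` is a `data.frame` (`sample_id`, `reason`).
#' @export
mnd_table <- function(la, gene_index, assignments,
                      sets = names(gene_index$sets),
                      collapse = c("per_call", "per_snp"),
                      detail = FALSE) {
  collapse <- match.arg(collapse)
  bad_sets <- setdiff(sets, names(gene_index$sets))
  if (length(bad_sets))
    abort_validation(sprintf("unknown gene set(s): %s",
                             paste(bad_sets, collapse = ", ")))
  assignments <- assignments[assignments$sample_id %in% la$samples, ,
                             drop = FALSE]
  excl <- data.frame(sample_id = character(0), reason = character(0))
  unmapped <- assignments$mt_ancestry == "UNMAPPED"
  if (any(unmapped))
    excl <- rbind(excl, data.frame(sample_id = assignments$sample_id[unmapped],
                                   reason = "unmapped mtDNA ancestry"))
  keep <- assignments[!unmapped, , drop = FALSE]
  if (nrow(keep) == 0) {
    out <- data.frame(sample_id = character(0), gene_set = character(0),
                      mean_mnd = numeric(0), n_genes_used = integer(0),
                      mt_ancestry = character(0))
    return(structure(out, exclusions = excl, class = c("mnd_table", "data.frame")))
  }
  mt <- stats::setNames(keep$mt_ancestry, keep$sample_id)
  all_genes <- unique(unlist(gene_index$sets[sets], use.names = FALSE))
  gm <- gene_mnd_matrix(la, gene_index, mt, genes = all_genes,
                        collapse = collapse)
  rows <- lapply(sets, function(s) {
    g <- intersect(gene_index$sets[[s]], colnames(gm))
    sub <- gm[, g, drop = FALSE]
    n_used <- rowSums(!is.na(sub))
    data.frame(sample_id = rownames(sub), gene_set = s,
               mean_mnd = ifelse(n_used > 0, rowMeans(sub, na.rm = TRUE),
                                 NA_real_),
               n_genes_used = as.integer(n_used),
               mt_ancestry = unname(mt[rownames(sub)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  no_genes <- is.na(out$mean_mnd)
  if (any(no_genes)) {
    excl <- rbind(excl, data.frame(
      sample_id = out$sample_id[no_genes],
      reason = sprintf("no usable gene in set %s", out$gene_set[no_genes])))
    out <- out[!no_genes, , drop = FALSE]
  }
  rownames(out) <- NULL
  structure(out, exclusions = excl,
            gene_detail = if (detail) gm else NULL,
            class = c("mnd_table", "data.frame"))
}

#' Global ancestry from local-ancestry averages
#'
#' The genome-wide proportion of each ancestry among a sample's non-missing
#' calls (sites x two haplotypes) -- the local-ancestry-averaged analogue
#' of a global ancestry estimate.
#'
#' @param la A [local_ancestry()] object.
#' @param samples Sample ids (default: all).
#' @return `data.frame` with `sample_id` and one proportion column per
#'   panel population; rows sum to 1.
#' @export
global_ancestry <- function(la, samples = la$samples) {
  si <- match(samples, la$samples)
  if (anyNA(si))
    abort_validation(sprintf("unknown sample(s): %s",
                             paste(samples[is.na(si)], collapse = ", ")))
  calls <- la$calls[si, , , drop = FALSE]
  counts <- vapply(la$panel$codes, function(k)
    rowSums(calls == k, na.rm = TRUE, dims = 1), numeric(length(si)))
  counts <- matrix(counts, nrow = length(si))
  tot <- rowSums(counts)
  if (any(tot == 0))
    abort_validation(sprintf("all calls missing for sample(s): %s",
                             paste(samples[tot == 0], collapse = ", ")))
  props <- counts / tot
  colnames(props) <- la$panel$names
  data.frame(sample_id = samples, props, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Global mitonuclear discordance
#'
#' One minus the nuclear ancestry proportion matching the mtDNA ancestry:
#' e.g. an individual with 55% European, 40% Native American and 5% African
#' nuclear ancestry carrying a Native American mtDNA haplogroup has global
#' MND 0.60 (the sum of the European and African components).
#'
#' @param proportions Named numeric vector of ancestry proportions (must be
#'   non-negative and sum to 1 within 1e-9), or a single row of
#'   [global_ancestry()] output.
#' @param mt_ancestry mtDNA ancestry label; must be one of the proportion
#'   names.
#' @return Proportion in \[0, 1\].
#' @examples
#' global_mnd(c(EUR = 0.55, NAT = 0.40, AFR = 0.05), "NAT")  # 0.6
#' @export
global_mnd <- function(proportions, mt_ancestry) {
  if (is.data.frame(proportions)) {
    stopifnot(nrow(proportions) == 1)
    proportions <- unlist(proportions[, setdiff(names(proportions), "sample_id")])
  }
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9)
    abort_validation("ancestry proportions must be >= 0 and sum to 1")
  if (!mt_ancestry %in% names(proportions))
    abort_validation(sprintf("mt ancestry '%s' not in panel (%s)", mt_ancestry,
                             paste(names(proportions), collapse = ", ")))
  unname(1 - proportions[[mt_ancestry]])
}

#' Intergenerational change in MND
#'
#' For each mother-offspring pair, the relative change
#' `delta = (MND_offspring - MND_mother) / MND_mother` on a given gene set.
#' Pairs where either member lacks an MND value, or where the mother's MND
#' is zero (division undefined), are excluded with a logged reason.
#'
#' @param mnd_tab An [mnd_table()].
#' @param pairs `data.frame` of pair records from [read_pairs()].
#' @param gene_set Gene-set name to use for both members.
#' @return `data.frame` of class `delta_mnd` with columns `mother_id`,
#'   `offspring_id`, `cohort`, `gene_set`, `mnd_mother`, `mnd_offspring`,
#'   `delta`; attribute `exclusions` lists dropped pairs.
#' @export
delta_mnd <- function(mnd_tab, pairs, gene_set) {
  sub <- mnd_tab[mnd_tab$gene_set == gene_set, , drop = FALSE]
  mm <- sub$mean_mnd[match(pairs$mother_id, sub$sample_id)]
  mo <- sub$mean_mnd[match(pairs$offspring_id, sub$sample_id)]
  reason <- rep(NA_character_, nrow(pairs))
  reason[is.na(mm)] <- "mother has no MND for gene set"
  reason[is.na(mo)] <- "offspring has no MND for gene set"
  reason[!is.na(mm) & mm == 0] <- "mother MND is zero (delta undefined)"
  keep <- is.na(reason)
  excl <- data.frame(mother_id = pairs$mother_id[!keep],
                     offspring_id = pairs$offspring_id[!keep],
                     reason = reason[!keep], stringsAsFactors = FALSE)
  out <- data.frame(
    mother_id = pairs$mother_id[keep],
    offspring_id = pairs$offspring_id[keep],
    cohort = if (is.null(pairs$cohort)) rep("all", sum(keep))
             else pairs$cohort[keep],
    gene_set = rep(gene_set, sum(keep)),
    mnd_mother = mm[keep],
    mnd_offspring = mo[keep],
    delta = (mo[keep] - mm[keep]) / mm[keep],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, exclusions = excl, class = c("delta_mnd", "data.frame"))
}
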