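#' Read a FLARE-style local-ancestry VCF
#'
#' Consumes the annotated VCF dialect emitted by local-ancestry tools such
#' as FLARE: FORMAT fields `AN1` and `AN2` carry the 0-based ancestry code
#' of each haplotype at each site, and a header line of the form
#' `##ANCESTRY=<0=NAT,1=EUR,2=AFR>` maps codes to population labels.
#'
#' Records where a sample's `AN1`/`AN2` are missing (`.`) are kept as `NA`
#' calls; downstream statistics exclude them from both numerator and
#' denominator.
#'
#' @param path Path to the VCF (uncompressed or bgzipped).
#' @param panel Optional [ancestry_panel()], or path to a sidecar panel file
#'   with lines `<code><TAB><name>`. When supplied it must agree with the
#'   `##ANCESTRY` header line if that line is present; when absent the
#'   header line is required.
#' @param site_filter Optional per-site QC hook: a function taking the sites
#'   `data.frame` (`chrom`, `pos`, `id`) and returning a logical keep vector.
#'   No filter is applied by default.
#' @return A [local_ancestry()] object.
#' @export
read_flare_vcf <- function(path, panel = NULL, site_filter = NULL) {
  if (!file.exists(path))
    abort_validation(sprintf("VCF not found: %s", path))
  header_panel <- .parse_ancestry_header(path)
  if (is.null(panel)) {
    panel <- header_panel
    if (is.null(panel))
      abort_validation(sprintf(
        "%s: no ##ANCESTRY header line and no panel supplied", path))
  } else {
    if (is.character(panel)) panel <- .read_panel_file(panel)
    if (!is.null(header_panel) && !identical(header_panel$names, panel$names))
      abort_validation(sprintf(
        "%s: supplied panel (%s) disagrees with ##ANCESTRY header (%s)",
        path, paste(panel$names, collapse = ","),
        paste(header_panel$names, collapse = ",")))
  }
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown")),
    error = function(e) abort_validation(
      sprintf("malformed VCF %s: %s", path, conditionMessage(e))))
  g <- VariantAnnotation::geno(vcf)
  if (!all(c("AN1", "AN2") %in% names(g)))
    abort_validation(sprintf(
      "%s: FORMAT must declare integer fields AN1 and AN2", path))
  rr <- SummarizedExperiment::rowRanges(vcf)
  ids <- names(rr)
  if (is.null(ids)) ids <- rep(".", length(rr))
  sites <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    id = ids,
    stringsAsFactors = FALSE)
  an1 <- t(as.matrix(g$AN1))  # samples x sites
  an2 <- t(as.matrix(g$AN2))
  calls <- array(NA_integer_, dim = c(nrow(an1), ncol(an1), 2L))
  calls[, , 1] <- an1
  calls[, , 2] <- an2
  if (!is.null(site_filter)) {
    keep <- site_filter(sites)
    stopifnot(is.logical(keep), length(keep) == nrow(sites))
    sites <- sites[keep, , drop = FALSE]
    calls <- calls[, keep, , drop = FALSE]
  }
  local_ancestry(rownames(an1), sites, calls, panel)
}

# "##ANCESTRY=<0=NAT,1=EUR,2=AFR>" -> ancestry_panel, or NULL if absent
.parse_ancestry_header <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  on.exit(close(con))
  open(con, "r")
  line <- NULL
  repeat {
    l <- readLines(con, n = 1L)
    if (length(l) == 0 || !startsWith(l, "##")) break
    if (startsWith(l, "##ANCESTRY=")) { line <- l; break }
  }
  if (is.null(line)) return(NULL)
  body <- sub("^##ANCESTRY=<(.*)>\\s*$", "\\1", line)
  if (identical(body, line))
    abort_validation(sprintf("malformed ##ANCESTRY line in %s: %s", path, line))
  kv <- strsplit(strsplit(body, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
  if (any(lengths(kv) != 2))
    abort_validation(sprintf("malformed ##ANCESTRY line in %s: %s", path, line))
  codes <- as.integer(vapply(kv, `[`, "", 1L))
  nms <- vapply(kv, `[`, "", 2L)
  if (anyNA(codes) || !identical(sort(codes), seq_along(codes) - 1L))
    abort_validation(sprintf(
      "##ANCESTRY codes in %s must be a contiguous 0-based range", path))
  ancestry_panel(nms[order(codes)])
}

.read_panel_file <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         col.names = c("code", "name"),
                         stringsAsFactors = FALSE)
  d <- d[order(d$code), ]
  if (!identical(as.integer(d$code), seq_len(nrow(d)) - 1L))
    abort_validation(sprintf("panel file %s: codes must be 0-based contiguous", path))
  ancestry_panel(d$name)
}

#' Write a FLARE-style local-ancestry VCF
#'
#' Emits a VCFv4.2 skeleton with FORMAT `GT:AN1:AN2`. Genotypes are
#' placeholder `0|0` (only the ancestry codes are meaningful); missing
#' calls are written as `.`. Output is deterministic: fixed column order,
#' `\n` line endings.
#'
#' @param la A [local_ancestry()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flare_vcf <- function(la, path) {
  stopifnot(inherits(la, "local_ancestry"))
  chroms <- unique(la$sites$chrom)
  chrom_len <- vapply(chroms, function(ch)
    max(la$sites$pos[la$sites$chrom == ch]) + 1000L, integer(1))
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##ANCESTRY=<%s>",
            paste(sprintf("%d=%s", la$panel$codes, la$panel$names),
                  collapse = ",")),
    sprintf("##contig=<ID=%s,length=%d>", chroms, chrom_len),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype (placeholder)\">",
    "##FORMAT=<ID=AN1,Number=1,Type=Integer,Description=\"Ancestry of haplotype 1\">",
    "##FORMAT=<ID=AN2,Number=1,Type=Integer,Description=\"Ancestry of haplotype 2\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", la$samples), collapse = "\t"))
  a1 <- la$calls[, , 1, drop = FALSE]; dim(a1) <- dim(la$calls)[1:2]
  a2 <- la$calls[, , 2, drop = FALSE]; dim(a2) <- dim(la$calls)[1:2]
  f1 <- ifelse(is.na(a1), ".", as.character(a1))
  f2 <- ifelse(is.na(a2), ".", as.character(a2))
  gt <- ifelse(is.na(a1) & is.na(a2), ".", "0|0")
  cells <- matrix(paste(gt, f1, f2, sep = ":"), nrow = nrow(f1))
  body <- vapply(seq_len(nrow(la$sites)), function(j) {
    paste(c(la$sites$chrom[j], la$sites$pos[j], la$sites$id[j],
            "A", "C", ".", "PASS", ".", "GT:AN1:AN2", cells[, j]),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path, sep = "\n")
  invisible(path)
}

#' Build a gene index from BED intervals and a gene-set table
#'
#' Maps each nuclear-encoded mitochondrial gene to the local-ancestry sites
#' it contains and records gene-set memberships. Containment follows format
#' standards: VCF positions are 1-based, BED intervals 0-based half-open, so
#' a site belongs to a gene iff chrom matches and `start <= pos - 1 < end`.
#' A site inside nested/overlapping genes is assigned to every such gene.
#'
#' @param bed_path BED file with >= 4 columns (chrom, start, end, gene_id).
#' @param sets_path TSV with columns `gene_id`, `in_all`, `in_oxphos`,
#'   `in_high_mt`, `in_low_mt` (0/1 flags). The expected relationships are
#'   enforced: OXPHOS genes are a subset of all mitonuclear genes; high-mt
#'   and low-mt are disjoint subsets.
#' @param matrix A [local_ancestry()] object supplying the site coordinates.
#' @return An object of class `gene_index`: `genes` (data.frame with 0-based
#'   half-open intervals), `sets` (named list of gene-id vectors), `site_map`
#'   (named list of integer site indices per gene), and `zero_site_genes`
#'   (gene ids with no overlapping sites; these are excluded from averaging).
#' @export
read_gene_index <- function(bed_path, sets_path, matrix) {
  stopifnot(inherits(matrix, "local_ancestry"))
  gr <- tryCatch(rtracklayer::import(bed_path, format = "BED"),
                 error = function(e) abort_validation(
                   sprintf("malformed BED %s: %s", bed_path, conditionMessage(e))))
  genes <- data.frame(
    gene_id = as.character(gr$name),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to BED 0-based
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  if (anyNA(genes$gene_id) || any(!nzchar(genes$gene_id)))
    abort_validation(sprintf("%s: BED needs a 4th column with gene ids", bed_path))
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup))
    abort_validation(sprintf("duplicate gene_id in %s: %s", bed_path,
                             paste(unique(dup), collapse = ", ")))
  if (any(genes$start >= genes$end))
    abort_validation(sprintf("%s: gene intervals must satisfy start < end", bed_path))

  sets_df <- data.table::fread(sets_path, sep = "\t", data.table = FALSE)
  need <- c("gene_id", "in_all", "in_oxphos", "in_high_mt", "in_low_mt")
  if (!all(need %in% names(sets_df)))
    abort_validation(sprintf("%s: expected columns %s", sets_path,
                             paste(need, collapse = ", ")))
  missing_genes <- setdiff(sets_df$gene_id, genes$gene_id)
  if (length(missing_genes))
    abort_validation(sprintf("gene-set members absent from BED: %s",
                             paste(missing_genes, collapse = ", ")))
  sets <- list(
    all_mitonuclear = sets_df$gene_id[sets_df$in_all == 1],
    oxphos = sets_df$gene_id[sets_df$in_oxphos == 1],
    high_mt = sets_df$gene_id[sets_df$in_high_mt == 1],
    low_mt = sets_df$gene_id[sets_df$in_low_mt == 1])
  if (length(setdiff(sets$oxphos, sets$all_mitonuclear)))
    abort_validation("oxphos set must be a subset of all_mitonuclear")
  if (length(setdiff(c(sets$high_mt, sets$low_mt), sets$all_mitonuclear)))
    abort_validation("high_mt and low_mt must be subsets of all_mitonuclear")
  if (length(intersect(sets$high_mt, sets$low_mt)))
    abort_validation("high_mt and low_mt must be disjoint")

  gene_index(genes, sets, matrix)
}

#' @rdname read_gene_index
#' @param genes `data.frame` with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), used directly instead of a BED file.
#' @param sets Named list of gene-id vectors.
#' @export
gene_index <- function(genes, sets, matrix) {
  genes_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  sites_gr <- GenomicRanges::GRanges(
    matrix$sites$chrom, IRanges::IRanges(matrix$sites$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(genes_gr, sites_gr)
  site_map <- rep(list(integer(0)), nrow(genes))
  names(site_map) <- genes$gene_id
  sp <- split(S4Vectors::subjectHits(hits),
              genes$gene_id[S4Vectors::queryHits(hits)])
  site_map[names(sp)] <- lapply(sp, function(x) sort(unique(x)))
  zero <- genes$gene_id[lengths(site_map) == 0]
  structure(list(genes = genes, sets = sets, site_map = site_map,
                 zero_site_genes = zero),
            class = "gene_index")
}

#' @export
print.gene_index <- function(x, ...) {
  cat(sprintf("<gene_index> %d genes; sets: %s\n", nrow(x$genes),
              paste(sprintf("%s=%d", names(x$sets), lengths(x$sets)),
                    collapse = ", ")))
  if (length(x$zero_site_genes))
    cat(sprintf("  genes with no overlapping sites: %d\n",
                length(x$zero_site_genes)))
  invisible(x)
}

#' Read a Haplogrep-style haplogroup table
#'
#' @param path TSV whose header contains `SampleID` and `Haplogroup` columns
#'   (case-insensitive; extra Haplogrep columns such as Quality are ignored).
#' @return `data.frame` with columns `sample_id`, `haplogroup`, `flagged`
#'   (TRUE when the haplogroup string is empty). Classification into
#'   macrohaplogroups is deferred to [assign_mt_ancestry()].
#' @export
read_haplogroups <- function(path) {
  d <- data.table::fread(path, sep = "\t", data.table = FALSE,
                         colClasses = "character")
  si <- match("sampleid", tolower(names(d)))
  hi <- match("haplogroup", tolower(names(d)))
  if (is.na(si) || is.na(hi))
    abort_validation(sprintf("%s: need SampleID and Haplogroup columns", path))
  out <- data.frame(sample_id = d[[si]], haplogroup = d[[hi]],
                    stringsAsFactors = FALSE)
  dup <- out$sample_id[duplicated(out$sample_id)]
  if (length(dup))
    abort_validation(sprintf("duplicate sample in %s: %s", path,
                             paste(unique(dup), collapse = ", ")))
  out$flagged <- is.na(out$haplogroup) | !nzchar(out$haplogroup)
  out
}

#' Read a mother-offspring pair table
#'
#' @param path TSV with columns `mother_id`, `offspring_id` and optional
#'   `cohort`.
#' @param samples Character vector of available sample ids; rows referencing
#'   unknown samples are dropped with a warning.
#' @return `data.frame` of pair records (`mother_id`, `offspring_id`,
#'   `cohort`).
#' @export
read_pairs <- function(path, samples) {
  d <- data.table::fread(path, sep = "\t", data.table = FALSE,
                         colClasses = "character")
  if (!all(c("mother_id", "offspring_id") %in% names(d)))
    abort_validation(sprintf("%s: need mother_id and offspring_id columns", path))
  if (is.null(d$cohort)) d$cohort <- "all"
  if (any(d$mother_id == d$offspring_id))
    abort_validation(sprintf("%s: mother_id equals offspring_id for %s", path,
                             paste(d$mother_id[d$mother_id == d$offspring_id],
                                   collapse = ", ")))
  known <- d$mother_id %in% samples & d$offspring_id %in% samples
  if (any(!known)) {
    warning(sprintf("dropping %d pair(s) with unknown sample ids: %s",
                    sum(!known),
                    paste(d$mother_id[!known], d$offspring_id[!known],
                          sep = "/", collapse = ", ")))
    d <- d[known, , drop = FALSE]
  }
  rownames(d) <- NULL
  d[, c("mother_id", "offspring_id", "cohort")]
}

# --- writers for the remaining tabular formats (deterministic output) ---

#' Write tabular pipeline inputs
#'
#' Writers for the plain-text formats the readers consume: BED4 gene
#' intervals, the gene-set flag TSV, Haplogrep-style haplogroup TSV and the
#' mother-offspring pair TSV. Column order and line endings are fixed so
#' that outputs are byte-reproducible.
#'
#' @param genes `data.frame` with `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  out <- genes[, c("chrom", "start", "end", "gene_id")]
  out$start <- as.integer(out$start)  # never scientific notation
  out$end <- as.integer(out$end)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_gene_bed
#' @param sets_df `data.frame` with `gene_id` and 0/1 columns `in_all`,
#'   `in_oxphos`, `in_high_mt`, `in_low_mt`.
#' @export
write_gene_sets <- function(sets_df, path) {
  cols <- c("gene_id", "in_all", "in_oxphos", "in_high_mt", "in_low_mt")
  data.table::fwrite(sets_df[, cols], path, sep = "\t", eol = "\n")
  invisible(path)
}

#' @rdname write_gene_bed
#' @param haplogroups `data.frame` with `sample_id`, `haplogroup`.
#' @export
write_haplogroups <- function(haplogroups, path) {
  out <- data.frame(SampleID = haplogroups$sample_id,
                    Haplogroup = haplogroups$haplogroup)
  data.table::fwrite(out, path, sep = "\t", eol = "\n")
  invisible(path)
}

#' @rdname write_gene_bed
#' @param pairs `data.frame` with `mother_id`, `offspring_id`, `cohort`.
#' @export
write_pairs <- function(pairs, path) {
  if (is.null(pairs$cohort)) pairs$cohort <- "all"
  data.table::fwrite(pairs[, c("mother_id", "offspring_id", "cohort")], path,
                     sep = "\t", eol = "\n")
  invisible(path)
}
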