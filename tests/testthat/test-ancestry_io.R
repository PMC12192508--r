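test_that("read_flare_vcf transcribes AN1/AN2 calls and panel from the header", {
  vcf <- write_tsv_fixture(c(
    "##fileformat=VCFv4.2",
    "##ANCESTRY=<0=NAT,1=EUR,2=AFR>",
    "##contig=<ID=chr1,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=AN1,Number=1,Type=Integer,Description=\"a1\">",
    "##FORMAT=<ID=AN2,Number=1,Type=Integer,Description=\"a2\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1"), collapse = "\t"),
    "chr1\t101\ts1\tA\tC\t.\tPASS\t.\tGT:AN1:AN2\t0|0:0:0",
    "chr1\t201\ts2\tA\tC\t.\tPASS\t.\tGT:AN1:AN2\t0|0:1:2"),
    path = tempfile(fileext = ".vcf"))
  la <- read_flare_vcf(vcf)
  expect_identical(la$panel$names, c("NAT", "EUR", "AFR"))
  expect_identical(la$samples, "S1")
  expect_identical(la$calls[1, , 1], c(0L, 1L))
  expect_identical(la$calls[1, , 2], c(0L, 2L))
  expect_identical(la$sites$pos, c(101L, 201L))
})

test_that("missing AN fields mark that site missing for that sample only", {
  vcf <- write_tsv_fixture(c(
    "##fileformat=VCFv4.2",
    "##ANCESTRY=<0=NAT,1=EUR,2=AFR>",
    "##contig=<ID=chr1,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=AN1,Number=1,Type=Integer,Description=\"a1\">",
    "##FORMAT=<ID=AN2,Number=1,Type=Integer,Description=\"a2\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t"),
    "chr1\t101\ts1\tA\tC\t.\tPASS\t.\tGT:AN1:AN2\t.:.:.\t0|0:2:2",
    "chr1\t201\ts2\tA\tC\t.\tPASS\t.\tGT:AN1:AN2\t0|0:1:0\t0|0:0:0"),
    path = tempfile(fileext = ".vcf"))
  la <- read_flare_vcf(vcf)
  expect_true(all(is.na(la$calls[1, 1, ])))
  expect_identical(la$calls[1, 2, ], c(1L, 0L))  # other site intact
  expect_identical(la$calls[2, 1, ], c(2L, 2L))  # other sample intact
})

test_that("read_flare_vcf validates codes, ordering and panel agreement", {
  mk <- function(records, anc = "##ANCESTRY=<0=NAT,1=EUR,2=AFR>") {
    write_tsv_fixture(c(
      "##fileformat=VCFv4.2", anc,
      "##contig=<ID=chr1,length=10000>",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
      "##FORMAT=<ID=AN1,Number=1,Type=Integer,Description=\"a1\">",
      "##FORMAT=<ID=AN2,Number=1,Type=Integer,Description=\"a2\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", "S1"), collapse = "\t"),
      records), path = tempfile(fileext = ".vcf"))
  }
  expect_error(read_flare_vcf(mk("chr1\t101\ts1\tA\tC\t.\tPASS\t.\tGT:AN1:AN2\t0|0:7:0")),
               "outside panel")
  expect_error(read_flare_vcf(mk(c(
    "chr1\t201\ts1\tA\tC\t.\tPASS\t.\tGT:AN1:AN2\t0|0:0:0",
    "chr1\t101\ts2\tA\tC\t.\tPASS\t.\tGT:AN1:AN2\t0|0:0:0"))),
    "unsorted")
  expect_error(read_flare_vcf(mk("chr1\t101\ts1\tA\tC\t.\tPASS\t.\tGT:AN1:AN2\t0|0:0:0"),
                              panel = ancestry_panel(c("X", "Y"))),
               "disagrees")
  # site-mask hook drops filtered sites
  la <- read_flare_vcf(mk(c(
    "chr1\t101\ts1\tA\tC\t.\tPASS\t.\tGT:AN1:AN2\t0|0:0:0",
    "chr1\t201\ts2\tA\tC\t.\tPASS\t.\tGT:AN1:AN2\t0|0:1:1")),
    site_filter = function(sites) sites$pos < 150)
  expect_identical(nrow(la$sites), 1L)
  expect_identical(la$calls[1, 1, ], c(0L, 0L))
})

test_that("gene containment uses 0-based half-open BED against 1-based positions", {
  # gene [100, 200) covers 0-based 100..199, i.e. 1-based positions
  # 101..200: pos 150 and 200 are inside, pos 100 is not
  calls <- array(0L, c(1, 3, 2))
  la <- tiny_la(calls, pos = c(100L, 150L, 200L))
  gi <- tiny_gene_index(la, list(geneA = c(100, 200)))
  expect_identical(gi$site_map$geneA, c(2L, 3L))
})

test_that("zero-site genes are recorded and nested genes share sites", {
  calls <- array(0L, c(1, 4, 2))
  la <- tiny_la(calls, pos = c(110L, 120L, 130L, 900L))
  gi <- tiny_gene_index(la, list(outer = c(100, 200), inner = c(115, 125),
                                 empty = c(300, 400)))
  expect_identical(gi$zero_site_genes, "empty")
  expect_identical(gi$site_map$outer, c(1L, 2L, 3L))
  expect_identical(gi$site_map$inner, 2L)  # site 120 belongs to both genes
  # multi-membership: total mapped sites >= sites covered by >= 1 gene
  covered <- length(unique(unlist(gi$site_map)))
  expect_gte(sum(lengths(gi$site_map)), covered)
})

test_that("read_gene_index validates ids and set relationships", {
  calls <- array(0L, c(1, 2, 2))
  la <- tiny_la(calls, pos = c(110L, 210L))
  bed <- write_tsv_fixture(c("chr1\t100\t200\tgeneA", "chr1\t200\t300\tgeneB"))
  dup_bed <- write_tsv_fixture(c("chr1\t100\t200\tgeneA", "chr1\t200\t300\tgeneA"))
  mk_sets <- function(rows) write_tsv_fixture(
    c("gene_id\tin_all\tin_oxphos\tin_high_mt\tin_low_mt", rows))
  ok <- mk_sets(c("geneA\t1\t1\t1\t0", "geneB\t1\t0\t0\t1"))
  gi <- read_gene_index(bed, ok, la)
  expect_identical(sort(gi$sets$all_mitonuclear), c("geneA", "geneB"))
  expect_identical(gi$genes$start, c(100L, 200L))  # BED 0-based preserved
  expect_error(read_gene_index(dup_bed, ok, la), "duplicate gene_id")
  expect_error(read_gene_index(bed, mk_sets("geneC\t1\t0\t0\t0"), la),
               "absent from BED.*geneC")
  expect_error(read_gene_index(bed, mk_sets(c("geneA\t0\t1\t0\t0",
                                              "geneB\t1\t0\t0\t0")), la),
               "oxphos")
  expect_error(read_gene_index(bed, mk_sets(c("geneA\t1\t0\t1\t1",
                                              "geneB\t1\t0\t0\t0")), la),
               "disjoint")
})

test_that("read_haplogroups returns records verbatim and flags problems", {
  p <- write_tsv_fixture(c("SampleID\tHaplogroup\tQuality",
                           "S1\tB2b\t0.9", "S2\tL1b1a\t0.8", "S3\t\t0.1"))
  h <- read_haplogroups(p)
  expect_identical(h$haplogroup[1:2], c("B2b", "L1b1a"))
  expect_identical(h$flagged, c(FALSE, FALSE, TRUE))
  dup <- write_tsv_fixture(c("SampleID\tHaplogroup", "S1\tB2b", "S1\tA2"))
  expect_error(read_haplogroups(dup), "duplicate sample")
  expect_error(read_haplogroups(write_tsv_fixture(c("a\tb", "1\t2"))),
               "SampleID and Haplogroup")
})

test_that("read_pairs verifies ids, drops unknowns with a warning", {
  p <- write_tsv_fixture(c("mother_id\toffspring_id", "M1\tO1", "M2\tOX"))
  expect_warning(pairs <- read_pairs(p, c("M1", "O1", "M2")), "unknown")
  expect_identical(pairs$mother_id, "M1")
  bad <- write_tsv_fixture(c("mother_id\toffspring_id", "M3\tM3"))
  expect_error(read_pairs(bad, "M3"), "equals")
})

test_that("every format round-trips bit-exactly through write and read", {
  co <- small_cohort(seed = 7, n = 8, n_pairs = 3, sites_per_gene = 4,
                     missing_rate = 0.05)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  rb <- read_cohort(d)
  expect_identical(rb$la$samples, co$la$samples)
  expect_identical(rb$la$sites$chrom, co$la$sites$chrom)
  expect_identical(rb$la$sites$pos, co$la$sites$pos)
  expect_identical(rb$la$calls, co$la$calls)
  expect_identical(rb$la$panel$names, co$la$panel$names)
  expect_identical(rb$gene_index$genes$gene_id, co$genes$gene_id)
  expect_identical(rb$gene_index$genes$start, as.integer(co$genes$start))
  expect_identical(rb$haplogroups$haplogroup, co$haplogroups$haplogroup)
  expect_identical(rb$pairs$mother_id, co$pairs$mother_id)
  expect_identical(rb$pairs$offspring_id, co$pairs$offspring_id)
})
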