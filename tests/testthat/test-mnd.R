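test_that("gene-wise MND counts per-haplotype calls", {
  # 3 sites in one gene; codes: NAT=0, EUR=1
  concordant <- array(0L, c(1, 3, 2))
  het <- array(c(0L, 0L, 0L, 1L, 1L, 1L), c(1, 3, 2))  # hap1 NAT, hap2 EUR
  discordant <- array(1L, c(1, 3, 2))
  gene <- list(geneA = c(100, 400))
  for (case in list(list(concordant, 0), list(het, 0.5), list(discordant, 1))) {
    la <- tiny_la(case[[1]])
    gi <- tiny_gene_index(la, gene)
    expect_equal(gene_wise_mnd(la, "S1", "geneA", gi, "NAT"), case[[2]])
  }
})

test_that("missing calls leave the denominator and zero-call genes are skipped", {
  calls <- array(c(1L, NA, NA, NA), c(1, 2, 2))  # site1: (1, NA); site2: (NA, NA)
  la <- tiny_la(calls)
  gi <- tiny_gene_index(la, list(gA = c(100, 150), gB = c(150, 300)))
  expect_equal(gene_wise_mnd(la, "S1", "gA", gi, "NAT"), 1)   # 1 of 1 calls
  expect_true(is.na(gene_wise_mnd(la, "S1", "gB", gi, "NAT")))
})

test_that("sample MND is the unweighted mean over genes with usable calls", {
  # gene A (5 sites): 2/10 calls mismatch -> 0.2; gene B (5 sites): 4/10 -> 0.4
  calls <- array(0L, c(1, 10, 2))
  calls[1, 1:2, 1] <- 1L           # gene A mismatches
  calls[1, 6:7, ] <- 1L            # gene B mismatches
  la <- tiny_la(calls)
  gi <- tiny_gene_index(la, list(gA = c(100, 600), gB = c(600, 1100)))
  assign <- data.frame(sample_id = "S1", haplogroup = "B2b",
                       macro = "B", mt_ancestry = "NAT")
  tab <- mnd_table(la, gi, assign, sets = "all_mitonuclear")
  expect_equal(tab$mean_mnd, 0.3)  # mean(0.2, 0.4), each gene one vote
  expect_identical(tab$n_genes_used, 2L)
  # knock out gene A entirely: mean falls back to the remaining gene
  calls2 <- calls; calls2[1, 1:5, ] <- NA
  la2 <- tiny_la(calls2)
  gi2 <- tiny_gene_index(la2, list(gA = c(100, 600), gB = c(600, 1100)))
  tab2 <- mnd_table(la2, gi2, assign, sets = "all_mitonuclear")
  expect_equal(tab2$mean_mnd, 0.4)
  expect_identical(tab2$n_genes_used, 1L)
})

test_that("vectorized gene-wise MND equals the naive per-call loop oracle", {
  co <- small_cohort(seed = 11, n = 20, n_genes = 25, sites_per_gene = 6,
                     missing_rate = 0.08)
  gi <- gene_index(co$genes, list(all_mitonuclear = co$genes$gene_id,
                                  oxphos = character(0),
                                  high_mt = character(0),
                                  low_mt = character(0)), co$la)
  mt <- stats::setNames(co$truth$mt_ancestry, co$truth$sample_id)
  fast <- gene_mnd_matrix(co$la, gi, mt)
  slow <- naive_gene_mnd(co$la, gi, mt)
  expect_identical(fast, slow)
})

test_that("UNMAPPED samples are excluded with a logged reason", {
  calls <- array(0L, c(2, 3, 2))
  la <- tiny_la(calls)
  gi <- tiny_gene_index(la, list(gA = c(100, 400)))
  assign <- data.frame(sample_id = c("S1", "S2"),
                       haplogroup = c("B2b", "Z9"),
                       macro = c("B", "Z"),
                       mt_ancestry = c("NAT", "UNMAPPED"))
  tab <- mnd_table(la, gi, assign, sets = "all_mitonuclear")
  expect_identical(unique(tab$sample_id), "S1")
  excl <- attr(tab, "exclusions")
  expect_identical(excl$sample_id, "S2")
  expect_match(excl$reason, "unmapped")
})

test_that("global ancestry matches a direct tally and behaves at the extremes", {
  co <- small_cohort(seed = 13, n = 10, missing_rate = 0.1)
  ga <- global_ancestry(co$la)
  for (i in c(1, 5, 10)) {
    v <- as.vector(co$la$calls[i, , ])
    v <- v[!is.na(v)]
    for (k in 0:2)
      expect_equal(ga[i, co$la$panel$names[k + 1]], mean(v == k))
  }
  expect_equal(rowSums(ga[, co$la$panel$names]), rep(1, 10),
               tolerance = 1e-12)
  # pure-ancestry individuals
  la1 <- tiny_la(array(1L, c(1, 4, 2)))
  g1 <- global_ancestry(la1)
  expect_equal(unlist(g1[, c("NAT", "EUR", "AFR")]), c(NAT = 0, EUR = 1, AFR = 0))
  la2 <- tiny_la(array(c(0L, 0L, 1L, 1L), c(1, 2, 2)))  # half NAT half EUR
  g2 <- global_ancestry(la2)
  expect_equal(g2$NAT, 0.5)
  expect_equal(g2$EUR, 0.5)
  la3 <- tiny_la(array(NA_integer_, c(1, 2, 2)))
  expect_error(global_ancestry(la3), "all calls missing")
})

test_that("global MND is one minus the matching component", {
  expect_equal(global_mnd(c(EUR = 0.55, NAT = 0.40, AFR = 0.05), "NAT"), 0.60)
  expect_equal(global_mnd(c(NAT = 1.0), "NAT"), 0)
  expect_equal(global_mnd(c(NAT = 0, AFR = 1.0), "NAT"), 1)
  expect_error(global_mnd(c(NAT = 0.5, EUR = 0.5), "AFR"), "not in panel")
  expect_error(global_mnd(c(NAT = 0.7, EUR = 0.7), "NAT"), "sum to 1")
})

test_that("delta MND follows the relative-change definition", {
  tab <- structure(data.frame(
    sample_id = c("M1", "O1", "M2", "O2", "M3", "O3", "M4", "O4"),
    gene_set = "all_mitonuclear",
    mean_mnd = c(0.5, 0.5, 0.4, 0.6, 0.6, 0.3, 0.0, 0.2),
    n_genes_used = 2L,
    mt_ancestry = "NAT"), class = c("mnd_table", "data.frame"))
  pairs <- data.frame(mother_id = c("M1", "M2", "M3", "M4"),
                      offspring_id = c("O1", "O2", "O3", "O4"),
                      cohort = "c")
  d <- delta_mnd(tab, pairs, "all_mitonuclear")
  expect_equal(d$delta, c(0, 0.5, -0.5))
  # zero-MND mother excluded, division undefined
  excl <- attr(d, "exclusions")
  expect_identical(excl$mother_id, "M4")
  expect_match(excl$reason, "zero")
  # identity: delta(m, m) = 0 exactly
  self <- delta_mnd(tab, data.frame(mother_id = "M2", offspring_id = "O2x",
                                    cohort = "c"), "all_mitonuclear")
  expect_identical(nrow(self), 0L)  # offspring missing -> excluded, not NA
})

test_that("MND stays in [0,1] and ignores site order within genes", {
  co <- small_cohort(seed = 17, n = 15, missing_rate = 0.05)
  gi <- gene_index(co$genes, list(all_mitonuclear = co$genes$gene_id,
                                  oxphos = character(0),
                                  high_mt = character(0),
                                  low_mt = character(0)), co$la)
  mt <- stats::setNames(co$truth$mt_ancestry, co$truth$sample_id)
  m <- gene_mnd_matrix(co$la, gi, mt)
  expect_true(all(m >= 0 & m <= 1, na.rm = TRUE))
  # permuting the site indices inside each gene leaves every value unchanged
  gi_perm <- gi
  set.seed(1)
  gi_perm$site_map <- lapply(gi$site_map, sample)
  expect_equal(gene_mnd_matrix(co$la, gi_perm, mt), m)
  # per-SNP majority collapse agrees with per-call counting when no call is
  # one-sided missing (ancestry-het sites count 0.5 either way)
  co2 <- small_cohort(seed = 18, n = 10)
  gi2 <- gene_index(co2$genes, list(all_mitonuclear = co2$genes$gene_id,
                                    oxphos = character(0),
                                    high_mt = character(0),
                                    low_mt = character(0)), co2$la)
  mt2 <- stats::setNames(co2$truth$mt_ancestry, co2$truth$sample_id)
  expect_equal(gene_mnd_matrix(co2$la, gi2, mt2, collapse = "per_snp"),
               gene_mnd_matrix(co2$la, gi2, mt2, collapse = "per_call"))
})

test_that("sample MND reduces to global MND for single-ancestry individuals", {
  # degenerate case: every call one ancestry -> gene-wise == global == MND
  calls <- array(1L, c(1, 10, 2))
  la <- tiny_la(calls)
  gi <- tiny_gene_index(la, list(gA = c(100, 600), gB = c(600, 1100)))
  assign <- data.frame(sample_id = "S1", haplogroup = "B2b",
                       macro = "B", mt_ancestry = "NAT")
  tab <- mnd_table(la, gi, assign, sets = "all_mitonuclear")
  gm <- global_mnd(global_ancestry(la, "S1"), "NAT")
  expect_equal(tab$mean_mnd, gm)
  expect_equal(gm, 1)
})
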