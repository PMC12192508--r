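#' Simulation configuration for a synthetic admixed cohort
#'
#' States the world the generator emulates: diploid individuals with
#' three-way (NAT/EUR/AFR) ancestry tracts laid down by the standard
#' Poisson admixture-tract approximation, maternally inherited mtDNA whose
#' ancestry is drawn from the individual's own ancestry proportions, and
#' mother-offspring pairs related by meiosis.
#'
#' Defaults are desk-scale: 50 individuals, 2 chromosomes of 1 Morgan
#' (mapped to 100 Mb each), 200 genes x 10 sites, 12 generations since
#' admixture (post-Columbian contact), and Dirichlet ancestry proportions
#' centered on a roughly half-Native American, half-European, low-African
#' admixed profile typical of Chilean cohorts.
#'
#' @param n_individuals Number of founder individuals.
#' @param n_pairs Number of mother-offspring pairs; the first `n_pairs`
#'   founders act as mothers and each offspring is appended as a new
#'   sample.
#' @param panel Population labels (see [ancestry_panel()]).
#' @param dirichlet_alpha Positive Dirichlet concentration per population;
#'   controls the spread of individual ancestry proportions.
#' @param generations Generations since admixture `g` (tract breakpoints
#'   arise at rate `g` per Morgan).
#' @param chromosomes `data.frame` with columns `name` and `morgans`
#'   (genetic length; physical length is `morgans * 1e8` bp).
#' @param n_genes,sites_per_gene Gene layout: genes are spaced evenly along
#'   chromosomes, each spanning `sites_per_gene` sites 100 bp apart.
#' @param mt_mode `"maternal_draw"` (mtDNA ancestry drawn from the
#'   individual's ancestry proportions, i.e. the maternal lineage is a
#'   random draw from the ancestry makeup) or `"fixed:<label>"`.
#' @param father_theta `"draw"` (father's ancestry proportions drawn from
#'   the same Dirichlet) or `"match"` (father's proportions equal the
#'   mother's -- useful for null expectations about intergenerational
#'   change).
#' @param missing_rate Probability that a sample x site record is missing
#'   (both haplotype calls dropped). Default 0.
#' @param seed Integer seed; the entire cohort is a deterministic function
#'   of the configuration and seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 50, n_pairs = 0,
                       panel = c("NAT", "EUR", "AFR"),
                       dirichlet_alpha = c(NAT = 4.5, EUR = 5.0, AFR = 0.5),
                       generations = 12,
                       chromosomes = data.frame(name = c("chr1", "chr2"),
                                                morgans = c(1, 1)),
                       n_genes = 200, sites_per_gene = 10,
                       mt_mode = "maternal_draw",
                       father_theta = c("draw", "match"),
                       missing_rate = 0, seed = NULL) {
  father_theta <- match.arg(father_theta)
  pn <- ancestry_panel(panel)
  alpha <- unlist(dirichlet_alpha)
  if (is.null(names(alpha))) names(alpha) <- pn$names
  if (!setequal(names(alpha), pn$names))
    abort_validation("dirichlet_alpha names must match the panel")
  alpha <- alpha[pn$names]
  if (any(alpha <= 0)) abort_validation("dirichlet_alpha must be > 0")
  if (generations < 1) abort_validation("generations must be >= 1")
  if (any(chromosomes$morgans <= 0))
    abort_validation("chromosome genetic lengths must be > 0")
  if (!identical(mt_mode, "maternal_draw") &&
      !startsWith(mt_mode, "fixed:"))
    abort_validation("mt_mode must be 'maternal_draw' or 'fixed:<label>'")
  if (startsWith(mt_mode, "fixed:")) {
    lab <- sub("^fixed:", "", mt_mode)
    if (!lab %in% pn$names)
      abort_validation(sprintf("fixed mt label '%s' not in panel", lab))
  }
  structure(list(n_individuals = n_individuals, n_pairs = n_pairs,
                 panel = pn, dirichlet_alpha = alpha,
                 generations = generations,
                 chromosomes = as.data.frame(chromosomes),
                 n_genes = n_genes, sites_per_gene = sites_per_gene,
                 mt_mode = mt_mode, father_theta = father_theta,
                 missing_rate = missing_rate, seed = seed),
            class = "sim_config")
}

# haplogroup labels consistent with each mtDNA ancestry; cosmetic strings
# chosen to exercise the macrohaplogroup rules (incl. the HV prefix case)
.hg_pools <- list(
  NAT = c("A2", "B2b", "C1b", "D1a"),
  EUR = c("H1a", "HV0a", "U5b", "T2b"),
  AFR = c("L1b1a", "L2a1", "L3e"))

.rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  stats::setNames(x / sum(x), names(alpha))
}

# deterministic gene/site layout from the config
.cohort_layout <- function(cfg) {
  chrs <- cfg$chromosomes
  per_chr <- diff(round(seq(0, cfg$n_genes, length.out = nrow(chrs) + 1)))
  genes <- list(); sites <- list()
  gidx <- 0L
  for (ci in seq_len(nrow(chrs))) {
    ng <- per_chr[ci]
    if (ng == 0) next
    phys_len <- chrs$morgans[ci] * 1e8
    spacing <- as.integer(phys_len %/% (ng + 1))
    width <- cfg$sites_per_gene * 100L
    start0 <- spacing * seq_len(ng)  # integer arithmetic: exact BED coords
    ids <- sprintf("gene%04d", gidx + seq_len(ng))
    gidx <- gidx + ng
    genes[[ci]] <- data.frame(gene_id = ids, chrom = chrs$name[ci],
                              start = start0, end = start0 + width,
                              stringsAsFactors = FALSE)
    pos <- as.integer(outer(100L * seq_len(cfg$sites_per_gene) - 50L, start0, `+`))
    pos <- sort(pos)
    sites[[ci]] <- data.frame(chrom = chrs$name[ci], pos = pos,
                              id = paste0(chrs$name[ci], "_", pos),
                              gpos = pos / phys_len * chrs$morgans[ci],
                              stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  sites <- do.call(rbind, sites)
  rownames(genes) <- rownames(sites) <- NULL
  list(genes = genes, sites = sites)
}

# gene-set memberships mirroring the relative sizes of the real resources
# (all mitonuclear 1035, OXPHOS 169, high-mt 167, low-mt 793); deterministic
.default_gene_sets <- function(gene_ids) {
  n <- length(gene_ids)
  n_ox <- max(1L, round(n * 169 / 1035))
  n_hi <- max(1L, round(n * 167 / 1035))
  n_lo <- max(1L, round(n * 793 / 1035))
  in_ox <- in_hi <- in_lo <- integer(n)
  in_ox[unique(round(seq(1, n, length.out = n_ox)))] <- 1L
  in_hi[seq_len(n_hi)] <- 1L
  in_lo[n_hi + seq_len(min(n_lo, n - n_hi))] <- 1L
  data.frame(gene_id = gene_ids, in_all = 1L, in_oxphos = in_ox,
             in_high_mt = in_hi, in_low_mt = in_lo,
             stringsAsFactors = FALSE)
}

#' Simulate one ancestry haplotype
#'
#' Tract breakpoints arise from a Poisson process of rate `g` per Morgan
#' along a chromosome; each tract's ancestry is drawn independently from
#' the individual's ancestry proportions `theta`. Sites inherit the
#' ancestry of the tract containing them.
#'
#' @param theta Probability vector over panel codes (in code order).
#' @param morgans Chromosome genetic length.
#' @param g Generations since admixture.
#' @return List with `breaks` (sorted breakpoint positions in Morgans) and
#'   `anc` (0-based ancestry code per tract, length `length(breaks) + 1`).
#' @export
simulate_haplotype <- function(theta, morgans, g) {
  stopifnot(abs(sum(theta) - 1) < 1e-9, all(theta >= 0))
  nb <- stats::rpois(1, g * morgans)
  breaks <- sort(stats::runif(nb, 0, morgans))
  anc <- sample.int(length(theta), nb + 1, replace = TRUE, prob = theta) - 1L
  list(breaks = breaks, anc = anc)
}

# ancestry codes of a haplotype at genetic positions
.hap_calls <- function(hap, gpos) {
  hap$anc[findInterval(gpos, hap$breaks) + 1L]
}

# meiosis: recombine two parental haplotypes (crossovers Poisson, rate 1
# per Morgan), returning a haplotype in the same representation
.splice_haplotypes <- function(hapA, hapB, morgans) {
  nxo <- stats::rpois(1, morgans)
  xo <- sort(stats::runif(nxo, 0, morgans))
  start <- sample.int(2L, 1)
  bounds <- sort(unique(c(hapA$breaks, hapB$breaks, xo)))
  mids <- (c(0, bounds) + c(bounds, morgans)) / 2
  phase <- (start - 1L + findInterval(mids, xo)) %% 2L  # 0 -> hapA
  anc <- ifelse(phase == 0L, .hap_calls(hapA, mids), .hap_calls(hapB, mids))
  # merge adjacent tracts with equal ancestry
  keep <- which(diff(anc) != 0)
  list(breaks = bounds[keep], anc = anc[c(keep, length(anc))])
}

# simulate one founder individual (two haplotypes per chromosome)
.simulate_individual <- function(cfg, layout, theta = NULL) {
  if (is.null(theta)) theta <- .rdirichlet1(cfg$dirichlet_alpha)
  haps <- lapply(seq_len(nrow(cfg$chromosomes)), function(ci) {
    L <- cfg$chromosomes$morgans[ci]
    list(simulate_haplotype(theta, L, cfg$generations),
         simulate_haplotype(theta, L, cfg$generations))
  })
  mt <- if (startsWith(cfg$mt_mode, "fixed:")) {
    sub("^fixed:", "", cfg$mt_mode)
  } else {
    cfg$panel$names[sample.int(length(theta), 1, prob = theta)]
  }
  pool <- .hg_pools[[mt]]
  if (is.null(pool)) pool <- paste0(substr(mt, 1, 1), "1")
  hg <- sample(pool, 1)
  list(theta = theta, haps = haps, mt_ancestry = mt, haplogroup = hg)
}

# offspring of a simulated mother and a (fresh) simulated father
.simulate_offspring <- function(mother, cfg, layout) {
  father_theta <- if (cfg$father_theta == "match") mother$theta else NULL
  father <- .simulate_individual(cfg, layout, theta = father_theta)
  haps <- lapply(seq_len(nrow(cfg$chromosomes)), function(ci) {
    L <- cfg$chromosomes$morgans[ci]
    list(.splice_haplotypes(mother$haps[[ci]][[1]], mother$haps[[ci]][[2]], L),
         .splice_haplotypes(father$haps[[ci]][[1]], father$haps[[ci]][[2]], L))
  })
  list(theta = (mother$theta + father$theta) / 2, haps = haps,
       mt_ancestry = mother$mt_ancestry,   # maternal inheritance
       haplogroup = mother$haplogroup,
       father_theta = father$theta)
}

# per-site calls (sites x 2) for an individual, given the layout
.individual_calls <- function(ind, cfg, layout) {
  chrs <- cfg$chromosomes$name
  calls <- matrix(NA_integer_, nrow(layout$sites), 2)
  for (ci in seq_along(chrs)) {
    on <- which(layout$sites$chrom == chrs[ci])
    if (!length(on)) next
    gpos <- layout$sites$gpos[on]
    calls[on, 1] <- .hap_calls(ind$haps[[ci]][[1]], gpos)
    calls[on, 2] <- .hap_calls(ind$haps[[ci]][[2]], gpos)
  }
  calls
}

#' Simulate a synthetic admixed cohort
#'
#' Generates founders and mother-offspring pairs under a [sim_config()],
#' returning the full in-memory model plus ground truth. Deterministic
#' given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_cohort`: list with `la` (a
#'   [local_ancestry()]), `genes`, `sets_df`, `haplogroups`, `pairs`,
#'   `truth` (per-sample true ancestry proportions, mtDNA ancestry,
#'   haplogroup, maternal link), `tracts` (one row per ancestry tract per
#'   haplotype, coordinates in Morgans), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  run <- function() .simulate_cohort_impl(config)
  if (!is.null(config$seed)) withr::with_seed(config$seed, run()) else run()
}

.simulate_cohort_impl <- function(cfg) {
  layout <- .cohort_layout(cfg)
  n_sites <- nrow(layout$sites)
  founders <- lapply(seq_len(cfg$n_individuals), function(i)
    .simulate_individual(cfg, layout))
  ids <- sprintf("F%03d", seq_len(cfg$n_individuals))
  inds <- founders
  roles <- rep("founder", cfg$n_individuals)
  mothers <- rep(NA_character_, cfg$n_individuals)
  pairs <- data.frame(mother_id = character(0), offspring_id = character(0),
                      cohort = character(0), stringsAsFactors = FALSE)
  if (cfg$n_pairs > 0) {
    if (cfg$n_pairs > cfg$n_individuals)
      abort_validation("n_pairs cannot exceed n_individuals")
    for (j in seq_len(cfg$n_pairs)) {
      off <- .simulate_offspring(founders[[j]], cfg, layout)
      inds <- c(inds, list(off))
      ids <- c(ids, sprintf("O%03d", j))
      roles <- c(roles, "offspring")
      mothers <- c(mothers, ids[j])
    }
    pairs <- data.frame(mother_id = ids[seq_len(cfg$n_pairs)],
                        offspring_id = sprintf("O%03d", seq_len(cfg$n_pairs)),
                        cohort = "sim", stringsAsFactors = FALSE)
  }
  calls <- array(NA_integer_, c(length(inds), n_sites, 2))
  for (i in seq_along(inds))
    calls[i, , ] <- .individual_calls(inds[[i]], cfg, layout)
  if (cfg$missing_rate > 0) {
    drop <- matrix(stats::runif(length(inds) * n_sites) < cfg$missing_rate,
                   length(inds), n_sites)
    calls[, , 1][drop] <- NA_integer_
    calls[, , 2][drop] <- NA_integer_
  }
  la <- local_ancestry(ids, layout$sites[, c("chrom", "pos", "id")], calls,
                       cfg$panel)
  theta_mat <- do.call(rbind, lapply(inds, `[[`, "theta"))
  truth <- data.frame(sample_id = ids, role = roles, mother_id = mothers,
                      theta_mat,
                      mt_ancestry = vapply(inds, `[[`, "", "mt_ancestry"),
                      haplogroup = vapply(inds, `[[`, "", "haplogroup"),
                      stringsAsFactors = FALSE, check.names = FALSE)
  names(truth)[3 + seq_along(cfg$panel$names)] <-
    paste0("theta_", cfg$panel$names)
  tracts <- do.call(rbind, lapply(seq_along(inds), function(i) {
    do.call(rbind, lapply(seq_len(nrow(cfg$chromosomes)), function(ci) {
      do.call(rbind, lapply(1:2, function(h) {
        hp <- inds[[i]]$haps[[ci]][[h]]
        b <- c(0, hp$breaks, cfg$chromosomes$morgans[ci])
        data.frame(sample_id = ids[i], chrom = cfg$chromosomes$name[ci],
                   haplotype = h, start_morgan = b[-length(b)],
                   end_morgan = b[-1],
                   ancestry = panel_name(cfg$panel, hp$anc),
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  rownames(tracts) <- NULL
  hap_df <- data.frame(sample_id = ids,
                       haplogroup = vapply(inds, `[[`, "", "haplogroup"),
                       stringsAsFactors = FALSE)
  structure(list(la = la, genes = layout$genes,
                 sets_df = .default_gene_sets(layout$genes$gene_id),
                 haplogroups = hap_df, pairs = pairs, truth = truth,
                 tracts = tracts, config = cfg),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d samples (%d pairs), %d genes, %d sites\n",
              length(x$la$samples), nrow(x$pairs), nrow(x$genes),
              nrow(x$la$sites)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits every format the pipeline readers consume -- FLARE-style VCF, gene
#' BED, gene-set TSV, Haplogrep-style haplogroup TSV, pairs TSV -- plus the
#' ground-truth tables (`truth.tsv`, `tracts.tsv`). Output is deterministic
#' given the simulation seed.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param outdir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir))
    stop(sprintf("cannot create output directory: %s", outdir))
  paths <- c(
    vcf = file.path(outdir, "cohort.vcf"),
    bed = file.path(outdir, "genes.bed"),
    sets = file.path(outdir, "gene_sets.tsv"),
    haplogroups = file.path(outdir, "haplogroups.tsv"),
    pairs = file.path(outdir, "pairs.tsv"),
    truth = file.path(outdir, "truth.tsv"),
    tracts = file.path(outdir, "tracts.tsv"))
  write_flare_vcf(cohort$la, paths[["vcf"]])
  write_gene_bed(cohort$genes, paths[["bed"]])
  write_gene_sets(cohort$sets_df, paths[["sets"]])
  write_haplogroups(cohort$haplogroups, paths[["haplogroups"]])
  write_pairs(cohort$pairs, paths[["pairs"]])
  data.table::fwrite(cohort$truth, paths[["truth"]], sep = "\t", eol = "\n")
  data.table::fwrite(cohort$tracts, paths[["tracts"]], sep = "\t", eol = "\n")
  invisible(paths)
}

#' Read a cohort directory back into the in-memory model
#'
#' Convenience wrapper around the individual readers, for directories laid
#' out by [write_cohort()] (or any directory using the same file names).
#'
#' @param dir Directory containing `cohort.vcf`, `genes.bed`,
#'   `gene_sets.tsv`, `haplogroups.tsv` and optionally `pairs.tsv`.
#' @param panel Optional panel override (see [read_flare_vcf()]).
#' @return List with `la`, `gene_index`, `haplogroups`, `pairs` (NULL if
#'   absent).
#' @export
read_cohort <- function(dir, panel = NULL) {
  la <- read_flare_vcf(file.path(dir, "cohort.vcf"), panel = panel)
  gi <- read_gene_index(file.path(dir, "genes.bed"),
                        file.path(dir, "gene_sets.tsv"), la)
  hg <- read_haplogroups(file.path(dir, "haplogroups.tsv"))
  pp <- file.path(dir, "pairs.tsv")
  pairs <- if (file.exists(pp)) read_pairs(pp, la$samples) else NULL
  list(la = la, gene_index = gi, haplogroups = hg, pairs = pairs)
}
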