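#' Pipeline run configuration
#'
#' Normalizes a configuration list (or JSON file) for the pipeline stages.
#' Recognized fields: input paths (`vcf`, `genes_bed`, `gene_sets_tsv`,
#'   `haplogroups_tsv`, `pairs_tsv`, `grouping_tsv`, `mnd_dir`), `out_dir`,
#' `gene_sets` (subset of all_mitonuclear/oxphos/high_mt/low_mt), `macros`
#' (optional macrohaplogroup restriction list), `collapse`
#' (per_call/per_snp), `haplogroup_config` (overrides for
#' [haplogroup_map()]), and stats options (`mode`, `effect`,
#' `variance_test`, `alpha`, `reference`).
#'
#' @param config A named list or path to a JSON file.
#' @return The normalized config list.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stopifnot(is.list(config))
  defaults <- list(gene_sets = NULL, macros = NULL, collapse = "per_call",
                   mode = "auto", effect = "rms", variance_test = "f",
                   alpha = 0.05, reference = NULL, haplogroup_config = NULL)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[k] <- defaults[k]
  config
}

.log <- function(fmt, ...) message(sprintf(fmt, ...))

# manifest: inputs, package version, config hash -- no timestamp, so reruns
# with identical inputs are byte-identical
.write_manifest <- function(config, out_dir, extra = list()) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, null = "null")
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- c(list(
    tool = "mndkit",
    version = as.character(utils::packageVersion("mndkit")),
    config = config,
    config_md5 = unname(tools::md5sum(tmp))), extra)
  unlink(tmp)
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

# shared input loading for compute/delta
.load_inputs <- function(config) {
  la <- read_flare_vcf(config$vcf)
  gi <- read_gene_index(config$genes_bed, config$gene_sets_tsv, la)
  hg <- read_haplogroups(config$haplogroups_tsv)
  map <- if (is.null(config$haplogroup_config)) haplogroup_map()
         else haplogroup_map_from_config(config$haplogroup_config)
  assign <- assign_mt_ancestry(hg, map, la$panel)
  n_before <- nrow(assign)
  macro_excl <- data.frame(sample_id = character(0), reason = character(0))
  if (!is.null(config$macros) && length(config$macros)) {
    kept <- restrict_to_macros(assign, unlist(config$macros))
    dropped <- setdiff(assign$sample_id, kept$sample_id)
    if (length(dropped))
      macro_excl <- data.frame(sample_id = dropped,
                               reason = "macrohaplogroup not in restriction list")
    assign <- kept
  }
  sets <- if (is.null(config$gene_sets)) names(gi$sets)
          else unlist(config$gene_sets)
  list(la = la, gi = gi, assign = assign, sets = sets,
       macro_excl = macro_excl, n_input = n_before)
}

#' Compute per-sample MND tables
#'
#' Pipeline stage: read inputs, assign mtDNA ancestry, optionally restrict
#' to a macrohaplogroup list, compute the gene-set-averaged MND table for
#' each requested gene set, and write one TSV per set plus an exclusion log
#' and a run manifest.
#'
#' @param config See [run_config()]. Required fields: `vcf`, `genes_bed`,
#'   `gene_sets_tsv`, `haplogroups_tsv`, `out_dir`.
#' @return Invisibly, a list with `mnd` (the combined [mnd_table()]),
#'   `paths`, and `exclusions`.
#' @export
run_compute <- function(config) {
  config <- run_config(config)
  inp <- .load_inputs(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- mnd_table(inp$la, inp$gi, inp$assign, sets = inp$sets,
                   collapse = config$collapse)
  excl <- rbind(inp$macro_excl, attr(tab, "exclusions"))
  if (nrow(tab) == 0) {
    brk <- table(excl$reason)
    abort_validation(paste0(
      "no samples survive MND computation; exclusions: ",
      paste(sprintf("%s (%d)", names(brk), brk), collapse = "; ")))
  }
  paths <- character(0)
  for (s in inp$sets) {
    p <- file.path(config$out_dir, sprintf("mnd_%s.tsv", s))
    data.table::fwrite(tab[tab$gene_set == s, , drop = FALSE], p,
                       sep = "\t", eol = "\n")
    paths[s] <- p
  }
  excl_path <- file.path(config$out_dir, "exclusions.tsv")
  data.table::fwrite(excl, excl_path, sep = "\t", eol = "\n")
  .write_manifest(config, config$out_dir,
                  extra = list(stage = "compute",
                               n_samples_in = inp$n_input,
                               n_samples_out = length(unique(tab$sample_id)),
                               n_excluded = length(unique(excl$sample_id))))
  .log("compute: %d samples in, %d with MND, %d excluded",
       inp$n_input, length(unique(tab$sample_id)),
       length(unique(excl$sample_id)))
  invisible(list(mnd = tab, paths = paths, exclusions = excl))
}

#' Compute intergenerational MND change for mother-offspring pairs
#'
#' @param config See [run_config()]; additionally requires `pairs_tsv`.
#' @return Invisibly, a list with `delta` (combined [delta_mnd()] rows over
#'   the requested gene sets), `paths`, and `exclusions`.
#' @export
run_delta <- function(config) {
  config <- run_config(config)
  if (is.null(config$pairs_tsv))
    abort_validation("run_delta requires a pairs_tsv input")
  inp <- .load_inputs(config)
  pairs <- read_pairs(config$pairs_tsv, inp$la$samples)
  if (nrow(pairs) == 0) abort_validation("no usable mother-offspring pairs")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- mnd_table(inp$la, inp$gi, inp$assign, sets = inp$sets,
                   collapse = config$collapse)
  paths <- character(0); all_delta <- list(); excl <- list()
  for (s in inp$sets) {
    d <- delta_mnd(tab, pairs, s)
    p <- file.path(config$out_dir, sprintf("delta_%s.tsv", s))
    data.table::fwrite(d, p, sep = "\t", eol = "\n")
    paths[s] <- p
    all_delta[[s]] <- d
    e <- attr(d, "exclusions")
    if (nrow(e)) excl[[s]] <- cbind(gene_set = s, e)
  }
  delta_all <- do.call(rbind, all_delta)
  if (nrow(delta_all) == 0) abort_validation("no pair retained for any gene set")
  excl_df <- if (length(excl)) do.call(rbind, excl)
             else data.frame(gene_set = character(0), mother_id = character(0),
                             offspring_id = character(0), reason = character(0))
  rownames(delta_all) <- rownames(excl_df) <- NULL
  data.table::fwrite(excl_df, file.path(config$out_dir, "delta_exclusions.tsv"),
                     sep = "\t", eol = "\n")
  .write_manifest(config, config$out_dir,
                  extra = list(stage = "delta", n_pairs_in = nrow(pairs),
                               n_pairs_out = nrow(all_delta[[1]])))
  .log("delta: %d pairs in, %d retained (first gene set)",
       nrow(pairs), nrow(all_delta[[1]]))
  invisible(list(delta = delta_all, paths = paths, exclusions = excl_df))
}

#' Run the cohort comparison layer on MND tables
#'
#' Reads per-gene-set MND TSVs (as written by [run_compute()]) and a
#' grouping TSV (`sample_id`, `group`), runs [compare_groups()] per gene
#' set, and writes a JSON report plus tidy TSVs per set.
#'
#' @param config See [run_config()]; requires `mnd_dir` (directory holding
#'   `mnd_<set>.tsv` files), `grouping_tsv` and `out_dir`.
#' @return Invisibly, a named list of `comparison_report` objects per gene
#'   set.
#' @export
run_compare <- function(config) {
  config <- run_config(config)
  if (is.null(config$mnd_dir) || is.null(config$grouping_tsv))
    abort_validation("run_compare requires mnd_dir and grouping_tsv")
  grouping <- data.table::fread(config$grouping_tsv, sep = "\t",
                                data.table = FALSE, colClasses = "character")
  if (!all(c("sample_id", "group") %in% names(grouping)))
    abort_validation("grouping TSV needs sample_id and group columns")
  sets <- config$gene_sets
  if (is.null(sets)) {
    files <- list.files(config$mnd_dir, pattern = "^mnd_.*\\.tsv$")
    sets <- sub("^mnd_(.*)\\.tsv$", "\\1", files)
  } else sets <- unlist(sets)
  if (!length(sets)) abort_validation("no MND tables found to compare")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  reports <- list()
  for (s in sets) {
    tab <- data.table::fread(file.path(config$mnd_dir,
                                       sprintf("mnd_%s.tsv", s)),
                             sep = "\t", data.table = FALSE)
    m <- merge(tab, grouping, by = "sample_id")
    if (length(unique(m$group)) < 2)
      abort_validation(sprintf("gene set %s: need >= 2 groups", s))
    rep <- compare_groups(m$mean_mnd, m$group, mode = config$mode,
                          effect = config$effect,
                          var_method = config$variance_test,
                          alpha = config$alpha,
                          reference = config$reference)
    reports[[s]] <- rep
    jsonlite::write_json(
      list(gene_set = s, summaries = rep$summaries, omnibus = rep$omnibus,
           pairwise = rep$pairwise, effects = rep$effects,
           variance_tests = rep$variance_tests, alpha = rep$alpha),
      file.path(config$out_dir, sprintf("compare_%s.json", s)),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    data.table::fwrite(rep$pairwise,
                       file.path(config$out_dir, sprintf("pairwise_%s.tsv", s)),
                       sep = "\t", eol = "\n")
    data.table::fwrite(rep$effects,
                       file.path(config$out_dir, sprintf("effects_%s.tsv", s)),
                       sep = "\t", eol = "\n")
    .log("compare[%s]: %s statistic=%.4g p=%.3g", s, rep$omnibus$name,
         rep$omnibus$statistic, rep$omnibus$p)
  }
  .write_manifest(config, config$out_dir,
                  extra = list(stage = "compare", gene_sets = sets))
  invisible(reports)
}

#' Run the simulate stage from a configuration
#'
#' @param config List or JSON path with [sim_config()] fields plus
#'   `out_dir`; `seed` is mandatory so runs are reproducible.
#' @return Invisibly, the written file paths.
#' @export
run_simulate <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (is.null(config$seed))
    abort_validation("simulate requires a seed (config field or --seed)")
  out_dir <- config$out_dir
  if (is.null(out_dir)) abort_validation("simulate requires out_dir")
  fields <- intersect(names(config), names(formals(sim_config)))
  cfg_args <- config[fields]
  if (!is.null(cfg_args$chromosomes))
    cfg_args$chromosomes <- as.data.frame(cfg_args$chromosomes)
  cfg <- do.call(sim_config, cfg_args)
  cohort <- simulate_cohort(cfg)
  paths <- write_cohort(cohort, out_dir)
  .write_manifest(config, out_dir,
                  extra = list(stage = "simulate", seed = config$seed,
                               n_samples = length(cohort$la$samples)))
  .log("simulate: wrote %d samples to %s", length(cohort$la$samples), out_dir)
  invisible(paths)
}

#' Command-line entry point
#'
#' Subcommands: `simulate | compute | delta | compare`, each driven by a
#' JSON configuration file (`--config`); `--seed` overrides the config
#' seed, `--out` the output directory. Returns (and, from the installed
#' `mnd-pipeline.R` script, exits with) 0 on success, 1 on validation
#' errors, 2 on runtime errors.
#'
#' @param args Character vector of command-line arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit code, invisibly.
#' @export
mnd_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: mnd-pipeline.R <simulate|compute|delta|compare> --config FILE [--seed N] [--out DIR]"
  if (length(args) < 1 || !args[1] %in%
      c("simulate", "compute", "delta", "compare")) {
    message(usage)
    return(invisible(1L))
  }
  sub <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--out", type = "character", default = NULL)))
  opts <- tryCatch(optparse::parse_args(parser, args = args[-1]),
                   error = function(e) NULL)
  if (is.null(opts) || is.null(opts$config)) {
    message(usage)
    return(invisible(1L))
  }
  status <- tryCatch({
    config <- jsonlite::read_json(opts$config, simplifyVector = TRUE)
    if (!is.null(opts$seed)) config$seed <- opts$seed
    if (!is.null(opts$out)) config$out_dir <- opts$out
    switch(sub,
           simulate = run_simulate(config),
           compute = run_compute(config),
           delta = run_delta(config),
           compare = run_compare(config))
    0L
  },
  mnd_validation_error = function(e) {
    message("validation error: ", conditionMessage(e)); 1L
  },
  error = function(e) {
    message("error: ", conditionMessage(e)); 2L
  })
  invisible(status)
}
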