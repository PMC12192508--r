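#' Ancestry panel
#'
#' A panel is the ordered set of source populations used for local-ancestry
#' inference. Codes are contiguous and 0-based, matching the integer codes
#' stored in local-ancestry VCF FORMAT fields.
#'
#' @param names Character vector of population labels (default
#'   `c("NAT", "EUR", "AFR")`: Native American, European, African).
#' @return An object of class `ancestry_panel` with elements `names`
#'   (labels, in code order) and `codes` (0-based integer codes).
#' @examples
#' p <- ancestry_panel()
#' panel_code(p, "EUR")
#' panel_name(p, 0L)
#' @export
ancestry_panel <- function(names = c("NAT", "EUR", "AFR")) {
  names <- as.character(names)
  if (length(names) < 2)
    abort_validation("an ancestry panel needs at least 2 populations")
  if (anyDuplicated(names))
    abort_validation("ancestry panel names must be unique")
  if (any(!nzchar(names)))
    abort_validation("ancestry panel names must be non-empty")
  structure(list(names = names, codes = seq_along(names) - 1L),
            class = "ancestry_panel")
}

#' @export
print.ancestry_panel <- function(x, ...) {
  cat("<ancestry_panel> ",
      paste(sprintf("%d=%s", x$codes, x$names), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname ancestry_panel
#' @param panel An `ancestry_panel`.
#' @param name Population label.
#' @export
panel_code <- function(panel, name) {
  i <- match(name, panel$names)
  if (anyNA(i))
    abort_validation(sprintf("label(s) not in panel: %s",
                             paste(name[is.na(i)], collapse = ", ")))
  panel$codes[i]
}

#' @rdname ancestry_panel
#' @param code 0-based integer ancestry code.
#' @export
panel_name <- function(panel, code) {
  i <- match(code, panel$codes)
  if (anyNA(i))
    abort_validation(sprintf("code(s) not in panel: %s",
                             paste(code[is.na(i)], collapse = ", ")))
  panel$names[i]
}

#' Local-ancestry call matrix
#'
#' In-memory model of per-haplotype local-ancestry calls: an
#' `n_samples x n_sites x 2` integer array of panel codes, `NA` marking
#' missing calls, plus site coordinates and the ancestry panel.
#'
#' @param samples Character vector of sample ids (unique, ordered).
#' @param sites `data.frame` with columns `chrom`, `pos` (1-based), `id`,
#'   sorted by (`chrom`, `pos`) with strictly increasing positions within
#'   each chromosome.
#' @param calls Integer array of dim `c(n_samples, n_sites, 2)` holding
#'   panel codes per haplotype; `NA` = missing.
#' @param panel An [ancestry_panel()].
#' @return An object of class `local_ancestry`.
#' @export
local_ancestry <- function(samples, sites, calls, panel) {
  samples <- as.character(samples)
  if (anyDuplicated(samples))
    abort_validation("duplicate sample ids in local-ancestry matrix")
  sites <- as.data.frame(sites)
  stopifnot(all(c("chrom", "pos", "id") %in% names(sites)))
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  sites$id <- as.character(sites$id)
  if (nrow(sites) > 0 && any(sites$pos < 1L))
    abort_validation("site positions must be >= 1 (1-based VCF coordinates)")
  .check_sorted_sites(sites)
  calls <- array(as.integer(calls), dim = dim(calls))
  if (length(dim(calls)) != 3L ||
      dim(calls)[1] != length(samples) ||
      dim(calls)[2] != nrow(sites) ||
      dim(calls)[3] != 2L)
    abort_validation("calls must be an n_samples x n_sites x 2 array")
  bad <- setdiff(unique(as.vector(calls)), c(panel$codes, NA))
  if (length(bad))
    abort_validation(sprintf("ancestry code outside panel: %s",
                             paste(bad, collapse = ", ")))
  structure(list(samples = samples, sites = sites, calls = calls,
                 panel = panel),
            class = "local_ancestry")
}

.check_sorted_sites <- function(sites) {
  if (nrow(sites) < 2) return(invisible(TRUE))
  same_chrom <- sites$chrom[-1] == sites$chrom[-nrow(sites)]
  inc <- diff(sites$pos) > 0
  if (any(same_chrom & !inc))
    abort_validation("unsorted sites: positions must be strictly increasing within chromosome")
  # a chromosome must not reappear after another chromosome intervened
  r <- rle(sites$chrom)
  if (anyDuplicated(r$values))
    abort_validation("unsorted sites: chromosome blocks are not contiguous")
  invisible(TRUE)
}

#' @export
print.local_ancestry <- function(x, ...) {
  cat(sprintf("<local_ancestry> %d samples x %d sites x 2 haplotypes (%s)\n",
              length(x$samples), nrow(x$sites),
              paste(x$panel$names, collapse = "/")))
  nmiss <- sum(is.na(x$calls))
  if (nmiss > 0) cat(sprintf("  missing calls: %d\n", nmiss))
  invisible(x)
}

#' @export
dim.local_ancestry <- function(x) dim(x$calls)

# condition helpers: validation errors map to CLI exit code 1
abort_validation <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("mnd_validation_error", "error", "condition"),
                 list(message = msg, call = call)))
}

is_validation_error <- function(e) inherits(e, "mnd_validation_error")
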