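#' Macrohaplogroup rules and ancestry mapping
#'
#' Full mtDNA haplogroup labels (e.g. `"B2b"`, `"L1b1a"`) are collapsed to
#' single-token macrohaplogroups by longest-prefix matching, with the
#' leading alphabetic character as fallback; macrohaplogroups are then
#' mapped to continental ancestry labels. Defaults follow the standard
#' mtDNA phylogeography: A-D are the Native American founding lineages, L
#' is the African macrolineage, and the common West-Eurasian branches
#' (H, HV, V, J, T, U, K, N, R, W, I, X) map to European. Haplogroup X is
#' geographically ambiguous (it occurs both in Europe and, as X2a, in
#' North America); the default maps it to EUR and can be overridden.
#'
#' A prefix rule ranked by length means `"HV0a"` collapses to `"HV"`, not
#' `"H"` -- pure first-letter truncation would misclassify the macro token.
#'
#' @param prefix_rules Named character vector, `prefix -> macro token`.
#' @param ancestry_map Named character vector, `macro token -> ancestry
#'   label` (labels should belong to the analysis panel). Macros absent
#'   from the map resolve to `"UNMAPPED"`.
#' @return An object of class `haplogroup_map`.
#' @examples
#' m <- haplogroup_map()
#' to_macro(c("B2b", "L1b1a", "HV0a"), m)
#' macro_ancestry(c("B", "L", "Z"), m)
#' @export
haplogroup_map <- function(prefix_rules = NULL, ancestry_map = NULL) {
  default_rules <- c(
    HV = "HV",
    A = "A", B = "B", C = "C", D = "D", L = "L",
    H = "H", V = "V", J = "J", T = "T", U = "U", K = "K",
    N = "N", R = "R", W = "W", I = "I", X = "X")
  default_anc <- c(
    A = "NAT", B = "NAT", C = "NAT", D = "NAT",
    L = "AFR",
    H = "EUR", HV = "EUR", V = "EUR", J = "EUR", T = "EUR", U = "EUR",
    K = "EUR", N = "EUR", R = "EUR", W = "EUR", I = "EUR", X = "EUR")
  if (is.null(prefix_rules)) prefix_rules <- default_rules
  if (is.null(ancestry_map)) ancestry_map <- default_anc
  prefix_rules <- unlist(prefix_rules)
  ancestry_map <- unlist(ancestry_map)
  if (anyDuplicated(names(prefix_rules)))
    abort_validation("duplicate prefixes in haplogroup prefix rules")
  structure(list(prefix_rules = prefix_rules, ancestry_map = ancestry_map),
            class = "haplogroup_map")
}

#' @rdname haplogroup_map
#' @param config A list (or path to a JSON file) with optional elements
#'   `prefix_rules` and `ancestry_map` overriding the defaults.
#' @export
haplogroup_map_from_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config)
  haplogroup_map(prefix_rules = config$prefix_rules,
                 ancestry_map = config$ancestry_map)
}

#' Collapse haplogroup strings to macrohaplogroups
#'
#' The longest matching prefix rule wins; haplogroups matching no rule fall
#' back to their leading alphabetic character. All L lineages (L0-L6)
#' collapse to `"L"` under the default rules.
#'
#' @param haplogroup Character vector of haplogroup labels (non-empty).
#' @param map A [haplogroup_map()].
#' @return Character vector of macrohaplogroup tokens.
#' @export
to_macro <- function(haplogroup, map = haplogroup_map()) {
  haplogroup <- as.character(haplogroup)
  if (any(is.na(haplogroup) | !nzchar(haplogroup)))
    abort_validation("empty haplogroup string")
  prefixes <- names(map$prefix_rules)
  ord <- order(nchar(prefixes), decreasing = TRUE)  # longest prefix first
  vapply(haplogroup, function(h) {
    for (i in ord) if (startsWith(h, prefixes[i])) return(map$prefix_rules[[i]])
    sub("^([A-Za-z]).*$", "\\1", h)
  }, character(1), USE.NAMES = FALSE)
}

#' Map macrohaplogroups to continental ancestry labels
#'
#' @param macro Character vector of macro tokens from [to_macro()].
#' @param map A [haplogroup_map()].
#' @return Character vector of ancestry labels; macros not covered by the
#'   map yield `"UNMAPPED"` (a value, not an error -- such samples are
#'   excluded from MND with a logged reason downstream).
#' @export
macro_ancestry <- function(macro, map = haplogroup_map()) {
  out <- unname(map$ancestry_map[macro])
  out[is.na(out)] <- "UNMAPPED"
  out
}

#' Assign mtDNA ancestry to samples
#'
#' Combines [to_macro()] and [macro_ancestry()] over a haplogroup table and
#' checks the resulting labels against the analysis panel.
#'
#' @param haplogroups `data.frame` from [read_haplogroups()] (columns
#'   `sample_id`, `haplogroup`).
#' @param map A [haplogroup_map()].
#' @param panel An [ancestry_panel()]; mapped labels outside the panel are
#'   demoted to `"UNMAPPED"`.
#' @return `data.frame` with `sample_id`, `haplogroup`, `macro`,
#'   `mt_ancestry`.
#' @export
assign_mt_ancestry <- function(haplogroups, map = haplogroup_map(),
                               panel = ancestry_panel()) {
  flagged <- if (!is.null(haplogroups$flagged)) haplogroups$flagged
             else !nzchar(haplogroups$haplogroup)
  macro <- rep(NA_character_, nrow(haplogroups))
  macro[!flagged] <- to_macro(haplogroups$haplogroup[!flagged], map)
  anc <- rep("UNMAPPED", nrow(haplogroups))
  anc[!flagged] <- macro_ancestry(macro[!flagged], map)
  anc[!anc %in% c(panel$names, "UNMAPPED")] <- "UNMAPPED"
  data.frame(sample_id = haplogroups$sample_id,
             haplogroup = haplogroups$haplogroup,
             macro = macro, mt_ancestry = anc,
             stringsAsFactors = FALSE)
}

#' Restrict samples to a set of macrohaplogroups
#'
#' Typical use is focusing an analysis on the Native American founding
#' lineages A-D, mirroring haplogroup-stratified cohort comparisons.
#'
#' @param assignments `data.frame` from [assign_mt_ancestry()].
#' @param allowed Character vector of macro tokens to keep.
#' @return The subset of `assignments` whose `macro` is in `allowed`, in the
#'   original order. Warns if empty.
#' @export
restrict_to_macros <- function(assignments, allowed) {
  out <- assignments[assignments$macro %in% allowed, , drop = FALSE]
  if (nrow(out) == 0)
    warning("no samples left after macrohaplogroup restriction")
  rownames(out) <- NULL
  out
}
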