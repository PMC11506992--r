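# Internal helpers: error conditions and chromosome ordering.

# Condition constructors. Every user-facing failure is signalled with one of
# these classes so callers (and the CLI exit-code mapping) can dispatch on it.
gt_abort <- function(msg, class, ...) {
  abort(msg, class = c(class, "genotracks_error"), ...)
}

gt_schema_error <- function(msg, ...) gt_abort(msg, "gt_schema_error", ...)
gt_value_error <- function(msg, ...) gt_abort(msg, "gt_value_error", ...)
gt_config_error <- function(msg, ...) gt_abort(msg, "gt_config_error", ...)
gt_nothing_to_plot <- function(msg = "nothing to plot: no features retained after filtering") {
  gt_abort(msg, "gt_nothing_to_plot")
}
gt_io_error <- function(msg, ...) gt_abort(msg, "gt_io_error", ...)

#' Natural ordering of chromosome identifiers
#'
#' Orders chromosome ids the way genome figures are read: ids that look like
#' numbers sort numerically ("2" before "10", so chromosome 0 — the
#' conventional bin for unplaced markers — comes first), and any remaining
#' ids (e.g. "X", "scaffold_12") follow in lexicographic order.
#'
#' @param ids Character vector of chromosome identifiers.
#' @return `ids` sorted into natural order, duplicates removed.
#' @examples
#' chrom_sort(c("10", "2", "X", "0"))
#' @export
chrom_sort <- function(ids) {
  ids <- unique(as.character(ids))
  num <- suppressWarnings(as.numeric(ids))
  numeric_ids <- ids[!is.na(num)][order(num[!is.na(num)])]
  other_ids <- sort(ids[is.na(num)])
  c(numeric_ids, other_ids)
}

# Factor with natural chromosome ordering, used for facet ordering.
chrom_factor <- function(x, levels = NULL) {
  factor(as.character(x), levels = levels %||% chrom_sort(x))
}

# Coerce x to a flat list of feature tables; accepts a single table, a list,
# or nested lists. NULLs dropped.
flatten_tables <- function(x) {
  if (is.null(x)) return(list())
  if (is_feature_table(x) || is.data.frame(x)) return(list(x))
  out <- list()
  for (el in x) out <- c(out, flatten_tables(el))
  out
}
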