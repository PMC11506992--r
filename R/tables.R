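# Input table validation and normalisation.
#
# Four table kinds are supported, each with its own mandatory columns:
#   gwas       chromosome, position, and score and/or padj
#   de         chromosome, start, end, score and/or padj,
#              log2FoldChange and/or foldChange
#   candidate  chromosome, start, end, name
#   custom     chromosome, position, score (plus an aes_type tag)
# Column names are case-sensitive. Any other column is preserved untouched
# and ignored by all computations, so users can keep metadata joined in.

TABLE_KINDS <- c("gwas", "de", "candidate", "custom")

new_feature_table <- function(df, kind, label = NULL, aes_type = NULL,
                              threshold = NULL) {
  out <- as_tibble(df)
  attr(out, "gt_kind") <- kind
  attr(out, "gt_label") <- label
  attr(out, "gt_aes_type") <- aes_type
  attr(out, "gt_threshold") <- threshold
  class(out) <- c("feature_table", class(out))
  out
}

#' Test for / inspect validated feature tables
#'
#' `is_feature_table()` reports whether an object has been through
#' [validate_table()]. `table_kind()`, `table_label()` and `table_aes_type()`
#' read back the track kind, display label and (for custom tracks) the
#' aesthetics tag attached at validation time.
#'
#' @param x An object.
#' @return `is_feature_table()`: a logical scalar; the accessors: a character
#'   scalar or `NULL`.
#' @export
is_feature_table <- function(x) inherits(x, "feature_table")

#' @rdname is_feature_table
#' @export
table_kind <- function(x) attr(x, "gt_kind")

#' @rdname is_feature_table
#' @export
table_label <- function(x) attr(x, "gt_label")

#' @rdname is_feature_table
#' @export
table_aes_type <- function(x) attr(x, "gt_aes_type")

# Per-track significance threshold (set by the polyploid-GWAS bridge).
table_threshold <- function(x) attr(x, "gt_threshold")

#' @export
print.feature_table <- function(x, ...) {
  kind <- table_kind(x)
  lbl <- table_label(x)
  cat("# Feature table [", kind, "]",
      if (!is.null(lbl)) paste0(" \"", lbl, "\""),
      if (!is.null(table_aes_type(x))) paste0(" (aes_type: ", table_aes_type(x), ")"),
      if (!is.null(table_threshold(x))) paste0(" (threshold: ", format(table_threshold(x)), ")"),
      "\n", sep = "")
  NextMethod()
}

mandatory_columns <- function(kind) {
  switch(kind,
    gwas = list(fixed = c("chromosome", "position"),
                either = list(c("score", "padj"))),
    de = list(fixed = c("chromosome", "start", "end"),
              either = list(c("score", "padj"), c("log2FoldChange", "foldChange"))),
    candidate = list(fixed = c("chromosome", "start", "end", "name"),
                     either = list()),
    custom = list(fixed = c("chromosome", "position", "score"),
                  either = list())
  )
}

#' Validate and normalise an input feature table
#'
#' Checks that a raw table of genomic features carries the mandatory columns
#' for its kind, then derives the normalised quantities every downstream step
#' works from:
#'
#' * a resolved `score` (GWAS, DE, custom): an existing `score` column is used
#'   as-is and any `padj` column is then ignored; otherwise the score is
#'   computed as \eqn{-\log_{10}(padj)} (see [resolve_score()]);
#' * a resolved `log2FoldChange` (DE): an existing `log2FoldChange` column
#'   takes precedence over `foldChange` (see [resolve_log2fc()]);
#' * a plotting `position` for interval features (DE, candidate): the
#'   half-way point between `start` and `end` (see [gene_midpoint()]). Any
#'   pre-existing `position` column on these kinds is overwritten, since
#'   `start`/`end` are the mandatory source of truth.
#'
#' All schema problems in a table (every missing mandatory column) are
#' collected and reported together, the way a user fixes a CSV. Row order is
#' preserved; columns the package does not use are kept untouched and ignored.
#' Validation is idempotent: re-validating a validated table is a no-op.
#' Duplicate records are kept (both are plotted).
#'
#' @param data A data frame (e.g. read from CSV with a header row; missing
#'   values as empty fields or "NA").
#' @param kind One of `"gwas"`, `"de"`, `"candidate"`, `"custom"`.
#' @param label Optional display name for the track this table becomes.
#' @param aes_type For `kind = "custom"`: the tag linking this table to a
#'   [track_aes()] entry. Falls back to an `aes_type` attribute on `data`.
#' @return A `feature_table`: a tibble with the derived columns above and the
#'   kind/label/aes_type recorded as attributes.
#' @examples
#' validate_table(
#'   data.frame(chromosome = "1", position = c(100, 250), padj = c(0.04, 0.9)),
#'   kind = "gwas"
#' )
#' @export
validate_table <- function(data, kind, label = NULL, aes_type = NULL) {
  if (!is.data.frame(data)) {
    gt_schema_error("`data` must be a data frame with named columns")
  }
  kind <- as.character(kind)
  if (length(kind) != 1 || !kind %in% TABLE_KINDS) {
    gt_config_error(paste0("`kind` must be one of: ",
                           paste(TABLE_KINDS, collapse = ", ")))
  }
  label <- label %||% table_label(data)
  if (kind == "custom") {
    aes_type <- aes_type %||% table_aes_type(data) %||% attr(data, "aes_type")
    if (is.null(aes_type) || length(aes_type) != 1 || is.na(aes_type)) {
      gt_schema_error("custom tables require a single `aes_type` tag")
    }
  }

  # Collect all missing-column problems before failing.
  req <- mandatory_columns(kind)
  problems <- character()
  for (col in req$fixed) {
    if (!col %in% names(data)) {
      problems <- c(problems, paste0("missing mandatory column `", col,
                                     "` for kind \"", kind, "\""))
    }
  }
  for (pair in req$either) {
    if (!any(pair %in% names(data))) {
      problems <- c(problems, paste0("need at least one of `",
                                     paste(pair, collapse = "`, `"),
                                     "` for kind \"", kind, "\""))
    }
  }
  if (length(problems) > 0) {
    gt_schema_error(c("invalid input table", setNames(problems, rep("x", length(problems)))))
  }

  df <- as_tibble(data)
  df$chromosome <- as.character(df$chromosome)

  check_numeric <- function(col) {
    v <- df[[col]]
    if (is.character(v) || is.factor(v)) {
      conv <- suppressWarnings(as.numeric(as.character(v)))
      if (any(!is.na(v) & is.na(conv))) {
        gt_value_error(paste0("column `", col, "` is not numeric (rows: ",
                              paste(head(which(!is.na(v) & is.na(conv)), 5), collapse = ", "), ")"))
      }
      v <- conv
    }
    if (!is.numeric(v)) gt_value_error(paste0("column `", col, "` is not numeric"))
    if (any(v < 0, na.rm = TRUE)) {
      gt_value_error(paste0("column `", col, "` contains negative positions (rows: ",
                            paste(head(which(v < 0), 5), collapse = ", "), ")"))
    }
    v
  }

  if (kind %in% c("gwas", "custom")) df$position <- check_numeric("position")
  if (kind %in% c("de", "candidate")) {
    df$start <- check_numeric("start")
    df$end <- check_numeric("end")
    bad <- which(!is.na(df$start) & !is.na(df$end) & df$end < df$start)
    if (length(bad) > 0) {
      gt_value_error(paste0("`end` < `start` on rows: ",
                            paste(head(bad, 5), collapse = ", ")))
    }
    df$position <- gene_midpoint(df$start, df$end)
  }

  if (kind %in% c("gwas", "de", "custom")) {
    score_in <- if ("score" %in% names(df)) df[[c("score")]] else NULL
    padj_in <- if ("padj" %in% names(df)) df[["padj"]] else NULL
    if (kind == "gwas" && !is.null(score_in) &&
        any(score_in < 0, na.rm = TRUE)) {
      gt_value_error("GWAS `score` must be non-negative (it is a -log10 p-value)")
    }
    df$score <- resolve_score(score_in %||% NA_real_, padj_in %||% NA_real_)
  }
  if (kind == "de") {
    l2fc <- if ("log2FoldChange" %in% names(df)) df[["log2FoldChange"]] else NULL
    fc <- if ("foldChange" %in% names(df)) df[["foldChange"]] else NULL
    df$log2FoldChange <- resolve_log2fc(l2fc %||% NA_real_, fc %||% NA_real_)
  }
  if (kind == "candidate" && "name" %in% names(df)) {
    df$name <- as.character(df$name)
  }

  new_feature_table(df, kind, label = label, aes_type = aes_type,
                    threshold = table_threshold(data))
}

#' @rdname validate_table
#' @export
as_gwas_table <- function(data, label = NULL) validate_table(data, "gwas", label = label)

#' @rdname validate_table
#' @export
as_de_table <- function(data, label = NULL) validate_table(data, "de", label = label)

#' @rdname validate_table
#' @export
as_candidate_table <- function(data, label = NULL) validate_table(data, "candidate", label = label)

#' @rdname validate_table
#' @export
as_custom_table <- function(data, aes_type = NULL, label = NULL) {
  validate_table(data, "custom", label = label, aes_type = aes_type)
}

#' Resolve a significance score from a score and/or adjusted p-value
#'
#' A feature's score is \eqn{-\log_{10}} of its (adjusted) p-value; higher
#' means more significant. When a score is supplied it is used unchanged and
#' the adjusted p-value is ignored; otherwise the score is computed from
#' `padj`. An adjusted p-value of exactly 0 resolves to `Inf`: such features
#' always pass thresholds, and colour scales cap at the largest finite score
#' so they render at the top of the gradient. `padj = 0.05` resolves to about
#' 1.3 and `padj = 1e-4` to 4 — the usual reference thresholds.
#'
#' @param score Numeric vector of scores, `NA` where absent.
#' @param padj Numeric vector of adjusted p-values in \[0, 1\], `NA` where
#'   absent. Values outside \[0, 1\] are an error.
#' @return Numeric vector of resolved scores (`NA` where neither is present).
#' @examples
#' resolve_score(NA, 0.05)
#' resolve_score(2.7, 0.05) # padj ignored
#' @export
resolve_score <- function(score, padj) {
  n <- max(length(score), length(padj))
  score <- rep_len(as.numeric(score %||% NA_real_), n)
  padj <- rep_len(as.numeric(padj %||% NA_real_), n)
  bad <- which(!is.na(padj) & (padj < 0 | padj > 1))
  if (length(bad) > 0) {
    gt_value_error(paste0("`padj` outside [0, 1] (rows: ",
                          paste(head(bad, 5), collapse = ", "), ")"))
  }
  out <- ifelse(!is.na(score), score,
                ifelse(!is.na(padj), -log10(padj), NA_real_))
  as.numeric(out)
}

#' Resolve a log2 fold-change from log2 and/or linear fold-change
#'
#' A supplied `log2FoldChange` is used unchanged and `foldChange` is then
#' ignored; otherwise the log2 fold-change is computed as
#' \eqn{\log_2(foldChange)}. A linear fold-change must be positive when used.
#'
#' @param log2FoldChange Numeric vector, `NA` where absent.
#' @param foldChange Positive numeric vector, `NA` where absent.
#' @return Numeric vector of resolved log2 fold-changes.
#' @examples
#' resolve_log2fc(NA, 2) # 1
#' resolve_log2fc(-0.5, 8) # foldChange ignored
#' @export
resolve_log2fc <- function(log2FoldChange, foldChange) {
  n <- max(length(log2FoldChange), length(foldChange))
  l2 <- rep_len(as.numeric(log2FoldChange %||% NA_real_), n)
  fc <- rep_len(as.numeric(foldChange %||% NA_real_), n)
  used <- is.na(l2) & !is.na(fc)
  bad <- which(used & fc <= 0)
  if (length(bad) > 0) {
    gt_value_error(paste0("`foldChange` must be positive (rows: ",
                          paste(head(bad, 5), collapse = ", "), ")"))
  }
  as.numeric(ifelse(!is.na(l2), l2, ifelse(!is.na(fc), log2(fc), NA_real_)))
}

#' Plotting position of an interval feature
#'
#' Interval features (genes, regions) are drawn at the half-way point between
#' their start and end positions: `(start + end) / 2`, kept fractional.
#'
#' @param start,end Numeric base-pair coordinates with `end >= start >= 0`.
#' @return Numeric midpoint positions.
#' @examples
#' gene_midpoint(100, 200)
#' gene_midpoint(1, 2) # 1.5, not rounded
#' @export
gene_midpoint <- function(start, end) {
  n <- max(length(start), length(end))
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  bad <- which(!is.na(start) & !is.na(end) & end < start)
  if (length(bad) > 0) {
    gt_value_error(paste0("`end` < `start` on rows: ",
                          paste(head(bad, 5), collapse = ", ")))
  }
  (start + end) / 2
}
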