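test_that("mandatory columns are enforced per kind, reported together", {
  # GWAS with only padj is valid: score resolved from the adjusted p-value.
  tb <- validate_table(gwas_df(), "gwas")
  expect_s3_class(tb, "feature_table")
  expect_equal(tb$score, c(-log10(0.05), 4, 0))

  # DE without any fold-change column is a schema error naming the columns.
  expect_error(
    validate_table(data.frame(chromosome = "1", start = 1, end = 2, score = 1), "de"),
    class = "gt_schema_error"
  )
  expect_error(
    validate_table(data.frame(chromosome = "1", position = 1), "gwas"),
    regexp = "score.*padj", class = "gt_schema_error"
  )
  # All missing columns reported at once, not fail-fast.
  err <- tryCatch(validate_table(data.frame(x = 1), "de"), condition = identity)
  msg <- paste(conditionMessage(err), collapse = " ")
  for (col in c("chromosome", "start", "end")) expect_match(msg, col)

  # Extra columns are preserved untouched and ignored.
  can <- can_df()
  can$source <- c("lit", "lit")
  tb <- validate_table(can, "candidate")
  expect_equal(tb$source, c("lit", "lit"))
})

test_that("value errors flag bad coordinates and ranges with row indices", {
  bad <- data.frame(chromosome = "1", start = c(10, 50), end = c(20, 40),
                    name = "g")
  expect_error(validate_table(bad, "candidate"), regexp = "2",
               class = "gt_value_error")
  expect_error(
    validate_table(data.frame(chromosome = "1", position = "abc", score = 1), "gwas"),
    class = "gt_value_error"
  )
  expect_error(
    validate_table(data.frame(chromosome = "1", position = -5, score = 1), "gwas"),
    class = "gt_value_error"
  )
  expect_error(resolve_score(NA, 1.5), class = "gt_value_error")
  expect_error(resolve_score(NA, -0.1), class = "gt_value_error")
  expect_error(resolve_log2fc(NA, -2), class = "gt_value_error")
})

test_that("score resolution: precedence, -log10 transform, padj = 0", {
  expect_equal(resolve_score(NA, 0.05), 1.30103, tolerance = 1e-5)
  expect_equal(resolve_score(NA, 1), 0)
  expect_equal(resolve_score(2.7, 0.05), 2.7) # padj ignored when score given
  expect_equal(resolve_score(NA, 1e-4), 4)
  expect_identical(resolve_score(NA, 0), Inf)
  expect_true(is.na(resolve_score(NA, NA)))
})

test_that("log2 fold-change resolution: precedence and log2 transform", {
  expect_equal(resolve_log2fc(NA, 2), 1)
  expect_equal(resolve_log2fc(NA, 1), 0)
  expect_equal(resolve_log2fc(-0.5, 8), -0.5) # foldChange ignored
  expect_true(is.na(resolve_log2fc(NA, NA)))
})

test_that("interval features sit at their fractional midpoint", {
  expect_equal(gene_midpoint(100, 200), 150)
  expect_equal(gene_midpoint(7, 7), 7)
  expect_equal(gene_midpoint(1, 2), 1.5)
  expect_error(gene_midpoint(10, 5), class = "gt_value_error")

  tb <- validate_table(de_df(), "de")
  expect_true(all(tb$start <= tb$position & tb$position <= tb$end))
  expect_equal(tb$log2FoldChange, c(1, 0))
})

test_that("validation is idempotent and survives a CSV round-trip", {
  for (args in list(list(gwas_df(), "gwas"), list(de_df(), "de"),
                    list(can_df(), "candidate"))) {
    once <- validate_table(args[[1]], args[[2]])
    twice <- validate_table(once, args[[2]])
    expect_equal(as.data.frame(twice), as.data.frame(once))
  }
  tb <- validate_table(de_df(), "de")
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tb, path, na = "NA")
  back <- validate_table(readr::read_csv(path, show_col_types = FALSE), "de")
  expect_equal(back$score, tb$score)
  expect_equal(back$position, tb$position)
  expect_equal(back$log2FoldChange, tb$log2FoldChange)
})

test_that("resolved score is monotone decreasing in the adjusted p-value", {
  padj <- sort(runif(50, 1e-8, 1))
  expect_true(all(diff(resolve_score(NA, padj)) <= 0))
})

test_that("custom tables need exactly one aes_type tag", {
  expect_s3_class(validate_table(custom_df(), "custom"), "feature_table")
  expect_equal(table_aes_type(validate_table(custom_df(), "custom")), "qtl")
  df <- custom_df()
  attr(df, "aes_type") <- NULL
  expect_error(validate_table(df, "custom"), class = "gt_schema_error")
  # explicit argument overrides the attribute
  expect_equal(table_aes_type(validate_table(df, "custom", aes_type = "dmr")), "dmr")
})
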