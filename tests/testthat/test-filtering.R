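test_that("threshold filtering keeps scores >= threshold and drops missing", {
  tb <- as_gwas_table(data.frame(
    chromosome = "1", position = 1:5 * 10,
    score = c(0.5, 1.3, 2.0, NA, 4.0)
  ))
  out <- apply_threshold(tb, score_thr = 1.3)
  expect_equal(out$score, c(1.3, 2.0, 4.0)) # boundary value retained
  expect_equal(out$position, c(20, 30, 50)) # order preserved

  # Zero thresholds keep everything with non-missing values.
  de <- as_de_table(data.frame(chromosome = "1", start = 1:4, end = 2:5,
                               score = c(1, 2, NA, 3),
                               log2FoldChange = c(-1, 0, 1, NA)))
  out <- apply_threshold(de, score_thr = 0, log2fc_thr = 0)
  expect_equal(nrow(out), 2)

  # DE: |log2fc| thresholding is symmetric in sign.
  out <- apply_threshold(de, score_thr = 0, log2fc_thr = 1)
  expect_equal(out$log2FoldChange, -1)

  # Empty in, empty out.
  expect_equal(nrow(apply_threshold(tb[0, ], 1)), 0)

  # Candidate tables pass through unfiltered; log2fc_thr is DE-only.
  can <- as_candidate_table(can_df())
  expect_identical(apply_threshold(can, 100), can)
  expect_error(apply_threshold(tb, 1, log2fc_thr = 1), class = "gt_config_error")
})

test_that("filtering is monotone, idempotent, and a subset of the input", {
  sim <- tiny_sim()
  tb <- as_gwas_table(sim$gwas)
  thresholds <- c(0, 0.5, 1.3, 2, 4, 6, 10)
  counts <- vapply(thresholds, function(t) nrow(apply_threshold(tb, t)), integer(1))
  expect_true(all(diff(counts) <= 0))
  for (t in c(1.3, 4)) {
    once <- apply_threshold(tb, t)
    expect_identical(as.data.frame(apply_threshold(once, t)), as.data.frame(once))
    # subset: every retained row exists in the input, unmodified
    expect_true(all(once$position %in% tb$position))
    expect_equal(once$score, tb$score[match(once$position, tb$position)])
  }
  # Infinite scores (padj = 0) always pass.
  inf_tb <- as_gwas_table(data.frame(chromosome = "1", position = 1, padj = 0))
  expect_equal(nrow(apply_threshold(inf_tb, 1e6)), 1)
})

test_that("chromosome lengths equal the brute-force per-chromosome maximum", {
  gwas <- as_gwas_table(data.frame(chromosome = "chr1",
                                   position = c(10, 500), score = 1))
  de <- as_de_table(data.frame(chromosome = "chr1", start = 700, end = 750,
                               score = 1, log2FoldChange = 1))
  len <- compute_chrom_length(list(gwas, de))
  expect_equal(len$length, 750) # max over {10, 500, 750}

  single <- as_gwas_table(data.frame(chromosome = "9", position = 1234, score = 1))
  expect_equal(compute_chrom_length(single)$length, 1234)

  sim <- tiny_sim()
  tbls <- list(as_gwas_table(sim$gwas), as_de_table(sim$de),
               as_candidate_table(sim$candidates))
  len <- compute_chrom_length(tbls)
  brute <- tapply(
    c(sim$gwas$position, sim$de$end, sim$candidates$end),
    c(sim$gwas$chromosome, sim$de$chromosome, sim$candidates$chromosome),
    max
  )
  expect_equal(len$length, as.numeric(brute[len$chromosome]))
  # natural chromosome order: "2" before "10"
  expect_equal(len$chromosome, as.character(sort(as.integer(len$chromosome))))

  expect_error(compute_chrom_length(list(single[0, ])), class = "gt_value_error")
})

test_that("user-supplied lengths override inferred ones for listed chromosomes", {
  tb <- as_gwas_table(data.frame(chromosome = c("1", "2"),
                                 position = c(100, 200), score = 1))
  len <- compute_chrom_length(tb, lengths = c("1" = 1000))
  expect_equal(len$length[len$chromosome == "1"], 1000)
  expect_equal(len$length[len$chromosome == "2"], 200)
  # chromosomes only listed by the user are included
  len <- compute_chrom_length(tb, lengths = c("3" = 500))
  expect_true("3" %in% len$chromosome)
  # a length shorter than the data warns but is honoured
  expect_warning(len <- compute_chrom_length(tb, lengths = c("1" = 50)))
  expect_equal(len$length[len$chromosome == "1"], 50)
})

test_that("chromosome limits crop to a closed window and warn on unknown ids", {
  tb <- as_gwas_table(data.frame(chromosome = "5",
                                 position = c(2e6, 2.1e6, 2.5e6, 3e6),
                                 score = 5))
  out <- apply_chrom_limits(tb, list("5" = c(2e6, 2.5e6)))
  expect_equal(out$position, c(2e6, 2.1e6, 2.5e6)) # boundaries retained

  # empty limits = identity; [0, length] = identity
  expect_identical(apply_chrom_limits(tb, NULL), tb)
  expect_identical(
    as.data.frame(apply_chrom_limits(tb, list("5" = c(0, 3e6)))),
    as.data.frame(tb)
  )
  expect_warning(apply_chrom_limits(tb, list("99" = c(1, 2))),
                 regexp = "unknown")
  expect_error(as_chrom_limits(list("5" = c(10, 5))), class = "gt_value_error")

  # property: after cropping, every position on a limited chromosome is inside
  sim <- tiny_sim()
  lim <- list("3" = c(29e6, 31e6), "7" = c(9e6, 11e6))
  out <- apply_chrom_limits(as_gwas_table(sim$gwas), lim)
  for (ch in names(lim)) {
    pos <- out$position[out$chromosome == ch]
    expect_true(all(pos >= lim[[ch]][1] & pos <= lim[[ch]][2]))
  }
})

test_that("empty chromosomes are dropped exactly when no track retains a record", {
  sim <- tiny_sim()
  g <- apply_threshold(as_gwas_table(sim$gwas), 4)
  len <- compute_chrom_length(as_gwas_table(sim$gwas))
  trimmed <- remove_empty_chromosomes(list(g), len)
  expect_setequal(trimmed$lengths$chromosome, unique(g$chromosome))

  # every chromosome occupied -> identity
  all_len <- compute_chrom_length(as_gwas_table(sim$gwas))
  keep_all <- remove_empty_chromosomes(list(as_gwas_table(sim$gwas)), all_len)
  expect_equal(keep_all$lengths, all_len)

  # no retained features anywhere -> empty lengths, layout then refuses
  none <- remove_empty_chromosomes(list(g[0, ]), len)
  expect_equal(nrow(none$lengths), 0)
  expect_error(build_plot_spec(list(g[0, ]), lengths = len),
               class = "gt_nothing_to_plot")
})

test_that("lengths and limits round-trip through their file formats", {
  dir <- withr::local_tempdir()
  readr::write_csv(data.frame(chromosome = c("1", "2"), length = c(100, 200)),
                   file.path(dir, "len.csv"))
  expect_equal(read_chrom_lengths(file.path(dir, "len.csv"))$length, c(100, 200))

  jsonlite::write_json(list("5" = c(2e6, 2.5e6)), file.path(dir, "lim.json"))
  lim <- read_chrom_limits(file.path(dir, "lim.json"))
  expect_equal(lim$min, 2e6)
  readr::write_csv(data.frame(chromosome = "5", min = 1, max = 10),
                   file.path(dir, "lim.csv"))
  expect_equal(read_chrom_limits(file.path(dir, "lim.csv"))$max, 10)
  expect_error(read_chrom_lengths(file.path(dir, "nope.csv")),
               class = "gt_io_error")
})
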