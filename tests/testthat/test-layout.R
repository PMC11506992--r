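test_that("one facet per chromosome, one track per table, one point per record", {
  gwas <- as_gwas_table(data.frame(chromosome = c("1", "2"),
                                   position = c(100, 900), score = c(5, 6)))
  de <- as_de_table(data.frame(chromosome = c("1", "2"), start = c(10, 20),
                               end = c(30, 40), score = 2, log2FoldChange = 1))
  can <- as_candidate_table(data.frame(chromosome = "1", start = 50, end = 60,
                                       name = "geneA"))
  spec <- build_plot_spec(list(gwas, de, can))
  g <- glance(spec)
  expect_equal(g$n_facets, 2)
  expect_equal(g$n_tracks, 3)
  expect_equal(g$n_points, nrow(gwas) + nrow(de) + nrow(can))
  expect_equal(g$n_guide_lines, g$n_points)

  # track order top to bottom: GWAS, DE, candidate
  ord <- spec$tracks$kind[order(-spec$tracks$y)]
  expect_equal(ord, c("gwas", "de", "candidate"))

  # every point x inside its facet range; every guide line x is a point x
  rng <- spec$facets[match(spec$points$chromosome, spec$facets$chromosome), ]
  expect_true(all(spec$points$x >= rng$xmin & spec$points$x <= rng$xmax))
  expect_setequal(spec$guide_lines$x, spec$points$x)
})

test_that("track stacking covers multiple tables per kind and custom placement", {
  g1 <- as_gwas_table(data.frame(chromosome = "1", position = 1, score = 5),
                      label = "trait one")
  g2 <- as_gwas_table(data.frame(chromosome = "1", position = 2, score = 5),
                      label = "trait two")
  cus <- as_custom_table(data.frame(chromosome = "1", position = 3, score = 5),
                         aes_type = "qtl")
  can <- as_candidate_table(data.frame(chromosome = "1", start = 4, end = 6,
                                       name = "g"))
  spec <- build_plot_spec(list(can, cus, g1, g2),
                          custom_aes = list(qtl = track_aes(y_label = "QTL")))
  expect_equal(spec$tracks$label[order(-spec$tracks$y)],
               c("trait one", "trait two", "QTL", "Candidate genes"))
  # two GWAS tracks share one score family / colour scale
  expect_equal(sum(names(spec$scales) == "gwas"), 1)
  expect_setequal(names(spec$scales), c("gwas", "qtl", "candidate"))
})

test_that("candidate labels appear only for non-missing names", {
  can <- as_candidate_table(data.frame(
    chromosome = "1", start = c(10, 5000), end = c(20, 6000),
    name = c("geneA", NA)
  ))
  spec <- build_plot_spec(list(can))
  expect_equal(glance(spec)$n_points, 2) # the unnamed point is still drawn
  expect_equal(spec$labels$text, "geneA")
})

test_that("unknown aes_type and empty input are rejected", {
  cus <- as_custom_table(data.frame(chromosome = "1", position = 1, score = 5),
                         aes_type = "mystery")
  expect_error(build_plot_spec(list(cus)), regexp = "mystery",
               class = "gt_config_error")
  g <- as_gwas_table(data.frame(chromosome = "1", position = 1, score = 5))
  expect_error(build_plot_spec(list(g[0, ])), class = "gt_nothing_to_plot")
})

test_that("the plot spec is deterministic and JSON-serialisable", {
  sim <- tiny_sim()
  build <- function() {
    genome_tracks(gwas = sim$gwas, de = sim$de, candidates = sim$candidates,
                  custom = sim$custom, custom_aes = sim_custom_aes())
  }
  s1 <- build()
  s2 <- build()
  expect_identical(s1, s2)
  expect_identical(as.character(plot_spec_json(s1)),
                   as.character(plot_spec_json(s2)))
  js <- jsonlite::fromJSON(plot_spec_json(s1))
  expect_equal(nrow(js$points), glance(s1)$n_points)
})

test_that("label placement is deterministic, in-range and pairwise disjoint", {
  # two labels at the same anchor stay visible and disjoint
  two <- place_labels(data.frame(x = c(100, 100), text = c("geneA", "geneB")),
                      xlim = c(0, 1000), band = c(1.1, 1.45))
  expect_equal(nrow(two), 2)
  expect_true(abs(two$label_x[1] - two$label_x[2]) >= (two$width[1] + two$width[2]) / 2 ||
                abs(two$label_y[1] - two$label_y[2]) >= two$height[1] * 0.999)
  expect_equal(two$x, c(100, 100)) # anchors untouched

  # single label: zero displacement; zero labels: empty placement
  one <- place_labels(data.frame(x = 500, text = "g"), xlim = c(0, 1000))
  expect_equal(one$label_x, 500)
  expect_equal(nrow(place_labels(data.frame(x = numeric(), text = character()),
                                 xlim = c(0, 1))), 0)
  expect_error(place_labels(data.frame(x = 2, text = "g"), xlim = c(0, 1)),
               class = "gt_value_error")

  # property: many clustered labels -> all placed boxes pairwise disjoint,
  # inside the axis range, and identical across repeated runs
  labs <- data.frame(x = rep(c(100, 105, 110, 500), each = 4),
                     text = paste0("gene_", 1:16))
  p1 <- suppressWarnings(place_labels(labs, xlim = c(0, 1000)))
  p2 <- suppressWarnings(place_labels(labs, xlim = c(0, 1000)))
  expect_identical(p1, p2)
  expect_true(all(p1$label_x - p1$width / 2 >= 0 & p1$label_x + p1$width / 2 <= 1000))
  if (nrow(p1) > 1) {
    for (i in seq_len(nrow(p1) - 1)) {
      for (j in seq(i + 1, nrow(p1))) {
        x_apart <- abs(p1$label_x[i] - p1$label_x[j]) >=
          (p1$width[i] + p1$width[j]) / 2 * 0.999
        y_apart <- abs(p1$label_y[i] - p1$label_y[j]) >= p1$height[i] * 0.999
        expect_true(x_apart || y_apart)
      }
    }
  }
})

test_that("DE points can be coloured by log2 fold-change", {
  de <- as_de_table(data.frame(chromosome = "1", start = c(1, 10),
                               end = c(2, 20), score = c(5, 6),
                               log2FoldChange = c(-2, 3)))
  spec <- build_plot_spec(list(de), colour_de_by_log2fc = TRUE)
  expect_setequal(spec$points$value, c(-2, 3))
  expect_equal(spec$scales$de$domain, c(-2, 3))
})

test_that("infinite scores cap at the finite maximum of their colour scale", {
  g <- as_gwas_table(data.frame(chromosome = "1", position = c(1, 2, 3),
                                padj = c(0, 1e-6, 0.5)))
  spec <- build_plot_spec(list(g))
  expect_equal(spec$scales$gwas$domain[2], 6)
  expect_equal(max(spec$points$value), 6) # Inf capped, record kept
  expect_equal(glance(spec)$n_points, 3)
})
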