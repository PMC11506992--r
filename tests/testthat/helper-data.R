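# Shared fixtures, built in code.

# Small, fast simulation used by most tests.
tiny_sim <- function(seed = 11, ...) {
  simulate_dataset(sim_config(n_markers = 600, n_genes = 250,
                              n_candidates = 8, seed = seed, ...))
}

# Hand-written four-kind tables with known values.
gwas_df <- function() {
  data.frame(chromosome = c("1", "1", "2"),
             position = c(100, 500, 250),
             padj = c(0.05, 1e-4, 1))
}

de_df <- function() {
  data.frame(chromosome = c("1", "2"),
             start = c(100, 7), end = c(200, 7),
             score = c(2, 0.5), foldChange = c(2, 1))
}

can_df <- function() {
  data.frame(chromosome = c("1", "2"), start = c(1, 10), end = c(2, 20),
             name = c("geneA", NA))
}

custom_df <- function() {
  df <- data.frame(chromosome = "1", position = c(10, 20), score = c(3, 1))
  attr(df, "aes_type") <- "qtl"
  df
}
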