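# Shared fixtures: scenarios are built once per test run and cached.

.scenario_cache <- new.env(parent = emptyenv())

# Default scenario (seed 1) with reads: the deterministic world the
# repeat-recovery and variant tests run on.
default_scenario <- function() {
  if (is.null(.scenario_cache$default)) {
    .scenario_cache$default <- build_scenario(scenario_config(seed = 1))
  }
  .scenario_cache$default
}

# Small, fast scenario configuration for parameterised runs.
small_config <- function(seed = 1, copy_number = 3, ...) {
  lead_copies <- max(1, copy_number - 1)
  scenario_config(
    seed = seed, host_length = 60000, n_host_contigs = 12,
    bgc_length = 6000, bgc_copy_number = copy_number,
    leading_segment_length = 600, leading_segment_copies = lead_copies,
    depth = 30,
    n_genes = c(annotated = 10, hypothetical = 10, pseudogene = 6,
                ribosomal = 8, bgc = 12),
    ...)
}

# Lightweight gene records from the gene layer (no contig placement).
gene_layer_records <- function(config) {
  gl <- simulate_gene_set(config)
  lapply(seq_len(nrow(gl$genes)), function(i) {
    gene_record(gl$genes$gene_id[i], "unplaced", 1,
                nchar(gl$genes$cds_seq[i]), "+", gl$genes$category[i],
                cds_seq = gl$genes$cds_seq[i])
  })
}

# TRUE when Tukey flags bgc against every other category.
bgc_flagged_vs_all <- function(contrast) {
  tb <- contrast$tukey
  rows <- tb$category_a == "bgc" | tb$category_b == "bgc"
  all(tb$different[rows])
}

# Random DNA string helper for IO round-trips.
rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
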