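# synthetic_data: generator determinism, depth/GC statistical structure,
# read simulation arithmetic, homolog-table fabrication.

test_that("build_scenario is byte-identical for a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  build_scenario(small_config(seed = 42), outdir = d1)
  build_scenario(small_config(seed = 42), outdir = d2)
  for (f in c("assembly.fasta", "genome_expanded.fasta", "genes.gff3",
              "reads.sam", "reads_R1.fastq", "homologs.tsv",
              "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("host depth and BGC depth ratio match the configured world", {
  sc <- default_scenario()
  cfg <- sc$config
  host_depths <- vapply(sc$contigs[sc$truth$host_contigs], function(ct)
    mean(contig_coverage(sc$pairs, ct)), numeric(1))
  expect_true(all(abs(host_depths - cfg$depth) / cfg$depth < 0.05))
  bgc <- sc$contigs[[sc$truth$bgc_contig]]
  body <- depth_summary(sc$pairs, bgc,
                        region = c(cfg$leading_segment_length + 1,
                                   bgc$length))
  ratio <- body$mean_depth / median(host_depths)
  expect_lt(abs(ratio - cfg$bgc_copy_number), 0.3)
  lead <- depth_summary(sc$pairs, bgc,
                        region = c(1, cfg$leading_segment_length))
  expect_lt(abs(lead$mean_depth / median(host_depths) -
                  cfg$leading_segment_copies), 0.3)
})

test_that("generated host contigs sit at the configured GC", {
  sc <- default_scenario()
  host_seq <- paste(vapply(sc$contigs[sc$truth$host_contigs], `[[`,
                           character(1), "seq"), collapse = "")
  expect_lt(abs(gc_fraction(host_seq) - sc$config$host_gc), 0.01)
  expect_lt(abs(gc_fraction(sc$contigs[["bgc_1"]]$seq) -
                  sc$config$bgc_gc), 0.015)
})

test_that("gene categories carry the designed GC and codon structure", {
  sc <- default_scenario()
  gdf <- genes_as_df(sc$genes, seqs = TRUE)
  mean_gc <- function(cat) {
    mean(vapply(gdf$cds_seq[gdf$category == cat], gc_fraction, numeric(1)))
  }
  expect_lt(abs(mean_gc("bgc") - sc$config$bgc_gc), 0.02)
  expect_lt(abs(mean_gc("ribosomal") - sc$config$host_gc), 0.02)
  expect_lt(abs(mean_gc("annotated") - sc$config$host_gc), 0.02)
  # pseudogenes are truncated: lengths not all multiples of 3
  pl <- nchar(gdf$cds_seq[gdf$category == "pseudogene"])
  fl <- gdf$cds_seq[gdf$category == "annotated"]
  expect_true(all(nchar(fl) %% 3 == 0))
  expect_lt(median(pl) / median(nchar(fl)), 0.7)
})

test_that("simulate_read_pairs count and degenerate inputs follow contract", {
  set.seed(5)
  ct <- contig("r1", rand_seq(10000))
  sim <- simulate_read_pairs(list(ct), read_length = 100,
                             insert_mean = 250, insert_sd = 20,
                             depth = 10, seed = 3)
  expect_equal(nrow(sim), 500L)  # 10 * 10000 / (2 * 100)
  expect_true(all(sim$frag_start >= 1 &
                    sim$frag_start + sim$frag_len - 1 <= 10000))

  expect_warning(empty <- simulate_read_pairs(list(), depth = 10),
                 "empty genome")
  expect_equal(nrow(empty), 0L)

  short <- contig("tiny", rand_seq(100))
  expect_warning(sim2 <- simulate_read_pairs(list(short), read_length = 100,
                                             insert_mean = 250, depth = 5),
                 "skipped")
  expect_equal(nrow(sim2), 0L)
  expect_error(simulate_read_pairs(list(ct), read_length = 300,
                                   insert_mean = 250, depth = 5),
               "insert_mean")
  expect_error(simulate_read_pairs(list(ct), depth = -1), "depth")
})

test_that("junction-spanning fragments map mates onto different contigs", {
  sc <- default_scenario()
  cross <- sc$pairs[sc$pairs$contig1 != sc$pairs$contig2, ]
  expect_gt(nrow(cross), 0)
  expect_true(any(cross$contig1 == "bgc_1" | cross$contig2 == "bgc_1"))
})

test_that("injected variants surface at the expected allele fraction", {
  sc <- default_scenario()
  v <- pileup_variants(sc$pairs, sc$contigs[["bgc_1"]],
                       copies = sc$truth$copy_number)
  truth <- sc$truth$variants
  snps <- truth[truth$type == "SNP", ]
  for (i in seq_len(nrow(snps))) {
    call <- v[v$pos == snps$pos[i] & v$type == "SNP", ]
    expect_equal(nrow(call), 1L)
    expected <- snps$n_copies[i] / sc$truth$copy_number
    n <- call$ad_ref + call$ad_alt
    se <- sqrt(expected * (1 - expected) / n)
    expect_lt(abs(call$alt_fraction - expected), 3 * se)
  }
})

test_that("make_homolog_table encodes truth in length ratios", {
  sc <- default_scenario()
  tab <- sc$homologs
  pseudo <- tab$gene_id %in% sc$truth$pseudogene_ids
  ratio <- tab$gene_aa_length / tab$homolog_aa_length
  expect_true(all(ratio[pseudo] < 0.8))
  expect_true(all(abs(ratio[pseudo] -
                        sc$truth$truncation_fraction) < 0.05))
  expect_true(all(ratio[!pseudo] > 0.88 & ratio[!pseudo] < 1.14))
  empty <- make_homolog_table(data.frame(gene_id = character(0),
                                         cds_seq = character(0)),
                              list(pseudogene_ids = character(0),
                                   truncation_fraction = 0.5))
  expect_equal(nrow(empty), 0L)
})

test_that("scenario_config validates variant specs and geometry", {
  expect_error(scenario_config(insertion_specs = data.frame(
    pos = 10^7, seq = "AAA", copies = "2")), "outside BGC")
  expect_error(scenario_config(depth = 0), "depth")
  expect_error(scenario_config(leading_segment_copies = 5,
                               bgc_copy_number = 3))
  expect_error(build_scenario(scenario_config(bgc_copy_number = 8)),
               "host contigs")
})
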