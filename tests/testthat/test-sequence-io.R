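# sequence_io: FASTA / GFF3+categories / SAM / GFA readers and writers.

test_that("read_fasta parses records, uppercases, joins wrapped lines", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1", "acgt"), p)
  ctgs <- read_fasta(p)
  expect_length(ctgs, 1L)
  expect_equal(ctgs[["c1"]]$seq, "ACGT")
  expect_equal(ctgs[["c1"]]$length, 4L)

  writeLines(c(">c1 some description", "AC", "GT"), p)
  ctgs <- read_fasta(p)
  expect_equal(names(ctgs), "c1")
  expect_equal(ctgs[["c1"]]$seq, "ACGT")
})

test_that("read_fasta handles degenerate and malformed input", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), p)
  expect_warning(ctgs <- read_fasta(p), "empty")
  expect_length(ctgs, 0L)

  writeLines(c("ACGT", ">c1", "ACGT"), p)
  expect_error(read_fasta(p), "line 1")
  expect_error(read_fasta("/nonexistent/x.fa"), "no such file")
})

test_that("FASTA round-trip preserves ids and sequences", {
  set.seed(11)
  ctgs <- lapply(1:5, function(i)
    contig(paste0("ctg", i), rand_seq(50 + 37 * i)))
  p <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(ctgs, p)
  back <- read_fasta(p)
  expect_equal(vapply(back, `[[`, character(1), "id"),
               vapply(ctgs, `[[`, character(1), "id"),
               ignore_attr = TRUE)
  expect_equal(vapply(back, `[[`, character(1), "seq"),
               vapply(ctgs, `[[`, character(1), "seq"),
               ignore_attr = TRUE)
})

test_that("read_gff_genes extracts strand-corrected CDS and categories", {
  ct <- contig("c1", "ATGAAATTTGGG")
  gff <- withr::local_tempfile(fileext = ".gff3")
  cat_tab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("##gff-version 3",
               "c1\tx\tCDS\t1\t6\t.\t+\t0\tID=g1",
               "c1\tx\tCDS\t1\t6\t.\t-\t0\tID=g2"), gff)
  writeLines(c("g1\tannotated", "g2\tribosomal"), cat_tab)
  genes <- read_gff_genes(gff, cat_tab, list(ct))
  expect_equal(genes[[1]]$cds_seq, "ATGAAA")
  expect_equal(genes[[2]]$cds_seq, "TTTCAT")  # reverse complement
  expect_equal(genes[[2]]$category, "ribosomal")
})

test_that("read_gff_genes validates categories and coordinates", {
  ct <- contig("c1", "ATGAAATTT")
  gff <- withr::local_tempfile(fileext = ".gff3")
  cat_tab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("##gff-version 3",
               "c1\tx\tCDS\t1\t6\t.\t+\t0\tID=g1"), gff)
  writeLines("g1\tplasmid_thing", cat_tab)
  expect_error(read_gff_genes(gff, cat_tab, list(ct)), "allowed")

  expect_warning(genes <- read_gff_genes(gff, NULL, list(ct)),
                 "hypothetical")
  expect_equal(genes[[1]]$category, "hypothetical")

  writeLines(c("##gff-version 3",
               "c1\tx\tCDS\t4\t30\t.\t+\t0\tID=g1"), gff)
  expect_error(suppressWarnings(read_gff_genes(gff, NULL, list(ct))),
               "outside contig")
})

test_that("GFF round-trip preserves coordinates, strand and category", {
  sc <- default_scenario()
  gff <- withr::local_tempfile(fileext = ".gff3")
  cat_tab <- withr::local_tempfile(fileext = ".tsv")
  write_gff_genes(sc$genes, gff, cat_tab)
  back <- read_gff_genes(gff, cat_tab, sc$contigs)
  a <- do.call(rbind, lapply(sc$genes, function(g)
    data.frame(g$gene_id, g$start, g$end, g$strand, g$category)))
  b <- do.call(rbind, lapply(back, function(g)
    data.frame(g$gene_id, g$start, g$end, g$strand, g$category)))
  expect_equal(a[order(a[[1]]), ], b[order(b[[1]]), ], ignore_attr = TRUE)
})

test_that("SAM round-trip of simulator output preserves alignments", {
  sc <- default_scenario()
  p <- withr::local_tempfile(fileext = ".sam")
  sub <- sc$pairs[1:500, ]
  write_sam_pairs(sub, sc$contigs, p)
  back <- read_sam_pairs(p)
  back <- back[match(sub$read_id, back$read_id), ]
  expect_equal(back$contig1, sub$contig1)
  expect_equal(back$pos1, sub$pos1)
  expect_equal(back$cigar2, sub$cigar2)
  expect_equal(back$alen2, sub$alen2)
  expect_equal(back$proper_pair, sub$proper_pair)
})

test_that("read_sam_pairs ignores secondary records and validates input", {
  p <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:c1\tLN:1000",
    "r1\t99\tc1\t1\t60\t10M\t=\t100\t0\tAAAAAAAAAA\t*",
    "r1\t147\tc1\t100\t60\t10M\t=\t1\t0\tAAAAAAAAAA\t*",
    # secondary alignment of mate 1: must be ignored
    "r1\t355\tc1\t500\t60\t10M\t=\t100\t0\tAAAAAAAAAA\t*"), p)
  pairs <- read_sam_pairs(p)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$pos1, 1L)

  writeLines(c("@SQ\tSN:c1\tLN:1000", "r1\t99\tc1\t1\t60"), p)
  expect_error(read_sam_pairs(p), "truncated")

  writeLines(c("@SQ\tSN:c1\tLN:1000",
               "r1\t99\tcX\t1\t60\t10M\t=\t100\t0\tAAAAAAAAAA\t*"), p)
  expect_error(read_sam_pairs(p), "absent from SAM header")
})

test_that("read_gfa maps orientations to contig ends and deduplicates", {
  p <- withr::local_tempfile(fileext = ".gfa")
  writeLines(c("H\tVN:Z:1.0", "S\ta\t*", "S\tb\t*",
               "L\ta\t+\tb\t+\t0M",
               "L\ta\t+\tb\t+\t0M"), p)
  g <- read_gfa(p)
  expect_equal(nrow(g$edges), 1L)
  e <- g$edges[1, ]
  expect_true(graph_has_edge(g, "a", "3p", "b", "5p"))

  writeLines(c("S\ta\t*", "S\tb\t*", "L\ta\t-\tb\t+\t0M"), p)
  g <- read_gfa(p)
  expect_true(graph_has_edge(g, "a", "5p", "b", "5p"))

  writeLines(c("S\ta\t*", "L\ta\t+\tzzz\t+\t0M"), p)
  expect_error(read_gfa(p), "unknown segment")
})

test_that("GFA round-trip preserves the edge set", {
  sc <- default_scenario()
  p <- withr::local_tempfile(fileext = ".gfa")
  write_gfa(sc$graph, contigs = NULL, path = p)
  back <- read_gfa(p)
  expect_setequal(back$nodes, sc$graph$nodes)
  expect_equal(back$edges[do.call(order, back$edges), ],
               sc$graph$edges[do.call(order, sc$graph$edges), ],
               ignore_attr = TRUE)
})

test_that("CDS extraction from a contig is deterministic", {
  sc <- default_scenario()
  g <- sc$genes[[7]]
  ct <- sc$contigs[[g$contig_id]]
  again <- gene_record(g$gene_id, g$contig_id, g$start, g$end, g$strand,
                       g$category, contig = ct)
  expect_identical(again$cds_seq, g$cds_seq)
})
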