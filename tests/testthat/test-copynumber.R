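# repeat_copy_number: depth summaries, copy-number ratios, junction
# counting, repeat-model reconciliation, pileup variants.

manual_pairs <- function(contig_id, pos1, pos2, alen = 100L) {
  n <- length(pos1)
  out <- data.frame(
    read_id = sprintf("m%03d", seq_len(n)),
    contig1 = contig_id, pos1 = pos1, alen1 = alen, strand1 = "+",
    cigar1 = paste0(alen, "M"), seq1 = strrep("A", alen),
    contig2 = contig_id, pos2 = pos2, alen2 = alen, strand2 = "-",
    cigar2 = paste0(alen, "M"), seq2 = strrep("A", alen),
    proper_pair = TRUE, stringsAsFactors = FALSE)
  class(out) <- c("read_pairs", "data.frame")
  out
}

test_that("depth_summary computes tiling means and degenerate cases", {
  ct <- contig("c1", strrep("A", 400))
  pairs <- manual_pairs("c1", 1, 101)
  ds <- depth_summary(pairs, ct, region = c(1, 200))
  expect_equal(ds$mean_depth, 1.0)

  expect_warning(z <- depth_summary(pairs, ct, region = c(300, 400)),
                 "zero coverage")
  expect_equal(z$mean_depth, 0)
  expect_equal(z$ci, c(0, 0))

  expect_error(depth_summary(empty_read_pairs(), ct), "empty alignment")
})

test_that("estimate_copy_number reproduces the published worked examples", {
  res <- estimate_copy_number(400.165, 135.16)
  expect_equal(res$ratio, 400.165 / 135.16, tolerance = 1e-12)
  expect_equal(round(res$ratio, 3), 2.961)
  expect_identical(res$copies, 3L)

  res2 <- estimate_copy_number(159.02, 48.24)
  expect_equal(round(res2$ratio, 3), 3.296)
  expect_identical(res2$copies, 3L)

  expect_identical(estimate_copy_number(50, 50)$copies, 1L)
  expect_error(estimate_copy_number(10, 0), "positive")
})

test_that("estimate_copy_number is scale invariant and floors at 1", {
  set.seed(4)
  for (k in c(0.2, 0.6, 1.4, 2.5, 3.49, 3.51, 4.2)) {
    x <- runif(1, 1, 500)
    res <- estimate_copy_number(k * x, x)
    expect_equal(res$ratio, k, tolerance = 1e-9)
    expect_identical(res$copies,
                     max(1L, as.integer(sign(k) * floor(abs(k) + 0.5))))
  }
  # ties round half away from zero
  expect_identical(estimate_copy_number(2.5, 1)$copies, 3L)
})

test_that("count_junctions recovers the repeat's connection structure", {
  sc <- default_scenario()
  j <- count_junctions(sc$pairs, "bgc_1", sc$contigs, graph = sc$graph)
  p <- j$partners
  expect_equal(sum(p$end == "3p"), 3L)
  expect_equal(sum(p$end == "5p"), 2L)
  expect_equal(sum(p$end == "internal"), 1L)
  expect_true(all(p$graph_confirmed[p$end %in% c("5p", "3p")]))
  off <- p$offset[p$end == "internal"]
  expect_lt(abs(off - sc$config$leading_segment_length), 400)

  # support thresholds are monotone
  j10 <- count_junctions(sc$pairs, "bgc_1", sc$contigs, min_support = 10)
  expect_lte(nrow(j10$partners), nrow(p))
  j_inf <- count_junctions(sc$pairs, "bgc_1", sc$contigs,
                           min_support = 10^6)
  expect_equal(nrow(j_inf$partners), 0L)
})

test_that("a single-copy scenario yields one partner per end", {
  sc1 <- build_scenario(small_config(seed = 7, copy_number = 1))
  j <- count_junctions(sc1$pairs, "bgc_1", sc1$contigs, graph = sc1$graph)
  expect_equal(sum(j$partners$end == "5p"), 1L)
  expect_equal(sum(j$partners$end == "3p"), 1L)
  expect_equal(sum(j$partners$end == "internal"), 0L)
})

test_that("reconcile_repeat_model recovers segment copies consistently", {
  sc <- default_scenario()
  m <- reconcile_repeat_model(sc$pairs, sc$contigs, "bgc_1")
  expect_equal(nrow(m$segments), 2L)
  expect_identical(m$segments$copies, c(2L, 3L))
  expect_equal(m$segments$start, c(1, sc$config$leading_segment_length + 1),
               tolerance = 0.15)
  expect_true(m$consistent)

  # single copy: one segment, copy 1
  sc1 <- build_scenario(small_config(seed = 7, copy_number = 1))
  m1 <- reconcile_repeat_model(sc1$pairs, sc1$contigs, "bgc_1")
  expect_equal(nrow(m1$segments), 1L)
  expect_identical(m1$segments$copies, 1L)
})

test_that("depth/junction disagreement is flagged, not silently fixed", {
  sc <- default_scenario()
  j <- count_junctions(sc$pairs, "bgc_1", sc$contigs)
  # drop one 3' partner: depth still says 3 copies, junctions say 2
  keep <- j$partners$end != "3p" | !duplicated(j$partners$end)
  j$partners <- j$partners[keep, , drop = FALSE]
  m <- reconcile_repeat_model(sc$pairs, sc$contigs, "bgc_1", junctions = j)
  expect_false(m$consistent)
  expect_match(m$flags, "3' junction partner", all = FALSE)
})

test_that("pileup recovers all injected variants exactly", {
  sc <- default_scenario()
  v <- pileup_variants(sc$pairs, sc$contigs[["bgc_1"]],
                       copies = sc$truth$copy_number)
  truth <- sc$truth$variants
  expect_equal(nrow(v), nrow(truth))
  for (i in seq_len(nrow(truth))) {
    hit <- v[abs(v$pos - truth$pos[i]) <= 2 & v$type == truth$type[i], ]
    expect_equal(nrow(hit), 1L, label = paste("variant", i))
    if (truth$type[i] == "insertion") {
      expect_identical(hit$ins_seq, truth$ins_seq[i])
    } else {
      expect_identical(hit$ref, truth$ref[i])
      expect_identical(hit$alt, truth$alt[i])
    }
    expect_equal(hit$est_copies, truth$n_copies[i])
  }
  expect_error(pileup_variants(sc$pairs, sc$contigs[["bgc_1"]], copies = 1),
               "single copy")
})

test_that("variant annotation classifies the injected variant set", {
  sc <- default_scenario()
  v <- annotate_variants(
    pileup_variants(sc$pairs, sc$contigs[["bgc_1"]], copies = 3),
    sc$genes)
  expect_equal(v$classification[v$type == "insertion"],
               rep("in_frame", 3))
  snp_cls <- v$classification[v$type == "SNP"]
  expect_true("synonymous" %in% snp_cls)
  expect_true("noncoding" %in% snp_cls)
})

test_that("no injected variants means no calls (false-positive control)", {
  for (s in c(101, 202, 303)) {
    cfg <- small_config(
      seed = s,
      insertion_specs = data.frame(pos = integer(0), seq = character(0),
                                   copies = character(0)),
      snp_specs = data.frame(pos = integer(0), ref = character(0),
                             alt = character(0), copies = character(0)))
    scn <- build_scenario(cfg)
    v <- pileup_variants(scn$pairs, scn$contigs[["bgc_1"]], copies = 3)
    expect_equal(nrow(v), 0L, label = paste("seed", s))
  }
})

test_that("copy number is recovered across copy numbers and seeds", {
  # scaled down from the spec'd 50-replicate sweep: 4 copy numbers x 3
  # seeds (stated world unchanged; runtime budget)
  for (cn in 1:4) {
    for (s in 1:3) {
      scn <- build_scenario(small_config(seed = 400 + 10 * cn + s,
                                         copy_number = cn))
      gd <- bin_reference_depth(scn$pairs, scn$contigs, exclude = "bgc_1")
      body_start <- if (cn > scn$config$leading_segment_copies)
        scn$config$leading_segment_length + 1 else 1
      ds <- depth_summary(scn$pairs, scn$contigs[["bgc_1"]],
                          region = c(body_start, 6000))
      est <- estimate_copy_number(ds$mean_depth, gd)
      expect_identical(est$copies, as.integer(cn),
                       label = sprintf("cn=%d seed=%d", cn, s))
    }
  }
})
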