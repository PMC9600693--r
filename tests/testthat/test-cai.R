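# codon_adaptation: relative adaptiveness, CAI, SNP/insertion
# classification.

test_that("build_reference follows the count-ratio and pseudocount rules", {
  # glycine observed only as GGC (twice): w(GGC)=1, others 0.5/2
  ref <- build_reference("GGCGGC")
  expect_equal(unname(ref$w[["GGC"]]), 1)
  expect_equal(unname(ref$w[["GGT"]]), 0.25)
  expect_equal(unname(ref$w[["GGA"]]), 0.25)
  expect_equal(unname(ref$w[["GGG"]]), 0.25)

  # GGC:2, GGT:1 -> w = 1, 0.5
  ref2 <- build_reference("GGCGGCGGT")
  expect_equal(unname(ref2$w[["GGC"]]), 1)
  expect_equal(unname(ref2$w[["GGT"]]), 0.5)
  # amino acids absent from the reference stay NA
  expect_true(is.na(ref2$w[["AAA"]]))

  expect_error(build_reference(character(0)), "empty")
  expect_error(build_reference("TAA"), "countable")
})

test_that("cai matches closed forms and is length-invariant", {
  ref <- build_reference("GGCGGCGGT")
  expect_equal(cai("GGCGGT", ref), sqrt(0.5), tolerance = 1e-12)
  expect_equal(cai("GGCGGC", ref), 1)
  # single-codon families are excluded from the geometric mean
  expect_equal(cai("ATGGGCTGG", ref), 1)
  # duplicating a gene leaves CAI unchanged
  expect_equal(cai(strrep("GGCGGT", 20), ref), cai("GGCGGT", ref),
               tolerance = 1e-12)
  expect_error(cai("ATG", ref), "countable")
})

test_that("partial trailing codons are dropped with a warning", {
  ref <- build_reference("GGCGGCGGT")
  expect_warning(val <- cai("GGCGGTGG", ref), "prefix")
  expect_equal(val, sqrt(0.5), tolerance = 1e-12)
})

test_that("reference-like genes outscore uniformly random synonymous usage", {
  sc <- default_scenario()
  ribo <- Filter(function(g) g$category == "ribosomal", sc$genes)
  ref <- build_reference(ribo)
  ref_cai <- mean(vapply(ribo, cai, numeric(1), ref = ref))
  # randomize synonymous choice within the same amino-acid sequence
  set.seed(13)
  code <- genetic_code_11()
  fams <- split(names(code)[code != "*"], code[code != "*"])
  rand_cai <- vapply(ribo[1:10], function(g) {
    cods <- split_codons(g$cds_seq)
    cods <- cods[code[cods] != "*"]
    shuffled <- vapply(cods, function(cd) {
      fam <- fams[[code[[cd]]]]
      fam[sample.int(length(fam), 1)]
    }, character(1))
    cai(paste(shuffled, collapse = ""), ref)
  }, numeric(1))
  expect_gt(ref_cai, mean(rand_cai))
})

test_that("classify_snp reproduces the published codon examples", {
  # TAC -> TAT: both tyrosine
  expect_equal(classify_snp("TAC", 3, "C", "T"), "synonymous")
  # TGC -> AGC: cysteine -> serine
  expect_equal(classify_snp("TGC", 1, "T", "A"), "nonsynonymous")
  # just past the CDS end: noncoding
  expect_equal(classify_snp("TAC", 4, "A", "G"), "noncoding")
  expect_equal(classify_snp("TAC", 0, "A", "G"), "noncoding")
  expect_error(classify_snp("TAC", 2, "C", "T"), "mismatch")
})

test_that("classify_snp agrees with brute-force translation of all 64x9", {
  code <- genetic_code_11()
  codons <- names(code)
  for (cd in codons) {
    if (code[[cd]] == "*") next  # stop codons cannot head a gene CDS here
    for (pos in 1:3) {
      ref <- substr(cd, pos, pos)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        alt_cd <- cd
        substr(alt_cd, pos, pos) <- alt
        # independent oracle: Biostrings translation of both codons
        aa <- as.character(Biostrings::translate(
          Biostrings::DNAStringSet(c(cd, alt_cd)),
          genetic.code = Biostrings::getGeneticCode("11"),
          no.init.codon = TRUE))
        expected <- if (aa[1] == aa[2]) "synonymous"
          else if (aa[2] == "*") "nonsense" else "nonsynonymous"
        expect_equal(classify_snp(cd, pos, ref, alt), expected,
                     label = paste(cd, pos, alt))
      }
    }
  }
})

test_that("classify_insertion applies the frame rule", {
  expect_equal(classify_insertion(60, within_cds = TRUE), "in_frame")
  expect_equal(classify_insertion(24, within_cds = TRUE), "in_frame")
  expect_equal(classify_insertion(54, within_cds = TRUE), "in_frame")
  expect_equal(classify_insertion(55, within_cds = TRUE), "frameshift")
  expect_equal(classify_insertion(60, within_cds = FALSE), "intergenic")
  expect_error(classify_insertion(0, TRUE))
})

test_that("scenario CAI pattern: bgc matches ribosomal, not background", {
  sc <- default_scenario()
  ribo <- Filter(function(g) g$category == "ribosomal", sc$genes)
  ref <- build_reference(ribo)
  obs <- suppressWarnings(gene_cai(sc$genes, ref))
  expect_true(all(obs$cai > 0 & obs$cai <= 1))
  res <- category_anova_tukey(obs, "cai")
  tb <- res$tukey
  pair <- function(a, b) {
    tb[(tb$category_a == a & tb$category_b == b) |
         (tb$category_a == b & tb$category_b == a), ]
  }
  expect_false(pair("bgc", "ribosomal")$different)
  expect_true(pair("bgc", "hypothetical")$different)
  expect_true(pair("ribosomal", "hypothetical")$different)
})
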