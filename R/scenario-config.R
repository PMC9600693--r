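# Scenario configuration and the gene-level generator.
#
# The generator emulates the data structure of a sponge-symbiont bin
# carrying a horizontally acquired, multi-copy biosynthetic gene cluster:
# a host bin with a homogeneous composition, an embedded BGC with shifted
# GC/5-mer composition but ribosomal-like synonymous codon usage, repeated
# in near-identical copies that differ by in-frame insertions and SNPs,
# one copy lacking a short leading segment. The default geometry scales
# the ~98-kb/3-kb repeat structure down ~5x (20-kb unit, 1-kb leading
# segment) to keep desk runtimes small.

#' Scenario configuration
#'
#' All knobs of the synthetic metagenome. Defaults state the emulated
#' world: 300-kb host bin at GC 0.54 split over 12 contigs, a 20-kb BGC at
#' GC 0.46 in 3 copies of which 2 carry the 1-kb leading segment, 2x150 bp
#' reads at 50x depth with a 300 +/- 30 bp insert, 50 genes per category,
#' pseudogenes truncated to half length. `insertion_specs` /`snp_specs`
#' may be NULL (derived from the realized gene layout, mirroring the
#' published variant table: three in-frame insertions of 60/24/54 bp, one
#' synonymous C->T SNP on a TAC codon, one intergenic SNP) or supplied as
#' data.frames (`pos`, `seq`, `copies` and `pos`, `ref`, `alt`, `copies`;
#' `copies` a comma-separated list of copy indices).
#'
#' @param seed integer seed driving every random choice
#' @param host_length,n_host_contigs host bin size (bp) and contig count
#' @param host_gc,bgc_gc GC fractions of host and BGC
#' @param bgc_length collapsed BGC unit length (bp)
#' @param bgc_copy_number copies of the BGC in the true genome
#' @param leading_segment_length,leading_segment_copies length (bp) of the
#'   leading segment and how many copies carry it
#' @param insertion_specs,snp_specs variant injections (see Details)
#' @param read_length,insert_mean,insert_sd,depth read simulation knobs
#' @param n_genes named integer vector: genes per category
#' @param pseudogene_truncation_fraction fraction of length kept when
#'   truncating a pseudogene
#' @param ribosomal_codon_bias_strength s >= 1; ribosomal and bgc genes
#'   draw synonymous codons so their expected per-codon log relative
#'   adaptiveness is -1/(s+3) in every family (stronger s, higher CAI)
#' @param error_rate per-base sequencing error rate (default 0)
#' @return list of class `scenario_config`
#' @export
scenario_config <- function(seed = 1L,
                            host_length = 300000L,
                            n_host_contigs = 12L,
                            host_gc = 0.54,
                            bgc_length = 20000L,
                            bgc_gc = 0.46,
                            bgc_copy_number = 3L,
                            leading_segment_length = 1000L,
                            leading_segment_copies = 2L,
                            insertion_specs = NULL,
                            snp_specs = NULL,
                            read_length = 150L,
                            insert_mean = 300,
                            insert_sd = 30,
                            depth = 50,
                            n_genes = c(annotated = 50L, hypothetical = 50L,
                                        pseudogene = 50L, ribosomal = 50L,
                                        bgc = 50L),
                            pseudogene_truncation_fraction = 0.5,
                            ribosomal_codon_bias_strength = 5,
                            error_rate = 0) {
  cfg <- list(seed = as.integer(seed), host_length = as.integer(host_length),
              n_host_contigs = as.integer(n_host_contigs),
              host_gc = host_gc, bgc_length = as.integer(bgc_length),
              bgc_gc = bgc_gc, bgc_copy_number = as.integer(bgc_copy_number),
              leading_segment_length = as.integer(leading_segment_length),
              leading_segment_copies = as.integer(leading_segment_copies),
              insertion_specs = insertion_specs, snp_specs = snp_specs,
              read_length = as.integer(read_length),
              insert_mean = insert_mean, insert_sd = insert_sd,
              depth = depth, n_genes = n_genes,
              pseudogene_truncation_fraction = pseudogene_truncation_fraction,
              ribosomal_codon_bias_strength = ribosomal_codon_bias_strength,
              error_rate = error_rate)
  with(cfg, {
    stopifnot(host_length > 0, bgc_length > 0, n_host_contigs >= 1,
              host_gc > 0, host_gc < 1, bgc_gc > 0, bgc_gc < 1,
              bgc_copy_number >= 1,
              leading_segment_length > 0,
              leading_segment_length < bgc_length,
              leading_segment_copies >= 1,
              leading_segment_copies <= bgc_copy_number,
              read_length > 0, insert_mean > read_length, depth > 0,
              pseudogene_truncation_fraction > 0,
              pseudogene_truncation_fraction < 0.8,
              ribosomal_codon_bias_strength >= 1,
              error_rate >= 0, error_rate < 1)
  })
  if (is.null(names(cfg$n_genes)) ||
      !all(names(cfg$n_genes) %in% GENE_CATEGORIES)) {
    stop("n_genes must be named by gene category")
  }
  if (!is.null(insertion_specs)) {
    if (any(insertion_specs$pos < 1 | insertion_specs$pos >= cfg$bgc_length))
      stop("insertion position outside BGC")
    if (any(grepl("[^ACGT]", toupper(insertion_specs$seq))))
      stop("insertion sequences must be over A/C/G/T")
  }
  if (!is.null(snp_specs) &&
      any(snp_specs$pos < 1 | snp_specs$pos > cfg$bgc_length)) {
    stop("SNP position outside BGC")
  }
  structure(cfg, class = "scenario_config")
}

# ---- codon machinery -------------------------------------------------

# Synonymous families of genetic code 11: list aa -> codons (sorted).
codon_families <- local({
  fams <- NULL
  function() {
    if (is.null(fams)) {
      code <- genetic_code_11()
      code <- code[code != "*"]
      fams <<- split(names(code), unname(code))
      fams <<- lapply(fams, sort)
    }
    fams
  }
})

# GC fraction of a codon string vector.
codon_gc <- function(codons) {
  (nchar(gsub("[AT]", "", codons))) / 3
}

# Probability of the preferred codon in a size-k family so that the
# expected log relative adaptiveness equals `target` (< 0), on the
# concentrated branch. w(pref) = 1, w(other) = ((1-q)/(k-1))/q.
solve_preferred_prob <- function(k, target) {
  if (k == 1L) return(1)
  g <- function(q) (1 - q) * log((1 - q) / ((k - 1) * q))
  qstar <- stats::optimize(g, c(1 / k + 1e-9, 1 - 1e-9))$minimum
  if (target < g(qstar)) {
    stop("codon bias target ", signif(target, 3),
         " unattainable for family size ", k)
  }
  uniroot(function(q) g(q) - target, c(qstar, 1 - 1e-9),
          tol = 1e-10)$root
}

# Codon sampling rules for one scenario: background (Dirichlet-perturbed
# uniform synonymous usage) and biased (concentrated on a preferred codon
# with family-size-matched expected log-w). Drawn from the current RNG.
make_codon_rules <- function(bias_strength, dirichlet_shape = 2) {
  fams <- codon_families()
  target <- -1 / (bias_strength + 3)
  bg <- list(); biased <- list()
  for (a in names(fams)) {
    k <- length(fams[[a]])
    p <- rgamma(k, shape = dirichlet_shape)
    bg[[a]] <- setNames(p / sum(p), fams[[a]])
    q <- solve_preferred_prob(k, target)
    pb <- rep((1 - q) / max(1L, k - 1L), k)
    pb[1] <- q  # preferred codon: alphabetically first
    if (k == 1L) pb <- 1
    biased[[a]] <- setNames(pb, fams[[a]])
  }
  list(background = bg, biased = biased)
}

# Amino-acid distribution tilted to hit a target GC under a codon rule:
# p_aa ~ exp(lambda * gcbar_aa), lambda solved by uniroot.
aa_distribution_for_gc <- function(rule_probs, target_gc) {
  fams <- codon_families()
  gcbar <- vapply(names(fams), function(a) {
    sum(rule_probs[[a]] * codon_gc(fams[[a]]))
  }, numeric(1))
  lo <- min(gcbar) + 1e-4; hi <- max(gcbar) - 1e-4
  if (target_gc <= lo || target_gc >= hi) {
    stop("target GC ", target_gc, " outside attainable range [",
         signif(lo, 3), ", ", signif(hi, 3), "]")
  }
  f <- function(lambda) {
    w <- exp(lambda * gcbar); w <- w / sum(w)
    sum(w * gcbar) - target_gc
  }
  lambda <- uniroot(f, c(-80, 80), tol = 1e-9)$root
  w <- exp(lambda * gcbar)
  setNames(w / sum(w), names(fams))
}

# Sample coding sequences: n genes with body lengths `len_codons`,
# amino acids from `aa_probs`, codons from `rule_probs`; ATG/TAA added.
sample_cds <- function(len_codons, aa_probs, rule_probs) {
  fams <- codon_families()
  total <- sum(len_codons)
  aa <- sample(names(aa_probs), total, replace = TRUE, prob = aa_probs)
  codons <- character(total)
  for (a in unique(aa)) {
    idx <- which(aa == a)
    codons[idx] <- sample(fams[[a]], length(idx), replace = TRUE,
                          prob = rule_probs[[a]])
  }
  ends <- cumsum(len_codons)
  starts <- ends - len_codons + 1L
  vapply(seq_along(len_codons), function(i) {
    paste0("ATG", paste(codons[starts[i]:ends[i]], collapse = ""), "TAA")
  }, character(1))
}

#' Simulate the gene layer of a scenario
#'
#' Draws the coding sequences of all five gene categories without placing
#' them on contigs: host-like categories (annotated, hypothetical,
#' pseudogene) use Dirichlet-perturbed background codon usage at the host
#' GC; ribosomal genes use the concentrated optimal-codon rule at host GC;
#' bgc genes use the same concentrated rule at the (typically lower) BGC
#' GC, so their synonymous usage matches ribosomal genes while their GC
#' does not. Pseudogenes are then truncated to
#' `pseudogene_truncation_fraction` of their length.
#'
#' Deterministic given `config$seed`.
#'
#' @param config [scenario_config()]
#' @return list with `genes` (data.frame: gene_id, category, cds_seq,
#'   full_length_bp) and `rules` (the codon sampling rules used)
#' @export
simulate_gene_set <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  rules <- make_codon_rules(config$ribosomal_codon_bias_strength)
  aa_bg_host <- aa_distribution_for_gc(rules$background, config$host_gc)
  aa_bi_host <- aa_distribution_for_gc(rules$biased, config$host_gc)
  aa_bi_bgc <- aa_distribution_for_gc(rules$biased, config$bgc_gc)

  spec <- list(
    annotated = list(aa = aa_bg_host, rule = rules$background,
                     len = c(150L, 350L)),
    hypothetical = list(aa = aa_bg_host, rule = rules$background,
                        len = c(150L, 350L)),
    pseudogene = list(aa = aa_bg_host, rule = rules$background,
                      len = c(150L, 350L)),
    ribosomal = list(aa = aa_bi_host, rule = rules$biased,
                     len = c(150L, 350L)),
    bgc = list(aa = aa_bi_bgc, rule = rules$biased, len = c(90L, 130L)))

  rows <- list()
  for (cat in GENE_CATEGORIES) {
    n <- config$n_genes[[cat]]
    if (is.null(n) || n == 0L) next
    sp <- spec[[cat]]
    lens <- sample(sp$len[1]:sp$len[2], n, replace = TRUE)
    cds <- sample_cds(lens, sp$aa, sp$rule)
    full_len <- nchar(cds)
    if (cat == "pseudogene") {
      cds <- substr(cds, 1L,
                    pmax(6L, floor(nchar(cds) *
                                     config$pseudogene_truncation_fraction)))
    }
    rows[[cat]] <- data.frame(
      gene_id = sprintf("%s_%03d", cat, seq_len(n)), category = cat,
      cds_seq = cds, full_length_bp = full_len, stringsAsFactors = FALSE)
  }
  list(genes = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       rules = rules)
}

#' Fabricate a homolog-length table consistent with scenario truth
#'
#' Non-pseudogenes receive a closest-homolog length within +/-10% of their
#' own amino-acid length; pseudogenes receive their pre-truncation length,
#' so their length ratio equals the truncation fraction (< 0.8).
#'
#' @param genes list of [gene_record()] (or the gene data.frame from
#'   [simulate_gene_set()])
#' @param truth scenario truth carrying `pseudogene_ids` and
#'   `truncation_fraction`
#' @return data.frame: gene_id, gene_aa_length, homolog_aa_length
#' @export
make_homolog_table <- function(genes, truth) {
  if (length(genes) == 0L ||
      (is.data.frame(genes) && nrow(genes) == 0L)) {
    return(data.frame(gene_id = character(0), gene_aa_length = numeric(0),
                      homolog_aa_length = numeric(0)))
  }
  if (is.data.frame(genes)) {
    ids <- genes$gene_id
    aa_len <- floor(nchar(genes$cds_seq) / 3)
  } else {
    ids <- vapply(genes, `[[`, character(1), "gene_id")
    aa_len <- floor(vapply(genes, function(g) nchar(g$cds_seq),
                           numeric(1)) / 3)
  }
  is_pseudo <- ids %in% truth$pseudogene_ids
  homolog <- numeric(length(ids))
  homolog[!is_pseudo] <- round(aa_len[!is_pseudo] *
                                 runif(sum(!is_pseudo), 0.9, 1.1))
  homolog[is_pseudo] <- round(aa_len[is_pseudo] /
                                truth$truncation_fraction)
  data.frame(gene_id = ids, gene_aa_length = aa_len,
             homolog_aa_length = pmax(1, homolog),
             stringsAsFactors = FALSE)
}
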