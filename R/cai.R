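# Codon adaptation index (CAI) against a highly-expressed (ribosomal)
# reference set, plus codon-level variant interpretation.
#
# CAI follows the classical relative-adaptiveness formulation: w(c) is the
# usage of codon c in the reference relative to the most-used synonymous
# codon of the same amino acid, and a gene's CAI is the geometric mean of w
# over its codons. Single-codon families (ATG, TGG) and stop codons carry
# no synonymous choice and are excluded from the geometric mean.

#' Build a relative-adaptiveness table from a reference gene set
#'
#' Counts codon usage over the concatenated reference genes (bacterial
#' genetic code, table 11). For each amino acid, w(c) = count(c) / max
#' count among its synonymous codons. Codons never observed in the
#' reference receive w = pseudocount / max-count so CAI never collapses to
#' zero; amino acids entirely absent from the reference get NA w and are
#' skipped when scoring genes.
#'
#' @param ribosomal_genes list of [gene_record()] (or character CDS
#'   sequences) forming the highly-expressed reference; lengths must be
#'   divisible by 3
#' @param pseudocount occurrences assigned to unobserved codons
#'   (default 0.5)
#' @return object of class `relative_adaptiveness`: list(w, counts,
#'   reference_gene_count, pseudocount)
#' @export
build_reference <- function(ribosomal_genes, pseudocount = 0.5) {
  seqs <- reference_seqs(ribosomal_genes)
  if (length(seqs) == 0L) stop("empty reference set")
  if (any(nchar(seqs) %% 3L != 0L)) {
    stop("reference gene length not divisible by 3")
  }
  code <- genetic_code_11()
  codons <- unlist(lapply(seqs, split_codons))
  codons <- codons[!grepl("[^ACGT]", codons)]
  codons <- codons[code[codons] != "*"]
  if (length(codons) == 0L) stop("reference has no countable codons")
  counts <- setNames(numeric(64), all_codons())
  tab <- table(codons)
  counts[names(tab)] <- as.numeric(tab)
  counts <- counts[code[names(counts)] != "*"]

  aa <- code[names(counts)]
  w <- setNames(rep(NA_real_, length(counts)), names(counts))
  for (a in unique(aa)) {
    idx <- which(aa == a)
    mx <- max(counts[idx])
    if (mx == 0) next  # amino acid absent from reference: w stays NA
    wi <- counts[idx] / mx
    wi[counts[idx] == 0] <- pseudocount / mx
    w[idx] <- wi
  }
  structure(list(w = w, counts = counts,
                 reference_gene_count = length(seqs),
                 pseudocount = pseudocount),
            class = "relative_adaptiveness")
}

reference_seqs <- function(genes) {
  if (length(genes) == 0L) return(character(0))
  if (is.character(genes)) return(toupper(genes))
  vapply(genes, `[[`, character(1), "cds_seq")
}

#' Codon adaptation index of a gene
#'
#' Geometric mean of relative adaptiveness over the gene's codons,
#' excluding ATG, TGG and stop codons:
#' CAI = exp( (1/L) * sum(log w(c_i)) ). For a pseudogene (or any sequence
#' whose length is not a multiple of 3) the longest in-frame prefix is
#' scored, with a warning.
#'
#' @param gene [gene_record()] or character CDS sequence
#' @param ref [build_reference()] table
#' @return CAI in (0, 1]
#' @export
cai <- function(gene, ref) {
  stopifnot(inherits(ref, "relative_adaptiveness"))
  seq <- if (is.character(gene)) toupper(gene) else gene$cds_seq
  if (nchar(seq) %% 3L != 0L) {
    warning("CDS length not divisible by 3; scoring longest in-frame prefix")
  }
  code <- genetic_code_11()
  codons <- split_codons(seq)
  codons <- codons[!grepl("[^ACGT]", codons)]
  keep <- codons[!(codons %in% c("ATG", "TGG")) & code[codons] != "*" &
                   !is.na(ref$w[codons])]
  if (length(keep) == 0L) stop("gene has no countable codons")
  exp(mean(log(ref$w[keep])))
}

#' CAI observations for a gene set
#' @param genes list of [gene_record()]
#' @param ref [build_reference()] table
#' @return data.frame with gene_id, category, cai
#' @export
gene_cai <- function(genes, ref) {
  data.frame(gene_id = vapply(genes, `[[`, character(1), "gene_id"),
             category = vapply(genes, `[[`, character(1), "category"),
             cai = vapply(genes, cai, numeric(1), ref = ref),
             stringsAsFactors = FALSE)
}

#' Classify a single-nucleotide substitution within (or outside) a CDS
#'
#' Translates the reference and alternate codons with the bacterial code
#' (table 11). Positions outside the CDS (or in a trailing partial codon)
#' are noncoding.
#'
#' @param cds_seq in-frame CDS sequence
#' @param pos 1-based position of the substitution within `cds_seq`;
#'   positions < 1 or > nchar(cds_seq) are noncoding
#' @param ref_base,alt_base single bases; `ref_base` must match the CDS
#' @return one of "synonymous", "nonsynonymous", "nonsense", "noncoding"
#' @export
classify_snp <- function(cds_seq, pos, ref_base, alt_base) {
  stopifnot(nchar(ref_base) == 1L, nchar(alt_base) == 1L)
  cds_seq <- toupper(cds_seq)
  n_inframe <- (nchar(cds_seq) %/% 3L) * 3L
  if (pos < 1L || pos > n_inframe) return("noncoding")
  have <- substr(cds_seq, pos, pos)
  if (have != toupper(ref_base)) {
    stop("reference base mismatch at CDS position ", pos,
         ": sequence has ", have, ", variant says ", ref_base)
  }
  codon_start <- pos - (pos - 1L) %% 3L
  ref_codon <- substr(cds_seq, codon_start, codon_start + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, pos - codon_start + 1L, pos - codon_start + 1L) <-
    toupper(alt_base)
  code <- genetic_code_11()
  aa_ref <- code[[ref_codon]]
  aa_alt <- code[[alt_codon]]
  if (aa_ref == aa_alt) "synonymous"
  else if (aa_alt == "*") "nonsense"
  else "nonsynonymous"
}

#' Classify an insertion relative to coding context
#'
#' Inside a CDS an insertion is in-frame iff its length is a multiple of
#' three (no frameshift); outside any CDS it is intergenic.
#' `between_domains` is annotation only (an in-frame insertion between
#' enzymatic domains is unlikely to disturb function) and does not change
#' the classification.
#'
#' @param length_bp insertion length, >= 1
#' @param within_cds logical
#' @param between_domains optional logical annotation
#' @return one of "in_frame", "frameshift", "intergenic"
#' @export
classify_insertion <- function(length_bp, within_cds,
                               between_domains = NA) {
  stopifnot(length_bp >= 1)
  if (!within_cds) return("intergenic")
  if (length_bp %% 3 == 0) "in_frame" else "frameshift"
}
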