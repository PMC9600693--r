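# Functional annotation of variant calls against gene models.

#' Annotate variant calls with a functional classification
#'
#' SNPs are classified synonymous / nonsynonymous / nonsense / noncoding
#' by translating the affected codon (strand-aware, genetic code 11);
#' insertions are in_frame / frameshift when the insertion junction lies
#' inside a CDS, intergenic otherwise.
#'
#' @param calls `variant_calls` data.frame from [pileup_variants()]
#' @param genes list of [gene_record()]
#' @return `calls` with added columns `classification` and `gene_id`
#' @export
annotate_variants <- function(calls, genes) {
  df <- genes_as_df(genes, seqs = TRUE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cls <- character(nrow(calls)); hit_gene <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    pos <- calls$pos[i]
    sub <- df[df$contig_id == calls$chrom[i] & df$start <= pos &
                df$end >= pos, , drop = FALSE]
    if (calls$type[i] == "insertion") {
      # junction between pos and pos+1 must lie strictly inside the CDS
      sub <- sub[sub$end >= pos + 1L, , drop = FALSE]
      if (nrow(sub) == 0L) {
        cls[i] <- "intergenic"; hit_gene[i] <- NA_character_
      } else {
        cls[i] <- classify_insertion(nchar(calls$ins_seq[i]),
                                     within_cds = TRUE)
        hit_gene[i] <- sub$gene_id[1]
      }
    } else {
      if (nrow(sub) == 0L) {
        cls[i] <- "noncoding"; hit_gene[i] <- NA_character_
      } else {
        g <- sub[1, ]
        if (g$strand == "+") {
          cds_pos <- pos - g$start + 1L
          ref <- calls$ref[i]; alt <- calls$alt[i]
        } else {
          cds_pos <- g$end - pos + 1L
          ref <- comp[[calls$ref[i]]]; alt <- comp[[calls$alt[i]]]
        }
        cls[i] <- classify_snp(g$cds_seq, cds_pos, ref, alt)
        hit_gene[i] <- g$gene_id
      }
    }
  }
  calls$classification <- cls
  calls$gene_id <- hit_gene
  calls
}
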