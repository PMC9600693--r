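# Genome-reduction metrics: pseudogene calling by homolog length ratio,
# category tallies, and repeat-aware length-weighted coding density.

#' Call pseudogenes by homolog length ratio
#'
#' A gene whose predicted protein is shorter than `cutoff` (default 80%)
#' of its closest homolog is a putative pseudogene (strict inequality, so
#' a ratio of exactly 0.80 is not flagged). Genes without a homolog are
#' reported as unclassified.
#'
#' @param homolog_table data.frame with gene_id, gene_aa_length,
#'   homolog_aa_length (NA = no homolog)
#' @param cutoff ratio threshold (default 0.8)
#' @return data.frame of class `pseudogene_calls`: gene_id,
#'   gene_aa_length, homolog_aa_length, ratio, is_pseudogene (NA when
#'   unclassified)
#' @export
call_pseudogenes <- function(homolog_table, cutoff = 0.8) {
  tab <- homolog_table
  classified <- !is.na(tab$homolog_aa_length)
  bad <- classified & (tab$homolog_aa_length <= 0 | tab$gene_aa_length <= 0)
  if (any(bad)) {
    stop("nonpositive length for gene(s): ",
         paste(tab$gene_id[bad], collapse = ", "))
  }
  ratio <- ifelse(classified, tab$gene_aa_length / tab$homolog_aa_length,
                  NA_real_)
  out <- data.frame(gene_id = tab$gene_id,
                    gene_aa_length = tab$gene_aa_length,
                    homolog_aa_length = tab$homolog_aa_length,
                    ratio = ratio,
                    is_pseudogene = ifelse(classified, ratio < cutoff, NA),
                    stringsAsFactors = FALSE)
  class(out) <- c("pseudogene_calls", "data.frame")
  out
}

#' Percentage of classified ORFs flagged as pseudogenes
#'
#' @param calls [call_pseudogenes()] output
#' @return percent (0-100) of classified genes flagged
#' @export
pseudogene_fraction <- function(calls) {
  classified <- !is.na(calls$is_pseudogene)
  if (!any(classified)) stop("no classified genes")
  100 * sum(calls$is_pseudogene[classified]) / sum(classified)
}

#' Repeat-aware length-weighted coding density
#'
#' Overall density = 100 x sum(copy x coding) / sum(copy x length), so a
#' repeat unit present in several copies contributes at its copy number.
#' The pseudogene-excluded variant removes pseudogene coding bp from the
#' numerator only.
#'
#' @param replicons data.frame with columns `length_bp`, `coding_bp`,
#'   `copy_number` and optionally `replicon_id` and
#'   `pseudogene_coding_bp` (default 0)
#' @return list of class `coding_density_report`: per_replicon
#'   (data.frame with density_percent), overall_percent,
#'   overall_excl_pseudogenes_percent
#' @export
coding_density <- function(replicons) {
  rp <- as.data.frame(replicons)
  if (nrow(rp) == 0L) stop("no replicons")
  if (is.null(rp$replicon_id)) rp$replicon_id <- sprintf("r%d", seq_len(nrow(rp)))
  if (is.null(rp$copy_number)) rp$copy_number <- 1
  if (is.null(rp$pseudogene_coding_bp)) rp$pseudogene_coding_bp <- 0
  if (any(rp$length_bp <= 0)) stop("nonpositive replicon length")
  if (any(rp$coding_bp > rp$length_bp)) {
    stop("coding bp exceeds replicon length for: ",
         paste(rp$replicon_id[rp$coding_bp > rp$length_bp], collapse = ", "))
  }
  if (any(rp$pseudogene_coding_bp > rp$coding_bp)) {
    stop("pseudogene coding bp exceeds coding bp")
  }
  rp$density_percent <- 100 * rp$coding_bp / rp$length_bp
  wlen <- sum(rp$copy_number * rp$length_bp)
  wcod <- sum(rp$copy_number * rp$coding_bp)
  wpse <- sum(rp$copy_number * rp$pseudogene_coding_bp)
  structure(list(per_replicon = rp,
                 overall_percent = 100 * wcod / wlen,
                 overall_excl_pseudogenes_percent =
                   100 * (wcod - wpse) / wlen),
            class = "coding_density_report")
}

#' @export
print.coding_density_report <- function(x, ...) {
  print(x$per_replicon[, c("replicon_id", "length_bp", "coding_bp",
                           "copy_number", "density_percent")], digits = 4)
  cat(sprintf("overall (length- and copy-weighted): %.2f%%\n",
              x$overall_percent))
  cat(sprintf("excluding pseudogenes: %.2f%%\n",
              x$overall_excl_pseudogenes_percent))
  invisible(x)
}

# Coding bp per contig from gene records (union of gene intervals).
coding_bp_by_contig <- function(genes, contigs, exclude_ids = character(0)) {
  contigs <- as_contig_set(contigs)
  df <- genes_as_df(genes)
  df <- df[!(df$gene_id %in% exclude_ids), , drop = FALSE]
  out <- setNames(numeric(length(contigs)), names(contigs))
  for (id in unique(df$contig_id)) {
    sub <- df[df$contig_id == id, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(sub$start, sub$end))
    out[id] <- sum(IRanges::width(ir))
  }
  out
}
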