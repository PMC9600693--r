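# GFF3 gene features plus the sidecar gene-category table.
#
# The category table is a two-column tab-delimited file
# (gene_id <TAB> category) because GFF3 attributes in the wild rarely carry
# a controlled functional-category vocabulary.

#' Read gene records from GFF3 plus a category table
#'
#' Every CDS feature with an ID attribute becomes a [gene_record()]. A CDS
#' whose ID is absent from the category table defaults to "hypothetical"
#' with a warning; an unknown category label is an error.
#'
#' @param gff_path GFF3 file with CDS features carrying ID attributes
#' @param category_table_path tab-delimited file `gene_id<TAB>category`
#'   (no header); may be `NULL` for all-default categories
#' @param contigs list of [contig()] used to extract and validate CDS
#'   sequences
#' @return list of [gene_record()]
#' @export
read_gff_genes <- function(gff_path, category_table_path, contigs) {
  if (!file.exists(gff_path)) stop("no such file: ", gff_path)
  contigs <- as_contig_set(contigs)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "CDS"]
  if (length(gr) == 0L) return(list())
  ids <- as.character(gr$ID)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("GFF3 CDS feature without an ID attribute")
  }

  categories <- setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(category_table_path)) {
    tab <- read.delim(category_table_path, header = FALSE, sep = "\t",
                      col.names = c("gene_id", "category"),
                      stringsAsFactors = FALSE)
    bad <- setdiff(tab$category, GENE_CATEGORIES)
    if (length(bad)) {
      stop("unknown category label(s): ", paste(bad, collapse = ", "),
           "; allowed: ", paste(GENE_CATEGORIES, collapse = ", "))
    }
    hit <- intersect(ids, tab$gene_id)
    categories[hit] <- tab$category[match(hit, tab$gene_id)]
  }
  n_missing <- sum(is.na(categories))
  if (n_missing > 0L) {
    warning(n_missing, " CDS feature(s) without a category; ",
            "defaulting to 'hypothetical'")
    categories[is.na(categories)] <- "hypothetical"
  }

  seqn <- as.character(GenomicRanges::seqnames(gr))
  missing_contig <- setdiff(seqn, names(contigs))
  if (length(missing_contig)) {
    stop("GFF references contig(s) absent from assembly: ",
         paste(missing_contig, collapse = ", "))
  }
  out <- vector("list", length(gr))
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  for (i in seq_along(gr)) {
    out[[i]] <- gene_record(ids[i], seqn[i], st[i], en[i], strand[i],
                            categories[[ids[i]]],
                            contig = contigs[[seqn[i]]])
  }
  out
}

#' Write gene records to GFF3 (and optionally the category table)
#'
#' @param genes list of [gene_record()]
#' @param gff_path output GFF3
#' @param category_table_path optional output for `gene_id<TAB>category`
#' @return `gff_path`, invisibly
#' @export
write_gff_genes <- function(genes, gff_path, category_table_path = NULL) {
  df <- genes_as_df(genes)
  lines <- c("##gff-version 3",
             sprintf("%s\tsymbgc\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     df$contig_id, df$start, df$end, df$strand, df$gene_id))
  writeLines(lines, gff_path)
  if (!is.null(category_table_path)) {
    write.table(df[, c("gene_id", "category")], category_table_path,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(gff_path)
}
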