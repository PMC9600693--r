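# Small tab-delimited interchange tables: VCF-like variant tables and
# homolog-length tables.

#' Read a VCF-like variant table
#'
#' Tab-delimited with header `CHROM POS ID REF ALT AD`; `AD` holds
#' "ref_count,alt_count" (allelic depth: informative reads supporting each
#' allele).
#'
#' @param path input file
#' @return data.frame with columns chrom, pos, id, ref, alt, ad_ref, ad_alt
#' @export
read_variant_table <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  names(tab) <- tolower(sub("^#?", "", names(tab)))
  need <- c("chrom", "pos", "id", "ref", "alt", "ad")
  if (!all(need %in% names(tab))) {
    stop("variant table must have columns CHROM POS ID REF ALT AD")
  }
  ad <- strsplit(as.character(tab$ad), ",", fixed = TRUE)
  data.frame(chrom = tab$chrom, pos = as.integer(tab$pos), id = tab$id,
             ref = tab$ref, alt = tab$alt,
             ad_ref = as.integer(vapply(ad, `[[`, character(1), 1L)),
             ad_alt = as.integer(vapply(ad, `[[`, character(1), 2L)),
             stringsAsFactors = FALSE)
}

#' Write variant calls as a VCF-like table
#'
#' @param calls data.frame of variant calls (see [pileup_variants()])
#' @param path output file
#' @return `path`, invisibly
#' @export
write_variant_table <- function(calls, path) {
  out <- data.frame(CHROM = calls$chrom, POS = calls$pos,
                    ID = calls$id, REF = calls$ref, ALT = calls$alt,
                    AD = paste(calls$ad_ref, calls$ad_alt, sep = ","))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a homolog-length table
#'
#' Tab-delimited with header `gene_id gene_aa_length homolog_aa_length`;
#' a homolog length of NA (or ".") marks a gene with no detected homolog.
#'
#' @param path input file
#' @return data.frame
#' @export
read_homolog_table <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = c("NA", "."))
  need <- c("gene_id", "gene_aa_length", "homolog_aa_length")
  if (!all(need %in% names(tab))) {
    stop("homolog table must have columns ", paste(need, collapse = ", "))
  }
  tab$gene_aa_length <- as.numeric(tab$gene_aa_length)
  tab$homolog_aa_length <- as.numeric(tab$homolog_aa_length)
  tab
}

#' Write a homolog-length table
#' @param tab data.frame with gene_id, gene_aa_length, homolog_aa_length
#' @param path output file
#' @return `path`, invisibly
#' @export
write_homolog_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
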