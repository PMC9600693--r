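# FASTA input/output (Biostrings-backed, with the validation the rest of
# the pipeline relies on).

#' Read contigs from a FASTA file
#'
#' Sequences are uppercased; record order is preserved; the header token
#' before the first whitespace becomes the contig id.
#'
#' @param path FASTA file
#' @return list of [contig()] objects, named by id
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)) & !startsWith(lines, ";"))
  if (length(nonblank) == 0L) {
    warning("empty FASTA file: ", path)
    return(structure(list(), names = character(0)))
  }
  if (!startsWith(lines[nonblank[1]], ">")) {
    stop("malformed FASTA at line ", nonblank[1],
         ": sequence line before any header")
  }
  dss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(dss))
  out <- vector("list", length(dss))
  for (i in seq_along(dss)) {
    out[[i]] <- contig(ids[i], as.character(dss[[i]]))
  }
  as_contig_set(out)
}

#' Write contigs to a FASTA file
#'
#' @param contigs list of [contig()] objects
#' @param path output file
#' @param width line-wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(contigs, path, width = 70L) {
  seqs <- Biostrings::DNAStringSet(vapply(contigs, `[[`, character(1), "seq"))
  names(seqs) <- vapply(contigs, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}
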