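# GFA1 assembly graphs (S and L lines only, which is what junction
# confirmation needs).
#
# Orientation mapping for an L line "from fo to to_or": the + end of the
# from-segment is its 3p end, "-" its 5p end; the + start of the to-segment
# is its 5p end, "-" its 3p end.

#' Read an assembly graph from GFA1
#'
#' @param path GFA1 file with S and L lines
#' @return [assembly_graph()]
#' @export
read_gfa <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  s <- strsplit(lines[startsWith(lines, "S\t")], "\t", fixed = TRUE)
  l <- strsplit(lines[startsWith(lines, "L\t")], "\t", fixed = TRUE)
  nodes <- vapply(s, `[[`, character(1), 2L)
  if (length(l) == 0L) {
    return(assembly_graph(nodes, data.frame(from = character(0),
                                            from_end = character(0),
                                            to = character(0),
                                            to_end = character(0))))
  }
  from <- vapply(l, `[[`, character(1), 2L)
  fo <- vapply(l, `[[`, character(1), 3L)
  to <- vapply(l, `[[`, character(1), 4L)
  to_or <- vapply(l, `[[`, character(1), 5L)
  bad <- setdiff(c(from, to), nodes)
  if (length(bad)) {
    stop("GFA L line names unknown segment: ",
         paste(unique(bad), collapse = ", "))
  }
  edges <- data.frame(from = from,
                      from_end = ifelse(fo == "+", "3p", "5p"),
                      to = to,
                      to_end = ifelse(to_or == "+", "5p", "3p"),
                      stringsAsFactors = FALSE)
  assembly_graph(nodes, edges) # constructor deduplicates symmetric dupes
}

#' Write an assembly graph as GFA1
#'
#' @param graph [assembly_graph()]
#' @param contigs optional list of [contig()]; when given, S lines carry
#'   sequences and LN tags
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gfa <- function(graph, contigs = NULL, path) {
  if (!is.null(contigs)) contigs <- as_contig_set(contigs)
  s_lines <- vapply(graph$nodes, function(id) {
    if (!is.null(contigs) && id %in% names(contigs)) {
      sprintf("S\t%s\t%s\tLN:i:%d", id, contigs[[id]]$seq,
              contigs[[id]]$length)
    } else sprintf("S\t%s\t*", id)
  }, character(1))
  e <- graph$edges
  l_lines <- if (nrow(e)) {
    sprintf("L\t%s\t%s\t%s\t%s\t0M", e$from,
            ifelse(e$from_end == "3p", "+", "-"),
            e$to, ifelse(e$to_end == "5p", "+", "-"))
  } else character(0)
  writeLines(c("H\tVN:Z:1.0", s_lines, l_lines), path)
  invisible(path)
}
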