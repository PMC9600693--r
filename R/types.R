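# Core data model: contigs, gene records, assembly graphs.
#
# Coordinates are 1-based inclusive everywhere (GFF/SAM convention); any
# half-open arithmetic is internal to the function that needs it.

#' Construct a contig record
#'
#' A contig is the unit of composition and coverage analysis: a sequence
#' plus an optional mean per-base read depth.
#'
#' @param id unique contig identifier
#' @param seq DNA string over A/C/G/T/N (uppercased on construction)
#' @param depth optional nonnegative mean per-base coverage
#' @return object of class `contig` with fields `id`, `seq`, `length`,
#'   `depth`
#' @export
contig <- function(id, seq, depth = NA_real_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    stop("contig '", id, "': sequence contains characters outside A/C/G/T/N")
  }
  if (!is.na(depth) && depth < 0) stop("contig '", id, "': negative depth")
  structure(list(id = id, seq = seq, length = nchar(seq), depth = depth),
            class = "contig")
}

#' @export
print.contig <- function(x, ...) {
  cat(sprintf("<contig %s: %d bp%s>\n", x$id, x$length,
              if (is.na(x$depth)) "" else sprintf(", depth %.1fx", x$depth)))
  invisible(x)
}

# Named list of contigs keyed by id; checks uniqueness.
as_contig_set <- function(contigs) {
  ids <- vapply(contigs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate contig ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(contigs) <- ids
  contigs
}

GENE_CATEGORIES <- c("annotated", "hypothetical", "pseudogene",
                     "ribosomal", "bgc")

#' Construct a gene record
#'
#' A located coding feature with a category label; the unit of GC, CAI and
#' pseudogene analysis. `cds_seq` must equal the strand-corrected substring
#' of the contig; pass the contig to have it extracted and checked.
#'
#' @param gene_id,contig_id identifiers
#' @param start,end 1-based inclusive coordinates on the contig
#' @param strand "+" or "-"
#' @param category one of annotated, hypothetical, pseudogene, ribosomal, bgc
#' @param contig optional `contig` object used to extract/verify `cds_seq`
#' @param cds_seq in-frame CDS sequence; derived from `contig` if missing
#' @return object of class `gene_record`
#' @export
gene_record <- function(gene_id, contig_id, start, end, strand, category,
                        contig = NULL, cds_seq = NULL) {
  stopifnot(length(gene_id) == 1L, length(start) == 1L, length(end) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (!(strand %in% c("+", "-"))) stop("gene '", gene_id, "': bad strand")
  if (!(category %in% GENE_CATEGORIES)) {
    stop("gene '", gene_id, "': unknown category '", category,
         "'; allowed: ", paste(GENE_CATEGORIES, collapse = ", "))
  }
  if (start < 1L || end < start) {
    stop("gene '", gene_id, "': invalid coordinates ", start, "..", end)
  }
  if (!is.null(contig)) {
    if (end > contig$length) {
      stop("gene '", gene_id, "': end ", end, " outside contig '",
           contig$id, "' (", contig$length, " bp)")
    }
    sub <- substr(contig$seq, start, end)
    if (strand == "-") sub <- revcomp(sub)
    if (is.null(cds_seq)) {
      cds_seq <- sub
    } else if (!identical(toupper(cds_seq), sub)) {
      stop("gene '", gene_id, "': cds_seq does not match contig substring")
    }
  }
  if (is.null(cds_seq)) stop("gene '", gene_id, "': need contig or cds_seq")
  cds_seq <- toupper(cds_seq)
  if (category != "pseudogene" && nchar(cds_seq) %% 3L != 0L) {
    stop("gene '", gene_id, "': CDS length ", nchar(cds_seq),
         " not divisible by 3 (category ", category, ")")
  }
  structure(list(gene_id = gene_id, contig_id = contig_id,
                 start = start, end = end, strand = strand,
                 category = category, cds_seq = cds_seq),
            class = "gene_record")
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("<gene %s [%s] %s:%d-%d(%s), %d bp>\n", x$gene_id, x$category,
              x$contig_id, x$start, x$end, x$strand, nchar(x$cds_seq)))
  invisible(x)
}

# data.frame view of a list of gene_records (without sequences by default).
genes_as_df <- function(genes, seqs = FALSE) {
  df <- data.frame(
    gene_id   = vapply(genes, `[[`, character(1), "gene_id"),
    contig_id = vapply(genes, `[[`, character(1), "contig_id"),
    start     = vapply(genes, `[[`, integer(1), "start"),
    end       = vapply(genes, `[[`, integer(1), "end"),
    strand    = vapply(genes, `[[`, character(1), "strand"),
    category  = vapply(genes, `[[`, character(1), "category"),
    stringsAsFactors = FALSE)
  if (seqs) df$cds_seq <- vapply(genes, `[[`, character(1), "cds_seq")
  df
}

#' Construct an assembly graph
#'
#' Undirected links between contig ends (5p/3p), the GFA1 view of an
#' assembly. Edges are stored once in a canonical orientation; the edge set
#' is symmetric under reversal by construction.
#'
#' @param nodes character vector of contig ids
#' @param edges data.frame with columns from, from_end, to, to_end
#'   (ends in "5p"/"3p")
#' @return object of class `assembly_graph`
#' @export
assembly_graph <- function(nodes, edges) {
  stopifnot(is.character(nodes))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("from", "from_end", "to", "to_end")
  if (!all(need %in% names(edges))) {
    stop("edges must have columns ", paste(need, collapse = ", "))
  }
  bad <- setdiff(c(edges$from, edges$to), nodes)
  if (length(bad)) stop("edge references unknown segment: ",
                        paste(unique(bad), collapse = ", "))
  if (nrow(edges) && !all(c(edges$from_end, edges$to_end) %in% c("5p", "3p"))) {
    stop("edge ends must be '5p' or '3p'")
  }
  # canonicalize: (from,from_end) lexicographically <= (to,to_end)
  if (nrow(edges)) {
    a <- paste(edges$from, edges$from_end)
    b <- paste(edges$to, edges$to_end)
    flip <- a > b
    edges[flip, c("from", "from_end", "to", "to_end")] <-
      edges[flip, c("to", "to_end", "from", "from_end")]
    edges <- unique(edges)
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges), class = "assembly_graph")
}

# TRUE if the graph joins (id_a, end_a) to (id_b, end_b).
graph_has_edge <- function(graph, id_a, end_a, id_b, end_b) {
  e <- graph$edges
  any((e$from == id_a & e$from_end == end_a & e$to == id_b & e$to_end == end_b) |
      (e$from == id_b & e$from_end == end_b & e$to == id_a & e$to_end == end_a))
}
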