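# SAM text alignments. Desk-scale SAM is plain tab-delimited text, which is
# all the repeat analyses need; BAM is deliberately out of scope.
#
# Read pairs are represented as a data.frame (class "read_pairs"), one row
# per pair: read_id, then contig/pos/alen/strand/cigar/seq for each mate,
# plus proper_pair. Positions are 1-based leftmost mapping positions;
# alen is the reference span (sum of M/D/N/=/X CIGAR lengths).

CIGAR_RE <- "([0-9]+)([MIDNSHP=X])"

# Parse one CIGAR string into a data.frame(len, op).
parse_cigar <- function(cigar) {
  if (cigar == "*") return(data.frame(len = integer(0), op = character(0)))
  m <- gregexpr(CIGAR_RE, cigar)[[1]]
  toks <- regmatches(cigar, gregexpr(CIGAR_RE, cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) stop("malformed CIGAR: ", cigar)
  data.frame(len = as.integer(sub("[A-Z=]$", "", toks)),
             op = sub("^[0-9]+", "", toks), stringsAsFactors = FALSE)
}

# Reference span consumed by a CIGAR.
cigar_ref_span <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}

#' Read paired-end alignments from a SAM text file
#'
#' Mates are joined by read id. Secondary (0x100) and supplementary (0x800)
#' alignments are ignored; unmapped records and reads whose mate is missing
#' are dropped with their count reported in a message.
#'
#' @param path SAM file (text)
#' @return data.frame of class `read_pairs`; one row per pair with columns
#'   `read_id`, `contig1`, `pos1`, `alen1`, `strand1`, `cigar1`, `seq1`,
#'   the same for mate 2, and `proper_pair`
#' @export
read_sam_pairs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  refs <- sub("\\t.*$", "",
              sub("^@SQ\\tSN:", "", hdr[startsWith(hdr, "@SQ")]))
  if (length(body) == 0L) {
    warning("SAM file has no alignment records: ", path)
    return(empty_read_pairs())
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    stop("truncated SAM record at line ",
         which(!startsWith(lines, "@"))[which(nf < 11L)[1]])
  }
  qname <- vapply(fields, `[[`, character(1), 1L)
  flag <- as.integer(vapply(fields, `[[`, character(1), 2L))
  rname <- vapply(fields, `[[`, character(1), 3L)
  pos <- as.integer(vapply(fields, `[[`, character(1), 4L))
  cig <- vapply(fields, `[[`, character(1), 6L)
  seq <- vapply(fields, `[[`, character(1), 10L)

  keep <- bitwAnd(flag, 0x100) == 0L & bitwAnd(flag, 0x800) == 0L &
    bitwAnd(flag, 0x4) == 0L & rname != "*"
  qname <- qname[keep]; flag <- flag[keep]; rname <- rname[keep]
  pos <- pos[keep]; cig <- cig[keep]; seq <- seq[keep]

  unknown <- setdiff(unique(rname), refs)
  if (length(refs) && length(unknown)) {
    stop("alignment reference(s) absent from SAM header: ",
         paste(unknown, collapse = ", "))
  }

  is1 <- bitwAnd(flag, 0x40) != 0L
  first <- data.frame(read_id = qname[is1], contig = rname[is1],
                      pos = pos[is1], cigar = cig[is1], seq = seq[is1],
                      flag = flag[is1], stringsAsFactors = FALSE)
  second <- data.frame(read_id = qname[!is1], contig = rname[!is1],
                       pos = pos[!is1], cigar = cig[!is1], seq = seq[!is1],
                       flag = flag[!is1], stringsAsFactors = FALSE)
  common <- intersect(first$read_id, second$read_id)
  n_drop <- (nrow(first) - length(common)) + (nrow(second) - length(common))
  if (n_drop > 0L) message("dropped ", n_drop, " unpaired SAM record(s)")
  i1 <- match(common, first$read_id)
  i2 <- match(common, second$read_id)
  out <- data.frame(
    read_id = common,
    contig1 = first$contig[i1], pos1 = first$pos[i1],
    alen1 = vapply(first$cigar[i1], cigar_ref_span, numeric(1),
                   USE.NAMES = FALSE),
    strand1 = ifelse(bitwAnd(first$flag[i1], 0x10) != 0L, "-", "+"),
    cigar1 = first$cigar[i1], seq1 = first$seq[i1],
    contig2 = second$contig[i2], pos2 = second$pos[i2],
    alen2 = vapply(second$cigar[i2], cigar_ref_span, numeric(1),
                   USE.NAMES = FALSE),
    strand2 = ifelse(bitwAnd(second$flag[i2], 0x10) != 0L, "-", "+"),
    cigar2 = second$cigar[i2], seq2 = second$seq[i2],
    proper_pair = bitwAnd(first$flag[i1], 0x2) != 0L,
    stringsAsFactors = FALSE)
  if (any(out$alen1 <= 0) || any(out$alen2 <= 0)) {
    stop("alignment with zero reference span")
  }
  class(out) <- c("read_pairs", "data.frame")
  out
}

empty_read_pairs <- function() {
  out <- data.frame(read_id = character(0), contig1 = character(0),
                    pos1 = integer(0), alen1 = numeric(0),
                    strand1 = character(0), cigar1 = character(0),
                    seq1 = character(0), contig2 = character(0),
                    pos2 = integer(0), alen2 = numeric(0),
                    strand2 = character(0), cigar2 = character(0),
                    seq2 = character(0), proper_pair = logical(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("read_pairs", "data.frame")
  out
}

#' Write paired alignments as SAM text
#'
#' @param pairs `read_pairs` data.frame (see [read_sam_pairs()])
#' @param contigs list of [contig()] providing the @SQ header
#' @param path output file
#' @return `path`, invisibly
#' @export
write_sam_pairs <- function(pairs, contigs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           vapply(contigs, function(ct)
             sprintf("@SQ\tSN:%s\tLN:%d", ct$id, ct$length), character(1)))
  rec <- function(id, flag, rname, pos, cigar, seq, rnext, pnext) {
    sprintf("%s\t%d\t%s\t%d\t60\t%s\t%s\t%d\t0\t%s\t*",
            id, flag, rname, pos, cigar,
            ifelse(rnext == rname, "=", rnext), pnext, seq)
  }
  f1 <- ifelse(pairs$proper_pair, 0x1 + 0x2, 0x1) + 0x40 +
    ifelse(pairs$strand1 == "-", 0x10, 0x0) +
    ifelse(pairs$strand2 == "-", 0x20, 0x0)
  f2 <- ifelse(pairs$proper_pair, 0x1 + 0x2, 0x1) + 0x80 +
    ifelse(pairs$strand2 == "-", 0x10, 0x0) +
    ifelse(pairs$strand1 == "-", 0x20, 0x0)
  lines <- character(0)
  if (nrow(pairs)) {
    lines <- c(rbind(
      rec(pairs$read_id, f1, pairs$contig1, pairs$pos1, pairs$cigar1,
          pairs$seq1, pairs$contig2, pairs$pos2),
      rec(pairs$read_id, f2, pairs$contig2, pairs$pos2, pairs$cigar2,
          pairs$seq2, pairs$contig1, pairs$pos1)))
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
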