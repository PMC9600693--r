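# Pileup variant detection on a collapsed repeat contig.
#
# Copies of a repeat collapsed onto one contig leave divergence between the
# copies as mixed alleles in the pileup: a SNP carried by c of n copies
# shows an alternate-base fraction near c/n, and an insertion shows as a
# consistent I operation (or clipped segment) at one reference junction.

BASE_LOOKUP <- local({
  v <- integer(128)
  v[utf8ToInt("A")] <- 1L; v[utf8ToInt("C")] <- 2L
  v[utf8ToInt("G")] <- 3L; v[utf8ToInt("T")] <- 4L
  v
})

# Decompose one mate's alignment into M blocks and insertion events.
# Returns list(blocks = data.frame(ref_start, ref_end, read_start),
#              ins = data.frame(ref_pos, seq)).
walk_cigar <- function(cigar, pos, seq) {
  ops <- parse_cigar(cigar)
  ref <- pos; rd <- 1L
  blocks <- list(); ins <- list()
  for (i in seq_len(nrow(ops))) {
    len <- ops$len[i]
    switch(ops$op[i],
      "M" = , "=" = , "X" = {
        blocks[[length(blocks) + 1L]] <-
          c(ref_start = ref, ref_end = ref + len - 1L, read_start = rd)
        ref <- ref + len; rd <- rd + len
      },
      "I" = {
        ins[[length(ins) + 1L]] <-
          list(ref_pos = ref - 1L, seq = substr(seq, rd, rd + len - 1L))
        rd <- rd + len
      },
      "S" = { rd <- rd + len },
      "D" = , "N" = { ref <- ref + len },
      "H" = , "P" = NULL)
  }
  list(blocks = blocks, ins = ins)
}

#' Detect repeat-divergence variants from a pileup
#'
#' Computes per-column base counts on the collapsed repeat contig. A SNP is
#' emitted where the most frequent non-reference base reaches
#' `min_alt_depth` reads and `min_alt_fraction` of the informative
#' (ref + alt) reads. Insertions are detected from reads carrying an
#' insertion operation at a common reference junction with a consistent
#' inserted sequence (exact-match clustering; set `max_mismatch = 1` for a
#' mismatch-tolerant mode when reads carry errors). The number of repeat
#' copies carrying the alternate allele is estimated as
#' round(copies x alt fraction), clamped to [1, copies - 1].
#'
#' @param pairs `read_pairs` data.frame with per-read sequences
#' @param collapsed_bgc [contig()] of the collapsed repeat
#' @param copies total repeat copy number (>= 2)
#' @param min_alt_depth minimum alternate-supporting reads (default 4)
#' @param min_alt_fraction minimum alternate fraction (default 0.1)
#' @param max_mismatch edit distance tolerated when clustering inserted
#'   sequences (default 0, exact)
#' @return data.frame of class `variant_calls`: chrom, pos, id, type
#'   (SNP/insertion), ref, alt, ins_seq, ad_ref, ad_alt, alt_fraction,
#'   est_copies, sorted by position
#' @export
pileup_variants <- function(pairs, collapsed_bgc, copies,
                            min_alt_depth = 4L, min_alt_fraction = 0.1,
                            max_mismatch = 0L) {
  if (copies < 2L) stop("copies < 2: a single copy cannot diverge")
  L <- collapsed_bgc$length
  m <- mates_of(pairs)
  m <- m[m$contig == collapsed_bgc$id, , drop = FALSE]
  if (nrow(m) == 0L) stop("no alignments on ", collapsed_bgc$id)

  simple <- grepl("^[0-9]+M$", m$cigar)
  pos_acc <- list(); base_acc <- list()
  span_start <- integer(0); span_end <- integer(0)
  ins_pos <- integer(0); ins_seq <- character(0)

  if (any(simple)) {
    ms <- m[simple, , drop = FALSE]
    lens <- as.integer(sub("M$", "", ms$cigar))
    pos_acc[[1]] <- sequence(lens, from = ms$pos)
    base_acc[[1]] <- BASE_LOOKUP[utf8ToInt(paste(ms$seq, collapse = ""))]
    span_start <- c(span_start, ms$pos)
    span_end <- c(span_end, ms$pos + lens - 1L)
  }
  for (i in which(!simple)) {
    w <- walk_cigar(m$cigar[i], m$pos[i], m$seq[i])
    for (b in w$blocks) {
      n <- b[["ref_end"]] - b[["ref_start"]] + 1L
      pos_acc[[length(pos_acc) + 1L]] <- seq.int(b[["ref_start"]],
                                                 b[["ref_end"]])
      base_acc[[length(base_acc) + 1L]] <- BASE_LOOKUP[
        utf8ToInt(substr(m$seq[i], b[["read_start"]],
                         b[["read_start"]] + n - 1L))]
      span_start <- c(span_start, b[["ref_start"]])
      span_end <- c(span_end, b[["ref_end"]])
    }
    for (e in w$ins) {
      if (e$ref_pos >= 1L) {
        ins_pos <- c(ins_pos, e$ref_pos)
        ins_seq <- c(ins_seq, e$seq)
      }
    }
  }
  all_pos <- unlist(pos_acc)
  all_base <- unlist(base_acc)
  inb <- all_pos >= 1L & all_pos <= L & all_base > 0L
  counts <- matrix(tabulate((all_base[inb] - 1L) * L + all_pos[inb],
                            nbins = 4L * L), nrow = L, ncol = 4L)
  colnames(counts) <- BASES

  ref_chars <- strsplit(collapsed_bgc$seq, "", fixed = TRUE)[[1]]
  ref_idx <- BASE_LOOKUP[utf8ToInt(collapsed_bgc$seq)]
  calls <- list()

  # --- SNPs -----------------------------------------------------------
  valid <- which(ref_idx > 0L)
  ref_count <- counts[cbind(valid, ref_idx[valid])]
  alt_counts <- counts[valid, , drop = FALSE]
  alt_counts[cbind(seq_along(valid), ref_idx[valid])] <- -1L
  alt_best <- max.col(alt_counts, ties.method = "first")
  alt_n <- alt_counts[cbind(seq_along(valid), alt_best)]
  informative <- ref_count + alt_n
  hit <- which(alt_n >= min_alt_depth & informative > 0 &
                 alt_n / informative >= min_alt_fraction)
  for (j in hit) {
    p <- valid[j]
    frac <- alt_n[j] / informative[j]
    calls[[length(calls) + 1L]] <- data.frame(
      chrom = collapsed_bgc$id, pos = p, type = "SNP",
      ref = ref_chars[p], alt = BASES[alt_best[j]], ins_seq = "",
      ad_ref = ref_count[j], ad_alt = alt_n[j], alt_fraction = frac,
      stringsAsFactors = FALSE)
  }

  # --- insertions -----------------------------------------------------
  if (length(ins_pos)) {
    key <- paste(ins_pos, ins_seq, sep = ":")
    clust <- data.frame(pos = ins_pos, seq = ins_seq, key = key,
                        stringsAsFactors = FALSE)
    tab <- as.data.frame(table(key = clust$key), stringsAsFactors = FALSE)
    tab$pos <- as.integer(sub(":.*$", "", tab$key))
    tab$seq <- sub("^[0-9]+:", "", tab$key)
    if (max_mismatch > 0L) {
      # fold near-identical clusters at the same junction into the
      # best-supported sequence
      for (p in unique(tab$pos)) {
        idx <- which(tab$pos == p)
        if (length(idx) < 2L) next
        idx <- idx[order(-tab$Freq[idx])]
        keep <- idx[1]
        for (i in idx[-1]) {
          if (adist(tab$seq[keep], tab$seq[i]) <= max_mismatch) {
            tab$Freq[keep] <- tab$Freq[keep] + tab$Freq[i]
            tab$Freq[i] <- 0L
          }
        }
      }
      tab <- tab[tab$Freq > 0L, , drop = FALSE]
    }
    # reads cleanly spanning each junction (no insertion there) support ref
    spans <- IRanges::IRanges(start = span_start,
                              end = pmax(span_start, span_end - 1L))
    for (i in seq_len(nrow(tab))) {
      p <- tab$pos[i]
      if (p < 1L || p >= L) next
      n_alt <- tab$Freq[i]
      n_span <- sum(IRanges::start(spans) <= p & IRanges::end(spans) >= p &
                      (span_end - span_start) >= 1L)
      n_ref <- max(0L, n_span)
      frac <- n_alt / (n_ref + n_alt)
      if (n_alt >= min_alt_depth && frac >= min_alt_fraction) {
        calls[[length(calls) + 1L]] <- data.frame(
          chrom = collapsed_bgc$id, pos = p, type = "insertion",
          ref = ref_chars[p], alt = paste0(ref_chars[p], tab$seq[i]),
          ins_seq = tab$seq[i], ad_ref = n_ref, ad_alt = n_alt,
          alt_fraction = frac, stringsAsFactors = FALSE)
      }
    }
  }

  if (length(calls) == 0L) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      id = character(0), type = character(0),
                      ref = character(0), alt = character(0),
                      ins_seq = character(0), ad_ref = integer(0),
                      ad_alt = integer(0), alt_fraction = numeric(0),
                      est_copies = integer(0), stringsAsFactors = FALSE)
    class(out) <- c("variant_calls", "data.frame")
    return(out)
  }
  out <- do.call(rbind, calls)
  out <- out[order(out$pos), , drop = FALSE]
  out$est_copies <- pmin(copies - 1L,
                         pmax(1L, as.integer(round_half_up(
                           copies * out$alt_fraction))))
  n_s <- cumsum(out$type == "SNP")
  n_i <- cumsum(out$type == "insertion")
  out$id <- ifelse(out$type == "SNP", paste0("SNP_", n_s),
                   paste0("INS_", n_i))
  out <- out[, c("chrom", "pos", "id", "type", "ref", "alt", "ins_seq",
                 "ad_ref", "ad_alt", "alt_fraction", "est_copies")]
  rownames(out) <- NULL
  class(out) <- c("variant_calls", "data.frame")
  out
}
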