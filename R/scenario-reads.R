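# Uniform paired-end read simulation from the (repeat-expanded) genome,
# and coordinate projection of the known fragment origins onto the
# collapsed assembly. Projection stands in for an external aligner: reads
# spanning a junction are soft-clipped to the contig holding the majority
# of the read, and insertions absent from the collapsed reference become I
# CIGAR operations (or clips at read edges).

#' Simulate paired-end read fragments with known origin
#'
#' Fragment left ends are uniform over valid positions of each replicon;
#' the pair count is chosen so total read bases / genome length matches
#' `depth`. Orientation is forward-reverse; reads are error-free unless
#' `error_rate` > 0.
#'
#' @param genome list of [contig()] (the true, repeat-expanded replicons)
#' @param read_length read length in bp
#' @param insert_mean,insert_sd fragment length distribution (mean must
#'   exceed `read_length`); replicons shorter than `insert_mean` are
#'   skipped with a warning
#' @param depth target mean depth
#' @param seed optional seed (uses the current RNG stream when NULL)
#' @param error_rate per-base substitution error probability
#' @return data.frame of class `sim_read_pairs`: read_id, replicon,
#'   frag_start, frag_len, seq1 (mate 1), seq2_fwd (mate 2 on the forward
#'   strand of the replicon)
#' @export
simulate_read_pairs <- function(genome, read_length = 150L,
                                insert_mean = 300, insert_sd = 30,
                                depth = 50, seed = NULL, error_rate = 0) {
  if (insert_mean <= read_length) stop("insert_mean must exceed read_length")
  if (depth <= 0) stop("depth must be positive")
  if (!is.null(seed)) set.seed(seed)
  empty <- data.frame(read_id = character(0), replicon = character(0),
                      frag_start = integer(0), frag_len = integer(0),
                      seq1 = character(0), seq2_fwd = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("sim_read_pairs", "data.frame")
  if (length(genome) == 0L) {
    warning("empty genome: no reads simulated")
    return(empty)
  }
  genome <- as_contig_set(genome)
  out <- list()
  for (ct in genome) {
    L <- ct$length
    if (L < insert_mean) {
      warning("replicon ", ct$id, " shorter than insert size; skipped")
      next
    }
    n <- as.integer(round(depth * L / (2 * read_length)))
    if (n == 0L) next
    flen <- pmax(read_length,
                 pmin(L, as.integer(round(rnorm(n, insert_mean,
                                                insert_sd)))))
    starts <- 1L + floor(runif(n) * (L - flen + 1))
    seq1 <- substring(ct$seq, starts, starts + read_length - 1L)
    seq2 <- substring(ct$seq, starts + flen - read_length,
                      starts + flen - 1L)
    if (error_rate > 0) {
      seq1 <- inject_errors(seq1, error_rate)
      seq2 <- inject_errors(seq2, error_rate)
    }
    out[[ct$id]] <- data.frame(
      read_id = sprintf("%s_p%06d", ct$id, seq_len(n)),
      replicon = ct$id, frag_start = as.integer(starts),
      frag_len = as.integer(flen), seq1 = seq1, seq2_fwd = seq2,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  class(res) <- c("sim_read_pairs", "data.frame")
  res
}

# Substitute random bases at the given per-base rate.
inject_errors <- function(seqs, rate) {
  n_err <- rbinom(1L, sum(nchar(seqs)), rate)
  if (n_err == 0L) return(seqs)
  width <- nchar(seqs[1])
  hit_read <- sample.int(length(seqs), n_err, replace = TRUE)
  hit_pos <- sample.int(width, n_err, replace = TRUE)
  for (i in seq_len(n_err)) {
    old <- substr(seqs[hit_read[i]], hit_pos[i], hit_pos[i])
    substr(seqs[hit_read[i]], hit_pos[i], hit_pos[i]) <-
      sample(setdiff(BASES, old), 1L)
  }
  seqs
}

#' Write simulated pairs as FASTQ
#'
#' Mate 2 is reverse-complemented (instrument orientation); qualities are
#' uniform maximum.
#'
#' @param sim `sim_read_pairs` data.frame
#' @param r1_path,r2_path output files
#' @return c(r1_path, r2_path), invisibly
#' @export
write_fastq <- function(sim, r1_path, r2_path) {
  qual1 <- strrep("I", nchar(sim$seq1))
  writeLines(as.vector(rbind(paste0("@", sim$read_id, "/1"),
                             sim$seq1, "+", qual1)), r1_path)
  r2 <- revcomp_many(sim$seq2_fwd)
  writeLines(as.vector(rbind(paste0("@", sim$read_id, "/2"),
                             r2, "+", strrep("I", nchar(r2)))), r2_path)
  invisible(c(r1_path, r2_path))
}

# ---- projection onto the collapsed assembly --------------------------

# A block map is a data.frame tiling replicon coordinates:
#   rep_start, rep_end, type ("M" collinear | "I" inserted), ref (contig
#   id), ref_start (type M), anchor (type I: reference position the
#   insertion follows).

# Project one mate interval [s, e]; returns list(contig, pos, cigar,
# alen) or NULL when the mate has no aligned block (e.g. fully inside an
# inserted segment).
project_mate <- function(map, s, e) {
  i1 <- findInterval(s, map$rep_start)
  i2 <- findInterval(e, map$rep_start)
  idx <- i1:i2
  ps <- pmax(s, map$rep_start[idx])
  pe <- pmin(e, map$rep_end[idx])
  len <- pe - ps + 1L
  type <- map$type[idx]
  ref <- map$ref[idx]
  refpos <- ifelse(type == "M",
                   map$ref_start[idx] + (ps - map$rep_start[idx]), NA)
  m_by_ref <- tapply(len[type == "M"], ref[type == "M"], sum)
  if (length(m_by_ref) == 0L) return(NULL)
  target <- names(m_by_ref)[which.max(m_by_ref)]
  op <- ifelse(type == "M" & ref == target, "M",
               ifelse(type == "I" & ref == target, "I", "S"))
  # leading/trailing insertions cannot anchor an alignment edge: clip them
  m_idx <- which(op == "M")
  first_m <- m_idx[1]; last_m <- m_idx[length(m_idx)]
  if (first_m > 1L) op[seq_len(first_m - 1L)] <- "S"
  if (last_m < length(op)) op[(last_m + 1L):length(op)] <- "S"
  # merge adjacent identical ops
  runs_len <- integer(0); runs_op <- character(0)
  for (j in seq_along(op)) {
    if (length(runs_op) && runs_op[length(runs_op)] == op[j]) {
      runs_len[length(runs_len)] <- runs_len[length(runs_len)] + len[j]
    } else {
      runs_op <- c(runs_op, op[j]); runs_len <- c(runs_len, len[j])
    }
  }
  list(contig = target, pos = as.integer(refpos[first_m]),
       cigar = paste0(runs_len, runs_op, collapse = ""),
       alen = sum(len[op == "M"]))
}

# Project all simulated pairs onto the collapsed assembly given per-
# replicon block maps. Returns a `read_pairs` data.frame; pairs with an
# unalignable mate are dropped (counted in a message).
project_pairs <- function(sim, maps, read_length) {
  if (nrow(sim) == 0L) return(empty_read_pairs())
  s1 <- sim$frag_start
  e1 <- s1 + read_length - 1L
  s2 <- sim$frag_start + sim$frag_len - read_length
  e2 <- sim$frag_start + sim$frag_len - 1L

  n <- nrow(sim)
  contig1 <- character(n); pos1 <- integer(n); cigar1 <- character(n)
  alen1 <- integer(n)
  contig2 <- character(n); pos2 <- integer(n); cigar2 <- character(n)
  alen2 <- integer(n)
  ok <- rep(TRUE, n)

  for (rep_id in unique(sim$replicon)) {
    map <- maps[[rep_id]]
    rows <- which(sim$replicon == rep_id)
    # fast path: mate falls inside a single collinear block
    for (mate in 1:2) {
      ms <- if (mate == 1L) s1[rows] else s2[rows]
      me <- if (mate == 1L) e1[rows] else e2[rows]
      blk <- findInterval(ms, map$rep_start)
      simple <- map$type[blk] == "M" & me <= map$rep_end[blk]
      ctg <- map$ref[blk]
      pp <- map$ref_start[blk] + (ms - map$rep_start[blk])
      cg <- paste0(read_length, "M")
      for (k in which(!simple)) {
        pr <- project_mate(map, ms[k], me[k])
        if (is.null(pr)) { ok[rows[k]] <- FALSE; next }
        ctg[k] <- pr$contig; pp[k] <- pr$pos; cg_k <- pr$cigar
        if (mate == 1L) {
          contig1[rows[k]] <- pr$contig; pos1[rows[k]] <- pr$pos
          cigar1[rows[k]] <- cg_k; alen1[rows[k]] <- pr$alen
        } else {
          contig2[rows[k]] <- pr$contig; pos2[rows[k]] <- pr$pos
          cigar2[rows[k]] <- cg_k; alen2[rows[k]] <- pr$alen
        }
      }
      w <- which(simple)
      if (mate == 1L) {
        contig1[rows[w]] <- ctg[w]; pos1[rows[w]] <- pp[w]
        cigar1[rows[w]] <- cg; alen1[rows[w]] <- read_length
      } else {
        contig2[rows[w]] <- ctg[w]; pos2[rows[w]] <- pp[w]
        cigar2[rows[w]] <- cg; alen2[rows[w]] <- read_length
      }
    }
  }
  if (any(!ok)) {
    message("dropped ", sum(!ok), " pair(s) without an aligned block")
  }
  out <- data.frame(
    read_id = sim$read_id[ok],
    contig1 = contig1[ok], pos1 = pos1[ok], alen1 = alen1[ok],
    strand1 = "+", cigar1 = cigar1[ok], seq1 = sim$seq1[ok],
    contig2 = contig2[ok], pos2 = pos2[ok], alen2 = alen2[ok],
    strand2 = "-", cigar2 = cigar2[ok], seq2 = sim$seq2_fwd[ok],
    stringsAsFactors = FALSE)
  out$proper_pair <- out$contig1 == out$contig2
  class(out) <- c("read_pairs", "data.frame")
  out
}
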