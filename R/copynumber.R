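# Copy-number inference for a collapsed repeat: depth ratios, terminal
# junction evidence from read pairs and the assembly graph, a reconciled
# segment-wise repeat model, and pileup variant detection.

# Run expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Flatten pairs to one row per mate: contig, pos, alen, cigar, seq.
mates_of <- function(pairs) {
  data.frame(
    contig = c(pairs$contig1, pairs$contig2),
    pos = c(pairs$pos1, pairs$pos2),
    alen = c(pairs$alen1, pairs$alen2),
    cigar = c(pairs$cigar1, pairs$cigar2),
    seq = c(pairs$seq1, pairs$seq2),
    stringsAsFactors = FALSE)
}

# Per-base coverage vector of one contig from aligned mate spans.
contig_coverage <- function(pairs, ct) {
  m <- mates_of(pairs)
  m <- m[m$contig == ct$id & m$pos <= ct$length, , drop = FALSE]
  if (nrow(m) == 0L) return(numeric(ct$length))
  ir <- IRanges::IRanges(start = m$pos,
                         end = pmin(m$pos + m$alen - 1L, ct$length))
  as.numeric(IRanges::coverage(ir, width = ct$length))
}

#' Depth summary of a region from paired-end alignments
#'
#' Per-base depth is computed from alignment reference spans; the mean over
#' the region is reported with a 95% bootstrap confidence interval obtained
#' by resampling non-overlapping windows.
#'
#' @param pairs `read_pairs` data.frame ([read_sam_pairs()])
#' @param contig [contig()] the region lives on
#' @param region `c(start, end)` 1-based inclusive; default whole contig
#' @param window tiling window size in bp (default 1000)
#' @param n_boot bootstrap resamples (default 1000)
#' @param seed RNG seed for the bootstrap
#' @return list of class `depth_summary`: region_id, mean_depth,
#'   window_depths, ci (2-vector), region
#' @export
depth_summary <- function(pairs, contig, region = NULL, window = 1000L,
                          n_boot = 1000L, seed = 1L) {
  if (nrow(pairs) == 0L) stop("empty alignment set")
  if (is.null(region)) region <- c(1L, contig$length)
  stopifnot(region[1] >= 1L, region[2] <= contig$length,
            region[1] <= region[2])
  cov <- contig_coverage(pairs, contig)[region[1]:region[2]]
  reg_len <- length(cov)
  region_id <- sprintf("%s:%d-%d", contig$id, region[1], region[2])
  if (all(cov == 0)) {
    warning("region ", region_id, " has zero coverage")
    return(structure(list(region_id = region_id, mean_depth = 0,
                          window_depths = numeric(0), ci = c(0, 0),
                          region = region), class = "depth_summary"))
  }
  n_win <- max(1L, reg_len %/% window)
  breaks <- floor(seq(0L, reg_len, length.out = n_win + 1L))
  win_means <- vapply(seq_len(n_win), function(i) {
    mean(cov[(breaks[i] + 1L):breaks[i + 1L]])
  }, numeric(1))
  ci <- if (n_win >= 2L) {
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      mean(win_means[sample.int(n_win, n_win, replace = TRUE)])
    }, numeric(1)))
    unname(quantile(boots, c(0.025, 0.975)))
  } else c(mean(cov), mean(cov))
  structure(list(region_id = region_id, mean_depth = mean(cov),
                 window_depths = win_means, ci = ci, region = region),
            class = "depth_summary")
}

#' Reference depth of the host bin
#'
#' Aggregates per-contig mean depths over the bin's contigs (excluding the
#' focus repeat contig); the median is the default aggregation, robust to
#' individual outlier contigs.
#'
#' @param pairs `read_pairs` data.frame
#' @param contigs list of [contig()]
#' @param exclude contig ids to leave out (the repeat contig)
#' @param aggregate "median" (default) or "mean"
#' @return scalar reference depth
#' @export
bin_reference_depth <- function(pairs, contigs, exclude = character(0),
                                aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  contigs <- as_contig_set(contigs)
  keep <- setdiff(names(contigs), exclude)
  if (length(keep) == 0L) stop("no contigs left after exclusion")
  depths <- vapply(contigs[keep],
                   function(ct) mean(contig_coverage(pairs, ct)),
                   numeric(1))
  if (aggregate == "median") median(depths) else mean(depths)
}

#' Integer copy number from a depth ratio
#'
#' @param bgc_depth mean depth of the repeat region
#' @param genome_depth reference depth of the genome/bin (> 0)
#' @return list(ratio, copies): copies = round(ratio) (half away from
#'   zero), minimum 1
#' @export
estimate_copy_number <- function(bgc_depth, genome_depth) {
  if (!is.finite(genome_depth) || genome_depth <= 0) {
    stop("genome depth must be positive")
  }
  ratio <- bgc_depth / genome_depth
  list(ratio = ratio, copies = max(1L, as.integer(round_half_up(ratio))))
}

# Median insert size from same-contig proper pairs.
estimate_insert_size <- function(pairs) {
  same <- pairs[pairs$contig1 == pairs$contig2, , drop = FALSE]
  if (nrow(same) == 0L) return(NA_real_)
  left <- pmin(same$pos1, same$pos2)
  right <- pmax(same$pos1 + same$alen1, same$pos2 + same$alen2) - 1L
  median(right - left + 1L)
}

#' Junction evidence at the ends of a focus contig
#'
#' A partner is any contig receiving at least `min_support` read pairs
#' with one mate in an end window of the focus contig and the other mate
#' in an end window of the partner. Partners whose focus-side mates
#' cluster away from both termini are reported separately as internal
#' attachment points with their median offset from the 5' end — the
#' signature of a repeat copy missing a terminal segment. Partners are
#' marked graph-confirmed when a GFA edge joins the same contig ends.
#'
#' @param pairs `read_pairs` data.frame
#' @param focus focus contig id
#' @param contigs list of [contig()] (for lengths)
#' @param graph optional [assembly_graph()]
#' @param end_window bp from each terminus counted as "terminal"; default
#'   2x the median insert size estimated from the pairs
#' @param min_support minimum read-pair support per partner (default 3)
#' @return list of class `junction_evidence`: `focus`, `end_window`,
#'   `partners` (data.frame: end in 5p/3p/internal, partner, support,
#'   partner_end, offset, graph_confirmed)
#' @export
count_junctions <- function(pairs, focus, contigs, graph = NULL,
                            end_window = NULL, min_support = 3L) {
  contigs <- as_contig_set(contigs)
  if (!focus %in% names(contigs)) stop("focus contig not in assembly")
  if (is.null(end_window)) {
    ins <- estimate_insert_size(pairs)
    if (is.na(ins)) stop("cannot estimate insert size; give end_window")
    end_window <- 2 * ins
  }
  L <- contigs[[focus]]$length
  empty <- data.frame(end = character(0), partner = character(0),
                      support = integer(0), partner_end = character(0),
                      offset = numeric(0), graph_confirmed = logical(0),
                      stringsAsFactors = FALSE)
  on1 <- pairs$contig1 == focus
  on2 <- pairs$contig2 == focus
  if (!any(on1 | on2)) {
    warning("no alignments on focus contig ", focus)
    return(structure(list(focus = focus, end_window = end_window,
                          min_support = min_support, partners = empty),
                     class = "junction_evidence"))
  }
  cross <- xor(on1, on2)
  cp <- pairs[cross, , drop = FALSE]
  if (nrow(cp) == 0L) {
    return(structure(list(focus = focus, end_window = end_window,
                          min_support = min_support, partners = empty),
                     class = "junction_evidence"))
  }
  f_is_1 <- cp$contig1 == focus
  f_pos <- ifelse(f_is_1, cp$pos1, cp$pos2)
  f_end <- f_pos + ifelse(f_is_1, cp$alen1, cp$alen2) - 1
  p_id <- ifelse(f_is_1, cp$contig2, cp$contig1)
  p_pos <- ifelse(f_is_1, cp$pos2, cp$pos1)
  p_aln <- ifelse(f_is_1, cp$alen2, cp$alen1)

  # partner mate must itself sit in a partner end window
  p_len <- vapply(contigs[p_id], `[[`, numeric(1), "length")
  near_p5 <- p_pos <= end_window
  near_p3 <- (p_pos + p_aln - 1) >= p_len - end_window + 1
  keep <- near_p5 | near_p3
  cp <- cp[keep, , drop = FALSE]
  if (nrow(cp) == 0L) {
    return(structure(list(focus = focus, end_window = end_window,
                          min_support = min_support, partners = empty),
                     class = "junction_evidence"))
  }
  f_pos <- f_pos[keep]; f_end <- f_end[keep]; p_id <- p_id[keep]
  d5 <- p_pos[keep]; d3 <- (p_len - (p_pos + p_aln - 1))[keep]
  partner_end <- ifelse(d5 <= d3, "5p", "3p")

  rows <- lapply(split(seq_along(p_id), p_id), function(idx) {
    med_start <- median(f_pos[idx])
    med_end <- median(f_end[idx])
    end_class <- if (med_start <= end_window) "5p"
      else if (med_end >= L - end_window + 1) "3p"
      else "internal"
    pe <- names(sort(table(partner_end[idx]), decreasing = TRUE))[1]
    data.frame(end = end_class, partner = p_id[idx][1],
               support = length(idx), partner_end = pe,
               offset = if (end_class == "internal") med_start else NA_real_,
               stringsAsFactors = FALSE)
  })
  partners <- do.call(rbind, rows)
  partners <- partners[partners$support >= min_support, , drop = FALSE]
  partners$graph_confirmed <- logical(nrow(partners))
  if (!is.null(graph) && nrow(partners)) {
    for (i in seq_len(nrow(partners))) {
      if (partners$end[i] %in% c("5p", "3p")) {
        partners$graph_confirmed[i] <- graph_has_edge(
          graph, focus, partners$end[i],
          partners$partner[i], partners$partner_end[i])
      }
    }
  }
  rownames(partners) <- NULL
  structure(list(focus = focus, end_window = end_window,
                 min_support = min_support, partners = partners),
            class = "junction_evidence")
}

#' @export
print.junction_evidence <- function(x, ...) {
  cat(sprintf("<junctions of %s (end window %g bp, min support %d)>\n",
              x$focus, x$end_window, x$min_support))
  print(x$partners)
  invisible(x)
}

#' Reconcile a segment-wise repeat model from depth and junctions
#'
#' Internal attachment points split the collapsed repeat contig into
#' segments; each segment's copy number is the rounded ratio of its mean
#' depth to the bin reference depth. Consistency checks compare the body
#' segment's copies with the number of 3' partners and the leading
#' segment's copies with the number of terminal 5' partners; disagreements
#' are flagged, never silently fixed.
#'
#' @param pairs `read_pairs` data.frame
#' @param contigs list of [contig()] (collapsed assembly)
#' @param focus repeat contig id
#' @param genome_depth reference depth; computed with
#'   [bin_reference_depth()] when NULL
#' @param junctions optional precomputed [count_junctions()] result
#' @param graph optional [assembly_graph()]
#' @param window depth window (default 1000 bp); segments shorter than one
#'   window are merged into their neighbor with a warning
#' @param seed RNG seed for depth bootstraps
#' @return list of class `repeat_model`: segments (data.frame: segment_id,
#'   start, end, mean_depth, ratio, copies), junctions, genome_depth,
#'   flags (character), consistent (logical)
#' @export
reconcile_repeat_model <- function(pairs, contigs, focus,
                                   genome_depth = NULL, junctions = NULL,
                                   graph = NULL, window = 1000L,
                                   seed = 1L) {
  contigs <- as_contig_set(contigs)
  ct <- contigs[[focus]]
  if (is.null(ct)) stop("focus contig not in assembly")
  if (is.null(genome_depth)) {
    genome_depth <- bin_reference_depth(pairs, contigs, exclude = focus)
  }
  if (is.null(junctions)) {
    junctions <- count_junctions(pairs, focus, contigs, graph = graph)
  }
  internal <- junctions$partners[junctions$partners$end == "internal", ,
                                 drop = FALSE]
  breaks <- sort(unique(round(internal$offset)))
  breaks <- breaks[breaks > 1 & breaks < ct$length]
  bounds <- unique(c(1, breaks, ct$length + 1))
  # merge segments shorter than one window into their neighbor
  while (length(bounds) > 2 && any(diff(bounds) < window)) {
    i <- which(diff(bounds) < window)[1]
    drop <- if (i == 1) 2 else i
    warning("repeat segment shorter than one window; merged into neighbor")
    bounds <- bounds[-drop]
  }
  n_seg <- length(bounds) - 1
  segs <- lapply(seq_len(n_seg), function(i) {
    region <- c(bounds[i], bounds[i + 1] - 1)
    ds <- depth_summary(pairs, ct, region = region, window = window,
                        n_boot = 200L, seed = seed + i)
    est <- estimate_copy_number(ds$mean_depth, genome_depth)
    data.frame(segment_id = sprintf("seg%d", i),
               start = region[1], end = region[2],
               mean_depth = ds$mean_depth, ratio = est$ratio,
               copies = est$copies, stringsAsFactors = FALSE)
  })
  segments <- do.call(rbind, segs)

  pj <- junctions$partners
  n3 <- sum(pj$end == "3p")
  n5 <- sum(pj$end == "5p")
  flags <- character(0)
  body_copies <- segments$copies[n_seg]
  lead_copies <- segments$copies[1]
  if (n3 > 0 && body_copies != n3) {
    flags <- c(flags, sprintf(
      "body segment depth implies %d copies but %d 3' junction partner(s)",
      body_copies, n3))
  }
  if (n5 > 0 && lead_copies != n5) {
    flags <- c(flags, sprintf(
      "leading segment depth implies %d copies but %d terminal 5' partner(s)",
      lead_copies, n5))
  }
  structure(list(segments = segments, junctions = junctions,
                 genome_depth = genome_depth, flags = flags,
                 consistent = length(flags) == 0L),
            class = "repeat_model")
}

#' @export
print.repeat_model <- function(x, ...) {
  cat(sprintf("<repeat model (reference depth %.2fx)>\n", x$genome_depth))
  print(x$segments, digits = 4)
  if (length(x$flags)) {
    cat("INCONSISTENT:\n"); cat(paste0("  - ", x$flags, "\n"))
  } else cat("depth and junction evidence consistent\n")
  invisible(x)
}
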