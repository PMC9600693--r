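# Full scenario assembly: contig layout, variant injection, the
# repeat-expanded genome with its block maps, and file emission.

# The three published repeat-divergence insertion sequences (60, 24 and
# 54 bp; all multiples of three).
DEFAULT_INSERTION_SEQS <- c(
  paste(rep("GGAGGATGGGGT", 5), collapse = ""),
  paste(rep("GGGGTCGGATGG", 2), collapse = ""),
  paste(rep("GCGGCGGTTGAGGCGGAG", 3), collapse = ""))

# Embed genes in a contig with i.i.d. spacers at `gc`. Returns
# list(seq, coords = data.frame(gene_id, start, end, strand)).
layout_contig <- function(cds, gene_ids, target_length, gc, strands) {
  total_gene <- sum(nchar(cds))
  n <- length(cds)
  spare <- target_length - total_gene
  n_slots <- n + 1L
  if (spare < 2L * n_slots) spare <- 2L * n_slots
  sp <- rep(spare %/% n_slots, n_slots)
  sp[seq_len(spare %% n_slots)] <- sp[seq_len(spare %% n_slots)] + 1L
  pieces <- character(2L * n + 1L)
  starts <- integer(n); ends <- integer(n)
  cursor <- 0L
  for (i in seq_len(n)) {
    pieces[2L * i - 1L] <- random_dna(sp[i], gc)
    cursor <- cursor + sp[i]
    embedded <- if (strands[i] == "-") revcomp(cds[i]) else cds[i]
    pieces[2L * i] <- embedded
    starts[i] <- cursor + 1L
    ends[i] <- cursor + nchar(embedded)
    cursor <- ends[i]
  }
  pieces[2L * n + 1L] <- random_dna(sp[n_slots], gc)
  list(seq = paste(pieces, collapse = ""),
       coords = data.frame(gene_id = gene_ids, start = starts, end = ends,
                           strand = strands, stringsAsFactors = FALSE))
}

# Derive the default variant set from the realized BGC layout: the three
# published insertion sequences at scaled in-CDS positions, one
# synonymous C->T SNP on a TAC codon, one intergenic A->G SNP just past
# the last gene. May rewrite one intergenic base of bgc_seq (to plant the
# intergenic A). Positions must respect the realized codon structure,
# which is why this runs after layout.
derive_default_variants <- function(bgc_seq, coords, bgc_length,
                                    copy_number) {
  pick_copthan <- function(k) min(k, copy_number)
  anchor <- function(p98) as.integer(round(p98 / 98000 * bgc_length))

  in_cds_position <- function(target) {
    margin <- 15L
    inside <- coords$start + margin <= target & target <= coords$end - margin
    if (any(inside)) return(target)
    mid <- (coords$start + coords$end) %/% 2L
    mid[which.min(abs(mid - target))]
  }
  ins_pos <- vapply(anchor(c(15246L, 24776L, 67976L)), in_cds_position,
                    integer(1))
  ins_copies <- list(pick_copthan(2), pick_copthan(3), pick_copthan(2))
  insertions <- data.frame(pos = ins_pos, seq = DEFAULT_INSERTION_SEQS,
                           copies = vapply(ins_copies, paste,
                                           character(1), collapse = ","),
                           stringsAsFactors = FALSE)

  # synonymous SNP: third base of a TAC codon, C->T (tyrosine/tyrosine)
  snp1_target <- anchor(93995L)
  best <- NULL
  for (i in seq_len(nrow(coords))) {
    if (coords$strand[i] != "+") next
    cds <- substr(bgc_seq, coords$start[i], coords$end[i])
    cods <- split_codons(cds)
    hits <- which(cods == "TAC")
    if (length(hits) == 0L) next
    gpos <- coords$start[i] + 3L * hits - 1L  # genomic pos of codon base 3
    j <- which.min(abs(gpos - snp1_target))
    if (is.null(best) || abs(gpos[j] - snp1_target) < abs(best - snp1_target))
      best <- gpos[j]
  }
  if (is.null(best)) stop("no TAC codon available for the synonymous SNP")

  # intergenic SNP just past the last gene
  snp2_pos <- max(coords$end) + 4L
  if (snp2_pos > bgc_length) snp2_pos <- max(coords$end) + 1L
  if (substr(bgc_seq, snp2_pos, snp2_pos) != "A") {
    substr(bgc_seq, snp2_pos, snp2_pos) <- "A"
  }
  snps <- data.frame(
    pos = c(best, snp2_pos), ref = c("C", "A"), alt = c("T", "G"),
    copies = c(as.character(pick_copthan(3)),
               paste(unique(c(pick_copthan(2), pick_copthan(3))),
                     collapse = ",")),
    stringsAsFactors = FALSE)
  list(insertions = insertions, snps = snps, bgc_seq = bgc_seq)
}

# Build one BGC copy sequence plus its block map onto the collapsed
# reference. `carried_ins`/`carried_snp` are logical selectors.
make_bgc_copy <- function(bgc_seq, bgc_id, insertions, snps, carried_ins,
                          carried_snp, drop_leading, lead_len) {
  seq <- bgc_seq
  for (i in which(carried_snp)) {
    substr(seq, snps$pos[i], snps$pos[i]) <- snps$alt[i]
  }
  ref_from <- if (drop_leading) lead_len + 1L else 1L
  L <- nchar(bgc_seq)
  ins <- insertions[carried_ins & insertions$pos >= ref_from, ,
                    drop = FALSE]
  ins <- ins[order(ins$pos), , drop = FALSE]
  bounds <- c(ref_from - 1L, ins$pos, L)
  pieces <- character(0)
  blocks <- list()
  cursor <- 0L
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i] + 1L; b <- bounds[i + 1L]
    pieces <- c(pieces, substr(seq, a, b))
    blocks[[length(blocks) + 1L]] <- data.frame(
      rep_start = cursor + 1L, rep_end = cursor + (b - a + 1L),
      type = "M", ref = bgc_id, ref_start = a, anchor = NA_integer_,
      stringsAsFactors = FALSE)
    cursor <- cursor + (b - a + 1L)
    if (i <= nrow(ins)) {
      iseq <- ins$seq[i]
      pieces <- c(pieces, iseq)
      blocks[[length(blocks) + 1L]] <- data.frame(
        rep_start = cursor + 1L, rep_end = cursor + nchar(iseq),
        type = "I", ref = bgc_id, ref_start = NA_integer_,
        anchor = ins$pos[i], stringsAsFactors = FALSE)
      cursor <- cursor + nchar(iseq)
    }
  }
  list(seq = paste(pieces, collapse = ""),
       map = do.call(rbind, blocks))
}

#' Build a complete synthetic scenario
#'
#' Deterministic given `config$seed`. Generates the gene layer, lays host
#' and BGC genes out on contigs, derives (or takes) the injected variant
#' set, constructs the repeat-expanded genome (the BGC occurring
#' `bgc_copy_number` times in distinct host contexts, one copy per missing
#' leading segment), simulates uniform paired-end reads from it and
#' projects them onto the collapsed assembly (host contigs plus a single
#' BGC contig), fabricates the homolog-length table, and optionally writes
#' everything to `outdir`.
#'
#' Files written: assembly.fasta, genome_expanded.fasta, genes.gff3,
#' categories.tsv, reads.sam, reads_R1.fastq/reads_R2.fastq,
#' assembly.gfa, homologs.tsv, truth.json.
#'
#' @param config [scenario_config()]
#' @param outdir output directory (created); NULL to skip writing
#' @param simulate_reads set FALSE to skip read simulation (gene/contig
#'   layers only; much faster for composition-only studies)
#' @return list of class `scenario`: config, contigs (collapsed assembly),
#'   genes (list of [gene_record()]), graph, pairs (`read_pairs`), sim
#'   (raw fragments), homologs, truth, files
#' @export
build_scenario <- function(config, outdir = NULL, simulate_reads = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  if (2L * config$bgc_copy_number > config$n_host_contigs) {
    stop("need at least 2 x bgc_copy_number host contigs for distinct ",
         "flanking contexts")
  }
  gene_layer <- simulate_gene_set(config)  # sets the seed
  gdf <- gene_layer$genes

  # --- host contigs ---------------------------------------------------
  host_df <- gdf[gdf$category != "bgc", , drop = FALSE]
  host_df <- host_df[sample.int(nrow(host_df)), , drop = FALSE]
  n_host <- config$n_host_contigs
  grp <- rep(seq_len(n_host), length.out = nrow(host_df))
  target <- config$host_length %/% n_host
  contigs <- list()
  coords_all <- list()
  for (j in seq_len(n_host)) {
    rows <- host_df[grp == j, , drop = FALSE]
    strands <- sample(c("+", "-"), nrow(rows), replace = TRUE)
    lay <- layout_contig(rows$cds_seq, rows$gene_id, target,
                         config$host_gc, strands)
    id <- sprintf("host_%02d", j)
    contigs[[id]] <- contig(id, lay$seq)
    lay$coords$contig_id <- id
    coords_all[[id]] <- lay$coords
  }

  # --- BGC contig -----------------------------------------------------
  bgc_df <- gdf[gdf$category == "bgc", , drop = FALSE]
  if (sum(nchar(bgc_df$cds_seq)) > 0.95 * config$bgc_length) {
    stop("bgc genes exceed 95% of bgc_length; reduce n_genes['bgc'] or ",
         "grow bgc_length")
  }
  lay <- layout_contig(bgc_df$cds_seq, bgc_df$gene_id, config$bgc_length,
                       config$bgc_gc, rep("+", nrow(bgc_df)))
  bgc_id <- "bgc_1"
  bgc_seq <- lay$seq
  bgc_coords <- lay$coords
  bgc_coords$contig_id <- bgc_id

  # --- variants -------------------------------------------------------
  if (is.null(config$insertion_specs) || is.null(config$snp_specs)) {
    if (config$bgc_copy_number >= 2L) {
      dv <- derive_default_variants(bgc_seq, bgc_coords,
                                    config$bgc_length,
                                    config$bgc_copy_number)
      bgc_seq <- dv$bgc_seq
      insertions <- if (is.null(config$insertion_specs)) dv$insertions
        else config$insertion_specs
      snps <- if (is.null(config$snp_specs)) dv$snps else config$snp_specs
    } else {
      insertions <- data.frame(pos = integer(0), seq = character(0),
                               copies = character(0))
      snps <- data.frame(pos = integer(0), ref = character(0),
                         alt = character(0), copies = character(0))
    }
  } else {
    insertions <- config$insertion_specs
    snps <- config$snp_specs
  }
  if (nrow(snps)) {
    have <- substring(bgc_seq, snps$pos, snps$pos)
    if (any(have != snps$ref)) {
      stop("snp_specs ref base disagrees with generated BGC sequence")
    }
  }
  parse_copies <- function(s) as.integer(strsplit(s, ",")[[1]])
  ins_copies <- lapply(insertions$copies, parse_copies)
  snp_copies <- lapply(snps$copies, parse_copies)

  contigs[[bgc_id]] <- contig(bgc_id, bgc_seq)
  contigs <- as_contig_set(contigs)

  # --- gene records on the collapsed assembly -------------------------
  coords <- do.call(rbind, c(coords_all, list(bgc_coords),
                             list(make.row.names = FALSE)))
  cat_of <- setNames(gdf$category, gdf$gene_id)
  genes <- lapply(seq_len(nrow(coords)), function(i) {
    gene_record(coords$gene_id[i], coords$contig_id[i], coords$start[i],
                coords$end[i], coords$strand[i],
                cat_of[[coords$gene_id[i]]],
                contig = contigs[[coords$contig_id[i]]])
  })

  # --- repeat-expanded genome and block maps --------------------------
  ncopy <- config$bgc_copy_number
  n_missing <- ncopy - config$leading_segment_copies
  replicons <- list()
  maps <- list()
  used_host <- character(0)
  for (i in seq_len(ncopy)) {
    hostA <- contigs[[sprintf("host_%02d", 2L * i - 1L)]]
    hostB <- contigs[[sprintf("host_%02d", 2L * i)]]
    used_host <- c(used_host, hostA$id, hostB$id)
    copy <- make_bgc_copy(
      bgc_seq, bgc_id, insertions, snps,
      carried_ins = vapply(ins_copies, function(cc) i %in% cc, logical(1)),
      carried_snp = vapply(snp_copies, function(cc) i %in% cc, logical(1)),
      drop_leading = i <= n_missing,
      lead_len = config$leading_segment_length)
    rep_id <- sprintf("replicon_%d", i)
    seq <- paste0(hostA$seq, copy$seq, hostB$seq)
    copy_map <- copy$map
    copy_map$rep_start <- copy_map$rep_start + hostA$length
    copy_map$rep_end <- copy_map$rep_end + hostA$length
    map <- rbind(
      data.frame(rep_start = 1L, rep_end = hostA$length, type = "M",
                 ref = hostA$id, ref_start = 1L, anchor = NA_integer_,
                 stringsAsFactors = FALSE),
      copy_map,
      data.frame(rep_start = hostA$length + nchar(copy$seq) + 1L,
                 rep_end = hostA$length + nchar(copy$seq) + hostB$length,
                 type = "M", ref = hostB$id, ref_start = 1L,
                 anchor = NA_integer_, stringsAsFactors = FALSE))
    replicons[[rep_id]] <- contig(rep_id, seq)
    maps[[rep_id]] <- map
  }
  for (id in setdiff(names(contigs), c(used_host, bgc_id))) {
    rep_id <- paste0("replicon_", id)
    replicons[[rep_id]] <- contig(rep_id, contigs[[id]]$seq)
    maps[[rep_id]] <- data.frame(
      rep_start = 1L, rep_end = contigs[[id]]$length, type = "M",
      ref = id, ref_start = 1L, anchor = NA_integer_,
      stringsAsFactors = FALSE)
  }

  # --- assembly graph (terminal junctions of the collapsed assembly) --
  edges <- list()
  for (i in seq_len(ncopy)) {
    hostA_id <- sprintf("host_%02d", 2L * i - 1L)
    hostB_id <- sprintf("host_%02d", 2L * i)
    if (i > n_missing) {  # full-leading copies attach at the 5' terminus
      edges[[length(edges) + 1L]] <- data.frame(
        from = hostA_id, from_end = "3p", to = bgc_id, to_end = "5p",
        stringsAsFactors = FALSE)
    }
    edges[[length(edges) + 1L]] <- data.frame(
      from = bgc_id, from_end = "3p", to = hostB_id, to_end = "5p",
      stringsAsFactors = FALSE)
  }
  graph <- assembly_graph(names(contigs),
                          if (length(edges)) do.call(rbind, edges)
                          else data.frame(from = character(0),
                                          from_end = character(0),
                                          to = character(0),
                                          to_end = character(0)))

  # --- reads ----------------------------------------------------------
  sim <- NULL; pairs <- empty_read_pairs()
  if (simulate_reads) {
    sim <- simulate_read_pairs(replicons, config$read_length,
                               config$insert_mean, config$insert_sd,
                               config$depth,
                               error_rate = config$error_rate)
    pairs <- project_pairs(sim, maps, config$read_length)
  }

  # --- truth and homologs ---------------------------------------------
  variants <- rbind(
    if (nrow(insertions)) data.frame(
      pos = insertions$pos, type = "insertion", ref = "", alt = "",
      ins_seq = insertions$seq, copies = insertions$copies,
      n_copies = lengths(ins_copies), stringsAsFactors = FALSE),
    if (nrow(snps)) data.frame(
      pos = snps$pos, type = "SNP", ref = snps$ref, alt = snps$alt,
      ins_seq = "", copies = snps$copies, n_copies = lengths(snp_copies),
      stringsAsFactors = FALSE))
  if (is.null(variants)) {
    variants <- data.frame(pos = integer(0), type = character(0),
                           ref = character(0), alt = character(0),
                           ins_seq = character(0), copies = character(0),
                           n_copies = integer(0))
  }
  variants <- variants[order(variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  truth <- list(
    bgc_contig = bgc_id,
    host_contigs = setdiff(names(contigs), bgc_id),
    copy_number = ncopy,
    leading_segment_copies = config$leading_segment_copies,
    leading_segment_length = config$leading_segment_length,
    n_missing_leading = n_missing,
    variants = variants,
    categories = setNames(gdf$category, gdf$gene_id),
    pseudogene_ids = gdf$gene_id[gdf$category == "pseudogene"],
    truncation_fraction = config$pseudogene_truncation_fraction,
    depth = config$depth)
  homologs <- make_homolog_table(gdf, truth)

  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      assembly = file.path(outdir, "assembly.fasta"),
      genome = file.path(outdir, "genome_expanded.fasta"),
      gff = file.path(outdir, "genes.gff3"),
      categories = file.path(outdir, "categories.tsv"),
      sam = file.path(outdir, "reads.sam"),
      fastq_r1 = file.path(outdir, "reads_R1.fastq"),
      fastq_r2 = file.path(outdir, "reads_R2.fastq"),
      gfa = file.path(outdir, "assembly.gfa"),
      homologs = file.path(outdir, "homologs.tsv"),
      truth = file.path(outdir, "truth.json"))
    write_fasta(contigs, files$assembly)
    write_fasta(replicons, files$genome)
    write_gff_genes(genes, files$gff, files$categories)
    if (simulate_reads) {
      write_sam_pairs(pairs, contigs, files$sam)
      write_fastq(sim, files$fastq_r1, files$fastq_r2)
    }
    write_gfa(graph, contigs = NULL, path = files$gfa)
    write_homolog_table(homologs, files$homologs)
    jsonlite::write_json(truth, files$truth, auto_unbox = TRUE,
                         digits = NA)
  }

  structure(list(config = config, contigs = contigs, genes = genes,
                 graph = graph, pairs = pairs, sim = sim,
                 homologs = homologs, truth = truth, replicons = replicons,
                 maps = maps, files = files),
            class = "scenario")
}
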