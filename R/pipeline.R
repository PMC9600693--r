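# Pipeline orchestration: run the evidence stages end to end and emit
# machine-readable tables plus a plain-text summary. The lines of
# evidence are independent, so missing inputs skip stages (logged)
# rather than aborting the run.

#' Pipeline run configuration
#'
#' Exactly one of synthetic mode (`scenario` set) or real-input mode
#' (paths set) is active.
#'
#' @param scenario optional [scenario_config()] for synthetic mode
#' @param assembly,gff,categories,sam,gfa,homologs optional input paths
#'   (real-input mode)
#' @param bgc_contig focus repeat contig id (default "bgc_1")
#' @param alpha significance threshold for the category contrasts
#' @param min_support junction read-pair support threshold
#' @param pseudogene_cutoff homolog length-ratio cutoff
#' @param cai_pseudocount pseudocount for unobserved reference codons
#' @param seed seed for every stochastic step
#' @param outdir output directory
#' @return list of class `run_config`
#' @export
run_config <- function(scenario = NULL, assembly = NULL, gff = NULL,
                       categories = NULL, sam = NULL, gfa = NULL,
                       homologs = NULL, bgc_contig = "bgc_1",
                       alpha = 0.05, min_support = 3L,
                       pseudogene_cutoff = 0.8, cai_pseudocount = 0.5,
                       seed = 1L, outdir = "symbgc_out") {
  synthetic <- !is.null(scenario)
  real <- !is.null(assembly)
  if (synthetic == real) {
    stop("exactly one of synthetic mode (scenario) or real-input mode ",
         "(assembly path) must be active")
  }
  structure(list(scenario = scenario, assembly = assembly, gff = gff,
                 categories = categories, sam = sam, gfa = gfa,
                 homologs = homologs, bgc_contig = bgc_contig,
                 alpha = alpha, min_support = as.integer(min_support),
                 pseudogene_cutoff = pseudogene_cutoff,
                 cai_pseudocount = cai_pseudocount,
                 seed = as.integer(seed), outdir = outdir,
                 synthetic = synthetic),
            class = "run_config")
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(abs(x - round(x)) < 1e-12, as.character(round(x)),
                signif(x, 4)))
}

write_tsv4 <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 4))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full evidence pipeline
#'
#' Stages: composition outliers and GC contrast, CAI contrast, repeat
#' copy number / junctions / repeat model / pileup variants, and
#' genome-reduction metrics. Writes one tab-delimited table per stage and
#' a plain-text summary whose every claim is derivable from the tables.
#'
#' @param config [run_config()]
#' @return list of class `pipeline_result` with all stage outputs and
#'   `summary_lines`
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  logf <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(...)), file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  logf("symbgc %s | R %s | seed %d",
       as.character(utils::packageVersion("symbgc")),
       getRversion(), config$seed)
  logf("thresholds: alpha=%g min_support=%d pseudogene_cutoff=%g cai_pseudocount=%g",
       config$alpha, config$min_support, config$pseudogene_cutoff,
       config$cai_pseudocount)

  # ---- inputs --------------------------------------------------------
  graph <- NULL; pairs <- NULL; homologs <- NULL
  if (config$synthetic) {
    logf("synthetic mode: building scenario (seed %d)",
         config$scenario$seed)
    sc <- build_scenario(config$scenario)
    contigs <- sc$contigs; genes <- sc$genes; graph <- sc$graph
    pairs <- sc$pairs; homologs <- sc$homologs
    bgc_id <- sc$truth$bgc_contig
  } else {
    contigs <- read_fasta(config$assembly)
    genes <- if (!is.null(config$gff)) {
      read_gff_genes(config$gff, config$categories, contigs)
    } else list()
    bgc_id <- config$bgc_contig
    if (!bgc_id %in% names(contigs)) {
      stop("bgc contig '", bgc_id, "' not in assembly")
    }
    if (!is.null(config$sam)) {
      pairs <- read_sam_pairs(config$sam)
      bad <- setdiff(unique(c(pairs$contig1, pairs$contig2)),
                     names(contigs))
      if (length(bad)) {
        stop("SAM references not in assembly: ", paste(bad, collapse = ", "))
      }
    }
    if (!is.null(config$gfa)) graph <- read_gfa(config$gfa)
    if (!is.null(config$homologs)) {
      homologs <- read_homolog_table(config$homologs)
    }
  }

  res <- list(config = config)
  summary_lines <- character(0)

  # ---- composition / HGT ---------------------------------------------
  profiles <- kmer_profiles(contigs)
  outliers <- composition_outlier_scores(profiles, focus_ids = bgc_id,
                                         seed = config$seed)
  res$outliers <- outliers
  write_tsv4(outliers$scores, file.path(outdir, "composition_outliers.tsv"))
  bgc_top <- outliers$scores$p[outliers$scores$id == bgc_id] <=
    1 / sum(!outliers$scores$is_focus)
  logf("composition: bgc score %.3f, empirical p %.4f",
       outliers$scores$score[outliers$scores$id == bgc_id],
       outliers$scores$p[outliers$scores$id == bgc_id])

  gc_contrast <- NULL; cai_contrast <- NULL
  if (length(genes)) {
    gc_obs <- gene_gc(genes)
    gc_contrast <- category_anova_tukey(gc_obs, "gc", config$alpha)
    res$gc_obs <- gc_obs; res$gc_contrast <- gc_contrast
    write_tsv4(gc_contrast$tukey, file.path(outdir, "anova_tukey_gc.tsv"))

    ribo <- Filter(function(g) g$category == "ribosomal", genes)
    if (length(ribo)) {
      ref <- build_reference(ribo, pseudocount = config$cai_pseudocount)
      cai_obs <- gene_cai(genes, ref)
      cai_contrast <- category_anova_tukey(cai_obs, "cai", config$alpha)
      res$cai_obs <- cai_obs; res$cai_contrast <- cai_contrast
      gene_tab <- merge(gc_obs, cai_obs[, c("gene_id", "cai")],
                        by = "gene_id")
      write_tsv4(gene_tab, file.path(outdir, "gene_gc_cai.tsv"))
      write_tsv4(cai_contrast$tukey,
                 file.path(outdir, "anova_tukey_cai.tsv"))
    } else {
      logf("skip: no ribosomal genes, CAI stage skipped")
      write_tsv4(gc_obs, file.path(outdir, "gene_gc_cai.tsv"))
    }
  } else {
    logf("skip: no gene features, composition contrasts skipped")
  }

  # ---- repeat copy number -------------------------------------------
  model <- NULL; variants <- NULL
  if (!is.null(pairs) && nrow(pairs)) {
    depth_tab <- do.call(rbind, lapply(contigs, function(ct) {
      ds <- depth_summary(pairs, ct, seed = config$seed)
      data.frame(region_id = ds$region_id, mean_depth = ds$mean_depth,
                 ci_lo = ds$ci[1], ci_hi = ds$ci[2],
                 stringsAsFactors = FALSE)
    }))
    write_tsv4(depth_tab, file.path(outdir, "depth_summary.tsv"))
    genome_depth <- bin_reference_depth(pairs, contigs, exclude = bgc_id)
    junctions <- count_junctions(pairs, bgc_id, contigs, graph = graph,
                                 min_support = config$min_support)
    write_tsv4(junctions$partners, file.path(outdir, "junctions.tsv"))
    model <- reconcile_repeat_model(pairs, contigs, bgc_id,
                                    genome_depth = genome_depth,
                                    junctions = junctions,
                                    seed = config$seed)
    write_tsv4(model$segments, file.path(outdir, "repeat_model.tsv"))
    res$junctions <- junctions; res$model <- model
    body_copies <- model$segments$copies[nrow(model$segments)]
    if (body_copies >= 2L) {
      variants <- pileup_variants(pairs, contigs[[bgc_id]],
                                  copies = body_copies)
      if (length(genes)) variants <- annotate_variants(variants, genes)
      res$variants <- variants
      vt <- variants
      write_tsv4(vt, file.path(outdir, "variant_calls.tsv"))
      write_variant_table(variants, file.path(outdir, "variants_vcf_like.tsv"))
    }
    logf("repeat: body copies %d, 3' partners %d, 5' partners %d",
         body_copies, sum(junctions$partners$end == "3p"),
         sum(junctions$partners$end == "5p"))
  } else {
    logf("skip: no alignments, repeat stages skipped")
  }

  # ---- genome reduction ---------------------------------------------
  pseudo <- NULL; density <- NULL
  if (!is.null(homologs)) {
    pseudo <- call_pseudogenes(homologs, cutoff = config$pseudogene_cutoff)
    write_tsv4(pseudo, file.path(outdir, "pseudogene_calls.tsv"))
    res$pseudogenes <- pseudo
  } else {
    logf("skip: no homolog table, pseudogene stage skipped")
  }
  if (length(genes)) {
    coding <- coding_bp_by_contig(genes, contigs)
    pseudo_ids <- if (!is.null(pseudo)) {
      pseudo$gene_id[!is.na(pseudo$is_pseudogene) & pseudo$is_pseudogene]
    } else character(0)
    coding_np <- coding_bp_by_contig(genes, contigs,
                                     exclude_ids = pseudo_ids)
    copies_of <- setNames(rep(1, length(contigs)), names(contigs))
    if (!is.null(model)) {
      copies_of[bgc_id] <- model$segments$copies[nrow(model$segments)]
    }
    rep_tab <- data.frame(
      replicon_id = names(contigs),
      length_bp = vapply(contigs, `[[`, numeric(1), "length"),
      coding_bp = coding[names(contigs)],
      copy_number = copies_of[names(contigs)],
      pseudogene_coding_bp = (coding - coding_np)[names(contigs)],
      stringsAsFactors = FALSE)
    density <- coding_density(rep_tab)
    res$density <- density
    write_tsv4(density$per_replicon, file.path(outdir, "coding_density.tsv"))
  }

  # ---- summary -------------------------------------------------------
  gc_flag <- cai_match <- NA
  if (!is.null(gc_contrast)) {
    tb <- gc_contrast$tukey
    bgc_rows <- tb$category_a == "bgc" | tb$category_b == "bgc"
    gc_flag <- all(tb$different[bgc_rows])
  }
  if (!is.null(cai_contrast)) {
    tb <- cai_contrast$tukey
    rib_row <- (tb$category_a == "bgc" & tb$category_b == "ribosomal") |
      (tb$category_b == "bgc" & tb$category_a == "ribosomal")
    cai_match <- !any(tb$different[rib_row])
  }
  yn <- function(x) if (is.na(x)) "NA" else if (x) "yes" else "no"
  summary_lines <- c(
    sprintf("copy number: %s", if (is.null(model)) "NA"
            else model$segments$copies[nrow(model$segments)]),
    sprintf("3' connections: %s", if (is.null(model)) "NA"
            else sum(model$junctions$partners$end == "3p")),
    sprintf("5' connections: %s", if (is.null(model)) "NA"
            else sum(model$junctions$partners$end == "5p")),
    sprintf("internal attachments: %s", if (is.null(model)) "NA"
            else sum(model$junctions$partners$end == "internal")),
    sprintf("variant calls: %s", if (is.null(variants)) "NA"
            else nrow(variants)),
    sprintf("BGC composition outlier (top, p <= 1/n): %s", yn(bgc_top)),
    sprintf("BGC GC differs from host: %s", yn(gc_flag)),
    sprintf("BGC CAI matches ribosomal: %s", yn(cai_match)),
    sprintf("pseudogene fraction (%%): %s", if (is.null(pseudo)) "NA"
            else fmt_num(pseudogene_fraction(pseudo))),
    sprintf("coding density (%%): %s", if (is.null(density)) "NA"
            else fmt_num(density$overall_percent)),
    sprintf("coding density excl. pseudogenes (%%): %s",
            if (is.null(density)) "NA"
            else fmt_num(density$overall_excl_pseudogenes_percent)))
  writeLines(summary_lines, file.path(outdir, "summary.txt"))
  logf("done")
  res$summary_lines <- summary_lines
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(x$summary_lines, sep = "\n")
  invisible(x)
}
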