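# Compositional evidence for horizontal acquisition: canonical k-mer
# profiles, a centroid-distance outlier statistic, per-gene GC, and the
# one-way ANOVA + Tukey HSD category contrast.

#' Canonical k-mer frequency profile of a sequence
#'
#' Slides a window of `k` with step 1; each window is collapsed to the
#' lexicographic minimum of itself and its reverse complement (canonical
#' k-mer), so the profile is strand-symmetric. Windows containing N (or any
#' non-ACGT character) contribute nothing. Counts are normalized to
#' frequencies.
#'
#' @param seq DNA string, length >= k
#' @param k word size (default 5; 512 canonical classes)
#' @param id identifier carried on the profile
#' @return object of class `kmer_profile`: list(id, k, freq) where `freq`
#'   is a named vector over canonical k-mers in lexicographic order,
#'   summing to 1 when any valid window exists
#' @export
kmer_profile <- function(seq, k = 5L, id = NA_character_) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) < k) {
    stop("sequence shorter than k (", nchar(seq), " < ", k, ")")
  }
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(seq), width = k)
  kmers <- names(counts)
  canon <- canonical_kmers(k)
  agg <- tapply(counts, canon$map[kmers], sum)
  freq <- setNames(numeric(length(canon$levels)), canon$levels)
  freq[names(agg)] <- agg
  tot <- sum(freq)
  if (tot > 0) freq <- freq / tot
  structure(list(id = id, k = as.integer(k), freq = freq),
            class = "kmer_profile")
}

# Canonical k-mer machinery, memoised per k.
canonical_kmers <- local({
  cache <- list()
  function(k) {
    key <- as.character(k)
    if (!is.null(cache[[key]])) return(cache[[key]])
    kmers <- Biostrings::mkAllStrings(BASES, k)
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
    map <- setNames(pmin(kmers, rc), kmers)
    res <- list(map = map, levels = sort(unique(unname(map))))
    cache[[key]] <<- res
    res
  }
})

#' Canonical k-mer profiles for a set of contigs
#' @param contigs list of [contig()]
#' @param k word size
#' @return list of [kmer_profile()] named by contig id
#' @export
kmer_profiles <- function(contigs, k = 5L) {
  contigs <- as_contig_set(contigs)
  lapply(contigs, function(ct) kmer_profile(ct$seq, k = k, id = ct$id))
}

#' Composition outlier scores against a background of profiles
#'
#' Each profile is scored by its Euclidean distance from the centroid of
#' the background (non-focus) profiles, standardized by the root mean
#' square of the background distances, so a profile equal to the centroid
#' scores exactly 0. The empirical p for a profile is the fraction of
#' background profiles at a distance at least as large as its own
#' (background profiles count themselves, so under the null the p values
#' are uniform on {1/n, ..., 1}).
#'
#' A deterministic 2-D principal-component embedding of all profiles is
#' returned for plotting, mirroring the role dimension-reduction plays in
#' composition-based binning; distances in the embedding are not used for
#' any statistic.
#'
#' @param profiles list of [kmer_profile()]
#' @param focus_ids ids treated as the query set (excluded from the
#'   background)
#' @param seed accepted for interface stability; the embedding is already
#'   deterministic
#' @return list of class `composition_outliers` with elements `scores`
#'   (data.frame: id, is_focus, dist, score, p) and `embedding` (matrix,
#'   columns dim1/dim2)
#' @export
composition_outlier_scores <- function(profiles, focus_ids, seed = 1L) {
  ids <- vapply(profiles, `[[`, character(1), "id")
  names(profiles) <- ids
  mat <- do.call(rbind, lapply(profiles, `[[`, "freq"))
  rownames(mat) <- ids
  is_focus <- ids %in% focus_ids
  n_bg <- sum(!is_focus)
  if (n_bg < 10L) {
    stop("need >= 10 background profiles for a stable centroid (got ",
         n_bg, ")")
  }
  centroid <- colMeans(mat[!is_focus, , drop = FALSE])
  d <- sqrt(rowSums(sweep(mat, 2L, centroid)^2))
  d_bg <- d[!is_focus]
  scale <- sqrt(mean(d_bg^2))
  score <- if (scale > 0) d / scale else ifelse(d == 0, 0, Inf)
  p <- vapply(d, function(di) mean(d_bg >= di), numeric(1))
  emb <- stats::prcomp(mat, center = TRUE)$x
  if (ncol(emb) < 2L) emb <- cbind(emb, 0)
  emb <- emb[, 1:2, drop = FALSE]
  colnames(emb) <- c("dim1", "dim2")
  structure(list(
    scores = data.frame(id = ids, is_focus = is_focus, dist = unname(d),
                        score = unname(score), p = unname(p),
                        stringsAsFactors = FALSE),
    embedding = emb), class = "composition_outliers")
}

#' Per-gene GC percentage
#'
#' @param genes list of [gene_record()]
#' @return data.frame with gene_id, category, gc_percent (GC over A/C/G/T
#'   only)
#' @export
gene_gc <- function(genes) {
  gc <- vapply(genes, function(g) {
    val <- gc_fraction(g$cds_seq)
    if (is.nan(val)) stop("gene '", g$gene_id, "': no A/C/G/T bases")
    100 * val
  }, numeric(1))
  data.frame(gene_id = vapply(genes, `[[`, character(1), "gene_id"),
             category = vapply(genes, `[[`, character(1), "category"),
             gc_percent = unname(gc), stringsAsFactors = FALSE)
}

#' One-way ANOVA plus Tukey HSD across gene categories
#'
#' Fixed-effects one-way ANOVA of a per-gene response (GC percent or CAI)
#' on category, followed by Tukey's honestly significant difference with
#' the Tukey-Kramer denominator for unbalanced groups (the pooled
#' within-group variance is used throughout). A pair is declared
#' "different" iff its adjusted p < `alpha`.
#'
#' @param observations data.frame with a `category` column and the
#'   response column
#' @param response which response column to contrast: "gc" (column
#'   `gc_percent`) or "cai" (column `cai`)
#' @param alpha significance threshold (default 0.05)
#' @return list of class `category_contrast`: `anova_F`, `anova_p`,
#'   `tukey` (data.frame: category_a, category_b, diff, p_adj, different),
#'   `alpha`
#' @export
category_anova_tukey <- function(observations, response = c("gc", "cai"),
                                 alpha = 0.05) {
  response <- match.arg(response)
  col <- switch(response, gc = "gc_percent", cai = "cai")
  if (!col %in% names(observations)) {
    stop("observations lack column '", col, "'")
  }
  value <- observations[[col]]
  categ <- factor(observations$category)
  if (nlevels(categ) < 2L) stop("need >= 2 categories")
  n_per <- table(categ)
  if (any(n_per < 2L)) {
    stop("category with < 2 observations: ",
         paste(names(n_per)[n_per < 2L], collapse = ", "))
  }
  if (stats::var(value) == 0) {
    # flat data carries no evidence of difference
    pairs <- utils::combn(levels(categ), 2)
    tukey <- data.frame(category_a = pairs[2, ], category_b = pairs[1, ],
                        diff = 0, p_adj = 1, different = FALSE,
                        stringsAsFactors = FALSE)
    return(structure(list(anova_F = 0, anova_p = 1, tukey = tukey,
                          alpha = alpha), class = "category_contrast"))
  }
  fit <- aov(value ~ categ)
  av <- summary(fit)[[1]]
  F_stat <- av[["F value"]][1]
  p_val <- av[["Pr(>F)"]][1]
  # degenerate case: zero within-group variance makes F 0/0; a flat data
  # set carries no evidence of difference
  if (!is.finite(F_stat) && av[["Sum Sq"]][1] == 0) {
    F_stat <- 0; p_val <- 1
  }
  tk <- TukeyHSD(fit, "categ")$categ
  tk[, "p adj"][!is.finite(tk[, "p adj"])] <-
    ifelse(tk[, "diff"][!is.finite(tk[, "p adj"])] == 0, 1, 0)
  pair_names <- strsplit(rownames(tk), "-", fixed = TRUE)
  tukey <- data.frame(
    category_a = vapply(pair_names, `[[`, character(1), 1L),
    category_b = vapply(pair_names, `[[`, character(1), 2L),
    diff = unname(tk[, "diff"]),
    p_adj = unname(tk[, "p adj"]),
    stringsAsFactors = FALSE)
  tukey$different <- tukey$p_adj < alpha
  structure(list(anova_F = F_stat, anova_p = p_val, tukey = tukey,
                 alpha = alpha),
            class = "category_contrast")
}

#' @export
print.category_contrast <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4g, p = %.4g\n", x$anova_F, x$anova_p))
  print(x$tukey, digits = 4)
  invisible(x)
}
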