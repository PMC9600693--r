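# composition_hgt: canonical 5-mer profiles, outlier scores, gene GC,
# ANOVA + Tukey HSD.

test_that("kmer_profile canonicalizes and normalizes", {
  p <- kmer_profile("AAAAA")
  expect_equal(unname(p$freq[["AAAAA"]]), 1)
  expect_equal(sum(p$freq), 1)

  # reverse-complement strand symmetry: TTTTT counts as AAAAA
  p2 <- kmer_profile("TTTTT")
  expect_equal(unname(p2$freq[["AAAAA"]]), 1)

  expect_length(p$freq, 512L)
  expect_error(kmer_profile("ACG"), "shorter than k")
})

test_that("windows containing N contribute nothing", {
  # every 5-window of this sequence overlaps the N
  p <- kmer_profile("AANAA")
  expect_equal(sum(p$freq), 0)
  # N splits the sequence: only the two clean windows count
  p2 <- kmer_profile("AAAAANGGGGG")
  expect_equal(sum(p2$freq), 1)
  expect_equal(unname(p2$freq[["AAAAA"]]), 0.5)
  expect_equal(unname(p2$freq[["CCCCC"]]), 0.5)  # GGGGG canonicalized
})

test_that("kmer_profile is invariant under reverse complement", {
  set.seed(21)
  for (i in 1:10) {
    s <- rand_seq(200 + 50 * i)
    a <- kmer_profile(s)$freq
    b <- kmer_profile(revcomp(s))$freq
    expect_equal(a, b, tolerance = 1e-12)
    expect_equal(sum(a), 1, tolerance = 1e-12)
  }
})

test_that("outlier score is 0 at the centroid and flat for identical input", {
  set.seed(31)
  profiles <- lapply(1:12, function(i)
    kmer_profile(rand_seq(4000), id = paste0("bg", i)))
  mat <- do.call(rbind, lapply(profiles, `[[`, "freq"))
  centroid_profile <- structure(
    list(id = "focus", k = 5L, freq = colMeans(mat)),
    class = "kmer_profile")
  res <- composition_outlier_scores(c(profiles, list(centroid_profile)),
                                    focus_ids = "focus")
  row <- res$scores[res$scores$id == "focus", ]
  expect_identical(row$score, 0)
  expect_identical(row$p, 1)

  same <- lapply(1:12, function(i) {
    structure(list(id = paste0("s", i), k = 5L, freq = mat[1, ]),
              class = "kmer_profile")
  })
  res2 <- composition_outlier_scores(same, focus_ids = "s1")
  expect_true(all(res2$scores$score == 0))

  expect_error(composition_outlier_scores(profiles[1:5], "bg1"),
               ">= 10 background")
})

test_that("empirical p is uniform on {1/n,...,1} under the null", {
  set.seed(77)
  n <- 30
  profiles <- lapply(seq_len(n), function(i)
    kmer_profile(rand_seq(3000), id = paste0("c", i)))
  res <- composition_outlier_scores(profiles, focus_ids = character(0))
  expect_equal(sort(res$scores$p), seq_len(n) / n, tolerance = 1e-12)
})

test_that("the shifted BGC contig attains the top outlier score", {
  sc <- default_scenario()
  res <- composition_outlier_scores(kmer_profiles(sc$contigs),
                                    focus_ids = "bgc_1")
  s <- res$scores
  # exhaustive comparison: no contig scores at or above the BGC contig
  expect_true(all(s$score[s$id != "bgc_1"] < s$score[s$id == "bgc_1"]))
  expect_lte(s$p[s$id == "bgc_1"], 1 / sum(!s$is_focus))
  expect_equal(dim(res$embedding), c(nrow(s), 2L))
})

test_that("gene_gc computes GC over cds sequences", {
  mk <- function(seq) gene_record("g", "c", 1, nchar(seq), "+",
                                  "pseudogene", cds_seq = seq)
  expect_equal(gene_gc(list(mk("GGCC")))$gc_percent, 100)
  expect_equal(gene_gc(list(mk("ATAT")))$gc_percent, 0)
  expect_equal(gene_gc(list(mk("ATGC")))$gc_percent, 50)
})

test_that("ANOVA/Tukey matches hand computation on the 3x3 toy data", {
  obs <- data.frame(
    category = rep(c("a", "b", "c"), each = 3),
    gc_percent = c(10, 11, 12, 20, 21, 22, 10, 12, 11))
  res <- category_anova_tukey(obs, "gc")
  # independent oracle: textbook one-way ANOVA on these nine numbers
  means <- c(11, 21, 11); grand <- mean(obs$gc_percent)
  ssb <- 3 * sum((means - grand)^2)           # 200
  ssw <- sum((obs$gc_percent - rep(means, each = 3))^2)  # 6
  F_hand <- (ssb / 2) / (ssw / 6)             # 100
  expect_equal(res$anova_F, F_hand, tolerance = 1e-12)
  expect_equal(res$anova_p, pf(F_hand, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  # studentized-range oracle for the a-b pair
  q_ab <- abs(21 - 11) / sqrt((ssw / 6) / 3)
  p_ab <- ptukey(q_ab, nmeans = 3, df = 6, lower.tail = FALSE)
  row <- res$tukey[(res$tukey$category_a == "b" &
                      res$tukey$category_b == "a") |
                     (res$tukey$category_a == "a" &
                        res$tukey$category_b == "b"), ]
  expect_equal(row$p_adj, p_ab, tolerance = 1e-9)
  expect_true(row$different)
  row_ac <- res$tukey[res$tukey$category_a == "c" &
                        res$tukey$category_b == "a", ]
  expect_false(row_ac$different)
})

test_that("degenerate and invalid contrasts are handled", {
  flat <- data.frame(category = rep(c("a", "b"), each = 3),
                     gc_percent = rep(5, 6))
  res <- category_anova_tukey(flat, "gc")
  expect_equal(res$anova_F, 0)
  expect_equal(res$anova_p, 1)
  expect_false(any(res$tukey$different))

  expect_error(category_anova_tukey(
    data.frame(category = c("a", "a", "b"), gc_percent = 1:3), "gc"),
    "< 2 observations")
  expect_error(category_anova_tukey(
    data.frame(category = "a", gc_percent = 1), "gc"), "2 categories")
})

test_that("Tukey adjusted p is at least the pooled pairwise t-test p", {
  set.seed(99)
  for (rep in 1:5) {
    obs <- data.frame(
      category = rep(c("a", "b", "c", "d"), times = c(5, 8, 6, 7)),
      gc_percent = rnorm(26, mean = rep(c(0, 0.5, 1, 0), c(5, 8, 6, 7))))
    res <- category_anova_tukey(obs, "gc")
    fit <- aov(gc_percent ~ category, data = obs)
    mse <- summary(fit)[[1]][["Mean Sq"]][2]
    dfw <- summary(fit)[[1]][["Df"]][2]
    n <- table(obs$category)
    for (i in seq_len(nrow(res$tukey))) {
      a <- res$tukey$category_a[i]; b <- res$tukey$category_b[i]
      se <- sqrt(mse * (1 / n[[a]] + 1 / n[[b]]))
      t_p <- 2 * pt(abs(res$tukey$diff[i]) / se, dfw, lower.tail = FALSE)
      expect_gte(res$tukey$p_adj[i] + 1e-12, t_p)
    }
  }
})
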