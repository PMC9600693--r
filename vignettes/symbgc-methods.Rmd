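---
title: "Methods: multi-copy BGC evidence in a symbiont metagenome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-copy BGC evidence in a symbiont metagenome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Sponge and other invertebrate natural products are frequently made not by
the animal but by an uncultivated bacterial symbiont, and the producing
genome can only be reached through metagenome assembly and binning. Once a
candidate biosynthetic gene cluster (BGC) and a candidate host bin are in
hand, several independent, quantitative lines of evidence tie them
together and characterize their history:

1. **Copy number from read depth.** A repeat assembled as a single
   (collapsed) contig accumulates the reads of all its copies, so the
   ratio of its mean depth to the bin's reference depth estimates its
   integer copy number.
2. **Junction connections.** Read pairs straddling a contig end, and
   assembly-graph links, reveal how many distinct genomic contexts a
   repeat end sits in. Three partners at the 3' end and two at the 5' end,
   with one partner attached internally, is the signature of three copies
   of which one lacks a leading segment.
3. **Repeat-divergence variants.** Copies that have diverged leave mixed
   alleles in the collapsed pileup: a SNP carried by *c* of *n* copies has
   an alternate-allele fraction near *c/n*; insertions appear as a
   consistent inserted sequence at one reference junction.
4. **Compositional evidence for horizontal acquisition.** Canonical 5-mer
   frequency vectors separate a recently transferred region from its host
   background; per-gene GC is contrasted across gene categories by
   one-way ANOVA with Tukey's HSD.
5. **Codon adaptation.** The codon adaptation index (CAI) of a gene set
   against a ribosomal-protein reference tests whether a horizontally
   acquired cluster has been translationally domesticated: the observed
   pattern of interest is BGC CAI indistinguishable from ribosomal CAI
   while both exceed ordinary genes.
6. **Genome reduction.** A gene shorter than 80% of its closest homolog is
   a putative pseudogene (strict inequality); coding density is computed
   length-weighted with repeat units counted at their copy number.

`symbgc` implements these computations as a tested pipeline and ships a
synthetic metagenome generator that produces data with exactly the
statistical structure the analyses assume, so every stage can be verified
against known truth.

# Statistical procedures and numerical choices

## Copy number

`estimate_copy_number(bgc_depth, genome_depth)` returns the raw ratio and
`round(ratio)` with ties rounded half away from zero and a floor of 1.
Rounding (not flooring) is the behaviour consistent with reading a ratio
of 3.296 as "roughly three". The bin reference depth is the **median** of
per-contig mean depths (`bin_reference_depth`), robust to individual
outlier contigs; the mean is available as an option.

Depth summaries tile a region into non-overlapping 1-kb windows and
bootstrap the window means (default 1000 resamples, seeded) for a 95%
confidence interval. Windows, not bases, are resampled because per-base
depths are strongly autocorrelated at the fragment scale.

## Junctions

A partner contig must receive at least `min_support` (default 3) read
pairs with one mate inside an end window of the focus contig and the
other mate inside an end window of the partner. The end window defaults
to twice the median insert size, which captures essentially all
junction-spanning fragments under a Gaussian insert distribution.
Partners whose focus-side mates cluster away from both termini are
reported as **internal attachments** with the median mate start as the
attachment-point estimate — the signature of a copy missing a terminal
segment. GFA edges confirm terminal partners; internal attachments have
no graph analogue and are never graph-confirmed.

`reconcile_repeat_model` splits the collapsed repeat at internal
attachment points, assigns each segment `round(depth ratio)` copies, and
cross-checks the body segment against the number of 3' partners and the
leading segment against terminal 5' partners. Disagreements are flagged
in the returned model, never silently adjusted.

## Pileup variants

Per-column base counts come from walking each read's CIGAR. A SNP is
called when the best non-reference base has at least `min_alt_depth = 4`
reads and at least `min_alt_fraction = 0.1` of informative (ref + alt)
reads. Insertions are clustered by exact (position, sequence) identity,
because the default synthetic reads are error-free; `max_mismatch = 1`
enables edit-distance-tolerant clustering for reads with errors. Reads
whose alignment passes an insertion junction contiguously count as
reference support. Copies carrying the alternate allele are estimated as
`round(copies x alt fraction)` clamped to `[1, copies - 1]`.
Phred-scaled genotype likelihoods are deliberately not produced: they are
a property of a specific caller's model, not of the data; allelic depth
and copy fractions are the supported outputs.

Insertion allele fractions are biased slightly downward relative to
*c/n*: only reads containing the full insertion with anchor bases on both
sides produce the insertion operation, while edge-overlapping reads are
soft-clipped and counted as neither allele. The SNP fractions are
unbiased, and the tests assert the binomial-error bound on SNPs only.

## Composition outliers

Profiles are canonical 5-mer frequency vectors (512 dimensions; each
word collapsed to the lexicographic minimum of itself and its reverse
complement; windows containing N are excluded; counts normalized).
Canonicalization is the common practice in composition-based binning and
makes the profile strand-symmetric.

The outlier statistic is the Euclidean distance of a profile from the
centroid of the background (non-focus) profiles, standardized by the
root-mean-square background distance. RMS standardization (rather than a
z-score) is chosen so a profile exactly at the centroid scores exactly 0.
The empirical p of a contig is the fraction of background contigs at
distance at least its own, with background contigs counting themselves;
under the null this makes the background p values exactly uniform on
{1/n, ..., 1}, and a focus contig more extreme than every background
contig reaches p = 0 <= 1/n. At least 10 background profiles are required
for a stable centroid.

A 2-D embedding is returned for plotting. It is a principal-component
projection, not a t-SNE: the embedding's role here is visual, and
stochastic-neighbor distances are not quantitatively stable enough to
test. The `seed` argument is accepted for interface stability; the PCA is
already deterministic.

## Category contrasts

`category_anova_tukey` fits a fixed-effects one-way ANOVA and applies
Tukey's HSD using the pooled within-group variance with the Tukey-Kramer
denominator, since gene counts per category differ. A pair is "different"
iff adjusted p < 0.05 (configurable). A degenerate all-equal data set is
reported as F = 0, p = 1 rather than 0/0. Note that the ANOVA p being at
most the smallest Tukey-adjusted p is *not* a theorem and is not
asserted; the tested property is that each Tukey-adjusted p is at least
the unadjusted pooled-variance pairwise t-test p.

## Codon adaptation index

Relative adaptiveness w(c) is the codon's count in the concatenated
ribosomal reference divided by the count of the most-used synonymous
codon of the same amino acid. Codons never seen in the reference receive
a pseudocount of 0.5 occurrences (`w = 0.5/max count`), the common remedy
that keeps the geometric mean away from zero; amino acids entirely absent
from the reference carry no information and are skipped. CAI is the
geometric mean of w over a gene's codons excluding ATG, TGG, and stops
(single-codon families carry no synonymous signal). Translation uses the
bacterial code (table 11). Pseudogene CAI is computed on the longest
in-frame prefix, since their true frames are broken; a warning marks the
truncation.

## Pseudogenes and coding density

The length-ratio rule is taken literally: a gene is flagged iff
gene length / homolog length **< 0.8** (a ratio of exactly 0.80 is not a
pseudogene). Homolog search itself is out of scope — the module consumes
a precomputed homolog-length table, removing an irreproducible
database-version dependency; the generator fabricates a table consistent
with its own truth. Coding density is
`100 x sum(copy x coding bp) / sum(copy x length)`, so repeat units count
at their copy number; the pseudogene-excluded variant subtracts
pseudogene coding bp from the numerator only.

# The synthetic world

`scenario_config()` states the world once; its defaults are not tuning
knobs:

| parameter | default | meaning |
|---|---|---|
| `host_length`, `n_host_contigs` | 300 kb, 12 | host bin size and contig count |
| `host_gc` | 0.54 | host GC (the studied bin is ~54%) |
| `bgc_length` | 20 kb | collapsed BGC unit (the real unit is ~98 kb; scaled ~5x for desk runtimes) |
| `bgc_gc` | 0.46 | BGC GC, an 8-point shift |
| `bgc_copy_number` | 3 | copies in the true genome |
| `leading_segment_length`, `leading_segment_copies` | 1 kb, 2 | the 3-kb-scale leading segment, absent from one copy |
| `read_length`, `insert_mean`/`insert_sd`, `depth` | 150 bp, 300/30 bp, 50x | Illumina-like paired-end geometry |
| `n_genes` | 50 per category | gene counts (50 gives the category contrasts their stated power) |
| `pseudogene_truncation_fraction` | 0.5 | pseudogenes keep half their length |
| `ribosomal_codon_bias_strength` | 5 | codon-bias strength of ribosomal and bgc genes (below) |

Host contigs carry annotated, hypothetical, pseudogene and ribosomal
genes embedded between i.i.d. spacers; the BGC contig carries the bgc
genes. When variant specs are not supplied, the generator derives them
from the realized layout, mirroring the published variant table: the
three printed insertion sequences (60, 24, 54 bp, all multiples of
three) placed inside CDSs at positions scaled from the 98-kb coordinates;
one synonymous C→T SNP on the third base of a TAC codon; one intergenic
A→G SNP just past the last gene. Positions must respect the realized
codon structure, which is why defaults are derived after layout rather
than fixed a priori.

The true genome places each BGC copy between a distinct pair of host
contigs; reads are drawn uniformly from it and **projected** onto the
collapsed assembly (host contigs + one BGC contig) from their known
origins: junction-spanning reads are soft-clipped to the contig holding
the read's majority, copy-specific insertions become I CIGAR operations
when internal to a read. This replaces an external aligner, which is the
only external tool the pipeline would otherwise need.

## GC and CAI are controlled independently

The delicate property of the emulated data is that bgc genes differ from
every host category in GC yet match ribosomal genes in CAI. The
generator achieves this by separating the two levers:

* **Synonymous choice** (the only thing CAI sees): ribosomal and bgc
  genes draw each codon from a concentrated distribution that picks a
  fixed preferred codon with family-size-specific probability
  \(q_k\), solved so the expected per-codon log relative adaptiveness is
  the same constant \(-1/(s+3)\) in every synonymous family
  (\(s\) = `ribosomal_codon_bias_strength`). Because the expectation is
  family-independent, a gene's expected CAI does not depend on its
  amino-acid composition — so the GC shift below cannot leak into CAI.
  Ordinary genes draw synonymous codons from a Dirichlet-perturbed
  background, giving them a markedly lower CAI.
* **Amino-acid composition** (the main GC lever): each category's
  amino-acid distribution is exponentially tilted,
  \(p_{aa} \propto \exp(\lambda\,\overline{gc}_{aa})\), with \(\lambda\)
  solved by `uniroot` so the expected GC matches the category target
  (host GC for host categories and ribosomal genes, BGC GC for bgc
  genes), with the codon rule in force folded into
  \(\overline{gc}_{aa}\).

A consequence of the concentrated rule is that background genes score a
very low CAI (~0.1) against the ribosomal reference — lower than typical
real genomes. The tested pattern (bgc ≈ ribosomal ≫ background) is the
paper-relevant structure; absolute background CAI levels are not.

## What a green test does and does not establish

The generator produces i.i.d. composition within each region, error-free
reads by default, exactly uniform fragment sampling, and a homolog table
whose noise never crosses the pseudogene boundary. Real data have
shared-ancestry codon structure, sequencing error, GC-dependent coverage
bias, chimeras, and homolog tables full of partial hits. Green tests
therefore establish that the *computations* are correct and that the
inference recovers truth under the stated model — not that the model
captures every failure mode of a real metagenome. The mismatch-tolerant
insertion clustering and the configurable `error_rate` exist to probe the
first steps beyond the clean world.

# Design decisions that were genuinely open

* **Depth definition.** Whether a binner's "k-mer coverage" is read depth
  or assembler k-mer depth is not observable from published numbers; this
  package defines depth as mean per-base read coverage and treats printed
  coverages as given inputs where cited.
* **Reference aggregation.** Copy ratios are taken against the median
  host-contig depth (configurable to mean).
* **Outlier score.** The centroid-distance statistic replaces t-SNE
  cluster inspection because it is testable; see above for the exact
  standardization and p convention.
* **Category vocabulary** is fixed to the five categories the contrasts
  need (annotated, hypothetical, pseudogene, ribosomal, bgc).
* **SAM text, GFA1, and the homolog table** are parsed directly: desk
  scale does not need BAM, no R GFA parser exists in the supported
  environment, and homolog search is excluded by design.
* **Junction support threshold.** The published analysis does not state
  the read-pair support used before PCR verification; `min_support = 3`
  is a recorded default.
* **TOML configs** are not supported (no parser in the supported
  environment); the CLI accepts JSON.

# Known limitations

* The pileup caller targets divergence between collapsed repeat copies
  at substantial allele fractions; it is not a general-purpose variant
  caller and has no quality model.
* Insertion detection relies on I operations internal to reads;
  insertions approaching the read length would be missed (the default
  world's longest is 60 bp against 150-bp reads).
* The composition statistic assumes the background contigs are a fair
  sample of one genome; heavy contamination in the bin would inflate the
  background spread and mask a real outlier.
* Coding-density weighting trusts the supplied copy numbers; it does not
  re-infer them.
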