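# Internal helpers shared across modules.

#' @importFrom stats median rnorm runif rgamma setNames uniroot aov
#'   TukeyHSD pf quantile sd rbinom
#' @importFrom utils read.delim write.table adist head tail
NULL

BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#' @param seq character scalar over A/C/G/T/N
#' @return character scalar
#' @keywords internal
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Vectorised reverse complement for many strings.
revcomp_many <- function(seqs) {
  if (length(seqs) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

#' GC fraction of a DNA string (A/C/G/T denominators only; N excluded)
#' @param seq character scalar
#' @return fraction in [0, 1], NaN if no A/C/G/T present
#' @export
gc_fraction <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  counts <- Biostrings::alphabetFrequency(Biostrings::DNAString(seq))
  acgt <- counts[c("A", "C", "G", "T")]
  if (sum(acgt) == 0) return(NaN)
  unname((acgt[["G"]] + acgt[["C"]]) / sum(acgt))
}

# Sample `n` i.i.d. bases at a given GC fraction, returned as one string.
random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Round half away from zero (base round() rounds half to even).
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Genetic code, bacterial table 11, DNA alphabet.
genetic_code_11 <- function() {
  Biostrings::getGeneticCode("11")
}

# All 64 codons in lexicographic order.
all_codons <- function() {
  as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0)[
    order(as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0)))])
}

# Split an in-frame DNA string into codons (drops trailing partial codon).
split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}
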