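# Codon-level utilities shared by the simulator and the divergence module.
# The standard genetic code is taken from Biostrings; stop codons translate
# to "*" and gap codons ("---") to "-".

genetic_code <- function() Biostrings::GENETIC_CODE

stop_codons <- function() names(genetic_code())[genetic_code() == "*"]

sense_codons <- function() names(genetic_code())[genetic_code() != "*"]

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0) stop("sequence length not a multiple of 3", call. = FALSE)
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

#' Translate a nucleotide sequence in frame 0
#'
#' Gap codons (`---`) translate to `-`; codons containing a gap or an
#' ambiguous base translate to `X`; stop codons to `*`.  The trailing
#' partial codon of a sequence whose length is not a multiple of three is
#' ignored.
#'
#' @param seq A nucleotide string (may contain `-`).
#' @return Amino-acid string.
#' @export
translate_dna <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3
  if (n == 0) return("")
  codons <- split_codons(substr(seq, 1, n))
  gc <- genetic_code()
  aa <- ifelse(codons == "---", "-",
               ifelse(codons %in% names(gc), gc[codons], "X"))
  paste(aa, collapse = "")
}

has_internal_stop <- function(seq) {
  aa <- translate_dna(seq)
  grepl("\\*", substr(aa, 1, nchar(aa)))
}

# Synonymous single-nucleotide neighbours of a codon at a given position.
codon_neighbours <- function(codon, pos) {
  base <- substr(codon, pos, pos)
  vapply(setdiff(c("A", "C", "G", "T"), base), function(b) {
    out <- codon
    substr(out, pos, pos) <- b
    out
  }, character(1))
}
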