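# Standard genetic code, taken from Biostrings. Codons containing N (or any
# non-ACGT base) translate to X; X is never a stop, so stop detection is
# unaffected by ambiguity.

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("U", "T", names(gc))
  gc
}

#' Translate a nucleotide sequence in a fixed frame
#'
#' Standard genetic code; trailing bases that do not fill a codon are
#' dropped; codons containing a base outside ACGT translate to `X`.
#' Stop codons translate to `*`.
#'
#' @param nt Nucleotide string over ACGTN.
#' @param offset 0-based offset into `nt` at which translation starts.
#' @return Amino-acid string (possibly containing `*` and `X`).
#' @export
translate_nt <- function(nt, offset = 0L) {
  n <- nchar(nt)
  start <- offset + 1L
  n_codons <- (n - offset) %/% 3L
  if (n_codons <= 0L) return("")
  pos <- start + 3L * (seq_len(n_codons) - 1L)
  codons <- substring(nt, pos, pos + 2L)
  tab <- .codon_table()
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Reverse-complement a nucleotide string
#'
#' @param nt Nucleotide string over ACGTN.
#' @return Reverse complement (N maps to N).
#' @export
revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

# Synonymous codons per amino acid (stop excluded), for reverse translation.
.codons_by_aa <- function() {
  tab <- .codon_table()
  split(names(tab), unname(tab))
}
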