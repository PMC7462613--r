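# Coding reference handling. Residues are 1-based everywhere in the API;
# codon i occupies coding_sequence[(3i-2)..3i].

AA_STOP <- "*"
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a protein reference from a coding DNA sequence
#'
#' A `protein_reference` bundles the coding DNA sequence of the assayed
#' protein, its standard-code translation, and the residue interval that was
#' subjected to saturation mutagenesis. All variant calling and simulation
#' functions are anchored to this object.
#'
#' @param name Identifier for the reference (e.g. the gene name).
#' @param coding_sequence Coding DNA string; length must be divisible by 3,
#'   only `A/C/G/T` allowed, and the translation must contain no internal
#'   stop codon.
#' @param mutagenized_range Inclusive 1-based residue interval covered by the
#'   mutagenesis library. Defaults to positions 2 through the last residue
#'   (the initiator methionine is conventionally left untouched).
#' @return An object of class `protein_reference` with fields `name`,
#'   `coding_sequence`, `protein_sequence` and `mutagenized_range`.
#' @examples
#' ref <- protein_reference("toy", "ATGCGGTGGAAA")
#' ref$protein_sequence
#' @export
protein_reference <- function(name, coding_sequence, mutagenized_range = NULL) {
  coding_sequence <- toupper(as.character(coding_sequence))
  if (length(coding_sequence) != 1L || nchar(coding_sequence) == 0L)
    stop("coding_sequence must be a single non-empty string")
  if (nchar(coding_sequence) %% 3L != 0L)
    stop("coding_sequence length must be divisible by 3")
  if (grepl("[^ACGT]", coding_sequence))
    stop("coding_sequence contains non-ACGT characters")
  codons <- split_codons(coding_sequence)
  aas <- translate_codons(codons)
  n <- length(aas)
  if (any(aas[-n] == AA_STOP))
    stop("reference translation contains an internal stop codon")
  # a terminal stop codon is tolerated but not part of the protein
  if (aas[n] == AA_STOP) {
    aas <- aas[-n]
    n <- n - 1L
  }
  if (is.null(mutagenized_range)) mutagenized_range <- c(min(2L, n), n)
  mutagenized_range <- as.integer(mutagenized_range)
  if (length(mutagenized_range) != 2L ||
      mutagenized_range[1] < 1L || mutagenized_range[2] > n ||
      mutagenized_range[1] > mutagenized_range[2])
    stop("mutagenized_range must be an inclusive interval within [1, ", n, "]")
  structure(
    list(name = as.character(name),
         coding_sequence = coding_sequence,
         protein_sequence = paste(aas, collapse = ""),
         mutagenized_range = mutagenized_range),
    class = "protein_reference"
  )
}

#' @export
print.protein_reference <- function(x, ...) {
  cat("protein_reference '", x$name, "': ", nchar(x$protein_sequence),
      " residues, mutagenized ", x$mutagenized_range[1], "-",
      x$mutagenized_range[2], "\n", sep = "")
  invisible(x)
}

#' Read a protein reference from a single-record FASTA file
#'
#' @param path Path to a FASTA file holding one coding DNA record.
#' @inheritParams protein_reference
#' @return A [protein_reference()] object named after the FASTA header.
#' @export
read_protein_reference <- function(path, mutagenized_range = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1L)
    stop("expected exactly one FASTA record, found ", length(seqs))
  protein_reference(names(seqs)[1], as.character(seqs[[1]]), mutagenized_range)
}

# split a coding sequence into its codons
split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# standard-code translation; codons containing non-ACGT characters give NA
translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

# reference codon at a residue position
codon_at <- function(reference, position) {
  substring(reference$coding_sequence, 3L * position - 2L, 3L * position)
}

wt_aa_at <- function(reference, position) {
  substring(reference$protein_sequence, position, position)
}
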