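#' Substrate oligonucleotide specification
#'
#' Describes an RNA substrate of the `ss22-X_n` design used in 3'-RACE-seq
#' tailing assays: a fixed prefix (22 nt by default) followed by a terminal
#' homopolymer (`terminal_base` repeated `terminal_count` times). The tail
#' caller requires an entirely correct prefix at the 5' end of a read and
#' attributes up to `terminal_count` leading `terminal_base` nucleotides of
#' the insert to the substrate rather than to the added tail.
#'
#' The default prefix is a documented placeholder 22-mer, not the sequence of
#' any real oligonucleotide; supply the true substrate sequence when analysing
#' real libraries.
#'
#' @param prefix Substrate prefix in DNA alphabet (A/C/G/T), typically 22 nt.
#'   RNA input (U) is converted to T.
#' @param terminal_base Single terminal base, one of `"A"`, `"C"`, `"G"`,
#'   `"T"` (or `"U"`, converted to `"T"`).
#' @param terminal_count Number of substrate-encoded terminal bases
#'   (non-negative integer; default 4).
#' @param name Label for the substrate.
#'
#' @return An object of class `substrate_spec`.
#' @examples
#' substrate_spec() # placeholder ss22-A4-style substrate
#' substrate_spec(terminal_base = "U", name = "ss22-U4")
#' @export
substrate_spec <- function(prefix = "ACGTACGTACGTACGTACGTAC",
                           terminal_base = "A",
                           terminal_count = 4L,
                           name = "substrate") {
  prefix <- toupper(rna_to_dna(prefix))
  terminal_base <- toupper(rna_to_dna(terminal_base))
  if (!is_dna_string(prefix)) {
    stop_racetails("`prefix` must be a non-empty A/C/G/T string",
                   "racetails_validation_error")
  }
  if (!terminal_base %in% DNA_BASES || nchar(terminal_base) != 1L) {
    stop_racetails("`terminal_base` must be one of A, C, G, T (or U)",
                   "racetails_validation_error")
  }
  terminal_count <- as.integer(terminal_count)
  if (is.na(terminal_count) || terminal_count < 0L) {
    stop_racetails("`terminal_count` must be a non-negative integer",
                   "racetails_validation_error")
  }
  structure(
    list(name = name, prefix = prefix, terminal_base = terminal_base,
         terminal_count = terminal_count),
    class = "substrate_spec"
  )
}

#' @export
print.substrate_spec <- function(x, ...) {
  cat("<substrate_spec> ", x$name, "\n",
      "  prefix (", nchar(x$prefix), " nt): ", x$prefix, "\n",
      "  terminal run: ", x$terminal_base, " x ", x$terminal_count, "\n",
      sep = "")
  invisible(x)
}

#' 3' adapter specification
#'
#' The oligonucleotide ligated to RNA 3' ends before reverse transcription
#' (e.g. the Illumina RA3 small-RNA adapter, 21 nt). The tail caller requires
#' an entirely correct copy of this sequence downstream of the insert. The
#' default is a configurable placeholder, not the RA3 sequence itself.
#'
#' @param sequence Adapter sequence in DNA alphabet (U converted to T).
#' @param name Label for the adapter.
#' @return An object of class `adapter_spec`.
#' @examples
#' adapter_spec()
#' @export
adapter_spec <- function(sequence = "TGGAATTCTCGGGTGCCAAGG",
                         name = "adapter") {
  sequence <- toupper(rna_to_dna(sequence))
  if (!is_dna_string(sequence)) {
    stop_racetails("adapter `sequence` must be a non-empty A/C/G/T string",
                   "racetails_validation_error")
  }
  structure(list(name = name, sequence = sequence), class = "adapter_spec")
}

#' @export
print.adapter_spec <- function(x, ...) {
  cat("<adapter_spec> ", x$name, " (", nchar(x$sequence), " nt): ",
      x$sequence, "\n", sep = "")
  invisible(x)
}
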