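#' Simulate a 3'-RACE-seq read set with known ground truth
#'
#' Generates sense-orientation amplicon reads of the form
#' `prefix + terminal run + added tail + adapter`, mixed with contaminant
#' classes, and records per-read ground truth (class, true tail). The
#' simulator is the stand-in for an undeposited sequencing run: every read
#' carries a known label so the tail caller can be validated exactly.
#'
#' Contaminant counts are allocated exactly as `round(fraction * n_reads)`
#' per class; the remaining reads are clean. Classes:
#' \describe{
#'   \item{no_prefix}{prefix replaced by a random same-length string
#'     guaranteed to differ in at least one position.}
#'   \item{no_adapter}{adapter omitted.}
#'   \item{long_insert}{insert padded with random bases to
#'     `long_insert_length`.}
#'   \item{junk}{at most 5 random bases followed by the adapter (never
#'     starting with the prefix).}
#' }
#' Quality strings are constant `"I"` since downstream analysis ignores
#' base qualities.
#'
#' @param substrate A [substrate_spec()].
#' @param adapter An [adapter_spec()].
#' @param tail_model A [tail_model()].
#' @param n_reads Positive number of reads.
#' @param contaminants A [contaminant_model()] (default: no contaminants).
#' @param seed Integer seed; the same seed reproduces the read set exactly.
#' @return A list with `reads` (tibble: `id`, `sequence`, `quality`) and
#'   `truth` (tibble: `read_id`, `class`, `true_tail`, `true_length`;
#'   `true_tail` is `NA` for junk reads).
#' @examples
#' sim <- simulate_reads(substrate_spec(), adapter_spec(),
#'                       default_tail_model(), n_reads = 5, seed = 1)
#' sim$truth
#' @export
simulate_reads <- function(substrate, adapter, tail_model,
                           n_reads,
                           contaminants = contaminant_model(),
                           seed = NULL) {
  stopifnot(inherits(substrate, "substrate_spec"),
            inherits(adapter, "adapter_spec"),
            inherits(tail_model, "tail_model"),
            inherits(contaminants, "contaminant_model"))
  n_reads <- as.integer(n_reads)
  if (is.na(n_reads) || n_reads <= 0L) {
    stop_racetails("`n_reads` must be a positive integer",
                   "racetails_validation_error")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  n_class <- round(contaminants$fractions * n_reads)
  if (sum(n_class) > n_reads) {
    stop_racetails("contaminant fractions allocate more reads than n_reads",
                   "racetails_validation_error")
  }
  classes <- c(rep(names(n_class), times = n_class),
               rep("clean", n_reads - sum(n_class)))
  classes <- sample(classes)  # interleave classes across the file

  run <- strrep(substrate$terminal_base, substrate$terminal_count)
  tails <- sample_tails(tail_model, n_reads)
  tails[classes == "junk"] <- NA_character_

  seqs <- character(n_reads)
  for (i in seq_len(n_reads)) {
    cls <- classes[i]
    if (cls == "junk") {
      k <- sample(0:5, 1L)
      lead <- paste0(sample(DNA_BASES, k, replace = TRUE), collapse = "")
      s <- paste0(lead, adapter$sequence)
      # guarantee rejection: never start with the substrate prefix
      if (startsWith(s, substrate$prefix)) {
        substr(s, 1L, 1L) <- setdiff(DNA_BASES, substr(s, 1L, 1L))[1L]
      }
      seqs[i] <- s
      next
    }
    insert <- paste0(run, tails[i])
    if (cls == "long_insert") {
      pad_n <- contaminants$long_insert_length - nchar(insert)
      pad <- paste0(sample(DNA_BASES, pad_n, replace = TRUE), collapse = "")
      insert <- paste0(insert, pad)
    }
    pre <- substrate$prefix
    if (cls == "no_prefix") {
      pre <- random_nonmatching_string(substrate$prefix)
    }
    post <- if (cls == "no_adapter") "" else adapter$sequence
    seqs[i] <- paste0(pre, insert, post)
  }

  ids <- sprintf("read_%06d", seq_len(n_reads))
  list(
    reads = tibble::tibble(id = ids, sequence = seqs,
                           quality = strrep("I", nchar(seqs))),
    truth = tibble::tibble(read_id = ids, class = classes, true_tail = tails,
                           true_length = ifelse(is.na(tails), NA_integer_,
                                                nchar(tails)))
  )
}

# Random A/C/G/T string of the same length as `template`, differing from it
# in at least one position.
random_nonmatching_string <- function(template) {
  n <- nchar(template)
  s <- paste0(sample(DNA_BASES, n, replace = TRUE), collapse = "")
  if (s == template) {
    pos <- sample.int(n, 1L)
    substr(s, pos, pos) <- setdiff(DNA_BASES, substr(s, pos, pos))[1L]
  }
  s
}
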