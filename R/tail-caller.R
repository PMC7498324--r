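#' Locate the substrate prefix at the 5' end of a read
#'
#' A read qualifies only if it begins with an entirely correct copy of the
#' substrate prefix — exact matching, zero mismatches and zero indels.
#'
#' @param sequence Read sequence (DNA alphabet, sense orientation).
#' @param substrate A [substrate_spec()].
#' @return A list with `match` (logical) and `end` (0-based half-open end
#'   offset of the prefix, i.e. the prefix length; `NA` if no match).
#' @examples
#' s <- substrate_spec()
#' locate_prefix(paste0(s$prefix, "AAAACC"), s)
#' @export
locate_prefix <- function(sequence, substrate) {
  stopifnot(inherits(substrate, "substrate_spec"))
  hit <- !is.na(sequence) & startsWith(sequence, substrate$prefix)
  list(match = hit,
       end = ifelse(hit, nchar(substrate$prefix), NA_integer_))
}

#' Locate the 3' adapter within a read
#'
#' Finds the leftmost entirely correct occurrence of the full adapter
#' sequence at or after `search_from`. Bases after the adapter (e.g. read-
#' through into sequencing primers) are ignored by downstream steps.
#'
#' @param sequence Read sequence.
#' @param adapter An [adapter_spec()].
#' @param search_from 0-based offset from which to search (typically the
#'   prefix end).
#' @return A list with `match` (logical) and `start` (0-based start offset
#'   of the adapter; `NA` if absent).
#' @examples
#' a <- adapter_spec()
#' locate_adapter(paste0("AAAA", a$sequence), a, search_from = 0)
#' @export
locate_adapter <- function(sequence, adapter, search_from = 0L) {
  stopifnot(inherits(adapter, "adapter_spec"))
  search_from <- as.integer(search_from)
  tailpart <- substr(sequence, search_from + 1L, nchar(sequence))
  pos <- regexpr(adapter$sequence, tailpart, fixed = TRUE)
  hit <- pos > 0L
  list(match = hit,
       start = ifelse(hit, search_from + as.integer(pos) - 1L, NA_integer_))
}

#' Split an insert into substrate-encoded bases and the added tail
#'
#' Removes up to `terminal_count` leading copies of the substrate's terminal
#' base from the 5' (substrate-proximal) end of the insert; the remainder is
#' the added tail. Because trimming is anchored at the substrate side and
#' capped at `terminal_count`, added nucleotides identical to the terminal
#' base are kept as tail — equivalent to reversing the insert so the
#' ultimate 3' end comes first and right-trimming the substrate run.
#'
#' @param insert Insert sequence (between prefix end and adapter start).
#' @param substrate A [substrate_spec()].
#' @return A list with `trimmed` (number of substrate bases removed,
#'   `0..terminal_count`) and `tail` (added tail, 5' to 3').
#' @examples
#' s <- substrate_spec(terminal_base = "A", terminal_count = 4)
#' trim_substrate_run("AAAACC", s)  # trimmed 4, tail "CC"
#' trim_substrate_run("AAAAAA", s)  # trimmed 4, tail "AA"
#' @export
trim_substrate_run <- function(insert, substrate) {
  stopifnot(inherits(substrate, "substrate_spec"))
  run <- regexpr(paste0("^", substrate$terminal_base, "*"), insert)
  run_len <- attr(run, "match.length")
  trimmed <- pmin(run_len, substrate$terminal_count)
  list(trimmed = as.integer(trimmed),
       tail = substr(insert, trimmed + 1L, nchar(insert)))
}

#' Call the added tail of a single read
#'
#' Applies the full selection and extraction procedure to one read; see
#' [call_batch()] for the rules. Provided for interactive inspection —
#' batch processing should use [call_batch()].
#'
#' @param read A one-row list or tibble with `id` and `sequence` (a bare
#'   character sequence is also accepted, with an empty id).
#' @inheritParams call_batch
#' @return A one-row tibble (see [call_batch()] for columns).
#' @examples
#' s <- substrate_spec(); a <- adapter_spec()
#' call_read(paste0(s$prefix, "AAAA", "CC", a$sequence), s, a)
#' @export
call_read <- function(read, substrate, adapter, max_insert = 100L,
                      junk_min_insert = NULL) {
  if (is.character(read)) read <- list(id = "", sequence = read)
  call_reads_impl(read$id, read$sequence, substrate, adapter,
                  max_insert, junk_min_insert)
}

#' Call added tails for a batch of reads
#'
#' Re-implements, natively and deterministically, the read selection and
#' tail extraction used for 3'-RACE-seq libraries:
#' \enumerate{
#'   \item the read must begin with an entirely correct substrate prefix
#'     (else `REJECTED`/`PREFIX_MISSING`);
#'   \item the full adapter must occur downstream, leftmost occurrence used
#'     (else `REJECTED`/`ADAPTER_MISSING`);
#'   \item the insert between prefix end and adapter start must not exceed
#'     `max_insert` nt (else `REJECTED`/`INSERT_TOO_LONG`);
#'   \item up to `terminal_count` substrate-encoded terminal bases are
#'     trimmed from the insert's 5' side; the remainder is the added tail.
#' }
#' Reads whose tail is empty are `UNTAILED`; otherwise `TAILED`. Reads whose
#' trimmed substrate run is shorter than `terminal_count` are retained but
#' flagged (`short_run`), since the substrate-encoded run is only expected,
#' not guaranteed, to be complete.
#'
#' An optional low-complexity ("junk") rule is off by default because its
#' published definition is ambiguous: when `junk_min_insert` is set, reads
#' failing the prefix match whose sequence before the leftmost adapter
#' occurrence is at most `junk_min_insert` nt are labelled `LOW_COMPLEXITY`
#' instead of `PREFIX_MISSING`. Untailed products are never discarded.
#'
#' @param reads Tibble/data.frame with columns `id` and `sequence` (e.g.
#'   from [read_fastq()] or [simulate_reads()]).
#' @param substrate A [substrate_spec()].
#' @param adapter An [adapter_spec()].
#' @param max_insert Maximum insert length in nt (default 100); longer
#'   inserts are rejected as contaminants.
#' @param junk_min_insert Optional integer enabling the low-complexity rule
#'   (default `NULL`, off).
#' @return A list with:
#' \describe{
#'   \item{calls}{tibble, one row per read in input order: `read_id`,
#'     `status` (`TAILED`/`UNTAILED`/`REJECTED`), `reject_reason`
#'     (`PREFIX_MISSING`/`ADAPTER_MISSING`/`INSERT_TOO_LONG`/
#'     `LOW_COMPLEXITY` or `NA`), `insert`, `trimmed`, `tail`,
#'     `tail_length`, `short_run`.}
#'   \item{summary}{list of counts per status and reject reason plus
#'     `n_reads` and `n_short_run`; see [summarize_calls()].}
#' }
#' @examples
#' s <- substrate_spec(); a <- adapter_spec()
#' reads <- tibble::tibble(
#'   id = c("r1", "r2"),
#'   sequence = c(paste0(s$prefix, "AAAACC", a$sequence),
#'                paste0(s$prefix, "AAAA", a$sequence)))
#' call_batch(reads, s, a)$calls
#' @export
call_batch <- function(reads, substrate, adapter, max_insert = 100L,
                       junk_min_insert = NULL) {
  stopifnot(is.data.frame(reads), all(c("id", "sequence") %in% names(reads)))
  calls <- call_reads_impl(reads$id, reads$sequence, substrate, adapter,
                           max_insert, junk_min_insert)
  list(calls = calls, summary = summarize_calls(calls))
}

call_reads_impl <- function(ids, seqs, substrate, adapter, max_insert,
                            junk_min_insert) {
  stopifnot(inherits(substrate, "substrate_spec"),
            inherits(adapter, "adapter_spec"))
  max_insert <- as.integer(max_insert)
  n <- length(seqs)
  seqs <- toupper(rna_to_dna(seqs))

  pre <- locate_prefix(seqs, substrate)
  ad <- locate_adapter(seqs, adapter,
                       search_from = ifelse(pre$match, pre$end, 0L))

  status <- rep("REJECTED", n)
  reason <- rep(NA_character_, n)
  insert <- rep(NA_character_, n)
  trimmed <- rep(NA_integer_, n)
  tail_seq <- rep(NA_character_, n)

  reason[!pre$match] <- "PREFIX_MISSING"
  if (!is.null(junk_min_insert)) {
    junk <- !pre$match & ad$match & ad$start <= as.integer(junk_min_insert)
    reason[junk] <- "LOW_COMPLEXITY"
  }
  reason[pre$match & !ad$match] <- "ADAPTER_MISSING"

  ok <- pre$match & ad$match
  if (any(ok)) {
    ins <- substr(seqs[ok], pre$end[ok] + 1L, ad$start[ok])
    too_long <- nchar(ins) > max_insert
    idx_ok <- which(ok)
    reason[idx_ok[too_long]] <- "INSERT_TOO_LONG"
    keep <- idx_ok[!too_long]
    ins <- ins[!too_long]
    tr <- trim_substrate_run(ins, substrate)
    insert[keep] <- ins
    trimmed[keep] <- tr$trimmed
    tail_seq[keep] <- tr$tail
    status[keep] <- ifelse(nchar(tr$tail) > 0L, "TAILED", "UNTAILED")
  }

  tibble::tibble(
    read_id = as.character(ids),
    status = status,
    reject_reason = reason,
    insert = insert,
    trimmed = trimmed,
    tail = tail_seq,
    tail_length = ifelse(is.na(tail_seq), NA_integer_, nchar(tail_seq)),
    short_run = !is.na(trimmed) & trimmed < substrate$terminal_count
  )
}

#' Summarise tail calls
#'
#' Counts calls per status and rejection reason. Counts always partition the
#' input: `n_tailed + n_untailed + n_rejected == n_reads`.
#'
#' @param calls Calls tibble from [call_batch()].
#' @return A list with `n_reads`, `n_tailed`, `n_untailed`, `n_rejected`,
#'   `reject_reasons` (named counts) and `n_short_run`.
#' @export
summarize_calls <- function(calls) {
  reasons <- c("PREFIX_MISSING", "ADAPTER_MISSING", "INSERT_TOO_LONG",
               "LOW_COMPLEXITY")
  rr <- table(factor(calls$reject_reason, levels = reasons))
  list(
    n_reads = nrow(calls),
    n_tailed = sum(calls$status == "TAILED"),
    n_untailed = sum(calls$status == "UNTAILED"),
    n_rejected = sum(calls$status == "REJECTED"),
    reject_reasons = setNames(as.integer(rr), reasons),
    n_short_run = sum(calls$short_run, na.rm = TRUE)
  )
}
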