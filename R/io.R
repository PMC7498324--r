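#' Read sequencing reads from FASTQ or FASTA
#'
#' FASTQ files are parsed as strict 4-line records; malformed records raise
#' an error naming the failing record index. Files whose first non-empty
#' byte is `>` are auto-detected as FASTA and read via
#' [Biostrings::readDNAStringSet()] (no qualities). Sequences are uppercased
#' and `U` is converted to `T` on input.
#'
#' @param path Path to a FASTQ or FASTA file.
#' @return A tibble with columns `id`, `sequence`, `quality` (`NA` for
#'   FASTA input).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) {
    stop_racetails(paste("no such file:", path), "racetails_io_error")
  }
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, ">")) {
    xs <- Biostrings::readBStringSet(path)
    return(tibble::tibble(id = names(xs),
                          sequence = unname(toupper(rna_to_dna(as.character(xs)))),
                          quality = NA_character_))
  }
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]  # drop trailing blanks
  if (length(lines) %% 4L != 0L) {
    stop_racetails(
      sprintf("malformed FASTQ: truncated record at index %d",
              length(lines) %/% 4L + 1L),
      "racetails_parse_error")
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(qual) != nchar(seqs))
  if (length(bad)) {
    stop_racetails(
      sprintf("malformed FASTQ record at index %d", bad[1L]),
      "racetails_parse_error")
  }
  tibble::tibble(
    id = sub("\\s.*$", "", substring(hdr, 2L)),
    sequence = toupper(rna_to_dna(seqs)),
    quality = qual
  )
}

#' Write reads as FASTQ
#'
#' @param reads Tibble with `id`, `sequence` and optionally `quality`
#'   (constant `"I"` qualities are written when absent).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads), all(c("id", "sequence") %in% names(reads)))
  qual <- if ("quality" %in% names(reads) && !anyNA(reads$quality)) {
    reads$quality
  } else {
    strrep("I", nchar(reads$sequence))
  }
  out <- as.vector(rbind(paste0("@", reads$id), reads$sequence, "+", qual))
  writeLines(out, path)
  invisible(path)
}

#' Read anisotropy titrations from TSV
#'
#' Expects a tab-separated file with header
#' `experiment_id  concentration_nM  anisotropy  replicate`. Rows with
#' non-numeric or negative concentrations, or non-numeric anisotropies,
#' are rejected with their line numbers.
#'
#' @param path Path to the TSV file.
#' @return A tibble of measurements.
#' @export
read_titrations <- function(path) {
  if (!file.exists(path)) {
    stop_racetails(paste("no such file:", path), "racetails_io_error")
  }
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, sep = "\t")
  need <- c("experiment_id", "concentration_nM", "anisotropy", "replicate")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_racetails(paste("titration file lacks column(s):",
                         paste(missing_cols, collapse = ", ")),
                   "racetails_schema_error")
  }
  conc <- suppressWarnings(as.numeric(df$concentration_nM))
  anis <- suppressWarnings(as.numeric(df$anisotropy))
  repl <- suppressWarnings(as.integer(df$replicate))
  bad <- which(is.na(conc) | is.na(anis) | is.na(repl) | conc < 0)
  if (length(bad)) {
    stop_racetails(
      sprintf("invalid titration row(s) at line(s): %s (1 = first data row)",
              paste(bad, collapse = ", ")),
      "racetails_validation_error")
  }
  tibble::tibble(experiment_id = df$experiment_id, concentration_nM = conc,
                 anisotropy = anis, replicate = repl)
}

#' Write anisotropy titrations as TSV
#'
#' @param measurements Tibble with `experiment_id`, `concentration_nM`,
#'   `anisotropy`, `replicate`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titrations <- function(measurements, path) {
  validate_measurements(measurements, need_experiment = TRUE)
  utils::write.table(measurements, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write tail calls as TSV
#'
#' @param calls Calls tibble from [call_batch()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a composition result as a tidy TSV
#'
#' One row per reported position with coverage and the four base
#' frequencies (RNA alphabet).
#'
#' @param composition A [positional_composition()] result.
#' @param path Output path.
#' @param variant Variant label written in the first column.
#' @return `path`, invisibly.
#' @export
write_composition <- function(composition, path, variant = "sample") {
  stopifnot(inherits(composition, "composition_result"))
  pos <- composition$reported_positions
  df <- data.frame(
    variant = variant,
    position = pos,
    coverage = unname(composition$coverage[as.character(pos)]),
    freq_A = composition$per_position["A", ],
    freq_C = composition$per_position["C", ],
    freq_G = composition$per_position["G", ],
    freq_U = composition$per_position["U", ]
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
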