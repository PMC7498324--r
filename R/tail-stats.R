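#' Build a minimal calls table from bare tail sequences
#'
#' Convenience constructor for analyses that start from tail sequences
#' rather than reads (e.g. model-based simulation of tails alone). Empty
#' strings become `UNTAILED` calls.
#'
#' @param tails Character vector of tails (DNA or RNA alphabet).
#' @return A calls tibble compatible with the composition statistics.
#' @examples
#' calls_from_tails(c("CC", "", "AC"))
#' @export
calls_from_tails <- function(tails) {
  tails <- toupper(rna_to_dna(tails))
  tibble::tibble(
    read_id = sprintf("tail_%06d", seq_along(tails)),
    status = ifelse(nchar(tails) > 0L, "TAILED", "UNTAILED"),
    reject_reason = NA_character_,
    insert = tails,
    trimmed = 0L,
    tail = tails,
    tail_length = nchar(tails),
    short_run = FALSE
  )
}

accepted_calls <- function(calls) {
  calls[calls$status %in% c("TAILED", "UNTAILED"), , drop = FALSE]
}

#' Tail length statistics
#'
#' Mean, median and histogram of added-tail lengths over non-rejected reads.
#' Untailed reads (length 0) are included by default; both conventions are
#' reported because summaries of tail length are sometimes quoted without
#' stating whether untailed molecules count.
#'
#' @param calls Calls tibble from [call_batch()] or [calls_from_tails()].
#' @param include_untailed Include length-0 reads in mean/median/histogram
#'   (default `TRUE`).
#' @return A list with `mean`, `median`, `histogram` (named integer counts
#'   by length), `n` and `include_untailed`.
#' @examples
#' length_stats(calls_from_tails(c("", "CC", "CC", "CCCCCCC")))
#' @export
length_stats <- function(calls, include_untailed = TRUE) {
  acc <- accepted_calls(calls)
  if (nrow(acc) == 0L) {
    stop_racetails("no non-rejected calls: length statistics undefined",
                   "racetails_empty_result_error")
  }
  lens <- acc$tail_length
  if (!include_untailed) lens <- lens[lens > 0L]
  if (length(lens) == 0L) {
    stop_racetails("no tailed calls after excluding untailed reads",
                   "racetails_empty_result_error")
  }
  hist <- table(factor(lens, levels = 0:max(lens)))
  list(mean = mean(lens), median = median(lens),
       histogram = setNames(as.integer(hist), names(hist)),
       n = length(lens), include_untailed = include_untailed)
}

#' Overall nucleotide frequencies in added tails
#'
#' Pools every nucleotide of every tail of non-rejected reads and reports
#' base fractions in RNA alphabet (T counted as U). This is the statistic
#' behind composition headlines such as "about 40-50% cytidines, under 1%
#' guanosines".
#'
#' @param calls Calls tibble.
#' @return Named numeric vector over `A`, `C`, `G`, `U`, summing to 1.
#' @examples
#' overall_frequencies(calls_from_tails(c("CC", "CT", "A")))
#' @export
overall_frequencies <- function(calls) {
  acc <- accepted_calls(calls)
  nt <- unlist(strsplit(acc$tail[acc$tail_length > 0L], ""), use.names = FALSE)
  if (length(nt) == 0L) {
    stop_racetails("no tail nucleotides: overall frequencies undefined",
                   "racetails_empty_result_error")
  }
  counts <- table(factor(nt, levels = DNA_BASES))
  setNames(as.numeric(counts) / length(nt), RNA_BASES)
}

#' 3'-anchored per-position tail composition
#'
#' Computes the per-position nucleotide composition of added tails anchored
#' at the 3' terminus (position 1 = last added nucleotide), the positional
#' coverage (fraction of tailed reads whose tail reaches each position), and
#' summary statistics. Positions are reported only while covered by at least
#' `min_coverage` of the tailed reads and up to `max_positions` from the 3'
#' end; both rules are display filters — coverage itself is recorded for
#' every position, and the overall frequencies use every tail nucleotide.
#'
#' @param calls Calls tibble.
#' @param min_coverage Minimum fraction of tailed reads covering a position
#'   for it to be reported (default 0.05).
#' @param max_positions Maximum number of 3'-anchored positions reported
#'   (default 25).
#' @param include_untailed Convention for the length mean/median carried in
#'   the result (default `TRUE`).
#' @return An object of class `composition_result`: `per_position` (4 x
#'   reported-positions matrix, RNA rownames), `reported_positions`,
#'   `coverage` (all positions), `position_counts` (tails reaching each
#'   position), `overall`, `tailed_fraction`, `n_tailed`, `n_untailed`,
#'   `length_mean`, `length_median`, `length_histogram`, and the filter
#'   parameters.
#' @examples
#' comp <- positional_composition(calls_from_tails(rep(c("CC", "AC", ""), 10)))
#' comp$per_position
#' @export
positional_composition <- function(calls, min_coverage = 0.05,
                                   max_positions = 25L,
                                   include_untailed = TRUE) {
  acc <- accepted_calls(calls)
  tails <- acc$tail[acc$tail_length > 0L]
  n_tailed <- length(tails)
  if (n_tailed == 0L) {
    stop_racetails("no tailed calls: positional composition undefined",
                   "racetails_empty_result_error")
  }
  n_untailed <- nrow(acc) - n_tailed
  lens <- nchar(tails)
  l_max <- max(lens)

  # 3'-anchored: reverse each tail so position 1 is the last added base,
  # then count column-wise — the reversal construction used for 3' ends.
  rev_tails <- reverse_strings(tails)
  counts <- matrix(0, nrow = 4L, ncol = l_max,
                   dimnames = list(DNA_BASES, as.character(1:l_max)))
  pos_counts <- integer(l_max)
  for (p in seq_len(l_max)) {
    b <- substr(rev_tails[lens >= p], p, p)
    pos_counts[p] <- length(b)
    tb <- table(factor(b, levels = DNA_BASES))
    counts[, p] <- as.integer(tb)
  }
  coverage <- pos_counts / n_tailed
  freq <- sweep(counts, 2L, pos_counts, "/")
  rownames(freq) <- RNA_BASES

  reported <- which(coverage >= min_coverage & seq_len(l_max) <= max_positions)
  ls <- length_stats(acc, include_untailed = include_untailed)

  structure(list(
    per_position = freq[, reported, drop = FALSE],
    reported_positions = reported,
    coverage = setNames(coverage, as.character(1:l_max)),
    position_counts = setNames(pos_counts, as.character(1:l_max)),
    overall = overall_frequencies(acc),
    tailed_fraction = n_tailed / (n_tailed + n_untailed),
    n_tailed = n_tailed,
    n_untailed = n_untailed,
    length_mean = ls$mean,
    length_median = ls$median,
    length_histogram = ls$histogram,
    min_coverage = min_coverage,
    max_positions = as.integer(max_positions),
    include_untailed = include_untailed
  ), class = "composition_result")
}

reverse_strings <- function(x) {
  vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

#' @export
print.composition_result <- function(x, ...) {
  cat("<composition_result>\n",
      sprintf("  %d tailed + %d untailed reads (tailed fraction %.3f)\n",
              x$n_tailed, x$n_untailed, x$tailed_fraction),
      sprintf("  tail length mean %.2f, median %.1f (untailed %s)\n",
              x$length_mean, x$length_median,
              if (x$include_untailed) "included" else "excluded"),
      "  overall frequencies: ",
      paste(sprintf("%s %.1f%%", names(x$overall), 100 * x$overall),
            collapse = ", "), "\n",
      sprintf("  %d position(s) reported (coverage >= %.0f%%, max %d)\n",
              ncol(x$per_position), 100 * x$min_coverage, x$max_positions),
      sep = "")
  invisible(x)
}

#' Combine composition results across enzyme variants
#'
#' Flattens one or more [positional_composition()] results into a tidy
#' long-format table: one row per (variant, position, base) plus overall-
#' frequency rows (`position = NA`), suitable for faceted plotting.
#'
#' @param results Named list of `composition_result` objects; names are the
#'   variant labels and must be unique.
#' @return A tibble with columns `variant`, `position`, `base`, `frequency`,
#'   `coverage` (`NA` on overall rows).
#' @examples
#' comp <- positional_composition(calls_from_tails(c("CC", "AC")))
#' compare_variants(list(wt = comp))
#' @export
compare_variants <- function(results) {
  if (length(results) == 0L) {
    stop_racetails("`results` must contain at least one composition result",
                   "racetails_validation_error")
  }
  if (is.null(names(results)) || anyDuplicated(names(results))) {
    stop_racetails("`results` must be uniquely named by variant",
                   "racetails_validation_error")
  }
  rows <- lapply(names(results), function(v) {
    r <- results[[v]]
    stopifnot(inherits(r, "composition_result"))
    pos <- r$reported_positions
    per <- if (length(pos)) {
      tibble::tibble(
        variant = v,
        position = rep(pos, each = 4L),
        base = rep(RNA_BASES, times = length(pos)),
        frequency = as.vector(r$per_position),
        coverage = rep(unname(r$coverage[as.character(pos)]), each = 4L)
      )
    } else NULL
    overall <- tibble::tibble(
      variant = v, position = NA_integer_, base = RNA_BASES,
      frequency = unname(r$overall), coverage = NA_real_
    )
    rbind(per, overall)
  })
  do.call(rbind, rows)
}
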