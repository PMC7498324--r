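#' Pipeline configuration
#'
#' Bundles the substrate, adapter and analysis thresholds used by
#' [run_pipeline()]. Defaults follow the published analysis conventions:
#' inserts over 100 nt are contaminants, composition positions are reported
#' while covered by at least 5% of tailed reads and up to 25 positions from
#' the 3' end.
#'
#' @param substrate A [substrate_spec()].
#' @param adapter An [adapter_spec()].
#' @param max_insert Maximum insert length, nt (default 100).
#' @param min_coverage Positional coverage threshold (default 0.05).
#' @param max_positions 3'-anchored position cap (default 25).
#' @param include_untailed Length-statistics convention (default `TRUE`).
#' @param seed Integer seed recorded with outputs.
#' @return An object of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config()
#' @export
pipeline_config <- function(substrate = substrate_spec(),
                            adapter = adapter_spec(),
                            max_insert = 100L,
                            min_coverage = 0.05,
                            max_positions = 25L,
                            include_untailed = TRUE,
                            seed = 1L) {
  stopifnot(inherits(substrate, "substrate_spec"),
            inherits(adapter, "adapter_spec"))
  max_insert <- as.integer(max_insert)
  max_positions <- as.integer(max_positions)
  if (is.na(max_insert) || max_insert < 1L) {
    stop_racetails("`max_insert` must be a positive integer",
                   "racetails_validation_error")
  }
  if (min_coverage < 0 || min_coverage > 1) {
    stop_racetails("`min_coverage` must lie in [0,1]",
                   "racetails_validation_error")
  }
  if (is.na(max_positions) || max_positions < 1L) {
    stop_racetails("`max_positions` must be a positive integer",
                   "racetails_validation_error")
  }
  structure(list(substrate = substrate, adapter = adapter,
                 max_insert = max_insert, min_coverage = min_coverage,
                 max_positions = max_positions,
                 include_untailed = isTRUE(include_untailed),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialise / restore a pipeline configuration
#'
#' Configurations round-trip losslessly through JSON.
#'
#' @param config A [pipeline_config()].
#' @param path JSON path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- list(
    substrate = unclass(config$substrate),
    adapter = unclass(config$adapter),
    max_insert = config$max_insert,
    min_coverage = config$min_coverage,
    max_positions = config$max_positions,
    include_untailed = config$include_untailed,
    seed = config$seed
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    substrate = substrate_spec(prefix = x$substrate$prefix,
                               terminal_base = x$substrate$terminal_base,
                               terminal_count = x$substrate$terminal_count,
                               name = x$substrate$name),
    adapter = adapter_spec(sequence = x$adapter$sequence,
                           name = x$adapter$name),
    max_insert = x$max_insert,
    min_coverage = x$min_coverage,
    max_positions = x$max_positions,
    include_untailed = x$include_untailed,
    seed = x$seed
  )
}

#' Run the tail-calling and composition pipeline end to end
#'
#' Reads a FASTQ/FASTA file, calls tails, computes composition statistics
#' and writes the standard output bundle into `out_dir`: `calls.tsv`,
#' `composition.tsv` and `summary.json` (call counts, overall frequencies,
#' tailed fraction, length statistics, the seed and a hash of the
#' configuration). Two runs with identical inputs and configuration produce
#' identical analytical content.
#'
#' @param config A [pipeline_config()].
#' @param reads_path Path to the input FASTQ/FASTA.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages (default `FALSE`).
#' @return Invisibly, a list with `calls`, `summary`, `composition` and
#'   `paths` of the written files.
#' @export
run_pipeline <- function(config, reads_path, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  reads <- read_fastq(reads_path)
  if (nrow(reads) == 0L) {
    stop_racetails("no reads in input file", "racetails_empty_input_error")
  }
  say("read %d reads from %s", nrow(reads), reads_path)

  res <- call_batch(reads, config$substrate, config$adapter,
                    max_insert = config$max_insert)
  s <- res$summary
  say("called: %d tailed, %d untailed, %d rejected",
      s$n_tailed, s$n_untailed, s$n_rejected)

  composition <- positional_composition(
    res$calls, min_coverage = config$min_coverage,
    max_positions = config$max_positions,
    include_untailed = config$include_untailed)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    calls = file.path(out_dir, "calls.tsv"),
    composition = file.path(out_dir, "composition.tsv"),
    summary = file.path(out_dir, "summary.json")
  )
  write_calls(res$calls, paths$calls)
  write_composition(composition, paths$composition,
                    variant = config$substrate$name)

  summary_out <- list(
    n_reads = s$n_reads,
    counts = list(tailed = s$n_tailed, untailed = s$n_untailed,
                  rejected = s$n_rejected),
    reject_reasons = as.list(s$reject_reasons),
    n_short_run = s$n_short_run,
    tailed_fraction = composition$tailed_fraction,
    overall_frequencies = as.list(composition$overall),
    length_mean = composition$length_mean,
    length_median = composition$length_median,
    seed = config$seed,
    config_hash = rlang::hash(unclass(config))
  )
  jsonlite::write_json(summary_out, paths$summary, auto_unbox = TRUE,
                       digits = NA)
  say("wrote %s", out_dir)
  invisible(list(calls = res$calls, summary = s, composition = composition,
                 paths = paths))
}
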