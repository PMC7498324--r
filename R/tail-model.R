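#' Probabilistic model of added 3' tails
#'
#' Defines the generative model the read simulator draws tails from: a
#' distribution over tail lengths and, for each position along the tail
#' (counted 5' to 3' from the first added nucleotide), a probability vector
#' over the four bases. An optional terminal override replaces the base
#' distribution at fixed distances from the 3' end (distance 1 = the last
#' added nucleotide), which is how a terminal-position incorporation bias —
#' such as a nucleotidyltransferase's preference for cytidine at the last and
#' penultimate tail positions — is expressed. The override wins wherever both
#' apply.
#'
#' @param length_probs Named numeric vector of probabilities over tail
#'   lengths; names are the lengths (0 allowed). Must sum to 1 within 1e-12.
#' @param base_probs Either a single named probability vector over
#'   `A`,`C`,`G`,`T` (used at every start position) or a 4-row matrix with
#'   rownames `A`,`C`,`G`,`T` and one column per start position 1..L_max.
#'   Each column must sum to 1 within 1e-12.
#' @param terminal_override Optional named list; names are distances from the
#'   3' end (`"1"` = last position), values are named probability vectors
#'   over `A`,`C`,`G`,`T`.
#' @param description Label for the model.
#'
#' @return An object of class `tail_model` with elements `length_probs`
#'   (dense vector over lengths `0..L_max`), `base_probs` (4 x L_max matrix),
#'   `terminal_override`, `description`.
#' @seealso [sample_tails()], [expected_composition()], [default_tail_model()]
#' @examples
#' # always exactly "CC"
#' tail_model(c(`2` = 1), c(A = 0, C = 1, G = 0, T = 0))
#' @export
tail_model <- function(length_probs, base_probs, terminal_override = NULL,
                       description = "tail model") {
  if (is.null(names(length_probs))) {
    stop_racetails("`length_probs` must be named by tail length",
                   "racetails_validation_error")
  }
  lens <- suppressWarnings(as.integer(names(length_probs)))
  if (anyNA(lens) || any(lens < 0L)) {
    stop_racetails("`length_probs` names must be non-negative integers",
                   "racetails_validation_error")
  }
  if (any(length_probs < 0) || any(length_probs > 1) ||
      abs(sum(length_probs) - 1) > 1e-12) {
    stop_racetails("`length_probs` must lie in [0,1] and sum to 1 (1e-12)",
                   "racetails_validation_error")
  }
  l_max <- max(lens)
  dense <- numeric(l_max + 1L)
  names(dense) <- 0:l_max
  dense[as.character(lens)] <- length_probs

  if (is.vector(base_probs) && !is.matrix(base_probs)) {
    base_probs <- matrix(rep(check_base_probs(base_probs), max(l_max, 1L)),
                         nrow = 4L, dimnames = list(DNA_BASES, NULL))
  } else {
    base_probs <- as.matrix(base_probs)
    if (is.null(rownames(base_probs))) rownames(base_probs) <- DNA_BASES
    base_probs <- base_probs[DNA_BASES, , drop = FALSE]
    if (ncol(base_probs) < l_max) {
      stop_racetails(
        "`base_probs` must provide one column per start position up to L_max",
        "racetails_validation_error")
    }
    for (j in seq_len(ncol(base_probs))) check_base_probs(base_probs[, j])
  }

  if (!is.null(terminal_override)) {
    if (is.null(names(terminal_override))) {
      stop_racetails("`terminal_override` must be named by distance from 3' end",
                     "racetails_validation_error")
    }
    d <- suppressWarnings(as.integer(names(terminal_override)))
    if (anyNA(d) || any(d < 1L)) {
      stop_racetails("`terminal_override` distances must be positive integers",
                     "racetails_validation_error")
    }
    terminal_override <- lapply(terminal_override, check_base_probs)
  }

  structure(
    list(length_probs = dense, base_probs = base_probs,
         terminal_override = terminal_override, description = description),
    class = "tail_model"
  )
}

check_base_probs <- function(p) {
  if (is.null(names(p))) names(p) <- DNA_BASES
  p <- p[DNA_BASES]
  if (anyNA(p) || any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-12) {
    stop_racetails(
      "base probabilities must be named over A/C/G/T, lie in [0,1] and sum to 1",
      "racetails_validation_error")
  }
  p
}

#' @export
print.tail_model <- function(x, ...) {
  cat("<tail_model> ", x$description, "\n  lengths 0..",
      length(x$length_probs) - 1L, ", terminal override at ",
      if (is.null(x$terminal_override)) "none" else
        paste(names(x$terminal_override), collapse = ", "),
      " position(s) from 3' end\n", sep = "")
  invisible(x)
}

tail_model_lmax <- function(model) length(model$length_probs) - 1L

# Base distribution for 3'-anchored position p of a tail of length len:
# terminal override at distance p if present, else the start-position column.
model_base_probs_at <- function(model, len, pos3) {
  ov <- model$terminal_override[[as.character(pos3)]]
  if (!is.null(ov)) return(ov)
  model$base_probs[, len - pos3 + 1L]
}

#' Default tail model emulating C-rich nucleotidyltransferase tails
#'
#' A ready-made [tail_model()] reflecting the behaviour of a CutA-type
#' template-independent transferase offered an equimolar NTP mix: short
#' heteropolymeric tails of 0–7 nt, overall composition dominated by
#' cytidine (~45%) with adenosine next, under 1% guanosine and a minor
#' uridine fraction, and a strengthened cytidine preference at the last and
#' penultimate tail positions.
#'
#' @return A `tail_model`.
#' @examples
#' m <- default_tail_model()
#' expected_composition(m)$overall
#' @export
default_tail_model <- function() {
  tail_model(
    length_probs = c(`0` = 0.30, `1` = 0.20, `2` = 0.16, `3` = 0.12,
                     `4` = 0.09, `5` = 0.06, `6` = 0.04, `7` = 0.03),
    base_probs = c(A = 0.515, C = 0.387, G = 0.008, T = 0.09),
    terminal_override = list(
      `1` = c(A = 0.302, C = 0.600, G = 0.008, T = 0.09),
      `2` = c(A = 0.402, C = 0.500, G = 0.008, T = 0.09)
    ),
    description = "C-dominant 0-7 nt tails, terminal C bias"
  )
}

#' Contaminant class fractions for read simulation
#'
#' Fractions of simulated reads allocated to each contaminant class. The
#' simulator allocates exact counts, `round(fraction * n_reads)` per class;
#' the remainder are clean reads. Classes mirror the filters of the tail
#' caller: reads without a correct substrate prefix, reads without the 3'
#' adapter, reads whose insert is padded beyond the insert-length cutoff,
#' and junk reads consisting of at most 5 random bases plus the adapter.
#'
#' @param fraction_no_prefix,fraction_no_adapter,fraction_long_insert,fraction_junk
#'   Fractions in \[0,1\]; their sum must not exceed 1.
#' @param long_insert_length Insert length for the long-insert class
#'   (must exceed 100, the default insert cutoff).
#' @return An object of class `contaminant_model`.
#' @examples
#' contaminant_model(fraction_no_adapter = 0.1)
#' @export
contaminant_model <- function(fraction_no_prefix = 0,
                              fraction_no_adapter = 0,
                              fraction_long_insert = 0,
                              fraction_junk = 0,
                              long_insert_length = 150L) {
  fr <- c(no_prefix = fraction_no_prefix, no_adapter = fraction_no_adapter,
          long_insert = fraction_long_insert, junk = fraction_junk)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1 + 1e-12) {
    stop_racetails("contaminant fractions must lie in [0,1] and sum to <= 1",
                   "racetails_validation_error")
  }
  long_insert_length <- as.integer(long_insert_length)
  if (is.na(long_insert_length) || long_insert_length <= 100L) {
    stop_racetails("`long_insert_length` must exceed 100",
                   "racetails_validation_error")
  }
  structure(list(fractions = fr, long_insert_length = long_insert_length),
            class = "contaminant_model")
}

#' Draw added tails from a tail model
#'
#' Samples `n` tails: the length from `length_probs`, then each base from the
#' start-position distribution, with the terminal override applied at its
#' stated distances from the 3' end. Uses the session RNG; seed via
#' [set.seed()] (or let [simulate_reads()] manage seeding) for
#' reproducibility.
#'
#' @param model A [tail_model()].
#' @param n Number of tails to draw.
#' @return Character vector of length `n` of DNA-alphabet tails (may contain
#'   empty strings for length-0 draws).
#' @examples
#' m <- tail_model(c(`2` = 1), c(A = 0, C = 1, G = 0, T = 0))
#' sample_tails(m, 3) # "CC" "CC" "CC"
#' @export
sample_tails <- function(model, n = 1L) {
  if (!inherits(model, "tail_model")) {
    stop_racetails("`model` must be a tail_model", "racetails_validation_error")
  }
  n <- as.integer(n)
  if (is.na(n) || n < 0L) {
    stop_racetails("`n` must be a non-negative integer",
                   "racetails_validation_error")
  }
  lens_support <- as.integer(names(model$length_probs))
  lens <- lens_support[sample.int(length(lens_support), n, replace = TRUE,
                                  prob = model$length_probs)]
  tails <- character(n)
  for (len in unique(lens[lens > 0L])) {
    idx <- which(lens == len)
    chars <- matrix("", nrow = length(idx), ncol = len)
    for (i in seq_len(len)) {
      p <- model_base_probs_at(model, len, pos3 = len - i + 1L)
      chars[, i] <- sample(DNA_BASES, length(idx), replace = TRUE, prob = p)
    }
    tails[idx] <- apply(chars, 1L, paste0, collapse = "")
  }
  tails
}

#' Analytic expected tail composition under a tail model
#'
#' Computes, by exact summation over the model's finite length support, the
#' quantities the empirical composition statistics estimate: per-position
#' base frequencies anchored at the 3' end (position 1 = last added
#' nucleotide), positional coverage, and the overall base frequencies across
#' all tail nucleotides. Serves as the oracle against which compositions
#' measured on simulated reads are checked.
#'
#' For 3'-anchored position `p`, coverage is `P(length >= p)` and the
#' frequency of base `b` is the length-distribution mixture of the base
#' distribution at start position `len - p + 1` (or the terminal override at
#' distance `p`), conditional on the tail reaching position `p`. Positions
#' with zero coverage are reported as `NA` (undefined), not zero.
#'
#' @param model A [tail_model()].
#' @param max_positions Number of 3'-anchored positions to report (defaults
#'   to the model's maximum length).
#' @return A list with `per_position` (4 x positions matrix, RNA rownames
#'   `A`,`C`,`G`,`U`), `coverage` (named vector), `overall` (named vector),
#'   and `mean_length` (expected tail length, untailed included).
#' @examples
#' m <- tail_model(c(`1` = 0.9, `2` = 0.1), c(A = 0, C = 1, G = 0, T = 0))
#' expected_composition(m)$coverage # 1.0, 0.1
#' @export
expected_composition <- function(model, max_positions = NULL) {
  if (!inherits(model, "tail_model")) {
    stop_racetails("`model` must be a tail_model", "racetails_validation_error")
  }
  l_max <- tail_model_lmax(model)
  if (is.null(max_positions)) max_positions <- l_max
  max_positions <- min(as.integer(max_positions), l_max)
  lens <- as.integer(names(model$length_probs))
  pl <- model$length_probs

  n_pos <- max(max_positions, 0L)
  per_position <- matrix(NA_real_, nrow = 4L, ncol = n_pos,
                         dimnames = list(RNA_BASES,
                                         if (n_pos) as.character(1:n_pos)))
  coverage <- numeric(n_pos)
  overall_counts <- setNames(numeric(4L), DNA_BASES)

  for (p in seq_len(l_max)) {
    reach <- lens >= p
    cov <- sum(pl[reach])
    mix <- setNames(numeric(4L), DNA_BASES)
    for (len in lens[reach & pl > 0]) {
      mix <- mix + pl[as.character(len)] * model_base_probs_at(model, len, p)
    }
    overall_counts <- overall_counts + mix
    if (p <= n_pos) {
      coverage[p] <- cov
      if (cov > 0) per_position[, p] <- mix / cov
    }
  }
  if (n_pos) names(coverage) <- as.character(1:n_pos)
  mean_length <- sum(lens * pl)
  overall <- if (mean_length > 0) overall_counts / mean_length else
    setNames(rep(NA_real_, 4L), DNA_BASES)
  names(overall) <- RNA_BASES
  list(per_position = per_position, coverage = coverage, overall = overall,
       mean_length = mean_length)
}
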