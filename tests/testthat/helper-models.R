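# Shared fixtures and independent oracles, built in code.

toy_substrate <- function() {
  substrate_spec(prefix = "ACGTACGTACGTACGTACGTAC", terminal_base = "A",
                 terminal_count = 4L, name = "ss22-A4")
}

toy_adapter <- function() adapter_spec(name = "RA3-like")

# Fully deterministic model: every tail is "CC".
cc_model <- function() {
  tail_model(c(`2` = 1),
             c(A = 0, C = 1, G = 0, T = 0),
             terminal_override = list(`1` = c(A = 0, C = 1, G = 0, T = 0),
                                      `2` = c(A = 0, C = 1, G = 0, T = 0)),
             description = "always CC")
}

# Mixed short-tail model with positional structure, L_max = 4.
mixed_model <- function() {
  tail_model(
    length_probs = c(`0` = 0.2, `1` = 0.3, `2` = 0.25, `3` = 0.15, `4` = 0.1),
    base_probs = matrix(c(0.4, 0.4, 0.1, 0.1,
                          0.3, 0.5, 0.05, 0.15,
                          0.25, 0.55, 0.02, 0.18,
                          0.2, 0.6, 0.01, 0.19),
                        nrow = 4L, dimnames = list(c("A", "C", "G", "T"), NULL)),
    terminal_override = list(`1` = c(A = 0.1, C = 0.8, G = 0.02, T = 0.08)),
    description = "mixed L_max=4"
  )
}

# Exhaustive-enumeration oracle for expected tail composition: enumerates
# every tail of every supported length with its exact probability and counts
# bases directly. Independent of expected_composition().
enum_composition <- function(model) {
  lens <- as.integer(names(model$length_probs))
  probs <- model$length_probs
  l_max <- max(lens)
  tails <- character(0)
  w <- numeric(0)
  for (len in lens[probs > 0]) {
    pl <- probs[[as.character(len)]]
    if (len == 0L) {
      tails <- c(tails, "")
      w <- c(w, pl)
      next
    }
    grid <- do.call(expand.grid,
                    c(rep(list(c("A", "C", "G", "T")), len),
                      stringsAsFactors = FALSE))
    pw <- rep(pl, nrow(grid))
    for (i in seq_len(len)) {
      d <- len - i + 1L
      q <- model$terminal_override[[as.character(d)]]
      if (is.null(q)) q <- model$base_probs[, i]
      pw <- pw * q[grid[[i]]]
    }
    tails <- c(tails, apply(grid, 1L, paste0, collapse = ""))
    w <- c(w, pw)
  }
  tlen <- nchar(tails)
  per_position <- matrix(NA_real_, 4L, l_max,
                         dimnames = list(c("A", "C", "G", "U"), 1:l_max))
  coverage <- numeric(l_max)
  for (p in seq_len(l_max)) {
    sel <- tlen >= p
    coverage[p] <- sum(w[sel])
    if (coverage[p] > 0) {
      b <- substr(tails[sel], tlen[sel] - p + 1L, tlen[sel] - p + 1L)
      for (k in seq_along(c("A", "C", "G", "T"))) {
        base <- c("A", "C", "G", "T")[k]
        per_position[k, p] <- sum(w[sel][b == base]) / coverage[p]
      }
    }
  }
  counts <- sapply(c("A", "C", "G", "T"), function(base) {
    sum(w * (nchar(tails) - nchar(gsub(base, "", tails, fixed = TRUE))))
  })
  total <- sum(w * tlen)
  overall <- setNames(counts / total, c("A", "C", "G", "U"))
  list(per_position = per_position, coverage = coverage, overall = overall,
       mean_length = total)
}

# Independent single-experiment competition fit by variable projection:
# for fixed IC50 the plateaus are linear, so profile the RSS over log10(IC50)
# with stats::optimize and solve the plateaus by linear least squares.
profile_competition_fit <- function(conc, anis) {
  rss_t <- function(t) {
    f <- 1 / (1 + conc / 10^t)
    X <- cbind(1 - f, f)
    sum(stats::lm.fit(X, anis)$residuals^2)
  }
  lo <- log10(min(conc[conc > 0])) - 2
  hi <- log10(max(conc)) + 2
  opt <- stats::optimize(rss_t, c(lo, hi), tol = 1e-12)
  # polish past golden-section precision: the profile RSS is locally
  # quadratic, so two rounds of parabolic-vertex refinement suffice
  t_hat <- opt$minimum
  for (h in c(1e-4, 1e-6)) {
    fm <- rss_t(t_hat - h); f0 <- rss_t(t_hat); fp <- rss_t(t_hat + h)
    denom <- fp - 2 * f0 + fm
    if (denom > 0) t_hat <- t_hat - h * (fp - fm) / (2 * denom)
  }
  f <- 1 / (1 + conc / 10^t_hat)
  cf <- stats::lm.fit(cbind(1 - f, f), anis)$coefficients
  list(ic50 = 10^t_hat, a_free = unname(cf[1L]),
       a_bound = unname(cf[2L]))
}
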