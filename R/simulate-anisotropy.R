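#' Design of a simulated anisotropy titration
#'
#' Describes either a saturation titration (fluorescent probe at fixed
#' concentration, protein titrated) or a competition titration (probe +
#' protein fixed, unlabeled competitor titrated), together with the
#' ground-truth parameters and Gaussian measurement noise. Defaults mirror
#' the assay designs the analysis targets: saturation with protein from 5 to
#' 3000 nM, and competition with competitor from 50 nM to 500 uM, both in
#' triplicate.
#'
#' @param mode `"saturation"` or `"competition"`.
#' @param concentrations Numeric vector of concentrations in nM (protein for
#'   saturation, competitor for competition); at least 2 distinct
#'   non-negative values.
#' @param replicates Number of replicates (saturation) or independent
#'   experiments (competition).
#' @param noise_sd Standard deviation of Gaussian anisotropy noise (>= 0).
#' @param truth Named list of true parameters. Saturation: `kd`, `a_free`,
#'   `a_max`. Competition: `ic50` plus `a_free` and `a_bound`, each either a
#'   scalar or a vector of one value per experiment.
#' @param seed Integer seed for reproducible noise.
#' @return An object of class `titration_design`.
#' @examples
#' titration_design("saturation",
#'                  truth = list(kd = 250, a_free = 0.05, a_max = 0.25))
#' @export
titration_design <- function(mode = c("saturation", "competition"),
                             concentrations = NULL,
                             replicates = 3L,
                             noise_sd = 0,
                             truth = list(),
                             seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(concentrations)) {
    concentrations <- if (mode == "saturation") {
      exp(seq(log(5), log(3000), length.out = 12L))
    } else {
      exp(seq(log(50), log(5e5), length.out = 12L))
    }
  }
  if (length(unique(concentrations)) < 2L || any(concentrations < 0)) {
    stop_racetails(
      "`concentrations` must hold >= 2 distinct non-negative nM values",
      "racetails_validation_error")
  }
  if (noise_sd < 0) {
    stop_racetails("`noise_sd` must be >= 0", "racetails_validation_error")
  }
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) {
    stop_racetails("`replicates` must be a positive integer",
                   "racetails_validation_error")
  }
  if (mode == "saturation") {
    need <- c("kd", "a_free", "a_max")
    if (!all(need %in% names(truth))) {
      stop_racetails("saturation `truth` needs kd, a_free, a_max",
                     "racetails_validation_error")
    }
    if (truth$kd <= 0) {
      stop_racetails("true `kd` must be positive", "racetails_validation_error")
    }
  } else {
    need <- c("ic50", "a_free", "a_bound")
    if (!all(need %in% names(truth))) {
      stop_racetails("competition `truth` needs ic50, a_free, a_bound",
                     "racetails_validation_error")
    }
    if (truth$ic50 <= 0) {
      stop_racetails("true `ic50` must be positive",
                     "racetails_validation_error")
    }
  }
  structure(list(mode = mode, concentrations = as.numeric(concentrations),
                 replicates = replicates, noise_sd = noise_sd, truth = truth,
                 seed = seed),
            class = "titration_design")
}

#' Simulate a saturation binding titration
#'
#' Generates anisotropy measurements from the one-site specific binding
#' model `A = A_free + (A_max - A_free) * [P] / (Kd + [P])` plus Gaussian
#' noise, one set per replicate.
#'
#' @param design A [titration_design()] with `mode = "saturation"`.
#' @return A tibble of measurements: `experiment_id`, `concentration_nM`,
#'   `anisotropy`, `replicate`.
#' @examples
#' d <- titration_design("saturation",
#'                       truth = list(kd = 250, a_free = 0.05, a_max = 0.25),
#'                       noise_sd = 0)
#' head(simulate_saturation(d))
#' @export
simulate_saturation <- function(design) {
  stopifnot(inherits(design, "titration_design"))
  if (design$mode != "saturation") {
    stop_racetails("`design` must have mode = 'saturation'",
                   "racetails_validation_error")
  }
  if (!is.null(design$seed)) withr::local_seed(design$seed)
  tr <- design$truth
  grids <- lapply(seq_len(design$replicates), function(r) {
    a <- saturation_model(design$concentrations, tr$kd, tr$a_free, tr$a_max)
    tibble::tibble(
      experiment_id = "saturation",
      concentration_nM = design$concentrations,
      anisotropy = a + rnorm(length(a), 0, design$noise_sd),
      replicate = r
    )
  })
  do.call(rbind, grids)
}

#' Simulate a competition binding titration
#'
#' Generates anisotropy measurements from the competition displacement model
#' `A = A_free + (A_bound - A_free) / (1 + [NTP]/IC50)` plus Gaussian noise.
#' Each replicate is an independent experiment with its own `experiment_id`
#' and (optionally) its own true plateaus — matching a global-fit design in
#' which IC50 is shared but the anisotropy plateaus are experiment-specific.
#'
#' @param design A [titration_design()] with `mode = "competition"`; the
#'   truth's `a_free`/`a_bound` may be scalars or per-experiment vectors.
#' @return A tibble of measurements: `experiment_id`, `concentration_nM`,
#'   `anisotropy`, `replicate`.
#' @examples
#' d <- titration_design("competition",
#'                       truth = list(ic50 = 500, a_free = 0.10, a_bound = 0.20),
#'                       noise_sd = 0)
#' head(simulate_competition(d))
#' @export
simulate_competition <- function(design) {
  stopifnot(inherits(design, "titration_design"))
  if (design$mode != "competition") {
    stop_racetails("`design` must have mode = 'competition'",
                   "racetails_validation_error")
  }
  if (!is.null(design$seed)) withr::local_seed(design$seed)
  tr <- design$truth
  a_free <- rep_len(tr$a_free, design$replicates)
  a_bound <- rep_len(tr$a_bound, design$replicates)
  grids <- lapply(seq_len(design$replicates), function(r) {
    a <- competition_model(design$concentrations, tr$ic50,
                           a_free[r], a_bound[r])
    tibble::tibble(
      experiment_id = sprintf("exp%d", r),
      concentration_nM = design$concentrations,
      anisotropy = a + rnorm(length(a), 0, design$noise_sd),
      replicate = r
    )
  })
  do.call(rbind, grids)
}
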