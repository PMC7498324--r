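#' One-site specific binding (saturation) model
#'
#' Anisotropy of a fixed-concentration fluorescent probe as protein is
#' titrated: `A([P]) = A_free + (A_max - A_free) * [P] / (Kd + [P])`.
#' Equals `A_free` at zero protein, the half-way point `(A_free + A_max)/2`
#' at `[P] = Kd`, and tends to `A_max` at saturation. Ligand depletion is
#' ignored (simple hyperbolic one-site binding).
#'
#' @param conc Protein concentration(s), nM (>= 0).
#' @param kd Dissociation constant, nM (> 0).
#' @param a_free Anisotropy of the free probe.
#' @param a_max Plateau anisotropy of the fully bound probe.
#' @return Anisotropy value(s), same length as `conc`.
#' @examples
#' saturation_model(250, kd = 250, a_free = 0.05, a_max = 0.25) # 0.15
#' @export
saturation_model <- function(conc, kd, a_free, a_max) {
  if (kd <= 0) {
    stop_racetails("`kd` must be positive", "racetails_validation_error")
  }
  if (any(conc < 0)) {
    stop_racetails("`conc` must be non-negative", "racetails_validation_error")
  }
  a_free + (a_max - a_free) * conc / (kd + conc)
}

#' Competition displacement binding model
#'
#' Anisotropy of a protein-bound fluorescent probe as unlabeled competitor
#' is titrated: `A([NTP]) = A_free + (A_bound - A_free) / (1 + [NTP]/IC50)`.
#' Equals `A_bound` at zero competitor, the midpoint `(A_free + A_bound)/2`
#' at `[NTP] = IC50`, and tends to `A_free` at full displacement.
#'
#' @param conc Competitor concentration(s), nM (>= 0).
#' @param ic50 Half-maximal displacement concentration, nM (> 0).
#' @param a_free Anisotropy of the free (fully displaced) probe.
#' @param a_bound Anisotropy of the probe bound in the absence of competitor.
#' @return Anisotropy value(s), same length as `conc`.
#' @examples
#' competition_model(500, ic50 = 500, a_free = 0.10, a_bound = 0.20) # 0.15
#' @export
competition_model <- function(conc, ic50, a_free, a_bound) {
  if (ic50 <= 0) {
    stop_racetails("`ic50` must be positive", "racetails_validation_error")
  }
  if (any(conc < 0)) {
    stop_racetails("`conc` must be non-negative", "racetails_validation_error")
  }
  a_free + (a_bound - a_free) / (1 + conc / ic50)
}
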