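#' Fit the one-site saturation binding model
#'
#' Unweighted nonlinear least squares of [saturation_model()] to anisotropy
#' measurements. Kd is parameterised as log10(Kd) for positivity and
#' conditioning, with a multi-start over a log-spaced Kd grid spanning
#' one decade beyond the concentration range on both sides; the best
#' (lowest residual sum of squares) start is kept. Standard errors are
#' asymptotic, from `s^2 (J'J)^-1` with the analytic Jacobian; the Kd
#' standard error is transported to the linear nM scale by the delta
#' method.
#'
#' @param data Measurements: a tibble/data.frame with columns
#'   `concentration_nM` and `anisotropy` (e.g. from [simulate_saturation()]
#'   or [read_titrations()]).
#' @return An object of class `saturation_fit` with elements `kd`, `a_free`,
#'   `a_max`, `se` (named vector: `kd`, `a_free`, `a_max`), `covariance`
#'   (on the internal `(log10_kd, a_free, a_max)` scale), `rss`,
#'   `n_points`, `converged`, `degenerate`.
#' @examples
#' d <- titration_design("saturation", noise_sd = 0,
#'                       truth = list(kd = 250, a_free = 0.05, a_max = 0.25))
#' fit_saturation(simulate_saturation(d))
#' @export
fit_saturation <- function(data) {
  data <- validate_measurements(data)
  conc <- data$concentration_nM
  a_obs <- data$anisotropy
  if (length(unique(conc)) < 3L) {
    stop_racetails(
      "saturation fit needs >= 3 distinct concentrations (underdetermined)",
      "racetails_underdetermined_error")
  }

  model_fun <- function(par) {
    saturation_model(conc, 10^par[1L], par[2L], par[3L])
  }
  resid_fun <- function(par) a_obs - model_fun(par)
  jac_fun <- function(par) {
    kd <- 10^par[1L]
    frac <- conc / (kd + conc)
    cbind(
      log10_kd = (par[3L] - par[2L]) * frac / (kd + conc) * kd * log(10),
      a_free = -(1 - frac),
      a_max = -frac
    )
  }

  cpos <- conc[conc > 0]
  grid <- seq(log10(min(cpos) / 10), log10(max(cpos) * 10), length.out = 7L)
  a_lo <- mean(a_obs[conc == min(conc)])
  a_hi <- mean(a_obs[conc == max(conc)])

  best <- NULL
  for (t0 in grid) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(t0, a_lo, a_hi), fn = resid_fun,
                         jac = jac_fun,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-15, ptol = 1e-15, maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop_racetails("saturation fit failed from every start",
                   "racetails_fit_error")
  }

  par <- best$par
  kd <- 10^par[1L]
  J <- jac_fun(par)
  cov <- asymptotic_covariance(J, best$deviance, length(a_obs))
  se_int <- unname(sqrt(pmax(diag(cov$vcov), 0)))
  se <- c(kd = kd * log(10) * se_int[1L],
          a_free = se_int[2L], a_max = se_int[3L])
  degenerate <- abs(par[3L] - par[2L]) <
    1e-6 * (abs(par[2L]) + abs(par[3L]) + 1e-12)

  structure(list(
    kd = kd, a_free = par[2L], a_max = par[3L], se = se,
    covariance = cov$vcov, rss = best$deviance, n_points = length(a_obs),
    converged = best$info %in% 1:4 && !degenerate && cov$ok,
    degenerate = degenerate
  ), class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat("<saturation_fit> one-site specific binding\n",
      sprintf("  Kd = %.4g +/- %.2g nM\n", x$kd, x$se[["kd"]]),
      sprintf("  A_free = %.4g, A_max = %.4g  (n = %d, RSS = %.3g)\n",
              x$a_free, x$a_max, x$n_points, x$rss),
      if (!x$converged) "  WARNING: fit not converged / degenerate\n" else "",
      sep = "")
  invisible(x)
}

#' Globally fit the competition binding model across experiments
#'
#' Joint unweighted least squares of [competition_model()] over one or more
#' experiments: a single shared log10(IC50) and an experiment-specific pair
#' `(A_free, A_bound)` — the fitting scheme used when replicate competition
#' titrations share the displacement midpoint but differ in plateau
#' anisotropies. Multi-start over a log10(IC50) grid spanning one decade
#' beyond the positive concentration range; asymptotic covariance
#' `s^2 (J'J)^-1` from the analytic Jacobian; pointwise delta-method
#' confidence bands for the fitted curve.
#'
#' The fit is flagged non-identifiable (rather than erroring) when the IC50
#' lands within 5% (log scale) of the search bounds, when the IC50
#' confidence interval spans more than two orders of magnitude, or when the
#' covariance is singular — as happens for flat (signal-free) data.
#'
#' @param data Measurements: tibble/data.frame with `experiment_id`,
#'   `concentration_nM`, `anisotropy`. Each experiment needs at least 2
#'   distinct concentrations.
#' @param level Confidence level for intervals and bands (default 0.95).
#' @return An object of class `competition_fit` with `ic50`, `se_ic50`,
#'   `ic50_ci` (on the nM scale), `experiments`, `a_free`, `a_bound`,
#'   `se_a_free`, `se_a_bound` (named per experiment), `covariance` (full
#'   internal-scale matrix, first parameter log10_ic50), `rss`, `n_points`,
#'   `level`, `converged`, `identifiable`, and `band(conc, experiment)` —
#'   a function returning a tibble `concentration_nM`, `fit`, `lower`,
#'   `upper`.
#' @examples
#' d <- titration_design("competition", replicates = 3, noise_sd = 0,
#'                       truth = list(ic50 = 500, a_free = 0.10, a_bound = 0.20))
#' fit_competition_global(simulate_competition(d))
#' @export
fit_competition_global <- function(data, level = 0.95) {
  data <- validate_measurements(data, need_experiment = TRUE)
  exps <- unique(data$experiment_id)
  n_exp <- length(exps)
  for (e in exps) {
    if (length(unique(data$concentration_nM[data$experiment_id == e])) < 2L) {
      stop_racetails(
        sprintf("experiment '%s' has a single concentration (underdetermined)", e),
        "racetails_underdetermined_error")
    }
  }
  conc <- data$concentration_nM
  a_obs <- data$anisotropy
  eidx <- match(data$experiment_id, exps)
  n_par <- 1L + 2L * n_exp

  unpack <- function(par) {
    list(ic50 = 10^par[1L],
         a_free = par[1L + 2L * seq_len(n_exp) - 1L],
         a_bound = par[1L + 2L * seq_len(n_exp)])
  }
  model_fun <- function(par) {
    p <- unpack(par)
    f <- 1 / (1 + conc / p$ic50)
    p$a_free[eidx] + (p$a_bound[eidx] - p$a_free[eidx]) * f
  }
  resid_fun <- function(par) a_obs - model_fun(par)
  jac_fun <- function(par) {
    p <- unpack(par)
    ic50 <- p$ic50
    f <- ic50 / (ic50 + conc)
    dfdt <- conc * ic50 * log(10) / (ic50 + conc)^2
    J <- matrix(0, nrow = length(conc), ncol = n_par)
    J[, 1L] <- -(p$a_bound[eidx] - p$a_free[eidx]) * dfdt
    for (e in seq_len(n_exp)) {
      rows <- eidx == e
      J[rows, 2L * e] <- -(1 - f[rows])      # a_free_e
      J[rows, 2L * e + 1L] <- -f[rows]       # a_bound_e
    }
    colnames(J) <- c("log10_ic50",
                     as.vector(rbind(paste0("a_free_", exps),
                                     paste0("a_bound_", exps))))
    J
  }

  cpos <- conc[conc > 0]
  t_lo <- log10(min(cpos)) - 1
  t_hi <- log10(max(conc)) + 1
  grid <- seq(t_lo, t_hi, length.out = 9L)
  a_bound0 <- vapply(exps, function(e) {
    sub <- data[data$experiment_id == e, ]
    mean(sub$anisotropy[sub$concentration_nM == min(sub$concentration_nM)])
  }, 0)
  a_free0 <- vapply(exps, function(e) {
    sub <- data[data$experiment_id == e, ]
    mean(sub$anisotropy[sub$concentration_nM == max(sub$concentration_nM)])
  }, 0)

  best <- NULL
  for (t0 in grid) {
    start <- c(t0, as.vector(rbind(a_free0, a_bound0)))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fun, jac = jac_fun,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-15, ptol = 1e-15, maxiter = 1000)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop_racetails("competition fit failed from every start",
                   "racetails_fit_error")
  }

  par <- best$par
  p <- unpack(par)
  J <- jac_fun(par)
  cov <- asymptotic_covariance(J, best$deviance, length(a_obs))
  se_int <- unname(sqrt(pmax(diag(cov$vcov), 0)))
  z <- qnorm((1 + level) / 2)
  t_hat <- par[1L]
  se_t <- se_int[1L]
  ci_t <- t_hat + c(-1, 1) * z * se_t
  ic50 <- 10^t_hat

  span <- t_hi - t_lo
  at_bound <- (t_hat - t_lo) < 0.05 * span || (t_hi - t_hat) < 0.05 * span
  wide_ci <- !is.finite(se_t) || diff(ci_t) > 2
  identifiable <- cov$ok && !at_bound && !wide_ci

  a_free <- setNames(p$a_free, exps)
  a_bound <- setNames(p$a_bound, exps)
  vcov_full <- cov$vcov

  band <- function(conc_grid, experiment = exps[1L]) {
    e <- match(experiment, exps)
    if (is.na(e)) {
      stop_racetails("unknown experiment id in `band()`",
                     "racetails_validation_error")
    }
    fitv <- competition_model(conc_grid, ic50, a_free[e], a_bound[e])
    f <- ic50 / (ic50 + conc_grid)
    dfdt <- conc_grid * ic50 * log(10) / (ic50 + conc_grid)^2
    se_fit <- vapply(seq_along(conc_grid), function(i) {
      g <- numeric(n_par)
      g[1L] <- (a_bound[e] - a_free[e]) * dfdt[i]
      g[2L * e] <- 1 - f[i]
      g[2L * e + 1L] <- f[i]
      sqrt(max(drop(t(g) %*% vcov_full %*% g), 0))
    }, 0)
    tibble::tibble(concentration_nM = conc_grid, fit = fitv,
                   lower = fitv - z * se_fit, upper = fitv + z * se_fit)
  }

  structure(list(
    ic50 = ic50,
    se_ic50 = ic50 * log(10) * se_t,
    ic50_ci = 10^ci_t,
    experiments = exps,
    a_free = a_free, a_bound = a_bound,
    se_a_free = setNames(se_int[2L * seq_len(n_exp)], exps),
    se_a_bound = setNames(se_int[2L * seq_len(n_exp) + 1L], exps),
    covariance = vcov_full,
    rss = best$deviance, n_points = length(a_obs),
    level = level,
    converged = best$info %in% 1:4,
    identifiable = identifiable,
    band = band
  ), class = "competition_fit")
}

#' @export
print.competition_fit <- function(x, ...) {
  cat("<competition_fit> shared IC50, per-experiment plateaus\n",
      sprintf("  IC50 = %.4g +/- %.2g nM  (%.0f%% CI %.4g-%.4g)\n",
              x$ic50, x$se_ic50, 100 * x$level,
              x$ic50_ci[1L], x$ic50_ci[2L]),
      sprintf("  %d experiment(s), n = %d, RSS = %.3g\n",
              length(x$experiments), x$n_points, x$rss),
      if (!x$identifiable) "  WARNING: IC50 not identifiable from these data\n"
      else "",
      sep = "")
  invisible(x)
}

# s^2 (J'J)^-1 with a pseudo-inverse fallback for singular designs.
asymptotic_covariance <- function(J, rss, n) {
  p <- ncol(J)
  dof <- max(n - p, 1L)
  s2 <- rss / dof
  JtJ <- crossprod(J)
  vcov <- tryCatch(s2 * solve(JtJ), error = function(e) NULL)
  ok <- !is.null(vcov) && all(is.finite(vcov))
  if (!ok) {
    sv <- svd(JtJ)
    inv_d <- ifelse(sv$d > max(sv$d) * 1e-12, 1 / sv$d, 0)
    vcov <- s2 * sv$v %*% diag(inv_d, p) %*% t(sv$u)
  }
  dimnames(vcov) <- dimnames(JtJ)
  list(vcov = vcov, ok = ok)
}

validate_measurements <- function(data, need_experiment = FALSE) {
  stopifnot(is.data.frame(data))
  need <- c("concentration_nM", "anisotropy",
            if (need_experiment) "experiment_id")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop_racetails(paste("measurements lack column(s):",
                         paste(missing_cols, collapse = ", ")),
                   "racetails_schema_error")
  }
  if (any(!is.finite(data$anisotropy)) || any(data$concentration_nM < 0)) {
    stop_racetails(
      "measurements must have finite anisotropy and non-negative concentration",
      "racetails_validation_error")
  }
  data
}
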