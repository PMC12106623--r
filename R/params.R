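#' Generative parameters for the two-scheme simulation model
#'
#' Parameter set of the generative model used throughout the simulation
#' studies: log-linear expected abundance with site-level residuals,
#' logit-linear availability with scheme-specific intercepts (a "protocol
#' effect" between the structured and semi-structured schemes) and a shared
#' covariate slope, and a log-linear half-normal detection scale with
#' site-visit residuals.
#'
#' @param beta0 Log-scale mean-abundance intercept.
#' @param beta Abundance covariate slope(s).
#' @param phi0_dsopen Logit-scale availability intercept, structured scheme.
#' @param phi0_ds Logit-scale availability intercept, semi-structured scheme.
#' @param gamma Availability covariate slope, shared between schemes.
#' @param sigma0 Log-scale detection-scale intercept (metres when
#'   exponentiated).
#' @param alpha Detection covariate slope.
#' @param sd_eps_abund Standard deviation of the site-level abundance
#'   residual (log scale), `>= 0`.
#' @param sd_eps_det Standard deviation of the site-visit detection residual
#'   (log scale), `>= 0`.
#' @param geometry Optional [distance_geometry()] used to warn when
#'   `exp(sigma0)` exceeds the truncation radius.
#' @return An object of class `ids_params` (named list).
#' @export
sim_params <- function(beta0 = 1, beta = 0.5,
                       phi0_dsopen = 0, phi0_ds = 0,
                       gamma = 0.5, sigma0 = log(50), alpha = 0.3,
                       sd_eps_abund = 0.2, sd_eps_det = 0.2,
                       geometry = NULL) {
  stopifnot(is.numeric(beta0), length(beta0) == 1, is.numeric(beta))
  if (sd_eps_abund < 0 || sd_eps_det < 0)
    stop("residual standard deviations must be non-negative")
  if (!is.null(geometry) && exp(sigma0) > geometry$B)
    warning("exp(sigma0) exceeds the truncation radius B; ",
            "detection is nearly flat within the point")
  structure(list(beta0 = beta0, beta = beta,
                 phi0_dsopen = phi0_dsopen, phi0_ds = phi0_ds,
                 gamma = gamma, sigma0 = sigma0, alpha = alpha,
                 sd_eps_abund = sd_eps_abund, sd_eps_det = sd_eps_det),
            class = "ids_params")
}

#' @export
print.ids_params <- function(x, ...) {
  cat("Generative parameters (two-scheme distance-sampling model)\n")
  v <- unlist(x[c("beta0", "phi0_dsopen", "phi0_ds", "gamma",
                  "sigma0", "alpha", "sd_eps_abund", "sd_eps_det")])
  print(round(c(v, beta = unname(x$beta)), 4))
  cat("  mean abundance exp(beta0) =", round(exp(x$beta0), 3),
      "; mean detection scale exp(sigma0) =", round(exp(x$sigma0), 1), "m\n")
  cat("  mean availability:", round(plogis(x$phi0_dsopen), 3), "(structured),",
      round(plogis(x$phi0_ds), 3), "(semi-structured)\n")
  invisible(x)
}

#' Parameters of the zero-inflated case-study model
#'
#' Parameter set for the richer single-species model used on real survey
#' data: zero-inflated Poisson abundance (a Bernoulli "unsuitable site"
#' mixture with suitability modelled on ecoregion and spatial continuity),
#' availability with quadratic date and hour-from-sunrise effects plus a
#' scheme offset, and detection with road-distance and habitat-category
#' effects.  Categorical covariates use reference-level coding: the first
#' category's offset is fixed at 0 and is not listed here.
#'
#' @param rho0 Logit-scale suitability intercept (probability a site is
#'   unsuitable).
#' @param delta_cat Per-ecoregion offsets on the suitability logit
#'   (excluding the reference level).
#' @param delta Spatial-continuity slope on the suitability logit.
#' @param gamma1,gamma2 Linear and quadratic julian-date availability slopes.
#' @param gamma3,gamma4 Linear and quadratic hour-from-sunrise slopes.
#' @param gamma_cat Scheme offset on availability (applied to
#'   semi-structured records in the integrated model only).
#' @param alpha_cat Detection offsets for the non-reference habitat
#'   categories (3 values for a 4-category habitat variable).
#' @param alpha_road Road-distance detection slope.
#' @param sd_session_avail,sd_obs_avail Availability random-effect SDs
#'   (session, observer).
#' @param sd_session_det,sd_obs_det Detection random-effect SDs.
#' @return An object of class `ids_case_params`.
#' @export
case_params <- function(rho0 = qlogis(0.2), delta_cat = numeric(0), delta = 0,
                        gamma1 = 0, gamma2 = 0, gamma3 = 0, gamma4 = 0,
                        gamma_cat = 0,
                        alpha_cat = numeric(3), alpha_road = 0,
                        sd_session_avail = 0, sd_obs_avail = 0,
                        sd_session_det = 0, sd_obs_det = 0) {
  sds <- c(sd_session_avail, sd_obs_avail, sd_session_det, sd_obs_det)
  if (any(sds < 0)) stop("random-effect standard deviations must be >= 0")
  structure(list(rho0 = rho0, delta_cat = delta_cat, delta = delta,
                 gamma1 = gamma1, gamma2 = gamma2,
                 gamma3 = gamma3, gamma4 = gamma4, gamma_cat = gamma_cat,
                 alpha_cat = alpha_cat, alpha_road = alpha_road,
                 sd_session_avail = sd_session_avail,
                 sd_obs_avail = sd_obs_avail,
                 sd_session_det = sd_session_det,
                 sd_obs_det = sd_obs_det),
            class = "ids_case_params")
}

#' Default parameter-draw ranges for the identifiability study
#'
#' Uniform bounds from which each generative parameter is drawn, one draw
#' per simulated case.  The mean-abundance intercept `beta0` is held fixed
#' across cases (its range is degenerate).  Availability intercepts span
#' `logit(0.05)` to `logit(0.95)` and the detection scale spans 20 to 200 m,
#' covering low- to high-availability/detectability species profiles;
#' covariate slopes span `[-1, 1]` and residual SDs `[0.1, 0.5]`.
#'
#' @param beta0 Fixed value of the abundance intercept.
#' @return Named list of `c(lower, upper)` bounds, class `ids_ranges`.
#' @export
default_param_ranges <- function(beta0 = 1) {
  structure(list(
    beta0        = c(beta0, beta0),
    beta         = c(-1, 1),
    phi0_dsopen  = c(qlogis(0.05), qlogis(0.95)),
    phi0_ds      = c(qlogis(0.05), qlogis(0.95)),
    gamma        = c(-1, 1),
    sigma0       = c(log(20), log(200)),
    alpha        = c(-1, 1),
    sd_eps_abund = c(0.1, 0.5),
    sd_eps_det   = c(0.1, 0.5)
  ), class = "ids_ranges")
}

#' Draw a generative parameter set uniformly within bounds
#'
#' Each parameter is drawn independently and uniformly within its
#' `c(lower, upper)` bounds; degenerate bounds (`lower == upper`) hold a
#' parameter fixed across cases, as done for `beta0`.
#'
#' @param ranges Named list of bounds, e.g. [default_param_ranges()].
#' @return An [sim_params()] object.
#' @export
draw_parameters <- function(ranges = default_param_ranges()) {
  need <- names(formals(sim_params))
  need <- setdiff(need, "geometry")
  vals <- lapply(names(ranges), function(nm) {
    b <- ranges[[nm]]
    if (length(b) != 2 || !is.numeric(b))
      stop("bounds for '", nm, "' must be numeric c(lower, upper)")
    if (b[1] > b[2]) stop("lower bound exceeds upper bound for '", nm, "'")
    if (b[1] == b[2]) b[1] else runif(1, b[1], b[2])
  })
  names(vals) <- names(ranges)
  missing <- setdiff(need, names(vals))
  if (length(missing))
    stop("ranges missing parameters: ", paste(missing, collapse = ", "))
  do.call(sim_params, vals[need])
}
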