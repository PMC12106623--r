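#' Linear predictors of the hierarchical distance-sampling model
#'
#' The three submodels share the standard link structure of hierarchical
#' distance sampling: log link for expected abundance, logit link for
#' availability (the probability an individual of the site superpopulation
#' is exposed to sampling on a visit), and log link for the half-normal
#' detection scale.
#'
#' @param beta0 Intercept on the log scale.
#' @param beta Slope vector.
#' @param x Covariate vector, same length as `beta`.
#' @param eps Residual (log-scale) added to the linear predictor.
#' @return `abundance_linpred()`: expected abundance `lambda > 0`.
#' @name linpreds
NULL

#' @rdname linpreds
#' @export
abundance_linpred <- function(beta0, beta = numeric(0), x = numeric(0),
                              eps = 0) {
  if (length(beta) != length(x))
    stop("covariate vector and slope vector lengths differ (",
         length(x), " vs ", length(beta), ")")
  exp(beta0 + sum(beta * x) + eps)
}

#' @rdname linpreds
#' @param phi0 Availability intercept on the logit scale.
#' @param slope_terms Sum (or vector) of slope-times-covariate contributions.
#' @param gamma_cat_offset Scheme offset, applied to semi-structured-
#'   equivalent records in the integrated formulation; 0 otherwise.
#' @return `availability_linpred()`: availability probability in `(0, 1)`.
#' @export
availability_linpred <- function(phi0, slope_terms = 0, gamma_cat_offset = 0) {
  plogis(phi0 + sum(slope_terms) + gamma_cat_offset)
}

#' @rdname linpreds
#' @param sigma0 Detection-scale intercept on the log scale.
#' @param eps_det Detection residual (log scale).
#' @return `detection_scale_linpred()`: detection scale `sigma` in metres.
#' @export
detection_scale_linpred <- function(sigma0, slope_terms = 0, eps_det = 0) {
  exp(sigma0 + sum(slope_terms) + eps_det)
}

#' Zero-inflated Poisson mean abundance
#'
#' Site-level expected abundance under the zero-inflation mixture:
#' `mu = lambda * (1 - omega)` where `omega` is the latent unsuitability
#' indicator, `omega ~ Bernoulli(rho)`.  With `omega` marginalized the
#' expected abundance is `lambda * (1 - rho)`.
#'
#' @param lambda Expected abundance of a suitable site, `>= 0`.
#' @param omega Unsuitability: either the latent 0/1 indicator or the
#'   marginal probability `rho` in `[0, 1]`.
#' @return Expected abundance `mu`.
#' @export
zip_mean <- function(lambda, omega) {
  if (any(lambda < 0)) stop("`lambda` must be non-negative")
  if (any(omega < 0 | omega > 1)) stop("`omega` must lie in [0, 1]")
  lambda * (1 - omega)
}
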