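# Marginalized likelihoods.  The latent hierarchy is summed out exactly:
# N and y collapse algebraically (Binomial-Multinomial thinning), the
# Poisson superpopulation M is summed to a truncation K chosen so the
# Poisson tail beyond K is negligible (< 1e-10), and the log-normal
# residuals of the generative model are integrated by Gauss-Hermite
# quadrature.  With residual SDs of 0 the likelihood is exact.

.gh_nodes <- function(n) {
  gh <- pracma::gaussHermite(n)
  list(x = gh$x * sqrt(2), w = gh$w / sqrt(pi)) # standard-normal nodes
}

.as_count_matrix <- function(y, nb) {
  if (length(dim(y)) == 3) {
    I <- dim(y)[1]; J <- dim(y)[2]
    m <- matrix(0L, I * J, nb)
    for (j in seq_len(J)) m[(seq_len(I) - 1) * J + j, ] <- y[, j, ]
    m
  } else {
    matrix(as.integer(y), nrow(y), nb)
  }
}

.ll_structured_core <- function(y, I, J, geom, log_lambda, logit_phi,
                                log_sigma, sd_a, sd_d, gh, rho = numeric(0),
                                K = 0L) {
  if (any(!is.finite(log_lambda)) || any(!is.finite(log_sigma)) ||
      any(!is.finite(logit_phi)))
    return(-Inf)
  C_structured_ll(y, I, J, geom$breaks, log_lambda, logit_phi, log_sigma,
                  sd_a, sd_d, gh$x, gh$w, rho, as.integer(K))
}

.ll_lists_core <- function(y, geom, log_lambda, logit_phi, log_sigma,
                           sd_a, sd_d, gh, rho = numeric(0)) {
  if (any(!is.finite(log_lambda)) || any(!is.finite(log_sigma)) ||
      any(!is.finite(logit_phi)))
    return(-Inf)
  C_lists_ll(y, geom$breaks, log_lambda, logit_phi, log_sigma,
             sd_a, sd_d, gh$x, gh$w, rho)
}

#' Marginal log-likelihood of a structured dataset
#'
#' Exact log joint probability of the observed binned counts given the
#' generative parameters, with the latent superpopulation `M` summed to a
#' truncation `K` and the per-visit availability/detection thinning
#' collapsed analytically.  Site-level abundance residuals and site-visit
#' detection residuals (when their SDs are positive) are integrated
#' numerically with `n_gh` Gauss-Hermite nodes; with both SDs zero the
#' value is exact.
#'
#' @param params An [sim_params()] object.
#' @param data An `ids_structured` dataset.
#' @param K Truncation bound for `M`; `NULL` chooses a site-specific bound
#'   with Poisson tail mass below 1e-10.
#' @param n_gh Number of quadrature nodes per residual dimension.
#' @return Log-likelihood (scalar).  Sites are independent, so the value
#'   is a sum of per-site contributions.
#' @export
structured_marginal_loglik <- function(params, data, K = NULL, n_gh = 15) {
  stopifnot(inherits(data, "ids_structured"))
  p <- params
  I <- data$n_sites; J <- data$n_visits
  geom <- data$geometry
  log_lambda <- p$beta0 + drop(data$X %*% p$beta)
  logit_phi <- as.numeric(t(p$phi0_dsopen + p$gamma * data$U)) # row (i-1)*J+j
  log_sigma <- as.numeric(t(p$sigma0 + p$alpha * data$Z))
  y <- .as_count_matrix(data$y, geom$n_bins)
  .ll_structured_core(y, I, J, geom, log_lambda, logit_phi, log_sigma,
                      p$sd_eps_abund, p$sd_eps_det, .gh_nodes(n_gh),
                      K = if (is.null(K)) 0L else K)
}

#' Marginal log-likelihood of semi-structured single-visit lists
#'
#' With a single visit the Poisson-Binomial-Multinomial chain collapses in
#' closed form: per-bin counts are independent
#' `Poisson(lambda_i * phi_i * pi_b)`.  This collapse is also the source of
#' single-visit confounding: the likelihood is invariant under
#' `lambda -> c * lambda`, `phi -> phi / c`, so availability cannot be
#' separated from abundance without the replicated dataset.
#'
#' @param params An [sim_params()] object (the scheme uses `phi0_ds`).
#' @param data An `ids_semistructured` dataset.
#' @param n_gh Quadrature nodes per residual dimension.
#' @return Log-likelihood (scalar).
#' @export
semistructured_marginal_loglik <- function(params, data, n_gh = 15) {
  stopifnot(inherits(data, "ids_semistructured"))
  p <- params
  geom <- data$geometry
  log_lambda <- p$beta0 + drop(data$X %*% p$beta)
  logit_phi <- p$phi0_ds + p$gamma * data$V
  log_sigma <- p$sigma0 + p$alpha * data$Z
  y <- .as_count_matrix(data$y, geom$n_bins)
  .ll_lists_core(y, geom, log_lambda, logit_phi, log_sigma,
                 p$sd_eps_abund, p$sd_eps_det, .gh_nodes(n_gh))
}

#' Joint log-likelihood of the integrated (IDS) formulation
#'
#' Sum of the structured and semi-structured marginal log-likelihoods under
#' shared abundance, availability-slope and detection parameters; only the
#' availability intercept differs between schemes (`phi0_dsopen` vs
#' `phi0_ds`).  The replicated dataset anchors availability, which is what
#' breaks the single-visit abundance-availability confounding.
#'
#' @param params An [sim_params()] object.
#' @param structured An `ids_structured` dataset.
#' @param semistructured An `ids_semistructured` dataset (may have 0 rows'
#'   worth of information but must share the structured geometry).
#' @param K,n_gh Passed to the component likelihoods.
#' @return Log-likelihood (scalar).
#' @export
joint_loglik <- function(params, structured, semistructured,
                         K = NULL, n_gh = 15) {
  if (!isTRUE(all.equal(structured$geometry$breaks,
                        semistructured$geometry$breaks)))
    stop("structured and semi-structured datasets use different ",
         "distance geometries")
  structured_marginal_loglik(params, structured, K = K, n_gh = n_gh) +
    semistructured_marginal_loglik(params, semistructured, n_gh = n_gh)
}
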