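# Independent oracles used across tests.

# Exhaustive enumeration of the latent hierarchy for one site:
# sum over M of Poisson(M | lambda) * prod_j sum over N of
# Binomial(N | M, phi_j) * Multinomial(y_j, undetected | N, pi_j, 1-sum pi_j).
enum_site_loglik <- function(y, lambda, phi, pis, K) {
  # y: J x nb matrix; phi: length J; pis: J x nb
  tot <- 0
  for (M in 0:K) {
    pm <- dpois(M, lambda)
    pv <- 1
    for (j in seq_len(nrow(y))) {
      yt <- sum(y[j, ])
      if (yt > M) { pv <- 0; break }
      s <- 0
      for (N in yt:M) {
        s <- s + dbinom(N, M, phi[j]) *
          dmultinom(c(y[j, ], N - yt),
                    prob = c(pis[j, ], 1 - sum(pis[j, ])))
      }
      pv <- pv * s
    }
    tot <- tot + pm * pv
  }
  log(tot)
}

# Adaptive-quadrature oracle for the point-transect cell integral.
quad_cell_probs <- function(breaks, sigma) {
  B <- breaks[length(breaks)]
  f <- function(r) exp(-r^2 / (2 * sigma^2)) * 2 * r / B^2
  vapply(seq_len(length(breaks) - 1), function(b)
    integrate(f, breaks[b], breaks[b + 1], rel.tol = 1e-12)$value,
    numeric(1))
}

# A small fixed two-scheme dataset for likelihood/fit tests.
tiny_case <- function(seed = 11, n_sites = 30, n_visits = 3, n_lists = 60) {
  simulate_ids_case(
    sim_params(beta0 = 1, beta = 0.5, phi0_dsopen = 0.4, phi0_ds = -0.4,
               gamma = 0.3, sigma0 = log(60), alpha = 0.2,
               sd_eps_abund = 0, sd_eps_det = 0),
    n_sites = n_sites, n_visits = n_visits, n_lists = n_lists,
    seed = seed)
}

# Structured dataset built directly from arrays (bypassing the simulator).
make_structured <- function(y, X, U, Z, geometry) {
  I <- dim(y)[1]
  structure(list(n_sites = I, n_visits = dim(y)[2], y = y,
                 X = X, U = U, Z = Z, geometry = geometry,
                 detections = data.frame(site = integer(0),
                                         visit = integer(0),
                                         distance = numeric(0),
                                         bin = integer(0))),
            class = "ids_structured")
}

make_semistructured <- function(y, X, V, Z, geometry, coordinates = NULL) {
  out <- list(n_lists = nrow(y), y = y, X = X, V = V, Z = Z,
              geometry = geometry,
              detections = data.frame(list = integer(0),
                                      distance = numeric(0),
                                      bin = integer(0)))
  if (!is.null(coordinates)) out$coordinates <- coordinates
  structure(out, class = "ids_semistructured")
}
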