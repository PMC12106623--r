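geom3 <- distance_geometry(c(0, 30, 80, 150))

# parameters with all covariate slopes zero so per-site lambda/phi/sigma
# are set directly through the intercepts
flat_params <- function(lambda, phi, sigma) {
  sim_params(beta0 = log(lambda), beta = 0, phi0_dsopen = qlogis(phi),
             phi0_ds = qlogis(phi), gamma = 0, sigma0 = log(sigma),
             alpha = 0, sd_eps_abund = 0, sd_eps_det = 0)
}

test_that("structured marginal likelihood equals exhaustive enumeration", {
  set.seed(101)
  K <- 15
  for (trial in 1:25) {
    I <- sample(1:2, 1)
    J <- sample(1:2, 1)
    lambda <- runif(1, 0.4, 2.5)
    phi <- runif(1, 0.15, 0.9)
    sigma <- runif(1, 20, 120)
    y <- array(rpois(I * J * geom3$n_bins, 0.8),
               dim = c(I, J, geom3$n_bins))
    st <- make_structured(y, matrix(0, I, 1), matrix(0, I, J),
                          matrix(0, I, J), geom3)
    pis <- matrix(rep(cell_probabilities(geom3, sigma,
                                         drop_undetected = TRUE), J),
                  J, geom3$n_bins, byrow = TRUE)
    oracle <- sum(vapply(seq_len(I), function(i)
      enum_site_loglik(matrix(y[i, , ], J), lambda, rep(phi, J), pis, K),
      numeric(1)))
    got <- structured_marginal_loglik(flat_params(lambda, phi, sigma),
                                      st, K = K)
    expect_lt(abs(got - oracle), 1e-10)
  }
})

test_that("Poisson truncation is stable once the tail is negligible", {
  set.seed(7)
  y <- array(rpois(6 * 2 * 3, 1), dim = c(6, 2, 3))
  st <- make_structured(y, matrix(0, 6, 1), matrix(0, 6, 2),
                        matrix(0, 6, 2), geom3)
  p <- flat_params(2, 0.5, 60)
  l40 <- structured_marginal_loglik(p, st, K = 40)
  l80 <- structured_marginal_loglik(p, st, K = 80)
  ladapt <- structured_marginal_loglik(p, st)
  expect_lt(abs(l40 - l80), 1e-8)
  expect_lt(abs(ladapt - l80), 1e-8)
})

test_that("single-visit semi-structured likelihood is closed-form Poisson", {
  # lambda*phi*sum(pi) = 1 split over bins; y = 0 contributes -1 per list
  geom1 <- distance_geometry(c(0, 100))
  pi1 <- sum(cell_probabilities(geom1, 70, drop_undetected = TRUE))
  lam <- 1 / (0.5 * pi1)
  se <- make_semistructured(matrix(0L, 4, 1), matrix(0, 4, 1),
                            rep(0, 4), rep(0, 4), geom1)
  ll <- semistructured_marginal_loglik(flat_params(lam, 0.5, 70), se)
  expect_equal(ll, -4, tolerance = 1e-10)
})

test_that("semi-structured likelihood equals the replicated machinery at J = 1", {
  set.seed(33)
  n <- 40
  y <- matrix(rpois(n * geom3$n_bins, 0.7), n, geom3$n_bins)
  X <- matrix(rnorm(n), n, 1)
  V <- rnorm(n); Z <- rnorm(n)
  p <- sim_params(beta0 = 0.8, beta = 0.4, phi0_dsopen = 0.2,
                  phi0_ds = 0.2, gamma = 0.3, sigma0 = log(70),
                  alpha = 0.25, sd_eps_abund = 0, sd_eps_det = 0)
  se <- make_semistructured(y, X, V, Z, geom3)
  st <- make_structured(array(y, dim = c(n, 1, geom3$n_bins)), X,
                        matrix(V, n, 1), matrix(Z, n, 1), geom3)
  expect_lt(abs(semistructured_marginal_loglik(p, se) -
                  structured_marginal_loglik(p, st)), 1e-10)
})

test_that("residual quadrature matches adaptive numerical integration", {
  # one site, one visit, sd_eps_abund > 0: Gauss-Hermite vs integrate()
  y <- array(c(2L, 1L, 3L), dim = c(1, 1, 3))
  st <- make_structured(y, matrix(0, 1, 1), matrix(0, 1, 1),
                        matrix(0, 1, 1), geom3)
  p0 <- flat_params(2, 0.6, 70)
  p <- p0; p$sd_eps_abund <- 0.4
  f <- function(e) vapply(e, function(ei) {
    pe <- p0; pe$beta0 <- p0$beta0 + ei
    exp(structured_marginal_loglik(pe, st)) * dnorm(ei, 0, 0.4)
  }, numeric(1))
  exact <- log(integrate(f, -10 * 0.4, 10 * 0.4, rel.tol = 1e-12)$value)
  expect_lt(abs(structured_marginal_loglik(p, st, n_gh = 25) - exact), 1e-8)
  # detection residual likewise
  pd <- p0; pd$sd_eps_det <- 0.3
  fd <- function(e) vapply(e, function(ei) {
    pe <- p0; pe$sigma0 <- p0$sigma0 + ei
    exp(structured_marginal_loglik(pe, st)) * dnorm(ei, 0, 0.3)
  }, numeric(1))
  exactd <- log(integrate(fd, -10 * 0.3, 10 * 0.3, rel.tol = 1e-12)$value)
  expect_lt(abs(structured_marginal_loglik(pd, st, n_gh = 25) - exactd),
            1e-6)
})

# For the trade-off reparameterization to act on every list, availability
# must be flat over lists (gamma = 0); the intercept then scales phi itself.
confounded_case <- function(seed = 44)
  simulate_ids_case(
    sim_params(beta0 = 1, beta = 0.5, phi0_dsopen = 0.4, phi0_ds = -0.4,
               gamma = 0, sigma0 = log(60), alpha = 0.2,
               sd_eps_abund = 0, sd_eps_det = 0),
    n_sites = 200, n_visits = 9, n_lists = 200, seed = seed)

test_that("single-visit likelihood is invariant to the lambda/phi trade-off", {
  case <- confounded_case()
  se <- case$semistructured
  p <- case$params
  base <- semistructured_marginal_loglik(p, se)
  for (cc in c(0.5, 1.3, 2)) {
    p2 <- p
    p2$beta0 <- p$beta0 + log(cc)
    p2$phi0_ds <- qlogis(plogis(p$phi0_ds) / cc) # requires phi/c in (0,1)
    expect_lt(abs(semistructured_marginal_loglik(p2, se) - base), 1e-10)
  }
})

test_that("joint likelihood is additive and not trade-off invariant", {
  case <- confounded_case()
  p <- case$params
  ll_st <- structured_marginal_loglik(p, case$structured)
  ll_se <- semistructured_marginal_loglik(p, case$semistructured)
  expect_equal(joint_loglik(p, case$structured, case$semistructured),
               ll_st + ll_se, tolerance = 1e-12)
  # the replicated block pins availability, breaking the c-invariance
  p2 <- p
  p2$beta0 <- p$beta0 + log(1.5)
  p2$phi0_ds <- qlogis(plogis(p$phi0_ds) / 1.5)
  p2$phi0_dsopen <- qlogis(plogis(p$phi0_dsopen) / 1.5)
  expect_gt(abs(joint_loglik(p2, case$structured, case$semistructured) -
                  joint_loglik(p, case$structured, case$semistructured)),
            0.1)
  # mismatched geometries refused
  se2 <- case$semistructured
  se2$geometry <- distance_geometry(c(0, 60, 120))
  expect_error(joint_loglik(p, case$structured, se2), "geometries")
})

test_that("joint likelihood peaks near the generating availability intercept", {
  case <- tiny_case(seed = 3, n_sites = 80, n_visits = 5, n_lists = 300)
  p <- case$params
  at <- function(shift) {
    p2 <- p; p2$phi0_ds <- p$phi0_ds + shift
    joint_loglik(p2, case$structured, case$semistructured)
  }
  expect_gt(at(0), at(-1))
  expect_gt(at(0), at(1))
})
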