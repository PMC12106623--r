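test_that("parameter draws respect their bounds and determinism", {
  rg <- default_param_ranges()
  set.seed(5)
  draws <- replicate(500, draw_parameters(rg)$phi0_dsopen)
  expect_gte(min(draws), qlogis(0.05))
  expect_lte(max(draws), qlogis(0.95))
  # degenerate bounds pin the parameter
  expect_true(all(replicate(5, draw_parameters(rg)$beta0) == 1))
  rg$beta <- c(0.3, 0.3)
  expect_equal(draw_parameters(rg)$beta, 0.3)
  rg$beta <- c(1, -1)
  expect_error(draw_parameters(rg), "lower bound exceeds")
  set.seed(42); a <- draw_parameters(default_param_ranges())
  set.seed(42); b <- draw_parameters(default_param_ranges())
  expect_identical(a, b)
})

test_that("simulated cases are reproducible bit-for-bit under a seed", {
  a <- simulate_ids_case(n_sites = 15, n_visits = 3, n_lists = 20, seed = 7)
  b <- simulate_ids_case(n_sites = 15, n_visits = 3, n_lists = 20, seed = 7)
  expect_identical(a, b)
  c2 <- simulate_ids_case(n_sites = 15, n_visits = 3, n_lists = 20, seed = 8)
  expect_false(identical(a$structured$y, c2$structured$y))
})

test_that("unavailable populations yield all-zero counts", {
  p <- sim_params(phi0_dsopen = -50, phi0_ds = -50, gamma = 0)
  set.seed(1)
  st <- simulate_structured(p, 25, 3)
  expect_true(all(st$y == 0))
  se <- simulate_semistructured(p, 40)
  expect_true(all(se$y == 0))
})

test_that("perfect availability and detection recover the superpopulation", {
  # one giant bin, sigma >> B, phi -> 1: every individual is counted
  geom <- distance_geometry(c(0, 150))
  p <- sim_params(phi0_dsopen = 50, gamma = 0, sigma0 = log(1e6),
                  alpha = 0, sd_eps_det = 0)
  set.seed(3)
  st <- simulate_structured(p, 40, 4, geometry = geom)
  for (j in 1:4) expect_equal(drop(st$y[, j, 1]), st$latent$M)
})

test_that("mean detected counts match the thinning expectation lambda*phi*sum(pi)", {
  geom <- distance_geometry()
  for (prm in list(sim_params(beta0 = 1, beta = 0, phi0_dsopen = qlogis(0.25),
                              phi0_ds = qlogis(0.25), gamma = 0,
                              sigma0 = log(50), alpha = 0,
                              sd_eps_abund = 0, sd_eps_det = 0),
                   sim_params(beta0 = 0.7, beta = 0, phi0_dsopen = qlogis(0.75),
                              phi0_ds = qlogis(0.75), gamma = 0,
                              sigma0 = log(200), alpha = 0,
                              sd_eps_abund = 0, sd_eps_det = 0))) {
    expected <- exp(prm$beta0) * plogis(prm$phi0_dsopen) *
      sum(cell_probabilities(geom, exp(prm$sigma0), drop_undetected = TRUE))
    set.seed(17)
    st <- simulate_structured(prm, 2000, 1, geometry = geom)
    obs <- rowSums(matrix(st$y, 2000))
    mc_se <- sd(obs) / sqrt(2000)
    expect_lt(abs(mean(obs) - expected), 3 * mc_se + 1e-9)
    set.seed(18)
    se <- simulate_semistructured(prm, 5000, geometry = geom)
    obs2 <- rowSums(se$y)
    expect_lt(abs(mean(obs2) - expected), 3 * sd(obs2) / sqrt(5000) + 1e-9)
  }
})

test_that("the two schemes coincide when intercepts match (same seed)", {
  p <- sim_params(phi0_dsopen = 0.3, phi0_ds = 0.3)
  set.seed(9); st <- simulate_structured(p, 50, 1)
  set.seed(9); se <- simulate_semistructured(p, 50)
  expect_equal(drop(st$y[, 1, ]), unname(se$y))
  expect_equal(st$latent$M, se$latent$M)
})

test_that("availability and detectability increase counts stochastically", {
  base <- sim_params(beta0 = 1.2, beta = 0, gamma = 0, alpha = 0,
                     sd_eps_abund = 0, sd_eps_det = 0)
  tot <- function(phi0, sigma0, seed = 31) {
    p <- base; p$phi0_dsopen <- phi0; p$sigma0 <- sigma0
    set.seed(seed)
    sum(simulate_structured(p, 400, 2)$y)
  }
  expect_lt(tot(qlogis(0.1), log(60)), tot(qlogis(0.9), log(60)))
  expect_lt(tot(qlogis(0.5), log(15)), tot(qlogis(0.5), log(150)))
})

test_that("design subsampling does the arithmetic and extends lists on demand", {
  case <- simulate_ids_case(n_sites = 200, n_visits = 2, n_lists = 1000,
                            seed = 21)
  sub <- subsample_design(case, 200, 1)
  expect_equal(sub$semistructured$n_lists, 200)
  expect_equal(sub$structured$n_sites, 200)
  sub2 <- subsample_design(case, 50, 6)
  expect_equal(sub2$semistructured$n_lists, 300)
  expect_equal(sub2$structured$n_sites, 50)
  # counts/covariates stay aligned after subsetting
  expect_equal(dim(sub2$structured$y)[1], 50)
  expect_equal(nrow(sub2$semistructured$X), 300)
  # same seed -> same subsample
  expect_identical(subsample_design(case, 80, 2, seed = 4)$structured$y,
                   subsample_design(case, 80, 2, seed = 4)$structured$y)
  # extension beyond the simulated pool
  sub3 <- subsample_design(case, 200, 6)
  expect_equal(sub3$semistructured$n_lists, 1200)
  expect_error(subsample_design(case, 200, 6, extend = FALSE), "disabled")
  expect_error(subsample_design(case, 500, 1), "only 200")
})

test_that("greedy spatial thinning honours the minimum separation", {
  # coincident lists: exactly one survives
  xy <- rbind(c(1, 1), c(1, 1), c(5, 5))
  expect_equal(spatial_thin(xy, 2), c(1, 3))
  # all mutually distant: all retained
  far <- cbind(seq(0, 40, by = 4), 0)
  expect_equal(spatial_thin(far, 2), seq_len(nrow(far)))
  # a cluster inside 1 km around a structured site: none retained
  set.seed(2)
  clust <- cbind(runif(10, 0, 1), runif(10, 0, 1))
  expect_length(spatial_thin(clust, 2, site_coordinates = rbind(c(0.5, 0.5))),
                0)
  # brute-force check: every retained pair is separated, every dropped
  # point is within range of an earlier retained one or a site
  set.seed(8)
  pts <- cbind(runif(60, 0, 12), runif(60, 0, 12))
  sites <- cbind(runif(4, 0, 12), runif(4, 0, 12))
  keep <- spatial_thin(pts, 2, site_coordinates = sites)
  d <- as.matrix(dist(rbind(pts[keep, ], sites)))
  diag(d) <- Inf
  expect_gte(min(d[seq_along(keep), ]), 2)
  for (i in setdiff(seq_len(nrow(pts)), keep)) {
    prior <- keep[keep < i]
    dmin <- min(c(sqrt(rowSums((sites -
      matrix(pts[i, ], nrow(sites), 2, byrow = TRUE))^2)),
      if (length(prior)) sqrt(rowSums((pts[prior, , drop = FALSE] -
        matrix(pts[i, ], length(prior), 2, byrow = TRUE))^2))))
    expect_lt(dmin, 2)
  }
  expect_error(spatial_thin(cbind(1, NA), 2), "complete numeric")
})

test_that("right truncation drops the distance tail and updates the radius", {
  d <- 1:100
  tr <- right_truncate(d, q = 0.95)
  # brute force: the 95th type-7 quantile of 1..100
  qb <- unname(quantile(d, 0.95))
  expect_equal(tr$radius, qb)
  expect_equal(tr$dropped, sum(d > qb))
  expect_true(all(tr$distances <= tr$radius))
  # equal distances: quantile equals the value, nothing dropped
  expect_equal(right_truncate(rep(30, 20))$dropped, 0)
  # q = 1 is the identity
  expect_equal(right_truncate(d, q = 1)$distances, d)
  expect_error(right_truncate(numeric(0)), "no observations")
})

test_that("dataset-level truncation rebins counts consistently", {
  p <- sim_params(sigma0 = log(150))
  set.seed(12)
  se <- simulate_semistructured(p, 300)
  tr <- right_truncate(se, q = 0.9)
  expect_lt(tr$geometry$B, se$geometry$B)
  expect_equal(sum(tr$y), sum(se$y) - round(0.1 * sum(se$y)),
               tolerance = 0.05 * sum(se$y))
  expect_equal(nrow(tr$detections), sum(tr$y))
  expect_true(all(tr$detections$distance <= tr$geometry$B))
})
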