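tiny_control <- mcmc_control(chains = 2, iter = 120, warmup = 80)

test_that("study-1 bookkeeping: rows, truth attachment, determinism", {
  tab <- run_study1(2, n_sites = 15, n_visits = 2, n_lists = 20,
                    formulations = c("IDS", "HDS"),
                    control = tiny_control, seed = 3)
  expect_s3_class(tab, "data.frame")
  n_par_ids <- sum(tab$case == 1 & tab$formulation == "IDS")
  n_par_hds <- sum(tab$case == 1 & tab$formulation == "HDS")
  expect_equal(nrow(tab), 2 * (n_par_ids + n_par_hds))
  # IDS monitors the scheme-specific availability intercept and the
  # DS-scheme residual SDs; HDS cannot
  expect_true("phi0_ds" %in% tab$parameter[tab$formulation == "IDS"])
  expect_false("phi0_ds" %in% tab$parameter[tab$formulation == "HDS"])
  # truth columns repeat the generated values within a case
  t1 <- tab[tab$case == 1 & tab$parameter == "sigma0", "true"]
  expect_equal(length(unique(t1)), 1)
  tab2 <- run_study1(2, n_sites = 15, n_visits = 2, n_lists = 20,
                     formulations = c("IDS", "HDS"),
                     control = tiny_control, seed = 3)
  expect_identical(tab, tab2)
})

test_that("recovery R-squared matches the closed-form regression oracle", {
  truth <- c(0.1, 0.4, 0.7, 1.1, 1.6)
  est <- c(0.15, 0.35, 0.8, 1.0, 1.7)
  tab <- data.frame(case = 1:5, formulation = "IDS", parameter = "beta",
                    true = truth, estimate = est, converged = TRUE)
  r2_oracle <- (sum((truth - mean(truth)) * (est - mean(est))))^2 /
    (sum((truth - mean(truth))^2) * sum((est - mean(est))^2))
  expect_equal(recovery_r2(tab, "beta"), r2_oracle, tolerance = 1e-12)
  expect_equal(recovery_r2(transform(tab, estimate = true), "beta"), 1)
  # non-converged rows are screened out
  tab$converged[3] <- FALSE
  expect_equal(recovery_r2(tab, "beta"),
               cor(truth[-3], est[-3])^2, tolerance = 1e-12)
  # constant truth refuses (histogram summary instead)
  tab0 <- transform(tab, true = 1, converged = TRUE)
  expect_error(recovery_r2(tab0, "beta"), "histogram")
  expect_error(recovery_r2(tab[1:2, ], "beta"), "fewer than 3")
})

test_that("bias summary uses the simulated-minus-estimated convention", {
  tab <- data.frame(case = 1:9, formulation = "IDS", parameter = "gamma",
                    true = 0.5, estimate = 0.5, converged = TRUE)
  expect_equal(bias_summary(tab, "gamma")$mean, 0)
  tab$estimate <- tab$true + 0.2
  b <- bias_summary(tab, "gamma")
  expect_equal(b$mean, -0.2)
  # quartiles agree with a brute-force sort
  set.seed(4)
  tab$estimate <- tab$true + rnorm(9)
  d <- sort(tab$true - tab$estimate)
  expect_equal(bias_summary(tab, "gamma")$quartiles,
               unname(quantile(d, c(0.25, 0.5, 0.75))))
})

test_that("study-2 runs both formulations per scenario cell", {
  tab <- run_study2(2, site_grid = 10, ratio_grid = 1, n_visits = 2,
                    control = tiny_control, seed = 5)
  # 2 cases x 1 scenario x 2 formulations
  expect_equal(nrow(unique(tab[c("case", "formulation")])), 4)
  expect_true(all(tab$width >= 0, na.rm = TRUE))
  expect_true(all(tab$n_structured == 10))
  tab2 <- run_study2(2, site_grid = 10, ratio_grid = 1, n_visits = 2,
                     control = tiny_control, seed = 5)
  expect_identical(tab$width, tab2$width)
})

# synthetic width table drawn from a known log-linear model
synth_width_table <- function(n_cases = 40, noise = 0.02, seed = 9) {
  set.seed(seed)
  grid <- expand.grid(case = seq_len(n_cases),
                      formulation = c("HDS", "IDS"),
                      parameter = c("beta", "sigma0"),
                      n_structured = c(50, 100, 200),
                      ratio = c(1, 3, 6), stringsAsFactors = FALSE)
  ids <- grid$formulation == "IDS"
  lw <- -1 + 0.3 * (grid$parameter == "sigma0") - 0.25 * ids -
    0.002 * grid$n_structured - 0.004 * ids * grid$n_structured -
    0.08 * ids * grid$ratio + rnorm(nrow(grid), 0, noise)
  data.frame(grid, true = 1, estimate = 1, width = exp(lw),
             converged = TRUE)
}

test_that("the log-width linear model recovers its generating coefficients", {
  tab <- synth_width_table()
  m <- fit_cri_width_model(tab)
  cf <- coef(m$fit)
  expect_equal(unname(cf["parametersigma0"]), 0.3, tolerance = 0.02)
  expect_equal(unname(cf["formulationHDS:n_structured"]), -0.002,
               tolerance = 0.02)
  expect_equal(unname(cf["formulationIDS:n_structured"]), -0.006,
               tolerance = 0.02)
  expect_equal(unname(cf["formulationIDS:ratio"]), -0.08, tolerance = 0.05)
  expect_lt(abs(cf["formulationHDS:ratio"]), 5e-3)
  # identical widths across formulations: no formulation shift, and the
  # design slopes coincide between the two formulations
  tab0 <- synth_width_table(noise = 0)
  tab0$width <- exp(-1 + 0.3 * (tab0$parameter == "sigma0") -
                      0.002 * tab0$n_structured)
  m0 <- fit_cri_width_model(tab0)
  cf0 <- coef(m0$fit)
  expect_lt(abs(cf0["formulationIDS"]), 1e-10)
  expect_lt(abs(cf0["formulationIDS:n_structured"] -
                  cf0["formulationHDS:n_structured"]), 1e-10)
  expect_lt(abs(cf0["formulationIDS:ratio"] - cf0["formulationHDS:ratio"]),
            1e-10)
  # grid predictions at cell means equal fitted cell means
  cell <- tab[tab$formulation == "IDS" & tab$n_structured == 100 &
                tab$ratio == 3, ]
  pred <- m$grid$log_width[m$grid$formulation == "IDS" &
                             m$grid$n_structured == 100 & m$grid$ratio == 3]
  expect_equal(pred, mean(log(cell$width)), tolerance = 0.02)
})

test_that("bootstrap bands wrap the full-data fit and are reproducible", {
  tab <- synth_width_table(n_cases = 25)
  # degenerate resample (every unit once) reproduces the base fit
  b1 <- bootstrap_cri_model(tab, n_boot = 1, resample_size = NULL)
  expect_equal(b1$grid$boot_mean, b1$grid$log_width, tolerance = 1e-12)
  b <- bootstrap_cri_model(tab, n_boot = 40, resample_size = 150, seed = 2)
  cover <- mean(b$grid$log_width >= b$grid$boot_lo &
                  b$grid$log_width <= b$grid$boot_hi)
  expect_gte(cover, 0.9)
  b2 <- bootstrap_cri_model(tab, n_boot = 40, resample_size = 150, seed = 2)
  expect_identical(b$boot, b2$boot)
  expect_error(bootstrap_cri_model(tab, n_boot = 2, resample_size = 1e6),
               "exceeds")
})
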