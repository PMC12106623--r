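# Simulation-study pipelines: identifiability (study 1) and
# credible-interval accuracy across sampling scenarios (study 2).

.truth_vector <- function(params, fit_summary) {
  # map fitted parameter names to their generated values; DS-scheme
  # residual-sd estimates are compared to the same generated sd
  tr <- c(beta0 = params$beta0,
          beta = unname(params$beta[1]),
          phi0_dsopen = params$phi0_dsopen, phi0_ds = params$phi0_ds,
          gamma = params$gamma, gamma_ds = params$gamma,
          sigma0 = params$sigma0, sigma0_ds = params$sigma0,
          alpha = params$alpha,
          sd_eps_abund = params$sd_eps_abund,
          sd_eps_det = params$sd_eps_det,
          sd_eps_abund_ds = params$sd_eps_abund,
          sd_eps_det_ds = params$sd_eps_det)
  tr[fit_summary$parameter]
}

.recovery_rows <- function(case_id, params, fit, n_structured, ratio) {
  s <- fit$summary
  data.frame(case = case_id, formulation = fit$formulation,
             parameter = s$parameter,
             true = unname(.truth_vector(params, s)),
             estimate = s$mean, sd = s$sd,
             q2.5 = s$q2.5, q97.5 = s$q97.5,
             width = s$q97.5 - s$q2.5,
             rhat = s$rhat, converged = fit$converged,
             n_structured = n_structured, ratio = ratio,
             stringsAsFactors = FALSE)
}

#' Identifiability study: simulate-and-refit over random parameter sets
#'
#' For each case, draws a generative parameter set uniformly within
#' `ranges`, simulates a structured dataset (`n_sites x n_visits`) and
#' `n_lists` single-visit lists, fits the requested formulations, and
#' records the generated ("true") value, the posterior summary and the
#' convergence flag for every monitored parameter.  The reference design
#' is 200 structured sites with 9 replicates plus 1000 lists; smaller
#' designs run proportionally faster.
#'
#' @param n_cases Number of simulated cases.
#' @param n_sites,n_visits,n_lists Design sizes.
#' @param ranges Parameter-draw bounds ([default_param_ranges()]).
#' @param formulations Character subset of `c("IDS", "HDS")`.
#' @param geometry Distance geometry shared by both schemes.
#' @param config Base [model_config()]; its formulation field is set per
#'   fit.
#' @param control [mcmc_control()] used for every fit.
#' @param max_tries Convergence retries per fit (see [fit_ids()]).
#' @param seed Master seed; case seeds are derived from it.
#' @param progress Print one line per case.
#' @return A recovery table (`data.frame`, class `ids_recovery`): one row
#'   per case, formulation and parameter.  Failed fits are recorded with
#'   `converged = FALSE` and `NA` estimates rather than aborting the run.
#' @export
run_study1 <- function(n_cases, n_sites = 200, n_visits = 9, n_lists = 1000,
                       ranges = default_param_ranges(),
                       formulations = "IDS",
                       geometry = distance_geometry(),
                       config = model_config(),
                       control = mcmc_control(),
                       max_tries = 2, seed = 1, progress = FALSE) {
  stopifnot(n_cases >= 1, all(formulations %in% c("IDS", "HDS")))
  rows <- vector("list", n_cases * length(formulations))
  k <- 0L
  for (cs in seq_len(n_cases)) {
    case_seed <- as.integer((seed * 7919 + cs * 104729) %% 2147483000)
    case <- simulate_ids_case(NULL, n_sites, n_visits, n_lists,
                              geometry = geometry, ranges = ranges,
                              seed = case_seed)
    for (fm in formulations) {
      k <- k + 1L
      cfg <- config; cfg$formulation <- fm
      fit <- try(fit_ids(case$structured, case$semistructured,
                         config = cfg, control = control,
                         seed = case_seed + 1L, max_tries = max_tries),
                 silent = TRUE)
      if (inherits(fit, "try-error")) {
        rows[[k]] <- data.frame(case = cs, formulation = fm,
                                parameter = NA_character_, true = NA,
                                estimate = NA, sd = NA, q2.5 = NA,
                                q97.5 = NA, width = NA, rhat = NA,
                                converged = FALSE,
                                n_structured = n_sites,
                                ratio = n_lists / n_sites)
      } else {
        rows[[k]] <- .recovery_rows(cs, case$params, fit, n_sites,
                                    n_lists / n_sites)
      }
      if (progress)
        cat(sprintf("case %d/%d %s %s\n", cs, n_cases, fm,
                    if (isTRUE(rows[[k]]$converged[1])) "ok" else "FAIL"))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ids_recovery", "data.frame")
  out
}

#' Squared correlation between generated and estimated parameter values
#'
#' Computed over converged fits only (non-converged cases are screened
#' out, as in the study design).  Refuses parameters whose generated value
#' is constant across cases (e.g. a fixed intercept), for which the
#' summary of interest is the histogram of estimates, not a regression.
#'
#' @param table A recovery table from [run_study1()] / [run_study2()].
#' @param parameter Parameter name.
#' @param formulation Which formulation's rows to use.
#' @return Squared Pearson correlation (scalar).
#' @export
recovery_r2 <- function(table, parameter, formulation = "IDS") {
  rows <- table[table$parameter %in% parameter &
                  table$formulation == formulation &
                  table$converged & is.finite(table$estimate), ,
                drop = FALSE]
  if (nrow(rows) < 3)
    stop("fewer than 3 converged cases for '", parameter, "'")
  if (var(rows$true) == 0)
    stop("'", parameter, "' was not varied across cases; R-squared is ",
         "undefined - summarize its estimates as a histogram instead")
  cor(rows$true, rows$estimate)^2
}

#' Distribution of (generated - estimated) differences
#'
#' Per-case differences on the parameter's link scale, over converged
#' fits; the sign convention is simulated minus estimated, so a positive
#' mean indicates underestimation.
#'
#' @inheritParams recovery_r2
#' @return List with `differences`, `mean`, `quartiles` and `mc_se` (the
#'   Monte-Carlo standard error of the mean difference).
#' @export
bias_summary <- function(table, parameter, formulation = "IDS") {
  rows <- table[table$parameter %in% parameter &
                  table$formulation == formulation &
                  table$converged & is.finite(table$estimate), ,
                drop = FALSE]
  if (!nrow(rows)) stop("no converged cases for '", parameter, "'")
  d <- rows$true - rows$estimate
  list(differences = d, mean = mean(d),
       quartiles = quantile(d, c(0.25, 0.5, 0.75), names = FALSE),
       mc_se = sd(d) / sqrt(length(d)))
}

#' Accuracy study: CRI widths across sampling scenarios
#'
#' Simulates (or reuses) full-size cases and, for every scenario on the
#' `site_grid x ratio_grid` lattice, subsamples each case to
#' `n_structured` sites and `n_structured * ratio` lists, then fits both
#' the HDS (structured block only) and IDS (both blocks) formulations and
#' records 95% CRI widths.  Base cases are simulated at
#' `max(site_grid)` sites and `max(site_grid) * max(ratio_grid)` lists so
#' every scenario is a genuine subsample of the same case.
#'
#' @param n_cases Number of base cases.
#' @param site_grid Numbers of structured sites (within 50..300 in the
#'   reference design).
#' @param ratio_grid Semi-structured lists per structured site (1..6).
#' @param n_visits Temporal replicates of the structured scheme (9, or 3
#'   for the reduced-replication variant).
#' @param cases Optional list of pre-simulated `ids_case` objects to reuse
#'   (e.g. the identifiability-study cases); they must be at least as
#'   large as the largest scenario unless extension is acceptable.
#' @inheritParams run_study1
#' @return Recovery table with one row per case, scenario, formulation
#'   and parameter (class `ids_recovery`).
#' @export
run_study2 <- function(n_cases, site_grid = c(50, 100, 200, 300),
                       ratio_grid = c(1, 3, 6), n_visits = 9,
                       ranges = default_param_ranges(),
                       geometry = distance_geometry(),
                       config = model_config(),
                       control = mcmc_control(),
                       max_tries = 2, cases = NULL, seed = 1,
                       progress = FALSE) {
  stopifnot(n_cases >= 1, all(site_grid >= 1), all(ratio_grid >= 1))
  I_max <- max(site_grid)
  L_max <- max(site_grid) * max(ratio_grid)
  rows <- list()
  for (cs in seq_len(n_cases)) {
    case_seed <- as.integer((seed * 7919 + cs * 104729) %% 2147483000)
    case <- if (!is.null(cases)) cases[[cs]] else
      simulate_ids_case(NULL, I_max, n_visits, L_max,
                        geometry = geometry, ranges = ranges,
                        seed = case_seed)
    # The ratio axis only adds semi-structured lists: the structured
    # subsample is drawn once per site count, so the HDS fit is computed
    # once per (case, n_structured) and its widths repeated across the
    # ratio grid (changing the number of lists cannot alter a model that
    # ignores them).  Scenario fits of the same case warm-start each
    # other: the posterior mode barely moves between subsamples and the
    # covariance scales roughly with the number of observation rows.
    warm <- list(HDS = NULL, IDS = NULL)
    for (ns in site_grid) {
      hds_fit <- NULL
      for (rt in ratio_grid) {
        sub <- subsample_design(case, ns, rt, seed = case_seed + ns)
        for (fm in c("HDS", "IDS")) {
          if (fm == "HDS" && !is.null(hds_fit)) {
            fit <- hds_fit
          } else {
            cfg <- config; cfg$formulation <- fm
            n_rows <- ns * n_visits + if (fm == "IDS") ns * rt else 0
            lap <- warm[[fm]]
            if (!is.null(lap)) {
              lap$cov <- lap$cov * (lap$rows / n_rows)
              lap <- lap[c("mode", "cov")]
            }
            fit <- try(fit_ids(sub$structured, sub$semistructured,
                               config = cfg, control = control,
                               seed = case_seed + 7L, laplace = lap,
                               max_tries = max_tries),
                       silent = TRUE)
            if (!inherits(fit, "try-error"))
              warm[[fm]] <- c(fit$laplace, list(rows = n_rows))
            if (fm == "HDS") hds_fit <- fit
          }
          rows[[length(rows) + 1L]] <-
            if (inherits(fit, "try-error"))
              data.frame(case = cs, formulation = fm,
                         parameter = NA_character_, true = NA,
                         estimate = NA, sd = NA, q2.5 = NA, q97.5 = NA,
                         width = NA, rhat = NA, converged = FALSE,
                         n_structured = ns, ratio = rt)
            else .recovery_rows(cs, case$params, fit, ns, rt)
        }
        if (progress)
          cat(sprintf("case %d/%d sites=%d ratio=%d done\n",
                      cs, n_cases, ns, rt))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ids_recovery", "data.frame")
  out
}

# parameters shared by both formulations (comparable CRI widths)
.shared_parameters <- function(table) {
  hds <- unique(table$parameter[table$formulation == "HDS"])
  ids <- unique(table$parameter[table$formulation == "IDS"])
  intersect(hds, ids)
}

#' Linear model of log CRI width over formulations and sampling designs
#'
#' Ordinary least squares of `log(width)` on parameter identity, model
#' formulation, and the interactions of formulation with the number of
#' structured sites and the semi-structured ratio, fitted on converged
#' rows of the shared parameters.  The interaction terms carry the
#' study's question: does additional semi-structured data narrow credible
#' intervals, and for which formulation?
#'
#' @param table Recovery table from [run_study2()].
#' @return List of class `ids_cri_model`: `fit` (the `lm`), `grid` and
#'   `predictions` (marginal predicted mean log-width per formulation over
#'   the design grid, averaged over parameters).
#' @export
fit_cri_width_model <- function(table) {
  tab <- table[table$converged & is.finite(table$width) &
                 table$width > 0 &
                 table$parameter %in% .shared_parameters(table), ,
               drop = FALSE]
  if (!all(c("HDS", "IDS") %in% tab$formulation))
    stop("both formulations must be present to model CRI widths")
  tab$formulation <- factor(tab$formulation, levels = c("HDS", "IDS"))
  tab$parameter <- factor(tab$parameter)
  fit <- lm(log(width) ~ parameter + formulation +
              formulation:n_structured + formulation:ratio, data = tab)
  a <- alias(fit)
  if (!is.null(a$Complete))
    stop("rank-deficient CRI-width model; aliased terms: ",
         paste(rownames(a$Complete), collapse = ", "))
  grid <- expand.grid(formulation = levels(tab$formulation),
                      n_structured = sort(unique(tab$n_structured)),
                      ratio = sort(unique(tab$ratio)))
  preds <- vapply(seq_len(nrow(grid)), function(i) {
    nd <- data.frame(parameter = levels(tab$parameter),
                     formulation = grid$formulation[i],
                     n_structured = grid$n_structured[i],
                     ratio = grid$ratio[i])
    mean(predict(fit, nd))
  }, numeric(1))
  structure(list(fit = fit, grid = cbind(grid, log_width = preds),
                 data = tab),
            class = "ids_cri_model")
}

#' @export
print.ids_cri_model <- function(x, ...) {
  cat("log CRI-width linear model over", nrow(x$data), "rows\n")
  print(round(coef(x$fit), 4))
  invisible(x)
}

#' Bootstrap confidence bands for the CRI-width model
#'
#' Refits the log-width linear model on `n_boot` case-level resamples of
#' converged cases (each resampled case keeps its paired HDS and IDS
#' rows), mirroring the study's 100 linear models on resamples of 250
#' converged models.
#'
#' @param table Recovery table from [run_study2()].
#' @param n_boot Number of bootstrap refits.
#' @param resample_size Cases per resample; `NULL` resamples as many
#'   case-scenario units as are available (with replacement).
#' @param seed RNG seed.
#' @return `ids_cri_model` with an additional `boot` matrix
#'   (`n_boot x nrow(grid)`) of replicate marginal predictions and
#'   `boot_mean` / `boot_lo` / `boot_hi` columns on `grid`.
#' @export
bootstrap_cri_model <- function(table, n_boot = 100, resample_size = 250,
                                seed = 1) {
  base <- fit_cri_width_model(table)
  tab <- base$data
  units <- unique(tab[, c("case", "n_structured", "ratio")])
  n_units <- nrow(units)
  if (!is.null(resample_size) && resample_size > n_units)
    stop("resample_size (", resample_size, ") exceeds the ", n_units,
         " available converged case-scenario units")
  m <- if (is.null(resample_size)) n_units else resample_size
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, nrow(base$grid))
  key_tab <- paste(tab$case, tab$n_structured, tab$ratio)
  key_units <- paste(units$case, units$n_structured, units$ratio)
  for (b in seq_len(n_boot)) {
    # NULL resample_size keeps every unit once (degenerate resample,
    # reproducing the full-data fit); otherwise sample with replacement
    pick <- if (is.null(resample_size)) seq_len(n_units) else
      sample.int(n_units, m, replace = TRUE)
    idx <- unlist(lapply(key_units[pick], function(k)
      which(key_tab == k)), use.names = FALSE)
    res <- try(fit_cri_width_model(tab[idx, , drop = FALSE]),
               silent = TRUE)
    if (!inherits(res, "try-error")) {
      mi <- match(paste(base$grid$formulation, base$grid$n_structured,
                        base$grid$ratio),
                  paste(res$grid$formulation, res$grid$n_structured,
                        res$grid$ratio))
      boot[b, ] <- res$grid$log_width[mi]
    }
  }
  base$boot <- boot
  base$grid$boot_mean <- colMeans(boot, na.rm = TRUE)
  base$grid$boot_lo <- apply(boot, 2, quantile, 0.025, na.rm = TRUE)
  base$grid$boot_hi <- apply(boot, 2, quantile, 0.975, na.rm = TRUE)
  base
}
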