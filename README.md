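# intds — integrated distance sampling for point-count surveys

`intds` estimates bird (or other point-count) abundance while separating
the three processes that stand between true abundance and a count:
exposure of individuals to a site (superpopulation), availability during
a visit (temporary emigration), and distance-dependent detection. It is
written for quantitative ecologists who have a *structured* survey
(fixed sites, repeated visits, measured observation distances) and a
much larger *semi-structured* checklist dataset (single visits), and who
want to use both at once.

## The model

Hierarchical distance sampling (HDS), per site `i` and visit `j`:

```
M_i  ~ Poisson(lambda_i)                    superpopulation
N_ij ~ Binomial(M_i, phi_ij)                availability
y_ij ~ Multinomial(N_ij, pi_ij)             binned distance counts
```

with a half-normal detection function `g(r) = exp(-r^2 / 2 sigma_ij^2)`
integrated over distance bins against the point-transect radial density
`2r / B^2`, and log/logit-linear submodels

```
log(lambda_i) = beta0 + beta X_i + eps_abund_i
logit(phi_ij) = phi0 + gamma U_ij
log(sigma_ij) = sigma0 + alpha Z_ij + eps_det_ij
```

The integrated formulation (IDS) adds single-visit checklists under a
joint likelihood with shared parameters and a scheme-specific
availability intercept `phi0_ds`. Single-visit data alone cannot
separate abundance from availability (their likelihood is invariant
under `lambda -> c lambda`, `phi -> phi / c`); the replicated dataset
breaks that confounding, and the checklists then sharpen every shared
parameter. A zero-inflated Poisson abundance family and session/observer
random effects are available for case-study-style models.

Likelihoods are fully marginalized (no latent-state sampling): `N` and
`y` collapse analytically, `M` is summed to a negligible-tail
truncation, and the log-normal residuals are integrated by
Gauss–Hermite quadrature. Fitting is Bayesian MCMC over the remaining
8–15 hyperparameters with split-R-hat convergence screening.

## A worked example

```r
library(intds)

p <- sim_params(beta0 = 1, beta = 0.5, phi0_dsopen = qlogis(0.6),
                phi0_ds = qlogis(0.35), gamma = 0.4, sigma0 = log(70),
                alpha = 0.3, sd_eps_abund = 0.2, sd_eps_det = 0.2)
case <- simulate_ids_case(p, n_sites = 120, n_visits = 6,
                          n_lists = 400, seed = 61)
fit <- fit_ids(case$structured, case$semistructured,
               config = model_config("IDS", n_gh = 5),
               control = mcmc_control(chains = 3, iter = 600,
                                      warmup = 350), seed = 62,
               max_tries = 2)
print(fit)
```

```
IDS fit: 3600 draws, 3 chains, sampler = mixture (converged)
       parameter   mean    sd   q2.5  q97.5  rhat     ess
           beta0  1.422 0.265  0.980  2.006 1.009 565.764
            beta  0.556 0.055  0.451  0.668 1.012 281.716
     phi0_dsopen -0.403 0.472 -1.317  0.539 1.006 526.575
         phi0_ds -1.301 0.369 -2.073 -0.581 1.010 519.421
           gamma  0.314 0.093  0.147  0.506 1.002 424.971
          sigma0  4.281 0.045  4.191  4.373 1.005 433.516
           alpha  0.310 0.036  0.244  0.389 1.009 298.285
    sd_eps_abund  0.153 0.101  0.007  0.358 1.005 317.024
      sd_eps_det  0.222 0.070  0.068  0.348 1.029 250.525
 sd_eps_abund_ds  0.209 0.133  0.011  0.505 1.003 447.096
   sd_eps_det_ds  0.141 0.099  0.009  0.370 1.011 459.198
```

Reading the output: every generating value (`beta0 = 1`,
`beta = 0.5`, `phi0_dsopen = 0.41`, `phi0_ds = -0.62`,
`sigma0 = log 70 = 4.25`, `alpha = 0.3`, residual SDs 0.2) lies inside
its 95% credible interval. The detection scale `sigma0` is pinned to a
couple of percent because every detection carries a distance, while the
availability intercepts are the wide ones — they are informed only
through the temporal replicates, and the scheme-specific intercepts are
still separated from each other, which single-visit data alone cannot
do. `rhat <= 1.1` for all parameters marks the fit as converged (this
run passed on its automatic second attempt, hence 3600 draws).

The two study pipelines reproduce the package's headline claims:

```r
tab <- run_study1(20, formulations = c("IDS", "HDS"), seed = 1)
recovery_r2(tab, "sigma0")     # ~0.98: generated vs estimated R^2
bias_summary(tab, "beta")$mean # ~0: simulated-minus-estimated

s2 <- run_study2(5, site_grid = c(50, 100, 200, 300),
                 ratio_grid = c(1, 3, 6), seed = 2)
boot <- bootstrap_cri_model(s2, n_boot = 100, resample_size = 40)
boot$grid  # bootstrap-mean log CRI widths: IDS below HDS throughout
```

There is also a command-line surface (`inst/scripts/intds`) with
`simulate`, `fit`, `study1`, `study2`, `thin` and `truncate`
subcommands; every run writes a JSON manifest with its seed and
options.

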