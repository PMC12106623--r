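# Laplace-initialized MCMC.  The marginalized posteriors here are low
# dimensional (8-15 hyperparameters) and close to Gaussian at the sample
# sizes of interest, so the sampler finds the posterior mode, builds a
# multivariate-t proposal from the local curvature, and samples with a
# mixture kernel: mode-centred independence proposals (fast global mixing
# when the Laplace approximation is good) interleaved with random-walk
# Metropolis moves (local escape when it is not).  Both kernels leave the
# posterior invariant; convergence is screened by split R-hat downstream.

#' Sampler settings
#'
#' @param chains Number of MCMC chains (at least 2 for split R-hat).
#' @param iter Post-warmup draws per chain.
#' @param warmup Warmup (burn-in) draws per chain, discarded.
#' @param method `"mixture"` (default: independence and random-walk moves
#'   interleaved), `"independence"`, or `"rw"` (pure adaptive random walk,
#'   run `rw_inflate` times longer to compensate for slower mixing).
#' @param prob_independence Probability of an independence move per
#'   iteration under the mixture kernel.
#' @param t_df Degrees of freedom of the multivariate-t independence
#'   proposal.
#' @param rw_inflate Iteration multiplier for the pure random walk.
#' @return A list of class `ids_mcmc_control`.
#' @export
mcmc_control <- function(chains = 4, iter = 600, warmup = 300,
                         method = c("mixture", "independence", "rw"),
                         prob_independence = 0.8, t_df = Inf,
                         rw_inflate = 3) {
  stopifnot(chains >= 2, iter >= 10, warmup >= 10)
  structure(list(chains = chains, iter = iter, warmup = warmup,
                 method = match.arg(method),
                 prob_independence = prob_independence,
                 t_df = t_df, rw_inflate = rw_inflate),
            class = "ids_mcmc_control")
}

# multivariate t draw / log-density given Cholesky factor (upper) of scale
.rmvt_chol <- function(mu, R, df) {
  d <- length(mu)
  z <- rnorm(d)
  u <- if (is.finite(df)) sqrt(df / rchisq(1, df)) else 1
  mu + u * drop(crossprod(R, z))
}

.dmvt_chol <- function(x, mu, R, R_logdet, df) {
  d <- length(mu)
  z <- backsolve(R, x - mu, transpose = TRUE)
  q2 <- sum(z^2)
  if (is.finite(df)) {
    lgamma((df + d) / 2) - lgamma(df / 2) - (d / 2) * log(df * pi) -
      R_logdet - ((df + d) / 2) * log1p(q2 / df)
  } else {
    -(d / 2) * log(2 * pi) - R_logdet - q2 / 2
  }
}

.find_mode <- function(logpost, init, max_retry = 8) {
  neg <- function(v) {
    lp <- logpost(v)
    if (!is.finite(lp)) 1e10 else -lp
  }
  cur <- init
  for (k in seq_len(max_retry)) {
    if (is.finite(logpost(cur))) {
      opt <- try(optim(cur, neg, method = "BFGS",
                       control = list(maxit = 200)),
                 silent = TRUE)
      if (!inherits(opt, "try-error") && is.finite(opt$value) &&
          opt$value < 1e9) {
        if (opt$convergence != 0) { # polish an unconverged BFGS run
          opt2 <- optim(opt$par, neg, method = "Nelder-Mead",
                        control = list(maxit = 200))
          if (opt2$value < opt$value) opt <- opt2
        }
        return(opt$par)
      }
    }
    cur <- init + rnorm(length(init), 0, 0.3 * k)
  }
  stop("could not find a finite posterior mode after ", max_retry,
       " re-initializations")
}

.laplace_cov <- function(logpost, mode) {
  neg <- function(v) {
    lp <- logpost(v)
    if (!is.finite(lp)) 1e10 else -lp
  }
  H <- optimHess(mode, neg)
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE)
  lam <- pmax(ev$values, max(abs(ev$values)) * 1e-8)
  cov <- ev$vectors %*% diag(1 / lam, length(lam)) %*% t(ev$vectors)
  (cov + t(cov)) / 2
}

# One phase of one chain of the mixture kernel.  p_ind = 1 gives pure
# independence sampling; p_ind = 0 pure random walk (with Robbins-Monro
# scale adaptation while `adapt` is TRUE).  `centre` is the independence-
# proposal location.  Returns draws plus the chain state for continuation.
.run_chain <- function(logpost, state, centre, R_ind, R_logdet, df, R_rw,
                       p_ind, n, discard = 0, adapt = FALSE,
                       target = 0.25) {
  d <- length(centre)
  keep <- n - discard
  draws <- matrix(NA_real_, max(keep, 0), d)
  x <- state$x
  ls <- state$ls
  lp_x <- state$lp
  lq_x <- if (p_ind > 0) .dmvt_chol(x, centre, R_ind, R_logdet, df) else 0
  acc <- 0L
  for (t in seq_len(n)) {
    if (runif(1) < p_ind) {
      z <- .rmvt_chol(centre, R_ind, df)
      lp_z <- logpost(z)
      if (is.finite(lp_z)) {
        lq_z <- .dmvt_chol(z, centre, R_ind, R_logdet, df)
        if (log(runif(1)) < lp_z - lp_x + lq_x - lq_z) {
          x <- z; lp_x <- lp_z; lq_x <- lq_z; acc <- acc + 1L
        }
      }
    } else {
      z <- x + exp(ls) * drop(crossprod(R_rw, rnorm(d)))
      lp_z <- logpost(z)
      a <- if (is.finite(lp_z)) min(1, exp(lp_z - lp_x)) else 0
      if (runif(1) < a) {
        x <- z; lp_x <- lp_z
        lq_x <- if (p_ind > 0) .dmvt_chol(x, centre, R_ind, R_logdet, df)
          else 0
        acc <- acc + 1L
      }
      if (adapt) ls <- ls + (a - target) / sqrt(t) # Robbins-Monro
    }
    if (t > discard) draws[t - discard, ] <- x
  }
  list(draws = draws, accept = acc / n,
       state = list(x = x, ls = ls, lp = lp_x))
}

.safe_chol <- function(cov) {
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  lam <- pmax(ev$values, max(ev$values) * 1e-8)
  chol(ev$vectors %*% diag(lam, length(lam)) %*% t(ev$vectors))
}

# Main driver.  Warmup draws are used to re-estimate the proposal
# (location and covariance) before the sampling phase, so the
# independence component tracks the actual posterior rather than the
# Laplace approximation.  Returns draws (iter x chains x d) + bookkeeping.
.run_mcmc <- function(logpost, init, control, seed, laplace = NULL) {
  set.seed(seed)
  if (is.null(laplace)) {
    mode <- .find_mode(logpost, init)
    cov <- .laplace_cov(logpost, mode)
  } else {
    # warm start from a previous fit of a closely related posterior:
    # refine the supplied mode cheaply and reuse its covariance
    neg <- function(v) {
      lp <- logpost(v)
      if (!is.finite(lp)) 1e10 else -lp
    }
    opt <- optim(laplace$mode, neg, method = "BFGS",
                 control = list(maxit = 40))
    mode <- opt$par
    cov <- laplace$cov
  }
  d <- length(mode)
  R_ind <- chol(cov * 1.4) # slightly over-dispersed independence proposal
  R_rw <- chol(cov)
  R_logdet <- sum(log(diag(R_ind)))

  p_ind <- switch(control$method, mixture = control$prob_independence,
                  independence = 1, rw = 0)
  iter <- control$iter
  warmup <- control$warmup
  if (control$method == "rw") {
    iter <- iter * control$rw_inflate
    warmup <- warmup * control$rw_inflate
  }

  # phase 1: warmup, mostly random-walk moves while the Laplace proposal
  # is still uncalibrated
  states <- vector("list", control$chains)
  wdraws <- vector("list", control$chains)
  ls0 <- log(2.38 / sqrt(d))
  for (c in seq_len(control$chains)) {
    start <- mode + 0.3 * drop(crossprod(R_rw, rnorm(d)))
    if (!is.finite(logpost(start))) start <- mode
    res <- .run_chain(logpost,
                      list(x = start, ls = ls0, lp = logpost(start)),
                      mode, R_ind, R_logdet, control$t_df, R_rw,
                      p_ind = min(p_ind, 0.3),
                      n = warmup, discard = max(10, warmup %/% 4),
                      adapt = TRUE)
    states[[c]] <- res$state
    wdraws[[c]] <- res$draws
  }

  # re-estimate the proposal from pooled warmup draws
  pool <- do.call(rbind, wdraws)
  if (nrow(pool) > 5 * d) {
    centre <- colMeans(pool)
    cov2 <- stats::cov(pool)
    ok <- try({
      R_ind <- .safe_chol(cov2 * 1.6)
      R_rw <- .safe_chol(cov2)
      R_logdet <- sum(log(diag(R_ind)))
      centre
    }, silent = TRUE)
    if (!inherits(ok, "try-error")) mode_prop <- centre else
      mode_prop <- mode
  } else mode_prop <- mode

  # phase 2: sampling with the adapted proposal
  chains <- vector("list", control$chains)
  accept <- numeric(control$chains)
  settle <- max(20, warmup %/% 5)
  for (c in seq_len(control$chains)) {
    res <- .run_chain(logpost, states[[c]], mode_prop, R_ind, R_logdet,
                      control$t_df, R_rw, p_ind, n = iter + settle,
                      discard = settle, adapt = FALSE)
    chains[[c]] <- res$draws
    accept[c] <- res$accept
  }
  draws <- array(NA_real_, dim = c(iter, control$chains, d))
  for (c in seq_len(control$chains)) draws[, c, ] <- chains[[c]]
  list(draws = draws, mode = mode, cov = cov, method = control$method,
       accept = accept)
}

#' Split R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so that within-chain trends register as apparent non-convergence.
#'
#' @param x Draws matrix, `iterations x chains`.
#' @return Split R-hat (scalar); `NA` if fewer than 4 draws per half-chain.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  if (half < 4) return(NA_real_)
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W <= 0) return(if (B <= 0) 1 else Inf)
  sqrt(((half - 1) / half * W + B / half) / W)
}

.ess_total <- function(x) {
  # sum of per-chain effective sizes (coda's initial-sequence estimator),
  # capped at the actual draw count per chain
  sum(apply(x, 2, function(ch)
    min(length(ch), coda::effectiveSize(coda::as.mcmc(ch)))))
}
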