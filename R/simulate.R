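# Generative simulator for the two survey schemes.  Both schemes share the
# same chain: site-level expected abundance with log-normal residuals ->
# Poisson superpopulation M -> per-visit Binomial availability N ->
# individuals placed at radial distances with density 2r/B^2 -> half-normal
# detection with log-normal scale residuals -> binned counts.

.sim_scheme <- function(I, J, geom, beta0, beta, phi0, gamma,
                        sigma0, alpha, sd_a, sd_d) {
  p <- length(beta)
  X <- matrix(rnorm(I * p), I, p)
  U <- matrix(rnorm(I * J), I, J)
  Z <- matrix(rnorm(I * J), I, J)
  eps_a <- rnorm(I, 0, sd_a)
  lambda <- exp(beta0 + drop(X %*% beta) + eps_a)
  M <- rpois(I, lambda)
  phi <- plogis(phi0 + gamma * U)
  eps_d <- matrix(rnorm(I * J, 0, sd_d), I, J)
  sigma <- exp(sigma0 + alpha * Z + eps_d)

  nb <- geom$n_bins
  y <- array(0L, dim = c(I, J, nb))
  det <- vector("list", I * J)
  N <- matrix(0L, I, J)
  for (i in seq_len(I)) {
    for (j in seq_len(J)) {
      N[i, j] <- rbinom(1, M[i], phi[i, j])
      n <- N[i, j]
      if (n > 0) {
        r <- geom$B * sqrt(runif(n))
        seen <- runif(n) < half_normal_g(r, sigma[i, j])
        if (any(seen)) {
          rs <- r[seen]
          bin <- findInterval(rs, geom$breaks, rightmost.closed = TRUE,
                              left.open = TRUE)
          y[i, j, ] <- tabulate(bin, nbins = nb)
          det[[(i - 1) * J + j]] <- data.frame(site = i, visit = j,
                                               distance = rs, bin = bin)
        }
      }
    }
  }
  det <- do.call(rbind, det[!vapply(det, is.null, logical(1))])
  if (is.null(det))
    det <- data.frame(site = integer(0), visit = integer(0),
                      distance = numeric(0), bin = integer(0))
  list(X = X, U = U, Z = Z, y = y, M = M, N = N, phi = phi, sigma = sigma,
       lambda = lambda, eps_a = eps_a, eps_d = eps_d, detections = det)
}

#' Simulate a structured (temporally replicated) point-count dataset
#'
#' Generates counts per site, visit and distance bin from the hierarchical
#' chain `M_i ~ Poisson(lambda_i)`, `N_{i,j} ~ Binomial(M_i, phi_{i,j})`,
#' individuals placed uniformly in the disc of radius `B` and detected with
#' half-normal probability at their radial distance.  Covariates `X`
#' (abundance, site level), `U` (availability, site-visit) and `Z`
#' (detection, site-visit) are drawn i.i.d. standard normal.
#'
#' @param params An [sim_params()] object.
#' @param n_sites,n_visits Design: number of sites `I >= 1` and of temporal
#'   replicates `J >= 1` (a structured scheme normally has `J >= 2`).
#' @param geometry A [distance_geometry()].
#' @param keep_latent Retain the latent state (`M`, `N`, residuals) for
#'   truth-checking.
#' @return Object of class `ids_structured`: counts `y` (`I x J x n_bins`),
#'   covariates `X`, `U`, `Z`, `geometry`, a `detections` data frame with
#'   exact distances, and (optionally) `latent`.
#' @export
simulate_structured <- function(params, n_sites, n_visits,
                                geometry = distance_geometry(),
                                keep_latent = TRUE) {
  stopifnot(inherits(params, "ids_params"), n_sites >= 1, n_visits >= 1)
  s <- .sim_scheme(n_sites, n_visits, geometry,
                   params$beta0, params$beta, params$phi0_dsopen,
                   params$gamma, params$sigma0, params$alpha,
                   params$sd_eps_abund, params$sd_eps_det)
  out <- list(n_sites = n_sites, n_visits = n_visits,
              y = s$y, X = s$X, U = s$U, Z = s$Z,
              geometry = geometry, detections = s$detections)
  if (keep_latent)
    out$latent <- list(M = s$M, N = s$N, lambda = s$lambda,
                       phi = s$phi, sigma = s$sigma,
                       eps_abund = s$eps_a, eps_det = s$eps_d)
  structure(out, class = "ids_structured")
}

#' Simulate a semi-structured (single-visit checklist) dataset
#'
#' Same generative chain as [simulate_structured()] with a single visit per
#' list, the scheme-specific availability intercept `phi0_ds`, and fresh
#' abundance residuals per list location.  Optionally assigns planar
#' coordinates (uniform in a square region) for use with [spatial_thin()].
#'
#' @param params An [sim_params()] object.
#' @param n_lists Number of single-visit lists.
#' @param geometry A [distance_geometry()].
#' @param region_km If non-`NULL`, side length (km) of the square region in
#'   which list coordinates are drawn uniformly.
#' @param keep_latent Retain latent state.
#' @return Object of class `ids_semistructured`: counts `y`
#'   (`n_lists x n_bins`), covariates `X`, `V` (availability), `Z`,
#'   `geometry`, `detections`, optional `coordinates` (km).
#' @export
simulate_semistructured <- function(params, n_lists,
                                    geometry = distance_geometry(),
                                    region_km = NULL, keep_latent = TRUE) {
  stopifnot(inherits(params, "ids_params"), n_lists >= 1)
  s <- .sim_scheme(n_lists, 1L, geometry,
                   params$beta0, params$beta, params$phi0_ds,
                   params$gamma, params$sigma0, params$alpha,
                   params$sd_eps_abund, params$sd_eps_det)
  out <- list(n_lists = n_lists,
              y = matrix(s$y, n_lists, geometry$n_bins),
              X = s$X, V = drop(s$U), Z = drop(s$Z),
              geometry = geometry,
              detections = s$detections[, c("site", "distance", "bin")])
  names(out$detections)[1] <- "list"
  if (!is.null(region_km))
    out$coordinates <- matrix(runif(n_lists * 2, 0, region_km), n_lists, 2,
                              dimnames = list(NULL, c("x_km", "y_km")))
  if (keep_latent)
    out$latent <- list(M = s$M, N = drop(s$N), lambda = s$lambda,
                       phi = drop(s$phi), sigma = drop(s$sigma),
                       eps_abund = s$eps_a, eps_det = drop(s$eps_d))
  structure(out, class = "ids_semistructured")
}

#' @export
print.ids_structured <- function(x, ...) {
  cat("Structured survey data:", x$n_sites, "sites x", x$n_visits,
      "visits x", x$geometry$n_bins, "distance bins\n")
  cat("  total detections:", sum(x$y), "\n")
  invisible(x)
}

#' @export
print.ids_semistructured <- function(x, ...) {
  cat("Semi-structured survey data:", x$n_lists, "single-visit lists x",
      x$geometry$n_bins, "distance bins\n")
  cat("  total detections:", sum(x$y), "\n")
  invisible(x)
}

#' Simulate a full two-scheme case
#'
#' Draws (or accepts) a generative parameter set and simulates both
#' datasets, mimicking a protocol effect through the distinct availability
#' intercepts of the two schemes.  The default design matches the
#' identifiability study: 200 structured sites with 9 temporal replicates
#' plus 1000 single-visit lists.  Regenerating with the same seed
#' reproduces the case bit-for-bit.
#'
#' @param params An [sim_params()] object, or `NULL` to draw one from
#'   `ranges`.
#' @param n_sites,n_visits,n_lists Design sizes.
#' @param geometry A [distance_geometry()].
#' @param ranges Parameter-draw bounds when `params` is `NULL`.
#' @param region_km Optional square-region side for list coordinates.
#' @param seed Integer seed controlling every random draw of the case.
#' @return Object of class `ids_case` with elements `params`, `structured`,
#'   `semistructured` and `seed`.
#' @export
simulate_ids_case <- function(params = NULL, n_sites = 200, n_visits = 9,
                              n_lists = 1000,
                              geometry = distance_geometry(),
                              ranges = default_param_ranges(),
                              region_km = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(params)) params <- draw_parameters(ranges)
  structured <- simulate_structured(params, n_sites, n_visits, geometry)
  semi <- simulate_semistructured(params, n_lists, geometry,
                                  region_km = region_km)
  structure(list(params = params, structured = structured,
                 semistructured = semi, seed = seed),
            class = "ids_case")
}

#' @export
print.ids_case <- function(x, ...) {
  cat("Two-scheme simulated case (seed", x$seed, ")\n")
  print(x$structured)
  print(x$semistructured)
  invisible(x)
}

#' Subsample a simulated case to a smaller sampling scenario
#'
#' Restricts a case to `n_structured` structured sites and
#' `n_structured * ratio` semi-structured lists, the scenario axes of the
#' accuracy study (sites 50 to 300, ratio of added lists 1 to 6).  When
#' more lists are requested than the case holds, additional lists are
#' simulated from the same generative parameters (if `extend = TRUE`).
#'
#' @param case An `ids_case`.
#' @param n_structured Number of structured sites to retain.
#' @param ratio Semi-structured lists per structured site.
#' @param extend Simulate extra lists on demand when the request exceeds
#'   the available lists.
#' @param seed Seed for the subsampling draw (and any list extension).
#' @return A new `ids_case` with the requested design; latent state is
#'   subset accordingly.
#' @export
subsample_design <- function(case, n_structured, ratio, extend = TRUE,
                             seed = 1) {
  stopifnot(inherits(case, "ids_case"))
  st <- case$structured
  if (n_structured > st$n_sites)
    stop("requested ", n_structured, " structured sites but only ",
         st$n_sites, " available")
  n_lists <- as.integer(round(n_structured * ratio))
  set.seed(seed)
  keep_s <- sort(sample.int(st$n_sites, n_structured))

  semi <- case$semistructured
  if (n_lists > semi$n_lists) {
    if (!extend)
      stop("requested ", n_lists, " lists but only ", semi$n_lists,
           " available and extension is disabled")
    extra <- simulate_semistructured(case$params, n_lists - semi$n_lists,
                                     semi$geometry,
                                     region_km = NULL)
    semi <- .bind_semi(semi, extra)
  }
  keep_l <- sort(sample.int(semi$n_lists, n_lists))

  out <- case
  out$structured <- .subset_structured(st, keep_s)
  out$semistructured <- .subset_semi(semi, keep_l)
  out
}

.subset_structured <- function(st, keep) {
  st$y <- st$y[keep, , , drop = FALSE]
  st$X <- st$X[keep, , drop = FALSE]
  st$U <- st$U[keep, , drop = FALSE]
  st$Z <- st$Z[keep, , drop = FALSE]
  st$n_sites <- length(keep)
  st$detections <- st$detections[st$detections$site %in% keep, , drop = FALSE]
  st$detections$site <- match(st$detections$site, keep)
  if (!is.null(st$latent))
    st$latent <- list(M = st$latent$M[keep],
                      N = st$latent$N[keep, , drop = FALSE],
                      lambda = st$latent$lambda[keep],
                      phi = st$latent$phi[keep, , drop = FALSE],
                      sigma = st$latent$sigma[keep, , drop = FALSE],
                      eps_abund = st$latent$eps_abund[keep],
                      eps_det = st$latent$eps_det[keep, , drop = FALSE])
  st
}

.subset_semi <- function(se, keep) {
  se$y <- se$y[keep, , drop = FALSE]
  se$X <- se$X[keep, , drop = FALSE]
  se$V <- se$V[keep]
  se$Z <- se$Z[keep]
  se$n_lists <- length(keep)
  se$detections <- se$detections[se$detections$list %in% keep, , drop = FALSE]
  se$detections$list <- match(se$detections$list, keep)
  if (!is.null(se$coordinates))
    se$coordinates <- se$coordinates[keep, , drop = FALSE]
  if (!is.null(se$latent))
    se$latent <- lapply(se$latent, function(v)
      if (is.matrix(v)) v[keep, , drop = FALSE] else v[keep])
  se
}

.bind_semi <- function(a, b) {
  n_a <- a$n_lists
  b$detections$list <- b$detections$list + n_a
  a$y <- rbind(a$y, b$y)
  a$X <- rbind(a$X, b$X)
  a$V <- c(a$V, b$V)
  a$Z <- c(a$Z, b$Z)
  a$detections <- rbind(a$detections, b$detections)
  a$n_lists <- n_a + b$n_lists
  if (!is.null(a$coordinates)) a$coordinates <- NULL # extension has none
  if (!is.null(a$latent) && !is.null(b$latent))
    a$latent <- Map(function(u, v) if (is.matrix(u)) rbind(u, v) else c(u, v),
                    a$latent, b$latent)
  a
}
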