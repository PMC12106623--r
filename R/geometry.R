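#' Distance-bin geometry for point-transect sampling
#'
#' Defines the distance bins used to discretize observer-to-individual
#' distances on a point count, together with the truncation radius `B`
#' (the outermost break).  Individuals are assumed uniformly distributed
#' in the disc of radius `B`, so radial distance has density `2r/B^2`.
#'
#' @param breaks Strictly increasing numeric vector of bin edges in metres,
#'   starting at 0.  The default `c(0, 25, 50, 100, 200)` spans typical
#'   songbird detection distances up to a 200 m radius.
#' @return An object of class `ids_geometry` with elements `breaks`,
#'   `B` (truncation radius) and `n_bins`.
#' @examples
#' geom <- distance_geometry()
#' cell_probabilities(geom, sigma = 50)
#' @export
distance_geometry <- function(breaks = c(0, 25, 50, 100, 200)) {
  if (!is.numeric(breaks) || length(breaks) < 2)
    stop("`breaks` must be a numeric vector with at least two edges")
  if (breaks[1] != 0) stop("`breaks` must start at 0")
  if (any(diff(breaks) <= 0)) stop("`breaks` must be strictly increasing")
  structure(list(breaks = as.numeric(breaks),
                 B = as.numeric(breaks[length(breaks)]),
                 n_bins = length(breaks) - 1L),
            class = "ids_geometry")
}

#' @export
print.ids_geometry <- function(x, ...) {
  cat("Point-transect distance geometry\n")
  cat("  breaks (m):", paste(x$breaks, collapse = ", "), "\n")
  cat("  truncation radius B:", x$B, "m;", x$n_bins, "bins\n")
  invisible(x)
}

#' Half-normal detection function
#'
#' Probability of detecting an individual at radial distance `r`, given it
#' is available: `g(r) = exp(-r^2 / (2 sigma^2))`.  Detection is perfect at
#' distance zero (`g(0) = 1`).
#'
#' @param r Distance(s) in metres, non-negative.
#' @param sigma Detection-scale parameter in metres, positive.
#' @return Detection probabilities in `[0, 1]`.
#' @export
half_normal_g <- function(r, sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("`sigma` must be positive")
  if (any(r < 0)) stop("`r` must be non-negative")
  exp(-r^2 / (2 * sigma^2))
}

#' Multinomial cell probabilities over distance bins
#'
#' Integrates the half-normal detection function against the point-transect
#' radial density `2r/B^2` over each distance bin:
#' `pi_b = (2 sigma^2 / B^2) * (exp(-r_b^2/(2 sigma^2)) - exp(-r_{b+1}^2/(2 sigma^2)))`.
#' The returned vector carries one extra cell for undetected individuals,
#' `1 - sum(pi_b)`, so that it always sums to one and the availability
#' binomial need not be conditioned on detection.
#'
#' @param geom An [distance_geometry()] object.
#' @param sigma Detection scale in metres, positive.
#' @param drop_undetected If `TRUE`, return only the observable bins.
#' @return Numeric vector of length `n_bins + 1` (or `n_bins`), named by bin.
#' @export
cell_probabilities <- function(geom, sigma, drop_undetected = FALSE) {
  stopifnot(inherits(geom, "ids_geometry"))
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive number")
  p <- C_cell_probs(geom$breaks, sigma)
  names(p) <- c(paste0("bin_", seq_len(geom$n_bins)), "undetected")
  if (drop_undetected) p[-length(p)] else p
}
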