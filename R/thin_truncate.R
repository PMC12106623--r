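#' Spatial thinning of semi-structured lists
#'
#' Greedy minimum-separation filter applied to checklist locations before
#' integration: a list is retained if and only if it lies at least
#' `min_separation_km` from every structured site and from every previously
#' retained list (single pass in input order).  The default 2 km mirrors a
#' structured scheme laid out on a 2 x 2 km systematic grid.
#'
#' @param coordinates Two-column matrix (km) of list locations, or an
#'   `ids_semistructured` object carrying `$coordinates`.
#' @param min_separation_km Minimum separation, km.
#' @param site_coordinates Optional two-column matrix (km) of structured
#'   site locations that retained lists must also avoid.
#' @return Integer vector of retained list indices (in input order).  When
#'   given an `ids_semistructured` object, the thinned object is returned
#'   instead, with the retained indices as attribute `"retained"`.
#' @export
spatial_thin <- function(coordinates, min_separation_km = 2,
                         site_coordinates = NULL) {
  if (inherits(coordinates, "ids_semistructured")) {
    obj <- coordinates
    if (is.null(obj$coordinates))
      stop("semi-structured data carry no coordinates; cannot thin")
    keep <- spatial_thin(obj$coordinates, min_separation_km,
                         site_coordinates)
    out <- .subset_semi(obj, keep)
    attr(out, "retained") <- keep
    return(out)
  }
  xy <- as.matrix(coordinates)
  if (ncol(xy) != 2 || !is.numeric(xy) || anyNA(xy))
    stop("coordinates must be a complete numeric two-column matrix")
  d2min <- min_separation_km^2
  has_sites <- !is.null(site_coordinates)
  if (has_sites) sxy <- as.matrix(site_coordinates)
  kept <- integer(0)
  for (i in seq_len(nrow(xy))) {
    p <- xy[i, ]
    if (has_sites &&
        any((sxy[, 1] - p[1])^2 + (sxy[, 2] - p[2])^2 < d2min)) next
    if (length(kept) &&
        any((xy[kept, 1] - p[1])^2 + (xy[kept, 2] - p[2])^2 < d2min)) next
    kept <- c(kept, i)
  }
  kept
}

#' Right-truncate extreme observation distances
#'
#' Removes observations beyond the empirical `q`-quantile of observation
#' distances (default 5% right-side truncation) and shrinks the truncation
#' radius `B` to that quantile, a standard robustness step before fitting a
#' detection function.
#'
#' @param distances Numeric vector of observation distances (m); or an
#'   object with a `detections` data frame (`ids_structured` /
#'   `ids_semistructured`), in which case counts, geometry and detections
#'   are all updated.
#' @param q Retained quantile, in `(0, 1]`; `q = 1` is the identity.
#' @param geometry Geometry the distances were collected under (used to
#'   rebuild the binning; breaks above the new radius are dropped).
#' @return For a distance vector: list with `distances` (retained),
#'   `radius` (the new `B`) and `dropped` (count removed).  For a dataset:
#'   the truncated dataset with updated `geometry`.
#' @export
right_truncate <- function(distances, q = 0.95, geometry = NULL) {
  if (inherits(distances, c("ids_structured", "ids_semistructured"))) {
    obj <- distances
    d <- obj$detections$distance
    if (!length(d)) stop("no observations to truncate")
    B_new <- unname(quantile(d, q, type = 7))
    keep <- d <= B_new
    breaks <- obj$geometry$breaks
    breaks <- c(breaks[breaks < B_new], B_new)
    geom <- distance_geometry(breaks)
    det <- obj$detections[keep, , drop = FALSE]
    det$bin <- findInterval(det$distance, geom$breaks,
                            rightmost.closed = TRUE, left.open = TRUE)
    obj$detections <- det
    obj$geometry <- geom
    if (inherits(obj, "ids_structured")) {
      y <- array(0L, dim = c(obj$n_sites, obj$n_visits, geom$n_bins))
      if (nrow(det))
        for (k in seq_len(nrow(det)))
          y[det$site[k], det$visit[k], det$bin[k]] <-
            y[det$site[k], det$visit[k], det$bin[k]] + 1L
      obj$y <- y
    } else {
      y <- matrix(0L, obj$n_lists, geom$n_bins)
      if (nrow(det))
        for (k in seq_len(nrow(det)))
          y[det$list[k], det$bin[k]] <- y[det$list[k], det$bin[k]] + 1L
      obj$y <- y
    }
    return(obj)
  }
  if (!length(distances)) stop("no observations to truncate")
  if (q <= 0 || q > 1) stop("`q` must lie in (0, 1]")
  B_new <- unname(quantile(distances, q, type = 7))
  keep <- distances <= B_new
  list(distances = distances[keep], radius = B_new,
       dropped = sum(!keep))
}
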