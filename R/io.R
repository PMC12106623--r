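# Delimited-text persistence.  Datasets are written as one CSV per scheme
# (one row per site-visit or per list, bin-count columns `bin_1..bin_K`,
# then covariates) plus a JSON sidecar carrying geometry, seed and -- for
# simulated data -- the generating parameters.

#' Write a survey dataset (or simulated case) to delimited text
#'
#' @param x An `ids_structured`, `ids_semistructured` or `ids_case`.
#' @param path Output file (CSV); for a case, a directory receiving
#'   `structured.csv`, `semistructured.csv` and `case.json`.
#' @return Invisibly, the path(s) written.
#' @export
write_survey <- function(x, path) {
  if (inherits(x, "ids_case")) {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    p1 <- write_survey(x$structured, file.path(path, "structured.csv"))
    p2 <- write_survey(x$semistructured,
                       file.path(path, "semistructured.csv"))
    meta <- list(seed = x$seed, params = unclass(x$params),
                 breaks = x$structured$geometry$breaks)
    jsonlite::write_json(meta, file.path(path, "case.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(c(p1, p2, file.path(path, "case.json"))))
  }
  nb <- x$geometry$n_bins
  bins <- paste0("bin_", seq_len(nb))
  if (inherits(x, "ids_structured")) {
    I <- x$n_sites; J <- x$n_visits
    df <- data.frame(site_id = rep(seq_len(I), each = J),
                     visit = rep(seq_len(J), I))
    ym <- .as_count_matrix(x$y, nb)
    df[bins] <- as.data.frame(ym)
    for (k in seq_len(ncol(x$X)))
      df[[paste0("X", k)]] <- rep(x$X[, k], each = J)
    df$U <- as.numeric(t(x$U))
    df$Z <- as.numeric(t(x$Z))
  } else if (inherits(x, "ids_semistructured")) {
    df <- data.frame(list_id = seq_len(x$n_lists))
    df[bins] <- as.data.frame(x$y)
    for (k in seq_len(ncol(x$X)))
      df[[paste0("X", k)]] <- x$X[, k]
    df$V <- x$V
    df$Z <- x$Z
    if (!is.null(x$coordinates)) {
      df$x_km <- x$coordinates[, 1]
      df$y_km <- x$coordinates[, 2]
    }
  } else stop("unsupported object")
  write.csv(df, path, row.names = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(list(breaks = x$geometry$breaks),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(path, sidecar))
}

.schema_fail <- function(file, msgs) {
  stop("invalid survey table '", file, "':\n  ",
       paste(msgs, collapse = "\n  "), call. = FALSE)
}

#' Read a survey dataset from delimited text
#'
#' Validates the schema and reports offending rows/columns by name.
#' Counts may be given either pre-binned (`bin_*` columns) or as a raw
#' `distance` column (one row per detection plus zero rows), in which case
#' the loader bins distances using the sidecar/supplied geometry.
#'
#' @param path CSV file written by [write_survey()] (or hand-assembled to
#'   the same schema).
#' @param schema `"structured"` (site_id/visit rows) or
#'   `"semistructured"` (list_id rows).
#' @param geometry Distance geometry; defaults to the JSON sidecar next
#'   to `path`.
#' @return An `ids_structured` or `ids_semistructured` object.
#' @export
read_survey_table <- function(path, schema = c("structured",
                                               "semistructured"),
                              geometry = NULL) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(geometry)) {
    sidecar <- sub("\\.csv$", ".json", path)
    if (!file.exists(sidecar))
      stop("no geometry given and no sidecar found at ", sidecar)
    geometry <- distance_geometry(
      as.numeric(jsonlite::read_json(sidecar)$breaks))
  }
  df <- read.csv(path)
  nb <- geometry$n_bins
  bins <- paste0("bin_", seq_len(nb))
  id_col <- if (schema == "structured") "site_id" else "list_id"
  msgs <- character(0)
  need <- c(id_col, if (schema == "structured") "visit")
  miss <- setdiff(need, names(df))
  if (length(miss))
    msgs <- c(msgs, paste("missing column(s):",
                          paste(miss, collapse = ", ")))
  has_bins <- all(bins %in% names(df))
  has_dist <- "distance" %in% names(df)
  if (!has_bins && !has_dist)
    msgs <- c(msgs, paste("expected either columns",
                          paste(bins, collapse = ", "),
                          "or a `distance` column"))
  if (length(msgs)) .schema_fail(path, msgs)

  if (!has_bins && has_dist) {
    bad <- which(df$distance < 0)
    if (length(bad))
      .schema_fail(path, paste("negative distance in row(s):",
                               paste(head(bad, 5), collapse = ", ")))
    key <- if (schema == "structured")
      interaction(df$site_id, df$visit, drop = FALSE) else df$list_id
    binned <- findInterval(df$distance, geometry$breaks,
                           rightmost.closed = TRUE, left.open = TRUE)
    df0 <- df[!duplicated(key), , drop = FALSE]
    ym <- matrix(0L, nrow(df0), nb)
    ok <- !is.na(df$distance) & binned >= 1 & binned <= nb
    rowi <- match(key, key[!duplicated(key)])
    for (r in which(ok)) ym[rowi[r], binned[r]] <- ym[rowi[r], binned[r]] + 1L
    raw_det <- if (schema == "structured")
      data.frame(site = df$site_id[ok], visit = df$visit[ok],
                 distance = df$distance[ok], bin = binned[ok])
    else
      data.frame(list = rowi[ok], distance = df$distance[ok],
                 bin = binned[ok])
    df <- df0
    df[bins] <- as.data.frame(ym)
  }
  for (b in bins) {
    v <- df[[b]]
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      msgs <- c(msgs, paste0("column ", b,
                             ": negative/non-integer count in row(s) ",
                             paste(head(bad, 5), collapse = ", ")))
  }
  if (length(msgs)) .schema_fail(path, msgs)
  y <- as.matrix(df[bins])
  storage.mode(y) <- "integer"
  xcols <- grep("^X[0-9]*$", names(df), value = TRUE)

  if (schema == "structured") {
    sites <- sort(unique(df$site_id))
    visits <- sort(unique(df$visit))
    I <- length(sites); J <- length(visits)
    if (nrow(df) != I * J)
      .schema_fail(path, sprintf(
        "expected %d x %d = %d site-visit rows, found %d",
        I, J, I * J, nrow(df)))
    if (J == 1)
      warning("structured data with a single visit: availability is ",
              "only weakly identified", call. = FALSE)
    o <- order(match(df$site_id, sites), match(df$visit, visits))
    df <- df[o, ]; y <- y[o, , drop = FALSE]
    arr <- array(0L, dim = c(I, J, nb))
    for (j in seq_len(J)) arr[, j, ] <- y[(seq_len(I) - 1) * J + j, ]
    X <- as.matrix(df[!duplicated(df$site_id), xcols, drop = FALSE])
    det <- if (exists("raw_det", inherits = FALSE)) {
      raw_det$site <- match(raw_det$site, sites)
      raw_det
    } else data.frame(site = integer(0), visit = integer(0),
                      distance = numeric(0), bin = integer(0))
    structure(list(n_sites = I, n_visits = J, y = arr, X = X,
                   U = matrix(df$U, I, J, byrow = TRUE),
                   Z = matrix(df$Z, I, J, byrow = TRUE),
                   geometry = geometry,
                   detections = det),
              class = "ids_structured")
  } else {
    n <- nrow(df)
    out <- list(n_lists = n, y = y,
                X = as.matrix(df[xcols]),
                V = df$V, Z = df$Z, geometry = geometry,
                detections = if (exists("raw_det", inherits = FALSE))
                  raw_det
                else data.frame(list = integer(0),
                                distance = numeric(0),
                                bin = integer(0)))
    if (all(c("x_km", "y_km") %in% names(df)))
      out$coordinates <- cbind(x_km = df$x_km, y_km = df$y_km)
    structure(out, class = "ids_semistructured")
  }
}

#' Write a fit summary table and its run manifest
#'
#' @param fit An `ids_fit`.
#' @param path Output CSV; a JSON manifest (config, priors, sampler,
#'   seed, package version) is written next to it.
#' @return Invisibly, the paths written.
#' @export
write_fit_summary <- function(fit, path) {
  stopifnot(inherits(fit, "ids_fit"))
  write.csv(fit$summary, path, row.names = FALSE)
  manifest <- list(
    formulation = fit$formulation,
    config = unclass(fit$config)[c("abundance_family",
                                   "share_detection_intercept",
                                   "share_availability_slope",
                                   "share_residual_sds",
                                   "random_effects", "n_gh")],
    priors = unclass(fit$config$priors),
    sampler = list(method = fit$method, chains = fit$n_chains,
                   draws = fit$n_draws,
                   accept = round(mean(fit$accept), 3)),
    seed = fit$seed, converged = fit$converged,
    package_version = as.character(utils::packageVersion("intds")))
  mpath <- sub("\\.csv$", "_manifest.json", path)
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(c(path, mpath))
}
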