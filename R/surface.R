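# PCA-based substance-use indices, PCA outlier ranking, and spatial
# interpolation of axis-1 scores over a geographic grid.

#' Correlation-matrix PCA of an analyte panel
#'
#' Eigendecomposition of the correlation matrix of (by default
#' log-transformed) concentrations.  Hair concentrations span four orders
#' of magnitude, so the raw correlation matrix is dominated by the few
#' extreme individuals; `log1p` (natural log of 1 + pg/mg, with
#' non-detects as 0) is the default and reproduces the published
#' eigenvalue spectrum of the tea index.  Sign convention: each axis is
#' oriented so its loadings sum positive, making higher axis-1 scores mean
#' higher overall exposure.
#'
#' @param x Numeric matrix (individuals x analytes) with non-detects
#'   already 0, or an `xeno_cohort` combined with `which`.
#' @param which Analyte subset when `x` is a cohort (default the three
#'   methylxanthines, the tea index).
#' @param transform `"log1p"` (default) or `"none"`.
#' @return An object of class `xeno_pca`: list with `eigenvalues`
#'   (descending, summing to the number of variables), `loadings`,
#'   `scores` (all axes; rownames = sample ids when available),
#'   `variables`, `transform`.
#' @export
#' @examples
#' p <- pca_correlation(load_cohort())
#' p$eigenvalues
pca_correlation <- function(x, which = XENO_METHYLXANTHINES,
                            transform = c("log1p", "none")) {
  transform <- match.arg(transform)
  if (inherits(x, "xeno_cohort")) x <- analyte_matrix(x, which)
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 variables", call. = FALSE)
  if (nrow(x) < 3) stop("need at least 3 rows", call. = FALSE)
  if (transform == "log1p") {
    if (any(x < 0)) stop("log1p transform requires non-negative values")
    x <- log1p(x)
  }
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  p <- prcomp(x, center = TRUE, scale. = TRUE)
  flip <- ifelse(colSums(p$rotation) < 0, -1, 1)
  loadings <- sweep(p$rotation, 2, flip, `*`)
  scores <- sweep(p$x, 2, flip, `*`)
  structure(list(
    eigenvalues = p$sdev^2,
    loadings = loadings,
    scores = scores,
    variables = colnames(x),
    transform = transform
  ), class = "xeno_pca")
}

#' Rank individuals by distance from the PCA centroid
#'
#' PCA over the five pooled analytes; individuals are ranked by Euclidean
#' distance from the origin in the plane of the first two axes (the
#' quantitative analogue of flagging outliers visually on a score plot).
#' Ties are broken by sample id for a stable order.
#'
#' @param cohort An `xeno_cohort` (at least 5 individuals).
#' @param k How many top-ranked individuals to return (default 4).
#' @param transform Passed to [pca_correlation()].
#' @return Tibble with `rank`, `sample_id`, `distance`.
#' @export
pca_outliers <- function(cohort, k = 4, transform = c("log1p", "none")) {
  transform <- match.arg(transform)
  if (nrow(cohort) < 5) stop("need at least 5 individuals", call. = FALSE)
  p <- pca_correlation(cohort, which = XENO_ANALYTES, transform = transform)
  d <- sqrt(rowSums(p$scores[, 1:2, drop = FALSE]^2))
  ord <- order(-d, cohort$sample_id)
  tibble::tibble(rank = seq_len(k),
                 sample_id = cohort$sample_id[ord[seq_len(k)]],
                 distance = d[ord[seq_len(k)]])
}

#' Interpolate site values over a lat/lon grid
#'
#' Piecewise-linear (barycentric) interpolation over the Delaunay
#' triangulation of the sites, evaluated on a regular grid spanning the
#' site bounding box (or an explicit one); grid nodes outside the convex
#' hull of the sites are absent from the result.  Finite values are then
#' affinely normalized to `[0, 0.7]`, the transparency range used for map
#' overlays; a constant field normalizes to the information-free midpoint
#' 0.35.
#'
#' @param sites Data frame with `lat_deg`, `lon_deg` and a value column.
#' @param values Numeric vector of site values (e.g. PCA axis-1 scores),
#'   or the name of a column of `sites`.
#' @param nx,ny Grid resolution (default 80 x 80).
#' @param bbox Optional list with `lat` and `lon` ranges (each length 2).
#' @param normalize Target range after normalization (default `c(0, 0.7)`).
#' @return An object of class `xeno_surface`: tibble `grid` with
#'   `lat_deg`, `lon_deg`, `value` (normalized), `value_raw`; plus the
#'   normalization range as attribute.
#' @export
interpolate_surface <- function(sites, values, nx = 80, ny = 80,
                                bbox = NULL, normalize = c(0, 0.7)) {
  if (is.character(values)) values <- sites[[values]]
  stopifnot(length(values) == nrow(sites))
  lon <- sites$lon_deg; lat <- sites$lat_deg
  if (nrow(unique(cbind(lon, lat))) < 3) {
    stop("need at least 3 distinct sites", call. = FALSE)
  }
  if (is.null(bbox)) bbox <- list(lat = range(lat), lon = range(lon))
  xo <- seq(bbox$lon[1], bbox$lon[2], length.out = nx)
  yo <- seq(bbox$lat[1], bbox$lat[2], length.out = ny)
  surf <- tryCatch(
    interp::interp(x = lon, y = lat, z = values, xo = xo, yo = yo,
                   method = "linear", duplicate = "mean"),
    error = function(e) stop("triangulation failed (collinear sites?): ",
                             conditionMessage(e), call. = FALSE))
  grid <- expand.grid(lon_deg = surf$x, lat_deg = surf$y)
  grid$value_raw <- as.vector(surf$z)
  grid <- grid[is.finite(grid$value_raw), c("lat_deg", "lon_deg",
                                            "value_raw")]
  rng <- range(grid$value_raw)
  grid$value <- if (diff(rng) == 0) {
    rep(mean(normalize), nrow(grid))
  } else {
    normalize[1] + (grid$value_raw - rng[1]) / diff(rng) * diff(normalize)
  }
  structure(tibble::as_tibble(grid[, c("lat_deg", "lon_deg", "value",
                                       "value_raw")]),
            normalize = normalize, class = c("xeno_surface", "tbl_df",
                                             "tbl", "data.frame"))
}
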