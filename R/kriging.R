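# Ordinary kriging of per-site scalar values (haplogroup frequencies or
# diversity indices) over geographic space, with empirical-variogram
# estimation and weighted-least-squares model fitting. Distances are
# geodesic (haversine, km): the study regions of interest span
# Europe to Iran, where planar approximations distort.

#' Construct a set of geo-referenced sample values
#'
#' @param lon,lat coordinates in decimal degrees.
#' @param value the scalar observed at each site (a haplogroup frequency
#'   in `[0,1]` or a diversity value `>= 0`).
#' @param label optional site labels.
#' @param is_frequency if TRUE, values are validated to lie in `[0,1]`.
#' @return data frame of class `geo_samples`.
#' @export
geo_samples <- function(lon, lat, value, label = NULL,
                        is_frequency = FALSE) {
  if (!all(is.finite(lon)) || !all(is.finite(lat)))
    stop("non-finite coordinates", call. = FALSE)
  if (is_frequency && (any(value < 0) || any(value > 1)))
    stop("frequency values must lie in [0,1]", call. = FALSE)
  df <- data.frame(lon = lon, lat = lat, value = value,
                   label = if (is.null(label))
                     paste0("site", seq_along(lon)) else label,
                   stringsAsFactors = FALSE)
  class(df) <- c("geo_samples", "data.frame")
  df
}

# haversine distance matrix in km
geo_dist_km <- function(lon1, lat1, lon2 = lon1, lat2 = lat1) {
  outer(seq_along(lon1), seq_along(lon2), function(i, j)
    geosphere::distHaversine(cbind(lon1[i], lat1[i]),
                             cbind(lon2[j], lat2[j]))) / 1000
}

#' Binned empirical semivariogram
#'
#' `gamma(h) = mean of (v_i - v_j)^2 / 2` over point pairs whose
#' great-circle separation falls in each distance bin.
#'
#' @param samples a [geo_samples()] set (>= 5 sites, or exactly 2 for the
#'   single-pair case).
#' @param n_bins number of equal-width distance bins.
#' @return data frame with `dist` (bin midpoint, km), `gamma` and
#'   `n_pairs`.
#' @export
empirical_variogram <- function(samples, n_bins = 10L) {
  n <- nrow(samples)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  d <- geo_dist_km(samples$lon, samples$lat)
  iu <- which(upper.tri(d), arr.ind = TRUE)
  h <- d[upper.tri(d)]
  if (all(h == 0)) stop("all samples are co-located", call. = FALSE)
  sv <- 0.5 * (samples$value[iu[, 1]] - samples$value[iu[, 2]])^2
  breaks <- seq(0, max(h) * (1 + 1e-9), length.out = n_bins + 1L)
  bin <- cut(h, breaks, include.lowest = TRUE, labels = FALSE)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) data.frame(
    dist = mean(h[bin == b]),
    gamma = mean(sv[bin == b]),
    n_pairs = sum(bin == b))))
  rownames(out) <- NULL
  out
}

#' Variogram model
#'
#' @param family `"spherical"` or `"exponential"` (practical-range
#'   parameterisation: the exponential reaches ~95% of the sill at
#'   `range`).
#' @param nugget non-negative nugget variance.
#' @param sill total sill (`>= nugget`).
#' @param range range parameter in km (`> 0`).
#' @return object of class `variogram_model`; call it on distances via
#'   [semivariance()].
#' @export
variogram_model <- function(family = c("spherical", "exponential"),
                            nugget = 0, sill = 1, range = 100) {
  family <- match.arg(family)
  if (nugget < 0 || sill < nugget || range <= 0)
    stop("require 0 <= nugget <= sill and range > 0", call. = FALSE)
  structure(list(family = family, nugget = nugget, sill = sill,
                 range = range),
            class = "variogram_model")
}

#' Evaluate a variogram model's semivariance at distances h (km)
#'
#' `semivariance(model, 0)` is 0 by definition (the nugget is the limit
#' from the right), which makes ordinary kriging honour the data exactly
#' at sample locations.
#'
#' @param model a [variogram_model()].
#' @param h vector of distances in km.
#' @export
semivariance <- function(model, h) {
  c0 <- model$nugget; c1 <- model$sill - model$nugget; a <- model$range
  g <- switch(model$family,
    spherical = ifelse(h >= a, c0 + c1,
                       c0 + c1 * (1.5 * h / a - 0.5 * (h / a)^3)),
    exponential = c0 + c1 * (1 - exp(-3 * h / a)))
  ifelse(h == 0, 0, g)
}

#' Fit a variogram model to a binned empirical variogram
#'
#' Weighted least squares over bins, weights equal to the pair counts.
#'
#' @param emp output of [empirical_variogram()].
#' @param family model family to fit.
#' @return a fitted [variogram_model()].
#' @export
fit_variogram <- function(emp, family = c("spherical", "exponential")) {
  family <- match.arg(family)
  w <- emp$n_pairs
  obj <- function(par) {
    m <- variogram_model(family, nugget = exp(par[1]),
                         sill = exp(par[1]) + exp(par[2]),
                         range = exp(par[3]))
    sum(w * (semivariance(m, emp$dist) - emp$gamma)^2)
  }
  s0 <- max(emp$gamma, 1e-8)
  par0 <- log(c(max(min(emp$gamma) * 0.5, 1e-8), s0, max(emp$dist) / 2))
  # keep the partial sill near the data scale and the range inside a few
  # multiples of the observed span: an exponential with an enormous range
  # fits a linear variogram equally well but with meaningless parameters
  upper <- log(c(s0 * 10, s0 * 10, max(emp$dist) * 5))
  lower <- log(c(1e-10, 1e-10, min(emp$dist) / 10))
  opt <- stats::optim(par0, obj, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 2000))
  variogram_model(family, nugget = exp(opt$par[1]),
                  sill = exp(opt$par[1]) + exp(opt$par[2]),
                  range = exp(opt$par[3]))
}

#' Build a lon/lat prediction grid covering the samples
#'
#' @param samples a [geo_samples()] set.
#' @param n_lon,n_lat grid resolution.
#' @param margin fractional margin added around the bounding box.
#' @return list with `lon` and `lat` axis vectors.
#' @export
make_grid <- function(samples, n_lon = 40L, n_lat = 40L, margin = 0.1) {
  span_lon <- diff(range(samples$lon)); span_lat <- diff(range(samples$lat))
  list(
    lon = seq(min(samples$lon) - margin * span_lon,
              max(samples$lon) + margin * span_lon, length.out = n_lon),
    lat = seq(min(samples$lat) - margin * span_lat,
              max(samples$lat) + margin * span_lat, length.out = n_lat))
}

#' Ordinary kriging of sample values onto a grid
#'
#' Solves, for every grid cell, the ordinary-kriging system on
#' semivariances with the unit-sum weight constraint (Lagrange
#' multiplier). With a zero nugget the surface honours the data exactly
#' at sample locations. Predicted frequencies are clipped to `[0,1]`
#' only at the reporting layer (`clip_frequency = TRUE`), never inside
#' the solver.
#'
#' @param samples a [geo_samples()] set; duplicate coordinates are an
#'   error (jitter upstream if needed).
#' @param model a [variogram_model()].
#' @param grid list with `lon` and `lat` vectors (see [make_grid()]).
#' @param clip_frequency clip reported values into `[0,1]`.
#' @return object of class `geo_surface`: list with `lon`, `lat`,
#'   `values` (matrix `length(lon) x length(lat)`), `variance` (kriging
#'   variance), and `max_weight_error` (largest deviation of any cell's
#'   weight sum from 1).
#' @export
ordinary_krige <- function(samples, model, grid = make_grid(samples),
                           clip_frequency = FALSE) {
  n <- nrow(samples)
  d <- geo_dist_km(samples$lon, samples$lat)
  if (any(d[upper.tri(d)] == 0))
    stop("duplicate sample coordinates make the kriging system singular",
         call. = FALSE)
  G <- semivariance(model, d)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  A_inv <- solve(A)

  cells <- expand.grid(lon = grid$lon, lat = grid$lat)
  d0 <- outer(seq_len(nrow(cells)), seq_len(n), function(i, j)
    geosphere::distHaversine(cbind(cells$lon[i], cells$lat[i]),
                             cbind(samples$lon[j], samples$lat[j]))) / 1000
  rhs <- cbind(semivariance(model, d0), 1)   # cells x (n+1)
  sol <- rhs %*% t(A_inv)                     # weights + multiplier
  w <- sol[, seq_len(n), drop = FALSE]
  pred <- as.vector(w %*% samples$value)
  krig_var <- rowSums(sol * rhs)              # sum w_i gamma_i0 + mu
  weight_err <- max(abs(rowSums(w) - 1))
  if (clip_frequency) pred <- pmin(1, pmax(0, pred))
  structure(list(
    lon = grid$lon, lat = grid$lat,
    values = matrix(pred, length(grid$lon), length(grid$lat)),
    variance = matrix(krig_var, length(grid$lon), length(grid$lat)),
    max_weight_error = weight_err,
    model = model),
    class = "geo_surface")
}

#' @export
print.geo_surface <- function(x, ...) {
  cat("<geo_surface>", length(x$lon), "x", length(x$lat),
      sprintf("grid; values in [%.3f, %.3f]; max weight error %.2e\n",
              min(x$values), max(x$values), x$max_weight_error))
  invisible(x)
}

#' Write a kriged surface as a plain-grid TSV (lon, lat, value)
#'
#' @param surface a `geo_surface`.
#' @param path output path.
#' @export
write_surface <- function(surface, path) {
  df <- expand.grid(lon = surface$lon, lat = surface$lat)
  df$value <- as.vector(surface$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}
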