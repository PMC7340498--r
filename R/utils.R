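# Shared internal helpers: age bands, Matern covariance, bilinear grid
# interpolation, and a damped Newton solver for penalized Poisson likelihoods.

# Five-year age bands 0-4 ... 80-84, 85+
age_band_breaks <- function() c(seq(0, 85, by = 5), Inf)

age_band_labels <- function() {
  lo <- seq(0, 85, by = 5)
  c(sprintf("%d-%d", lo[-length(lo)], lo[-length(lo)] + 4L), "85+")
}

#' Assign five-year age bands
#'
#' Cuts ages in years into the 5-year bands `0-4`, `5-9`, ..., `80-84`, `85+`
#' used throughout the package (rate tables, standardization, risk before 70).
#'
#' @param age Numeric vector of ages in years (>= 0).
#' @return A factor with the 18 five-year band levels.
#' @export
#' @examples
#' cut_age_band(c(0, 3, 17, 69, 90))
cut_age_band <- function(age) {
  if (any(age < 0, na.rm = TRUE)) abort("`age` must be non-negative.")
  cut(age, breaks = age_band_breaks(), labels = age_band_labels(),
      right = FALSE, include.lowest = TRUE)
}

# labels for the 14 bands spanning ages 0-69
bands_0_69 <- function() age_band_labels()[1:14]

band_lower <- function(band) {
  lo <- suppressWarnings(as.numeric(sub("[-+].*$", "", as.character(band))))
  lo
}

# Matern covariance, smoothness nu (default 1), parameterized by marginal sd
# and range rho (distance at which correlation has dropped substantially).
matern_cov <- function(d, sd, range, nu = 1) {
  if (range <= 0) abort("`range` must be positive.")
  kappa <- sqrt(2 * nu) / range
  out <- d
  pos <- d > 0
  x <- kappa * d[pos]
  out[pos] <- sd^2 * (2^(1 - nu) / gamma(nu)) * (x^nu) * besselK(x, nu)
  out[!pos] <- sd^2
  out
}

# Regular lon/lat grid of cell centres over a bounding box.
grid_centres <- function(bbox, nx, ny) {
  lon <- seq(bbox[["lon_min"]], bbox[["lon_max"]], length.out = nx)
  lat <- seq(bbox[["lat_min"]], bbox[["lat_max"]], length.out = ny)
  tidyr::expand_grid(lat = lat, lon = lon)[, c("lon", "lat")]
}

# Bilinear interpolation weights from a regular grid (gx, gy axis values,
# row-major over expand_grid(lat, lon) i.e. lon varies fastest) to arbitrary
# points. Points outside the grid hull are clamped to the border. Returns a
# dense n x (nx*ny) matrix.
bilinear_basis <- function(px, py, gx, gy) {
  nx <- length(gx); ny <- length(gy)
  px <- pmin(pmax(px, gx[1]), gx[nx])
  py <- pmin(pmax(py, gy[1]), gy[ny])
  ix <- findInterval(px, gx, all.inside = TRUE)
  iy <- findInterval(py, gy, all.inside = TRUE)
  wx <- (px - gx[ix]) / (gx[ix + 1] - gx[ix])
  wy <- (py - gy[iy]) / (gy[iy + 1] - gy[iy])
  n <- length(px)
  A <- matrix(0, n, nx * ny)
  idx <- function(i, j) (j - 1L) * nx + i
  rows <- seq_len(n)
  A[cbind(rows, idx(ix, iy))] <- (1 - wx) * (1 - wy)
  A[cbind(rows, idx(ix + 1L, iy))] <- wx * (1 - wy)
  A[cbind(rows, idx(ix, iy + 1L))] <- (1 - wx) * wy
  A[cbind(rows, idx(ix + 1L, iy + 1L))] <- wx * wy
  A
}

# Damped Newton maximization of a penalized Poisson log likelihood
#   l(xi) = sum(y * eta - exp(eta)) - 0.5 * xi' P xi,  eta = offset + C xi
# Returns the mode, the negative Hessian at the mode (C'WC + P) and the
# attained objective. eta is clamped to avoid overflow.
pois_newton <- function(C, y, offset, P, init = NULL, maxit = 100, tol = 1e-9) {
  d <- ncol(C)
  xi <- init %||% rep(0, d)
  obj <- function(xi) {
    eta <- pmin(offset + drop(C %*% xi), 30)
    sum(y * eta - exp(eta)) - 0.5 * sum(xi * (P %*% xi))
  }
  f <- obj(xi)
  for (it in seq_len(maxit)) {
    eta <- pmin(offset + drop(C %*% xi), 30)
    mu <- exp(eta)
    g <- drop(crossprod(C, y - mu)) - drop(P %*% xi)
    H <- crossprod(C * sqrt(mu)) + P
    ch <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(ch)) {
      H <- H + diag(1e-6, d)
      ch <- chol(H)
    }
    step <- backsolve(ch, forwardsolve(t(ch), g))
    s <- 1
    repeat {
      xi_new <- xi + s * step
      f_new <- obj(xi_new)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      s <- s / 2
      if (s < 1e-8) break
    }
    moved <- abs(f_new - f)
    xi <- xi_new
    f <- f_new
    if (moved < tol * (abs(f) + 1)) break
  }
  eta <- pmin(offset + drop(C %*% xi), 30)
  H <- crossprod(C * sqrt(exp(eta))) + P
  list(xi = xi, H = H, objective = f)
}

log_det_chol <- function(M) 2 * sum(log(diag(chol(M))))

# day-of-year on a fixed 365-day calendar; Feb 29 folds into Feb 28
day_of_year_365 <- function(dates) {
  yd <- lubridate::yday(dates)
  leap <- lubridate::leap_year(dates)
  ifelse(leap & yd >= 60, yd - 1L, yd)
}

stopifnot_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
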