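#' Allowed diffuser lengths
#'
#' Cylindrical diffusing fibers are available with diffusing parts of 2,
#' 2.5, 3, 4 and 5 cm; any other length is rejected at validation.
#' @format Numeric vector, mm.
#' @export
allowed_diffuser_lengths <- c(20, 25, 30, 40, 50)

#' Measured diffuser emission profile
#'
#' Normalized relative emission intensity along the diffusing part, with
#' axial position 0 at the proximal end of the diffuser.
#'
#' @param position Axial positions in mm, strictly increasing, >= 0.
#' @param intensity Non-negative relative intensities.
#' @return An `emission_profile` data frame.
#' @export
emission_profile <- function(position, intensity) {
  if (length(position) < 5L) stop("at least 5 profile samples are required")
  if (length(position) != length(intensity))
    stop("position and intensity lengths differ")
  if (any(diff(position) <= 0)) stop("positions must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  structure(data.frame(position = position, intensity = intensity),
            class = c("emission_profile", "data.frame"))
}

#' Read an emission profile from a two-column delimited file
#'
#' @param path Whitespace- or tab-delimited text: axial position (mm),
#'   normalized intensity. Lines starting with `#` are comments.
#' @export
read_emission_profile <- function(path) {
  tab <- utils::read.table(path, comment.char = "#", col.names =
                             c("position", "intensity"))
  emission_profile(tab$position, tab$intensity)
}

#' Super-Gaussian axial emission model
#'
#' `p(z) proportional to exp(-((z - center)^2 / (2 width^2))^order)` on the
#' support `[0, length]`; order 1 recovers a Gaussian, larger orders give
#' the flat-topped profiles typical of cylindrical diffusers.
#'
#' @param center Profile centre, mm.
#' @param width Width parameter, mm, > 0.
#' @param order Super-Gaussian order, > 0 (flat-top as order grows).
#' @param length Diffuser length L, mm; the PDF support is `[0, L]`.
#' @return A `super_gaussian` parameter object.
#' @export
super_gaussian <- function(center, width, order, length) {
  if (width <= 0) stop("width must be > 0")
  if (order <= 0) stop("order must be > 0")
  if (length <= 0) stop("length must be > 0")
  structure(list(center = center, width = width, order = order,
                 length = length),
            class = "super_gaussian")
}

#' @export
print.super_gaussian <- function(x, ...) {
  cat(sprintf(
    "<super_gaussian> center %.3g mm, width %.3g mm, order %.3g on [0, %g] mm\n",
    x$center, x$width, x$order, x$length))
  invisible(x)
}

# unnormalized shape
super_gaussian_shape <- function(z, params) {
  exp(-(((z - params$center)^2) / (2 * params$width^2))^params$order)
}

#' Super-Gaussian emission PDF
#'
#' Density of the axial launch-position distribution, normalized over the
#' diffuser support `[0, L]` by adaptive quadrature (zero outside).
#'
#' @param z Axial positions, mm.
#' @param params A [super_gaussian()] parameter object.
#' @return Density values, per mm.
#' @export
super_gaussian_pdf <- function(z, params) {
  Z <- super_gaussian_norm(params)
  out <- ifelse(z < 0 | z > params$length, 0,
                super_gaussian_shape(z, params) / Z)
  out
}

super_gaussian_norm <- function(params) {
  stats::integrate(function(z) super_gaussian_shape(z, params),
                   0, params$length, rel.tol = 1e-12,
                   subdivisions = 500L)$value
}

#' Fit a super-Gaussian to a measured emission profile
#'
#' Least-squares fit of `A * exp(-((z - c)^2 / (2 w^2))^k)` to the profile
#' intensities (Levenberg-Marquardt with bounded restarts from perturbed
#' moment-based starting values), returning the PDF parameters normalized
#' over `[0, L]`.
#'
#' @param profile An [emission_profile()].
#' @param length Diffuser length L in mm; defaults to the largest sampled
#'   position.
#' @param max_restarts Restarts from jittered starts before giving up.
#' @return A [super_gaussian()] with attributes `amplitude` and `rss`.
#' @export
fit_super_gaussian <- function(profile, length = NULL, max_restarts = 8L) {
  z <- profile$position
  y <- profile$intensity
  if (is.null(length)) length <- max(z)

  wsum <- sum(y)
  c0 <- if (wsum > 0) sum(z * y) / wsum else mean(z)
  w0 <- if (wsum > 0) sqrt(sum((z - c0)^2 * y) / wsum) else diff(range(z)) / 4
  start <- c(A = max(y), center = c0, width = max(w0, 1e-3), order = 1.5)
  lower <- c(A = 1e-9, center = min(z) - length, width = 1e-4, order = 0.2)
  upper <- c(A = 10 * max(y, 1), center = max(z) + length,
             width = 10 * length, order = 25)

  fit <- NULL
  for (attempt in seq_len(max_restarts + 1L)) {
    st <- start
    if (attempt > 1L) { # deterministic jitter ladder, no RNG consumed
      fac <- 1 + 0.25 * (attempt - 1L) * c(0, 1, -1, 1)
      st <- pmin(pmax(start * fac, lower + 1e-9), upper - 1e-9)
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * exp(-(((z - center)^2) / (2 * width^2))^order),
        start = as.list(st), lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("super-Gaussian fit failed to converge after ", max_restarts,
         " restarts (n = ", length(z), " samples, range [",
         min(z), ", ", max(z), "] mm)")
  cf <- stats::coef(fit)
  out <- super_gaussian(cf[["center"]], cf[["width"]], cf[["order"]], length)
  attr(out, "amplitude") <- cf[["A"]]
  attr(out, "rss") <- sum(stats::residuals(fit)^2)
  out
}

#' Sample photon launch positions along the diffuser axis
#'
#' Numeric inverse-CDF sampling of the super-Gaussian PDF on a 4096-point
#' grid over the support (grid density chosen so interpolation error is far
#' below Monte Carlo noise). Draws from R's RNG stream: call `set.seed()`
#' (or pass `seed`) for reproducibility.
#'
#' @param params A [super_gaussian()].
#' @param n Number of positions.
#' @param seed Optional integer seed applied before sampling.
#' @return Numeric vector of axial positions in `[0, L]`, mm.
#' @export
sample_axial_positions <- function(params, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  zg <- seq(0, params$length, length.out = 4096L)
  dens <- super_gaussian_shape(zg, params)
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(zg)))
  cdf <- cdf / cdf[length(cdf)]
  keep <- c(TRUE, diff(cdf) > 0) # drop flat (underflowed) tail segments
  u <- stats::runif(n)
  stats::approx(cdf[keep], zg[keep], xout = u, rule = 2)$y
}

# numeric CDF on a fine trapezoid grid (independent of the 4096-point
# inverse-CDF sampling grid)
super_gaussian_cdf <- function(z, params) {
  zg <- seq(0, params$length, length.out = 20001L)
  dens <- super_gaussian_shape(zg, params)
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(zg)))
  cdf <- cdf / cdf[length(cdf)]
  stats::approx(zg, cdf, xout = pmin(pmax(z, 0), params$length))$y
}

#' Sample isotropic unit direction vectors
#'
#' Uniform on the unit sphere: cos(theta) uniform on \[-1, 1\], azimuth
#' uniform on \[0, 2pi). Draws from R's RNG stream.
#'
#' @param n Number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
sample_isotropic_direction <- function(n) {
  ct <- stats::runif(n, -1, 1)
  st <- sqrt(1 - ct^2)
  psi <- stats::runif(n, 0, 2 * pi)
  cbind(st * cos(psi), st * sin(psi), ct)
}

#' Default flat-top diffuser emission model
#'
#' Used when no measured profile is supplied: order 3, width 0.42 L,
#' centred at L/2 — a flat-topped profile falling off near the diffuser
#' ends, matching the qualitative shape of measured cylindrical-diffuser
#' profiles.
#'
#' @param length Diffuser length, mm.
#' @export
default_diffuser_profile <- function(length) {
  super_gaussian(center = length / 2, width = 0.42 * length, order = 3,
                 length = length)
}

#' Build an isotropic line source from a fiber trajectory
#'
#' The diffusing part lies on the entry-to-target axis with its distal end
#' at the target point, extending the diffuser length back toward the entry
#' point (the convention is configurable via `distal_at_target`).
#'
#' @param traj A [fiber_trajectory()].
#' @param params Axial emission PDF; defaults to
#'   [default_diffuser_profile()] for the trajectory's diffuser length.
#' @param linear_power Source power per diffuser length, mW/cm (default
#'   200).
#' @param distal_at_target Place the distal diffuser end at the target
#'   point (default) rather than the proximal end.
#' @return A `line_source`: segment endpoints (proximal, distal), length,
#'   PDF and power. Total power is `linear_power * length`.
#' @export
build_line_source <- function(traj, params = NULL, linear_power = 200,
                              distal_at_target = TRUE) {
  seg <- diffuser_segment(traj, distal_at_target = distal_at_target)
  L <- traj$diffuser_length
  if (is.null(params)) params <- default_diffuser_profile(L)
  if (abs(params$length - L) > 1e-9)
    stop("emission PDF support (", params$length,
         " mm) does not match diffuser length (", L, " mm)")
  structure(list(proximal = seg[1, ], distal = seg[2, ], length = L,
                 pdf = params, linear_power = linear_power,
                 total_power = linear_power * L / 10),
            class = "line_source")
}

#' @export
print.line_source <- function(x, ...) {
  cat(sprintf(
    "<line_source> %g mm diffuser, %g mW/cm (%g mW total)\n  proximal (%.1f, %.1f, %.1f) -> distal (%.1f, %.1f, %.1f) mm\n",
    x$length, x$linear_power, x$total_power,
    x$proximal[1], x$proximal[2], x$proximal[3],
    x$distal[1], x$distal[2], x$distal[3]))
  invisible(x)
}

#' Isotropic point source
#'
#' All packets launch from one world point with isotropic directions.
#' Mainly used for validating the transport engine against the
#' diffusion-theory and Beer-Lambert closed forms.
#'
#' @param position World point, mm.
#' @param power Source power, mW.
#' @export
point_source <- function(position, power = 1) {
  structure(list(position = as.numeric(position), total_power = power),
            class = "point_source")
}
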