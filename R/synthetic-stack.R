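#' Specification for a synthetic birefringent fiber phantom
#'
#' Describes a phantom field of view populated with straight birefringent
#' fibers on a dark background, from which a crossed-polarizer rotation
#' stack can be rendered by \code{\link{generate_stack}}. On a fiber pixel
#' with amplitude A and in-plane orientation phi, frame z has expected
#' value \code{gain * (A * sin^2(2(theta_z - phi)) + dark_offset)}; on
#' background pixels \code{gain * dark_offset}. Fiber orientations are
#' drawn from a von Mises distribution on the doubled (90-degree-periodic)
#' circle, so \code{fiber_orientation_concentration = 0} gives a fully
#' disordered phantom and large values give tightly aligned fibers.
#'
#' @param width,height phantom size in pixels.
#' @param pixel_size micrometres per pixel (default 0.8).
#' @param fiber_count if not \code{NULL}, render exactly this many fibers;
#'   otherwise fibers are added until \code{coverage_fraction} is reached.
#' @param fiber_orientation_mean mean fiber orientation in degrees,
#'   reduced modulo 90.
#' @param fiber_orientation_concentration nonnegative von Mises
#'   concentration on the doubled circle (0 = uniform).
#' @param amplitude_range length-2 numeric, min and max signal amplitude A
#'   assigned per fiber (uniform draw).
#' @param dark_offset nonnegative baseline signal (crossed-polarizer leak).
#' @param noise_sd additive Gaussian noise scale per pixel per frame;
#'   rendered intensities are clipped at 0 (detectors are nonnegative).
#' @param gain_map_sd scale of the smooth multiplicative flood-field
#'   inhomogeneity (0 = perfectly uniform illumination).
#' @param coverage_fraction target fraction of pixels covered by fibers,
#'   in (0, 1].
#' @param fiber_width fiber thickness in pixels (anti-aliased).
#' @param fiber_length_range length-2 numeric, fiber length range in
#'   pixels; default \code{c(0.25, 0.75) * min(width, height)}.
#' @param seed integer seed; the generator is fully reproducible.
#' @return an object of class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(width = 256, height = 256, pixel_size = 0.8,
                         fiber_count = NULL,
                         fiber_orientation_mean = 45,
                         fiber_orientation_concentration = 4,
                         amplitude_range = c(0.4, 0.9),
                         dark_offset = 0.02,
                         noise_sd = 0.01,
                         gain_map_sd = 0,
                         coverage_fraction = 0.3,
                         fiber_width = 3,
                         fiber_length_range = NULL,
                         seed = 1L) {
  if (width < 1 || height < 1) stop("zero-area image")
  if (coverage_fraction <= 0 || coverage_fraction > 1)
    stop("`coverage_fraction` must be in (0, 1]")
  for (nm in c("fiber_orientation_concentration", "dark_offset", "noise_sd",
               "gain_map_sd"))
    if (get(nm) < 0) stop("`", nm, "` must be nonnegative")
  if (length(amplitude_range) != 2 || any(amplitude_range <= 0) ||
      diff(amplitude_range) < 0)
    stop("`amplitude_range` must be an increasing positive pair")
  if (is.null(fiber_length_range))
    fiber_length_range <- c(0.25, 0.75) * min(width, height)
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size, fiber_count = fiber_count,
                 fiber_orientation_mean = fiber_orientation_mean %% 90,
                 fiber_orientation_concentration = fiber_orientation_concentration,
                 amplitude_range = amplitude_range, dark_offset = dark_offset,
                 noise_sd = noise_sd, gain_map_sd = gain_map_sd,
                 coverage_fraction = coverage_fraction,
                 fiber_width = fiber_width,
                 fiber_length_range = fiber_length_range,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); kappa = 0 -> uniform
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- mu + sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  out %% (2 * pi)
}

# smooth low-frequency multiplicative gain field with mean exactly 1
make_gain_map <- function(h, w, sd, knots = 6L) {
  if (sd == 0) return(matrix(1, h, w))
  coarse <- matrix(stats::rnorm(knots * knots, 0, sd), knots, knots)
  g <- 1 + bilinear_upsample(coarse, h, w)
  g <- pmax(g, 0.05)
  g / mean(g)
}

# separable linear interpolation of a coarse grid onto an h x w raster
bilinear_upsample <- function(m, h, w) {
  ky <- nrow(m); kx <- ncol(m)
  ry <- apply(m, 2L, function(col)
    stats::approx(seq(0, 1, length.out = ky), col,
                  xout = seq(0, 1, length.out = h))$y)
  t(apply(ry, 1L, function(row)
    stats::approx(seq(0, 1, length.out = kx), row,
                  xout = seq(0, 1, length.out = w))$y))
}

# render one anti-aliased fiber segment; updates amplitude/orientation maps
# in place semantics via return (stronger fiber wins on overlap)
render_fiber <- function(amp_map, ori_map, cx, cy, theta_deg, len, width, A) {
  h <- nrow(amp_map); w <- ncol(amp_map)
  th <- theta_deg * pi / 180
  dx <- cos(th) * len / 2; dy <- sin(th) * len / 2
  x1 <- cx - dx; x2 <- cx + dx; y1 <- cy - dy; y2 <- cy + dy
  pad <- width / 2 + 1.5
  xr <- max(1, floor(min(x1, x2) - pad)):min(w, ceiling(max(x1, x2) + pad))
  yr <- max(1, floor(min(y1, y2) - pad)):min(h, ceiling(max(y1, y2) + pad))
  if (!length(xr) || !length(yr)) return(list(amp = amp_map, ori = ori_map))
  px <- matrix(xr, nrow = length(yr), ncol = length(xr), byrow = TRUE)
  py <- matrix(yr, nrow = length(yr), ncol = length(xr))
  # distance from each pixel center to the segment
  vx <- x2 - x1; vy <- y2 - y1
  L2 <- vx^2 + vy^2
  t_ <- ((px - x1) * vx + (py - y1) * vy) / L2
  t_ <- pmin(pmax(t_, 0), 1)
  d <- sqrt((px - (x1 + t_ * vx))^2 + (py - (y1 + t_ * vy))^2)
  alpha <- pmin(pmax(width / 2 + 0.5 - d, 0), 1)  # anti-aliased coverage
  a_new <- A * alpha
  sub_a <- amp_map[yr, xr, drop = FALSE]
  sub_o <- ori_map[yr, xr, drop = FALSE]
  take <- a_new > sub_a
  sub_a[take] <- a_new[take]
  sub_o[take] <- theta_deg %% 90
  amp_map[yr, xr] <- sub_a
  ori_map[yr, xr] <- sub_o
  list(amp = amp_map, ori = ori_map)
}

#' Render a crossed-polarizer rotation stack from a fiber phantom
#'
#' Places anti-aliased straight fibers until the target coverage fraction
#' (or fixed fiber count) is reached, then renders the 18-frame stack for
#' polarizer angles 0, 5, ..., 85 degrees under the sinusoid-squared
#' birefringence model, with optional smooth flood-field gain and additive
#' Gaussian noise (clipped at 0). Where fibers overlap, the stronger fiber
#' determines both amplitude and orientation, keeping the ground truth
#' single-valued.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return list with elements \code{stack} (a \code{\link{polar_stack}})
#'   and \code{truth}: a list with \code{orientation_map} (degrees in
#'   \code{[0, 90)}, \code{NA} on background), \code{amplitude_map},
#'   \code{fiber_mask}, \code{gain_map} and the originating \code{spec}.
#' @examples
#' ph <- generate_stack(phantom_spec(width = 64, height = 64, seed = 7))
#' mean(ph$truth$fiber_mask)
#' @export
generate_stack <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  amp <- matrix(0, h, w)
  ori <- matrix(NA_real_, h, w)
  n_max <- if (is.null(spec$fiber_count)) 50000L else spec$fiber_count
  mu2 <- spec$fiber_orientation_mean * pi / 45  # doubled-circle mean
  i <- 0L
  while (i < n_max) {
    i <- i + 1L
    theta <- (rvonmises(1L, mu2, spec$fiber_orientation_concentration) * 45 / pi) %% 90
    cx <- stats::runif(1, 1, w); cy <- stats::runif(1, 1, h)
    len <- stats::runif(1, spec$fiber_length_range[1], spec$fiber_length_range[2])
    A <- stats::runif(1, spec$amplitude_range[1], spec$amplitude_range[2])
    res <- render_fiber(amp, ori, cx, cy, theta, len, spec$fiber_width, A)
    amp <- res$amp; ori <- res$ori
    if (is.null(spec$fiber_count) && mean(amp > 0) >= spec$coverage_fraction)
      break
  }
  gain <- make_gain_map(h, w, spec$gain_map_sd)
  angles <- seq(0, 85, by = 5)
  frames <- array(0, dim = c(h, w, length(angles)))
  phi <- ifelse(is.na(ori), 0, ori)
  for (z in seq_along(angles)) {
    signal <- amp * sin(2 * (angles[z] - phi) * pi / 180)^2 + spec$dark_offset
    fr <- gain * signal
    if (spec$noise_sd > 0)
      fr <- fr + stats::rnorm(h * w, 0, spec$noise_sd)
    frames[, , z] <- pmax(fr, 0)
  }
  truth <- list(orientation_map = ori, amplitude_map = amp,
                fiber_mask = amp > 0, gain_map = gain, spec = spec)
  list(stack = polar_stack(frames, angles, spec$pixel_size), truth = truth)
}
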