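#' Polarimetric image stack
#'
#' Container for a set of co-registered grayscale frames acquired while a
#' crossed-polarizer pair is rotated in uniform angular steps. The standard
#' acquisition covers 0--85 degrees in 5-degree increments (18 frames); the
#' birefringent signal has a 90-degree period, so this samples one full
#' period.
#'
#' @param frames numeric array \code{[height, width, Z]} of nonnegative
#'   pixel intensities, one slice per polarizer angle.
#' @param angles numeric vector of polarizer angles in degrees, strictly
#'   increasing with a uniform step; must have length \code{Z}. Default
#'   \code{seq(0, 85, by = 5)}.
#' @param pixel_size pixel side length in micrometres (default 0.8).
#' @return an object of class \code{"polar_stack"}: a list with elements
#'   \code{frames}, \code{angles}, \code{pixel_size}.
#' @examples
#' frames <- array(runif(8 * 8 * 18), dim = c(8, 8, 18))
#' stk <- polar_stack(frames)
#' dim(stk$frames)
#' @export
polar_stack <- function(frames, angles = seq(0, 85, by = 5), pixel_size = 0.8) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a 3-D array [height, width, Z]")
  if (dim(frames)[1] < 1L || dim(frames)[2] < 1L)
    stop("zero-area image")
  if (dim(frames)[3] != length(angles))
    stop("number of frames (", dim(frames)[3], ") does not match number of angles (",
         length(angles), ")")
  if (length(angles) >= 2L) {
    steps <- diff(angles)
    if (any(steps <= 0) || max(abs(steps - steps[1])) > 1e-9)
      stop("`angles` must be strictly increasing with a uniform step")
  }
  if (any(frames < 0)) stop("frame intensities must be nonnegative")
  structure(list(frames = frames, angles = as.numeric(angles),
                 pixel_size = pixel_size),
            class = "polar_stack")
}

#' @export
print.polar_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<polar_stack> %d x %d px, %d frames (%g..%g deg, step %g), %g um/px\n",
              d[1], d[2], d[3], min(x$angles), max(x$angles),
              if (d[3] > 1) x$angles[2] - x$angles[1] else NA_real_,
              x$pixel_size))
  invisible(x)
}

# flatten frames to a [n_pixels x Z] matrix (column-major pixel order)
stack_matrix <- function(stack) {
  d <- dim(stack$frames)
  dim(stack$frames) <- c(d[1] * d[2], d[3])
  m <- stack$frames
  attr(m, "img_dim") <- d[1:2]
  m
}

#' Flood-field correction of a polarimetric stack
#'
#' Divides every frame by its spatial illumination pattern, estimated from a
#' reference stack acquired without a sample. Each sample frame is divided
#' pixel-wise by the matching reference frame normalized to unit mean, so
#' overall brightness is preserved while illumination inhomogeneity is
#' removed.
#'
#' @param stack a \code{\link{polar_stack}} acquired with the sample.
#' @param reference a \code{\link{polar_stack}} acquired without the sample;
#'   must match \code{stack} in shape and angles and be strictly positive.
#' @return a corrected \code{polar_stack}.
#' @export
flood_field_correct <- function(stack, reference) {
  stopifnot(inherits(stack, "polar_stack"), inherits(reference, "polar_stack"))
  if (!identical(dim(stack$frames), dim(reference$frames)))
    stop("reference shape does not match stack shape")
  if (length(stack$angles) != length(reference$angles) ||
      max(abs(stack$angles - reference$angles)) > 1e-9)
    stop("reference angles do not match stack angles")
  n_bad <- sum(reference$frames <= 0)
  if (n_bad > 0)
    stop("reference contains ", n_bad, " nonpositive pixel(s); cannot correct")
  out <- stack$frames
  Z <- dim(out)[3]
  for (z in seq_len(Z)) {
    ref_z <- reference$frames[, , z]
    out[, , z] <- stack$frames[, , z] / (ref_z / mean(ref_z))
  }
  polar_stack(out, stack$angles, stack$pixel_size)
}
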