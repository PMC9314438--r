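#' Birefringence intensity image (per-pixel angular standard deviation)
#'
#' On birefringent (collagenous) pixels the transmitted intensity between
#' rotating crossed polarizers modulates strongly with polarizer angle; on
#' non-birefringent tissue it stays at a flat dark level. The intensity
#' image quantifies that modulation as the sample standard deviation of each
#' pixel's brightness across the Z frames (divisor Z - 1), so a constant
#' pixel maps to exactly 0 and the map scales linearly with brightness.
#'
#' @param stack a \code{\link{polar_stack}} with at least 2 frames.
#' @return numeric matrix of per-pixel intensity values (same units as the
#'   input brightness).
#' @export
intensity_image <- function(stack) {
  stopifnot(inherits(stack, "polar_stack"))
  Z <- dim(stack$frames)[3]
  if (Z < 2) stop("at least 2 frames are required")
  m <- stack_matrix(stack)
  mu <- rowMeans(m)
  ss <- rowSums((m - mu)^2)
  out <- sqrt(ss / (Z - 1))
  dim(out) <- attr(m, "img_dim")
  out
}

#' Peak-signal orientation image
#'
#' For each pixel, the polarizer angle at which the measured signal is
#' maximal. For an ideal birefringent fiber with in-plane orientation phi
#' the signal sin^2(2(theta - phi)) peaks where theta - phi = 45 degrees
#' (mod 90), so the peak angle encodes fiber orientation up to a fixed
#' offset; it is only used through pairwise differences downstream. Ties
#' (e.g. constant background pixels) resolve to the smallest angle.
#'
#' @param stack a \code{\link{polar_stack}}.
#' @return numeric matrix of angles in degrees, values drawn from
#'   \code{stack$angles} reduced modulo 90.
#' @export
orientation_image <- function(stack) {
  stopifnot(inherits(stack, "polar_stack"))
  m <- stack_matrix(stack)
  idx <- max.col(m, ties.method = "first")
  out <- stack$angles[idx] %% 90
  dim(out) <- attr(m, "img_dim")
  out
}

#' Alignment image (windowed mean pairwise angular difference)
#'
#' Slides an odd square window (default 5 x 5, i.e. 4 um x 4 um at 0.8
#' um/px) over a peak-signal orientation image and computes, at each center
#' pixel, the mean over all unordered pixel pairs in the window of the
#' wrapped absolute angular difference
#' \code{d(a, b) = min(|a - b|, 90 - |a - b|)}. Orientations are equivalence
#' classes modulo 90 degrees (the crossed-polarizer signal period), hence
#' the wrap; the maximum possible value is 45. Low values indicate locally
#' aligned fibers, high values disordered ones.
#'
#' Pixels whose window does not fit fully inside the image are marked
#' invalid rather than padded.
#'
#' @param orient numeric matrix of orientations in degrees (values in
#'   \code{[0, 90)}), as from \code{\link{orientation_image}}.
#' @param window odd integer window side, at least 3 and at most the
#'   smaller image dimension. Default 5.
#' @return list with \code{mad} (numeric matrix, \code{NA} where invalid),
#'   \code{valid_mask} (logical matrix) and \code{window}.
#' @export
alignment_image <- function(orient, window = 5L) {
  if (!is.matrix(orient)) stop("`orient` must be a matrix")
  w <- as.integer(window)
  if (w %% 2L == 0L || w < 3L) stop("`window` must be an odd integer >= 3")
  if (w > min(dim(orient))) stop("`window` exceeds the image dimensions")
  h <- nrow(orient); wd <- ncol(orient)
  vh <- h - w + 1L; vw <- wd - w + 1L
  n <- w * w
  n_pairs <- n * (n - 1) / 2

  lev <- sort(unique(as.vector(orient)))
  if (length(lev) == 1L) {
    acc <- matrix(0, vh, vw)
  } else if (length(lev) <= 32L) {
    # discrete orientations (e.g. the 18-angle grid): box-count each level
    # with an integral image, then combine level pairs
    counts <- lapply(lev, function(v) box_sum(orient == v, w))
    acc <- matrix(0, vh, vw)
    for (i in seq_along(lev)[-length(lev)]) {
      for (j in seq((i + 1), length(lev))) {
        dd <- abs(lev[i] - lev[j])
        dd <- min(dd, 90 - dd)
        if (dd > 0) acc <- acc + counts[[i]] * counts[[j]] * dd
      }
    }
  } else {
    # continuous orientations: explicit pair loop over window offsets
    nb <- matrix(0, vh * vw, n)
    k <- 0L
    for (dx in 0:(w - 1L)) for (dy in 0:(w - 1L)) {
      k <- k + 1L
      nb[, k] <- orient[(1L + dy):(vh + dy), (1L + dx):(vw + dx)]
    }
    acc_v <- numeric(vh * vw)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      dd <- abs(nb[, i] - nb[, j])
      acc_v <- acc_v + pmin(dd, 90 - dd)
    }
    acc <- matrix(acc_v, vh, vw)
  }

  half <- (w - 1L) %/% 2L
  mad <- matrix(NA_real_, h, wd)
  mad[(half + 1L):(half + vh), (half + 1L):(half + vw)] <- acc / n_pairs
  valid <- !is.na(mad)
  list(mad = mad, valid_mask = valid, window = w)
}

# windowed box sum via 2-D integral image; returns (h-w+1) x (w-...) matrix
box_sum <- function(m, w) {
  m <- apply(m, 2L, cumsum)
  m <- t(apply(m, 1L, cumsum))
  h <- nrow(m); wd <- ncol(m)
  pad <- matrix(0, h + 1L, wd + 1L)
  pad[-1L, -1L] <- m
  i <- 1L:(h - w + 1L); j <- 1L:(wd - w + 1L)
  pad[i + w, j + w, drop = FALSE] - pad[i, j + w, drop = FALSE] -
    pad[i + w, j, drop = FALSE] + pad[i, j, drop = FALSE]
}

#' Collagen abundance image (sinusoid-squared goodness of fit)
#'
#' Fits each pixel's angular modulation to the birefringence model
#' \code{A * sin^2(2(theta - phi)) + c}. Via the double-angle identity this
#' family is exactly the harmonic model
#' \code{a0 + a1 cos(4 theta) + a2 sin(4 theta)}, so the fit is solved in
#' closed form by linear least squares -- no iterative optimizer, fully
#' deterministic. The goodness of fit R^2 is amplitude-independent: weakly
#' and strongly birefringent collagen both score near 1, while
#' non-modulating tissue scores near 0. Pixels with zero modulation
#' variance are assigned R^2 = 0; raw scores are clamped to \code{[0, 1]}.
#' The default detection threshold of 0.75 separates collagenous stroma
#' from other tissue.
#'
#' @param stack a \code{\link{polar_stack}} with at least 4 frames.
#' @param threshold R^2 detection threshold in (0, 1); default 0.75.
#' @return list with \code{r2} (numeric matrix in \code{[0, 1]}),
#'   \code{mask} (logical matrix, \code{r2 > threshold}) and
#'   \code{threshold}.
#' @export
abundance_image <- function(stack, threshold = 0.75) {
  stopifnot(inherits(stack, "polar_stack"))
  Z <- dim(stack$frames)[3]
  if (Z < 4) stop("at least 4 frames are required for the 3-parameter fit")
  m <- stack_matrix(stack)
  ang <- stack$angles * pi / 180
  X <- cbind(1, cos(4 * ang), sin(4 * ang))
  # closed-form LS coefficients for all pixels at once
  B <- m %*% X %*% solve(crossprod(X))
  fitted <- tcrossprod(B, X)
  sse <- rowSums((m - fitted)^2)
  mu <- rowMeans(m)
  sst <- rowSums((m - mu)^2)
  r2 <- ifelse(sst > 0, 1 - sse / sst, 0)
  r2 <- pmin(pmax(r2, 0), 1)
  dim(r2) <- attr(m, "img_dim")
  list(r2 = r2, mask = r2 > threshold, threshold = threshold)
}

#' Derive all parametric images from a stack
#'
#' Convenience wrapper producing the three parametric images (intensity,
#' alignment, abundance) plus the intermediate peak-signal orientation map.
#'
#' @inheritParams abundance_image
#' @inheritParams alignment_image
#' @return list with \code{intensity} (matrix), \code{orientation} (matrix),
#'   \code{alignment} (list, see \code{\link{alignment_image}}) and
#'   \code{abundance} (list, see \code{\link{abundance_image}}).
#' @export
parametric_images <- function(stack, threshold = 0.75, window = 5L) {
  orient <- orientation_image(stack)
  list(intensity = intensity_image(stack),
       orientation = orient,
       alignment = alignment_image(orient, window),
       abundance = abundance_image(stack, threshold))
}
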