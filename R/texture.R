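#' Quantize an image patch to 8 gray levels
#'
#' Linear binning of the patch's own \code{[min, max]} range into
#' \code{levels} equal-width bins, labelled 1..levels. Using the per-patch
#' range makes downstream texture features invariant to affine rescaling of
#' the raw image. A constant patch maps entirely to level 1.
#'
#' @param patch non-empty numeric matrix; \code{NA}s not allowed.
#' @param levels number of gray levels (default 8).
#' @return integer matrix with values in \code{1..levels}.
#' @export
quantize <- function(patch, levels = 8L) {
  if (length(patch) == 0) stop("empty patch")
  if (anyNA(patch)) stop("patch contains NA")
  rng <- range(patch)
  if (rng[1] == rng[2]) {
    out <- patch; out[] <- 1L
  } else {
    out <- pmin(floor((patch - rng[1]) / (rng[2] - rng[1]) * levels) + 1L,
                levels)
  }
  storage.mode(out) <- "integer"
  out
}

# pixel offset (drow, dcol) for a GLCM direction at unit distance
glcm_offset <- function(direction, distance = 1L) {
  d <- as.integer(distance)
  switch(as.character(direction),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("`direction` must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix
#'
#' Counts how often pairs of quantized gray levels occur at the given
#' offset (distance 1 pixel by default, direction 0/45/90/135 degrees),
#' accumulating each pair in both orders (symmetric GLCM), and normalizes
#' to a joint probability matrix.
#'
#' @param quantized integer matrix with values in \code{1..levels}, as
#'   from \code{\link{quantize}}.
#' @param direction one of 0, 45, 90, 135 (degrees).
#' @param distance offset length in pixels (default 1).
#' @param levels number of gray levels (default 8).
#' @return \code{levels x levels} numeric matrix summing to 1.
#' @export
glcm <- function(quantized, direction, distance = 1L, levels = 8L) {
  if (any(quantized < 1L | quantized > levels))
    stop("quantized values must lie in 1..levels")
  off <- glcm_offset(direction, distance)
  h <- nrow(quantized); w <- ncol(quantized)
  rlo <- max(1L, 1L - off[1]); rhi <- min(h, h - off[1])
  clo <- max(1L, 1L - off[2]); chi <- min(w, w - off[2])
  if (rlo > rhi || clo > chi) stop("no valid pixel pairs for this offset")
  r1 <- rlo:rhi; c1 <- clo:chi
  i1 <- quantized[r1, c1, drop = FALSE]
  i2 <- quantized[r1 + off[1], c1 + off[2], drop = FALSE]
  counts <- tabulate((i1 - 1L) * levels + i2, nbins = levels * levels)
  G <- matrix(counts, levels, levels, byrow = TRUE)
  G <- G + t(G)
  G / sum(G)
}

#' Haralick features of a normalized GLCM
#'
#' The five classical co-occurrence texture features: contrast
#' \code{sum p(i,j) (i-j)^2}, correlation
#' \code{sum (i-mu_i)(j-mu_j) p(i,j) / (sigma_i sigma_j)} (defined as 0
#' when either marginal variance is zero), energy \code{sum p^2},
#' homogeneity \code{sum p / (1 + |i-j|)}, and entropy
#' \code{-sum p log2 p} in bits with the \code{0 log 0 = 0} convention.
#'
#' @param g normalized symmetric GLCM (entries summing to 1).
#' @return named numeric vector \code{(contrast, correlation, energy,
#'   homogeneity, entropy)}.
#' @export
haralick <- function(g) {
  if (abs(sum(g) - 1) > 1e-8) stop("GLCM is not normalized")
  n <- nrow(g)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  px <- rowSums(g); py <- colSums(g)
  mi <- sum(seq_len(n) * px); mj <- sum(seq_len(n) * py)
  si <- sqrt(sum((seq_len(n) - mi)^2 * px))
  sj <- sqrt(sum((seq_len(n) - mj)^2 * py))
  contrast <- sum(g * (i - j)^2)
  correlation <- if (si * sj > 0) sum((i - mi) * (j - mj) * g) / (si * sj) else 0
  energy <- sum(g^2)
  homogeneity <- sum(g / (1 + abs(i - j)))
  pos <- g[g > 0]
  entropy <- -sum(pos * log2(pos))
  c(contrast = contrast, correlation = correlation, energy = energy,
    homogeneity = homogeneity, entropy = entropy)
}

#' Direction-averaged ROI texture features
#'
#' Extracts the ROI patch from a parametric image, quantizes it to 8 gray
#' levels over its own range, builds the four directional GLCMs at unit
#' distance, computes the five Haralick features per direction and returns
#' their means -- direction-independent texture metrics. Rows or columns
#' of the patch that are entirely \code{NA} (the invalid border of an
#' alignment image) are cropped before quantization.
#'
#' @param image numeric matrix (one of the parametric images).
#' @param roi ROI rectangle: a list or named vector with \code{x},
#'   \code{y}, \code{width}, \code{height}; 0-based, half-open pixel
#'   intervals (so \code{x = 0, width = ncol} spans all columns).
#' @param levels gray levels (default 8).
#' @param distance GLCM offset in pixels (default 1).
#' @return named numeric vector of the 5 direction-averaged features.
#' @export
roi_texture <- function(image, roi, levels = 8L, distance = 1L) {
  patch <- extract_roi(image, roi)
  keep_r <- rowSums(!is.na(patch)) > 0
  keep_c <- colSums(!is.na(patch)) > 0
  patch <- patch[keep_r, keep_c, drop = FALSE]
  if (length(patch) == 0 || anyNA(patch))
    stop("ROI patch has no complete valid region")
  q <- quantize(patch, levels)
  feats <- vapply(c(0, 45, 90, 135),
                  function(d) haralick(glcm(q, d, distance, levels)),
                  numeric(5))
  rowMeans(feats)
}

# extract an ROI rectangle (0-based, half-open) from a matrix
extract_roi <- function(image, roi) {
  roi <- as.list(roi)
  x <- roi$x; y <- roi$y; w <- roi$width; h <- roi$height
  if (is.null(x) || is.null(y) || is.null(w) || is.null(h))
    stop("roi must provide x, y, width, height")
  if (w < 1 || h < 1) stop("roi has zero area")
  if (x < 0 || y < 0 || x + w > ncol(image) || y + h > nrow(image))
    stop("roi extends outside the image")
  image[(y + 1):(y + h), (x + 1):(x + w), drop = FALSE]
}
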