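#' Write a polarimetric stack as multi-page TIFF with JSON sidecar
#'
#' Frames are written in ascending-angle page order as 32-bit grayscale.
#' TIFF storage is scaled to \code{[0, 1]}; the scale factor, the angles
#' and the pixel size go into a JSON sidecar next to the TIFF so the stack
#' round-trips exactly in value.
#'
#' @param stack a \code{\link{polar_stack}}.
#' @param path output TIFF path; the sidecar is \code{<path>.json}.
#' @return invisibly, \code{path}.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "polar_stack"))
  mx <- max(stack$frames)
  scale <- if (mx > 1) mx else 1
  pages <- lapply(seq_along(stack$angles),
                  function(z) stack$frames[, , z] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(angles = stack$angles,
                            pixel_size = stack$pixel_size,
                            scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a polarimetric stack written by \code{\link{write_stack}}
#'
#' @param path TIFF path with a \code{<path>.json} sidecar.
#' @return a \code{\link{polar_stack}}.
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (z in seq_along(pages)) {
    pg <- pages[[z]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]
    frames[, , z] <- pg * meta$scale
  }
  polar_stack(frames, meta$angles, meta$pixel_size)
}

#' Read an ROI rectangle table
#'
#' Expects columns \code{patient_id}, \code{roi_id}, \code{x}, \code{y},
#' \code{width}, \code{height} (0-based, half-open pixel intervals).
#'
#' @param path CSV path.
#' @return data.frame of ROI rectangles.
#' @export
read_roi_csv <- function(path) {
  rois <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "roi_id", "x", "y", "width", "height")
  miss <- setdiff(need, names(rois))
  if (length(miss))
    stop("ROI table lacks column(s): ", paste(miss, collapse = ", "))
  rois
}

#' Extract the 18-feature table for a set of ROIs on one stack
#'
#' Image-level front end: derives the parametric images from a stack and
#' computes the full feature vector for each ROI rectangle.
#'
#' @param stack a \code{\link{polar_stack}} (flood-field corrected if a
#'   reference is available, see \code{\link{flood_field_correct}}).
#' @param rois data.frame of ROI rectangles as from
#'   \code{\link{read_roi_csv}}.
#' @param threshold,window,levels,distance analysis constants (see
#'   \code{\link{pipeline_config}}).
#' @return data.frame with \code{patient_id}, \code{roi_id} and the 18
#'   named feature columns.
#' @export
extract_features <- function(stack, rois, threshold = 0.75, window = 5L,
                             levels = 8L, distance = 1L) {
  imgs <- parametric_images(stack, threshold, window)
  feats <- lapply(seq_len(nrow(rois)), function(i)
    roi_features(imgs, rois[i, ], levels, distance))
  out <- data.frame(patient_id = rois$patient_id, roi_id = rois$roi_id,
                    do.call(rbind, feats), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
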