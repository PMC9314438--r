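#' Polarimetric ROI summaries
#'
#' The three first-order ROI descriptors: the median of the intensity
#' image, the median of the alignment image over its valid pixels, and the
#' abundance ratio -- the fraction of all ROI pixels whose sinusoid-squared
#' fit exceeds the detection threshold.
#'
#' @param images output of \code{\link{parametric_images}}.
#' @param roi ROI rectangle (see \code{\link{roi_texture}}).
#' @return named numeric vector \code{(median_intensity,
#'   median_alignment, abundance_ratio)}.
#' @export
summarize_roi <- function(images, roi) {
  mir <- extract_roi(images$intensity, roi)
  mad <- extract_roi(images$alignment$mad, roi)
  msk <- extract_roi(images$abundance$mask, roi)
  mad_valid <- mad[!is.na(mad)]
  if (length(mad_valid) == 0)
    stop("ROI contains no valid alignment pixels")
  c(median_intensity = stats::median(mir),
    median_alignment = stats::median(mad_valid),
    abundance_ratio = mean(msk))
}

#' Full 18-feature vector for one ROI
#'
#' Concatenates the three polarimetric summaries with the five
#' direction-averaged Haralick texture features computed on each of the
#' three parametric images (intensity, alignment, abundance R^2 map), in
#' the canonical order of \code{\link{feature_names}}.
#'
#' @inheritParams summarize_roi
#' @inheritParams roi_texture
#' @return named numeric vector of length 18.
#' @export
roi_features <- function(images, roi, levels = 8L, distance = 1L) {
  base <- summarize_roi(images, roi)
  tex <- c(roi_texture(images$intensity, roi, levels, distance),
           roi_texture(images$alignment$mad, roi, levels, distance),
           roi_texture(images$abundance$r2, roi, levels, distance))
  out <- c(base, tex)
  names(out) <- feature_names()
  out
}

#' Assemble per-ROI feature vectors into a cohort table
#'
#' @param features numeric matrix (one row per ROI, 18 columns) or list of
#'   named length-18 vectors as from \code{\link{roi_features}}.
#' @param patient_id,roi_id character vectors, one entry per ROI.
#' @param survival data.frame with columns \code{patient_id} and
#'   \code{survived} (0/1), one row per patient.
#' @return data.frame keyed by \code{(patient_id, roi_id)} with the 18
#'   named feature columns and \code{survived}.
#' @export
assemble_cohort <- function(features, patient_id, roi_id, survival) {
  if (is.list(features) && !is.data.frame(features))
    features <- do.call(rbind, features)
  features <- as.matrix(features)
  if (ncol(features) != 18)
    stop("expected 18 feature columns, got ", ncol(features))
  if (anyNA(features)) {
    bad <- roi_id[which(rowSums(is.na(features)) > 0)[1]]
    stop("missing feature values for ROI ", bad)
  }
  if (length(patient_id) != nrow(features) || length(roi_id) != nrow(features))
    stop("patient_id/roi_id length does not match the feature rows")
  miss <- setdiff(unique(patient_id), survival$patient_id)
  if (length(miss))
    stop("no survival label for patient ", miss[1])
  colnames(features) <- feature_names()
  out <- data.frame(patient_id = patient_id, roi_id = roi_id, features,
                    stringsAsFactors = FALSE)
  out$survived <- survival$survived[match(out$patient_id, survival$patient_id)]
  out
}

#' Fit the two-step feature normalizer
#'
#' The clustering models consume features after a logarithmic
#' transformation followed by per-feature z-scoring. Features that are not
#' strictly positive (GLCM correlation can be negative) are shifted by
#' \code{s = 1 - min(x)} before the log, which preserves ordering while
#' taming skew. The fitted shift, post-log mean and SD are stored so that
#' later vectors (e.g. patient-averaged ROIs) can be mapped into the same
#' normalized space.
#'
#' @param x numeric matrix (rows = ROIs) or a cohort data.frame containing
#'   the 18 feature columns.
#' @return an object of class \code{"feature_normalizer"} with per-feature
#'   \code{shift}, \code{mean}, \code{sd}.
#' @export
fit_normalizer <- function(x) {
  if (is.data.frame(x)) x <- cohort_feature_matrix(x)
  if (nrow(x) < 2) stop("at least 2 rows are required")
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%02d", seq_len(ncol(x)))
  mins <- apply(x, 2L, min)
  const <- apply(x, 2L, function(v) max(v) == min(v))
  if (any(const))
    stop("constant feature column: ", colnames(x)[which(const)[1]])
  shift <- ifelse(mins <= 0, 1 - mins, 0)
  u <- log(sweep(x, 2L, shift, "+"))
  mu <- colMeans(u)
  sd <- apply(u, 2L, stats::sd)
  if (any(sd == 0))
    stop("constant feature column after log: ", colnames(x)[which(sd == 0)[1]])
  structure(list(shift = shift, mean = mu, sd = sd,
                 features = colnames(x)),
            class = "feature_normalizer")
}

#' Apply a fitted normalizer
#'
#' @param model a \code{\link{fit_normalizer}} result.
#' @param x numeric matrix or named vector with the model's feature
#'   columns, in raw space.
#' @return matrix (or vector) in normalized (log, z-scored) space.
#' @export
apply_normalizer <- function(model, x) {
  stopifnot(inherits(model, "feature_normalizer"))
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.null(colnames(x))) {
    if (!all(model$features %in% colnames(x)))
      stop("input lacks feature(s): ",
           paste(setdiff(model$features, colnames(x)), collapse = ", "))
    x <- x[, model$features, drop = FALSE]
  } else if (ncol(x) != length(model$features)) {
    stop("input has ", ncol(x), " columns; model expects ",
         length(model$features))
  }
  shifted <- sweep(x, 2L, model$shift, "+")
  if (any(shifted <= 0)) {
    bad <- model$features[which(colSums(shifted <= 0) > 0)[1]]
    stop("value out of the log-transform domain for feature ", bad)
  }
  u <- log(shifted)
  out <- sweep(sweep(u, 2L, model$mean, "-"), 2L, model$sd, "/")
  if (vec) out[1, ] else out
}
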