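#' Specification for a synthetic ROI-feature cohort
#'
#' Describes a patient cohort with planted two-cluster structure in an
#' 18-dimensional ROI feature space, mirroring the design of a stromal
#' polarimetry study: around 32 patients, 3--14 regions of interest each,
#' roughly 72\% of patients in the survivor-enriched latent class, and
#' 5-year survival probability depending on the latent class. Features are
#' generated in raw (pre-normalization) space; the second feature's class
#' means are negative so the logarithmic normalization's shift handling is
#' exercised.
#'
#' Class separation is expressed through the two mean vectors: the defaults
#' separate the classes by \code{4 * cluster_sd} in every feature, i.e.
#' clearly resolvable planted structure, so that downstream failures
#' indicate pipeline defects rather than statistical ambiguity.
#'
#' @param n_patients number of patients (default 32, at least 2).
#' @param rois_per_patient_range length-2 integer range of ROIs per patient
#'   (uniform draw), min at least 1; default \code{c(3, 14)}.
#' @param cluster_means list of two length-18 numeric vectors, the latent
#'   class means in raw feature space. Default: class 1 at a baseline,
#'   class 2 shifted by \code{4 * cluster_sd} per feature.
#' @param cluster_sd positive scalar or length-18 vector of within-class
#'   feature standard deviations (default 1).
#' @param cluster1_fraction probability a patient's latent class is 1
#'   (default 23/32).
#' @param within_patient_mixing probability that an individual ROI's latent
#'   class differs from its patient's class (default 0.1).
#' @param survival_prob_by_class length-2 probabilities of 5-year survival
#'   for latent classes 1 and 2 (default \code{c(0.9, 0.3)}).
#' @param seed integer seed.
#' @return an object of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(n_patients = 32L,
                        rois_per_patient_range = c(3L, 14L),
                        cluster_means = NULL,
                        cluster_sd = 1,
                        cluster1_fraction = 23 / 32,
                        within_patient_mixing = 0.1,
                        survival_prob_by_class = c(0.9, 0.3),
                        seed = 1L) {
  if (n_patients < 2) stop("`n_patients` must be at least 2")
  if (rois_per_patient_range[1] < 1) stop("minimum ROIs per patient is 1")
  if (diff(rois_per_patient_range) < 0) stop("invalid ROI range")
  probs <- c(cluster1_fraction, within_patient_mixing, survival_prob_by_class)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (is.null(cluster_means)) {
    m1 <- rep(0, 18); m1[2] <- -0.5
    cluster_means <- list(m1, m1 + 4 * mean(cluster_sd))
  }
  if (length(cluster_means) != 2 || any(lengths(cluster_means) != 18))
    stop("`cluster_means` must be two length-18 vectors")
  if (any(cluster_sd <= 0)) stop("`cluster_sd` must be positive")
  structure(list(n_patients = as.integer(n_patients),
                 rois_per_patient_range = as.integer(rois_per_patient_range),
                 n_features = 18L,
                 cluster_means = cluster_means, cluster_sd = cluster_sd,
                 cluster1_fraction = cluster1_fraction,
                 within_patient_mixing = within_patient_mixing,
                 survival_prob_by_class = survival_prob_by_class,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic ROI-feature cohort with planted clusters
#'
#' Draws, per patient, a latent class (survivor-enriched class 1 with
#' probability \code{cluster1_fraction}), an ROI count, and a 5-year
#' survival label with class-dependent probability; then, per ROI, a latent
#' class (the patient's, flipped with probability
#' \code{within_patient_mixing}) and an 18-feature Gaussian vector around
#' that class mean. Fully reproducible under the spec's seed.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return data.frame with columns \code{patient_id}, \code{roi_id},
#'   \code{f01}..\code{f18}, \code{latent_class_patient},
#'   \code{latent_class_roi}, \code{survived} (0/1, constant within
#'   patient).
#' @examples
#' coh <- generate_cohort(cohort_spec(n_patients = 8, seed = 3))
#' table(coh$latent_class_roi)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  p <- spec$n_patients
  pat_class <- ifelse(stats::runif(p) < spec$cluster1_fraction, 1L, 2L)
  n_rois <- sample(seq(spec$rois_per_patient_range[1],
                       spec$rois_per_patient_range[2]), p, replace = TRUE)
  survived <- as.integer(stats::runif(p) <
                           spec$survival_prob_by_class[pat_class])
  sdv <- rep(spec$cluster_sd, length.out = 18)
  rows <- vector("list", p)
  for (i in seq_len(p)) {
    k <- n_rois[i]
    flip <- stats::runif(k) < spec$within_patient_mixing
    roi_class <- ifelse(flip, 3L - pat_class[i], pat_class[i])
    feat <- t(vapply(roi_class, function(cl)
      spec$cluster_means[[cl]] + stats::rnorm(18) * sdv, numeric(18)))
    colnames(feat) <- sprintf("f%02d", 1:18)
    rows[[i]] <- data.frame(
      patient_id = sprintf("P%02d", i),
      roi_id = sprintf("P%02d_R%02d", i, seq_len(k)),
      feat,
      latent_class_patient = pat_class[i],
      latent_class_roi = roi_class,
      survived = survived[i],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Names of the 18 ROI features
#'
#' The canonical feature order: 3 polarimetric ROI summaries followed by 5
#' Haralick texture features for each of the three parametric images. The
#' synthetic cohort generator uses the positional aliases
#' \code{f01}..\code{f18} in the same order (so \code{f01}..\code{f03} are
#' the polarimetric block and \code{f04}..\code{f18} the texture block).
#'
#' @return character vector of length 18.
#' @export
feature_names <- function() {
  c("median_intensity", "median_alignment", "abundance_ratio",
    paste(rep(c("intensity", "alignment", "abundance"), each = 5),
          rep(c("contrast", "correlation", "energy", "homogeneity",
                "entropy"), 3), sep = "_"))
}

# extract the 18-feature numeric matrix from a cohort table
cohort_feature_matrix <- function(table) {
  cand <- list(sprintf("f%02d", 1:18), feature_names())
  for (cols in cand)
    if (all(cols %in% names(table)))
      return(as.matrix(table[, cols]))
  stop("cohort table lacks the 18 feature columns (f01..f18 or named set)")
}
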