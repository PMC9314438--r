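#' Pipeline configuration
#'
#' Collects the constants of the analysis (defaults match the method's
#' stated values: R^2 threshold 0.75, 5x5 alignment window, 8 gray levels,
#' unit GLCM distance) together with the cohort to analyze, the models and
#' aggregation rules to run, and a root seed from which every stage's
#' randomness is derived.
#'
#' @param seed root integer seed.
#' @param cohort a \code{\link{cohort_spec}} (the cohort is generated), or
#'   a cohort data.frame with feature columns, \code{patient_id} and
#'   \code{survived}.
#' @param models subset of \code{c("kmeans", "fcm", "gmm")}.
#' @param methods subset of \code{c("majority_vote", "feature_average")}.
#' @param restarts restarts for the clustering fits.
#' @param threshold,window,gray_levels,glcm_distance analysis constants
#'   (used by the image-level stages; recorded in the manifest).
#' @param feature_subsets named list of feature index vectors for the
#'   odds-ratio contribution analysis; default polarimetry-only (1:3),
#'   texture-only (4:18) and both (1:18).
#' @param output_dir if not \code{NULL}, artifacts (feature CSV,
#'   assignment CSV, report JSON, manifest JSON) are written there.
#' @return an object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(seed = 1L,
                            cohort = cohort_spec(seed = seed),
                            models = c("kmeans", "fcm", "gmm"),
                            methods = c("majority_vote", "feature_average"),
                            restarts = 20L,
                            threshold = 0.75, window = 5L,
                            gray_levels = 8L, glcm_distance = 1L,
                            feature_subsets = list(polarimetry = 1:3,
                                                   texture = 4:18,
                                                   both = 1:18),
                            output_dir = NULL) {
  models <- match.arg(models, c("kmeans", "fcm", "gmm"), several.ok = TRUE)
  methods <- match.arg(methods, c("majority_vote", "feature_average"),
                       several.ok = TRUE)
  structure(list(seed = as.integer(seed), cohort = cohort, models = models,
                 methods = methods, restarts = as.integer(restarts),
                 threshold = threshold, window = window,
                 gray_levels = gray_levels, glcm_distance = glcm_distance,
                 feature_subsets = feature_subsets, output_dir = output_dir),
            class = "pipeline_config")
}

fit_model <- function(kind, x, seed, restarts) {
  switch(kind,
         kmeans = fit_kmeans(x, seed = seed, restarts = restarts),
         fcm = fit_fcm(x, seed = seed, restarts = restarts),
         gmm = fit_gmm(x, seed = seed, restarts = restarts),
         stop("unknown model: ", kind))
}

#' Run the cohort-level analysis pipeline
#'
#' Generates (or takes) an ROI-feature cohort, fits the two-step
#' normalizer, clusters the normalized ROI vectors with each requested
#' model, aggregates ROI labels to patients by each requested rule, and
#' cross-tabulates patient clusters against 5-year survival. Also refits
#' each model on the polarimetry-only, texture-only and combined feature
#' subsets (feature-average aggregation) to quantify each feature type's
#' contribution via odds ratios.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list of class \code{"pipeline_report"} with elements
#'   \code{summary} (data.frame: model, method, n, the five diagnostic
#'   metrics, Fisher p), \code{or_table} (data.frame: model, subset, OR
#'   and CI), \code{assignments}, \code{cohort}, \code{models} (the
#'   fitted cluster objects) and \code{manifest}.
#' @examples
#' \donttest{
#' rep <- run_pipeline(pipeline_config(seed = 1,
#'   cohort = cohort_spec(n_patients = 12, seed = 1),
#'   models = "kmeans"))
#' rep$summary
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "simulate"
  out <- tryCatch({
    cohort <- if (inherits(config$cohort, "cohort_spec"))
      generate_cohort(config$cohort) else config$cohort
    survival <- unique(cohort[, c("patient_id", "survived")])

    stage <- "normalize"
    xraw <- cohort_feature_matrix(cohort)
    norm <- fit_normalizer(xraw)
    x <- apply_normalizer(norm, xraw)

    stage <- "cluster"
    seeds <- config$seed + seq_along(config$models) * 1000L
    fits <- Map(function(kind, s) fit_model(kind, x, s, config$restarts),
                config$models, seeds)

    stage <- "assign"
    assignments <- list()
    for (kind in config$models) {
      if ("majority_vote" %in% config$methods)
        assignments[[paste(kind, "majority_vote", sep = ".")]] <-
          cbind(model = kind,
                assign_majority(fits[[kind]]$labels, cohort$patient_id))
      if ("feature_average" %in% config$methods)
        assignments[[paste(kind, "feature_average", sep = ".")]] <-
          cbind(model = kind,
                assign_feature_average(x, cohort$patient_id, fits[[kind]]))
    }

    stage <- "evaluate"
    evals <- lapply(assignments, evaluate_assignments, survival = survival)
    summary <- do.call(rbind, Map(function(nm, ev) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      d <- ev$diagnostics
      data.frame(model = parts[1], method = parts[2],
                 n = d$n, sensitivity = d$sensitivity,
                 specificity = d$specificity, accuracy = d$accuracy,
                 ppv = d$ppv, npv = d$npv, fisher_p = ev$fisher$p,
                 n_unassigned = ev$n_unassigned)
    }, names(evals), evals))
    rownames(summary) <- NULL

    stage <- "feature_subsets"
    or_rows <- list()
    for (kind in config$models) {
      for (sn in names(config$feature_subsets)) {
        idx <- config$feature_subsets[[sn]]
        xs <- x[, idx, drop = FALSE]
        sfit <- fit_model(kind, xs, config$seed + 77L, config$restarts)
        asn <- assign_feature_average(xs, cohort$patient_id, sfit)
        orr <- odds_ratio(contingency(asn, survival))
        or_rows[[paste(kind, sn)]] <- data.frame(
          model = kind, subset = sn, n_features = length(idx),
          or = orr$or,
          ci_lo = if (is.null(orr$ci95)) NA_real_ else orr$ci95[1],
          ci_hi = if (is.null(orr$ci95)) NA_real_ else orr$ci95[2])
      }
    }
    or_table <- do.call(rbind, or_rows)
    rownames(or_table) <- NULL

    manifest <- list(seed = config$seed, models = config$models,
                     methods = config$methods, restarts = config$restarts,
                     threshold = config$threshold, window = config$window,
                     gray_levels = config$gray_levels,
                     glcm_distance = config$glcm_distance,
                     n_rois = nrow(cohort),
                     n_patients = length(unique(cohort$patient_id)),
                     package_version =
                       as.character(utils::packageVersion("polaristroma")))
    structure(list(summary = summary, or_table = or_table,
                   assignments = do.call(rbind, assignments),
                   cohort = cohort, models = fits, normalizer = norm,
                   manifest = manifest),
              class = "pipeline_report")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(config$output_dir)) write_report(out, config$output_dir)
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Write pipeline artifacts
#'
#' Writes the cohort feature table and patient assignments as CSV and the
#' summary report and run manifest as JSON into a directory.
#'
#' @param report a \code{"pipeline_report"}.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(features = file.path(dir, "features.csv"),
             assignments = file.path(dir, "assignments.csv"),
             report = file.path(dir, "report.json"),
             manifest = file.path(dir, "manifest.json"))
  utils::write.csv(report$cohort, paths["features"], row.names = FALSE)
  utils::write.csv(report$assignments, paths["assignments"],
                   row.names = FALSE)
  jsonlite::write_json(list(summary = report$summary,
                            or_table = report$or_table),
                       paths["report"], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  jsonlite::write_json(report$manifest, paths["manifest"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
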