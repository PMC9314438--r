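#' 2x2 contingency table of patient cluster vs 5-year survival
#'
#' Cell convention (the "ideal grouping" reading, where Cluster 2 predicts
#' non-survival): \code{a} = non-survivors in Cluster 2 (true positives),
#' \code{b} = non-survivors in Cluster 1, \code{c} = survivors in Cluster
#' 2, \code{d} = survivors in Cluster 1 (true negatives).
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @return an object of class \code{"contingency2x2"}.
#' @export
contingency2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers")
  if (sum(cells) < 1) stop("empty table")
  structure(as.list(cells), n = sum(cells), class = "contingency2x2")
}

#' @export
print.contingency2x2 <- function(x, ...) {
  cat(sprintf("<2x2> non-surv: C2=%d C1=%d | surv: C2=%d C1=%d (N=%d)\n",
              x$a, x$b, x$c, x$d, attr(x, "n")))
  invisible(x)
}

#' Cross-tabulate patient assignments against survival
#'
#' Patients left unassigned by majority vote (exact ROI-label ties) are
#' excluded before counting; their number is recorded in the
#' \code{n_unassigned} attribute.
#'
#' @param assignments data.frame with \code{patient_id} and \code{cluster}
#'   (1, 2 or \code{NA}), as from \code{\link{assign_majority}} or
#'   \code{\link{assign_feature_average}}.
#' @param survival data.frame with \code{patient_id} and \code{survived}
#'   (0/1).
#' @return a \code{\link{contingency2x2}} with attribute
#'   \code{n_unassigned}.
#' @export
contingency <- function(assignments, survival) {
  if (nrow(assignments) == 0) stop("empty assignment list")
  miss <- setdiff(assignments$patient_id, survival$patient_id)
  if (length(miss)) stop("no survival label for patient ", miss[1])
  surv <- survival$survived[match(assignments$patient_id,
                                  survival$patient_id)]
  keep <- !is.na(assignments$cluster)
  cl <- assignments$cluster[keep]; sv <- surv[keep]
  out <- contingency2x2(a = sum(cl == 2 & sv == 0),
                        b = sum(cl == 1 & sv == 0),
                        c = sum(cl == 2 & sv == 1),
                        d = sum(cl == 1 & sv == 1))
  attr(out, "n_unassigned") <- sum(!keep)
  out
}

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test: the p-value sums the point probabilities of
#' all tables with the observed margins that are no more probable than the
#' observed one (the standard two-sided convention).
#'
#' @param t a \code{\link{contingency2x2}}.
#' @return list with \code{p} (two-tailed p-value in (0, 1]).
#' @export
fisher_two_tailed <- function(t) {
  stopifnot(inherits(t, "contingency2x2"))
  if ((t$a + t$b) == 0 || (t$c + t$d) == 0 ||
      (t$a + t$c) == 0 || (t$b + t$d) == 0)
    stop("a margin of the table is zero; association undefined")
  m <- matrix(c(t$a, t$b, t$c, t$d), 2, 2, byrow = TRUE)
  list(p = stats::fisher.test(m)$p.value)
}

#' Diagnostic metrics of a cluster-vs-survival table
#'
#' Treating Cluster 2 as a positive (non-survival) prediction:
#' sensitivity \code{a/(a+b)}, specificity \code{d/(c+d)}, accuracy
#' \code{(a+d)/N}, positive predictive value \code{a/(a+c)}, negative
#' predictive value \code{d/(b+d)}. Ratios with a zero denominator are
#' returned as \code{NA} and flagged in \code{undefined}.
#'
#' @param t a \code{\link{contingency2x2}}.
#' @return list with the five metrics, \code{n}, and \code{undefined}
#'   (character vector naming any undefined metrics).
#' @export
diagnostics <- function(t) {
  stopifnot(inherits(t, "contingency2x2"))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(sensitivity = ratio(t$a, t$a + t$b),
              specificity = ratio(t$d, t$c + t$d),
              accuracy = ratio(t$a + t$d, attr(t, "n")),
              ppv = ratio(t$a, t$a + t$c),
              npv = ratio(t$d, t$b + t$d),
              n = attr(t, "n"))
  out$undefined <- names(out)[vapply(out, function(v) is.na(v[1]), TRUE)]
  out
}

#' Odds ratio with Woolf (log-method) confidence interval
#'
#' \code{OR = ad/bc}; undefined (flagged, no substitute value) when
#' \code{b} or \code{c} is zero. The 95\% interval
#' \code{exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))} is reported
#' when all four cells are positive. No continuity correction is applied:
#' a zero cell yields an explicitly incalculable OR rather than a
#' corrected one.
#'
#' @param t a \code{\link{contingency2x2}}.
#' @return list with \code{or}, \code{ci95} (length-2 or \code{NULL}),
#'   \code{defined} (logical).
#' @export
odds_ratio <- function(t) {
  stopifnot(inherits(t, "contingency2x2"))
  if (t$b * t$c == 0)
    return(list(or = NA_real_, ci95 = NULL, defined = FALSE))
  or <- (t$a * t$d) / (t$b * t$c)
  ci <- NULL
  if (min(t$a, t$b, t$c, t$d) > 0) {
    se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
    ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  }
  list(or = or, ci95 = ci, defined = TRUE)
}

#' Full association report for one assignment table
#'
#' @param assignments,survival see \code{\link{contingency}}.
#' @return list with the contingency counts, diagnostic metrics, Fisher p
#'   and odds ratio.
#' @export
evaluate_assignments <- function(assignments, survival) {
  t <- contingency(assignments, survival)
  list(table = t,
       diagnostics = diagnostics(t),
       fisher = fisher_two_tailed(t),
       odds_ratio = odds_ratio(t),
       n_unassigned = attr(t, "n_unassigned"))
}

#' Reference contingency tables from a 32-patient colorectal-cancer cohort
#'
#' Cluster-vs-survival 2x2 tables for a stage III colorectal cancer
#' reference cohort of 32 patients (23 five-year survivors, 9
#' non-survivors), one table per clustering model (K-means, Fuzzy C-means,
#' Gaussian mixture) and patient-aggregation rule (majority vote excludes
#' exact-tie patients, hence its smaller n; feature averaging assigns all
#' 32). The tables are reconstructed from the cohort's reported diagnostic
#' metrics and serve as fixed inputs for the association statistics.
#'
#' @return named list of \code{\link{contingency2x2}} tables:
#'   \code{kmeans_majority}, \code{kmeans_average}, \code{fcm_majority},
#'   \code{fcm_average}, \code{gmm_majority}, \code{gmm_average}.
#' @export
crc_reference_tables <- function() {
  list(kmeans_majority = contingency2x2(3, 6, 5, 17),
       kmeans_average  = contingency2x2(7, 2, 5, 18),
       fcm_majority    = contingency2x2(7, 2, 6, 16),
       fcm_average     = contingency2x2(8, 1, 6, 17),
       gmm_majority    = contingency2x2(3, 6, 0, 21),
       gmm_average     = contingency2x2(4, 5, 2, 21))
}
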