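#' @name cluster-models
#' @title Two-cluster models over normalized ROI features
#'
#' @description
#' Three unsupervised models partition the normalized ROI feature vectors
#' into k = 2 clusters: hard K-means, Fuzzy C-means (soft memberships),
#' and a Gaussian mixture model (posterior probabilities). All three
#' return a common \code{"polar_cluster"} result with canonical labels:
#' cluster 1 is the larger cluster by ROI count (ties broken to the lower
#' centroid norm), matching the convention that the majority,
#' survivor-enriched group is "Cluster 1".
#'
#' @param x numeric matrix of normalized features, one row per ROI.
#' @param k number of clusters (fixed at 2 for this pipeline).
#' @param seed integer seed controlling initialization.
#' @param restarts number of random restarts; the best fit by the model's
#'   objective is kept.
#' @return an object of class \code{"polar_cluster"}: list with
#'   \code{kind}, \code{labels} (1/2 per row), \code{memberships}
#'   (\code{n x 2}, rows summing to 1; one-hot for K-means),
#'   \code{centers} (\code{2 x p}), \code{objective}, and fit parameters.
NULL

new_polar_cluster <- function(kind, labels, memberships, centers, objective,
                              seed, params = list()) {
  # canonical labels: cluster 1 = larger cluster; tie -> lower centroid norm
  n1 <- sum(labels == 1L); n2 <- sum(labels == 2L)
  swap <- if (n1 != n2) n2 > n1 else
    sqrt(sum(centers[2, ]^2)) < sqrt(sum(centers[1, ]^2))
  if (swap) {
    labels <- 3L - labels
    memberships <- memberships[, 2:1, drop = FALSE]
    centers <- centers[2:1, , drop = FALSE]
    if (!is.null(params$model)) params$swapped <- TRUE
  }
  structure(list(kind = kind, labels = labels, memberships = memberships,
                 centers = centers, objective = objective, seed = seed,
                 params = params),
            class = "polar_cluster")
}

#' @export
print.polar_cluster <- function(x, ...) {
  cat(sprintf("<polar_cluster:%s> n = %d, sizes = %d/%d\n", x$kind,
              length(x$labels), sum(x$labels == 1), sum(x$labels == 2)))
  invisible(x)
}

# k-means++ seeding (Arthur & Vassilvitskii)
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- colSums((t(x) - centers[1, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1L, prob = p), ]
    d2 <- pmin(d2, colSums((t(x) - centers[j, ])^2))
  }
  centers
}

#' @rdname cluster-models
#' @export
fit_kmeans <- function(x, k = 2L, seed = 1L, restarts = 20L) {
  x <- as.matrix(x)
  if (nrow(unique(x)) < k) stop("fewer distinct rows than clusters")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- kmeanspp_init(x, k)
    fit <- suppressWarnings(
      stats::kmeans(x, centers = init, iter.max = 100L, algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  labels <- as.integer(best$cluster)
  memb <- matrix(0, nrow(x), k)
  memb[cbind(seq_len(nrow(x)), labels)] <- 1
  new_polar_cluster("kmeans", labels, memb, best$centers,
                    objective = best$tot.withinss, seed = seed,
                    params = list(restarts = restarts))
}

# FCM membership of rows of `x` given centers (fuzzifier m); rows at a
# centroid get membership 1 for it (singularity rule)
fcm_membership <- function(x, centers, m = 2) {
  d2 <- vapply(seq_len(nrow(centers)),
               function(j) colSums((t(x) - centers[j, ])^2), numeric(nrow(x)))
  d2 <- matrix(d2, nrow = nrow(x))
  u <- matrix(0, nrow(x), nrow(centers))
  for (i in seq_len(nrow(x))) {
    zero <- d2[i, ] <= .Machine$double.eps
    if (any(zero)) {
      u[i, zero] <- 1 / sum(zero)
    } else {
      w <- d2[i, ]^(-1 / (m - 1))
      u[i, ] <- w / sum(w)
    }
  }
  u
}

#' @rdname cluster-models
#' @param m fuzzifier exponent for Fuzzy C-means (default 2).
#' @param max_iter iteration cap for Fuzzy C-means (default 300).
#' @export
fit_fcm <- function(x, k = 2L, m = 2, max_iter = 300L, seed = 1L,
                    restarts = 20L) {
  x <- as.matrix(x)
  if (nrow(unique(x)) < k) stop("fewer distinct rows than clusters")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- e1071::cmeans(x, centers = k, iter.max = max_iter,
                         method = "cmeans", m = m)
    if (is.null(best) || fit$withinerror < best$withinerror) best <- fit
  }
  converged <- best$iter < max_iter
  if (!converged)
    warning("Fuzzy C-means hit the iteration cap; returning the best iterate")
  memb <- fcm_membership(x, best$centers, m)
  labels <- max.col(memb, ties.method = "first")
  new_polar_cluster("fcm", labels, memb, best$centers,
                    objective = best$withinerror, seed = seed,
                    params = list(m = m, restarts = restarts,
                                  converged = converged))
}

#' @rdname cluster-models
#' @param reg covariance ridge fallback for the Gaussian mixture; when the
#'   unconstrained full-covariance fit is singular the model is refit with
#'   a data-driven regularizing prior.
#' @importFrom mclust mclustBIC
#' @export
fit_gmm <- function(x, k = 2L, reg = 1e-6, seed = 1L, restarts = 20L) {
  x <- as.matrix(x)
  if (nrow(x) <= ncol(x))
    stop("need more rows than feature dimensions for a full-covariance fit")
  set.seed(seed)
  fit <- mclust::Mclust(x, G = k, modelNames = "VVV", verbose = FALSE)
  if (is.null(fit))
    fit <- mclust::Mclust(x, G = k, modelNames = "VVV", verbose = FALSE,
                          prior = mclust::priorControl())
  if (is.null(fit)) stop("Gaussian mixture fit failed (singular covariance)")
  memb <- fit$z
  labels <- max.col(memb, ties.method = "first")
  centers <- t(fit$parameters$mean)
  new_polar_cluster("gmm", labels, memb, centers,
                    objective = fit$loglik, seed = seed,
                    params = list(model = fit, reg = reg))
}

#' Classify new feature vectors with a fitted cluster model
#'
#' Applies the fitted model's own rule: nearest centroid for K-means,
#' the membership formula for Fuzzy C-means, posterior responsibility for
#' the Gaussian mixture. Labels follow the canonicalized cluster identity
#' of the fit.
#'
#' @param object a \code{"polar_cluster"} fit.
#' @param newdata numeric matrix (or single vector) in the same normalized
#'   feature space.
#' @param ... unused.
#' @return list with \code{cluster} (integer vector) and
#'   \code{membership} (\code{n x 2} matrix).
#' @export
predict.polar_cluster <- function(object, newdata, ...) {
  x <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else
    as.matrix(newdata)
  if (ncol(x) != ncol(object$centers))
    stop("newdata has ", ncol(x), " features; model expects ",
         ncol(object$centers))
  memb <- switch(object$kind,
    kmeans = {
      d2 <- vapply(1:2, function(j) colSums((t(x) - object$centers[j, ])^2),
                   numeric(nrow(x)))
      d2 <- matrix(d2, nrow = nrow(x))
      m <- matrix(0, nrow(x), 2)
      m[cbind(seq_len(nrow(x)), max.col(-d2, ties.method = "first"))] <- 1
      m
    },
    fcm = fcm_membership(x, object$centers, object$params$m),
    gmm = {
      z <- predict(object$params$model, newdata = x)$z
      if (isTRUE(object$params$swapped)) z <- z[, 2:1, drop = FALSE]
      z
    },
    stop("unknown model kind"))
  list(cluster = max.col(memb, ties.method = "first"), membership = memb)
}

#' Patient assignment by majority vote over ROI labels
#'
#' A patient is assigned to the cluster holding a strict majority of their
#' ROI labels, however slim (51--49 counts as a majority). Patients with
#' an even ROI count split exactly 50--50 cannot be assigned and receive
#' \code{NA}.
#'
#' @param labels integer vector of ROI cluster labels (1/2).
#' @param patient_id character vector, same length, the patient of each
#'   ROI.
#' @return data.frame with \code{patient_id}, \code{method},
#'   \code{cluster} (1, 2 or \code{NA}) and \code{weight} (the winning
#'   vote fraction).
#' @export
assign_majority <- function(labels, patient_id) {
  stopifnot(length(labels) == length(patient_id))
  ids <- unique(patient_id)
  res <- lapply(ids, function(p) {
    l <- labels[patient_id == p]
    n1 <- sum(l == 1L); n2 <- sum(l == 2L)
    if (n1 == n2) data.frame(patient_id = p, method = "majority_vote",
                             cluster = NA_integer_, weight = 0.5)
    else data.frame(patient_id = p, method = "majority_vote",
                    cluster = if (n1 > n2) 1L else 2L,
                    weight = max(n1, n2) / (n1 + n2))
  })
  do.call(rbind, res)
}

#' Patient assignment by feature averaging
#'
#' Averages each patient's normalized ROI feature vectors into one
#' patient-representing vector and classifies it with the fitted model.
#' Every patient receives a cluster -- exact ROI-label ties are resolved
#' by where the averaged vector falls.
#'
#' @param x numeric matrix of normalized ROI features.
#' @param patient_id character vector, the patient of each row.
#' @param model a fitted \code{"polar_cluster"}.
#' @return data.frame with \code{patient_id}, \code{method},
#'   \code{cluster} and \code{weight} (membership of the assigned
#'   cluster).
#' @export
assign_feature_average <- function(x, patient_id, model) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(patient_id))
  ids <- unique(patient_id)
  avg <- t(vapply(ids, function(p)
    colMeans(x[patient_id == p, , drop = FALSE]), numeric(ncol(x))))
  pr <- predict(model, avg)
  data.frame(patient_id = ids, method = "feature_average",
             cluster = pr$cluster,
             weight = pr$membership[cbind(seq_along(ids), pr$cluster)])
}
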