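# two well-separated Gaussian blobs with a 60/40 (or custom) split
make_blobs <- function(n1, n2, center2 = 8, d = 2, sd = 0.5, seed = 71) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n1 * d, 0, sd), n1, d),
             matrix(rnorm(n2 * d, center2, sd), n2, d))
  list(x = x, truth = rep(c(1L, 2L), c(n1, n2)))
}

test_that("k-means separates blobs and labels the heavier mass Cluster 1", {
  b <- make_blobs(60, 40)
  fit <- fit_kmeans(b$x, seed = 1)
  expect_identical(fit$labels, b$truth)
  expect_equal(sum(fit$labels == 1), 60)
  # memberships are one-hot and consistent with labels
  expect_true(all(rowSums(fit$memberships) == 1))
  expect_identical(max.col(fit$memberships), as.integer(fit$labels))
  # duplicating every row leaves the centroids unchanged
  fit2 <- fit_kmeans(rbind(b$x, b$x), seed = 1)
  expect_equal(sort(fit2$centers[, 1]), sort(fit$centers[, 1]),
               tolerance = 1e-8)
  expect_error(fit_kmeans(matrix(1, 5, 2)), "distinct rows")
})

test_that("k-means recovers planted cohort classes perfectly at 6-SD separation", {
  m1 <- rep(0, 18); m1[2] <- -0.5
  sp <- cohort_spec(cluster_means = list(m1, m1 + 6), seed = 42)
  coh <- generate_cohort(sp)
  xr <- cohort_feature_matrix(coh)
  x <- apply_normalizer(fit_normalizer(xr), xr)
  fit <- fit_kmeans(x, seed = 42)
  expect_equal(mclust::adjustedRandIndex(fit$labels, coh$latent_class_roi), 1)
})

test_that("fuzzy C-means memberships obey the update equations and singularity rule", {
  b <- make_blobs(60, 40)
  fit <- fit_fcm(b$x, seed = 2)
  expect_equal(rowSums(fit$memberships), rep(1, 100), tolerance = 1e-9)
  expect_identical(max.col(fit$memberships), as.integer(fit$labels))
  # hard labels agree with k-means on well-separated blobs
  km <- fit_kmeans(b$x, seed = 2)
  expect_identical(fit$labels, km$labels)
  # memberships match the closed-form membership equation at the centroids
  for (i in c(1, 50, 100))
    expect_equal(fit$memberships[i, ],
                 oracle_fcm_membership(b$x[i, ], fit$centers),
                 tolerance = 1e-6)
  # a point equidistant from both centroids splits 50/50
  mid <- colMeans(fit$centers)
  pr <- predict(fit, mid)
  expect_equal(pr$membership[1, ], c(0.5, 0.5), tolerance = 1e-9)
  # a point exactly at a centroid belongs to it fully
  pr1 <- predict(fit, fit$centers[2, ])
  expect_equal(unname(pr1$membership[1, 2]), 1)
  expect_equal(pr1$cluster, 2L)
})

test_that("the Gaussian mixture recovers planted parameters and posteriors", {
  b <- make_blobs(120, 80, center2 = 3, sd = 0.5, seed = 73)  # 6-SD separation
  fit <- fit_gmm(b$x, seed = 3)
  expect_identical(fit$labels, b$truth)
  # posterior rows are probabilities
  expect_equal(rowSums(fit$memberships), rep(1, 200), tolerance = 1e-9)
  expect_true(all(fit$memberships >= 0 & fit$memberships <= 1))
  # component means within 0.2 of the planted means (cluster 1 = heavier blob)
  expect_lt(max(abs(fit$centers[1, ] - 0)), 0.2)
  expect_lt(max(abs(fit$centers[2, ] - 3)), 0.2)
  expect_error(fit_gmm(matrix(rnorm(10), 5, 2) [1:2, ]), "more rows")
})

test_that("cluster 1 is always the larger cluster across models", {
  b <- make_blobs(30, 70, seed = 74)  # heavier blob second
  for (fit in list(fit_kmeans(b$x, seed = 4), fit_fcm(b$x, seed = 4),
                   fit_gmm(b$x, seed = 4))) {
    expect_gte(sum(fit$labels == 1), sum(fit$labels == 2))
    expect_equal(sum(fit$labels == 1), 70)
  }
})

test_that("majority vote assigns strict majorities and leaves exact ties open", {
  a <- assign_majority(c(1L, 1L, 2L), rep("P1", 3))
  expect_equal(a$cluster, 1L)
  expect_equal(a$weight, 2 / 3)
  a2 <- assign_majority(c(1L, 2L), rep("P2", 2))
  expect_true(is.na(a2$cluster))
  a3 <- assign_majority(rep(2L, 7), rep("P3", 7))
  expect_equal(a3$cluster, 2L)
  expect_equal(a3$weight, 1)
})

test_that("feature averaging assigns every patient, resolving ties by geometry", {
  b <- make_blobs(60, 40)
  fit <- fit_kmeans(b$x, seed = 5)
  # single-ROI and identical-ROI patients keep their ROI label
  one <- assign_feature_average(b$x[100, , drop = FALSE], "P1", fit)
  expect_equal(one$cluster, fit$labels[100])
  same <- assign_feature_average(b$x[c(3, 3, 3), ], rep("P2", 3), fit)
  expect_equal(same$cluster, fit$labels[3])
  # a 6-6 tied patient goes to the cluster its averaged vector is nearer to
  near1 <- sweep(matrix(rnorm(12, 0, 0.01), 6, 2), 2, fit$centers[1, ], "+")
  near2 <- sweep(matrix(rnorm(12, 0, 0.01), 6, 2), 2, fit$centers[2, ], "+")
  tied <- rbind(near1, near2 * 3)  # pull the average toward cluster 2's side
  labs <- predict(fit, tied)$cluster
  expect_equal(sum(labs == 1), 6)  # confirmed exact tie
  avg_assign <- assign_feature_average(tied, rep("P9", 12), fit)
  expect_false(is.na(avg_assign$cluster))
  want <- which.min(colSums((t(fit$centers) - colMeans(tied))^2))
  expect_equal(avg_assign$cluster, as.integer(want))
})

test_that("cluster fits are reproducible under a fixed seed", {
  coh <- generate_cohort(cohort_spec(n_patients = 10, seed = 6))
  xr <- cohort_feature_matrix(coh)
  x <- apply_normalizer(fit_normalizer(xr), xr)
  for (f in list(fit_kmeans, fit_fcm, fit_gmm)) {
    r1 <- f(x, seed = 99)
    r2 <- f(x, seed = 99)
    expect_identical(r1$labels, r2$labels)
    expect_equal(r1$centers, r2$centers, tolerance = 1e-12)
  }
})
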