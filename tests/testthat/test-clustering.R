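test_that("standardisation centres and scales with the population convention", {
  z <- standardize(cbind(x = c(1, 2, 3)))
  expect_equal(unname(z$data[, 1]), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(unname(z$params$sd["x"]), sqrt(2 / 3))
  # idempotence: re-standardising standardised data changes nothing
  z2 <- standardize(z$data)
  expect_equal(z2$data, z$data, tolerance = 1e-10)
  expect_error(standardize(cbind(ok = 1:3, flat = rep(2, 3))), "flat")
  # stored params are invertible
  x <- matrix(stats::rnorm(40), 10, 4, dimnames = list(NULL, letters[1:4]))
  z3 <- standardize(x)
  back <- sweep(sweep(z3$data, 2, z3$params$sd, "*"), 2, z3$params$mean, "+")
  expect_equal(back, x, tolerance = 1e-12)
})

test_that("PCA explains variance correctly and picks k by cumulative target", {
  # rank-1 case: perfectly correlated features -> one component, 100%
  x <- cbind(a = 1:20, b = 2 * (1:20))
  fit <- fit_pca(standardize(x)$data, var_target = 0.9)
  expect_equal(fit$model$k, 1L)
  expect_equal(fit$model$explained[1], 1, tolerance = 1e-12)
  # full-rank ratios sum to one
  set.seed(9)
  y <- matrix(stats::rnorm(300), 50, 6)
  full <- fit_pca(y, n_components = 6)
  expect_equal(sum(full$model$explained), 1, tolerance = 1e-12)
  # oracle: score variances match eigenvalues of the sample covariance
  eig <- eigen(stats::cov(y), symmetric = TRUE)$values
  score_var <- apply(full$scores, 2, stats::var)
  expect_equal(unname(score_var), eig, tolerance = 1e-9)
  expect_error(fit_pca(y, var_target = 1.5), "var_target")
})

test_that("PCA scores are invariant (up to sign fixed by convention) to feature order", {
  set.seed(4)
  x <- matrix(stats::rnorm(200), 40, 5, dimnames = list(NULL, letters[1:5]))
  f1 <- fit_pca(x, n_components = 3)
  f2 <- fit_pca(x[, c(3, 1, 5, 2, 4)], n_components = 3)
  expect_equal(abs(f1$scores), abs(f2$scores), tolerance = 1e-9)
})

test_that("k-means recovers separable blobs and satisfies boundary cases", {
  blobs <- make_blobs(30, rbind(c(0, 0), c(10, 10)), seed = 2)
  fit <- kmeans_cluster(blobs$x, 2, seed = 1)
  # partition matches the planting up to label permutation
  tab <- table(fit$labels, blobs$labels)
  expect_equal(sort(as.vector(tab)), c(0, 0, 30, 30))
  expect_true(all(tabulate(fit$labels, 2) > 0))
  # k = n puts every point in its own cluster with zero inertia
  x <- matrix(stats::rnorm(10), 5, 2)
  expect_equal(kmeans_cluster(x, 5, seed = 1)$inertia, 0, tolerance = 1e-12)
  expect_error(kmeans_cluster(x, 6, seed = 1), "exceeds")
  # fixed seed reproduces labels after row permutation (up to relabelling)
  set.seed(7); perm <- sample(60)
  fit2 <- kmeans_cluster(blobs$x[perm, ], 2, seed = 1)
  agree <- table(fit$labels[perm], fit2$labels)
  expect_equal(sum(apply(agree, 1, max)), 60)
})

test_that("DBSCAN finds dense blobs, marks outliers, and matches the oracle", {
  blobs <- make_blobs(25, rbind(c(0, 0), c(8, 8)), sd = 0.3, seed = 5)
  x <- rbind(blobs$x, c(50, 50), c(-40, 20), c(30, -30))
  labels <- dbscan_cluster(x, eps = 1.5, min_samples = 4)
  expect_equal(length(setdiff(unique(labels), 0L)), 2L)
  expect_equal(sum(labels == 0L), 3L)          # the three far outliers
  expect_equal(labels, oracle_dbscan(x, 1.5, 4))
  # eps covering everything -> one cluster, no noise
  all_one <- dbscan_cluster(x, eps = 1e6, min_samples = 4)
  expect_equal(unique(all_one), 1L)
  expect_error(dbscan_cluster(x, eps = 0, min_samples = 4), "eps")
  expect_error(dbscan_cluster(x, eps = 1, min_samples = 0), "min_samples")
})

test_that("DBSCAN equals brute-force region growing on random instances", {
  for (seed in 1:25) {
    set.seed(seed)
    x <- matrix(stats::runif(2 * sample(20:60, 1), 0, 4), ncol = 2)
    eps <- stats::runif(1, 0.3, 1.2)
    ms <- sample(2:6, 1)
    expect_equal(dbscan_cluster(x, eps, ms), oracle_dbscan(x, eps, ms),
                 info = paste("seed", seed))
  }
})

test_that("silhouette behaves at its limits and matches the brute-force oracle", {
  tight <- rbind(matrix(stats::rnorm(40, sd = 1e-4), 20, 2),
                 matrix(stats::rnorm(40, sd = 1e-4) + 1e5, 20, 2))
  lab <- rep(1:2, each = 20)
  expect_equal(silhouette_score(tight, lab), 1, tolerance = 1e-6)
  expect_error(silhouette_score(tight, rep(1, 40)), "2 non-noise")
  # singleton convention: a lone point scores 0
  x <- rbind(c(0, 0), c(0.1, 0), c(5, 5))
  s <- silhouette_score(x, c(1, 1, 2))
  expect_equal(s, oracle_silhouette(x, c(1, 1, 2)))
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(20:80, 1)
    x <- matrix(stats::rnorm(2 * n), ncol = 2)
    lab <- sample(1:4, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(silhouette_score(x, lab), oracle_silhouette(x, lab),
                 tolerance = 1e-9, info = paste("seed", seed))
  }
})

test_that("silhouette agrees with the cluster package on a reference case", {
  skip_if_not_installed("cluster")
  set.seed(12)
  x <- matrix(stats::rnorm(120), 60, 2)
  lab <- sample(1:3, 60, replace = TRUE)
  ours <- silhouette_score(x, lab)
  ref <- mean(cluster::silhouette(lab, stats::dist(x))[, "sil_width"])
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("noise points are excluded from the silhouette mean", {
  x <- rbind(matrix(stats::rnorm(20, sd = 0.1), 10, 2),
             matrix(stats::rnorm(20, sd = 0.1) + 10, 10, 2),
             c(500, -500))
  lab <- c(rep(1, 10), rep(2, 10), 0)
  expect_equal(silhouette_score(x, lab),
               silhouette_score(x[1:20, ], lab[1:20]), tolerance = 1e-12)
})

test_that("model selection returns the silhouette argmax with a full leaderboard", {
  blobs <- make_blobs(40, rbind(c(0, 0), c(8, 0), c(4, 7)), sd = 0.4, seed = 8)
  model <- select_model(blobs$x, kmeans_k = 2:6, dbscan_grid = NULL, seed = 1)
  expect_equal(model$n_clusters, 3L)
  expect_true(all(model$leaderboard$silhouette <= model$silhouette + 1e-12,
                  na.rm = TRUE))
  # single-candidate space returns that candidate
  only3 <- select_model(blobs$x, kmeans_k = 3, dbscan_grid = NULL, seed = 1)
  expect_equal(only3$params$k, 3)
  expect_error(select_model(blobs$x, kmeans_k = integer(0), dbscan_grid = NULL),
               "empty")
  # mixed space: DBSCAN candidates are scored too
  grid <- data.frame(eps = c(1, 2), min_samples = c(4, 4))
  mixed <- select_model(blobs$x, kmeans_k = 2:4, dbscan_grid = grid, seed = 1)
  expect_equal(nrow(mixed$leaderboard), 5L)
  expect_true(all(c("kmeans", "dbscan") %in% mixed$leaderboard$algorithm))
})

test_that("nearest-centroid assignment is consistent, tie-broken low, and refuses DBSCAN", {
  blobs <- make_blobs(25, rbind(c(0, 0), c(6, 0), c(3, 5)), sd = 0.3, seed = 6)
  model <- select_model(blobs$x, kmeans_k = 3, dbscan_grid = NULL, seed = 1)
  # training points map to their own labels
  expect_equal(assign_cluster(model, blobs$x), model$labels)
  # exact tie goes to the lowest label; perturbation resolves it
  hand <- list(centroids = rbind(c(0, 0), c(2, 0), c(10, 10)))
  expect_equal(assign_cluster(hand, rbind(c(1, 0))), 1L)
  expect_equal(assign_cluster(hand, rbind(c(1.2, 0))), 2L)
  expect_equal(assign_cluster(hand, rbind(c(9, 9))), 3L)
  dmodel <- list(centroids = NULL, algorithm = "dbscan")
  expect_error(assign_cluster(dmodel, rbind(c(1, 0))), "centroid")
})
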