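#' Z-score standardisation
#'
#' Centres every column to mean 0 and scales to standard deviation 1.
#' The population convention (denominator `n`) is the default so that the
#' transform is exactly invertible and reproducible; the sample convention
#' (`n - 1`) is available via `method`.
#'
#' @param x Numeric matrix or data frame (no missing values).
#' @param method `"population"` (default) or `"sample"` sd denominator.
#' @return List with `data` (the z-scored matrix) and `params` (list of
#'   per-column `mean` and `sd`).
#' @export
standardize <- function(x, method = c("population", "sample")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (anyNA(x)) stop("standardize: input contains missing values")
  n <- nrow(x)
  mu <- colMeans(x)
  centred <- sweep(x, 2L, mu, "-")
  ss <- colSums(centred^2)
  sd <- sqrt(ss / if (method == "population") n else n - 1L)
  zero <- which(sd == 0)
  if (length(zero) > 0L) {
    nm <- colnames(x)[zero]
    if (is.null(nm)) nm <- as.character(zero)
    stop("zero-variance column(s): ", paste(nm, collapse = ", "))
  }
  z <- sweep(centred, 2L, sd, "/")
  list(data = z,
       params = list(mean = mu, sd = sd, method = method))
}

#' Apply stored standardisation parameters to new data
#' @param params `params` element from [standardize()].
#' @param x New numeric matrix with the same columns.
#' @return Z-scored matrix.
#' @export
apply_standardization <- function(params, x) {
  x <- as.matrix(x)
  if (!is.null(names(params$mean)) && !is.null(colnames(x))) {
    missing_cols <- setdiff(names(params$mean), colnames(x))
    if (length(missing_cols) > 0L) {
      stop("new data lacks columns: ", paste(missing_cols, collapse = ", "))
    }
    x <- x[, names(params$mean), drop = FALSE]
  }
  sweep(sweep(x, 2L, params$mean, "-"), 2L, params$sd, "/")
}

#' Principal component analysis with variance-target selection
#'
#' Fits PCA on a (standardised) table via [stats::prcomp()]. The number of
#' retained components is either fixed (`n_components`) or, by default, the
#' smallest number whose cumulative explained-variance ratio reaches
#' `var_target`. Component signs are fixed deterministically: the
#' largest-magnitude loading of every component is made positive.
#'
#' @param z Numeric matrix (rows = patients), typically z-scored.
#' @param n_components Optional fixed number of components.
#' @param var_target Cumulative explained-variance target in (0, 1];
#'   default 0.62.
#' @return List with `model` (list: `rotation` — loadings for the retained
#'   components, `explained` — *all* explained-variance ratios, `k`) and
#'   `scores` (n x k matrix of projections).
#' @export
fit_pca <- function(z, n_components = NULL, var_target = 0.62) {
  z <- as.matrix(z)
  if (nrow(z) < 2L) stop("fit_pca needs at least 2 rows")
  if (anyNA(z)) stop("fit_pca: input contains missing values")
  if (is.null(n_components) &&
      (!is.numeric(var_target) || var_target <= 0 || var_target > 1)) {
    stop("var_target must be in (0, 1]")
  }
  fit <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  vars <- fit$sdev^2
  explained <- vars / sum(vars)
  k <- if (!is.null(n_components)) {
    min(as.integer(n_components), length(explained))
  } else {
    which(cumsum(explained) >= var_target - 1e-12)[1L]
  }
  rotation <- fit$rotation[, seq_len(k), drop = FALSE]
  scores <- fit$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rotation[, j]))
    if (rotation[i, j] < 0) {
      rotation[, j] <- -rotation[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(model = list(rotation = rotation, explained = explained, k = k,
                    center = fit$center),
       scores = scores)
}

#' Project new (standardised) rows onto a fitted PCA basis
#' @param model `model` element from [fit_pca()].
#' @param z New z-scored matrix with matching columns.
#' @return Score matrix (n x k).
#' @export
project_pca <- function(model, z) {
  z <- as.matrix(z)
  sweep(z, 2L, model$center, "-") %*% model$rotation
}

# k-means++ seeding: spread initial centres with probability proportional
# to squared distance from the nearest centre already chosen.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  first <- sample.int(n, 1L)
  centers[1L, ] <- x[first, ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ], "-")^2)
  if (k > 1L) {
    for (j in 2:k) {
      if (all(d2 == 0)) {
        idx <- sample.int(n, 1L)
      } else {
        idx <- sample.int(n, 1L, prob = d2)
      }
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ], "-")^2))
    }
  }
  centers
}

#' K-means clustering with k-means++ restarts
#'
#' Runs Lloyd's algorithm ([stats::kmeans()]) from `n_init` k-means++
#' seedings and keeps the restart with the lowest inertia (total
#' within-cluster sum of squares). Deterministic given `seed`.
#'
#' @param x Numeric matrix of points (e.g. PCA scores).
#' @param k Number of clusters, `2 <= k <= nrow(x)`.
#' @param seed Integer seed controlling all restarts. Default 42.
#' @param n_init Number of restarts. Default 10.
#' @param max_iter Lloyd iteration cap per restart. Default 300.
#' @return List with `labels` (integers 1..k, every cluster nonempty),
#'   `centroids` (k x d), `inertia`, `k`, `seed`.
#' @export
kmeans_cluster <- function(x, k, seed = 42L, n_init = 10L, max_iter = 300L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k (", k, ") exceeds number of points (", n, ")")
  if (k < 1L) stop("k must be >= 1")
  best <- NULL
  for (i in seq_len(n_init)) {
    set.seed(seed + i - 1L)
    centers <- kmeanspp_centers(x, k)
    fit <- suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = max_iter,
                    algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  list(labels = as.integer(best$cluster),
       centroids = unname(best$centers),
       inertia = best$tot.withinss, k = as.integer(k), seed = as.integer(seed))
}

#' DBSCAN density clustering
#'
#' Core points have at least `min_samples` neighbours within `eps`
#' (themselves included). Clusters are the connected components of the
#' core-point graph; a non-core point within `eps` of a core point joins the
#' cluster of its nearest such core (ties to the lower label), which makes
#' the labelling deterministic. Remaining points are noise (label 0).
#'
#' @param x Numeric matrix of points.
#' @param eps Neighbourhood radius, > 0.
#' @param min_samples Density threshold, >= 1.
#' @return Integer vector of labels: 1..k for clusters, 0 for noise.
#' @export
dbscan_cluster <- function(x, eps, min_samples) {
  if (eps <= 0) stop("eps must be > 0")
  if (min_samples < 1) stop("min_samples must be >= 1")
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  nb <- d <= eps
  core <- rowSums(nb) >= min_samples
  labels <- integer(n)
  # connected components over core points via union-find
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  core_idx <- which(core)
  for (i in core_idx) {
    for (j in core_idx[nb[i, core_idx]]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  if (length(core_idx) > 0L) {
    roots <- vapply(core_idx, find, 1L)
    comp <- match(roots, unique(roots))  # label in order of first appearance
    labels[core_idx] <- comp
    border <- which(!core)
    if (length(border) > 0L) {
      for (i in border) {
        cand <- core_idx[nb[i, core_idx]]
        if (length(cand) > 0L) {
          di <- d[i, cand]
          best <- cand[di == min(di)]
          labels[i] <- min(labels[best])
        }
      }
    }
  }
  labels
}

#' Mean silhouette coefficient
#'
#' For each point, `a` is its mean distance to the other members of its own
#' cluster and `b` the smallest mean distance to any other cluster; the
#' silhouette is `(b - a) / max(a, b)`, with singleton clusters scored 0.
#' The returned value is the mean over all scored points. Points labelled 0
#' (DBSCAN noise) are excluded from both the means and the neighbourhoods.
#' Distances are Euclidean on `x` unless a precomputed `dist` is given.
#'
#' @param x Numeric matrix of points, or a `dist`/square distance matrix.
#' @param labels Integer cluster labels (0 = noise, excluded).
#' @param max_n Above this many scored points a seeded subsample of `max_n`
#'   is used (the exact computation is O(n^2)). Default 20000.
#' @param seed Seed for the subsample draw. Default 1.
#' @return Mean silhouette in \[-1, 1\].
#' @export
silhouette_score <- function(x, labels, max_n = 20000L, seed = 1L) {
  labels <- as.integer(labels)
  keep <- which(labels != 0L)
  if (length(unique(labels[keep])) < 2L) {
    stop("silhouette needs at least 2 non-noise clusters")
  }
  d_full <- if (inherits(x, "dist")) as.matrix(x)
            else if (is.matrix(x) && nrow(x) == ncol(x) && isSymmetric(unname(x)) &&
                     length(labels) == nrow(x) && all(diag(x) == 0)) x
            else as.matrix(stats::dist(as.matrix(x)))
  if (length(keep) > max_n) {
    set.seed(seed)
    keep <- sort(sample(keep, max_n))
    if (length(unique(labels[keep])) < 2L) {
      stop("silhouette subsample degenerated to a single cluster")
    }
  }
  d <- d_full[keep, keep, drop = FALSE]
  lab <- labels[keep]
  cl <- sort(unique(lab))
  m <- outer(lab, cl, "==") * 1           # n x k membership
  counts <- colSums(m)
  sums <- d %*% m                          # total distance to each cluster
  own <- match(lab, cl)
  n <- length(lab)
  a <- sums[cbind(seq_len(n), own)] / pmax(counts[own] - 1L, 1L)
  mean_to <- sweep(sums, 2L, counts, "/")
  mean_to[cbind(seq_len(n), own)] <- Inf
  b <- apply(mean_to, 1L, min)
  s <- (b - a) / pmax(a, b)
  s[counts[own] == 1L] <- 0                # singleton convention
  mean(s)
}

#' Fit clustering candidates and pick the best by silhouette
#'
#' Fits K-means for every `k` in `kmeans_k` and DBSCAN for every row of
#' `dbscan_grid`, scores each candidate by mean silhouette (noise excluded),
#' and returns the argmax. Ties are broken towards fewer clusters, then
#' K-means over DBSCAN, then the lower `k`/`eps`. Candidates that collapse
#' to fewer than two clusters are unscored.
#'
#' @param scores Numeric matrix of points (typically PCA scores).
#' @param kmeans_k Integer vector of K-means cluster counts. Default 2:10.
#' @param dbscan_grid Data frame with columns `eps` and `min_samples`, or
#'   `NULL` to skip DBSCAN. Default grid: eps in {0.3, 0.5, 0.8, 1.2, 2.0}
#'   crossed with min_samples in {5, 10, 20}.
#' @param seed Seed passed to [kmeans_cluster()]. Default 42.
#' @param silhouette_max_n Passed to [silhouette_score()].
#' @return A `cluster_model`: list with `algorithm`, `params`, `labels`,
#'   `centroids` (K-means only), `silhouette`, `n_clusters`, `seed`, and
#'   `leaderboard` (one row per candidate).
#' @export
select_model <- function(scores,
                         kmeans_k = 2:10,
                         dbscan_grid = default_dbscan_grid(),
                         seed = 42L,
                         silhouette_max_n = 20000L) {
  scores <- as.matrix(scores)
  if (length(kmeans_k) == 0L && (is.null(dbscan_grid) || nrow(dbscan_grid) == 0L)) {
    stop("empty candidate search space")
  }
  d <- stats::dist(scores)
  dm <- as.matrix(d)
  rows <- list()
  candidates <- list()
  score_candidate <- function(labels) {
    keep <- labels != 0L
    k_eff <- length(unique(labels[keep]))
    if (k_eff < 2L) return(list(sil = NA_real_, k_eff = k_eff))
    list(sil = silhouette_score(dm, labels, max_n = silhouette_max_n),
         k_eff = k_eff)
  }
  for (k in kmeans_k) {
    fit <- kmeans_cluster(scores, k, seed = seed)
    sc <- score_candidate(fit$labels)
    id <- length(candidates) + 1L
    candidates[[id]] <- list(algorithm = "kmeans", params = list(k = k),
                             labels = fit$labels, centroids = fit$centroids,
                             inertia = fit$inertia)
    rows[[id]] <- data.frame(algorithm = "kmeans", k = k, eps = NA_real_,
                             min_samples = NA_integer_,
                             n_clusters = sc$k_eff, n_noise = 0L,
                             silhouette = sc$sil, stringsAsFactors = FALSE)
  }
  if (!is.null(dbscan_grid) && nrow(dbscan_grid) > 0L) {
    for (i in seq_len(nrow(dbscan_grid))) {
      eps <- dbscan_grid$eps[i]
      ms <- dbscan_grid$min_samples[i]
      labels <- dbscan_cluster(scores, eps, ms)
      sc <- score_candidate(labels)
      id <- length(candidates) + 1L
      candidates[[id]] <- list(algorithm = "dbscan",
                               params = list(eps = eps, min_samples = ms),
                               labels = labels, centroids = NULL,
                               inertia = NA_real_)
      rows[[id]] <- data.frame(algorithm = "dbscan", k = NA_integer_, eps = eps,
                               min_samples = as.integer(ms),
                               n_clusters = sc$k_eff,
                               n_noise = sum(labels == 0L),
                               silhouette = sc$sil, stringsAsFactors = FALSE)
    }
  }
  leaderboard <- do.call(rbind, rows)
  scored <- which(!is.na(leaderboard$silhouette))
  if (length(scored) == 0L) {
    stop("all clustering candidates were degenerate (fewer than 2 clusters)")
  }
  lb <- leaderboard[scored, , drop = FALSE]
  ord <- order(-lb$silhouette, lb$n_clusters,
               lb$algorithm != "kmeans",
               ifelse(is.na(lb$k), lb$eps, lb$k))
  best_id <- scored[ord[1L]]
  best <- candidates[[best_id]]
  structure(list(algorithm = best$algorithm,
                 params = best$params,
                 labels = best$labels,
                 centroids = best$centroids,
                 silhouette = leaderboard$silhouette[best_id],
                 n_clusters = leaderboard$n_clusters[best_id],
                 seed = as.integer(seed),
                 leaderboard = leaderboard),
            class = "cluster_model")
}

#' @rdname select_model
#' @export
default_dbscan_grid <- function() {
  expand.grid(eps = c(0.3, 0.5, 0.8, 1.2, 2.0),
              min_samples = c(5L, 10L, 20L))
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("Clustering model (", x$algorithm, ")\n", sep = "")
  cat("  clusters:  ", x$n_clusters, "\n", sep = "")
  cat("  silhouette:", format(x$silhouette, digits = 4), "\n")
  if (!is.null(x$params$k)) cat("  k:         ", x$params$k, "\n", sep = "")
  if (!is.null(x$params$eps)) {
    cat("  eps:       ", x$params$eps, "  min_samples: ",
        x$params$min_samples, "\n", sep = "")
  }
  invisible(x)
}

#' Assign new points to the nearest K-means centroid
#'
#' @param model A `cluster_model` with centroids (K-means), or any list with
#'   a `centroids` matrix.
#' @param x Numeric matrix of new points in the same space as the centroids
#'   (i.e. already standardised and PCA-projected).
#' @return Integer labels; ties go to the lowest label.
#' @export
assign_cluster <- function(model, x) {
  if (is.null(model$centroids)) {
    stop("assign_cluster requires centroids (a K-means model); ",
         "density models do not support assignment")
  }
  x <- matrix(as.numeric(x), ncol = ncol(model$centroids))
  cen <- model$centroids
  # squared distances, n x k
  d2 <- outer(rowSums(x^2), rep(1, nrow(cen))) -
    2 * x %*% t(cen) + outer(rep(1, nrow(x)), rowSums(cen^2))
  apply(d2, 1L, which.min)  # which.min takes the first (lowest) on ties
}
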