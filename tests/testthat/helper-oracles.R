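# Independent brute-force oracles, deliberately written as plain loops over
# the definitions so they share no code path with the package implementations.

oracle_cosine <- function(u, v) {
  num <- 0; su <- 0; sv <- 0
  for (i in seq_along(u)) {
    num <- num + u[i] * v[i]
    su <- su + u[i]^2
    sv <- sv + v[i]^2
  }
  if (su == 0 || sv == 0) return(0)
  num / (sqrt(su) * sqrt(sv))
}

# silhouette by direct per-point loops; noise label 0 excluded; singletons 0
oracle_silhouette <- function(x, labels) {
  d <- as.matrix(stats::dist(x))
  idx <- which(labels != 0)
  s <- numeric(0)
  for (i in idx) {
    own <- setdiff(idx[labels[idx] == labels[i]], i)
    if (length(own) == 0) { s <- c(s, 0); next }
    a <- mean(d[i, own])
    b <- Inf
    for (cl in setdiff(unique(labels[idx]), labels[i])) {
      members <- idx[labels[idx] == cl]
      b <- min(b, mean(d[i, members]))
    }
    s <- c(s, (b - a) / max(a, b))
  }
  mean(s)
}

# classic queue-based DBSCAN region growing; border points are attached to
# the cluster of their nearest core point (ties -> lower label), matching
# the deterministic rule the package documents
oracle_dbscan <- function(x, eps, min_samples) {
  d <- as.matrix(stats::dist(x))
  n <- nrow(d)
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, 1L) >= min_samples
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue) > 0) {
      p <- queue[1]; queue <- queue[-1]
      for (q in nb[[p]]) {
        if (core[q] && labels[q] == 0L) {
          labels[q] <- cl
          queue <- c(queue, q)
        }
      }
    }
  }
  for (i in which(!core)) {
    cores_near <- which(core & d[i, ] <= eps)
    if (length(cores_near) > 0) {
      nearest <- cores_near[d[i, cores_near] == min(d[i, cores_near])]
      labels[i] <- min(labels[nearest])
    }
  }
  labels
}

# planted gaussian blobs for clustering tests
make_blobs <- function(n_per, centers, sd = 0.5, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  x <- do.call(rbind, lapply(seq_len(k), function(g) {
    matrix(stats::rnorm(n_per * ncol(centers), sd = sd),
           n_per, ncol(centers)) + matrix(centers[g, ], n_per,
                                          ncol(centers), byrow = TRUE)
  }))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

# random small rating matrix with clusters, for property tests
random_rating_matrix <- function(n = 12, d = 5, g = 3, seed = 1) {
  set.seed(seed)
  ratings <- matrix(sample(0:2, n * d, replace = TRUE, prob = c(0.5, 0.25, 0.25)),
                    n, d, dimnames = list(sprintf("p%02d", 1:n),
                                          paste0("drug", 1:d)))
  rating_matrix(ratings, cluster = sample(1:g, n, replace = TRUE))
}

fixture_path <- function() {
  p <- system.file("extdata", "preproc_fixture.csv", package = "drugrec")
  if (nzchar(p)) p else test_path("..", "..", "inst", "extdata", "preproc_fixture.csv")
}
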