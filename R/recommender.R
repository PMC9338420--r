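#' Patient-by-drug rating matrix
#'
#' Container for the collaborative-filtering matrix: encoded dose values
#' (0 = drug not administered, 1 = decreased/steady, 2 = increased under the
#' default encoding) with one row per patient and the patient's cluster
#' label alongside.
#'
#' @param ratings Numeric matrix, rownames = patient ids, colnames = drugs.
#' @param cluster Integer cluster label per patient.
#' @return An object of class `rating_matrix`.
#' @export
rating_matrix <- function(ratings, cluster) {
  ratings <- as.matrix(ratings)
  if (is.null(rownames(ratings))) {
    stop("ratings must carry patient ids as rownames")
  }
  if (length(cluster) != nrow(ratings)) {
    stop("cluster labels (", length(cluster),
         ") do not cover all patients (", nrow(ratings), ")")
  }
  if (anyNA(cluster)) stop("every patient needs a cluster label")
  structure(list(ratings = ratings, cluster = as.integer(cluster)),
            class = "rating_matrix")
}

#' @export
print.rating_matrix <- function(x, ...) {
  cat("Rating matrix: ", nrow(x$ratings), " patients x ",
      ncol(x$ratings), " drugs, ",
      length(unique(x$cluster)), " clusters\n", sep = "")
  invisible(x)
}

#' Build the rating matrix from a preprocessed feature table
#'
#' Takes the drug-dose columns of [build_feature_table()] output and attaches
#' per-patient cluster labels.
#'
#' @param table Feature table from [build_feature_table()].
#' @param labels Integer cluster labels, one per row of `table`.
#' @return A [rating_matrix].
#' @export
build_rating_matrix <- function(table, labels) {
  fm <- feature_matrix(table)
  rating_matrix(fm$ratings, labels)
}

#' Cosine similarity between rating vectors
#'
#' `dot(u, v) / (||u|| ||v||)`; if either vector is all zero the similarity
#' is defined to be 0 (no shared prescriptions, no evidence of similarity).
#' For nonnegative ratings the value lies in \[0, 1\].
#'
#' @param u,v Numeric vectors of equal length.
#' @return A single number.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

# Ranking priority of prediction provenance: direct evidence outranks
# fallback guesses when scores tie.
provenance_rank <- function(p) {
  match(p, c("observed", "neighbors", "cluster_mean", "global_mean", "none"))
}

# All pairwise cosine similarities between the rows of two matrices,
# with all-zero rows mapped to similarity 0.
cosine_matrix <- function(a, b) {
  na <- sqrt(rowSums(a^2))
  nb <- sqrt(rowSums(b^2))
  s <- tcrossprod(a, b)
  denom <- outer(na, nb)
  s <- ifelse(denom == 0, 0, s / ifelse(denom == 0, 1, denom))
  s
}

#' Predict a dose value by cluster-restricted collaborative filtering
#'
#' The prediction for patient `u` and a drug is the similarity-weighted mean
#' of the observed (nonzero) ratings of that drug among the *other* patients
#' in `u`'s cluster with positive cosine similarity to `u`. When no such
#' neighbour exists the prediction falls back to the mean nonzero rating of
#' the drug within the cluster, then to the global mean nonzero rating of
#' the drug; the `provenance` field records which branch fired
#' (`"neighbors"`, `"cluster_mean"`, `"global_mean"`, or `"none"` when the
#' drug has no nonzero rating anywhere).
#'
#' @param matrix A [rating_matrix] (the training data).
#' @param patient Patient id (rowname) present in `matrix`.
#' @param drug Drug name (colname) present in `matrix`.
#' @return List with `patient`, `drug`, `rating`, `provenance`.
#' @export
predict_rating <- function(matrix, patient, drug) {
  stopifnot(inherits(matrix, "rating_matrix"))
  i <- match(as.character(patient), rownames(matrix$ratings))
  if (is.na(i)) stop("unknown patient: ", patient)
  j <- match(drug, colnames(matrix$ratings))
  if (is.na(j)) stop("unknown drug: ", drug)
  pred <- predict_for_queries(matrix,
                              query = matrix$ratings[i, , drop = FALSE],
                              query_cluster = matrix$cluster[i],
                              exclude = rownames(matrix$ratings)[i])
  list(patient = as.character(patient), drug = drug,
       rating = unname(pred$rating[1L, j]),
       provenance = unname(pred$provenance[1L, j]))
}

# Vectorised CF prediction: for each query row (with a cluster label),
# predict every drug from the training matrix. `exclude` names training
# patients to leave out of their own neighbourhoods (leave-one-out when
# queries are training rows).
predict_for_queries <- function(train, query, query_cluster, exclude = NULL) {
  R <- train$ratings
  q <- as.matrix(query)
  nq <- nrow(q)
  nd <- ncol(R)
  has <- (R > 0) * 1
  global_mean <- vapply(seq_len(nd), function(j) {
    v <- R[, j][R[, j] > 0]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, 1)
  rating <- matrix(NA_real_, nq, nd, dimnames = list(rownames(q), colnames(R)))
  provenance <- matrix("none", nq, nd, dimnames = dimnames(rating))
  for (cl in unique(query_cluster)) {
    qi <- which(query_cluster == cl)
    ti <- which(train$cluster == cl)
    cl_mean <- if (length(ti) > 0L) {
      vapply(seq_len(nd), function(j) {
        v <- R[ti, j][R[ti, j] > 0]
        if (length(v) == 0L) NA_real_ else mean(v)
      }, 1)
    } else rep(NA_real_, nd)
    if (length(ti) > 0L) {
      S <- cosine_matrix(q[qi, , drop = FALSE], R[ti, , drop = FALSE])
      if (!is.null(exclude) && !is.null(rownames(q))) {
        # leave-one-out: a query that is itself a training patient must not
        # appear in its own neighbourhood
        for (a in seq_along(qi)) {
          qid <- rownames(q)[qi[a]]
          if (qid %in% exclude) S[a, rownames(R)[ti] == qid] <- 0
        }
      }
      S[S < 0] <- 0
      num <- S %*% (R[ti, , drop = FALSE] * has[ti, , drop = FALSE])
      den <- S %*% has[ti, , drop = FALSE]
      nb <- den > 0
      rating[qi, ][nb] <- (num / ifelse(den == 0, 1, den))[nb]
      provenance[qi, ][nb] <- "neighbors"
    } else {
      nb <- matrix(FALSE, length(qi), nd)
    }
    fall <- !nb
    if (any(fall)) {
      cm <- matrix(cl_mean, length(qi), nd, byrow = TRUE)
      use_cm <- fall & !is.na(cm)
      rating[qi, ][use_cm] <- cm[use_cm]
      provenance[qi, ][use_cm] <- "cluster_mean"
      rest <- fall & is.na(cm)
      gm <- matrix(global_mean, length(qi), nd, byrow = TRUE)
      use_gm <- rest & !is.na(gm)
      rating[qi, ][use_gm] <- gm[use_gm]
      provenance[qi, ][use_gm] <- "global_mean"
      none <- rest & is.na(gm)
      rating[qi, ][none] <- 0
    }
  }
  list(rating = rating, provenance = provenance)
}

#' Complete the rating matrix with predicted dose values
#'
#' Every zero (not-administered) cell is filled with its collaborative-
#' filtering prediction; observed nonzero cells are kept unchanged.
#'
#' @param matrix A [rating_matrix].
#' @return List with `rating` (dense numeric matrix) and `provenance`
#'   (matrix of `"observed"` / `"neighbors"` / `"cluster_mean"` /
#'   `"global_mean"` / `"none"`).
#' @export
complete_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "rating_matrix"))
  R <- matrix$ratings
  pred <- predict_for_queries(matrix, query = R,
                              query_cluster = matrix$cluster,
                              exclude = rownames(R))
  out <- pred$rating
  prov <- pred$provenance
  obs <- R > 0
  out[obs] <- R[obs]
  prov[obs] <- "observed"
  list(rating = out, provenance = prov)
}

#' Top-N drug recommendations for a patient
#'
#' Ranks drugs for one patient by completed score — the observed dose value
#' where one exists, otherwise the collaborative-filtering prediction
#' (`use_observed = FALSE` ranks purely by prediction). Administered drugs
#' are *not* excluded by default; set `exclude_administered = TRUE` to
#' recommend only unprescribed drugs. Ties are broken alphabetically.
#'
#' @param matrix A [rating_matrix] (training data).
#' @param patient Patient id present in `matrix`, or a list with elements
#'   `ratings` (numeric vector) and `cluster` for an unseen patient.
#' @param n Number of drugs to return (>= 1). If `n` exceeds the number of
#'   candidate drugs, all are returned with a warning.
#' @param use_observed Rank observed cells by their observed value
#'   (default `TRUE`).
#' @param exclude_administered Drop drugs the patient already received.
#' @return List with `patient`, `drugs` (character, length <= n, scores
#'   nonincreasing), `scores`, `provenance`.
#' @export
recommend_top_n <- function(matrix, patient, n = 3L,
                            use_observed = TRUE,
                            exclude_administered = FALSE) {
  stopifnot(inherits(matrix, "rating_matrix"))
  if (n < 1L) stop("n must be >= 1")
  if (is.list(patient)) {
    q <- matrix(patient$ratings, nrow = 1L,
                dimnames = list("new", colnames(matrix$ratings)))
    cl <- patient$cluster
    observed <- q[1L, ]
    id <- "new"
    pred <- predict_for_queries(matrix, q, cl)
  } else {
    i <- match(as.character(patient), rownames(matrix$ratings))
    if (is.na(i)) stop("unknown patient: ", patient)
    observed <- matrix$ratings[i, ]
    id <- as.character(patient)
    pred <- predict_for_queries(matrix,
                                matrix$ratings[i, , drop = FALSE],
                                matrix$cluster[i],
                                exclude = id)
  }
  scores <- pred$rating[1L, ]
  prov <- pred$provenance[1L, ]
  if (use_observed) {
    obs <- observed > 0
    scores[obs] <- observed[obs]
    prov[obs] <- "observed"
  }
  if (exclude_administered) {
    keep <- observed == 0
    scores <- scores[keep]
    prov <- prov[keep]
  }
  if (n > length(scores)) {
    warning("n (", n, ") exceeds number of candidate drugs (", length(scores),
            "); returning all")
    n <- length(scores)
  }
  ord <- order(-scores, provenance_rank(prov), names(scores))
  top <- ord[seq_len(n)]
  list(patient = id, drugs = names(scores)[top],
       scores = unname(scores[top]), provenance = unname(prov[top]))
}

#' The worked 5-patient example matrix
#'
#' A small published-style collaborative-filtering matrix: five patients,
#' four medications, dose codes in {0, 1, 2} and cluster labels
#' {1, 2, 1, 3, 2}. Useful for demos and as a fixture.
#'
#' @return A [rating_matrix].
#' @export
example_rating_matrix <- function() {
  ratings <- matrix(c(1, 0, 2, 1,
                      0, 1, 1, 1,
                      2, 0, 0, 1,
                      1, 2, 0, 0,
                      1, 1, 2, 0),
                    nrow = 5L, byrow = TRUE,
                    dimnames = list(paste0("patient_", 1:5),
                                    paste0("medication_", 1:4)))
  rating_matrix(ratings, cluster = c(1L, 2L, 1L, 3L, 2L))
}
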