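#' Evaluation configuration
#'
#' @param train_fraction Fraction of patients used for training, in (0, 1).
#'   Default 0.80.
#' @param seed Seed for the patient split. Default 42.
#' @param top_n Length of the recommendation list. Default 3.
#' @param relevance_threshold A held-out drug is relevant when its observed
#'   dose value is strictly greater than this. Default 1 (i.e. an increased
#'   dose under the default encoding).
#' @return A list of class `eval_config`.
#' @export
eval_config <- function(train_fraction = 0.80, seed = 42L, top_n = 3L,
                        relevance_threshold = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1, top_n >= 1)
  structure(list(train_fraction = train_fraction, seed = as.integer(seed),
                 top_n = as.integer(top_n),
                 relevance_threshold = relevance_threshold),
            class = "eval_config")
}

#' Seeded train/test split by patient
#'
#' Draws `round(train_fraction * n)` patients uniformly at random (seeded)
#' for training; the rest are the test set. Splitting is by patient, never
#' by individual rating cell.
#'
#' @param ids Character vector of patient ids (or anything with length n).
#' @param config An [eval_config()].
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_patients <- function(ids, config = eval_config()) {
  n <- length(ids)
  if (n < 2L) stop("need at least 2 patients to split")
  n_train <- round(config$train_fraction * n)
  if (n_train == 0L || n_train == n) {
    stop("split leaves an empty train or test set (n = ", n, ")")
  }
  # draw in sorted-id order so the selected patients do not depend on the
  # row order of the input
  ord <- order(as.character(ids))
  set.seed(config$seed)
  train <- sort(ord[sample.int(n, n_train)])
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Mean squared error of predicted dose values on held-out patients
#'
#' For every test patient and every drug the patient actually received
#' (observed nonzero rating), the dose value is predicted from the training
#' patients in the test patient's assigned cluster; the MSE averages the
#' squared error over all such cells. Test patients' ratings never enter any
#' neighbourhood.
#'
#' @param train A [rating_matrix] of training patients.
#' @param test_ratings Numeric matrix of test patients' observed ratings
#'   (rownames = patient ids, same drug columns as `train`).
#' @param test_cluster Integer cluster label per test patient (from
#'   [assign_cluster()] on their features).
#' @return List with `mse`, `n_cells`, and `per_cluster` (data frame).
#' @export
evaluate_predictions <- function(train, test_ratings, test_cluster) {
  stopifnot(inherits(train, "rating_matrix"))
  test_ratings <- as.matrix(test_ratings)
  pred <- predict_for_queries(train, test_ratings, test_cluster)
  obs <- test_ratings > 0
  if (!any(obs)) stop("no observed nonzero test ratings to evaluate")
  err2 <- (pred$rating - test_ratings)^2
  cl_of_cell <- matrix(test_cluster, nrow(test_ratings), ncol(test_ratings))
  per_cluster <- stats::aggregate(
    err2[obs], by = list(cluster = cl_of_cell[obs]), FUN = mean)
  names(per_cluster)[2L] <- "mse"
  per_cluster$n_cells <- as.vector(table(cl_of_cell[obs]))
  list(mse = mean(err2[obs]), n_cells = sum(obs), per_cluster = per_cluster)
}

#' Precision of top-N recommendations on held-out patients
#'
#' A held-out drug is relevant when its observed dose value exceeds the
#' relevance threshold (default: dose value > 1). For each test patient with
#' at least one relevant drug, the top-N list is computed purely from
#' training-data predictions, and the patient's precision is
#' `|recommended intersect relevant| / N`. The reported precision is the mean
#' over those patients; patients with no relevant drug are excluded from the
#' mean and counted separately.
#'
#' @inheritParams evaluate_predictions
#' @param config An [eval_config()] (supplies `top_n` and
#'   `relevance_threshold`).
#' @return List with `precision`, `n_evaluated`, `n_without_relevant`,
#'   `per_cluster` (data frame).
#' @export
evaluate_recommendations <- function(train, test_ratings, test_cluster,
                                     config = eval_config()) {
  stopifnot(inherits(train, "rating_matrix"))
  test_ratings <- as.matrix(test_ratings)
  pred <- predict_for_queries(train, test_ratings, test_cluster)
  n_drugs <- ncol(test_ratings)
  top_n <- min(config$top_n, n_drugs)
  drug_names <- colnames(test_ratings)
  prec <- rep(NA_real_, nrow(test_ratings))
  for (i in seq_len(nrow(test_ratings))) {
    relevant <- which(test_ratings[i, ] > config$relevance_threshold)
    if (length(relevant) == 0L) next
    ord <- order(-pred$rating[i, ], provenance_rank(pred$provenance[i, ]),
                 drug_names)
    top <- ord[seq_len(top_n)]
    prec[i] <- length(intersect(top, relevant)) / top_n
  }
  evaluated <- !is.na(prec)
  if (!any(evaluated)) {
    return(list(precision = NA_real_, n_evaluated = 0L,
                n_without_relevant = nrow(test_ratings),
                per_cluster = NULL))
  }
  per_cluster <- stats::aggregate(
    prec[evaluated], by = list(cluster = test_cluster[evaluated]), FUN = mean)
  names(per_cluster)[2L] <- "precision"
  list(precision = mean(prec[evaluated]),
       n_evaluated = sum(evaluated),
       n_without_relevant = sum(!evaluated),
       per_cluster = per_cluster)
}

#' Run the full recommendation experiment end to end
#'
#' Preprocesses raw encounters into the per-patient feature table, splits
#' patients into train/test, fits standardisation + PCA + clustering on the
#' training patients, assigns test patients to their nearest centroid,
#' builds the training rating matrix, and evaluates held-out dose
#' predictions (MSE) and top-N recommendations (precision).
#'
#' @param encounters Raw encounter data frame (e.g. [read_encounters()] or
#'   [generate_encounters()] output), or an already-built feature table from
#'   [build_feature_table()].
#' @param preprocess A [preprocess_config()].
#' @param evaluation An [eval_config()].
#' @param pca_components Fixed number of PCA components, or `NULL` to use
#'   `var_target`.
#' @param var_target Cumulative explained-variance target. Default 0.62.
#' @param kmeans_k Candidate K-means cluster counts. Default 2:10.
#' @param dbscan_grid DBSCAN candidate grid or `NULL`. Default `NULL`
#'   (K-means only; pass [default_dbscan_grid()] to compare both).
#' @param seed Seed for clustering restarts (the split seed lives in
#'   `evaluation`).
#' @return A list of class `eval_report`: sample sizes, the selected
#'   clustering (algorithm, parameters, silhouette, cluster count), PCA
#'   summary, `mse`, `precision`, per-cluster breakdowns, and a config echo.
#' @export
run_evaluation <- function(encounters,
                           preprocess = preprocess_config(),
                           evaluation = eval_config(),
                           pca_components = NULL,
                           var_target = 0.62,
                           kmeans_k = 2:10,
                           dbscan_grid = NULL,
                           seed = 42L) {
  table <- if (!is.null(attr(encounters, "drug_cols"))) encounters
           else build_feature_table(encounters, preprocess)
  fm <- feature_matrix(table)
  split <- split_patients(fm$patient_id, evaluation)
  feats <- fm$features
  # degenerate (constant) columns cannot be standardised; drop them here
  train_feats <- feats[split$train, , drop = FALSE]
  keep_cols <- apply(train_feats, 2L, function(v) stats::var(v) > 0)
  feats <- feats[, keep_cols, drop = FALSE]
  std <- standardize(feats[split$train, , drop = FALSE])
  pca <- fit_pca(std$data, n_components = pca_components,
                 var_target = var_target)
  model <- select_model(pca$scores, kmeans_k = kmeans_k,
                        dbscan_grid = dbscan_grid, seed = seed)
  if (is.null(model$centroids)) {
    stop("selected model has no centroids; cannot assign test patients ",
         "(use a K-means candidate set)")
  }
  train_rm <- rating_matrix(fm$ratings[split$train, , drop = FALSE],
                            model$labels)
  test_z <- apply_standardization(std$params,
                                  feats[split$test, , drop = FALSE])
  test_scores <- project_pca(pca$model, test_z)
  test_cluster <- assign_cluster(model, test_scores)
  test_ratings <- fm$ratings[split$test, , drop = FALSE]
  mse <- evaluate_predictions(train_rm, test_ratings, test_cluster)
  prec <- evaluate_recommendations(train_rm, test_ratings, test_cluster,
                                   evaluation)
  structure(list(
    n_patients = length(fm$patient_id),
    n_train = length(split$train),
    n_test = length(split$test),
    clustering = list(algorithm = model$algorithm, params = model$params,
                      n_clusters = model$n_clusters,
                      silhouette = model$silhouette),
    pca = list(k = pca$model$k,
               explained_variance = sum(pca$model$explained[seq_len(pca$model$k)])),
    mse = mse$mse,
    mse_n_cells = mse$n_cells,
    precision = prec$precision,
    precision_n_evaluated = prec$n_evaluated,
    precision_n_without_relevant = prec$n_without_relevant,
    per_cluster = list(mse = mse$per_cluster, precision = prec$per_cluster),
    config = list(evaluation = unclass(evaluation),
                  preprocess = list(
                    min_medications = preprocess$min_medications,
                    missingness_threshold = preprocess$missingness_threshold,
                    imbalance_threshold = preprocess$imbalance_threshold,
                    min_drug_prevalence = preprocess$min_drug_prevalence),
                  kmeans_k = kmeans_k, seed = seed),
    model = model,
    split = split,
    test_cluster = test_cluster),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Held-out evaluation (", x$n_train, " train / ", x$n_test, " test)\n",
      sep = "")
  cat("  clustering: ", x$clustering$algorithm, ", ",
      x$clustering$n_clusters, " clusters, silhouette ",
      format(x$clustering$silhouette, digits = 4), "\n", sep = "")
  cat("  PCA: ", x$pca$k, " components, ",
      format(100 * x$pca$explained_variance, digits = 3),
      "% variance\n", sep = "")
  cat("  MSE (", x$mse_n_cells, " cells): ", format(x$mse, digits = 4),
      "\n", sep = "")
  cat("  precision@", x$config$evaluation$top_n, " (",
      x$precision_n_evaluated, " patients): ",
      format(x$precision, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Serialise an evaluation report to JSON
#' @param report An `eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  out <- unclass(report)
  out$model <- NULL
  out$split <- NULL
  out$test_cluster <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}
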