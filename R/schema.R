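#' @keywords internal
"_PACKAGE"

# Canonical column vocabulary of the 130-US-hospitals encounter schema.
# Header matching elsewhere is case-insensitive after whitespace stripping,
# so "diabetesMed" and "A1Cresult" in raw files map onto these names.

#' Drug dose-change columns of the encounter schema
#'
#' The 23 per-drug columns recording whether a drug was administered during
#' the encounter and how its dose changed (`No`, `Down`, `Steady`, `Up`).
#'
#' @return Character vector of canonical drug column names.
#' @export
drug_columns <- function() {
  c("metformin", "repaglinide", "nateglinide", "chlorpropamide",
    "glimepiride", "acetohexamide", "glipizide", "glyburide", "tolbutamide",
    "pioglitazone", "rosiglitazone", "acarbose", "miglitol", "troglitazone",
    "tolazamide", "examide", "citoglipton", "insulin",
    "glyburide-metformin", "glipizide-metformin",
    "glimepiride-pioglitazone", "metformin-rosiglitazone",
    "metformin-pioglitazone")
}

#' Drugs retained after prevalence filtering
#'
#' The ten drugs that survive the default variable-selection rules: every
#' other drug is either never administered or given to well under 1% of
#' patients and is dropped by the default configuration.
#'
#' @return Character vector of drug column names, most- to least-prevalent.
#' @export
retained_drugs <- function() {
  c("insulin", "metformin", "glipizide", "glyburide", "pioglitazone",
    "rosiglitazone", "glimepiride", "repaglinide", "glyburide-metformin",
    "nateglinide")
}

#' @rdname drug_columns
#' @export
dose_tokens <- function() c("No", "Down", "Steady", "Up")

# Non-drug columns, in raw-file order.
non_drug_columns <- function() {
  c("encounter_id", "patient_nbr", "race", "gender", "age", "weight",
    "admission_type_id", "discharge_disposition_id", "admission_source_id",
    "time_in_hospital", "payer_code", "medical_specialty",
    "num_lab_procedures", "num_procedures", "num_medications",
    "number_outpatient", "number_emergency", "number_inpatient",
    "diag_1", "diag_2", "diag_3", "number_diagnoses",
    "max_glu_serum", "a1cresult", "change", "diabetesmed", "readmitted")
}

#' Full canonical encounter schema
#' @return Character vector of all canonical column names in file order.
#' @export
encounter_columns <- function() {
  cols <- non_drug_columns()
  c(cols[seq_len(which(cols == "a1cresult"))], drug_columns(),
    c("change", "diabetesmed", "readmitted"))
}

# Columns that must parse as nonnegative integers.
integer_columns <- function() {
  c("time_in_hospital", "num_lab_procedures", "num_procedures",
    "num_medications", "number_outpatient", "number_emergency",
    "number_inpatient", "number_diagnoses",
    "admission_type_id", "discharge_disposition_id", "admission_source_id")
}

canonical_name <- function(x) {
  key <- tolower(gsub("\\s+", "", x))
  known <- c(non_drug_columns(), drug_columns())
  idx <- match(key, tolower(known))
  ifelse(is.na(idx), x, known[idx])
}

#' Read hospital encounters from CSV
#'
#' Parses a comma-separated encounter file in the 130-US-hospitals dialect:
#' header row, UTF-8, `"?"` (or an empty field) marking missing values.
#' Column names are matched case-insensitively against the canonical schema;
#' unknown extra columns are retained untouched. Drug tokens are normalised
#' to `No`/`Down`/`Steady`/`Up` regardless of case.
#'
#' @param path Path to a CSV file with a header row.
#' @param na Character vector of raw missing-value markers.
#' @return A `data.frame` with one row per encounter, original order
#'   preserved; missing values are `NA`; integer-coded columns are integer.
#' @export
read_encounters <- function(path, na = c("?", "")) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  names(raw) <- canonical_name(names(raw))
  as_encounters(raw, na = na)
}

# Validate/normalise a character data.frame already carrying canonical names.
as_encounters <- function(raw, na = c("?", "")) {
  drug_cols <- intersect(drug_columns(), names(raw))
  mandatory <- c("patient_nbr")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(drug_cols) == 0L) missing_cols <- c(missing_cols, "<any drug column>")
  if (length(missing_cols) > 0L) {
    stop("encounter file is missing mandatory columns: ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in names(raw)) {
    v <- as.character(raw[[col]])
    v[v %in% na] <- NA_character_
    raw[[col]] <- v
  }
  for (col in intersect(integer_columns(), names(raw))) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(v))
    if (length(bad) > 0L) {
      stop("unparseable numeric value in column '", col, "' at row ", bad[1L])
    }
    raw[[col]] <- v
  }
  tokens <- dose_tokens()
  for (col in drug_cols) {
    idx <- match(tolower(raw[[col]]), tolower(tokens))
    bad <- which(!is.na(raw[[col]]) & is.na(idx))
    if (length(bad) > 0L) {
      stop("invalid dose token '", raw[[col]][bad[1L]], "' in column '",
           col, "' at row ", bad[1L])
    }
    raw[[col]] <- tokens[idx]
  }
  rownames(raw) <- NULL
  raw
}

#' Write and read the per-patient feature table
#'
#' CSV round trip for the numeric feature table produced by
#' [build_feature_table()]: first column is the patient identifier, all
#' remaining columns are numeric. `read_feature_table(write_feature_table(x))`
#' reproduces `x` exactly, including column names.
#'
#' @param table Data frame whose first column is `patient_id`.
#' @param path Output/input CSV path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns the data frame.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (anyDuplicated(names(table))) {
    stop("duplicate column names: ",
         paste(unique(names(table)[duplicated(names(table))]), collapse = ", "))
  }
  tmp <- paste0(path, ".tmp")
  ok <- tryCatch({
    utils::write.csv(table, tmp, row.names = FALSE)
    TRUE
  }, error = function(e) {
    unlink(tmp)
    stop("cannot write feature table to '", path, "': ", conditionMessage(e))
  })
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE,
                         colClasses = c("character"))
  if (anyDuplicated(names(tab))) {
    stop("duplicate column names in '", path, "'")
  }
  if (ncol(tab) > 1L) {
    for (col in names(tab)[-1L]) tab[[col]] <- as.numeric(tab[[col]])
  }
  tab
}

#' Write and read a rating matrix
#'
#' Serialises a [rating_matrix] (patients x drugs dose codes plus cluster
#' labels) to CSV: `patient_id` first, one column per drug, and a final
#' `cluster` column.
#'
#' @param matrix A `rating_matrix` object.
#' @param path CSV path.
#' @return `write_rating_matrix` returns `path` invisibly;
#'   `read_rating_matrix` returns a `rating_matrix`.
#' @export
write_rating_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "rating_matrix"))
  df <- data.frame(patient_id = rownames(matrix$ratings),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(matrix$ratings, check.names = FALSE))
  df$cluster <- matrix$cluster
  write_feature_table(df, path)
}

#' @rdname write_rating_matrix
#' @export
read_rating_matrix <- function(path) {
  df <- read_feature_table(path)
  if (!all(c("patient_id", "cluster") %in% names(df))) {
    stop("'", path, "' is not a rating-matrix file (needs patient_id and cluster)")
  }
  drug_cols <- setdiff(names(df), c("patient_id", "cluster"))
  ratings <- as.matrix(df[, drug_cols, drop = FALSE])
  rownames(ratings) <- df$patient_id
  rating_matrix(ratings, cluster = df$cluster)
}

#' Persist a fitted clustering model as JSON
#'
#' Stores standardisation parameters, the PCA basis and explained-variance
#' ratios, cluster labels, centroids (K-means), the silhouette score and the
#' seed, so that new patients can be projected and assigned later.
#'
#' @param model A `cluster_model` from [select_model()] or friends.
#' @param path JSON path.
#' @return `write_model` returns `path` invisibly; `read_model` the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cluster_model"))
  payload <- unclass(model)
  payload$centroids <- if (is.null(model$centroids)) NULL else {
    list(values = as.vector(model$centroids), dim = dim(model$centroids),
         colnames = colnames(model$centroids))
  }
  if (!is.null(model$pca)) {
    payload$pca <- list(
      rotation = list(values = as.vector(model$pca$rotation),
                      dim = dim(model$pca$rotation),
                      rownames = rownames(model$pca$rotation)),
      explained = model$pca$explained,
      k = model$pca$k)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(p$centroids)) {
    cen <- matrix(p$centroids$values, nrow = p$centroids$dim[1L])
    colnames(cen) <- p$centroids$colnames
    p$centroids <- cen
  }
  if (!is.null(p$pca)) {
    rot <- matrix(p$pca$rotation$values, nrow = p$pca$rotation$dim[1L])
    rownames(rot) <- p$pca$rotation$rownames
    p$pca <- list(rotation = rot, explained = p$pca$explained, k = p$pca$k)
  }
  if (!is.null(p$standardization)) {
    p$standardization$mean <- unlist(p$standardization$mean)
    p$standardization$sd <- unlist(p$standardization$sd)
  }
  structure(p, class = "cluster_model")
}
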