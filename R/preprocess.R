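#' Preprocessing configuration
#'
#' Bundles the cleaning, filtering and encoding rules applied by
#' [build_feature_table()].
#'
#' @param missingness_threshold Columns whose missing fraction exceeds this
#'   are dropped. Default 0.50.
#' @param imbalance_threshold Non-drug columns where a single value covers
#'   more than this fraction of rows are dropped. Default 0.95.
#' @param min_drug_prevalence Drug columns administered to less than this
#'   fraction of patients are dropped. Default 0.005.
#' @param min_medications Patients with fewer distinct administered drugs are
#'   removed. Default 2.
#' @param explicit_drop Columns removed a priori: identifiers, the two
#'   near-empty free-text columns, the secondary/tertiary diagnoses, and the
#'   thirteen rarely-used drugs that the default pipeline discards.
#' @param dose_encoding Named numeric vector mapping dose-change tokens to
#'   ratings. Must assign `No` the value 0 and be monotone
#'   `No <= Down <= Up`. `Steady` defaults to 1 (administered, unchanged).
#' @param readmitted_encoding Named vector mapping readmission categories to
#'   ordered codes (no readmission 0, late 1, early 2).
#' @param gender_encoding Named vector; values not listed encode as 0.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(missingness_threshold = 0.50,
                              imbalance_threshold = 0.95,
                              min_drug_prevalence = 0.005,
                              min_medications = 2L,
                              explicit_drop = default_explicit_drop(),
                              dose_encoding = c(No = 0, Down = 1, Steady = 1, Up = 2),
                              readmitted_encoding = c("NO" = 0, ">30" = 1, "<30" = 2),
                              gender_encoding = c(Male = 1, Female = 0)) {
  stopifnot(missingness_threshold > 0, missingness_threshold <= 1,
            imbalance_threshold > 0, imbalance_threshold <= 1,
            min_drug_prevalence >= 0, min_drug_prevalence <= 1)
  if (min_medications < 0) stop("min_medications must be >= 0")
  tokens <- dose_tokens()
  if (!all(tokens %in% names(dose_encoding))) {
    stop("dose_encoding must name all of: ", paste(tokens, collapse = ", "))
  }
  de <- dose_encoding[tokens]
  if (de[["No"]] != 0) stop("dose_encoding must assign No the value 0")
  if (!(de[["No"]] <= de[["Down"]] && de[["Down"]] <= de[["Up"]])) {
    stop("dose_encoding must be monotone: No <= Down <= Up")
  }
  structure(list(missingness_threshold = missingness_threshold,
                 imbalance_threshold = imbalance_threshold,
                 min_drug_prevalence = min_drug_prevalence,
                 min_medications = as.integer(min_medications),
                 explicit_drop = explicit_drop,
                 dose_encoding = de,
                 readmitted_encoding = readmitted_encoding,
                 gender_encoding = gender_encoding),
            class = "preprocess_config")
}

#' @rdname preprocess_config
#' @export
default_explicit_drop <- function() {
  c("encounter_id", "payer_code", "weight", "medical_specialty",
    "diag_2", "diag_3",
    setdiff(drug_columns(), retained_drugs()))
}

#' Keep one encounter per patient
#'
#' Retains the first encounter (file order) for every `patient_nbr`,
#' preserving the order of first appearance. Idempotent.
#'
#' @param encounters Encounter data frame from [read_encounters()].
#' @return The deduplicated data frame.
#' @export
deduplicate_patients <- function(encounters) {
  stopifnot("patient_nbr" %in% names(encounters))
  out <- encounters[!duplicated(encounters$patient_nbr), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop patients with too few administered drugs
#'
#' A drug counts as administered when its token is not `No`. Patients with
#' fewer than `min_medications` administered drugs (over the drug columns
#' present in `encounters`) are removed.
#'
#' @inheritParams deduplicate_patients
#' @param min_medications Minimum number of administered drugs to keep a row.
#' @return The filtered data frame.
#' @export
filter_medicated <- function(encounters, min_medications = 2L) {
  if (min_medications < 0) stop("min_medications must be >= 0")
  drug_cols <- intersect(drug_columns(), names(encounters))
  if (length(drug_cols) == 0L) stop("no drug columns present")
  administered <- vapply(drug_cols, function(col) {
    v <- encounters[[col]]
    !is.na(v) & v != "No"
  }, logical(nrow(encounters)))
  if (nrow(encounters) == 1L) administered <- matrix(administered, nrow = 1L)
  keep <- rowSums(administered) >= min_medications
  out <- encounters[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map an ICD-9 code to a disease category
#'
#' Categories follow the standard grouping for this encounter data set, keyed
#' on the three-digit ICD-9 prefix: circulatory (390-459, 785), respiratory
#' (460-519, 786), digestive (520-579, 787), diabetes (prefix 250),
#' genitourinary (580-629, 788), injury (800-999), musculoskeletal (710-739),
#' neoplasms (140-239); V/E codes, missing codes and everything else map to
#' `other`. Total and vectorised.
#'
#' @param icd9 Character vector of ICD-9 codes (may contain a decimal part).
#' @return Character vector of category names.
#' @export
group_diagnosis <- function(icd9) {
  groups <- diagnosis_groups()
  out <- rep("other", length(icd9))
  code <- as.character(icd9)
  prefix <- suppressWarnings(as.numeric(sub("\\..*$", "", code)))
  num <- !is.na(prefix)
  p <- prefix[num]
  g <- rep("other", length(p))
  g[p >= 390 & p <= 459 | p == 785] <- "circulatory"
  g[p >= 460 & p <= 519 | p == 786] <- "respiratory"
  g[p >= 520 & p <= 579 | p == 787] <- "digestive"
  g[floor(p) == 250] <- "diabetes"
  g[p >= 580 & p <= 629 | p == 788] <- "genitourinary"
  g[p >= 800 & p <= 999] <- "injury"
  g[p >= 710 & p <= 739] <- "musculoskeletal"
  g[p >= 140 & p <= 239] <- "neoplasms"
  out[num] <- g
  out
}

#' @rdname group_diagnosis
#' @export
diagnosis_groups <- function() {
  c("circulatory", "diabetes", "digestive", "genitourinary", "injury",
    "musculoskeletal", "neoplasms", "respiratory", "other")
}

#' Encode an age bracket as its midpoint
#'
#' `"[L-U)"` with `U = L + 10` becomes `(L + U) / 2`, so the ten brackets map
#' to 5, 15, ..., 95 years.
#'
#' @param bracket Character vector of brackets such as `"[40-50)"`.
#' @return Numeric vector of midpoints in years.
#' @export
encode_age <- function(bracket) {
  m <- regmatches(bracket, regexec("^\\[(\\d+)-(\\d+)\\)$", as.character(bracket)))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad & !is.na(bracket))) {
    stop("malformed age bracket: '", bracket[which(bad & !is.na(bracket))[1L]], "'")
  }
  lo <- vapply(m, function(x) if (length(x) == 3L) as.numeric(x[2L]) else NA_real_, 1)
  hi <- vapply(m, function(x) if (length(x) == 3L) as.numeric(x[3L]) else NA_real_, 1)
  (lo + hi) / 2
}

#' Encode dose-change tokens as numeric ratings
#'
#' Fixed points of the encoding: `No` is 0 (drug not administered), `Down`
#' is 1 (dose decreased) and `Up` is 2 (dose increased); `Steady` defaults
#' to 1 and is configurable.
#'
#' @param token Character vector of dose tokens.
#' @param config A [preprocess_config()] (supplies `dose_encoding`).
#' @return Numeric vector of ratings.
#' @export
encode_dose <- function(token, config = preprocess_config()) {
  enc <- config$dose_encoding
  idx <- match(token, names(enc))
  bad <- which(is.na(idx) & !is.na(token))
  if (length(bad) > 0L) stop("unknown dose token: '", token[bad[1L]], "'")
  unname(enc[idx])
}

#' Rule-based column selection
#'
#' Applies, in order: (1) missingness — columns whose missing fraction
#' exceeds `missingness_threshold`; (2) the explicit a-priori drop list;
#' (3) imbalance — non-drug columns where one value covers more than
#' `imbalance_threshold` of rows; (4) prevalence — drug columns administered
#' to fewer than `min_drug_prevalence` of the rows. `patient_nbr` is kept as
#' the row identifier but reported as dropped from the feature set. Every
#' input column lands either in the output or in the drop report with
#' exactly one reason.
#'
#' @param encounters Encounter data frame (post dedup/medication filter).
#' @param config A [preprocess_config()].
#' @return List with `data` (surviving columns) and `drop_report`
#'   (data frame: `column`, `reason`, `statistic`).
#' @export
select_variables <- function(encounters, config = preprocess_config()) {
  n <- nrow(encounters)
  if (n == 0L) stop("no rows to select variables on")
  drug_cols <- intersect(drug_columns(), names(encounters))
  report <- list()
  dropped <- character()
  drop <- function(col, reason, statistic) {
    report[[length(report) + 1L]] <<- data.frame(
      column = col, reason = reason, statistic = statistic,
      stringsAsFactors = FALSE)
    dropped <<- c(dropped, col)
  }
  for (col in names(encounters)) {
    if (col %in% dropped) next
    frac <- mean(is.na(encounters[[col]]))
    if (frac > config$missingness_threshold) drop(col, "missingness", frac)
  }
  if ("patient_nbr" %in% names(encounters) && !("patient_nbr" %in% dropped)) {
    drop("patient_nbr", "identifier", NA_real_)
  }
  for (col in intersect(config$explicit_drop, names(encounters))) {
    if (!(col %in% dropped)) drop(col, "irrelevant", NA_real_)
  }
  for (col in setdiff(names(encounters), c(dropped, drug_cols))) {
    tab <- table(encounters[[col]], useNA = "no")
    if (length(tab) == 0L) next
    frac <- max(tab) / n
    if (frac > config$imbalance_threshold) drop(col, "imbalance", frac)
  }
  for (col in setdiff(drug_cols, dropped)) {
    v <- encounters[[col]]
    prevalence <- mean(!is.na(v) & v != "No")
    if (prevalence < config$min_drug_prevalence) drop(col, "prevalence", prevalence)
  }
  keep <- setdiff(names(encounters), setdiff(dropped, "patient_nbr"))
  if (length(setdiff(keep, "patient_nbr")) == 0L) {
    stop("variable selection dropped every column")
  }
  list(data = encounters[, keep, drop = FALSE],
       drop_report = do.call(rbind, report))
}

#' Build the numeric per-patient feature table
#'
#' Runs the full preprocessing pipeline: deduplicate patients, drop
#' under-medicated patients, select variables, then transform to a fully
#' numeric table — gender and yes/no flags to 0/1, lab results to
#' performed/not-performed flags, readmission to an ordered 0/1/2 code, age
#' brackets to midpoints, race to one-hot columns, the first diagnosis to
#' one-hot disease-category columns, and drug tokens to dose ratings.
#'
#' @param encounters Encounter data frame from [read_encounters()].
#' @param config A [preprocess_config()].
#' @return A data frame with `patient_id` first, then numeric feature
#'   columns, then the encoded drug columns. Attributes: `drop_report`
#'   (from [select_variables()], extended with transformed source columns),
#'   `drug_cols` (names of the drug rating columns), and `log` (one line per
#'   pipeline rule with row/column counts).
#' @export
build_feature_table <- function(encounters, config = preprocess_config()) {
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))
  n0 <- nrow(encounters)
  enc <- deduplicate_patients(encounters)
  note("deduplicate_patients: ", n0, " -> ", nrow(enc), " rows")
  n1 <- nrow(enc)
  enc <- filter_medicated(enc, config$min_medications)
  note("filter_medicated(min=", config$min_medications, "): ",
       n1, " -> ", nrow(enc), " rows")
  if (nrow(enc) == 0L) stop("no patients survive the medication filter")
  sel <- select_variables(enc, config)
  enc <- sel$data
  report <- sel$drop_report
  note("select_variables: ", ncol(sel$data), " columns kept, ",
       nrow(report), " dropped")

  drug_cols <- intersect(drug_columns(), names(enc))
  out <- data.frame(patient_id = as.character(enc$patient_nbr),
                    stringsAsFactors = FALSE, check.names = FALSE)
  add_report <- function(col, reason) {
    report <<- rbind(report, data.frame(column = col, reason = reason,
                                        statistic = NA_real_,
                                        stringsAsFactors = FALSE))
  }
  yes_no <- function(v, yes) as.numeric(!is.na(v) & v %in% yes)
  for (col in setdiff(names(enc), c("patient_nbr", drug_cols))) {
    v <- enc[[col]]
    if (col == "gender") {
      enc_map <- config$gender_encoding
      idx <- match(v, names(enc_map))
      out[[col]] <- ifelse(is.na(idx), 0, unname(enc_map[idx]))
    } else if (col == "age") {
      out[[col]] <- encode_age(v)
    } else if (col %in% c("max_glu_serum", "a1cresult")) {
      out[[col]] <- as.numeric(!is.na(v) & v != "None")
    } else if (col == "change") {
      out[[col]] <- yes_no(v, c("Ch", "Yes", "ch", "yes"))
    } else if (col == "diabetesmed") {
      out[[col]] <- yes_no(v, c("Yes", "yes"))
    } else if (col == "readmitted") {
      idx <- match(v, names(config$readmitted_encoding))
      out[[col]] <- ifelse(is.na(idx), 0, unname(config$readmitted_encoding[idx]))
    } else if (col == "race") {
      races <- c("AfricanAmerican", "Asian", "Caucasian", "Hispanic", "Other")
      r <- ifelse(is.na(v) | !(v %in% races), "Other", v)
      for (race in races) out[[race]] <- as.numeric(r == race)
      add_report("race", "transformed")
    } else if (col == "diag_1") {
      grp <- group_diagnosis(v)
      for (g in diagnosis_groups()) out[[g]] <- as.numeric(grp == g)
      add_report("diag_1", "transformed")
    } else if (is.numeric(v)) {
      if (anyNA(v)) {
        # stray missing values in a retained count column: drop the rows
        keep <- !is.na(v)
        out <- out[keep, , drop = FALSE]
        enc <- enc[keep, , drop = FALSE]
        v <- v[keep]
        note("dropped ", sum(!keep), " rows with missing '", col, "'")
      }
      out[[col]] <- as.numeric(v)
    } else {
      add_report(col, "non_numeric")
      note("dropped non-numeric column '", col, "'")
    }
  }
  for (col in drug_cols) {
    tok <- enc[[col]]
    tok[is.na(tok)] <- "No"
    out[[col]] <- encode_dose(tok, config)
  }
  rownames(out) <- NULL
  note("feature table: ", nrow(out), " patients x ", ncol(out) - 1L, " variables")
  attr(out, "drop_report") <- report
  attr(out, "drug_cols") <- drug_cols
  attr(out, "log") <- log
  out
}

#' Split a feature table into clustering features and drug ratings
#'
#' @param table Output of [build_feature_table()].
#' @return List with `patient_id`, numeric `features` matrix (all variables,
#'   drugs included, as used for clustering) and `ratings` matrix (drug
#'   columns only).
#' @export
feature_matrix <- function(table) {
  drug_cols <- attr(table, "drug_cols")
  if (is.null(drug_cols)) drug_cols <- intersect(drug_columns(), names(table))
  feats <- as.matrix(table[, setdiff(names(table), "patient_id"), drop = FALSE])
  rownames(feats) <- table$patient_id
  ratings <- feats[, drug_cols, drop = FALSE]
  list(patient_id = table$patient_id, features = feats, ratings = ratings)
}
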