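# Synthetic encounter generator: plants per-cluster demographic profiles,
# diagnosis mixes and deterministic drug-dose signatures in the raw
# 130-US-hospitals schema so the whole pipeline is testable offline.

age_brackets <- function() sprintf("[%d-%d)", seq(0, 90, 10), seq(10, 100, 10))

# Representative ICD-9 codes per disease category (sampling pool).
icd9_pool <- function() {
  list(circulatory = c("401", "414", "427", "428.0"),
       diabetes = c("250", "250.01", "250.6"),
       digestive = c("530", "558", "578.9"),
       genitourinary = c("584", "599.0"),
       injury = c("820", "850", "996"),
       musculoskeletal = c("715", "722.1"),
       neoplasms = c("153", "174", "197"),
       respiratory = c("486", "491", "518.81"),
       other = c("276", "300", "V57", "E849"))
}

count_variables <- function() {
  c("time_in_hospital", "num_lab_procedures", "num_procedures",
    "num_medications", "number_outpatient", "number_emergency",
    "number_inpatient", "number_diagnoses")
}

count_noise_scale <- function() {
  c(time_in_hospital = 3, num_lab_procedures = 15, num_procedures = 1.5,
    num_medications = 4, number_outpatient = 1.5, number_emergency = 1,
    number_inpatient = 1, number_diagnoses = 2)
}

count_bounds <- function() {
  list(time_in_hospital = c(1, 14), num_lab_procedures = c(1, 132),
       num_procedures = c(0, 6), num_medications = c(1, 81),
       number_outpatient = c(0, 42), number_emergency = c(0, 76),
       number_inpatient = c(0, 21), number_diagnoses = c(1, 16))
}

default_cluster_profiles <- function() {
  prof <- function(age, race, p_male, diag, signature, counts, adm,
                   readmit, p_glu, p_a1c) {
    list(age = age, race = race, p_male = p_male, diag = diag,
         signature = signature, counts = counts, adm = adm,
         readmit = readmit, p_glu = p_glu, p_a1c = p_a1c)
  }
  cnt <- function(...) {
    stats::setNames(c(...), count_variables())
  }
  # Profiles are unimodal in the discrete variables (one modal age bracket,
  # race and diagnosis category each); minority mass enters only through the
  # sigma resampling noise, so the planted clusters stay coherent blobs.
  list(
    # insulin-treated, African American, circulatory problems, middle-aged
    prof(c("[50-60)" = 1),
         c(AfricanAmerican = 1),
         0.394,
         c(circulatory = 1),
         c(insulin = "Up", glipizide = "Up", metformin = "Up",
           glyburide = "Steady", pioglitazone = "Steady"),
         cnt(2, 20, 0, 6, 0, 0, 1, 4),
         adm = c(1, 1, 7),
         readmit = c("NO" = 0.5, ">30" = 0.3, "<30" = 0.2),
         p_glu = 0.10, p_a1c = 0.30),
    # oral agents, Caucasian, respiratory problems, no insulin
    prof(c("[60-70)" = 1),
         c(Caucasian = 1),
         0.50,
         c(respiratory = 1),
         c(metformin = "Up", glipizide = "Up", glyburide = "Up",
           rosiglitazone = "Steady", repaglinide = "Down"),
         cnt(4, 35, 1, 9, 2, 1, 0, 6),
         adm = c(2, 3, 1),
         readmit = c("NO" = 0.6, ">30" = 0.3, "<30" = 0.1),
         p_glu = 0.20, p_a1c = 0.50),
    # small cluster, Caucasian, other/metabolic problems, no insulin, older
    prof(c("[70-80)" = 1),
         c(Caucasian = 1),
         0.45,
         c(other = 1),
         c(glyburide = "Up", metformin = "Up", glipizide = "Up",
           glimepiride = "Steady"),
         cnt(6, 50, 2, 12, 4, 2, 2, 8),
         adm = c(3, 6, 4),
         readmit = c("NO" = 0.7, ">30" = 0.2, "<30" = 0.1),
         p_glu = 0.30, p_a1c = 0.20),
    # largest cluster, insulin + oral, circulatory problems
    prof(c("[60-70)" = 1),
         c(Caucasian = 1),
         0.55,
         c(circulatory = 1),
         c(insulin = "Up", metformin = "Up", glipizide = "Up",
           pioglitazone = "Down"),
         cnt(8, 65, 3, 15, 1, 3, 1, 5),
         adm = c(1, 2, 2),
         readmit = c("NO" = 0.4, ">30" = 0.4, "<30" = 0.2),
         p_glu = 0.15, p_a1c = 0.40),
    # sulfonylurea-treated, Hispanic, circulatory problems, no insulin
    prof(c("[50-60)" = 1),
         c(Hispanic = 1),
         0.50,
         c(circulatory = 1),
         c(glyburide = "Up", glipizide = "Up", metformin = "Up",
           nateglinide = "Steady"),
         cnt(10, 80, 4, 18, 3, 1, 3, 7),
         adm = c(2, 5, 5),
         readmit = c("NO" = 0.6, ">30" = 0.2, "<30" = 0.2),
         p_glu = 0.25, p_a1c = 0.60),
    # insulin + combination therapy, diabetes-coded admissions, younger
    prof(c("[40-50)" = 1),
         c(Caucasian = 1),
         0.48,
         c(diabetes = 1),
         c(insulin = "Up", metformin = "Up", glipizide = "Up",
           `glyburide-metformin` = "Steady", glyburide = "Steady"),
         cnt(12, 95, 5, 21, 5, 0, 0, 9),
         adm = c(3, 4, 6),
         readmit = c("NO" = 0.5, ">30" = 0.25, "<30" = 0.25),
         p_glu = 0.05, p_a1c = 0.10))
}

#' Synthetic-data configuration
#'
#' Describes the planted structure of generated encounter files: cluster
#' sizes, per-cluster demographic and diagnosis profiles, deterministic
#' per-cluster drug-dose signatures, and two noise knobs. The defaults plant
#' six clusters with size proportions, insulin usage (prevalent in three
#' clusters, absent from the other three), race/diagnosis mixes and age
#' mass mirroring the patient groups the pipeline is designed to recover.
#'
#' @param n_patients Number of distinct patients. Default 2000.
#' @param profiles List of per-cluster profiles (see
#'   `default_cluster_profiles` in the package source); length defines the
#'   number of planted clusters G >= 2.
#' @param proportions Cluster-size proportions (sum to 1). Default
#'   `(875, 910, 412, 1369, 646, 965) / 5177`.
#' @param duplicate_rate Expected fraction of patients receiving a second
#'   encounter row (exercises deduplication). Default 0.1.
#' @param sigma Feature-noise level >= 0: jitters count variables (sd =
#'   `sigma` x per-variable scale) and resamples each categorical value —
#'   including each drug token over the signature's domain — with
#'   probability `min(sigma, 0.9)`. At 0 the drug pattern is exactly the
#'   cluster signature. Default 0.1.
#' @param epsilon Label-flip rate in \[0, 0.5): probability that a patient's
#'   data are drawn from a random *other* cluster while the recorded ground
#'   truth keeps the original label. Default 0.
#' @param min_medications Feasibility floor: every signature must administer
#'   at least this many drugs. Default 2.
#' @param seed Integer seed; all generation randomness flows from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 2000L,
                             profiles = default_cluster_profiles(),
                             proportions = c(875, 910, 412, 1369, 646, 965) / 5177,
                             duplicate_rate = 0.1,
                             sigma = 0.1,
                             epsilon = 0,
                             min_medications = 2L,
                             seed = 42L) {
  G <- length(profiles)
  if (G < 2L) stop("need at least 2 cluster profiles")
  if (length(proportions) != G) stop("proportions must match the number of profiles")
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  if (sigma < 0) stop("sigma must be >= 0")
  if (epsilon < 0 || epsilon >= 0.5) stop("epsilon must be in [0, 0.5)")
  for (g in seq_len(G)) {
    p <- profiles[[g]]
    for (dist in list(p$age, p$race, p$diag, p$readmit)) {
      if (abs(sum(dist) - 1) > 1e-8) {
        stop("profile ", g, ": distribution does not sum to 1")
      }
    }
    n_admin <- sum(p$signature != "No")
    if (n_admin < min_medications) {
      stop("profile ", g, " administers only ", n_admin,
           " drugs; min_medications = ", min_medications)
    }
  }
  structure(list(n_patients = as.integer(n_patients), profiles = profiles,
                 G = G, proportions = proportions,
                 duplicate_rate = duplicate_rate, sigma = sigma,
                 epsilon = epsilon, min_medications = as.integer(min_medications),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

sample_cat <- function(n, dist) {
  sample(names(dist), n, replace = TRUE, prob = dist)
}

# Categories each discrete variable can take across all profiles. Noise
# resampling draws from these pools (not the full vocabulary): after
# z-scoring, a one-hot column with near-zero prevalence puts its carriers
# enormous distances away, which would plant spurious micro-clusters.
profile_pools <- function(profiles) {
  pool_of <- function(get) unique(unlist(lapply(profiles, get)))
  list(race = pool_of(function(p) names(p$race)),
       age = pool_of(function(p) names(p$age)),
       diag = pool_of(function(p) names(p$diag)),
       adm1 = pool_of(function(p) as.character(p$adm[1L])),
       adm2 = pool_of(function(p) as.character(p$adm[2L])),
       adm3 = pool_of(function(p) as.character(p$adm[3L])))
}

# One encounter row (list of character fields) for a patient of cluster g.
synth_row <- function(cfg, g, pools = profile_pools(cfg$profiles)) {
  p <- cfg$profiles[[g]]
  sigma <- cfg$sigma
  flip <- min(sigma, 0.9)
  resample <- function(value, pool) {
    if (length(pool) > 1L && stats::runif(1) < flip) sample(pool, 1L) else value
  }
  row <- list()
  row$race <- resample(sample_cat(1L, p$race), pools$race)
  row$gender <- if (stats::runif(1) < p$p_male) "Male" else "Female"
  row$age <- resample(sample_cat(1L, p$age), pools$age)
  row$weight <- if (stats::runif(1) < 0.97) "?" else "75-100"
  adm <- p$adm
  row$admission_type_id <- as.character(resample(as.character(adm[1L]), pools$adm1))
  row$discharge_disposition_id <- as.character(resample(as.character(adm[2L]), pools$adm2))
  row$admission_source_id <- as.character(resample(as.character(adm[3L]), pools$adm3))
  bounds <- count_bounds()
  scale <- count_noise_scale()
  for (v in count_variables()) {
    val <- round(p$counts[[v]] + stats::rnorm(1L, 0, sigma * scale[[v]]))
    b <- bounds[[v]]
    row[[v]] <- as.character(max(b[1L], min(b[2L], val)))
  }
  row$payer_code <- sample(c("MC", "BC", "SP", "HM", "?"), 1L)
  row$medical_specialty <- if (stats::runif(1) < 0.53) "?" else {
    sample(c("InternalMedicine", "Cardiology", "Family/GeneralPractice"), 1L)
  }
  pool <- icd9_pool()
  diag_cat <- resample(sample_cat(1L, p$diag), pools$diag)
  row$diag_1 <- sample(pool[[diag_cat]], 1L)
  row$diag_2 <- sample(unlist(pool), 1L)
  row$diag_3 <- sample(unlist(pool), 1L)
  row$max_glu_serum <- if (stats::runif(1) < p$p_glu) sample(c("Norm", ">200", ">300"), 1L) else "None"
  row$a1cresult <- if (stats::runif(1) < p$p_a1c) sample(c("Norm", ">7", ">8"), 1L) else "None"
  tokens <- stats::setNames(rep("No", length(drug_columns())), drug_columns())
  tokens[names(p$signature)] <- p$signature
  for (drug in retained_drugs()) {
    if (stats::runif(1) < flip) tokens[[drug]] <- sample(dose_tokens(), 1L)
  }
  for (drug in drug_columns()) row[[drug]] <- tokens[[drug]]
  row$change <- if (any(tokens %in% c("Up", "Down"))) "Ch" else "No"
  row$diabetesmed <- if (any(tokens != "No")) "Yes" else "No"
  row$readmitted <- sample_cat(1L, p$readmit)
  row
}

#' Generate synthetic encounters in the raw schema
#'
#' Draws `n_patients` patients from the configured cluster profiles,
#' injects duplicate encounters and `"?"` missing markers (weight,
#' medical_specialty), and returns the raw rows together with a sidecar
#' ground-truth table that is never written into the data itself.
#'
#' @param config A [synthetic_config()].
#' @return List with `encounters` (data frame in the raw schema, parsed the
#'   same way as [read_encounters()] output) and `truth` (data frame:
#'   `patient_nbr`, `cluster`).
#' @export
generate_encounters <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_patients
  truth_cluster <- sample(seq_len(config$G), n, replace = TRUE,
                          prob = config$proportions)
  data_cluster <- truth_cluster
  if (config$epsilon > 0) {
    flip <- stats::runif(n) < config$epsilon
    for (i in which(flip)) {
      data_cluster[i] <- sample(setdiff(seq_len(config$G), truth_cluster[i]), 1L)
    }
  }
  ids <- sprintf("P%05d", seq_len(n))
  pools <- profile_pools(config$profiles)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    r <- synth_row(config, data_cluster[i], pools)
    r <- c(list(encounter_id = sprintf("E%06d", i), patient_nbr = ids[i]), r)
    rows[[i]] <- r
  }
  dup <- which(stats::runif(n) < config$duplicate_rate)
  k <- n
  for (i in dup) {
    k <- k + 1L
    r <- synth_row(config, data_cluster[i], pools)
    r <- c(list(encounter_id = sprintf("E%06d", k), patient_nbr = ids[i]), r)
    rows[[k]] <- r
  }
  cols <- names(rows[[1L]])
  df <- as.data.frame(do.call(rbind, lapply(rows, function(r) unlist(r[cols]))),
                      stringsAsFactors = FALSE)
  names(df) <- cols
  # duplicates go after the patient's first encounter, order otherwise kept
  ord <- order(match(df$patient_nbr, ids))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  enc <- as_encounters(df)
  list(encounters = enc,
       truth = data.frame(patient_nbr = ids, cluster = truth_cluster,
                          stringsAsFactors = FALSE))
}

#' Write generated encounters to CSV (with sidecar truth file)
#'
#' @param gen Output of [generate_encounters()].
#' @param path CSV path for the raw data.
#' @param truth_path Optional CSV path for the ground-truth labels.
#' @return `path`, invisibly.
#' @export
write_encounters <- function(gen, path, truth_path = NULL) {
  df <- gen$encounters
  for (col in names(df)) {
    v <- as.character(df[[col]])
    v[is.na(v)] <- "?"
    df[[col]] <- v
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth_path)) {
    utils::write.csv(gen$truth, truth_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Generate a rating matrix directly from planted signatures
#'
#' Shortcut generator that skips the raw schema: per-cluster deterministic
#' dose signatures over the retained drugs, token noise `sigma`, labels as
#' planted.
#'
#' @param config A [synthetic_config()].
#' @return List with `matrix` (a [rating_matrix]) and `truth` (data frame).
#' @export
generate_rating_matrix <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  n <- config$n_patients
  cluster <- sample(seq_len(config$G), n, replace = TRUE,
                    prob = config$proportions)
  drugs <- retained_drugs()
  enc <- preprocess_config()$dose_encoding
  flip <- min(config$sigma, 0.9)
  ratings <- matrix(0, n, length(drugs),
                    dimnames = list(sprintf("P%05d", seq_len(n)), drugs))
  for (g in seq_len(config$G)) {
    sig <- stats::setNames(rep("No", length(drugs)), drugs)
    s <- config$profiles[[g]]$signature
    sig[names(s)] <- s
    rows <- which(cluster == g)
    base <- unname(enc[sig])
    for (i in rows) {
      tok <- sig
      do_flip <- stats::runif(length(drugs)) < flip
      tok[do_flip] <- sample(dose_tokens(), sum(do_flip), replace = TRUE)
      ratings[i, ] <- unname(enc[tok])
    }
  }
  list(matrix = rating_matrix(ratings, cluster),
       truth = data.frame(patient_nbr = rownames(ratings), cluster = cluster,
                          stringsAsFactors = FALSE))
}
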