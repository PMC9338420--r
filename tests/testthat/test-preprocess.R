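make_enc <- function(patient, insulin = "No", metformin = "No", ...) {
  df <- data.frame(patient_nbr = patient, insulin = insulin,
                   metformin = metformin, stringsAsFactors = FALSE, ...)
  df
}

test_that("deduplication keeps the first encounter per patient, in order", {
  enc <- make_enc(c("A", "B", "A", "C"), insulin = c("Up", "No", "Down", "No"))
  out <- deduplicate_patients(enc)
  expect_equal(out$patient_nbr, c("A", "B", "C"))
  expect_equal(out$insulin[1], "Up")          # A's first row won
  expect_equal(deduplicate_patients(out), out)  # idempotent
})

test_that("deduplication collapses multi-encounter synthetic patients to one row", {
  enc <- make_enc(rep(sprintf("P%02d", 1:10), each = 3))
  expect_equal(nrow(deduplicate_patients(enc)), 10L)
})

test_that("the medication filter counts non-No drugs against the threshold", {
  enc <- make_enc("A", insulin = "Up", metformin = "Steady")
  expect_equal(nrow(filter_medicated(enc, 2)), 1L)
  enc0 <- make_enc("B")                        # nothing administered
  expect_equal(nrow(filter_medicated(enc0, 1)), 0L)
  expect_error(filter_medicated(enc, -1), "min_medications")

  # brute-force count over a randomly generated 20-record fixture
  set.seed(42)
  n_drugs <- sample(0:3, 20, replace = TRUE)
  enc <- data.frame(patient_nbr = sprintf("P%02d", 1:20),
                    insulin = ifelse(n_drugs >= 1, "Up", "No"),
                    metformin = ifelse(n_drugs >= 2, "Steady", "No"),
                    glipizide = ifelse(n_drugs >= 3, "Down", "No"),
                    stringsAsFactors = FALSE)
  expected <- sum(n_drugs >= 2)
  expect_equal(nrow(filter_medicated(enc, 2)), expected)
})

test_that("ICD-9 codes map onto the nine disease categories", {
  expect_equal(group_diagnosis("250.42"), "diabetes")
  expect_equal(group_diagnosis("428"), "circulatory")
  expect_equal(group_diagnosis("V57"), "other")
  expect_equal(group_diagnosis(c("486", "996", "715", "153", "584", "530",
                                 "785", "788", "E849", NA)),
               c("respiratory", "injury", "musculoskeletal", "neoplasms",
                 "genitourinary", "digestive", "circulatory", "genitourinary",
                 "other", "other"))
})

test_that("age brackets encode to their midpoints", {
  brackets <- sprintf("[%d-%d)", seq(0, 90, 10), seq(10, 100, 10))
  expect_equal(encode_age(brackets), seq(5, 95, 10))
  expect_equal(encode_age("[40-50)"), 45)
  expect_error(encode_age("40-50"), "malformed")
})

test_that("dose tokens encode with the fixed 0/1/2 anchor points", {
  cfg <- preprocess_config()
  expect_equal(encode_dose(c("No", "Down", "Steady", "Up"), cfg), c(0, 1, 1, 2))
  expect_error(encode_dose("Sideways", cfg), "Sideways")
  # order preservation under any admissible config
  cfg2 <- preprocess_config(dose_encoding = c(No = 0, Down = 1, Steady = 2, Up = 2))
  e <- encode_dose(c("No", "Down", "Steady", "Up"), cfg2)
  expect_true(e[1] < e[2] && e[2] <= e[3] && e[3] <= e[4])
  expect_error(preprocess_config(dose_encoding = c(No = 1, Down = 1, Steady = 1, Up = 2)),
               "No the value 0")
  expect_error(preprocess_config(dose_encoding = c(No = 0, Down = 2, Steady = 1, Up = 1)),
               "monotone")
})

test_that("variable selection drops by missingness, imbalance and prevalence with reasons", {
  n <- 40
  enc <- data.frame(
    patient_nbr = sprintf("P%02d", 1:n),
    mostly_missing = c(rep(NA_character_, 39), "x"),   # 97.5% missing
    near_constant = c(rep("same", 39), "diff"),        # 97.5% one value
    balanced = rep(c("a", "b"), n / 2),
    insulin = rep(c("Up", "Steady"), n / 2),
    examide = rep("No", n),                            # administered to nobody
    stringsAsFactors = FALSE)
  cfg <- preprocess_config(explicit_drop = character(0))
  sel <- select_variables(enc, cfg)
  rep <- sel$drop_report
  expect_equal(rep$reason[rep$column == "mostly_missing"], "missingness")
  expect_equal(rep$reason[rep$column == "near_constant"], "imbalance")
  expect_equal(rep$reason[rep$column == "examide"], "prevalence")
  expect_true("balanced" %in% names(sel$data))
  expect_true("insulin" %in% names(sel$data))
  # completeness: every column is in the output or reported exactly once
  expect_equal(sort(c(setdiff(names(sel$data), "patient_nbr"),
                      setdiff(rep$column, "patient_nbr"))),
               sort(setdiff(names(enc), "patient_nbr")))
  expect_false(anyDuplicated(rep$column) > 0)
})

test_that("the packaged 50-row fixture reproduces its hand-counted reductions", {
  enc <- read_encounters(fixture_path())
  expect_equal(nrow(enc), 50L)
  expect_equal(length(unique(enc$patient_nbr)), 45L)
  tab <- build_feature_table(enc)
  expect_equal(nrow(tab), 38L)             # 45 unique - 7 under-medicated
  rep <- attr(tab, "drop_report")
  reason_of <- function(col) rep$reason[rep$column == col]
  expect_equal(reason_of("weight"), "missingness")
  expect_equal(reason_of("medical_specialty"), "missingness")
  expect_equal(reason_of("admission_type_id"), "imbalance")
  expect_equal(reason_of("payer_code"), "irrelevant")
})

test_that("feature tables are numeric, complete, with one-hot groups summing to one", {
  enc <- read_encounters(fixture_path())
  tab <- build_feature_table(enc)
  vals <- tab[, setdiff(names(tab), "patient_id")]
  expect_false(anyNA(vals))
  expect_true(all(vapply(vals, is.numeric, TRUE)))
  races <- c("AfricanAmerican", "Asian", "Caucasian", "Hispanic", "Other")
  expect_equal(unname(rowSums(tab[, races])), rep(1, nrow(tab)))
  expect_equal(unname(rowSums(tab[, diagnosis_groups()])), rep(1, nrow(tab)))
  expect_false(anyDuplicated(tab$patient_id) > 0)
})

test_that("raising thresholds never enlarges the surviving set", {
  enc <- read_encounters(fixture_path())
  n_at <- function(m) nrow(build_feature_table(enc, preprocess_config(min_medications = m)))
  counts <- vapply(0:3, n_at, 1L)
  expect_true(all(diff(counts) <= 0))
  drugs_at <- function(p) length(attr(build_feature_table(
    enc, preprocess_config(min_drug_prevalence = p)), "drug_cols"))
  dcounts <- vapply(c(0, 0.02, 0.06, 0.2), drugs_at, 1L)
  expect_true(all(diff(dcounts) <= 0))
})
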