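test_that("cosine similarity reproduces the worked matrix values", {
  m <- example_rating_matrix()
  expect_equal(cosine_similarity(m$ratings[1, ], m$ratings[3, ]),
               3 / sqrt(30), tolerance = 1e-12)
  u <- c(1, 0, 2, 1)
  expect_equal(cosine_similarity(u, u), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(0, 0), c(1, 2)), 0)  # zero-vector convention
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("cosine similarity is symmetric, scale-invariant and matches the oracle", {
  set.seed(3)
  for (i in 1:30) {
    u <- sample(0:2, 6, replace = TRUE)
    v <- sample(0:2, 6, replace = TRUE)
    expect_equal(cosine_similarity(u, v), cosine_similarity(v, u))
    expect_equal(cosine_similarity(u, 3 * v), cosine_similarity(u, v))
    expect_equal(cosine_similarity(u, v), oracle_cosine(u, v), tolerance = 1e-12)
  }
})

test_that("prediction uses same-cluster neighbours with nonzero ratings only", {
  m <- example_rating_matrix()
  # patient 3's only same-cluster neighbour with medication_3 is patient 1
  p <- predict_rating(m, "patient_3", "medication_3")
  expect_equal(p$rating, 2)
  expect_equal(p$provenance, "neighbors")
  expect_error(predict_rating(m, "nobody", "medication_3"), "unknown patient")
  expect_error(predict_rating(m, "patient_3", "aspirin"), "unknown drug")
})

test_that("unanimous neighbourhoods predict their shared rating exactly", {
  ratings <- rbind(a = c(2, 1), b = c(2, 0), c = c(2, 2), d = c(0, 1))
  colnames(ratings) <- c("x", "y")
  m <- rating_matrix(ratings, cluster = c(1, 1, 1, 1))
  expect_equal(predict_rating(m, "d", "x")$rating, 2)
})

test_that("fallbacks fire in order: neighbours, cluster mean, global mean", {
  ratings <- rbind(a = c(2, 0, 0), b = c(1, 0, 0), c = c(0, 2, 0))
  colnames(ratings) <- c("x", "y", "z")
  m <- rating_matrix(ratings, cluster = c(1, 1, 2))
  # y never rated in cluster 1 -> global mean (patient c's 2)
  p <- predict_rating(m, "a", "y")
  expect_equal(p$provenance, "global_mean")
  expect_equal(p$rating, 2)
  # z never rated anywhere -> no estimate, rating 0
  p0 <- predict_rating(m, "a", "z")
  expect_equal(p0$provenance, "none")
  expect_equal(p0$rating, 0)
  # orthogonal same-cluster rows: no positive-similarity neighbour for x
  ortho <- rating_matrix(rbind(a = c(2, 0), b = c(0, 1)), cluster = c(1, 1))
  colnames(ortho$ratings) <- c("x", "y")
  pb <- predict_rating(ortho, "b", "x")
  expect_equal(pb$provenance, "cluster_mean")
  expect_equal(pb$rating, 2)
})

test_that("an identical duplicate row dominates its twin's predictions", {
  ratings <- rbind(a = c(1, 0, 2, 1), a2 = c(1, 0, 2, 1), z = c(0, 2, 0, 0))
  colnames(ratings) <- paste0("d", 1:4)
  m <- rating_matrix(ratings, cluster = c(1, 1, 2))
  for (drug in c("d1", "d3", "d4")) {
    expect_equal(predict_rating(m, "a", drug)$rating,
                 unname(ratings["a2", drug]))
  }
})

test_that("matrix completion preserves observations and bounds neighbour predictions", {
  m <- example_rating_matrix()
  cm <- complete_matrix(m)
  obs <- m$ratings > 0
  expect_equal(sum(obs), 13L)                 # the worked matrix has 13 ratings
  expect_equal(cm$rating[obs], m$ratings[obs])
  expect_equal(cm$provenance[obs], rep("observed", 13))
  expect_equal(sum(!obs), 7L)
  expect_true(all(cm$rating[!obs] >= 0))
  nb <- !obs & cm$provenance == "neighbors"
  expect_true(all(cm$rating[nb] >= 1 & cm$rating[nb] <= 2))
  # a matrix with no zeros is returned unchanged
  dense <- rating_matrix(matrix(1, 3, 2, dimnames = list(letters[1:3], c("x", "y"))),
                         cluster = c(1, 1, 2))
  expect_equal(complete_matrix(dense)$rating, dense$ratings)
})

test_that("neighbour predictions are convex combinations of neighbour ratings", {
  for (seed in 1:10) {
    m <- random_rating_matrix(n = 15, d = 6, g = 2, seed = seed)
    cm <- complete_matrix(m)
    nb <- cm$provenance == "neighbors" & m$ratings == 0
    if (!any(nb)) next
    for (idx in which(nb)) {
      j <- (idx - 1) %/% nrow(m$ratings) + 1
      others <- m$ratings[, j][m$ratings[, j] > 0]
      expect_true(cm$rating[idx] >= min(others) - 1e-12 &&
                    cm$rating[idx] <= max(others) + 1e-12)
    }
  }
})

test_that("top-N ranking is deterministic with alphabetical tie-breaks", {
  ratings <- rbind(p1 = c(A = 2, B = 1.4, C = 1.4, D = 0.2),
                   p2 = c(A = 2, B = 2, C = 2, D = 2))
  m <- rating_matrix(ratings, cluster = c(1, 1))
  rec <- recommend_top_n(m, "p1", n = 3)
  expect_equal(rec$drugs, c("A", "B", "C"))
  expect_true(all(diff(rec$scores) <= 0))
  expect_false(anyDuplicated(rec$drugs) > 0)
  expect_warning(rec_all <- recommend_top_n(m, "p1", n = 10), "exceeds")
  expect_equal(length(rec_all$drugs), 4L)
  expect_error(recommend_top_n(m, "p1", n = 0), "n must be")
})

test_that("recommendations for the worked matrix rank the completed row", {
  m <- example_rating_matrix()
  cm <- complete_matrix(m)
  rec1 <- recommend_top_n(m, "patient_3", n = 1)
  row <- cm$rating["patient_3", ]
  expect_equal(unname(row[rec1$drugs]), max(row))
  # excluding administered drugs removes them from the candidate set
  rec_ex <- recommend_top_n(m, "patient_3", n = 2, exclude_administered = TRUE)
  expect_true(all(m$ratings["patient_3", rec_ex$drugs] == 0))
})

test_that("rating matrices validate labels and expose the worked example faithfully", {
  expect_error(rating_matrix(matrix(1, 2, 2, dimnames = list(c("a", "b"), NULL)),
                             cluster = 1L), "cluster")
  m <- example_rating_matrix()
  expect_equal(dim(m$ratings), c(5L, 4L))
  expect_equal(m$cluster, c(1L, 2L, 1L, 3L, 2L))
  expect_equal(unname(m$ratings[1, ]), c(1, 0, 2, 1))
  expect_equal(unname(m$ratings[5, ]), c(1, 1, 2, 0))
  # test-time all-zero row is valid
  ok <- rating_matrix(rbind(a = c(0, 0), b = c(1, 2)), cluster = c(1, 1))
  expect_equal(unname(ok$ratings["a", ]), c(0, 0))
})

test_that("build_rating_matrix carries drug columns and labels through", {
  enc <- read_encounters(fixture_path())
  tab <- build_feature_table(enc)
  labels <- rep_len(1:2, nrow(tab))
  m <- build_rating_matrix(tab, labels)
  expect_equal(rownames(m$ratings), tab$patient_id)
  expect_setequal(colnames(m$ratings), attr(tab, "drug_cols"))
  expect_error(build_rating_matrix(tab, labels[-1]), "cluster")
})
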