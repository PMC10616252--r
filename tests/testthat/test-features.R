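test_that("one-hot encoding reproduces the standard binary codes", {
  enc <- one_hot_encode(meta_fixture(gender = c("Male", "Female"), age = c(30, 36)))
  expect_equal(unlist(enc[1, c("gender_Male", "gender_Female")], use.names = FALSE), c(1, 0))
  expect_equal(unlist(enc[2, c("gender_Male", "gender_Female")], use.names = FALSE), c(0, 1))
  expect_equal(unlist(enc[2, c("age_Young", "age_Middle", "age_Old")], use.names = FALSE),
               c(0, 1, 0))
})

test_that("age and BMI bin boundaries follow the printed definitions", {
  enc <- one_hot_encode(meta_fixture(age = c(35, 36, 59, 60), bmi = c(18.4, 18.5, 23.95, 24)))
  age_cat <- c("age_Young", "age_Middle", "age_Old")
  expect_equal(apply(enc[age_cat], 1, which.max), c(1, 2, 2, 3), ignore_attr = TRUE)
  bmi_cat <- c("bmi_Low", "bmi_Middle", "bmi_High")
  expect_equal(apply(enc[bmi_cat], 1, which.max), c(1, 2, 2, 3), ignore_attr = TRUE)
})

test_that("encoding has one active bit per variable and is invertible", {
  set.seed(31)
  meta <- meta_fixture(gender = sample(c("Male", "Female"), 25, TRUE),
                       age = sample(20:80, 25, TRUE),
                       bmi = runif(25, 16, 32),
                       probiotics = sample(c("yes", "no"), 25, TRUE),
                       health_status = sample(c("healthy", "unhealthy"), 25, TRUE))
  spec <- encoding_spec()
  enc <- one_hot_encode(meta, spec)
  m <- as.matrix(enc[-1])
  expect_true(all(rowSums(m) == length(spec$variables)))
  # invert the gender block
  got <- spec$categories$gender[apply(enc[c("gender_Male", "gender_Female")], 1, which.max)]
  expect_equal(got, meta$gender)
})

test_that("unmappable metadata values fail loudly, naming the sample", {
  meta <- meta_fixture(gender = c("Male", "Malformed"))
  expect_error(one_hot_encode(meta), "S02")
  expect_error(one_hot_encode(meta_fixture(age = -3)), "age")
})

test_that("fusion concatenates genus-first and L2-normalizes rows", {
  microbial <- tibble::tibble(sample_id = c("A", "B"), g__x = c(3, 0), g__y = c(4, 0))
  encoded <- tibble::tibble(sample_id = c("A", "B"), gender_Male = c(0, 0), gender_Female = c(0, 0))
  expect_warning(fused <- fuse_and_normalize(microbial, encoded), "all-zero")
  expect_equal(names(fused), c("sample_id", "g__x", "g__y", "gender_Male", "gender_Female"))
  expect_equal(unlist(fused[1, -1], use.names = FALSE), c(0.6, 0.8, 0, 0))
  expect_equal(unlist(fused[2, -1], use.names = FALSE), rep(0, 4))

  swapped <- encoded[2:1, ]
  expect_error(fuse_and_normalize(microbial, swapped), "sample order")
})

test_that("fused rows have unit L2 norm and expected dimension", {
  d <- small_cohort(seed = 21, n = 30)
  enc <- one_hot_encode(d$metadata)
  bio10 <- genus_columns(d$abundance)[1:10]
  fused <- fuse_and_normalize(d$abundance[c("sample_id", bio10)], enc)
  expect_equal(ncol(fused) - 1, 10 + ncol(enc) - 1)
  norms <- sqrt(rowSums(as.matrix(fused[-1])^2))
  expect_true(all(abs(norms - 1) < 1e-9))
})

test_that("a perfectly separating genus ranks first across seeds", {
  hits <- vapply(1:10, function(s) {
    withr::with_seed(500 + s, {
      n <- 60
      y <- rep(c("LE", "HE"), each = n / 2)
      m <- matrix(runif(n * 6), n)
      m[, 3] <- ifelse(y == "HE", runif(n, 0.8, 1), runif(n, 0, 0.2))
      tbl <- abundance_fixture(m / rowSums(m))
    })
    r <- rank_features(tbl, y, hyperparams = list(nrounds = 50), seed = s)
    r$feature[1] == "g__g3"
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("with permuted labels no feature dominates the ranking across seeds", {
  withr::with_seed(77, {
    n <- 60
    m <- matrix(runif(n * 10), n)
    tbl <- abundance_fixture(m / rowSums(m))
    y0 <- rep(c("LE", "HE"), each = n / 2)
  })
  tops <- vapply(1:20, function(s) {
    y <- withr::with_seed(600 + s, sample(y0))
    rank_features(tbl, y, hyperparams = list(nrounds = 30), seed = s)$feature[1]
  }, character(1))
  expect_lt(max(table(tops)) / 20, 0.5)
})

test_that("duplicated columns share the split importance of the original", {
  withr::with_seed(13, {
    n <- 120
    y <- rep(c("LE", "HE"), each = n / 2)
    base <- matrix(runif(n * 5), n)
    base[, 1] <- ifelse(y == "HE", runif(n, 0.5, 1), runif(n, 0, 0.5))
  })
  tbl_single <- abundance_fixture(base / rowSums(base),
                                  c("g__sig", "g__n1", "g__n2", "g__n3", "g__n4"))
  dup <- cbind(base[, 1, drop = FALSE], base)
  tbl_dup <- abundance_fixture(dup / rowSums(dup),
                               c("g__siga", "g__sigb", "g__n1", "g__n2", "g__n3", "g__n4"))
  hp <- list(nrounds = 60)
  r1 <- rank_features(tbl_single, y, hyperparams = hp, seed = 1)
  r2 <- rank_features(tbl_dup, y, hyperparams = hp, seed = 1)
  single_imp <- r1$importance[r1$feature == "g__sig"]
  combined <- sum(r2$importance[r2$feature %in% c("g__siga", "g__sigb")])
  expect_lt(abs(combined - single_imp) / single_imp, 0.2)
})

test_that("rank_features enforces its preconditions and is deterministic", {
  d <- small_cohort(seed = 3, n = 30)
  expect_error(rank_features(d$abundance, rep("HE", 30)), "both classes")
  expect_error(rank_features(d$abundance[1:5, ], d$y[1:5]), "at least 10")
  r1 <- rank_features(d$abundance, d$y, seed = 5)
  r2 <- rank_features(d$abundance, d$y, seed = 5)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_true(all(diff(r1$importance) <= 0))
})

test_that("the learning curve at k = #features equals the all-feature CV AUC", {
  d <- small_cohort(seed = 8, n = 60)
  r <- rank_features(d$abundance, d$y, hyperparams = list(nrounds = 40), seed = 2)
  n_feat <- nrow(r)
  curve <- learning_curve(r, d$abundance, d$y, k_values = n_feat,
                          hyperparams = list(nrounds = 40), seed = 9)
  # same columns in the ranking's order: boosting is sensitive to
  # column order when splits tie, so align it before comparing
  full <- tune_and_train(d$abundance[c("sample_id", r$feature)], d$y,
                         search_space = data.frame(max_depth = 4, eta = 0.3,
                                                   nrounds = 40, lambda = 1),
                         seed = 9)
  expect_equal(curve$mean_auc, full$cv_auc)
})

test_that("the learning curve plateaus at the biomarker cutoff and declines with all features", {
  res <- vapply(1:10, function(s) {
    d <- small_cohort(seed = 700 + s, n = 100)
    r <- rank_features(d$abundance, d$y, hyperparams = list(nrounds = 50), seed = s)
    curve <- learning_curve(r, d$abundance, d$y, k_values = c(2, 5, 10, 20, 49),
                            hyperparams = list(nrounds = 50), seed = s)
    a <- curve$mean_auc
    c(plateau_gap = max(a) - min(a[curve$k %in% c(5, 10)]),
      decline = a[curve$k == 49] < max(a))
  }, numeric(2))
  # once the five planted genera are in, adding up to the tenth feature
  # moves the CV AUC by little...
  expect_lte(median(res["plateau_gap", ]), 0.03)
  # ...while carrying all 49 genera hurts (the overfitting decline)
  expect_gte(mean(res["decline", ]), 0.8)
})

test_that("select_biomarkers takes the top of the ranking and validates k", {
  r <- structure(tibble::tibble(feature = sprintf("g__%02d", 1:49),
                                importance = seq(49, 1) / 49, rank = 1:49),
                 class = c("se_ranking", class(tibble::tibble())))
  expect_equal(select_biomarkers(r, 10), sprintf("g__%02d", 1:10))
  expect_equal(select_biomarkers(r, 1), "g__01")
  expect_length(select_biomarkers(r, 49), 49)
  expect_error(select_biomarkers(r, 0), "positive")
  expect_error(select_biomarkers(r, 50), "exceeds")
})

test_that("shared_biomarkers equals the set intersection of the top-k sets", {
  mk_ranking <- function(features) {
    structure(tibble::tibble(feature = features,
                             importance = seq(length(features), 1) / length(features),
                             rank = seq_along(features)),
              class = c("se_ranking", class(tibble::tibble())))
  }
  pool <- sprintf("g__m%02d", 1:30)
  shared3 <- c("g__A", "g__B", "g__C")
  r1 <- mk_ranking(c(shared3, pool[1:7]))
  r2 <- mk_ranking(c(pool[8:11], shared3, pool[12:14]))
  r3 <- mk_ranking(c(pool[15:21], shared3))
  expect_equal(shared_biomarkers(list(r1, r2, r3), k = 10), sort(shared3))
  # order-invariant, equal to the mathematical intersection
  expect_equal(shared_biomarkers(list(r3, r1, r2), k = 10),
               sort(Reduce(intersect, list(r1$feature[1:10], r2$feature[1:10], r3$feature[1:10]))))
  expect_equal(shared_biomarkers(list(r1, r1), k = 10), sort(r1$feature[1:10]))
  expect_warning(out <- shared_biomarkers(list(mk_ranking(pool[1:10]), mk_ranking(pool[11:20]))),
                 "no biomarker")
  expect_length(out, 0)
})

test_that("planted biomarkers are recovered by top-10 selection", {
  hits <- vapply(1:20, function(s) {
    d <- small_cohort(seed = 800 + s, n = 150)
    r <- rank_features(d$abundance, d$y, seed = s)
    sum(d$truth$signal_genera %in% select_biomarkers(r, 10))
  }, numeric(1))
  expect_gte(mean(hits >= 4), 0.8)
})
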