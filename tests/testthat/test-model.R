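dummy_model <- function() {
  # tiny fitted model used where only scoring plumbing is under test
  d <- small_cohort(seed = 1, n = 30)
  tune_and_train(d$abundance, d$y,
                 search_space = data.frame(max_depth = 2, eta = 0.3, nrounds = 10, lambda = 1),
                 seed = 1)
}

test_that("AUC follows the rank definition with ties counting one half", {
  scores <- c(0.9, 0.8, 0.1, 0.2)
  y <- c("HE", "HE", "LE", "LE")
  expect_equal(oracle_auc(scores, y), 1)
  expect_equal(oracle_auc(rep(0.5, 4), y), 0.5)
  expect_equal(oracle_auc(c(0.8, 0.4, 0.6, 0.2), y), 0.75)

  m <- dummy_model()
  X <- m$train_X[1:4, , drop = FALSE]
  # evaluate_auc routes through the same rank AUC; check on the trivials
  ev <- evaluate_auc(m, tibble::as_tibble(X, rownames = "sample_id"), m$train_y[1:4])
  expect_equal(ev$auc, oracle_auc(ev$scores$score, as.character(ev$scores$label)))
})

test_that("rank AUC equals the exhaustive pairwise oracle on random instances", {
  m <- dummy_model()
  set.seed(55)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    y <- sample(c("LE", "HE"), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c("LE", "HE")
    # discretised scores force ties
    s <- round(runif(n), 1)
    X <- matrix(0, n, length(m$features), dimnames = list(sprintf("T%d", 1:n), m$features))
    ev <- suppressWarnings(evaluate_auc(m, tibble::as_tibble(X, rownames = "sample_id"), y))
    # oracle applied to the model's actual scores
    expect_equal(ev$auc, oracle_auc(ev$scores$score, y), tolerance = 1e-12)
  }
})

test_that("a single-class test set is flagged, not an error", {
  m <- dummy_model()
  X <- tibble::as_tibble(m$train_X[1:3, , drop = FALSE], rownames = "sample_id")
  expect_warning(ev <- evaluate_auc(m, X, rep("HE", 3)), "single-class")
  expect_true(is.na(ev$auc))
  expect_match(ev$flag, "undefined")
})

test_that("tuning is deterministic and finds strong signal", {
  d <- small_cohort(seed = 40, n = 80, signal_effect = 2.5)
  X <- apply_recipe(feature_recipe(d$truth$signal_genera), d$abundance, d$metadata)
  m1 <- tune_and_train(X, d$y, seed = 6)
  m2 <- tune_and_train(X, d$y, seed = 6)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$train_pred, m2$train_pred)
  expect_gte(m1$cv_auc, 0.95)
  expect_error(tune_and_train(X, rep("LE", nrow(X))), "both classes")
})

test_that("label-permuted training data gives chance-level CV AUC", {
  aucs <- vapply(1:20, function(s) {
    d <- small_cohort(seed = 900 + s, n = 60)
    y <- withr::with_seed(s, sample(as.character(d$y)))
    m <- tune_and_train(d$abundance, y,
                        search_space = data.frame(max_depth = 3, eta = 0.3,
                                                  nrounds = 30, lambda = 1),
                        seed = s)
    m$cv_auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.07)
})

test_that("applying a bundle to its own training cohort reproduces training predictions", {
  d <- small_cohort(seed = 14, n = 50)
  rec <- feature_recipe(genus_columns(d$abundance)[1:10])
  X <- apply_recipe(rec, d$abundance, d$metadata)
  m <- tune_and_train(X, d$y, search_space = data.frame(max_depth = 3, eta = 0.3,
                                                        nrounds = 30, lambda = 1),
                      recipe = rec, seed = 2)
  ev <- transfer_evaluate(m, d$abundance, d$metadata, labels = d$y)
  expect_identical(ev$scores$score, m$train_pred)
  expect_equal(ev$auc, oracle_auc(m$train_pred, as.character(d$y)))
})

test_that("transfer zero-fills genera the target lacks, naming them", {
  d <- small_cohort(seed = 15, n = 50)
  bio <- genus_columns(d$abundance)[1:10]
  rec <- feature_recipe(bio)
  m <- tune_and_train(apply_recipe(rec, d$abundance, d$metadata), d$y,
                      search_space = data.frame(max_depth = 3, eta = 0.3,
                                                nrounds = 30, lambda = 1),
                      recipe = rec, seed = 2)
  target <- d$abundance[setdiff(names(d$abundance), bio[1:3])]
  expect_message(ev <- transfer_evaluate(m, target, d$metadata, labels = d$y),
                 paste(bio[1:3], collapse = ", "))
  expect_false(is.na(ev$auc))
  expect_error(transfer_evaluate(m, d$abundance, d$metadata[, "sample_id"], labels = d$y),
               "variable")
})

test_that("calibration never leaks between calibration and test sets, and n = 0 equals transfer", {
  d2 <- small_cohort(seed = 26, n = 40)
  d1 <- small_cohort(seed = 25, n = 60)
  rec <- feature_recipe(genus_columns(d1$abundance)[1:8])
  m <- tune_and_train(apply_recipe(rec, d1$abundance, d1$metadata), d1$y,
                      search_space = data.frame(max_depth = 3, eta = 0.3,
                                                nrounds = 20, lambda = 1),
                      recipe = rec, seed = 3)
  cal <- calibrate_hybrid(m, d2$abundance, d2$metadata, labels = d2$y,
                          n_mix = c(0, 5, 10), n_repeats = 3, seed = 7)
  draws <- attr(cal, "draws")
  for (i in seq_len(nrow(draws))) {
    expect_length(intersect(draws$test_idx[[i]], draws$calib_idx[[i]]), 0)
  }
  # n = 0 retrains on the base data alone: identical model, so its AUC
  # per repeat equals the base model evaluated on that repeat's test set
  X2 <- sehybrid::apply_recipe(rec, d2$abundance, d2$metadata)
  zero <- draws[draws$n_mixed == 0, ]
  for (i in seq_len(nrow(zero))) {
    idx <- zero$test_idx[[i]]
    ev <- evaluate_auc(m, X2[idx, ], d2$y[idx])
    expect_equal(zero$auc[i], ev$auc)
  }
  expect_warning(
    calibrate_hybrid(m, d2$abundance, d2$metadata, labels = d2$y,
                     n_mix = c(5, 400), n_repeats = 2, seed = 1),
    "skipped")
})

test_that("with no batch shift the calibration curve is flat", {
  spec <- synthetic_spec(n_samples_per_batch = c(100, 80), batch_to_region = c(1, 1),
                         stages = "before", batch_shift_sd = 0, seed = 33)
  co <- generate_cohort(spec)
  lab <- derive_absorption_labels(co$metadata)
  b1 <- lab$batch == "Batch1"
  ab1 <- co$abundance[b1, ]; ab2 <- co$abundance[!b1, ]
  r <- rank_features(ab1, lab$efficiency[b1], seed = 1)
  rec <- feature_recipe(select_biomarkers(r, 10))
  m <- tune_and_train(apply_recipe(rec, ab1, lab[b1, ]), lab$efficiency[b1],
                      search_space = data.frame(max_depth = 3, eta = 0.3,
                                                nrounds = 50, lambda = 1),
                      recipe = rec, seed = 1)
  cal <- calibrate_hybrid(m, ab2, lab[!b1, ], labels = lab$efficiency[!b1], seed = 1)
  expect_lte(max(cal$auc_mean) - min(cal$auc_mean), 0.08)
})

test_that("cross-cohort refinement with the full set on the base cohort is the identity case", {
  d <- small_cohort(seed = 44, n = 60)
  bio <- genus_columns(d$abundance)[1:10]
  rec <- feature_recipe(bio)
  src <- list(abundance = d$abundance, metadata = d$metadata, labels = d$y)
  m <- tune_and_train(apply_recipe(rec, d$abundance, d$metadata), d$y,
                      search_space = data.frame(max_depth = 3, eta = 0.3,
                                                nrounds = 30, lambda = 1),
                      recipe = rec, source_data = src, seed = 4)
  ref <- cross_cohort_refine(m, bio, d$abundance, d$metadata, labels = d$y)
  # same features, same data, same params: target evaluation reproduces
  # the refit's training predictions
  expect_identical(ref$evaluation$scores$score, ref$model$train_pred)
  expect_equal(ref$evaluation$auc, oracle_auc(ref$model$train_pred, as.character(d$y)))

  expect_error(cross_cohort_refine(m, character(0), d$abundance, d$metadata),
               "shared_biomarkers")
  expect_error(cross_cohort_refine(m, "g__NotThere", d$abundance, d$metadata),
               "absent")
})

test_that("tidy and glance methods expose importance and fit summaries", {
  m <- dummy_model()
  td <- generics::tidy(m)
  expect_setequal(names(td), c("feature", "weight", "gain"))
  expect_setequal(td$feature, m$features)
  gl <- generics::glance(m)
  expect_equal(gl$cv_auc, m$cv_auc)
  ev <- evaluate_auc(m, tibble::as_tibble(m$train_X, rownames = "sample_id"), m$train_y)
  expect_equal(generics::glance(ev)$auc, ev$auc)
  expect_equal(nrow(generics::tidy(ev)), nrow(m$train_X))
})
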