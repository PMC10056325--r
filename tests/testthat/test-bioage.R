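test_that("train/test split is exact, disjoint, exhaustive and seeded", {
  tab <- data.frame(id = 1:10)
  parts <- split_train_test(tab, 0.8, seed = 5)
  expect_equal(nrow(parts$train), 8L)
  expect_equal(nrow(parts$test), 2L)
  expect_length(intersect(parts$train$id, parts$test$id), 0L)
  expect_setequal(c(parts$train$id, parts$test$id), tab$id)
  expect_identical(split_train_test(tab, 0.8, seed = 5), parts)
  expect_false(identical(split_train_test(tab, 0.8, seed = 6), parts))
  expect_error(split_train_test(tab, 1.2, seed = 1), "\\(0, 1\\)")
  expect_error(split_train_test(tab[0, , drop = FALSE], 0.8, 1), "non-empty")
})

test_that("clock configuration enforces its invariants", {
  expect_error(bioage_config(epochs = 0), "epochs")
  expect_error(bioage_config(train_fraction = 1), "train_fraction")
  expect_length(bioage_config()$input_features, 38L)
})

small_clock_cohort <- function(n = 1200, seed = 41) {
  generate_cohort(cohort_config(n_subjects = n, seed = seed,
                                missingness_rates = numeric(0),
                                diet_missing_rate = 0))
}

test_that("clock training is deterministic and errors on missing features", {
  tab <- small_clock_cohort()
  cfg <- bioage_config(hidden = 4L, epochs = 60L, seed = 3L)
  m1 <- train_bioage(tab, cfg)
  m2 <- train_bioage(tab, cfg)
  expect_equal(predict(m1, tab), predict(m2, tab), tolerance = 1e-6)
  bad <- tab[setdiff(names(tab), "bm_glucose")]
  expect_error(train_bioage(bad, cfg), "bm_glucose")
})

test_that("delta-age is exactly BA minus CA and shifts with the CA origin", {
  tab <- small_clock_cohort()
  model <- train_bioage(tab, bioage_config(hidden = 4L, epochs = 80L, seed = 3L))
  da <- predict_delta_age(model, tab)
  expect_identical(da$delta_age, da$ba - da$ca)
  shifted <- tab
  shifted$age <- shifted$age + 5
  da2 <- predict_delta_age(model, shifted)
  expect_equal(da2$delta_age, da$delta_age - 5, tolerance = 1e-9)
  # training-set mean delta-age ~ 0 for an (approximately) unbiased fit
  expect_lt(abs(mean(da$delta_age)),
            2 * sd(da$delta_age) / sqrt(nrow(da)) + 0.2)
})

test_that("permutation importance isolates the informative feature", {
  # hand-built signal: one biomarker carries all the age signal; importance
  # is evaluated on a held-out half so overfit noise features stay quiet
  tab <- small_clock_cohort(n = 2400, seed = 43)
  set.seed(44)
  for (nm in bm_cols()) tab[[nm]] <- rnorm(nrow(tab))
  tab$bm_glucose <- tab$age + rnorm(nrow(tab), 0, 2)
  train <- tab[1:1500, ]
  tab <- tab[1501:2400, ] # held-out evaluation set
  model <- train_bioage(train, bioage_config(hidden = 3L, epochs = 150L, seed = 5L))
  imp <- permutation_importance(model, tab, n_permutations = 5L, seed = 6L)
  expect_gt(imp$loss_drop[imp$feature == "bm_glucose"], 0.05)
  expect_true(imp$influential[imp$feature == "bm_glucose"])
  noise_drop <- imp$loss_drop[imp$feature %in%
                                setdiff(bm_cols(), "bm_glucose")]
  expect_lt(max(abs(noise_drop)), 0.05)
  # a constant column has exactly zero permutation importance
  tab$bm_crp <- 1.7
  imp2 <- permutation_importance(model, tab, n_permutations = 3L, seed = 7L)
  expect_equal(imp2$loss_drop[imp2$feature == "bm_crp"], 0, tolerance = 1e-12)
  # seeded repeat is identical
  expect_identical(permutation_importance(model, tab, 3L, seed = 7L), imp2)
  expect_error(permutation_importance(model, tab, 0L), "n_permutations")
  expect_error(permutation_importance(model, tab[0, ], 3L), "non-empty")
})

test_that("row-level biomarker QC drops heavily incomplete records", {
  tab <- small_clock_cohort(n = 400, seed = 45)
  tab[1:5, bm_cols()[1:20]] <- NA   # > max_missing_biomarkers
  tab[6, bm_cols()[1]] <- NA        # below threshold: median-imputed
  model <- train_bioage(tab, bioage_config(hidden = 3L, epochs = 40L, seed = 2L))
  expect_equal(model$n_dropped_qc, 5L)
  expect_equal(model$n_train, 395L)
})
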