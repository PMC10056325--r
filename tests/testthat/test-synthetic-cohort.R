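test_that("generation is deterministic given the seed", {
  cfg <- cohort_config(n_subjects = 100, seed = 7)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- cohort_config(n_subjects = 100, seed = 8)
  expect_false(identical(generate_cohort(cfg), generate_cohort(cfg2)))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(cohort_config(n_subjects = 0, seed = 1), "n_subjects")
  expect_error(cohort_config(n_subjects = 10, seed = 1, male_fraction = 1.2),
               "male_fraction")
  expect_error(cohort_config(n_subjects = 10, seed = 1,
                             age_range = c(90, 35)), "age_range")
  expect_error(cohort_config(n_subjects = 10, seed = 1,
                             missingness_rates = c(bmi = 2)),
               "missingness_rates")
  expect_error(cohort_config(n_subjects = 10, seed = 1,
                             missingness_rates = c(shoe_size = 0.1)),
               "missingness_rates")
  short_panel <- setNames(rep(1, 35), biomarker_names()[1:35])
  expect_error(cohort_config(n_subjects = 10, seed = 1,
                             biomarker_age_slopes = short_panel),
               "biomarker_age_slopes")
})

test_that("generated marginals respect the configuration", {
  cfg <- cohort_config(n_subjects = 4510, seed = 21, male_fraction = 0.52)
  tab <- generate_cohort(cfg)
  expect_true(all(tab$age >= 35 & tab$age <= 90))
  expect_true(all(is.na(tab$energy) | tab$energy > 0))
  expect_equal(sum(grepl("^bm_", names(tab))), 36L)
  # male count within the binomial 99% band around 0.52 * 4510 = 2345
  males <- sum(tab$sex == "male")
  expect_gte(males, qbinom(0.005, 4510, 0.52))
  expect_lte(males, qbinom(0.995, 4510, 0.52))
})

test_that("MCAR masks hit only the requested covariates at the given rate", {
  cfg <- cohort_config(n_subjects = 300, seed = 3,
                       missingness_rates = numeric(0),
                       diet_missing_rate = 0)
  tab <- generate_cohort(cfg)
  expect_identical(inject_missingness(tab, numeric(0)), tab)
  out0 <- inject_missingness(tab, c(bmi = 0), seed = 4)
  expect_identical(out0, tab)
  out1 <- inject_missingness(tab, c(bmi = 1), seed = 4)
  expect_true(all(is.na(out1$bmi)))
  expect_false(anyNA(tab$bmi))  # input untouched
  expect_identical(out1[names(out1) != "bmi"], tab[names(tab) != "bmi"])
  expect_error(inject_missingness(tab, c(not_a_column = 0.5)), "not_a_column")
  expect_error(inject_missingness(tab, c(bmi = -0.1)), "0, 1")
})

test_that("hormone-therapy missingness rate reproduces the expected count", {
  # rate 0.0226 on n = 4510 has expectation ~102 missing records
  cfg <- cohort_config(n_subjects = 4510, seed = 13,
                       missingness_rates = c(hormone_therapy = 102 / 4510),
                       diet_missing_rate = 0)
  tab <- generate_cohort(cfg)
  n_miss <- sum(is.na(tab$hormone_therapy))
  expect_gte(n_miss, qbinom(0.0005, 4510, 102 / 4510))
  expect_lte(n_miss, qbinom(0.9995, 4510, 102 / 4510))
})

test_that("direct-mode delta-age carries the configured effect structure", {
  cfg <- mc_config(seed = 31, n = 6000, beta = 0.4,
                   missingness = numeric(0))
  sc <- scored_cohort(cfg)
  fit <- lm(delta_age ~ edii_std + age + sex, data = sc)
  b <- coef(summary(fit))["edii_std", ]
  expect_lt(abs(b["Estimate"] - 0.4), 3.5 * b["Std. Error"])
  # marginal delta-age SD near the calibrated 7.7 y
  expect_gt(sd(sc$delta_age), 6.5)
  expect_lt(sd(sc$delta_age), 9.0)
})

test_that("mediated mode shifts only the responsive biomarkers", {
  base <- cohort_config(n_subjects = 5000, seed = 17, beta_true = 0,
                        missingness_rates = numeric(0))
  high <- cohort_config(n_subjects = 5000, seed = 17, beta_true = 8,
                        missingness_rates = numeric(0))
  t0 <- generate_cohort(base)
  t1 <- generate_cohort(high)
  panel <- biomarker_panel()
  resp <- paste0("bm_", panel$name[panel$diet_responsive == 1])
  inert <- paste0("bm_", panel$name[panel$diet_responsive == 0])
  expect_identical(t1[inert], t0[inert])
  # the shift is beta * slope * standardized score, so columns move
  # subject-wise even though the cohort mean shift is ~0
  d_resp <- max(abs(as.matrix(t1[resp]) - as.matrix(t0[resp])))
  expect_gt(d_resp, 0.01)
})
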