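test_that("model specs encode the two adjustment sets", {
  expect_false("energy" %in% model_spec("edii", "minimal")$covariates)
  expect_true("energy" %in% model_spec("dis", "minimal")$covariates)
  mv <- model_spec("edii", "multivariable")$covariates
  expect_true(all(c("education", "housing", "urban", "leisure_pa", "smoking",
                    "bmi", "cvd", "cancer", "diabetes", "hypertension",
                    "hyperlipidemia", "menopause", "hormone_therapy") %in% mv))
})

test_that("OLS recovers an exact noiseless effect and flags collinearity", {
  set.seed(61)
  n <- 120
  tab <- data.frame(
    edii_std = rnorm(n), age = runif(n, 35, 90),
    sex = factor(sample(c("male", "female"), n, TRUE),
                 levels = c("male", "female")))
  tab$delta_age <- 0.30 * tab$edii_std
  # the noiseless construct makes lm warn about a perfect fit; that is the point
  fit <- suppressWarnings(fit_model(tab, model_spec("edii", "minimal")))
  expect_equal(unname(fit$coef["edii_std"]), 0.30, tolerance = 1e-10)
  expect_error(fit_model(tab, model_spec("edii", "minimal"),
                         extra_terms = "I(age * 1)"),
               "collinear")
})

test_that("Rubin pooling matches hand-computed values and its identities", {
  pooled <- pool_rubin(c(1, 3), c(1, 1))
  expect_equal(pooled$beta, 2)
  expect_equal(pooled$W, 1)
  expect_equal(pooled$B, 2)
  expect_equal(pooled$T_var, 4) # W + (1 + 1/2) * B
  expect_equal(pooled$se, 2)
  same <- pool_rubin(rep(1.7, 5), rep(0.04, 5))
  expect_equal(same$B, 0)
  expect_equal(same$T_var, same$W)
  set.seed(62)
  for (i in 1:20) {
    m <- sample(2:12, 1)
    b <- rnorm(m); v <- runif(m, 0.1, 2)
    p <- pool_rubin(b, v, dfcom = sample(c(50, 500, Inf), 1))
    expect_equal(p$T_var, p$W + (1 + 1 / m) * p$B, tolerance = 1e-12)
    expect_gte(p$T_var, p$W)
    expect_equal(p$beta, mean(b))
  }
  expect_error(pool_rubin(1, 1), "at least 2")
})

test_that("imputation preserves observed data and is seeded", {
  cfg <- mc_config(seed = 63, n = 700)
  sc <- scored_cohort(cfg)
  imp <- impute(sc, imputation_config(m = 3, seed = 9))
  expect_length(imp, 3L)
  for (tt in imp) {
    expect_false(anyNA(tt[covariate_cols <- intersect(
      c("bmi", "smoking", "education", "cvd", "hormone_therapy"),
      names(tt))]))
    for (v in covariate_cols) {
      obs <- !is.na(sc[[v]])
      expect_identical(tt[[v]][obs], sc[[v]][obs])
    }
  }
  expect_identical(impute(sc, imputation_config(m = 3, seed = 9)), imp)
  expect_false(identical(imp[[1]], imp[[2]]))
  # complete data -> m identical copies, and pooling equals the single fit
  sc0 <- scored_cohort(mc_config(seed = 64, n = 700,
                                 missingness = numeric(0)))
  imp0 <- impute(sc0, imputation_config(m = 4, seed = 9))
  expect_identical(imp0[[1]], sc0)
  expect_identical(imp0[[2]], imp0[[3]])
  spec <- model_spec("edii", "multivariable")
  pooled <- fit_pooled(imp0, spec)
  single <- fit_model(sc0, spec)
  expect_equal(coef(pooled), single$coef)
  expect_equal(pooled$pooled$B, rep(0, length(single$coef)))
  expect_equal(pooled$pooled$se, sqrt(diag(single$vcov)),
               ignore_attr = TRUE)
  # exposure or outcome missing is an error
  bad <- sc
  bad$delta_age[1] <- NA
  expect_error(impute(bad, imputation_config(m = 2, seed = 1)), "complete")
})

test_that("imputed-covariate coefficients track the complete-data fit", {
  # MCAR 20% missing BMI; pooled BMI coefficient vs complete-data oracle
  set.seed(65)
  diffs <- replicate(60, {
    n <- 500
    tab <- data.frame(
      edii_std = rnorm(n), age = runif(n, 35, 90),
      sex = factor(sample(c("male", "female"), n, TRUE),
                   levels = c("male", "female")),
      bmi = rnorm(n, 28, 4.5))
    tab$delta_age <- 0.3 * tab$edii_std + 0.2 * (tab$bmi - 28) + rnorm(n, 0, 5)
    spec <- model_spec("edii", "minimal")
    full <- fit_model(tab, spec, extra_terms = "bmi")$coef["bmi"]
    masked <- tab
    masked$bmi[runif(n) < 0.2] <- NA
    imp <- impute(masked, imputation_config(m = 5, seed = sample.int(1e6, 1)))
    fits <- lapply(imp, fit_model, spec = spec, extra_terms = "bmi")
    pooled <- pool_rubin(sapply(fits, function(f) f$coef["bmi"]),
                         sapply(fits, function(f) diag(f$vcov)["bmi"]))
    pooled$beta - full
  })
  expect_lt(abs(mean(diffs)), 0.05)
})

test_that("effect estimates are unbiased with nominal coverage (null and strong)", {
  for (beta in c(0, 0.5)) {
    res <- sapply(1:200, function(i) {
      sc <- scored_cohort(mc_config(seed = 70000 + 997 * i + round(1000 * beta),
                                    n = 2000, beta = beta,
                                    missingness = numeric(0)))
      fit <- fit_pooled(list(sc, sc), model_spec("edii", "multivariable"))
      r <- fit$pooled[fit$pooled$term == "edii_std", ]
      c(r$beta, r$ci95_low, r$ci95_high)
    })
    bias <- mean(res[1, ]) - beta
    coverage <- mean(res[2, ] <= beta & res[3, ] >= beta)
    expect_lt(abs(bias), 0.05)
    expect_gte(coverage, 0.90)
    expect_lte(coverage, 0.99)
  }
})

test_that("subgroup analysis recovers sex-specific effects and strata sizes", {
  # injected effects: 0.1 in men, 0.4 in women
  ok <- sapply(1:20, function(i) {
    sc <- scored_cohort(mc_config(seed = 81000 + i, n = 5000, beta = 0.1,
                                  interaction_sex = 0.3,
                                  missingness = numeric(0)))
    sg <- subgroup_analysis(list(sc, sc), model_spec("edii", "multivariable"),
                            "sex")
    sg$beta[sg$stratum == "female"] > sg$beta[sg$stratum == "male"]
  })
  expect_gte(mean(ok), 0.85)
  # age median split gives near-equal strata
  sc <- scored_cohort(mc_config(seed = 82, n = 2001, missingness = numeric(0)))
  sg <- subgroup_analysis(list(sc, sc), model_spec("edii", "minimal"),
                          "age_group")
  expect_lte(abs(sg$n[1] - sg$n[2]), 1L)
})

test_that("interaction test is null-calibrated and guards degenerate modifiers", {
  ps <- sapply(1:20, function(i) {
    sc <- scored_cohort(mc_config(seed = 83000 + i, n = 1500,
                                  missingness = numeric(0)))
    interaction_test(list(sc, sc), model_spec("edii", "multivariable"),
                     "sex")$p_value
  })
  expect_gte(mean(ps > 0.05), 0.80)
  sc <- scored_cohort(mc_config(seed = 84, n = 400, missingness = numeric(0)))
  sc$onelevel <- factor("a")
  expect_error(interaction_test(list(sc, sc), model_spec("edii", "minimal"),
                                "onelevel"), "2 observed levels")
})

test_that("sensitivity suite: leave-one-out stability and small-subset guard", {
  sc <- scored_cohort(mc_config(seed = 85, n = 10000,
                                missingness = numeric(0)))
  spec <- model_spec("edii", "multivariable")
  sens <- sensitivity_suite(list(sc, sc), spec)
  principal <- sens$beta[sens$analysis == "principal"]
  loo <- sens$beta[grepl("^without_", sens$analysis)]
  # comorbidities are independent of the exposure-outcome noise, so removing
  # one at a time barely moves the estimate
  expect_lt(max(abs(loo - principal)), 0.02)
  guarded <- sensitivity_suite(list(sc, sc), spec, min_n = 10^6)
  expect_true(all(!guarded$fitted[grepl("^age_", guarded$analysis)]))
  expect_true(all(is.na(guarded$beta[grepl("^age_", guarded$analysis)])))
  expect_true(guarded$fitted[guarded$analysis == "principal"])
})
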