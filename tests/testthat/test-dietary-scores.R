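test_that("z-scores standardize raw and energy-adjusted intakes", {
  spec <- list(global_mean = 10, global_sd = 2,
               energy_adjusted_mean = 5, energy_adjusted_sd = 1)
  expect_equal(z_score(12, spec), 1.0)
  expect_equal(z_score(10, spec), 0)
  expect_equal(z_score(10 + 2 * 2, spec), 2)
  # density method: 12 g over 2000 kcal = 6 g/1000 kcal -> z = 1
  expect_equal(z_score(12, spec, energy_adjusted = TRUE, energy = 2000), 1.0)
  expect_error(z_score(12, spec, energy_adjusted = TRUE, energy = 0),
               "positive")
  expect_error(z_score(12, spec, energy_adjusted = TRUE), "required")
})

test_that("centered proportion maps z through the normal CDF into (-1, 1)", {
  expect_equal(centered_proportion(0), 0)
  # frozen from the numerical-integration oracle:
  # 2 * integrate(dnorm, -Inf, 1) - 1 = 0.6826894921
  expect_equal(centered_proportion(1), 0.6826894921, tolerance = 1e-9)
  z <- seq(-4, 4, by = 0.37)
  expect_equal(centered_proportion(-z), -centered_proportion(z)) # odd
  expect_true(all(diff(centered_proportion(z)) > 0))             # increasing
  expect_true(all(abs(centered_proportion(c(-30, 30))) <= 1))
  expect_error(centered_proportion(Inf), "finite")
  expect_error(centered_proportion(NA_real_), "finite")
})

test_that("DII of a toy diet matches hand computation and its invariants", {
  reg <- as_food_registry(data.frame(
    name = c("a", "b"), unit = "g",
    global_mean = c(10, 5), global_sd = c(2, 1),
    energy_adjusted_mean = c(5, 2.5), energy_adjusted_sd = c(1, 0.5),
    effect_score = c(0.5, -0.4), stringsAsFactors = FALSE))
  res <- dii_score(c(a = 12, b = 5), reg)
  # hand: cp(1) * 0.5 + cp(0) * (-0.4) = 0.6826895 * 0.5
  expect_equal(res$score, 0.6826894921 * 0.5, tolerance = 1e-9)
  expect_equal(res$score, sum(res$contributions), tolerance = 1e-12)
  # null diet scores exactly 0
  expect_identical(dii_score(c(a = 10, b = 5), reg)$score, 0)
  # missing parameter contributes 0
  expect_equal(dii_score(c(a = 12), reg)$score, 0.6826894921 * 0.5,
               tolerance = 1e-9)
  # contributions bounded by |effect score|
  big <- dii_score(c(a = 1e6, b = -1e6 + 5), reg)
  expect_true(all(abs(big$contributions) <= abs(reg$effect_score)))
  # monotone in a positive-effect parameter
  grid <- sapply(seq(2, 30, by = 0.5), function(x)
    dii_score(c(a = x, b = 7), reg)$score)
  expect_true(all(diff(grid) >= 0))
  expect_error(dii_score(c(a = 1), reg[0, ]), "empty")
})

test_that("DIS is a weighted sum of standardized components", {
  reg <- as_dis_registry(data.frame(
    name = "veg", weight = 2, mean = 100, sd = 20, stringsAsFactors = FALSE))
  expect_equal(as.numeric(dis_score(c(veg = 130), reg)), 3.0) # z = 1.5, w = 2
  expect_identical(as.numeric(dis_score(c(veg = 100), reg)), 0)
  reg2 <- toy_dis_registry(5)
  diet <- setNames(reg2$mean + reg2$sd, reg2$name)
  s1 <- as.numeric(dis_score(diet, reg2))
  reg2$weight <- reg2$weight * 2
  expect_equal(as.numeric(dis_score(diet, reg2)), 2 * s1) # linear in weights
  expect_error(dis_score(diet, reg2[0, ]), "empty")
})

test_that("E-DII is invariant under proportional diet and energy scaling", {
  reg <- toy_food_registry(8)
  dreg <- toy_dis_registry(4)
  tab <- random_diets(50, reg, dreg, seed = 11)
  scaled <- tab
  fp <- grep("^fp_", names(tab), value = TRUE)
  scaled[fp] <- scaled[fp] * 1.3
  scaled$energy <- scaled$energy * 1.3
  s1 <- score_cohort(tab, reg, dreg, energy_adjusted = TRUE)$edii
  s2 <- score_cohort(scaled, reg, dreg, energy_adjusted = TRUE)$edii
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("vectorized scores agree with the scalar brute-force oracle", {
  reg <- toy_food_registry(7, seed = 5)
  dreg <- toy_dis_registry(5, seed = 6)
  tab <- random_diets(150, reg, dreg, seed = 7)
  sc <- score_cohort(tab, reg, dreg, energy_adjusted = TRUE)
  for (i in c(1, 17, 50, 149)) {
    expect_equal(sc$edii[i],
                 oracle_dii(tab[i, ], reg, TRUE, tab$energy[i]),
                 tolerance = 1e-10)
    expect_equal(sc$dis[i], oracle_dis(tab[i, ], dreg), tolerance = 1e-10)
  }
  sc_raw <- score_cohort(tab, reg, dreg, energy_adjusted = FALSE)
  expect_equal(sc_raw$dii[3], oracle_dii(tab[3, ], reg, FALSE),
               tolerance = 1e-10)
})

test_that("score standardization yields mean 0, sample SD 1, idempotently", {
  expect_equal(standardize_scores(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(8)
  x <- rnorm(200, 4, 9)
  z <- standardize_scores(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardize_scores(z), z, tolerance = 1e-12)
  expect_error(standardize_scores(rep(2, 10)), "distinct")
})

test_that("quartile assignment balances groups and respects ties", {
  expect_equal(as.vector(table(quartile_assign(c(8, 1, 5, 3, 7, 2, 6, 4)))),
               c(2, 2, 2, 2))
  set.seed(9)
  q <- quartile_assign(sample(rnorm(4510)))
  sizes <- as.vector(table(q))
  expect_true(all(sizes %in% c(1127, 1128)))
  expect_equal(sum(sizes), 4510)
  # remainder goes to the lower quartiles first
  expect_equal(sizes[1] >= sizes[4], TRUE)
  # ties share a quartile
  qt <- quartile_assign(c(1, 2, 2, 2, 3, 4, 5, 6))
  expect_equal(length(unique(qt[2:4])), 1L)
  expect_warning(q1 <- quartile_assign(rep(3, 10)), "identical")
  expect_true(all(q1 == 1L))
  expect_error(quartile_assign(c(1, 2, 3)), "at least 4")
})
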