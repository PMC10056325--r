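# Shared fixtures: toy registries, random toy diets, and independent
# scalar oracles for the scores.

toy_food_registry <- function(p = 5, seed = 1) {
  set.seed(seed)
  as_food_registry(data.frame(
    name = paste0("par", seq_len(p)),
    unit = "g",
    global_mean = runif(p, 5, 300),
    global_sd = runif(p, 1, 60),
    energy_adjusted_mean = runif(p, 2, 150),
    energy_adjusted_sd = runif(p, 0.5, 30),
    effect_score = round(runif(p, -0.7, 0.5), 3),
    stringsAsFactors = FALSE
  ))
}

toy_dis_registry <- function(p = 4, seed = 2) {
  set.seed(seed)
  as_dis_registry(data.frame(
    name = paste0("grp", seq_len(p)),
    weight = round(runif(p, -1, 1), 3),
    mean = runif(p, 10, 200),
    sd = runif(p, 2, 60),
    stringsAsFactors = FALSE
  ))
}

# random toy diets around the registry references
random_diets <- function(n, food_reg, dis_reg, seed = 3) {
  set.seed(seed)
  fp <- sapply(seq_len(nrow(food_reg)), function(j) {
    pmax(rnorm(n, food_reg$global_mean[j], food_reg$global_sd[j]), 0.01)
  })
  colnames(fp) <- paste0("fp_", food_reg$name)
  dc <- sapply(seq_len(nrow(dis_reg)), function(j) {
    pmax(rnorm(n, dis_reg$mean[j], dis_reg$sd[j]), 0.01)
  })
  colnames(dc) <- paste0("dis_", dis_reg$name)
  cbind(data.frame(subject_id = seq_len(n),
                   energy = runif(n, 1200, 3200)),
        as.data.frame(fp), as.data.frame(dc))
}

# Scalar brute-force oracles: one subject, one parameter at a time.
oracle_dii <- function(row, food_reg, energy_adjusted, energy = NULL) {
  total <- 0
  for (j in seq_len(nrow(food_reg))) {
    x <- row[[paste0("fp_", food_reg$name[j])]]
    if (is.null(x) || is.na(x)) next
    z <- if (energy_adjusted) {
      (x / energy * 1000 - food_reg$energy_adjusted_mean[j]) /
        food_reg$energy_adjusted_sd[j]
    } else {
      (x - food_reg$global_mean[j]) / food_reg$global_sd[j]
    }
    total <- total + (2 * pnorm(z) - 1) * food_reg$effect_score[j]
  }
  total
}

oracle_dis <- function(row, dis_reg) {
  total <- 0
  for (j in seq_len(nrow(dis_reg))) {
    x <- row[[paste0("dis_", dis_reg$name[j])]]
    if (is.null(x) || is.na(x)) next
    total <- total + dis_reg$weight[j] * (x - dis_reg$mean[j]) / dis_reg$sd[j]
  }
  total
}

# one fully scored, standardized analytic table from a config
scored_cohort <- function(cfg) {
  tab <- apply_exclusions(generate_cohort(cfg))$table
  sc <- score_cohort(tab)
  sc$edii_std <- standardize_scores(sc$edii)
  sc$dis_std <- standardize_scores(sc$dis)
  sc
}

# quick direct-mode config used by the Monte-Carlo studies
mc_config <- function(seed, n = 2000, beta = 0.25, interaction_sex = 0,
                      missingness = default_missingness_rates()) {
  cohort_config(n_subjects = n, seed = seed, beta_true = beta,
                interaction_sex = interaction_sex, effect_mode = "direct",
                missingness_rates = missingness)
}
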