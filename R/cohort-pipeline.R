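#' Apply cohort eligibility filters
#'
#' Excludes subjects with missing dietary data, implausible energy intake
#' (below 800 or above 4000 kcal/d in men; below 500 or above 3500 kcal/d
#' in women), or medical/dietary questionnaires judged unreliable
#' (boolean flags supplied by the data). Rules are evaluated independently
#' and combined by union, so per-rule counts need not sum to the number
#' excluded; the filter is idempotent.
#'
#' @param table Cohort data.frame with `sex` and `energy` columns;
#'   reliability flag columns are optional and treated as all-`FALSE` when
#'   absent.
#' @return A list with the retained `table` and an `exclusion_report`
#'   (class `exclusion_report`): `n_input`, per-rule `counts`,
#'   `n_excluded`, `n_retained` and the per-subject logical `hits` matrix.
#' @export
#' @examples
#' tab <- data.frame(sex = factor(c("male", "female"), c("male", "female")),
#'                   energy = c(750, 3400))
#' apply_exclusions(tab)$report$counts
apply_exclusions <- function(table) {
  if (!all(c("sex", "energy") %in% names(table))) {
    stopf("`table` needs `sex` and `energy` columns")
  }
  n <- nrow(table)
  flag <- function(col) {
    v <- table[[col]] %||% rep(FALSE, n)
    v & !is.na(v)
  }
  missing_diet <- is.na(table$energy) | flag("diet_missing")
  men <- table$sex == "male"
  e <- table$energy
  implausible <- !is.na(e) &
    ifelse(men, e < 800 | e > 4000, e < 500 | e > 3500)
  hits <- cbind(
    missing_diet = missing_diet,
    implausible_energy = implausible,
    unreliable_medical = flag("unreliable_medical"),
    unreliable_dietary = flag("unreliable_dietary")
  )
  excluded <- rowSums(hits) > 0
  report <- structure(list(
    n_input = n,
    counts = colSums(hits),
    n_excluded = sum(excluded),
    n_retained = n - sum(excluded),
    hits = hits
  ), class = "exclusion_report")
  list(table = table[!excluded, , drop = FALSE], report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Exclusion report: %d -> %d subjects (%d excluded)\n",
              x$n_input, x$n_retained, x$n_excluded))
  for (r in names(x$counts)) cat(sprintf("  %-20s %d\n", r, x$counts[[r]]))
  invisible(x)
}

#' Body-mass-index class
#'
#' Classifies BMI as normal (<= 25 kg/m2), overweight (> 25 and < 30) or
#' obese (>= 30); both boundaries follow the epidemiological convention
#' that 25.0 is still normal and 30.0 is already obese.
#'
#' @param bmi Numeric BMI in kg/m2, strictly positive (`NA` passes
#'   through).
#' @return Factor with levels `normal`, `overweight`, `obese`.
#' @export
#' @examples
#' derive_bmi_class(c(25, 27.5, 30)) # normal overweight obese
derive_bmi_class <- function(bmi) {
  if (any(!is.na(bmi) & bmi <= 0)) stopf("`bmi` must be strictly positive")
  cls <- ifelse(is.na(bmi), NA_character_,
                ifelse(bmi <= 25, "normal",
                       ifelse(bmi < 30, "overweight", "obese")))
  factor(cls, levels = c("normal", "overweight", "obese"))
}

#' Quartile descriptive table
#'
#' Summarizes the sample overall and across quartiles of an inflammation
#' score: continuous characteristics as mean (SD), categorical ones as
#' column percentages. Each row carries a p-value for association with the
#' quartile index adjusted for sex and chronological age (plus energy for
#' DIS): linear regression for continuous rows, binomial or multinomial
#' logistic regression (likelihood-ratio test) for categorical rows.
#'
#' @param table Scored cohort data.frame (needs the score column plus
#'   whatever characteristics are present).
#' @param score_name `"edii"` or `"dis"` (a column of `table`).
#' @return A data.frame of class `descriptive_table` with columns
#'   `characteristic`, `level`, `all`, `q1`..`q4`, `p_value`; quartile
#'   sizes in attribute `"quartile_n"`.
#' @export
descriptive_table <- function(table, score_name = c("edii", "dis")) {
  score_name <- match.arg(score_name)
  if (!score_name %in% names(table)) {
    stopf("unknown score column `%s`", score_name)
  }
  q <- quartile_assign(table[[score_name]])
  adj <- if (score_name == "dis") c("sex", "age", "energy") else c("sex", "age")
  adj <- intersect(adj, names(table))

  cont_rows <- intersect(c("age", "ba", "delta_age", "bmi", "leisure_pa",
                           "energy", "fp_fiber"), names(table))
  cat_rows <- intersect(c("sex", "education", "housing", "urban", "smoking",
                          "bmi_class", "menopause", "hormone_therapy",
                          "cvd", "cancer", "diabetes", "hypertension",
                          "hyperlipidemia", "comorbidity"), names(table))
  if (!"bmi_class" %in% names(table) && "bmi" %in% names(table)) {
    table$bmi_class <- derive_bmi_class(table$bmi)
    cat_rows <- c(cat_rows, "bmi_class")
  }
  if (!"comorbidity" %in% names(table) &&
      all(c("cvd", "cancer", "diabetes", "hypertension", "hyperlipidemia")
          %in% names(table))) {
    any_com <- rowSums(table[c("cvd", "cancer", "diabetes", "hypertension",
                               "hyperlipidemia")], na.rm = TRUE) > 0
    table$comorbidity <- factor(ifelse(any_com, "one_or_more", "none"),
                                levels = c("none", "one_or_more"))
    cat_rows <- c(cat_rows, "comorbidity")
  }

  adj_rhs <- function(var) paste(setdiff(adj, var), collapse = " + ")
  p_cont <- function(var) {
    rhs <- adj_rhs(var)
    fml <- stats::as.formula(paste(var, "~ q",
                                   if (nzchar(rhs)) paste("+", rhs) else ""))
    fit <- stats::lm(fml, data = cbind(table, q = q))
    stats::coef(summary(fit))["q", "Pr(>|t|)"]
  }
  p_cat <- function(var) {
    d <- cbind(table, q = q)
    d <- d[stats::complete.cases(d[c(var, "q", setdiff(adj, var))]), ]
    y <- droplevels(as.factor(d[[var]]))
    if (nlevels(y) < 2L) return(NA_real_)
    rhs <- adj_rhs(var)
    f1 <- stats::as.formula(paste("y ~ q", if (nzchar(rhs)) paste("+", rhs) else ""))
    f0 <- stats::as.formula(paste("y ~", if (nzchar(rhs)) rhs else "1"))
    if (nlevels(y) == 2L) {
      m1 <- stats::glm(f1, data = d, family = stats::binomial())
      m0 <- stats::glm(f0, data = d, family = stats::binomial())
      stats::pchisq(m0$deviance - m1$deviance, 1, lower.tail = FALSE)
    } else {
      m1 <- nnet::multinom(f1, data = d, trace = FALSE)
      m0 <- nnet::multinom(f0, data = d, trace = FALSE)
      stats::pchisq(m0$deviance - m1$deviance, nlevels(y) - 1,
                    lower.tail = FALSE)
    }
  }

  rows <- list()
  fmt_cell <- function(x) sprintf("%.1f (%.1f)", mean(x, na.rm = TRUE),
                                  stats::sd(x, na.rm = TRUE))
  for (v in cont_rows) {
    cells <- c(fmt_cell(table[[v]]),
               vapply(1:4, function(k) fmt_cell(table[[v]][q == k]),
                      character(1)))
    rows[[length(rows) + 1L]] <- data.frame(
      characteristic = v, level = "mean (SD)",
      all = cells[1], q1 = cells[2], q2 = cells[3], q3 = cells[4],
      q4 = cells[5], p_value = p_cont(v), stringsAsFactors = FALSE)
  }
  for (v in cat_rows) {
    y <- as.factor(table[[v]])
    p <- p_cat(v)
    for (lev in levels(y)) {
      pct <- function(sel) sprintf("%.1f", 100 * mean(y[sel] == lev, na.rm = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        characteristic = v, level = lev,
        all = pct(rep(TRUE, length(y))), q1 = pct(q == 1), q2 = pct(q == 2),
        q3 = pct(q == 3), q4 = pct(q == 4),
        p_value = if (lev == levels(y)[1]) p else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "quartile_n") <- as.integer(table(q))
  attr(out, "score_name") <- score_name
  class(out) <- c("descriptive_table", "data.frame")
  out
}

#' @export
print.descriptive_table <- function(x, ...) {
  cat(sprintf("Descriptive table across %s quartiles (n = %s)\n",
              toupper(attr(x, "score_name")),
              paste(attr(x, "quartile_n"), collapse = "/")))
  print.data.frame(as.data.frame(x), digits = 3, right = FALSE)
  invisible(x)
}
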