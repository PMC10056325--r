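#' Model specification for the delta-age regressions
#'
#' Defines which exposure and covariate set a delta-age linear model uses.
#' The minimal model adjusts for age and sex, plus total energy intake for
#' DIS (the E-DII is already energy-adjusted, so energy is not added
#' there); the multivariable model additionally adjusts for education,
#' housing, urban/rural residence, leisure-time physical activity, smoking,
#' BMI, CVD, cancer, diabetes, hypertension, hyperlipidemia, menopausal
#' status and hormone-replacement therapy. The exposure enters as the
#' standardized score column (`edii_std` / `dis_std`), so coefficients read
#' as years of delta-age per 1 SD of score.
#'
#' @param exposure `"edii"` or `"dis"`.
#' @param model `"minimal"` or `"multivariable"`.
#' @return An object of class `model_spec` with fields `exposure`,
#'   `exposure_col`, `model`, `covariates`.
#' @export
model_spec <- function(exposure = c("edii", "dis"),
                       model = c("multivariable", "minimal")) {
  exposure <- match.arg(exposure)
  model <- match.arg(model)
  covs <- c("age", "sex")
  if (exposure == "dis") covs <- c(covs, "energy")
  if (model == "multivariable") {
    covs <- c(covs, "education", "housing", "urban", "leisure_pa", "smoking",
              "bmi", "cvd", "cancer", "diabetes", "hypertension",
              "hyperlipidemia", "menopause", "hormone_therapy")
  }
  structure(list(exposure = exposure,
                 exposure_col = paste0(exposure, "_std"),
                 model = model, covariates = covs),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> delta_age ~ %s (%s): %s\n", x$exposure_col,
              x$model, paste(x$covariates, collapse = " + ")))
  invisible(x)
}

#' Fit one delta-age linear model
#'
#' Ordinary least squares of `delta_age` on the standardized exposure and
#' the spec's covariates, with conventional (model-based) variances.
#' Covariates that are constant in `table` are dropped with a message (this
#' arises in subgroup strata, e.g. menopausal status among men); a
#' rank-deficient design after that is an error listing the collinear
#' terms.
#'
#' @param table A completed (no missing covariate) data.frame.
#' @param spec A [model_spec()]; `extra_terms` adds raw formula terms
#'   (used internally for interaction products).
#' @param extra_terms Character vector of extra RHS terms.
#' @return A list with `coef`, `vcov`, `sigma`, `df_residual`, `n`.
#' @export
fit_model <- function(table, spec, extra_terms = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  # menopause / hormone therapy carry a structural "not_applicable" level
  # for men; with sex in the model the 3-level coding is collinear with the
  # sex indicator, so these enter as yes/no indicators (men = no)
  if (is.factor(table$menopause) &&
      "not_applicable" %in% levels(table$menopause)) {
    table$menopause <- as.numeric(table$menopause == "post")
  }
  if (is.factor(table$hormone_therapy) &&
      "not_applicable" %in% levels(table$hormone_therapy)) {
    table$hormone_therapy <- as.numeric(table$hormone_therapy == "yes")
  }
  covs <- intersect(spec$covariates, names(table))
  missing_covs <- setdiff(spec$covariates, names(table))
  if (length(missing_covs)) {
    stopf("covariate(s) absent from table: %s",
          paste(missing_covs, collapse = ", "))
  }
  constant <- vapply(covs, function(v) {
    length(unique(stats::na.omit(table[[v]]))) < 2L
  }, logical(1))
  if (any(constant)) {
    message("dropping constant covariate(s): ",
            paste(covs[constant], collapse = ", "))
    covs <- covs[!constant]
  }
  rhs <- paste(c(spec$exposure_col, covs, extra_terms), collapse = " + ")
  fml <- stats::as.formula(paste("delta_age ~", rhs))
  mf <- stats::model.frame(fml, data = table, na.action = stats::na.fail)
  X <- stats::model.matrix(fml, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("rank-deficient design; collinear term(s): %s",
          paste(bad, collapse = ", "))
  }
  fit <- stats::lm(fml, data = table)
  list(coef = stats::coef(fit), vcov = stats::vcov(fit),
       sigma = stats::sigma(fit), df_residual = fit$df.residual,
       n = nrow(X))
}

#' Pool estimates across imputations by Rubin's rules
#'
#' For each term: the pooled estimate is the mean of the per-imputation
#' estimates, the within-imputation variance `W` the mean of the
#' variances, the between-imputation variance `B` the sample variance of
#' the estimates, and the total variance `T = W + (1 + 1/m) B`. Degrees of
#' freedom use the Barnard-Rubin small-sample adjustment when a
#' complete-data residual df is supplied (`dfcom`), otherwise the classical
#' large-sample formula; 95% CIs and two-sided p-values come from the t
#' reference with those df.
#'
#' @param betas Numeric vector (length m) or m-by-k matrix of estimates.
#' @param variances Matching vector or matrix of squared standard errors.
#' @param dfcom Complete-data residual degrees of freedom (`Inf` for the
#'   large-sample formula).
#' @return A data.frame of class `pooled_estimate` with columns `term`,
#'   `beta`, `se`, `ci95_low`, `ci95_high`, `p_value`, `W`, `B`, `T_var`,
#'   `df`, `m`.
#' @export
#' @examples
#' pool_rubin(c(1, 3), c(1, 1)) # beta 2, W 1, B 2, T 4
pool_rubin <- function(betas, variances, dfcom = Inf) {
  if (is.null(dim(betas))) betas <- matrix(betas, ncol = 1)
  if (is.null(dim(variances))) variances <- matrix(variances, ncol = 1)
  m <- nrow(betas)
  if (m < 2L) stopf("Rubin pooling needs at least 2 estimates")
  stopifnot(all(dim(betas) == dim(variances)))
  qbar <- colMeans(betas)
  W <- colMeans(variances)
  B <- apply(betas, 2, stats::var)
  T_var <- W + (1 + 1 / m) * B
  lambda <- (1 + 1 / m) * B / T_var
  df <- ifelse(B <= 0 | lambda < 1e-12, dfcom, {
    df_old <- (m - 1) / pmax(lambda, 1e-12)^2
    if (is.finite(dfcom)) {
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      df_old * df_obs / (df_old + df_obs)
    } else df_old
  })
  se <- sqrt(T_var)
  tcrit <- stats::qt(0.975, df)
  p <- 2 * stats::pt(abs(qbar / se), df, lower.tail = FALSE)
  out <- data.frame(
    term = colnames(betas) %||% paste0("term", seq_along(qbar)),
    beta = qbar, se = se,
    ci95_low = qbar - tcrit * se, ci95_high = qbar + tcrit * se,
    p_value = p, W = W, B = B, T_var = T_var, df = df, m = m,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("pooled_estimate", "data.frame")
  out
}

#' Fit and pool a delta-age model across imputed datasets
#'
#' Fits the specified linear model on each completed dataset and pools all
#' coefficients by Rubin's rules. With no missingness (identical tables)
#' the pooled results equal the single-fit results exactly.
#'
#' @param tables A list of completed data.frames (e.g. from [impute()]).
#' @param spec A [model_spec()].
#' @return An object of class `pooled_fit`: the `pooled_estimate` table,
#'   the spec, `m`, `n`, and `dfcom`.
#' @export
fit_pooled <- function(tables, spec) {
  stopifnot(length(tables) >= 2L)
  fits <- lapply(tables, fit_model, spec = spec)
  terms_ref <- names(fits[[1]]$coef)
  betas <- t(vapply(fits, function(f) f$coef[terms_ref], numeric(length(terms_ref))))
  vars <- t(vapply(fits, function(f) diag(f$vcov)[terms_ref],
                   numeric(length(terms_ref))))
  colnames(betas) <- colnames(vars) <- terms_ref
  pooled <- pool_rubin(betas, vars, dfcom = fits[[1]]$df_residual)
  structure(list(pooled = pooled, spec = spec, m = length(tables),
                 n = fits[[1]]$n, dfcom = fits[[1]]$df_residual),
            class = "pooled_fit")
}

#' @export
print.pooled_fit <- function(x, ...) {
  row <- x$pooled[x$pooled$term == x$spec$exposure_col, ]
  cat(sprintf("Pooled %s model (m = %d imputations, n = %d)\n",
              x$spec$model, x$m, x$n))
  cat(sprintf("  %s: beta = %.3f (95%% CI %.3f, %.3f), p = %.3g\n",
              x$spec$exposure_col, row$beta, row$ci95_low, row$ci95_high,
              row$p_value))
  invisible(x)
}

#' @export
summary.pooled_fit <- function(object, ...) {
  object$pooled
}

#' @export
coef.pooled_fit <- function(object, ...) {
  stats::setNames(object$pooled$beta, object$pooled$term)
}

#' @export
confint.pooled_fit <- function(object, parm = NULL, level = 0.95, ...) {
  p <- object$pooled
  if (!is.null(parm)) p <- p[p$term %in% parm, ]
  tcrit <- stats::qt(1 - (1 - level) / 2, p$df)
  out <- cbind(p$beta - tcrit * p$se, p$beta + tcrit * p$se)
  dimnames(out) <- list(p$term,
                        sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                   1 - (1 - level) / 2)))
  out
}

# Fit and pool, dropping covariates whose terms become perfectly collinear
# in a restricted sample (e.g. menopausal status coinciding with sex among
# the over-70s). Used by the subgroup and sensitivity machinery; the
# user-facing fit_model() keeps its strict rank-deficiency error.
fit_pooled_robust <- function(tables, spec) {
  for (attempt in 1:4) {
    res <- tryCatch(suppressMessages(fit_pooled(tables, spec)),
                    error = function(e) e)
    if (!inherits(res, "error")) return(res)
    msg <- conditionMessage(res)
    if (!grepl("collinear term", msg)) stop(res)
    bad_terms <- strsplit(sub(".*collinear term\\(s\\): ", "", msg), ", ")[[1]]
    bad_covs <- unique(unlist(lapply(bad_terms, function(tm) {
      spec$covariates[startsWith(tm, spec$covariates)]
    })))
    if (length(bad_covs) == 0L) stop(res)
    message("dropping collinear covariate(s) in restricted sample: ",
            paste(bad_covs, collapse = ", "))
    spec$covariates <- setdiff(spec$covariates, bad_covs)
  }
  stop("could not obtain a full-rank design after dropping covariates")
}

# Derive a stratification factor for the Table-3-style subgroups.
derive_stratifier <- function(table, stratifier, age_cut = NULL) {
  switch(stratifier,
    sex = table$sex,
    age_group = {
      cut_at <- age_cut %||% stats::median(table$age)
      factor(ifelse(table$age <= cut_at, "younger", "older"),
             levels = c("younger", "older"))
    },
    bmi_class = derive_bmi_class(table$bmi),
    smoking = table$smoking,
    comorbidity = {
      any_com <- rowSums(table[c("cvd", "cancer", "diabetes", "hypertension",
                                 "hyperlipidemia")]) > 0
      factor(ifelse(any_com, "one_or_more", "none"),
             levels = c("none", "one_or_more"))
    },
    stopf("unknown stratifier `%s`", stratifier)
  )
}

# Covariates to drop from the model when stratifying on `stratifier`.
stratifier_covariates <- function(stratifier) {
  switch(stratifier,
    sex = "sex",
    age_group = character(0), # age stays as a continuous adjuster
    bmi_class = "bmi",
    smoking = "smoking",
    comorbidity = c("cvd", "cancer", "diabetes", "hypertension",
                    "hyperlipidemia"),
    character(0))
}

#' Subgroup analysis across strata of an effect modifier
#'
#' Refits the pooled model within each stratum of the modifier, removing
#' the stratification variable from the covariate set ("when not
#' stratified for"), and tests effect modification with a multiplicative
#' interaction term ([interaction_test()]). The age split uses the sample
#' median of the first imputed dataset; BMI uses the three conventional
#' classes; comorbidity compares none versus one or more.
#'
#' @param tables List of completed data.frames.
#' @param spec A [model_spec()].
#' @param stratifier One of `"sex"`, `"age_group"`, `"bmi_class"`,
#'   `"smoking"`, `"comorbidity"`.
#' @return A data.frame of class `subgroup_analysis` (one row per
#'   stratum: `stratum`, `n`, `beta`, `se`, `ci95_low`, `ci95_high`,
#'   `p_value`) with the interaction p-value in attribute
#'   `"interaction_p"`.
#' @export
subgroup_analysis <- function(tables, spec, stratifier) {
  age_cut <- if (stratifier == "age_group") {
    stats::median(tables[[1]]$age)
  } else NULL
  g1 <- derive_stratifier(tables[[1]], stratifier, age_cut)
  if (nlevels(droplevels(g1)) < 2L) {
    stopf("stratifier `%s` has fewer than 2 observed levels", stratifier)
  }
  drop_covs <- stratifier_covariates(stratifier)
  sub_spec <- spec
  sub_spec$covariates <- setdiff(spec$covariates, drop_covs)
  rows <- lapply(levels(droplevels(g1)), function(lev) {
    sub_tabs <- lapply(tables, function(tt) {
      g <- derive_stratifier(tt, stratifier, age_cut)
      tt[g == lev, , drop = FALSE]
    })
    fit <- suppressMessages(fit_pooled_robust(sub_tabs, sub_spec))
    row <- fit$pooled[fit$pooled$term == spec$exposure_col, ]
    data.frame(stratum = lev, n = fit$n, beta = row$beta, se = row$se,
               ci95_low = row$ci95_low, ci95_high = row$ci95_high,
               p_value = row$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  it <- interaction_test(tables, spec, stratifier, age_cut = age_cut)
  attr(out, "interaction_p") <- it$p_value
  attr(out, "stratifier") <- stratifier
  class(out) <- c("subgroup_analysis", "data.frame")
  out
}

#' @export
print.subgroup_analysis <- function(x, ...) {
  cat(sprintf("Subgroup analysis by %s (interaction p = %.3g)\n",
              attr(x, "stratifier"), attr(x, "interaction_p")))
  print.data.frame(as.data.frame(x), digits = 3)
  invisible(x)
}

#' Multiplicative interaction test
#'
#' Adds score-by-modifier product terms to the model in each imputed
#' dataset and tests the pooled product coefficients with a multivariate
#' Wald test combined across imputations (the D1 statistic: the pooled
#' within-imputation covariance is inflated by the average relative
#' increase in variance, and the quadratic form is referred to an F
#' distribution). Two-sided; significance is conventionally read at
#' alpha = 0.05.
#'
#' @param tables List of completed data.frames.
#' @param spec A [model_spec()].
#' @param modifier A stratifier name understood by [subgroup_analysis()]
#'   or any categorical/binary column of the tables.
#' @param age_cut Internal: fixed age cut for `"age_group"`.
#' @return A list of class `interaction_test` with `p_value`, `statistic`
#'   (F), `df1`, `df2`, `modifier`.
#' @export
interaction_test <- function(tables, spec, modifier, age_cut = NULL) {
  known <- c("sex", "age_group", "bmi_class", "smoking", "comorbidity")
  add_modifier <- function(tt) {
    tt$.modifier <- if (modifier %in% known) {
      derive_stratifier(tt, modifier,
                        age_cut %||% stats::median(tables[[1]]$age))
    } else {
      if (!modifier %in% names(tt)) stopf("unknown modifier `%s`", modifier)
      as.factor(tt[[modifier]])
    }
    tt$.modifier <- droplevels(tt$.modifier)
    tt
  }
  t1 <- add_modifier(tables[[1]])
  if (nlevels(t1$.modifier) < 2L) {
    stopf("modifier `%s` has fewer than 2 observed levels", modifier)
  }
  int_spec <- spec
  # the modifier main effect must be present; drop raw covariates that the
  # derived modifier replaces to avoid collinearity
  int_spec$covariates <- union(
    setdiff(spec$covariates, stratifier_covariates(modifier)), ".modifier")
  prod_term <- paste0(spec$exposure_col, ":.modifier")
  fits <- lapply(tables, function(tt) {
    suppressMessages(fit_model(add_modifier(tt), int_spec,
                               extra_terms = prod_term))
  })
  sel <- grep(paste0("^", spec$exposure_col, ":\\.modifier"),
              names(fits[[1]]$coef), value = TRUE)
  k <- length(sel)
  m <- length(fits)
  Q <- matrix(unlist(lapply(fits, function(f) f$coef[sel])),
              ncol = k, byrow = TRUE)
  Ubar <- Reduce(`+`, lapply(fits, function(f) f$vcov[sel, sel, drop = FALSE])) / m
  qbar <- colMeans(Q)
  if (m >= 2) {
    Bmat <- stats::cov(Q)
    r <- (1 + 1 / m) * sum(diag(Bmat %*% solve(Ubar))) / k
  } else {
    r <- 0
  }
  r <- max(r, 0)
  Fstat <- as.numeric(t(qbar) %*% solve(Ubar) %*% qbar) / (k * (1 + r))
  if (r < 1e-10) {
    df2 <- Inf
  } else {
    t_df <- k * (m - 1)
    df2 <- if (t_df > 4) {
      4 + (t_df - 4) * (1 + (1 - 2 / t_df) / r)^2
    } else {
      t_df * (1 + 1 / k) * (1 + 1 / r)^2 / 2
    }
  }
  p <- stats::pf(Fstat, k, df2, lower.tail = FALSE)
  structure(list(p_value = p, statistic = Fstat, df1 = k, df2 = df2,
                 modifier = modifier),
            class = "interaction_test")
}

#' @export
print.interaction_test <- function(x, ...) {
  cat(sprintf(
    "Interaction test (%s x score): F(%d, %.4g) = %.3f, p = %.4g\n",
    x$modifier, x$df1, x$df2, x$statistic, x$p_value))
  invisible(x)
}

#' Sensitivity analyses around the principal model
#'
#' Re-estimates the pooled exposure effect (a) removing one comorbidity at
#' a time from the principal covariate set and (b) restricting the sample
#' by age at the 65- and 70-year cut-offs (both sides of each cut).
#' Subsets smaller than `min_n` are flagged and not fitted.
#'
#' @param tables List of completed data.frames.
#' @param spec A [model_spec()] (the principal model).
#' @param min_n Minimum subset size to attempt a fit.
#' @return A data.frame of class `sensitivity_suite`: `analysis`, `n`,
#'   `fitted`, `beta`, `ci95_low`, `ci95_high`, `p_value`; the principal
#'   estimate is the first row.
#' @export
sensitivity_suite <- function(tables, spec, min_n = 200L) {
  comorbs <- intersect(c("cvd", "cancer", "diabetes", "hypertension",
                         "hyperlipidemia"), spec$covariates)
  exposure_row <- function(fit) fit$pooled[fit$pooled$term == spec$exposure_col, ]
  principal <- fit_pooled(tables, spec)
  rows <- list(data.frame(analysis = "principal", n = principal$n,
                          fitted = TRUE, exposure_row(principal)[
                            c("beta", "ci95_low", "ci95_high", "p_value")]))
  for (v in comorbs) {
    s2 <- spec
    s2$covariates <- setdiff(spec$covariates, v)
    fit <- fit_pooled(tables, s2)
    rows[[length(rows) + 1L]] <- data.frame(
      analysis = paste0("without_", v), n = fit$n, fitted = TRUE,
      exposure_row(fit)[c("beta", "ci95_low", "ci95_high", "p_value")])
  }
  for (cut in c(65, 70)) {
    for (side in c("le", "gt")) {
      keep1 <- if (side == "le") tables[[1]]$age <= cut else tables[[1]]$age > cut
      lbl <- sprintf("age_%s_%d", side, cut)
      if (sum(keep1) < min_n) {
        rows[[length(rows) + 1L]] <- data.frame(
          analysis = lbl, n = sum(keep1), fitted = FALSE, beta = NA_real_,
          ci95_low = NA_real_, ci95_high = NA_real_, p_value = NA_real_)
        next
      }
      sub_tabs <- lapply(tables, function(tt) {
        tt[if (side == "le") tt$age <= cut else tt$age > cut, , drop = FALSE]
      })
      fit <- suppressMessages(fit_pooled_robust(sub_tabs, spec))
      rows[[length(rows) + 1L]] <- data.frame(
        analysis = lbl, n = fit$n, fitted = TRUE,
        exposure_row(fit)[c("beta", "ci95_low", "ci95_high", "p_value")])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sensitivity_suite", "data.frame")
  out
}

#' @export
print.sensitivity_suite <- function(x, ...) {
  cat("Sensitivity analyses (exposure effect per analysis)\n")
  print.data.frame(as.data.frame(x), digits = 3)
  invisible(x)
}
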