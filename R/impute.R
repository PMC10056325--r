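#' Multiple-imputation configuration
#'
#' @param m Number of imputed datasets, >= 2 (default 10).
#' @param seed Integer seed; each of the `m` imputations uses a derived
#'   seed.
#' @return An object of class `imputation_config`.
#' @export
imputation_config <- function(m = 10L, seed = 1L) {
  if (!is.numeric(m) || length(m) != 1L || m < 2) stopf("`m` must be >= 2")
  structure(list(m = as.integer(m), seed = as.integer(seed)),
            class = "imputation_config")
}

# Draw from the approximate posterior of a Bayesian normal linear model and
# return imputations for the missing rows ("norm" method).
impute_norm <- function(y, X, mis) {
  obs <- !mis & !is.na(y)
  Xo <- X[obs, , drop = FALSE]
  qrX <- qr(Xo)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  Xo <- Xo[, keep, drop = FALSE]
  bhat <- qr.coef(qr(Xo), y[obs])
  res <- y[obs] - Xo %*% bhat
  df <- max(length(y[obs]) - ncol(Xo), 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  XtXi <- chol2inv(chol(crossprod(Xo) + diag(1e-8, ncol(Xo))))
  bstar <- bhat + t(chol(sigma2 * XtXi)) %*% stats::rnorm(ncol(Xo))
  Xm <- X[mis, keep, drop = FALSE]
  as.numeric(Xm %*% bstar + stats::rnorm(sum(mis), 0, sqrt(sigma2)))
}

# Posterior-draw logistic imputation for a 0/1 outcome.
impute_logit <- function(y, X, mis) {
  obs <- !mis & !is.na(y)
  Xo <- X[obs, , drop = FALSE]
  qrX <- qr(Xo)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  Xo <- Xo[, keep, drop = FALSE]
  yo <- y[obs]
  if (length(unique(yo)) < 2L) {
    # degenerate: all observed values identical
    return(rep(yo[1], sum(mis)))
  }
  fit <- suppressWarnings(stats::glm.fit(Xo, yo, family = stats::binomial()))
  bhat <- fit$coefficients
  w <- fit$weights
  V <- chol2inv(chol(crossprod(Xo * sqrt(w)) + diag(1e-8, ncol(Xo))))
  bstar <- bhat + t(chol(V)) %*% stats::rnorm(ncol(Xo))
  p <- stats::plogis(as.numeric(X[mis, keep, drop = FALSE] %*% bstar))
  stats::rbinom(sum(mis), 1, p)
}

# Impute a factor via nested dichotomies of posterior-draw logistics.
impute_factor <- function(y, X, mis) {
  levs <- levels(y)
  out <- rep(NA_character_, sum(mis))
  remaining <- rep(TRUE, sum(mis))
  pool <- levs
  obs_tab <- table(y[!mis])
  pool <- names(obs_tab)[obs_tab > 0]
  if (length(pool) == 1L) return(factor(rep(pool, sum(mis)), levels = levs))
  for (k in seq_len(length(pool) - 1L)) {
    lev <- pool[k]
    in_play_obs <- !mis & !is.na(y) & (y %in% pool[k:length(pool)])
    yk <- as.numeric(y == lev)
    misk <- rep(FALSE, length(y))
    misk[which(mis)[remaining]] <- TRUE
    sel <- in_play_obs | misk
    draw <- impute_logit(yk[sel], X[sel, , drop = FALSE], misk[sel])
    hit <- draw == 1
    idx <- which(remaining)
    out[idx[hit]] <- lev
    remaining[idx[hit]] <- FALSE
    if (!any(remaining)) break
  }
  out[is.na(out)] <- pool[length(pool)]
  factor(out, levels = levs)
}

#' Multiply impute missing covariates
#'
#' Produces `m` completed copies of a cohort table, filling missing
#' covariate values by draws from per-variable conditional models:
#' Bayesian normal linear regression for continuous covariates,
#' posterior-draw logistic regression for binary ones, and nested
#' dichotomies of logistic regressions for multi-level categoricals. Each
#' conditional model uses the analysis outcome (`delta_age`), the
#' standardized exposure score(s), age, sex and energy as predictors —
#' all of which are complete by design — so a single pass per variable is
#' exact and no chaining iterations are needed. Structurally inapplicable
#' levels (menopause and hormone therapy in men) are restored
#' deterministically, and imputation models for those variables are fit
#' among women only.
#'
#' Observed cells are never modified; with no missing values the result is
#' `m` identical copies. The exposure score(s) and outcome must be
#' complete.
#'
#' @param table Cohort data.frame (post-exclusion, scored; needs
#'   `delta_age` and at least one of `edii_std` / `dis_std`).
#' @param config An [imputation_config()].
#' @return A list of `m` completed data.frames, classed `imputed_tables`.
#' @export
impute <- function(table, config = imputation_config()) {
  stopifnot(inherits(config, "imputation_config"))
  score_cols <- intersect(c("edii_std", "dis_std"), names(table))
  if (!"delta_age" %in% names(table) || length(score_cols) == 0L) {
    stopf("`table` must carry `delta_age` and a standardized score column")
  }
  if (anyNA(table$delta_age) || anyNA(table[score_cols])) {
    stopf("exposure and outcome must be complete before imputation")
  }
  vars <- intersect(covariate_columns(), names(table))
  vars <- vars[vapply(vars, function(v) anyNA(table[[v]]), logical(1))]

  pred_cols <- intersect(c("delta_age", score_cols, "age", "energy"),
                         names(table))
  base_X <- cbind(`(Intercept)` = 1, as.matrix(table[pred_cols]),
                  sex_male = as.numeric(table$sex == "male"))

  complete_one <- function(seed) {
    with_seed(seed, {
      out <- table
      for (v in vars) {
        y <- out[[v]]
        mis <- is.na(y)
        if (!any(mis)) next
        structural <- v %in% c("menopause", "hormone_therapy") &&
          is.factor(y) && "not_applicable" %in% levels(y)
        if (structural) {
          men <- out$sex == "male"
          y[mis & men] <- "not_applicable"
          out[[v]] <- y
          mis <- is.na(y)
          if (!any(mis)) next
          women <- !men
          yw <- droplevels(y[women])
          imp <- impute_factor(yw, base_X[women, , drop = FALSE], mis[women])
          y[which(women)[mis[women]]] <- as.character(imp)
          out[[v]] <- y
        } else if (is.factor(y)) {
          if (nlevels(droplevels(y)) <= 2L) {
            yb <- as.numeric(y == levels(droplevels(y))[2])
            draw <- impute_logit(yb, base_X, mis)
            y[mis] <- levels(droplevels(y))[draw + 1]
          } else {
            y[mis] <- as.character(impute_factor(y, base_X, mis))
          }
          out[[v]] <- y
        } else if (all(stats::na.omit(y) %in% c(0, 1))) {
          y[mis] <- impute_logit(y, base_X, mis)
          out[[v]] <- y
        } else {
          y[mis] <- impute_norm(y, base_X, mis)
          out[[v]] <- y
        }
      }
      out
    })
  }
  sets <- lapply(seq_len(config$m), function(i) {
    complete_one(derive_seed(config$seed, paste0("impute_", i)))
  })
  structure(sets, class = "imputed_tables", m = config$m)
}

#' @export
print.imputed_tables <- function(x, ...) {
  cat(sprintf("<imputed_tables> m = %d completed datasets, %d rows each\n",
              attr(x, "m"), nrow(x[[1]])))
  invisible(x)
}
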