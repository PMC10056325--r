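#' Standardize an intake against a food-parameter reference
#'
#' Computes the z-score of a reported daily intake against a food
#' parameter's global reference mean and SD. With `energy_adjusted = TRUE`
#' the intake is first converted to a nutrient density (amount per 1000
#' kcal) and compared against the energy-adjusted reference.
#'
#' @param intake Reported amount per day (registry units). May be a vector.
#' @param spec One registry row (a list or one-row data.frame with
#'   `global_mean`, `global_sd`, `energy_adjusted_mean`,
#'   `energy_adjusted_sd`).
#' @param energy_adjusted Use the density method against the
#'   energy-adjusted reference?
#' @param energy Daily energy intake in kcal/d, required (and strictly
#'   positive) when `energy_adjusted = TRUE`.
#' @return Dimensionless z-score(s).
#' @export
#' @examples
#' spec <- list(global_mean = 10, global_sd = 2,
#'              energy_adjusted_mean = 5, energy_adjusted_sd = 1)
#' z_score(12, spec) # 1
z_score <- function(intake, spec, energy_adjusted = FALSE, energy = NULL) {
  if (energy_adjusted) {
    if (is.null(energy)) stopf("`energy` is required when energy_adjusted = TRUE")
    if (any(!is.finite(energy)) || any(energy <= 0)) {
      stopf("`energy` must be strictly positive kcal/d for energy adjustment")
    }
    dens <- intake / energy * 1000
    (dens - spec$energy_adjusted_mean) / spec$energy_adjusted_sd
  } else {
    (intake - spec$global_mean) / spec$global_sd
  }
}

#' Centered proportion of a z-score
#'
#' Maps a z-score into the open interval (-1, 1) through the standard normal
#' CDF: `2 * pnorm(z) - 1`. This is the centered-percentile transform of the
#' published DII methodology; it is odd and strictly increasing, so a diet
#' exactly at the global reference mean contributes 0.
#'
#' @param z Finite z-score(s).
#' @return Value(s) in (-1, 1).
#' @export
#' @examples
#' centered_proportion(0) # 0
#' centered_proportion(1) # 0.6827
centered_proportion <- function(z) {
  if (any(!is.finite(z))) stopf("`z` must be finite")
  2 * stats::pnorm(z) - 1
}

#' DII / E-DII score of one diet
#'
#' For each food parameter in the registry the reported intake is
#' standardized against the global reference ([z_score()]), mapped to a
#' centered proportion and multiplied by the parameter's inflammatory
#' effect score; the overall score is the sum of these per-parameter
#' contributions. With `energy_adjusted = TRUE` this is the E-DII: intakes
#' are expressed per 1000 kcal and compared against the energy-adjusted
#' reference, which makes the score invariant under proportional scaling of
#' the whole diet and its energy.
#'
#' Parameters absent from `intakes` (or `NA`) contribute 0 — the
#' conservative choice, equivalent to an intake at the reference mean.
#'
#' @param intakes Named numeric vector of daily intakes; names must match
#'   registry parameter names.
#' @param registry A `food_registry` (see [read_food_registry()]).
#' @param energy_adjusted Compute the E-DII instead of the raw DII?
#' @param energy Daily energy intake (kcal/d), required for the E-DII.
#' @return A list of class `dii_score` with elements `score`,
#'   `contributions` (named, one per registry parameter) and
#'   `energy_adjusted`.
#' @export
#' @examples
#' reg <- as_food_registry(data.frame(
#'   name = c("a", "b"), unit = "g", global_mean = c(10, 5),
#'   global_sd = c(2, 1), energy_adjusted_mean = c(5, 2.5),
#'   energy_adjusted_sd = c(1, 0.5), effect_score = c(0.5, -0.4)))
#' dii_score(c(a = 12, b = 5), reg)$score # 0.3413
dii_score <- function(intakes, registry, energy_adjusted = FALSE,
                      energy = NULL) {
  registry <- as_food_registry(registry)
  x <- intakes[match(registry$name, names(intakes))]
  x <- as.numeric(x)
  contrib <- numeric(nrow(registry))
  present <- !is.na(x)
  if (any(present)) {
    if (energy_adjusted) {
      z <- z_score(x[present], list(
        energy_adjusted_mean = registry$energy_adjusted_mean[present],
        energy_adjusted_sd = registry$energy_adjusted_sd[present]
      ), energy_adjusted = TRUE, energy = energy)
    } else {
      z <- z_score(x[present], list(
        global_mean = registry$global_mean[present],
        global_sd = registry$global_sd[present]
      ))
    }
    contrib[present] <- centered_proportion(z) * registry$effect_score[present]
  }
  names(contrib) <- registry$name
  structure(list(score = sum(contrib), contributions = contrib,
                 energy_adjusted = energy_adjusted),
            class = "dii_score")
}

#' @export
print.dii_score <- function(x, ...) {
  cat(sprintf("%s score: %.4f  (%d parameters, %d non-zero)\n",
              if (x$energy_adjusted) "E-DII" else "DII",
              x$score, length(x$contributions), sum(x$contributions != 0)))
  invisible(x)
}

#' Dietary inflammation score (DIS) of one diet
#'
#' Sum over the 19 components of `weight * (intake - mean) / sd`. Components
#' absent or `NA` contribute 0.
#'
#' @param intakes Named numeric vector of daily component intakes.
#' @param registry A `dis_registry` (see [read_dis_registry()]).
#' @return The dimensionless score, with the per-component contributions in
#'   attribute `"contributions"`.
#' @export
dis_score <- function(intakes, registry) {
  registry <- as_dis_registry(registry)
  x <- as.numeric(intakes[match(registry$name, names(intakes))])
  contrib <- numeric(nrow(registry))
  present <- !is.na(x)
  contrib[present] <- registry$weight[present] *
    (x[present] - registry$mean[present]) / registry$sd[present]
  names(contrib) <- registry$name
  structure(sum(contrib), contributions = contrib)
}

#' Score every subject of a cohort table
#'
#' Vectorized computation of the E-DII (or raw DII) and the DIS over a
#' cohort table whose food-parameter intakes sit in `fp_<name>` columns and
#' DIS-component intakes in `dis_<name>` columns, with energy in `energy`.
#' Scores are appended as columns `edii` (or `dii`) and `dis`.
#'
#' @param table Cohort data.frame (see [generate_cohort()] for the layout).
#' @param edii_registry,dis_registry Registries; package defaults if `NULL`.
#' @param energy_adjusted Energy-adjust the DII (i.e. compute the E-DII)?
#' @return `table` with score columns appended.
#' @export
score_cohort <- function(table, edii_registry = NULL, dis_registry = NULL,
                         energy_adjusted = TRUE) {
  edii_registry <- as_food_registry(edii_registry %||% default_edii_registry())
  dis_registry <- as_dis_registry(dis_registry %||% default_dis_registry())

  fp <- paste0("fp_", edii_registry$name)
  have <- fp %in% names(table)
  x <- matrix(NA_real_, nrow(table), nrow(edii_registry))
  x[, have] <- as.matrix(table[fp[have]])
  if (energy_adjusted) {
    energy <- table$energy
    if (is.null(energy)) stopf("`energy` column required for the E-DII")
    if (any(!is.na(energy) & energy <= 0)) {
      stopf("`energy` must be strictly positive kcal/d for energy adjustment")
    }
    dens <- x / energy * 1000
    z <- sweep(sweep(dens, 2, edii_registry$energy_adjusted_mean), 2,
               edii_registry$energy_adjusted_sd, "/")
  } else {
    z <- sweep(sweep(x, 2, edii_registry$global_mean), 2,
               edii_registry$global_sd, "/")
  }
  contrib <- (2 * stats::pnorm(z) - 1) *
    rep(edii_registry$effect_score, each = nrow(table))
  contrib[is.na(contrib)] <- 0
  table[[if (energy_adjusted) "edii" else "dii"]] <- rowSums(contrib)
  # rows with no dietary data at all score NA, not 0
  none <- rowSums(!is.na(x)) == 0
  if (energy_adjusted) none <- none | is.na(table$energy)
  table[[if (energy_adjusted) "edii" else "dii"]][none] <- NA_real_

  dc <- paste0("dis_", dis_registry$name)
  have <- dc %in% names(table)
  y <- matrix(NA_real_, nrow(table), nrow(dis_registry))
  y[, have] <- as.matrix(table[dc[have]])
  zd <- sweep(sweep(y, 2, dis_registry$mean), 2, dis_registry$sd, "/")
  cd <- zd * rep(dis_registry$weight, each = nrow(table))
  cd[is.na(cd)] <- 0
  table$dis <- rowSums(cd)
  table$dis[rowSums(!is.na(y)) == 0] <- NA_real_
  table
}

#' Standardize a score vector to mean 0, SD 1
#'
#' Uses the sample SD over the analytic sample, so both inflammation scores
#' become comparable (effect sizes read as "per 1 SD of score").
#'
#' @param scores Numeric vector with at least 2 distinct finite values.
#' @return Standardized vector.
#' @export
#' @examples
#' standardize_scores(c(1, 2, 3)) # -1 0 1
standardize_scores <- function(scores) {
  ok <- is.finite(scores)
  if (length(unique(scores[ok])) < 2L) {
    stopf("cannot standardize: need at least 2 distinct values")
  }
  (scores - mean(scores[ok])) / stats::sd(scores[ok])
}

#' Rank-based quartile assignment
#'
#' Assigns subjects to quartiles 1-4 by rank, with group sizes differing by
#' at most one when values are distinct; any remainder goes to the lower
#' quartiles first. Tied subjects share the quartile of their mean rank, so
#' ties never straddle a cut.
#'
#' @param scores Numeric vector, length >= 4.
#' @return Integer vector of quartile labels in `1:4`.
#' @export
quartile_assign <- function(scores) {
  n <- length(scores)
  if (n < 4L) stopf("quartile assignment needs at least 4 values")
  if (length(unique(scores)) == 1L) {
    warning("all score values identical; assigning a single quartile group")
    return(rep(1L, n))
  }
  sizes <- rep(n %/% 4L, 4L)
  r <- n %% 4L
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  cuts <- cumsum(sizes)
  rk <- rank(scores, ties.method = "average")
  q <- findInterval(rk, cuts + 0.5) + 1L
  as.integer(pmin(q, 4L))
}
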