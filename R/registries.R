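#' Food-parameter and DIS-component registries
#'
#' The DII/E-DII score is computed against a registry of food parameters,
#' each carrying a global reference mean and SD (raw and per 1000 kcal) and
#' an inflammatory effect score; the DIS is computed against a registry of
#' 19 food groups (18 whole foods and beverages plus one composite
#' micronutrient supplement group), each carrying a weight and a
#' standardization mean/SD. Registries are plain delimited text so users can
#' swap in their own reference databases.
#'
#' The registries shipped with the package
#' (`edii_reference_synthetic.csv`, `dis_reference_synthetic.csv`) contain
#' synthetic illustrative values: the real global comparative database and
#' the published component weights are proprietary to their sources.
#'
#' @param path Path to a CSV file. Food-parameter files need columns
#'   `name, unit, global_mean, global_sd, energy_adjusted_mean,
#'   energy_adjusted_sd, effect_score`; DIS files need
#'   `name, weight, mean, sd`. Lines starting with `#` are comments.
#' @return A validated data.frame of class `food_registry` or
#'   `dis_registry`.
#' @export
#' @examples
#' reg <- default_edii_registry()
#' nrow(reg) # 34 food parameters
read_food_registry <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  as_food_registry(df)
}

#' @rdname read_food_registry
#' @export
read_dis_registry <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  as_dis_registry(df)
}

#' @param df A data.frame with the registry columns.
#' @rdname read_food_registry
#' @export
as_food_registry <- function(df) {
  need <- c("name", "unit", "global_mean", "global_sd",
            "energy_adjusted_mean", "energy_adjusted_sd", "effect_score")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stopf("food registry is missing columns: %s",
          paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) stopf("food registry is empty")
  if (anyDuplicated(df$name)) stopf("food registry has duplicated names")
  if (any(df$global_sd <= 0) || any(df$energy_adjusted_sd <= 0)) {
    stopf("food registry SDs must be strictly positive")
  }
  structure(df[need], class = c("food_registry", "data.frame"))
}

#' @rdname read_food_registry
#' @export
as_dis_registry <- function(df) {
  need <- c("name", "weight", "mean", "sd")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stopf("DIS registry is missing columns: %s",
          paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) stopf("DIS registry is empty")
  if (anyDuplicated(df$name)) stopf("DIS registry has duplicated names")
  if (any(df$sd <= 0)) stopf("DIS registry standardization SDs must be > 0")
  structure(df[need], class = c("dis_registry", "data.frame"))
}

#' @rdname read_food_registry
#' @export
default_edii_registry <- function() {
  read_food_registry(system.file("extdata", "edii_reference_synthetic.csv",
                                 package = "inflammage", mustWork = TRUE))
}

#' @rdname read_food_registry
#' @export
default_dis_registry <- function() {
  read_dis_registry(system.file("extdata", "dis_reference_synthetic.csv",
                                package = "inflammage", mustWork = TRUE))
}
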