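#' Seeded random train/test split
#'
#' Partitions a table into disjoint, exhaustive train and test sets with
#' `floor(train_fraction * n)` training rows, reproducibly for a given
#' seed. An 80:20 split of 23,858 quality-controlled records therefore
#' yields a test partition of 4,772.
#'
#' @param table A data.frame (non-empty).
#' @param train_fraction Proportion in (0, 1), default 0.8.
#' @param seed Integer seed.
#' @return A list with elements `train` and `test`.
#' @export
split_train_test <- function(table, train_fraction = 0.8, seed = 1L) {
  n <- nrow(table)
  if (is.null(n) || n == 0L) stopf("`table` must be non-empty")
  if (!is.numeric(train_fraction) || length(train_fraction) != 1L ||
      train_fraction <= 0 || train_fraction >= 1) {
    stopf("`train_fraction` must lie strictly inside (0, 1)")
  }
  n_train <- floor(train_fraction * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = table[idx, , drop = FALSE],
       test = table[-idx, , drop = FALSE])
}

#' Configuration of the biological-age clock
#'
#' The clock is a feed-forward neural network regressing chronological age
#' on the 36 circulating biomarkers plus sex and recruiting center (38
#' input features). Inputs are standardized internally (training-set mean
#' and SD), sex is coded 0/1 and center is one-hot encoded. The network has
#' one hidden layer of `hidden` logistic units plus skip-layer (direct
#' input-to-output) connections and a linear output, trained by quasi-Newton
#' optimization of the squared-error loss; `epochs` caps the optimizer
#' iterations (default 1000). Because the loss surface of a small MLP has
#' local optima, training runs `restarts` seeded weight initializations and
#' keeps the fit with the lowest training loss (deterministic given
#' `seed`). Rows with more than `max_missing_biomarkers` missing markers
#' are dropped at training time; remaining missing values are imputed by
#' training-set medians.
#'
#' @param hidden Hidden-layer width (default 8).
#' @param epochs Maximum optimizer iterations, >= 1 (default 1000).
#' @param train_fraction Training proportion for [split_train_test()].
#' @param seed Integer seed for weight initialization.
#' @param decay Weight-decay regularization (default 1e-3 on the
#'   standardized scale).
#' @param restarts Number of random weight initializations (default 3).
#' @param max_missing_biomarkers Row-level quality-control threshold.
#' @return An object of class `bioage_config`.
#' @export
bioage_config <- function(hidden = 8L, epochs = 1000L, train_fraction = 0.8,
                          seed = 1L, decay = 1e-3, restarts = 3L,
                          max_missing_biomarkers = 6L) {
  if (!is.numeric(epochs) || length(epochs) != 1L || epochs < 1) {
    stopf("`epochs` must be >= 1")
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    stopf("`train_fraction` must lie strictly inside (0, 1)")
  }
  if (!is.numeric(restarts) || restarts < 1) stopf("`restarts` must be >= 1")
  features <- c(bm_cols(), "sex", "center")
  stopifnot(length(features) == 38L)
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 train_fraction = train_fraction, seed = as.integer(seed),
                 decay = decay, restarts = as.integer(restarts),
                 max_missing_biomarkers = as.integer(max_missing_biomarkers),
                 input_features = features),
            class = "bioage_config")
}

# Encode the 38 input features into the numeric design matrix the net sees.
# `prep` (from training) supplies medians, centers and scales at predict time.
encode_bioage_features <- function(table, prep = NULL) {
  feats <- c(bm_cols(), "sex", "center")
  missing_cols <- setdiff(feats, names(table))
  if (length(missing_cols)) {
    stopf("missing input feature column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  bm <- as.matrix(table[bm_cols()])
  if (is.null(prep)) {
    med <- apply(bm, 2, stats::median, na.rm = TRUE)
  } else {
    med <- prep$medians
  }
  for (j in seq_len(ncol(bm))) bm[is.na(bm[, j]), j] <- med[j]
  sexn <- as.numeric(table$sex == "male")
  ctr <- stats::model.matrix(~ center, data = table)[, -1, drop = FALSE]
  x <- cbind(bm, sex = sexn, ctr)
  if (is.null(prep)) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
    prep <- list(medians = med, center = center, scale = scale)
  }
  x <- sweep(sweep(x, 2, prep$center), 2, prep$scale, "/")
  list(x = x, prep = prep)
}

#' Train the biological-age clock
#'
#' Fits the neural-network age clock described in [bioage_config()] on a
#' training table containing the 36 `bm_*` biomarker columns, `sex`,
#' `center` and the chronological-age label `age`. Training is
#' deterministic given `config$seed`.
#'
#' @param train_table Training data.frame.
#' @param config A [bioage_config()].
#' @return An object of class `bioage_model`: the fitted network plus its
#'   preprocessing constants, config, and training metrics (`train_mse`,
#'   `n_train`, `n_dropped_qc`).
#' @export
train_bioage <- function(train_table, config = bioage_config()) {
  stopifnot(inherits(config, "bioage_config"))
  if (!"age" %in% names(train_table)) {
    stopf("missing input feature column(s): age (training label)")
  }
  n_missing <- rowSums(is.na(as.matrix(train_table[
    intersect(bm_cols(), names(train_table))])))
  keep <- n_missing <= config$max_missing_biomarkers & !is.na(train_table$age)
  dropped <- sum(!keep)
  train_table <- train_table[keep, , drop = FALSE]
  if (nrow(train_table) < 10L) stopf("too few training rows after QC")
  enc <- encode_bioage_features(train_table)
  y <- train_table$age
  # the label is standardized too: optimizing on raw years badly conditions
  # the quasi-Newton search and leaves the net short of convergence
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  yz <- (y - y_center) / y_scale
  nw <- (ncol(enc$x) + 1) * config$hidden + (config$hidden + 1) +
    ncol(enc$x) # hidden + output + skip weights
  net <- NULL
  for (k in seq_len(config$restarts)) {
    cand <- with_seed(derive_seed(config$seed, paste0("init_", k)),
                      nnet::nnet(
      x = enc$x, y = yz, size = config$hidden, linout = TRUE, skip = TRUE,
      decay = config$decay, maxit = config$epochs,
      MaxNWts = max(nw + 50, 2000), trace = FALSE))
    if (is.null(net) || cand$value < net$value) net <- cand
  }
  pred <- y_center + y_scale * as.numeric(stats::predict(net, enc$x))
  structure(list(net = net, prep = enc$prep, config = config,
                 y_center = y_center, y_scale = y_scale,
                 train_mse = mean((pred - y)^2), n_train = nrow(train_table),
                 n_dropped_qc = dropped),
            class = "bioage_model")
}

#' @export
print.bioage_model <- function(x, ...) {
  cat("<bioage_model> neural-network age clock\n")
  cat(sprintf("  38 input features, %d hidden units (+ skip), seed %d\n",
              x$config$hidden, x$config$seed))
  cat(sprintf("  trained on %d rows (%d dropped by QC); training MSE %.2f y^2\n",
              x$n_train, x$n_dropped_qc, x$train_mse))
  invisible(x)
}

#' Predicted biological age
#'
#' @param object A `bioage_model`.
#' @param newdata Table with the clock's input feature columns.
#' @param ... Unused.
#' @return Numeric vector of biological ages (years).
#' @export
predict.bioage_model <- function(object, newdata, ...) {
  enc <- encode_bioage_features(newdata, prep = object$prep)
  object$y_center +
    object$y_scale * as.numeric(stats::predict(object$net, enc$x))
}

#' Biological age and delta-age for each subject
#'
#' Applies the clock and computes delta-age as biological minus
#' chronological age; positive values indicate accelerated aging.
#'
#' @param model A `bioage_model`.
#' @param table Table with feature columns and chronological `age`.
#' @return A data.frame `subject_id`, `ba`, `ca`, `delta_age` with
#'   `delta_age = ba - ca` exactly.
#' @export
predict_delta_age <- function(model, table) {
  ba <- stats::predict(model, table)
  data.frame(subject_id = table$subject_id %||% seq_len(nrow(table)),
             ba = ba, ca = table$age, delta_age = ba - table$age,
             stringsAsFactors = FALSE)
}

#' Permutation feature importance of the clock
#'
#' Shuffles one input feature at a time within the evaluation table and
#' reports the relative increase of the squared-error loss,
#' `loss_drop = (permuted_mse - baseline_mse) / baseline_mse`, averaged
#' over `n_permutations` shuffles. Features with a loss drop of at least
#' 5% are flagged as influential.
#'
#' @param model A `bioage_model`.
#' @param test_table Non-empty evaluation table with `age`.
#' @param n_permutations Number of shuffles per feature, >= 1.
#' @param seed Integer seed.
#' @param threshold Influence threshold on the relative loss drop
#'   (default 0.05).
#' @return A data.frame of class `feature_importance` with columns
#'   `feature`, `loss_drop`, `influential`, sorted by decreasing drop;
#'   baseline loss in attribute `"baseline_mse"`.
#' @export
permutation_importance <- function(model, test_table, n_permutations = 5L,
                                   seed = 1L, threshold = 0.05) {
  if (nrow(test_table) == 0L) stopf("`test_table` must be non-empty")
  if (n_permutations < 1) stopf("`n_permutations` must be >= 1")
  feats <- model$config$input_features
  base_mse <- mean((stats::predict(model, test_table) - test_table$age)^2)
  drops <- with_seed(seed, vapply(feats, function(f) {
    mean(vapply(seq_len(n_permutations), function(k) {
      tt <- test_table
      tt[[f]] <- tt[[f]][sample.int(nrow(tt))]
      mean((stats::predict(model, tt) - tt$age)^2)
    }, numeric(1)))
  }, numeric(1)))
  loss_drop <- (drops - base_mse) / base_mse
  out <- data.frame(feature = feats, loss_drop = loss_drop,
                    influential = loss_drop >= threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$loss_drop), ]
  rownames(out) <- NULL
  attr(out, "baseline_mse") <- base_mse
  class(out) <- c("feature_importance", "data.frame")
  out
}

#' @export
print.feature_importance <- function(x, n = 10L, ...) {
  cat(sprintf("Permutation feature importance (baseline MSE %.2f y^2)\n",
              attr(x, "baseline_mse")))
  cat(sprintf("  influential (loss drop >= 5%%): %s\n",
              paste(x$feature[x$influential], collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), n), digits = 3)
  invisible(x)
}
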