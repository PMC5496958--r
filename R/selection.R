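#' Bayesian Information Criterion of a fitted model
#'
#' `BIC = k * log(n) - 2 * logLik`, with `k` the number of predictor
#' columns, `n` the number of trials the model was fitted on, and the
#' log-likelihood taken without the ridge penalty. Lower is better.
#'
#' @param model a `choice_fit`.
#' @return The BIC value.
#' @export
bic <- function(model) {
  stopifnot(inherits(model, "choice_fit"), model$n_trials > 0L)
  model$n_parameters * log(model$n_trials) - 2 * model$log_likelihood
}

# fold assignment: uniform shuffle under the seed, fold sizes differing by
# at most one trial; deterministic given (n, k, seed)
cv_fold_assignment <- function(n, k_folds, seed) {
  with_seed(seed, {
    idx <- sample.int(n)
    folds <- integer(n)
    folds[idx] <- rep_len(seq_len(k_folds), n)
    folds
  })
}

#' Cross-validated prediction accuracy
#'
#' Shuffles the trials under the seed into `k_folds` near-equal folds;
#' each fold is classified by a model fitted on the remaining folds, and
#' the accuracy is pooled over all held-out trials (micro-average). A
#' fold whose training data lacks support for some predictor column is
#' not an error: the ridge penalty shrinks that coefficient to ~0.
#'
#' @param dataset a [choice_dataset()].
#' @param spec a [model_spec()].
#' @param k_folds number of folds (>= 2), 10 by default.
#' @param seed integer seed for the fold shuffle.
#' @param lambda,tol,max_iter passed to [fit_logistic()] for every fold.
#' @return Pooled held-out classification accuracy.
#' @export
cross_validate <- function(dataset, spec, k_folds = 10L, seed = 1L,
                           lambda = 1e-9, tol = 1e-8, max_iter = 100L) {
  stopifnot(k_folds >= 2L)
  n <- nrow(dataset$trials)
  if (n < k_folds) stop("fewer trials (", n, ") than folds (", k_folds, ")")
  design <- build_design(dataset, spec)
  folds <- cv_fold_assignment(n, k_folds, seed)
  correct <- 0L
  for (f in seq_len(k_folds)) {
    test <- folds == f
    train_design <- subset_design(design, !test)
    test_design <- subset_design(design, test)
    fit <- suppressWarnings(
      fit_logistic(train_design, lambda = lambda, tol = tol,
                   max_iter = max_iter))
    correct <- correct + round(classify_accuracy(fit, test_design) * sum(test))
  }
  correct / n
}

subset_design <- function(design, keep) {
  out <- design
  out$x <- design$x[keep, , drop = FALSE]
  out$y <- design$y[keep]
  out$start_lane <- design$start_lane[keep]
  out
}

#' Compare choice models by BIC and cross-validated accuracy
#'
#' Fits every spec on the full dataset for the BIC column and
#' cross-validates each with the *same* fold assignment for the accuracy
#' column, so all rows are computed on the identical trial subset.
#'
#' @param dataset a [choice_dataset()] (filter by condition first with
#'   [filter_condition()] for a per-condition table).
#' @param specs named list of [model_spec()] objects; the default battery
#'   is [default_spec_battery()].
#' @param k_folds,seed,lambda,tol,max_iter as in [cross_validate()].
#' @return A data frame of class `comparison_report`, one row per spec
#'   (`model`, `family`, `start_lane`, `lane_bias`, `n_parameters`,
#'   `bic`, `cv_accuracy`), sorted by BIC ascending.
#' @export
#' @examples
#' d <- simulate_dataset(generative_model(),
#'                       generate_balanced_design(n_subjects = 17, seed = 1),
#'                       seed = 1)
#' compare_models(filter_condition(d, "slow"), k_folds = 5, seed = 1)
compare_models <- function(dataset, specs = default_spec_battery(),
                           k_folds = 10L, seed = 1L,
                           lambda = 1e-9, tol = 1e-8, max_iter = 100L) {
  stopifnot(length(specs) >= 1L)
  if (is.null(names(specs))) names(specs) <- paste0("model_", seq_along(specs))
  rows <- lapply(names(specs), function(nm) {
    spec <- specs[[nm]]
    fit <- suppressWarnings(
      fit_logistic(build_design(dataset, spec), lambda = lambda,
                   tol = tol, max_iter = max_iter))
    data.frame(
      model = nm,
      family = spec$family,
      start_lane = spec$start_lane,
      lane_bias = spec$lane_bias,
      n_parameters = fit$n_parameters,
      bic = bic(fit),
      cv_accuracy = cross_validate(dataset, spec, k_folds = k_folds,
                                   seed = seed, lambda = lambda,
                                   tol = tol, max_iter = max_iter),
      stringsAsFactors = FALSE
    )
  })
  report <- do.call(rbind, rows)
  report <- report[order(report$bic), , drop = FALSE]
  rownames(report) <- NULL
  class(report) <- c("comparison_report", "data.frame")
  report
}

#' Default six-model comparison battery
#'
#' The pairing, obstacle and cluster models with both bias predictors,
#' plus the three bias-ablation variants of the cluster model (dropping
#' the starting lane, the lane bias, or both). Parameter counts for the
#' default catalog: 155, 20, 7, 6, 6, 5.
#'
#' @param cluster_map cluster assignment for the cluster-family rows;
#'   defaults to the semantic five-category map.
#' @return Named list of [model_spec()] objects.
#' @export
default_spec_battery <- function(cluster_map = category_cluster_map()) {
  list(
    pairing = model_spec("pairing"),
    obstacle = model_spec("obstacle"),
    cluster = model_spec("cluster", cluster_map = cluster_map),
    cluster_no_sl = model_spec("cluster", start_lane = FALSE,
                               cluster_map = cluster_map),
    cluster_no_lb = model_spec("cluster", lane_bias = FALSE,
                               cluster_map = cluster_map),
    cluster_no_biases = model_spec("cluster", start_lane = FALSE,
                                   lane_bias = FALSE,
                                   cluster_map = cluster_map)
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Model comparison (BIC ascending; accuracy = pooled 10-fold CV)\n")
  print.data.frame(x, row.names = FALSE, digits = 4, ...)
  invisible(x)
}
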