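#' Empty-lane error rate
#'
#' Uses trials in which one lane is empty as controls: driving into the
#' lane holding the sole obstacle is counted as an error (a
#' non-deliberate response), since no meaningful preference favors
#' hitting something over nothing. Chance level is 50%; for data
#' generated with lapse rate `eps`, the estimator converges to `eps / 2`
#' (a lapse picks a lane uniformly, hitting the sole obstacle half the
#' time).
#'
#' @param dataset a [choice_dataset()].
#' @param condition `"slow"`, `"fast"`, or `"both"`.
#' @return Fraction of empty-lane trials in which the sole obstacle was
#'   hit.
#' @export
estimate_error_rate <- function(dataset, condition = "both") {
  dataset <- filter_condition(dataset, condition)
  tr <- dataset$trials
  empty_id <- empty_obstacle_id(dataset$catalog)
  is_empty_trial <- tr$left_obstacle == empty_id | tr$right_obstacle == empty_id
  if (!any(is_empty_trial)) {
    stop("no empty-lane trials in condition '", condition, "'")
  }
  et <- tr[is_empty_trial, , drop = FALSE]
  empty_lane <- ifelse(et$left_obstacle == empty_id, "left", "right")
  mean(et$chosen_lane != empty_lane)
}

# nested design: obstacle columns + starting lane (no lane bias by default,
# matching the shared-scale contrast); nesting adds a duplicate column set
# active only in `dup_condition` rows
llr_designs <- function(dataset, lane_bias, dup_condition) {
  spec <- model_spec("obstacle", start_lane = TRUE, lane_bias = lane_bias)
  nested <- build_design(dataset, spec)
  dup_rows <- dataset$trials$condition == dup_condition
  dup <- nested$x * dup_rows
  colnames(dup) <- paste0(colnames(nested$x), "_", dup_condition)
  nesting <- nested
  nesting$x <- cbind(nested$x, dup)
  nesting$predictor_names <- colnames(nesting$x)
  list(nested = nested, nesting = nesting)
}

#' Nested likelihood-ratio test for a condition difference
#'
#' Tests whether the two timing conditions need separate value-of-life
#' scales. The nested model fits one shared set of predictors (the 18
#' obstacle columns plus the starting lane — 19 predictors by default) to
#' the joint dataset; the nesting model adds a duplicate set of the same
#' predictors that is active only in the slow-condition rows (38
#' predictors), letting the slow condition deviate from the shared
#' solution. The statistic `2 * (logLik_nesting - logLik_nested)` is
#' referred to the chi-square distribution with df = number of added
#' predictors; the tiny ridge penalty perturbs the likelihoods
#' negligibly.
#'
#' @param dataset a [choice_dataset()] containing both conditions.
#' @param lane_bias also include the lane-bias column in both models
#'   (df then 20)?
#' @param dup_condition which condition carries the duplicate predictors;
#'   the statistic is invariant to this choice.
#' @param lambda,tol,max_iter passed to [fit_logistic()].
#' @return List of class `llr_result`: `log_lik_nested`,
#'   `log_lik_nesting`, `statistic`, `df`, `p_value`.
#' @export
nested_llr_test <- function(dataset, lane_bias = FALSE,
                            dup_condition = "slow",
                            lambda = 1e-9, tol = 1e-8, max_iter = 200L) {
  present <- unique(dataset$trials$condition)
  if (!all(condition_tokens() %in% present)) {
    stop("dataset must contain both the slow and the fast condition")
  }
  designs <- llr_designs(dataset, lane_bias, dup_condition)
  fit_nested <- suppressWarnings(
    fit_logistic(designs$nested, lambda = lambda, tol = tol,
                 max_iter = max_iter))
  fit_nesting <- suppressWarnings(
    fit_logistic(designs$nesting, lambda = lambda, tol = tol,
                 max_iter = max_iter))
  df <- fit_nesting$n_parameters - fit_nested$n_parameters
  stat <- 2 * (fit_nesting$log_likelihood - fit_nested$log_likelihood)
  stat <- max(stat, 0)
  structure(
    list(log_lik_nested = fit_nested$log_likelihood,
         log_lik_nesting = fit_nesting$log_likelihood,
         statistic = stat,
         df = df,
         p_value = stats::pchisq(stat, df = df, lower.tail = FALSE)),
    class = "llr_result"
  )
}

#' @export
print.llr_result <- function(x, ...) {
  cat("Nested likelihood-ratio test\n",
      "  logLik nested  = ", format(x$log_lik_nested, digits = 6), "\n",
      "  logLik nesting = ", format(x$log_lik_nesting, digits = 6), "\n",
      "  statistic = ", format(x$statistic, digits = 5),
      ", df = ", x$df,
      ", p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Exclude outlier subjects
#'
#' Flags subjects whose observed choices oppose the model's predicted
#' lane in strictly more than half of their trials. The reference model
#' (obstacle family with both bias predictors by default) is fitted once
#' per condition on the full pooled data; each subject's opposite
#' fraction pools their trials across conditions (trial-weighted). A
#' single fit-then-exclude pass is performed, without iteration.
#'
#' @param dataset a [choice_dataset()].
#' @param spec the reference [model_spec()].
#' @param threshold exclusion threshold on the opposite fraction
#'   (exclusive; default 0.5).
#' @param lambda,tol,max_iter passed to [fit_logistic()].
#' @return List with `retained` (a [choice_dataset()]), `excluded`
#'   (character vector of subject ids) and `opposite_fraction` (named,
#'   all subjects).
#' @export
exclude_outlier_subjects <- function(dataset, spec = model_spec("obstacle"),
                                     threshold = 0.5,
                                     lambda = 1e-9, tol = 1e-8,
                                     max_iter = 100L) {
  tr <- dataset$trials
  if (length(unique(tr$subject_id)) < 2L) stop("need at least 2 subjects")
  opposed <- logical(nrow(tr))
  for (cond in unique(tr$condition)) {
    sub <- filter_condition(dataset, cond)
    design <- build_design(sub, spec)
    fit <- suppressWarnings(
      fit_logistic(design, lambda = lambda, tol = tol, max_iter = max_iter))
    p <- predict_proba(fit, design)
    pred_left <- ifelse(p == 0.5, design$start_lane == "left", p > 0.5)
    opposed[tr$condition == cond] <- pred_left != (design$y == 1L)
  }
  frac <- tapply(opposed, tr$subject_id, mean)
  excluded <- names(frac)[frac > threshold]
  keep <- !(tr$subject_id %in% excluded)
  retained <- dataset
  retained$trials <- tr[keep, , drop = FALSE]
  rownames(retained$trials) <- NULL
  list(retained = retained,
       excluded = excluded,
       opposite_fraction = frac)
}
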