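#' Logistic function
#'
#' `sigmoid(x) = 1 / (1 + exp(-x))`, evaluated stably for large `|x|`.
#'
#' @param x numeric vector of log-odds.
#' @return Probabilities in (0, 1).
#' @export
#' @examples
#' sigmoid(2.76 - 2.12)  # 0.655: chance of sparing the higher-valued obstacle
sigmoid <- function(x) stats::plogis(x)

# Unpenalized Bernoulli log-likelihood at linear predictor eta, computed
# through log-sigmoids so that near-saturated fits do not underflow.
bernoulli_loglik <- function(eta, y) {
  sum(stats::plogis(ifelse(y == 1, eta, -eta), log.p = TRUE))
}

#' Fit a penalized logistic choice model
#'
#' Maximizes the ridge-penalized Bernoulli log-likelihood
#' `sum(y * log(p) + (1 - y) * log(1 - p)) - lambda / 2 * sum(coef^2)`
#' by Newton / iteratively reweighted least squares with step-halving.
#' The default penalty `lambda = 1e-9` is essentially unpenalized maximum
#' likelihood; its role is to keep the optimum finite under perfect
#' separation and to pin the additive gauge freedom of obstacle- and
#' cluster-scale coefficients near the minimum-norm solution. All
#' columns, including the bias predictors, are penalized equally.
#'
#' @param design a `choice_design` from [build_design()].
#' @param lambda ridge penalty (>= 0).
#' @param tol convergence tolerance on the maximum absolute coefficient
#'   change.
#' @param max_iter maximum Newton iterations.
#' @return An object of class `choice_fit` with elements `coefficients`
#'   (named vector), `log_likelihood` (unpenalized, at the optimum),
#'   `n_trials`, `n_parameters`, `converged`, `n_iterations`, `spec`,
#'   `predictor_names`, `catalog`.
#' @export
#' @examples
#' d <- simulate_dataset(generative_model(),
#'                       generate_balanced_design(n_subjects = 20, seed = 1),
#'                       seed = 1)
#' fit <- fit_logistic(build_design(d, model_spec("obstacle")))
#' fit$log_likelihood
fit_logistic <- function(design, lambda = 1e-9, tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(design, "choice_design"), lambda >= 0)
  x <- design$x
  y <- design$y
  n <- nrow(x)
  p <- ncol(x)
  if (n == 0L) stop("empty design")
  beta <- numeric(p)
  pen_ll <- function(b) bernoulli_loglik(drop(x %*% b), y) - lambda / 2 * sum(b^2)
  ll_old <- pen_ll(beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(x %*% beta)
    mu <- sigmoid(eta)
    w <- mu * (1 - mu)
    grad <- drop(crossprod(x, y - mu)) - lambda * beta
    hess <- crossprod(x * w, x)
    diag(hess) <- diag(hess) + lambda
    step <- tryCatch(solve(hess, grad), error = function(e) {
      # near-singular curvature (e.g. saturated fit): damp the solve
      solve(hess + diag(1e-10, p), grad)
    })
    # step-halving: penalized log-likelihood must not decrease
    fac <- 1
    repeat {
      beta_new <- beta + fac * step
      ll_new <- pen_ll(beta_new)
      if (ll_new >= ll_old - 1e-12 || fac < 1e-8) break
      fac <- fac / 2
    }
    delta <- max(abs(beta_new - beta))
    ll_gain <- ll_new - ll_old
    beta <- beta_new
    ll_old <- ll_new
    # converged when coefficients settle, or when a full Newton step no
    # longer improves the objective beyond numerical noise (near-separated
    # columns creep at ~exp(-|beta|) per iteration long after the
    # likelihood has stabilized)
    if (delta < tol || (fac == 1 && ll_gain < 1e-10 * (1 + abs(ll_new)))) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("fit_logistic did not converge in ", max_iter, " iterations")
  }
  names(beta) <- design$predictor_names
  structure(
    list(coefficients = beta,
         log_likelihood = bernoulli_loglik(drop(x %*% beta), y),
         n_trials = n,
         n_parameters = p,
         converged = converged,
         n_iterations = iter,
         lambda = lambda,
         spec = design$spec,
         predictor_names = design$predictor_names,
         catalog = design$catalog),
    class = "choice_fit"
  )
}

#' @export
print.choice_fit <- function(x, ...) {
  cat("Penalized logistic fit (", x$spec$family, " family): ",
      x$n_parameters, " parameters, ", x$n_trials, " trials\n",
      "  logLik = ", format(x$log_likelihood, digits = 6),
      ", converged = ", x$converged,
      " (", x$n_iterations, " iterations)\n", sep = "")
  cat("  sign conventions: response 1 = left lane chosen;",
      "start_lane s = +1 left start (coef > 0: omission bias);",
      "lane_bias > 0: left-lane preference;",
      "obstacle/cluster scales defined up to an additive constant\n")
  invisible(x)
}

#' Predicted left-lane probabilities
#'
#' @param model a `choice_fit`.
#' @param design a `choice_design` with the same predictor columns.
#' @return Numeric vector of probabilities of choosing (driving into) the
#'   left lane.
#' @export
predict_proba <- function(model, design) {
  stopifnot(inherits(model, "choice_fit"), inherits(design, "choice_design"))
  if (!identical(design$predictor_names, model$predictor_names)) {
    stop("design columns do not match the fitted model's predictors")
  }
  unname(sigmoid(drop(design$x %*% model$coefficients)))
}

#' Classification accuracy of a fitted model
#'
#' Predicts the left lane when the fitted probability exceeds 0.5; a
#' probability of exactly 0.5 is resolved by predicting the trial's
#' starting lane (the deterministic stay-put reading of an undecided
#' model).
#'
#' @param model a `choice_fit`.
#' @param design a `choice_design` carrying the responses to score.
#' @return Fraction of trials classified correctly.
#' @export
classify_accuracy <- function(model, design) {
  if (nrow(design$x) == 0L) stop("empty design")
  p <- predict_proba(model, design)
  pred_left <- ifelse(p == 0.5, design$start_lane == "left", p > 0.5)
  mean(pred_left == (design$y == 1L))
}

#' Serialize / restore a fitted model
#'
#' Writes predictor names, coefficients and fit diagnostics as JSON so a
#' fit can be reused by reporting or testing without refitting.
#'
#' @param model a `choice_fit`.
#' @param path output JSON path.
#' @return `write_fit()` returns `path` invisibly; `read_fit_coefficients()`
#'   returns the named coefficient vector stored at `path`.
#' @export
write_fit <- function(model, path) {
  stopifnot(inherits(model, "choice_fit"))
  payload <- list(
    family = model$spec$family,
    predictor_names = model$predictor_names,
    coefficients = unname(model$coefficients),
    log_likelihood = model$log_likelihood,
    n_trials = model$n_trials,
    n_parameters = model$n_parameters,
    converged = model$converged,
    n_iterations = model$n_iterations,
    lambda = model$lambda
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit_coefficients <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  stats::setNames(payload$coefficients, payload$predictor_names)
}
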