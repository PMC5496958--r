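test_that("sigmoid reproduces the printed worked-example probabilities", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(2.76 - 2.12), 0.655, tolerance = 1e-3)
  expect_equal(sigmoid(1.79 - 2.12), 0.418, tolerance = 1e-3)
  # numerically stable in the tails
  expect_equal(sigmoid(800), 1)
  expect_equal(sigmoid(-800), 0)
})

test_that("the ridge keeps separated fits finite with saturated predictions", {
  tr <- toy_trials()[rep(1, 12), ]
  tr$trial_index <- 1:12
  tr$chosen_lane <- "left"
  d <- choice_dataset(tr)
  des <- build_design(d, model_spec("obstacle", start_lane = FALSE,
                                    lane_bias = FALSE))
  fit <- fit_logistic(des)
  expect_true(all(is.finite(fit$coefficients)))
  expect_gt(max(abs(fit$coefficients)), 5)
  expect_true(all(predict_proba(fit, des) > 0.999))
  expect_lte(fit$log_likelihood, 0)
})

test_that("mirror-symmetric data drives the lane bias to zero", {
  d <- random_dataset(61, n_subjects = 3)
  mirrored <- d$trials
  mirrored$subject_id <- paste0(mirrored$subject_id, "m")
  tmp <- mirrored$left_obstacle
  mirrored$left_obstacle <- mirrored$right_obstacle
  mirrored$right_obstacle <- tmp
  mirrored$start_lane <- ifelse(mirrored$start_lane == "left", "right", "left")
  mirrored$chosen_lane <- ifelse(mirrored$chosen_lane == "left",
                                 "right", "left")
  sym <- choice_dataset(rbind(d$trials, mirrored))
  fit <- fit_logistic(build_design(sym, model_spec("obstacle")))
  expect_equal(unname(fit$coefficients["lane_bias"]), 0, tolerance = 1e-6)
})

test_that("IRLS matches an independent direct optimizer and glm", {
  for (seed in 1:5) {
    des <- random_small_design(seed)
    fit <- fit_logistic(des)
    ll_irls <- penalized_loglik(des, fit$coefficients)
    ll_oracle <- optim_oracle_loglik(des)
    expect_lt(abs(ll_irls - ll_oracle) / abs(ll_oracle), 1e-6)
    expect_gte(ll_irls, ll_oracle - 1e-8 * abs(ll_oracle))
  }
  # unpenalized cross-check against glm: the cluster columns carry an
  # exact additive gauge (each row sums to 0), so coefficients are not
  # unique — fitted probabilities are, and must agree
  des <- random_small_design(9)
  fit <- fit_logistic(des, lambda = 0)
  ref <- suppressWarnings(
    stats::glm.fit(des$x, des$y, family = stats::binomial()))
  expect_equal(unname(sigmoid(drop(des$x %*% fit$coefficients))),
               unname(ref$fitted.values), tolerance = 1e-5)
})

test_that("nested predictor sets never lose log-likelihood", {
  d <- filter_condition(random_dataset(71, n_subjects = 12), "slow")
  full <- fit_logistic(build_design(d, model_spec("obstacle")))
  no_biases <- fit_logistic(build_design(
    d, model_spec("obstacle", start_lane = FALSE, lane_bias = FALSE)))
  expect_gte(full$log_likelihood, no_biases$log_likelihood - 1e-8)
})

test_that("predictions follow the coefficients and reject mismatched designs", {
  d <- random_dataset(81, n_subjects = 3)
  des <- build_design(d, model_spec("obstacle"))
  fit <- fit_logistic(des)
  zero <- fit
  zero$coefficients[] <- 0
  expect_equal(predict_proba(zero, des), rep(0.5, nrow(des$x)))
  other <- build_design(d, model_spec("pairing"))
  expect_error(predict_proba(fit, other), "do not match")
})

test_that("classification uses the 0.5 threshold with a start-lane tie-break", {
  # fully deterministic choices (huge value spread, no lapses): the fitted
  # model reproduces every response and scores exactly 1
  sat <- generative_model(value_of_life = fig4_values() * 100,
                          omega_s = 0, omega_b = 0,
                          lapse_rate = c(slow = 0, fast = 0))
  d_sat <- simulate_dataset(
    sat, generate_balanced_design(n_subjects = 4, seed = 13), seed = 14)
  des_sat <- build_design(d_sat, model_spec("obstacle"))
  fit_sat <- suppressWarnings(fit_logistic(des_sat))
  expect_equal(classify_accuracy(fit_sat, des_sat), 1)

  d <- random_dataset(91, n_subjects = 3)
  des <- build_design(d, model_spec("obstacle"))
  big <- fit_logistic(des)

  # constant-0.5 model: accuracy equals the empirical stay rate
  zero <- big
  zero$coefficients[] <- 0
  stay <- mean(d$trials$chosen_lane == d$trials$start_lane)
  expect_equal(classify_accuracy(zero, des), stay)

  # 4-trial toy set, hand-computed
  tr <- data.frame(
    subject_id = "S1", condition = "slow", block = 1L, trial_index = 1:4,
    left_obstacle = c("boy", "boy", "dog", "dog"),
    right_obstacle = c("man", "man", "pylon", "pylon"),
    start_lane = c("left", "left", "right", "right"),
    chosen_lane = c("left", "right", "left", "right"),
    stringsAsFactors = FALSE
  )
  toy <- choice_dataset(tr)
  toy_des <- build_design(toy, model_spec("obstacle"))
  expect_equal(classify_accuracy(zero, toy_des), 0.5)
})

test_that("the generative model approaches the analytic Bayes accuracy", {
  gm <- generative_model(value_of_life = fig4_values(),
                         lapse_rate = c(slow = 0.1, fast = 0.1))
  sched <- generate_balanced_design(n_subjects = 60, conditions = "slow",
                                    seed = 5)
  d <- simulate_dataset(gm, sched, seed = 6)
  p_true <- true_choice_probability(gm, d$trials$left_obstacle,
                                    d$trials$right_obstacle,
                                    d$trials$start_lane, "slow")
  bayes <- mean(pmax(p_true, 1 - p_true))
  observed <- mean((p_true > 0.5) == (d$trials$chosen_lane == "left"))
  n <- nrow(d$trials)
  expect_lt(abs(observed - bayes), 3 * sqrt(bayes * (1 - bayes) / n) + 0.01)
})

test_that("fits serialize to JSON and back", {
  des <- random_small_design(3)
  fit <- fit_logistic(des)
  path <- tempfile(fileext = ".json")
  write_fit(fit, path)
  coefs <- read_fit_coefficients(path)
  expect_equal(coefs, fit$coefficients)
})
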