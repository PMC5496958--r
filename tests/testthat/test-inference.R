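test_that("empty-lane error rate is plain arithmetic on control trials", {
  # 100 empty-lane trials, 12 hits of the sole obstacle -> 0.12
  tr <- data.frame(
    subject_id = "S1", condition = "slow", block = 1L, trial_index = 1:100,
    left_obstacle = "empty",
    right_obstacle = rep(c("dog", "boy"), 50),
    start_lane = "left",
    chosen_lane = c(rep("right", 12), rep("left", 88)),
    stringsAsFactors = FALSE
  )
  d <- choice_dataset(tr)
  expect_equal(estimate_error_rate(d, "slow"), 0.12)
  expect_error(estimate_error_rate(d, "fast"), "no trials")

  no_empty <- choice_dataset(toy_trials()[1:2, ])
  expect_error(estimate_error_rate(no_empty, "slow"), "empty-lane")
})

test_that("the error estimator recovers half the lapse rate", {
  # lapse-free, widely spread values: no errors at all
  gm0 <- generative_model(value_of_life = fig4_values() * 8,
                          lapse_rate = c(slow = 0, fast = 0))
  d0 <- simulate_dataset(gm0,
                         generate_balanced_design(n_subjects = 101, seed = 2),
                         seed = 3)
  expect_equal(estimate_error_rate(d0, "slow"), 0)

  # lapses pick a lane uniformly: estimator ~ eps / 2
  eps <- 0.2
  gm <- generative_model(value_of_life = fig4_values() * 4,
                         lapse_rate = c(slow = eps, fast = eps))
  d <- simulate_dataset(gm,
                        generate_balanced_design(n_subjects = 300,
                                                 conditions = "slow",
                                                 seed = 4),
                        seed = 5)
  est <- estimate_error_rate(d, "slow")
  n_empty <- 300  # one empty-lane trial per subject block
  se <- sqrt((eps / 2) * (1 - eps / 2) / n_empty)
  expect_lt(abs(est - eps / 2), 3 * se)

  # uniformly random choices sit at the 50% chance level
  gm1 <- generative_model(lapse_rate = c(slow = 1, fast = 1))
  d1 <- simulate_dataset(gm1,
                         generate_balanced_design(n_subjects = 200,
                                                  conditions = "slow",
                                                  seed = 6),
                         seed = 7)
  expect_lt(abs(estimate_error_rate(d1, "slow") - 0.5),
            3 * sqrt(0.25 / 200))
})

test_that("the nested LLR test obeys its structural identities", {
  gm <- generative_model(lapse_rate = c(slow = 0.056, fast = 0.056))
  d <- simulate_dataset(gm,
                        generate_balanced_design(n_subjects = 34, seed = 8),
                        seed = 9)
  res <- nested_llr_test(d)
  expect_s3_class(res, "llr_result")
  expect_equal(res$df, 19L)
  expect_gte(res$statistic, 0)
  expect_equal(res$statistic,
               2 * (res$log_lik_nesting - res$log_lik_nested),
               tolerance = 1e-9)
  expect_equal(res$p_value,
               stats::pchisq(res$statistic, 19, lower.tail = FALSE))

  # with the duplicate coefficients forced to zero, the nesting model's
  # likelihood reproduces the nested fit exactly
  designs <- moralchoice:::llr_designs(d, lane_bias = FALSE,
                                       dup_condition = "slow")
  fit_nested <- fit_logistic(designs$nested)
  padded <- c(fit_nested$coefficients, rep(0, 19))
  expect_equal(penalized_loglik(designs$nesting, padded, lambda = 0),
               fit_nested$log_likelihood, tolerance = 1e-9)

  # statistic is invariant to which condition carries the duplicates
  res_fast <- nested_llr_test(d, dup_condition = "fast")
  expect_equal(res_fast$statistic, res$statistic, tolerance = 1e-4)

  # df grows to 20 when the lane bias is included
  expect_equal(nested_llr_test(d, lane_bias = TRUE)$df, 20L)

  slow_only <- filter_condition(d, "slow")
  expect_error(nested_llr_test(slow_only), "both")
})

test_that("a halved fast-condition scale is detected at study scale", {
  gm <- generative_model(lapse_rate = c(slow = 0.056, fast = 0.056),
                         value_scale = c(slow = 1, fast = 0.5))
  d <- simulate_dataset(gm,
                        generate_balanced_design(n_subjects = 101, seed = 10),
                        seed = 11)
  expect_lt(nested_llr_test(d)$p_value, 0.01)
})

test_that("planted anti-preference subjects are excluded, and only those", {
  gm <- generative_model(value_of_life = fig4_values() * 4,
                         lapse_rate = c(slow = 0.02, fast = 0.02))
  d <- simulate_dataset(gm,
                        generate_balanced_design(n_subjects = 34, seed = 12),
                        seed = 13)
  planted <- c("S003", "S011", "S020")
  tr <- d$trials
  flip <- tr$subject_id %in% planted
  tr$chosen_lane[flip] <- ifelse(tr$chosen_lane[flip] == "left",
                                 "right", "left")
  d_planted <- choice_dataset(tr)
  res <- exclude_outlier_subjects(d_planted)
  expect_setequal(res$excluded, planted)
  expect_false(any(res$retained$trials$subject_id %in% planted))
  expect_equal(nrow(res$retained$trials) + sum(flip), nrow(tr))

  # idempotence: a second pass on the retained set excludes nobody
  res2 <- exclude_outlier_subjects(res$retained)
  expect_length(res2$excluded, 0L)

  # a subject matching every prediction is retained
  expect_true(all(res$opposite_fraction[setdiff(names(res$opposite_fraction),
                                                planted)] < 0.5))
})

test_that("the exclusion threshold is strict at one half", {
  # subject opposing the prediction in 6 of 9 trials (0.667) is excluded
  gm <- generative_model(value_of_life = fig4_values() * 100,
                         lapse_rate = c(slow = 0, fast = 0))
  d <- simulate_dataset(gm,
                        generate_balanced_design(n_subjects = 18,
                                                 conditions = "slow",
                                                 seed = 14),
                        seed = 15)
  tr <- d$trials
  s1 <- tr$subject_id == "S001"
  flip_idx <- which(s1)[1:6]
  tr$chosen_lane[flip_idx] <- ifelse(tr$chosen_lane[flip_idx] == "left",
                                     "right", "left")
  res <- exclude_outlier_subjects(choice_dataset(tr))
  expect_true("S001" %in% res$excluded)
  expect_gt(res$opposite_fraction[["S001"]], 0.5)
})
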