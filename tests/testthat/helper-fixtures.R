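# Shared fixtures: small catalogs, hand-built trial tables, generative
# models used across test files. Everything is built in code.

tiny_catalog <- function() {
  obstacle_catalog(
    obstacle_id = c("empty", "cone", "cat", "adult"),
    category = c("empty", "object", "animal", "human")
  )
}

# a minimal well-formed trial table against the default catalog
toy_trials <- function() {
  data.frame(
    subject_id = c("S1", "S1", "S2"),
    condition = c("slow", "slow", "fast"),
    block = 1L,
    trial_index = c(1L, 2L, 1L),
    left_obstacle = c("boy", "dog", "empty"),
    right_obstacle = c("man", "pylon", "goat"),
    start_lane = c("left", "right", "left"),
    chosen_lane = c("left", "left", "right"),
    stringsAsFactors = FALSE
  )
}

# random valid dataset for round-trip / property tests
random_dataset <- function(seed, n_subjects = 4) {
  gm <- generative_model(lapse_rate = c(slow = 0.3, fast = 0.3))
  simulate_dataset(gm,
                   generate_balanced_design(n_subjects = n_subjects,
                                            seed = seed),
                   seed = seed + 1)
}

# generative values with a Figure-4-like spread: categories ordered
# empty < object < animal < human < group over ~6 log-odds units, with
# mild within-category structure; the empty lane is NOT detached from
# the rest, so no obstacle is perfectly separated at study scale
fig4_values <- function() {
  c(empty = 0, pylon = 1.2, trash_bin = 1.5, hay_bale = 1.8,
    boar = 2.6, goat = 2.75, deer = 2.9, sheep = 3.05, pig = 3.2, dog = 3.4,
    elderly_man = 4.1, elderly_woman = 4.25, woman = 4.45, man = 4.6,
    girl = 4.8, boy = 4.9, human_animal_group = 5.7, human_group = 6.0)
}

# category-level values with zero within-category spread (cluster ground
# truth) and a variant with wide within-category spread but identical
# category means
cluster_truth_values <- function() {
  cat18 <- default_catalog()
  catvals <- c(empty = 0, object = 1.5, animal = 3, human = 4.5, group = 6)
  stats::setNames(catvals[cat18$category], cat18$obstacle_id)
}

spread_truth_values <- function(amount = 1.6) {
  offsets <- c(0, -1, 0, 1,
               -1.25, -0.75, -0.25, 0.25, 0.75, 1.25,
               -1.25, -0.75, -0.25, 0.25, 0.75, 1.25,
               -0.5, 0.5)
  v <- cluster_truth_values() + amount * offsets
  v
}

# hand-built fitted-model object for prediction arithmetic tests
synthetic_obstacle_fit <- function(values, omega_s = 0, omega_b = 0,
                                   catalog = default_catalog()) {
  spec <- model_spec("obstacle")
  coefs <- c(stats::setNames(values[catalog$obstacle_id],
                             paste0("obstacle_", catalog$obstacle_id)),
             start_lane = omega_s, lane_bias = omega_b)
  structure(
    list(coefficients = coefs,
         log_likelihood = 0, n_trials = 1L,
         n_parameters = length(coefs), converged = TRUE, n_iterations = 0L,
         lambda = 1e-9, spec = spec,
         predictor_names = names(coefs), catalog = catalog),
    class = "choice_fit"
  )
}

# direct (independent) penalized likelihood maximization via optim/BFGS
optim_oracle_loglik <- function(design, lambda = 1e-9) {
  x <- design$x
  y <- design$y
  nll <- function(b) {
    -(sum(stats::plogis(ifelse(y == 1, 1, -1) * drop(x %*% b),
                        log.p = TRUE)) - lambda / 2 * sum(b^2))
  }
  gr <- function(b) {
    mu <- stats::plogis(drop(x %*% b))
    -(drop(crossprod(x, y - mu)) - lambda * b)
  }
  o <- stats::optim(numeric(ncol(x)), nll, gr, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-14))
  -o$value
}

# penalized log-likelihood of a coefficient vector on a design
penalized_loglik <- function(design, beta, lambda = 1e-9) {
  eta <- drop(design$x %*% beta)
  sum(stats::plogis(ifelse(design$y == 1, 1, -1) * eta, log.p = TRUE)) -
    lambda / 2 * sum(beta^2)
}

# 50-trial design built from random blocks of several pseudo-subjects
random_small_design <- function(seed, family = "cluster") {
  gm <- generative_model(lapse_rate = c(slow = 0.1, fast = 0.1))
  sched <- do.call(rbind, lapply(1:6, function(i) {
    s <- generate_block_schedule(seed = 97 * seed + i)
    s$subject_id <- paste0("S", i)
    s$condition <- "slow"
    s$block <- 1L
    s$trial_index <- seq_len(nrow(s))
    s
  }))
  sched <- sched[1:50, ]
  sched$trial_index <- ave(seq_len(nrow(sched)), sched$subject_id,
                           FUN = seq_along)
  d <- simulate_dataset(gm, sched, seed = 333 + seed)
  spec <- if (family == "cluster") {
    model_spec("cluster", cluster_map = category_cluster_map())
  } else {
    model_spec(family)
  }
  build_design(d, spec)
}

temp_csv <- function() tempfile(fileext = ".csv")

with_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}
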