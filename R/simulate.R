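#' Generative value-of-life model
#'
#' Defines the latent structure choices are simulated from: one
#' value-of-life coefficient per obstacle (log-odds scale; higher = more
#' likely to be spared), a starting-lane coefficient (positive = omission
#' bias, i.e. a tendency to stay in the starting lane), a lane-bias
#' constant (positive = preference for driving in the left lane), a lapse
#' rate per condition (probability of a non-deliberate response that picks
#' a lane uniformly at random), and an optional per-condition multiplier
#' on the value scale (used to emulate the compressed coefficient range
#' observed under time pressure).
#'
#' The default values of life follow the category ordering empty <
#' objects < animals < single humans < groups, with the non-empty
#' categories spanning about 6 log-odds units and within-category spread
#' (children above adults, the dog as the most valued animal). The empty
#' lane sits well below the cheapest object (gap ~ 4.8), encoding that a
#' deliberate driver essentially never crashes into an obstacle when an
#' empty lane is available; empty-lane errors are then almost entirely
#' lapses. The default lapse rates (0.056 slow, 0.24 fast) are
#' calibrated so that the expected empty-lane error estimate, which
#' equals half the lapse rate, lands at 2.8% and 12.0%.
#'
#' @param value_of_life named numeric vector, one finite value per
#'   obstacle id.
#' @param omega_s starting-lane coefficient (log-odds; `s = +1` when the
#'   car starts in the left lane).
#' @param omega_b lane-bias coefficient (log-odds offset toward choosing
#'   the left lane).
#' @param lapse_rate named numeric vector of per-condition lapse
#'   probabilities in \[0, 1\].
#' @param value_scale named numeric per-condition multiplier applied to
#'   `value_of_life` (and not to the bias terms).
#' @param catalog the [obstacle_catalog()] the values refer to.
#'
#' @return An object of class `generative_model`.
#' @export
#' @examples
#' gm <- generative_model()
#' gm$value_of_life[c("empty", "dog", "boy")]
generative_model <- function(value_of_life = default_values_of_life(catalog),
                             omega_s = 0.47,
                             omega_b = 0,
                             lapse_rate = c(slow = 0.056, fast = 0.24),
                             value_scale = c(slow = 1, fast = 1),
                             catalog = default_catalog()) {
  assert_catalog(catalog)
  if (is.null(names(value_of_life)) ||
      !setequal(names(value_of_life), catalog$obstacle_id)) {
    stop("value_of_life must be named with exactly the catalog obstacle ids")
  }
  value_of_life <- value_of_life[catalog$obstacle_id]
  if (any(!is.finite(value_of_life))) stop("value_of_life entries must be finite")
  if (any(lapse_rate < 0 | lapse_rate > 1)) {
    stop("lapse rates must lie in [0, 1]")
  }
  structure(
    list(value_of_life = value_of_life,
         omega_s = omega_s, omega_b = omega_b,
         lapse_rate = lapse_rate, value_scale = value_scale,
         catalog = catalog),
    class = "generative_model"
  )
}

#' @rdname generative_model
#' @export
default_values_of_life <- function(catalog = default_catalog()) {
  v <- c(
    empty = -4,
    pylon = 0.8, trash_bin = 1.0, hay_bale = 1.2,
    boar = 2.4, goat = 2.6, deer = 2.8, sheep = 3.0, pig = 3.2, dog = 3.6,
    elderly_man = 4.4, elderly_woman = 4.6, woman = 4.9, man = 5.1,
    girl = 5.4, boy = 5.6,
    human_animal_group = 6.2, human_group = 6.5
  )
  if (!setequal(names(v), catalog$obstacle_id)) {
    stop("default values are defined for the default catalog only; ",
         "supply value_of_life explicitly for a custom catalog")
  }
  v[catalog$obstacle_id]
}

# Run code under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Random 9-trial block schedule
#'
#' Draws a uniformly random perfect matching of the catalog obstacles into
#' pairs (9 pairs for the default 18 obstacles), assigns each pair random
#' lane sides and a random starting lane. Every obstacle appears exactly
#' once in the block.
#'
#' @param catalog an [obstacle_catalog()] with an even number of entries.
#' @param seed integer seed; the same seed reproduces the same block.
#' @return Data frame with columns `left_obstacle`, `right_obstacle`,
#'   `start_lane`.
#' @export
generate_block_schedule <- function(catalog = default_catalog(), seed = 1L) {
  assert_catalog(catalog)
  n <- nrow(catalog)
  if (n %% 2L != 0L) {
    stop("catalog must have an even number of obstacles for a perfect matching")
  }
  with_seed(seed, {
    perm <- sample(catalog$obstacle_id)
    first <- perm[seq(1L, n, by = 2L)]
    second <- perm[seq(2L, n, by = 2L)]
    data.frame(
      left_obstacle = first,
      right_obstacle = second,
      start_lane = sample(lane_tokens(), n / 2L, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
}

# Round-robin (circle method) 1-factorization of the complete graph on the
# catalog obstacles: for 18 obstacles, 17 rounds of 9 disjoint pairs whose
# union is all 153 unordered pairings. Returns a list of data frames
# (first, second) in a fixed deterministic orientation.
round_robin_rounds <- function(catalog) {
  ids <- catalog$obstacle_id
  n <- length(ids)
  stopifnot(n %% 2L == 0L)
  m <- n - 1L
  rounds <- vector("list", m)
  rot <- seq_len(m)           # indices 1..n-1 rotate; index n is fixed
  for (r in seq_len(m)) {
    idx <- c(rot, n)
    first <- idx[seq_len(n / 2L)]
    second <- rev(idx)[seq_len(n / 2L)]
    rounds[[r]] <- data.frame(first = ids[first], second = ids[second],
                              stringsAsFactors = FALSE)
    rot <- c(rot[m], rot[-m]) # rotate by one
  }
  rounds
}

#' Balanced multi-subject design
#'
#' Builds a schedule in which pairings, lane allocations and starting
#' lanes are balanced across subjects. The 153 possible pairings of the
#' 18 obstacles decompose, by the round-robin 1-factorization of the
#' complete graph, into 17 rounds of 9 disjoint pairs; subject `i`
#' receives round `((i - 1) mod 17) + 1` in every condition, so across
#' any 17 consecutive subjects each pairing occurs exactly once per
#' condition. Lane sides flip between successive 17-subject cycles and
#' starting lanes alternate within a block (with the phase flipping per
#' cycle), counterbalancing both in the long run. Trial order within each
#' block is shuffled per subject under the seed.
#'
#' @param catalog an [obstacle_catalog()].
#' @param n_subjects number of subjects (>= 1).
#' @param conditions which conditions each subject completes (one block of
#'   `n/2` trials per condition).
#' @param seed integer seed controlling the within-block shuffles only;
#'   per-subject streams are derived at fixed offsets so adding subjects
#'   never perturbs earlier subjects' schedules.
#' @return Data frame with columns `subject_id`, `condition`, `block`,
#'   `trial_index`, `left_obstacle`, `right_obstacle`, `start_lane`.
#' @export
#' @examples
#' sched <- generate_balanced_design(n_subjects = 17, seed = 1)
#' nrow(sched)  # 17 subjects x 2 conditions x 9 trials = 306
generate_balanced_design <- function(catalog = default_catalog(),
                                     n_subjects,
                                     conditions = c("slow", "fast"),
                                     seed = 1L) {
  assert_catalog(catalog)
  stopifnot(n_subjects >= 1L)
  conditions <- match.arg(conditions, condition_tokens(), several.ok = TRUE)
  rounds <- round_robin_rounds(catalog)
  n_rounds <- length(rounds)
  n_pairs <- nrow(rounds[[1L]])
  out <- vector("list", n_subjects * length(conditions))
  k <- 0L
  for (i in seq_len(n_subjects)) {
    round_i <- ((i - 1L) %% n_rounds) + 1L
    cycle <- (i - 1L) %/% n_rounds
    flip_sides <- cycle %% 2L == 1L
    pairs <- rounds[[round_i]]
    left <- if (flip_sides) pairs$second else pairs$first
    right <- if (flip_sides) pairs$first else pairs$second
    start <- rep_len(if (flip_sides) rev(lane_tokens()) else lane_tokens(),
                     n_pairs)
    for (ci in seq_along(conditions)) {
      ord <- with_seed((seed + 7919 * i + 104729 * ci) %% 2147483647,
                       sample.int(n_pairs))
      k <- k + 1L
      out[[k]] <- data.frame(
        subject_id = sprintf("S%03d", i),
        condition = conditions[ci],
        block = ci,
        trial_index = seq_len(n_pairs),
        left_obstacle = left[ord],
        right_obstacle = right[ord],
        start_lane = start[ord],
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Probability of choosing the left lane under the generative model
#'
#' The deliberate decision follows the obstacle (value-of-life) model:
#' the linear predictor is the right-lane value minus the left-lane value
#' (each scaled by the condition's `value_scale`), plus `s * omega_s`
#' (`s = +1` starting left, `-1` starting right) plus `omega_b`. With
#' probability equal to the condition's lapse rate the response is
#' instead a uniform coin flip, so the returned probability is
#' `(1 - eps) * sigmoid(X) + eps / 2`.
#'
#' @param model a [generative_model()].
#' @param left_obstacle,right_obstacle obstacle ids.
#' @param start_lane `"left"` or `"right"`.
#' @param condition `"slow"` or `"fast"` (selects lapse rate and scale).
#' @return Probability (vectorized over trials) of driving into the left
#'   lane, i.e. hitting the left obstacle and sparing the right one.
#' @export
true_choice_probability <- function(model, left_obstacle, right_obstacle,
                                    start_lane, condition = "slow") {
  stopifnot(inherits(model, "generative_model"))
  v <- model$value_of_life
  scale <- model$value_scale[condition]
  scale[is.na(scale)] <- 1
  eps <- model$lapse_rate[condition]
  if (any(is.na(eps))) stop("no lapse rate defined for condition")
  s <- ifelse(start_lane == "left", 1, -1)
  x <- scale * (v[right_obstacle] - v[left_obstacle]) +
    s * model$omega_s + model$omega_b
  unname((1 - eps) * sigmoid(x) + eps / 2)
}

#' Simulate choices over a schedule
#'
#' Draws each trial's `chosen_lane` as a Bernoulli sample with
#' [true_choice_probability()]. Choices are drawn per subject from RNG
#' streams at fixed offsets of `seed`, so adding subjects to a schedule
#' never changes earlier subjects' simulated choices.
#'
#' @param model a [generative_model()].
#' @param schedule data frame as returned by [generate_balanced_design()]
#'   (columns `subject_id`, `condition`, `block`, `trial_index`,
#'   `left_obstacle`, `right_obstacle`, `start_lane`).
#' @param seed integer seed.
#' @return A validated [choice_dataset()].
#' @export
simulate_dataset <- function(model, schedule, seed = 1L) {
  stopifnot(inherits(model, "generative_model"))
  p_left <- true_choice_probability(model,
                                    schedule$left_obstacle,
                                    schedule$right_obstacle,
                                    schedule$start_lane,
                                    schedule$condition)
  subjects <- unique(schedule$subject_id)
  chosen <- character(nrow(schedule))
  for (j in seq_along(subjects)) {
    idx <- which(schedule$subject_id == subjects[j])
    u <- with_seed((seed + 15485863 * j) %% 2147483647,
                   stats::runif(length(idx)))
    chosen[idx] <- ifelse(u < p_left[idx], "left", "right")
  }
  trials <- schedule
  trials$chosen_lane <- chosen
  choice_dataset(trials, model$catalog)
}
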