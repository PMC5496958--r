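#' Model specification
#'
#' Selects the predictor family and the bias predictors of a choice
#' model:
#' * `pairing` — one free coefficient per unordered obstacle pairing
#'   (153 for the 18-obstacle catalog); permits intransitive preferences.
#' * `obstacle` — one coefficient per obstacle, the value-of-life scale;
#'   predictions depend only on coefficient differences.
#' * `cluster` — one coefficient per obstacle cluster; requires a
#'   `cluster_map` assigning every catalog obstacle to a cluster label.
#'
#' The starting-lane predictor (`s = +1` starting left, `-1` starting
#' right; a positive coefficient is an omission bias) and the lane-bias
#' predictor (a constant offset toward the left lane) can each be
#' included or ablated. With both included, parameter counts for the
#' default catalog are 155 (pairing), 20 (obstacle) and 7 (5-cluster).
#'
#' @param family `"pairing"`, `"obstacle"` or `"cluster"`.
#' @param start_lane include the starting-lane predictor?
#' @param lane_bias include the lane-bias (constant offset) predictor?
#' @param cluster_map named character vector mapping every obstacle id to
#'   a cluster label (required iff `family = "cluster"`).
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' model_spec("obstacle")
#' model_spec("cluster", cluster_map = category_cluster_map())
model_spec <- function(family = c("obstacle", "pairing", "cluster"),
                       start_lane = TRUE, lane_bias = TRUE,
                       cluster_map = NULL) {
  family <- match.arg(family)
  if (family == "cluster") {
    if (is.null(cluster_map) || is.null(names(cluster_map))) {
      stop("cluster family requires a named cluster_map (obstacle_id -> label)")
    }
    cluster_map <- vapply(cluster_map, as.character, character(1))
  } else {
    cluster_map <- NULL
  }
  structure(list(family = family,
                 start_lane = isTRUE(start_lane),
                 lane_bias = isTRUE(lane_bias),
                 cluster_map = cluster_map),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model spec:", x$family,
      "| start lane:", x$start_lane,
      "| lane bias:", x$lane_bias, "\n")
  if (!is.null(x$cluster_map)) {
    cat("  clusters:", paste(sort(unique(x$cluster_map)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Semantic five-category cluster map
#'
#' Maps each catalog obstacle to its semantic category (empty, object,
#' animal, human, group), the externally imposed clustering used to
#' compare conditions on a common footing.
#'
#' @param catalog an [obstacle_catalog()].
#' @return Named character vector, obstacle id -> category label.
#' @export
category_cluster_map <- function(catalog = default_catalog()) {
  stats::setNames(catalog$category, catalog$obstacle_id)
}

#' Number of unordered obstacle pairings
#'
#' @param catalog an [obstacle_catalog()].
#' @return `n * (n - 1) / 2` for `n` catalog obstacles (153 for 18).
#' @export
count_pairings <- function(catalog = default_catalog()) {
  n <- nrow(catalog)
  as.integer(n * (n - 1L) / 2L)
}

# canonical unordered-pair label: catalog order decides which id comes first
pairing_labels <- function(catalog) {
  ids <- catalog$obstacle_id
  n <- length(ids)
  first <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  offs <- unlist(lapply(seq_len(n - 1L), function(i) seq(i + 1L, n)))
  paste(ids[first], ids[offs], sep = ":")
}

design_colnames <- function(spec, catalog) {
  base <- switch(spec$family,
    pairing = paste0("pair_", pairing_labels(catalog)),
    obstacle = paste0("obstacle_", catalog$obstacle_id),
    cluster = paste0("cluster_", sort(unique(spec$cluster_map)))
  )
  c(base,
    if (spec$start_lane) "start_lane",
    if (spec$lane_bias) "lane_bias")
}

#' Build the design matrix of a choice model
#'
#' Encodes every trial of a dataset into the numeric predictor row of the
#' given model family. The response is 1 when the left lane was chosen
#' (driven into). Encoding conventions:
#' * obstacle family: the right obstacle's column gets +1 and the left
#'   obstacle's column -1, so the linear predictor is the right-minus-left
#'   value difference and a larger coefficient means a more-spared
#'   obstacle;
#' * cluster family: the same on cluster columns; a within-cluster
#'   pairing contributes 0 to every cluster column;
#' * pairing family: the trial's pairing column (canonical orientation:
#'   catalog order decides the pair's first obstacle) is `+1` when the
#'   canonically-first obstacle sits in the left lane, `-1` otherwise;
#' * `start_lane` column: +1 starting left, -1 starting right;
#' * `lane_bias` column: constant 1.
#'
#' @param dataset a [choice_dataset()].
#' @param spec a [model_spec()].
#' @return An object of class `choice_design` with elements `x` (numeric
#'   matrix, trials x predictors), `y` (0/1 response, 1 = left chosen),
#'   `predictor_names`, `start_lane`, `spec`, `catalog`.
#' @export
#' @examples
#' d <- simulate_dataset(generative_model(),
#'                       generate_balanced_design(n_subjects = 3, seed = 1),
#'                       seed = 1)
#' ncol(build_design(d, model_spec("obstacle"))$x)  # 20
build_design <- function(dataset, spec) {
  stopifnot(inherits(dataset, "choice_dataset"), inherits(spec, "model_spec"))
  catalog <- dataset$catalog
  tr <- dataset$trials
  n <- nrow(tr)
  if (spec$family == "cluster") {
    missing_ids <- setdiff(catalog$obstacle_id, names(spec$cluster_map))
    if (length(missing_ids)) {
      stop("cluster_map does not cover obstacle(s): ",
           paste(missing_ids, collapse = ", "))
    }
  }
  cols <- design_colnames(spec, catalog)
  x <- matrix(0, nrow = n, ncol = length(cols),
              dimnames = list(NULL, cols))
  rows <- seq_len(n)
  if (spec$family == "obstacle") {
    x[cbind(rows, match(paste0("obstacle_", tr$right_obstacle), cols))] <- 1
    x[cbind(rows, match(paste0("obstacle_", tr$left_obstacle), cols))] <- -1
  } else if (spec$family == "cluster") {
    rc <- paste0("cluster_", spec$cluster_map[tr$right_obstacle])
    lc <- paste0("cluster_", spec$cluster_map[tr$left_obstacle])
    # within-cluster pairings contribute 0 to every cluster column
    x[cbind(rows, match(rc, cols))] <- x[cbind(rows, match(rc, cols))] + 1
    x[cbind(rows, match(lc, cols))] <- x[cbind(rows, match(lc, cols))] - 1
  } else {
    ord <- match(tr$left_obstacle, catalog$obstacle_id) <
      match(tr$right_obstacle, catalog$obstacle_id)
    pair <- ifelse(ord,
                   paste0("pair_", tr$left_obstacle, ":", tr$right_obstacle),
                   paste0("pair_", tr$right_obstacle, ":", tr$left_obstacle))
    x[cbind(rows, match(pair, cols))] <- ifelse(ord, 1, -1)
  }
  if (spec$start_lane) {
    x[, "start_lane"] <- ifelse(tr$start_lane == "left", 1, -1)
  }
  if (spec$lane_bias) {
    x[, "lane_bias"] <- 1
  }
  structure(
    list(x = x,
         y = as.integer(tr$chosen_lane == "left"),
         predictor_names = cols,
         start_lane = tr$start_lane,
         spec = spec,
         catalog = catalog),
    class = "choice_design"
  )
}

#' Encode a single trial as a predictor row
#'
#' Convenience wrapper around [build_design()] for one trial; the choice
#' itself is not needed to form the predictor row.
#'
#' @inheritParams true_choice_probability
#' @param spec a [model_spec()].
#' @param catalog an [obstacle_catalog()].
#' @return Named numeric predictor vector.
#' @export
encode_trial <- function(left_obstacle, right_obstacle, start_lane,
                         spec, catalog = default_catalog()) {
  tr <- data.frame(subject_id = "S1", condition = "slow", block = 1L,
                   trial_index = 1L,
                   left_obstacle = left_obstacle,
                   right_obstacle = right_obstacle,
                   start_lane = start_lane, chosen_lane = "left",
                   stringsAsFactors = FALSE)
  d <- build_design(choice_dataset(tr, catalog), spec)
  d$x[1L, ]
}

#' @export
print.choice_design <- function(x, ...) {
  cat("Choice design:", nrow(x$x), "trials x", ncol(x$x), "predictors (",
      x$spec$family, "family )\n")
  invisible(x)
}
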