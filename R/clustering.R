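#' Observed sparing frequencies
#'
#' For each obstacle, the fraction of its appearances (in the selected
#' condition) in which it sat on the unchosen lane, i.e. was spared.
#' These one-dimensional frequencies are the clustering feature.
#'
#' @param dataset a [choice_dataset()].
#' @param condition `"slow"`, `"fast"`, or `"both"`.
#' @return Named numeric vector of sparing fractions, in catalog order;
#'   obstacles with zero appearances are dropped with a warning.
#' @export
sparing_frequencies <- function(dataset, condition = "both") {
  dataset <- filter_condition(dataset, condition)
  tr <- dataset$trials
  spared <- spared_obstacle(dataset)
  ids <- dataset$catalog$obstacle_id
  appearances <- table(factor(c(tr$left_obstacle, tr$right_obstacle),
                              levels = ids))
  spared_counts <- table(factor(spared, levels = ids))
  absent <- appearances == 0L
  if (any(absent)) {
    warning("obstacle(s) with no appearances excluded: ",
            paste(ids[absent], collapse = ", "))
  }
  freq <- as.numeric(spared_counts[!absent]) / as.numeric(appearances[!absent])
  stats::setNames(freq, ids[!absent])
}

#' Bottom-up clustering of sparing frequencies
#'
#' Agglomerative clustering of the one-dimensional sparing frequencies
#' using absolute frequency differences as the distance. The default
#' Ward linkage merges the pair of clusters whose union has the smallest
#' within-cluster variance increase, so low cuts of the tree coincide
#' with the minimum-within-spread partition of the 1-D values (greedy
#' pairwise linkages such as average linkage can chain away from it).
#' Returns the full nested sequence of solutions from `n` clusters down
#' to 1, so a model can be fitted for every cluster count.
#'
#' @param frequencies named numeric vector from [sparing_frequencies()].
#' @param linkage linkage rule passed to [stats::hclust()] (`"ward.D2"`
#'   by default; `"average"`, `"complete"` and `"single"` are accepted —
#'   in 1-D every one of them produces interval clusters of the sorted
#'   frequencies).
#' @return Object of class `cluster_solutions`: list with `tree` (the
#'   `hclust` object, merge heights and history included), `frequencies`,
#'   and `assignments`, a list mapping each k (as character) to a named
#'   integer cluster-label vector with labels `1..k`.
#' @export
#' @examples
#' fr <- c(a = 0.10, b = 0.12, c = 0.50, d = 0.90)
#' sol <- agglomerate(fr)
#' cluster_assignment(sol, 2)
agglomerate <- function(frequencies, linkage = "ward.D2") {
  if (length(frequencies) < 2L) stop("need at least 2 obstacles to cluster")
  if (is.null(names(frequencies))) stop("frequencies must be named")
  tree <- stats::hclust(stats::dist(frequencies, method = "manhattan"),
                        method = linkage)
  ks <- seq(length(frequencies), 1L)
  assignments <- lapply(ks, function(k) stats::cutree(tree, k = k))
  names(assignments) <- as.character(ks)
  structure(list(tree = tree,
                 frequencies = frequencies,
                 assignments = assignments),
            class = "cluster_solutions")
}

#' @rdname agglomerate
#' @param solutions a `cluster_solutions` object.
#' @param k number of clusters.
#' @export
cluster_assignment <- function(solutions, k) {
  stopifnot(inherits(solutions, "cluster_solutions"))
  a <- solutions$assignments[[as.character(k)]]
  if (is.null(a)) stop("no solution with k = ", k)
  a
}

#' Merge history of a clustering
#'
#' @param solutions a `cluster_solutions` object.
#' @return Data frame with one row per merge (`step`, `member_a`,
#'   `member_b`, `height`), heights non-decreasing; negative entries in
#'   `hclust`'s merge matrix are resolved to obstacle ids, positive ones
#'   to `step<i>` labels.
#' @export
merge_history <- function(solutions) {
  tree <- solutions$tree
  lab <- function(v) {
    vapply(v, function(i) if (i < 0) tree$labels[-i] else paste0("step", i),
           character(1))
  }
  data.frame(step = seq_len(nrow(tree$merge)),
             member_a = lab(tree$merge[, 1]),
             member_b = lab(tree$merge[, 2]),
             height = tree$height,
             stringsAsFactors = FALSE)
}

#' Select the cluster count by BIC
#'
#' Fits a cluster-family choice model for every cluster count in the
#' nested sequence and returns the BIC-minimizing solution together with
#' the full per-k table.
#'
#' @param dataset the [choice_dataset()] (already restricted to one
#'   condition) the frequencies came from.
#' @param solutions a `cluster_solutions` from [agglomerate()] on the
#'   same data.
#' @param start_lane,lane_bias bias predictors to include in every
#'   fitted cluster model.
#' @param lambda,tol,max_iter passed to [fit_logistic()].
#' @return List with `best_k`, `best_assignment` (named obstacle ->
#'   label vector), and `table` (data frame `k`, `n_parameters`, `bic`).
#' @export
select_cluster_count <- function(dataset, solutions,
                                 start_lane = TRUE, lane_bias = TRUE,
                                 lambda = 1e-9, tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(solutions, "cluster_solutions"))
  ids <- dataset$catalog$obstacle_id
  missing_ids <- setdiff(ids, names(solutions$frequencies))
  if (length(missing_ids)) {
    stop("clustering does not cover obstacle(s): ",
         paste(missing_ids, collapse = ", "))
  }
  ks <- as.integer(names(solutions$assignments))
  rows <- lapply(ks, function(k) {
    a <- cluster_assignment(solutions, k)
    spec <- model_spec("cluster", start_lane = start_lane,
                       lane_bias = lane_bias,
                       cluster_map = stats::setNames(as.character(a), names(a)))
    fit <- suppressWarnings(
      fit_logistic(build_design(dataset, spec), lambda = lambda,
                   tol = tol, max_iter = max_iter))
    data.frame(k = k, n_parameters = fit$n_parameters, bic = bic(fit))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$k), , drop = FALSE]
  rownames(tab) <- NULL
  best_k <- tab$k[which.min(tab$bic)]
  a <- cluster_assignment(solutions, best_k)
  list(best_k = best_k,
       best_assignment = stats::setNames(as.character(a), names(a)),
       table = tab)
}
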