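#' Forced-choice trial datasets
#'
#' A choice dataset couples a trial table with the obstacle catalog it was
#' recorded against. Each row of the trial table is one forced-choice
#' trial: two distinct obstacles, one per lane, a starting lane, and the
#' lane that was finally driven into (`chosen_lane` records the lane whose
#' obstacle was HIT; the spared obstacle is the one on the other lane and
#' is always derived, never stored).
#'
#' @param trials data frame with columns `subject_id`, `condition`
#'   (`"slow"` or `"fast"`), `block`, `trial_index`, `left_obstacle`,
#'   `right_obstacle`, `start_lane` and `chosen_lane` (both `"left"` or
#'   `"right"`).
#' @param catalog an [obstacle_catalog()].
#'
#' @return An object of class `choice_dataset` with elements `trials` and
#'   `catalog`.
#' @export
#' @examples
#' d <- simulate_dataset(generative_model(),
#'                       generate_balanced_design(n_subjects = 2, seed = 1),
#'                       seed = 1)
#' head(d$trials)
choice_dataset <- function(trials, catalog = default_catalog()) {
  assert_catalog(catalog)
  trials <- validate_trials(trials, catalog)
  structure(list(trials = trials, catalog = catalog),
            class = "choice_dataset")
}

trial_columns <- function() {
  c("subject_id", "condition", "block", "trial_index",
    "left_obstacle", "right_obstacle", "start_lane", "chosen_lane")
}

lane_tokens <- function() c("left", "right")
condition_tokens <- function() c("slow", "fast")

validate_trials <- function(trials, catalog) {
  trials <- as.data.frame(trials, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trial_columns(), names(trials))
  if (length(missing_cols)) {
    stop("trial table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  trials <- trials[trial_columns()]
  for (col in c("subject_id", "condition", "left_obstacle",
                "right_obstacle", "start_lane", "chosen_lane")) {
    trials[[col]] <- as.character(trials[[col]])
  }
  trials$block <- as.integer(trials$block)
  trials$trial_index <- as.integer(trials$trial_index)

  fail_rows <- function(bad, what) {
    if (any(bad)) {
      stop("invalid trial table: ", what, " in row(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "),
           if (sum(bad) > 5L) " ..." else "")
    }
  }
  fail_rows(!trials$condition %in% condition_tokens(), "unknown condition token")
  fail_rows(!trials$start_lane %in% lane_tokens(), "unknown start_lane token")
  fail_rows(!trials$chosen_lane %in% lane_tokens(), "unknown chosen_lane token")
  known <- catalog$obstacle_id
  fail_rows(!trials$left_obstacle %in% known, "unknown left_obstacle id")
  fail_rows(!trials$right_obstacle %in% known, "unknown right_obstacle id")
  fail_rows(trials$left_obstacle == trials$right_obstacle,
            "same obstacle on both lanes")
  key <- paste(trials$subject_id, trials$condition, trials$block,
               trials$trial_index, sep = "\r")
  fail_rows(duplicated(key), "duplicate (subject, condition, block, trial) key")
  rownames(trials) <- NULL
  trials
}

#' @export
print.choice_dataset <- function(x, ...) {
  tr <- x$trials
  cat("Choice dataset: ", nrow(tr), " trials, ",
      length(unique(tr$subject_id)), " subjects, conditions: ",
      paste(sort(unique(tr$condition)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Obstacle spared in each trial
#'
#' The spared obstacle is the one on the lane *not* driven into.
#'
#' @param dataset a [choice_dataset()].
#' @return Character vector of spared obstacle ids, one per trial.
#' @export
spared_obstacle <- function(dataset) {
  tr <- dataset$trials
  ifelse(tr$chosen_lane == "left", tr$right_obstacle, tr$left_obstacle)
}

#' Restrict a dataset to one condition
#'
#' @param dataset a [choice_dataset()].
#' @param condition `"slow"`, `"fast"`, or `"both"`.
#' @return A [choice_dataset()] with the selected trials.
#' @export
filter_condition <- function(dataset, condition = c("both", "slow", "fast")) {
  condition <- match.arg(condition)
  if (condition == "both") return(dataset)
  keep <- dataset$trials$condition == condition
  if (!any(keep)) stop("no trials in condition '", condition, "'")
  out <- dataset
  out$trials <- dataset$trials[keep, , drop = FALSE]
  rownames(out$trials) <- NULL
  out
}

#' Read and write trial tables
#'
#' Trial tables are stored as comma-separated UTF-8 text with a fixed
#' header (`subject_id, condition, block, trial_index, left_obstacle,
#' right_obstacle, start_lane, chosen_lane`). `read_trials()` validates
#' every row against the catalog; `write_trials()` produces deterministic
#' output so that identical datasets yield byte-identical files.
#'
#' @param path file path of the CSV trial table.
#' @param catalog an [obstacle_catalog()] the obstacle ids must resolve
#'   against.
#' @return `read_trials()` returns a [choice_dataset()]; `write_trials()`
#'   returns `path` invisibly.
#' @export
read_trials <- function(path, catalog = default_catalog()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  choice_dataset(raw, catalog)
}

#' @rdname read_trials
#' @param dataset a [choice_dataset()] to write.
#' @export
write_trials <- function(dataset, path) {
  stopifnot(inherits(dataset, "choice_dataset"))
  utils::write.csv(dataset$trials[trial_columns()], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
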