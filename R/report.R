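#' Reported value-of-life scale
#'
#' Obstacle- and cluster-scale coefficients are identified only up to an
#' additive constant (adding a constant to every value leaves all
#' predicted probabilities unchanged; the tiny ridge merely pins the fit
#' near the minimum-norm gauge). For reporting, the scale is re-centred
#' so the empty lane (or its cluster) sits at 0.
#'
#' @param model a `choice_fit` of the obstacle or cluster family.
#' @return Named numeric vector: per-obstacle (or per-cluster) values
#'   with the empty-lane value pinned at 0.
#' @export
value_of_life_scale <- function(model) {
  stopifnot(inherits(model, "choice_fit"))
  fam <- model$spec$family
  if (!fam %in% c("obstacle", "cluster")) {
    stop("value-of-life scale is defined for obstacle and cluster fits")
  }
  prefix <- paste0(fam, "_")
  scale_cols <- grep(paste0("^", prefix), model$predictor_names, value = TRUE)
  v <- model$coefficients[scale_cols]
  names(v) <- sub(prefix, "", names(v))
  empty_id <- empty_obstacle_id(model$catalog)
  ref <- if (fam == "obstacle") empty_id else model$spec$cluster_map[empty_id]
  v - v[[ref]]
}

#' Pairwise sparing-probability matrix
#'
#' `cell[i, j]` is the predicted probability of sparing row obstacle `i`
#' when it is paired against column obstacle `j`. For the obstacle and
#' cluster families the cell is the sigmoid of the coefficient
#' difference; for the pairing family it comes from the pairing
#' coefficient. Evaluated at a neutral starting lane; with
#' `zero_biases = TRUE` (default) the lane-bias term is dropped too, and
#' the matrix is complementary: `cell[i, j] + cell[j, i] = 1`. Rows and
#' columns are sorted by coefficient (obstacle/cluster) or by marginal
#' sparing rate (pairing); the diagonal is `NA` (no self-pairings).
#'
#' @param model a `choice_fit`.
#' @param zero_biases drop the lane-bias term from the evaluation?
#' @return Square numeric matrix with obstacle ids as dimnames, most
#'   spared first.
#' @export
prediction_matrix <- function(model, zero_biases = TRUE) {
  stopifnot(inherits(model, "choice_fit"))
  catalog <- model$catalog
  ids <- catalog$obstacle_id
  n <- length(ids)
  offset <- if (!zero_biases && model$spec$lane_bias) {
    model$coefficients[["lane_bias"]]
  } else 0
  if (model$spec$family %in% c("obstacle", "cluster")) {
    v <- value_of_life_scale(model)
    vobs <- if (model$spec$family == "obstacle") {
      v[ids]
    } else {
      stats::setNames(v[model$spec$cluster_map[ids]], ids)
    }
    # row obstacle in the right lane, column obstacle in the left:
    # sparing the row obstacle = choosing (driving into) the left lane
    m <- outer(vobs, vobs, function(a, b) sigmoid(a - b + offset))
    ord <- order(vobs, decreasing = TRUE)
  } else {
    m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        coef_ij <- model$coefficients[[paste0("pair_", ids[i], ":", ids[j])]]
        # c = +1 when the canonically-first obstacle (i) is on the left;
        # sparing j = hitting i = choosing left in that configuration
        m[ids[j], ids[i]] <- sigmoid(coef_ij + offset)
        m[ids[i], ids[j]] <- sigmoid(-coef_ij + offset)
      }
    }
    ord <- order(rowMeans(m, na.rm = TRUE), decreasing = TRUE)
  }
  dimnames(m) <- list(ids, ids)
  diag(m) <- NA_real_
  m[ord, ord]
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> (optional outlier exclusion) -> per-condition
#' model comparison, clustering and error-rate estimation -> joint nested
#' likelihood-ratio test -> coefficient and prediction-matrix reports,
#' writing every artifact under one output directory. Identical config
#' and seed give identical outputs.
#'
#' @param config a named list, or the path of a YAML/JSON file holding
#'   one. Recognized keys (all optional): `seed`, `n_subjects`,
#'   `conditions`, `values_of_life` (named list), `omega_s`, `omega_b`,
#'   `lapse_rate` (named list), `value_scale` (named list), `input_csv`
#'   (analyse an existing trial table instead of simulating),
#'   `exclude_outliers`, `k_folds`, `lambda`, `output_dir`.
#' @return Invisibly, a list with the in-memory results (`dataset`,
#'   `excluded`, `comparison`, `clustering`, `error_rates`, `llr`,
#'   `values`, `output_dir`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(list(
    seed = 1L, n_subjects = 101L, conditions = c("slow", "fast"),
    omega_s = 0.47, omega_b = 0,
    lapse_rate = list(slow = 0.056, fast = 0.24),
    value_scale = list(slow = 1, fast = 1),
    exclude_outliers = TRUE, k_folds = 10L, lambda = 1e-9,
    output_dir = file.path(tempdir(), paste0(
      "moralchoice_run_", format(Sys.time(), "%Y%m%d_%H%M%S")))
  ), config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$output_dir, "run_log.txt")
  log_line <- function(...) cat(..., "\n", sep = "", file = log_path,
                                append = TRUE)
  cat("", file = log_path)
  log_line("moralchoice pipeline")
  log_line("seed: ", cfg$seed)

  catalog <- default_catalog()
  if (!is.null(cfg$input_csv)) {
    dataset <- read_trials(cfg$input_csv, catalog)
    log_line("input: ", cfg$input_csv, " (", nrow(dataset$trials), " trials)")
  } else {
    vol <- if (is.null(cfg$values_of_life)) default_values_of_life(catalog)
           else unlist(cfg$values_of_life)
    gm <- generative_model(
      value_of_life = vol, omega_s = cfg$omega_s, omega_b = cfg$omega_b,
      lapse_rate = unlist(cfg$lapse_rate),
      value_scale = unlist(cfg$value_scale), catalog = catalog)
    schedule <- generate_balanced_design(catalog, cfg$n_subjects,
                                         cfg$conditions, seed = cfg$seed)
    dataset <- simulate_dataset(gm, schedule, seed = cfg$seed + 1)
    write_trials(dataset, file.path(cfg$output_dir, "trials.csv"))
    log_line("simulated ", nrow(dataset$trials), " trials, ",
             cfg$n_subjects, " subjects")
  }

  excluded <- character(0)
  if (isTRUE(cfg$exclude_outliers)) {
    excl <- exclude_outlier_subjects(dataset, lambda = cfg$lambda)
    excluded <- excl$excluded
    dataset <- excl$retained
    log_line("excluded subjects: ",
             if (length(excluded)) paste(excluded, collapse = ", ") else "none")
  }

  conditions <- intersect(condition_tokens(),
                          unique(dataset$trials$condition))
  comparison <- list()
  clustering <- list()
  error_rates <- numeric(0)
  values <- list()
  for (cond in conditions) {
    sub <- filter_condition(dataset, cond)
    rep_cond <- compare_models(sub, k_folds = cfg$k_folds, seed = cfg$seed,
                               lambda = cfg$lambda)
    comparison[[cond]] <- rep_cond
    utils::write.csv(rep_cond,
                     file.path(cfg$output_dir,
                               paste0("comparison_", cond, ".csv")),
                     row.names = FALSE)
    freq <- sparing_frequencies(sub)
    sol <- agglomerate(freq)
    sel <- select_cluster_count(sub, sol, lambda = cfg$lambda)
    clustering[[cond]] <- sel
    utils::write.csv(sel$table,
                     file.path(cfg$output_dir,
                               paste0("cluster_bic_", cond, ".csv")),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(obstacle_id = names(sel$best_assignment),
                 cluster = unname(sel$best_assignment)),
      file.path(cfg$output_dir, paste0("cluster_assignment_", cond, ".csv")),
      row.names = FALSE)
    utils::write.csv(merge_history(sol),
                     file.path(cfg$output_dir,
                               paste0("cluster_merges_", cond, ".csv")),
                     row.names = FALSE)
    error_rates[cond] <- estimate_error_rate(dataset, cond)
    fit <- suppressWarnings(
      fit_logistic(build_design(sub, model_spec("obstacle")),
                   lambda = cfg$lambda))
    values[[cond]] <- value_of_life_scale(fit)
    utils::write.csv(
      data.frame(obstacle_id = names(values[[cond]]),
                 value_of_life = unname(values[[cond]])),
      file.path(cfg$output_dir, paste0("values_", cond, ".csv")),
      row.names = FALSE)
    pm <- prediction_matrix(fit)
    utils::write.csv(as.data.frame(pm),
                     file.path(cfg$output_dir,
                               paste0("prediction_matrix_", cond, ".csv")))
    log_line(cond, ": error rate ", format(error_rates[cond], digits = 4),
             ", best cluster k = ", sel$best_k)
  }

  llr <- NULL
  if (length(conditions) == 2L) {
    llr <- nested_llr_test(dataset, lambda = cfg$lambda)
    jsonlite::write_json(unclass(llr),
                         file.path(cfg$output_dir, "llr_test.json"),
                         auto_unbox = TRUE, digits = NA)
    log_line("LLR test: statistic ", format(llr$statistic, digits = 5),
             ", df ", llr$df, ", p ", format(llr$p_value, digits = 4))
  }
  jsonlite::write_json(
    list(error_rates = as.list(error_rates),
         excluded_subjects = excluded,
         seed = cfg$seed),
    file.path(cfg$output_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA)

  invisible(list(dataset = dataset, excluded = excluded,
                 comparison = comparison, clustering = clustering,
                 error_rates = error_rates, llr = llr, values = values,
                 output_dir = cfg$output_dir))
}
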