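#' Experiment configuration
#'
#' A single serializable configuration drives dataset generation, model
#' training and evaluation; a run is reproducible from its config alone
#' (all randomness flows from `seed` through named sub-seeds).
#'
#' @param n_patients Number of patients in the factorial design.
#' @param n_surface,n_interior Points per cloud.
#' @param params A [deformation_params()] list.
#' @param models Models to compare; subset of `c("baseline", "heuristic",
#'   "rf", "rf_adaptive", "gbr", "mor")`.
#' @param objectives Objectives to run; subset of `c("average",
#'   "hausdorff")`.
#' @param grid,n_grid,tune_rows,inner_folds Passed to [train_config()].
#' @param tune_per_fold Re-tune hyperparameters inside every outer fold
#'   (default: tune once on the first fold's training patients and reuse).
#' @param heuristic_rate Sampling rate for the heuristic fit.
#' @param seed Root seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_patients = 6L, n_surface = 400L, n_interior = 600L,
                       params = deformation_params(),
                       models = c("baseline", "heuristic", "rf"),
                       objectives = c("average", "hausdorff"),
                       grid = "desk", n_grid = 4L, tune_rows = 30000L,
                       inner_folds = 1L, tune_per_fold = FALSE,
                       heuristic_rate = 65, seed = 1L) {
  structure(
    list(n_patients = as.integer(n_patients),
         n_surface = as.integer(n_surface),
         n_interior = as.integer(n_interior), params = params,
         models = models, objectives = objectives, grid = grid,
         n_grid = as.integer(n_grid), tune_rows = as.integer(tune_rows),
         inner_folds = as.integer(inner_folds), tune_per_fold = tune_per_fold,
         heuristic_rate = heuristic_rate, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Short reproducibility hash of a configuration
#'
#' @param config Any serializable object (typically a [run_config()]).
#' @return Character scalar (hex digest of the JSON serialization).
#' @export
config_hash <- function(config) {
  json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
  sprintf("%08x", derive_seed(0L, as.character(json)))
}

.predict_fold_cases <- function(model, dataset, idx) {
  purrr::map(dataset[idx], function(b) {
    predict_post(model, b$pre, b$cylinder, b$case)
  })
}

#' Run the full comparison experiment
#'
#' Generates (or reuses) the synthetic dataset, runs leave-one-patient-out
#' evaluation for every requested model and objective, and returns the
#' pooled distance comparison table. Distances are pooled over all test
#' cases of all folds (surface points only); the baseline needs no
#' training and is evaluated on every case directly.
#'
#' @param config A [run_config()].
#' @param dataset Optional pre-generated `bcs_dataset` matching the config
#'   (generated when `NULL`).
#' @return A tibble of class `bcs_comparison`: columns `model`,
#'   `objective`, `metric`, `mu`, `sigma`, `max`, `n_points`, ordered by
#'   pair-wise mean within objective; the dataset and config hash are
#'   attached as attributes.
#' @export
run_experiment <- function(config = run_config(), dataset = NULL) {
  cases <- enumerate_cases(config$n_patients, config$seed)
  if (is.null(dataset)) {
    dataset <- generate_dataset(cases, config$n_surface, config$n_interior,
                                config$params, config$seed)
  }
  splits <- lopo_splits(cases)
  posts <- purrr::map(dataset, "post")
  pres <- purrr::map(dataset, "pre")

  rows <- list()
  for (objective in config$objectives) {
    for (model_name in config$models) {
      preds <- switch(
        model_name,
        baseline = pres,
        heuristic = .run_heuristic(dataset, splits, config),
        rf = ,
        rf_adaptive = ,
        gbr = ,
        mor = .run_learned(model_name, dataset, splits, config, objective)
      )
      rep <- evaluate_cases(preds, posts)
      rep$model <- model_name
      rep$objective <- objective
      rows[[length(rows) + 1L]] <- rep
    }
  }
  out <- dplyr::bind_rows(rows)[, c("model", "objective", "metric", "mu",
                                    "sigma", "max", "n_points")]
  p2p_order <- out |>
    dplyr::filter(.data$metric == "p2p") |>
    dplyr::arrange(.data$objective, .data$mu)
  out <- dplyr::arrange(
    out, .data$objective,
    match(.data$model, unique(p2p_order$model)), .data$metric
  )
  structure(out, class = c("bcs_comparison", class(out)),
            config_hash = config_hash(config))
}

.run_heuristic <- function(dataset, splits, config) {
  preds <- vector("list", length(dataset))
  for (f in seq_len(nrow(splits))) {
    hm <- fit_heuristic(dataset[splits$train_idx[[f]]],
                        sampling_rate = config$heuristic_rate,
                        seed = config$seed + f)
    for (i in splits$test_idx[[f]]) {
      b <- dataset[[i]]
      preds[[i]] <- predict_heuristic(hm, b$pre, b$case)
    }
  }
  preds
}

.run_learned <- function(model_name, dataset, splits, config, objective) {
  kind <- if (model_name %in% c("rf", "rf_adaptive")) "rf" else model_name
  preds <- vector("list", length(dataset))
  hp <- NULL
  for (f in seq_len(nrow(splits))) {
    tc <- train_config(
      model = kind, objective = objective, grid = config$grid,
      n_grid = config$n_grid, tune_rows = config$tune_rows,
      inner_folds = config$inner_folds,
      adaptive = model_name == "rf_adaptive",
      seed = config$seed + 1000L * f
    )
    train_set <- dataset[splits$train_idx[[f]]]
    if (is.null(hp) || config$tune_per_fold) {
      tune_tc <- tc
      tune_tc$seed <- config$seed  # tuning shared across folds
      hp <- tune_hyperparams(train_set, tune_tc)
    }
    model <- train_deform_model(train_set, tc, hp)
    for (i in splits$test_idx[[f]]) {
      b <- dataset[[i]]
      preds[[i]] <- predict_post(model, b$pre, b$cylinder, b$case)
    }
  }
  preds
}

#' @export
print.bcs_comparison <- function(x, ...) {
  cat(sprintf("<bcs_comparison> config %s — distances in mm (surface points)\n",
              attr(x, "config_hash")))
  NextMethod()
}

#' Sampling-rate study
#'
#' Re-trains the per-axis RF at each requested sampling rate (fixed
#' hyperparameters, first leave-one-patient-out fold) and records the
#' objective value on the held-out patient together with the wall time —
#' the experiment shape behind the published rate-versus-error curves.
#'
#' @param dataset A `bcs_dataset`.
#' @param rates Rates to test, subset of `{5, 10, ..., 100}`.
#' @param objective `"average"` or `"hausdorff"`.
#' @param hp Hyperparameters (default: the desk grid's cheapest point).
#' @param seed Integer seed.
#' @return Tibble with columns `rate`, `objective`, `value` (mm),
#'   `seconds`.
#' @export
sampling_sweep <- function(dataset, rates = seq(5, 100, by = 5),
                           objective = c("average", "hausdorff"),
                           hp = list(n_trees = 10L, max_features = 8L,
                                     leaf_size = 5L),
                           seed = 1L) {
  objective <- match.arg(objective)
  stopifnot(all(rates %in% seq(5, 100, by = 5)))
  cases <- dataset_cases(dataset)
  splits <- lopo_splits(cases)
  train_idx <- splits$train_idx[[1]]
  test_idx <- splits$test_idx[[1]]
  train_full <- assemble_training_matrix(dataset[train_idx])
  purrr::map_dfr(rates, function(rate) {
    t0 <- proc.time()[["elapsed"]]
    tr <- sample_points(train_full, rate, seed)
    fits <- .fit_axes(tr, hp, "rf", seed = seed)
    d <- unlist(purrr::map(dataset[test_idx], function(b) {
      ft <- compute_features(b$pre, b$cylinder, b$case, b$damaged)
      disp <- .predict_axes(fits, ft)
      pred <- set_coords(b$pre, pcl_matrix(b$pre) + as.matrix(disp))
      pointwise_distances(pred, b$post)
    }))
    tibble::tibble(rate = rate, objective = objective,
                   value = .objective_value(d, objective),
                   seconds = proc.time()[["elapsed"]] - t0)
  })
}

#' Write a generated dataset to disk
#'
#' Writes per-case `pre.ply`, `post.ply` and `case.json` files plus a
#' manifest CSV linking cases to files.
#'
#' @param dataset A `bcs_dataset`.
#' @param out_dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- purrr::map_dfr(dataset, function(b) {
    cdir <- file.path(out_dir, b$case$case_id)
    dir.create(cdir, showWarnings = FALSE)
    write_pcl_ply(b$pre, file.path(cdir, "pre.ply"))
    write_pcl_ply(b$post, file.path(cdir, "post.ply"))
    write_case_json(b$case, b$pre, file.path(cdir, "case.json"))
    tibble::tibble(case_id = b$case$case_id,
                   patient_id = b$case$patient_id,
                   dir = cdir)
  })
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}
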