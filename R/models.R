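#' Training configuration
#'
#' Bundles everything that defines a training run: the regressor family,
#' the tuning objective, the point sampling rate, the hyperparameter grid
#' and the adaptive-weighting settings.
#'
#' The tuning objective is either `"average"` (minimize the mean pair-wise
#' distance between predicted and post-surgery clouds) or `"hausdorff"`
#' (minimize the maximum pair-wise distance). The default sampling rates
#' follow the objective: 65% for the average objective and 75% for the
#' Hausdorff objective, the optima of the published sampling-rate study.
#'
#' Two grids are built in. `grid = "desk"` is a coarsened grid sized for
#' interactive runs on a single CPU (n_trees {5, 10}, max_features {4, 8},
#' leaf_size {5}; learning rate {0.1, 0.3} for gradient boosting), with
#' `n_grid` randomly chosen candidates evaluated on at most `tune_rows`
#' subsampled training rows. `grid = "full"` is the full published grid
#' (n_trees {5, 10, ..., 500}, max_features {2, ..., 23}, leaf_size
#' {1, ..., 5}, learning rate {0.01, ..., 1}). Grid size is an experiment
#' knob, not method content; all desk values lie inside the full ranges.
#'
#' @param model `"rf"` (per-axis random forest), `"gbr"` (per-axis
#'   gradient boosting) or `"mor"` (joint multi-output forest).
#' @param objective `"average"` or `"hausdorff"`.
#' @param sampling_rate Training-point sampling rate in percent, from
#'   `{5, 10, ..., 100}`; `NULL` picks the objective's default (65 / 75).
#' @param grid `"desk"`, `"full"`, or a named list with components
#'   `n_trees`, `max_features`, `leaf_size` (and `learning_rate` for
#'   `"gbr"`).
#' @param n_grid Number of randomized grid candidates scored during tuning.
#' @param tune_rows Row cap for tuning fits (the final refit always uses
#'   all sampled training rows).
#' @param inner_folds Number of inner leave-one-patient-out folds used for
#'   tuning (capped at the number of training patients minus one).
#' @param adaptive Use the adaptive instance-weighting loop for the final
#'   model (RF family only).
#' @param max_adaptive_iters,patience Adaptive-loop stopping: hard
#'   iteration cap and the number of consecutive non-improving iterations
#'   tolerated.
#' @param oob Use out-of-bag predictions (instead of in-sample) for the
#'   adaptive residuals.
#' @param seed Integer seed governing subsampling, grid randomization and
#'   forest growth.
#' @return A list of class `train_config`.
#' @export
train_config <- function(model = c("rf", "gbr", "mor"),
                         objective = c("average", "hausdorff"),
                         sampling_rate = NULL,
                         grid = "desk",
                         n_grid = 4L,
                         tune_rows = 30000L,
                         inner_folds = 1L,
                         adaptive = FALSE,
                         max_adaptive_iters = 100L,
                         patience = 3L,
                         oob = FALSE,
                         seed = 1L) {
  model <- match.arg(model)
  objective <- match.arg(objective)
  if (is.null(sampling_rate)) {
    sampling_rate <- if (objective == "average") 65 else 75
  }
  if (!sampling_rate %in% seq(5, 100, by = 5)) {
    stop("sampling_rate must be in {5, 10, ..., 100}", call. = FALSE)
  }
  if (is.character(grid)) {
    grid <- switch(match.arg(grid, c("desk", "full")),
      desk = list(n_trees = c(5L, 10L), max_features = c(4L, 8L),
                  leaf_size = 5L, learning_rate = c(0.1, 0.3)),
      full = list(n_trees = seq(5L, 500L, by = 5L),
                   max_features = 2:23, leaf_size = 1:5,
                   learning_rate = seq(0.01, 1, by = 0.01))
    )
  }
  stopifnot(all(c("n_trees", "max_features", "leaf_size") %in% names(grid)))
  if (!all(grid$n_trees %in% seq(5, 500, 5)) ||
      !all(grid$max_features %in% 2:23) ||
      !all(grid$leaf_size %in% 1:5)) {
    stop("grid values must lie within the published ranges", call. = FALSE)
  }
  if (length(grid$n_trees) * length(grid$max_features) *
      length(grid$leaf_size) < 1) {
    stop("empty hyperparameter grid", call. = FALSE)
  }
  structure(
    list(model = model, objective = objective, sampling_rate = sampling_rate,
         grid = grid, n_grid = as.integer(n_grid),
         tune_rows = as.integer(tune_rows),
         inner_folds = as.integer(inner_folds), adaptive = adaptive,
         max_adaptive_iters = as.integer(max_adaptive_iters),
         patience = as.integer(patience), oob = oob, seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Leave-one-patient-out splits
#'
#' One fold per patient: all of that patient's cases form the test set and
#' every other patient's cases the training set, so no patient contributes
#' to both sides of a fold.
#'
#' @param cases A case tibble (needs a `patient_id` column), e.g. from
#'   [enumerate_cases()] or [dataset_cases()].
#' @return Tibble with columns `fold`, `test_patient`, and list-columns
#'   `train_idx` / `test_idx` of row indices into `cases`.
#' @export
lopo_splits <- function(cases) {
  patients <- unique(cases$patient_id)
  if (length(patients) < 2) {
    stop("leave-one-patient-out needs at least 2 patients", call. = FALSE)
  }
  tibble::tibble(
    fold = seq_along(patients),
    test_patient = patients,
    train_idx = purrr::map(patients, ~ which(cases$patient_id != .x)),
    test_idx = purrr::map(patients, ~ which(cases$patient_id == .x))
  )
}

#' Subsample training rows per case
#'
#' Draws a uniform without-replacement subsample of `ceil(rate% * n)` rows
#' within each case (test rows are never subsampled: this applies to
#' training tables only).
#'
#' @param table A stacked training tibble with a `case_id` column.
#' @param rate Sampling rate in percent, from `{5, 10, ..., 100}`.
#' @param seed Integer seed.
#' @return The subsampled tibble (row order: cases in original order).
#' @export
sample_points <- function(table, rate, seed = 1L) {
  if (!rate %in% seq(5, 100, by = 5)) {
    stop("rate must be in {5, 10, ..., 100}", call. = FALSE)
  }
  if (rate == 100) return(table)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  idx <- unlist(lapply(split(seq_len(nrow(table)), table$case_id), function(i) {
    sort(sample(i, ceiling(rate / 100 * length(i))))
  }), use.names = FALSE)
  table[sort(idx), ]
}

#' Integer weight from a residual distance
#'
#' The adaptive-weighting rule: the ceiling of the point-wise residual
#' distance, clamped to the range 1 to 6.
#'
#' @param p2p_distance Numeric vector of non-negative distances (mm).
#' @return Integer vector of weights in `1:6`.
#' @export
#' @examples
#' weight_from_distance(c(0.3, 4.2, 9.7))  # 1 5 6
weight_from_distance <- function(p2p_distance) {
  if (any(p2p_distance < 0)) {
    stop("distances must be non-negative", call. = FALSE)
  }
  as.integer(pmax(1, pmin(6, ceiling(p2p_distance))))
}

# --- fitting backends -------------------------------------------------------

.fit_axis <- function(X, y, hp, model, weights = NULL, seed = 1L) {
  if (model == "rf") {
    ranger::ranger(
      x = X, y = y,
      num.trees = hp$n_trees,
      mtry = min(hp$max_features, ncol(X)),
      min.node.size = hp$leaf_size,
      case.weights = weights,
      importance = "impurity",
      num.threads = 1L,
      seed = seed
    )
  } else {  # gbr: boosted weak trees, leaves <= 3 and depth <= 5
    dm <- xgboost::xgb.DMatrix(as.matrix(X), label = y,
                               weight = if (is.null(weights)) NULL else weights)
    xgboost::xgb.train(
      params = list(
        objective = "reg:squarederror",
        tree_method = "hist", grow_policy = "lossguide",
        max_leaves = 3L, max_depth = 5L,
        eta = hp$learning_rate %||% 0.1,
        colsample_bynode = min(1, hp$max_features / ncol(X)),
        min_child_weight = hp$leaf_size,
        nthread = 1L, seed = seed
      ),
      data = dm, nrounds = hp$n_trees, verbose = 0
    )
  }
}

.predict_axis <- function(fit, X) {
  if (inherits(fit, "ranger")) {
    stats::predict(fit, data = X, num.threads = 1L)$predictions
  } else {
    stats::predict(fit, as.matrix(X))
  }
}

.fit_axes <- function(train, hp, model, weights = NULL, seed = 1L) {
  feats <- feature_columns()
  if (model == "mor") {
    fit <- mvrf_fit(as.matrix(train[, feats]),
                    cbind(train$dx, train$dy, train$dz),
                    n_trees = hp$n_trees, mtry = hp$max_features,
                    min_node = max(hp$leaf_size, 5L), seed = seed)
    return(list(joint = fit))
  }
  X <- as.data.frame(train[, feats])
  list(
    x = .fit_axis(X, train$dx, hp, model, weights, seed),
    y = .fit_axis(X, train$dy, hp, model, weights, seed + 1L),
    z = .fit_axis(X, train$dz, hp, model, weights, seed + 2L)
  )
}

.predict_axes <- function(fits, features) {
  if (!is.null(fits$joint)) {
    m <- stats::predict(fits$joint, features[, feature_columns()])
    return(tibble::tibble(dx = m[, 1], dy = m[, 2], dz = m[, 3]))
  }
  X <- as.data.frame(features[, feature_columns()])
  tibble::tibble(
    dx = .predict_axis(fits$x, X),
    dy = .predict_axis(fits$y, X),
    dz = .predict_axis(fits$z, X)
  )
}

.objective_value <- function(distances, objective) {
  if (objective == "average") mean(distances) else max(distances)
}

.new_deform_model <- function(kind, fits, hp, config, weights = NULL,
                              trace = NULL) {
  structure(
    list(kind = kind, fits = fits, hyperparams = hp,
         sampling_rate = config$sampling_rate, objective = config$objective,
         config = config, weights = weights, trace = trace,
         feature_names = feature_columns()),
    class = "deform_model"
  )
}

#' @export
print.deform_model <- function(x, ...) {
  hp <- x$hyperparams
  cat(sprintf(
    "<deform_model> %s (%s objective), n_trees = %d, max_features = %d, leaf_size = %d, sampling %d%%%s\n",
    x$kind, x$objective, hp$n_trees, hp$max_features, hp$leaf_size,
    x$sampling_rate,
    if (!is.null(x$trace)) sprintf(", adaptive (%d iterations)", nrow(x$trace)) else ""
  ))
  invisible(x)
}

# --- tuning and training ----------------------------------------------------

.expand_grid_candidates <- function(config) {
  g <- config$grid
  cand <- tidyr::expand_grid(
    n_trees = g$n_trees, max_features = g$max_features,
    leaf_size = g$leaf_size,
    learning_rate = if (config$model == "gbr") g$learning_rate else NA_real_
  )
  # cheapest-model tie-break order: smaller n_trees, then smaller max_features
  cand <- dplyr::arrange(cand, .data$n_trees, .data$max_features,
                         .data$leaf_size)
  if (nrow(cand) > config$n_grid) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(config$seed + 7L)
    keep <- sort(sample(nrow(cand), config$n_grid))
    cand <- cand[keep, ]
  }
  cand
}

.case_feature_tables <- function(dataset) {
  purrr::map(dataset, function(b) {
    compute_features(b$pre, b$cylinder, b$case, b$damaged)
  })
}

.inner_objective <- function(fits, dataset, idx, objective) {
  d <- unlist(purrr::map(dataset[idx], function(b) {
    ft <- compute_features(b$pre, b$cylinder, b$case, b$damaged)
    disp <- .predict_axes(fits, ft)
    pred <- set_coords(b$pre, pcl_matrix(b$pre) + as.matrix(disp))
    pointwise_distances(pred, b$post)
  }))
  .objective_value(d, objective)
}

#' Tune hyperparameters by inner leave-one-patient-out validation
#'
#' Scores a randomized subset of the hyperparameter grid: for each inner
#' fold one training patient is held out, the remaining rows (sampled at
#' the configured rate, capped at `tune_rows`) train a candidate model,
#' and the objective is the pair-wise distance of the held-out patient's
#' predicted clouds. The candidate minimizing the mean objective across
#' inner folds wins; ties break toward the cheapest model (fewest trees,
#' then fewest features).
#'
#' @param dataset A `bcs_dataset` restricted to the training patients
#'   (>= 2 patients).
#' @param config A [train_config()].
#' @return The winning hyperparameter row (tibble with the scored
#'   objective in `score`).
#' @export
tune_hyperparams <- function(dataset, config) {
  cases <- dataset_cases(dataset)
  patients <- unique(cases$patient_id)
  cand <- .expand_grid_candidates(config)
  if (nrow(cand) == 1L) {  # nothing to tune
    cand$score <- NA_real_
    out <- cand
    attr(out, "candidates") <- cand
    return(out)
  }
  if (length(patients) < 2) {
    stop("tuning needs at least 2 training patients", call. = FALSE)
  }
  n_folds <- min(config$inner_folds, length(patients) - 1L)
  val_patients <- utils::tail(patients, n_folds)
  train_full <- assemble_training_matrix(dataset)
  scores <- matrix(NA_real_, nrow(cand), n_folds)
  for (f in seq_len(n_folds)) {
    vp <- val_patients[f]
    tr <- train_full[train_full$patient_id != vp, ]
    tr <- sample_points(tr, config$sampling_rate, config$seed + f)
    if (nrow(tr) > config$tune_rows) {
      old <- .Random.seed_save()
      set.seed(config$seed + 31L * f)
      tr <- tr[sort(sample(nrow(tr), config$tune_rows)), ]
      .Random.seed_restore(old)
    }
    val_idx <- which(cases$patient_id == vp)
    for (k in seq_len(nrow(cand))) {
      fits <- .fit_axes(tr, as.list(cand[k, ]), config$model,
                        seed = config$seed + 100L * k)
      scores[k, f] <- .inner_objective(fits, dataset, val_idx,
                                       config$objective)
    }
  }
  cand$score <- rowMeans(scores)
  best <- which.min(cand$score)  # candidates pre-sorted cheapest-first
  out <- cand[best, ]
  attr(out, "candidates") <- cand
  out
}

#' Train a displacement model with fixed hyperparameters
#'
#' Fits the per-axis (or joint) regressors on all training rows sampled at
#' the configured rate; when `config$adaptive` is set, the RF family is
#' trained through the adaptive weighting loop instead of a single fit.
#'
#' @inheritParams tune_hyperparams
#' @param hp A hyperparameter row / list with `n_trees`, `max_features`,
#'   `leaf_size` (and `learning_rate` for `"gbr"`).
#' @return A `deform_model`.
#' @export
train_deform_model <- function(dataset, config, hp) {
  if (config$model == "mor") {
    return(train_multi_output(dataset, config, hp))
  }
  train <- assemble_training_matrix(dataset)
  train <- sample_points(train, config$sampling_rate, config$seed)
  if (config$adaptive) {
    if (config$model != "rf") {
      stop("adaptive weighting is defined for the RF family", call. = FALSE)
    }
    return(adaptive_weight_loop(train, config, hp))
  }
  fits <- .fit_axes(train, as.list(hp), config$model, seed = config$seed)
  .new_deform_model(config$model, fits, as.list(hp), config)
}

#' Tune, then train, a displacement regression model
#'
#' The standard entry point: inner-validation grid search followed by a
#' final refit on all training rows at the configured sampling rate.
#'
#' @inheritParams tune_hyperparams
#' @return A `deform_model` (its `hyperparams` carry the tuning `score`).
#' @export
tune_and_train <- function(dataset, config = train_config()) {
  hp <- tune_hyperparams(dataset, config)
  train_deform_model(dataset, config, hp)
}

#' Adaptive instance-weighting loop
#'
#' Iteratively re-weights training points by their residual distance:
#' starting from unit weights, each iteration fits the per-axis forests
#' with the current weights, computes each training point's residual
#' point-wise distance (in-sample, or out-of-bag with `config$oob`),
#' updates the weights via [weight_from_distance()], and evaluates the
#' training objective. The loop stops after `max_adaptive_iters`
#' iterations or when the objective has not improved for `patience`
#' consecutive iterations, and returns the best-objective model seen.
#'
#' @param train A sampled training tibble (features + targets).
#' @param config A [train_config()].
#' @param hp Hyperparameter list.
#' @return A `deform_model` with the iteration `trace` (tibble of
#'   `iteration`, `objective`) attached.
#' @export
adaptive_weight_loop <- function(train, config, hp) {
  n <- nrow(train)
  weights <- rep(1L, n)
  best <- NULL
  best_obj <- Inf
  stall <- 0L
  trace <- list()
  target <- cbind(train$dx, train$dy, train$dz)
  for (it in seq_len(config$max_adaptive_iters)) {
    fits <- .fit_axes(train, as.list(hp), "rf", weights = weights,
                      seed = config$seed + it)
    if (config$oob) {
      pred <- cbind(fits$x$predictions, fits$y$predictions,
                    fits$z$predictions)
      pred[is.na(pred)] <- 0
    } else {
      p <- .predict_axes(fits, train)
      pred <- as.matrix(p)
    }
    res <- sqrt(rowSums((pred - target)^2))
    obj <- .objective_value(res, config$objective)
    trace[[it]] <- tibble::tibble(iteration = it, objective = obj)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best <- list(fits = fits, weights = weights)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
    weights <- weight_from_distance(res)
  }
  .new_deform_model("rf", best$fits, as.list(hp), config,
                    weights = best$weights,
                    trace = dplyr::bind_rows(trace))
}

#' Predict displacements or the post-surgery cloud
#'
#' `predict()` on a `deform_model` with a feature tibble returns per-point
#' displacements; [predict_post()] runs the full chain
#' features -> displacement -> predicted cloud for one case, preserving
#' index correspondence (prediction = pre-surgery coordinates + predicted
#' displacement).
#'
#' @param object A `deform_model`.
#' @param newdata Feature tibble containing the columns of
#'   [feature_columns()].
#' @param ... Unused.
#' @return Tibble with `dx`, `dy`, `dz` (mm).
#' @export
predict.deform_model <- function(object, newdata, ...) {
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing) > 0) {
    stop("schema error: missing feature columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  .predict_axes(object$fits, newdata)
}

#' @rdname predict.deform_model
#' @param model A `deform_model`.
#' @param pcl Pre-surgery [breast_pcl()].
#' @param cyl The case's `excision_cylinder`.
#' @param case One-row case tibble.
#' @export
predict_post <- function(model, pcl, cyl, case) {
  ft <- compute_features(pcl, cyl, case)
  disp <- stats::predict(model, ft)
  set_coords(pcl, pcl_matrix(pcl) + as.matrix(disp))
}

#' Per-feature and grouped importances
#'
#' Importances of the trained per-axis tree ensembles, normalized to sum
#' to 100% per axis, with each feature's group attached (grouped
#' importance = the mean of the group's individual importances).
#'
#' @param model A `deform_model` of the RF or GBR family.
#' @return Tibble with columns `axis`, `feature`, `group`,
#'   `importance_pct`.
#' @export
feature_importances <- function(model) {
  if (model$kind == "mor") {
    stop("importances are unsupported for the multi-output model", call. = FALSE)
  }
  purrr::map_dfr(c("x", "y", "z"), function(ax) {
    fit <- model$fits[[ax]]
    if (inherits(fit, "ranger")) {
      imp <- fit$variable.importance
    } else {
      tab <- xgboost::xgb.importance(model = fit)
      imp <- stats::setNames(tab$Gain, tab$Feature)
      imp <- imp[model$feature_names]
      imp[is.na(imp)] <- 0
      names(imp) <- model$feature_names
    }
    tibble::tibble(axis = ax, feature = names(imp),
                   importance_pct = 100 * imp / sum(imp))
  }) |>
    dplyr::left_join(feature_groups(), by = "feature") |>
    dplyr::select("axis", "feature", "group", "importance_pct")
}

#' @rdname feature_importances
#' @export
grouped_importances <- function(model) {
  feature_importances(model) |>
    dplyr::group_by(.data$axis, .data$group) |>
    dplyr::summarise(importance_pct = mean(.data$importance_pct),
                     .groups = "drop")
}

#' @importFrom rlang .data %||%
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# --- broom-style methods ----------------------------------------------------

#' Tidy a fitted displacement model
#'
#' @param x A `deform_model`.
#' @param ... Unused.
#' @return [tidy()][generics::tidy]: the per-axis feature importances;
#'   [glance()][generics::glance]: a one-row model summary.
#' @export
tidy.deform_model <- function(x, ...) {
  feature_importances(x)
}

#' @rdname tidy.deform_model
#' @export
glance.deform_model <- function(x, ...) {
  hp <- x$hyperparams
  tibble::tibble(
    kind = x$kind, objective = x$objective,
    n_trees = hp$n_trees, max_features = hp$max_features,
    leaf_size = hp$leaf_size,
    learning_rate = hp$learning_rate %||% NA_real_,
    sampling_rate = x$sampling_rate,
    adaptive = !is.null(x$trace),
    adaptive_iterations = if (is.null(x$trace)) NA_integer_ else nrow(x$trace),
    tuning_score = hp$score %||% NA_real_
  )
}
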