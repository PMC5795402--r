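#' Multivariate (multi-output) random forest
#'
#' A joint regressor predicting the three displacement components with a
#' single ensemble of multivariate regression trees: every split is scored
#' on all three targets at once, so the forest can exploit correlation
#' between the axes that per-axis forests ignore. Splits maximize the
#' joint variance reduction of the whitened targets (each target centered
#' and scaled by its training standard deviation, an approximation to full
#' covariance weighting); leaves predict the mean target vector. Trees are
#' grown on bootstrap resamples with a random feature subset drawn at each
#' node.
#'
#' This is a compact reference implementation intended for the moderate
#' problem sizes of the comparator study, not a tuned large-scale learner.
#'
#' @param X Numeric matrix or data frame of predictors.
#' @param Y Numeric matrix of targets (n x 3).
#' @param n_trees Number of trees.
#' @param mtry Features sampled per node.
#' @param min_node Minimum node size to attempt a split.
#' @param max_depth Depth cap.
#' @param seed Integer seed.
#' @return An object of class `mvrf` (list of trees plus scaling info).
#' @export
mvrf_fit <- function(X, Y, n_trees = 10L, mtry = 8L, min_node = 5L,
                     max_depth = 20L, seed = 1L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  ctr <- colMeans(Y)
  scl <- apply(Y, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Yw <- sweep(sweep(Y, 2, ctr), 2, scl, "/")
  mtry <- min(mtry, ncol(X))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  trees <- lapply(seq_len(n_trees), function(b) {
    idx <- sample.int(nrow(X), nrow(X), replace = TRUE)
    .mvrf_grow(X, Yw, idx, mtry, min_node, max_depth)
  })
  structure(list(trees = trees, center = ctr, scale = scl,
                 features = colnames(X)),
            class = "mvrf")
}

# grow one multivariate tree; nodes stored in a flat list
.mvrf_grow <- function(X, Y, idx, mtry, min_node, max_depth) {
  nodes <- list()
  new_node <- function(node) {
    nodes[[length(nodes) + 1L]] <<- node
    length(nodes)
  }
  grow <- function(rows, depth) {
    n <- length(rows)
    pred <- colMeans(Y[rows, , drop = FALSE])
    if (n < 2L * min_node || depth >= max_depth) {
      return(new_node(list(leaf = TRUE, pred = pred)))
    }
    best <- .mvrf_best_split(X, Y, rows, mtry, min_node)
    if (is.null(best)) {
      return(new_node(list(leaf = TRUE, pred = pred)))
    }
    left <- rows[X[rows, best$var] <= best$cut]
    right <- rows[X[rows, best$var] > best$cut]
    l_id <- grow(left, depth + 1L)
    r_id <- grow(right, depth + 1L)
    new_node(list(leaf = FALSE, var = best$var, cut = best$cut,
                  left = l_id, right = r_id))
  }
  root <- grow(idx, 0L)
  list(nodes = nodes, root = root)
}

# best split over a random feature subset: maximize joint SSE reduction,
# computed in O(n log n) per feature via cumulative sums
.mvrf_best_split <- function(X, Y, rows, mtry, min_node) {
  vars <- sample.int(ncol(X), mtry)
  n <- length(rows)
  best <- NULL
  best_gain <- 1e-12
  for (v in vars) {
    x <- X[rows, v]
    ord <- order(x)
    xo <- x[ord]
    yo <- Y[rows[ord], , drop = FALSE]
    cs <- apply(yo, 2, cumsum)
    cs2 <- apply(yo^2, 2, cumsum)
    tot <- cs[n, ]
    tot2 <- cs2[n, ]
    k <- seq_len(n - 1L)
    valid <- k >= min_node & (n - k) >= min_node & xo[k] < xo[k + 1L]
    if (!any(valid)) next
    kv <- k[valid]
    sse_l <- rowSums(cs2[kv, , drop = FALSE] -
                       cs[kv, , drop = FALSE]^2 / kv)
    sr <- sweep(-cs[kv, , drop = FALSE], 2, tot, `+`)
    sr2 <- sweep(-cs2[kv, , drop = FALSE], 2, tot2, `+`)
    sse_r <- rowSums(sr2 - sr^2 / (n - kv))
    sse_tot <- sum(tot2 - tot^2 / n)
    gain <- sse_tot - (sse_l + sse_r)
    j <- which.max(gain)
    if (gain[j] > best_gain) {
      best_gain <- gain[j]
      best <- list(var = v, cut = (xo[kv[j]] + xo[kv[j] + 1L]) / 2)
    }
  }
  best
}

#' @rdname mvrf_fit
#' @param object A fitted `mvrf`.
#' @param newdata Matrix or data frame of predictors.
#' @param ... Unused.
#' @return `predict()`: numeric matrix (n x 3) of predicted targets on the
#'   original scale.
#' @export
predict.mvrf <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  d <- length(object$center)
  acc <- matrix(0, nrow(X), d)
  for (tree in object$trees) {
    acc <- acc + .mvrf_tree_predict(tree, X, d)
  }
  acc <- acc / length(object$trees)
  sweep(sweep(acc, 2, object$scale, `*`), 2, object$center, `+`)
}

.mvrf_tree_predict <- function(tree, X, d) {
  out <- matrix(0, nrow(X), d)
  recurse <- function(node_id, rows) {
    node <- tree$nodes[[node_id]]
    if (node$leaf) {
      out[rows, ] <<- matrix(node$pred, length(rows),
                             length(node$pred), byrow = TRUE)
      return(invisible(NULL))
    }
    go_left <- X[rows, node$var] <= node$cut
    if (any(go_left)) recurse(node$left, rows[go_left])
    if (any(!go_left)) recurse(node$right, rows[!go_left])
  }
  recurse(tree$root, seq_len(nrow(X)))
  out
}

#' Train the joint multi-output displacement model
#'
#' Fits a single [mvrf_fit()] forest on the stacked training rows
#' (sampled at the configured rate) predicting `(dx, dy, dz)` jointly,
#' under the same tuning and evaluation contract as the per-axis models.
#'
#' @param dataset A `bcs_dataset` restricted to training patients.
#' @param config A [train_config()] with `model = "mor"`.
#' @param hp Hyperparameter list (`n_trees`, `max_features`, `leaf_size`).
#' @return A `deform_model` of kind `"mor"`.
#' @export
train_multi_output <- function(dataset, config, hp) {
  train <- assemble_training_matrix(dataset)
  train <- sample_points(train, config$sampling_rate, config$seed)
  fit <- mvrf_fit(
    as.matrix(train[, feature_columns()]),
    cbind(train$dx, train$dy, train$dz),
    n_trees = hp$n_trees, mtry = hp$max_features,
    min_node = max(hp$leaf_size, 5L), seed = config$seed
  )
  .new_deform_model("mor", list(joint = fit), as.list(hp), config)
}
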