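#' Pair-wise (point-wise) distance between corresponding clouds
#'
#' The per-index Euclidean distance between two clouds with shared point
#' correspondence, summarized by its mean, population standard deviation
#' and maximum. Evaluation is restricted to surface (skin) points when
#' `breast_pcl` objects are supplied.
#'
#' @param pred,target Clouds to compare: `breast_pcl` objects (surface
#'   points used) or plain n x 3 matrices / tibbles with `x,y,z`.
#' @return Tibble with one row: `mu`, `sigma`, `max` (mm) and `n_points`.
#' @export
#' @examples
#' a <- cbind(x = c(0, 1), y = c(0, 0), z = c(0, 0))
#' b <- cbind(x = c(3, 1), y = c(4, 0), z = c(0, 0))
#' pairwise_distance(a, b)  # distances 5 and 0
pairwise_distance <- function(pred, target) {
  p <- .eval_points(pred)
  t <- .eval_points(target)
  if (nrow(p) != nrow(t)) {
    stop("correspondence error: clouds differ in length", call. = FALSE)
  }
  d <- sqrt(rowSums((p - t)^2))
  .dist_summary(d)
}

#' Per-point distances between corresponding clouds
#'
#' @inheritParams pairwise_distance
#' @return Numeric vector of per-index Euclidean distances (mm).
#' @export
pointwise_distances <- function(pred, target) {
  p <- .eval_points(pred)
  t <- .eval_points(target)
  if (nrow(p) != nrow(t)) {
    stop("correspondence error: clouds differ in length", call. = FALSE)
  }
  sqrt(rowSums((p - t)^2))
}

#' Directed global (nearest-neighbour) distance between clouds
#'
#' For every source point, the distance to its nearest target point
#' (nearest-neighbour ties broken by lowest target index), summarized by
#' mean, population standard deviation and maximum. Unlike the pair-wise
#' distance this needs no correspondence and is direction-dependent; both
#' directions are reported separately by [evaluate_prediction()].
#'
#' @param source,target Clouds: `breast_pcl` (surface points used) or
#'   n x 3 matrices / tibbles with `x,y,z`.
#' @param chunk Rows of `source` processed per block (memory/speed
#'   trade-off).
#' @return Tibble with one row: `mu`, `sigma`, `max` (mm), `n_points`.
#' @export
global_distance <- function(source, target, chunk = 2048L) {
  s <- .eval_points(source)
  t <- .eval_points(target)
  if (nrow(s) == 0 || nrow(t) == 0) {
    stop("global distance needs non-empty clouds", call. = FALSE)
  }
  tt <- rowSums(t^2)
  mins <- numeric(nrow(s))
  for (i0 in seq(1, nrow(s), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, nrow(s))
    block <- s[idx, , drop = FALSE]
    # locate the nearest neighbour via the |s-t|^2 expansion (ties -> lowest
    # index), then recompute its distance directly for full precision
    d2 <- outer(rowSums(block^2), tt, `+`) - 2 * tcrossprod(block, t)
    j <- apply(d2, 1, which.min)
    mins[idx] <- sqrt(rowSums((block - t[j, , drop = FALSE])^2))
  }
  .dist_summary(mins)
}

.eval_points <- function(x) {
  if (inherits(x, "breast_pcl")) return(pcl_points(x, surface_only = TRUE))
  if (is.data.frame(x)) return(cbind(x$x, x$y, x$z))
  as.matrix(x)
}

.dist_summary <- function(d) {
  n <- length(d)
  tibble::tibble(
    mu = mean(d),
    sigma = sqrt(mean((d - mean(d))^2)),  # population sd
    max = max(d),
    n_points = n
  )
}

#' Full distance evaluation of a predicted cloud
#'
#' Assembles the standard report: pair-wise distance between prediction
#' and target, directed global distances in both directions, and (when the
#' pre-surgery cloud is given) the baseline evaluation in which the
#' prediction is taken to be the pre-surgery cloud itself. All metrics use
#' surface points only.
#'
#' @param pred Predicted cloud.
#' @param target Post-surgery (ground-truth) cloud.
#' @param pre Optional pre-surgery cloud for the baseline columns.
#' @return Tibble (class `eval_report`) with columns `metric`
#'   (`p2p`, `global_src_to_tgt`, `global_tgt_to_src`), `mu`, `sigma`,
#'   `max`, `n_points`, `baseline` (logical).
#' @export
evaluate_prediction <- function(pred, target, pre = NULL) {
  rows <- dplyr::bind_rows(
    dplyr::mutate(pairwise_distance(pred, target), metric = "p2p"),
    dplyr::mutate(global_distance(pred, target), metric = "global_src_to_tgt"),
    dplyr::mutate(global_distance(target, pred), metric = "global_tgt_to_src")
  )
  rows$baseline <- FALSE
  if (!is.null(pre)) {
    base <- dplyr::bind_rows(
      dplyr::mutate(pairwise_distance(pre, target), metric = "p2p"),
      dplyr::mutate(global_distance(pre, target), metric = "global_src_to_tgt"),
      dplyr::mutate(global_distance(target, pre), metric = "global_tgt_to_src")
    )
    base$baseline <- TRUE
    rows <- dplyr::bind_rows(rows, base)
  }
  out <- rows[, c("metric", "baseline", "mu", "sigma", "max", "n_points")]
  class(out) <- c("eval_report", class(out))
  out
}

#' Baseline (no-method) evaluation
#'
#' The reference evaluation in which the predicted cloud is exactly the
#' pre-surgery cloud; by definition its pair-wise row equals
#' `pairwise_distance(pre, post)`.
#'
#' @param pre,post Pre- and post-surgery clouds with correspondence.
#' @return An `eval_report` tibble (all rows flagged `baseline = TRUE`).
#' @export
baseline_eval <- function(pre, post) {
  out <- evaluate_prediction(pre, post)
  out$baseline <- TRUE
  out
}

#' Pooled distance evaluation over many cases
#'
#' Pools per-point distances across a list of (pred, target) cloud pairs
#' and summarizes them once, so `mu` is the mean over all points of all
#' cases and `max` the global maximum.
#'
#' @param preds,targets Lists of clouds of equal length.
#' @param pres Optional list of pre-surgery clouds for baseline rows.
#' @return An `eval_report` tibble.
#' @export
evaluate_cases <- function(preds, targets, pres = NULL) {
  stopifnot(length(preds) == length(targets))
  p2p <- unlist(purrr::map2(preds, targets, pointwise_distances))
  g_st <- dplyr::bind_rows(purrr::map2(preds, targets, global_distance))
  g_ts <- dplyr::bind_rows(purrr::map2(targets, preds, global_distance))
  pool_dir <- function(g) {
    # pooled mean/sd over all points requires re-pooling the per-case stats
    n <- sum(g$n_points)
    mu <- sum(g$mu * g$n_points) / n
    m2 <- sum((g$sigma^2 + g$mu^2) * g$n_points) / n
    tibble::tibble(mu = mu, sigma = sqrt(pmax(m2 - mu^2, 0)),
                   max = max(g$max), n_points = n)
  }
  rows <- dplyr::bind_rows(
    dplyr::mutate(.dist_summary(p2p), metric = "p2p"),
    dplyr::mutate(pool_dir(g_st), metric = "global_src_to_tgt"),
    dplyr::mutate(pool_dir(g_ts), metric = "global_tgt_to_src")
  )
  rows$baseline <- FALSE
  if (!is.null(pres)) {
    base <- evaluate_cases(pres, targets)
    base$baseline <- TRUE
    rows <- dplyr::bind_rows(rows, base)
  }
  out <- rows[, c("metric", "baseline", "mu", "sigma", "max", "n_points")]
  class(out) <- c("eval_report", class(out))
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> distances in mm (surface points)\n")
  NextMethod()
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `eval_report` tibble.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
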