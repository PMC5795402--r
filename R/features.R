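#' Names of the 23 regression features
#'
#' Grouped as: point coordinates (`px`, `py`, `pz`), signed per-axis
#' differences to the excision cylinder (`dispx`, `dispy`, `dispz`),
#' Euclidean distance to the cylinder solid (`d_cyl`), cylindrical
#' coordinates in the cylinder frame (`rho`, `phi`, `zc`), tumor size
#' one-hot (`s1`, `s2`, `s3` for S/M/L), laterality one-hot (`R`, `L`),
#' density one-hot (`A`, `B`, `C`, `D`) and tumor-quadrant one-hot
#' (`R1`..`R4` for UOQ/UIQ/LOQ/LIQ).
#'
#' @return Character vector of length 23.
#' @export
feature_columns <- function() {
  c("px", "py", "pz", "dispx", "dispy", "dispz", "d_cyl",
    "rho", "phi", "zc", "s1", "s2", "s3", "R", "L",
    "A", "B", "C", "D", "R1", "R2", "R3", "R4")
}

#' Feature groups for grouped importances
#'
#' @return Tibble with columns `feature` and `group`.
#' @export
feature_groups <- function() {
  tibble::tibble(
    feature = feature_columns(),
    group = c(rep("coordinates", 3), rep("coordinate_difference", 3),
              "distance_to_cylinder", rep("polar_distance", 3),
              rep("tumor_size", 3), rep("laterality", 2),
              rep("density", 4), rep("tumor_region", 4))
  )
}

#' Compute the per-point feature table for a case
#'
#' Coordinates are centered on the cloud's centroid (the cylinder is
#' shifted consistently so all cylinder-relative quantities are unchanged).
#' For each point: `dispx/y/z` are the signed per-axis differences to the
#' nearest point of the cylinder axis segment; `d_cyl` is the Euclidean
#' distance to the cylinder solid (0 inside); `rho`, `phi`, `zc` are
#' cylindrical coordinates in the frame whose z-axis is the cylinder axis
#' anchored at the base point, with `phi` measured from the breast's
#' lateral direction projected into the plane normal to the axis. All
#' seven distance-family features are set to exactly zero for damaged
#' points (inside the excision cylinder). Categorical one-hot columns come
#' from the case specification.
#'
#' @param pcl Pre-surgery [breast_pcl()].
#' @param cyl An `excision_cylinder`.
#' @param case One-row case tibble (columns `density`, `quadrant`,
#'   `tumor_size`, `laterality`, plus ids).
#' @param damaged Optional logical vector of damaged labels; computed with
#'   [label_damaged()] when missing.
#' @return Tibble with the 23 feature columns of [feature_columns()] plus
#'   bookkeeping columns `case_id`, `patient_id`, `is_surface`, `damaged`.
#' @export
compute_features <- function(pcl, cyl, case, damaged = NULL) {
  pts <- pcl_matrix(pcl)
  if (is.null(damaged)) damaged <- label_damaged(pts, cyl)
  stopifnot(length(damaged) == nrow(pts))
  centroid <- colMeans(pts)
  ctr <- sweep(pts, 2, centroid)
  cyl_c <- cyl
  cyl_c$base_point <- cyl$base_point - centroid
  cyl_c$tumor_center <- cyl$tumor_center - centroid

  # nearest point of the axis segment (axial coordinate clamped to [0, h])
  rel <- sweep(ctr, 2, cyl_c$base_point)
  t_ax <- drop(rel %*% cyl_c$axis)
  t_cl <- pmin(pmax(t_ax, 0), cyl_c$height)
  nearest_axis <- t(cyl_c$base_point + t(outer(t_cl, cyl_c$axis)))
  disp <- ctr - nearest_axis

  d_cyl <- cylinder_distance(ctr, cyl_c)

  # cylinder-frame cylindrical coordinates
  radial <- rel - outer(t_ax, cyl_c$axis)
  rho <- sqrt(rowSums(radial^2))
  lat_sign <- if (attr(pcl, "laterality") == "R") 1 else -1
  lat_dir <- c(lat_sign, 0, 0)
  e1 <- lat_dir - sum(lat_dir * cyl_c$axis) * cyl_c$axis
  e1n <- sqrt(sum(e1^2))
  if (e1n < 1e-9) {  # axis parallel to the lateral direction: fall back to z
    e1 <- c(0, 0, 1) - sum(c(0, 0, 1) * cyl_c$axis) * cyl_c$axis
    e1n <- sqrt(sum(e1^2))
  }
  e1 <- e1 / e1n
  e2 <- .cross3(cyl_c$axis, e1)
  phi <- atan2(drop(radial %*% e2), drop(radial %*% e1))
  phi[rho < 1e-12] <- 0

  zero <- function(v) { v[damaged] <- 0; v }
  disp[damaged, ] <- 0

  onehot <- function(value, levels) {
    m <- outer(rep(value, nrow(pts)), levels, `==`) * 1L
    m[1:nrow(pts), , drop = FALSE]
  }
  size_oh <- onehot(case$tumor_size, c("S", "M", "L"))
  lat_oh <- onehot(attr(pcl, "laterality"), c("R", "L"))
  dens_oh <- onehot(case$density, c("A", "B", "C", "D"))
  quad_oh <- onehot(case$quadrant, c("UOQ", "UIQ", "LOQ", "LIQ"))

  tibble::tibble(
    case_id = case$case_id,
    patient_id = case$patient_id,
    is_surface = pcl$is_surface,
    damaged = damaged,
    px = ctr[, 1], py = ctr[, 2], pz = ctr[, 3],
    dispx = disp[, 1], dispy = disp[, 2], dispz = disp[, 3],
    d_cyl = zero(d_cyl),
    rho = zero(rho), phi = zero(phi), zc = zero(t_ax),
    s1 = size_oh[, 1], s2 = size_oh[, 2], s3 = size_oh[, 3],
    R = lat_oh[, 1], L = lat_oh[, 2],
    A = dens_oh[, 1], B = dens_oh[, 2], C = dens_oh[, 3], D = dens_oh[, 4],
    R1 = quad_oh[, 1], R2 = quad_oh[, 2], R3 = quad_oh[, 3], R4 = quad_oh[, 4]
  )
}

#' Assemble the stacked training matrix with per-axis targets
#'
#' Stacks the feature tables of all cases and appends the regression
#' targets `dx`, `dy`, `dz`: the per-point displacement from the
#' pre-surgery to the post-surgery cloud (so that adding the predicted
#' displacement to the pre-surgery coordinates recovers the predicted
#' shape). Surface and interior points are both included.
#'
#' @param dataset A `bcs_dataset` from [generate_dataset()] (or any list of
#'   bundles with `pre`, `post`, `cylinder`, `case`, `damaged`).
#' @return Tibble: bookkeeping columns, the 23 features, and targets
#'   `dx`, `dy`, `dz` (mm).
#' @export
assemble_training_matrix <- function(dataset) {
  purrr::map_dfr(dataset, function(b) {
    if (nrow(b$pre) != nrow(b$post)) {
      stop("correspondence error: pre and post clouds differ in length for case ",
           b$case$case_id, call. = FALSE)
    }
    ft <- compute_features(b$pre, b$cylinder, b$case, b$damaged)
    ft$dx <- b$post$x - b$pre$x
    ft$dy <- b$post$y - b$pre$y
    ft$dz <- b$post$z - b$pre$z
    ft
  })
}

#' Write / read feature tables as CSV
#'
#' @param features A feature tibble from [compute_features()] or
#'   [assemble_training_matrix()].
#' @param path File path.
#' @export
write_features_csv <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
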