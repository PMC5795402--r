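#' Quadrant planes
#'
#' The breast is discretized into four quadrants — Upper-Outer (UOQ),
#' Upper-Inner (UIQ), Lower-Outer (LOQ) and Lower-Inner (LIQ) — by two
#' planes through the nipple, themselves anchored on the pectoral (chest
#' wall) plane. Three planes are built sequentially:
#'
#' 1. the *pectoral plane*, whose unit normal is the normalized cross
#'    product of the two edge vectors spanned by the three pectoral corner
#'    points (two superior, one inferior);
#' 2. the *superior-inferior plane*, parallel to the xy-plane (normal along
#'    z, the inferior-to-superior axis) and crossing the nipple;
#' 3. the *lateral-medial plane*, perpendicular to the pectoral plane,
#'    crossing the nipple, and containing the superior-inferior plane's
#'    normal direction (its normal is the cross product of the pectoral
#'    normal with the z axis).
#'
#' A plane is stored as `list(normal, offset)` with unit `normal` and
#' `offset` such that a point `p` is on the plane iff `sum(normal * p) ==
#' offset`.
#'
#' @param pcl A [breast_pcl()] (its `nipple` and `pectoral_corners`
#'   attributes are used).
#' @return An object of class `quadrant_planes`: a list with elements
#'   `pectoral`, `superior_inferior` and `lateral_medial`, each a
#'   `list(normal, offset)`.
#' @export
#' @examples
#' corners <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 0, 100))
#' pts <- tibble::tibble(x = 50, y = 60, z = 50, is_surface = TRUE)
#' pcl <- breast_pcl(pts, "R", nipple = c(50, 60, 50),
#'                   pectoral_corners = corners, breast_volume = 1e6)
#' build_quadrant_planes(pcl)
build_quadrant_planes <- function(pcl) {
  corners <- attr(pcl, "pectoral_corners")
  nipple <- attr(pcl, "nipple")
  v1 <- corners[2, ] - corners[1, ]
  v2 <- corners[3, ] - corners[1, ]
  n_pect <- .cross3(v1, v2)
  len <- sqrt(sum(n_pect^2))
  if (len < 1e-9) stop("degenerate geometry: pectoral corners are collinear", call. = FALSE)
  n_pect <- n_pect / len
  n_si <- c(0, 0, 1)
  n_lm <- .cross3(n_pect, n_si)
  lm_len <- sqrt(sum(n_lm^2))
  if (lm_len < 1e-9) {
    stop("degenerate geometry: pectoral normal is parallel to the superior-inferior axis",
         call. = FALSE)
  }
  n_lm <- n_lm / lm_len
  structure(
    list(
      pectoral = list(normal = n_pect, offset = sum(n_pect * corners[1, ])),
      superior_inferior = list(normal = n_si, offset = sum(n_si * nipple)),
      lateral_medial = list(normal = n_lm, offset = sum(n_lm * nipple))
    ),
    class = "quadrant_planes"
  )
}

#' Signed distance from points to a plane
#'
#' @param points Numeric matrix (n x 3) or length-3 vector.
#' @param plane A `list(normal, offset)` plane.
#' @return Numeric vector of signed distances (positive on the side the
#'   normal points to).
#' @export
plane_distance <- function(points, plane) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  drop(points %*% plane$normal) - plane$offset
}

#' Assign breast quadrants
#'
#' Each point falls in one of UOQ, UIQ, LOQ, LIQ according to the signs of
#' its distances to the superior-inferior and lateral-medial planes. The
#' "outer" (lateral) side depends on laterality: for a right breast the
#' lateral side is the positive side of the lateral-medial plane normal
#' (which points along +x when the pectoral normal is +y); for a left
#' breast it is the negative side. Points exactly on a boundary plane go to
#' the superior / lateral side (deterministic tie rule).
#'
#' @param points Numeric matrix (n x 3), length-3 vector, or a
#'   [breast_pcl()].
#' @param planes A `quadrant_planes` object.
#' @param laterality `"R"` or `"L"`; defaults to the cloud's own laterality
#'   when `points` is a `breast_pcl`.
#' @return Character vector in `c("UOQ","UIQ","LOQ","LIQ")`, one per point.
#' @export
assign_quadrant <- function(points, planes, laterality = NULL) {
  if (inherits(points, "breast_pcl")) {
    if (is.null(laterality)) laterality <- attr(points, "laterality")
    points <- pcl_matrix(points)
  }
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  laterality <- match.arg(laterality, c("R", "L"))
  d_si <- plane_distance(points, planes$superior_inferior)
  d_lm <- plane_distance(points, planes$lateral_medial)
  upper <- d_si >= 0
  lat_sign <- if (laterality == "R") 1 else -1
  # tie rule: points exactly on the lateral-medial plane go lateral (outer)
  outer <- (lat_sign * d_lm) >= 0
  unname(ifelse(upper,
                ifelse(outer, "UOQ", "UIQ"),
                ifelse(outer, "LOQ", "LIQ")))
}

#' Excision cylinder
#'
#' The volume excised during breast-conserving surgery is approximated by a
#' cylinder containing the tumor, with axis perpendicular to the chest
#' wall, extending from the pectoral muscle to the skin. The axis direction
#' is the unit vector from the tumor center's orthogonal projection on the
#' pectoral plane to the tumor center; the height is the largest axial
#' projection of the skin surface near the axis; the radius follows from
#' the prescribed excision volume fraction:
#' `radius = sqrt(volume_fraction * breast_volume / (pi * height))`.
#'
#' Eligibility for breast-conserving surgery bounds the excision at 20% of
#' the breast volume; the simulated tumor size classes use 5%, 7.5% and 10%
#' (small, medium, large).
#'
#' @param pcl A [breast_pcl()].
#' @param tumor_center Numeric length-3, tumor center (mm).
#' @param volume_fraction Excision volume as a fraction of breast volume
#'   (default classes 0.05 / 0.075 / 0.10; any value <= 0.20 accepted).
#' @param k_height Number of radially-nearest surface points used to locate
#'   the skin along the axis (the height is the maximum of their axial
#'   projections).
#' @return An object of class `excision_cylinder`: list with `base_point`,
#'   `axis` (unit), `height`, `radius`, `volume_fraction`, `tumor_center`.
#' @export
make_excision_cylinder <- function(pcl, tumor_center, volume_fraction,
                                   k_height = 10L) {
  stopifnot(length(tumor_center) == 3)
  if (!isTRUE(volume_fraction > 0 && volume_fraction <= 0.20)) {
    stop("volume_fraction must be in (0, 0.20]", call. = FALSE)
  }
  planes <- build_quadrant_planes(pcl)
  pect <- planes$pectoral
  d <- plane_distance(tumor_center, pect)
  base_point <- as.numeric(tumor_center) - d * pect$normal
  if (abs(d) < 1e-9) {
    stop("geometry error: tumor center lies on the pectoral plane", call. = FALSE)
  }
  axis <- sign(d) * pect$normal  # from muscle toward the tumor / skin
  surf <- pcl_points(pcl, surface_only = TRUE)
  rel <- sweep(surf, 2, base_point)
  t_ax <- drop(rel %*% axis)
  r_ax <- sqrt(pmax(rowSums(rel^2) - t_ax^2, 0))
  k <- min(k_height, nrow(surf))
  nearest <- order(r_ax)[seq_len(k)]
  height <- max(t_ax[nearest])
  if (!isTRUE(height > 0)) {
    stop("geometry error: non-positive cylinder height", call. = FALSE)
  }
  breast_volume <- attr(pcl, "breast_volume")
  radius <- sqrt(volume_fraction * breast_volume / (pi * height))
  extent <- max(abs(pcl$x - mean(range(pcl$x))), na.rm = TRUE)
  if (radius > extent) {
    warning("excision cylinder radius exceeds the breast's lateral extent",
            call. = FALSE)
  }
  structure(
    list(base_point = base_point, axis = axis, height = height,
         radius = radius, volume_fraction = volume_fraction,
         tumor_center = as.numeric(tumor_center)),
    class = "excision_cylinder"
  )
}

#' @export
print.excision_cylinder <- function(x, ...) {
  cat(sprintf(
    "<excision_cylinder> r = %.2f mm, h = %.2f mm, volume fraction %.3f\n",
    x$radius, x$height, x$volume_fraction
  ))
  invisible(x)
}

#' Cylinder-frame coordinates of points
#'
#' Axial coordinate `t` (projection on the axis, anchored at the base
#' point) and radial distance `r` to the axis line, for each point.
#'
#' @param points Numeric matrix (n x 3).
#' @param cyl An `excision_cylinder`.
#' @return List with numeric vectors `t` and `r`.
#' @keywords internal
cylinder_coords <- function(points, cyl) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  rel <- sweep(points, 2, cyl$base_point)
  t_ax <- drop(rel %*% cyl$axis)
  r_ax <- sqrt(pmax(rowSums(rel^2) - t_ax^2, 0))
  list(t = t_ax, r = r_ax)
}

#' Label points damaged by the excision
#'
#' A point is damaged iff it lies inside the excision cylinder: its axial
#' projection falls in `[0, height]` and its radial distance to the axis is
#' at most the radius.
#'
#' @param pcl A [breast_pcl()] or numeric matrix (n x 3).
#' @param cyl An `excision_cylinder`.
#' @return Logical vector, one flag per point.
#' @export
label_damaged <- function(pcl, cyl) {
  pts <- if (inherits(pcl, "breast_pcl")) pcl_matrix(pcl) else pcl
  cc <- cylinder_coords(pts, cyl)
  unname(cc$t >= 0 & cc$t <= cyl$height & cc$r <= cyl$radius)
}

#' Euclidean distance from points to the cylinder solid
#'
#' Zero inside the cylinder; outside, the distance to the nearest point of
#' the closed cylinder (lateral wall, caps, or rim).
#'
#' @inheritParams label_damaged
#' @return Numeric vector of distances (mm, >= 0).
#' @export
cylinder_distance <- function(pcl, cyl) {
  pts <- if (inherits(pcl, "breast_pcl")) pcl_matrix(pcl) else pcl
  cc <- cylinder_coords(pts, cyl)
  dr <- pmax(cc$r - cyl$radius, 0)
  dt <- pmax(pmax(-cc$t, cc$t - cyl$height), 0)
  sqrt(dr^2 + dt^2)
}
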