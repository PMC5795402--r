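#' Breast point clouds
#'
#' A breast point cloud (`breast_pcl`) is a tibble of 3D points (columns
#' `x`, `y`, `z` in mm and a logical `is_surface`) carrying per-breast
#' metadata as attributes: `laterality` (`"R"` or `"L"`), `nipple` (length-3
#' numeric, mm), `pectoral_corners` (3x3 matrix, one corner per row, the
#' first two superior and the third inferior), `breast_volume` (mm^3) and
#' `patient_id`. Surface (skin) points come first, interior points after;
#' row order is the point correspondence used throughout: row `i` of a
#' pre-surgery cloud corresponds to row `i` of its post-surgery (or
#' predicted) cloud.
#'
#' The coordinate frame is right-handed with x running medial to lateral
#' (the lateral sense flips with laterality), y posterior to anterior (the
#' direction the breast protrudes, away from the chest wall) and z inferior
#' to superior. Planes separating superior from inferior therefore have a
#' z-aligned normal.
#'
#' @param points A data frame with numeric columns `x`, `y`, `z` (mm) and a
#'   logical column `is_surface`. Surface rows must precede interior rows.
#' @param laterality `"R"` or `"L"`.
#' @param nipple Numeric length-3, nipple position (mm).
#' @param pectoral_corners Numeric 3x3 matrix of pectoral-muscle corner
#'   points (rows); the three must not be collinear.
#' @param breast_volume Breast volume in mm^3 (> 0).
#' @param patient_id Patient identifier.
#'
#' @return A `breast_pcl`: a tibble with the metadata attached as attributes.
#' @export
#' @examples
#' pts <- tibble::tibble(
#'   x = c(0, 10, 5), y = c(50, 40, 20), z = c(0, 5, -5),
#'   is_surface = c(TRUE, TRUE, FALSE)
#' )
#' corners <- rbind(c(-60, 0, 50), c(60, 0, 50), c(0, 0, -55))
#' pcl <- breast_pcl(pts, "R", nipple = c(0, 55, 0),
#'                   pectoral_corners = corners, breast_volume = 5e5,
#'                   patient_id = "P1")
#' n_surface(pcl)
breast_pcl <- function(points, laterality, nipple, pectoral_corners,
                       breast_volume, patient_id = NA_character_) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("x", "y", "z", "is_surface") %in% names(points)))
  laterality <- match.arg(laterality, c("R", "L"))
  nipple <- as.numeric(nipple)
  stopifnot(length(nipple) == 3)
  pectoral_corners <- as.matrix(pectoral_corners)
  stopifnot(identical(dim(pectoral_corners), c(3L, 3L)))
  if (.collinear(pectoral_corners)) {
    stop("degenerate geometry: pectoral corners are collinear", call. = FALSE)
  }
  if (!isTRUE(breast_volume > 0)) stop("breast_volume must be > 0", call. = FALSE)
  if (is.unsorted(rev(points$is_surface))) {
    stop("surface points must precede interior points", call. = FALSE)
  }
  structure(
    points,
    laterality = laterality,
    nipple = nipple,
    pectoral_corners = pectoral_corners,
    breast_volume = breast_volume,
    patient_id = patient_id,
    class = c("breast_pcl", class(tibble::tibble()))
  )
}

.collinear <- function(m, tol = 1e-9) {
  v1 <- m[2, ] - m[1, ]
  v2 <- m[3, ] - m[1, ]
  cr <- .cross3(v1, v2)
  sqrt(sum(cr^2)) < tol * max(1, sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @rdname breast_pcl
#' @param pcl A `breast_pcl`.
#' @export
n_surface <- function(pcl) sum(pcl$is_surface)

#' @rdname breast_pcl
#' @export
n_interior <- function(pcl) sum(!pcl$is_surface)

#' @rdname breast_pcl
#' @export
pcl_matrix <- function(pcl) {
  cbind(x = pcl$x, y = pcl$y, z = pcl$z)
}

#' @rdname breast_pcl
#' @param surface_only Keep only surface (skin) rows.
#' @export
pcl_points <- function(pcl, surface_only = FALSE) {
  m <- pcl_matrix(pcl)
  if (surface_only) m <- m[pcl$is_surface, , drop = FALSE]
  m
}

#' Replace the coordinates of a cloud, keeping metadata and row order
#'
#' @param pcl A `breast_pcl`.
#' @param xyz Numeric matrix (n x 3) of new coordinates.
#' @return A `breast_pcl` with the same metadata and `is_surface` flags.
#' @export
set_coords <- function(pcl, xyz) {
  stopifnot(nrow(xyz) == nrow(pcl))
  out <- pcl
  out$x <- xyz[, 1]
  out$y <- xyz[, 2]
  out$z <- xyz[, 3]
  out
}

#' @export
print.breast_pcl <- function(x, ...) {
  cat(sprintf(
    "<breast_pcl> patient %s, laterality %s, %d surface + %d interior points, volume %.0f mm^3\n",
    attr(x, "patient_id"), attr(x, "laterality"),
    n_surface(x), n_interior(x), attr(x, "breast_volume")
  ))
  NextMethod()
}

# --- IO ---------------------------------------------------------------------

#' Read and write point clouds and case metadata
#'
#' Clouds round-trip as ASCII PLY (`x`, `y`, `z` plus an `is_surface`
#' property) or as XYZ CSV with header `x,y,z,is_surface`; per-case
#' metadata round-trips as JSON. The PLY reader accepts plain vertex-only
#' ASCII files written by this package or other tools (float/double
#' properties; faces are ignored).
#'
#' @param pcl A `breast_pcl` (or plain tibble with `x,y,z,is_surface`).
#' @param path File path.
#' @name pcl_io
NULL

#' @rdname pcl_io
#' @export
write_pcl_ply <- function(pcl, path) {
  n <- nrow(pcl)
  header <- c(
    "ply", "format ascii 1.0",
    "comment bcsdeform breast point cloud",
    sprintf("element vertex %d", n),
    "property double x", "property double y", "property double z",
    "property uchar is_surface",
    "end_header"
  )
  body <- sprintf("%.10g %.10g %.10g %d", pcl$x, pcl$y, pcl$z,
                  as.integer(pcl$is_surface))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname pcl_io
#' @export
read_pcl_ply <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "ply")) stop("not a PLY file: ", path, call. = FALSE)
  end <- match("end_header", lines)
  header <- lines[seq_len(end)]
  vline <- grep("^element vertex", header, value = TRUE)[1]
  n <- as.integer(sub("element vertex\\s+", "", vline))
  props <- sub("^property\\s+\\S+\\s+", "", grep("^property", header, value = TRUE))
  body <- lines[end + seq_len(n)]
  vals <- utils::read.table(text = body, col.names = props)
  out <- tibble::as_tibble(vals)
  if (!"is_surface" %in% names(out)) out$is_surface <- TRUE
  out$is_surface <- as.logical(out$is_surface)
  out[, c("x", "y", "z", "is_surface")]
}

#' @rdname pcl_io
#' @export
write_pcl_xyz <- function(pcl, path) {
  readr::write_csv(
    tibble::tibble(x = pcl$x, y = pcl$y, z = pcl$z,
                   is_surface = as.integer(pcl$is_surface)),
    path
  )
  invisible(path)
}

#' @rdname pcl_io
#' @export
read_pcl_xyz <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  out$is_surface <- as.logical(out$is_surface)
  out
}

#' @rdname pcl_io
#' @param case A one-row case tibble (see [enumerate_cases()]) or a list of
#'   case metadata.
#' @export
write_case_json <- function(case, pcl, path) {
  meta <- list(
    patient_id = attr(pcl, "patient_id"),
    laterality = attr(pcl, "laterality"),
    density = case$density,
    quadrant = case$quadrant,
    size_class = case$size_class,
    tumor_size = case$tumor_size,
    nipple = attr(pcl, "nipple"),
    pectoral_corners = attr(pcl, "pectoral_corners"),
    breast_volume = attr(pcl, "breast_volume"),
    seed = case$seed
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pcl_io
#' @export
read_case_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Rebuild a `breast_pcl` from points + metadata read back from disk
#'
#' @param points Tibble with `x,y,z,is_surface`.
#' @param meta List as returned by [read_case_json()].
#' @return A `breast_pcl`.
#' @export
pcl_from_parts <- function(points, meta) {
  pc <- meta$pectoral_corners
  if (!is.matrix(pc)) pc <- matrix(as.numeric(unlist(pc)), 3, 3, byrow = TRUE)
  breast_pcl(points,
             laterality = meta$laterality,
             nipple = as.numeric(meta$nipple),
             pectoral_corners = pc,
             breast_volume = meta$breast_volume,
             patient_id = meta$patient_id)
}
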