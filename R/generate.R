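#' Deformation-field parameters for the synthetic simulator
#'
#' The synthetic post-surgery generator contracts the breast toward the
#' excision cylinder with an exponential-decay displacement field. With
#' `e = exp(-d / decay_length)` (`d` the point's Euclidean distance to the
#' cylinder solid, zero inside) and the class factor
#' `k = density_factor[density] * size_factor[tumor_size]`, each point's
#' displacement magnitude is
#' `base_amplitude * e * (1 + (k - 1) * e * q) * (1 + eps)`,
#' where `q` is 1 for points in the quadrant containing the tumor and 0
#' elsewhere. At the excision the magnitude is the fully class-scaled
#' `base_amplitude * k`; outside the excised quadrant the field is the
#' class-independent generic settling `base_amplitude * e` of the
#' surrounding tissue — the wound's size and the tissue stiffness govern
#' contraction of the operated quadrant, while more distant tissue
#' settles generically. The density multipliers {A:4, B:3, C:2, D:1} and
#' size multipliers {L:3, M:2, S:1} encode the two dominant clinical
#' effects: displacement magnitude decreases with breast density (dense,
#' fibroglandular-rich breasts deform less) and grows with tumor size (a
#' larger excised volume leaves a larger void for tissue to fill).
#'
#' @param base_amplitude Displacement scale (mm): the magnitude at the
#'   excision for the least-deforming class (density D, small tumor), for
#'   which the field is exactly `base_amplitude * e`.
#' @param decay_length Exponential decay length of the field (mm).
#' @param noise_sd Standard deviation of the multiplicative noise `eps`,
#'   expressed as a fraction of the local magnitude; `eps` is clipped at
#'   +/- 0.5.
#' @param settle_frac Fraction of the displacement budget spent on
#'   posterior settling (movement toward the chest wall) rather than on
#'   radial contraction toward the excision axis. Wound-healing
#'   contraction both pulls tissue toward the void and lets the breast
#'   settle back toward the pectoral wall; the settling component is
#'   coherent across a quadrant (and mirror-invariant), which is what
#'   makes per-quadrant mean displacements informative.
#' @return A list of parameters (class `deformation_params`).
#' @export
deformation_params <- function(base_amplitude = 5, decay_length = 30,
                               noise_sd = 0.05, settle_frac = 0.5) {
  stopifnot(base_amplitude > 0, decay_length > 0, noise_sd >= 0,
            settle_frac >= 0, settle_frac < 1)
  structure(
    list(
      base_amplitude = base_amplitude,
      decay_length = decay_length,
      density_factor = c(A = 4, B = 3, C = 2, D = 1),
      size_factor = c(L = 3, M = 2, S = 1),
      noise_sd = noise_sd,
      settle_frac = settle_frac
    ),
    class = "deformation_params"
  )
}

# half-ellipsoid semi-axes (x lateral, y anterior, z vertical) for a target
# volume; fixed anisotropy ratios give breast-like proportions
.semi_axes <- function(volume) {
  rb <- 0.9   # z/x ratio
  rc <- 0.65  # y/x ratio
  a <- (volume / ((2 / 3) * pi * rb * rc))^(1 / 3)
  c(a = a, b = rb * a, c = rc * a)
}

# uniform-ish sample of n points on the anterior dome of the half-ellipsoid
.sample_dome <- function(n, semi) {
  g <- matrix(stats::rnorm(3 * n), ncol = 3)
  g <- g / sqrt(rowSums(g^2))
  g[, 2] <- abs(g[, 2])
  cbind(semi["a"] * g[, 1], semi["c"] * g[, 2], semi["b"] * g[, 3])
}

# uniform sample of n points inside the half-ellipsoid (rejection)
.sample_interior <- function(n, semi) {
  out <- matrix(numeric(0), ncol = 3)
  while (nrow(out) < n) {
    m <- ceiling((n - nrow(out)) / 0.5)
    cand <- cbind(stats::runif(m, -semi["a"], semi["a"]),
                  stats::runif(m, 0, semi["c"]),
                  stats::runif(m, -semi["b"], semi["b"]))
    keep <- (cand[, 1] / semi["a"])^2 + (cand[, 2] / semi["c"])^2 +
      (cand[, 3] / semi["b"])^2 <= 1
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic pre-surgery breast point cloud
#'
#' Builds a breast-like half-ellipsoid attached to a flat pectoral plane
#' (y = 0): surface (skin) points sampled on the anterior dome, interior
#' points uniform in the enclosed volume, nipple at the apex, pectoral
#' corner points on the chest-wall plane. The semi-axes are set from the
#' patient's target volume (the `volume` column of [patient_roster()]), so
#' the analytic enclosed volume equals the target exactly. Left breasts
#' are produced by mirroring x. Geometry is reproducible: it depends only
#' on the patient (via `patient_seed`), so all cases of one patient share
#' the same pre-surgery cloud.
#'
#' @param case A one-row tibble from [enumerate_cases()] (columns
#'   `patient_id`, `laterality`, `volume`, `patient_seed` used).
#' @param n_surface,n_interior Point counts (>= 50 each). Defaults are
#'   desk-scale; the full-resolution clouds of the source data would be
#'   about 1900 surface and 2500 interior points.
#' @return A [breast_pcl()].
#' @export
generate_breast_pcl <- function(case, n_surface = 400L, n_interior = 600L) {
  stopifnot(n_surface >= 50, n_interior >= 50)
  semi <- .semi_axes(case$volume)
  seed <- if ("patient_seed" %in% names(case)) case$patient_seed else case$seed
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  dome <- .sample_dome(n_surface - 1L, semi)
  apex <- c(0, semi[["c"]], 0)
  surf <- rbind(apex, dome)
  inter <- .sample_interior(n_interior, semi)
  pts <- rbind(surf, inter)
  dimnames(pts) <- NULL
  if (case$laterality == "L") pts[, 1] <- -pts[, 1]
  corners <- rbind(c(-semi[["a"]], 0, semi[["b"]]),
                   c(semi[["a"]], 0, semi[["b"]]),
                   c(0, 0, -semi[["b"]]))
  breast_pcl(
    tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                   is_surface = rep(c(TRUE, FALSE), c(n_surface, n_interior))),
    laterality = case$laterality,
    nipple = c(0, semi[["c"]], 0),
    pectoral_corners = corners,
    breast_volume = case$volume,
    patient_id = case$patient_id
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Place a tumor center inside a target quadrant
#'
#' Candidates are drawn uniformly inside the breast volume (restricted to
#' mid-depth, 25-75% of the anterior extent) and rejected until one falls
#' in the requested quadrant and the full excision cylinder cross-section
#' fits inside the breast's chest-wall ellipse.
#'
#' @param pcl A [breast_pcl()] from [generate_breast_pcl()].
#' @param quadrant Target quadrant (`"UOQ"`, `"UIQ"`, `"LOQ"`, `"LIQ"`).
#' @param volume_fraction Excision volume fraction (for the fit check).
#' @param seed Integer seed for the rejection sampler.
#' @param max_tries Sampling attempts before giving up.
#' @return Numeric length-3 tumor center (mm).
#' @export
place_tumor <- function(pcl, quadrant, volume_fraction, seed,
                        max_tries = 500L) {
  planes <- build_quadrant_planes(pcl)
  semi <- .semi_axes(attr(pcl, "breast_volume"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  theta <- seq(0, 2 * pi, length.out = 25L)[-25L]
  for (i in seq_len(max_tries)) {
    cand <- .sample_interior(1L, semi)[1, ]
    if (attr(pcl, "laterality") == "L") cand[1] <- -cand[1]
    if (cand[2] < 0.25 * semi[["c"]] || cand[2] > 0.75 * semi[["c"]]) next
    if (assign_quadrant(cand, planes, attr(pcl, "laterality")) != quadrant) next
    cyl <- tryCatch(
      suppressWarnings(make_excision_cylinder(pcl, cand, volume_fraction)),
      error = function(e) NULL
    )
    if (is.null(cyl)) next
    r <- cyl$radius
    fits <- all(((cand[1] + r * cos(theta)) / semi[["a"]])^2 +
                  ((cand[3] + r * sin(theta)) / semi[["b"]])^2 <= 1)
    if (fits) return(cand)
  }
  stop("could not place a tumor in quadrant ", quadrant,
       " with a fitting excision cylinder", call. = FALSE)
}

# deterministic geometric pseudo-noise: a function of point coordinates and
# the seed only, so the displacement field is invariant under row reordering
.geom_noise <- function(pts, seed, sd) {
  if (sd == 0) return(rep(0, nrow(pts)))
  s0 <- (seed %% 100000L) / 977.0
  v <- sin(pts[, 1] * 12.9898 + pts[, 2] * 78.233 + pts[, 3] * 37.719 + s0) *
    43758.5453
  u <- v - floor(v)
  u <- pmin(pmax(u, 1e-8), 1 - 1e-8)
  pmin(pmax(stats::qnorm(u) * sd, -0.5), 0.5)
}

#' Simulate the post-surgery cloud for a case
#'
#' Applies the exponential-decay contraction field of
#' [deformation_params()]: every point receives the displacement
#' magnitude budget described there (class-scaled at the excision,
#' decaying to class-independent settling far from it; `d_cyl` is zero
#' for damaged points, which thus collapse toward the axis at the full
#' class amplitude). A fraction
#' `settle_frac` of the budget moves the point along the cylinder axis
#' toward the chest wall (posterior settling); the rest moves it radially
#' toward the axis, capped at 95% of the point's radial distance so
#' points never cross the axis. Index correspondence with the pre-surgery
#' cloud is preserved, and the field is a deterministic function of
#' geometry and seed.
#'
#' @param pcl Pre-surgery [breast_pcl()].
#' @param cyl An `excision_cylinder` (see [make_excision_cylinder()]).
#' @param params A [deformation_params()] list.
#' @param density Breast density category (`"A".."D"`).
#' @param tumor_size Tumor size class (`"S"`, `"M"`, `"L"`).
#' @param tumor_quadrant The quadrant containing the tumor (`"UOQ"`,
#'   `"UIQ"`, `"LOQ"`, `"LIQ"`); when `NULL` the class-scaled term applies
#'   to the whole cloud.
#' @param seed Integer seed for the noise component.
#' @return List with elements `post` (the displaced [breast_pcl()]),
#'   `displacement` (tibble `dx`, `dy`, `dz` in mm) and `damaged`
#'   (logical vector).
#' @export
simulate_post_surgery <- function(pcl, cyl, params = deformation_params(),
                                  density, tumor_size, tumor_quadrant = NULL,
                                  seed = 1L) {
  pts <- pcl_matrix(pcl)
  damaged <- label_damaged(pts, cyl)
  d <- cylinder_distance(pts, cyl)
  k <- params$density_factor[[density]] * params$size_factor[[tumor_size]]
  eps <- .geom_noise(pts, seed, params$noise_sd)
  e <- exp(-d / params$decay_length)
  q <- if (is.null(tumor_quadrant)) {
    rep(1, nrow(pts))
  } else {
    planes <- build_quadrant_planes(pcl)
    as.numeric(assign_quadrant(pts, planes, attr(pcl, "laterality")) ==
                 tumor_quadrant)
  }
  mag <- params$base_amplitude * e * (1 + (k - 1) * e * q) * (1 + eps)
  # radial direction toward the axis
  rel <- sweep(pts, 2, cyl$base_point)
  t_ax <- drop(rel %*% cyl$axis)
  radial <- rel - outer(t_ax, cyl$axis)
  r <- sqrt(rowSums(radial^2))
  s <- params$settle_frac
  mag_rad <- pmin((1 - s) * mag, 0.95 * r)
  mag_settle <- s * mag
  unit <- radial / ifelse(r > 1e-12, r, 1)
  disp <- -unit * mag_rad - outer(mag_settle, cyl$axis)
  disp[r <= 1e-12, ] <- -outer(mag_settle[r <= 1e-12], cyl$axis)
  post <- set_coords(pcl, pts + disp)
  list(
    post = post,
    displacement = tibble::tibble(dx = disp[, 1], dy = disp[, 2], dz = disp[, 3]),
    damaged = damaged
  )
}

#' Generate a full paired synthetic dataset
#'
#' For each case of the factorial design this generates the patient's
#' pre-surgery cloud, places the tumor, builds the excision cylinder and
#' simulates the post-surgery cloud. The result is the package's standard
#' dataset container: a list of case bundles, each holding `case` (one-row
#' spec tibble), `pre`, `post`, `cylinder`, `displacement` and `damaged`.
#'
#' @param cases A case tibble from [enumerate_cases()] (or a subset of its
#'   rows).
#' @param n_surface,n_interior Per-cloud point counts.
#' @param params A [deformation_params()] list.
#' @param seed Root seed used to derive patient-level geometry seeds.
#' @return An object of class `bcs_dataset` (list of case bundles).
#' @export
#' @examples
#' cases <- enumerate_cases(2)[1:4, ]
#' ds <- generate_dataset(cases, n_surface = 60, n_interior = 60)
#' length(ds)
generate_dataset <- function(cases, n_surface = 400L, n_interior = 600L,
                             params = deformation_params(), seed = 1L) {
  cases$patient_seed <- derive_seed(seed, paste0("patient:", cases$patient_id))
  bundles <- purrr::map(seq_len(nrow(cases)), function(i) {
    case <- cases[i, ]
    pre <- generate_breast_pcl(case, n_surface, n_interior)
    center <- place_tumor(pre, case$quadrant, case$volume_fraction, case$seed)
    cyl <- suppressWarnings(
      make_excision_cylinder(pre, center, case$volume_fraction)
    )
    sim <- simulate_post_surgery(pre, cyl, params, case$density,
                                 case$tumor_size, case$quadrant, case$seed)
    list(case = case, pre = pre, post = sim$post, cylinder = cyl,
         displacement = sim$displacement, damaged = sim$damaged)
  })
  structure(bundles, class = "bcs_dataset", params = params, seed = seed)
}

#' @export
print.bcs_dataset <- function(x, ...) {
  cases <- dplyr::bind_rows(purrr::map(x, "case"))
  cat(sprintf("<bcs_dataset> %d cases, %d patients, %d points per cloud\n",
              length(x), dplyr::n_distinct(cases$patient_id),
              nrow(x[[1]]$pre)))
  invisible(x)
}

#' Collect the case table of a dataset
#'
#' @param dataset A `bcs_dataset`.
#' @return Tibble of the case specifications, one row per bundle.
#' @export
dataset_cases <- function(dataset) {
  dplyr::bind_rows(purrr::map(dataset, "case"))
}
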