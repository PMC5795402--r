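test_that("quadrant planes match the hand-computed cross-product construction", {
  pts <- tibble::tibble(x = 50, y = 60, z = 50, is_surface = TRUE)
  corners <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 0, 100))
  pcl <- breast_pcl(pts, "R", nipple = c(50, 60, 50),
                    pectoral_corners = corners, breast_volume = 1e6)
  pl <- build_quadrant_planes(pcl)

  # pectoral normal is +/- y (corners span the xz-plane)
  expect_equal(abs(pl$pectoral$normal), c(0, 1, 0), tolerance = 1e-12)
  # superior-inferior plane: z = 50; lateral-medial plane: x = 50
  expect_equal(abs(pl$superior_inferior$normal), c(0, 0, 1))
  expect_equal(pl$superior_inferior$offset / pl$superior_inferior$normal[3], 50)
  expect_equal(abs(pl$lateral_medial$normal), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(abs(pl$lateral_medial$offset), 50, tolerance = 1e-12)

  # both nipple planes contain the nipple
  expect_lt(abs(plane_distance(c(50, 60, 50), pl$superior_inferior)), 1e-9)
  expect_lt(abs(plane_distance(c(50, 60, 50), pl$lateral_medial)), 1e-9)
  # lateral-medial normal orthogonal to pectoral normal
  expect_lt(abs(sum(pl$lateral_medial$normal * pl$pectoral$normal)), 1e-9)

  # permuting the corners changes the plane only up to normal sign
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    pcl2 <- breast_pcl(pts, "R", nipple = c(50, 60, 50),
                       pectoral_corners = corners[perm, ],
                       breast_volume = 1e6)
    pl2 <- build_quadrant_planes(pcl2)
    expect_equal(abs(pl2$pectoral$normal), abs(pl$pectoral$normal),
                 tolerance = 1e-12)
  }

  # collinear corners are a degenerate geometry error
  bad <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
  expect_error(
    breast_pcl(pts, "R", nipple = c(50, 60, 50), pectoral_corners = bad,
               breast_volume = 1e6),
    "collinear"
  )
})

test_that("quadrant assignment covers all sign pairs, lateralities and ties", {
  pcl <- toy_pcl()
  pl <- build_quadrant_planes(pcl)
  # nipple at x = 0, z = 0; for a right breast lateral (outer) is +x
  up_out <- c(10, 30, 10); up_in <- c(-10, 30, 10)
  lo_out <- c(10, 30, -10); lo_in <- c(-10, 30, -10)
  expect_equal(assign_quadrant(up_out, pl, "R"), "UOQ")
  expect_equal(assign_quadrant(up_in, pl, "R"), "UIQ")
  expect_equal(assign_quadrant(lo_out, pl, "R"), "LOQ")
  expect_equal(assign_quadrant(lo_in, pl, "R"), "LIQ")
  # left breast: the lateral sense flips
  expect_equal(assign_quadrant(up_out, pl, "L"), "UIQ")
  expect_equal(assign_quadrant(up_in, pl, "L"), "UOQ")
  # mirrored point maps to the mirrored quadrant
  expect_equal(assign_quadrant(c(-10, 30, 10), pl, "L"),
               assign_quadrant(c(10, 30, 10), pl, "R"))
  # ties go superior / lateral
  expect_equal(assign_quadrant(c(0, 30, 0), pl, "R"), "UOQ")
  expect_equal(assign_quadrant(c(0, 30, 0), pl, "L"), "UOQ")
})

test_that("quadrant assignment partitions the cloud and mirrors correctly", {
  pcl <- toy_pcl(seed = 7)
  pl <- build_quadrant_planes(pcl)
  q <- assign_quadrant(pcl, pl)
  expect_length(q, nrow(pcl))
  expect_true(all(q %in% c("UOQ", "UIQ", "LOQ", "LIQ")))
  expect_equal(sum(table(q)), nrow(pcl))

  # mirroring through the lateral-medial plane swaps outer and inner labels
  mirrored <- pcl_matrix(pcl)
  mirrored[, 1] <- -mirrored[, 1]
  qm <- assign_quadrant(mirrored, pl, "R")
  swap <- c(UOQ = "UIQ", UIQ = "UOQ", LOQ = "LIQ", LIQ = "LOQ")
  on_plane <- abs(pcl$x) < 1e-12
  expect_equal(qm[!on_plane], unname(swap[q[!on_plane]]))
})

test_that("excision cylinder geometry follows the closed-form construction", {
  # flat skin at y = 50 above the tumor makes the height exactly 50
  surf <- expand.grid(x = seq(-30, 30, by = 5), z = seq(-30, 30, by = 5))
  pts <- tibble::tibble(x = surf$x, y = 50, z = surf$z, is_surface = TRUE)
  corners <- rbind(c(-40, 0, 40), c(40, 0, 40), c(0, 0, -40))
  pcl <- breast_pcl(pts, "R", nipple = c(0, 50, 0),
                    pectoral_corners = corners, breast_volume = 1e6)
  cyl <- suppressWarnings(
    make_excision_cylinder(pcl, c(0, 25, 0), 0.10)
  )
  expect_equal(cyl$height, 50)
  expect_equal(cyl$radius, sqrt(1e5 / (50 * pi)), tolerance = 1e-12)
  expect_equal(cyl$radius, 25.231, tolerance = 1e-4)
  expect_equal(sqrt(sum(cyl$axis^2)), 1, tolerance = 1e-12)

  # volume identity holds to 1e-6 relative for any fraction
  for (frac in c(0.05, 0.075, 0.10, 0.20)) {
    cl <- suppressWarnings(make_excision_cylinder(pcl, c(0, 25, 0), frac))
    expect_equal(pi * cl$radius^2 * cl$height / 1e6, frac,
                 tolerance = 1e-6)
  }
  # radius scaling law between 5% and 10% at the same height
  c05 <- suppressWarnings(make_excision_cylinder(pcl, c(0, 25, 0), 0.05))
  c10 <- suppressWarnings(make_excision_cylinder(pcl, c(0, 25, 0), 0.10))
  expect_equal(c10$radius / c05$radius, sqrt(2), tolerance = 1e-12)

  # eligibility bound and degenerate tumor position
  expect_error(make_excision_cylinder(pcl, c(0, 25, 0), 0.25), "0.20")
  expect_error(make_excision_cylinder(pcl, c(0, 0, 0), 0.05), "pectoral")
})

test_that("damaged labelling matches a brute-force point-in-cylinder oracle", {
  pcl <- toy_pcl(n_surface = 150, n_interior = 350, seed = 31)
  center <- place_tumor(pcl, "UOQ", 0.075, seed = 31)
  cyl <- suppressWarnings(make_excision_cylinder(pcl, center, 0.075))

  lab <- label_damaged(pcl, cyl)
  pts <- pcl_matrix(pcl)
  oracle <- vapply(seq_len(nrow(pts)), function(i) {
    rel <- pts[i, ] - cyl$base_point
    t <- sum(rel * cyl$axis)
    r <- sqrt(max(sum(rel^2) - t^2, 0))
    t >= 0 && t <= cyl$height && r <= cyl$radius
  }, logical(1))
  expect_identical(lab, oracle)
  expect_gt(sum(lab), 0)

  # point on the axis at mid-height is damaged; radius + eps is healthy
  mid <- cyl$base_point + 0.5 * cyl$height * cyl$axis
  expect_true(label_damaged(matrix(mid, 1), cyl))
  perp <- c(cyl$axis[2], -cyl$axis[1], 0)
  perp <- perp / sqrt(sum(perp^2))
  expect_false(label_damaged(matrix(mid + (cyl$radius + 1e-6) * perp, 1), cyl))
  expect_true(label_damaged(matrix(mid + (cyl$radius - 1e-6) * perp, 1), cyl))
})

test_that("distance to the cylinder solid matches a dense surface-sampling oracle", {
  pcl <- toy_pcl(seed = 13)
  center <- place_tumor(pcl, "LIQ", 0.05, seed = 13)
  cyl <- suppressWarnings(make_excision_cylinder(pcl, center, 0.05))

  set.seed(99)
  pts <- cbind(runif(200, -80, 80), runif(200, 0, 60), runif(200, -80, 80))
  d <- cylinder_distance(pts, cyl)

  # dense sampling of the cylinder boundary (wall + caps)
  theta <- seq(0, 2 * pi, length.out = 720L)
  hs <- seq(0, cyl$height, length.out = 700L)
  rs <- seq(0, cyl$radius, length.out = 120L)
  e1 <- c(cyl$axis[2], -cyl$axis[1], 0); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(cyl$axis[2] * e1[3] - cyl$axis[3] * e1[2],
          cyl$axis[3] * e1[1] - cyl$axis[1] * e1[3],
          cyl$axis[1] * e1[2] - cyl$axis[2] * e1[1])
  wall <- purrr::map_dfr(hs, function(h) {
    tibble::tibble(
      x = cyl$base_point[1] + h * cyl$axis[1] +
        cyl$radius * (cos(theta) * e1[1] + sin(theta) * e2[1]),
      y = cyl$base_point[2] + h * cyl$axis[2] +
        cyl$radius * (cos(theta) * e1[2] + sin(theta) * e2[2]),
      z = cyl$base_point[3] + h * cyl$axis[3] +
        cyl$radius * (cos(theta) * e1[3] + sin(theta) * e2[3])
    )
  })
  caps <- purrr::map_dfr(c(0, cyl$height), function(h) {
    purrr::map_dfr(rs, function(r) {
      tibble::tibble(
        x = cyl$base_point[1] + h * cyl$axis[1] +
          r * (cos(theta) * e1[1] + sin(theta) * e2[1]),
        y = cyl$base_point[2] + h * cyl$axis[2] +
          r * (cos(theta) * e1[2] + sin(theta) * e2[2]),
        z = cyl$base_point[3] + h * cyl$axis[3] +
          r * (cos(theta) * e1[3] + sin(theta) * e2[3])
      )
    })
  })
  surfm <- rbind(as.matrix(wall), as.matrix(caps))
  inside <- label_damaged(pts, cyl)
  tt <- rowSums(surfm^2)
  oracle <- vapply(seq_len(nrow(pts)), function(i) {
    if (inside[i]) return(0)
    sqrt(min(tt - 2 * drop(surfm %*% pts[i, ]) + sum(pts[i, ]^2)))
  }, numeric(1))
  expect_true(all(abs(d - oracle) < 0.1))
  expect_true(all(d >= 0))
})
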