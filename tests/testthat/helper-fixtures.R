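# shared small fixtures, built once per test run and cached

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# a canonical right-breast cloud with a flat chest wall at y = 0
toy_pcl <- function(n_surface = 120, n_interior = 180, laterality = "R",
                    patient = "P1", seed = 101) {
  case <- tibble::tibble(
    patient_id = patient, laterality = laterality, volume = 8e5,
    patient_seed = seed
  )
  generate_breast_pcl(case, n_surface, n_interior)
}

# small full-factorial dataset: 2 patients x 4 densities x 4 quadrants x 3 sizes
tiny_dataset <- function() {
  fixture("tiny_dataset", function() {
    cases <- enumerate_cases(2, seed = 5)
    generate_dataset(cases, n_surface = 80, n_interior = 120, seed = 5)
  })
}

# a single generated case bundle
tiny_bundle <- function() tiny_dataset()[[1]]

# dataset whose displacements follow the heuristic's own generative rule:
# constant per-quadrant vectors, multiplied by b*s inside the tumor quadrant
rule_dataset <- function(cases, n_surface = 60, n_interior = 80, seed = 9) {
  v_map <- list(UOQ = c(0.4, -0.8, -0.3), UIQ = c(-0.3, -0.7, -0.2),
                LOQ = c(0.5, -0.6, 0.4), LIQ = c(-0.2, -0.9, 0.3))
  b_map <- c(A = 4, B = 3, C = 2, D = 1)
  s_map <- c(L = 3, M = 2, S = 1)
  cases$patient_seed <- derive_seed(seed, paste0("patient:", cases$patient_id))
  purrr::map(seq_len(nrow(cases)), function(i) {
    case <- cases[i, ]
    pre <- generate_breast_pcl(case, n_surface, n_interior)
    center <- place_tumor(pre, case$quadrant, case$volume_fraction, case$seed)
    cyl <- suppressWarnings(
      make_excision_cylinder(pre, center, case$volume_fraction)
    )
    planes <- build_quadrant_planes(pre)
    quad <- assign_quadrant(pre, planes)
    disp <- t(vapply(quad, function(q) v_map[[q]], numeric(3)))
    mult <- ifelse(quad == case$quadrant,
                   b_map[[case$density]] * s_map[[case$tumor_size]], 1)
    disp <- disp * mult
    post <- set_coords(pre, pcl_matrix(pre) + disp)
    list(case = case, pre = pre, post = post, cylinder = cyl,
         displacement = tibble::tibble(dx = disp[, 1], dy = disp[, 2],
                                       dz = disp[, 3]),
         damaged = label_damaged(pre, cyl))
  })
}

random_cloud <- function(n, seed = 1) {
  set.seed(seed)
  matrix(stats::rnorm(3 * n, sd = 30), ncol = 3)
}
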