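#' Patient roster for dataset construction
#'
#' Six reference breasts with a uniform spread of size (2 small, 2 medium,
#' 2 large) and laterality (3 left, 3 right), together with their target
#' volumes in mm^3. These are the generator's default study subjects; for
#' `n_patients != 6` the pattern recycles with fresh patient ids.
#'
#' @param n_patients Number of patients (>= 1).
#' @return Tibble with columns `patient_id`, `size_class`
#'   (`Small/Medium/Large`), `laterality` (`R/L`) and `volume` (mm^3).
#' @export
patient_roster <- function(n_patients = 6L) {
  stopifnot(n_patients >= 1)
  base <- tibble::tibble(
    size_class = c("Small", "Medium", "Large", "Medium", "Large", "Small"),
    laterality = c("L", "L", "R", "L", "R", "R"),
    volume = c(495948, 802661, 1314990, 1052500, 1202500, 559677)
  )
  idx <- ((seq_len(n_patients) - 1L) %% 6L) + 1L
  out <- base[idx, ]
  out$patient_id <- sprintf("P%d", seq_len(n_patients))
  out[, c("patient_id", "size_class", "laterality", "volume")]
}

#' Enumerate the factorial case design
#'
#' Dataset instances combine each patient with every breast density
#' (A, B, C, D), tumor quadrant (UOQ, UIQ, LOQ, LIQ) and tumor size class
#' (S, M, L, i.e. excision volume fractions 0.05, 0.075, 0.10), in that
#' nesting order: 6 patients give 24 density-cases, 96 quadrant-cases and
#' 288 cases in total. Order is deterministic and each case carries a
#' derived seed.
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Root seed from which per-case seeds are derived.
#' @return A tibble of case specifications with columns `case_id`,
#'   `patient_id`, `size_class`, `laterality`, `volume`, `density`,
#'   `quadrant`, `tumor_size`, `volume_fraction`, `seed`.
#' @export
#' @examples
#' nrow(enumerate_cases(6))  # 288
enumerate_cases <- function(n_patients = 6L, seed = 1L) {
  roster <- patient_roster(n_patients)
  grid <- tidyr::expand_grid(
    patient_id = roster$patient_id,
    density = c("A", "B", "C", "D"),
    quadrant = c("UOQ", "UIQ", "LOQ", "LIQ"),
    tumor_size = c("S", "M", "L")
  )
  out <- dplyr::left_join(grid, roster, by = "patient_id")
  out$volume_fraction <- c(S = 0.05, M = 0.075, L = 0.10)[out$tumor_size]
  out$case_id <- sprintf("%s_%s_%s_%s", out$patient_id, out$density,
                         out$quadrant, out$tumor_size)
  out$seed <- derive_seed(seed, out$case_id)
  out[, c("case_id", "patient_id", "size_class", "laterality", "volume",
          "density", "quadrant", "tumor_size", "volume_fraction", "seed")]
}

#' Derive a reproducible sub-seed from a root seed and a label
#'
#' A small deterministic string hash (polynomial rolling hash mod a prime
#' below 2^31) keeps all derived seeds valid R integers.
#'
#' @param seed Root integer seed.
#' @param label Character vector of labels.
#' @return Integer vector of derived seeds, one per label.
#' @export
derive_seed <- function(seed, label) {
  mod <- 2147483629
  vapply(label, function(lb) {
    h <- as.double(seed %% mod)
    for (ch in utf8ToInt(lb)) h <- (h * 131 + ch) %% mod
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}
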