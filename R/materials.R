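#' Density-weighted tissue material properties
#'
#' Breast density categories (BI-RADS A-D) correspond to increasing
#' fibroglandular-to-fat ratios: A 10/90, B 35/65, C 60/40, D 85/15. Each
#' category's effective Mooney-Rivlin parameter `c1` and material density
#' `rho0` are the fibroglandular-fraction-weighted averages of the two
#' tissue reference values (fibroglandular: c1 = 120 Pa, rho0 = 1020
#' kg m^-3; fat: c1 = 80 Pa, rho0 = 910 kg m^-3); `c2` is 0 for both
#' tissues and hence for every category. These properties are carried as
#' case metadata (the regression itself uses the density category).
#'
#' @param density Character vector of categories in `c("A","B","C","D")`.
#' @return A tibble with columns `density`, `fibro_fraction`, `c1` (Pa),
#'   `c2` (Pa), `rho0` (kg m^-3), one row per input element.
#' @export
#' @examples
#' weighted_material_properties(c("A", "D"))
weighted_material_properties <- function(density = c("A", "B", "C", "D")) {
  frac <- c(A = 0.10, B = 0.35, C = 0.60, D = 0.85)
  if (!all(density %in% names(frac))) {
    stop("unknown density category; expected A, B, C or D", call. = FALSE)
  }
  w <- unname(frac[density])
  tibble::tibble(
    density = density,
    fibro_fraction = w,
    c1 = w * 120 + (1 - w) * 80,
    c2 = 0,
    rho0 = w * 1020 + (1 - w) * 910
  )
}
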