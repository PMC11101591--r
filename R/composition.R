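# Bone-matrix composition at the pixel scale. Each bone pixel is a mixture
# of organic matter (constant fraction phi_o), mineral (phi_m) and water
# (phi_w) with phi_m + phi_o + phi_w = 1. The mineral content is tracked by
# the ash fraction alpha = mineral mass / dry mass, from which phi_m, the
# matrix density and the calcium content follow algebraically.

#' Material constants of the bone matrix
#'
#' Mass densities of mineral, organic matter and water, the constant
#' organic area fraction, and the hydroxyapatite calcium-to-mineral mass
#' ratio (10 Ca per Ca10(PO4)6(OH)2 unit, ~0.3989).
#'
#' @param rho_m,rho_o,rho_w Mass densities, g/cm^3.
#' @param phi_o Organic area fraction, identical for all bone pixels and
#'   constant in time.
#' @param ca_per_mineral Mass ratio m_Ca / m_mineral.
#' @return A named list of class `material_constants`.
#' @export
material_constants <- function(rho_m = 3.2, rho_o = 1.1, rho_w = 1.0,
                               phi_o = 1 / 3, ca_per_mineral = 0.3989) {
  stopifnot(rho_m > 0, rho_o > 0, rho_w > 0,
            phi_o > 0, phi_o < 1, ca_per_mineral > 0)
  structure(list(rho_m = rho_m, rho_o = rho_o, rho_w = rho_w,
                 phi_o = phi_o, ca_per_mineral = ca_per_mineral),
            class = "material_constants")
}

#' Calcium content from the ash fraction
#'
#' Ca wt% = 100 * 0.3989 * alpha, the hydroxyapatite stoichiometric ratio
#' applied to the ash fraction. Reported on the 0-100 scale used by qBEI.
#'
#' @param alpha Ash fraction(s) in \[0, 1\].
#' @param constants A [material_constants] list.
#' @return Calcium content in wt% (same length as `alpha`).
#' @export
ca_from_ash <- function(alpha, constants = material_constants()) {
  if (any(alpha < 0 | alpha > 1, na.rm = TRUE))
    stop("ash fraction must lie in [0, 1]")
  100 * constants$ca_per_mineral * alpha
}

#' Ash fraction from calcium content
#'
#' Inverse of [ca_from_ash()].
#'
#' @param ca_wt_pct Calcium content, wt%.
#' @inheritParams ca_from_ash
#' @return Ash fraction(s).
#' @export
ash_from_ca <- function(ca_wt_pct, constants = material_constants()) {
  ca_wt_pct / (100 * constants$ca_per_mineral)
}

#' Mineral area fraction from the ash fraction
#'
#' phi_m = alpha * rho_o * phi_o / (rho_m * (1 - alpha)). The induced water
#' fraction phi_w = 1 - phi_o - phi_m must remain non-negative; a violation
#' signals an inconsistent mineralisation-law calibration.
#'
#' @inheritParams ca_from_ash
#' @return Mineral area fraction(s).
#' @export
mineral_fraction_from_ash <- function(alpha, constants = material_constants()) {
  if (any(alpha < 0 | alpha >= 1, na.rm = TRUE))
    stop("ash fraction must lie in [0, 1)")
  phi_m <- alpha * constants$rho_o * constants$phi_o /
    (constants$rho_m * (1 - alpha))
  phi_w <- 1 - constants$phi_o - phi_m
  if (any(phi_w < -1e-12, na.rm = TRUE))
    stop("ash fraction too large: induced water fraction would be negative")
  phi_m
}

#' Ash fraction from the mineral area fraction
#'
#' alpha = rho_m phi_m / (rho_m phi_m + rho_o phi_o); the exact algebraic
#' inverse of [mineral_fraction_from_ash()].
#'
#' @param phi_m Mineral area fraction(s) in \[0, 1 - phi_o\].
#' @inheritParams ca_from_ash
#' @return Ash fraction(s).
#' @export
ash_from_mineral_fraction <- function(phi_m, constants = material_constants()) {
  if (any(phi_m < 0 | phi_m > 1 - constants$phi_o + 1e-12, na.rm = TRUE))
    stop("mineral fraction must lie in [0, 1 - phi_o]")
  constants$rho_m * phi_m /
    (constants$rho_m * phi_m + constants$rho_o * constants$phi_o)
}

#' Composition of freshly deposited osteoid
#'
#' New bone is completely unmineralised: one third organic matter, no
#' mineral, two thirds water.
#'
#' @inheritParams ca_from_ash
#' @return Named vector `c(phi_o, phi_m, phi_w)`.
#' @export
init_new_bone <- function(constants = material_constants()) {
  c(phi_o = constants$phi_o, phi_m = 0, phi_w = 1 - constants$phi_o)
}

#' Mass density of a bone-matrix point
#'
#' rho = rho_m phi_m + rho_o phi_o + rho_w phi_w for a composition triple
#' satisfying phi_m + phi_o + phi_w = 1.
#'
#' @param phi_m,phi_o,phi_w Area fractions (vectors recycle).
#' @inheritParams ca_from_ash
#' @return Density in g/cm^3.
#' @export
point_density <- function(phi_m, phi_o, phi_w,
                          constants = material_constants()) {
  if (any(abs(phi_m + phi_o + phi_w - 1) > 1e-9, na.rm = TRUE))
    stop("composition fractions must sum to 1")
  constants$rho_m * phi_m + constants$rho_o * phi_o + constants$rho_w * phi_w
}

#' Matrix density directly from the ash fraction
#'
#' Convenience composition of [mineral_fraction_from_ash()] and
#' [point_density()] with the constant organic fraction.
#'
#' @inheritParams ca_from_ash
#' @return Density in g/cm^3 (vectorised; `NA` passes through).
#' @export
density_from_ash <- function(alpha, constants = material_constants()) {
  phi_m <- alpha * constants$rho_o * constants$phi_o /
    (constants$rho_m * (1 - alpha))
  phi_w <- 1 - constants$phi_o - phi_m
  constants$rho_m * phi_m + constants$rho_o * constants$phi_o +
    constants$rho_w * phi_w
}

#' Apparent mass density of the bone matrix
#'
#' rho_app = (1 / Nb_RVE) * sum of matrix density over bone pixels, i.e.
#' the bone area fraction times the mean bone-pixel density. Marrow carries
#' no composition and contributes zero.
#'
#' @param field Matrix of per-pixel ash fractions (`NA` on marrow), same
#'   dimensions as the grid.
#' @param grid A [label_grid].
#' @inheritParams ca_from_ash
#' @return Apparent density, g/cm^3 (0 for an all-marrow grid).
#' @export
apparent_density <- function(field, grid, constants = material_constants()) {
  stopifnot(inherits(grid, "label_grid"))
  bone <- grid$labels != 0
  if (!any(bone)) return(0)
  a <- field[bone]
  if (anyNA(a)) stop("ash fraction undefined on some bone pixels")
  sum(density_from_ash(a, constants)) / grid$Nb_RVE
}
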