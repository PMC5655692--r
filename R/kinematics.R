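#' Green strain from a principal stretch ratio
#'
#' The finite-deformation (Green-Lagrange) strain in a principal direction,
#' \eqn{E = (\lambda^2 - 1)/2}.
#'
#' @param lam Stretch ratio(s), must be positive.
#' @return Green strain(s), same length as `lam`.
#' @seealso [stretch_from_strain()] for the inverse map.
#' @export
#' @examples
#' green_strain(1.3)   # 0.345
green_strain <- function(lam) {
  if (!is.numeric(lam) || any(!is.finite(lam)) || any(lam <= 0)) {
    stop("stretch ratios must be positive finite numbers", call. = FALSE)
  }
  (lam^2 - 1) / 2
}

#' Stretch ratio from a Green strain
#'
#' Inverse of [green_strain()]: \eqn{\lambda = \sqrt{2E + 1}}.
#'
#' @param E Green strain(s); must satisfy `2*E + 1 > 0`.
#' @return Stretch ratio(s).
#' @export
stretch_from_strain <- function(E) {
  if (!is.numeric(E) || any(!is.finite(E)) || any(2 * E + 1 <= 0)) {
    stop("Green strain must satisfy 2E + 1 > 0", call. = FALSE)
  }
  sqrt(2 * E + 1)
}

#' Radial stretch under incompressibility
#'
#' For an incompressible wall, \eqn{\lambda_r = 1/(\lambda_\theta \lambda_z)}.
#'
#' @param lam_theta Circumferential stretch ratio(s).
#' @param lam_z Axial stretch ratio(s).
#' @return Radial stretch ratio(s).
#' @export
radial_stretch <- function(lam_theta, lam_z) {
  if (any(lam_theta <= 0) || any(lam_z <= 0)) {
    stop("stretch ratios must be positive", call. = FALSE)
  }
  1 / (lam_theta * lam_z)
}

#' Triaxial kinematic state
#'
#' Bundles the three principal stretches and their Green strains. By default
#' the radial stretch is derived from incompressibility
#' (\eqn{\lambda_\theta \lambda_z \lambda_r = 1}); an explicit `lam_r` may be
#' supplied for off-manifold states, which is needed when differentiating the
#' strain-energy functions with the three stretches treated as independent
#' arguments.
#'
#' All fields are vectorized: supplying vectors of equal length (or length 1,
#' recycled) yields a state describing several material points at once.
#'
#' @param lam_theta Circumferential stretch ratio(s).
#' @param lam_z Axial stretch ratio(s).
#' @param lam_r Radial stretch ratio(s); default `NULL` derives it from
#'   incompressibility.
#' @return An object of class `kinematic_state`: a list with fields
#'   `lam_theta`, `lam_z`, `lam_r`, `E_theta`, `E_z`, `E_r`.
#' @export
#' @examples
#' st <- kinematic_state(1.4, 1.3)
#' st$lam_r * st$lam_theta * st$lam_z  # 1
kinematic_state <- function(lam_theta, lam_z, lam_r = NULL) {
  if (is.null(lam_r)) lam_r <- radial_stretch(lam_theta, lam_z)
  if (any(lam_theta <= 0) || any(lam_z <= 0) || any(lam_r <= 0)) {
    stop("stretch ratios must be positive", call. = FALSE)
  }
  n <- max(length(lam_theta), length(lam_z), length(lam_r))
  lam_theta <- rep_len(lam_theta, n)
  lam_z <- rep_len(lam_z, n)
  lam_r <- rep_len(lam_r, n)
  structure(
    list(
      lam_theta = lam_theta, lam_z = lam_z, lam_r = lam_r,
      E_theta = green_strain(lam_theta),
      E_z = green_strain(lam_z),
      E_r = green_strain(lam_r)
    ),
    class = "kinematic_state"
  )
}

#' Loaded inner radius from wall-volume conservation
#'
#' The deformed inner radius of an incompressible wall,
#' \eqn{r_i = \sqrt{r_o^2 - A_0/(\pi \lambda_z)}}, where \eqn{A_0} is the
#' no-load wall cross-sectional area.
#'
#' @param r_o Loaded outer radius (mm).
#' @param A0 No-load wall cross-sectional area (mm^2).
#' @param lam_z Axial stretch ratio.
#' @return Loaded inner radius (mm).
#' @export
loaded_inner_radius <- function(r_o, A0, lam_z) {
  if (any(A0 < 0) || any(lam_z <= 0) || any(r_o <= 0)) {
    stop("need r_o > 0, A0 >= 0, lam_z > 0", call. = FALSE)
  }
  arg <- r_o^2 - A0 / (pi * lam_z)
  if (any(arg <= 0)) {
    stop("infeasible geometry: r_o^2 <= A0/(pi*lam_z); measurement inconsistent",
         call. = FALSE)
  }
  sqrt(arg)
}

#' Loaded wall geometry
#'
#' Derives the loaded inner radius and wall thickness from the loaded outer
#' radius, the no-load wall area and the axial stretch, carrying along the
#' zero-stress mid-wall circumferential length `l0`.
#'
#' @param r_o Loaded outer radius (mm).
#' @param A0 No-load wall cross-sectional area (mm^2).
#' @param l0 Zero-stress mid-wall circumferential length (mm).
#' @param lam_z Axial stretch ratio.
#' @return Object of class `loaded_geometry` with fields `r_o`, `r_i`, `h`,
#'   `A0`, `l0`.
#' @export
loaded_geometry <- function(r_o, A0, l0, lam_z) {
  if (any(l0 <= 0)) stop("l0 must be positive", call. = FALSE)
  r_i <- loaded_inner_radius(r_o, A0, lam_z)
  structure(
    list(r_o = r_o, r_i = r_i, h = r_o - r_i, A0 = A0, l0 = l0),
    class = "loaded_geometry"
  )
}

# 1 mmHg in kPa
.MMHG_KPA <- 0.1333224

#' Convert pressure between mmHg and kPa
#'
#' Transmural pressures are reported in mmHg; all internal stress computation
#' uses kPa (with lengths in mm and forces in mN, so that kPa * mm^2 = mN).
#'
#' @param p Pressure value(s).
#' @return Converted pressure value(s).
#' @export
mmHg_to_kPa <- function(p) p * .MMHG_KPA

#' @rdname mmHg_to_kPa
#' @export
kPa_to_mmHg <- function(p) p / .MMHG_KPA

#' Mid-wall circumferential stretch of a loaded vessel
#'
#' The homogenized (mean-wall) circumferential stretch, evaluated at the
#' mid-wall radius: \eqn{\lambda_\theta = \pi (r_i + r_o) / l_0}.
#'
#' @param geom A `loaded_geometry`.
#' @return Circumferential stretch ratio.
#' @export
midwall_lam_theta <- function(geom) {
  pi * (geom$r_i + geom$r_o) / geom$l0
}
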