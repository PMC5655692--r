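#' Passive (Fung exponential) material constants
#'
#' Constants of the three-dimensional Fung pseudo-strain-energy function
#' \eqn{W_{passive} = (C_1/2)(e^Q - 1)} with quadratic form
#' \eqn{Q = a_1 E_\theta^2 + a_2 E_z^2 + a_3 E_r^2 + 2 a_4 E_\theta E_z +
#' 2 a_5 E_z E_r + 2 a_6 E_r E_\theta}.
#'
#' `C1` carries units of stress (kPa); `a1`--`a6` are dimensionless.
#'
#' @param C1 Stress-like scale (kPa), positive.
#' @param a1,a2,a3,a4,a5,a6 Quadratic-form coefficients, positive.
#' @param subject_id,layer Optional provenance labels.
#' @return Object of class `passive_constants`.
#' @export
passive_constants <- function(C1, a1, a2, a3, a4, a5, a6,
                              subject_id = NULL, layer = NULL) {
  vals <- c(C1 = C1, a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5, a6 = a6)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("passive constants C1, a1..a6 must all be positive", call. = FALSE)
  }
  structure(
    list(C1 = C1, a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5, a6 = a6,
         subject_id = subject_id, layer = layer),
    class = "passive_constants"
  )
}

#' Active (smooth-muscle) material constants
#'
#' Constants of the error-function active strain-energy
#' \eqn{W_{active} = C_2 [\mathrm{Erf}(Q') - 1]} with
#' \eqn{Q' = \lambda_\theta/b_1 + \lambda_z/b_2 + \lambda_r/b_3 - b'}.
#' The offsets that would enter through the numerator constants of \eqn{b'}
#' are unidentifiable individually and only their combination `b_prime` is
#' stored.
#'
#' @param C2 Stress-like scale (kPa), positive.
#' @param b1,b2,b3 Stretch-scale constants (dimensionless), positive. `b3`
#'   may be `Inf` to represent the planar (2D) active law with no radial
#'   term; see [active_constants_2d()].
#' @param b_prime Offset of the activation argument, positive.
#' @param subject_id,layer Optional provenance labels.
#' @return Object of class `active_constants`.
#' @export
active_constants <- function(C2, b1, b2, b3, b_prime,
                             subject_id = NULL, layer = NULL) {
  vals <- c(C2 = C2, b1 = b1, b2 = b2, b3 = b3, b_prime = b_prime)
  if (any(is.na(vals)) || any(vals <= 0)) {
    stop("active constants C2, b1..b3, b_prime must all be positive",
         call. = FALSE)
  }
  structure(
    list(C2 = C2, b1 = b1, b2 = b2, b3 = b3, b_prime = b_prime,
         subject_id = subject_id, layer = layer),
    class = "active_constants"
  )
}

#' Planar active constants (no radial term)
#'
#' Convenience constructor for the two-dimensional active law used for model
#' comparison: the radial stretch does not enter the activation argument
#' (`b3 = Inf`) and the radial active stress is identically zero.
#'
#' @inheritParams active_constants
#' @export
active_constants_2d <- function(C2, b1, b2, b_prime,
                                subject_id = NULL, layer = NULL) {
  active_constants(C2, b1, b2, Inf, b_prime, subject_id, layer)
}

# quadratic form Q of the Fung exponent, vectorized over the state
fung_Q <- function(state, pc) {
  Et <- state$E_theta; Ez <- state$E_z; Er <- state$E_r
  pc$a1 * Et^2 + pc$a2 * Ez^2 + pc$a3 * Er^2 +
    2 * pc$a4 * Et * Ez + 2 * pc$a5 * Ez * Er + 2 * pc$a6 * Er * Et
}

# activation argument Q' of the error-function law
active_Qp <- function(state, ac) {
  state$lam_theta / ac$b1 + state$lam_z / ac$b2 + state$lam_r / ac$b3 -
    ac$b_prime
}

# guard against numerical blow-up of exp(Q); keeps optimizers on a finite
# penalized landscape instead of propagating Inf/NaN
.Q_MAX <- 700

#' Passive strain-energy density
#'
#' \eqn{W_{passive} = (C_1/2)(e^Q - 1)} in kPa.
#'
#' @param state A [kinematic_state()].
#' @param pc [passive_constants()].
#' @return Energy density (kPa), vectorized over the state.
#' @export
passive_energy <- function(state, pc) {
  Q <- fung_Q(state, pc)
  if (any(Q > .Q_MAX)) {
    stop("diverged energy: Fung exponent Q exceeds overflow guard",
         call. = FALSE)
  }
  0.5 * pc$C1 * (exp(Q) - 1)
}

#' Active strain-energy density
#'
#' \eqn{W_{active} = C_2[\mathrm{Erf}(Q') - 1]} in kPa; always in
#' \eqn{(-2 C_2, 0]}, approaching 0 as the activation argument grows.
#'
#' @param state A [kinematic_state()].
#' @param ac [active_constants()].
#' @return Energy density (kPa), vectorized over the state.
#' @export
active_energy <- function(state, ac) {
  ac$C2 * (pracma::erf(active_Qp(state, ac)) - 1)
}

# partial derivatives of W_passive w.r.t. the three Green strains
dW_passive_dE <- function(state, pc) {
  Q <- fung_Q(state, pc)
  if (any(Q > .Q_MAX)) {
    stop("diverged energy: Fung exponent Q exceeds overflow guard",
         call. = FALSE)
  }
  eQ <- pc$C1 * exp(Q)
  list(
    theta = eQ * (pc$a1 * state$E_theta + pc$a4 * state$E_z + pc$a6 * state$E_r),
    z     = eQ * (pc$a2 * state$E_z + pc$a4 * state$E_theta + pc$a5 * state$E_r),
    r     = eQ * (pc$a3 * state$E_r + pc$a5 * state$E_z + pc$a6 * state$E_theta)
  )
}

stress_triple <- function(T_theta, T_z, T_r) {
  structure(list(T_theta = T_theta, T_z = T_z, T_r = T_r),
            class = "stress_triple")
}

#' Passive first Piola-Kirchhoff stresses
#'
#' Analytic derivatives of the passive energy with the three stretches
#' treated as independent arguments:
#' \eqn{T_i = \lambda_i \, \partial W_{passive} / \partial E_i}.
#'
#' @param state A [kinematic_state()].
#' @param pc [passive_constants()].
#' @return A `stress_triple` (kPa) with fields `T_theta`, `T_z`, `T_r`.
#' @export
first_pk_passive <- function(state, pc) {
  dW <- dW_passive_dE(state, pc)
  stress_triple(
    state$lam_theta * dW$theta,
    state$lam_z * dW$z,
    state$lam_r * dW$r
  )
}

#' Active first Piola-Kirchhoff stresses
#'
#' \eqn{T_i = \partial W_{active}/\partial \lambda_i =
#' (2 C_2 / (b_i \sqrt{\pi})) \exp(-Q'^2)}. Each component is positive and
#' attains its maximum \eqn{2 C_2/(b_i\sqrt{\pi})} exactly where the
#' activation argument crosses zero. For planar constants (`b3 = Inf`) the
#' radial component is identically zero.
#'
#' @param state A [kinematic_state()].
#' @param ac [active_constants()].
#' @return A `stress_triple` (kPa).
#' @export
first_pk_active <- function(state, ac) {
  g <- (2 * ac$C2 / sqrt(pi)) * exp(-active_Qp(state, ac)^2)
  stress_triple(g / ac$b1, g / ac$b2, g / ac$b3)
}

#' Total (passive + active) first Piola-Kirchhoff stresses
#'
#' @param state A [kinematic_state()].
#' @param pc [passive_constants()].
#' @param ac [active_constants()].
#' @return A `stress_triple` (kPa).
#' @export
first_pk_total <- function(state, pc, ac) {
  Tp <- first_pk_passive(state, pc)
  Ta <- first_pk_active(state, ac)
  stress_triple(Tp$T_theta + Ta$T_theta, Tp$T_z + Ta$T_z, Tp$T_r + Ta$T_r)
}

#' Cauchy stresses from first Piola-Kirchhoff stresses
#'
#' Incompressible conversion \eqn{\sigma_i = \lambda_i T_i} (no summation).
#'
#' @param state A [kinematic_state()].
#' @param T A `stress_triple` of 1st PK stresses.
#' @return A list with `sigma_theta`, `sigma_z`, `sigma_r` (kPa).
#' @export
cauchy_normal <- function(state, T) {
  list(
    sigma_theta = state$lam_theta * T$T_theta,
    sigma_z = state$lam_z * T$T_z,
    sigma_r = state$lam_r * T$T_r
  )
}

#' Convexity / hyperelasticity diagnostics of the Fung quadratic form
#'
#' Two modes are provided because the published constraint is ambiguous.
#' `strict` checks true positive-definiteness of the symmetric coefficient
#' matrix \eqn{[[a_1,a_4,a_6],[a_4,a_2,a_5],[a_6,a_5,a_3]]} through its three
#' leading principal minors. `printed` evaluates the published inequality,
#' \eqn{a_4^2+a_5^2+a_6^2-a_1a_2-a_2a_3-a_1a_3 > 0}, which is the reverse of
#' the usual positive-definiteness surrogate; published constant sets satisfy
#' one, the other, neither or both, so neither mode is silently enforced on
#' fixtures.
#'
#' @param pc [passive_constants()].
#' @param mode `"strict"` (default) or `"printed"`.
#' @return A list with `pass` (logical), `mode`, `minors` (the three leading
#'   principal minors) and `criterion` (the printed-inequality value).
#' @export
convexity_check <- function(pc, mode = c("strict", "printed")) {
  mode <- match.arg(mode)
  m1 <- pc$a1
  m2 <- pc$a1 * pc$a2 - pc$a4^2
  A <- matrix(c(pc$a1, pc$a4, pc$a6,
                pc$a4, pc$a2, pc$a5,
                pc$a6, pc$a5, pc$a3), 3, 3)
  m3 <- det(A)
  crit <- pc$a4^2 + pc$a5^2 + pc$a6^2 -
    pc$a1 * pc$a2 - pc$a2 * pc$a3 - pc$a1 * pc$a3
  pass <- if (mode == "strict") (m1 > 0 && m2 > 0 && m3 > 0) else (crit > 0)
  list(pass = pass, mode = mode, minors = c(m1, m2, m3), criterion = crit)
}

#' Theoretical mean-wall stress curves over a circumferential-stretch sweep
#'
#' Evaluates passive, active and total 1st PK stress components over a grid
#' of circumferential stretches at fixed axial stretch, with the radial
#' stretch from incompressibility. This is the theoretical counterpart of
#' the stress-stretch plots used to present fitted constants.
#'
#' @param pc [passive_constants()].
#' @param ac [active_constants()] or `NULL` for passive-only curves.
#' @param lam_theta Vector of circumferential stretches.
#' @param lam_z Axial stretch (scalar).
#' @return A data.frame with columns `lam_theta`, `component`
#'   (`theta`/`z`/`r`), `passive`, `active`, `total` (kPa).
#' @export
stress_curves <- function(pc, ac = NULL, lam_theta, lam_z = 1.3) {
  st <- kinematic_state(lam_theta, lam_z)
  Tp <- first_pk_passive(st, pc)
  if (is.null(ac)) {
    Ta <- stress_triple(0 * lam_theta, 0 * lam_theta, 0 * lam_theta)
  } else {
    Ta <- first_pk_active(st, ac)
  }
  data.frame(
    lam_theta = rep(lam_theta, 3),
    component = rep(c("theta", "z", "r"), each = length(lam_theta)),
    passive = c(Tp$T_theta, Tp$T_z, Tp$T_r),
    active = c(Ta$T_theta, Ta$T_z, Ta$T_r),
    total = c(Tp$T_theta + Ta$T_theta, Tp$T_z + Ta$T_z, Tp$T_r + Ta$T_r)
  )
}
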