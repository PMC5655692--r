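#' Inflation-extension protocol specification
#'
#' The default protocol mirrors the mechanical-test protocol the constants
#' were derived from: transmural pressures 20 to 200 mmHg in steps of
#' 20 mmHg, axial stretches 1.3 and 1.5, and both the passive (Ca2+-free)
#' and maximally activated (60 mM K+, `"total"`) states. Multiplicative
#' Gaussian noise with coefficient of variation `noise_cv` is applied to the
#' measured quantities (outer diameter and axial force), not to derived
#' stresses, mirroring the experimental error pathway.
#'
#' @param pressures Transmural pressures (mmHg), positive ascending.
#' @param lam_z Axial stretch ratios.
#' @param states Activation states, subset of `c("passive", "total")`.
#' @param noise_cv Relative s.d. of the multiplicative measurement noise.
#' @param seed Integer RNG seed; recorded in the generated dataset.
#' @return Object of class `protocol_spec`.
#' @export
protocol_spec <- function(pressures = seq(20, 200, by = 20),
                          lam_z = c(1.3, 1.5),
                          states = c("passive", "total"),
                          noise_cv = 0, seed = 1L) {
  if (any(diff(pressures) <= 0) || any(pressures <= 0)) {
    stop("pressures must be positive and ascending", call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  stopifnot(all(states %in% c("passive", "total")))
  structure(list(pressures = pressures, lam_z = lam_z, states = states,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "protocol_spec")
}

#' Ground truth for synthetic data generation
#'
#' Bundles the constitutive constants and reference geometry of a synthetic
#' vessel. Default geometry (`A0 = 1.6` mm^2, `l0 = 8.4` mm) makes the
#' mean-wall circumferential stretch span roughly 1.1--1.7 over
#' 20--200 mmHg at axial stretch 1.3 for published wall constants,
#' matching the stretch range over which those constants were presented.
#'
#' @param passive [passive_constants()].
#' @param active [active_constants()] (may be `NULL` if only passive
#'   records will be generated).
#' @param A0 No-load wall cross-sectional area (mm^2).
#' @param l0 Zero-stress mid-wall circumferential length (mm).
#' @param r_o_noload No-load outer radius (mm), reporting only.
#' @param subject_id Label carried into generated records.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(passive, active = NULL, A0 = 1.6, l0 = 8.4,
                         r_o_noload = 1.5, subject_id = "synthetic") {
  stopifnot(inherits(passive, "passive_constants"),
            is.null(active) || inherits(active, "active_constants"),
            A0 > 0, l0 > 0)
  structure(list(passive = passive, active = active, A0 = A0, l0 = l0,
                 r_o_noload = r_o_noload, subject_id = subject_id),
            class = "ground_truth")
}

# loaded geometry as a function of the mean-wall circumferential stretch:
# with s = lam_theta * l0 / pi = r_i + r_o and wall-volume conservation
# r_o^2 - r_i^2 = A0/(pi lam_z) = c, we get closed forms
# r_i = (s^2 - c)/(2s), r_o = (s^2 + c)/(2s), h = c/s.
geometry_at_lam_theta <- function(lam_theta, A0, l0, lam_z) {
  s <- lam_theta * l0 / pi
  cc <- A0 / (pi * lam_z)
  if (any(s^2 <= cc)) {
    stop("infeasible geometry at requested circumferential stretch",
         call. = FALSE)
  }
  list(r_i = (s^2 - cc) / (2 * s), r_o = (s^2 + cc) / (2 * s), h = cc / s)
}

# theoretical mean-wall circumferential 1st PK stress at a protocol state
theory_T_theta <- function(lam_theta, lam_z, truth, state) {
  st <- kinematic_state(lam_theta, lam_z)
  Tt <- first_pk_passive(st, truth$passive)$T_theta
  if (state == "total") {
    if (is.null(truth$active)) {
      stop("ground truth has no active constants", call. = FALSE)
    }
    Tt <- Tt + first_pk_active(st, truth$active)$T_theta
  }
  Tt
}

#' Equilibrium circumferential stretch at a given pressure
#'
#' Root-finds the mean-wall circumferential stretch at which the theoretical
#' mean-wall circumferential stress balances the pressure-derived value
#' \eqn{P r_i / (\lambda_\theta h)}, inside the admissible bracket
#' (1.01, 2.5).
#'
#' @param truth [ground_truth()].
#' @param P_mmHg Transmural pressure (mmHg).
#' @param lam_z Axial stretch ratio.
#' @param state `"passive"` or `"total"`.
#' @return Scalar stretch ratio.
#' @export
equilibrium_lam_theta <- function(truth, P_mmHg, lam_z,
                                  state = c("passive", "total")) {
  state <- match.arg(state)
  P <- mmHg_to_kPa(P_mmHg)
  cc <- truth$A0 / (pi * lam_z)
  lo <- max(1.01, 1.0001 * pi * sqrt(cc) / truth$l0)
  g <- function(lt) {
    geo <- geometry_at_lam_theta(lt, truth$A0, truth$l0, lam_z)
    theory_T_theta(lt, lam_z, truth, state) - P * geo$r_i / (lt * geo$h)
  }
  glo <- g(lo); ghi <- g(2.5)
  if (!is.finite(glo) || !is.finite(ghi) || glo * ghi > 0) {
    stop(sprintf(
      "infeasible protocol: no equilibrium stretch in (%.3f, 2.5) at P=%g mmHg",
      lo, P_mmHg), call. = FALSE)
  }
  stats::uniroot(g, c(lo, 2.5), tol = 1e-12)$root
}

#' Forward-generate one inflation-extension record
#'
#' Inverts the stress-reduction formulas: solves for the loaded outer
#' diameter at which the theoretical circumferential stress balances the
#' pressure load, then sets the axial force so that the reduced axial stress
#' equals its theoretical value. By construction,
#' [reduce_record()] applied to the generated record returns the theoretical
#' circumferential and axial stresses exactly; the reduced radial stress is
#' the equilibrium (pressure-derived) value, which differs from the
#' constitutive radial stress by the homogenized model's intrinsic radial
#' residual (see the methods vignette).
#'
#' @inheritParams equilibrium_lam_theta
#' @return One-row data.frame in measurement-CSV layout.
#' @export
forward_record <- function(truth, P_mmHg, lam_z,
                           state = c("passive", "total")) {
  state <- match.arg(state)
  lt <- equilibrium_lam_theta(truth, P_mmHg, lam_z, state)
  geo <- geometry_at_lam_theta(lt, truth$A0, truth$l0, lam_z)
  st <- kinematic_state(lt, lam_z)
  Tz <- first_pk_passive(st, truth$passive)$T_z
  if (state == "total") Tz <- Tz + first_pk_active(st, truth$active)$T_z
  P <- mmHg_to_kPa(P_mmHg)
  area <- pi * (geo$r_o^2 - geo$r_i^2)
  F_mN <- area * (lam_z * Tz - P * geo$r_i^2 / (geo$h * (geo$r_o + geo$r_i)))
  data.frame(
    subject_id = truth$subject_id,
    layer = if (is.null(truth$passive$layer)) "wall" else truth$passive$layer,
    state = state, lam_z = lam_z, P_mmHg = P_mmHg,
    d_o_mm = 2 * geo$r_o, F_mN = F_mN
  )
}

#' Generate a synthetic inflation-extension dataset
#'
#' One record per (pressure, axial stretch, activation state) of the
#' protocol, via [forward_record()], with multiplicative Gaussian noise of
#' coefficient of variation `noise_cv` applied independently to the measured
#' outer diameter and axial force. Reproducible for a fixed protocol seed.
#'
#' @param truth [ground_truth()].
#' @param protocol [protocol_spec()].
#' @return data.frame in measurement-CSV layout, with attributes `seed` and
#'   `noise_cv`.
#' @export
generate_dataset <- function(truth, protocol = protocol_spec()) {
  stopifnot(inherits(protocol, "protocol_spec"))
  grid <- expand.grid(P_mmHg = protocol$pressures, lam_z = protocol$lam_z,
                      state = protocol$states, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    forward_record(truth, grid$P_mmHg[i], grid$lam_z[i], grid$state[i])
  })
  out <- do.call(rbind, rows)
  if (protocol$noise_cv > 0) {
    set.seed(protocol$seed)
    n <- nrow(out)
    out$d_o_mm <- out$d_o_mm * (1 + protocol$noise_cv * stats::rnorm(n))
    out$F_mN <- out$F_mN * (1 + protocol$noise_cv * stats::rnorm(n))
  }
  attr(out, "seed") <- protocol$seed
  attr(out, "noise_cv") <- protocol$noise_cv
  out
}

#' Model-consistent synthetic stress points
#'
#' Generates stress points directly from the constitutive law at the
#' equilibrium stretch of each protocol state: the circumferential stretch
#' solves the pressure balance, and all three stress components are the
#' theoretical (model) values there. Unlike the measurement route
#' ([generate_dataset()] then [reduce_dataset()]), whose radial component is
#' the pressure-derived equilibrium estimate, data from this route lie
#' exactly in the model family, which makes it the appropriate input for
#' parameter-recovery studies. Optional multiplicative Gaussian noise is
#' applied to the stress components.
#'
#' @inheritParams generate_dataset
#' @return data.frame with `state`, `lam_z`, `P_mmHg`, `lam_theta`,
#'   `T_theta`, `T_z`, `T_r`.
#' @export
generate_stress_points <- function(truth, protocol = protocol_spec()) {
  grid <- expand.grid(P_mmHg = protocol$pressures, lam_z = protocol$lam_z,
                      state = protocol$states, stringsAsFactors = FALSE)
  lt <- mapply(function(P, lz, stt) equilibrium_lam_theta(truth, P, lz, stt),
               grid$P_mmHg, grid$lam_z, grid$state)
  st <- kinematic_state(lt, grid$lam_z)
  Tp <- first_pk_passive(st, truth$passive)
  Tt <- Tp
  if (any(grid$state == "total")) {
    Ta <- first_pk_active(st, truth$active)
    tot <- grid$state == "total"
    Tt$T_theta[tot] <- Tp$T_theta[tot] + Ta$T_theta[tot]
    Tt$T_z[tot] <- Tp$T_z[tot] + Ta$T_z[tot]
    Tt$T_r[tot] <- Tp$T_r[tot] + Ta$T_r[tot]
  }
  out <- data.frame(state = grid$state, lam_z = grid$lam_z,
                    P_mmHg = grid$P_mmHg, lam_theta = lt,
                    T_theta = Tt$T_theta, T_z = Tt$T_z, T_r = Tt$T_r)
  if (protocol$noise_cv > 0) {
    set.seed(protocol$seed)
    n <- nrow(out)
    for (cn in c("T_theta", "T_z", "T_r")) {
      out[[cn]] <- out[[cn]] * (1 + protocol$noise_cv * stats::rnorm(n))
    }
  }
  attr(out, "seed") <- protocol$seed
  attr(out, "noise_cv") <- protocol$noise_cv
  out
}
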