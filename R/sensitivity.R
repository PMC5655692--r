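#' Sensitivity specification for the active stretch-scale constants
#'
#' Describes a one-at-a-time sweep of `b1`, `b2` or `b3` (multiplicative)
#' and the circumferential-stretch grid over which the active stress curves
#' are evaluated at fixed axial stretch.
#'
#' @param base [active_constants()].
#' @param parameter `"b1"`, `"b2"` or `"b3"`.
#' @param multipliers Positive multipliers applied to the parameter.
#' @param lam_theta Sweep grid, inside (1, 2).
#' @param lam_z Fixed axial stretch.
#' @return Object of class `sensitivity_spec`.
#' @export
sensitivity_spec <- function(base, parameter = c("b1", "b2", "b3"),
                             multipliers = c(0.5, 1, 2),
                             lam_theta = seq(1.05, 1.9, by = 0.01),
                             lam_z = 1.3) {
  parameter <- match.arg(parameter)
  if (any(multipliers <= 0)) stop("multipliers must be positive", call. = FALSE)
  if (any(lam_theta <= 1) || any(lam_theta >= 2)) {
    stop("sweep must lie inside (1, 2)", call. = FALSE)
  }
  stopifnot(inherits(base, "active_constants"))
  structure(list(base = base, parameter = parameter,
                 multipliers = multipliers, lam_theta = lam_theta,
                 lam_z = lam_z),
            class = "sensitivity_spec")
}

#' Active stress sensitivity curves
#'
#' For each multiplier of the swept constant, the three active 1st PK
#' stress components over the circumferential-stretch grid, with peak
#' summaries. In closed form the peak of component *i* is
#' \eqn{2 C_2/(b_i \sqrt{\pi})}, attained where the activation argument
#' crosses zero: rescaling `b3` changes the radial peak magnitude
#' (proportional to `1/b3`) but not the circumferential one, while
#' rescaling `b1` or `b2` only shifts the stretch at which the radial peak
#' occurs.
#'
#' @param spec [sensitivity_spec()].
#' @return List with `curves` (data.frame: `multiplier`, `lam_theta`,
#'   `T_theta`, `T_z`, `T_r`) and `peaks` (data.frame: `multiplier`,
#'   `component`, `peak_value`, `peak_lam_theta`, `q_crosses_zero`).
#' @export
sensitivity_curves <- function(spec) {
  stopifnot(inherits(spec, "sensitivity_spec"))
  curves <- NULL; peaks <- NULL
  for (m in spec$multipliers) {
    ac <- spec$base
    ac[[spec$parameter]] <- ac[[spec$parameter]] * m
    st <- kinematic_state(spec$lam_theta, spec$lam_z)
    Ta <- first_pk_active(st, ac)
    qp <- active_Qp(st, ac)
    curves <- rbind(curves, data.frame(
      multiplier = m, lam_theta = spec$lam_theta,
      T_theta = Ta$T_theta, T_z = Ta$T_z, T_r = Ta$T_r))
    for (comp in c("theta", "z", "r")) {
      v <- Ta[[paste0("T_", comp)]]
      i <- which.max(abs(v))
      peaks <- rbind(peaks, data.frame(
        multiplier = m, component = comp, peak_value = v[i],
        peak_lam_theta = spec$lam_theta[i],
        q_crosses_zero = min(qp) < 0 && max(qp) > 0))
    }
  }
  list(curves = curves, peaks = peaks)
}

#' Pointwise ordering of theoretical stress components
#'
#' Checks the reported ordering \eqn{T_\theta > T_z > |T_r|} of the
#' theoretical mean-wall 1st PK stresses over a circumferential-stretch
#' sweep, for the passive and (if active constants are given) total curves.
#'
#' @param pc [passive_constants()].
#' @param ac [active_constants()] or `NULL`.
#' @param lam_theta Sweep grid.
#' @param lam_z Axial stretch.
#' @return List of logicals `passive` and `total` (`NA` if no active
#'   constants), each `TRUE` when the ordering holds at every grid point.
#' @export
stress_ordering_holds <- function(pc, ac = NULL,
                                  lam_theta = seq(1.15, 1.6, by = 0.01),
                                  lam_z = 1.3) {
  st <- kinematic_state(lam_theta, lam_z)
  Tp <- first_pk_passive(st, pc)
  ordered <- function(Tt) {
    all(Tt$T_theta > Tt$T_z) && all(Tt$T_z > abs(Tt$T_r))
  }
  out <- list(passive = ordered(Tp), total = NA)
  if (!is.null(ac)) out$total <- ordered(first_pk_total(st, pc, ac))
  out
}
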