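#' Layer specification for the two-layer wall model
#'
#' A layer is defined by its own stress-free (cut-open) configuration:
#' inner and outer radii and the opening angle `Phi` of the missing wedge
#' (`Phi = 0` means no residual strain), plus its constitutive constants.
#' Only the intima-media (IM) layer may carry an active law.
#'
#' @param R_in,R_out Stress-free inner/outer radii (mm), `0 < R_in < R_out`.
#' @param opening_angle Opening angle Phi (radians), in `[0, pi)`.
#' @param passive [passive_constants()].
#' @param active [active_constants()] or `NULL` (adventitia).
#' @param name Layer label.
#' @return Object of class `layer_spec`.
#' @export
layer_spec <- function(R_in, R_out, opening_angle, passive, active = NULL,
                       name = "layer") {
  if (!(R_in > 0 && R_out > R_in)) {
    stop("need 0 < R_in < R_out", call. = FALSE)
  }
  if (opening_angle < 0 || opening_angle >= pi) {
    stop("opening angle must be in [0, pi)", call. = FALSE)
  }
  stopifnot(inherits(passive, "passive_constants"),
            is.null(active) || inherits(active, "active_constants"))
  structure(list(R_in = R_in, R_out = R_out,
                 opening_angle = opening_angle, k = pi / (pi - opening_angle),
                 passive = passive, active = active, name = name),
            class = "layer_spec")
}

#' Deformed radius map of an opened layer
#'
#' Incompressible radial map from the stress-free radius `R` to the loaded
#' radius, anchored at the layer's deformed inner radius:
#' \eqn{r = \sqrt{r_{in}^2 + (R^2 - R_{in}^2)/(k \lambda_z)}} with
#' \eqn{k = \pi/(\pi - \Phi)}.
#'
#' @param R Stress-free radius (>= `R_in`).
#' @param r_in_layer Deformed inner radius of the layer (mm).
#' @param lam_z Axial stretch.
#' @param k Opening factor \eqn{\pi/(\pi-\Phi)}.
#' @param R_in Stress-free inner radius of the layer.
#' @return Deformed radius (mm), vectorized over `R`.
#' @export
deformed_map <- function(R, r_in_layer, lam_z, k, R_in) {
  arg <- r_in_layer^2 + (R^2 - R_in^2) / (k * lam_z)
  if (any(arg <= 0)) {
    stop("infeasible deformation: negative squared radius", call. = FALSE)
  }
  sqrt(arg)
}

#' Local kinematic state across a residually strained layer
#'
#' Pointwise stretches of the opening-angle kinematics:
#' \eqn{\lambda_\theta = k r / R}, \eqn{\lambda_r = 1/(\lambda_\theta
#' \lambda_z)}.
#'
#' @param r Deformed radius.
#' @param R Stress-free radius.
#' @param k Opening factor.
#' @param lam_z Axial stretch.
#' @return A [kinematic_state()].
#' @export
local_state <- function(r, R, k, lam_z) {
  kinematic_state(k * r / R, lam_z)
}

#' Circumferential minus radial Cauchy stress at a wall point
#'
#' The Lagrange multiplier of the incompressible formulation cancels in the
#' difference, leaving
#' \eqn{\sigma_\theta - \sigma_r = \lambda_\theta^2 \partial W_p/\partial
#' E_\theta - \lambda_r^2 \partial W_p/\partial E_r} plus, when the layer is
#' activated, \eqn{\lambda_\theta \partial W_a/\partial\lambda_\theta -
#' \lambda_r \partial W_a/\partial\lambda_r}.
#'
#' @param state [kinematic_state()] (vectorized).
#' @param layer [layer_spec()].
#' @param activation `"passive"` or `"active"`.
#' @return Stress difference (kPa), vectorized.
#' @export
stress_difference <- function(state, layer,
                              activation = c("passive", "active")) {
  activation <- match.arg(activation)
  dW <- dW_passive_dE(state, layer$passive)
  out <- state$lam_theta^2 * dW$theta - state$lam_r^2 * dW$r
  if (activation == "active" && !is.null(layer$active)) {
    Ta <- first_pk_active(state, layer$active)
    out <- out + state$lam_theta * Ta$T_theta - state$lam_r * Ta$T_r
  }
  out
}

# assemble per-point fields of the deformed two-layer wall for a candidate
# deformed inner radius; returns grids needed by the equilibrium integral
wall_fields <- function(layers, r_i, lam_z, activation, n_grid) {
  stopifnot(length(layers) == 2)
  pieces <- list()
  r_anchor <- r_i
  for (j in 1:2) {
    ly <- layers[[j]]
    R <- seq(ly$R_in, ly$R_out, length.out = n_grid)
    r <- deformed_map(R, r_anchor, lam_z, ly$k, ly$R_in)
    st <- local_state(r, R, ly$k, lam_z)
    dif <- stress_difference(st, ly, activation)
    pieces[[j]] <- data.frame(
      r = r, layer = ly$name, sigma_diff = dif,
      lam_theta = st$lam_theta, lam_r = st$lam_r
    )
    r_anchor <- r[n_grid]   # deformed continuity at the interface
  }
  pieces
}

#' Solve the two-layer inflated wall
#'
#' Shooting on the deformed inner radius: for a candidate \eqn{r_i}, the
#' radial equilibrium \eqn{d\sigma_r/dr = (\sigma_\theta - \sigma_r)/r} is
#' integrated outward from \eqn{\sigma_r(r_i) = -P} across both layers
#' (deformed radii continuous at the interface; each layer keeps its own
#' stress-free reference), and \eqn{r_i} is root-found so that
#' \eqn{\sigma_r(r_o) = 0}. The radial stress is continuous by construction;
#' the circumferential stress jumps at the interface whenever the layers'
#' residual strains or constants differ.
#'
#' @param layers List of two [layer_spec()]s, inner (IM) first.
#' @param P_mmHg Transmural pressure (mmHg).
#' @param lam_z Axial stretch.
#' @param activation `"passive"` or `"active"` (activates layers that carry
#'   an active law).
#' @param n_grid Grid points per layer.
#' @param bc_tol Outer-boundary tolerance on \eqn{\sigma_r(r_o)} (kPa).
#' @return Object of class `transmural_profile`: a data.frame with columns
#'   `r`, `x_norm`, `layer`, `sigma_theta`, `sigma_r`, `lam_theta`, `lam_r`
#'   and attributes `r_i`, `r_o`, `r_interface`, `P_mmHg`, `lam_z`,
#'   `activation`, `interface_index` (last row of the inner layer).
#' @export
solve_wall <- function(layers, P_mmHg, lam_z = 1.3,
                       activation = c("passive", "active"),
                       n_grid = 200, bc_tol = 1e-6) {
  activation <- match.arg(activation)
  P <- mmHg_to_kPa(P_mmHg)

  outer_sigma_r <- function(r_i) {
    pieces <- wall_fields(layers, r_i, lam_z, activation, n_grid)
    s <- -P
    for (pc in pieces) {
      s <- s + utils::tail(pracma::cumtrapz(pc$r, pc$sigma_diff / pc$r), 1)
    }
    s
  }

  # bracket the shooting variable through the inner-wall stretch
  lam_grid <- seq(0.55, 2.4, length.out = 75)
  r_cand <- lam_grid * layers[[1]]$R_in / layers[[1]]$k
  vals <- vapply(r_cand, function(r) {
    tryCatch(outer_sigma_r(r), error = function(e) NA_real_)
  }, numeric(1))
  ok <- which(is.finite(vals))
  sgn <- sign(vals[ok])
  flip <- which(diff(sgn) != 0)
  if (!length(flip)) {
    stop(sprintf(
      "no solution: outer-boundary residual does not change sign (range %.3g to %.3g kPa over inner stretch %.2f-%.2f)",
      min(vals[ok]), max(vals[ok]), lam_grid[ok[1]],
      lam_grid[ok[length(ok)]]), call. = FALSE)
  }
  i1 <- ok[flip[1]]; i2 <- ok[flip[1] + 1]
  root <- stats::uniroot(outer_sigma_r, c(r_cand[i1], r_cand[i2]),
                         tol = 1e-13)
  r_i <- root$root
  # secant polish until the outer boundary condition meets bc_tol
  f <- outer_sigma_r(r_i)
  iter <- 0
  while (abs(f) > bc_tol && iter < 30) {
    dr <- 1e-8 * max(r_i, 1)
    fp <- (outer_sigma_r(r_i + dr) - f) / dr
    if (!is.finite(fp) || fp == 0) break
    r_i <- r_i - f / fp
    f <- outer_sigma_r(r_i)
    iter <- iter + 1
  }

  pieces <- wall_fields(layers, r_i, lam_z, activation, n_grid)
  sig_r <- numeric(0); rows <- NULL
  s0 <- -P
  for (pc in pieces) {
    s <- s0 + as.numeric(pracma::cumtrapz(pc$r, pc$sigma_diff / pc$r))
    sig_r <- c(sig_r, s)
    s0 <- s[length(s)]
    rows <- rbind(rows, pc)
  }
  r_o <- rows$r[nrow(rows)]
  prof <- data.frame(
    r = rows$r,
    x_norm = (rows$r - r_i) / (r_o - r_i),
    layer = rows$layer,
    sigma_theta = sig_r + rows$sigma_diff,
    sigma_r = sig_r,
    lam_theta = rows$lam_theta,
    lam_r = rows$lam_r
  )
  structure(prof,
            class = c("transmural_profile", "data.frame"),
            r_i = r_i, r_o = r_o,
            r_interface = pieces[[1]]$r[n_grid],
            interface_index = n_grid,
            P_mmHg = P_mmHg, lam_z = lam_z, activation = activation,
            outer_residual = f)
}

#' Thickness-averaged circumferential Cauchy stress of a profile
#'
#' \eqn{\bar\sigma_\theta = \int \sigma_\theta \, dr / (r_o - r_i)}.
#'
#' @param profile A `transmural_profile`.
#' @return Scalar (kPa).
#' @export
mean_sigma_theta <- function(profile) {
  as.numeric(utils::tail(pracma::cumtrapz(profile$r, profile$sigma_theta), 1)) /
    (attr(profile, "r_o") - attr(profile, "r_i"))
}

#' Calibrate stress-free layer thicknesses to loaded-state targets
#'
#' Rescales the stress-free thicknesses of both layers (keeping each layer's
#' stress-free inner radius and opening angle) so that the solved loaded
#' wall thickness and IM thickness fraction match targets. Fixed-point
#' iteration on the two thicknesses; converges to the default 0.5% relative
#' tolerance in a handful of solves.
#'
#' @param layers Template list of two [layer_spec()]s, inner (IM) first.
#' @param target_h Target loaded wall thickness (mm).
#' @param target_im_fraction Target loaded IM-thickness fraction of the wall.
#' @param P_mmHg,lam_z,activation Loading at which the targets are imposed.
#' @param tol Relative tolerance on both targets.
#' @param max_iter Iteration cap.
#' @param n_grid Grid points per layer for the inner solves.
#' @return List with `layers` (calibrated), `profile` (solved at the
#'   calibration load), `h`, `im_fraction`, `iterations`.
#' @export
calibrate_geometry <- function(layers, target_h, target_im_fraction,
                               P_mmHg, lam_z = 1.3, activation = "active",
                               tol = 0.005, max_iter = 60, n_grid = 120) {
  t_im <- layers[[1]]$R_out - layers[[1]]$R_in
  t_ad <- layers[[2]]$R_out - layers[[2]]$R_in
  for (it in seq_len(max_iter)) {
    cur <- list(
      layer_spec(layers[[1]]$R_in, layers[[1]]$R_in + t_im,
                 layers[[1]]$opening_angle, layers[[1]]$passive,
                 layers[[1]]$active, layers[[1]]$name),
      layer_spec(layers[[2]]$R_in, layers[[2]]$R_in + t_ad,
                 layers[[2]]$opening_angle, layers[[2]]$passive,
                 layers[[2]]$active, layers[[2]]$name)
    )
    prof <- solve_wall(cur, P_mmHg, lam_z, activation, n_grid = n_grid)
    h <- attr(prof, "r_o") - attr(prof, "r_i")
    h_im <- attr(prof, "r_interface") - attr(prof, "r_i")
    frac <- h_im / h
    err_h <- abs(h - target_h) / target_h
    err_f <- abs(frac - target_im_fraction) / target_im_fraction
    if (err_h < tol && err_f < tol) {
      return(list(layers = cur, profile = prof, h = h, im_fraction = frac,
                  iterations = it))
    }
    t_im <- t_im * (target_h * target_im_fraction) / h_im
    t_ad <- t_ad * (target_h * (1 - target_im_fraction)) / (h - h_im)
  }
  stop(sprintf(
    "geometry calibration did not converge: h=%.4f (target %.4f), IM fraction=%.4f (target %.4f)",
    h, target_h, frac, target_im_fraction), call. = FALSE)
}

#' Relative stress differences at the layer interface
#'
#' \eqn{|\Delta\sigma_\theta/\sigma_\theta|} and
#' \eqn{|\Delta\sigma_r/\sigma_r|} between two solved profiles, evaluated at
#' the interface on the media side, with profile `a` as the reference in the
#' denominator.
#'
#' @param profile_a,profile_b Two `transmural_profile`s over the same
#'   geometry and loading.
#' @return Named vector `c(sigma_theta=, sigma_r=)`.
#' @export
interface_metrics <- function(profile_a, profile_b) {
  ia <- attr(profile_a, "interface_index")
  ib <- attr(profile_b, "interface_index")
  sa_t <- profile_a$sigma_theta[ia]; sb_t <- profile_b$sigma_theta[ib]
  sa_r <- profile_a$sigma_r[ia]; sb_r <- profile_b$sigma_r[ib]
  if (sa_t == 0 || sa_r == 0) {
    stop("undefined interface metric: zero reference stress", call. = FALSE)
  }
  c(sigma_theta = abs((sa_t - sb_t) / sa_t),
    sigma_r = abs((sa_r - sb_r) / sa_r))
}

#' Wall thickness maintaining uniform circumferential stress
#'
#' Under the uniform circumferential stress hypothesis the wall thickens
#' with pressure so that the thickness-averaged circumferential Cauchy
#' stress stays at its baseline value. For each pressure the loaded wall
#' thickness is root-found (by recalibrating the stress-free geometry and
#' resolving the wall) so the averaged stress matches the baseline average
#' within `tol`.
#'
#' @param P_series Pressures (mmHg).
#' @param baseline Result of [calibrate_geometry()] at the baseline state.
#' @param im_fraction Loaded IM-thickness fraction held fixed.
#' @param lam_z,activation Loading.
#' @param tol Relative tolerance on the averaged stress.
#' @param n_grid Grid points per layer.
#' @return data.frame with `P_mmHg`, `h`, `mean_sigma_theta`, plus the
#'   calibrated geometries in attribute `calibrations`.
#' @export
uniform_stress_thickness <- function(P_series, baseline, im_fraction = 0.5,
                                     lam_z = 1.3, activation = "active",
                                     tol = 0.005, n_grid = 100) {
  target <- mean_sigma_theta(baseline$profile)
  h0 <- baseline$h
  P0 <- attr(baseline$profile, "P_mmHg")
  cals <- list()
  rows <- lapply(seq_along(P_series), function(i) {
    P <- P_series[i]
    obj <- function(h) {
      cal <- calibrate_geometry(baseline$layers, h, im_fraction, P, lam_z,
                                activation, n_grid = n_grid)
      mean_sigma_theta(cal$profile) - target
    }
    h_guess <- h0 * P / P0
    lo <- h_guess / 2.5; hi <- h_guess * 2.5
    fl <- obj(lo); fh <- obj(hi)
    if (fl * fh > 0) {
      stop("thickness bracketing failed at P = ", P, " mmHg", call. = FALSE)
    }
    h <- stats::uniroot(obj, c(lo, hi), tol = h_guess * tol * 1e-3)$root
    cal <- calibrate_geometry(baseline$layers, h, im_fraction, P, lam_z,
                              activation, n_grid = n_grid)
    cals[[i]] <<- cal
    data.frame(P_mmHg = P, h = h,
               mean_sigma_theta = mean_sigma_theta(cal$profile))
  })
  out <- do.call(rbind, rows)
  attr(out, "calibrations") <- cals
  out
}

#' Write / read a transmural profile CSV
#'
#' Columns: `r_mm, x_norm, layer, sigma_theta_kPa, sigma_r_kPa, lam_theta,
#' lam_r`; solver metadata is stored in comment-style header lines.
#'
#' @param profile A `transmural_profile`.
#' @param path File path.
#' @export
write_profile_csv <- function(profile, path) {
  hdr <- sprintf("# P_mmHg=%g lam_z=%g activation=%s r_i=%.8g r_o=%.8g",
                 attr(profile, "P_mmHg"), attr(profile, "lam_z"),
                 attr(profile, "activation"), attr(profile, "r_i"),
                 attr(profile, "r_o"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- data.frame(r_mm = profile$r, x_norm = profile$x_norm,
                   layer = profile$layer,
                   sigma_theta_kPa = profile$sigma_theta,
                   sigma_r_kPa = profile$sigma_r,
                   lam_theta = profile$lam_theta, lam_r = profile$lam_r)
  utils::write.csv(df, con, row.names = FALSE)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Default synthetic two-layer geometry template
#'
#' A configurable stand-in for unavailable layer-specific stress-free
#' geometry: IM layer with a larger opening angle than the adventitia
#' (qualitatively matching the reported layer asymmetry), IM passive
#' constants from the IM-table means, adventitia passive constants from the
#' wall-table means, and the pooled two-layer active law in the IM layer.
#' Thicknesses are meant to be rescaled by [calibrate_geometry()] to the
#' loaded-state targets of interest.
#'
#' @param im_active [active_constants()] for the IM layer (default the
#'   pooled two-layer constants).
#' @return List of two [layer_spec()]s, IM first.
#' @export
default_layer_template <- function(im_active = published_constants("two_layer")) {
  im_pc <- mean_constants("IM")$passive
  ad_pc <- mean_constants("wall")$passive
  list(
    layer_spec(1.54, 1.72, opening_angle = 1.745, passive = im_pc,
               active = im_active, name = "IM"),
    layer_spec(1.71, 1.87, opening_angle = 1.047, passive = ad_pc,
               active = NULL, name = "adventitia")
  )
}
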