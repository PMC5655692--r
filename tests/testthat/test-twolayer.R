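test_that("the opening-angle radial map conserves layer volume", {
  # no residual strain, no axial stretch, anchored at the reference: identity
  R <- seq(1.2, 1.5, length.out = 11)
  expect_equal(deformed_map(R, 1.2, 1, 1, 1.2), R, tolerance = 1e-14)

  # algebraic area conservation for random admissible inputs
  set.seed(41)
  for (k in 1:10) {
    kk <- pi / (pi - runif(1, 0, 2.5))
    lz <- runif(1, 1.1, 1.6)
    R_in <- runif(1, 0.8, 1.5); R <- R_in + runif(1, 0, 0.5)
    r_in <- runif(1, 0.5, 2)
    r <- deformed_map(R, r_in, lz, kk, R_in)
    expect_equal(kk * lz * (r^2 - r_in^2), R^2 - R_in^2, tolerance = 1e-12)
  }

  # boundary anchoring at the layer's inner surface
  expect_equal(deformed_map(1.3, 0.9, 1.3, pi / (pi - pi / 2), 1.3), 0.9)
  expect_error(deformed_map(0.1, 0.05, 1.3, 2, 1.5), "infeasible")
})

test_that("the local state encodes the opening-angle kinematics", {
  st <- local_state(1.1, 1.0, 1.2, 1.3)
  expect_equal(st$lam_theta, 1.32)
  expect_equal(st$lam_r, 1 / (1.32 * 1.3))
  st0 <- local_state(2, 2, 1, 1.3)
  expect_equal(st0$lam_theta, 1)
  set.seed(42)
  sts <- local_state(runif(20, 0.9, 1.4), runif(20, 0.9, 1.4),
                     runif(20, 1, 1.5), 1.3)
  expect_equal(sts$lam_theta * sts$lam_z * sts$lam_r, rep(1, 20),
               tolerance = 1e-12)
})

test_that("the stress difference matches energy differentiation on an isochoric path", {
  tmpl <- default_layer_template()
  im <- tmpl[[1]]
  ref <- kinematic_state(1, 1)
  expect_equal(stress_difference(ref, im, "passive"), 0)

  # independent oracle: sigma_theta - sigma_r = lam_theta dW/dlam_theta with
  # lam_r eliminated through incompressibility at fixed lam_z
  lz <- 1.3
  W_iso <- function(lt, activation) {
    s <- kinematic_state(lt, lz)
    w <- passive_energy(s, im$passive)
    if (activation == "active") w <- w + active_energy(s, im$active)
    w
  }
  for (lt in c(1.15, 1.3, 1.45)) for (act in c("passive", "active")) {
    st <- kinematic_state(lt, lz)
    fd <- lt * central_fd(function(x) W_iso(x, act), lt, 1e-6)
    expect_equal(stress_difference(st, im, act), fd, tolerance = 1e-5)
  }

  # the active term is present only under activation
  st <- kinematic_state(1.35, lz)
  expect_gt(abs(stress_difference(st, im, "active") -
                  stress_difference(st, im, "passive")), 0.1)
  adv <- tmpl[[2]]   # no active law: activation flag is inert
  expect_equal(stress_difference(st, adv, "active"),
               stress_difference(st, adv, "passive"))
})

test_that("an unloaded residual-stress-free wall stays stress-free", {
  pc <- mean_constants("wall")$passive
  layers <- list(layer_spec(1.4, 1.5, 0, pc, NULL, "IM"),
                 layer_spec(1.5, 1.6, 0, pc, NULL, "adventitia"))
  prof <- solve_wall(layers, 0, 1, "passive", n_grid = 60)
  expect_lt(max(abs(prof$sigma_theta)), 1e-6)
  expect_lt(max(abs(prof$sigma_r)), 1e-6)
  expect_equal(prof$lam_theta, rep(1, nrow(prof)), tolerance = 1e-8)
})

test_that("the solved wall satisfies boundary and interface conditions", {
  cal <- calibrate_geometry(default_layer_template(), 0.22, 0.5, 80, 1.3,
                            "active")
  prof <- solve_wall(cal$layers, 80, 1.3, "active", n_grid = 200)
  ii <- attr(prof, "interface_index")
  expect_equal(prof$sigma_r[1], -mmHg_to_kPa(80), tolerance = 1e-12)
  expect_lt(abs(prof$sigma_r[nrow(prof)]), 1e-6)
  # radial stress continuous, circumferential stress discontinuous
  expect_lt(abs(prof$sigma_r[ii + 1] - prof$sigma_r[ii]), 1e-6)
  expect_gt(abs(prof$sigma_theta[ii + 1] - prof$sigma_theta[ii]), 10)
  # stretches jump at the interface too (different residual strain)
  expect_gt(abs(prof$lam_theta[ii + 1] - prof$lam_theta[ii]), 0.01)
  # radii weakly increasing overall, strictly within each layer
  expect_true(all(diff(prof$r) >= 0))
  expect_true(all(diff(prof$r[prof$layer == "IM"]) > 0))
  expect_true(all(prof$x_norm >= 0 & prof$x_norm <= 1))

  # equilibrium residual on a refined grid
  fine <- solve_wall(cal$layers, 80, 1.3, "active", n_grid = 2000)
  for (lay in c("IM", "adventitia")) {
    d <- fine[fine$layer == lay, ]
    n <- nrow(d)
    dsr <- (d$sigma_r[3:n] - d$sigma_r[1:(n - 2)]) /
      (d$r[3:n] - d$r[1:(n - 2)])
    f <- (d$sigma_theta - d$sigma_r) / d$r
    expect_lt(max(abs(dsr - f[2:(n - 1)])), 1e-4)
  }

  # grid convergence of the interface circumferential stress
  c2 <- solve_wall(cal$layers, 80, 1.3, "active", n_grid = 400)
  expect_lt(abs(prof$sigma_theta[200] - c2$sigma_theta[400]) /
              abs(c2$sigma_theta[400]), 1e-3)
})

test_that("a thin single-material wall recovers the Laplace law", {
  pc <- mean_constants("wall")$passive
  layers <- list(layer_spec(2.00, 2.02, 0, pc, NULL, "IM"),
                 layer_spec(2.02, 2.04, 0, pc, NULL, "adventitia"))
  prof <- solve_wall(layers, 80, 1.3, "passive", n_grid = 150)
  r_i <- attr(prof, "r_i"); r_o <- attr(prof, "r_o")
  laplace <- mmHg_to_kPa(80) * r_i / (r_o - r_i)
  expect_lt(abs(mean_sigma_theta(prof) - laplace) / laplace, 0.02)
})

test_that("geometry calibration hits loaded-state targets", {
  cal <- calibrate_geometry(default_layer_template(), 0.22, 0.5, 80, 1.3,
                            "active")
  expect_lt(abs(cal$h - 0.22) / 0.22, 0.005)
  expect_lt(abs(cal$im_fraction - 0.5) / 0.5, 0.005)
  # recalibrating an already calibrated geometry converges immediately
  again <- calibrate_geometry(cal$layers, 0.22, 0.5, 80, 1.3, "active")
  expect_lte(again$iterations, 2)

  # pressure-overload scenario solves across IM fractions
  for (f in c(0.5, 0.7)) {
    c6 <- calibrate_geometry(default_layer_template(), 0.44, f, 160, 1.3,
                             "active")
    expect_lt(abs(c6$h - 0.44) / 0.44, 0.005)
    expect_lt(abs(c6$im_fraction - f) / f, 0.005)
  }
})

test_that("transmural behaviour matches the two-layer physics", {
  cal <- calibrate_geometry(default_layer_template(), 0.22, 0.5, 80, 1.3,
                            "active")
  act <- cal$profile
  pas <- solve_wall(cal$layers, 80, 1.3, "passive", n_grid = 120)

  # |sigma_r| decreases monotonically from inner to outer boundary
  expect_true(all(diff(abs(act$sigma_r)) <= 1e-9))

  # muscle activation lowers IM circumferential stress, radial nearly fixed
  im_a <- act$sigma_theta[act$layer == "IM"]
  im_p <- pas$sigma_theta[pas$layer == "IM"]
  expect_lt(mean(im_a), mean(im_p))
  expect_lt(max(abs(act$sigma_r - pas$sigma_r)), 1)  # kPa

  # pressure overload raises the inner radial-to-circumferential ratio
  c6 <- calibrate_geometry(default_layer_template(), 0.44, 0.5, 160, 1.3,
                           "active")
  ratio_norm <- abs(act$sigma_r[1]) / act$sigma_theta[1]
  ratio_over <- abs(c6$profile$sigma_r[1]) / c6$profile$sigma_theta[1]
  expect_gt(ratio_over, ratio_norm)
})

test_that("interface metrics compare two solutions at the media side", {
  cal3 <- calibrate_geometry(default_layer_template(), 0.22, 0.5, 80, 1.3,
                             "active")
  expect_equal(unname(interface_metrics(cal3$profile, cal3$profile)),
               c(0, 0))
  tmpl2 <- default_layer_template(im_active = published_constants("fig4", "2d"))
  cal2 <- calibrate_geometry(tmpl2, 0.22, 0.5, 80, 1.3, "active")
  m <- interface_metrics(cal3$profile, cal2$profile)
  expect_true(all(m > 0))
  # hand computation on the stored profiles
  ia <- attr(cal3$profile, "interface_index")
  ib <- attr(cal2$profile, "interface_index")
  expect_equal(unname(m["sigma_theta"]),
               abs((cal3$profile$sigma_theta[ia] -
                      cal2$profile$sigma_theta[ib]) /
                     cal3$profile$sigma_theta[ia]), tolerance = 1e-12)
})

test_that("uniform-stress thickening keeps the averaged stress constant", {
  cal <- calibrate_geometry(default_layer_template(), 0.22, 0.5, 80, 1.3,
                            "active", n_grid = 80)
  us <- uniform_stress_thickness(c(80, 160), cal, 0.5, n_grid = 60)
  target <- mean_sigma_theta(cal$profile)
  expect_equal(us$mean_sigma_theta / target, c(1, 1), tolerance = 0.005)
  expect_equal(us$h[1], cal$h, tolerance = 0.01)
  # doubling the pressure approximately doubles the thickness
  expect_equal(us$h[2] / us$h[1], 2, tolerance = 0.1)
})

test_that("profiles round-trip through the CSV writer", {
  cal <- calibrate_geometry(default_layer_template(), 0.22, 0.5, 80, 1.3,
                            "active", n_grid = 60)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(cal$profile, path)
  back <- read_profile_csv(path)
  expect_equal(back$sigma_theta_kPa, cal$profile$sigma_theta,
               tolerance = 1e-8)
  expect_equal(readLines(path, n = 1),
               sprintf("# P_mmHg=80 lam_z=1.3 activation=active r_i=%.8g r_o=%.8g",
                       attr(cal$profile, "r_i"), attr(cal$profile, "r_o")))
})
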