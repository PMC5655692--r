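test_that("passive energy matches an independently scripted evaluation", {
  ref <- kinematic_state(1, 1)
  pc <- published_constants("wall", "Heart 1")$passive
  expect_equal(passive_energy(ref, pc), 0)

  # independent two-line oracle: explicit Q then W with Table 1 Heart 1
  st <- kinematic_state(1.3, 1.3)
  Et <- 0.345; Ez <- 0.345; lr <- 1 / 1.69; Er <- (lr^2 - 1) / 2
  Q <- 1.96 * Et^2 + 6.60 * Ez^2 + 6.11 * Er^2 +
    2 * 1.72 * Et * Ez + 2 * 6.70 * Ez * Er + 2 * 1.64 * Er * Et
  expect_equal(passive_energy(st, pc), 0.5 * 5.70 * (exp(Q) - 1),
               tolerance = 1e-12)
  expect_gt(passive_energy(st, pc), 0)

  # linear in C1
  pc2 <- passive_constants(2 * pc$C1, pc$a1, pc$a2, pc$a3, pc$a4, pc$a5, pc$a6)
  expect_equal(passive_energy(st, pc2), 2 * passive_energy(st, pc))

  # overflow guard raises a diverged-energy error, not Inf
  big <- passive_constants(1, 50, 50, 50, 1e-3, 1e-3, 1e-3)
  huge <- kinematic_state(30, 30, 30)
  expect_error(passive_energy(huge, big), "diverged")
})

test_that("active energy follows the error-function law", {
  ac <- published_constants("two_layer")
  st <- kinematic_state(1.4, 1.3)
  qp <- 1.4 / 0.43 + 1.3 / 1.62 + st$lam_r / 4.38 - 4.87
  expect_equal(active_energy(st, ac), 28.92 * (erf_indep(qp) - 1),
               tolerance = 1e-10)

  # W_active in (-2 C2, 0]; -C2 exactly where the activation argument is 0
  st0 <- kinematic_state(1.4, 1.3,
                         lam_r = 4.38 * (4.87 - 1.4 / 0.43 - 1.3 / 1.62))
  expect_equal(active_energy(st0, ac), -ac$C2, tolerance = 1e-12)
  set.seed(21)
  sts <- kinematic_state(runif(50, 1.05, 1.9), runif(50, 1.1, 1.6))
  W <- active_energy(sts, ac)
  expect_true(all(W > -2 * ac$C2 & W <= 0))
  far <- kinematic_state(3.5, 1.5)   # activation argument far above zero
  expect_gt(active_energy(far, ac), -1e-6)
})

test_that("analytic 1st PK stresses match finite differences of the energies", {
  ref <- kinematic_state(1, 1)
  pc <- published_constants("wall", "Heart 1")$passive
  T0 <- first_pk_passive(ref, pc)
  expect_equal(c(T0$T_theta, T0$T_z, T0$T_r), c(0, 0, 0))

  set.seed(22)
  worst <- 0
  for (k in 1:5) {
    pcr <- passive_constants(runif(1, 1, 10), runif(1, 0.5, 6),
                             runif(1, 0.5, 6), runif(1, 0.5, 6),
                             runif(1, 0.5, 6), runif(1, 0.5, 6),
                             runif(1, 0.5, 6))
    acr <- active_constants(runif(1, 5, 50), runif(1, 0.2, 0.8),
                            runif(1, 0.4, 1.5), runif(1, 1, 6),
                            runif(1, 3, 10))
    for (lz in c(1.3, 1.5)) for (lt in seq(1.05, 1.7, length.out = 5)) {
      st <- kinematic_state(lt, lz)
      lam <- c(st$lam_theta, st$lam_z, st$lam_r)
      Tp <- first_pk_passive(st, pcr); Ta <- first_pk_active(st, acr)
      ana <- c(Tp$T_theta + Ta$T_theta, Tp$T_z + Ta$T_z, Tp$T_r + Ta$T_r)
      for (i in 1:3) {
        W_i <- function(x) {
          l <- lam; l[i] <- x
          s <- kinematic_state(l[1], l[2], l[3])
          passive_energy(s, pcr) + active_energy(s, acr)
        }
        fd <- central_fd(W_i, lam[i], 1e-5 * lam[i])
        worst <- max(worst, abs(fd - ana[i]) / max(abs(ana[i]), 1e-6))
      }
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("the Fung quadratic form has the expected symmetry", {
  # with a2 = a3 and lam_z = lam_r, swapping (a4, a6) swaps T_z and T_r
  st <- kinematic_state(1.4, 1.2, lam_r = 1.2)
  p1 <- passive_constants(3, 2, 4, 4, 1.5, 2.5, 0.7)
  p2 <- passive_constants(3, 2, 4, 4, 0.7, 2.5, 1.5)
  T1 <- first_pk_passive(st, p1); T2 <- first_pk_passive(st, p2)
  expect_equal(T1$T_z, T2$T_r, tolerance = 1e-12)
  expect_equal(T1$T_r, T2$T_z, tolerance = 1e-12)
})

test_that("active stress components have the closed-form structure", {
  ac <- published_constants("two_layer")
  # at the zero of the activation argument: T_theta = 2 C2 / (b1 sqrt(pi))
  st0 <- kinematic_state(1.4, 1.3,
                         lam_r = 4.38 * (4.87 - 1.4 / 0.43 - 1.3 / 1.62))
  Ta0 <- first_pk_active(st0, ac)
  expect_equal(Ta0$T_theta, 2 * 28.92 / (0.43 * sqrt(pi)), tolerance = 1e-12)
  expect_equal(Ta0$T_theta, 75.890, tolerance = 1e-4)

  # shared Gaussian factor: component ratios fixed by the b's
  set.seed(23)
  sts <- kinematic_state(runif(20, 1.1, 1.8), runif(20, 1.2, 1.5))
  Ta <- first_pk_active(sts, ac)
  expect_equal(Ta$T_theta / Ta$T_r, rep(ac$b3 / ac$b1, 20), tolerance = 1e-12)
  expect_true(all(Ta$T_theta > 0))

  # Gaussian tails vanish
  far <- kinematic_state(3.8, 1.5)
  Tf <- first_pk_active(far, ac)
  expect_lt(max(abs(c(Tf$T_theta, Tf$T_z, Tf$T_r))), 1e-8)

  # planar law: no radial active stress
  ac2d <- published_constants("fig4", "2d")
  T2d <- first_pk_active(sts, ac2d)
  expect_true(all(T2d$T_r == 0))
})

test_that("Cauchy conversion is the stretch-weighted identity", {
  st1 <- kinematic_state(1, 1)
  Tt <- first_pk_passive(st1, strictly_convex_passive())
  sg <- cauchy_normal(st1, Tt)
  expect_equal(sg$sigma_theta, Tt$T_theta)

  st <- kinematic_state(1.4, 1.3)
  T_r <- -10
  sg2 <- cauchy_normal(st, stress_triple_for_test(0, 0, T_r))
  expect_equal(sg2$sigma_r, st$lam_r * T_r)
})

test_that("convexity check distinguishes the strict and printed criteria", {
  ident <- passive_constants(1, 1, 1, 1, 1e-9, 1e-9, 1e-9)
  expect_true(convexity_check(ident, "strict")$pass)
  expect_false(convexity_check(ident, "printed")$pass)
  expect_equal(convexity_check(ident, "printed")$criterion, -3, tolerance = 1e-6)

  h1 <- published_constants("wall", "Heart 1")$passive
  chk1 <- convexity_check(h1, "printed")
  expect_equal(chk1$criterion, -14.6996, tolerance = 1e-4)  # direct arithmetic
  expect_false(chk1$pass)

  h5 <- published_constants("wall", "Heart 5")$passive
  expect_gt(convexity_check(h5, "printed")$criterion, 0)
  expect_true(convexity_check(h5, "printed")$pass)
  expect_false(convexity_check(h5, "strict")$pass)
})
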