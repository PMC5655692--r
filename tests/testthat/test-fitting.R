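toy_passive_points <- function() {
  # tiny fixed passive set for oracle comparisons
  data.frame(state = "passive", lam_z = c(1.3, 1.3, 1.5),
             lam_theta = c(1.2, 1.4, 1.3),
             T_theta = c(10, 40, 25), T_z = c(6, 18, 14),
             T_r = c(-2, -6, -4))
}

test_that("objectives match an independently scripted sum of squares", {
  pc <- published_constants("IM", "Heart 1")$passive
  pts <- toy_passive_points()
  # independent oracle: loop over points with explicit formulas
  sse <- 0
  for (i in seq_len(nrow(pts))) {
    lt <- pts$lam_theta[i]; lz <- pts$lam_z[i]; lr <- 1 / (lt * lz)
    E <- c((lt^2 - 1) / 2, (lz^2 - 1) / 2, (lr^2 - 1) / 2)
    Q <- pc$a1 * E[1]^2 + pc$a2 * E[2]^2 + pc$a3 * E[3]^2 +
      2 * pc$a4 * E[1] * E[2] + 2 * pc$a5 * E[2] * E[3] +
      2 * pc$a6 * E[3] * E[1]
    dQ <- c(pc$a1 * E[1] + pc$a4 * E[2] + pc$a6 * E[3],
            pc$a2 * E[2] + pc$a4 * E[1] + pc$a5 * E[3],
            pc$a3 * E[3] + pc$a5 * E[2] + pc$a6 * E[1])
    Tth <- c(lt, lz, lr) * pc$C1 * exp(Q) * dQ
    sse <- sse + (Tth[1] - pts$T_theta[i])^2 + (Tth[2] - pts$T_z[i])^2 +
      (Tth[3] - pts$T_r[i])^2
  }
  expect_equal(passive_objective(pc, pts), sse, tolerance = 1e-10)
  expect_error(passive_objective(pc, pts[0, ]), "non-empty")

  # self-consistency: zero at the generating constants
  truth <- heart1_im_truth()
  mpts <- generate_stress_points(truth, protocol_spec())
  expect_lt(passive_objective(truth$passive,
                              mpts[mpts$state == "passive", ]), 1e-10)
  tot <- mpts[mpts$state == "total", ]
  expect_lt(total_objective(truth$active, truth$passive, tot), 1e-10)

  # vanishing active scale reduces the total objective to the passive
  # residual against total data
  tiny <- active_constants(1e-9, 1, 1, 1, 5)
  man <- {
    st <- kinematic_state(tot$lam_theta, tot$lam_z)
    Tp <- first_pk_passive(st, truth$passive)
    sum((Tp$T_theta - tot$T_theta)^2 + (Tp$T_z - tot$T_z)^2 +
          (Tp$T_r - tot$T_r)^2)
  }
  expect_equal(total_objective(tiny, truth$passive, tot), man,
               tolerance = 1e-6)
})

test_that("R^2 follows the standard definition per component", {
  ex <- toy_passive_points()
  expect_equal(unname(r_squared(ex, ex)), c(1, 1, 1))
  mean_pred <- ex
  for (cn in c("T_theta", "T_z", "T_r")) mean_pred[[cn]] <- mean(ex[[cn]])
  expect_equal(unname(r_squared(mean_pred, ex)), c(0, 0, 0))
  # hand arithmetic on the circumferential component
  th <- ex; th$T_theta <- c(12, 38, 24)
  expect_equal(unname(r_squared(th, ex)["theta"]),
               1 - (4 + 4 + 1) / sum((ex$T_theta - 25)^2), tolerance = 1e-12)
  degen <- ex; degen$T_z <- 5
  expect_error(r_squared(ex, degen), "variance")
})

test_that("the LM warm start refines without ever degrading", {
  truth <- heart1_im_truth()
  pts <- generate_stress_points(truth, protocol_spec())
  pas <- pts[pts$state == "passive", ]
  res_fn <- function(par) {
    pc <- passive_constants(par[1], par[2], par[3], par[4], par[5], par[6],
                            par[7])
    st <- kinematic_state(pas$lam_theta, pas$lam_z)
    Tt <- first_pk_passive(st, pc)
    c(Tt$T_theta - pas$T_theta, Tt$T_z - pas$T_z, Tt$T_r - pas$T_r)
  }
  b <- default_bounds("passive")
  x_true <- c(truth$passive$C1, truth$passive$a1, truth$passive$a2,
              truth$passive$a3, truth$passive$a4, truth$passive$a5,
              truth$passive$a6)
  at_truth <- lm_warm_start(res_fn, x_true, b$lower, b$upper)
  expect_lt(at_truth$objective, 1e-12)

  near <- lm_warm_start(res_fn, x_true * 1.1, b$lower, b$upper)
  # recovered stresses within 0.5% RMS of the data
  rms_rel <- sqrt(mean(res_fn(near$par)^2)) /
    sqrt(mean(c(pas$T_theta, pas$T_z, pas$T_r)^2))
  expect_lt(rms_rel, 0.005)

  expect_error(lm_warm_start(res_fn, c(100, x_true[-1]), b$lower, b$upper),
               "bounds")
})

test_that("the GA is deterministic, elitist and monotone in best-ever", {
  sphere <- function(p) sum((p - c(2, 3))^2)
  bounds <- list(lower = c(0, 0), upper = c(10, 10))
  cfg <- fit_config(population_size = 30, generations = 25, seed = 5)
  a <- ga_fit(sphere, cfg, bounds, stage = "active")
  b <- ga_fit(sphere, cfg, bounds, stage = "active")
  expect_identical(a, b)
  expect_true(all(diff(a$trace) <= 0))
  expect_lt(a$objective, 0.05)

  # injected optimum is never lost
  c <- ga_fit(sphere, fit_config(30, 3, seed = 6), bounds,
              x_warm = c(2, 3), stage = "active")
  expect_lte(c$objective, sphere(c(2, 3)) + 1e-15)
})

test_that("sequential fitting recovers the generating stress curves", {
  truth <- heart1_im_truth()
  pts <- generate_stress_points(truth, protocol_spec())
  cfg <- fast_config(seed = 7)
  fp <- fit_passive(pts[pts$state == "passive", ], cfg)
  expect_true(all(fp$r2 > 0.999))
  expect_lt(fp$objective, 1e-8)
  fa <- fit_active(pts[pts$state == "total", ], fp$constants, cfg)
  expect_true(all(fa$r2 > 0.999))
  # positivity always holds for returned constants
  k <- fa$constants
  expect_true(all(unlist(k[c("C2", "b1", "b2", "b3", "b_prime")]) > 0))
  expect_identical(fa$seed, 7L)
})

test_that("the configured convexity mode is honoured by the fit", {
  pc_true <- strictly_convex_passive()
  truth <- ground_truth(pc_true)
  pts <- generate_stress_points(truth, protocol_spec(states = "passive"))
  cfg <- fit_config(population_size = 30, generations = 20, seed = 3,
                    constraint_mode = "strict")
  fp <- fit_passive(pts, cfg, n_starts = 4)
  expect_true(convexity_check(fp$constants, "strict")$pass)
  expect_true(all(fp$r2 > 0.98))
})
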