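# Parameter vector packing. Passive fits work on log-free natural scale
# with box constraints handled by the optimizers.
pc_from_par <- function(par) {
  passive_constants(par[1], par[2], par[3], par[4], par[5], par[6], par[7])
}
ac_from_par <- function(par) {
  active_constants(par[1], par[2], par[3], par[4], par[5])
}
par_from_pc <- function(pc) {
  c(pc$C1, pc$a1, pc$a2, pc$a3, pc$a4, pc$a5, pc$a6)
}
par_from_ac <- function(ac) c(ac$C2, ac$b1, ac$b2, ac$b3, ac$b_prime)

# large finite penalty used when the energy diverges, so optimizers see a
# finite (heavily penalized) objective rather than NaN
.DIVERGED_PENALTY <- 1e12

check_points <- function(points, state) {
  if (!is.data.frame(points) || nrow(points) == 0) {
    stop("need a non-empty stress-point data.frame", call. = FALSE)
  }
  need <- c("state", "lam_z", "lam_theta", "T_theta", "T_z", "T_r")
  missing_cols <- setdiff(need, names(points))
  if (length(missing_cols)) {
    stop("stress points lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(points$state == state)) {
    stop("all points must have state '", state, "'", call. = FALSE)
  }
  invisible(points)
}

# residual vector (theory - experiment), all three components stacked
passive_residuals <- function(pc, points) {
  st <- kinematic_state(points$lam_theta, points$lam_z)
  Tt <- first_pk_passive(st, pc)
  c(Tt$T_theta - points$T_theta, Tt$T_z - points$T_z, Tt$T_r - points$T_r)
}

total_residuals <- function(ac, pc_fixed, points) {
  st <- kinematic_state(points$lam_theta, points$lam_z)
  Tt <- first_pk_total(st, pc_fixed, ac)
  c(Tt$T_theta - points$T_theta, Tt$T_z - points$T_z, Tt$T_r - points$T_r)
}

#' Passive least-squares objective
#'
#' Sum over passive stress points of the squared differences between the
#' theoretical and experimental 1st PK stresses in all three normal
#' directions (kPa^2). States where the Fung exponential overflows
#' contribute a large finite penalty instead of NaN.
#'
#' @param pc [passive_constants()].
#' @param points Passive stress points (columns `state`, `lam_z`,
#'   `lam_theta`, `T_theta`, `T_z`, `T_r`).
#' @return Scalar objective (kPa^2).
#' @export
passive_objective <- function(pc, points) {
  check_points(points, "passive")
  tryCatch(sum(passive_residuals(pc, points)^2),
           error = function(e) .DIVERGED_PENALTY)
}

#' Total (vasoconstricted) least-squares objective
#'
#' Sum over activated ("total") stress points of the squared differences
#' between theoretical passive-plus-active and experimental total 1st PK
#' stresses in all three directions, with the passive constants held fixed.
#'
#' @param ac [active_constants()].
#' @param pc_fixed Previously fitted [passive_constants()].
#' @param points Total-state stress points.
#' @return Scalar objective (kPa^2).
#' @export
total_objective <- function(ac, pc_fixed, points) {
  check_points(points, "total")
  tryCatch(sum(total_residuals(ac, pc_fixed, points)^2),
           error = function(e) .DIVERGED_PENALTY)
}

#' Fit configuration
#'
#' Knobs of the genetic-algorithm search and its constraint handling. The
#' published description names the knobs (population size, crossover and
#' mutation probabilities, mutation scale, tournament selection, generation
#' count) without values; the defaults here are robust choices for the
#' <= 8-parameter problems at hand and are all configurable.
#'
#' @param population_size Individuals per generation (>= 10).
#' @param generations Number of generations.
#' @param crossover_prob Blend-crossover probability.
#' @param mutation_scale Initial per-parameter Gaussian mutation s.d. as a
#'   fraction of the bound width; decays linearly to 0.01 by the last
#'   generation.
#' @param tournament_size Tournament selection size.
#' @param elitism Number of best individuals copied unchanged.
#' @param seed Integer RNG seed, recorded in all outputs.
#' @param bounds Optional list with `lower`/`upper` per-parameter vectors;
#'   defaults depend on the stage (see [default_bounds()]).
#' @param constraint_mode Convexity constraint applied to passive fits:
#'   `"none"` (default), `"strict"` or `"printed"`; see [convexity_check()].
#'   Published constant sets violate one or both inequalities, so no mode is
#'   enforced by default.
#' @return Object of class `fit_config`.
#' @export
fit_config <- function(population_size = 120, generations = 300,
                       crossover_prob = 0.8, mutation_scale = 0.1,
                       tournament_size = 3, elitism = 2, seed = 1L,
                       bounds = NULL,
                       constraint_mode = c("none", "strict", "printed")) {
  constraint_mode <- match.arg(constraint_mode)
  if (population_size < 10) stop("population_size must be >= 10", call. = FALSE)
  if (crossover_prob < 0 || crossover_prob > 1) {
    stop("crossover_prob must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(bounds) && any(bounds$lower >= bounds$upper)) {
    stop("bounds must satisfy lower < upper", call. = FALSE)
  }
  structure(list(
    population_size = as.integer(population_size),
    generations = as.integer(generations),
    crossover_prob = crossover_prob, mutation_scale = mutation_scale,
    tournament_size = as.integer(tournament_size),
    elitism = as.integer(elitism), seed = as.integer(seed),
    bounds = bounds, constraint_mode = constraint_mode
  ), class = "fit_config")
}

#' Default parameter bounds per fitting stage
#'
#' Wide boxes covering the published constant ranges with margin:
#' (1e-4, 50) for `C1` and `a1..a6`; (1e-3, 200) for `C2`;
#' (1e-3, 20) for `b1..b3` and `b_prime`.
#'
#' @param stage `"passive"` or `"active"`.
#' @return List with `lower` and `upper` named vectors.
#' @export
default_bounds <- function(stage = c("passive", "active")) {
  stage <- match.arg(stage)
  if (stage == "passive") {
    nm <- c("C1", "a1", "a2", "a3", "a4", "a5", "a6")
    list(lower = stats::setNames(rep(1e-4, 7), nm),
         upper = stats::setNames(rep(50, 7), nm))
  } else {
    nm <- c("C2", "b1", "b2", "b3", "b_prime")
    list(lower = stats::setNames(c(1e-3, rep(1e-3, 3), 1e-3), nm),
         upper = stats::setNames(c(200, rep(20, 3), 20), nm))
  }
}

# constraint violation magnitude for the configured convexity mode (passive
# stage only; positivity is enforced by the box bounds)
convexity_violation <- function(par, stage, mode) {
  if (stage != "passive" || mode == "none") return(0)
  pc <- tryCatch(pc_from_par(par), error = function(e) NULL)
  if (is.null(pc)) return(1)
  chk <- convexity_check(pc, if (mode == "strict") "strict" else "printed")
  if (mode == "strict") sum(pmax(0, -chk$minors)) else max(0, -chk$criterion)
}

#' Levenberg-Marquardt warm start
#'
#' Bounded Levenberg-Marquardt least-squares refinement of a starting
#' parameter vector; the global search is subsequently seeded from its
#' solution. Deterministic given the start.
#'
#' @param residual_fn Function mapping a parameter vector to the residual
#'   vector.
#' @param x0 Start, inside the bounds.
#' @param lower,upper Box bounds.
#' @param max_iter Iteration cap.
#' @return List with `par`, `objective`, `converged`.
#' @export
lm_warm_start <- function(residual_fn, x0, lower, upper, max_iter = 200) {
  if (any(x0 < lower) || any(x0 > upper)) {
    stop("warm-start x0 outside bounds", call. = FALSE)
  }
  safe_res <- function(p) {
    r <- tryCatch(residual_fn(p), error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) {
      rep(sqrt(.DIVERGED_PENALTY / length(x0)), 3)  # finite fallback
    } else r
  }
  fit <- minpack.lm::nls.lm(par = x0, lower = lower, upper = upper,
                            fn = safe_res,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter, ftol = 1e-14, ptol = 1e-14))
  obj <- sum(safe_res(fit$par)^2)
  obj0 <- sum(safe_res(x0)^2)
  if (obj > obj0) {   # never degrade the start
    fit$par <- x0
    obj <- obj0
  }
  converged <- fit$info %in% 1:4
  if (!converged) {
    warning("Levenberg-Marquardt did not converge; returning best iterate",
            call. = FALSE)
  }
  list(par = fit$par, objective = obj, converged = converged)
}

#' Genetic-algorithm minimization
#'
#' Real-coded GA with tournament selection, blend crossover, Gaussian
#' mutation with a linearly decaying scale, and elitism. The initial
#' population mixes individuals scattered around the warm-start solution
#' with uniformly random individuals inside the bounds (infeasible draws are
#' rejection-resampled); constraint violations are handled during evolution
#' through a large static penalty added to the objective. The best-ever
#' individual is tracked and returned, so the final objective never exceeds
#' the warm-start objective.
#'
#' @param objective_fn Function mapping a parameter vector to a scalar
#'   objective (kPa^2).
#' @param config [fit_config()].
#' @param bounds List with `lower`/`upper`.
#' @param x_warm Optional warm-start vector injected into the initial
#'   population.
#' @param stage `"passive"` or `"active"` (selects the constraint set).
#' @return List with `par`, `objective`, `trace` (best-ever objective per
#'   generation), `seed`.
#' @export
ga_fit <- function(objective_fn, config, bounds, x_warm = NULL,
                   stage = c("passive", "active")) {
  stage <- match.arg(stage)
  lower <- bounds$lower; upper <- bounds$upper
  d <- length(lower)
  width <- upper - lower
  set.seed(config$seed)

  penalized <- function(p) {
    v <- convexity_violation(p, stage, config$constraint_mode)
    objective_fn(p) + 1e9 * v
  }
  feasible <- function(p) {
    all(p >= lower) && all(p <= upper) &&
      convexity_violation(p, stage, config$constraint_mode) == 0
  }

  np <- config$population_size
  pop <- matrix(NA_real_, np, d)
  n_seeded <- if (is.null(x_warm)) 0 else ceiling(np / 3)
  tries <- 0
  for (i in seq_len(np)) {
    attempt <- 0
    repeat {
      attempt <- attempt + 1
      cand <- if (i == 1 && !is.null(x_warm) && attempt == 1) {
        x_warm
      } else if (!is.null(x_warm) && i <= n_seeded) {
        pmin(pmax(x_warm * exp(stats::rnorm(d, 0, 0.1)), lower), upper)
      } else {
        lower + stats::runif(d) * width
      }
      tries <- tries + 1
      if (feasible(cand)) break
      if (tries > 200 * np) {
        stop("could not initialize a feasible population under constraint ",
             "mode '", config$constraint_mode, "'", call. = FALSE)
      }
    }
    pop[i, ] <- cand
  }

  fitness <- apply(pop, 1, penalized)
  best_i <- which.min(fitness)
  best_par <- pop[best_i, ]
  best_obj <- fitness[best_i]
  trace <- numeric(config$generations)

  for (gen in seq_len(config$generations)) {
    scale <- config$mutation_scale +
      (0.01 - config$mutation_scale) * (gen - 1) /
      max(1, config$generations - 1)
    newpop <- matrix(NA_real_, np, d)
    ord <- order(fitness)
    n_el <- min(config$elitism, np)
    newpop[seq_len(n_el), ] <- pop[ord[seq_len(n_el)], , drop = FALSE]
    for (i in seq(n_el + 1, np)) {
      pick <- function() {
        idx <- sample.int(np, config$tournament_size)
        idx[which.min(fitness[idx])]
      }
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      child <- if (stats::runif(1) < config$crossover_prob) {
        w <- stats::runif(d, -0.25, 1.25)   # BLX-style blend
        w * p1 + (1 - w) * p2
      } else p1
      child <- child + stats::rnorm(d, 0, scale * width)
      newpop[i, ] <- pmin(pmax(child, lower), upper)
    }
    pop <- newpop
    fitness <- apply(pop, 1, penalized)
    gi <- which.min(fitness)
    if (fitness[gi] < best_obj) {
      best_obj <- fitness[gi]
      best_par <- pop[gi, ]
    }
    trace[gen] <- best_obj
  }
  list(par = best_par, objective = best_obj, trace = trace,
       seed = config$seed)
}

#' Coefficient of determination per stress component
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with the total sum of squares about the
#' experimental mean, computed separately for the circumferential, axial and
#' radial components.
#'
#' @param theory data.frame with columns `T_theta`, `T_z`, `T_r` (theory).
#' @param experiment data.frame with the same columns (experiment).
#' @return Named numeric vector `c(theta=, z=, r=)`.
#' @export
r_squared <- function(theory, experiment) {
  if (nrow(experiment) < 2) stop("need >= 2 points for R^2", call. = FALSE)
  out <- vapply(c(T_theta = "T_theta", T_z = "T_z", T_r = "T_r"),
                function(cn) {
    y <- experiment[[cn]]; f <- theory[[cn]]
    ss_tot <- sum((y - mean(y))^2)
    if (ss_tot == 0) stop("zero experimental variance: R^2 undefined in ",
                          cn, call. = FALSE)
    1 - sum((y - f)^2) / ss_tot
  }, numeric(1))
  names(out) <- c("theta", "z", "r")
  out
}

theory_at_points <- function(points, pc, ac = NULL) {
  st <- kinematic_state(points$lam_theta, points$lam_z)
  Tt <- if (is.null(ac)) first_pk_passive(st, pc) else
    first_pk_total(st, pc, ac)
  data.frame(T_theta = Tt$T_theta, T_z = Tt$T_z, T_r = Tt$T_r)
}

multi_start_lm <- function(residual_fn, bounds, n_starts, x_center) {
  lower <- bounds$lower; upper <- bounds$upper
  d <- length(lower)
  starts <- list(x_center)
  # deterministic extra starts: scattered geometrically around the center
  for (k in seq_len(max(0, n_starts - 1))) {
    starts[[k + 1]] <- pmin(pmax(
      x_center * exp(stats::rnorm(d, 0, 0.5)), lower), upper)
  }
  best <- NULL
  for (x0 in starts) {
    fit <- suppressWarnings(lm_warm_start(residual_fn, x0, lower, upper))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  best
}

#' Fit passive constants to passive stress points
#'
#' Sequential stage one of the estimation protocol: bounded multi-start
#' Levenberg-Marquardt warm starts followed by the genetic-algorithm global
#' search seeded from the best local solution.
#'
#' @param points Passive stress points.
#' @param config [fit_config()].
#' @param n_starts Number of LM starts.
#' @return Object of class `fit_result` with fields `constants`,
#'   `objective`, `r2`, `trace`, `seed`, `config`.
#' @export
fit_passive <- function(points, config = fit_config(), n_starts = 8) {
  check_points(points, "passive")
  bounds <- if (is.null(config$bounds)) default_bounds("passive") else
    config$bounds
  res_fn <- function(par) passive_residuals(pc_from_par(par), points)
  set.seed(config$seed)
  x_center <- c(5, rep(2, 6))  # order of magnitude of published constants
  warm <- multi_start_lm(res_fn, bounds, n_starts, x_center)
  ga <- ga_fit(function(par) passive_objective(pc_from_par(par), points),
               config, bounds, x_warm = warm$par, stage = "passive")
  pc <- pc_from_par(ga$par)
  structure(list(
    constants = pc, objective = ga$objective,
    r2 = r_squared(theory_at_points(points, pc), points),
    trace = ga$trace, seed = config$seed, config = config,
    warm_objective = warm$objective
  ), class = "fit_result")
}

#' Fit active constants to total stress points
#'
#' Sequential stage two: with the passive constants fixed, the active
#' constants minimize the total-stress objective; LM warm starts plus GA as
#' in [fit_passive()].
#'
#' @param points Total-state stress points.
#' @param pc_fixed Fitted [passive_constants()].
#' @param config [fit_config()].
#' @param n_starts Number of LM starts.
#' @return Object of class `fit_result`.
#' @export
fit_active <- function(points, pc_fixed, config = fit_config(),
                       n_starts = 8) {
  check_points(points, "total")
  bounds <- if (is.null(config$bounds)) default_bounds("active") else
    config$bounds
  res_fn <- function(par) total_residuals(ac_from_par(par), pc_fixed, points)
  set.seed(config$seed)
  x_center <- c(20, 0.5, 1, 3, 5)
  warm <- multi_start_lm(res_fn, bounds, n_starts, x_center)
  ga <- ga_fit(function(par)
    total_objective(ac_from_par(par), pc_fixed, points),
    config, bounds, x_warm = warm$par, stage = "active")
  ac <- ac_from_par(ga$par)
  structure(list(
    constants = ac, objective = ga$objective,
    r2 = r_squared(theory_at_points(points, pc_fixed, ac), points),
    trace = ga$trace, seed = config$seed, config = config,
    warm_objective = warm$objective
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  k <- x$constants
  nm <- setdiff(names(k), c("subject_id", "layer"))
  vals <- unlist(k[nm])
  cat("<fit_result>\n  constants:",
      paste(sprintf("%s=%.4g", nm, vals), collapse = ", "),
      "\n  objective:", format(x$objective), "kPa^2\n  R^2:",
      paste(sprintf("%s=%.4f", names(x$r2), x$r2), collapse = ", "),
      "\n  seed:", x$seed, "\n")
  invisible(x)
}
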