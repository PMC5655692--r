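# Independent oracles used across tests; none of these call package
# internals for the quantity they check.

# Gauss error function through the normal CDF (base R), independent of the
# erf used inside the package.
erf_indep <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# central finite difference of f at x
central_fd <- function(f, x, h) (f(x + h) - f(x - h)) / (2 * h)

# a strictly convex (diagonally dominant) passive constant set, used where a
# fit must satisfy the strict hyperelasticity mode
strictly_convex_passive <- function() {
  passive_constants(5, 4, 4.5, 5, 0.5, 0.6, 0.4)
}

# small fit configuration keeping unit tests fast
fast_config <- function(seed = 1, ...) {
  fit_config(population_size = 40, generations = 40, seed = seed, ...)
}

# bare stress triple built without the package constructor
stress_triple_for_test <- function(T_theta, T_z, T_r) {
  structure(list(T_theta = T_theta, T_z = T_z, T_r = T_r),
            class = "stress_triple")
}

heart1_im_truth <- function() {
  k <- published_constants("IM", "Heart 1")
  ground_truth(k$passive, k$active)
}
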