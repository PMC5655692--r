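#!/usr/bin/env Rscript
# Stage 5: figures and tables from the stored stage outputs. Deterministic:
# re-running regenerates identical files from the same inputs.

suppressPackageStartupMessages({
  library(triaxwall)
  library(ggplot2)
})

need <- c("results/fitted_vs_data.csv", "results/profile_80mmHg_active.csv",
          "results/profile_80mmHg_passive.csv",
          "results/sensitivity_curves_3d.csv")
missing <- need[!file.exists(need)]
if (length(missing)) {
  stop("missing stage outputs (run analysis/01..04 first):\n  ",
       paste(missing, collapse = "\n  "), call. = FALSE)
}

theme_set(theme_bw(base_size = 10))

## fitted vs synthetic stress-stretch curves
fv <- utils::read.csv("results/fitted_vs_data.csv")
fv13 <- subset(fv, lam_z == 1.3)
long <- do.call(rbind, lapply(c("theta", "z", "r"), function(cmp) {
  data.frame(lam_theta = fv13$lam_theta, state = fv13$state,
             component = cmp,
             data = fv13[[paste0("T_", cmp)]],
             fit = fv13[[paste0("T_", cmp, "_fit")]])
}))
p1 <- ggplot(long, aes(lam_theta, data, colour = state)) +
  geom_point(size = 1.2) +
  geom_line(aes(y = fit, linetype = state)) +
  facet_wrap(~component, scales = "free_y") +
  labs(x = expression(lambda[theta]),
       y = "1st PK stress (kPa)",
       title = "Fitted vs synthetic mean-wall stresses (axial stretch 1.3)")
ggsave("results/fig_fit_curves.pdf", p1, width = 7.5, height = 3)

## transmural profiles
pa <- utils::read.csv("results/profile_80mmHg_active.csv", comment.char = "#")
pp <- utils::read.csv("results/profile_80mmHg_passive.csv", comment.char = "#")
pa$activation <- "active"; pp$activation <- "passive"
pr <- rbind(pa, pp)
p2 <- ggplot(pr, aes(x_norm, sigma_theta_kPa,
                     colour = activation, group = interaction(activation, layer))) +
  geom_line() +
  labs(x = "normalized wall coordinate", y = expression(sigma[theta]~"(kPa)"),
       title = "Transmural circumferential Cauchy stress, 80 mmHg")
ggsave("results/fig_profile_sigma_theta.pdf", p2, width = 5, height = 3.2)
p3 <- ggplot(pr, aes(x_norm, sigma_r_kPa, colour = activation,
                     group = interaction(activation, layer))) +
  geom_line() +
  labs(x = "normalized wall coordinate", y = expression(sigma[r]~"(kPa)"),
       title = "Transmural radial Cauchy stress, 80 mmHg")
ggsave("results/fig_profile_sigma_r.pdf", p3, width = 5, height = 3.2)

## sensitivity families
sens <- utils::read.csv("results/sensitivity_curves_3d.csv")
p4 <- ggplot(sens, aes(lam_theta, T_r, colour = factor(multiplier))) +
  geom_line() + facet_wrap(~parameter) +
  labs(x = expression(lambda[theta]), y = expression(T[r*","*active]~"(kPa)"),
       colour = "multiplier",
       title = "Radial active stress under b1-b3 rescaling")
ggsave("results/fig_sensitivity_Tr.pdf", p4, width = 7.5, height = 3)

cat("wrote figures: results/fig_*.pdf\n")
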