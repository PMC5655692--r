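---
title: "Triaxial passive and active coronary wall mechanics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triaxial passive and active coronary wall mechanics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triaxwall)
```

## Scope

`triaxwall` implements a three-dimensional analysis of passive and active
(smooth-muscle) mechanics of the coronary artery wall in the three normal
directions -- circumferential ($\theta$), axial ($z$) and radial ($r$) --
together with a two-layer thick-wall cylinder model of the transmural
stress distribution. The pipeline has four stages, mirrored by the scripts
under `analysis/`: synthetic data generation, reduction of
inflation--extension records to mean-wall stresses, constrained estimation
of material constants, and the layered boundary-value problem.

All internal computation uses kPa, mm and mN (so that kPa mm$^2$ = mN);
pressures cross the public interface in mmHg and are converted at the
boundary (1 mmHg = 0.1333224 kPa). The stress scales $C_1$, $C_2$ carry
kPa, which places the predicted stresses in the tens-to-hundreds of kPa
range expected for coronary wall tissue.

## Constitutive model

The passive wall is a Fung-type incompressible pseudo-hyperelastic solid,

$$W_{passive} = \tfrac{1}{2} C_1 \left( e^Q - 1 \right), \qquad
Q = a_1 E_\theta^2 + a_2 E_z^2 + a_3 E_r^2
  + 2 a_4 E_\theta E_z + 2 a_5 E_z E_r + 2 a_6 E_r E_\theta ,$$

with Green strains $E_i = (\lambda_i^2 - 1)/2$ and incompressibility
$\lambda_\theta \lambda_z \lambda_r = 1$. Smooth-muscle activation
(maximal K$^+$-induced constriction) is modelled by an empirical
error-function energy

$$W_{active} = C_2\left[\mathrm{Erf}(Q') - 1\right], \qquad
Q' = \frac{\lambda_\theta}{b_1} + \frac{\lambda_z}{b_2} +
\frac{\lambda_r}{b_3} - b' .$$

A contracting muscle is not literally hyperelastic; the active energy is an
empirical descriptor of the measured length--tension behaviour. The
numerator constants that would compose the offset are individually
unidentifiable (only their combination enters $Q'$), so the implementation
stores the single offset `b_prime`, which is also how the published
constant sets report it.

First Piola--Kirchhoff (1st PK) stresses are direct partial derivatives of
the total energy with the three stretches treated as independent
arguments,

$$T_i = \lambda_i \frac{\partial W_{passive}}{\partial E_i}
      + \frac{\partial W_{active}}{\partial \lambda_i},$$

which is consistent with the experimental definitions $T_i = \sigma_i /
\lambda_i$ used in the stress reduction; no Lagrange multiplier appears in
the homogenized mean-wall setting (states are always constructed on the
incompressibility manifold). The active components have the closed form
$T_{i,active} = 2C_2/(b_i\sqrt{\pi}) \, e^{-Q'^2}$: each component is
positive, peaks exactly where $Q'$ crosses zero, and its peak value
$2C_2/(b_i\sqrt{\pi})$ depends only on $C_2$ and its own $b_i$. This is
the closed-form backbone of the sensitivity analysis: rescaling $b_3$
rescales the radial peak ($\propto 1/b_3$) and leaves the circumferential
peak unchanged, while rescaling $b_1$ or $b_2$ only moves the stretch at
which the peak occurs -- provided the zero crossing stays inside the
examined stretch window, which the sensitivity functions record
(`q_crosses_zero`).

A planar (2D) variant of the active law, with no radial term
(`active_constants_2d`, $b_3 = \infty$), is provided for model comparison
in the layered wall; its radial active stress is identically zero.

### Hyperelasticity constraint

The convexity of $Q$ is diagnosed in two modes because the published
constraint is ambiguous: `strict` requires positive-definiteness of the
coefficient matrix (three positive leading principal minors), while
`printed` evaluates the published inequality
$a_4^2+a_5^2+a_6^2-a_1a_2-a_2a_3-a_1a_3 > 0$, which is the reverse of the
usual definiteness surrogate. The packaged per-subject constant sets are
inconsistent with both (some satisfy one, some the other, some neither),
so no mode is enforced on fixtures and the default fitting configuration
applies no convexity penalty (`constraint_mode = "none"`); both modes
remain available and are honoured when configured. This is also why the
parameter-recovery studies run unconstrained: the published ground-truth
constants themselves violate both inequalities.

## Stress reduction from inflation--extension records

A record is (transmural pressure $P$, loaded outer diameter $d_o$, axial
force $F$) at a fixed axial stretch and activation state, with reference
geometry: no-load wall area $A_0$ and zero-stress mid-wall circumferential
length $l_0$. Wall-volume conservation gives the loaded inner radius
$r_i = \sqrt{r_o^2 - A_0/(\pi\lambda_z)}$, and the mean-wall experimental
stresses are

$$T_\theta = \frac{P r_i}{\lambda_\theta h}, \qquad
T_z = \frac{1}{\lambda_z}\left[\frac{F}{\pi(r_o^2-r_i^2)} +
\frac{P r_i^2}{h(r_o+r_i)}\right], \qquad
T_r = \frac{-r_i P}{(r_o+r_i)\lambda_r},$$

with $h = r_o - r_i$. The circumferential stretch of the homogenized wall
is evaluated at the mid-wall radius, $\lambda_\theta = \pi(r_i+r_o)/l_0$
-- the reference radius is not uniquely dictated by the mean-wall
formulation, and mid-wall is the standard choice for mean-stress
reduction. The axial force is taken as the externally measured transducer
force (the explicit pressure term in $T_z$ indicates the formula expects
it); the axial length at no-load is assumed equal to that at zero stress.

## Synthetic data generator

The generator emulates the stated experimental protocol: pressures
20--200 mmHg in 20 mmHg steps, axial stretches 1.3 and 1.5, passive
(Ca$^{2+}$-free) and maximally constricted (60 mM K$^+$) states. For each
condition it root-finds the mean-wall circumferential stretch at which the
theoretical circumferential stress balances the pressure-derived value
(bracket 1.01--2.5), converts it to an outer diameter, and then sets the
axial force by inverting the axial-stress formula, so that reducing the
record returns the theoretical circumferential and axial stresses to
machine precision.

The default reference geometry ($A_0 = 1.6$ mm$^2$, $l_0 = 8.4$ mm,
declared plausible rather than reconstructed -- the real vessels'
geometry is not published) makes the circumferential stretch span about
1.16--1.70 over the default protocol, matching the stretch window over
which the published constants were presented.

Two properties of this construction deserve emphasis:

* **The radial component is overdetermined.** A record has two free
  measured quantities ($d_o$, $F$) but the reduction produces three
  stresses; the reduced radial stress is the pressure-derived equilibrium
  estimate and cannot simultaneously be made equal to the constitutive
  radial stress. This is not an artefact: it is exactly the model-vs-data
  radial residual that the original fits absorb (their radial
  goodness-of-fit is below the circumferential one for the same reason).
  Consequently the measurement route (`generate_dataset` then
  `reduce_dataset`) is deliberately model-inconsistent in the radial
  component.
* **Parameter recovery uses the model route.** Recovery studies ask
  whether the estimator finds the generating constants, which is only
  well-posed when the data lie in the model family;
  `generate_stress_points` therefore emits all three components from the
  constitutive law at the equilibrium stretches. Noise is multiplicative
  Gaussian with a given coefficient of variation: applied to diameter and
  force in the measurement route (mirroring the experimental error
  pathway) and to the stress components in the model route.

Passing recovery tests on these data show the estimator works; they do not
show that real vessels follow the Fung/error-function family, nor do the
synthetic records reproduce preconditioning transients, hysteresis, or
between-animal covariance.

## Fitting protocol

Estimation is sequential, matching the order in which the objectives are
posed: passive constants minimize the summed squared differences between
theoretical and experimental passive stresses in all three directions;
active constants then minimize the total-stress objective with the passive
set fixed. Each stage runs bounded multi-start Levenberg--Marquardt
(8 starts, deterministic given the seed) and seeds a real-coded genetic
algorithm from the best local solution: tournament selection (size 3),
blend crossover (probability 0.8), Gaussian mutation with a per-parameter
scale decaying linearly from 0.1 to 0.01 of the bound width, elitism of 2,
population 120 and 300 generations by default. The published description
names these knobs but not their values; the defaults are robust choices
for problems of at most eight parameters, and every knob is configurable.
Constraint handling adds a $10^9 \times$ violation static penalty during
evolution and rejection-resamples infeasible individuals at
initialization. Default bounds cover the published constant ranges with
margin: $(10^{-4}, 50)$ for $C_1, a_{1..6}$; $(10^{-3}, 200)$ for $C_2$;
$(10^{-3}, 20)$ for $b_{1..3}, b'$.

Divergence of the Fung exponential ($Q > 700$) raises an error that the
objectives convert into a large finite penalty ($10^{12}$ kPa$^2$), so
optimizers see a finite landscape instead of NaNs. $R^2$ is reported per
stress component about the experimental mean (the standard definition; the
source tables do not define theirs). The tests and the acceptance script
run the GA at population 60 for 80 generations, sizes at which the
noiseless recovery reproduces all six stress--stretch curves with
$R^2 = 1$ to numerical precision and 2%-noise replicates stay above 0.99;
these sizes are the package's choice for routine runs, with the larger
defaults available for harder data.

## Two-layer wall model

The wall is two concentric layers -- intima--media (IM), which carries the
active law, and adventitia, passive only -- each with its own stress-free
(cut-open) configuration described by inner/outer radii and an opening
angle $\Phi$ ($k = \pi/(\pi-\Phi)$; $\Phi = 0$ means no residual strain).
The layers are treated as independently cut: each keeps its own
stress-free reference, and they are coupled only by continuity of the
deformed radius at the interface. The incompressible radial map within a
layer is $r(R) = \sqrt{r_{in}^2 + (R^2 - R_{in}^2)/(k\lambda_z)}$ with
pointwise stretches $\lambda_\theta = k r / R$,
$\lambda_r = 1/(\lambda_\theta\lambda_z)$.

Radial equilibrium $d\sigma_r/dr = (\sigma_\theta - \sigma_r)/r$ is
integrated outward from $\sigma_r(r_i) = -P$; the Lagrange multiplier of
the incompressible formulation cancels in the difference
$\sigma_\theta - \sigma_r = \lambda_\theta^2 \partial W_p/\partial
E_\theta - \lambda_r^2 \partial W_p/\partial E_r$ (plus the analogous
active term when the layer is activated), so the integrand is an explicit
function of radius and the whole radial profile follows by cumulative
trapezoidal quadrature on a per-layer grid (default 200 points per layer).
The deformed inner radius is the shooting variable: a sign-change scan
over inner-wall stretches 0.55--2.4 brackets the root of
$\sigma_r(r_o) = 0$, `uniroot` refines it, and a secant polish drives the
outer boundary residual below $10^{-6}$ kPa. Radial stress is continuous
across the interface by construction; circumferential stress and the
stretches jump there whenever the layers' residual strains or constants
differ. By this construction $\sigma_r$ is monotone whenever
$\sigma_\theta > \sigma_r$ throughout the wall, which holds for all
pressurized scenarios examined.

Layer-specific stress-free geometry for the original vessels is not
published, so the default template is synthetic and configurable: IM
opening angle 1.745 rad larger than the adventitia's 1.047 rad (matching
the reported layer asymmetry qualitatively), IM passive constants from the
IM-table means, adventitia passive constants from the wall-table means,
and the pooled two-layer active constants
($C_2 = 28.92$, $b_1 = 0.43$, $b_2 = 1.62$, $b_3 = 4.38$, $b' = 4.87$) in
the IM layer. `calibrate_geometry` rescales the stress-free thicknesses by
fixed-point iteration until the *loaded* wall thickness and IM fraction
hit printed targets (0.22 mm with IM = $h/2$ at 80 mmHg for the
physiological state; 0.44 mm at 160 mmHg for pressure overload) within
0.5%. Because the stress magnitudes then depend on these synthetic
choices, the transmural results are validated directionally (monotone
$|\sigma_r|$, interface discontinuity of $\sigma_\theta$, activation
lowering IM $\sigma_\theta$ with little radial change, overload raising
the inner radial-to-circumferential ratio) rather than against printed
kPa values. With the default template the physiological state gives an
inner ratio of about 0.13 (close to the reported one-seventh) rising to
about 0.29 under overload at IM = $h/2$.

The uniform-circumferential-stress series root-finds, for each pressure,
the loaded thickness at which the thickness-averaged $\sigma_\theta$
equals its baseline value within 0.5%; thickness approximately doubles
when pressure doubles, as the thin-wall limit predicts. The 2D-vs-3D
comparison re-solves the wall with the planar active law in the IM layer
(published stretch scales $b_1 = 0.12$, $b_2 = 0.18$; its stress scale and
offset are not published, so package defaults complete the set -- the
comparison is therefore qualitative, and only the existence of a nonzero
interface difference is asserted, not its trend with pressure).

## Numerical choices

* Overflow guard at $Q > 700$; energies never return Inf.
* Equilibrium-stretch root-finding: bracket (1.01, 2.5), `uniroot`
  tolerance $10^{-12}$; infeasible protocols fail with the offending
  pressure.
* Shooting: bracket scan of 75 candidate inner stretches, `uniroot`
  tolerance $10^{-13}$ on the radius, secant polish to $|\sigma_r(r_o)| <
  10^{-6}$ kPa; no sign change raises a diagnostic error with the scanned
  residual range.
* Grid sizes: 200 points/layer for production profiles (grid-doubling
  moves the interface stress by under 0.1%), 2000 for equilibrium-residual
  verification (residual below $10^{-4}$ kPa/mm), 60--150 inside
  calibration loops where only integral quantities are needed.
* Calibration: fixed-point update of the two stress-free thicknesses,
  0.5% relative tolerance, 60-iteration cap with a diagnostic error.
* All stochastic components (noise, LM start scatter, GA) consume a
  recorded integer seed; identical seeds give bit-identical results.

## Known limitations

Shear deformation, viscoelasticity, perivascular tethering, more than two
layers, growth/remodelling and fibre-level microstructure are out of
scope. The mean-wall reduction assigns one homogenized state per record;
its radial stress is an equilibrium estimate, not a constitutive quantity,
and carries the irreducible residual discussed above. The printed summary
rows of the published constant tables are internally inconsistent with
their own subject rows in several cells (the means to within one final
digit, several SD cells beyond that); the packaged fixtures keep the
subject rows verbatim and the tests document the discrepancy rather than
adjusting either side.
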