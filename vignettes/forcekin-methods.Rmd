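---
title: "Models and methods behind forcekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind forcekin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forcekin)
```

`forcekin` analyses how mechanical force reshapes the dissociation kinetics
of TCR/pMHC bonds and, through them, T-cell antigen discrimination. This
vignette documents the models, the estimators, the synthetic-data
generators that stand in for raw measurements, and the numerical and design
choices a user should know about.

## Bell kinetics and the discrimination calculus

The core phenomenology is Bell's model for a bond under constant load,

$$k_{\mathrm{off}}(F) = k^0_{\mathrm{off}}\,
  e^{F x_\beta / k_B T},$$

with $k^0_{\mathrm{off}}$ in 1/s, $F$ in pN, $x_\beta$ in nm and $k_B T$ in
pN nm. $x_\beta$ is interpretable as the distance from the bound state to
the transition state; $x_\beta > 0$ is a slip bond, $x_\beta < 0$ a catch
bond. The default thermal energy is $k_B T = 0.0138 \times 310.15 = 4.28$
pN nm (physiological temperature); the proofreading module instead fixes
the constant 4.2797 pN nm used throughout its calculations, so that its
closed-form examples are bit-reproducible. Both are configurable.

Discrimination is a *fold-change* question: for two ligands whose zero-force
off-rates differ 100-fold, an applied force amplifies the membrane off-rate
ratio when $x_\beta$ increases with $k_{\mathrm{off}}$ (to roughly 820-fold
at 15 pN with $x_\beta = +0.3\log_{10} k_{\mathrm{off}}$ nm) and dampens it
when $x_\beta$ decreases (to roughly 12-fold with slope $-0.3$). The
package's measured and simulated slopes are negative, which motivates the
whole analysis: force impairs discrimination.

`fit_bell()` fits the model by linear regression of $\ln k$ on $F$. This is
a deliberate choice: off-rate estimates have multiplicative errors, the
exponential model is exactly linear in log space, and the standard errors
come from the closed-form regression covariance. A nonlinear least-squares
mode (`method = "nls"`) is provided for users who prefer fitting in rate
space; on noiseless data the two agree to numerical precision. Off-rate
standard errors, when supplied, enter as inverse-variance weights on the
log scale (delta method); duplicate force points are kept as-is. Whether
the original analyses weighted these fits is not documented, so both modes
are exposed and the unweighted fit is the default.

## Flow-chamber hydrodynamics

In the laminar flow chamber, a receptor-coated microsphere arrested by a
single bond feels a drag force $R = 1.7005 \times 6\pi \mu a^2 G$ and a
torque $\Gamma = 0.9440 \times 4 \mu a^3 G$, amplified by the tether lever
arm: $F = (R + \Gamma/a)\sqrt{a/2L}$. Two printed-formula subtleties are
handled explicitly:

* The flow-to-shear conversion is implemented as $G = 6Q/(l H^2)$ — the
  plane-Poiseuille wall shear with the channel width $l$ included for
  dimensional consistency.
* The torque prefactor is implemented without a factor of $\pi$, exactly
  as printed in the source formula; `bead_model(torque_includes_pi = TRUE)`
  switches to the $4\pi$ literature form. The default favours fidelity to
  the printed coefficient set, with which the drag prefactor identity
  $1.7005 \times 6\pi \approx 32$ holds.

Defaults not fixed by the assay description — bead radius 2.25 um (Dynal
M-450), viscosity $10^{-3}$ Pa s, tether length 30 nm, wall-sphere
translation factor $c_t = 0.7431$ — are all configurable; with them,
bead velocities of 2–120 um/s map to bond forces of roughly 1–80 pN,
covering most of the assay's working range.

## Arrest-survival analysis

`ligand_force_spectrum()` chains the full measurement pipeline:

1. events pool into half-open velocity bins [2,10), [10,20), [20,40),
   [40,60), [60,80), [80,120) um/s; the bin-mean velocity sets the force;
2. the empirical survival $s(t) = P(\text{duration} \ge t)$ is evaluated
   at every observed event time ($s(0) = 1$, right-continuous steps);
3. non-specific correction subtracts the paired no-pMHC control as a
   *count-weighted mixture*: $s_{\mathrm{corr}} = (w_s s_s - w_c s_c)/(w_s -
   w_c)$ with weights in arrests per unit distance, clipped to $[0,1]$.
   The weighted form preserves the probabilistic interpretation (the
   sample is literally a mixture of specific and non-specific arrests); a
   pointwise unweighted subtraction mode exists for comparison. A bin whose
   control weight reaches the sample weight is refused as fully
   non-specific;
4. bins with fewer than 15 events in (1 s, 2 s] are excluded;
5. off-rates are estimated three ways and all three are reported:
   * survival at 1 s (the headline method): $k = -\ln s(1)/1$, using the
     first event time at or after 1 s;
   * survival at 2 s, analogously;
   * a one-phase exponential with plateau, $s(t) = (A - B)e^{-kt} + B$,
     fitted to the first 5 s with bounds $0 \le B \le A \le 1.05$;
6. Bell's model is fitted across bins, per estimator.

The geometric mean with a multiplicative geometric SEM factor
$e^{\mathrm{sd}(\ln x)/\sqrt n}$ summarises binding linear densities
(arrests/mm), and the specificity filter drops velocity bins whose
fold-change lower bound (geometric mean divided by the SEM factor) is
below 1 — error bars of log-scale data are multiplicative, so division is
the natural reading of "mean − SEM"; a subtraction mode is available.

**Estimator bias and the plateau.** With a long-lived arrest subpopulation
(fraction $p$), the survival-at-$t$ estimator saturates near $-\ln p$ once
the Bell rate is fast, so its fitted $x_\beta$ is biased low at high force.
The exponential-plateau fit absorbs the subpopulation into $B$ and tracks
the dominant rate; it is therefore the estimator used for quantitative
recovery checks, while the pipeline reports all three for robustness
comparison, mirroring the original analysis strategy.

**Frame quantization and the fit origin.** Durations are multiples of the
frame interval (20 ms at 50 fps), and the empirical survival equals 1 at
the first resolvable frame *by construction*. Fitted from $t = 0$, the
exponential's amplitude must then absorb a factor $e^{k/\mathrm{fps}}$,
which collides with the $A \le 1.05$ bound once $k \gtrsim 2.5$/s and
biases $k$ low. `fit_exponential_plateau(origin = "first_event")` instead
starts the exponential clock at the first event time; the pipeline uses
this origin, while the default (`origin = "zero"`) fits the model exactly
as written for unquantized data.

## Synthetic assays

`simulate_arrest_table()` emulates the measurement process with known
ground truth: specific arrest durations are a mixture
$(1-p_B)\,\mathrm{Exp}(k(F)) + p_B\,\mathrm{Exp}(k_{\mathrm{plateau}})$,
non-specific arrests are fast-exponential and present on sample and
control surfaces alike, counts are Poisson with means proportional to
ligand density, travelled distance and a logistic binding probability that
decays with velocity (fast beads have too little encounter time to bind —
this shapes counts only, never lifetimes), durations are rounded to the
frame grid with sub-half-frame arrests dropped, and everything is censored
at the movie end.

Defaults are chosen once to be realistic for this assay class: plateau
fraction 0.1 with rate 0.02/s (a visible but slowly-decaying tail —
exponential rather than infinite-lived so censoring behaves sensibly),
non-specific rate 2/s, specific binding density 0.55 arrests/mm at unit
ligand density versus 0.1 arrests/mm non-specific, logistic midpoint
150 um/s with scale 30 um/s, 90 s movies at 50 fps. The generator does
**not** emulate bead collisions, tracking noise beyond frame quantization,
or history-dependent re-binding; passing recovery tests therefore shows
the estimators are correct for the generative model stated above, not that
real-data systematics are absent.

Parameter-recovery checks run at roughly 500 events per bin across six
bins (bead counts scaled per velocity to balance bins), where the
exponential-plateau route recovers a planted $(k^0_{\mathrm{off}} = 0.29$/s,
$x_\beta = 0.3$ nm$)$ bond within 15% and 25% respectively, and
a planted negative $x_\beta$–$\log_{10} K_D$ slope is detected with the
correct sign in ≥95% of 100 seeded replicates.

## Coarse-grained pulling simulations

The simulator represents each residue as one bead at the Cα position.
Native contacts are detected on heavy atoms with an overlap criterion
(distance below $1.24\,(r_i^{\mathrm{vdW}} + r_j^{\mathrm{vdW}})$; a plain
4.5 Å cutoff is the documented fallback, and the only sensible choice for
Cα-only toy structures), excluding intra-chain pairs $(i,i+1)$ and
$(i,i+2)$. The potential comprises stiff harmonic backbone springs,
harmonic springs for *intra*-molecular contacts (so individual chains
cannot unfold), 12-6 Lennard-Jones wells of depth $\varepsilon$ at the
native distance for *inter*-molecular contacts, harmonic disulphide
springs, and a short-range $r^{-12}$ repulsion for everything else.
Energies are in $k_B T$, lengths in Å, and the time unit $\tau$ is left
symbolic (rates are reported as $k_{\mathrm{off}}\tau$).

Pulling uses two springs of stiffness $\kappa = 0.12\,k_BT/$Å²: one holds
the TCRβ C-terminus at its native position, the other retracts from the
MHC C-terminus at constant speed along the initial attachment axis (not
re-aligned during pulling). The recorded response force is the pulling
spring's extension projected on that axis. Dynamics default to overdamped
Brownian (Euler–Maruyama); an underdamped BAOAB mode exists and reduces to
velocity Verlet at zero friction and temperature, which is how the
integrator's energy conservation is verified (drift < 0.1% over $10^5$
steps). The time step is auto-derived from the stiffest interaction
(0.05 γ/k), and replicate trajectories differ only by seed —
identical seeds give bit-identical traces.

Rupture forces are the maximum of the lightly smoothed trace, validated by
a monitor requiring all inter-molecular contacts broken (pair distance
beyond 1.5 × native) with the force staying below 10% of the peak
afterwards. The mean rupture force over replicates, as a function of
pulling speed, follows the Bell–Evans relation
$F = (k_BT/x_\beta)\ln(x_\beta \kappa v / k_BT k_{\mathrm{off}})$, which
`fit_bell_evans()` inverts by weighted linear regression of $F$ on
$\ln v$; when the logarithm's argument drops below 1 the most probable
rupture force is reported as 0 (rupture is thermally dominated; a negative
force has no meaning in this phenomenology).

The integrator itself is validated against a semi-analytic oracle: for a
single Lennard-Jones bond pulled through the dual-spring arrangement, the
mean rupture force predicted by quasi-adiabatic Kramers escape (mean
first-passage-time integrals over the instantaneous tilted potential, with
relative-coordinate diffusion $2k_BT/\gamma$ and the two springs loading
the bond in series at stiffness $\kappa/2$) agrees with simulation within
a few percent across pulling speeds.

**Toy protocol.** Tests and the acceptance run use a two-chain antiparallel
toy complex (30 beads, planted interface, shear-loading geometry) rather
than a full TCR/pMHC structure. For this miniature system the contact depth
is set to $\varepsilon = 6\,k_BT$ and speeds to 0.01–0.05 Å/τ: at the
1 $k_BT$ per-contact depth conventional for full-size structure-based
models, the eight-contact toy interface dissolves thermally and the trace
is drag-dominated, whereas at 6 $k_BT$ rupture is force-activated with
clean single peaks for every nested deletion construct. Nested deletions of
the planted interface then reproduce the qualitative simulation result:
weaker constructs rupture at lower force at every speed, dissociate faster
($k_{\mathrm{off}}\tau$ up), have shorter unbinding lengths ($x_\beta$
down), and the regression of $x_\beta$ on $\log_{10}(k_{\mathrm{off}}\tau)$
has a negative slope. Only these signs and orderings are asserted — the
quantitative slopes of full-size complexes are parameter-sensitive and out
of scope at desk scale. The Bell-Evans intercept extrapolation is noisy for
intermediate constructs at this scale, so directional per-deletion checks
compare the full construct against the most-deleted one.

## Mechanical proofreading

A bound TCR must traverse $N$ steps at rate $k_p$ before signalling:

$$C_N = \left(1 + k^m_{\mathrm{off}}(F)/k_p\right)^{-N} C_T, \qquad
C_T = \tfrac12\!\left(L_0 + R_0 + K - \sqrt{(L_0+R_0+K)^2 - 4L_0R_0}\right)$$

with $K = k^m_{\mathrm{off}}/k_{\mathrm{on}}$, and the force entering
through the empirical relation $x_\beta = -0.029\log_{10}(K_D) - 0.11$ nm.
Fixed constants follow the fitted cellular model: $N = 2.46$,
$k_p = 2.15$/s, $k_{\mathrm{on}} = 0.0447$ uM⁻¹s⁻¹, activation threshold
$C_N = 10^{-4}$.

Potency $P$ is the ligand concentration at which $C_N$ reaches the
threshold, solved by monotone bisection on $\log_{10} L_0$ over
$[10^{-8}, 10^6]$ uM (relative tolerance $10^{-6}$; an unreachable
threshold returns an infinite-potency flag). In the receptor-excess,
far-from-saturation regime this reduces to the closed form
$P = \lambda + N\log_{10}(1 + k^m_{\mathrm{off}}/k_p)$ (log₁₀ uM), which is
what `fit_potency()` fits to experimental potency-vs-affinity data — "log"
is log₁₀ and $\lambda$ is an additive offset to a log concentration, so
$R_0$ is irrelevant on the fitting path. Force is always fitted per
condition; $\lambda$ is shared (`global_lambda`) or per-condition
(`local_lambda`), and the nested models are compared with an F-test whose
type-I error calibrates to 0.05 under the null in simulation. Degrees of
freedom are data points minus free parameters. Points can be weighted by
their reported SEM (`weighted = TRUE`); the default is unweighted since the
original weighting is undocumented.

**Units caveat.** $K_D$ enters the relation's logarithm in uM, consistent
with $k_{\mathrm{on}}$ in uM⁻¹s⁻¹ and with this package's closed-form
examples. The intercept −0.11 makes the relation's zero crossing
unit-dependent: in uM units every ligand with $K_D \ge 1$ uM has
$x_\beta < 0$, so potency *decreases* with force there, while expressing
$K_D$ in M would flip that regime. Both conventions leave the acceptance
surface unchanged — discrimination power
$\alpha = \Delta\log_{10}P / \Delta\log_{10}k_{\mathrm{off}}$ (evaluated
between reference ligands with $k_{\mathrm{off}} = 0.5$ and $10^{1.5}$/s,
$\alpha \approx 1.51$ at zero force) is non-increasing in force under
either — but absolute potency-vs-force directions at intermediate
affinities depend on it. The relation's coefficients are plain parameters
of `kp_params()`, so users can supply either convention.

$F = 100$ pN sits in the flat region of the potency curve for realistic
affinity panels — exactly the model's point, that high force erases
affinity discrimination — so its fitted standard error is legitimately
large; recovery tests assert consistency in standard-error units, not
absolute precision.

## Binding affinity

Equilibrium responses follow the 1:1 Langmuir isotherm
$B = B_{\max}[{\rm TCR}]/(K_D + [{\rm TCR}])$, fitted with $B_{\max}$ free
or constrained through the antibody standard curve: the conformation-
sensitive W6/32 saturation response $R_{\max}$ (from the empirical
hyperbola $R = R_{\max}t/(K_t + t)$) is regressed against TCR $B_{\max}$
across reference surfaces — through the origin, since both count active
immobilized sites; an affine mode exists — using only surfaces whose own
titration saturated (top concentration ≥ 2.5 × fitted $K_D$). The reported
$K_D$ is the constrained one when it exceeds 20 uM and the free-fit one
otherwise (weak binders never saturate, so the free $B_{\max}$ is
unreliable exactly where the constraint helps). Dissociation traces are
fitted mono-exponentially, starting one sample after the window opens to
skip injection-stop artefacts, and $k_{\mathrm{on}} = k_{\mathrm{off}}/K_D$.
Double referencing is assumed done upstream; instrument-file parsing is
out of scope.

## Problem sizes and reproducibility

Every stochastic routine takes an explicit seed and is a pure function of
(parameters, seed). The shipped test suite uses the problem sizes the
methods were designed around: ~500 events/bin × 6 bins for pipeline
recovery, 100 seeded replicates for sign-level slope detection, 10
trajectories × 3 speeds × 3 constructs on the 30-bead toy complex for the
pulling protocol, 500 replicates for F-test calibration, and 30-digit
precomputed constants for all closed-form checks at $10^{-9}$ relative
tolerance.

## Known limitations

* Bell's single-exponential phenomenology only: no two-pathway or
  multi-barrier catch-bond models, and bonds that are not Bell-like are
  reported per-bin without a force fit.
* The hydrodynamic map uses the rigid-lever approximation: no bead
  Brownian motion, tether elasticity, or finite-element flow corrections.
* The coarse-grained model omits torsional and angle terms and leaves the
  Lennard-Jones width at its 12-6 default; the time unit is symbolic.
* Survival analysis truncates at 5 s, mirroring the collision-limited
  observation window, and treats frame-quantized durations as exact.
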