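---
title: "Host-aware modeling and in-silico optogenetic control of co-culture composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host-aware modeling and in-silico optogenetic control of co-culture composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optoculture)
```

This vignette explains the models implemented in `optoculture`, the
assumptions behind them, the parameters that matter (with units, defaults and
the reasoning that fixed them), what the synthetic-data generators emulate,
and the numerical and design choices a maintainer should know about. It
states no empirical result that the test suite or `scripts/acceptance.R` do
not themselves compute.

## 1. The host model: proteome partition and growth laws

The host is described by four coarse proteome sectors: house-keeping
$\Phi_Q = 1-\Phi_R^{max}$ (fixed), ribosomal $\Phi_R$, catabolic $\Phi_P$,
and a synthetic sector $\Phi_S$ occupied by circuit proteins. Two empirical
growth laws — $\lambda = \gamma(\Phi_R - \Phi_{R0})$ under translation
limitation and $\lambda = \nu(\Phi_R^{max} - \Phi_R)$ under nutrient
limitation — combine into the burden-dependent growth rate

$$\lambda(\Phi_S) = (\Phi_R^{max} - \Phi_{R0} - \Phi_S)\,
\frac{\gamma\,\nu}{\gamma + \nu}.$$

Defaults: $\Phi_R^{max} = 0.55$, $\Phi_{R0} = 0.066$,
$\gamma_0 = 5.9\ \mathrm{h}^{-1}$ — standard proteome-partition constants for
*E. coli* in common growth conditions; all overridable through the `host`
config section. Nutrient quality $\nu$ is not a free parameter: it is
calibrated analytically (`calibrate_nu()`) so that the antibiotic-free growth
rate matches observation (default target $2.0\ \mathrm{h}^{-1}$, fast growth
in rich medium; with the shipped strain defaults this yields
$\nu \approx 13.8\ \mathrm{h}^{-1}$).

**Units.** Time is in hours, light in LED digital levels (0–800 arb units),
and concentrations in µM throughout. Protein concentrations convert to
proteome fractions through $\Phi_S = \sum_i n_i X_i/\rho_{cell}$ with
$\rho_{cell} = 3\times 10^6$ µM of protein-bound amino acids (≈ 2.7 M, the
standard cytoplasmic protein density). Keeping µM rather than normalizing
$\rho_{cell}$ to one keeps the enzymatic constants of CAT
($k_{cat} = 3.6\times10^5\ \mathrm{h}^{-1} = 100\ \mathrm{s}^{-1}$,
$K_M = 12$ µM) and the chloramphenicol concentrations on their literature
scales — with a normalized density, the CAT concentration needed to detoxify
the medium would correspond to an impossible proteome fraction.

**Quasi-steady growth.** $\lambda$ is an algebraic function of the current
state, evaluated at every derivative call: growth-rate adaptation is assumed
fast relative to circuit protein dynamics. This is the framework's central
approximation; it is supported by the absence of a delay between resistance
levels and growth in the system being modeled, but it is an extrapolation of
equilibrium growth laws to transients and will misrepresent circuits whose
dynamics are faster than physiological adaptation (minutes).

## 2. Generic host-aware circuits

`gene_spec()`/`circuit_model()`/`assemble_system()` embed an arbitrary
circuit: for each gene, mRNA follows
$\dot m_i = \omega_i T_i(\cdot)\frac{\lambda}{\nu} + F_i(\cdot) - \delta_i m_i$
(no growth dilution — active degradation dominates mRNA turnover) and protein
follows $\dot X_i = \alpha_i m_i \lambda + G_i(\cdot) - \lambda X_i$. The
$\lambda/\nu$ factor on transcription applies only to host-transcribed genes;
a T7-driven gene sets `host_transcription = FALSE`. Protein-level
(mRNA-lumped) species and auxiliary states (e.g. intracellular antibiotic)
carry user rate contracts, so any future exact formulation drops in without
touching the machinery. A `frozen_lambda` mode reduces everything to a
conventional constant-dilution model (used as an analytic oracle in the
tests).

**Integration.** No stiff-ODE package is assumed: the package ships an
adaptive Dormand–Prince 5(4) integrator with cubic-Hermite dense output —
pure R for generic circuits, and an identical algorithm compiled via Rcpp
for the concrete strain system (the gain screen and least-squares fitting
need thousands of simulations). The two routes are cross-checked against
each other to $10^{-6}$ in the suite. Light programs are piecewise constant
and integration restarts at each discontinuity. Default tolerances:
`rtol = 1e-7`, `atol = 1e-10`; states are clipped at zero only for
excursions below $10^{-9}$–$10^{-6}$ scale, larger negativity is an error.

## 3. The photophilic strain

States (µM): T7 monomer $D$, active homodimer $A$, CAT $C$, intracellular
chloramphenicol $c_{in}$.

$$\begin{aligned}
\dot D &= \beta_{T7}\lambda^2/\nu - 2k_a(L)D^2 + 2k_{off}A - \lambda D\\
\dot A &= k_a(L)D^2 - k_{off}A - \lambda A\\
\dot C &= \beta_{CAT}A\lambda - \lambda C\\
\dot c_{in} &= k_{perm}(c_{ext} - c_{in}) - k_{cat}C\,\frac{c_{in}}{K_M + c_{in}} - \lambda c_{in}
\end{aligned}$$

with $k_a(L) = k_{a,dark} + k_{a,light}\,L/(K_L+L)$,
$\gamma = \gamma_0/(1 + c_{in}/I_{50})$, and
$\Phi_S = (n_{T7}(D + 2A) + n_{CAT}C)/\rho_{cell}$. The $\lambda^2/\nu$
monomer production lumps host transcription ($\lambda/\nu$) and translation
($\lambda$) with mRNA at quasi-steady state; CAT transcription is
T7-orthogonal, so its production carries only the translation factor; CAT is
untagged and removed by dilution only.

**Calibration instead of a fitted table.** The quantitative anchors are the
printed steady-state growth rates at the working 3.4 µg/mL (= 10.5 µM)
chloramphenicol: $\approx 1.0\ \mathrm{h}^{-1}$ dark,
$\approx 1.9\ \mathrm{h}^{-1}$ at 800 arb units, and
$2.0\ \mathrm{h}^{-1}$ antibiotic-free. `calibrate_endpoints()` fixes
$\nu$, $k_{a,dark}$ and $k_{a,light}$ by nested 1-D root finding on the
algebraic steady state (a single root in $\lambda$; all other species follow
in closed form), achieving the endpoints to much better than the contracted
1%.

**Choice of $I_{50}$ (6.5 µM).** With the inhibition constant far below the
working concentration (e.g. 1 µM), the calibrated dark state ends up deep in
the enzyme-dominated regime where a positive feedback loop — more CAT, faster
growth, more expression, more CAT — has a gain close to one; relaxation
towards the dark steady state then acquires an hours-long tail (settling
times beyond 20 h) and the sampled feedback loop cannot regulate the
composition. At $I_{50} = 6.5$ µM the dark growth rate is instead nearly the
permeation-limited floor: residual CAT barely matters in the dark, so a
downshift is governed by dilution of the enzyme — which is exactly the
mechanism the measured asymmetric transients point to (fast ≈ 2 h upshifts
set by gene expression, slower ≈ 4 h downshifts set by dilution). This value
was fixed once, from that structural argument, before the test suite was
frozen; the acceptance suite then checks that the calibrated model settles in
1–3 h after an upshift and 3–5 h after a downshift.

Remaining defaults ($k_{off} = 6\ \mathrm{h}^{-1}$, $K_L = 200$ au,
$k_{perm} = 20\ \mathrm{h}^{-1}$, $\beta_{T7} = 10$ µM/h,
$\beta_{CAT} = 10$, $n_{T7} = 883$ aa, $n_{CAT} = 450$ aa for the
CAT–mCherry fusion, fluorescence scale $10^5$ au/µM) are literature-scale
placeholders whose absolute values the calibration absorbs; the expression
scales are deliberately not fitted (see §6).

## 4. Co-culture dynamics and the constitutive partner

The photophilic fraction obeys
$\dot\varphi_p = (\lambda_p(L(t)) - \lambda_c)(1-\varphi_p)\varphi_p$, with
$\lambda_p(t)$ supplied by the full strain model (the strain's internal
state is shared culture-wide — the derivation treats $\lambda_p$ as a single
time function, excluding per-lineage heterogeneity). Fixed points 0 and 1
exchange stability with the sign of $\lambda_p - \lambda_c$; under constant
rates the solution is logistic, which serves as the oracle for the numerical
path.

$\lambda_c$ defaults to $1.5\ \mathrm{h}^{-1}$. It must lie strictly inside
the controllable range $[1.0, 1.9]$; it is set *above* the midpoint so that
the growth-rate gap is larger in the dark than under full light, making dark
convergence the faster direction — the behavior observed in the modeled
system. (At exactly the midpoint, 1.45, both directions would be equally
fast.) Closed-loop comparisons against the printed tracking experiments are
run at 1.45, passed explicitly.

## 5. Feedback control

`pid_step()` implements a discrete PID with actuator saturation (0–800 arb
units) and back-calculation anti-windup, sampled every 0.5 h (zero-order
hold between samples). Default gains $K_p = 5.9055\times10^3$,
$K_i = 3.0382$, $K_d = 2.3427\times10^5$, $K_{bc} = 0.01K_i$.

Two implementation decisions matter:

* **Time base.** The gain triple is only dimensionally coherent in seconds:
  $K_d/K_p \approx 40$ s of derivative time and $K_p/K_i \approx 1943$ s
  (≈ the 30-min sampling period) of integral time. `pid_step()` therefore
  converts the sampling interval to seconds internally. On an hour base the
  same numbers would imply a 40 h derivative time whose sample-to-sample
  spikes saturate the actuator permanently.
* **Implicit anti-windup.** With $K_{bc}K_i\Delta t_s \approx 166 \gg 1$,
  the explicit-Euler update
  $I \mathrel{+}= e\,\Delta t + K_{bc}(u - u_{raw})\Delta t$ is numerically
  unstable (the correction overshoots by two orders of magnitude each
  sample). The package uses the backward-Euler solution of the same tracking
  law, which is unconditionally stable, reduces to the explicit form for
  small $K_{bc}K_i\Delta t$, and at these gains effectively re-seats the
  integrator on the saturation boundary — the standard "tracking integrator"
  regime. When unsaturated the integrator is the plain error integral.

The derivative acts on the error by default (the setpoint program is
piecewise constant); a derivative-on-measurement flag avoids the kick at
setpoint steps if wanted. The first sample uses a zero derivative.

The sampled loop does not settle exactly on the setpoint: the asymmetric
plant (fast up, slow down) biases the residual limit cycle slightly high, by
≈ 0.02–0.03 at 30-min sampling. Halving the sampling period halves the
oscillation amplitude and the bias — the suite asserts both, and asserts
mean tracking within the contracted 0.03.

## 6. Gain screen and model fitting

**Screen.** `run_screen()` draws gain sets log-uniformly ($K_p \in
[10^2,10^5]$, $K_i \in [10^{-1},10^2]$, $K_d \in [10^3,10^6]$, $K_{bc} =
0.01K_i$; ~1.5 decades around the adopted optimum), simulates the closed loop
for setpoints 0.3 and 0.7 over 16 h, and scores each trajectory by
$\int |\varphi - \varphi^{set}|\,dt$ against the ideal instantaneous step —
penalizing transient duration, overshoot and residual oscillation together.
Failures score `Inf`; the screen never aborts. Sample count defaults to 200
at desk scale. The suite checks the adopted gains land in the top quartile
of a 200-sample screen.

**Fitting.** `fit_photophilic()` runs weighted bound-constrained least
squares on growth + fluorescence time courses of three-phase shift
experiments (pre-culture at ambient light $L_0$ to equilibrium; 6 h at a
first intensity; a second intensity to the horizon), in log-parameter space
with multi-start (5 perturbed starts) via `optim(L-BFGS-B)`. Channels are
weighted by their per-channel standard deviations to mix h⁻¹ and arbitrary
fluorescence units. $L_0$ is estimated first by inverting the monotone dose
response at the initial growth rate and held fixed; because that inversion
uses the current model, it is re-estimated once from the fitted model and
the fit repeated — without this second round, a poor starting parameter set
visibly biases $L_0$ and the shape parameters absorb the error.

**Identifiability.** Bulk growth and fluorescence pin the CAT concentration
absolutely (through the detoxification flux and the fluorescence readout)
but only the *products* $\beta_{CAT}k_a\beta_{T7}^2$ — the monomer and dimer
expression scales form a sloppy subspace because their proteome burden is
negligible at these expression levels. In the permeation-limited dark regime
$k_{a,dark}$ also has almost no observable effect. The default free set is
therefore the identifiable $\{k_{a,light}, K_L, I_{50},
\text{fluor\_scale}\}$; freeing the expression scales is possible but
recovery is then undefined along the sloppy directions. The suite verifies
recovery of the identifiable set within 20% across 5 noise seeds.

## 7. The virtual culturing platform

`simulate_turbidostat()` grows OD exponentially at the supplied (possibly
time-varying) rate and dilutes instantaneously from 0.15 back to 0.10 —
pump dynamics are hardware detail; the instantaneous reset preserves the
sawtooth from which `estimate_growth_rate()` recovers the rate as the
least-squares slope of log OD (exact on noise-free data; a segment spanning
a dilution is an error). OD readings default to a 0.05 h cadence with 1%
multiplicative noise — plausible sensor behavior, not a measured value.

`cytometry_sample()` draws per-event GFP intensities from log-normal
positive/negative populations (medians $2\times10^4$ and $2\times10^3$ au,
geometric SD 1.8) and gates at the fixed 6500 au threshold. Only the
threshold is anchored; the distributions are synthetic and deliberately
overlap (~2% misclassification each way), so the fraction estimate carries a
small systematic bias in addition to binomial noise — as a real fixed-gate
readout does. Debris/doublet gating is not simulated because the generator
produces only single-cell events.

**What a green test does not establish.** The generators emulate the
platform's sampling structure and noise, not its failure modes: no biofilm
drift of the OD sensor, no oxygen limitation, no escape mutations (which in
long real experiments erode controllability after ~80 generations), no
cytometer carry-over. Conclusions about robustness to those phenomena cannot
be drawn from these simulations.

## 8. Numerical choices and degenerate inputs

* Steady states: algebraic 1-D root finding for the concrete strain
  (tolerance $10^{-13}$ on $\lambda$); long integration with equilibrium
  detection plus damped-Newton polish for generic circuits (derivative norm
  $< 10^{-8}$, time cap 2000 h).
* Infeasible burden ($\Phi_S > \Phi_R^{max} - \Phi_{R0}$) raises a typed
  error everywhere rather than clamping — a state that would imply negative
  growth is a modeling error the user must see.
* $\nu = 0$ (no nutrient) gives $\lambda = 0$ exactly; $c_{ext} = 0$ short
  circuits the intracellular-antibiotic root to 0.
* Ties/edges: light programs are right-continuous (the level at a breakpoint
  is the new level); the settling-time scan returns `NA` if the trajectory
  never stays in the band.
* All stochastic operations take explicit seeds and restore the caller's
  RNG state; a closed-loop run with a fixed seed is bit-reproducible.

## 9. Known limitations

* Growth-law extrapolation to transients (§1) is the dominant structural
  assumption.
* The split-T7 is modeled as a homodimer; true heterodimer stoichiometry
  would halve the effective production exponent on $\lambda$.
* Protein-level lumping hides mRNA dynamics (minutes); the ≈ 1 h response
  delay seen in step experiments is therefore only partially reproduced.
* The constitutive strain is a single constant rate — no burden or antibiotic
  coupling of its own.
* Fluorescence maturation of the mCherry reporter is not modeled; the
  fluorescence channel is proportional to enzymatically active CAT.
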