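---
title: "Models and methods: self-association, DNA binding and degradation kinetics from NMR observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrbind)
```

# Scope

`nmrbind` infers equilibrium and kinetic constants for small aromatic drugs
(camptothecin-family scaffolds are the motivating case) from four solution-NMR
observables:

1. **Dilution chemical shifts** — indefinite self-association (stacking) by the
   isodesmic model;
2. **Titration chemical shifts** — 1:1 binding to a short DNA duplex;
3. **Diffusion coefficients (DOSY)** — the same 1:1 binding constant by a
   closed-form population argument;
4. **Intact-fraction time courses** — first-order degradation and half-life.

Each analysis has a seeded synthetic-data generator built on the identical
forward model, so every fitting routine is validated by parameter recovery.

# The isodesmic self-association model

A ligand L that stacks indefinitely with a single step constant
$K_a$ (mM$^{-1}$),

$$L_n + L \rightleftharpoons L_{n+1}, \qquad
  K_a = \frac{[L_{n+1}]}{[L_n][L]} \;\; \text{for all } n,$$

has stack populations $[L_n] = K_a^{\,n-1} [L]^n$ and the mass balance
$L_0 = [L]/(1-K_a[L])^2$, whose physical inverse is the closed form

$$[L] \;=\; L_0 \left(\frac{2}{1+\sqrt{1+4K_aL_0}}\right)^{2}.$$

Under fast exchange the observed shift of each proton is a population-weighted
average; the shift change relative to the monomer obeys

$$\Delta\delta_{obs} \;=\; \delta_{mon}-\delta_{obs}
  \;=\; \Delta\delta_{max}\, K_a L_0
  \left(\frac{2}{1+\sqrt{1+4K_aL_0}}\right)^{2},$$

which equals $\Delta\delta_{max}\cdot K_a[L]$ — the fraction of stacked
nearest-neighbour contacts.  The printed form of this equation in the source
literature is typographically corrupted; the reconstruction above is pinned
down by its two required limits ($\to 0$ as $L_0 \to 0$;
$\to \Delta\delta_{max}$ as $K_aL_0 \to \infty$) and by the $K_a[L]$ identity,
both of which are property-tested.

**Sign convention.** $\Delta\delta_{obs} = \delta_{mon}-\delta_{obs}$, so
protons that move upfield (to low frequency) on stacking have positive
$\Delta\delta_{max}$.  Protons that shift the other way are handled by letting
$\Delta\delta_{max}$ be negative rather than by exclusion — real stacking
systems typically show one such proton at a ring-current edge.

**Fitting.** `fit_isodesmic()` runs unweighted nonlinear least squares per
proton over $(K_a, \delta_{mon}, \Delta\delta_{max})$ with
`minpack.lm::nlsLM`, $K_a$ bounded to $[0, 10^3]$ mM$^{-1}$ (start 1),
$\delta_{mon}$ started at the lowest-concentration shift (the 0.003 mM end is
near, but not at, infinite dilution, so $\delta_{mon}$ stays free), and
$\Delta\delta_{max}$ started at the observed range.  Up to four jittered
starts guard against local minima; persistent non-convergence is an error
naming the proton.  The pooled constant is, by default, the arithmetic
**mean ± SD of the independent per-proton fits** — the convention used when a
single "average" constant is quoted for a compound.  A `mode = "global"`
shared-$K_a$ fit (per-proton shift parameters, one constant) is available as
an alternative; its SD slot then carries the asymptotic standard error.
Protons whose observed shift range is below $3\times$ the noise floor
(default 0.002 ppm) carry no isotherm and are excluded from the pooled mean,
mirroring the practice of using only clean, responsive signals.

# 1:1 binding from shift titration

For $DNA + L \rightleftharpoons DNA\!\cdot\!L$ with totals $C_{DNA}$ (duplexes,
not strands) and $C_L$, the free duplex is the positive root of

$$K_a[DNA]^2 + (1 + K_aC_L - K_aC_{DNA})[DNA] - C_{DNA} = 0,$$

computed on the numerically stable branch of the quadratic formula.  The
fast-exchange shift change of a ligand proton is

$$\Delta\delta \;=\; \delta_{obs}-\delta_L \;=\;
  \Delta\delta_{DNA\cdot L}\,\frac{K_a[DNA]}{1+K_a[DNA]}.$$

Published isotherm fits differ in whether $[DNA]$ means the *equilibrium free*
duplex or the *total* titrant.  Both are exposed:
`dna_mode = "free_exact"` (default; the equilibrium definition is the one the
mass-action model actually implies) and `"total_approx"` (the common shortcut,
adequate under large duplex excess and mild saturation — note the two agree to
1 % only comfortably inside that regime, not on its edge).  Stoichiometry is
fixed at 1:1; treating the two equivalent G-C duplex ends as separate sites is
out of scope, and users who prefer that convention can double the duplex
concentration column.

$\delta_L$ defaults to the shift measured at $C_{DNA}=0$ at the experiment's
ligand concentration.  Because the ligand also self-stacks, withdrawing
monomer into the DNA complex lets the residual free ligand de-stack, so
$\delta_L$ drifts over the titration for protons dominated by
self-association.  `baseline_mode = "self_assoc"` re-evaluates
$\delta_L$ from the isodesmic model at the residual free-ligand concentration
$C_L - [DNA\!\cdot\!L]$ inside the optimiser; a paired simulator option
generates data with exactly this confound, and the test suite shows the fixed
baseline is then biased while the correction recovers the truth.

Saturation below 20 % across the whole titration triggers a
"Ka poorly constrained" warning; pooling and exclusion follow the isodesmic
conventions.

# Binding from diffusion averaging

Under fast exchange the observed diffusion coefficient of the ligand in a
mixture is the population-weighted average
$D_{obs,L} = MF_L D_L + (1-MF_L) D_{DNA\cdot L}$, so

$$MF_L = \frac{D_{obs,L} - D_{DNA\cdot L}}{D_L - D_{DNA\cdot L}},\qquad
  [DNA\!\cdot\!L] = (1-MF_L)\,C_L,\qquad
  K_a = \frac{[DNA\!\cdot\!L]}{(C_{DNA}-[DNA\!\cdot\!L])(C_L-[DNA\!\cdot\!L])}.$$

The complex is assumed to diffuse like the duplex
($D_{DNA\cdot L} \simeq D_{obs,DNA}$), justified because an 8-mer duplex is
much larger than the ligand; the flag recording this assumption travels with
every result row.  `ka_from_diffusion()` is the exact algebraic inverse of
`predict_observed_diffusion()` — a round-trip identity the suite checks to
$10^{-8}$ relative over a random parameter grid, and the module's primary
oracle.  Because the ligand self-associates, $D_L$ depends on its own
concentration, so each record carries `D_L_free` measured at matched free
ligand concentration instead of assuming a constant.

Numerical guards: mole fractions outside $[0,1]$ by up to 0.02 (absolute) are
clipped with a warning — ordinary measurement noise; larger excursions are an
error, as is a complex concentration that exhausts either total ("saturated —
Ka unbounded") and a free/complex diffusion contrast too small to divide by.
`dosy_mc_error()` propagates relative Gaussian noise on all measured
coefficients by Monte Carlo, since the point estimate alone hides the
sensitivity of the simplification above.

# Degradation kinetics

The degradation route (retro-Mannich elimination of the C9 substituent,
pseudo-unimolecular in water) motivates a first-order default,

$$f(t) = A_0 e^{-kt}, \qquad t_{1/2} = \ln 2 / k,$$

with the amplitude either pinned to 1 (`"fixed_1"`, after normalising the
series to its first point so NMR integral ratios and HPLC area fractions enter
on any scale) or fitted (`"fitted_A0"`).  The kinetic order is not
experimentally established over long times; a zero-order option
(`order = 0`, $t_{1/2} = A_0/2k$) is provided for sensitivity analysis.  A
log-linear regression of $\log f$ on $t$ serves as an internal oracle in the
tests.  Constant series abort ("no decay detectable"); a negative fitted rate
is clipped to zero with a warning.

# The synthetic-data generators

The generators exist so that every fit is testable by parameter recovery
without any deposited raw spectra.  They emulate the study designs:

* **Dilution**: 12 log-spaced concentrations from 0.003 to 1.2 mM — the span
  over which a millimolar-$K_a$ stacking isotherm is actually resolved —
  6 protons, Gaussian shift noise $\sigma = 0.002$ ppm (a typical
  shift-reading error at 500 MHz).
* **Titration**: fixed $C_L$ (default 0.3 mM), duplex stepped
  $0 \to 3C_L$ in 8 points (reaching the 1:3 ligand:duplex ratio at which the
  two binding routes are compared), $\sigma = 0.003$ ppm.
* **Diffusion**: free coefficients $4.0\times10^{-10}$ m$^2$s$^{-1}$ (ligand)
  and $1.3\times10^{-10}$ m$^2$s$^{-1}$ (8-mer duplex), typical of the two
  species in water near ambient temperature; optional relative noise
  (default 2 % when used).
* **Decay**: $t_{1/2} = 50$ days, 11 points over 0–100 days,
  $\sigma = 0.02$ on the fraction, truncated to $[0,1]$ (unphysical values
  are never reported by an integrator; the truncation's small boundary bias
  is documented and tested).

The default proton panels carry heterogeneous limiting shifts
(0.06–0.4 ppm in magnitude) with one sign-reversed proton each, matching the
qualitative pattern of ring A/B/C protons responding strongly and ring E
protons weakly, plus the occasional reversed proton.  Weak-response protons
dominate the sampling spread of the pooled mean — deliberately so, since real
panels have them.

Noise is additive Gaussian on the observable (ppm for shifts, relative for
diffusion, absolute for fractions) — the simplest model consistent with how
those quantities are read off spectra.  What the generators do **not**
emulate: peak overlap and mis-assignment, baseline and referencing drift,
temperature gradients, convection artefacts in diffusion, slow-exchange line
shapes, and any systematic deviation from 1:1 or isodesmic behaviour.
Passing recovery tests therefore demonstrate correctness of the inference
given the model, not the adequacy of the model for any particular real
sample.

# Numerical and design choices

* Closed forms are preferred to iterative root-finding everywhere they exist
  (monomer concentration, free duplex, diffusion inversion); the test suite
  cross-checks each against an independent `uniroot` oracle at $10^{-10}$
  relative tolerance.
* All concentrations are mM and constants mM$^{-1}$; shifts ppm; diffusion
  m$^2$s$^{-1}$; times days.  Conversion of shifts to Hz would need the
  spectrometer frequency (499.8 MHz for the motivating instrument) and is
  deliberately not baked in.
* Least squares is unweighted by default (no per-point uncertainties are
  normally recorded for shift readings); `fit_isodesmic()` accepts optional
  weights.
* Monte-Carlo study sizes in the test suite (200 replicates for the bias
  checks, 400 draws for the diffusion error propagation) were chosen so the
  Monte-Carlo error is comfortably below the tested tolerances while the
  whole suite stays fast.
* `run_study()` derives per-stage seeds deterministically from one base seed,
  so a study is reproducible bit-for-bit from its manifest.

# Limitations

* Only 1:1 (binding) and isodesmic (stacking) models are implemented; no
  dimerisation-only, cooperative, or multi-site variants.
* The diffusion route inherits the $D_{DNA\cdot L} \simeq D_{obs,DNA}$
  simplification; for a ligand comparable in size to its host it would break
  down.
* Kinetics assumes a single decaying species with no product interference in
  the monitored signal.
* Raw spectra (peak picking, referencing, gradient-attenuation fitting) are
  upstream of this package: inputs are already-reduced tables.
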