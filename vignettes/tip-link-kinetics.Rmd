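---
title: "Kinetic models and analysis methods for the tip-link connection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic models and analysis methods for the tip-link connection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiplink)
```

## The system and the models

The tip link of the inner-ear hair cell is a double-stranded filament: two
PCDH15 molecules bound to two CDH23 molecules, transmitting the force that
gates mechanotransduction channels.  `tiplink` implements the kinetic
machinery needed to analyse its strength from single-molecule pulling
experiments and to predict its lifetime under physiological stimulation.

### The single bond

Each PCDH15--CDH23 bond is a slip bond: its off-rate grows exponentially
with applied force,

$$k_{\mathrm{off}}(F) = k_{\mathrm{off}}^0\, e^{F/f_\beta},$$

where $f_\beta = k_BT/x_{\mathrm{ts}}$ is the force that accelerates
unbinding $e$-fold and $x_{\mathrm{ts}}$ the distance to the unbinding
transition state.  Under a force ramp $F = l_r t$ the most-probable rupture
force follows the Evans--Ritchie relation
$f^* = f_\beta \ln\!\big(l_r/(f_\beta k_{\mathrm{off}}^0)\big)$, which is
linear in $\ln l_r$ — the basis of the weighted Bell--Evans fit in
`fit_bell_evans()`.  Negative predictions at very slow loading are returned
unclamped so the relation stays exact; callers needing a physical force
clamp at zero.

### The double-stranded connection

The connection is modelled as a three-state chain
$B_2 \leftrightarrow B_1 \rightarrow U$: doubly bound, singly bound,
unbound.  With the load shared equally in $B_2$, the transitions are

* $B_2 \to B_1$ at $2k_2$, $k_2 = k_{\mathrm{off}}^0 e^{F/2f_\beta}$
  (each bond carries $F/2$),
* $B_1 \to U$ at $k_1 = k_{\mathrm{off}}^0 e^{F/f_\beta}$,
* $B_1 \to B_2$ (rebinding) at $C_{\mathrm{eff}}(F)\,k_{\mathrm{on}}$.

Rebinding is controlled by the effective concentration of the transiently
free binding domains.  Because the strands are elastic, the free ends
separate as tension on the loaded strand grows, and

$$C_{\mathrm{eff}}(F) = C_{\mathrm{eff}}^0\, e^{-(F/f_c)^2},
\qquad f_c = \sqrt{2\kappa k_BT},$$

with $\kappa$ the strand stiffness.  `rupture_density()` integrates this
chain under linear loading and returns the rupture density
$k_1(t)B_1(t)$, whose maximum times $l_r$ is the predicted most-probable
rupture force; `dimer_mean_lifetime()` gives the constant-force mean
first-passage time in closed form,

$$\tau(F) = \frac{k_1 + C_{\mathrm{eff}}(F)k_{\mathrm{on}} + 2k_2}{2k_1k_2},$$

derived from the standard first-step recursion for the chain and
cross-validated in the test suite against an independent Gillespie
first-passage simulation (`gillespie_lifetimes()`), at ten random parameter
sets and forces, to within three standard errors.

For a connection with two different bond types (one strand carrying a
mutation), the chain has two singly-bound states and
`hetero_rupture_density()` integrates the four-state analogue with
per-type off-rates $k_{ij} = k_{\mathrm{off}[j]}e^{F/i f_{\beta j}}$.  The
doubly-bound state loses probability at $k_{21}+k_{22}$, matching the gain
terms of the singly-bound states so probability is conserved and the model
collapses exactly onto the three-state chain when the two types are
identical — a degeneracy the tests check to $10^{-6}$ relative in mode
force.

### What the parameters mean

| Parameter | Meaning | Wild-type value used in examples |
|---|---|---|
| $k_{\mathrm{off}}^0$ | zero-force single-bond off-rate | 0.5 s$^{-1}$ |
| $f_\beta$ | force scale of unbinding | 13.5 pN |
| $k_{\mathrm{on}}$ | solution on-rate | $6.2\times10^4$ M$^{-1}$s$^{-1}$ |
| $C_{\mathrm{eff}}^0$ | zero-force effective concentration | 465 µM |
| $f_c$ | compliance force scale of $C_{\mathrm{eff}}$ | 10 pN |

Thermal energy is fixed package-wide at `kT` = 4.114 pN nm (298 K).  Units
are pN, nm, s and M throughout; conversions (e.g. µM in config files,
mN/m for the gating spring) happen only at I/O boundaries.

## Numerical choices

Two integration paths coexist deliberately.  The reference path
(`engine = "lsoda"`) uses a stiff-capable solver at `rtol = 1e-8`,
`atol = 1e-12`, on a uniform grid extended to ten times the mode-time
estimate; beyond the point where survival has fallen below $10^{-7}$ the
states are set to zero exactly, since the off-rates grow without bound
there while carrying no probability.  The fast path (`engine = "rk"`, used
inside fitting via `predict_mode_force()`) integrates the homogeneous
chain with a rate-adaptive fourth-order step and the heterogeneous chain
with the L-stable TR-BDF2 scheme — necessary because once only the strong
bond survives, the weak bond's off-rate can exceed the dynamics' time
scales by many orders of magnitude, and explicit stepping would need
billions of steps.  The two paths agree to $10^{-4}$ relative in mode
force in the tests.  For the heterogeneous reference path the density is
computed as $-\mathrm{d}S/\mathrm{d}t$ by central differences rather than
as the unbinding flux, because the flux form multiplies the solver's
absolute error by the (arbitrarily large) weak-bond off-rate.

Mode finding uses a coarse grid argmax followed by local parabolic
refinement; the density is smooth and unimodal for slip bonds.  (In the
degenerate limit $f_{\beta,2}\to 0^+$ a finite-height, vanishing-mass
spike appears at the low-force boundary; the tests characterize it
explicitly.)

Chi-square fitting follows the derivative-free simplex approach: free
parameters are log-transformed (enforcing positivity), minimization is
restarted from jittered starts and flagged if the restarts disagree, and
the forward model inside the fit uses the fast integration path with the
final chi-square re-evaluated at tighter stepping.  Parameter errors come
from the local curvature of the chi-square surface,
$\sigma_i^2 = 2(\partial^2\chi^2/\partial x_i^2)^{-1}$, by central second
differences at four step sizes with a Richardson consistency check.  Note
this is a *per-parameter* (conditional) error: it ignores correlations
between parameters, which is the convention the curvature formula
implies; the tests verify it against $1/\sqrt{[X^TWX]_{ii}}$ for the
linear model.  Directions with non-positive curvature are flagged
unconstrained rather than assigned a number.  For the truncated-construct
use case, where rebinding may be undetectable, `fit_avidity()` always
reports $\Delta\chi^2$ against the no-rebinding variant so that a fitted
$C_{\mathrm{eff}}^0$ is never interpreted when the data cannot
distinguish rebinding from none.

## Rupture-force statistics

`estimate_mode_kde()` estimates the most-probable rupture force as the
argmax of a Gaussian kernel density with Silverman's rule-of-thumb
bandwidth, and reports the bandwidth as the point's error — the
convention used for all dynamic-force-spectrum fitting weights
($1/\mathrm{error}^2$).  These rupture-force densities have broad, nearly
flat tops, so the mode estimator's replicate-to-replicate scatter is
comparable to the bandwidth itself; propagated through the weighted fit
this makes the fitted-parameter errors an honest description of the
scatter one sees across synthetic replicates (about $\pm 2$ pN on
$f_\beta$ under the wild-type single-bond conditions).

`extract_loading_rate()` takes the slope of the final near-linear window
of the force ramp.  The window is grown backwards from the last quarter of
the ramp while the linear fit shows no lack of fit — residual SD within
25% of the per-trace noise SD estimated robustly from first differences.
An $R^2$ threshold was deliberately not used: $R^2$ measures the residual
against the window's signal variance, so on clean traces it accepts the
whole curved ramp (biasing the slope far low) while on realistically
noisy traces it rejects every window.

`fit_wlc()` fits the extensible Marko--Siggia interpolation
$F = (k_BT/L_p)\left[\tfrac{1}{4(1-l)^2} - \tfrac14 + l\right]$ with
$l = x/L_c - F/K$, solved by safeguarded Newton iteration; rupture is
detected as a force drop exceeding five noise SDs within three samples.
`filter_single_tethers()` applies the standard contour/persistence-length
gates that reject double tethers (half contour length) and nonspecific
attachments.  `fd_histogram()` implements Freedman--Diaconis binning with
the bin origin scanned over at least 20 offsets within one bin width,
keeping the offset that maximizes the modal-bin count (ties to the
smaller offset).

## Biolayer interferometry

Sensorgrams are double-referenced ((experimental − drift) − (binding
control − its drift)) and smoothed with a Savitzky--Golay filter (window
25 samples, order 3 — checked on the synthetic suite to bias the fitted
lifetime by under 1%).  Dissociation is fitted as
$A e^{-t/\tau} + c_0$ and association as $A(1 - e^{-k_{\mathrm{obs}}t}) + c_0$;
the offsets absorb residual baselines that survive referencing.  The
effective on-rate is $(k_{\mathrm{obs}} - 1/\tau)/C$ when the lifetime is
known, otherwise $k_{\mathrm{obs}}/C$ flagged as uncorrected.  Inverting
the zero-force lifetime formula
(`invert_lifetime_to_ceff()`) turns a measured lifetime into an empirical
effective concentration; with the printed $k_{\mathrm{off}}^0 = 0.5$
s$^{-1}$ and $k_{\mathrm{on}} = 6.2\times10^4$ M$^{-1}$s$^{-1}$, a 63.3-s
lifetime gives $\approx 486$ µM, whereas the source study reports
$650 \pm 200$ µM from unrounded fit inputs — both are documented and the
inversion is not forced to agree.

## The hair-bundle Monte Carlo

`simulate_tip_link_lifetime()` drives the three-state chain with the
instantaneous tension of a sinusoidally deflected hair bundle,

$$F_t = \max\{0,\; F_{\mathrm{rest}} + \gamma k_g (x - x_a)\},$$

with gating-spring stiffness $k_g = 0.6$ mN m$^{-1}$, geometric factor
$\gamma = 0.12$ and resting tension 10 pN; the gating spring cannot push,
so tension clamps at zero.  Deflection is displacement-controlled (the
stiff-probe limit); a compliant-probe mode is an extension hook, not a
default.  Channel gating itself is not coupled into $F_t$: the force
model is the linear gating-spring expression above.  Each fixed time step
evaluates the rates at $F_t$ and draws transitions with probability
$1 - e^{-r\,\delta t}$ (linearized below $10^{-3}$).  The step is chosen
so that $\max(r)\,\delta t < 0.01$ and at least 20 steps resolve each
stimulus cycle; an unsatisfiable constraint (below 1 ns) is refused with
a diagnostic.  Runs are capped at ten times the zero-amplitude mean
lifetime; capped runs are flagged, counted and excluded from means.

Slow adaptation moves the motor position $x_a$: climbing at 1.6 µm
s$^{-1}$ (tension-increasing) and slipping at a rate proportional to
tension.  The printed slip law ("slip rate 0.01 s$^{-1}$ with slip
distance proportional to force") underdetermines units, so the slip
coefficient is calibrated so the zero-stimulus fixed point reproduces the
10 pN resting tension exactly: $c_{\mathrm{slip}} =
v_{\mathrm{climb}}/F_{\mathrm{rest}} = 160$ nm s$^{-1}$ pN$^{-1}$,
giving a motor time constant $1/(c_{\mathrm{slip}}\gamma k_g) \approx 87$
ms — in the tens-of-milliseconds range expected for slow adaptation.
When adaptation is enabled the motor is first burned in deterministically
for ten time constants: phase-randomized stimuli describe connections
that form during *ongoing* stimulation, so the motor starts from its
stimulus-adapted steady state rather than from rest, and stimulus-onset
transients are deliberately not part of the measured lifetime.

## The synthetic-data generator

All pipeline inputs are generated, never downloaded.  Rupture forces are
sampled from the kinetic models themselves: exactly (closed-form
inverse CDF) for the single bond, and by inverse-CDF lookup on the
integrated survival curve for the multi-state models, cross-validated
against a per-step stochastic chain sampler (two-sample KS test).
Measured force is $l_r t$ plus Gaussian noise of SD 0.5 pN — consistent
with nanometre-scale bead tracking at ~0.1 pN nm$^{-1}$ trap stiffness;
the study does not print a noise figure, so this is a package choice,
configurable per `generator_spec()`.  Force-extension traces follow the
extensible WLC for a 2385-bp DNA tether plus protein (contour
$\approx 850$ nm at 0.34 nm/bp, persistence 45 nm, stretch modulus 1200
pN) sampled at 1400 frames s$^{-1}$, ending in an abrupt drop and a
baseline tail.  Sensorgrams are single-exponential association/
dissociation with shared linear drift and independent Gaussian noise
(0.005 nm).

`tip_link_conditions()` packages the eight published study conditions
with their printed parameters, loading-rate ranges (0.39--377.8 pN
s$^{-1}$) and event totals (e.g. 411 single-bond and 247 dimer events),
split equally across loading rates since per-rate counts are not printed.
Two entries require stand-ins: the 50 µM Ca$^{2+}$ single bond uses a
doubled off-rate (the printed statement is a halved lifetime), and the
truncated EC1-5 construct uses $C_{\mathrm{eff}}^0 = 170$ µM (from its
measured zero-force lifetime) with $f_c = 2.5$ pN, small enough that
rebinding vanishes above ~6 pN as observed.  These stand-ins are
generator conveniences, not fitted results.

What the generator does *not* emulate: bead-tracking artifacts, drift in
the traps, multiple tethers within one recording, day-to-day preparation
variability, or non-Markovian bond memory.  Passing the recovery tests
therefore shows the analysis chain is correct and well-calibrated for the
assumed noise model, not that the instrument's systematics are handled.

## Replication scatter and what the recovery suites show

The synthetic recovery suites regenerate every published condition and
refit it.  Two facts emerged that shape the tests' tolerances.  First,
the recovered $f_\beta$ scatters across seeded replicates with SD
$\approx 2$ pN under the wild-type single-bond conditions — numerically
equal to the study's printed $\pm 2.0$ pN, as it should be, because the
printed error is exactly the bandwidth-weighted fit error of this
estimator under these conditions.  The same holds for the dimer's
$f_c$ (scatter $\approx 2$ pN vs printed $\pm 1.8$).  A consequence is
that a "recovered within printed $\pm1\sigma$" check covers ~68% of
replicates, not more — the package reports ensemble medians (which land
within a few percent of the printed values) alongside per-replicate
coverage.  Second, the mutant-bond recovery from the simultaneous
het/hom fit is stable to about 10% (median $f_\beta \approx 1.8$--2.0
pN) with a mild upward bias traceable to kernel smoothing of the
strongly skewed mutant rupture distributions.

Problem sizes used by the packaged suites: 20 seeded replicates per
recovery target at the published event counts; $10^5$ trajectories for
the constant-force stochastic cross-check; 500 Monte Carlo runs per
stimulus-grid cell (the study's figure used 5000; the mean's SEM scales
as $n^{-1/2}$ and the packaged grid is for verification, not figure
reproduction).

## Known limitations

* The curvature-based errors are conditional per-parameter errors; they
  understate marginal uncertainty when parameters are strongly
  correlated (e.g. $C_{\mathrm{eff}}^0$ with $f_c$).
* The KDE mode on flat-topped rupture densities is intrinsically noisy;
  error bars equal to the bandwidth describe this honestly but modes from
  small samples (n < 30) should not be over-interpreted.
* The motor slip law is a calibration, not a measurement; only its fixed
  point (resting tension) and time-constant order of magnitude are
  constrained.
* Catch bonds, free-energy-surface (Dudko--Hummer--Szabo) analysis,
  >2-strand generalizations and mass-transport-limited BLI kinetics are
  out of scope.
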