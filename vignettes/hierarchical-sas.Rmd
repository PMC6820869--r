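---
title: "Multi-level Unified analysis of hierarchical scattering data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level Unified analysis of hierarchical scattering data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sashier)
```

This vignette is the package's account of the science it implements: the
multi-level Unified scattering model, the least-squares estimator built on
it, the level separation and demagnification machinery, the distance
distribution transforms and the bead-model stage, together with the
numerical decisions a maintainer would want written down.

## The Unified model and its assumptions

A hierarchically organised material — the reference system is a glucose
oxidase (GOx) enzyme matrix on single-layer graphene, with dimers packed
into mass-fractal aggregates packed into dense clusters — scatters over
several overlapping regimes. Each structural level $i$ contributes

$$I_i(q) = G_i e^{-q^2 R_{g,i}^2/3}
          + B_i\, e^{-q^2 R_{\mathrm{cut},i}^2/3}\,(q_i^*)^{-d_{f,i}},
\qquad q_i^* = \frac{q}{\mathrm{erf}(q\,k_{sc}R_{g,i}/\sqrt6)^3},$$

and the total intensity is the sum over levels, smallest first. The
damping radius $R_{\mathrm{cut},i}$ is the $R_g$ of the level below
(0 for the lowest), so each power law switches off where the smaller
structure takes over. Assumptions inherited from this form: scattering is
isotropic and azimuthally averaged; levels add incoherently (no
cross-level interference terms); the contrast $\Delta\rho$ is common to
all levels, which is what makes ratios of Guinier prefactors countable as
aggregation numbers; instrument resolution smearing is *not* modelled —
profiles are treated as unsmeared, so smeared data should be desmeared
upstream or fitted knowing that $R_g$ values will be slightly biased.

Numerically the power-law factor is evaluated as
$\mathrm{erf}(\cdot)^{3d_f} q^{-d_f}$, which underflows to zero at small
$q$ instead of overflowing through $(q^*)^{-d_f}$.

Parameters per level, with units and the defaults used by the 3-level
convenience path:

| parameter | meaning | units | default / constraint |
|---|---|---|---|
| $G$ | Guinier prefactor ($n V^2 \Delta\rho^2$) | cm$^{-1}$ | free, $>0$ |
| $R_g$ | radius of gyration | Å | free, strictly increasing across levels |
| $B$ | power-law prefactor | cm$^{-1}$Å$^{-d_f}$ | free; fixed at 0 for the lowest level |
| $d_f$ | power-law exponent | — | free in $(0,4]$; fixed at 4 (Porod) for the top level |
| $k_{sc}$ | crossover constant | — | 1.06, overridable per level |

Fixing $B$ of the lowest level to zero reproduces the published 3-level
parameter tables exactly by default (a compact enzyme whose Porod regime
lies beyond the measured window); when enabled, its exponent defaults to
the Porod value 4. The cluster exponent is fixed at 4 because a steep
$q^{-4}$ drop-off indicates a well-defined surface, but remains exposed.
Any exponent whose prefactor is fixed at zero is dropped from the free
set automatically (it is unidentifiable).

## Fitting: seeding, optimisation, uncertainties

`unified_fit()` minimises
$\chi^2=\sum_k [(I_{\mathrm{model}}(q_k)-I_k)/\sigma_k]^2$ with
Levenberg–Marquardt (`minpack.lm`), i.e. the experimental-$\sigma$
weighting that also underlies the error-sharing rule below; log-space
residual weighting is deliberately not offered. Constraints are handled
by reparameterisation rather than bounds: amplitudes in log space, the
exponent as $4\,\mathrm{logis}(t)$, and the radii as a multiplicative
chain $R_{g,i+1}=R_{g,i}(1+e^{t_i})$ that keeps the ordering strict for
any real $t$.

The starting model (`unified_init()`) reads the curve the way a
practitioner does: points with $I \le 2\sigma$ are dropped, the smoothed
log–log slope is scanned for shoulders (interior maxima shallower than
$-3$, plus the low-$q$ edge), knees at least a quarter decade apart become
levels via $R_g \approx 1.5/q_{\mathrm{knee}}$, and missing knees (levels
that appear only as a shelf between power laws) are filled at geometric
means of their neighbours. Levels are then refined largest-first by
iterated Guinier regression on the running residual, with two safeguards
that matter on noisy residuals: subtracted levels keep their window around
their own knee and may not drift beyond a factor 2.5 from it (a refinement
pinned against that clamp is discarded in favour of the knee estimate),
and a level's $G$ is clamped to the neighbourhood of the curve height at
its own knee, floored at 5 % of the *total* curve there. Power-law seeds
use the inter-knee log–log slope, with the prefactor always recomputed as
the geometric mean of $I\,q^{d_f}$ over the window so a clamped exponent
cannot produce an absurd prefactor; the same reconciliation is applied
when the user fixes an exponent the seed disagreed with. A featureless
curve (log-range < 0.2) falls back to a log-spaced $R_g$ ladder with a
warning.

Eight optimiser starts are used by default: the seed, two mild and five
stronger perturbations (sd 0.3 / 0.7 in transform space). Lowest $\chi^2$
wins; near-ties (within $10^{-9}$ relative) go to the start with the
better-conditioned curvature, for determinism. Convergence tolerances are
`ftol = ptol = 1e-13` with generous iteration budgets, tight enough that
noise-free round trips return the generating parameters to $10^{-11}$
relative (asserted in the tests).

Uncertainties are the local covariance at the optimum,
$\hat\sigma^2 (J^\top J)^{-1}$ in transform space, mapped to the natural
scale by the delta method; fixed parameters report 0, a singular
curvature reports `NA`. Two caveats are documented rather than hidden:
the sampling distributions of the power-law prefactors are strongly
skewed (log-normal-like, through the $B$–$d_f$ trade-off), so natural-scale
$\pm\sigma$ intervals on $B$ undercover in the downward direction; and at
2 % noise on the reference window the likelihood is occasionally
multimodal, with a merged aggregate/cluster solution beating the
generating basin — replicate medians, not single fits, are therefore what
`scripts/acceptance.R` reports for the recovered parameters. The
replicate suite in the tests checks the honest calibration statement
instead: ~68 % of free parameters fall within $\pm1$ reported $\sigma$
(±15 pp), and the median recovered $z_a$ matches the generating value.

## Level separation, error sharing, demagnification

`split_levels()` evaluates the *upper* levels from their fitted
parameters and assigns the lowest level the residual
$I_G = I_{\mathrm{exp}} - I_c - I_a$ against the experimental data, so
the three curves sum to the data exactly at every point and genuine
features of the data survive in the monomer curve used for shape
modelling (the fitted-formula alternative is available via
`lowest_from = "model"` for noise-free work). Errors are shared as
$s_i = \sqrt{s^2_{\mathrm{exp}} I_i/I_{\mathrm{exp}}}$, which preserves
$\sum_i s_i^2 = s_{\mathrm{exp}}^2$ wherever the sum identity holds;
negative residual points enter with $|I_i|$ and are flagged rather than
dropped (dropping would bias low-intensity tails), and points with
non-positive experimental intensity are excluded and flagged.

`rescale_q()` demagnifies level $i$ by stretching its $q$ axis by
$R_{g,i}/R_{g,G} \ge 1$, which moves the level's Guinier knee onto the
monomer's: a Guinier analysis of the rescaled curve returns an apparent
radius equal to $R_{g,G}$ (asserted within 2 % on synthetic data). This
is what lets every level be modelled in a monomer-sized search volume, at
the cost of a resolution coarsening proportional to the level's size. For
shape modelling the level curve is evaluated from its fitted parameters
on 200 log-spaced points spanning $0.05/R_{g,i}$–$10/R_{g,i}$ (Guinier
shoulder well into the power law; pushing further into the tail only adds
points whose error shares are large), with the experimental error model
interpolated onto that grid through the same sharing rule.

## Hierarchy metrics

`hierarchy_metrics()` derives $z_a=G_a/G_G$, $z_c=G_c/G_a$,
$z_{\mathrm{tot}}=G_c/G_G$ (telescoping exactly), $R_g^3$ volume ratios,
packing fractions $\varphi = z/\mathrm{VR}$ and the Cates resistivity
exponent $d_f/2$. All are ratios and hence invariant under absolute
intensity recalibration. A packing fraction above 1 is reported with a
warning, not clamped: it is itself the diagnostic that the subunits are
anisometric (rods/platelets), whose volume grows slower than $R_g^3$. No
quantitative anisometry correction is attempted. Uncertainties propagate
from the fit covariance to first order. Display rounds to 2–3 significant
figures; full precision is always in the `value` column.

## Distance distributions

`pr_direct()` implements the quadrature
$p(r)=(r^2/2\pi^2)\int I(q)\,\mathrm{sinc}(qr)\,q^2\,dq$ over the
measured window (trapezoidal); window truncation leaves ripple and a
small non-zero tail at $D_{\max}$, which is why the regularised route is
the default for real data. `pr_indirect()` expands $p$ in 60 cubic
B-splines vanishing at 0 and $D_{\max}$ and minimises
$\chi^2 + \alpha \int p''^2$, matching the smoothness prior to the
penalty; non-negativity (on by default, appropriate for compact
particles) is imposed through the non-negative coefficients of the
B-spline basis via `pracma::lsqnonneg`, and should be switched off for
demagnified fractal levels, whose apparent distributions may oscillate.
$\alpha$ is chosen by an L-curve scan (21-point log grid around the
Frobenius-ratio scale, Menger-curvature corner), with a discrepancy
guard: a corner whose misfit exceeds both 1.5 and twice the best
attainable reduced $\chi^2$ is rejected in favour of the largest $\alpha$
that keeps the misfit within 10 % of the best (or below 1). $D_{\max}$
defaults to $2.75 R_g$, the midpoint of the conventional 2.5–3 range; for
demagnified *fractal* levels the analysis and tests use the top of that
range ($3 R_g$), because mass-fractal objects carry more weight at long
intra-particle distances and the tighter support truncates it. For the
monomer level of the reference system the conventional starting value is
$D_{\max} = 70$ Å. Sphere oracles (analytic form factor in, closed-form
distance distribution out) pin both routes in the tests: < 5 % normalised
RMS for the direct route, < 2 % for the indirect, $R_g=\sqrt{3/5}R$
within 2 %.

## Bead-model reconstruction

The bead stage is a deliberately simplified dummy-atom modeller, not a
port of the classical annealing programs: its purpose here is to close
the demagnification loop (upper levels become monomer-scale envelopes),
and its acceptance surface is property-based (sphere recovery, NSD), not
envelope matching. Beads live on a hexagonal close-packed lattice
(nearest-neighbour spacing = one bead diameter, default radius
$D_{\max}/40$, ≈ $10^3$–$10^4$ sites) inside the $D_{\max}$ sphere.
Single-bead-flip Metropolis annealing minimises the reduced $\chi^2$
between the scale-free Debye curve — the scale factor is solved
analytically per evaluation, removing a nuisance parameter — and the
target (a measured/decomposed profile, or the intensity regenerated from
a `pofr`), plus a compactness prior (weight 0.05) penalising isolated
beads and unsaturated neighbour shells, the role the connectivity bias
plays in classical dummy-atom modelling. The schedule is geometric
($T_{k+1}=0.98\,T_k$, $100\,n_{\mathrm{beads}}$ proposals per
temperature, stop below 0.1 % acceptance); $T_0$ is calibrated from the
mean move magnitude when not given. Target curves are capped at
$q \le \pi/(2 r_{\mathrm{bead}})$ — finer features than the beads cannot
be represented — and log-subsampled to 40 points. The pair sum uses
distance binning at $r_{\mathrm{bead}}/4$ above 300 beads and exact pairs
below, so the 1- and 2-bead closed forms are matched exactly. Runs are
bit-reproducible at a fixed seed, and a zero-temperature-step call
returns the seeded random start untouched.

NSD follows the standard symmetrised nearest-neighbour definition
normalised by the lattice spacings, minimised over superpositions by
principal-axes alignment with all eight sign combinations (enantiomers
included) and Nelder–Mead rigid-body refinement. `average_models()`
aligns replicates to the lowest-mean-NSD reference, accumulates occupancy
on the reference lattice and keeps sites at or above half the maximum
occupancy, excluding models beyond mean + 2 sd of the NSD distribution —
a filter meant for the conventional ~20-replicate sets; with only a
handful of models the spread estimate is weak and outliers may survive.

## The synthetic-data generator

`simulate_unified()` emulates the study conditions the analysis assumes:
200 log-spaced points on 0.003–0.5 Å⁻¹ (the three-configuration
pinhole-SANS window), multiplicative Gaussian noise with fraction 0.02
and an absolute $\sigma$ floor of $10^{-4}$ cm⁻¹ standing in for the
counting statistics of long acquisitions; a `poisson_like` mode lets the
relative error grow as intensity falls. The reported $\sigma$ column is
$\max(0.02 I, 10^{-4})$, so the deep high-$q$ tail of the reference curve
sits at the floor — those ~60 points carry no structural information,
exactly as background-limited real data would. What the generator does
*not* emulate: resolution smearing ($\Delta\lambda/\lambda$ effects),
correlated residuals from imperfect background subtraction,
inter-particle structure factors, and polydispersity beyond what the
Unified form absorbs. Passing round-trip tests therefore demonstrate
estimator correctness under the stated noise model, not robustness to
those real-data effects.

## Problem sizes used in the tests

The suite runs round trips at 200-point curves with 25 noisy replicates
for the recovery/coverage statistics; p(r) oracles use 400-point sphere
curves; reconstructions use 300 beads of radius 2 Å in a 60 Å search
sphere with a shortened schedule (15 000 proposals per temperature,
cooling 0.95) — sizes chosen so the full pipeline stays desk-scale while
every property keeps a comfortable signal margin. The acceptance script
fits 25 replicates and reconstructs twice at 400 beads.

## Known limitations

* No resolution smearing or polydispersity; fits to smeared data bias
  $R_g$ low at the few-percent level typical of
  $\Delta\lambda/\lambda = 0.15$.
* $n_i$, $S_i$, $V_i$ and $\Delta\rho$ are not individually identifiable
  from a single contrast; only their ratios are reported, and no
  $B$-based absolute metric is computed.
* The $B$–$d_f$ degeneracy makes natural-scale intervals on $B$ strongly
  asymmetric; treat $\pm\sigma$ on prefactors as local curvature, not as
  coverage intervals.
* Demagnified envelopes inherit the coarse resolution of their level and
  the non-uniqueness of any intensity-to-shape inversion; they are
  illustrations consistent with the data, not unique structures.
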