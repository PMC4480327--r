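---
title: "Trait-based fitness landscapes for annual arable weeds: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based fitness landscapes for annual arable weeds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weedfitness)
```

## The model

`weedfitness` implements a generic single-season demographic model of an
annual arable weed whose parameters are predicted from two functional
traits: maximum plant height $H$ (cm) and 1000-seed weight $W$ (mg).  The
population is tracked as a seedbank density $S_t$ (seeds m$^{-2}$) and its
fitness over one growing season is

$$\lambda = S_{t+1} / S_t.$$

One cycle chains the following stages (all densities continuous, no
demographic stochasticity):

1. **Emergence.** $E = S_t \cdot e$, with $e$ the proportion of the bank
   emerging.  At the defaults ($S_t = 1000$, $e = 0.071$) this gives the 71
   seedlings m$^{-2}$ of the reference parameterisation.
2. **Herbicide survival.** $N = E(1 - \mu)$, $\mu$ the scenario's herbicide
   mortality (0.96 high use, 0.5 low use).
3. **Competition.** Competitive ability is the density causing a 5% crop
   yield loss, predicted from height on the log scale,
   $\ln D_{5\%} = 4.51 - 0.020\,H$ (sign convention below).  The
   one-parameter Cousens hyperbola with asymptote $m$ fixed at the cap
   (100%) is anchored at that density by back-solving
   $i = 5 / \left(D_{5\%}(1 - 5/m)\right)$, giving percent yield loss
   $Y = iN/(1 + iN/m)$.
4. **Fertility filter.** At high fertility $Y$ is unchanged.  At low
   fertility it is multiplied by a coefficient $f \in (0,1]$ expressing how
   much relative competitive ability the weed retains when fertiliser is
   withheld (see below).
5. **Biomass.** Total mature weed biomass is linear in adjusted yield loss,
   $B = cY$, with $c$ (g m$^{-2}$ per %) the calibrated coefficient.
6. **Fecundity.** Ln(seed production) is allometric in Ln(biomass) with
   slope 1; the intercept (Ln seeds produced by 1 g of biomass) is
   quadratic in $x = \ln W$: $a(x) = -0.14x^2 - 0.70x + 5.85$.  Fresh seed
   $= N \, e^{a} (B/N)^{1} = e^{a} B$: with slope 1, production depends
   only on total biomass, not on how it is split among plants (this
   identity is asserted numerically in the tests).
7. **Return to the bank.** A proportion $\ell = 0.79$ of fresh seed is lost
   to predation and fatal germination; the residual bank (after the
   germinated seed was removed) decays exponentially with half-life $h$
   (default 1 year): carry-over $= (S_t - E)\,e^{-\ln 2\,\Delta t/h}$ with
   $\Delta t = 1$.

$\lambda$ is the sum of carry-over and surviving seed rain divided by
$S_t$.  There is no multi-year projection and no between-year density
dependence: $\lambda$ is a single-season fitness index, read against the
threshold $\lambda = 1$.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `initial_seedbank` | 1000 | seeds m$^{-2}$ | reference bank; $\lambda$ is scale-free in it when all else is fixed |
| `emergence_fraction` | 0.071 | proportion yr$^{-1}$ | median of the (right-skewed) database distribution |
| `fresh_seed_loss` | 0.79 | proportion | chosen, jointly with $\mu = 0.96$, as the maximum feasible stress (see calibration) |
| `seedbank_half_life` | 1 | years | database median; decay rate $\ln 2 / h$ |
| `crop_height` | 80 | cm | reference crop for relative height in the fertility filter |
| `allometric_slope` | 1 | -- | size-invariant seeds-per-gram |
| `yield_loss_cap` | 100 | % | asymptote of the one-parameter hyperbola |
| `biomass_coeff` | calibrated (~15.3) | g m$^{-2}$ per % | see below |

## Numerical and design choices

**Sign of the competition slope.** The printed competition fit has slope
magnitude 0.020 with intercept 4.51 on $\ln D_{5\%}$.  Taken with a
positive sign it would make taller weeds *less* competitive, contradicting
both the qualitative description of the relationship and the behaviour of
the published fitness contours.  The package's default is therefore
$\ln D_{5\%} = 4.51 - 0.020H$, with the sign exposed as a switch
(`competition_height_model(sign = +1)`) for anyone who wants the literal
reading.

**Calibration of `biomass_coeff`.** The biomass-per-yield-loss
relationship comes from unpublished trial data and has no printed
coefficients, but the reference parameterisation states its own anchor:
under high herbicide and high fertility the *shortest* plant in the system
(10 cm) should just be able to maintain a viable population by tuning seed
size.  `calibrate_biomass_coeff()` therefore bisects on $c$ until
$\max_{W \in [0.01, 20]} \lambda(H = 10) = 1$ (tolerance $10^{-8}$;
$\lambda$ is linear and increasing in $c$, so the root is unique and
bracketing by doubling always succeeds when the carry-over alone is below
1).  At the defaults this gives $c \approx 15.28$ g m$^{-2}$ per %.

**Fertility filter.** The original low-fertility competition function was
parameterised in an earlier field study and is not reproducible from
printed coefficients.  The package ships a documented default behind a
stable interface: a logistic in relative height $H/H_{crop}$ (midpoint
0.25, steepness 5) shifted by $+0.1 \ln W$, so that weeds taller than
about a quarter of the crop keep most of their competitive ability at low
fertility while short, small-seeded nitrophilous ruderals lose most of
theirs.  Any replacement `fertility_fn` is accepted; its values are checked
to lie in $(0, 1]$ and the coefficient always multiplies percent yield
loss (the other conceivable attachment points -- biomass or $D_{5\%}$ --
are not used).  Exact reproduction of the published contour panels is
contingent on supplying the original parameterisation.

**Trait domains.** Predictions clamp their inputs to the ranges over which
the regressions were estimated and the sweep runs -- seed weight 0.01--20
mg, height 10--200 cm -- with a warning; `clamp = FALSE` permits
extrapolation.  The fecundity quadratic is concave with vertex at
$x = -2.5$ ($W \approx 0.082$ mg), so within the domain fecundity is
strictly decreasing in seed weight above that vertex.

**Viability threshold.** Species are classified viable when
$\lambda \ge 1$ (the comparison used by the headline counts); the
contour-figure phrasing $\lambda > 1$ is available via
`comparator = "gt"`.  Species are evaluated at their exact trait values,
never snapped to the sweep grid, which avoids resolution artefacts at the
$\lambda = 1$ boundary; the grid exists only for contours (extracted by
marching squares via `grDevices::contourLines`).

**Sensitivity analysis.** One-at-a-time multiplicative perturbations
(default $\times 1.05$, read from "incrementing each parameter by 5%");
perturbed proportions are capped at 1, so under the high-herbicide
scenario the mortality perturbation saturates at total kill and dominates
every ranking -- a boundary artefact worth knowing about.  Where the cap
is slack, the fecundity intercept $c_0$ ranks first: a 5% increment on
$c_0$ multiplies seed production by $e^{0.05 \times 5.85} \approx 1.34$,
a disproportionate effect relative to the increment.  The published
headline figure for this effect (a 19.6% change in $\lambda$) cannot be
pinned because its baseline weed and scenario are unstated; the package
asserts the closed-form identity instead: at $W = 1$ mg (where the
effective intercept equals $c_0$),
$(\lambda' - c)/(\lambda - c) = e^{f c_0}$ with $c$ the carry-over
fraction.

## The synthetic-data generator

`generate_wtdb()` emulates the real 19-species database: seed weight
log-uniform over 0.01--20 mg, height uniform over 10--200 cm, fecundity
intercepts scattered around the default quadratic (Gaussian, sd 0.3),
maximum emergence depths around the default line (log-normal
multiplicative, sd 0.2), $\ln D_{5\%}$ around the default competition line
(sd 0.3) with hyperbola parameters $(i, m)$ back-derived from the noisy
$D_{5\%}$, and right-skewed emergence-fraction and half-life distributions.
The skewed distributions are log-normals parameterised by their medians
(7.1% and 1 year) with log-sd 0.9 -- the source describes the shapes only
as "highly skewed" towards low values, so the family and spread are
package choices, fixed once.  What a green parameter-recovery test
establishes is that the fitting machinery is unbiased and correctly
calibrated *for this noise model*; it does not establish that the real
database satisfies these error assumptions (real records are multi-source,
heteroscedastic, and unevenly replicated across species).

`generate_species_pools()` defines "common-like" and "declining-like"
pools by rejection sampling against the model's *own* calibrated
high-herbicide/high-fertility surface, rather than by fixed trait boxes,
so the construction guarantees (100% / 0% viable under the reference
scenario) survive recalibration.  One consequence, verified rather than
assumed: the short-stature/heavy-seed corner of trait space is non-viable
under *every* scenario (even with zero herbicide mortality its seed
production cannot offset 79% fresh-seed losses), so a declining pool
sampled uniformly from the non-viable region is never fully rescued by the
low/low scenario -- unlike the real declining species, which do not occupy
that corner.  Tests therefore assert the qualitative filtering pattern,
not a 100% rescue.

## Known limitations

* Single season, two traits, deterministic: no stochastic parameter
  sampling, no multidimensional trait sweeps, no species-specific herbicide
  susceptibility.
* The endpoint fixture of the published database stores only printed
  min/max values with entry counts; summaries computed from it are labelled
  `endpoint_only` and are not substitutes for full-database means.
* The published viability counts for real species pools (17/22 common,
  9/31 declining) depend on a supplementary trait table that is not
  printed; the package reproduces the machinery and the rounding
  arithmetic, not those counts.
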