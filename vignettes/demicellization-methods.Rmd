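---
title: "Demicellization thermodynamics from titration calorimetry: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demicellization thermodynamics from titration calorimetry: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demicell)
```

## The system and the model

Bile salts are steroidal biosurfactants with a facially segregated
polar/apolar surface; above the critical micelle concentration (cmc) they
pack back-to-back into small aggregates. `demicell` analyses the
thermodynamics of this aggregation for C3-substituted sodium cholate
derivatives from two instrument classes: isothermal titration calorimetry
(ITC) dilution experiments and drop-volume tensiometry.

The core description is the closed mass-action model

$$ n\,S \rightleftharpoons M_n, \qquad K = \frac{[M_n]}{[S]^n}, $$

with a single aggregate species of aggregation number $n$ (not necessarily
integer; fits routinely return values such as 10.5) and equilibrium
constant $K$ in mM$^{1-n}$. The mass balance
$S_{tot} = [S] + nK[S]^n$ links the free-monomer concentration to the
total concentration. All concentrations are mM internally, matching how
cmc values are tabulated for these compounds.

### Solving the mass balance

`monomer_concentration()` brackets the root of
$[S] + nK[S]^n - S_{tot}$ in $\log [S]$, where both terms are evaluated by
log-sum-exp so that $nK[S]^n$ cannot overflow even for $n \approx 60$ and
$K \approx 10^{30}$, then polishes with Newton steps in linear space. The
returned root is verified against the mass balance to a relative residual
of $10^{-10}$; failure to converge is an error, never a silent clamp. The
derivative $d[S]/dS_{tot} = (1 + n^2K[S]^{n-1})^{-1}$ is evaluated as an
inverse logit of a log-scale argument for the same reason.

### Attaching a cmc to $(n, K)$

The mass-action model has no sharp transition, so a convention must fix
what "the" cmc of a parameter pair is. We use the inflection criterion:
the total concentration at which $d^2[S]/dS_{tot}^2$ is extremal, i.e.
the steepest point of the sigmoid ITC transition. Differentiating the
analytic second derivative in $\log [S]$ shows the extremum satisfies

$$ n^2 K [S]^{\,n-1} = t^\* = \frac{n-2}{2n-1}, $$

which gives a closed form for the cmc and makes
`params_from_cmc()`/`cmc_from_params()` exact inverses of one another
(the numeric grid-plus-refinement search that one would otherwise use
survives as an independent oracle in the test suite). The criterion is
degenerate at $n \le 2$, where the second derivative has no interior
extremum; both functions refuse those inputs explicitly. A mole-fraction
convention $K = x_{cmc}^{-n}$ is available behind the `convention`
argument for comparison with literature that defines $K$ that way.

## From heats to aggregation numbers

A demicellization ITC experiment titrates a micellar solution (well above
the cmc) into buffer. While the cell is below the cmc, essentially all
injected micelles dissolve and the per-mole heat sits at
$\Delta H_{dil} + \Delta H_{demic}$; far above the cmc only the dilution
background $\Delta H_{dil}$ remains. The degree of demicellization of
injection $i$,

$$ x_i = \frac{\Delta H_i - \Delta H_{dil}}{\Delta H_{demic}}, $$

estimates $d[S]/dS_{tot}$, and the mass-action model obeys the exact
identity

$$ \frac{d\,\ln\{x^{-1} - 1\}}{d\,\ln S_{tot}}
   = \frac{n-1}{n} + \frac{(n-1)^2}{n}\,x , $$

so plotting the log-derivative against $x$ gives a straight line whose
intercept and slope both encode $n$. `aggregation_number_from_line()`
inverts either parameter alone (the slope-only estimate is the larger
root of $n^2 - (slope+2)n + 1 = 0$, the intercept-only estimate
$1/(1-intercept)$) and reports a joint estimate minimizing the sum of
squared *relative* residuals of both parameters. The relative scaling is
deliberate: the slope is an order of magnitude larger than the intercept,
and equal absolute weighting would let it dominate completely. When the
two single-parameter estimates disagree by more than 50% the result is
flagged, not rejected.

### Numerics of the linearization

The identity involves a derivative of noisy, discretely sampled data, and
the numerical choices matter more than anything else in this pipeline:

* **Cell bookkeeping.** Cumulative concentrations follow the standard
  perfusion displacement model
  $c_i = c_{syr}(1 - \prod_{j\le i}(1 - v_j/V_0))$; each heat is
  attributed to the midpoint of its injection interval, since the
  measured heat is a secant average of $d[S]/dS_{tot}$ over the interval.
* **Staggered differencing.** $y = d\ln(x^{-1}-1)/d\ln S_{tot}$ is
  estimated by two-point differences centred *between* consecutive
  points and paired with the mean of the two $x$ values. Compared with a
  collocated three-point central stencil this halves the truncation bias
  near the steep transition, where the curvature of $\ln(x^{-1}-1)$ is
  large.
* **Clipping.** Points with $x$ outside $(10^{-4}, 1-10^{-4})$ carry no
  information about the transition and are dropped (their count is
  reported); fewer than four usable points is an explicit error.
* **Weights.** Propagating a constant heat noise through
  $\ln(x^{-1}-1)$ and the difference quotient gives
  $\mathrm{var}(y) \propto (x(1-x)\,\Delta\ln S_{tot})^{-2}$, so each
  staggered point is weighted by $(x(1-x)\,\Delta\ln S_{tot})^2$; the two
  extreme points are additionally down-weighted by 0.5.

### The fit itself

`fit_demicellization()` treats $(\Delta H_{demic}, \Delta H_{dil})$ as
outer optimization parameters (Nelder--Mead, initialized from the means
of the first and last 10% of the heats) and scores each candidate by the
normalized weighted residual of the linearized points around the
mass-action line *family* $y = \frac{n-1}{n} + \frac{(n-1)^2}{n}x$, whose
single parameter is $n$ itself. Constraining the inner fit to this
family, rather than fitting a free two-parameter line, is essential under
noise: a free line can be made spuriously straight (even with negative
intercepts, which no aggregation number can produce) by sliding the
enthalpies, and the outer search will happily go there. The free-line
intercept, slope and $r^2$ are still computed at convergence and reported
as diagnostics, together with both single-parameter estimates of $n$.

Two further safeguards address properties of the discretized problem:

* **Truncation-bias correction.** Even noise-free model data do not fall
  exactly on the theoretical line after discrete differencing; the
  residual depends on the injection schedule. After each outer round the
  current parameter estimates are pushed through a noise-free simulation
  of the same schedule, the systematic residual of the simulated
  linearized points from the exact line is interpolated as a function of
  $x$, and subtracted from the data before the next round. On clean
  synthetic data this self-consistent loop converges to the generating
  parameters to better than 0.1%; three rounds are the default.
* **Trust region.** The first outer round searches a broad box around
  the plateau-derived start (the demicellization enthalpy may move by a
  factor of 2.5, the dilution enthalpy by $\pm|\Delta H_{demic}|$);
  once the bias correction is active the box shrinks around the previous
  round, because the correction could otherwise manufacture
  self-consistent but wrong solutions far from the data-determined
  plateaus.

The cmc is read off where the raw $x$ series crosses the model's
transition-center value $x^\* = 1/(1+t^\*) = \frac{2n-1}{3(n-1)}$ (the
inflection point of the enthalpogram, evaluated at the fitted $n$), by
log-linear interpolation between the bracketing injections. Using the
inflection value rather than the naive $x = 0.5$ keeps the fitted cmc on
the same convention as `params_from_cmc()` — for $n = 10$ the two differ
by some 16%, which would otherwise contaminate every derived constant.
$K$ then follows from `params_from_cmc(n, cmc)`. Titrations that never
cross the transition, or whose heat range does not exceed the noise
floor, raise explicit "no cmc in scanned range" errors. Dropping the
first injection — common practice for the diffusion-contaminated first
aliquot — is available via `drop_first` and changes clean-data fits by
well under 1%.

## Derived state functions

For an ionic surfactant a fraction $\beta$ of the counterions condenses
onto the micelle, and the effective constant is
$K_{mic} = K\,[\mathrm{Na^+}]^{\beta n}$ (`k_mic()`, computed in log
space). Per mole of monomer,

$$ \Delta G_{demic} = \frac{RT}{n} \ln K_{mic}, \qquad
   \Delta S_{demic} = \frac{\Delta H_{demic} - \Delta G_{demic}}{T}, $$

with $R = 8.314$ J mol$^{-1}$ K$^{-1}$ exactly. All quantities refer to
*demicellization* ($\Delta G_{demic} > 0$, $\Delta S_{demic} < 0$ for
these systems); micellization values are the negatives and are never
stored. The heat capacity $\Delta C_{P,demic}$ is the ordinary
least-squares slope of $\Delta H_{demic}$ against temperature
(`heat_capacity_demic()`), positive when hydrophobic surface becomes
water-exposed on dissociation. The mole-fraction cmc divides the molar
cmc by a water molarity of 55.5 M — the value back-derived consistently
from published cmc/mole-fraction column pairs for these compounds — and
is overridable. The magnitude of the $[\mathrm{Na^+}]^{\beta n}$
contribution to $\Delta G_{demic}$ reduces to $RT\beta|\ln[\mathrm{Na^+}]|$
(the aggregation number cancels); it is reported as a magnitude because
the literal term is negative for sub-molar sodium.

The packaged reference table of per-temperature state functions for the
three hydrophobic cholate derivatives (NaAdC, NaAdCH2C, NatButPhC)
reports $\Delta G$ values that depend on the authors' unstated
$K(n, cmc)$ convention and exact sodium concentration; the pipeline
therefore treats tabulated $\Delta G$ as an input when regenerating
$\Delta S$, rather than attempting to reproduce it absolutely.

## Counterion binding and buffer speciation

The Corrin--Harkins relation
$\log_{10} cmc = A - \beta \log_{10}[\mathrm{Na^+}]$ is fitted by
ordinary least squares in double-log space (`corrin_harkins_fit()`);
$\beta$ outside $[0,1]$ is flagged, never clamped. Base-10 logarithms are
used here, natural logarithms only inside the free-energy expressions.
For carbonate/bicarbonate buffers both species carry sodium (one and two
ions respectively), so
$[\mathrm{Na^+}] = c_{buf}\,(1 + f)$ with the carbonate fraction
$f = (1 + 10^{pK_{a2} - pH})^{-1}$. The default $pK_{a2} = 10.33$ is the
thermodynamic 25 °C value; ionic-strength corrections are deliberately
omitted, and only buffer sodium is counted (the surfactant's own
counterion contribution is below the precision of everything downstream
at sub-millimolar cmc values).

## Tensiometry breakpoints

Below the cmc the surface tension falls approximately linearly in
$\ln c$; above it the curve flattens. `detect_cmc_breakpoint()` fits a
continuous two-segment linear model in $(\ln c, \gamma)$ by exhaustive
closed-form search: for every interior interval, unconstrained lines are
fitted to the left and right subsets, and their intersection is the
optimal continuous breakpoint whenever it falls inside the interval
(otherwise the breakpoint is pinned at the interval ends and the
constrained three-parameter model refitted). Ties in residual sum of
squares break toward the lower concentration. An F-test (2 extra
parameters) against the single-line model guards against spurious breaks
at significance 0.05, and a post-cmc slope steeper than the pre-cmc slope
is flagged as physically suspicious. The estimate is exactly equivariant
under affine transforms of $\gamma$ and rescaling of the concentration
unit. No Gibbs-isotherm surface-excess analysis is attempted.

## Lipophilicity and the cmc

Micellization and octanol/water partitioning both transfer the
hydrophobic face of the bile anion out of water, so
$\log P$ and $\log_{10}(cmc)$ are linearly related. The package ships the
published calibration for bile-salt derivatives,
$\log P = 2.79 - 1.00\,\log_{10}(cmc/\mathrm{mM})$ ($r^2 = 0.948$), as a
constant (`reference_logp_cmc_fit()`): the underlying point set draws on
literature cmc values that are not redistributable, so the line is for
use, not regeneration. `predict_logp_from_cmc()` and
`predict_cmc_from_logp()` are exact inverses. All $\log P$ values refer
to the monoanion, the species that actually aggregates at the working pH.

Computational $\log P$ predictors are benchmarked by the mean of squared
residuals against experimental values,
$\sum(\log P_{theor} - \log P_{exp})^2 / N$ with a plain $N$ denominator
— the only reading that reproduces the published benchmark row — and
classified as reliable ($\le 0.5$), acceptable ($\le 1$) or not
acceptable ($> 1$), with inclusive upper boundaries.

## What the synthetic generators do and do not emulate

The raw instrument data behind the reference tables were never
deposited, so every pipeline input can be simulated with known ground
truth (`synthetic_truth()` and the `gen_*` functions), and all
generators are deterministic functions of an explicit seed (the caller's
RNG stream is saved and restored).

* `gen_itc_experiment()` produces per-injection heats
  $\Delta H_{dil} + \Delta H_{demic}\,\Delta[S]/\Delta S_{tot}$ from the
  exact mass-action model with displacement bookkeeping, plus additive
  Gaussian noise (default 1% of $|\Delta H_{demic}|$). The default
  schedule mirrors the usual protocol on a 200 µL cell: 38 injections of
  2 µL at 4 mM. It does *not* simulate raw power--time thermograms,
  baseline drift, or the Origin-style peak integration step — the heats
  are taken as already integrated.
* `gen_surface_tension_curve()` draws an exactly two-segment curve in
  $(\ln c, \gamma)$; real curves round off near the break.
* `gen_corrin_harkins_series()` uses lognormal noise on the cmc
  (multiplicative, keeping concentrations positive), Gaussian noise being
  reserved for heats.
* `gen_logp_cmc_dataset()` draws cmc values log-uniform over 0.1--15 mM,
  the span typical of bile-salt derivatives.

Passing recovery tests on these generators demonstrates that the
estimators invert their own forward models at realistic noise; it does
not certify behaviour under instrument artefacts the generators omit
(baseline curvature, occasional outlier injections, pre-cmc premicellar
association).

## Problem sizes and test design

The recovery studies in the test suite use the default 38-injection
schedule, 50 seeds for the ITC and tensiometry Monte-Carlo studies and
100 seeds for the counterion study — enough for stable medians while
keeping the whole suite interactive. At 2% heat noise the median
aggregation-number error is around 8% (the suite asserts $\le 10$%);
noise-free round trips are asserted at 2% but converge to better than
0.1%. The regenerated entropy column of the packaged reference table
agrees with the printed values to 0.5 J mol$^{-1}$ K$^{-1}$ on all 15
rows; the regenerated mole-fraction column agrees to $0.01\times10^{-6}$
on 13 of 15 rows — the two rows with a printed cmc of 0.220 mM were
evidently computed from unrounded concentrations before printing, and no
single water molarity reconciles all 15 printed pairs. The test suite
asserts the strict band and therefore documents this as a known, bounded
discrepancy of the source table rather than hiding it.

## Known limitations

Single aggregate species only (no premicellar dimers, no sphere-to-rod
transitions — the largest derivative studied here likely violates this
above the cmc, which shows up as scattered fitted $n$); no activity
coefficients; dilution enthalpy treated as concentration-independent;
the unconstrained-line $r^2$ reported for noisy titrations is pessimistic
because the staggered derivative amplifies noise at both plateaus even
after weighting.
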