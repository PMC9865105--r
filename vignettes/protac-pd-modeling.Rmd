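---
title: "Mechanistic PD modeling of PROTAC degraders with protacpd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic PD modeling of PROTAC degraders with protacpd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protacpd)
```

## The problem

Proteolysis targeting chimeras (PROTACs) are heterobifunctional molecules
that bind a protein of interest (POI) with one warhead and an E3 ubiquitin
ligase with the other. The resulting POI--PROTAC--E3 *ternary complex*
marks the target for proteasomal degradation. Two features make the
pharmacology of these compounds unusual:

* **The hook effect.** At high drug concentrations, binary POI--PROTAC and
  PROTAC--E3 complexes outcompete the ternary complex, so degradation
  *falls* again: concentration-degradation profiles are bell-shaped on a
  log axis. Hyperbolic Emax fits, the habitual default, cannot represent
  this and bias both curve description and compound ranking.
* **Event-driven action.** Degradation is catalytic: a small engaged
  fraction, turned over repeatedly, removes most of the protein. Observed
  profiles therefore depend strongly on incubation time relative to the
  target's turnover half-life, and parameters read off a pre-steady-state
  experiment can be far from their steady-state values.

`protacpd` implements a three-model framework for these data: a
descriptive **hook model** for fitting profiles, a mechanistic **kcat
model** linking biochemistry to degradation, and a **PD model** combining
degradation and inhibition into a downstream response -- together with the
fitting, inference, design, and simulation machinery around them.

## Target engagement

With binary dissociation constants $K_{D,P}$ (POI side) and $K_{D,E}$ (E3
side), cooperativity $\alpha$, and total ligase $E_0$, the fraction of
target protein engaged in a ternary complex at unbound PROTAC
concentration $C$ is, assuming the ligase is not saturated by the target,

$$TE(C) = \frac{\alpha E_0}{\alpha E_0 + K_{D,P} + K_{D,E} +
K_{D,P}K_{D,E}/C + C}.$$

Engagement vanishes at both concentration extremes and peaks at the
geometric mean $C = \sqrt{K_{D,P}K_{D,E}}$ -- the molecular origin of the
hook effect. `ternary_te()` evaluates this form; `ternary_te_exact()`
evaluates the full quadratic (smaller-root) solution that retains the
target expression level $P_0$, implemented in a cancellation-safe form
($2c/(b + \sqrt{b^2-4c})$ rather than the textbook difference) so small
and large concentrations do not lose precision. The two agree to better
than $10^{-4}$ whenever $P_0/E_0 \le 10^{-4}$; in cells the simplified
form is the working model, which is why $P_0$ never needs to be measured.

```{r}
b <- ternary_binding(kd_poi = 100, kd_e3 = 100, alpha = 10)
ternary_te(c(10, 100, 1000), b, e3_total = 50)
```

## Degradation: the kcat model and the hook model

Target turnover is an indirect-response process: synthesis balanced by
baseline degradation (rate $k_{deg,P} = \ln 2 / t_{1/2,P}$), with
PROTAC-catalyzed destruction adding a term $k_{cat}\,TE(C)$. Because
engagement is constant over time in vitro, the relative protein level has
a closed-form solution; the degraded fraction is

$$D(C,t) = D_{ss}(C)\left(1 - e^{-\ln 2\, t / (t_{1/2,P}(1 -
D_{ss}(C)))}\right),\qquad
D_{ss} = \frac{k_{cat}TE}{k_{deg,P} + k_{cat}TE}.$$

A note on the exponent: re-deriving from the turnover equation gives an
effective rate $k_{deg,P} + k_{cat}TE = k_{deg,P}/(1 - D_{ss})$, i.e. the
half-life is *divided* by $(1-D_{ss})$ in the exponent. The alternative
reading (multiplying) is inconsistent with the time courses this package
validates against its ODE oracle, and is not used.

Substituting the engagement expression makes $D_{ss}(C)$ itself a
bell-shaped function of concentration. Lumping parameters yields the
descriptive **hook model** with three interpretable parameters --
maximal degradation $D_{max}$, half-maximal concentration $DC_{50}$, and
peak concentration $DC_{max}$:

$$D(C) = \frac{D_{max}(DC_{50}^2 + DC_{max}^2 - 2 DC_{50}DC_{max})}
{DC_{50}^2 + DC_{max}^2 - 4 DC_{50}DC_{max} + DC_{50}C +
DC_{50}DC_{max}^2/C}.$$

The two views are *exactly* equivalent: `hook_from_mechanistic()` maps
$(K_{D,P}, K_{D,E}, \alpha, E_0, t_{1/2,P}, k_{cat})$ to
$(D_{max}, DC_{50}, DC_{max})$ in closed form ($DC_{max} =
\sqrt{K_{D,P}K_{D,E}}$; $DC_{50}$ as the smaller root of a quadratic,
evaluated in the same cancellation-safe form), and the test suite verifies
the mapped curve against the mechanistic one to $10^{-9}$ on log grids.
Useful exact identities: $D(DC_{max}) = D_{max}$, $D(DC_{50}) =
D_{max}/2$, and log-axis symmetry $D(C) = D(DC_{max}^2/C)$.

For $C \ll DC_{max}$ the hook model reduces to the hyperbolic Emax model
with $E_{max} = D_{max}$ and $EC_{50} = DC_{50}$; because the two are
nested, the best hook fit can never have a larger residual sum of squares
than the best Emax fit.

The catalytic efficiency $TE_{50} = k_{deg,P}/k_{cat}$ is the engagement
needed for 50% steady-state degradation; values near 1% are typical and
explain why degraders work at engagement levels far below what occupancy
pharmacology would require.

```{r}
p <- mechanistic_params(b, cell_system(e3_total = 50, half_life = 45),
                        kcat = 4.6)
hook_from_mechanistic(p)
te50(p)
```

## Inhibition and the PD model

Inhibitor-derived warheads also inhibit whatever target remains. In the
catalytic regime (engagement $\ll 1$) inhibition is binary-site occupancy
$I = C/(K_{D,P} + C)$; when only cell-level data exist it is
re-expressed through the potency $IC_{50}$ of a matched non-degrading
control as $I = C(1-P_{50}) / (C(1-P_{50}) + IC_{50}P_{50})$. Degradation
and inhibition compose into target modulation $TM = D + I - DI$, and the
downstream response follows the direct-response model

$$PD = PD_{min} + (1-PD_{min})\frac{(1-TM)^n (1-P_{50}^n)}
{P_{50}^n + (1-TM)^n(1 - 2P_{50}^n)},$$

anchored at $PD(0) = 1$ and $PD(1) = PD_{min}$, strictly decreasing, with
$P_{50}$ the remaining-protein level that halves the target-dependent
response and $n$ an empirical Hill coefficient for far-downstream
readouts.

Two consequences worth knowing:

* **Validity bound.** The denominator stays positive for all $TM$ exactly
  when $P_{50}^n \le 1/2$. The package enforces the *non-strict* bound:
  the boundary case (e.g. $P_{50} = 0.5$, $n = 1$, where the model
  degenerates gracefully to $PD = 1 - TM$) is a legitimate and practically
  occurring parameterization, so rejecting it would be wrong. During
  fitting the constraint is enforced by construction -- the optimizer
  works on $s = P_{50}^n \in (0, \tfrac12]$ via a scaled logistic
  transform -- never by penalties or rejection.
* **No hook downstream.** With degradation and inhibition sharing the same
  $K_{D,P}$, the loss of degradation at high concentrations is always
  compensated by rising occupancy: $TM$, and hence the PD effect, is
  monotone in concentration even where $D$ hooks downward. The test suite
  checks this over 1000 random parameter draws. The corollary matters for
  interpretation: a hook in protein levels need not appear in the
  biomarker, *unless* the PROTAC is non-inhibiting.

`deconvolve_contributions()` splits $TM$ between the two mechanisms.
Since $TM$ is symmetric in $D$ and $I$, the default attribution is the
symmetric (Shapley) one -- each mechanism carries half the interaction
term -- with a sequential degradation-first split available via
`method = "sequential"`. The split is a reporting convention, not physics;
both options are exact decompositions of $TM$.

## Fitting

All models are estimated by unweighted least squares on the
fraction-of-baseline scale (readouts are normalized percent data, so this
is the natural error scale; an observation-weight hook exists but is off
by default). The engine is Levenberg--Marquardt on unconstrained
transformed parameters: log for concentrations, rates, and the
$DC_{max}/DC_{50}$ ratio (which also enforces $DC_{50} < DC_{max}$),
logit for fractions. Five seeded, jittered starts guard against local
minima in the hook surface, with the best RSS kept; starting values come
from data heuristics (depth of the response minimum for $D_{max}$, its
location for $DC_{max}$, the first half-depth crossing for $DC_{50}$).
Transformed parameters are clamped to a wide numerically safe region so
that extreme excursions of the optimizer degrade the objective instead of
throwing.

Specific behaviors:

* `fit_hook()` on hook-free (monotone) data pushes $DC_{max}$ beyond the
  observed range and reproduces the Emax fit there; an
  extra-sum-of-squares F-test (5% level) against the nested Emax model
  then flags that the third parameter is unjustified and recommends the
  simpler model.
* `fit_emax(exclude_above_hook = TRUE)` implements the conventional
  workaround of fitting only concentrations *strictly below* the
  empirical degradation maximum, and records the excluded rows in the
  result so the convention stays auditable.
* `fit_extended_hook()` estimates steady-state parameters from
  pre-steady-state profiles; the half-life can be fixed (single time
  point) or co-estimated (at least two time points -- with one time point
  it is structurally unidentifiable and the call errors). Either mode is
  exposed because typical reports do not state which was used.
* `fit_kcat()` estimates the single mechanistic free parameter with
  binding and cell parameters fixed from orthogonal assays. Data with no
  degradation signal return $k_{cat} = 0$ with a warning rather than a
  spurious positive rate.
* `fit_pd()` composes $TM$ from supplied degradation parameters and
  optional $IC_{50}$-based inhibition, and supports several compounds
  sharing $(P_{50}, n, PD_{min})$ in one simultaneous fit.

Residual errors are treated as additive on the fraction scale (the
residual bootstrap resamples them exchangeably); assay error models are
rarely reported, and additive-on-fraction is the conservative default.

## Inference

`bootstrap_ci()` draws nonparametric *residual* bootstrap resamples:
centered residuals are resampled onto the fitted curve and the model is
refitted from the original estimates. Case resampling is deliberately
avoided -- with 2--3 replicates per concentration it would frequently drop
whole design points. Intervals are percentile 95% by default and fully
reproducible given the seed. `welch_compare()` tests a parameter between
two fits using bootstrap standard errors with Welch--Satterthwaite degrees
of freedom; its type-I error calibrates near the nominal 5% in the test
suite. `kendall_rank_agreement()` computes Kendall's $\tau$ (tau-b) for
comparing compound rankings between models.

## Experimental design

`min_incubation_time()` answers "how long must I incubate before fitted
parameters can be read as steady-state values?". Criteria: the apparent
$DC_{50}$ within a 1.5-fold factor, and the apparent $D_{max}$ within 5
percentage points, of their steady-state values, for profiles evolving
with the exponential-approach kinetics above on a hyperbolic steady-state
shape. The apparent $DC_{50}$ at time $t$ is defined as the concentration
where the time-$t$ profile reaches half the *steady-state* $D_{max}$;
this operational convention was chosen because it is the one whose
integer-hour grid matches the reference table reproduced in the test
suite cell-for-cell. Under the default tolerances the $DC_{50}$ criterion
always binds and admits the closed form

$$t^\ast = t_{1/2,P}\,(1 - 0.6\,D_{max})\,\ln 6 / \ln 2,$$

rounded up to whole hours; the generic simulate-then-solve route is kept
alongside (and is what the `"simulate"` method and non-default tolerances
use), with closed-form/simulation agreement property-tested on random
inputs. Both criteria remain implemented so that non-default tolerances
behave sensibly even where the $D_{max}$ criterion would bind.

Practical reading: waiting times scale linearly with half-life and shrink
with deeper degradation. For targets with half-lives beyond ~24 h the
required times exceed feasible incubations -- that is precisely when the
extended hook model, not a longer experiment, is the right tool.

`recommend_concentrations()` lays out a log-spaced grid, symmetric about
the predicted $DC_{max}$ (from $\sqrt{K_{D,P}K_{D,E}}$ or a prior fit),
spanning at least four decades and widened downward until the predicted
degradation falls below 5% of $D_{max}$ -- guaranteeing points in the
no-effect, rising, peak, and hook regions. Covering the hook region is
not cosmetic: it is what makes $DC_{max}$ identifiable and provides
direct evidence of the degrader mechanism.

## The synthetic-data generator

`synthetic_truth()` / `simulate_dataset()` generate the datasets used by
every recovery, calibration, and round-trip test: log-spaced
concentration series (typically 10 points), one or more incubation
times, 3 replicates, and additive Gaussian noise with sd 0.05 on the
fraction scale (multiplicative noise via a CV is available), truncated to
$[0, 1.2]$ as normalized readouts are. These settings emulate
plate-reader or Western-blot degradation assays in their replication and
noise level.

What the generator does *not* emulate -- and what passing tests therefore
do not demonstrate about real data: systematic normalization drift between
plates, concentration-dependent error (cytotoxicity and solubility
artefacts concentrate at the top of the range), correlated replicates,
and model misspecification (real ternary-complex kinetics, nonequilibrium
binding, protein-binding corrections to the applied concentration).
Recovery results here certify the estimation machinery, not assay
biology.

## Numerical choices and degenerate inputs

* $C = 0$ is always handled by analytic limits ($TE = D = I = 0$), never
  by evaluating $1/C$.
* Both quadratic roots in the package (exact engagement, mechanistic
  $DC_{50}$) use the stable smaller-root form.
* Optimizer ties are broken by best RSS across the seeded multi-start;
  refits inside the bootstrap use a single start from the original
  estimates for speed and stability.
* Simulation problem sizes in the shipped tests: 100 datasets for the
  noisy recovery study, 200 datasets with 200 bootstrap resamples for
  coverage, 200 null repetitions with 100 resamples for the Welch
  calibration. These sizes put Monte Carlo error comfortably inside the
  asserted bands while keeping the default suite quick.
* All randomness (generator, multi-start jitter, bootstrap) flows through
  explicit integer seeds, and package functions restore the caller's RNG
  state.

## A worked example

```{r}
# simulate a 6 h profile from steady-state parameters, then ask what a
# plain hook fit at 6 h would report
steady <- extended_hook_params(hook_params(0.949, 0.29, 68.9),
                               half_life = 45)
d6 <- simulate_dataset(synthetic_truth(
  "extended_hook", steady, concentrations = 10^seq(-3, 4, length.out = 40),
  times = 6, replicates = 1, noise_sd = 0, seed = 1))
coef(fit_hook(d6))
```

At 6 h the apparent $D_{max}$ is ~80% (steady state: 94.9%) and the
apparent $DC_{50}$ is inflated roughly eight-fold -- the quantitative
reason incubation-time planning and time-aware fitting exist. Refitting
the same truth at 24 h brings $D_{max}$ close to (and, as a fitting
artefact of the flattened peak, marginally above) its steady-state value
while $DC_{50}$ is still about double -- $DC_{50}$ is the slowest
parameter to converge, and $DC_{max}$ is essentially time-invariant.

## Known limitations

* No pharmacokinetics: concentrations are constant unbound in vitro
  exposures; in vivo dosing is out of scope.
* The unbound intracellular concentration is taken equal to the applied
  medium concentration (no protein-binding or permeability correction).
* Ternary-complex formation is modeled at rapid equilibrium;
  ubiquitination-chain and proteasome kinetics are subsumed into the
  single rate constant $k_{cat}$.
* The exact engagement solution (with finite $P_0$) exists for
  biochemical-assay settings; the cellular models deliberately use the
  ligase-unsaturated form throughout.
* `required_affinity_change()` searches a single shared fold-change over
  the chosen binding parameters. This keeps the answer unique and
  interpretable; independent per-parameter searches are a deliberate
  non-feature of the default interface.
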