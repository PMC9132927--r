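---
title: "Additivity models for chemical-mixture toxicity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additivity models for chemical-mixture toxicity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixadd)
```

## The problem

Organisms are exposed to chemical *products* — mixtures — far more often
than to single substances, yet toxicity testing of every combination is
combinatorially hopeless: an inventory of just twenty chemicals already
admits `r format(enumerate_mixture_count(20, 2))` binary blends and over a
million mixtures of three or more components
(`enumerate_mixture_count(20, c(3, 20))`). Additivity models bridge the
gap: they predict a mixture's dose–response behaviour from the
dose–response curves (DRCs) of its components, without any mixture
experiment. `mixadd` implements the four standard additivity constructions
plus a fallback for data-poor settings, together with the curve
infrastructure they need.

## Dose–response curves

A DRC maps a strictly positive concentration $c$ to a fractional effect
$E \in [0, 1]$ and is monotone non-decreasing. The registry implements 13
regression models in the parameter conventions of the mixture-ecotoxicology
literature, serialized in $(\alpha, \beta, \gamma, \delta)$ order with
trailing parameters omitted:

| family | form ($x = \log_{10} c$) | parameters |
|---|---|---|
| `Logit` / `Logit_three` / `Logit_four` | $\delta + (\gamma-\delta)\,\mathrm{logistic}(\alpha + \beta x)$ | location $\alpha$, slope $\beta > 0$, asymptotes |
| `Weibull` / `Weibull_three` / `Weibull_four` | $\delta + (\gamma-\delta)\,[1 - e^{-e^{\alpha + \beta x}}]$ | as above |
| `Hill` / `Hill_three` / `Hill_four` | $\delta + (\gamma-\delta)/[1 + (\alpha/c)^\beta]$ | $\alpha$ = EC50-type location |
| `Hill_two` | $\beta c/(\alpha + c)$ | $\beta$ is the asymptote |
| `BCW` / `BCL` | Weibull/logit link on the Box–Cox axis $(c^\gamma-1)/\gamma$ | exponent $\gamma \neq 0$ |
| `GL` | $[1 + e^{-\alpha-\beta x}]^{-\gamma}$ | generalized logit |

Every model carries a closed-form inverse, an analytic maximum attainable
effect (the asymptote $\gamma$ for the three-parameter families — a
*partial agonist* has $\gamma < 1$) and, for the Box–Cox families, a
restricted effect range whose limits are computed from the model's
behaviour at $c \to 0^+$ and $c \to \infty$. Effects are fractions
internally; reports print percent.

Fitting (`fit_drc()`) is nonlinear least squares by Levenberg–Marquardt
with five deterministic starting points derived from link-scale linear
regression of the data, so fits are seedless and reproducible; the lowest
residual sum of squares wins, and the parameter covariance is kept for the
bootstrap. On noise-free data every registered model recovers its
generating parameters to well below $10^{-4}$ relative error (this is a
test invariant).

### Units

Five concentration units are supported — nM, µM, mM (molar) and µg/L,
mg/L (mass) — with exact metric arithmetic inside each family and
molecular-weight conversion across the boundary. Composition fractions are
interpreted on the basis of the working unit (molar fractions for molar
units, mass fractions for mass units); consequently predictions are
unit-invariant exactly when a unit change rescales all components equally
(always within a family; across the boundary when molecular weights
coincide). Conversions are linear, so the engine precomputes one scale per
component and keeps string handling out of the solver loops.

### The predictable effect range

A mixture prediction at effect level $e$ needs every component inverse
$f_i^{-1}(e)$; a level at or above some component's asymptote is
*unattainable* there. `predictable_effect_range()` therefore truncates the
requested grid (default 10–90% in decadal steps) to the levels strictly
inside every curve's attainable interval, and grid points outside it are
omitted from reports rather than reported as failures. A mixture of
partial agonists whose weakest asymptote is, say, 0.65 reports a 10–60%
table; a component topping out below the lowest requested level raises a
"no predictable range" error.

## The additivity models

Writing $p_i$ for composition fractions ($\sum p_i = 1$) and $c$ for the
total mixture concentration in the output unit:

**Concentration addition** (CA, Loewe additivity; similar modes of
action). The effective concentration at level $e$ has closed form
$$c_e = \Big(\sum_i p_i / f_i^{-1}(e)\Big)^{-1},$$
the reciprocal fraction-weighted harmonic combination of component
effective concentrations.

**Independent action** (IA, Bliss independence; dissimilar modes of
action) combines non-responses at the scaled doses:
$$E(c) = 1 - \prod_i \big(1 - f_i(p_i c)\big),$$
inverted numerically for effective concentrations. Below a component's
numerical domain its factor is 1 (no effect) — the well-known IA behaviour
around no-observed-effect concentrations. IA's attainable supremum is
$1 - \prod_i (1 - \max_i)$.

**Generalized concentration addition** (GCA) extends CA to mixtures
containing partial agonists by solving, at fixed $c$,
$$\sum_i \frac{p_i\,c}{f_i^{-1}(E)} = 1 \quad \text{for } E,$$
with each Hill-family inverse continued past its asymptote: for a
Hill-three curve the reciprocal inverse is
$(\gamma/E - 1)^{1/\beta} / \alpha$, which passes smoothly through zero at
$E = \gamma$ and goes negative above it. That continuation is exactly the
classical construction at Hill slope $\beta = 1$; for $\beta \neq 1$ the
signed power $\mathrm{sign}(u)\,|u|^{1/\beta}$ is used, a package choice
documented here because the literature defines the extension canonically
only at slope 1. Non-Hill families have no such continuation and instead
cap the feasible effect at their own asymptote. The left side is strictly
decreasing in $E$, so the solver is a plain bisection. Two consequences
worth knowing:

* whenever every grid level lies below all component asymptotes, the GCA
  solution coincides with CA (a test invariant), and
* GCA can predict levels *above* the weakest partial agonist's asymptote,
  which CA cannot reach at any concentration.

**Simple CA** covers the data-poor case of a safety data sheet that lists
only summary endpoints: $\mathrm{EC50}_{mix} = (\sum_i w_i /
\mathrm{EC50}_i)^{-1}$. The weights are used **exactly as entered, not
renormalized** — a worst-case scenario built from the maxima of published
composition ranges may sum to less than 1, and renormalizing would change
the answer. Only a scalar endpoint is produced; no curve is plotted.

**Two-stage prediction** (TSP) handles mixtures containing both similar
and dissimilar modes of action: components are grouped into putative
mode-of-action (MoA) clusters from structure alone, then CA is applied
within each cluster and IA across clusters. Stage 1 treats cluster $g$
(total fraction $P_g$, internal fractions $q_i = p_i / P_g$) as a
pseudo-chemical whose effect at dose $d$ solves
$\sum_{i \in g} q_i d / f_i^{-1}(E) = 1$; stage 2 combines cluster effects
by IA at doses $P_g c$. The degenerate cases are exact reductions: one
cluster ⇒ CA, all singletons ⇒ IA (test invariants at $10^{-6}$
relative). Note the construction does not guarantee that the TSP EC50
falls between the CA and IA EC50s — with one dominant cluster, IA across
clusters can sit slightly above full CA.

### Structure-based MoA grouping

For three or more components the pipeline is descriptors → PCA → k-means:

* **Descriptors** (`compute_descriptor_matrix()`): an open set built from
  OpenBabel physicochemical properties (logP, TPSA, molar refractivity,
  H-bond counts, ...), element counts, and hashed path- (FP2) and
  circular-environment (ECFP6) fingerprint occupancy features — about
  5000 raw columns on a typical pesticide set. Undefined and constant
  columns are dropped and the rest standardized. Commercial descriptor
  engines used in this field are server-bound and not redistributable, so
  exact cluster reproduction against tools built on them is not
  guaranteed; the pipeline's *structure* (descriptors, PCA compression,
  k-means, CA-within/IA-across) is independent of the descriptor vendor.
* **PCA** (`pca_reduce()`): retains the fewest components reaching 95%
  cumulative explained variance (configurable); each score column's sign
  is fixed so its largest-magnitude loading is positive, making the
  pipeline reproducible bit-for-bit.
* **k selection** (`select_k()`): the number of MoA groups maximizes the
  mean silhouette width over $k \in \{2, \dots, \min(n-1, 8)\}$, ties
  toward fewer clusters; a user-supplied `k` always wins. k-means runs
  with a fixed seed (default 20220525) and 25 restarts, and labels are
  renumbered by first occurrence so they are stable across runs and row
  orders.
* **Binary mixtures** bypass clustering: ECFP6 (diameter-6 circular)
  fingerprint Tanimoto similarity strictly above 0.7 implies a shared MoA
  and CA; at or below 0.7, IA. The threshold is strict by design. The
  fingerprints are kept at the backend's native 4096-bit hashed width:
  folding to 2048 bits measurably inflates collision error (benzene vs
  toluene moves from 0.211 to 0.167, against 0.214 from an independent
  Morgan-radius-3 implementation).

## Confidence intervals

Result tables can carry `[2.5th; 97.5th]` percentile intervals from a
parametric bootstrap of the component curve parameters: draws come from
the fitted parameter covariance when the curve was fitted in-package, and
otherwise — curves entered as bare parameter sets, as in the packaged case
studies — from a documented default 5% relative Gaussian perturbation.
The interval method is this package's own choice; treat the bands as
sensitivity envelopes, not as inferential intervals, when the covariance
is the default one. The bootstrap is seeded per call and restores the
caller's RNG state.

## Numerical choices

* All inversions are deterministic bisections — on $\log_{10} c$ for
  concentration solves (bracket auto-expanded one decade at a time from
  the model midpoint; absolute effect tolerance $10^{-9}$) and on $E$ for
  the GCA/cluster solves (interval tolerance $10^{-13}$). Monotonicity of
  every registered curve makes bisection robust and derivative-free.
* Concentration 0 is outside the model domain (log-concentration models
  are undefined there); callers must use strictly positive doses.
* Components with fraction 0 are dropped with a warning; duplicate CAS
  numbers are allowed (sub-mixtures can repeat a chemical) but warned
  about.
* Inversion round-trips hold to $10^{-8}$ on effects and unit-conversion
  round-trips to machine precision; CA/IA predictions agree with a
  $10^5$-point grid-search oracle to better than 0.1% (all test
  invariants).

## Packaged examples and the synthetic generator

Three case studies ship in the template dialect the reader writes
(`case_study_fixture()`):

* **cs2** — a four-component coating product known only from its safety
  data sheet: worst-case composition maxima (summing to 0.90) and
  *Daphnia magna* 48-h EC50s, as published. Simple CA gives 15.314 mg/L;
  this value is asserted in the acceptance tests.
* **cs1** — a 23-component pesticide mixture with mixed MoAs for the
  CA/IA/TSP comparison. The structures are real pesticides; the
  composition fractions and DRC parameters are **synthetic stand-ins**
  generated once under a fixed seed (the study design it mirrors
  published only the resulting predictions, not the component parameter
  table). Predictions on cs1 therefore exercise every code path with
  realistic magnitudes but do not reproduce any published table.
* **cs3** — three perfluorinated carboxylic acids as partial agonists
  (Hill-three, asymptotes 0.65–0.80, again synthetic stand-ins mirroring
  a published study design); the weakest asymptote truncates the decadal
  grid at exactly 10–60%, exercising predictable-range handling and GCA.

`generate_synthetic_mixture()` draws mixtures with fully known ground
truth: EC50s log-uniform over a configurable range (default 0.05–20 µM,
spanning the potency spread typical of pesticide mixture studies), slopes
uniform in 1.2–3.5, equal or Dirichlet fractions, and a configurable share
of Hill-three partial agonists with asymptotes in $[0.5, 0.9)$.
Generation is seed-reproducible and returns the generating truth for
oracle tests. What passing tests on such data show is that the *engine* is
correct — curve inversion, additivity algebra, range truncation,
clustering determinism; what they cannot show is fidelity to any
particular laboratory mixture, since real data add observation noise,
model misspecification and inter-laboratory endpoint variation that the
generator deliberately omits.

Problem sizes throughout the suite (mixtures of 2–23 components, decadal
grids, $10^5$-point oracles, 20–50 bootstrap draws in tests) were chosen
as the smallest that exercise each code path convincingly.

## Limitations

* Only monotone additivity is modelled: no hormesis, no
  synergism/antagonism, no time-resolved toxicity, and no exposure or
  risk characterization.
* The MoA clustering is a structural heuristic; chemicals with similar
  scaffolds but different targets will be co-clustered.
* The GCA slope extension beyond $\beta = 1$ is a pragmatic continuation,
  not a mechanistic claim.
* Spreadsheet I/O is delimited-text only (CSV/TSV, which spreadsheet
  applications read and write directly); structure input accepts SMILES
  lists, MOL and SDF.
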