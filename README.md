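# mixadd — additivity models for chemical-mixture toxicity

Risk assessors increasingly have to judge *products* — mixtures of
chemicals — rather than single substances, and no laboratory can test
every combination: twenty chemicals already admit 190 binary blends and
over a million mixtures of three or more components. `mixadd` predicts a
mixture's toxicity from the dose–response curves (DRCs) of its
components using the standard additivity constructions of mixture
ecotoxicology:

* **CA** — concentration addition (Loewe additivity), for components with
  a similar mode of action (MoA):
  `EC_e,mix = (Σ_i p_i / EC_e,i)^-1`;
* **IA** — independent action (Bliss independence / response addition),
  for dissimilar MoAs: `E(c) = 1 − Π_i (1 − f_i(p_i c))`;
* **GCA** — generalized concentration addition, which solves
  `Σ_i p_i c / f_i^{-1}(E) = 1` with inverse functions continued past the
  asymptote, so mixtures containing *partial agonists* (maximal effect
  below 100%) can be predicted at levels CA cannot reach;
* **TSP** — a structure-based two-stage prediction for mixtures with both
  similar and dissimilar MoAs: molecular descriptors → PCA → k-means
  cluster the components into putative MoA groups, then CA applies within
  groups and IA across them (binary mixtures instead use an ECFP6
  Tanimoto similarity rule: > 0.7 ⇒ CA, otherwise IA);
* **Simple CA** — a fallback for safety-data-sheet settings where only
  summary EC50/LC50 values exist: `EC50_mix = (Σ_i w_i / EC50_i)^-1`,
  with the composition weights used exactly as entered.

Around these sit a registry of 13 monotone DRC regression models
(Hill/Weibull/Logit families, Box–Cox and generalized-logit variants)
with closed-form inverses, nonlinear least-squares fitting, exact
inter-conversion of nM/µM/mM/µg/L/mg/L, automatic determination of the
*predictable effect range* (grids truncate where a weak component's
asymptote makes a level unattainable), bootstrap confidence intervals,
delimited-text mixture templates, structure input (SMILES/MOL/SDF) and a
command-line interface. The methods and design decisions are documented
in `vignettes/mixture-additivity.Rmd`.

## Worked example

Three case studies are packaged (`case_study_fixture()`). The mixture of
three perfluorinated carboxylic acids is a partial-agonist case: the
weakest component tops out at 65% effect, so the decadal grid truncates
automatically at 60%:

```r
library(mixadd)
cs3 <- case_study_fixture("cs3")
p   <- predict_mixture(cs3, c("CA", "IA", "GCA"), bootstrap_n = 200, seed = 1)
print(p)
#> Mixture toxicity prediction for 'perfluorinated carboxylic acid mixture' (EC50, uM)
#>   Effect grid (% vs uM):
#>     effect CA                      IA                      GCA
#>        10% 5.879 [5.102; 6.594]  6.592 [5.436; 7.695]  5.879 [5.102; 6.594]
#>        20% 12.204 [10.878; 13.498]  12.840 [10.966; 14.422]  12.204 [10.878; 13.498]
#>        30% 20.596 [18.412; 23.060]  19.857 [17.419; 22.096]  20.596 [18.412; 23.060]
#>        40% 33.271 [29.529; 38.703]  28.238 [25.057; 31.469]  33.271 [29.529; 38.703]
#>        50% 56.396 [47.330; 71.731]  38.841 [34.661; 43.027]  56.396 [47.330; 71.731]
#>        60% 120.392 [89.022; 184.526]  53.243 [48.005; 59.548]  120.392 [89.107; 236.149]
#>   Lowest predicted EC50: 38.84 uM (IA)
```

Each row is the mixture concentration predicted to produce that effect
level, with `[2.5th; 97.5th]` bootstrap percentiles; the "lowest
predicted EC50" is the most conservative (most toxic) estimate across
the selected models — here IA, because the partial agonists make the
CA-type models flatten out at high effect levels. The coating-product
example (`cs2`) has no curves at all, only SDS endpoints, and Simple CA
gives its mixture EC50 directly:

```r
predict_mixture(case_study_fixture("cs2"), "SimpleCA")
#>   SimpleCA mixture EC50 = 15.31 mg/L (scalar; no DRC plotted)
```

The same runs work from a shell:

```sh
Rscript inst/cli/mixadd.R --input inst/extdata/cs2_coating_sds.csv \
        --models simple-ca --unit mg/L --output report/
```

Note on fixtures: `cs2` carries published SDS values; `cs1` (23
pesticides) and `cs3` carry **synthetic stand-in** compositions and curve
parameters (their source studies published predictions, not component
parameter tables) with real chemical structures — see the fixture file
headers and the vignette.

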