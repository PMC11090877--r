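---
title: "Methods: diet optimization under nutritional, emission and habit constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet optimization under nutritional, emission and habit constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sustdiet)
```

## The two models and their assumptions

`sustdiet` solves two diet-optimization problems over a universe of food
categories (74 by default, mapped to 16 main categories), differing only
in their objective:

* the **minimum-cost model** minimizes total diet cost $p'x$ — a linear
  program whose solutions are extreme points of the feasible set, and
  therefore typically sparse diets built from very few foods;
* the **minimum-deviation model** minimizes
  $\sum_i \left((x_i - x_i^0)/x_i^0\right)^2$, the sum of squared
  relative deviations from the observed baseline diet $x^0$ — a
  quadratic program whose curvature matrix $\mathrm{diag}(2/x_i^{0\,2})$
  is symmetric positive definite, so the problem is strictly convex and
  its optimum unique.

Both are subject to the same linear constraint families:

* an **isocaloric equality** $e'x = E_0$ fixing energy at its observed
  level — the models study diet *composition*, not energy intake;
* **nutrient adequacy rows** $L_j \le (Ax)_j \le U_j$ for every bounded
  nutrient (by default 61: 30 macronutrients including 9 amino acids,
  13 vitamins, 18 minerals);
* an optional **GHGE cap** $g'x \le \theta G_0$ with $\theta = 2/3$ or
  $1/2$ of the baseline emission level;
* a **dairy–beef jointness row**
  $\rho \sum_i b_i x_i - \sum_i r_i x_i \ge 0$: each gram of beef carcass
  is co-produced with $\rho$ grams of raw milk, so a diet's raw-milk
  demand must be covered by the beef-carcass demand its meat consumption
  implies;
* **food-habit box bounds** $P10_i \le x_i \le P90_i$ (minimum-deviation
  model only) at the empirical 10th/90th centiles of per-person
  consumption; the minimum-cost model carries only non-negativity.

The jointness row is included in both models: it describes the food
system, not a property of either objective. The relative-deviation
objective implicitly assumes that a 1% change is equally hard for every
food; this is the standard acceptability proxy in this literature, and
the habit bounds temper its weaknesses at the tails.

## Parameters that matter

| Parameter | Unit | Default | Why |
|---|---|---|---|
| quantities | g/capita/d | — | matches how intake surveys report consumption |
| prices | EUR/g | — | avoids per-100g ambiguity; totals print as EUR/cap/d |
| GHGE coefficients | g CO2e/g | — | totals reported as kg CO2e/cap/d |
| `milk_per_beef` ($\rho$) | g milk / g beef carcass | 33.9 | Finnish dairy-chain estimate |
| beef-carcass fractions | — | beef 1.0, offal 0.88, meat products 0.5, sausages/sausage cuts/meat cuts 0.075 | published composition of the relevant categories |
| `amino_safety_multiplier` | — | 1.24 | amino-acid requirement plus 24% safety margin, appropriate when inputs are group means rather than usual-intake distributions |
| energy conversion factors | kJ/g | fat 37, protein 17, carbohydrate 17, alcohol 29 | standard Atwater-type factors used to linearize %E bounds |
| `iron_rule_female` | — | on | the female iron lower bound equals baseline iron intake: under the isocaloric equality this restates "keep the iron concentration of the current diet" exactly |
| $\theta$ | — | 2/3 or 1/2 | the two emission-reduction scenarios |
| feasibility / binding tolerance | — | 1e-6 | conventional for double-precision LP/QP |

Percent-of-energy bounds are linear only because $E_0$ is fixed: the row
for a %E nutrient uses coefficients $c_j a_{ji}$ (conversion factor times
component density) with bounds $L_j E_0 / 100$ and $U_j E_0 / 100$.

## What the synthetic generator emulates — and what it does not

No deposited dataset exists for the Finnish application: the dietary
intake survey, the household budget survey behind the unit-value prices,
and the life-cycle emission coefficients are all access-restricted. The
generator therefore reproduces the *statistical structure* the analysis
needs, not Finnish values:

* 74 food categories in the 16 standard main categories, with
  animal-source categories (meat, dairy, fish, eggs) given elevated
  prices and emission coefficients (beef and offal markedly so), and the
  published beef-carcass fractions and dairy raw-milk equivalents;
* energy-component fractions per food chosen so that
  $17 a_{protein} + 37 a_{fat} + 17 a_{carb} + 29 a_{alc} = e_i$ holds
  exactly, making the %E machinery self-consistent;
* nutrient densities strictly positive everywhere with plausible
  concentration patterns (iron in meat, calcium in dairy, vitamin C in
  produce, fiber in plant staples), but deliberately broad-based so that
  substitution between categories remains nutritionally possible — as it
  is in real food supplies;
* per-person consumption simulated as zero-inflated lognormals (sigma
  0.8, category-specific never-eater probabilities), yielding
  right-skewed distributions whose 10th centile can be zero for rarely
  eaten foods — so habit bounds can permit exclusion, as observed;
* baseline diets scaled to hit the energy target exactly: 7311 kJ/d for
  females, 28% higher (9358 kJ/d) for males;
* nutrient bounds placed at `slack_lo = 0.8` and `slack_hi = 1.5` times
  the baseline-implied intake, so the baseline is feasible by
  construction and the health-only minimum-deviation solution is the
  baseline itself. Amino-acid bounds are generated *before* the safety
  margin (i.e. at `slack_lo / 1.24` times baseline) so that the
  effective, post-margin bound honours the slack semantics. In **stress
  mode** the lower bounds of a plant-rich subset (vitamin C, folate,
  fiber) are raised 10% above baseline, making the baseline infeasible
  and forcing genuine optimization in the same direction as an emission
  cap would push.

`generate_dataset()` additionally *certifies* scenario feasibility: it
minimizes GHGE subject to the health-only constraint set (an LP) and, if
even that minimum exceeds half the baseline, deterministically widens the
habit bounds (raising P90 for low-emission foods, lowering P10 for
high-emission ones) and re-checks. This implements the generator's
contract that every scenario of both models is solvable on generated
data.

What passing tests on this generator demonstrate is that the *machinery*
is correct — constraint assembly, solver behaviour, conservation
identities, decomposition exactness, cap attainment. They do not
demonstrate anything about real Finnish prices, intakes or emission
coefficients; the packaged reference tables carry the published numbers,
and real data can be supplied through the CSV schemas
(`read_universe()`, `read_group()`, `bounds.csv`).

## Numerical choices

* **LP** solved by the simplex implementation in `boot`; **QP** by the
  dual active-set method in `quadprog`. Both receive rows scaled to unit
  maximum coefficient, which keeps kJ-scale energy rows and EUR-scale
  price data well conditioned in one system. An always-satisfied wide
  row is appended when a system has no finite upper-bounded row, working
  around a corner case in the simplex routine.
* The QP is solved in the original intake variables with the curvature
  matrix supplied explicitly (no substitution $z_i = x_i/x_i^0$);
  the diagonal matrix factors exactly, and keeping grams as the variable
  makes the binding-set report directly interpretable.
* Fixed variables ($P10_i = P90_i$) and equality rows enter the QP's
  equality block rather than as opposing inequalities.
* Solutions are snapped onto the variable box after solving (removing
  ~1e-12 negative roundoff), and every reported objective and total is
  recomputed from the returned diet, never read from solver internals.
* A solution is *optimal* only if an independent dense re-evaluation of
  every row confirms feasibility within 1e-6 (row-scaled); constraints
  with absolute scaled slack below 1e-6 are reported binding.
* Minimum-cost optima can be degenerate: the *diet* returned is "a"
  minimum-cost diet; only the objective value is contractually unique.
  Reported food lists from the LP should be read accordingly.
* Infeasibility is diagnosed by one-at-a-time family relaxation (drop
  all rows of one family, re-test feasibility) — bounded effort with
  actionable output, rather than a full irreducible-infeasible-subset
  search.
* Quantile strata (income tertiles/quintiles) use type-7 empirical
  quantiles with ties assigned to the lower stratum: deterministic and
  invariant to monotone rescaling of income. Habit percentiles use the
  same estimator on unweighted samples; survey weights are out of scope.
* In the decomposition, a category with zero baseline quantity has no
  baseline mean unit value; by convention its whole change is counted as
  inter-category.

## Design decisions on genuinely open points

* **Decomposition weighting.** The additive split uses baseline
  (Laspeyres-type) category mean unit values for the inter term and
  assigns the residual at final quantities to the intra term. This is
  the simplest exact two-term additive scheme consistent with the
  published table structure; a Paasche-type (final-weighted) variant
  would also be exact, and the published values alone cannot adjudicate
  between them.
* **Unpriced foods.** Expenditure surveys cover foods and non-alcoholic
  beverages, so some categories (notably alcohol) have no matched source
  price; `category_price()` flags them and a user-supplied fallback
  price is expected rather than silently imputed.
* **No alcohol-specific constraint.** Alcohol is restrained only through
  the nutrient bounds (its %E component) and, in the minimum-deviation
  model, its habit bounds; the minimum-cost model is free to zero it
  out, and does.
* **Raw-milk equivalents** for processed dairy are inputs (the
  published work states the beef side of the jointness but not
  per-product milk yields); the generator assigns 1 g/g for liquid
  milks, 2.5 for fresh products, 9 for cheeses.
* **Reporting rounding.** Internal values stay at full precision; cost
  and GHGE print at 2 decimals, shares at 2 decimals, percentages as
  integers — rounding happens only at presentation.

## Problem sizes used in the test suite

Unit and property tests run on reduced instances (20 foods in 8 main
categories, 120 simulated persons) chosen to exercise every code path
quickly; solver-oracle comparisons use 2–6 food instances where
brute-force vertex enumeration and projected-gradient references are
exact and fast. The acceptance-level suites run the full default
configuration (74 foods, 61 nutrients, 780 persons) over 20 seeds for
baseline recovery and cap-monotonicity, which keeps the whole suite
under a minute on one core.

## Known limitations

* The universe is at food-ingredient-category level; no recipe
  disaggregation from foods as eaten is performed, and valuing
  ingredients rather than final foods will understate absolute costs
  (relative comparisons are unaffected if the bias is systematic).
* No integer constraints, meal structure, seasonality, multi-objective
  weighting or consumer-surplus ("taste cost") objectives.
* The generator guarantees feasibility by construction; it is not an
  estimator of any real population's intake distribution, and its
  defaults should not be tuned to chase published point values.
* Survey weights are not applied anywhere; all sample statistics are
  unweighted.
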