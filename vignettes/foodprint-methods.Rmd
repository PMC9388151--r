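---
title: "Estimating the environmental impact of multi-ingredient food products"
author: "foodprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the environmental impact of multi-ingredient food products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodprint)
```

## The problem

The environmental impact of a packaged food product is determined by the
mass and the production impacts of each of its ingredients, but the
quantitative recipe of a retail product is almost always a trade secret.
What *is* public, in the UK and Ireland, is the back-of-pack ingredient
list: ingredients must be listed in decreasing order of mass, and the
percentage of "characterizing" ingredients (the beef in a beef lasagna)
must be printed (the QUID rule).  `foodprint` turns that partial
information into per-100 g estimates of four environmental indicators —
greenhouse gas emissions (kg CO2e), land use (m2), scarcity-weighted
water use (L-eq) and aquatic eutrophication potential (g PO4e) — plus a
composite 0–100 impact index and a NutriScore-based nutrition impact
score, and ships the masking harness used to quantify how accurate the
estimates are.

## Composition inference

For a product with $n$ ingredients, the unknown composition
$p_1,\dots,p_n$ (percent by mass) lives on the polytope

$$ p_i \ge 0,\qquad \sum_i p_i = 100,\qquad p_1 \ge p_2 \ge \dots \ge p_n, $$

with declared (QUID) values fixed.  Two legal subtleties are honored:

* **Small-quantity exception.**  Ingredients at or below 2% may legally
  be listed in any order, so an order inversion between two *declared*
  values at or below 2% is accepted verbatim (the labels are ground
  truth) and the ordering chain is cut at that link.  Larger inversions
  are reported as infeasible labels.  Free (estimated) quantities are
  kept fully monotone even below 2%: that stricter choice can never make
  a feasible label infeasible, and it keeps the projection deterministic.
* **Concentrated ingredients.**  Declared values may exceed 100 g per
  100 g of product (dried meat declaring 150% raw beef).  When the
  declared sum exceeds 100, declared values are rescaled to sum to 100
  and the excess is carried as a per-ingredient raw-equivalent factor, so
  impact scoring still accounts for the full raw-commodity mass.

`feasible_bounds()` computes the exact attainable interval of every
ingredient over this polytope.  The chain structure makes this analytic:
a free position $j$ is bracketed by the nearest declared values in its
chain segment, and a candidate value $c$ is attainable iff (i) the
smallest free mass consistent with it — predecessors pushed down to
$\max(L_i, c)$, everything else at its lower envelope — does not exceed
the undeclared mass, and (ii) the largest consistent free mass —
successors capped at $c$, everything else at its upper envelope —
reaches it.  Both mass functions are monotone in $c$, so each endpoint is
a bisection; the all-lower and all-upper profiles are themselves valid
monotone fillings, which is what makes the interval characterization
exact rather than a relaxation.  The test suite cross-checks these
bounds against an independent brute-force sweep of the 0.1%-resolution
grid for products with up to four ingredients.

`infer_composition()` then fills in the unknowns deterministically:

1. each unknown is initialized from the **prior**: the median declared
   percentage observed for the same (food category, rank bucket) cell in
   the corpus, falling back to the category marginal, the rank-bucket
   marginal (ranks are bucketed 1, 2, 3, 4, 5+ to keep the sparse tail
   populated), and finally the midpoint of its feasible interval;
2. the unknowns are rescaled to absorb exactly the undeclared mass;
3. the vector is projected onto the ordering constraints by weighted
   pool-adjacent-violators with declared entries held fixed;
4. every unknown is clipped to its feasible interval;

steps 2–4 iterate to a fixed point (mass change below $10^{-6}$, at most
100 iterations), and a final bounded redistribution removes any residual
mass.  The procedure involves no randomness.  The median was chosen as
the cell statistic because declared compositions are strongly
right-skewed; "similar products" is operationalized as same category and
rank bucket.  Products are only *presented* when at least 75% of their
estimated mass maps to a known food category (`coverage_gate()`,
inclusive threshold).

## Monte-Carlo impact estimation

Ingredient sourcing (country, production system) is not printed on
packs, so a single intensity per ingredient would misstate certainty.
Each food category in the environmental database carries multiple
production observations (four intensities per kg of raw commodity plus a
production-share weight).  `monte_carlo()` repeatedly (default 1000
iterations; the draw count is configurable) samples one observation per
ingredient with probability proportional to its weight and accumulates

$$ \text{impact} = \sum_i \frac{p_i}{100}\; f_i\; \iota_i \times 0.1 , $$

where $f_i$ is the raw-equivalent factor and the 0.1 converts per-kg
intensities to a per-100 g basis.  Fish categories first choose
aquaculture versus wild-capture with probability 1/2 each (the assumed
50:50 production split) and then sample within the chosen system.
Organic ingredients sample from the category's organic observations when
at least five exist, and from all systems otherwise.  Post-retail
processing, packaging and transport are excluded from the system
boundary.  Each indicator is summarized by mean, SD and the 5/10/25/50/
75/90/95th percentiles; draws are common-random-number aligned so two
runs under the same seed (e.g. a masked and an unmasked estimate) see
identical sourcing draws.

## The composite 0–100 index

Each indicator is linearly scaled so the highest-impact product of the
scored corpus sits at 100 (half the impact scores 50), the four scaled
values are averaged with equal weights, and the average is rescaled to
put the corpus maximum at 100.  The index is therefore linear — a
product scoring 20 has one fifth of the impact of the top product — and
deliberately corpus-relative: scores are only comparable within one
scored corpus, and the reference maxima are attached to every result so
new products can be scored against a frozen reference
(`composite_from_reference()`).  An indicator that is zero across the
whole corpus contributes 0 with a warning.  Per-serving scores are the
per-100 g scores times serving/100, with missing serving sizes borrowed
from the mean of same-Shelf (then same-Aisle) products, averaging the
per-label means for products categorized to several Shelves or Aisles.

## NutriScore

Nutrition quality uses the 2017 Santé Publique France / FSA
nutrient-profiling tables, shipped as an editable YAML resource
(`ns_thresholds()`): four penalty components (energy, saturated fat,
sodium, sugars; 0–10 points each) minus three reward components
(protein, fiber, fruit/vegetable/nut/specified-oils content; 0–5 each),
with beverage variants (including the 0–2–4–10 fruit ladder), the
added-fats saturated-to-total-fat ratio table, the protein cap (protein
not counted when penalties reach 11 unless the fruit component is at its
maximum; cheese exempt) and food-type-specific A–E cut-points.  The
total in $[-15, 40]$ maps to the letter, to the numeric score 1–5 used
for averaging across products, and affinely to the 0–100 nutrition
impact scale, $100\,(t+15)/55$.  Alcoholic products are rejected —
the profiling model does not account for alcohol.  Which table revision
the upstream work used is not stated; the 2017 tables in force in
2019–2022 are assumed, and since all logic reads the YAML resource a
revised table is a drop-in replacement.

## Masking validation

`run_validate()` reproduces the accuracy protocol end to end.  The
validation set contains every product whose composition is fully known
from the label: all or all but one ingredient declared (the missing one
filled by the sum-to-100 residual), more than one ingredient, declared
values summing to 100.  For each product the *known* score comes from
the declared composition; then, for each masking level $m$, up to 100
random unique combinations of $m$ declared values are hidden (order
retained), the composition is re-inferred with the corpus prior, and the
impact is re-estimated under the same Monte-Carlo seed.  Accuracy is
recorded both as $\log_2(\text{estimated}/\text{known})$ and as the
percent difference; `summarize_accuracy()` reports the mean difference
with a normal-approximation CI, the fractions within 10% and 25%, and
the mischaracterization fractions outside $[2/3, 3/2]$ and $[1/2, 2]$ of
the known score.  With nothing masked the estimated score equals the
known score exactly (shared draws), which anchors the harness.

Two directions are checked statistically on the synthetic corpus: mean
$|\log_2|$ error decreases as the share of known composition grows
(per-trial regression), and the *signed* accuracy shows no trend in
ingredient count (regression on per-count bin means — bias, not
dispersion, is the claim being tested; the absolute error does grow
mildly with ingredient count in the synthetic corpus, which the trial
tables expose directly).

## The synthetic corpus

Real retailer corpora and the production-system databases behind them
are licensed, so the package ships a generator
(`generate_env_db()`, `generate_products()`) that emulates their
structure: 111 food categories (109 commodity categories plus zero-impact
water and salt) with at least five right-skewed lognormal production
observations each (a shared per-farm factor induces cross-indicator
correlation), positive production-share weights, alternating categories
with 6 versus 2 organic observations (so the five-observation organic
rule is exercised on both sides), and a fish category carrying both
aquaculture and capture systems.  True compositions are symmetric
Dirichlet(1) draws sorted descending (guaranteeing the labeling order),
declared percentages are revealed for a Bernoulli subset targeting the
10.4% share observed on real labels with a 2.5-fold bias toward rank 1
(the characterizing-ingredient convention; the capped probabilities are
redistributed so a reveal fraction of 1 declares everything), and
nutrition panels are accumulated from fixed per-category nutrient
profiles so the corpus spans NutriScore classes A–E.  Ingredient counts
run 1–10 with about 4% single-ingredient products, and water is the most
common ingredient, mirroring retail assortments.

What the generator does *not* emulate: brand-level variety, real
synonym noise in ingredient names (the starter lexicon resolves the
synthetic names it generates plus common label synonyms), compound
sub-recipes, correlated recipe structure within a Shelf, or the true
skew of retail assortments.  Passing tests on this corpus demonstrate
that the algorithmic machinery is correct and that accuracy behaves in
the documented directions; they do not certify accuracy percentages on
any real corpus — those depend on the corpus and the intensity database
supplied by the user.

## Numerical choices and problem sizes

Convergence tolerance $10^{-6}$ mass units with a 100-iteration cap;
bound endpoints by 80-step bisection (exact to machine precision at the
scale of the problem); ties in the composite index broken by nothing —
equal impacts give equal scores; coverage clamped to $[0, 1]$.  The
test suite and the acceptance script run the pipeline at deliberately
modest sizes — corpora of 40–210 products, 50–10,000 Monte-Carlo
iterations, at least 500 masking trials for the trend checks — chosen so
the full suite completes in about half a minute while keeping every
statistical assertion comfortably powered.

## Known limitations

* Ingredient sourcing (country of origin, transport mode) is not
  modeled; the Monte-Carlo spread is a proxy for sourcing uncertainty,
  not a sourcing model.
* The composite index is corpus-relative by construction; cross-corpus
  comparisons require a frozen reference.
* Compound ingredients are flattened: the parent name is mapped and
  parenthetical sub-ingredients are only consulted when the parent is
  unmapped.
* The prior is built from the same corpus being scored (including, for
  validation products, their own declared cells); a leave-one-out prior
  would be marginally stricter but is not what a production scorer would
  use.
* NutriScore is computed from the printed panel; preparation effects
  (frying, reconstitution) are out of scope.
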