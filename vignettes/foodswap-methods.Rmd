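---
title: "Labelling, scoring and switching: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Labelling, scoring and switching: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodswap)
```

`foodswap` turns a barcode-keyed branded food-composition table into three
interpretive outputs: a traffic-light label, a nutrient-profile score, and
a ranked list of healthier same-category alternatives. This vignette
explains the underlying rules, the package's tunable parameters, the
numerical choices made where the published schemes leave room, and what
the synthetic test data do and do not establish.

## The data model

One record is one stock-keeping unit: a digit-string barcode, a product
and brand name, a category identifier resolving into a category table, a
beverage flag, and a nutrient panel declared per 100 g (foods) or per
100 ml (beverages): energy (kJ), protein, total fat, saturated fat,
carbohydrate, sugars (g) and sodium (mg), optionally fibre, calcium, a
fruit/vegetable/nut/legume (fvnl) composition, and a serving size.

Two conventions matter throughout:

* **Absence is not zero.** Fibre, calcium and fvnl content are not part of
  the mandatory Australian nutrient declaration, so they are genuinely
  missing in real data. Missing optional values are `NA` in memory and
  empty cells in CSV; a literal `0` is an observation. The imputation
  rules below depend on this distinction being preserved end to end.
* **Sodium in, salt out.** Panels declare sodium in mg; front-of-pack
  thresholds are written in grams of salt. The standard conversion
  `salt_g = sodium_mg × 2.5 / 1000` is applied immediately before
  classification and nowhere else.

Barcode check digits (GTIN mod-10, lengths 8/12/13/14) are validated but
advisory by default: real-world crowdsourced barcodes occasionally fail
the checksum, and refusing them would lose data. `strict_checksum = TRUE`
upgrades the warning to an error.

## Traffic-light classification

Each of total fat, saturated fat, sugars and salt is classified
independently: green when at or below the green maximum, red when
strictly above the red cut, amber between. Energy is displayed without a
colour. The defaults are the UK FSA criteria (foods per 100 g, drinks per
100 ml); thresholds are configuration (`read_thresholds()`), constrained
only by `green_max < red_exceeds` per nutrient.

Boundary semantics are taken literally from the printed bands: the bands
are `≤ g`, `> g to ≤ r`, `> r`, so a value exactly on a cut takes the
lower colour. Comparisons are performed on exact stored values — no
rounding to label precision first. The published criteria do not state a
pre-comparison rounding rule, and rounding would make the classifier
non-monotone at band edges; a product declaring 3.04 g/100 g fat is amber
here even though its label might print "3.0".

For foods with a known serving size, a nutrient whose per-portion amount
(`value × serving/100`) strictly exceeds the per-portion criterion is
upgraded to red whatever its per-100 g colour. The override can only move
a colour toward red, never away. It is applied unconditionally whenever a
serving size is present (and never for drinks, which have no per-portion
column); the UK guidance's portion-size preconditions are not modelled,
but the override can be disabled (`portion_override = FALSE`).

## The nutrient-profile score

Scoring category: 1 for beverages; 3 for edible oils, spreads, margarine
and butter (a category-table flag) and for cheese/processed cheese with
strictly more than 320 mg calcium per 100 g; 2 otherwise. The cheese rule
is the one place the score needs calcium, which is why calcium imputation
is restricted to cheese categories. The category table carries an
`is_cheese` flag so the calcium condition knows where to apply; flagged
non-cheese categories (oils, spreads) are category 3 unconditionally.

Baseline points accrue for energy, saturated fat, sugars and sodium;
modifying points are subtracted for fvnl content (V), protein (P) and
fibre (F): `final = baseline − V − P − F`, an exact integer identity that
the tests assert for every scored record. Lower is healthier, and the
switch engine ranks on this value.

The published scheme fixes the caps (10/30/10/30 baseline, V max 8,
P max 5, F max 2) and the V value set {0, 1, 2, 5, 8} but the package
treats the per-point increments as configuration
(`read_point_tables()`). The shipped defaults use the published FSANZ
granularity — one point per 335 kJ, 1 g saturated fat, 4.5 g sugars,
90 mg sodium, 1.6 g protein, 0.9 g fibre — with a single table set for
all three scoring categories; the category-specific table variants of the
full FSANZ scheme are representable in configuration but not defaulted.

**Lookup semantics.** A component scores *k* points when its amount
strictly exceeds the *k*-th step threshold. This is the semantics of the
published point tables (bands written "> 335", "> 670", …): 670 kJ sits
exactly on the second threshold and scores 1 point, not 2. Points are
integers by construction; there is no interpolation.

**V points.** fvnl% is computed from the declared composition with
concentrated components double-weighted,
`100·(nonconc + 2·conc)/(nonconc + 2·conc + non-fvnl)`, or imputed (next
section). The default lookup awards 1/2/5 points above 40/60/80 % and the
maximum 8 points at 100 %; the cut points are configurable but the
monotone-increasing constraint is enforced. P and F ranges printed as
"1–5" and "1–2" are read as caps on tables starting at 0 — a food with no
protein must score no protein points.

**Protein-cap rule.** The full FSANZ scheme withholds P points when
baseline exceeds 13 unless V ≥ 5. The rule is implemented
(`protein_cap_rule` in the point tables) but off by default, since the
core scheme as adopted here does not include it; note that with the rule
enabled the score is no longer weakly monotone in protein.

## Imputation

Computed once per database release, before scoring, from the raw data:

| field | category says impossible | category says possible |
|---|---|---|
| fibre | 0 (zero-rule) | mean of observed values in the category |
| calcium | — (only cheese categories are filled) | category mean |
| fvnl % | 0 (zero-rule) | category-level default percentage |

Observed values pass through untouched; every filled field is recorded in
a report (`upc`, `field`, `source`, `value`) and echoed on the resulting
score as `imputed_inputs`. Means are arithmetic means over observed
values only — a category needs at least one observation, and the count is
reported; no minimum sample size is imposed beyond that. Imputed values
never feed back into the means (stats are computed from the raw database,
then applied), which makes the operation idempotent and keeps mean-imputed
values inside the observed min–max of their category. An unresolvable case
— missing value, no observations, no default — is a hard error naming the
field and category, not a silent zero.

Category fvnl defaults live in the category table (`default_fvnl_pct`)
rather than in code: assigning category-typical percentages is an
editorial judgement, and configuration is the only auditable place for
it.

## The switch engine

"Healthier" is read strictly: an alternative must share the query's
category, not be the query, and have a strictly lower sort key — a
lateral move to an equal score is not a switch. In `npsc` mode the key is
the final score with ties broken by name then barcode; in `salt` mode
(for sodium-focused use) the key is sodium with ties broken by final
score, then name, then barcode. Deterministic tie-breaks make output
reproducible across runs and platforms. At most `max_results`
(default 10) alternatives are returned; the cap is configurable since no
canonical list length exists. Categories flagged `switch_excluded`
(e.g. sugar-sweetened soft drinks) return their standard advisory message
and an empty list — recommending a marginally-less-sugary soft drink
would undercut the advice that water is the healthier choice.

Recommendation requires a scored database (`score_database()`); querying
an unscored one is a state error, while an unknown barcode is a `NULL` /
crowdsource-prompt signal rather than an error, because it is the normal
trigger of the submission path: `scan_product()` returns a prompt asking
for the three labelled photographs, `record_missing_scan()` queues it
(coalescing repeat scans of the same barcode), `enter_submission()`
models the manual transcription step, and `merge_submissions()` builds
the next release — collisions with existing barcodes are skipped and
reported, never overwritten, which also makes merging idempotent.

## The synthetic-data generator

`generate_database()` exists so the whole pipeline is testable without
any external data. It emulates the *structure* of a surveyed branded-food
database: ten supermarket archetypes (bread, breakfast cereal, cheese,
oils/margarine, sugar-sweetened soft drinks, juice, yogurt, snack bars,
canned vegetables, confectionery) with archetype-specific nutrient
ranges; saturated fat generated as a fraction of total fat and sugars of
carbohydrate so the panel invariants hold by construction; valid GTIN-13
barcodes; per-record missingness of fibre, calcium and fvnl at
configurable rates (defaults 0.3 / 0.4 / 0.9, reflecting that fibre and
calcium are declared only sometimes and fvnl composition almost never);
and at least one excluded category carrying a standard message. A guard
keeps every fibre-possible category with at least one observed fibre
value (and cheese with one calcium value) so imputation stays resolvable;
at the scales used in the tests this shifts realized missingness by well
under a standard error. Generation is deterministic given the seed, which
is recorded in the output's metadata.

What it does **not** emulate: real market nutrient distributions (ranges
are uniform within archetype bounds, not fitted to any survey),
correlations between nutrients beyond the two construction constraints,
brand structure, reformulation over time, or dirty data (malformed rows,
unit errors, checksum-failing barcodes). Passing tests therefore
establish the engine's contracts — boundary exactness, monotonicity,
identity, oracle equivalence, round-trip fidelity — not distributional
claims about any real food supply.

## Numerical choices and degenerate inputs

* All threshold and step-table comparisons are strict/inclusive exactly
  as the printed bands read; no epsilon tolerances are introduced, so
  grid sweeps in the tests use exactly representable decimal grids.
* An all-zero fvnl composition is undefined under the percentage formula
  (zero denominator) and is treated as "not declared", falling back to
  imputation; `fvnl_percent()` itself refuses it.
* An empty database loads, saves and scores (to an empty score table)
  without error; empty categories yield undefined means with zero counts.
* Records inherit the category's beverage flag when their own is missing;
  a record-level flag wins, supporting drink-like foods and vice versa.
* Scoring-relevant test sizes: property suites run on synthetic databases
  of roughly 200–1,200 records (the switch-oracle equivalence uses
  ~1,100 records with every record as a query in npsc mode and a
  150-query sample in salt mode); these sizes exercise every rule path
  while keeping the full suite around two minutes.

## Known limitations

* Single-jurisdiction databases only; no federation across countries.
* No ingredient or allergen modelling (so no gluten-style filtering), no
  fuzzy name search, no OCR of submitted photographs — transcription is
  modelled as an external manual step.
* The scoring defaults collapse the category-specific FSANZ table
  variants into one table set; users needing the full regulatory
  calculator should supply their own point-table configuration.
* The per-portion override ignores portion-size preconditions; users
  wanting the stricter UK guidance behaviour can disable the override or
  pre-filter serving sizes.
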