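# foodswap

Interpretive nutrition labelling and healthier-product recommendation for
packaged foods, as an R package.

Most packaged food carries a back-of-pack nutrient declaration that few
shoppers read and fewer interpret. `foodswap` implements the computational
core of a barcode-driven labelling service for public-health nutrition
work: given a branded food-composition database keyed by barcode (UPC/GTIN),
it renders each product as an interpretive front-of-pack "traffic light"
label, scores it with an FSANZ-style nutrient profiling score, and
recommends same-category products with a more favourable profile. Barcodes
that are not in the database flow into a crowdsourcing queue (photographs of
the pack, the nutrition information panel and the ingredients list) whose
transcribed entries can be merged into the next database release.

## The labelling and scoring model

**Traffic lights.** Total fat, saturated fat, sugars and salt are each
classified green / amber / red against UK FSA cut points, per 100 g for
foods and per 100 ml for drinks, with energy shown as an uncoloured fifth
value. A nutrient is green when at or below the green maximum, red when
strictly above the red cut (boundaries inclusive downward), amber between.
For foods with a known serving size there is an additional per-portion red
criterion: e.g. total fat at 15 g/100 g is amber, but a 150 g serving
carries 22.5 g > 21.0 g/portion and is upgraded to red. Salt is derived
from declared sodium as `salt_g = sodium_mg × 2.5 / 1000` before
classification.

| nutrient (food, /100 g) | green ≤ | red > | red > (per portion) |
|---|---|---|---|
| total fat | 3.0 g | 20.0 g | 21.0 g |
| saturated fat | 1.5 g | 5.0 g | 6.0 g |
| sugars | 5.0 g | 12.5 g | 15.0 g |
| salt | 0.30 g | 1.50 g | 2.40 g |

(Drinks use their own, stricter per-100 ml table and have no per-portion
column.)

**Nutrient profile score (NPSC).** Each product scores in one of three
categories — 1 beverages; 2 ordinary foods; 3 edible oils, spreads,
margarine, butter, and cheese with > 320 mg calcium/100 g. Baseline points
accrue for energy (0–10), saturated fat (0–30), sugars (0–10) and sodium
(0–30); modifying points are subtracted for fruit/vegetable/nut/legume
content (V ∈ {0, 1, 2, 5, 8}, with concentrated components double-weighted:
fvnl% = 100·(nonconc + 2·conc)/(nonconc + 2·conc + non-fvnl)), protein
(0–5) and fibre (0–2):

```
final score = baseline − V − P − F        (lower = healthier)
```

Missing fibre, calcium and fvnl values are imputed before scoring:
zero for categories known not to contain the nutrient, otherwise the mean
of observed values in the category (fibre, calcium) or a category-level
default percentage (fvnl); every imputed field is flagged on the score.

**Switches.** Alternatives come from the product's own category and must be
strictly better: lower final score (`mode = "npsc"`) or lower sodium
(`mode = "salt"`, tie-broken by score). Categories where a like-for-like
swap is not meaningful (e.g. sugar-sweetened soft drinks) return a standard
advisory message instead.

## Worked example

```r
library(foodswap)

db  <- generate_database(generator_config(seed = 42))  # 200-SKU synthetic db
sdb <- score_database(db)                              # impute + score all
scan_product(sdb, "9300032072923")
```

```
<traffic_light_label> 9300032072923 (per100g_food)
  total_fat      amber
  saturated_fat  amber
  sugars         amber
  salt           green
  energy         371 kJ (no colour)
<npsc_score> 9300032072923 (category 2)
  baseline 6 (energy 1 + satfat 3 + sugars 2 + sodium 0)
  modifying V 0, P 1, F 0
  final score 5 (lower is healthier)
  imputed: fvnl_pct
<switch_result> 9300032072923 (mode: npsc)
# A tibble: 10 × 4
   upc           name               final_score sodium_mg
 1 9300032072831 Yogurt product 142          -1      55.5
 2 9300032072848 Yogurt product 143          -1      57.5
 3 9300032072862 Yogurt product 145           0      58.6
 ...
```

Reading the output: this yogurt is amber for fat, saturated fat and sugars
and green for salt; its baseline 6 points (1 energy + 3 saturated fat +
2 sugars) are offset by 1 protein point for a final score of 5; its fvnl
percentage was imputed from the category default. Ten same-category
products score strictly lower, best first — scanning any of their barcodes
instead would be the healthier switch.

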