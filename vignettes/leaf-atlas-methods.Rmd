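---
title: "Methods: a quantitative cellular and subcellular atlas of a reference leaf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a quantitative cellular and subcellular atlas of a reference leaf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafatlas)
```

## The problem and the model

Quantitative modelling of leaf metabolism needs a consistent set of
anatomical constants: how many cells of each type a leaf contains, how big
they are, how their volume is partitioned among organelles, how much
membrane surface each compartment exposes, and how amounts reported per
gram fresh weight, per mg chlorophyll or per unit leaf area relate to
concentrations inside compartments. `leafatlas` implements that bookkeeping
for a reference *Arabidopsis thaliana* rosette leaf (the first adult leaf,
"leaf 6", at 21 days after initiation) as a typed, unit-aware pipeline with
tested arithmetic rather than a spreadsheet.

The pipeline has five stages:

1. **Compendium** — a provenance-tracked parameter table (value, sd, unit,
   quality flag, reference, method, growth conditions) serialised as a
   long-format CSV; `read_compendium()` / `write_compendium()` round-trip
   it losslessly. Units come from a closed registry; internally all volumes
   are femtolitres (1 µm³ = 1 fL), lengths µm, leaf areas mm².
2. **Census** — each of the 15 leaf cell types carries exactly one count
   rule: surface density × leaf area (epidermal and mesophyll cells),
   vein metrics (cells per vein cross-section × vein length / cell length,
   the conical midrib divided by 3), 12 basal cells per trichome, or a
   fixed count. Counts stay real-valued internally so subtotals partition
   the total exactly; rounding is a rendering concern.
3. **Budgets** — per-cell-type fractional occupancies assembled from
   organelle records (count × unit volume, or a direct measured fraction;
   when both exist, count × volume wins and the discrepancy is messaged,
   never hidden). Gross "cytosol" fractions from electron microscopy lump
   cytosol, ER, Golgi and sometimes the nucleus; `cytosol_net()` unbundles
   them with the ER at 3.23% of the gross fraction and the Golgi at one
   tenth of the ER. Each budget closes on a free variable — the vacuole
   for whole cells, starch for the chloroplast sub-budget (closing at
   10.5%), the intermembrane space for the mitochondrion (closing at
   15.7%) — and a closed budget sums to exactly 1.
4. **Surfaces** — closed-form shape models: pavement cells are prisms with
   a jigsaw shape factor (perimeter = k·√area, k = 14; k = 4 recovers a
   square exactly), palisade cells are capsules (cylinder + two half
   oblate-spheroid caps, Thomsen exponent p = 1.6075), spongy cells
   spheres sized from their volume, guard cells semi-tori with discoid
   ends, bundle-sheath and vein cells cylinders (tracheids hollow — no end
   walls). Wall volume = internal surface × thickness (1 µm tracheary
   elements, 0.3 µm sieve elements, 0.15 µm otherwise).
5. **Unit harmonisation** — metabolite records in heterogeneous units are
   first expressed in nmol/g LFW (per mg chl × 1.2; per g LDW ÷ 7.97; per
   leaf × 45.5; per m² via the 121 mm² leaf area), then divided by the
   summed leaf-level volume (µL/g LFW) of the compartments in their
   curated localisation: nmol/µL = mM, × 1000 = µM. Equal concentrations
   across the listed compartments are assumed, and recorded as such.

## Key parameters

| parameter | default | unit | role |
|---|---|---|---|
| leaf area S | 121 | mm² | census, ratios, per-m² conversions |
| maximal area MS | 144 | mm² | developmental stage S/MS + D |
| leaves per g LFW | 45.5 | g⁻¹ | per-leaf ↔ per-g-LFW basis |
| chlorophyll | 1.2 | mg/g LFW | per-g-LFW ↔ per-mg-chl basis |
| LFW/LDW | 7.97 | – | dry-weight conversions |
| apoplast fluid | 21.4 | µL/g LFW | apoplast compartment volume |
| vein length | 370 | mm | vein-derived censuses |
| ER share of gross cytosol | 0.0323 | – | cytosol decomposition |
| Thomsen exponent p | 1.6075 | – | spheroid areas (≤ 1.2% error) |
| pavement shape factor k | 14 | – | jigsaw perimeter model |

The basis conversions form a group (per leaf → per g LFW → per mg chl →
per leaf recovers the input to float tolerance), and quality flags
propagate as the weakest input (`reference_condition` > `near_condition` >
`assumption`).

## The bundled fixture and what is synthetic in it

`reference_leaf6_fixture()` encodes every constant printed in the primary
literature for this leaf. The underlying curated workbook (per-cell-type
densities, vein cross-section counts, vein-cell sizes, the mitochondrion
unit volume behind the published occupancies, per-chloroplast thylakoid
and envelope areas, the plastoglobuli fraction, the vein-order length
split) is not redistributable, so those slots are **synthetic stand-ins**:
flagged `assumption` with reference `"synthetic"`, and calibrated once so
that the leaf-level aggregates reproduce the published bookkeeping — a
census of roughly 764,000 cells splitting 286,000 vein / 295,000
photosynthetic / 183,000 epidermal, vein cells at 0.7% and photosynthetic
cells at 86% of the cellular volume, pavement + mesophyll covering 94.4%,
vacuoles near 84% of the covered volume, a mesophyll:epidermal
mitochondrial split near 89:11, and membrane ratios of 800× (thylakoid),
28.8× (envelope) and 12.4× (mitochondrial outer membrane) relative to leaf
area. The calibration was fixed before the test suite was written and has
not been revisited since. A green test on this fixture therefore
establishes that the *pipeline arithmetic* reproduces the published
aggregates from plausible primary inputs — not that the stand-in primary
values are the measured ones.

Three published quantities are *fully determined* by printed constants
(census split, cell volumes, shape models) and land away from their
printed figures in this stated world; they are asserted at
printed-rounding tolerance and deliberately left failing in
`test-acceptance.R`:

* plasma membrane: computed ≈ 31× leaf area vs printed "30-fold" — the
  source itself also prints a total of 33 cm², which over a 1.21 cm² leaf
  is 27.3×, so the printed pair is internally inconsistent;
* chloroplasts: computed ≈ 9.4% of the cellular volume vs printed 10%;
  the printed occupancies (9.3% of 100 pL palisade, 15.5% of 60 pL
  spongy) cannot reach 10% under the printed census split;
* microscopic wall fraction: computed ≈ 2.5% vs printed 2.7% (macroscopic
  cross-check 2.9%).

Two further source-internal tensions are recorded but not asserted: the
bundle-sheath chloroplast occupancy (20 × 92 fL with a printed 5.4%
implies a 34 pL cell, while the published cylinder model gives 10.3 pL;
the cylinder is kept), and the ER share (printed "3.23%" from a quotient,
1405/41898 µm³, that actually equals 3.35%; the printed value is the
default).

## The synthetic-data generators

`make_toy_atlas()` draws log-normal densities and single-cell volumes
(positivity is the only distributional assumption the sources license) and
budget fractions as gamma draws renormalised to a sub-unit total, so
budgets are feasible by construction; a rejection guard remains for future
budget structures. `make_metabolite_table()` draws true concentrations
log-normally around 100 µM, picks a localisation set and an original unit,
and *forward*-converts, so `convert_batch()` must recover the ledger
exactly (tested at 1e-9 relative over 100 seeds). Ledgers are separate
objects the pipeline never reads. The generators emulate the shape of real
inputs, not their biology: no condition dependence (light, watering), no
correlated errors between parameters, no diurnal starch dynamics (only the
end-of-day closure value is represented), and no spatial vein topology.

## Numerical choices

* Closed-form volumes are verified against hit-or-miss Monte-Carlo oracles
  (3 standard errors at 10⁶ samples) and closed-form areas against
  quadrature of the parametrised surfaces (1e-4 relative), except
  Thomsen-approximated spheroids, which carry a documented ≤ 1.2% bound
  against the exact oblate eccentricity formula.
* `close_budget()` nudges the free entry by the summation residual so the
  closed budget sums *bit-exactly* to 1 under R's extended-precision
  `sum()`.
* "Ratio between perimeter and area (14)" is dimensionally inconsistent as
  a literal quotient; the committed convention is perimeter = k·√area,
  with the literal quotient retained behind
  `pavement_perimeter(convention = "literal_quotient")` for fidelity
  testing.
* The semi-torus ends are two flat discs of the tube radius; the exact
  construction used in the source is unpublished, so the formula is
  isolated in `semi_torus_area()` where it can be swapped.
* Pavement totals count both periclinal faces (outer and inner walls) plus
  the anticlinal band — wall volume needs the full internal surface; the
  single-face reading is available via `both_faces = FALSE`.
* Membrane ratios use the one-sided projected leaf area (121 mm²).
* Wall thickness is thin relative to cell size, so one surface is used
  without midline correction.
* Counts, fractions and volumes are full precision internally; rounding to
  printed significant figures happens only in reports.

## Worked example

```{r example}
atlas <- reference_leaf6_fixture()
leaf_developmental_stage(atlas$context)

tc <- total_cells(atlas)
tc$by_class
rosette_extrapolation(tc$total, 121, 10500) / 1e6  # million cells

agg <- aggregate_to_leaf(atlas)   # per g LFW, covered cell types
agg$coverage
head(agg$volumes)

vols <- compartment_volume_table(atlas)
rec <- data.frame(name = "sucrose", amount_value = 10,
                  amount_min = NA_real_, amount_max = NA_real_,
                  original_unit = "nmol_per_mgchl",
                  localisation = "cytosol;vacuole")
convert_batch(rec, vols, atlas$context)$harmonised$uM_value
```

## Limitations

The atlas is a reference state, not a growth model: parameters are those
of one leaf under one growth regime, and the harmonisation explicitly
assumes compartment volumes constant across studies and conditions (the
volume table is injectable to probe sensitivity). Epidermal and vein
metabolism is neglected in the default volume table. Shared walls between
adjacent cells are counted twice by construction, air-space surfaces are
not modelled, and isomer splitting by equilibrium constants is left to the
user (only exact name-group sums are provided).
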