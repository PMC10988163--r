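# leafatlas

A unit-aware R implementation of a quantitative cellular and subcellular
atlas of a reference *Arabidopsis thaliana* rosette leaf (leaf 6, the
first adult leaf, 21 days after initiation). It is aimed at metabolic
modellers and quantitative cell biologists who need consistent anatomical
constants: cell censuses, organelle volume budgets, membrane surface
areas, cell-wall volumes, and metabolite concentrations harmonised to µM
for constraint-based models.

## What it computes

Starting from a provenance-tracked parameter compendium (CSV; every value
carries a unit from a closed registry, an optional sd, a quality flag and
a literature key), the pipeline derives:

* **Census** — counts for the 15 leaf cell types, via surface densities
  (N = ρ · S), vein metrics (N = n_cs · L / ℓ, the conical midrib ÷ 3),
  trichome multipliers or fixed counts; leaf developmental stage
  LDS = S/MS + D.
* **Budgets** — fractional volume occupancies f = V_organelle / V_cell per
  cell type, closed on a free variable so Σ f = 1 exactly (vacuole for
  cells; starch for the chloroplast sub-budget; intermembrane space for
  the mitochondrion).
* **Surfaces** — closed-form areas for the shape models (sphere,
  ellipsoid with Thomsen's p = 1.6075 approximation, capsule, cylinder,
  semi-torus, jigsaw pavement prism with perimeter k·√A), membrane/leaf
  area ratios, and wall volumes (area × thickness).
* **Unit harmonisation** — amounts per g LFW / g LDW / mg chlorophyll /
  leaf / m² converted to nmol·(g LFW)⁻¹, then divided by the summed
  leaf-level volume (µL·(g LFW)⁻¹) of the compartments in each record's
  curated localisation: nmol/µL = mM → µM.
* **Basis conversions** — per leaf ↔ per g LFW (× 45.5) ↔ per mg
  chlorophyll (÷ 1.2), composing and inverting exactly.

A bundled fixture (`reference_leaf6_fixture()`, also serialised at
`inst/extdata/leaf6_compendium_synthetic.csv`) encodes the published
constants; slots whose primary sources are not redistributable are
synthetic stand-ins flagged as such (see the methods vignette). Synthetic
generators with ground-truth ledgers (`make_toy_atlas()`,
`make_metabolite_table()`) make every stage testable end to end.

## Worked example

```r
library(leafatlas)
atlas <- reference_leaf6_fixture()

leaf_developmental_stage(atlas$context)
#> [1] 0.8402778          # leaf at 84% of its maximal area, printed as 0.84

tc <- total_cells(atlas)
tc$by_class
#>     tissue_class    count  volume_uL
#> 1      epidermal 182999.5  3.3886959
#> 2 photosynthetic 294998.7 20.9920157
#> 3           vein 286000.2  0.1648894
round(tc$total)
#> [1] 763998             # ~764,000 cells in one reference leaf

round(rosette_extrapolation(tc$total, 121, 10500) / 1e6, 1)
#> [1] 66.3               # million cells in a 10,500 mm2 rosette

agg <- aggregate_to_leaf(atlas)   # covered types: pavement + mesophyll
round(agg$coverage, 3)
#> [1] 0.944              # share of the cellular volume they represent
agg$volumes[c(1, 9), ]
#>   compartment volume_uL_leaf  volume
#> 1 chloroplast          2.178  99.10  # uL per g fresh weight
#> 9     vacuole         19.540 889.20  # vacuoles dominate the cell volume

round(surface_report(atlas)$ratios, 1)
#>         plasma_membrane               thylakoid    chloroplast_envelope
#>                    31.0                   800.0                    28.8
#>     mitochondrial_outer thylakoid_over_envelope
#>                    12.4                    27.8

# 10 nmol/mg chl of sucrose, localised to cytosol + vacuole -> ~15 uM
vols <- compartment_volume_table(atlas)
rec <- data.frame(name = "sucrose", amount_value = 10,
                  amount_min = NA_real_, amount_max = NA_real_,
                  original_unit = "nmol_per_mgchl",
                  localisation = "cytosol;vacuole")
convert_batch(rec, vols, atlas$context)$harmonised$uM_value
#> [1] 14.92244
```

The thylakoid ratio reads: the leaf packs ~800 m² of thylakoid membrane
per m² of leaf surface.

## Command line

```sh
inst/exec/atlas validate inst/extdata/leaf6_compendium_synthetic.csv
inst/exec/atlas census   inst/extdata/leaf6_compendium_synthetic.csv --basis per_gram_LFW
inst/exec/atlas budget   builtin:leaf6
inst/exec/atlas synth    --seed 3 --out out/
```
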