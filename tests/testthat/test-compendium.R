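test_that("quantity enforces the closed registry and basic invariants", {
  q <- quantity(121, "mm2", sd = 5, quality = "reference_condition")
  expect_s3_class(q, "quantity")
  expect_error(quantity(1, "furlong"), "unknown unit")
  expect_error(quantity(Inf, "mm2"), "finite")
  expect_error(quantity(1, "mm2", sd = -1), "sd")
  expect_error(quantity(-3, "count"), "non-negative")
  expect_error(quantity(1.2, "fraction"), "\\[0, 1\\]")
  expect_error(quantity(1, "mm2", quality = "excellent"), "quality")
})

test_that("volume unit conversions are exact in round trips", {
  expect_identical(volume_convert(1, "um3", "fL"), 1)
  expect_identical(volume_convert(1, "pL", "fL"), 1e3)
  expect_identical(volume_convert(1, "uL", "fL"), 1e9)
  q <- quantity(2.5, "pL", sd = 0.1)
  back <- q_volume_as(q_volume_as(q, "fL"), "pL")
  expect_equal(back$value, q$value)
  expect_equal(back$sd, q$sd)
})

test_that("quality flags propagate as the weakest input", {
  expect_equal(combine_quality("reference_condition", "near_condition"),
               "near_condition")
  expect_equal(combine_quality("reference_condition", "assumption",
                               "near_condition"), "assumption")
  expect_equal(combine_quality("reference_condition"), "reference_condition")
  expect_error(combine_quality("great"), "unknown quality")
})

test_that("leaf developmental stage follows S/MS + D", {
  # reference leaf: S 121 mm2, MS 144 mm2, D 0 -> 0.84
  expect_equal(round(leaf_developmental_stage(leaf6$context), 2), 0.84)
  mk <- function(S, MS, D) leaf_context(
    leaf_area = S, max_leaf_area = MS, days_past_full_expansion = D,
    leaf_fresh_weight = 22.3, leaves_per_gram_LFW = 45.5, lfw_over_ldw = 7.97,
    chlorophyll_per_gram_LFW = 1.2, apoplast_volume = 21.4,
    rosette_leaf_area = 10500)
  expect_equal(leaf_developmental_stage(mk(144, 144, 0)), 1)
  expect_equal(leaf_developmental_stage(mk(144, 144, 3)), 4)
  expect_error(mk(150, 144, 0), "cannot exceed")
})

test_that("basis conversions use the printed factors and form a group", {
  ctx <- leaf6$context
  q <- quantity(1, "uL_per_leaf")
  # 1 uL/leaf -> 45.5 uL/g LFW (45.5 leaves per g LFW)
  expect_equal(convert_basis(q, "per_leaf", "per_gram_LFW", ctx)$value, 45.5)
  # 1.2 uL/g LFW -> 1.0 uL/mg chl (1.2 mg chl per g LFW)
  q2 <- quantity(1.2, "uL_per_gLFW")
  expect_equal(convert_basis(q2, "per_gram_LFW", "per_mg_chl", ctx)$value, 1)
  # identity
  expect_identical(convert_basis(q, "per_leaf", "per_leaf", ctx), q)
  # full cycle recovers the input within float tolerance; sd scales along
  q3 <- quantity(3.7, "uL_per_leaf", sd = 0.2)
  cyc <- convert_basis(convert_basis(convert_basis(
    q3, "per_leaf", "per_gram_LFW", ctx), "per_gram_LFW", "per_mg_chl", ctx),
    "per_mg_chl", "per_leaf", ctx)
  expect_equal(cyc$value, q3$value)
  expect_equal(cyc$sd, q3$sd)
  expect_error(convert_basis(q, "per_leaf", "per_acre", ctx), "unknown basis")
})

test_that("compendium round trip: atlas -> CSV -> atlas -> CSV is stable", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_compendium(leaf6, f1)
  back <- read_compendium(f1)
  expect_equal(nrow(back$cell_types), 15L)
  expect_s3_class(back$context, "leaf_context")
  # numeric content identical through the round trip
  expect_equal(total_cells(back)$total, total_cells(leaf6)$total)
  expect_equal(cell_budget(back, "palisade")$entries,
               cell_budget(leaf6, "palisade")$entries)
  # second serialisation is byte-identical (column order is part of the schema)
  write_compendium(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the bundled CSV fixture loads to the in-code fixture", {
  path <- system.file("extdata", "leaf6_compendium_synthetic.csv",
                      package = "leafatlas")
  expect_true(nzchar(path))
  atlas <- read_compendium(path)
  expect_equal(sort(atlas$cell_types$id), sort(leaf6$cell_types$id))
  expect_equal(total_cells(atlas)$total, total_cells(leaf6)$total)
})

test_that("reader rejects bad schemas, units and cell types", {
  f <- withr::local_tempfile(fileext = ".csv")
  tab <- as_compendium_table(leaf6)

  bad <- tab; bad$unit[5] <- "furlong"
  write_compendium(bad, f)
  expect_error(read_compendium(f), "furlong")

  bad <- tab[, setdiff(names(tab), "unit")]
  utils::write.csv(bad, f, row.names = FALSE, na = "")
  expect_error(read_compendium(f), "missing mandatory column")

  bad <- tab; bad$cell_type[bad$sheet == "cells"][1] <- "mystery_cell"
  write_compendium(bad, f)
  expect_error(read_compendium(f), "mystery_cell")

  expect_error(read_compendium(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("atlas validation catches structural violations", {
  broken <- leaf6
  broken$cell_types$density_per_mm2[broken$cell_types$id == "hydathode"] <- 10
  expect_error(validate_atlas(broken), "more than one count rule")

  broken <- leaf6
  broken$cell_types$cell_length_um[broken$cell_types$id == "sieve_element"] <- NA
  expect_error(validate_atlas(broken), "cell_length")

  broken <- leaf6
  broken$mitochondrion_sub$fraction <- c(0.7, 0.4)
  expect_error(validate_atlas(broken), ">= 1")
})
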