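test_that("to_per_gram_LFW applies the printed conversion factors", {
  ctx <- leaf6$context
  # 10 nmol/mg chl -> 12 nmol/g LFW (1.2 mg chl per g LFW)
  expect_equal(to_per_gram_LFW(10, "nmol_per_mgchl", ctx), 12)
  # 79.7 nmol/g LDW -> 10 nmol/g LFW (LFW/LDW = 7.97)
  expect_equal(to_per_gram_LFW(79.7, "nmol_per_gLDW", ctx), 10)
  # identity
  expect_equal(to_per_gram_LFW(5.5, "nmol_per_gLFW", ctx), 5.5)
  # per leaf: x 45.5 leaves per g
  expect_equal(to_per_gram_LFW(2, "nmol_per_leaf", ctx), 91)
  # per m2 of leaf: through the leaf area (121 mm2) and leaves per g
  expect_equal(to_per_gram_LFW(1, "umol_per_m2_leaf", ctx),
               1000 * 121e-6 * 45.5)
  expect_error(to_per_gram_LFW(1, "nmol_per_acre", ctx), "unsupported unit")
})

test_that("unit-path independence: per-mg-chl via per-g-LFW equals the composite", {
  ctx <- leaf6$context
  x <- 7.3
  composite <- x * ctx$chlorophyll_per_gram_LFW
  expect_equal(to_per_gram_LFW(x, "nmol_per_mgchl", ctx), composite)
})

test_that("concentration_uM divides by the summed localisation volume", {
  vols <- c(cytosol = 40, vacuole = 60, plastid_stroma = 50)
  # 100 nmol/g over 100 uL/g -> 1 nmol/uL = 1 mM = 1000 uM
  r <- concentration_uM(100, c("cytosol", "vacuole"), vols)
  expect_true(r$ok)
  expect_equal(r$uM, 1000)
  expect_equal(concentration_uM(0, "cytosol", vols)$uM, 0)
  # adding a compartment strictly decreases the concentration
  r2 <- concentration_uM(100, c("cytosol", "vacuole", "plastid_stroma"), vols)
  expect_lt(r2$uM, r$uM)
  # failure modes are statuses, not exceptions
  expect_false(concentration_uM(100, character(0), vols)$ok)
  expect_false(concentration_uM(100, "mystery", vols)$ok)
  expect_false(concentration_uM(100, "cytosol", c(cytosol = 0))$ok)
})

test_that("localisation synonyms map conservatively", {
  expect_equal(normalise_localisation(c("Chloroplast", "cytoplasm", "whole leaf")),
               c("plastid_stroma", "cytosol", "whole_cell"))
  expect_true(is.na(normalise_localisation("membrane raft")))
  expect_true(all(compartment_ontology() %in%
                    unname(normalise_localisation(compartment_ontology()))))
})

test_that("compartment volume table is mesophyll-weighted and complete", {
  vols <- compartment_volume_table(leaf6)
  expect_setequal(names(vols), compartment_ontology())
  expect_true(all(vols >= 0))
  expect_equal(unname(vols[["apoplast"]]), 21.4)
  # stroma is 61% of the mesophyll chloroplast volume per g LFW
  meso <- aggregate_to_leaf(leaf6, c("palisade", "spongy"))
  chl <- meso$volumes$volume[meso$volumes$compartment == "chloroplast"]
  expect_equal(unname(vols[["plastid_stroma"]]), chl * 0.61)
})

test_that("convert_batch: round trip, rejects, ranges, isomers, pass-through", {
  vols <- compartment_volume_table(leaf6)
  ctx <- leaf6$context
  syn <- make_metabolite_table(synthetic_spec(seed = 101, n_metabolites = 30),
                               vols, ctx, blank_localisation = 3)
  res <- convert_batch(syn$records, vols, ctx)
  expect_equal(nrow(res$rejects), 3)
  expect_true(all(res$rejects$reason == "no localisation"))
  m <- merge(res$harmonised[, c("name", "uM_value")], syn$ledger, by = "name")
  expect_equal(m$uM_value, m$true_uM, tolerance = 1e-9)
  # ranges preserve min <= value <= max
  rng <- res$harmonised[!is.na(res$harmonised$uM_min), ]
  expect_true(all(rng$uM_min <= rng$uM_max))
  # the metabolite name is duplicated in the final column
  expect_equal(names(res$harmonised)[ncol(res$harmonised)], "metabolite_name")
  expect_equal(res$harmonised$metabolite_name, res$harmonised$name)

  # hand-built corner cases: uM pass-through and isomer summation
  rec <- data.frame(
    name = c("alpha-D-glucose", "beta-D-glucose", "citrate"),
    amount_value = c(40, 60, 5), amount_min = NA_real_, amount_max = NA_real_,
    original_unit = c("nmol_per_gLFW", "nmol_per_gLFW", "uM"),
    localisation = c("cytosol", "cytosol", ""),
    isomer_group = c("D-glucose", "D-glucose", NA),
    stringsAsFactors = FALSE)
  out <- convert_batch(rec, vols, ctx)
  expect_equal(nrow(out$rejects), 0)
  h <- out$harmonised
  expect_equal(h$uM_value[h$name == "citrate"], 5)
  expect_equal(h$conversion_flag[h$name == "citrate"], "as_published_uM")
  glc <- h[h$isomer_group %in% "D-glucose", ]
  expect_equal(unique(glc$uM_isomer_group_sum), sum(glc$uM_value))
  expect_true(all(grepl("isomer_sum", glc$conversion_flag)))

  # unmapped localisation is rejected, never guessed
  rec2 <- data.frame(name = "x", amount_value = 1, amount_min = NA_real_,
                     amount_max = NA_real_, original_unit = "nmol_per_gLFW",
                     localisation = "lipid raft", stringsAsFactors = FALSE)
  out2 <- convert_batch(rec2, vols, ctx)
  expect_equal(nrow(out2$harmonised), 0)
  expect_match(out2$rejects$reason, "unmapped localisation")
})

test_that("volumes are injectable: concentrations respond to the volume table", {
  ctx <- leaf6$context
  vols <- c(cytosol = 50)
  rec <- data.frame(name = "x", amount_value = 10, amount_min = NA_real_,
                    amount_max = NA_real_, original_unit = "nmol_per_gLFW",
                    localisation = "cytosol", stringsAsFactors = FALSE)
  a <- convert_batch(rec, vols, ctx)$harmonised$uM_value
  b <- convert_batch(rec, vols * 2, ctx)$harmonised$uM_value
  expect_equal(a, 2 * b)
})
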