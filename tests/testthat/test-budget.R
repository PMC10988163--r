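test_that("fractional occupancy reproduces the published worked values", {
  # guard cell: 5 chloroplasts of 33.5 fL in 783 fL -> 21.4%
  expect_equal(fractional_occupancy(5 * sphere_volume(2), 783), 0.214,
               tolerance = 1e-3)
  # palisade: 100 x 93 fL in 100 pL -> 9.3%
  expect_equal(fractional_occupancy(100 * 93, 100e3), 0.093)
  # spongy: same chloroplast pool in 60 pL -> 15.5%
  expect_equal(fractional_occupancy(100 * 93, 60e3), 0.155)
  # trichome leucoplasts: 100 x 8.4 fL in 3800 pL -> 0.022%
  expect_equal(fractional_occupancy(100 * ellipsoid_volume(2, 2, 0.5), 3.8e6),
               0.00022, tolerance = 2e-3)
  expect_equal(fractional_occupancy(0, 500), 0)
  expect_warning(fractional_occupancy(600, 500), "exceeds")
  expect_error(fractional_occupancy(10, 0), "> 0")
})

test_that("budget closure sets the free variable and sums to exactly 1", {
  # mitochondrial sub-budget: matrix 50%, membranes 34.3% -> IMS 15.7%
  b <- close_budget(compartment_budget(
    "mitochondrion", c(matrix = 0.50, membranes = 0.343),
    free_variable = "intermembrane_space"))
  expect_equal(unname(b$entries[["intermembrane_space"]]), 0.157)
  expect_true(sum(b$entries) == 1)
  # saturated budget: free variable gets 0
  b2 <- close_budget(compartment_budget("x", c(a = 0.4, b = 0.6), "free"))
  expect_equal(unname(b2$entries[["free"]]), 0)
  # infeasible budgets are rejected with the excess reported
  expect_error(close_budget(compartment_budget("x", c(a = 0.7, b = 0.4), "v")),
               "infeasible")
  expect_error(compartment_budget("x", c(a = 0.5, v = 0.2), "v"),
               "must not be among")
  expect_error(compartment_budget("x", c(0.5, 0.2), "v"), "named")
})

test_that("chloroplast sub-budget closes on starch at the published value", {
  sub <- sub_organelle_budgets(leaf6)
  # envelope 3.9 + stroma 61 + lumen 7.7 + thylakoid 14.9 + nucleoid 1
  # + plastoglobuli 1 (synthetic slot) leaves 10.5% starch
  expect_equal(unname(sub$chloroplast$entries[["starch"]]), 0.105,
               tolerance = 1e-9)
  expect_equal(unname(sub$mitochondrion$entries[["intermembrane_space"]]), 0.157)
  expect_true(sum(sub$chloroplast$entries) == 1)
  expect_true(sum(sub$mitochondrion$entries) == 1)
})

test_that("cytosol decomposition follows the ER/Golgi shares", {
  # mesophyll: gross 3.77%, nucleus measured separately
  parts <- cytosol_net(0.0377, 0)
  expect_equal(parts$ER, 0.0377 * 0.0323)
  expect_equal(parts$Golgi, 0.0377 * 0.00323)
  expect_equal(parts$cytosol, 0.0377 - parts$ER - parts$Golgi)
  # Golgi is one tenth of the ER by construction
  expect_equal(parts$Golgi / parts$ER, 0.1)
  # zero shares: net cytosol = gross - nucleus
  expect_equal(cytosol_net(0.05, 0.01, 0, 0)$cytosol, 0.04)
  expect_error(cytosol_net(0.01, 0.02), "smaller than")
  expect_error(cytosol_net(0.01, 0.0099, er_share = 0.9), "negative")
})

test_that("cell budgets of the covered types close with realistic vacuoles", {
  for (id in c("pavement_abaxial", "pavement_adaxial", "palisade", "spongy")) {
    b <- cell_budget(leaf6, id)
    expect_true(b$closed)
    expect_true(sum(b$entries) == 1)
    expect_true(all(b$entries >= 0))
    expect_equal(unname(b$entries[["lipid_droplet"]]), 0)
  }
  # epidermal vacuoles ~94% (printed for spinach epidermis), spongy ~79.4%
  expect_equal(unname(cell_budget(leaf6, "pavement_abaxial")$entries[["vacuole"]]),
               0.94, tolerance = 0.01)
  expect_equal(unname(cell_budget(leaf6, "spongy")$entries[["vacuole"]]),
               0.794, tolerance = 0.005)
  # count x volume wins over a conflicting direct fraction, with a message
  conflicted <- leaf6
  i <- with(conflicted$organelles,
            which(cell_type == "spongy" & organelle == "peroxisome"))
  conflicted$organelles$fraction[i] <- 0.0014  # published alternative route
  expect_message(b <- cell_budget(conflicted, "spongy"), "count x volume")
  expect_equal(unname(b$entries[["peroxisome"]]), 92 * 0.97 / 60e3)
})

test_that("leaf-level aggregation: coverage, vacuole share, organelle shares", {
  agg <- aggregate_to_leaf(leaf6, basis = "per_leaf")
  # pavement + mesophyll cover 94.4% of the cellular volume
  expect_equal(agg$coverage, 0.944, tolerance = 1e-3)
  v <- setNames(agg$volumes$volume_uL_leaf, agg$volumes$compartment)
  covered <- agg$covered_volume_uL_leaf
  # vacuoles ~84% of the (covered) cellular volume
  expect_equal(unname(v[["vacuole"]]) / covered, 0.84, tolerance = 0.01)
  # nuclei ~0.2%, peroxisomes < 0.1%
  expect_equal(unname(v[["nucleus"]]) / covered, 0.002, tolerance = 0.01)
  expect_lt(unname(v[["peroxisome"]]) / covered, 0.001)
  # mesophyll:epidermal mitochondrial split ~89:11
  meso <- aggregate_to_leaf(leaf6, c("palisade", "spongy"), basis = "per_leaf")
  vm <- setNames(meso$volumes$volume_uL_leaf, meso$volumes$compartment)
  expect_equal(unname(vm[["mitochondrion"]] / v[["mitochondrion"]]), 0.89,
               tolerance = 0.005)
  # additive over disjoint sets
  epi <- aggregate_to_leaf(leaf6, c("pavement_abaxial", "pavement_adaxial"),
                           basis = "per_leaf")
  ve <- setNames(epi$volumes$volume_uL_leaf, epi$volumes$compartment)
  common <- intersect(names(vm), names(ve))
  expect_equal(vm[common] + ve[common], v[common])
  # basis conversion of the aggregate
  agg_g <- aggregate_to_leaf(leaf6, basis = "per_gram_LFW")
  expect_equal(agg_g$volumes$volume, agg$volumes$volume_uL_leaf * 45.5)
  # unclosed types are refused
  expect_error(aggregate_to_leaf(leaf6, c("palisade", "sieve_element")),
               "completeness")
})
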