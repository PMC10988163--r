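#' @title Synthetic data with ground-truth ledgers
#' @name synthetic_data
#' @description
#' Generators for randomised fixtures so every pipeline stage can be tested
#' against a known ground truth without any download: toy parameter
#' atlases (random densities, volumes and feasible budgets, with a ledger
#' of the true totals) and synthetic metabolite tables (true uM drawn
#' first, then forward-converted into a randomly chosen original unit).
#' Ledgers are returned as separate objects and never read by the pipeline
#' under test. Volumes and densities are drawn log-normally (positivity
#' with multiplicative noise); budget fractions are gamma draws renormalised
#' to a feasible sub-unit total.
NULL

#' Specification for the synthetic generators
#'
#' @param seed integer seed; the same seed yields identical output.
#' @param n_cell_types number of toy cell types (>= 2).
#' @param n_metabolites number of metabolite records.
#' @param noise_cv coefficient of variation of reported parameter errors
#'   (0 switches all `sd` fields off).
#' @param unit_mix named weights over original metabolite units (subset of
#'   nmol_per_gLFW, nmol_per_gLDW, nmol_per_mgchl, nmol_per_leaf,
#'   umol_per_m2_leaf).
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L, n_cell_types = 5L, n_metabolites = 20L,
                           noise_cv = 0.1,
                           unit_mix = c(nmol_per_gLFW = 1, nmol_per_gLDW = 1,
                                        nmol_per_mgchl = 1, nmol_per_leaf = 1,
                                        umol_per_m2_leaf = 1)) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (n_cell_types < 2) stop("need at least 2 cell types")
  structure(list(seed = as.integer(seed), n_cell_types = as.integer(n_cell_types),
                 n_metabolites = as.integer(n_metabolites), noise_cv = noise_cv,
                 unit_mix = unit_mix),
            class = "synthetic_spec")
}

.toy_ids <- c("palisade", "spongy", "pavement_abaxial", "pavement_adaxial",
              "stomata_guard", "bundle_sheath", "trichome", "hydathode",
              "phloem_companion", "xylem_parenchyma")

#' Generate a toy atlas with a ground-truth ledger
#'
#' Cell types get log-normal densities and single-cell volumes; each gets a
#' feasible compartment budget (fixed fractions drawn and renormalised to
#' sum to less than 1, vacuole free). The ledger records the true counts,
#' volumes and closed budgets for assertion; it is computed from the draws,
#' independently of the census/budget code under test.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `atlas` (a `leaf_atlas`) and `ledger` (true totals).
#' @export
make_toy_atlas <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- min(spec$n_cell_types, length(.toy_ids))
  ids <- .toy_ids[seq_len(n)]
  leaf_area <- 121
  rlnorm_cv <- function(k, meanlog, cv = 0.5) stats::rlnorm(k, meanlog, sqrt(log(1 + cv^2)))
  density <- rlnorm_cv(n, log(300))
  volume_pL <- rlnorm_cv(n, log(30))
  sdv <- if (spec$noise_cv == 0) rep(0, n) else volume_pL * spec$noise_cv

  cell_types <- data.frame(
    id = ids, tissue_class = "photosynthetic", side = NA_character_,
    count_rule = "density_times_area", vein_orders = NA_character_,
    shape_kind = "sphere_from_volume", density_per_mm2 = density, sides = 1,
    fixed_count = NA_real_, trichome_multiplier = NA_real_,
    vein_n_cs = NA_real_, cell_length_um = NA_real_,
    single_cell_volume_pL = volume_pL, height_um = NA_real_,
    wall_thickness_um = 0.15, shape_r = NA_real_, shape_l = NA_real_,
    shape_r_c = NA_real_, shape_h = NA_real_, shape_r_s = NA_real_,
    shape_R = NA_real_, quality = "assumption", reference = "synthetic",
    stringsAsFactors = FALSE)

  # feasible budgets by construction: gamma draws renormalised to a total
  # drawn uniformly in (0.05, 0.6); rejection is therefore never needed,
  # but kept as a guard for future budget structures
  compartments <- c("chloroplast", "mitochondrion", "nucleus", "peroxisome",
                    "cytosol_gross")
  og_list <- list()
  budgets_true <- list()
  for (i in seq_len(n)) {
    repeat {
      w <- stats::rgamma(length(compartments), shape = 2)
      total <- stats::runif(1, 0.05, 0.6)
      fr <- w / sum(w) * total
      if (sum(fr) < 1) break
      message("infeasible budget draw; regenerating")  # unreachable guard
    }
    names(fr) <- compartments
    og_list[[i]] <- data.frame(
      cell_type = ids[i], organelle = compartments,
      source_mode = "direct_fraction", count_per_cell = NA_real_,
      unit_volume_fL = NA_real_, fraction = unname(fr),
      quality = "assumption", reference = "synthetic",
      stringsAsFactors = FALSE)
    er <- fr[["cytosol_gross"]] * 0.0323
    golgi <- fr[["cytosol_gross"]] * 0.00323
    fixed <- c(fr[setdiff(compartments, "cytosol_gross")],
               cytosol = unname(fr[["cytosol_gross"]] - er - golgi),
               ER = unname(er), Golgi = unname(golgi), lipid_droplet = 0)
    budgets_true[[ids[i]]] <- c(fixed, vacuole = unname(1 - sum(fixed)))
  }
  organelles <- do.call(rbind, og_list)

  ctx <- leaf_context(leaf_area = leaf_area, max_leaf_area = 144,
                      days_past_full_expansion = 0, leaf_fresh_weight = 22.3,
                      leaves_per_gram_LFW = 45.5, lfw_over_ldw = 7.97,
                      chlorophyll_per_gram_LFW = 1.2, apoplast_volume = 21.4,
                      rosette_leaf_area = 10500)
  veins <- data.frame(order = c("midrib", "secondary", "higher"),
                      length_mm = c(10, 60, 300),
                      cone_corrected = c(TRUE, FALSE, FALSE),
                      stringsAsFactors = FALSE)
  atlas <- leaf_atlas(
    context = ctx, veins = veins, cell_types = cell_types,
    organelles = organelles,
    chloroplast_sub = data.frame(compartment = c("envelope", "stroma"),
                                 fraction = c(0.039, 0.61),
                                 stringsAsFactors = FALSE),
    mitochondrion_sub = data.frame(compartment = c("matrix", "membranes"),
                                   fraction = c(0.50, 0.343),
                                   stringsAsFactors = FALSE),
    params = list(stomatal_density_abaxial = 0, stomatal_density_adaxial = 0,
                  stomatal_complex_area = 0, pavement_shape_factor = 14,
                  er_share_of_cytosol = 0.0323, golgi_share_of_cytosol = 0.00323,
                  thylakoid_area_per_chloroplast = 4000,
                  envelope_area_per_chloroplast = 150,
                  macroscopic_wall_fraction = 0.029))

  counts_true <- density * leaf_area
  ledger <- list(
    counts = stats::setNames(counts_true, ids),
    total_cells = sum(counts_true),
    total_volume_uL = sum(counts_true * volume_pL * 1e-6),
    sd_volume_pL = stats::setNames(sdv, ids),
    budgets = budgets_true)
  list(atlas = atlas, ledger = ledger)
}

#' Generate a synthetic metabolite table with a true-uM ledger
#'
#' For each metabolite a true concentration (uM, log-normal around 100 uM)
#' and a random non-empty localisation set are drawn; the corresponding
#' amount per g LFW follows from the volume table, and is then expressed in
#' an original unit drawn from `unit_mix` by inverting the documented unit
#' conversions. Optionally a min-max range (around the value) is emitted.
#' A `blank_localisation` count of records gets its localisation emptied to
#' exercise the rejects path.
#'
#' @param spec a [synthetic_spec()].
#' @param vols named compartment volume table, uL per g LFW.
#' @param ctx a [leaf_context()].
#' @param blank_localisation number of records with localisation removed.
#' @return list with `records` (data.frame for [convert_batch()]) and
#'   `ledger` (true uM per record; `NA` for blanked records).
#' @export
make_metabolite_table <- function(spec = synthetic_spec(), vols, ctx,
                                  blank_localisation = 0L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  n <- spec$n_metabolites
  units <- names(spec$unit_mix)
  comps <- setdiff(names(vols), "whole_cell")
  from_per_g <- function(value, unit) {
    # inverse of to_per_gram_LFW, used only by the generator
    switch(unit,
      nmol_per_gLFW = value,
      nmol_per_gLDW = value * ctx$lfw_over_ldw,
      nmol_per_mgchl = value / ctx$chlorophyll_per_gram_LFW,
      nmol_per_leaf = value / ctx$leaves_per_gram_LFW,
      umol_per_m2_leaf = value / (1000 * ctx$leaf_area * 1e-6 * ctx$leaves_per_gram_LFW))
  }
  true_uM <- stats::rlnorm(n, log(100), 1)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sample(1:3, 1)
    loc <- sample(comps, k)
    unit <- sample(units, 1, prob = spec$unit_mix)
    per_g <- true_uM[i] / 1000 * sum(vols[loc])
    value <- from_per_g(per_g, unit)
    has_range <- stats::runif(1) < 0.3
    recs[[i]] <- data.frame(
      name = sprintf("metabolite_%03d", i),
      molecular_weight = round(stats::runif(1, 80, 600), 2),
      kegg = sprintf("C%05d", i), chebi = sprintf("CHEBI:%d", 10000 + i),
      amount_value = value,
      amount_min = if (has_range) value * 0.8 else NA_real_,
      amount_max = if (has_range) value * 1.2 else NA_real_,
      original_unit = unit,
      material = "whole leaf", method = "synthetic draw",
      localisation = paste(loc, collapse = ";"),
      reference = "synthetic", isomer_group = NA_character_,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  if (blank_localisation > 0L) {
    blank <- sample(n, min(blank_localisation, n))
    records$localisation[blank] <- ""
    true_uM[blank] <- NA_real_
  }
  list(records = records, ledger = data.frame(name = records$name,
                                              true_uM = true_uM,
                                              stringsAsFactors = FALSE))
}
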