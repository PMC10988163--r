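#' The bundled reference leaf 6 atlas
#'
#' An in-code fixture encoding the quantitative description of a fully
#' expanded Arabidopsis thaliana Col-0 rosette leaf 6 (21 days after
#' initiation, long-day reference growth conditions): leaf area 121 mm2,
#' maximal area 144 mm2, 45.5 leaves per g fresh weight, fresh/dry weight
#' ratio 7.97, 1.2 mg chlorophyll per g LFW, 21.4 uL apoplast fluid per g
#' LFW, 37 cm of veins, and the 15 leaf cell types with their count rules,
#' single-cell volumes, shape models and wall thicknesses, plus organelle
#' counts/volumes and sub-organelle fractions for the covered cell types.
#'
#' Quantities printed in the source literature carry their literature
#' quality flags. Slots the primary literature leaves open (individual cell
#' densities, vein cross-section counts, vein-cell volumes, per-organelle
#' membrane areas, the plastoglobuli fraction) are SYNTHETIC stand-ins:
#' they are flagged `assumption` with reference `"synthetic"`, and were
#' calibrated once so that the leaf-level aggregates reproduce the
#' published census and volume bookkeeping (about 764,000 cells split
#' 286,000 vein / 295,000 photosynthetic / 183,000 epidermal; vein cells
#' 0.7% and photosynthetic cells 86% of the cellular volume; covered cells
#' 94.4%). They are a consistent stand-in for the unpublished workbook
#' sheets, not measurements. See the methods vignette.
#'
#' @return a validated `leaf_atlas`.
#' @export
reference_leaf6_fixture <- function() {
  ctx <- leaf_context(
    leaf_area = 121, max_leaf_area = 144, days_past_full_expansion = 0,
    leaf_fresh_weight = 22.3, leaves_per_gram_LFW = 45.5, lfw_over_ldw = 7.97,
    chlorophyll_per_gram_LFW = 1.2, apoplast_volume = 21.4,
    rosette_leaf_area = 10500)

  # 37 cm of veins; the midrib is modelled as a cone (counts of its
  # circumscribing cylinder divided by 3). The split across orders is a
  # synthetic stand-in.
  veins <- data.frame(
    order = c("midrib", "secondary", "higher"),
    length_mm = c(10, 60, 300),
    cone_corrected = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)

  ctrow <- function(id, tissue_class, side = NA, count_rule,
                    density = NA, sides = NA, fixed_count = NA,
                    trichome_multiplier = NA, vein_n_cs = NA, vein_orders = NA,
                    cell_length = NA, volume_pL, height = NA, wall = 0.15,
                    shape, r = NA, l = NA, r_c = NA, h = NA, r_s = NA, R = NA,
                    quality = "reference_condition", reference = "literature") {
    data.frame(id = id, tissue_class = tissue_class, side = side,
               count_rule = count_rule, vein_orders = vein_orders,
               shape_kind = shape, density_per_mm2 = density, sides = sides,
               fixed_count = fixed_count, trichome_multiplier = trichome_multiplier,
               vein_n_cs = vein_n_cs, cell_length_um = cell_length,
               single_cell_volume_pL = volume_pL, height_um = height,
               wall_thickness_um = wall, shape_r = r, shape_l = l,
               shape_r_c = r_c, shape_h = h, shape_r_s = r_s, shape_R = R,
               quality = quality, reference = reference,
               stringsAsFactors = FALSE)
  }

  # vein cell radii follow from volume and length assuming circular sections
  r_cyl <- function(V_pL, l_um) sqrt(V_pL * 1e3 / (pi * l_um))

  cell_types <- rbind(
    ctrow("pavement_abaxial", "epidermal", "abaxial", "density_times_area",
          density = 480, sides = 1, volume_pL = 18.62, height = 6,
          shape = "pavement_prism", quality = "assumption", reference = "synthetic"),
    ctrow("pavement_adaxial", "epidermal", "adaxial", "density_times_area",
          density = 375.5, sides = 1, volume_pL = 38.08, height = 8,
          shape = "pavement_prism", quality = "assumption", reference = "synthetic"),
    ctrow("stomata_guard", "epidermal", NA, "density_times_area",
          density = 644, sides = 1, volume_pL = 0.783,
          shape = "semi_torus", r = 3, R = 7.5),
    ctrow("trichome", "epidermal", NA, "fixed", fixed_count = 120,
          volume_pL = 3800, shape = "sphere_from_volume",
          quality = "near_condition"),
    ctrow("trichome_basal", "epidermal", NA, "per_trichome_multiplier",
          trichome_multiplier = 12, volume_pL = 41.7,
          shape = "sphere_from_volume", quality = "assumption",
          reference = "synthetic"),
    ctrow("palisade", "photosynthetic", NA, "density_times_area",
          density = 1314.4, sides = 1, volume_pL = 100,
          shape = "capsule", h = 50, r_s = 5),
    ctrow("spongy", "photosynthetic", NA, "density_times_area",
          density = 613.3, sides = 1, volume_pL = 60,
          shape = "sphere_from_volume"),
    ctrow("bundle_sheath", "photosynthetic", NA, "vein_derived",
          vein_n_cs = 8.353, vein_orders = "secondary;higher",
          cell_length = 48.7, volume_pL = pi * 8.2^2 * 48.7 / 1e3,
          shape = "cylinder_closed", r = 8.2, l = 48.7,
          quality = "assumption", reference = "synthetic"),
    ctrow("phloem_companion", "vein", NA, "vein_derived",
          vein_n_cs = 8.1468, vein_orders = "midrib;secondary;higher",
          cell_length = 100, volume_pL = 0.3,
          shape = "cylinder_closed", r = r_cyl(0.3, 100), l = 100,
          quality = "assumption", reference = "synthetic"),
    ctrow("phloem_parenchyma", "vein", NA, "vein_derived",
          vein_n_cs = 10.1835, vein_orders = "midrib;secondary;higher",
          cell_length = 100, volume_pL = 0.8,
          shape = "cylinder_closed", r = r_cyl(0.8, 100), l = 100,
          quality = "assumption", reference = "synthetic"),
    ctrow("sieve_element", "vein", NA, "vein_derived",
          vein_n_cs = 12.2202, vein_orders = "midrib;secondary;higher",
          cell_length = 100, volume_pL = 0.143, wall = 0.3,
          shape = "cylinder_closed", r = r_cyl(0.143, 100), l = 100,
          quality = "assumption", reference = "synthetic"),
    ctrow("xylem_parenchyma", "vein", NA, "vein_derived",
          vein_n_cs = 12.2202, vein_orders = "midrib;secondary;higher",
          cell_length = 100, volume_pL = 0.9,
          shape = "cylinder_closed", r = r_cyl(0.9, 100), l = 100,
          quality = "assumption", reference = "synthetic"),
    ctrow("xylem_tracheid", "vein", NA, "vein_derived",
          vein_n_cs = 10.1835, vein_orders = "midrib;secondary;higher",
          cell_length = 80, volume_pL = 1.0, wall = 1.0,
          shape = "cylinder_hollow", r = r_cyl(1.0, 80), l = 80,
          quality = "assumption", reference = "synthetic"),
    ctrow("cambial", "vein", NA, "vein_derived",
          vein_n_cs = 13.7477, vein_orders = "midrib;secondary;higher",
          cell_length = 60, volume_pL = 0.4,
          shape = "cylinder_closed", r = r_cyl(0.4, 60), l = 60,
          quality = "assumption", reference = "synthetic"),
    ctrow("hydathode", "vein", NA, "fixed", fixed_count = 1100,
          volume_pL = 0.5, shape = "sphere_from_volume",
          quality = "assumption", reference = "synthetic"))

  og <- function(cell_type, organelle, source_mode, count = NA, unit_fL = NA,
                 fraction = NA, quality = "near_condition",
                 reference = "literature") {
    data.frame(cell_type = cell_type, organelle = organelle,
               source_mode = source_mode, count_per_cell = count,
               unit_volume_fL = unit_fL, fraction = fraction,
               quality = quality, reference = reference,
               stringsAsFactors = FALSE)
  }

  # organelle unit volumes follow the published shape idealisations:
  # epidermal chloroplasts are 2 x 2 x 0.5 um ellipsoids, bundle sheath
  # chloroplasts 2.8-um-radius spheres, guard cell chloroplasts 2-um-radius
  # spheres; mesophyll chloroplasts average 93 fL.
  epi_chl <- ellipsoid_volume(2, 2, 0.5)      # 8.4 fL
  bs_chl <- sphere_volume(2.8)                # 92 fL
  guard_chl <- sphere_volume(2)               # 33.5 fL
  mito_fL <- 3.9                              # synthetic unit volume
  perox_fL <- 0.97

  organelles <- rbind(
    og("palisade", "chloroplast", "count_times_volume", 100, 93),
    og("spongy", "chloroplast", "derived_share", 100, 93,
       quality = "assumption"),
    og("pavement_abaxial", "chloroplast", "count_times_volume", 10, epi_chl),
    og("pavement_adaxial", "chloroplast", "count_times_volume", 10, epi_chl),
    og("stomata_guard", "chloroplast", "count_times_volume", 5, guard_chl),
    og("bundle_sheath", "chloroplast", "count_times_volume", 20, bs_chl),
    og("trichome", "plastid", "count_times_volume", 100, epi_chl,
       quality = "assumption"),
    og("phloem_companion", "plastid", "count_times_volume", 10, 17.3),

    og("palisade", "mitochondrion", "count_times_volume", 615.4, mito_fL,
       quality = "assumption", reference = "synthetic"),
    og("spongy", "mitochondrion", "count_times_volume", 184.6, mito_fL,
       quality = "assumption", reference = "synthetic"),
    og("pavement_abaxial", "mitochondrion", "count_times_volume", 65.4, mito_fL,
       quality = "assumption", reference = "synthetic"),
    og("pavement_adaxial", "mitochondrion", "count_times_volume", 214.8, mito_fL,
       quality = "assumption", reference = "synthetic"),

    og("palisade", "nucleus", "direct_fraction", fraction = 0.0015),
    og("spongy", "nucleus", "direct_fraction", fraction = 0.0015),
    og("pavement_abaxial", "nucleus", "direct_fraction", fraction = 0.0080558),
    og("pavement_adaxial", "nucleus", "direct_fraction", fraction = 0.0039391),

    og("palisade", "peroxisome", "derived_share", 92, perox_fL,
       quality = "assumption"),
    og("spongy", "peroxisome", "count_times_volume", 92, perox_fL),
    og("pavement_abaxial", "peroxisome", "derived_share", 10, perox_fL,
       quality = "assumption"),
    og("pavement_adaxial", "peroxisome", "derived_share", 10, perox_fL,
       quality = "assumption"),
    og("stomata_guard", "peroxisome", "count_times_volume", 10, perox_fL),

    og("palisade", "cytosol_gross", "direct_fraction", fraction = 0.0377),
    og("spongy", "cytosol_gross", "direct_fraction", fraction = 0.0377),
    og("pavement_abaxial", "cytosol_gross_incl_nucleus", "direct_fraction",
       fraction = 0.0496),
    og("pavement_adaxial", "cytosol_gross_incl_nucleus", "direct_fraction",
       fraction = 0.0496),

    og("palisade", "lipid_droplet", "direct_fraction", fraction = 0),
    og("spongy", "lipid_droplet", "direct_fraction", fraction = 0),
    og("pavement_abaxial", "lipid_droplet", "direct_fraction", fraction = 0),
    og("pavement_adaxial", "lipid_droplet", "direct_fraction", fraction = 0))

  # chloroplast sub-fractions; starch is the free variable and closes at
  # 10.5% with the synthetic plastoglobuli slot at 1%
  chloroplast_sub <- data.frame(
    compartment = c("envelope", "stroma", "thylakoid_lumen", "thylakoid",
                    "nucleoid", "plastoglobuli"),
    fraction = c(0.039, 0.61, 0.077, 0.149, 0.01, 0.010),
    stringsAsFactors = FALSE)

  # mitochondrial sub-fractions; the intermembrane space closes at 15.7%
  mitochondrion_sub <- data.frame(
    compartment = c("matrix", "membranes"),
    fraction = c(0.50, 0.343),
    stringsAsFactors = FALSE)

  params <- list(
    stomatal_density_abaxial = 191,      # complexes per mm2 (synthetic)
    stomatal_density_adaxial = 131,
    stomatal_complex_area = 130,         # um2 per complex (synthetic)
    pavement_shape_factor = 14,
    er_share_of_cytosol = 0.0323,
    golgi_share_of_cytosol = 0.00323,
    thylakoid_area_per_chloroplast = 4150,   # um2, synthetic calibration
    envelope_area_per_chloroplast = 149.4,   # um2, synthetic calibration
    macroscopic_wall_fraction = 0.029)

  leaf_atlas(context = ctx, veins = veins, cell_types = cell_types,
             organelles = organelles, chloroplast_sub = chloroplast_sub,
             mitochondrion_sub = mitochondrion_sub, params = params)
}
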