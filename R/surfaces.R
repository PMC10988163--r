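#' @title Membrane and cell-surface areas, cell-wall volumes
#' @name surfaces
#' @description
#' Per-cell surface areas from the shape models, leaf-level membrane area
#' ratios (membrane area over one-sided projected leaf area) and cell-wall
#' volumes (internal cell surface times wall thickness), including the
#' microscopic-versus-macroscopic wall-fraction cross-check.
NULL

#' Pavement-cell surface areas
#'
#' Periclinal area: leaf area minus the area occupied by stomatal
#' complexes, divided by the number of pavement cells on that face.
#' Anticlinal area: the jigsaw perimeter (shape factor times sqrt(area))
#' times the cell height. The per-cell total counts both periclinal faces
#' (outer and inner walls) plus the anticlinal band by default; set
#' `both_faces = FALSE` for the single-face reading.
#'
#' @param leaf_area one-sided leaf area, mm2.
#' @param stomatal_complex_fraction fraction of the face occupied by
#'   stomatal complexes (in [0, 1)).
#' @param n_cells pavement cells on this face.
#' @param height cell height, um.
#' @param k pavement shape factor (see [pavement_perimeter()]).
#' @param both_faces count the periclinal area twice?
#' @param convention perimeter convention, passed to [pavement_perimeter()].
#' @return list with `periclinal`, `anticlinal` and `total` areas per cell,
#'   um2.
#' @export
pavement_cell_area <- function(leaf_area, stomatal_complex_fraction, n_cells,
                               height, k = 14, both_faces = TRUE,
                               convention = "sqrt_area") {
  if (stomatal_complex_fraction >= 1 || stomatal_complex_fraction < 0)
    stop("stomatal complex fraction must lie in [0, 1)")
  if (leaf_area <= 0 || n_cells <= 0) stop("inputs must be positive")
  if (height < 0) stop("height must be >= 0")
  periclinal <- leaf_area * 1e6 * (1 - stomatal_complex_fraction) / n_cells
  perimeter <- pavement_perimeter(periclinal, k = k, convention = convention)
  anticlinal <- perimeter * height
  total <- (if (both_faces) 2 else 1) * periclinal + anticlinal
  list(periclinal = periclinal, anticlinal = anticlinal, total = total)
}

# stomatal complex fraction on one leaf face
.stomatal_fraction <- function(atlas, side) {
  dens <- atlas$params[[paste0("stomatal_density_", side)]]
  a <- atlas$params$stomatal_complex_area
  if (is.null(dens) || is.null(a)) return(0)
  dens * a / 1e6  # per mm2 x um2 -> fraction
}

#' Surface area of one cell of a given type
#'
#' Dispatches on the cell type's shape model: pavement prism (via
#' [pavement_cell_area()], needing the census for the per-cell periclinal
#' share), capsule (cylinder radius solved from the cell volume when not
#' given), sphere (radius from the volume when only the volume is known),
#' closed/hollow cylinder, semi-torus.
#'
#' @param atlas a `leaf_atlas`.
#' @param cell_type cell type id.
#' @return surface area per cell, um2.
#' @export
cell_surface_area <- function(atlas, cell_type) {
  ct <- atlas$cell_types[atlas$cell_types$id == cell_type, ]
  if (nrow(ct) != 1L) stop("unknown cell type: ", cell_type)
  V_fL <- ct$single_cell_volume_pL * 1e3
  switch(ct$shape_kind,
    pavement_prism = {
      cen <- cell_census(atlas)
      n <- cen$count[cen$id == cell_type]
      side <- ct$side
      pavement_cell_area(atlas$context$leaf_area,
                         .stomatal_fraction(atlas, side), n,
                         height = ct$height_um,
                         k = atlas$params$pavement_shape_factor)$total
    },
    capsule = {
      r_c <- if (is.na(ct$shape_r_c))
        solve_capsule_radius(V_fL, ct$shape_h, ct$shape_r_s) else ct$shape_r_c
      capsule_area(r_c, ct$shape_h, ct$shape_r_s)
    },
    sphere = sphere_area(ct$shape_r),
    sphere_from_volume = sphere_area(sphere_radius_from_volume(V_fL)),
    cylinder_closed = cylinder_area(ct$shape_r, ct$shape_l, closed = TRUE),
    cylinder_hollow = cylinder_area(ct$shape_r, ct$shape_l, closed = FALSE),
    semi_torus = semi_torus_area(ct$shape_r, ct$shape_R),
    stop("configuration error: unresolved shape for cell type '", cell_type, "'")
  )
}

#' Membrane-to-leaf area ratio
#' @param total_membrane_area_um2 total membrane area, um2.
#' @param leaf_area_mm2 one-sided projected leaf area, mm2.
#' @return dimensionless ratio.
#' @export
leaf_area_ratio <- function(total_membrane_area_um2, leaf_area_mm2) {
  if (leaf_area_mm2 <= 0) stop("leaf area must be > 0")
  total_membrane_area_um2 / (leaf_area_mm2 * 1e6)
}

#' Cell-wall volume for one cell type at the leaf level
#' @param area_um2 internal surface area per cell, um2.
#' @param thickness_um wall thickness, um.
#' @param count number of cells.
#' @return wall volume, uL per leaf. Linear in area, thickness and count.
#' @export
wall_volume <- function(area_um2, thickness_um, count) {
  if (any(c(area_um2, thickness_um, count) < 0)) stop("inputs must be >= 0")
  area_um2 * thickness_um * count * 1e-9  # um3 -> uL
}

#' Per-type surface areas, membrane ratios and wall volumes
#'
#' The workhorse report: per-cell and per-leaf surface areas for every cell
#' type; total plasma membrane area and its ratio to leaf area (trichomes
#' and their basal cells are excluded from the plasma-membrane total, whose
#' epidermal contribution neglects them by construction, but are included
#' in wall volumes); thylakoid, chloroplast envelope and mitochondrial
#' outer membrane areas and ratios; cell-wall volumes and the microscopic
#' wall fraction of the total cellular volume.
#'
#' @param atlas a `leaf_atlas`.
#' @return list with `per_type` (data.frame), `plasma_membrane_um2`,
#'   `ratios` (named vector of membrane/leaf-area ratios),
#'   `wall_volume_uL`, `wall_fraction`, `macroscopic_wall_fraction`,
#'   `total_chloroplast_area_cm2`.
#' @export
surface_report <- function(atlas) {
  cen <- cell_census(atlas)
  ct <- atlas$cell_types
  per_cell <- vapply(ct$id, function(id) cell_surface_area(atlas, id), numeric(1))
  per_type <- data.frame(
    id = ct$id,
    area_per_cell_um2 = unname(per_cell),
    count = cen$count[match(ct$id, cen$id)],
    wall_thickness_um = ct$wall_thickness_um,
    stringsAsFactors = FALSE)
  per_type$area_leaf_um2 <- per_type$area_per_cell_um2 * per_type$count
  per_type$wall_volume_uL <- wall_volume(per_type$area_per_cell_um2,
                                         per_type$wall_thickness_um,
                                         per_type$count)

  pm_excluded <- c("trichome", "trichome_basal")
  pm_total <- sum(per_type$area_leaf_um2[!per_type$id %in% pm_excluded])

  # mitochondrial outer membranes: spherical mitochondria, count x unit volume
  mito <- atlas$organelles[atlas$organelles$organelle == "mitochondrion", ]
  mito_area <- 0
  for (i in seq_len(nrow(mito))) {
    o <- mito[i, ]
    if (is.na(o$count_per_cell) || is.na(o$unit_volume_fL)) next
    n_cells <- cen$count[cen$id == o$cell_type]
    mito_area <- mito_area +
      n_cells * o$count_per_cell * sphere_area(sphere_radius_from_volume(o$unit_volume_fL))
  }

  # thylakoid and envelope areas: per-chloroplast parameters apply to the
  # mesophyll chloroplast pool (the only one with sub-plastidial data)
  chl <- atlas$organelles[atlas$organelles$organelle %in% c("chloroplast", "plastid") &
                            atlas$organelles$cell_type %in% c("palisade", "spongy"), ]
  n_chl <- sum(vapply(seq_len(nrow(chl)), function(i)
    cen$count[cen$id == chl$cell_type[i]] * chl$count_per_cell[i], numeric(1)))
  thylakoid_area <- n_chl * atlas$params$thylakoid_area_per_chloroplast
  envelope_area <- n_chl * atlas$params$envelope_area_per_chloroplast

  S <- atlas$context$leaf_area
  ratios <- c(
    plasma_membrane = leaf_area_ratio(pm_total, S),
    thylakoid = leaf_area_ratio(thylakoid_area, S),
    chloroplast_envelope = leaf_area_ratio(envelope_area, S),
    mitochondrial_outer = leaf_area_ratio(mito_area, S),
    thylakoid_over_envelope = thylakoid_area / envelope_area)

  wall_total <- sum(per_type$wall_volume_uL)
  list(per_type = per_type,
       plasma_membrane_um2 = pm_total,
       plasma_membrane_cm2 = pm_total / 1e8,
       total_chloroplast_area_cm2 = envelope_area / 1e8,
       ratios = ratios,
       wall_volume_uL = wall_total,
       wall_fraction = wall_total / sum(cen$volume_uL),
       macroscopic_wall_fraction = atlas$params$macroscopic_wall_fraction)
}

#' Microscopic cell-wall fraction of the total cellular volume
#' @param atlas a `leaf_atlas`.
#' @return fraction (dimensionless).
#' @export
leaf_wall_fraction <- function(atlas) {
  surface_report(atlas)$wall_fraction
}
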