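#' @title Cell census
#' @name census
#' @description
#' Cell numbers per reference leaf resolved from four count rules:
#' surface densities times leaf area (epidermal and mesophyll cells),
#' vein metrics (number per vein cross-section times vein length over cell
#' length, with a cone correction for the conical midrib), a fixed
#' multiplier per trichome (basal cells), and fixed counts. Counts are kept
#' as real numbers internally and rounded only for reporting, so subtotal
#' conservation is exact.
NULL

#' Cell count from a surface density
#' @param density cells per mm2 of one-sided leaf area.
#' @param leaf_area one-sided leaf area, mm2.
#' @param sides 1 or 2 (count one or both leaf faces).
#' @return cell count.
#' @export
cells_from_density <- function(density, leaf_area, sides = 1) {
  if (density < 0) stop("density must be >= 0")
  if (leaf_area <= 0) stop("leaf_area must be > 0")
  if (!sides %in% c(1, 2)) stop("sides must be 1 or 2")
  density * leaf_area * sides
}

#' Cell count from vein metrics
#'
#' Number per cross-section times vein length over cell length; the count
#' for the conical midrib is that of its circumscribing cylinder divided
#' by 3 ([cone_correction()]).
#'
#' @param n_cs average number of cells of this type per vein cross-section.
#' @param length_mm vein length, mm.
#' @param cell_length_um cell length along the vein axis, um.
#' @param cone apply the cone correction (midrib)?
#' @return cell count.
#' @export
vein_cell_count <- function(n_cs, length_mm, cell_length_um, cone = FALSE) {
  if (n_cs < 0 || length_mm < 0) stop("vein metrics must be >= 0")
  if (cell_length_um <= 0) stop("cell_length_um must be > 0")
  n <- n_cs * (length_mm * 1000 / cell_length_um)
  if (cone) cone_correction(n) else n
}

#' Basal cell count from the trichome count
#' @param n_trichomes trichome count.
#' @param multiplier basal cells per trichome (default 12).
#' @return basal cell count.
#' @export
trichome_basal_count <- function(n_trichomes, multiplier = 12) {
  if (n_trichomes < 0 || multiplier < 0) stop("counts must be >= 0")
  n_trichomes * multiplier
}

# Effective vein length (mm) for one cell type: the sum over the vein
# orders it occupies, with cone-corrected orders contributing length/3
# (equivalent to cone-correcting their counts).
.effective_vein_length <- function(atlas, orders) {
  sel <- atlas$veins$order %in% orders
  if (!any(sel)) stop("no vein orders matched: ", paste(orders, collapse = ";"))
  with(atlas$veins[sel, ], sum(ifelse(cone_corrected, length_mm / 3, length_mm)))
}

#' Resolve the census of a leaf atlas
#'
#' Applies each cell type's count rule and returns one row per type with
#' its count, tissue class and single-cell volume.
#'
#' @param atlas a `leaf_atlas`.
#' @return data.frame with columns `id`, `tissue_class`, `count`,
#'   `single_cell_volume_pL`, `volume_uL` (count x single-cell volume,
#'   uL per leaf).
#' @export
cell_census <- function(atlas) {
  ct <- atlas$cell_types
  counts <- numeric(nrow(ct))
  names(counts) <- ct$id
  # trichomes must resolve before their basal cells
  ord <- order(ct$count_rule == "per_trichome_multiplier")
  for (i in ord) {
    row <- ct[i, ]
    counts[row$id] <- switch(row$count_rule,
      density_times_area = cells_from_density(
        row$density_per_mm2, atlas$context$leaf_area,
        if (is.na(row$sides)) 1 else row$sides),
      vein_derived = {
        orders <- strsplit(row$vein_orders, ";", fixed = TRUE)[[1]]
        vein_cell_count(row$vein_n_cs,
                        .effective_vein_length(atlas, orders),
                        row$cell_length_um, cone = FALSE)
      },
      per_trichome_multiplier = trichome_basal_count(
        counts[["trichome"]], row$trichome_multiplier),
      fixed = row$fixed_count,
      stop("unknown count rule: ", row$count_rule))
  }
  missing <- names(counts)[is.na(counts)]
  if (length(missing))
    stop("census completeness error: unresolved cell types: ",
         paste(missing, collapse = ", "))
  data.frame(id = ct$id, tissue_class = ct$tissue_class, count = unname(counts),
             single_cell_volume_pL = ct$single_cell_volume_pL,
             volume_uL = unname(counts) * ct$single_cell_volume_pL * 1e-6,
             stringsAsFactors = FALSE)
}

#' Total cell number with per-type and tissue-class subtotals
#' @param atlas a `leaf_atlas`.
#' @return list with `total`, `by_type` (census data.frame) and `by_class`
#'   (counts and volumes per tissue class). Subtotals partition the total
#'   exactly.
#' @export
total_cells <- function(atlas) {
  cen <- cell_census(atlas)
  by_class <- aggregate(cbind(count, volume_uL) ~ tissue_class, data = cen, FUN = sum)
  list(total = sum(cen$count), by_type = cen, by_class = by_class)
}

#' Total cellular volume per leaf
#' @param atlas a `leaf_atlas`.
#' @return uL per leaf, summed over all cell types.
#' @export
total_cell_volume <- function(atlas) {
  sum(cell_census(atlas)$volume_uL)
}

#' Extrapolate a per-leaf count to the whole rosette
#' @param leaf_count cells per reference leaf.
#' @param leaf_area reference leaf area, mm2.
#' @param rosette_area total rosette leaf area, mm2.
#' @return extrapolated rosette cell count (linear in `leaf_count`).
#' @export
rosette_extrapolation <- function(leaf_count, leaf_area, rosette_area) {
  if (leaf_area <= 0) stop("leaf_area must be > 0")
  if (rosette_area <= 0) stop("rosette_area must be > 0")
  leaf_count * rosette_area / leaf_area
}

#' Census report in a chosen basis
#'
#' Table-2-style summary: per-type counts and volumes, with volumes
#' optionally re-expressed per g fresh weight or per mg chlorophyll.
#'
#' @param atlas a `leaf_atlas`.
#' @param basis `"per_leaf"` (default), `"per_gram_LFW"` or `"per_mg_chl"`.
#' @return data.frame of the census with a `volume` column in the requested
#'   basis (uL per basis unit).
#' @export
census_report <- function(atlas, basis = "per_leaf") {
  cen <- cell_census(atlas)
  f <- .basis_factor_from_leaf(basis, atlas$context)
  cen$volume <- cen$volume_uL * f
  cen$basis <- basis
  cen
}
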