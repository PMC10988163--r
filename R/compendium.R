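#' @title The parameter compendium
#' @name compendium
#' @description
#' A `leaf_atlas` bundles everything the pipeline needs: the leaf-level
#' context constants, the vein-length table, one record per cell type
#' (count rule, single-cell volume, shape model, wall thickness), the
#' organelle specifications used to build compartment budgets, the
#' sub-organelle budgets of the chloroplast and the mitochondrion, and a
#' small set of named scalar parameters (stomatal densities, membrane
#' areas per chloroplast, shape factors). The on-disk form is a single
#' long-format CSV mirroring a curated multi-sheet workbook: one record
#' per row with sheet, name, cell type, compartment, value, sd, unit,
#' basis, quality and provenance columns.
NULL

.compendium_columns <- c("sheet", "line_ref", "name", "cell_type", "compartment",
                         "value", "sd", "unit", "basis", "quality", "reference",
                         "method", "growth_conditions", "comment")

.tissue_classes <- c("epidermal", "photosynthetic", "vein")

.count_rules <- c("density_times_area", "vein_derived", "per_trichome_multiplier", "fixed")

.shape_kinds <- c("sphere", "sphere_from_volume", "ellipsoid", "capsule",
                  "cylinder_closed", "cylinder_hollow", "semi_torus",
                  "pavement_prism")

.cell_type_ids <- c(
  "pavement_abaxial", "pavement_adaxial", "stomata_guard", "trichome",
  "trichome_basal", "palisade", "spongy", "bundle_sheath",
  "phloem_companion", "phloem_parenchyma", "sieve_element",
  "xylem_parenchyma", "xylem_tracheid", "cambial", "hydathode")

#' Enumerated vocabulary of the compendium
#' @return a list with the accepted cell-type ids, tissue classes, count
#'   rules and shape kinds.
#' @export
atlas_vocabulary <- function() {
  list(cell_types = .cell_type_ids, tissue_classes = .tissue_classes,
       count_rules = .count_rules, shape_kinds = .shape_kinds)
}

# numeric columns of the cell-type table, all serialised as individual rows
.cell_numeric_fields <- c(
  density_per_mm2 = "per_mm2", sides = "count", fixed_count = "count",
  trichome_multiplier = "count", vein_n_cs = "count", cell_length_um = "um",
  single_cell_volume_pL = "pL", height_um = "um", wall_thickness_um = "um",
  shape_r = "um", shape_l = "um", shape_r_c = "um", shape_h = "um",
  shape_r_s = "um", shape_R = "um")

.cell_category_fields <- c("tissue_class", "side", "count_rule", "shape_kind",
                           "vein_orders")

#' Construct a leaf atlas
#'
#' Low-level constructor; see [reference_leaf6_fixture()] for the bundled
#' reference atlas and [make_toy_atlas()] for randomised test atlases.
#'
#' @param context a [leaf_context()].
#' @param veins data.frame with columns `order` (midrib/secondary/higher),
#'   `length_mm`, `cone_corrected` (logical; midrib only).
#' @param cell_types data.frame, one row per cell type (see package vignette
#'   for the column contract).
#' @param organelles data.frame with columns `cell_type`, `organelle`,
#'   `source_mode` (count_times_volume / direct_fraction / derived_share),
#'   `count_per_cell`, `unit_volume_fL`, `fraction`, `quality`, `reference`.
#' @param chloroplast_sub,mitochondrion_sub data.frames with columns
#'   `compartment`, `fraction` for the fixed sub-organelle entries (the
#'   free compartments, starch and intermembrane space, are not listed).
#' @param params named list of scalar parameters.
#' @return an object of class `leaf_atlas`.
#' @export
leaf_atlas <- function(context, veins, cell_types, organelles,
                       chloroplast_sub, mitochondrion_sub, params) {
  stopifnot(inherits(context, "leaf_context"))
  atlas <- structure(
    list(context = context, veins = veins, cell_types = cell_types,
         organelles = organelles, chloroplast_sub = chloroplast_sub,
         mitochondrion_sub = mitochondrion_sub, params = params),
    class = "leaf_atlas")
  validate_atlas(atlas)
  atlas
}

#' Validate a leaf atlas
#'
#' Checks the structural invariants: known cell types, tissue classes,
#' count rules and shapes; exactly one active count rule per cell type;
#' vein-derived types carry a cell length; pavement types carry a height;
#' organelle fractions in [0, 1]; sub-budget fixed entries summing to < 1.
#'
#' @param atlas a `leaf_atlas`.
#' @return the atlas, invisibly; stops with an informative error otherwise.
#' @export
validate_atlas <- function(atlas) {
  ct <- atlas$cell_types
  if (!all(ct$tissue_class %in% .tissue_classes))
    stop("unknown tissue class: ",
         paste(setdiff(ct$tissue_class, .tissue_classes), collapse = ", "))
  if (!all(ct$count_rule %in% .count_rules))
    stop("unknown count rule: ",
         paste(setdiff(ct$count_rule, .count_rules), collapse = ", "))
  if (!all(ct$shape_kind %in% .shape_kinds))
    stop("unknown shape kind: ",
         paste(setdiff(ct$shape_kind, .shape_kinds), collapse = ", "))
  if (anyDuplicated(ct$id))
    stop("duplicated cell type id")
  rule_fields <- list(
    density_times_area = "density_per_mm2", vein_derived = "vein_n_cs",
    per_trichome_multiplier = "trichome_multiplier", fixed = "fixed_count")
  for (i in seq_len(nrow(ct))) {
    row <- ct[i, ]
    need <- rule_fields[[row$count_rule]]
    if (is.na(row[[need]]))
      stop("cell type '", row$id, "': count rule ", row$count_rule,
           " requires field ", need)
    others <- setdiff(unlist(rule_fields), need)
    if (any(!is.na(unlist(row[others]))))
      stop("cell type '", row$id, "': more than one count rule active")
    if (row$count_rule == "vein_derived" && is.na(row$cell_length_um))
      stop("cell type '", row$id, "': vein-derived census requires cell_length_um")
    if (row$shape_kind == "pavement_prism" && is.na(row$height_um))
      stop("cell type '", row$id, "': pavement cells require height_um")
    if (!is.na(row$single_cell_volume_pL) && row$single_cell_volume_pL <= 0)
      stop("cell type '", row$id, "': single-cell volume must be positive")
  }
  og <- atlas$organelles
  if (!all(og$cell_type %in% ct$id))
    stop("organelle rows reference unknown cell types: ",
         paste(setdiff(og$cell_type, ct$id), collapse = ", "))
  fr <- og$fraction[!is.na(og$fraction)]
  if (any(fr < 0 | fr > 1)) stop("organelle fractions must lie in [0, 1]")
  for (nm in c("chloroplast_sub", "mitochondrion_sub")) {
    s <- sum(atlas[[nm]]$fraction)
    if (s >= 1) stop(nm, ": fixed sub-compartment fractions sum to ", s, " >= 1")
  }
  invisible(atlas)
}

#' @export
print.leaf_atlas <- function(x, ...) {
  cat("<leaf_atlas>\n")
  cat("  leaf area:", x$context$leaf_area, "mm2; LDS",
      round(leaf_developmental_stage(x$context), 2), "\n")
  cat("  cell types:", nrow(x$cell_types), "; vein classes:",
      nrow(x$veins), "\n")
  cat("  organelle records:", nrow(x$organelles), "\n")
  invisible(x)
}

# ---- serialisation ---------------------------------------------------------

.row <- function(sheet, name, value, unit, cell_type = NA, compartment = NA,
                 sd = NA, basis = NA, quality = "reference_condition",
                 reference = NA, method = NA, growth_conditions = NA,
                 comment = NA) {
  data.frame(sheet = sheet, line_ref = NA_integer_, name = name,
             cell_type = cell_type, compartment = compartment,
             value = as.character(value), sd = as.numeric(sd), unit = unit,
             basis = basis, quality = quality, reference = reference,
             method = method, growth_conditions = growth_conditions,
             comment = comment, stringsAsFactors = FALSE)
}

#' Flatten a leaf atlas into the long-format compendium table
#' @param atlas a `leaf_atlas`.
#' @return data.frame in the documented column schema.
#' @export
as_compendium_table <- function(atlas) {
  out <- list()
  ctx <- atlas$context
  for (nm in names(ctx)) {
    unit <- switch(nm,
      leaf_area = , max_leaf_area = , rosette_leaf_area = "mm2",
      days_past_full_expansion = "days", leaf_fresh_weight = "mg",
      leaves_per_gram_LFW = "count_per_g", lfw_over_ldw = "dimensionless",
      chlorophyll_per_gram_LFW = "mg_per_gLFW", apoplast_volume = "uL_per_gLFW")
    out[[length(out) + 1L]] <- .row("leaf", nm, ctx[[nm]], unit)
  }
  for (i in seq_len(nrow(atlas$veins))) {
    v <- atlas$veins[i, ]
    out[[length(out) + 1L]] <- .row("veins", "length", v$length_mm, "mm",
                                    compartment = v$order,
                                    comment = if (v$cone_corrected) "cone_corrected" else NA)
  }
  ct <- atlas$cell_types
  for (i in seq_len(nrow(ct))) {
    row <- ct[i, ]
    for (f in .cell_category_fields) {
      if (!is.na(row[[f]]))
        out[[length(out) + 1L]] <- .row("cells", f, row[[f]], "category",
                                        cell_type = row$id)
    }
    for (f in names(.cell_numeric_fields)) {
      if (!is.na(row[[f]]))
        out[[length(out) + 1L]] <- .row("cells", f, row[[f]],
                                        .cell_numeric_fields[[f]],
                                        cell_type = row$id,
                                        quality = row$quality,
                                        reference = row$reference)
    }
  }
  og <- atlas$organelles
  for (i in seq_len(nrow(og))) {
    o <- og[i, ]
    out[[length(out) + 1L]] <- .row("budgets", "source_mode", o$source_mode,
                                    "category", cell_type = o$cell_type,
                                    compartment = o$organelle)
    if (!is.na(o$count_per_cell))
      out[[length(out) + 1L]] <- .row("budgets", "count_per_cell", o$count_per_cell,
                                      "count", cell_type = o$cell_type,
                                      compartment = o$organelle,
                                      quality = o$quality, reference = o$reference)
    if (!is.na(o$unit_volume_fL))
      out[[length(out) + 1L]] <- .row("budgets", "unit_volume", o$unit_volume_fL,
                                      "fL", cell_type = o$cell_type,
                                      compartment = o$organelle,
                                      quality = o$quality, reference = o$reference)
    if (!is.na(o$fraction))
      out[[length(out) + 1L]] <- .row("budgets", "fraction", o$fraction,
                                      "fraction", cell_type = o$cell_type,
                                      compartment = o$organelle,
                                      quality = o$quality, reference = o$reference)
  }
  for (i in seq_len(nrow(atlas$chloroplast_sub)))
    out[[length(out) + 1L]] <- .row("chloroplast_sub", "fraction",
                                    atlas$chloroplast_sub$fraction[i], "fraction",
                                    compartment = atlas$chloroplast_sub$compartment[i])
  for (i in seq_len(nrow(atlas$mitochondrion_sub)))
    out[[length(out) + 1L]] <- .row("mitochondrion_sub", "fraction",
                                    atlas$mitochondrion_sub$fraction[i], "fraction",
                                    compartment = atlas$mitochondrion_sub$compartment[i])
  for (nm in names(atlas$params)) {
    unit <- switch(nm,
      stomatal_density_abaxial = , stomatal_density_adaxial = "per_mm2",
      stomatal_complex_area = , thylakoid_area_per_chloroplast = ,
      envelope_area_per_chloroplast = "um2",
      macroscopic_wall_fraction = , er_share_of_cytosol = ,
      golgi_share_of_cytosol = "fraction",
      pavement_shape_factor = "dimensionless",
      "dimensionless")
    out[[length(out) + 1L]] <- .row("params", nm, atlas$params[[nm]], unit)
  }
  tab <- do.call(rbind, out)
  tab$line_ref <- seq_len(nrow(tab))
  tab
}

#' Write a compendium CSV
#' @param atlas a `leaf_atlas` (or a long-format compendium data.frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_compendium <- function(atlas, path) {
  tab <- if (inherits(atlas, "leaf_atlas")) as_compendium_table(atlas) else atlas
  utils::write.csv(tab, path, row.names = FALSE, na = "", fileEncoding = "UTF-8",
                   quote = which(names(tab) %in%
                                   c("method", "growth_conditions", "comment")))
  invisible(path)
}

.num <- function(x) {
  suppressWarnings(as.numeric(x))
}

.pick <- function(tab, sheet, name, cell_type = NULL, compartment = NULL) {
  sel <- tab$sheet == sheet & tab$name == name
  if (!is.null(cell_type)) sel <- sel & !is.na(tab$cell_type) & tab$cell_type == cell_type
  if (!is.null(compartment)) sel <- sel & !is.na(tab$compartment) & tab$compartment == compartment
  tab[sel, , drop = FALSE]
}

.pick1 <- function(tab, sheet, name, cell_type = NULL, compartment = NULL,
                   numeric = TRUE, default = NA) {
  hit <- .pick(tab, sheet, name, cell_type, compartment)
  if (nrow(hit) == 0L) return(default)
  if (nrow(hit) > 1L)
    stop("compendium: duplicate entry for ", sheet, "/", name)
  if (numeric) .num(hit$value) else hit$value
}

#' Read a compendium CSV into a leaf atlas
#'
#' Rejects files whose header does not match the documented column schema,
#' rows with units outside the closed registry (naming the offending row),
#' and unknown cell types.
#'
#' @param path path to a compendium CSV written by [write_compendium()].
#' @return a validated `leaf_atlas`.
#' @export
read_compendium <- function(path) {
  if (!file.exists(path)) stop("compendium file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         colClasses = "character", fileEncoding = "UTF-8")
  missing_cols <- setdiff(.compendium_columns, names(tab))
  if (length(missing_cols))
    stop("compendium schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  tab <- tab[, .compendium_columns]
  tab$sd <- .num(tab$sd)
  tab$line_ref <- as.integer(tab$line_ref)
  bad_unit <- which(!tab$unit %in% .unit_registry)
  if (length(bad_unit))
    stop("compendium unit error: unparseable unit '", tab$unit[bad_unit[1]],
         "' in row ", bad_unit[1], " (", tab$sheet[bad_unit[1]], "/",
         tab$name[bad_unit[1]], ")")
  known_ct <- !is.na(tab$cell_type)
  bad_ct <- setdiff(tab$cell_type[known_ct], .cell_type_ids)
  if (length(bad_ct))
    stop("compendium error: unknown cell type(s): ", paste(bad_ct, collapse = ", "))

  ctx_names <- c("leaf_area", "max_leaf_area", "days_past_full_expansion",
                 "leaf_fresh_weight", "leaves_per_gram_LFW", "lfw_over_ldw",
                 "chlorophyll_per_gram_LFW", "apoplast_volume", "rosette_leaf_area")
  ctx_vals <- lapply(ctx_names, function(nm) .pick1(tab, "leaf", nm))
  names(ctx_vals) <- ctx_names
  if (any(is.na(unlist(ctx_vals))))
    stop("compendium error: incomplete leaf context")
  context <- do.call(leaf_context, ctx_vals)

  vein_rows <- tab[tab$sheet == "veins", , drop = FALSE]
  veins <- data.frame(order = vein_rows$compartment,
                      length_mm = .num(vein_rows$value),
                      cone_corrected = !is.na(vein_rows$comment) &
                        vein_rows$comment == "cone_corrected",
                      stringsAsFactors = FALSE)

  ids <- unique(tab$cell_type[tab$sheet == "cells" & !is.na(tab$cell_type)])
  ct_list <- lapply(ids, function(id) {
    row <- list(id = id)
    for (f in .cell_category_fields)
      row[[f]] <- .pick1(tab, "cells", f, cell_type = id, numeric = FALSE,
                         default = NA_character_)
    for (f in names(.cell_numeric_fields))
      row[[f]] <- .pick1(tab, "cells", f, cell_type = id, default = NA_real_)
    qrow <- .pick(tab, "cells", "single_cell_volume_pL", cell_type = id)
    row$quality <- if (nrow(qrow)) qrow$quality[1] else "assumption"
    row$reference <- if (nrow(qrow)) qrow$reference[1] else NA_character_
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  cell_types <- do.call(rbind, ct_list)

  brow <- tab[tab$sheet == "budgets", , drop = FALSE]
  keys <- unique(brow[, c("cell_type", "compartment")])
  og_list <- lapply(seq_len(nrow(keys)), function(i) {
    ctid <- keys$cell_type[i]; org <- keys$compartment[i]
    qrow <- .pick(tab, "budgets", "fraction", ctid, org)
    if (nrow(qrow) == 0L) qrow <- .pick(tab, "budgets", "count_per_cell", ctid, org)
    data.frame(
      cell_type = ctid, organelle = org,
      source_mode = .pick1(tab, "budgets", "source_mode", ctid, org, numeric = FALSE),
      count_per_cell = .pick1(tab, "budgets", "count_per_cell", ctid, org, default = NA_real_),
      unit_volume_fL = .pick1(tab, "budgets", "unit_volume", ctid, org, default = NA_real_),
      fraction = .pick1(tab, "budgets", "fraction", ctid, org, default = NA_real_),
      quality = if (nrow(qrow)) qrow$quality[1] else "assumption",
      reference = if (nrow(qrow)) qrow$reference[1] else NA_character_,
      stringsAsFactors = FALSE)
  })
  organelles <- do.call(rbind, og_list)

  sub_tab <- function(sheet) {
    rows <- tab[tab$sheet == sheet, , drop = FALSE]
    data.frame(compartment = rows$compartment, fraction = .num(rows$value),
               stringsAsFactors = FALSE)
  }
  prow <- tab[tab$sheet == "params", , drop = FALSE]
  params <- as.list(.num(prow$value))
  names(params) <- prow$name

  leaf_atlas(context = context, veins = veins, cell_types = cell_types,
             organelles = organelles,
             chloroplast_sub = sub_tab("chloroplast_sub"),
             mitochondrion_sub = sub_tab("mitochondrion_sub"),
             params = params)
}
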