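#' @title Metabolite unit harmonisation
#' @name unitconv
#' @description
#' Converts metabolite quantitations published in heterogeneous units into
#' a single harmonised unit (concentration in uM), via an intermediate
#' amount per gram of leaf fresh weight and the leaf-level volumes of the
#' compartments in which each metabolite is localised. When a metabolite is
#' distributed over several compartments, equal concentrations across them
#' are assumed: amount (nmol/g LFW) divided by the summed compartment
#' volume (uL/g LFW) gives nmol/uL = mM, times 1000 gives uM. Compartment
#' volumes are assumed constant across studies and conditions; the volume
#' table is injectable to probe that assumption.
NULL

.metabolite_units <- c("nmol_per_gLFW", "nmol_per_gLDW", "nmol_per_mgchl",
                       "nmol_per_leaf", "umol_per_m2_leaf", "uM")

.compartment_ontology <- c("cytosol", "plastid_stroma", "thylakoid_lumen",
                           "mitochondrial_matrix", "intermembrane_space",
                           "peroxisome", "vacuole", "ER", "Golgi", "nucleus",
                           "apoplast", "whole_cell")

# free-text localisation strings -> ontology ids; unmatched strings are
# never guessed (the record becomes not-convertible instead)
.localisation_synonyms <- c(
  "cytosol" = "cytosol", "cytoplasm" = "cytosol",
  "chloroplast" = "plastid_stroma", "plastid" = "plastid_stroma",
  "stroma" = "plastid_stroma", "plastid_stroma" = "plastid_stroma",
  "thylakoid_lumen" = "thylakoid_lumen", "lumen" = "thylakoid_lumen",
  "mitochondrion" = "mitochondrial_matrix", "matrix" = "mitochondrial_matrix",
  "mitochondrial_matrix" = "mitochondrial_matrix",
  "intermembrane_space" = "intermembrane_space",
  "peroxisome" = "peroxisome", "vacuole" = "vacuole",
  "er" = "ER", "endoplasmic_reticulum" = "ER", "golgi" = "Golgi",
  "nucleus" = "nucleus", "apoplast" = "apoplast", "cell_wall" = "apoplast",
  "whole_cell" = "whole_cell", "whole_leaf" = "whole_cell", "cell" = "whole_cell")

#' The compartment ontology used for metabolite localisation
#' @return character vector of compartment ids.
#' @export
compartment_ontology <- function() .compartment_ontology

#' Map free-text localisation strings onto the compartment ontology
#' @param strings character vector (case-insensitive; spaces map to `_`).
#' @return character vector of ontology ids, `NA` where unmatched.
#' @export
normalise_localisation <- function(strings) {
  key <- gsub(" ", "_", tolower(trimws(strings)))
  unname(.localisation_synonyms[key])
}

#' Convert a published amount to nmol per g leaf fresh weight
#'
#' Supported original units: nmol/g LFW (identity), nmol/g LDW (divide by
#' the fresh/dry weight ratio), nmol/mg chlorophyll (times mg chl per g
#' LFW), nmol/leaf (times leaves per g LFW), umol/m2 of leaf (via the
#' one-sided leaf area and leaves per g LFW).
#'
#' @param value numeric amount in `unit`.
#' @param unit one of the supported unit symbols.
#' @param ctx a [leaf_context()].
#' @return amount in nmol per g LFW.
#' @export
to_per_gram_LFW <- function(value, unit, ctx) {
  if (!unit %in% setdiff(.metabolite_units, "uM"))
    stop("conversion error: unsupported unit '", unit, "'")
  needed <- c("lfw_over_ldw", "chlorophyll_per_gram_LFW", "leaves_per_gram_LFW",
              "leaf_area")
  if (any(vapply(needed, function(nm) is.null(ctx[[nm]]), logical(1))))
    stop("configuration error: leaf context is missing a conversion factor")
  switch(unit,
    nmol_per_gLFW = value,
    nmol_per_gLDW = value / ctx$lfw_over_ldw,
    nmol_per_mgchl = value * ctx$chlorophyll_per_gram_LFW,
    nmol_per_leaf = value * ctx$leaves_per_gram_LFW,
    umol_per_m2_leaf = value * 1000 * (ctx$leaf_area * 1e-6) * ctx$leaves_per_gram_LFW
  )
}

#' Leaf-level compartment volume table
#'
#' Builds the uL-per-g-LFW volume table used for concentration
#' calculations. The default neglects epidermal and vein cells (little is
#' known about their metabolism and they contribute a small share of the
#' leaf volume) and is therefore the mesophyll-weighted table: palisade and
#' spongy budgets aggregated to the leaf, plus the sub-plastidial and
#' sub-mitochondrial splits and the measured apoplast volume.
#'
#' @param atlas a `leaf_atlas`.
#' @param cell_types cell types included (default palisade + spongy).
#' @return named numeric vector, uL per g LFW, over the compartment
#'   ontology.
#' @export
compartment_volume_table <- function(atlas, cell_types = c("palisade", "spongy")) {
  agg <- aggregate_to_leaf(atlas, included_cell_types = cell_types,
                           basis = "per_gram_LFW")
  v <- stats::setNames(agg$volumes$volume, agg$volumes$compartment)
  sub <- sub_organelle_budgets(atlas)
  chl <- v[["chloroplast"]]
  mit <- v[["mitochondrion"]]
  vols <- c(
    cytosol = v[["cytosol"]],
    plastid_stroma = chl * sub$chloroplast$entries[["stroma"]],
    thylakoid_lumen = chl * sub$chloroplast$entries[["thylakoid_lumen"]],
    mitochondrial_matrix = mit * sub$mitochondrion$entries[["matrix"]],
    intermembrane_space = mit * sub$mitochondrion$entries[["intermembrane_space"]],
    peroxisome = v[["peroxisome"]],
    vacuole = v[["vacuole"]],
    ER = v[["ER"]],
    Golgi = v[["Golgi"]],
    nucleus = v[["nucleus"]],
    apoplast = atlas$context$apoplast_volume,
    whole_cell = sum(v))
  if (any(vols < 0)) stop("negative compartment volume")
  vols
}

#' Concentration in uM from an amount and a localisation set
#'
#' @param amount_nmol_per_g amount, nmol per g LFW.
#' @param localisation character vector of compartment ontology ids.
#' @param vols named volume table, uL per g LFW (see
#'   [compartment_volume_table()]).
#' @return list with `uM` (numeric or `NA`), `ok` (logical) and `reason`
#'   (why a record is not convertible; conversion failures do not throw, so
#'   batches keep going).
#' @export
concentration_uM <- function(amount_nmol_per_g, localisation, vols) {
  localisation <- localisation[!is.na(localisation)]
  if (length(localisation) == 0L)
    return(list(uM = NA_real_, ok = FALSE, reason = "no localisation"))
  unknown <- setdiff(localisation, names(vols))
  if (length(unknown))
    return(list(uM = NA_real_, ok = FALSE,
                reason = paste0("unknown compartment: ", paste(unknown, collapse = ";"))))
  total_vol <- sum(vols[unique(localisation)])
  if (total_vol <= 0)
    return(list(uM = NA_real_, ok = FALSE, reason = "zero compartment volume"))
  list(uM = amount_nmol_per_g / total_vol * 1000, ok = TRUE, reason = NA_character_)
}

#' Harmonise a batch of metabolite records to uM
#'
#' Input records carry a name, identifiers, an amount (single value and/or
#' min-max range) in an original unit, and a curated localisation
#' (semicolon-separated free text, mapped through the synonym table; an
#' unmatched string makes the record not-convertible, it is never guessed).
#' Output mirrors the input with intermediate nmol-per-g-LFW columns and
#' final uM columns appended, the metabolite name duplicated in the last
#' column; amounts already published as uM pass through with a flag. Rows
#' sharing a non-empty `isomer_group` additionally get the summed group
#' concentration (isomers in spontaneous equilibrium are reported as their
#' sum). Failures are collected in a rejects table with reasons.
#'
#' @param records data.frame with columns `name`, `amount_value`,
#'   `amount_min`, `amount_max`, `original_unit`, `localisation`; optional
#'   `molecular_weight`, identifier columns, `material`, `method`,
#'   `reference`, `isomer_group`.
#' @param vols named compartment volume table, uL per g LFW.
#' @param ctx a [leaf_context()].
#' @return list with `harmonised` and `rejects` data.frames.
#' @export
convert_batch <- function(records, vols, ctx) {
  need <- c("name", "amount_value", "amount_min", "amount_max",
            "original_unit", "localisation")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("metabolite table schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  n <- nrow(records)
  out <- records
  for (col in c("nmol_per_gLFW_value", "nmol_per_gLFW_min", "nmol_per_gLFW_max",
                "uM_value", "uM_min", "uM_max"))
    out[[col]] <- NA_real_
  out$conversion_flag <- NA_character_
  ok <- logical(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    rec <- records[i, ]
    amounts <- c(value = rec$amount_value, min = rec$amount_min, max = rec$amount_max)
    if (all(is.na(amounts))) { reason[i] <- "no amount"; next }
    if (!is.na(rec$amount_min) && !is.na(rec$amount_max) &&
        rec$amount_min > rec$amount_max) { reason[i] <- "min > max"; next }
    if (rec$original_unit == "uM") {
      # as-published concentration (e.g. non-aqueous fractionation):
      # passed through, flagged, not re-normalised
      for (k in names(amounts))
        out[[paste0("uM_", k)]][i] <- amounts[[k]]
      out$conversion_flag[i] <- "as_published_uM"
      ok[i] <- TRUE
      next
    }
    if (!rec$original_unit %in% .metabolite_units) {
      reason[i] <- paste0("unsupported unit: ", rec$original_unit)
      next
    }
    loc_raw <- strsplit(as.character(rec$localisation), ";", fixed = TRUE)[[1]]
    loc_raw <- loc_raw[nzchar(trimws(loc_raw))]
    loc <- normalise_localisation(loc_raw)
    if (length(loc_raw) && anyNA(loc)) {
      reason[i] <- paste0("unmapped localisation: ",
                          paste(loc_raw[is.na(loc)], collapse = ";"))
      next
    }
    per_g <- vapply(amounts, function(a)
      if (is.na(a)) NA_real_ else to_per_gram_LFW(a, rec$original_unit, ctx),
      numeric(1))
    conc <- concentration_uM(per_g[["value"]], loc, vols)
    if (!conc$ok && length(loc) == 0L) { reason[i] <- "no localisation"; next }
    if (!conc$ok && !is.na(per_g[["value"]])) { reason[i] <- conc$reason; next }
    total_vol <- sum(vols[unique(loc)])
    for (k in names(amounts)) {
      out[[paste0("nmol_per_gLFW_", k)]][i] <- per_g[[k]]
      out[[paste0("uM_", k)]][i] <-
        if (is.na(per_g[[k]])) NA_real_ else per_g[[k]] / total_vol * 1000
    }
    out$conversion_flag[i] <- "converted"
    ok[i] <- TRUE
  }
  if ("isomer_group" %in% names(out)) {
    out$uM_isomer_group_sum <- NA_real_
    grp <- out$isomer_group
    for (g in unique(grp[!is.na(grp) & nzchar(grp)])) {
      sel <- which(!is.na(grp) & grp == g & ok)
      if (length(sel) > 1L) {
        out$uM_isomer_group_sum[sel] <- sum(out$uM_value[sel], na.rm = TRUE)
        out$conversion_flag[sel] <- paste0(out$conversion_flag[sel], "+isomer_sum")
      }
    }
  }
  out$metabolite_name <- out$name  # duplicated in the final column
  rejects <- cbind(records[!ok, , drop = FALSE],
                   reason = reason[!ok], stringsAsFactors = FALSE)
  list(harmonised = out[ok, , drop = FALSE], rejects = rejects)
}
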