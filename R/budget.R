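#' @title Compartment volume budgets
#' @name budget
#' @description
#' Per-cell-type fractional volume occupancies with free-variable closure.
#' Each budget lists fixed compartment fractions (from organelle counts
#' times unit volumes, or direct measured fractions) and designates one
#' free compartment whose fraction is set to one minus the sum of the
#' others: the vacuole for whole cells, starch for the chloroplast
#' sub-budget, the intermembrane space for the mitochondrial sub-budget.
NULL

#' Fractional volume occupancy
#'
#' @param total_organelle_volume summed organelle volume in the cell, fL.
#' @param cell_volume cell volume, fL.
#' @return the ratio. A ratio above 1 is physically inconsistent and raises
#'   a warning (never silently accepted); negative inputs are errors.
#' @export
fractional_occupancy <- function(total_organelle_volume, cell_volume) {
  if (cell_volume <= 0) stop("cell_volume must be > 0")
  if (total_organelle_volume < 0) stop("organelle volume must be >= 0")
  f <- total_organelle_volume / cell_volume
  if (f > 1)
    warning("organelle volume exceeds cell volume (occupancy ", signif(f, 4), ")")
  f
}

#' Construct a compartment budget
#'
#' @param cell_type cell type id (or a label for sub-organelle budgets).
#' @param entries named numeric vector of fixed fractions in [0, 1].
#' @param free_variable compartment whose fraction closes the budget; must
#'   not appear among the fixed entries.
#' @return object of class `compartment_budget`, not yet closed.
#' @export
compartment_budget <- function(cell_type, entries, free_variable = "vacuole") {
  if (is.null(names(entries)) || any(!nzchar(names(entries))))
    stop("budget entries must be named")
  if (free_variable %in% names(entries))
    stop("free variable '", free_variable, "' must not be among the fixed entries")
  if (any(entries < 0 | entries > 1))
    stop("budget fractions must lie in [0, 1]")
  structure(list(cell_type = cell_type, entries = entries,
                 free_variable = free_variable, closed = FALSE),
            class = "compartment_budget")
}

#' Close a budget via its free variable
#'
#' Sets the free compartment to 1 minus the sum of the fixed entries, so
#' the closed fractions sum to exactly 1.
#'
#' @param b a `compartment_budget`.
#' @return the closed budget; its `entries` gain the free compartment.
#' @export
close_budget <- function(b) {
  stopifnot(inherits(b, "compartment_budget"))
  if (b$closed) return(b)
  s <- sum(b$entries)
  if (s > 1)
    stop("infeasible budget for '", b$cell_type, "': fixed fractions sum to ",
         signif(s, 6), " (excess ", signif(s - 1, 4), ")")
  free <- 1 - s
  # nudge the free entry so that the summed closed budget is bit-exactly 1
  # (sum() accumulates in extended precision, so 1 - sum(fixed) alone can
  # leave a one-ulp residual)
  for (k in 1:5) {
    resid <- 1 - sum(c(b$entries, free))
    if (resid == 0) break
    free <- free + resid
  }
  if (free < 0 && free > -1e-9) free <- 0
  b$entries <- c(b$entries, stats::setNames(free, b$free_variable))
  b$closed <- TRUE
  b
}

#' @export
print.compartment_budget <- function(x, ...) {
  cat("<compartment_budget> ", x$cell_type,
      if (x$closed) " (closed)" else " (open)", "\n", sep = "")
  print(round(x$entries, 5))
  invisible(x)
}

#' Split a gross cytosol fraction into cytosol, ER and Golgi
#'
#' Electron-microscopy 'cytosol' fractions usually lump the cytosol proper
#' with the ER, the Golgi and sometimes the nucleus. The ER is taken as a
#' fixed share of the gross fraction (default 3.23%) and the Golgi as one
#' tenth of the ER (0.323%); the nucleus fraction, when included in the
#' gross figure, is subtracted (pass 0 when measured separately).
#'
#' @param gross_fraction gross cytosol fraction of the cell volume.
#' @param nucleus_fraction nucleus fraction contained in the gross figure.
#' @param er_share ER share of the gross fraction.
#' @param golgi_share Golgi share of the gross fraction.
#' @return named list with `cytosol`, `ER` and `Golgi` fractions (all >= 0).
#' @export
cytosol_net <- function(gross_fraction, nucleus_fraction = 0,
                        er_share = 0.0323, golgi_share = 0.00323) {
  if (gross_fraction < nucleus_fraction)
    stop("gross cytosol fraction smaller than the nucleus fraction it contains")
  ER <- gross_fraction * er_share
  Golgi <- gross_fraction * golgi_share
  cytosol <- gross_fraction - nucleus_fraction - ER - Golgi
  if (cytosol < 0)
    stop("infeasible cytosol decomposition: net cytosol is negative")
  list(cytosol = cytosol, ER = ER, Golgi = Golgi)
}

# Fraction of the cell volume occupied by one organelle record.
.organelle_fraction <- function(o, cell_volume_fL) {
  has_cxv <- !is.na(o$count_per_cell) && !is.na(o$unit_volume_fL)
  if (has_cxv) {
    f <- fractional_occupancy(o$count_per_cell * o$unit_volume_fL, cell_volume_fL)
    if (!is.na(o$fraction) && abs(f - o$fraction) > 1e-6 * max(1e-12, o$fraction))
      message("organelle '", o$organelle, "' in '", o$cell_type,
              "': count x volume gives ", signif(f, 4),
              " but a direct fraction ", signif(o$fraction, 4),
              " is also recorded; using count x volume")
    f
  } else if (!is.na(o$fraction)) {
    o$fraction
  } else {
    stop("organelle '", o$organelle, "' in '", o$cell_type,
         "': neither count x volume nor fraction available")
  }
}

#' Build the closed compartment budget of one cell type
#'
#' Collects the cell type's organelle records, decomposes the gross
#' cytosol fraction into cytosol/ER/Golgi (subtracting the nucleus when the
#' gross figure includes it), carries an explicit zero for lipid droplets,
#' and closes with the vacuole as the free variable.
#'
#' @param atlas a `leaf_atlas`.
#' @param cell_type a cell type id present in the atlas organelle table.
#' @return a closed `compartment_budget` whose entries sum to exactly 1.
#' @export
cell_budget <- function(atlas, cell_type) {
  og <- atlas$organelles[atlas$organelles$cell_type == cell_type, , drop = FALSE]
  if (nrow(og) == 0L)
    stop("no subcellular data for cell type '", cell_type, "'")
  ct <- atlas$cell_types[atlas$cell_types$id == cell_type, ]
  cell_vol <- ct$single_cell_volume_pL * 1e3  # fL
  entries <- c()
  gross <- NA_real_
  gross_incl_nucleus <- FALSE
  for (i in seq_len(nrow(og))) {
    o <- og[i, ]
    if (o$organelle %in% c("cytosol_gross", "cytosol_gross_incl_nucleus")) {
      gross <- .organelle_fraction(o, cell_vol)
      gross_incl_nucleus <- o$organelle == "cytosol_gross_incl_nucleus"
    } else {
      entries[o$organelle] <- .organelle_fraction(o, cell_vol)
    }
  }
  if (!is.na(gross)) {
    nuc_in_gross <- if (gross_incl_nucleus) {
      if (is.na(entries["nucleus"]))
        stop("cell type '", cell_type,
             "': gross cytosol includes the nucleus but no nucleus record found")
      unname(entries["nucleus"])
    } else 0
    parts <- cytosol_net(gross, nuc_in_gross,
                         er_share = atlas$params$er_share_of_cytosol,
                         golgi_share = atlas$params$golgi_share_of_cytosol)
    entries["cytosol"] <- parts$cytosol
    entries["ER"] <- parts$ER
    entries["Golgi"] <- parts$Golgi
  }
  if (!"lipid_droplet" %in% names(entries)) entries["lipid_droplet"] <- 0
  close_budget(compartment_budget(cell_type, entries, free_variable = "vacuole"))
}

#' Closed sub-organelle budgets of the chloroplast and the mitochondrion
#'
#' The chloroplast budget closes on starch; the mitochondrial budget closes
#' on the intermembrane space.
#'
#' @param atlas a `leaf_atlas`.
#' @return named list of two closed `compartment_budget`s, `chloroplast`
#'   and `mitochondrion`.
#' @export
sub_organelle_budgets <- function(atlas) {
  chl <- close_budget(compartment_budget(
    "chloroplast",
    stats::setNames(atlas$chloroplast_sub$fraction, atlas$chloroplast_sub$compartment),
    free_variable = "starch"))
  mit <- close_budget(compartment_budget(
    "mitochondrion",
    stats::setNames(atlas$mitochondrion_sub$fraction, atlas$mitochondrion_sub$compartment),
    free_variable = "intermembrane_space"))
  list(chloroplast = chl, mitochondrion = mit)
}

#' Cell types with complete subcellular data
#'
#' A cell type is "covered" when its organelle records are complete enough
#' to close a whole-cell budget: it needs a gross cytosol fraction, a
#' mitochondrion record and a nucleus record (plastid-only types such as
#' vein cells are excluded). In the reference atlas these are the epidermal
#' pavement cells and the two mesophyll cell types.
#'
#' @param atlas a `leaf_atlas`.
#' @return character vector of cell type ids.
#' @export
covered_cell_types <- function(atlas) {
  og <- atlas$organelles
  has <- function(id, orgs) any(og$cell_type == id & og$organelle %in% orgs)
  ids <- unique(og$cell_type)
  ids[vapply(ids, function(id)
    has(id, c("cytosol_gross", "cytosol_gross_incl_nucleus")) &&
      has(id, "mitochondrion") && has(id, "nucleus"), logical(1))]
}

#' Aggregate compartment volumes to the leaf level
#'
#' Sums fraction x single-cell volume x cell count over the included cell
#' types (those with complete, closable budgets), reports the coverage of
#' the total cellular volume, and re-expresses totals in the requested
#' basis. Additive over disjoint cell-type sets.
#'
#' @param atlas a `leaf_atlas`.
#' @param included_cell_types character vector of cell type ids; the default
#'   takes every covered type (see [covered_cell_types()]).
#' @param basis reporting basis for the `volume` column.
#' @return list with `volumes` (data.frame compartment / volume_uL_leaf /
#'   volume in basis), `coverage` (fraction of total cellular volume
#'   represented), `included`, `basis`.
#' @export
aggregate_to_leaf <- function(atlas,
                              included_cell_types = covered_cell_types(atlas),
                              basis = "per_gram_LFW") {
  cen <- cell_census(atlas)
  missing <- setdiff(included_cell_types, covered_cell_types(atlas))
  if (length(missing))
    stop("completeness error: no closed budget available for: ",
         paste(missing, collapse = ", "))
  totals <- list()
  for (ctid in included_cell_types) {
    b <- cell_budget(atlas, ctid)
    row <- cen[cen$id == ctid, ]
    vols <- b$entries * row$single_cell_volume_pL * 1e-6 * row$count  # uL/leaf
    for (nm in names(vols))
      totals[[nm]] <- (if (is.null(totals[[nm]])) 0 else totals[[nm]]) + vols[[nm]]
  }
  vols_df <- data.frame(compartment = names(totals),
                        volume_uL_leaf = unlist(totals, use.names = FALSE),
                        stringsAsFactors = FALSE)
  f <- .basis_factor_from_leaf(basis, atlas$context)
  vols_df$volume <- vols_df$volume_uL_leaf * f
  covered <- sum(cen$volume_uL[cen$id %in% included_cell_types])
  list(volumes = vols_df, coverage = covered / sum(cen$volume_uL),
       covered_volume_uL_leaf = covered, included = included_cell_types,
       basis = basis)
}
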