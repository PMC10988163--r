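#' @title Unit registry and provenance-tracked quantities
#' @name quantity
#' @description
#' Every measured or derived number in the atlas is carried as a `quantity`:
#' a value in a canonical unit, an optional absolute uncertainty, a quality
#' flag and a provenance record. The unit vocabulary is a closed registry;
#' unknown unit symbols are rejected at construction so that unit errors
#' surface at the I/O boundary rather than deep inside a calculation.
#'
#' Internal conventions: lengths in um, areas in um2 (leaf-level areas in
#' mm2), volumes in fL (1 um3 == 1 fL, 1 pL == 1e3 fL, 1 uL == 1e9 fL),
#' masses in mg, amounts of substance in nmol.
NULL

# Closed unit registry. "category" marks non-numeric compendium entries
# (e.g. shape kinds) that are carried through I/O but never computed with.
.unit_registry <- c(
  "um", "um2", "um3", "mm", "mm2", "cm2",
  "fL", "pL", "nL", "uL",
  "mg", "g",
  "count", "dimensionless", "fraction", "percent", "days",
  "per_mm2", "per_leaf", "count_per_g",
  "uL_per_gLFW", "uL_per_leaf", "uL_per_mgchl",
  "mg_per_gLFW", "g_per_mol",
  "nmol_per_gLFW", "nmol_per_gLDW", "nmol_per_mgchl", "nmol_per_leaf",
  "umol_per_m2_leaf", "uM", "mM",
  "category"
)

# Exact scale factors to fL for the volume sub-registry.
.volume_to_fL <- c(um3 = 1, fL = 1, pL = 1e3, nL = 1e6, uL = 1e9)

#' List the closed unit registry
#' @return character vector of accepted unit symbols.
#' @export
unit_registry <- function() .unit_registry

#' Quality flags, ordered from strongest to weakest
#'
#' Three levels mirror the colour code of a curated parameter table:
#' measured under the reference growth conditions, measured under nearby
#' conditions, or assumed/extrapolated. Derived values take the weakest
#' flag among their inputs.
#' @export
quality_levels <- function() c("reference_condition", "near_condition", "assumption")

#' Combine quality flags, keeping the weakest
#' @param ... quality flag strings.
#' @return the weakest (largest-index) flag among the inputs.
#' @export
combine_quality <- function(...) {
  flags <- unlist(list(...))
  flags <- flags[!is.na(flags)]
  if (length(flags) == 0L) return("assumption")
  lv <- quality_levels()
  bad <- setdiff(flags, lv)
  if (length(bad)) stop("unknown quality flag: ", paste(bad, collapse = ", "))
  lv[max(match(flags, lv))]
}

#' Construct a provenance-tracked quantity
#'
#' @param value finite numeric value in `unit`.
#' @param unit unit symbol from [unit_registry()].
#' @param sd optional absolute uncertainty (same unit), `NA` if unknown.
#' @param quality one of [quality_levels()].
#' @param reference literature key (`firstauthor_year_PMID` convention) or
#'   `"synthetic"` for constructed stand-in values.
#' @param method free-text method label.
#' @param growth_conditions free-text growth-conditions label.
#' @return an object of class `quantity`.
#' @export
quantity <- function(value, unit, sd = NA_real_,
                     quality = "reference_condition",
                     reference = NA_character_, method = NA_character_,
                     growth_conditions = NA_character_) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("quantity value must be a single finite number")
  if (!unit %in% .unit_registry)
    stop("unknown unit: '", unit, "' (not in the closed registry)")
  if (!is.na(sd) && sd < 0) stop("sd must be >= 0")
  if (!quality %in% quality_levels())
    stop("unknown quality flag: ", quality)
  if (unit == "count" && value < 0) stop("counts must be non-negative")
  if (unit == "fraction" && (value < 0 || value > 1))
    stop("fractions must lie in [0, 1]")
  structure(
    list(value = value, unit = unit, sd = as.numeric(sd), quality = quality,
         reference = reference, method = method,
         growth_conditions = growth_conditions),
    class = "quantity"
  )
}

#' @export
print.quantity <- function(x, ...) {
  sd_txt <- if (is.na(x$sd)) "" else paste0(" ± ", format(x$sd))
  cat(format(x$value), sd_txt, " ", x$unit, " [", x$quality, "]\n", sep = "")
  invisible(x)
}

#' @export
format.quantity <- function(x, ...) {
  paste0(format(x$value, ...), " ", x$unit)
}

#' Rescale a quantity by an exact factor (uncertainty scales proportionally)
#' @param q a `quantity`.
#' @param factor scale factor.
#' @param unit unit of the result (defaults to the input unit).
#' @param quality quality of the result (defaults to the input flag).
#' @return a `quantity`.
#' @export
q_scale <- function(q, factor, unit = q$unit, quality = q$quality) {
  quantity(q$value * factor, unit, sd = if (is.na(q$sd)) NA_real_ else q$sd * abs(factor),
           quality = quality, reference = q$reference, method = q$method,
           growth_conditions = q$growth_conditions)
}

#' Convert a volume quantity between volume units exactly
#' @param q a `quantity` in a volume unit (um3, fL, pL, nL, uL).
#' @param unit target volume unit.
#' @return a `quantity` in `unit`; round trips are exact.
#' @export
q_volume_as <- function(q, unit) {
  if (!q$unit %in% names(.volume_to_fL))
    stop("not a volume unit: ", q$unit)
  if (!unit %in% names(.volume_to_fL))
    stop("not a volume unit: ", unit)
  q_scale(q, .volume_to_fL[[q$unit]] / .volume_to_fL[[unit]], unit = unit)
}

#' Convert a plain numeric volume between volume units
#' @param x numeric vector.
#' @param from,to volume unit symbols.
#' @export
volume_convert <- function(x, from, to) {
  if (!from %in% names(.volume_to_fL) || !to %in% names(.volume_to_fL))
    stop("volume_convert: units must be volume units")
  x * .volume_to_fL[[from]] / .volume_to_fL[[to]]
}
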