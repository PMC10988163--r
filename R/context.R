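#' Leaf-level context constants
#'
#' Bundles the macroscopic constants of the reference leaf that drive basis
#' conversions and leaf-level extrapolations: one-sided leaf area S (mm2),
#' maximal leaf area MS (mm2), days past full expansion D, leaf fresh
#' weight (mg), the number of leaves per gram fresh weight, the fresh
#' weight / dry weight ratio, chlorophyll content (mg per g LFW), apoplast
#' fluid volume (uL per g LFW) and whole-rosette leaf area (mm2).
#'
#' @param leaf_area one-sided leaf area S, mm2.
#' @param max_leaf_area maximal (fully expanded) leaf area MS, mm2.
#' @param days_past_full_expansion D, days (>= 0).
#' @param leaf_fresh_weight mg.
#' @param leaves_per_gram_LFW leaves per g fresh weight.
#' @param lfw_over_ldw fresh weight over dry weight, dimensionless.
#' @param chlorophyll_per_gram_LFW mg chlorophyll per g LFW.
#' @param apoplast_volume uL per g LFW.
#' @param rosette_leaf_area total rosette leaf area, mm2.
#' @return an object of class `leaf_context`.
#' @export
leaf_context <- function(leaf_area, max_leaf_area, days_past_full_expansion = 0,
                         leaf_fresh_weight, leaves_per_gram_LFW, lfw_over_ldw,
                         chlorophyll_per_gram_LFW, apoplast_volume,
                         rosette_leaf_area) {
  vals <- c(leaf_area = leaf_area, max_leaf_area = max_leaf_area,
            leaf_fresh_weight = leaf_fresh_weight,
            leaves_per_gram_LFW = leaves_per_gram_LFW,
            lfw_over_ldw = lfw_over_ldw,
            chlorophyll_per_gram_LFW = chlorophyll_per_gram_LFW,
            apoplast_volume = apoplast_volume,
            rosette_leaf_area = rosette_leaf_area)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all leaf context constants must be finite and strictly positive")
  if (days_past_full_expansion < 0) stop("days_past_full_expansion must be >= 0")
  if (days_past_full_expansion == 0 && leaf_area > max_leaf_area)
    stop("leaf_area cannot exceed max_leaf_area before full expansion")
  structure(as.list(c(vals, days_past_full_expansion = days_past_full_expansion)),
            class = "leaf_context")
}

#' Leaf developmental stage
#'
#' LDS = S/MS + D: the ratio of current to maximal leaf area, plus the
#' number of days past full expansion. A leaf at 84% expansion and not yet
#' fully expanded has LDS 0.84; each day past full expansion adds 1.
#'
#' @param ctx a [leaf_context()].
#' @return dimensionless developmental stage.
#' @export
leaf_developmental_stage <- function(ctx) {
  stopifnot(inherits(ctx, "leaf_context"))
  if (ctx$max_leaf_area <= 0) stop("max_leaf_area must be > 0")
  ctx$leaf_area / ctx$max_leaf_area + ctx$days_past_full_expansion
}

.bases <- c("per_leaf", "per_gram_LFW", "per_mg_chl")

# Multiplicative factor taking an amount per leaf to an amount per `basis`.
.basis_factor_from_leaf <- function(basis, ctx) {
  switch(basis,
    per_leaf = 1,
    per_gram_LFW = ctx$leaves_per_gram_LFW,
    per_mg_chl = ctx$leaves_per_gram_LFW / ctx$chlorophyll_per_gram_LFW,
    stop("unknown basis: ", basis)
  )
}

#' Convert an extensive quantity between reporting bases
#'
#' The three reporting bases form a group under composition: per leaf,
#' per gram of leaf fresh weight (x leaves/g LFW) and per mg chlorophyll
#' (further / mg chl per g LFW). Conversions compose and invert exactly;
#' uncertainty scales proportionally; the quality flag is unchanged
#' (the conversion factors are part of the stated context).
#'
#' @param q a `quantity` whose basis is `from`.
#' @param from,to one of `"per_leaf"`, `"per_gram_LFW"`, `"per_mg_chl"`.
#' @param ctx a [leaf_context()] supplying the conversion factors.
#' @return the rescaled `quantity`.
#' @export
convert_basis <- function(q, from, to, ctx) {
  if (!from %in% .bases) stop("unknown basis: ", from)
  if (!to %in% .bases) stop("unknown basis: ", to)
  if (from == to) return(q)
  if (is.null(ctx$leaves_per_gram_LFW) || is.null(ctx$chlorophyll_per_gram_LFW))
    stop("leaf context is missing a conversion factor")
  f <- .basis_factor_from_leaf(to, ctx) / .basis_factor_from_leaf(from, ctx)
  q_scale(q, f)
}
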