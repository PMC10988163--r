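#' @title Closed-form shape primitives
#' @name geometry
#' @description
#' Volume and surface-area formulas for the idealised shapes used to model
#' leaf cells and organelles: spheres and ellipsoids (organelles, spongy
#' mesophyll), capsules (palisade mesophyll), closed and hollow cylinders
#' (vein cells, bundle sheath), semi-tori with discoid ends (stomatal guard
#' cells) and prisms with a jigsaw shape factor (epidermal pavement cells).
#' Lengths are in um; volumes come out in um3 (== fL) and areas in um2.
NULL

.check_pos <- function(...) {
  v <- c(...)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("geometry: all dimensions must be finite and strictly positive")
  invisible(v)
}

#' Ellipsoid volume
#' @param a,b,c semi-axes, um.
#' @return volume, fL.
#' @export
ellipsoid_volume <- function(a, b, c) {
  .check_pos(a, b, c)
  4 / 3 * pi * a * b * c
}

#' Sphere volume and its inverse
#' @param r radius, um.
#' @return `sphere_volume`: volume in fL; `sphere_radius_from_volume`:
#'   radius in um. Mutually inverse to floating-point tolerance.
#' @export
sphere_volume <- function(r) {
  .check_pos(r)
  4 / 3 * pi * r^3
}

#' @rdname sphere_volume
#' @param V volume, fL.
#' @export
sphere_radius_from_volume <- function(V) {
  .check_pos(V)
  (3 * V / (4 * pi))^(1 / 3)
}

#' Sphere surface area
#' @param r radius, um.
#' @return area, um2.
#' @export
sphere_area <- function(r) {
  .check_pos(r)
  4 * pi * r^2
}

#' Capsule volume
#'
#' A capsule is a cylinder of radius `r_c` and height `h` capped by two
#' half oblate spheroids of equatorial radius `r_c` and polar radius `r_s`
#' (the two halves together make one full spheroid).
#'
#' @param r_c cylinder radius, um.
#' @param h cylinder height, um (may be 0: degenerate spheroid case).
#' @param r_s polar radius of the caps, um.
#' @return volume, fL.
#' @export
capsule_volume <- function(r_c, h, r_s) {
  .check_pos(r_c, r_s)
  if (!is.finite(h) || h < 0) stop("geometry: capsule height must be >= 0")
  pi * r_c^2 * h + 4 / 3 * pi * r_c^2 * r_s
}

#' Solve the capsule cylinder radius from a target volume
#'
#' Inverts [capsule_volume()] for `r_c` at fixed `h` and `r_s`:
#' r_c = sqrt(V / (pi (h + 4/3 r_s))).
#'
#' @param V target volume, fL.
#' @param h cylinder height, um.
#' @param r_s cap polar radius, um.
#' @return cylinder radius, um.
#' @export
solve_capsule_radius <- function(V, h, r_s) {
  .check_pos(V, r_s)
  if (!is.finite(h) || h < 0) stop("geometry: capsule height must be >= 0")
  sqrt(V / (pi * (h + 4 / 3 * r_s)))
}

#' Thomsen approximation of the ellipsoid surface area
#'
#' 4 pi ((a^p b^p + a^p c^p + b^p c^p)/3)^(1/p) with the standard exponent
#' p = 1.6075; exact in the sphere limit, with a documented worst-case
#' relative error of about 1.2% (about 1.1% for typical oblate shapes).
#'
#' @param a,b,c semi-axes, um.
#' @param p Thomsen exponent.
#' @return approximate surface area, um2.
#' @export
oblate_spheroid_area <- function(a, b, c, p = 1.6075) {
  .check_pos(a, b, c, p)
  4 * pi * ((a^p * b^p + a^p * c^p + b^p * c^p) / 3)^(1 / p)
}

#' Exact oblate spheroid surface area (eccentricity closed form)
#'
#' For an oblate spheroid with equatorial radius `a` and polar radius
#' `c` < `a`: 2 pi a^2 (1 + (1 - e^2)/e atanh(e)), e^2 = 1 - c^2/a^2.
#' Used as the independent check on the Thomsen approximation.
#'
#' @param a equatorial radius, um.
#' @param c polar radius, um (c <= a).
#' @return surface area, um2.
#' @export
oblate_spheroid_area_exact <- function(a, c) {
  .check_pos(a, c)
  if (c > a) stop("oblate form requires c <= a")
  if (isTRUE(all.equal(a, c))) return(4 * pi * a^2)
  e <- sqrt(1 - c^2 / a^2)
  2 * pi * a^2 * (1 + (1 - e^2) / e * atanh(e))
}

#' Capsule surface area
#'
#' Lateral surface of the open cylinder (2 pi r_c h) plus the surface of
#' one full oblate spheroid with equatorial radius `r_c` and polar radius
#' `r_s` (the two end caps), via the Thomsen approximation.
#'
#' @inheritParams capsule_volume
#' @return surface area, um2.
#' @export
capsule_area <- function(r_c, h, r_s) {
  .check_pos(r_c, r_s)
  if (!is.finite(h) || h < 0) stop("geometry: capsule height must be >= 0")
  2 * pi * r_c * h + oblate_spheroid_area(r_c, r_c, r_s)
}

#' Cylinder area, volume and radius from a cross-section
#'
#' Closed cylinders include the two end discs (2 pi r (l + r)); hollow
#' cylinders (cells lacking walls at their extremities) only the lateral
#' surface (2 pi r l).
#'
#' @param r radius, um.
#' @param l length, um.
#' @param closed include the two end discs?
#' @return `cylinder_area`: um2; `cylinder_volume`: fL;
#'   `radius_from_cross_section`: um.
#' @export
cylinder_area <- function(r, l, closed = TRUE) {
  .check_pos(r, l)
  if (closed) 2 * pi * r * (l + r) else 2 * pi * r * l
}

#' @rdname cylinder_area
#' @export
cylinder_volume <- function(r, l) {
  .check_pos(r, l)
  pi * r^2 * l
}

#' @rdname cylinder_area
#' @param A cross-section area, um2.
#' @export
radius_from_cross_section <- function(A) {
  .check_pos(A)
  sqrt(A / pi)
}

#' Semi-torus surface area with two discoid ends
#'
#' Half of a torus tube surface (4 pi^2 R r / 2) plus two flat discs of
#' the tube radius closing the cut: the guard-cell shape model. The tube
#' radius `r` must be smaller than the centreline radius `R`.
#'
#' @param r tube (small) radius, um.
#' @param R centreline (large) radius, um.
#' @return surface area, um2.
#' @export
semi_torus_area <- function(r, R) {
  .check_pos(r, R)
  if (r >= R) stop("semi-torus requires r < R")
  2 * pi^2 * R * r + 2 * pi * r^2
}

#' Semi-torus volume
#'
#' Half of the torus volume 2 pi^2 R r^2 (Pappus). Used for oracle checks;
#' guard-cell volumes in the atlas are measured, not derived.
#'
#' @inheritParams semi_torus_area
#' @return volume, fL.
#' @export
semi_torus_volume <- function(r, R) {
  .check_pos(r, R)
  if (r >= R) stop("semi-torus requires r < R")
  pi^2 * R * r^2
}

#' Cone correction
#'
#' A cone holds one third of the volume of its circumscribing cylinder;
#' counts or volumes computed for a cylindrical midrib are divided by 3.
#'
#' @param x count or volume (>= 0); linear, so applies to either.
#' @return x / 3.
#' @export
cone_correction <- function(x) {
  if (any(x < 0)) stop("cone_correction: input must be >= 0")
  x / 3
}

#' Pavement-cell perimeter from periclinal area and shape factor
#'
#' Epidermal pavement cells have jigsaw-puzzle outlines; their perimeter is
#' modelled as k * sqrt(A) with a dimensionless shape factor k (k = 4 is an
#' exact square; the default 14 reflects strongly lobed mature cells).
#' A literal perimeter/area quotient convention (perimeter = k * A, k in
#' 1/um) is retained for fidelity testing via `convention`.
#'
#' @param A periclinal area, um2.
#' @param k shape factor (default 14, dimensionless under the default
#'   convention).
#' @param convention `"sqrt_area"` (default) or `"literal_quotient"`.
#' @return perimeter, um.
#' @export
pavement_perimeter <- function(A, k = 14, convention = c("sqrt_area", "literal_quotient")) {
  .check_pos(A, k)
  convention <- match.arg(convention)
  switch(convention,
    sqrt_area = k * sqrt(A),
    literal_quotient = k * A
  )
}
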