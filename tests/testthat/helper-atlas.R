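# Shared fixtures and independent numeric oracles.

# The bundled reference atlas is deterministic; build it once per run.
leaf6 <- reference_leaf6_fixture()

# --- hit-or-miss Monte-Carlo volume oracles --------------------------------
# Sample a bounding box uniformly and count membership; the estimate and its
# standard error are returned so tests can assert agreement within k SE.

mc_volume <- function(inside, box_lo, box_hi, n = 1e5) {
  d <- length(box_lo)
  u <- matrix(runif(n * d), ncol = d)
  pts <- sweep(sweep(u, 2, box_hi - box_lo, "*"), 2, box_lo, "+")
  hit <- inside(pts)
  vbox <- prod(box_hi - box_lo)
  p <- mean(hit)
  list(volume = vbox * p, se = vbox * sqrt(p * (1 - p) / n))
}

mc_capsule_volume <- function(r_c, h, r_s, n = 1e5) {
  inside <- function(p) {
    x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
    rho2 <- x^2 + y^2
    in_cyl <- z >= 0 & z <= h & rho2 <= r_c^2
    in_lo <- z < 0 & rho2 / r_c^2 + (z / r_s)^2 <= 1
    in_hi <- z > h & rho2 / r_c^2 + ((z - h) / r_s)^2 <= 1
    in_cyl | in_lo | in_hi
  }
  mc_volume(inside, c(-r_c, -r_c, -r_s), c(r_c, r_c, h + r_s), n)
}

mc_sphere_volume <- function(r, n = 1e5) {
  inside <- function(p) rowSums(p^2) <= r^2
  mc_volume(inside, rep(-r, 3), rep(r, 3), n)
}

mc_semi_torus_volume <- function(r, R, n = 1e5) {
  # half torus: y >= 0 half of ((sqrt(x^2+y^2)-R)^2 + z^2 <= r^2)
  inside <- function(p) {
    x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
    y >= 0 & (sqrt(x^2 + y^2) - R)^2 + z^2 <= r^2
  }
  mc_volume(inside, c(-(R + r), 0, -r), c(R + r, R + r, r), n)
}

# --- quadrature surface oracles --------------------------------------------

# surface of revolution of x(z) about the z axis
quad_revolution_area <- function(xfun, dxfun, lo, hi) {
  stats::integrate(function(z) 2 * pi * xfun(z) * sqrt(1 + dxfun(z)^2),
                   lo, hi, rel.tol = 1e-10)$value
}

quad_oblate_spheroid_area <- function(a, c) {
  # x(z) = a sqrt(1 - z^2/c^2); integrand is singular at the poles, so
  # substitute z = c sin(t)
  f <- function(t) {
    z <- c * sin(t)
    x <- a * cos(t)
    dxdz <- -a * z / (c^2 * sqrt(pmax(1 - z^2 / c^2, 1e-300)))
    2 * pi * x * sqrt(1 + dxdz^2) * c * cos(t)
  }
  stats::integrate(f, -pi / 2, pi / 2, rel.tol = 1e-9)$value
}

quad_semi_torus_tube_area <- function(r, R, nth = 2000, nph = 2000) {
  # parametrised tube surface, theta in [0, pi): dA = r (R + r cos phi)
  phi <- seq(0, 2 * pi, length.out = nph + 1)[-1]
  sum(r * (R + r * cos(phi))) * (2 * pi / nph) * pi
}

# deterministic per-test seeds without touching the global state afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  force(code)
}
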