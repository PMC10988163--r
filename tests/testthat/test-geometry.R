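test_that("ellipsoid and sphere volumes reproduce the published organelle values", {
  # epidermal chloroplast: 2 x 2 x 0.5 um ellipsoid, prints as 8.4 fL
  expect_equal(ellipsoid_volume(2, 2, 0.5), 8.37758, tolerance = 1e-5)
  expect_equal(round(ellipsoid_volume(2, 2, 0.5), 1), 8.4)
  # bundle sheath chloroplast: r = 2.8 um sphere, prints as 92 fL
  expect_equal(ellipsoid_volume(2.8, 2.8, 2.8), 91.9523, tolerance = 1e-5)
  # guard cell chloroplast: 4-um-diameter sphere, prints as 33.5 fL
  expect_equal(sphere_volume(2), 33.5103, tolerance = 1e-5)
  # sphere limit of the ellipsoid
  expect_equal(ellipsoid_volume(1, 1, 1), sphere_volume(1))
  expect_error(ellipsoid_volume(-1, 1, 1), "positive")
})

test_that("sphere radius/volume are mutually inverse and agree with Monte Carlo", {
  for (r in c(0.5, 2, 24.3))
    expect_equal(sphere_radius_from_volume(sphere_volume(r)), r)
  # spongy mesophyll cell: 60 pL sphere has r = 24.3 um (frozen from the
  # closed form, cross-checked by hit-or-miss MC below)
  expect_equal(sphere_radius_from_volume(60e3), 24.2851, tolerance = 1e-4)
  mc <- with_seed(11, mc_sphere_volume(24.2851, n = 2e5))
  expect_lt(abs(mc$volume - 60e3), 3 * mc$se)
  expect_error(sphere_radius_from_volume(0), "positive")
})

test_that("capsule volume matches the Monte-Carlo oracle and degenerates to a sphere", {
  # palisade cell: r_c 23.7, h 50, r_s 5 -> ~100 pL
  v <- capsule_volume(23.7, 50, 5)
  expect_equal(v / 1e3, 100, tolerance = 2e-4)  # pL, prints as ~100 pL
  mc <- with_seed(12, mc_capsule_volume(23.7, 50, 5, n = 2e5))
  expect_lt(abs(mc$volume - v), 3 * mc$se)
  # degenerate capsule (h = 0, r_s = r_c) is a sphere
  expect_equal(capsule_volume(3, 0, 3), sphere_volume(3))
  # random triples against MC
  with_seed(13, {
    for (i in 1:3) {
      p <- runif(3, 1, 30)
      mc <- mc_capsule_volume(p[1], p[2], p[3], n = 1e5)
      expect_lt(abs(mc$volume - capsule_volume(p[1], p[2], p[3])), 4 * mc$se)
    }
  })
})

test_that("solve_capsule_radius inverts capsule_volume", {
  # published palisade model: 100 pL, h = 50 um, r_s = 5 um -> r_c = 23.7 um
  expect_equal(solve_capsule_radius(100e3, 50, 5), 23.7, tolerance = 1e-3)
  # sphere case: h -> 0, r_s = r recovers r
  r <- 4.2
  expect_equal(solve_capsule_radius(sphere_volume(r), 0, r), r)
  with_seed(14, {
    for (i in 1:100) {
      h <- runif(1, 0, 80); r_s <- runif(1, 0.5, 20); V <- runif(1, 1e2, 1e6)
      r_c <- solve_capsule_radius(V, h, r_s)
      expect_equal(capsule_volume(r_c, h, r_s), V, tolerance = 1e-12)
    }
  })
})

test_that("Thomsen spheroid area is exact for spheres and within 1.2% of the closed form", {
  for (r in c(1, 5, 23.7))
    expect_equal(oblate_spheroid_area(r, r, r), 4 * pi * r^2, tolerance = 1e-12)
  # palisade end caps: strongly oblate 23.7 x 23.7 x 5
  approx <- oblate_spheroid_area(23.7, 23.7, 5)
  exact <- oblate_spheroid_area_exact(23.7, 5)
  expect_lt(abs(approx - exact) / exact, 0.012)
  # the exact closed form itself agrees with quadrature
  expect_equal(exact, quad_oblate_spheroid_area(23.7, 5), tolerance = 1e-7)
  # monotone in each axis
  expect_gt(oblate_spheroid_area(24, 23.7, 5), approx)
  expect_gt(oblate_spheroid_area(23.7, 23.7, 6), approx)
})

test_that("capsule area = open cylinder + one full spheroid", {
  a <- capsule_area(23.7, 50, 5)
  expect_equal(a, 2 * pi * 23.7 * 50 + oblate_spheroid_area(23.7, 23.7, 5))
  # quadrature oracle: lateral surface exact + exact spheroid, within the
  # Thomsen error bound
  oracle <- 2 * pi * 23.7 * 50 + quad_oblate_spheroid_area(23.7, 5)
  expect_lt(abs(a - oracle) / oracle, 0.012)
  # r_s = r_c: cylinder side + sphere area
  expect_equal(capsule_area(3, 10, 3), 2 * pi * 3 * 10 + sphere_area(3),
               tolerance = 1e-12)
})

test_that("cylinder primitives and cross-section inversion", {
  # bundle sheath cell: closed cylinder r 8.2, l 48.7 -> 2931 um2
  expect_equal(cylinder_area(8.2, 48.7, closed = TRUE), 2 * pi * 8.2 * (48.7 + 8.2))
  expect_equal(cylinder_area(8.2, 48.7, closed = TRUE), 2931.7, tolerance = 1e-4)
  expect_equal(cylinder_area(3, 7, closed = TRUE) - cylinder_area(3, 7, closed = FALSE),
               2 * pi * 9)
  expect_equal(radius_from_cross_section(pi * 8.2^2), 8.2)
  expect_equal(cylinder_volume(2, 10), pi * 4 * 10)
})

test_that("semi-torus area agrees with the surface-integral oracle", {
  a <- semi_torus_area(3, 7.5)
  # guard cell model: half tube + two discs
  expect_equal(a, 2 * pi^2 * 7.5 * 3 + 2 * pi * 9)
  expect_equal(round(a, 1), 500.7)
  tube <- quad_semi_torus_tube_area(3, 7.5)
  expect_equal(a - 2 * pi * 9, tube, tolerance = 1e-6)
  # volume against MC (Pappus)
  mc <- with_seed(15, mc_semi_torus_volume(3, 7.5, n = 2e5))
  expect_lt(abs(mc$volume - semi_torus_volume(3, 7.5)), 3 * mc$se)
  expect_error(semi_torus_area(8, 7.5), "r < R")
})

test_that("cone correction is division by three, linear, and zero-preserving", {
  expect_equal(cone_correction(300), 100)
  expect_equal(cone_correction(0), 0)
  expect_equal(cone_correction(3 * 17.3), 17.3)
})

test_that("pavement perimeter conventions", {
  # k = 4 with the sqrt convention gives the exact square perimeter
  expect_equal(pavement_perimeter(25, k = 4), 20)
  expect_equal(pavement_perimeter(2000, k = 14), 14 * sqrt(2000))
  expect_equal(round(pavement_perimeter(2000, k = 14)), 626)
  # scales as sqrt(A)
  expect_equal(pavement_perimeter(4 * 2000, k = 14), 2 * pavement_perimeter(2000, k = 14))
  # literal quotient retained as an explicit option
  expect_equal(pavement_perimeter(10, k = 2, convention = "literal_quotient"), 20)
})

test_that("primitives are homogeneous under uniform scaling", {
  with_seed(16, {
    for (i in 1:20) {
      s <- runif(1, 0.3, 4)
      p <- runif(3, 1, 20)
      expect_equal(capsule_volume(s * p[1], s * p[2], s * p[3]),
                   s^3 * capsule_volume(p[1], p[2], p[3]))
      expect_equal(capsule_area(s * p[1], s * p[2], s * p[3]),
                   s^2 * capsule_area(p[1], p[2], p[3]), tolerance = 1e-12)
      expect_equal(oblate_spheroid_area(s * p[1], s * p[1], s * p[3]),
                   s^2 * oblate_spheroid_area(p[1], p[1], p[3]), tolerance = 1e-12)
      r <- min(p[1], 0.9 * p[2])
      expect_equal(semi_torus_area(s * r, s * p[2]),
                   s^2 * semi_torus_area(r, p[2]), tolerance = 1e-12)
    }
  })
})
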